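# Labelled synthetic C-alpha structures: ideal helices, strands, assembled
# sheets, self-avoiding coils and mixed topologies. These generators stand in
# for a curated experimental corpus: they produce the geometric signal the
# classifier must separate (tight right-handed helical turns, extended
# zigzags with cross-strand stacking, irregular expanded coils) with exact
# labels and no chain breaks.

#' Ideal alpha-helix trace
#'
#' Places C-alpha atoms on a regular helix using textbook parameters
#' (1.5 A rise, 2.3 A radius, 100 degrees per residue), giving a
#' consecutive C-alpha distance of ~3.8 A and the characteristic
#' ~5.05 A i,i+3 contact.
#'
#' @param n Number of residues.
#' @param rise Rise per residue in Angstrom.
#' @param radius Helix radius in Angstrom.
#' @param twist Turn per residue in degrees.
#' @param handedness `+1` for the natural right-handed helix, `-1` for its
#'   mirror.
#' @return List with `trace` (tibble) and `labels` (all `"H"`).
#' @export
make_helix <- function(n, rise = 1.5, radius = 2.3, twist = 100, handedness = 1) {
  i <- seq_len(n) - 1
  th <- i * twist * pi / 180 * sign(handedness)
  trace <- ca_trace(radius * cos(th), radius * sin(th), i * rise)
  list(trace = trace, labels = strrep("H", n))
}

#' Ideal beta-strand trace
#'
#' A planar zigzag: axial step 3.3 A with lateral alternation chosen so the
#' consecutive C-alpha distance is exactly 3.8 A. An optional slow twist
#' about the strand axis mimics the natural strand twist.
#'
#' @param n Number of residues.
#' @param axial_step Advance along the strand axis per residue (A).
#' @param lateral Half-amplitude of the zigzag (A).
#' @param twist Rotation about the strand axis per residue, degrees.
#' @return List with `trace` and `labels` (all `"E"`).
#' @export
make_strand <- function(n, axial_step = 3.3, lateral = 0.942, twist = 0) {
  i <- seq_len(n) - 1
  y0 <- ifelse(i %% 2 == 0, lateral, -lateral)
  ph <- i * twist * pi / 180
  trace <- ca_trace(i * axial_step, y0 * cos(ph), y0 * sin(ph))
  list(trace = trace, labels = strrep("E", n))
}

# Equal-chord circular-arc connector: m intermediate points between A and B,
# bulging towards `bulge` (unit-izable vector not parallel to B-A), with a
# per-step chord close to `step`.
arc_connector <- function(A, B, m, bulge, step = 3.5) {
  k <- m + 1L
  d <- sqrt(sum((B - A)^2))
  if (d >= step * k) abort("loop too short to span the gap; increase loop_len")
  ratio <- d / step
  f <- function(phi) sin(phi / 2) - ratio * sin(phi / (2 * k))
  phi <- stats::uniroot(f, c(1e-8, 2 * pi - 1e-8), tol = 1e-12)$root
  R <- d / (2 * sin(phi / 2))
  e_u <- (B - A) / d
  w <- bulge - sum(bulge * e_u) * e_u
  wl <- sqrt(sum(w^2))
  if (wl < 1e-9) abort("bulge direction is parallel to the gap")
  e_w <- w / wl
  M <- (A + B) / 2
  C <- M - R * cos(phi / 2) * e_w
  e1 <- (A - C) / R
  e2 <- cos(phi / 2) * e_u + sin(phi / 2) * e_w
  t_j <- seq_len(m) * phi / k
  t(vapply(t_j, function(t) C + R * (cos(t) * e1 + sin(t) * e2), numeric(3)))
}

#' Multi-strand beta sheet with connecting loops
#'
#' Lays `n_strands` ideal strands side by side at the given inter-strand
#' spacing (4.8 A is the cross-strand C-alpha spacing of real sheets) and
#' joins consecutive strands with circular-arc coil loops, yielding one
#' contiguous chain with labels E on strands and C on loops.
#'
#' Antiparallel sheets (the default) alternate strand direction so short
#' hairpin loops suffice; parallel sheets need `loop_len` large enough for
#' the crossover (roughly `strand_len` residues).
#'
#' @param n_strands Number of strands (>= 2).
#' @param strand_len Residues per strand.
#' @param spacing Inter-strand spacing in Angstrom.
#' @param antiparallel Alternate strand directions.
#' @param loop_len Residues per connecting loop.
#' @return List with `trace` and `labels`.
#' @export
make_sheet <- function(n_strands, strand_len, spacing = 4.8,
                       antiparallel = TRUE, loop_len = 4L) {
  if (n_strands < 2L) abort("a sheet needs at least 2 strands")
  base <- trace_coords(make_strand(strand_len)$trace)
  span <- (strand_len - 1) * 3.3
  coords <- NULL
  labels <- character(0)
  for (s in seq_len(n_strands) - 1L) {
    st <- base
    if (antiparallel && s %% 2L == 1L) st[, 1] <- span - st[, 1]
    st[, 3] <- st[, 3] + s * spacing
    if (s > 0L) {
      A <- coords[nrow(coords), ]
      B <- st[1, ]
      end_x <- if (A[1] > span / 2) 1 else -1
      bulge <- if (antiparallel) c(end_x, 0, 0) else c(0, 1, 0)
      loop <- arc_connector(A, B, loop_len, bulge)
      coords <- rbind(coords, loop)
      labels <- c(labels, rep("C", loop_len))
    }
    coords <- rbind(coords, st)
    labels <- c(labels, rep("E", strand_len))
  }
  list(trace = ca_trace(coords[, 1], coords[, 2], coords[, 3]),
       labels = ss_collapse(labels))
}

#' Self-avoiding random coil
#'
#' A seeded random walk with 3.8 A steps whose pseudo-bond angles are drawn
#' uniformly from \[60, 180\] degrees, resampling any step that brings two
#' non-adjacent residues within 4.0 A. The resulting conformations are
#' expanded and irregular — few spatial neighbours, no persistent i,i+3
#' geometry — which is exactly what distinguishes loops from regular
#' secondary structure.
#'
#' @param n Number of residues.
#' @param seed Integer seed; fixed seed gives an identical trace.
#' @param step Bond length in Angstrom.
#' @return List with `trace` and `labels` (all `"C"`).
#' @export
make_coil <- function(n, seed = 1L, step = 3.8) {
  with_seed(seed, {
    for (restart in 1:30) {
      co <- matrix(NA_real_, n, 3)
      co[1, ] <- c(0, 0, 0)
      if (n >= 2L) co[2, ] <- c(step, 0, 0)
      ok <- TRUE
      i <- 3L
      while (i <= n) {
        u <- (co[i - 1L, ] - co[i - 2L, ]) / step
        placed <- FALSE
        for (try in 1:60) {
          theta <- runif(1, 60, 180) * pi / 180   # pseudo-bond angle
          alpha <- pi - theta                      # direction change
          ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
          a <- cross3(u, ref); a <- a / sqrt(sum(a^2))
          b <- cross3(u, a)
          psi <- runif(1, 0, 2 * pi)
          dir <- cos(alpha) * u + sin(alpha) * (cos(psi) * a + sin(psi) * b)
          p <- co[i - 1L, ] + step * dir
          prev <- co[1:(i - 2L), , drop = FALSE]
          if (all(rowSums(sweep(prev, 2, p)^2) >= 16)) {
            co[i, ] <- p; placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
        i <- i + 1L
      }
      if (ok) {
        return(list(trace = ca_trace(co[, 1], co[, 2], co[, 3]),
                    labels = strrep("C", n)))
      }
    }
    abort("coil generation failed; try another seed")
  })
}

#' Parse a topology string
#'
#' @param spec E.g. `"H10-C5-E8"`: helix of 10, coil of 5, strand of 8.
#' @return Tibble with columns `kind` and `length`.
#' @export
parse_topology <- function(spec) {
  parts <- strsplit(spec, "-", fixed = TRUE)[[1]]
  if (!length(parts) || !all(grepl("^[HEC][0-9]+$", parts))) {
    abort("invalid topology spec; expected e.g. 'H10-C5-E8'")
  }
  tibble(kind = substr(parts, 1, 1),
         length = as.integer(substring(parts, 2)))
}

#' Assemble a mixed-topology chain
#'
#' Concatenates segment generators (helix, strand, coil) into one contiguous
#' chain: each new segment is rigidly rotated (proper rotations only, so
#' chirality is preserved) and attached 3.8 A beyond the previous segment,
#' re-drawing the placement until no two non-adjacent residues come within
#' 3.5 A. Deterministic for a fixed seed.
#'
#' @param segments A topology string (see [parse_topology()]) or a tibble
#'   with columns `kind` and `length`.
#' @param seed Integer seed.
#' @return List with `trace` and `labels`.
#' @export
make_protein <- function(segments, seed = 1L) {
  if (is.character(segments)) segments <- parse_topology(segments)
  if (!all(segments$kind %in% ss_alphabet) || any(segments$length < 1L)) {
    abort("invalid topology spec")
  }
  with_seed(seed, {
    coil_seeds <- sample.int(.Machine$integer.max - 1L, nrow(segments))
    coords <- NULL
    labels <- character(0)
    for (g in seq_len(nrow(segments))) {
      kind <- segments$kind[g]
      len <- segments$length[g]
      seg <- switch(kind,
        H = make_helix(len),
        E = make_strand(len),
        C = make_coil(len, seed = coil_seeds[g])
      )
      loc <- trace_coords(seg$trace)
      loc <- sweep(loc, 2, loc[1, ])
      if (is.null(coords)) {
        coords <- loc
      } else {
        placed <- FALSE
        for (try in 1:200) {
          Q <- random_rotation()
          u <- random_unit()
          anchor <- coords[nrow(coords), ] + 3.8 * u
          cand <- sweep(loc %*% t(Q), 2, anchor, "+")
          old_chk <- coords[seq_len(max(0, nrow(coords) - 1L)), , drop = FALSE]
          dmin_old <- if (nrow(old_chk)) min_cross_dist(cand, old_chk) else Inf
          d_junction2 <- if (nrow(cand) >= 2L)
            sqrt(sum((cand[2, ] - coords[nrow(coords), ])^2)) else Inf
          if (dmin_old >= 3.5 && d_junction2 >= 3.5) { placed <- TRUE; break }
        }
        if (!placed) abort("assembly clash: could not place segment; try another seed")
        coords <- rbind(coords, cand)
      }
      labels <- c(labels, rep(kind, len))
    }
    list(trace = ca_trace(coords[, 1], coords[, 2], coords[, 3]),
         labels = ss_collapse(labels))
  })
}

random_unit <- function() {
  repeat {
    v <- rnorm(3)
    l <- sqrt(sum(v^2))
    if (l > 1e-6) return(v / l)
  }
}

# Uniform proper rotation via QR of a Gaussian matrix, det forced to +1.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

min_cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))
  sqrt(max(0, min(d2)))
}

#' Mirror a trace through the xy-plane
#'
#' An improper isometry: all unsigned features are preserved while every
#' chirality-signed i,i+3 distance changes sign.
#'
#' @param trace A trace tibble.
#' @return The reflected trace.
#' @export
mirror_trace <- function(trace) {
  validate_trace(trace)
  trace$z <- -trace$z
  trace
}

#' Generate a labelled corpus of synthetic chains
#'
#' Draws a mixture of topologies — pure helices, helix-coil assemblies,
#' two- and three-stranded antiparallel sheets, isolated strand assemblies
#' and random coils — with seeds derived from one master seed, so the corpus
#' is fully reproducible.
#'
#' @param n_chains Number of chains.
#' @param seed Master seed.
#' @return Tibble with columns `id`, `kind`, `trace` (list), `labels`.
#' @export
make_structure_set <- function(n_chains = 600L, seed = 1L) {
  kinds <- c("helix", "helix_coil", "sheet2", "sheet3", "strand_mix", "coil")
  weights <- c(0.17, 0.18, 0.18, 0.12, 0.15, 0.20)
  with_seed(seed, {
    kind <- sample(kinds, n_chains, replace = TRUE, prob = weights)
    seeds <- sample.int(.Machine$integer.max - 1L, n_chains)
  })
  rows <- purrr::map(seq_len(n_chains), function(i) {
    s <- seeds[i]
    obj <- with_seed(s, switch(kind[i],
      helix = make_protein(tibble(kind = c("C", "H", "C"),
                                  length = c(2L, sample(12:22, 1), 2L)),
                           seed = s),
      helix_coil = make_protein(tibble(kind = c("H", "C", "H"),
                                       length = c(sample(8:14, 1), sample(4:7, 1),
                                                  sample(8:14, 1))),
                                seed = s),
      sheet2 = make_sheet(2L, sample(6:10, 1)),
      sheet3 = make_sheet(3L, sample(6:9, 1)),
      strand_mix = make_protein(tibble(kind = c("E", "C", "E"),
                                       length = c(sample(6:10, 1), sample(4:7, 1),
                                                  sample(6:10, 1))),
                                seed = s),
      coil = make_coil(sample(18:36, 1), seed = s)
    ))
    tibble(id = sprintf("syn%04d", i), kind = kind[i],
           trace = list(obj$trace), labels = obj$labels)
  })
  bind_rows(rows)
}

#' Write a synthetic corpus as PDB and label files
#'
#' One CA-only PDB file and one FASTA-like label file per chain, named by
#' the chain id, so synthetic data exercises the same I/O path as deposited
#' structures.
#'
#' @param set Tibble from [make_structure_set()] (or any tibble with `id`,
#'   `trace`, `labels`).
#' @param pdb_dir,label_dir Output directories (created if needed).
#' @return Invisibly, a tibble of written paths.
#' @export
write_structure_files <- function(set, pdb_dir, label_dir = pdb_dir) {
  dir.create(pdb_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(label_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::pmap(set[, c("id", "trace", "labels")], function(id, trace, labels) {
    pdb <- file.path(pdb_dir, paste0(id, ".pdb"))
    lab <- file.path(label_dir, paste0(id, ".ssfa"))
    write_ca_pdb(trace, pdb)
    write_labels(stats::setNames(labels, id), lab)
    tibble(id = id, pdb = pdb, labels = lab)
  })
  invisible(bind_rows(paths))
}
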