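# Rotation- and translation-invariant geometric features computed over a
# sliding window of C-alpha positions.

#' Window/feature configuration
#'
#' Fixes the fragment length N and the feature blocks used by both training
#' and inference. The `local` block (chirality-signed chain distances) is the
#' backbone of the representation and is always present; `neighbors` and
#' `hbonds` are nested on top of it, mirroring the feature-set variants the
#' classifier is compared across.
#'
#' @param N Odd fragment length, one of 5, 7, 9, 11, 13.
#' @param features Subset of `c("local", "neighbors", "hbonds")`.
#' @param cutoffs Ascending neighbour-count distance cutoffs in Angstrom.
#' @param min_seq_sep Minimum sequence separation |i-j| for a neighbour to
#'   count; 3 excludes atoms within two residues along the chain.
#'
#' @return A `window_config` list.
#' @export
window_config <- function(N = 11L, features = c("local", "neighbors", "hbonds"),
                          cutoffs = c(4, 4.5, 5, 6), min_seq_sep = 3L) {
  N <- as.integer(N)
  if (!(N %in% c(5L, 7L, 9L, 11L, 13L))) abort("N must be one of 5, 7, 9, 11, 13")
  features <- match.arg(features, c("local", "neighbors", "hbonds"), several.ok = TRUE)
  if (!"local" %in% features) abort("the 'local' feature block is always required")
  if (is.unsorted(cutoffs, strictly = TRUE)) abort("cutoffs must be strictly ascending")
  structure(
    list(N = N, features = features, cutoffs = as.numeric(cutoffs),
         min_seq_sep = as.integer(min_seq_sep)),
    class = "window_config"
  )
}

#' Feature vector length implied by a window configuration
#'
#' The local block contributes (N-2) + (N-3) + (N-4) = 3N-9 distances, the
#' neighbour block 4N counts and the hydrogen-bond block N counts.
#'
#' @param cfg A [window_config()].
#' @return Integer length.
#' @export
feature_length <- function(cfg) {
  n <- 3L * cfg$N - 9L
  if ("neighbors" %in% cfg$features) n <- n + length(cfg$cutoffs) * cfg$N
  if ("hbonds" %in% cfg$features) n <- n + cfg$N
  n
}

feature_names <- function(cfg) {
  N <- cfg$N
  nm <- c(
    sprintf("r2_%d", 0:(N - 3)),
    sprintf("r3s_%d", 0:(N - 4)),
    sprintf("r4_%d", 0:(N - 5))
  )
  if ("neighbors" %in% cfg$features) {
    nm <- c(nm, as.vector(t(outer(0:(N - 1), cfg$cutoffs,
                                  function(i, co) sprintf("nb_%d_%g", i, co)))))
  }
  if ("hbonds" %in% cfg$features) nm <- c(nm, sprintf("hb_%d", 0:(N - 1)))
  nm
}

#' Chirality-signed i,i+3 distance
#'
#' Magnitude is the distance |p3 - p0|; the sign is that of the triple
#' product of the three consecutive pseudo-bond vectors, which separates
#' right-handed from left-handed local conformations (a mirror image flips
#' the sign and nothing else). A planar quadruplet (triple product exactly 0)
#' is signed +1.
#'
#' @param p0,p1,p2,p3 Numeric 3-vectors.
#' @return Signed distance in Angstrom.
#' @export
signed_r3 <- function(p0, p1, p2, p3) {
  v0 <- p1 - p0; v1 <- p2 - p1; v2 <- p3 - p2
  tp <- sum(cross3(v0, v1) * v2)
  # deadband: an exactly planar quadruplet evaluates to rounding noise after
  # a rigid motion; clamp it to the +1 tie-break so features stay invariant
  if (abs(tp) < 1e-7) tp <- 0
  s <- if (tp < 0) -1 else 1
  s * sqrt(sum((p3 - p0)^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Local distance block of one window
#'
#' Computes all r(i,i+2), signed r(i,i+3) and r(i,i+4) distances within an
#' N-residue window: N-2, N-3 and N-4 values respectively.
#'
#' @param window_coords N x 3 coordinate matrix, N >= 5.
#' @return List with numeric vectors `r2`, `r3s`, `r4`.
#' @export
local_distances <- function(window_coords) {
  co <- as.matrix(window_coords)
  N <- nrow(co)
  if (N < 5L) abort("window too short: need at least 5 residues")
  gap_dist <- function(k) {
    i <- 1:(N - k)
    sqrt(rowSums((co[i + k, , drop = FALSE] - co[i, , drop = FALSE])^2))
  }
  r3s <- vapply(1:(N - 3), function(i) {
    signed_r3(co[i, ], co[i + 1, ], co[i + 2, ], co[i + 3, ])
  }, numeric(1))
  list(r2 = gap_dist(2L), r3s = r3s, r4 = gap_dist(4L))
}

#' Spatial neighbour counts per residue
#'
#' For every residue, counts C-alpha atoms of the same trace within each
#' cutoff, excluding atoms closer than `min_seq_sep` along the sequence.
#' Densely packed (core) residues score high, solvent-exposed loops low.
#'
#' @param trace A trace tibble.
#' @param cutoffs Ascending distance cutoffs in Angstrom.
#' @param min_seq_sep Minimum |i-j| along the chain for a pair to count.
#' @return Integer matrix, one row per residue, one column per cutoff.
#' @export
neighbor_counts <- function(trace, cutoffs = c(4, 4.5, 5, 6), min_seq_sep = 3L) {
  validate_trace(trace)
  co <- trace_coords(trace)
  n <- nrow(co)
  D <- as.matrix(dist(co))
  idx <- seq_len(n)
  sep <- abs(outer(idx, idx, "-"))
  eligible <- sep >= min_seq_sep
  out <- vapply(cutoffs, function(co_cut) {
    as.integer(rowSums(eligible & D <= co_cut))
  }, integer(n))
  if (n == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- sprintf("%g", cutoffs)
  out
}

#' Assemble per-window feature vectors for a whole chain
#'
#' Slides an N-residue window along the trace (step 1) and emits one feature
#' row per window whose span contains no chain break. Each row describes the
#' window's middle residue, reported in the `center` column (1-based index
#' into the trace). Block order is fixed: r2, signed r3, r4, then neighbour
#' counts residue-major/cutoff-ascending, then hydrogen-bond counts.
#'
#' @param trace A trace tibble.
#' @param cfg A [window_config()].
#' @param hbonds Optional per-residue hydrogen-bond counts aligned to the
#'   trace; computed with `criteria` when omitted and required.
#' @param criteria [hbond_criteria()] used when `hbonds` is computed here.
#' @param breaks Chain-break indices; computed with defaults when `NULL`.
#'
#' @return A tibble with a `center` column followed by one named feature
#'   column per dimension; zero rows (with a warning) when the trace is
#'   shorter than N.
#' @export
featurize_chain <- function(trace, cfg = window_config(), hbonds = NULL,
                            criteria = hbond_criteria(), breaks = NULL) {
  validate_trace(trace)
  N <- cfg$N
  n <- nrow(trace)
  nms <- feature_names(cfg)
  if (n < N) {
    warn("trace shorter than the window; no features computed")
    empty <- matrix(numeric(0), 0, length(nms), dimnames = list(NULL, nms))
    return(tibble(center = integer(0)) %>% dplyr::bind_cols(as_tibble(empty)))
  }
  co <- trace_coords(trace)
  if (is.null(breaks)) breaks <- detect_chain_breaks(trace)
  use_nb <- "neighbors" %in% cfg$features
  use_hb <- "hbonds" %in% cfg$features
  nb <- if (use_nb) neighbor_counts(trace, cfg$cutoffs, cfg$min_seq_sep) else NULL
  if (use_hb && is.null(hbonds)) hbonds <- hbond_counts(trace, criteria)
  if (use_hb && length(hbonds) != n) abort("hbond counts do not align with the trace")

  starts <- 1:(n - N + 1)
  # a window starting at s spans bonds s .. s+N-2
  ok <- vapply(starts, function(s) !any(breaks >= s & breaks <= s + N - 2L), logical(1))
  starts <- starts[ok]
  half <- (N - 1L) %/% 2L
  rows <- lapply(starts, function(s) {
    w <- s:(s + N - 1L)
    loc <- local_distances(co[w, , drop = FALSE])
    v <- c(loc$r2, loc$r3s, loc$r4)
    if (use_nb) v <- c(v, as.vector(t(nb[w, , drop = FALSE])))
    if (use_hb) v <- c(v, hbonds[w])
    v
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- nms
  dplyr::bind_cols(tibble(center = starts + half), as_tibble(mat))
}

#' Export a feature table as TSV lines
#'
#' @param features Tibble from [featurize_chain()].
#' @param path Optional file; when `NULL` the lines are returned.
#' @return TSV lines, invisibly when written.
#' @export
write_feature_tsv <- function(features, path = NULL) {
  header <- paste(names(features), collapse = "\t")
  rows <- apply(features, 1, function(r) paste(format(r, trim = TRUE, digits = 10), collapse = "\t"))
  lines <- c(header, rows)
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
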