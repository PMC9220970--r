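# Coarse-grained C-alpha-only hydrogen bonds.
#
# A backbone hydrogen bond cannot be observed directly in a C-alpha-only
# model, but the regular geometry of paired strands constrains where the
# C-alpha atoms sit. A triangle is built on every three consecutive C-alpha
# atoms; two triangles that are roughly parallel, roughly stacked along
# their normals and at cross-strand distance are scored as one
# coarse-grained hydrogen bond. Each triangle has two sides (the +/- normal
# directions), and each side can host at most one bond, so per-residue
# counts are always 0, 1 or 2.

#' Geometric criteria for coarse-grained hydrogen bonds
#'
#' @param dist_min,dist_max Allowed triangle-centroid distance window in
#'   Angstrom. The default window brackets the ~4.8 A cross-strand
#'   C-alpha spacing of paired beta strands.
#' @param normal_cos Minimum |cos| between the two triangle normals
#'   (parallelism gate; unsigned so parallel and antiparallel sheets both
#'   qualify).
#' @param disp_cos Minimum |cos| between the centroid displacement and each
#'   triangle normal (stacking gate).
#' @param min_seq_sep Minimum sequence separation between the central
#'   residues of the two triangles.
#'
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(dist_min = 4.0, dist_max = 6.0,
                           normal_cos = 0.7, disp_cos = 0.5, min_seq_sep = 3L) {
  if (dist_min >= dist_max) abort("dist_min must be below dist_max")
  if (normal_cos <= 0 || normal_cos > 1 || disp_cos <= 0 || disp_cos > 1) {
    abort("cosine thresholds must lie in (0, 1]")
  }
  if (min_seq_sep < 3L) abort("min_seq_sep must be at least 3")
  structure(
    list(dist_min = dist_min, dist_max = dist_max, normal_cos = normal_cos,
         disp_cos = disp_cos, min_seq_sep = as.integer(min_seq_sep)),
    class = "hbond_criteria"
  )
}

#' Residue triangle (centroid and normal)
#'
#' @param p_prev,p,p_next Coordinates of three consecutive C-alpha atoms.
#' @param index Residue index of the central atom.
#' @return List with `residue_index`, `centroid`, unit `normal`, and
#'   `degenerate` flag (collinear points have no normal and never bond).
#' @export
residue_triangle <- function(p_prev, p, p_next, index = NA_integer_) {
  nrm <- cross3(p - p_prev, p_next - p)
  len <- sqrt(sum(nrm^2))
  if (len < 1e-9) {
    return(list(residue_index = index, centroid = (p_prev + p + p_next) / 3,
                normal = c(NA_real_, NA_real_, NA_real_), degenerate = TRUE))
  }
  list(residue_index = index, centroid = (p_prev + p + p_next) / 3,
       normal = nrm / len, degenerate = FALSE)
}

#' Test one triangle pair against the bond criteria
#'
#' The pair bonds when the centroid distance falls in the allowed window,
#' the normals are near-parallel, and the displacement is near-normal to
#' both triangles (the test is symmetric in a and b so bonding is a
#' property of the pair). The returned side is the sign of the projection
#' of the displacement onto `a`'s normal.
#'
#' @param a,b [residue_triangle()] values.
#' @param criteria [hbond_criteria()].
#' @return `0` (no bond) or `+1`/`-1`: the side of `a` facing `b`.
#' @export
triangle_pair_bonded <- function(a, b, criteria = hbond_criteria()) {
  if (abs(a$residue_index - b$residue_index) < criteria$min_seq_sep) return(0)
  if (isTRUE(a$degenerate) || isTRUE(b$degenerate)) return(0)
  d <- b$centroid - a$centroid
  dist <- sqrt(sum(d^2))
  if (dist < criteria$dist_min || dist > criteria$dist_max) return(0)
  if (abs(sum(a$normal * b$normal)) < criteria$normal_cos) return(0)
  dhat <- d / dist
  pa <- sum(dhat * a$normal)
  pb <- sum(dhat * b$normal)
  if (min(abs(pa), abs(pb)) < criteria$disp_cos) return(0)
  if (pa >= 0) 1 else -1
}

#' Per-residue coarse-grained hydrogen-bond counts
#'
#' Builds a triangle for every residue with both neighbours present,
#' evaluates all eligible triangle pairs, keeps at most one bond per
#' triangle side (nearest centroid wins; ties go to the lower partner
#' index), and reports the number of occupied sides: 0, 1 or 2. Terminal
#' residues carry no triangle and always score 0.
#'
#' @param trace A trace tibble with at least 3 residues.
#' @param criteria [hbond_criteria()].
#' @return Integer vector of per-residue counts in \{0, 1, 2\}.
#' @export
hbond_counts <- function(trace, criteria = hbond_criteria()) {
  validate_trace(trace)
  n <- nrow(trace)
  counts <- integer(n)
  if (n < 3L) return(counts)
  co <- trace_coords(trace)
  mid <- 2:(n - 1)
  # vectorized triangle construction
  v1 <- co[mid, , drop = FALSE] - co[mid - 1L, , drop = FALSE]
  v2 <- co[mid + 1L, , drop = FALSE] - co[mid, , drop = FALSE]
  nrm <- cbind(v1[, 2] * v2[, 3] - v1[, 3] * v2[, 2],
               v1[, 3] * v2[, 1] - v1[, 1] * v2[, 3],
               v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1])
  nlen <- sqrt(rowSums(nrm^2))
  degen <- nlen < 1e-9
  nrm <- nrm / ifelse(nlen < 1e-9, 1, nlen)
  cent <- (co[mid - 1L, , drop = FALSE] + co[mid, , drop = FALSE] +
             co[mid + 1L, , drop = FALSE]) / 3
  m <- length(mid)
  D <- as.matrix(dist(cent))
  sep <- abs(outer(mid, mid, "-"))
  cand <- which(
    upper.tri(D) & D >= criteria$dist_min & D <= criteria$dist_max &
      sep >= criteria$min_seq_sep & !outer(degen, degen, "|"),
    arr.ind = TRUE
  )
  # best (nearest) partner per triangle side; row = triangle, col 1 = side +1
  best_d <- matrix(Inf, m, 2)
  best_p <- matrix(NA_integer_, m, 2)
  if (nrow(cand)) {
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (abs(sum(nrm[i, ] * nrm[j, ])) < criteria$normal_cos) next
      d <- cent[j, ] - cent[i, ]
      dist_ij <- D[i, j]
      dhat <- d / dist_ij
      pi_ <- sum(dhat * nrm[i, ])
      pj <- sum(dhat * nrm[j, ])
      if (min(abs(pi_), abs(pj)) < criteria$disp_cos) next
      side_i <- if (pi_ >= 0) 1L else 2L
      side_j <- if (-pj >= 0) 1L else 2L
      if (dist_ij < best_d[i, side_i] ||
          (dist_ij == best_d[i, side_i] && isTRUE(j < best_p[i, side_i]))) {
        best_d[i, side_i] <- dist_ij; best_p[i, side_i] <- j
      }
      if (dist_ij < best_d[j, side_j] ||
          (dist_ij == best_d[j, side_j] && isTRUE(i < best_p[j, side_j]))) {
        best_d[j, side_j] <- dist_ij; best_p[j, side_j] <- i
      }
    }
  }
  counts[mid] <- rowSums(!is.na(best_p))
  counts
}
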