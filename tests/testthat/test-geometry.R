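test_that("local distances of ideal helix and strand windows match closed forms", {
  hw <- trace_coords(make_helix(7)$trace)
  ld <- local_distances(hw)
  expect_equal(ld$r2, rep(helix_chord(2), 5), tolerance = 1e-9)
  expect_equal(ld$r3s, rep(+helix_chord(3), 4), tolerance = 1e-9)
  expect_equal(ld$r4, rep(helix_chord(4), 3), tolerance = 1e-9)

  sw <- trace_coords(make_strand(7)$trace)
  ls <- local_distances(sw)
  expect_equal(ls$r2, rep(strand_chord(2), 5), tolerance = 1e-9)  # 6.60
  expect_equal(abs(ls$r3s), rep(strand_chord(3), 4), tolerance = 1e-9)  # 10.08
  expect_equal(ls$r4, rep(strand_chord(4), 3), tolerance = 1e-9)  # 13.20

  expect_error(local_distances(hw[1:4, ]), "window too short")
})

test_that("signed r3 is chirality-odd and uses the +1 tie-break when planar", {
  h <- trace_coords(make_helix(4)$trace)
  v <- signed_r3(h[1, ], h[2, ], h[3, ], h[4, ])
  expect_gt(v, 0)  # right-handed helix
  expect_equal(v, helix_chord(3), tolerance = 1e-9)
  # mirroring flips the sign, keeps the magnitude
  m <- h %*% diag(c(1, 1, -1))
  vm <- signed_r3(m[1, ], m[2, ], m[3, ], m[4, ])
  expect_equal(vm, -v, tolerance = 1e-12)
  # left-handed helix is negative
  l <- trace_coords(make_helix(4, handedness = -1)$trace)
  expect_lt(signed_r3(l[1, ], l[2, ], l[3, ], l[4, ]), 0)
  # collinear quadruplet: zero triple product signs +1
  p <- sapply(0:3, function(i) c(i * 3.8, 0, 0))
  expect_equal(signed_r3(p[, 1], p[, 2], p[, 3], p[, 4]), 11.4, tolerance = 1e-12)
})

test_that("neighbour counts match the ideal-geometry closed forms", {
  # isolated strand: nearest eligible partner (i+-3) sits at ~10.1 A
  s <- make_strand(15)$trace
  nb_s <- neighbor_counts(s)
  expect_true(all(nb_s == 0L))
  # helix interior: i+-3 at ~5.05 A inside 6 A; i+-4 at ~6.20 A outside
  h <- make_helix(20)$trace
  nb_h <- neighbor_counts(h)
  expect_equal(nb_h[10, "6"], 2L, ignore_attr = TRUE)
  expect_equal(nb_h[10, "5"], 0L, ignore_attr = TRUE)
})

test_that("neighbour counts equal a brute-force pairwise recount", {
  brute <- function(trace, cutoffs, min_sep) {
    co <- trace_coords(trace)
    n <- nrow(co)
    out <- matrix(0L, n, length(cutoffs))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (abs(i - j) < min_sep) next
      d <- sqrt(sum((co[i, ] - co[j, ])^2))
      out[i, ] <- out[i, ] + as.integer(d <= cutoffs)
    }
    out
  }
  withr::with_seed(42, {
    for (rep in 1:5) {
      tr <- random_walk_trace(sample(10:60, 1))
      got <- neighbor_counts(tr)
      expect_identical(unname(got), brute(tr, c(4, 4.5, 5, 6), 3L))
    }
  })
})

test_that("neighbour counts are monotone in the cutoff", {
  withr::with_seed(7, {
    tr <- random_walk_trace(50)
    nb <- neighbor_counts(tr)
    expect_true(all(nb[, 4] >= nb[, 1]))
    expect_true(all(t(apply(nb, 1, diff)) >= 0))
  })
})

test_that("window features have the published layout and slide by one residue", {
  cfg7 <- window_config(7)
  tr <- make_helix(20)$trace
  f <- featurize_chain(tr, cfg7)
  expect_equal(nrow(f), 14L)            # 20 - 7 + 1
  expect_equal(f$center, 4:17)          # middle residues, 1-based
  expect_equal(ncol(f) - 1L, 47L)       # 12 local + 28 neighbour + 7 hbond
  expect_equal(sum(startsWith(names(f), "r2_")), 5L)
  expect_equal(sum(startsWith(names(f), "r3s_")), 4L)
  expect_equal(sum(startsWith(names(f), "r4_")), 3L)
  expect_equal(sum(startsWith(names(f), "nb_")), 28L)
  expect_equal(sum(startsWith(names(f), "hb_")), 7L)

  short <- make_helix(6)$trace
  expect_warning(f0 <- featurize_chain(short, cfg7), "shorter")
  expect_equal(nrow(f0), 0L)

  for (N in c(5L, 7L, 9L, 11L, 13L)) {
    full <- window_config(N)
    expect_equal(feature_length(full), (3L * N - 9L) + 4L * N + N)
    expect_equal(feature_length(window_config(N, "local")), 3L * N - 9L)
    expect_equal(feature_length(window_config(N, c("local", "neighbors"))),
                 3L * N - 9L + 4L * N)
  }
})

test_that("windows spanning a chain break are dropped", {
  a <- make_helix(8)$trace
  b <- make_helix(8)$trace
  b[, c("x", "y", "z")] <- b[, c("x", "y", "z")] + 30
  tr <- ca_trace(c(a$x, b$x), c(a$y, b$y), c(a$z, b$z))
  f <- featurize_chain(tr, window_config(5, "local"))
  # windows 5..8 (starts) touch the broken bond 8->9 and are gone
  expect_equal(nrow(f), 8L)
  expect_true(all(f$center %in% c(3:6, 11:14)))
})

test_that("features are invariant under rigid motion and only r3s flips under mirror", {
  withr::with_seed(13, {
    tr <- random_walk_trace(25)
    cfg <- window_config(7)
    f0 <- as.matrix(featurize_chain(tr, cfg)[, -1])
    for (k in 1:10) {
      moved <- apply_rigid(tr, random_rotation_matrix(), rnorm(3, sd = 20))
      fk <- as.matrix(featurize_chain(moved, cfg)[, -1])
      expect_lt(max(abs(fk - f0)), 1e-9)
    }
    fm <- as.matrix(featurize_chain(mirror_trace(tr), cfg)[, -1])
    is_r3s <- startsWith(colnames(f0), "r3s_")
    expect_lt(max(abs(fm[, is_r3s] + f0[, is_r3s])), 1e-9)
    expect_lt(max(abs(fm[, !is_r3s] - f0[, !is_r3s])), 1e-9)
  })
})
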