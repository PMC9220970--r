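test_that("helix generator reproduces ideal alpha-helical geometry", {
  h <- make_helix(10)
  expect_identical(h$labels, strrep("H", 10))
  co <- trace_coords(h$trace)
  d1 <- sqrt(rowSums((co[-1, ] - co[-10, ])^2))
  expect_equal(d1, rep(helix_chord(1), 9), tolerance = 1e-9)  # ~3.83 A
  expect_true(all(d1 > 2.5 & d1 < 4.3))
  ld <- local_distances(co[1:5, ])
  expect_equal(ld$r3s[1], helix_chord(3), tolerance = 1e-9)  # ~5.05, right-handed
  lh <- make_helix(10, handedness = -1)
  expect_lt(local_distances(trace_coords(lh$trace)[1:5, ])$r3s[1], 0)
})

test_that("strand generator is an exact 3.8-A zigzag", {
  s <- make_strand(8)
  expect_identical(s$labels, strrep("E", 8))
  co <- trace_coords(s$trace)
  d1 <- sqrt(rowSums((co[-1, ] - co[-8, ])^2))
  expect_equal(d1, rep(sqrt(3.3^2 + (2 * 0.942)^2), 7), tolerance = 1e-12)  # 3.80
  ld <- local_distances(co[1:8, ])
  expect_equal(ld$r2[1], 6.6, tolerance = 1e-12)
  expect_equal(ld$r3s[1], strand_chord(3), tolerance = 1e-12)  # planar: sign +1
  expect_equal(ld$r4[1], 13.2, tolerance = 1e-12)
})

test_that("sheets assemble contiguously with E strands and C loops", {
  sh <- make_sheet(3, 8, loop_len = 4)
  expect_equal(nchar(sh$labels), 3 * 8 + 2 * 4)
  expect_identical(sh$labels, paste0(strrep("E", 8), "CCCC", strrep("E", 8),
                                     "CCCC", strrep("E", 8)))
  expect_identical(detect_chain_breaks(sh$trace), integer(0))
  # parallel sheets need longer crossover loops
  expect_error(make_sheet(2, 8, antiparallel = FALSE, loop_len = 4), "loop too short")
  par <- make_sheet(2, 8, antiparallel = FALSE, loop_len = 10)
  expect_identical(detect_chain_breaks(par$trace), integer(0))
})

test_that("coils are seed-deterministic, contiguous and self-avoiding", {
  c1 <- make_coil(30, seed = 17)
  c2 <- make_coil(30, seed = 17)
  expect_identical(c1$trace, c2$trace)
  expect_identical(c1$labels, strrep("C", 30))
  expect_identical(detect_chain_breaks(c1$trace), integer(0))
  co <- trace_coords(c1$trace)
  D <- as.matrix(dist(co))
  sep <- abs(outer(1:30, 1:30, "-"))
  expect_gte(min(D[sep >= 2]), 4.0)
})

test_that("coil i,i+3 geometry rarely mimics the helical 5.05-A contact", {
  hits <- 0L; total <- 0L
  for (s in 1:100) {
    co <- trace_coords(make_coil(12, seed = s)$trace)
    d3 <- sqrt(rowSums((co[4:12, ] - co[1:9, ])^2))
    hits <- hits + sum(abs(d3 - helix_chord(3)) < 0.3)
    total <- total + length(d3)
  }
  expect_lt(hits / total, 0.10)
})

test_that("mixed topologies concatenate with exact labels and no breaks", {
  p <- make_protein("H10-C5-E8", seed = 7)
  expect_equal(nchar(p$labels), 23L)
  expect_identical(p$labels, paste0(strrep("H", 10), strrep("C", 5), strrep("E", 8)))
  expect_identical(detect_chain_breaks(p$trace), integer(0))
  expect_identical(p$trace, make_protein("H10-C5-E8", seed = 7)$trace)
  f <- featurize_chain(p$trace, window_config(7))
  expect_equal(nrow(f), 23L - 7L + 1L)
  expect_error(parse_topology("H10-X5"), "invalid topology")
})

test_that("mirroring is an involution that flips exactly the signed distances", {
  # helix and coil segments only: strand windows are exactly planar, where
  # the chirality sign falls back to the +1 tie-break on both mirror images
  tr <- make_protein("H8-C4-H6", seed = 2)$trace
  expect_identical(mirror_trace(mirror_trace(tr)), tr)
  f0 <- as.matrix(featurize_chain(tr, window_config(5))[, -1])
  fm <- as.matrix(featurize_chain(mirror_trace(tr), window_config(5))[, -1])
  is_r3s <- startsWith(colnames(f0), "r3s_")
  expect_equal(fm[, is_r3s], -f0[, is_r3s], tolerance = 1e-12)
  expect_equal(fm[, !is_r3s], f0[, !is_r3s], tolerance = 1e-12)
})

test_that("every corpus chain is contiguous and labelled residue for residue", {
  set <- make_structure_set(25, seed = 99)
  expect_equal(nrow(set), 25L)
  for (i in seq_len(nrow(set))) {
    expect_identical(detect_chain_breaks(set$trace[[i]]), integer(0))
    expect_equal(nchar(set$labels[i]), nrow(set$trace[[i]]))
  }
  set2 <- make_structure_set(25, seed = 99)
  expect_identical(set$labels, set2$labels)
  expect_identical(set$trace[[10]], set2$trace[[10]])
})
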