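test_that("initialisation is seed-deterministic with one weight matrix per layer gap", {
  lay <- network_layout(47)
  m1 <- init_mlp(lay, seed = 3)
  m2 <- init_mlp(lay, seed = 3)
  m3 <- init_mlp(lay, seed = 4)
  expect_identical(m1$W, m2$W)
  expect_false(identical(m1$W, m3$W))
  expect_length(m1$W, 3L)  # input->h1, h1->h2, h2->out
  expect_equal(dim(m1$W[[1]]), c(47L, 128L))
  expect_equal(dim(m1$W[[3]]), c(128L, 3L))
})

test_that("forward probabilities are a proper softmax distribution", {
  lay <- network_layout(6, hidden = c(8, 8))
  m <- init_mlp(lay, seed = 1, window = window_config(5, "local"))
  withr::with_seed(2, {
    X <- matrix(rnorm(1000 * 6), ncol = 6)
    p <- mlp_forward(m, X)
    expect_equal(rowSums(p), rep(1, 1000), tolerance = 1e-9)
    expect_true(all(p > 0))
  })
  # zero final layer -> equal logits -> uniform over the three classes
  m0 <- m
  m0$W[[3]][] <- 0; m0$b[[3]][] <- 0
  expect_equal(as.numeric(mlp_forward(m0, X[1, ])), rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(mlp_forward(m, X[, 1:4]), "feature dimension error")
})

test_that("analytic gradients match central differences on a small batch", {
  lay <- network_layout(5, hidden = c(7, 6))
  m <- init_mlp(lay, seed = 11, window = window_config(5, "local"))
  withr::with_seed(12, {
    X <- matrix(rnorm(5 * 5), 5, 5)
    Y <- diag(3)[sample(1:3, 5, TRUE), ]
  })
  g <- cassign:::mlp_gradients(m, X, Y)
  eps <- 1e-6
  for (l in seq_along(m$W)) {
    idx <- cbind(c(1, nrow(m$W[[l]])), c(1, ncol(m$W[[l]])))
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      mp <- m; mp$W[[l]][i, j] <- mp$W[[l]][i, j] + eps
      mm <- m; mm$W[[l]][i, j] <- mm$W[[l]][i, j] - eps
      fp <- cassign:::cross_entropy(cassign:::mlp_forward_raw(mp, X)[[4]], Y)
      fm <- cassign:::cross_entropy(cassign:::mlp_forward_raw(mm, X)[[4]], Y)
      num <- (fp - fm) / (2 * eps)
      expect_equal(g$dW[[l]][i, j], num, tolerance = 1e-5)
    }
  }
})

test_that("training separates a linearly separable toy problem and reduces the loss", {
  withr::with_seed(5, {
    X <- rbind(matrix(rnorm(200, mean = -2, sd = 0.5), ncol = 2),
               matrix(rnorm(200, mean = +2, sd = 0.5), ncol = 2))
    y <- rep(c("H", "C"), each = 100)
  })
  lay <- network_layout(2, hidden = c(8, 8))
  m <- init_mlp(lay, seed = 6, window = window_config(5, "local"))
  fit <- fit_mlp(m, X, y, train_control(epochs = 200, seed = 6))
  p <- mlp_forward(fit, X)
  acc <- mean(c("H", "E", "C")[max.col(p)] == y)
  expect_equal(acc, 1.0)
  h <- fit$history
  expect_lt(mean(tail(h, 10)), mean(head(h, 10)))
  expect_error(fit_mlp(m, X, rep("H", 200), train_control(epochs = 1)),
               "degenerate training set")
})

test_that("training is bit-reproducible for a fixed seed", {
  withr::with_seed(9, {
    X <- matrix(rnorm(60 * 4), ncol = 4)
    y <- sample(c("H", "E", "C"), 60, TRUE)
  })
  lay <- network_layout(4, hidden = c(6, 6))
  f1 <- fit_mlp(init_mlp(lay, 2, window_config(5, "local")), X, y,
                train_control(epochs = 15, seed = 2))
  f2 <- fit_mlp(init_mlp(lay, 2, window_config(5, "local")), X, y,
                train_control(epochs = 15, seed = 2))
  expect_identical(f1$W, f2$W)
  expect_identical(f1$history, f2$history)
})

test_that("model files round-trip weights, statistics and configuration exactly", {
  withr::with_seed(14, {
    X <- matrix(rnorm(60 * 6), ncol = 6)
    y <- sample(c("H", "E", "C"), 60, TRUE)
  })
  lay <- network_layout(6, hidden = c(9, 7))
  m <- fit_mlp(init_mlp(lay, 3, window_config(5, "local")), X, y,
               train_control(epochs = 5, seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  save_mlp(m, path)
  m2 <- load_mlp(path)
  expect_equal(m2$W, m$W, tolerance = 0)
  expect_equal(m2$feature_mean, m$feature_mean, tolerance = 0)
  expect_identical(m2$window$N, m$window$N)
  withr::with_seed(15, Xn <- matrix(rnorm(100 * 6), ncol = 6))
  expect_equal(mlp_forward(m2, Xn), mlp_forward(m, Xn), tolerance = 1e-12)
  # corrupted / inconsistent files are rejected
  lines <- readLines(path)
  trunc_path <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(lines, collapse = ""), 1, 200), trunc_path)
  expect_error(load_mlp(trunc_path), "model file error")
  doc <- jsonlite::read_json(path)
  doc$layout$input_width <- 12
  bad_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad_path, auto_unbox = TRUE, digits = NA)
  expect_error(load_mlp(bad_path), "model file error")
})

test_that("a synthetically trained model assigns helices with coil termini", {
  fit <- get_test_model()
  helix <- make_helix(40)$trace
  res <- predict_chain(fit$model, helix)
  expect_identical(res$ss[1:5], rep("C", 5))
  expect_identical(res$ss[36:40], rep("C", 5))
  expect_true(all(res$ss[6:35] == "H"))
  # probabilities on forced-terminal residues are the coil point mass
  expect_equal(unlist(res[1, c("pH", "pE", "pC")]), c(pH = 0, pE = 0, pC = 1))
  # rigid motion does not change the assignment
  moved <- withr::with_seed(3, apply_rigid(helix, random_rotation_matrix(), rnorm(3, sd = 30)))
  expect_identical(predict_chain(fit$model, moved)$ss, res$ss)
})

test_that("traces shorter than the window yield an all-coil assignment with a warning", {
  fit <- get_test_model()
  short <- make_helix(8)$trace
  expect_warning(res <- predict_chain(fit$model, short), "shorter")
  expect_identical(paste(res$ss, collapse = ""), "CCCCCCCC")
})

test_that("tidy and glance expose the training history and architecture", {
  fit <- get_test_model()
  td <- tidy(fit$model)
  expect_identical(names(td), c("epoch", "loss"))
  expect_equal(nrow(td), length(fit$model$history))
  g <- glance(fit$model)
  expect_identical(g$hidden, "128x128")
  expect_true(g$trained)
  expect_s3_class(autoplot(fit$model), "ggplot")
  expect_s3_class(autoplot(fit$validation), "ggplot")
})
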