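# The feed-forward classifier: a multi-layer perceptron with sigmoid hidden
# layers and a softmax output over the three secondary-structure classes,
# trained by mini-batch stochastic gradient descent on the categorical
# cross-entropy. The network, backpropagation and optimiser are implemented
# here; tests check the analytic gradients against central differences.

#' Network layout
#'
#' @param input_width Feature-vector length.
#' @param hidden Hidden-layer widths; the default 128 x 128 two-layer shape
#'   is the configuration the method settled on.
#' @param output_width Number of classes; fixed at 3 (H, E, C).
#' @return A `network_layout` list.
#' @export
network_layout <- function(input_width, hidden = c(128L, 128L), output_width = 3L) {
  if (length(hidden) < 1L) abort("at least one hidden layer is required")
  if (output_width != 3L) abort("output_width must be 3 (H, E, C)")
  structure(
    list(input_width = as.integer(input_width), hidden = as.integer(hidden),
         output_width = as.integer(output_width)),
    class = "network_layout"
  )
}

#' Training hyperparameters
#'
#' Defaults follow the settled protocol: learning rate 0.01, 3500 epochs and
#' an 80/20 train/test split. The batch size is configurable (32 by
#' default). Synthetic-corpus runs in this package's tests use far fewer
#' epochs because the synthetic task converges early (see the methods
#' vignette).
#'
#' @param learning_rate SGD step size.
#' @param epochs Number of passes over the training rows.
#' @param batch_size Mini-batch size.
#' @param train_fraction Fraction of chains used for training in chain-level
#'   splits.
#' @param seed Seed driving initialisation and shuffling.
#' @return A `train_control` list.
#' @export
train_control <- function(learning_rate = 0.01, epochs = 3500L, batch_size = 32L,
                          train_fraction = 0.8, seed = 1L) {
  if (learning_rate <= 0) abort("learning_rate must be positive")
  if (epochs < 1L) abort("epochs must be at least 1")
  if (train_fraction <= 0 || train_fraction >= 1) abort("train_fraction must be in (0, 1)")
  structure(
    list(learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), train_fraction = train_fraction,
         seed = as.integer(seed)),
    class = "train_control"
  )
}

#' Initialise an untrained model
#'
#' Weights are drawn from the symmetric scaled-uniform (Glorot) interval
#' `+/- sqrt(6 / (fan_in + fan_out))`; biases start at zero. The same seed
#' reproduces the same model bit for bit.
#'
#' @param layout A [network_layout()].
#' @param seed Integer seed.
#' @param window A [window_config()] recorded for training/inference parity.
#' @param criteria The [hbond_criteria()] recorded alongside.
#' @return A `ca_mlp` model object.
#' @export
init_mlp <- function(layout, seed = 1L, window = window_config(),
                     criteria = hbond_criteria()) {
  widths <- c(layout$input_width, layout$hidden, layout$output_width)
  with_seed(seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(widths) - 1L)) {
      lim <- sqrt(6 / (widths[l] + widths[l + 1L]))
      W[[l]] <- matrix(runif(widths[l] * widths[l + 1L], -lim, lim),
                       widths[l], widths[l + 1L])
      b[[l]] <- numeric(widths[l + 1L])
    }
    structure(
      list(layout = layout, W = W, b = b,
           feature_mean = numeric(layout$input_width),
           feature_sd = rep(1, layout$input_width),
           feature_names = NULL, window = window, criteria = criteria,
           trained = FALSE, history = numeric(0)),
      class = "ca_mlp"
    )
  })
}

sigmoid <- function(z) 1 / (1 + exp(-z))

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass on an already-standardized matrix; returns activations per
# layer (needed by backprop) and class probabilities.
mlp_forward_raw <- function(model, Xs) {
  L <- length(model$W)
  a <- vector("list", L + 1L)
  a[[1]] <- Xs
  for (l in seq_len(L - 1L)) {
    a[[l + 1L]] <- sigmoid(sweep(a[[l]] %*% model$W[[l]], 2, model$b[[l]], "+"))
  }
  z_out <- sweep(a[[L]] %*% model$W[[L]], 2, model$b[[L]], "+")
  a[[L + 1L]] <- softmax_rows(z_out)
  a
}

standardize <- function(model, X) {
  sweep(sweep(X, 2, model$feature_mean, "-"), 2, model$feature_sd, "/")
}

#' Class probabilities for feature rows
#'
#' Features are standardized with the model's stored per-column mean and
#' standard deviation, passed through the sigmoid hidden layers and the
#' softmax output.
#'
#' @param model A `ca_mlp` model.
#' @param features A numeric matrix (rows = windows), a single feature
#'   vector, or a tibble from [featurize_chain()] (its `center` column is
#'   ignored).
#' @return Matrix of probabilities with columns `H`, `E`, `C` summing to 1.
#' @export
mlp_forward <- function(model, features) {
  X <- as_feature_matrix(features)
  if (ncol(X) != model$layout$input_width) {
    abort(sprintf("feature dimension error: got %d columns, model expects %d",
                  ncol(X), model$layout$input_width))
  }
  p <- mlp_forward_raw(model, standardize(model, X))[[length(model$W) + 1L]]
  colnames(p) <- ss_alphabet
  p
}

as_feature_matrix <- function(features) {
  if (is.data.frame(features)) {
    features <- as.matrix(features[, setdiff(names(features), "center"), drop = FALSE])
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  storage.mode(features) <- "double"
  features
}

one_hot <- function(y) {
  ch <- ss_chars(y)
  if (!all(ch %in% ss_alphabet)) abort("labels must be over {H,E,C}")
  Y <- matrix(0, length(ch), 3L)
  Y[cbind(seq_along(ch), match(ch, ss_alphabet))] <- 1
  Y
}

# Mean categorical cross-entropy of probability rows against one-hot targets.
cross_entropy <- function(P, Y) {
  -mean(log(pmax(rowSums(P * Y), 1e-300)))
}

# Analytic gradients of the mean cross-entropy over one batch.
mlp_gradients <- function(model, Xs, Y) {
  L <- length(model$W)
  a <- mlp_forward_raw(model, Xs)
  nb <- nrow(Xs)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- (a[[L + 1L]] - Y) / nb
  for (l in L:1) {
    dW[[l]] <- crossprod(a[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(model$W[[l]])) * a[[l]] * (1 - a[[l]])
    }
  }
  list(dW = dW, db = db, loss = cross_entropy(a[[L + 1L]], Y))
}

#' Train the classifier on feature rows
#'
#' Labels are one-hot encoded and the categorical cross-entropy is minimised
#' by mini-batch SGD with a seeded shuffle each epoch, so a fixed seed gives
#' bit-reproducible training. Standardization statistics are computed from
#' the supplied rows (the caller holds out validation chains beforehand);
#' zero-variance columns are stored with unit spread.
#'
#' @param model A `ca_mlp` from [init_mlp()].
#' @param features Feature rows (matrix or [featurize_chain()] tibble).
#' @param labels H/E/C labels, one per row (string or letter vector).
#' @param control A [train_control()].
#' @return The trained model; `$history` holds the mean training loss per
#'   epoch.
#' @export
fit_mlp <- function(model, features, labels, control = train_control()) {
  X <- as_feature_matrix(features)
  ch <- ss_chars(labels)
  if (nrow(X) != length(ch)) abort("features and labels differ in length")
  if (length(unique(ch)) < 2L) abort("degenerate training set: fewer than 2 classes")
  Y <- one_hot(ch)
  mu <- unname(colMeans(X))
  sdev <- unname(apply(X, 2, sd))
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  model$feature_mean <- mu
  model$feature_sd <- sdev
  model$feature_names <- colnames(X)
  dimnames(X) <- NULL
  Xs <- standardize(model, X)
  n <- nrow(Xs)
  lr <- control$learning_rate
  history <- numeric(control$epochs)
  with_seed(control$seed, {
    for (ep in seq_len(control$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      for (s in seq(1L, n, control$batch_size)) {
        ix <- ord[s:min(s + control$batch_size - 1L, n)]
        g <- mlp_gradients(model, Xs[ix, , drop = FALSE], Y[ix, , drop = FALSE])
        for (l in seq_along(model$W)) {
          model$W[[l]] <- model$W[[l]] - lr * g$dW[[l]]
          model$b[[l]] <- model$b[[l]] - lr * g$db[[l]]
        }
        losses <- c(losses, g$loss)
      }
      history[ep] <- mean(losses)
    }
  })
  model$trained <- TRUE
  model$history <- c(model$history, history)
  model
}

#' Assign secondary structure to a whole chain
#'
#' Features are recomputed with the window configuration and hydrogen-bond
#' criteria stored in the model (training/inference parity). Residues
#' without a complete break-free window — the (N-1)/2 residues at each
#' terminus and residues next to a chain break — are assigned `C` with
#' probabilities (0, 0, 1). Other residues take the argmax class;
#' probability ties resolve in the order H > E > C.
#'
#' @param model A trained `ca_mlp`.
#' @param trace A trace tibble.
#' @return A tibble with columns `chain`, `resseq`, `icode`, `ss`, `pH`,
#'   `pE`, `pC`. A trace shorter than the window is returned all-`C` with a
#'   warning.
#' @export
predict_chain <- function(model, trace) {
  validate_trace(trace)
  n <- nrow(trace)
  out <- tibble(
    chain = trace$chain, resseq = trace$resseq, icode = trace$icode,
    ss = rep("C", n), pH = rep(0, n), pE = rep(0, n), pC = rep(1, n)
  )
  if (n < model$window$N) {
    warn("trace shorter than the model window; returning an all-coil assignment")
    return(out)
  }
  feats <- featurize_chain(trace, model$window, criteria = model$criteria)
  if (nrow(feats) == 0L) return(out)
  p <- mlp_forward(model, feats)
  pick <- apply(p, 1, function(r) which(r == max(r))[1])  # ties: H > E > C order
  out$ss[feats$center] <- ss_alphabet[pick]
  out$pH[feats$center] <- p[, 1]
  out$pE[feats$center] <- p[, 2]
  out$pC[feats$center] <- p[, 3]
  out
}

#' @export
print.ca_mlp <- function(x, ...) {
  cat(sprintf(
    "<ca_mlp> %d -> %s -> %d  (%s, N=%d, features: %s)\n",
    x$layout$input_width, paste(x$layout$hidden, collapse = " -> "),
    x$layout$output_width, if (x$trained) "trained" else "untrained",
    x$window$N, paste(x$window$features, collapse = "+")
  ))
  invisible(x)
}

#' Tidy the training history of a model
#'
#' @param x A `ca_mlp`.
#' @param ... Unused.
#' @return Tibble with `epoch` and mean training `loss`.
#' @method tidy ca_mlp
#' @export
tidy.ca_mlp <- function(x, ...) {
  tibble(epoch = seq_along(x$history), loss = x$history)
}

#' One-row summary of a model
#'
#' @param x A `ca_mlp`.
#' @param ... Unused.
#' @method glance ca_mlp
#' @export
glance.ca_mlp <- function(x, ...) {
  n_par <- sum(vapply(x$W, length, integer(1))) + sum(vapply(x$b, length, integer(1)))
  tibble(
    input_width = x$layout$input_width,
    hidden = paste(x$layout$hidden, collapse = "x"),
    output_width = x$layout$output_width,
    n_parameters = n_par,
    window_N = x$window$N,
    features = paste(x$window$features, collapse = "+"),
    trained = x$trained,
    epochs_trained = length(x$history),
    final_loss = if (length(x$history)) x$history[length(x$history)] else NA_real_
  )
}

#' Plot the training loss curve
#'
#' @param object A `ca_mlp`.
#' @param ... Unused.
#' @method autoplot ca_mlp
#' @export
autoplot.ca_mlp <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Epoch", y = "Mean training cross-entropy") +
    ggplot2::theme_minimal()
}

# Serialization ---------------------------------------------------------------

MODEL_FORMAT <- "cassign-mlp/1"

#' Save / load a model as portable text
#'
#' The model file is a versioned JSON document carrying the layout,
#' row-major weight matrices, biases, per-column standardization statistics,
#' the window configuration, the hydrogen-bond criteria and the feature
#' ordering manifest, written at full decimal precision so a round trip
#' reproduces the forward pass exactly.
#'
#' @param model A `ca_mlp`.
#' @param path Output/input file path.
#' @return `load_mlp()` returns the restored `ca_mlp`.
#' @export
save_mlp <- function(model, path) {
  doc <- list(
    format = MODEL_FORMAT,
    layout = list(input_width = model$layout$input_width,
                  hidden = model$layout$hidden,
                  output_width = model$layout$output_width),
    weights = lapply(model$W, function(w) list(nrow = nrow(w), ncol = ncol(w),
                                               data = as.vector(t(w)))),
    biases = model$b,
    feature_mean = model$feature_mean,
    feature_sd = model$feature_sd,
    feature_names = model$feature_names,
    window = unclass(model$window),
    criteria = unclass(model$criteria),
    trained = model$trained,
    history = model$history
  )
  # digits = I(17): full significant-digit precision, exact double round-trip
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname save_mlp
#' @export
load_mlp <- function(path) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) abort("model file error: unreadable or corrupted file"))
  if (!identical(doc$format, MODEL_FORMAT)) abort("model file error: unknown format version")
  layout <- network_layout(doc$layout$input_width, doc$layout$hidden, doc$layout$output_width)
  widths <- c(layout$input_width, layout$hidden, layout$output_width)
  W <- vector("list", length(widths) - 1L)
  b <- vector("list", length(widths) - 1L)
  biases <- doc$biases
  if (is.matrix(biases)) biases <- lapply(seq_len(nrow(biases)), function(i) biases[i, ])
  for (l in seq_along(W)) {
    wl <- if (is.data.frame(doc$weights)) {
      list(nrow = doc$weights$nrow[l], ncol = doc$weights$ncol[l],
           data = doc$weights$data[[l]])
    } else doc$weights[[l]]
    if (wl$nrow != widths[l] || wl$ncol != widths[l + 1L]) {
      abort("model file error: weight shape does not match the stored layout")
    }
    if (length(wl$data) != wl$nrow * wl$ncol) {
      abort("model file error: truncated weight array")
    }
    W[[l]] <- matrix(wl$data, wl$nrow, wl$ncol, byrow = TRUE)
    b[[l]] <- as.numeric(biases[[l]])
    if (length(b[[l]]) != widths[l + 1L]) abort("model file error: bias length mismatch")
  }
  if (length(doc$feature_mean) != layout$input_width ||
      length(doc$feature_sd) != layout$input_width) {
    abort("model file error: standardization statistics do not match input width")
  }
  window <- window_config(doc$window$N, doc$window$features,
                          doc$window$cutoffs, doc$window$min_seq_sep)
  criteria <- hbond_criteria(doc$criteria$dist_min, doc$criteria$dist_max,
                             doc$criteria$normal_cos, doc$criteria$disp_cos,
                             doc$criteria$min_seq_sep)
  if (feature_length(window) != layout$input_width) {
    abort("model file error: stored input width does not match the window configuration")
  }
  structure(
    list(layout = layout, W = W, b = b,
         feature_mean = doc$feature_mean, feature_sd = doc$feature_sd,
         feature_names = doc$feature_names, window = window, criteria = criteria,
         trained = isTRUE(doc$trained), history = as.numeric(doc$history)),
    class = "ca_mlp"
  )
}
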