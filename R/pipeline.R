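# End-to-end training pipeline: corpus -> windows -> fitted classifier ->
# held-out evaluation.

#' Feature windows and center labels for one labelled chain
#'
#' @param trace A trace tibble.
#' @param labels Label string aligned to the trace.
#' @param window A [window_config()].
#' @param criteria [hbond_criteria()].
#' @return List with `features` (tibble from [featurize_chain()]) and `y`
#'   (label letters of the window centers).
#' @export
chain_windows <- function(trace, labels, window = window_config(),
                          criteria = hbond_criteria()) {
  ch <- ss_chars(labels)
  if (length(ch) != nrow(trace)) abort("alignment error: labels do not match trace length")
  feats <- featurize_chain(trace, window, criteria = criteria)
  list(features = feats, y = ch[feats$center])
}

#' Train an assigner on a labelled corpus
#'
#' Splits chains (not windows) into train/held-out sets with the seeded
#' fraction from `control`, featurizes the training chains, fits the
#' network, and scores the held-out chains window-by-window: every residue
#' owning a complete window is predicted from the trained model and
#' compared with its label. Terminal residues (no window) are not part of
#' this window-level validation; whole-chain scoring, where they count as
#' forced coil, is available through [predict_chain()] + [eval_report()].
#'
#' @param structures Tibble with columns `id`, `trace` (list) and `labels`
#'   (see [make_structure_set()]).
#' @param window A [window_config()].
#' @param criteria [hbond_criteria()].
#' @param control A [train_control()].
#' @return List with `model` (trained `ca_mlp`), `validation` (an
#'   [eval_report()] over held-out windows), `train_q3`, and the id vectors
#'   of both splits.
#' @export
train_assigner <- function(structures, window = window_config(),
                           criteria = hbond_criteria(), control = train_control()) {
  n <- nrow(structures)
  if (n < 2L) abort("need at least 2 chains to split")
  n_train <- max(1L, round(control$train_fraction * n))
  ord <- with_seed(control$seed, sample.int(n))
  train_ix <- sort(ord[seq_len(n_train)])
  test_ix <- sort(ord[-seq_len(n_train)])
  if (!length(test_ix)) abort("train_fraction leaves no held-out chains")

  wins <- purrr::map2(structures$trace, structures$labels, chain_windows,
                      window = window, criteria = criteria)
  X_train <- do.call(rbind, lapply(wins[train_ix], function(w) as_feature_matrix(w$features)))
  y_train <- unlist(lapply(wins[train_ix], `[[`, "y"), use.names = FALSE)

  model <- init_mlp(network_layout(feature_length(window)), seed = control$seed,
                    window = window, criteria = criteria)
  model <- fit_mlp(model, X_train, y_train, control)

  p_train <- mlp_forward(model, X_train)
  train_q3 <- mean(ss_alphabet[max.col(p_train, ties.method = "first")] == y_train)

  pred <- list(); truth <- list()
  for (i in test_ix) {
    w <- wins[[i]]
    if (!nrow(w$features)) next
    p <- mlp_forward(model, w$features)
    id <- structures$id[i]
    pred[[id]] <- ss_collapse(ss_alphabet[max.col(p, ties.method = "first")])
    truth[[id]] <- ss_collapse(w$y)
  }
  list(
    model = model,
    validation = eval_report(pred, truth),
    train_q3 = train_q3,
    train_ids = structures$id[train_ix],
    heldout_ids = structures$id[test_ix]
  )
}
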