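# Shared fixtures: tiny PDB texts, random traces, closed-form oracles and a
# lazily trained small model reused across tests.

pdb_line <- function(serial, resno, x, y, z, chain = "A", elety = "CA",
                     altloc = " ", resid = "ALA", occ = 1, record = "ATOM  ") {
  sprintf("%s%5d %4s%s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
          record, serial, sprintf(" %-3s", elety), altloc, resid, chain, resno,
          x, y, z, occ)
}

three_residue_pdb <- function() {
  c(
    pdb_line(1, 1, 1.000, 2.000, 3.000),
    pdb_line(2, 2, 4.800, 2.000, 3.000),
    pdb_line(3, 3, 8.600, 2.000, 3.000),
    "TER", "END"
  )
}

# unconstrained random walk with fixed step; irregular but contiguous
random_walk_trace <- function(n, step = 3.8) {
  dirs <- matrix(rnorm(3 * (n - 1)), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  co <- apply(rbind(c(0, 0, 0), step * dirs), 2, cumsum)
  ca_trace(co[, 1], co[, 2], co[, 3])
}

random_rotation_matrix <- function() {
  q <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(q)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(trace, Q, shift) {
  co <- trace_coords(trace) %*% t(Q)
  co <- sweep(co, 2, shift, "+")
  ca_trace(co[, 1], co[, 2], co[, 3],
           chain = trace$chain, resseq = trace$resseq, icode = trace$icode)
}

# closed-form chord oracles for ideal geometries
helix_chord <- function(k, rise = 1.5, radius = 2.3, twist_deg = 100) {
  sqrt((2 * radius * sin(k * twist_deg * pi / 180 / 2))^2 + (k * rise)^2)
}

strand_chord <- function(k, axial = 3.3, lateral = 0.942) {
  dy <- if (k %% 2 == 0) 0 else 2 * lateral
  sqrt((k * axial)^2 + dy^2)
}

# Small trained model shared by inference tests; built once per test run.
test_model_env <- new.env(parent = emptyenv())

get_test_model <- function() {
  if (is.null(test_model_env$fit)) {
    set <- make_structure_set(120, seed = 5)
    test_model_env$fit <- train_assigner(
      set, window_config(11),
      control = train_control(epochs = 250, seed = 5)
    )
  }
  test_model_env$fit
}
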