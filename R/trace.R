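# Reading, validating and writing C-alpha traces and label strings.

#' Build a C-alpha trace tibble
#'
#' A trace is an ordered per-residue table with one C-alpha coordinate per
#' row. All geometry in the package consumes this layout.
#'
#' @param x,y,z Numeric coordinates in Angstrom.
#' @param chain Chain identifier (single string, recycled).
#' @param resseq Integer residue numbers; defaults to `1:n`.
#' @param icode Insertion codes; defaults to `""`.
#'
#' @return A tibble with columns `chain`, `resseq`, `icode`, `x`, `y`, `z`.
#' @export
ca_trace <- function(x, y, z, chain = "A", resseq = seq_along(x), icode = "") {
  tr <- tibble(
    chain = as.character(chain),
    resseq = as.integer(resseq),
    icode = as.character(icode),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z)
  )
  validate_trace(tr)
  tr
}

validate_trace <- function(trace) {
  need <- c("chain", "resseq", "icode", "x", "y", "z")
  missing <- setdiff(need, names(trace))
  if (length(missing)) {
    abort(paste0("trace is missing columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(trace) < 1L) abort("empty trace")
  co <- trace_coords(trace)
  if (!all(is.finite(co))) abort("trace contains non-finite coordinates")
  invisible(trace)
}

#' Extract the coordinate matrix of a trace
#'
#' @param trace A trace tibble (see [ca_trace()]).
#' @return An n x 3 numeric matrix.
#' @export
trace_coords <- function(trace) {
  as.matrix(trace[, c("x", "y", "z")])
}

#' Read the C-alpha trace of one chain from PDB text
#'
#' Parses ATOM/HETATM records (via bio3d), keeps only CA atoms of the
#' requested chain and model, and resolves alternate locations by keeping the
#' highest-occupancy record (first in file order on a tie). HETATM CA records
#' (e.g. selenomethionine) are accepted. Residues are returned in file order.
#'
#' @param pdb Path to a PDB file, or PDB-format text (a string containing
#'   newlines, or a character vector of lines).
#' @param chain Chain identifier; `NULL` picks the first chain with CA atoms.
#' @param model 1-based model index for multi-model files.
#'
#' @return A trace tibble (see [ca_trace()]).
#' @export
read_ca_trace <- function(pdb, chain = NULL, model = 1L) {
  path <- as_pdb_path(pdb)
  multi <- model > 1L
  p <- bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  at <- p$atom
  if (multi) {
    if (is.null(dim(p$xyz)) || nrow(p$xyz) < model) abort("model not found")
    xyz <- matrix(p$xyz[model, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  }
  if (is.null(chain)) {
    ca_chains <- unique(at$chain[at$elety == "CA"])
    if (!length(ca_chains)) abort("empty trace")
    chain <- ca_chains[[1]]
  }
  if (!any(at$chain == chain, na.rm = TRUE)) abort("chain not found")
  ca <- at[!is.na(at$chain) & at$chain == chain & at$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) abort("empty trace")
  ca$o[is.na(ca$o)] <- 1
  ca$insert[is.na(ca$insert)] <- ""
  # altloc resolution: per residue keep the highest-occupancy CA, first on tie
  key <- paste(ca$resno, ca$insert, sep = "\r")
  keep <- unlist(lapply(
    split(seq_len(nrow(ca)), factor(key, levels = unique(key))),
    function(ix) ix[which.max(ca$o[ix])]
  ), use.names = FALSE)
  ca <- ca[sort(keep), , drop = FALSE]
  ca_trace(ca$x, ca$y, ca$z, chain = chain, resseq = ca$resno, icode = ca$insert)
}

as_pdb_path <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb, fixed = TRUE) && file.exists(pdb)) {
    return(pdb)
  }
  lines <- if (length(pdb) == 1L) strsplit(pdb, "\n", fixed = TRUE)[[1]] else pdb
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

#' Detect chain breaks from consecutive C-alpha distances
#'
#' A deposited chain with missing residues shows consecutive C-alpha atoms at
#' a non-physical separation. Bonds outside `[d_min, d_max]` are flagged; the
#' defaults admit the trans peptide (~3.8 A) and the rarer cis peptide
#' (~2.9 A).
#'
#' @param trace A trace tibble of length >= 2.
#' @param d_min,d_max Allowed consecutive-distance window in Angstrom.
#'
#' @return Integer vector of 1-based indices `i` for which the bond
#'   `i -> i+1` is out of range; `integer(0)` means a contiguous chain.
#' @export
detect_chain_breaks <- function(trace, d_min = 2.5, d_max = 4.3) {
  validate_trace(trace)
  if (nrow(trace) < 2L) abort("trace must contain at least 2 residues")
  co <- trace_coords(trace)
  d <- sqrt(rowSums((co[-1, , drop = FALSE] - co[-nrow(co), , drop = FALSE])^2))
  which(d < d_min | d > d_max)
}

#' Reduce 8-state DSSP labels to 3 states
#'
#' Maps the eight DSSP classes onto helix/strand/coil with the common
#' convention H,G,I -> H; E,B -> E; T,S,C and blanks -> C.
#'
#' @param eight_state Character vector of label strings over
#'   `{H,G,I,E,B,T,S,C,-, }`.
#' @return Character vector of H/E/C strings of the same lengths.
#' @export
reduce_dssp_classes <- function(eight_state) {
  vapply(eight_state, function(s) {
    ch <- strsplit(s, "")[[1]]
    bad <- setdiff(ch, c("H", "G", "I", "E", "B", "T", "S", "C", "-", " "))
    if (length(bad)) abort(paste0("invalid DSSP code: ", paste(unique(bad), collapse = "")))
    out <- rep("C", length(ch))
    out[ch %in% c("H", "G", "I")] <- "H"
    out[ch %in% c("E", "B")] <- "E"
    ss_collapse(out)
  }, character(1), USE.NAMES = FALSE)
}

#' Serialize a per-residue assignment
#'
#' @param trace A trace tibble.
#' @param labels An H/E/C label string (or letter vector) aligned to `trace`.
#' @param format `"plain"` for the bare label string, `"tsv"` for a
#'   per-residue table with header
#'   `chain  resseq  icode  ss  pH  pE  pC`.
#' @param probs Optional n x 3 matrix of class probabilities (columns H,E,C)
#'   included in the TSV output.
#' @return A single string (plain) or character vector of TSV lines.
#' @export
write_assignment <- function(trace, labels, format = c("plain", "tsv"), probs = NULL) {
  format <- match.arg(format)
  validate_trace(trace)
  ch <- ss_chars(labels)
  if (length(ch) != nrow(trace)) abort("alignment error: labels do not match trace length")
  if (!all(ch %in% ss_alphabet)) abort("labels must be over {H,E,C}")
  if (format == "plain") return(ss_collapse(ch))
  if (is.null(probs)) probs <- matrix(NA_real_, nrow(trace), 3)
  header <- "chain\tresseq\ticode\tss\tpH\tpE\tpC"
  rows <- sprintf(
    "%s\t%d\t%s\t%s\t%s\t%s\t%s",
    trace$chain, trace$resseq, trace$icode, ch,
    fmt_prob(probs[, 1]), fmt_prob(probs[, 2]), fmt_prob(probs[, 3])
  )
  c(header, rows)
}

fmt_prob <- function(p) ifelse(is.na(p), "NA", sprintf("%.6f", p))

#' Write a trace as CA-only PDB text
#'
#' Emits wwPDB v3.3 fixed-width ATOM records (CA atoms of alanine residues)
#' so synthetic structures exercise the same input path as deposited files.
#'
#' @param trace A trace tibble.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @return Character vector of PDB lines, invisibly when written to `path`.
#' @export
write_ca_pdb <- function(trace, path = NULL) {
  validate_trace(trace)
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(nrow(trace)), substr(trace$chain, 1, 1), trace$resseq,
    ifelse(trace$icode == "", " ", substr(trace$icode, 1, 1)),
    trace$x, trace$y, trace$z
  )
  lines <- c(lines, "TER", "END")
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read/write label strings as FASTA-like text
#'
#' Label files hold one record per chain: a `>` header followed by the label
#' string.
#'
#' @param path File path.
#' @return `read_labels()` returns a named character vector of label strings.
#' @export
read_labels <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- names(set)
  out
}

#' @rdname read_labels
#' @param labels Named character vector of label strings.
#' @export
write_labels <- function(labels, path) {
  set <- Biostrings::BStringSet(labels)
  names(set) <- if (is.null(names(labels))) paste0("chain_", seq_along(labels)) else names(labels)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
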