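#' Residue node features
#'
#' Every residue node carries a 26-dimensional attribute vector: 5
#' physico-chemical factor scores (the five principal components extracted
#' from 237 AAIndex properties; shipped as packaged data) followed by a
#' 21-dimensional sequence-profile block (20 position-specific scores in
#' `ARNDCQEGHILKMFPSTWYV` order, then the per-position information
#' content). Column order is fixed: factors 1-5, profile 1-20, IC.
#'
#' @name features
NULL

.dockgat_env <- new.env(parent = emptyenv())

physchem_table <- function() {
  if (is.null(.dockgat_env$physchem)) {
    path <- system.file("extdata", "physchem5.csv", package = "dockgat")
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    m <- as.matrix(tab[, -1])
    rownames(m) <- tab$aa
    .dockgat_env$physchem <- m
  }
  .dockgat_env$physchem
}

#' Five-factor physico-chemical encoding of an amino acid
#'
#' @param aa Character vector of one-letter codes; `"X"` (UNK) maps to the
#'   zero vector.
#' @return Numeric matrix `length(aa) x 5`.
#' @export
physchem_encode <- function(aa) {
  tab <- physchem_table()
  out <- matrix(0, length(aa), 5)
  known <- aa %in% rownames(tab)
  out[known, ] <- tab[aa[known], , drop = FALSE]
  colnames(out) <- colnames(tab)
  out
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: two header lines, one row per
#' position with the 20 log-odds columns (and, when present, the trailing
#' per-position information content column).
#'
#' @param path Path to the PSSM file.
#' @param chain Optional chain id to attach.
#' @return A `SequenceProfile`: list with `length`, `sequence`, `scores`
#'   (`n x 20` matrix, columns in `ARNDCQEGHILKMFPSTWYV` order) and `ic`
#'   (numeric length `n`).
#' @export
read_pssm_ascii <- function(path, chain = NULL) {
  lines <- readLines(path, warn = FALSE)
  # locate the header row listing the 20 amino acids (twice)
  hdr <- which(vapply(lines, function(l) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    length(f) >= 20 && all(f[1:20] == AA_ORDER)
  }, logical(1)))
  if (!length(hdr)) stop("malformed PSSM: no amino-acid header row found")
  body <- lines[(hdr[1] + 1):length(lines)]
  rows <- list(); seqs <- character(0); ics <- numeric(0)
  for (l in body) {
    f <- strsplit(trimws(l), "\\s+")[[1]]
    if (length(f) < 22 || is.na(suppressWarnings(as.integer(f[1])))) break
    sc <- suppressWarnings(as.numeric(f[3:22]))
    if (anyNA(sc)) stop("malformed PSSM row: ", l)
    rows[[length(rows) + 1L]] <- sc
    seqs <- c(seqs, f[2])
    # full dialect: 20 log-odds + 20 percentages + information + weight
    ic <- if (length(f) >= 43) suppressWarnings(as.numeric(f[43])) else NA_real_
    ics <- c(ics, ic)
  }
  if (!length(rows)) stop("malformed PSSM: no position rows")
  scores <- do.call(rbind, rows)
  colnames(scores) <- AA_ORDER
  if (anyNA(ics)) {
    # IC column absent: derive probabilities from the percentage block when
    # present, else from the observed residue (single-sequence model)
    ics <- vapply(seq_len(nrow(scores)), function(i) {
      p <- point_mass_prob(seqs[i])
      compute_ic(p)
    }, numeric(1))
  }
  structure(list(chain = chain, length = nrow(scores), sequence = seqs,
                 scores = scores, ic = ics),
            class = "SequenceProfile")
}

point_mass_prob <- function(aa) {
  p <- rep(0, 20); names(p) <- AA_ORDER
  if (aa %in% AA_ORDER) p[aa] <- 1 else p[] <- 1 / 20
  p
}

#' Per-position information content
#'
#' Relative entropy of the position's residue distribution against a
#' background: `IC = sum_a p_a * log2(p_a / q_a)` with `0 * log 0 := 0`.
#'
#' @param probabilities Non-negative 20-vector summing to 1 (tolerance 1e-6).
#' @param background Background distribution; uniform 1/20 by default.
#' @return Information content in bits.
#' @export
compute_ic <- function(probabilities, background = rep(1 / 20, 20)) {
  stopifnot(length(probabilities) == 20, length(background) == 20)
  if (any(background <= 0)) stop("background probabilities must be positive")
  if (any(probabilities < 0) || abs(sum(probabilities) - 1) > 1e-6) {
    stop("probabilities must be non-negative and sum to 1")
  }
  nz <- probabilities > 0
  sum(probabilities[nz] * log2(probabilities[nz] / background[nz]))
}

#' Deterministic fallback sequence profile
#'
#' When no precomputed PSSM is available, each position gets the BLOSUM62
#' substitution row of its observed residue as the 20 profile scores, and
#' the information content implied by the single-sequence (point-mass)
#' probability model: `log2(20)` bits for a known residue, 0 for UNK.
#'
#' @param sequence One-letter amino-acid string (or character vector).
#' @param chain Optional chain id to attach.
#' @return A `SequenceProfile` of the same length as `sequence`.
#' @export
fallback_profile <- function(sequence, chain = NULL) {
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1]] else sequence
  if (!length(aa)) stop("empty sequence")
  b62 <- blosum62_matrix()
  scores <- matrix(0, length(aa), 20, dimnames = list(NULL, AA_ORDER))
  known <- aa %in% AA_ORDER
  scores[known, ] <- b62[aa[known], AA_ORDER, drop = FALSE]
  ic <- vapply(aa, function(a) compute_ic(point_mass_prob(a)), numeric(1))
  structure(list(chain = chain, length = length(aa), sequence = aa,
                 scores = scores, ic = unname(ic)),
            class = "SequenceProfile")
}

blosum62_matrix <- function() {
  if (is.null(.dockgat_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .dockgat_env$blosum62 <- e$BLOSUM62
  }
  .dockgat_env$blosum62
}

#' Attach 26-D node features to a residue graph
#'
#' @param g A `ResidueGraph` from [build_graph()].
#' @param s The `Structure` the graph was built from.
#' @param profiles Optional named list of per-chain `SequenceProfile`s
#'   (names = chain ids). Each profile length must equal the chain's
#'   residue count.
#' @param fallback Use [fallback_profile()] for chains without a profile
#'   (default `TRUE`); if `FALSE`, a missing profile is an error.
#' @param squash Apply a logistic squash `1/(1+exp(-x))` to the 20 profile
#'   score columns (default `FALSE`: raw log-odds).
#' @return `g` with `node_features` set (`n_nodes x 26`).
#' @export
featurize <- function(g, s, profiles = NULL, fallback = TRUE, squash = FALSE) {
  stopifnot(inherits(g, "ResidueGraph"), inherits(s, "Structure"))
  if (g$n_nodes != nrow(s$residues)) stop("graph/structure node mismatch")
  pc <- physchem_encode(s$residues$aa)
  prof_block <- matrix(0, g$n_nodes, 21)
  for (ch in s$chains) {
    rows <- which(s$residues$chain == ch)
    prof <- profiles[[ch]]
    if (is.null(prof)) {
      if (!fallback) stop("no profile for chain ", ch, " and fallback disabled")
      prof <- fallback_profile(s$residues$aa[rows], chain = ch)
    }
    if (prof$length != length(rows)) {
      stop("profile for chain ", ch, " has ", prof$length,
           " positions but the chain has ", length(rows), " residues")
    }
    prof_block[rows, 1:20] <- if (squash) sigmoid(prof$scores) else prof$scores
    prof_block[rows, 21] <- prof$ic
  }
  feats <- cbind(pc, prof_block)
  colnames(feats) <- c(paste0("pc", 1:5), paste0("pssm_", AA_ORDER), "ic")
  g$node_features <- feats
  g
}
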