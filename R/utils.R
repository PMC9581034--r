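# Internal helpers shared across modules.

#' @importFrom data.table data.table setkey :=
NULL

.datatable.aware <- TRUE

# Amino-acid alphabet in PSSM column order (PSI-BLAST convention).
AA_ORDER <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

# Non-standard residues with an accepted parent; anything else becomes UNK.
AA_NONSTANDARD <- c(
  MSE = "M", SEC = "C", PYL = "K", CSO = "C", SEP = "S", TPO = "T",
  PTR = "Y", MLY = "K", HYP = "P", KCX = "K", CME = "C", CSD = "C",
  HSD = "H", HSE = "H", HSP = "H", AIB = "A", ORN = "K"
)

aa_three_to_one <- function(resname) {
  out <- AA3TO1[resname]
  ns <- is.na(out)
  out[ns] <- AA_NONSTANDARD[resname[ns]]
  out[is.na(out)] <- "X"
  unname(out)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Rotation matrix for angle theta about unit axis (Rodrigues).
rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

vnorm <- function(v) sqrt(sum(v^2))
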