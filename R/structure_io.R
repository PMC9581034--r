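#' Read a PDB coordinate file into a Structure
#'
#' Parses fixed-column `ATOM`/`HETATM` records of a multi-chain docking model
#' (native complex or decoy) into an internal `Structure` object. Only the
#' first `MODEL` is read; alternate locations are resolved to the
#' highest-occupancy atom; hydrogens are retained but flagged; `HETATM`
#' residues are kept only when they carry a CA atom (i.e. look like amino
#' acids), with non-standard names mapped to their parent residue where a
#' standard mapping exists and to `UNK` (`"X"`) otherwise.
#'
#' @param path Path to a PDB file with at least two chains.
#' @param target_id Identifier of the complex the model belongs to.
#' @param model_id Identifier of this model; defaults to the file name.
#' @param receptor_chains Optional character vector of chain ids forming the
#'   receptor; see [assign_partition()] for the default size heuristic.
#' @return A `Structure`: a list with `target_id`, `model_id`, `chains`
#'   (in order of first appearance), `residues` (data.frame with
#'   `residue_index`, `chain`, `seq_position`, `aa`), `atoms` (data.frame
#'   with `residue_index`, `name`, `element`, `x`, `y`, `z`,
#'   `is_hydrogen`), and `partition` (named vector chain ->
#'   `"receptor"`/`"ligand"`).
#' @export
read_pdb <- function(path, target_id, model_id = NULL, receptor_chains = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl)) lines <- lines[seq_len(endmdl[1] - 1L)]
  sel <- which(startsWith(lines, "ATOM  ") | startsWith(lines, "HETATM"))
  if (!length(sel)) stop("no ATOM records in ", path)
  rec <- lines[sel]

  fx <- function(a, b) trimws(substr(rec, a, b))
  atom_name <- fx(13, 16)
  altloc    <- substr(rec, 17, 17)
  resname   <- fx(18, 20)
  chain     <- substr(rec, 22, 22)
  resseq    <- fx(23, 26)
  icode     <- trimws(substr(rec, 27, 27))
  x <- suppressWarnings(as.numeric(substr(rec, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(rec, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(rec, 47, 54)))
  occ <- suppressWarnings(as.numeric(substr(rec, 55, 60)))
  occ[is.na(occ)] <- 1
  element <- toupper(fx(77, 78))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | chain == "" | resseq == "")
  if (length(bad)) {
    stop("unparseable ATOM record at line ", sel[bad[1]], " of ", path)
  }
  # infer element from the atom name when column 77-78 is absent
  noel <- element == ""
  if (any(noel)) {
    nm <- atom_name[noel]
    first <- substr(gsub("[0-9']", "", nm), 1, 1)
    element[noel] <- toupper(first)
  }

  is_het <- startsWith(rec, "HETATM")
  df <- data.frame(
    atom_name = atom_name, altloc = altloc, resname = resname,
    chain = chain, resseq = resseq, icode = icode,
    x = x, y = y, z = z, occ = occ, element = element, is_het = is_het,
    stringsAsFactors = FALSE
  )
  # drop waters and HETATM residues without a CA (non-amino-acid ligands)
  df <- df[df$resname != "HOH", , drop = FALSE]
  rkey <- paste(df$chain, df$resseq, df$icode, sep = "|")
  has_ca <- rkey %in% rkey[df$atom_name == "CA"]
  df <- df[!df$is_het | has_ca, , drop = FALSE]
  if (!nrow(df)) stop("no usable residues in ", path)

  # altloc: keep the highest-occupancy copy of each (residue, atom name)
  df$line <- seq_len(nrow(df))
  akey <- paste(df$chain, df$resseq, df$icode, df$atom_name, sep = "|")
  ord <- order(akey, -df$occ)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(paste(df$chain, df$resseq, df$icode, df$atom_name,
                             sep = "|")), , drop = FALSE]
  df <- df[order(df$line), , drop = FALSE]

  chains <- unique(chain)            # order of first appearance in file
  if (length(unique(df$chain)) < 2L) stop("not a complex: fewer than 2 chains")

  # order residues by (chain appearance, residue number, insertion code);
  # atoms keep their file order within a residue
  chain_rank <- match(df$chain, chains)
  ord <- order(chain_rank, as.integer(df$resseq), df$icode)
  df <- df[ord, , drop = FALSE]
  seq_position <- paste0(df$resseq, df$icode)
  rkey <- paste(df$chain, seq_position, sep = "|")
  residue_index <- cumsum(!duplicated(rkey))
  first <- !duplicated(rkey)

  s <- structure(list(
    target_id = target_id,
    model_id = model_id %||% sub("\\.pdb$", "", basename(path)),
    chains = intersect(chains, unique(df$chain)),
    residues = data.frame(
      residue_index = residue_index[first],
      chain = df$chain[first],
      seq_position = seq_position[first],
      aa = aa_three_to_one(df$resname[first]),
      resname = df$resname[first],
      stringsAsFactors = FALSE
    ),
    atoms = data.frame(
      residue_index = residue_index,
      name = df$atom_name,
      element = df$element,
      x = df$x, y = df$y, z = df$z,
      is_hydrogen = df$element == "H",
      stringsAsFactors = FALSE
    ),
    partition = NULL
  ), class = "Structure")
  assign_partition(s, receptor_chains)
}

#' Assign receptor/ligand roles to the chains of a Structure
#'
#' When `receptor_chains` is not given, the single chain with the most
#' residues becomes the receptor and all remaining chains form the ligand
#' (ties broken by lexicographic chain id). Docking decoy sets rarely state
#' which partner is which, so the convention is a size heuristic with an
#' explicit override.
#'
#' @param s A `Structure`.
#' @param receptor_chains Optional non-empty proper subset of `s$chains`.
#' @return `s` with `partition` set.
#' @export
assign_partition <- function(s, receptor_chains = NULL) {
  stopifnot(inherits(s, "Structure"))
  chains <- s$chains
  if (!is.null(receptor_chains)) {
    receptor_chains <- as.character(receptor_chains)
    if (!all(receptor_chains %in% chains)) {
      stop("unknown receptor chain(s): ",
           paste(setdiff(receptor_chains, chains), collapse = ","))
    }
    if (length(receptor_chains) == 0L || length(receptor_chains) >= length(chains)) {
      stop("receptor_chains must be a non-empty proper subset of chains")
    }
    rec <- receptor_chains
  } else {
    sizes <- table(factor(s$residues$chain, levels = chains))
    rec <- names(sizes)[order(-as.integer(sizes), names(sizes))][1]
  }
  part <- ifelse(chains %in% rec, "receptor", "ligand")
  names(part) <- chains
  s$partition <- part
  s
}

#' Write a Structure back to a PDB file
#'
#' Emits standard fixed-column `ATOM` records (one `TER` per chain). Round
#' trips with [read_pdb()]: residue count, chain ids and coordinates are
#' preserved to the 3-decimal precision of the format.
#'
#' @param s A `Structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "Structure"))
  res <- s$residues
  at <- s$atoms
  resname <- res$resname %||% rep("GLY", nrow(res))
  lines <- character(0)
  serial <- 0L
  for (ch in s$chains) {
    ridx <- res$residue_index[res$chain == ch]
    for (ri in ridx) {
      rows <- which(at$residue_index == ri)
      r <- res[res$residue_index == ri, ]
      resseq <- as.integer(sub("[A-Za-z]$", "", r$seq_position))
      icode <- sub("^[-0-9]+", "", r$seq_position)
      for (ai in rows) {
        serial <- serial + 1L
        nm <- at$name[ai]
        # column 13 is blank for names shorter than 4 chars
        nmfmt <- if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
        lines <- c(lines, sprintf(
          "ATOM  %5d %s %3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nmfmt, substr(resname[res$residue_index == ri], 1, 3),
          ch, resseq, ifelse(nchar(icode), icode, " "),
          at$x[ai], at$y[ai], at$z[ai], 1, 0, at$element[ai]
        ))
      }
    }
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

#' One-letter sequences of each chain
#'
#' @param s A `Structure`.
#' @return Named character vector, one sequence per chain.
#' @export
chain_sequences <- function(s) {
  stopifnot(inherits(s, "Structure"))
  out <- vapply(s$chains, function(ch) {
    paste(s$residues$aa[s$residues$chain == ch], collapse = "")
  }, character(1))
  names(out) <- s$chains
  out
}

# residue indices belonging to each partition
partition_indices <- function(s) {
  stopifnot(!is.null(s$partition))
  part <- s$partition[s$residues$chain]
  list(receptor = s$residues$residue_index[part == "receptor"],
       ligand = s$residues$residue_index[part == "ligand"])
}

# n_atoms x 3 coordinate matrix
atom_coords <- function(s) {
  cbind(s$atoms$x, s$atoms$y, s$atoms$z)
}

#' @export
print.Structure <- function(x, ...) {
  cat("Structure", x$target_id, "/", x$model_id, ":",
      length(x$chains), "chains,", nrow(x$residues), "residues,",
      nrow(x$atoms), "atoms\n")
  if (!is.null(x$partition)) {
    cat("  receptor:", paste(names(x$partition)[x$partition == "receptor"],
                             collapse = ","),
        " ligand:", paste(names(x$partition)[x$partition == "ligand"],
                          collapse = ","), "\n")
  }
  invisible(x)
}
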