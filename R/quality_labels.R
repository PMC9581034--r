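#' CAPRI-derived quality metrics for docking decoys
#'
#' A decoy is compared with its native complex through three standard
#' indicators: `fnat` (fraction of native cross-partition residue contacts
#' reproduced in the decoy), `lrmsd` (backbone RMSD of the ligand after
#' superposing decoy and native receptors) and `irmsd` (backbone RMSD of the
#' native-defined interface residues after superposing the interfaces).
#' The binary label collapses the CAPRI tiers: a decoy is *negative*
#' (incorrect) iff `fnat < 0.1` or (`lrmsd > 10.0` and `irmsd > 4.0`), and
#' *positive* (near-native) otherwise. All thresholds are strict.
#'
#' @name quality_labels
NULL

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

# 1:1 residue correspondence by (chain, seq_position); raises on mismatch,
# mirroring the removal of decoys whose sequences disagree with the native.
map_residues <- function(native, decoy) {
  nk <- paste(native$residues$chain, native$residues$seq_position)
  dk <- paste(decoy$residues$chain, decoy$residues$seq_position)
  idx <- match(nk, dk)
  if (anyNA(idx) || length(nk) != length(dk)) {
    stop("sequence inconsistency between native and decoy")
  }
  if (any(native$residues$aa != decoy$residues$aa[idx])) {
    stop("sequence inconsistency between native and decoy (residue identity)")
  }
  idx # decoy residue_index for each native residue_index
}

#' Native cross-partition residue contacts
#'
#' @param native A `Structure` with both partitions non-empty.
#' @param cutoff Heavy-atom distance threshold in Angstrom (default 5).
#' @return `ContactSet`: integer matrix with columns `receptor`, `ligand`
#'   holding residue indices of contacting cross-partition pairs
#'   (minimum atom-pair distance strictly below `cutoff`).
#' @export
native_contacts <- function(native, cutoff = 5) {
  stopifnot(inherits(native, "Structure"), cutoff > 0)
  part <- native$partition[native$residues$chain]
  if (!any(part == "receptor") || !any(part == "ligand")) {
    stop("both partitions must be non-empty")
  }
  pairs <- residue_contact_pairs(atom_coords(native),
                                 native$atoms$residue_index, cutoff)
  if (!nrow(pairs)) {
    out <- matrix(integer(0), 0, 2)
  } else {
    cross <- part[pairs[, 1]] != part[pairs[, 2]]
    pairs <- pairs[cross, , drop = FALSE]
    # orient as (receptor, ligand)
    swap <- part[pairs[, 1]] == "ligand"
    out <- pairs
    out[swap, ] <- pairs[swap, 2:1]
  }
  colnames(out) <- c("receptor", "ligand")
  out
}

#' Fraction of native contacts reproduced in a decoy
#'
#' @param native,decoy `Structure`s with 1:1 residue correspondence by
#'   (chain, residue number + insertion code).
#' @param cutoff Contact cutoff in Angstrom applied to both structures.
#' @param nat_contacts Optional precomputed [native_contacts()] of `native`
#'   at the same cutoff, to avoid rescanning the native per decoy.
#' @return `fnat` in `[0, 1]`.
#' @export
fnat <- function(native, decoy, cutoff = 5, nat_contacts = NULL) {
  idx <- map_residues(native, decoy)
  nat <- nat_contacts %||% native_contacts(native, cutoff)
  if (!nrow(nat)) stop("native structure has no cross-partition contacts")
  # inherit the native's receptor/ligand roles so pair orientation agrees
  if (setequal(decoy$chains, native$chains)) {
    decoy$partition <- native$partition[decoy$chains]
  }
  dec <- native_contacts(decoy, cutoff)
  natk <- paste(idx[nat[, 1]], idx[nat[, 2]])
  deck <- paste(dec[, 1], dec[, 2])
  sum(natk %in% deck) / nrow(nat)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between two
#' paired point sets, via SVD of the cross-covariance matrix with the usual
#' determinant sign correction.
#'
#' @param mobile,reference Numeric `n x 3` matrices, `n >= 3`, same `n`.
#' @return List with `rotation` (3x3, determinant +1), `translation`
#'   (length 3) and `rmsd`; the transform maps `mobile %*% rotation +
#'   translation` onto `reference`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3)
  if (nrow(mobile) != nrow(reference) || nrow(mobile) < 3) {
    stop("need >= 3 paired points")
  }
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)   # mobile %*% R aligns to reference
  t_vec <- cr - as.vector(cm %*% R)
  moved <- mobile %*% R
  moved <- sweep(moved, 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((moved - reference)^2)))
  list(rotation = R, translation = t_vec, rmsd = rmsd)
}

# paired backbone coordinate matrices over a residue subset.
# nat_res: native residue indices; idx maps native -> decoy residue index.
paired_backbone <- function(native, decoy, nat_res, idx) {
  sel_n <- native$atoms[native$atoms$residue_index %in% nat_res &
                          native$atoms$name %in% BACKBONE_ATOMS, ]
  if (!nrow(sel_n)) {
    sel_n <- native$atoms[native$atoms$residue_index %in% nat_res &
                            native$atoms$name == "CA", ]
  }
  key_n <- paste(idx[sel_n$residue_index], sel_n$name)
  key_d <- paste(decoy$atoms$residue_index, decoy$atoms$name)
  pos <- match(key_n, key_d)
  ok <- !is.na(pos)
  if (sum(ok) < 3) stop("no shared backbone atoms")
  nmat <- cbind(sel_n$x, sel_n$y, sel_n$z)[ok, , drop = FALSE]
  dmat <- cbind(decoy$atoms$x, decoy$atoms$y, decoy$atoms$z)[pos[ok], , drop = FALSE]
  list(native = nmat, decoy = dmat)
}

#' Ligand RMSD of a decoy
#'
#' Superposes the decoy receptor backbone onto the native receptor backbone
#' and reports the backbone RMSD over the ligand residues under that
#' transform. Backbone = N, CA, C, O when present (CA-only fallback).
#'
#' @inheritParams fnat
#' @return RMSD in Angstrom.
#' @export
lrmsd <- function(native, decoy) {
  idx <- map_residues(native, decoy)
  pi_nat <- partition_indices(native)
  rec <- paired_backbone(native, decoy, pi_nat$receptor, idx)
  fit <- kabsch_superpose(rec$decoy, rec$native)
  lig <- paired_backbone(native, decoy, pi_nat$ligand, idx)
  moved <- sweep(lig$decoy %*% fit$rotation, 2, fit$translation, `+`)
  sqrt(mean(rowSums((moved - lig$native)^2)))
}

#' Interface RMSD of a decoy
#'
#' Interface residues are defined on the *native*: any residue with an atom
#' strictly within `interface_cutoff` (default 10 Angstrom, the CAPRI
#' convention) of the opposite partition. The decoy's interface backbone is
#' superposed onto the native's and that minimised RMSD is reported.
#'
#' @inheritParams fnat
#' @param interface_cutoff Interface definition cutoff in Angstrom.
#' @param nat_interface Optional precomputed [interface_mask()] of the
#'   native at the same cutoff.
#' @return RMSD in Angstrom.
#' @export
irmsd <- function(native, decoy, interface_cutoff = 10, nat_interface = NULL) {
  idx <- map_residues(native, decoy)
  mask <- nat_interface %||% interface_mask(native, interface_cutoff)
  ires <- native$residues$residue_index[mask]
  if (length(ires) < 3) stop("fewer than 3 native interface residues")
  bb <- paired_backbone(native, decoy, ires, idx)
  kabsch_superpose(bb$decoy, bb$native)$rmsd
}

#' Binary CAPRI-derived label
#'
#' Negative (incorrect) iff `fnat < 0.1` or (`lrmsd > 10.0` and
#' `irmsd > 4.0`); positive otherwise. Inequalities are strict, so boundary
#' values are positive.
#'
#' @param fnat,lrmsd,irmsd Finite quality metrics.
#' @return `"positive"` or `"negative"` (vectorised).
#' @export
classify <- function(fnat, lrmsd, irmsd) {
  stopifnot(all(is.finite(fnat)), all(is.finite(lrmsd)), all(is.finite(irmsd)))
  ifelse(fnat < 0.1 | (lrmsd > 10.0 & irmsd > 4.0), "negative", "positive")
}

#' All quality metrics and the label for one decoy
#'
#' @inheritParams fnat
#' @inheritParams irmsd
#' @param contact_cutoff fnat contact cutoff (Angstrom).
#' @return One-row data.frame: `target_id`, `model_id`, `fnat`, `irmsd`,
#'   `lrmsd`, `label`.
#' @export
quality_metrics <- function(native, decoy, contact_cutoff = 5,
                            interface_cutoff = 10, nat_contacts = NULL,
                            nat_interface = NULL) {
  fn <- fnat(native, decoy, contact_cutoff, nat_contacts)
  lr <- lrmsd(native, decoy)
  ir <- irmsd(native, decoy, interface_cutoff, nat_interface)
  data.frame(
    target_id = decoy$target_id, model_id = decoy$model_id,
    fnat = fn, irmsd = ir, lrmsd = lr,
    label = classify(fn, lr, ir),
    stringsAsFactors = FALSE
  )
}

#' Label a directory (or list) of decoys against a native complex
#'
#' @param native A native `Structure`.
#' @param decoys List of decoy `Structure`s, or a directory of decoy PDBs.
#' @param out Optional TSV output path.
#' @inheritParams quality_metrics
#' @return data.frame of [quality_metrics()] rows.
#' @export
label_decoys <- function(native, decoys, out = NULL, contact_cutoff = 5,
                         interface_cutoff = 10) {
  if (is.character(decoys)) {
    files <- sort(list.files(decoys, pattern = "\\.pdb$", full.names = TRUE))
    decoys <- lapply(files, read_pdb, target_id = native$target_id)
  }
  res <- do.call(rbind, lapply(decoys, function(d) {
    quality_metrics(native, d, contact_cutoff, interface_cutoff)
  }))
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
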