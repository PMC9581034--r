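cfg_ql <- sim_config(res_receptor = 15, res_ligand = 10, seed = 11)
native_ql <- make_native(cfg_ql, 1)

test_that("native_contacts matches the brute-force scan and is cross-partition", {
  nc <- native_contacts(native_ql, 5)
  oracle <- oracle_contact_pairs(native_ql, 5)
  part <- native_ql$partition[native_ql$residues$chain]
  cross <- oracle[part[oracle[, 1]] != part[oracle[, 2]], , drop = FALSE]
  got <- cbind(pmin(nc[, 1], nc[, 2]), pmax(nc[, 1], nc[, 2]))
  expect_equal(got[order(got[, 1], got[, 2]), , drop = FALSE],
               cross[order(cross[, 1], cross[, 2]), , drop = FALSE],
               ignore_attr = TRUE)
  # same-partition pairs are never reported
  expect_true(all(part[nc[, 1]] == "receptor" & part[nc[, 2]] == "ligand"))
  # random blob structures, several seeds
  for (sd in 1:5) {
    s <- random_structure(seed = sd)
    nc <- native_contacts(s, 5)
    oracle <- oracle_contact_pairs(s, 5)
    part <- s$partition[s$residues$chain]
    cross <- oracle[part[oracle[, 1]] != part[oracle[, 2]], , drop = FALSE]
    expect_equal(nrow(nc), nrow(cross))
  }
})

test_that("fnat is 1 for the identity decoy and 0 for a far translation", {
  expect_equal(fnat(native_ql, native_ql), 1.0)
  far <- make_decoy_translated(native_ql, 100, c(1, 0, 0))
  expect_equal(fnat(native_ql, far), 0.0)
})

test_that("fnat counts reproduced contacts on a constructed fixture", {
  # construct a native with exactly 10 contacts and a decoy preserving 3:
  # residue pairs (i, i') at controlled distances
  mk <- function(dists) {
    res_list <- list(); atom_list <- list(); ridx <- 0
    for (i in 1:10) {
      ridx <- ridx + 1
      res_list[[ridx]] <- data.frame(residue_index = ridx, chain = "A",
                                     seq_position = as.character(i), aa = "A",
                                     resname = "ALA", stringsAsFactors = FALSE)
      atom_list[[ridx]] <- data.frame(residue_index = ridx, name = "CA",
                                      element = "C", x = i * 20, y = 0, z = 0,
                                      is_hydrogen = FALSE, stringsAsFactors = FALSE)
    }
    for (i in 1:10) {
      ridx <- ridx + 1
      res_list[[ridx]] <- data.frame(residue_index = ridx, chain = "B",
                                     seq_position = as.character(i), aa = "G",
                                     resname = "GLY", stringsAsFactors = FALSE)
      atom_list[[ridx]] <- data.frame(residue_index = ridx, name = "CA",
                                      element = "C", x = i * 20, y = dists[i], z = 0,
                                      is_hydrogen = FALSE, stringsAsFactors = FALSE)
    }
    s <- structure(list(target_id = "FX", model_id = "m", chains = c("A", "B"),
                        residues = do.call(rbind, res_list),
                        atoms = do.call(rbind, atom_list), partition = NULL),
                   class = "Structure")
    assign_partition(s, "A")
  }
  native <- mk(rep(3, 10))            # 10 contacts
  decoy <- mk(c(rep(3, 3), rep(8, 7))) # 3 preserved
  expect_equal(nrow(native_contacts(native)), 10)
  expect_equal(fnat(native, decoy), 0.3)
})

test_that("fnat raises on sequence inconsistency", {
  d <- native_ql
  d$residues$aa[1] <- if (d$residues$aa[1] == "A") "G" else "A"
  expect_error(fnat(native_ql, d), "sequence inconsistency")
  d2 <- native_ql
  d2$residues$seq_position[1] <- "999"
  expect_error(fnat(native_ql, d2), "sequence inconsistency")
})

test_that("kabsch_superpose recovers rigid motions and matches the quaternion oracle", {
  set.seed(3)
  ref <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(ref, ref)$rmsd, 0)
  # exact recovery of rotation + translation
  R90 <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  mob <- sweep(ref %*% R90, 2, c(5, 0, 0), `+`)
  fit <- kabsch_superpose(mob, ref)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # noisy cases equal the independent quaternion implementation
  for (sd in 1:10) {
    set.seed(sd)
    ref <- matrix(rnorm(12), 4, 3)
    mob <- ref %*% rotation_matrix_test(rnorm(3), runif(1, 0, pi)) +
      matrix(rnorm(12, sd = 0.5), 4, 3)
    expect_equal(kabsch_superpose(mob, ref)$rmsd,
                 oracle_superpose_rmsd(mob, ref), tolerance = 1e-6)
  }
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), ">= 3")
})

test_that("lrmsd: identity 0, planted translation d exact, global motion removed", {
  expect_lt(lrmsd(native_ql, native_ql), 1e-9)
  for (d in c(2.5, 10, 31.4)) {
    dec <- make_decoy_translated(native_ql, d, c(0.3, -1, 2))
    expect_equal(lrmsd(native_ql, dec), d, tolerance = 1e-6)
  }
  # whole-complex rigid motion leaves lrmsd at 0
  rot <- rotate_structure_test(native_ql, rotation_matrix_test(c(1, 2, 3), 1.1),
                               c(4, -2, 7))
  expect_lt(lrmsd(native_ql, rot), 1e-6)
  expect_lt(irmsd(native_ql, rot), 1e-6)
  expect_equal(fnat(native_ql, rot), 1.0)
})

test_that("irmsd equals an independent select-then-superpose reimplementation", {
  decs <- make_decoys(native_ql, sim_config(res_receptor = 15, res_ligand = 10,
                                            decoys_per_target = 6,
                                            positive_fraction = 0.5, seed = 2))
  for (dec in decs) {
    d <- dec$structure
    # independent: select native interface residues, gather backbone pairs,
    # then superpose with the quaternion oracle
    mask <- interface_mask(native_ql, 10)
    ires <- which(mask)
    bbsel <- native_ql$atoms$residue_index %in% ires &
      native_ql$atoms$name %in% c("N", "CA", "C", "O")
    natm <- atom_coords_test(native_ql)[bbsel, ]
    key_n <- paste(native_ql$atoms$residue_index, native_ql$atoms$name)[bbsel]
    key_d <- paste(d$atoms$residue_index, d$atoms$name)
    dmat <- atom_coords_test(d)[match(key_n, key_d), ]
    expect_equal(irmsd(native_ql, d), oracle_superpose_rmsd(dmat, natm),
                 tolerance = 1e-6)
  }
})

test_that("classify reproduces the printed predicate incl. boundaries", {
  expect_equal(classify(0.05, 2.0, 1.0), "negative")  # low fnat alone
  expect_equal(classify(0.5, 12.0, 3.0), "positive")  # conjunction incomplete
  expect_equal(classify(0.10, 10.0, 4.0), "positive") # strict boundaries
  # monotonicity: raising fnat or lowering RMSDs never flips pos -> neg
  set.seed(9)
  for (i in 1:200) {
    fn <- runif(1); lr <- runif(1, 0, 20); ir <- runif(1, 0, 8)
    if (classify(fn, lr, ir) == "positive") {
      expect_equal(classify(min(fn + runif(1, 0, .3), 1),
                            max(lr - runif(1, 0, 5), 0),
                            max(ir - runif(1, 0, 2), 0)), "positive")
    }
  }
})

test_that("label_decoys produces a labelled table over a decoy directory", {
  dir <- tempfile(); dir.create(dir)
  dec <- make_decoys(native_ql, sim_config(res_receptor = 15, res_ligand = 10,
                                           decoys_per_target = 3,
                                           positive_fraction = 0.5, seed = 4))
  for (d in dec) write_pdb(d$structure, file.path(dir, paste0(d$structure$model_id, ".pdb")))
  out <- tempfile(fileext = ".tsv")
  res <- label_decoys(native_ql, dir, out = out)
  expect_equal(nrow(res), 3)
  expect_true(all(c("target_id", "model_id", "fnat", "irmsd", "lrmsd", "label")
                  %in% names(res)))
  re <- utils::read.delim(out)
  expect_equal(re$label, res$label)
})
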