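# In-code fixtures: tiny PDB files and random structures/graphs.

pdb_atom_line <- function(serial, name, resname, chain, resseq, x, y, z,
                          altloc = " ", occ = 1, element = NULL, icode = " ",
                          record = "ATOM  ") {
  if (is.null(element)) element <- substr(name, 1, 1)
  nmfmt <- if (nchar(name) >= 4) substr(name, 1, 4) else sprintf(" %-3s", name)
  sprintf("%-6s%5d %s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nmfmt, altloc, resname, chain, resseq, icode,
          x, y, z, occ, 0, element)
}

# 2-chain, 4-residue toy complex (2 residues per chain, CA+CB each)
write_toy_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CB", "ALA", "A", 1, 1.5, 0, 0),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(4, "CB", "GLY", "A", 2, 4.5, 1, 0),
    pdb_atom_line(5, "CA", "LEU", "B", 1, 0, 4, 0),
    pdb_atom_line(6, "CB", "LEU", "B", 1, 1, 4.5, 0),
    pdb_atom_line(7, "CA", "TRP", "B", 2, 3.8, 4, 0),
    pdb_atom_line(8, "CB", "TRP", "B", 2, 4.2, 5, 0),
    "END"
  )
  writeLines(lines, path)
  path
}

# altloc A/B on one atom: highest occupancy must win
write_altloc_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0, altloc = "A", occ = 0.4),
    pdb_atom_line(2, "CA", "ALA", "A", 1, 0.5, 0, 0, altloc = "B", occ = 0.6),
    pdb_atom_line(3, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(4, "CA", "LEU", "B", 1, 0, 4, 0),
    pdb_atom_line(5, "CA", "TRP", "B", 2, 3.8, 4, 0),
    "END"
  )
  writeLines(lines, path)
  path
}

write_three_chain_pdb <- function(path = tempfile(fileext = ".pdb")) {
  lines <- c(
    pdb_atom_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", "A", 2, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "LEU", "B", 1, 0, 4, 0),
    pdb_atom_line(4, "CA", "TRP", "C", 1, 0, 8, 0),
    "END"
  )
  writeLines(lines, path)
  path
}

# random blob-shaped synthetic Structure (not via the simulator) for
# oracle comparisons; chains A/B with n_a/n_b residues, 1-4 atoms each
random_structure <- function(n_a = 6, n_b = 5, spread = 8, seed = 1) {
  set.seed(seed)
  res_list <- list(); atom_list <- list()
  ridx <- 0L
  for (spec in list(list(ch = "A", n = n_a, off = c(0, 0, 0)),
                    list(ch = "B", n = n_b, off = c(spread / 2, 0, 0)))) {
    for (i in seq_len(spec$n)) {
      ridx <- ridx + 1L
      centre <- runif(3, 0, spread) + spec$off
      k <- sample(1:4, 1)
      res_list[[ridx]] <- data.frame(
        residue_index = ridx, chain = spec$ch, seq_position = as.character(i),
        aa = sample(c("A", "G", "L", "W", "X"), 1), resname = "ALA",
        stringsAsFactors = FALSE
      )
      atom_list[[ridx]] <- data.frame(
        residue_index = ridx,
        name = c("CA", "CB", "CG", "CD")[seq_len(k)],
        element = "C",
        x = centre[1] + rnorm(k), y = centre[2] + rnorm(k),
        z = centre[3] + rnorm(k),
        is_hydrogen = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  s <- structure(list(
    target_id = "RND", model_id = "r1", chains = c("A", "B"),
    residues = do.call(rbind, res_list),
    atoms = do.call(rbind, atom_list), partition = NULL
  ), class = "Structure")
  assign_partition(s)
}

# small featurized random graph for model tests
random_graph <- function(n = 6, p_edge = 0.5, n_interface = 3, d = 26,
                         seed = 1, label = "unlabeled") {
  set.seed(seed)
  edges <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  edges <- edges[runif(nrow(edges)) < p_edge, , drop = FALSE]
  mask <- rep(FALSE, n)
  mask[sample.int(n, min(n_interface, n))] <- TRUE
  structure(list(
    target_id = "G", model_id = sprintf("g%d", seed), n_nodes = n,
    edges = unname(cbind(edges[, 1], edges[, 2])),
    node_features = matrix(rnorm(n * d), n, d),
    interface_mask = mask,
    partition_tag = rep(c("receptor", "ligand"), length.out = n),
    label = label, aa = rep("A", n), chain = rep("A", n),
    seq_position = as.character(seq_len(n)), format_version = 1L
  ), class = "ResidueGraph")
}

# apply a node permutation to a featurized graph
permute_graph <- function(g, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  g2 <- g
  g2$node_features <- g$node_features[perm, , drop = FALSE]
  g2$interface_mask <- g$interface_mask[perm]
  g2$partition_tag <- g$partition_tag[perm]
  g2$aa <- g$aa[perm]
  e <- g$edges
  e2 <- cbind(inv[e[, 1]], inv[e[, 2]])
  g2$edges <- cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
  g2
}

atom_coords_test <- function(s) cbind(s$atoms$x, s$atoms$y, s$atoms$z)

rotation_matrix_test <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

# apply a global rigid motion to every atom of a structure
rotate_structure_test <- function(s, R, t) {
  co <- atom_coords_test(s) %*% R
  co <- sweep(co, 2, t, `+`)
  s$atoms$x <- co[, 1]; s$atoms$y <- co[, 2]; s$atoms$z <- co[, 3]
  s
}

small_hyper <- function(...) {
  dgann_hyper(hidden = 8, k = 4, conv_channels = 3, dropout = 0, ...)
}
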