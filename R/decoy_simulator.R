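#' Synthetic native complexes and rigid-body decoys
#'
#' The simulator emulates the world the pipeline is built for without any
#' downloads: a toy two-chain native complex (idealized pseudo-peptide
#' helices, 3.8 A CA spacing, dummy N/C/O/CB atoms), rigid-body perturbed
#' decoys spanning the quality spectrum (sub-Angstrom moves for
#' near-natives; 5-10 A "hard" and 15-45 A "far" moves for incorrect
#' models), the extreme class imbalance the ensemble stage assumes, and an
#' optional planted feature signal that makes positives learnable so that
#' training can be tested for parameter recovery. Every decoy records its
#' ground-truth rigid transform, so the ligand RMSD of a pure translation is
#' analytically known.
#'
#' @name decoy_simulator
NULL

#' Simulator configuration
#'
#' @param n_targets Number of synthetic complexes (default 5).
#' @param res_receptor,res_ligand Residues per chain (defaults 30/20,
#'   desk-scale; the unequal sizes make the receptor/ligand size heuristic
#'   deterministic).
#' @param decoys_per_target Decoys per complex (default 200; the benchmark
#'   scale of thousands per complex is reached by raising this).
#' @param positive_fraction Intended fraction of near-native decoys
#'   (default 0.05, i.e. the 1:~20 imbalance at desk scale; the benchmark's
#'   1:100s regime uses smaller values).
#' @param pos_disp,far_disp Translation magnitude ranges (A) for
#'   near-native and far (non-contacting) negative decoys.
#' @param relocate_frac Fraction of negatives generated by re-docking the
#'   ligand onto a different receptor patch (contacting interface, no
#'   native contacts — the hard negatives real samplers produce);
#'   the rest are far translations.
#' @param pos_rot,neg_rot Max rotation angle (radians) about the ligand
#'   centroid for positives / far negatives.
#' @param signal_strength Additive shift planted on feature columns of
#'   interface residues of positive decoys (default 0 = no signal).
#' @param signal_columns Feature columns carrying the planted signal.
#' @param seed Root integer seed.
#' @return `SimConfig` list.
#' @export
sim_config <- function(n_targets = 5, res_receptor = 30, res_ligand = 20,
                       decoys_per_target = 200, positive_fraction = 0.05,
                       pos_disp = c(0, 1), far_disp = c(15, 45),
                       relocate_frac = 0.6, pos_rot = 0.05, neg_rot = 0.2,
                       signal_strength = 0, signal_columns = 1:5, seed = 1) {
  stopifnot(positive_fraction >= 0, positive_fraction < 1,
            res_receptor >= 5, res_ligand >= 5, all(pos_disp >= 0),
            relocate_frac >= 0, relocate_frac <= 1)
  list(n_targets = n_targets, res_receptor = res_receptor,
       res_ligand = res_ligand, decoys_per_target = decoys_per_target,
       positive_fraction = positive_fraction, pos_disp = pos_disp,
       far_disp = far_disp, relocate_frac = relocate_frac,
       pos_rot = pos_rot, neg_rot = neg_rot,
       signal_strength = signal_strength,
       signal_columns = signal_columns, seed = seed)
}

# idealized helical CA trace with ~3.8 A consecutive spacing
helix_trace <- function(n_res) {
  w <- 100 * pi / 180
  r <- 2.3
  rise <- sqrt(max(3.8^2 - 2 * r^2 * (1 - cos(w)), 0.5))
  i <- seq_len(n_res)
  cbind(r * cos(w * i), r * sin(w * i), rise * i)
}

# N/CA/C/O/CB dummy atoms around each CA using the local chain direction
build_chain_atoms <- function(ca) {
  n <- nrow(ca)
  dirs <- ca[pmin(n, seq_len(n) + 1L), , drop = FALSE] -
    ca[pmax(1L, seq_len(n) - 1L), , drop = FALSE]
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    d <- dirs[i, ]; d <- d / max(vnorm(d), 1e-9)
    ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    p <- c(d[2] * ref[3] - d[3] * ref[2],
           d[3] * ref[1] - d[1] * ref[3],
           d[1] * ref[2] - d[2] * ref[1])
    p <- p / vnorm(p)
    q <- c(d[2] * p[3] - d[3] * p[2],
           d[3] * p[1] - d[1] * p[3],
           d[1] * p[2] - d[2] * p[1])
    pos <- rbind(ca[i, ] - 1.2 * d,        # N
                 ca[i, ],                  # CA
                 ca[i, ] + 1.2 * d,        # C
                 ca[i, ] + 1.2 * d + 1.23 * p,  # O
                 ca[i, ] + 1.53 * q)       # CB
    atoms[[i]] <- pos
  }
  do.call(rbind, atoms)
}

ATOM_NAMES <- c("N", "CA", "C", "O", "CB")
ATOM_ELEMENTS <- c("N", "C", "C", "O", "C")

as_sim_structure <- function(target_id, model_id, chains_coords, chains_aa) {
  chains <- names(chains_coords)
  res_list <- list(); atom_list <- list()
  ridx <- 0L
  aa1to3 <- stats::setNames(names(AA3TO1), AA3TO1)
  for (ch in chains) {
    co <- chains_coords[[ch]]
    aa <- chains_aa[[ch]]
    n <- length(aa)
    for (i in seq_len(n)) {
      ridx <- ridx + 1L
      res_list[[ridx]] <- data.frame(
        residue_index = ridx, chain = ch, seq_position = as.character(i),
        aa = aa[i], resname = unname(aa1to3[aa[i]]),
        stringsAsFactors = FALSE
      )
      rows <- ((i - 1L) * 5L + 1L):(i * 5L)
      atom_list[[ridx]] <- data.frame(
        residue_index = ridx, name = ATOM_NAMES, element = ATOM_ELEMENTS,
        x = co[rows, 1], y = co[rows, 2], z = co[rows, 3],
        is_hydrogen = FALSE, stringsAsFactors = FALSE
      )
    }
  }
  s <- structure(list(
    target_id = target_id, model_id = model_id, chains = chains,
    residues = do.call(rbind, res_list),
    atoms = do.call(rbind, atom_list),
    partition = NULL
  ), class = "Structure")
  assign_partition(s)
}

# Slide a ligand (coordinates relative to the receptor centroid) along -u
# until >= min_contacts cross residue contacts form without a clash
# (min atom distance <= 2.5 A). Returns the translation scalar t such that
# ligand + t*u is docked, or NULL when a clash precedes enough contacts.
slide_into_contact <- function(rec_atoms, rec_res, lig_atoms, lig_res, u,
                               rec_cent, min_contacts = 3, cutoff = 5,
                               step = 0.25) {
  proj_rec <- as.vector(sweep(rec_atoms, 2, rec_cent) %*% u)
  proj_lig <- as.vector(lig_atoms %*% u)
  t0 <- max(proj_rec) - min(proj_lig) + cutoff + 1.5
  for (t in seq(t0, 2, by = -step)) {
    cand <- sweep(lig_atoms, 2, rec_cent + t * u, `+`)
    cc <- count_cross_contacts(rec_atoms, cand, rec_res, lig_res, cutoff)
    if (cc$mind <= 2.5) return(NULL)
    if (cc$n >= min_contacts) return(t)
  }
  NULL
}

# count residue-residue cross-chain contacts below 5 A
count_cross_contacts <- function(rec_atoms, lig_atoms, rec_res, lig_res,
                                 cutoff = 5) {
  d2 <- outer(rowSums(rec_atoms^2), rowSums(lig_atoms^2), `+`) -
    2 * rec_atoms %*% t(lig_atoms)
  mind <- sqrt(max(min(d2), 0))
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (!nrow(hit)) return(list(n = 0L, mind = mind))
  pairs <- unique(cbind(rec_res[hit[, 1]], lig_res[hit[, 2]]))
  list(n = nrow(pairs), mind = mind)
}

#' Generate a synthetic native complex
#'
#' Two idealized pseudo-peptide chains (receptor chain A, ligand chain B)
#' docked so that at least 3 cross-chain residue contacts lie below 5 A with
#' no steric clash (minimum atom distance > 2.5 A). Deterministic per
#' (seed, target index).
#'
#' @param cfg A `SimConfig`.
#' @param target_index 1-based target index.
#' @return A `Structure` with `target_id = sprintf("T%03d", target_index)`.
#' @export
make_native <- function(cfg = sim_config(), target_index = 1) {
  stopifnot(cfg$res_receptor >= 5, cfg$res_ligand >= 5)
  with_seed(cfg$seed + 7919L * target_index, {
    rec_ca <- helix_trace(cfg$res_receptor)
    rec_ca <- sweep(rec_ca, 2, colMeans(rec_ca))
    Rr <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
    rec_ca <- rec_ca %*% Rr
    rec_atoms <- build_chain_atoms(rec_ca)
    rec_res <- rep(seq_len(cfg$res_receptor), each = 5L)

    lig_ca0 <- helix_trace(cfg$res_ligand)
    lig_ca0 <- sweep(lig_ca0, 2, colMeans(lig_ca0))
    lig_res <- rep(seq_len(cfg$res_ligand), each = 5L)

    rec_cent <- colMeans(rec_atoms)
    placed <- NULL
    for (try in 1:50) {
      Rl <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
      u <- stats::rnorm(3); u <- u / vnorm(u)
      lig_atoms0 <- build_chain_atoms(lig_ca0 %*% Rl)
      lig_atoms0 <- sweep(lig_atoms0, 2, colMeans(lig_atoms0))
      t <- slide_into_contact(rec_atoms, rec_res, lig_atoms0, lig_res, u,
                              rec_cent, min_contacts = 3)
      if (!is.null(t)) {
        placed <- sweep(lig_atoms0, 2, rec_cent + t * u, `+`)
        break
      }
    }
    if (is.null(placed)) stop("failed to dock synthetic chains")

    aa <- list(
      A = sample(AA_ORDER, cfg$res_receptor, replace = TRUE),
      B = sample(AA_ORDER, cfg$res_ligand, replace = TRUE)
    )
    as_sim_structure(sprintf("T%03d", target_index), "native",
                     list(A = rec_atoms, B = placed), aa)
  })
}

# apply a rigid transform (rotate about ligand centroid, then translate)
# to the ligand partition of a structure
transform_ligand <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  lig_chains <- names(s$partition)[s$partition == "ligand"]
  lig_res <- s$residues$residue_index[s$residues$chain %in% lig_chains]
  rows <- s$atoms$residue_index %in% lig_res
  co <- cbind(s$atoms$x[rows], s$atoms$y[rows], s$atoms$z[rows])
  centroid <- colMeans(co)
  moved <- sweep(sweep(co, 2, centroid) %*% rotation, 2,
                 centroid + translation, `+`)
  s$atoms$x[rows] <- moved[, 1]
  s$atoms$y[rows] <- moved[, 2]
  s$atoms$z[rows] <- moved[, 3]
  s
}

#' Generate rigid-body decoys of a native complex
#'
#' Each decoy moves the ligand partition by a sampled rigid transform: with
#' probability `positive_fraction` a near-native move (small rotation,
#' translation from `pos_disp`); otherwise either a relocation onto a
#' different receptor patch (probability `relocate_frac` among negatives:
#' the approach direction is rotated by 90-180 degrees, the ligand
#' re-oriented at random and slid back into contact) or a far translation
#' from `far_disp`. The applied transform is returned with each decoy; true
#' labels must still be computed with [quality_metrics()].
#'
#' @param native From [make_native()].
#' @param cfg A `SimConfig`.
#' @return List of `list(structure, rotation, translation, magnitude,
#'   angle, intended)`.
#' @export
make_decoys <- function(native, cfg = sim_config()) {
  stopifnot(inherits(native, "Structure"))
  tgt_seed <- cfg$seed + 7919L * as.integer(sub("^T", "", native$target_id)) + 31L
  pidx <- partition_indices(native)
  arows <- native$atoms$residue_index %in% pidx$receptor
  rec_atoms <- atom_coords(native)[arows, , drop = FALSE]
  rec_res <- native$atoms$residue_index[arows]
  lig_atoms0 <- atom_coords(native)[!arows, , drop = FALSE]
  lig_res <- native$atoms$residue_index[!arows]
  rec_cent <- colMeans(rec_atoms)
  lig_cent <- colMeans(lig_atoms0)
  with_seed(tgt_seed, {
    lapply(seq_len(cfg$decoys_per_target), function(i) {
      pos <- stats::runif(1) < cfg$positive_fraction
      relocate <- !pos && stats::runif(1) < cfg$relocate_frac
      if (relocate) {
        # spin the approach direction 90-180 degrees about the receptor and
        # slide the randomly re-oriented ligand back into contact
        w0 <- lig_cent - rec_cent; w0 <- w0 / vnorm(w0)
        perp <- stats::rnorm(3); perp <- perp - sum(perp * w0) * w0
        perp <- perp / vnorm(perp)
        theta <- stats::runif(1, pi / 2, pi)
        w1 <- cos(theta) * w0 + sin(theta) * perp
        R <- rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
        spun <- sweep(lig_atoms0, 2, lig_cent) %*% R
        t <- slide_into_contact(rec_atoms, rec_res, spun, lig_res, w1,
                                rec_cent, min_contacts = 1, step = 0.5)
        if (is.null(t)) t <- 30
        tvec <- rec_cent + t * w1 - lig_cent
        d <- vnorm(tvec); ang <- NA_real_
      } else {
        if (pos) {
          d <- stats::runif(1, cfg$pos_disp[1], cfg$pos_disp[2])
          ang <- stats::runif(1, 0, cfg$pos_rot)
        } else {
          d <- stats::runif(1, cfg$far_disp[1], cfg$far_disp[2])
          ang <- stats::runif(1, 0, cfg$neg_rot)
        }
        u <- stats::rnorm(3); u <- u / vnorm(u)
        R <- rotation_matrix(stats::rnorm(3), ang)
        tvec <- d * u
      }
      s <- transform_ligand(native, R, tvec)
      s$model_id <- sprintf("d%04d", i)
      list(structure = s, rotation = R, translation = tvec,
           magnitude = d, angle = ang,
           intended = ifelse(pos, "positive", "negative"))
    })
  })
}

#' Pure-translation decoy with analytically known ligand RMSD
#'
#' Translating a rigid ligand by `d` preserves every per-atom deviation, so
#' `lrmsd(native, decoy) == d` exactly (to superposition tolerance).
#'
#' @param native From [make_native()].
#' @param d Translation magnitude in Angstrom.
#' @param direction Translation direction (default x).
#' @param model_id Decoy id.
#' @return A `Structure`.
#' @export
make_decoy_translated <- function(native, d, direction = c(1, 0, 0),
                                  model_id = "trans") {
  u <- direction / vnorm(direction)
  s <- transform_ligand(native, diag(3), d * u)
  s$model_id <- model_id
  s
}

#' Plant a separable feature signal on positive graphs
#'
#' Adds `sigma` to the stated feature columns of the *interface* nodes of
#' positive-labelled graphs; negatives are never modified. Deterministic.
#'
#' @param graphs List of labelled, featurized `ResidueGraph`s.
#' @param sigma Signal strength (additive shift).
#' @param columns Feature column indices (default 1:5).
#' @param seed Unused placeholder kept for interface stability.
#' @return The modified list of graphs.
#' @export
plant_signal <- function(graphs, sigma, columns = 1:5, seed = NULL) {
  if (sigma == 0) return(graphs)
  lapply(graphs, function(g) {
    if (identical(g$label, "positive") && any(g$interface_mask)) {
      g$node_features[g$interface_mask, columns] <-
        g$node_features[g$interface_mask, columns] + sigma
    }
    g
  })
}

#' Simulate, label, graph and featurize a full synthetic dataset
#'
#' Runs the whole upstream pipeline for `cfg$n_targets` complexes: native
#' generation, decoy sampling, CAPRI labelling, graph construction,
#' featurization (fallback profiles) and optional signal planting.
#'
#' @param cfg A `SimConfig`.
#' @param edge_cutoff Graph edge / interface cutoff (default 5 A).
#' @return List with `natives` (per target), `labels` (data.frame of
#'   quality metrics for every decoy), `graphs` (named list,
#'   `target_id/model_id`), `transforms` (per decoy ground truth),
#'   `sequences` (named per-target concatenated chain sequences).
#' @export
simulate_dataset <- function(cfg = sim_config(), edge_cutoff = 5) {
  natives <- list(); labels <- list(); graphs <- list(); transforms <- list()
  sequences <- character(0)
  for (ti in seq_len(cfg$n_targets)) {
    native <- make_native(cfg, ti)
    natives[[native$target_id]] <- native
    sequences[native$target_id] <- paste(chain_sequences(native), collapse = "")
    decoys <- make_decoys(native, cfg)
    nat_con <- native_contacts(native, 5)
    nat_ifc <- interface_mask(native, 10)
    for (dec in decoys) {
      met <- quality_metrics(native, dec$structure,
                             nat_contacts = nat_con, nat_interface = nat_ifc)
      g <- build_graph(dec$structure, edge_cutoff)
      g <- featurize(g, dec$structure)
      g$label <- met$label
      key <- paste(native$target_id, dec$structure$model_id, sep = "/")
      labels[[key]] <- met
      graphs[[key]] <- g
      transforms[[key]] <- dec[c("rotation", "translation", "magnitude",
                                 "angle", "intended")]
    }
  }
  graphs <- plant_signal(graphs, cfg$signal_strength, cfg$signal_columns)
  list(natives = natives, labels = do.call(rbind, labels), graphs = graphs,
       transforms = transforms, sequences = sequences)
}
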