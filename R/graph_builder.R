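#' Residue contact graph construction
#'
#' A docking model is represented as a residue-level graph over the *whole*
#' complex: one node per residue, and an undirected edge between two
#' residues whenever the minimum distance over all atom pairs is strictly
#' below the cutoff (default 5 Angstrom). Neighbor search uses a cell list
#' (spatial hash) with cell size equal to the cutoff, so only atoms in the
#' 27 surrounding cells are examined.
#'
#' @name graph_builder
NULL

# All residue pairs (i < j) whose minimum atom-atom distance is < cutoff.
# Two equivalent strategies: a vectorized all-pairs scan (fast for the small
# structures decoy sets are made of) and a cell-list spatial hash whose cost
# scales with local density rather than m^2. "auto" switches at 600 atoms.
residue_contact_pairs <- function(coords, res_idx, cutoff,
                                  method = c("auto", "cell", "dense")) {
  method <- match.arg(method)
  m <- nrow(coords)
  if (m < 2L) return(matrix(integer(0), 0, 2))
  if (method == "dense" || (method == "auto" && m <= 2000L)) {
    # bounding-sphere prefilter on residue centroids, then exact per-pair
    # atom block minima
    res_ids <- sort(unique(res_idx))
    pos <- match(res_idx, res_ids)
    nres <- length(res_ids)
    cent <- rowsum(coords, pos) / as.vector(table(pos))
    dr <- sqrt(rowSums((coords - cent[pos, , drop = FALSE])^2))
    rad <- vapply(split(dr, pos), max, numeric(1))
    csq <- rowSums(cent^2)
    dc <- sqrt(pmax(outer(csq, csq, `+`) - 2 * tcrossprod(cent), 0))
    lim <- outer(rad, rad, `+`) + cutoff
    cand <- which(dc < lim & upper.tri(dc), arr.ind = TRUE)
    if (!nrow(cand)) return(matrix(integer(0), 0, 2))
    alist <- split(seq_len(m), pos)
    sq <- rowSums(coords^2)
    keep <- logical(nrow(cand))
    for (kk in seq_len(nrow(cand))) {
      ai <- alist[[cand[kk, 1]]]; aj <- alist[[cand[kk, 2]]]
      d2 <- outer(sq[ai], sq[aj], `+`) -
        2 * coords[ai, , drop = FALSE] %*% t(coords[aj, , drop = FALSE])
      keep[kk] <- min(d2) < cutoff^2
    }
    pairs <- cbind(res_ids[cand[keep, 1]], res_ids[cand[keep, 2]])
    if (!nrow(pairs)) return(matrix(integer(0), 0, 2))
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    return(pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE])
  }
  cell <- floor(coords / cutoff)
  dt <- data.table::data.table(
    id = seq_len(m), r = res_idx,
    x = coords[, 1], y = coords[, 2], z = coords[, 3],
    cx = as.integer(cell[, 1]), cy = as.integer(cell[, 2]),
    cz = as.integer(cell[, 3])
  )
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  # keep the home cell and one representative of each +/- offset pair
  keep <- apply(offs, 1, function(o) {
    o[1] > 0 || (o[1] == 0 && (o[2] > 0 || (o[2] == 0 && o[3] >= 0)))
  })
  offs <- offs[keep, , drop = FALSE]
  data.table::setkey(dt, cx, cy, cz)
  acc <- vector("list", nrow(offs))
  for (oi in seq_len(nrow(offs))) {
    o <- offs[oi, ]
    probe <- data.table::data.table(
      cx = dt$cx + o[1], cy = dt$cy + o[2], cz = dt$cz + o[3],
      id1 = dt$id, r1 = dt$r, x1 = dt$x, y1 = dt$y, z1 = dt$z
    )
    hit <- dt[probe, on = c("cx", "cy", "cz"), nomatch = NULL,
              allow.cartesian = TRUE]
    if (!nrow(hit)) next
    if (all(o == 0)) hit <- hit[hit$id > hit$id1, ]
    if (!nrow(hit)) next
    d2 <- (hit$x - hit$x1)^2 + (hit$y - hit$y1)^2 + (hit$z - hit$z1)^2
    hit <- hit[d2 < cutoff^2 & hit$r != hit$r1, ]
    if (nrow(hit)) {
      acc[[oi]] <- cbind(pmin(hit$r, hit$r1), pmax(hit$r, hit$r1))
    }
  }
  pairs <- do.call(rbind, acc)
  if (is.null(pairs) || !nrow(pairs)) return(matrix(integer(0), 0, 2))
  pairs <- unique(pairs)
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

#' Build the residue contact graph of a docking model
#'
#' @param s A `Structure` with its partition assigned.
#' @param edge_cutoff Distance threshold in Angstrom; an edge connects two
#'   residues iff some atom pair is strictly closer than this (default 5).
#' @param interface_cutoff Cutoff used for the interface mask; defaults to
#'   `edge_cutoff` so that a node is at the interface exactly when it has a
#'   cross-partition edge.
#' @return A `ResidueGraph`: list with `n_nodes`, `edges` (2-column matrix,
#'   `i < j`, deduplicated, no self-edges), `node_features` (`NULL` until
#'   [featurize()]), `interface_mask`, `partition_tag`, `label`
#'   (`"unlabeled"` until set), plus node metadata (`aa`, `chain`,
#'   `seq_position`) and ids.
#' @export
build_graph <- function(s, edge_cutoff = 5, interface_cutoff = edge_cutoff) {
  stopifnot(inherits(s, "Structure"), edge_cutoff > 0)
  coords <- atom_coords(s)
  edges <- residue_contact_pairs(coords, s$atoms$residue_index, edge_cutoff)
  part <- unname(s$partition[s$residues$chain])
  # with equal cutoffs the interface mask is exactly cross-partition edge
  # incidence, so the edge scan can be reused
  mask <- if (interface_cutoff == edge_cutoff) {
    m <- rep(FALSE, nrow(s$residues))
    if (nrow(edges)) {
      cross <- part[edges[, 1]] != part[edges[, 2]]
      m[unique(as.vector(edges[cross, , drop = FALSE]))] <- TRUE
    }
    m
  } else interface_mask(s, interface_cutoff)
  g <- structure(list(
    target_id = s$target_id,
    model_id = s$model_id,
    n_nodes = nrow(s$residues),
    edges = edges,
    node_features = NULL,
    interface_mask = mask,
    partition_tag = part,
    label = "unlabeled",
    aa = s$residues$aa,
    chain = s$residues$chain,
    seq_position = s$residues$seq_position,
    format_version = 1L
  ), class = "ResidueGraph")
  g
}

#' Interface mask of a docking model
#'
#' A residue is flagged as interface when any of its atoms lies strictly
#' within `cutoff` of any atom of the opposite partition.
#'
#' @param s A `Structure` with partition assigned.
#' @param cutoff Distance threshold in Angstrom (default 5, the edge cutoff).
#' @return Logical vector, one entry per residue.
#' @export
interface_mask <- function(s, cutoff = 5) {
  stopifnot(inherits(s, "Structure"), !is.null(s$partition))
  part <- s$partition[s$residues$chain]
  if (!any(part == "receptor") || !any(part == "ligand")) {
    stop("both partitions must be non-empty")
  }
  coords <- atom_coords(s)
  pairs <- residue_contact_pairs(coords, s$atoms$residue_index, cutoff)
  mask <- rep(FALSE, nrow(s$residues))
  if (nrow(pairs)) {
    cross <- part[pairs[, 1]] != part[pairs[, 2]]
    mask[unique(as.vector(pairs[cross, , drop = FALSE]))] <- TRUE
  }
  mask
}

#' Serialize a ResidueGraph to a versioned JSON container
#'
#' The on-disk layout is plain JSON: node table (aa, chain, seq_position,
#' partition, interface flag), edge list, optional feature matrix, label and
#' a `format_version` field. Round-trips losslessly (coordinates are not
#' part of a graph).
#'
#' @param g A `ResidueGraph`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graph <- function(g, path) {
  stopifnot(inherits(g, "ResidueGraph"))
  obj <- list(
    format_version = g$format_version %||% 1L,
    target_id = g$target_id, model_id = g$model_id,
    n_nodes = g$n_nodes,
    edges = if (nrow(g$edges)) unclass(as.data.frame(g$edges)) else list(),
    interface_mask = g$interface_mask,
    partition_tag = g$partition_tag,
    label = g$label,
    aa = g$aa, chain = g$chain, seq_position = g$seq_position,
    node_features = if (!is.null(g$node_features)) g$node_features else NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format_version) || obj$format_version != 1L) {
    stop("unsupported graph format version")
  }
  edges <- if (length(obj$edges)) {
    cbind(as.integer(obj$edges[[1]]), as.integer(obj$edges[[2]]))
  } else matrix(integer(0), 0, 2)
  structure(list(
    target_id = obj$target_id, model_id = obj$model_id,
    n_nodes = as.integer(obj$n_nodes),
    edges = edges,
    node_features = if (!is.null(obj$node_features)) as.matrix(obj$node_features) else NULL,
    interface_mask = as.logical(obj$interface_mask),
    partition_tag = obj$partition_tag,
    label = obj$label,
    aa = obj$aa, chain = obj$chain, seq_position = obj$seq_position,
    format_version = 1L
  ), class = "ResidueGraph")
}

#' @export
print.ResidueGraph <- function(x, ...) {
  cat("ResidueGraph", x$target_id, "/", x$model_id, ":",
      x$n_nodes, "nodes,", nrow(x$edges), "edges,",
      sum(x$interface_mask), "interface nodes, label =", x$label, "\n")
  invisible(x)
}
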