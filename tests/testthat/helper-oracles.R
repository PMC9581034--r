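# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (cell lists, SVD Kabsch, vectorised softmax, ranking) so
# they can arbitrate correctness.

# O(N^2 M^2) residue contact scan: explicit double loop over residues and
# per-atom distance minima.
oracle_contact_pairs <- function(s, cutoff) {
  n <- nrow(s$residues)
  co <- cbind(s$atoms$x, s$atoms$y, s$atoms$z)
  ri <- s$atoms$residue_index
  out <- list()
  for (i in seq_len(n - 1)) {
    A <- co[ri == i, , drop = FALSE]
    for (j in (i + 1):n) {
      B <- co[ri == j, , drop = FALSE]
      mind2 <- Inf
      for (a in seq_len(nrow(A))) {
        mind2 <- min(mind2, min(rowSums(sweep(B, 2, A[a, ])^2)))
      }
      if (mind2 < cutoff^2) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

# Horn (1987) quaternion superposition: closed-form optimal rotation from
# the maximal eigenvector of the 4x4 correlation form.
oracle_superpose_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(A, B)
  N <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2], S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3], S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1], -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3], S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]
  ), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

# EF by literal counting in the sorted top window.
oracle_ef <- function(scores, labels, x_percent, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("m%09d", seq_along(scores))
  y <- if (is.character(labels)) labels == "positive" else labels > 0
  n <- length(scores)
  n_top <- max(1, round(x_percent / 100 * n))
  ord <- order(-scores, ids)
  hits <- 0
  for (r in seq_len(n_top)) if (y[ord[r]]) hits <- hits + 1
  (hits / n_top) * (n / sum(y))
}

# explicit exp/sum softmax over each node's neighbourhood (self-loop added)
oracle_attention <- function(h, W, edges) {
  n <- nrow(h)
  G <- h %*% W
  nb <- lapply(seq_len(n), function(i) i)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1]; j <- edges[e, 2]
    nb[[i]] <- union(nb[[i]], j)
    nb[[j]] <- union(nb[[j]], i)
  }
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ex <- vapply(nb[[i]], function(j) exp(sum(G[i, ] * G[j, ])), numeric(1))
    A[i, nb[[i]]] <- ex / sum(ex)
  }
  A
}

# hand-rolled per-node GAT layer loop
oracle_gat_layer <- function(h, W, edges) {
  A <- oracle_attention(h, W, edges)
  n <- nrow(h)
  G <- h %*% W
  out <- matrix(0, n, ncol(G))
  for (i in seq_len(n)) {
    acc <- rep(0, ncol(G))
    for (j in seq_len(n)) acc <- acc + A[i, j] * G[j, ]
    out[i, ] <- tanh(acc)
  }
  out
}
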