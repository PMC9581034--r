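#' Graph attention classifier for docking decoys
#'
#' The classifier stacks graph-attention (GAT) layers over the residue
#' contact graph of the whole docking model, pools the interface nodes with
#' sort-based top-k pooling, and scores the pooled embedding with a 1-D
#' convolution plus a fully-connected sigmoid head:
#'
#' * layer 1 maps the 26-D node attributes to 32-D embeddings with a shared
#'   26 x 32 weight matrix; the attention logit between neighbours is the
#'   dot product `e_ij = (W h_i) . (W h_j)`, softmax-normalised over the
#'   neighbourhood (self-loops added); activation `tanh`;
#' * layer 2 maps 32-D embeddings to a scalar per node (shared 32 x 1
#'   weights) interpreted as node importance;
#' * top-k pooling keeps the k most important *interface* nodes (stable
#'   ties by node ordinal), concatenates the last hidden embedding (32)
#'   with the importance (1) per kept node, and zero-pads to `k x 33`;
#' * the head applies a kernel-size-1 1-D convolution (33 -> 16 channels,
#'   ReLU), flattens, and a fully-connected layer with sigmoid produces the
#'   near-native probability. Dropout (0.5) acts on the fully-connected
#'   input during training only.
#'
#' The canonical concat-form GAT attention (`attention = "gat_v1"`), global
#' mean/max interface pooling (`pooling`), and 1-4 stacked layers are
#' selectable; with a single layer the raw node attributes of the pooled
#' nodes are read out directly and the layer provides importances only.
#'
#' @name dgann_model
NULL

#' Hyper-parameter set for a classifier
#'
#' @param n_layers Number of stacked GAT layers (1-4; default 2).
#' @param hidden Hidden embedding width (default 32).
#' @param k Top-k pooling size (default 100).
#' @param conv_channels Channels of the kernel-1 convolution (default 16).
#' @param dropout Dropout rate on the fully-connected input (default 0.5).
#' @param attention `"dot"` (printed-equation form) or `"gat_v1"`
#'   (canonical concat form with LeakyReLU).
#' @param pooling `"topk"`, `"mean"` or `"max"` (global interface pooling).
#' @param in_dim Node feature dimension (default 26).
#' @return Named list of hyper-parameters.
#' @export
dgann_hyper <- function(n_layers = 2, hidden = 32, k = 100, conv_channels = 16,
                        dropout = 0.5, attention = c("dot", "gat_v1"),
                        pooling = c("topk", "mean", "max"), in_dim = 26) {
  attention <- match.arg(attention)
  pooling <- match.arg(pooling)
  stopifnot(n_layers >= 1, n_layers <= 4, hidden >= 1, k >= 1,
            conv_channels >= 1, dropout >= 0, dropout < 1)
  list(n_layers = n_layers, hidden = hidden, k = k,
       conv_channels = conv_channels, dropout = dropout,
       attention = attention, pooling = pooling, in_dim = in_dim)
}

# embedding channels entering the scoring head
emb_channels <- function(hyper) {
  if (hyper$n_layers == 1) hyper$in_dim else hyper$hidden + 1L
}

# rows of the pooled embedding
emb_rows <- function(hyper) {
  if (hyper$pooling == "topk") hyper$k else 1L
}

#' Initialise classifier parameters
#'
#' Xavier-uniform weights, zero biases; deterministic given `seed`.
#'
#' @param hyper From [dgann_hyper()].
#' @param seed Integer seed.
#' @return `DgannParams`: list with `hyper`, `layers` (each `W` and, for
#'   `gat_v1`, attention vectors `a1`, `a2`), `conv_W`, `conv_b`, `fc_W`,
#'   `fc_b`.
#' @export
dgann_init <- function(hyper = dgann_hyper(), seed = 1) {
  with_seed(seed, {
    xavier <- function(din, dout) {
      s <- sqrt(6 / (din + dout))
      matrix(stats::runif(din * dout, -s, s), din, dout)
    }
    L <- hyper$n_layers
    layers <- vector("list", L)
    for (l in seq_len(L)) {
      din <- if (l == 1) hyper$in_dim else hyper$hidden
      dout <- if (l == L) 1L else hyper$hidden
      layer <- list(W = xavier(din, dout))
      if (hyper$attention == "gat_v1") {
        layer$a1 <- stats::runif(dout, -0.1, 0.1)
        layer$a2 <- stats::runif(dout, -0.1, 0.1)
      }
      layers[[l]] <- layer
    }
    cin <- emb_channels(hyper)
    params <- list(
      hyper = hyper,
      layers = layers,
      conv_W = xavier(cin, hyper$conv_channels),
      conv_b = rep(0, hyper$conv_channels),
      fc_W = stats::runif(emb_rows(hyper) * hyper$conv_channels, -0.05, 0.05),
      fc_b = 0
    )
    class(params) <- "DgannParams"
    params
  })
}

# ---- parameter vector <-> list ------------------------------------------

dg_flatten <- function(params) {
  v <- numeric(0)
  for (layer in params$layers) {
    v <- c(v, as.vector(layer$W), layer$a1, layer$a2)
  }
  c(v, as.vector(params$conv_W), params$conv_b, params$fc_W, params$fc_b)
}

dg_unflatten <- function(vec, template) {
  pos <- 0L
  take <- function(n) {
    out <- vec[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  out <- template
  for (l in seq_along(template$layers)) {
    W <- template$layers[[l]]$W
    out$layers[[l]]$W <- matrix(take(length(W)), nrow(W), ncol(W))
    if (!is.null(template$layers[[l]]$a1)) {
      out$layers[[l]]$a1 <- take(length(template$layers[[l]]$a1))
      out$layers[[l]]$a2 <- take(length(template$layers[[l]]$a2))
    }
  }
  out$conv_W <- matrix(take(length(template$conv_W)),
                       nrow(template$conv_W), ncol(template$conv_W))
  out$conv_b <- take(length(template$conv_b))
  out$fc_W <- take(length(template$fc_W))
  out$fc_b <- take(1L)
  stopifnot(pos == length(vec))
  out
}

# zero-valued gradient container with the same shape as params
dg_zero_like <- function(params) {
  dg_unflatten(rep(0, length(dg_flatten(params))), params)
}

# ---- forward pass --------------------------------------------------------

# neighbourhood mask (logical n x n) with self-loops
adjacency_mask <- function(g) {
  n <- g$n_nodes
  M <- diag(TRUE, n)
  if (nrow(g$edges)) {
    M[g$edges] <- TRUE
    M[g$edges[, 2:1, drop = FALSE]] <- TRUE
  }
  M
}

#' Attention coefficients of one GAT layer
#'
#' Logits `e_ij = (W h_i) . (W h_j)` (or the canonical concat form under
#' `attention = "gat_v1"`), softmax-normalised over each node's
#' neighbourhood including a self-loop. Rows sum to 1.
#'
#' @param h `n x d_in` node embedding matrix.
#' @param W `d_in x d_out` shared weight matrix.
#' @param edges 2-column undirected edge matrix.
#' @param attention `"dot"` or `"gat_v1"`.
#' @param a1,a2 Attention vectors (gat_v1 only).
#' @return `n x n` matrix of coefficients; `alpha[i, j]` is the weight of
#'   neighbour `j` in node `i`'s aggregation (zero off-neighbourhood).
#' @export
attention_coefficients <- function(h, W, edges, attention = "dot",
                                   a1 = NULL, a2 = NULL) {
  g <- list(n_nodes = nrow(h), edges = edges)
  M <- adjacency_mask(g)
  gat_attention(h %*% W, M, attention, a1, a2)$A
}

gat_attention <- function(G, M, attention, a1 = NULL, a2 = NULL) {
  n <- nrow(G)
  if (attention == "dot") {
    E <- tcrossprod(G)
    P <- NULL
  } else {
    u <- as.vector(G %*% a1)
    v <- as.vector(G %*% a2)
    P <- outer(u, rep(1, n)) + outer(rep(1, n), v)
    E <- ifelse(P > 0, P, 0.2 * P)   # LeakyReLU(0.2)
  }
  E[!M] <- -Inf
  Emax <- apply(E, 1, max)
  A <- exp(E - Emax)
  A[!M] <- 0
  A <- A / rowSums(A)
  list(A = A, P = P)
}

#' One GAT layer
#'
#' `h'_i = tanh(sum_j alpha_ij W h_j)` over the neighbourhood of `i`
#' (self-loop included).
#'
#' @inheritParams attention_coefficients
#' @return `n x d_out` matrix of updated embeddings.
#' @export
gat_layer <- function(h, W, edges, attention = "dot", a1 = NULL, a2 = NULL) {
  g <- list(n_nodes = nrow(h), edges = edges)
  M <- adjacency_mask(g)
  G <- h %*% W
  A <- gat_attention(G, M, attention, a1, a2)$A
  tanh(A %*% G)
}

#' Interface-restricted top-k sort pooling
#'
#' Candidate nodes are the interface nodes; they are sorted by the
#' importance scalar (descending, stable ties by ascending node ordinal) and
#' the top `min(k, candidates)` are kept. Each kept node contributes the
#' concatenation of its hidden embedding and its importance; the output is
#' zero-padded to exactly `k` rows. An empty candidate set yields the
#' all-zero embedding (decoy with no interface contacts).
#'
#' @param hidden `n x d` hidden embedding matrix.
#' @param importance Numeric length-`n` importance scores.
#' @param mask Logical interface mask, length `n`.
#' @param k Number of rows to keep.
#' @param warn Warn when the mask is empty (default `TRUE`).
#' @return List: `embedding` (`k x (d+1)` matrix), `selected` (ordinals of
#'   kept nodes, possibly shorter than `k`).
#' @export
topk_pool <- function(hidden, importance, mask, k, warn = TRUE) {
  stopifnot(k >= 1, nrow(hidden) == length(importance),
            length(mask) == length(importance))
  cand <- which(mask)
  if (!length(cand) && warn) {
    warning("empty interface mask: pooling to all-zero embedding")
  }
  sel <- cand[order(-importance[cand], cand)]
  sel <- utils::head(sel, min(k, length(sel)))
  emb <- matrix(0, k, ncol(hidden) + 1L)
  if (length(sel)) {
    emb[seq_along(sel), ] <- cbind(hidden[sel, , drop = FALSE], importance[sel])
  }
  list(embedding = emb, selected = sel)
}

#' Scoring head: kernel-1 convolution, flatten, fully-connected, sigmoid
#'
#' @param emb Pooled embedding matrix (`k x channels`).
#' @param params `DgannParams` (uses `conv_W`, `conv_b`, `fc_W`, `fc_b`).
#' @return Probability in (0, 1).
#' @export
score_head <- function(emb, params) {
  Z <- sweep(emb %*% params$conv_W, 2, params$conv_b, `+`)
  Cc <- pmax(Z, 0)
  f <- as.vector(t(Cc))
  as.vector(sigmoid(sum(f * params$fc_W) + params$fc_b))
}

# Full forward pass with cache for backprop. dropout_mask (0/1 over the
# flattened head input) is supplied by the training loop; NULL = inference.
dgann_forward <- function(params, g, dropout_mask = NULL, warn = FALSE) {
  if (is.null(g$node_features)) stop("graph has no node features; run featurize()")
  hyper <- params$hyper
  L <- hyper$n_layers
  M <- adjacency_mask(g)
  H <- vector("list", L + 1L)
  H[[1]] <- g$node_features
  att <- vector("list", L)
  Gs <- vector("list", L)
  for (l in seq_len(L)) {
    layer <- params$layers[[l]]
    G <- H[[l]] %*% layer$W
    at <- gat_attention(G, M, hyper$attention, layer$a1, layer$a2)
    H[[l + 1L]] <- tanh(at$A %*% G)
    att[[l]] <- at
    Gs[[l]] <- G
  }
  s <- H[[L + 1L]][, 1]
  rep_mat <- if (L == 1) H[[1]] else H[[L]]
  cand <- which(g$interface_mask)

  if (hyper$pooling == "topk") {
    pool <- topk_pool(rep_mat, s, g$interface_mask, hyper$k, warn = warn)
    selected <- pool$selected
    emb <- if (L == 1) {
      # single-layer variant: read out the raw attributes of the kept nodes
      e <- matrix(0, hyper$k, hyper$in_dim)
      if (length(selected)) {
        e[seq_along(selected), ] <- rep_mat[selected, , drop = FALSE]
      }
      e
    } else pool$embedding
    argmax <- NULL
  } else {
    C_emb <- if (L == 1) rep_mat else cbind(rep_mat, s)
    if (!length(cand)) {
      if (warn) warning("empty interface mask: pooling to all-zero embedding")
      emb <- matrix(0, 1L, ncol(C_emb))
      argmax <- integer(0)
    } else if (hyper$pooling == "mean") {
      emb <- matrix(colMeans(C_emb[cand, , drop = FALSE]), 1L)
      argmax <- NULL
    } else {
      block <- C_emb[cand, , drop = FALSE]
      am <- max.col(t(block), ties.method = "first")
      emb <- matrix(block[cbind(am, seq_len(ncol(block)))], 1L)
      argmax <- cand[am]
    }
    selected <- cand
  }

  Z <- sweep(emb %*% params$conv_W, 2, params$conv_b, `+`)
  Cc <- pmax(Z, 0)
  f <- as.vector(t(Cc))
  if (!is.null(dropout_mask)) {
    f <- f * dropout_mask / (1 - hyper$dropout)
  }
  logit <- sum(f * params$fc_W) + params$fc_b
  prob <- sigmoid(logit)
  list(prob = prob,
       cache = list(H = H, att = att, Gs = Gs, M = M, s = s,
                    selected = selected, argmax = argmax, cand = cand,
                    emb = emb, Z = Z, f = f, dropout_mask = dropout_mask,
                    logit = logit))
}

#' Score a featurized residue graph
#'
#' @param params `DgannParams`.
#' @param g A featurized `ResidueGraph`.
#' @param warn Warn on empty interface mask.
#' @return Near-native probability in (0, 1).
#' @export
dgann_score <- function(params, g, warn = TRUE) {
  dgann_forward(params, g, warn = warn)$prob
}

#' @rdname dgann_score
#' @param graphs List of featurized graphs.
#' @export
dgann_score_all <- function(params, graphs, warn = FALSE) {
  vapply(graphs, function(g) dgann_forward(params, g, warn = warn)$prob,
         numeric(1))
}

# ---- backward pass -------------------------------------------------------

# Gradient of a scalar loss with d loss / d logit = dlogit.
dgann_backward <- function(params, g, fwd, dlogit) {
  hyper <- params$hyper
  L <- hyper$n_layers
  ch <- fwd$cache
  grads <- dg_zero_like(params)

  f <- ch$f
  grads$fc_b <- dlogit
  grads$fc_W <- dlogit * f
  df <- dlogit * params$fc_W
  if (!is.null(ch$dropout_mask)) {
    df <- df * ch$dropout_mask / (1 - hyper$dropout)
  }
  dCc <- matrix(df, nrow = nrow(ch$Z), byrow = TRUE)
  dZ <- dCc * (ch$Z > 0)
  grads$conv_W <- crossprod(ch$emb, dZ)
  grads$conv_b <- colSums(dZ)
  dEmb <- dZ %*% t(params$conv_W)

  n <- g$n_nodes
  dH <- vector("list", L + 1L)
  for (l in seq_len(L + 1L)) dH[[l]] <- matrix(0, n, ncol(ch$H[[l]]))

  # un-pool: route dEmb back to node embeddings and importances
  route <- function(node, grad_row) {
    if (L == 1) {
      dH[[1]][node, ] <<- dH[[1]][node, ] + grad_row
    } else {
      d <- hyper$hidden
      dH[[L]][node, ] <<- dH[[L]][node, ] + grad_row[1:d]
      dH[[L + 1L]][node, 1] <<- dH[[L + 1L]][node, 1] + grad_row[d + 1L]
    }
  }
  if (hyper$pooling == "topk") {
    for (r in seq_along(ch$selected)) route(ch$selected[r], dEmb[r, ])
  } else if (length(ch$cand)) {
    if (hyper$pooling == "mean") {
      for (node in ch$cand) route(node, dEmb[1, ] / length(ch$cand))
    } else {
      for (j in seq_along(ch$argmax)) {
        row <- numeric(ncol(dEmb)); row[j] <- dEmb[1, j]
        route(ch$argmax[j], row)
      }
    }
  }

  for (l in rev(seq_len(L))) {
    layer <- params$layers[[l]]
    A <- ch$att[[l]]$A
    G <- ch$Gs[[l]]
    Hout <- ch$H[[l + 1L]]
    dS <- dH[[l + 1L]] * (1 - Hout^2)
    dA <- dS %*% t(G)
    dG <- crossprod(A, dS)
    dE <- A * sweep(dA, 1, rowSums(A * dA))
    if (hyper$attention == "dot") {
      dG <- dG + dE %*% G + crossprod(dE, G)
    } else {
      P <- ch$att[[l]]$P
      dP <- dE * ifelse(P > 0, 1, 0.2)
      du <- rowSums(dP)
      dv <- colSums(dP)
      dG <- dG + outer(du, layer$a1) + outer(dv, layer$a2)
      grads$layers[[l]]$a1 <- as.vector(crossprod(G, du))
      grads$layers[[l]]$a2 <- as.vector(crossprod(G, dv))
    }
    grads$layers[[l]]$W <- crossprod(ch$H[[l]], dG)
    dH[[l]] <- dH[[l]] + dG %*% t(layer$W)
  }
  grads
}

#' Binary cross-entropy loss and parameter gradient over a batch of graphs
#'
#' @param params `DgannParams`.
#' @param graphs List of featurized graphs.
#' @param labels Numeric 0/1 (or `"positive"`/`"negative"`) labels.
#' @param dropout Apply dropout masks (training mode); draws from the
#'   current RNG stream.
#' @return List with `loss` (mean BCE) and `grads` (same shape as params).
#' @export
dgann_loss_grad <- function(params, graphs, labels, dropout = FALSE) {
  if (is.character(labels)) labels <- as.numeric(labels == "positive")
  stopifnot(length(graphs) == length(labels))
  hyper <- params$hyper
  nf <- emb_rows(hyper) * hyper$conv_channels
  total <- dg_flatten(dg_zero_like(params))
  loss <- 0
  for (i in seq_along(graphs)) {
    mask <- if (dropout && hyper$dropout > 0) {
      stats::rbinom(nf, 1, 1 - hyper$dropout)
    } else NULL
    fwd <- dgann_forward(params, graphs[[i]], dropout_mask = mask)
    p <- min(max(fwd$prob, 1e-12), 1 - 1e-12)
    y <- labels[i]
    loss <- loss - (y * log(p) + (1 - y) * log(1 - p))
    dlogit <- fwd$prob - y
    total <- total + dg_flatten(dgann_backward(params, graphs[[i]], fwd, dlogit))
  }
  m <- length(graphs)
  list(loss = loss / m, grads = dg_unflatten(total / m, params))
}

# mean BCE without gradients (validation)
dgann_loss <- function(params, graphs, labels) {
  if (is.character(labels)) labels <- as.numeric(labels == "positive")
  p <- dgann_score_all(params, graphs)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Save / load parameter checkpoints
#'
#' JSON checkpoints embed a hash of the hyper-parameter configuration so a
#' mismatched architecture is detected on load.
#'
#' @param params `DgannParams`.
#' @param path File path.
#' @return `path` (write) / `DgannParams` (read).
#' @export
write_checkpoint <- function(params, path) {
  hyper <- params$hyper
  obj <- list(
    hyper = hyper,
    config_hash = config_hash(hyper),
    theta = dg_flatten(params)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$hyper) || is.null(obj$theta)) {
    stop("not a checkpoint file: ", path)
  }
  hyper <- do.call(dgann_hyper, as.list(obj$hyper))
  if (!identical(obj$config_hash, config_hash(hyper))) {
    stop("checkpoint config hash mismatch")
  }
  template <- dgann_init(hyper, seed = 1)
  params <- dg_unflatten(as.numeric(obj$theta), template)
  class(params) <- "DgannParams"
  params
}

config_hash <- function(hyper) {
  s <- paste(names(hyper), unlist(hyper), sep = "=", collapse = ";")
  # tiny FNV-style rolling hash; stdlib-only and stable across sessions
  h <- 2166136261
  for (cc in utf8ToInt(s)) h <- (xor(h, cc) * 16777619) %% 2^32
  sprintf("%08x", h)
}
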