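test_that("attention coefficients: softmax rows, singleton, equal logits", {
  # node with two neighbours having identical embeddings -> 0.5 / 0.5
  h <- rbind(c(1, 0), c(0, 1), c(0, 1))
  W <- diag(2)
  edges <- rbind(c(1, 2), c(1, 3))
  A <- attention_coefficients(h, W, edges)
  expect_equal(A[1, 2], A[1, 3])
  expect_equal(rowSums(A), rep(1, 3), tolerance = 1e-6)
  # isolated node: self-loop only -> alpha = 1 on itself
  h2 <- rbind(c(1, 2), c(3, 4))
  A2 <- attention_coefficients(h2, diag(2), matrix(integer(0), 0, 2))
  expect_equal(diag(A2), c(1, 1))
})

test_that("attention matches the explicit exp/sum oracle on random graphs", {
  for (sd in 1:6) {
    set.seed(sd)
    n <- 6
    h <- matrix(rnorm(n * 4), n, 4)
    W <- matrix(rnorm(4 * 3), 4, 3)
    edges <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    edges <- edges[runif(nrow(edges)) < 0.4, , drop = FALSE]
    A <- attention_coefficients(h, W, edges)
    expect_equal(A, oracle_attention(h, W, edges),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("gat_layer: zero input -> zero output; identity self-loop; dense oracle", {
  n <- 5
  edges <- rbind(c(1, 2), c(2, 3), c(4, 5))
  expect_equal(gat_layer(matrix(0, n, 3), matrix(1, 3, 2), edges),
               matrix(0, n, 2), ignore_attr = TRUE)
  # single node (self-loop only), identity W -> tanh(h)
  h1 <- matrix(c(0.3, -0.7), 1, 2)
  expect_equal(gat_layer(h1, diag(2), matrix(integer(0), 0, 2)),
               tanh(h1), tolerance = 1e-12)
  for (sd in 1:5) {
    set.seed(sd)
    h <- matrix(rnorm(5 * 4), 5, 4)
    W <- matrix(rnorm(4 * 2), 4, 2)
    expect_equal(gat_layer(h, W, edges), oracle_gat_layer(h, W, edges),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("topk_pool: padding, sort oracle, k = 1", {
  set.seed(4)
  n <- 8
  hidden <- matrix(rnorm(n * 3), n, 3)
  imp <- rnorm(n)
  mask <- rep(TRUE, n)
  # 3 interface nodes, k = 5 -> rows 4:5 zero
  mask3 <- c(TRUE, TRUE, TRUE, rep(FALSE, 5))
  out <- topk_pool(hidden, imp, mask3, 5)
  expect_equal(dim(out$embedding), c(5, 4))
  expect_equal(out$embedding[4:5, ], matrix(0, 2, 4), ignore_attr = TRUE)
  # selection equals brute-force argsort on masked candidates
  out2 <- topk_pool(hidden, imp, mask, 4)
  expect_equal(out2$selected, order(-imp)[1:4])
  # k = 1 keeps the argmax node
  out3 <- topk_pool(hidden, imp, mask, 1)
  expect_equal(out3$selected, which.max(imp))
  expect_equal(out3$embedding[1, ], c(hidden[which.max(imp), ], max(imp)))
  # stable tie-break by ascending ordinal
  tied <- rep(1, n)
  expect_equal(topk_pool(hidden, tied, mask, 3)$selected, 1:3)
  # empty mask warns and zero-pads
  expect_warning(z <- topk_pool(hidden, imp, rep(FALSE, n), 3), "empty interface")
  expect_equal(z$embedding, matrix(0, 3, 4), ignore_attr = TRUE)
})

test_that("score_head outputs in (0,1) and matches direct arithmetic", {
  hy <- small_hyper()
  params <- dgann_init(hy, seed = 5)
  set.seed(1)
  emb <- matrix(rnorm(hy$k * (hy$hidden + 1)), hy$k)
  p <- score_head(emb, params)
  expect_gt(p, 0); expect_lt(p, 1)
  # independent arithmetic
  Z <- emb %*% params$conv_W + matrix(params$conv_b, hy$k,
                                      hy$conv_channels, byrow = TRUE)
  f <- as.vector(t(pmax(Z, 0)))
  expect_equal(p, 1 / (1 + exp(-(sum(f * params$fc_W) + params$fc_b))),
               tolerance = 1e-12)
  # all-zero embedding: deterministic bias path
  z0 <- matrix(0, hy$k, hy$hidden + 1)
  expect_equal(score_head(z0, params), score_head(z0, params))
})

test_that("forward pass is deterministic and permutation-invariant", {
  g <- random_graph(n = 10, seed = 8)
  params <- dgann_init(small_hyper(), seed = 2)
  p1 <- dgann_score(params, g)
  expect_identical(p1, dgann_score(params, g))
  for (sd in 1:5) {
    set.seed(100 + sd)
    perm <- sample(g$n_nodes)
    expect_equal(dgann_score(params, permute_graph(g, perm)), p1,
                 tolerance = 1e-6)
  }
})

test_that("empty-interface decoys take the zero-embedding path with a warning", {
  g <- random_graph(n = 6, seed = 9)
  g$interface_mask[] <- FALSE
  params <- dgann_init(small_hyper(), seed = 3)
  expect_warning(p <- dgann_score(params, g), "empty interface")
  z0 <- matrix(0, params$hyper$k, params$hyper$hidden + 1)
  expect_equal(p, score_head(z0, params))
})

test_that("attention rows sum to 1 inside full forward passes", {
  for (sd in 1:3) {
    g <- random_graph(n = 9, seed = sd)
    for (attn in c("dot", "gat_v1")) {
      params <- dgann_init(small_hyper(attention = attn), seed = sd)
      fwd <- dgann_forward(params, g)
      for (at in fwd$cache$att) {
        expect_equal(rowSums(at$A), rep(1, g$n_nodes), tolerance = 1e-6)
      }
    }
  }
})

test_that("backprop matches finite differences on a 5-node fixture", {
  g <- random_graph(n = 5, p_edge = 0.6, n_interface = 3, seed = 12)
  g$label <- "positive"
  for (attn in c("dot", "gat_v1")) {
    for (nl in c(2, 3)) {
      hy <- dgann_hyper(n_layers = nl, hidden = 6, k = 3, conv_channels = 2,
                        dropout = 0, attention = attn)
      params <- dgann_init(hy, seed = 7)
      lg <- dgann_loss_grad(params, list(g), 1)
      ana <- dg_flatten(lg$grads)
      theta <- dg_flatten(params)
      eps <- 1e-5
      num <- vapply(seq_along(theta), function(i) {
        tp <- theta; tp[i] <- tp[i] + eps
        tm <- theta; tm[i] <- tm[i] - eps
        lp <- dgann_loss(dg_unflatten(tp, params), list(g), 1)
        lm <- dgann_loss(dg_unflatten(tm, params), list(g), 1)
        (lp - lm) / (2 * eps)
      }, numeric(1))
      denom <- pmax(abs(num), abs(ana), 1e-8)
      expect_lt(max(abs(num - ana) / denom), 1e-4)
    }
  }
})

test_that("single-layer variant pools raw attributes; global poolings agree on 1 interface node", {
  g <- random_graph(n = 7, n_interface = 1, seed = 15)
  # 1-layer: head channels = 26
  p1 <- dgann_init(dgann_hyper(n_layers = 1, k = 3, conv_channels = 2,
                               dropout = 0), seed = 1)
  fwd <- dgann_forward(p1, g)
  expect_equal(dim(fwd$cache$emb), c(3, 26))
  node <- which(g$interface_mask)
  expect_equal(fwd$cache$emb[1, ], unname(g$node_features[node, ]))
  # mean / max / topk(k=1) coincide on a single interface node
  probs <- vapply(c("topk", "mean", "max"), function(pl) {
    hy <- dgann_hyper(hidden = 6, k = 1, conv_channels = 2, dropout = 0,
                      pooling = pl)
    dgann_score(dgann_init(hy, seed = 11), g)
  }, numeric(1))
  expect_equal(unname(probs[1]), unname(probs[2]), tolerance = 1e-12)
  expect_equal(unname(probs[2]), unname(probs[3]), tolerance = 1e-12)
})

test_that("checkpoints round-trip and detect config mismatch", {
  params <- dgann_init(small_hyper(), seed = 21)
  path <- tempfile(fileext = ".json")
  write_checkpoint(params, path)
  back <- read_checkpoint(path)
  expect_equal(dg_flatten(back), dg_flatten(params), tolerance = 1e-12)
  g <- random_graph(n = 6, seed = 2)
  expect_equal(dgann_score(back, g), dgann_score(params, g), tolerance = 1e-12)
  # tampered hyper -> hash mismatch
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$hyper$hidden <- 99
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(read_checkpoint(path), "hash mismatch")
})
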