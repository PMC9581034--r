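test_that("greedy identity clustering: identical join, unrelated split, oracle", {
  expect_length(greedy_identity_cluster(
    c(a = "MKTAYIAKQRQISFVK", b = "MKTAYIAKQRQISFVK"), 0.4), 1)
  set.seed(5)
  r1 <- paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 40, TRUE),
              collapse = "")
  r2 <- paste(sample(c("G", "P", "W", "C"), 40, TRUE), collapse = "")
  expect_length(greedy_identity_cluster(c(a = r1, b = r2), 0.4), 2)
  expect_error(greedy_identity_cluster(c(a = "", b = "AA")), "empty")

  # 10-sequence fixture: greedy clustering equals all-pairs single-linkage
  # at the same identity function
  set.seed(42)
  base <- vapply(1:4, function(i) {
    paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 30, TRUE),
          collapse = "")
  }, character(1))
  mutate <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), k)
    v[pos] <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], k, TRUE)
    paste(v, collapse = "")
  }
  seqs <- c(base, vapply(base, mutate, character(1), k = 3),
            mutate(base[1], 4), mutate(base[2], 5))
  names(seqs) <- paste0("t", seq_along(seqs))
  got <- greedy_identity_cluster(seqs, 0.4)
  # oracle: single-linkage components of the >= 0.4 identity graph
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    idy <- seq_identity(seqs[[i]], seqs[[j]])
    adj[i, j] <- adj[j, i] <- idy >= 0.4
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in 1:n) for (j in 1:n) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  oracle_sets <- lapply(split(names(seqs), comp), sort)
  got_sets <- lapply(got, sort)
  expect_setequal(
    vapply(got_sets, paste, character(1), collapse = ","),
    vapply(oracle_sets, paste, character(1), collapse = ",")
  )
})

test_that("make_splits deals clusters round-robin, keeps clusters atomic", {
  cl <- list(c("a", "a2"), "b", "c", "d", "e", "f")
  sp <- make_splits(cl, n_folds = 5, seed = 3)
  expect_equal(sort(names(sp$fold)), sort(unlist(cl)))
  expect_equal(sp$fold[["a"]], sp$fold[["a2"]]) # cluster atomicity
  expect_length(sp$arrangements, 5)
  for (arr in sp$arrangements) {
    all_t <- c(arr$train, arr$validation, arr$test)
    expect_setequal(all_t, unlist(cl))
    expect_length(intersect(arr$train, arr$test), 0)
    expect_length(intersect(arr$validation, arr$test), 0)
  }
  # determinism, and 5 singleton clusters -> one target per fold
  expect_identical(make_splits(cl, 5, seed = 3)$fold, sp$fold)
  sp5 <- make_splits(as.list(letters[1:5]), 5, seed = 1)
  expect_equal(sort(unname(table(sp5$fold))), rep(1L, 5), ignore_attr = TRUE)
  expect_error(make_splits(as.list(letters[1:3]), 5), "fewer clusters")
})

test_that("assert_no_leakage passes identity-clustered splits and catches leaks", {
  set.seed(8)
  seqs <- vapply(1:6, function(i) {
    paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 25, TRUE),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("t", 1:6)
  cl <- greedy_identity_cluster(seqs, 0.4)
  sp <- make_splits(cl, n_folds = 5, seed = 1)
  expect_true(assert_no_leakage(sp, seqs, 0.4))
  # duplicate a training sequence into the test fold -> leak
  seqs_bad <- seqs
  arr <- sp$arrangements[[1]]
  seqs_bad[arr$test[1]] <- seqs_bad[arr$train[1]]
  expect_error(assert_no_leakage(sp, seqs_bad, 0.4), "leakage")
})

test_that("bootstrap subsets are balanced, contain all positives, deterministic", {
  set.seed(2)
  labels <- data.frame(
    target_id = rep(c("T1", "T2"), c(100, 60)),
    model_id = sprintf("d%03d", c(1:100, 1:60)),
    label = "negative", stringsAsFactors = FALSE
  )
  labels$label[c(1:10, 101:103)] <- "positive" # T1: 10 pos, T2: 3 pos
  subs <- bootstrap_subsets(labels, B = 5, seed = 7)
  expect_length(subs, 5)
  key <- paste(labels$target_id, labels$model_id, sep = "/")
  pos_keys <- key[labels$label == "positive"]
  for (sub in subs) {
    expect_true(all(pos_keys %in% sub$ids))
    expect_equal(length(sub$ids), 2 * length(pos_keys))
    neg <- setdiff(sub$ids, pos_keys)
    expect_equal(length(neg), length(unique(neg)))
    # per-target negative counts match per-target positive counts
    neg_t <- sub("/.*", "", neg)
    expect_equal(sort(unname(table(neg_t))), c(3, 10), ignore_attr = TRUE)
  }
  expect_identical(bootstrap_subsets(labels, B = 5, seed = 7)[[3]]$ids,
                   subs[[3]]$ids)
  expect_error(bootstrap_subsets(labels[labels$label == "negative", ], 2, 1),
               "no positive samples")
})

test_that("train_one: learnability, early-stopping contract, lr = 0 freeze", {
  set.seed(31)
  train_graphs <- c(lapply(1:8, function(i) random_graph(8, seed = 200 + i,
                                                         label = "positive")),
                    lapply(1:8, function(i) random_graph(8, seed = 300 + i,
                                                         label = "negative")))
  # plant a strong separable signal on the positives
  train_graphs[1:8] <- lapply(train_graphs[1:8], function(g) {
    g$node_features[, 1:5] <- g$node_features[, 1:5] + 4
    g
  })
  val_graphs <- train_graphs
  cfg <- train_config(batch = 8, patience = 50, max_epochs = 25, seed = 5,
                      hyper = small_hyper())
  fit <- train_one(train_graphs, val_graphs, cfg)
  expect_lt(fit$log$train_loss[nrow(fit$log)], fit$log$train_loss[1])
  expect_equal(fit$best_epoch, which.min(fit$log$val_loss))
  expect_equal(fit$best_val, min(fit$log$val_loss))

  # lr = 0: parameters stay at initialisation
  cfg0 <- train_config(lr = 0, batch = 8, patience = 3, max_epochs = 3,
                       seed = 5, hyper = small_hyper())
  fit0 <- train_one(train_graphs, val_graphs, cfg0)
  expect_equal(dg_flatten(fit0$params),
               dg_flatten(dgann_init(small_hyper(), seed = 5)),
               tolerance = 1e-12)
})

test_that("ensemble_score: single member, arithmetic, max >= mean", {
  g <- random_graph(n = 7, seed = 77)
  cps <- lapply(1:3, function(i) dgann_init(small_hyper(), seed = i))
  single <- dgann_score(cps[[1]], g)
  expect_equal(ensemble_score(cps[1], g, "mean"), single)
  expect_equal(ensemble_score(cps[1], g, "max"), single)
  ps <- vapply(cps, function(cp) dgann_score(cp, g), numeric(1))
  expect_equal(ensemble_score(cps, g, "mean"), mean(ps))
  expect_equal(ensemble_score(cps, g, "max"), max(ps))
  for (sd in 1:10) {
    g2 <- random_graph(n = 6, seed = 500 + sd)
    expect_gte(ensemble_score(cps, g2, "max"), ensemble_score(cps, g2, "mean"))
  }
})
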