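#' Dataset splitting, bootstrap ensembles and training
#'
#' Targets (complexes) are clustered at a sequence-identity threshold
#' (default 40%) so that similar complexes never straddle the train/test
#' boundary; clusters are dealt round-robin into 5 cross-validation folds.
#' Class imbalance (~1 near-native per hundreds of decoys) is addressed by
#' bootstrap balanced subsets: every subset holds *all* positive samples of
#' the training targets plus an equal number of negatives drawn per target.
#' One classifier is trained per subset (Adam, binary cross-entropy,
#' early stopping on the full imbalanced validation set) and the ensemble
#' prediction is the mean or maximum of the member probabilities.
#'
#' @name training_ensemble
NULL

# global sequence identity = matches / length of the shorter sequence,
# with a shared-k-mer prescreen to skip hopeless pairs quickly.
seq_identity <- function(a, b, kmer = 4) {
  if (!nchar(a) || !nchar(b)) stop("empty sequence")
  if (min(nchar(a), nchar(b)) > kmer) {
    ka <- substring(a, 1:(nchar(a) - kmer + 1), kmer:nchar(a))
    kb <- substring(b, 1:(nchar(b) - kmer + 1), kmer:nchar(b))
    if (!length(intersect(ka, kb))) return(0)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62_matrix(),
    gapOpening = 10, gapExtension = 0.5, type = "global"
  )
  Biostrings::nmatch(pa) / min(nchar(a), nchar(b))
}

#' Greedy incremental sequence-identity clustering
#'
#' Targets are sorted by sequence length (descending); each joins the first
#' existing cluster whose representative (its longest member) shares at
#' least `threshold` identity, else seeds a new cluster. Deterministic.
#'
#' @param sequences Named character vector: target id -> concatenated chain
#'   sequence.
#' @param threshold Identity threshold in (0, 1]; default 0.4.
#' @return List of character vectors of target ids; each cluster's first
#'   element is its representative.
#' @export
greedy_identity_cluster <- function(sequences, threshold = 0.4) {
  stopifnot(threshold > 0, threshold <= 1, length(sequences) >= 1)
  if (any(!nchar(sequences))) stop("empty sequence")
  ord <- order(-nchar(sequences), names(sequences))
  ids <- names(sequences)[ord]
  clusters <- list()
  for (id in ids) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      rep_id <- clusters[[ci]][1]
      if (seq_identity(sequences[[rep_id]], sequences[[id]]) >= threshold) {
        clusters[[ci]] <- c(clusters[[ci]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) clusters[[length(clusters) + 1L]] <- id
  }
  clusters
}

#' Cross-validation folds over clusters
#'
#' Whole clusters (never individual targets) are dealt round-robin into
#' `n_folds` folds by descending cluster size (ties shuffled reproducibly by
#' `seed`). Arrangement `f` uses fold `f` as test, the next fold as
#' validation and the rest as training.
#'
#' @param clusters From [greedy_identity_cluster()].
#' @param n_folds Number of folds (default 5).
#' @param seed Integer seed for tie shuffling.
#' @return `TargetSplit`: list with `fold` (named integer vector target ->
#'   fold) and `arrangements` (list of `list(train, validation, test)`
#'   target-id vectors, one per fold).
#' @export
make_splits <- function(clusters, n_folds = 5, seed = 1) {
  if (length(clusters) < n_folds) {
    stop("fewer clusters (", length(clusters), ") than folds (", n_folds, ")")
  }
  sizes <- lengths(clusters)
  ord <- with_seed(seed, order(-sizes, stats::runif(length(sizes))))
  fold_of_cluster <- integer(length(clusters))
  fold_of_cluster[ord] <- rep_len(seq_len(n_folds), length(clusters))
  fold <- integer(0)
  for (ci in seq_along(clusters)) {
    f <- rep(fold_of_cluster[ci], length(clusters[[ci]]))
    names(f) <- clusters[[ci]]
    fold <- c(fold, f)
  }
  arrangements <- lapply(seq_len(n_folds), function(f) {
    test_f <- f
    val_f <- f %% n_folds + 1L
    list(
      train = names(fold)[!fold %in% c(test_f, val_f)],
      validation = names(fold)[fold == val_f],
      test = names(fold)[fold == test_f]
    )
  })
  structure(list(fold = fold, arrangements = arrangements, n_folds = n_folds),
            class = "TargetSplit")
}

#' Assert no sequence leakage across a train/test boundary
#'
#' Errors if any train/test target pair shares identity at or above the
#' threshold.
#'
#' @param split A `TargetSplit`.
#' @param sequences Named sequences as in [greedy_identity_cluster()].
#' @param threshold Identity threshold (default 0.4).
#' @return `TRUE` invisibly.
#' @export
assert_no_leakage <- function(split, sequences, threshold = 0.4) {
  for (arr in split$arrangements) {
    for (tr in arr$train) {
      for (te in arr$test) {
        idy <- seq_identity(sequences[[tr]], sequences[[te]])
        if (idy >= threshold) {
          stop("leakage: train target ", tr, " and test target ", te,
               " share identity ", round(idy, 3))
        }
      }
    }
  }
  invisible(TRUE)
}

#' Bootstrap balanced training subsets
#'
#' Each subset contains all positive samples of the training targets plus,
#' per target, a uniform without-replacement draw of negatives matching that
#' target's positive count (shortfalls topped up from other targets, with a
#' message). Subset `b` uses seed `seed + b`.
#'
#' @param labels data.frame with columns `target_id`, `model_id`, `label`
#'   (`"positive"`/`"negative"`), restricted to training targets.
#' @param B Number of subsets (default 100).
#' @param seed Root integer seed.
#' @return List of `BootstrapSubset`s: `list(index, ids, seed)` where `ids`
#'   are `target_id/model_id` keys.
#' @export
bootstrap_subsets <- function(labels, B = 100, seed = 1) {
  stopifnot(B >= 1)
  key <- paste(labels$target_id, labels$model_id, sep = "/")
  pos <- key[labels$label == "positive"]
  if (!length(pos)) stop("no positive samples in training targets")
  lapply(seq_len(B), function(b) {
    sub_seed <- seed + b
    ids <- with_seed(sub_seed, {
      negs <- character(0)
      shortfall <- 0L
      leftover <- character(0)
      for (tg in unique(labels$target_id)) {
        tpos <- sum(labels$label == "positive" & labels$target_id == tg)
        tneg <- key[labels$label == "negative" & labels$target_id == tg]
        take <- min(tpos, length(tneg))
        drawn <- if (take) sample(tneg, take) else character(0)
        negs <- c(negs, drawn)
        shortfall <- shortfall + (tpos - take)
        leftover <- c(leftover, setdiff(tneg, drawn))
      }
      if (shortfall > 0L) {
        message("bootstrap subset ", b, ": topping up ", shortfall,
                " negatives across targets")
        negs <- c(negs, sample(leftover, min(shortfall, length(leftover))))
      }
      c(pos, negs)
    })
    structure(list(index = b, ids = ids, seed = sub_seed),
              class = "BootstrapSubset")
  })
}

#' Training configuration
#'
#' @param lr Adam learning rate (default 0.001).
#' @param decay Multiplicative learning-rate decay factor applied on a
#'   validation plateau (default 0.9); set `decay_mode = "weight"` to use it
#'   as an L2 weight-decay coefficient instead (the printed "0.9 decay" is
#'   ambiguous; both readings are exposed).
#' @param batch Mini-batch size (default 256).
#' @param patience Early-stopping patience in epochs (default 30).
#' @param max_epochs Hard epoch cap (default 200).
#' @param decay_mode `"plateau"` or `"weight"`.
#' @param plateau Epochs without improvement before an LR decay step
#'   (default 10).
#' @param seed Integer seed.
#' @param hyper Model hyper-parameters ([dgann_hyper()]).
#' @return `TrainConfig` list.
#' @export
train_config <- function(lr = 0.001, decay = 0.9, batch = 256, patience = 30,
                         max_epochs = 200, decay_mode = c("plateau", "weight"),
                         plateau = 10, seed = 1, hyper = dgann_hyper()) {
  decay_mode <- match.arg(decay_mode)
  stopifnot(lr >= 0, decay > 0, batch >= 1, patience >= 1, max_epochs >= 1)
  list(lr = lr, decay = decay, batch = batch, patience = patience,
       max_epochs = max_epochs, decay_mode = decay_mode, plateau = plateau,
       seed = seed, hyper = hyper)
}

adam_init <- function(n) list(m = rep(0, n), v = rep(0, n), t = 0L)

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train one classifier on a bootstrap subset
#'
#' Mini-batch Adam on binary cross-entropy. After every epoch the loss on
#' the full (imbalanced) validation graphs is computed; training stops when
#' it has not improved for `patience` consecutive epochs, and the
#' best-validation parameters are returned.
#'
#' @param train_graphs Non-empty list of featurized, labelled graphs.
#' @param val_graphs Non-empty list of validation graphs (all decoys of the
#'   validation targets, imbalance preserved).
#' @param cfg A `TrainConfig`.
#' @return List with `params` (best checkpoint) and `log` (data.frame of
#'   epoch, train_loss, val_loss, lr).
#' @export
train_one <- function(train_graphs, val_graphs, cfg = train_config()) {
  stopifnot(length(train_graphs) >= 1, length(val_graphs) >= 1)
  ytr <- vapply(train_graphs, function(g) g$label, character(1))
  yva <- vapply(val_graphs, function(g) g$label, character(1))
  stopifnot(all(ytr %in% c("positive", "negative")))
  params <- dgann_init(cfg$hyper, seed = cfg$seed)
  theta <- dg_flatten(params)
  st <- adam_init(length(theta))
  lr <- cfg$lr
  best <- list(val = Inf, theta = theta, epoch = 0L)
  since_best <- 0L
  log <- list()
  with_seed(cfg$seed + 104729L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(length(train_graphs))
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, length(ord), by = cfg$batch)) {
        idx <- ord[start:min(start + cfg$batch - 1L, length(ord))]
        lg <- dgann_loss_grad(params, train_graphs[idx], ytr[idx],
                              dropout = cfg$hyper$dropout > 0)
        g <- dg_flatten(lg$grads)
        if (!all(is.finite(g)) || !is.finite(lg$loss)) {
          stop("training diverged (non-finite loss/gradient) at epoch ", epoch)
        }
        if (cfg$decay_mode == "weight") g <- g + cfg$decay * 0.001 * theta
        stepped <- adam_step(theta, g, st, lr)
        theta <- stepped$theta; st <- stepped$state
        params <- dg_unflatten(theta, params)
        ep_loss <- ep_loss + lg$loss; nb <- nb + 1L
      }
      val <- dgann_loss(params, val_graphs, yva)
      log[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                 val_loss = val, lr = lr)
      if (val < best$val - 1e-9) {
        best <- list(val = val, theta = theta, epoch = epoch)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (cfg$decay_mode == "plateau" && since_best %% cfg$plateau == 0L) {
          lr <- lr * cfg$decay
        }
        if (since_best >= cfg$patience) break
      }
    }
  })
  best_params <- dg_unflatten(best$theta, params)
  class(best_params) <- "DgannParams"
  list(params = best_params, log = do.call(rbind, log),
       best_epoch = best$epoch, best_val = best$val)
}

#' Train a bootstrap ensemble
#'
#' @param graphs Named list of all featurized labelled graphs
#'   (names `target_id/model_id`).
#' @param subsets From [bootstrap_subsets()].
#' @param val_graphs Validation graphs (full imbalanced set).
#' @param cfg Base `TrainConfig`; member `b` trains with `seed + b`.
#' @return List of `train_one()` results, one per subset.
#' @export
train_ensemble <- function(graphs, subsets, val_graphs, cfg = train_config()) {
  lapply(subsets, function(sub) {
    cfg_b <- cfg
    cfg_b$seed <- cfg$seed + sub$index
    missing <- setdiff(sub$ids, names(graphs))
    if (length(missing)) stop("subset references unknown graphs: ", missing[1])
    train_one(graphs[sub$ids], val_graphs, cfg_b)
  })
}

#' Ensemble score of a decoy
#'
#' Aggregates the member classifiers' probabilities by mean or maximum
#' (the maximum is the headline ensemble mode).
#'
#' @param checkpoints List of `DgannParams` (or of `train_one()` results).
#' @param g A featurized `ResidueGraph`.
#' @param mode `"max"` (default) or `"mean"`.
#' @return Probability in `[0, 1]`.
#' @export
ensemble_score <- function(checkpoints, g, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  stopifnot(length(checkpoints) >= 1)
  ps <- vapply(checkpoints, function(cp) {
    if (!inherits(cp, "DgannParams") && !is.null(cp$params)) cp <- cp$params
    dgann_forward(cp, g, warn = FALSE)$prob
  }, numeric(1))
  if (mode == "max") max(ps) else mean(ps)
}

#' @rdname ensemble_score
#' @param graphs List of graphs to score.
#' @export
ensemble_score_all <- function(checkpoints, graphs, mode = c("max", "mean")) {
  mode <- match.arg(mode)
  vapply(graphs, function(g) ensemble_score(checkpoints, g, mode), numeric(1))
}
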