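#' Ranking evaluation: enrichment factors and success rates
#'
#' A scored decoy set is evaluated by the enrichment factor at percentage
#' checkpoints,
#' `EF_x% = (positives in top x%) / (samples in top x%) * N / N_positives`,
#' whose attainable ceiling is `EF_max = N / N_positives`, and by the
#' success-rate curve: the fraction of targets with at least one positive
#' among their N best-scored decoys. The top window holds
#' `max(1, round(x/100 * N))` decoys, so EF at 0.01% of 3,600 decoys is the
#' top-1 window. Score ties are broken deterministically by model id.
#'
#' @name evaluation
NULL

# order of decoys by descending score, ties by model_id then index
rank_order <- function(scores, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("m%09d", seq_along(scores))
  order(-scores, ids)
}

#' Enrichment factor at a percentage checkpoint
#'
#' @param scores Numeric decoy scores (higher = more native-like).
#' @param labels `"positive"`/`"negative"` (or 0/1) true labels.
#' @param x_percent Checkpoint in (0, 100].
#' @param ids Optional model ids for deterministic tie-breaks.
#' @return The enrichment factor (1.0 at `x_percent = 100`).
#' @export
enrichment_factor <- function(scores, labels, x_percent, ids = NULL) {
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            x_percent > 0, x_percent <= 100)
  y <- if (is.character(labels)) labels == "positive" else labels > 0
  n <- length(scores)
  npos <- sum(y)
  if (npos == 0) stop("EF undefined: no positive samples")
  n_top <- max(1L, round(x_percent / 100 * n))
  top <- rank_order(scores, ids)[seq_len(n_top)]
  (sum(y[top]) / n_top) * (n / npos)
}

#' Maximum attainable enrichment factor
#'
#' @inheritParams enrichment_factor
#' @return `N / N_positives`.
#' @export
ef_max <- function(labels) {
  y <- if (is.character(labels)) labels == "positive" else labels > 0
  if (!sum(y)) stop("EF undefined: no positive samples")
  length(y) / sum(y)
}

#' Success-rate curve over top-N ranks
#'
#' @param per_target List of per-target data.frames with columns `score`,
#'   `label` and optionally `model_id`.
#' @param n_max Largest rank N to report.
#' @return Numeric vector `sr[N]`, N = 1..n_max: fraction of targets whose
#'   top-N decoys contain at least one positive. Monotone non-decreasing.
#' @export
success_rate <- function(per_target, n_max) {
  stopifnot(length(per_target) >= 1, n_max >= 1)
  firsts <- vapply(per_target, function(df) {
    y <- if (is.character(df$label)) df$label == "positive" else df$label > 0
    ord <- rank_order(df$score, df$model_id)
    hit <- which(y[ord])
    if (length(hit)) hit[1] else Inf
  }, numeric(1))
  vapply(seq_len(n_max), function(N) mean(firsts <= N), numeric(1))
}

#' Confusion counts at a probability threshold
#'
#' @inheritParams enrichment_factor
#' @param threshold Decision threshold (default 0.5).
#' @return Named vector `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  y <- if (is.character(labels)) labels == "positive" else labels > 0
  pred <- scores >= threshold
  c(tp = sum(pred & y), fp = sum(pred & !y),
    tn = sum(!pred & !y), fn = sum(!pred & y))
}

#' Evaluation report for one target
#'
#' Targets with zero positives cannot be evaluated by EF and should be
#' excluded upstream (see [aggregate_folds()]).
#'
#' @param df data.frame with `score`, `label`, optionally `model_id`.
#' @param checkpoints EF checkpoints in percent
#'   (default `c(0.01, 0.1, 0.5, 1, 5, 10)`).
#' @param n_max Success-curve depth (default `min(nrow, 10)`).
#' @param threshold Confusion-count threshold.
#' @return `EvalReport`: list with `ef` (named vector per checkpoint),
#'   `ef_max`, `success` (curve), `confusion`.
#' @export
evaluate_target <- function(df, checkpoints = c(0.01, 0.1, 0.5, 1, 5, 10),
                            n_max = min(nrow(df), 10L), threshold = 0.5) {
  ef <- vapply(checkpoints, function(x) {
    enrichment_factor(df$score, df$label, x, df$model_id)
  }, numeric(1))
  names(ef) <- paste0("EF_", checkpoints, "%")
  structure(list(
    ef = ef,
    ef_max = ef_max(df$label),
    success = success_rate(list(df), n_max),
    confusion = confusion_counts(df$score, df$label, threshold),
    checkpoints = checkpoints
  ), class = "EvalReport")
}

#' Average per-target reports over targets, then over folds
#'
#' Targets lacking positives are dropped (with a message giving the count),
#' mirroring the removal of complexes without any near-native decoy.
#'
#' @param folds List (per fold) of lists (per target) of data.frames as in
#'   [evaluate_target()].
#' @param checkpoints EF checkpoints in percent.
#' @return List with `ef` (named mean EF per checkpoint), `ef_max` (mean),
#'   `n_targets` used per fold.
#' @export
aggregate_folds <- function(folds, checkpoints = c(0.01, 0.1, 0.5, 1, 5, 10)) {
  dropped <- 0L
  per_fold <- lapply(folds, function(targets) {
    keep <- Filter(function(df) {
      y <- if (is.character(df$label)) df$label == "positive" else df$label > 0
      any(y)
    }, targets)
    dropped <<- dropped + (length(targets) - length(keep))
    if (!length(keep)) return(NULL)
    efs <- vapply(keep, function(df) {
      evaluate_target(df, checkpoints)$ef
    }, numeric(length(checkpoints)))
    efs <- matrix(efs, nrow = length(checkpoints),
                  dimnames = list(paste0("EF_", checkpoints, "%"), NULL))
    list(ef = rowMeans(efs),
         ef_max = mean(vapply(keep, function(df) ef_max(df$label), numeric(1))),
         n = length(keep))
  })
  per_fold <- Filter(Negate(is.null), per_fold)
  if (!length(per_fold)) stop("no evaluable targets in any fold")
  if (dropped) message(dropped, " target(s) without positives excluded")
  ef_mat <- do.call(rbind, lapply(per_fold, `[[`, "ef"))
  list(
    ef = colMeans(ef_mat),
    ef_max = mean(vapply(per_fold, `[[`, numeric(1), "ef_max")),
    n_targets = vapply(per_fold, `[[`, integer(1), "n")
  )
}
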