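# Classifier evaluation: rank-based ROC/AUC, confusion statistics with
# confidence intervals, and the two resampling validation harnesses
# (repeated stratified down-sampling of a fixed model's predictions, and
# repeated train/test splits with full refits).

as_binary_labels <- function(labels, positive = NULL) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.integer(labels))
  labels <- as.character(labels)
  u <- unique(labels)
  if (length(u) != 2) stop("labels must have exactly two classes", call. = FALSE)
  if (is.null(positive)) positive <- u[[1]]
  as.integer(labels == positive)
}

# fast rank-statistic AUC (ties get half credit)
auc_score <- function(scores, y) {
  pos <- y == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: one class absent", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' AUC is the rank (Mann-Whitney) estimate, `P(score_pos > score_neg) +
#' 0.5 P(tie)`; ROC points are computed at every unique score threshold.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Binary 0/1 vector or two-class labels.
#' @param positive Positive class when `labels` is not already 0/1.
#' @return List with `auc` and `roc_points` (tibble of `threshold`, `fpr`,
#'   `tpr`, sorted by increasing fpr).
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  y <- as_binary_labels(labels, positive)
  auc <- auc_score(scores, y)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- purrr::map_dfr(thr, function(t) {
    pred <- scores >= t
    tibble::tibble(threshold = t,
                   fpr = sum(pred & y == 0) / sum(y == 0),
                   tpr = sum(pred & y == 1) / sum(y == 1))
  })
  list(auc = auc, roc_points = pts)
}

clopper_pearson <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  ci <- stats::binom.test(x, n, conf.level = conf)$conf.int
  c(ci[[1]], ci[[2]])
}

#' Confusion statistics with confidence intervals
#'
#' Calls a sample positive when its score is strictly above `threshold`,
#' tabulates the 2x2 confusion table, and reports accuracy, sensitivity
#' (TPR) and specificity (TNR) with exact Clopper-Pearson intervals, plus
#' the AUC with a stratified bootstrap percentile interval.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold (default 0.5).
#' @param boot Bootstrap resamples for the AUC interval (default 2000).
#' @param seed Seed for the bootstrap.
#' @param conf Confidence level (default 0.95).
#' @return A `tcr_eval` object; see [tidy.tcr_eval()] and
#'   [glance.tcr_eval()].
#' @export
confusion_stats <- function(scores, labels, threshold = 0.5, positive = NULL,
                            boot = 2000, seed = 1, conf = 0.95) {
  y <- as_binary_labels(labels, positive)
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1 & y == 1); fn <- sum(pred == 0 & y == 1)
  tn <- sum(pred == 0 & y == 0); fp <- sum(pred == 1 & y == 0)
  n <- length(y)
  roc <- roc_auc(scores, y)

  set.seed(seed)
  idx_pos <- which(y == 1); idx_neg <- which(y == 0)
  boot_auc <- vapply(seq_len(boot), function(i) {
    bi <- c(sample(idx_pos, replace = TRUE), sample(idx_neg, replace = TRUE))
    auc_score(scores[bi], y[bi])
  }, numeric(1))
  alpha <- (1 - conf) / 2

  structure(list(
    auc = roc$auc,
    auc_ci = unname(stats::quantile(boot_auc, c(alpha, 1 - alpha))),
    accuracy = (tp + tn) / n,
    accuracy_ci = clopper_pearson(tp + tn, n, conf),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    sensitivity_ci = clopper_pearson(tp, tp + fn, conf),
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    specificity_ci = clopper_pearson(tn, tn + fp, conf),
    confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                       dimnames = list(predicted = c("pos", "neg"),
                                       truth = c("pos", "neg"))),
    roc_points = roc$roc_points,
    threshold = threshold, n = n, conf = conf
  ), class = "tcr_eval")
}

#' @export
print.tcr_eval <- function(x, ...) {
  cat(sprintf(paste0("<tcr_eval> n=%d thr=%.2f | AUC %.3f [%.3f, %.3f] | ",
                     "acc %.3f | sens %.3f | spec %.3f\n"),
              x$n, x$threshold, x$auc, x$auc_ci[[1]], x$auc_ci[[2]],
              x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' Subset a cohort by sample id
#' @param cohort A `tcr_cohort`.
#' @param sample_ids Sample ids to keep.
#' @return A `tcr_cohort`.
#' @export
subset_cohort <- function(cohort, sample_ids) {
  as_cohort(cohort$repertoires[sample_ids], groups = cohort_groups(cohort))
}

stratified_indices <- function(labels, frac, replace = FALSE) {
  unlist(lapply(unique(labels), function(g) {
    idx <- which(labels == g)
    sample(idx, size = max(1, ceiling(frac * length(idx))), replace = replace)
  }), use.names = FALSE)
}

#' Down-sampling validation of a fitted model
#'
#' Scores the whole cohort once with the fitted ensemble, then repeatedly
#' evaluates sensitivity, specificity and AUC on stratified random subsets
#' (fraction `frac` of each class per iteration).
#'
#' @param model A `tcr_stack_ensemble`.
#' @param cohort Labelled `tcr_cohort`.
#' @param iters Number of iterations (default 1000).
#' @param frac Fraction of each class retained per iteration (default 0.8).
#' @param seed Seed.
#' @param threshold Decision threshold; defaults to the model's.
#' @return List with `iterations` (tibble: iter, sensitivity, specificity,
#'   auc) and `summary` (tibble of median and IQR per metric).
#' @export
downsample_validation <- function(model, cohort, iters = 1000, frac = 0.8,
                                  seed = 1, threshold = NULL) {
  if (is.null(threshold)) threshold <- model$threshold
  preds <- stats::predict(model, cohort)
  y <- as.integer(preds$label == model$groups[[1]])
  set.seed(seed)
  res <- purrr::map_dfr(seq_len(iters), function(i) {
    idx <- stratified_indices(y, frac)
    s <- preds$score[idx]; yy <- y[idx]
    pred <- as.integer(s > threshold)
    tibble::tibble(
      iter = i,
      sensitivity = sum(pred == 1 & yy == 1) / sum(yy == 1),
      specificity = sum(pred == 0 & yy == 0) / sum(yy == 0),
      auc = auc_score(s, yy)
    )
  })
  summary <- res |>
    tidyr::pivot_longer(-"iter", names_to = "metric") |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(median = stats::median(.data$value),
                     q25 = stats::quantile(.data$value, 0.25),
                     q75 = stats::quantile(.data$value, 0.75),
                     .groups = "drop")
  list(iterations = res, summary = summary)
}

#' Repeated random-split validation
#'
#' Repeatedly splits the cohort into stratified train/test sets, refits the
#' full pipeline on the train split, and records train and test AUC.
#'
#' @param cohort Labelled `tcr_cohort`.
#' @param task Optional `c(positive, negative)`.
#' @param iters Number of splits (default 1000).
#' @param train_frac Training fraction per split (default 0.7).
#' @param seed Seed.
#' @param grids Grids from [model_grids()]; reduced profiles keep repeated
#'   refits affordable.
#' @param ... Passed on to [fit_pipeline()].
#' @return Tibble with columns `iter`, `train_auc`, `test_auc`.
#' @export
split_validation <- function(cohort, task = NULL, iters = 1000,
                             train_frac = 0.7, seed = 1,
                             grids = model_grids("minimal"), ...) {
  groups <- if (!is.null(task)) task else cohort_groups(cohort)
  labels <- cohort$samples$label
  dots <- list(...)
  raw <- compute_raw_features(
    cohort,
    k = dots$k %||% 5,
    weighted_motifs = dots$weighted_motifs %||% FALSE,
    encoder = dots$encoder %||% encoder_spec(),
    n_top = dots$n_top %||% 100)
  subset_raw <- function(ids) {
    list(motif_raw = raw$motif_raw[ids, , drop = FALSE],
         emb = raw$emb[ids, , drop = FALSE])
  }
  purrr::map_dfr(seq_len(iters), function(i) {
    set.seed(derive_seed(seed, 11, i))
    idx <- stratified_indices(labels, train_frac)
    train_ids <- cohort$samples$sample_id[sort(idx)]
    test_ids <- setdiff(cohort$samples$sample_id, train_ids)
    fit <- do.call(fit_pipeline, c(list(
      subset_cohort(cohort, train_ids), task = groups,
      seed = derive_seed(seed, 13, i), grids = grids,
      raw_features = subset_raw(train_ids)), dots))
    p_tr <- stats::predict(fit, subset_cohort(cohort, train_ids),
                           raw_features = subset_raw(train_ids))
    p_te <- stats::predict(fit, subset_cohort(cohort, test_ids),
                           raw_features = subset_raw(test_ids))
    tibble::tibble(
      iter = i,
      train_auc = auc_score(p_tr$score,
                            as.integer(p_tr$label == groups[[1]])),
      test_auc = auc_score(p_te$score,
                           as.integer(p_te$label == groups[[1]]))
    )
  })
}
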