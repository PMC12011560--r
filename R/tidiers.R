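# broom-style tidiers for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the selected models of a stacked ensemble
#'
#' One row per fitted model in both layers, with its feature block, family,
#' hyperparameters and cross-validated AUC.
#'
#' @param x A `tcr_stack_ensemble`.
#' @param ... Unused.
#' @return Tibble with columns `layer`, `block`, `family`, `params`
#'   (character), `cv_auc`.
#' @export
tidy.tcr_stack_ensemble <- function(x, ...) {
  fmt <- function(p) paste(names(p), unlist(p), sep = "=", collapse = ", ")
  l1 <- tibble::tibble(
    layer = 1L,
    block = x$layer1$selected$block,
    family = x$layer1$selected$family,
    params = vapply(x$layer1$selected$params, fmt, ""),
    cv_auc = x$layer1$selected$cv_auc
  )
  l2 <- tibble::tibble(
    layer = 2L, block = "stack",
    family = x$stackers$family,
    params = vapply(x$stackers$params, fmt, ""),
    cv_auc = x$stackers$cv_auc
  )
  dplyr::bind_rows(l1, l2)
}

#' One-row summary of a stacked ensemble
#'
#' @param x A `tcr_stack_ensemble`.
#' @param ... Unused.
#' @return Tibble with the task, training size, model counts and mean
#'   cross-validated stacker AUC.
#' @export
glance.tcr_stack_ensemble <- function(x, ...) {
  tibble::tibble(
    positive = x$groups[[1]], negative = x$groups[[2]],
    n_train = x$n_train,
    n_layer1 = nrow(x$layer1$selected),
    n_stackers = nrow(x$stackers),
    mean_stacker_cv_auc = mean(x$stackers$cv_auc),
    threshold = x$threshold
  )
}

#' Tidy an evaluation report
#'
#' @param x A `tcr_eval` from [confusion_stats()].
#' @param ... Unused.
#' @return Tibble with columns `metric`, `estimate`, `conf.low`, `conf.high`.
#' @export
tidy.tcr_eval <- function(x, ...) {
  tibble::tibble(
    metric = c("auc", "accuracy", "sensitivity", "specificity"),
    estimate = c(x$auc, x$accuracy, x$sensitivity, x$specificity),
    conf.low = c(x$auc_ci[[1]], x$accuracy_ci[[1]],
                 x$sensitivity_ci[[1]], x$specificity_ci[[1]]),
    conf.high = c(x$auc_ci[[2]], x$accuracy_ci[[2]],
                  x$sensitivity_ci[[2]], x$specificity_ci[[2]])
  )
}

#' One-row summary of an evaluation report
#'
#' @param x A `tcr_eval`.
#' @param ... Unused.
#' @return One-row tibble of the point estimates, threshold and n.
#' @export
glance.tcr_eval <- function(x, ...) {
  tibble::tibble(auc = x$auc, accuracy = x$accuracy,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 threshold = x$threshold, n = x$n)
}
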