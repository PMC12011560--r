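# Clonal diversity statistics. All logarithms are natural; clone fractions
# are the p_i of a repertoire (summing to 1).

check_fractions <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0) stop("empty fraction vector", call. = FALSE)
  if (any(p < 0)) stop("negative clone fraction", call. = FALSE)
  s <- sum(p)
  if (abs(s - 1) > 1e-6) {
    stop("clone fractions sum to ", format(s), ", not 1", call. = FALSE)
  }
  p
}

#' Shannon diversity of a clone-fraction vector
#'
#' \eqn{H = -\sum_i p_i \ln p_i}; zero fractions contribute 0.
#'
#' @param fractions Numeric vector of clone fractions summing to 1.
#' @return Non-negative scalar, at most `log(length(fractions))`.
#' @export
shannon <- function(fractions) {
  p <- check_fractions(fractions)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Gini-Simpson diversity of a clone-fraction vector
#'
#' \eqn{D = 1 - \sum_i p_i^2}: the probability that two reads drawn at random
#' come from different clones.
#'
#' @inheritParams shannon
#' @return Scalar in \[0, 1).
#' @export
simpson <- function(fractions) {
  p <- check_fractions(fractions)
  1 - sum(p^2)
}

#' Clonal evenness
#'
#' Shannon diversity divided by the log of richness, \eqn{E = H / \ln R};
#' defined as 0 for a single-clone repertoire.
#'
#' @inheritParams shannon
#' @return Scalar in \[0, 1\].
#' @export
evenness <- function(fractions) {
  p <- check_fractions(fractions)
  r <- length(p[p > 0])
  if (r <= 1) return(0)
  shannon(p) / log(r)
}

#' Clones needed to cover half the repertoire
#'
#' The smallest number of top clones whose cumulative fraction strictly
#' exceeds 0.5.
#'
#' @inheritParams shannon
#' @return Positive integer.
#' @export
clones_to_half <- function(fractions) {
  p <- check_fractions(fractions)
  cum <- cumsum(sort(p, decreasing = TRUE))
  k <- which(cum > 0.5)
  if (length(k) == 0) length(p) else k[[1]]
}

#' Per-sample diversity table for a cohort
#'
#' Computes Shannon, Gini-Simpson, richness (number of clonotypes), evenness,
#' top clone fraction and clones-to-half for every repertoire.
#'
#' @param cohort A `tcr_cohort`.
#' @return Tibble with one row per sample: `sample_id`, `chain`, `label`,
#'   `richness`, `shannon`, `simpson`, `evenness`, `top_clone_fraction`,
#'   `clones_to_half`.
#' @export
diversity_table <- function(cohort) {
  stopifnot(inherits(cohort, "tcr_cohort"))
  purrr::map_dfr(cohort$repertoires, function(r) {
    p <- r$fraction
    tibble::tibble(
      sample_id = attr(r, "sample_id"),
      chain = attr(r, "chain"),
      label = attr(r, "label"),
      richness = nrow(r),
      shannon = shannon(p),
      simpson = simpson(p),
      evenness = evenness(p),
      top_clone_fraction = max(p),
      clones_to_half = clones_to_half(p)
    )
  })
}
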