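# Read-level repertoire simulator: subset clones, renormalise, draw reads by
# multinomial sampling proportional to clone fraction, regroup by CDR3 amino
# acid sequence, re-rank, and emit clonotype tables.

#' Simulation configuration
#'
#' Defaults: one million reads per simulated dataset, half of the source
#' clones retained, 100 datasets per group.
#'
#' @param n_reads Reads per simulated dataset (default 1e6).
#' @param clone_keep_frac Fraction of unique clones retained (default 0.5).
#' @param n_datasets Datasets per group (default 100).
#' @param seed Integer seed.
#' @param label Group label attached to simulated repertoires.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_reads = 1e6, clone_keep_frac = 0.5,
                              n_datasets = 100, seed = 1, label = NULL) {
  stopifnot(n_reads >= 1, clone_keep_frac > 0, clone_keep_frac <= 1,
            n_datasets >= 1)
  structure(list(n_reads = as.integer(n_reads),
                 clone_keep_frac = clone_keep_frac,
                 n_datasets = as.integer(n_datasets),
                 seed = as.integer(seed), label = label),
            class = "sim_config")
}

#' Simulate one read-level dataset from a source repertoire
#'
#' Retains `ceiling(clone_keep_frac * richness)` uniformly random clones,
#' renormalises their fractions, draws `n_reads` reads in one multinomial
#' draw with those probabilities (equivalent to `n_reads` independent
#' categorical draws), groups the reads by CDR3 amino-acid sequence, and
#' re-ranks. Clones drawn zero times are absent from the output; counts sum
#' to exactly `n_reads` and fractions to 1.
#'
#' @param source A `tcr_repertoire` with at least 2 clonotypes.
#' @param cfg A [simulation_config()].
#' @param sample_id Identifier for the simulated repertoire.
#' @return A `tcr_repertoire`.
#' @export
simulate_one <- function(source, cfg = simulation_config(),
                         sample_id = "sim") {
  stopifnot(inherits(source, "tcr_repertoire"))
  m <- ceiling(cfg$clone_keep_frac * nrow(source))
  if (m < 1) stop("clone_keep_frac leaves no clones", call. = FALSE)
  if (nrow(source) < 2) stop("source needs >= 2 clonotypes", call. = FALSE)
  keep <- sort(sample(nrow(source), m))
  p <- source$fraction[keep]
  p <- p / sum(p)
  counts <- as.vector(stats::rmultinom(1, cfg$n_reads, p))
  drawn <- counts > 0
  df <- tibble::tibble(
    count = counts[drawn],
    fraction = counts[drawn] / cfg$n_reads,
    cdr3_aa = source$cdr3_aa[keep][drawn],
    v_gene = source$v_gene[keep][drawn],
    j_gene = source$j_gene[keep][drawn]
  )
  as_repertoire(df, sample_id = sample_id, chain = attr(source, "chain"),
                label = cfg$label)
}

#' Pool the clonotypes of all samples with a given label
#'
#' Clonotype fractions are summed across samples (each sample contributes a
#' fraction vector summing to 1) and renormalised, so samples are weighted
#' equally; duplicate CDR3s merge under the standard rule.
#'
#' @param cohort A `tcr_cohort`.
#' @param label Group label to pool.
#' @return A `tcr_repertoire` with `sample_id = paste0(label, "_pool")`.
#' @export
pool_label <- function(cohort, label) {
  sel <- cohort$samples$sample_id[cohort$samples$label == label]
  if (length(sel) == 0) stop("label '", label, "' absent from cohort", call. = FALSE)
  df <- dplyr::bind_rows(lapply(cohort$repertoires[sel], tibble::as_tibble))
  chain <- unique(cohort$samples$chain[cohort$samples$label == label])
  as_repertoire(df, sample_id = paste0(label, "_pool"),
                chain = if (length(chain) == 1) chain else NULL,
                label = label)
}

#' Simulate a batch of datasets for one group
#'
#' Pools all clonotypes of the labelled samples into one source repertoire
#' and generates `cfg$n_datasets` simulated repertoires, optionally written
#' as `<label>_sim<k>.tsv`.
#'
#' @param cohort A labelled `tcr_cohort`.
#' @param label Group to simulate.
#' @param cfg A [simulation_config()].
#' @param out_dir Directory for the TSV files; `NULL` skips writing.
#' @return List of `tcr_repertoire` objects (invisibly also written to
#'   `out_dir` when given).
#' @export
simulate_group <- function(cohort, label, cfg = simulation_config(),
                           out_dir = NULL) {
  source <- pool_label(cohort, label)
  cfg$label <- label
  sims <- lapply(seq_len(cfg$n_datasets), function(k) {
    set.seed(derive_seed(cfg$seed, match(label, sort(unique(cohort$samples$label))), k))
    simulate_one(source, cfg, sample_id = sprintf("%s_sim%d", label, k))
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (s in sims) {
      write_clonotype_table(s, file.path(out_dir, paste0(attr(s, "sample_id"), ".tsv")))
    }
  }
  sims
}
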