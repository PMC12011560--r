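# Synthetic two-group cohort generator with planted, parameterised effects:
# 5-mer motif enrichment, V-J usage skew, and CDR3 length shifts, on top of
# a Zipf clone-abundance model. Every pipeline stage is testable against
# cohorts from this module without external data.

#' Specification of a synthetic two-group cohort
#'
#' @param n_per_group Samples per group (default 60).
#' @param clones_per_sample Clonotypes per sample (default 300).
#' @param groups Ordered pair of group labels (positive first).
#' @param cdr3_len_range Inclusive CDR3 length range; lengths are drawn from
#'   a discretised normal centred in the range (default 8-20, within the
#'   5-24 band used by the positional analyses).
#' @param v_genes,j_genes Gene name pools; V names must carry a TRB/TRD/TRG
#'   prefix so the chain is derivable.
#' @param planted_motifs Data frame with columns `motif` (5-mer),
#'   `enrichment` (>= 1, multiplies the insertion rate) and `group` (target).
#' @param vj_skew Data frame with columns `vj` ("V|J"), `log2_effect` and
#'   `group`: the pair's base probability is multiplied by `2^log2_effect`
#'   in the target group.
#' @param len_shift Added to the mean CDR3 length of `len_shift_group`
#'   (amino acids, default 0).
#' @param len_shift_group Group receiving the length shift (default the
#'   second group).
#' @param base_motif_rate Baseline per-clone insertion probability of each
#'   planted motif (default 0.05).
#' @param zipf_exponent Clone-abundance Zipf exponent (default 1.2).
#' @param reads_per_sample Total reads a sample's counts add up to
#'   (default 1e5).
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group = 60, clones_per_sample = 300,
                        groups = c("case", "control"),
                        cdr3_len_range = c(8, 20),
                        v_genes = paste0("TRBV", 1:8),
                        j_genes = paste0("TRBJ", c("1-1", "1-2", "2-1", "2-7")),
                        planted_motifs = NULL, vj_skew = NULL,
                        len_shift = 0, len_shift_group = groups[[2]],
                        base_motif_rate = 0.05, zipf_exponent = 1.2,
                        reads_per_sample = 1e5, seed = 1) {
  stopifnot(length(groups) == 2, n_per_group >= 1, clones_per_sample >= 2,
            cdr3_len_range[[1]] >= 5, cdr3_len_range[[2]] >= cdr3_len_range[[1]])
  if (!is.null(planted_motifs)) {
    planted_motifs <- tibble::as_tibble(planted_motifs)
    stopifnot(all(c("motif", "enrichment", "group") %in% names(planted_motifs)),
              all(planted_motifs$enrichment >= 1),
              all(planted_motifs$group %in% groups))
    if (any(nchar(planted_motifs$motif) > cdr3_len_range[[1]])) {
      stop("planted motif longer than the minimum CDR3 length", call. = FALSE)
    }
  }
  if (!is.null(vj_skew)) {
    vj_skew <- tibble::as_tibble(vj_skew)
    stopifnot(all(c("vj", "log2_effect", "group") %in% names(vj_skew)),
              all(vj_skew$group %in% groups))
  }
  structure(list(
    n_per_group = as.integer(n_per_group),
    clones_per_sample = as.integer(clones_per_sample),
    groups = groups, cdr3_len_range = cdr3_len_range,
    v_genes = v_genes, j_genes = j_genes,
    planted_motifs = planted_motifs, vj_skew = vj_skew,
    len_shift = len_shift, len_shift_group = len_shift_group,
    base_motif_rate = base_motif_rate, zipf_exponent = zipf_exponent,
    reads_per_sample = reads_per_sample, seed = as.integer(seed)
  ), class = "cohort_spec")
}

random_cdr3 <- function(len) {
  # canonical junction anchors: C...F
  core <- sample(AA_ALPHABET, len - 2, replace = TRUE)
  paste0("C", paste(core, collapse = ""), "F")
}

insert_motif <- function(seq, motif) {
  L <- nchar(seq); k <- nchar(motif)
  lo <- if (L >= k + 2) 2 else 1
  hi <- if (L >= k + 2) L - k else L - k + 1
  start <- if (hi > lo) sample(lo:hi, 1) else lo
  paste0(substr(seq, 1, start - 1), motif, substr(seq, start + k, L))
}

generate_sample <- function(spec, group, sample_id) {
  rng <- spec$cdr3_len_range
  mean_len <- mean(rng) +
    if (group == spec$len_shift_group) spec$len_shift else 0
  n <- spec$clones_per_sample

  # V-J pair distribution, tilted for the target group
  pairs <- expand.grid(v = spec$v_genes, j = spec$j_genes,
                       stringsAsFactors = FALSE)
  pp <- rep(1, nrow(pairs))
  if (!is.null(spec$vj_skew)) {
    key <- paste(pairs$v, pairs$j, sep = "|")
    for (i in seq_len(nrow(spec$vj_skew))) {
      hit <- key == spec$vj_skew$vj[[i]]
      if (!any(hit)) stop("vj_skew pair not in gene pools: ",
                          spec$vj_skew$vj[[i]], call. = FALSE)
      if (group == spec$vj_skew$group[[i]]) {
        pp[hit] <- pp[hit] * 2^spec$vj_skew$log2_effect[[i]]
      }
    }
  }
  pp <- pp / sum(pp)

  motifs <- spec$planted_motifs
  make_one <- function() {
    len <- round(stats::rnorm(1, mean_len, 1.5))
    len <- min(max(len, rng[[1]]), rng[[2]])
    s <- random_cdr3(len)
    if (!is.null(motifs)) {
      for (i in seq_len(nrow(motifs))) {
        rate <- spec$base_motif_rate *
          (if (group == motifs$group[[i]]) motifs$enrichment[[i]] else 1)
        if (stats::runif(1) < min(1, rate)) s <- insert_motif(s, motifs$motif[[i]])
      }
    }
    s
  }
  seqs <- character(n)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_len(n)) {
    for (tries in 1:1000) {
      s <- make_one()
      if (is.null(seen[[s]])) { seen[[s]] <- TRUE; break }
    }
    seqs[[i]] <- s
  }
  pair_idx <- sample(nrow(pairs), n, replace = TRUE, prob = pp)
  p <- (seq_len(n))^(-spec$zipf_exponent)
  p <- p / sum(p)
  counts <- pmax(1, round(p * spec$reads_per_sample))
  as_repertoire(
    tibble::tibble(count = counts, cdr3_aa = seqs,
                   v_gene = pairs$v[pair_idx], j_gene = pairs$j[pair_idx]),
    sample_id = sample_id, label = group
  )
}

#' Generate a synthetic labelled cohort
#'
#' Deterministic under the spec's seed: clone fractions follow a normalised
#' Zipf law, CDR3s are random amino-acid strings with canonical C/F anchors,
#' planted motifs are inserted with probability scaled by their enrichment
#' factor in the target group, V-J pairs are drawn from a categorical
#' distribution tilted by the requested skews, and the mean CDR3 length is
#' shifted in the target group.
#'
#' @param spec A [cohort_spec()].
#' @return A `tcr_cohort` with `groups` set from the spec.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  reps <- list()
  for (g in spec$groups) {
    for (i in seq_len(spec$n_per_group)) {
      id <- sprintf("%s_%02d", g, i)
      reps[[id]] <- generate_sample(spec, g, id)
    }
  }
  as_cohort(reps, groups = spec$groups)
}

#' Realised vs requested planted effects
#'
#' Measures, on a generated cohort, the realised motif enrichment (ratio of
#' the per-clone motif occurrence rates between target and other group), the
#' realised V-J log2 usage skew, and the realised mean CDR3 length
#' difference, next to the requested values.
#'
#' @param cohort Cohort from [generate_cohort()].
#' @param spec The [cohort_spec()] that produced it.
#' @return Tibble with columns `effect_type`, `key`, `group`, `requested`,
#'   `realized`.
#' @export
planted_effect_report <- function(cohort, spec) {
  cl <- cohort_clonotypes(cohort)
  out <- list()
  if (!is.null(spec$planted_motifs)) {
    out$motifs <- purrr::pmap_dfr(spec$planted_motifs,
                                  function(motif, enrichment, group) {
      rate <- function(g) {
        s <- cl$cdr3_aa[cl$label == g]
        mean(grepl(motif, s, fixed = TRUE))
      }
      other <- setdiff(spec$groups, group)
      tibble::tibble(effect_type = "motif_enrichment", key = motif,
                     group = group, requested = enrichment,
                     realized = rate(group) / max(rate(other), 1e-12))
    })
  }
  if (!is.null(spec$vj_skew)) {
    freq <- function(pair, g) {
      s <- cl[cl$label == g, ]
      mean(paste(s$v_gene, s$j_gene, sep = "|") == pair)
    }
    out$vj <- purrr::pmap_dfr(spec$vj_skew, function(vj, log2_effect, group) {
      other <- setdiff(spec$groups, group)
      tibble::tibble(effect_type = "vj_skew", key = vj, group = group,
                     requested = log2_effect,
                     realized = log2(freq(vj, group) / max(freq(vj, other), 1e-12)))
    })
  }
  if (spec$len_shift != 0) {
    other <- setdiff(spec$groups, spec$len_shift_group)
    mlen <- function(g) mean(nchar(cl$cdr3_aa[cl$label == g]))
    out$len <- tibble::tibble(effect_type = "len_shift", key = "mean_cdr3_length",
                              group = spec$len_shift_group,
                              requested = spec$len_shift,
                              realized = mlen(spec$len_shift_group) - mlen(other))
  }
  dplyr::bind_rows(out)
}

#' Write a synthetic cohort to disk with a manifest
#'
#' @param cohort A `tcr_cohort`.
#' @param out_dir Output directory.
#' @return Path of the written manifest CSV, invisibly.
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::map_dfr(cohort$repertoires, function(r) {
    id <- attr(r, "sample_id")
    f <- paste0(id, ".tsv")
    write_clonotype_table(r, file.path(out_dir, f))
    tibble::tibble(sample_id = id, path = f, chain = attr(r, "chain"),
                   label = attr(r, "label"))
  })
  manifest <- file.path(out_dir, "manifest.csv")
  readr::write_csv(rows, manifest, progress = FALSE)
  invisible(manifest)
}
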