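# Group-level descriptive repertoire features: V-J pair usage, positional
# amino-acid composition, CDR3 length comparisons, 5-mer motif matrices,
# one-vs-rest differential motif testing, motif overlap curves, and the
# pairwise repertoire-overlap matrix.

#' V-J pair frequencies per group
#'
#' Counts clonotypes per V-J pair and group, drops pairs supported by fewer
#' than `min_clones` clonotypes across the whole cohort, and renormalises the
#' remaining frequencies so each group column sums to 1.
#'
#' @param cohort A labelled `tcr_cohort`.
#' @param min_clones Minimum total clonotype support across the cohort for a
#'   V-J pair to be retained (default 100).
#' @return Tibble with columns `vj` ("V|J"), `group`, `support` (clonotypes
#'   in that group), `frequency` (sums to 1 within each group).
#' @export
vj_frequencies <- function(cohort, min_clones = 100) {
  cl <- cohort_clonotypes(cohort)
  if (all(is.na(cl$label))) stop("cohort has no group labels", call. = FALSE)
  tab <- cl |>
    dplyr::mutate(vj = paste(.data$v_gene, .data$j_gene, sep = "|")) |>
    dplyr::count(.data$vj, .data$label, name = "support")
  keep <- tab |>
    dplyr::count(.data$vj, wt = .data$support, name = "total") |>
    dplyr::filter(.data$total >= min_clones)
  tab <- dplyr::semi_join(tab, keep, by = "vj")
  if (nrow(tab) == 0) {
    stop("no V-J pair reaches min_clones = ", min_clones, call. = FALSE)
  }
  tab |>
    dplyr::group_by(.data$label) |>
    dplyr::mutate(frequency = .data$support / sum(.data$support)) |>
    dplyr::ungroup() |>
    dplyr::rename(group = "label") |>
    dplyr::arrange(.data$vj, .data$group)
}

#' Log2 usage preference between two groups
#'
#' \eqn{\log_2((f_A + \epsilon) / (f_B + \epsilon))} per V-J pair; exactly
#' antisymmetric under swapping the groups. Pairs absent from one group get
#' frequency 0 there.
#'
#' @param table Output of [vj_frequencies()].
#' @param group_a,group_b Group names (numerator, denominator).
#' @param pseudo Pseudocount added to both frequencies (default 1e-6).
#' @return Tibble with columns `vj`, `freq_a`, `freq_b`, `log2_ratio`.
#' @export
vj_preference <- function(table, group_a, group_b, pseudo = 1e-6) {
  if (!all(c(group_a, group_b) %in% table$group)) {
    stop("unknown group name(s): ",
         paste(setdiff(c(group_a, group_b), table$group), collapse = ", "),
         call. = FALSE)
  }
  wide <- table |>
    dplyr::select("vj", "group", "frequency") |>
    tidyr::pivot_wider(names_from = "group", values_from = "frequency",
                       values_fill = 0)
  tibble::tibble(
    vj = wide$vj,
    freq_a = wide[[group_a]],
    freq_b = wide[[group_b]],
    # difference of logs keeps group-swap antisymmetry bit-exact
    log2_ratio = log2(wide[[group_a]] + pseudo) - log2(wide[[group_b]] + pseudo)
  ) |>
    dplyr::arrange(.data$vj)
}

#' Positional amino-acid composition of a group
#'
#' Clone-fraction-weighted frequency of each amino acid at each CDR3
#' position (1-based from the N-terminus), over clones whose CDR3 length is
#' within `[len_min, len_max]`. Each position column sums to 1 over the
#' amino acids present among clones long enough to reach that position.
#'
#' @param cohort A `tcr_cohort`.
#' @param group Group label to restrict to; `NULL` uses all samples.
#' @param len_min,len_max CDR3 length filter (defaults 5 and 24).
#' @return Numeric matrix, 20 amino acids (rows) x `len_max` positions.
#' @export
positional_aa_matrix <- function(cohort, group = NULL, len_min = 5, len_max = 24) {
  cl <- cohort_clonotypes(cohort)
  if (!is.null(group)) cl <- dplyr::filter(cl, .data$label == group)
  len <- nchar(cl$cdr3_aa)
  cl <- cl[len >= len_min & len <= len_max, , drop = FALSE]
  mat <- matrix(0, nrow = 20, ncol = len_max,
                dimnames = list(AA_ALPHABET, seq_len(len_max)))
  if (nrow(cl) == 0) return(mat)
  for (i in seq_len(nrow(cl))) {
    aas <- strsplit(cl$cdr3_aa[[i]], "")[[1]]
    w <- cl$fraction[[i]]
    for (pos in seq_along(aas)) mat[aas[[pos]], pos] <- mat[aas[[pos]], pos] + w
  }
  cs <- colSums(mat)
  nz <- cs > 0
  mat[, nz] <- sweep(mat[, nz, drop = FALSE], 2, cs[nz], "/")
  mat
}

#' Positional amino-acid preference between two groups
#'
#' Entry-wise \eqn{\log_2((a + \epsilon)/(b + \epsilon))} of two positional
#' composition matrices; antisymmetric under swapping.
#'
#' @param mat_a,mat_b Matrices from [positional_aa_matrix()] with identical
#'   dimensions.
#' @param pseudo Pseudocount (default 1e-6).
#' @return Tibble with columns `position`, `aa`, `log2_ratio`.
#' @export
positional_aa_preference <- function(mat_a, mat_b, pseudo = 1e-6) {
  stopifnot(identical(dim(mat_a), dim(mat_b)))
  lr <- log2(mat_a + pseudo) - log2(mat_b + pseudo)
  tibble::tibble(
    position = rep(as.integer(colnames(lr)), each = nrow(lr)),
    aa = rep(rownames(lr), times = ncol(lr)),
    log2_ratio = as.vector(lr)
  )
}

#' Mean CDR3 length per sample and per-chain group comparison
#'
#' The per-sample statistic is the unweighted mean CDR3 length over distinct
#' clonotypes. Within each chain, groups are compared with a Welch two-sided
#' t-test; chains where either group has fewer than 2 samples are skipped
#' with a warning.
#'
#' @param cohort A labelled `tcr_cohort`.
#' @return List with `sample_means` (tibble: sample_id, chain, label,
#'   mean_length) and `tests` (tibble: chain, group_a, group_b, mean_a,
#'   mean_b, t, p_value).
#' @export
cdr3_length_stats <- function(cohort) {
  means <- purrr::map_dfr(cohort$repertoires, function(r) {
    tibble::tibble(sample_id = attr(r, "sample_id"),
                   chain = attr(r, "chain"),
                   label = attr(r, "label"),
                   mean_length = mean(nchar(r$cdr3_aa)))
  })
  groups <- cohort_groups(cohort)
  if (is.null(groups)) groups <- utils::head(unique(means$label), 2)
  tests <- purrr::map_dfr(unique(means$chain), function(ch) {
    a <- means$mean_length[means$chain == ch & means$label == groups[[1]]]
    b <- means$mean_length[means$chain == ch & means$label == groups[[2]]]
    if (length(a) < 2 || length(b) < 2) {
      warning("chain ", ch, ": fewer than 2 samples in a group; test skipped",
              call. = FALSE)
      return(tibble::tibble(chain = ch, group_a = groups[[1]],
                            group_b = groups[[2]], mean_a = mean(a),
                            mean_b = mean(b), t = NA_real_, p_value = NA_real_))
    }
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # zero within-group variance: Welch t degenerates to 0 or +/-Inf
      d <- mean(a) - mean(b)
      return(tibble::tibble(chain = ch, group_a = groups[[1]],
                            group_b = groups[[2]], mean_a = mean(a),
                            mean_b = mean(b),
                            t = if (d == 0) 0 else sign(d) * Inf,
                            p_value = if (d == 0) 1 else 0))
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    tibble::tibble(chain = ch, group_a = groups[[1]], group_b = groups[[2]],
                   mean_a = mean(a), mean_b = mean(b),
                   t = unname(tt$statistic), p_value = tt$p.value)
  })
  list(sample_means = means, tests = tests)
}

count_kmers_str <- function(seqs, k, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(seqs))
  n_k <- pmax(0L, nchar(seqs) - k + 1L)
  if (sum(n_k) == 0) return(stats::setNames(numeric(0), character(0)))
  idx <- rep.int(seq_along(seqs), n_k)
  starts <- sequence(n_k)
  kmers <- substring(seqs[idx], starts, starts + k - 1L)
  v <- rowsum(weights[idx], kmers)
  stats::setNames(as.vector(v), rownames(v))
}

#' K-mer motif counts of one repertoire
#'
#' Counts all overlapping k-mers over the repertoire's CDR3 sequences. Each
#' distinct clonotype contributes once by default; with `weighted = TRUE` it
#' contributes its clone count times. Sequences shorter than `k` contribute
#' nothing, so the unweighted total equals
#' \eqn{\sum_c \max(0, \mathrm{len}(c) - k + 1)}.
#'
#' @param rep A `tcr_repertoire`.
#' @param k Motif length (default 5).
#' @param weighted Weight motifs by clone count (default `FALSE`).
#' @return Tibble with columns `motif`, `count`, sorted by motif.
#' @export
kmer_counts <- function(rep, k = 5, weighted = FALSE) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  w <- if (weighted) rep$count else NULL
  v <- count_kmers_str(rep$cdr3_aa, k, w)
  tibble::tibble(motif = names(v), count = unname(v)) |>
    dplyr::arrange(.data$motif)
}

#' Samples x motifs count matrix for a cohort
#'
#' @param cohort A `tcr_cohort`.
#' @inheritParams kmer_counts
#' @return Numeric matrix, samples (rows) x k-mers (columns, sorted), raw
#'   counts.
#' @export
motif_matrix <- function(cohort, k = 5, weighted = FALSE) {
  rows <- purrr::map(cohort$repertoires, function(r) {
    count_kmers_str(r$cdr3_aa, k, if (weighted) r$count else NULL)
  })
  motifs <- sort(unique(unlist(purrr::map(rows, names))))
  mat <- matrix(0, nrow = length(rows), ncol = length(motifs),
                dimnames = list(names(rows), motifs))
  for (i in seq_along(rows)) mat[i, names(rows[[i]])] <- rows[[i]]
  mat
}

#' Per-group motif fractions, ranked
#'
#' The fraction of each motif within a group is its summed count divided by
#' the group's total motif count. Rows are sorted by descending fraction,
#' ties broken lexicographically by motif.
#'
#' @param matrix Samples x motifs count matrix from [motif_matrix()].
#' @param labels Named group vector (names = sample ids) or vector aligned
#'   with the matrix rows.
#' @param group Group to summarise.
#' @return Tibble with columns `motif`, `count`, `fraction`, ranked.
#' @export
motif_fractions <- function(matrix, labels, group) {
  if (!is.null(names(labels))) labels <- labels[rownames(matrix)]
  sel <- which(labels == group)
  if (length(sel) == 0) stop("group '", group, "' not found", call. = FALSE)
  tot <- colSums(matrix[sel, , drop = FALSE])
  tot <- tot[tot > 0]
  tibble::tibble(motif = names(tot), count = unname(tot),
                 fraction = unname(tot) / sum(tot)) |>
    dplyr::arrange(dplyr::desc(.data$fraction), .data$motif)
}

#' Overlap between two ranked motif lists at increasing depth
#'
#' For each n, the share of motifs common to the top-n of both rankings,
#' `|top_n(A) ∩ top_n(B)| / n`.
#'
#' @param frac_a,frac_b Ranked tibbles from [motif_fractions()].
#' @param ns Integer vector of depths.
#' @return Tibble with columns `n`, `overlap_ratio`.
#' @export
motif_overlap_curve <- function(frac_a, frac_b, ns) {
  avail <- min(nrow(frac_a), nrow(frac_b))
  purrr::map_dfr(ns, function(n) {
    m <- min(n, avail)
    if (m < n) warning("n = ", n, " exceeds available motifs; using ", m,
                       call. = FALSE)
    top_a <- frac_a$motif[seq_len(m)]
    top_b <- frac_b$motif[seq_len(m)]
    tibble::tibble(n = n, overlap_ratio = length(intersect(top_a, top_b)) / m)
  })
}

#' Normalise a motif count matrix
#'
#' Total-count scaling of each sample to `scale_factor`, then `log1p` — the
#' normalisation under which differential motifs are tested.
#'
#' @param matrix Raw samples x motifs count matrix.
#' @param scale_factor Target library size (default 10,000).
#' @return Matrix of the same shape.
#' @export
normalize_motif_matrix <- function(matrix, scale_factor = 1e4) {
  rs <- rowSums(matrix)
  rs[rs == 0] <- 1
  log1p(matrix / rs * scale_factor)
}

# Two-sided Wilcoxon rank-sum p-value. Exact full-enumeration permutation
# distribution when both groups have <= `exact_max` observations (valid under
# ties, using midranks); otherwise normal approximation with tie correction
# and continuity correction.
.combn_cache <- new.env(parent = emptyenv())

cached_combn <- function(n, k) {
  key <- paste(n, k)
  if (is.null(.combn_cache[[key]])) .combn_cache[[key]] <- utils::combn(n, k)
  .combn_cache[[key]]
}

wilcox_rank_sum_p <- function(x, y, exact_max = 8) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  if (nx <= exact_max && ny <= exact_max) {
    combos <- cached_combn(n, nx)
    sums <- colSums(matrix(r[combos], nrow = nx))
    lo <- mean(sums <= w + 1e-9)
    hi <- mean(sums >= w - 1e-9)
    return(min(1, 2 * min(lo, hi)))
  }
  mu <- nx * (n + 1) / 2
  ties <- table(r)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)
  z <- w - mu
  z <- (z - sign(z) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' One-vs-rest differential motifs
#'
#' For each group, compares every motif's normalised abundance (total-count
#' scaling to 10,000, then log1p) in that group against all other samples
#' with a two-sided Wilcoxon rank-sum test. Retains motifs with
#' `p < p_thresh`, detected (count > 0) in at least `min_pct` of the
#' in-group samples, and average log2 fold-change at least `logfc_thresh`.
#' The p-value is exact (full permutation enumeration) when both groups have
#' at most 8 samples.
#'
#' @param matrix Raw samples x motifs count matrix from [motif_matrix()].
#' @param labels Group labels, named by sample id or aligned with rows.
#' @param p_thresh Raw p-value cut-off (default 0.01).
#' @param min_pct Minimum in-group detection fraction (default 0.1).
#' @param logfc_thresh Minimum average log2 fold-change (default 0.25).
#' @param scale_factor Library-size target for normalisation.
#' @return Tibble with columns `motif`, `group`, `p_value`, `avg_log2fc`,
#'   `pct_in`, `pct_out`, sorted by group then p-value.
#' @export
differential_motifs <- function(matrix, labels, p_thresh = 0.01,
                                min_pct = 0.1, logfc_thresh = 0.25,
                                scale_factor = 1e4) {
  if (!is.null(names(labels))) labels <- labels[rownames(matrix)]
  labels <- as.character(labels)
  tab <- table(labels)
  if (any(tab < 2)) {
    stop("every group needs >= 2 samples for the rank-sum test; got: ",
         paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
         call. = FALSE)
  }
  norm <- normalize_motif_matrix(matrix, scale_factor)
  detected <- matrix > 0
  out <- purrr::map_dfr(names(tab), function(g) {
    sel <- labels == g
    pct_in <- colMeans(detected[sel, , drop = FALSE])
    pct_out <- colMeans(detected[!sel, , drop = FALSE])
    cand <- which(pct_in >= min_pct)
    if (length(cand) == 0) return(tibble::tibble())
    # average log2 fold-change on the de-logged normalised scale
    m_in <- colMeans(expm1(norm[sel, cand, drop = FALSE]))
    m_out <- colMeans(expm1(norm[!sel, cand, drop = FALSE]))
    lfc <- log2(m_in + 1) - log2(m_out + 1)
    cand2 <- cand[lfc >= logfc_thresh]
    lfc <- lfc[lfc >= logfc_thresh]
    if (length(cand2) == 0) return(tibble::tibble())
    p <- vapply(cand2, function(j) {
      wilcox_rank_sum_p(norm[sel, j], norm[!sel, j])
    }, numeric(1))
    tibble::tibble(motif = colnames(matrix)[cand2], group = g,
                   p_value = p, avg_log2fc = lfc,
                   pct_in = pct_in[cand2], pct_out = pct_out[cand2]) |>
      dplyr::filter(.data$p_value < p_thresh)
  })
  if (nrow(out) == 0) {
    return(tibble::tibble(motif = character(0), group = character(0),
                          p_value = numeric(0), avg_log2fc = numeric(0),
                          pct_in = numeric(0), pct_out = numeric(0)))
  }
  dplyr::arrange(out, .data$group, .data$p_value, .data$motif)
}

#' Pairwise repertoire overlap matrix
#'
#' Overlap between the CDR3 amino-acid sets of every pair of samples.
#' `"jaccard"` (default) is |A∩B| / |A∪B|; `"overlap"` is
#' |A∩B| / min(|A|, |B|).
#'
#' @param cohort A `tcr_cohort` with at least 2 repertoires.
#' @param method `"jaccard"` or `"overlap"`.
#' @return Symmetric samples x samples matrix with unit diagonal.
#' @export
repertoire_overlap_matrix <- function(cohort, method = c("jaccard", "overlap")) {
  method <- match.arg(method)
  sets <- purrr::map(cohort$repertoires, function(r) unique(r$cdr3_aa))
  n <- length(sets)
  if (n < 2) stop("need >= 2 repertoires", call. = FALSE)
  ids <- names(sets)
  mat <- diag(1, n)
  dimnames(mat) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      inter <- length(intersect(sets[[i]], sets[[j]]))
      denom <- switch(method,
                      jaccard = length(union(sets[[i]], sets[[j]])),
                      overlap = min(length(sets[[i]]), length(sets[[j]])))
      mat[i, j] <- mat[j, i] <- if (denom == 0) 0 else inter / denom
    }
  }
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("empty repertoire(s): ", paste(ids[empty], collapse = ", "),
            call. = FALSE)
    mat[empty, ] <- 0; mat[, empty] <- 0
  }
  mat
}
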