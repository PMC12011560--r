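# Fixture builders and independent oracles shared across the suite.

# build a validated repertoire from raw vectors
make_rep <- function(counts, seqs, v = NULL, j = NULL, sample_id = "s1",
                     label = NULL) {
  n <- length(counts)
  if (is.null(v)) v <- rep("TRBV1", n)
  if (is.null(j)) j <- rep("TRBJ1-1", n)
  as_repertoire(
    data.frame(count = counts, cdr3_aa = seqs, v_gene = v, j_gene = j),
    sample_id = sample_id, label = label
  )
}

random_aa_seq <- function(len) {
  paste(sample(AA_ALPHABET, len, replace = TRUE), collapse = "")
}

# random repertoire with unique CDR3s
random_rep <- function(n_clones = 20, sample_id = "r1", label = NULL) {
  seqs <- character(0)
  while (length(seqs) < n_clones) {
    seqs <- unique(c(seqs, replicate(n_clones, random_aa_seq(sample(6:16, 1)))))
  }
  make_rep(sample(1:100, n_clones, replace = TRUE), seqs[seq_len(n_clones)],
           sample_id = sample_id, label = label)
}

# small labelled cohort with a planted motif, for classifier tests
quick_cohort <- function(n_per_group = 12, clones = 60, enrichment = 4,
                         seed = 11) {
  generate_cohort(cohort_spec(
    n_per_group = n_per_group, clones_per_sample = clones,
    planted_motifs = data.frame(motif = "GEKLF", enrichment = enrichment,
                                group = "case"),
    seed = seed
  ))
}

# --- independent oracles -------------------------------------------------

oracle_shannon <- function(p) {
  s <- 0
  for (x in p) if (x > 0) s <- s - x * log(x)
  s
}

oracle_simpson <- function(p) {
  s <- 0
  for (x in p) s <- s + x * x
  1 - s
}

oracle_clones_to_half <- function(p) {
  p <- sort(p, decreasing = TRUE)
  acc <- 0
  for (i in seq_along(p)) {
    acc <- acc + p[i]
    if (acc > 0.5) return(i)
  }
  length(p)
}

# all-pairs concordance AUC
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]; neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# exact two-sided rank-sum p by explicit enumeration of label assignments
oracle_wilcox_exact <- function(x, y) {
  n <- length(x) + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_along(x)])
  sums <- apply(utils::combn(n, length(x)), 2, function(idx) sum(r[idx]))
  lo <- mean(sums <= w_obs + 1e-9)
  hi <- mean(sums >= w_obs - 1e-9)
  min(1, 2 * min(lo, hi))
}

# motif total expected from the length contract
oracle_motif_total <- function(rep, k = 5) {
  sum(pmax(0, nchar(rep$cdr3_aa) - (k - 1)))
}
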