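vj_cohort <- function() {
  # group A: 60 clones V1|J1, 40 clones V2|J1 (each clone distinct)
  seqs <- function(n, tag) paste0("C", tag, vapply(seq_len(n), function(i) {
    paste(AA_ALPHABET[1 + (c(i, i %/% 20, i %/% 4, i %% 20) %% 20)], collapse = "")
  }, ""), "F")
  a <- make_rep(rep(1, 100), seqs(100, "A"),
                v = rep(c("TRBV1", "TRBV2"), c(60, 40)),
                j = rep("TRBJ1-1", 100), sample_id = "a", label = "A")
  b <- make_rep(rep(1, 100), seqs(100, "W"),
                v = rep(c("TRBV1", "TRBV2"), c(50, 50)),
                j = rep("TRBJ1-1", 100), sample_id = "b", label = "B")
  as_cohort(list(a, b))
}

test_that("vj_frequencies normalises per group and applies the support filter", {
  tab <- vj_frequencies(vj_cohort(), min_clones = 1)
  a <- tab[tab$group == "A", ]
  expect_equal(a$frequency[a$vj == "TRBV1|TRBJ1-1"], 0.6)
  expect_equal(a$frequency[a$vj == "TRBV2|TRBJ1-1"], 0.4)
  expect_equal(sum(a$frequency), 1, tolerance = 1e-9)

  # pair support: V1 has 110 clones, V2 has 90 across cohort
  tab2 <- vj_frequencies(vj_cohort(), min_clones = 100)
  expect_setequal(unique(tab2$vj), "TRBV1|TRBJ1-1")
  expect_equal(tab2$frequency, c(1, 1))
  expect_error(vj_frequencies(vj_cohort(), min_clones = 1000), "min_clones")
})

test_that("vj_preference computes log2 ratios and is exactly antisymmetric", {
  tab <- vj_frequencies(vj_cohort(), min_clones = 1)
  pref <- vj_preference(tab, "A", "B", pseudo = 0)
  v1 <- pref$log2_ratio[pref$vj == "TRBV1|TRBJ1-1"]
  expect_equal(v1, log2(0.6 / 0.5), tolerance = 1e-12)
  swapped <- vj_preference(tab, "B", "A", pseudo = 0)
  expect_identical(pref$log2_ratio, -swapped$log2_ratio)
  expect_error(vj_preference(tab, "A", "Z"), "unknown group")
  # identical frequencies give zero
  prefAA <- vj_preference(tab, "A", "A", pseudo = 1e-6)
  expect_true(all(prefAA$log2_ratio == 0))
})

test_that("positional composition is clone-weighted and length-filtered", {
  coh <- as_cohort(list(
    make_rep(c(1, 1), c("CAAAA", "CSSSS"), sample_id = "s", label = "A"),
    make_rep(1, "CWWWWW", sample_id = "t", label = "B")
  ))
  m <- positional_aa_matrix(coh, group = "A")
  expect_equal(unname(m["C", 1]), 1)
  expect_equal(unname(m["A", 2]), 0.5)
  expect_equal(unname(m["S", 2]), 0.5)
  expect_true(all(abs(colSums(m)[1:5] - 1) < 1e-12))

  # length-4 clone is excluded entirely
  coh2 <- as_cohort(list(make_rep(c(3, 1), c("CAAF", "CASSLGETF"),
                                  sample_id = "u", label = "A")))
  m2 <- positional_aa_matrix(coh2, group = "A")
  expect_equal(unname(m2["C", 1]), 1)  # only the long clone contributes
  expect_equal(unname(colSums(m2)[4]), 1)
})

test_that("positional preference is antisymmetric and zero for equal matrices", {
  coh <- quick_cohort(n_per_group = 3, clones = 30)
  ma <- positional_aa_matrix(coh, "case")
  mb <- positional_aa_matrix(coh, "control")
  p1 <- positional_aa_preference(ma, mb)
  p2 <- positional_aa_preference(mb, ma)
  expect_identical(p1$log2_ratio, -p2$log2_ratio)
  expect_true(all(positional_aa_preference(ma, ma)$log2_ratio == 0))
  # explicit cell: 0.4 vs 0.1 with no pseudocount gives 2
  a <- matrix(0.4, 1, 1, dimnames = list("A", "1"))
  b <- matrix(0.1, 1, 1, dimnames = list("A", "1"))
  expect_equal(positional_aa_preference(a, b, pseudo = 0)$log2_ratio, 2)
})

test_that("cdr3_length_stats computes per-sample means and Welch tests", {
  mk <- function(id, lab, lens) {
    seqs <- vapply(seq_along(lens), function(i) {
      paste0("C", strrep(AA_ALPHABET[i], lens[i] - 2), "F")
    }, "")
    make_rep(rep(1, length(lens)), seqs, sample_id = id, label = lab)
  }
  coh <- as_cohort(list(
    mk("a1", "A", c(10, 14)), mk("a2", "A", c(10, 14)), mk("a3", "A", c(10, 14)),
    mk("b1", "B", c(14, 14)), mk("b2", "B", c(14, 14)), mk("b3", "B", c(14, 14))
  ), groups = c("A", "B"))
  st <- cdr3_length_stats(coh)
  expect_equal(st$sample_means$mean_length[1], 12)
  # constant groups {12,12,12} vs {14,14,14}: Welch t degenerates
  expect_equal(st$tests$t, -Inf)
  expect_lt(st$tests$p_value, 0.01)
  # groups with spread match the closed-form Welch t on the sample means
  coh2 <- as_cohort(list(
    mk("a1", "A", c(9, 10)), mk("a2", "A", c(10, 10)), mk("a3", "A", c(10, 11)),
    mk("b1", "B", c(13, 14)), mk("b2", "B", c(14, 14)), mk("b3", "B", c(14, 15))
  ), groups = c("A", "B"))
  st2 <- cdr3_length_stats(coh2)
  tt <- stats::t.test(c(9.5, 10, 10.5), c(13.5, 14, 14.5), var.equal = FALSE)
  expect_equal(st2$tests$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(st2$tests$p_value, tt$p.value, tolerance = 1e-12)
  # identical groups give t = 0, p = 1
  coh3 <- as_cohort(list(
    mk("a1", "A", 10), mk("a2", "A", 10),
    mk("b1", "B", 10), mk("b2", "B", 10)
  ), groups = c("A", "B"))
  st3 <- cdr3_length_stats(coh3)
  expect_equal(st3$tests$t, 0)
  expect_equal(st3$tests$p_value, 1)
})

test_that("kmer counting follows the overlapping-window contract", {
  r <- make_rep(1, "CASSLGETQYF")
  kc <- kmer_counts(r)
  expect_equal(sum(kc$count), 7)  # 11 - 5 + 1
  r2 <- make_rep(1, "AAAAAA")
  expect_equal(kmer_counts(r2)$count, 2)
  expect_equal(kmer_counts(r2)$motif, "AAAAA")
  r3 <- make_rep(c(1, 1), c("CASF", "CASSLGETQYF"))
  expect_equal(sum(kmer_counts(r3)$count), 7)  # length-4 contributes nothing
  expect_error(kmer_counts(r, k = 0), "k must be")
  # weighted counting multiplies by clone count
  r4 <- make_rep(c(3, 2), c("AAAAA", "CCCCC"))
  kw <- kmer_counts(r4, weighted = TRUE)
  expect_equal(kw$count[kw$motif == "AAAAA"], 3)
})

test_that("motif matrix row sums equal the length contract on random fixtures", {
  withr::with_seed(21, {
    reps <- lapply(1:6, function(i) random_rep(15, sample_id = paste0("s", i)))
  })
  coh <- as_cohort(reps)
  mm <- motif_matrix(coh)
  expect_equal(unname(rowSums(mm)),
               vapply(reps, oracle_motif_total, numeric(1)))
})

test_that("motif fractions rank descending with lexicographic ties", {
  mm <- matrix(c(3, 1, 1), 1, 3, dimnames = list("s1", c("ZZZZZ", "AAAAA", "MMMMM")))
  fr <- motif_fractions(mm, c(s1 = "G"), "G")
  expect_equal(fr$fraction, c(0.6, 0.2, 0.2))
  expect_equal(fr$motif, c("ZZZZZ", "AAAAA", "MMMMM"))
  expect_equal(sum(fr$fraction), 1)
  one <- motif_fractions(matrix(5, 1, 1, dimnames = list("s1", "QQQQQ")),
                         c(s1 = "G"), "G")
  expect_equal(one$fraction, 1)
})

test_that("motif overlap curve matches set arithmetic and its bounds", {
  fa <- tibble::tibble(motif = c("X", "Y", "Z"), fraction = c(.5, .3, .2))
  fb <- tibble::tibble(motif = c("X", "Q", "R"), fraction = c(.5, .3, .2))
  expect_equal(motif_overlap_curve(fa, fb, 3)$overlap_ratio, 1 / 3)
  expect_equal(motif_overlap_curve(fa, fa, 3)$overlap_ratio, 1)
  fc <- tibble::tibble(motif = c("P", "S", "T"), fraction = c(.5, .3, .2))
  expect_equal(motif_overlap_curve(fa, fc, 2)$overlap_ratio, 0)
  expect_warning(out <- motif_overlap_curve(fa, fb, 10), "exceeds")
  expect_equal(out$overlap_ratio, 1 / 3)
})

test_that("rank-sum p-values match exact enumeration, including spec cases", {
  # normalized values A = 10,11,12 vs B = 1,2,3: p = 2/20 = 0.1
  expect_equal(tcrstack:::wilcox_rank_sum_p(c(10, 11, 12), c(1, 2, 3)), 0.1)
  # fully separated 8 vs 8: p = 2 / choose(16, 8)
  expect_equal(tcrstack:::wilcox_rank_sum_p(9:16, 1:8), 2 / choose(16, 8))
  withr::with_seed(31, {
    for (i in 1:25) {
      nx <- sample(2:8, 1); ny <- sample(2:8, 1)
      x <- sample(0:5, nx, replace = TRUE)  # ties likely
      y <- sample(0:5, ny, replace = TRUE)
      expect_equal(tcrstack:::wilcox_rank_sum_p(x, y),
                   oracle_wilcox_exact(x, y), tolerance = 1e-12)
    }
    # tie-free values also agree with stats::wilcox.test exact p
    for (i in 1:10) {
      x <- rnorm(6); y <- rnorm(5)
      expect_equal(tcrstack:::wilcox_rank_sum_p(x, y),
                   stats::wilcox.test(x, y, exact = TRUE)$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("differential_motifs filters on p, detection and fold change", {
  coh <- quick_cohort(n_per_group = 8, clones = 60, enrichment = 6, seed = 13)
  mm <- motif_matrix(coh)
  labels <- stats::setNames(coh$samples$label, coh$samples$sample_id)
  dm <- differential_motifs(mm, labels)
  expect_true(all(dm$p_value < 0.01))
  expect_true(all(dm$avg_log2fc >= 0.25))
  expect_true(all(dm$pct_in >= 0.1))
  expect_true("GEKLF" %in% dm$motif[dm$group == "case"])

  # a motif identical across groups is never reported
  const <- matrix(5, 6, 1, dimnames = list(paste0("s", 1:6), "AAAAA"))
  expect_equal(nrow(differential_motifs(const, rep(c("a", "b"), each = 3))), 0)
  expect_error(differential_motifs(mm, rep(c("a", "b"), c(1, 15))), ">= 2")
})

test_that("repertoire overlap matrix is symmetric with unit diagonal", {
  r1 <- make_rep(c(1, 1, 1), c("CAAAF", "CWWWF", "CCCCF"), sample_id = "x")
  r2 <- make_rep(c(1, 1, 1), c("CWWWF", "CCCCF", "CDDDF"), sample_id = "y")
  m <- repertoire_overlap_matrix(as_cohort(list(r1, r2)))
  expect_equal(unname(m["x", "y"]), 0.5)  # 2 shared / 4 union
  expect_equal(unname(diag(m)), c(1, 1))
  expect_identical(m, t(m))
  # identical repertoires overlap fully; disjoint ones not at all
  r3 <- make_rep(c(1, 1, 1), c("CAAAF", "CWWWF", "CCCCF"), sample_id = "z")
  m2 <- repertoire_overlap_matrix(as_cohort(list(r1, r3)))
  expect_equal(unname(m2["x", "z"]), 1)
  r4 <- make_rep(c(1, 1), c("CEEEF", "CFFFF"), sample_id = "w")
  m3 <- repertoire_overlap_matrix(as_cohort(list(r1, r4)))
  expect_equal(unname(m3["x", "w"]), 0)
})
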