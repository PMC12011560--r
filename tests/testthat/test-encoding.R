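test_that("descriptor encoder returns the documented 41-dim layout", {
  v <- encode_sequence("AAAAA")
  expect_length(v, 41)
  expect_equal(unname(v["comp_A"]), 1)
  expect_equal(unname(sum(v[paste0("comp_", AA_ALPHABET)])), 1)
  expect_equal(unname(v["length"]), 5)
  af <- atchley_factors()
  expect_equal(unname(v["af_all_1"]), af["A", 1])
  expect_error(encode_sequence("CASX1"), "invalid residue")
})

test_that("encoder is deterministic and segment blocks are position-sensitive", {
  s <- "CASSLGETQYF"
  expect_identical(encode_sequence(s), encode_sequence(s))
  # direct descriptor oracle for the composition and whole-sequence blocks
  aas <- strsplit(s, "")[[1]]
  af <- atchley_factors()
  comp <- as.numeric(table(factor(aas, levels = AA_ALPHABET))) / length(aas)
  v <- encode_sequence(s)
  expect_equal(unname(v[paste0("comp_", AA_ALPHABET)]), comp)
  expect_equal(unname(v[paste0("af_all_", 1:5)]),
               unname(colMeans(af[aas, ])), tolerance = 1e-12)
  expect_equal(unname(v[paste0("af_nterm_", 1:5)]),
               unname(colMeans(af[aas[1:3], ])), tolerance = 1e-12)
  expect_equal(unname(v[paste0("af_cterm_", 1:5)]),
               unname(colMeans(af[aas[9:11], ])), tolerance = 1e-12)
  expect_equal(unname(v[paste0("af_central_", 1:5)]),
               unname(colMeans(af[aas[4:8], ])), tolerance = 1e-12)
  # "CA" vs "AC": same composition, different terminal segments
  a <- encode_sequence("CA"); b <- encode_sequence("AC")
  expect_equal(a[paste0("comp_", AA_ALPHABET)], b[paste0("comp_", AA_ALPHABET)])
  expect_false(isTRUE(all.equal(a[paste0("af_nterm_", 1:5)],
                                b[paste0("af_nterm_", 1:5)])))
  expect_equal(unname(a["af_nterm_1"]), af["C", 1])
  expect_equal(unname(b["af_nterm_1"]), af["A", 1])
})

test_that("custom encoder adapters are validated", {
  sp <- encoder_spec("toy", dim = 2, fn = function(s) c(nchar(s), 1))
  expect_equal(encode_sequence("CASSF", sp), c(5, 1))
  bad <- encoder_spec("bad", dim = 3, fn = function(s) 1)
  expect_error(encode_sequence("CASSF", bad), "length")
  expect_error(encoder_spec("nofn", dim = 2), "requires fn")
})

test_that("top_n_cdr3 keeps the most abundant sequences with lexicographic ties", {
  rep <- make_rep(c(5, 2, 2, 1),
                  c("CDDDF", "CWWWF", "CAAAF", "CEEEF"))
  expect_equal(top_n_cdr3(rep, 2), c("CDDDF", "CAAAF"))
  expect_equal(length(top_n_cdr3(rep, 100)), 4)
  withr::with_seed(4, {
    big <- random_rep(150)
  })
  expect_length(top_n_cdr3(big, 100), 100)
})

test_that("sample_embedding aggregates encodings as documented", {
  r1 <- make_rep(1, "CASSF", sample_id = "one")
  e1 <- sample_embedding(r1)
  expect_equal(as.numeric(e1), unname(encode_sequence("CASSF")))
  expect_equal(attr(e1, "n_sequences_used"), 1)

  r2 <- make_rep(c(1, 1), c("CASSF", "CAIRF"), sample_id = "two")
  e2 <- sample_embedding(r2)
  expect_equal(as.numeric(e2),
               unname((encode_sequence("CASSF") + encode_sequence("CAIRF")) / 2),
               tolerance = 1e-12)

  r3 <- make_rep(c(9, 1), c("CASSF", "CAIRF"), sample_id = "three")
  e3 <- sample_embedding(r3, weighting = "fraction")
  expect_equal(as.numeric(e3),
               unname(0.9 * encode_sequence("CASSF") +
                        0.1 * encode_sequence("CAIRF")),
               tolerance = 1e-12)

  # invariant to clonotype input order (repertoires sort on construction)
  r4 <- make_rep(c(1, 9), c("CAIRF", "CASSF"), sample_id = "four")
  expect_equal(as.numeric(sample_embedding(r4, weighting = "fraction")),
               as.numeric(e3), tolerance = 1e-12)
})

test_that("PCA satisfies its structural contracts", {
  withr::with_seed(42, {
    x <- matrix(rnorm(10 * 200), 10, 200,
                dimnames = list(NULL, paste0("f", 1:200)))
  })
  m <- fit_pca(x, 50)
  expect_equal(m$n_components, 9)  # min(50, n-1, p)
  expect_equal(crossprod(m$rotation), diag(9), tolerance = 1e-8,
               ignore_attr = TRUE)
  sc <- apply_pca(m, x)
  expect_equal(unname(colMeans(sc)), rep(0, 9), tolerance = 1e-8)

  # data exactly on a line: first component carries all variance
  t <- seq(-1, 1, length.out = 8)
  line <- outer(t, c(1, 2, 3, 4, 5))
  colnames(line) <- paste0("f", 1:5)
  ml <- fit_pca(line)
  expect_equal(ml$explained_variance_ratio[1], 1, tolerance = 1e-10)

  # a new sample equal to the training mean maps to the origin
  mu <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
  expect_equal(unname(as.numeric(apply_pca(m, mu))), rep(0, 9),
               tolerance = 1e-10)

  # name-based column alignment: permuted columns give identical scores
  perm <- x[, sample(ncol(x))]
  expect_equal(apply_pca(m, perm), sc, tolerance = 1e-12)
  expect_error(apply_pca(m, x[, 1:100]), "fit-time feature")
  expect_error(fit_pca(x[1, , drop = FALSE]), ">= 2 samples")
})

test_that("PCA reconstruction error is non-increasing in rank", {
  withr::with_seed(17, {
    x <- matrix(rnorm(20 * 30), 20, 30, dimnames = list(NULL, paste0("f", 1:30)))
  })
  m <- fit_pca(x, 19)
  xs <- sweep(sweep(x, 2, m$mean, "-"), 2, m$scale, "/")
  errs <- vapply(1:19, function(k) {
    rot <- m$rotation[, 1:k, drop = FALSE]
    sum((xs - xs %*% rot %*% t(rot))^2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-8))
})
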