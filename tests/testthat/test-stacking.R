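# Separable two-block feature fixture: class means differ strongly in both
# blocks, so every reasonable base model should rank near-perfectly.
separable_blocks <- function(n_per_class = 16, p = 8, delta = 5, seed = 99) {
  withr::with_seed(seed, {
    y <- rep(c(1L, 0L), each = n_per_class)
    mk <- function() {
      x <- matrix(rnorm(2 * n_per_class * p), ncol = p)
      x[y == 1, 1:3] <- x[y == 1, 1:3] + delta
      colnames(x) <- paste0("f", seq_len(p))
      x
    }
    list(motif = mk(), cdr3 = mk(), y = y)
  })
}

test_that("grid profiles have the published cardinalities", {
  g <- model_grids("full")
  expect_equal(nrow(g$GLM), 6)
  expect_equal(nrow(g$XGB), 48)
  expect_equal(nrow(g$RF), 6)
  expect_equal(nrow(g$NN), 9)
  expect_equal(sort(g$GLM$alpha), c(0, 0.2, 0.4, 0.6, 0.8, 1))
  expect_setequal(unique(g$XGB$nrounds), c(100, 200))
  expect_setequal(unique(g$XGB$max_depth), c(3, 6))
  expect_setequal(unique(g$XGB$eta), c(0.01, 0.1))
  expect_setequal(unique(g$XGB$gamma), c(0, 0.1))
  expect_setequal(unique(g$XGB$subsample), c(0.7, 0.8, 0.9))
  expect_setequal(unique(g$RF$mtry), c(2, 4, 6))
  expect_setequal(unique(g$RF$ntree), c(500, 1000))
  expect_setequal(unique(g$NN$size), c(3, 4, 5))
  expect_setequal(unique(g$NN$decay), c(0.001, 0.01, 0.1))
  # reduced profiles keep >= 5 points per family so selection is unchanged
  for (prof in c("fast", "minimal")) {
    gg <- model_grids(prof)
    for (fam in c("GLM", "XGB", "RF", "NN")) expect_gte(nrow(gg[[fam]]), 5)
  }
})

test_that("stratified folds cover all samples and balance classes", {
  y <- rep(c(0, 1), c(20, 15))
  f <- make_stratified_folds(y, 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5) expect_setequal(unique(y[f == k]), c(0, 1))
  expect_identical(f, make_stratified_folds(y, 5, seed = 3))
  expect_error(make_stratified_folds(rep(c(0, 1), c(3, 20)), 5), "stratified")
})

test_that("layer 1 selects 5 models per family per block and is deterministic", {
  blk <- separable_blocks()
  g <- model_grids("minimal")
  bank <- train_layer1(blk$motif, blk$cdr3, blk$y, seed = 5, grids = g)
  expect_equal(nrow(bank$selected), 40)
  counts <- table(bank$selected$block, bank$selected$family)
  expect_true(all(counts == 5))
  expect_equal(dim(bank$oof_predictions), c(32, 40))
  # grid log covers every point of every family for both blocks
  expect_equal(nrow(bank$grid_log),
               2 * sum(vapply(g[c("GLM", "XGB", "RF", "NN")], nrow, 1L)))
  # separable fixture: every selected model ranks well
  expect_true(all(bank$selected$cv_auc >= 0.9))

  bank2 <- train_layer1(blk$motif, blk$cdr3, blk$y, seed = 5, grids = g)
  expect_identical(bank$selected$tag, bank2$selected$tag)
  expect_equal(bank$oof_predictions, bank2$oof_predictions, tolerance = 1e-8)
})

test_that("layer 2 retains exactly 10 stackers and handles degenerate input", {
  blk <- separable_blocks()
  g <- model_grids("minimal")
  bank <- train_layer1(blk$motif, blk$cdr3, blk$y, seed = 5, grids = g)
  st <- train_layer2(bank, seed = 5, grids = g)
  expect_equal(nrow(st), 10)
  expect_true(all(st$cv_auc >= 0.5))

  # constant out-of-fold columns must not produce NaN scores
  bank$oof_predictions[] <- 0.5
  st2 <- train_layer2(bank, seed = 5, grids = g)
  preds <- vapply(st2$model, function(m) {
    tcrstack:::predict_base_model(m, bank$oof_predictions)
  }, numeric(length(blk$y)))
  expect_true(all(is.finite(preds)))
})

test_that("label mixing destroys stacker cross-validated AUC", {
  blk <- separable_blocks(n_per_class = 20)
  withr::with_seed(6, {
    y_perm <- sample(blk$y)
  })
  g <- model_grids("minimal")
  bank <- train_layer1(blk$motif, blk$cdr3, y_perm, seed = 6, grids = g)
  st <- train_layer2(bank, seed = 6, grids = g)
  expect_gt(mean(st$cv_auc), 0.25)
  expect_lt(mean(st$cv_auc), 0.75)
})

test_that("fit_pipeline classifies a separable synthetic cohort end to end", {
  coh <- quick_cohort(n_per_group = 10, clones = 60, enrichment = 6, seed = 23)
  fit <- fit_pipeline(coh, seed = 2, grids = model_grids("minimal"))
  expect_s3_class(fit, "tcr_stack_ensemble")
  expect_equal(nrow(fit$layer1$selected), 40)
  expect_equal(nrow(fit$stackers), 10)

  p <- predict(fit, coh)
  expect_true(all(p$score >= 0 & p$score <= 1))
  expect_equal(roc_auc(p$score, p$label, positive = "case")$auc, 1)

  # averaging rule: the final score is the exact mean of the stacker scores
  feats <- tcrstack:::featurize_cohort(coh, fit)
  l1 <- vapply(seq_len(40), function(i) {
    row <- fit$layer1$selected[i, ]
    tcrstack:::predict_base_model(row$model[[1]], feats[[row$block]])
  }, numeric(nrow(coh$samples)))
  colnames(l1) <- fit$layer1$selected$tag
  l2 <- vapply(fit$stackers$model, function(m) {
    tcrstack:::predict_base_model(m, l1)
  }, numeric(nrow(l1)))
  expect_equal(p$score, rowMeans(l2), tolerance = 1e-12)

  # boundary rule: a score exactly at the threshold is called negative
  thr <- p$score[[1]]
  p2 <- predict(fit, coh, threshold = thr)
  expect_equal(p2$class[[1]], "control")

  # persistence round trip reproduces predictions exactly
  f <- withr::local_tempfile(fileext = ".rds")
  write_ensemble(fit, f)
  expect_equal(predict(read_ensemble(f), coh)$score, p$score)

  # tidy/glance summaries reflect the model structure
  td <- tidy(fit)
  expect_equal(sum(td$layer == 1), 40)
  expect_equal(sum(td$layer == 2), 10)
  gl <- glance(fit)
  expect_equal(gl$n_layer1, 40)
  expect_equal(gl$n_stackers, 10)
  expect_equal(gl$positive, "case")
})

test_that("fit_pipeline validates its inputs", {
  coh <- quick_cohort(n_per_group = 3, clones = 30)
  expect_error(fit_pipeline(coh, cv_folds = 5, grids = model_grids("minimal")),
               "too small")
  unl <- as_cohort(list(make_rep(c(1, 1), c("CAAAF", "CWWWF"))))
  expect_error(fit_pipeline(unl), "two groups")
})
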