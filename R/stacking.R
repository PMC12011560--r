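# Two-layer stacked ensemble. Layer 1: hyperparameter grids of four base
# families (elastic-net GLM, XGBoost, random forest, single-hidden-layer
# neural network) fit per feature block (motif PCA scores, CDR3-embedding
# PCA scores) under stratified cross-validation; the 5 best models per
# family per block (40 in total) are kept and their out-of-fold scores form
# the layer-2 design matrix. Layer 2: the same families fit on the 40
# out-of-fold columns; the 10 best stackers are kept and their probabilities
# averaged into the final score.

FAMILY_ORDER <- c("GLM", "XGB", "RF", "NN")

#' Hyperparameter grids for the ensemble
#'
#' `"full"` is the complete default grid (6 GLM + 48 XGBoost + 6 random
#' forest + 9 neural network = 69 points per feature block). `"fast"` and
#' `"minimal"` are reduced profiles for quick runs and repeated-refit
#' harnesses; every family keeps at least 5 points so the 5-per-family
#' selection rule is unchanged.
#'
#' @param profile One of `"full"`, `"fast"`, `"minimal"`.
#' @return Named list of per-family parameter data frames (in the fixed
#'   family order GLM, XGB, RF, NN) plus a `ctrl` list of fitting controls.
#' @export
model_grids <- function(profile = c("full", "fast", "minimal")) {
  profile <- match.arg(profile)
  g <- switch(profile,
    full = list(
      GLM = data.frame(alpha = c(0, 0.2, 0.4, 0.6, 0.8, 1)),
      XGB = expand.grid(nrounds = c(100, 200), max_depth = c(3, 6),
                        eta = c(0.01, 0.1), gamma = c(0, 0.1),
                        subsample = c(0.7, 0.8, 0.9)),
      RF  = expand.grid(mtry = c(2, 4, 6), ntree = c(500, 1000)),
      NN  = expand.grid(size = c(3, 4, 5), decay = c(0.001, 0.01, 0.1)),
      ctrl = list(glm_nfolds = 5, nn_maxit = 2000)
    ),
    fast = list(
      GLM = data.frame(alpha = c(0, 0.2, 0.4, 0.6, 0.8, 1)),
      XGB = expand.grid(nrounds = 60, max_depth = c(3, 6),
                        eta = 0.1, gamma = 0, subsample = c(0.7, 0.8, 0.9)),
      RF  = expand.grid(mtry = c(2, 4, 6), ntree = c(200, 400)),
      NN  = expand.grid(size = c(2, 3, 4), decay = c(0.01, 0.1)),
      ctrl = list(glm_nfolds = 3, nn_maxit = 500, glm_nlambda = 50)
    ),
    minimal = list(
      GLM = data.frame(alpha = c(0, 0.25, 0.5, 0.75, 1)),
      XGB = expand.grid(nrounds = 40, max_depth = 3, eta = 0.1, gamma = 0,
                        subsample = c(0.6, 0.7, 0.8, 0.9, 1)),
      RF  = expand.grid(mtry = c(2, 3, 4, 5, 6), ntree = 100),
      NN  = expand.grid(size = c(1, 2, 3, 4, 5), decay = 0.01),
      ctrl = list(glm_nfolds = 3, nn_maxit = 200, glm_nlambda = 30)
    )
  )
  structure(g, profile = profile)
}

# deterministic derived seed, kept under 2^31
derive_seed <- function(seed, ...) {
  parts <- list(seed, ...)
  s <- 0
  for (p in parts) {
    v <- if (is.character(p)) sum(utf8ToInt(p)) else as.numeric(p)
    s <- (s * 131 + v) %% 2147483629
  }
  as.integer(s + 1)
}

#' Stratified cross-validation folds
#'
#' @param y Binary 0/1 vector.
#' @param k Number of folds.
#' @param seed Seed for the shuffle.
#' @return Integer fold assignment per sample.
#' @export
make_stratified_folds <- function(y, k = 5, seed = 1) {
  if (min(table(y)) < k) {
    stop("each class needs >= ", k, " samples for ", k,
         "-fold stratified CV", call. = FALSE)
  }
  set.seed(seed)
  folds <- integer(length(y))
  for (cls in unique(y)) {
    idx <- sample(which(y == cls))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

fit_base_model <- function(family, params, x, y, seed, ctrl) {
  set.seed(seed)
  # degenerate designs (e.g. all-constant predictors) break some fitters;
  # fall back to a constant predictor at the class base rate
  tryCatch(
    fit_base_model_impl(family, params, x, y, ctrl),
    error = function(e) list(family = "CONST", p = mean(y))
  )
}

fit_base_model_impl <- function(family, params, x, y, ctrl) {
  # an all-constant design has nothing to fit and stalls some backends
  if (all(x == rep(x[1, ], each = nrow(x)))) {
    stop("zero-variance design", call. = FALSE)
  }
  switch(family,
    GLM = {
      tab <- table(y)
      if (min(tab) >= 3) {
        # inner-CV lambda selection on class-stratified folds; glmnet warns
        # about small folds at the sample sizes typical here, which is benign
        k <- min(max(3, ctrl$glm_nfolds), min(tab))
        foldid <- integer(length(y))
        for (cls in names(tab)) {
          idx <- sample(which(y == cls))
          foldid[idx] <- rep_len(seq_len(k), length(idx))
        }
        fit <- suppressWarnings(
          glmnet::cv.glmnet(x, y, family = "binomial", alpha = params$alpha,
                            foldid = foldid, type.measure = "deviance",
                            nlambda = ctrl$glm_nlambda %||% 100))
        list(family = "GLM", fit = fit, s = "lambda.min")
      } else {
        # too few per class for inner CV: fall back to the smallest lambda
        fit <- glmnet::glmnet(x, y, family = "binomial", alpha = params$alpha,
                              nlambda = ctrl$glm_nlambda %||% 100)
        list(family = "GLM", fit = fit, s = fit$lambda[length(fit$lambda)])
      }
    },
    XGB = {
      dtrain <- xgboost::xgb.DMatrix(x, label = y, nthread = 1)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic",
                      max_depth = params$max_depth, eta = params$eta,
                      gamma = params$gamma, subsample = params$subsample,
                      nthread = 1),
        data = dtrain, nrounds = params$nrounds, verbose = 0)
      list(family = "XGB", fit = fit, feature_names = colnames(x))
    },
    RF = {
      fit <- randomForest::randomForest(
        x = x, y = factor(y, levels = c(0, 1)),
        mtry = min(params$mtry, ncol(x)), ntree = params$ntree)
      list(family = "RF", fit = fit)
    },
    NN = {
      fit <- nnet::nnet(x = x, y = y, size = params$size,
                        decay = params$decay, maxit = ctrl$nn_maxit,
                        entropy = TRUE, trace = FALSE, MaxNWts = 5000)
      list(family = "NN", fit = fit)
    },
    stop("unknown family: ", family, call. = FALSE)
  )
}

predict_base_model <- function(model, x) {
  p <- switch(model$family,
    GLM = as.numeric(stats::predict(model$fit, newx = x, s = model$s,
                                    type = "response")),
    XGB = {
      d <- xgboost::xgb.DMatrix(x[, model$feature_names, drop = FALSE],
                                nthread = 1)
      as.numeric(stats::predict(model$fit, d))
    },
    RF = as.numeric(stats::predict(model$fit, x, type = "prob")[, "1"]),
    NN = as.numeric(stats::predict(model$fit, x)),
    CONST = rep(model$p, nrow(x))
  )
  # guard against numerically degenerate fits
  p[!is.finite(p)] <- 0.5
  pmin(pmax(p, 0), 1)
}

# evaluate a whole grid under CV: returns tibble with one row per grid point
# (family, param_id, params, cv_auc, oof list-column)
evaluate_grid <- function(x, y, grids, folds, seed, block) {
  ctrl <- grids$ctrl
  purrr::map_dfr(FAMILY_ORDER, function(fam) {
    grid <- grids[[fam]]
    purrr::map_dfr(seq_len(nrow(grid)), function(pi) {
      params <- as.list(grid[pi, , drop = FALSE])
      oof <- rep(NA_real_, length(y))
      for (f in sort(unique(folds))) {
        tr <- folds != f
        m <- fit_base_model(fam, params, x[tr, , drop = FALSE], y[tr],
                            derive_seed(seed, block, match(fam, FAMILY_ORDER),
                                        pi, f),
                            ctrl)
        oof[!tr] <- predict_base_model(m, x[!tr, , drop = FALSE])
      }
      tibble::tibble(block = block, family = fam, param_id = pi,
                     params = list(params), cv_auc = roc_auc(oof, y)$auc,
                     oof = list(oof))
    })
  })
}

#' Train the first ensemble layer
#'
#' Fits every grid point of the four base families on each feature block
#' under stratified cross-validation, ranks grid points by out-of-fold AUC,
#' keeps the best 5 per family per block (ties broken by grid order), refits
#' the 40 selected models on the full training data, and assembles the
#' out-of-fold score matrix used to train the second layer.
#'
#' @param features_motif,features_cdr3 PCA-reduced feature matrices with
#'   aligned rows (samples).
#' @param labels Binary 0/1 vector (1 = positive class).
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed Integer seed controlling folds and every model fit.
#' @param grids Grids from [model_grids()].
#' @param n_select Models kept per family per block (default 5).
#' @return A `tcr_layer1_bank`: selected model table (with fitted models),
#'   the samples x 40 out-of-fold matrix, the fold assignment and the full
#'   grid log.
#' @export
train_layer1 <- function(features_motif, features_cdr3, labels, cv_folds = 5,
                         seed = 1, grids = model_grids("full"),
                         n_select = 5) {
  y <- as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)), nrow(features_motif) == length(y),
            nrow(features_cdr3) == length(y))
  if (length(unique(y)) != 2) stop("labels must contain both classes", call. = FALSE)
  folds <- make_stratified_folds(y, cv_folds, derive_seed(seed, 1))
  blocks <- list(motif = features_motif, cdr3 = features_cdr3)
  log <- purrr::imap_dfr(blocks, function(x, bl) {
    evaluate_grid(x, y, grids, folds, seed, bl)
  })
  selected <- log |>
    dplyr::group_by(.data$block, .data$family) |>
    dplyr::arrange(dplyr::desc(.data$cv_auc), .data$param_id,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = n_select) |>
    dplyr::ungroup() |>
    dplyr::arrange(match(.data$block, c("motif", "cdr3")),
                   match(.data$family, FAMILY_ORDER), .data$param_id)
  # refit the selected models on the full training data
  selected$model <- purrr::pmap(
    list(selected$block, selected$family, selected$param_id, selected$params),
    function(bl, fam, pi, params) {
      fit_base_model(fam, params, blocks[[bl]], y,
                     derive_seed(seed, bl, match(fam, FAMILY_ORDER), pi, 0),
                     grids$ctrl)
    })
  selected$tag <- sprintf("%s_%s_%02d", selected$block, selected$family,
                          selected$param_id)
  oof <- do.call(cbind, selected$oof)
  colnames(oof) <- selected$tag
  structure(list(selected = selected, oof_predictions = oof, y = y,
                 folds = folds,
                 grid_log = dplyr::select(log, -"oof")),
            class = "tcr_layer1_bank")
}

#' Train the second (stacking) layer
#'
#' Fits the same four families (their grids from `grids`) on the layer-1
#' out-of-fold score matrix under stratified cross-validation, and keeps the
#' 10 grid points with the highest out-of-fold AUC overall (ties broken by
#' family order GLM, XGB, RF, NN, then grid order), refit on the full
#' out-of-fold matrix.
#'
#' @param bank A `tcr_layer1_bank` from [train_layer1()].
#' @param cv_folds Number of stratified folds (default 5).
#' @param seed Integer seed.
#' @param grids Grids from [model_grids()].
#' @param n_select Stackers kept (default 10).
#' @return Tibble of stackers with columns `family`, `param_id`, `params`,
#'   `cv_auc`, `model`.
#' @export
train_layer2 <- function(bank, cv_folds = 5, seed = 1,
                         grids = model_grids("full"), n_select = 10) {
  stopifnot(inherits(bank, "tcr_layer1_bank"))
  y <- bank$y
  x <- bank$oof_predictions
  folds <- make_stratified_folds(y, cv_folds, derive_seed(seed, 2))
  log <- evaluate_grid(x, y, grids, folds, derive_seed(seed, 3), "stack")
  stackers <- log |>
    dplyr::arrange(dplyr::desc(.data$cv_auc), match(.data$family, FAMILY_ORDER),
                   .data$param_id) |>
    dplyr::slice_head(n = n_select)
  stackers$model <- purrr::pmap(
    list(stackers$family, stackers$param_id, stackers$params),
    function(fam, pi, params) {
      fit_base_model(fam, params, x, y,
                     derive_seed(seed, "stack", match(fam, FAMILY_ORDER), pi, 0),
                     grids$ctrl)
    })
  dplyr::select(stackers, -"oof", -"block")
}

#' Raw feature matrices for a cohort
#'
#' Computes the two raw feature blocks consumed by [fit_pipeline()] and
#' [predict.tcr_stack_ensemble()]: the samples x 5-mer count matrix and the
#' samples x descriptor embedding matrix. Computing them once and passing
#' row subsets avoids re-counting motifs in repeated-refit harnesses.
#'
#' @param cohort A `tcr_cohort`.
#' @param k Motif length.
#' @param weighted_motifs Weight motif counts by clone count.
#' @param encoder An [encoder_spec()].
#' @param n_top Top CDR3s per sample to embed.
#' @return List with `motif_raw` and `emb` matrices (rows = samples).
#' @export
compute_raw_features <- function(cohort, k = 5, weighted_motifs = FALSE,
                                 encoder = encoder_spec(), n_top = 100) {
  list(motif_raw = motif_matrix(cohort, k = k, weighted = weighted_motifs),
       emb = embedding_matrix(cohort, spec = encoder, n = n_top))
}

align_motif_columns <- function(norm_matrix, vocab) {
  out <- matrix(0, nrow = nrow(norm_matrix), ncol = length(vocab),
                dimnames = list(rownames(norm_matrix), vocab))
  common <- intersect(colnames(norm_matrix), vocab)
  out[, common] <- norm_matrix[, common]
  out
}

featurize_cohort <- function(cohort, ensemble_meta, raw_features = NULL) {
  if (is.null(raw_features)) {
    raw_features <- compute_raw_features(
      cohort, k = ensemble_meta$k,
      weighted_motifs = ensemble_meta$weighted_motifs,
      encoder = ensemble_meta$encoder, n_top = ensemble_meta$n_top)
  }
  # library sizes over the sample's full motif complement, then restrict to
  # the model vocabulary before the (expensive) log/align steps
  libs <- rowSums(raw_features$motif_raw)
  libs[libs == 0] <- 1
  sub <- align_motif_columns(raw_features$motif_raw, ensemble_meta$motif_vocab)
  motif_feats <- log1p(sub / libs * 1e4)
  list(motif = apply_pca(ensemble_meta$pca_motif, motif_feats),
       cdr3 = apply_pca(ensemble_meta$pca_cdr3, raw_features$emb))
}

#' Fit the full classification pipeline on a labelled cohort
#'
#' End to end: raw 5-mer motif matrix, library-size normalisation and PCA to
#' at most 50 components; per-sample CDR3 descriptor embeddings and PCA to
#' at most 50 components; first-layer grid training and selection of 40
#' models; second-layer training and selection of 10 stackers.
#'
#' @param cohort A binary-labelled `tcr_cohort`.
#' @param task Optional ordered pair `c(positive, negative)`; defaults to the
#'   cohort's groups.
#' @param encoder An [encoder_spec()].
#' @param seed Integer seed governing all randomness.
#' @param grids Grids from [model_grids()].
#' @param cv_folds Stratified folds for both layers (default 5).
#' @param n_top Top CDR3s per sample to embed (default 100).
#' @param k Motif length (default 5).
#' @param n_components PCA components per block (default 50).
#' @param threshold Decision threshold on the averaged score (default 0.5;
#'   a positive call requires score strictly above it).
#' @param weighted_motifs Weight motif counts by clone count (default FALSE).
#' @param min_motif_samples Motifs detected in fewer training samples than
#'   this are excluded from the motif feature block (default 2): a k-mer
#'   seen in a single sample carries no between-sample signal and inflates
#'   the PCA with noise dimensions. Library-size normalisation still uses
#'   every motif of each sample.
#' @param raw_features Optional precomputed output of
#'   [compute_raw_features()] for this cohort (rows aligned with its
#'   samples), to avoid recounting in repeated-refit harnesses.
#' @return A `tcr_stack_ensemble`.
#' @export
fit_pipeline <- function(cohort, task = NULL, encoder = encoder_spec(),
                         seed = 1, grids = model_grids("full"),
                         cv_folds = 5, n_top = 100, k = 5,
                         n_components = 50, threshold = 0.5,
                         weighted_motifs = FALSE, min_motif_samples = 2,
                         raw_features = NULL) {
  groups <- if (!is.null(task)) task else cohort_groups(cohort)
  if (is.null(groups) || length(groups) != 2) {
    stop("a binary task needs two groups; pass task = c(positive, negative)",
         call. = FALSE)
  }
  labels <- cohort$samples$label
  if (!all(labels %in% groups)) {
    stop("cohort contains labels outside the task: ",
         paste(setdiff(labels, groups), collapse = ", "), call. = FALSE)
  }
  y <- as.integer(labels == groups[[1]])
  if (min(table(y)) < cv_folds) {
    stop("class sizes ", paste(table(y), collapse = "/"),
         " are too small for ", cv_folds, "-fold stratified CV", call. = FALSE)
  }

  if (is.null(raw_features)) {
    raw_features <- compute_raw_features(cohort, k = k,
                                         weighted_motifs = weighted_motifs,
                                         encoder = encoder, n_top = n_top)
  }
  keep <- colSums(raw_features$motif_raw > 0) >= min_motif_samples
  if (!any(keep)) stop("no motif detected in >= ", min_motif_samples,
                       " samples", call. = FALSE)
  libs <- rowSums(raw_features$motif_raw)
  libs[libs == 0] <- 1
  norm <- log1p(raw_features$motif_raw[, keep, drop = FALSE] / libs * 1e4)
  pca_motif <- fit_pca(norm, n_components)
  emb <- raw_features$emb
  pca_cdr3 <- fit_pca(emb, n_components)

  f_motif <- apply_pca(pca_motif, norm)
  f_cdr3 <- apply_pca(pca_cdr3, emb)

  bank <- train_layer1(f_motif, f_cdr3, y, cv_folds = cv_folds, seed = seed,
                       grids = grids)
  stackers <- train_layer2(bank, cv_folds = cv_folds, seed = seed,
                           grids = grids)
  structure(list(
    version = 1L,
    groups = groups,
    encoder = encoder,
    n_top = n_top, k = k, weighted_motifs = weighted_motifs,
    motif_vocab = rownames(pca_motif$rotation),
    pca_motif = pca_motif, pca_cdr3 = pca_cdr3,
    layer1 = bank, stackers = stackers,
    threshold = threshold,
    n_train = length(y)
  ), class = "tcr_stack_ensemble")
}

#' @export
print.tcr_stack_ensemble <- function(x, ...) {
  cat(sprintf(paste0("<tcr_stack_ensemble v%d> %s vs %s | %d layer-1 models,",
                     " %d stackers | threshold %.2f\n"),
              x$version, x$groups[[1]], x$groups[[2]],
              nrow(x$layer1$selected), nrow(x$stackers), x$threshold))
  invisible(x)
}

#' Predict group membership for a cohort
#'
#' Featurises the cohort with the stored motif vocabulary, encoder and PCA
#' transforms, scores it with the 40 first-layer models, feeds those scores
#' to the 10 stackers, and averages the stacker probabilities. A sample is
#' called positive when its averaged score is strictly above the threshold.
#'
#' @param object A `tcr_stack_ensemble`.
#' @param cohort A `tcr_cohort`.
#' @param threshold Decision threshold; defaults to the one stored in the
#'   model.
#' @param raw_features Optional precomputed [compute_raw_features()] output
#'   for this cohort.
#' @param ... Unused.
#' @return Tibble with `sample_id`, `score`, `class`, and `label` (NA when
#'   unknown).
#' @export
predict.tcr_stack_ensemble <- function(object, cohort, threshold = NULL,
                                       raw_features = NULL, ...) {
  if (is.null(threshold)) threshold <- object$threshold
  feats <- featurize_cohort(cohort, object, raw_features)
  l1 <- vapply(seq_len(nrow(object$layer1$selected)), function(i) {
    row <- object$layer1$selected[i, ]
    predict_base_model(row$model[[1]], feats[[row$block]])
  }, numeric(nrow(cohort$samples)))
  if (is.null(dim(l1))) l1 <- matrix(l1, nrow = 1)
  colnames(l1) <- object$layer1$selected$tag
  l2 <- vapply(object$stackers$model, function(m) {
    predict_base_model(m, l1)
  }, numeric(nrow(l1)))
  if (is.null(dim(l2))) l2 <- matrix(l2, nrow = 1)
  score <- rowMeans(l2)
  tibble::tibble(
    sample_id = cohort$samples$sample_id,
    score = score,
    class = ifelse(score > threshold, object$groups[[1]], object$groups[[2]]),
    label = cohort$samples$label
  )
}

#' Persist a fitted ensemble
#'
#' Serialised with a versioned schema; [read_ensemble()] restores a model
#' giving predictions identical to the in-memory object.
#'
#' @param model A `tcr_stack_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(model, path) {
  stopifnot(inherits(model, "tcr_stack_ensemble"))
  saveRDS(model, path)
  invisible(path)
}

#' Restore a persisted ensemble
#' @param path Path written by [write_ensemble()].
#' @return A `tcr_stack_ensemble`.
#' @export
read_ensemble <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "tcr_stack_ensemble")) {
    stop("not a tcr_stack_ensemble file: ", path, call. = FALSE)
  }
  if (is.null(model$version) || model$version > 1L) {
    stop("unsupported model schema version", call. = FALSE)
  }
  model
}
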