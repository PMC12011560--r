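# CDR3 sequence encoding: top-n clonotype selection, a deterministic
# physicochemical descriptor encoder (with an adapter slot for external
# protein language models), per-sample aggregation, and PCA reduction.

#' Atchley physicochemical factors
#'
#' The five Atchley factor scores per amino acid (polarity/accessibility,
#' secondary-structure propensity, molecular size, codon composition,
#' electrostatic charge), used by the default descriptor encoder.
#'
#' @return 20 x 5 numeric matrix, rows named by amino acid.
#' @export
atchley_factors <- function() {
  vals <- c(
    A = c(-0.591, -1.302, -0.733,  1.570, -0.146),
    C = c(-1.343,  0.465, -0.862, -1.020, -0.255),
    D = c( 1.050,  0.302, -3.656, -0.259, -3.242),
    E = c( 1.357, -1.453,  1.477,  0.113, -0.837),
    F = c(-1.006, -0.590,  1.891, -0.397,  0.412),
    G = c(-0.384,  1.652,  1.330,  1.045,  2.064),
    H = c( 0.336, -0.417, -1.673, -1.474, -0.078),
    I = c(-1.239, -0.547,  2.131,  0.393,  0.816),
    K = c( 1.831, -0.561,  0.533, -0.277,  1.648),
    L = c(-1.019, -0.987, -1.505,  1.266, -0.912),
    M = c(-0.663, -1.524,  2.219, -1.005,  1.212),
    N = c( 0.945,  0.828,  1.299, -0.169,  0.933),
    P = c( 0.189,  2.081, -1.628,  0.421, -1.392),
    Q = c( 0.931, -0.179, -3.005, -0.503, -1.853),
    R = c( 1.538, -0.055,  1.502,  0.440,  2.897),
    S = c(-0.228,  1.399, -4.760,  0.670, -2.647),
    T = c(-0.032,  0.326,  2.213,  0.908,  1.313),
    V = c(-1.337, -0.279, -0.544,  1.242, -1.262),
    W = c(-0.595,  0.009,  0.672, -2.128, -0.184),
    Y = c( 0.260,  0.830,  3.097, -0.838,  1.512)
  )
  m <- matrix(vals, ncol = 5, byrow = TRUE,
              dimnames = list(AA_ALPHABET, paste0("AF", 1:5)))
  m
}

#' Encoder specification
#'
#' Describes a sequence encoder: the built-in `"descriptor"` encoder, or an
#' adapter around an external embedding function (e.g. a protein language
#' model) supplied as `fn`.
#'
#' @param name Encoder name; `"descriptor"` selects the built-in encoder.
#' @param dim Output dimension (41 for the descriptor encoder).
#' @param deterministic Whether repeated calls are bit-identical.
#' @param fn For custom encoders, a function `(character sequence) -> numeric
#'   vector of length dim`.
#' @return An `encoder_spec` object.
#' @export
encoder_spec <- function(name = "descriptor", dim = 41L,
                         deterministic = TRUE, fn = NULL) {
  if (name == "descriptor") {
    dim <- 41L; deterministic <- TRUE; fn <- NULL
  } else if (!is.function(fn)) {
    stop("custom encoder '", name, "' requires fn", call. = FALSE)
  }
  structure(list(name = name, dim = as.integer(dim),
                 deterministic = deterministic, fn = fn),
            class = "encoder_spec")
}

atchley_mean <- function(aas, af) {
  if (length(aas) == 0) return(numeric(5))
  if (length(aas) == 1) return(af[aas, ]) else colMeans(af[aas, , drop = FALSE])
}

encode_descriptor <- function(seq) {
  aas <- strsplit(seq, "")[[1]]
  bad <- setdiff(aas, AA_ALPHABET)
  if (length(bad) > 0) {
    stop("invalid residue(s) in CDR3: ", paste(bad, collapse = ""), call. = FALSE)
  }
  af <- atchley_factors()
  L <- length(aas)
  comp <- table(factor(aas, levels = AA_ALPHABET)) / L
  # terminal segments take min(3, floor(L/2)) residues each so that even very
  # short sequences keep N- vs C-terminal contrast; the central segment is the
  # remainder (zeros when empty)
  k <- min(3L, L %/% 2L)
  nterm <- if (k > 0) aas[seq_len(k)] else character(0)
  cterm <- if (k > 0) aas[(L - k + 1):L] else character(0)
  central <- if (L - 2 * k > 0) aas[(k + 1):(L - k)] else character(0)
  v <- c(as.numeric(comp),
         atchley_mean(aas, af),
         atchley_mean(nterm, af),
         atchley_mean(central, af),
         atchley_mean(cterm, af),
         L)
  names(v) <- c(paste0("comp_", AA_ALPHABET),
                paste0("af_all_", 1:5), paste0("af_nterm_", 1:5),
                paste0("af_central_", 1:5), paste0("af_cterm_", 1:5),
                "length")
  v
}

#' Encode one CDR3 amino-acid sequence
#'
#' The default `"descriptor"` encoder returns a deterministic 41-dimensional
#' vector: the 20 amino-acid composition frequencies, the 5 Atchley-factor
#' means over the whole sequence, the 5 Atchley-factor means over each of the
#' N-terminal, central and C-terminal segments, and the length.
#'
#' @param seq CDR3 amino-acid string.
#' @param spec An [encoder_spec()].
#' @return Named numeric vector of length `spec$dim`.
#' @export
encode_sequence <- function(seq, spec = encoder_spec()) {
  stopifnot(inherits(spec, "encoder_spec"))
  if (spec$name == "descriptor") return(encode_descriptor(seq))
  v <- spec$fn(seq)
  if (length(v) != spec$dim) {
    stop("encoder '", spec$name, "' returned length ", length(v),
         ", expected ", spec$dim, call. = FALSE)
  }
  as.numeric(v)
}

#' The n most abundant CDR3 sequences of a repertoire
#'
#' Ties in fraction are broken by lexicographic sequence order; fewer
#' sequences are returned when richness is below `n`.
#'
#' @param rep A `tcr_repertoire`.
#' @param n Number of sequences (default 100).
#' @return Character vector of CDR3 sequences.
#' @export
top_n_cdr3 <- function(rep, n = 100) {
  ord <- order(-rep$fraction, rep$cdr3_aa)
  rep$cdr3_aa[ord][seq_len(min(n, nrow(rep)))]
}

#' Per-sample CDR3 embedding
#'
#' Encodes the `n` most abundant CDR3s and aggregates them into one vector:
#' an unweighted mean by default, or a clone-fraction-weighted mean with
#' `weighting = "fraction"`.
#'
#' @param rep A `tcr_repertoire`.
#' @param spec An [encoder_spec()].
#' @param n Number of top sequences (default 100).
#' @param weighting `"uniform"` or `"fraction"`.
#' @return Named numeric vector with attributes `sample_id` and
#'   `n_sequences_used`.
#' @export
sample_embedding <- function(rep, spec = encoder_spec(), n = 100,
                             weighting = c("uniform", "fraction")) {
  weighting <- match.arg(weighting)
  seqs <- top_n_cdr3(rep, n)
  mat <- vapply(seqs, function(s) encode_sequence(s, spec), numeric(spec$dim))
  w <- if (weighting == "uniform") {
    rep(1 / length(seqs), length(seqs))
  } else {
    f <- rep$fraction[match(seqs, rep$cdr3_aa)]
    f / sum(f)
  }
  v <- as.numeric(mat %*% w)
  names(v) <- rownames(mat)
  attr(v, "sample_id") <- attr(rep, "sample_id")
  attr(v, "n_sequences_used") <- length(seqs)
  v
}

#' Samples x features embedding matrix for a cohort
#'
#' @param cohort A `tcr_cohort`.
#' @inheritParams sample_embedding
#' @return Numeric matrix, one row per sample.
#' @export
embedding_matrix <- function(cohort, spec = encoder_spec(), n = 100,
                             weighting = "uniform") {
  rows <- purrr::map(cohort$repertoires, sample_embedding,
                     spec = spec, n = n, weighting = weighting)
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(cohort$repertoires)
  mat
}

#' Fit a PCA reduction
#'
#' Columns are centred and scaled to unit variance (constant columns get
#' unit scale); components come from the SVD of the standardised matrix with
#' a deterministic sign convention (the largest-magnitude loading of each
#' component is positive). The number of components is capped at
#' `min(n_components, n_samples - 1, n_features)`.
#'
#' @param matrix Samples x features numeric matrix with column names.
#' @param n_components Maximum number of components (default 50).
#' @return A `tcr_pca` object with `mean`, `scale`, `rotation` (features x
#'   components), `explained_variance_ratio`.
#' @export
fit_pca <- function(matrix, n_components = 50) {
  if (nrow(matrix) < 2) stop("PCA needs >= 2 samples", call. = FALSE)
  if (is.null(colnames(matrix))) {
    colnames(matrix) <- paste0("f", seq_len(ncol(matrix)))
  }
  n <- nrow(matrix)
  mu <- colMeans(matrix)
  # vectorised column sd; apply() is too slow for motif-scale matrices
  sc <- sqrt(pmax(0, (colSums(matrix^2) - n * mu^2) / (n - 1)))
  sc[sc < 1e-12 | !is.finite(sc)] <- 1
  x <- sweep(sweep(matrix, 2, mu, "-"), 2, sc, "/")
  k <- min(n_components, nrow(matrix) - 1L, ncol(matrix))
  if (ncol(x) > nrow(x)) {
    # wide data: eigendecompose the n x n Gram matrix instead of a full SVD
    eg <- eigen(tcrossprod(x), symmetric = TRUE)
    d2 <- pmax(eg$values, 0)
    d <- sqrt(d2[seq_len(k)])
    rot <- crossprod(x, eg$vectors[, seq_len(k), drop = FALSE])
    ok <- d > 1e-10
    rot[, ok] <- sweep(rot[, ok, drop = FALSE], 2, d[ok], "/")
    rot[, !ok] <- 0
    sv <- list(d = sqrt(d2), v = rot)
  } else {
    sv <- svd(x, nu = 0, nv = k)
  }
  rot <- sv$v
  # sign convention: largest |loading| positive
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  dimnames(rot) <- list(colnames(matrix), paste0("PC", seq_len(k)))
  ev <- sv$d[seq_len(k)]^2
  tot <- sum(sv$d^2)
  structure(list(mean = mu, scale = sc, rotation = rot,
                 n_components = k,
                 explained_variance_ratio = ev / tot),
            class = "tcr_pca")
}

#' Project a matrix onto a fitted PCA
#'
#' Columns are aligned to the fit-time features by name; extra columns are
#' dropped and the projection of the training matrix reproduces the fit-time
#' scores to 1e-8.
#'
#' @param model A `tcr_pca` from [fit_pca()].
#' @param matrix Samples x features matrix whose columns include the
#'   fit-time features.
#' @return Samples x components score matrix.
#' @export
apply_pca <- function(model, matrix) {
  stopifnot(inherits(model, "tcr_pca"))
  feats <- rownames(model$rotation)
  if (is.null(colnames(matrix))) {
    if (ncol(matrix) != length(feats)) {
      stop("unnamed matrix with wrong number of columns", call. = FALSE)
    }
    colnames(matrix) <- feats
  }
  missing_f <- setdiff(feats, colnames(matrix))
  if (length(missing_f) > 0) {
    stop("matrix lacks ", length(missing_f), " fit-time feature(s), e.g. ",
         missing_f[[1]], call. = FALSE)
  }
  x <- matrix[, feats, drop = FALSE]
  x <- sweep(sweep(x, 2, model$mean, "-"), 2, model$scale, "/")
  x %*% model$rotation
}
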