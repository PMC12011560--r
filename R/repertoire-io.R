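# Reading, validating and writing MiXCR-export-style clonotype tables, and
# the in-memory repertoire/cohort containers used throughout the package.

#' Standard amino-acid alphabet
#'
#' The 20 one-letter amino-acid codes accepted in CDR3 sequences.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

VALID_CHAINS <- c("TRB", "TRD", "TRG")

#' Default MiXCR column-name map
#'
#' Maps canonical field names to the candidate column names searched for in a
#' clonotype TSV, in priority order. Override individual entries via the
#' `col_map` argument of [read_clonotype_table()].
#'
#' @return Named list of character vectors.
#' @export
mixcr_col_map <- function() {
  list(
    count    = c("cloneCount", "readCount", "count"),
    fraction = c("cloneFraction", "readFraction", "frequency", "fraction"),
    cdr3_aa  = c("aaSeqCDR3", "cdr3aa", "CDR3.aa", "junction_aa"),
    v_gene   = c("vGene", "bestVGene", "allVHitsWithScore", "v_call", "V.name"),
    j_gene   = c("jGene", "bestJGene", "allJHitsWithScore", "j_call", "J.name")
  )
}

# "TRBV7-9*00(1234.5)" -> "TRBV7-9"; keeps the first hit of a comma list.
clean_gene <- function(x) {
  x <- sub(",.*$", "", as.character(x))
  x <- sub("\\*.*$", "", x)
  sub("\\(.*$", "", trimws(x))
}

chain_from_v <- function(v_gene) {
  out <- rep(NA_character_, length(v_gene))
  hit <- grepl("^TR[BDG]V", v_gene)
  out[hit] <- substr(v_gene[hit], 1, 3)
  out
}

valid_cdr3 <- function(x) {
  nzchar(x) & !is.na(x) & grepl(paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$"), x)
}

#' Build a validated repertoire from a clonotype data frame
#'
#' Applies the canonical clean-up contract: rows whose CDR3 contains
#' characters outside the 20-letter amino-acid alphabet (e.g. the MiXCR
#' out-of-frame/stop markers `_` and `*`) are dropped; duplicate CDR3 amino
#' acid sequences are merged (counts and fractions summed, V/J genes of the
#' most abundant contributor kept); fractions are renormalised to sum to 1;
#' clonotypes are sorted by descending fraction and `clone_id` reassigned as
#' the 0-based rank.
#'
#' @param df Data frame with columns `count`, `fraction` (or `count` only),
#'   `cdr3_aa`, `v_gene`, `j_gene`.
#' @param sample_id Sample identifier string.
#' @param chain Chain locus, one of `"TRB"`, `"TRD"`, `"TRG"`; inferred from
#'   the V-gene prefixes when `NULL`.
#' @param label Optional group label.
#' @return A `tcr_repertoire`: a tibble of clonotypes with attributes
#'   `sample_id`, `chain` and `label`.
#' @export
as_repertoire <- function(df, sample_id, chain = NULL, label = NULL) {
  stopifnot(is.data.frame(df))
  need <- c("count", "cdr3_aa", "v_gene", "j_gene")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("clonotype table for '", sample_id, "' lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  df$v_gene <- clean_gene(df$v_gene)
  df$j_gene <- clean_gene(df$j_gene)
  df$cdr3_aa <- as.character(df$cdr3_aa)
  if (!"fraction" %in% names(df)) df$fraction <- df$count / sum(df$count)

  df <- df[valid_cdr3(df$cdr3_aa) & !is.na(df$count) & df$count >= 0, , drop = FALSE]
  if (nrow(df) == 0) {
    stop("repertoire '", sample_id, "' is empty after CDR3 validation", call. = FALSE)
  }

  inferred <- chain_from_v(df$v_gene)
  if (!is.null(chain)) {
    chain <- match.arg(chain, VALID_CHAINS)
    bad <- !is.na(inferred) & inferred != chain
    if (any(bad)) {
      stop("sample '", sample_id, "': V genes ",
           paste(unique(df$v_gene[bad]), collapse = ", "),
           " are inconsistent with chain ", chain, call. = FALSE)
    }
  } else {
    seen <- unique(inferred[!is.na(inferred)])
    if (length(seen) > 1) {
      stop("sample '", sample_id, "' mixes chains (", paste(seen, collapse = ", "),
           "); split the file or pass chain explicitly", call. = FALSE)
    }
    if (length(seen) == 0) {
      stop("sample '", sample_id, "': chain not derivable from V genes; ",
           "pass chain explicitly", call. = FALSE)
    }
    chain <- seen
  }

  # merge duplicate CDR3s; V/J from the single most abundant contributor
  df <- df |>
    dplyr::group_by(.data$cdr3_aa) |>
    dplyr::summarise(
      count = sum(.data$count),
      fraction = sum(.data$fraction),
      v_gene = .data$v_gene[which.max(.data$count)],
      j_gene = .data$j_gene[which.max(.data$count)],
      .groups = "drop"
    )
  df$fraction <- df$fraction / sum(df$fraction)
  df <- df[order(-df$fraction, df$cdr3_aa), , drop = FALSE]
  df <- tibble::tibble(
    clone_id = seq_len(nrow(df)) - 1L,
    count = df$count,
    fraction = df$fraction,
    cdr3_aa = df$cdr3_aa,
    v_gene = df$v_gene,
    j_gene = df$j_gene
  )
  structure(df,
            class = c("tcr_repertoire", class(tibble::tibble())),
            sample_id = as.character(sample_id),
            chain = chain,
            label = if (is.null(label)) NA_character_ else as.character(label))
}

#' @export
print.tcr_repertoire <- function(x, ...) {
  cat(sprintf("<tcr_repertoire> %s  chain=%s  label=%s  clonotypes=%d\n",
              attr(x, "sample_id"), attr(x, "chain"),
              attr(x, "label"), nrow(x)))
  NextMethod()
}

#' Read a MiXCR-export-style clonotype table
#'
#' Reads a tab-separated clonotype export, resolves column names through a
#' configurable map, and returns a validated repertoire (see
#' [as_repertoire()] for the clean-up contract).
#'
#' @param path Path to a TSV file.
#' @param chain_hint Optional chain (`"TRB"`, `"TRD"`, `"TRG"`) checked
#'   against the V-gene prefixes.
#' @param sample_id Sample identifier; defaults to the file name without
#'   extension.
#' @param label Optional group label attached to the repertoire.
#' @param col_map Column-name map as produced by [mixcr_col_map()].
#' @return A `tcr_repertoire` tibble.
#' @export
read_clonotype_table <- function(path, chain_hint = NULL, sample_id = NULL,
                                 label = NULL, col_map = mixcr_col_map()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) stop("empty clonotype table: ", path, call. = FALSE)

  pick <- function(field) {
    hit <- intersect(col_map[[field]], names(raw))
    if (length(hit) == 0 && field != "fraction") {
      stop("missing required column for '", field, "' (looked for: ",
           paste(col_map[[field]], collapse = ", "), ") in ", path,
           call. = FALSE)
    }
    if (length(hit) == 0) NULL else raw[[hit[[1]]]]
  }
  df <- tibble::tibble(
    count = as.numeric(pick("count")),
    cdr3_aa = as.character(pick("cdr3_aa")),
    v_gene = as.character(pick("v_gene")),
    j_gene = as.character(pick("j_gene"))
  )
  frac <- pick("fraction")
  if (!is.null(frac)) df$fraction <- as.numeric(frac)
  as_repertoire(df, sample_id = sample_id, chain = chain_hint, label = label)
}

#' Write a repertoire as a clonotype TSV
#'
#' Emits the MiXCR-style dialect (`cloneId`, `cloneCount`, `cloneFraction`,
#' `aaSeqCDR3`, `vGene`, `jGene`) readable by [read_clonotype_table()];
#' a read/write round trip reproduces fractions to 1e-9.
#'
#' @param rep A `tcr_repertoire`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_clonotype_table <- function(rep, path) {
  stopifnot(inherits(rep, "tcr_repertoire"))
  if (nrow(rep) == 0) stop("refusing to write an empty repertoire", call. = FALSE)
  out <- tibble::tibble(
    cloneId = rep$clone_id,
    cloneCount = rep$count,
    cloneFraction = rep$fraction,
    aaSeqCDR3 = rep$cdr3_aa,
    vGene = rep$v_gene,
    jGene = rep$j_gene
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Assemble repertoires into a cohort
#'
#' @param repertoires List of `tcr_repertoire` objects with unique sample ids.
#' @param groups Optional ordered pair `c(positive, negative)` naming the two
#'   groups of a binary task; inferred from the labels (first-appearance
#'   order) when `NULL` and exactly two labels are present.
#' @return A `tcr_cohort`: list with elements `repertoires` (named list) and
#'   `samples` (tibble of sample_id, chain, label), plus a `groups` attribute.
#' @export
as_cohort <- function(repertoires, groups = NULL) {
  stopifnot(is.list(repertoires), length(repertoires) > 0)
  ids <- vapply(repertoires, attr, "", which = "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids in cohort", call. = FALSE)
  names(repertoires) <- ids
  samples <- tibble::tibble(
    sample_id = unname(ids),
    chain = unname(vapply(repertoires, attr, "", which = "chain")),
    label = unname(vapply(repertoires, attr, "", which = "label"))
  )
  labs <- unique(samples$label[!is.na(samples$label)])
  if (is.null(groups) && length(labs) == 2) groups <- labs
  if (!is.null(groups)) {
    stopifnot(length(groups) == 2)
    if (!all(groups %in% samples$label)) {
      stop("groups ", paste(setdiff(groups, samples$label), collapse = ", "),
           " absent from cohort labels", call. = FALSE)
    }
  }
  structure(list(repertoires = repertoires, samples = samples),
            class = "tcr_cohort", groups = groups)
}

#' @export
print.tcr_cohort <- function(x, ...) {
  cat(sprintf("<tcr_cohort> %d samples", nrow(x$samples)))
  tab <- table(x$samples$label, useNA = "ifany")
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Cohort group labels
#' @param cohort A `tcr_cohort`.
#' @return Ordered pair `c(positive, negative)` or `NULL`.
#' @export
cohort_groups <- function(cohort) attr(cohort, "groups")

#' All clonotypes of a cohort as one tidy table
#'
#' @param cohort A `tcr_cohort`.
#' @return Tibble with one row per clonotype, carrying `sample_id`, `label`
#'   and `chain` alongside the clonotype fields.
#' @export
cohort_clonotypes <- function(cohort) {
  purrr::map_dfr(cohort$repertoires, function(r) {
    dplyr::mutate(tibble::as_tibble(r),
                  sample_id = attr(r, "sample_id"),
                  label = attr(r, "label"),
                  chain = attr(r, "chain"))
  })
}

#' Replace the group labels of a cohort
#'
#' Useful for permutation controls: relabels every repertoire and the sample
#' table, keeping the group pair.
#'
#' @param cohort A `tcr_cohort`.
#' @param labels Character vector of new labels, in the order of
#'   `cohort$samples`, or named by sample id.
#' @return A `tcr_cohort`.
#' @export
relabel_cohort <- function(cohort, labels) {
  if (!is.null(names(labels))) labels <- labels[cohort$samples$sample_id]
  stopifnot(length(labels) == nrow(cohort$samples))
  reps <- purrr::map2(cohort$repertoires, labels, function(r, l) {
    attr(r, "label") <- l
    r
  })
  as_cohort(reps, groups = cohort_groups(cohort))
}

#' Load a cohort from a manifest
#'
#' The manifest is a CSV/TSV (or data frame) with columns `sample_id`,
#' `path`, `chain`, `label`; paths are resolved relative to `data_dir` when
#' given.
#'
#' @param manifest Path to a manifest file, or a data frame.
#' @param data_dir Optional directory against which relative paths resolve.
#' @param binary When `TRUE`, require exactly two distinct labels; `NULL`
#'   (default) sets up a binary task only if two labels are present.
#' @param quiet Suppress the load log.
#' @return A `tcr_cohort`.
#' @export
load_cohort <- function(manifest, data_dir = NULL, binary = NULL, quiet = FALSE) {
  if (is.character(manifest)) {
    delim <- if (grepl("\\.tsv$", manifest)) "\t" else ","
    manifest <- readr::read_delim(manifest, delim = delim,
                                  show_col_types = FALSE, progress = FALSE)
  }
  manifest <- tibble::as_tibble(manifest)
  need <- c("sample_id", "path", "label")
  if (!all(need %in% names(manifest))) {
    stop("manifest needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  labs <- unique(manifest$label)
  if (isTRUE(binary) && length(labs) != 2) {
    stop("binary task requested but manifest has ", length(labs),
         " distinct labels: ", paste(labs, collapse = ", "), call. = FALSE)
  }
  reps <- purrr::pmap(manifest, function(sample_id, path, label, ...) {
    dots <- list(...)
    full <- if (!is.null(data_dir)) file.path(data_dir, path) else path
    if (!file.exists(full)) {
      stop("file for sample '", sample_id, "' not found: ", full, call. = FALSE)
    }
    read_clonotype_table(full, chain_hint = dots$chain,
                         sample_id = sample_id, label = label)
  })
  cohort <- as_cohort(reps)
  if (!quiet) {
    tab <- table(manifest$label)
    message("loaded ", nrow(manifest), " repertoires; labels: ",
            paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
  }
  cohort
}
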