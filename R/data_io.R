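#' Gene signatures
#'
#' A gene signature is an ordered list of gene symbols, e.g. the marker genes
#' of prognostically relevant tumor-associated macrophage subtypes used as the
#' model's feature space. Symbols are whitespace-trimmed and upper-cased;
#' duplicates (after normalization) are rejected.
#'
#' @param genes character vector of gene symbols.
#' @return An object of class `gene_signature` (a character vector).
#' @examples
#' sig <- gene_signature(c("CXCL8", "MMP7", "TSPAN8"))
#' length(sig)
#' @export
gene_signature <- function(genes) {
  if (!is.character(genes) || length(genes) == 0L) {
    stop_cf("a gene signature needs at least one gene symbol",
            class = "coxformer_format_error")
  }
  genes <- toupper(trimws(genes))
  if (any(genes == "")) {
    stop_cf("empty gene symbol in signature", class = "coxformer_format_error")
  }
  if (anyDuplicated(genes)) {
    stop_cf("duplicate gene symbols in signature after case-normalization: ",
            paste(unique(genes[duplicated(genes)]), collapse = ", "),
            class = "coxformer_format_error")
  }
  structure(genes, class = "gene_signature")
}

#' Survival cohorts
#'
#' Container pairing a continuous expression matrix (samples x genes) with
#' per-sample overall-survival follow-up: `time` in days (> 0) and `event`
#' (1 = death observed, 0 = censored). All downstream modules (training,
#' evaluation, cross-validation, attribution) consume this type.
#'
#' @param X numeric matrix, samples in rows, genes in columns.
#' @param sample_ids character vector of unique sample identifiers.
#' @param genes character vector of gene symbols (column order of `X`).
#' @param time numeric vector of positive follow-up durations (days).
#' @param event integer vector in \{0, 1\}.
#' @param require_event require at least one observed event (needed for the
#'   partial likelihood to be defined). Default `TRUE`.
#' @return An object of class `survival_cohort`.
#' @export
survival_cohort <- function(X, sample_ids, genes, time, event,
                            require_event = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  sample_ids <- as.character(sample_ids)
  genes <- toupper(trimws(as.character(genes)))
  if (length(sample_ids) != n || length(time) != n || length(event) != n) {
    stop_cf("sample_ids, time and event must match the number of rows of X",
            class = "coxformer_validation_error")
  }
  if (ncol(X) != length(genes)) {
    stop_cf("genes must match the number of columns of X",
            class = "coxformer_validation_error")
  }
  if (anyDuplicated(sample_ids)) {
    stop_cf("duplicate sample ids: ",
            paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
            class = "coxformer_validation_error")
  }
  if (anyNA(X) || any(!is.finite(X))) {
    stop_cf("expression matrix contains missing or non-finite values",
            class = "coxformer_validation_error")
  }
  time <- as.numeric(time)
  bad_t <- which(!is.finite(time) | time <= 0)
  if (length(bad_t)) {
    stop_cf("non-positive or missing follow-up time for sample ",
            sample_ids[bad_t[1L]], class = "coxformer_validation_error")
  }
  bad_e <- which(!(event %in% c(0, 1)))
  if (length(bad_e)) {
    stop_cf("event indicator outside {0,1} for sample ", sample_ids[bad_e[1L]],
            class = "coxformer_validation_error")
  }
  event <- as.integer(event)
  if (require_event && sum(event) == 0L) {
    stop_cf("cohort has no observed events; the Cox partial likelihood is undefined",
            class = "coxformer_validation_error")
  }
  dimnames(X) <- list(sample_ids, genes)
  structure(
    list(sample_ids = sample_ids, genes = genes, X = X,
         time = time, event = event),
    class = "survival_cohort"
  )
}

#' @export
print.survival_cohort <- function(x, ...) {
  cat(sprintf("survival_cohort: %d samples x %d genes, %d events (%.1f%% censored)\n",
              nrow(x$X), ncol(x$X), sum(x$event),
              100 * mean(x$event == 0)))
  invisible(x)
}

#' @export
dim.survival_cohort <- function(x) dim(x$X)

#' Subset a cohort by sample rows
#'
#' @param cohort a `survival_cohort`.
#' @param rows integer or logical index of samples to keep.
#' @param require_event require at least one event in the subset.
#' @return a `survival_cohort` with the selected rows.
#' @export
subset_cohort <- function(cohort, rows, require_event = TRUE) {
  survival_cohort(cohort$X[rows, , drop = FALSE],
                  cohort$sample_ids[rows], cohort$genes,
                  cohort$time[rows], cohort$event[rows],
                  require_event = require_event)
}

#' Load a cohort from expression and clinical TSV files
#'
#' The expression table is TSV with a `sample_id` first column and one column
#' per gene symbol. The clinical table is TSV with columns `sample_id`,
#' `time` (days) and `event` (0/1). The returned cohort contains the samples
#' present in both files, in expression-file order. Duplicate gene columns
#' keep the first occurrence with a warning.
#'
#' @param expression_path path to the expression TSV.
#' @param clinical_path path to the clinical TSV.
#' @return a `survival_cohort`.
#' @export
load_cohort <- function(expression_path, clinical_path) {
  expr <- utils::read.delim(expression_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  clin <- utils::read.delim(clinical_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (ncol(expr) < 2L || names(expr)[1L] != "sample_id") {
    stop_cf("expression file must have a leading 'sample_id' column followed by gene columns",
            class = "coxformer_format_error")
  }
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(clin))) {
    stop_cf("clinical file must have columns sample_id, time, event (missing: ",
            paste(setdiff(need, names(clin)), collapse = ", "), ")",
            class = "coxformer_format_error")
  }
  genes <- toupper(trimws(names(expr)[-1L]))
  if (anyDuplicated(genes)) {
    dup <- unique(genes[duplicated(genes)])
    warning("duplicate gene columns, keeping first occurrence: ",
            paste(dup, collapse = ", "))
    keep <- !duplicated(genes)
    expr <- expr[, c(TRUE, keep), drop = FALSE]
    genes <- genes[keep]
  }
  ids_expr <- as.character(expr$sample_id)
  ids_clin <- as.character(clin$sample_id)
  common <- ids_expr[ids_expr %in% ids_clin]  # expression-file order
  if (length(common) == 0L) {
    stop_cf("no overlapping samples between expression and clinical files",
            class = "coxformer_join_error")
  }
  expr <- expr[match(common, ids_expr), , drop = FALSE]
  clin <- clin[match(common, ids_clin), , drop = FALSE]
  X <- as.matrix(expr[, -1L, drop = FALSE])
  survival_cohort(X, common, genes, clin$time, clin$event)
}

#' Write a cohort to expression and clinical TSV files
#'
#' Inverse of [load_cohort()]: values are written in full double precision
#' (`%.17g`) so a write/load round trip reproduces the cohort bit-identically.
#'
#' @param cohort a `survival_cohort`.
#' @param expression_path,clinical_path output paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, expression_path, clinical_path) {
  ed <- data.frame(sample_id = cohort$sample_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  xs <- apply(cohort$X, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(xs))) xs <- matrix(xs, nrow = nrow(cohort$X))
  colnames(xs) <- cohort$genes
  ed <- cbind(ed, as.data.frame(xs, check.names = FALSE))
  utils::write.table(ed, expression_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  cd <- data.frame(sample_id = cohort$sample_ids,
                   time = sprintf("%.17g", cohort$time),
                   event = cohort$event)
  utils::write.table(cd, clinical_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(expression_path, clinical_path))
}

#' Restrict a cohort to a gene signature
#'
#' Keeps the signature genes present in the cohort, in signature order, and
#' reports which signature genes were absent. Mirrors the usual attrition when
#' mapping a marker-gene signature onto an external expression cohort, where
#' only part of the signature is measured.
#'
#' @param cohort a `survival_cohort`.
#' @param sig a [gene_signature()] (or character vector).
#' @return A list with elements `cohort` (the aligned `survival_cohort`),
#'   `report` (data.frame with columns `gene`, `present`), and `retention`
#'   (fraction of signature genes found).
#' @export
align_to_signature <- function(cohort, sig) {
  if (!inherits(sig, "gene_signature")) sig <- gene_signature(sig)
  present <- as.integer(sig %in% cohort$genes)
  kept <- sig[present == 1L]
  if (length(kept) == 0L) {
    stop_cf("no signature genes found in cohort; model would have no features",
            class = "coxformer_validation_error")
  }
  idx <- match(kept, cohort$genes)
  aligned <- survival_cohort(cohort$X[, idx, drop = FALSE],
                             cohort$sample_ids, kept,
                             cohort$time, cohort$event)
  list(cohort = aligned,
       report = data.frame(gene = as.character(sig), present = present,
                           stringsAsFactors = FALSE),
       retention = mean(present))
}

#' Write an alignment report as TSV
#'
#' @param alignment result of [align_to_signature()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_alignment_report <- function(alignment, path) {
  utils::write.table(alignment$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Per-gene standardization fitted on training samples only
#'
#' Estimates per-gene mean and standard deviation on the training rows and
#' returns a `standardizer` that transforms any cohort on the same gene space
#' with those statistics, so held-out folds never leak into the location/scale
#' estimates. Genes constant on the training rows get scale 1 (transformed
#' values 0) rather than dividing by zero.
#'
#' @param cohort a `survival_cohort`.
#' @param train_rows integer (or logical) index of training rows.
#' @return an object of class `standardizer` with fields `genes`, `center`,
#'   `scale`.
#' @export
fit_standardizer <- function(cohort, train_rows = seq_len(nrow(cohort$X))) {
  Xtr <- cohort$X[train_rows, , drop = FALSE]
  if (nrow(Xtr) == 0L) {
    stop_cf("train_rows must be non-empty", class = "coxformer_validation_error")
  }
  center <- colMeans(Xtr)
  scale <- apply(Xtr, 2L, stats::sd)
  if (nrow(Xtr) == 1L) scale[] <- NA_real_
  scale[!is.finite(scale) | scale == 0] <- 1
  structure(list(genes = cohort$genes, center = center, scale = scale),
            class = "standardizer")
}

#' Apply (or invert) a fitted standardizer
#'
#' @param std a `standardizer` from [fit_standardizer()].
#' @param cohort a `survival_cohort` on the same gene space.
#' @param invert undo the transform instead of applying it.
#' @return a transformed `survival_cohort`.
#' @export
apply_standardizer <- function(std, cohort, invert = FALSE) {
  if (!identical(std$genes, cohort$genes)) {
    stop_cf("standardizer gene space does not match the cohort",
            class = "coxformer_validation_error")
  }
  X <- if (invert) {
    sweep(sweep(cohort$X, 2L, std$scale, "*"), 2L, std$center, "+")
  } else {
    sweep(sweep(cohort$X, 2L, std$center, "-"), 2L, std$scale, "/")
  }
  survival_cohort(X, cohort$sample_ids, cohort$genes, cohort$time,
                  cohort$event, require_event = FALSE)
}
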