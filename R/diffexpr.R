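# Count container, TPM normalization, differential-expression calling and
# the reverse-regulated gene set.

#' Gene x sample count matrix with condition labels
#'
#' @param values Nonnegative integer matrix, genes in rows (rownames) and
#'   samples in columns (colnames).
#' @param conditions Named character vector or factor mapping every sample
#'   to one of exactly three conditions (control, disease model, treated).
#' @return An object of class `count_matrix` (a list with `values` and
#'   `conditions`).
#' @export
count_matrix <- function(values, conditions) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must be a matrix with gene rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene identifiers", call. = FALSE)
  if (anyDuplicated(colnames(values))) stop("duplicate sample identifiers", call. = FALSE)
  if (any(!is.finite(values)) || any(values < 0) ||
      any(abs(values - round(values)) > 1e-8)) {
    stop("counts must be finite nonnegative integers", call. = FALSE)
  }
  conditions <- as.character(conditions)[match(colnames(values), names(conditions))]
  if (anyNA(conditions)) {
    stop("every sample must be mapped to a condition", call. = FALSE)
  }
  if (length(unique(conditions)) != 3L) {
    stop("exactly three conditions are required", call. = FALSE)
  }
  structure(list(values = values,
                 conditions = stats::setNames(conditions, colnames(values))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%s)\n",
              nrow(x$values), ncol(x$values),
              paste(sprintf("%s n=%d", names(table(x$conditions)),
                            table(x$conditions)), collapse = ", ")))
  invisible(x)
}

#' TPM normalization
#'
#' Rescales every sample column so its values sum to one million
#' (transcripts per million clean tags). For tag-count data each tag is
#' one transcript, so no length correction is involved.
#'
#' @param counts A [count_matrix()] or a numeric matrix.
#' @return Numeric matrix of the same shape; each column sums to 1e6.
#' @export
normalize_tpm <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$values else counts
  totals <- colSums(m)
  if (any(totals == 0)) {
    stop(sprintf("cannot TPM-normalize all-zero sample(s): %s",
                 paste(colnames(m)[totals == 0], collapse = ", ")),
         call. = FALSE)
  }
  sweep(m, 2, totals, "/") * 1e6
}

#' Differential expression between two conditions
#'
#' Built-in stand-in test on the pluggable DE interface: per-gene log2
#' fold change of mean TPM (pseudocount 1), two-sided p from Welch's
#' unequal-variance t-test on log2(TPM + 1), and Benjamini-Hochberg FDR
#' over all genes. A precomputed table (columns `gene`, `log2fc`,
#' `pvalue`, `fdr`) can be supplied instead via `precomputed` and is
#' ingested verbatim.
#'
#' @param counts A [count_matrix()].
#' @param contrast Character vector `c(numerator, denominator)`, e.g.
#'   `c("disease", "control")` for disease-vs-control.
#' @param precomputed Optional data frame with columns `gene`, `log2fc`,
#'   `pvalue`, `fdr`, returned after validation.
#' @return Data frame with columns `gene`, `log2fc`, `pvalue`, `fdr` and
#'   attribute `contrast` (`"<numerator>_vs_<denominator>"`).
#' @export
test_differential <- function(counts, contrast, precomputed = NULL) {
  label <- paste(contrast, collapse = "_vs_")
  if (!is.null(precomputed)) {
    need <- c("gene", "log2fc", "pvalue", "fdr")
    if (!all(need %in% names(precomputed))) {
      stop("precomputed table must have columns gene, log2fc, pvalue, fdr",
           call. = FALSE)
    }
    bad <- with(precomputed, pvalue < 0 | pvalue > 1 | fdr < 0 | fdr > 1)
    if (any(bad, na.rm = TRUE)) stop("p-values outside [0, 1]", call. = FALSE)
    out <- precomputed[, need]
    attr(out, "contrast") <- label
    return(out)
  }
  stopifnot(inherits(counts, "count_matrix"), length(contrast) == 2L)
  if (!all(contrast %in% counts$conditions)) {
    stop(sprintf("contrast condition(s) absent from condition map: %s",
                 paste(setdiff(contrast, counts$conditions), collapse = ", ")),
         call. = FALSE)
  }
  i1 <- counts$conditions == contrast[1]
  i2 <- counts$conditions == contrast[2]
  if (sum(i1) < 2 || sum(i2) < 2) {
    stop("each contrast condition needs at least 2 samples", call. = FALSE)
  }

  tpm <- normalize_tpm(counts)
  x1 <- tpm[, i1, drop = FALSE]
  x2 <- tpm[, i2, drop = FALSE]
  log2fc <- log2((rowMeans(x1) + 1) / (rowMeans(x2) + 1))

  l1 <- log2(x1 + 1)
  l2 <- log2(x2 + 1)
  n1 <- ncol(l1); n2 <- ncol(l2)
  m1 <- rowMeans(l1); m2 <- rowMeans(l2)
  v1 <- rowSums((l1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((l2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  pvalue <- 2 * pt(-abs(tstat), df)
  # degenerate genes: identical values in both groups carry no evidence
  flat <- se2 == 0
  pvalue[flat & (m1 == m2)] <- 1
  pvalue[flat & (m1 != m2)] <- 0
  allzero <- rowSums(counts$values[, i1 | i2, drop = FALSE]) == 0
  log2fc[allzero] <- 0
  pvalue[allzero] <- 1

  out <- data.frame(gene = rownames(tpm), log2fc = log2fc, pvalue = pvalue,
                    fdr = p.adjust(pvalue, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- label
  out
}

#' Call differentially expressed genes
#'
#' A gene is a DEG when `fdr < fdr_max` and `|log2fc| > abs_log2fc_min`,
#' both strict inequalities.
#'
#' @param table Differential table from [test_differential()].
#' @param fdr_max FDR threshold (default 0.10).
#' @param abs_log2fc_min Absolute log2-fold-change threshold (default 0.58).
#' @return Data frame `gene`, `direction` (`"up"`/`"down"`), `log2fc`, `fdr`.
#' @export
call_degs <- function(table, fdr_max = 0.10, abs_log2fc_min = 0.58) {
  check_number(fdr_max, "fdr_max", lower = 0, upper = 1)
  check_number(abs_log2fc_min, "abs_log2fc_min", lower = 0)
  keep <- table$fdr < fdr_max & abs(table$log2fc) > abs_log2fc_min
  out <- data.frame(gene = table$gene[keep],
                    direction = ifelse(table$log2fc[keep] > 0, "up", "down"),
                    log2fc = table$log2fc[keep],
                    fdr = table$fdr[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "contrast") <- attr(table, "contrast")
  out
}

#' Reverse-regulated gene set
#'
#' Intersects the disease-vs-control and treated-vs-disease DEG sets and
#' keeps genes whose fold changes have opposite signs: these are the genes
#' the treatment pushes back toward the control state. A gene up in
#' disease and down under treatment is labeled `inversely_down`; the
#' mirror case `inversely_up` (labels anchored on the treated-vs-disease
#' direction). Same-sign overlaps are excluded.
#'
#' @param disease_degs Signed DEG set from the disease-vs-control contrast
#'   (output of [call_degs()]).
#' @param treatment_degs Signed DEG set from the treated-vs-disease contrast.
#' @return Data frame `gene`, `direction`
#'   (`"inversely_up"`/`"inversely_down"`).
#' @export
reverse_regulated <- function(disease_degs, treatment_degs) {
  common <- intersect(disease_degs$gene, treatment_degs$gene)
  dd <- disease_degs$direction[match(common, disease_degs$gene)]
  td <- treatment_degs$direction[match(common, treatment_degs$gene)]
  opp <- dd != td
  data.frame(gene = common[opp],
             direction = ifelse(td[opp] == "up", "inversely_up",
                                "inversely_down"),
             row.names = NULL, stringsAsFactors = FALSE)
}
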