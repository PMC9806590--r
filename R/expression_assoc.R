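# Association between gene expression and immune-trigger status of RNA-seq
# samples: tpm binarization, one-sided Fisher exact test, Bonferroni
# correction, significance stars, per-sample z-scores.

#' Construct an expression study
#'
#' @param tpm Non-negative numeric matrix, genes x samples, with row and
#'   column names.
#' @param triggered Named logical vector over the samples: `TRUE` for
#'   immune-triggered or infected samples, `FALSE` for mock/untreated
#'   controls.
#' @param species_id Species the study belongs to.
#' @param study Optional named character/factor giving a study id per sample
#'   (for the stratified test).
#' @return Object of class `expression_study`.
#' @export
expression_study <- function(tpm, triggered, species_id = "unknown",
                             study = NULL) {
  stopifnot(is.matrix(tpm), is.numeric(tpm))
  if (is.null(rownames(tpm)) || is.null(colnames(tpm))) {
    stop("tpm matrix needs gene row names and sample column names")
  }
  if (any(tpm < 0)) stop("tpm values must be non-negative")
  miss <- setdiff(colnames(tpm), names(triggered))
  if (length(miss)) {
    stop("samples without trigger flag: ", paste(miss, collapse = ", "))
  }
  triggered <- triggered[colnames(tpm)]
  if (!is.null(study)) study <- study[colnames(tpm)]
  structure(list(tpm = tpm, triggered = triggered, species_id = species_id,
                 study = study),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study (", x$species_id, "): ", nrow(x$tpm), " genes x ",
      ncol(x$tpm), " samples (", sum(x$triggered), " triggered, ",
      sum(!x$triggered), " control)\n", sep = "")
  invisible(x)
}

#' Read an expression study from TSV files
#'
#' @param tpm_path TSV, first column gene id, remaining columns samples.
#' @param meta_path TSV with columns `sample_id`, `triggered` (0/1) and
#'   optionally `study_id`.
#' @param species_id Species label.
#' @return An `expression_study`.
#' @export
read_expression <- function(tpm_path, meta_path, species_id = "unknown") {
  tab <- utils::read.table(tpm_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  tpm <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(tpm) <- tab[[1L]]
  meta <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "triggered") %in% names(meta)))
  trig <- stats::setNames(as.integer(meta$triggered) > 0L, meta$sample_id)
  study <- if ("study_id" %in% names(meta)) {
    stats::setNames(meta$study_id, meta$sample_id)
  }
  expression_study(tpm, trig, species_id, study)
}

#' Binarize a tpm matrix
#'
#' A gene counts as expressed in a sample iff its tpm is strictly greater
#' than `threshold` (default 0, i.e. any detected transcript).
#'
#' @param tpm Non-negative numeric matrix.
#' @param threshold Non-negative expression threshold.
#' @return Logical matrix of the same shape.
#' @export
binarize_expression <- function(tpm, threshold = 0) {
  stopifnot(is.numeric(tpm), threshold >= 0)
  if (any(tpm < 0)) stop("tpm values must be non-negative")
  tpm > threshold
}

#' One-sided Fisher exact test (enrichment in triggered samples)
#'
#' For a 2x2 table `(a, b, c, d)` with `a` = triggered and expressed, `b` =
#' control and expressed, `c` = triggered and not expressed, `d` = control
#' and not expressed, computes the exact upper hypergeometric tail
#' `P(X >= a)` for `X` drawn with the observed margins, i.e. the one-sided
#' Fisher p-value for expression being more likely in triggered samples.
#' Evaluated in log space via the hypergeometric distribution, accurate to
#' well below 1e-12 relative error for the margins arising here. Degenerate
#' margins (a row or column sum of zero) return `p = 1`, which keeps the
#' number of tests stable under Bonferroni correction.
#'
#' @param contingency Numeric vector `c(a, b, c, d)` of non-negative counts.
#' @return The p-value in (0, 1].
#' @export
fisher_one_sided_greater <- function(contingency) {
  stopifnot(length(contingency) == 4L)
  if (any(contingency < 0)) stop("contingency cells must be non-negative")
  if (any(contingency != round(contingency))) stop("contingency cells must be integers")
  a <- contingency[1L]; b <- contingency[2L]
  cc <- contingency[3L]; d <- contingency[4L]
  if ((a + b) == 0 || (cc + d) == 0 || (a + cc) == 0 || (b + d) == 0) return(1)
  # X ~ Hypergeometric(expressed = a+b, not = c+d, drawn = a+c); upper tail at a
  p <- stats::phyper(a - 1, m = a + b, n = cc + d, k = a + cc,
                     lower.tail = FALSE)
  min(1, max(p, .Machine$double.xmin))
}

#' Bonferroni correction
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param m Number of tests (defaults to `length(p_values)`; must be at
#'   least that).
#' @return Adjusted p-values `min(1, m * p)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p_values)) stop("m must be >= number of tests")
  pmin(1, m * p_values)
}

#' Significance stars for adjusted p-values
#'
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05, `""`
#' otherwise; comparisons are strict, so p = 0.05 earns no star.
#'
#' @param p_adjusted Numeric vector in \[0, 1\].
#' @param alphas Decreasing thresholds for `*`, `**`, `***`.
#' @return Character vector of star strings.
#' @export
significance_stars <- function(p_adjusted, alphas = c(0.05, 0.01, 0.001)) {
  stopifnot(length(alphas) == 3L, all(diff(alphas) < 0))
  if (any(p_adjusted < 0 | p_adjusted > 1)) stop("p-values must lie in [0, 1]")
  vapply(p_adjusted, function(p) {
    if (p < alphas[3L]) "***"
    else if (p < alphas[2L]) "**"
    else if (p < alphas[1L]) "*"
    else ""
  }, "")
}

#' Per-sample z-scores of tpm values
#'
#' Standardizes each sample (column) to mean 0 and unit standard deviation
#' over its genes, using the sample (n - 1 denominator) standard deviation.
#' RNA-seq samples pooled from different studies use different library
#' preparations; per-sample standardization makes expression levels
#' comparable for display. Constant columns become all-zero with a warning.
#'
#' @param tpm Numeric matrix with at least two genes (rows).
#' @return Matrix of z-scores with the same dimnames.
#' @export
zscore_per_sample <- function(tpm) {
  stopifnot(is.matrix(tpm), is.numeric(tpm))
  if (nrow(tpm) < 2L) stop("z-scores need at least two genes per sample")
  z <- tpm
  const <- character()
  for (j in seq_len(ncol(tpm))) {
    s <- stats::sd(tpm[, j])
    if (is.na(s) || s == 0) {
      z[, j] <- 0
      const <- c(const, colnames(tpm)[j])
    } else {
      z[, j] <- (tpm[, j] - mean(tpm[, j])) / s
    }
  }
  if (length(const)) {
    warning("constant sample(s) set to zero z-scores: ",
            paste(const, collapse = ", "))
  }
  z
}

#' Test trigger association for a set of genes
#'
#' For every gene in `gene_subset`, builds the 2x2 table of expressed
#' (tpm > `threshold`) versus trigger status over the study's samples, tests
#' one-sided enrichment in triggered samples with the exact Fisher test, and
#' applies Bonferroni correction with `m` equal to the number of genes
#' tested (the set of candidate genes per species). A two-sided alternative
#' and a per-study stratified test (Cochran-Mantel-Haenszel pooling over the
#' `study` factor) are available but off by default.
#'
#' @param study An `expression_study`.
#' @param gene_subset Genes to test (default: all genes in the study).
#' @param threshold Expression threshold for [binarize_expression()].
#' @param m Bonferroni denominator (default `length(gene_subset)`).
#' @param alternative `"greater"` (enrichment in triggered) or `"two.sided"`.
#' @param stratify_by_study Pool 2x2 tables per study id instead of over all
#'   samples (requires the study factor).
#' @param alphas Star thresholds, passed to [significance_stars()].
#' @return Data frame: `gene_id`, `a`, `b`, `c`, `d`, `p_value`,
#'   `p_adjusted`, `stars`.
#' @export
run_association <- function(study, gene_subset = rownames(study$tpm),
                            threshold = 0, m = length(gene_subset),
                            alternative = c("greater", "two.sided"),
                            stratify_by_study = FALSE,
                            alphas = c(0.05, 0.01, 0.001)) {
  stopifnot(inherits(study, "expression_study"))
  alternative <- match.arg(alternative)
  miss <- setdiff(gene_subset, rownames(study$tpm))
  if (length(miss)) stop("genes not in study: ", paste(miss, collapse = ", "))
  if (sum(study$triggered) == 0L || sum(!study$triggered) == 0L) {
    stop("need at least one triggered and one control sample")
  }
  if (stratify_by_study && is.null(study$study)) {
    stop("stratified test requires per-sample study ids")
  }
  expressed <- binarize_expression(study$tpm[gene_subset, , drop = FALSE],
                                   threshold)
  trig <- study$triggered
  res <- lapply(gene_subset, function(g) {
    e <- expressed[g, ]
    a <- sum(e & trig); b <- sum(e & !trig)
    cc <- sum(!e & trig); d <- sum(!e & !trig)
    p <- if (stratify_by_study) {
      strata <- factor(study$study)
      tab <- table(
        expressed = factor(e, levels = c(TRUE, FALSE)),
        triggered = factor(trig, levels = c(TRUE, FALSE)),
        strata)
      ok <- apply(tab, 3L, sum) > 0
      out <- tryCatch(
        stats::mantelhaen.test(
          tab[, , ok, drop = FALSE], exact = TRUE,
          alternative = if (alternative == "greater") "greater" else "two.sided"
        )$p.value,
        error = function(e) 1)
      min(1, out)
    } else if (alternative == "greater") {
      fisher_one_sided_greater(c(a, b, cc, d))
    } else {
      stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2L, byrow = TRUE))$p.value
    }
    data.frame(gene_id = g, a = a, b = b, c = cc, d = d, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bonferroni(out$p_value, m = max(m, nrow(out)))
  out$stars <- significance_stars(out$p_adjusted, alphas)
  rownames(out) <- NULL
  out
}

#' Write association results to TSV
#'
#' @param results Data frame from [run_association()].
#' @param path Output file.
#' @export
write_association <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(results)
}
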