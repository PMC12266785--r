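#' Log-normalize a TPM matrix
#'
#' Elementwise `log2(TPM + 1)`, the dominant convention for expression-level
#' differential analyses of TPM matrices.
#'
#' @param raw_tpm Non-negative genes-by-samples matrix of TPM values.
#' @return Matrix of the same shape on the log2(TPM + 1) scale.
#' @export
lognorm_tpm <- function(raw_tpm) {
  stopifnot(is.numeric(raw_tpm))
  if (any(raw_tpm < 0, na.rm = TRUE)) stop("TPM values must be >= 0")
  log2(raw_tpm + 1)
}

#' Filter genes by expression prevalence
#'
#' Keeps genes expressed (strictly positive) in at least
#' `ceiling(min_fraction * n_samples)` samples; gene order is preserved.
#' The default retains genes expressed in at least 75% of samples.
#'
#' @param cohort An [expression_cohort()].
#' @param min_fraction Required fraction of samples, in (0, 1].
#' @return The filtered cohort (possibly with zero genes, with a warning).
#' @export
filter_genes <- function(cohort, min_fraction = 0.75) {
  stopifnot(inherits(cohort, "expression_cohort"),
            min_fraction > 0, min_fraction <= 1)
  need <- ceiling(min_fraction * ncol(cohort$expr))
  keep <- rowSums(cohort$expr > 0) >= need
  if (!any(keep)) warning("no genes pass the prevalence filter")
  out <- cohort
  out$expr <- cohort$expr[keep, , drop = FALSE]
  if (!is.null(out$truth) && !is.null(out$truth$archetypes)) {
    out$truth$archetypes <-
      out$truth$archetypes[out$truth$archetypes$gene %in% rownames(out$expr), ,
                           drop = FALSE]
  }
  out
}

#' Empirical-Bayes batch adjustment
#'
#' Removes per-batch location and scale effects with the parametric
#' empirical-Bayes (ComBat) adjustment, protecting the biological covariates
#' in `covariates` (age and sex by default) during standardization. A
#' single-batch cohort is returned unchanged. Genes whose residual variance
#' after the covariate-plus-batch fit is (numerically) zero carry no noise to
#' shrink and are passed through unadjusted.
#'
#' @param cohort An [expression_cohort()] with >= 2 batches of >= 2 samples.
#' @param covariates One-sided formula over columns of `cohort$samples`
#'   naming the biological signal to protect.
#' @param quiet Suppress the adjustment's progress messages.
#' @return The cohort with `expr` replaced by the batch-adjusted matrix
#'   (same genes, samples and ordering).
#' @export
combat_adjust <- function(cohort, covariates = ~ age + sex, quiet = TRUE) {
  stopifnot(inherits(cohort, "expression_cohort"))
  batch <- droplevels(cohort$samples$batch)
  if (nlevels(batch) < 2) {
    message("single batch: nothing to adjust")
    return(cohort)
  }
  if (any(table(batch) < 2)) stop("every batch needs >= 2 samples")
  mod <- model.matrix(covariates, data = cohort$samples)
  full <- cbind(mod, model.matrix(~batch)[, -1, drop = FALSE])
  if (qr(full)$rank < ncol(full)) {
    stop("batch is confounded with the protected covariates; ",
         "the location/scale model is not identifiable")
  }
  n <- ncol(cohort$expr)
  resid_var <- .ols_rss(cohort$expr, full) / (n - ncol(full))
  adjustable <- resid_var > 1e-10
  out <- cohort
  if (any(adjustable)) {
    run <- function() sva::ComBat(dat = cohort$expr[adjustable, , drop = FALSE],
                                  batch = batch, mod = mod)
    out$expr[adjustable, ] <- if (quiet) suppressMessages(run()) else run()
  }
  out
}

#' Batch-correction quality-control report
#'
#' Compares per-batch median expression and the sample-sample Pearson
#' correlation matrix before and after batch adjustment. The summary spread
#' statistic is the range (max - min) of per-batch medians; effective
#' correction shrinks it.
#'
#' @param before,after [expression_cohort()]s with identical genes/samples.
#' @return An object of class `batch_qc`: list with `medians` (batch, state,
#'   median), `cor_before`, `cor_after` and `spread` (named length-2 vector).
#' @export
batch_qc <- function(before, after) {
  stopifnot(inherits(before, "expression_cohort"),
            inherits(after, "expression_cohort"))
  if (!identical(dimnames(before$expr), dimnames(after$expr))) {
    stop("before/after must share genes and samples")
  }
  per_batch_median <- function(cohort) {
    vapply(levels(cohort$samples$batch), function(b) {
      median(cohort$expr[, cohort$samples$batch == b, drop = FALSE])
    }, numeric(1))
  }
  mb <- per_batch_median(before)
  ma <- per_batch_median(after)
  medians <- data.frame(
    batch = rep(names(mb), 2),
    state = rep(c("before", "after"), each = length(mb)),
    median = c(mb, ma), row.names = NULL
  )
  structure(list(
    medians = medians,
    cor_before = cor(before$expr),
    cor_after = cor(after$expr),
    spread = c(before = diff(range(mb)), after = diff(range(ma)))
  ), class = "batch_qc")
}

#' @export
print.batch_qc <- function(x, ...) {
  cat("batch_qc report\n")
  cat("  between-batch median spread: before",
      format(x$spread["before"], digits = 4), "-> after",
      format(x$spread["after"], digits = 4), "\n")
  cat("  per-batch medians:\n")
  print(x$medians, row.names = FALSE)
  invisible(x)
}
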