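# Shared vectorized least-squares machinery -------------------------------

# Residual sum of squares of every row of Y regressed on design X.
.ols_rss <- function(Y, X) {
  Q <- qr.Q(qr(X))
  P <- Y %*% Q
  pmax(rowSums(Y * Y) - rowSums(P * P), 0)
}

# Per-gene OLS with Type II (marginal) F tests for each non-intercept term.
# Y: genes x samples; X: design with intercept in column 1.
.typeII_tests <- function(Y, X) {
  n <- ncol(Y)
  p <- ncol(X)
  df_resid <- n - p
  if (df_resid < 1) stop("no residual degrees of freedom")
  beta <- t(qr.coef(qr(X), t(Y)))
  beta[is.na(beta)] <- 0
  rss_full <- .ols_rss(Y, X)
  terms <- colnames(X)[-1]
  Fs <- Ps <- matrix(NA_real_, nrow(Y), length(terms),
                     dimnames = list(rownames(Y), terms))
  for (k in seq_along(terms)) {
    rss_red <- .ols_rss(Y, X[, -(k + 1), drop = FALSE])
    ss <- pmax(rss_red - rss_full, 0)
    f <- (ss / 1) / (rss_full / df_resid)
    pv <- pf(f, 1, df_resid, lower.tail = FALSE)
    # constant genes (0/0): no evidence, not an error
    degenerate <- is.na(f)
    f[degenerate] <- 0
    pv[degenerate] <- 1
    Fs[, k] <- f
    Ps[, k] <- pv
  }
  list(beta = beta, F = Fs, p = Ps,
       sigma2 = rss_full / df_resid, df_resid = df_resid)
}

# Age / sex linear model ----------------------------------------------------

#' Per-gene linear model of expression on age and sex
#'
#' Fits, for every gene, the ordinary least-squares model
#' \deqn{y_g = \alpha_g + \beta_{1g}\,\mathrm{age} + \beta_{2g}\,\mathrm{sex}
#'   + \varepsilon_g,}
#' tests age and sex with Type II (marginal) sums of squares — SS(age | sex)
#' and SS(sex | age) against the full-model residual — and adjusts the age
#' p-values across genes with the Benjamini-Hochberg step-up procedure.
#' Sex is coded as a 0/1 contrast with the alphabetically first level as
#' reference. Genes with zero variance return `beta_age = 0`, `p_age = 1`.
#'
#' @param cohort An [expression_cohort()] with > 3 samples, both sexes
#'   present, and non-constant age.
#' @return An object of class `age_lm`: list with `table` (per-gene
#'   `gene`, `alpha`, `beta_age`, `beta_sex`, `sigma2`, `F_age`, `F_sex`,
#'   `p_age`, `p_sex`, `q_age`, `direction`), `n`, `df_resid`.
#' @seealso [classify_degs()], [deswan_scan()]
#' @examples
#' coh <- simulate_cohort(40, c(1, 99), archetype_table(10, "linear"),
#'                        noise_sd = 0.3, seed = 7)
#' fit <- fit_age_lm(coh)
#' head(fit$table)
#' @export
fit_age_lm <- function(cohort) {
  stopifnot(inherits(cohort, "expression_cohort"))
  age <- cohort$samples$age
  sex <- droplevels(cohort$samples$sex)
  n <- length(age)
  if (n <= 3) stop("need more than 3 samples")
  if (length(unique(age)) < 2) stop("age is constant")
  if (nlevels(sex) < 2) stop("both sexes must be present")
  X <- cbind("(Intercept)" = 1, age = age,
             sex = as.numeric(sex == levels(sex)[2]))
  ft <- .typeII_tests(cohort$expr, X)
  tab <- data.frame(
    gene = rownames(cohort$expr),
    alpha = ft$beta[, 1],
    beta_age = ft$beta[, "age"],
    beta_sex = ft$beta[, "sex"],
    sigma2 = ft$sigma2,
    F_age = ft$F[, "age"],
    F_sex = ft$F[, "sex"],
    p_age = ft$p[, "age"],
    p_sex = ft$p[, "sex"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  tab$q_age <- bh_adjust(tab$p_age)
  tab$direction <- sign(tab$beta_age)
  structure(list(table = tab, n = n, df_resid = ft$df_resid,
                 sex_reference = levels(sex)[1]),
            class = "age_lm")
}

#' @export
print.age_lm <- function(x, ...) {
  cat("age_lm:", nrow(x$table), "genes,", x$n, "samples (df_resid =",
      paste0(x$df_resid, ")"), "\n")
  cat("  genes with q_age < 0.05:", sum(x$table$q_age < 0.05), "\n")
  invisible(x)
}

#' @export
summary.age_lm <- function(object, q_cut = 0.05, beta_cut = 0.005, ...) {
  d <- classify_degs(object, q_cut = q_cut, beta_cut = beta_cut)
  out <- list(
    n_genes = nrow(object$table),
    n_deg = sum(d$deg),
    n_up = sum(d$deg & d$direction == "up"),
    n_down = sum(d$deg & d$direction == "down"),
    n_enrichment = sum(d$enrichment_eligible),
    q_cut = q_cut, beta_cut = beta_cut
  )
  class(out) <- "summary.age_lm"
  out
}

#' @export
print.summary.age_lm <- function(x, ...) {
  cat("age-associated differential expression (q <", x$q_cut, "strict)\n")
  cat("  DEGs:", x$n_deg, "of", x$n_genes,
      sprintf("(%d up, %d down)", x$n_up, x$n_down), "\n")
  cat("  enrichment-eligible (|beta_age| >", x$beta_cut, "):",
      x$n_enrichment, "\n")
  invisible(x)
}

#' @export
coef.age_lm <- function(object, ...) {
  m <- as.matrix(object$table[, c("alpha", "beta_age", "beta_sex")])
  rownames(m) <- object$table$gene
  m
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjusted p-values (monotone, capped at 1).
#'
#' @param p Numeric vector of p-values in \[0, 1\]; NA/NaN are rejected.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Classify age-associated DEGs
#'
#' A gene is a DEG iff `q_age < q_cut` (strict); DEGs are `"up"` or `"down"`
#' by the sign of `beta_age`. DEGs with `|beta_age| > beta_cut` (strict) are
#' additionally flagged eligible for enrichment analysis.
#'
#' @param fit An [fit_age_lm()] result.
#' @param q_cut Adjusted-p threshold for DEG status (default 0.05).
#' @param beta_cut Absolute-slope threshold (log-expression units per year)
#'   for enrichment eligibility (default 0.005).
#' @return `data.frame` with `gene`, `deg`, `direction`
#'   (`"up"`/`"down"`/`"none"`), `enrichment_eligible`.
#' @export
classify_degs <- function(fit, q_cut = 0.05, beta_cut = 0.005) {
  stopifnot(inherits(fit, "age_lm"))
  tab <- fit$table
  deg <- tab$q_age < q_cut
  data.frame(
    gene = tab$gene,
    deg = deg,
    direction = ifelse(!deg, "none", ifelse(tab$beta_age > 0, "up", "down")),
    enrichment_eligible = deg & abs(tab$beta_age) > beta_cut,
    stringsAsFactors = FALSE
  )
}

#' Write an age-model table as TSV
#'
#' @param fit An `age_lm` object.
#' @param path Output path.
#' @param q_cut,beta_cut Thresholds passed to [classify_degs()].
#' @return Invisibly, `path`.
#' @export
write_age_lm <- function(fit, path, q_cut = 0.05, beta_cut = 0.005) {
  d <- classify_degs(fit, q_cut, beta_cut)
  out <- cbind(fit$table, deg_flag = d$deg, deg_direction = d$direction)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
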