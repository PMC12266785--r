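#' Build a table of gene-trajectory archetypes
#'
#' An archetype describes the noise-free mean log-expression of a gene as a
#' function of donor age and sex. Four kinds are supported, mirroring the
#' trajectory families seen in lifespan PBMC cohorts:
#'
#' * `"flat"` — constant at `baseline`.
#' * `"linear"` — `baseline + slope * age`.
#' * `"saturating"` — a logistic rise (or fall, for negative `amplitude`)
#'   of size `amplitude` centred at `change_age` with scale `half_width`;
#'   captures early-life-rapid-then-plateau shapes.
#' * `"transient"` — an asymmetric difference of logistics: a rapid onset
#'   whose inflection sits exactly at `change_age` (scale `half_width / 4`)
#'   followed by a slow return to baseline (offset inflection at
#'   `change_age + 3 * half_width`, scale `half_width`). The maximal rate of
#'   change is at `change_age`, so a cohort of such genes produces a
#'   sliding-window DEG-count crest at that age (see [deswan_scan()]). A
#'   symmetric bump would instead put crests at its two flanks, because the
#'   window statistic is a box-smoothed derivative of the trajectory.
#'
#' All kinds additionally add `sex_effect` to male samples.
#'
#' @param n Number of genes (rows) to generate.
#' @param kind Archetype kind(s); recycled to length `n`. One of
#'   `"flat"`, `"linear"`, `"saturating"`, `"transient"`.
#' @param baseline Baseline log-expression, recycled.
#' @param slope Slope in log-expression units per year (linear kind).
#' @param change_age Age in years at which saturating/transient genes change.
#' @param half_width Positive width parameter in years.
#' @param amplitude Size of the change in log-expression units.
#' @param sex_effect Additive male-vs-female contrast in log-expression units.
#' @param gene_prefix Prefix for generated gene identifiers.
#'
#' @return A `data.frame` with columns `gene`, `kind`, `baseline`, `slope`,
#'   `change_age`, `half_width`, `amplitude`, `sex_effect`.
#' @examples
#' arch <- archetype_table(3, kind = c("flat", "linear", "transient"))
#' archetype_mean(arch, age = c(10, 50), sex = c("F", "M"))
#' @export
archetype_table <- function(n, kind = "flat", baseline = 5, slope = 0.02,
                            change_age = 40, half_width = 8, amplitude = 1,
                            sex_effect = 0, gene_prefix = "g") {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  kinds <- c("flat", "linear", "saturating", "transient")
  kind <- rep_len(as.character(kind), n)
  bad <- setdiff(unique(kind), kinds)
  if (length(bad)) {
    stop("unknown archetype kind(s): ", paste(bad, collapse = ", "))
  }
  out <- data.frame(
    gene = sprintf("%s%04d", gene_prefix, seq_len(n)),
    kind = kind,
    baseline = rep_len(baseline, n),
    slope = rep_len(slope, n),
    change_age = rep_len(change_age, n),
    half_width = rep_len(half_width, n),
    amplitude = rep_len(amplitude, n),
    sex_effect = rep_len(sex_effect, n),
    stringsAsFactors = FALSE
  )
  validate_archetypes(out)
  out
}

validate_archetypes <- function(archetypes) {
  stopifnot(is.data.frame(archetypes), nrow(archetypes) >= 1)
  req <- c("gene", "kind", "baseline", "slope", "change_age", "half_width",
           "amplitude", "sex_effect")
  miss <- setdiff(req, names(archetypes))
  if (length(miss)) stop("archetype table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(archetypes$gene)) stop("gene ids must be unique")
  if (any(archetypes$half_width <= 0)) stop("half_width must be > 0")
  if (any(!is.finite(archetypes$amplitude))) stop("amplitude must be finite")
  invisible(archetypes)
}

#' Evaluate archetype mean trajectories
#'
#' @param archetypes Archetype table from [archetype_table()].
#' @param age Numeric vector of donor ages in years.
#' @param sex Character/factor vector (`"F"`/`"M"`), same length as `age`.
#' @return A genes-by-samples matrix of noise-free mean log-expression.
#' @export
archetype_mean <- function(archetypes, age, sex) {
  validate_archetypes(archetypes)
  stopifnot(length(age) == length(sex))
  sexm <- as.numeric(as.character(sex) == "M")
  n <- length(age)
  g <- nrow(archetypes)
  out <- matrix(rep(archetypes$baseline, n), g, n) +
    outer(archetypes$sex_effect, sexm)

  idx <- archetypes$kind == "linear"
  if (any(idx)) {
    out[idx, ] <- out[idx, , drop = FALSE] + outer(archetypes$slope[idx], age)
  }
  idx <- archetypes$kind == "saturating"
  if (any(idx)) {
    a <- archetypes[idx, , drop = FALSE]
    t <- outer(-a$change_age, rep(1, n)) + outer(rep(1, sum(idx)), age)
    out[idx, ] <- out[idx, , drop = FALSE] +
      a$amplitude * plogis(t / a$half_width)
  }
  idx <- archetypes$kind == "transient"
  if (any(idx)) {
    a <- archetypes[idx, , drop = FALSE]
    t <- outer(-a$change_age, rep(1, n)) + outer(rep(1, sum(idx)), age)
    onset <- plogis(t / (a$half_width / 4))
    offset <- plogis((t - 3 * a$half_width) / a$half_width)
    out[idx, ] <- out[idx, , drop = FALSE] + a$amplitude * (onset - offset)
  }
  rownames(out) <- archetypes$gene
  out
}
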