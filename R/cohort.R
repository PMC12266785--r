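#' Construct an expression cohort
#'
#' A light container for a genes-by-samples matrix of log2(TPM + 1) values
#' with per-sample metadata (age in whole years, sex, batch, optional group
#' label). All downstream bulk analyses ([fit_age_lm()], [deswan_scan()],
#' [fit_trajectories()], [combat_adjust()]) take this object.
#'
#' @param expr Numeric genes-by-samples matrix with row and column names.
#' @param samples `data.frame` with columns `sample`, `age`, `sex`, `batch`
#'   (and optionally `group`); one row per column of `expr`, same order.
#' @param truth Optional list carried along by the simulator (ground truth).
#' @return An object of class `expression_cohort`: a list with elements
#'   `expr`, `samples` and (optionally) `truth`.
#' @export
expression_cohort <- function(expr, samples, truth = NULL) {
  stopifnot(is.matrix(expr), is.numeric(expr), is.data.frame(samples))
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expr must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(expr))) stop("gene ids must be unique")
  if (anyDuplicated(colnames(expr))) stop("sample ids must be unique")
  req <- c("sample", "age", "sex", "batch")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop("samples lacks columns: ", paste(miss, collapse = ", "))
  if (!identical(as.character(samples$sample), colnames(expr))) {
    stop("samples$sample must match colnames(expr) exactly (same order)")
  }
  if (!all(is.finite(expr))) stop("expr must be finite")
  if (any(samples$age < 1)) stop("age must be >= 1 year")
  samples$sex <- factor(as.character(samples$sex))
  samples$batch <- factor(as.character(samples$batch))
  structure(list(expr = expr, samples = samples, truth = truth),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("expression_cohort:", nrow(x$expr), "genes x", ncol(x$expr), "samples\n")
  cat("  age range:", paste(range(x$samples$age), collapse = "-"),
      " sex:", paste(sprintf("%s=%d", levels(x$samples$sex),
                             tabulate(x$samples$sex)), collapse = " "),
      " batches:", nlevels(x$samples$batch), "\n")
  if (!is.null(x$truth)) cat("  carries simulation ground truth\n")
  invisible(x)
}

#' @export
dim.expression_cohort <- function(x) dim(x$expr)

#' Subset an expression cohort
#'
#' @param x An `expression_cohort`.
#' @param i Gene (row) index. @param j Sample (column) index.
#' @param ... Ignored.
#' @return The subsetted `expression_cohort` (truth dropped).
#' @export
`[.expression_cohort` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$expr))
  if (missing(j)) j <- seq_len(ncol(x$expr))
  expression_cohort(x$expr[i, j, drop = FALSE],
                    droplevels(x$samples[j, , drop = FALSE]))
}

#' Simulate a bulk expression cohort with known ground truth
#'
#' Generates a lifespan cohort on the log2(TPM + 1) scale. Each gene follows
#' its archetype mean (see [archetype_table()]); batch effects are applied in
#' the generative form assumed by empirical-Bayes location/scale batch
#' correction — an additive per-batch offset plus a multiplicative per-batch
#' scale on the noise term:
#' \deqn{y_{gij} = m_g(age_j, sex_j) + \gamma_b + \delta_b \epsilon_{gj},
#'   \quad \epsilon \sim N(0, \sigma^2).}
#'
#' Ages are drawn as whole years (cohort ages are reported in whole years);
#' sexes are a balanced F/M split assigned by seeded permutation; batches are
#' assigned round-robin. Ages, sexes and the noise matrix are drawn before
#' batch parameters are applied, so two calls with the same seed but
#' different batch effects are paired sample-for-sample and noise-for-noise.
#'
#' @param n_samples Number of samples (>= 4).
#' @param age_range Length-2 integer vector within \[1, 100\], low < high.
#' @param archetypes Archetype table from [archetype_table()].
#' @param batch_offsets Numeric vector of per-batch additive offsets; its
#'   length sets the number of batches.
#' @param batch_scales Per-batch noise scales (> 0), recycled to the number
#'   of batches.
#' @param noise_sd Gaussian noise SD in log-expression units (>= 0).
#' @param seed Integer seed.
#' @param age_sampling `"uniform"` draws ages uniformly over the range;
#'   `"even"` spreads them as evenly as possible across the range.
#' @return An [expression_cohort()] whose `truth` element records the
#'   archetype table, batch parameters, `noise_sd` and `seed`.
#' @examples
#' coh <- simulate_cohort(20, c(1, 99), archetype_table(5, "linear"),
#'                        noise_sd = 0.3, seed = 1)
#' coh
#' @export
simulate_cohort <- function(n_samples, age_range = c(1, 99), archetypes,
                            batch_offsets = 0, batch_scales = 1,
                            noise_sd = 0.5, seed = 1L,
                            age_sampling = c("uniform", "even")) {
  age_sampling <- match.arg(age_sampling)
  stopifnot(n_samples >= 4, length(age_range) == 2)
  if (age_range[1] < 1 || age_range[2] > 100 || age_range[1] >= age_range[2]) {
    stop("age_range must be non-degenerate and within [1, 100]")
  }
  validate_archetypes(archetypes)
  n_batch <- length(batch_offsets)
  batch_scales <- rep_len(batch_scales, n_batch)
  if (any(batch_scales <= 0)) stop("batch scales must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")

  set.seed(as.integer(seed))
  ages_avail <- seq.int(age_range[1], age_range[2])
  age <- switch(age_sampling,
    uniform = sample(ages_avail, n_samples, replace = TRUE),
    even = sort(rep_len(ages_avail, n_samples))
  )
  sex <- sample(rep_len(c("F", "M"), n_samples))   # balanced, random order
  g <- nrow(archetypes)
  eps <- matrix(rnorm(g * n_samples, sd = noise_sd), g, n_samples)

  batch <- paste0("B", rep_len(seq_len(n_batch), n_samples))  # round-robin
  b <- match(batch, paste0("B", seq_len(n_batch)))
  m <- archetype_mean(archetypes, age, sex)
  expr <- m +
    matrix(batch_offsets[b], g, n_samples, byrow = TRUE) +
    matrix(batch_scales[b], g, n_samples, byrow = TRUE) * eps
  colnames(expr) <- sprintf("s%03d", seq_len(n_samples))

  samples <- data.frame(
    sample = colnames(expr), age = age, sex = sex, batch = batch,
    stringsAsFactors = FALSE
  )
  expression_cohort(expr, samples, truth = list(
    archetypes = archetypes, batch_offsets = batch_offsets,
    batch_scales = batch_scales, noise_sd = noise_sd, seed = as.integer(seed)
  ))
}

#' Write / read a cohort as TSV
#'
#' The expression matrix is written genes-as-rows (first column `gene`),
#' samples as columns; metadata as a sample/age/sex/batch table. Simulation
#' ground truth, when present, goes to a YAML sidecar next to `meta_path`.
#'
#' @param cohort An `expression_cohort`.
#' @param expr_path,meta_path Output TSV paths.
#' @param truth_path Optional path for the YAML ground-truth sidecar
#'   (default: `meta_path` with a `.truth.yaml` extension when truth exists).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, expr_path, meta_path, truth_path = NULL) {
  stopifnot(inherits(cohort, "expression_cohort"))
  df <- data.frame(gene = rownames(cohort$expr), cohort$expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$samples, meta_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(expr_path, meta_path)
  if (!is.null(cohort$truth)) {
    if (is.null(truth_path)) {
      truth_path <- sub("(\\.tsv)?$", ".truth.yaml", meta_path)[1]
    }
    truth <- cohort$truth
    truth$archetypes <- lapply(truth$archetypes, function(col) unname(col))
    yaml::write_yaml(truth, truth_path)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(expr_path, meta_path) {
  df <- read.delim(expr_path, check.names = FALSE, stringsAsFactors = FALSE)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df[[1]]
  samples <- read.delim(meta_path, stringsAsFactors = FALSE)
  expression_cohort(expr, samples)
}
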