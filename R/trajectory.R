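#' LOESS fit of one gene's expression over age
#'
#' Local polynomial regression (degree 2, tricube weights, no robustness
#' iterations, exact "direct" surface) evaluated on an age grid. A span of
#' 0.75 means each local fit uses the 75% nearest samples.
#'
#' @param x Ages (years). @param y Expression values, same length.
#' @param span LOESS span in (0, 1].
#' @param degree Local polynomial degree (1 or 2).
#' @param grid Prediction grid; defaults to integer years spanning the
#'   observed age range.
#' @return Numeric vector of predictions on `grid` (as attribute `grid`).
#' @export
loess_fit <- function(x, y, span = 0.75, degree = 2, grid = NULL) {
  stopifnot(length(x) == length(y), span > 0, span <= 1)
  if (length(unique(x)) < max(4, degree + 2)) {
    stop("need at least ", max(4, degree + 2), " distinct x values")
  }
  if (is.null(grid)) grid <- seq(floor(min(x)), ceiling(max(x)))
  fit <- loess(y ~ x, data = data.frame(x = x, y = y), span = span,
               degree = degree, family = "gaussian",
               control = loess.control(surface = "direct"))
  pred <- predict(fit, newdata = data.frame(x = grid))
  attr(pred, "grid") <- grid
  pred
}

#' Per-gene LOESS trajectories over age
#'
#' Fits [loess_fit()] to every gene of a cohort and z-scores each predicted
#' curve across the grid (genes with zero curve variance get an all-zero
#' z-curve and are flagged flat).
#'
#' @param cohort An [expression_cohort()].
#' @param span,degree Passed to [loess_fit()].
#' @param grid Age grid; defaults to integer years over the observed range.
#' @return An object of class `trajectory_atlas`: list with `grid`, `pred`
#'   (genes x grid predictions), `z` (z-scored curves), `flat` (logical),
#'   and after [cluster_trajectories()] also `cluster` and `cluster_means`.
#' @export
fit_trajectories <- function(cohort, span = 0.75, degree = 2, grid = NULL) {
  stopifnot(inherits(cohort, "expression_cohort"))
  age <- cohort$samples$age
  if (is.null(grid)) grid <- seq(min(age), max(age))
  pred <- t(vapply(seq_len(nrow(cohort$expr)), function(i) {
    as.numeric(loess_fit(age, cohort$expr[i, ], span = span, degree = degree,
                         grid = grid))
  }, numeric(length(grid))))
  rownames(pred) <- rownames(cohort$expr)
  colnames(pred) <- grid
  sds <- apply(pred, 1, sd)
  # numerically zero curve variance counts as flat
  flat <- sds <= 1e-10 * pmax(1, abs(rowMeans(pred)))
  z <- (pred - rowMeans(pred)) / ifelse(flat, 1, sds)
  z[flat, ] <- 0
  structure(list(grid = grid, pred = pred, z = z, flat = flat,
                 span = span, degree = degree),
            class = "trajectory_atlas")
}

#' @export
print.trajectory_atlas <- function(x, ...) {
  cat("trajectory_atlas:", nrow(x$pred), "genes on ages",
      paste(range(x$grid), collapse = "-"),
      sprintf("(span %.2f, degree %d)", x$span, x$degree), "\n")
  if (!is.null(x$cluster)) {
    cat("  clusters:", paste(sprintf("%s=%d", names(table(x$cluster)),
                                     table(x$cluster)), collapse = " "), "\n")
  }
  invisible(x)
}

#' Hierarchical clustering of trajectory shapes
#'
#' Agglomerative clustering (Euclidean distance on the z-scored curves,
#' complete linkage by default) cut at `k` groups. Following common practice
#' for lifespan trajectory atlases the tree is cut into 6 to 12 groups; `k`
#' is a user decision within `k_range`. Genes flagged flat (zero curve
#' variance, z-score undefined) are set aside in a dedicated cluster `0`
#' before clustering.
#'
#' @param atlas A [fit_trajectories()] result.
#' @param k Number of shape clusters (within `k_range`).
#' @param k_range Allowed inclusive range for `k`; default `c(6, 12)`.
#'   Widen it deliberately for small fixtures.
#' @param linkage `hclust` agglomeration method (default `"complete"`).
#' @return The atlas with added `cluster` (named integer vector; 0 = flat)
#'   and `cluster_means` (cluster-by-grid matrix of mean z-curves).
#' @export
cluster_trajectories <- function(atlas, k, k_range = c(6, 12),
                                 linkage = "complete") {
  stopifnot(inherits(atlas, "trajectory_atlas"))
  if (k < k_range[1] || k > k_range[2]) {
    stop("k = ", k, " outside the allowed range [", k_range[1], ", ",
         k_range[2], "]")
  }
  shaped <- !atlas$flat
  if (sum(shaped) < k) stop("need at least k non-flat genes")
  hc <- hclust(dist(atlas$z[shaped, , drop = FALSE]), method = linkage)
  lab <- integer(nrow(atlas$z))
  names(lab) <- rownames(atlas$z)
  lab[shaped] <- cutree(hc, k = k)
  atlas$cluster <- lab
  atlas$hclust <- hc
  means <- t(vapply(sort(unique(lab)), function(cl) {
    colMeans(atlas$z[lab == cl, , drop = FALSE])
  }, numeric(length(atlas$grid))))
  rownames(means) <- sort(unique(lab))
  atlas$cluster_means <- means
  atlas
}

#' Mean silhouette width across candidate cluster numbers
#'
#' Records, for every `k` in `k_range`, the mean silhouette width of the
#' [cluster_trajectories()] partition — a guide (not a rule) for picking `k`.
#' Requires the `cluster` package.
#'
#' @param atlas A `trajectory_atlas`.
#' @param k_range Inclusive range of `k` values to evaluate.
#' @param linkage Passed to [cluster_trajectories()].
#' @return `data.frame` with columns `k` and `mean_silhouette`.
#' @export
trajectory_silhouettes <- function(atlas, k_range = c(6, 12),
                                   linkage = "complete") {
  if (!requireNamespace("cluster", quietly = TRUE)) {
    stop("the 'cluster' package is required")
  }
  shaped <- !atlas$flat
  d <- dist(atlas$z[shaped, , drop = FALSE])
  ks <- seq(k_range[1], k_range[2])
  sil <- vapply(ks, function(k) {
    a <- cluster_trajectories(atlas, k, k_range = k_range, linkage = linkage)
    mean(cluster::silhouette(a$cluster[shaped], d)[, "sil_width"])
  }, numeric(1))
  data.frame(k = ks, mean_silhouette = sil)
}

#' Plot trajectory clusters
#'
#' One panel overlaying each cluster's mean z-scored curve.
#'
#' @param x A clustered `trajectory_atlas`. @param ... Passed to `matplot`.
#' @export
plot.trajectory_atlas <- function(x, ...) {
  if (is.null(x$cluster_means)) stop("run cluster_trajectories() first")
  graphics::matplot(x$grid, t(x$cluster_means), type = "l", lty = 1,
                    xlab = "age (years)", ylab = "mean z-scored expression",
                    ...)
  legend("topright", legend = rownames(x$cluster_means), bty = "n",
         col = seq_len(nrow(x$cluster_means)), lty = 1, cex = 0.8)
  invisible(x)
}

#' Write trajectory atlas tables as TSV
#'
#' @param atlas A `trajectory_atlas` (clustered or not).
#' @param pred_path Path for the gene-by-grid prediction table.
#' @param labels_path,means_path Optional paths for cluster labels and
#'   cluster mean curves (written only if the atlas is clustered).
#' @return Invisibly, the paths written.
#' @export
write_trajectories <- function(atlas, pred_path, labels_path = NULL,
                               means_path = NULL) {
  df <- data.frame(gene = rownames(atlas$pred), atlas$pred,
                   check.names = FALSE)
  write.table(df, pred_path, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- pred_path
  if (!is.null(atlas$cluster) && !is.null(labels_path)) {
    write.table(data.frame(gene = names(atlas$cluster),
                           cluster = unname(atlas$cluster)),
                labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, labels_path)
  }
  if (!is.null(atlas$cluster_means) && !is.null(means_path)) {
    write.table(data.frame(cluster = rownames(atlas$cluster_means),
                           atlas$cluster_means, check.names = FALSE),
                means_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, means_path)
  }
  invisible(paths)
}
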