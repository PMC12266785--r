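#' Binarize ages around a sliding-window center
#'
#' Samples with age in `[center - half_width, center)` are `"low"`, ages in
#' `[center, center + half_width]` are `"high"`, all others `"excluded"`.
#' The boundary age equal to the center goes to `"high"` (half-open
#' convention, applied consistently across centers).
#'
#' @param ages Numeric vector of ages (years).
#' @param center Window center k (years).
#' @param half_width Window half-width in years (> 0), default 10.
#' @return Character vector in `{"low", "high", "excluded"}`.
#' @export
binarize_age <- function(ages, center, half_width = 10) {
  stopifnot(half_width > 0)
  out <- rep("excluded", length(ages))
  out[ages >= center - half_width & ages < center] <- "low"
  out[ages >= center & ages <= center + half_width] <- "high"
  out
}

#' Sliding-window differential expression along age (DE-SWAN)
#'
#' For every center k on `centers`, samples within `half_width` years are
#' binarized below/above k and each gene is fitted with
#' \deqn{y_g = \alpha_g + \beta_{1g}\,I_k^{low/high} + \beta_{2g}\,
#'   \mathrm{sex} + \varepsilon_g,}
#' the window indicator tested with a Type II F test (adjusted for sex), and
#' p-values BH-adjusted within the center across genes. DEG counts at each
#' q cutoff trace the "wave" curve whose local maxima ([find_crests()],
#' applied to the q < `crest_cutoff` counts after a moving-average smooth of
#' width `crest_smooth`) are the crest ages. Centers where either window
#' side has fewer than `min_per_side` samples, or only one sex, are flagged
#' underpowered and skipped in counting and crest detection.
#'
#' @param cohort A preprocessed [expression_cohort()].
#' @param centers Integer vector of window centers (default 10:90, step 1).
#' @param half_width Window half-width in years (default 10).
#' @param q_cutoffs Adjusted-p cutoffs for the count curves.
#' @param crest_cutoff Which cutoff's count curve drives crest detection.
#' @param crest_smooth Moving-average width for crest detection (odd; 1 = no
#'   smoothing).
#' @param min_per_side Minimum samples required on each window side.
#' @return An object of class `deswan`: list with `centers`, `half_width`,
#'   `beta`/`p`/`q` (gene-by-center matrices), `counts` (long data.frame
#'   center/cutoff/count), `underpowered` (logical per center), `crests`
#'   (numeric crest ages), `smoothed` (smoothed crest-detection curve).
#' @examples
#' arch <- archetype_table(50, c(rep("flat", 40), rep("transient", 10)))
#' coh <- simulate_cohort(120, c(1, 99), arch, noise_sd = 0.5, seed = 3)
#' dw <- deswan_scan(coh, centers = seq(20, 60, 2))
#' dw
#' @export
deswan_scan <- function(cohort, centers = 10:90, half_width = 10,
                        q_cutoffs = c(0.001, 0.01, 0.05),
                        crest_cutoff = 0.05, crest_smooth = 3,
                        min_per_side = 3) {
  stopifnot(inherits(cohort, "expression_cohort"), length(centers) >= 1)
  stopifnot(crest_cutoff %in% q_cutoffs)
  ages <- cohort$samples$age
  sex <- cohort$samples$sex
  g <- nrow(cohort$expr)
  nc <- length(centers)
  beta <- p <- q <- matrix(NA_real_, g, nc,
                           dimnames = list(rownames(cohort$expr), centers))
  underpowered <- logical(nc)
  for (i in seq_len(nc)) {
    lab <- binarize_age(ages, centers[i], half_width)
    keep <- lab != "excluded"
    n_low <- sum(lab == "low")
    n_high <- sum(lab == "high")
    if (n_low < min_per_side || n_high < min_per_side ||
        length(unique(sex[keep])) < 2) {
      underpowered[i] <- TRUE
      next
    }
    sx <- droplevels(factor(sex[keep]))
    X <- cbind("(Intercept)" = 1,
               window = as.numeric(lab[keep] == "high"),
               sex = as.numeric(sx == levels(sx)[2]))
    ft <- .typeII_tests(cohort$expr[, keep, drop = FALSE], X)
    beta[, i] <- ft$beta[, "window"]
    p[, i] <- ft$p[, "window"]
    q[, i] <- bh_adjust(ft$p[, "window"])
  }
  if (all(underpowered)) stop("all centers are underpowered")
  counts <- do.call(rbind, lapply(q_cutoffs, function(cut) {
    data.frame(center = centers, cutoff = cut,
               count = ifelse(underpowered, NA_integer_,
                              colSums(q < cut, na.rm = TRUE)))
  }))
  ok <- !underpowered
  crest_counts <- counts$count[counts$cutoff == crest_cutoff][ok]
  smoothed <- .moving_average(crest_counts, crest_smooth)
  crests <- if (sum(ok) >= 3) {
    find_crests(crest_counts, centers = centers[ok],
                smooth_width = crest_smooth)
  } else {
    numeric(0)   # too few centers for local-maximum detection
  }
  structure(list(centers = centers, half_width = half_width,
                 q_cutoffs = q_cutoffs, crest_cutoff = crest_cutoff,
                 beta = beta, p = p, q = q, counts = counts,
                 underpowered = underpowered, crests = crests,
                 smoothed = setNames(smoothed, centers[ok]),
                 n_genes = g),
            class = "deswan")
}

#' @export
print.deswan <- function(x, ...) {
  cat("deswan:", x$n_genes, "genes,", length(x$centers), "centers (+/-",
      x$half_width, "years)\n")
  if (any(x$underpowered)) {
    cat("  underpowered centers:",
        paste(x$centers[x$underpowered], collapse = " "), "\n")
  }
  cat("  crest ages (q <", x$crest_cutoff, "curve):",
      if (length(x$crests)) paste(x$crests, collapse = ", ") else "none",
      "\n")
  invisible(x)
}

#' Plot DE-SWAN count curves
#'
#' @param x A `deswan` object. @param ... Passed to `plot`.
#' @export
plot.deswan <- function(x, ...) {
  cuts <- sort(unique(x$counts$cutoff), decreasing = TRUE)
  first <- x$counts[x$counts$cutoff == cuts[1], ]
  plot(first$center, first$count, type = "l", xlab = "window center (years)",
       ylab = "number of DEGs", col = 1, ...)
  for (i in seq_along(cuts)[-1]) {
    ci <- x$counts[x$counts$cutoff == cuts[i], ]
    lines(ci$center, ci$count, col = i)
  }
  abline(v = x$crests, lty = 3, col = "grey40")
  legend("topright", legend = paste("q <", cuts), col = seq_along(cuts),
         lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

.moving_average <- function(x, width) {
  if (width <= 1) return(as.numeric(x))
  if (width %% 2 == 0) stop("smooth width must be odd")
  h <- (width - 1) / 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])   # partial windows at the ends
  }, numeric(1))
}

#' Locate crests (local maxima) of a DEG-count curve
#'
#' After an optional moving-average smooth, a crest is a run of equal values
#' strictly greater than both neighbouring values. Endpoint runs qualify if
#' greater than their single neighbour; plateau crests report the plateau's
#' midpoint center (left-of-middle for even-length plateaus, so crest ages
#' always lie on the center grid). A constant curve has no crests.
#'
#' @param count_curve Numeric vector of DEG counts (length >= 3).
#' @param centers Center ages matching `count_curve` (default indices).
#' @param smooth_width Odd moving-average width; 1 (default) = raw curve.
#' @return Numeric vector of crest center ages, with the smoothed curve
#'   heights as attribute `height`.
#' @examples
#' find_crests(c(0, 5, 0))            # middle center
#' find_crests(c(0, 3, 3, 0))         # plateau midpoint
#' find_crests(c(1, 2, 3, 4))         # rising endpoint
#' @export
find_crests <- function(count_curve, centers = seq_along(count_curve),
                        smooth_width = 1) {
  stopifnot(length(count_curve) >= 3,
            length(centers) == length(count_curve))
  y <- .moving_average(count_curve, smooth_width)
  r <- rle(y)
  k <- length(r$values)
  if (k == 1) return(numeric(0))  # constant curve
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  crest_idx <- integer(0)
  heights <- numeric(0)
  for (j in seq_len(k)) {
    left_ok <- j == 1 || r$values[j] > r$values[j - 1]
    right_ok <- j == k || r$values[j] > r$values[j + 1]
    if (left_ok && right_ok) {
      mid <- floor((starts[j] + ends[j]) / 2)
      crest_idx <- c(crest_idx, mid)
      heights <- c(heights, r$values[j])
    }
  }
  structure(centers[crest_idx], height = heights)
}

#' Top DEGs at each crest
#'
#' Genes passing `q < q_cut` and `|beta_window| > beta_cut` (both strict) at
#' each crest center, split into local increase/decrease by the sign of the
#' window coefficient.
#'
#' @param profile A [deswan_scan()] result.
#' @param q_cut Adjusted-p threshold (default 0.01).
#' @param beta_cut Absolute window-coefficient threshold (default 0.5).
#' @param crests Crest centers to report (default `profile$crests`).
#' @return `data.frame` with `center`, `gene`, `beta`, `q`, `direction`
#'   (`"increase"`/`"decrease"`).
#' @export
top_degs <- function(profile, q_cut = 0.01, beta_cut = 0.5, crests = NULL) {
  stopifnot(inherits(profile, "deswan"))
  if (is.null(crests)) crests <- as.numeric(profile$crests)
  out <- lapply(crests, function(k) {
    i <- match(k, profile$centers)
    if (is.na(i)) stop("crest ", k, " is not a scanned center")
    hit <- !is.na(profile$q[, i]) & profile$q[, i] < q_cut &
      abs(profile$beta[, i]) > beta_cut
    if (!any(hit)) return(NULL)
    data.frame(center = k, gene = rownames(profile$q)[hit],
               beta = profile$beta[hit, i], q = profile$q[hit, i],
               direction = ifelse(profile$beta[hit, i] > 0,
                                  "increase", "decrease"),
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(center = numeric(0), gene = character(0),
                      beta = numeric(0), q = numeric(0),
                      direction = character(0))
  }
  out[order(out$center, out$q), , drop = FALSE]
}

#' Write DE-SWAN outputs as TSV
#'
#' @param profile A `deswan` object.
#' @param counts_path Path for the long (center, cutoff, count) table.
#' @param stats_path Optional path for the per-center per-gene statistics.
#' @param crests_path Optional path for the crest list.
#' @return Invisibly, the paths written.
#' @export
write_deswan <- function(profile, counts_path, stats_path = NULL,
                         crests_path = NULL) {
  write.table(profile$counts, counts_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- counts_path
  if (!is.null(stats_path)) {
    long <- data.frame(
      gene = rep(rownames(profile$beta), times = length(profile$centers)),
      center = rep(profile$centers, each = nrow(profile$beta)),
      beta = as.vector(profile$beta),
      p = as.vector(profile$p),
      q = as.vector(profile$q)
    )
    write.table(long, stats_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, stats_path)
  }
  if (!is.null(crests_path)) {
    write.table(data.frame(crest_age = as.numeric(profile$crests),
                           height = attr(profile$crests, "height")),
                crests_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, crests_path)
  }
  invisible(paths)
}
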