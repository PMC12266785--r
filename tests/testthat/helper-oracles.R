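# Independent oracles used to cross-check the package's own computations.

# closed-form OLS via the normal equations
ols_oracle <- function(y, X) {
  drop(solve(t(X) %*% X, t(X) %*% y))
}

# pointwise tricube weighted-least-squares local regression
loess_wls_oracle <- function(x, y, grid, span = 0.75, degree = 2) {
  n <- length(x)
  q <- floor(span * n)
  vapply(grid, function(x0) {
    d <- abs(x - x0)
    h <- sort(d)[min(q, n)]
    w <- (1 - pmin(d / h, 1)^3)^3
    X <- vapply(0:degree, function(p) (x - x0)^p, numeric(n))
    b <- solve(t(X) %*% (w * X), t(X) %*% (w * y))
    b[1]
  }, numeric(1))
}

# exhaustive two-sided rank-sum enumeration
ranksum_enum <- function(a, b) {
  v <- c(a, b)
  na <- length(a)
  r <- rank(v)
  w_obs <- sum(r[seq_len(na)])
  sums <- utils::combn(length(v), na, function(i) sum(r[i]))
  list(w = w_obs,
       p = min(1, 2 * min(mean(sums <= w_obs), mean(sums >= w_obs))))
}

# double-loop Gini
gini_loop <- function(x) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) s <- s + abs(x[i] - x[j])
  s / (2 * n^2 * mean(x))
}

# naive complete-linkage agglomeration to k groups
complete_linkage_oracle <- function(z, k) {
  D <- as.matrix(dist(z))
  groups <- as.list(seq_len(nrow(z)))
  while (length(groups) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(groups)) {
      for (j in seq_len(i - 1)) {
        d <- max(D[groups[[i]], groups[[j]]])
        if (d < best[1]) best <- c(d, j, i)
      }
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
  }
  lab <- integer(nrow(z))
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

same_partition <- function(a, b) {
  identical(outer(a, a, "==") , outer(b, b, "=="))
}

# all partitions of integer n into unordered positive parts
integer_partitions <- function(n, max_part = n) {
  if (n == 0) return(list(integer(0)))
  out <- list()
  for (p in seq_len(min(n, max_part))) {
    for (rest in integer_partitions(n - p, p)) {
      out[[length(out) + 1]] <- c(p, rest)
    }
  }
  out
}

# standard transient-plus-background archetype set used in DE-SWAN checks
deswan_arch <- function(n_genes = 2000, n_transient = 200, change_age = 40,
                        half_width = 8, amplitude = 1) {
  archetype_table(
    n_genes,
    kind = c(rep("flat", n_genes - n_transient),
             rep("transient", n_transient)),
    change_age = change_age, half_width = half_width, amplitude = amplitude
  )
}
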