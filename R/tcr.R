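#' Construct a clonotype table
#'
#' Cell-level clone assignments for TCR repertoire analysis: one row per
#' cell with its clone id, T-cell subtype, sample (donor) and optionally
#' donor age. Only cells annotated as T cells belong here; pass
#' `keep_types` to drop other annotations at construction.
#'
#' @param df `data.frame` with columns `cell`, `clone`, `subtype`, `sample`
#'   and optionally `age`.
#' @param keep_types Optional character vector of admissible (T-cell)
#'   subtype labels; rows with other subtypes are dropped.
#' @return Object of class `clonotype_table` (a validated data.frame).
#' @export
clonotype_table <- function(df, keep_types = NULL) {
  stopifnot(is.data.frame(df))
  req <- c("cell", "clone", "subtype", "sample")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("clonotype table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!is.null(keep_types)) df <- df[df$subtype %in% keep_types, , drop = FALSE]
  if (anyDuplicated(df$cell)) stop("cell ids must be unique")
  if (anyNA(df$clone)) stop("every cell needs exactly one clone id")
  class(df) <- c("clonotype_table", "data.frame")
  df
}

#' Gini coefficient of a clone-size distribution
#'
#' \deqn{G = \sum_i \sum_j |x_i - x_j| / (2 n^2 \bar x)} over clone sizes;
#' 0 for a perfectly even repertoire (and for a single clone).
#'
#' @param clone_sizes Positive integer clone sizes (>= 1 clone).
#' @return Gini coefficient in \[0, 1).
#' @examples
#' gini_coefficient(c(1, 1, 1, 7))  # 0.45
#' @export
gini_coefficient <- function(clone_sizes) {
  stopifnot(length(clone_sizes) >= 1)
  if (any(clone_sizes <= 0)) stop("clone sizes must be > 0")
  n <- length(clone_sizes)
  if (n == 1) return(0)
  x <- sort(as.numeric(clone_sizes))
  # sum_i sum_j |xi - xj| = 2 * sum_i (2i - n - 1) x_(i)
  s <- 2 * sum((2 * seq_len(n) - n - 1) * x)
  s / (2 * n^2 * mean(x))
}

#' Entropy-based clonal-expansion index
#'
#' One minus the Shannon evenness of the clone-frequency distribution:
#' \deqn{1 - H / H_{max}, \quad H = -\sum_i p_i \log_2 p_i, \quad
#'   H_{max} = \log_2(\#clones).}
#' 0 for an all-singleton repertoire; a single-clone repertoire returns 1 by
#' convention (the limit of vanishing evenness; `H_max = 0` leaves the ratio
#' undefined).
#'
#' @param clone_sizes Positive clone sizes.
#' @param log_base Entropy base (default 2; bits).
#' @return Expansion index in \[0, 1\].
#' @examples
#' expansion_index(c(1, 1, 2))  # 1 - 1.5/log2(3)
#' @export
expansion_index <- function(clone_sizes, log_base = 2) {
  stopifnot(length(clone_sizes) >= 1)
  if (any(clone_sizes <= 0)) stop("clone sizes must be > 0")
  k <- length(clone_sizes)
  if (k == 1) return(1)
  p <- clone_sizes / sum(clone_sizes)
  h <- -sum(p * log(p, base = log_base))
  1 - h / log(k, base = log_base)
}

.clone_entropy <- function(counts, log_base = 2) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1) return(0)
  p <- counts / sum(counts)
  -sum(p * log(p, base = log_base))
}

#' Cell-state transition potential of a subtype
#'
#' For every clone with at least one cell in `subtype`, the Shannon entropy
#' (bits) of that clone's cell distribution across all subtypes; the index
#' is the average of these entropies weighted by each clone's cell count
#' within `subtype`. Clones confined to single subtypes give 0.
#'
#' @param table A [clonotype_table()].
#' @param subtype Subtype label (must be present).
#' @param log_base Entropy base (default 2).
#' @return Non-negative entropy (bits by default).
#' @seealso [pairwise_transition()]
#' @export
transition_index <- function(table, subtype, log_base = 2) {
  stopifnot(inherits(table, "clonotype_table"))
  if (!subtype %in% table$subtype) stop("subtype not present: ", subtype)
  tab <- table(table$clone, table$subtype)
  w <- tab[, subtype]
  keep <- w > 0
  if (!any(keep)) return(0)
  ent <- apply(tab[keep, , drop = FALSE], 1, .clone_entropy,
               log_base = log_base)
  sum(w[keep] * ent) / sum(w[keep])
}

#' Pairwise transition index between two subtypes
#'
#' The same entropy computation restricted to the `{a, b}` subtype pair:
#' clones are weighted by their total cell count within the pair, which
#' makes the index symmetric, `pairwise_transition(t, a, b) ==
#' pairwise_transition(t, b, a)`. A clone split 50/50 between the two
#' subtypes contributes 1 bit; clones confined to one side contribute 0.
#'
#' @param table A [clonotype_table()].
#' @param a,b Distinct subtype labels.
#' @param log_base Entropy base (default 2).
#' @return Non-negative entropy (bits by default).
#' @export
pairwise_transition <- function(table, a, b, log_base = 2) {
  stopifnot(inherits(table, "clonotype_table"), a != b)
  sub <- table[table$subtype %in% c(a, b), , drop = FALSE]
  if (!nrow(sub)) return(0)
  tab <- table(sub$clone, factor(sub$subtype, levels = c(a, b)))
  w <- rowSums(tab)
  keep <- w > 0
  ent <- apply(tab[keep, , drop = FALSE], 1, .clone_entropy,
               log_base = log_base)
  sum(w[keep] * ent) / sum(w[keep])
}

#' Repertoire indices per sample and subtype, with age trends
#'
#' Computes, for every (sample, subtype) group, the number of cells and
#' clones, the Gini coefficient, the expansion index, and the within-sample
#' transition index of the subtype. Groups with fewer than 2 clones carry a
#' low-support flag. Indices are computed per donor and never pooled. When
#' donor ages are available a polynomial trend (degree `poly_degree`) of
#' Gini and expansion vs age is fitted per subtype.
#'
#' @param table A [clonotype_table()] (with an `age` column for trends).
#' @param poly_degree Degree of the age-trend polynomial (default 2).
#' @return Object of class `repertoire_summary`: list with `indices` (the
#'   per-group data.frame) and `trends` (per-subtype coefficient table, or
#'   NULL without ages).
#' @export
repertoire_by_group <- function(table, poly_degree = 2) {
  stopifnot(inherits(table, "clonotype_table"))
  groups <- unique(table[, c("sample", "subtype")])
  if (nrow(groups) < 2) stop("need >= 2 (sample, subtype) groups")
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    s <- groups$sample[i]; ty <- groups$subtype[i]
    sub <- table[table$sample == s, , drop = FALSE]
    class(sub) <- c("clonotype_table", "data.frame")
    in_ty <- sub[sub$subtype == ty, , drop = FALSE]
    sizes <- as.numeric(table(in_ty$clone))
    data.frame(
      sample = s, subtype = ty,
      age = if (!is.null(sub$age)) sub$age[1] else NA_real_,
      n_cells = nrow(in_ty), n_clones = length(sizes),
      gini = gini_coefficient(sizes),
      expansion = expansion_index(sizes),
      transition = transition_index(sub, ty),
      low_support = length(sizes) < 2,
      stringsAsFactors = FALSE
    )
  })
  indices <- do.call(rbind, rows)
  trends <- NULL
  if (!all(is.na(indices$age))) {
    trends <- do.call(rbind, lapply(unique(indices$subtype), function(ty) {
      d <- indices[indices$subtype == ty & !is.na(indices$age), ]
      if (nrow(d) <= poly_degree + 1) return(NULL)
      out <- lapply(c("gini", "expansion"), function(metric) {
        cf <- coef(lm(d[[metric]] ~ poly(d$age, poly_degree, raw = TRUE)))
        names(cf) <- paste0("poly", seq_along(cf) - 1)
        cbind(data.frame(subtype = ty, metric = metric,
                         stringsAsFactors = FALSE),
              as.data.frame(as.list(cf)))
      })
      do.call(rbind, out)
    }))
  }
  structure(list(indices = indices, trends = trends),
            class = "repertoire_summary")
}

#' @export
print.repertoire_summary <- function(x, ...) {
  cat("repertoire indices over", nrow(x$indices), "(sample, subtype) groups\n")
  print(head(x$indices, 10), row.names = FALSE)
  if (nrow(x$indices) > 10) cat("  ...\n")
  invisible(x)
}

#' Compare a repertoire index between two named donor groups
#'
#' Two-sided Wilcoxon rank-sum comparison of a per-sample index (e.g. the
#' expansion index of a subtype between frail and healthy advanced-aged
#' donors).
#'
#' @param summary A [repertoire_by_group()] result.
#' @param subtype Subtype to compare.
#' @param samples_a,samples_b Character vectors of sample ids.
#' @param metric `"expansion"`, `"gini"` or `"transition"`.
#' @return `data.frame` with group medians, W statistic and p-value.
#' @export
compare_repertoire <- function(summary, subtype, samples_a, samples_b,
                               metric = c("expansion", "gini", "transition")) {
  stopifnot(inherits(summary, "repertoire_summary"))
  metric <- match.arg(metric)
  d <- summary$indices[summary$indices$subtype == subtype, ]
  va <- d[[metric]][d$sample %in% samples_a]
  vb <- d[[metric]][d$sample %in% samples_b]
  if (!length(va) || !length(vb)) stop("empty comparison group")
  wt <- suppressWarnings(wilcox.test(va, vb, exact = FALSE, correct = FALSE))
  p <- wt$p.value
  if (is.nan(p)) p <- 1   # all values tied: no evidence either way
  data.frame(subtype = subtype, metric = metric,
             median_a = median(va), median_b = median(vb),
             n_a = length(va), n_b = length(vb),
             W = unname(wt$statistic), p = p,
             stringsAsFactors = FALSE)
}

#' Ground-truth parameters for clonotype simulation
#'
#' @param n_cells Named integer vector: sample id -> number of T cells.
#' @param ages Named numeric vector of donor ages (same names), optional.
#' @param subtypes Character vector of subtype labels.
#' @param clone_dist `"geometric"` (sizes `1 + Geom(rate)`, mean `1/rate`)
#'   or `"powerlaw"` (sizes on `1..max_size` with P(s) proportional to
#'   `s^-exponent`).
#' @param rate Geometric success probability per sample (recycled; 1 =
#'   all-singleton repertoire).
#' @param exponent Power-law exponent (recycled).
#' @param max_size Largest clone size for the power-law distribution.
#' @param sharing Subtype-by-subtype matrix; row i gives the probability
#'   that a cell of a clone anchored in subtype i is observed in each
#'   subtype. Identity (default) means no clone sharing across subtypes.
#' @param seed Integer seed.
#' @return List of class `clonotype_truth`.
#' @export
clonotype_truth <- function(n_cells, ages = NULL,
                            subtypes = c("CD4_Treg", "CD8_CTL", "CD8_Tem"),
                            clone_dist = c("geometric", "powerlaw"),
                            rate = 0.5, exponent = 2.5, max_size = 1000,
                            sharing = NULL, seed = 1L) {
  clone_dist <- match.arg(clone_dist)
  stopifnot(all(n_cells >= 1), !is.null(names(n_cells)))
  if (is.null(sharing)) {
    sharing <- diag(length(subtypes))
    dimnames(sharing) <- list(subtypes, subtypes)
  }
  if (any(sharing < 0 | sharing > 1)) stop("sharing probabilities in [0,1]")
  rate <- rep_len(rate, length(n_cells))
  exponent <- rep_len(exponent, length(n_cells))
  if (clone_dist == "geometric" && any(rate <= 0 | rate > 1)) {
    stop("geometric rate must lie in (0, 1]")
  }
  structure(list(n_cells = n_cells, ages = ages, subtypes = subtypes,
                 clone_dist = clone_dist, rate = rate, exponent = exponent,
                 max_size = max_size, sharing = sharing,
                 seed = as.integer(seed)),
            class = "clonotype_truth")
}

#' Simulate a cell-level clonotype table
#'
#' Per sample, clone sizes are drawn from the truth's distribution until the
#' requested cell count is reached (the last clone is truncated to fit);
#' each clone gets an anchor subtype (uniform over subtypes) and each of its
#' cells a subtype drawn from the anchor's row of the sharing matrix. With
#' the identity sharing matrix every clone stays in its anchor subtype.
#'
#' @param truth A [clonotype_truth()].
#' @return A [clonotype_table()] with known ground truth in attribute
#'   `truth`.
#' @export
simulate_clonotypes <- function(truth) {
  stopifnot(inherits(truth, "clonotype_truth"))
  set.seed(truth$seed)
  subtypes <- truth$subtypes
  rows <- list()
  clone_counter <- 0L
  for (si in seq_along(truth$n_cells)) {
    s <- names(truth$n_cells)[si]
    n <- truth$n_cells[[si]]
    sizes <- integer(0)
    while (sum(sizes) < n) {
      draw <- switch(truth$clone_dist,
        geometric = 1L + rgeom(n, prob = truth$rate[si]),
        powerlaw = sample(seq_len(truth$max_size), n, replace = TRUE,
                          prob = seq_len(truth$max_size)^(-truth$exponent[si]))
      )
      sizes <- c(sizes, draw)
    }
    m <- which(cumsum(sizes) >= n)[1]
    sizes <- sizes[seq_len(m)]
    sizes[m] <- sizes[m] - (sum(sizes) - n)  # truncate last clone to fit
    sizes <- sizes[sizes > 0]
    anchor <- sample(subtypes, length(sizes), replace = TRUE)
    cell_subtype <- unlist(lapply(seq_along(sizes), function(ci) {
      pr <- truth$sharing[anchor[ci], ]
      sample(subtypes, sizes[ci], replace = TRUE, prob = pr)
    }))
    clone_ids <- sprintf("cl%05d", clone_counter + rep(seq_along(sizes),
                                                       times = sizes))
    clone_counter <- clone_counter + length(sizes)
    rows[[si]] <- data.frame(
      cell = sprintf("%s_c%05d", s, seq_len(n)),
      clone = clone_ids,
      subtype = cell_subtype,
      sample = s,
      age = if (!is.null(truth$ages)) truth$ages[[s]] else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  out <- clonotype_table(do.call(rbind, rows))
  attr(out, "truth") <- truth
  out
}
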