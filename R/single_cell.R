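#' Construct a cell-level expression matrix
#'
#' Container for cells-by-genes log-normalized expression with per-cell
#' metadata: cell type label, sample (donor) id, donor age and age group.
#'
#' @param expr Numeric cells-by-genes matrix with cell rownames and gene
#'   colnames.
#' @param cells `data.frame` with columns `cell`, `type`, `sample`, and
#'   optionally `age`, `age_group`; one row per row of `expr`, same order.
#'   If `age` is present and `age_group` missing, groups are assigned with
#'   [assign_age_group()].
#' @return Object of class `cell_matrix` (list `expr`, `cells`).
#' @export
cell_matrix <- function(expr, cells) {
  stopifnot(is.matrix(expr), is.numeric(expr), is.data.frame(cells))
  req <- c("cell", "type", "sample")
  miss <- setdiff(req, names(cells))
  if (length(miss)) stop("cells lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cells$cell)) stop("cell ids must be unique")
  if (!identical(as.character(cells$cell), rownames(expr))) {
    stop("cells$cell must match rownames(expr) exactly")
  }
  if (is.null(cells$age_group) && !is.null(cells$age)) {
    cells$age_group <- assign_age_group(cells$age)
  }
  structure(list(expr = expr, cells = cells), class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix:", nrow(x$expr), "cells x", ncol(x$expr), "genes;",
      length(unique(x$cells$type)), "cell types,",
      length(unique(x$cells$sample)), "samples\n")
  invisible(x)
}

#' Assign lifespan age groups
#'
#' The fixed donor age-group vocabulary used throughout the cell-level
#' analyses: child (1-11 years), young (23-58), aged (60-72), advanced-aged
#' (77-100). Frail elderly form a status group assigned by
#' [classify_frailty()], not by age alone. Ages falling in the gaps between
#' bins return `NA`.
#'
#' @param age Numeric vector of donor ages in years.
#' @return Factor with levels `child`, `young`, `aged`, `advanced-aged`,
#'   `frail`.
#' @export
assign_age_group <- function(age) {
  lv <- c("child", "young", "aged", "advanced-aged", "frail")
  out <- rep(NA_character_, length(age))
  out[age >= 1 & age <= 11] <- "child"
  out[age >= 23 & age <= 58] <- "young"
  out[age >= 60 & age <= 72] <- "aged"
  out[age >= 77 & age <= 100] <- "advanced-aged"
  factor(out, levels = lv)
}

#' Simulate a cell-level expression matrix
#'
#' Cells of each type share a log-normal expression profile (normal on the
#' log scale) around `base_mean`; marker genes get per-type additive mean
#' shifts on the log scale. Cells are allocated to donors round-robin and
#' to types by a balanced seeded permutation, so both compositions are
#' balanced without confounding type with donor.
#'
#' @param n_cells Number of cells (>= 10).
#' @param cell_types Character vector of >= 2 type labels.
#' @param markers Optional `data.frame(type, gene, shift)` of marker
#'   mean-shifts (log units); genes must exist in the gene universe.
#' @param n_genes Size of the gene universe (gene ids `g001`...), or a
#'   character vector of gene names to use directly.
#' @param base_mean,base_sd Log-scale mean and SD of background expression.
#' @param sample_ages Named numeric vector: donor id -> age (years).
#' @param seed Integer seed; identical seeds give bit-identical matrices.
#' @return A [cell_matrix()].
#' @export
simulate_single_cell <- function(n_cells, cell_types, markers = NULL,
                                 n_genes = 100, base_mean = 1, base_sd = 0.5,
                                 sample_ages = c(d1 = 30, d2 = 70),
                                 seed = 1L) {
  stopifnot(n_cells >= 10, length(cell_types) >= 2)
  genes <- if (is.character(n_genes)) n_genes
           else sprintf("g%03d", seq_len(n_genes))
  if (!is.null(markers)) {
    missing_genes <- setdiff(markers$gene, genes)
    if (length(missing_genes)) {
      stop("marker genes absent from gene universe: ",
           paste(missing_genes, collapse = ", "))
    }
    if (!all(markers$type %in% cell_types)) stop("unknown marker cell type")
  }
  set.seed(as.integer(seed))
  type <- sample(rep_len(cell_types, n_cells))
  donor <- rep_len(names(sample_ages), n_cells)
  mu <- matrix(base_mean, n_cells, length(genes),
               dimnames = list(NULL, genes))
  if (!is.null(markers)) {
    for (i in seq_len(nrow(markers))) {
      mu[type == markers$type[i], markers$gene[i]] <-
        mu[type == markers$type[i], markers$gene[i]] + markers$shift[i]
    }
  }
  expr <- mu + matrix(rnorm(n_cells * length(genes), sd = base_sd),
                      n_cells, length(genes))
  rownames(expr) <- sprintf("c%05d", seq_len(n_cells))
  cells <- data.frame(
    cell = rownames(expr), type = type, sample = donor,
    age = unname(sample_ages[donor]), stringsAsFactors = FALSE
  )
  cell_matrix(expr, cells)
}

#' Per-cell gene-set score with binned control genes
#'
#' The score of a cell is the mean expression of the gene set minus the mean
#' expression of a control set matched on overall expression level: genes
#' are binned into `n_bins` equal-size bins by their dataset-average
#' expression, and for each set gene `ctrl_size` control genes are sampled
#' (without replacement, seeded, set genes excluded) from its bin; the
#' control set is the union of the samples. The default set is the 20-gene
#' SASP signature [sasp_genes].
#'
#' @param cells A [cell_matrix()].
#' @param gene_set Character vector of gene names; genes absent from the
#'   matrix are dropped (error if all are absent).
#' @param n_bins Number of expression bins (>= 2), default 25.
#' @param ctrl_size Control genes sampled per set gene, default 50.
#' @param seed Integer seed for control sampling.
#' @param control_pool Optional explicit control gene vector overriding the
#'   binned sampling (e.g. for self-consistency checks).
#' @return Named numeric vector of per-cell scores with attributes
#'   `gene_set`, `controls`, `n_bins`, `ctrl_size`, `seed`.
#' @export
score_gene_set <- function(cells, gene_set = sasp_genes, n_bins = 25,
                           ctrl_size = 50, seed = 0L, control_pool = NULL) {
  stopifnot(inherits(cells, "cell_matrix"), n_bins >= 2)
  genes <- colnames(cells$expr)
  present <- intersect(gene_set, genes)
  if (!length(present)) {
    stop("gene set entirely absent from the matrix; missing: ",
         paste(gene_set, collapse = ", "))
  }
  if (is.null(control_pool)) {
    avg <- colMeans(cells$expr)
    n_bins_eff <- min(n_bins, length(genes))
    bin <- as.integer(cut(rank(avg, ties.method = "first"), n_bins_eff))
    names(bin) <- genes
    set.seed(as.integer(seed))
    control_pool <- unique(unlist(lapply(present, function(gs) {
      cand <- setdiff(genes[bin == bin[gs]], present)
      if (!length(cand)) return(character(0))
      sample(cand, min(ctrl_size, length(cand)))
    })))
    if (!length(control_pool)) control_pool <- present  # degenerate universe
  } else {
    control_pool <- intersect(control_pool, genes)
  }
  score <- rowMeans(cells$expr[, present, drop = FALSE]) -
    rowMeans(cells$expr[, control_pool, drop = FALSE])
  structure(score, gene_set = present, controls = control_pool,
            n_bins = n_bins, ctrl_size = ctrl_size, seed = seed)
}

# Exact two-sided rank-sum p by exhaustive enumeration of group assignments.
.ranksum_exact_p <- function(r, na) {
  w <- sum(r[seq_len(na)])
  sums <- combn(r, na, sum)
  p <- 2 * min(mean(sums <= w), mean(sums >= w))
  min(1, p)
}

#' Rank-sum differential expression between two cell groups
#'
#' Per-gene two-sided Wilcoxon rank-sum test of group A vs group B, with
#' midranks and the tie-corrected normal approximation; when both groups
#' have at most `exact_max` cells the p-value is computed by exhaustive
#' enumeration of group assignments instead. P-values are BH-adjusted across
#' genes. The log2 fold change follows the usual single-cell convention on
#' log-normalized data:
#' `log2((expm1(mean_A) + 1e-9) / (expm1(mean_B) + 1e-9))`.
#' A gene is a DEG iff `q < q_cut` and `log2FC > lfc_cut` (both strict).
#'
#' @param cells A [cell_matrix()].
#' @param group_a,group_b Logical vectors over cells, integer indices, or
#'   character cell ids; >= 3 cells each, disjoint.
#' @param q_cut,lfc_cut DEG thresholds (defaults 0.05 and 0.25).
#' @param exact_max Largest per-group size for exact enumeration.
#' @return `data.frame` with `gene`, `w` (rank sum of group A), `p`, `q`,
#'   `log2fc`, `deg`.
#' @export
rank_sum_de <- function(cells, group_a, group_b, q_cut = 0.05,
                        lfc_cut = 0.25, exact_max = 10) {
  stopifnot(inherits(cells, "cell_matrix"))
  resolve <- function(sel) {
    if (is.character(sel)) return(match(sel, cells$cells$cell))
    if (is.logical(sel)) return(which(sel))
    as.integer(sel)
  }
  ia <- resolve(group_a)
  ib <- resolve(group_b)
  if (anyNA(ia) || anyNA(ib)) stop("unknown cell ids in selector")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  na <- length(ia)
  nb <- length(ib)
  if (na < 3 || nb < 3) stop("each group needs at least 3 cells")
  n <- na + nb
  exact <- na <= exact_max && nb <= exact_max
  genes <- colnames(cells$expr)
  res <- vapply(genes, function(g) {
    v <- c(cells$expr[ia, g], cells$expr[ib, g])
    r <- rank(v)
    w <- sum(r[seq_len(na)])
    if (exact) {
      p <- .ranksum_exact_p(r, na)
    } else {
      ties <- table(v)
      tie_term <- sum(ties^3 - ties) / (n * (n - 1))
      v_w <- na * nb / 12 * ((n + 1) - tie_term)
      if (v_w <= 0) {
        p <- 1
      } else {
        z <- (w - na * (n + 1) / 2) / sqrt(v_w)
        p <- 2 * pnorm(-abs(z))
      }
    }
    ma <- mean(cells$expr[ia, g])
    mb <- mean(cells$expr[ib, g])
    lfc <- log2((expm1(ma) + 1e-9) / (expm1(mb) + 1e-9))
    c(w = w, p = p, log2fc = lfc)
  }, numeric(3))
  out <- data.frame(gene = genes, w = res["w", ], p = res["p", ],
                    q = bh_adjust(res["p", ]), log2fc = res["log2fc", ],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$deg <- out$q < q_cut & out$log2fc > lfc_cut
  out
}

#' Cell-type proportion vs donor age
#'
#' Per sample, the fraction of cells of each type; per type, the Pearson
#' correlation of that fraction with donor age, flags for |PCC| above 0.2
#' and 0.4, and a least-squares polynomial trend (degree 2 by default).
#' Types with zero variance in proportion get PCC 0 with a flag; types
#' absent from more than half the samples are flagged sparse.
#'
#' @param cells A [cell_matrix()] whose metadata carries donor `age`.
#' @param poly_degree Degree of the polynomial age trend.
#' @return Object of class `prop_age`: list with `props` (sample-by-type
#'   fraction matrix), `ages` (per sample), and `table` (per-type `pcc`,
#'   `abs_gt_0.2`, `abs_gt_0.4`, `zero_variance`, `sparse`, and polynomial
#'   coefficients `poly0..polyd`).
#' @export
proportion_age_correlation <- function(cells, poly_degree = 2) {
  stopifnot(inherits(cells, "cell_matrix"))
  meta <- cells$cells
  if (is.null(meta$age)) stop("cell metadata must carry donor age")
  samples <- unique(meta$sample)
  if (length(samples) < 4) stop("need >= 4 samples with known donor age")
  types <- sort(unique(meta$type))
  props <- t(vapply(samples, function(s) {
    tab <- table(factor(meta$type[meta$sample == s], levels = types))
    as.numeric(tab) / sum(tab)
  }, numeric(length(types))))
  dimnames(props) <- list(samples, types)
  ages <- vapply(samples, function(s) meta$age[meta$sample == s][1],
                 numeric(1))
  sparse <- colSums(props > 0) < length(samples) / 2
  if (any(sparse)) {
    warning("cell type(s) absent from more than half the samples: ",
            paste(types[sparse], collapse = ", "))
  }
  rows <- lapply(types, function(ty) {
    fr <- props[, ty]
    zv <- sd(fr) == 0
    pcc <- if (zv) 0 else cor(fr, ages)
    cf <- coef(lm(fr ~ poly(ages, poly_degree, raw = TRUE)))
    names(cf) <- paste0("poly", seq_along(cf) - 1)
    cbind(data.frame(type = ty, pcc = pcc,
                     abs_gt_0.2 = abs(pcc) > 0.2,
                     abs_gt_0.4 = abs(pcc) > 0.4,
                     zero_variance = zv, sparse = sparse[ty],
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(cf)))
  })
  structure(list(props = props, ages = ages,
                 table = do.call(rbind, rows)),
            class = "prop_age")
}

#' @export
print.prop_age <- function(x, ...) {
  cat("cell-type proportion vs age over", nrow(x$props), "samples\n")
  print(x$table[, c("type", "pcc", "abs_gt_0.2", "abs_gt_0.4")],
        row.names = FALSE)
  invisible(x)
}

#' Rockwood-style frailty index
#'
#' Proportion of health deficits present out of deficits assessed.
#'
#' @param deficits_present,deficits_assessed Non-negative counts
#'   (`deficits_assessed > 0`).
#' @return Numeric index in \[0, 1\].
#' @export
frailty_index <- function(deficits_present, deficits_assessed) {
  if (any(deficits_assessed <= 0)) stop("deficits_assessed must be > 0")
  if (any(deficits_present < 0 | deficits_present > deficits_assessed)) {
    stop("deficits_present must lie in [0, deficits_assessed]")
  }
  deficits_present / deficits_assessed
}

#' Classify donors as frail
#'
#' A donor is frail iff older than 65 years AND the frailty index exceeds
#' 0.2 (both strict inequalities).
#'
#' @param age Donor ages in years.
#' @param index Frailty indices in \[0, 1\] (see [frailty_index()]).
#' @return Factor with levels `non-frail`, `frail`.
#' @export
classify_frailty <- function(age, index) {
  stopifnot(length(age) == length(index))
  if (any(index < 0 | index > 1)) stop("index must lie in [0, 1]")
  factor(ifelse(age > 65 & index > 0.2, "frail", "non-frail"),
         levels = c("non-frail", "frail"))
}
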