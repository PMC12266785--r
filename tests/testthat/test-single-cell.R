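test_that("age groups follow the lifespan bins with gaps", {
  expect_equal(as.character(assign_age_group(c(1, 11, 23, 58, 60, 72, 77,
                                               100))),
               c("child", "child", "young", "young", "aged", "aged",
                 "advanced-aged", "advanced-aged"))
  expect_true(all(is.na(assign_age_group(c(15, 59, 75)))))
})

test_that("gene-set score is zero under self-control and zero input", {
  cells <- simulate_single_cell(30, c("T", "B"), n_genes = 50, seed = 41)
  gs <- sprintf("g%03d", 1:5)
  s <- score_gene_set(cells, gs, control_pool = gs)
  expect_true(all(s == 0))
  zero <- cells
  zero$expr[] <- 0
  expect_true(all(score_gene_set(zero, gs, n_bins = 5, ctrl_size = 5,
                                 seed = 1) == 0))
  expect_error(score_gene_set(cells, c("nope1", "nope2")), "absent")
})

test_that("scores match a brute-force two-mean oracle", {
  cells <- simulate_single_cell(30, c("T", "B"), n_genes = 80, seed = 42)
  gs <- sprintf("g%03d", c(3, 17, 40, 66))
  s <- score_gene_set(cells, gs, n_bins = 8, ctrl_size = 10, seed = 7)
  ctrl <- attr(s, "controls")
  oracle <- vapply(seq_len(nrow(cells$expr)), function(i) {
    set_mean <- 0
    for (g in gs) set_mean <- set_mean + cells$expr[i, g]
    ctrl_mean <- 0
    for (g in ctrl) ctrl_mean <- ctrl_mean + cells$expr[i, g]
    set_mean / length(gs) - ctrl_mean / length(ctrl)
  }, numeric(1))
  expect_equal(unname(as.numeric(s)), oracle, tolerance = 1e-10)
  # control pool excludes the set and is reproducible under the seed
  expect_length(intersect(ctrl, gs), 0)
  s2 <- score_gene_set(cells, gs, n_bins = 8, ctrl_size = 10, seed = 7)
  expect_identical(as.numeric(s), as.numeric(s2))
})

test_that("bin-matched controls make scores shift-consistent", {
  cells <- simulate_single_cell(20, c("T", "B"), n_genes = 60, seed = 43)
  gs <- sprintf("g%03d", 1:4)
  s1 <- score_gene_set(cells, gs, n_bins = 6, ctrl_size = 8, seed = 2)
  shifted <- cells
  shifted$expr <- cells$expr + 5   # same bins, same controls, same score
  s2 <- score_gene_set(shifted, gs, n_bins = 6, ctrl_size = 8, seed = 2)
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-12)
})

test_that("rank-sum DE is null on duplicated groups", {
  cells <- simulate_single_cell(20, c("T", "B"), n_genes = 15, seed = 44)
  dup_expr <- rbind(cells$expr[1:10, ], cells$expr[1:10, ])
  rownames(dup_expr) <- sprintf("c%05d", 1:20)
  meta <- data.frame(cell = rownames(dup_expr), type = rep(c("A", "B"),
                                                           each = 10),
                     sample = "d1", age = 50)
  dup <- cell_matrix(dup_expr, meta)
  de <- rank_sum_de(dup, 1:10, 11:20)
  expect_true(all(de$p == 1))
  expect_false(any(de$deg))
})

test_that("small groups use exact enumeration matching the oracle", {
  set.seed(45)
  a <- rnorm(5) + 10   # completely separated from b
  b <- rnorm(5)
  expr <- matrix(c(a, b), ncol = 1, dimnames = list(sprintf("c%05d", 1:10),
                                                    "g1"))
  cells <- cell_matrix(expr, data.frame(cell = rownames(expr),
                                        type = rep(c("A", "B"), each = 5),
                                        sample = "d1", age = 50))
  de <- rank_sum_de(cells, 1:5, 6:10)
  en <- ranksum_enum(a, b)
  expect_equal(de$w, en$w)
  expect_equal(de$p, 2 / 252)
  expect_equal(de$p, en$p)
  # agreement with the classical exact test on untied data
  wt <- wilcox.test(a, b, exact = TRUE)
  expect_equal(de$p, wt$p.value, tolerance = 1e-12)
})

test_that("rank-sum p-values are invariant to monotone transforms", {
  cells <- simulate_single_cell(24, c("T", "B"), n_genes = 10, seed = 46)
  g_a <- cells$cells$type == "T"
  g_b <- cells$cells$type == "B"
  de1 <- rank_sum_de(cells, g_a, g_b)
  mono <- cells
  mono$expr <- exp(cells$expr / 2)
  de2 <- rank_sum_de(mono, g_a, g_b)
  expect_equal(de1$p, de2$p, tolerance = 1e-12)
  expect_equal(de1$w, de2$w)
})

test_that("the DEG flag requires both q and log2FC thresholds", {
  # craft two genes: clear separation below the lfc cutoff, and above it
  n <- 40
  set.seed(47)
  jitter <- rnorm(n, sd = 0.01)
  expr <- cbind(g1 = 1 + rep(c(0, 0.1), each = n / 2) + jitter,
                g2 = 1 + rep(c(0, 2), each = n / 2) + jitter)
  rownames(expr) <- sprintf("c%05d", 1:n)
  cells <- cell_matrix(expr, data.frame(cell = rownames(expr),
                                        type = rep(c("A", "B"),
                                                   each = n / 2),
                                        sample = "d1", age = 50))
  de <- rank_sum_de(cells, (n / 2 + 1):n, 1:(n / 2))
  expect_true(all(de$q < 0.05))
  g1 <- de[de$gene == "g1", ]
  expect_lt(g1$log2fc, 0.25)
  expect_false(g1$deg)            # significant but below the fold cutoff
  expect_true(de$deg[de$gene == "g2"])
  expect_error(rank_sum_de(cells, 1:2, 3:40), "at least 3")
})

test_that("proportions correlate with age as constructed", {
  # build cells whose type-A fraction is exactly linear in age
  ages <- c(10, 20, 30, 40, 50, 60, 70, 80)
  frac_a <- ages / 100
  rows <- do.call(rbind, lapply(seq_along(ages), function(i) {
    n_a <- round(20 * frac_a[i])
    data.frame(cell = sprintf("s%d_c%02d", i, 1:20),
               type = c(rep("A", n_a), rep("B", 20 - n_a)),
               sample = paste0("d", i), age = ages[i])
  }))
  expr <- matrix(0, nrow(rows), 3,
                 dimnames = list(rows$cell, c("g1", "g2", "g3")))
  cells <- cell_matrix(expr, rows)
  pa <- proportion_age_correlation(cells)
  expect_equal(unname(rowSums(pa$props)), rep(1, length(ages)),
               tolerance = 1e-12)
  expect_equal(pa$table$pcc[pa$table$type == "A"], 1, tolerance = 1e-12)
  expect_true(pa$table$abs_gt_0.4[pa$table$type == "A"])
  # permutation null: observed |PCC| = 1 is never beaten
  obs <- 1
  set.seed(48)
  perm <- replicate(1000, abs(cor(frac_a, sample(ages))))
  expect_lt(mean(perm >= obs) , 0.01)
})

test_that("constant proportions get the zero-variance convention", {
  rows <- do.call(rbind, lapply(1:4, function(i) {
    data.frame(cell = sprintf("s%d_c%02d", i, 1:10),
               type = rep(c("A", "B"), each = 5),
               sample = paste0("d", i), age = c(20, 40, 60, 80)[i])
  }))
  expr <- matrix(0, nrow(rows), 2, dimnames = list(rows$cell, c("g1", "g2")))
  pa <- proportion_age_correlation(cell_matrix(expr, rows))
  expect_true(all(pa$table$pcc == 0))
  expect_true(all(pa$table$zero_variance))
})

test_that("frailty classification matches the deficit-accumulation rule", {
  grid <- expand.grid(age = c(60, 66, 70), index = c(0.15, 0.20, 0.25))
  got <- classify_frailty(grid$age, grid$index)
  want <- with(grid, ifelse(age > 65 & index > 0.2, "frail", "non-frail"))
  expect_equal(as.character(got), want)
  # both inequalities are strict
  expect_equal(as.character(classify_frailty(70, 0.20)), "non-frail")
  expect_equal(as.character(classify_frailty(65, 0.50)), "non-frail")
  expect_equal(as.character(classify_frailty(66, 0.21)), "frail")
  expect_equal(frailty_index(3, 12), 0.25)
  expect_error(frailty_index(1, 0), "assessed")
  expect_error(classify_frailty(70, 1.2), "0, 1")
})
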