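test_that("archetype table validates its invariants", {
  expect_error(archetype_table(2, kind = "wiggly"), "unknown archetype")
  expect_error(archetype_table(2, half_width = 0), "half_width")
  expect_error(archetype_table(2, amplitude = Inf), "amplitude")
  arch <- archetype_table(3, kind = c("flat", "linear", "transient"))
  expect_equal(nrow(arch), 3)
  expect_false(anyDuplicated(arch$gene) > 0)
})

test_that("transient archetype changes fastest at change_age", {
  arch <- archetype_table(1, kind = "transient", change_age = 40,
                          half_width = 8)
  ages <- 1:99
  m <- archetype_mean(arch, ages, rep("F", length(ages)))[1, ]
  d <- diff(m)
  # steepest one-year rise brackets the onset inflection at 40
  expect_true(which.max(d) %in% c(39, 40))
  expect_lt(m[1], 0.05 + arch$baseline)          # starts near baseline
  expect_lt(m[99], 0.25 + arch$baseline)         # returns toward baseline
})

test_that("zero-noise flat cohort reproduces baselines exactly", {
  arch <- archetype_table(5, kind = "flat", baseline = 2.5, sex_effect = 0)
  coh <- simulate_cohort(12, c(1, 99), arch, noise_sd = 0, seed = 1)
  expect_true(all(coh$expr == 2.5))
})

test_that("noiseless linear cohort yields the exact slope by OLS", {
  arch <- archetype_table(2, kind = "linear", slope = 0.02)
  coh <- simulate_cohort(24, c(1, 99), arch, noise_sd = 0, seed = 2)
  X <- cbind(1, coh$samples$age)
  for (g in 1:2) {
    b <- ols_oracle(coh$expr[g, ], X)
    expect_equal(b[2], 0.02, tolerance = 1e-10)
  }
})

test_that("OLS slope estimates are unbiased across replicate cohorts", {
  arch <- archetype_table(1, kind = "linear", slope = 0.02)
  est <- vapply(1:50, function(s) {
    coh <- simulate_cohort(180, c(1, 99), arch, noise_sd = 0.5, seed = s)
    ols_oracle(coh$expr[1, ], cbind(1, coh$samples$age))[2]
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.02), 2 * se)
})

test_that("cohort generation is reproducible and validates preconditions", {
  arch <- archetype_table(4, kind = "linear")
  a <- simulate_cohort(10, c(1, 50), arch, seed = 42)
  b <- simulate_cohort(10, c(1, 50), arch, seed = 42)
  expect_identical(a$expr, b$expr)
  expect_identical(a$samples, b$samples)
  expect_error(simulate_cohort(3, c(1, 50), arch), "n_samples")
  expect_error(simulate_cohort(10, c(30, 30), arch), "age_range")
  expect_error(simulate_cohort(10, c(0, 50), arch), "age_range")
})

test_that("sexes are balanced and ages cover the requested range", {
  arch <- archetype_table(2)
  coh <- simulate_cohort(101, c(1, 99), arch, seed = 3)
  tab <- table(coh$samples$sex)
  expect_lte(abs(tab[["F"]] - tab[["M"]]), 1)
  expect_lt(min(coh$samples$age), 12)
  expect_gt(max(coh$samples$age), 88)
  expect_true(all(coh$samples$age == round(coh$samples$age)))
})

test_that("same seed pairs batch-affected and batch-free cohorts", {
  arch <- archetype_table(10, kind = "linear")
  with_b <- simulate_cohort(30, c(1, 99), arch, batch_offsets = c(0, 3),
                            batch_scales = c(1, 2), noise_sd = 0.4, seed = 9)
  no_b <- simulate_cohort(30, c(1, 99), arch, batch_offsets = c(0, 0),
                          noise_sd = 0.4, seed = 9)
  expect_identical(with_b$samples, no_b$samples)
  b2 <- with_b$samples$batch == "B2"
  m <- archetype_mean(arch, with_b$samples$age, with_b$samples$sex)
  recovered <- m + (with_b$expr - m -
                      3 * matrix(b2, nrow(m), ncol(m), byrow = TRUE)) /
    matrix(ifelse(b2, 2, 1), nrow(m), ncol(m), byrow = TRUE)
  expect_equal(unname(recovered), unname(no_b$expr), tolerance = 1e-12)
})

test_that("single-cell simulation is seeded and checks markers", {
  a <- simulate_single_cell(30, c("T", "B"), seed = 5)
  b <- simulate_single_cell(30, c("T", "B"), seed = 5)
  expect_identical(a$expr, b$expr)
  expect_error(
    simulate_single_cell(30, c("T", "B"),
                         markers = data.frame(type = "T", gene = "nope",
                                              shift = 1)),
    "absent from gene universe")
})

test_that("marker-shifted genes dominate the effect-size ranking", {
  mk <- data.frame(type = "T", gene = sprintf("g%03d", 1:10), shift = 2)
  cells <- simulate_single_cell(200, c("T", "B"), markers = mk,
                                n_genes = 60, seed = 8)
  de <- rank_sum_de(cells, cells$cells$type == "T", cells$cells$type == "B")
  top10 <- de$gene[order(-de$log2fc)][1:10]
  expect_setequal(top10, mk$gene)
})

test_that("null cell groups rarely produce DEGs", {
  clean <- vapply(1:20, function(s) {
    cells <- simulate_single_cell(60, c("T", "B"), n_genes = 40, seed = s)
    de <- rank_sum_de(cells, cells$cells$type == "T",
                      cells$cells$type == "B")
    sum(de$deg) == 0
  }, logical(1))
  expect_gte(sum(clean), 19)  # >= 95% of seeds clean
})

test_that("clonotype simulation honours its truth parameters", {
  # all-singleton repertoire
  tr <- clonotype_truth(c(d1 = 50), clone_dist = "geometric", rate = 1,
                        seed = 1)
  tab <- simulate_clonotypes(tr)
  sizes <- as.numeric(table(tab$clone))
  expect_true(all(sizes == 1))
  expect_equal(gini_coefficient(sizes), 0)
  expect_equal(expansion_index(sizes), 0)

  # identity sharing -> no cross-subtype clones
  tr2 <- clonotype_truth(c(d1 = 200), rate = 0.4, seed = 2)
  tab2 <- simulate_clonotypes(tr2)
  sub <- unique(tab2$subtype)
  for (i in seq_along(sub)) {
    for (j in seq_len(i - 1)) {
      expect_equal(pairwise_transition(tab2, sub[i], sub[j]), 0)
    }
  }

  # determinism
  expect_identical(simulate_clonotypes(tr2), simulate_clonotypes(tr2))
})

test_that("geometric clone sizes match the analytic mean", {
  rate <- 0.4
  means <- vapply(1:10, function(s) {
    tr <- clonotype_truth(c(d1 = 400), clone_dist = "geometric",
                          rate = rate, seed = s)
    tab <- simulate_clonotypes(tr)
    # drop the final (possibly truncated) clone of the sample
    sizes <- table(tab$clone)
    mean(head(as.numeric(sizes[order(names(sizes))]), -1))
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - 1 / rate), 2 * se)
})
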