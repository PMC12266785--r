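toy_table <- function(clones, subtypes, sample = "d1", age = 50) {
  clonotype_table(data.frame(
    cell = sprintf("c%03d", seq_along(clones)),
    clone = clones, subtype = subtypes, sample = sample, age = age))
}

test_that("Gini matches the double-loop oracle and its known values", {
  expect_equal(gini_coefficient(c(5, 5, 5)), 0)
  expect_equal(gini_coefficient(10), 0)
  expect_equal(gini_coefficient(c(1, 1, 1, 7)), 0.45, tolerance = 1e-12)
  expect_equal(gini_coefficient(c(1, 1, 1, 7)), gini_loop(c(1, 1, 1, 7)),
               tolerance = 1e-12)
  expect_error(gini_coefficient(c(1, 0)), "> 0")
  set.seed(51)
  for (i in 1:10) {
    x <- sample(1:20, sample(2:8, 1), replace = TRUE)
    expect_equal(gini_coefficient(x), gini_loop(x), tolerance = 1e-12)
  }
})

test_that("Gini and expansion are invariant to relabeling and scaling", {
  x <- c(2, 5, 9, 1)
  expect_equal(gini_coefficient(x), gini_coefficient(rev(x)))
  expect_equal(gini_coefficient(x), gini_coefficient(10 * x))
  expect_equal(expansion_index(x), expansion_index(sample(x)))
  expect_equal(expansion_index(x), expansion_index(3 * x))
})

test_that("moving a cell from smallest to largest clone raises Gini", {
  # exhaustive over all partitions of 8 cells with at least two clone
  # sizes; the transfer must keep the number of clones fixed, so the donor
  # clone needs >= 2 cells
  for (part in integer_partitions(8)) {
    if (length(part) < 2) next
    x <- sort(part)
    if (x[1] == x[length(x)] || x[1] < 2) next
    y <- x
    y[1] <- y[1] - 1
    y[length(y)] <- y[length(y)] + 1
    y <- y[y > 0]
    expect_gt(gini_coefficient(y), gini_coefficient(x))
    expect_equal(gini_coefficient(y), gini_loop(y), tolerance = 1e-12)
  }
})

test_that("expansion index matches hand-computed entropies", {
  expect_equal(expansion_index(c(1, 1, 1)), 0)
  expect_equal(expansion_index(c(1, 1, 2)), 1 - 1.5 / log2(3),
               tolerance = 1e-12)
  expect_equal(expansion_index(100), 1)   # single clone: fully clonal
  expect_error(expansion_index(c(2, -1)), "> 0")
})

test_that("transition potential reflects clone sharing", {
  confined <- toy_table(c("a", "a", "b", "b"), c("T1", "T1", "T2", "T2"))
  expect_equal(transition_index(confined, "T1"), 0)
  expect_equal(transition_index(confined, "T2"), 0)

  split <- toy_table(c("a", "a", "a", "a"), c("T1", "T1", "T2", "T2"))
  expect_equal(pairwise_transition(split, "T1", "T2"), 1)  # H(1/2,1/2)

  lopsided <- toy_table(c("a", "a"), c("T1", "T1"))
  expect_equal(pairwise_transition(lopsided, "T1", "T2"), 0)
  expect_error(transition_index(confined, "T9"), "not present")
})

test_that("pairwise transition is symmetric", {
  set.seed(52)
  tr <- clonotype_truth(c(d1 = 300), rate = 0.4,
                        sharing = matrix(c(0.7, 0.2, 0.1,
                                           0.2, 0.7, 0.1,
                                           0.1, 0.1, 0.8), 3, 3,
                                         byrow = TRUE,
                                         dimnames = rep(list(c("CD4_Treg",
                                                               "CD8_CTL",
                                                               "CD8_Tem")),
                                                        2)),
                        seed = 52)
  tab <- simulate_clonotypes(tr)
  sub <- unique(tab$subtype)
  for (i in seq_along(sub)) {
    for (j in seq_len(i - 1)) {
      expect_equal(pairwise_transition(tab, sub[i], sub[j]),
                   pairwise_transition(tab, sub[j], sub[i]),
                   tolerance = 1e-12)
    }
  }
})

test_that("per-group indices cover evenness and identical samples", {
  tab <- clonotype_table(data.frame(
    cell = sprintf("c%03d", 1:12),
    clone = rep(sprintf("cl%d", 1:6), 2)[1:12],
    subtype = "CD8_CTL",
    sample = rep(c("d1", "d2"), each = 6),
    age = rep(c(70, 70), each = 6)))
  # make the two samples identical repertoires of singletons
  tab$clone <- c(paste0("a", 1:6), paste0("b", 1:6))
  rs <- repertoire_by_group(tab)
  expect_equal(rs$indices$gini, c(0, 0))
  expect_equal(rs$indices$expansion, c(0, 0))
  cmp <- compare_repertoire(rs, "CD8_CTL", "d1", "d2", "gini")
  expect_equal(cmp$p, 1)
})

test_that("age-concentrated repertoires show a positive late-life trend", {
  ages <- c(30, 45, 55, 62, 68, 75, 82, 90)
  rates <- c(0.9, 0.9, 0.9, 0.6, 0.5, 0.45, 0.4, 0.35)
  hits <- vapply(1:20, function(s) {
    tr <- clonotype_truth(setNames(rep(120, 8), paste0("d", 1:8)),
                          ages = setNames(ages, paste0("d", 1:8)),
                          subtypes = "CD8_CTL", rate = rates, seed = s)
    tab <- simulate_clonotypes(tr)
    rs <- repertoire_by_group(tab)
    old <- rs$indices[rs$indices$age > 60, ]
    coef(lm(old$gini ~ old$age))[2] > 0
  }, logical(1))
  expect_gte(sum(hits), 18)  # >= 90% of seeds
})

test_that("clonotype tables are validated and filterable", {
  df <- data.frame(cell = c("c1", "c2", "c3"), clone = c("a", "a", "b"),
                   subtype = c("CD8_CTL", "CD8_CTL", "NK"), sample = "d1")
  kept <- clonotype_table(df, keep_types = c("CD8_CTL"))
  expect_equal(nrow(kept), 2)
  expect_error(clonotype_table(df[, -2]), "lacks columns")
  df$cell[2] <- "c1"
  expect_error(clonotype_table(df), "unique")
})
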