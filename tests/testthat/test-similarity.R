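make_expr <- function(means, n_reps = 3, noise_sd = 0, seed = 71) {
  # means: gene x 3 matrix (SPR, DP, SPF)
  pops <- c("SPR", "DP", "SPF")
  samples <- data.frame(
    sample = paste0(rep(pops, each = n_reps), "_r", seq_len(n_reps)),
    population = rep(pops, each = n_reps),
    replicate = rep(seq_len(n_reps), 3)
  )
  set.seed(seed)
  expr <- means[, rep(1:3, each = n_reps)] +
    matrix(rnorm(nrow(means) * 3 * n_reps, sd = noise_sd), nrow = nrow(means))
  rownames(expr) <- paste0("g", seq_len(nrow(means)))
  colnames(expr) <- samples$sample
  list(expr = expr, samples = samples)
}

test_that("fold-change and p-value rules select the obvious genes", {
  means <- rbind(c(10, 9, 8),    # 4-fold SPR vs SPF
                 c(8.6, 8.3, 8)) # 1.5-fold: below threshold
  tab <- make_expr(means, noise_sd = 0.05)
  de <- differential_genes(tab$expr, tab$samples)
  expect_true("g1" %in% de$union)
  expect_false(de$flags["g2", "SPR_SPF"])
})

test_that("constant genes are excluded with a warning", {
  means <- rbind(c(8, 8, 8), c(12, 10, 8))
  tab <- make_expr(means, noise_sd = 0)
  expect_warning(
    expect_warning(
      expect_warning(de <- differential_genes(tab$expr, tab$samples), "constant"),
      "constant"),
    "constant")  # g1 is constant in all three pairs
  expect_identical(de$union, "g2")
})

test_that("DE recall exceeds 95% on tables with known labels", {
  tab <- simulate_expression_table(n_genes = 300, effect_size = 2.5,
                                   noise_sd = 0.25, seed = 72)
  de <- differential_genes(tab$expr, tab$samples)
  expect_gte(mean(de$flags[, "SPR_SPF"]), 0.95)
})

test_that("the similarity index hits its defining anchors", {
  expect_equal(similarity_index(10, 10, 8), 1)    # DP = SPR
  expect_equal(similarity_index(10, 8, 8), -1)    # DP = SPF
  expect_equal(similarity_index(10, 9, 8), 0)     # midpoint
  expect_true(is.na(similarity_index(8.1, 8, 8))) # denominator floor
})

test_that("similarity is affine-invariant and antisymmetric under label swap", {
  set.seed(73)
  spr <- rnorm(50, 10); spf <- spr - 2.5; dp <- spf + runif(50, -1, 4)
  s <- similarity_index(spr, dp, spf)
  expect_equal(similarity_index(spr + 7, dp + 7, spf + 7), s)
  expect_equal(similarity_index(spf, dp, spr), -s)
  bins <- as.character(bin_similarity(s)$bin)
  mirrored <- as.character(bin_similarity(-s)$bin)
  map <- c("SPR-like" = "SPF-like", "SPF-like" = "SPR-like",
           "intermediate" = "intermediate",
           "distinct-low" = "distinct-high", "distinct-high" = "distinct-low")
  expect_identical(mirrored, unname(map[bins]))
})

test_that("bin breakpoints sit at -1.5, -0.5, 0.5, 1.5", {
  s <- c(1.0, 1.7, 0.0, -1.0, -1.7, 0.5, 1.5, -0.5, -1.5, NA)
  bins <- as.character(bin_similarity(s)$bin)
  expect_identical(bins,
    c("SPR-like", "distinct-high", "intermediate", "SPF-like", "distinct-low",
      "SPR-like", "SPR-like", "intermediate", "SPF-like", "undefined"))
})

test_that("population correlations reflect construction", {
  set.seed(76)
  means <- cbind(rnorm(100, 8, 2), 0, 0)
  means[, 2] <- means[, 1]                      # DP duplicates SPR
  means[, 3] <- 16 - means[, 1]                 # SPF anti-correlated
  tab <- make_expr(means, noise_sd = 0)
  cc <- population_correlation(tab$expr, tab$samples)
  expect_equal(unname(diag(cc)), rep(1, 3))
  expect_equal(cc["SPR", "DP"], 1)
  expect_lt(cc["SPR", "SPF"], 0)

  # DP built closer to SPR correlates more with SPR than SPF
  tab2 <- simulate_expression_table(n_genes = 500, seed = 74)
  cc2 <- population_correlation(tab2$expr, tab2$samples)
  expect_gt(cc2["DP", "SPR"], cc2["DP", "SPF"])

  expect_error(population_correlation(tab$expr[1:10, ], tab$samples), ">= 50")
})

test_that("the full similarity analysis recovers generator bin fractions", {
  tab <- simulate_expression_table(n_genes = 800, seed = 75)
  res <- similarity_analysis(tab)
  expect_gt(length(res$de$union) / 800, 0.95)
  fr <- res$fractions
  expect_lt(abs(fr[["SPR-like"]] - 0.48), 0.06)
  expect_lt(abs(fr[["intermediate"]] - 0.30), 0.06)
  expect_lt(abs(fr[["distinct-low"]] + fr[["distinct-high"]] - 0.20), 0.06)
})
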