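test_that("zero-amplitude noise-free clones render flat baseline traces", {
  spec <- population_spec("Th17", n_clones = 1, noise_sd = 0)
  p <- clone_params("DN", baseline = 5, noise_sd = 0)
  tr <- simulate_clone_trace(p, spec)
  expect_equal(nrow(tr), 52 / 0.5 + 1)
  expect_true(all(tr$total_G == 5))
  expect_true(all(tr$total_R == 5))
})

test_that("with zero noise the sigmoid crosses half-maximum at the onset time", {
  spec <- population_spec("Th17", n_clones = 1, noise_sd = 0, rise_width = 0.1)
  p <- clone_params("SPR", onset_time_G = 20, amplitude_G = 40, baseline = 5,
                    rise_width = 0.1, noise_sd = 0)
  tr <- simulate_clone_trace(p, spec)
  crossing <- tr$time_hr[min(which(tr$total_G >= 5 + 40 / 2))]
  expect_equal(crossing, 20, tolerance = 1e-8)
})

test_that("traces are bitwise reproducible under a fixed seed", {
  spec <- population_spec("Th17", n_clones = 1)
  p <- clone_params("DP", onset_time_G = 20, onset_time_R = 40,
                    division_times = 38, seed = 11)
  expect_identical(simulate_clone_trace(p, spec), simulate_clone_trace(p, spec))
  pop1 <- simulate_population(population_spec("Th17", n_clones = 20), seed = 3)
  pop2 <- simulate_population(population_spec("Th17", n_clones = 20), seed = 3)
  expect_identical(pop1$traces, pop2$traces)
  expect_identical(pop1$metadata, pop2$metadata)
})

test_that("non-positive rise width is rejected", {
  expect_error(clone_params("SPR", rise_width = 0), "rise_width")
  expect_error(clone_params("SPR", rise_width = -1), "rise_width")
})

test_that("total fluorescence is continuous across division times", {
  spec <- population_spec("Th17", n_clones = 1, noise_sd = 0)
  p <- clone_params("SPR", onset_time_G = 15, amplitude_G = 40, baseline = 5,
                    division_times = c(30, 44), noise_sd = 0)
  tr <- simulate_clone_trace(p, spec)
  # noise-free trace: largest frame-to-frame jump near a division must be
  # of the same order as elsewhere (no doubling discontinuity)
  steps <- abs(diff(tr$total_G))
  near_div <- which(tr$time_hr[-1] %in% c(30, 30.5, 44, 44.5))
  expect_lt(max(steps[near_div]), 3 * max(steps[-near_div]))
  # and the signal has doubled by each division relative to the previous one
  sig <- tr$total_G - 5
  expect_gt(sig[tr$time_hr == 44] / sig[tr$time_hr == 30], 1.8)
})

test_that("population fates follow the requested fractions", {
  spec <- population_spec("Th17", fate_fractions = c(SPR = 1), n_clones = 50)
  pop <- simulate_population(spec, seed = 1)
  expect_true(all(pop$metadata$true_fate == "SPR"))

  spec <- population_spec("Th17", fate_fractions = c(SPR = .57, DP = .22, DN = .21),
                          n_clones = 1000)
  pop <- simulate_population(spec, seed = 2)
  frac <- mean(pop$metadata$true_fate == "SPR")
  expect_lt(abs(frac - 0.57), 3 * sqrt(0.57 * 0.43 / 1000))
})

test_that("onset and division draws converge to the population-spec distributions", {
  spec <- population_spec("Th17", fate_fractions = c(DP = 1), n_clones = 2000)
  pop <- simulate_population(spec, seed = 4)
  for (col_dist in list(c("onset_G", 21.8, 9.4), c("onset_R", 39.3, 8.2),
                        c("first_division_time", 38.8, 5))) {
    x <- pop$metadata[[col_dist[1]]]
    m <- as.numeric(col_dist[2]); s <- as.numeric(col_dist[3])
    expect_lt(abs(mean(x) - m), 3 * s / sqrt(2000))
  }
})

test_that("pixel angles concentrate at the expected fate anchors", {
  spec <- population_spec("Th17", n_clones = 1)
  dp <- clone_params("DP", onset_time_G = 20, onset_time_R = 30,
                     division_times = 38, seed = 21)
  fr <- simulate_well_pixels(dp, spec, pixel_noise_sd = 0.01)
  ang <- pixel_angles(fr[[105]])
  expect_gt(length(ang), 50)
  expect_lt(abs(median(ang) - 45), 3)

  spr <- clone_params("SPR", onset_time_G = 20, division_times = 38, seed = 22)
  fr <- simulate_well_pixels(spr, spec, pixel_noise_sd = 0.01)
  ang <- pixel_angles(fr[[105]])
  expect_gt(median(ang), 85)

  dn <- clone_params("DN", seed = 23)
  fr <- simulate_well_pixels(dn, spec)
  # background-level pixels fall below the intensity floor
  expect_lt(length(pixel_angles(fr[[105]])), 10)
})

test_that("flow events honour transition probabilities and dye labels", {
  id <- diag(4); dimnames(id) <- list(c("SPR", "DP", "SPF", "DN"),
                                      c("SPR", "DP", "SPF", "DN"))
  ev <- simulate_flow_events(500, origin_fractions = c(SPR = 0.5, DP = 0.5),
                             transition_probs = id, seed = 5)
  expect_true(all(ev$destination_true == ev$origin))
  expect_true(all(ev$dye_positive == (ev$origin == "SPR")))

  tp <- id; tp["SPR", "DP"] <- 0.217; tp["SPR", "SPR"] <- 1 - 0.217
  ev <- simulate_flow_events(10000, origin_fractions = c(SPR = 1),
                             transition_probs = tp, seed = 6)
  frac <- mean(ev$destination_true[ev$dye_positive] == "DP")
  expect_lt(abs(frac - 0.217), 3 * sqrt(0.217 * 0.783 / 10000))

  ev <- simulate_flow_events(100, origin_fractions = c(SPR = 1),
                             dye_labeling = FALSE, seed = 7)
  expect_false("origin" %in% names(ev))
  expect_false("dye_positive" %in% names(ev))
})

test_that("expression tables round-trip their assigned similarity classes", {
  tab <- simulate_expression_table(n_genes = 400, noise_sd = 0, seed = 8)
  m <- population_means(tab$expr, tab$samples)
  s <- similarity_index(m[, "SPR"], m[, "DP"], m[, "SPF"])
  bins <- as.character(bin_similarity(s)$bin)
  recovered <- ifelse(bins %in% c("distinct-low", "distinct-high"), "distinct", bins)
  expect_identical(recovered, tab$truth$class)
  expect_equal(unname(s), tab$truth$similarity, tolerance = 1e-10)
})

test_that("frac_spr_like = 1 pins DP means to SPR means", {
  tab <- simulate_expression_table(n_genes = 50, frac_spr_like = 1,
                                   frac_intermediate = 0, frac_distinct = 0,
                                   noise_sd = 0, seed = 9)
  m <- population_means(tab$expr, tab$samples)
  expect_equal(unname(m[, "DP"]), unname(m[, "SPR"]), tolerance = 1e-10)
})

test_that("zero effect size yields no differentially expressed genes", {
  tab <- simulate_expression_table(n_genes = 300, effect_size = 0, seed = 10)
  de <- differential_genes(tab$expr, tab$samples)
  expect_lt(length(de$union) / 300, 0.02)
})
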