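test_that("response threshold is mean + k * sd of naive t0 signals", {
  expect_equal(compute_response_threshold(rep(7, 12), rep(7, 12), k = 3)$threshold_G, 7)
  expect_equal(compute_response_threshold(1:20, 1:20, k = 0)$threshold_G, mean(1:20))
  set.seed(41)
  x <- rnorm(200, 100, 10)
  thr <- compute_response_threshold(x, x, k = 3)
  expect_equal(thr$threshold_G, mean(x) + 3 * sd(x))
  expect_lt(abs(thr$threshold_G - 130), 3)
  expect_error(compute_response_threshold(1:5, 1:20), ">= 10")
})

test_that("rise time is the first persistent crossing", {
  tr <- make_trace(c(rep(1, 40), rep(10, 65)), rep(1, 105))
  expect_equal(compute_rise_time(tr, 5, "G"), 20)
  expect_true(is.na(compute_rise_time(tr, 5, "R")))
  # a single-frame spike does not count with persistence 2
  spike <- make_trace(c(rep(1, 10), 10, rep(1, 20), rep(10, 5)), rep(1, 36))
  expect_equal(compute_rise_time(spike, 5, "G", persistence_frames = 2), 15.5)
  expect_equal(compute_rise_time(spike, 5, "G", persistence_frames = 1), 5)
})

test_that("rise-time estimates recover a noisy sigmoid onset within 1 hr", {
  spec <- population_spec("Th17", n_clones = 1)
  p <- clone_params("SPR", onset_time_G = 21.8, seed = 42)
  tr <- simulate_clone_trace(p, spec)
  thr <- compute_response_threshold(rnorm(50, 5, 2), rnorm(50, 5, 2), k = 3)
  est <- compute_rise_time(tr, thr, "G")
  expect_lt(abs(est - 21.8), 1)
})

test_that("rise times match a brute-force frame scan on random traces", {
  set.seed(43)
  for (i in 1:300) {
    n <- sample(10:60, 1)
    values <- round(runif(n, 0, 10), 1)
    thr <- runif(1, 2, 8)
    pers <- sample(1:4, 1)
    tr <- make_trace(values, values)
    expect_identical(
      compute_rise_time(tr, thr, "G", persistence_frames = pers),
      oracle_rise_time(values, tr$time_hr, thr, pers)
    )
  }
})

test_that("clones are classified by which channels rise", {
  thr <- 5
  up <- function(at) c(rep(1, at), rep(10, 105 - at))
  flat <- rep(1, 105)
  expect_equal(classify_clone(make_trace(up(40), flat), thr)$fate, "SPR")
  expect_equal(classify_clone(make_trace(flat, up(80)), thr)$fate, "SPF")
  expect_equal(classify_clone(make_trace(up(40), up(80)), thr)$fate, "DP")
  expect_equal(classify_clone(make_trace(flat, flat), thr)$fate, "DN")
  # endpoint MFI is the mean total over the last 5 frames
  expect_equal(classify_clone(make_trace(up(40), flat), thr)$endpoint_MFI_G, 10)
})

test_that("every clone gets exactly one fate and counts partition the wells", {
  pop <- simulate_population(population_spec("Th17", n_clones = 120), seed = 44)
  res <- classify_population(pop$traces)
  expect_equal(nrow(res$calls), length(res$included))
  expect_true(all(res$calls$fate %in% c("SPR", "SPF", "DP", "DN")))
  expect_equal(sum(table(res$calls$fate)), nrow(res$calls))
})

test_that("raising the threshold never shortens rise times nor revives DN calls", {
  pop <- simulate_population(population_spec("Th17", n_clones = 40), seed = 45)
  for (tr in pop$traces[1:20]) {
    r1 <- compute_rise_time(tr, 15, "G")
    r2 <- compute_rise_time(tr, 40, "G")
    if (!is.na(r2)) expect_gte(r2, r1)
    if (is.na(r1)) expect_true(is.na(r2))
  }
})

test_that("fate fractions and rise-time means are recovered on synthetic populations", {
  spec <- population_spec("Th17", n_clones = 500)
  pop <- simulate_population(spec, seed = 46)
  res <- classify_population(pop$traces)
  for (fate in c("SPR", "DP", "DN")) {
    p0 <- spec$fate_fractions[[fate]]
    expect_lt(abs(mean(res$calls$fate == fate) - p0),
              3 * sqrt(p0 * (1 - p0) / 500) + 0.02)
  }
  g <- res$calls$rise_time_G[res$calls$fate %in% c("SPR", "DP")]
  g <- g[!is.na(g)]
  expect_lt(abs(mean(g) - 21.8), 3 * sd(g) / sqrt(length(g)))
})

test_that("rise-time summaries and Welch tests behave at the anchors", {
  a <- c(20, 21, 22, 23, 24)
  res <- summarize_rise_times(list(g1 = a, g2 = a))
  expect_gt(res$tests$p_value, 0.99)
  expect_equal(res$summary$mean, c(22, 22))

  set.seed(47)
  g1 <- rnorm(200, 21.8, 9.4); g2 <- rnorm(200, 39.3, 8.2)
  res <- summarize_rise_times(list(ror = g1, foxp3 = g2))
  expect_lt(res$tests$p_value, 1e-10)
  expect_lt(abs(res$summary$mean[1] - 21.8), 3 * 9.4 / sqrt(200))
  # closed-form Welch statistic agrees
  tt <- (mean(g1) - mean(g2)) / sqrt(var(g1) / 200 + var(g2) / 200)
  expect_equal(res$tests$t, tt, tolerance = 1e-10)
})

test_that("division-vs-rise fractions hit the deterministic anchors", {
  calls <- data.frame(
    well_id = letters[1:4], condition = "Th17", fate = "DP",
    rise_time_G = c(20, 20, 20, 20), rise_time_R = c(40, 40, 40, 40),
    endpoint_MFI_G = 1, endpoint_MFI_R = 1, first_division_time = 30
  )
  dv <- division_vs_rise(calls)
  expect_equal(unname(dv$fraction_after_division["R"]), 1)
  expect_equal(unname(dv$fraction_after_division["G"]), 0)
  expect_equal(dv$division_summary$median, 30)
})

test_that("Foxp3 rises mostly after division, RORgt mostly before, at defaults", {
  th17 <- simulate_population(population_spec("Th17", n_clones = 700), seed = 48)
  treg <- simulate_population(population_spec("Treg", n_clones = 700), seed = 49)
  traces <- c(th17$traces, treg$traces)
  md <- rbind(th17$metadata, treg$metadata)
  res <- classify_population(traces)
  calls <- res$calls
  calls$first_division_time <- md$first_division_time[match(calls$well_id, md$well_id)]
  dv <- division_vs_rise(calls)
  expect_gt(unname(dv$fraction_after_division["R"]), 0.5)
  expect_lt(unname(dv$fraction_after_division["G"]), 0.5)
  # Th17 divides later than Treg
  ds <- dv$division_summary
  expect_gt(ds$median[ds$condition == "Th17"], ds$median[ds$condition == "Treg"])
})
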