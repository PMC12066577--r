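test_that("pixel angles hit the pure-channel and balanced anchors", {
  fr <- make_frame(G = c(10, 0, 7), R = c(0, 10, 7))
  expect_equal(pixel_angles(fr, intensity_floor = 0), c(90, 0, 45))
})

test_that("angles are scale-invariant and channel-swap symmetric", {
  set.seed(61)
  G <- runif(100, 0.1, 5); R <- runif(100, 0.1, 5)
  a1 <- pixel_angles(make_frame(G, R), intensity_floor = 0)
  a2 <- pixel_angles(make_frame(7.3 * G, 7.3 * R), intensity_floor = 0)
  expect_equal(a1, a2)
  swapped <- pixel_angles(make_frame(R, G), intensity_floor = 0)
  expect_equal(swapped, 90 - a1)
  expect_true(all(a1 >= 0 & a1 <= 90))
})

test_that("the intensity floor drops near-background pixels and (0,0) is excluded", {
  fr <- make_frame(G = c(0.05, 5, 0), R = c(0.05, 5, 0))
  expect_length(pixel_angles(fr, intensity_floor = 1), 1)
  expect_length(pixel_angles(fr, intensity_floor = 0), 2)  # (0,0) dropped
})

test_that("a balanced well yields a smoothed mode at 45 degrees", {
  well <- make_well(G = rep(7, 200), R = rep(7, 200))
  d <- angle_distribution(well, intensity_floor = 0)
  expect_equal(sum(d$counts), 1000)
  pk <- detect_peaks(d)
  expect_equal(pk$n_peaks_raw, 1)
  expect_equal(pk$peak_angles, 45)
})

test_that("wells below the floor give an empty distribution with zero peaks", {
  well <- make_well(G = rep(0.01, 30), R = rep(0.01, 30))
  d <- angle_distribution(well, intensity_floor = 1)
  expect_true(d$empty)
  expect_equal(detect_peaks(d)$n_peaks_raw, 0)
})

test_that("fewer than five frames is an error", {
  well <- make_well(G = rep(5, 10), R = rep(5, 10))
  expect_error(angle_distribution(well[1:3]), "at least 5")
})

test_that("peak detection resolves well-separated bimodal angle mixtures", {
  set.seed(62)
  theta <- c(rnorm(400, 5, 5), rnorm(400, 85, 5))
  theta <- pmin(pmax(theta, 0), 90)
  G <- sin(theta * pi / 180); R <- cos(theta * pi / 180)
  well <- make_well(G = G, R = R)
  pk <- detect_peaks(angle_distribution(well, intensity_floor = 0))
  expect_equal(pk$n_peaks_raw, 2)
  expect_lt(abs(pk$peak_angles[1] - 5), 7)
  expect_lt(abs(pk$peak_angles[2] - 85), 7)
  # peak count is invariant to histogram mass scaling
  well10 <- make_well(G = rep(G, 10), R = rep(R, 10))
  pk10 <- detect_peaks(angle_distribution(well10, intensity_floor = 0))
  expect_equal(pk10$n_peaks_raw, pk$n_peaks_raw)
})

test_that("detect_peaks agrees with an exhaustive local-maximum oracle", {
  set.seed(63)
  centers <- seq(0, 90, by = 3)
  for (i in 1:400) {
    # random smoothed-like densities: mixtures, flats, plateaus, spikes
    y <- switch(sample(3, 1),
                abs(rnorm(31)) + dnorm(centers, runif(1, 0, 90), runif(1, 3, 20)) * 50,
                round(runif(31, 0, 5)),
                rep(sample(0:3, 1), 31))
    d <- structure(list(well_id = "w", bin_centers = centers, bin_width = 3,
                        counts = y, smoothed = y, n_pixels = sum(y),
                        empty = FALSE),
                   class = "angle_distribution")
    got <- detect_peaks(d, min_prominence_frac = 0.1, min_separation_deg = 15)
    want <- oracle_peaks(y, centers, 0.1, 15)
    expect_identical(which(centers %in% got$peak_angles), as.integer(want))
  }
})

test_that("composing SPR and SPF wells creates a detectable two-peak clone", {
  spec <- population_spec("Th17", n_clones = 1)
  spr <- simulate_well_pixels(clone_params("SPR", onset_time_G = 20,
                                           division_times = 38, seed = 64), spec)
  spf <- simulate_well_pixels(clone_params("SPF", onset_time_R = 35,
                                           division_times = 36, seed = 65), spec)
  comp <- compose_artificial_heterogeneous(spr, spf, "SPR", "SPF")
  pk <- detect_peaks(angle_distribution(comp))
  expect_equal(pk$n_peaks, 2L)
  expect_equal(pk$classification, "heterogeneous")

  # union with itself only rescales the histogram: same peak count
  self <- compose_artificial_heterogeneous(spr, spr)
  expect_equal(detect_peaks(angle_distribution(self))$n_peaks_raw,
               detect_peaks(angle_distribution(spr))$n_peaks_raw)

  # a DN partner contributes no retained pixels
  dn <- simulate_well_pixels(clone_params("DN", seed = 66), spec)
  with_dn <- compose_artificial_heterogeneous(spr, dn, "SPR", "DN")
  expect_equal(detect_peaks(angle_distribution(with_dn))$n_peaks_raw, 1L)

  expect_warning(compose_artificial_heterogeneous(spr, spr, "SPR", "SPR"),
                 "same fate")
  expect_error(compose_artificial_heterogeneous(spr, spf[1:3]), "matching frame")
})

test_that("the detector is specific on homogeneous wells and sensitive on composites", {
  spec <- population_spec("Th17", fate_fractions = c(SPR = 1/3, DP = 1/3, SPF = 1/3),
                          n_clones = 120)
  pop <- simulate_population(spec, seed = 67, render_pixels = TRUE,
                             n_pixel_wells = 120)
  fates <- pop$metadata$true_fate
  npix <- vapply(pop$frames, function(fr) angle_distribution(fr)$n_pixels, numeric(1))
  bright <- npix >= 100
  spr <- pop$frames[fates == "SPR" & bright]
  spf <- pop$frames[fates == "SPF" & bright]
  n_pairs <- min(25, length(spr), length(spf))
  comp <- lapply(seq_len(n_pairs), function(i) {
    compose_artificial_heterogeneous(spr[[i]], spf[[i]])
  })
  ev <- evaluate_detector(pop$frames, comp)
  expect_lte(ev$frac_multipeak_homogeneous, 0.01)
  expect_gte(ev$frac_multipeak_artificial, 0.9)
  tab <- peak_count_table(ev$reports_homogeneous)
  expect_equal(sum(tab$wells), 120)
  expect_gt(tab$percent[tab$n_peaks == 1], 90)
})
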