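#' Parameters of one simulated clone
#'
#' Bundles everything needed to render a single micro-well clone: its fate,
#' the per-channel onset times and amplitudes, the sigmoid steepness, the
#' division schedule and the trace noise level.
#'
#' `onset_time_G` / `onset_time_R` are defined on the observable scale: the
#' time at which the noise-free total-fluorescence trace reaches the naive
#' background detection level (baseline + 3 * `noise_sd`). The logistic
#' midpoint is derived internally from that definition, so onset parameters
#' are directly comparable to threshold-crossing rise times. With
#' `noise_sd = 0` the detection level falls back to the half-maximum, i.e.
#' the onset is the sigmoid midpoint.
#'
#' @param fate one of `"SPR"`, `"SPF"`, `"DP"`, `"DN"`.
#' @param onset_time_G,onset_time_R channel onset times in hours (`Inf` or
#'   `NA` for a channel that never rises; forced for fates that lack the
#'   channel).
#' @param amplitude_G,amplitude_R plateau amplitudes (fluorescence units) of
#'   the undivided clone; total signal additionally scales with clone growth.
#' @param baseline background total fluorescence of the well.
#' @param rise_width sigmoid steepness in hours (must be positive).
#' @param division_times sorted positive division times in hours (annotation;
#'   also drives the growth factor). May extend past the imaging window.
#' @param noise_sd additive Gaussian noise sd on the total trace.
#' @param seed RNG seed for this clone's noise draws.
#' @return an object of class `clone_params`.
#' @export
clone_params <- function(fate = c("SPR", "SPF", "DP", "DN"),
                         onset_time_G = NA_real_, onset_time_R = NA_real_,
                         amplitude_G = 40, amplitude_R = 40,
                         baseline = 5, rise_width = 0.5,
                         division_times = numeric(), noise_sd = 2,
                         seed = NULL) {
  fate <- match.arg(fate)
  if (!is_number(rise_width) || rise_width <= 0) {
    stopf("rise_width must be a positive number, got %s", format(rise_width))
  }
  if (amplitude_G < 0 || amplitude_R < 0) stopf("amplitudes must be >= 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  onset_time_G <- as.numeric(onset_time_G)
  onset_time_R <- as.numeric(onset_time_R)
  if (isTRUE(onset_time_G < 0) || isTRUE(onset_time_R < 0)) {
    stopf("onset times must be >= 0")
  }
  # A fate without a channel carries no signal in that channel.
  if (fate %in% c("SPF", "DN")) amplitude_G <- 0
  if (fate %in% c("SPR", "DN")) amplitude_R <- 0
  division_times <- sort(as.numeric(division_times))
  if (length(division_times) && any(division_times <= 0)) {
    stopf("division times must be positive")
  }
  structure(
    list(fate = fate,
         onset_time_G = onset_time_G, onset_time_R = onset_time_R,
         amplitude_G = amplitude_G, amplitude_R = amplitude_R,
         baseline = baseline, rise_width = rise_width,
         division_times = division_times, noise_sd = noise_sd,
         seed = seed),
    class = "clone_params"
  )
}

#' Specification of a simulated micro-well population
#'
#' Describes the experimental condition and the distributions from which
#' clone-level parameters are drawn. Defaults reproduce the study
#' conditions: 52 hr of imaging at 30-minute intervals; RORgt onsets
#' around 21.8 +/- 9.4 hr, Foxp3 onsets around 39.3 +/- 8.2 hr; first
#' divisions around 38.8 hr (Th17) or 36 hr (Treg).
#'
#' @param condition `"Th17"` or `"Treg"`.
#' @param fate_fractions named probabilities over `SPR`, `SPF`, `DP`, `DN`
#'   (must sum to 1). Defaults follow the reported end-of-experiment
#'   fractions for the condition.
#' @param onset_G_dist,onset_R_dist `c(mean, sd)` in hours of the channel
#'   onset-time distributions.
#' @param division_time_dist `c(mean, sd)` in hours of the first-division
#'   time.
#' @param n_clones number of wells to simulate.
#' @param frame_interval imaging interval in hours.
#' @param duration imaging duration in hours (must be a multiple of
#'   `frame_interval`).
#' @param amplitude_G,amplitude_R,baseline,rise_width,noise_sd trace model
#'   parameters passed to every clone (see [clone_params()]).
#' @return an object of class `population_spec`.
#' @export
population_spec <- function(condition = c("Th17", "Treg"),
                            fate_fractions = NULL,
                            onset_G_dist = c(21.8, 9.4),
                            onset_R_dist = c(39.3, 8.2),
                            division_time_dist = NULL,
                            n_clones = 100,
                            frame_interval = 0.5, duration = 52,
                            amplitude_G = 40, amplitude_R = 40,
                            baseline = 5, rise_width = 0.5, noise_sd = 2) {
  condition <- match.arg(condition)
  if (is.null(fate_fractions)) {
    fate_fractions <- if (condition == "Th17") {
      c(SPR = 0.57, DP = 0.22, SPF = 0, DN = 0.21)
    } else {
      c(SPR = 0, DP = 0.20, SPF = 0.46, DN = 0.34)
    }
  }
  fates <- c("SPR", "SPF", "DP", "DN")
  full <- stats::setNames(numeric(4), fates)
  full[names(fate_fractions)] <- fate_fractions
  if (any(full < 0) || abs(sum(full) - 1) > 1e-8) {
    stopf("fate_fractions must be non-negative and sum to 1")
  }
  if (is.null(division_time_dist)) {
    division_time_dist <- if (condition == "Th17") c(38.8, 5) else c(36, 5)
  }
  for (d in list(onset_G_dist, onset_R_dist, division_time_dist)) {
    if (length(d) != 2 || d[2] < 0) stopf("distributions are c(mean, sd) with sd >= 0")
  }
  if (frame_interval <= 0 || duration <= 0) stopf("frame grid must be positive")
  n_frames <- duration / frame_interval
  if (abs(n_frames - round(n_frames)) > 1e-8) {
    stopf("frame_interval must divide duration")
  }
  structure(
    list(condition = condition, fate_fractions = full,
         onset_G_dist = onset_G_dist, onset_R_dist = onset_R_dist,
         division_time_dist = division_time_dist, n_clones = n_clones,
         frame_interval = frame_interval, duration = duration,
         amplitude_G = amplitude_G, amplitude_R = amplitude_R,
         baseline = baseline, rise_width = rise_width, noise_sd = noise_sd),
    class = "population_spec"
  )
}

# Clone growth factor 2^d(t): d(t) is piecewise linear, reaching k at the
# k-th division time and constant after the last one. Continuous in t, so
# total fluorescence never jumps at a division (cells split signal between
# daughters without loss).
growth_factor <- function(t, division_times) {
  if (!length(division_times)) return(rep(1, length(t)))
  knots_x <- c(0, division_times)
  knots_y <- seq_along(knots_x) - 1
  d <- stats::approx(knots_x, knots_y, xout = t, rule = 2)$y
  2^d
}

# Number of physical cells at time t (doubles discretely at divisions).
cell_count <- function(t, division_times) {
  if (!length(division_times)) return(rep(1L, length(t)))
  vapply(t, function(tt) as.integer(2^sum(division_times <= tt)), integer(1))
}

# Logistic midpoint consistent with the observable-onset definition: the
# noise-free trace crosses baseline + 3*noise_sd (or half-maximum when
# noise-free) at `onset`.
sigmoid_midpoint <- function(onset, amplitude, rise_width, noise_sd,
                             division_times, k_ref = 3) {
  g_on <- growth_factor(onset, division_times)
  level <- if (noise_sd > 0) k_ref * noise_sd else amplitude * g_on / 2
  ratio <- amplitude * g_on / level
  if (!is.finite(ratio) || ratio <= 1) return(onset)
  onset + rise_width * log(ratio - 1)
}

# Noise-free per-channel signal (above baseline) on a time grid.
channel_signal <- function(times, onset, amplitude, rise_width, noise_sd,
                           division_times) {
  if (amplitude <= 0 || !is.finite(onset) || is.na(onset)) {
    return(rep(0, length(times)))
  }
  t50 <- sigmoid_midpoint(onset, amplitude, rise_width, noise_sd,
                          division_times)
  amplitude * growth_factor(times, division_times) *
    stats::plogis((times - t50) / rise_width)
}

#' Simulate the total-fluorescence trace of one clone
#'
#' Renders per-channel total fluorescence
#' `F_c(t) = baseline + amplitude_c * growth(t) * logistic((t - t50_c)/rise_width) + noise`,
#' where `growth(t)` doubles the clone's signal capacity by each division
#' time (continuously, so the total is conserved at the division itself)
#' and `t50_c` is placed so the noise-free trace reaches the naive
#' detection level at the clone's onset time. Negative noisy totals are
#' clipped to zero.
#'
#' @param params a [clone_params()] object.
#' @param spec a [population_spec()] object supplying the frame grid.
#' @return a `clone_trace`: data frame with `time_hr`, `total_G`, `total_R`
#'   and attributes `well_id`, `condition`, `n_cells_t0`, `n_beads_t0`,
#'   `division_times`, `true_fate`.
#' @export
simulate_clone_trace <- function(params, spec) {
  stopifnot(inherits(params, "clone_params"), inherits(spec, "population_spec"))
  times <- seq(0, spec$duration, by = spec$frame_interval)
  sig_G <- channel_signal(times, params$onset_time_G, params$amplitude_G,
                          params$rise_width, params$noise_sd,
                          params$division_times)
  sig_R <- channel_signal(times, params$onset_time_R, params$amplitude_R,
                          params$rise_width, params$noise_sd,
                          params$division_times)
  noise <- with_seed(params$seed, {
    matrix(stats::rnorm(2 * length(times), sd = params$noise_sd), ncol = 2)
  })
  trace <- data.frame(
    time_hr = times,
    total_G = pmax(params$baseline + sig_G + noise[, 1], 0),
    total_R = pmax(params$baseline + sig_R + noise[, 2], 0)
  )
  new_clone_trace(trace,
                  well_id = "well_1", condition = spec$condition,
                  n_cells_t0 = 1L, n_beads_t0 = 1L,
                  division_times = params$division_times,
                  true_fate = params$fate)
}

new_clone_trace <- function(df, well_id, condition, n_cells_t0, n_beads_t0,
                            division_times = numeric(), true_fate = NA_character_) {
  stopifnot(all(c("time_hr", "total_G", "total_R") %in% names(df)))
  if (is.unsorted(df$time_hr, strictly = TRUE)) {
    stopf("trace times must be strictly increasing")
  }
  structure(df, class = c("clone_trace", "data.frame"),
            well_id = well_id, condition = condition,
            n_cells_t0 = n_cells_t0, n_beads_t0 = n_beads_t0,
            division_times = division_times, true_fate = true_fate)
}

#' Render abstract pixel sets for one simulated well
#'
#' Distributes each frame's noise-free clone signal over
#' `cells x n_pixels_per_cell` cell pixels (equal shares, matching the
#' assumption that sister cells express alike) and adds `n_background`
#' pure-background pixels. Each pixel carries both channel intensities with
#' independent Gaussian pixel noise; spatial layout is not modelled because
#' no downstream computation uses it.
#'
#' @param params,spec as in [simulate_clone_trace()].
#' @param n_pixels_per_cell pixels representing each cell (>= 1).
#' @param n_background background pixels per frame.
#' @param pixel_background mean background intensity per channel.
#' @param pixel_noise_sd Gaussian pixel noise sd.
#' @param frames integer frame indices to render (default: all).
#' @return list of `well_pixel_frame` objects (fields `well_id`,
#'   `frame_index`, `time_hr`, `G`, `R`, `is_cell`), with attributes
#'   `background` and `background_sd` recording the generator's background
#'   model (the in-silico analogue of estimating background outside the
#'   well ROI).
#' @export
simulate_well_pixels <- function(params, spec, n_pixels_per_cell = 30,
                                 n_background = 50,
                                 pixel_background = 0.5,
                                 pixel_noise_sd = 0.05,
                                 frames = NULL) {
  stopifnot(inherits(params, "clone_params"), inherits(spec, "population_spec"))
  if (n_pixels_per_cell < 1) stopf("n_pixels_per_cell must be >= 1")
  times <- seq(0, spec$duration, by = spec$frame_interval)
  if (is.null(frames)) frames <- seq_along(times)
  sig_G <- channel_signal(times, params$onset_time_G, params$amplitude_G,
                          params$rise_width, params$noise_sd,
                          params$division_times)
  sig_R <- channel_signal(times, params$onset_time_R, params$amplitude_R,
                          params$rise_width, params$noise_sd,
                          params$division_times)
  cells <- cell_count(times, params$division_times)
  well_id <- if (is.null(params$seed)) "well_1" else paste0("well_", params$seed)
  with_seed(params$seed, {
    lapply(frames, function(i) {
      n_cell_px <- cells[i] * n_pixels_per_cell
      share_G <- sig_G[i] / n_cell_px
      share_R <- sig_R[i] / n_cell_px
      n_px <- n_cell_px + n_background
      is_cell <- c(rep(TRUE, n_cell_px), rep(FALSE, n_background))
      G <- pixel_background + c(rep(share_G, n_cell_px), rep(0, n_background)) +
        stats::rnorm(n_px, sd = pixel_noise_sd)
      R <- pixel_background + c(rep(share_R, n_cell_px), rep(0, n_background)) +
        stats::rnorm(n_px, sd = pixel_noise_sd)
      structure(
        list(well_id = well_id, frame_index = i, time_hr = times[i],
             G = pmax(G, 0), R = pmax(R, 0), is_cell = is_cell),
        class = "well_pixel_frame",
        background = c(G = pixel_background, R = pixel_background),
        background_sd = pixel_noise_sd
      )
    })
  })
}

#' Simulate a full micro-well population
#'
#' Draws fates from `fate_fractions`, onset times and first-division times
#' from the population spec's Gaussian distributions (onsets truncated at 0; draws
#' landing beyond the imaging window simply never rise, emulating
#' end-of-experiment censoring), then renders every clone's trace and,
#' optionally, pixel frames.
#'
#' @param spec a [population_spec()].
#' @param seed integer seed for the whole population.
#' @param render_pixels render pixel frames for the first `n_pixel_wells`
#'   wells (pixel rendering dominates runtime, so it is opt-in).
#' @param n_pixel_wells number of wells to render when `render_pixels`.
#' @param pixel_args list of arguments passed on to
#'   [simulate_well_pixels()].
#' @return list with `spec`, `params` (list of [clone_params()]), `traces`
#'   (list of `clone_trace`), `frames` (named list of pixel-frame lists or
#'   empty), and `metadata` (one row per well: `well_id`, `condition`,
#'   `n_cells_t0`, `n_beads_t0`, `true_fate`, `onset_G`, `onset_R`,
#'   `first_division_time`).
#' @export
simulate_population <- function(spec, seed = NULL, render_pixels = FALSE,
                                n_pixel_wells = 50, pixel_args = list()) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_clones
  if (n < 1) stopf("simulation stage: n_clones must be >= 1")
  draws <- with_seed(seed, {
    fates <- sample(names(spec$fate_fractions), n, replace = TRUE,
                    prob = spec$fate_fractions)
    onset_G <- pmax(stats::rnorm(n, spec$onset_G_dist[1], spec$onset_G_dist[2]), 0)
    onset_R <- pmax(stats::rnorm(n, spec$onset_R_dist[1], spec$onset_R_dist[2]), 0)
    division <- pmax(stats::rnorm(n, spec$division_time_dist[1],
                                  spec$division_time_dist[2]), 1)
    clone_seeds <- sample.int(1000000L, n)
    list(fates = fates, onset_G = onset_G, onset_R = onset_R,
         division = division, clone_seeds = clone_seeds)
  })
  params <- vector("list", n)
  traces <- vector("list", n)
  frames <- list()
  for (i in seq_len(n)) {
    fate <- draws$fates[i]
    params[[i]] <- clone_params(
      fate = fate,
      onset_time_G = if (fate %in% c("SPR", "DP")) draws$onset_G[i] else NA_real_,
      onset_time_R = if (fate %in% c("SPF", "DP")) draws$onset_R[i] else NA_real_,
      amplitude_G = spec$amplitude_G, amplitude_R = spec$amplitude_R,
      baseline = spec$baseline, rise_width = spec$rise_width,
      division_times = draws$division[i], noise_sd = spec$noise_sd,
      seed = draws$clone_seeds[i]
    )
    tr <- simulate_clone_trace(params[[i]], spec)
    attr(tr, "well_id") <- sprintf("%s_w%04d", spec$condition, i)
    traces[[i]] <- tr
    if (render_pixels && i <= n_pixel_wells) {
      fr <- do.call(simulate_well_pixels,
                    c(list(params = params[[i]], spec = spec), pixel_args))
      fr <- lapply(fr, function(f) { f$well_id <- attr(tr, "well_id"); f })
      frames[[attr(tr, "well_id")]] <- fr
    }
  }
  metadata <- data.frame(
    well_id = vapply(traces, attr, character(1), "well_id"),
    condition = spec$condition,
    n_cells_t0 = 1L,
    n_beads_t0 = 1L,
    true_fate = draws$fates,
    onset_G = ifelse(draws$fates %in% c("SPR", "DP"), draws$onset_G, NA_real_),
    onset_R = ifelse(draws$fates %in% c("SPF", "DP"), draws$onset_R, NA_real_),
    first_division_time = draws$division,
    stringsAsFactors = FALSE
  )
  list(spec = spec, params = params, traces = traces, frames = frames,
       metadata = metadata)
}
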