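# Shared builders for the test suite. Everything is generated in code;
# no fixture files.

# A single-fate population spec with the study's default distributions.
single_fate_spec <- function(fate, n_clones, condition = "Th17", ...) {
  ff <- stats::setNames(as.numeric(c("SPR", "SPF", "DP", "DN") == fate),
                        c("SPR", "SPF", "DP", "DN"))
  population_spec(condition, fate_fractions = ff, n_clones = n_clones, ...)
}

# A minimal noise-free pixel frame with explicit channel vectors.
make_frame <- function(G, R, time_hr = 0, frame_index = 1, well_id = "w",
                       background = c(G = 0, R = 0), background_sd = 0) {
  structure(
    list(well_id = well_id, frame_index = frame_index, time_hr = time_hr,
         G = G, R = R, is_cell = rep(TRUE, length(G))),
    class = "well_pixel_frame",
    background = background, background_sd = background_sd
  )
}

# Five identical frames from one pixel set (for angle pooling tests).
make_well <- function(G, R, well_id = "w", ...) {
  lapply(1:5, function(i) {
    f <- make_frame(G, R, time_hr = i - 1, frame_index = i,
                    well_id = well_id, ...)
    f
  })
}

# A hand-built clone trace on an arbitrary grid.
make_trace <- function(total_G, total_R, interval = 0.5, well_id = "w",
                       condition = "Th17", division_times = numeric()) {
  n <- length(total_G)
  structure(
    data.frame(time_hr = seq(0, by = interval, length.out = n),
               total_G = total_G, total_R = total_R),
    class = c("clone_trace", "data.frame"),
    well_id = well_id, condition = condition,
    n_cells_t0 = 1L, n_beads_t0 = 1L,
    division_times = division_times, true_fate = NA_character_
  )
}

# Independent brute-force oracle for rise times: scan every frame and test
# the persistence window explicitly.
oracle_rise_time <- function(values, times, threshold, persistence) {
  for (i in seq_len(length(values) - persistence + 1)) {
    if (all(values[i:(i + persistence - 1)] > threshold)) return(times[i])
  }
  NA_real_
}

# Independent brute-force oracle for peak detection: exhaustive scan for
# local maxima, prominence by full left/right walks, then greedy
# separation, mirroring the documented rules.
oracle_peaks <- function(y, centers, min_prominence_frac, min_separation) {
  n <- length(y)
  if (n == 0 || max(y) == 0) return(integer(0))
  cand <- integer(0)
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1] == y[i]) j <- j + 1
    left_ok <- i == 1 || y[i - 1] < y[i]
    right_ok <- j == n || y[j + 1] < y[i]
    if (left_ok && right_ok) cand <- c(cand, (i + j) %/% 2L)
    i <- j + 1
  }
  prom <- vapply(cand, function(p) {
    h <- y[p]
    walk <- function(idx) {
      lowest <- h
      for (q in idx) {
        if (y[q] > h) return(c(lowest, TRUE))
        lowest <- min(lowest, y[q])
      }
      c(lowest, FALSE)
    }
    l <- if (p > 1) walk((p - 1):1) else c(h, FALSE)
    r <- if (p < n) walk((p + 1):n) else c(h, FALSE)
    key <- if (l[2] && r[2]) max(l[1], r[1])
           else if (l[2]) l[1]
           else if (r[2]) r[1]
           else min(l[1], r[1])
    h - key
  }, numeric(1))
  ok <- prom >= min_prominence_frac * max(y)
  cand <- cand[ok]
  keep <- integer(0)
  for (p in cand[order(y[cand], decreasing = TRUE)]) {
    if (!length(keep) ||
        all(abs(centers[p] - centers[keep]) >= min_separation)) {
      keep <- c(keep, p)
    }
  }
  sort(keep)
}
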