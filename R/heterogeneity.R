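#' Pixel angles of one frame in the RFP--GFP plane
#'
#' Background-subtracts and clips both channels, drops pixels whose
#' combined intensity falls below `intensity_floor` (near-background pixels
#' have noise-dominated angles), and returns `atan2(G, R)` in degrees:
#' pure GFP pixels map to 90 degrees, pure RFP to 0, balanced
#' co-expression to 45. Pixels at exactly (0, 0) after clipping are
#' excluded rather than assigned an angle.
#'
#' @param frame a `well_pixel_frame`.
#' @param intensity_floor minimum background-subtracted `G + R` for a pixel
#'   to be retained (default: twice the sd of the combined background
#'   noise, when the frame records its background model; else 0).
#' @param background length-2 `c(G, R)` background to subtract (default:
#'   the frame's recorded background, else 0).
#' @return numeric vector of angles in `[0, 90]` degrees.
#' @export
pixel_angles <- function(frame, intensity_floor = NULL, background = NULL) {
  if (is.null(background)) {
    background <- attr(frame, "background") %||% c(0, 0)
  }
  if (is.null(intensity_floor)) {
    bg_sd <- attr(frame, "background_sd")
    intensity_floor <- if (is.null(bg_sd)) 0 else 2 * sqrt(2) * bg_sd
  }
  if (intensity_floor < 0) stopf("intensity_floor must be >= 0")
  G <- pmax(frame$G - background[[1]], 0)
  R <- pmax(frame$R - background[[2]], 0)
  keep <- (G + R) >= intensity_floor & (G + R) > 0
  atan2(G[keep], R[keep]) * 180 / pi
}

#' Smoothed pixel-angle distribution over the final frames
#'
#' Pools pixel angles over the last `n_frames` frames of a well into a
#' histogram on `[0, 90]` degrees (bins centred on multiples of
#' `bin_width`, so the pure-channel anchors 0/45/90 sit at bin centres) and
#' smooths it with a Gaussian kernel using reflecting boundaries at 0 and
#' 90 degrees.
#'
#' @param frames list of `well_pixel_frame`s; the last `n_frames` by time
#'   are used (fewer is an error).
#' @param bin_width_deg histogram bin width in degrees (default 3).
#' @param smoothing_sigma_bins Gaussian kernel sd in bins (default 2).
#' @param n_frames number of final frames to pool (default 5).
#' @param min_pixels wells retaining fewer pooled pixels than this are
#'   flagged empty (default 20): a distribution cannot be assessed from a
#'   handful of noise pixels.
#' @inheritParams pixel_angles
#' @return `angle_distribution`: list with `well_id`, `bin_centers`,
#'   `bin_width`, `counts`, `smoothed`, `n_pixels`, `empty`.
#' @export
angle_distribution <- function(frames, bin_width_deg = 3,
                               smoothing_sigma_bins = 2, n_frames = 5,
                               intensity_floor = NULL, background = NULL,
                               min_pixels = 20) {
  if (length(frames) < n_frames) {
    stopf("angle_distribution needs at least %d frames, got %d",
          n_frames, length(frames))
  }
  ord <- order(vapply(frames, function(f) f$time_hr, numeric(1)))
  last <- frames[ord][seq(length(frames) - n_frames + 1, length(frames))]
  angles <- unlist(lapply(last, pixel_angles,
                          intensity_floor = intensity_floor,
                          background = background))
  centers <- seq(0, 90, by = bin_width_deg)
  edges <- c(centers - bin_width_deg / 2, 90 + bin_width_deg / 2)
  counts <- as.integer(table(cut(angles, breaks = edges, include.lowest = TRUE)))
  empty <- length(angles) < min_pixels
  smoothed <- if (empty) rep(0, length(counts)) else {
    gaussian_smooth_reflect(counts, smoothing_sigma_bins)
  }
  structure(
    list(well_id = last[[1]]$well_id, bin_centers = centers,
         bin_width = bin_width_deg, counts = counts, smoothed = smoothed,
         n_pixels = length(angles), empty = empty),
    class = "angle_distribution"
  )
}

# Gaussian smoothing with reflecting boundaries. `sigma` in bins; kernel
# truncated at 4 sigma.
gaussian_smooth_reflect <- function(x, sigma) {
  if (sigma <= 0) return(as.numeric(x))
  n <- length(x)
  half <- ceiling(4 * sigma)
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  pad <- c(rev(x[seq_len(min(half, n))]),
           x,
           rev(x[seq.int(n - min(half, n) + 1, n)]))
  # if half > n the reflection above is short; extend by repetition
  while (length(pad) < n + 2 * half) pad <- c(pad[1], pad, pad[length(pad)])
  sm <- stats::filter(pad, kern, sides = 2)
  as.numeric(sm[(half + 1):(half + n)])
}

#' Detect peaks in a smoothed angle distribution
#'
#' Local maxima of the smoothed density are kept if their topographic
#' prominence reaches `min_prominence_frac` of the density maximum and,
#' greedily from the highest peak down, if they are at least
#' `min_separation_deg` away from every already-kept peak. The number of
#' peaks is reported in the categories 0 / 1 / 2, where "2" means two or
#' more; a well is called heterogeneous when it shows >= 2 peaks.
#'
#' @param dist an [angle_distribution()].
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   density maximum. The default 0.1 is calibrated so that slow angle
#'   drift within the pooled endpoint window of a homogeneous clone (a
#'   late-rising channel moving the whole distribution) does not register
#'   as a second peak, while genuinely mixed wells, whose secondary mode
#'   carries a comparable pixel mass, are far above it.
#' @param min_separation_deg minimum distance between reported peaks
#'   (default 15).
#' @return `peak_report`: list with `well_id`, `n_peaks` (capped category),
#'   `n_peaks_raw`, `peak_angles`, `peak_heights`, `peak_prominences`,
#'   `classification` (`"homogeneous"` or `"heterogeneous"`).
#' @export
detect_peaks <- function(dist, min_prominence_frac = 0.1,
                         min_separation_deg = 15) {
  stopifnot(inherits(dist, "angle_distribution"))
  y <- dist$smoothed
  cand <- local_maxima(y)
  keep <- integer(0)
  if (length(cand) && max(y) > 0) {
    prom <- vapply(cand, function(i) peak_prominence(y, i), numeric(1))
    ok <- prom >= min_prominence_frac * max(y)
    cand <- cand[ok]; prom <- prom[ok]
    # greedy separation filter, highest first
    ord <- order(y[cand], decreasing = TRUE)
    for (i in cand[ord]) {
      if (!length(keep) ||
          all(abs(dist$bin_centers[i] - dist$bin_centers[keep]) >=
              min_separation_deg)) {
        keep <- c(keep, i)
      }
    }
    keep <- sort(keep)
  }
  n_raw <- length(keep)
  structure(
    list(well_id = dist$well_id,
         n_peaks = min(n_raw, 2L),
         n_peaks_raw = n_raw,
         peak_angles = dist$bin_centers[keep],
         peak_heights = y[keep],
         peak_prominences = if (n_raw) vapply(keep, function(i) peak_prominence(y, i), numeric(1)) else numeric(0),
         classification = if (n_raw >= 2) "heterogeneous" else "homogeneous"),
    class = "peak_report"
  )
}

# Indices of strict local maxima; plateaus collapse to their central index.
# A run of equal values is a maximum if both flanking values are lower
# (boundaries count as lower when the run touches an edge and the array is
# not constant-positive everywhere, in which case the single plateau is one
# maximum).
local_maxima <- function(y) {
  n <- length(y)
  if (n == 0 || max(y) == 0) return(integer(0))
  r <- rle(y)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  m <- length(r$values)
  out <- integer(0)
  for (j in seq_len(m)) {
    left_lower <- j == 1 || r$values[j - 1] < r$values[j]
    right_lower <- j == m || r$values[j + 1] < r$values[j]
    if (left_lower && right_lower) {
      out <- c(out, (starts[j] + ends[j]) %/% 2L)
    }
  }
  out
}

# Topographic prominence of the peak at index i: height minus the higher of
# the two key saddles (the minimum en route to the nearest higher ground on
# each side; the global minimum of the side if no higher ground exists).
peak_prominence <- function(y, i) {
  h <- y[i]
  side_min <- function(idx) {
    lowest <- h
    for (j in idx) {
      if (y[j] > h) return(lowest)
      lowest <- min(lowest, y[j])
    }
    lowest
  }
  left <- if (i > 1) side_min((i - 1):1) else h
  right <- if (i < length(y)) side_min((i + 1):length(y)) else h
  higher_left <- i > 1 && any(y[1:(i - 1)] > h)
  higher_right <- i < length(y) && any(y[(i + 1):length(y)] > h)
  key <- if (higher_left && higher_right) max(left, right)
         else if (higher_left) left
         else if (higher_right) right
         else min(left, right)
  h - key
}

#' Compose an artificial heterogeneous clone from two wells
#'
#' Framewise union of the pixel sets of two wells, producing the pixel
#' distribution of a hypothetical clone containing both populations; used
#' to validate that the peak detector flags truly mixed clones.
#'
#' @param well_a,well_b lists of `well_pixel_frame`s with matching frame
#'   counts.
#' @param fate_a,fate_b optional fate labels; identical fates trigger a
#'   warning (allowed, but not a validation pair).
#' @return list of combined `well_pixel_frame`s.
#' @export
compose_artificial_heterogeneous <- function(well_a, well_b,
                                             fate_a = NULL, fate_b = NULL) {
  if (length(well_a) != length(well_b)) {
    stopf("wells must have matching frame counts")
  }
  if (!is.null(fate_a) && !is.null(fate_b) && identical(fate_a, fate_b)) {
    warnf("composing two wells of the same fate class (%s); not a validation pair", fate_a)
  }
  Map(function(a, b) {
    structure(
      list(well_id = paste(a$well_id, b$well_id, sep = "+"),
           frame_index = a$frame_index, time_hr = a$time_hr,
           G = c(a$G, b$G), R = c(a$R, b$R),
           is_cell = c(a$is_cell %||% rep(NA, length(a$G)),
                       b$is_cell %||% rep(NA, length(b$G)))),
      class = "well_pixel_frame",
      background = attr(a, "background"),
      background_sd = attr(a, "background_sd")
    )
  }, well_a, well_b)
}

#' Specificity and sensitivity of the heterogeneity detector
#'
#' Runs the full angle-distribution + peak-detection pipeline on a set of
#' true-homogeneous wells and on composed artificial heterogeneous wells,
#' and reports the fraction of each called multi-peak (>= 2 peaks): the
#' false-positive rate and the sensitivity.
#'
#' @param homogeneous_wells list of wells (each a list of frames).
#' @param artificial_wells list of composed wells.
#' @param ... passed to [angle_distribution()] and [detect_peaks()]
#'   (`bin_width_deg`, `smoothing_sigma_bins`, `min_prominence_frac`,
#'   `min_separation_deg`, ...).
#' @return list with `frac_multipeak_homogeneous`,
#'   `frac_multipeak_artificial`, `n_homogeneous`, `n_artificial`,
#'   `reports_homogeneous`, `reports_artificial`.
#' @export
evaluate_detector <- function(homogeneous_wells, artificial_wells = list(), ...) {
  args <- list(...)
  dist_args <- args[names(args) %in% names(formals(angle_distribution))]
  peak_args <- args[names(args) %in% names(formals(detect_peaks))[-1]]
  run <- function(frames) {
    d <- do.call(angle_distribution, c(list(frames = frames), dist_args))
    do.call(detect_peaks, c(list(dist = d), peak_args))
  }
  rep_h <- lapply(homogeneous_wells, run)
  rep_a <- lapply(artificial_wells, run)
  multi <- function(reps) {
    if (!length(reps)) return(NA_real_)
    mean(vapply(reps, function(r) r$n_peaks >= 2, logical(1)))
  }
  list(frac_multipeak_homogeneous = multi(rep_h),
       frac_multipeak_artificial = multi(rep_a),
       n_homogeneous = length(rep_h), n_artificial = length(rep_a),
       reports_homogeneous = rep_h, reports_artificial = rep_a)
}

#' Tabulate peak-count categories across wells
#'
#' Aggregates a set of peak reports into the 0 / 1 / 2+ peak-count table
#' used to summarise intra-clonal homogeneity across an experiment.
#'
#' @param reports list of `peak_report`s.
#' @return data frame `n_peaks` (0, 1, 2), `wells`, `percent`.
#' @export
peak_count_table <- function(reports) {
  counts <- vapply(reports, function(r) r$n_peaks, integer(1))
  tab <- table(factor(counts, levels = 0:2))
  data.frame(n_peaks = 0:2, wells = as.integer(tab),
             percent = 100 * as.integer(tab) / max(length(counts), 1L))
}
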