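#' Pointwise median and spread traces per clone group
#'
#' Framewise median and standard deviation of total fluorescence per
#' channel across the traces of each fate group. All traces must share one
#' acquisition grid; no resampling is done.
#'
#' @param traces list of `clone_trace` objects.
#' @param fates character vector of group labels, one per trace.
#' @param min_traces minimum group size (default 3); smaller groups are
#'   dropped with a warning.
#' @return named list of `median_trace` data frames (`time_hr`, `median_G`,
#'   `std_G`, `median_R`, `std_R`) with attributes `population`, `n`.
#' @export
median_traces <- function(traces, fates, min_traces = 3) {
  stopifnot(length(traces) == length(fates))
  grid <- traces[[1]]$time_hr
  same <- vapply(traces, function(tr) {
    length(tr$time_hr) == length(grid) && all(tr$time_hr == grid)
  }, logical(1))
  if (!all(same)) stopf("all traces must share one time grid (no resampling)")
  out <- list()
  for (pop in unique(fates)) {
    grp <- traces[fates == pop]
    if (length(grp) < min_traces) {
      warnf("group %s has fewer than %d traces; skipped", pop, min_traces)
      next
    }
    G <- vapply(grp, function(tr) tr$total_G, numeric(length(grid)))
    R <- vapply(grp, function(tr) tr$total_R, numeric(length(grid)))
    mt <- data.frame(
      time_hr = grid,
      median_G = apply(G, 1, stats::median),
      std_G = apply(G, 1, stats::sd),
      median_R = apply(R, 1, stats::median),
      std_R = apply(R, 1, stats::sd)
    )
    attr(mt, "population") <- pop
    attr(mt, "n") <- length(grp)
    class(mt) <- c("median_trace", "data.frame")
    out[[pop]] <- mt
  }
  out
}

#' Phase-space trajectory of a median trace
#'
#' The group's path in the Foxp3--RORgt plane: x = median RFP (Foxp3),
#' y = median GFP (RORgt), ordered by time; start and end points flagged.
#'
#' @param median_trace a [median_traces()] element.
#' @return `trajectory` data frame (`time_hr`, `x`, `y`, `endpoint`).
#' @export
phase_trajectory <- function(median_trace) {
  stopifnot(inherits(median_trace, "median_trace"))
  n <- nrow(median_trace)
  tr <- data.frame(
    time_hr = median_trace$time_hr,
    x = median_trace$median_R,
    y = median_trace$median_G,
    endpoint = c("start", rep(NA_character_, max(n - 2, 0)), if (n > 1) "end"),
    stringsAsFactors = FALSE
  )
  class(tr) <- c("trajectory", "data.frame")
  tr
}

#' Extrapolated single-positive trajectory
#'
#' The trajectory a DP clone would follow if each reporter obeyed its
#' single-positive dynamics independently: at each time point, x is the
#' SPF group's median Foxp3 signal and y is the SPR group's median RORgt
#' signal.
#'
#' @param spr,spf `median_trace` objects for the SPR and SPF groups on the
#'   same time grid.
#' @return `trajectory` data frame as in [phase_trajectory()].
#' @export
extrapolated_trajectory <- function(spr, spf) {
  stopifnot(inherits(spr, "median_trace"), inherits(spf, "median_trace"))
  if (nrow(spr) != nrow(spf) || any(spr$time_hr != spf$time_hr)) {
    stopf("SPR and SPF median traces must share one time grid")
  }
  if (is.unsorted(spr$time_hr, strictly = TRUE)) {
    stopf("times must be strictly increasing")
  }
  n <- nrow(spr)
  tr <- data.frame(
    time_hr = spr$time_hr,
    x = spf$median_R,
    y = spr$median_G,
    endpoint = c("start", rep(NA_character_, max(n - 2, 0)), if (n > 1) "end"),
    stringsAsFactors = FALSE
  )
  class(tr) <- c("trajectory", "data.frame")
  tr
}

#' Normalized RMS distance between two trajectories
#'
#' Root-mean-square pointwise Euclidean distance between matched points,
#' divided by the RMS magnitude of the expected trajectory. Zero for
#' identical paths; invariant to a joint rescaling of both trajectories.
#'
#' @param observed,expected `trajectory` data frames of equal length.
#' @return non-negative dimensionless distance.
#' @export
trajectory_distance <- function(observed, expected) {
  if (nrow(observed) != nrow(expected)) {
    stopf("trajectories must have equal length")
  }
  num <- sqrt(mean((observed$x - expected$x)^2 + (observed$y - expected$y)^2))
  den <- sqrt(mean(expected$x^2 + expected$y^2))
  if (den == 0) {
    if (num == 0) return(0)
    stopf("expected trajectory has zero magnitude")
  }
  num / den
}

#' Bootstrap null for the DP-versus-extrapolation comparison
#'
#' Distribution of the trajectory distance expected from sampling noise
#' alone: the DP traces are repeatedly split into random halves, each
#' half's median phase trajectory is computed, and the distance between
#' the halves is recorded. A DP-versus-extrapolated distance inside this
#' null is indistinguishable from two samples of the same dynamics.
#'
#' @param dp_traces list of DP `clone_trace` objects (>= 6).
#' @param n_boot number of random splits.
#' @param seed RNG seed.
#' @return numeric vector of `n_boot` null distances.
#' @export
trajectory_split_null <- function(dp_traces, n_boot = 100, seed = NULL) {
  n <- length(dp_traces)
  if (n < 6) stopf("need >= 6 DP traces for a split null")
  with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n %/% 2)
      halves <- median_traces(
        c(dp_traces[idx], dp_traces[-idx]),
        rep(c("a", "b"), c(length(idx), n - length(idx)))
      )
      trajectory_distance(phase_trajectory(halves$a),
                          phase_trajectory(halves$b))
    }, numeric(1))
  })
}
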