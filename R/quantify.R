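#' Extract a total-fluorescence trace from pixel frames
#'
#' Sums background-subtracted pixel intensities per channel and frame:
#' `total_c = sum(max(pixel_c - background_c, 0))`. Frames with no pixels
#' contribute zero totals (with a warning).
#'
#' @param frames list of `well_pixel_frame` objects for one well, any order;
#'   the trace is ordered by `time_hr`.
#' @param background length-2 numeric `c(G, R)` background estimate per
#'   channel (defaults to the frames' recorded background model when
#'   present, else 0).
#' @param metadata optional named list/row with `condition`, `n_cells_t0`,
#'   `n_beads_t0`, `division_times` carried onto the trace.
#' @return a `clone_trace` data frame (`time_hr`, `total_G`, `total_R`).
#' @export
extract_well_trace <- function(frames, background = NULL, metadata = NULL) {
  if (!length(frames)) stopf("extract_well_trace needs at least one frame")
  if (is.null(background)) {
    background <- attr(frames[[1]], "background")
    if (is.null(background)) background <- c(G = 0, R = 0)
  }
  if (length(background) != 2 || any(background < 0)) {
    stopf("background must be two non-negative values c(G, R)")
  }
  times <- vapply(frames, function(f) f$time_hr, numeric(1))
  ord <- order(times)
  frames <- frames[ord]
  times <- times[ord]
  totals <- t(vapply(frames, function(f) {
    if (!length(f$G)) {
      warnf("well %s frame %s has no pixels; totals set to 0",
            f$well_id, f$frame_index)
      return(c(0, 0))
    }
    c(sum(pmax(f$G - background[[1]], 0)),
      sum(pmax(f$R - background[[2]], 0)))
  }, numeric(2)))
  md <- function(field, default) {
    if (!is.null(metadata) && !is.null(metadata[[field]])) metadata[[field]] else default
  }
  new_clone_trace(
    data.frame(time_hr = times, total_G = totals[, 1], total_R = totals[, 2]),
    well_id = frames[[1]]$well_id,
    condition = md("condition", NA_character_),
    n_cells_t0 = md("n_cells_t0", NA_integer_),
    n_beads_t0 = md("n_beads_t0", NA_integer_),
    division_times = md("division_times", numeric())
  )
}

#' Apply the well-inclusion filter
#'
#' Keeps wells seeded with exactly one cell and at least one activation
#' bead. When a calibrated [response_threshold] and per-well t0 signals are
#' supplied, wells already fluorescent in either channel at the start of
#' the experiment are additionally excluded, so every retained well begins
#' as a single naive cell.
#'
#' @param metadata data frame with `well_id`, `n_cells_t0`, `n_beads_t0`.
#' @param t0_signals optional data frame `well_id`, `t0_G`, `t0_R`.
#' @param threshold optional [compute_response_threshold()] result.
#' @return character vector of included `well_id`s.
#' @export
filter_wells <- function(metadata, t0_signals = NULL, threshold = NULL) {
  required <- c("well_id", "n_cells_t0", "n_beads_t0")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols)) {
    stopf("metadata is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  keep <- metadata$n_cells_t0 == 1L & metadata$n_beads_t0 >= 1L
  ids <- metadata$well_id[keep]
  if (!is.null(threshold) && !is.null(t0_signals)) {
    stopifnot(inherits(threshold, "response_threshold"))
    t0 <- t0_signals[match(ids, t0_signals$well_id), , drop = FALSE]
    dark <- t0$t0_G <= threshold$threshold_G & t0$t0_R <= threshold$threshold_R
    ids <- ids[!is.na(dark) & dark]
  }
  ids
}

#' t0 signals of a set of traces
#'
#' Convenience accessor: the first-frame totals per channel, used both for
#' threshold calibration and for the t0-fluorescence exclusion in
#' [filter_wells()].
#'
#' @param traces list of `clone_trace` objects.
#' @return data frame `well_id`, `t0_G`, `t0_R`.
#' @export
trace_t0_signals <- function(traces) {
  data.frame(
    well_id = vapply(traces, attr, character(1), "well_id"),
    t0_G = vapply(traces, function(tr) tr$total_G[1], numeric(1)),
    t0_R = vapply(traces, function(tr) tr$total_R[1], numeric(1)),
    stringsAsFactors = FALSE
  )
}
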