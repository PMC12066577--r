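#' Calibrate the response threshold from naive t0 signals
#'
#' The threshold separating naive background from reporter expression is
#' set per channel from the start-of-experiment signals of naive wells:
#' `threshold_c = mean_c + k * sd_c`.
#'
#' @param t0_G,t0_R numeric vectors of first-frame total fluorescence per
#'   channel (>= 10 wells each).
#' @param k number of standard deviations above the naive mean (default 3).
#' @return object of class `response_threshold` with `threshold_G`,
#'   `threshold_R` and the per-channel calibration `(mean, sd, k)`.
#' @export
compute_response_threshold <- function(t0_G, t0_R, k = 3) {
  if (length(t0_G) < 10 || length(t0_R) < 10) {
    stopf("threshold calibration needs >= 10 t0 measurements per channel")
  }
  if (!is_number(k) || k < 0) stopf("k must be a non-negative number")
  cal <- function(x) c(mean = mean(x), sd = stats::sd(x), k = k)
  cg <- cal(t0_G); cr <- cal(t0_R)
  structure(
    list(threshold_G = unname(cg["mean"] + k * cg["sd"]),
         threshold_R = unname(cr["mean"] + k * cr["sd"]),
         calibration = list(G = cg, R = cr)),
    class = "response_threshold"
  )
}

#' Rise time of a trace above the response threshold
#'
#' First time point opening a run of at least `persistence_frames`
#' consecutive frames strictly above the channel threshold; `NA` when no
#' such run occurs before the end of the trace. The persistence requirement
#' suppresses single-frame noise crossings.
#'
#' @param trace a `clone_trace`.
#' @param threshold a [compute_response_threshold()] result (or a number).
#' @param channel `"G"` or `"R"`.
#' @param persistence_frames minimum run length (default 2).
#' @return rise time in hours, or `NA_real_`.
#' @export
compute_rise_time <- function(trace, threshold, channel = c("G", "R"),
                              persistence_frames = 2) {
  channel <- match.arg(channel)
  thr <- if (inherits(threshold, "response_threshold")) {
    threshold[[paste0("threshold_", channel)]]
  } else if (is_number(threshold)) {
    threshold
  } else {
    stopf("threshold must be a response_threshold or a single number")
  }
  values <- trace[[paste0("total_", channel)]]
  if (length(values) < persistence_frames) {
    stopf("trace shorter than persistence_frames")
  }
  above <- values > thr
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  hit <- which(runs$values & runs$lengths >= persistence_frames)
  if (!length(hit)) return(NA_real_)
  trace$time_hr[starts[hit[1]]]
}

#' Classify one clone from its trace
#'
#' Fate is determined by which channels show a persistent rise by the end
#' of the experiment: both = DP, only GFP = SPR, only RFP = SPF, neither =
#' DN. Endpoint MFI per channel is the mean total fluorescence over the
#' last `endpoint_frames` frames.
#'
#' @inheritParams compute_rise_time
#' @param endpoint_frames frames in the endpoint window (default 5).
#' @return one-row data frame (`clone_call`): `well_id`, `condition`,
#'   `fate`, `rise_time_G`, `rise_time_R`, `endpoint_MFI_G`,
#'   `endpoint_MFI_R`, `first_division_time`.
#' @export
classify_clone <- function(trace, threshold, persistence_frames = 2,
                           endpoint_frames = 5) {
  rise_G <- compute_rise_time(trace, threshold, "G", persistence_frames)
  rise_R <- compute_rise_time(trace, threshold, "R", persistence_frames)
  fate <- if (!is.na(rise_G) && !is.na(rise_R)) "DP"
          else if (!is.na(rise_G)) "SPR"
          else if (!is.na(rise_R)) "SPF"
          else "DN"
  n <- nrow(trace)
  idx <- seq.int(max(1L, n - endpoint_frames + 1L), n)
  div <- attr(trace, "division_times")
  data.frame(
    well_id = attr(trace, "well_id") %||% NA_character_,
    condition = attr(trace, "condition") %||% NA_character_,
    fate = fate,
    rise_time_G = rise_G,
    rise_time_R = rise_R,
    endpoint_MFI_G = mean(trace$total_G[idx]),
    endpoint_MFI_R = mean(trace$total_R[idx]),
    first_division_time = if (length(div)) div[1] else NA_real_,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Censored-Gaussian MLE of the onset mean/sd: observed rise times are
# events, NA entries are right-censored at the experiment end.
censored_mean_fit <- function(x, horizon) {
  obs <- x[!is.na(x)]
  n_cens <- sum(is.na(x))
  if (length(obs) < 2) {
    return(list(mean = NA_real_, sd = NA_real_, sem = NA_real_))
  }
  time <- c(obs, rep(horizon, n_cens))
  event <- c(rep(1, length(obs)), rep(0, n_cens))
  fit <- survival::survreg(survival::Surv(time, event) ~ 1,
                           dist = "gaussian")
  list(mean = unname(stats::coef(fit)[1]),
       sd = fit$scale,
       sem = sqrt(fit$var[1, 1]))
}

#' Classify a whole population of traces
#'
#' Convenience wrapper running the full classification stage: calibrate the
#' naive threshold from t0 signals of seeding-filtered wells, drop wells
#' fluorescent at t0, then call [classify_clone()] on every retained trace.
#'
#' @param traces list of `clone_trace` objects.
#' @param metadata well metadata (see [filter_wells()]); defaults to the
#'   traces' own attributes.
#' @param k,persistence_frames,endpoint_frames see the underlying
#'   operations.
#' @return list with `calls` (data frame of clone calls), `threshold`, and
#'   `included` well ids.
#' @export
classify_population <- function(traces, metadata = NULL, k = 3,
                                persistence_frames = 2, endpoint_frames = 5) {
  if (is.null(metadata)) {
    metadata <- data.frame(
      well_id = vapply(traces, attr, character(1), "well_id"),
      n_cells_t0 = vapply(traces, function(tr) as.integer(attr(tr, "n_cells_t0") %||% 1L), integer(1)),
      n_beads_t0 = vapply(traces, function(tr) as.integer(attr(tr, "n_beads_t0") %||% 1L), integer(1)),
      stringsAsFactors = FALSE
    )
  }
  names(traces) <- vapply(traces, attr, character(1), "well_id")
  seeded <- filter_wells(metadata)
  t0 <- trace_t0_signals(traces[seeded])
  threshold <- compute_response_threshold(t0$t0_G, t0$t0_R, k = k)
  included <- filter_wells(metadata, t0_signals = t0, threshold = threshold)
  calls <- do.call(rbind, lapply(traces[included], classify_clone,
                                 threshold = threshold,
                                 persistence_frames = persistence_frames,
                                 endpoint_frames = endpoint_frames))
  rownames(calls) <- NULL
  list(calls = calls, threshold = threshold, included = included)
}

#' Group summaries and pairwise tests of rise times
#'
#' Per-group mean, sd, sem and median of the observed rise times, plus
#' Welch two-sample t-tests for the requested group pairs (all pairs by
#' default), mirroring the rise-time comparisons between SPR/DP and DP/SPF
#' clones.
#'
#' A fixed-duration experiment right-censors late risers: a clone whose
#' channel has not crossed the threshold by the final frame contributes no
#' observed rise time, so the plain mean of observed times underestimates
#' the population onset mean. When `censored_at` is supplied, `NA` entries
#' are treated as right-censored at that time and each group additionally
#' gets the censored-Gaussian maximum-likelihood estimate of the onset
#' mean and sd (via [survival::survreg()]), which is the unbiased group
#' summary for such data.
#'
#' @param groups named list of numeric rise-time vectors; `NA` marks a
#'   clone without an observed rise.
#' @param pairs optional list of length-2 character vectors naming group
#'   pairs to test.
#' @param censored_at end-of-experiment time in hours, or `NULL` to drop
#'   `NA`s without modelling censoring.
#' @return list with `summary` (data frame: group, n, n_censored, mean,
#'   sd, sem, median and, with `censored_at`, mle_mean, mle_sd, mle_sem)
#'   and `tests` (data frame: group1, group2, t, df, p_value; observed
#'   times only).
#' @export
summarize_rise_times <- function(groups, pairs = NULL, censored_at = NULL) {
  n_censored <- vapply(groups, function(x) sum(is.na(x)), integer(1))
  mle <- NULL
  if (!is.null(censored_at)) {
    mle <- lapply(groups, censored_mean_fit, horizon = censored_at)
  }
  groups <- lapply(groups, function(x) x[!is.na(x)])
  empty <- vapply(groups, length, integer(1)) == 0
  if (any(empty)) {
    warnf("dropping empty group(s): %s", paste(names(groups)[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  if (length(groups) < 1) stopf("no non-empty groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stopf("each group needs >= 2 defined rise times")
  }
  summary <- data.frame(
    group = names(groups),
    n = vapply(groups, length, integer(1)),
    n_censored = n_censored[names(groups)],
    mean = vapply(groups, mean, numeric(1)),
    sd = vapply(groups, stats::sd, numeric(1)),
    sem = vapply(groups, function(x) stats::sd(x) / sqrt(length(x)), numeric(1)),
    median = vapply(groups, stats::median, numeric(1)),
    stringsAsFactors = FALSE
  )
  if (!is.null(mle)) {
    mle <- mle[names(groups)]
    summary$mle_mean <- vapply(mle, `[[`, numeric(1), "mean")
    summary$mle_sd <- vapply(mle, `[[`, numeric(1), "sd")
    summary$mle_sem <- vapply(mle, `[[`, numeric(1), "sem")
  }
  rownames(summary) <- NULL
  if (is.null(pairs) && length(groups) >= 2) {
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  }
  tests <- NULL
  if (length(pairs)) {
    tests <- do.call(rbind, lapply(pairs, function(p) {
      tt <- stats::t.test(groups[[p[1]]], groups[[p[2]]], var.equal = FALSE)
      data.frame(group1 = p[1], group2 = p[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, stringsAsFactors = FALSE)
    }))
    rownames(tests) <- NULL
  }
  list(summary = summary, tests = tests)
}

#' Order of reporter rise relative to the first division
#'
#' For clones with an annotated first division, the fraction whose channel
#' rise time falls after the division, per channel; plus per-condition
#' median division times with a Welch test between conditions when two are
#' present. Quantifies whether reporter onset can be inherited from the
#' parental cell (rise before division) or must arise independently in the
#' daughters (rise after).
#'
#' @param calls data frame of clone calls (see [classify_clone()]).
#' @return list with `fraction_after_division` (named: G, R), `n` (clones
#'   entering each fraction), `division_summary` (per condition n, median,
#'   mean, sd, sem) and `division_test` (Welch test across conditions, or
#'   NULL). All `NULL`/`NA` when no divisions are annotated.
#' @export
division_vs_rise <- function(calls) {
  has_div <- !is.na(calls$first_division_time)
  if (!any(has_div)) {
    warnf("no division annotations present")
    return(list(fraction_after_division = c(G = NA_real_, R = NA_real_),
                n = c(G = 0L, R = 0L),
                division_summary = NULL, division_test = NULL))
  }
  dd <- calls[has_div, , drop = FALSE]
  frac <- function(rise) {
    ok <- !is.na(rise)
    if (!any(ok)) return(c(NA_real_, 0L))
    c(mean(rise[ok] > dd$first_division_time[ok]), sum(ok))
  }
  fg <- frac(dd$rise_time_G)
  fr <- frac(dd$rise_time_R)
  division_summary <- do.call(rbind, lapply(split(dd, dd$condition), function(d) {
    x <- d$first_division_time
    data.frame(condition = d$condition[1], n = length(x),
               median = stats::median(x), mean = mean(x), sd = stats::sd(x),
               sem = stats::sd(x) / sqrt(length(x)), stringsAsFactors = FALSE)
  }))
  rownames(division_summary) <- NULL
  division_test <- NULL
  conds <- unique(dd$condition)
  if (length(conds) == 2) {
    tt <- stats::t.test(first_division_time ~ condition, data = dd, var.equal = FALSE)
    division_test <- data.frame(group1 = conds[1], group2 = conds[2],
                                t = unname(tt$statistic), df = unname(tt$parameter),
                                p_value = tt$p.value, stringsAsFactors = FALSE)
  }
  list(fraction_after_division = c(G = fg[1], R = fr[1]),
       n = c(G = as.integer(fg[2]), R = as.integer(fr[2])),
       division_summary = division_summary,
       division_test = division_test)
}
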