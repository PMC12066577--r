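#' Quadrant-gate flow events into reporter states
#'
#' Assigns each event a fate by comparing its two channel intensities to
#' the calibrated thresholds: both above = DP, GFP only = SPR, RFP only =
#' SPF, neither = DN.
#'
#' @param events a flow event table (data frame with `G`, `R`).
#' @param threshold a [compute_response_threshold()] result or a named
#'   numeric `c(G = ..., R = ...)`.
#' @return the event table with a `fate` column appended.
#' @export
gate_events <- function(events, threshold) {
  if (inherits(threshold, "response_threshold")) {
    thr_G <- threshold$threshold_G; thr_R <- threshold$threshold_R
  } else {
    thr_G <- threshold[["G"]]; thr_R <- threshold[["R"]]
  }
  above_G <- events$G > thr_G
  above_R <- events$R > thr_R
  events$fate <- ifelse(above_G & above_R, "DP",
                 ifelse(above_G, "SPR",
                 ifelse(above_R, "SPF", "DN")))
  events
}

#' Calibrate flow gates from a negative (naive) event population
#'
#' Thresholds at `mean + k * sd` of each channel over the declared
#' negative events, the flow analogue of the imaging response threshold.
#'
#' @param negative_events data frame with `G`, `R` of unstimulated events.
#' @param k standard deviations above the negative mean (default 3).
#' @return a `response_threshold` object.
#' @export
calibrate_flow_gates <- function(negative_events, k = 3) {
  compute_response_threshold(negative_events$G, negative_events$R, k = k)
}

#' State-transition frequencies from gated, origin-traced events
#'
#' For every origin population (within condition and mixture ratio), the
#' fraction of its events gated into each destination state, with binomial
#' standard errors. Origin groups with fewer than 20 events are flagged
#' low-confidence.
#'
#' @param gated event table from [gate_events()] with an origin column.
#' @param origin_col name of the origin column (default `"origin"`; use a
#'   dye-to-origin mapping upstream for other staining designs).
#' @return data frame: `condition`, `mixture_ratio`, `origin`,
#'   `destination`, `n_origin`, `count`, `frequency`, `se`,
#'   `low_confidence`.
#' @export
transition_frequencies <- function(gated, origin_col = "origin") {
  if (!origin_col %in% names(gated)) {
    stopf("origin column '%s' not present; transition frequencies need traced origins",
          origin_col)
  }
  if (!"fate" %in% names(gated)) stopf("events must be gated first (no 'fate' column)")
  states <- c("SPR", "DP", "SPF", "DN")
  groups <- split(gated, list(gated$condition, gated$mixture_ratio,
                              gated[[origin_col]]), drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    n <- nrow(g)
    counts <- table(factor(g$fate, levels = states))
    p <- as.numeric(counts) / n
    data.frame(
      condition = g$condition[1], mixture_ratio = g$mixture_ratio[1],
      origin = g[[origin_col]][1], destination = states,
      n_origin = n, count = as.integer(counts),
      frequency = p, se = sqrt(p * (1 - p) / n),
      low_confidence = n < 20,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Homogeneity of a transition frequency across mixture ratios
#'
#' Chi-square test that the given origin-to-destination transition
#' frequency is the same at every co-culture composition, plus the largest
#' absolute frequency difference between ratios. A small maximum
#' difference with a non-significant test supports composition-independent
#' transitions.
#'
#' @param frequencies output of [transition_frequencies()].
#' @param origin,destination the transition to compare.
#' @return list with `statistic`, `df`, `p_value`, `max_abs_diff`,
#'   `ratios`, `frequencies`.
#' @export
compare_across_ratios <- function(frequencies, origin, destination) {
  rows <- frequencies[frequencies$origin == origin &
                      frequencies$destination == destination, , drop = FALSE]
  if (nrow(rows) < 2) {
    stopf("need >= 2 mixture ratios to compare (got %d)", nrow(rows))
  }
  hits <- rows$count
  n <- rows$n_origin
  test <- suppressWarnings(stats::prop.test(hits, n))
  list(statistic = unname(test$statistic),
       df = unname(test$parameter),
       p_value = test$p.value,
       max_abs_diff = max(rows$frequency) - min(rows$frequency),
       ratios = rows$mixture_ratio,
       frequencies = rows$frequency)
}
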