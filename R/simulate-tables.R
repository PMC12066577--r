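#' Default flow-cytometry population model
#'
#' Two-channel (GFP = RORgt, RFP = Foxp3) intensity means and sds for the
#' four gated states, in arbitrary flow units. Positive channels sit far
#' above the naive background so quadrant gating is essentially error-free,
#' as in a well-compensated experiment.
#'
#' @return list with `means` and `sds`, each a named list of `c(G, R)`.
#' @export
flow_population_defaults <- function() {
  list(
    means = list(DN  = c(G = 100,  R = 100),
                 SPR = c(G = 2000, R = 105),
                 SPF = c(G = 108,  R = 2100),
                 DP  = c(G = 1900, R = 1950)),
    sds   = list(DN  = c(G = 30,  R = 30),
                 SPR = c(G = 400, R = 32),
                 SPF = c(G = 33,  R = 420),
                 DP  = c(G = 380, R = 390))
  )
}

#' Default co-culture transition probabilities
#'
#' Row = origin state, column = destination state after two days of
#' re-culture. Off-diagonal defaults follow the reported frequencies:
#' SPR to DP 21.7%, DP to SPR 15.01%, SPF to DP 30%.
#'
#' @return 4x4 row-stochastic matrix over SPR/DP/SPF/DN.
#' @export
default_transition_probs <- function() {
  states <- c("SPR", "DP", "SPF", "DN")
  m <- diag(4)
  dimnames(m) <- list(states, states)
  m["SPR", "DP"] <- 0.217;  m["SPR", "SPR"] <- 1 - 0.217
  m["DP", "SPR"] <- 0.1501; m["DP", "DP"]   <- 1 - 0.1501
  m["SPF", "DP"] <- 0.30;   m["SPF", "SPF"] <- 1 - 0.30
  m
}

#' Simulate a dye-labeled co-culture flow event table
#'
#' Each event originates in one population (per `origin_fractions`), may
#' transition to a destination state with the row probabilities of
#' `transition_probs`, and then has its two-channel intensities drawn from
#' the destination population's distribution (truncated at 0). The
#' proliferation-stable dye label is inherited from the origin, so origin
#' identity survives the transition, exactly as in the dye-tracing design.
#'
#' @param n_events number of events.
#' @param origin_fractions named fractions over origin states (sum to 1).
#' @param population_means,population_sds named lists of `c(G, R)` per
#'   state; defaults from [flow_population_defaults()].
#' @param transition_probs row-stochastic origin x destination matrix;
#'   default [default_transition_probs()].
#' @param dye_labeling if `TRUE`, emit `origin` and `dye_positive` columns
#'   (`dye_positive = origin == dye_positive_origin`); if `FALSE`, origins
#'   are untraceable and both columns are absent.
#' @param dye_positive_origin the stained origin population.
#' @param condition,mixture_ratio labels copied onto every event.
#' @param seed RNG seed.
#' @return `flow_event_table` data frame with `event_id`, `G`, `R`,
#'   (`origin`, `dye_positive`), `destination_true`, `condition`,
#'   `mixture_ratio`.
#' @export
simulate_flow_events <- function(n_events,
                                 origin_fractions = c(SPR = 0.5, DP = 0.5),
                                 population_means = NULL,
                                 population_sds = NULL,
                                 transition_probs = NULL,
                                 dye_labeling = TRUE,
                                 dye_positive_origin = "SPR",
                                 condition = "Th17",
                                 mixture_ratio = "50:50",
                                 seed = NULL) {
  defaults <- flow_population_defaults()
  if (is.null(population_means)) population_means <- defaults$means
  if (is.null(population_sds)) population_sds <- defaults$sds
  if (is.null(transition_probs)) transition_probs <- default_transition_probs()
  if (any(transition_probs < 0) || any(transition_probs > 1) ||
      any(abs(rowSums(transition_probs) - 1) > 1e-8)) {
    stopf("transition_probs rows must be probability distributions")
  }
  if (abs(sum(origin_fractions) - 1) > 1e-8 || any(origin_fractions < 0)) {
    stopf("origin_fractions must be non-negative and sum to 1")
  }
  with_seed(seed, {
    origin <- sample(names(origin_fractions), n_events, replace = TRUE,
                     prob = origin_fractions)
    dest <- vapply(origin, function(o) {
      sample(colnames(transition_probs), 1, prob = transition_probs[o, ])
    }, character(1))
    mu <- t(vapply(dest, function(d) population_means[[d]], numeric(2)))
    sd <- t(vapply(dest, function(d) population_sds[[d]], numeric(2)))
    tab <- data.frame(
      event_id = seq_len(n_events),
      G = pmax(stats::rnorm(n_events, mu[, 1], sd[, 1]), 0),
      R = pmax(stats::rnorm(n_events, mu[, 2], sd[, 2]), 0),
      destination_true = unname(dest),
      condition = condition,
      mixture_ratio = mixture_ratio,
      stringsAsFactors = FALSE
    )
    if (dye_labeling) {
      tab$origin <- unname(origin)
      tab$dye_positive <- tab$origin == dye_positive_origin
    }
    class(tab) <- c("flow_event_table", "data.frame")
    tab
  })
}

#' Simulate a three-population bulk expression table
#'
#' Every gene is constructed as differentially expressed between SPR and
#' SPF with a log2 separation of `effect_size` (random sign), and its DP
#' mean is placed on the SPR--SPF axis according to an assigned similarity
#' class, anchored at index 1 (SPR-like: DP equals SPR), 0 (intermediate),
#' -1 (SPF-like: DP equals SPF) or +/-2 (distinct), with optional uniform
#' jitter of half-width `class_spread` inside the class's bin. Replicates
#' add Gaussian noise. Default class fractions follow the reported
#' composition (~48% SPR-like, ~30% intermediate, ~20% distinct).
#'
#' @param n_genes number of genes.
#' @param frac_spr_like,frac_intermediate,frac_distinct class fractions
#'   (must sum to <= 1; remainder is SPF-like).
#' @param effect_size log2 separation between SPR and SPF means.
#' @param n_reps replicates per population (>= 2).
#' @param class_spread uniform jitter half-width around the class anchor
#'   (capped at 0.4 so jittered indices stay inside the class bin).
#' @param noise_sd replicate noise sd (log2 units).
#' @param base_mean typical log2 expression level.
#' @param seed RNG seed.
#' @return `expression_table`: list with `expr` (gene x sample log2
#'   matrix), `samples` (sample sheet: `sample`, `population`,
#'   `replicate`) and `truth` (`gene_id`, `class`, `similarity`).
#' @export
simulate_expression_table <- function(n_genes = 1500,
                                      frac_spr_like = 0.48,
                                      frac_intermediate = 0.30,
                                      frac_distinct = 0.20,
                                      effect_size = 2.5,
                                      n_reps = 3,
                                      class_spread = 0,
                                      noise_sd = 0.25,
                                      base_mean = 8,
                                      seed = NULL) {
  fr <- c(frac_spr_like, frac_intermediate, frac_distinct)
  if (any(fr < 0) || sum(fr) > 1 + 1e-8) {
    stopf("class fractions must be non-negative and sum to <= 1")
  }
  if (n_reps < 2) stopf("n_reps must be >= 2")
  with_seed(seed, {
    classes <- sample(c("SPR-like", "intermediate", "distinct", "SPF-like"),
                      n_genes, replace = TRUE,
                      prob = c(fr, 1 - sum(fr)))
    spread <- min(abs(class_spread), 0.4)
    s_true <- vapply(classes, function(cl) {
      anchor <- switch(cl,
                       "SPR-like" = 1,
                       "intermediate" = 0,
                       "SPF-like" = -1,
                       "distinct" = sample(c(-2, 2), 1))
      anchor + if (spread > 0) stats::runif(1, -spread, spread) else 0
    }, numeric(1))
    sign <- sample(c(-1, 1), n_genes, replace = TRUE)
    mean_spf <- stats::rnorm(n_genes, base_mean, 1.5)
    mean_spr <- mean_spf + sign * effect_size
    mean_dp <- mean_spf + (s_true + 1) / 2 * (mean_spr - mean_spf)
    pops <- c("SPR", "DP", "SPF")
    samples <- data.frame(
      sample = paste0(rep(pops, each = n_reps), "_r", seq_len(n_reps)),
      population = rep(pops, each = n_reps),
      replicate = rep(seq_len(n_reps), times = 3),
      stringsAsFactors = FALSE
    )
    means <- cbind(
      matrix(mean_spr, n_genes, n_reps),
      matrix(mean_dp, n_genes, n_reps),
      matrix(mean_spf, n_genes, n_reps)
    )
    expr <- means + matrix(stats::rnorm(length(means), sd = noise_sd),
                           nrow = n_genes)
    rownames(expr) <- sprintf("gene_%04d", seq_len(n_genes))
    colnames(expr) <- samples$sample
    structure(
      list(expr = expr, samples = samples,
           truth = data.frame(gene_id = rownames(expr), class = classes,
                              similarity = unname(s_true),
                              stringsAsFactors = FALSE)),
      class = "expression_table"
    )
  })
}
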