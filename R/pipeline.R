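#' Default end-to-end run configuration
#'
#' Every tunable parameter of the pipeline with its default, as a nested
#' list that round-trips losslessly through YAML. The defaults are the
#' study conditions: 52 hr imaging at 30-minute intervals, RORgt onsets
#' 21.8 +/- 9.4 hr, Foxp3 onsets 39.3 +/- 8.2 hr, Th17 fate fractions
#' 57/22/21 (SPR/DP/DN), first divisions 38.8 hr (Th17) and 36 hr (Treg),
#' threshold k = 3 with 2-frame persistence, 3-degree angle bins smoothed
#' with a 2-bin Gaussian, 5% prominence, 15-degree separation, fold-change
#' 2 with p < 0.05 for DE selection, and the reported co-culture
#' transition probabilities.
#'
#' @param seed global seed fanned out to per-stage child seeds
#'   (`stage seed = (seed mod 2e7) * 100 + stage index`).
#' @return a `run_config` list.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    populations = list(
      Th17 = list(condition = "Th17", n_clones = 300),
      Treg = list(condition = "Treg", n_clones = 300)
    ),
    classification = list(k = 3, persistence_frames = 2, endpoint_frames = 5),
    heterogeneity = list(
      bin_width_deg = 3, smoothing_sigma_bins = 2, n_frames = 5,
      min_prominence_frac = 0.1, min_separation_deg = 15, min_pixels = 20,
      n_pixel_wells = 40, n_pixels_per_cell = 30, n_background = 50,
      pixel_background = 0.5, pixel_noise_sd = 0.05, n_artificial_pairs = 20
    ),
    trajectory = list(n_boot = 50, agreement_threshold = 0.1),
    expression = list(n_genes = 1500, frac_spr_like = 0.48,
                      frac_intermediate = 0.30, frac_distinct = 0.20,
                      effect_size = 2.5, n_reps = 3, noise_sd = 0.25,
                      fc_threshold = 2, p_threshold = 0.05,
                      denominator_floor = 0.25),
    flow = list(n_events_per_ratio = 4000,
                mixture_ratios = c("100:0", "75:25", "50:50"))
  ), class = "run_config")
}

#' Read / write a run configuration
#'
#' @param path YAML file path.
#' @param config a `run_config` list.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- unclass(default_config(seed = cfg$seed %||% 1))
  cfg <- utils::modifyList(base, cfg)
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# FNV-1a hash of the deparsed config, recorded in every output so a result
# can be traced to the exact parameter set that produced it.
config_hash <- function(config) {
  bytes <- utf8ToInt(paste(deparse(unclass(config)), collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' simulate (both conditions, with pixel rendering for a subset of wells)
#' -> quantify/filter -> classify -> rise-time and division summaries ->
#' phase-space trajectory comparison -> pixel-angle heterogeneity ->
#' expression similarity -> co-culture transitions. Writes `calls.csv`,
#' `peaks.csv`, `trajectory.json`, `similarity.csv`, `transitions.csv` and
#' `summary.json` under `out_dir`; stages that already produced output
#' leave their files behind even if a later stage fails.
#'
#' @param config a `run_config` (see [default_config()]).
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @return (invisibly) list with all stage results and the `summary` list.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(name, writer) {
    if (!is.null(out_dir)) writer(file.path(out_dir, name))
  }
  seed <- config$seed
  hash <- config_hash(config)
  het <- config$heterogeneity
  cls <- config$classification

  # -- simulate ----------------------------------------------------------
  pops <- run_stage("simulate", {
    lapply(seq_along(config$populations), function(i) {
      pc <- config$populations[[i]]
      spec_args <- pc[names(pc) %in% names(formals(population_spec))]
      spec <- do.call(population_spec, spec_args)
      simulate_population(
        spec, seed = stage_seed(seed, i),
        render_pixels = TRUE, n_pixel_wells = het$n_pixel_wells,
        pixel_args = list(n_pixels_per_cell = het$n_pixels_per_cell,
                          n_background = het$n_background,
                          pixel_background = het$pixel_background,
                          pixel_noise_sd = het$pixel_noise_sd)
      )
    })
  })
  names(pops) <- names(config$populations)
  traces <- unlist(lapply(pops, `[[`, "traces"), recursive = FALSE)
  metadata <- do.call(rbind, lapply(pops, `[[`, "metadata"))
  rownames(metadata) <- NULL

  # -- classify ----------------------------------------------------------
  classified <- run_stage("classify", {
    res <- classify_population(traces, metadata[, c("well_id", "n_cells_t0", "n_beads_t0")],
                               k = cls$k, persistence_frames = cls$persistence_frames,
                               endpoint_frames = cls$endpoint_frames)
    res$calls$first_division_time <-
      metadata$first_division_time[match(res$calls$well_id, metadata$well_id)]
    res
  })
  calls <- classified$calls
  emit("calls.csv", function(p) utils::write.csv(calls, p, row.names = FALSE))

  rise <- run_stage("summarize", {
    groups <- list(
      SPR_G = calls$rise_time_G[calls$fate == "SPR" & calls$condition == "Th17"],
      DP_G = calls$rise_time_G[calls$fate == "DP" & calls$condition == "Th17"],
      DP_R = calls$rise_time_R[calls$fate == "DP" & calls$condition == "Th17"],
      SPF_R = calls$rise_time_R[calls$fate == "SPF" & calls$condition == "Treg"]
    )
    groups <- groups[vapply(groups, function(x) sum(!is.na(x)) >= 2, logical(1))]
    summarize_rise_times(groups, pairs = intersect_pairs(names(groups)))
  })
  division <- run_stage("summarize", division_vs_rise(calls))

  # -- trajectory --------------------------------------------------------
  trajectory <- run_stage("trajectory", {
    fate_of <- calls$fate[match(vapply(traces, attr, character(1), "well_id"),
                                calls$well_id)]
    keep <- !is.na(fate_of) & fate_of %in% c("SPR", "SPF", "DP")
    med <- median_traces(traces[keep], fate_of[keep])
    if (!all(c("SPR", "SPF", "DP") %in% names(med))) {
      stopf("need SPR, SPF and DP groups for the trajectory comparison")
    }
    dp_traj <- phase_trajectory(med$DP)
    extrap <- extrapolated_trajectory(med$SPR, med$SPF)
    dist <- trajectory_distance(dp_traj, extrap)
    null <- trajectory_split_null(traces[keep][fate_of[keep] == "DP"],
                                  n_boot = config$trajectory$n_boot,
                                  seed = stage_seed(seed, 21))
    list(distance = dist,
         null_q95 = unname(stats::quantile(null, 0.95)),
         agreement = dist <= config$trajectory$agreement_threshold,
         within_null = dist <= unname(stats::quantile(null, 0.95)),
         dp = dp_traj, extrapolated = extrap, null = null)
  })
  emit("trajectory.json", function(p) {
    jsonlite::write_json(
      list(config_hash = hash,
           distance = trajectory$distance,
           null_q95 = trajectory$null_q95,
           agreement = trajectory$agreement,
           dp = trajectory$dp[, c("time_hr", "x", "y")],
           extrapolated = trajectory$extrapolated[, c("time_hr", "x", "y")]),
      p, auto_unbox = TRUE, digits = NA)
  })

  # -- heterogeneity -----------------------------------------------------
  heterogeneity <- run_stage("heterogeneity", {
    wells <- unlist(lapply(pops, `[[`, "frames"), recursive = FALSE)
    names(wells) <- unlist(lapply(pops, function(p) names(p$frames)))
    fate_by_id <- stats::setNames(metadata$true_fate, metadata$well_id)
    well_fates <- fate_by_id[sub("^[^.]*\\.", "", names(wells))]
    # pair only wells that retain enough signal pixels on their own, the
    # in-silico analogue of composing pairs from classified (expressing)
    # single-positive wells
    bright <- vapply(wells, function(fr) {
      do.call(angle_distribution,
              c(list(frames = fr), list(bin_width_deg = het$bin_width_deg,
                                        smoothing_sigma_bins = het$smoothing_sigma_bins,
                                        n_frames = het$n_frames,
                                        min_pixels = het$min_pixels)))$n_pixels >= 100
    }, logical(1))
    spr_wells <- wells[well_fates == "SPR" & bright]
    spf_wells <- wells[well_fates == "SPF" & bright]
    n_pairs <- min(het$n_artificial_pairs, length(spr_wells), length(spf_wells))
    artificial <- lapply(seq_len(n_pairs), function(i) {
      compose_artificial_heterogeneous(spr_wells[[i]], spf_wells[[i]],
                                       fate_a = "SPR", fate_b = "SPF")
    })
    ev <- evaluate_detector(
      wells[well_fates != "DN"], artificial,
      bin_width_deg = het$bin_width_deg,
      smoothing_sigma_bins = het$smoothing_sigma_bins,
      n_frames = het$n_frames, min_pixels = het$min_pixels,
      min_prominence_frac = het$min_prominence_frac,
      min_separation_deg = het$min_separation_deg
    )
    ev$table <- peak_count_table(ev$reports_homogeneous)
    ev
  })
  emit("peaks.csv", function(p) {
    reports <- heterogeneity$reports_homogeneous
    df <- data.frame(
      well_id = vapply(reports, `[[`, character(1), "well_id"),
      n_peaks = vapply(reports, `[[`, integer(1), "n_peaks"),
      peak_angles = vapply(reports, function(r) paste(r$peak_angles, collapse = ";"), character(1)),
      classification = vapply(reports, `[[`, character(1), "classification"),
      stringsAsFactors = FALSE
    )
    utils::write.csv(df, p, row.names = FALSE)
  })

  # -- similarity --------------------------------------------------------
  similarity <- run_stage("similarity", {
    ex <- config$expression
    tab <- simulate_expression_table(
      n_genes = ex$n_genes, frac_spr_like = ex$frac_spr_like,
      frac_intermediate = ex$frac_intermediate,
      frac_distinct = ex$frac_distinct, effect_size = ex$effect_size,
      n_reps = ex$n_reps, noise_sd = ex$noise_sd,
      seed = stage_seed(seed, 31)
    )
    res <- similarity_analysis(tab, fc_threshold = ex$fc_threshold,
                               p_threshold = ex$p_threshold,
                               denominator_floor = ex$denominator_floor)
    res$table <- tab
    res
  })
  emit("similarity.csv", function(p) {
    utils::write.csv(similarity$per_gene, p, row.names = FALSE)
  })

  # -- transitions -------------------------------------------------------
  transitions <- run_stage("transitions", {
    fl <- config$flow
    negative <- simulate_flow_events(
      2000, origin_fractions = c(DN = 1),
      transition_probs = diag_transition(), dye_labeling = FALSE,
      seed = stage_seed(seed, 41)
    )
    gates <- calibrate_flow_gates(negative, k = cls$k)
    tables <- lapply(seq_along(fl$mixture_ratios), function(i) {
      ratio <- fl$mixture_ratios[i]
      parts <- as.numeric(strsplit(ratio, ":")[[1]])
      ev <- simulate_flow_events(
        fl$n_events_per_ratio,
        origin_fractions = c(SPR = parts[1], DP = parts[2]) / sum(parts),
        mixture_ratio = ratio,
        seed = stage_seed(seed, 41 + i)
      )
      gate_events(ev, gates)
    })
    freq <- do.call(rbind, lapply(tables, transition_frequencies))
    comparison <- compare_across_ratios(
      freq[freq$n_origin > 0, ], origin = "SPR", destination = "DP"
    )
    list(frequencies = freq, comparison = comparison, gates = gates)
  })
  emit("transitions.csv", function(p) {
    utils::write.csv(transitions$frequencies, p, row.names = FALSE)
  })

  # -- summary -----------------------------------------------------------
  fate_tab <- table(factor(calls$fate, levels = c("SPR", "DP", "SPF", "DN")),
                    calls$condition)
  spr_dp <- transitions$frequencies
  spr_dp <- spr_dp[spr_dp$origin == "SPR" & spr_dp$destination == "DP" &
                   spr_dp$mixture_ratio == "100:0", , drop = FALSE]
  summary <- list(
    config_hash = hash,
    seed = seed,
    n_wells = nrow(calls),
    fate_fractions = lapply(colnames(fate_tab), function(cc) {
      as.list(prop.table(fate_tab[, cc]))
    }) |> stats::setNames(colnames(fate_tab)),
    rise_times = rise$summary,
    rise_time_tests = rise$tests,
    division = list(
      fraction_after_division = as.list(division$fraction_after_division),
      summary = division$division_summary
    ),
    trajectory = list(distance = trajectory$distance,
                      null_q95 = trajectory$null_q95,
                      agreement = trajectory$agreement,
                      within_null = trajectory$within_null),
    heterogeneity = list(
      frac_multipeak_homogeneous = heterogeneity$frac_multipeak_homogeneous,
      frac_multipeak_artificial = heterogeneity$frac_multipeak_artificial,
      table = heterogeneity$table
    ),
    similarity = list(
      n_de = length(similarity$de$union),
      de_per_pair = as.list(similarity$de$n_per_pair),
      bin_fractions = as.list(similarity$fractions)
    ),
    transitions = list(
      SPR_to_DP = if (nrow(spr_dp)) spr_dp$frequency else NA_real_,
      comparison_p = transitions$comparison$p_value,
      max_abs_diff = transitions$comparison$max_abs_diff
    )
  )
  emit("summary.json", function(p) {
    jsonlite::write_json(summary, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  })
  invisible(list(populations = pops, calls = calls,
                 threshold = classified$threshold, rise = rise,
                 division = division, trajectory = trajectory,
                 heterogeneity = heterogeneity, similarity = similarity,
                 transitions = transitions, summary = summary))
}

# identity transition matrix (no transitions)
diag_transition <- function() {
  m <- diag(4)
  dimnames(m) <- list(c("SPR", "DP", "SPF", "DN"), c("SPR", "DP", "SPF", "DN"))
  m
}

# rise-time test pairs actually present
intersect_pairs <- function(groups) {
  wanted <- list(c("SPR_G", "DP_G"), c("DP_R", "SPF_R"))
  Filter(function(p) all(p %in% groups), wanted)
}
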