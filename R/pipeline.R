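#' Run one paired mortality experiment on a culture
#'
#' At one start time along a culture trajectory, runs the three mortality
#' measurements over the same window: a virtual dilution series, a virtual
#' FLB disappearance experiment, and direct observation of the undisturbed
#' culture; also reads the true grazing/lysis decomposition off the loss
#' ledger.
#'
#' @param sc a \code{\link{scenario}} list (or any list with
#'   \code{params}, \code{init}, \code{t_grid}).
#' @param traj the culture \code{\link{trajectory}} (simulated from
#'   \code{sc} if missing).
#' @param t_start experiment start time (d).
#' @param duration incubation length (d).
#' @param fractions dilution fractions of whole water.
#' @param tracer_fraction FLB addition as a fraction of prey abundance.
#' @param replicates bottles per treatment level.
#' @param sampling a \code{\link{sampling_model}}; its seed is used for
#'   all bottles of this experiment.
#' @param alpha significance level for detectability.
#' @return list with \code{dilution}, \code{dilution_two_point},
#'   \code{flb}, \code{observed} (\code{\link{rate_estimate}}s) and
#'   \code{truth} (the \code{\link{true_mortality}} decomposition),
#'   plus \code{window}.
#' @export
run_experiment <- function(sc, traj = NULL, t_start, duration = 0.25,
                           fractions = c(1, 0.8, 0.4, 0.2),
                           tracer_fraction = 0.25, replicates = 3L,
                           sampling = sampling_model(), alpha = 0.05) {
  if (is.null(traj))
    traj <- simulate_community(sc$params, sc$init, sc$t_grid)
  window <- c(t_start, t_start + duration)
  state <- state_at(traj, t_start)
  # distinct RNG substreams per experiment arm
  s_dln <- sampling; s_dln$seed <- sampling$seed
  s_flb <- sampling; s_flb$seed <- sampling$seed + 1L
  s_obs <- sampling; s_obs$seed <- sampling$seed + 2L

  label <- if (is.null(sc$label)) NA_character_ else sc$label
  dln_bottles <- make_dilution_series(sc$params, state,
                                      fractions = fractions,
                                      duration = duration,
                                      replicates = replicates,
                                      sampling = s_dln,
                                      scenario = label)
  flb_bottles <- make_flb_experiment(sc$params, state,
                                     tracer_fraction = tracer_fraction,
                                     duration = duration,
                                     replicates = replicates,
                                     sampling = s_flb,
                                     scenario = label)
  obs_bottles <- observe_culture(traj, window, replicates = replicates,
                                 sampling = s_obs, scenario = label)

  observed <- observed_mortality(obs_bottles, alpha = alpha)
  pts <- dilution_points(dln_bottles)
  dln <- fit_dilution(pts, alpha = alpha, window = window,
                      mean_log10_P = observed$mean_log10_P)
  two_fr <- sort(fractions)[1:2]
  dln2 <- fit_dilution_two_point(pts, fractions = two_fr, alpha = alpha,
                                 window = window,
                                 mean_log10_P = observed$mean_log10_P)
  flb <- estimate_flb(flb_bottles, alpha = alpha,
                      mean_log10_P = observed$mean_log10_P)
  flb$window <- window

  list(dilution = dln, dilution_two_point = dln2, flb = flb,
       observed = observed, truth = true_mortality(traj, window),
       window = window,
       bottles = rbind(dln_bottles, flb_bottles, obs_bottles))
}

#' Run the laboratory comparison over a culture's decline
#'
#' Repeats \code{\link{run_experiment}} at a sequence of start times along
#' one scenario's trajectory and assembles the paired comparison records:
#' estimated vs observed rate, percent difference, and the mean log10 prey
#' abundance indexing each experiment. Windows whose observed rate is a
#' non-detect (reported 0) are excluded from percent differences with a
#' recorded reason, as the ratio is undefined.
#'
#' @param sc a \code{\link{scenario}}.
#' @param t_starts experiment start times (d); the default spans the
#'   decline phase of the built-in laboratory scenarios.
#' @param seed base integer seed; experiment i uses seed + 10 i.
#' @param noise counting-noise model for all bottles.
#' @param analyzed_volume enumerated volume (mL).
#' @inheritParams run_experiment
#' @return data.frame of comparison records with columns \code{method},
#'   \code{treatment}, \code{t0}, \code{t1}, \code{estimated},
#'   \code{observed}, \code{true_grazing}, \code{true_total},
#'   \code{percent_difference}, \code{mean_log10_P}, \code{detectable};
#'   excluded windows carried with \code{excluded_reason} set.
#' @export
run_lab_comparison <- function(sc, t_starts = seq(1, 2.25, by = 1 / 8),
                               duration = 0.25,
                               fractions = c(1, 0.8, 0.4, 0.2),
                               tracer_fraction = 0.25, replicates = 3L,
                               analyzed_volume = 0.05,
                               noise = "poisson", seed = 0L,
                               alpha = 0.05) {
  traj <- simulate_community(sc$params, sc$init, sc$t_grid)
  treatment <- if (grepl("virus", sc$label)) "grazer_virus" else
    "grazer_only"
  rows <- list()
  for (i in seq_along(t_starts)) {
    smp <- sampling_model(analyzed_volume, noise,
                          seed = as.integer(seed + 10L * i))
    ex <- tryCatch(
      run_experiment(sc, traj, t_starts[i], duration = duration,
                     fractions = fractions,
                     tracer_fraction = tracer_fraction,
                     replicates = replicates, sampling = smp,
                     alpha = alpha),
      error = function(e) NULL)
    if (is.null(ex)) next  # e.g. prey crashed to zero counts
    obs <- ex$observed
    for (method in c("dilution", "flb")) {
      est <- ex[[method]]
      excluded <- if (obs$value == 0) "observed_zero" else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        method = method, treatment = treatment, scenario = sc$label,
        t0 = ex$window[1], t1 = ex$window[2],
        estimated = est$value, estimated_raw = est$raw_value,
        observed = obs$value,
        true_grazing = ex$truth$grazing, true_total = ex$truth$total,
        percent_difference = if (is.na(excluded))
          percent_difference(est$value, obs$value) else NA_real_,
        mean_log10_P = obs$mean_log10_P,
        detectable = est$detectable,
        excluded_reason = excluded,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Apply the outlier rule to comparison records
#'
#' Removes percent-difference outliers separately per method using the
#' IQR fences, after dropping records excluded upstream (observed-zero
#' windows).
#'
#' @param records output of \code{\link{run_lab_comparison}}.
#' @param k IQR fence multiplier.
#' @return the kept records, with attribute \code{n_removed} (per method).
#' @export
filter_comparison <- function(records, k = 1.5) {
  records <- records[is.na(records$excluded_reason), , drop = FALSE]
  kept <- list(); removed <- integer(0)
  for (m in unique(records$method)) {
    sub <- records[records$method == m, , drop = FALSE]
    f <- iqr_filter(sub$percent_difference, k = k)
    keep <- sub$percent_difference >= f$fences[1] &
      sub$percent_difference <= f$fences[2]
    kept[[m]] <- sub[keep, , drop = FALSE]
    removed[m] <- sum(!keep)
  }
  out <- do.call(rbind, kept)
  rownames(out) <- NULL
  attr(out, "n_removed") <- removed
  out
}

#' Laboratory summary table
#'
#' Method x treatment means with standard errors for estimated rates,
#' observed rates and percent differences — the shape of the laboratory
#' summary.
#'
#' @param records filtered comparison records.
#' @return data.frame with one row per method x treatment.
#' @export
lab_summary <- function(records) {
  est <- summarize_rates(records, "estimated", c("method", "treatment"))
  obs <- summarize_rates(records, "observed", c("method", "treatment"))
  pd <- summarize_rates(records, "percent_difference",
                        c("method", "treatment"))
  out <- est
  names(out)[names(out) %in% c("mean", "se")] <- c("estimated_mean",
                                                   "estimated_se")
  out$observed_mean <- obs$mean
  out$observed_se <- obs$se
  out$pct_diff_mean <- pd$mean
  out$pct_diff_se <- pd$se
  out
}

#' Estimator recovery study
#'
#' Repeats one scenario's paired experiment across many counting-noise
#' seeds and reports, per estimator, the ratio of estimate to true grazing
#' mortality — the accuracy/precision characterization of the estimators
#' under controlled conditions.
#'
#' @param sc a \code{\link{scenario}}; the experiment runs from the
#'   scenario's initial state.
#' @param n_reps number of seeded replicates.
#' @param seed base seed; replicate i uses seed + 100 i.
#' @param t_start,duration experiment window (d).
#' @param analyzed_volume enumerated volume (mL); the default 1 mL keeps
#'   expected counts >= 10^4 in every bottle of the ideal scenarios.
#' @param tracer_fraction FLB addition as a fraction of prey.
#' @param alpha significance level.
#' @return data.frame with one row per replicate: \code{dilution},
#'   \code{dilution_raw}, \code{flb}, \code{true_grazing}, and the ratio
#'   columns \code{dilution_ratio}, \code{flb_ratio}.
#' @export
recovery_study <- function(sc, n_reps = 100L, seed = 0L, t_start = 0,
                           duration = 0.5, analyzed_volume = 1,
                           tracer_fraction = 0.25, alpha = 0.05) {
  traj <- simulate_community(sc$params, sc$init, sc$t_grid)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    smp <- sampling_model(analyzed_volume, "poisson",
                          seed = as.integer(seed + 100L * i))
    ex <- run_experiment(sc, traj, t_start, duration = duration,
                         tracer_fraction = tracer_fraction,
                         sampling = smp, alpha = alpha)
    tg <- ex$truth$grazing
    rows[[i]] <- data.frame(
      rep = i, dilution = ex$dilution$value,
      dilution_raw = ex$dilution$raw_value,
      flb = ex$flb$value, flb_raw = ex$flb$raw_value,
      observed = ex$observed$value, true_grazing = tg,
      dilution_ratio = ex$dilution$value / tg,
      flb_ratio = ex$flb$value / tg)
  }
  do.call(rbind, rows)
}

#' Run the field-mode comparison
#'
#' Runs dilution (bulk chlorophyll-proxy readout, nutrient-amended design)
#' and FLB (fixed tracer addition) experiments for each depth scenario
#' over a 24-h incubation, then assembles the per-depth field report.
#'
#' @param depth_scenarios named list of \code{\link{scenario}}s, names are
#'   depth labels (default the built-in surface and deep-chlorophyll
#'   scenarios at 25 m and 125 m).
#' @param n_experiments experiments per depth (dates x incubation modes).
#' @param seed base seed.
#' @param fractions field dilution fractions of whole seawater.
#' @param tracer_abundance fixed FLB addition (mL^-1).
#' @param duration incubation (d).
#' @param analyzed_volume enumerated volume (mL).
#' @param alpha significance level.
#' @return list with \code{rates} (one row per experiment) and
#'   \code{report} (see \code{\link{field_report}}).
#' @export
run_field_comparison <- function(depth_scenarios = list(
                                   "25" = scenario("field_surface"),
                                   "125" = scenario("field_dcm")),
                                 n_experiments = 6L, seed = 0L,
                                 fractions = c(0.25, 0.5, 0.75, 1),
                                 tracer_abundance = 5e4,
                                 duration = 1, analyzed_volume = 0.5,
                                 alpha = 0.05) {
  rows <- list()
  for (d in names(depth_scenarios)) {
    sc <- depth_scenarios[[d]]
    traj <- simulate_community(sc$params, sc$init, sc$t_grid)
    state <- state_at(traj, 0)
    for (i in seq_len(n_experiments)) {
      base <- as.integer(seed + 1000L * i + 10L * match(d, names(depth_scenarios)))
      s_dln <- sampling_model(analyzed_volume, "poisson", seed = base)
      s_flb <- sampling_model(analyzed_volume, "poisson", seed = base + 1L)
      dln_bottles <- make_dilution_series(
        sc$params, state, fractions = fractions, duration = duration,
        sampling = s_dln, population = "bulk_proxy")
      flb_bottles <- make_flb_experiment(
        sc$params, state, tracer_abundance = tracer_abundance,
        duration = duration, sampling = s_flb)
      dln <- fit_dilution(dilution_points(dln_bottles), alpha = alpha)
      flb <- estimate_flb(flb_bottles, alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        method = c("dilution", "flb"), depth = d, experiment = i,
        value = c(dln$value, flb$value),
        raw_value = c(dln$raw_value, flb$raw_value),
        detectable = c(dln$detectable, flb$detectable),
        stringsAsFactors = FALSE)
    }
  }
  rates <- do.call(rbind, rows)
  rownames(rates) <- NULL
  list(rates = rates, report = field_report(rates))
}
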