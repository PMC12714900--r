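#' Bottle observation table
#'
#' One row per enumerated population per incubation bottle: counts at the
#' start and end of the incubation under a sampling model, plus bottle
#' metadata. This is the interchange format between the virtual-experiment
#' constructors and the rate estimators, and the schema of the bottle CSVs.
#'
#' Columns: \code{scenario}, \code{bottle_id}, \code{role} (undisturbed,
#' dilution, flb, flb_control), \code{fraction_wsw}, \code{population}
#' (prey, flb, bulk_proxy), \code{replicate}, \code{t0} and \code{t1}
#' (window endpoints, d), \code{count_0}, \code{count_t},
#' \code{analyzed_volume} (mL).
#'
#' @name bottle_observation
NULL

bottle_roles <- c("undisturbed", "dilution", "flb", "flb_control")
bottle_populations <- c("prey", "flb", "bulk_proxy")

new_bottles <- function(df) {
  validate_bottles(df)
  structure(df, class = c("bottle_observation", "data.frame"))
}

bottle_columns <- c("scenario", "bottle_id", "role", "fraction_wsw",
                    "population", "replicate", "t0", "t1", "count_0",
                    "count_t", "analyzed_volume")

validate_bottles <- function(df, where = "bottle table") {
  missing_cols <- setdiff(bottle_columns, names(df))
  if (length(missing_cols))
    stop(where, ": missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad_role <- !df$role %in% bottle_roles
  if (any(bad_role))
    stop(where, ": invalid role at row ", which(bad_role)[1], call. = FALSE)
  bad_pop <- !df$population %in% bottle_populations
  if (any(bad_pop))
    stop(where, ": invalid population at row ", which(bad_pop)[1],
         call. = FALSE)
  bad_frac <- !is.finite(df$fraction_wsw) | df$fraction_wsw <= 0 |
    df$fraction_wsw > 1
  if (any(bad_frac))
    stop(where, ": fraction_wsw outside (0, 1] at row ",
         which(bad_frac)[1], call. = FALSE)
  bad_t <- !is.finite(df$t0) | !is.finite(df$t1) | df$t1 <= df$t0
  if (any(bad_t))
    stop(where, ": need t1 > t0 at row ", which(bad_t)[1],
         call. = FALSE)
  bad_n <- !is.finite(df$count_0) | df$count_0 < 0 |
    !is.finite(df$count_t) | df$count_t < 0
  if (any(bad_n))
    stop(where, ": negative or non-finite count at row ",
         which(bad_n)[1], call. = FALSE)
  invisible(df)
}

bottle_row <- function(bottle_id, role, fraction_wsw, population, replicate,
                       t0, t1, count_0, count_t, analyzed_volume,
                       scenario = NA_character_) {
  data.frame(scenario = scenario, bottle_id = bottle_id, role = role,
             fraction_wsw = fraction_wsw, population = population,
             replicate = replicate, t0 = t0, t1 = t1,
             count_0 = count_0, count_t = count_t,
             analyzed_volume = analyzed_volume,
             stringsAsFactors = FALSE)
}

# Simulate one bottle from `state` for `duration` days and return the
# trajectory (fine internal grid for accurate endpoints).
simulate_bottle <- function(params, state, duration, n_steps = 48L) {
  t_grid <- seq(0, duration, length.out = max(n_steps, 8L) + 1L)
  simulate_community(params, state, t_grid)
}

#' Construct a virtual dilution series
#'
#' Prepares bottles at the given fractions of whole water by diluting
#' \code{state} with particle-free medium, forward-simulates each bottle
#' for \code{duration}, and enumerates the prey population (P + I, or a
#' chlorophyll-like bulk proxy) at the start and end under the sampling
#' model. Each fraction is replicated; under Poisson noise replicates
#' differ only in counting draws, as the truth layer is deterministic.
#'
#' @param params a \code{\link{community_params}}.
#' @param state source \code{\link{community_state}} (the undiluted water).
#' @param fractions fractions of whole water, each in (0, 1]. The
#'   laboratory default is \code{c(1, 0.8, 0.4, 0.2)} (undiluted, 20\%,
#'   60\% and 80\% diluted); the field default is
#'   \code{c(0.25, 0.5, 0.75, 1)}.
#' @param duration incubation length (d), > 0.
#' @param replicates bottles per fraction.
#' @param sampling a \code{\link{sampling_model}}.
#' @param population \code{"prey"} (cell counts) or \code{"bulk_proxy"}
#'   (chlorophyll-like readout).
#' @param scenario optional scenario label recorded on every row.
#' @return a \code{bottle_observation} data.frame.
#' @examples
#' p <- community_params()
#' s <- community_state(P = 1e6, G = 5e3, DOM = 1e5)
#' make_dilution_series(p, s, duration = 0.25,
#'                      sampling = sampling_model(0.05, "none"))
#' @export
make_dilution_series <- function(params, state,
                                 fractions = c(1, 0.8, 0.4, 0.2),
                                 duration = 0.25, replicates = 3L,
                                 sampling = sampling_model(),
                                 population = c("prey", "bulk_proxy"),
                                 scenario = NA_character_) {
  population <- match.arg(population)
  if (any(fractions <= 0 | fractions > 1))
    stop("all fractions must lie in (0, 1]", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  readout <- function(traj, row) {
    if (population == "prey") traj$P[row] + traj$I[row]
    else chlorophyll_proxy(traj[row, , drop = FALSE])
  }
  t_ref <- attr(state, "t")
  if (is.null(t_ref)) t_ref <- 0
  rows <- list()
  with_seed(sampling$seed, {
    for (fr in fractions) {
      traj <- simulate_bottle(params, dilute_state(state, fr), duration)
      n0 <- readout(traj, 1L)
      nt <- readout(traj, nrow(traj))
      for (rep in seq_len(replicates)) {
        rows[[length(rows) + 1L]] <- bottle_row(
          bottle_id = sprintf("dln_f%0.2f_r%d", fr, rep),
          role = "dilution", fraction_wsw = fr, population = population,
          replicate = rep, t0 = t_ref, t1 = t_ref + duration,
          count_0 = sample_counts(n0, sampling),
          count_t = sample_counts(nt, sampling),
          analyzed_volume = sampling$analyzed_volume,
          scenario = scenario)
      }
    }
  })
  new_bottles(do.call(rbind, rows))
}

#' Construct a virtual FLB disappearance experiment
#'
#' Grazed bottles start from \code{state} with the FLB tracer added at
#' \code{tracer_fraction} of the prey abundance (the laboratory design) or
#' at a fixed \code{tracer_abundance} (the field design, typically
#' 5e4 mL^-1); control bottles contain the tracer alone in particle-free
#' medium, where it decays only at the non-grazing loss rate \code{w}.
#' Both are forward-simulated and the tracer is enumerated at the start
#' and end of the incubation.
#'
#' @inheritParams make_dilution_series
#' @param tracer_fraction FLB added as a fraction of prey abundance
#'   (default 0.25, within the 20--30\% laboratory design); ignored when
#'   \code{tracer_abundance} is given.
#' @param tracer_abundance absolute FLB addition (mL^-1), or \code{NULL}.
#' @param controls number of control bottles.
#' @return a \code{bottle_observation} data.frame with roles \code{flb}
#'   and \code{flb_control}.
#' @export
make_flb_experiment <- function(params, state, tracer_fraction = 0.25,
                                tracer_abundance = NULL,
                                duration = 0.25, replicates = 3L,
                                controls = 3L,
                                sampling = sampling_model(),
                                scenario = NA_character_) {
  if (is.null(tracer_abundance)) {
    if (tracer_fraction <= 0)
      stop("tracer_fraction must be > 0", call. = FALSE)
    F0 <- tracer_fraction * prey_abundance(state)
  } else {
    if (tracer_abundance <= 0)
      stop("tracer_abundance must be > 0", call. = FALSE)
    F0 <- tracer_abundance
  }
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  s <- unclass(state)
  grazed0 <- community_state(P = s[["P"]], G = s[["G"]], V = s[["V"]],
                             I = s[["I"]], B = s[["B"]], F_ = F0,
                             DOM = s[["DOM"]])
  control0 <- community_state(F_ = F0, DOM = s[["DOM"]])
  t_ref <- attr(state, "t")
  if (is.null(t_ref)) t_ref <- 0
  rows <- list()
  with_seed(sampling$seed, {
    traj_g <- simulate_bottle(params, grazed0, duration)
    traj_c <- simulate_bottle(params, control0, duration)
    for (rep in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- bottle_row(
        bottle_id = sprintf("flb_r%d", rep), role = "flb",
        fraction_wsw = 1, population = "flb", replicate = rep,
        t0 = t_ref, t1 = t_ref + duration,
        count_0 = sample_counts(traj_g$F[1], sampling),
        count_t = sample_counts(traj_g$F[nrow(traj_g)], sampling),
        analyzed_volume = sampling$analyzed_volume,
        scenario = scenario)
    }
    for (rep in seq_len(controls)) {
      rows[[length(rows) + 1L]] <- bottle_row(
        bottle_id = sprintf("flbctl_r%d", rep), role = "flb_control",
        fraction_wsw = 1, population = "flb", replicate = rep,
        t0 = t_ref, t1 = t_ref + duration,
        count_0 = sample_counts(traj_c$F[1], sampling),
        count_t = sample_counts(traj_c$F[nrow(traj_c)], sampling),
        analyzed_volume = sampling$analyzed_volume,
        scenario = scenario)
    }
  })
  new_bottles(do.call(rbind, rows))
}

#' Observe undisturbed bottles over a window
#'
#' Enumerates the prey population of the source culture itself at the two
#' window endpoints, replicated — the direct "observed mortality" readout.
#'
#' @param traj a \code{\link{trajectory}} of the source culture.
#' @param window numeric (t0, t1) in days within the trajectory span.
#' @param replicates number of replicate enumerations.
#' @param sampling a \code{\link{sampling_model}}.
#' @return a \code{bottle_observation} data.frame with role
#'   \code{undisturbed}.
#' @export
observe_culture <- function(traj, window, replicates = 3L,
                            sampling = sampling_model(),
                            scenario = NA_character_) {
  stopifnot(inherits(traj, "trajectory"), length(window) == 2L)
  if (window[2] <= window[1]) stop("window must satisfy t1 > t0",
                                   call. = FALSE)
  n0 <- traj_at(traj, window[1], "P") + traj_at(traj, window[1], "I")
  nt <- traj_at(traj, window[2], "P") + traj_at(traj, window[2], "I")
  if (any(is.na(c(n0, nt))))
    stop("window lies outside the trajectory span", call. = FALSE)
  rows <- list()
  with_seed(sampling$seed, {
    for (rep in seq_len(replicates)) {
      rows[[length(rows) + 1L]] <- bottle_row(
        bottle_id = sprintf("obs_r%d", rep), role = "undisturbed",
        fraction_wsw = 1, population = "prey", replicate = rep,
        t0 = window[1], t1 = window[2],
        count_0 = sample_counts(n0, sampling),
        count_t = sample_counts(nt, sampling),
        analyzed_volume = sampling$analyzed_volume,
        scenario = scenario)
    }
  })
  new_bottles(do.call(rbind, rows))
}
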