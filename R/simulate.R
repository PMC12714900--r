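#' Simulate community dynamics
#'
#' Integrates the deterministic prey--grazer--virus--bacteria model forward
#' over a time grid and returns the trajectory together with a loss ledger:
#' the cumulative prey cells (per mL) lost to grazing and to viral lysis,
#' and the cumulative prey births. The ledger defines "true" mortality for
#' estimator evaluation (see \code{\link{true_mortality}}).
#'
#' Dynamics (continuous time; all states clipped at zero):
#' \itemize{
#'   \item effective clearance \eqn{c = c_{max}/(1 + P_{tot}/K_{sat})} with
#'     edible pool \eqn{P_{tot} = P + I + pref_B B + s_{FLB} F};
#'   \item prey: growth \eqn{\mu_P(t) P}, losses to grazing \eqn{c G P} and
#'     infection \eqn{\phi V P};
#'   \item infected class: enters by adsorption, exits by lysis at rate
#'     \eqn{1/\tau} and by grazing \eqn{c G I};
#'   \item viruses: \eqn{\beta} per lysis, lost by adsorption;
#'   \item grazers: yield \eqn{Y_G} on total ingestion, background loss
#'     \eqn{d_G};
#'   \item bacteria: Monod growth on DOM, grazed with weight \eqn{pref_B};
#'   \item FLB: no growth, grazed with weight \eqn{s_{FLB}}, non-grazing
#'     loss \eqn{w};
#'   \item DOM: fed by unassimilated grazed biomass and lysed cells,
#'     drawn down by bacterial growth.
#' }
#'
#' @param params a \code{\link{community_params}} object.
#' @param init a \code{\link{community_state}} object.
#' @param t_grid strictly increasing numeric vector of output times (d);
#'   integration starts at \code{t_grid[1]}.
#' @param rtol,atol relative and absolute integrator tolerances.
#'
#' @return An object of class \code{trajectory}: a data.frame with columns
#'   \code{t}, the seven compartments, and the cumulative ledger columns
#'   \code{births}, \code{loss_grazing}, \code{loss_lysis}
#'   (prey cells mL^-1), with the parameters attached as an attribute.
#' @examples
#' p <- community_params(c_max = 0, phi = 0)
#' tr <- simulate_community(p, community_state(P = 1e5), seq(0, 2, 0.1))
#' tail(tr, 1)$P / 1e5  # exp(mu_P * 2)
#' @export
simulate_community <- function(params, init, t_grid,
                               rtol = 1e-8, atol = 1e-4) {
  stopifnot(inherits(params, "community_params"))
  validate_community_params(params)
  if (!inherits(init, "community_state"))
    stop("init must be a community_state", call. = FALSE)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0))
    stop("t_grid must be strictly increasing with >= 2 points",
         call. = FALSE)

  y0 <- c(unclass(init)[state_compartments],
          births = 0, loss_grazing = 0, loss_lysis = 0)
  out <- deSolve::ode(y = y0, times = t_grid, func = community_rhs,
                      parms = params, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0 || any(!is.finite(out)))
    stop("integration failure near t = ",
         signif(max(out[stats::complete.cases(out), "time"]), 6),
         call. = FALSE)
  traj <- as.data.frame(out)
  names(traj)[1] <- "t"
  # lsoda can leave tiny negative excursions; clip below tolerance
  num <- setdiff(names(traj), "t")
  traj[num] <- lapply(traj[num], function(v) pmax(v, 0))
  structure(traj, params = params, class = c("trajectory", "data.frame"))
}

# Square-wave light multiplier, mean 1 over 24 h. `photoperiod` is
# c(light_h, dark_h); the day starts in the light.
light_factor <- function(t, photoperiod) {
  if (is.null(photoperiod)) return(rep(1, length(t)))
  frac_light <- photoperiod[1] / 24
  in_light <- (t %% 1) < frac_light
  ifelse(in_light, 1 / frac_light, 0)
}

community_rhs <- function(t, y, p) {
  y <- pmax(y, 0)
  P <- y[["P"]]; G <- y[["G"]]; V <- y[["V"]]; I <- y[["I"]]
  B <- y[["B"]]; F <- y[["F"]]; DOM <- y[["DOM"]]

  P_tot <- P + I + p$pref_B * B + p$s_FLB * F
  clear <- p$c_max / (1 + P_tot / p$K_sat)
  graz_P <- clear * G * P
  graz_I <- clear * G * I
  graz_B <- clear * G * p$pref_B * B
  graz_F <- clear * G * p$s_FLB * F
  ingest <- graz_P + graz_I + graz_B + graz_F

  adsorb <- p$phi * V * P
  lysis <- if (p$tau > 0) I / p$tau else adsorb
  infection_in <- if (p$tau > 0) adsorb else 0

  growth_P <- p$mu_P * light_factor(t, p$photoperiod) * P
  mu_B <- p$mu_B_max * DOM / (p$k_DOM + DOM)

  dP <- growth_P - graz_P - adsorb
  dI <- infection_in - lysis * (p$tau > 0) - graz_I
  dG <- p$Y_G * ingest - p$d_G * G
  dV <- p$beta * lysis - adsorb
  dB <- mu_B * B - graz_B
  dF <- -graz_F - p$w * F
  dDOM <- (1 - p$Y_G) * ingest + lysis - mu_B * B

  list(c(P = dP, G = dG, V = dV, I = dI, B = dB, F = dF, DOM = dDOM,
         births = growth_P,
         loss_grazing = graz_P + graz_I,
         loss_lysis = lysis))
}

#' @export
print.trajectory <- function(x, ...) {
  cat("Community trajectory: ", nrow(x), " states over t = [",
      min(x$t), ", ", max(x$t), "] d\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 4), digits = 4)
  if (nrow(x) > 4) cat("  ... ", nrow(x) - 4, " more rows\n", sep = "")
  invisible(x)
}

# Linear interpolation of one trajectory column at arbitrary times.
traj_at <- function(traj, times, col) {
  stats::approx(traj$t, traj[[col]], xout = times, rule = 1)$y
}

#' True mortality decomposition over a window
#'
#' Converts the trajectory's cumulative loss ledger into per-capita rates:
#' each component equals (cells lost in the window) divided by (log-mean
#' prey abundance x window length). Under pure exponential decline this
#' reproduces the instantaneous specific loss rate exactly, making the
#' ledger the recovery oracle for the incubation-based estimators.
#'
#' @param traj a \code{\link{trajectory}}.
#' @param window numeric length-2, (t0, t1) in days, inside the trajectory
#'   span; prey (P + I) must be positive throughout.
#' @return list with elements \code{grazing}, \code{lysis}, \code{total}
#'   (all d^-1).
#' @examples
#' p <- community_params(c_max = 0, phi = 0)
#' tr <- simulate_community(p, community_state(P = 1e5), seq(0, 2, 0.1))
#' true_mortality(tr, c(0, 2))  # all zero
#' @export
true_mortality <- function(traj, window) {
  stopifnot(inherits(traj, "trajectory"), length(window) == 2L)
  t0 <- window[1]; t1 <- window[2]
  if (t1 <= t0) stop("window must satisfy t1 > t0", call. = FALSE)
  if (t0 < min(traj$t) - 1e-12 || t1 > max(traj$t) + 1e-12)
    stop("window lies outside the trajectory span", call. = FALSE)
  prey <- traj$P + traj$I
  in_win <- traj$t >= t0 - 1e-12 & traj$t <= t1 + 1e-12
  if (any(prey[in_win] <= 0))
    stop("prey abundance must be positive throughout the window",
         call. = FALSE)
  P0 <- traj_at(traj, t0, "P") + traj_at(traj, t0, "I")
  P1 <- traj_at(traj, t1, "P") + traj_at(traj, t1, "I")
  Pbar <- log_mean_abundance(P0, P1)
  dt <- t1 - t0
  g <- (traj_at(traj, t1, "loss_grazing") -
          traj_at(traj, t0, "loss_grazing")) / (Pbar * dt)
  l <- (traj_at(traj, t1, "loss_lysis") -
          traj_at(traj, t0, "loss_lysis")) / (Pbar * dt)
  list(grazing = g, lysis = l, total = g + l)
}

#' Dilute a community state with particle-free medium
#'
#' All particulate compartments (P, G, V, I, B, F) are multiplied by the
#' retained fraction of whole water. The dissolved pool keeps the source
#' concentration: the diluent is nutrient-replete medium, so dissolved
#' resources are never limiting and prey growth is dilution-invariant by
#' construction.
#'
#' @param state a \code{\link{community_state}}.
#' @param fraction_wsw fraction of whole (undiluted) water retained, in
#'   (0, 1]. A "20\% diluted" bottle retains 0.8.
#' @return a diluted \code{community_state}.
#' @examples
#' s <- community_state(P = 1e6, G = 1e3)
#' dilute_state(s, 0.2)
#' @export
dilute_state <- function(state, fraction_wsw) {
  stopifnot(inherits(state, "community_state"))
  if (!is.numeric(fraction_wsw) || length(fraction_wsw) != 1L ||
      fraction_wsw <= 0 || fraction_wsw > 1)
    stop("fraction_wsw must lie in (0, 1]", call. = FALSE)
  s <- unclass(state)
  part <- c("P", "G", "V", "I", "B", "F")
  s[part] <- s[part] * fraction_wsw
  community_state(P = s[["P"]], G = s[["G"]], V = s[["V"]], I = s[["I"]],
                  B = s[["B"]], F_ = s[["F"]], DOM = s[["DOM"]],
                  t = attr(state, "t"))
}

#' Bulk chlorophyll-like proxy of phototroph abundance
#'
#' Weighted sum of the phototrophic compartments (uninfected and infected
#' prey) by per-cell fluorescence yield. Used as the \code{bulk_proxy}
#' population when field-style dilution bottles are read out as total
#' chlorophyll rather than cell counts.
#'
#' @param states a \code{trajectory}, \code{community_state}, or data.frame
#'   with columns \code{P} and \code{I}.
#' @param yields named numeric, per-cell yields for \code{P} and \code{I}
#'   (arbitrary units per cell); both must be >= 0.
#' @return numeric proxy value per state.
#' @export
chlorophyll_proxy <- function(states, yields = c(P = 1, I = 1)) {
  if (any(yields < 0)) stop("yields must be >= 0", call. = FALSE)
  yP <- if ("P" %in% names(yields)) yields[["P"]] else 0
  yI <- if ("I" %in% names(yields)) yields[["I"]] else 0
  if (inherits(states, "community_state"))
    return(unname(yP * states[["P"]] + yI * states[["I"]]))
  yP * states$P + yI * states$I
}
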