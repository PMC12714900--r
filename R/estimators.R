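#' Apparent growth rate from two counts
#'
#' The net per-capita rate observed in a bottle,
#' \eqn{k = \ln(N_t/N_0)/t} (d^-1).
#'
#' @param N0,Nt abundances or counts at the start and end of the
#'   incubation; both must be positive (a zero count is an error, not an
#'   infinite rate — supply \code{pseudo_count} to floor counts instead).
#' @param t incubation length (d), > 0.
#' @param pseudo_count optional floor added-free replacement for zero
#'   counts; default \code{NULL} (disabled).
#' @return k (d^-1); vectorized over \code{N0}, \code{Nt}.
#' @examples
#' apparent_growth(100, 200, 1)  # log(2)
#' @export
apparent_growth <- function(N0, Nt, t, pseudo_count = NULL) {
  if (any(t <= 0)) stop("t must be > 0", call. = FALSE)
  if (!is.null(pseudo_count)) {
    N0 <- pmax(N0, pseudo_count)
    Nt <- pmax(Nt, pseudo_count)
  }
  if (any(N0 <= 0) || any(Nt <= 0))
    stop("zero or negative count: rate undefined ",
         "(set pseudo_count to floor counts)", call. = FALSE)
  log(Nt / N0) / t
}

#' Decay (disappearance) rate from two counts
#'
#' \eqn{g = -\ln(N_t/N_0)/t}: positive when the population declined. This
#' is the per-capita disappearance rate used both for the FLB tracer and
#' for observed prey mortality.
#'
#' @inheritParams apparent_growth
#' @return g (d^-1), \code{= -apparent_growth(N0, Nt, t)} exactly.
#' @examples
#' decay_rate(100, 100 / exp(1), 1)  # 1
#' @export
decay_rate <- function(N0, Nt, t, pseudo_count = NULL) {
  -apparent_growth(N0, Nt, t, pseudo_count)
}

#' Logarithmic-mean abundance over an interval
#'
#' \eqn{\bar P = (P_2 - P_1)/(\ln P_2 - \ln P_1)}, the time-averaged
#' abundance under exponential change; equal arguments return their common
#' value (the continuous limit). Every experiment is indexed by
#' \eqn{\log_{10}\bar P}.
#'
#' @param P1,P2 positive abundances; vectorized.
#' @return the logarithmic mean, between min and max of the arguments.
#' @examples
#' log_mean_abundance(100, 1000)  # 900 / log(10)
#' @export
log_mean_abundance <- function(P1, P2) {
  if (any(P1 <= 0) || any(P2 <= 0))
    stop("abundances must be > 0", call. = FALSE)
  ifelse(P1 == P2, P1, (P2 - P1) / (log(P2) - log(P1)))
}

#' Rate estimate container
#'
#' @param value rate (d^-1); 0 when not detectable (the raw computed rate
#'   is kept in \code{raw_value}).
#' @param se standard error (d^-1) or NA.
#' @param n number of bottles/points used.
#' @param detectable logical: did the rate pass the zero test?
#' @param method one of observed, flb, dilution, dilution_two_point.
#' @param window numeric (t0, t1) in days.
#' @param mean_log10_P log10 of the log-mean prey abundance over the
#'   window, or NA (field bulk-proxy rates).
#' @param p p-value of the zero test, or NA.
#' @param raw_value the computed rate before the non-detect rule.
#' @param extra named list of method-specific fields (e.g. the dilution
#'   intercept \code{mu}).
#' @return an object of class \code{rate_estimate}.
#' @export
rate_estimate <- function(value, se = NA_real_, n, detectable, method,
                          window = c(NA_real_, NA_real_),
                          mean_log10_P = NA_real_, p = NA_real_,
                          raw_value = value, extra = list()) {
  stopifnot(n >= 1, is.logical(detectable))
  if (!detectable && value != 0)
    stop("non-detectable estimates must carry value 0", call. = FALSE)
  structure(c(list(value = value, se = se, n = n, detectable = detectable,
                   method = method, window = window,
                   mean_log10_P = mean_log10_P, p = p,
                   raw_value = raw_value), extra),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<%s> %s%.4g d^-1 (se %.3g, n %d, p %.3g)%s\n",
              x$method, if (x$detectable) "" else "[non-detect] ",
              x$value, x$se, x$n, x$p,
              if (is.finite(x$mean_log10_P))
                sprintf(", mean log10 P = %.2f", x$mean_log10_P) else ""))
  invisible(x)
}

# Non-detect rule for replicate-based rates: one-sample two-sided t test
# against zero when n >= 3 and rates vary; otherwise a Poisson counting
# z test on the pooled counts.
replicate_detectability <- function(rates, counts0 = NULL, countst = NULL,
                                    alpha = 0.05) {
  if (length(rates) >= 3 && stats::sd(rates) > 0) {
    p <- stats::t.test(rates, mu = 0)$p.value
    return(list(detectable = p < alpha, p = p))
  }
  if (!is.null(counts0) && !is.null(countst)) {
    s0 <- sum(counts0); st <- sum(countst)
    # z test on log(st/s0): var ~ 1/s0 + 1/st by the delta method
    z <- log(st / s0) / sqrt(1 / s0 + 1 / st)
    p <- 2 * stats::pnorm(-abs(z))
    return(list(detectable = p < alpha, p = p))
  }
  list(detectable = NA, p = NA_real_)
}

apply_nondetect <- function(value, det) {
  if (isTRUE(det$detectable)) value else 0
}

#' Fit the dilution regression
#'
#' Model I (ordinary least squares) regression of apparent growth rate on
#' the fraction of whole water, fitted on all replicate points. The
#' negative of the slope is the grazing mortality rate m (d^-1), reported
#' positive; the intercept is the grazer-free growth estimate mu. The rate
#' is detectable when the two-sided slope t test has p < alpha and the
#' slope is negative; otherwise the estimate is 0 (non-detect rule), with
#' the signed computed rate preserved in \code{raw_value}.
#'
#' @param points data.frame with columns \code{fraction_wsw} (in (0, 1])
#'   and \code{k} (apparent growth, d^-1); a \code{replicate} column is
#'   carried but not used in the fit.
#' @param alpha significance level for the slope test.
#' @param window optional (t0, t1) recorded in the estimate.
#' @param mean_log10_P optional index abundance recorded in the estimate.
#' @return a \code{\link{rate_estimate}} with method \code{"dilution"};
#'   \code{extra} fields \code{mu} (intercept) and \code{mu_se}.
#' @examples
#' pts <- data.frame(fraction_wsw = rep(c(1, 0.8, 0.4, 0.2), 3))
#' pts$k <- 1 - 5 * pts$fraction_wsw
#' fit_dilution(pts)  # m = 5, mu = 1
#' @export
fit_dilution <- function(points, alpha = 0.05,
                         window = c(NA_real_, NA_real_),
                         mean_log10_P = NA_real_) {
  stopifnot(all(c("fraction_wsw", "k") %in% names(points)))
  if (any(points$fraction_wsw <= 0 | points$fraction_wsw > 1))
    stop("fraction_wsw must lie in (0, 1]", call. = FALSE)
  if (length(unique(points$fraction_wsw)) < 2L)
    stop("degenerate design: need >= 2 distinct fractions", call. = FALSE)
  fit <- stats::lm(k ~ fraction_wsw, data = points)
  # summary warns on exact-fit fixtures (zero residual variance); harmless
  co <- suppressWarnings(summary(fit))$coefficients
  slope <- co["fraction_wsw", "Estimate"]
  if (nrow(points) > 2L) {
    se <- co["fraction_wsw", "Std. Error"]
    p <- co["fraction_wsw", "Pr(>|t|)"]
  } else {
    se <- NA_real_; p <- NA_real_
  }
  detectable <- isTRUE(p < alpha) && slope < 0
  m_raw <- -slope
  rate_estimate(value = if (detectable) m_raw else 0, se = se,
                n = nrow(points), detectable = detectable,
                method = "dilution", window = window,
                mean_log10_P = mean_log10_P, p = p, raw_value = m_raw,
                extra = list(mu = co["(Intercept)", "Estimate"],
                             mu_se = co["(Intercept)", "Std. Error"]))
}

#' Two-point dilution estimate from the most dilute pair
#'
#' Mortality from the replicate means at exactly two fractions:
#' \eqn{m = -(\bar k(D_2) - \bar k(D_1))/(D_2 - D_1)}. Used to probe
#' whether grazing saturation at high prey abundance biases the full
#' regression: the most dilute bottles sit furthest from saturation.
#' Detectability is a Welch two-sample t test of the apparent growth rates
#' between the two fractions (requires >= 2 replicates per fraction with
#' variance; otherwise the rate is reported undetermined-detectable).
#'
#' @inheritParams fit_dilution
#' @param fractions length-2 fractions to use (default the 80\% and 60\%
#'   diluted bottles, i.e. 0.2 and 0.4); \code{points} may contain more —
#'   only these are used.
#' @return a \code{\link{rate_estimate}} with method
#'   \code{"dilution_two_point"}.
#' @export
fit_dilution_two_point <- function(points, fractions = c(0.2, 0.4),
                                   alpha = 0.05,
                                   window = c(NA_real_, NA_real_),
                                   mean_log10_P = NA_real_) {
  stopifnot(all(c("fraction_wsw", "k") %in% names(points)))
  fractions <- sort(fractions)
  if (length(fractions) != 2L || fractions[1] == fractions[2])
    stop("degenerate design: need two distinct fractions", call. = FALSE)
  sub <- points[points$fraction_wsw %in% fractions, , drop = FALSE]
  k1 <- sub$k[sub$fraction_wsw == fractions[1]]
  k2 <- sub$k[sub$fraction_wsw == fractions[2]]
  if (!length(k1) || !length(k2))
    stop("no points at the requested fractions", call. = FALSE)
  m_raw <- -(mean(k2) - mean(k1)) / (fractions[2] - fractions[1])
  if (length(k1) >= 2 && length(k2) >= 2 &&
      (stats::sd(k1) > 0 || stats::sd(k2) > 0)) {
    p <- stats::t.test(k2, k1)$p.value
    detectable <- p < alpha && m_raw > 0
  } else {
    p <- NA_real_
    detectable <- TRUE  # exact replicates: no noise model to test against
  }
  rate_estimate(value = if (detectable) m_raw else 0, se = NA_real_,
                n = nrow(sub), detectable = detectable,
                method = "dilution_two_point", window = window,
                mean_log10_P = mean_log10_P, p = p, raw_value = m_raw)
}

#' Mean non-grazing tracer loss rate from control bottles
#'
#' Arithmetic mean of per-bottle FLB decay rates in grazer-free controls;
#' subtracted from experimental-bottle rates to correct for wall adsorption
#' and other non-grazing losses.
#'
#' @param controls a \code{bottle_observation} table (rows with role
#'   \code{flb_control} are used; other rows ignored).
#' @return mean control decay rate (d^-1).
#' @export
mean_control_rate <- function(controls) {
  ctl <- controls[controls$role == "flb_control", , drop = FALSE]
  if (!nrow(ctl))
    stop("no control bottles supplied", call. = FALSE)
  if (any(ctl$count_0 <= 0) || any(ctl$count_t <= 0))
    stop("control bottles must have positive counts", call. = FALSE)
  mean(decay_rate(ctl$count_0, ctl$count_t, ctl$t1 - ctl$t0))
}

#' Control-corrected FLB rate from raw rates
#'
#' @param g_raw raw FLB disappearance rate (d^-1), scalar or replicate
#'   vector.
#' @param g_control mean control loss rate (d^-1).
#' @param alpha significance level for the replicate zero test.
#' @param window,mean_log10_P recorded metadata.
#' @return a \code{\link{rate_estimate}} with method \code{"flb"}. The
#'   corrected value (possibly negative) is preserved in \code{raw_value};
#'   \code{value} is zeroed only when the zero test fails.
#' @export
control_corrected_flb <- function(g_raw, g_control, alpha = 0.05,
                                  window = c(NA_real_, NA_real_),
                                  mean_log10_P = NA_real_) {
  if (any(!is.finite(g_raw)) || !is.finite(g_control))
    stop("rates must be finite", call. = FALSE)
  corrected <- g_raw - g_control
  m <- mean(corrected)
  se <- if (length(corrected) > 1)
    stats::sd(corrected) / sqrt(length(corrected)) else NA_real_
  det <- replicate_detectability(corrected, alpha = alpha)
  if (is.na(det$detectable))
    det$detectable <- TRUE  # single exact rate: nothing to test against
  rate_estimate(value = apply_nondetect(m, det), se = se,
                n = length(corrected), detectable = isTRUE(det$detectable),
                method = "flb", window = window,
                mean_log10_P = mean_log10_P, p = det$p, raw_value = m)
}

#' FLB disappearance estimate from a bottle table
#'
#' Per-bottle tracer decay rates in the grazed bottles, corrected by the
#' mean control rate, averaged over replicates, with the replicate-based
#' zero test for detectability.
#'
#' @param bottles a \code{bottle_observation} table containing roles
#'   \code{flb} and \code{flb_control}.
#' @param alpha significance level.
#' @param mean_log10_P recorded index abundance (the prey log-mean over
#'   the window, supplied by the caller; the tracer itself does not carry
#'   it).
#' @return a \code{\link{rate_estimate}} with method \code{"flb"}.
#' @export
estimate_flb <- function(bottles, alpha = 0.05, mean_log10_P = NA_real_) {
  grz <- bottles[bottles$role == "flb", , drop = FALSE]
  if (!nrow(grz)) stop("no FLB bottles supplied", call. = FALSE)
  g_control <- mean_control_rate(bottles)
  g_raw <- decay_rate(grz$count_0, grz$count_t, grz$t1 - grz$t0)
  est <- control_corrected_flb(g_raw, g_control, alpha = alpha,
                               window = c(grz$t0[1], grz$t1[1]),
                               mean_log10_P = mean_log10_P)
  est$g_control <- g_control
  est
}

#' Observed mortality from undisturbed counts
#'
#' Direct prey decay rate over a window: per-replicate
#' \code{\link{decay_rate}} values averaged, with replicate standard error,
#' the replicate-based zero test, and the log10 log-mean prey abundance
#' attached as the experiment's index.
#'
#' @param bottles a \code{bottle_observation} table (role
#'   \code{undisturbed}); counts must be positive.
#' @param alpha significance level.
#' @return a \code{\link{rate_estimate}} with method \code{"observed"}.
#' @export
observed_mortality <- function(bottles, alpha = 0.05) {
  obs <- bottles[bottles$role == "undisturbed", , drop = FALSE]
  if (!nrow(obs)) stop("no undisturbed bottles supplied", call. = FALSE)
  rates <- decay_rate(obs$count_0, obs$count_t, obs$t1 - obs$t0)
  m <- mean(rates)
  se <- if (length(rates) > 1)
    stats::sd(rates) / sqrt(length(rates)) else NA_real_
  det <- replicate_detectability(rates, obs$count_0, obs$count_t,
                                 alpha = alpha)
  # index abundance from mean counts converted back to per-mL
  vol <- obs$analyzed_volume
  P0 <- mean(obs$count_0 / vol); Pt <- mean(obs$count_t / vol)
  rate_estimate(value = apply_nondetect(m, det), se = se,
                n = length(rates), detectable = isTRUE(det$detectable),
                method = "observed", window = c(obs$t0[1], obs$t1[1]),
                mean_log10_P = log10(log_mean_abundance(P0, Pt)),
                p = det$p, raw_value = m)
}

#' Apparent growth points from dilution bottles
#'
#' @param bottles a \code{bottle_observation} table (role \code{dilution}).
#' @param pseudo_count optional zero-count floor passed to
#'   \code{\link{apparent_growth}}.
#' @return data.frame with columns \code{fraction_wsw}, \code{k},
#'   \code{replicate}.
#' @export
dilution_points <- function(bottles, pseudo_count = NULL) {
  dl <- bottles[bottles$role == "dilution", , drop = FALSE]
  if (!nrow(dl)) stop("no dilution bottles supplied", call. = FALSE)
  data.frame(fraction_wsw = dl$fraction_wsw,
             k = apparent_growth(dl$count_0, dl$count_t,
                                 dl$t1 - dl$t0,
                                 pseudo_count = pseudo_count),
             replicate = dl$replicate)
}
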