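#' Community model parameters
#'
#' Constructs the parameter set for the deterministic
#' prey--grazer--virus--bacteria community model. Units are days and
#' cells per mL throughout.
#'
#' The grazer follows a type-II (saturating) functional response over its
#' total edible pool \eqn{P_{tot} = P + I + pref_B B + s_{FLB} F}: the
#' effective per-capita clearance is
#' \eqn{c_{max} / (1 + P_{tot}/K_{sat})}, so ingestion is linear in prey at
#' \eqn{P_{tot} \ll K_{sat}} and saturates at \eqn{c_{max} K_{sat}} cells
#' per grazer per day. Viral lysis acts through an explicit infected class
#' with mean latent period \code{tau}. Heterotrophic bacteria grow on a
#' single dissolved-organics pool fed by grazing and lysis byproducts.
#'
#' @param mu_P prey intrinsic growth rate (d^-1).
#' @param c_max grazer maximum per-capita clearance (mL grazer^-1 d^-1).
#' @param K_sat total edible abundance at half-maximal ingestion
#'   (cells mL^-1); must be positive.
#' @param Y_G grazer gross growth efficiency (grazers produced per cell
#'   consumed), in (0, 1].
#' @param d_G grazer background loss rate (d^-1).
#' @param phi viral adsorption rate constant (mL d^-1).
#' @param beta burst size (virions per lysed cell).
#' @param tau latent period (d). \code{tau = 0} lyses adsorbed cells
#'   immediately (no infected class accumulates).
#' @param mu_B_max maximum bacterial growth rate (d^-1).
#' @param k_DOM half-saturation of bacterial growth on dissolved organics
#'   (arbitrary concentration units).
#' @param pref_B grazer preference weight for bacteria relative to prey
#'   (dimensionless, >= 0).
#' @param s_FLB tracer selectivity: ratio of clearance on the FLB tracer to
#'   clearance on prey (dimensionless, >= 0). \code{s_FLB = 1} encodes the
#'   tracer method's core assumption that surrogate prey are consumed at the
#'   same rate as natural prey.
#' @param w non-grazing tracer loss rate (d^-1), e.g. wall adsorption;
#'   the only FLB loss term in grazer-free control bottles.
#' @param photoperiod light:dark hours per 24 h as a length-2 numeric
#'   (e.g. \code{c(14, 10)}), or \code{NULL} (default) for continuous light.
#'   When set, \code{mu_P} is modulated by a square wave rescaled so the
#'   24-h mean growth rate still equals \code{mu_P}.
#'
#' @return An object of class \code{community_params} (a named list).
#' @examples
#' p <- community_params(mu_P = 0.5, c_max = 2e-4, K_sat = 2e6)
#' p$mu_P
#' @export
community_params <- function(mu_P = 0.5,
                             c_max = 2e-4,
                             K_sat = 2e6,
                             Y_G = 0.005,
                             d_G = 0.1,
                             phi = 0,
                             beta = 40,
                             tau = 0.25,
                             mu_B_max = 2,
                             k_DOM = 1e6,
                             pref_B = 0.3,
                             s_FLB = 1,
                             w = 0,
                             photoperiod = NULL) {
  p <- list(mu_P = mu_P, c_max = c_max, K_sat = K_sat, Y_G = Y_G,
            d_G = d_G, phi = phi, beta = beta, tau = tau,
            mu_B_max = mu_B_max, k_DOM = k_DOM, pref_B = pref_B,
            s_FLB = s_FLB, w = w, photoperiod = photoperiod)
  validate_community_params(p)
  structure(p, class = "community_params")
}

validate_community_params <- function(p) {
  num <- c("mu_P", "c_max", "K_sat", "Y_G", "d_G", "phi", "beta", "tau",
           "mu_B_max", "k_DOM", "pref_B", "s_FLB", "w")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    if (v < 0)
      stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  if (p$K_sat <= 0)
    stop("K_sat must be > 0", call. = FALSE)
  if (p$Y_G <= 0 || p$Y_G > 1)
    stop("Y_G must lie in (0, 1]", call. = FALSE)
  if (!is.null(p$photoperiod)) {
    pp <- p$photoperiod
    if (!is.numeric(pp) || length(pp) != 2L || any(pp < 0) ||
        abs(sum(pp) - 24) > 1e-9)
      stop("photoperiod must be light:dark hours summing to 24",
           call. = FALSE)
  }
  invisible(p)
}

#' @export
print.community_params <- function(x, ...) {
  cat("Community model parameters (d, cells/mL):\n")
  flat <- x[!vapply(x, is.null, logical(1))]
  keys <- setdiff(names(flat), "photoperiod")
  cat(paste0("  ", format(keys), " = ",
             vapply(flat[keys], format, character(1))), sep = "\n")
  if (!is.null(x$photoperiod))
    cat("  photoperiod = ", x$photoperiod[1], ":", x$photoperiod[2],
        " h light:dark\n", sep = "")
  else
    cat("  photoperiod = continuous light\n")
  invisible(x)
}

#' Community state
#'
#' Abundances of all model compartments at one instant.
#'
#' @param P uninfected prey (cells mL^-1).
#' @param G grazers (cells mL^-1).
#' @param V free viruses (particles mL^-1).
#' @param I infected prey (cells mL^-1).
#' @param B heterotrophic bacteria (cells mL^-1).
#' @param F_ FLB tracer particles (mL^-1). Named \code{F_} to avoid the
#'   base-R \code{F} binding.
#' @param DOM dissolved organic matter pool (arbitrary units).
#' @param t time (d); defaults to 0.
#'
#' @return An object of class \code{community_state} (named numeric vector
#'   with attribute \code{t}).
#' @examples
#' community_state(P = 1e7, G = 5e3)
#' @export
community_state <- function(P = 0, G = 0, V = 0, I = 0, B = 0, F_ = 0,
                            DOM = 0, t = 0) {
  s <- c(P = P, G = G, V = V, I = I, B = B, F = F_, DOM = DOM)
  if (any(!is.finite(s)) || any(s < 0))
    stop("all compartments must be finite and non-negative", call. = FALSE)
  structure(s, t = t, class = "community_state")
}

state_compartments <- c("P", "G", "V", "I", "B", "F", "DOM")

#' @export
print.community_state <- function(x, ...) {
  cat("Community state at t =", attr(x, "t"), "d:\n")
  print(stats::setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Total countable prey abundance of a state
#'
#' Flow cytometry does not distinguish infected from uninfected prey cells,
#' so counted "prey" is P + I.
#'
#' @param state a \code{community_state} or a named vector/one-row frame
#'   with elements \code{P} and \code{I}.
#' @return numeric abundance (cells mL^-1).
#' @export
prey_abundance <- function(state) {
  unname(state[["P"]] + state[["I"]])
}
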