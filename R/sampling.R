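#' Flow-cytometric sampling model
#'
#' Describes how abundances become enumerated counts: the analyzed volume
#' and whether counting noise is applied. With \code{noise = "poisson"}
#' a count is a Poisson draw with mean abundance x volume, which is the
#' counting statistics of enumerating a well-mixed subsample; with
#' \code{noise = "none"} the exact expected count is returned.
#'
#' @param analyzed_volume volume enumerated per sample (mL), > 0.
#' @param noise \code{"none"} or \code{"poisson"}.
#' @param seed integer random seed used by the experiment constructors for
#'   reproducible draws.
#' @return An object of class \code{sampling_model}.
#' @examples
#' sampling_model(0.05, "poisson", seed = 1)
#' @export
sampling_model <- function(analyzed_volume = 0.05, noise = c("none", "poisson"),
                           seed = 0L) {
  noise <- match.arg(noise)
  if (!is.numeric(analyzed_volume) || length(analyzed_volume) != 1L ||
      analyzed_volume <= 0)
    stop("analyzed_volume must be > 0", call. = FALSE)
  structure(list(analyzed_volume = analyzed_volume, noise = noise,
                 seed = as.integer(seed)),
            class = "sampling_model")
}

#' @export
print.sampling_model <- function(x, ...) {
  cat("Sampling model: ", x$analyzed_volume, " mL analyzed, noise = ",
      x$noise, ", seed = ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Enumerate a sample
#'
#' @param abundance true abundance (mL^-1), >= 0; vectorized.
#' @param sampling a \code{\link{sampling_model}}. Poisson draws use the
#'   current RNG state; the experiment constructors seed it from
#'   \code{sampling$seed}.
#' @return counts (integers under Poisson noise; exact expected counts,
#'   possibly non-integer, under \code{noise = "none"}).
#' @examples
#' sample_counts(1e4, sampling_model(0.05, "none"))  # 500
#' @export
sample_counts <- function(abundance, sampling) {
  stopifnot(inherits(sampling, "sampling_model"))
  if (any(!is.finite(abundance)) || any(abundance < 0))
    stop("abundance must be finite and >= 0", call. = FALSE)
  mu <- abundance * sampling$analyzed_volume
  if (sampling$noise == "none") return(mu)
  stats::rpois(length(mu), mu)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
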