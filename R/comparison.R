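#' Percent difference between an estimated and an observed rate
#'
#' \eqn{100 (estimated - observed)/observed}; negative values mean the
#' estimator under-reported the directly observed mortality.
#'
#' @param estimated,observed rates (d^-1); vectorized. \code{observed}
#'   must be non-zero (zero-observed records are excluded upstream).
#' @return percent difference (\%).
#' @examples
#' percent_difference(4.9, 7.4)
#' @export
percent_difference <- function(estimated, observed) {
  if (any(observed == 0))
    stop("observed rate is 0: percent difference undefined", call. = FALSE)
  100 * (estimated - observed) / observed
}

#' Interquartile-range outlier filter
#'
#' Removes values outside [Q1 - k IQR, Q3 + k IQR] (Tukey fences, type-7
#' quantiles). Applied separately per estimation method before comparing
#' percent differences.
#'
#' @param values numeric vector.
#' @param k fence multiplier (default 1.5; \code{Inf} keeps everything).
#' @return list with \code{kept}, \code{removed}, and the \code{fences}.
#' @examples
#' iqr_filter(c(1, 2, 3, 4, 100))$removed
#' @export
iqr_filter <- function(values, k = 1.5) {
  if (length(values) < 4L) {
    warning("fewer than 4 values: IQR filter is the identity")
    return(list(kept = values, removed = numeric(0),
                fences = c(-Inf, Inf)))
  }
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  fences <- c(q[1] - k * iqr, q[2] + k * iqr)
  if (is.infinite(k)) fences <- c(-Inf, Inf)
  out <- values < fences[1] | values > fences[2]
  list(kept = values[!out], removed = values[out], fences = fences)
}

#' Align an abundance curve at a reference log abundance
#'
#' Shifts the time axis so that the curve passes through the reference
#' log10 abundance at shifted time zero, using linear interpolation at the
#' first downward crossing. Aligning all treatments at a common reference
#' (default log10 = 5.6, midway through the crash) removes temporal
#' offsets in the onset of decline so curve shapes can be compared.
#'
#' @param series data.frame with columns \code{t} (hours or days — the
#'   shift is returned in the same unit) and \code{log10_P}.
#' @param reference reference log10 abundance.
#' @param label treatment label carried on the result.
#' @return an object of class \code{aligned_curve}: the series with
#'   \code{t_shifted}, plus attributes \code{shift} and \code{label}.
#' @examples
#' s <- data.frame(t = 0:40, log10_P = 7 - 0.1 * (0:40))
#' attr(align_curve(s, 5.6), "shift")  # -14
#' @export
align_curve <- function(series, reference = 5.6, label = NA_character_) {
  stopifnot(all(c("t", "log10_P") %in% names(series)))
  x <- series[order(series$t), , drop = FALSE]
  lp <- x$log10_P
  cross <- which(lp[-length(lp)] >= reference & lp[-1] < reference)
  at_ref <- which(lp == reference)
  if (!length(cross) && !length(at_ref))
    stop("curve '", label, "' never crosses reference ", reference,
         " on a declining segment", call. = FALSE)
  if (length(at_ref) && (!length(cross) || at_ref[1] <= cross[1])) {
    t_cross <- x$t[at_ref[1]]
  } else {
    i <- cross[1]
    # linear interpolation between bracketing points
    t_cross <- x$t[i] + (reference - lp[i]) / (lp[i + 1] - lp[i]) *
      (x$t[i + 1] - x$t[i])
  }
  x$t_shifted <- x$t - t_cross
  structure(x, shift = -t_cross, label = label,
            class = c("aligned_curve", "data.frame"))
}

#' Slope of an aligned curve within a log-abundance window
#'
#' OLS slope of log10 abundance against shifted time, restricted to points
#' strictly inside the open window (lo, hi). On a pure exponential decline
#' at rate g (d^-1) the slope is \eqn{-g/\ln 10} per day.
#'
#' @param aligned an \code{\link{aligned_curve}} (or any data.frame with
#'   \code{t_shifted} and \code{log10_P}).
#' @param lo,hi open-window bounds in log10 abundance (defaults 4.5, 6.5).
#' @param per \code{"day"} or \code{"hour"}: unit of the time axis of
#'   \code{aligned}; the slope is reported in log10 units per that unit.
#' @return list with \code{slope}, \code{se}, \code{r_squared}, \code{n}.
#' @export
window_slope <- function(aligned, lo = 4.5, hi = 6.5,
                         per = c("day", "hour")) {
  per <- match.arg(per)
  stopifnot(all(c("t_shifted", "log10_P") %in% names(aligned)))
  sub <- aligned[aligned$log10_P > lo & aligned$log10_P < hi, ,
                 drop = FALSE]
  if (nrow(sub) < 3L)
    stop("fewer than 3 points inside the (", lo, ", ", hi, ") window",
         call. = FALSE)
  fit <- stats::lm(log10_P ~ t_shifted, data = sub)
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[2]),
       se = sm$coefficients[2, "Std. Error"],
       r_squared = sm$r.squared, n = nrow(sub), per = per)
}

#' Welch's unequal-variance t test
#'
#' Two-sided test of equal means without assuming equal variances
#' (Welch--Satterthwaite degrees of freedom). Thin wrapper over
#' \code{stats::t.test} returning the triple used in reports.
#'
#' @param a,b numeric vectors, each n >= 2 with nonzero combined variance.
#' @return list with \code{t}, \code{df}, \code{p}.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (identical(mean(a), mean(b)))
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("degenerate groups: zero variance in both", call. = FALSE)
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-sample Wilcoxon rank-sum test with family-wise adjustment
#'
#' Exact two-sided p for small untied samples (via \code{stats::wilcox.test});
#' the adjusted p applies a family-wise correction over \code{n_comparisons}
#' tests made in the same report.
#'
#' @param a,b numeric vectors, each n >= 2.
#' @param adjust adjustment method for \code{stats::p.adjust}
#'   (default \code{"bonferroni"}).
#' @param n_comparisons size of the comparison family (default 1).
#' @return list with \code{W}, \code{p}, \code{p_adjusted}.
#' @export
rank_sum_test <- function(a, b, adjust = "bonferroni", n_comparisons = 1L) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs n >= 2", call. = FALSE)
  ht <- suppressWarnings(stats::wilcox.test(a, b))
  p_adj <- stats::p.adjust(rep(ht$p.value, n_comparisons),
                           method = adjust)[1]
  list(W = unname(ht$statistic), p = ht$p.value, p_adjusted = p_adj)
}

#' Kruskal--Wallis rank-sum test across groups
#'
#' Ties-corrected H statistic with a chi-square p (via
#' \code{stats::kruskal.test}). With all observations identical the
#' ties-corrected statistic is undefined (0/0); this wrapper reports
#' H = 0, p = 1 for that degenerate case.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with \code{H}, \code{df}, \code{p}.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L || any(lengths(groups) < 2L))
    stop("need >= 2 groups, each n >= 2", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- stats::kruskal.test(values, g)
  list(H = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Bin records by mean log10 abundance
#'
#' Half-open bins [lo, lo + width) anchored at multiples of the width,
#' returned in descending abundance order (experiments progress from high
#' to low prey abundance).
#'
#' @param records data.frame with a \code{mean_log10_P} column.
#' @param bin_width bin width in log10 units (default 0.5; \code{Inf}
#'   yields a single bin).
#' @return the records with a \code{bin} factor column (levels descending),
#'   plus attribute \code{breaks}.
#' @export
bin_by_abundance <- function(records, bin_width = 0.5) {
  stopifnot("mean_log10_P" %in% names(records))
  x <- records$mean_log10_P
  if (is.infinite(bin_width)) {
    records$bin <- factor(rep("all", nrow(records)))
    return(records)
  }
  lo <- floor(x / bin_width) * bin_width
  lab <- sprintf("[%g,%g)", lo, lo + bin_width)
  lev <- unique(lab[order(-lo)])
  records$bin <- factor(lab, levels = lev)
  attr(records, "breaks") <- sort(unique(c(lo, lo + bin_width)))
  records
}

#' Group means with standard errors
#'
#' Mean, standard error (sd/sqrt(n); 0 for n = 1 by convention) and n per
#' group — the shape of the lab and field summary tables. Non-detect
#' rates enter as their reported zeros.
#'
#' @param df data.frame of records.
#' @param value_col column to summarize.
#' @param by character vector of grouping columns.
#' @return data.frame with the grouping columns plus \code{mean},
#'   \code{se}, \code{n}.
#' @export
summarize_rates <- function(df, value_col = "value", by) {
  stopifnot(value_col %in% names(df), all(by %in% names(df)))
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    v <- g[[value_col]]
    cbind(g[1, by, drop = FALSE],
          data.frame(mean = mean(v),
                     se = if (length(v) > 1)
                       stats::sd(v) / sqrt(length(v)) else 0,
                     n = length(v)))
  }))
  rownames(out) <- NULL
  out
}

#' Field report: per-depth method comparison
#'
#' The field-mode endpoint: per-depth mean ± SE for each method, a grand
#' mean per method across depths (mean of the per-depth means), and a
#' Wilcoxon rank-sum comparison of the two methods at each depth with
#' Bonferroni adjustment across depths. Non-detect rates must already be
#' encoded as zeros in \code{value}.
#'
#' @param rates data.frame with columns \code{method} (two levels,
#'   e.g. dilution and flb), \code{depth}, \code{value}.
#' @param adjust family-wise adjustment method (default Bonferroni); the
#'   unadjusted p is also reported.
#' @return list with \code{summary} (method x depth rows), \code{grand}
#'   (per-method grand means), and \code{tests} (one row per depth).
#' @export
field_report <- function(rates, adjust = "bonferroni") {
  stopifnot(all(c("method", "depth", "value") %in% names(rates)))
  methods <- sort(unique(rates$method))
  depths <- sort(unique(rates$depth))
  summary_tab <- summarize_rates(rates, "value", c("method", "depth"))
  grand <- do.call(rbind, lapply(methods, function(m) {
    per_depth <- summary_tab$mean[summary_tab$method == m]
    data.frame(method = m, grand_mean = mean(per_depth),
               n_depths = length(per_depth))
  }))
  tests <- NULL
  if (length(methods) == 2L) {
    tests <- do.call(rbind, lapply(depths, function(d) {
      a <- rates$value[rates$method == methods[1] & rates$depth == d]
      b <- rates$value[rates$method == methods[2] & rates$depth == d]
      if (length(a) < 2L || length(b) < 2L) {
        warning("depth ", d, ": too few rates for a test")
        return(data.frame(depth = d, W = NA, p = NA, p_adjusted = NA))
      }
      tt <- rank_sum_test(a, b, adjust = adjust,
                          n_comparisons = length(depths))
      data.frame(depth = d, W = tt$W, p = tt$p,
                 p_adjusted = tt$p_adjusted)
    }))
  } else {
    warning("field report expects exactly 2 methods; tests skipped")
  }
  list(summary = summary_tab, grand = grand, tests = tests)
}
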