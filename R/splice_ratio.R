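## log(AS/FS) splicing ratios, their rhythm fold range, and the
## ratio-versus-temperature regression.

#' Default pseudo-count for splicing ratios
#'
#' Half the smallest nonzero abundance in the dataset; added symmetrically
#' to numerator and denominator so ratios stay defined at below-detection
#' points.
#'
#' @param abundances numeric vector of normalized abundances (>= 0).
#' @return Numeric scalar.
#' @export
default_pseudocount <- function(abundances) {
  nz <- abundances[abundances > 0]
  if (length(nz) == 0L) stop("no nonzero abundances to set a pseudo-count")
  min(nz) / 2
}

#' Compute a log(AS/FS) splicing-ratio series
#'
#' Aligns an AS isoform series with its fully spliced counterpart on
#' (sample, time, replicate) and computes
#' `log_base((AS + pseudo) / (FS + pseudo))`. Points where both isoforms
#' are below detection are dropped and counted.
#'
#' @param as_series,fs_series data.frames with columns `zt`, `replicate`,
#'   `norm_abundance` (and optionally `sample_id`, `clock_time` carried
#'   through from the AS series).
#' @param pseudo pseudo-count; default [default_pseudocount()] of the two
#'   series pooled.
#' @param base log base, 10 (default) or `exp(1)`.
#' @return data.frame with the alignment keys, `as_abundance`,
#'   `fs_abundance`, `log_ratio`; attributes `pseudo`, `base`, and
#'   `n_dropped` (points with both isoforms below detection).
#' @export
ratio_series <- function(as_series, fs_series, pseudo = NULL, base = 10) {
  ## sample ids disambiguate the duplicated wrapped time points of a
  ## >24-h course; without them, (zt, replicate) must be unique
  keys <- if ("sample_id" %in% names(as_series) &&
              "sample_id" %in% names(fs_series)) "sample_id"
          else c("zt", "replicate")
  stopifnot(all(keys %in% names(as_series)),
            all(keys %in% names(fs_series)))
  a_key <- do.call(paste, c(as_series[keys], sep = "\r"))
  f_key <- do.call(paste, c(fs_series[keys], sep = "\r"))
  miss <- union(setdiff(a_key, f_key), setdiff(f_key, a_key))
  if (length(miss) > 0L)
    stop("alignment error: unmatched (zt, replicate) keys: ",
         paste(gsub("\r", "/", miss), collapse = ", "))
  idx <- match(a_key, f_key)
  as_ab <- as_series$norm_abundance
  fs_ab <- fs_series$norm_abundance[idx]
  if (is.null(pseudo)) pseudo <- default_pseudocount(c(as_ab, fs_ab))
  if (pseudo < 0) stop("pseudo-count must be >= 0")
  drop <- as_ab == 0 & fs_ab == 0
  carry <- setdiff(intersect(c("sample_id", "clock_time", "organ",
                               "season_id", "zt", "replicate"),
                             names(as_series)), keys)
  out <- cbind(as_series[!drop, c(carry, keys), drop = FALSE],
               data.frame(as_abundance = as_ab[!drop],
                          fs_abundance = fs_ab[!drop]))
  out$log_ratio <- log((out$as_abundance + pseudo) /
                         (out$fs_abundance + pseudo), base = base)
  rownames(out) <- NULL
  attr(out, "pseudo") <- pseudo
  attr(out, "base") <- base
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Fold range of a splicing-ratio rhythm
#'
#' The ratio between the maximum and minimum AS/FS ratio on the linear
#' scale, i.e. `base^(max - min)` of the log-ratio series (optionally
#' LOESS-smoothed first). This reading is invariant to the log base. The
#' literal ratio of the two log values is available behind
#' `literal_log_ratio = TRUE` for comparison.
#'
#' @param ratio output of [ratio_series()].
#' @param smooth logical; smooth the series with [fit_loess()] before
#'   taking the range (default `FALSE`).
#' @param span LOESS span when smoothing.
#' @param literal_log_ratio report `max(log)/min(log)` instead of the
#'   linear-scale fold.
#' @return Numeric scalar fold.
#' @export
ratio_fold_range <- function(ratio, smooth = FALSE, span = 0.5,
                             literal_log_ratio = FALSE) {
  if (nrow(ratio) < 2L) stop("fold range undefined: fewer than 2 points")
  base <- attr(ratio, "base")
  if (is.null(base)) base <- 10
  vals <- if (smooth) {
    fit <- fit_loess(data.frame(zt = ratio$zt,
                                abundance = ratio$log_ratio),
                     span = span, n_boot = 0L)
    fit$fitted[!is.na(fit$fitted)]
  } else {
    ratio$log_ratio
  }
  if (literal_log_ratio) return(max(vals) / min(vals))
  base^(max(vals) - min(vals))
}

#' Interpolate ambient temperature at sampling instants
#'
#' Linear interpolation of a weather-station series to arbitrary clock
#' times within one season.
#'
#' @param temps data.frame with `clock_time` (decimal hours, increasing
#'   over the logged span) and `temp_c`.
#' @param clock_time times to interpolate at.
#' @return Numeric vector of degrees Celsius.
#' @export
temperature_at <- function(temps, clock_time) {
  if (any(clock_time < min(temps$clock_time) - 1e-9) ||
      any(clock_time > max(temps$clock_time) + 1e-9))
    stop("temperature series does not cover all sampling instants")
  stats::approx(temps$clock_time, temps$temp_c, xout = clock_time,
                ties = "ordered")$y
}

#' Regress splicing ratios on ambient temperature
#'
#' Ordinary least squares of log(AS/FS) on temperature over a pooled group
#' of points, with the two-sided p-value of the slope. A significant
#' negative correlation requires `slope < 0` and `p < alpha`.
#'
#' @param ratio output of [ratio_series()] (or any data.frame with
#'   `log_ratio` and `clock_time`).
#' @param temps temperature series as in [temperature_at()]; ignored when
#'   `temp_c` is supplied directly.
#' @param temp_c optional vector of temperatures matched to `ratio` rows.
#' @param alpha significance level (default 0.05).
#' @return List of class `temp_regression`: `slope` (per degree C),
#'   `intercept`, `r_squared`, `p_value`, `n`, `significant_negative`.
#' @export
temp_regression <- function(ratio, temps = NULL, temp_c = NULL,
                            alpha = 0.05) {
  if (is.null(temp_c)) {
    if (is.null(temps)) stop("supply `temps` or `temp_c`")
    temp_c <- temperature_at(temps, ratio$clock_time)
  }
  keep <- is.finite(ratio$log_ratio) & is.finite(temp_c)
  y <- ratio$log_ratio[keep]
  x <- temp_c[keep]
  if (length(y) < 3L)
    stop("insufficient data: need >= 3 matched points for the regression")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2L])
  p <- sm$coefficients[2L, 4L]
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = sm$r.squared, p_value = p, n = length(y),
                 significant_negative = slope < 0 && p < alpha),
            class = "temp_regression")
}

#' @export
print.temp_regression <- function(x, ...) {
  cat(sprintf(
    "<temp_regression> slope %.4f /degC, R^2 %.3f, p %.3g, n %d%s\n",
    x$slope, x$r_squared, x$p_value, x$n,
    if (x$significant_negative) " (significant negative)" else ""))
  invisible(x)
}
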