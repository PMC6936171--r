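## LOESS trend fitting for diel abundance series, peak-phase extraction,
## expression calls, and the study's group comparisons.

#' Fit a LOESS trend to a diel abundance series
#'
#' Local-linear LOESS with tricube weights over all replicate points
#' (replicates are not pre-averaged), evaluated on a fixed zeitgeber-time
#' grid. Standard errors come from a seeded bootstrap over replicate
#' points. A series with no variation returns the constant with zero SE.
#'
#' @param points data.frame with columns `zt` and `abundance` (one row per
#'   replicate per time point); additional columns are ignored.
#' @param span LOESS span (fraction of points per local fit, default 0.5).
#' @param grid_step grid resolution in hours (default 0.1).
#' @param n_boot bootstrap resamples for the SE band (default 200; 0 skips
#'   the band).
#' @param seed integer seed for the bootstrap.
#' @return Object of class `loess_fit`: list with `grid`, `fitted`, `se`,
#'   `span`, `peak_zt`, `peak_value` (peak searched on the default
#'   [find_peak()] window).
#' @export
fit_loess <- function(points, span = 0.5, grid_step = 0.1, n_boot = 200L,
                      seed = 1L) {
  stopifnot(all(c("zt", "abundance") %in% names(points)))
  zt <- points$zt
  y <- points$abundance
  if (length(unique(zt)) < 4L)
    stop("need >= 4 distinct time points for a LOESS fit")
  grid <- seq(0, 24 - grid_step, by = grid_step)
  if (stats::var(y) == 0) {
    fit <- structure(list(grid = grid, fitted = rep(y[1L], length(grid)),
                          se = rep(0, length(grid)), span = span),
                     class = "loess_fit")
  } else {
    fitted <- loess_predict(zt, y, grid, span)
    se <- rep(NA_real_, length(grid))
    if (n_boot > 0L) {
      boot <- withr::with_seed(seed, {
        vapply(seq_len(n_boot), function(b) {
          i <- sample.int(length(y), replace = TRUE)
          loess_predict(zt[i], y[i], grid, span)
        }, numeric(length(grid)))
      })
      se <- apply(boot, 1L, stats::sd, na.rm = TRUE)
    }
    fit <- structure(list(grid = grid, fitted = fitted, se = se,
                          span = span),
                     class = "loess_fit")
  }
  pk <- find_peak(fit)
  fit$peak_zt <- pk[["peak_zt"]]
  fit$peak_value <- pk[["peak_value"]]
  fit
}

loess_predict <- function(zt, y, grid, span) {
  lo <- suppressWarnings(
    stats::loess(y ~ zt, data = data.frame(zt = zt, y = y),
                 span = span, degree = 1, family = "gaussian",
                 control = stats::loess.control(surface = "direct")))
  out <- suppressWarnings(stats::predict(lo, newdata = data.frame(zt = grid)))
  ## do not extrapolate beyond the observed time span
  out[grid < min(zt) - 1e-9 | grid > max(zt) + 1e-9] <- NA_real_
  as.numeric(out)
}

#' @export
print.loess_fit <- function(x, ...) {
  cat(sprintf("<loess_fit> span %.2f, grid %.1f..%.1f: peak %.2f at ZT %.1f\n",
              x$span, min(x$grid), max(x$grid), x$peak_value, x$peak_zt))
  invisible(x)
}

#' Locate the rhythm peak on a LOESS curve
#'
#' The peak of a rhythm is the maximum of the LOESS curve inside the search
#' window, by default ZT0 to ZT22. Ties take the earliest grid point.
#'
#' @param fit a `loess_fit`.
#' @param window two-element numeric, inclusive zeitgeber-time window
#'   (default `c(0, 22)`).
#' @return Named numeric vector `c(peak_zt, peak_value)`.
#' @export
find_peak <- function(fit, window = c(0, 22)) {
  keep <- fit$grid >= window[1L] & fit$grid <= window[2L] &
    !is.na(fit$fitted)
  if (!any(keep)) stop("empty peak-search window")
  g <- fit$grid[keep]
  f <- fit$fitted[keep]
  i <- which.max(f)           # which.max returns the first (earliest) tie
  c(peak_zt = g[i], peak_value = f[i])
}

#' Call an isoform expressed or not expressed
#'
#' An isoform counts as expressed when its fitted peak reaches an absolute
#' floor and a fraction of its paired fully spliced isoform's peak. The 5%
#' default is this package's operational definition — the original study
#' reports such calls without stating a criterion.
#'
#' @param fit `loess_fit` of the isoform under test.
#' @param fs_fit `loess_fit` of the paired fully spliced isoform (required
#'   when `threshold > 0`).
#' @param threshold fraction of the FS peak (default 0.05).
#' @param floor absolute abundance floor (default 0).
#' @return `"expressed"` or `"not_expressed"`.
#' @export
expression_call <- function(fit, fs_fit = NULL, threshold = 0.05,
                            floor = 0) {
  if (threshold > 0 && is.null(fs_fit))
    stop("configuration error: paired FS fit required for the relative threshold")
  ok <- fit$peak_value >= floor &&
    (threshold <= 0 || fit$peak_value >= threshold * fs_fit$peak_value)
  if (ok) "expressed" else "not_expressed"
}

#' Compare replicate groups (paired t-test or one-way ANOVA + Tukey HSD)
#'
#' `paired_t` runs a two-sided paired Student's t-test on two equal-length
#' vectors. `anova_tukey` runs a one-way ANOVA across two or more groups
#' followed by Tukey's HSD. Degenerate inputs (no variance anywhere) are
#' flagged rather than raised.
#'
#' @param groups list of numeric vectors. For `paired_t`, exactly two of
#'   equal length (>= 2); pairing is by position.
#' @param design `"paired_t"` or `"anova_tukey"`.
#' @param alpha significance level (default 0.05).
#' @return List with `design`, `statistic`, `p_value`, `significant`,
#'   `degenerate`, and for `anova_tukey` a `tukey` data.frame of pairwise
#'   comparisons (`pair`, `diff`, `p_adj`, `significant`).
#' @export
compare_groups <- function(groups, design = c("paired_t", "anova_tukey"),
                           alpha = 0.05) {
  design <- match.arg(design)
  if (design == "paired_t") {
    stopifnot(length(groups) == 2L)
    a <- groups[[1L]]; b <- groups[[2L]]
    if (length(a) != length(b) || length(a) < 2L)
      stop("paired t-test needs two equal-length vectors of length >= 2")
    d <- a - b
    if (stats::sd(d) == 0) {
      p <- if (mean(d) == 0) 1 else 0
      return(list(design = design, statistic = if (mean(d) == 0) 0 else Inf,
                  p_value = p, significant = p < alpha, degenerate = TRUE))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    list(design = design, statistic = unname(tt$statistic),
         p_value = tt$p.value, significant = tt$p.value < alpha,
         degenerate = FALSE)
  } else {
    stopifnot(length(groups) >= 2L, all(lengths(groups) >= 2L))
    values <- unlist(groups, use.names = FALSE)
    g <- factor(rep(seq_along(groups), lengths(groups)),
                labels = if (is.null(names(groups)))
                  paste0("g", seq_along(groups)) else names(groups))
    if (stats::var(values) == 0)
      return(list(design = design, statistic = 0, p_value = 1,
                  significant = FALSE, degenerate = TRUE,
                  tukey = data.frame(pair = character(0), diff = numeric(0),
                                     p_adj = numeric(0),
                                     significant = logical(0))))
    fit <- stats::aov(values ~ g)
    p <- summary(fit)[[1L]][["Pr(>F)"]][1L]
    f <- summary(fit)[[1L]][["F value"]][1L]
    tk <- stats::TukeyHSD(fit)$g
    tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                        p_adj = tk[, "p adj"],
                        significant = tk[, "p adj"] < alpha,
                        stringsAsFactors = FALSE, row.names = NULL)
    list(design = design, statistic = f, p_value = p,
         significant = p < alpha, degenerate = FALSE, tukey = tukey)
  }
}
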