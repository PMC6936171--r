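## Zeitgeber-time normalization of field sampling times to a reference
## 12 h day / 12 h night photoperiod.

#' Parse a clock time
#'
#' Accepts `"HH:MM"` strings or decimal hours and returns decimal hours.
#'
#' @param x character or numeric vector.
#' @return Numeric vector of decimal hours.
#' @export
parse_clock_time <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  out <- vapply(x, function(s) {
    if (grepl(":", s, fixed = TRUE)) {
      parts <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
      parts[1] + parts[2] / 60
    } else {
      as.numeric(s)
    }
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(out)) stop("unparseable clock time(s): ",
                       paste(x[is.na(out)], collapse = ", "))
  out
}

#' Define a seasonal photoperiod
#'
#' @param season_id label, e.g. `"winter"`.
#' @param dawn,dusk clock times (`"HH:MM"` or decimal hours since midnight).
#' @return Object of class `photoperiod`: list with `season_id`, `dawn`,
#'   `dusk`, `day_length` (hours of day, dusk - dawn) and `night_length`
#'   (24 - day length).
#' @export
photoperiod <- function(season_id, dawn, dusk) {
  dawn <- parse_clock_time(dawn)
  dusk <- parse_clock_time(dusk)
  if (dawn < 0 || dawn >= 24 || dusk >= 24)
    stop("dawn/dusk must lie within a civil day")
  if (dusk <= dawn)
    stop("dusk must fall after dawn (polar photoperiods unsupported)")
  structure(list(season_id = season_id, dawn = dawn, dusk = dusk,
                 day_length = dusk - dawn,
                 night_length = 24 - (dusk - dawn)),
            class = "photoperiod")
}

#' @export
print.photoperiod <- function(x, ...) {
  cat(sprintf("<photoperiod> %s: dawn %.2f h, dusk %.2f h (%.2f h day / %.2f h night)\n",
              x$season_id, x$dawn, x$dusk, x$day_length, x$night_length))
  invisible(x)
}

#' Normalize hours-since-dawn to zeitgeber time
#'
#' Maps time since dawn under a seasonal photoperiod onto the reference
#' 12 h/12 h day: during the day `ZT = 12 T / P_d`; during the night
#' `ZT = 12 + 12 (T - P_d) / P_n`, where `P_d` and `P_n` are the day and
#' night lengths. Times beyond 24 h wrap into `[0, 24)` with the cycle
#' counter retained.
#'
#' @param T numeric vector, hours since dawn (may exceed 24 across a long
#'   course; may not be negative).
#' @param pp a [photoperiod()].
#' @return data.frame with `T` (input), `T_mod` (reduced into `[0,24)`),
#'   `zt` in `[0, 24)` and integer `day_index` (`floor(T / 24)`).
#' @export
zt_normalize <- function(T, pp) {
  stopifnot(inherits(pp, "photoperiod"), all(T >= 0))
  day_index <- floor(T / 24)
  T_mod <- T - 24 * day_index
  zt <- ifelse(T_mod < pp$day_length,
               12 * T_mod / pp$day_length,
               12 + 12 * (T_mod - pp$day_length) / pp$night_length)
  data.frame(T = T, T_mod = T_mod, zt = zt, day_index = as.integer(day_index))
}

#' Invert the zeitgeber-time map
#'
#' Solves each branch of the normalization for the time since dawn.
#'
#' @param zt numeric vector of zeitgeber times in `[0, 24)`.
#' @param pp a [photoperiod()].
#' @return Numeric vector of hours since dawn in `[0, 24)`.
#' @export
zt_inverse <- function(zt, pp) {
  stopifnot(inherits(pp, "photoperiod"), all(zt >= 0), all(zt < 24))
  ifelse(zt < 12,
         zt * pp$day_length / 12,
         pp$day_length + (zt - 12) * pp$night_length / 12)
}

#' Round a zeitgeber time to its integer display label
#'
#' Display labels such as "ZT22" use round-half-up on the decimal value;
#' computation always stays in decimal hours.
#'
#' @param zt numeric vector.
#' @return Integer vector (mod 24).
#' @export
zt_label <- function(zt) {
  as.integer(floor(zt + 0.5)) %% 24L
}

#' Build a diel sampling schedule
#'
#' Time points start a fixed offset before dawn and repeat at a fixed
#' interval for the stated duration (endpoint included). The field design
#' default is sampling every 2 h for 26 h starting 2 h before dawn: 14
#' points.
#'
#' @param pp a [photoperiod()].
#' @param start_offset hours before dawn at which sampling starts.
#' @param interval hours between points (> 0).
#' @param duration total span in hours (>= interval).
#' @return data.frame with `point` (1..n), `clock_time` (decimal hours,
#'   increasing past 24 across midnight), `T` (hours since first dawn),
#'   `zt` and `day_index`.
#' @export
sampling_schedule <- function(pp, start_offset = 2, interval = 2,
                              duration = 26) {
  stopifnot(inherits(pp, "photoperiod"), interval > 0,
            duration >= interval)
  rel <- seq(0, duration, by = interval)
  T <- rel - start_offset          # hours since first dawn; starts negative
  clock_time <- pp$dawn + T
  ## fold pre-dawn times into the previous cycle so T >= 0 for zt mapping
  T_pos <- ifelse(T < 0, T + 24, T)
  zt <- zt_normalize(T_pos, pp)
  data.frame(point = seq_along(rel), clock_time = clock_time, T = T,
             zt = zt$zt,
             day_index = ifelse(T < 0, -1L, zt$day_index))
}
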