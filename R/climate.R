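## Climate covariate construction.
##
## Survival over the interval between breeding seasons t and t+1 is
## regressed on conditions of the nonbreeding (austral winter) period
## inside that interval: the mean daily minimum temperature and summed
## precipitation over April-August, and the mean monthly multivariate ENSO
## index from April through the following March. Recapture probability is
## regressed on annual catch effort.

# interval t (between occasions labeled year[t] and year[t+1]) is driven by
# the winter of calendar year year[t] + 1
interval_winter_year <- function(years) years[-length(years)] + 1L

#' Aggregate daily weather into per-interval covariates
#'
#' For each inter-occasion interval, computes the mean daily minimum
#' temperature and the summed daily precipitation over the nonbreeding
#' window (April 1 - August 31) that falls inside the interval. Small gaps
#' in the daily series are filled by linear interpolation in time; the fill
#' count is logged and attached as an attribute.
#'
#' @param daily data frame with columns `date`, `tmin_c`, `precip_mm`.
#' @param years occasion year labels (length T); covariates are produced for
#'   the T-1 intervals between consecutive occasions.
#' @param max_gap_frac maximum tolerated fraction of missing days per window
#'   (default 0.2) before a hard error.
#' @return data frame with columns `interval`, `winter_year`, `temp`,
#'   `precip`; attribute `n_filled` counts interpolated days.
#' @export
aggregate_weather <- function(daily, years, max_gap_frac = 0.2) {
  stopifnot(all(c("date", "tmin_c", "precip_mm") %in% names(daily)))
  daily$date <- as.Date(daily$date)
  wy <- interval_winter_year(years)
  n_filled <- 0L
  one <- function(y) {
    days <- seq(as.Date(sprintf("%d-04-01", y)), as.Date(sprintf("%d-08-31", y)), by = "day")
    idx <- match(days, daily$date)
    tmin <- daily$tmin_c[idx]
    prec <- daily$precip_mm[idx]
    nmiss <- sum(is.na(tmin) | is.na(prec))
    if (nmiss == length(days))
      stop("weather window entirely missing for year ", y, call. = FALSE)
    if (nmiss / length(days) > max_gap_frac)
      stop(sprintf("weather window for year %d has %.0f%% missing days (limit %.0f%%)",
                   y, 100 * nmiss / length(days), 100 * max_gap_frac), call. = FALSE)
    fill <- function(x) {
      if (!anyNA(x)) return(x)
      ok <- which(!is.na(x))
      stats::approx(ok, x[ok], xout = seq_along(x), rule = 2)$y
    }
    n_filled <<- n_filled + sum(is.na(tmin)) + sum(is.na(prec))
    tmin <- fill(tmin); prec <- fill(prec)
    c(temp = mean(tmin), precip = sum(prec))
  }
  agg <- t(vapply(wy, one, c(temp = 0, precip = 0)))
  if (n_filled > 0L) cjs_log("aggregate_weather: interpolated %d missing daily values", n_filled)
  out <- data.frame(interval = seq_along(wy), winter_year = wy,
                    temp = agg[, "temp"], precip = agg[, "precip"])
  attr(out, "n_filled") <- n_filled
  out
}

#' Aggregate monthly ENSO index into per-interval covariates
#'
#' For interval t the covariate is the arithmetic mean of the 12 monthly
#' index values from April of the interval's winter year through March of
#' the following year (nonbreeding season through the end of the subsequent
#' breeding season).
#'
#' @param monthly data frame with columns `year`, `month`, `mei`.
#' @param years occasion year labels (length T).
#' @return data frame with columns `interval`, `winter_year`, `enso`.
#' @export
aggregate_enso <- function(monthly, years) {
  stopifnot(all(c("year", "month", "mei") %in% names(monthly)))
  wy <- interval_winter_year(years)
  key <- monthly$year * 12L + monthly$month
  one <- function(y) {
    months <- c((y * 12L) + 4:12, ((y + 1L) * 12L) + 1:3)
    v <- monthly$mei[match(months, key)]
    if (anyNA(v))
      stop("missing ENSO month(s) in window Apr ", y, " - Mar ", y + 1L, call. = FALSE)
    mean(v)
  }
  data.frame(interval = seq_along(wy), winter_year = wy,
             enso = vapply(wy, one, numeric(1)))
}

#' Assemble and standardize the per-occasion covariate design
#'
#' Combines weather, ENSO, effort and a linear year term into the design
#' used by the survival and recapture regressions; centers and scales every
#' continuous covariate to sample SD 1; computes pairwise Pearson
#' correlations among the three weather/climate covariates and flags any
#' pair at or above `max_abs_corr`.
#'
#' @param weather output of [aggregate_weather()].
#' @param enso output of [aggregate_enso()].
#' @param effort data frame with columns `occasion_year`, `net_hours_area`
#'   covering all occasion years.
#' @param years occasion year labels (length T, T >= 3).
#' @param max_abs_corr collinearity gate threshold on `|r|` (default 0.5).
#' @param fail_on_collinear if `TRUE`, a gated pair is an error instead of
#'   a warning.
#' @return an object of class `cjs_design`: list with `years`, `intervals`
#'   (data frame of raw and `_z` standardized interval covariates `year`,
#'   `temp`, `precip`, `enso`), `effort` (length-T raw vector) and
#'   `effort_z`, plus the correlation matrix `cor_climate`.
#' @export
standardize_and_gate <- function(weather, enso, effort, years,
                                 max_abs_corr = 0.5, fail_on_collinear = FALSE) {
  T <- length(years)
  if (T < 3L) stop("need at least 3 occasions", call. = FALSE)
  iv <- data.frame(interval = seq_len(T - 1L),
                   year = as.numeric(seq_len(T - 1L)),
                   temp = weather$temp, precip = weather$precip, enso = enso$enso)
  for (v in c("year", "temp", "precip", "enso")) iv[[paste0(v, "_z")]] <- zstd(iv[[v]], v)
  eff <- effort$net_hours_area[match(years, effort$occasion_year)]
  if (anyNA(eff)) stop("effort missing for occasion year(s): ",
                       paste(years[is.na(eff)], collapse = ", "), call. = FALSE)
  cm <- stats::cor(iv[, c("temp", "precip", "enso")])
  worst <- max(abs(cm[upper.tri(cm)]))
  if (worst >= max_abs_corr) {
    msg <- sprintf("collinearity gate: max |r| among climate covariates = %.3f (threshold %.2f)",
                   worst, max_abs_corr)
    if (fail_on_collinear) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(list(years = years, intervals = iv,
                 effort = eff, effort_z = zstd(eff, "effort"),
                 cor_climate = cm),
            class = "cjs_design")
}

#' @export
print.cjs_design <- function(x, ...) {
  cat("CJS covariate design:", length(x$years), "occasions (",
      min(x$years), "-", max(x$years), ")\n")
  cat("max |r| among climate covariates:",
      round(max(abs(x$cor_climate[upper.tri(x$cor_climate)])), 3), "\n")
  invisible(x)
}

#' Test a covariate series for a temporal trend
#'
#' Ordinary least-squares regression of the series on its occasion index,
#' with the two-sided t-test p-value for the slope.
#'
#' @param series numeric per-occasion (or per-interval) values, length >= 3.
#' @return list with `slope`, `se`, `p_value` and the fitted `lm` object.
#' @export
trend_test <- function(series) {
  stopifnot(length(series) >= 3L)
  t_idx <- seq_along(series)
  fit <- stats::lm(series ~ t_idx)
  cf <- summary(fit)$coefficients
  if (nrow(cf) < 2L) {            # constant series: slope dropped by lm
    return(list(slope = 0, se = NA_real_, p_value = NA_real_, fit = fit))
  }
  list(slope = unname(cf[2L, 1L]), se = unname(cf[2L, 2L]),
       p_value = unname(cf[2L, 4L]), fit = fit)
}

#' Trend tests for all climate covariates of a design
#'
#' @param design a `cjs_design`.
#' @return data frame with one row per covariate (`temp`, `precip`, `enso`):
#'   OLS slope per occasion and its p-value.
#' @export
climate_trends <- function(design) {
  vars <- c("temp", "precip", "enso")
  do.call(rbind, lapply(vars, function(v) {
    tt <- trend_test(design$intervals[[v]])
    data.frame(covariate = v, slope = tt$slope, se = tt$se, p_value = tt$p_value)
  }))
}
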