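#' Monthly anomalies of a climate table
#'
#' Departure of each (year, month) value from that month's mean over the
#' reference span; per-month anomaly means over the reference span are 0 by
#' construction.
#'
#' @param climate data.frame(year, month, tmin_c, tavg_c, tmax_c, prcp_mm).
#' @param ref_span years used for the reference means (default 1950:2005).
#' @param vars columns to anomalize.
#' @return data.frame(year, month, <var>_anom ...).
#' @export
monthly_anomalies <- function(climate, ref_span = 1950:2005,
                              vars = c("tavg_c", "prcp_mm")) {
  check_climate(climate)
  if (!all(ref_span %in% climate$year))
    stop("ref_span must lie within the climate data span")
  ref <- climate[climate$year %in% ref_span, ]
  cnt <- table(ref$year)
  if (any(cnt != 12L)) stop("incomplete months in reference span")
  out <- climate[, c("year", "month")]
  for (v in vars) {
    clim <- tapply(ref[[v]], ref$month, mean)
    out[[paste0(sub("_(c|mm)$", "", v), "_anom")]] <-
      climate[[v]] - as.numeric(clim[as.character(climate$month)])
  }
  out
}

check_climate <- function(climate) {
  need <- c("year", "month", "tavg_c", "prcp_mm")
  if (!all(need %in% names(climate)))
    stop("climate table must have columns ", paste(need, collapse = ", "))
  if (all(c("tmin_c", "tmax_c") %in% names(climate)) &&
      any(climate$tmin_c > climate$tavg_c |
          climate$tavg_c > climate$tmax_c))
    stop("climate table violates tmin <= tavg <= tmax")
  invisible(climate)
}

anom_value <- function(anomalies, year, month, col = "tavg_anom") {
  v <- anomalies[[col]][anomalies$year == year & anomalies$month == month]
  if (length(v) != 1L)
    stop("missing month ", month, " in year ", year)
  v
}

#' Growing-season-length proxy: mean April + September temperature anomaly
#'
#' @param anomalies output of [monthly_anomalies()].
#' @param years years to evaluate (default: all years present).
#' @return named numeric vector (degrees C), one value per year.
#' @export
season_length_index <- function(anomalies, years = unique(anomalies$year)) {
  vapply(years, function(y)
    mean(c(anom_value(anomalies, y, 4), anom_value(anomalies, y, 9))),
    1.0, USE.NAMES = FALSE) |> stats::setNames(years)
}

#' Summer-heat proxy: mean June-August temperature anomaly
#'
#' @inheritParams season_length_index
#' @return named numeric vector (degrees C), one value per year.
#' @export
summer_heat_index <- function(anomalies, years = unique(anomalies$year)) {
  vapply(years, function(y)
    mean(vapply(6:8, function(m) anom_value(anomalies, y, m), 1.0)),
    1.0, USE.NAMES = FALSE) |> stats::setNames(years)
}

#' Bootstrapped Pearson correlation between a chronology and a predictor
#'
#' Point estimate is the Pearson correlation on the full pairing; the CI is
#' the percentile interval of the correlation over `n_boot` resamples of
#' (year, BAI, predictor) tuples drawn jointly with replacement (pairs kept
#' intact). The association is flagged significant iff the CI excludes 0.
#'
#' @param bai numeric chronology values (paired with `predictor` by year).
#' @param predictor numeric predictor values, same length.
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param level CI level (default 0.95).
#' @param seed RNG seed.
#' @return list(r, ci_lo, ci_hi, significant, n).
#' @export
bootstrap_correlation <- function(bai, predictor, n_boot = 1000,
                                  level = 0.95, seed = NULL) {
  ok <- is.finite(bai) & is.finite(predictor)
  x <- bai[ok]; y <- predictor[ok]
  n <- length(x)
  if (n < 10L) stop("need at least 10 complete paired years")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance chronology or predictor")
  r <- stats::cor(x, y)
  rs <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
    vapply(seq_len(n_boot), function(b) {
      i <- idx[, b]
      if (stats::sd(x[i]) == 0 || stats::sd(y[i]) == 0) NA_real_
      else stats::cor(x[i], y[i])
    }, 1.0)
  })
  qs <- stats::quantile(rs, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, names = FALSE)
  list(r = r, ci_lo = qs[1], ci_hi = qs[2],
       significant = qs[1] > 0 || qs[2] < 0, n = n)
}

#' Full climate-growth correlation function for one chronology
#'
#' Correlates the mean BAI chronology with monthly average temperature and
#' monthly total precipitation for January--September of the ring-formation
#' year, plus the April+September and June--August composite means of each
#' variable, each with a bootstrap percentile CI. Prior-year months can be
#' added with `include_prev_year` (correlations there were weak to moderate
#' in this system, so the default window is the formation year only).
#'
#' @param chronology a [build_mean_chronology()] result (or
#'   data.frame(year, mean_bai_cm2)).
#' @param climate monthly climate table.
#' @param n_boot,level,seed passed to [bootstrap_correlation()].
#' @param months months of the formation year (default 1:9).
#' @param vars climate variables (default tavg_c and prcp_mm).
#' @param include_prev_year also include the previous year's months.
#' @return data.frame(group, variable, window, r, ci_lo, ci_hi,
#'   significant).
#' @export
correlation_function <- function(chronology, climate, n_boot = 1000,
                                 level = 0.95, seed = NULL,
                                 months = 1:9,
                                 vars = c("tavg_c", "prcp_mm"),
                                 include_prev_year = FALSE) {
  check_climate(climate)
  yrs <- chronology$year
  bai <- chronology$mean_bai_cm2
  month_names <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun", "Jul", "Aug",
                   "Sep", "Oct", "Nov", "Dec")
  grab <- function(var, m, lag = 0L) {
    key <- paste(yrs - lag, m)
    climate[[var]][match(key, paste(climate$year, climate$month))]
  }
  rows <- list()
  k <- 0L
  for (v in vars) {
    vlab <- if (v == "tavg_c") "tavg" else sub("_mm$", "", v)
    windows <- list()
    if (include_prev_year)
      for (m in months)
        windows[[paste0("prev", month_names[m])]] <- grab(v, m, lag = 1L)
    for (m in months) windows[[month_names[m]]] <- grab(v, m)
    windows[["AprSep"]] <- (grab(v, 4) + grab(v, 9)) / 2
    windows[["JunAug"]] <- (grab(v, 6) + grab(v, 7) + grab(v, 8)) / 3
    for (w in names(windows)) {
      k <- k + 1L
      bc <- bootstrap_correlation(bai, windows[[w]], n_boot = n_boot,
                                  level = level,
                                  seed = child_seed(seed, paste(v, w)))
      rows[[k]] <- data.frame(
        group = attr(chronology, "group") %||% "chronology",
        variable = vlab, window = w, r = bc$r, ci_lo = bc$ci_lo,
        ci_hi = bc$ci_hi, significant = bc$significant)
    }
  }
  do.call(rbind, rows)
}
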