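#' Recorded insect-epidemic calendar
#'
#' Defaults encode the documented outbreaks for the study area: a 9-year
#' triangular spruce budworm (SBW) impact (0.2, 0.4, 0.6, 0.8, 1, 0.8, 0.6,
#' 0.4, 0.2) centered on 1974, and forest tent caterpillar (FTC)
#' intensities of 1 in 1980 and 2001 and 0.5 in 2000.
#'
#' @param sbw_center_year peak year of the SBW epidemic.
#' @param sbw_weights odd-length weight vector, peak (= max) at the center.
#' @param ftc_intensity named numeric: year -> intensity in \[0, 1\].
#' @return object of class `epidemic_calendar`.
#' @export
epidemic_calendar <- function(sbw_center_year = 1974L,
                              sbw_weights = c(0.2, 0.4, 0.6, 0.8, 1,
                                              0.8, 0.6, 0.4, 0.2),
                              ftc_intensity = c("1980" = 1, "2000" = 0.5,
                                                "2001" = 1)) {
  if (length(sbw_weights) %% 2L == 0L)
    stop("sbw_weights must have odd length")
  center <- (length(sbw_weights) + 1L) / 2L
  if (sbw_weights[center] != max(sbw_weights))
    stop("peak weight must be at the center of sbw_weights")
  if (any(ftc_intensity < 0 | ftc_intensity > 1))
    stop("ftc intensities must lie in [0, 1]")
  structure(list(sbw_center_year = as.integer(sbw_center_year),
                 sbw_weights = sbw_weights,
                 ftc_intensity = ftc_intensity),
            class = "epidemic_calendar")
}

#' Spruce budworm epidemic-intensity covariate
#'
#' Triangular impact window around the center year; 0 elsewhere. Years
#' outside the supplied span clip the window.
#'
#' @param calendar an [epidemic_calendar()].
#' @param years calendar years to evaluate.
#' @return named numeric vector of intensities.
#' @export
build_sbw_covariate <- function(calendar = epidemic_calendar(),
                                years) {
  w <- calendar$sbw_weights
  half <- (length(w) - 1L) / 2L
  win_years <- calendar$sbw_center_year + (-half:half)
  out <- stats::setNames(numeric(length(years)), years)
  hit <- match(years, win_years)
  out[!is.na(hit)] <- w[hit[!is.na(hit)]]
  out
}

#' Forest tent caterpillar epidemic-intensity covariate
#'
#' @inheritParams build_sbw_covariate
#' @return named numeric vector of intensities (0 outside recorded years).
#' @export
build_ftc_covariate <- function(calendar = epidemic_calendar(),
                                years) {
  out <- stats::setNames(numeric(length(years)), years)
  hit <- match(as.character(years), names(calendar$ftc_intensity))
  out[!is.na(hit)] <- calendar$ftc_intensity[hit[!is.na(hit)]]
  out
}

#' Long-term linear trend covariate
#'
#' An incremental integer centered so that 1950 maps to -27 and 2005 to
#' +28 over the default span (value = year - 1977); requires contiguous
#' years.
#'
#' @param years contiguous calendar years (default 1950:2005).
#' @param center_year year mapped to 0 (default 1977).
#' @return named integer vector.
#' @export
build_trend_covariate <- function(years = 1950:2005, center_year = 1977L) {
  years <- as.integer(years)
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("years must be contiguous")
  stats::setNames(years - as.integer(center_year), years)
}

#' Assemble the per-year covariate table
#'
#' Columns: trend, season_length (C), summer_heat (C), sbw and ftc
#' intensities (0-1), complete over the requested years. Anomalies are
#' referenced to `ref_span`.
#'
#' @param climate monthly climate table covering `years`.
#' @param years covariate years (default 1950:2005).
#' @param calendar an [epidemic_calendar()].
#' @param ref_span anomaly reference span (default 1950:2005).
#' @return data.frame(year, trend, season_length, summer_heat, sbw, ftc).
#' @export
build_covariate_table <- function(climate, years = 1950:2005,
                                  calendar = epidemic_calendar(),
                                  ref_span = 1950:2005) {
  anoms <- monthly_anomalies(climate, ref_span = ref_span)
  data.frame(
    year = as.integer(years),
    trend = as.integer(build_trend_covariate(years)),
    season_length = as.numeric(season_length_index(anoms, years)),
    summer_heat = as.numeric(summer_heat_index(anoms, years)),
    sbw = as.numeric(build_sbw_covariate(calendar, years)),
    ftc = as.numeric(build_ftc_covariate(calendar, years))
  )
}

#' Rank year-to-year BAI changes and flag epidemic coincidences
#'
#' First differences `diff_t = BAI_t - BAI_(t-1)` are assigned to the later
#' year `t` (a drop "into" an epidemic year is that year's anomaly).
#' Decreases are ranked by ascending difference (most negative = rank 1),
#' increases by descending difference (largest rise = rank 1); ties give
#' the earlier calendar year the better rank. Each year is flagged when it
#' falls inside the SBW triangular window or is a recorded FTC year.
#'
#' @param chronology a [build_mean_chronology()] result (length >= 2).
#' @param calendar an [epidemic_calendar()].
#' @return data.frame(year, diff_cm2, decrease_rank, increase_rank,
#'   sbw_window, ftc_year).
#' @export
rank_first_differences <- function(chronology,
                                   calendar = epidemic_calendar()) {
  if (nrow(chronology) < 2L) stop("chronology must have length >= 2")
  yrs <- chronology$year[-1]
  d <- diff(chronology$mean_bai_cm2)
  dec <- d < 0
  inc <- d > 0
  decrease_rank <- rep(NA_integer_, length(d))
  increase_rank <- rep(NA_integer_, length(d))
  if (any(dec))
    decrease_rank[dec] <- rank_with_year_ties(d[dec], yrs[dec],
                                              decreasing = FALSE)
  if (any(inc))
    increase_rank[inc] <- rank_with_year_ties(d[inc], yrs[inc],
                                              decreasing = TRUE)
  sbw <- build_sbw_covariate(calendar, yrs)
  data.frame(year = yrs, diff_cm2 = d,
             decrease_rank = decrease_rank,
             increase_rank = increase_rank,
             sbw_window = sbw > 0,
             ftc_year = as.character(yrs) %in%
               names(calendar$ftc_intensity))
}

# rank values (1 = first in the given direction), earlier year wins ties
rank_with_year_ties <- function(values, years, decreasing) {
  ord <- order(if (decreasing) -values else values, years)
  rnk <- integer(length(values))
  rnk[ord] <- seq_along(values)
  rnk
}
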