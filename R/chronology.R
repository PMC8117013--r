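#' Estimate the distance from the innermost measured ring to the pith
#'
#' When the innermost ring's visible arc geometry (chord `c`, height `h`)
#' is recorded, the pith distance is the radius of the circle through the
#' arc, `r = c^2/(8h) + h/2`. Without geometry, a fallback multiplies the
#' mean of the five innermost ring widths by an expected missing-ring
#' count. Series with pith present return 0.
#'
#' @param series a [ring_width_series()].
#' @param missing_ring_count expected number of rings lost to the pith in
#'   fallback mode (default 5).
#' @return estimated distance to pith in mm.
#' @export
estimate_distance_to_pith <- function(series, missing_ring_count = 5) {
  if (series$has_pith) return(0)
  if (!is.na(series$arc_chord_mm) && !is.na(series$arc_height_mm)) {
    h <- series$arc_height_mm
    if (h <= 0) stop("arc height must be > 0")
    return(series$arc_chord_mm^2 / (8 * h) + h / 2)
  }
  if (length(series$widths) < 5L)
    stop("fallback pith estimation needs at least 5 innermost rings")
  mean(series$widths[1:5]) * missing_ring_count
}

#' Convert ring widths to basal area increments
#'
#' Cumulative radius `r_t = pith_offset + sum(widths[1:t])` (mm);
#' `BAI_t = pi * (r_t^2 - r_(t-1)^2)` mm2, converted to cm2 (/100). The
#' telescoping identity `sum(BAI) = pi * (r_n^2 - r_0^2)` holds exactly.
#'
#' @param series a [ring_width_series()] (or bare numeric widths in mm with
#'   `first_year` supplied).
#' @param pith_offset distance from pith to innermost ring boundary, mm.
#' @param first_year needed only when `series` is a bare numeric vector.
#' @return data.frame(year, bai_cm2).
#' @export
ring_widths_to_bai <- function(series, pith_offset = 0, first_year = NULL) {
  if (inherits(series, "ring_width_series")) {
    widths <- series$widths
    first_year <- series$first_year
  } else {
    widths <- as.numeric(series)
    if (is.null(first_year)) stop("first_year required for bare widths")
  }
  if (any(widths < 0)) stop("widths must be >= 0")
  if (pith_offset < 0) stop("pith_offset must be >= 0")
  r <- pith_offset + cumsum(widths)
  r_prev <- c(pith_offset, r[-length(r)])
  bai_mm2 <- pi * (r^2 - r_prev^2)
  data.frame(year = first_year + seq_along(widths) - 1L,
             bai_cm2 = bai_mm2 / 100)
}

#' Cambial age of each ring
#'
#' Ring index plus the number of rings missing to the pith: 0 when the pith
#' is present, a configured count otherwise (the innermost measured ring of
#' a pith-present series has cambial age 1).
#'
#' @param series a [ring_width_series()].
#' @param missing_ring_count rings assumed lost to the pith when absent.
#' @return integer vector, one age per ring.
#' @export
cambial_ages <- function(series, missing_ring_count = 5) {
  offset <- if (series$has_pith) 0L else as.integer(missing_ring_count)
  seq_along(series$widths) + offset
}

#' Drop juvenile rings below a minimum cambial age
#'
#' Removes each tree's rings with cambial age below `min_age` (the first 14
#' rings at the default of 15 for a pith-present tree). Trees with no rings
#' left are dropped from the returned list.
#'
#' @param bai_list named list of data.frame(year, bai_cm2), one per tree.
#' @param age_list matching list of cambial age vectors.
#' @param min_age minimum cambial age retained (default 15).
#' @return filtered named list of BAI data.frames.
#' @export
filter_cambial_age <- function(bai_list, age_list, min_age = 15) {
  stopifnot(length(bai_list) == length(age_list))
  out <- list()
  for (i in seq_along(bai_list)) {
    keep <- age_list[[i]] >= min_age
    if (!any(keep)) next
    out[[names(bai_list)[i] %||% as.character(i)]] <-
      bai_list[[i]][keep, , drop = FALSE]
  }
  out
}

#' Per-tree BAI series for a group of ring-width series
#'
#' Convenience wrapper: estimates pith offsets (unless the sidecar truth is
#' supplied), converts widths to BAI, and applies the cambial-age filter.
#'
#' @param series list of [ring_width_series()].
#' @param min_age minimum cambial age (default 15).
#' @param missing_ring_count fallback missing-ring count.
#' @return named list of data.frame(year, bai_cm2).
#' @export
group_bai_series <- function(series, min_age = 15, missing_ring_count = 5) {
  bai_list <- list(); age_list <- list()
  for (s in series) {
    off <- estimate_distance_to_pith(s, missing_ring_count)
    bai_list[[s$tree_id]] <- ring_widths_to_bai(s, pith_offset = off)
    age_list[[s$tree_id]] <- cambial_ages(s, missing_ring_count)
  }
  filter_cambial_age(bai_list, age_list, min_age = min_age)
}

#' Build the mean BAI chronology for one group
#'
#' Per-year arithmetic mean over the trees present that year, with
#' SEM = sd/sqrt(n) (n-1 denominator) and the sample depth.
#'
#' @param bai_list named list of per-tree data.frame(year, bai_cm2).
#' @param group group label.
#' @param span analysis years (default 1950:2005).
#' @return object of class `mean_chronology`: data.frame(year,
#'   mean_bai_cm2, sem_cm2, n_trees) with attributes `group` and `span`.
#' @export
build_mean_chronology <- function(bai_list, group = "group",
                                  span = 1950:2005) {
  if (length(bai_list) == 0L) stop("empty group: no trees contribute")
  years <- sort(span)
  mat <- matrix(NA_real_, nrow = length(years), ncol = length(bai_list),
                dimnames = list(years, names(bai_list)))
  for (j in seq_along(bai_list)) {
    b <- bai_list[[j]]
    sel <- b$year %in% years
    mat[as.character(b$year[sel]), j] <- b$bai_cm2[sel]
  }
  n <- rowSums(!is.na(mat))
  if (any(n == 0L))
    stop("span year with zero trees: ", years[which(n == 0L)[1]])
  mean_bai <- rowMeans(mat, na.rm = TRUE)
  sdv <- apply(mat, 1, stats::sd, na.rm = TRUE)
  sem <- ifelse(n > 1, sdv / sqrt(n), NA_real_)
  out <- data.frame(year = years, mean_bai_cm2 = as.numeric(mean_bai),
                    sem_cm2 = as.numeric(sem), n_trees = as.integer(n))
  structure(out, group = group, span = range(years),
            class = c("mean_chronology", "data.frame"))
}

#' Descriptive crossdating statistics for a group of series
#'
#' Computed on ring widths (mm): mean ring width, its sd, mean sensitivity
#' `MS = mean(2|w_(t+1) - w_t| / (w_(t+1) + w_t))` averaged over series,
#' first-order autocorrelation (lag-1 Pearson, averaged over series;
#' constant series excluded as undefined), and series intercorrelation —
#' the mean over series of the Pearson correlation between each
#' first-differenced series and the mean of the other series' first
#' differences on the overlapping years (leave-one-out). A high-pass
#' first-difference is used in place of spline-based detrending, so the
#' statistic is fully specified and testable.
#'
#' @param series list of [ring_width_series()] (>= 2, each length >= 3).
#' @return one-row data.frame of statistics.
#' @export
chronology_stats <- function(series) {
  if (length(series) < 2L) stop("need at least 2 series")
  if (any(vapply(series, function(s) length(s$widths), 1L) < 3L))
    stop("each series must have length >= 3")
  ms_one <- function(w) {
    num <- 2 * abs(diff(w)); den <- w[-1] + w[-length(w)]
    mean(ifelse(den == 0, 0, num / den))
  }
  ar1_one <- function(w) {
    n <- length(w)
    if (stats::sd(w[-1]) == 0 || stats::sd(w[-n]) == 0) return(NA_real_)
    stats::cor(w[-1], w[-n])
  }
  widths <- lapply(series, `[[`, "widths")
  ms <- mean(vapply(widths, ms_one, 1.0))
  ar1v <- vapply(widths, ar1_one, 1.0)
  ar1 <- if (all(is.na(ar1v))) NA_real_ else mean(ar1v, na.rm = TRUE)
  # leave-one-out intercorrelation on first differences
  all_years <- sort(unique(unlist(lapply(series, series_years))))
  dmat <- matrix(NA_real_, length(all_years), length(series),
                 dimnames = list(all_years, NULL))
  for (j in seq_along(series)) {
    yrs <- series_years(series[[j]])[-1]
    dmat[as.character(yrs), j] <- diff(series[[j]]$widths)
  }
  ic <- vapply(seq_along(series), function(j) {
    others <- dmat[, -j, drop = FALSE]
    ref <- rowMeans(others, na.rm = TRUE)
    ok <- !is.na(dmat[, j]) & !is.nan(ref) & !is.na(ref)
    if (sum(ok) < 3L) return(NA_real_)
    if (stats::sd(dmat[ok, j]) == 0 || stats::sd(ref[ok]) == 0)
      return(NA_real_)
    stats::cor(dmat[ok, j], ref[ok])
  }, 1.0)
  data.frame(
    n_trees = length(series),
    mean_ring_width_mm = mean(vapply(widths, mean, 1.0)),
    sd_mm = mean(vapply(widths, stats::sd, 1.0)),
    mean_sensitivity = ms,
    ar1 = ar1,
    series_intercorrelation = mean(ic, na.rm = TRUE)
  )
}

#' Table of descriptive statistics for all chronology groups
#'
#' @param series_by_group named list (group -> list of series).
#' @param chronologies optional named list of [build_mean_chronology()]
#'   results; when given, mean BAI over the span is appended.
#' @return data.frame, one row per group.
#' @export
chronology_stats_table <- function(series_by_group, chronologies = NULL) {
  rows <- lapply(names(series_by_group), function(g) {
    st <- chronology_stats(series_by_group[[g]])
    st <- cbind(group = g, st)
    if (!is.null(chronologies) && g %in% names(chronologies))
      st$mean_bai_cm2 <- mean(chronologies[[g]]$mean_bai_cm2)
    st
  })
  do.call(rbind, rows)
}
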