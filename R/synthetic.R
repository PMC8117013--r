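#' Default generating truth for the synthetic study
#'
#' Bundles the "true" model coefficients per chronology group together with
#' the noise and population settings used by the synthetic-data generator.
#' Group baselines equal the observed group mean BAIs (2.5, 3.0, 2.2, 9.3,
#' 8.8 cm2) and tree counts equal the observed radii counts (61, 73, 30, 22,
#' 11); coefficient signs encode the qualitative response structure of the
#' study system — spruce grows with longer growing seasons, suffers under
#' summer heat and spruce budworm (SBW) defoliation, and, where it co-occurs
#' with aspen, benefits from forest tent caterpillar (FTC) epidemics that
#' suppress the aspen canopy; aspen growth is roughly halved by FTC
#' outbreaks.
#'
#' @param group_params named list (one entry per group label) of lists with
#'   `alpha` (named numeric: baseline, trend, season_length, summer_heat,
#'   sbw, ftc) and `sigma` (residual sd, cm2). Defaults described above.
#' @param ar1_coef lag-1 autocorrelation of the yearly noise on group BAI
#'   (marginal sd stays `sigma`); default 0 so the generator matches the
#'   model's iid-normal likelihood.
#' @param tree_sd sd of the between-tree multiplicative lognormal growth
#'   factor (mean-one parameterization).
#' @param n_trees named integer vector of trees per group.
#' @param years calendar years simulated (must cover 1950--2005).
#' @param seed base RNG seed for all generator stages.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(group_params = NULL,
                            ar1_coef = 0,
                            tree_sd = 0.2,
                            n_trees = c(spruce_PBS = 61L, spruce_M = 73L,
                                        spruce_PTA = 30L, aspen_PTA = 22L,
                                        aspen_M = 11L),
                            years = 1920:2005,
                            seed = 1L) {
  if (is.null(group_params)) {
    a <- function(baseline, trend, sl, sh, sb, tc, sigma) {
      list(alpha = c(baseline = baseline, trend = trend,
                     season_length = sl, summer_heat = sh,
                     sbw = sb, ftc = tc),
           sigma = sigma)
    }
    group_params <- list(
      spruce_PBS = a(2.5,  0.000, 0.15, -0.15, -0.35,  0.00, 0.30),
      spruce_M   = a(3.0, -0.020, 0.25, -0.10, -0.60,  0.80, 0.30),
      spruce_PTA = a(2.2,  0.020, 0.20, -0.15, -0.50,  0.60, 0.30),
      aspen_PTA  = a(9.3, -0.030, 0.05, -0.30,  0.00, -4.50, 0.90),
      aspen_M    = a(8.8,  0.030, 0.05, -0.30,  0.00, -4.00, 0.90)
    )
  }
  stopifnot(abs(ar1_coef) < 1, tree_sd >= 0, all(n_trees >= 2),
            all(1950:2005 %in% years))
  for (g in names(group_params)) {
    p <- group_params[[g]]
    if (p$sigma < 0) stop("sigma must be >= 0 for group ", g)
    if (length(p$alpha) != 6L) stop("alpha must have six entries for ", g)
  }
  structure(list(group_params = group_params, ar1_coef = ar1_coef,
                 tree_sd = tree_sd, n_trees = n_trees,
                 years = years, seed = seed),
            class = "synthetic_truth")
}

#' Monthly climate generator parameters
#'
#' Climatology for a boreal clay-belt site in western Quebec: July normal
#' 16.9 C, January -18.2 C, annual mean about 0.7 C, annual precipitation
#' about 890 mm of which roughly half falls May--September. Months are
#' independent Gaussians around the climatology (temperature) and gamma
#' deviates (precipitation); an optional linear warming trend exists with
#' default slope 0.
#'
#' @param tavg_clim monthly mean temperature climatology (12 values, C).
#' @param tavg_sd interannual sd per month (C), all > 0.
#' @param prcp_mean monthly mean total precipitation (mm), all >= 0.
#' @param prcp_cv coefficient of variation of monthly precipitation.
#' @param diurnal_spread half-distance from tavg to tmin/tmax (C).
#' @param warming_slope linear trend in tavg (C per year), default 0.
#' @return object of class `climate_gen_params`.
#' @export
climate_gen_params <- function(tavg_clim = c(-18.2, -16.0, -9.0, 0.5, 8.5,
                                             14.0, 16.9, 15.5, 10.0, 3.5,
                                             -4.0, -14.5),
                               tavg_sd = c(3.5, 3.2, 2.6, 1.9, 1.7, 1.4,
                                           1.3, 1.3, 1.4, 1.6, 2.4, 3.2),
                               prcp_mean = c(57, 43, 50, 56, 77, 90, 100,
                                             101, 106, 81, 69, 60),
                               prcp_cv = 0.4,
                               diurnal_spread = 5,
                               warming_slope = 0) {
  if (length(tavg_clim) != 12L || length(tavg_sd) != 12L ||
      length(prcp_mean) != 12L)
    stop("climatology vectors must have 12 monthly values")
  if (any(tavg_sd < 0)) stop("monthly temperature sd must be >= 0")
  if (any(prcp_mean < 0)) stop("monthly precipitation must be >= 0")
  if (prcp_cv < 0) stop("prcp_cv must be >= 0")
  structure(list(tavg_clim = tavg_clim, tavg_sd = tavg_sd,
                 prcp_mean = prcp_mean, prcp_cv = prcp_cv,
                 diurnal_spread = diurnal_spread,
                 warming_slope = warming_slope),
            class = "climate_gen_params")
}

#' Generate a synthetic monthly climate table
#'
#' One row per (year, month) with tmin <= tavg <= tmax and nonnegative
#' precipitation; fully reproducible under a fixed seed.
#'
#' @param params a [climate_gen_params()] object.
#' @param years integer vector of calendar years (nonempty).
#' @param seed RNG seed.
#' @return data.frame with columns year, month, tmin_c, tavg_c, tmax_c,
#'   prcp_mm.
#' @export
generate_monthly_climate <- function(params = climate_gen_params(),
                                     years, seed = NULL) {
  stopifnot(inherits(params, "climate_gen_params"))
  if (length(years) == 0L) stop("years must be nonempty")
  years <- sort(unique(as.integer(years)))
  n <- length(years)
  with_seed(seed, {
    tab <- expand.grid(month = 1:12, year = years,
                       KEEP.OUT.ATTRS = FALSE)[, c("year", "month")]
    m <- tab$month
    trend <- params$warming_slope * (tab$year - min(years))
    tavg <- params$tavg_clim[m] + trend +
      stats::rnorm(nrow(tab), 0, params$tavg_sd[m])
    # asymmetric, strictly positive offsets keep the min/avg/max ordering
    spread_hi <- params$diurnal_spread + abs(stats::rnorm(nrow(tab), 0, 1))
    spread_lo <- params$diurnal_spread + abs(stats::rnorm(nrow(tab), 0, 1))
    if (params$prcp_cv > 0) {
      shape <- 1 / params$prcp_cv^2
      prcp <- stats::rgamma(nrow(tab), shape = shape,
                            scale = pmax(params$prcp_mean[m], 1e-12) / shape)
      prcp[params$prcp_mean[m] == 0] <- 0
    } else {
      prcp <- params$prcp_mean[m]
    }
    data.frame(year = tab$year, month = m,
               tmin_c = tavg - spread_lo, tavg_c = tavg,
               tmax_c = tavg + spread_hi, prcp_mm = prcp)
  })
}

#' Simulate a group-level mean BAI series from the generating model
#'
#' Deterministic linear predictor
#' `baseline + Trend*a_tr + SeasonLength*a_sl + SummerHeat*a_sh +
#' Budworm*a_sb + Caterpillar*a_tc` plus an AR(1) noise path with marginal
#' sd `sigma` and lag-1 coefficient `ar1_coef`. With `sigma = 0` the series
#' equals the predictor exactly.
#'
#' @param truth a [synthetic_truth()] object.
#' @param covariates covariate table (see [build_covariate_table()]) whose
#'   years cover `truth$years` (or any span you pass via `years`).
#' @param group one of [chronology_groups()] (or a name in
#'   `truth$group_params`).
#' @param seed RNG seed.
#' @return data.frame(year, bai_cm2).
#' @export
simulate_group_bai <- function(truth, covariates, group, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!group %in% names(truth$group_params))
    stop("unknown group label: ", group)
  yrs <- truth$years
  miss <- setdiff(yrs, covariates$year)
  if (length(miss))
    stop("covariates do not cover the year span (missing ",
         length(miss), " years)")
  cv <- covariates[match(yrs, covariates$year), ]
  p <- truth$group_params[[group]]
  al <- p$alpha
  mu <- al["baseline"] + cv$trend * al["trend"] +
    cv$season_length * al["season_length"] +
    cv$summer_heat * al["summer_heat"] +
    cv$sbw * al["sbw"] + cv$ftc * al["ftc"]
  eps <- with_seed(seed, ar1_path(length(yrs), truth$ar1_coef, p$sigma))
  data.frame(year = yrs, bai_cm2 = as.numeric(mu + eps))
}

# stationary AR(1) path with *marginal* sd sigma
ar1_path <- function(n, phi, sigma) {
  if (sigma == 0 || n == 0L) return(numeric(n))
  innov_sd <- sigma * sqrt(1 - phi^2)
  e <- numeric(n)
  e[1] <- stats::rnorm(1, 0, sigma)
  if (n > 1) {
    z <- stats::rnorm(n - 1, 0, innov_sd)
    for (t in 2:n) e[t] <- phi * e[t - 1] + z[t - 1]
  }
  e
}

#' Disaggregate a group BAI series into per-tree ring-width series
#'
#' Each tree receives a mean-one lognormal growth factor (sd `tree_sd`), a
#' pith offset drawn uniform on 0--10 mm, and a staggered establishment year
#' within the first 12 years of the span. Ring widths are obtained by
#' inverting cumulative-area growth: the tree's basal area accumulates its
#' scaled share of the group BAI and `width_t = sqrt(A_t/pi) -
#' sqrt(A_(t-1)/pi)`. Roughly half the trees keep their pith; the rest carry
#' arc (chord/height) geometry of the innermost ring consistent with the
#' true offset, so distance-to-pith estimation can be validated against
#' known truth.
#'
#' @param truth a [synthetic_truth()] object.
#' @param group_bai data.frame(year, bai_cm2), strictly positive.
#' @param group group label (used for ids/species/stand metadata).
#' @param seed RNG seed.
#' @return list with `series` (list of [ring_width_series()]) and `truth`
#'   (data.frame of per-tree generating values: factor, pith offset, start
#'   year).
#' @export
simulate_tree_ring_widths <- function(truth, group_bai, group, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!group %in% names(truth$group_params))
    stop("unknown group label: ", group)
  if (any(group_bai$bai_cm2 <= 0))
    stop("group BAI must be strictly positive to invert to ring widths")
  n_trees <- truth$n_trees[[group]]
  yrs <- group_bai$year
  prefix <- c(spruce_PBS = "SBP", spruce_M = "SBM", spruce_PTA = "SBA",
              aspen_PTA = "TAP", aspen_M = "TAM")[[group]]
  with_seed(seed, {
    per_tree <- data.frame(
      tree_id = sprintf("%s%03d", prefix, seq_len(n_trees)),
      factor = exp(stats::rnorm(n_trees, -truth$tree_sd^2 / 2,
                                truth$tree_sd)),
      pith_offset_mm = stats::runif(n_trees, 0, 10),
      start_year = yrs[1] + sample.int(min(12L, length(yrs)), n_trees,
                                       replace = TRUE) - 1L,
      has_pith = stats::runif(n_trees) < 0.5
    )
    per_tree$pith_offset_mm[per_tree$has_pith] <- 0
    series <- vector("list", n_trees)
    for (i in seq_len(n_trees)) {
      sel <- yrs >= per_tree$start_year[i]
      bai_i <- per_tree$factor[i] * group_bai$bai_cm2[sel]
      r0_cm <- per_tree$pith_offset_mm[i] / 10
      area <- pi * r0_cm^2 + cumsum(bai_i)            # cm2
      radii <- sqrt(area / pi)                        # cm
      widths <- diff(c(r0_cm, radii)) * 10            # mm
      geom <- list(chord = NA_real_, height = NA_real_)
      if (!per_tree$has_pith[i] && per_tree$pith_offset_mm[i] > 0.05) {
        r <- per_tree$pith_offset_mm[i]
        h <- max(0.05, min(stats::runif(1, 0.5, 2), 1.6 * r))
        geom <- list(chord = sqrt(8 * h * r - 4 * h^2), height = h)
      }
      series[[i]] <- ring_width_series(
        tree_id = per_tree$tree_id[i],
        species = group_species(group),
        stand_type = group_stand(group),
        first_year = per_tree$start_year[i],
        widths = widths,
        has_pith = per_tree$has_pith[i],
        arc_chord_mm = geom$chord,
        arc_height_mm = geom$height
      )
    }
    list(series = series, truth = per_tree)
  })
}

#' Generate the complete synthetic study inputs
#'
#' Runs climate generation, covariate construction, group-level BAI
#' simulation, and per-tree disaggregation for all five chronology groups;
#' the one-stop entry point for the downstream pipeline and for tests.
#'
#' @param truth a [synthetic_truth()] object.
#' @param climate_params a [climate_gen_params()] object.
#' @param calendar an [epidemic_calendar()] object.
#' @param span analysis span used as the anomaly reference period.
#' @return list with `climate`, `covariates`, `group_bai` (named list of
#'   data.frames), `series` (named list, per group, of ring-width series
#'   lists), `tree_truth` (per-tree generating values), and `truth`.
#' @export
generate_study <- function(truth = synthetic_truth(),
                           climate_params = climate_gen_params(),
                           calendar = epidemic_calendar(),
                           span = 1950:2005) {
  seed <- truth$seed
  climate <- generate_monthly_climate(climate_params, truth$years,
                                      seed = child_seed(seed, "climate"))
  covariates <- build_covariate_table(climate, years = truth$years,
                                      calendar = calendar, ref_span = span)
  group_bai <- list(); series <- list(); tree_truth <- list()
  for (g in names(truth$group_params)) {
    gb <- simulate_group_bai(truth, covariates, g,
                             seed = child_seed(seed, paste0("bai_", g)))
    tr <- simulate_tree_ring_widths(truth, gb, g,
                                    seed = child_seed(seed, paste0("tree_", g)))
    group_bai[[g]] <- gb
    series[[g]] <- tr$series
    tr$truth$group <- g
    tree_truth[[g]] <- tr$truth
  }
  list(climate = climate, covariates = covariates, group_bai = group_bai,
       series = series, tree_truth = do.call(rbind, tree_truth),
       truth = truth)
}

#' Write the generating-truth sidecar JSON
#'
#' Records every generating parameter and seed next to the emitted data
#' files so downstream estimates can be validated against known truth.
#'
#' @param truth a [synthetic_truth()] object.
#' @param tree_truth per-tree truth data.frame from [generate_study()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, tree_truth, path) {
  obj <- list(
    group_params = lapply(truth$group_params, function(p)
      list(alpha = as.list(p$alpha), sigma = p$sigma)),
    ar1_coef = truth$ar1_coef, tree_sd = truth$tree_sd,
    n_trees = as.list(truth$n_trees),
    years = range(truth$years), seed = truth$seed,
    trees = tree_truth
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
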