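#' Slope/aspect correction factor for potential evapotranspiration
#'
#' Terrain exposure modifies radiation load and hence potential
#' evapotranspiration (PET). The correction multiplies monthly PET by a
#' factor `kPMod` derived from slope and aspect: a slope score
#' `s = min(slope/45 * 2, 2)` is signed by exposure (south-facing positive,
#' north-facing negative) to give `kSlAsp` in `[-2, 2]`, and
#' `kPMod = 1 + 0.125 * kSlAsp` on south-facing terrain or
#' `1 + 0.063 * kSlAsp` otherwise. Flat terrain gives exactly 1.
#'
#' @param slope Slope in degrees, `>= 0`.
#' @param aspect Aspect in degrees clockwise from north, in `[0, 360)`.
#' @param method `"cosine"` (default) interpolates the exposure sign
#'   continuously as `-cos(aspect)` so that due north gives -1 and due south
#'   +1; `"binary"` classifies aspects in (90, 270) as south-facing (+1) and
#'   all others as north-facing (-1).
#' @return Numeric vector of `kPMod` values, bounded in `[0.874, 1.25]`.
#' @examples
#' slope_aspect_factor(0, 123)    # 1
#' slope_aspect_factor(45, 180)   # 1.25
#' slope_aspect_factor(45, 0)     # 0.874
#' @export
slope_aspect_factor <- function(slope, aspect, method = c("cosine", "binary")) {
  method <- match.arg(method)
  if (any(!is.finite(slope)) || any(slope < 0)) {
    stop("`slope` must be finite and >= 0")
  }
  if (any(!is.finite(aspect)) || any(aspect < 0) || any(aspect >= 360)) {
    stop("`aspect` must be in [0, 360)")
  }
  s <- pmin(slope / 45 * 2, 2)
  sign_asp <- switch(method,
    cosine = -cos(aspect * pi / 180),
    binary = ifelse(aspect > 90 & aspect < 270, 1, -1)
  )
  k_sl_asp <- s * sign_asp
  ifelse(k_sl_asp > 0, 1 + k_sl_asp * 0.125, 1 + k_sl_asp * 0.063)
}

# Mid-month day-of-year and month lengths for the daylength correction.
.month_days <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
.month_mid_doy <- cumsum(c(0L, .month_days[-12])) + .month_days %/% 2L

# Mean daylength [h] of each month at a given latitude (standard solar
# declination formula, clamped at the poles).
.monthly_daylength <- function(latitude) {
  phi <- latitude * pi / 180
  decl <- 0.409 * sin(2 * pi * .month_mid_doy / 365 - 1.39)
  x <- pmin(pmax(-tan(phi) * tan(decl), -1), 1)
  24 / pi * acos(x)
}

#' Monthly Thornthwaite potential evapotranspiration
#'
#' Classic Thornthwaite (1948) monthly PET with daylength/day-count
#' correction, multiplied by the slope/aspect factor `kpmod`. The annual heat
#' index is `I = sum((T_i/5)^1.514)` over months with mean temperature above
#' 0 degrees C, the exponent is the standard cubic in `I`, and
#' `PET = 16 (L/12)(N/30) (10 T / I)^a` mm/month for `0 < T < 26.5`; the
#' high-temperature branch `-415.85 + 32.24 T - 0.43 T^2` (Willmott) applies
#' above 26.5 degrees C. Months at or below 0 degrees C evaporate nothing.
#'
#' @param monthly_tmean Numeric vector of 12 monthly mean temperatures
#'   (degrees C), January to December.
#' @param latitude Latitude in degrees, in `[-90, 90]`.
#' @param kpmod Slope/aspect PET multiplier (see [slope_aspect_factor()]).
#' @return Numeric vector of 12 corrected monthly PET values (mm).
#' @export
monthly_pet <- function(monthly_tmean, latitude, kpmod = 1) {
  if (length(monthly_tmean) != 12L) {
    stop("`monthly_tmean` must have exactly 12 monthly values")
  }
  if (!is.finite(latitude) || latitude < -90 || latitude > 90) {
    stop("`latitude` must be in [-90, 90]")
  }
  tm <- monthly_tmean
  heat <- sum(pmax(tm, 0)^1.514 / 5^1.514)
  pet <- numeric(12L)
  if (heat > 0) {
    a <- 6.75e-7 * heat^3 - 7.71e-5 * heat^2 + 1.792e-2 * heat + 0.49239
    corr <- (.monthly_daylength(latitude) / 12) * (.month_days / 30)
    warm <- tm > 0 & tm < 26.5
    hot <- tm >= 26.5
    pet[warm] <- 16 * (10 * tm[warm] / heat)^a * corr[warm]
    pet[hot] <- (-415.85 + 32.24 * tm[hot] - 0.43 * tm[hot]^2) * corr[hot]
  }
  pet * kpmod
}

#' Soil water bucket size
#'
#' Maximum plant-available soil water store
#' `BS = SDR * AWC * (1 - CFV)` where `SDR` is soil depth to bedrock
#' (capped at 2 m and converted to cm), `AWC` the plant-available water
#' capacity (dimensionless fraction) and `CFV` the volumetric
#' coarse-fragment fraction.
#'
#' @param sdr_m Soil depth to bedrock in metres, `>= 0`.
#' @param awc Available water capacity, fraction in `[0, 1]`.
#' @param cfv Coarse-fragment volumetric fraction in `[0, 1]`.
#' @return Bucket size in cm.
#' @examples
#' bucket_size(2, 0.20, 0)  # 40 cm
#' @export
bucket_size <- function(sdr_m, awc, cfv) {
  if (any(sdr_m < 0)) stop("`sdr_m` must be >= 0")
  if (any(awc < 0 | awc > 1)) stop("`awc` must be in [0, 1]")
  if (any(cfv < 0 | cfv > 1)) stop("`cfv` must be in [0, 1]")
  pmin(sdr_m, 2) * 100 * awc * (1 - cfv)
}

# Split a daily climate data.frame into year/month vectors; validates basic
# ClimateSeries invariants.
.climate_parts <- function(climate) {
  stopifnot(all(c("date", "tmean_c", "precip_mm") %in% names(climate)))
  dates <- as.Date(climate$date)
  if (anyNA(dates)) stop("unparseable dates in climate series")
  if (is.unsorted(dates, strictly = TRUE)) {
    stop("climate series dates must be strictly increasing")
  }
  if (any(climate$precip_mm < 0)) stop("negative precipitation in climate series")
  list(
    date = dates,
    year = as.integer(format(dates, "%Y")),
    month = as.integer(format(dates, "%m")),
    tmean = climate$tmean_c,
    precip = climate$precip_mm
  )
}

# Days expected in a month (no leap handling for February needed in-season:
# the April-October window is leap-independent).
.days_in_month <- function(year, month) {
  ifelse(month == 2L & (year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0)),
    29L, .month_days[month]
  )
}

#' Mean seasonal degree-day sum
#'
#' For each requested year, sums the daily mean-temperature excess above
#' 5.5 degrees C over April 1 to October 31, then averages across years.
#' Every day of each seasonal window must be present; missing days raise an
#' error (no imputation).
#'
#' @param climate Data frame with columns `date`, `tmean_c`, `precip_mm`.
#' @param years Integer vector of calendar years to average over; default is
#'   all years with a complete April-October window in the series.
#' @param base Base temperature, degrees C (default 5.5).
#' @return Mean seasonal degree-day sum (degree C days).
#' @export
degree_day_sum <- function(climate, years = NULL, base = 5.5) {
  cp <- .climate_parts(climate)
  in_season <- cp$month >= 4L & cp$month <= 10L
  if (is.null(years)) {
    cnt <- table(cp$year[in_season])
    years <- as.integer(names(cnt)[cnt == 214L])
    if (length(years) == 0L) stop("no complete April-October season in series")
  }
  per_year <- vapply(years, function(y) {
    sel <- in_season & cp$year == y
    if (sum(sel) != 214L) {
      stop(sprintf("incomplete April-October coverage in year %d (%d/214 days)",
                   y, sum(sel)))
    }
    sum(pmax(cp$tmean[sel] - base, 0))
  }, numeric(1))
  mean(per_year)
}

#' Mean seasonal water balance
#'
#' For each requested year, computes monthly precipitation sums and monthly
#' mean temperatures from daily data, derives slope/aspect-corrected monthly
#' Thornthwaite PET (the heat index is computed per calendar year from the
#' months present in that year), and sums April-October
#' `precip - PET'`. The mean over years is returned.
#'
#' @param climate Data frame with columns `date`, `tmean_c`, `precip_mm`.
#' @param kpmod Slope/aspect PET multiplier for this plot.
#' @param latitude Plot latitude in degrees (default 47, central Europe).
#' @param years Years to average over; default all years with complete
#'   April-October daily coverage.
#' @return Mean seasonal water balance (mm).
#' @export
seasonal_water_balance <- function(climate, kpmod = 1, latitude = 47,
                                   years = NULL) {
  cp <- .climate_parts(climate)
  in_season <- cp$month >= 4L & cp$month <= 10L
  if (is.null(years)) {
    cnt <- table(cp$year[in_season])
    years <- as.integer(names(cnt)[cnt == 214L])
    if (length(years) == 0L) stop("no complete April-October season in series")
  }
  per_year <- vapply(years, function(y) {
    sel_y <- cp$year == y
    if (!any(sel_y)) stop(sprintf("year %d absent from climate series", y))
    # complete-month check within the season
    for (m in 4:10) {
      n_m <- sum(sel_y & cp$month == m)
      if (n_m != .days_in_month(y, m)) {
        stop(sprintf("incomplete month %d-%02d in climate series (%d days)",
                     y, m, n_m))
      }
    }
    tmon <- rep(NA_real_, 12L)
    pmon <- rep(0, 12L)
    for (m in 1:12) {
      sel <- sel_y & cp$month == m
      if (any(sel)) {
        tmon[m] <- mean(cp$tmean[sel])
        pmon[m] <- sum(cp$precip[sel])
      }
    }
    # months absent from the series contribute nothing to heat index or PET
    tmon[is.na(tmon)] <- 0
    pet <- monthly_pet(tmon, latitude, kpmod)
    sum(pmon[4:10] - pet[4:10])
  }, numeric(1))
  mean(per_year)
}

#' Derive per-plot site environment from climate and terrain tables
#'
#' Pipeline wrapper: computes the slope/aspect factor, mean seasonal
#' degree-day sum, mean seasonal water balance and bucket size for every
#' plot in a terrain table, given a daily climate table covering the plots.
#'
#' @param climate Data frame `plot_id, date, tmean_c, precip_mm` (daily).
#' @param terrain Data frame `plot_id, slope_deg, aspect_deg, sdr_m,
#'   awc_frac, cfv_frac` and optionally `latitude`.
#' @param years Years to average over (default: all complete seasons).
#' @param aspect_method Passed to [slope_aspect_factor()].
#' @return Data frame `plot_id, dds, wb, bs, kpmod` (one row per plot).
#' @export
site_environment <- function(climate, terrain, years = NULL,
                             aspect_method = "cosine") {
  need <- c("plot_id", "slope_deg", "aspect_deg", "sdr_m", "awc_frac", "cfv_frac")
  stopifnot(all(need %in% names(terrain)))
  lat <- if ("latitude" %in% names(terrain)) terrain$latitude else rep(47, nrow(terrain))
  kpmod <- slope_aspect_factor(terrain$slope_deg, terrain$aspect_deg,
                               method = aspect_method)
  out <- data.frame(
    plot_id = terrain$plot_id,
    dds = NA_real_, wb = NA_real_,
    bs = bucket_size(terrain$sdr_m, terrain$awc_frac, terrain$cfv_frac),
    kpmod = kpmod,
    stringsAsFactors = FALSE
  )
  for (r in seq_len(nrow(terrain))) {
    cl <- climate[climate$plot_id == terrain$plot_id[r], , drop = FALSE]
    if (nrow(cl) == 0L) {
      stop(sprintf("no climate series for plot '%s'", terrain$plot_id[r]))
    }
    out$dds[r] <- degree_day_sum(cl, years)
    out$wb[r] <- seasonal_water_balance(cl, kpmod = kpmod[r],
                                        latitude = lat[r], years = years)
  }
  out
}
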