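#' Monthly climate record for one grid cell
#'
#' @param tmin,tmean,tmax Monthly temperature 12-vectors (deg C), with
#'   `tmin <= tmean <= tmax` in every month.
#' @param precip Monthly precipitation 12-vector (mm, non-negative).
#' @param awc Available soil water capacity (mm, non-negative).
#' @param latitude Latitude in degrees, within \[-90, 90\].
#' @return Object of class `cell_climate`.
#' @export
cell_climate <- function(tmin, tmean, tmax, precip, awc, latitude) {
  stopifnot(length(tmin) == 12, length(tmean) == 12, length(tmax) == 12,
            length(precip) == 12)
  if (any(tmin > tmean + 1e-9) || any(tmean > tmax + 1e-9))
    stop("monthly temperatures must satisfy tmin <= tmean <= tmax",
         call. = FALSE)
  if (any(precip < 0)) stop("precipitation must be non-negative",
                            call. = FALSE)
  if (awc < 0) stop("available soil water capacity must be non-negative",
                    call. = FALSE)
  if (latitude < -90 || latitude > 90)
    stop("latitude must lie in [-90, 90]", call. = FALSE)
  structure(list(tmin = as.numeric(tmin), tmean = as.numeric(tmean),
                 tmax = as.numeric(tmax), precip = as.numeric(precip),
                 awc = as.numeric(awc), latitude = as.numeric(latitude)),
            class = "cell_climate")
}

MONTH_DAYS <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
MONTH_MID_DOY <- cumsum(MONTH_DAYS) - MONTH_DAYS / 2

# Mean day length (hours) at mid-month, from solar declination.
day_length_hours <- function(latitude, doy = MONTH_MID_DOY) {
  phi <- latitude * pi / 180
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- -tan(phi) * tan(decl)
  x <- pmin(pmax(x, -1), 1)  # polar day / night
  ws <- acos(x)
  24 * ws / pi
}

#' Monthly potential evapotranspiration (Thornthwaite)
#'
#' Temperature-only PET with a day-length correction: for months with mean
#' temperature above 0 deg C,
#' \eqn{PET_m = 16 (10 T_m / I)^a (L_m/12)(N_m/30)} where \eqn{I} is the
#' annual heat index \eqn{\sum (T_m/5)^{1.514}} over warm months, \eqn{a}
#' a cubic function of \eqn{I}, \eqn{L_m} mean day length and \eqn{N_m}
#' days in the month. PET is 0 in months with mean temperature at or below
#' freezing. For mean temperatures above 26 deg C the standard
#' high-temperature polynomial replaces the power law.
#'
#' @param climate A [cell_climate()].
#' @param heat_index Optional fixed heat index `I` (mainly for testing the
#'   monotone temperature response in isolation).
#' @return Numeric 12-vector of monthly PET (mm).
#' @export
potential_et <- function(climate, heat_index = NULL) {
  stopifnot(inherits(climate, "cell_climate"))
  Tm <- climate$tmean
  warm <- Tm > 0
  I <- if (is.null(heat_index)) sum((Tm[warm] / 5)^1.514) else heat_index
  pet <- numeric(12)
  if (I <= 0) return(pet)
  a <- 6.75e-7 * I^3 - 7.71e-5 * I^2 + 1.792e-2 * I + 0.49239
  L <- day_length_hours(climate$latitude)
  corr <- (L / 12) * (MONTH_DAYS / 30)
  hot <- warm & Tm > 26
  mid <- warm & !hot
  pet[mid] <- 16 * (10 * Tm[mid] / I)^a * corr[mid]
  pet[hot] <- (-415.85 + 32.24 * Tm[hot] - 0.43 * Tm[hot]^2) * corr[hot]
  pet
}

#' Single-bucket soil water balance
#'
#' Iterates the annual cycle of a one-bucket soil water model to a periodic
#' steady state. Each month, actual evapotranspiration is
#' `AET_m = min(PET_m, precip_m + storage)`; storage is then updated with
#' the month's water balance and clamped to `[0, awc]`, with water above
#' capacity leaving as surplus. The cycle is repeated until the storage
#' entering January changes by less than `tol` between consecutive years.
#'
#' @param climate A [cell_climate()].
#' @param monthly_pet Monthly PET 12-vector (mm), e.g. from
#'   [potential_et()].
#' @param tol Convergence tolerance on the January storage (mm).
#' @param max_cycles Upper bound on annual iterations.
#' @return List with 12-vectors `aet`, `soil_water` (end-of-month storage),
#'   `surplus`, and scalars `n_cycles`, `converged`.
#' @export
bucket_aet <- function(climate, monthly_pet, tol = 1e-6, max_cycles = 1000) {
  stopifnot(inherits(climate, "cell_climate"), length(monthly_pet) == 12)
  if (any(monthly_pet < 0)) stop("PET must be non-negative", call. = FALSE)
  awc <- climate$awc; prec <- climate$precip
  storage <- awc
  aet <- soil <- surplus <- numeric(12)
  converged <- FALSE; cyc <- 0
  while (cyc < max_cycles) {
    cyc <- cyc + 1
    start <- storage
    for (m in 1:12) {
      aet[m] <- min(monthly_pet[m], prec[m] + storage)
      storage <- storage + prec[m] - aet[m]
      surplus[m] <- max(storage - awc, 0)
      storage <- min(storage, awc)
      soil[m] <- storage
    }
    if (abs(storage - start) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("soil-water balance failed to reach a periodic steady state",
         call. = FALSE)
  list(aet = aet, soil_water = soil, surplus = surplus,
       n_cycles = cyc, converged = converged)
}

#' Degree-days from monthly mean temperatures
#'
#' Growing degree-days sum `max(T - base, 0)` and freezing degree-days sum
#' `max(base - T, 0)`, each weighted by the number of days in the month.
#'
#' @param tmean Monthly mean temperature 12-vector (deg C).
#' @param base Base temperature (deg C): 5 for growing, 0 for freezing
#'   degree-days.
#' @param direction `"above"` (growing) or `"below"` (freezing).
#' @return Scalar degree-days.
#' @export
degree_days <- function(tmean, base = 5, direction = c("above", "below")) {
  direction <- match.arg(direction)
  stopifnot(length(tmean) == 12, all(is.finite(tmean)))
  dev <- if (direction == "above") pmax(tmean - base, 0) else
    pmax(base - tmean, 0)
  sum(dev * MONTH_DAYS)
}

#' Growing-season water-balance summary
#'
#' Sums monthly PET and AET over the growing season (calendar May-August)
#' and returns the growing-season climatic water deficit
#' `CWD_GS = PET_GS - AET_GS`.
#'
#' @param monthly_pet,monthly_aet Monthly 12-vectors (mm).
#' @param months Growing-season months (default May-August).
#' @return List with `pet_gs`, `aet_gs`, `cwd_gs` (mm).
#' @export
growing_season_summary <- function(monthly_pet, monthly_aet, months = 5:8) {
  stopifnot(length(monthly_pet) == 12, length(monthly_aet) == 12)
  pet_gs <- sum(monthly_pet[months])
  aet_gs <- sum(monthly_aet[months])
  list(pet_gs = pet_gs, aet_gs = aet_gs, cwd_gs = pet_gs - aet_gs)
}

#' Full water-balance derivation for one cell
#'
#' Chains [potential_et()], [bucket_aet()], [growing_season_summary()] and
#' [degree_days()] into the climate covariates used by the occurrence
#' model: growing-season PET, AET and climatic water deficit, plus growing
#' (>5 deg C) and freezing (<0 deg C) degree-days.
#'
#' @param climate A [cell_climate()].
#' @param pet_fun PET function taking a `cell_climate` and returning a
#'   monthly 12-vector; pluggable so alternative formulations can be
#'   swapped in.
#' @return Object of class `water_balance_result`: `pet_gs`, `aet_gs`,
#'   `cwd_gs`, `gdd`, `fdd`, `monthly_pet`, `monthly_aet`,
#'   `monthly_soil_water`.
#' @export
water_balance <- function(climate, pet_fun = potential_et) {
  pet <- pet_fun(climate)
  bal <- bucket_aet(climate, pet)
  gs <- growing_season_summary(pet, bal$aet)
  structure(list(pet_gs = gs$pet_gs, aet_gs = gs$aet_gs,
                 cwd_gs = gs$cwd_gs,
                 gdd = degree_days(climate$tmean, 5, "above"),
                 fdd = degree_days(climate$tmean, 0, "below"),
                 monthly_pet = pet, monthly_aet = bal$aet,
                 monthly_soil_water = bal$soil_water,
                 monthly_surplus = bal$surplus),
            class = "water_balance_result")
}

#' @export
print.water_balance_result <- function(x, ...) {
  cat(sprintf(
    "water balance: PET_GS = %.1f mm, AET_GS = %.1f mm, CWD_GS = %.1f mm\n",
    x$pet_gs, x$aet_gs, x$cwd_gs))
  cat(sprintf("  GDD(>5C) = %.0f, FDD(<0C) = %.0f degree-days\n",
              x$gdd, x$fdd))
  invisible(x)
}

#' Tabular water-balance mode
#'
#' Applies [water_balance()] to every row of a wide climate table (the
#' format written by [generate_climate_series()]: `tmin_1..12`,
#' `tmean_1..12`, `tmax_1..12`, `prec_1..12`, `awc`, `latitude`).
#'
#' @param climate_table Data frame or path to a CSV file.
#' @param out_file Optional path for the result CSV.
#' @return Data frame with columns `pet_gs`, `aet_gs`, `cwd_gs`, `gdd`,
#'   `fdd` (plus `cell_id` when present in the input).
#' @export
water_balance_table <- function(climate_table, out_file = NULL) {
  if (is.character(climate_table))
    climate_table <- read.csv(climate_table, check.names = FALSE)
  m <- 1:12
  res <- lapply(seq_len(nrow(climate_table)), function(i) {
    row <- climate_table[i, ]
    cl <- cell_climate(as.numeric(row[paste0("tmin_", m)]),
                       as.numeric(row[paste0("tmean_", m)]),
                       as.numeric(row[paste0("tmax_", m)]),
                       as.numeric(row[paste0("prec_", m)]),
                       as.numeric(row[["awc"]]),
                       as.numeric(row[["latitude"]]))
    wb <- water_balance(cl)
    data.frame(pet_gs = wb$pet_gs, aet_gs = wb$aet_gs, cwd_gs = wb$cwd_gs,
               gdd = wb$gdd, fdd = wb$fdd)
  })
  out <- do.call(rbind, res)
  if ("cell_id" %in% names(climate_table))
    out <- cbind(cell_id = climate_table$cell_id, out)
  if (!is.null(out_file)) write.csv(out, out_file, row.names = FALSE)
  out
}
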