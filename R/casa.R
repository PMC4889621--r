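#' Convert land-surface-temperature digital numbers to degrees Celsius
#'
#' Satellite land-surface-temperature products store Kelvin scaled by 50;
#' the physical value is `dn * 0.02 - 273.15` degrees C.
#'
#' @param dn Raw digital numbers (non-negative).
#' @return Temperatures in degrees C.
#' @export
lst_dn_to_celsius <- function(dn) {
  if (any(dn < 0, na.rm = TRUE)) stop("digital numbers must be non-negative")
  dn * 0.02 - 273.15
}

#' Days in a calendar month (Gregorian, leap-aware)
#'
#' @param year,month Calendar month.
#' @return Integer day count.
#' @export
days_in_month <- function(year, month) {
  if (any(!(month %in% 1:12))) stop("month must be in 1..12")
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  n <- base[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | (year %% 400 == 0)
  n + ifelse(month == 2 & leap, 1L, 0L)
}

#' Convert mean daily precipitation to a monthly total
#'
#' Reanalysis precipitation is often distributed as a daily-mean rate; the
#' monthly total multiplies it by the number of days in that calendar month.
#'
#' @param daily_mean Mean precipitation rate, mm/day (non-negative).
#' @param year,month Calendar month (leap years respected).
#' @return Total precipitation, mm/month.
#' @export
daily_to_monthly_precip <- function(daily_mean, year, month) {
  if (any(daily_mean < 0, na.rm = TRUE)) stop("precipitation must be non-negative")
  daily_mean * days_in_month(year, month)
}

#' CASA temperature scalar
#'
#' The classic two-factor CASA temperature stress term. `T1` penalises
#' sites whose optimum lies far from the mid range,
#' `T1 = 0.8 + 0.02 topt - 0.0005 topt^2`; `T2` is a double-logistic
#' response of the current temperature about the optimum,
#' `T2 = 1.1814 / ((1 + exp(0.2 (topt - 10 - t))) (1 + exp(0.3 (-topt - 10 + t))))`.
#' The product is clipped to `[0, 1]`. The scalar is unimodal in `t` with
#' its maximum near `topt` and decays to 0 at extreme cold or heat.
#'
#' @param t Air/surface temperature, degrees C (vector or matrix).
#' @param topt Optimum temperature for vegetation growth, degrees C (scalar
#'   or conformable array).
#' @return Dimensionless scalar in `[0, 1]`.
#' @export
temperature_scalar <- function(t, topt) {
  t1 <- 0.8 + 0.02 * topt - 0.0005 * topt^2
  t2 <- 1.1814 /
    ((1 + exp(0.2 * (topt - 10 - t))) * (1 + exp(0.3 * (-topt - 10 + t))))
  pmin(pmax(t1 * t2, 0), 1)
}

#' Priestley-Taylor potential evapotranspiration
#'
#' `PET = alpha * Delta / (Delta + gamma) * Rn / lambda` with alpha = 1.26,
#' psychrometric constant gamma = 0.066 kPa/degC, latent heat
#' lambda = 2.45 MJ/kg (1 kg water over 1 m2 is 1 mm), and the slope of the
#' saturation vapour-pressure curve
#' `Delta(t) = 4098 * 0.6108 * exp(17.27 t / (t + 237.3)) / (t + 237.3)^2`.
#'
#' @param t Temperature, degrees C.
#' @param rn Monthly net radiation proxy, MJ m-2 month-1 (non-negative);
#'   here the surface solar irradiance input.
#' @return PET in mm/month, floored at 0.
#' @export
priestley_taylor_pet <- function(t, rn) {
  if (any(rn < 0, na.rm = TRUE)) stop("radiation must be non-negative")
  delta <- 4098 * 0.6108 * exp(17.27 * t / (t + 237.3)) / (t + 237.3)^2
  pmax(1.26 * delta / (delta + 0.066) * rn / 2.45, 0)
}

#' Soil-texture water-holding parameters
#'
#' Six texture classes ordered from organic soils (largest storage) down to
#' lithosols (smallest): `organic`, `clay_0_5`, `clay_5_15`, `clay_15_30`,
#' `clay_ge_30`, `lithosol`. Each carries field capacities (mm) for the
#' three model layers — surface organic matter, topsoil, subsoil to rooting
#' depth. The clay classes interpolate linearly between 25/100/200 mm
#' (0-5 % clay) and 15/60/120 mm (>= 30 % clay). All values are defaults
#' exposed for configuration, not measurements.
#'
#' @return Tibble with `class_code`, `code`, `cap1`, `cap2`, `cap3` (mm).
#' @export
soil_texture_defaults <- function() {
  tibble::tibble(
    class_code = c(
      "organic", "clay_0_5", "clay_5_15", "clay_15_30", "clay_ge_30",
      "lithosol"
    ),
    code = 1:6,
    cap1 = c(40, 25, 25 - 10 / 3, 25 - 20 / 3, 15, 10),
    cap2 = c(150, 100, 100 - 40 / 3, 100 - 80 / 3, 60, 40),
    cap3 = c(300, 200, 200 - 80 / 3, 200 - 160 / 3, 120, 80)
  )
}

#' Per-pixel layer capacities from a soil-texture code raster
#'
#' Expands an integer soil-texture raster into three capacity matrices
#' using a texture table, applying the rooting-depth multiplier to the
#' subsoil layer. A multiplier of 1.8 reproduces the deep-rooted woodland
#' adjustment (80 % more available subsoil water for trees and shrubs);
#' the default 1 leaves capacities unchanged.
#'
#' @param soil_raster [raster_grid()] of integer texture codes, or a single
#'   code to use everywhere (then `spec` is required).
#' @param table Texture table as from [soil_texture_defaults()].
#' @param rooting_multiplier Subsoil capacity multiplier (>= 1).
#' @param spec Grid spec, needed only when `soil_raster` is a single code.
#' @return List of matrices `cap1`, `cap2`, `cap3` (mm).
#' @export
soil_capacity_grids <- function(soil_raster, table = soil_texture_defaults(),
                                rooting_multiplier = 1, spec = NULL) {
  stopifnot(rooting_multiplier >= 1)
  if (!inherits(soil_raster, "raster_grid")) {
    if (is.null(spec)) stop("spec is required when soil_raster is a single code")
    soil_raster <- raster_fill(spec, as.numeric(soil_raster))
  }
  codes <- soil_raster$values
  seen <- unique(codes[!is.na(codes)])
  if (!all(seen %in% table$code)) {
    stop(
      "soil raster contains unknown texture codes: ",
      paste(sort(setdiff(seen, table$code)), collapse = ", ")
    )
  }
  pick <- function(cap) {
    m <- codes
    m[] <- cap[match(codes, table$code)]
    m
  }
  list(
    cap1 = pick(table$cap1),
    cap2 = pick(table$cap2),
    cap3 = pick(table$cap3) * rooting_multiplier
  )
}

#' One monthly step of the three-layer bucket water balance
#'
#' Estimated evapotranspiration is demand-limited and supply-limited,
#' `EET = min(PET, precip + stored water)`: it is satisfied first from the
#' month's precipitation, then drawn top-down from the soil store. The
#' remaining precipitation then recharges the layers top-down until field
#' capacity is reached, and the excess leaves the system as drainage —
#' so under sustained `precip >> PET` the store converges to full
#' capacity. The moisture scalar is `W = 0.5 + 0.5 EET/PET` (W = 1 when
#' PET = 0), so even fully dry soil retains W = 0.5. Water is conserved
#' exactly: `precip = change in storage + EET + drainage`.
#'
#' All arguments may be equal-shaped matrices; the step is elementwise.
#'
#' @param state List of three layer-content matrices/vectors `l1`, `l2`,
#'   `l3` (mm), each within `[0, capacity]`.
#' @param precip Precipitation, mm/month (non-negative).
#' @param pet Potential evapotranspiration, mm/month (non-negative).
#' @param caps List of capacities `cap1`, `cap2`, `cap3` (mm), as from
#'   [soil_capacity_grids()].
#' @return List with `state` (updated layers), `eet` (mm), `w_scalar`
#'   (in `[0.5, 1]`) and `drainage` (mm).
#' @export
water_balance_step <- function(state, precip, pet, caps) {
  if (any(precip < 0, na.rm = TRUE) || any(pet < 0, na.rm = TRUE)) {
    stop("precipitation and PET must be non-negative")
  }
  s1 <- state$l1; s2 <- state$l2; s3 <- state$l3
  demand <- pmin(pet, precip + s1 + s2 + s3)
  # evaporative draw: precipitation first, then the store top-down
  e_p <- pmin(demand, precip)
  r <- demand - e_p
  e1 <- pmin(s1, r)
  s1 <- s1 - e1
  r <- r - e1
  e2 <- pmin(s2, r)
  s2 <- s2 - e2
  r <- r - e2
  e3 <- pmin(s3, r)
  s3 <- s3 - e3
  eet <- e_p + e1 + e2 + e3 # = demand up to rounding; keeps budget exact
  # recharge with what precipitation remains, top-down to field capacity
  rest <- precip - e_p
  a1 <- pmin(caps$cap1 - s1, rest)
  s1 <- s1 + a1
  rest <- rest - a1
  a2 <- pmin(caps$cap2 - s2, rest)
  s2 <- s2 + a2
  rest <- rest - a2
  a3 <- pmin(caps$cap3 - s3, rest)
  s3 <- s3 + a3
  drainage <- rest - a3
  w <- ifelse(pet > 0, 0.5 + 0.5 * eet / pet, 1)
  w <- pmin(pmax(w, 0.5), 1)
  list(
    state = list(l1 = s1, l2 = s2, l3 = s3),
    eet = eet, w_scalar = w, drainage = drainage
  )
}

#' CASA model parameters
#'
#' @param e_max Maximum light-use efficiency, gC per MJ PAR; the canonical
#'   calibration is 0.55. The NPP equation multiplies total shortwave
#'   irradiance directly — the shortwave-to-PAR conversion is absorbed into
#'   this constant.
#' @param topt Optimum temperature: a scalar (degrees C, within `[0, 35]`),
#'   a [raster_grid()], or `NULL` to derive it per pixel as the long-term
#'   mean temperature of the climatologically warmest month, clipped to
#'   `[0, 35]`.
#' @param npp_nonnegative Treat negative vegetation-index values as 0 so
#'   NPP never goes negative (default `TRUE`).
#' @return A `casa_params` list.
#' @export
casa_params <- function(e_max = 0.55, topt = NULL, npp_nonnegative = TRUE) {
  stopifnot(e_max > 0)
  if (is.numeric(topt) && length(topt) == 1L) {
    stopifnot(topt >= 0, topt <= 35)
  }
  structure(
    list(e_max = e_max, topt = topt, npp_nonnegative = npp_nonnegative),
    class = "casa_params"
  )
}

#' Climate forcing bundle
#'
#' @param temperature [monthly_stack()], degrees C.
#' @param precipitation [monthly_stack()], mm/month (non-negative).
#' @param solar [monthly_stack()], MJ m-2 month-1 total surface irradiance
#'   (non-negative).
#' @return A `climate_inputs` list; the three stacks must share grid and
#'   calendar span.
#' @export
climate_inputs <- function(temperature, precipitation, solar) {
  for (s in list(precipitation, solar)) {
    if (!same_spec(s$spec, temperature$spec) ||
        !identical(s$years, temperature$years) ||
        !identical(s$months, temperature$months)) {
      stop("climate stacks must share grid and calendar span")
    }
  }
  if (any(precipitation$values < 0, na.rm = TRUE)) {
    stop("precipitation must be non-negative")
  }
  if (any(solar$values < 0, na.rm = TRUE)) stop("solar must be non-negative")
  structure(
    list(
      temperature = temperature, precipitation = precipitation, solar = solar
    ),
    class = "climate_inputs"
  )
}

#' Derive the optimum-temperature grid from climate
#'
#' Per pixel: the long-term mean temperature of the climatologically
#' warmest calendar month, clipped to `[0, 35]` degrees C (polar to hot
#' desert range).
#'
#' @param temperature [monthly_stack()] of temperature, degrees C.
#' @return Matrix of topt values.
#' @export
derive_topt <- function(temperature) {
  nr <- temperature$spec$n_rows
  nc <- temperature$spec$n_cols
  clim <- array(NA_real_, c(nr, nc, 12))
  for (m in 1:12) {
    i <- which(temperature$months == m)
    if (length(i)) {
      clim[, , m] <- apply(
        temperature$values[, , i, drop = FALSE], c(1, 2), mean
      )
    }
  }
  topt <- apply(clim, c(1, 2), max, na.rm = TRUE)
  topt[!is.finite(topt)] <- NA_real_
  pmin(pmax(topt, 0), 35)
}

#' Monthly NPP from the light-use-efficiency equation
#'
#' `NPP = Sr x IVI x e_max x T x W` — irradiance times the interpolated
#' vegetation index times maximum light-use efficiency, down-regulated by
#' the temperature and moisture scalars.
#'
#' @param sr Surface solar irradiance, MJ m-2 month-1.
#' @param ivi Interpolated vegetation index (dimensionless).
#' @param e_max Maximum light-use efficiency, gC/MJ.
#' @param t_scalar,w_scalar Stress scalars in `[0, 1]`.
#' @param npp_nonnegative Clamp negative vegetation index to 0.
#' @return NPP in gC m-2 month-1.
#' @export
casa_npp_month <- function(sr, ivi, e_max, t_scalar, w_scalar,
                           npp_nonnegative = TRUE) {
  if (npp_nonnegative) ivi <- pmax(ivi, 0)
  sr * ivi * e_max * t_scalar * w_scalar
}

# Spin-up / reporting split: the model needs 24 months of climate before
# the first reported month. If the climate starts >= 24 months before the
# vegetation span those months force the spin-up; if it starts exactly at
# the reporting span, the first reporting year is repeated twice instead
# (documented fallback).
casa_forcing_schedule <- function(climate, years, months) {
  ckey <- climate$temperature$years * 12L + (climate$temperature$months - 1L)
  rkey <- years * 12L + (months - 1L)
  if (!all(rkey %in% ckey)) {
    stop("climate does not cover the vegetation-index span")
  }
  report_idx <- match(rkey, ckey)
  pre <- which(ckey < rkey[1])
  if (length(pre) >= 24L) {
    spin_idx <- utils::tail(pre, 24L)
  } else {
    first_year <- which(ckey >= rkey[1] & ckey < rkey[1] + 12L)
    if (length(first_year) < 12L) {
      stop(
        "climate must either precede the reporting span by >= 24 months ",
        "or cover a full first reporting year to repeat as spin-up"
      )
    }
    spin_idx <- c(first_year, first_year)
  }
  list(spin = spin_idx, report = report_idx)
}

#' Initialise soil moisture by a two-year spin-up
#'
#' Starting from half-capacity layers, the water balance is stepped through
#' 24 months of forcing; the end state initialises the first reporting
#' year. The run is deterministic.
#'
#' @param climate A [climate_inputs()] spanning at least 24 months.
#' @param caps Layer capacities from [soil_capacity_grids()].
#' @param month_idx Optional indices of the 24 forcing months within the
#'   climate span (default: the first 24).
#' @return A soil-moisture state: list of matrices `l1`, `l2`, `l3` (mm).
#' @export
spin_up <- function(climate, caps, month_idx = NULL) {
  nt <- n_months(climate$temperature)
  if (is.null(month_idx)) {
    if (nt < 24L) stop("spin-up needs at least 24 months of climate")
    month_idx <- 1:24
  }
  state <- list(l1 = caps$cap1 / 2, l2 = caps$cap2 / 2, l3 = caps$cap3 / 2)
  for (i in month_idx) {
    tm <- climate$temperature$values[, , i]
    pr <- climate$precipitation$values[, , i]
    sr <- climate$solar$values[, , i]
    pet <- priestley_taylor_pet(tm, sr)
    state <- water_balance_step(state, pr, pet, caps)$state
  }
  state
}

#' Run the CASA model for one land-cover class
#'
#' Per pixel: spin up the soil-moisture store over 24 months, then for each
#' reporting month compute the temperature scalar, Priestley-Taylor PET,
#' one water-balance step (giving the moisture scalar), and the NPP
#' product. The grid run is the exact pixelwise composition of the scalar
#' operations.
#'
#' @param ivi_stack Per-class interpolated vegetation-index
#'   [monthly_stack()]; its span is the reporting span.
#' @param climate A [climate_inputs()] covering the reporting span, and
#'   ideally the 24 months before it (see Details in [spin_up()]).
#' @param caps Layer capacities from [soil_capacity_grids()].
#' @param params A [casa_params()].
#' @return List with `npp` (monthly_stack, gC m-2 month-1), `diagnostics`
#'   (monthly_stacks `t_scalar`, `w_scalar`, `pet`, `eet`, `drainage`),
#'   `topt` (matrix) and `final_state`.
#' @export
run_casa_class <- function(ivi_stack, climate, caps, params = casa_params()) {
  spec <- ivi_stack$spec
  if (!same_spec(spec, climate$temperature$spec)) {
    stop("vegetation-index and climate grids are not aligned")
  }
  sched <- casa_forcing_schedule(climate, ivi_stack$years, ivi_stack$months)
  topt <- params$topt
  if (is.null(topt)) {
    topt <- derive_topt(climate$temperature)
  } else if (inherits(topt, "raster_grid")) {
    topt <- topt$values
  }
  state <- spin_up(climate, caps, month_idx = sched$spin)
  nt <- n_months(ivi_stack)
  nr <- spec$n_rows
  nc <- spec$n_cols
  npp <- array(NA_real_, c(nr, nc, nt))
  diag_names <- c("t_scalar", "w_scalar", "pet", "eet", "drainage")
  diags <- lapply(diag_names, function(x) array(NA_real_, c(nr, nc, nt)))
  names(diags) <- diag_names
  for (t in seq_len(nt)) {
    i <- sched$report[t]
    tm <- climate$temperature$values[, , i]
    pr <- climate$precipitation$values[, , i]
    sr <- climate$solar$values[, , i]
    ts <- temperature_scalar(tm, topt)
    pet <- priestley_taylor_pet(tm, sr)
    wb <- water_balance_step(state, pr, pet, caps)
    state <- wb$state
    npp[, , t] <- casa_npp_month(
      sr, ivi_stack$values[, , t], params$e_max, ts, wb$w_scalar,
      npp_nonnegative = params$npp_nonnegative
    )
    diags$t_scalar[, , t] <- ts
    diags$w_scalar[, , t] <- wb$w_scalar
    diags$pet[, , t] <- pet
    diags$eet[, , t] <- wb$eet
    diags$drainage[, , t] <- wb$drainage
  }
  mk <- function(a, u) monthly_stack(a, spec, ivi_stack$years,
                                     ivi_stack$months, units = u)
  list(
    npp = mk(npp, "gC m-2 month-1"),
    diagnostics = list(
      t_scalar = mk(diags$t_scalar, ""),
      w_scalar = mk(diags$w_scalar, ""),
      pet = mk(diags$pet, "mm month-1"),
      eet = mk(diags$eet, "mm month-1"),
      drainage = mk(diags$drainage, "mm month-1")
    ),
    topt = topt,
    final_state = state
  )
}
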