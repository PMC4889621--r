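test_that("LST digital numbers convert by the published scaling", {
  expect_equal(lst_dn_to_celsius(13657.5), 0)
  expect_equal(lst_dn_to_celsius(15157.5), 30)
  expect_equal(lst_dn_to_celsius(0), -273.15)
  expect_error(lst_dn_to_celsius(-1), "non-negative")
})

test_that("daily precipitation scales by leap-aware month length", {
  expect_equal(daily_to_monthly_precip(2, 2005, 1), 62)
  expect_equal(daily_to_monthly_precip(1, 2000, 2), 29) # leap year
  expect_equal(daily_to_monthly_precip(1, 1900, 2), 28) # century non-leap
  expect_equal(daily_to_monthly_precip(1, 2000, 2:4), c(29, 31, 30))
  expect_equal(daily_to_monthly_precip(0, 2005, 7), 0)
  expect_error(daily_to_monthly_precip(1, 2005, 13), "month")
})

test_that("temperature scalar matches its closed form and stays in [0,1]", {
  # independent evaluation of the stated form at t = topt = 20
  topt <- 20
  t1 <- 0.8 + 0.02 * topt - 0.0005 * topt^2
  t2 <- 1.1814 / ((1 + exp(0.2 * (topt - 10 - topt))) *
                    (1 + exp(0.3 * (-topt - 10 + topt))))
  expect_equal(temperature_scalar(20, 20), t1 * t2, tolerance = 1e-12)
  # cold limit: the first logistic saturates and the scalar goes to 0
  expect_lt(temperature_scalar(-80, 20), 1e-6)
  expect_equal(temperature_scalar(-1e6, 20), 0)
  # bounds over a broad random sweep
  set.seed(3)
  tt <- runif(500, -60, 60)
  to <- runif(500, 0, 35)
  v <- temperature_scalar(tt, to)
  expect_true(all(v >= 0 & v <= 1))
})

test_that("temperature scalar is unimodal with its peak near topt", {
  grid <- seq(-40, 60, by = 0.1)
  v <- temperature_scalar(grid, 20)
  peak <- grid[which.max(v)]
  expect_lt(abs(peak - 20), 3)
  # rises monotonically before the peak, falls after
  rising <- diff(v[grid <= peak]) >= 0
  falling <- diff(v[grid >= peak]) <= 0
  expect_true(all(rising))
  expect_true(all(falling))
})

test_that("Priestley-Taylor PET matches its closed form", {
  expect_equal(priestley_taylor_pet(20, 0), 0)
  # linear and increasing in radiation
  expect_equal(priestley_taylor_pet(20, 800), 2 * priestley_taylor_pet(20, 400))
  expect_gt(priestley_taylor_pet(20, 401), priestley_taylor_pet(20, 400))
  # independent evaluation at t = 20, rn = 400
  t <- 20
  delta <- 4098 * 0.6108 * exp(17.27 * t / (t + 237.3)) / (t + 237.3)^2
  want <- 1.26 * delta / (delta + 0.066) * 400 / 2.45
  expect_equal(priestley_taylor_pet(20, 400), want, tolerance = 1e-9)
  expect_error(priestley_taylor_pet(20, -5), "non-negative")
})

test_that("water balance: no forcing leaves the state untouched with W = 1", {
  caps <- list(cap1 = 40, cap2 = 150, cap3 = 300)
  state <- list(l1 = 10, l2 = 50, l3 = 100)
  out <- water_balance_step(state, 0, 0, caps)
  expect_equal(out$state, state)
  expect_equal(out$eet, 0)
  expect_equal(out$drainage, 0)
  expect_equal(out$w_scalar, 1)
})

test_that("water balance: saturated soil sheds all precipitation", {
  caps <- list(cap1 = 40, cap2 = 150, cap3 = 300)
  state <- list(l1 = 40, l2 = 150, l3 = 300)
  out <- water_balance_step(state, 50, 0, caps)
  expect_equal(out$drainage, 50)
  expect_equal(out$state, state)
  expect_equal(out$eet, 0)
})

test_that("water budget closes to 1e-9 mm over 36 months x 1000 pixels", {
  set.seed(11)
  n <- 1000
  caps <- list(
    cap1 = runif(n, 10, 40), cap2 = runif(n, 40, 150),
    cap3 = runif(n, 80, 300)
  )
  state <- list(l1 = caps$cap1 / 2, l2 = caps$cap2 / 2, l3 = caps$cap3 / 2)
  for (m in 1:36) {
    precip <- rexp(n, 1 / 60)
    pet <- runif(n, 0, 150)
    before <- state$l1 + state$l2 + state$l3
    out <- water_balance_step(state, precip, pet, caps)
    after <- out$state$l1 + out$state$l2 + out$state$l3
    # conservation: precip = change in storage + EET + drainage
    expect_lt(max(abs(precip - (after - before) - out$eet - out$drainage)),
              1e-9)
    expect_true(all(out$w_scalar >= 0.5 & out$w_scalar <= 1))
    expect_true(all(out$state$l1 >= 0 & out$state$l1 <= caps$cap1 + 1e-12))
    expect_true(all(out$state$l2 >= 0 & out$state$l2 <= caps$cap2 + 1e-12))
    expect_true(all(out$state$l3 >= 0 & out$state$l3 <= caps$cap3 + 1e-12))
    expect_true(all(out$drainage >= 0 & out$eet >= 0))
    state <- out$state
  }
})

make_uniform_climate <- function(spec, years, temp = 15, precip = 60,
                                 solar = 400) {
  yy <- rep(years, each = 12)
  mm <- rep(1:12, length(years))
  climate_inputs(
    temperature = const_stack(spec, temp, yy, mm, "degC"),
    precipitation = const_stack(spec, precip, yy, mm, "mm month-1"),
    solar = const_stack(spec, solar, yy, mm, "MJ m-2 month-1")
  )
}

test_that("spin-up reaches the expected fixed points and is deterministic", {
  spec <- tiny_spec(2, 2)
  caps <- soil_capacity_grids(1, spec = spec)
  wet <- make_uniform_climate(spec, 1999:2000, temp = 5, precip = 2000,
                              solar = 100)
  s_wet <- spin_up(wet, caps)
  expect_equal(s_wet$l1, caps$cap1)
  expect_equal(s_wet$l2, caps$cap2)
  expect_equal(s_wet$l3, caps$cap3)
  dry <- make_uniform_climate(spec, 1999:2000, temp = 25, precip = 0,
                              solar = 500)
  s_dry <- spin_up(dry, caps)
  expect_equal(max(abs(s_dry$l1)), 0)
  expect_equal(max(abs(s_dry$l2 + s_dry$l3)), 0)
  expect_identical(spin_up(wet, caps), s_wet)
  short <- make_uniform_climate(spec, 1999, precip = 10)
  expect_error(spin_up(short, caps), "24 months")
})

test_that("the NPP product behaves multiplicatively", {
  expect_equal(casa_npp_month(100, 0, 0.55, 1, 1), 0)
  expect_equal(casa_npp_month(100, 1, 0.55, 1, 1), 55)
  expect_equal(
    casa_npp_month(200, 0.5, 0.55, 0.8, 0.7),
    2 * casa_npp_month(100, 0.5, 0.55, 0.8, 0.7)
  )
  # negative vegetation index is clamped under the non-negativity flag
  expect_equal(casa_npp_month(100, -0.1, 0.55, 1, 1), 0)
  expect_equal(casa_npp_month(100, -0.1, 0.55, 1, 1, npp_nonnegative = FALSE),
               -5.5)
  # monotone non-decreasing in every factor
  base <- casa_npp_month(100, 0.5, 0.55, 0.6, 0.7)
  expect_gte(casa_npp_month(110, 0.5, 0.55, 0.6, 0.7), base)
  expect_gte(casa_npp_month(100, 0.6, 0.55, 0.6, 0.7), base)
  expect_gte(casa_npp_month(100, 0.5, 0.55, 0.7, 0.7), base)
  expect_gte(casa_npp_month(100, 0.5, 0.55, 0.6, 0.8), base)
})

test_that("uniform inputs give spatially uniform NPP; zero IVI kills NPP only", {
  spec <- tiny_spec(3, 3)
  climate <- make_uniform_climate(spec, 1999:2003)
  caps <- soil_capacity_grids(2, spec = spec)
  ivi <- const_stack(spec, 0.6, rep(2001:2003, each = 12), rep(1:12, 3))
  run <- run_casa_class(ivi, climate, caps, casa_params(topt = 15))
  for (i in seq_len(n_months(run$npp))) {
    layer <- run$npp$values[, , i]
    expect_equal(max(layer), min(layer))
  }
  ivi0 <- const_stack(spec, 0, rep(2001:2003, each = 12), rep(1:12, 3))
  run0 <- run_casa_class(ivi0, climate, caps, casa_params(topt = 15))
  expect_true(all(run0$npp$values == 0))
  # the water balance still evolves under forcing
  expect_gt(sum(run0$diagnostics$eet$values), 0)
})

test_that("a grid run equals the pixelwise composition of scalar operations", {
  spec <- tiny_spec(5, 5)
  set.seed(21)
  yy <- rep(1999:2001, each = 12)
  mm <- rep(1:12, 3)
  nt <- length(yy)
  mk <- function(lo, hi) {
    monthly_stack(array(runif(25 * nt, lo, hi), c(5, 5, nt)), spec, yy, mm)
  }
  climate <- climate_inputs(mk(-5, 25), mk(0, 150), mk(100, 600))
  soil <- raster_grid(matrix(sample(1:6, 25, TRUE), 5, 5), spec)
  caps <- soil_capacity_grids(soil)
  ivi <- monthly_stack(
    array(runif(25 * 12, 0, 0.9), c(5, 5, 12)), spec,
    rep(2001, 12), 1:12
  )
  run <- run_casa_class(ivi, climate, caps, casa_params(topt = 18))

  # scalar-path oracle on a single pixel
  r <- 3; c <- 4
  tab <- soil_texture_defaults()
  krow <- match(soil$values[r, c], tab$code)
  cap <- list(cap1 = tab$cap1[krow], cap2 = tab$cap2[krow],
              cap3 = tab$cap3[krow])
  state <- list(l1 = cap$cap1 / 2, l2 = cap$cap2 / 2, l3 = cap$cap3 / 2)
  for (i in 1:24) { # spin-up months 1999-2000
    pet <- priestley_taylor_pet(
      climate$temperature$values[r, c, i], climate$solar$values[r, c, i]
    )
    state <- water_balance_step(
      state, climate$precipitation$values[r, c, i], pet, cap
    )$state
  }
  for (t in 1:12) {
    i <- 24 + t
    tm <- climate$temperature$values[r, c, i]
    pet <- priestley_taylor_pet(tm, climate$solar$values[r, c, i])
    wb <- water_balance_step(
      state, climate$precipitation$values[r, c, i], pet, cap
    )
    state <- wb$state
    want <- casa_npp_month(
      climate$solar$values[r, c, i], ivi$values[r, c, t], 0.55,
      temperature_scalar(tm, 18), wb$w_scalar
    )
    expect_equal(run$npp$values[r, c, t], want, tolerance = 1e-12)
  }
})

test_that("warm and wet conditions reach the closed-form NPP limit", {
  spec <- tiny_spec(2, 2)
  topt <- 20
  climate <- make_uniform_climate(spec, 1999:2001, temp = topt,
                                  precip = 1e5, solar = 400)
  caps <- soil_capacity_grids(1, spec = spec)
  ivi <- const_stack(spec, 0.7, rep(2001, 12), 1:12)
  run <- run_casa_class(ivi, climate, caps, casa_params(topt = topt))
  want <- 400 * 0.7 * 0.55 * temperature_scalar(topt, topt)
  expect_true(all(abs(run$npp$values - want) <= 1e-9))
})

test_that("climate shorter than the spin-up requirement falls back or fails", {
  spec <- tiny_spec(2, 2)
  caps <- soil_capacity_grids(1, spec = spec)
  ivi <- const_stack(spec, 0.5, rep(2001, 12), 1:12)
  # exactly the reporting year: first year repeated twice as spin-up
  climate1 <- make_uniform_climate(spec, 2001)
  run <- run_casa_class(ivi, climate1, caps, casa_params(topt = 15))
  expect_equal(n_months(run$npp), 12L)
  # climate not covering the reporting span at all
  climate0 <- make_uniform_climate(spec, 1995)
  expect_error(run_casa_class(ivi, climate0, caps), "cover")
})

test_that("topt derivation picks the warmest-month climatology, clipped", {
  spec <- tiny_spec(2, 2)
  yy <- rep(2000:2001, each = 12)
  mm <- rep(1:12, 2)
  base <- 10 + 15 * cos(2 * pi * (mm - 7) / 12) # warmest in July: 25
  arr <- array(rep(base, each = 4), c(2, 2, 24))
  topt <- derive_topt(monthly_stack(arr, spec, yy, mm))
  expect_equal(topt, matrix(25, 2, 2))
  # clipping at 35
  arr2 <- arr + 20
  expect_equal(derive_topt(monthly_stack(arr2, spec, yy, mm)),
               matrix(35, 2, 2))
})

test_that("soil capacity grids map codes and scale the subsoil layer", {
  spec <- tiny_spec(2, 2)
  soil <- raster_grid(matrix(c(1, 6, 2, 5), 2, 2), spec)
  caps <- soil_capacity_grids(soil)
  tab <- soil_texture_defaults()
  expect_equal(caps$cap1[1, 1], tab$cap1[tab$class_code == "organic"])
  expect_equal(caps$cap3[2, 1], tab$cap3[tab$class_code == "lithosol"])
  deep <- soil_capacity_grids(soil, rooting_multiplier = 1.8)
  expect_equal(deep$cap3, caps$cap3 * 1.8)
  expect_equal(deep$cap1, caps$cap1)
  expect_error(
    soil_capacity_grids(raster_grid(matrix(9, 2, 2), spec)),
    "unknown"
  )
  # ordering invariant: organic largest, lithosol smallest
  expect_true(all(diff(tab$cap3) < 0))
  expect_true(all(diff(tab$cap1) < 0))
})
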