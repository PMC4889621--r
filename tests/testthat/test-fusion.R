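test_that("uniform fine cover yields fraction 1 for that class, 0 elsewhere", {
  classes <- cover_classes(c("water", "grasslands"), c(1, 7))
  fine <- raster_grid(
    matrix(1, 20, 20),
    grid_spec(0, 1, 0.05, 20, 20)
  )
  coarse <- grid_spec(0, 1, 0.25, 4, 4)
  frac <- aggregate_fractional_cover(fine, coarse, classes)
  expect_equal(frac$fractions$water, matrix(1, 4, 4))
  expect_equal(frac$fractions$grasslands, matrix(0, 4, 4))
})

test_that("fractions are counted over fine-cell centers (13x13 block)", {
  # one coarse pixel holding a 13x13 fine block: 84 forest + 85 grass cells
  codes <- c(rep(2L, 84), rep(7L, 85))
  fine <- raster_grid(
    matrix(codes, 13, 13),
    grid_spec(0, 0.004, 0.004 / 13, 13, 13)
  )
  coarse <- grid_spec(0, 0.004, 0.004, 1, 1)
  classes <- cover_classes(c("evergreen forest", "grasslands"), c(2, 7))
  frac <- aggregate_fractional_cover(fine, coarse, classes)
  expect_equal(frac$fractions[["evergreen forest"]][1, 1], 84 / 169)
  expect_equal(frac$fractions[["grasslands"]][1, 1], 85 / 169)
})

test_that("coarse pixels with no valid fine cells are nodata in all classes", {
  classes <- cover_classes("water", 1)
  m <- matrix(1, 4, 4)
  m[, 3:4] <- NA # right half of the fine grid missing
  fine <- raster_grid(m, grid_spec(0, 2, 0.5, 4, 4))
  coarse <- grid_spec(0, 2, 1, 2, 2)
  frac <- aggregate_fractional_cover(fine, coarse, classes)
  expect_equal(frac$fractions$water[, 1], c(1, 1))
  expect_true(all(is.na(frac$fractions$water[, 2])))
})

test_that("unknown fine codes are rejected with the offending code named", {
  classes <- cover_classes("water", 1)
  fine <- raster_grid(matrix(c(1, 1, 1, 99), 2, 2), grid_spec(0, 1, 0.5, 2, 2))
  expect_error(
    aggregate_fractional_cover(fine, grid_spec(0, 1, 1, 1, 1), classes),
    "99"
  )
})

test_that("fractions sum to 1 on every valid pixel across random scenes", {
  for (seed in 1:5) {
    scene <- make_landscape(small_cfg(seed))
    frac <- aggregate_fractional_cover(
      scene$landcover, small_cfg(seed)$spec, small_cfg(seed)$classes
    )
    total <- Reduce(`+`, frac$fractions)
    expect_true(all(abs(total - 1) <= 1e-6))
  }
})

test_that("pure-pixel threshold is inclusive at exactly 0.9", {
  classes <- cover_classes(c("a", "b"), c(1, 2))
  spec <- grid_spec(0, 1, 1, 1, 3)
  frac <- structure(
    list(
      spec = spec, classes = classes,
      fractions = list(
        a = matrix(c(0.9, 0.899, 0.95), 1, 3),
        b = matrix(c(0.1, 0.101, 0.05), 1, 3)
      )
    ),
    class = "fractional_cover"
  )
  pts <- suppressWarnings(identify_pure_pixels(frac, 0.9))
  a_cols <- pts$col[pts$class == "a"]
  expect_setequal(a_cols, c(1L, 3L)) # 0.9 in, 0.899 out
  expect_false(any(pts$class == "b"))
  # points sit at pixel centers
  expect_equal(pts$lon[pts$col == 1 & pts$class == "a"], 0.5)
  expect_equal(pts$lat[pts$col == 1 & pts$class == "a"], 0.5)
})

test_that("an all-mixed landscape yields empty sample sets with a warning", {
  classes <- cover_classes(c("a", "b"), c(1, 2))
  frac <- structure(
    list(
      spec = grid_spec(0, 1, 1, 1, 2), classes = classes,
      fractions = list(
        a = matrix(0.5, 1, 2),
        b = matrix(0.5, 1, 2)
      )
    ),
    class = "fractional_cover"
  )
  expect_warning(pts <- identify_pure_pixels(frac, 0.9), "no pure pixels")
  expect_equal(nrow(pts), 0L)
})

test_that("point sampling extracts the containing pixel and flags missing", {
  spec <- tiny_spec(3, 3, cell = 1, lon = 0, lat = 3)
  m <- matrix(as.numeric(1:9), 3, 3, byrow = TRUE)
  m2 <- m
  m2[2, 2] <- NA
  st <- monthly_stack(
    array(c(m, m2), c(3, 3, 2)), spec,
    c(2000, 2000), c(1, 2)
  )
  pts <- tibble::tibble(class = "a", lon = c(1.5, 0.5), lat = c(1.5, 2.5))
  s <- sample_evi_at_points(st, pts)
  expect_equal(nrow(s), 4L)
  # exact center of pixel (2,2) -> value 5; (1,1) -> 1
  expect_equal(s$evi[s$month == 1 & s$lon == 1.5], 5)
  expect_equal(s$evi[s$month == 1 & s$lon == 0.5], 1)
  # nodata month is missing, not zero
  expect_true(is.na(s$evi[s$month == 2 & s$lon == 1.5]))
  expect_error(
    sample_evi_at_points(st, tibble::tibble(class = "a", lon = 99, lat = 0)),
    "outside"
  )
})

test_that("uniform field samples uniformly", {
  spec <- tiny_spec(3, 3)
  st <- const_stack(spec, 0.5, 2000, 1)
  pts <- identify_pure_pixels(
    structure(
      list(
        spec = spec, classes = cover_classes("a", 1),
        fractions = list(a = matrix(1, 3, 3))
      ),
      class = "fractional_cover"
    )
  )
  s <- sample_evi_at_points(st, pts)
  expect_true(all(s$evi == 0.5))
})

test_that("LOO RMSPE matches a hand-built brute-force oracle", {
  # 3 collinear points, values 0, 1, 2
  s <- tibble::tibble(
    class = "a", lon = c(0, 1, 2), lat = c(0, 0, 0),
    year = 2000, month = 1, evi = c(0, 1, 2)
  )
  got <- idw_rmspe(s, 2000, 1, power = 2)
  want <- rmspe_brute(s$lon, s$lat, s$evi, 2)
  expect_equal(got, want, tolerance = 1e-12)
  # and against the explicit closed form: leaving out the middle point,
  # weights 1 and 1 -> predict 1 (error 0); ends predict
  # (1*1 + 2*0.25)/1.25 = 1.2 (err 1.2) and symmetric 0.8 (err 1.2)
  expect_equal(got, sqrt(mean(c(1.2^2, 0, 1.2^2))), tolerance = 1e-12)
})

test_that("RMSPE is zero for constant fields and coincident duplicates", {
  s <- tibble::tibble(
    class = "a", lon = runif(6), lat = runif(6),
    year = 2000, month = 1, evi = 0.4
  )
  expect_equal(idw_rmspe(s, 2000, 1, 2), 0)
  # duplicate every point: the exact-match rule predicts each sample from
  # its coincident twin
  s2 <- tibble::tibble(
    class = "a", lon = rep(c(0, 1, 2), 2), lat = 0,
    year = 2000, month = 1, evi = rep(c(0.1, 0.5, 0.9), 2)
  )
  expect_equal(idw_rmspe(s2, 2000, 1, 2), 0)
  expect_error(
    idw_rmspe(s[1, ], 2000, 1, 2),
    "at least 2"
  )
})

test_that("power selection minimises RMSPE, ties to the smallest power", {
  set.seed(99)
  s <- tibble::tibble(
    class = "a", lon = runif(15), lat = runif(15),
    year = 2000, month = 1
  )
  s$evi <- 0.3 + 0.4 * s$lon + 0.2 * s$lat + rnorm(15, sd = 0.01)
  cand <- seq(1, 4, by = 0.5)
  # exhaustive-search oracle over the brute-force RMSPE
  oracle <- vapply(cand, function(p) rmspe_brute(s$lon, s$lat, s$evi, p),
                   numeric(1))
  got <- select_idw_power(s, 2000, 1, cand, max_neighbors = 99)
  expect_equal(got, cand[which.min(oracle)])
  expect_equal(select_idw_power(s, 2000, 1, 2.0), 2.0)
  # constant field: every power gives RMSPE 0, so the smallest wins
  s$evi <- 0.5
  expect_equal(select_idw_power(s, 2000, 1, c(3, 1.5), max_neighbors = 99), 1.5)
})

test_that("IDW is an exact interpolator and convex in the samples", {
  s <- tibble::tibble(
    class = "a",
    lon = c(0.1, 0.52, 0.9), lat = c(0.1, 0.48, 0.9),
    year = 2000, month = 1, evi = c(0.73, 0.2, 0.6)
  )
  spec <- grid_spec(0, 1, 0.2, 5, 5)
  # sample 1 sits exactly on the center of cell (row 5, col 1)
  s$lon[1] <- 0.1
  s$lat[1] <- 0.1
  out <- idw_interpolate(s, 2000, 1, spec, idw_params(power = 2))
  expect_identical(out$values[5, 1], 0.73)
  expect_true(all(out$values >= min(s$evi) - 1e-12))
  expect_true(all(out$values <= max(s$evi) + 1e-12))
  # all samples equal -> constant surface
  s$evi <- 0.31
  out <- idw_interpolate(s, 2000, 1, spec, idw_params(power = 2))
  expect_equal(out$values, matrix(0.31, 5, 5))
})

test_that("IDW matches the explicit weight-sum formula and brute force", {
  # 3 samples, power 2, one target cell: explicit formula oracle
  s <- tibble::tibble(
    class = "a", lon = c(0, 1, 0), lat = c(0, 0, 1),
    year = 2000, month = 1, evi = c(0.2, 0.8, 0.5)
  )
  tgt <- grid_spec(0.25, 0.75, 1, 1, 1) # center (0.75, 0.25)
  d2 <- (0.75 - s$lon)^2 + (0.25 - s$lat)^2
  w <- d2^(-1)
  want <- sum(w * s$evi) / sum(w)
  out <- idw_interpolate(s, 2000, 1, tgt, idw_params(power = 2))
  expect_equal(out$values[1, 1], want, tolerance = 1e-12)

  # oracle equivalence on grids <= 20x20 with <= 25 samples
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(5:25, 1)
    sx <- runif(n); sy <- runif(n); sz <- runif(n, 0, 0.9)
    samp <- tibble::tibble(
      class = "a", lon = sx, lat = sy, year = 2000, month = 1, evi = sz
    )
    spec <- grid_spec(0, 1, 1 / 20, 20, 20)
    got <- idw_interpolate(samp, 2000, 1, spec,
                           idw_params(power = 2, max_neighbors = n))
    ctr <- cell_centers(spec)
    want <- idw_brute(sx, sy, sz, ctr$lon, ctr$lat, 2)
    expect_equal(
      as.vector(t(got$values)), want,
      tolerance = 1e-10
    )
  }
})

test_that("zero valid samples for a month is an error naming the context", {
  s <- tibble::tibble(
    class = "grasslands", lon = 0.5, lat = 0.5,
    year = 2000, month = 1, evi = NA_real_
  )
  expect_error(
    idw_interpolate(s, 2000, 1, tiny_spec(2, 2), idw_params()),
    "grasslands"
  )
})

test_that("constant-per-class checkerboard is recovered by the IVI chain", {
  # alternating pure pixels of two classes with constant EVI 0.2 / 0.8
  n <- 8
  spec <- grid_spec(0, n * 0.004, 0.004, n, n)
  chk <- outer(1:n, 1:n, function(r, c) (r + c) %% 2L)
  frac <- structure(
    list(
      spec = spec, classes = cover_classes(c("A", "B"), c(1, 2)),
      fractions = list(A = 1 - chk, B = chk + 0)
    ),
    class = "fractional_cover"
  )
  evi_vals <- 0.2 * (1 - chk) + 0.8 * chk
  evi <- monthly_stack(array(evi_vals, c(n, n, 1)), spec, 2000, 6)
  ivi <- build_ivi(evi, frac, idw_params(power = 2), tune = FALSE)
  expect_true(all(abs(ivi$A$values - 0.2) <= 1e-6))
  expect_true(all(abs(ivi$B$values - 0.8) <= 1e-6))
})

test_that("classes with no pure pixels are flagged unavailable", {
  n <- 4
  spec <- grid_spec(0, n * 0.004, 0.004, n, n)
  frac <- structure(
    list(
      spec = spec, classes = cover_classes(c("A", "B"), c(1, 2)),
      fractions = list(A = matrix(0.95, n, n), B = matrix(0.05, n, n))
    ),
    class = "fractional_cover"
  )
  evi <- const_stack(spec, 0.5, 2000, 6)
  expect_warning(
    ivi <- build_ivi(evi, frac, idw_params(), tune = FALSE),
    "unavailable"
  )
  expect_named(ivi, "A")
  expect_identical(attr(ivi, "unavailable"), "B")
})
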