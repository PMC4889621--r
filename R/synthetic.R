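#' Synthetic scene configuration
#'
#' Bundles every knob of the seeded scene generators. The defaults describe
#' the reference study conditions used throughout the package's tests: a
#' 40 x 40 coarse model grid of 0.004-degree cells over a mid-latitude
#' landscape, fine land cover at 1/13 of the coarse cell (mimicking ~30-m
#' cover inside ~500-m index pixels), three vegetated cover classes with
#' distinct seasonal phenologies, three reporting years preceded by two
#' spin-up years of climate, and modest observation noise.
#'
#' @param seed Integer seed; every generator is a pure function of the
#'   config including this seed.
#' @param n_rows,n_cols Coarse grid dimensions.
#' @param cell_size Coarse cell size, degrees.
#' @param origin_lon,origin_lat North-west corner of the grid, degrees.
#' @param fine_ratio Fine cells per coarse cell edge (>= 2).
#' @param classes [cover_classes()] tibble of the classes to simulate.
#' @param phenology Tibble `class`, `mean_evi`, `amplitude`, `peak_month`;
#'   defaults give forest/grassland/cropland-like seasonal curves whose
#'   values stay within the vegetation-index range `[-0.2, 1]`.
#' @param report_years Calendar years of the vegetation-index (reporting)
#'   span.
#' @param spinup_years Extra climate-only years preceding the reporting
#'   span (default 2, the model's initialisation requirement).
#' @param patch_cells Smoothing window of the patch process, in fine cells;
#'   larger values give larger, purer patches.
#' @param temp_mean,temp_amplitude Annual temperature cycle, degrees C.
#' @param precip_mean,precip_amplitude Annual precipitation cycle, mm/month.
#' @param evi_noise_sd,temp_noise_sd,precip_noise_sd Per-pixel-month
#'   i.i.d. noise standard deviations.
#' @param transmissivity Clear-sky atmospheric transmissivity for the
#'   flat-surface solar generator.
#' @return A `scene_config` list.
#' @export
scene_config <- function(seed = 1L,
                         n_rows = 40L, n_cols = 40L,
                         cell_size = 0.004,
                         origin_lon = -111, origin_lat = 45,
                         fine_ratio = 13L,
                         classes = cover_classes(
                           c("evergreen forest", "grasslands", "croplands"),
                           c(2L, 7L, 8L)
                         ),
                         phenology = NULL,
                         report_years = 2001:2003,
                         spinup_years = 2L,
                         patch_cells = 39L,
                         temp_mean = 8, temp_amplitude = 12,
                         precip_mean = 60, precip_amplitude = 30,
                         evi_noise_sd = 0.02,
                         temp_noise_sd = 1,
                         precip_noise_sd = 10,
                         transmissivity = 0.75) {
  stopifnot(fine_ratio >= 2, spinup_years >= 0, length(report_years) >= 1)
  if (is.null(phenology)) {
    k <- nrow(classes)
    phenology <- tibble::tibble(
      class = classes$class,
      mean_evi = rep_len(c(0.45, 0.35, 0.40), k),
      amplitude = rep_len(c(0.15, 0.25, 0.30), k),
      peak_month = rep_len(c(7L, 6L, 7L), k)
    )
  }
  if (!setequal(phenology$class, classes$class)) {
    stop("phenology must cover exactly the configured classes")
  }
  if (any(phenology$mean_evi + phenology$amplitude > 1) ||
      any(phenology$mean_evi - phenology$amplitude < -0.2)) {
    stop("phenology amplitudes leave the valid vegetation-index range")
  }
  structure(
    list(
      seed = as.integer(seed),
      spec = grid_spec(origin_lon, origin_lat, cell_size, n_rows, n_cols),
      fine_ratio = as.integer(fine_ratio),
      classes = classes, phenology = phenology,
      report_years = as.integer(report_years),
      spinup_years = as.integer(spinup_years),
      patch_cells = as.integer(patch_cells),
      temp_mean = temp_mean, temp_amplitude = temp_amplitude,
      precip_mean = precip_mean, precip_amplitude = precip_amplitude,
      evi_noise_sd = evi_noise_sd, temp_noise_sd = temp_noise_sd,
      precip_noise_sd = precip_noise_sd,
      transmissivity = transmissivity
    ),
    class = "scene_config"
  )
}

fine_spec_of <- function(cfg) {
  grid_spec(
    cfg$spec$origin_lon, cfg$spec$origin_lat,
    cfg$spec$cell_size / cfg$fine_ratio,
    cfg$spec$n_rows * cfg$fine_ratio,
    cfg$spec$n_cols * cfg$fine_ratio
  )
}

# Circular box smoothing along both axes, applied twice for a roughly
# Gaussian kernel; keeps patch edges soft so coarse pixels mix classes.
smooth_field <- function(m, w) {
  if (w %% 2 == 0) w <- w + 1
  k <- rep(1 / w, w)
  cols <- function(x) apply(x, 2, function(v) {
    as.numeric(stats::filter(v, k, circular = TRUE))
  })
  both <- function(x) t(cols(t(cols(x))))
  both(both(m))
}

#' Generate a patchy categorical landscape with known fractional cover
#'
#' Per class, a smoothed random field is drawn on the fine grid; each fine
#' cell takes the class whose field is largest (threshold allocation),
#' producing contiguous patches with mixed coarse pixels at patch
#' boundaries. The exact fractional cover is computed alongside by direct
#' per-coarse-pixel counting, providing an independent oracle for
#' [aggregate_fractional_cover()].
#'
#' @param cfg A [scene_config()].
#' @return List with `landcover` (fine categorical [raster_grid()]),
#'   `true_fractions` (named list of coarse fraction matrices) and
#'   `fine_spec`.
#' @export
make_landscape <- function(cfg) {
  fspec <- fine_spec_of(cfg)
  k <- nrow(cfg$classes)
  fields <- withr::with_seed(cfg$seed, {
    lapply(seq_len(k), function(i) {
      smooth_field(
        matrix(stats::rnorm(fspec$n_rows * fspec$n_cols),
               fspec$n_rows, fspec$n_cols),
        cfg$patch_cells
      )
    })
  })
  fields <- lapply(fields, function(f) (f - mean(f)) / stats::sd(f))
  winner <- matrix(1L, fspec$n_rows, fspec$n_cols)
  best <- fields[[1]]
  if (k > 1) {
    for (i in 2:k) {
      better <- fields[[i]] > best
      winner[better] <- i
      best[better] <- fields[[i]][better]
    }
  }
  codes <- matrix(cfg$classes$code[winner], fspec$n_rows, fspec$n_cols)
  # independent counting oracle, coarse pixel by coarse pixel
  R <- cfg$fine_ratio
  truth <- lapply(cfg$classes$code, function(code) {
    m <- matrix(NA_real_, cfg$spec$n_rows, cfg$spec$n_cols)
    for (r in seq_len(cfg$spec$n_rows)) {
      rows <- ((r - 1) * R + 1):(r * R)
      for (c in seq_len(cfg$spec$n_cols)) {
        block <- codes[rows, ((c - 1) * R + 1):(c * R)]
        m[r, c] <- sum(block == code) / length(block)
      }
    }
    m
  })
  names(truth) <- cfg$classes$class
  list(
    landcover = raster_grid(codes, fspec, units = "class code"),
    true_fractions = truth,
    fine_spec = fspec
  )
}

class_curve <- function(mean_evi, amplitude, peak_month, month) {
  mean_evi + amplitude * cos(2 * pi * (month - peak_month) / 12)
}

#' Generate a vegetation-index stack consistent with the landscape
#'
#' Each coarse pixel-month mixes the per-class seasonal phenology curves by
#' the true fractional cover, plus i.i.d. noise, clipped to `[-0.2, 1]`.
#' The true curves are returned so fusion recovery can be checked.
#'
#' @param cfg A [scene_config()].
#' @param landscape Output of [make_landscape()].
#' @return List with `evi` ([monthly_stack()] over the reporting years) and
#'   `true_curves` (tibble `class`, `month`, `evi`).
#' @export
make_evi <- function(cfg, landscape) {
  spec <- cfg$spec
  years <- rep(cfg$report_years, each = 12L)
  months <- rep(1:12, times = length(cfg$report_years))
  nt <- length(years)
  mix <- matrix(0, spec$n_rows * spec$n_cols, 12)
  for (i in seq_len(nrow(cfg$classes))) {
    ph <- cfg$phenology[cfg$phenology$class == cfg$classes$class[i], ]
    curve <- class_curve(ph$mean_evi, ph$amplitude, ph$peak_month, 1:12)
    f <- as.vector(landscape$true_fractions[[cfg$classes$class[i]]])
    mix <- mix + outer(f, curve)
  }
  arr <- withr::with_seed(cfg$seed + 1L, {
    a <- array(NA_real_, c(spec$n_rows, spec$n_cols, nt))
    for (t in seq_len(nt)) {
      noise <- if (cfg$evi_noise_sd > 0) {
        stats::rnorm(length(mix[, 1]), sd = cfg$evi_noise_sd)
      } else {
        0
      }
      a[, , t] <- matrix(
        pmin(pmax(mix[, months[t]] + noise, -0.2), 1),
        spec$n_rows, spec$n_cols
      )
    }
    a
  })
  truth <- tidyr::crossing(class = cfg$classes$class, month = 1:12) |>
    dplyr::left_join(cfg$phenology, by = "class") |>
    dplyr::mutate(
      evi = class_curve(.data$mean_evi, .data$amplitude, .data$peak_month,
                        .data$month)
    ) |>
    dplyr::select("class", "month", "evi")
  list(
    evi = monthly_stack(arr, spec, years, months, units = "EVI"),
    true_curves = truth
  )
}

#' Monthly clear-sky solar irradiance on a flat surface
#'
#' Daily extraterrestrial radiation from solar geometry (eccentricity,
#' declination, sunset hour angle) scaled by a clear-sky transmissivity and
#' summed over the month. A simple flat-surface stand-in for a terrain
#' solar-radiation model; it peaks in June at northern mid-latitudes.
#'
#' @param lat Latitude, degrees (vectorised).
#' @param year,month Calendar month.
#' @param transmissivity Fraction of extraterrestrial radiation reaching
#'   the surface (default 0.75).
#' @return Monthly total irradiance, MJ m-2 month-1 (never negative).
#' @export
clear_sky_solar <- function(lat, year, month, transmissivity = 0.75) {
  phi <- lat * pi / 180
  first <- as.Date(sprintf("%04d-%02d-01", year, month))
  jdays <- as.integer(format(
    seq(first, by = "day", length.out = days_in_month(year, month)), "%j"
  ))
  total <- 0
  for (j in jdays) {
    dr <- 1 + 0.033 * cos(2 * pi * j / 365)
    decl <- 0.409 * sin(2 * pi * j / 365 - 1.39)
    x <- pmin(pmax(-tan(phi) * tan(decl), -1), 1)
    ws <- acos(x)
    ra <- (24 * 60 / pi) * 0.0820 * dr *
      (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
    total <- total + pmax(ra, 0)
  }
  transmissivity * total
}

#' Generate seasonal climate forcing
#'
#' Temperature and precipitation follow sinusoidal annual cycles (July peak
#' for temperature, June for precipitation) with seeded pixel noise;
#' precipitation is floored at 0. Solar irradiance is the deterministic
#' flat-surface clear-sky monthly total at each pixel's latitude. The span
#' covers the configured spin-up years followed by the reporting years.
#'
#' @param cfg A [scene_config()].
#' @return A [climate_inputs()].
#' @export
make_climate <- function(cfg) {
  spec <- cfg$spec
  y0 <- min(cfg$report_years) - cfg$spinup_years
  all_years <- y0:max(cfg$report_years)
  years <- rep(all_years, each = 12L)
  months <- rep(1:12, times = length(all_years))
  nt <- length(years)
  lat <- spec$origin_lat - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
  npix <- spec$n_rows * spec$n_cols
  solar_arr <- array(NA_real_, c(spec$n_rows, spec$n_cols, nt))
  for (t in seq_len(nt)) {
    col <- clear_sky_solar(lat, years[t], months[t], cfg$transmissivity)
    solar_arr[, , t] <- matrix(col, spec$n_rows, spec$n_cols)
  }
  out <- withr::with_seed(cfg$seed + 2L, {
    ta <- array(NA_real_, c(spec$n_rows, spec$n_cols, nt))
    pa <- array(NA_real_, c(spec$n_rows, spec$n_cols, nt))
    for (t in seq_len(nt)) {
      tmu <- cfg$temp_mean +
        cfg$temp_amplitude * cos(2 * pi * (months[t] - 7) / 12)
      pmu <- cfg$precip_mean +
        cfg$precip_amplitude * cos(2 * pi * (months[t] - 6) / 12)
      tn <- if (cfg$temp_noise_sd > 0) stats::rnorm(npix, sd = cfg$temp_noise_sd) else 0
      pn <- if (cfg$precip_noise_sd > 0) stats::rnorm(npix, sd = cfg$precip_noise_sd) else 0
      ta[, , t] <- matrix(tmu + tn, spec$n_rows, spec$n_cols)
      pa[, , t] <- matrix(pmax(pmu + pn, 0), spec$n_rows, spec$n_cols)
    }
    list(ta = ta, pa = pa)
  })
  climate_inputs(
    temperature = monthly_stack(out$ta, spec, years, months, units = "degC"),
    precipitation = monthly_stack(out$pa, spec, years, months,
                                  units = "mm month-1"),
    solar = monthly_stack(solar_arr, spec, years, months,
                          units = "MJ m-2 month-1")
  )
}

#' Generate a soil-texture code raster
#'
#' A smoothed random field quantile-sliced into the configured number of
#' texture classes, giving spatially coherent soil units.
#'
#' @param cfg A [scene_config()].
#' @param n_classes Number of texture codes drawn from
#'   [soil_texture_defaults()] (default all 6).
#' @return Integer [raster_grid()] of texture codes on the coarse grid.
#' @export
make_soil <- function(cfg, n_classes = 6L) {
  spec <- cfg$spec
  f <- withr::with_seed(cfg$seed + 3L, {
    smooth_field(
      matrix(stats::rnorm(spec$n_rows * spec$n_cols),
             spec$n_rows, spec$n_cols),
      max(3L, cfg$spec$n_rows %/% 8L)
    )
  })
  q <- stats::quantile(f, probs = seq(0, 1, length.out = n_classes + 1))
  codes <- matrix(
    as.integer(cut(f, breaks = q, include.lowest = TRUE)),
    spec$n_rows, spec$n_cols
  )
  raster_grid(codes, spec, units = "soil texture code")
}

#' Generate tower GPP records from a known composite NPP
#'
#' Places sites at seeded random valid pixels of the composite and emits
#' monthly GPP as `composite NPP / true_ratio + noise`, floored at 0 — so
#' converting back with [npp_from_gpp()] at `true_ratio` recovers the
#' composite exactly at zero noise. The 0.47 default is the published
#' forest NPP:GPP central value. Every site spans the full reporting years,
#' so all pass [filter_sites()] when three or more years were simulated.
#'
#' @param cfg A [scene_config()].
#' @param composite [monthly_stack()] of composite NPP.
#' @param n_sites Number of tower sites.
#' @param true_ratio NPP:GPP ratio used in generation.
#' @param noise_sd Standard deviation of additive GPP noise
#'   (gC m-2 month-1).
#' @param frac Optional `fractional_cover` used to label each site with its
#'   dominant cover class (otherwise `"unknown"`).
#' @return A [tower_records()] tibble.
#' @export
make_towers <- function(cfg, composite, n_sites = 6L, true_ratio = 0.47,
                        noise_sd = 0, frac = NULL) {
  spec <- composite$spec
  valid <- which(apply(!is.na(composite$values), c(1, 2), all))
  if (length(valid) < n_sites) stop("not enough valid pixels for towers")
  withr::with_seed(cfg$seed + 4L, {
    pick <- sample(valid, n_sites)
    rows <- ((pick - 1) %% spec$n_rows) + 1
    cols <- ((pick - 1) %/% spec$n_rows) + 1
    recs <- purrr::map_dfr(seq_len(n_sites), function(i) {
      lon <- spec$origin_lon + (cols[i] - 0.5) * spec$cell_size
      lat <- spec$origin_lat - (rows[i] - 0.5) * spec$cell_size
      npp <- unname(composite$values[rows[i], cols[i], ])
      gpp <- npp / true_ratio
      if (noise_sd > 0) gpp <- gpp + stats::rnorm(length(gpp), sd = noise_sd)
      cover <- "unknown"
      if (!is.null(frac)) {
        at <- vapply(frac$fractions, function(m) m[rows[i], cols[i]],
                     numeric(1))
        if (any(is.finite(at))) cover <- names(which.max(at))
      }
      tibble::tibble(
        site_id = sprintf("SYN%02d", i), lon = lon, lat = lat,
        cover = cover, year = composite$years, month = composite$months,
        gpp = pmax(gpp, 0)
      )
    })
    tower_records(recs)
  })
}

#' Write a complete synthetic scene to a directory
#'
#' Emits every pipeline input as plain files: the fine land-cover grid and
#' coarse soil grid (`.asc`), monthly vegetation-index and climate grids
#' (`{var}_{YYYY}_{MM}.asc`), tower records (`towers.csv`), and the
#' generator ground truth (`truth.json`: class fractions summary, phenology
#' curves, tower generation ratio).
#'
#' @param cfg A [scene_config()].
#' @param dir Output directory (created if needed).
#' @param n_sites,true_ratio,noise_sd Passed to [make_towers()].
#' @return `dir`, invisibly; side effect is the written scene.
#' @export
simulate_scene <- function(cfg, dir, n_sites = 6L, true_ratio = 0.47,
                           noise_sd = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scene <- make_landscape(cfg)
  evi <- make_evi(cfg, scene)
  climate <- make_climate(cfg)
  soil <- make_soil(cfg)
  write_raster(scene$landcover, file.path(dir, "landcover.asc"))
  write_raster(soil, file.path(dir, "soil.asc"))
  dump_stack <- function(st, var) {
    for (i in seq_len(n_months(st))) {
      write_raster(
        raster_grid(st$values[, , i], st$spec, units = st$units),
        file.path(dir, sprintf("%s_%04d_%02d.asc", var, st$years[i],
                               st$months[i]))
      )
    }
  }
  dump_stack(evi$evi, "evi")
  dump_stack(climate$temperature, "temperature")
  dump_stack(climate$precipitation, "precipitation")
  dump_stack(climate$solar, "solar")
  result <- run_fusion_casa(scene$landcover, evi$evi, climate, soil,
                            classes = cfg$classes)
  towers <- make_towers(cfg, result$composite, n_sites = n_sites,
                        true_ratio = true_ratio, noise_sd = noise_sd,
                        frac = result$frac)
  utils::write.csv(towers, file.path(dir, "towers.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(
      seed = cfg$seed,
      classes = cfg$classes,
      phenology = cfg$phenology,
      tower_true_ratio = true_ratio,
      tower_noise_sd = noise_sd,
      report_years = cfg$report_years
    ),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
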