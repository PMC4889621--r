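# Shared fixtures, all built in code.

tiny_spec <- function(n_rows = 5, n_cols = 5, cell = 0.004,
                      lon = -111, lat = 45) {
  grid_spec(lon, lat, cell, n_rows, n_cols)
}

# A small synthetic scene configuration that keeps tests fast.
small_cfg <- function(seed = 1L, n = 8L, ratio = 5L, ...) {
  scene_config(
    seed = seed, n_rows = n, n_cols = n, fine_ratio = ratio,
    patch_cells = 3L * ratio, ...
  )
}

# Uniform single-month stack helper.
const_stack <- function(spec, value, years, months, units = "") {
  arr <- array(value, c(spec$n_rows, spec$n_cols, length(years)))
  monthly_stack(arr, spec, years, months, units = units)
}

# Brute-force all-pairs IDW (independent of the package implementation):
# plain loops, full neighbourhoods, explicit weight sums.
idw_brute <- function(sx, sy, sz, tx, ty, power) {
  out <- numeric(length(tx))
  for (i in seq_along(tx)) {
    d <- sqrt((tx[i] - sx)^2 + (ty[i] - sy)^2)
    if (any(d == 0)) {
      out[i] <- mean(sz[d == 0])
    } else {
      w <- d^(-power)
      out[i] <- sum(w * sz) / sum(w)
    }
  }
  out
}

# Leave-one-out RMSPE via the brute-force predictor.
rmspe_brute <- function(sx, sy, sz, power) {
  err <- vapply(seq_along(sz), function(i) {
    idw_brute(sx[-i], sy[-i], sz[-i], sx[i], sy[i], power) - sz[i]
  }, numeric(1))
  sqrt(mean(err^2))
}
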