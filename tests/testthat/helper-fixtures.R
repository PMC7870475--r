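# Shared fixtures: small bases keep unit tests fast; the acceptance tests
# build the full-size configuration themselves.

# Two scales, 6 orientations x 2 phases -> K = (1 + 4) * 12 = 60.
small_basis <- function(size = 32) {
  noise_basis(image_size = size, scales = c(2, 4), grid_dims = c(1, 2))
}

# Single-component basis (K = 1).
unit_basis <- function(size = 16) {
  noise_basis(image_size = size, scales = 2, grid_dims = 1,
              orientations = 0, phases = pi / 2)
}

# Reduced-K basis for multiplicity calibration: K = (1 + 4) * 6 = 30.
reduced_basis <- function(size = 16) {
  noise_basis(image_size = size, scales = c(2, 4), grid_dims = c(1, 2),
              orientations = c(0, 60, 120))
}

# Brute-force oracle for one basis component: direct per-pixel evaluation of
# the windowed sinusoid, independent of the synthesis kernel.
oracle_component <- function(basis, k) {
  row <- basis$components[k, ]
  g <- row$grid_dim
  p <- basis$image_size / g
  img <- matrix(0, basis$image_size, basis$image_size)
  th <- row$orientation * pi / 180
  for (yy in 0:(p - 1)) {
    for (xx in 0:(p - 1)) {
      val <- sin(2 * pi * basis$cycles_per_patch *
                   (xx * cos(th) + yy * sin(th)) / p + row$phase)
      img[(row$patch_row - 1) * p + yy + 1,
          (row$patch_col - 1) * p + xx + 1] <- val
    }
  }
  img
}

# A deterministic trial frame from explicit labels.
trial_frame <- function(labels) {
  data.frame(trial_id = seq_along(labels), pv_id = seq_along(labels),
             label = labels, response4 = NA_character_,
             decision_var = NA_real_)
}

# Contribution table stub with chosen |d| values, for ranking oracles.
fake_contribution <- function(d, scale = rep(2, length(d))) {
  structure(data.frame(index = seq_along(d), scale = scale, d = d,
                       significant = FALSE),
            alpha = 0.05, class = c("contribution_table", "data.frame"))
}
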