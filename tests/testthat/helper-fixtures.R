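# shared fixtures, built in code at test time

test_lib <- build_spectral_library()

# small demo phantom shared across tests: dermis block, epidermis strip,
# BCC nodule, fat lobule (800 x 600 um at 5 um/px)
test_phantom <- function(seed = 1L, dye_fraction = 0) {
  cfg <- default_run_config(seed)
  render_phantom(cfg$phantom$layout, cfg$phantom$width_um,
                 cfg$phantom$height_um, pixel_size = cfg$phantom$pixel_size,
                 seed = seed, dye_fraction = dye_fraction)
}

# a feasible 6-member batch on a uniform region of the phantom
fat_batch <- function(cx = 580, cy = 420) {
  assign_zero_order(tibble::tibble(
    x_um = cx + c(0, -50, 50, -30, 30, 10),
    y_um = cy + c(0, -25, -15, -5, 5, 25),
    segment_id = 1L, origin = "af"))
}

# independent forward oracle for noise-free expected track-sum counts:
# direct Gaussian-sum smoothing (matrix product, no convolve()) and linear
# interpolation onto the calibrated column axis
oracle_beam_counts <- function(spec_vals, axis, weight, cfg, calib,
                               col_offset) {
  sg <- cfg$slit_fwhm_cm1 / (2 * sqrt(2 * log(2)))
  half <- ceiling(4 * sg)
  K <- outer(axis, axis, function(a, b) {
    k <- exp(-(a - b)^2 / (2 * sg^2))
    k[abs(a - b) > half] <- 0
    k
  })
  K <- sweep(K, 1, rowSums(K), "/")
  sm <- as.vector(K %*% spec_vals)
  nu <- wavenumber_at(calib, (seq_len(cfg$cols) - 1) - col_offset)
  s <- stats::approx(axis, sm, xout = nu, rule = 1)$y
  s[is.na(s)] <- 0
  cfg$signal_scale * weight * cfg$t_int * pmax(0, s)
}
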