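#' Acquisition configuration for the CCD forward simulator
#'
#' Defaults describe the simulated instrument: a 256 x 1024 pixel CCD read
#' at 50 kHz, 2 s integration, and a 0th-order beam carrying 10x the power
#' of a near-axis 1st-order beam, with 1st-order throughput falling off
#' quadratically to 10% at the FOV edge (hologram efficiency plus
#' vignetting). In `"blazed"` mode the hologram's blazing function is
#' assumed optimized so the total beam budget is shared evenly
#' (`total_weight / n_beams` each), the configuration used for tissue
#' measurements with 10 or fewer beams.
#'
#' @param t_int Integration time (s).
#' @param weight_mode `"native"` (0th order 10x) or `"blazed"` (equalized).
#' @param rows,cols CCD shape.
#' @param readout_khz Read-out rate label (kHz).
#' @param zero_order_weight Native 0th-order throughput weight.
#' @param first_order_edge_ratio Edge/center 1st-order throughput ratio.
#' @param total_weight Total beam-weight budget shared in blazed mode.
#' @param slit_fwhm_cm1 Spectral broadening FWHM from the pseudo-slit width.
#' @param signal_scale Detected counts per basis-intensity unit per second
#'   per unit beam weight.
#' @param full_well Saturation level (counts).
#' @param bias Detector bias level (counts).
#' @param read_noise Read noise (counts RMS, per track).
#' @param cosmic_rate Mean cosmic-ray events per frame.
#' @param fluor_scale Global fluorescence-baseline multiplier.
#' @param fluor_jitter Lognormal sigma of the per-spectrum fluorescence
#'   amplitude variability (tissue autofluorescence varies point to point).
#' @param dye_fluor_scale Extra broad emission for dye-contaminated points.
#' @param mgf2 Include the MgF2 substrate peak at 320 cm^-1.
#' @param mgf2_amp Substrate peak amplitude (basis units).
#' @param max_col_offset Maximum per-beam dispersion-direction offset (px).
#' @param inject_saturation Force one beam to saturate (for QC testing).
#' @return `acquisition_config` list.
#' @export
acquisition_config <- function(t_int = 2, weight_mode = c("native", "blazed"),
                               rows = 256, cols = 1024, readout_khz = 50,
                               zero_order_weight = 10,
                               first_order_edge_ratio = 0.1,
                               total_weight = 10, slit_fwhm_cm1 = 8,
                               signal_scale = 250, full_well = 65535,
                               bias = 100, read_noise = 5, cosmic_rate = 1,
                               fluor_scale = 1, fluor_jitter = 0.3,
                               dye_fluor_scale = 6,
                               mgf2 = TRUE, mgf2_amp = 0.8,
                               max_col_offset = 20,
                               inject_saturation = FALSE) {
  weight_mode <- match.arg(weight_mode)
  stopifnot(full_well > 0, rows >= 2, cols >= 2, t_int >= 0,
            first_order_edge_ratio > 0, first_order_edge_ratio <= 1)
  structure(list(t_int = t_int, weight_mode = weight_mode, rows = rows,
                 cols = cols, readout_khz = readout_khz,
                 zero_order_weight = zero_order_weight,
                 first_order_edge_ratio = first_order_edge_ratio,
                 total_weight = total_weight, slit_fwhm_cm1 = slit_fwhm_cm1,
                 signal_scale = signal_scale, full_well = full_well,
                 bias = bias, read_noise = read_noise,
                 cosmic_rate = cosmic_rate, fluor_scale = fluor_scale,
                 fluor_jitter = fluor_jitter,
                 dye_fluor_scale = dye_fluor_scale, mgf2 = mgf2,
                 mgf2_amp = mgf2_amp, max_col_offset = max_col_offset,
                 inject_saturation = inject_saturation),
            class = "acquisition_config")
}

# broad fluorescence emission shape: 4th-order polynomial in the scaled
# wavenumber, positive and slowly decreasing toward high wavenumbers
fluor_shape <- function(nu) {
  u <- (nu - 300) / 1600
  1.2 - 1.1 * u + 0.55 * u^2 - 0.25 * u^3 + 0.05 * u^4
}

fluor_class_factor <- function() {
  c(background = 0.1, bcc = 1.0, epidermis = 0.8, dermis = 0.6,
    fat = 0.5, dye = 1.0)
}

# 1st-order throughput falloff: quadratic in distance from the FOV center,
# reaching `edge_ratio` at the FOV corner
first_order_falloff <- function(dx, dy, geom, edge_ratio) {
  r_edge <- sqrt((geom$width / 2)^2 + (geom$height / 2)^2)
  r <- sqrt(dx^2 + dy^2)
  pmax(edge_ratio, 1 - (1 - edge_ratio) * (r / r_edge)^2)
}

beam_weights <- function(members, geom, cfg) {
  anch <- members[members$zero_order, ]
  if (cfg$weight_mode == "blazed") {
    return(rep(cfg$total_weight / nrow(members), nrow(members)))
  }
  w <- first_order_falloff(members$x_um - anch$x_um, members$y_um - anch$y_um,
                           geom, cfg$first_order_edge_ratio)
  w[members$zero_order] <- cfg$zero_order_weight
  w
}

# noise-free expected summed-track counts (both rows, bias excluded) for one
# beam; the independent forward model used by the simulator and, at
# identical arguments, by direct-summation test oracles
expected_beam_counts <- function(spec_vals, lib_axis, weight, cfg, calib,
                                 col_offset) {
  kern_sigma <- cfg$slit_fwhm_cm1 / (2 * sqrt(2 * log(2)))
  kx <- seq(-ceiling(4 * kern_sigma), ceiling(4 * kern_sigma))
  kern <- exp(-kx^2 / (2 * kern_sigma^2))
  kern <- kern / sum(kern)
  conv <- stats::convolve(spec_vals, rev(kern), type = "open")
  conv <- conv[(length(kx) - 1) / 2 + seq_along(spec_vals)]
  nu_cols <- wavenumber_at(calib, (seq_len(cfg$cols) - 1) - col_offset)
  s <- stats::approx(lib_axis, conv, xout = nu_cols, rule = 1)$y
  s[is.na(s)] <- 0
  cfg$signal_scale * weight * cfg$t_int * pmax(0, s)
}

#' Simulate one multifocal CCD frame
#'
#' Forward-simulates the detector image for one batch: each beam excites the
#' tissue class under its sampling point, whose basis spectrum (plus
#' fluorescence baseline, dye emission where the point is contaminated, and
#' the MgF2 substrate peak) is broadened by the pseudo-slit kernel, scaled
#' by beam weight x integration time, mapped to detector columns through the
#' wavenumber calibration with a per-beam dispersion offset, and written
#' into two adjacent CCD rows. Poisson shot noise, Gaussian read noise,
#' cosmic-ray spikes and full-well clipping are then applied.
#'
#' @param members One batch's member tibble (needs `x_um`, `y_um`,
#'   `zero_order`; at most `geom$batch_size` rows).
#' @param phantom A [render_phantom()] result.
#' @param lib A [build_spectral_library()] result.
#' @param cfg An [acquisition_config()].
#' @param calib A `calibration_model` (default [default_calibration()]).
#' @param geom A [fov_geometry()].
#' @param seed Integer seed.
#' @param noise Disable to get the deterministic noise-free expectation
#'   (plus bias).
#' @return `ccd_frame`: list with numeric `counts` matrix, `layout` tibble
#'   (beam_id, row1, row2, col_offset, x_um, y_um, zero_order, weight),
#'   `full_well`, `bias`, `seed`.
#' @export
simulate_ccd_frame <- function(members, phantom, lib, cfg = acquisition_config(),
                               calib = default_calibration(),
                               geom = fov_geometry(), seed = 1L,
                               noise = TRUE) {
  members <- tibble::as_tibble(members)
  if (nrow(members) > geom$batch_size) {
    stop("batch has more than ", geom$batch_size, " members")
  }
  if (!"zero_order" %in% names(members)) {
    members$origin <- if ("origin" %in% names(members)) members$origin else "af"
    members <- assign_zero_order(members)
  }
  # beams may overhang the section edge by up to one FOV (they then sample
  # bare substrate = background); farther out indicates a planning error
  w_img <- ncol(phantom$label) * phantom$pixel_size
  h_img <- nrow(phantom$label) * phantom$pixel_size
  outside <- members$x_um < -geom$width | members$x_um > w_img + geom$width |
    members$y_um < -geom$height | members$y_um > h_img + geom$height
  if (any(outside)) {
    stop("sampling point(s) ", paste(which(outside), collapse = ", "),
         " outside the phantom")
  }
  anch <- members[members$zero_order, ]
  yl <- members$y_um - anch$y_um + geom$height / 2   # FOV-local, 0..height
  xl <- members$x_um - anch$x_um                     # FOV-local, centered
  row1 <- round(yl / geom$height * (cfg$rows - 4)) + 1L
  row2 <- row1 + 1L
  occ <- cbind(row1, row2)
  for (i in seq_len(nrow(members))) for (j in seq_len(nrow(members))) {
    if (i < j && length(intersect(occ[i, ], occ[j, ])) > 0) {
      stop("CCD row collision between beams ", i, " and ", j)
    }
  }
  col_off <- round(xl / (geom$width / 2) * cfg$max_col_offset)
  weights <- beam_weights(members, geom, cfg)
  cls <- phantom_class_at(phantom, members$x_um, members$y_um)
  dye <- phantom_dye_at(phantom, members$x_um, members$y_um)
  axis <- lib$axis
  mg <- if (cfg$mgf2) {
    sg <- 6 / (2 * sqrt(2 * log(2)))
    cfg$mgf2_amp * exp(-(axis - 320)^2 / (2 * sg^2))
  } else 0
  counts <- matrix(0, cfg$rows, cfg$cols)
  expected <- matrix(0, nrow(members), cfg$cols)
  jit <- if (cfg$fluor_jitter > 0) {
    withr::with_seed(seed + 131L,
                     exp(stats::rnorm(nrow(members), 0, cfg$fluor_jitter)))
  } else rep(1, nrow(members))
  for (i in seq_len(nrow(members))) {
    s <- lib$basis[, cls[i]] + jit[i] *
      cfg$fluor_scale * fluor_class_factor()[[cls[i]]] * fluor_shape(axis) + mg
    if (dye[i]) s <- s + cfg$dye_fluor_scale * fluor_shape(axis)
    expected[i, ] <- expected_beam_counts(s, axis, weights[i], cfg, calib,
                                          col_off[i])
  }
  if (cfg$inject_saturation && nrow(members) > 0) {
    i <- which.max(apply(expected, 1, max))
    mx <- max(expected[i, ])
    if (mx > 0) expected[i, ] <- expected[i, ] * (2.4 * cfg$full_well / mx)
  }
  frame <- withr::with_seed(seed, {
    for (i in seq_len(nrow(members))) {
      lam <- expected[i, ] / 2
      for (r in c(row1[i], row2[i])) {
        if (noise) {
          counts[r, ] <- cfg$bias + stats::rpois(cfg$cols, lam) +
            stats::rnorm(cfg$cols, 0, cfg$read_noise)
        } else {
          counts[r, ] <- cfg$bias + lam
        }
      }
    }
    if (noise && cfg$read_noise > 0) {
      idle <- setdiff(seq_len(cfg$rows), c(row1, row2))
      counts[idle, ] <- cfg$bias +
        stats::rnorm(length(idle) * cfg$cols, 0, cfg$read_noise)
    } else {
      idle <- setdiff(seq_len(cfg$rows), c(row1, row2))
      counts[idle, ] <- cfg$bias
    }
    if (noise && cfg$cosmic_rate > 0) {
      ncr <- stats::rpois(1, cfg$cosmic_rate)
      if (ncr > 0) {
        rr <- sample.int(cfg$rows, ncr, replace = TRUE)
        cc <- sample.int(cfg$cols, ncr, replace = TRUE)
        counts[cbind(rr, cc)] <- counts[cbind(rr, cc)] +
          stats::runif(ncr, 0.2, 1) * cfg$full_well
      }
    }
    counts
  })
  frame <- pmin(pmax(frame, 0), cfg$full_well)
  layout <- tibble::tibble(beam_id = seq_len(nrow(members)),
                           row1 = row1, row2 = row2, col_offset = col_off,
                           x_um = members$x_um, y_um = members$y_um,
                           zero_order = members$zero_order, weight = weights,
                           class = cls)
  structure(list(counts = frame, layout = layout, full_well = cfg$full_well,
                 bias = cfg$bias, seed = seed),
            class = "ccd_frame")
}

#' @export
print.ccd_frame <- function(x, ...) {
  cat("<ccd_frame> ", nrow(x$counts), "x", ncol(x$counts), " px, ",
      nrow(x$layout), " beams, max ", round(max(x$counts)), " counts\n",
      sep = "")
  invisible(x)
}
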