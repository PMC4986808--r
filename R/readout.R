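#' Fit the wavenumber calibration from reference peaks
#'
#' Least-squares cubic mapping detector column (0-based) to relative
#' wavenumber, fitted on reference peaks — by default the five polystyrene
#' fingerprint bands measured with the 0th-order beam. The fit must be
#' strictly monotone over the detector width.
#'
#' @param peak_pixels Peak positions (detector columns, 0-based); >= 4.
#' @param peak_wavenumbers Corresponding reference wavenumbers (cm^-1).
#' @param cols Detector width (monotonicity checked over 0..cols-1).
#' @return `calibration_model`: coefficients (intercept, linear, quadratic,
#'   cubic), `residual_rms`, `peaks` tibble.
#' @export
calibrate_axis <- function(peak_pixels, peak_wavenumbers, cols = 1024) {
  if (length(peak_pixels) < 4) {
    stop("need at least 4 reference peaks for a cubic calibration")
  }
  stopifnot(length(peak_pixels) == length(peak_wavenumbers))
  if (any(peak_pixels < 0 | peak_pixels > cols - 1)) {
    stop("reference peak pixel outside the detector")
  }
  X <- stats::poly(peak_pixels, degree = 3, raw = TRUE)
  fit <- stats::lm(peak_wavenumbers ~ X)
  beta <- unname(stats::coef(fit))
  model <- new_calibration(beta, cols = cols,
                           peaks = tibble::tibble(pixel = peak_pixels,
                                                  wavenumber = peak_wavenumbers),
                           residual_rms = sqrt(mean(stats::residuals(fit)^2)))
  model
}

new_calibration <- function(beta, cols = 1024, peaks = NULL,
                            residual_rms = 0) {
  grid <- 0:(cols - 1)
  d <- beta[2] + 2 * beta[3] * grid + 3 * beta[4] * grid^2
  if (any(d <= 0)) {
    bad <- range(grid[d <= 0])
    stop("calibration not monotone over columns ", bad[1], "-", bad[2])
  }
  structure(list(coefficients = beta, cols = cols, peaks = peaks,
                 residual_rms = residual_rms),
            class = "calibration_model")
}

#' Wavenumber at detector columns
#' @param calib A `calibration_model`.
#' @param cols 0-based column positions (may be fractional).
#' @return Wavenumbers (cm^-1).
#' @export
wavenumber_at <- function(calib, cols) {
  b <- calib$coefficients
  b[1] + b[2] * cols + b[3] * cols^2 + b[4] * cols^3
}

#' Default instrument calibration
#'
#' A representative cubic dispersion model spanning roughly 240-1900 cm^-1
#' over the 1024-column detector.
#' @param cols Detector width.
#' @return `calibration_model`.
#' @export
default_calibration <- function(cols = 1024) {
  new_calibration(c(240, 1.75, -1.2e-4, 2e-8), cols = cols)
}

#' Conventional polystyrene reference peaks
#'
#' The five fingerprint-region polystyrene bands used for wavenumber
#' calibration (cm^-1). These are configuration, not canon — override them
#' if your reference standard differs.
#' @return Numeric vector of 5 wavenumbers.
#' @export
polystyrene_peaks <- function() c(620.9, 1001.4, 1031.8, 1155.3, 1583.1)

#' @export
print.calibration_model <- function(x, ...) {
  cat("<calibration_model> nu(c) = ",
      paste(signif(x$coefficients, 6), collapse = " + "),
      " (powers of column); residual RMS ", signif(x$residual_rms, 4),
      " cm^-1\n", sep = "")
  invisible(x)
}

#' Extract per-beam track spectra from a CCD frame
#'
#' For each beam, sums its two CCD rows and shifts by the beam's
#' dispersion-direction column offset so all beams share the 0th-order
#' column frame. Raw per-track vectors are retained for cosmic-ray removal
#' and the raw maximum for saturation QC.
#'
#' @param frame A [simulate_ccd_frame()] result (or compatible list).
#' @param layout Track layout tibble (default `frame$layout`): `beam_id`,
#'   `row1`, `row2`, `col_offset`.
#' @return Spectra tibble: one row per beam with metadata columns and
#'   list-columns `pixel` (0-based aligned columns), `intensity`,
#'   `track_a`, `track_b`.
#' @export
extract_tracks <- function(frame, layout = frame$layout) {
  counts <- frame$counts
  if (any(layout$row1 < 1 | layout$row2 > nrow(counts))) {
    stop("track layout row outside the frame")
  }
  rows_used <- c(layout$row1, layout$row2)
  if (anyDuplicated(rows_used) > 0) stop("track row pairs are not disjoint")
  nc <- ncol(counts)
  res <- lapply(seq_len(nrow(layout)), function(i) {
    a <- counts[layout$row1[i], ]
    b <- counts[layout$row2[i], ]
    off <- layout$col_offset[i]
    # column c of the track corresponds to aligned (0th-order frame)
    # column c - off; shift so index = aligned column
    src <- seq_len(nc) + off
    ok <- src >= 1 & src <= nc
    aa <- rep(NA_real_, nc); bb <- rep(NA_real_, nc)
    aa[ok] <- a[src[ok]]; bb[ok] <- b[src[ok]]
    tibble::tibble(pixel = list(0:(nc - 1)), track_a = list(aa),
                   track_b = list(bb), intensity = list(aa + bb),
                   raw_max = max(c(a, b)))
  })
  out <- dplyr::bind_cols(layout, dplyr::bind_rows(res))
  out$saturated <- FALSE
  out$no_substrate_peak <- FALSE
  out$cosmic_corrected <- FALSE
  tibble::as_tibble(out)
}

#' Apply the wavenumber calibration to extracted spectra
#'
#' @param spectra An [extract_tracks()] tibble.
#' @param calib A `calibration_model`.
#' @return The tibble with a `wavenumber` list-column.
#' @export
apply_calibration <- function(spectra, calib) {
  spectra$wavenumber <- lapply(spectra$pixel, function(p)
    wavenumber_at(calib, p))
  spectra
}

#' Remove cosmic rays by two-track comparison
#'
#' A cosmic-ray spike hits one track but (almost always) not the other, so
#' pixels where the two tracks disagree beyond `k` times the expected
#' shot-plus-read noise are replaced in the summed spectrum by twice the
#' lower track. Spikes that happen to coincide on both tracks are caught by
#' a 5-point rolling-median fallback on the sum. Spike-free input is
#' returned unchanged.
#'
#' @param spectra An [extract_tracks()] tibble.
#' @param read_noise Read noise per track (counts RMS).
#' @param k Detection threshold in noise sigmas.
#' @return The tibble with cleaned `intensity` and updated
#'   `cosmic_corrected` flags.
#' @export
remove_cosmic_rays <- function(spectra, read_noise = 5, k = 6) {
  cleaned <- lapply(seq_len(nrow(spectra)), function(i) {
    despike_tracks(spectra$track_a[[i]], spectra$track_b[[i]],
                   read_noise = read_noise, k = k)
  })
  spectra$intensity <- lapply(cleaned, `[[`, "intensity")
  spectra$cosmic_corrected <- vapply(cleaned, `[[`, logical(1), "corrected")
  spectra
}

despike_tracks <- function(a, b, read_noise = 5, k = 6) {
  s <- a + b
  ok <- !is.na(a) & !is.na(b)
  sigma <- sqrt(pmax(a + b, 0) + 2 * read_noise^2)
  hit <- ok & abs(a - b) > k * sigma
  s[hit] <- 2 * pmin(a[hit], b[hit])
  med <- stats::runmed(ifelse(is.na(s), 0, s), 5, endrule = "median")
  resid_sigma <- sqrt(pmax(med, 0) + 4 * read_noise^2)
  coin <- ok & (s - med) > k * resid_sigma & !hit
  s[coin] <- med[coin]
  list(intensity = s, corrected = any(hit) || any(coin))
}

#' Correct the per-beam wavenumber shift using the MgF2 substrate peak
#'
#' Locates the substrate Raman peak near 320 cm^-1 by quadratic sub-bin
#' interpolation of the local maximum and translates the axis so the peak
#' sits exactly at 320 cm^-1. Beams without a sufficiently prominent peak
#' in the window are flagged `no_substrate_peak` and left unshifted.
#'
#' @param spectra A calibrated spectra tibble (with `wavenumber`).
#' @param center Substrate peak reference position (cm^-1).
#' @param half_window Search half-width (cm^-1).
#' @param prominence Minimum peak prominence in MAD units of the window.
#' @return The tibble with shifted `wavenumber` and a `shift_cm1` column.
#' @export
correct_shift_mgf2 <- function(spectra, center = 320, half_window = 30,
                               prominence = 5) {
  shifts <- numeric(nrow(spectra))
  flags <- logical(nrow(spectra))
  for (i in seq_len(nrow(spectra))) {
    nu <- spectra$wavenumber[[i]]
    y <- spectra$intensity[[i]]
    sel <- which(!is.na(y) & nu >= center - half_window &
                   nu <= center + half_window)
    if (length(sel) < 5) { flags[i] <- TRUE; next }
    yy <- y[sel]; xx <- nu[sel]
    n <- length(yy)
    # remove the local fluorescence slope before testing prominence
    xa <- mean(xx[1:3]); ya <- mean(yy[1:3])
    xb <- mean(xx[(n - 2):n]); yb <- mean(yy[(n - 2):n])
    rr <- yy - (ya + (xx - xa) * (yb - ya) / (xb - xa))
    pk <- which.max(rr)
    away <- abs(xx - xx[pk]) > half_window / 2
    scale <- if (sum(away) >= 4) stats::mad(rr[away]) else stats::mad(rr)
    if (scale == 0 || rr[pk] < prominence * scale || pk == 1 || pk == n) {
      flags[i] <- TRUE
      next
    }
    yy <- rr
    # quadratic interpolation through the peak and its neighbors
    y0 <- yy[pk - 1]; y1 <- yy[pk]; y2 <- yy[pk + 1]
    denom <- y0 - 2 * y1 + y2
    d <- if (denom == 0) 0 else 0.5 * (y0 - y2) / denom
    step <- (xx[pk + 1] - xx[pk - 1]) / 2
    peak_nu <- xx[pk] + d * step
    shifts[i] <- peak_nu - center
    spectra$wavenumber[[i]] <- nu - shifts[i]
  }
  spectra$shift_cm1 <- shifts
  spectra$no_substrate_peak <- flags
  spectra
}

#' Crop spectra to a wavenumber range on a shared grid
#'
#' Keeps `lo <= nu <= hi` and resamples (linear interpolation) onto the
#' shared 1 cm^-1 grid, so every beam has an identical axis regardless of
#' its dispersion offset.
#'
#' @param spectra A calibrated spectra tibble.
#' @param lo,hi Range bounds (cm^-1). Storage range 520-1830 by default;
#'   use 600-1800 for classification.
#' @return The tibble with `wavenumber`/`intensity` on the common grid.
#' @export
crop_range <- function(spectra, lo = 520, hi = 1830) {
  grid <- seq(lo, hi, by = 1)
  for (i in seq_len(nrow(spectra))) {
    nu <- spectra$wavenumber[[i]]
    y <- spectra$intensity[[i]]
    ok <- !is.na(y)
    if (!any(ok) || min(nu[ok]) > lo || max(nu[ok]) < hi) {
      stop("beam ", i, " axis does not cover ", lo, "-", hi, " cm^-1")
    }
    spectra$wavenumber[[i]] <- grid
    spectra$intensity[[i]] <- stats::approx(nu[ok], y[ok], xout = grid)$y
  }
  spectra$pixel <- NULL
  spectra
}

#' Standard normal variate normalization
#'
#' Rescales every spectrum to zero mean and unit standard deviation.
#'
#' @param spectra A spectra tibble.
#' @return The tibble with normalized `intensity`.
#' @export
snv_normalize <- function(spectra) {
  spectra$intensity <- lapply(spectra$intensity, function(y) {
    s <- stats::sd(y)
    if (!is.finite(s) || s == 0) {
      stop("cannot SNV-normalize a constant spectrum")
    }
    (y - mean(y)) / s
  })
  spectra
}

#' Flag saturated spectra
#'
#' A spectrum is flagged when any raw count on either of its tracks reached
#' the detector full well; flagged spectra are excluded downstream.
#'
#' @param spectra An [extract_tracks()] tibble (carries `raw_max`).
#' @param full_well Saturation level (counts).
#' @return The tibble with the `saturated` flag set.
#' @export
qc_saturation <- function(spectra, full_well) {
  spectra$saturated <- spectra$raw_max >= full_well
  spectra
}

#' Signal-to-noise ratio of a spectrum
#'
#' Signal: baseline-subtracted maximum of the 1450 cm^-1 CH-deformation
#' band (window 1440-1460, local linear baseline through the mean of the 3
#' samples at each window edge). Noise: RMS of the linearly detrended
#' 1490-1510 cm^-1 region. A zero-noise spectrum reports +Inf.
#'
#' @param spectra A spectra tibble on a wavenumber axis.
#' @return The tibble with an `snr` column.
#' @export
compute_snr <- function(spectra) {
  spectra$snr <- vapply(seq_len(nrow(spectra)), function(i) {
    snr_one(spectra$wavenumber[[i]], spectra$intensity[[i]])
  }, numeric(1))
  spectra
}

snr_one <- function(nu, y) {
  sig_idx <- which(nu >= 1440 & nu <= 1460)
  noi_idx <- which(nu >= 1490 & nu <= 1510)
  if (length(sig_idx) < 7 || length(noi_idx) < 5) {
    stop("axis does not cover the SNR signal/noise windows")
  }
  ys <- y[sig_idx]; xs <- nu[sig_idx]
  n <- length(ys)
  xa <- mean(xs[1:3]); ya <- mean(ys[1:3])
  xb <- mean(xs[(n - 2):n]); yb <- mean(ys[(n - 2):n])
  base <- ya + (xs - xa) * (yb - ya) / (xb - xa)
  signal <- max(ys - base)
  yn <- y[noi_idx]; xn <- nu[noi_idx]
  fit <- stats::lm.fit(cbind(1, xn), yn)
  noise <- sqrt(mean(fit$residuals^2))
  if (noise <= 1e-10 * (abs(signal) + 1)) return(Inf)
  signal / noise
}

#' Full preprocessing chain for one simulated frame
#'
#' extract -> cosmic-ray removal -> calibrate -> substrate-shift correction
#' -> crop -> saturation QC -> SNV, in the acquisition order used on the
#' instrument.
#'
#' @param frame A [simulate_ccd_frame()] result.
#' @param calib A `calibration_model`.
#' @param cfg The [acquisition_config()] used (for full well / read noise).
#' @param lo,hi Stored spectral range (cm^-1).
#' @return Preprocessed spectra tibble with `snr` computed on the
#'   pre-normalization (count-scale) spectra.
#' @export
preprocess_frame <- function(frame, calib = default_calibration(),
                             cfg = acquisition_config(), lo = 520, hi = 1830) {
  frame |>
    extract_tracks() |>
    remove_cosmic_rays(read_noise = cfg$read_noise) |>
    apply_calibration(calib) |>
    correct_shift_mgf2() |>
    crop_range(lo = lo, hi = hi) |>
    qc_saturation(full_well = cfg$full_well) |>
    compute_snr() |>
    snv_normalize()
}
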