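make_frame <- function(counts, layout) {
  structure(list(counts = counts, layout = layout, full_well = 65535,
                 bias = 0, seed = 0L), class = "ccd_frame")
}

test_that("track extraction sums the two rows of each beam", {
  counts <- matrix(0, 16, 32)
  counts[5, ] <- 7; counts[6, ] <- 7
  lay <- tibble::tibble(beam_id = 1L, row1 = 5L, row2 = 6L, col_offset = 0L)
  sp <- extract_tracks(make_frame(counts, lay))
  expect_true(all(sp$intensity[[1]] == 14))
  # random frame vs brute-force row sums, with a dispersion offset
  set.seed(1)
  rc <- matrix(rpois(16 * 32, 50), 16, 32)
  lay2 <- tibble::tibble(beam_id = 1:2, row1 = c(3L, 9L), row2 = c(4L, 10L),
                         col_offset = c(0L, 2L))
  sp2 <- extract_tracks(make_frame(rc, lay2))
  expect_equal(sp2$intensity[[1]], rc[3, ] + rc[4, ])
  want <- c((rc[9, ] + rc[10, ])[3:32], NA, NA)
  expect_equal(sp2$intensity[[2]], want)
  # out-of-frame layout errors
  bad <- tibble::tibble(beam_id = 1L, row1 = 16L, row2 = 17L,
                        col_offset = 0L)
  expect_error(extract_tracks(make_frame(rc, bad)), "outside the frame")
})

test_that("cubic calibration recovers a noiseless cubic exactly", {
  beta <- c(240, 1.75, -1.2e-4, 2e-8)
  px <- c(50, 300, 500, 700, 950)
  nu <- beta[1] + beta[2] * px + beta[3] * px^2 + beta[4] * px^3
  cal <- calibrate_axis(px, nu)
  expect_equal(cal$coefficients, beta, tolerance = 1e-9)
  expect_lt(cal$residual_rms, 1e-9)
  expect_error(calibrate_axis(px[1:3], nu[1:3]), "at least 4")
})

test_that("noisy calibration matches the normal-equations oracle", {
  set.seed(2)
  beta <- c(250, 1.7, -1e-4, 1e-8)
  px <- c(50, 300, 500, 700, 950) + rnorm(5, 0, 0.2)
  nu <- polystyrene_peaks()
  cal <- calibrate_axis(px, nu)
  X <- cbind(1, px, px^2, px^3)
  want <- qr.coef(qr(X), nu)   # least-squares oracle via QR
  expect_equal(cal$coefficients, as.vector(want), tolerance = 1e-6)
})

test_that("non-monotone calibrations are rejected", {
  # exact cubic whose derivative goes negative mid-detector
  beta <- c(240, 3, -0.006, 2.4e-6)
  px <- c(50, 300, 500, 700, 950)
  nu <- beta[1] + beta[2] * px + beta[3] * px^2 + beta[4] * px^3
  expect_error(calibrate_axis(px, nu), "not monotone")
})

test_that("substrate-peak shift is recovered to within half a bin", {
  ph <- test_phantom(seed = 1)
  cfg <- acquisition_config(cosmic_rate = 0)
  fr <- simulate_ccd_frame(fat_batch(), ph, test_lib, cfg, seed = 3,
                           noise = FALSE)
  sp <- fr |> extract_tracks() |> apply_calibration(default_calibration())
  # remove the instrumental quantization residual first
  sp0 <- correct_shift_mgf2(sp)
  expect_true(all(!sp0$no_substrate_peak))
  # now displace by +6 cm^-1 and recover
  sp0$wavenumber <- lapply(sp0$wavenumber, function(nu) nu + 6)
  sp6 <- correct_shift_mgf2(sp0)
  half_bin <- 1.75 / 2  # detector column pitch in cm^-1 near 320
  expect_true(all(abs(sp6$shift_cm1 - 6) <= half_bin))
  # peak already at 320: shift ~0
  sp00 <- correct_shift_mgf2(sp0 |> dplyr::mutate(
    wavenumber = lapply(wavenumber, function(nu) nu - 6)))
  expect_true(all(abs(sp00$shift_cm1) <= half_bin))
})

test_that("flat spectra are flagged no-substrate-peak and left unshifted", {
  flat <- tibble::tibble(beam_id = 1L,
                         wavenumber = list(seq(250, 500)),
                         intensity = list(rep(5, 251)))
  out <- correct_shift_mgf2(flat)
  expect_true(out$no_substrate_peak)
  expect_equal(out$wavenumber[[1]], flat$wavenumber[[1]])
})

test_that("cropping yields the shared 1 cm^-1 grid regardless of offsets", {
  mk <- function(shift) tibble::tibble(
    beam_id = 1L, wavenumber = list(seq(300, 1900) + shift),
    intensity = list(sin(seq(300, 1900) / 50) + 2))
  a <- crop_range(mk(0))
  expect_length(a$wavenumber[[1]], 1311)
  b <- crop_range(mk(8)); c2 <- crop_range(mk(-8))
  expect_identical(b$wavenumber[[1]], c2$wavenumber[[1]])
  expect_identical(b$wavenumber[[1]], seq(520, 1830, by = 1))
  low <- tibble::tibble(beam_id = 1L, wavenumber = list(seq(100, 500)),
                        intensity = list(rep(1, 401)))
  expect_error(crop_range(low), "does not cover")
})

test_that("spike-free tracks pass through cosmic-ray removal unchanged", {
  set.seed(3)
  a <- rpois(200, 400); b <- rpois(200, 400)
  out <- ramanmsi:::despike_tracks(a, b)
  expect_equal(out$intensity, a + b)
  expect_false(out$corrected)
})

test_that("a large single-track spike is removed with <2% band-area impact", {
  nu <- seq(520, 1830)
  shape <- 300 + 200 * exp(-(nu - 1450)^2 / (2 * 25))
  set.seed(4)
  a <- rpois(length(nu), shape); b <- rpois(length(nu), shape)
  # 1450-band area with the same local linear baseline rule
  area1450 <- function(y) {
    idx <- which(nu >= 1430 & nu <= 1470)
    xs <- nu[idx]; ys <- y[idx]; n <- length(ys)
    base <- mean(ys[1:3]) + (xs - mean(xs[1:3])) *
      (mean(ys[(n - 2):n]) - mean(ys[1:3])) /
      (mean(xs[(n - 2):n]) - mean(xs[1:3]))
    sum(diff(xs) * ((ys - base)[-1] + (ys - base)[-n]) / 2)
  }
  clean <- area1450(a + b)
  a_sp <- a
  hit <- which(nu == 1460)   # spike inside the band window, one track only
  a_sp[hit] <- a_sp[hit] + 1e4
  out <- ramanmsi:::despike_tracks(a_sp, b)
  expect_true(out$corrected)
  expect_lt(abs(out$intensity[hit] - (a + b)[hit]), 100)
  expect_lt(abs(area1450(out$intensity) - clean) / abs(clean), 0.02)
})

test_that("coincident spikes on both tracks fall to the median fallback", {
  nu <- seq(520, 1830)
  set.seed(5)
  a <- rpois(length(nu), 400); b <- rpois(length(nu), 400)
  hit <- 600
  a2 <- a; b2 <- b
  a2[hit] <- a2[hit] + 2e4; b2[hit] <- b2[hit] + 2e4
  out <- ramanmsi:::despike_tracks(a2, b2)
  expect_true(out$corrected)
  expect_lt(abs(out$intensity[hit] - (a + b)[hit]), 200)
})

test_that("SNV yields exactly zero mean and unit SD, and is affine-invariant", {
  sp <- tibble::tibble(beam_id = 1L, wavenumber = list(seq(600, 1800)),
                       intensity = list(sin(seq(600, 1800) / 90)))
  out <- snv_normalize(sp)
  expect_lt(abs(mean(out$intensity[[1]])), 1e-12)
  expect_equal(sd(out$intensity[[1]]), 1, tolerance = 1e-12)
  aff <- sp
  aff$intensity <- list(3.2 * sp$intensity[[1]] + 17)
  expect_equal(snv_normalize(aff)$intensity[[1]], out$intensity[[1]],
               tolerance = 1e-12)
  cst <- tibble::tibble(beam_id = 1L, wavenumber = list(1:10),
                        intensity = list(rep(4, 10)))
  expect_error(snv_normalize(cst), "constant")
})

test_that("saturation QC flags exactly the beams that hit full well", {
  sp <- tibble::tibble(beam_id = 1:3, raw_max = c(65535, 65534, 70000))
  out <- qc_saturation(sp, 65535)
  expect_equal(out$saturated, c(TRUE, FALSE, TRUE))
  # simulated saturating batch matches a per-pixel oracle scan
  ph <- test_phantom(seed = 1)
  cfg <- acquisition_config(inject_saturation = TRUE)
  fr <- simulate_ccd_frame(fat_batch(), ph, test_lib, cfg, seed = 9)
  sp2 <- qc_saturation(extract_tracks(fr), cfg$full_well)
  oracle <- vapply(seq_len(nrow(fr$layout)), function(i)
    max(fr$counts[c(fr$layout$row1[i], fr$layout$row2[i]), ]) >=
      cfg$full_well, logical(1))
  expect_equal(sp2$saturated, oracle)
})

test_that("SNR estimates height/sigma for a synthetic band plus noise", {
  nu <- seq(600, 1800)
  band <- 50 * exp(-(nu - 1450)^2 / (2 * (12 / 2.3548)^2))
  # noiseless: +Inf sentinel
  clean <- tibble::tibble(beam_id = 1L, wavenumber = list(nu),
                          intensity = list(band))
  expect_equal(compute_snr(clean)$snr, Inf)
  # Monte-Carlo: mean SNR ~ h/sigma within 15%
  set.seed(6)
  h <- 50; sigma <- 5
  snrs <- vapply(1:100, function(i) {
    y <- band + rnorm(length(nu), 0, sigma)
    ramanmsi:::snr_one(nu, y)
  }, numeric(1))
  expect_equal(mean(snrs), h / sigma, tolerance = 0.15)
  # pure noise: positive, small
  pn <- vapply(1:50, function(i)
    ramanmsi:::snr_one(nu, rnorm(length(nu), 0, sigma)), numeric(1))
  expect_true(all(pn > 0))
  expect_lt(mean(pn), 5)
})

test_that("full preprocessing chain is deterministic on a fixed frame", {
  ph <- test_phantom(seed = 1)
  cfg <- acquisition_config()
  fr <- simulate_ccd_frame(fat_batch(), ph, test_lib, cfg, seed = 11)
  a <- preprocess_frame(fr, cfg = cfg)
  b <- preprocess_frame(fr, cfg = cfg)
  expect_identical(a$intensity, b$intensity)
  expect_identical(a$wavenumber, b$wavenumber)
})
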