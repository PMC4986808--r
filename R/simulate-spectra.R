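#' Simulate labelled training spectra
#'
#' Draws per-class spectra directly at the detector count scale — basis
#' spectrum plus fluorescence baseline, slit broadening, Poisson shot noise
#' and Gaussian read noise — then crops to the classification range and
#' SNV-normalizes. This is the generator used to build band-ratio training
#' sets that emulate the raster-scan reference measurements.
#'
#' @param n_per_class Spectra per class.
#' @param classes Classes to draw (default the three model classes).
#' @param lib A [build_spectral_library()] result.
#' @param cfg An [acquisition_config()] (count scale, broadening, noise).
#' @param weight Beam throughput weight per spectrum (default one
#'   single-beam-equivalent unit).
#' @param lo,hi Classification range (cm^-1).
#' @param seed Integer seed.
#' @return Spectra tibble: `class`, `wavenumber`, `intensity` list-columns,
#'   `saturated` (FALSE), ready for [band_features()].
#' @export
simulate_labelled_spectra <- function(n_per_class = 100,
                                      classes = c("bcc", "epidermis", "dermis"),
                                      lib = build_spectral_library(),
                                      cfg = acquisition_config(),
                                      weight = 1, lo = 600, hi = 1800,
                                      seed = 1L) {
  axis <- lib$axis
  grid <- seq(lo, hi, by = 1)
  kern_sigma <- cfg$slit_fwhm_cm1 / (2 * sqrt(2 * log(2)))
  kx <- seq(-ceiling(4 * kern_sigma), ceiling(4 * kern_sigma))
  kern <- exp(-kx^2 / (2 * kern_sigma^2)); kern <- kern / sum(kern)
  scale <- cfg$signal_scale * weight * cfg$t_int
  withr::with_seed(seed, {
    rows <- lapply(classes, function(cl) {
      base <- lib$basis[, cl]
      fl <- cfg$fluor_scale * fluor_class_factor()[[cl]] * fluor_shape(axis)
      smooth <- function(v) {
        cv <- stats::convolve(v, rev(kern), type = "open")
        cv <- cv[(length(kx) - 1) / 2 + seq_along(v)]
        pmax(0, stats::approx(axis, cv, xout = grid)$y)
      }
      lam_base <- scale * smooth(base)
      lam_fl <- scale * smooth(fl)
      lapply(seq_len(n_per_class), function(i) {
        jit <- exp(stats::rnorm(1, 0, cfg$fluor_jitter))
        lam <- lam_base + jit * lam_fl
        y <- stats::rpois(length(grid), lam) +
          stats::rnorm(length(grid), 0, sqrt(2) * cfg$read_noise)
        y <- (y - mean(y)) / stats::sd(y)
        tibble::tibble(class = cl, wavenumber = list(grid),
                       intensity = list(y), saturated = FALSE)
      })
    })
    dplyr::bind_rows(unlist(rows, recursive = FALSE))
  })
}

#' Simulate a labelled band-ratio feature table
#'
#' Convenience wrapper: [simulate_labelled_spectra()] followed by
#' [band_features()], returning one feature row per spectrum.
#'
#' @inheritParams simulate_labelled_spectra
#' @return Tibble with `class`, A1..A7, r1..r5.
#' @export
simulate_labelled_features <- function(n_per_class = 100,
                                       classes = c("bcc", "epidermis",
                                                   "dermis"),
                                       lib = build_spectral_library(),
                                       cfg = acquisition_config(),
                                       weight = 1, seed = 1L) {
  sp <- simulate_labelled_spectra(n_per_class, classes, lib, cfg,
                                  weight = weight, seed = seed)
  band_features(sp) |>
    dplyr::select(-dplyr::any_of(c("wavenumber", "intensity")))
}

#' Simulate spatially isolated sampling-point clusters
#'
#' Generates `n_clusters` well-separated clusters on a coarse grid (400 um
#' pitch), each fitting inside one FOV placement: members are stacked at
#' exactly the minimum vertical separation (so every cluster can be padded
#' to a full batch) with uniform horizontal jitter. Cluster sizes are a
#' seeded permutation of a fixed size profile summing to `n_points`. This
#' emulates the sparse, fragmented point sets that AF-guided sampling
#' produces on real tissue, where most batches contain only a few genuine
#' points and are padded with random fills.
#'
#' @param n_clusters Number of clusters (default 318).
#' @param n_points Total points (default 794); must be representable as
#'   sizes between 1 and 6 over `n_clusters`.
#' @param min_sep Vertical spacing within a cluster (um).
#' @param seed Integer seed.
#' @return Tibble of sampling points (`x_um`, `y_um`).
#' @export
simulate_isolated_clusters <- function(n_clusters = 318, n_points = 794,
                                       min_sep = 10, seed = 1L) {
  stopifnot(n_points >= n_clusters, n_points <= 6 * n_clusters)
  sizes <- rep(n_points %/% n_clusters, n_clusters)
  extra <- n_points - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  side <- ceiling(sqrt(n_clusters))
  grid <- expand.grid(gx = seq_len(side) - 1, gy = seq_len(side) - 1)
  grid <- grid[seq_len(n_clusters), ]
  withr::with_seed(seed, {
    sizes <- sample(sizes)
    dplyr::bind_rows(lapply(seq_len(n_clusters), function(i) {
      n <- sizes[i]
      tibble::tibble(
        x_um = grid$gx[i] * 400 + 200 + stats::runif(n, -40, 40),
        y_um = grid$gy[i] * 400 + 200 + (seq_len(n) - 1) * min_sep)
    }))
  })
}
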