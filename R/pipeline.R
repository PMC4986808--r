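#' Default end-to-end demo configuration
#'
#' A small tissue phantom (800 x 600 um at 5 um/px): a dermis block with an
#' epidermis strip along the top edge, a BCC nodule and a sebaceous/fat
#' lobule, AF-segmented and sampled at a density giving a handful of
#' batches. All stages use defaults; every stochastic stage derives its
#' stream from the single `seed`.
#'
#' @param seed Global seed.
#' @return Named list understood by [run_end_to_end()].
#' @export
default_run_config <- function(seed = 1L) {
  layout <- dplyr::bind_rows(
    phantom_region("dermis", "rect", x = 400, y = 330, rx = 380, ry = 250),
    phantom_region("epidermis", "rect", x = 400, y = 120, rx = 380, ry = 40),
    phantom_region("bcc", "disk", x = 250, y = 340, rx = 90, ry = 75),
    phantom_region("fat", "disk", x = 580, y = 420, rx = 80, ry = 65))
  list(
    seed = seed,
    phantom = list(layout = layout, width_um = 800, height_um = 600,
                   pixel_size = 5, dye_fraction = 0),
    segmentation = list(n_levels = 3, min_area = 40),
    sampling = list(density = 120, min_per_segment = 4,
                    priority_exponent = 1),
    geometry = list(width = 180, height = 60, min_sep = 10, batch_size = 6),
    acquisition = list(t_int = 2, weight_mode = "blazed"),
    store_range = c(520, 1830), classify_range = c(600, 1800),
    training = list(n_per_class = 200, folds = 5, target_sensitivity = 0.95)
  )
}

#' Run the full MSI pipeline on a synthetic phantom
#'
#' Executes every stage in acquisition order: phantom rendering, AF
#' segmentation, sampling-point generation, batch planning, per-batch CCD
#' simulation, spectral preprocessing, PCA screening, classifier training
#' on library-derived synthetic features, segment-averaged diagnosis, and
#' comparison against the phantom ground truth. Intermediate artifacts are
#' written under `outdir` when given.
#'
#' @param config A configuration list (see [default_run_config()]).
#' @param outdir Optional output directory for artifacts.
#' @param verbose Emit per-stage messages.
#' @return Manifest list: counts, per-batch SNR summary, acquisition-time
#'   estimate, per-segment calls, confusion matrix and accuracy, artifact
#'   paths.
#' @export
run_end_to_end <- function(config = default_run_config(), outdir = NULL,
                           verbose = FALSE) {
  say <- function(...) if (verbose) message("[ramanmsi] ", ...)
  seed <- as.integer(config$seed)
  paths <- list()

  say("stage 1/8: spectral library + phantom")
  lib <- build_spectral_library()
  ph <- config$phantom
  phantom <- render_phantom(ph$layout, ph$width_um, ph$height_um,
                            pixel_size = ph$pixel_size, seed = seed,
                            dye_fraction = ph$dye_fraction %||% 0)
  say("stage 2/8: AF segmentation")
  seg <- segment_af_image(phantom$af, n_levels = config$segmentation$n_levels,
                          min_area = config$segmentation$min_area,
                          pixel_size = phantom$pixel_size)
  say("stage 3/8: sampling points")
  pts <- generate_sampling_points(
    seg, density = config$sampling$density,
    min_per_segment = config$sampling$min_per_segment,
    priority_exponent = config$sampling$priority_exponent, seed = seed + 1L)
  if (!is.null(config$landmarks)) {
    tf <- fit_coordinate_transform(config$landmarks)
    pts <- apply_transform(tf, pts)
  }
  say("stage 4/8: batch planning (", nrow(pts), " AF points)")
  geom <- do.call(fov_geometry, config$geometry)
  plan <- plan_batches(pts, geom, seed = seed + 2L,
                       bounds = list(xlim = c(0, ph$width_um),
                                     ylim = c(0, ph$height_um)))

  say("stage 5/8: CCD simulation + preprocessing (",
      plan$counts$n_batches, " batches)")
  acq <- config$acquisition
  cfg <- acquisition_config(t_int = acq$t_int %||% 2,
                            weight_mode = acq$weight_mode %||% "blazed")
  calib <- default_calibration()
  sr <- config$store_range
  spectra <- dplyr::bind_rows(lapply(seq_len(plan$counts$n_batches),
                                     function(b) {
    mem <- plan$members[plan$members$batch_id == b, ]
    frame <- simulate_ccd_frame(mem, phantom, lib, cfg, calib, geom,
                                seed = seed + 100L + b)
    sp <- preprocess_frame(frame, calib, cfg, lo = sr[1], hi = sr[2])
    sp$batch_id <- b
    sp$segment_id <- mem$segment_id
    sp$origin <- mem$origin
    sp
  }))

  say("stage 6/8: QC + PCA screen")
  tissue <- spectra[!is.na(spectra$segment_id) & !spectra$saturated &
                      !vapply(spectra$intensity, anyNA, logical(1)), ]
  cr <- config$classify_range
  tissue <- crop_range(tissue, lo = cr[1], hi = cr[2])
  tissue <- pca_screen(tissue, lib)

  say("stage 7/8: classifier training")
  tr <- config$training
  feats <- simulate_labelled_features(tr$n_per_class, lib = lib, cfg = cfg,
                                      seed = seed + 9L)
  model <- train_classifier(feats, folds = tr$folds,
                            target_sensitivity = tr$target_sensitivity,
                            seed = seed + 10L)

  say("stage 8/8: segment-averaged diagnosis")
  diag <- segment_average_classify(tissue, model)
  truth <- segment_truth(seg, phantom)
  diag <- dplyr::left_join(diag, truth, by = "segment_id")
  measured <- diag[diag$measured & !is.na(diag$truth), ]
  confusion <- table(truth = measured$truth, call = measured$call)
  accuracy <- if (nrow(measured) > 0) {
    mean(measured$call == measured$truth)
  } else NA_real_

  snr_by_batch <- spectra |>
    dplyr::group_by(.data$batch_id) |>
    dplyr::summarise(min_snr = min(.data$snr), mean_snr = mean(.data$snr),
                     .groups = "drop")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths$phantom <- write_phantom(phantom, file.path(outdir, "phantom"))
    paths$plan <- write_batch_plan(plan, file.path(outdir, "plan"),
                                   t_int = cfg$t_int)
    paths$calibration <- write_calibration(calib,
                                           file.path(outdir, "calibration.json"))
    paths$model <- write_classifier(model, file.path(outdir, "model.json"))
    readr::write_csv(diag, file.path(outdir, "diagnosis.csv"))
    paths$diagnosis <- file.path(outdir, "diagnosis.csv")
  }

  manifest <- list(
    seed = seed,
    counts = c(plan$counts, list(n_segments = sum(seg$summary$segment_id > 0),
                                 n_spectra = nrow(spectra))),
    acquisition_time_s = estimate_acquisition_time(plan, cfg$t_int),
    snr_by_batch = snr_by_batch,
    diagnosis = diag,
    confusion = confusion,
    segment_accuracy = accuracy,
    paths = paths)
  if (!is.null(outdir)) {
    m <- manifest
    m$paths <- lapply(paths, basename) # manifest is outdir-relative
    m$confusion <- as.data.frame(confusion)
    jsonlite::write_json(m, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  manifest
}

# majority phantom class per segment
segment_truth <- function(seg, phantom) {
  ids <- seg$summary$segment_id[seg$summary$segment_id > 0]
  dplyr::bind_rows(lapply(ids, function(id) {
    cls <- phantom$label[seg$label == id]
    tb <- table(cls)
    tibble::tibble(segment_id = id,
                   truth = phantom$classes[as.integer(names(tb)[
                     which.max(tb)]) + 1L])
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
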