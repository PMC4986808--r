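#' Write a matrix as 16-bit grayscale TIFF
#'
#' Values are scaled by `max_value` into the 16-bit range.
#' @param m Numeric matrix.
#' @param path Output path.
#' @param max_value Full-scale value (default the matrix maximum).
#' @return `path`, invisibly (attribute `max_value` records the scale).
#' @export
write_tiff16 <- function(m, path, max_value = max(m, 1)) {
  tiff::writeTIFF(pmin(pmax(m / max_value, 0), 1), path,
                  bits.per.sample = 16L)
  invisible(structure(path, max_value = max_value))
}

#' Read a 16-bit grayscale TIFF into a matrix
#' @param path File path.
#' @param max_value Full-scale value used when writing.
#' @return Numeric matrix.
#' @export
read_tiff16 <- function(path, max_value = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m * max_value
}

#' Write a tissue phantom to disk
#'
#' Label, AF and dye-mask images as 16-bit TIFF plus a JSON sidecar with
#' the pixel size, seed and intensity scales.
#' @param phantom A [render_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tiff16(phantom$label, file.path(dir, "label.tif"), max_value = 65535)
  af_max <- max(phantom$af, 1)
  write_tiff16(phantom$af, file.path(dir, "af.tif"), max_value = af_max)
  write_tiff16(phantom$dye_mask * 1, file.path(dir, "dye_mask.tif"),
               max_value = 65535)
  jsonlite::write_json(list(pixel_size = phantom$pixel_size,
                            seed = phantom$seed, af_max = af_max,
                            classes = phantom$classes),
                       file.path(dir, "phantom.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a tissue phantom written by [write_phantom()]
#' @param dir Directory path.
#' @return `tissue_phantom`.
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  label <- round(read_tiff16(file.path(dir, "label.tif"), 65535))
  storage.mode(label) <- "integer"
  structure(list(label = label,
                 af = read_tiff16(file.path(dir, "af.tif"), meta$af_max),
                 dye_mask = read_tiff16(file.path(dir, "dye_mask.tif"),
                                        65535) > 0.5,
                 pixel_size = meta$pixel_size, classes = meta$classes,
                 seed = meta$seed),
            class = "tissue_phantom")
}

#' Write a simulated CCD frame (16-bit TIFF + track-layout CSV)
#' @param frame A [simulate_ccd_frame()] result.
#' @param path TIFF path; the layout goes to `<path>_layout.csv`.
#' @return `path`, invisibly.
#' @export
write_ccd_frame <- function(frame, path) {
  write_tiff16(frame$counts, path, max_value = frame$full_well)
  readr::write_csv(frame$layout,
                   paste0(sub("\\.tiff?$", "", path), "_layout.csv"))
  invisible(path)
}

#' Read a CCD frame written by [write_ccd_frame()]
#' @param path TIFF path.
#' @param full_well Full-well scale used at write time.
#' @param bias Bias level to record.
#' @return `ccd_frame`.
#' @export
read_ccd_frame <- function(path, full_well = 65535, bias = 100) {
  counts <- read_tiff16(path, full_well)
  layout <- readr::read_csv(paste0(sub("\\.tiff?$", "", path),
                                   "_layout.csv"),
                            show_col_types = FALSE)
  structure(list(counts = counts, layout = tibble::as_tibble(layout),
                 full_well = full_well, bias = bias, seed = NA_integer_),
            class = "ccd_frame")
}

#' Write a batch plan (members CSV + JSON summary)
#' @param plan A [plan_batches()] result.
#' @param dir Output directory.
#' @param t_int Integration time recorded in the summary (s).
#' @return The directory, invisibly.
#' @export
write_batch_plan <- function(plan, dir, t_int = 2) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(plan$members, file.path(dir, "batches.csv"))
  jsonlite::write_json(c(plan$counts,
                         list(t_int = t_int, seed = plan$seed,
                              fov = unclass(plan$geom))),
                       file.path(dir, "plan.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a batch plan written by [write_batch_plan()]
#' @param dir Directory path.
#' @return `batch_plan`.
#' @export
read_batch_plan <- function(dir) {
  members <- readr::read_csv(file.path(dir, "batches.csv"),
                             col_types = readr::cols(
                               segment_id = readr::col_integer(),
                               batch_id = readr::col_integer(),
                               member_idx = readr::col_integer()))
  meta <- jsonlite::read_json(file.path(dir, "plan.json"),
                              simplifyVector = TRUE)
  geom <- fov_geometry(meta$fov$width, meta$fov$height, meta$fov$min_sep,
                       meta$fov$batch_size)
  members <- tibble::as_tibble(members)
  stage <- members |>
    dplyr::filter(.data$zero_order) |>
    dplyr::transmute(batch_id = .data$batch_id, x_um = .data$x_um,
                     y_um = .data$y_um)
  structure(list(members = members, stage_targets = stage, geom = geom,
                 seed = meta$seed,
                 counts = list(n_af = meta$n_af, n_fill = meta$n_fill,
                               n_batches = meta$n_batches)),
            class = "batch_plan")
}

#' Write a calibration model as JSON
#' @param calib A `calibration_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(list(coefficients = calib$coefficients,
                            cols = calib$cols,
                            residual_rms = calib$residual_rms,
                            peaks = calib$peaks),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration model written by [write_calibration()]
#' @param path File path.
#' @return `calibration_model`.
#' @export
read_calibration <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_calibration(m$coefficients, cols = m$cols,
                  peaks = if (!is.null(m$peaks)) tibble::as_tibble(m$peaks),
                  residual_rms = m$residual_rms)
}

#' Write a trained classifier as JSON
#' @param model A [train_classifier()] fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(model, path) {
  jsonlite::write_json(list(weights = model$weights,
                            classes = model$classes, lambda = model$lambda,
                            threshold = model$threshold,
                            target_sensitivity = model$target_sensitivity,
                            cv_report = model$cv_report),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a classifier written by [write_classifier()]
#' @param path File path.
#' @return `raman_classifier`.
#' @export
read_classifier <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- as.matrix(m$weights)
  colnames(W) <- m$classes
  cv <- tibble::as_tibble(m$cv_report)
  summ <- cv |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(sensitivity = mean(.data$sensitivity),
                     specificity = mean(.data$specificity),
                     .groups = "drop")
  structure(list(weights = W, lambda = m$lambda, threshold = m$threshold,
                 classes = m$classes, cv_report = cv, cv_summary = summ,
                 target_sensitivity = m$target_sensitivity,
                 seed = NA_integer_),
            class = "raman_classifier")
}

#' Write preprocessed spectra as a long CSV
#'
#' One row per (beam, wavenumber) sample with the beam metadata repeated.
#' @param spectra A spectra tibble.
#' @param path Output path.
#' @param meta_cols Metadata columns to carry (defaults to the scalar
#'   columns present).
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(spectra, path, meta_cols = NULL) {
  if (is.null(meta_cols)) {
    meta_cols <- names(spectra)[!vapply(spectra, is.list, logical(1))]
  }
  long <- dplyr::bind_rows(lapply(seq_len(nrow(spectra)), function(i) {
    dplyr::bind_cols(spectra[i, meta_cols],
                     tibble::tibble(wavenumber = spectra$wavenumber[[i]],
                                    intensity = spectra$intensity[[i]]))
  }))
  readr::write_csv(long, path)
  invisible(path)
}

#' Write a phase hologram as 16-bit TIFF (phase scaled from \[0, 2pi))
#' @param h A `phase_hologram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hologram <- function(h, path) {
  write_tiff16(h$phase, path, max_value = 2 * pi)
  invisible(path)
}

#' Write a spot pattern as CSV
#' @param spots A [spot_pattern()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spot_pattern <- function(spots, path) {
  readr::write_csv(spots, path)
  invisible(path)
}

#' Read a run configuration from YAML
#' @param path YAML file.
#' @return Named list.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
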