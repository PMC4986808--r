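#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

raster_df <- function(m, value = "value") {
  tibble::tibble(x = rep(seq_len(ncol(m)), each = nrow(m)),
                 y = rep(seq_len(nrow(m)), ncol(m)),
                 !!value := as.vector(m))
}

#' @export
autoplot.tissue_phantom <- function(object, ...) {
  df <- raster_df(object$label, "code")
  df$class <- factor(object$classes[df$code + 1L],
                     levels = object$classes)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Tissue phantom", x = "x (px)", y = "y (px)")
}

#' @export
autoplot.ccd_frame <- function(object, ...) {
  df <- raster_df(object$counts, "counts")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = log10(.data$counts + 1))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(title = "Simulated CCD frame", x = "column", y = "row",
                  fill = "log10 counts")
}

#' @export
autoplot.batch_plan <- function(object, ...) {
  m <- object$members
  ggplot2::ggplot(m, ggplot2::aes(.data$x_um, .data$y_um,
                                  colour = factor(.data$batch_id),
                                  shape = .data$origin)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = m[m$zero_order, ], shape = 1, size = 4,
                        colour = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(title = "Batch plan (circled: 0th-order anchors)",
                  x = "x (um)", y = "y (um)")
}

#' Plot spectra from a spectra tibble
#'
#' @param spectra A spectra tibble with `wavenumber`/`intensity`.
#' @param offset Vertical offset between consecutive spectra.
#' @return A ggplot.
#' @export
plot_spectra <- function(spectra, offset = 0) {
  df <- dplyr::bind_rows(lapply(seq_len(nrow(spectra)), function(i) {
    tibble::tibble(beam = i, wavenumber = spectra$wavenumber[[i]],
                   intensity = spectra$intensity[[i]] + (i - 1) * offset)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavenumber, .data$intensity,
                                   colour = factor(.data$beam))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Raman shift (cm⁻¹)", y = "intensity (a.u.)",
                  colour = "beam")
}

#' @export
autoplot.diagnosis_map <- function(object, seg = NULL, ...) {
  if (is.null(seg)) {
    df <- tibble::as_tibble(object)
    return(ggplot2::ggplot(df, ggplot2::aes(.data$segment_id, .data$p_bcc,
                                            fill = .data$call)) +
             ggplot2::geom_col() +
             ggplot2::labs(title = "Per-segment diagnosis",
                           x = "segment", y = "P(BCC)"))
  }
  img <- render_diagnosis_map(object, seg)
  df <- raster_df(img, "code")
  lv <- c("unmeasured", phantom_class_names())
  df$call <- factor(lv[df$code + 2L], levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$call)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Diagnosis map", x = "x (px)", y = "y (px)")
}
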