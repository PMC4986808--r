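#' Describe a phantom region
#'
#' Helper building one row of a phantom layout. Coordinates and sizes are in
#' micrometres; the image origin is the top-left corner, x rightward (columns),
#' y downward (rows), pixel centers at half-integer pixel coordinates.
#'
#' @param class Tissue class name (see [phantom_class_names()]).
#' @param shape `"rect"` or `"disk"`.
#' @param x,y Region center (um).
#' @param rx,ry Half-width and half-height (um). For a disk `ry` defaults to `rx`.
#' @return One-row tibble usable in a layout.
#' @export
phantom_region <- function(class, shape = c("rect", "disk"), x, y, rx, ry = rx) {
  shape <- match.arg(shape)
  if (!class %in% phantom_class_names()) {
    stop("unknown phantom class: ", class)
  }
  if (rx <= 0 || ry <= 0) stop("zero-area region: rx and ry must be > 0")
  tibble::tibble(class = class, shape = shape, x = x, y = y, rx = rx, ry = ry)
}

default_af_params <- function() {
  tibble::tibble(
    class   = phantom_class_names(),
    af_mean = c(20, 160, 150, 60, 140, 150),
    af_sd   = c(5, 12, 12, 10, 12, 12)
  )
}

#' Render a synthetic tissue phantom
#'
#' Rasterizes a region layout into a class-label image and draws a
#' co-registered autofluorescence (AF) image with per-class intensity
#' distributions. The AF means of BCC, epidermis and fat are deliberately
#' overlapping (AF has high sensitivity but low specificity for tumour), so
#' AF segmentation can find tissue structure but cannot distinguish those
#' classes. A dye-contamination mask marks a configurable fraction of
#' tumour-adjacent pixels plus any explicit `dye` regions.
#'
#' @param layout Tibble of regions (rows from [phantom_region()]); later rows
#'   overwrite earlier ones where they overlap.
#' @param width_um,height_um Image extent (um).
#' @param pixel_size Pixel size (um), default 5.
#' @param seed Integer seed; the phantom is bit-identical for a fixed seed.
#' @param af_params Optional tibble (class, af_mean, af_sd) overriding the AF
#'   intensity model.
#' @param dye_fraction Fraction of the tumour-adjacent rim (dilation radius 3
#'   px) marked as dye-contaminated. Default 0.
#' @return `tissue_phantom`: list with integer `label` matrix, `af` matrix,
#'   logical `dye_mask`, `pixel_size`, `classes`, `seed`.
#' @export
render_phantom <- function(layout, width_um, height_um, pixel_size = 5,
                           seed = 1L, af_params = NULL, dye_fraction = 0) {
  layout <- tibble::as_tibble(layout)
  nc <- max(1L, as.integer(round(width_um / pixel_size)))
  nr <- max(1L, as.integer(round(height_um / pixel_size)))
  if (any(layout$rx <= 0 | layout$ry <= 0)) stop("zero-area region in layout")
  out_of_bounds <- layout$x - layout$rx < 0 | layout$x + layout$rx > width_um |
    layout$y - layout$ry < 0 | layout$y + layout$ry > height_um
  if (any(out_of_bounds)) {
    stop("region(s) ", paste(which(out_of_bounds), collapse = ", "),
         " extend outside the image bounds")
  }
  classes <- phantom_class_names()
  label <- matrix(0L, nrow = nr, ncol = nc)
  # pixel-center coordinates in um
  xc <- (seq_len(nc) - 0.5) * pixel_size
  yc <- (seq_len(nr) - 0.5) * pixel_size
  for (i in seq_len(nrow(layout))) {
    r <- layout[i, ]
    code <- match(r$class, classes) - 1L
    if (r$shape == "rect") {
      inside <- outer(abs(yc - r$y) <= r$ry, abs(xc - r$x) <= r$rx, `&`)
    } else {
      inside <- outer(((yc - r$y) / r$ry)^2, ((xc - r$x) / r$rx)^2, `+`) <= 1
    }
    label[inside] <- code
  }
  if (is.null(af_params)) af_params <- default_af_params()
  withr::with_seed(seed, {
    af <- matrix(0, nrow = nr, ncol = nc)
    for (cl in classes) {
      code <- match(cl, classes) - 1L
      idx <- label == code
      if (!any(idx)) next
      p <- af_params[af_params$class == cl, ]
      af[idx] <- pmax(0, stats::rnorm(sum(idx), p$af_mean, p$af_sd))
    }
    dye_mask <- label == match("dye", classes) - 1L
    if (dye_fraction > 0) {
      bcc <- label == match("bcc", classes) - 1L
      if (any(bcc)) {
        kern <- EBImage::makeBrush(7, shape = "disc")
        rim <- EBImage::dilate(EBImage::Image(bcc * 1), kern) > 0.5
        rim <- rim & !bcc & label > 0L
        cand <- which(rim)
        take <- sample(cand, size = round(dye_fraction * length(cand)))
        dye_mask[take] <- TRUE
      }
    }
  })
  structure(list(label = label, af = af, dye_mask = dye_mask,
                 pixel_size = pixel_size, classes = classes, seed = seed),
            class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat("<tissue_phantom> ", nrow(x$label), "x", ncol(x$label), " px @ ",
      x$pixel_size, " um/px; classes present: ",
      paste(x$classes[sort(unique(as.vector(x$label))) + 1L], collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Class name at a stage coordinate
#'
#' Coordinates outside the rendered image read as `background`: the
#' specimen sits on a larger substrate, and padding beams near the section
#' edge can land off-tissue.
#'
#' @param phantom A [render_phantom()] result.
#' @param x_um,y_um Coordinates (um), vectorized.
#' @return Character vector of class names.
#' @export
phantom_class_at <- function(phantom, x_um, y_um) {
  col <- ceiling(x_um / phantom$pixel_size)
  row <- ceiling(y_um / phantom$pixel_size)
  out <- rep("background", length(col))
  ok <- col >= 1 & col <= ncol(phantom$label) &
    row >= 1 & row <= nrow(phantom$label)
  out[ok] <- phantom$classes[phantom$label[cbind(row[ok], col[ok])] + 1L]
  out
}

#' Dye contamination at a stage coordinate
#' @inheritParams phantom_class_at
#' @return Logical vector (FALSE outside the image).
#' @export
phantom_dye_at <- function(phantom, x_um, y_um) {
  col <- ceiling(x_um / phantom$pixel_size)
  row <- ceiling(y_um / phantom$pixel_size)
  out <- rep(FALSE, length(col))
  ok <- col >= 1 & col <= ncol(phantom$label) &
    row >= 1 & row <= nrow(phantom$label)
  out[ok] <- phantom$dye_mask[cbind(row[ok], col[ok])]
  out
}
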