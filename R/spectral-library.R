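#' Per-class Raman basis spectra
#'
#' Builds a library of noise-free basis spectra, one per tissue class, on a
#' shared 1 cm^-1 wavenumber grid. Each basis is a sum of Gaussian bands
#' taken from a band table (center, FWHM, amplitude) plus a broad class
#' background encoded as an extra very wide band row. The default table
#' carries the marker bands used throughout skin Raman diagnostics: DNA
#' backbone bands at 788 and 1098 cm^-1 for basal cell carcinoma (BCC),
#' collagen proline/hydroxyproline bands at 851 and 950 cm^-1 for dermis,
#' lipid bands at 850, 1070, 1267, 1301, 1450 and 1660 cm^-1 for fat, the
#' phenylalanine band at 1004 cm^-1, and a CH-deformation band at 1450
#' cm^-1 in every tissue class.
#'
#' @param band_overrides Optional tibble with columns `class`, `center_cm1`,
#'   `fwhm_cm1`, `amplitude`, or a named list of such tables (class name ->
#'   table, the `class` column then optional). Classes present here replace
#'   the default band table for that class entirely; an empty (zero-row)
#'   override for a class yields a flat zero basis.
#' @param axis Wavenumber axis (cm^-1), strictly ascending on a 1 cm^-1
#'   grid. Default 300--1900.
#' @return An object of class `spectral_library`: list with `axis`, `basis`
#'   (matrix, length(axis) x classes), and `bands` (the band tibble).
#' @export
build_spectral_library <- function(band_overrides = NULL, axis = 300:1900) {
  stopifnot(all(diff(axis) > 0))
  bands <- default_band_table()
  if (!is.null(band_overrides)) {
    if (is.list(band_overrides) && !is.data.frame(band_overrides)) {
      if (is.null(names(band_overrides))) {
        stop("a list of band overrides must be named by class")
      }
      replaced <- names(band_overrides)
      ov <- dplyr::bind_rows(lapply(replaced, function(cl) {
        tb <- tibble::as_tibble(band_overrides[[cl]])
        tb$class <- rep(cl, nrow(tb))
        tb
      }))
    } else {
      ov <- tibble::as_tibble(band_overrides)
      if (!"class" %in% names(ov)) {
        stop("band_overrides must have a class column")
      }
      replaced <- unique(ov$class)
    }
    need <- c("center_cm1", "fwhm_cm1", "amplitude")
    if (nrow(ov) > 0 && !all(need %in% names(ov))) {
      stop("band_overrides must have columns class, ",
           paste(need, collapse = ", "))
    }
    bands <- dplyr::bind_rows(bands[!bands$class %in% replaced, ], ov)
  }
  real <- bands[bands$amplitude != 0 | bands$fwhm_cm1 <= 0, ]
  if (nrow(real) > 0) {
    if (any(real$fwhm_cm1 <= 0)) stop("band widths must be > 0")
    if (any(real$amplitude < 0)) stop("band amplitudes must be >= 0")
    bad <- real$center_cm1 < min(axis) | real$center_cm1 > max(axis)
    if (any(bad)) {
      stop("band_center_outside_axis: centers ",
           paste(real$center_cm1[bad], collapse = ", "),
           " outside [", min(axis), ", ", max(axis), "]")
    }
  }
  classes <- phantom_class_names()
  basis <- matrix(0, nrow = length(axis), ncol = length(classes),
                  dimnames = list(NULL, classes))
  for (cl in classes) {
    tb <- bands[bands$class == cl, ]
    if (nrow(tb) == 0) next
    sigma <- tb$fwhm_cm1 / (2 * sqrt(2 * log(2)))
    for (i in seq_len(nrow(tb))) {
      basis[, cl] <- basis[, cl] +
        tb$amplitude[i] * exp(-(axis - tb$center_cm1[i])^2 / (2 * sigma[i]^2))
    }
  }
  structure(list(axis = as.numeric(axis), basis = basis, bands = bands),
            class = "spectral_library")
}

#' @export
print.spectral_library <- function(x, ...) {
  cat("<spectral_library> ", ncol(x$basis), " classes, axis ",
      min(x$axis), "-", max(x$axis), " cm^-1 (", length(x$axis),
      " points)\n", sep = "")
  invisible(x)
}

#' Canonical phantom class names
#'
#' Integer label codes are `match(class, phantom_class_names()) - 1`, i.e.
#' background = 0.
#' @return Character vector of class names.
#' @export
phantom_class_names <- function() {
  c("background", "bcc", "epidermis", "dermis", "fat", "dye")
}

# Default band table. Narrow rows are Raman bands (8 cm^-1 FWHM); the wide
# (600 cm^-1) rows are the broad class background hump.
default_band_table <- function() {
  w <- 8
  tribble <- tibble::tribble(
    ~class,      ~center_cm1, ~fwhm_cm1, ~amplitude,
    # BCC: nucleic-acid rich
    "bcc",        788,  w, 1.00,
    "bcc",       1098,  w, 0.80,
    "bcc",       1004,  w, 0.60,
    "bcc",       1245, 14, 0.45,
    "bcc",       1340, 14, 0.40,
    "bcc",       1450, 12, 0.85,
    "bcc",       1660, 18, 1.00,
    "bcc",       1330, 600, 0.25,
    # epidermis: keratinocytes
    "epidermis",  788,  w, 0.10,
    "epidermis",  853,  w, 0.25,
    "epidermis", 1004,  w, 0.95,
    "epidermis", 1127,  w, 0.30,
    "epidermis", 1245, 14, 0.55,
    "epidermis", 1450, 12, 1.00,
    "epidermis", 1660, 18, 1.10,
    "epidermis", 1330, 600, 0.20,
    # dermis: collagen
    "dermis",     851,  w, 1.00,
    "dermis",     921,  w, 0.45,
    "dermis",     950,  w, 0.80,
    "dermis",    1004,  w, 0.50,
    "dermis",    1245, 14, 0.90,
    "dermis",    1270, 14, 0.60,
    "dermis",    1450, 12, 0.80,
    "dermis",    1660, 18, 1.00,
    "dermis",    1330, 600, 0.20,
    # fat / sebaceous: lipid
    "fat",        850,  w, 0.30,
    "fat",       1004,  w, 0.05,
    "fat",       1070,  w, 0.60,
    "fat",       1267, 12, 0.70,
    "fat",       1301, 10, 1.00,
    "fat",       1450, 12, 1.20,
    "fat",       1660, 14, 0.90,
    "fat",       1330, 600, 0.10,
    # dye contamination: broad fluorescence-like hump only
    "dye",       1250, 500, 1.00
  )
  tribble
}
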