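#' Build a multifocal spot pattern
#'
#' A spot pattern lists the far-field (sample-plane) targets for the
#' hologram: the fixed undiffracted 0th-order spot at the origin plus
#' reconfigurable 1st-order spots around it. Offsets are in far-field pixel
#' units of the Fourier grid.
#'
#' @param x,y Integer-valued offsets of the 1st-order spots.
#' @param requested_power Relative power per 1st-order spot (default equal).
#' @return A tibble with columns `x`, `y`, `order`, `requested_power`; the
#'   0th-order row is always present at the origin.
#' @export
spot_pattern <- function(x = numeric(), y = numeric(),
                         requested_power = rep(1, length(x))) {
  stopifnot(length(x) == length(y), length(requested_power) == length(x))
  n1 <- length(x)
  sp <- tibble::tibble(x = c(0, x), y = c(0, y),
                       order = c(0L, rep(1L, n1)),
                       requested_power = c(1, requested_power))
  if (anyDuplicated(sp[, c("x", "y")]) > 0) {
    stop("no two spots may coincide (the 0th order occupies the origin)")
  }
  sp
}

new_phase_hologram <- function(phase, blazing = 1) {
  structure(list(phase = phase %% (2 * pi), blazing = blazing),
            class = "phase_hologram")
}

#' @export
print.phase_hologram <- function(x, ...) {
  cat("<phase_hologram> ", nrow(x$phase), "x", ncol(x$phase),
      " px, blazing b = ", x$blazing, "\n", sep = "")
  invisible(x)
}

#' Gratings-and-lenses hologram synthesis
#'
#' Superposes one linear phase ramp per requested 1st-order spot (plus an
#' optional quadratic lens term per spot for axial displacement) and takes
#' the argument of the complex sum as the phase-only hologram. The 0th-order
#' spot needs no ramp: it is the undiffracted residual of the phase-only
#' approximation and is deliberately retained as a sampling beam.
#'
#' @param spots A [spot_pattern()] tibble. An optional `defocus` column adds
#'   a quadratic lens phase per spot.
#' @param shape Side length of the square hologram (default 512).
#' @return A `phase_hologram`.
#' @export
gratings_and_lenses <- function(spots, shape = 512) {
  n <- shape
  s1 <- spots[spots$order == 1L, ]
  if (any(abs(s1$x) > n / 2 | abs(s1$y) > n / 2)) {
    stop("spot offset beyond the Nyquist range (|offset| <= ", n / 2, ")")
  }
  if (nrow(s1) == 0) return(new_phase_hologram(matrix(0, n, n)))
  cx <- 0:(n - 1)
  field <- matrix(0 + 0i, n, n)
  for (i in seq_len(nrow(s1))) {
    ramp_r <- exp(2i * pi * s1$y[i] * cx / n)
    ramp_c <- exp(2i * pi * s1$x[i] * cx / n)
    ph <- outer(ramp_r, ramp_c)
    if ("defocus" %in% names(s1) && isTRUE(s1$defocus[i] != 0)) {
      r2 <- outer((cx - n / 2)^2, (cx - n / 2)^2, `+`)
      ph <- ph * exp(1i * pi * s1$defocus[i] * r2 / n^2)
    }
    field <- field + sqrt(s1$requested_power[i]) * ph
  }
  new_phase_hologram(Arg(field))
}

#' Far-field intensity of a phase hologram
#'
#' Squared magnitude of the discrete Fourier transform of the unit-amplitude
#' field `exp(i * phase)`, normalized so that total far-field power equals
#' the SLM-plane power (`shape^2`, Parseval).
#'
#' @param h A `phase_hologram`.
#' @return Numeric matrix in unshifted DFT indexing: the 0th order is at
#'   `[1, 1]`; a spot offset `(dx, dy)` sits at `[dy mod n + 1, dx mod n + 1]`.
#' @export
far_field_intensity <- function(h) {
  f <- exp(1i * h$phase)
  F <- stats::fft(f)
  Mod(F)^2 / length(f)
}

# index of signed far-field offset in unshifted DFT layout
ff_index <- function(off, n) (off %% n) + 1L

#' Power of each spot in the far field
#'
#' Summed intensity in a 3x3 window centered on each spot's nominal offset
#' (windows wrap at the grid edges).
#'
#' @param h A `phase_hologram`.
#' @param spots A [spot_pattern()] tibble.
#' @return The `spots` tibble with a `power` column appended.
#' @export
spot_powers <- function(h, spots) {
  I <- far_field_intensity(h)
  n <- nrow(I)
  spots$power <- vapply(seq_len(nrow(spots)), function(i) {
    rows <- ff_index(spots$y[i] + (-1:1), n)
    cols <- ff_index(spots$x[i] + (-1:1), n)
    sum(I[rows, cols])
  }, numeric(1))
  spots
}

#' Locate the brightest far-field peaks
#'
#' @param I Far-field intensity matrix (unshifted indexing).
#' @param k Number of peaks.
#' @param exclusion Half-width of the square zeroed around each found peak.
#' @return Tibble with signed offsets `x`, `y` and `intensity`, brightest first.
#' @export
far_field_peaks <- function(I, k = 1, exclusion = 3) {
  n <- nrow(I)
  J <- I
  out <- vector("list", k)
  for (i in seq_len(k)) {
    idx <- which.max(J)
    r <- (idx - 1) %% n
    c <- (idx - 1) %/% n
    sx <- ((c + n / 2) %% n) - n / 2
    sy <- ((r + n / 2) %% n) - n / 2
    out[[i]] <- tibble::tibble(x = sx, y = sy, intensity = J[idx])
    rows <- ff_index(sy + (-exclusion:exclusion), n)
    cols <- ff_index(sx + (-exclusion:exclusion), n)
    J[rows, cols] <- -Inf
  }
  dplyr::bind_rows(out)
}

#' Gerchberg-Saxton phase retrieval
#'
#' Alternating projections between the SLM plane (unit amplitude, free
#' phase) and the far field (amplitude fixed to the square root of the
#' target intensity, free phase). The per-iteration reconstruction error is
#' one minus the normalized correlation (cosine similarity) between the
#' achieved and target intensities on the target support.
#'
#' @param target Non-negative far-field intensity target in unshifted DFT
#'   indexing (same layout as [far_field_intensity()]).
#' @param iterations Number of iterations (>= 1).
#' @param seed Seed for the random initial phase.
#' @return A `phase_hologram` with attribute `errors` (length `iterations`).
#' @export
gerchberg_saxton <- function(target, iterations = 30, seed = 1L) {
  if (any(target < 0)) stop("target intensity must be non-negative")
  if (all(target == 0)) stop("all-zero target intensity")
  stopifnot(iterations >= 1)
  n <- nrow(target)
  amp_far <- sqrt(target)
  support <- target > 0
  tvec <- target[support]
  phase <- withr::with_seed(seed, matrix(stats::runif(n * n, 0, 2 * pi), n, n))
  errors <- numeric(iterations)
  for (it in seq_len(iterations)) {
    F <- stats::fft(exp(1i * phase))
    I <- Mod(F)^2 / (n * n)
    iv <- I[support]
    errors[it] <- 1 - sum(iv * tvec) / sqrt(sum(iv^2) * sum(tvec^2))
    Fc <- amp_far * exp(1i * Arg(F))
    f <- stats::fft(Fc, inverse = TRUE)
    phase <- Arg(f)
  }
  h <- new_phase_hologram(phase)
  attr(h, "errors") <- errors
  h
}

#' Blazing: scale the hologram modulation depth
#'
#' Rescales the phase excursion about its circular mean by a factor
#' `b` in \[0, 1\]. `b = 1` leaves the hologram unchanged; `b = 0` gives a
#' uniform phase (all power undiffracted into the 0th order). Lowering `b`
#' transfers far-field power from the 1st orders into the 0th order, which
#' is how per-beam power is balanced against the retained 0th-order beam.
#'
#' @param h A `phase_hologram`.
#' @param b Blazing level in \[0, 1\].
#' @return A `phase_hologram` with `blazing = b`.
#' @export
apply_blazing <- function(h, b) {
  if (!is.numeric(b) || length(b) != 1 || b < 0 || b > 1) {
    stop("blazing level b must be a single value in [0, 1]")
  }
  mu <- Arg(mean(exp(1i * h$phase)))
  dev <- ((h$phase - mu + pi) %% (2 * pi)) - pi
  new_phase_hologram(mu + b * dev, blazing = b)
}

#' Optimize blazing for even power between beams
#'
#' Scans a grid of blazing levels, evaluates each blazed hologram's
#' far-field spot powers (including the 0th order), and returns the level
#' minimizing the max/min power ratio over all spots.
#'
#' @param spots A [spot_pattern()] tibble (>= 2 spots including 0th order).
#' @param b_grid Candidate blazing levels.
#' @param shape Hologram side length.
#' @return List: `hologram` (best blazed hologram), `b`, `ratio`
#'   (achieved max/min power ratio), and `scan` (tibble b, ratio).
#' @export
optimize_uniformity <- function(spots, b_grid = seq(0.40, 1, by = 0.02),
                                shape = 512) {
  if (length(b_grid) == 0) stop("empty blazing grid")
  if (nrow(spots) < 2) {
    h <- gratings_and_lenses(spots, shape)
    return(list(hologram = h, b = 1, ratio = 1,
                scan = tibble::tibble(b = 1, ratio = 1)))
  }
  h0 <- gratings_and_lenses(spots, shape)
  ratios <- vapply(b_grid, function(b) {
    p <- spot_powers(apply_blazing(h0, b), spots)$power
    max(p) / min(p)
  }, numeric(1))
  best <- which.min(ratios)
  list(hologram = apply_blazing(h0, b_grid[best]), b = b_grid[best],
       ratio = ratios[best],
       scan = tibble::tibble(b = b_grid, ratio = ratios))
}
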