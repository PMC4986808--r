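#' Multi-level Otsu thresholds
#'
#' Chooses `n_classes - 1` thresholds minimizing the pooled within-class
#' intensity variance (the multi-level Otsu criterion) by dynamic
#' programming over a fixed-width histogram. Binning is range-based, so the
#' partition is invariant to monotone affine rescaling of the intensities.
#'
#' @param values Numeric intensities.
#' @param n_classes Number of intensity classes (>= 1).
#' @param n_bins Histogram bins (default 128).
#' @return Numeric thresholds (length `n_classes - 1`), as intensity values;
#'   class k is `thr[k-1] < x <= thr[k]`.
#' @export
otsu_thresholds <- function(values, n_classes, n_bins = 128) {
  stopifnot(n_classes >= 1)
  if (n_classes == 1) return(numeric(0))
  rng <- range(values)
  if (diff(rng) == 0) return(numeric(0))
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- pmin(n_bins, pmax(1L, findInterval(values, edges, rightmost.closed = TRUE)))
  cnt <- tabulate(bin, n_bins)
  # prefix sums for O(1) within-class sum of squares on any bin range
  c0 <- cumsum(cnt)
  c1 <- cumsum(cnt * mids)
  c2 <- cumsum(cnt * mids^2)
  sseg <- function(i, j) { # within-class SS for bins i..j (vectorized in i)
    w <- c0[j] - ifelse(i > 1, c0[i - 1], 0)
    s <- c1[j] - ifelse(i > 1, c1[i - 1], 0)
    q <- c2[j] - ifelse(i > 1, c2[i - 1], 0)
    ifelse(w > 0, q - s^2 / w, 0)
  }
  K <- n_classes
  D <- matrix(Inf, K, n_bins)     # D[k, j]: best SS for bins 1..j in k classes
  P <- matrix(NA_integer_, K, n_bins) # split point: first bin of class k
  D[1, ] <- sseg(1, seq_len(n_bins))
  for (k in 2:K) {
    for (j in k:n_bins) {
      i <- k:j                    # candidate first bin of class k
      cost <- D[k - 1, i - 1] + sseg(i, j)
      b <- which.min(cost)
      D[k, j] <- cost[b]
      P[k, j] <- i[b]
    }
  }
  splits <- integer(K - 1)
  j <- n_bins
  for (k in K:2) {
    splits[k - 1] <- P[k, j]
    j <- P[k, j] - 1L
  }
  edges[splits]                    # threshold = lower edge of each class start
}

#' Segment an autofluorescence image
#'
#' Thresholds the AF image into `n_levels` intensity classes by the
#' multi-level Otsu criterion, splits each non-background class into
#' connected components, and merges components smaller than `min_area`
#' pixels into their dominant neighbor. The lowest-intensity class is
#' background (label 0).
#'
#' @param af Non-negative intensity matrix.
#' @param n_levels Number of intensity classes including background.
#' @param min_area Minimum component area in pixels (smaller components are
#'   merged into the neighboring segment sharing the longest border).
#' @param pixel_size Pixel size (um), carried into the summary.
#' @return `segment_map`: list with integer `label` matrix (0 = background),
#'   `summary` tibble (segment_id, area_px, mean_af, priority) and
#'   `pixel_size`. Priority is the segment mean AF relative to the mean AF
#'   over all non-background pixels.
#' @export
segment_af_image <- function(af, n_levels = 3, min_area = 20, pixel_size = 1) {
  if (any(af < 0)) stop("AF image must be non-negative")
  stopifnot(n_levels >= 1)
  if (diff(range(af)) == 0) {
    warning("constant AF image: returning a single segment")
    lab <- matrix(0L, nrow(af), ncol(af))
    summ <- tibble::tibble(segment_id = 0L, area_px = length(af),
                           mean_af = af[1], priority = 1)
    return(structure(list(label = lab, summary = summ, pixel_size = pixel_size),
                     class = "segment_map"))
  }
  thr <- otsu_thresholds(as.vector(af), n_levels)
  cls <- matrix(findInterval(af, thr), nrow(af), ncol(af)) # 0..n_levels-1
  lab <- matrix(0L, nrow(af), ncol(af))
  nxt <- 0L
  for (k in seq_len(max(cls))) {
    comp <- EBImage::bwlabel(EBImage::Image((cls == k) * 1))
    comp <- matrix(as.integer(comp), nrow(af), ncol(af))
    pos <- comp > 0L
    lab[pos] <- comp[pos] + nxt
    nxt <- nxt + max(comp)
  }
  lab <- merge_small_segments(lab, min_area)
  ids <- sort(unique(as.vector(lab)))
  fg_mean <- if (any(lab > 0)) mean(af[lab > 0]) else mean(af)
  summ <- dplyr::bind_rows(lapply(ids, function(id) {
    idx <- lab == id
    tibble::tibble(segment_id = id, area_px = sum(idx), mean_af = mean(af[idx]),
                   priority = if (id == 0) 0 else mean(af[idx]) / fg_mean)
  }))
  structure(list(label = lab, summary = summ, pixel_size = pixel_size),
            class = "segment_map")
}

# merge components below min_area into the neighbor (or background) with the
# longest shared border, then relabel contiguously from 1
merge_small_segments <- function(lab, min_area) {
  repeat {
    areas <- table(lab[lab > 0])
    small <- as.integer(names(areas)[areas < min_area])
    if (length(small) == 0) break
    changed <- FALSE
    for (id in small) {
      mask <- lab == id
      ring <- EBImage::dilate(EBImage::Image(mask * 1),
                              EBImage::makeBrush(3, "box")) > 0.5
      nb <- lab[ring & !mask]
      nb <- nb[nb != id]
      tgt <- if (length(nb) == 0) 0L else {
        tb <- table(nb)
        as.integer(names(tb)[which.max(tb)])
      }
      if (tgt != id) { lab[mask] <- tgt; changed <- TRUE }
    }
    if (!changed) break
  }
  old <- sort(unique(as.vector(lab[lab > 0])))
  if (length(old) > 0) {
    lut <- integer(max(old)); lut[old] <- seq_along(old)
    pos <- lab > 0L
    lab[pos] <- lut[lab[pos]]
  }
  lab
}

#' @export
print.segment_map <- function(x, ...) {
  cat("<segment_map> ", nrow(x$label), "x", ncol(x$label), " px, ",
      sum(x$summary$segment_id > 0), " segments + background\n", sep = "")
  invisible(x)
}

#' Generate Raman sampling points from an AF segment map
#'
#' Emits, per non-background segment,
#' `max(min_per_segment, round(area_mm2 * density * priority))` points placed
#' by seeded blue-noise (best-candidate) sampling inside the segment mask.
#' The priority multiplier raises the density in high-AF segments. A
#' single-point segment request is placed at the segment's interior pole
#' (the deepest-inside pixel of its distance transform).
#'
#' @param seg A [segment_af_image()] result.
#' @param density Points per mm^2.
#' @param min_per_segment Minimum points per segment (default 1).
#' @param priority_exponent Exponent on the segment priority score
#'   (default 1; 0 disables prioritization).
#' @param seed Integer seed.
#' @return Tibble of sampling points: `x_um`, `y_um`, `segment_id`, `origin`
#'   (all `"af"`).
#' @export
generate_sampling_points <- function(seg, density, min_per_segment = 1,
                                     priority_exponent = 1, seed = 1L) {
  stopifnot(density > 0)
  px <- seg$pixel_size
  segs <- seg$summary[seg$summary$segment_id > 0, ]
  out <- vector("list", nrow(segs))
  withr::with_seed(seed, {
    for (i in seq_len(nrow(segs))) {
      id <- segs$segment_id[i]
      mask <- seg$label == id
      area_mm2 <- segs$area_px[i] * (px / 1000)^2
      pr <- segs$priority[i]^priority_exponent
      n <- max(min_per_segment, round(area_mm2 * density * pr))
      if (n > segs$area_px[i]) {
        warning("segment ", id, " too small for ", n, " points; reduced")
        n <- segs$area_px[i]
      }
      if (n == 0) next
      pix <- which(mask, arr.ind = TRUE) # row (y), col (x)
      if (n == 1) {
        dm <- EBImage::distmap(EBImage::Image(mask * 1))
        pole <- which.max(as.matrix(dm))
        sel <- cbind((pole - 1) %% nrow(mask) + 1,
                     (pole - 1) %/% nrow(mask) + 1)
      } else {
        sel <- blue_noise_select(pix, n)
      }
      out[[i]] <- tibble::tibble(
        x_um = (sel[, 2] - 0.5) * px,
        y_um = (sel[, 1] - 0.5) * px,
        segment_id = id, origin = "af")
    }
  })
  dplyr::bind_rows(out)
}

# best-candidate blue-noise sampling over a pixel set (rows = [row, col])
blue_noise_select <- function(pix, n, candidates = 16) {
  m <- nrow(pix)
  if (n >= m) return(pix)
  chosen <- matrix(0, n, 2)
  chosen[1, ] <- pix[sample.int(m, 1), ]
  for (i in 2:n) {
    cand <- pix[sample.int(m, min(candidates, m)), , drop = FALSE]
    d <- vapply(seq_len(nrow(cand)), function(j) {
      min((chosen[1:(i - 1), 1] - cand[j, 1])^2 +
            (chosen[1:(i - 1), 2] - cand[j, 2])^2)
    }, numeric(1))
    chosen[i, ] <- cand[which.max(d), ]
  }
  chosen
}

#' Fit an affine coordinate transform from landmark pairs
#'
#' Least-squares 6-parameter affine map between two microscope stage frames
#' (AF microscope to Raman stage): magnification scaling, rotation, shear
#' and translation are absorbed into the linear part and offset.
#'
#' @param pairs Tibble with columns `x_src`, `y_src`, `x_dst`, `y_dst` (um);
#'   at least 3 non-collinear pairs.
#' @return `affine_map`: list with 2x2 `A`, length-2 `b`, `residual_rms`.
#' @export
fit_coordinate_transform <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (nrow(pairs) < 3) stop("need at least 3 landmark pairs")
  X <- cbind(1, pairs$x_src, pairs$y_src)
  if (qr(X)$rank < 3) stop("landmark pairs are collinear")
  fx <- stats::lm.fit(X, pairs$x_dst)
  fy <- stats::lm.fit(X, pairs$y_dst)
  cfx <- unname(fx$coefficients); cfy <- unname(fy$coefficients)
  A <- rbind(c(cfx[2], cfx[3]), c(cfy[2], cfy[3]))
  if (abs(det(A)) < 1e-12) stop("degenerate (singular) affine fit")
  rss <- sum(fx$residuals^2) + sum(fy$residuals^2)
  structure(list(A = A, b = c(cfx[1], cfy[1]),
                 residual_rms = sqrt(rss / (2 * nrow(pairs)))),
            class = "affine_map")
}

#' Apply an affine map to points
#' @param map An `affine_map`.
#' @param points Tibble with `x_um`, `y_um` (other columns preserved).
#' @return The tibble with transformed coordinates.
#' @export
apply_transform <- function(map, points) {
  xy <- as.matrix(points[, c("x_um", "y_um")]) %*% t(map$A)
  points$x_um <- xy[, 1] + map$b[1]
  points$y_um <- xy[, 2] + map$b[2]
  points
}

#' Invert an affine map
#' @param map An `affine_map`.
#' @return The inverse `affine_map`.
#' @export
invert_transform <- function(map) {
  Ai <- solve(map$A)
  structure(list(A = Ai, b = as.vector(-Ai %*% map$b),
                 residual_rms = map$residual_rms),
            class = "affine_map")
}

#' @export
print.affine_map <- function(x, ...) {
  cat("<affine_map> A = [", paste(signif(t(x$A), 6), collapse = ", "),
      "], b = (", paste(signif(x$b, 6), collapse = ", "),
      "), residual RMS = ", signif(x$residual_rms, 4), " um\n", sep = "")
  invisible(x)
}
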