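#' Field-of-view geometry for multifocal batches
#'
#' The defaults describe the instrument geometry: a 180 x 60 um field of
#' view addressable by the 1st-order beams around the central 0th-order
#' beam, a 10 um minimum vertical separation between sampling points (so
#' their dispersed spectra occupy disjoint CCD tracks), and 6 points per
#' batch. Six points at 10 um spacing pack a 60 um FOV height exactly.
#'
#' @param width,height FOV extent (um).
#' @param min_sep Minimum vertical separation (um).
#' @param batch_size Points per batch.
#' @return `fov_geometry` list.
#' @export
fov_geometry <- function(width = 180, height = 60, min_sep = 10,
                         batch_size = 6) {
  stopifnot(width > 0, height > 0, min_sep > 0, batch_size >= 1)
  if ((batch_size - 1) * min_sep > height) {
    stop("batch_size points at min_sep spacing cannot fit the FOV height")
  }
  structure(list(width = width, height = height, min_sep = min_sep,
                 batch_size = batch_size), class = "fov_geometry")
}

#' Assign the 0th-order beam within a batch
#'
#' Flags the member closest (Euclidean) to the centroid of the AF-derived
#' members as the 0th-order sampling point; random-fill members are excluded
#' from the centroid so padding cannot move the anchor. Ties break to the
#' lowest member index.
#'
#' @param members Tibble with `x_um`, `y_um`, `origin`.
#' @return The tibble with a logical `zero_order` column (exactly one TRUE).
#' @export
assign_zero_order <- function(members) {
  stopifnot(nrow(members) >= 1)
  af <- members$origin == "af"
  ref <- if (any(af)) members[af, ] else members
  cx <- mean(ref$x_um); cy <- mean(ref$y_um)
  d <- (members$x_um - cx)^2 + (members$y_um - cy)^2
  if (any(af)) d[!af] <- Inf
  members$zero_order <- seq_len(nrow(members)) == which.min(d)
  members
}

# anchored feasibility: can `members` (AF points) form one batch?
# needs: size <= batch_size; all within +-w/2, +-h/2 of the zero-order
# anchor; pairwise vertical gaps >= min_sep; enough residual vertical slots
# to pad up to batch_size.
batch_feasible <- function(members, geom) {
  m <- nrow(members)
  if (m > geom$batch_size) return(FALSE)
  a <- assign_zero_order(members)
  anch <- a[a$zero_order, ]
  if (any(abs(members$x_um - anch$x_um) > geom$width / 2 + 1e-9) ||
      any(abs(members$y_um - anch$y_um) > geom$height / 2 + 1e-9)) {
    return(FALSE)
  }
  ys <- sort(members$y_um)
  if (m > 1 && any(diff(ys) < geom$min_sep - 1e-9)) return(FALSE)
  pad_capacity(ys, anch$y_um, geom) >= geom$batch_size - m
}

# how many extra points with pairwise vertical gaps >= min_sep fit alongside
# the existing sorted ys inside the FOV anchored at y_anchor
pad_capacity <- function(ys, y_anchor, geom) {
  lo <- y_anchor - geom$height / 2
  hi <- y_anchor + geom$height / 2
  s <- geom$min_sep
  if (length(ys) == 0) return(floor((hi - lo) / s) + 1)
  gaps <- c(ys[1] - lo, diff(ys), hi - ys[length(ys)])
  inner <- if (length(ys) > 1) sum(pmax(0, floor(gaps[2:length(ys)] / s) - 1)) else 0
  floor(gaps[1] / s) + floor(gaps[length(gaps)] / s) + inner
}

# split AF members into feasible subgroups (recursive bisection by kmeans on
# y then coordinates); terminates at singletons, which are always feasible
split_until_feasible <- function(members, geom) {
  if (batch_feasible(members, geom)) return(list(members))
  if (nrow(members) == 1) return(list(members))
  ord <- order(members$y_um, members$x_um)
  half <- ceiling(nrow(members) / 2)
  a <- members[ord[seq_len(half)], ]
  b <- members[ord[-seq_len(half)], ]
  c(split_until_feasible(a, geom), split_until_feasible(b, geom))
}

#' Enforce CCD vertical separation within one batch
#'
#' AF-derived members are never moved: if two of them sit closer than
#' `min_sep` vertically (their spectra would overlap on the CCD), the batch
#' is split and every AF point preserved. Random-fill members are re-drawn
#' in feasible vertical slots. Returns a list of member tibbles (one per
#' resulting batch), each padded to the batch size.
#'
#' @param members Tibble with `x_um`, `y_um`, `origin`.
#' @param geom A [fov_geometry()].
#' @param seed Integer seed for the padding draws.
#' @param bounds Optional world bounds (`list(xlim =, ylim =)`) that padding
#'   points must also respect (e.g. the specimen extent).
#' @return List of member tibbles; each has `batch_size` rows, pairwise
#'   vertical gaps >= `min_sep`, and exactly one `zero_order` member.
#' @export
enforce_separation <- function(members, geom, seed = 1L, bounds = NULL) {
  af <- members[members$origin == "af", , drop = FALSE]
  groups <- split_until_feasible(af, geom)
  withr::with_seed(seed, lapply(groups, pad_batch, geom = geom,
                                bounds = bounds))
}

# pad one feasible AF group to batch_size with random in-FOV fills that
# respect the vertical separation; falls back to deterministic greedy slot
# packing if rejection sampling stalls
pad_batch <- function(af_members, geom, bounds = NULL, max_tries = 200) {
  b <- assign_zero_order(af_members)
  anch <- b[b$zero_order, ]
  need <- geom$batch_size - nrow(af_members)
  if (need <= 0) return(b)
  lo <- anch$y_um - geom$height / 2
  hi <- anch$y_um + geom$height / 2
  xlo <- anch$x_um - geom$width / 2
  xhi <- anch$x_um + geom$width / 2
  if (!is.null(bounds)) {
    ylo2 <- max(lo, bounds$ylim[1]); yhi2 <- min(hi, bounds$ylim[2])
    if (yhi2 - ylo2 >= (geom$batch_size - 1) * geom$min_sep) {
      lo <- ylo2; hi <- yhi2
    }
    xlo2 <- max(xlo, bounds$xlim[1]); xhi2 <- min(xhi, bounds$xlim[2])
    if (xhi2 > xlo2) { xlo <- xlo2; xhi <- xhi2 }
  }
  grid <- seq(lo, hi, by = 0.5)
  draw_fills <- function(random) {
    ys <- af_members$y_um
    picked <- numeric(0)
    for (i in seq_len(need)) {
      ok <- vapply(grid, function(g) all(abs(g - c(ys, picked)) >=
                                           geom$min_sep - 1e-9), logical(1))
      feas <- grid[ok]
      if (length(feas) == 0) return(NULL)
      picked <- c(picked, if (random) feas[sample.int(length(feas), 1)] else feas[1])
    }
    picked
  }
  fy <- NULL
  for (t in seq_len(max_tries)) {
    fy <- draw_fills(random = TRUE)
    if (!is.null(fy)) break
  }
  if (is.null(fy)) fy <- draw_fills(random = FALSE)
  if (is.null(fy)) stop("cannot pad batch: no feasible vertical slots")
  fills <- tibble::tibble(
    x_um = stats::runif(need, xlo, xhi),
    y_um = fy, segment_id = NA_integer_, origin = "fill")
  out <- dplyr::bind_rows(af_members, fills)
  assign_zero_order(out)
}

# deterministic farthest-point seeding: the first center is fixed by the
# seed, each further center is the point farthest from all chosen centers
farthest_point_centers <- function(xy, k, seed) {
  n <- nrow(xy)
  idx <- integer(k)
  idx[1] <- (abs(seed) %% n) + 1L
  d2 <- (xy[, 1] - xy[idx[1], 1])^2 + (xy[, 2] - xy[idx[1], 2])^2
  for (i in seq_len(k - 1L)) {
    idx[i + 1L] <- which.max(d2)
    d2 <- pmin(d2, (xy[, 1] - xy[idx[i + 1L], 1])^2 +
                 (xy[, 2] - xy[idx[i + 1L], 2])^2)
  }
  xy[idx, , drop = FALSE]
}

seeded_kmeans <- function(xy, k, seed) {
  if (k >= nrow(xy)) return(seq_len(nrow(xy)))
  centers <- farthest_point_centers(xy, k, seed)
  fit <- tryCatch(
    suppressWarnings(stats::kmeans(xy, centers = centers, iter.max = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    # degenerate geometry: fall back to nearest-seed assignment
    d <- outer(rowSums(xy^2), rowSums(centers^2), `+`) -
      2 * xy %*% t(centers)
    return(max.col(-d))
  }
  fit$cluster
}

#' Plan power-shared acquisition batches
#'
#' Groups sampling points into batches of `batch_size` that each fit one
#' FOV placement: k-means is run with k starting at `ceiling(N /
#' batch_size)` and incremented (deterministically re-seeded) until every
#' cluster is feasible — at most `batch_size` members, all within the FOV
#' anchored on the 0th-order member, vertical gaps compatible with the CCD
#' separation constraint. Short batches are padded with seeded random
#' in-FOV points so every batch carries the full beam count (keeping the
#' per-beam power share, and hence the power density on tissue, constant).
#'
#' @param points Tibble with `x_um`, `y_um` (and optionally `segment_id`).
#' @param geom A [fov_geometry()].
#' @param seed Integer seed.
#' @param bounds Optional world bounds for padding points
#'   (`list(xlim =, ylim =)`), e.g. the specimen extent.
#' @return `batch_plan`: list with `members` tibble (batch_id, member_idx,
#'   x_um, y_um, segment_id, origin, zero_order), `stage_targets` tibble,
#'   `geom`, `seed`, and `counts`.
#' @export
plan_batches <- function(points, geom = fov_geometry(), seed = 1L,
                         bounds = NULL) {
  points <- tibble::as_tibble(points)
  if (!"segment_id" %in% names(points)) points$segment_id <- NA_integer_
  points$origin <- "af"
  stopifnot(all(is.finite(points$x_um)), all(is.finite(points$y_um)))
  n <- nrow(points)
  if (n == 0) {
    return(structure(list(members = tibble::tibble(), stage_targets = tibble::tibble(),
                          geom = geom, seed = seed,
                          counts = list(n_af = 0L, n_fill = 0L, n_batches = 0L)),
                     class = "batch_plan"))
  }
  xy <- as.matrix(points[, c("x_um", "y_um")])
  k <- max(1L, ceiling(n / geom$batch_size))
  repeat {
    cl <- seeded_kmeans(xy, k, seed + k)
    feas <- vapply(split(seq_len(n), cl), function(idx)
      batch_feasible(points[idx, ], geom), logical(1))
    if (all(feas) || k >= n) break
    # every infeasible cluster needs at least one additional centroid
    k <- min(n, k + max(1L, sum(!feas)))
  }
  # deterministic batch order: by smallest original point index per cluster
  groups <- split(seq_len(n), cl)
  groups <- groups[order(vapply(groups, min, numeric(1)))]
  batches <- list()
  for (g in groups) {
    batches <- c(batches,
                 enforce_separation(points[g, ], geom,
                                    seed = seed + 7919L * (length(batches) + 1L),
                                    bounds = bounds))
  }
  members <- dplyr::bind_rows(lapply(seq_along(batches), function(i) {
    b <- batches[[i]]
    b$batch_id <- i
    b$member_idx <- seq_len(nrow(b))
    b
  }))
  members <- members[, c("batch_id", "member_idx", "x_um", "y_um",
                         "segment_id", "origin", "zero_order")]
  stage <- members |>
    dplyr::filter(.data$zero_order) |>
    dplyr::transmute(batch_id = .data$batch_id, x_um = .data$x_um,
                     y_um = .data$y_um)
  structure(list(members = members, stage_targets = stage, geom = geom,
                 seed = seed,
                 counts = list(n_af = sum(members$origin == "af"),
                               n_fill = sum(members$origin == "fill"),
                               n_batches = length(batches))),
            class = "batch_plan")
}

#' @export
print.batch_plan <- function(x, ...) {
  cat("<batch_plan> ", x$counts$n_batches, " batches (",
      x$counts$n_af, " AF points + ", x$counts$n_fill, " random fills = ",
      nrow(x$members), " sampling points)\n", sep = "")
  invisible(x)
}

#' Total acquisition time of a batch plan
#'
#' One CCD exposure per batch: `batches * t_int * overhead_multiplier`.
#' Stage moves, readout and hologram computation are not modelled
#' individually; the overhead multiplier stands in for them (in practice
#' such delays roughly double the raw exposure total).
#'
#' @param plan A `batch_plan`.
#' @param t_int Integration time per batch (s).
#' @param overhead_multiplier Dimensionless factor (default 1).
#' @return Seconds.
#' @export
estimate_acquisition_time <- function(plan, t_int, overhead_multiplier = 1) {
  stopifnot(t_int > 0)
  plan$counts$n_batches * t_int * overhead_multiplier
}

#' Per-beam excitation power under power sharing
#'
#' Divides the laser power delivered to the sample plane evenly over the
#' beams: `total_power_w * transmission / n_beams`, reported in mW.
#'
#' @param total_power_w Laser output power (W), default 3.6.
#' @param transmission Optical throughput from laser to sample plane,
#'   default 0.33.
#' @param n_beams Number of simultaneous beams, default 10.
#' @return Per-beam power in mW.
#' @export
power_per_beam <- function(total_power_w = 3.6, transmission = 0.33,
                           n_beams = 10) {
  stopifnot(total_power_w > 0, transmission > 0, transmission <= 1,
            n_beams >= 1)
  1000 * total_power_w * transmission / n_beams
}
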