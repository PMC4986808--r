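# brute-force single-threshold Otsu oracle: exhaustive scan over all
# candidate splits of the binned values
otsu1_oracle <- function(values, n_bins = 128) {
  edges <- seq(min(values), max(values), length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  bin <- pmin(n_bins, pmax(1, findInterval(values, edges,
                                           rightmost.closed = TRUE)))
  cnt <- tabulate(bin, n_bins)
  ss <- function(idx) {
    w <- sum(cnt[idx])
    if (w == 0) return(0)
    mu <- sum(cnt[idx] * mids[idx]) / w
    sum(cnt[idx] * (mids[idx] - mu)^2)
  }
  best <- which.min(vapply(2:n_bins, function(s)
    ss(1:(s - 1)) + ss(s:n_bins), numeric(1))) + 1
  edges[best]
}

test_that("a two-value image segments pixel-perfectly into 2 segments", {
  img <- matrix(50, 60, 60)
  disk <- outer((1:60 - 30)^2, (1:60 - 30)^2, `+`) <= 15^2
  img[disk] <- 200
  seg <- segment_af_image(img, n_levels = 2, min_area = 5)
  expect_equal(sort(unique(as.vector(seg$label))), c(0L, 1L))
  expect_identical(seg$label == 1L, disk)
})

test_that("the chosen threshold matches a brute-force variance minimizer", {
  set.seed(42)
  vals <- c(rnorm(4000, 60, 12), rnorm(2000, 150, 15))
  vals <- pmax(0, vals)
  thr <- otsu_thresholds(vals, 2)
  expect_equal(thr, otsu1_oracle(vals), tolerance = 1e-12)
  # multi-level solution beats any 1-level split in pooled variance terms
  img <- matrix(vals[1:3600], 60, 60)
  seg <- segment_af_image(img, n_levels = 2, min_area = 1)
  expect_gt(sum(seg$summary$segment_id >= 0), 0)
})

test_that("a constant image yields one segment with a warning", {
  expect_warning(seg <- segment_af_image(matrix(7, 20, 20), n_levels = 3),
                 "constant")
  expect_equal(unique(as.vector(seg$label)), 0L)
  expect_equal(nrow(seg$summary), 1)
})

test_that("segmentation is invariant to monotone affine intensity rescaling", {
  ph <- test_phantom(seed = 5)
  a <- segment_af_image(ph$af, n_levels = 3, min_area = 40)
  b <- segment_af_image(ph$af * 3.7 + 11, n_levels = 3, min_area = 40)
  expect_identical(a$label, b$label)
})

test_that("per-segment point counts follow area x density x priority", {
  img <- matrix(10, 100, 100)
  img[10:49, 10:89] <- 200   # 40x80 = 3200 px
  img[70:89, 10:49] <- 200   # 20x40 = 800 px  (area ratio 4:1)
  seg <- segment_af_image(img, n_levels = 2, min_area = 5, pixel_size = 10)
  segs <- seg$summary[seg$summary$segment_id > 0, ]
  expect_equal(sort(segs$area_px), c(800, 3200))
  # equal AF means -> equal priority; min 0 via min_per_segment = 0
  pts <- generate_sampling_points(seg, density = 100, min_per_segment = 0,
                                  priority_exponent = 0, seed = 3)
  n_by_seg <- table(pts$segment_id)
  big <- which.max(segs$area_px)
  ratio <- as.numeric(n_by_seg[as.character(segs$segment_id[big])]) /
    as.numeric(n_by_seg[as.character(segs$segment_id[-big][1])])
  expect_equal(ratio, 4, tolerance = 0.35) # +-1 point on the small segment
})

test_that("a single requested point sits at the segment interior pole", {
  img <- matrix(10, 50, 50)
  img[20:30, 20:30] <- 200
  seg <- segment_af_image(img, n_levels = 2, min_area = 5, pixel_size = 2)
  pts <- generate_sampling_points(seg, density = 1e-9, min_per_segment = 1,
                                  seed = 1)
  expect_equal(nrow(pts), 1)
  # center of the 11x11 square, pixel centers at half-integers
  expect_equal(pts$x_um, (25 - 0.5) * 2, tolerance = 2)
  expect_equal(pts$y_um, (25 - 0.5) * 2, tolerance = 2)
})

test_that("all sampling points lie inside their segment; sampling is seeded", {
  ph <- test_phantom(seed = 6)
  seg <- segment_af_image(ph$af, n_levels = 3, min_area = 40, pixel_size = 5)
  pts <- generate_sampling_points(seg, density = 150, min_per_segment = 2,
                                  seed = 7)
  col <- ceiling(pts$x_um / 5); row <- ceiling(pts$y_um / 5)
  expect_true(all(seg$label[cbind(row, col)] == pts$segment_id))
  pts2 <- generate_sampling_points(seg, density = 150, min_per_segment = 2,
                                   seed = 7)
  expect_identical(pts, pts2)
})

test_that("affine transform recovers rotation + scale + translation exactly", {
  th <- 17 * pi / 180; sc <- 1.6
  A <- sc * rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  b <- c(250, -80)
  set.seed(1)
  src <- matrix(runif(20, 0, 1000), ncol = 2)
  dst <- t(A %*% t(src) + b)
  pairs <- tibble::tibble(x_src = src[, 1], y_src = src[, 2],
                          x_dst = dst[, 1], y_dst = dst[, 2])
  fit <- fit_coordinate_transform(pairs)
  expect_equal(fit$A, A, tolerance = 1e-6)
  expect_equal(fit$b, b, tolerance = 1e-6)
  expect_lt(fit$residual_rms, 1e-9)
  # identity pairs
  idp <- tibble::tibble(x_src = c(0, 1, 0), y_src = c(0, 0, 1),
                        x_dst = c(0, 1, 0), y_dst = c(0, 0, 1))
  fid <- fit_coordinate_transform(idp)
  expect_equal(fid$A, diag(2), tolerance = 1e-12)
  expect_equal(fid$b, c(0, 0), tolerance = 1e-12)
})

test_that("noisy-landmark residual RMS matches the normal-equations oracle", {
  set.seed(8)
  src <- matrix(runif(20, 0, 500), ncol = 2)
  A <- rbind(c(1.2, 0.1), c(-0.05, 0.9)); b <- c(10, -5)
  dst <- t(A %*% t(src) + b) + matrix(rnorm(20, 0, 1), ncol = 2)
  pairs <- tibble::tibble(x_src = src[, 1], y_src = src[, 2],
                          x_dst = dst[, 1], y_dst = dst[, 2])
  fit <- fit_coordinate_transform(pairs)
  # oracle: explicit normal equations
  X <- cbind(1, src)
  bx <- solve(t(X) %*% X, t(X) %*% dst[, 1])
  by <- solve(t(X) %*% X, t(X) %*% dst[, 2])
  rss <- sum((dst[, 1] - X %*% bx)^2) + sum((dst[, 2] - X %*% by)^2)
  expect_equal(fit$residual_rms, sqrt(rss / (2 * nrow(src))),
               tolerance = 1e-10)
})

test_that("degenerate landmark sets are rejected", {
  two <- tibble::tibble(x_src = c(0, 1), y_src = c(0, 0),
                        x_dst = c(0, 1), y_dst = c(0, 0))
  expect_error(fit_coordinate_transform(two), "at least 3")
  col <- tibble::tibble(x_src = c(0, 1, 2), y_src = c(0, 1, 2),
                        x_dst = c(0, 1, 2), y_dst = c(0, 1, 2))
  expect_error(fit_coordinate_transform(col), "collinear")
})

test_that("transform round-trips to 1e-9 on 1000 random points", {
  set.seed(9)
  src <- matrix(runif(12, 0, 800), ncol = 2)
  A <- rbind(c(1.4, 0.2), c(-0.1, 1.1)); b <- c(33, -12)
  dst <- t(A %*% t(src) + b)
  fit <- fit_coordinate_transform(tibble::tibble(
    x_src = src[, 1], y_src = src[, 2], x_dst = dst[, 1], y_dst = dst[, 2]))
  pts <- tibble::tibble(x_um = runif(1000, -1e3, 1e3),
                        y_um = runif(1000, -1e3, 1e3))
  back <- apply_transform(invert_transform(fit), apply_transform(fit, pts))
  expect_lt(max(abs(back$x_um - pts$x_um), abs(back$y_um - pts$y_um)), 1e-9)
})
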