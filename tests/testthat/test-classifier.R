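test_that("band areas vanish on straight lines and scale linearly", {
  nu <- seq(600, 1800)
  line <- 3 + 0.01 * nu
  a <- band_areas(nu, line)
  expect_true(all(abs(a) < 1e-9))
  set.seed(1)
  y <- runif(length(nu))
  expect_equal(band_areas(nu, 3 * y), 3 * band_areas(nu, y),
               tolerance = 1e-12)
})

test_that("A4 of a phenylalanine-like Gaussian matches a numerical oracle", {
  nu <- seq(600, 1800)
  y <- exp(-(nu - 1001)^2 / (2 * 25))
  a <- band_areas(nu, y)
  # oracle: fine-grid Riemann integral of the analytically
  # baseline-subtracted band over the A4 window
  fine <- seq(993, 1022, by = 0.01)
  g <- function(x) exp(-(x - 1001)^2 / (2 * 25))
  xs <- nu[nu >= 993 & nu <= 1022]
  n <- length(xs)
  xa <- mean(xs[1:3]); ya <- mean(g(xs[1:3]))
  xb <- mean(xs[(n - 2):n]); yb <- mean(g(xs[(n - 2):n]))
  base <- function(x) ya + (x - xa) * (yb - ya) / (xb - xa)
  want <- sum((g(fine) - base(fine)) * 0.01)
  expect_equal(a[["A4"]], want, tolerance = 0.01)
  # other windows essentially empty
  expect_true(all(abs(a[c("A1", "A2", "A5", "A6", "A7")]) < 0.05 * a[["A4"]]))
})

test_that("feature ratios are ordered, scale-invariant, and guard zeros", {
  areas <- c(A1 = 2, A2 = 4, A3 = 6, A4 = 2, A5 = 8, A6 = 3, A7 = 6)
  r <- feature_ratios(areas)
  expect_equal(as.numeric(r), c(1, 2, 3, 4, 0.5))
  expect_equal(feature_ratios(areas * 7), r, tolerance = 1e-12)
  same <- feature_ratios(c(A1 = 5, A2 = 5, A3 = 5, A4 = 5, A5 = 5, A6 = 5,
                           A7 = 5))
  expect_equal(as.numeric(same), rep(1, 5))
  bad <- feature_ratios(c(A1 = 1, A2 = 1, A3 = 1, A4 = 0, A5 = 1, A6 = 1,
                          A7 = 1))
  expect_true(all(is.na(bad)))
  expect_true(attr(bad, "unclassifiable"))
})

test_that("ratios computed on random spectra match the by-hand composition", {
  set.seed(2)
  nu <- seq(600, 1800)
  sp <- tibble::tibble(beam_id = 1:3,
                       wavenumber = rep(list(nu), 3),
                       intensity = lapply(1:3, function(i)
                         runif(length(nu))))
  f <- band_features(sp)
  for (i in 1:3) {
    r <- feature_ratios(band_areas(nu, sp$intensity[[i]]))
    expect_equal(as.numeric(unlist(f[i, paste0("r", 1:5)])),
                 as.numeric(r))
  }
})

test_that("PCA screen keeps a homogeneous set and catches spiked fat", {
  set.seed(3)
  sp <- simulate_labelled_spectra(60, classes = "dermis", seed = 4)
  scr <- pca_screen(sp, test_lib)
  expect_true(all(scr$screen_label == "keep"))
  # 5% fat-basis spectra spiked into dermis
  spk <- simulate_labelled_spectra(3, classes = "fat", seed = 5)
  mix <- dplyr::bind_rows(sp, spk)
  scr2 <- pca_screen(mix, test_lib)
  expect_gte(mean(scr2$screen_label[61:63] == "fat"), 0.9)
  # false-removal rate on the dermis majority stays low
  expect_lt(mean(scr2$screen_label[1:60] != "keep"), 0.1)
  # determinism
  scr3 <- pca_screen(mix, test_lib)
  expect_identical(scr2$screen_label, scr3$screen_label)
  expect_error(pca_screen(sp[1:5, ], test_lib), "at least 10")
})

test_that("reference-map clustering recovers a two-class raster", {
  set.seed(6)
  n <- 16
  truth <- matrix(1L, n, n); truth[, (n / 2 + 1):n] <- 2L
  sp <- simulate_labelled_spectra(n * n / 2,
                                  classes = c("dermis", "fat"), seed = 7)
  X <- rbind(do.call(rbind, sp$intensity[sp$class == "dermis"]),
             do.call(rbind, sp$intensity[sp$class == "fat"]))
  lab <- cluster_reference_map(X, k = 2, grid_dim = c(n, n), seed = 8)
  agree <- max(mean(lab == truth), mean(lab == 3L - truth))
  expect_gte(agree, 0.99)
  expect_identical(lab, cluster_reference_map(X, 2, c(n, n), seed = 8))
  one <- cluster_reference_map(X, 1, c(n, n), seed = 8)
  expect_true(all(one == 1L))
})

test_that("linearly separable classes are classified perfectly in CV", {
  set.seed(9)
  n <- 60
  feats <- tibble::tibble(
    class = rep(c("bcc", "epidermis", "dermis"), each = n),
    r1 = c(rnorm(n, 5, 0.1), rnorm(n, 0, 0.1), rnorm(n, 0, 0.1)),
    r2 = c(rnorm(n, 0, 0.1), rnorm(n, 5, 0.1), rnorm(n, 0, 0.1)),
    r3 = c(rnorm(n, 0, 0.1), rnorm(n, 0, 0.1), rnorm(n, 5, 0.1)),
    r4 = rnorm(3 * n, 1, 0.1), r5 = rnorm(3 * n, 1, 0.1))
  m <- train_classifier(feats, seed = 1)
  rep <- m$cv_report[m$cv_report$lambda == m$lambda, ]
  expect_equal(mean(rep$sensitivity), 1)
  expect_equal(mean(rep$specificity), 1)
  # prototype feature vectors come back as their own class
  out <- classify(m, feats)
  expect_equal(out$call, feats$class)
})

test_that("the selected regularization matches an independent grid-scan", {
  feats <- simulate_labelled_features(60, seed = 21)
  m <- train_classifier(feats, seed = 2)
  # oracle: re-run the fold loop with glmnet directly and apply the
  # stated selection rule (max specificity s.t. mean sensitivity >= target)
  rc <- paste0("r", 1:5)
  X <- as.matrix(feats[, rc])
  y <- factor(feats$class, levels = c("bcc", "epidermis", "dermis"))
  fold <- ramanmsi:::stratified_folds(y, 5, seed = 2)
  grid <- 10^seq(-5, 0, length.out = 12)
  res <- expand.grid(lambda = grid, fold = 1:5)
  perf <- lapply(seq_len(nrow(res)), function(i) {
    lam <- res$lambda[i]; f <- res$fold[i]
    tr <- fold != f
    fit <- glmnet::glmnet(X[tr, ], y[tr], family = "multinomial",
                          alpha = 0, lambda = lam, standardize = TRUE)
    pr <- function(M) {
      p <- predict(fit, M, s = lam, type = "response")[, , 1]
      p[, "bcc"]
    }
    thr <- ramanmsi:::bcc_threshold_from(pr(X[tr, ])[y[tr] == "bcc"],
                                         pr(X[tr, ])[y[tr] != "bcc"], 0.95)
    c(sens = mean(pr(X[!tr, , drop = FALSE])[y[!tr] == "bcc"] >= thr),
      spec = mean(pr(X[!tr, , drop = FALSE])[y[!tr] != "bcc"] < thr))
  })
  perf <- cbind(res, do.call(rbind, perf))
  agg <- stats::aggregate(cbind(sens, spec) ~ lambda, perf, mean)
  ok <- agg$sens >= 0.95
  want <- if (any(ok)) agg$lambda[ok][which.max(agg$spec[ok])] else
    agg$lambda[which.max(agg$sens)]
  expect_equal(m$lambda, want)
})

test_that("class probabilities normalize and match the stored weights", {
  feats <- simulate_labelled_features(40, seed = 22)
  m <- train_classifier(feats, seed = 3)
  out <- classify(m, feats)
  psum <- out$p_bcc + out$p_epidermis + out$p_dermis
  expect_true(all(abs(psum - 1) < 1e-12))
  # oracle: evaluate the stored weights by hand for a few rows
  X <- as.matrix(feats[1:5, paste0("r", 1:5)])
  eta <- cbind(1, X) %*% m$weights
  p <- exp(eta) / rowSums(exp(eta))
  expect_equal(out$p_bcc[1:5], unname(p[, "bcc"]), tolerance = 1e-10)
  want <- ifelse(p[, "bcc"] >= m$threshold, "bcc",
                 c("epidermis", "dermis")[max.col(p[, 2:3])])
  expect_equal(out$call[1:5], unname(want))
})

test_that("tidy and glance expose the fitted model", {
  feats <- simulate_labelled_features(40, seed = 23)
  m <- train_classifier(feats, seed = 4)
  td <- tidy(m)
  expect_equal(nrow(td), 18) # 3 classes x (intercept + 5 ratios)
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("lambda", "threshold", "cv_sensitivity") %in% names(gl)))
})

test_that("segment averaging equals the single-spectrum path for replicas", {
  sp1 <- simulate_labelled_spectra(1, classes = "bcc", seed = 24)
  feats <- simulate_labelled_features(150, seed = 25)
  m <- train_classifier(feats, seed = 5)
  reps <- dplyr::bind_rows(sp1, sp1, sp1)
  reps$segment_id <- 1L
  diag <- segment_average_classify(reps, m)
  single <- classify(m, tibble::as_tibble(as.list(
    feature_ratios(band_areas(sp1$wavenumber[[1]], sp1$intensity[[1]])))))
  expect_equal(diag$call, single$call)
  expect_equal(diag$p_bcc, single$p_bcc, tolerance = 1e-12)
})

test_that("averaging n noisy replicates shrinks residual noise like 1/sqrt(n)", {
  set.seed(26)
  nu <- seq(600, 1800)
  base <- sin(nu / 120)
  n <- 16; sigma <- 1
  ratio <- replicate(100, {
    reps <- lapply(1:n, function(i) base + rnorm(length(nu), 0, sigma))
    avg <- Reduce(`+`, reps) / n
    sd(avg - base)
  })
  expect_equal(mean(ratio), sigma / sqrt(n), tolerance = 0.2)
})

test_that("segments whose spectra all fail QC come back unmeasured", {
  sp <- simulate_labelled_spectra(4, classes = "dermis", seed = 27)
  sp$segment_id <- c(1L, 1L, 2L, 2L)
  sp$saturated <- c(FALSE, FALSE, TRUE, TRUE)
  feats <- simulate_labelled_features(150, seed = 25)
  m <- train_classifier(feats, seed = 5)
  diag <- segment_average_classify(sp, m)
  expect_true(diag$measured[diag$segment_id == 1])
  expect_false(diag$measured[diag$segment_id == 2])
  expect_true(is.na(diag$call[diag$segment_id == 2]))
})

test_that("feature pipeline is invariant to added straight lines per spectrum", {
  set.seed(28)
  nu <- seq(600, 1800)
  y <- runif(length(nu)) + exp(-(nu - 1001)^2 / 50)
  r0 <- feature_ratios(band_areas(nu, y))
  r1 <- feature_ratios(band_areas(nu, y + 5 + 0.003 * nu))
  expect_equal(r0, r1, tolerance = 1e-6)
  r2 <- feature_ratios(band_areas(nu, 4 * y))
  expect_equal(r0, r2, tolerance = 1e-9)
})
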