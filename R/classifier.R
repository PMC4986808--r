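#' Diagnostic band windows
#'
#' The seven fingerprint-region integration windows used for the band-area
#' features. A2 (843-865) lies inside A3 (825-946); both are integrated as
#' defined, without de-overlapping.
#' @return Tibble: `band`, `lo`, `hi` (cm^-1).
#' @export
band_windows <- function() {
  tibble::tibble(
    band = paste0("A", 1:7),
    lo = c(772, 843, 825, 993, 1070, 1235, 1279),
    hi = c(800, 865, 946, 1022, 1115, 1279, 1327))
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Band areas under local linear baselines
#'
#' For each window, subtracts the straight line through the mean of the 3
#' samples at each window edge and trapezoid-integrates the residual. A
#' straight-line spectrum therefore has zero area in every window, and
#' areas scale linearly with the spectrum.
#'
#' @param nu,y Wavenumber axis and intensities of one spectrum; the axis
#'   must cover 772-1327 cm^-1.
#' @return Named numeric vector A1..A7 (intensity x cm^-1).
#' @export
band_areas <- function(nu, y) {
  w <- band_windows()
  out <- stats::setNames(numeric(nrow(w)), w$band)
  for (i in seq_len(nrow(w))) {
    idx <- which(nu >= w$lo[i] & nu <= w$hi[i])
    if (length(idx) < 7 || min(nu) > w$lo[i] || max(nu) < w$hi[i]) {
      stop("spectrum does not cover band window ", w$band[i],
           " (", w$lo[i], "-", w$hi[i], " cm^-1)")
    }
    xs <- nu[idx]; ys <- y[idx]
    n <- length(ys)
    xa <- mean(xs[1:3]); ya <- mean(ys[1:3])
    xb <- mean(xs[(n - 2):n]); yb <- mean(ys[(n - 2):n])
    base <- ya + (xs - xa) * (yb - ya) / (xb - xa)
    out[i] <- trapz(xs, ys - base)
  }
  out
}

#' Band-area ratio features
#'
#' The five scale-invariant ratios `A1/A4, A2/A4, A3/A4, A5/A4, A6/A7`. A
#' spectrum with a zero denominator is unclassifiable (`NA` ratios).
#'
#' @param areas Named vector from [band_areas()].
#' @return Named numeric vector r1..r5; attribute `unclassifiable`.
#' @export
feature_ratios <- function(areas) {
  bad <- areas[["A4"]] == 0 || areas[["A7"]] == 0
  r <- if (bad) rep(NA_real_, 5) else c(
    areas[["A1"]] / areas[["A4"]], areas[["A2"]] / areas[["A4"]],
    areas[["A3"]] / areas[["A4"]], areas[["A5"]] / areas[["A4"]],
    areas[["A6"]] / areas[["A7"]])
  names(r) <- paste0("r", 1:5)
  attr(r, "unclassifiable") <- bad
  r
}

#' Band features for a spectra tibble
#'
#' Computes A1..A7 and r1..r5 per spectrum and appends them as columns.
#'
#' @param spectra A spectra tibble with `wavenumber` and `intensity`.
#' @return The tibble with columns A1..A7, r1..r5, `unclassifiable`.
#' @export
band_features <- function(spectra) {
  feats <- lapply(seq_len(nrow(spectra)), function(i) {
    a <- band_areas(spectra$wavenumber[[i]], spectra$intensity[[i]])
    r <- feature_ratios(a)
    c(as.list(a), as.list(r), list(unclassifiable = attr(r, "unclassifiable")))
  })
  dplyr::bind_cols(spectra, dplyr::bind_rows(lapply(feats, tibble::as_tibble)))
}

#' PCA screen for dye- and fat-dominated spectra
#'
#' Scores every normalized spectrum on a small set of leading principal
#' components (signs fixed by making each loading's largest-magnitude
#' element positive) and flags scores beyond `median +- m * MAD` on any of
#' them as candidates for removal. A flagged spectrum is labelled `dye` or
#' `fat` when its spectrum correlates best with the broad dye-emission or
#' lipid reference signature; flagged spectra that still match a
#' tissue-class signature best (minority tissue classes also produce
#' extreme PC scores) are kept. Everything else is labelled `keep`.
#'
#' Which components carry the dye and fat contrasts depends on the
#' composition of the spectra set (with strong baseline variability they
#' are typically the second and third); the default screens the first
#' three so the contrast is caught wherever it lands.
#'
#' @param spectra A normalized spectra tibble (>= 10 rows, common axis).
#' @param lib A [build_spectral_library()] (for the reference signatures).
#' @param m MAD multiplier for the outlier cutoff (default 4).
#' @param components Principal components to threshold (default 1:3).
#' @return The tibble with a `screen_label` column.
#' @export
pca_screen <- function(spectra, lib = build_spectral_library(), m = 4,
                       components = 1:3) {
  n <- nrow(spectra)
  if (n < 10) stop("PCA screen needs at least 10 spectra")
  X <- do.call(rbind, spectra$intensity)
  if (anyNA(X)) stop("spectra contain NA intensities")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  nu <- spectra$wavenumber[[1]]
  sig <- function(cls) {
    s <- stats::approx(lib$axis, lib$basis[, cls], xout = nu)$y
    if (cls == "dye") s <- s + 6 * fluor_shape(nu) # dye rides on broad emission
    (s - mean(s)) / stats::sd(s)
  }
  refs <- vapply(c("bcc", "epidermis", "dermis", "fat", "dye"), sig,
                 numeric(length(nu)))
  zmat <- matrix(0, n, length(components))
  for (j in seq_along(components)) {
    load <- pc$rotation[, components[j]]
    if (load[which.max(abs(load))] < 0) load <- -load
    score <- X %*% load
    med <- stats::median(score)
    s <- stats::mad(score)
    zmat[, j] <- if (s > 0) abs(score - med) / s else 0
  }
  flagged <- apply(zmat, 1, max) > m
  labels <- rep("keep", n)
  if (any(flagged)) {
    cors <- stats::cor(t(X[flagged, , drop = FALSE]), refs)
    best <- colnames(refs)[max.col(cors)]
    labels[flagged] <- ifelse(best %in% c("dye", "fat"), best, "keep")
  }
  spectra$screen_label <- labels
  spectra
}

#' k-means clustering of a raster Raman map
#'
#' Clusters normalized raster-scan spectra (for example a 960 x 960 um map
#' at 15 um steps, 64 x 64 spectra) into k groups; the resulting label
#' image is compared with an adjacent-section annotation to assign training
#' labels.
#'
#' @param spec_matrix Spectra in rows.
#' @param k Number of clusters.
#' @param grid_dim `c(nrow, ncol)` of the raster (prod must equal nrow of
#'   the matrix).
#' @param seed Integer seed.
#' @return Integer label matrix of shape `grid_dim`.
#' @export
cluster_reference_map <- function(spec_matrix, k, grid_dim, seed = 1L) {
  stopifnot(prod(grid_dim) == nrow(spec_matrix), k >= 1)
  cl <- if (k == 1) rep(1L, nrow(spec_matrix)) else withr::with_seed(seed, {
    stats::kmeans(spec_matrix, centers = k, nstart = 5, iter.max = 100)$cluster
  })
  matrix(cl, nrow = grid_dim[1], ncol = grid_dim[2])
}

softmax_rows <- function(eta) {
  m <- apply(eta, 1, max)
  e <- exp(eta - m)
  e / rowSums(e)
}

model_probs <- function(model, X) {
  eta <- cbind(1, X) %*% model$weights
  p <- softmax_rows(eta)
  colnames(p) <- colnames(model$weights)
  p
}

# BCC-vs-rest operating point: the threshold on P(BCC) maximizing training
# specificity subject to training sensitivity >= target; specificity ties
# break toward the lower threshold (higher sensitivity)
bcc_threshold_from <- function(p_pos, p_neg, target) {
  cand <- sort(unique(c(p_pos, p_neg)))
  sens <- vapply(cand, function(t) mean(p_pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(p_neg < t), numeric(1))
  feas <- sens >= target
  if (!any(feas)) feas <- sens == max(sens)
  best <- max(spec[feas])
  thr <- min(cand[feas & spec == best])
  below <- cand[cand < thr]
  if (length(below) > 0) thr <- (thr + max(below)) / 2 # mid-gap margin
  min(max(thr, 1e-6), 1 - 1e-6)
}

stratified_folds <- function(y, folds, seed) {
  withr::with_seed(seed, {
    f <- integer(length(y))
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < folds) {
        stop("class ", cl, " has fewer members than folds")
      }
      f[idx] <- sample(rep(seq_len(folds), length.out = length(idx)))
    }
    f
  })
}

fit_multinomial <- function(X, y, lambda) {
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                        lambda = lambda, standardize = TRUE)
  co <- stats::coef(fit, s = lambda)
  W <- vapply(co, function(b) as.numeric(b), numeric(ncol(X) + 1))
  colnames(W) <- names(co)
  W
}

#' Train the band-ratio multinomial classifier
#'
#' Ridge-regularized multinomial logistic regression of class (BCC,
#' epidermis, dermis) on the five band-area ratios. The regularization
#' strength is selected over a lambda grid by 5-fold stratified
#' cross-validation, maximizing mean fold specificity subject to mean fold
#' sensitivity >= `target_sensitivity`; within each fold the BCC-vs-rest
#' decision threshold on P(BCC) is tuned on the training portion to the
#' sensitivity target. The final model is refitted on all data at the
#' chosen lambda, with the threshold tuned the same way on the full
#' training set.
#'
#' @param features Tibble with columns r1..r5 and `class` (must contain
#'   bcc, epidermis, dermis).
#' @param folds Number of CV folds.
#' @param target_sensitivity BCC sensitivity target (default 0.95).
#' @param lambda_grid Ridge penalty grid.
#' @param seed Integer seed (fold assignment).
#' @return `raman_classifier`: list with `weights` (6 x 3), `lambda`,
#'   `threshold`, `classes`, `cv_report` tibble, `target_sensitivity`.
#' @export
train_classifier <- function(features, folds = 5, target_sensitivity = 0.95,
                             lambda_grid = 10^seq(-5, 0, length.out = 12),
                             seed = 1L) {
  features <- tibble::as_tibble(features)
  rc <- paste0("r", 1:5)
  stopifnot(all(rc %in% names(features)), "class" %in% names(features))
  keep <- stats::complete.cases(features[, rc])
  features <- features[keep, ]
  y <- factor(features$class, levels = c("bcc", "epidermis", "dermis"))
  if (any(is.na(y)) || nlevels(droplevels(y)) < 3) {
    stop("features must contain the classes bcc, epidermis and dermis")
  }
  X <- as.matrix(features[, rc])
  if (!all(is.finite(X))) stop("non-finite feature values")
  fold <- stratified_folds(y, folds, seed)
  report <- list()
  for (lam in lambda_grid) {
    for (f in seq_len(folds)) {
      tr <- fold != f
      W <- fit_multinomial(X[tr, ], y[tr], lam)
      model_f <- list(weights = W)
      p_tr <- model_probs(model_f, X[tr, ])[, "bcc"]
      thr <- bcc_threshold_from(p_tr[y[tr] == "bcc"],
                                p_tr[y[tr] != "bcc"], target_sensitivity)
      p_te <- model_probs(model_f, X[!tr, , drop = FALSE])[, "bcc"]
      yte <- y[!tr]
      report[[length(report) + 1]] <- tibble::tibble(
        lambda = lam, fold = f, threshold = thr,
        sensitivity = mean(p_te[yte == "bcc"] >= thr),
        specificity = mean(p_te[yte != "bcc"] < thr))
    }
  }
  report <- dplyr::bind_rows(report)
  summ <- report |>
    dplyr::group_by(.data$lambda) |>
    dplyr::summarise(sensitivity = mean(.data$sensitivity),
                     specificity = mean(.data$specificity),
                     .groups = "drop")
  ok <- summ$sensitivity >= target_sensitivity
  best_lambda <- if (any(ok)) {
    summ$lambda[ok][which.max(summ$specificity[ok])]
  } else {
    summ$lambda[order(-summ$sensitivity, -summ$specificity)][1]
  }
  W <- fit_multinomial(X, y, best_lambda)
  p_all <- model_probs(list(weights = W), X)[, "bcc"]
  thr <- bcc_threshold_from(p_all[y == "bcc"], p_all[y != "bcc"],
                            target_sensitivity)
  structure(list(weights = W, lambda = best_lambda, threshold = thr,
                 classes = levels(y), cv_report = report,
                 cv_summary = summ,
                 target_sensitivity = target_sensitivity, seed = seed),
            class = "raman_classifier")
}

#' @export
print.raman_classifier <- function(x, ...) {
  s <- x$cv_summary[x$cv_summary$lambda == x$lambda, ]
  cat("<raman_classifier> lambda = ", signif(x$lambda, 3),
      ", BCC threshold = ", signif(x$threshold, 3),
      "; CV sensitivity ", round(100 * s$sensitivity, 1),
      "%, specificity ", round(100 * s$specificity, 1), "%\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.raman_classifier <- function(x, ...) {
  w <- x$weights
  tibble::tibble(class = rep(colnames(w), each = nrow(w)),
                 term = rep(c("(Intercept)", paste0("r", 1:5)), ncol(w)),
                 estimate = as.vector(w))
}

#' @export
glance.raman_classifier <- function(x, ...) {
  s <- x$cv_summary[x$cv_summary$lambda == x$lambda, ]
  tibble::tibble(lambda = x$lambda, threshold = x$threshold,
                 cv_sensitivity = s$sensitivity,
                 cv_specificity = s$specificity,
                 target_sensitivity = x$target_sensitivity)
}

#' Classify band-ratio features
#'
#' Calls BCC whenever P(BCC) >= the model's sensitivity-tuned threshold,
#' otherwise the most probable of the remaining classes. Unclassifiable
#' feature rows (NA ratios) propagate as `NA` calls.
#'
#' @param model A [train_classifier()] fit.
#' @param features Tibble (or data frame) with columns r1..r5.
#' @return Tibble: `call`, `probability` (of the call), `p_bcc`,
#'   `p_epidermis`, `p_dermis`.
#' @export
classify <- function(model, features) {
  rc <- paste0("r", 1:5)
  X <- as.matrix(tibble::as_tibble(features)[, rc])
  out <- tibble::tibble(call = rep(NA_character_, nrow(X)),
                        probability = NA_real_, p_bcc = NA_real_,
                        p_epidermis = NA_real_, p_dermis = NA_real_)
  ok <- stats::complete.cases(X)
  if (any(ok)) {
    p <- model_probs(model, X[ok, , drop = FALSE])
    call <- ifelse(p[, "bcc"] >= model$threshold, "bcc",
                   model$classes[-1][max.col(p[, c("epidermis", "dermis"),
                                               drop = FALSE])])
    out$call[ok] <- call
    out$p_bcc[ok] <- p[, "bcc"]
    out$p_epidermis[ok] <- p[, "epidermis"]
    out$p_dermis[ok] <- p[, "dermis"]
    out$probability[ok] <- p[cbind(seq_len(sum(ok)),
                                   match(call, colnames(p)))]
  }
  out
}

#' Segment-averaged diagnosis
#'
#' Implements the segment-level decision: per AF segment, QC-failed spectra
#' are dropped, dye/fat-screened spectra vote directly for those calls, the
#' surviving spectra are averaged into a single spectrum whose band
#' features are classified by the model. Segments with no usable spectra
#' are marked unmeasured.
#'
#' @param spectra Preprocessed spectra tibble with `segment_id`,
#'   `wavenumber`, `intensity`, `saturated`, optionally `screen_label`.
#' @param model A [train_classifier()] fit.
#' @return `diagnosis_map` tibble: `segment_id`, `n_spectra`, `n_used`,
#'   `call`, `probability`, `p_bcc`, `measured`.
#' @export
segment_average_classify <- function(spectra, model) {
  stopifnot("segment_id" %in% names(spectra))
  if (!"screen_label" %in% names(spectra)) spectra$screen_label <- "keep"
  segs <- sort(unique(spectra$segment_id))
  rows <- lapply(segs, function(id) {
    sub <- spectra[spectra$segment_id == id, ]
    usable <- !sub$saturated
    sub <- sub[usable, ]
    base <- tibble::tibble(segment_id = id, n_spectra = length(usable),
                           n_used = nrow(sub))
    if (nrow(sub) == 0) {
      return(dplyr::bind_cols(base, tibble::tibble(
        call = NA_character_, probability = NA_real_, p_bcc = NA_real_,
        measured = FALSE)))
    }
    scr <- table(sub$screen_label)
    dom <- names(scr)[which.max(scr)]
    if (dom %in% c("dye", "fat") && scr[dom] > nrow(sub) / 2) {
      return(dplyr::bind_cols(base, tibble::tibble(
        call = dom, probability = NA_real_, p_bcc = NA_real_,
        measured = TRUE)))
    }
    sub <- sub[sub$screen_label == "keep", ]
    if (nrow(sub) == 0) {
      return(dplyr::bind_cols(base, tibble::tibble(
        call = NA_character_, probability = NA_real_, p_bcc = NA_real_,
        measured = FALSE)))
    }
    avg <- Reduce(`+`, sub$intensity) / nrow(sub)
    nu <- sub$wavenumber[[1]]
    r <- feature_ratios(band_areas(nu, avg))
    res <- classify(model, tibble::as_tibble(as.list(r)))
    dplyr::bind_cols(base, tibble::tibble(
      call = res$call, probability = res$probability, p_bcc = res$p_bcc,
      measured = !is.na(res$call)))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("diagnosis_map", class(out))
  out
}

#' Render a diagnosis map over the segment image
#'
#' @param diagnosis A [segment_average_classify()] result.
#' @param seg The [segment_af_image()] map the spectra came from.
#' @return Integer matrix of class codes (see [phantom_class_names()]);
#'   unmeasured segments and background are 0/-1.
#' @export
render_diagnosis_map <- function(diagnosis, seg) {
  codes <- match(diagnosis$call, phantom_class_names()) - 1L
  out <- matrix(0L, nrow(seg$label), ncol(seg$label))
  for (i in seq_len(nrow(diagnosis))) {
    id <- diagnosis$segment_id[i]
    v <- if (is.na(codes[i])) -1L else codes[i]
    out[seg$label == id] <- v
  }
  out
}
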