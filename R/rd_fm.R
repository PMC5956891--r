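#' Morphology: opening/closing area regularity
#'
#' Normalized area difference between the morphological closing and opening
#' of the region with one disc structuring element:
#' `f1 = (A_closed - A_opened) / A_initial`. Irregular, spiculated borders
#' inflate the closing and deflate the opening, so larger values indicate
#' less regular regions; it is always non-negative.
#'
#' @param region a `candidate_region` (or any list with a logical `mask`).
#' @param se_radius disc structuring-element radius in pixels.
#' @return scalar feature.
#' @export
morphology_f1 <- function(region, se_radius = 2) {
  m <- region$mask
  pad <- se_radius + 1L
  big <- matrix(0, nrow(m) + 2 * pad, ncol(m) + 2 * pad)
  big[pad + seq_len(nrow(m)), pad + seq_len(ncol(m))] <- m
  brush <- EBImage::makeBrush(2L * se_radius + 1L, shape = "disc")
  a_closed <- sum(EBImage::closing(big, brush))
  a_opened <- sum(EBImage::opening(big, brush))
  (a_closed - a_opened) / sum(m)
}

# Resample a closed boundary polygon to n equidistant points (arc length).
.resample_boundary <- function(boundary, n = 128) {
  b <- rbind(boundary, boundary[1, , drop = FALSE])
  seg <- sqrt(diff(b[, 1])^2 + diff(b[, 2])^2)
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(matrix(rep(boundary[1, ], each = n), n, 2))
  t_new <- seq(0, total, length.out = n + 1)[seq_len(n)]
  cbind(approx(cum, b[, 1], xout = t_new)$y,
        approx(cum, b[, 2], xout = t_new)$y)
}

# Low-pass Fourier reconstruction of a closed polygon: keep harmonics with
# |frequency| <= keep (plus the DC term).
.fourier_reconstruct <- function(points, keep) {
  n <- nrow(points)
  z <- complex(real = points[, 1], imaginary = points[, 2])
  zf <- fft(z)
  freq <- pmin(seq_len(n) - 1, n - (seq_len(n) - 1))
  zf[freq > keep] <- 0
  zr <- fft(zf, inverse = TRUE) / n
  cbind(Re(zr), Im(zr))
}

.polygon_perimeter <- function(points) {
  b <- rbind(points, points[1, , drop = FALSE])
  sum(sqrt(diff(b[, 1])^2 + diff(b[, 2])^2))
}

#' Morphology: perimeter regularity via Fourier smoothing
#'
#' Resamples the region boundary to `n_points` equidistant points, removes
#' Fourier harmonics above `keep_freq`, and reports the normalized change
#' in perimeter: `f2 = |P_initial - P_reconstruction| / P_initial`. Rapidly
#' varying boundaries lose more perimeter under low-pass smoothing. The
#' initial perimeter is itself measured on a high-band reconstruction
#' (`antialias_freq` harmonics) so that the pixel-level staircase of the
#' rasterized boundary, present in every region regardless of shape, does
#' not register as irregularity.
#'
#' @param region a `candidate_region`.
#' @param keep_freq number of low-order harmonics retained.
#' @param n_points boundary resampling length.
#' @param antialias_freq harmonic cut-off defining the reference perimeter (default 16).
#' @return scalar feature (>= 0).
#' @export
morphology_f2 <- function(region, keep_freq = 8, n_points = 128,
                          antialias_freq = 16) {
  pts <- .resample_boundary(region$boundary, n_points)
  p0 <- .polygon_perimeter(.fourier_reconstruct(pts, antialias_freq))
  if (p0 == 0) return(0)
  pr <- .polygon_perimeter(.fourier_reconstruct(pts, keep_freq))
  abs(p0 - pr) / p0
}

# Even-odd scanline rasterization of a polygon onto an nr x nc pixel grid.
.fill_polygon <- function(points, nr, nc) {
  out <- matrix(FALSE, nr, nc)
  n <- nrow(points)
  if (n < 3) return(out)
  x <- points[, 1]; y <- points[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  for (r in seq_len(nr)) {
    rl <- r + 1e-7 # nudge off vertices
    cross <- (x <= rl & x2 > rl) | (x2 <= rl & x > rl)
    if (!any(cross)) next
    cc <- y[cross] + (rl - x[cross]) * (y2[cross] - y[cross]) /
      (x2[cross] - x[cross])
    cc <- sort(cc)
    for (i in seq(1, length(cc) - 1, by = 2)) {
      c0 <- ceiling(cc[i]); c1 <- floor(cc[i + 1])
      if (c1 >= c0)
        out[r, max(1, c0):min(nc, c1)] <- TRUE
    }
  }
  out
}

#' Morphology: band discrepancy of Fourier reconstructions
#'
#' Compares a low-frequency and a higher-frequency Fourier reconstruction
#' of the region boundary by rasterizing both and taking the Jaccard-style
#' discrepancy `f3 = |A_low XOR A_high| / |A_low OR A_high|`; values lie in
#' [0, 1] and vanish for band-limited (smooth) shapes.
#'
#' @param region a `candidate_region`.
#' @param low_freq,high_freq harmonic cut-offs, `low_freq < high_freq`.
#' @param n_points boundary resampling length.
#' @return scalar feature in [0, 1].
#' @export
morphology_f3 <- function(region, low_freq = 2, high_freq = 16,
                          n_points = 128) {
  if (low_freq > high_freq) stop_config("low_freq must be <= high_freq")
  pts <- .resample_boundary(region$boundary, n_points)
  nr <- nrow(region$mask); nc <- ncol(region$mask)
  a_low <- .fill_polygon(.fourier_reconstruct(pts, low_freq), nr, nc)
  a_high <- .fill_polygon(.fourier_reconstruct(pts, high_freq), nr, nc)
  uni <- sum(a_low | a_high)
  if (uni == 0) return(0)
  sum(xor(a_low, a_high)) / uni
}

#' Bilateral asymmetry features
#'
#' Splits the region along each principal axis (through the centroid) and
#' compares the two half areas: `f = (A_large - A_small) / A_normalize`.
#' Four variants are produced: split along the major or minor axis,
#' normalized by the whole-region area or by the smaller half. Pixels lying
#' exactly on the split line contribute half to each side. A degenerate
#' zero-area half caps the normalize-by-smaller variant at `cap`.
#'
#' @param region a `candidate_region`.
#' @param cap sentinel for the degenerate smaller-half normalization.
#' @return named numeric length 4:
#'   `major_whole`, `major_smaller`, `minor_whole`, `minor_smaller`.
#' @export
asymmetry_features <- function(region, cap = 10) {
  idx <- which(region$mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  xc <- sweep(idx, 2, ctr)
  cv <- crossprod(xc) / nrow(xc)
  ev <- eigen(cv, symmetric = TRUE)
  # split along the major axis -> halves separated by the minor direction
  out <- numeric(0)
  a_whole <- nrow(xc)
  for (split in c("major", "minor")) {
    normal <- if (split == "major") ev$vectors[, 2] else ev$vectors[, 1]
    proj <- as.numeric(xc %*% normal)
    on_line <- abs(proj) <= 1e-9
    a1 <- sum(proj > 1e-9) + sum(on_line) / 2
    a2 <- sum(proj < -1e-9) + sum(on_line) / 2
    a_large <- max(a1, a2); a_small <- min(a1, a2)
    f_whole <- (a_large - a_small) / a_whole
    f_small <- if (a_small == 0) {
      warning("degenerate sliver half in asymmetry; capped")
      cap
    } else min((a_large - a_small) / a_small, cap)
    out <- c(out, f_whole, f_small)
  }
  names(out) <- c("major_whole", "major_smaller",
                  "minor_whole", "minor_smaller")
  out
}

# The 18 shared GLCM statistics from a normalized symmetric GLCM `P`
# (levels x levels, 1-based level values), matching the voxel-level C++
# definitions. Correlation and the information measure fall back to 0 for
# degenerate marginals.
.glcm_stats_R <- function(P) {
  L <- nrow(P)
  iv <- matrix(seq_len(L), L, L)
  jv <- t(iv)
  px <- rowSums(P)
  mu <- sum(seq_len(L) * px)
  var <- sum((seq_len(L) - mu)^2 * px)
  nz <- P > 0
  entropy <- -sum(P[nz] * log2(P[nz]))
  psum <- tapply(as.vector(P), as.vector(iv + jv), sum)
  ks <- as.numeric(names(psum))
  sa <- sum(ks * psum)
  se <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  sv <- sum((ks - sa)^2 * psum)
  pdiff <- tapply(as.vector(P), as.vector(abs(iv - jv)), sum)
  kd <- as.numeric(names(pdiff))
  da <- sum(kd * pdiff)
  de <- -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0]))
  dv <- sum((kd - da)^2 * pdiff)
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  pp <- outer(px, px)
  hxy1 <- -sum(P[nz] * log2(pp[nz]))
  corr <- if (var > 1e-300) (sum(iv * jv * P) - mu^2) / var else 0
  imc <- if (hx > 1e-12) (entropy - hxy1) / hx else 0
  c(energy = sum(P^2),
    contrast = sum((iv - jv)^2 * P),
    correlation = corr,
    variance = var,
    idmn = sum(P / (1 + (iv - jv)^2 / L^2)),
    sum_average = sa,
    sum_variance = sv,
    entropy = entropy,
    sum_entropy = se,
    difference_entropy = de,
    imc = imc,
    homogeneity = sum(P / (1 + abs(iv - jv))),
    autocorrelation = sum(iv * jv * P),
    difference_variance = dv,
    dissimilarity = sum(abs(iv - jv) * P),
    cluster_shade = sum((iv + jv - 2 * mu)^3 * P),
    cluster_prominence = sum((iv + jv - 2 * mu)^4 * P),
    max_probability = max(P))
}

# Build the region-global symmetric normalized GLCM from horizontal
# neighbour pairs whose two pixels both lie in the ROI.
.region_glcm <- function(vals_img, mask, levels) {
  lo <- min(vals_img[mask]); hi <- max(vals_img[mask])
  q <- matrix(1L, nrow(mask), ncol(mask))
  if (hi > lo) {
    q[mask] <- pmin(as.integer((vals_img[mask] - lo) / (hi - lo) * levels) +
                      1L, levels)
  }
  nc <- ncol(mask)
  left <- mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE]
  P <- matrix(0, levels, levels)
  if (any(left)) {
    a <- q[, -nc, drop = FALSE][left]
    b <- q[, -1, drop = FALSE][left]
    for (t in seq_along(a)) {
      P[a[t], b[t]] <- P[a[t], b[t]] + 1
      P[b[t], a[t]] <- P[b[t], a[t]] + 1
    }
    P <- P / sum(P)
    attr(P, "degenerate") <- FALSE
  } else {
    P[1, 1] <- 1
    attr(P, "degenerate") <- TRUE
  }
  P
}

#' Region physiology features (26)
#'
#' Seven first-order statistics over the in-ROI pixel intensities (mean,
#' median, population SD, min, max, Fisher kurtosis, skewness) plus 19
#' second-order statistics from a single region-global grey-level
#' co-occurrence matrix built from horizontal adjacent pixel pairs in which
#' both pixels belong to the ROI (min-max quantization to `levels` bins,
#' symmetric, normalized). The 19th second-order statistic is the entropy
#' normalized by its maximum `log2(levels^2)`. If the ROI admits no valid
#' horizontal pair, the second-order block falls back to the degenerate
#' single-level GLCM and the result carries attribute `degenerate_glcm`.
#'
#' @param region a `candidate_region`.
#' @param channel 2-D matrix: the imaging channel on the region's slice.
#' @param levels GLCM quantization bins.
#' @return named numeric vector of length 26.
#' @export
physiology_features <- function(region, channel, levels = 32) {
  v <- channel[region$mask]
  if (length(v) == 0) stop_structural("region mask is empty on this slice")
  n <- length(v)
  m1 <- mean(v)
  var <- mean((v - m1)^2)
  degen <- var <= 1e-12 * max(1, m1^2)
  fo <- c(mean = m1, median = median(v), sd = sqrt(var),
          min = min(v), max = max(v),
          kurtosis = if (degen) 0 else mean((v - m1)^4) / var^2 - 3,
          skewness = if (degen) 0 else mean((v - m1)^3) / var^1.5)
  P <- .region_glcm(channel, region$mask, levels)
  so <- .glcm_stats_R(P)
  so <- c(so[1:10], normalized_entropy = unname(so["entropy"]) /
            log2(levels^2), so[11:18])
  out <- c(fo, so)
  attr(out, "degenerate_glcm") <- attr(P, "degenerate")
  out
}

#' Assemble the 242-entry region feature vector
#'
#' Concatenates 3 morphology + 4 asymmetry + 1 size features (shape-only,
#' identical across channels) with 26 physiology features per imaging
#' channel over the nine channels, giving 3 + 4 + 1 + 26 x 9 = 242 named
#' entries. Size is the region area in mm^2 (voxel count times in-plane
#' voxel area). Channels are looked up by name, so input ordering is
#' irrelevant.
#'
#' @param region a `candidate_region`.
#' @param case a `patient_case` with all nine channels.
#' @param channel_order the canonical channel name order.
#' @param levels physiology GLCM quantization bins.
#' @param se_radius,keep_freq,low_freq,high_freq morphology parameters.
#' @return named numeric vector of length 242.
#' @export
assemble_region_vector <- function(region, case,
                                   channel_order = c("T2w", "ADC", "rADC",
                                                     "CHB_DWI", "CDI", "b0",
                                                     "b100", "b400",
                                                     "b1000"),
                                   levels = 32, se_radius = 2,
                                   keep_freq = 8, low_freq = 2,
                                   high_freq = 16) {
  missing_ch <- setdiff(channel_order, names(case$channels))
  if (length(missing_ch) > 0)
    stop_config("missing channels: ", paste(missing_ch, collapse = ", "))
  morph <- c(morph_f1 = morphology_f1(region, se_radius),
             morph_f2 = morphology_f2(region, keep_freq),
             morph_f3 = morphology_f3(region, low_freq, high_freq))
  asym <- asymmetry_features(region)
  names(asym) <- paste0("asym_", names(asym))
  spacing <- if (!is.null(case$voxel_spacing)) case$voxel_spacing else c(1, 1, 1)
  size <- c(size_mm2 = region$area * spacing[1] * spacing[2])
  phys <- unlist(lapply(channel_order, function(ch) {
    p <- physiology_features(region,
                             case$channels[[ch]][, , region$slice_index],
                             levels)
    setNames(as.numeric(p), paste0("phys_", names(p), ".", ch))
  }))
  out <- c(morph, asym, size, phys)
  out[!is.finite(out)] <- 0
  out
}

# Equal-frequency discretization into at most `bins` levels.
.discretize_ef <- function(x, bins = 10) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 2) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

# Mutual information (bits) between two discrete vectors.
.mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  pa <- rowSums(p); pb <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(pa, pb)[nz]))
}

#' mRMR feature selection
#'
#' Greedy maximum-relevance minimum-redundancy selection: features are
#' discretized (equal-frequency, `bins` levels) and scored by mutual
#' information with the class label; the first pick maximizes relevance and
#' each subsequent pick maximizes `MI(f; y) - mean MI(f; selected)`. Ties
#' break to the lower column index.
#'
#' @param X numeric feature matrix.
#' @param y binary labels (logical, 0/1, or 2-level factor).
#' @param k number of features to select (capped at `ncol(X)`).
#' @param bins discretization levels.
#' @return integer vector of selected column indices, in selection order.
#' @export
mrmr_select <- function(X, y, k, bins = 10) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop_structural("X must be finite")
  p <- ncol(X)
  if (k > p) {
    warning("k larger than the number of features; capped")
    k <- p
  }
  yd <- as.integer(as.factor(y))
  D <- lapply(seq_len(p), function(j) .discretize_ef(X[, j], bins))
  rel <- vapply(D, .mutual_information, numeric(1), b = yd)
  sel <- which.max(rel)
  red <- matrix(NA_real_, p, p)
  while (length(sel) < k) {
    cand <- setdiff(seq_len(p), sel)
    j_new <- sel[length(sel)]
    for (cj in cand) {
      if (is.na(red[cj, j_new])) {
        red[cj, j_new] <- .mutual_information(D[[cj]], D[[j_new]])
        red[j_new, cj] <- red[cj, j_new]
      }
    }
    score <- rel[cand] -
      rowMeans(matrix(red[cand, sel, drop = FALSE], length(cand)))
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}

# Evaluate a criterion from predicted labels/scores against truth.
.criterion_value <- function(pred_label, score, y, criterion) {
  y <- as.logical(y)
  if (criterion == "auc") {
    if (length(unique(y)) < 2) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                   quiet = TRUE, direction = "<")))
  } else if (criterion == "sensitivity") {
    if (!any(y)) return(NA_real_)
    mean(pred_label[y])
  } else {
    if (all(y)) return(NA_real_)
    mean(!pred_label[!y])
  }
}

# Fit an RBF SVM on z-scored selected columns; returns a closure-free model
# list used by classify/evaluation. Classes are inverse-frequency weighted:
# the candidate stage is deliberately sensitivity-first, so true-positive
# regions are a small minority of the training set.
.fit_margin_classifier <- function(X, y, cost = 1, gamma = NULL) {
  y <- as.logical(y)
  if (length(unique(y)) < 2) stop_structural("training set has one class")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd); scl[scl == 0] <- 1
  Xs <- scale(X, ctr, scl)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  cw <- length(y) / (2 * c("FALSE" = sum(!y), "TRUE" = sum(y)))
  fit <- e1071::svm(Xs, factor(y, levels = c(FALSE, TRUE)),
                    kernel = "radial", cost = cost, gamma = gamma,
                    class.weights = cw, scale = FALSE)
  list(fit = fit, center = ctr, scale = scl)
}

.predict_margin_classifier <- function(model, X) {
  Xs <- scale(as.matrix(X), model$center, model$scale)
  pr <- predict(model$fit, Xs, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  # orient the margin so positive score favours the positive class
  pos_first <- strsplit(colnames(dv)[1], "/")[[1]][1] == "TRUE"
  score <- if (pos_first) dv[, 1] else -dv[, 1]
  list(label = pr == "TRUE", score = as.numeric(score))
}

#' Two-stage criterion-driven feature selection
#'
#' Stage 1 ranks each channel's 26 physiology features by mRMR and picks
#' the prefix length `n_i` (grid over 1..26) whose classifier maximizes the
#' chosen criterion on the training regions; the 8 shape features
#' (morphology + asymmetry + size) are treated as one group the same way.
#' Stage 2 pools the stage-1 survivors, re-ranks them by mRMR and picks the
#' final prefix by the same grid. All fitting and scoring uses only the
#' training rows supplied; ties in the grid break to the smaller subset.
#'
#' @param X region feature matrix with [assemble_region_vector] column
#'   names.
#' @param y binary region labels.
#' @param criterion `"sensitivity"`, `"specificity"` or `"auc"`.
#' @param cost,gamma SVM hyper-parameters (gamma defaults to 1/d).
#' @return a `selection_plan`: per-channel selections, shape-group
#'   selection, final selected column names, criterion, and the achieved
#'   training criterion value.
#' @export
two_stage_selection <- function(X, y, criterion = c("specificity",
                                                    "sensitivity", "auc"),
                                cost = 1, gamma = NULL) {
  criterion <- match.arg(criterion)
  X <- as.matrix(X)
  y <- as.logical(y)
  nms <- colnames(X)
  mas_cols <- which(!startsWith(nms, "phys_"))
  phys_cols <- which(startsWith(nms, "phys_"))
  channels <- unique(sub("^.*\\.", "", nms[phys_cols]))

  eval_prefix <- function(cols_ordered) {
    best_n <- 1L; best_v <- -Inf
    for (n in seq_along(cols_ordered)) {
      cols <- cols_ordered[seq_len(n)]
      mdl <- .fit_margin_classifier(X[, cols, drop = FALSE], y,
                                    cost = cost, gamma = gamma)
      pr <- .predict_margin_classifier(mdl, X[, cols, drop = FALSE])
      v <- .criterion_value(pr$label, pr$score, y, criterion)
      if (!is.na(v) && v > best_v + 1e-12) {
        best_v <- v; best_n <- n
      }
    }
    list(cols = cols_ordered[seq_len(best_n)], value = best_v)
  }

  per_channel <- list()
  for (ch in channels) {
    cols <- phys_cols[endsWith(nms[phys_cols], paste0(".", ch))]
    ord <- cols[mrmr_select(X[, cols, drop = FALSE], y, length(cols))]
    per_channel[[ch]] <- eval_prefix(ord)$cols
  }
  mas_ord <- mas_cols[mrmr_select(X[, mas_cols, drop = FALSE], y,
                                  length(mas_cols))]
  mas_sel <- eval_prefix(mas_ord)$cols

  pool <- unique(c(unlist(per_channel), mas_sel))
  if (length(pool) == 0) stop_structural("empty survivor pool")
  ord2 <- pool[mrmr_select(X[, pool, drop = FALSE], y, length(pool))]
  final <- eval_prefix(ord2)
  structure(list(per_channel_selected = lapply(per_channel,
                                               function(i) nms[i]),
                 mas_selected = nms[mas_sel],
                 final_selected = nms[final$cols],
                 criterion = criterion,
                 training_value = final$value),
            class = "selection_plan")
}

#' Train and apply the region margin classifier
#'
#' Fits an RBF-kernel SVM on the plan's final feature subset (z-scored with
#' training statistics) and scores the test regions. Returns binary labels
#' and continuous margin scores oriented so larger means more
#' cancer-like.
#'
#' @param train_X,train_y training region features and binary labels.
#' @param test_X test region features (same columns).
#' @param plan a `selection_plan` fitted on the training patients.
#' @param cost,gamma SVM hyper-parameters.
#' @return list with `label` (logical) and `score` (numeric) per test row,
#'   plus `model` (the fitted classifier, reusable via
#'   `classify_regions(..., model = )`).
#' @export
classify_regions <- function(train_X, train_y, test_X, plan,
                             cost = 1, gamma = NULL) {
  cols <- plan$final_selected
  mdl <- .fit_margin_classifier(as.matrix(train_X)[, cols, drop = FALSE],
                                train_y, cost = cost, gamma = gamma)
  pr <- .predict_margin_classifier(mdl,
                                   as.matrix(test_X)[, cols, drop = FALSE])
  list(label = unname(pr$label), score = pr$score, model = mdl)
}

#' Region-level ground-truth label
#'
#' A candidate region is positive iff at least `frac` of its area overlaps
#' the voxel-level truth mask.
#'
#' @param region a `candidate_region`.
#' @param truth_mask 3-D logical truth array.
#' @param frac overlap fraction threshold in (0, 1].
#' @return logical.
#' @export
region_truth_label <- function(region, truth_mask, frac = 0.5) {
  tr <- truth_mask[, , region$slice_index]
  sum(tr & region$mask) / region$area >= frac
}
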