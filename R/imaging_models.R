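#' Construct a b-value stack
#'
#' Bundles an ordered set of co-registered diffusion-weighted volumes with
#' their diffusion weightings (b-values) and voxel spacing. This is the raw
#' input from which all derived diffusion channels (ADC, computed high-b DWI,
#' correlated diffusion imaging) are computed.
#'
#' @param volumes list of 3-D numeric arrays (signal intensity, arbitrary
#'   units), one per b-value, all sharing one shape. Non-negative.
#' @param bvalues numeric vector of b-values (s/mm^2), strictly increasing,
#'   same length as `volumes`, at least two entries.
#' @param voxel_spacing numeric length-3, voxel size in mm along each axis.
#' @return an object of class `bvalue_stack`.
#' @export
bvalue_stack <- function(volumes, bvalues, voxel_spacing = c(1, 1, 1)) {
  if (!is.list(volumes) || length(volumes) != length(bvalues))
    stop_structural("`volumes` must be a list matching `bvalues` in length")
  if (length(bvalues) < 2)
    stop_config("at least 2 b-values are required")
  if (any(diff(bvalues) <= 0) || any(bvalues < 0))
    stop_structural("b-values must be non-negative and strictly increasing")
  dims <- lapply(volumes, dim)
  if (any(vapply(dims, length, 1L) != 3))
    stop_structural("all volumes must be 3-D arrays")
  if (!all(vapply(dims, function(d) identical(d, dims[[1]]), TRUE)))
    stop_structural("all volumes must share one shape")
  if (any(vapply(volumes, function(v) any(v < 0), TRUE)))
    stop_structural("signal intensities must be non-negative")
  if (length(voxel_spacing) != 3 || any(voxel_spacing <= 0))
    stop_structural("voxel_spacing must be 3 positive reals")
  structure(list(volumes = volumes, bvalues = as.numeric(bvalues),
                 voxel_spacing = as.numeric(voxel_spacing),
                 dim = dims[[1]]),
            class = "bvalue_stack")
}

#' @export
print.bvalue_stack <- function(x, ...) {
  cat("<bvalue_stack> ", paste(x$dim, collapse = " x "),
      " voxels, b = {", paste(x$bvalues, collapse = ", "), "} s/mm^2\n",
      sep = "")
  invisible(x)
}

# Ordinary least-squares fit of ln S on b for every voxel at once.
# Returns slope/intercept matrices shaped like the volumes.
.dwi_loglinear_fit <- function(stack, floor = 1e-6, ridge = 0) {
  b <- stack$bvalues
  n <- length(b)
  Y <- vapply(stack$volumes, function(v) log(pmax(as.numeric(v), floor)),
              numeric(prod(stack$dim)))
  invalid <- Reduce(`&`, lapply(stack$volumes, function(v) v < floor))
  bc <- b - mean(b)
  ybar <- rowMeans(Y)
  slope <- as.numeric(Y %*% bc) / (sum(bc^2) + ridge)
  intercept <- ybar - slope * mean(b)
  slope[invalid] <- 0
  intercept[invalid] <- 0
  list(slope = array(slope, stack$dim),
       intercept = array(intercept, stack$dim),
       invalid = array(as.vector(invalid), stack$dim))
}

#' Fit the apparent diffusion coefficient (ADC) map
#'
#' Fits the mono-exponential diffusion decay `S = S0 * exp(-b * D)` per voxel
#' by ordinary least squares of `ln S` against `b`; the ADC is the negated
#' slope. Signals are clipped to a positive floor before the logarithm, and
#' voxels whose signal is below the floor at every b-value are flagged
#' invalid and assigned D = 0. Negative slope estimates (possible under
#' noise) are clamped to zero so the map is a valid diffusivity.
#'
#' @param stack a [bvalue_stack].
#' @param floor signal floor applied before taking logarithms.
#' @return 3-D array of D estimates (mm^2/s) with attributes `log_s0`
#'   (fitted log intercept per voxel) and `invalid` (logical array flagging
#'   all-zero-signal voxels).
#' @export
fit_adc <- function(stack, floor = 1e-6) {
  if (!inherits(stack, "bvalue_stack")) stop_structural("need a bvalue_stack")
  fit <- .dwi_loglinear_fit(stack, floor = floor)
  adc <- pmax(-fit$slope, 0)
  attr(adc, "log_s0") <- fit$intercept
  attr(adc, "invalid") <- fit$invalid
  adc
}

#' Compute high-b DWI by extrapolation (CHB-DWI)
#'
#' Synthesizes a diffusion-weighted image at a b-value beyond the acquired
#' range by extrapolating the per-voxel log-linear least-squares fit of the
#' mono-exponential decay: `S(target_b) = exp(log_s0 - target_b * D)`. An
#' optional ridge penalty on the slope shrinks the decay estimate towards
#' zero, which stabilizes the extrapolation for noisy low-signal voxels; the
#' default is the plain least-squares fit.
#'
#' @param stack a [bvalue_stack].
#' @param target_b target b-value (s/mm^2); must be at least the largest
#'   acquired b-value (equality reproduces the fitted, not raw, signal).
#' @param ridge non-negative ridge weight added to the slope denominator.
#' @param floor signal floor before logarithms.
#' @return 3-D array of extrapolated signal.
#' @export
compute_chb_dwi <- function(stack, target_b = 2000, ridge = 0, floor = 1e-6) {
  if (!inherits(stack, "bvalue_stack")) stop_structural("need a bvalue_stack")
  if (target_b < max(stack$bvalues))
    stop_config("target_b must not be below the largest acquired b-value")
  fit <- .dwi_loglinear_fit(stack, floor = floor, ridge = ridge)
  d <- pmax(-fit$slope, 0)
  out <- exp(fit$intercept - target_b * d)
  out[fit$invalid] <- 0
  out
}

# Separable Gaussian smoothing with border renormalization: the result at a
# voxel is a weighted mean over the in-bounds part of the kernel support, so
# a constant field stays constant near borders.
.gaussian_smooth3d <- function(a, sigma_vox) {
  dims <- dim(a)
  num <- a
  den <- array(1, dims)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s < 1e-8) next
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    num <- .conv_axis(num, k, ax)
    den <- .conv_axis(den, k, ax)
  }
  num / den
}

# 1-D convolution along one axis via shift-and-add with zero padding.
.conv_axis <- function(a, k, ax) {
  dims <- dim(a)
  r <- (length(k) - 1L) / 2L
  out <- array(0, dims)
  n <- dims[ax]
  for (i in seq_along(k)) {
    off <- i - r - 1L
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep)) next
    idx_dst <- which(keep)
    idx_src <- src[keep]
    if (ax == 1) out[idx_dst, , ] <- out[idx_dst, , ] + k[i] * a[idx_src, , ]
    else if (ax == 2) out[, idx_dst, ] <- out[, idx_dst, ] + k[i] * a[, idx_src, ]
    else out[, , idx_dst] <- out[, , idx_dst] + k[i] * a[, , idx_src]
  }
  out
}

#' Correlated diffusion imaging (CDI)
#'
#' Mixes the signal across all acquired b-values over a local subvolume: the
#' per-voxel product of the channel signals is averaged under a normalized
#' isotropic Gaussian kernel of physical radius `kernel_radius_mm`. A radius
#' of zero degenerates to the plain per-voxel cross-b-value product. The
#' Gaussian local mixing stands in for the conditional joint signal density
#' over the subvolume; its width is configurable.
#'
#' @param stack a [bvalue_stack].
#' @param kernel_radius_mm Gaussian sigma in mm (>= 0) of the local mixing
#'   kernel; converted to voxel units per axis using the stack spacing.
#' @return 3-D array of CDI signal (arbitrary units).
#' @export
compute_cdi <- function(stack, kernel_radius_mm = 2) {
  if (!inherits(stack, "bvalue_stack")) stop_structural("need a bvalue_stack")
  if (kernel_radius_mm < 0) stop_config("kernel_radius_mm must be >= 0")
  prod_vol <- Reduce(`*`, stack$volumes)
  if (kernel_radius_mm == 0) return(prod_vol)
  sigma_vox <- kernel_radius_mm / stack$voxel_spacing
  .gaussian_smooth3d(prod_vol, sigma_vox)
}

# Normalize candidate masks to a list of 3-D logical arrays over `dims`.
# Accepts: a single 3-D array, a list of 3-D arrays, or a list of
# list(mask = 2-D matrix, slice_index = k).
.as_candidate_masks <- function(candidates, dims) {
  if (is.array(candidates) && length(dim(candidates)) == 3)
    candidates <- list(candidates)
  lapply(candidates, function(cm) {
    if (is.list(cm) && !is.null(cm$mask)) {
      m <- array(FALSE, dims)
      if (is.matrix(cm$mask)) {
        if (is.null(cm$slice_index))
          stop_structural("2-D candidate mask needs a slice_index")
        m[, , cm$slice_index] <- cm$mask > 0
      } else m <- cm$mask > 0
      m
    } else if (is.array(cm) && length(dim(cm)) == 3) {
      array(cm > 0, dims)
    } else stop_structural("unrecognized candidate mask format")
  })
}

# Per-slice binary dilation with a disc structuring element.
.dilate_slicewise <- function(mask3d, radius_vox) {
  brush <- EBImage::makeBrush(2L * radius_vox + 1L, shape = "disc")
  out <- mask3d
  for (k in seq_len(dim(mask3d)[3])) {
    sl <- mask3d[, , k]
    if (!any(sl)) next
    out[, , k] <- EBImage::dilate(sl * 1, brush) > 0
  }
  out
}

#' Relative ADC map
#'
#' Normalizes an ADC map per candidate region of interest by its local
#' surround, correcting for interpatient variation in absolute ADC. Each
#' ROI is dilated in-plane with a disc structuring element; the surround is
#' the dilated band minus the ROI, and the dilated ROI is divided by the
#' median ADC of its surround. Where dilated ROIs overlap, a voxel takes
#' its value from the ROI whose centroid is nearest. Voxels outside every
#' dilated ROI are divided by the mean of the per-ROI surround medians, so
#' the whole map is expressed relative to normal-tissue ADC.
#'
#' @param adc 3-D ADC array.
#' @param candidates candidate ROI masks: a 3-D logical array, a list of
#'   such arrays, or a list of `list(mask = <2-D matrix>, slice_index = k)`.
#' @param se_radius_vox disc structuring-element radius in voxels (>= 1).
#' @return 3-D array of dimensionless relative ADC, with attribute
#'   `surround_medians` (one per retained ROI).
#' @export
compute_relative_adc <- function(adc, candidates, se_radius_vox = 3) {
  if (length(dim(adc)) != 3) stop_structural("adc must be a 3-D array")
  if (se_radius_vox < 1) stop_config("se_radius_vox must be >= 1")
  masks <- .as_candidate_masks(candidates, dim(adc))
  if (any(!vapply(masks, any, TRUE)))
    stop_structural("candidate masks must be non-empty")

  meds <- numeric(0)
  dilated <- list()
  centroids <- list()
  keep <- logical(length(masks))
  for (i in seq_along(masks)) {
    dil <- .dilate_slicewise(masks[[i]], se_radius_vox)
    surround <- dil & !masks[[i]]
    if (!any(surround)) {
      warning("ROI ", i, " has an empty surround after clipping; skipped")
      next
    }
    med <- median(adc[surround])
    if (med == 0) {
      warning("ROI ", i, " has a zero-median surround; skipped")
      next
    }
    keep[i] <- TRUE
    meds <- c(meds, med)
    dilated <- c(dilated, list(dil))
    idx <- which(masks[[i]], arr.ind = TRUE)
    centroids <- c(centroids, list(colMeans(idx)))
  }
  if (length(meds) == 0)
    stop_structural("no usable candidate ROI (all degenerate)")

  out <- adc / mean(meds)
  covered <- Reduce(`|`, dilated)
  vox <- which(covered, arr.ind = TRUE)
  if (length(dilated) == 1) {
    out[covered] <- adc[covered] / meds[1]
  } else {
    inside <- matrix(vapply(dilated, function(d) d[covered],
                            logical(nrow(vox))), nrow = nrow(vox))
    d2 <- matrix(vapply(centroids, function(ce)
      (vox[, 1] - ce[1])^2 + (vox[, 2] - ce[2])^2 + (vox[, 3] - ce[3])^2,
      numeric(nrow(vox))), nrow = nrow(vox))
    d2[!inside] <- Inf
    owner <- max.col(-d2, ties.method = "first")
    out[covered] <- adc[covered] / meds[owner]
  }
  attr(out, "surround_medians") <- meds
  out
}
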