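#' Voxel feature bank configuration
#'
#' The voxel-resolution texture bank holds 96 features per voxel: 4
#' first-order window statistics, 72 second-order grey-level co-occurrence
#' statistics (18 statistics at each of 4 in-plane directions), 12 Gabor
#' magnitudes (3 wavelengths x 4 orientations) and 8 Kirsch compass edge
#' responses. Each operator group is evaluated on one configured source
#' channel; the default assignment places the intensity-statistics groups
#' on the ADC map, the Gabor bank on T2w and the Kirsch bank on CHB-DWI,
#' which keeps the bank at exactly 96 columns while leaving the
#' channel-to-group mapping open to reconfiguration.
#'
#' @param window odd in-plane window side (voxels) for the windowed groups.
#' @param glcm_levels grey-level quantization bins (>= 2).
#' @param gabor_wavelengths 3 wavelengths (pixels).
#' @param gabor_orientations 4 orientations (radians).
#' @param channel_assignment named list mapping each operator group
#'   (`first_order`, `glcm`, `gabor`, `kirsch`) to a channel name.
#' @return a `voxel_feature_config` list.
#' @export
voxel_feature_config <- function(window = 5, glcm_levels = 32,
                                 gabor_wavelengths = c(2, 4, 8),
                                 gabor_orientations = pi * c(0, 1, 2, 3) / 4,
                                 channel_assignment = list(
                                   first_order = "ADC", glcm = "ADC",
                                   gabor = "T2w", kirsch = "CHB_DWI")) {
  if (window < 3 || window %% 2 == 0)
    stop_config("window must be odd and >= 3")
  if (glcm_levels < 2) stop_config("glcm_levels must be >= 2")
  if (length(gabor_wavelengths) != 3 || length(gabor_orientations) != 4)
    stop_config("the Gabor bank is 3 wavelengths x 4 orientations")
  structure(list(window = window, glcm_levels = glcm_levels,
                 gabor_wavelengths = gabor_wavelengths,
                 gabor_orientations = gabor_orientations,
                 channel_assignment = channel_assignment),
            class = "voxel_feature_config")
}

.glcm_stat_names <- c("energy", "contrast", "correlation", "variance",
                      "idmn", "sum_average", "sum_variance", "entropy",
                      "sum_entropy", "difference_entropy", "imc",
                      "homogeneity", "autocorrelation",
                      "difference_variance", "dissimilarity",
                      "cluster_shade", "cluster_prominence",
                      "max_probability")

# GLCM pair offsets (drow, dcol) for directions 0, 45, 90, 135 degrees.
.glcm_offsets <- function() {
  matrix(c(0L, 1L, -1L, 1L, -1L, 0L, -1L, -1L), ncol = 2, byrow = TRUE,
         dimnames = list(c("d0", "d45", "d90", "d135"), NULL))
}

# 2-D integral image (zero-padded on top/left) for fast clipped-window sums.
.integral2d <- function(m) {
  s <- apply(m, 2, cumsum)
  s <- t(apply(s, 1, cumsum))
  rbind(0, cbind(0, s))
}

.window_sums <- function(ii, rows, cols, half, nr, nc) {
  r0 <- pmax(rows - half, 1L); r1 <- pmin(rows + half, nr)
  c0 <- pmax(cols - half, 1L); c1 <- pmin(cols + half, nc)
  ii[cbind(r1 + 1L, c1 + 1L)] - ii[cbind(r0, c1 + 1L)] -
    ii[cbind(r1 + 1L, c0)] + ii[cbind(r0, c0)]
}

#' First-order window statistics
#'
#' Mean, population standard deviation, Fisher (excess) kurtosis and
#' skewness over the in-plane window centred at each in-mask pixel; windows
#' are clipped at the image border. A zero-variance window yields standard
#' deviation, skewness and kurtosis 0.
#'
#' @param channel 2-D matrix (one slice).
#' @param mask 2-D logical matrix of pixels to evaluate.
#' @param window odd window side.
#' @return matrix `[n_mask x 4]`, columns mean/sd/kurtosis/skewness, rows in
#'   column-major `which(mask)` order.
#' @export
first_order_features <- function(channel, mask, window = 5) {
  if (window %% 2 == 0) stop_config("window must be odd")
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(matrix(numeric(0), 0, 4,
                  dimnames = list(NULL, c("mean", "sd", "kurtosis",
                                          "skewness"))))
  nr <- nrow(channel); nc <- ncol(channel); half <- window %/% 2
  s1 <- .integral2d(channel)
  s2 <- .integral2d(channel^2)
  s3 <- .integral2d(channel^3)
  s4 <- .integral2d(channel^4)
  cnt <- .integral2d(matrix(1, nr, nc))
  n <- .window_sums(cnt, idx[, 1], idx[, 2], half, nr, nc)
  m1 <- .window_sums(s1, idx[, 1], idx[, 2], half, nr, nc) / n
  m2 <- .window_sums(s2, idx[, 1], idx[, 2], half, nr, nc) / n
  m3 <- .window_sums(s3, idx[, 1], idx[, 2], half, nr, nc) / n
  m4 <- .window_sums(s4, idx[, 1], idx[, 2], half, nr, nc) / n
  v <- pmax(m2 - m1^2, 0)
  mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
  mu4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
  degen <- v <= 1e-12 * pmax(1, m1^2)
  skew <- ifelse(degen, 0, mu3 / v^1.5)
  kurt <- ifelse(degen, 0, mu4 / v^2 - 3)
  cbind(mean = m1, sd = sqrt(v), kurtosis = kurt, skewness = skew)
}

#' Windowed GLCM statistics
#'
#' For each in-mask pixel, quantizes the clipped in-plane window to
#' `levels` grey bins (min-max within the window), accumulates a symmetric
#' normalized grey-level co-occurrence matrix at each of the four standard
#' in-plane directions (0, 45, 90, 135 degrees) and computes 18
#' Haralick-family statistics per direction. Degenerate single-grey-level
#' windows yield energy 1, contrast 0, entropy 0, correlation 0.
#'
#' @param channel 2-D matrix (one slice).
#' @param mask 2-D logical matrix.
#' @param window odd window side.
#' @param levels quantization bins (>= 2).
#' @return matrix `[n_mask x 72]` (18 statistics x 4 directions), rows in
#'   column-major `which(mask)` order.
#' @export
glcm_voxel_features <- function(channel, mask, window = 5, levels = 32) {
  if (levels < 2) stop_config("levels must be >= 2")
  offs <- .glcm_offsets()
  out <- glcm_window_stats_cpp(channel, mask, as.integer(window),
                               as.integer(levels), offs)
  colnames(out) <- as.vector(vapply(rownames(offs), function(d)
    paste0("glcm_", .glcm_stat_names, "_", d), character(18)))
  out
}

# Build one complex Gabor kernel pair (even DC-corrected, odd).
.gabor_kernels <- function(wavelength, theta, sigma = 0.56 * wavelength) {
  r <- max(2L, ceiling(2.5 * sigma))
  g <- expand.grid(x = -r:r, y = -r:r)
  xr <- g$x * cos(theta) + g$y * sin(theta)
  yr <- -g$x * sin(theta) + g$y * cos(theta)
  env <- exp(-(xr^2 + yr^2) / (2 * sigma^2))
  even <- env * cos(2 * pi * xr / wavelength)
  odd <- env * sin(2 * pi * xr / wavelength)
  even <- even - mean(even) # remove DC so the response ignores offsets
  odd <- odd - mean(odd)
  n <- 2L * r + 1L
  list(even = matrix(even, n, n), odd = matrix(odd, n, n))
}

.filter2_rep <- function(m, k) {
  # filter2 requires the kernel to fit inside the image; replicate-pad
  # small images first, then crop (identical result under replication)
  pr <- max(0L, nrow(k) - nrow(m) + 1L)
  pc <- max(0L, ncol(k) - ncol(m) + 1L)
  if (pr > 0 || pc > 0) {
    ri <- c(rep(1L, pr), seq_len(nrow(m)), rep(nrow(m), pr))
    ci <- c(rep(1L, pc), seq_len(ncol(m)), rep(ncol(m), pc))
    out <- EBImage::filter2(m[ri, ci], k, boundary = "replicate")
    return(out[pr + seq_len(nrow(m)), pc + seq_len(ncol(m))])
  }
  EBImage::filter2(m, k, boundary = "replicate")
}

#' Gabor magnitude features
#'
#' Magnitude responses of a bank of 2-D Gabor filters (3 wavelengths x 4
#' orientations) evaluated per slice; the even kernel is DC-corrected so
#' responses are invariant to constant intensity offsets.
#'
#' @param channel 2-D matrix (one slice).
#' @param wavelengths 3 wavelengths in pixels.
#' @param orientations 4 orientations in radians.
#' @return array `[nrow, ncol, 12]` of magnitudes with dimnames on the
#'   feature axis.
#' @export
gabor_features <- function(channel, wavelengths = c(2, 4, 8),
                           orientations = pi * c(0, 1, 2, 3) / 4) {
  if (length(wavelengths) != 3 || length(orientations) != 4)
    stop_config("need 3 wavelengths and 4 orientations")
  nms <- character(0)
  out <- array(0, c(nrow(channel), ncol(channel), 12))
  f <- 0L
  for (w in wavelengths) {
    for (th in orientations) {
      f <- f + 1L
      k <- .gabor_kernels(w, th)
      re <- .filter2_rep(channel, k$even)
      im <- .filter2_rep(channel, k$odd)
      out[, , f] <- sqrt(re^2 + im^2)
      nms <- c(nms, sprintf("gabor_w%g_o%d", w, round(th * 180 / pi)))
    }
  }
  dimnames(out) <- list(NULL, NULL, nms)
  out
}

# The 8 standard Kirsch compass kernels (rotations of the north kernel).
.kirsch_kernels <- function() {
  base <- c(5, 5, 5, -3, 0, -3, -3, -3, -3) # clockwise ring from top-left
  ring_idx <- c(1, 2, 3, 6, 9, 8, 7, 4) # clockwise ring positions
  dirs <- c("n", "ne", "e", "se", "s", "sw", "w", "nw")
  ring0 <- base[ring_idx]
  lapply(setNames(seq_along(dirs) - 1L, dirs), function(s) {
    k <- numeric(9)
    ring <- ring0[((seq_len(8) - 1L + s) %% 8L) + 1L]
    k[ring_idx] <- ring
    matrix(k, 3, 3, byrow = TRUE)
  })
}

#' Kirsch compass edge responses
#'
#' Convolves the slice with the 8 standard Kirsch 3x3 compass kernels
#' (replicated borders). Kernels sum to zero, so constant images give zero
#' response in every direction.
#'
#' @param channel 2-D matrix (one slice).
#' @return array `[nrow, ncol, 8]` of signed responses.
#' @export
kirsch_features <- function(channel) {
  ks <- .kirsch_kernels()
  out <- array(0, c(nrow(channel), ncol(channel), 8))
  for (i in seq_along(ks)) out[, , i] <- .filter2_rep(channel, ks[[i]])
  dimnames(out) <- list(NULL, NULL, paste0("kirsch_", names(ks)))
  out
}

#' Assemble the 96-column voxel feature bank
#'
#' Evaluates the four operator groups on their configured source channels
#' for every gland voxel of a patient case and concatenates them into the
#' 96-column voxel feature matrix (4 first-order + 72 GLCM + 12 Gabor + 8
#' Kirsch). Non-finite entries are imputed to 0. Column names carry the
#' operator, statistic/direction and source channel.
#'
#' @param case a `patient_case` (or any list with `channels` of 3-D arrays).
#' @param mask 3-D logical array of voxels to include; defaults to the
#'   case's gland mask.
#' @param config a [voxel_feature_config].
#' @return list with `values` (matrix `[n_voxels x 96]`) and `voxel_index`
#'   (data.frame slice/row/col matching the rows).
#' @export
build_voxel_feature_bank <- function(case, mask = NULL,
                                     config = voxel_feature_config()) {
  if (is.null(mask)) mask <- case$gland_mask
  ca <- config$channel_assignment
  for (ch in unlist(ca)) {
    if (is.null(case$channels[[ch]]))
      stop_config("channel assignment names a missing channel: ", ch)
  }
  nsl <- dim(mask)[3]
  rows <- list(); index <- list()
  nms <- NULL
  for (k in seq_len(nsl)) {
    msk <- mask[, , k]
    nvox <- sum(msk)
    fo <- first_order_features(case$channels[[ca$first_order]][, , k], msk,
                               config$window)
    colnames(fo) <- paste0("fo_", colnames(fo), ".", ca$first_order)
    gl <- glcm_voxel_features(case$channels[[ca$glcm]][, , k], msk,
                              config$window, config$glcm_levels)
    colnames(gl) <- paste0(colnames(gl), ".", ca$glcm)
    ga <- gabor_features(case$channels[[ca$gabor]][, , k],
                         config$gabor_wavelengths,
                         config$gabor_orientations)
    ki <- kirsch_features(case$channels[[ca$kirsch]][, , k])
    lin <- which(msk)
    gam <- matrix(vapply(seq_len(12), function(f) ga[, , f][lin],
                         numeric(nvox)), nvox, 12,
                  dimnames = list(NULL, paste0(dimnames(ga)[[3]], ".",
                                               ca$gabor)))
    kim <- matrix(vapply(seq_len(8), function(f) ki[, , f][lin],
                         numeric(nvox)), nvox, 8,
                  dimnames = list(NULL, paste0(dimnames(ki)[[3]], ".",
                                               ca$kirsch)))
    block <- cbind(fo, gl, gam, kim)
    if (is.null(nms)) nms <- colnames(block)
    rows[[k]] <- block
    ij <- which(msk, arr.ind = TRUE)
    index[[k]] <- data.frame(slice = rep(k, nvox),
                             row = ij[, 1], col = ij[, 2])
  }
  values <- do.call(rbind, rows)
  colnames(values) <- nms
  values[!is.finite(values)] <- 0
  list(values = values, voxel_index = do.call(rbind, index))
}
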