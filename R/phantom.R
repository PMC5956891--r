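#' Specify a synthetic MP-MRI phantom
#'
#' Describes one synthetic patient: an ellipsoidal gland embedded in
#' background tissue, zero or more ellipsoidal low-diffusivity lesions, a
#' smoothly varying proton-density (S0) field, and Rician magnitude noise.
#' Diffusion-weighted channels follow the mono-exponential decay
#' `S = S0 * exp(-b * D)` with tissue-dependent diffusivity D; lesions are
#' ADC-dark and T2w-hypointense, as prostate peripheral-zone tumours
#' typically appear. Defaults use typical peripheral-zone magnitudes:
#' background D = 1.6e-3 mm^2/s, lesion D = 0.7e-3 mm^2/s.
#'
#' @param shape integer length-3 volume shape in voxels.
#' @param voxel_spacing numeric length-3 voxel size (mm).
#' @param gland list with `center` (voxels, defaults to volume centre) and
#'   `semiaxes` (voxels) of the gland ellipsoid.
#' @param tumours list of lesions, each a list with `center` (voxels),
#'   `radius_vox` (>= 2, scalar or length-3 semiaxes), `D_lesion` (mm^2/s)
#'   and `t2w_contrast` (multiplicative T2w signal factor < 1).
#' @param bvalues acquired b-values (s/mm^2).
#' @param D_background gland-tissue diffusivity (mm^2/s).
#' @param D_outside diffusivity outside the gland (mm^2/s).
#' @param s0 list with `base` signal level and `gradient` (relative
#'   left-right linear drift of the S0 field emulating coil shading).
#' @param t2w list with `gland`, `outside` base T2w intensities.
#' @param noise_sigma Rician noise sigma (signal units, >= 0).
#' @param blend_vox width (voxels) of the smooth tissue-boundary falloff
#'   outside each structure; tissue values are exact inside the structure.
#' @param seed integer seed making the phantom reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48, 48, 8),
                         voxel_spacing = c(1.56, 1.56, 3),
                         gland = list(center = NULL, semiaxes = c(15, 11, 2.8)),
                         tumours = list(),
                         bvalues = c(0, 100, 400, 1000),
                         D_background = 1.6e-3,
                         D_outside = 1.0e-3,
                         s0 = list(base = 1000, gradient = 0.1),
                         t2w = list(gland = 800, outside = 400),
                         noise_sigma = 15,
                         blend_vox = 2,
                         seed = 1L) {
  if (noise_sigma < 0) stop_config("noise_sigma must be >= 0")
  if (is.null(gland$center)) gland$center <- (shape + 1) / 2
  for (tu in tumours) {
    if (any(tu$radius_vox < 2)) stop_config("tumour radius must be >= 2 voxels")
    if (tu$D_lesion >= D_background)
      stop_config("lesions must be ADC-dark: D_lesion < D_background")
  }
  structure(list(shape = as.integer(shape), voxel_spacing = voxel_spacing,
                 gland = gland, tumours = tumours, bvalues = bvalues,
                 D_background = D_background, D_outside = D_outside,
                 s0 = s0, t2w = t2w, noise_sigma = noise_sigma,
                 blend_vox = blend_vox, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Normalized ellipsoid radius field: r <= 1 inside the ellipsoid.
.ellipsoid_radius <- function(shape, center, semiaxes) {
  semiaxes <- rep_len(semiaxes, 3)
  gx <- (seq_len(shape[1]) - center[1]) / semiaxes[1]
  gy <- (seq_len(shape[2]) - center[2]) / semiaxes[2]
  gz <- (seq_len(shape[3]) - center[3]) / semiaxes[3]
  sqrt(outer(outer(gx^2, gy^2, `+`), gz^2, `+`))
}

# Soft membership: exactly 1 inside (r <= 1), Gaussian falloff outside with
# sigma of `blend` voxels, truncated to zero beyond 3 sigma so tissue
# values away from any boundary are exact.
.soft_inside <- function(r, semiaxes, blend) {
  if (blend <= 0) return((r <= 1) * 1)
  d <- (r - 1) * mean(rep_len(semiaxes, 3)) # approx. distance in voxels
  w <- exp(-(d / blend)^2)
  w[d >= 3 * blend] <- 0
  w[r <= 1] <- 1
  w
}

#' Add Rician noise to a magnitude image
#'
#' MR magnitude images carry Rician noise: the observed value is the modulus
#' of the true signal plus complex Gaussian noise,
#' `out = sqrt((v + n1)^2 + n2^2)` with `n1, n2 ~ N(0, sigma^2)`.
#' `sigma = 0` returns the input unchanged.
#'
#' @param volume numeric array of true signal.
#' @param sigma noise standard deviation (>= 0).
#' @param seed optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return array of noisy magnitudes, same shape as `volume`.
#' @export
add_rician_noise <- function(volume, sigma, seed = NULL) {
  if (sigma < 0) stop_config("sigma must be >= 0")
  if (sigma == 0) return(volume)
  if (!is.null(seed)) set.seed(seed)
  n <- length(volume)
  out <- sqrt((volume + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  array(out, dim(volume))
}

#' Generate a synthetic patient case
#'
#' Builds the nine co-registered channels of one synthetic patient from a
#' [phantom_spec]: the four acquired DWI channels (b = 0, 100, 400, 1000 by
#' default) from the mono-exponential decay with a tissue-dependent
#' diffusivity map, a T2w channel with lesion hypo-intensity, and the four
#' derived channels (ADC, CHB-DWI, CDI, relative ADC) computed from the
#' noisy acquisitions with the same estimators the pipeline applies to real
#' data. The relative-ADC channel stored on the case is normalized against
#' the gland's own surround (candidate-driven relative ADC is recomputed
#' later in the pipeline once candidate regions exist). Deterministic for a
#' fixed seed.
#'
#' @param spec a [phantom_spec].
#' @param target_b CHB-DWI extrapolation b-value (s/mm^2).
#' @param cdi_radius_mm CDI local-mixing kernel sigma (mm).
#' @return an object of class `patient_case`: list with `channels` (named
#'   list of 9 arrays: T2w, ADC, rADC, CHB_DWI, CDI, b0, b100, b400, b1000),
#'   `gland_mask`, `truth_mask`, `patient_id`, `voxel_spacing`, `spec`.
#' @export
generate_phantom <- function(spec, target_b = 2000, cdi_radius_mm = 2) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape
  r_gland <- .ellipsoid_radius(shape, spec$gland$center, spec$gland$semiaxes)
  gland_mask <- r_gland <= 1
  w_gland <- .soft_inside(r_gland, spec$gland$semiaxes, spec$blend_vox)

  D <- spec$D_outside + (spec$D_background - spec$D_outside) * w_gland
  t2w_true <- spec$t2w$outside +
    (spec$t2w$gland - spec$t2w$outside) * w_gland

  truth_mask <- array(FALSE, shape)
  for (tu in spec$tumours) {
    semi <- rep_len(tu$radius_vox, 3)
    r_tu <- .ellipsoid_radius(shape, tu$center, semi)
    inside <- r_tu <= 1
    if (!all(gland_mask[inside]))
      stop_config("tumour extends outside the gland")
    w_tu <- .soft_inside(r_tu, semi, spec$blend_vox)
    D <- D + (tu$D_lesion - spec$D_background) * w_tu * w_gland
    D[inside] <- tu$D_lesion
    ctr <- if (is.null(tu$t2w_contrast)) 0.6 else tu$t2w_contrast
    t2w_true <- t2w_true * (1 - (1 - ctr) * w_tu)
    truth_mask <- truth_mask | inside
  }

  # smooth S0 field: base level with a mild in-plane linear drift
  gx <- (seq_len(shape[1]) - (shape[1] + 1) / 2) / shape[1]
  s0_true <- spec$s0$base * (1 + spec$s0$gradient *
                               array(rep(gx, prod(shape[2:3])), shape))

  set.seed(spec$seed)
  dwi <- lapply(spec$bvalues, function(b)
    add_rician_noise(s0_true * exp(-b * D), spec$noise_sigma))
  t2w <- add_rician_noise(t2w_true, spec$noise_sigma)

  stack <- bvalue_stack(dwi, spec$bvalues, spec$voxel_spacing)
  adc <- fit_adc(stack)
  chb <- compute_chb_dwi(stack, target_b = target_b)
  cdi <- compute_cdi(stack, kernel_radius_mm = cdi_radius_mm)
  radc <- compute_relative_adc(adc, gland_mask, se_radius_vox = 3)

  channels <- list(T2w = t2w, ADC = as.array(adc), rADC = as.array(radc),
                   CHB_DWI = chb, CDI = cdi,
                   b0 = dwi[[1]], b100 = dwi[[2]],
                   b400 = dwi[[3]], b1000 = dwi[[4]])
  names(channels)[6:9] <- paste0("b", spec$bvalues)
  structure(list(channels = channels, gland_mask = gland_mask,
                 truth_mask = truth_mask,
                 patient_id = sprintf("phantom_%04d", spec$seed),
                 voxel_spacing = spec$voxel_spacing, spec = spec),
            class = "patient_case")
}

#' @export
print.patient_case <- function(x, ...) {
  cat("<patient_case> ", x$patient_id, ": ",
      paste(dim(x$channels[[1]]), collapse = " x "), " voxels, ",
      length(x$channels), " channels, ",
      sum(x$truth_mask), " truth voxels\n", sep = "")
  invisible(x)
}

#' Generate a cohort of phantoms
#'
#' Convenience wrapper producing `n` patient cases with and without lesions
#' under one master seed: patients `1..n_with_lesion` carry one lesion at a
#' randomized in-gland location, the rest are lesion-free.
#'
#' @param n number of patients.
#' @param n_with_lesion how many carry a lesion.
#' @param seed master seed; per-patient seeds are derived from it.
#' @param ... overrides passed to [phantom_spec].
#' @return list of `patient_case` objects.
#' @export
generate_cohort <- function(n = 10, n_with_lesion = 5, seed = 1L, ...) {
  set.seed(seed)
  base <- phantom_spec(...)
  lapply(seq_len(n), function(i) {
    tumours <- list()
    if (i <= n_with_lesion) {
      # lesion centre placed off-centre but safely inside the gland
      ang <- runif(1, 0, 2 * pi)
      frac <- runif(1, 0.2, 0.45)
      ctr <- base$gland$center +
        c(cos(ang) * frac * base$gland$semiaxes[1],
          sin(ang) * frac * base$gland$semiaxes[2], 0)
      tumours <- list(list(center = ctr, radius_vox = c(3.5, 3.5, 2),
                           D_lesion = 0.7e-3, t2w_contrast = 0.6))
    }
    sp <- phantom_spec(shape = base$shape,
                       voxel_spacing = base$voxel_spacing,
                       gland = base$gland, tumours = tumours,
                       bvalues = base$bvalues,
                       D_background = base$D_background,
                       D_outside = base$D_outside, s0 = base$s0,
                       t2w = base$t2w, noise_sigma = base$noise_sigma,
                       blend_vox = base$blend_vox,
                       seed = seed * 1000L + i)
    case <- generate_phantom(sp)
    case$patient_id <- sprintf("P%02d", i)
    case
  })
}
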