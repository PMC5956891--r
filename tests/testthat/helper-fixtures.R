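# Small deterministic fixtures shared across test files.

# Noiseless mono-exponential stack with a spatially varying D map.
make_decay_stack <- function(d_map, s0 = 100, bvalues = c(0, 100, 400, 1000),
                             spacing = c(1, 1, 1)) {
  vols <- lapply(bvalues, function(b) s0 * exp(-b * d_map))
  bvalue_stack(vols, bvalues, spacing)
}

# A small lesion-bearing phantom used where full-size cases are overkill.
small_lesion_case <- function(seed = 5, noise_sigma = 15) {
  sp <- phantom_spec(
    tumours = list(list(center = c(28, 28, 4.5), radius_vox = c(3.5, 3.5, 2),
                        D_lesion = 0.7e-3, t2w_contrast = 0.6)),
    noise_sigma = noise_sigma, seed = seed)
  generate_phantom(sp)
}

# Rectangular candidate region on an empty slice.
rect_region <- function(nr = 32, nc = 32, r0 = 10, r1 = 21, c0 = 12, c1 = 19,
                        slice = 1) {
  m <- matrix(FALSE, nr, nc)
  m[r0:r1, c0:c1] <- TRUE
  extract_candidate_regions(m, min_area_vox = 1, patient_id = "fix")[[1]]
}

# Independent brute-force GLCM oracle: enumerate ordered pixel pairs of a
# quantized patch at one offset, symmetrize, normalize, and compute the
# statistics directly from their definitions.
oracle_glcm <- function(patch, levels, drow, dcol) {
  lo <- min(patch); hi <- max(patch)
  q <- if (hi > lo) pmin(floor((patch - lo) / (hi - lo) * levels) + 1, levels)
       else matrix(1, nrow(patch), ncol(patch))
  P <- matrix(0, levels, levels)
  for (r in seq_len(nrow(patch))) {
    for (cc in seq_len(ncol(patch))) {
      r2 <- r + drow; c2 <- cc + dcol
      if (r2 < 1 || r2 > nrow(patch) || c2 < 1 || c2 > ncol(patch)) next
      P[q[r, cc], q[r2, c2]] <- P[q[r, cc], q[r2, c2]] + 1
      P[q[r2, c2], q[r, cc]] <- P[q[r2, c2], q[r, cc]] + 1
    }
  }
  if (sum(P) == 0) P[1, 1] <- 1
  P / sum(P)
}

oracle_glcm_stats <- function(P) {
  L <- nrow(P)
  s <- setNames(numeric(18),
                c("energy", "contrast", "correlation", "variance", "idmn",
                  "sum_average", "sum_variance", "entropy", "sum_entropy",
                  "difference_entropy", "imc", "homogeneity",
                  "autocorrelation", "difference_variance", "dissimilarity",
                  "cluster_shade", "cluster_prominence", "max_probability"))
  px <- rowSums(P); py <- colSums(P)
  mu <- sum(seq_len(L) * px)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    p <- P[i, j]
    if (p <= 0) next
    s["energy"] <- s["energy"] + p^2
    s["contrast"] <- s["contrast"] + (i - j)^2 * p
    s["idmn"] <- s["idmn"] + p / (1 + (i - j)^2 / L^2)
    s["entropy"] <- s["entropy"] - p * log2(p)
    s["homogeneity"] <- s["homogeneity"] + p / (1 + abs(i - j))
    s["autocorrelation"] <- s["autocorrelation"] + i * j * p
    s["dissimilarity"] <- s["dissimilarity"] + abs(i - j) * p
    s["cluster_shade"] <- s["cluster_shade"] + (i + j - 2 * mu)^3 * p
    s["cluster_prominence"] <- s["cluster_prominence"] + (i + j - 2 * mu)^4 * p
    s["max_probability"] <- max(s["max_probability"], p)
  }
  varx <- sum((seq_len(L) - mu)^2 * px)
  s["variance"] <- varx
  s["correlation"] <- if (varx > 0)
    (sum(outer(seq_len(L), seq_len(L)) * P) - mu^2) / varx else 0
  psum <- numeric(2 * L - 1)
  pdiff <- numeric(L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    psum[i + j - 1] <- psum[i + j - 1] + P[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + P[i, j]
  }
  ks <- seq_len(2 * L - 1) + 1
  s["sum_average"] <- sum(ks * psum)
  s["sum_variance"] <- sum((ks - s["sum_average"])^2 * psum)
  s["sum_entropy"] <- -sum(psum[psum > 0] * log2(psum[psum > 0]))
  kd <- seq_len(L) - 1
  da <- sum(kd * pdiff)
  s["difference_variance"] <- sum((kd - da)^2 * pdiff)
  s["difference_entropy"] <- -sum(pdiff[pdiff > 0] * log2(pdiff[pdiff > 0]))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hxy1 <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (P[i, j] > 0) hxy1 <- hxy1 - P[i, j] * log2(px[i] * py[j])
  }
  s["imc"] <- if (hx > 1e-12) (s["entropy"] - hxy1) / hx else 0
  s
}

# Recursive flood-fill component labelling oracle (8-connectivity).
oracle_flood_fill <- function(mask) {
  labs <- matrix(0L, nrow(mask), ncol(mask))
  lab <- 0L
  for (start in which(mask)) {
    if (labs[start] != 0L) next
    lab <- lab + 1L
    stack <- start
    while (length(stack) > 0) {
      p <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (labs[p] != 0L || !mask[p]) next
      labs[p] <- lab
      r <- (p - 1L) %% nrow(mask) + 1L
      cc <- (p - 1L) %/% nrow(mask) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; c2 <- cc + dc
        if (rr >= 1 && rr <= nrow(mask) && c2 >= 1 && c2 <= ncol(mask) &&
            mask[rr, c2] && labs[rr, c2] == 0L)
          stack <- c(stack, (c2 - 1L) * nrow(mask) + rr)
      }
    }
  }
  labs
}
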