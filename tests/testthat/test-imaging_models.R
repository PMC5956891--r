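test_that("ADC fit is exact on noiseless mono-exponential decay", {
  # two-point log-linear fit
  st2 <- bvalue_stack(list(array(100, c(2, 2, 1)),
                           array(100 * exp(-2), c(2, 2, 1))),
                      c(0, 1000))
  expect_equal(as.vector(fit_adc(st2)), rep(0.002, 4), tolerance = 1e-12)

  # constant signal -> D = 0
  stc <- bvalue_stack(list(array(50, c(2, 2, 1)), array(50, c(2, 2, 1))),
                      c(0, 1000))
  expect_equal(as.vector(fit_adc(stc)), rep(0, 4))

  # 4-b-value noiseless decay, spatially varying D, recovered to 1e-9
  set.seed(3)
  d_map <- array(runif(4 * 4 * 2, 5e-4, 2e-3), c(4, 4, 2))
  st <- make_decay_stack(d_map)
  expect_lt(max(abs(fit_adc(st) - d_map)), 1e-9)
})

test_that("all-zero-signal voxels get D = 0 and are flagged", {
  v <- array(100, c(2, 2, 1)); v[1, 1, 1] <- 0
  v2 <- array(100 * exp(-1), c(2, 2, 1)); v2[1, 1, 1] <- 0
  st <- bvalue_stack(list(v, v2), c(0, 1000))
  adc <- fit_adc(st)
  expect_equal(adc[1, 1, 1], 0)
  expect_true(attr(adc, "invalid")[1, 1, 1])
  expect_false(any(attr(adc, "invalid")[-1]))
})

test_that("b-value stack validates its invariants", {
  v <- array(1, c(2, 2, 1))
  expect_error(bvalue_stack(list(v), 0), class = "mpcad_config_error")
  expect_error(bvalue_stack(list(v, v), c(1000, 0)),
               class = "mpcad_structural_error")
  expect_error(bvalue_stack(list(v, array(1, c(3, 2, 1))), c(0, 1000)),
               class = "mpcad_structural_error")
  expect_error(bvalue_stack(list(v, -v), c(0, 1000)),
               class = "mpcad_structural_error")
})

test_that("CHB-DWI extrapolates the fitted decay", {
  st <- make_decay_stack(array(0.001, c(3, 3, 2)), s0 = 100)
  chb <- compute_chb_dwi(st, 2000)
  expect_equal(as.vector(chb), rep(100 * exp(-2), 18), tolerance = 1e-9)

  # D = 0 voxel keeps its fitted S0
  stc <- bvalue_stack(list(array(80, c(2, 2, 1)), array(80, c(2, 2, 1))),
                      c(0, 1000))
  expect_equal(as.vector(compute_chb_dwi(stc, 2000)), rep(80, 4),
               tolerance = 1e-9)

  # monotonicity: larger D -> smaller extrapolated signal
  d_lo <- compute_chb_dwi(make_decay_stack(array(5e-4, c(2, 2, 1))), 2000)
  d_hi <- compute_chb_dwi(make_decay_stack(array(2e-3, c(2, 2, 1))), 2000)
  expect_true(all(d_hi < d_lo))

  # at b == max(bvalues) the fitted (not raw) signal is reproduced
  st4 <- make_decay_stack(array(8e-4, c(2, 2, 1)))
  expect_equal(as.vector(compute_chb_dwi(st4, 1000)),
               rep(100 * exp(-0.8), 4), tolerance = 1e-9)
  expect_error(compute_chb_dwi(st4, 400), class = "mpcad_config_error")
})

test_that("CDI with zero radius is the plain cross-b-value product", {
  set.seed(4)
  vols <- lapply(1:3, function(i) array(runif(5 * 5 * 2, 1, 4), c(5, 5, 2)))
  st <- bvalue_stack(vols, c(0, 400, 1000))
  expect_equal(compute_cdi(st, 0), vols[[1]] * vols[[2]] * vols[[3]])

  # trivial two-channel product at one voxel
  st2 <- bvalue_stack(list(array(2, c(1, 1, 1)), array(3, c(1, 1, 1))),
                      c(0, 1000))
  expect_equal(as.vector(compute_cdi(st2, 0)), 6)
})

test_that("CDI kernel is normalized and matches a brute-force convolution", {
  ones <- bvalue_stack(list(array(1, c(5, 5, 3)), array(1, c(5, 5, 3))),
                       c(0, 1000))
  expect_equal(compute_cdi(ones, 2.5), array(1, c(5, 5, 3)),
               tolerance = 1e-12)

  # explicit weighted-sum oracle on a single 5x5 slice, sigma = 1 voxel
  set.seed(9)
  a <- array(runif(25, 1, 3), c(5, 5, 1))
  b <- array(runif(25, 1, 3), c(5, 5, 1))
  st <- bvalue_stack(list(a, b), c(0, 1000), voxel_spacing = c(1, 1, 10))
  got <- compute_cdi(st, 1)
  prod_sl <- (a * b)[, , 1]
  r <- 3
  k1 <- dnorm(-r:r, sd = 1); k1 <- k1 / sum(k1)
  expected <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    num <- 0; den <- 0
    for (di in -r:r) for (dj in -r:r) {
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > 5 || jj < 1 || jj > 5) next
      w <- k1[di + r + 1] * k1[dj + r + 1]
      num <- num + w * prod_sl[ii, jj]
      den <- den + w
    }
    expected[i, j] <- num / den
  }
  expect_equal(got[, , 1], expected, tolerance = 1e-10)
})

test_that("relative ADC is unity on constant maps and scale invariant", {
  adc <- array(1.3, c(12, 12, 2))
  roi <- array(FALSE, c(12, 12, 2)); roi[5:8, 5:8, 1] <- TRUE
  rel <- compute_relative_adc(adc, roi, se_radius_vox = 2)
  expect_equal(as.vector(rel), rep(1, length(adc)), tolerance = 1e-12)

  set.seed(11)
  adc2 <- array(runif(12 * 12 * 2, 0.5, 2), c(12, 12, 2))
  r1 <- compute_relative_adc(adc2, roi, 2)
  r2 <- compute_relative_adc(3.7 * adc2, roi, 2)
  expect_equal(as.vector(r1), as.vector(r2), tolerance = 1e-12)
})

test_that("relative ADC matches a hand-executed single-ROI oracle", {
  # 9x9 slice with known values; ROI is the central 3x3, SE radius 1
  vals <- matrix(seq(1, 81) / 10, 9, 9)
  adc <- array(vals, c(9, 9, 1))
  roi <- array(FALSE, c(9, 9, 1)); roi[4:6, 4:6, 1] <- TRUE
  rel <- compute_relative_adc(adc, roi, se_radius_vox = 1)

  # oracle: dilation by the radius-1 disc SE (here the full 3x3 box)
  dil <- matrix(FALSE, 9, 9)
  for (r in 4:6) for (cc in 4:6) {
    dil[(r - 1):(r + 1), (cc - 1):(cc + 1)] <- TRUE
  }
  surround <- dil & !roi[, , 1]
  med <- median(vals[surround])
  expected <- vals / med # single ROI: mean of medians == the median
  expect_equal(rel[, , 1][dil], expected[dil], tolerance = 1e-12)
  expect_equal(rel[, , 1][!dil], expected[!dil], tolerance = 1e-12)
  expect_equal(attr(rel, "surround_medians"), med)
})

test_that("degenerate-surround ROIs are skipped with a warning", {
  adc <- array(0, c(8, 8, 1))
  adc[3:5, 3:5, 1] <- 1
  roi1 <- array(FALSE, c(8, 8, 1)); roi1[3:5, 3:5, 1] <- TRUE # surround all 0
  roi2 <- array(FALSE, c(8, 8, 1)); roi2[4, 4, 1] <- TRUE     # surround 1s
  expect_warning(rel <- compute_relative_adc(adc, list(roi1, roi2), 1),
                 "zero-median")
  expect_equal(length(attr(rel, "surround_medians")), 1L)
  expect_error(suppressWarnings(compute_relative_adc(adc, list(roi1), 1)),
               class = "mpcad_structural_error")
})
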