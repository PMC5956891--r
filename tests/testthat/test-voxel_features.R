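test_that("first-order window statistics match direct arithmetic", {
  # printed 3x3 patch {1..9}
  ch <- matrix(1:9, 3, 3)
  msk <- matrix(FALSE, 3, 3); msk[2, 2] <- TRUE
  fo <- first_order_features(ch, msk, window = 3)
  v <- 1:9
  expect_equal(unname(fo[1, "mean"]), 5)
  expect_equal(unname(fo[1, "sd"]), sqrt(mean((v - 5)^2)))
  expect_equal(unname(fo[1, "skewness"]), mean((v - 5)^3) / mean((v - 5)^2)^1.5)
  expect_equal(unname(fo[1, "kurtosis"]), mean((v - 5)^4) / mean((v - 5)^2)^2 - 3)

  # constant patch -> (value, 0, 0, 0)
  foc <- first_order_features(matrix(5, 4, 4),
                              matrix(TRUE, 4, 4), window = 3)
  expect_true(all(foc[, "mean"] == 5))
  expect_true(all(foc[, c("sd", "kurtosis", "skewness")] == 0))

  # border clipping: 1-voxel mask at a corner stays finite
  mskc <- matrix(FALSE, 4, 4); mskc[1, 1] <- TRUE
  foc2 <- first_order_features(matrix(rnorm(16), 4, 4), mskc, window = 3)
  expect_true(all(is.finite(foc2)))
  expect_equal(nrow(foc2), 1L)
})

test_that("first-order statistics equal a windowed oracle on random slices", {
  set.seed(31)
  ch <- matrix(rnorm(20 * 16), 20, 16)
  msk <- matrix(runif(20 * 16) < 0.3, 20, 16)
  fo <- first_order_features(ch, msk, window = 5)
  idx <- which(msk, arr.ind = TRUE)
  for (t in seq_len(nrow(idx))) {
    r <- idx[t, 1]; cc <- idx[t, 2]
    w <- ch[max(1, r - 2):min(20, r + 2), max(1, cc - 2):min(16, cc + 2)]
    m <- mean(w); v <- mean((w - m)^2)
    expect_equal(unname(fo[t, "mean"]), m, tolerance = 1e-10)
    expect_equal(unname(fo[t, "sd"]), sqrt(v), tolerance = 1e-10)
    expect_equal(unname(fo[t, "skewness"]), mean((w - m)^3) / v^1.5,
                 tolerance = 1e-8)
  }
})

test_that("windowed GLCM statistics match brute-force pair enumeration", {
  offs <- list(d0 = c(0, 1), d45 = c(-1, 1), d90 = c(-1, 0),
               d135 = c(-1, -1))
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(3:6, 1)
    levels <- sample(c(4, 8, 32), 1)
    patch <- matrix(sample(0:9, n * n, replace = TRUE), n, n)
    msk <- matrix(FALSE, n, n)
    ctr <- (n + 1) %/% 2
    msk[ctr, ctr] <- TRUE
    got <- glcm_voxel_features(patch, msk, window = 2 * n + 1,
                               levels = levels)
    for (d in seq_along(offs)) {
      P <- oracle_glcm(patch, levels, offs[[d]][1], offs[[d]][2])
      want <- oracle_glcm_stats(P)
      block <- got[1, (d - 1) * 18 + seq_len(18)]
      expect_equal(unname(block), unname(want), tolerance = 1e-9,
                   label = sprintf("rep %d dir %s", rep, names(offs)[d]))
    }
  }
})

test_that("GLCM handles the checkerboard and degenerate windows as defined", {
  # 2x2 checkerboard, levels 2, horizontal offset: all mass off-diagonal
  cb <- matrix(c(0, 1, 1, 0), 2, 2)
  msk <- matrix(FALSE, 2, 2); msk[1, 1] <- TRUE
  got <- glcm_voxel_features(cb, msk, window = 3, levels = 2)
  expect_equal(unname(got[1, "glcm_contrast_d0"]), 1)
  expect_equal(unname(got[1, "glcm_energy_d0"]), 0.5)

  # constant window: energy 1, contrast 0, entropy 0, correlation 0
  gotc <- glcm_voxel_features(matrix(7, 5, 5),
                              matrix(TRUE, 5, 5), window = 5, levels = 8)
  expect_true(all(gotc[, grep("energy", colnames(gotc))] == 1))
  expect_true(all(gotc[, grep("_contrast_", colnames(gotc))] == 0))
  expect_true(all(gotc[, grep("_entropy_", colnames(gotc))] == 0))
  expect_true(all(gotc[, grep("glcm_correlation", colnames(gotc))] == 0))
})

test_that("gabor bank has 12 zero-mean filters with offset-invariant magnitude", {
  z <- gabor_features(matrix(0, 16, 16))
  expect_equal(dim(z)[3], 12L)
  expect_true(all(z == 0))

  set.seed(7)
  img <- matrix(rnorm(16 * 16), 16, 16)
  g1 <- gabor_features(img)
  g2 <- gabor_features(img + 100)
  expect_equal(g1, g2, tolerance = 1e-7)
})

test_that("kirsch bank responds to edges and vanishes on constants", {
  k0 <- kirsch_features(matrix(3.3, 10, 10))
  expect_equal(dim(k0)[3], 8L)
  expect_lt(max(abs(k0)), 1e-9)

  # vertical step edge (constant within rows, step across columns):
  # strongest |response| on the east/west kernels
  img <- matrix(0, 9, 9); img[, 5:9] <- 10
  kk <- kirsch_features(img)
  resp <- abs(kk[5, 5, ])
  ew <- which(dimnames(kk)[[3]] %in% c("kirsch_e", "kirsch_w"))
  expect_true(min(resp[ew]) >= max(resp[-ew]))
})

test_that("the assembled bank has exactly 96 provenance-named columns", {
  case <- small_lesion_case(seed = 3)
  msk <- array(FALSE, dim(case$gland_mask))
  msk[20:26, 20:26, 4] <- TRUE
  bank <- build_voxel_feature_bank(case, msk)
  expect_equal(ncol(bank$values), 96L)
  expect_equal(nrow(bank$values), 49L)
  expect_equal(anyDuplicated(colnames(bank$values)), 0L)
  expect_true(all(is.finite(bank$values)))
  expect_equal(sum(startsWith(colnames(bank$values), "fo_")), 4L)
  expect_equal(sum(startsWith(colnames(bank$values), "glcm_")), 72L)
  expect_equal(sum(startsWith(colnames(bank$values), "gabor_")), 12L)
  expect_equal(sum(startsWith(colnames(bank$values), "kirsch_")), 8L)

  # pure function: identical inputs give identical matrices
  bank2 <- build_voxel_feature_bank(case, msk)
  expect_identical(bank$values, bank2$values)

  # missing channel in the assignment errors
  cfg <- voxel_feature_config(channel_assignment = list(
    first_order = "nope", glcm = "ADC", gabor = "T2w", kirsch = "CHB_DWI"))
  expect_error(build_voxel_feature_bank(case, msk, cfg),
               class = "mpcad_config_error")
})

test_that("bank rows are translation equivariant", {
  # masks sit deep enough inside that no filter support touches a border
  set.seed(13)
  base <- array(rnorm(60 * 60 * 1), c(60, 60, 1))
  shift <- array(0, c(60, 60, 1))
  shift[4:60, 3:60, 1] <- base[1:57, 1:58, 1]
  msk <- array(FALSE, c(60, 60, 1)); msk[25:28, 25:28, 1] <- TRUE
  msk_s <- array(FALSE, c(60, 60, 1)); msk_s[28:31, 27:30, 1] <- TRUE
  mk_case <- function(a) list(channels = list(T2w = a, ADC = a,
                                              CHB_DWI = a),
                              gland_mask = NULL)
  b1 <- build_voxel_feature_bank(mk_case(base), msk)
  b2 <- build_voxel_feature_bank(mk_case(shift), msk_s)
  expect_equal(b1$values, b2$values, tolerance = 1e-6)
})
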