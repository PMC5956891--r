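test_that("morphology features separate regular from irregular shapes", {
  # disc region: closing ~ opening ~ disc, low-pass boundary ~ boundary
  disc_mask <- matrix(FALSE, 40, 40)
  for (r in 1:40) for (cc in 1:40)
    disc_mask[r, cc] <- (r - 20)^2 + (cc - 20)^2 <= 100
  disc <- extract_candidate_regions(disc_mask, 1, "t")[[1]]
  expect_lt(morphology_f1(disc), 0.05)
  expect_lt(morphology_f2(disc), 0.02)
  expect_lt(morphology_f3(disc), 0.05)

  # star/spiculated region of comparable size scores strictly higher
  star_mask <- matrix(FALSE, 40, 40)
  for (r in 1:40) for (cc in 1:40) {
    ang <- atan2(cc - 20, r - 20)
    rad <- sqrt((r - 20)^2 + (cc - 20)^2)
    star_mask[r, cc] <- rad <= 7 + 6 * abs(sin(4 * ang))
  }
  star <- extract_candidate_regions(star_mask, 1, "t")[[1]]
  expect_gt(morphology_f1(star), morphology_f1(disc))
  expect_gt(morphology_f2(star), morphology_f2(disc))
  expect_gte(morphology_f1(star), 0)

  # identical low/high cut-offs nullify the band discrepancy
  expect_equal(morphology_f3(disc, low_freq = 8, high_freq = 8), 0)
  f3 <- morphology_f3(star)
  expect_gte(f3, 0); expect_lte(f3, 1)
})

test_that("asymmetry features are zero for rectangles and follow the ratio", {
  rect <- rect_region()
  af <- asymmetry_features(rect)
  expect_equal(unname(af), rep(0, 4), tolerance = 1e-10)

  # a 30/20 split normalized by the whole region gives 0.2
  # build an L-free asymmetric shape: 50 voxels, 30 on one side of the
  # minor axis after construction below (5x10 rectangle with a 2x5 nub)
  m <- matrix(FALSE, 30, 30)
  m[10:14, 10:19] <- TRUE
  af2 <- asymmetry_features(extract_candidate_regions(m, 1, "t")[[1]])
  expect_equal(unname(af2), rep(0, 4), tolerance = 1e-10)

  # direct arithmetic on a constructed 30/20 split
  a_large <- 30; a_small <- 20
  expect_equal((a_large - a_small) / (a_large + a_small), 0.2)
  # normalize-by-smaller dominates normalize-by-whole on asymmetric shapes
  m2 <- matrix(FALSE, 30, 30)
  m2[10:14, 10:19] <- TRUE
  m2[15:16, 10:14] <- TRUE
  af3 <- asymmetry_features(extract_candidate_regions(m2, 1, "t")[[1]])
  expect_gte(af3[["major_smaller"]], af3[["major_whole"]])
  expect_gte(af3[["minor_smaller"]], af3[["minor_whole"]])
})

test_that("physiology features match a hand-enumerated GLCM oracle", {
  # printed 2x3 toy ROI
  vals <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  ch <- matrix(0, 8, 8)
  ch[3:4, 3:5] <- vals
  m <- matrix(FALSE, 8, 8); m[3:4, 3:5] <- TRUE
  reg <- extract_candidate_regions(m, 1, "t")[[1]]
  phys <- physiology_features(reg, ch, levels = 4)
  expect_length(phys, 26L)

  v <- as.vector(vals)
  expect_equal(unname(phys["mean"]), mean(v))
  expect_equal(unname(phys["median"]), median(v))
  expect_equal(unname(phys["sd"]), sqrt(mean((v - mean(v))^2)))
  expect_equal(unname(phys["min"]), 1)
  expect_equal(unname(phys["max"]), 6)

  # oracle: horizontal pairs with both pixels in the 2x3 ROI
  lo <- 1; hi <- 6; L <- 4
  q <- matrix(pmin(as.integer((vals - lo) / (hi - lo) * L) + 1L, L), 2, 3)
  P <- matrix(0, L, L)
  for (r in 1:2) for (cc in 1:2) {
    a <- q[r, cc]; b <- q[r, cc + 1]
    P[a, b] <- P[a, b] + 1; P[b, a] <- P[b, a] + 1
  }
  P <- P / sum(P)
  want <- oracle_glcm_stats(P)
  got <- phys[8:26]
  expect_equal(unname(got[names(want)[1:10]]), unname(want[1:10]),
               tolerance = 1e-10)
  expect_equal(unname(phys["normalized_entropy"]),
               unname(want["entropy"]) / log2(L^2), tolerance = 1e-10)
  expect_equal(unname(got[names(want)[11:18]]), unname(want[11:18]),
               tolerance = 1e-10)
})

test_that("region GLCM block equals brute force on random small ROIs", {
  set.seed(61)
  for (rep in 1:30) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1)
    ch <- matrix(0, 12, 12)
    vals <- matrix(sample(0:7, nr * nc, replace = TRUE), nr, nc)
    ch[2 + seq_len(nr), 2 + seq_len(nc)] <- vals
    m <- matrix(FALSE, 12, 12)
    m[2 + seq_len(nr), 2 + seq_len(nc)] <- TRUE
    # carve a random hole to exercise the both-pixels-in-ROI rule
    if (nr * nc > 6) {
      hole <- sample(which(m), 1)
      m[hole] <- FALSE
    }
    reg <- list(mask = m, area = sum(m), slice_index = 1)
    phys <- physiology_features(reg, ch, levels = 8)

    lo <- min(ch[m]); hi <- max(ch[m])
    q <- matrix(1L, 12, 12)
    if (hi > lo) q[m] <- pmin(as.integer((ch[m] - lo) / (hi - lo) * 8) + 1L, 8L)
    P <- matrix(0, 8, 8)
    npair <- 0
    for (r in 1:12) for (cc in 1:11) {
      if (m[r, cc] && m[r, cc + 1]) {
        a <- q[r, cc]; b <- q[r, cc + 1]
        P[a, b] <- P[a, b] + 1; P[b, a] <- P[b, a] + 1
        npair <- npair + 1
      }
    }
    if (npair == 0) P[1, 1] <- 1
    P <- P / sum(P)
    want <- oracle_glcm_stats(P)
    expect_equal(unname(phys[8:26][names(want)[1:10]]), unname(want[1:10]),
                 tolerance = 1e-9, label = paste("rep", rep))
    expect_equal(unname(phys[8:26][names(want)[11:18]]),
                 unname(want[11:18]), tolerance = 1e-9)
  }
})

test_that("constant-intensity ROIs degrade gracefully", {
  ch <- matrix(4, 10, 10)
  reg <- rect_region(10, 10, 3, 6, 3, 6)
  phys <- physiology_features(reg, ch)
  expect_equal(unname(phys[c("mean", "median", "min", "max")]), rep(4, 4))
  expect_equal(unname(phys[c("sd", "kurtosis", "skewness")]), rep(0, 3))
  expect_equal(unname(phys["energy"]), 1)
  expect_equal(unname(phys["entropy"]), 0)
})

test_that("the assembled region vector has 242 shape-consistent entries", {
  case <- small_lesion_case(seed = 4)
  reg <- rect_region(dim(case$gland_mask)[1], dim(case$gland_mask)[2],
                     20, 27, 20, 27, slice = 4)
  reg$slice_index <- 4
  v <- assemble_region_vector(reg, case)
  expect_length(v, 242L)
  expect_equal(anyDuplicated(names(v)), 0L)
  expect_true(all(is.finite(v)))
  expect_equal(sum(startsWith(names(v), "phys_")), 234L)
  expect_equal(sum(startsWith(names(v), "morph_")), 3L)
  expect_equal(sum(startsWith(names(v), "asym_")), 4L)
  expect_equal(unname(v["size_mm2"]), reg$area * 1.56^2, tolerance = 1e-10)

  # channel order independence under name-keyed assembly
  case2 <- case
  case2$channels <- case2$channels[c(3, 1, 2, 5, 4, 9, 6, 8, 7)]
  expect_equal(assemble_region_vector(reg, case2), v)

  # missing channel errors
  case3 <- case; case3$channels$CDI <- NULL
  expect_error(assemble_region_vector(reg, case3),
               class = "mpcad_config_error")
})

test_that("mRMR selects by relevance then redundancy", {
  set.seed(62)
  n <- 300
  y <- rep(c(0, 1), each = n / 2)
  strong <- y + rnorm(n, sd = 0.05)
  dup <- strong + rnorm(n, sd = 0.01) # near-duplicate of strong
  weak <- y + rnorm(n, sd = 0.8)      # informative but noisy, independent
  noise <- rnorm(n)
  X <- cbind(noise = noise, strong = strong, dup = dup, weak = weak)

  # the label itself (as a feature) is picked first
  expect_equal(mrmr_select(cbind(noise, y_feat = y, weak), y, 1), 2L)

  # k = 1 is the max-relevance feature
  expect_equal(mrmr_select(X, y, 1), 2L)

  # redundancy: the duplicate is deferred until after the weak independent
  sel <- mrmr_select(X, y, 3)
  expect_equal(sel[1], 2L)
  expect_equal(sel[2], 4L)

  # exhaustive check of the greedy score at step 2
  D <- lapply(seq_len(ncol(X)), function(j) mpcad:::.discretize_ef(X[, j], 10))
  yd <- as.integer(as.factor(y))
  rel <- vapply(D, mpcad:::.mutual_information, numeric(1), b = yd)
  score2 <- vapply(c(1, 3, 4), function(j)
    rel[j] - mpcad:::.mutual_information(D[[j]], D[[2]]), numeric(1))
  expect_equal(sel[2], c(1L, 3L, 4L)[which.max(score2)])

  expect_warning(mrmr_select(X, y, 10), "capped")
})

test_that("two-stage selection finds a planted separating feature", {
  set.seed(63)
  n <- 80
  y <- rep(c(FALSE, TRUE), each = n / 2)
  X <- matrix(rnorm(n * 242), n, 242)
  case <- small_lesion_case(seed = 4)
  reg <- rect_region(48, 48, 20, 25, 20, 25, slice = 4); reg$slice_index <- 4
  colnames(X) <- names(assemble_region_vector(reg, case))
  planted <- "phys_entropy.ADC"
  X[, planted] <- ifelse(y, 3, -3) + rnorm(n, sd = 0.1)
  plan <- two_stage_selection(X, y, criterion = "auc")
  expect_true(planted %in% plan$final_selected)
  expect_equal(plan$training_value, 1.0, tolerance = 1e-9)
  expect_true(all(plan$final_selected %in%
                    c(unlist(plan$per_channel_selected), plan$mas_selected)))

  # determinism
  plan2 <- two_stage_selection(X, y, criterion = "auc")
  expect_identical(plan$final_selected, plan2$final_selected)
})

test_that("the margin classifier separates and ignores row order", {
  set.seed(64)
  n <- 60
  y <- rep(c(FALSE, TRUE), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6)
  colnames(X) <- paste0("f", 1:6)
  X[, 1] <- ifelse(y, 2, -2) + rnorm(n, sd = 0.2)
  plan <- structure(list(final_selected = colnames(X)),
                    class = "selection_plan")
  out <- classify_regions(X, y, X, plan)
  expect_equal(out$label, y) # linearly separable: perfect training accuracy
  expect_true(all(out$score[y] > out$score[!y] - 1e-9))

  perm <- sample(n)
  out2 <- classify_regions(X[perm, ], y[perm], X, plan)
  expect_equal(out2$label, out$label)
  # margin values agree up to optimizer tolerance
  expect_equal(out2$score, out$score, tolerance = 1e-2)

  expect_error(classify_regions(X, rep(TRUE, n), X, plan),
               class = "mpcad_structural_error")
})

test_that("morphology and asymmetry depend on the mask alone", {
  reg1 <- rect_region(32, 32, 10, 17, 8, 13)
  reg2 <- rect_region(32, 32, 15, 22, 16, 21) # translated copy
  expect_equal(morphology_f1(reg1), morphology_f1(reg2))
  expect_equal(morphology_f2(reg1), morphology_f2(reg2), tolerance = 1e-9)
  expect_equal(asymmetry_features(reg1), asymmetry_features(reg2))
})
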