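test_that("PCA compaction picks the smallest u reaching the variance target", {
  # 2-component Gaussian data with one dominant direction (~95% variance)
  set.seed(51)
  n <- 2000
  X <- cbind(rnorm(n, sd = sqrt(19)), rnorm(n, sd = 1)) %*%
    matrix(c(0.8, 0.6, -0.6, 0.8), 2, 2)
  cp <- pca_compact(X, 0.90)
  expect_equal(cp$u, 1L)
  expect_gte(cumsum(cp$explained)[cp$u], 0.90)

  # variance_fraction 1 keeps the full rank
  cp2 <- pca_compact(X, 1.0)
  expect_equal(cp2$u, 2L)

  # held-out projection reproduces training scores
  pr <- project_compact(cp, X)
  expect_equal(unname(pr), unname(cp$values), tolerance = 1e-10)
})

test_that("EM recovers well-separated mixture parameters", {
  set.seed(52)
  n <- 2000
  mu1 <- c(0, 0); mu2 <- c(5, 5) # 5-sigma separation (unit variance)
  X <- rbind(matrix(rnorm(n, sd = 1), n / 2, 2),
             sweep(matrix(rnorm(n, sd = 1), n / 2, 2), 2, mu2, `+`))
  model <- learn_sparse_texture_model(X, m = 2, seed = 7)
  means <- t(vapply(model$atoms, `[[`, numeric(2), "mean"))
  ord <- order(means[, 1])
  expect_lt(max(abs(means[ord[1], ] - mu1)), 0.05)
  expect_lt(max(abs(means[ord[2], ] - mu2)), 0.05)
  w <- vapply(model$atoms, `[[`, 1, "weight")
  expect_equal(sum(w), 1, tolerance = 1e-9)

  # determinism under a fixed seed
  model2 <- learn_sparse_texture_model(X, m = 2, seed = 7)
  expect_equal(model, model2)

  # m = 1 degenerates to the sample mean / covariance
  m1 <- learn_sparse_texture_model(X, m = 1, seed = 1)
  expect_equal(m1$atoms[[1]]$mean, colMeans(X), tolerance = 1e-12)
  expect_equal(m1$atoms[[1]]$covariance,
               crossprod(scale(X, scale = FALSE)) / nrow(X) + diag(1e-6, 2),
               tolerance = 1e-9)
})

test_that("EM agrees with an independent mixture fit on separable data", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  set.seed(53)
  X <- rbind(matrix(rnorm(600, sd = 1), 300, 2),
             matrix(rnorm(600, mean = 6, sd = 1.3), 300, 2))
  ours <- learn_sparse_texture_model(X, m = 2, seed = 3)
  ref <- Mclust(X, G = 2, modelNames = "VVV", verbose = FALSE)
  ref_means <- t(ref$parameters$mean)
  our_means <- t(vapply(ours$atoms, `[[`, numeric(2), "mean"))
  ord_o <- order(our_means[, 1]); ord_r <- order(ref_means[, 1])
  expect_lt(max(abs(our_means[ord_o, ] - ref_means[ord_r, ])), 0.05)
})

test_that("distinctiveness follows the printed divergence exactly", {
  # identical atoms have zero distinctiveness
  a <- list(mean = c(1, 2), covariance = diag(2))
  expect_equal(kl_distinctiveness(a, a), 0)

  # identity covariances: beta = ||dmu||^2 / 2
  b <- list(mean = c(3, 2), covariance = diag(2))
  expect_equal(kl_distinctiveness(a, b), 2) # (2,0): 0 - 2 + 2 + 4/2

  # random PD atoms match a term-by-term symbolic oracle
  set.seed(54)
  for (rep in 1:20) {
    mk <- function() {
      A <- matrix(rnorm(9), 3, 3)
      list(mean = rnorm(3), covariance = crossprod(A) + diag(0.5, 3))
    }
    ai <- mk(); aj <- mk()
    sj_inv <- solve(aj$covariance)
    dmu <- aj$mean - ai$mean
    want <- log(det(aj$covariance) / det(ai$covariance)) - 3 +
      sum(diag(sj_inv %*% ai$covariance)) +
      as.numeric(t(dmu) %*% sj_inv %*% dmu) / 2
    expect_equal(kl_distinctiveness(ai, aj), want, tolerance = 1e-9)
  }
})

test_that("the distinctiveness matrix has a zero diagonal and is >= 0 on PD atoms", {
  set.seed(55)
  X <- matrix(rnorm(3000), 1000, 3)
  model <- learn_sparse_texture_model(X, m = 4, seed = 2)
  beta <- distinctiveness_matrix(model)
  expect_equal(diag(beta), rep(0, 4))
  expect_true(all(beta >= 0))
})

test_that("saliency combines distinctiveness and occupancy as printed", {
  beta <- matrix(c(0, 4, 4, 0), 2, 2)
  expect_equal(compute_saliency(beta, c(0.9, 0.1)), c(3.6, 0.4))
  expect_equal(compute_saliency(beta, c(0.9, 0.1), prob_index = "j"),
               c(0.4, 3.6))
  # zero distinctiveness -> zero saliency; linear in beta
  expect_equal(compute_saliency(matrix(0, 2, 2), c(0.5, 0.5)), c(0, 0))
  expect_equal(compute_saliency(3 * beta, c(0.9, 0.1)),
               3 * compute_saliency(beta, c(0.9, 0.1)))
  expect_error(compute_saliency(beta, c(0.9, 0.3)),
               class = "mpcad_structural_error")
})

test_that("salient-voxel labelling thresholds at half the maximum strictly", {
  alpha <- c(1.0, 0.6, 0.4)
  lab <- label_salient_voxels(c(1, 2, 3, 2), alpha)
  expect_equal(lab, c(TRUE, TRUE, FALSE, TRUE))
  # all atoms equal -> all salient; all-zero alpha -> nothing salient
  expect_true(all(label_salient_voxels(1:3, c(2, 2, 2))))
  expect_false(any(label_salient_voxels(1:3, c(0, 0, 0))))
})

test_that("candidate extraction matches a flood-fill oracle", {
  set.seed(56)
  for (rep in 1:25) {
    msk <- matrix(runif(16 * 16) < 0.35, 16, 16)
    labs <- mpcad:::.label_components8(msk)
    want <- oracle_flood_fill(msk)
    # same partition (labels may be permuted)
    expect_equal(max(labs), max(want))
    if (max(labs) > 0) {
      for (l in seq_len(max(labs))) {
        cells <- labs == l & msk
        expect_equal(length(unique(want[cells])), 1L)
      }
    }
  }
})

test_that("candidate regions carry area, centroid and closed boundaries", {
  m <- matrix(FALSE, 20, 20)
  m[3:6, 3:6] <- TRUE           # blob 1: 16 voxels
  m[12:13, 12:16] <- TRUE       # blob 2: 10 voxels
  m[18, 18] <- TRUE             # single voxel, below min_area
  regs <- extract_candidate_regions(m, min_area_vox = 2, patient_id = "t")
  expect_length(regs, 2L)
  areas <- vapply(regs, `[[`, 1, "area")
  expect_equal(sort(areas), c(10, 16))
  sq <- regs[[which(areas == 16)]]
  expect_equal(unname(sq$centroid), c(4.5, 4.5))
  # boundary pixels all lie on the mask edge
  expect_true(all(sq$mask[sq$boundary]))

  # min_area filtering removes everything when set high
  expect_length(extract_candidate_regions(m, min_area_vox = 50), 0L)
})
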