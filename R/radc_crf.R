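#' Unary potentials from region classification results
#'
#' Maps the region-resolution classifier output to per-voxel label costs on
#' one slice. Each voxel inside a candidate region receives the region's
#' positive-class probability via logistic squashing of its margin score;
#' voxels outside every candidate region receive the small background
#' probability `p_bg`. Costs are the negative log-probabilities
#' `psi_u(y=1) = -log p`, `psi_u(y=0) = -log(1-p)`, clamped at `cost_cap`.
#'
#' @param regions list of `candidate_region`s on this slice.
#' @param labels logical vector: classifier label per region.
#' @param scores numeric vector: classifier margin score per region.
#' @param shape slice dimensions (nrow, ncol).
#' @param p_bg background positive probability.
#' @param cost_cap clamp for infinite costs.
#' @return list with `p` (probability matrix) and `unary` (array
#'   `[nrow, ncol, 2]`, cost of label 0 then label 1).
#' @export
build_unary <- function(regions, labels, scores, shape, p_bg = 0.01,
                        cost_cap = 1e6) {
  p <- matrix(p_bg, shape[1], shape[2])
  for (i in seq_along(regions)) {
    pr <- 1 / (1 + exp(-scores[i]))
    # a region labelled negative should not push voxels positive
    if (!labels[i]) pr <- min(pr, 0.5)
    p[regions[[i]]$mask] <- pr
  }
  u0 <- pmin(-log(1 - p), cost_cap)
  u1 <- pmin(-log(p), cost_cap)
  list(p = p, unary = array(c(u0, u1), c(shape, 2)))
}

#' Assemble a CRF labelling problem on one slice
#'
#' Builds the clique structure (4-neighbour in-plane pairs inside the
#' working mask) and the contrast-sensitive pairwise weights
#' `w * exp(-||f_i - f_j||^2 / (2 sigma^2))` from per-voxel feature
#' vectors. When `sigma` is `NULL` it defaults to the median pairwise
#' feature distance over the edges (1 if all distances vanish), so
#' smoothing adapts to the feature contrast scale.
#'
#' @param unary array `[nrow, ncol, 2]` of label costs.
#' @param features matrix `[n_mask x d]` of voxel features aligned with
#'   column-major `which(mask)` order (e.g. compacted relative-ADC texture
#'   features).
#' @param mask 2-D logical working mask.
#' @param w pairwise weight (>= 0).
#' @param sigma feature-contrast bandwidth (> 0), or `NULL` for the median
#'   heuristic.
#' @return a `crf_problem` list: `unary` (`[n x 2]`), `edges` (`[m x 2]`
#'   indices into mask voxels), `edge_weights`, `mask`, `n`.
#' @export
make_crf_problem <- function(unary, features, mask, w = 1, sigma = NULL) {
  if (w < 0) stop_config("w must be >= 0")
  nr <- nrow(mask); nc <- ncol(mask)
  if (!all(dim(unary)[1:2] == c(nr, nc)))
    stop_structural("unary and mask shapes differ")
  lin <- which(mask)
  n <- length(lin)
  id <- matrix(0L, nr, nc)
  id[lin] <- seq_len(n)
  edges <- NULL
  # right neighbours and down neighbours (4-connectivity)
  right <- mask[, -nc, drop = FALSE] & mask[, -1, drop = FALSE]
  if (any(right)) {
    ij <- which(right, arr.ind = TRUE)
    edges <- cbind(id[cbind(ij[, 1], ij[, 2])],
                   id[cbind(ij[, 1], ij[, 2] + 1L)])
  }
  down <- mask[-nr, , drop = FALSE] & mask[-1, , drop = FALSE]
  if (any(down)) {
    ij <- which(down, arr.ind = TRUE)
    edges <- rbind(edges, cbind(id[cbind(ij[, 1], ij[, 2])],
                                id[cbind(ij[, 1] + 1L, ij[, 2])]))
  }
  if (is.null(edges)) edges <- matrix(integer(0), 0, 2)
  features <- as.matrix(features)
  if (nrow(features) != n)
    stop_structural("features must have one row per mask voxel")
  if (nrow(edges) > 0) {
    d2 <- rowSums((features[edges[, 1], , drop = FALSE] -
                     features[edges[, 2], , drop = FALSE])^2)
    if (is.null(sigma)) {
      sigma <- sqrt(median(d2))
      if (sigma <= 0) sigma <- 1
    }
    if (sigma <= 0) stop_config("sigma must be > 0")
    ew <- w * exp(-d2 / (2 * sigma^2))
  } else ew <- numeric(0)
  u <- cbind(unary[, , 1][lin], unary[, , 2][lin])
  if (any(!is.finite(u))) stop_structural("unary costs must be finite")
  structure(list(unary = u, edges = edges, edge_weights = ew,
                 mask = mask, n = n, w = w, sigma = sigma),
            class = "crf_problem")
}

#' CRF energy of a (relaxed) label field
#'
#' `E(Y) = sum_i [(1-y_i) psi_u(0) + y_i psi_u(1)]
#'        + sum_(i,j) w_ij |y_i - y_j|`,
#' the linear interpolation of the unary costs in each `y_i in [0, 1]` plus
#' the contrast-weighted total-variation pairwise term. For binary Y this
#' is the exact discrete labelling energy.
#'
#' @param problem a `crf_problem`.
#' @param Y numeric vector in [0, 1], one entry per mask voxel.
#' @return scalar energy.
#' @export
crf_energy <- function(problem, Y) {
  if (length(Y) != problem$n) stop_structural("label field length mismatch")
  e <- sum((1 - Y) * problem$unary[, 1] + Y * problem$unary[, 2])
  if (nrow(problem$edges) > 0)
    e <- e + sum(problem$edge_weights *
                   abs(Y[problem$edges[, 1]] - Y[problem$edges[, 2]]))
  e
}

# Smoothed energy and gradient used by the descent (|t| ~ sqrt(t^2 + eps)).
.crf_energy_smooth <- function(problem, Y, eps = 1e-8) {
  e <- sum((1 - Y) * problem$unary[, 1] + Y * problem$unary[, 2])
  if (nrow(problem$edges) > 0) {
    dd <- Y[problem$edges[, 1]] - Y[problem$edges[, 2]]
    e <- e + sum(problem$edge_weights * sqrt(dd^2 + eps))
  }
  e
}

.crf_grad_smooth <- function(problem, Y, eps = 1e-8) {
  g <- problem$unary[, 2] - problem$unary[, 1]
  if (nrow(problem$edges) > 0) {
    i <- problem$edges[, 1]; j <- problem$edges[, 2]
    dd <- Y[i] - Y[j]
    t <- problem$edge_weights * dd / sqrt(dd^2 + eps)
    rs <- rowsum(c(t, -t), c(i, j))
    idx <- as.integer(rownames(rs))
    g[idx] <- g[idx] + rs[, 1]
  }
  g
}

#' Refine labels by projected gradient descent on the CRF energy
#'
#' Minimizes the relaxed energy over `Y in [0, 1]^n` by projected gradient
#' descent with the pairwise absolute difference smoothed as
#' `sqrt(d^2 + 1e-8)`. The relaxed objective (linear unary plus weighted
#' total variation) is convex, so descent reaches the global optimum up to
#' the smoothing and step tolerance; the step is halved whenever a move
#' would increase the energy, making the recorded energy trace
#' non-increasing. The final binary field thresholds at 0.5.
#'
#' @param problem a `crf_problem`.
#' @param step initial gradient step.
#' @param max_iter iteration cap.
#' @param tol stop when the largest label change drops below `tol`.
#' @return list with `labels` (logical), `relaxed` (numeric in [0, 1]),
#'   `energy_trace` (smoothed energies, non-increasing), `energy` (exact
#'   energy of the binary labels), `converged`.
#' @export
refine_labels <- function(problem, step = 0.25, max_iter = 500,
                          tol = 1e-5) {
  if (step <= 0) stop_config("step must be > 0")
  step_cap <- step * 8
  step0 <- step
  Y <- as.numeric(problem$unary[, 2] < problem$unary[, 1])
  trace <- numeric(0)
  converged <- FALSE
  # graduated smoothing: soften the |y_i - y_j| kink first so coupled
  # voxel blocks can slide jointly, then tighten towards the exact energy;
  # the recorded energy is non-increasing both within and across stages
  # (shrinking eps can only lower the smoothed energy at fixed Y)
  eps_stages <- c(1e-2, 1e-4, 1e-8)
  iters_per_stage <- ceiling(max_iter / length(eps_stages))
  for (eps in eps_stages) {
    e <- .crf_energy_smooth(problem, Y, eps)
    trace <- c(trace, e)
    step <- step0
    converged <- FALSE
    for (it in seq_len(iters_per_stage)) {
      g <- .crf_grad_smooth(problem, Y, eps)
      accepted <- FALSE
      for (h in 1:40) {
        Ynew <- pmin(pmax(Y - step * g, 0), 1)
        enew <- .crf_energy_smooth(problem, Ynew, eps)
        if (enew <= e) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) {
        converged <- TRUE
        break
      }
      delta <- max(abs(Ynew - Y))
      Y <- Ynew
      e <- enew
      trace <- c(trace, e)
      # regrow the step after a successful move so the descent cannot
      # stall on a transiently small step near the kinks
      step <- min(step * 1.5, step_cap)
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("CRF descent reached max_iter without meeting tolerance")
  labels <- Y > 0.5
  labels <- .icm_polish(problem, labels)
  list(labels = labels, relaxed = Y, energy_trace = trace,
       energy = crf_energy(problem, as.numeric(labels)),
       converged = converged)
}

# Greedy single-voxel flips on the discrete energy until no flip improves:
# removes the residual rounding error of thresholding the relaxed field.
.icm_polish <- function(problem, labels, max_sweeps = 20) {
  y <- as.numeric(labels)
  n <- problem$n
  has_edges <- nrow(problem$edges) > 0
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in seq_len(n)) {
      d_unary <- (problem$unary[i, 2] - problem$unary[i, 1]) * (1 - 2 * y[i])
      d_pair <- 0
      if (has_edges) {
        on_i <- problem$edges[, 1] == i | problem$edges[, 2] == i
        if (any(on_i)) {
          j <- ifelse(problem$edges[on_i, 1] == i,
                      problem$edges[on_i, 2], problem$edges[on_i, 1])
          wj <- problem$edge_weights[on_i]
          d_pair <- sum(wj * (abs(1 - y[i] - y[j]) - abs(y[i] - y[j])))
        }
      }
      if (d_unary + d_pair < -1e-12) {
        y[i] <- 1 - y[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  y > 0.5
}

#' Relative-ADC voxel texture features for the CRF pairwise term
#'
#' Evaluates the full 96-column voxel texture bank with every operator
#' group assigned to the relative-ADC channel, then compacts it by PCA to
#' the components explaining `variance_fraction` of the variance. The
#' compacted per-voxel vectors drive the contrast-sensitive pairwise
#' weights of the CRF.
#'
#' @param case a `patient_case` with an `rADC` channel.
#' @param mask 3-D logical array of voxels to evaluate (default gland).
#' @param config a [voxel_feature_config]; its channel assignment is
#'   overridden to `rADC` for all groups.
#' @param variance_fraction PCA compaction target.
#' @return list with `features` (compact scores), `voxel_index`, `compact`
#'   (the fitted `compact_features`), `raw` (the 96-column bank).
#' @export
voxel_features_on_radc <- function(case, mask = NULL,
                                   config = voxel_feature_config(),
                                   variance_fraction = 0.90) {
  if (is.null(case$channels[["rADC"]]))
    stop_config("case has no rADC channel")
  config$channel_assignment <- list(first_order = "rADC", glcm = "rADC",
                                    gabor = "rADC", kirsch = "rADC")
  bank <- build_voxel_feature_bank(case, mask, config)
  if (nrow(bank$values) <= ncol(bank$values)) {
    # too few voxels for a meaningful PCA: use standardized raw features
    scl <- apply(bank$values, 2, sd); scl[scl == 0] <- 1
    scores <- scale(bank$values, scale = scl)
    return(list(features = scores, voxel_index = bank$voxel_index,
                compact = NULL, raw = bank$values))
  }
  cp <- pca_compact(bank$values, variance_fraction)
  list(features = cp$values, voxel_index = bank$voxel_index,
       compact = cp, raw = bank$values)
}
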