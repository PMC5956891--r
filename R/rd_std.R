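#' PCA compaction of the voxel feature bank
#'
#' Z-scores each feature column and keeps the smallest number `u` of
#' principal components whose cumulative explained variance reaches
#' `variance_fraction` (default 90%). Zero-variance columns are left
#' centred but unscaled. The returned object carries the training
#' centring/scaling and loadings so held-out data can be projected into
#' the same compact space.
#'
#' @param features feature matrix `[n_voxels x p]`, or the list returned by
#'   [build_voxel_feature_bank].
#' @param variance_fraction target cumulative explained variance in (0, 1].
#' @return a `compact_features` list: `values` (scores `[n x u]`), `u`,
#'   `rotation`, `center`, `scale`, `explained` (per-component variance
#'   fractions).
#' @export
pca_compact <- function(features, variance_fraction = 0.90) {
  X <- if (is.list(features) && !is.null(features$values)) features$values
       else features
  if (any(!is.finite(X))) stop_structural("features must be finite")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  scl[scl == 0] <- 1
  Xs <- scale(X, center = ctr, scale = scl)
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(expl)
  u <- which(cum >= variance_fraction)[1]
  if (is.na(u)) {
    warning("rank-deficient input: explained variance capped below target")
    u <- length(expl)
  }
  structure(list(values = pc$x[, seq_len(u), drop = FALSE], u = u,
                 rotation = pc$rotation, center = ctr, scale = scl,
                 explained = expl,
                 variance_fraction = variance_fraction),
            class = "compact_features")
}

#' Project new data into a fitted compact space
#'
#' @param compact a `compact_features` object.
#' @param X new feature matrix with the same columns as the training data.
#' @return score matrix `[n x u]`.
#' @export
project_compact <- function(compact, X) {
  Xs <- scale(X, center = compact$center, scale = compact$scale)
  (Xs %*% compact$rotation)[, seq_len(compact$u), drop = FALSE]
}

# k-means++ seeding: first centre uniform, then proportional to squared
# distance from the nearest chosen centre.
.kmeanspp_centers <- function(X, m) {
  n <- nrow(X)
  centers <- matrix(0, m, ncol(X))
  i <- sample.int(n, 1)
  centers[1, ] <- X[i, ]
  d2 <- rowSums((X - rep(centers[1, ], each = n))^2)
  for (k in seq_len(m - 1) + 1) {
    p <- d2 / sum(d2)
    i <- sample.int(n, 1, prob = p)
    centers[k, ] <- X[i, ]
    d2 <- pmin(d2, rowSums((X - rep(centers[k, ], each = n))^2))
  }
  centers
}

# Log density of each row of X under each Gaussian atom: [n x m].
# Uses the Cholesky factor once per atom and a single BLAS multiply for
# the whitening, which keeps the E-step cheap on large voxel sets.
.atom_logdens <- function(X, atoms) {
  n <- nrow(X); d <- ncol(X)
  out <- matrix(0, n, length(atoms))
  for (k in seq_along(atoms)) {
    a <- atoms[[k]]
    ch <- chol(a$covariance) # A = R'R, Mahalanobis = ||(x - mu) R^-1||^2
    z <- (X - rep(a$mean, each = n)) %*% backsolve(ch, diag(d))
    out[, k] <- -0.5 * rowSums(z^2) - sum(log(diag(ch))) -
      0.5 * d * log(2 * pi)
  }
  out
}

#' Learn the sparse texture model by expectation maximization
#'
#' Fits an m-component Gaussian mixture (full covariances) to the compact
#' texture representations. Each component is one texture atom (mean,
#' covariance, weight). Initialization is k-means++; to reduce
#' sensitivity to the initialization, `n_restarts` short EM runs
#' (`short_iter` iterations each, seeds derived from `seed`) are compared
#' by log-likelihood and the best one is continued to convergence.
#' Covariances carry a ridge of 1e-6 on the diagonal; EM stops when the
#' mean per-voxel log-likelihood gain drops below `tol` (1e-6) or after
#' 500 iterations. A collapsing component (weight below 1e-8) is
#' re-seeded once from a random data point before the fit is abandoned.
#'
#' @param compact a `compact_features` object or a plain score matrix.
#' @param m number of texture atoms (>= 1).
#' @param seed integer seed for the initialization.
#' @param ridge covariance regularization added to the diagonal.
#' @param tol mean per-voxel log-likelihood convergence tolerance.
#' @param max_iter iteration cap for the final run.
#' @param n_restarts number of short-run initializations compared.
#' @param short_iter iterations per short run.
#' @return a `sparse_texture_model`: list with `atoms` (each mean,
#'   covariance, weight), `m`, `seed`, `loglik`, `iterations`.
#' @export
learn_sparse_texture_model <- function(compact, m = 8, seed = 1L,
                                       ridge = 1e-6, tol = 1e-6,
                                       max_iter = 500, n_restarts = 3,
                                       short_iter = 30) {
  X <- if (is.list(compact) && !is.null(compact$values)) compact$values
       else as.matrix(compact)
  n <- nrow(X); d <- ncol(X)
  if (m < 1) stop_config("m must be >= 1")
  if (m > 1 && n < 10 * m)
    stop_config("need at least 10 voxels per texture atom")
  if (m == 1) {
    set.seed(seed)
    cov1 <- crossprod(scale(X, scale = FALSE)) / n + diag(ridge, d)
    atoms <- list(list(mean = colMeans(X), covariance = cov1, weight = 1))
    return(structure(list(atoms = atoms, m = 1L, seed = seed,
                          loglik = sum(.atom_logdens(X, atoms)),
                          iterations = 0L),
                     class = "sparse_texture_model"))
  }
  best <- NULL
  for (r in seq_len(max(1, n_restarts))) {
    init <- .em_init(X, m, seed = seed + (r - 1L) * 1009L, ridge = ridge)
    run <- .em_run(X, init$atoms, init$w, ridge = ridge, tol = tol,
                   max_iter = min(short_iter, max_iter))
    if (is.null(best) || run$loglik > best$loglik) best <- run
  }
  fit <- .em_run(X, best$atoms, best$w, ridge = ridge, tol = tol,
                 max_iter = max_iter)
  structure(list(atoms = fit$atoms, m = as.integer(m), seed = seed,
                 loglik = fit$loglik,
                 iterations = best$iterations + fit$iterations),
            class = "sparse_texture_model")
}

# k-means++ hard-assignment initialization of the mixture parameters.
.em_init <- function(X, m, seed, ridge) {
  n <- nrow(X); d <- ncol(X)
  set.seed(seed)
  centers <- .kmeanspp_centers(X, m)
  assign <- max.col(-(rowSums(X^2) %o% rep(1, m) - 2 * X %*% t(centers) +
                        rep(1, n) %o% rowSums(centers^2)),
                    ties.method = "first")
  gcov <- crossprod(scale(X, scale = FALSE)) / n + diag(ridge, d)
  atoms <- lapply(seq_len(m), function(k) {
    idx <- which(assign == k)
    mu <- if (length(idx) > 0) colMeans(X[idx, , drop = FALSE])
          else centers[k, ]
    cv <- if (length(idx) > d) {
      crossprod(scale(X[idx, , drop = FALSE], scale = FALSE)) /
        length(idx) + diag(ridge, d)
    } else gcov
    list(mean = mu, covariance = cv, weight = max(length(idx), 1) / n)
  })
  w <- vapply(atoms, `[[`, 1, "weight")
  list(atoms = atoms, w = w / sum(w))
}

# The EM loop proper, from given parameters to convergence or the cap.
.em_run <- function(X, atoms, w, ridge, tol, max_iter) {
  n <- nrow(X); d <- ncol(X); m <- length(atoms)
  gcov <- crossprod(scale(X, scale = FALSE)) / n + diag(ridge, d)
  reseeded <- FALSE
  ll_old <- -Inf
  ll <- -Inf
  iter <- 0L
  repeat {
    iter <- iter + 1L
    ld <- .atom_logdens(X, atoms)
    lw <- ld + rep(log(w), each = n)
    mx <- apply(lw, 1, max)
    lse <- mx + log(rowSums(exp(lw - mx)))
    ll <- sum(lse)
    resp <- exp(lw - lse)
    nk <- colSums(resp)
    if (any(nk / n < 1e-8)) {
      if (reseeded) stop_structural("EM component collapsed twice")
      reseeded <- TRUE
      for (k in which(nk / n < 1e-8)) {
        atoms[[k]] <- list(mean = X[sample.int(n, 1), ], covariance = gcov,
                           weight = 1 / m)
      }
      w <- vapply(atoms, `[[`, 1, "weight"); w <- w / sum(w)
      ll_old <- -Inf
      next
    }
    w <- nk / n
    for (k in seq_len(m)) {
      rk <- resp[, k]
      mu <- colSums(X * rk) / nk[k]
      Xc <- sweep(X, 2, mu)
      cv <- crossprod(Xc * sqrt(rk)) / nk[k] + diag(ridge, d)
      atoms[[k]] <- list(mean = mu, covariance = cv, weight = w[k])
    }
    if (ll - ll_old < tol * n || iter >= max_iter) break
    ll_old <- ll
  }
  list(atoms = atoms, w = w, loglik = ll, iterations = iter)
}

#' Atom occupancy and voxel assignment on a test set
#'
#' Computes the posterior responsibility of every texture atom for each
#' voxel of a (typically held-out) compact feature matrix. The occupancy of
#' atom i is its mean responsibility over the test voxels — the occurrence
#' probability of that texture pattern in the test data — and each voxel is
#' hard-assigned to its maximum-responsibility atom.
#'
#' @param model a `sparse_texture_model`.
#' @param X compact feature matrix `[n x u]`.
#' @return list with `occupancy` (length m, sums to 1), `assignments`
#'   (length n) and `responsibilities` (`[n x m]`).
#' @export
texture_occupancy <- function(model, X) {
  X <- as.matrix(X)
  w <- vapply(model$atoms, `[[`, 1, "weight")
  ld <- .atom_logdens(X, model$atoms)
  lw <- ld + rep(log(w), each = nrow(X))
  mx <- apply(lw, 1, max)
  resp <- exp(lw - (mx + log(rowSums(exp(lw - mx)))))
  occ <- colMeans(resp)
  list(occupancy = occ / sum(occ),
       assignments = max.col(resp, ties.method = "first"),
       responsibilities = resp)
}

#' Statistical textural distinctiveness of two texture atoms
#'
#' Kullback-Leibler-type divergence between two Gaussian texture atoms:
#' `beta = log(|S_j|/|S_i|) - u + trace(S_j^-1 S_i)
#'         + (mu_j - mu_i)' S_j^-1 (mu_j - mu_i) / 2`,
#' where only the Mahalanobis term is halved. It is 0 for identical atoms
#' and grows as the texture patterns become more distinct.
#'
#' @param atom_i,atom_j lists with `mean` and `covariance` (positive
#'   definite).
#' @param u dimensionality; defaults to `length(atom_i$mean)`.
#' @return scalar distinctiveness.
#' @export
kl_distinctiveness <- function(atom_i, atom_j, u = length(atom_i$mean)) {
  chi <- tryCatch(chol(atom_i$covariance), error = function(e) NULL)
  chj <- tryCatch(chol(atom_j$covariance), error = function(e) NULL)
  if (is.null(chi) || is.null(chj)) {
    ridge <- diag(1e-8, length(atom_i$mean))
    chi <- chol(atom_i$covariance + ridge)
    chj <- chol(atom_j$covariance + ridge)
  }
  logdet_i <- 2 * sum(log(diag(chi)))
  logdet_j <- 2 * sum(log(diag(chj)))
  sj_inv <- chol2inv(chj)
  dmu <- atom_j$mean - atom_i$mean
  (logdet_j - logdet_i) - u + sum(sj_inv * atom_i$covariance) +
    as.numeric(t(dmu) %*% sj_inv %*% dmu) / 2
}

#' Pairwise distinctiveness matrix of a sparse texture model
#'
#' @param model a `sparse_texture_model`.
#' @return `m x m` matrix with zero diagonal.
#' @export
distinctiveness_matrix <- function(model) {
  m <- model$m
  beta <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i == j) next
      beta[i, j] <- kl_distinctiveness(model$atoms[[i]], model$atoms[[j]])
    }
  }
  beta
}

#' Atom saliency from distinctiveness and occupancy
#'
#' Combines the pairwise distinctiveness matrix with the atom occurrence
#' probabilities on the test data: under the default (printed) form the
#' probability factor is indexed by the atom being scored,
#' `alpha_i = sum_j beta_ij * P_i` — equivalently `P_i * sum_j beta_ij`.
#' `prob_index = "j"` evaluates the variant `alpha_i = sum_j beta_ij * P_j`
#' instead, in which rare-but-distinct atoms are scored by the abundance of
#' the atoms they differ from.
#'
#' @param beta `m x m` distinctiveness matrix (or a `sparse_texture_model`,
#'   from which it is computed).
#' @param occupancy probability vector over atoms (sums to 1).
#' @param prob_index `"i"` (default, as printed) or `"j"`.
#' @return numeric saliency vector `alpha` of length m.
#' @export
compute_saliency <- function(beta, occupancy, prob_index = c("i", "j")) {
  prob_index <- match.arg(prob_index)
  if (inherits(beta, "sparse_texture_model"))
    beta <- distinctiveness_matrix(beta)
  if (abs(sum(occupancy) - 1) > 1e-6 || any(occupancy < 0))
    stop_structural("occupancy must be a probability vector over atoms")
  if (prob_index == "i") as.numeric(rowSums(beta) * occupancy)
  else as.numeric(beta %*% occupancy)
}

#' Label salient voxels
#'
#' A voxel is salient (suspicious) iff the saliency of its assigned atom
#' strictly exceeds half the maximum atom saliency; all other voxels are
#' healthy.
#'
#' @param assignments integer vector of per-voxel atom assignments.
#' @param alpha atom saliency vector.
#' @return logical vector, `TRUE` for salient voxels.
#' @export
label_salient_voxels <- function(assignments, alpha) {
  salient_atom <- alpha > max(alpha) / 2
  salient_atom[assignments]
}

# Two-pass 8-connected component labelling of a binary matrix (union-find).
.label_components8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  nextlab <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      if (!mask[r, cc]) next
      nb <- integer(0)
      if (r > 1) {
        if (cc > 1 && labels[r - 1, cc - 1] > 0) nb <- c(nb, labels[r - 1, cc - 1])
        if (labels[r - 1, cc] > 0) nb <- c(nb, labels[r - 1, cc])
        if (cc < nc && labels[r - 1, cc + 1] > 0) nb <- c(nb, labels[r - 1, cc + 1])
      }
      if (cc > 1 && labels[r, cc - 1] > 0) nb <- c(nb, labels[r, cc - 1])
      if (length(nb) == 0) {
        nextlab <- nextlab + 1L
        parent[nextlab] <- nextlab
        labels[r, cc] <- nextlab
      } else {
        roots <- unique(vapply(nb, find, 1L))
        labels[r, cc] <- min(roots)
        for (x in roots) parent[x] <- min(roots)
      }
    }
  }
  if (nextlab == 0L) return(labels)
  root <- vapply(seq_len(nextlab), find, 1L)
  relab <- match(root, sort(unique(root)))
  labels[labels > 0] <- relab[labels[labels > 0]]
  labels
}

# Moore-neighbour boundary tracing; returns ordered (row, col) matrix.
.trace_boundary <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 1) return(idx)
  # clockwise neighbour ring starting west
  offs <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                 ncol = 2, byrow = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  inmask <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc &&
    mask[p[1], p[2]]
  # start: first foreground pixel in reading order (row-major)
  ord <- order(idx[, 1], idx[, 2])
  start <- idx[ord[1], ]
  boundary <- matrix(start, 1, 2)
  prev_dir <- 1L # backtrack is west of start
  cur <- start
  maxit <- 4L * (nrow(idx) + 4L)
  for (it in seq_len(maxit)) {
    found <- FALSE
    for (s in 0:7) {
      d <- ((prev_dir - 1L + s) %% 8L) + 1L
      cand <- cur + offs[d, ]
      if (inmask(cand)) {
        cur <- cand
        # next search starts from the neighbour before the found one,
        # rotated back two steps (standard Moore backtracking)
        prev_dir <- ((d - 1L - 2L) %% 8L) + 1L
        found <- TRUE
        break
      }
    }
    if (!found) break # isolated pixel
    if (all(cur == start)) break
    boundary <- rbind(boundary, cur)
  }
  colnames(boundary) <- c("row", "col")
  boundary
}

#' Extract candidate regions from a salient-voxel mask
#'
#' Decomposes the binary mask into per-slice 8-connected components,
#' drops those below a minimum area, and records each survivor's mask,
#' boundary polygon, centroid and slice. These are the tumour candidate
#' regions handed to the region-resolution feature model.
#'
#' @param mask 3-D logical array (or 2-D matrix, treated as one slice).
#' @param min_area_vox minimum component area in voxels.
#' @param patient_id identifier stored on each region.
#' @return list of `candidate_region` objects: `mask` (2-D logical),
#'   `slice_index`, `area`, `centroid` (row, col), `boundary` (ordered
#'   (row, col) matrix), `region_id`, `patient_id`.
#' @export
extract_candidate_regions <- function(mask, min_area_vox = 10,
                                      patient_id = "") {
  if (is.matrix(mask)) mask <- array(mask, c(dim(mask), 1))
  regions <- list()
  rid <- 0L
  for (k in seq_len(dim(mask)[3])) {
    sl <- mask[, , k]
    if (!any(sl)) next
    labs <- .label_components8(sl)
    for (l in seq_len(max(labs))) {
      comp <- labs == l
      area <- sum(comp)
      if (area < min_area_vox) next
      rid <- rid + 1L
      ij <- which(comp, arr.ind = TRUE)
      regions[[rid]] <- structure(
        list(mask = comp, slice_index = k, area = area,
             centroid = colMeans(ij), boundary = .trace_boundary(comp),
             region_id = rid, patient_id = patient_id),
        class = "candidate_region")
    }
  }
  regions
}
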