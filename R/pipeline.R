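#' Pipeline configuration
#'
#' One nested list holding every tunable constant of the three-stage
#' pipeline with its default. Blocks: `voxel_features` (texture bank),
#' `rd_std` (compaction, texture atoms, candidate extraction), `rd_fm`
#' (region model, selection criterion, SVM), `relative_adc`, `crf`.
#'
#' @param ... named overrides replacing entire blocks or scalars (see
#'   defaults in the function body).
#' @return a `mpcad_config` list.
#' @export
mpcad_config <- function(...) {
  cfg <- list(
    voxel_features = voxel_feature_config(),
    rd_std = list(variance_fraction = 0.90, m = 8, min_area_vox = 10,
                  max_train_voxels = 15000, saliency_prob_index = "j",
                  candidates_from = "all_atoms"),
    relative_adc = list(se_radius_vox = 3),
    rd_fm = list(criterion = "specificity", overlap_frac = 0.5,
                 cost = 1, gamma = NULL, levels = 32,
                 augment_truth_regions = TRUE),
    crf = list(w = 1, sigma = NULL, p_bg = 0.01, step = 0.25,
               max_iter = 200, tol = 1e-5),
    seed = 1L)
  dots <- list(...)
  for (nm in names(dots)) {
    if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "mpcad_config")
}

# Voxel-feature working mask: the gland interior, eroded in-plane by the
# texture-window half-width so no window straddles the gland capsule.
# Boundary windows mix gland and outside tissue and produce extreme
# partial-volume texture atoms that crowd out real in-gland patterns.
.interior_mask <- function(case, config) {
  r <- config$voxel_features$window %/% 2
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  out <- case$gland_mask
  for (k in seq_len(dim(out)[3])) {
    sl <- out[, , k]
    if (!any(sl)) next
    out[, , k] <- EBImage::erode(sl * 1, brush) > 0
  }
  out
}

.case_bank <- function(case, config) {
  build_voxel_feature_bank(case, .interior_mask(case, config),
                           config$voxel_features)
}

# Stage-1 voxel labelling for one case given a fitted compact space and
# sparse texture model; returns the salient-voxel mask and candidates.
.apply_rd_std <- function(case, bank, compact, model, config) {
  scores <- project_compact(compact, bank$values)
  occ <- texture_occupancy(model, scores)
  beta <- distinctiveness_matrix(model)
  alpha <- compute_saliency(beta, occ$occupancy,
                            prob_index = config$rd_std$saliency_prob_index)
  salient <- label_salient_voxels(occ$assignments, alpha)
  vm <- array(FALSE, dim(case$gland_mask))
  vi <- bank$voxel_index
  vm[cbind(vi$row, vi$col, vi$slice)] <- salient
  # candidates are extracted per texture set: voxels sharing one atom form
  # a candidate, so texturally different neighbours are never merged into
  # one blob. By default every atom proposes candidates (sensitivity-first;
  # the region model does the discrimination); "salient_atoms" restricts
  # candidacy to atoms passing the half-max saliency rule.
  atom_set <- if (identical(config$rd_std$candidates_from, "salient_atoms"))
    which(alpha > max(alpha) / 2) else seq_along(alpha)
  regions <- list()
  for (a in atom_set) {
    va <- array(FALSE, dim(case$gland_mask))
    sel <- occ$assignments == a
    va[cbind(vi$row, vi$col, vi$slice)[sel, , drop = FALSE]] <- TRUE
    regions <- c(regions,
                 extract_candidate_regions(va, config$rd_std$min_area_vox,
                                           case$patient_id))
  }
  for (i in seq_along(regions)) regions[[i]]$region_id <- i
  list(voxel_mask = vm, regions = regions, alpha = alpha,
       assignments = occ$assignments)
}

# Candidate-driven relative ADC: replace the case's rADC channel using the
# detected candidate regions as ROIs (falling back to the stored channel
# when there are no candidates).
.candidate_radc <- function(case, regions, config) {
  if (length(regions) == 0) return(case)
  masks <- lapply(regions, function(r)
    list(mask = r$mask, slice_index = r$slice_index))
  radc <- tryCatch(
    compute_relative_adc(case$channels$ADC, masks,
                         config$relative_adc$se_radius_vox),
    error = function(e) NULL)
  if (!is.null(radc)) case$channels$rADC <- as.array(radc)
  case
}

.region_feature_matrix <- function(regions, case, config) {
  if (length(regions) == 0) return(NULL)
  rows <- lapply(regions, assemble_region_vector, case = case,
                 levels = config$rd_fm$levels)
  do.call(rbind, rows)
}

#' Train the pipeline models on a set of patients
#'
#' Fits everything the pipeline learns from data, using only the supplied
#' (training) cases: the PCA compaction and the sparse texture model on a
#' subsample of the pooled gland-voxel feature banks, then stage-1
#' candidates on each training case, their 242-entry region vectors and
#' overlap-based truth labels, and finally the two-stage feature-selection
#' plan. Region labels, scores and the classifier all stay inside the
#' training cohort, so a held-out patient never leaks into model fitting.
#'
#' @param cases list of `patient_case`s (the training patients).
#' @param config a [mpcad_config].
#' @param banks optional precomputed voxel banks (one per case, as from
#'   [build_voxel_feature_bank]) to avoid recomputation across folds.
#' @return a `mpcad_models` list: `compact`, `texture_model`, `plan`,
#'   `train_X`, `train_y`, `config`.
#' @export
train_mpcad <- function(cases, config = mpcad_config(), banks = NULL) {
  if (is.null(banks))
    banks <- lapply(cases, .case_bank, config = config)
  X <- do.call(rbind, lapply(banks, `[[`, "values"))
  set.seed(config$seed)
  if (nrow(X) > config$rd_std$max_train_voxels)
    X <- X[sample.int(nrow(X), config$rd_std$max_train_voxels), ]
  compact <- pca_compact(X, config$rd_std$variance_fraction)
  model <- learn_sparse_texture_model(compact, m = config$rd_std$m,
                                      seed = config$seed)
  reg_X <- NULL; reg_y <- logical(0)
  for (i in seq_along(cases)) {
    st1 <- .apply_rd_std(cases[[i]], banks[[i]], compact, model, config)
    regions <- st1$regions
    labels <- vapply(regions, region_truth_label, TRUE,
                     truth_mask = cases[[i]]$truth_mask,
                     frac = config$rd_fm$overlap_frac)
    # the truth components of a *training* patient are known and serve as
    # canonical positive exemplars, so every fold has both classes even
    # when the candidate stage only grazes that patient's lesions
    if (isTRUE(config$rd_fm$augment_truth_regions) &&
        any(cases[[i]]$truth_mask)) {
      tru <- extract_candidate_regions(cases[[i]]$truth_mask,
                                       config$rd_std$min_area_vox,
                                       cases[[i]]$patient_id)
      regions <- c(regions, tru)
      labels <- c(labels, rep(TRUE, length(tru)))
    }
    if (length(regions) == 0) next
    case_r <- .candidate_radc(cases[[i]], st1$regions, config)
    Xi <- .region_feature_matrix(regions, case_r, config)
    rownames(Xi) <- rep(cases[[i]]$patient_id, nrow(Xi))
    reg_X <- rbind(reg_X, Xi)
    reg_y <- c(reg_y, labels)
  }
  if (is.null(reg_X) || length(unique(reg_y)) < 2) {
    # degenerate fold: no two-class region set; the region classifier is
    # disabled and candidates pass through stage 2 unfiltered
    warning("training cohort yields no two-class region set; ",
            "region classifier disabled for this model")
    plan <- NULL
  } else {
    plan <- two_stage_selection(reg_X, reg_y,
                                criterion = config$rd_fm$criterion,
                                cost = config$rd_fm$cost,
                                gamma = config$rd_fm$gamma)
  }
  structure(list(compact = compact, texture_model = model, plan = plan,
                 train_X = reg_X, train_y = reg_y, config = config),
            class = "mpcad_models")
}

# CRF refinement of the RD-FM result for one case.
.apply_crf <- function(case, regions, labels, scores, config) {
  dims <- dim(case$gland_mask)
  refined <- array(FALSE, dims)
  slices <- sort(unique(vapply(regions, `[[`, 1L, "slice_index")))
  for (k in slices) {
    on_k <- vapply(regions, function(r) r$slice_index == k, TRUE)
    wmask <- case$gland_mask[, , k]
    for (r in regions[on_k]) wmask <- wmask | r$mask
    if (sum(wmask) < 2) next
    mask3 <- array(FALSE, dims); mask3[, , k] <- wmask
    feats <- voxel_features_on_radc(case, mask3,
                                    config$voxel_features)
    un <- build_unary(regions[on_k], labels[on_k], scores[on_k],
                      dims[1:2], p_bg = config$crf$p_bg)
    prob <- make_crf_problem(un$unary, feats$features, wmask,
                             w = config$crf$w, sigma = config$crf$sigma)
    res <- refine_labels(prob, step = config$crf$step,
                         max_iter = config$crf$max_iter,
                         tol = config$crf$tol)
    sl <- matrix(FALSE, dims[1], dims[2])
    sl[which(wmask)] <- res$labels
    refined[, , k] <- sl
  }
  refined
}

#' Run the three-stage pipeline on one patient
#'
#' Applies, in order: (1) voxel-resolution textural-distinctiveness
#' candidate detection, (2) region-resolution feature-model classification
#' of the candidates (on the candidate-driven relative-ADC channel), and
#' (3) relative-ADC-driven CRF refinement of the positive regions at voxel
#' resolution. Each stage consumes the previous stage's output. Models
#' must have been trained on other patients.
#'
#' @param case a `patient_case`.
#' @param models a `mpcad_models` from [train_mpcad].
#' @param config a [mpcad_config] (defaults to the one stored in
#'   `models`).
#' @return list of three `detection_result`s (stages `rd_std`, `rd_fm`,
#'   `radc_crf`), each with `stage`, `regions`, `labels`, `scores`,
#'   `voxel_mask`, `patient_id`.
#' @export
run_mpcad <- function(case, models, config = models$config) {
  bank <- .case_bank(case, config)
  st1 <- .apply_rd_std(case, bank, models$compact, models$texture_model,
                       config)
  res1 <- structure(list(stage = "rd_std", regions = st1$regions,
                         labels = rep(TRUE, length(st1$regions)),
                         scores = rep(NA_real_, length(st1$regions)),
                         voxel_mask = st1$voxel_mask,
                         patient_id = case$patient_id),
                    class = "detection_result")
  dims <- dim(case$gland_mask)
  if (length(st1$regions) == 0) {
    empty <- structure(list(stage = "rd_fm", regions = list(),
                            labels = logical(0), scores = numeric(0),
                            voxel_mask = array(FALSE, dims),
                            patient_id = case$patient_id),
                       class = "detection_result")
    crf_empty <- empty; crf_empty$stage <- "radc_crf"
    return(list(rd_std = res1, rd_fm = empty, radc_crf = crf_empty))
  }
  case_r <- .candidate_radc(case, st1$regions, config)
  Xt <- .region_feature_matrix(st1$regions, case_r, config)
  if (is.null(models$plan)) {
    cl <- list(label = rep(TRUE, length(st1$regions)),
               score = rep(0, length(st1$regions)))
  } else {
    cl <- classify_regions(models$train_X, models$train_y, Xt, models$plan,
                           cost = config$rd_fm$cost,
                           gamma = config$rd_fm$gamma)
  }
  vm2 <- array(FALSE, dims)
  for (i in which(cl$label))
    vm2[, , st1$regions[[i]]$slice_index] <-
      vm2[, , st1$regions[[i]]$slice_index] | st1$regions[[i]]$mask
  res2 <- structure(list(stage = "rd_fm", regions = st1$regions,
                         labels = cl$label, scores = cl$score,
                         voxel_mask = vm2, patient_id = case$patient_id),
                    class = "detection_result")
  refined <- .apply_crf(case_r, st1$regions, cl$label, cl$score, config)
  # refinement may shrink regions but never adds voxels beyond RD-FM output
  vm3 <- refined & vm2
  labels3 <- cl$label
  regions3 <- st1$regions
  for (i in seq_along(regions3)) {
    if (!labels3[i]) next
    newmask <- regions3[[i]]$mask & vm3[, , regions3[[i]]$slice_index]
    regions3[[i]]$mask <- newmask
    regions3[[i]]$area <- sum(newmask)
    if (regions3[[i]]$area == 0) labels3[i] <- FALSE
  }
  res3 <- structure(list(stage = "radc_crf", regions = regions3,
                         labels = labels3, scores = cl$score,
                         voxel_mask = vm3, patient_id = case$patient_id),
                    class = "detection_result")
  list(rd_std = res1, rd_fm = res2, radc_crf = res3)
}

# Wilson 95% confidence interval for a binomial proportion, clipped.
.wilson_ci <- function(x, n, z = 1.96) {
  if (n == 0) return(c(NA_real_, NA_real_))
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Region-level evaluation of a detection result
#'
#' Scores candidate regions against the voxel truth mask: a
#' positive-labelled region is a true positive iff at least `overlap_frac`
#' of its area overlaps the truth, otherwise a false positive;
#' negative-labelled regions are scored analogously (false negative when
#' they overlap truth). Truth components never touched by any candidate
#' region count as additional false negatives, so lesions missed by the
#' candidate stage are not silently ignored. Confidence intervals are
#' Wilson 95% intervals.
#'
#' @param result a `detection_result` (or a list with `regions`, `labels`).
#' @param truth_mask 3-D logical truth array.
#' @param overlap_frac region/truth overlap threshold in (0, 1].
#' @return an `eval_report`: counts (TP/FP/TN/FN), sensitivity,
#'   specificity, accuracy, each with a 95% CI.
#' @export
evaluate_regions <- function(result, truth_mask, overlap_frac = 0.5) {
  if (overlap_frac <= 0 || overlap_frac > 1)
    stop_config("overlap_frac must be in (0, 1]")
  regions <- result$regions
  labels <- result$labels
  tp <- fp <- tn <- fn <- 0L
  hit <- array(FALSE, dim(truth_mask))
  for (i in seq_along(regions)) {
    r <- regions[[i]]
    if (r$area == 0) next
    ov <- sum(truth_mask[, , r$slice_index] & r$mask) / r$area
    is_cancer <- ov >= overlap_frac
    if (labels[i]) {
      if (is_cancer) tp <- tp + 1L else fp <- fp + 1L
      if (is_cancer) hit[, , r$slice_index] <-
          hit[, , r$slice_index] | r$mask
    } else {
      if (is_cancer) fn <- fn + 1L else tn <- tn + 1L
    }
  }
  # truth components missed by every positive region are missed lesions
  truth_regions <- extract_candidate_regions(truth_mask, min_area_vox = 1)
  pos <- regions[labels]
  for (tr in truth_regions) {
    touched <- length(pos) > 0 && any(vapply(pos, function(r)
      r$slice_index == tr$slice_index && sum(r$mask & tr$mask) > 0, TRUE))
    if (!touched) fn <- fn + 1L
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else 1
  total <- tp + fp + tn + fn
  acc <- if (total > 0) (tp + tn) / total else NA_real_
  structure(list(counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 sensitivity = sens, sensitivity_ci = .wilson_ci(tp, tp + fn),
                 specificity = spec, specificity_ci = .wilson_ci(tn, tn + fp),
                 accuracy = acc, accuracy_ci = .wilson_ci(tp + tn, total)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> TP %d FP %d TN %d FN %d | sens %.3f spec %.3f acc %.3f\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"],
              x$sensitivity, x$specificity, x$accuracy))
  invisible(x)
}

#' Patient-level decision
#'
#' A patient is called cancerous iff the final stage reports at least
#' `k_regions` positive regions.
#'
#' @param result a `detection_result` (typically the `radc_crf` stage).
#' @param k_regions positive-region threshold (>= 1).
#' @return logical.
#' @export
patient_level_decision <- function(result, k_regions = 1) {
  if (k_regions < 1) stop_config("k_regions must be >= 1")
  sum(result$labels) >= k_regions
}

#' Leave-one-patient-out detection over a cohort
#'
#' For each patient, trains all models on the remaining patients
#' ([train_mpcad]) and runs the full pipeline on the held-out case. Voxel
#' feature banks are computed once per patient and reused across folds
#' (they are a pure per-patient function, so no information crosses
#' folds).
#'
#' @param cases list of `patient_case`s.
#' @param config a [mpcad_config].
#' @param verbose print per-fold progress.
#' @return list (one per patient) of the three stage results from
#'   [run_mpcad].
#' @export
lopo_detect <- function(cases, config = mpcad_config(), verbose = FALSE) {
  banks <- lapply(cases, .case_bank, config = config)
  out <- vector("list", length(cases))
  names(out) <- vapply(cases, `[[`, "", "patient_id")
  for (i in seq_along(cases)) {
    if (verbose) message("fold ", i, "/", length(cases))
    models <- train_mpcad(cases[-i], config, banks = banks[-i])
    out[[i]] <- run_mpcad(cases[[i]], models, config)
  }
  out
}

#' Pooled cohort evaluation
#'
#' Region-level metrics pooled over all patients for each stage, plus the
#' patient-level confusion at threshold `k_regions`.
#'
#' @param detections output of [lopo_detect].
#' @param cases the matching list of `patient_case`s.
#' @param overlap_frac region/truth overlap threshold.
#' @param k_regions patient-level positive-region threshold.
#' @return list with per-stage pooled counts and metrics, and
#'   `patient_level` (sensitivity, specificity, accuracy, decisions).
#' @export
evaluate_cohort <- function(detections, cases, overlap_frac = 0.5,
                            k_regions = 1) {
  stages <- c("rd_std", "rd_fm", "radc_crf")
  pooled <- lapply(stages, function(st) {
    cts <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
    for (i in seq_along(cases)) {
      ev <- evaluate_regions(detections[[i]][[st]], cases[[i]]$truth_mask,
                             overlap_frac)
      cts <- cts + ev$counts
    }
    tp <- cts["TP"]; fp <- cts["FP"]; tn <- cts["TN"]; fn <- cts["FN"]
    list(counts = cts,
         sensitivity = if (tp + fn > 0) unname(tp / (tp + fn)) else NA_real_,
         specificity = if (tn + fp > 0) unname(tn / (tn + fp)) else NA_real_,
         accuracy = unname((tp + tn) / max(1, sum(cts))))
  })
  names(pooled) <- stages
  truth_pat <- vapply(cases, function(cs) any(cs$truth_mask), TRUE)
  call_pat <- vapply(seq_along(cases), function(i)
    patient_level_decision(detections[[i]]$radc_crf, k_regions), TRUE)
  tp <- sum(call_pat & truth_pat); fp <- sum(call_pat & !truth_pat)
  tn <- sum(!call_pat & !truth_pat); fn <- sum(!call_pat & truth_pat)
  pooled$patient_level <- list(
    threshold = k_regions, decisions = call_pat, truth = truth_pat,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(cases))
  pooled
}
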