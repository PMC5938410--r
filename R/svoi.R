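#' Significant-cluster volume of interest (SVOI)
#'
#' The significant clusters of one lesion type are merged into a single
#' region; each subject's SVOI is the volume (ml) of their FULL lesion
#' mask falling inside that region. Pass the unfiltered tensor: clinical
#' lesion overlap is anatomical and is not subject to the
#' minimum-prevalence voxel filter.
#'
#' @param cluster_set a [threshold_and_cluster()] result.
#' @param tensor an (unfiltered) [lesion_tensor()].
#' @param lesion_type which cluster block to use; defaults to the
#'   tensor's own lesion type.
#' @return Numeric per-subject overlap volume in ml, named by subject.
#' @export
compute_svoi <- function(cluster_set, tensor, lesion_type = NULL) {
  lesion_type <- lesion_type %||% tensor$lesion_type
  region <- cluster_union(cluster_set, lesion_type)
  if (!length(region)) {
    warn_mlsmap("empty significant-cluster set for %s; SVOI is all zero",
                lesion_type)
    return(setNames(numeric(n_subjects(tensor)), tensor$subject_ids))
  }
  cols <- which(tensor$voxel_index %in% region)
  counts <- if (length(cols))
    rowSums(tensor$data[, cols, drop = FALSE]) else
      numeric(n_subjects(tensor))
  setNames(counts * voxel_volume_ml(tensor$grid), tensor$subject_ids)
}

#' SVOI from an explicit voxel region
#'
#' Overlap volume between each subject's mask and a fixed set of voxels
#' (e.g. a planted ground-truth region in simulations).
#'
#' @param region flat voxel indices.
#' @param tensor an (unfiltered) [lesion_tensor()].
#' @return Numeric per-subject overlap volume in ml.
#' @export
region_svoi <- function(region, tensor) {
  cols <- which(tensor$voxel_index %in% region)
  counts <- if (length(cols))
    rowSums(tensor$data[, cols, drop = FALSE]) else
      numeric(n_subjects(tensor))
  setNames(counts * voxel_volume_ml(tensor$grid), tensor$subject_ids)
}

# LOOCV linear-SVR accuracy of a small predictor set against a raw score.
# Predictors are z-scored INSIDE each training fold and the held-out row
# is transformed with the training fold's center/scale, so no information
# from the held-out subject reaches training. Per fold, the C grid is
# swept in ascending order with warm starts; a capped iteration budget
# keeps the huge-C tail (a heavy-overfit regime that LOOCV never selects)
# from dominating the runtime — those solves are approximate but
# deterministic.
ladder_loocv <- function(Z, y, C_grid, epsilon = 0.1, max_iter = 5000L) {
  M <- length(y)
  C_grid <- sort(C_grid)
  preds <- matrix(NA_real_, M, length(C_grid))
  for (m in seq_len(M)) {
    Ztr <- Z[-m, , drop = FALSE]
    ctr <- colMeans(Ztr)
    scl <- apply(Ztr, 2L, sd)
    scl[!is.finite(scl) | scl == 0] <- 1
    Zs <- sweep(sweep(Ztr, 2L, ctr), 2L, scl, "/")
    zte <- (Z[m, ] - ctr) / scl
    ytr <- y[-m]
    yc <- mean(ytr); ys <- sd(ytr); if (!is.finite(ys) || ys == 0) ys <- 1
    K <- tcrossprod(Zs)
    yss <- (ytr - yc) / ys
    kx <- as.numeric(Zs %*% zte)
    warm <- NULL
    for (g in seq_along(C_grid)) {
      fit <- svr_smo(K, yss, C_grid[g], epsilon, 1e-6, max_iter, warm)
      warm <- fit$beta
      preds[m, g] <- (sum(kx * fit$beta) + fit$b) * ys + yc
    }
  }
  acc <- t(apply(preds, 2L, accuracy_stats, real = y))
  finite <- which(is.finite(acc[, 1]))
  if (!length(finite)) stop_mlsmap("no ladder C yielded a defined accuracy")
  best_idx <- finite[which.max(acc[finite, 1])]   # first max: smallest C
  list(accuracy = unname(acc[best_idx, 1]), p = unname(acc[best_idx, 2]),
       C = C_grid[best_idx], pred = preds[, best_idx])
}

#' Default nested predictor ladder
#'
#' The canonical comparison ladder: demographics only; plus total AIL
#' volume; plus total WMH volume; then each SVOI extension of interest.
#'
#' @param svoi_names names of available SVOI predictors.
#' @return Named list of predictor-name vectors.
#' @export
default_ladder_models <- function(svoi_names = character()) {
  m1 <- c("age", "sex", "education")
  m2 <- c(m1, "ail_volume_ml")
  m3 <- c(m2, "wmh_volume_ml")
  models <- list(model1_demographics = m1,
                 model2_plus_ail_volume = m2,
                 model3_plus_wmh_volume = m3)
  for (nm in svoi_names)
    models[[paste0("model3_plus_", nm)]] <- c(m3, nm)
  if (length(svoi_names) > 1L)
    models[[paste0("model3_plus_", paste(svoi_names, collapse = "_"))]] <-
      c(m3, svoi_names)
  models
}

#' Run the SVOI behavior-prediction ladder
#'
#' Each model is a linear epsilon-SVR from a named predictor set
#' (demographics, lesion volumes, SVOIs) to the RAW behavior score,
#' trained with LOOCV over the C grid; accuracy is the Pearson
#' correlation between held-out predictions and the raw score. Deltas are
#' reported against a stated baseline model. Note the usual caveat: when
#' SVOIs are derived from clusters estimated on the same cohort, the
#' ladder is an internal comparison, not external validation (a message
#' is emitted).
#'
#' @param table cohort data frame (must contain every non-SVOI predictor).
#' @param svois named list of per-subject SVOI vectors.
#' @param score_column raw score column name.
#' @param models named list of predictor-name vectors; default
#'   [default_ladder_models()].
#' @param baseline name of the model deltas are measured against.
#' @param C_grid linear C grid (default 2^-20..2^20).
#' @param epsilon tube half width.
#' @param internal_svoi emit the same-cohort caveat message.
#' @return An object of class `prediction_ladder`: data frame `results`
#'   with accuracy, p, C and delta per model, plus `predictions`.
#' @export
run_ladder <- function(table, svois = list(), score_column = "score",
                       models = NULL, baseline = "model2_plus_ail_volume",
                       C_grid = NULL, epsilon = 0.1,
                       internal_svoi = TRUE) {
  if (!score_column %in% names(table))
    stop_mlsmap("score column '%s' not in the cohort table", score_column)
  y <- as.numeric(table[[score_column]])
  models <- models %||% default_ladder_models(names(svois))
  C_grid <- C_grid %||% default_c_grid("linear")
  if (length(svois) && internal_svoi)
    message("note: SVOIs evaluated on the cohort that produced the clusters; ",
            "accuracies are internal, not external validation")
  pool <- c(as.list(table), svois)
  results <- list(); predictions <- list()
  for (nm in names(models)) {
    preds_names <- models[[nm]]
    miss <- setdiff(preds_names, names(pool))
    if (length(miss))
      stop_mlsmap("model %s: missing predictor(s): %s", nm,
                  paste(miss, collapse = ", "))
    Z <- do.call(cbind, lapply(pool[preds_names], as.numeric))
    if (anyNA(Z)) stop_mlsmap("model %s: missing values in predictors", nm)
    res <- ladder_loocv(Z, y, C_grid, epsilon)
    results[[nm]] <- data.frame(model = nm,
                                predictors = paste(preds_names,
                                                   collapse = "+"),
                                accuracy = res$accuracy, p = res$p,
                                C = res$C)
    predictions[[nm]] <- res$pred
  }
  out <- do.call(rbind, results)
  rownames(out) <- NULL
  base_acc <- if (baseline %in% out$model)
    out$accuracy[out$model == baseline] else NA_real_
  out$delta_vs_baseline <- out$accuracy - base_acc
  structure(list(results = out, baseline = baseline,
                 predictions = predictions, score_column = score_column),
            class = "prediction_ladder")
}

#' @export
print.prediction_ladder <- function(x, ...) {
  cat(sprintf("<prediction_ladder> raw score '%s', baseline %s\n",
              x$score_column, x$baseline))
  print(x$results[, c("model", "accuracy", "p", "delta_vs_baseline")],
        row.names = FALSE)
  invisible(x)
}
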