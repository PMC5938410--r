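ols_residuals <- function(y, covariates, what = "covariate") {
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != length(y))
    stop_mlsmap("covariate rows (%d) do not match scores (%d)",
                nrow(covariates), length(y))
  X <- cbind(`(intercept)` = 1, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop_mlsmap("%s matrix is rank deficient; collinear column(s): %s",
                what, paste(bad, collapse = ", "))
  }
  as.numeric(qr.resid(qrX, y))
}

#' Norm-correct behavior scores for demographic covariates
#'
#' Within-sample covariate adjustment: ordinary-least-squares residuals of
#' the scores on an intercept plus the covariate matrix (typically age,
#' sex, education). The residuals are exactly orthogonal to every
#' covariate.
#'
#' @param scores numeric vector.
#' @param covariates numeric matrix or data frame, one row per subject.
#' @return Residual vector (same length and order as `scores`).
#' @export
norm_correct <- function(scores, covariates) {
  ols_residuals(as.numeric(scores), covariates, "covariate")
}

#' Regress lesion volumes out of norm-corrected scores
#'
#' The "regress-out" volume-control strategy: OLS residuals of the
#' norm-corrected score on an intercept plus one or two total lesion
#' volume columns.
#'
#' @param residual norm-corrected score vector.
#' @param volumes matrix/data frame with 1 or 2 volume columns.
#' @return Residual vector orthogonal to every volume column.
#' @export
regress_out_volumes <- function(residual, volumes) {
  volumes <- as.matrix(volumes)
  if (!ncol(volumes) %in% c(1L, 2L))
    stop_mlsmap("volumes must have 1 or 2 columns")
  ols_residuals(as.numeric(residual), volumes, "volume")
}

#' Transform a norm-corrected score to a deficit score
#'
#' SVR weight inference assumes larger response means worse performance.
#' When the raw score is declared "higher is better" (e.g. a cognitive
#' screening total) the norm-corrected residual is negated; otherwise it
#' is passed through unchanged.
#'
#' @param residual norm-corrected (optionally volume-regressed) vector.
#' @param score_direction `"higher_is_better"` (negate) or
#'   `"higher_is_worse"` (identity).
#' @return Deficit vector.
#' @export
to_deficit <- function(residual, score_direction = c("higher_is_better",
                                                     "higher_is_worse")) {
  score_direction <- match.arg(score_direction)
  if (score_direction == "higher_is_better") -residual else residual
}

#' Prepare behavior scores for lesion-symptom mapping
#'
#' Fixed composition: norm-correct for covariates, optionally regress out
#' total lesion volume(s) (volume-control strategy `"regress_out"`), then
#' transform to a deficit score. Downstream permutation inference shuffles
#' the final deficit vector only.
#'
#' @param table cohort data frame.
#' @param score_column name of the score column.
#' @param covariates names of covariate columns (default age, sex,
#'   education).
#' @param volume_control `"none"`, `"voxelwise"` or `"regress_out"`. Only
#'   `"regress_out"` touches the scores here; `"voxelwise"` is handled in
#'   the design matrix.
#' @param volume_columns volume columns used under `"regress_out"`.
#' @param score_direction see [to_deficit()].
#' @return An object of class `prepared_scores`: list with `subject_ids`,
#'   `raw`, `residual`, `deficit`, `covariates_used`, `volumes_regressed`.
#' @export
prepare_scores <- function(table, score_column = "score",
                           covariates = c("age", "sex", "education"),
                           volume_control = c("none", "voxelwise",
                                              "regress_out"),
                           volume_columns = NULL,
                           score_direction = "higher_is_better") {
  volume_control <- match.arg(volume_control)
  miss <- setdiff(c(score_column, covariates), names(table))
  if (length(miss))
    stop_mlsmap("cohort table lacks column(s): %s", paste(miss, collapse = ", "))
  raw <- as.numeric(table[[score_column]])
  if (anyNA(raw) || anyNA(table[covariates]))
    stop_mlsmap("missing values in score or covariate columns")
  residual <- norm_correct(raw, table[covariates])
  volumes_regressed <- character()
  if (volume_control == "regress_out") {
    if (is.null(volume_columns))
      volume_columns <- intersect(c("ail_volume_ml", "wmh_volume_ml"),
                                  names(table))
    if (!length(volume_columns))
      stop_mlsmap("regress_out volume control needs volume column(s)")
    residual <- regress_out_volumes(residual, table[volume_columns])
    volumes_regressed <- volume_columns
  }
  structure(list(subject_ids = as.character(table$id %||%
                                              seq_along(raw)),
                 raw = raw, residual = residual,
                 deficit = to_deficit(residual, score_direction),
                 covariates_used = covariates,
                 volumes_regressed = volumes_regressed,
                 volume_control = volume_control,
                 score_direction = score_direction),
            class = "prepared_scores")
}

#' @export
print.prepared_scores <- function(x, ...) {
  cat(sprintf(paste0("<prepared_scores> %d subjects; covariates: %s; ",
                     "volume control: %s\n"),
              length(x$raw), paste(x$covariates_used, collapse = ", "),
              x$volume_control))
  invisible(x)
}
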