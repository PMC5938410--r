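# Kernel matrices (the solver handles the intercept itself).
kernel_matrix <- function(X, kernel, gamma = NULL, X2 = NULL) {
  if (kernel == "linear") {
    if (is.null(X2)) tcrossprod(X) else tcrossprod(X2, X)
  } else if (kernel == "rbf") {
    if (is.null(gamma) || gamma <= 0) stop_mlsmap("rbf kernel needs gamma > 0")
    A <- if (is.null(X2)) X else X2
    d2 <- outer(rowSums(A^2), rowSums(X^2), "+") - 2 * tcrossprod(A, X)
    exp(-gamma * pmax(d2, 0))
  } else stop_mlsmap("unknown kernel '%s'", kernel)
}

#' Fit epsilon-insensitive support vector regression
#'
#' Solves the epsilon-SVR dual by sequential minimal optimization with an
#' equality-constrained (unregularized) intercept and second-order
#' working-set selection — the standard kernel-SVM algorithm. The response
#' is z-scored before training by default; dual coefficients live on that
#' standardized scale and predictions are mapped back. The problem is
#' convex, so refits on identical input are identical.
#'
#' @param design a `multilesion_design` or plain numeric matrix
#'   (subjects x features).
#' @param deficit numeric response (a deficit score: larger = worse).
#' @param kernel `"linear"` or `"rbf"`.
#' @param C box constraint (> 0).
#' @param gamma rbf kernel scale (ignored for linear).
#' @param epsilon insensitive-tube half width on the standardized response
#'   scale.
#' @param scale_y z-score the response before training.
#' @param tol,max_iter solver convergence controls (KKT violation
#'   tolerance; iteration cap).
#' @return An object of class `fitted_svr`: `dual_coef` (per-subject, on
#'   the standardized scale), `intercept`, `y_center`, `y_scale`,
#'   `kernel`, `C`, `gamma`, `epsilon`, `X` (training features),
#'   `support` (indices with nonzero dual coefficient).
#' @export
fit_svr <- function(design, deficit, kernel = c("linear", "rbf"),
                    C = 1, gamma = NULL, epsilon = 0.1, scale_y = TRUE,
                    tol = 1e-8, max_iter = 200000L) {
  kernel <- match.arg(kernel)
  if (C <= 0) stop_mlsmap("C must be positive")
  X <- if (inherits(design, "multilesion_design")) design$matrix else
    as.matrix(design)
  y <- as.numeric(deficit)
  if (nrow(X) != length(y)) stop_mlsmap("design rows do not match response")
  y_center <- 0; y_scale <- 1
  if (scale_y) {
    y_center <- mean(y)
    s <- sd(y)
    y_scale <- if (is.finite(s) && s > 0) s else 1
  }
  ys <- (y - y_center) / y_scale
  K <- kernel_matrix(X, kernel, gamma)
  fit <- svr_smo(K, ys, C, epsilon, tol, as.integer(max_iter))
  if (!fit$converged)
    stop_mlsmap("SVR solver did not converge within %d iterations", max_iter)
  structure(list(dual_coef = as.numeric(fit$beta), intercept = fit$b,
                 y_center = y_center, y_scale = y_scale,
                 kernel = kernel, C = C, gamma = gamma, epsilon = epsilon,
                 X = X, K = K,
                 support = which(fit$beta != 0),
                 iter = fit$iter),
            class = "fitted_svr")
}

#' @export
print.fitted_svr <- function(x, ...) {
  cat(sprintf("<fitted_svr> %s kernel, C=%g%s, %d/%d support vectors\n",
              x$kernel, x$C,
              if (x$kernel == "rbf") sprintf(", gamma=%g", x$gamma) else "",
              length(x$support), nrow(x$X)))
  invisible(x)
}

#' @param object a `fitted_svr`.
#' @param newdata matrix of new rows (default: training rows).
#' @param ... unused.
#' @rdname fit_svr
#' @export
predict.fitted_svr <- function(object, newdata = NULL, ...) {
  Kx <- if (is.null(newdata)) object$K else
    kernel_matrix(object$X, object$kernel, object$gamma,
                  X2 = as.matrix(newdata))
  raw <- as.numeric(Kx %*% object$dual_coef) + object$intercept
  raw * object$y_scale + object$y_center
}

default_c_grid <- function(kernel) {
  if (kernel == "linear") 2^seq(-20L, 20L) else 2^seq(-20L, 6L)
}

default_gamma_grid <- function() 1:16

# Pearson accuracy and its one-sided p (r > 0) via the t approximation.
# Held-out predictions whose spread is below the LOOCV fold-statistic
# noise floor (~ sd(y)/M) are effectively constant: their correlation
# with the response is an artifact of each training fold's summary
# statistics depending on the excluded label, and can reach |r| ~ 1 with
# zero real signal. Such settings get an undefined accuracy.
accuracy_stats <- function(pred, real) {
  if (sd(pred) < sd(real) / length(real))
    return(c(accuracy = NA_real_, p = NA_real_))
  r <- suppressWarnings(cor(pred, real))
  if (!is.finite(r)) return(c(accuracy = NA_real_, p = NA_real_))
  n <- length(real)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  c(accuracy = r, p = pt(tt, n - 2, lower.tail = FALSE))
}

#' Leave-one-out cross-validated hyperparameter training
#'
#' For every grid point, each subject is held out once, the SVR is fitted
#' on the remaining subjects (response standardized inside the training
#' fold), and the held-out subject is predicted. Prediction accuracy of a
#' grid point is the Pearson correlation between the M held-out
#' predictions and the true responses; the selected setting maximizes it,
#' with ties broken toward smaller C then smaller gamma. Default grids are
#' integer powers of two: C in 2^-20..2^20 (linear) or 2^-20..2^6 crossed
#' with gamma 1..16 (rbf).
#'
#' @param design a `multilesion_design` or numeric matrix.
#' @param deficit numeric response.
#' @param kernel `"linear"` or `"rbf"`.
#' @param C_grid,gamma_grid hyperparameter grids.
#' @param epsilon tube half width (standardized scale).
#' @return An object of class `training_report`: `grid` (data frame with
#'   C, gamma, accuracy, p), `best` (selected row), `best_loocv_pred`
#'   (held-out predictions at the selected setting), `kernel`.
#' @export
loocv_train <- function(design, deficit, kernel = c("linear", "rbf"),
                        C_grid = NULL, gamma_grid = NULL, epsilon = 0.1) {
  kernel <- match.arg(kernel)
  X <- if (inherits(design, "multilesion_design")) design$matrix else
    as.matrix(design)
  y <- as.numeric(deficit)
  M <- length(y)
  if (M < 10L) warn_mlsmap("only %d subjects; LOOCV accuracy will be unstable", M)
  if (sd(y) == 0) stop_mlsmap("deficit vector is constant; accuracy undefined")
  C_grid <- sort(C_grid %||% default_c_grid(kernel))
  if (!length(C_grid)) stop_mlsmap("empty C grid")
  gamma_grid <- if (kernel == "rbf") sort(gamma_grid %||% default_gamma_grid())
    else NA_real_
  settings <- expand.grid(C = C_grid, gamma = gamma_grid,
                          KEEP.OUT.ATTRS = FALSE)
  # order ties toward smaller C then smaller gamma: evaluate in that order
  settings <- settings[order(settings$C, settings$gamma), , drop = FALSE]
  preds <- matrix(NA_real_, M, nrow(settings))
  for (gam in unique(settings$gamma)) {
    gset <- which(settings$gamma == gam | (is.na(gam) & is.na(settings$gamma)))
    gset <- gset[order(settings$C[gset])]
    K <- kernel_matrix(X, kernel, if (kernel == "rbf") gam else NULL)
    for (m in seq_len(M)) {
      ytr <- y[-m]
      ctr <- mean(ytr); sc <- sd(ytr); if (!is.finite(sc) || sc == 0) sc <- 1
      yss <- (ytr - ctr) / sc
      Ktr <- K[-m, -m, drop = FALSE]
      kx <- K[m, -m]
      warm <- NULL   # ascending-C path with warm starts within the fold
      for (g in gset) {
        fit <- svr_smo(Ktr, yss, settings$C[g], epsilon, 1e-6, 3000L, warm)
        warm <- fit$beta
        preds[m, g] <- (sum(kx * fit$beta) + fit$b) * sc + ctr
      }
    }
  }
  acc <- t(apply(preds, 2L, accuracy_stats, real = y))
  grid_df <- data.frame(C = settings$C, gamma = settings$gamma,
                        accuracy = acc[, 1], p = acc[, 2])
  finite <- which(is.finite(grid_df$accuracy))
  if (!length(finite)) stop_mlsmap("no grid point yielded a defined accuracy")
  best_idx <- finite[which.max(grid_df$accuracy[finite])]  # first max: small C/gamma
  structure(list(grid = grid_df, best = grid_df[best_idx, ],
                 best_loocv_pred = preds[, best_idx],
                 kernel = kernel, epsilon = epsilon, M = M),
            class = "training_report")
}

#' @export
print.training_report <- function(x, ...) {
  cat(sprintf(paste0("<training_report> %s kernel, %d grid points; best ",
                     "C=%g%s with LOOCV accuracy %.4f (p=%.3g)\n"),
              x$kernel, nrow(x$grid), x$best$C,
              if (x$kernel == "rbf") sprintf(", gamma=%g", x$best$gamma) else "",
              x$best$accuracy, x$best$p))
  invisible(x)
}

#' Extract voxel weight (beta) maps from a fitted SVR
#'
#' For the linear kernel this is the exact primal weight vector
#' `beta = X' lambda` (so `X beta + b` reproduces the model's own
#' predictions). For the rbf kernel the same dual expansion is returned as
#' the first-order sensitivity approximation of the decision function.
#' The vector is split into the design's lesion-type blocks.
#'
#' @param model a [fit_svr()] result.
#' @param design the `multilesion_design` the model was fitted on.
#' @return An object of class `beta_maps`: list with `beta` (per-block
#'   named list), `columns`, `volume_mode`, `kernel`.
#' @export
extract_beta <- function(model, design) {
  X <- if (inherits(design, "multilesion_design")) design$matrix else
    as.matrix(design)
  if (!identical(dim(X), dim(model$X)))
    stop_mlsmap("design does not match the model's training design")
  beta <- as.numeric(crossprod(X, model$dual_coef))
  if (inherits(design, "multilesion_design")) {
    structure(list(beta = split_by_block(beta, design),
                   columns = design$columns,
                   volume_mode = design$volume_mode,
                   kernel = model$kernel, grid = design$grid),
              class = "beta_maps")
  } else {
    structure(list(beta = list(lesion = beta), columns = NULL,
                   volume_mode = "none", kernel = model$kernel, grid = NULL),
              class = "beta_maps")
  }
}

#' @export
print.beta_maps <- function(x, ...) {
  sizes <- vapply(x$beta, length, 0L)
  cat(sprintf("<beta_maps> %s kernel: %s\n", x$kernel,
              paste(sprintf("%s=%d voxels", names(sizes), sizes),
                    collapse = ", ")))
  invisible(x)
}
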