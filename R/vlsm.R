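# Vectorized pooled-variance two-sample t statistics for every voxel
# column at once. Returns t (NA where untestable), df, and flags.
voxel_t_all <- function(scores, lesion_mat) {
  M <- length(scores)
  n1 <- colSums(lesion_mat)            # lesioned
  n0 <- M - n1
  s1 <- as.numeric(crossprod(lesion_mat, scores))
  s  <- sum(scores)
  ss1 <- as.numeric(crossprod(lesion_mat, scores^2))
  ss  <- sum(scores^2)
  m1 <- s1 / n1
  m0 <- (s - s1) / n0
  pooled_ss <- (ss1 - n1 * m1^2) + ((ss - ss1) - n0 * m0^2)
  df <- M - 2L
  var_p <- pooled_ss / df
  se <- sqrt(var_p * (1 / n1 + 1 / n0))
  t <- (m1 - m0) / se
  testable <- n1 >= 2L & n0 >= 2L
  degenerate <- testable & (var_p <= .Machine$double.eps * max(1, ss)) &
    abs(m1 - m0) > 0
  t[!testable | degenerate] <- NA_real_
  t[testable & !degenerate & !is.finite(t)] <- 0  # 0/0: equal means, zero var
  list(t = t, df = df, testable = testable, degenerate = degenerate)
}

#' Pooled two-sample t test of one lesion column
#'
#' Compares scores of lesioned versus intact subjects with the classical
#' pooled-variance two-sample t statistic. Negative t means lesioned
#' subjects score lower. Voxels where either group has fewer than two
#' subjects, or with zero pooled variance but unequal means, are
#' untestable (`t = NA`).
#'
#' @param scores numeric vector.
#' @param lesion_col binary vector, 1 = lesioned.
#' @return List with `t`, `df`, `testable`, `degenerate`.
#' @export
voxel_t <- function(scores, lesion_col) {
  res <- voxel_t_all(as.numeric(scores), cbind(as.numeric(lesion_col)))
  list(t = res$t[1], df = res$df, testable = res$testable[1],
       degenerate = res$degenerate[1])
}

# all length(x)! permutations (small n only) for exact inference
all_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L, 1L))
  out <- matrix(x[1], 0L, n)
  sub <- all_permutations(x[-1])
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], x[1],
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  out
}

#' Mass-univariate VLSM with permutation correction
#'
#' Computes the pooled two-sample t per retained voxel and corrects for
#' multiple comparisons by permutation: the score vector is shuffled `P`
#' times, all voxel t's are recomputed, and each permutation's maximum
#' `|t|` forms the null. The familywise-adjusted p of a voxel is
#' `(1 + #\{max-null >= |t|\}) / (P + 1)` (maxT). `correction =
#' "uncorrected"` instead compares each voxel against its own permutation
#' t's. `exact = TRUE` enumerates all `M!` shuffles (tiny cohorts only)
#' and uses the unsmoothed `count / M!` rule, which then equals the
#' exhaustive permutation p.
#'
#' @param scores a [prepare_scores()] result or plain numeric vector (its
#'   deficit/residual is NOT used: VLSM tests the norm-corrected score).
#' @param tensor a [lesion_tensor()], already filtered at k.
#' @param P number of permutations.
#' @param seed integer seed for the shuffle stream.
#' @param correction `"maxT"` or `"uncorrected"`.
#' @param sided `"two"` (default) or `"one"` (one-sided toward lower
#'   scores in lesioned subjects, i.e. negative t).
#' @param exact enumerate all permutations instead of sampling.
#' @return An object of class `vlsm_result`: per-voxel `t`, `p_adj`,
#'   `voxel_index`, `testable`, plus `df`, `P`, `seed`, `correction`.
#' @export
vlsm_run <- function(scores, tensor, P = 1000L, seed = 1L,
                     correction = c("maxT", "uncorrected"),
                     sided = c("two", "one"), exact = FALSE) {
  correction <- match.arg(correction)
  sided <- match.arg(sided)
  y <- if (inherits(scores, "prepared_scores")) scores$residual else
    as.numeric(scores)
  X <- tensor$data
  storage.mode(X) <- "double"
  M <- length(y)
  if (nrow(X) != M) stop_mlsmap("scores and tensor disagree in subjects")
  if (!exact && P < 100L)
    warn_mlsmap("P = %d permutations is too coarse for p < 0.05 inference", P)
  real <- voxel_t_all(y, X)
  stat <- function(t) if (sided == "two") abs(t) else -t
  real_stat <- stat(real$t)
  if (exact) {
    if (M > 8L) stop_mlsmap("exact enumeration is limited to M <= 8")
    perms <- all_permutations(seq_len(M))
    nperm <- nrow(perms)
    smooth <- 0L          # identity permutation is in the enumeration
  } else {
    set.seed(seed)
    perms <- t(replicate(P, sample.int(M)))
    nperm <- P
    smooth <- 1L
  }
  testable_idx <- which(real$testable & !real$degenerate)
  Xt <- X[, testable_idx, drop = FALSE]
  count <- numeric(length(testable_idx))
  for (b in seq_len(nperm)) {
    pt_ <- voxel_t_all(y[perms[b, ]], Xt)
    ps <- stat(pt_$t)
    ps[is.na(ps)] <- -Inf
    if (correction == "maxT") {
      mx <- if (length(ps)) max(ps) else -Inf
      count <- count + (mx >= real_stat[testable_idx])
    } else {
      count <- count + (ps >= real_stat[testable_idx])
    }
  }
  p_adj <- rep(NA_real_, ncol(X))
  p_adj[testable_idx] <- (smooth + count) / (smooth + nperm)
  structure(list(voxel_index = tensor$voxel_index, t = real$t,
                 p_adj = p_adj, testable = real$testable & !real$degenerate,
                 degenerate = real$degenerate, df = real$df,
                 P = nperm, seed = seed, correction = correction,
                 sided = sided, exact = exact,
                 lesion_type = tensor$lesion_type, grid = tensor$grid),
            class = "vlsm_result")
}

#' @export
print.vlsm_result <- function(x, ...) {
  cat(sprintf(paste0("<vlsm_result> %s: %d voxels (%d testable), %d ",
                     "permutations (%s), %d voxels with adjusted p < 0.05\n"),
              x$lesion_type, length(x$t), sum(x$testable), x$P, x$correction,
              sum(x$p_adj < 0.05, na.rm = TRUE)))
  invisible(x)
}
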