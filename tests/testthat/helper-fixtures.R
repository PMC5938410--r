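# Shared fixtures, all built in code.

tiny_grid <- function(shape = c(5, 5, 5), voxel = c(1, 1, 1)) {
  reference_grid(shape, voxel)
}

# hand-built 4-subject tensor on a 5x5x5 grid;
# column sums 3, 2, 4, 1 and subject volumes 3, 2, 4, 1 voxels
tiny_tensor <- function(lesion_type = "AIL") {
  data <- rbind(c(1, 1, 1, 0),
                c(1, 0, 1, 0),
                c(1, 1, 1, 1),
                c(0, 0, 1, 0))
  lesion_tensor(data, voxel_index = c(10L, 22L, 63L, 101L), tiny_grid(),
                lesion_type = lesion_type,
                subject_ids = sprintf("s%02d", 1:4))
}

# small simulated cohort for integration-style tests
small_cohort <- function(seed = 7, M = 30) {
  cfg <- sim_config(grid_shape = c(16, 16, 16), voxel_size = c(2, 2, 2),
                    n_subjects = M,
                    ail_spec = lesion_spec(0.12, c(2, 3)),
                    wmh_spec = lesion_spec(0.15, c(2, 3)),
                    seed = seed)
  sample_cohort(cfg)
}

# independent epsilon-SVR oracle: the same dual (equality-constrained
# intercept) solved as a quadratic program; tiny ridge for solve.QP's
# positive-definiteness requirement
qp_svr_oracle <- function(K, y, C, eps) {
  M <- length(y)
  D <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-9, 2 * M)
  d <- -c(eps - y, eps + y)
  A <- cbind(c(rep(1, M), rep(-1, M)), diag(2 * M), -diag(2 * M))
  b0 <- c(0, rep(0, 2 * M), rep(-C, 2 * M))
  s <- quadprog::solve.QP(D, d, A, b0, meq = 1)$solution
  beta <- s[1:M] - s[(M + 1):(2 * M)]
  free <- which(abs(beta) > 1e-7 & abs(abs(beta) - C) > 1e-7 * max(1, C))
  b <- if (length(free))
    mean(y[free] - sign(beta[free]) * eps - (K %*% beta)[free]) else NA_real_
  list(beta = beta, b = b)
}

rank_auc <- function(score, truth) {
  r <- rank(score)
  n1 <- sum(truth); n0 <- sum(!truth)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
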