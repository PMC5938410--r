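test_that("voxel t matches the pooled two-sample closed form and t.test", {
  # frozen closed-form oracle: {1,2,3} lesioned vs {4,5,6} intact
  res <- voxel_t(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(res$t, -3.674235, tolerance = 1e-6)
  expect_equal(res$df, 4L)
  # independent oracle on random instances
  set.seed(5)
  for (i in 1:20) {
    y <- rnorm(20, 20, 4)
    x <- rbinom(20, 1, 0.4)
    if (sum(x) < 2 || sum(1 - x) < 2) next
    ours <- voxel_t(y, x)
    ref <- t.test(y[x == 1], y[x == 0], var.equal = TRUE)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter))
  }
})

test_that("degenerate voxels are flagged, equal groups give t = 0", {
  expect_equal(voxel_t(c(1, 2, 1, 2), c(1, 1, 0, 0))$t, 0)
  # a group with < 2 subjects is untestable
  r <- voxel_t(c(1, 2, 3, 4), c(1, 0, 0, 0))
  expect_false(r$testable)
  expect_true(is.na(r$t))
  # zero pooled variance with unequal means: flagged, not infinite
  r2 <- voxel_t(c(2, 2, 5, 5), c(1, 1, 0, 0))
  expect_true(r2$degenerate)
  expect_true(is.na(r2$t))
})

test_that("maxT counting rule and monotonicity hold", {
  set.seed(8)
  co <- small_cohort(seed = 41, M = 24)
  tn <- apply_min_subject_filter(co$ail, 3)
  ps <- prepare_scores(co$table)
  expect_warning(vr99 <- vlsm_run(ps, tn, P = 99, seed = 1), "coarse")
  vr <- vlsm_run(ps, tn, P = 200, seed = 1)
  expect_true(all(vr$p_adj >= 1 / 201, na.rm = TRUE))
  expect_true(all(vr$p_adj <= 1, na.rm = TRUE))
  # monotone: larger |t| never earns a larger adjusted p
  ok <- vr$testable
  o <- order(abs(vr$t[ok]), decreasing = TRUE)
  expect_true(all(diff(vr$p_adj[ok][o]) >= 0))
  # reproducibility
  vr2 <- vlsm_run(ps, tn, P = 200, seed = 1)
  expect_identical(vr$p_adj, vr2$p_adj)
})

test_that("constant scores give all-one adjusted p at t = 0", {
  tn <- apply_min_subject_filter(small_cohort(seed = 43, M = 12)$ail, 3)
  vr <- vlsm_run(rep(5, 12), tn, P = 100, seed = 2)
  expect_true(all(vr$t[vr$testable] == 0))
  expect_true(all(vr$p_adj[vr$testable] == 1))
})

test_that("exact enumeration equals the exhaustive permutation p at M = 7", {
  set.seed(12)
  y <- c(11, 14, 19, 22, 24, 26, 30)
  x <- c(1, 1, 1, 0, 0, 0, 0)
  g <- tiny_grid()
  tn <- lesion_tensor(cbind(x), 13L, g, "AIL", sprintf("s%d", 1:7))
  vr <- vlsm_run(y, tn, seed = 1, exact = TRUE)
  # exhaustive oracle: all C(7,3) equally likely lesioned-group assignments
  combos <- combn(7, 3)
  t_all <- apply(combos, 2, function(idx) {
    unname(t.test(y[idx], y[-idx], var.equal = TRUE)$statistic)
  })
  t_real <- unname(t.test(y[x == 1], y[x == 0], var.equal = TRUE)$statistic)
  p_exhaustive <- mean(abs(t_all) >= abs(t_real) - 1e-12)
  expect_equal(vr$p_adj[1], p_exhaustive, tolerance = 1e-12)
  # on a 1-voxel problem maxT and uncorrected agree by construction
  vr_unc <- vlsm_run(y, tn, seed = 1, exact = TRUE,
                     correction = "uncorrected")
  expect_equal(vr$p_adj, vr_unc$p_adj)
})

test_that("regress-out volume control changes the tested scores", {
  co <- small_cohort(seed = 47, M = 24)
  tn <- apply_min_subject_filter(co$ail, 3)
  ps_none <- prepare_scores(co$table, volume_control = "none")
  ps_vol <- prepare_scores(co$table, volume_control = "regress_out",
                           volume_columns = "ail_volume_ml")
  expect_lt(abs(cor(ps_vol$residual, co$table$ail_volume_ml)), 1e-10)
  vr1 <- vlsm_run(ps_none, tn, P = 100, seed = 3)
  vr2 <- vlsm_run(ps_vol, tn, P = 100, seed = 3)
  expect_false(isTRUE(all.equal(vr1$t, vr2$t)))
})
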