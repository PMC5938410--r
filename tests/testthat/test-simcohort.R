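test_that("brain mask is contained, deterministic, and degenerate grids error", {
  cfg <- sim_config(grid_shape = c(20, 20, 20), seed = 1)
  m <- generate_brain_mask(cfg)
  expect_true(sum(m) > 0 && sum(m) < 8000)
  expect_identical(m, generate_brain_mask(cfg))
  expect_error(sim_config(grid_shape = c(1, 1, 1)), "too small")
})

test_that("sample_cohort is bit-reproducible under a fixed config", {
  cfg <- sim_config(grid_shape = c(14, 14, 14), n_subjects = 12, seed = 42)
  a <- sample_cohort(cfg)
  b <- sample_cohort(cfg)
  expect_identical(a$ail$data, b$ail$data)
  expect_identical(a$wmh$data, b$wmh$data)
  expect_identical(a$table, b$table)
})

test_that("AIL and WMH are exclusive per subject-voxel (AIL wins)", {
  co <- small_cohort(seed = 3)
  common <- intersect(co$ail$voxel_index, co$wmh$voxel_index)
  ia <- match(common, co$ail$voxel_index)
  iw <- match(common, co$wmh$voxel_index)
  expect_true(all(co$ail$data[, ia] + co$wmh$data[, iw] <= 1L))
})

test_that("empirical prevalence matches the sampler's own rate", {
  # Monte-Carlo check of the coverage calibration: mean per-voxel
  # prevalence over the prior support within +-0.05 of target at M = 100
  cfg <- sim_config(grid_shape = c(16, 16, 16), n_subjects = 100,
                    ail_spec = lesion_spec(0.15, c(2, 4)),
                    wmh_spec = lesion_spec(0.10, c(2, 3)), seed = 11)
  co <- sample_cohort(cfg)
  mask <- generate_brain_mask(cfg)
  prev <- prevalence_map(co$ail)[mask] / 100
  expect_lt(abs(mean(prev) - 0.15), 0.05)
})

test_that("empty spatial prior errors", {
  prior <- array(0, c(10, 10, 10))
  cfg <- sim_config(grid_shape = c(10, 10, 10), n_subjects = 5,
                    ail_spec = lesion_spec(0.1, c(1, 2), prior = prior),
                    seed = 1)
  expect_error(sample_cohort(cfg), "empty spatial prior")
})

test_that("noiseless scores follow the planted linear model exactly", {
  cfg0 <- sim_config(grid_shape = c(12, 12, 12), n_subjects = 20,
                     ail_spec = lesion_spec(0.2, c(2, 3)),
                     wmh_spec = lesion_spec(0.2, c(2, 3)), seed = 5)
  mask <- generate_brain_mask(cfg0)
  co0 <- sample_cohort(cfg0)
  # choose a strategic voxel that is actually lesioned in some subjects
  v <- co0$ail$voxel_index[which.max(colSums(co0$ail$data))]
  cfg <- sim_config(grid_shape = c(12, 12, 12), n_subjects = 20,
                    ail_spec = lesion_spec(0.2, c(2, 3)),
                    wmh_spec = lesion_spec(0.2, c(2, 3)),
                    strategic_ail = list(voxels = v, weights = 5),
                    covariate_effects = c(age = 0, sex = 0, education = 0),
                    base_score = 30, noise_sd = 0, seed = 5)
  co <- sample_cohort(cfg)
  lesioned <- co$ail$data[, match(v, co$ail$voxel_index)] == 1L
  expect_true(any(lesioned))
  expect_equal(co$table$score[lesioned], rep(25, sum(lesioned)))
  expect_equal(co$table$score[!lesioned], rep(30, sum(!lesioned)))
})

test_that("scores reconstruct exactly from truth maps at noise 0", {
  w <- planted_cohort_config(2, n_subjects = 20, noise_sd = 2)
  cfg <- w$config
  cfg$noise_sd <- 0
  co <- sample_cohort(cfg)
  recon <- cfg$base_score -
    as.numeric(co$ail$data %*% co$truth_beta_ail[co$ail$voxel_index]) -
    as.numeric(co$wmh$data %*% co$truth_beta_wmh[co$wmh$voxel_index]) +
    cfg$covariate_effects["age"] * (co$table$age - mean(co$table$age)) +
    cfg$covariate_effects["education"] *
      (co$table$education - mean(co$table$education))
  recon <- pmin(pmax(recon, 0), 30)
  expect_equal(co$table$score, as.numeric(recon), tolerance = 1e-12)
})

test_that("score noise has the configured standard deviation", {
  # chi-square bound: sample sd of (score - noiseless) over 200 subjects
  cfg <- sim_config(grid_shape = c(12, 12, 12), n_subjects = 200,
                    noise_sd = 2, base_score = 15,  # keep clipping inactive
                    score_range = c(-30, 60), seed = 9)
  co <- sample_cohort(cfg)
  s <- sd(co$table$score - co$table$score_noiseless)
  expect_gt(s, 1.6)
  expect_lt(s, 2.4)
})

test_that("regression on planted columns recovers truth weights at noise 0", {
  cfg0 <- sim_config(grid_shape = c(12, 12, 12), n_subjects = 40,
                     ail_spec = lesion_spec(0.25, c(2, 3)),
                     wmh_spec = lesion_spec(0.25, c(2, 3)), seed = 21)
  co0 <- sample_cohort(cfg0)
  va <- co0$ail$voxel_index[order(-colSums(co0$ail$data))[1:2]]
  vw <- co0$wmh$voxel_index[which.max(colSums(co0$wmh$data))]
  cfg <- sim_config(grid_shape = c(12, 12, 12), n_subjects = 40,
                    ail_spec = lesion_spec(0.25, c(2, 3)),
                    wmh_spec = lesion_spec(0.25, c(2, 3)),
                    strategic_ail = list(voxels = va, weights = c(3, 1.5)),
                    strategic_wmh = list(voxels = vw, weights = 2),
                    covariate_effects = c(age = 0, sex = 0, education = 0),
                    base_score = 30, noise_sd = 0,
                    score_range = c(-100, 100), seed = 21)
  co <- sample_cohort(cfg)
  X <- cbind(co$ail$data[, match(va, co$ail$voxel_index)],
             co$wmh$data[, match(vw, co$wmh$voxel_index)])
  fit <- lm(co$table$score ~ X)
  expect_equal(unname(coef(fit)[-1]), c(-3, -1.5, -2), tolerance = 1e-8)
})

test_that("write_cohort emits masks, table, truth maps and config", {
  dir <- withr::local_tempdir()
  co <- small_cohort(seed = 13, M = 4)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "cohort.csv")))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))
  expect_true(file.exists(file.path(dir, "truth_beta_ail.nii.gz")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  got <- load_cohort(file.path(dir, "manifest.tsv"),
                     file.path(dir, "cohort.csv"))
  expect_equal(unname(got$tensors$AIL$data), unname(co$ail$data))
  expect_equal(unname(got$tensors$WMH$data), unname(co$wmh$data))
})
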