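#' Lesion sampler specification for one lesion type
#'
#' Lesions are unions of spheres: every voxel of the spatial-prior support
#' independently becomes a sphere center with a small probability, and the
#' center probability is calibrated (by `uniroot` on the exact coverage
#' identity for the mean radius) so that the average per-voxel lesion
#' prevalence over the prior support equals `target_prevalence`. This gives
#' blob-shaped lesions whose per-voxel hit rate is known by construction,
#' which is what parameter-recovery tests need.
#'
#' @param target_prevalence mean per-voxel probability of lesion over the
#'   prior support, in (0, 1).
#' @param radius_range inclusive sphere radius range in voxels (>= 1);
#'   radii are drawn uniformly (continuously) in this range.
#' @param prior either `"uniform"` (uniform over the brain mask) or a 3-D
#'   non-negative weight array on the grid; positive entries form the
#'   support and weight the center probabilities.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(target_prevalence = 0.1, radius_range = c(2, 4),
                        prior = "uniform") {
  if (!is.numeric(target_prevalence) || target_prevalence <= 0 ||
      target_prevalence >= 1)
    stop_mlsmap("target_prevalence must be in (0, 1)")
  if (length(radius_range) == 1L) radius_range <- rep(radius_range, 2L)
  if (any(radius_range < 1)) stop_mlsmap("sphere radii must be >= 1 voxel")
  structure(list(target_prevalence = target_prevalence,
                 radius_range = sort(as.numeric(radius_range)),
                 prior = prior),
            class = "lesion_spec")
}

#' Configuration of a synthetic two-lesion cohort
#'
#' Describes a simulated stroke-like cohort: binary acute-lesion (AIL) and
#' white-matter-hyperintensity (WMH) masks on a common grid, demographics,
#' and a behavior score generated as
#' `base - sum(truth_ail * x_ail) - sum(truth_wmh * x_wmh) + covariate
#' effects + N(0, noise_sd)`, clipped to `score_range`. Lesions therefore
#' LOWER the score, like a cognitive screening scale. Where a voxel is
#' drawn as both AIL and WMH, AIL wins (the acute event masks the chronic
#' one on imaging).
#'
#' @param grid_shape 3 positive integers (voxels per axis).
#' @param voxel_size mm per axis.
#' @param n_subjects cohort size M (>= 2).
#' @param ail_spec,wmh_spec [lesion_spec()] per lesion type.
#' @param strategic_ail,strategic_wmh optional lists `list(voxels =, weights =)`
#'   with flat voxel indices (inside the brain mask) and per-voxel true
#'   score penalties.
#' @param covariate_effects named numeric: per-unit score effects of
#'   `age`, `sex`, `education` (applied to centered covariates).
#' @param age_range,education_range uniform sampling ranges (years).
#' @param p_female probability of `sex == 1`.
#' @param base_score noiseless lesion-free score at covariate means.
#' @param noise_sd Gaussian score noise (>= 0), score units.
#' @param score_range inclusive clipping range, e.g. `c(0, 30)`.
#' @param brain_mask optional logical 3-D array replacing the default
#'   ellipsoid brain mask.
#' @param seed integer master seed; all cohort randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(grid_shape = c(24, 24, 24), voxel_size = c(2, 2, 2),
                       n_subjects = 60L,
                       ail_spec = lesion_spec(0.10, c(2, 4)),
                       wmh_spec = lesion_spec(0.15, c(2, 4)),
                       strategic_ail = NULL, strategic_wmh = NULL,
                       covariate_effects = c(age = -0.08, sex = 0,
                                             education = 0.25),
                       age_range = c(50, 82), education_range = c(0, 14),
                       p_female = 0.42, base_score = 27,
                       noise_sd = 2, score_range = c(0, 30),
                       brain_mask = NULL, seed = 1L) {
  if (!is_count(n_subjects, 2L)) stop_mlsmap("n_subjects must be >= 2")
  if (noise_sd < 0) stop_mlsmap("noise_sd must be >= 0")
  stopifnot(inherits(ail_spec, "lesion_spec"), inherits(wmh_spec, "lesion_spec"))
  cfg <- structure(list(grid_shape = as.integer(grid_shape),
                        voxel_size = voxel_size, n_subjects = as.integer(n_subjects),
                        ail_spec = ail_spec, wmh_spec = wmh_spec,
                        strategic_ail = strategic_ail, strategic_wmh = strategic_wmh,
                        covariate_effects = covariate_effects,
                        age_range = age_range, education_range = education_range,
                        p_female = p_female, base_score = base_score,
                        noise_sd = noise_sd, score_range = score_range,
                        brain_mask = brain_mask, seed = as.integer(seed)),
                   class = "sim_config")
  mask <- generate_brain_mask(cfg)
  for (s in c("strategic_ail", "strategic_wmh")) {
    st <- cfg[[s]]
    if (!is.null(st)) {
      if (length(st$voxels) != length(st$weights))
        stop_mlsmap("%s voxels and weights differ in length", s)
      if (any(st$voxels < 1) || any(st$voxels > length(mask)) ||
          !all(mask[st$voxels]))
        stop_mlsmap("%s voxels must lie inside the brain mask", s)
    }
  }
  cfg
}

#' Default ellipsoidal brain mask for a simulation grid
#'
#' An axis-aligned ellipsoid with semi-axes at 90% of the half-extent of
#' each axis (or the user-supplied mask from the config).
#'
#' @param config a [sim_config()].
#' @return Logical 3-D array.
#' @export
generate_brain_mask <- function(config) {
  if (!is.null(config$brain_mask)) {
    m <- config$brain_mask
    if (!identical(dim(m), as.integer(config$grid_shape)))
      stop_mlsmap("brain_mask shape does not match grid_shape")
    return(m != 0)
  }
  s <- config$grid_shape
  ctr <- (s + 1) / 2
  semi <- 0.9 * (s - 1) / 2
  if (any(semi <= 0))
    stop_mlsmap("grid too small to contain an interior brain voxel")
  g <- expand.grid(x = seq_len(s[1]), y = seq_len(s[2]), z = seq_len(s[3]))
  d <- ((g$x - ctr[1]) / semi[1])^2 + ((g$y - ctr[2]) / semi[2])^2 +
    ((g$z - ctr[3]) / semi[3])^2
  mask <- array(d <= 1, dim = s)
  if (!any(mask))
    stop_mlsmap("grid too small to contain an interior brain voxel")
  mask
}

# Per-voxel center probabilities calibrated so the mean prevalence over the
# prior support equals the target, using the exact coverage identity
#   P(voxel v lesioned) = 1 - prod_{c in B(v, r)} (1 - q_c)
# evaluated at the mean radius.
calibrate_centers <- function(spec, mask, grid_shape) {
  support <- if (identical(spec$prior, "uniform")) {
    w <- as.numeric(mask)
    w
  } else {
    w <- as.numeric(spec$prior)
    if (length(w) != length(mask))
      stop_mlsmap("prior shape does not match the grid")
    w[!mask] <- 0
    w
  }
  idx <- which(support > 0)
  if (!length(idx)) stop_mlsmap("empty spatial prior")
  w <- support[idx] / mean(support[idx])   # mean weight 1 over support
  # expected coverage per support voxel v: sum over candidate centers c of
  # w_c * P(radius reaches the c-to-v distance), radius ~ U(radius_range)
  coords <- arrayInd(idx, .dim = grid_shape)
  rmin <- spec$radius_range[1]; rmax <- spec$radius_range[2]
  off <- sphere_offsets(rmax)
  d <- sqrt(rowSums(off^2))
  pw <- if (rmax > rmin) pmin(1, pmax(0, (rmax - d) / (rmax - rmin))) else
    as.numeric(d <= rmax)
  pw[d <= rmin] <- 1
  wmap <- array(0, dim = grid_shape)
  wmap[idx] <- w
  cover <- numeric(length(idx))
  for (k in seq_len(nrow(off))) {
    if (pw[k] == 0) next
    nb <- sweep(coords, 2L, off[k, ], "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= grid_shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= grid_shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= grid_shape[3]
    flat <- nb[ok, 1] + grid_shape[1] * (nb[ok, 2] - 1) +
      grid_shape[1] * grid_shape[2] * (nb[ok, 3] - 1)
    cover[ok] <- cover[ok] + pw[k] * wmap[flat]
  }
  target <- spec$target_prevalence
  f <- function(s) mean(1 - exp(-s * cover)) - target
  # 1 - (1-q)^n ~ 1 - exp(-q n) for small q; solve on the exp scale then map back
  hi <- 1
  while (f(hi) < 0 && hi < 1e6) hi <- hi * 2
  srate <- stats::uniroot(f, c(1e-12, hi), tol = 1e-10)$root
  q <- 1 - exp(-srate * w)                 # per-voxel center probability
  list(idx = idx, q = pmin(q, 1), offsets = off)
}

sphere_offsets <- function(r) {
  ri <- floor(r)
  g <- expand.grid(x = -ri:ri, y = -ri:ri, z = -ri:ri)
  g <- g[g$x^2 + g$y^2 + g$z^2 <= r^2, , drop = FALSE]
  as.matrix(g)
}

sample_subject_mask <- function(cal, spec, mask, grid_shape) {
  out <- array(FALSE, dim = grid_shape)
  centers <- cal$idx[runif(length(cal$idx)) < cal$q]
  if (length(centers)) {
    cc <- arrayInd(centers, .dim = grid_shape)
    radii <- runif(length(centers), spec$radius_range[1], spec$radius_range[2])
    for (j in seq_along(centers)) {
      off <- sphere_offsets(radii[j])
      nb <- sweep(off, 2L, cc[j, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= grid_shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= grid_shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= grid_shape[3]
      out[nb[ok, , drop = FALSE]] <- TRUE
    }
  }
  out & mask
}

#' Sample a synthetic two-lesion cohort
#'
#' Draws per-subject AIL and WMH masks (unions of spheres from each lesion
#' type's spatial prior), resolves AIL/WMH co-occurrence in favor of AIL,
#' samples demographics, and fills in behavior scores via
#' [generate_scores()]. Fully deterministic given the config (including its
#' seed).
#'
#' @param config a [sim_config()].
#' @return An object of class `simulated_cohort`: list with `config`,
#'   `ail` and `wmh` ([lesion_tensor()]s over all ever-lesioned voxels),
#'   `table` (cohort data frame), `truth_beta_ail`/`truth_beta_wmh`
#'   (per-voxel true penalty maps, full-grid vectors) and `brain_mask`.
#' @export
sample_cohort <- function(config) {
  grid <- reference_grid(config$grid_shape, config$voxel_size,
                         space = "simulated")
  mask <- generate_brain_mask(config)
  M <- config$n_subjects
  set.seed(substream_seed(config$seed, "lesions"))
  cal_a <- calibrate_centers(config$ail_spec, mask, config$grid_shape)
  cal_w <- calibrate_centers(config$wmh_spec, mask, config$grid_shape)
  ail_full <- matrix(0L, M, prod(config$grid_shape))
  wmh_full <- matrix(0L, M, prod(config$grid_shape))
  for (m in seq_len(M)) {
    a <- sample_subject_mask(cal_a, config$ail_spec, mask, config$grid_shape)
    w <- sample_subject_mask(cal_w, config$wmh_spec, mask, config$grid_shape)
    w[a] <- FALSE                     # exclusivity: AIL overrides WMH
    ail_full[m, ] <- as.integer(a)
    wmh_full[m, ] <- as.integer(w)
  }
  ids <- sprintf("sub-%03d", seq_len(M))
  set.seed(substream_seed(config$seed, "covariates"))
  table <- data.frame(
    id = ids,
    age = round(runif(M, config$age_range[1], config$age_range[2]), 1),
    sex = rbinom(M, 1L, config$p_female),
    education = round(runif(M, config$education_range[1],
                            config$education_range[2])),
    stringsAsFactors = FALSE)
  vox_ml <- voxel_volume_ml(grid)
  table$ail_volume_ml <- rowSums(ail_full) * vox_ml
  table$wmh_volume_ml <- rowSums(wmh_full) * vox_ml
  keep_a <- which(colSums(ail_full) > 0L)
  keep_w <- which(colSums(wmh_full) > 0L)
  truth_a <- numeric(prod(config$grid_shape))
  truth_w <- numeric(prod(config$grid_shape))
  if (!is.null(config$strategic_ail))
    truth_a[config$strategic_ail$voxels] <- config$strategic_ail$weights
  if (!is.null(config$strategic_wmh))
    truth_w[config$strategic_wmh$voxels] <- config$strategic_wmh$weights
  cohort <- structure(list(
    config = config,
    ail = lesion_tensor(ail_full[, keep_a, drop = FALSE], keep_a, grid,
                        "AIL", ids, table$ail_volume_ml),
    wmh = lesion_tensor(wmh_full[, keep_w, drop = FALSE], keep_w, grid,
                        "WMH", ids, table$wmh_volume_ml),
    table = table, truth_beta_ail = truth_a, truth_beta_wmh = truth_w,
    brain_mask = mask), class = "simulated_cohort")
  cohort$table <- generate_scores(cohort)
  cohort
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf(paste0("<simulated_cohort> M=%d on %s grid; ",
                     "%d AIL / %d WMH voxels ever lesioned\n"),
              x$config$n_subjects, paste(x$config$grid_shape, collapse = "x"),
              ncol(x$ail$data), ncol(x$wmh$data)))
  invisible(x)
}

#' Generate behavior scores for a simulated cohort
#'
#' `score = base - X_ail %*% truth_ail - X_wmh %*% truth_wmh +
#' covariate effects (on centered covariates) + N(0, noise_sd)`, clipped to
#' the configured score range. With `noise_sd = 0` and no clipping active
#' the scores are an exact linear function of the planted lesion columns.
#'
#' @param cohort a `simulated_cohort` (scores column is (re)computed).
#' @return The cohort table with `score` and `score_noiseless` columns.
#' @export
generate_scores <- function(cohort) {
  cfg <- cohort$config
  tb <- cohort$table
  lesion_term <- as.numeric(
    cohort$ail$data %*% cohort$truth_beta_ail[cohort$ail$voxel_index] +
    cohort$wmh$data %*% cohort$truth_beta_wmh[cohort$wmh$voxel_index])
  ce <- cfg$covariate_effects
  cov_term <- (ce["age"] %||% 0) * (tb$age - mean(tb$age)) +
    (ce["sex"] %||% 0) * (tb$sex - mean(tb$sex)) +
    (ce["education"] %||% 0) * (tb$education - mean(tb$education))
  cov_term <- as.numeric(cov_term)
  noiseless <- cfg$base_score - lesion_term + cov_term
  set.seed(substream_seed(cfg$seed, "noise"))
  score <- noiseless + rnorm(nrow(tb), 0, cfg$noise_sd)
  tb$score_noiseless <- noiseless
  tb$score <- pmin(pmax(score, cfg$score_range[1]), cfg$score_range[2])
  tb
}

#' Write a simulated cohort to disk in standard formats
#'
#' One NIfTI mask per subject per lesion type, `cohort.csv`, truth weight
#' maps, and the resolved config as YAML.
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man_a <- write_lesion_masks(cohort$ail, file.path(dir, "masks"))
  man_w <- write_lesion_masks(cohort$wmh, file.path(dir, "masks"))
  manifest <- rbind(man_a, man_w)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.csv(cohort$table, file.path(dir, "cohort.csv"), row.names = FALSE)
  g <- cohort$ail$grid
  write_nifti(array(cohort$truth_beta_ail, g$shape),
              file.path(dir, "truth_beta_ail.nii.gz"), g$voxel_size, g$affine,
              "float32")
  write_nifti(array(cohort$truth_beta_wmh, g$shape),
              file.path(dir, "truth_beta_wmh.nii.gz"), g$voxel_size, g$affine,
              "float32")
  cfg <- cohort$config
  cfg$brain_mask <- NULL
  yaml::write_yaml(rapply(unclass(cfg), unclass, how = "replace"),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Reference planted-signal validation world
#'
#' A fixed synthetic two-lesion world used by the package's own validation
#' suite: a 20x20x20 grid of 2 mm voxels, 60 subjects, Gaussian spatial
#' priors (sd 4 voxels) centered on two disjoint strategic spheres (radius
#' 2 voxels, about 0.26 ml) — a deep "AIL" focus and a periventricular-like
#' "WMH" focus — lesions as unions of spheres of radius 2-3 voxels with
#' mean per-voxel prevalence 0.15 over each prior, and MoCA-like scores:
#' base 27, clip 0-30, age/education gradients, noise sd 2. Strategic
#' per-voxel weights decay from the region center (Gaussian, sd 1.25
#' voxels) and are rescaled so that the mean score penalty among subjects
#' lesioned in a region equals `effect_multiple` times the noise sd
#' (1.5 by default: the planted effect is 1.5 noise SDs).
#'
#' The weight rescaling is computed from the cohort the seed itself
#' generates (lesion masks are independent of the weights, so the
#' calibration is exact for that cohort and fully reproducible).
#'
#' @param seed integer master seed.
#' @param n_subjects cohort size.
#' @param effect_multiple planted effect in units of noise sd.
#' @param noise_sd score noise (score units).
#' @return List with `config` (a calibrated [sim_config()]),
#'   `strategic_ail`, `strategic_wmh` (flat voxel index vectors of the
#'   planted regions).
#' @export
planted_cohort_config <- function(seed, n_subjects = 60L,
                                  effect_multiple = 1.5, noise_sd = 2) {
  shape <- c(20L, 20L, 20L)
  g <- as.matrix(expand.grid(x = 1:20, y = 1:20, z = 1:20))
  gaussian_prior <- function(center, sigma = 4) {
    array(exp(-rowSums(sweep(g, 2, center)^2) / (2 * sigma^2)), dim = shape)
  }
  region <- function(c0, radius = 2, tau = 1.25) {
    d2 <- rowSums(sweep(g, 2, c0)^2)
    vox <- which(d2 <= radius^2 + 1e-9)
    w <- exp(-d2[vox] / (2 * tau^2))
    list(vox = vox, w = w / sum(w))
  }
  ctr_ail <- c(6, 9, 10); ctr_wmh <- c(15, 12, 10)
  ra <- region(ctr_ail); rw <- region(ctr_wmh)
  eff <- effect_multiple * noise_sd
  cfg <- sim_config(
    grid_shape = shape, voxel_size = c(2, 2, 2), n_subjects = n_subjects,
    ail_spec = lesion_spec(0.15, c(2, 3), prior = gaussian_prior(ctr_ail)),
    wmh_spec = lesion_spec(0.15, c(2, 3), prior = gaussian_prior(ctr_wmh)),
    strategic_ail = list(voxels = ra$vox, weights = eff * ra$w),
    strategic_wmh = list(voxels = rw$vox, weights = eff * rw$w),
    covariate_effects = c(age = -0.12, sex = 0, education = 0.3),
    base_score = 27, noise_sd = noise_sd, score_range = c(0, 30),
    seed = seed)
  # rescale weights so the mean penalty among region carriers equals eff
  co0 <- sample_cohort(cfg)
  carrier_mean <- function(tensor, reg) {
    cols <- match(reg$vox, tensor$voxel_index)
    keep <- !is.na(cols)
    pen <- as.numeric(tensor$data[, cols[keep], drop = FALSE] %*%
                        (eff * reg$w[keep]))
    mean(pen[pen > 0])
  }
  cfg$strategic_ail$weights <- cfg$strategic_ail$weights *
    eff / carrier_mean(co0$ail, ra)
  cfg$strategic_wmh$weights <- cfg$strategic_wmh$weights *
    eff / carrier_mean(co0$wmh, rw)
  list(config = cfg, strategic_ail = ra$vox, strategic_wmh = rw$vox)
}

#' Null lesion tensor for calibration studies
#'
#' Draws an M x V binary lesion tensor with independent Bernoulli voxels
#' (per-voxel prevalence uniform in `prevalence_range`), placed at random
#' positions of the grid. Behavior scores generated independently of such
#' a tensor form a global-null cohort for false-positive calibration of
#' the inference machinery.
#'
#' @param M number of subjects.
#' @param V number of voxels.
#' @param grid a [reference_grid()] (default 20^3 at 2 mm).
#' @param prevalence_range per-voxel lesion probability range.
#' @param lesion_type label.
#' @param seed integer seed.
#' @return A [lesion_tensor()].
#' @export
random_lesion_tensor <- function(M, V,
                                 grid = reference_grid(c(20, 20, 20),
                                                       c(2, 2, 2)),
                                 prevalence_range = c(0.1, 0.4),
                                 lesion_type = "lesion", seed = 1L) {
  set.seed(seed)
  vox <- sort(sample.int(n_voxels(grid), V))
  prev <- runif(V, prevalence_range[1], prevalence_range[2])
  data <- matrix(rbinom(M * V, 1L, rep(prev, each = M)), M, V)
  lesion_tensor(data, vox, grid, lesion_type = lesion_type)
}
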