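#' Permutation significance of SVR voxel weights
#'
#' Shuffles the deficit vector `P` times, refits the SVR at the fixed,
#' already-selected hyperparameters (no per-permutation re-training), and
#' extracts pseudo weight maps. The per-voxel p is the smoothed exceedance
#' rate `(1 + #\{pseudo >= real\}) / (P + 1)`, one-sided toward large
#' positive weights — under the deficit convention, damage that worsens
#' the score earns a positive weight. Ties count as exceedance
#' (conservative). For a two-lesion design the pseudo weights of both
#' blocks come from the same shuffles, so the two lesion types are tested
#' at the same significance level.
#'
#' @param design a `multilesion_design`.
#' @param deficit numeric deficit vector.
#' @param C,gamma,kernel,epsilon the already-selected model specification.
#' @param P number of permutations (>= 100 recommended).
#' @param seed integer seed for the shuffle stream.
#' @param alternative `"greater"` (default, positive-weight one-sided) or
#'   `"two.sided"` (on `|beta|`).
#' @return An object of class `permutation_p_maps`: per-column `beta`,
#'   `count`, `p`, plus `columns`, `P`, `seed`, `model_spec`.
#' @export
permutation_p <- function(design, deficit, C, gamma = NULL,
                          kernel = c("linear", "rbf"), epsilon = 0.1,
                          P = 1000L, seed = 1L,
                          alternative = c("greater", "two.sided")) {
  kernel <- match.arg(kernel)
  alternative <- match.arg(alternative)
  if (P < 100L)
    warn_mlsmap("P = %d permutations is too coarse for p < 0.05 inference", P)
  X <- design$matrix
  y <- as.numeric(deficit)
  M <- length(y)
  model <- fit_svr(design, y, kernel = kernel, C = C, gamma = gamma,
                   epsilon = epsilon)
  real_beta <- as.numeric(crossprod(X, model$dual_coef))
  ys <- (y - model$y_center) / model$y_scale
  set.seed(seed)
  perm_y <- vapply(seq_len(P), function(i) ys[sample.int(M)], numeric(M))
  res <- svr_perm_counts(model$K, X, real_beta, perm_y, C, epsilon,
                         1e-8, 200000L, alternative == "two.sided")
  if (res$n_nonconverged > 0L)
    warn_mlsmap("%d of %d permutation refits did not fully converge",
                res$n_nonconverged, P)
  counts <- as.numeric(res$counts)
  structure(list(beta = real_beta, count = counts,
                 p = (1 + counts) / (P + 1),
                 columns = design$columns, blocks = design$blocks,
                 block_sizes = design$block_sizes,
                 grid = design$grid, P = as.integer(P), seed = seed,
                 alternative = alternative,
                 model_spec = list(kernel = kernel, C = C, gamma = gamma,
                                   epsilon = epsilon,
                                   volume_mode = design$volume_mode,
                                   retrained_per_permutation = "no"),
                 model = model),
            class = "permutation_p_maps")
}

#' @export
print.permutation_p_maps <- function(x, ...) {
  for (lt in x$blocks) {
    sel <- x$columns$lesion_type == lt
    cat(sprintf("  %s: %d voxels, %d with p < 0.05\n", lt, sum(sel),
                sum(x$p[sel] < 0.05)))
  }
  invisible(x)
}

neighbor_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  if (connectivity == 6L) g[rowSums(abs(g)) == 1L, , drop = FALSE]
  else if (connectivity == 18L) g[rowSums(abs(g)) <= 2L, , drop = FALSE]
  else if (connectivity == 26L) g
  else stop_mlsmap("connectivity must be 6, 18 or 26")
}

# connected components over a set of flat voxel indices
connected_components <- function(voxels, grid, connectivity = 26L) {
  if (!length(voxels)) return(list())
  off <- neighbor_offsets(connectivity)
  shape <- grid$shape
  inset <- new.env(hash = TRUE, size = length(voxels))
  for (v in voxels) assign(as.character(v), TRUE, envir = inset)
  seen <- new.env(hash = TRUE, size = length(voxels))
  comps <- list()
  for (v in voxels) {
    if (!is.null(seen[[as.character(v)]])) next
    queue <- v; seen[[as.character(v)]] <- TRUE
    members <- integer()
    while (length(queue)) {
      u <- queue[[1]]; queue <- queue[-1]
      members <- c(members, u)
      cu <- arrayInd(u, .dim = shape)
      nb <- sweep(off, 2L, as.integer(cu), "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
        nb[, 2] >= 1 & nb[, 2] <= shape[2] &
        nb[, 3] >= 1 & nb[, 3] <= shape[3]
      flat <- nb[ok, 1] + shape[1] * (nb[ok, 2] - 1) +
        shape[1] * shape[2] * (nb[ok, 3] - 1)
      for (f in flat) {
        key <- as.character(f)
        if (!is.null(inset[[key]]) && is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          queue <- c(queue, f)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

#' Threshold p-maps and extract significant clusters
#'
#' Binarizes each lesion type's p-map at `alpha` and decomposes the
#' significant voxels into maximal connected components (26-connectivity
#' by default, so voxels touching even at a corner join; no minimum
#' cluster size).
#'
#' @param p_maps a [permutation_p()] result (or a [vlsm_run()] result,
#'   whose adjusted p's are used).
#' @param alpha significance threshold in (0, 1).
#' @param connectivity 6, 18 or 26.
#' @return An object of class `cluster_set`: per lesion type a list of
#'   clusters, each with `voxels` (flat indices), `n_voxels`, `ml`,
#'   `peak` (flat index of max `|beta|`, or max `|t|` for VLSM input) and
#'   `centroid` (grid coordinates).
#' @export
threshold_and_cluster <- function(p_maps, alpha = 0.05, connectivity = 26L) {
  if (alpha <= 0 || alpha >= 1) stop_mlsmap("alpha must be in (0, 1)")
  if (inherits(p_maps, "vlsm_result")) {
    tab <- data.frame(lesion_type = p_maps$lesion_type,
                      voxel_index = p_maps$voxel_index,
                      stat = p_maps$t, p = p_maps$p_adj)
    grid <- p_maps$grid
  } else {
    tab <- data.frame(p_maps$columns, stat = p_maps$beta, p = p_maps$p)
    grid <- p_maps$grid
  }
  vox_ml <- voxel_volume_ml(grid)
  out <- list()
  for (lt in unique(tab$lesion_type)) {
    sub <- tab[tab$lesion_type == lt & !is.na(tab$p) & tab$p < alpha, ]
    comps <- connected_components(sub$voxel_index, grid, connectivity)
    out[[lt]] <- lapply(comps, function(vx) {
      st <- sub$stat[match(vx, sub$voxel_index)]
      coords <- flat_to_coord(vx, grid)
      list(voxels = vx, n_voxels = length(vx), ml = length(vx) * vox_ml,
           peak = vx[which.max(abs(st))],
           centroid = colMeans(coords))
    })
  }
  structure(list(clusters = out, alpha = alpha, connectivity = connectivity,
                 grid = grid), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  for (lt in names(x$clusters)) {
    cl <- x$clusters[[lt]]
    cat(sprintf("  %s: %d cluster(s), %d voxel(s) total\n", lt, length(cl),
                sum(vapply(cl, `[[`, 0L, "n_voxels"))))
  }
  invisible(x)
}

cluster_union <- function(cluster_set, lesion_type) {
  cl <- cluster_set$clusters[[lesion_type]]
  if (is.null(cl) || !length(cl)) return(integer())
  sort(unique(unlist(lapply(cl, `[[`, "voxels"))))
}

#' Tabulate significant-cluster TSV
#'
#' @param cluster_set a [threshold_and_cluster()] result.
#' @return Data frame with one row per cluster: lesion type, id, size in
#'   voxels and ml, peak voxel grid coordinates.
#' @export
cluster_table <- function(cluster_set) {
  rows <- list()
  for (lt in names(cluster_set$clusters)) {
    cl <- cluster_set$clusters[[lt]]
    for (i in seq_along(cl)) {
      pk <- flat_to_coord(cl[[i]]$peak, cluster_set$grid)
      rows[[length(rows) + 1L]] <-
        data.frame(lesion_type = lt, cluster_id = i,
                   n_voxels = cl[[i]]$n_voxels, ml = cl[[i]]$ml,
                   peak_i = pk[1], peak_j = pk[2], peak_k = pk[3])
    }
  }
  if (!length(rows))
    return(data.frame(lesion_type = character(), cluster_id = integer(),
                      n_voxels = integer(), ml = numeric(),
                      peak_i = integer(), peak_j = integer(),
                      peak_k = integer()))
  do.call(rbind, rows)
}

#' Atlas overlap report for significant clusters
#'
#' For every atlas label and lesion type: region size in voxels, voxels
#' tested (retained in the design), significant voxels (count and % of
#' region size), and the number of subjects whose lesion overlaps the
#' region by at least one voxel. Significant voxels outside every label
#' are reported in an `"unlabeled"` row, so per-label counts plus the
#' unlabeled row always partition the total.
#'
#' @param cluster_set a [threshold_and_cluster()] result.
#' @param atlas integer 3-D array of label codes on the same grid.
#' @param labels data frame with columns `code`, `name` (optional; codes
#'   are used as names when absent).
#' @param tensors named list of (unfiltered) [lesion_tensor()]s keyed by
#'   lesion type, for the subject-overlap column.
#' @param tested named list of flat voxel index vectors per lesion type
#'   (the voxels retained in the analysis design); optional.
#' @return Data frame, one row per (lesion type, label).
#' @export
atlas_overlap_report <- function(cluster_set, atlas, labels = NULL,
                                 tensors = NULL, tested = NULL) {
  grid <- cluster_set$grid
  if (!identical(dim(atlas), as.integer(grid$shape)))
    stop_mlsmap("atlas grid does not match the analysis grid")
  atlas <- as.integer(atlas)
  codes <- sort(unique(atlas[atlas != 0L]))
  name_of <- function(code) {
    if (!is.null(labels)) {
      i <- match(code, labels$code)
      if (!is.na(i)) return(as.character(labels$name[i]))
    }
    sprintf("label-%d", code)
  }
  rows <- list()
  for (lt in names(cluster_set$clusters)) {
    sig <- cluster_union(cluster_set, lt)
    sig_codes <- atlas[sig]
    tst <- tested[[lt]] %||% integer()
    for (code in codes) {
      region <- sum(atlas == code)
      n_sig <- sum(sig_codes == code)
      n_subj <- NA_integer_
      if (!is.null(tensors[[lt]])) {
        tn <- tensors[[lt]]
        inregion <- which(atlas[tn$voxel_index] == code)
        n_subj <- if (length(inregion))
          sum(rowSums(tn$data[, inregion, drop = FALSE]) > 0L) else 0L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        lesion_type = lt, region = name_of(code), code = code,
        n_subjects_with_lesion = n_subj, region_size_voxels = region,
        tested_voxels = if (length(tst)) sum(atlas[tst] == code) else NA_integer_,
        significant_voxels = n_sig,
        significant_pct = round(100 * n_sig / region, 2))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      lesion_type = lt, region = "unlabeled", code = 0L,
      n_subjects_with_lesion = NA_integer_,
      region_size_voxels = sum(atlas == 0L),
      tested_voxels = if (length(tst)) sum(atlas[tst] == 0L) else NA_integer_,
      significant_voxels = sum(sig_codes == 0L),
      significant_pct = NA_real_)
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
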