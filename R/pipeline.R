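#' Load a run configuration
#'
#' Reads a YAML run config (or accepts a list) and fills defaults. The
#' analysis block understands: `method` (`vlsm`, `svr-lsm`, `svr-mlsm`),
#' `score`, `covariates`, `volume_control`, `kernel`, `k`, `P`, `alpha`,
#' `connectivity`, `seed`, `c_grid`, `gamma_grid`, `epsilon`,
#' `score_direction`.
#'
#' @param config path to a YAML file or a list.
#' @return Normalized config list of class `run_config`.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(method = "svr-mlsm", score = "score",
                   covariates = c("age", "sex", "education"),
                   volume_control = "none", kernel = "linear",
                   k = 3L, P = 1000L, alpha = 0.05, connectivity = 26L,
                   seed = 1L, c_grid = NULL, gamma_grid = NULL,
                   epsilon = 0.1, score_direction = "higher_is_better")
  analysis <- utils::modifyList(defaults, config$analysis %||% list())
  structure(list(paths = config$paths %||% list(), analysis = analysis),
            class = "run_config")
}

write_map_nifti <- function(values, voxel_index, grid, path,
                            background = NA_real_) {
  vol <- map_to_volume(values, voxel_index, grid, background)
  write_nifti(vol, path, grid$voxel_size, grid$affine, "float32")
}

#' Run a full lesion-symptom mapping analysis
#'
#' Orchestrates load -> filter -> score preparation -> design -> fit/train
#' -> permutation inference -> clustering -> reports, writing intermediate
#' artifacts under `out_dir/{maps,clusters,reports,logs}`. All randomness
#' derives from the single configured seed via named substreams, so
#' re-running an identical config reproduces every output.
#'
#' @param config a [load_run_config()] result, YAML path, or list.
#' @param cohort optionally a preloaded `list(tensors=, table=)` (e.g. a
#'   [sample_cohort()] output reshaped by [cohort_inputs()]); otherwise
#'   the config's `paths$manifest` and `paths$table` are loaded.
#' @param out_dir output directory (overrides `paths$out_dir`).
#' @return Invisibly, a list with the stage artifacts (`design`, `pmaps`
#'   or `vlsm`, `clusters`, `svoi`, `report_paths`).
#' @export
run_full <- function(config, cohort = NULL, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else
    load_run_config(config)
  a <- cfg$analysis
  out_dir <- out_dir %||% cfg$paths$out_dir %||%
    stop_mlsmap("no output directory configured")
  for (d in c("", "maps", "clusters", "reports", "logs"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "logs", "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = logf, append = TRUE)
  cat(sprintf("mlsmap %s run, seed %d\n",
              as.character(utils::packageVersion("mlsmap")), a$seed),
      file = logf)
  yaml::write_yaml(list(paths = cfg$paths, analysis = a),
                   file.path(out_dir, "resolved_config.yaml"))
  if (is.null(cohort)) {
    if (is.null(cfg$paths$manifest) || is.null(cfg$paths$table))
      stop_mlsmap("stage load: config needs paths$manifest and paths$table")
    cohort <- load_cohort(cfg$paths$manifest, cfg$paths$table)
  }
  tensors <- cohort$tensors
  table <- cohort$table
  logline("stage load: %d subjects, lesion types: %s", nrow(table),
          paste(names(tensors), collapse = ", "))

  volume_columns <- paste0(tolower(names(tensors)), "_volume_ml")
  volume_columns <- intersect(volume_columns, names(table))
  prepared <- prepare_scores(table, score_column = a$score,
                             covariates = a$covariates,
                             volume_control = a$volume_control,
                             volume_columns =
                               if (a$method == "svr-mlsm") volume_columns
                               else volume_columns[1],
                             score_direction = a$score_direction)
  artifacts <- list(prepared = prepared)
  grid <- tensors[[1]]$grid

  if (a$method == "vlsm") {
    t1 <- apply_min_subject_filter(tensors[[1]], a$k)
    vr <- vlsm_run(prepared, t1, P = a$P,
                   seed = substream_seed(a$seed, "permutations"))
    write_map_nifti(vr$t, vr$voxel_index, grid,
                    file.path(out_dir, "maps", "t_map.nii.gz"))
    write_map_nifti(vr$p_adj, vr$voxel_index, grid,
                    file.path(out_dir, "maps", "p_adj_map.nii.gz"))
    report <- data.frame(voxel_index = vr$voxel_index, t = vr$t,
                         p_adj = vr$p_adj)
    write.table(report, file.path(out_dir, "reports", "vlsm_voxels.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    clusters <- threshold_and_cluster(vr, a$alpha, a$connectivity)
    artifacts$vlsm <- vr
    logline("stage vlsm: %d voxels tested, %d significant at alpha=%g",
            sum(vr$testable), sum(vr$p_adj < a$alpha, na.rm = TRUE), a$alpha)
  } else {
    if (a$method == "svr-mlsm") {
      if (a$kernel != "linear")
        stop_mlsmap("stage design: only the linear kernel is supported for the multi-lesion model")
      if (length(tensors) < 2L)
        stop_mlsmap("stage design: svr-mlsm needs two lesion types")
      design <- build_multilesion_design(tensors[[1]], tensors[[2]], a$k,
                                         a$volume_control)
    } else {
      design <- build_single_design(apply_min_subject_filter(tensors[[1]],
                                                             a$k),
                                    1L, a$volume_control)
    }
    report <- loocv_train(design, prepared$deficit, kernel = a$kernel,
                          C_grid = a$c_grid, gamma_grid = a$gamma_grid,
                          epsilon = a$epsilon)
    jsonlite::write_json(list(kernel = report$kernel, grid = report$grid,
                              best = report$best),
                         file.path(out_dir, "reports",
                                   "training_report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    logline("stage train: best C=%g accuracy=%.4f", report$best$C,
            report$best$accuracy)
    pmaps <- permutation_p(design, prepared$deficit, C = report$best$C,
                           gamma = if (a$kernel == "rbf")
                             report$best$gamma else NULL,
                           kernel = a$kernel, epsilon = a$epsilon,
                           P = a$P,
                           seed = substream_seed(a$seed, "permutations"))
    for (lt in pmaps$blocks) {
      sel <- pmaps$columns$lesion_type == lt
      if (!any(sel)) next
      write_map_nifti(pmaps$beta[sel], pmaps$columns$voxel_index[sel], grid,
                      file.path(out_dir, "maps",
                                sprintf("beta_%s.nii.gz", tolower(lt))))
      write_map_nifti(pmaps$p[sel], pmaps$columns$voxel_index[sel], grid,
                      file.path(out_dir, "maps",
                                sprintf("p_%s.nii.gz", tolower(lt))))
      write_map_nifti(-log10(pmaps$p[sel]), pmaps$columns$voxel_index[sel],
                      grid, file.path(out_dir, "maps",
                                      sprintf("neglog10p_%s.nii.gz",
                                              tolower(lt))))
    }
    clusters <- threshold_and_cluster(pmaps, a$alpha, a$connectivity)
    artifacts$design <- design
    artifacts$training <- report
    artifacts$pmaps <- pmaps
  }
  ct <- cluster_table(clusters)
  write.table(ct, file.path(out_dir, "clusters", "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (lt in names(clusters$clusters)) {
    un <- cluster_union(clusters, lt)
    vol <- array(0L, grid$shape); vol[un] <- 1L
    write_nifti(vol, file.path(out_dir, "clusters",
                               sprintf("sig_mask_%s.nii.gz", tolower(lt))),
                grid$voxel_size, grid$affine, "uint8")
  }
  logline("stage cluster: %s",
          paste(sprintf("%s=%d", names(clusters$clusters),
                        vapply(clusters$clusters, length, 0L)),
                collapse = ", "))
  artifacts$clusters <- clusters

  if (!is.null(cfg$paths$atlas)) {
    if (!file.exists(cfg$paths$atlas))
      stop_mlsmap("stage report: atlas file not found: %s", cfg$paths$atlas)
    atl <- read_nifti(cfg$paths$atlas)
    labels <- NULL
    if (!is.null(cfg$paths$atlas_labels))
      labels <- read.delim(cfg$paths$atlas_labels, sep = "\t",
                           stringsAsFactors = FALSE)
    tested <- if (!is.null(artifacts$pmaps))
      split(artifacts$pmaps$columns$voxel_index,
            artifacts$pmaps$columns$lesion_type) else
      setNames(list(artifacts$vlsm$voxel_index), names(tensors)[1])
    rep_df <- atlas_overlap_report(clusters, array(as.integer(atl$img),
                                                   dim = grid$shape),
                                   labels, tensors, tested)
    write.table(rep_df, file.path(out_dir, "reports", "atlas_overlap.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts$atlas_report <- rep_df
  }
  manifest <- list(method = a$method, seed = a$seed,
                   outputs = list.files(out_dir, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(artifacts)
}

#' Reshape a simulated cohort into pipeline inputs
#'
#' @param cohort a [sample_cohort()] result.
#' @return `list(tensors=, table=)` as expected by [run_full()].
#' @export
cohort_inputs <- function(cohort) {
  list(tensors = list(AIL = cohort$ail, WMH = cohort$wmh),
       table = cohort$table)
}
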