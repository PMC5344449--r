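#' Null calibration of the cluster procedure (printed-table twin)
#'
#' Reproduces the Monte Carlo calibration grid: subjects' channel contrasts
#' are drawn as iid standard-normal noise at the montage's channel
#' coordinates, interpolated to the voxel grid, and passed through the
#' sign-flip permutation procedure. The resulting table of familywise
#' false-positive proportions over (cluster size, voxel p threshold) cells is
#' what calibrates the corrected threshold (cluster extent 70 at p < 0.001
#' for a corrected rate near 0.05).
#'
#' @param n_subjects number of null subjects (the calibration used 30 data
#'   sets).
#' @param layout probe montage providing channel coordinates.
#' @param n_perm sign-flip permutations.
#' @param seed RNG seed (drives both the null draws and the flips).
#' @param voxel_size,mask_distance,kernel_fwhm grid/interpolation parameters
#'   (mm).
#' @param cluster_sizes,p_thresholds,connectivity calibration grid cells.
#' @return an `fpr_table` (see [signflip_mc()]) with the grid attached.
#' @export
cluster_fpr_calibration <- function(n_subjects = 30,
                                    layout = default_montage(),
                                    n_perm = 1000, seed = 1,
                                    voxel_size = 4, mask_distance = 20,
                                    kernel_fwhm = 15,
                                    cluster_sizes = c(10, 30, 50, 70),
                                    p_thresholds = c(0.05, 0.01, 0.001,
                                                     0.0001),
                                    connectivity = 18) {
  coords <- channels_from_optodes(layout)
  grid <- channel_support_grid(coords, voxel_size, mask_distance)
  contrasts <- with_seed(seed,
    matrix(stats::rnorm(n_subjects * nrow(coords)), n_subjects))
  volumes <- channels_to_volume(contrasts, coords, grid, kernel_fwhm,
                                support_distance = mask_distance)
  out <- signflip_mc(volumes, grid, n_perm = n_perm,
                     cluster_sizes = cluster_sizes,
                     p_thresholds = p_thresholds,
                     connectivity = connectivity, seed = seed + 1L)
  out$grid <- grid
  out
}

#' Group analysis of subject channel contrasts
#'
#' Carries a subjects x channels contrast matrix through the full group
#' stage: channel-to-voxel interpolation, one-sample group t-map, cluster
#' extraction at the corrected threshold, channel-wise t statistics, and the
#' dual voxel/channel significance criterion.
#'
#' @param contrasts n_subjects x n_channels matrix (`NA` = unusable channel;
#'   voxel interpolation uses each subject's usable channels only when any
#'   are missing).
#' @param coords n_channels x 3 channel MNI coordinates.
#' @param grid optional `volume_grid`; built from the coordinates by default.
#' @param kernel_fwhm,mask_distance interpolation parameters (mm).
#' @param p_thresh,cluster_threshold,connectivity cluster criterion.
#' @param channel_alpha channel-wise significance level.
#' @param radius channel/cluster correspondence radius (mm).
#' @return list `grid`, `tmap`, `clusters`, `channel_stats`, `findings`.
#' @export
run_group_analysis <- function(contrasts, coords, grid = NULL,
                               kernel_fwhm = 15, mask_distance = 20,
                               p_thresh = 0.001, cluster_threshold = 70,
                               connectivity = 18, channel_alpha = 0.05,
                               radius = 20) {
  contrasts <- as.matrix(contrasts)
  if (is.null(grid))
    grid <- channel_support_grid(coords, mask_distance = mask_distance)
  if (anyNA(contrasts)) {
    volumes <- t(vapply(seq_len(nrow(contrasts)), function(s) {
      ok <- is.finite(contrasts[s, ])
      channels_to_volume(contrasts[s, ok], coords[ok, , drop = FALSE], grid,
                         kernel_fwhm, support_distance = mask_distance)
    }, numeric(length(grid$index))))
  } else {
    volumes <- channels_to_volume(contrasts, coords, grid, kernel_fwhm,
                                  support_distance = mask_distance)
  }
  adjacency <- grid_adjacency(grid, connectivity)
  tmap <- group_t_map(volumes, grid)
  clusters <- threshold_and_cluster(tmap, grid, p_thresh, connectivity,
                                    cluster_threshold, adjacency)
  channel_stats <- channelwise_t(contrasts, alpha = channel_alpha)
  findings <- dual_criterion(clusters, channel_stats, coords, tmap, grid,
                             p_thresh, connectivity, radius, adjacency)
  list(grid = grid, tmap = tmap, clusters = clusters,
       channel_stats = channel_stats, findings = findings,
       volumes = volumes)
}

#' Simulate and analyze a whole study end to end
#'
#' For each simulated subject: forward optical model, preprocessing
#' (dead-channel QC, MBLL, detrend, low-pass, PCA spatial filter,
#' downsample), first-level GLM and contrast; then median-coordinate
#' registration, the group voxel/channel analysis, and the behavioral
#' statistics.
#'
#' @param config a `sim_config`.
#' @param task task to analyze.
#' @param contrast_name `"I>C"` or `"G>C"` preset, or a named weight vector.
#' @param preprocess a `preprocess_config`.
#' @param layout probe montage.
#' @param jitter_sd per-subject optode placement jitter (mm, SD) applied
#'   before median registration.
#' @param ... further arguments to [run_group_analysis()].
#' @return list `group` (see [run_group_analysis()]), `behavior`,
#'   `subject_contrasts`, `median_coords`, `qc` (per-subject dead-channel
#'   masks).
#' @export
simulate_and_analyze <- function(config, task = config$tasks[1],
                                 contrast_name = "I>C",
                                 preprocess = preprocess_config(),
                                 layout = default_montage(), jitter_sd = 2,
                                 ...) {
  coords0 <- channels_from_optodes(layout)
  n_sub <- config$n_subjects
  contrasts <- matrix(NA_real_, n_sub, nrow(coords0))
  coords_list <- vector("list", n_sub)
  qc <- vector("list", n_sub)
  trials <- vector("list", n_sub)
  for (s in seq_len(n_sub)) {
    sub <- simulate_subject(config, subject = s, task = task)
    prep <- preprocess_subject(sub$od, preprocess)
    des <- build_design(sub$schedule, prep$frame_times,
                        trial_duration = config$trial_duration)
    good <- which(!prep$dead$exclude)
    fit <- fit_glm(prep$series[good, , drop = FALSE], des)
    con <- contrast(fit, contrast_name)
    contrasts[s, good] <- con$value
    coords_list[[s]] <- coords0 + with_seed(sub$seed + 3L,
      matrix(stats::rnorm(length(coords0), 0, jitter_sd), nrow(coords0)))
    qc[[s]] <- prep$dead
    trials[[s]] <- sub$behavior
  }
  reg <- register_to_median(coords_list,
                            lapply(seq_len(n_sub), function(s) contrasts[s, ]))
  group <- run_group_analysis(reg$values, reg$median_coords, ...)
  behavior <- analyze_behavior(do.call(rbind, trials))
  list(group = group, behavior = behavior, subject_contrasts = reg$values,
       median_coords = reg$median_coords, qc = qc)
}

## default pipeline configuration as a plain list (YAML-serializable)
default_pipeline_config <- function() {
  list(simulate = list(n_subjects = 31, seed = 1, task = "gesture",
                       noise_sd = 1,
                       active_channels = NULL),
       preprocess = list(dead_rms_factor = 10, lowpass_cutoff = 0.1,
                         wavelet = "d4", pca_mode = "remove_top_k",
                         pca_k = 1, downsample_factor = 10),
       glm = list(contrast = "I>C", trial_duration = 1.5),
       group = list(voxel_size = 4, mask_distance = 20, kernel_fwhm = 15,
                    p_thresh = 0.001, cluster_threshold = 70,
                    connectivity = 18, channel_alpha = 0.05, radius = 20),
       calibration = list(run = FALSE, n_perm = 1000))
}

pipeline_config_schema <- function() {
  lapply(default_pipeline_config(), names)
}

validate_pipeline_config <- function(config) {
  defaults <- default_pipeline_config()
  bad_top <- setdiff(names(config), names(defaults))
  if (length(bad_top) > 0)
    stop("unknown config section: ", paste(bad_top, collapse = ", "))
  for (sec in names(config)) {
    bad <- setdiff(names(config[[sec]]), names(defaults[[sec]]))
    if (length(bad) > 0)
      stop(sprintf("unknown config key in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
    defaults[[sec]][names(config[[sec]])] <- config[[sec]]
  }
  defaults
}

#' Run the full simulate-preprocess-GLM-group-behavior pipeline
#'
#' Orchestrates an end-to-end synthetic run from a YAML configuration (or an
#' equivalent nested list) and writes all stage outputs — cluster and channel
#' tables, findings, behavioral statistics, QC, and a provenance manifest —
#' to an output directory.
#'
#' @param config path to a YAML file or a nested configuration list with
#'   sections `simulate`, `preprocess`, `glm`, `group`, `calibration`;
#'   unknown keys are rejected by name.
#' @param out_dir output directory (created if needed); `NULL` skips writing.
#' @return (invisibly) the result list of [simulate_and_analyze()] plus
#'   `manifest` and, if requested, `calibration`.
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)

  ac <- cfg$simulate$active_channels
  if (!is.null(ac)) ac <- as.data.frame(ac)
  sim <- sim_config(n_subjects = cfg$simulate$n_subjects,
                    seed = cfg$simulate$seed,
                    noise_sd = cfg$simulate$noise_sd,
                    active_channels = ac,
                    trial_duration = cfg$glm$trial_duration)
  prep <- preprocess_config(
    dead_rms_factor = cfg$preprocess$dead_rms_factor,
    lowpass_cutoff = cfg$preprocess$lowpass_cutoff,
    wavelet = cfg$preprocess$wavelet,
    pca_mode = cfg$preprocess$pca_mode, pca_k = cfg$preprocess$pca_k,
    downsample_factor = cfg$preprocess$downsample_factor)

  res <- simulate_and_analyze(
    sim, task = cfg$simulate$task, contrast_name = cfg$glm$contrast,
    preprocess = prep,
    kernel_fwhm = cfg$group$kernel_fwhm,
    mask_distance = cfg$group$mask_distance,
    p_thresh = cfg$group$p_thresh,
    cluster_threshold = cfg$group$cluster_threshold,
    connectivity = cfg$group$connectivity,
    channel_alpha = cfg$group$channel_alpha, radius = cfg$group$radius)

  if (isTRUE(cfg$calibration$run))
    res$calibration <- cluster_fpr_calibration(
      n_subjects = cfg$simulate$n_subjects, n_perm = cfg$calibration$n_perm,
      seed = cfg$simulate$seed)

  res$manifest <- run_manifest(cfg)
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

#' Provenance manifest for a pipeline run
#'
#' @param cfg validated configuration list.
#' @return list with the configuration, its md5 hash (identical
#'   configuration and seed give an identical hash), package version and
#'   timestamp.
#' @export
run_manifest <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(cfg), tf)
  list(config = cfg, config_hash = unname(tools::md5sum(tf)),
       package_version = as.character(utils::packageVersion("nirstroop")),
       timestamp = format(Sys.time(), tz = "UTC"))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  write_tsv(res$group$clusters, "clusters.tsv")
  write_tsv(res$group$channel_stats, "channel_stats.tsv")
  write_tsv(res$group$findings, "findings.tsv")
  write_tsv(res$behavior$tests, "behavior_tests.tsv")
  write_tsv(res$behavior$rt$summary, "rt_summary.tsv")
  jsonlite::write_json(
    list(accuracy = as.list(res$behavior$accuracy)),
    file.path(out_dir, "accuracy.json"), auto_unbox = TRUE, digits = NA)
  manifest <- res$manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(res$calibration))
    jsonlite::write_json(
      list(fpr = as.data.frame(res$calibration$fpr),
           n_perm = res$calibration$n_perm, seed = res$calibration$seed),
      file.path(out_dir, "calibration.json"), digits = NA)
  invisible(out_dir)
}
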