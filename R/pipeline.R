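# The four pipeline stages decouple via on-disk artifacts — volumes, maps,
# the cohort table — so the expensive entropy maps are computed once and the
# statistics can be iterated cheaply:
#   run_simulate() -> run_map() -> run_aggregate() -> run_stats()
# A thin command-line front end over these functions ships at inst/cli/.

config_hash <- function(obj) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(f))
}

file_inventory <- function(paths) {
  data.frame(file = basename(paths),
             md5 = unname(tools::md5sum(paths)),
             bytes = file.size(paths),
             stringsAsFactors = FALSE)
}

write_report <- function(out_dir, stage, config, seed, timings, counts,
                         files) {
  report <- list(stage = stage,
                 seed = seed,
                 config_hash = config_hash(config),
                 config = config,
                 timing_sec = timings,
                 counts = counts,
                 inventory = file_inventory(files))
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "columns", pretty = TRUE)
  report
}

#' Simulate a cohort to disk
#'
#' Writes one NIfTI per scan, the block atlas with its sidecar, the ground
#' truth (JSON), and — last, so that a partially written cohort is never
#' mistaken for a complete one — the scan manifest CSV. A run report with
#' checksums of every emitted file closes the stage.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if missing).
#' @param tr Repetition time in seconds for the NIfTI headers.
#' @return The run report, invisibly.
#' @export
run_simulate <- function(config, out_dir, tr = 0.72) {
  t0 <- proc.time()[["elapsed"]]
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  cohort <- simulate_cohort(config)
  files <- character(0)
  manifest <- NULL
  for (sc in cohort$scans) {
    fn <- sprintf("bold_%s_%s_%d.nii.gz", sc$meta$subject_id,
                  sc$meta$condition, sc$meta$scan_index)
    write_bold_nifti(sc$bold, file.path(out_dir, fn), tr = tr)
    files <- c(files, file.path(out_dir, fn))
    manifest <- rbind(manifest, cbind(sc$meta, file = fn))
  }
  atlas_path <- file.path(out_dir, "atlas.nii.gz")
  write_atlas_nifti(cohort$atlas, atlas_path)
  files <- c(files, atlas_path, paste0(atlas_path, ".rois.json"))
  truth_path <- file.path(out_dir, "ground_truth.json")
  jsonlite::write_json(list(seed = cohort$truth$seed,
                            n_clipped = cohort$truth$n_clipped,
                            truth = cohort$truth$truth),
                       truth_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  files <- c(files, truth_path)
  manifest_path <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, manifest_path, row.names = FALSE)
  files <- c(files, manifest_path)
  cfg <- unclass(config)
  report <- write_report(out_dir, "simulate", cfg, config$seed,
                         c(total = proc.time()[["elapsed"]] - t0),
                         list(scans = nrow(manifest),
                              clipped_phi = cohort$truth$n_clipped),
                         files)
  message("simulate: ", nrow(manifest), " scans written to ", out_dir)
  invisible(report)
}

#' Compute entropy maps for every scan in a manifest
#'
#' Reads each volume named by the manifest, truncates rest scans longer than
#' `truncate_to` down to that length (so entropy is compared at the task
#' series length), computes the voxelwise sample entropy map, and writes it
#' with its undefined-voxel sidecars. Per-scan failures are logged and
#' summarised, never silently dropped; any failure makes the stage error
#' after the loop so a shell caller exits nonzero. Existing outputs are
#' refused unless `force = TRUE`, preserving the provenance of prior runs.
#'
#' @param manifest_path Cohort manifest CSV ([run_simulate()] format).
#' @param atlas_path Atlas NIfTI; only its grid is needed at this stage, the
#'   in-mask region is labels > 0 (pass `mask_background = TRUE` to map
#'   background voxels too).
#' @param params [sampen_params()].
#' @param truncate_to Target series length, or `NULL` for no truncation.
#' @param out_dir Output directory for the maps.
#' @param force Overwrite existing outputs.
#' @param mask_background Include background (label 0) voxels.
#' @return The run report, invisibly (also written as JSON).
#' @export
run_map <- function(manifest_path, atlas_path, params = sampen_params(),
                    truncate_to = NULL, out_dir, force = FALSE,
                    mask_background = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE,
                              colClasses = c(subject_id = "character"))
  atlas <- read_atlas_nifti(atlas_path)
  mask <- if (mask_background) NULL else atlas$labels > 0L
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  files <- character(0)
  failures <- character(0)
  undef <- c(`short-series` = 0L, `zero-variance` = 0L, `zero-matches` = 0L)
  map_manifest <- manifest
  map_manifest$map_file <- NA_character_
  for (i in seq_len(nrow(manifest))) {
    fn <- sprintf("entropy_%s_%s_%d.nii.gz", manifest$subject_id[i],
                  manifest$condition[i], manifest$scan_index[i])
    out_path <- file.path(out_dir, fn)
    if (file.exists(out_path) && !force) {
      stop("output ", out_path, " exists; rerun with force = TRUE to ",
           "overwrite", call. = FALSE)
    }
    res <- tryCatch({
      vol <- read_bold_nifti(file.path(dirname(manifest_path),
                                       manifest$file[i]))
      if (!is.null(truncate_to) && dim(vol)[4] > truncate_to)
        vol <- truncate_bold(vol, truncate_to)
      map <- sample_entropy_map(vol, mask = mask, params = params)
      write_entropy_nifti(map, out_path)
      map
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", manifest$file[i],
                                      conditionMessage(res)))
      message("map: FAILED ", manifest$file[i], ": ", conditionMessage(res))
      next
    }
    undef <- undef + res$undefined_counts
    stem <- sub("\\.nii\\.gz$", "", out_path)
    files <- c(files, out_path, paste0(stem, "_reason.nii.gz"),
               paste0(stem, "_undefined.json"))
    map_manifest$map_file[i] <- fn
    message("map: ", fn, " (undefined voxels: ",
            sum(res$undefined_counts), ")")
  }
  mm_path <- file.path(out_dir, "maps_manifest.csv")
  utils::write.csv(map_manifest, mm_path, row.names = FALSE)
  files <- c(files, mm_path)
  cfg <- list(manifest = manifest_path, atlas = atlas_path,
              params = unclass(params), truncate_to = truncate_to)
  report <- write_report(out_dir, "map", cfg, NA,
                         c(total = proc.time()[["elapsed"]] - t0),
                         list(scans_processed = sum(!is.na(map_manifest$map_file)),
                              scans_failed = length(failures),
                              failures = failures,
                              undefined_voxels = as.list(undef)),
                         files)
  if (length(failures))
    stop("map: ", length(failures), " scan(s) failed (see run_report.json)",
         call. = FALSE)
  invisible(report)
}

#' Aggregate entropy maps into the cohort table
#'
#' @param maps_dir Directory holding the maps and `maps_manifest.csv` from
#'   [run_map()].
#' @param atlas_path Atlas NIfTI (+ sidecar).
#' @param out_csv Output CSV for the scans-by-regions table.
#' @return The `roi_table`, invisibly (written to `out_csv`).
#' @export
run_aggregate <- function(maps_dir, atlas_path, out_csv) {
  manifest <- utils::read.csv(file.path(maps_dir, "maps_manifest.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(subject_id = "character"))
  manifest <- manifest[!is.na(manifest$map_file), , drop = FALSE]
  atlas <- read_atlas_nifti(atlas_path)
  maps <- lapply(file.path(maps_dir, manifest$map_file), read_entropy_nifti)
  meta <- manifest[, intersect(c("subject_id", "condition", "scan_index",
                                 "phase_encode"), names(manifest))]
  table <- build_cohort_table(maps, meta, atlas)
  write_roi_table(table, out_csv)
  message("aggregate: ", nrow(table$mean), " scans x ", ncol(table$mean),
          " regions -> ", out_csv)
  invisible(table)
}

#' Group-level statistics report bundle
#'
#' Emits the study's tabular outputs from a cohort table, all
#' randomness-free given the input:
#' \describe{
#'   \item{table1_class_condition.csv}{mean/SD of the cortical and
#'     subcortical per-scan aggregates, by condition.}
#'   \item{table2_network_condition.csv}{per-network rest/task mean, SD, and
#'     the rest-vs-task paired t with raw and Bonferroni-adjusted p (family
#'     = number of networks).}
#'   \item{table3_anova_class.csv}{two-factor ANOVA: condition x class on
#'     the class aggregates.}
#'   \item{table4_anova_network.csv}{two-factor ANOVA: condition x network
#'     on the per-network means.}
#'   \item{table5_consistency.csv}{scan-1 vs scan-2 per-network ICC(3,1),
#'     Pearson r, and two-tailed paired p, for rest and task.}
#'   \item{table6_per_scan_network.csv}{per-network mean/SD split by
#'     condition and scan index.}
#'   \item{cor_(rest|task)_networks.csv, cor_(rest|task)_all.csv}{between-
#'     region correlation matrices across the condition's scans.}
#' }
#'
#' @param table_csv Cohort table CSV from [run_aggregate()], or a
#'   `roi_table` object.
#' @param out_dir Output directory.
#' @param network_class Region class treated as "the networks" in the
#'   network-level tables (the canonical seven networks are cortical).
#' @param whole_brain_family Bonferroni family size for the class-level
#'   rest-vs-task test (default 1: a single planned comparison).
#' @return List of the computed tables, invisibly; CSVs + run report on
#'   disk.
#' @export
run_stats <- function(table_csv, out_dir, network_class = "cortical",
                      whole_brain_family = 1L) {
  t0 <- proc.time()[["elapsed"]]
  table <- if (inherits(table_csv, "roi_table")) table_csv
           else read_roi_table(table_csv)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sc <- table$scans
  is_rest <- sc$condition == "rest"
  nets <- table$rois$name[table$rois$class == network_class]
  files <- character(0)
  emit <- function(df, fn, row_names = FALSE) {
    path <- file.path(out_dir, fn)
    utils::write.csv(format(df, digits = 17, scientific = NA, trim = TRUE),
                     path, row.names = row_names, quote = FALSE)
    files <<- c(files, path)
    path
  }
  out <- list()

  # table 1: class x condition summary of the per-scan class aggregates
  t1 <- NULL
  for (cls in unique(table$rois$class)) {
    agg <- class_aggregate(table, cls)
    for (cond in c("rest", "task")) {
      v <- agg[sc$condition == cond]
      t1 <- rbind(t1, data.frame(class = cls, condition = cond,
                                 mean = mean(v), sd = stats::sd(v),
                                 n_scans = length(v)))
    }
  }
  out$table1 <- t1
  emit(t1, "table1_class_condition.csv")

  # pairing for rest-vs-task: by (subject, scan_index)
  key <- function(rows) order(sc$subject_id[rows], sc$scan_index[rows])
  rest_rows <- which(is_rest)[key(which(is_rest))]
  task_rows <- which(!is_rest)[key(which(!is_rest))]

  # table 2: per-network condition means + paired t (family = #networks)
  t2 <- NULL
  for (nm in nets) {
    rest_v <- table$mean[rest_rows, nm]
    task_v <- table$mean[task_rows, nm]
    tt <- paired_ttest(rest_v, task_v, n_tests = length(nets))
    t2 <- rbind(t2, data.frame(
      network = nm,
      rest_mean = mean(rest_v), rest_sd = stats::sd(rest_v),
      task_mean = mean(task_v), task_sd = stats::sd(task_v),
      mean_diff = tt$mean_diff, t_stat = tt$t_stat, df = tt$df,
      p_raw = tt$p_raw, p_bonferroni = tt$p_adjusted,
      bonferroni_family = length(nets)))
  }
  out$table2 <- t2
  emit(t2, "table2_network_condition.csv")

  # whole-brain class contrast (paired t across scans on class aggregates)
  classes <- unique(table$rois$class)
  if (all(c("cortical", "subcortical") %in% classes)) {
    ctx <- class_aggregate(table, "cortical")
    sub <- class_aggregate(table, "subcortical")
    wb <- NULL
    for (cond in c("rest", "task")) {
      r <- sc$condition == cond
      tt <- paired_ttest(sub[r], ctx[r], n_tests = whole_brain_family)
      wb <- rbind(wb, data.frame(
        condition = cond, contrast = "subcortical_minus_cortical",
        test = "paired_t_across_scans",
        mean_diff = tt$mean_diff, t_stat = tt$t_stat, df = tt$df,
        p_raw = tt$p_raw, p_bonferroni = tt$p_adjusted))
    }
    out$class_contrast <- wb
    emit(wb, "class_contrast.csv")

    # table 3: 2 x 2 ANOVA (condition x class) on class aggregates
    vals <- c(ctx, sub)
    condf <- rep(sc$condition, 2L)
    clsf <- rep(c("cortical", "subcortical"), each = nrow(table$mean))
    out$table3 <- two_factor_anova(vals, condf, clsf,
                                   names_ab = c("rest_task", "class"))
    emit(out$table3, "table3_anova_class.csv")
  }

  # table 4: 2 x K ANOVA (condition x network) on network means
  net_m <- table$mean[, nets, drop = FALSE]
  out$table4 <- two_factor_anova(as.vector(net_m),
                                 rep(sc$condition, times = length(nets)),
                                 rep(nets, each = nrow(net_m)),
                                 names_ab = c("rest_task", "network"))
  emit(out$table4, "table4_anova_network.csv")

  # table 5: scan-1 vs scan-2 consistency, per condition (needs >= 3
  # subjects for the ICC decomposition)
  t5 <- NULL
  if (length(unique(sc$subject_id)) >= 3L) for (cond in c("rest", "task")) {
    r1 <- sc$condition == cond & sc$scan_index == 1L
    r2 <- sc$condition == cond & sc$scan_index == 2L
    sub1 <- subset_roi_table(table, r1)
    sub2 <- subset_roi_table(table, r2)
    cons <- scan_consistency(sub1, sub2)
    per <- cons$per_roi[cons$per_roi$name %in% nets, ]
    per <- cbind(condition = cond, per, group_r = cons$group_r)
    t5 <- rbind(t5, per)
  }
  out$table5 <- t5
  if (!is.null(t5)) emit(t5, "table5_consistency.csv")
  else message("stats: fewer than 3 subjects, skipping consistency table")

  # table 6: per-network mean/SD by condition and scan index
  t6 <- NULL
  for (cond in c("rest", "task")) for (si in 1:2) {
    r <- sc$condition == cond & sc$scan_index == si
    for (nm in nets) {
      v <- table$mean[r, nm]
      t6 <- rbind(t6, data.frame(condition = cond, scan_index = si,
                                 network = nm, mean = mean(v),
                                 sd = stats::sd(v), n = length(v)))
    }
  }
  out$table6 <- t6
  emit(t6, "table6_per_scan_network.csv")

  # correlation matrices: networks and all regions, per condition
  for (cond in c("rest", "task")) {
    cm_net <- correlation_matrix(table, rois = nets, condition = cond)
    out[[paste0("cor_", cond, "_networks")]] <- cm_net
    write_cor_csv(cm_net, emit_path <- file.path(
      out_dir, sprintf("cor_%s_networks.csv", cond)))
    files <- c(files, emit_path)
    cm_all <- correlation_matrix(table, condition = cond)
    out[[paste0("cor_", cond, "_all")]] <- cm_all
    write_cor_csv(cm_all, p2 <- file.path(out_dir,
                                          sprintf("cor_%s_all.csv", cond)))
    files <- c(files, p2)
  }

  cfg <- list(table = if (is.character(table_csv)) table_csv else "(object)",
              network_class = network_class,
              bonferroni_families = list(networks = length(nets),
                                         whole_brain = whole_brain_family))
  write_report(out_dir, "stats", cfg, NA,
               c(total = proc.time()[["elapsed"]] - t0),
               list(scans = nrow(table$mean), networks = length(nets)),
               files)
  message("stats: report bundle written to ", out_dir)
  invisible(out)
}

# Row-subset of a roi_table (keeps region metadata).
subset_roi_table <- function(table, rows) {
  structure(list(mean = table$mean[rows, , drop = FALSE],
                 sd = table$sd[rows, , drop = FALSE],
                 n_valid = table$n_valid[rows, , drop = FALSE],
                 scans = {
                   s <- table$scans[rows, , drop = FALSE]
                   rownames(s) <- NULL
                   s
                 },
                 rois = table$rois),
            class = "roi_table")
}

write_cor_csv <- function(cm, path) {
  m <- cm$values
  df <- data.frame(roi = rownames(m),
                   format(as.data.frame(m), digits = 17, trim = TRUE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
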