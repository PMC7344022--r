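#' Parcel specification for the synthetic cohort generator
#'
#' Temporal regularity is the generator's complexity knob: each parcel's
#' voxels follow an AR(1) process whose coefficient `phi` sets how
#' predictable the signal is — higher `phi` means a more regular series and
#' therefore lower sample entropy. A nonnegative `phi_task_delta` makes the
#' task condition more regular than rest, encoding the rest > task entropy
#' direction.
#'
#' @param label Positive integer parcel label.
#' @param name Parcel name.
#' @param class `"cortical"`, `"subcortical"` or `"network"`.
#' @param phi_rest AR(1) coefficient at rest, in `[0, 0.98]`.
#' @param phi_task_delta Additive shift to `phi` under task (`>= 0`);
#'   `phi_rest + phi_task_delta` must stay in `[0, 0.98]`.
#' @param voxel_count Number of voxels in the parcel (`>= 1`).
#' @return A one-row data frame.
#' @export
parcel_spec <- function(label, name, class, phi_rest, phi_task_delta = 0,
                        voxel_count = 64L) {
  class <- match.arg(class, c("cortical", "subcortical", "network"))
  stopifnot(label >= 1, voxel_count >= 1,
            phi_rest >= 0, phi_rest <= 0.98,
            phi_task_delta >= 0, phi_rest + phi_task_delta <= 0.98)
  data.frame(label = as.integer(label), name = name, class = class,
             phi_rest = phi_rest, phi_task_delta = phi_task_delta,
             voxel_count = as.integer(voxel_count),
             stringsAsFactors = FALSE)
}

#' Default parcel set: seven cortical networks plus subcortex
#'
#' Seven parcels named after the canonical seven-network cortical
#' parcellation plus two subcortical parcels. Subcortical parcels are given
#' lower `phi` (less regular, hence higher entropy) than cortical ones, and
#' every parcel is more regular under task than at rest — the qualitative
#' pattern the group statistics are expected to recover.
#'
#' @param voxel_count Voxels per parcel.
#' @param phi_task_delta Task regularity shift applied to every parcel.
#' @return Data frame of parcel specifications.
#' @export
default_parcels <- function(voxel_count = 64L, phi_task_delta = 0.1) {
  specs <- list(
    parcel_spec(1L, "Visual",           "cortical", 0.55, phi_task_delta, voxel_count),
    parcel_spec(2L, "Somatomotor",      "cortical", 0.58, phi_task_delta, voxel_count),
    parcel_spec(3L, "DorsalAttention",  "cortical", 0.60, phi_task_delta, voxel_count),
    parcel_spec(4L, "VentralAttention", "cortical", 0.62, phi_task_delta, voxel_count),
    parcel_spec(5L, "Limbic",           "cortical", 0.68, phi_task_delta, voxel_count),
    parcel_spec(6L, "Frontoparietal",   "cortical", 0.64, phi_task_delta, voxel_count),
    parcel_spec(7L, "Default",          "cortical", 0.66, phi_task_delta, voxel_count),
    parcel_spec(8L, "Thalamus",         "subcortical", 0.38, phi_task_delta, voxel_count),
    parcel_spec(9L, "Putamen",          "subcortical", 0.42, phi_task_delta, voxel_count))
  do.call(rbind, specs)
}

#' Cohort configuration for the synthetic generator
#'
#' Each subject is scanned twice at rest and twice under task. Per scan and
#' parcel the effective AR(1) coefficient is
#' `phi_base(condition) + subject_offset + scan_offset`, clipped to
#' `[0, 0.98]` (clip events are counted, not fatal): the persistent subject
#' offset drives test-retest reliability (ICC), the per-scan offset — shared
#' by every parcel in the scan — drives between-region entropy correlation.
#'
#' @param n_subjects Number of subjects (`>= 2`).
#' @param n_timepoints Time points per scan (default 405, about 5 min at a
#'   0.72 s repetition time).
#' @param grid_shape 3D grid extents for the full-volume path.
#' @param parcels Parcel data frame, e.g. [default_parcels()].
#' @param subject_sd SD of the per-subject `phi` offset.
#' @param shared_scan_sd SD of the per-scan global `phi` offset.
#' @param innovation_sd AR(1) innovation SD (signal units; entropy with a
#'   per-series tolerance is scale-free, so this mostly matters for I/O).
#' @param rest_timepoints Optional longer rest-scan length, to exercise
#'   rest-to-task truncation; `NULL` generates matched lengths.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 8L, n_timepoints = 405L,
                          grid_shape = c(12L, 12L, 12L),
                          parcels = default_parcels(),
                          subject_sd = 0.03, shared_scan_sd = 0.03,
                          innovation_sd = 1, rest_timepoints = NULL,
                          seed = 1L) {
  stopifnot(n_subjects >= 2L, n_timepoints >= 10L,
            length(grid_shape) == 3L,
            subject_sd >= 0, shared_scan_sd >= 0, innovation_sd > 0)
  if (sum(parcels$voxel_count) > prod(grid_shape))
    stop("GRID_TOO_SMALL: parcels need ", sum(parcels$voxel_count),
         " voxels, grid has ", prod(grid_shape), call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_timepoints = as.integer(n_timepoints),
                 grid_shape = as.integer(grid_shape),
                 parcels = parcels,
                 subject_sd = subject_sd, shared_scan_sd = shared_scan_sd,
                 innovation_sd = innovation_sd,
                 rest_timepoints = if (is.null(rest_timepoints)) NULL
                                   else as.integer(rest_timepoints),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Deterministic block atlas
#'
#' Lays parcels out as consecutive blocks in column-major voxel order; every
#' parcel gets exactly its requested voxel count, the remainder is
#' background 0.
#'
#' @param grid_shape 3D extents.
#' @param parcels Parcel data frame ([parcel_spec()] rows).
#' @return An [atlas_labels()] object.
#' @export
make_block_atlas <- function(grid_shape, parcels) {
  grid_shape <- as.integer(grid_shape)
  total <- sum(parcels$voxel_count)
  if (total > prod(grid_shape))
    stop("GRID_TOO_SMALL: parcels need ", total, " voxels, grid has ",
         prod(grid_shape), call. = FALSE)
  labels <- integer(prod(grid_shape))
  at <- 1L
  for (k in seq_len(nrow(parcels))) {
    n <- parcels$voxel_count[k]
    labels[at:(at + n - 1L)] <- parcels$label[k]
    at <- at + n
  }
  atlas_labels(array(labels, grid_shape),
               stats::setNames(parcels$name, as.character(parcels$label)),
               stats::setNames(parcels$class, as.character(parcels$label)))
}

#' Simulate one AR(1) voxel series
#'
#' `x_t = phi * x_(t-1) + e_t` with iid Gaussian innovations and stationary
#' initialisation (`x_1` drawn from the stationary distribution), so the
#' series has no startup transient.
#'
#' @param phi AR(1) coefficient, `|phi| < 1`.
#' @param n Series length.
#' @param innovation_sd Innovation SD.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return Numeric vector of length `n`.
#' @export
simulate_voxel_series <- function(phi, n, innovation_sd = 1, seed = NULL) {
  if (abs(phi) >= 1)
    stop("NONSTATIONARY_PHI: |phi| must be < 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  drop(simulate_ar1_matrix(phi, n, 1L, innovation_sd))
}

# n x n_series matrix of independent AR(1) series at a common phi,
# stationary start; vectorised over series.
simulate_ar1_matrix <- function(phi, n, n_series, innovation_sd) {
  x <- matrix(0, n, n_series)
  x[1L, ] <- stats::rnorm(n_series, 0, innovation_sd / sqrt(1 - phi^2))
  if (n > 1L) {
    eps <- matrix(stats::rnorm((n - 1L) * n_series, 0, innovation_sd),
                  n - 1L, n_series)
    for (t in 2:n) x[t, ] <- phi * x[t - 1L, ] + eps[t - 1L, ]
  }
  x
}

# Draw the cohort's effect structure: per-subject offsets, per-scan offsets,
# and the resulting clipped effective phi per scan x parcel. This is the
# ground-truth record both generator paths share.
draw_cohort_truth <- function(config) {
  set.seed(config$seed)
  subjects <- sprintf("sub%03d", seq_len(config$n_subjects))
  subj_offset <- stats::setNames(
    stats::rnorm(config$n_subjects, 0, config$subject_sd), subjects)
  scans <- expand.grid(scan_index = c(1L, 2L),
                       condition = c("rest", "task"),
                       subject_id = subjects,
                       stringsAsFactors = FALSE)[, 3:1]
  scans <- scans[order(scans$subject_id, scans$condition, scans$scan_index), ]
  rownames(scans) <- NULL
  scans$phase_encode <- ifelse(scans$scan_index == 1L, "RL", "LR")
  scans$scan_offset <- stats::rnorm(nrow(scans), 0, config$shared_scan_sd)
  p <- config$parcels
  grid <- expand.grid(row = seq_len(nrow(scans)), parcel = seq_len(nrow(p)))
  truth <- cbind(scans[grid$row, c("subject_id", "condition", "scan_index")],
                 p[grid$parcel, c("label", "name", "class")])
  truth$phi_base <- ifelse(truth$condition == "task",
                           p$phi_rest[grid$parcel] + p$phi_task_delta[grid$parcel],
                           p$phi_rest[grid$parcel])
  truth$subject_offset <- subj_offset[truth$subject_id]
  truth$scan_offset <- scans$scan_offset[grid$row]
  raw <- truth$phi_base + truth$subject_offset + truth$scan_offset
  truth$phi_effective <- pmin(pmax(raw, 0), 0.98)
  truth$clipped <- raw != truth$phi_effective
  rownames(truth) <- NULL
  list(scans = scans, truth = truth,
       n_clipped = sum(truth$clipped), seed = config$seed)
}

#' Simulate a full 4D synthetic cohort
#'
#' Generates, for every subject x condition x scan index, a 4D volume in
#' which each parcel's voxels are independent AR(1) series at that scan's
#' effective `phi` (see [cohort_config()]); background voxels are white
#' noise. Returns the volumes, the block atlas, and the complete ground
#' truth. Reproducible bit-for-bit from the config's seed.
#'
#' @param config A [cohort_config()].
#' @return List with `scans` (list of `list(bold, meta)`), `atlas`
#'   (an [atlas_labels()] object), and `truth` (list: per-scan x parcel
#'   effective-phi data frame, scan table, clip count, seed).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  gt <- draw_cohort_truth(config)
  atlas <- make_block_atlas(config$grid_shape, config$parcels)
  grid <- config$grid_shape
  n_vox <- prod(grid)
  parcel_idx <- lapply(config$parcels$label,
                       function(l) which(atlas$labels == l))
  bg_idx <- which(atlas$labels == 0L)
  out <- vector("list", nrow(gt$scans))
  for (s in seq_len(nrow(gt$scans))) {
    meta <- gt$scans[s, c("subject_id", "condition", "scan_index",
                          "phase_encode")]
    n_t <- if (meta$condition == "rest" && !is.null(config$rest_timepoints))
             config$rest_timepoints else config$n_timepoints
    flat <- matrix(0, n_vox, n_t)
    rows <- gt$truth$subject_id == meta$subject_id &
            gt$truth$condition == meta$condition &
            gt$truth$scan_index == meta$scan_index
    phis <- gt$truth[rows, ]
    for (k in seq_len(nrow(config$parcels))) {
      phi <- phis$phi_effective[phis$label == config$parcels$label[k]]
      flat[parcel_idx[[k]], ] <-
        t(simulate_ar1_matrix(phi, n_t, length(parcel_idx[[k]]),
                              config$innovation_sd))
    }
    if (length(bg_idx))
      flat[bg_idx, ] <- stats::rnorm(length(bg_idx) * n_t, 0,
                                     config$innovation_sd)
    vol <- array(flat, c(grid, n_t))
    rownames(meta) <- NULL
    out[[s]] <- list(bold = vol, meta = meta)
  }
  list(scans = out, atlas = atlas, truth = gt)
}

#' Fast parcel-level cohort: entropy table without voxel simulation
#'
#' Draws the same effect structure as [simulate_cohort()] but maps each
#' scan x parcel effective `phi` straight to a region-mean entropy through
#' the Monte-Carlo reference curve (phi to expected SampEn at the configured
#' series length): `mean = curve_mean(phi) + noise`, with noise SD
#' `curve_sd(phi) / sqrt(voxel_count)` — the sampling error of a mean over
#' independent voxels. Used where the statistics layer is the object under
#' study and full voxelwise simulation would add nothing but runtime.
#'
#' @param config A [cohort_config()].
#' @param curve Reference curve data frame (`phi`, `mean_se`, `sd_se`), by
#'   default the packaged fixture for 405-point series ([load_phi_curve()]).
#' @return List with `table` (a `roi_table`) and `truth`.
#' @export
simulate_cohort_table <- function(config, curve = load_phi_curve()) {
  stopifnot(inherits(config, "cohort_config"))
  gt <- draw_cohort_truth(config)
  tr <- gt$truth
  mu <- interp_phi_curve(tr$phi_effective, curve, "mean_se")
  sdv <- interp_phi_curve(tr$phi_effective, curve, "sd_se")
  vc <- config$parcels$voxel_count[match(tr$label, config$parcels$label)]
  tr$mean_entropy <- mu + stats::rnorm(nrow(tr), 0, sdv / sqrt(vc))
  rois <- config$parcels[, c("label", "name", "class")]
  n_scans <- nrow(gt$scans)
  shape <- function(col, default) {
    m <- matrix(default, n_scans, nrow(rois),
                dimnames = list(NULL, rois$name))
    m
  }
  mean_m <- shape("mean", NA_real_)
  sd_m <- shape("sd", NA_real_)
  n_m <- shape("n", 0L)
  scan_key <- paste(gt$scans$subject_id, gt$scans$condition,
                    gt$scans$scan_index)
  row_of <- match(paste(tr$subject_id, tr$condition, tr$scan_index),
                  scan_key)
  col_of <- match(tr$name, rois$name)
  mean_m[cbind(row_of, col_of)] <- tr$mean_entropy
  sd_m[cbind(row_of, col_of)] <- sdv
  n_m[cbind(row_of, col_of)] <- vc
  storage.mode(n_m) <- "integer"
  table <- structure(list(mean = mean_m, sd = sd_m, n_valid = n_m,
                          scans = gt$scans[, c("subject_id", "condition",
                                               "scan_index", "phase_encode")],
                          rois = rois),
                     class = "roi_table")
  list(table = table, truth = gt)
}
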