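#' Scan metadata record
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param condition `"rest"` or `"task"`.
#' @param scan_index 1 or 2 (first or second scan of that condition).
#' @param phase_encode Optional phase-encode tag (e.g. `"RL"`, `"LR"`).
#' @return A one-row data frame.
#' @export
scan_metadata <- function(subject_id, condition, scan_index,
                          phase_encode = NA_character_) {
  condition <- match.arg(condition, c("rest", "task"))
  scan_index <- as.integer(scan_index)
  stopifnot(scan_index %in% c(1L, 2L))
  data.frame(subject_id = as.character(subject_id), condition = condition,
             scan_index = scan_index,
             phase_encode = as.character(phase_encode),
             stringsAsFactors = FALSE)
}

#' Assemble the scans-by-regions entropy table for a cohort
#'
#' Summarises each scan's entropy map over the atlas with [roi_summary()]
#' and stacks the results into the pivot object for all group statistics:
#' matrices of per-region mean entropy, SD, and valid-voxel counts, one row
#' per scan, with scan metadata and region annotations attached. Rows are
#' ordered deterministically by (subject, condition, scan index) so
#' downstream correlation matrices are reproducible bit for bit.
#'
#' @param maps List of `entropy_map` objects (or 3D arrays), one per scan.
#' @param metadata Data frame with one row per map: columns `subject_id`,
#'   `condition`, `scan_index` (and optionally `phase_encode`). The triple
#'   must be unique.
#' @param atlas An [atlas_labels()] object shared by all maps.
#' @return An object of class `roi_table`: list with matrices `mean`, `sd`,
#'   `n_valid` (scans x regions), data frame `scans` (row metadata) and data
#'   frame `rois` (label, name, class).
#' @export
build_cohort_table <- function(maps, metadata, atlas) {
  stopifnot(inherits(atlas, "atlas3d"), is.data.frame(metadata))
  if (length(maps) != nrow(metadata))
    stop("one metadata row per map required", call. = FALSE)
  key <- paste(metadata$subject_id, metadata$condition, metadata$scan_index)
  if (anyDuplicated(key))
    stop("DUPLICATE_SCAN: duplicated (subject, condition, scan_index): ",
         key[duplicated(key)][1], call. = FALSE)
  ord <- order(metadata$subject_id, metadata$condition, metadata$scan_index)
  metadata <- metadata[ord, , drop = FALSE]
  maps <- maps[ord]
  rownames(metadata) <- NULL

  summaries <- lapply(maps, roi_summary, atlas = atlas)
  rois <- summaries[[1]][, c("label", "name", "class")]
  as_row <- function(s, col) stats::setNames(s[[col]], s$name)
  mean_m <- do.call(rbind, lapply(summaries, as_row, col = "mean"))
  sd_m <- do.call(rbind, lapply(summaries, as_row, col = "sd"))
  n_m <- do.call(rbind, lapply(summaries, as_row, col = "n_valid"))
  structure(list(mean = mean_m, sd = sd_m, n_valid = n_m,
                 scans = metadata, rois = rois),
            class = "roi_table")
}

#' @export
print.roi_table <- function(x, ...) {
  cat("ROI entropy table: ", nrow(x$mean), " scans x ", ncol(x$mean),
      " regions (", sum(x$scans$condition == "rest"), " rest, ",
      sum(x$scans$condition == "task"), " task)\n", sep = "")
  invisible(x)
}

#' Collapse a table to one value per scan over a region class
#'
#' Unweighted mean, across all regions of the given class, of the per-region
#' mean entropies — one scalar per scan. This is the series the whole-brain
#' cortical-vs-subcortical comparisons and the 2 x 2 ANOVA consume. A
#' voxel-count-weighted variant is available via `weight`.
#'
#' @param table A `roi_table`.
#' @param class `"cortical"`, `"subcortical"` or `"network"`.
#' @param weight `"equal"` (default: each region counts once) or `"voxel"`
#'   (regions weighted by their valid-voxel counts).
#' @return Numeric vector, one value per scan (named by row order).
#' @export
class_aggregate <- function(table, class, weight = c("equal", "voxel")) {
  stopifnot(inherits(table, "roi_table"))
  weight <- match.arg(weight)
  sel <- table$rois$class == class
  if (!any(sel))
    stop("UNKNOWN_CLASS: no regions of class '", class, "'", call. = FALSE)
  m <- table$mean[, sel, drop = FALSE]
  if (weight == "equal") {
    rowMeans(m, na.rm = TRUE)
  } else {
    w <- table$n_valid[, sel, drop = FALSE]
    rowSums(m * w, na.rm = TRUE) / rowSums(w * !is.na(m), na.rm = TRUE)
  }
}

#' Write a cohort table to CSV
#'
#' One row per scan; metadata columns (`subject_id`, `condition`,
#' `scan_index`, `phase_encode`) first, then `mean_<region>`, `sd_<region>`
#' and `nvalid_<region>` columns in region order. Region class annotations go
#' to a JSON sidecar next to the CSV. Values are written at full double
#' precision so the file round-trips losslessly.
#'
#' @param table A `roi_table`.
#' @param path Output CSV path; the sidecar is `<path>.rois.json`.
#' @return `path`, invisibly.
#' @export
write_roi_table <- function(table, path) {
  stopifnot(inherits(table, "roi_table"))
  df <- table$scans
  add <- function(prefix, m) {
    m <- as.data.frame(m)
    names(m) <- paste0(prefix, "_", table$rois$name)
    m
  }
  df <- cbind(df, add("mean", table$mean), add("sd", table$sd),
              add("nvalid", table$n_valid))
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(rois = table$rois),
    paste0(path, ".rois.json"), dataframe = "columns", auto_unbox = TRUE)
  invisible(path)
}

#' Read a cohort table written by [write_roi_table()]
#'
#' @param path CSV path; expects the `<path>.rois.json` sidecar beside it.
#' @return A `roi_table`.
#' @export
read_roi_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  side <- jsonlite::read_json(paste0(path, ".rois.json"),
                              simplifyVector = TRUE)
  rois <- as.data.frame(side$rois, stringsAsFactors = FALSE)
  grab <- function(prefix) {
    m <- as.matrix(df[, paste0(prefix, "_", rois$name), drop = FALSE])
    colnames(m) <- rois$name
    rownames(m) <- NULL
    m
  }
  scans <- df[, intersect(c("subject_id", "condition", "scan_index",
                            "phase_encode"), names(df)), drop = FALSE]
  scans$scan_index <- as.integer(scans$scan_index)
  structure(list(mean = grab("mean"), sd = grab("sd"),
                 n_valid = {
                   m <- grab("nvalid"); storage.mode(m) <- "integer"; m
                 },
                 scans = scans, rois = rois),
            class = "roi_table")
}
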