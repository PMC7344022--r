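#' Construct an atlas of integer parcel labels
#'
#' Wraps a 3D integer label lattice together with parcel names and a
#' cortical/subcortical/network class annotation per parcel. Label 0 is
#' reserved for background and excluded from every summary.
#'
#' @param labels 3D integer array; 0 = background.
#' @param label_names Named character vector mapping label (as name) to
#'   parcel name; must cover every nonzero label present.
#' @param label_class Named character vector mapping label to one of
#'   `"cortical"`, `"subcortical"`, `"network"`.
#' @return An object of class `atlas3d`.
#' @export
atlas_labels <- function(labels, label_names, label_class) {
  labels <- unclass(labels)
  attributes(labels) <- list(dim = dim(labels))
  if (length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE))
    stop("labels must be nonnegative", call. = FALSE)
  present <- sort(unique(labels[labels > 0L]))
  if (!all(as.character(present) %in% names(label_names)))
    stop("every nonzero label must appear in 'label_names'", call. = FALSE)
  cls <- label_class[names(label_names)]
  if (anyNA(cls) || !all(cls %in% c("cortical", "subcortical", "network")))
    stop("'label_class' must give cortical/subcortical/network for each label",
         call. = FALSE)
  structure(list(labels = labels,
                 label_names = label_names,
                 label_class = cls),
            class = "atlas3d")
}

#' @export
print.atlas3d <- function(x, ...) {
  cat("Atlas ", paste(dim(x$labels), collapse = " x "), ": ",
      length(x$label_names), " parcels (",
      paste(names(table(x$label_class)), table(x$label_class),
            sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

atlas_label_ids <- function(atlas) as.integer(names(atlas$label_names))

#' Validate an atlas against a data grid
#'
#' Checks that the label lattice matches the expected 3D grid, enumerates
#' the parcels, and flags declared parcels with zero voxels. A grid mismatch
#' is an error; an empty parcel is a warning entry so partial atlases remain
#' usable.
#'
#' @param atlas An [atlas_labels()] object.
#' @param grid Integer vector of length 3: the data grid extents.
#' @return A list with `n_parcels`, `parcels` (data frame of label, name,
#'   class, voxel count) and `warnings` (character vector).
#' @export
validate_atlas <- function(atlas, grid) {
  stopifnot(inherits(atlas, "atlas3d"))
  grid <- as.integer(grid)
  if (!identical(as.integer(dim(atlas$labels)), grid))
    stop("GRID_MISMATCH: atlas grid ",
         paste(dim(atlas$labels), collapse = "x"),
         " != data grid ", paste(grid, collapse = "x"), call. = FALSE)
  ids <- atlas_label_ids(atlas)
  counts <- vapply(ids, function(l) sum(atlas$labels == l), integer(1))
  warns <- character(0)
  for (k in which(counts == 0L))
    warns <- c(warns, sprintf("parcel %d (%s) has zero voxels",
                              ids[k], atlas$label_names[k]))
  list(n_parcels = length(ids),
       parcels = data.frame(label = ids,
                            name = unname(atlas$label_names),
                            class = unname(atlas$label_class),
                            n_voxels = counts,
                            stringsAsFactors = FALSE),
       warnings = warns)
}

#' Per-region summary of an entropy map
#'
#' For each nonzero atlas label, the mean and sample SD of the defined
#' (non-`NA`) voxel entropies in that parcel, plus the count of contributing
#' voxels. A parcel whose voxels are all undefined yields `NA` mean/SD and a
#' zero count — never a silent 0.
#'
#' @param map An `entropy_map` from [sample_entropy_map()] (or a bare 3D
#'   numeric array of voxel entropies with `NA` for undefined).
#' @param atlas An [atlas_labels()] object on the same grid.
#' @return Data frame with one row per parcel: `label`, `name`, `class`,
#'   `mean`, `sd`, `n_valid`.
#' @export
roi_summary <- function(map, atlas) {
  stopifnot(inherits(atlas, "atlas3d"))
  values <- if (inherits(map, "entropy_map")) map$values else map
  if (!identical(dim(values), dim(atlas$labels)))
    stop("GRID_MISMATCH: map grid ", paste(dim(values), collapse = "x"),
         " != atlas grid ", paste(dim(atlas$labels), collapse = "x"),
         call. = FALSE)
  ids <- atlas_label_ids(atlas)
  out <- data.frame(label = ids,
                    name = unname(atlas$label_names),
                    class = unname(atlas$label_class),
                    mean = NA_real_, sd = NA_real_,
                    n_valid = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    v <- values[atlas$labels == ids[k]]
    v <- v[!is.na(v)]
    out$n_valid[k] <- length(v)
    if (length(v)) {
      out$mean[k] <- mean(v)
      out$sd[k] <- if (length(v) > 1L) stats::sd(v) else 0
    }
  }
  out
}
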