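#' Extract per-ROI mean time courses from a labelled 4D volume
#'
#' Averages the voxel time series within each parcellation label at every
#' timepoint (unweighted mean over member voxels). Labels with zero voxels
#' are not silently dropped: they appear in the output with an `NA` series
#' and `n_voxels = 0`, so the field-of-view exclusion rule can act on them.
#'
#' @param volumes 4D numeric array (x, y, z, time), or a path to a NIfTI file
#'   (read with the RNifti package).
#' @param parcellation 3D integer array of labels on the same spatial grid
#'   (0 = background), or a NIfTI path.
#' @param roi_ids Optional named map from label value to ROI id; default
#'   `ROI<label>`. Labels listed here but absent from the grid are reported
#'   with zero voxels.
#' @param subject,session,tr Metadata carried into the output.
#' @return A recordings tibble: `subject`, `session`, `roi`, `tr`, `n_voxels`,
#'   and a `series` list-column (NA series for absent ROIs).
#' @export
extract_roi_timecourses <- function(volumes, parcellation, roi_ids = NULL,
                                    subject = "sub01", session = "RS1", tr = 2) {
  volumes <- read_volume(volumes, ndim = 4L)
  parcellation <- read_volume(parcellation, ndim = 3L)
  if (!identical(dim(volumes)[1:3], dim(parcellation))) {
    abort(sprintf(
      "Spatial grids differ: data %s vs parcellation %s.",
      paste(dim(volumes)[1:3], collapse = "x"), paste(dim(parcellation), collapse = "x")
    ))
  }
  n_t <- dim(volumes)[4]
  labels_present <- sort(unique(as.integer(parcellation)))
  labels_present <- labels_present[labels_present > 0]
  labels <- if (is.null(roi_ids)) labels_present else as.integer(names(roi_ids))
  ids <- if (is.null(roi_ids)) sprintf("ROI%d", labels) else unname(roi_ids)

  flat <- matrix(volumes, ncol = n_t) # voxels x time
  lab_vec <- as.integer(parcellation)
  rows <- map(seq_along(labels), function(i) {
    members <- which(lab_vec == labels[i])
    if (length(members) == 0) {
      list(series = rep(NA_real_, n_t), n_voxels = 0L)
    } else {
      list(series = colMeans(flat[members, , drop = FALSE]), n_voxels = length(members))
    }
  })
  tibble(
    subject = subject, session = session, roi = ids, tr = tr,
    n_voxels = map_dbl(rows, "n_voxels"),
    series = map(rows, "series")
  )
}

read_volume <- function(x, ndim) {
  if (is.character(x)) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      abort("Reading NIfTI files requires the RNifti package.")
    }
    x <- as.array(RNifti::readNifti(x))
  }
  if (!is.array(x) || length(dim(x)) != ndim) {
    abort(sprintf("Expected a %dD array.", ndim))
  }
  x
}

#' Field-of-view exclusion rule
#'
#' A region that is absent (zero voxels, or an all-NA series) in ANY
#' subject or session is removed for ALL subjects and sessions, so every
#' retained region is comparable across the whole study. The exclusions,
#' with the subject/session combinations that triggered each, are attached
#' as the `"exclusions"` attribute and available via [fov_exclusions()].
#'
#' @param recordings A recordings tibble; absence is flagged by a
#'   `n_voxels == 0` column or an all-NA `series`.
#' @return The recordings tibble with excluded ROIs dropped everywhere.
#' @examples
#' # a 246-region study where one region misses the field of view in one
#' # subject retains 245 regions for everyone
#' @export
apply_fov_exclusion <- function(recordings) {
  stopifnot(is_tibble(recordings), all(c("subject", "session", "roi") %in% names(recordings)))
  absent <- if ("n_voxels" %in% names(recordings)) {
    recordings$n_voxels == 0
  } else {
    map_lgl(recordings$series, function(s) all(is.na(s)))
  }
  report <- recordings[absent, c("roi", "subject", "session")]
  report <- report |>
    group_by(.data$roi) |>
    summarise(
      reason = "absent from field of view",
      triggering = paste(unique(paste0(.data$subject, "/", .data$session)), collapse = ";"),
      .groups = "drop"
    )
  keep <- !(recordings$roi %in% report$roi)
  if (!any(keep)) abort("All ROIs excluded by the field-of-view rule.")
  out <- recordings[keep, ]
  attr(out, "exclusions") <- report
  attr(out, "ground_truth") <- attr(recordings, "ground_truth")
  out
}

#' @importFrom purrr map_lgl
#' @rdname apply_fov_exclusion
#' @param x A recordings tibble returned by [apply_fov_exclusion()].
#' @export
fov_exclusions <- function(x) {
  attr(x, "exclusions") %||% tibble(roi = character(), reason = character(), triggering = character())
}

#' Overlap between two binary masks
#'
#' Voxel count of the intersection and the Jaccard index of two masks on the
#' same grid, as used to report how discovered regions overlap reference
#' cluster sets (e.g. a fear-extinction network mask).
#'
#' @param mask_a,mask_b Logical or 0/1 numeric arrays of identical dimensions.
#' @return A one-row tibble: `n_a`, `n_b`, `n_intersection`, `n_union`,
#'   `jaccard` (0 when both masks are empty).
#' @export
mask_overlap <- function(mask_a, mask_b) {
  if (!identical(dim(mask_a) %||% length(mask_a), dim(mask_b) %||% length(mask_b))) {
    abort("Masks must share a grid (identical dimensions).")
  }
  a <- as.logical(mask_a)
  b <- as.logical(mask_b)
  inter <- sum(a & b)
  uni <- sum(a | b)
  tibble(
    n_a = sum(a), n_b = sum(b), n_intersection = inter, n_union = uni,
    jaccard = if (uni == 0) 0 else inter / uni
  )
}
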