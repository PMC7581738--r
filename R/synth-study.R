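#' Specify a synthetic rest-task-rest study
#'
#' Describes a multi-subject, multi-session, multi-ROI study with known
#' ground truth: every ROI gets a baseline Hurst exponent and variance, and
#' selected "effect" ROIs shift H and/or variance in selected sessions.
#' Defaults mirror a typical resting-state fMRI study of this design:
#' 23 subjects, three sessions (rest / task / rest), 245 regions, 300 volumes
#' at TR = 2 s, baseline H drawn uniformly on (0.66, 0.86) and baseline
#' variance uniformly on (180, 900) signal units squared.
#'
#' @param n_subjects,n_rois,n_timepoints Design dimensions.
#' @param tr Repetition time in seconds.
#' @param sessions Ordered character vector of session labels.
#' @param base_h Per-ROI baseline Hurst exponents in (0, 1); a single value is
#'   recycled; `NULL` draws them uniformly on `h_range` using `seed`.
#' @param base_var Per-ROI baseline variances (> 0); `NULL` draws them
#'   uniformly on `var_range`.
#' @param h_range,var_range Sampling ranges used when `base_h` / `base_var`
#'   are not supplied.
#' @param effects A list of effects, each a list with elements `session`
#'   (label), `rois` (integer indices), and either/both `delta_h` (additive
#'   shift of H) and `var_mult` (multiplicative variance factor).
#' @param bandpass Optional length-2 numeric `(low_hz, high_hz)`; if set,
#'   simulated series are band-pass filtered (off by default: filtering
#'   biases short-series Hurst estimates upward).
#' @param seed Master seed. One master seed spawns per-subject/session/ROI
#'   substreams, so any subset of the study is reproducible.
#' @return An object of class `study_spec`.
#' @examples
#' spec <- study_spec(n_subjects = 4, n_rois = 6, seed = 1)
#' spec$ground_truth
#' @export
study_spec <- function(n_subjects = 23, n_rois = 245, n_timepoints = 300,
                       tr = 2, sessions = c("RS1", "FE", "RS2"),
                       base_h = NULL, base_var = NULL,
                       h_range = c(0.66, 0.86), var_range = c(180, 900),
                       effects = list(), bandpass = NULL, seed = NULL) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  n_rois <- check_count(n_rois, "n_rois")
  n_timepoints <- check_count(n_timepoints, "n_timepoints", lower = 12L)
  check_number(tr, "tr", 0, closed_lower = FALSE)
  stopifnot(is.character(sessions), length(sessions) >= 1, !anyDuplicated(sessions))

  drawn <- with_seed_or_not(seed, list(
    h = stats::runif(n_rois, h_range[1], h_range[2]),
    v = stats::runif(n_rois, var_range[1], var_range[2])
  ))
  base_h <- if (is.null(base_h)) drawn$h else rep_len(base_h, n_rois)
  base_var <- if (is.null(base_var)) drawn$v else rep_len(base_var, n_rois)
  if (any(base_h <= 0 | base_h >= 1)) abort("`base_h` must lie strictly in (0, 1).")
  if (any(base_var <= 0)) abort("`base_var` must be positive.")

  roi_ids <- sprintf("ROI%03d", seq_len(n_rois))
  truth <- tidyr::expand_grid(session = sessions, roi = roi_ids)
  truth$true_h <- base_h[match(truth$roi, roi_ids)]
  truth$true_var <- base_var[match(truth$roi, roi_ids)]

  for (ef in effects) {
    if (!ef$session %in% sessions) {
      abort(sprintf("Effect session '%s' is not a declared session.", ef$session))
    }
    hit <- truth$session == ef$session & truth$roi %in% roi_ids[ef$rois]
    if (!is.null(ef$delta_h)) truth$true_h[hit] <- truth$true_h[hit] + ef$delta_h
    if (!is.null(ef$var_mult)) truth$true_var[hit] <- truth$true_var[hit] * ef$var_mult
  }
  if (any(truth$true_h <= 0 | truth$true_h >= 1)) {
    abort("An effect pushes a per-session Hurst exponent outside (0, 1).")
  }
  if (any(truth$true_var <= 0)) abort("An effect pushes a variance to zero or below.")
  if (!is.null(bandpass)) {
    stopifnot(is.numeric(bandpass), length(bandpass) == 2, bandpass[1] < bandpass[2])
  }

  structure(
    list(
      n_subjects = n_subjects, n_rois = n_rois, n_timepoints = n_timepoints,
      tr = tr, sessions = sessions, roi_ids = roi_ids,
      base_h = base_h, base_var = base_var, effects = effects,
      bandpass = bandpass, seed = seed,
      ground_truth = as_tibble(truth)
    ),
    class = "study_spec"
  )
}

#' @export
print.study_spec <- function(x, ...) {
  cat(sprintf(
    "<study_spec> %d subjects x %d sessions (%s) x %d ROIs, %d volumes @ TR %g s\n",
    x$n_subjects, length(x$sessions), paste(x$sessions, collapse = ", "),
    x$n_rois, x$n_timepoints, x$tr
  ))
  cat(sprintf("  effects: %d; bandpass: %s; seed: %s\n",
              length(x$effects),
              if (is.null(x$bandpass)) "off" else paste(x$bandpass, collapse = "-"),
              x$seed %||% "unset"))
  invisible(x)
}

#' Simulate a study from a specification
#'
#' Draws one exact fGn series per subject x session x ROI at that cell's
#' ground-truth Hurst exponent and variance (ROIs are simulated
#' independently; the downstream analysis is univariate per ROI). Returns a
#' tidy recordings table with one row per series.
#'
#' @param spec A [study_spec()].
#' @return A tibble with columns `subject`, `session`, `roi`, `tr`, and a
#'   `series` list-column of numeric vectors; the spec's `ground_truth`
#'   tibble is attached as attribute `"ground_truth"`.
#' @examples
#' rec <- simulate_study(study_spec(n_subjects = 2, n_rois = 3, seed = 1))
#' rec
#' @export
simulate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  cells <- tidyr::expand_grid(
    subject = sprintf("sub%02d", seq_len(spec$n_subjects)),
    session = spec$sessions,
    roi = spec$roi_ids
  )
  cells <- left_join(cells, spec$ground_truth, by = c("session", "roi"))
  cells$cell_seed <- spawn_seeds(spec$seed, nrow(cells))
  series <- pmap(
    list(cells$true_h, cells$true_var, cells$cell_seed),
    function(h, v, s) {
      x <- sqrt(v) * fgn_unit(spec$n_timepoints, h, s, allow_approx = FALSE)
      if (!is.null(spec$bandpass)) {
        x <- bandpass(x, spec$tr, spec$bandpass[1], spec$bandpass[2])
      }
      x
    }
  )
  out <- tibble(
    subject = cells$subject, session = cells$session, roi = cells$roi,
    tr = spec$tr, series = series
  )
  attr(out, "ground_truth") <- spec$ground_truth
  out
}

#' Write / read a recordings table as TSV + JSON sidecars
#'
#' One TSV per subject x session (rows = ROIs, first column `roi`, remaining
#' columns timepoints `t1..tN`) plus a JSON sidecar holding `subject`,
#' `session`, and `tr`. [read_recordings()] reverses the layout losslessly.
#'
#' @param recordings A recordings tibble (see [simulate_study()]).
#' @param dir Output directory (created if missing).
#' @return `write_recordings()` returns the written file paths invisibly;
#'   `read_recordings()` returns a recordings tibble.
#' @export
write_recordings <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cells <- distinct(recordings, .data$subject, .data$session, .data$tr)
  paths <- pmap(cells, function(subject, session, tr) {
    rows <- filter(recordings, .data$subject == !!subject, .data$session == !!session)
    mat <- do.call(rbind, rows$series)
    colnames(mat) <- paste0("t", seq_len(ncol(mat)))
    df <- tibble(roi = rows$roi) |> dplyr::bind_cols(as_tibble(mat))
    stem <- file.path(dir, sprintf("%s_%s", subject, session))
    readr::write_tsv(df, paste0(stem, ".tsv"))
    jsonlite::write_json(
      list(subject = subject, session = session, tr = tr),
      paste0(stem, ".json"), auto_unbox = TRUE
    )
    paste0(stem, c(".tsv", ".json"))
  })
  gt <- attr(recordings, "ground_truth")
  if (!is.null(gt)) readr::write_tsv(gt, file.path(dir, "ground_truth.tsv"))
  invisible(unlist(paths))
}

#' @rdname write_recordings
#' @export
read_recordings <- function(dir) {
  sidecars <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  sidecars <- sidecars[basename(sidecars) != "ground_truth.json"]
  if (length(sidecars) == 0) abort(sprintf("No recording sidecars found in '%s'.", dir))
  out <- map(sidecars, function(js) {
    meta <- jsonlite::read_json(js)
    tab <- readr::read_tsv(sub("\\.json$", ".tsv", js), show_col_types = FALSE)
    tibble(
      subject = meta$subject, session = meta$session, roi = tab$roi,
      tr = as.numeric(meta$tr),
      series = lapply(seq_len(nrow(tab)), function(i) as.numeric(tab[i, -1]))
    )
  }) |> list_rbind()
  gt_path <- file.path(dir, "ground_truth.tsv")
  if (file.exists(gt_path)) {
    attr(out, "ground_truth") <- readr::read_tsv(gt_path, show_col_types = FALSE)
  }
  out
}
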