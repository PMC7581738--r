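#' Configure a rest-task-rest analysis
#'
#' Bundles the analysis settings: session labels, contrast pairs, DFA
#' settings, variance convention, significance level, and how step-1
#' screening admits regions to the remaining contrasts.
#'
#' @param sessions Ordered session labels; the first and last are the two
#'   rest sessions used for screening and for the fit-quality gate.
#' @param contrasts List of length-2 character vectors `c(a, b)` meaning the
#'   paired contrast a - b; the FIRST entry is the screening contrast.
#'   Default: RS2-RS1 (screening), FE-RS1, RS2-FE.
#' @param windows,detrend_order,aggregation Passed to [dfa()].
#' @param ddof Variance divisor convention, see [signal_variance()].
#' @param alpha Significance level for screening and the gate (default 0.05).
#' @param screen_on `"raw"` (default) admits regions to step 2 on raw
#'   p < alpha; `"fdr"` requires q < alpha.
#' @return A `study_config` list.
#' @export
study_config <- function(sessions = c("RS1", "FE", "RS2"),
                         contrasts = list(c("RS2", "RS1"), c("FE", "RS1"), c("RS2", "FE")),
                         windows = NULL, detrend_order = 1,
                         aggregation = c("mean", "rms"),
                         ddof = 0, alpha = 0.05,
                         screen_on = c("raw", "fdr")) {
  aggregation <- arg_match(aggregation)
  screen_on <- arg_match(screen_on)
  check_number(alpha, "alpha", 0, 1, closed_lower = FALSE, closed_upper = FALSE)
  for (ct in contrasts) {
    if (!all(ct %in% sessions)) {
      abort(sprintf("Contrast %s references an undeclared session.",
                    paste(ct, collapse = "-")))
    }
  }
  structure(
    list(sessions = sessions, contrasts = contrasts, windows = windows,
         detrend_order = detrend_order, aggregation = aggregation,
         ddof = ddof, alpha = alpha, screen_on = screen_on),
    class = "study_config"
  )
}

#' Per-series DFA and variance metrics for a whole study
#'
#' Runs [dfa()] and [signal_variance()] on every subject x session x ROI
#' series. The study must be complete (every subject recorded in every
#' session for every ROI); gaps are an error that lists the missing cells.
#' Constant (zero-fluctuation) series are not an error here: they are
#' flagged with `ok = FALSE` and a reason, and carry NA metrics.
#'
#' @param recordings A recordings tibble ([simulate_study()],
#'   [read_recordings()], or [extract_roi_timecourses()] output).
#' @param config A [study_config()].
#' @return A tibble with one row per series: `subject`, `session`, `roi`,
#'   `alpha`, `hurst`, `regime`, `r_squared`, `variance`, `ok`, `reason`.
#' @export
session_metrics <- function(recordings, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  stopifnot(all(c("subject", "session", "roi", "series") %in% names(recordings)))
  grid <- tidyr::expand_grid(
    subject = unique(recordings$subject),
    session = config$sessions,
    roi = unique(recordings$roi)
  )
  missing_cells <- dplyr::anti_join(grid, recordings, by = c("subject", "session", "roi"))
  if (nrow(missing_cells) > 0) {
    gaps <- head(sprintf("%s/%s/%s", missing_cells$subject, missing_cells$session,
                         missing_cells$roi), 10)
    abort(sprintf("Incomplete study: %d missing subject/session/ROI cells (e.g. %s).",
                  nrow(missing_cells), paste(gaps, collapse = ", ")))
  }

  lens <- lengths(recordings$series)
  if (length(unique(lens)) != 1) {
    abort("All series must share one length within a study.")
  }
  mat <- do.call(cbind, recordings$series)
  sds <- apply(mat, 2, sd)
  usable <- is.finite(sds) & sds > 0

  out <- tibble(
    subject = recordings$subject, session = recordings$session, roi = recordings$roi,
    alpha = NA_real_, hurst = NA_real_, regime = NA_character_,
    r_squared = NA_real_, variance = NA_real_,
    ok = usable,
    reason = ifelse(usable, NA_character_, "constant or non-finite series")
  )
  if (any(usable)) {
    fit <- dfa_matrix(mat[, usable, drop = FALSE], windows = config$windows,
                      detrend_order = config$detrend_order,
                      aggregation = config$aggregation)
    out$alpha[usable] <- fit$alpha
    out$hurst[usable] <- fit$hurst
    out$regime[usable] <- fit$regime
    out$r_squared[usable] <- fit$r_squared
    n <- nrow(mat)
    out$variance[usable] <- colSums((mat[, usable, drop = FALSE] -
      rep(colMeans(mat[, usable, drop = FALSE]), each = n))^2) / (n - config$ddof)
  }
  out
}

#' Group summary of study metrics
#'
#' Mean and standard deviation across subjects of the Hurst exponent,
#' variance, and fit R-squared, per session and ROI — the "mean (+/- sd)"
#' columns of a session-comparison table.
#'
#' @param metrics Output of [session_metrics()].
#' @return A tibble with one row per session x ROI.
#' @export
summarise_metrics <- function(metrics) {
  metrics |>
    filter(.data$ok) |>
    group_by(.data$session, .data$roi) |>
    summarise(
      across(c("hurst", "variance", "r_squared"),
             list(mean = mean, sd = sd)),
      n_subjects = n(), .groups = "drop"
    )
}

#' Two-step paired session contrasts with FDR control
#'
#' Implements the two-step comparison strategy for a rest-task-rest study.
#' Step 1 screens every region on the rest-versus-rest contrast (the first
#' configured contrast) with a paired Wilcoxon signed-rank test per region
#' and Benjamini-Hochberg adjustment across regions. Step 2 then tests ONLY
#' the screened regions on the remaining contrasts (task effects), again
#' with BH adjustment within each contrast family. For the Hurst metric,
#' regions first pass the fit-quality gate ([fit_quality_gate()]) comparing
#' the two rest sessions' R-squared values; gated regions are excluded from
#' all H contrasts and reported.
#'
#' @param metrics Output of [session_metrics()].
#' @param config A [study_config()]; `screen_on` chooses whether raw
#'   p < alpha or q < alpha admits a region to step 2 (raw by default; both
#'   p and q are always reported).
#' @return A tibble of class `contrast_tables`: one row per metric x contrast
#'   x region with the per-session means/sds, `w`, `p_value`, `q_value`,
#'   `n_pairs`, `step`, and `screened`. Gate exclusions are in attribute
#'   `"gate_exclusions"`; regions unusable for testing (missing metrics) in
#'   attribute `"dropped"`.
#' @export
session_contrasts <- function(metrics, config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  screen_pair <- config$contrasts[[1]]
  rest_a <- screen_pair[1]
  rest_b <- screen_pair[2]

  bad <- metrics |>
    filter(!.data$ok) |>
    distinct(.data$roi) |>
    mutate(reason = "metrics unavailable for at least one subject/session")
  usable <- filter(metrics, !.data$roi %in% bad$roi)

  # fit-quality gate on the two screening (rest) sessions, H metric only
  gate <- usable |>
    filter(.data$session %in% screen_pair) |>
    tidyr::pivot_wider(id_cols = c("subject", "roi"), names_from = "session",
                       values_from = "r_squared") |>
    group_by(.data$roi) |>
    summarise(fit_quality_gate(.data[[rest_a]], .data[[rest_b]], config$alpha),
              .groups = "drop")
  gate_excluded <- filter(gate, !.data$include)

  summary <- summarise_metrics(usable)

  one_family <- function(metric, pair, rois, step) {
    wide <- usable |>
      filter(.data$roi %in% rois, .data$session %in% pair) |>
      tidyr::pivot_wider(id_cols = c("subject", "roi"), names_from = "session",
                         values_from = dplyr::all_of(metric))
    tests <- wide |>
      group_by(.data$roi) |>
      summarise(wilcoxon_signed_rank(.data[[pair[1]]], .data[[pair[2]]]),
                .groups = "drop")
    tests$q_value <- bh_fdr(tests$p_value)
    means <- summary |>
      filter(.data$roi %in% rois, .data$session %in% pair) |>
      select("session", "roi", mean = dplyr::all_of(paste0(metric, "_mean")),
             sd = dplyr::all_of(paste0(metric, "_sd"))) |>
      tidyr::pivot_wider(names_from = "session", values_from = c("mean", "sd"))
    tests |>
      mutate(metric = metric, contrast = paste(pair[1], pair[2], sep = "-"),
             step = step, .before = 1) |>
      left_join(means, by = "roi")
  }

  results <- map(c("hurst", "variance"), function(metric) {
    rois_all <- unique(usable$roi)
    if (metric == "hurst") rois_all <- setdiff(rois_all, gate_excluded$roi)
    if (length(rois_all) == 0) return(NULL)
    step1 <- one_family(metric, screen_pair, rois_all, step = 1L)
    crit <- if (config$screen_on == "raw") step1$p_value else step1$q_value
    step1$screened <- crit < config$alpha
    screened_rois <- step1$roi[step1$screened]
    step2 <- map(config$contrasts[-1], function(pair) {
      if (length(screened_rois) == 0) return(NULL)
      tab <- one_family(metric, pair, screened_rois, step = 2L)
      tab$screened <- TRUE
      tab
    }) |> list_rbind()
    bind_rows(step1, step2)
  }) |> list_rbind()

  structure(
    results,
    gate_exclusions = gate_excluded,
    dropped = bad,
    class = c("contrast_tables", class(results))
  )
}

#' Gate exclusions and dropped regions of a contrast table
#'
#' @param x A `contrast_tables` object from [session_contrasts()].
#' @return A tibble of gated regions (`gate_exclusions()`) or of regions
#'   dropped for missing metrics (`dropped_rois()`).
#' @export
gate_exclusions <- function(x) attr(x, "gate_exclusions")

#' @rdname gate_exclusions
#' @export
dropped_rois <- function(x) attr(x, "dropped")

#' Covariate associations with per-region metrics
#'
#' Spearman correlation of a per-subject covariate (e.g. an anxiety score)
#' with each region's Hurst exponent and variance, per session, with BH
#' adjustment within each session x metric family.
#'
#' @param metrics Output of [session_metrics()].
#' @param covariates Tibble with columns `subject` and `score`.
#' @return A tibble: `session`, `metric`, `roi`, `rho`, `p_value`,
#'   `q_value`, `n`.
#' @export
covariate_associations <- function(metrics, covariates) {
  stopifnot(all(c("subject", "score") %in% names(covariates)))
  if (sd(covariates$score) == 0) {
    abort("Constant covariate: ranks are undefined for a Spearman correlation.")
  }
  long <- metrics |>
    filter(.data$ok) |>
    tidyr::pivot_longer(c("hurst", "variance"), names_to = "metric") |>
    left_join(covariates, by = "subject")
  out <- long |>
    group_by(.data$session, .data$metric, .data$roi) |>
    summarise(spearman(.data$value, .data$score), .groups = "drop")
  out |>
    group_by(.data$session, .data$metric) |>
    mutate(q_value = bh_fdr(.data$p_value)) |>
    ungroup()
}

#' Run the full rest-task-rest analysis
#'
#' End-to-end orchestration: field-of-view exclusion, per-series metrics,
#' group summaries, the two-step contrasts with the fit-quality gate, and
#' (optionally) covariate associations. Optionally writes all tables as TSV
#' plus a JSON log of the settings used. The analysis path contains no
#' randomness: rerunning on the same inputs reproduces every number.
#'
#' @param recordings A recordings tibble.
#' @param config A [study_config()].
#' @param covariates Optional tibble (`subject`, `score`).
#' @param out_dir Optional output directory for TSV/JSON report files.
#' @return A `study_report` list: `metrics`, `summary`, `contrasts`,
#'   `gate_exclusions`, `fov_exclusions`, `covariates`.
#' @export
run_study <- function(recordings, config = study_config(), covariates = NULL,
                      out_dir = NULL) {
  recordings <- apply_fov_exclusion(recordings)
  metrics <- session_metrics(recordings, config)
  contrasts <- session_contrasts(metrics, config)
  report <- structure(
    list(
      metrics = metrics,
      summary = summarise_metrics(metrics),
      contrasts = contrasts,
      gate_exclusions = gate_exclusions(contrasts),
      fov_exclusions = fov_exclusions(recordings),
      covariates = if (is.null(covariates)) NULL
        else covariate_associations(metrics, covariates),
      config = config
    ),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    paste0("<study_report> %d subjects, %d ROIs, sessions %s\n",
           "  step-1 screened: %d (hurst), %d (variance); gate-excluded: %d\n"),
    g$n_subjects, g$n_rois, paste(x$config$sessions, collapse = "/"),
    g$screened_hurst, g$screened_variance, g$n_gate_excluded
  ))
  invisible(x)
}

#' @rdname run_study
#' @param x,object A `study_report`.
#' @param ... Unused.
#' @export
glance.study_report <- function(x, ...) {
  ct <- x$contrasts
  s1 <- filter(ct, .data$step == 1L)
  tibble(
    n_subjects = dplyr::n_distinct(x$metrics$subject),
    n_rois = dplyr::n_distinct(x$metrics$roi),
    screened_hurst = sum(s1$screened[s1$metric == "hurst"]),
    screened_variance = sum(s1$screened[s1$metric == "variance"]),
    n_gate_excluded = nrow(x$gate_exclusions),
    n_fov_excluded = nrow(x$fov_exclusions)
  )
}

#' @rdname run_study
#' @export
tidy.study_report <- function(x, ...) as_tibble(x$contrasts)

#' Write a study report to disk
#'
#' TSV tables (full double precision; p and q additionally formatted at four
#' decimals in `*_display` columns, matching the conventional table style)
#' plus a JSON log of the configuration.
#'
#' @param report A `study_report`.
#' @param dir Output directory (created if missing).
#' @return The written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ct <- as_tibble(report$contrasts) |>
    mutate(p_display = sprintf("%.4f", .data$p_value),
           q_display = sprintf("%.4f", .data$q_value))
  paths <- c(
    metrics = file.path(dir, "metrics.tsv"),
    summary = file.path(dir, "summary.tsv"),
    contrasts = file.path(dir, "contrasts.tsv"),
    gate = file.path(dir, "gate_exclusions.tsv"),
    fov = file.path(dir, "fov_exclusions.tsv")
  )
  readr::write_tsv(report$metrics, paths["metrics"])
  readr::write_tsv(report$summary, paths["summary"])
  readr::write_tsv(ct, paths["contrasts"])
  readr::write_tsv(report$gate_exclusions, paths["gate"])
  readr::write_tsv(report$fov_exclusions, paths["fov"])
  if (!is.null(report$covariates)) {
    paths <- c(paths, covariates = file.path(dir, "covariate_associations.tsv"))
    readr::write_tsv(report$covariates, paths["covariates"])
  }
  cfg <- report$config
  jsonlite::write_json(
    list(sessions = cfg$sessions,
         contrasts = lapply(cfg$contrasts, paste, collapse = "-"),
         windows = cfg$windows %||% "auto (12,15,20,25,30 within N/10)",
         detrend_order = cfg$detrend_order, aggregation = cfg$aggregation,
         ddof = cfg$ddof, alpha = cfg$alpha, screen_on = cfg$screen_on,
         package_version = as.character(utils::packageVersion("fractalrest"))),
    file.path(dir, "log.json"), auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}

#' Session-level distribution plot of a study metric
#'
#' Violin/jitter view of the across-subject distribution of a metric per
#' session — a quick look at whether a session shifted the study-wide H or
#' variance level.
#'
#' @param metrics Output of [session_metrics()].
#' @param metric `"hurst"` or `"variance"`.
#' @return A ggplot object.
#' @export
plot_session_metric <- function(metrics, metric = c("hurst", "variance")) {
  metric <- arg_match(metric)
  dat <- filter(metrics, .data$ok)
  dat$session <- factor(dat$session, levels = unique(metrics$session))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$session, y = .data[[metric]])) +
    ggplot2::geom_violin(fill = "grey90") +
    ggplot2::stat_summary(fun = mean, geom = "point", colour = "red") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}
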