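# End-to-end analyses mirroring the shapes of a reference-plane comparison
# study: cohort plane comparison, observer-reliability study, pre/post
# symmetry assessment. Inputs may be landmark_set objects or file paths;
# outputs are CSV/JSON files stamped with the package version and a config
# hash so reruns are auditable.

.config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967291)
}

.stamp_header <- function(cfg) {
  sprintf("# cephaloplane %s config_hash=%s",
          as.character(utils::packageVersion("cephaloplane")),
          .config_hash(cfg))
}

.write_stamped_csv <- function(df, path, header) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

.as_landmark_sets <- function(x) {
  if (inherits(x, "landmark_set")) return(list(x))
  lapply(x, function(el) {
    if (inherits(el, "landmark_set")) el
    else if (is.character(el)) {
      tryCatch(read_landmarks(el), parse_error = function(e) {
        stop_parse(sprintf("%s: %s", el, conditionMessage(e)))
      })
    } else stop_usage("inputs must be landmark_set objects or file paths")
  })
}

#' Cohort comparison of the five reference planes
#'
#' For every subject, builds the five horizontal planes and the bilateral
#' dental difference metrics (U3, U6, L3, L6); summarises each
#' (plane, metric) cell as mean and SD across the cohort; and tests each
#' metric for differences among the five planes with the Friedman rank test
#' (blocks = subjects, treatments = planes).
#'
#' @param subjects List of [landmark_set()]s or file paths (>= 2 subjects).
#' @param out_dir Output directory; two CSVs (`plane_comparison_long.csv`,
#'   `plane_comparison_wide.csv`) and `plane_comparison_friedman.json` are
#'   written when supplied.
#' @param label Group label for the summary.
#' @param alpha Significance level recorded alongside each Friedman p-value.
#' @return List with `summary` ([summarize_cohort()] result), `wide`
#'   (mean±SD table), `friedman` (named list of [friedman_test()] results,
#'   one per metric), `n`.
#' @export
run_plane_comparison <- function(subjects, out_dir = NULL, label = "",
                                 alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_usage("alpha must be in (0, 1)")
  sets <- .as_landmark_sets(subjects)
  if (length(sets) < 2L) stop_usage("plane comparison needs >= 2 subjects")
  reports <- lapply(sets, function(ls) {
    bilateral_differences(ls, build_horizontal_planes(ls))
  })
  summ <- summarize_cohort(reports, label = label)
  metrics <- unique(reports[[1]]$metric)
  planes <- unique(reports[[1]]$plane)
  fried <- lapply(metrics, function(m) {
    blocks <- t(vapply(reports, function(r) {
      stats::setNames(r$value[r$metric == m], r$plane[r$metric == m])[planes]
    }, numeric(length(planes))))
    ft <- friedman_test(blocks)
    ft$significant <- ft$p_value < alpha
    ft
  })
  names(fried) <- metrics
  cfg <- list(analysis = "plane_comparison", n = length(sets), label = label,
              alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- .stamp_header(cfg)
    long <- do.call(rbind, Map(function(r, i) {
      cbind(subject = if (nzchar(attr(r, "subject_id"))) attr(r, "subject_id")
            else sprintf("S%02d", i), r)
    }, reports, seq_along(reports)))
    .write_stamped_csv(long, file.path(out_dir, "plane_comparison_long.csv"), hdr)
    .write_stamped_csv(cohort_summary_wide(summ),
                       file.path(out_dir, "plane_comparison_wide.csv"), hdr)
    jsonlite::write_json(
      c(list(package = as.character(utils::packageVersion("cephaloplane")),
             config_hash = .config_hash(cfg)),
        lapply(fried, unclass)),
      file.path(out_dir, "plane_comparison_friedman.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(summary = summ, wide = cohort_summary_wide(summ), friedman = fried,
       n = length(sets))
}

#' Observer-reliability study
#'
#' Runs [landmark_reliability()] in both intraobserver (trial 1 vs trial 2
#' per observer) and interobserver (observer vs observer, trial-matched)
#' modes and writes the wide per-axis reliability tables.
#'
#' @param trials List of [landmark_set()]s (or file paths) carrying subject,
#'   observer and trial metadata.
#' @param out_dir Output directory; `reliability_intraobserver.csv` and
#'   `reliability_interobserver.csv` are written when supplied.
#' @param landmarks Landmarks to analyse (default: common to all sets).
#' @return List with `intraobserver` and `interobserver`
#'   [landmark_reliability()] reports.
#' @export
run_reliability <- function(trials, out_dir = NULL, landmarks = NULL) {
  sets <- .as_landmark_sets(trials)
  obs <- unique(vapply(sets, function(s) s$observer, ""))
  if (length(obs) < 2L) {
    stop_usage("interobserver reliability needs two observers in the input")
  }
  intra <- landmark_reliability(sets, "intraobserver", landmarks = landmarks)
  inter <- landmark_reliability(sets, "interobserver", landmarks = landmarks)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_reliability_csv(intra, file.path(out_dir, "reliability_intraobserver.csv"))
    write_reliability_csv(inter, file.path(out_dir, "reliability_interobserver.csv"))
  }
  list(intraobserver = intra, interobserver = inter)
}

#' Pre/post facial symmetry assessment
#'
#' Computes the signed midline offsets of ANS, UI, LI, Pog and Me to the
#' four FHP-derived midsagittal planes for the pre- and postoperative
#' landmark sets, and tests for differences among the planes with the
#' Friedman rank test (blocks = midline landmarks, treatments = planes,
#' absolute offsets).
#'
#' @param pre,post [landmark_set()]s (or file paths) for one subject.
#' @param out_dir Output directory; `symmetry_preop.csv`,
#'   `symmetry_postop.csv` and `symmetry_friedman.json` are written when
#'   supplied.
#' @param alpha Significance level recorded with the Friedman p-values.
#' @return List with `pre`, `post` (wide signed-offset tables), `reports`
#'   (the long [midline_offsets()] reports) and `friedman` (per session).
#' @export
run_symmetry_assessment <- function(pre, post, out_dir = NULL, alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_usage("alpha must be in (0, 1)")
  pre <- .as_landmark_sets(pre)[[1]]
  post <- .as_landmark_sets(post)[[1]]
  reports <- lapply(list(pre = pre, post = post), function(ls) {
    midline_offsets(ls, build_reference_planes(ls))
  })
  fried <- lapply(reports, function(r) {
    w <- midline_offsets_wide(r)
    ft <- friedman_test(abs(as.matrix(w[, -1])))
    ft$significant <- ft$p_value < alpha
    ft
  })
  cfg <- list(analysis = "symmetry", subject = pre$subject_id, alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    hdr <- .stamp_header(cfg)
    .write_stamped_csv(midline_offsets_wide(reports$pre),
                       file.path(out_dir, "symmetry_preop.csv"), hdr)
    .write_stamped_csv(midline_offsets_wide(reports$post),
                       file.path(out_dir, "symmetry_postop.csv"), hdr)
    jsonlite::write_json(
      c(list(package = as.character(utils::packageVersion("cephaloplane")),
             config_hash = .config_hash(cfg)),
        lapply(fried, unclass)),
      file.path(out_dir, "symmetry_friedman.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(pre = midline_offsets_wide(reports$pre),
       post = midline_offsets_wide(reports$post),
       reports = reports, friedman = fried)
}
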