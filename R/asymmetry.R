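# Bilateral distance-asymmetry metrics and signed midline symmetry offsets.

.metric_pairs <- list(
  U3 = c(left = "UL3", right = "UR3"),
  U6 = c(left = "UL6", right = "UR6"),
  L3 = c(left = "LL3", right = "LR3"),
  L6 = c(left = "LL6", right = "LR6")
)

.midline_probe_landmarks <- c("ANS", "UI", "LI", "Pog", "Me")

#' Bilateral dental distance differences (U3, U6, L3, L6)
#'
#' For each horizontal reference plane, the difference between the left and
#' right tooth's distance to the plane: U3 compares the maxillary canines
#' (UL3 vs UR3), U6 the maxillary first molars, L3/L6 the mandibular
#' counterparts. By default the absolute difference of unsigned distances is
#' reported (a nonnegative asymmetry magnitude); `signed = TRUE` keeps the
#' left-minus-right sign.
#'
#' @param ls A [landmark_set()] with the eight dental landmarks.
#' @param planes Result of [build_reference_planes()] or
#'   [build_horizontal_planes()].
#' @param signed Keep the left-minus-right sign instead of taking the
#'   absolute value.
#' @return An `asymmetry_report` data frame with columns `plane`, `metric`,
#'   `value` (mm) and attributes `subject_id`, `session`.
#' @export
bilateral_differences <- function(ls, planes, signed = FALSE) {
  horiz <- if (inherits(planes, "reference_plane_set")) planes$horizontal else planes
  require_landmarks(ls, unlist(.metric_pairs, use.names = FALSE))
  rows <- list()
  for (pn in names(horiz)) {
    pl <- horiz[[pn]]
    for (mn in names(.metric_pairs)) {
      pr <- .metric_pairs[[mn]]
      dl <- point_plane_distance(ls$points[pr["left"], ], pl)
      dr <- point_plane_distance(ls$points[pr["right"], ], pl)
      v <- dl - dr
      rows[[length(rows) + 1L]] <- data.frame(
        plane = pn, metric = mn, value = if (signed) v else abs(v),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "subject_id") <- ls$subject_id
  attr(out, "session") <- ls$session
  attr(out, "signed") <- signed
  class(out) <- c("asymmetry_report", class(out))
  out
}

#' Signed midline offsets to the derived midsagittal planes
#'
#' Signed distance of each midline landmark (ANS, UI, LI, Pog, Me) to the
#' midsagittal plane derived from each horizontal reference plane. Positive
#' values mean the landmark lies on the subject's right of the midsagittal
#' plane. By default only the four FHP-derived midsagittal planes are
#' reported; `include_lsp = TRUE` adds the LSP-derived one.
#'
#' @param ls A [landmark_set()] with ANS, UI, LI, Pog, Me (plus N, Ba used
#'   when `planes` must be built).
#' @param planes A [build_reference_planes()] result.
#' @param landmarks Midline landmarks to report.
#' @param include_lsp Also report the LSP-derived midsagittal plane.
#' @return A `midline_offset_report` data frame with columns `plane`
#'   (the horizontal plane the midsagittal plane was derived from),
#'   `landmark`, `offset` (signed mm).
#' @export
midline_offsets <- function(ls, planes, landmarks = .midline_probe_landmarks,
                            include_lsp = FALSE) {
  if (!inherits(planes, "reference_plane_set")) {
    stop_usage("`planes` must be a reference_plane_set (need midsagittal planes)")
  }
  require_landmarks(ls, landmarks)
  keep <- if (include_lsp) names(planes$midsagittal) else
    intersect(names(planes$midsagittal), horizontal_plane_names(fhp_only = TRUE))
  rows <- list()
  for (pn in keep) {
    ms <- planes$midsagittal[[pn]]
    off <- point_plane_distance(ls$points[landmarks, , drop = FALSE], ms,
                                signed = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      plane = pn, landmark = landmarks, offset = unname(off),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "subject_id") <- ls$subject_id
  attr(out, "session") <- ls$session
  class(out) <- c("midline_offset_report", class(out))
  out
}

#' Chin-deviation asymmetry classification
#'
#' Classifies a subject as facially asymmetric when the chin (menton)
#' deviates from the midsagittal plane by more than a threshold, 4 mm by
#' default — the clinical cut-off used for physical-examination grouping.
#'
#' @param me_offset_mm Signed menton midline offset (mm), e.g. the `Me` row
#'   of [midline_offsets()].
#' @param threshold_mm Deviation magnitude above which the face is called
#'   asymmetric.
#' @return Logical: `TRUE` if `|me_offset_mm| > threshold_mm`.
#' @export
classify_asymmetry <- function(me_offset_mm, threshold_mm = 4.0) {
  abs(me_offset_mm) > threshold_mm
}

#' Cohort summary of asymmetry reports
#'
#' Sample mean and standard deviation (n - 1 denominator) of each
#' (plane, metric) cell across subjects.
#'
#' @param reports List of [bilateral_differences()] reports (at least two)
#'   sharing the same plane/metric grid.
#' @param label Optional group label stored on the result.
#' @return A `cohort_summary` data frame with columns `plane`, `metric`,
#'   `mean`, `sd`, `n`.
#' @export
summarize_cohort <- function(reports, label = "") {
  if (!length(reports)) stop_usage("no asymmetry reports supplied")
  if (length(reports) < 2L) {
    stop_usage("cohort summary needs at least 2 subjects")
  }
  key0 <- paste(reports[[1]]$plane, reports[[1]]$metric)
  vals <- sapply(reports, function(r) {
    if (!identical(paste(r$plane, r$metric), key0)) {
      stop_usage("all reports must share the same plane/metric grid")
    }
    r$value
  })
  out <- data.frame(plane = reports[[1]]$plane, metric = reports[[1]]$metric,
                    mean = rowMeans(vals),
                    sd = apply(vals, 1L, stats::sd),
                    n = length(reports), stringsAsFactors = FALSE)
  attr(out, "label") <- label
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Write a tidy (long) asymmetry CSV
#'
#' One row per (subject, session, plane, metric) with its value in mm.
#'
#' @param reports A single report or list of reports from
#'   [bilateral_differences()] and/or [midline_offsets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_asymmetry_csv <- function(reports, path) {
  if (inherits(reports, "data.frame")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    if (inherits(r, "midline_offset_report")) {
      data.frame(subject_id = attr(r, "subject_id"), session = attr(r, "session"),
                 plane = r$plane, metric = paste0("offset_", r$landmark),
                 value = r$offset, stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = attr(r, "subject_id"), session = attr(r, "session"),
                 plane = r$plane, metric = r$metric, value = r$value,
                 stringsAsFactors = FALSE)
    }
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Reshape a cohort summary to the wide mean±SD layout
#'
#' One row per plane, one `Mean±SD` column per metric — the layout used in
#' published cross-plane comparison tables.
#'
#' @param summary A [summarize_cohort()] result.
#' @param digits Digits for the formatted mean and SD.
#' @return A data frame with a `plane` column and one character column per
#'   metric.
#' @export
cohort_summary_wide <- function(summary, digits = 2) {
  metrics <- unique(summary$metric)
  planes <- unique(summary$plane)
  out <- data.frame(plane = planes, stringsAsFactors = FALSE)
  for (m in metrics) {
    sub <- summary[summary$metric == m, ]
    out[[m]] <- sprintf(paste0("%.", digits, "f±%.", digits, "f"),
                        sub$mean[match(planes, sub$plane)],
                        sub$sd[match(planes, sub$plane)])
  }
  out
}

#' Reshape midline offsets to the wide per-plane layout
#'
#' One row per midline landmark, one signed-offset column per FHP-derived
#' midsagittal plane.
#'
#' @param report A [midline_offsets()] result.
#' @return A data frame with a `landmark` column and one numeric column per
#'   plane.
#' @export
midline_offsets_wide <- function(report) {
  planes <- unique(report$plane)
  lms <- unique(report$landmark)
  out <- data.frame(landmark = lms, stringsAsFactors = FALSE)
  for (p in planes) {
    sub <- report[report$plane == p, ]
    out[[p]] <- sub$offset[match(lms, sub$landmark)]
  }
  out
}
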