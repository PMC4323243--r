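# Controlled landmark vocabulary, validated landmark containers, CSV/JSON I/O.

.paired_landmarks <- list(
  Or = c(right = "OrR", left = "OrL"),
  Po = c(right = "PoR", left = "PoL"),
  Ls = c(right = "LsR", left = "LsL"),
  U3 = c(right = "UR3", left = "UL3"),
  U6 = c(right = "UR6", left = "UL6"),
  L3 = c(right = "LR3", left = "LL3"),
  L6 = c(right = "LR6", left = "LL6")
)

.midline_landmarks <- c("N", "Ba", "ANS", "UI", "LI", "Pog", "Me")

.derived_landmarks <- c("OrA", "PoA")

#' Landmark vocabulary
#'
#' The controlled set of 3D cephalometric landmark names understood by the
#' package: paired orbitale (OrR/OrL), porion (PoR/PoL), lateral semicircular
#' canal (LsR/LsL), dental canines and first molars (UR3/UL3, LR3/LL3,
#' UR6/UL6, LR6/LL6), midline landmarks (nasion N, basion Ba, anterior nasal
#' spine ANS, incisor midpoints UI/LI, pogonion Pog, menton Me) and the
#' derived averaged orbitale/porion midpoints (OrA/PoA), which are computed
#' rather than digitised.
#'
#' @param include_derived Include the derived midpoint names OrA and PoA.
#' @return Character vector of landmark names.
#' @export
landmark_vocabulary <- function(include_derived = TRUE) {
  v <- c(unlist(.paired_landmarks, use.names = FALSE), .midline_landmarks)
  if (include_derived) v <- c(v, .derived_landmarks)
  unname(v)
}

#' Create a validated landmark set
#'
#' A landmark set holds the named 3D coordinates (mm) digitised for one
#' subject in one session by one observer in one trial.
#'
#' @param points Named list of length-3 numeric vectors, or an n x 3 numeric
#'   matrix with landmark names as rownames.
#' @param subject_id,session,observer Character metadata (free text; `session`
#'   is conventionally `"preop"` or `"postop"`).
#' @param trial Integer trial number (repeat digitisations).
#' @return Object of class `landmark_set`: a list with a `points` matrix
#'   (rownames = landmark names, columns x/y/z) and the metadata fields.
#' @export
landmark_set <- function(points, subject_id = "", session = "",
                         observer = "", trial = 1L) {
  if (is.list(points) && !is.data.frame(points)) {
    nm <- names(points)
    points <- do.call(rbind, lapply(points, function(p) as.numeric(p)))
    rownames(points) <- nm
  }
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop_usage("landmark points must have 3 coordinates")
  nm <- rownames(points)
  if (is.null(nm)) stop_usage("landmark points must be named")
  unknown <- setdiff(nm, landmark_vocabulary())
  if (length(unknown)) {
    stop_parse(sprintf("unknown landmark name(s): %s",
                       paste(unknown, collapse = ", ")))
  }
  dup <- nm[duplicated(nm)]
  if (length(dup)) {
    stop_parse(sprintf("duplicate landmark name(s): %s",
                       paste(unique(dup), collapse = ", ")))
  }
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) stop_parse("non-finite landmark coordinate")
  colnames(points) <- c("x", "y", "z")
  structure(list(points = points,
                 subject_id = as.character(subject_id),
                 session = as.character(session),
                 observer = as.character(observer),
                 trial = as.integer(trial)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks", nrow(x$points)))
  meta <- c(subject = x$subject_id, session = x$session, observer = x$observer)
  meta <- meta[nzchar(meta)]
  if (length(meta)) {
    cat(" | ", paste(sprintf("%s=%s", names(meta), meta), collapse = ", "),
        sprintf(", trial=%d", x$trial), sep = "")
  }
  cat("\n")
  print(round(x$points, 3))
  invisible(x)
}

landmark_names <- function(ls) rownames(ls$points)

#' Check that required landmarks are present
#'
#' @param ls A [landmark_set()].
#' @param names Character vector of required landmark names (may be empty).
#' @return `ls`, invisibly; raises a `missing_landmark_error` naming every
#'   absent landmark otherwise.
#' @export
require_landmarks <- function(ls, names) {
  missing <- setdiff(names, landmark_names(ls))
  if (length(missing)) stop_missing_landmark(missing)
  invisible(ls)
}

#' Get one landmark's coordinates
#' @param ls A [landmark_set()].
#' @param name Landmark name.
#' @return Length-3 numeric vector (mm).
#' @export
landmark_point <- function(ls, name) {
  require_landmarks(ls, name)
  ls$points[name, ]
}

#' Add derived midpoint landmarks OrA and PoA
#'
#' OrA is the midpoint of the right and left orbitale, PoA the midpoint of
#' the right and left porion. Idempotent: existing OrA/PoA entries are
#' recomputed from the paired landmarks.
#'
#' @param ls A [landmark_set()] containing OrR, OrL, PoR, PoL.
#' @return A copy of `ls` with OrA and PoA set.
#' @export
with_derived_midpoints <- function(ls) {
  require_landmarks(ls, c("OrR", "OrL", "PoR", "PoL"))
  pts <- ls$points[setdiff(landmark_names(ls), .derived_landmarks), , drop = FALSE]
  pts <- rbind(pts,
               OrA = midpoint3(ls$points["OrR", ], ls$points["OrL", ]),
               PoA = midpoint3(ls$points["PoR", ], ls$points["PoL", ]))
  out <- ls
  out$points <- pts
  out
}

#' Rigidly transform a landmark set
#' @param ls A [landmark_set()].
#' @param transform A [rigid_transform()].
#' @return The transformed [landmark_set()].
#' @export
transform_landmarks <- function(ls, transform) {
  out <- ls
  pts <- apply_rigid(transform, ls$points)
  dimnames(pts) <- dimnames(ls$points)
  out$points <- pts
  out
}

#' Mirror a landmark set about a plane
#'
#' Reflects every coordinate about the given plane. Used to test symmetry
#' properties (signed midline offsets must negate, unsigned metrics must be
#' preserved). Note reflection is not a rigid motion.
#'
#' @param ls A [landmark_set()].
#' @param plane A [plane3()]; defaults to the X = 0 plane.
#' @return The reflected [landmark_set()].
#' @export
reflect_landmarks <- function(ls, plane = plane3(c(1, 0, 0), 0)) {
  s <- point_plane_distance(ls$points, plane, signed = TRUE)
  out <- ls
  pts <- ls$points - 2 * outer(s, plane$normal)
  dimnames(pts) <- dimnames(ls$points)
  out$points <- pts
  out
}

## ---- file I/O -------------------------------------------------------------

#' Read a landmark set from CSV or JSON
#'
#' CSV dialect: comma-separated, UTF-8, decimal point, header row
#' `name,x,y,z` with optional extra columns `subject_id`, `session`,
#' `observer`, `trial` (constant per file). JSON: an object with optional
#' metadata fields and a `points` object mapping landmark name to an
#' `[x, y, z]` array. Units are millimetres. The derived names OrA/PoA are
#' rejected on input; they are computed, never digitised.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A [landmark_set()].
#' @export
read_landmarks <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_usage(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") .read_landmarks_json(path) else .read_landmarks_csv(path)
}

.meta_or <- function(x, default) if (is.null(x) || !length(x)) default else x[[1]]

.read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df))) {
    stop_parse(sprintf("CSV must have columns %s; found: %s",
                       paste(need, collapse = ","),
                       paste(names(df), collapse = ",")))
  }
  if (!nrow(df)) stop_parse("no landmark rows")
  seen <- character(0)
  pts <- matrix(NA_real_, nrow(df), 3L,
                dimnames = list(df$name, c("x", "y", "z")))
  vocab <- setdiff(landmark_vocabulary(), .derived_landmarks)
  for (i in seq_len(nrow(df))) {
    nm <- df$name[i]
    if (!nm %in% vocab) {
      stop_parse(sprintf("unknown landmark name \"%s\"", nm), row = i)
    }
    if (nm %in% seen) stop_parse(sprintf("duplicate landmark \"%s\"", nm), row = i)
    seen <- c(seen, nm)
    xyz <- suppressWarnings(as.numeric(c(df$x[i], df$y[i], df$z[i])))
    if (any(!is.finite(xyz))) {
      stop_parse(sprintf("non-numeric coordinate for \"%s\"", nm), row = i)
    }
    pts[i, ] <- xyz
  }
  landmark_set(pts,
               subject_id = .meta_or(df$subject_id, ""),
               session = .meta_or(df$session, ""),
               observer = .meta_or(df$observer, ""),
               trial = as.integer(.meta_or(df$trial, 1L)))
}

.read_landmarks_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$points)) stop_parse("JSON landmark file must have a `points` object")
  vocab <- setdiff(landmark_vocabulary(), .derived_landmarks)
  pts <- list()
  for (nm in names(obj$points)) {
    if (!nm %in% vocab) stop_parse(sprintf("unknown landmark name \"%s\"", nm))
    xyz <- suppressWarnings(as.numeric(unlist(obj$points[[nm]])))
    if (length(xyz) != 3L || any(!is.finite(xyz))) {
      stop_parse(sprintf("invalid coordinates for \"%s\"", nm))
    }
    pts[[nm]] <- xyz
  }
  landmark_set(pts,
               subject_id = .meta_or(obj$subject_id, ""),
               session = .meta_or(obj$session, ""),
               observer = .meta_or(obj$observer, ""),
               trial = as.integer(.meta_or(obj$trial, 1L)))
}

#' Write a landmark set to CSV or JSON
#'
#' Emits the same dialect that [read_landmarks()] accepts; a write/read
#' round trip reproduces coordinates to full double precision. Derived
#' OrA/PoA entries are dropped on output.
#'
#' @param ls A [landmark_set()].
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(ls, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  keep <- setdiff(landmark_names(ls), .derived_landmarks)
  pts <- ls$points[keep, , drop = FALSE]
  if (format == "csv") {
    df <- data.frame(name = rownames(pts),
                     x = sprintf("%.17g", pts[, 1]),
                     y = sprintf("%.17g", pts[, 2]),
                     z = sprintf("%.17g", pts[, 3]),
                     subject_id = ls$subject_id, session = ls$session,
                     observer = ls$observer, trial = ls$trial,
                     stringsAsFactors = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    obj <- list(subject_id = ls$subject_id, session = ls$session,
                observer = ls$observer, trial = ls$trial,
                points = stats::setNames(
                  lapply(rownames(pts), function(nm) unname(pts[nm, ])),
                  rownames(pts)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
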