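# The five landmark-oriented horizontal reference planes and the derived
# midsagittal planes.
#
# Four Frankfort horizontal plane (FHP) variants arise from the four
# orbitale/porion landmarks because three points define a plane: either one
# of the four points is omitted (FHP-L, FHP-R) or a bilateral pair is
# averaged (FHP-P uses the porion midpoint, FHP-O the orbitale midpoint).
# The fifth horizontal plane (LSP) passes through both lateral semicircular
# canal points and nasion. Each midsagittal plane contains nasion and basion
# and is perpendicular to one chosen horizontal plane.

.horizontal_defs <- list(
  FHP_P = c("PoA", "OrR", "OrL"),
  FHP_O = c("OrA", "PoR", "PoL"),
  FHP_L = c("PoL", "OrR", "OrL"),
  FHP_R = c("PoR", "OrR", "OrL"),
  LSP   = c("LsR", "LsL", "N")
)

#' Names of the horizontal reference planes
#' @param fhp_only If `TRUE`, only the four FHP variants (omitting LSP).
#' @return Character vector.
#' @export
horizontal_plane_names <- function(fhp_only = FALSE) {
  nm <- names(.horizontal_defs)
  if (fhp_only) setdiff(nm, "LSP") else nm
}

#' Build the five horizontal reference planes
#'
#' Constructs FHP-P (PoA, OrR, OrL), FHP-O (OrA, PoR, PoL), FHP-L (PoL, OrR,
#' OrL), FHP-R (PoR, OrR, OrL) and LSP (LsR, LsL, N) from a landmark set.
#' The averaged midpoints OrA/PoA are derived internally. Normals are
#' oriented superiorly (positive Y).
#'
#' @param ls A [landmark_set()] containing OrR, OrL, PoR, PoL, LsR, LsL, N.
#' @return Named list of [plane3()] objects, one per plane, each carrying a
#'   `"defined_by"` attribute with its three landmark names.
#' @export
build_horizontal_planes <- function(ls) {
  require_landmarks(ls, c("OrR", "OrL", "PoR", "PoL", "LsR", "LsL", "N"))
  ls <- with_derived_midpoints(ls)
  out <- lapply(names(.horizontal_defs), function(nm) {
    def <- .horizontal_defs[[nm]]
    pl <- plane_from_points(ls$points[def[1], ], ls$points[def[2], ],
                            ls$points[def[3], ],
                            orient = "superior", labels = def)
    attr(pl, "defined_by") <- def
    pl
  })
  stats::setNames(out, names(.horizontal_defs))
}

#' Build a midsagittal plane from nasion, basion and a horizontal plane
#'
#' The midsagittal plane is the unique plane passing through nasion (N) and
#' basion (Ba) and perpendicular to the chosen horizontal plane; its normal
#' is `cross(horizontal normal, Ba - N)`, sign-fixed to point toward the
#' subject's right (positive X), so that positive signed offsets mean a
#' landmark lies on the subject's right of the midline.
#'
#' @param ls A [landmark_set()] containing N and Ba.
#' @param horizontal A horizontal reference [plane3()].
#' @param eps_ang Degeneracy threshold (radians): the N-to-Ba direction must
#'   make an angle greater than this with the horizontal normal.
#' @return A [plane3()].
#' @export
build_midsagittal <- function(ls, horizontal, eps_ang = 1e-6) {
  require_landmarks(ls, c("N", "Ba"))
  if (!is_plane(horizontal)) stop_usage("`horizontal` must be a ceph_plane")
  N <- ls$points["N", ]; Ba <- ls$points["Ba", ]
  d <- Ba - N
  dn <- sqrt(sum(d^2))
  if (dn < 1e-9) stop_degenerate("N and Ba coincide")
  n <- cross3(horizontal$normal, d)
  if (sqrt(sum(n^2)) / dn < sin(eps_ang)) {
    stop_degenerate("Ba - N is (near-)parallel to the horizontal plane normal")
  }
  n <- n / sqrt(sum(n^2))
  if (n[1] < 0) n <- -n
  plane3(n, sum(n * N))
}

#' Build the full set of reference planes for one subject
#'
#' @param ls A [landmark_set()] with the plane landmarks plus Ba.
#' @return Object of class `reference_plane_set`: a list with `horizontal`
#'   (five named [plane3()]s) and `midsagittal` (one per horizontal plane it
#'   was derived from, same names). Midsagittal planes derived from the four
#'   FHPs are the conventional symmetry references; the LSP-derived one is
#'   included for completeness and excluded from FHP-shaped reports.
#' @export
build_reference_planes <- function(ls) {
  require_landmarks(ls, c("Ba"))
  horiz <- build_horizontal_planes(ls)
  mids <- lapply(horiz, function(h) build_midsagittal(ls, h))
  structure(list(horizontal = horiz, midsagittal = mids,
                 subject_id = ls$subject_id, session = ls$session),
            class = "reference_plane_set")
}

#' @export
print.reference_plane_set <- function(x, ...) {
  cat("<reference_plane_set>",
      if (nzchar(x$subject_id)) sprintf("subject=%s", x$subject_id) else "",
      if (nzchar(x$session)) sprintf("session=%s", x$session) else "", "\n")
  for (nm in names(x$horizontal)) {
    h <- x$horizontal[[nm]]
    cat(sprintf("  %-6s normal (%+.4f, %+.4f, %+.4f) offset %8.3f  [%s]\n",
                nm, h$normal[1], h$normal[2], h$normal[3], h$offset,
                paste(attr(h, "defined_by"), collapse = ", ")))
  }
  cat(sprintf("  + %d derived midsagittal planes (N, Ba, perpendicular to each)\n",
              length(x$midsagittal)))
  invisible(x)
}

#' Vertical-distance discrepancy between two reference planes
#'
#' For each probe landmark, the absolute difference between its unsigned
#' distances to the two planes — how much the choice of reference plane
#' changes a measured vertical distance.
#'
#' @param ls A [landmark_set()].
#' @param a,b [plane3()] objects.
#' @param probes Character vector of probe landmark names (default: the
#'   eight dental landmarks).
#' @return Named numeric vector of discrepancies (mm), one per probe.
#' @export
plane_pair_discrepancy <- function(ls, a, b, probes = dental_landmarks()) {
  require_landmarks(ls, probes)
  p <- ls$points[probes, , drop = FALSE]
  abs(point_plane_distance(p, a) - point_plane_distance(p, b))
}

#' The eight dental probe landmarks
#'
#' Canine cusps and first-molar mesio-buccal cusps on both sides of both
#' arches, used for occlusal-cant style bilateral comparisons.
#' @return Character vector of eight names.
#' @export
dental_landmarks <- function() {
  c("UL3", "UR3", "UL6", "UR6", "LL3", "LR3", "LL6", "LR6")
}

#' Export a reference plane set to JSON
#'
#' Writes each plane's unit normal, offset and defining landmark names.
#'
#' @param rps A [build_reference_planes()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_planes_json <- function(rps, path) {
  enc <- function(pl, parent = NULL) {
    out <- list(normal = unname(pl$normal), offset = pl$offset)
    def <- attr(pl, "defined_by")
    if (!is.null(def)) out$defined_by <- def
    if (!is.null(parent)) out$perpendicular_to <- parent
    out
  }
  obj <- list(
    subject_id = rps$subject_id, session = rps$session,
    horizontal = lapply(rps$horizontal, enc),
    midsagittal = stats::setNames(
      lapply(names(rps$midsagittal),
             function(nm) enc(rps$midsagittal[[nm]], parent = nm)),
      names(rps$midsagittal))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
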