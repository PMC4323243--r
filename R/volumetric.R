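# Cranial-base superimposition, plane-bounded region extraction, voxel
# volume differencing, and the soft-to-hard tissue average-movement ratio.

#' Default cranial-base landmark basis for superimposition
#'
#' Landmarks on or near the cranial base, which orthognathic surgery does not
#' move, so pre/post registration on them isolates the surgical change.
#' @return Character vector: N, Ba, PoR, PoL, LsR, LsL.
#' @export
cranial_base_landmarks <- function() c("N", "Ba", "PoR", "PoL", "LsR", "LsL")

#' Superimpose postoperative models onto the preoperative frame
#'
#' Estimates the rigid motion mapping the postoperative cranial-base
#' landmarks onto the preoperative ones ([kabsch_superimpose()]) and applies
#' it to every supplied postoperative surface model.
#'
#' @param pre,post [landmark_set()]s for the two sessions, both containing
#'   the basis landmarks.
#' @param models List of postoperative [surface_model()]s to transform (may
#'   be a single model).
#' @param basis Landmark names used for registration (>= 3, non-collinear).
#' @return List with `models` (transformed, same order), `transform` (the
#'   [rigid_transform()]) and `rmsd` (mm, residual on the basis landmarks).
#' @export
superimpose_models <- function(pre, post, models,
                               basis = cranial_base_landmarks()) {
  if (length(basis) < 3L) {
    stop_degenerate(sprintf("superimposition basis needs >= 3 landmarks, got %d",
                            length(basis)))
  }
  require_landmarks(pre, basis)
  require_landmarks(post, basis)
  fit <- kabsch_superimpose(post$points[basis, , drop = FALSE],
                            pre$points[basis, , drop = FALSE])
  if (inherits(models, "surface_model")) models <- list(models)
  list(models = lapply(models, transform_mesh, transform = fit$transform),
       transform = fit$transform, rmsd = fit$rmsd)
}

## ---- region specifications ------------------------------------------------

#' Plane-bounded region specification
#'
#' A facial region is the intersection of half-spaces, each given by a plane
#' and the side of it to keep (`+1`: keep where the signed distance is
#' nonnegative, `-1`: the other side).
#'
#' @param name Region name (e.g. `"chin"`).
#' @param halfspaces List of `list(plane = <plane3>, side = +1 or -1)`.
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(name, halfspaces) {
  if (!length(halfspaces)) stop_usage("a region needs at least one half-space")
  for (h in halfspaces) {
    if (!is_plane(h$plane) || !h$side %in% c(-1, 1)) {
      stop_usage("each half-space must be list(plane = <plane3>, side = +-1)")
    }
  }
  structure(list(name = name, halfspaces = halfspaces), class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("<region_spec> \"%s\": %d half-space(s)\n", x$name,
              length(x$halfspaces)))
  invisible(x)
}

# Plane parallel to `plane` passing through `point`.
plane_through_point <- function(plane, point) {
  plane3(plane$normal, sum(plane$normal * as.numeric(point)))
}

#' Default facial region specifications
#'
#' Package conventions (not clinical standards) for the four regions used in
#' soft-to-hard movement analysis, built from a subject's reference planes
#' and landmarks. With horizontal plane H and its derived midsagittal plane
#' M: the *chin* is everything below the H-parallel plane through the lower
#' incisor (LI); the *right/left mandible* are below the H-parallel plane
#' through the maxillary molars and right/left of M; the *lower lip* is the
#' slab between the H-parallel planes through LI and Me, anterior of the
#' M-and-H-perpendicular plane through Pog.
#'
#' @param ls A [landmark_set()] with LI, Me, Pog, UR6, UL6.
#' @param planes A [build_reference_planes()] result.
#' @param plane Name of the horizontal plane anchoring the borders.
#' @return Named list of [region_spec()]s: chin, right_mandible,
#'   left_mandible, lower_lip.
#' @export
default_regions <- function(ls, planes, plane = "FHP_P") {
  require_landmarks(ls, c("LI", "Me", "Pog", "UR6", "UL6"))
  H <- planes$horizontal[[plane]]
  M <- planes$midsagittal[[plane]]
  li_pl <- plane_through_point(H, ls$points["LI", ])
  me_pl <- plane_through_point(H, ls$points["Me", ])
  occ_pl <- plane_through_point(H, midpoint3(ls$points["UR6", ], ls$points["UL6", ]))
  ant_n <- cross3(H$normal, M$normal)            # anterior-posterior direction
  ant_n <- ant_n / sqrt(sum(ant_n^2))
  if (ant_n[3] < 0) ant_n <- -ant_n              # point anteriorly
  pog_pl <- plane3(ant_n, sum(ant_n * ls$points["Pog", ]) - 20)  # 20 mm behind Pog
  list(
    chin = region_spec("chin", list(list(plane = li_pl, side = -1))),
    right_mandible = region_spec("right_mandible", list(
      list(plane = occ_pl, side = -1), list(plane = M, side = 1))),
    left_mandible = region_spec("left_mandible", list(
      list(plane = occ_pl, side = -1), list(plane = M, side = -1))),
    lower_lip = region_spec("lower_lip", list(
      list(plane = li_pl, side = -1), list(plane = me_pl, side = 1),
      list(plane = pog_pl, side = 1)))
  )
}

#' Read region specifications from YAML
#'
#' Layout: a top-level `regions` list, each with `name` and a `halfspaces`
#' list of `{normal: [x,y,z], offset: d, side: +-1}` entries.
#'
#' @param path YAML file path.
#' @return Named list of [region_spec()]s.
#' @export
read_regions_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  if (is.null(obj$regions)) stop_parse("YAML must have a top-level `regions` list")
  out <- lapply(obj$regions, function(r) {
    hs <- lapply(r$halfspaces, function(h) {
      list(plane = plane3(as.numeric(h$normal), as.numeric(h$offset)),
           side = as.numeric(h$side))
    })
    region_spec(r$name, hs)
  })
  stats::setNames(out, vapply(out, function(r) r$name, ""))
}

#' Write region specifications to YAML
#' @param regions List of [region_spec()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_yaml <- function(regions, path) {
  obj <- list(regions = lapply(unname(regions), function(r) {
    list(name = r$name, halfspaces = lapply(r$halfspaces, function(h) {
      list(normal = as.numeric(h$plane$normal), offset = h$plane$offset,
           side = h$side)
    }))
  }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

## ---- clipping and volume differencing -------------------------------------

#' Clip a closed model to a plane-bounded region
#'
#' Intersects the model with every half-space of the region, capping each cut
#' so the result stays closed. Cap faces are marked in the result's `cap`
#' field and excluded from anatomical surface-area measurements.
#'
#' @param model A closed [surface_model()].
#' @param region A [region_spec()].
#' @return A closed [surface_model()] (possibly empty, with an
#'   `empty_region_warning`, if the region misses the model).
#' @export
clip_region <- function(model, region) {
  assert_closed(model, "input model")
  out <- model
  for (h in region$halfspaces) {
    out <- clip_mesh_halfspace(out, h$plane, h$side)
    if (!nrow(out$faces)) break
  }
  if (!nrow(out$faces)) {
    ceph_warn("empty_region_warning",
              sprintf("region \"%s\" does not intersect the model", region$name))
  }
  out
}

# Faces lying entirely on one of the region's bounding planes are region
# borders, not anatomy; exclude them (like caps) from surface area.
.on_region_boundary <- function(mesh, region, tol = 1e-6) {
  if (!nrow(mesh$faces)) return(logical(0))
  on_face <- rep(FALSE, nrow(mesh$faces))
  for (h in region$halfspaces) {
    d <- abs(point_plane_distance(mesh$vertices, h$plane, signed = TRUE))
    von <- d <= tol
    on_face <- on_face | (von[mesh$faces[, 1]] & von[mesh$faces[, 2]] &
                            von[mesh$faces[, 3]])
  }
  on_face
}

#' Regional volume difference and average surface movement
#'
#' Clips both (already superimposed) models to the region, voxelizes them on
#' a common grid, and reports the symmetric volume difference (voxels covered
#' by exactly one model), the signed net change, the preoperative anatomical
#' surface area inside the region (clip caps and faces on region borders
#' excluded), and the average movement = volume difference / surface area.
#'
#' @param pre,post Closed [surface_model()]s in a common frame.
#' @param region A [region_spec()].
#' @param voxel_mm Voxel edge length (mm); 0.4 matches typical CBCT
#'   resolution.
#' @param cell_budget Maximum number of grid cells before aborting with
#'   advice to enlarge the voxel.
#' @return A `volume_report_entry` list: `region`, `tissue`, `volume_pre`,
#'   `volume_post`, `volume_difference`, `net_change` (all mm^3),
#'   `region_surface_area` (mm^2), `average_movement` (mm), `voxel_mm`.
#' @export
volume_difference <- function(pre, post, region, voxel_mm = 0.4,
                              cell_budget = 4e7) {
  if (voxel_mm <= 0) stop_usage("voxel_mm must be positive")
  assert_closed(pre, "pre model")
  assert_closed(post, "post model")
  pre_c <- clip_region(pre, region)
  post_c <- suppressWarnings(clip_region(post, region))
  if (!nrow(pre_c$faces) && !nrow(post_c$faces)) {
    return(.volume_entry(region, pre, 0, 0, 0, 0, 0, voxel_mm))
  }
  # common grid covering both clipped models, padded by 2 voxels
  both <- rbind(pre_c$vertices, post_c$vertices)
  lo <- apply(both, 2L, min) - 2 * voxel_mm
  hi <- apply(both, 2L, max) + 2 * voxel_mm
  n_cells <- pmax(1L, as.integer(ceiling((hi - lo) / voxel_mm)))
  mask_pre <- voxelize_mesh(pre_c, lo, n_cells, voxel_mm, cell_budget)
  mask_post <- voxelize_mesh(post_c, lo, n_cells, voxel_mm, cell_budget)
  vox3 <- voxel_mm^3
  n_pre <- sum(mask_pre); n_post <- sum(mask_post)
  diff_n <- sum(xor(mask_pre, mask_post))
  area <- mesh_area_region(pre_c, region)
  .volume_entry(region, pre, n_pre * vox3, n_post * vox3, diff_n * vox3,
                (n_post - n_pre) * vox3, area, voxel_mm)
}

# Anatomical (non-cap, non-border) area of a clipped model.
mesh_area_region <- function(clipped, region) {
  if (!nrow(clipped$faces)) return(0)
  drop_face <- clipped$cap | .on_region_boundary(clipped, region)
  keep <- clipped
  keep$faces <- clipped$faces[!drop_face, , drop = FALSE]
  keep$cap <- clipped$cap[!drop_face]
  mesh_area(keep)
}

.volume_entry <- function(region, pre, v_pre, v_post, v_diff, net, area, voxel) {
  structure(list(region = region$name, tissue = pre$tissue,
                 volume_pre = v_pre, volume_post = v_post,
                 volume_difference = v_diff, net_change = net,
                 region_surface_area = area,
                 average_movement = if (area > 0) v_diff / area else NA_real_,
                 voxel_mm = voxel),
            class = "volume_report_entry")
}

#' @export
print.volume_report_entry <- function(x, ...) {
  cat(sprintf(
    "<volume_report_entry> region=%s tissue=%s: dV=%.1f mm^3 (net %+.1f), area=%.1f mm^2, avg movement=%.3f mm (voxel %.2f mm)\n",
    x$region, x$tissue, x$volume_difference, x$net_change,
    x$region_surface_area, x$average_movement, x$voxel_mm))
  invisible(x)
}

#' Soft-to-hard tissue average-movement ratio
#'
#' Ratio of the soft-tissue region's average surface movement to the hard
#' (bone) region's; values near 1 mean the soft tissue follows the skeletal
#' movement fully.
#'
#' @param soft,hard [volume_difference()] entries for the same region.
#' @param eps Minimum hard-tissue average movement (mm) below which the
#'   ratio is undefined.
#' @return The dimensionless ratio.
#' @export
soft_to_hard_ratio <- function(soft, hard, eps = 1e-6) {
  hm <- hard$average_movement
  if (!is.finite(hm) || hm <= eps) {
    stop_undefined_ratio(
      "hard-tissue average movement is (near-)zero; ratio undefined")
  }
  soft$average_movement / hm
}

#' Write volume-report entries as CSV
#'
#' One row per entry, shaped like a region-by-plane ratio table when a
#' `plane` column is supplied.
#'
#' @param entries List of [volume_difference()] entries.
#' @param path Output path.
#' @param plane Optional plane label(s) recycled across entries.
#' @return `path`, invisibly.
#' @export
write_volume_csv <- function(entries, path, plane = NA_character_) {
  rows <- Map(function(e, pl) {
    data.frame(plane = pl, region = e$region, tissue = e$tissue,
               volume_pre = e$volume_pre, volume_post = e$volume_post,
               volume_difference = e$volume_difference,
               net_change = e$net_change,
               region_surface_area = e$region_surface_area,
               average_movement = e$average_movement,
               voxel_mm = e$voxel_mm, stringsAsFactors = FALSE)
  }, entries, rep_len(plane, length(entries)))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
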