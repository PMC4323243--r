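# Synthetic skull landmark sets, observer-noise replicates, and pre/post
# mesh phantoms with closed-form ground truth. The generator defines the
# validation conditions for every downstream stage of the package.

# Idealized bilaterally symmetric adult-scale template (mm). Mirror plane is
# X = 0; the Frankfort horizontal is Y = 0 and, by construction, the lateral
# semicircular canal landmarks and nasion lie in it too, so all five
# horizontal reference planes coincide exactly at zero deformation — the
# idealized limit in which the planes are interchangeable.
.skull_template_points <- rbind(
  OrR = c( 32,    0,  68),
  OrL = c(-32,    0,  68),
  PoR = c( 55,    0, -10),
  PoL = c(-55,    0, -10),
  LsR = c( 33,    0,  -6),
  LsL = c(-33,    0,  -6),
  N   = c(  0,    0,  72),
  Ba  = c(  0,  -20, -30),
  ANS = c(  0,  -48,  90),
  UI  = c(  0,  -74,  95),
  LI  = c(  0,  -78,  93),
  Pog = c(  0, -105,  92),
  Me  = c(  0, -112,  85),
  UR3 = c( 17,  -72,  82),
  UL3 = c(-17,  -72,  82),
  UR6 = c( 30,  -70,  48),
  UL6 = c(-30,  -70,  48),
  LR3 = c( 16,  -76,  80),
  LL3 = c(-16,  -76,  80),
  LR6 = c( 29,  -74,  46),
  LL6 = c(-29,  -74,  46))

#' Symmetric skull landmark template
#'
#' A bilaterally symmetric adult-scale landmark template (inter-porion width
#' 110 mm, canine half-width 17/16 mm, molar half-width 30/29 mm). The
#' mirror plane is X = 0; all horizontal-plane landmarks (Or, Po, Ls, N) lie
#' in the plane Y = 0, so the five horizontal reference planes coincide at
#' zero deformation. Coordinates are package conventions, not measurements.
#'
#' @param subject_id,session Metadata for the returned set.
#' @return A [landmark_set()] with all 21 digitised landmark names.
#' @export
skull_template <- function(subject_id = "template", session = "preop") {
  landmark_set(.skull_template_points, subject_id = subject_id,
               session = session)
}

#' Deformation specification for synthetic subjects
#'
#' @param chin_deviation_mm Signed lateral chin deviation (mm); positive
#'   moves the chin toward the subject's right. Clinical asymmetry cases run
#'   roughly 4-11.5 mm.
#' @param occlusal_cant_deg Signed occlusal cant (degrees) about the
#'   anterior-posterior axis through the dental arch midline; positive drops
#'   the subject's right side.
#' @param setback_right_mm,setback_left_mm Mandibular setback (mm, posterior
#'   shift) per side.
#' @return Object of class `deformation_spec`.
#' @export
deformation_spec <- function(chin_deviation_mm = 0, occlusal_cant_deg = 0,
                             setback_right_mm = 0, setback_left_mm = 0) {
  vals <- c(chin_deviation_mm, occlusal_cant_deg, setback_right_mm,
            setback_left_mm)
  if (!all(is.finite(vals))) stop_usage("deformation parameters must be finite")
  structure(list(chin_deviation_mm = chin_deviation_mm,
                 occlusal_cant_deg = occlusal_cant_deg,
                 setback_right_mm = setback_right_mm,
                 setback_left_mm = setback_left_mm),
            class = "deformation_spec")
}

.dental_all <- c("UI", "LI", "UL3", "UR3", "UL6", "UR6", "LL3", "LR3",
                 "LL6", "LR6")
.mandibular_right <- c("LR3", "LR6")
.mandibular_left <- c("LL3", "LL6")
.mandibular_midline <- c("LI", "Pog", "Me")

#' Generate a synthetic subject with known ground truth
#'
#' Applies deformations to the symmetric template in a fixed order — occlusal
#' cant (rotation of the dental landmarks about the anterior-posterior axis
#' through the arch midline), then lateral chin deviation (translation of Me,
#' Pog and LI along X), then per-side mandibular setback (posterior shift of
#' the lateral mandibular dental landmarks, midline mandibular landmarks
#' shifted by the side average). Cranial landmarks (Or, Po, Ls, N, Ba) are
#' never moved, so the true midsagittal plane remains X = 0 and the true
#' horizontal planes remain Y = 0.
#'
#' @param spec A [deformation_spec()].
#' @param template Template [landmark_set()].
#' @param subject_id,session Metadata for the returned set.
#' @return List with `landmarks` (the deformed [landmark_set()]) and `truth`:
#'   the true mirror plane (`midplane`), the true horizontal plane
#'   (`horizontal`), signed `midline_offsets` (X of each midline landmark),
#'   and the true bilateral `u_metrics` (U3, U6, L3, L6 in mm, identical for
#'   every horizontal plane since all five coincide in the template).
#' @export
make_subject <- function(spec = deformation_spec(), template = skull_template(),
                         subject_id = "synthetic", session = "preop") {
  pts <- template$points
  # 1) occlusal cant: rotate dental landmarks about the Z axis through
  #    (x = 0, y = occlusal level)
  th <- spec$occlusal_cant_deg * pi / 180
  if (th != 0) {
    y0 <- mean(pts[c("UI", "LI"), 2])
    d <- intersect(.dental_all, rownames(pts))
    x <- pts[d, 1]; y <- pts[d, 2] - y0
    pts[d, 1] <- cos(th) * x - sin(th) * y
    pts[d, 2] <- sin(th) * x + cos(th) * y + y0
  }
  # 2) chin deviation: lateral translation of Me, Pog, LI
  if (spec$chin_deviation_mm != 0) {
    chin <- intersect(c("Me", "Pog", "LI"), rownames(pts))
    pts[chin, 1] <- pts[chin, 1] + spec$chin_deviation_mm
  }
  # 3) per-side mandibular setback along -Z
  if (spec$setback_right_mm != 0 || spec$setback_left_mm != 0) {
    pts[.mandibular_right, 3] <- pts[.mandibular_right, 3] - spec$setback_right_mm
    pts[.mandibular_left, 3] <- pts[.mandibular_left, 3] - spec$setback_left_mm
    mid <- (spec$setback_right_mm + spec$setback_left_mm) / 2
    pts[.mandibular_midline, 3] <- pts[.mandibular_midline, 3] - mid
  }
  ls <- landmark_set(pts, subject_id = subject_id, session = session)
  horiz <- plane3(c(0, 1, 0), 0)
  u_true <- vapply(.metric_pairs, function(pr) {
    abs(abs(pts[pr["left"], 2]) - abs(pts[pr["right"], 2]))
  }, numeric(1))
  truth <- list(
    midplane = plane3(c(1, 0, 0), 0),
    horizontal = horiz,
    midline_offsets = stats::setNames(pts[.midline_probe_landmarks, 1],
                                      .midline_probe_landmarks),
    u_metrics = u_true,
    spec = spec)
  list(landmarks = ls, truth = truth)
}

.string_seed <- function(s) {
  if (!nzchar(s)) return(0L)
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 99991L
}

#' Simulate an observer digitising a landmark set
#'
#' Adds independent zero-mean Gaussian placement noise per axis. The noise is
#' deterministic per (seed, observer, trial, landmark): each landmark's
#' perturbation is drawn from its own derived stream, so the same landmark
#' gets the same noise regardless of which other landmarks are present.
#'
#' @param ls The true [landmark_set()].
#' @param sigma_mm Per-axis noise standard deviations (length 1 or 3, mm).
#' @param observer Observer label.
#' @param trial Trial number.
#' @param seed Integer base seed.
#' @return A [landmark_set()] with the observer/trial metadata set.
#' @export
observe_landmarks <- function(ls, sigma_mm = c(0.2, 0.2, 0.2), observer = "O1",
                              trial = 1L, seed = 1L) {
  sigma <- rep_len(as.numeric(sigma_mm), 3L)
  if (any(sigma < 0)) stop_usage("sigma_mm must be nonnegative")
  pts <- ls$points
  base <- (as.integer(seed) %% 100000L) * 7919L + .string_seed(observer) * 101L +
    as.integer(trial) * 13L + .string_seed(ls$subject_id)
  for (nm in rownames(pts)) {
    old <- .Random.seed_get()
    set.seed((base + .string_seed(nm)) %% .Machine$integer.max)
    pts[nm, ] <- pts[nm, ] + stats::rnorm(3L, 0, sigma)
    .Random.seed_restore(old)
  }
  landmark_set(pts, subject_id = ls$subject_id, session = ls$session,
               observer = observer, trial = trial)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulate a two-observer repeated-digitisation reliability study
#'
#' Generates `n_subjects` subjects whose anatomy differs by Gaussian
#' per-landmark offsets of SD `anatomy_sd_mm` from the template (real
#' subjects differ by millimetres to centimetres, far more than observer
#' placement noise — this between-subject spread is what makes the paired
#' coordinate correlations informative), then has each observer digitise
#' each subject in each trial with placement noise of SD `sigma_mm` per
#' axis.
#'
#' @param n_subjects Number of subjects.
#' @param sigma_mm Observer placement noise SD per axis (mm).
#' @param anatomy_sd_mm Between-subject anatomical SD per landmark axis (mm).
#' @param observers Observer labels (two for interobserver analysis).
#' @param trials Trial numbers (1:2 for intraobserver analysis).
#' @param seed Integer seed.
#' @return List of observed [landmark_set()]s with subject/observer/trial
#'   metadata, ready for [landmark_reliability()] or [run_reliability()].
#' @export
reliability_study <- function(n_subjects = 10, sigma_mm = 0.2,
                              anatomy_sd_mm = 5, observers = c("O1", "O2"),
                              trials = 1:2, seed = 1L) {
  tpl <- skull_template()
  out <- list()
  for (i in seq_len(n_subjects)) {
    old <- .Random.seed_get()
    set.seed((as.integer(seed) * 613L + i) %% .Machine$integer.max)
    pts <- tpl$points + matrix(stats::rnorm(length(tpl$points), 0, anatomy_sd_mm),
                               nrow(tpl$points), 3L)
    .Random.seed_restore(old)
    dimnames(pts) <- dimnames(tpl$points)
    truth <- landmark_set(pts, subject_id = sprintf("S%02d", i))
    for (ob in observers) for (tr in trials) {
      out[[length(out) + 1L]] <- observe_landmarks(truth, sigma_mm,
                                                   observer = ob, trial = tr,
                                                   seed = as.integer(seed))
    }
  }
  out
}

#' Pre/post mesh phantoms with analytic ground truth
#'
#' `"slab"`: a closed axis-aligned box whose +Z face is offset outward
#' postoperatively by `offset_mm`, so the true volume difference is
#' `size[1] * size[2] * offset_mm`, the moved-face area `size[1] * size[2]`,
#' and the true average movement `offset_mm`. `"ellipsoid"`: an ellipsoid
#' whose semi-axes are scaled by `scale` postoperatively; the true volume
#' difference is the analytic ellipsoid-volume difference.
#'
#' @param kind `"slab"` or `"ellipsoid"`.
#' @param size Slab edge lengths (mm).
#' @param offset_mm Slab face offset (mm, along +Z).
#' @param semiaxes Ellipsoid semi-axes (mm).
#' @param scale Postoperative per-axis scale factors (length 1 or 3).
#' @param tissue Tissue label for both meshes.
#' @return List with `pre`, `post` ([surface_model()]s) and `truth` (list
#'   with `volume_difference`, `area`, `average_movement` for slabs;
#'   `volume_pre`, `volume_post`, `volume_difference` for ellipsoids).
#' @export
make_mesh_phantom <- function(kind = c("slab", "ellipsoid"),
                              size = c(20, 20, 20), offset_mm = 2,
                              semiaxes = c(25, 20, 22), scale = 1.05,
                              tissue = "hard") {
  kind <- match.arg(kind)
  if (kind == "slab") {
    if (any(size <= 0)) stop_usage("slab size must be positive")
    pre <- box_mesh(c(0, 0, 0), size, tissue = tissue, session = "preop")
    post <- box_mesh(c(0, 0, 0), size + c(0, 0, offset_mm), tissue = tissue,
                     session = "postop")
    truth <- list(volume_difference = size[1] * size[2] * abs(offset_mm),
                  area = size[1] * size[2],
                  average_movement = abs(offset_mm))
  } else {
    sc <- rep_len(scale, 3L)
    if (any(semiaxes <= 0) || any(sc <= 0)) {
      stop_usage("semiaxes and scale must be positive")
    }
    pre <- ellipsoid_mesh(semiaxes, tissue = tissue, session = "preop")
    post <- ellipsoid_mesh(semiaxes * sc, tissue = tissue, session = "postop")
    v_pre <- 4 / 3 * pi * prod(semiaxes)
    v_post <- 4 / 3 * pi * prod(semiaxes * sc)
    truth <- list(volume_pre = v_pre, volume_post = v_post,
                  volume_difference = abs(v_post - v_pre))
  }
  list(pre = pre, post = post, truth = truth)
}

#' Simulate and write a cohort directory
#'
#' Generates `n_subjects` synthetic subjects with deformation parameters
#' drawn from clinically plausible ranges, digitised by each observer in
#' each trial with Gaussian placement noise, and writes one landmark CSV per
#' (subject, session, observer, trial) plus a `ground_truth.json` with each
#' subject's deformation and true metrics. Identical seeds reproduce
#' byte-identical output files.
#'
#' @param dir Output directory (created if needed).
#' @param n_subjects Number of subjects.
#' @param group `"symmetric"` (zero deformation) or `"asymmetric"` (chin
#'   deviation drawn uniformly from 4-11.5 mm with random side, cant from
#'   -3 to 3 degrees).
#' @param observers Observer labels.
#' @param trials Trial numbers.
#' @param sigma_mm Per-axis observer noise SD (mm).
#' @param seed Integer seed controlling both deformations and noise.
#' @return Invisibly, a data frame manifest (subject, observer, trial, file).
#' @export
simulate_cohort <- function(dir, n_subjects = 10,
                            group = c("asymmetric", "symmetric"),
                            observers = c("O1", "O2"), trials = 1:2,
                            sigma_mm = c(0.2, 0.2, 0.2), seed = 1L) {
  group <- match.arg(group)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(seed))
  manifest <- list(); truths <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    spec <- if (group == "symmetric") deformation_spec() else
      deformation_spec(
        chin_deviation_mm = sample(c(-1, 1), 1) * stats::runif(1, 4, 11.5),
        occlusal_cant_deg = stats::runif(1, -3, 3))
    subj <- make_subject(spec, subject_id = sid)
    truths[[sid]] <- list(spec = unclass(spec),
                          midline_offsets = as.list(subj$truth$midline_offsets),
                          u_metrics = as.list(subj$truth$u_metrics))
    for (ob in observers) for (tr in trials) {
      obs <- observe_landmarks(subj$landmarks, sigma_mm, observer = ob,
                               trial = tr, seed = as.integer(seed))
      f <- file.path(dir, sprintf("%s_%s_trial%d.csv", sid, ob, tr))
      write_landmarks(obs, f, format = "csv")
      manifest[[length(manifest) + 1L]] <- data.frame(
        subject = sid, observer = ob, trial = tr, file = f,
        stringsAsFactors = FALSE)
    }
  }
  jsonlite::write_json(list(seed = as.integer(seed), group = group,
                            sigma_mm = rep_len(sigma_mm, 3L),
                            subjects = truths),
                       file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(do.call(rbind, manifest))
}
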