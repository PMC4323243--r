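slab_region <- function(size = c(20, 20, 20), floor_frac = 0.5) {
  region_spec("slab", list(
    list(plane = plane3(c(1, 0, 0), 0), side = 1),
    list(plane = plane3(c(1, 0, 0), size[1]), side = -1),
    list(plane = plane3(c(0, 1, 0), 0), side = 1),
    list(plane = plane3(c(0, 1, 0), size[2]), side = -1),
    list(plane = plane3(c(0, 0, 1), size[3] * floor_frac), side = 1)))
}

test_that("identical models have zero volume difference", {
  ph <- make_mesh_phantom("slab")
  vr <- volume_difference(ph$pre, ph$pre, slab_region(), voxel_mm = 0.5)
  expect_equal(vr$volume_difference, 0)
  expect_equal(vr$net_change, 0)
})

test_that("the 2 mm slab offset is recovered within voxelization tolerance", {
  ph <- make_mesh_phantom("slab", size = c(20, 20, 20), offset_mm = 2)
  vr <- volume_difference(ph$pre, ph$post, slab_region(), voxel_mm = 0.4)
  expect_equal(vr$volume_difference, ph$truth$volume_difference,
               tolerance = 0.05)
  expect_equal(vr$region_surface_area, ph$truth$area, tolerance = 0.01)
  expect_equal(vr$average_movement, ph$truth$average_movement,
               tolerance = 0.05)
  expect_equal(vr$net_change, vr$volume_difference)  # pure outward growth
})

test_that("halving the voxel size shrinks the slab discretization error", {
  ph <- make_mesh_phantom("slab", size = c(20, 20, 20), offset_mm = 2)
  errs <- vapply(c(0.4, 0.2, 0.1), function(vx) {
    vr <- volume_difference(ph$pre, ph$post, slab_region(), voxel_mm = vx)
    abs(vr$average_movement - 2)
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
  expect_lt(errs[3], 0.02)
})

test_that("the soft-to-hard ratio recovers the phantom ground truth", {
  hard <- make_mesh_phantom("slab", offset_mm = 2, tissue = "hard")
  soft <- make_mesh_phantom("slab", offset_mm = 1.6, tissue = "soft")
  reg <- slab_region()
  vh <- volume_difference(hard$pre, hard$post, reg, voxel_mm = 0.4)
  vs <- volume_difference(soft$pre, soft$post, reg, voxel_mm = 0.4)
  expect_equal(soft_to_hard_ratio(vs, vh), 0.8, tolerance = 0.05)
  expect_equal(soft_to_hard_ratio(vh, vh), 1.0, tolerance = 1e-12)

  same <- volume_difference(hard$pre, hard$pre, reg, voxel_mm = 0.4)
  expect_error(soft_to_hard_ratio(vs, same), class = "undefined_ratio_error")
})

test_that("the ellipsoid phantom matches its analytic volume difference", {
  ph <- make_mesh_phantom("ellipsoid", semiaxes = c(15, 12, 13), scale = 1.05)
  region_all <- region_spec("all", list(
    list(plane = plane3(c(0, 1, 0), -100), side = 1)))
  vr <- volume_difference(ph$pre, ph$post, region_all, voxel_mm = 0.5)
  expect_equal(vr$volume_difference, ph$truth$volume_difference,
               tolerance = 0.08)
})

test_that("cranial-base superimposition restores the preoperative frame", {
  set.seed(161)
  s <- make_subject(deformation_spec(chin_deviation_mm = 5))
  pre_ls <- s$landmarks
  tf <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 30))
  post_ls <- transform_landmarks(pre_ls, tf)
  mesh <- make_mesh_phantom("slab")$pre
  moved <- transform_mesh(mesh, tf)
  out <- superimpose_models(pre_ls, post_ls, list(moved))
  expect_lt(out$rmsd, 1e-9)
  expect_lt(max(abs(out$models[[1]]$vertices - mesh$vertices)), 1e-9)

  # noisy landmarks: residual at the noise scale
  noisy_post <- observe_landmarks(post_ls, 0.1, observer = "O1", seed = 9)
  out2 <- superimpose_models(pre_ls, noisy_post, moved)
  expect_lte(out2$rmsd, 0.3)

  expect_error(superimpose_models(pre_ls, post_ls, moved, basis = c("N", "Ba")),
               class = "degenerate_geometry_error")
})

test_that("region specs round-trip through YAML", {
  tpl <- skull_template()
  rps <- build_reference_planes(tpl)
  regs <- default_regions(tpl, rps)
  expect_named(regs, c("chin", "right_mandible", "left_mandible", "lower_lip"))
  f <- withr::local_tempfile(fileext = ".yaml")
  write_regions_yaml(regs, f)
  back <- read_regions_yaml(f)
  expect_named(back, names(regs))
  for (nm in names(regs)) {
    for (i in seq_along(regs[[nm]]$halfspaces)) {
      expect_equal(back[[nm]]$halfspaces[[i]]$plane$normal,
                   regs[[nm]]$halfspaces[[i]]$plane$normal, tolerance = 1e-12)
      expect_equal(back[[nm]]$halfspaces[[i]]$side,
                   regs[[nm]]$halfspaces[[i]]$side)
    }
  }
})

test_that("default regions split the mandible left/right around the midline", {
  tpl <- skull_template()
  rps <- build_reference_planes(tpl)
  regs <- default_regions(tpl, rps)
  ball <- ellipsoid_mesh(c(40, 15, 30), center = c(0, -90, 70),
                         n_theta = 32, n_phi = 16)
  right <- clip_region(ball, regs$right_mandible)
  left <- clip_region(ball, regs$left_mandible)
  expect_true(is_closed_mesh(right) && is_closed_mesh(left))
  expect_equal(mesh_volume(right), mesh_volume(left), tolerance = 1e-6)
  expect_gt(mesh_volume(right), 0)
  expect_lt(mesh_volume(right) + mesh_volume(left), mesh_volume(ball) + 1e-6)
})

test_that("volume reports export as a region table CSV", {
  ph <- make_mesh_phantom("slab")
  vr <- volume_difference(ph$pre, ph$post, slab_region(), voxel_mm = 0.5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_volume_csv(list(vr), f, plane = "FHP_P")
  df <- utils::read.csv(f)
  expect_equal(df$plane, "FHP_P")
  expect_equal(df$average_movement, vr$average_movement)
})
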