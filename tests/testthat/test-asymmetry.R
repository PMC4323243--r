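test_that("the symmetric template has zero asymmetry everywhere", {
  tpl <- skull_template()
  rps <- build_reference_planes(tpl)
  bd <- bilateral_differences(tpl, rps)
  expect_equal(nrow(bd), 5 * 4)
  expect_lt(max(bd$value), 1e-9)
  mo <- midline_offsets(tpl, rps)
  expect_lt(max(abs(mo$offset)), 1e-9)
})

test_that("a displacement along the plane normal maps 1:1 to the metric", {
  tpl <- skull_template()
  horiz <- build_horizontal_planes(tpl)
  pts <- tpl$points
  pts["LL3", ] <- pts["LL3", ] + 1.5 * horiz$FHP_P$normal
  bd <- bilateral_differences(landmark_set(pts), horiz)
  expect_equal(bd$value[bd$plane == "FHP_P" & bd$metric == "L3"], 1.5,
               tolerance = 1e-9)
})

test_that("an occlusal cant produces the closed-form molar difference", {
  for (theta in c(1, 3, 5)) {
    s <- make_subject(deformation_spec(occlusal_cant_deg = theta))
    bd <- bilateral_differences(s$landmarks,
                                build_horizontal_planes(s$landmarks))
    w6 <- 30   # maxillary molar half-width in the template
    for (pl in horizontal_plane_names()) {
      expect_equal(bd$value[bd$plane == pl & bd$metric == "U6"],
                   2 * w6 * sin(theta * pi / 180), tolerance = 1e-9)
    }
    expect_equal(unname(s$truth$u_metrics["U6"]),
                 2 * w6 * sin(theta * pi / 180), tolerance = 1e-9)
  }
})

test_that("chin deviation is recovered with the positive-right sign convention", {
  right <- make_subject(deformation_spec(chin_deviation_mm = 6.6))
  rps <- build_reference_planes(right$landmarks)
  mo <- midline_offsets(right$landmarks, rps)
  expect_equal(mo$offset[mo$landmark == "Me"], rep(6.6, 4), tolerance = 1e-9)
  expect_equal(mo$offset[mo$landmark == "Pog"], rep(6.6, 4), tolerance = 1e-9)

  left <- make_subject(deformation_spec(chin_deviation_mm = -5.7))
  mo2 <- midline_offsets(left$landmarks, build_reference_planes(left$landmarks))
  expect_equal(mo2$offset[mo2$landmark == "Me"], rep(-5.7, 4), tolerance = 1e-9)
})

test_that("asymmetry metrics are rigid-motion invariant", {
  set.seed(101)
  s <- make_subject(deformation_spec(chin_deviation_mm = 7, occlusal_cant_deg = 2))
  ls <- s$landmarks
  bd0 <- bilateral_differences(ls, build_reference_planes(ls))
  mo0 <- midline_offsets(ls, build_reference_planes(ls))
  tf <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 50))
  ls2 <- transform_landmarks(ls, tf)
  bd1 <- bilateral_differences(ls2, build_reference_planes(ls2))
  mo1 <- midline_offsets(ls2, build_reference_planes(ls2))
  expect_equal(bd1$value, bd0$value, tolerance = 1e-9)
  expect_equal(abs(mo1$offset), abs(mo0$offset), tolerance = 1e-9)
})

test_that("mirroring negates signed offsets and preserves unsigned metrics", {
  s <- make_subject(deformation_spec(chin_deviation_mm = 4.2,
                                     occlusal_cant_deg = -1.5))
  ls <- s$landmarks
  mir <- reflect_landmarks(ls, s$truth$midplane)
  bd0 <- bilateral_differences(ls, build_reference_planes(ls))
  bd1 <- bilateral_differences(mir, build_reference_planes(mir))
  expect_equal(bd1$value, bd0$value, tolerance = 1e-9)
  mo0 <- midline_offsets(ls, build_reference_planes(ls))
  mo1 <- midline_offsets(mir, build_reference_planes(mir))
  expect_equal(mo1$offset, -mo0$offset, tolerance = 1e-9)
})

test_that("the 4-mm chin deviation rule classifies asymmetry", {
  expect_false(classify_asymmetry(3.9))
  expect_false(classify_asymmetry(-4.0))
  expect_true(classify_asymmetry(4.1))
  expect_true(classify_asymmetry(-11.5))
})

test_that("cohort summaries compute mean and n-1 SD per cell", {
  tpl <- skull_template()
  rps <- build_reference_planes(tpl)
  r0 <- bilateral_differences(tpl, rps)
  same <- summarize_cohort(list(r0, r0))
  expect_equal(same$sd, rep(0, nrow(same)))
  expect_equal(same$mean, r0$value)

  r1 <- r0; r1$value <- rep(1, nrow(r1))
  r2 <- r0; r2$value <- rep(2, nrow(r2))
  r3 <- r0; r3$value <- rep(3, nrow(r3))
  s123 <- summarize_cohort(list(r1, r2, r3))
  expect_equal(s123$mean, rep(2, nrow(s123)))
  expect_equal(s123$sd, rep(1, nrow(s123)))
  expect_equal(s123$n[1], 3)

  expect_error(summarize_cohort(list()), class = "usage_error")
  expect_error(summarize_cohort(list(r0)), class = "usage_error")
})

test_that("noisy cohort means stay near the generator truth", {
  set.seed(111)
  truth <- 6
  reports <- lapply(1:10, function(i) {
    s <- make_subject(deformation_spec(chin_deviation_mm = truth))
    obs <- observe_landmarks(s$landmarks, 0.2, observer = "O1", trial = 1L,
                             seed = 200 + i)
    mo <- midline_offsets(obs, build_reference_planes(obs))
    # reuse the bilateral-report shape for summarising
    data.frame(plane = mo$plane, metric = mo$landmark, value = mo$offset)
  })
  summ <- summarize_cohort(reports)
  me <- summ$mean[summ$metric == "Me"]
  expect_lt(max(abs(me - truth)), 3 * 0.2 * sqrt(2) / sqrt(10) + 0.2)
})

test_that("asymmetry reports export tidy and wide CSV shapes", {
  s <- make_subject(deformation_spec(chin_deviation_mm = 5),
                    subject_id = "S01")
  rps <- build_reference_planes(s$landmarks)
  f <- withr::local_tempfile(fileext = ".csv")
  write_asymmetry_csv(list(bilateral_differences(s$landmarks, rps),
                           midline_offsets(s$landmarks, rps)), f)
  df <- utils::read.csv(f)
  expect_setequal(names(df), c("subject_id", "session", "plane", "metric", "value"))
  expect_true(any(df$metric == "offset_Me"))

  wide <- midline_offsets_wide(midline_offsets(s$landmarks, rps))
  expect_equal(names(wide), c("landmark", "FHP_P", "FHP_O", "FHP_L", "FHP_R"))
  expect_equal(wide$FHP_P[wide$landmark == "Me"], 5, tolerance = 1e-9)
})
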