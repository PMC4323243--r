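test_that("all five horizontal planes coincide on the symmetric template", {
  tpl <- skull_template()
  horiz <- build_horizontal_planes(tpl)
  expect_named(horiz, c("FHP_P", "FHP_O", "FHP_L", "FHP_R", "LSP"))
  probes <- tpl$points[c("Me", "UI", "ANS", "UR6"), ]
  d <- sapply(horiz, function(h) point_plane_distance(probes, h))
  expect_lt(max(apply(d, 1, function(r) diff(range(r)))), 1e-9)
  # normals oriented superiorly
  for (h in horiz) expect_gt(h$normal[2], 0)
})

test_that("each horizontal plane contains its defining landmarks", {
  set.seed(71)
  for (i in 1:20) {
    ls <- with_derived_midpoints(random_landmark_set())
    horiz <- build_horizontal_planes(ls)
    for (h in horiz) {
      def <- attr(h, "defined_by")
      expect_plane_contains(h, lapply(def, function(nm) ls$points[nm, ]))
    }
  }
})

test_that("raising PoL splits FHP_L from FHP_R with a consistent angle", {
  tpl <- skull_template()
  pts <- tpl$points
  pts["PoL", 2] <- pts["PoL", 2] + 2
  ls <- landmark_set(pts)
  horiz <- build_horizontal_planes(ls)
  ang <- plane_angle(horiz$FHP_L, horiz$FHP_R)
  expect_gt(ang, 1e-3)
  # independent oracle: SVD normals from the defining points
  n_l <- svd_plane_normal(pts["PoL", ], pts["OrR", ], pts["OrL", ])
  n_r <- svd_plane_normal(pts["PoR", ], pts["OrR", ], pts["OrL", ])
  ang_svd <- acos(min(1, abs(sum(n_l * n_r))))
  expect_equal(ang, ang_svd, tolerance = 1e-9)
})

test_that("missing plane landmarks are reported by name", {
  tpl <- skull_template()
  noLsR <- landmark_set(tpl$points[setdiff(rownames(tpl$points), "LsR"), ])
  err <- expect_error(build_horizontal_planes(noLsR),
                      class = "missing_landmark_error")
  expect_match(conditionMessage(err), "LsR")
})

test_that("the midsagittal plane contains N and Ba, is perpendicular, and points right", {
  ls <- landmark_set(list(N = c(0, 0, 80), Ba = c(0, -20, -30)))
  ms <- build_midsagittal(ls, plane3(c(0, 1, 0), 0))
  expect_equal(ms$normal, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(ms$offset, 0, tolerance = 1e-12)

  set.seed(81)
  for (i in 1:20) {
    ls <- random_landmark_set()
    horiz <- build_horizontal_planes(ls)
    for (h in horiz) {
      ms <- build_midsagittal(ls, h)
      expect_plane_contains(ms, list(ls$points["N", ], ls$points["Ba", ]))
      expect_lt(abs(sum(ms$normal * h$normal)), 1e-9)
      expect_gte(ms$normal[1], 0)
    }
  }
})

test_that("Ba directly above N along the horizontal normal is degenerate", {
  ls <- landmark_set(list(N = c(0, 0, 72), Ba = c(0, 40, 72)))
  expect_error(build_midsagittal(ls, plane3(c(0, 1, 0), 0)),
               class = "degenerate_geometry_error")
})

test_that("midsagittal planes of the symmetric template are the mirror plane", {
  tpl <- skull_template()
  rps <- build_reference_planes(tpl)
  mids <- rownames(tpl$points)[tpl$points[, 1] == 0]
  for (ms in rps$midsagittal) {
    expect_lt(max(abs(point_plane_distance(tpl$points[mids, , drop = FALSE],
                                           ms, signed = TRUE))), 1e-9)
    # paired landmarks mirror: equal magnitude, opposite sign
    sR <- point_plane_distance(tpl$points["UR6", ], ms, signed = TRUE)
    sL <- point_plane_distance(tpl$points["UL6", ], ms, signed = TRUE)
    expect_equal(sR, -sL, tolerance = 1e-9)
    expect_gt(sR, 0)   # right-side landmark on the positive (right) side
  }
})

test_that("plane construction is equivariant under rigid motion", {
  set.seed(91)
  ls <- random_landmark_set()
  probes <- dental_landmarks()
  h0 <- build_horizontal_planes(ls)
  for (i in 1:5) {
    tf <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 80))
    ls2 <- transform_landmarks(ls, tf)
    h1 <- build_horizontal_planes(ls2)
    for (nm in names(h0)) {
      d0 <- point_plane_distance(ls$points[probes, ], h0[[nm]])
      d1 <- point_plane_distance(ls2$points[probes, ], h1[[nm]])
      expect_equal(d1, d0, tolerance = 1e-9)
    }
  }
})

test_that("plane-pair discrepancies match direct recomputation and are symmetric", {
  a_eq <- plane3(c(0, 1, 0), 0)
  expect_equal(unname(plane_pair_discrepancy(skull_template(), a_eq, a_eq)),
               rep(0, 8))
  b <- plane3(c(0, 1, 0), 1)
  expect_equal(unname(plane_pair_discrepancy(skull_template(), a_eq, b)),
               rep(1, 8), tolerance = 1e-12)

  s <- make_subject(deformation_spec(chin_deviation_mm = 5,
                                     occlusal_cant_deg = 2))
  ls <- s$landmarks
  horiz <- build_horizontal_planes(ls)
  probes <- dental_landmarks()
  got <- plane_pair_discrepancy(ls, horiz$FHP_O, horiz$FHP_P, probes)
  manual <- vapply(probes, function(nm) {
    p <- ls$points[nm, ]
    abs(abs(sum(horiz$FHP_O$normal * p) - horiz$FHP_O$offset) -
          abs(sum(horiz$FHP_P$normal * p) - horiz$FHP_P$offset))
  }, numeric(1))
  expect_equal(got, manual, tolerance = 1e-12)
  expect_equal(plane_pair_discrepancy(ls, horiz$FHP_P, horiz$FHP_O, probes),
               got, tolerance = 1e-15)
})

test_that("reference plane sets export to JSON with defining landmarks", {
  rps <- build_reference_planes(skull_template())
  f <- withr::local_tempfile(fileext = ".json")
  write_planes_json(rps, f)
  obj <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(sort(names(obj$horizontal)), sort(horizontal_plane_names()))
  expect_equal(obj$horizontal$FHP_P$defined_by, c("PoA", "OrR", "OrL"))
  expect_equal(obj$midsagittal$FHP_O$perpendicular_to, "FHP_O")
})
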