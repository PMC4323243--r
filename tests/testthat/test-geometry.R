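test_that("planes through three points contain their defining points", {
  pl <- plane_from_points(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  expect_equal(abs(pl$normal), c(0, 0, 1))
  expect_equal(pl$offset, 0)

  pl5 <- plane_from_points(c(0, 0, 5), c(1, 0, 5), c(0, 1, 5))
  expect_equal(abs(pl5$offset), 5)
  expect_equal(abs(pl5$normal), c(0, 0, 1))

  set.seed(11)
  for (i in 1:100) {
    pts <- matrix(stats::rnorm(9, sd = 40), 3, 3)
    pl <- plane_from_points(pts[1, ], pts[2, ], pts[3, ])
    expect_plane_contains(pl, list(pts[1, ], pts[2, ], pts[3, ]))
  }
})

test_that("degenerate point triples are rejected with the offending landmarks", {
  err <- expect_error(
    plane_from_points(c(0, 0, 0), c(1, 1, 1), c(2, 2, 2),
                      labels = c("OrR", "OrL", "PoA")),
    class = "degenerate_geometry_error")
  expect_match(conditionMessage(err), "OrR, OrL, PoA")
  expect_error(plane_from_points(c(1, 2, 3), c(1, 2, 3), c(4, 5, 6)),
               class = "degenerate_geometry_error")
})

test_that("point-plane distances follow the signed/unsigned contract", {
  z0 <- plane3(c(0, 0, 1), 0)
  expect_equal(point_plane_distance(c(0, 0, 7), z0), 7)
  expect_equal(point_plane_distance(c(0, 0, 7), z0, signed = TRUE), 7)
  expect_equal(point_plane_distance(c(0, 0, -7), z0, signed = TRUE), -7)
  expect_equal(point_plane_distance(c(3, -2, 0), z0), 0)
  x0 <- plane3(c(1, 0, 0), 0)
  expect_equal(point_plane_distance(c(3, 4, 0), x0), 3)
})

test_that("midpoint is the componentwise mean", {
  expect_equal(midpoint3(c(0, 0, 0), c(2, 0, 0)), c(1, 0, 0))
  expect_equal(midpoint3(c(4, -1, 2), c(4, -1, 2)), c(4, -1, 2))
  expect_equal(midpoint3(c(-1, 4, 2), c(3, -2, 0)), c(1, 1, 1))
})

test_that("swapping defining points flips at most the normal sign", {
  set.seed(21)
  for (i in 1:25) {
    pts <- matrix(stats::rnorm(9, sd = 30), 3, 3)
    probe <- stats::rnorm(3, sd = 30)
    a <- plane_from_points(pts[1, ], pts[2, ], pts[3, ])
    b <- plane_from_points(pts[3, ], pts[1, ], pts[2, ])
    c_ <- plane_from_points(pts[2, ], pts[1, ], pts[3, ])
    expect_equal(point_plane_distance(probe, b), point_plane_distance(probe, a),
                 tolerance = 1e-12)
    expect_equal(point_plane_distance(probe, c_), point_plane_distance(probe, a),
                 tolerance = 1e-12)
  }
})

test_that("distances are invariant under joint rigid motion of point and plane", {
  set.seed(31)
  for (i in 1:25) {
    pts <- matrix(stats::rnorm(9, sd = 30), 3, 3)
    pl <- plane_from_points(pts[1, ], pts[2, ], pts[3, ])
    probe <- stats::rnorm(3, sd = 30)
    tf <- rigid_transform(random_rotation(), stats::rnorm(3, sd = 50))
    d0 <- point_plane_distance(probe, pl, signed = TRUE)
    d1 <- point_plane_distance(apply_rigid(tf, probe), transform_plane(tf, pl),
                               signed = TRUE)
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("rigid superimposition recovers exact and noisy motions", {
  set.seed(41)
  X <- matrix(stats::rnorm(12, sd = 30), 4, 3)
  idfit <- kabsch_superimpose(X, X)
  expect_lt(idfit$rmsd, 1e-9)
  expect_equal(idfit$transform$rotation, diag(3), tolerance = 1e-9)
  expect_equal(idfit$transform$translation, c(0, 0, 0), tolerance = 1e-9)

  for (i in 1:20) {
    n <- sample(4:12, 1)
    X <- matrix(stats::rnorm(3 * n, sd = 40), n, 3)
    R <- random_rotation(); tvec <- stats::rnorm(3, sd = 60)
    Y <- X %*% t(R) + matrix(tvec, n, 3, byrow = TRUE)
    fit <- kabsch_superimpose(X, Y)
    expect_lt(max(abs(fit$transform$rotation - R)), 1e-6)
    expect_lt(max(abs(fit$transform$translation - tvec)), 1e-6)
    expect_lt(fit$rmsd, 1e-9)
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
  }
})

test_that("noisy superimposition stays near the noise scale", {
  set.seed(51)
  angs <- numeric(20)
  for (i in 1:20) {
    X <- matrix(stats::rnorm(30, sd = 40), 10, 3)
    R <- random_rotation(); tvec <- stats::rnorm(3, sd = 40)
    Y <- X %*% t(R) + matrix(tvec, 10, 3, byrow = TRUE) +
      matrix(stats::rnorm(30, sd = 0.1), 10, 3)
    fit <- kabsch_superimpose(X, Y)
    expect_lt(fit$rmsd, 3 * 0.1)
    err <- rigid_transform(t(R) %*% fit$transform$rotation)
    angs[i] <- rotation_angle(err)
  }
  expect_lt(max(angs), 1 * pi / 180)
})

test_that("forward and reverse superimpositions are mutually inverse", {
  set.seed(61)
  X <- matrix(stats::rnorm(18, sd = 30), 6, 3)
  R <- random_rotation()
  Y <- X %*% t(R) + matrix(c(5, -3, 9), 6, 3, byrow = TRUE) +
    matrix(stats::rnorm(18, sd = 0.05), 6, 3)
  f <- kabsch_superimpose(X, Y)$transform
  g <- kabsch_superimpose(Y, X)$transform
  gi <- invert_rigid(g)
  expect_lt(max(abs(f$rotation - gi$rotation)), 1e-6)
  expect_lt(max(abs(f$translation - gi$translation)), 1e-5)
})

test_that("superimposition rejects deficient configurations", {
  expect_error(kabsch_superimpose(matrix(1:6, 2, 3), matrix(1:6, 2, 3)),
               class = "degenerate_geometry_error")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superimpose(line, line + 1),
               class = "degenerate_geometry_error")
})
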