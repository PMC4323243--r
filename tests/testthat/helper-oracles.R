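# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Friedman statistic by first-principles midranks and tie correction.
brute_friedman_statistic <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  R <- matrix(0, n, k)
  for (i in seq_len(n)) for (j in seq_len(k)) {
    R[i, j] <- sum(x[i, ] < x[i, j]) + (sum(x[i, ] == x[i, j]) + 1) / 2
  }
  Rj <- colSums(R)
  num <- 12 * sum((Rj - n * (k + 1) / 2)^2)
  tsum <- 0
  for (i in seq_len(n)) for (v in unique(x[i, ])) {
    t <- sum(x[i, ] == v)
    tsum <- tsum + t^3 - t
  }
  den <- n * k * (k + 1) - tsum / (k - 1)
  if (den <= 0) 0 else num / den
}

# Uniformly random proper rotation via QR decomposition.
random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# A plausible random subject: the symmetric template plus per-landmark
# anatomical offsets, large relative to any tolerance in play.
random_landmark_set <- function(sd_mm = 5) {
  tpl <- skull_template()
  pts <- tpl$points + matrix(stats::rnorm(length(tpl$points), 0, sd_mm),
                             nrow(tpl$points), 3)
  dimnames(pts) <- dimnames(tpl$points)
  landmark_set(pts, subject_id = "rand")
}

# Plane normal by an SVD route independent of cross products: the least
# singular direction of the centered defining points.
svd_plane_normal <- function(p1, p2, p3) {
  m <- rbind(p1, p2, p3)
  sv <- svd(scale(m, scale = FALSE))
  sv$v[, 3]
}

expect_plane_contains <- function(plane, points, tol = 1e-9) {
  for (p in points) {
    expect_lt(point_plane_distance(p, plane), tol)
  }
}
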