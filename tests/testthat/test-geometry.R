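test_that("reference plane passes through the along-head point with head-normal", {
  pl <- build_reference_plane(c(0, 0, 0), c(0, 0, 1), 112)
  expect_equal(pl$point, c(0, 0, 112))
  expect_equal(pl$normal, c(0, 0, 1))

  pl2 <- build_reference_plane(c(1, 2, 3), c(0, 1, 0), 10)
  expect_equal(pl2$point, c(1, 12, 3))

  # basis is orthonormal and in-plane; the plane point satisfies the equation
  set.seed(11)
  for (i in 1:50) {
    d <- stats::rnorm(3); d <- d / sqrt(sum(d^2))
    p <- stats::rnorm(3, sd = 10)
    pl <- build_reference_plane(p, d, 112)
    expect_equal(sum(pl$normal * pl$point) - pl$offset, 0, tolerance = 1e-9)
    expect_equal(sum(pl$normal * pl$basis_u), 0, tolerance = 1e-9)
    expect_equal(sum(pl$normal * pl$basis_v), 0, tolerance = 1e-9)
    expect_equal(sqrt(sum(pl$basis_u^2)), 1, tolerance = 1e-9)
    expect_equal(sqrt(sum(pl$basis_v^2)), 1, tolerance = 1e-9)
  }
  expect_error(build_reference_plane(c(0, 0, 0), c(0, 0, 0)), "non-zero")
})

test_that("ray-plane intersection solves the axis-aligned and oblique cases", {
  pl <- build_reference_plane(c(0, 0, 0), c(0, 0, 1), 112)
  hit <- intersect_ray_plane(c(0, 0, 0), c(0, 0, 1), pl)
  expect_equal(hit$point, c(0, 0, 112), tolerance = 1e-10)
  expect_equal(c(hit$u, hit$v), c(0, 0), tolerance = 1e-10)

  # parallel ray: the named degenerate case
  expect_null(intersect_ray_plane(c(0, 0, 0), c(1, 0, 0), pl))
  # ray lying in the plane: the other degenerate case
  expect_null(intersect_ray_plane(c(0, 0, 112), c(1, 0, 0), pl))

  hit <- intersect_ray_plane(c(0, 0, 0), c(0, 0.6, 0.8), pl)
  expect_equal(hit$t, 140, tolerance = 1e-10)
  expect_equal(hit$point, c(0, 84, 112), tolerance = 1e-10)
})

test_that("linear-solve intersection matches the parametric oracle on random rays", {
  set.seed(42)
  worst <- 0
  for (i in 1:300) {
    hd <- stats::rnorm(3); hd <- hd / sqrt(sum(hd^2))
    pl <- build_reference_plane(stats::rnorm(3, sd = 5), hd, 112)
    gd <- stats::rnorm(3); gd <- gd / sqrt(sum(gd^2))
    go <- stats::rnorm(3, sd = 5)
    a <- intersect_ray_plane(go, gd, pl)
    b <- oracle_intersect(go, gd, pl)
    expect_false(is.null(a)); expect_false(is.null(b))
    worst <- max(worst, max(abs(a$point - b$point)), abs(a$u - b$u),
                 abs(a$v - b$v))
    # the solution satisfies the plane equation
    expect_lt(abs(sum(pl$normal * a$point) - pl$offset), 1e-9)
  }
  expect_lt(worst, 1e-8)
})

test_that("projection is invariant under joint rotation about the world-up axis", {
  rot_y <- function(a) rbind(c(cos(a), 0, sin(a)), c(0, 1, 0),
                             c(-sin(a), 0, cos(a)))
  set.seed(3)
  for (i in 1:20) {
    R <- rot_y(stats::runif(1, 0, 2 * pi))
    hp <- stats::rnorm(3, sd = 3)
    hd <- stats::rnorm(3); hd <- hd / sqrt(sum(hd^2))
    go <- hp + stats::rnorm(3, sd = 0.5)
    gd <- hd + stats::rnorm(3, sd = 0.1); gd <- gd / sqrt(sum(gd^2))
    a <- intersect_ray_plane(go, gd, build_reference_plane(hp, hd, 112))
    b <- intersect_ray_plane(as.numeric(R %*% go), as.numeric(R %*% gd),
                             build_reference_plane(as.numeric(R %*% hp),
                                                   as.numeric(R %*% hd), 112))
    expect_equal(c(a$u, a$v), c(b$u, b$v), tolerance = 1e-8)
  }
})

test_that("project_frames drops low-quality and backward frames, keeps indices aligned", {
  f <- flat_frames(10, gaze_q = c(1, 1, 0.2, 0.2, 1, 0.2, 1, 1, 0.2, 1))
  pr <- project_frames(f)
  expect_equal(nrow(pr$points), 6)
  expect_equal(pr$invalid_frames, c(3, 4, 6, 9))
  expect_equal(pr$points$frame_index, c(1, 2, 5, 7, 8, 10))

  # all-good frames survive in full
  pr2 <- project_frames(flat_frames(10))
  expect_equal(nrow(pr2$points), 10)

  # backward intersection (plane behind the gaze) is invalid
  fb <- flat_frames(1)
  fb$gazedir_z <- -1
  expect_equal(nrow(project_frames(fb)$points), 0)
  expect_equal(project_frames(fb)$invalid_frames, 1)

  # empty input, empty output
  pr0 <- project_frames(flat_frames(0))
  expect_equal(nrow(pr0$points), 0)
})

test_that("pixel coordinates stay aligned with frames after invalid frames", {
  # regression: u_px must be the pixel scaling of the same frame's u_cm
  f <- flat_frames(6, gaze_q = c(1, 1, 0.5, 1, 1, 1))
  f$gazedir_x <- c(0.01, 0.02, 0.03, 0.04, 0.05, 0.06)
  nrm <- sqrt(f$gazedir_x^2 + 1)
  f$gazedir_x <- f$gazedir_x / nrm; f$gazedir_z <- 1 / nrm
  pr <- project_frames(f, px_per_cm = 32)
  expect_equal(pr$points$u_px, pr$points$u_cm * 32)
  # frame 4 looks along slope 0.04: |u| = 112 * 0.04 (sign set by the chart)
  row <- pr$points[pr$points$frame_index == 4, ]
  expect_equal(abs(row$u_cm), 112 * 0.04, tolerance = 1e-9)
})

test_that("per-frame planes reproduce a brute-force loop over frames", {
  set.seed(8)
  n <- 200
  hd <- matrix(stats::rnorm(3 * n, sd = c(0.2, 0.2, 1)), n, 3, byrow = FALSE)
  hd[, 3] <- abs(hd[, 3]) + 0.5
  hd <- hd / sqrt(rowSums(hd^2))
  gd <- hd + matrix(stats::rnorm(3 * n, sd = 0.05), n, 3)
  gd <- gd / sqrt(rowSums(gd^2))
  f <- flat_frames(n)
  f$headdir_x <- hd[, 1]; f$headdir_y <- hd[, 2]; f$headdir_z <- hd[, 3]
  f$gazedir_x <- gd[, 1]; f$gazedir_y <- gd[, 2]; f$gazedir_z <- gd[, 3]
  pr <- project_frames(f)
  expect_equal(nrow(pr$points), n)
  for (i in seq(1, n, by = 17)) {
    pl <- build_reference_plane(c(0, 0, 0), hd[i, ], 112)
    o <- oracle_intersect(c(0, 0, 0), gd[i, ], pl)
    row <- pr$points[pr$points$frame_index == i, ]
    expect_equal(c(row$u_cm, row$v_cm), c(o$u, o$v), tolerance = 1e-8)
  }
})
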