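test_that("back-projection follows the pinhole model", {
  K <- camera_intrinsics(fx = 600, fy = 580, cx = 30, cy = 20,
                         width = 64, height = 48)
  fr <- matrix(NA_real_, 48, 64)
  fr[21, 31] <- 500           # principal point (u = 30, v = 20)
  cl <- depth_to_pointcloud(fr, K)
  expect_equal(unname(cl$points[1, ]), c(0, 0, 500))

  fr2 <- matrix(NA_real_, 48, 64)
  # one focal length right of the principal point would be u = cx + fx;
  # use a smaller offset that stays in frame: x = (u - cx) * z / fx
  fr2[21, 41] <- 400
  cl2 <- depth_to_pointcloud(fr2, K)
  expect_equal(unname(cl2$points[1, ]), c(10 * 400 / 600, 0, 400))

  expect_equal(nrow(depth_to_pointcloud(matrix(NA_real_, 48, 64),
                                        K)$points), 0)
  expect_error(depth_to_pointcloud(matrix(300, 10, 10), K), "dimensions")
})

test_that("projecting a rendered cloud back through the intrinsics
           reproduces the source pixels", {
  sim <- run_condition(amp = 3, rr = 60, phase = 0, cycles = 2, seed = 21)
  K <- sim$cfg$intrinsics
  cl <- depth_to_pointcloud(sim$seq$frames[, , 10], K)
  u <- K$cx + cl$points[, 1] * K$fx / cl$points[, 3]
  v <- K$cy + cl$points[, 2] * K$fy / cl$points[, 3]
  expect_lt(max(abs(u - cl$pixel_index[, 1])), 0.5)
  expect_lt(max(abs(v - cl$pixel_index[, 2])), 0.5)
})

test_that("sphere selection is a pixel disc around the seed", {
  K <- camera_intrinsics(fx = 500, fy = 500, cx = 20, cy = 20,
                         width = 41, height = 41)
  cl <- depth_to_pointcloud(matrix(300, 41, 41), K)
  # brute-force lattice-point oracle
  n_expected <- 0
  for (du in -8:8) for (dv in -8:8)
    if (du^2 + dv^2 <= 64) n_expected <- n_expected + 1
  expect_equal(n_expected, 197)
  roi <- select_sphere_roi(cl, roi_spec(20, 20, 8))
  expect_equal(nrow(roi$points), n_expected)

  tiny <- select_sphere_roi(cl, roi_spec(20, 20, 0.5))
  expect_equal(nrow(tiny$points), 1)
  expect_equal(unname(tiny$pixel_index[1, ]), c(20, 20))

  holed <- matrix(300, 41, 41)
  holed[13:29, 13:29] <- NA  # seed and every neighbour within radius 8
  expect_error(select_sphere_roi(depth_to_pointcloud(holed, K),
                                 roi_spec(20, 20, 8)),
               "ROI seed")
})

test_that("plane fitting recovers analytic planes and matches a
           total-least-squares oracle on noisy data", {
  grid <- expand.grid(x = seq(-10, 10, 2), y = seq(-10, 10, 2))
  flat <- fit_plane(make_cloud(cbind(grid$x, grid$y, 300)))
  expect_equal(flat$a, 0, tolerance = 1e-12)
  expect_equal(flat$b, 0, tolerance = 1e-12)
  expect_equal(flat$c, 300, tolerance = 1e-9)
  expect_equal(abs(flat$normal), c(0, 0, 1), tolerance = 1e-12)
  expect_lt(sum(flat$normal * c(0, 0, 300)), 0)  # towards the camera

  tilted <- fit_plane(make_cloud(cbind(grid$x, grid$y, grid$x + 100)))
  expect_equal(tilted$a, 1, tolerance = 1e-9)
  expect_equal(tilted$b, 0, tolerance = 1e-9)
  expect_equal(tilted$c, 100, tolerance = 1e-9)
  expect_equal(abs(tilted$normal), abs(c(1, 0, -1) / sqrt(2)),
               tolerance = 1e-9)

  set.seed(101)
  x <- runif(200, -20, 20)
  y <- runif(200, -20, 20)
  z <- 0.3 * x - 0.2 * y + 250 + rnorm(200, sd = 0.05)
  pts <- cbind(x, y, z)
  ols <- fit_plane(make_cloud(pts))$normal
  # independent oracle: smallest-eigenvector total least squares
  ev <- eigen(stats::cov(pts))$vectors[, 3]
  ev <- ev / sqrt(sum(ev^2))
  ang <- acos(min(1, abs(sum(ols * ev))))
  expect_lt(ang, 1e-3)

  expect_error(fit_plane(make_cloud(rbind(c(0, 0, 1), c(1, 1, 2)))),
               "degenerate")
  line_pts <- cbind(seq(0, 9), seq(0, 9), 5)  # collinear in x-y
  expect_error(fit_plane(make_cloud(line_pts)), "degenerate")
})

test_that("the cylinder is anchored on the plane with a metric radius", {
  K <- camera_intrinsics(fx = 600, fy = 600, cx = 40, cy = 40,
                         width = 81, height = 81)
  cl <- depth_to_pointcloud(matrix(320, 81, 81), K)
  roi <- select_sphere_roi(cl, roi_spec(40, 40, 8))
  model <- build_cylinder(roi, roi_spec(40, 40, 8), K)
  expect_equal(model$radius_mm, 8 * 320 / 600, tolerance = 1e-9)
  expect_equal(model$c0, c(0, 0, 320), tolerance = 1e-9)

  # tilted plane z = 300 + 0.3 x: solve for depth per pixel ray, where
  # x = (u - cx) z / fx
  grid <- expand.grid(u = 32:48, v = 32:48)
  keep <- (grid$u - 40)^2 + (grid$v - 40)^2 <= 64
  g <- grid[keep, ]
  fr <- matrix(NA_real_, 81, 81)
  fr[cbind(g$v + 1, g$u + 1)] <- 300 / (1 - 0.3 * (g$u - 40) / 600)
  cl2 <- depth_to_pointcloud(fr, K)
  roi2 <- select_sphere_roi(cl2, roi_spec(40, 40, 8))
  m2 <- build_cylinder(roi2, roi_spec(40, 40, 8), K)
  pl <- m2$plane
  expect_equal(pl$a * m2$c0[1] + pl$b * m2$c0[2] + pl$c - m2$c0[3], 0,
               tolerance = 1e-9)

  expect_identical(build_cylinder(roi, roi_spec(40, 40, 8), K),
                   build_cylinder(roi, roi_spec(40, 40, 8), K))
})

test_that("cylinder membership matches a brute-force distance oracle", {
  model <- structure(list(c0 = c(5, -3, 300),
                          n = c(0.1, -0.2, -1) / sqrt(1.05),
                          radius_mm = 4),
                     class = "roi_model")
  expect_equal(nrow(points_in_cylinder(
    make_cloud(matrix(model$c0 + 5 * model$n, 1, 3)), model)$points), 1)
  tangent <- c(1, 0, 0.1) - sum(c(1, 0, 0.1) * model$n) * model$n
  tangent <- tangent / sqrt(sum(tangent^2))
  expect_equal(nrow(points_in_cylinder(
    make_cloud(matrix(model$c0 + 4.01 * tangent, 1, 3)), model)$points), 0)

  set.seed(77)
  pts <- cbind(runif(1000, -10, 20), runif(1000, -15, 10),
               runif(1000, 280, 320))
  inside <- logical(1000)
  for (i in seq_len(1000)) {          # brute force, one point at a time
    rel <- pts[i, ] - model$c0
    proj <- sum(rel * model$n) * model$n
    inside[i] <- sqrt(sum((rel - proj)^2)) <= model$radius_mm
  }
  got <- points_in_cylinder(make_cloud(pts), model)
  expect_equal(nrow(got$points), sum(inside))
  expect_equal(got$points, pts[inside, , drop = FALSE],
               ignore_attr = TRUE)
})

test_that("centroid and camera distance follow the definitions", {
  single <- centroid_and_distance(make_cloud(matrix(c(0, 0, 400), 1, 3)))
  expect_equal(single$centroid, c(0, 0, 400))
  expect_equal(single$distance, 400)

  sym <- centroid_and_distance(make_cloud(rbind(c(1, 0, 300),
                                                c(-1, 0, 300))))
  expect_equal(sym$centroid, c(0, 0, 300))
  expect_equal(sym$distance, 300)

  set.seed(13)
  pts <- matrix(runif(150, 100, 400), 50, 3)
  got <- centroid_and_distance(make_cloud(pts))
  expect_equal(got$distance, sqrt(sum(colMeans(pts)^2)), tolerance = 1e-9)

  expect_error(centroid_and_distance(make_cloud(matrix(0, 0, 3))), "empty")
})

test_that("the fitted normal tracks the membrane normal under tilt", {
  for (tilt in c(0, 15, 30)) {
    cfg <- phantom_config(amp_rc = 0, amp_ab = 0, duration_s = 1 / 30,
                          rr = 40,
                          intrinsics = test_intrinsics(),
                          pose = phantom_pose(tilt_x_deg = tilt), seed = 1)
    ph <- suppressWarnings(generate_phantom(cfg))
    s <- ph$truth$roi_seed_rc
    cl <- depth_to_pointcloud(ph$sequence$frames[, , 1], cfg$intrinsics)
    roi <- select_sphere_roi(cl, roi_spec(s[1], s[2], 8))
    model <- build_cylinder(roi, roi_spec(s[1], s[2], 8), cfg$intrinsics)
    true_n <- as.numeric(cfg$pose$rotation %*% c(0, 0, 1))
    ang <- acos(min(1, abs(sum(model$n * true_n)))) * 180 / pi
    expect_lt(ang, 2)
  }
})
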