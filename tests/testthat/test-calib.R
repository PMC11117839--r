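test_that("DLT on noiseless pinhole projections is exact and triangulation
           recovers the targets", {
  cams <- small_rig()
  X <- random_cloud(50)
  dlt <- lapply(cams, function(cm) dlt_calibrate(X, project_points(cm, X)))
  expect_lt(dlt[[1]]$rms_reprojection, 1e-6)
  expect_lt(dlt[[2]]$rms_reprojection, 1e-6)
  pair <- camera_pair(dlt[[1]], dlt[[2]])
  tri <- triangulate(pair, project_points(cams[[1]], X),
                     project_points(cams[[2]], X))
  expect_lt(max(sqrt(rowSums((tri$points3d - X)^2))), 1e-6)
  expect_lt(max(tri$residual_px), 1e-6)
})

test_that("coplanar targets raise a rank-deficiency error", {
  cams <- small_rig()
  X <- random_cloud(30)
  X[, 3] <- 5  # flatten to a plane
  expect_error(dlt_calibrate(X, project_points(cams[[1]], X)), "coplanar")
  expect_error(dlt_calibrate(X[1:4, ], project_points(cams[[1]], X[1:4, ])),
               "at least 6")
})

test_that("single-run 3D RMS error agrees with its Monte-Carlo average and
           grows monotonically with feature noise", {
  cams <- small_rig()
  X <- random_cloud(50)
  uv <- lapply(cams, function(cm) project_points(cm, X))
  one_rms <- function(sigma, seed) {
    set.seed(seed)
    uvn <- lapply(uv, function(m) m + matrix(rnorm(length(m), 0, sigma),
                                             ncol = 2))
    dlt <- lapply(1:2, function(i) dlt_calibrate(X, uvn[[i]]))
    tri <- triangulate(camera_pair(dlt[[1]], dlt[[2]]),
                       uvn[[1]], uvn[[2]])
    sqrt(mean(rowSums((tri$points3d - X)^2)))
  }
  mc <- vapply(1:100, function(s) one_rms(0.5, s), 0)
  expect_lt(abs(one_rms(0.5, 1) - mean(mc)) / mean(mc), 0.2)
  by_sigma <- vapply(c(0.1, 0.3, 0.6, 1.0), function(sg)
    mean(vapply(1:20, function(s) one_rms(sg, s), 0)), 0)
  expect_true(all(diff(by_sigma) > 0))
})

test_that("calibration is equivariant under a rigid transform of the
           target frame", {
  cams <- small_rig()
  X <- random_cloud(40)
  th <- 0.4
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  tvec <- c(2, -1, 3)
  X2 <- sweep(X %*% t(R), 2, tvec, `+`)
  uv <- lapply(cams, function(cm) project_points(cm, X))
  dlt2 <- lapply(1:2, function(i) dlt_calibrate(X2, uv[[i]]))
  tri2 <- triangulate(camera_pair(dlt2[[1]], dlt2[[2]]), uv[[1]], uv[[2]])
  # reconstruction lands in the transformed frame
  expect_lt(max(abs(tri2$points3d - X2)), 1e-6)
})

test_that("triangulation sensitivity matches a finite-difference oracle", {
  cams <- small_rig()
  X <- rbind(c(0.5, -0.3, 12.2))
  dlt <- lapply(cams, function(cm)
    dlt_calibrate(random_cloud(50), project_points(cm, random_cloud(50))))
  pair <- camera_pair(dlt[[1]], dlt[[2]])
  ua <- project_points(cams[[1]], X); ub <- project_points(cams[[2]], X)
  base <- triangulate(pair, ua, ub)$points3d
  # 1 px perturbation moves the point by roughly depth/focal mm
  pert <- triangulate(pair, ua + c(1, 0), ub)$points3d
  shift <- sqrt(sum((pert - base)^2))
  depth_over_f <- scleradic:::camera_depth(cams[[1]], X) / cams[[1]]$f
  expect_gt(shift, 0.3 * depth_over_f)
  expect_lt(shift, 3 * depth_over_f)
  # symmetric +/- delta perturbations: residual grows, midpoint recovered
  for (d in c(0.5, 1, 2)) {
    up <- triangulate(pair, ua + c(0, d), ub + c(0, -d))
    dn <- triangulate(pair, ua + c(0, -d), ub + c(0, d))
    mid <- (up$points3d + dn$points3d) / 2
    # the midpoint matches to second order in the perturbation
    expect_lt(max(abs(mid - base)), 1.5e-3 * d^2 + 1e-6)
    expect_gt(up$residual_px, d / 4)
  }
  res_seq <- vapply(c(0.5, 1, 2), function(d)
    triangulate(pair, ua + c(0, d), ub + c(0, -d))$residual_px, 0)
  expect_true(all(diff(res_seq) > 0))
})

test_that("identical cameras are rejected as a degenerate pair", {
  cams <- small_rig()
  X <- random_cloud(30)
  d1 <- dlt_calibrate(X, project_points(cams[[1]], X))
  expect_error(camera_pair(d1, d1), "zero baseline")
})

test_that("displacement error propagation is exactly sqrt(2) and matches a
           sampling oracle", {
  expect_equal(propagate_displacement_error(0), 0)
  expect_equal(propagate_displacement_error(0.010), 0.010 * sqrt(2))
  expect_equal(round(propagate_displacement_error(0.010) * 1000, 1), 14.1)
  expect_error(propagate_displacement_error(-1), "non-negative")
  # difference of two iid isotropic Gaussian positions with 10 um RMS
  set.seed(99)
  n <- 1e5
  sig <- 0.010 / sqrt(3)
  a <- matrix(rnorm(3 * n, 0, sig), n)
  b <- matrix(rnorm(3 * n, 0, sig), n)
  rmse <- sqrt(mean(rowSums((a - b)^2))) * 1000
  expect_lt(abs(rmse - 14.1), 0.3)
})

test_that("pair validation against the cylinder standard reports a
           micrometre-scale error under realistic feature noise", {
  tg <- make_cylinder_target(noise_sigma_px = 0.05, seed = 2)
  v <- validate_pair_3d(tg)
  expect_lt(v$rms_3d_mm, 0.050)
  expect_gt(v$rms_3d_mm, 0.001)
  expect_equal(v$pair$cam_a$mse_3d, v$rms_3d_mm)
})

test_that("camera DLT JSON serialization round-trips", {
  cams <- small_rig()
  X <- random_cloud(30)
  d1 <- dlt_calibrate(X, project_points(cams[[1]], X))
  f <- tempfile(fileext = ".json")
  write_camera_json(d1, f)
  d2 <- read_camera_json(f)
  expect_equal(d2$L, d1$L, tolerance = 1e-12)
})
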