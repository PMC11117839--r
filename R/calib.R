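#' Direct linear transformation (DLT) camera calibration
#'
#' Estimates the classic 11-parameter DLT mapping world coordinates (mm) to
#' image coordinates (px),
#' \deqn{u = \frac{L_1 X + L_2 Y + L_3 Z + L_4}{L_9 X + L_{10} Y + L_{11} Z + 1}, \qquad
#'       v = \frac{L_5 X + L_6 Y + L_7 Z + L_8}{L_9 X + L_{10} Y + L_{11} Z + 1},}
#' by homogeneous linear least squares with Hartley-style coordinate
#' normalization (both the 3D and 2D point sets are centred and isotropically
#' scaled before solving, for conditioning).
#'
#' @param points3d n x 3 matrix of known target coordinates (mm).
#' @param points2d n x 2 matrix of measured image coordinates (px).
#' @param image_size optional c(width, height) px, stored as metadata.
#' @return object of class `camera_dlt` with elements `L` (11 parameters),
#'   `rms_reprojection` (px), `condition` (design-matrix condition number),
#'   `n_points`.
#' @export
dlt_calibrate <- function(points3d, points2d, image_size = NULL) {
  X <- as.matrix(points3d); U <- as.matrix(points2d)
  stopifnot(ncol(X) == 3, ncol(U) == 2, nrow(X) == nrow(U))
  n <- nrow(X)
  if (n < 6) stop("DLT needs at least 6 correspondences, got ", n)

  # coplanarity / degeneracy diagnostic on the 3D configuration
  sv3 <- svd(scale(X, center = TRUE, scale = FALSE))$d
  if (sv3[3] < 1e-8 * sv3[1])
    stop("rank-deficient calibration target: 3D points are coplanar ",
         "(singular value ratio ", format(sv3[3] / sv3[1], digits = 3), ")")

  # normalization transforms
  c3 <- colMeans(X); s3 <- mean(sqrt(rowSums(sweep(X, 2, c3)^2)))
  c2 <- colMeans(U); s2 <- mean(sqrt(rowSums(sweep(U, 2, c2)^2)))
  if (s3 < 1e-12 || s2 < 1e-12) stop("degenerate point configuration")
  Xn <- sweep(X, 2, c3) * (sqrt(3) / s3)
  Un <- sweep(U, 2, c2) * (sqrt(2) / s2)

  A <- matrix(0, 2 * n, 11)
  b <- numeric(2 * n)
  for (i in seq_len(n)) {
    x <- Xn[i, ]; u <- Un[i, 1]; v <- Un[i, 2]
    A[2 * i - 1, ] <- c(x, 1, 0, 0, 0, 0, -u * x)
    A[2 * i, ]     <- c(0, 0, 0, 0, x, 1, -v * x)
    b[2 * i - 1] <- u
    b[2 * i] <- v
  }
  sv <- svd(A)
  cond <- sv$d[1] / sv$d[11]
  if (sv$d[11] < 1e-10 * sv$d[1])
    stop("rank-deficient DLT system (condition number ",
         format(cond, digits = 3), "): degenerate camera/target geometry")
  Ln <- sv$v %*% ((t(sv$u) %*% b) / sv$d)

  # undo normalization: recover L for raw coordinates.
  # With T2 * [u,v,1]' ~ Pn * T3 * [X,1]' the raw matrix is
  # P = T2^{-1} Pn T3, rescaled so P[3,4] = 1.
  Pn <- rbind(matrix(Ln[1:8], 2, 4, byrow = TRUE), c(Ln[9:11], 1))
  T3 <- rbind(cbind(diag(3) * (sqrt(3) / s3), -(sqrt(3) / s3) * c3),
              c(0, 0, 0, 1))
  T2inv <- rbind(cbind(diag(2) * (s2 / sqrt(2)), c2), c(0, 0, 1))
  P <- T2inv %*% Pn %*% T3
  P <- P / P[3, 4]
  L <- c(t(P[1:2, ]), P[3, 1:3])

  cam <- structure(list(L = L, image_size = image_size,
                        rms_reprojection = NA_real_, mse_3d = NA_real_,
                        condition = cond, n_points = n),
                   class = "camera_dlt")
  res <- dlt_project(cam, X) - U
  cam$rms_reprojection <- sqrt(mean(res^2))
  cam
}

#' Project 3D points through a calibrated DLT camera
#'
#' @param cam a `camera_dlt`.
#' @param X n x 3 matrix of world points (mm).
#' @return n x 2 matrix of px coordinates.
#' @export
dlt_project <- function(cam, X) {
  X <- rbind(X)
  L <- cam$L
  den <- X %*% L[9:11] + 1
  if (any(abs(den) < 1e-12)) stop("point on the camera's principal plane")
  cbind(u = (X %*% L[1:3] + L[4]) / den,
        v = (X %*% L[5:7] + L[8]) / den)
}

#' @export
print.camera_dlt <- function(x, ...) {
  cat("DLT camera:", x$n_points, "points, RMS reprojection",
      format(x$rms_reprojection, digits = 4), "px, condition",
      format(x$condition, digits = 3), "\n")
  invisible(x)
}

#' Calibrated stereo camera pair
#'
#' @param cam_a,cam_b `camera_dlt` objects calibrated against the same
#'   target frame.
#' @return object of class `camera_pair`.
#' @export
camera_pair <- function(cam_a, cam_b) {
  stopifnot(inherits(cam_a, "camera_dlt"), inherits(cam_b, "camera_dlt"))
  if (max(abs(cam_a$L - cam_b$L)) < 1e-9)
    stop("degenerate stereo geometry: the two cameras are identical ",
         "(zero baseline)")
  structure(list(cam_a = cam_a, cam_b = cam_b), class = "camera_pair")
}

#' Two-view DLT triangulation
#'
#' Recovers 3D points from matched pixel coordinates in a calibrated pair by
#' linear least squares on the four DLT ray equations (two per camera).  The
#' per-point residual is the RMS reprojection error over both views; matches
#' whose residual exceeds a threshold should be rejected by the caller.
#'
#' @param pair a [camera_pair()].
#' @param pts_a,pts_b n x 2 px coordinates in cameras A and B.
#' @return list with `points3d` (n x 3 mm), `residual_px` (n), and
#'   `condition` (n; large values flag near-parallel rays).
#' @export
triangulate <- function(pair, pts_a, pts_b) {
  stopifnot(inherits(pair, "camera_pair"))
  pts_a <- rbind(pts_a); pts_b <- rbind(pts_b)
  stopifnot(nrow(pts_a) == nrow(pts_b))
  n <- nrow(pts_a)
  La <- pair$cam_a$L; Lb <- pair$cam_b$L
  out <- matrix(NA_real_, n, 3)
  cond <- res <- numeric(n)
  for (i in seq_len(n)) {
    A <- rbind(La[1:3] - pts_a[i, 1] * La[9:11],
               La[5:7] - pts_a[i, 2] * La[9:11],
               Lb[1:3] - pts_b[i, 1] * Lb[9:11],
               Lb[5:7] - pts_b[i, 2] * Lb[9:11])
    b <- c(pts_a[i, 1] - La[4], pts_a[i, 2] - La[8],
           pts_b[i, 1] - Lb[4], pts_b[i, 2] - Lb[8])
    sv <- svd(A)
    cond[i] <- sv$d[1] / sv$d[3]
    x <- sv$v %*% ((t(sv$u) %*% b) / sv$d)
    out[i, ] <- x
    ra <- dlt_project(pair$cam_a, t(x)) - pts_a[i, ]
    rb <- dlt_project(pair$cam_b, t(x)) - pts_b[i, ]
    res[i] <- sqrt(mean(c(ra^2, rb^2)))
  }
  if (any(cond > 1e6))
    warning(sum(cond > 1e6), " triangulated point(s) from near-parallel ",
            "rays (ill-conditioned)")
  list(points3d = out, residual_px = res, condition = cond)
}

#' Pair-level 3D validation error
#'
#' Calibrates both cameras of a pair against a target, triangulates the
#' target features back, and reports the RMS Euclidean 3D error in mm (the
#' "mean squared error of 3D coordinates" read as an RMS length).
#'
#' @param target output of [make_cylinder_target()].
#' @param use_noisy use the noisy projections (default) or the exact ones.
#' @return list with `pair`, `rms_3d_mm`, `per_point_mm`.
#' @export
validate_pair_3d <- function(target, use_noisy = TRUE) {
  vis <- Reduce(`&`, target$visible[1:2])
  pts <- target$points3d[vis, , drop = FALSE]
  p2 <- if (use_noisy) target$points2d else target$points2d_true
  cam_a <- dlt_calibrate(pts, p2[[1]][vis, , drop = FALSE])
  cam_b <- dlt_calibrate(pts, p2[[2]][vis, , drop = FALSE])
  pair <- camera_pair(cam_a, cam_b)
  tri <- triangulate(pair, p2[[1]][vis, , drop = FALSE],
                     p2[[2]][vis, , drop = FALSE])
  err <- sqrt(rowSums((tri$points3d - pts)^2))
  rms <- sqrt(mean(err^2))
  pair$cam_a$mse_3d <- pair$cam_b$mse_3d <- rms
  list(pair = pair, rms_3d_mm = rms, per_point_mm = err)
}

#' Displacement error from per-point position error
#'
#' A displacement is the difference of two independently reconstructed,
#' equally noisy positions, so its RMS error is the per-point RMS error
#' times sqrt(2): a 10 micrometre point error propagates to a 14.1
#' micrometre displacement error.
#'
#' @param per_point_mse RMS 3D position error (mm), >= 0.
#' @return displacement RMS error (mm).
#' @examples
#' propagate_displacement_error(0.010)  # 0.01414 mm = 14.1 um
#' @export
propagate_displacement_error <- function(per_point_mse) {
  if (any(per_point_mse < 0)) stop("per-point error must be non-negative")
  sqrt(2) * per_point_mse
}

#' Serialize / restore DLT parameters as JSON
#'
#' @param cam a `camera_dlt`.
#' @param path output JSON file.
#' @export
write_camera_json <- function(cam, path) {
  jsonlite::write_json(list(L = cam$L, image_size = cam$image_size,
                            rms_reprojection = cam$rms_reprojection,
                            n_points = cam$n_points),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_camera_json
#' @export
read_camera_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(L = as.numeric(j$L), image_size = j$image_size,
                 rms_reprojection = j$rms_reprojection, mse_3d = NA_real_,
                 condition = NA_real_, n_points = j$n_points),
            class = "camera_dlt")
}
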