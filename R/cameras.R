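#' Ideal pinhole camera
#'
#' Constructs an ideal (distortion-free) pinhole camera used by the synthetic
#' scene generator.  The camera frame follows the usual computer-vision
#' convention: x to the right, y down, z along the optical axis.  Lengths are
#' in mm, image coordinates in px.
#'
#' @param position numeric length-3, camera centre in world coordinates (mm).
#' @param look_at numeric length-3, a world point on the optical axis (mm).
#' @param up numeric length-3, approximate world "up" used to fix the roll.
#' @param focal_px focal length in pixels.
#' @param image_size integer length-2, image width and height in px.
#' @param principal numeric length-2, principal point in px; defaults to the
#'   image centre.
#' @return an object of class `pinhole_camera`.
#' @examples
#' cam <- pinhole_camera(c(0, 0, 112), c(0, 0, 12), focal_px = 3000)
#' project_points(cam, rbind(c(0, 0, 12)))  # projects to the principal point
#' @export
pinhole_camera <- function(position, look_at, up = c(0, 1, 0),
                           focal_px = 3000, image_size = c(640, 640),
                           principal = image_size / 2) {
  position <- as.numeric(position); look_at <- as.numeric(look_at)
  stopifnot(length(position) == 3, length(look_at) == 3,
            focal_px > 0, all(image_size >= 1))
  fwd <- look_at - position
  nf <- sqrt(sum(fwd^2))
  if (nf < 1e-12) stop("camera position and look_at coincide")
  fwd <- fwd / nf
  right <- pracma_cross(fwd, as.numeric(up))
  nr <- sqrt(sum(right^2))
  if (nr < 1e-12) stop("`up` is parallel to the optical axis")
  right <- right / nr
  down <- pracma_cross(fwd, right)  # y axis points "down" in the image
  R <- rbind(right, down, fwd)
  structure(list(R = R, C = position, f = focal_px,
                 pp = as.numeric(principal),
                 image_size = as.integer(image_size)),
            class = "pinhole_camera")
}

# cross product, kept local so the geometry has no external dependency
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Project world points through a pinhole camera
#'
#' @param cam a `pinhole_camera`.
#' @param X n x 3 matrix of world points (mm).
#' @return n x 2 matrix of pixel coordinates (u, v).
#' @export
project_points <- function(cam, X) {
  X <- rbind(X)
  Xc <- sweep(X, 2, cam$C) %*% t(cam$R)
  if (any(Xc[, 3] <= 0))
    stop("point behind camera (non-positive depth)")
  cbind(u = cam$f * Xc[, 1] / Xc[, 3] + cam$pp[1],
        v = cam$f * Xc[, 2] / Xc[, 3] + cam$pp[2])
}

# depth of world points along the optical axis (mm)
camera_depth <- function(cam, X) {
  X <- rbind(X)
  as.numeric(sweep(X, 2, cam$C) %*% cam$R[3, ])
}

#' @export
print.pinhole_camera <- function(x, ...) {
  cat("pinhole camera: f =", x$f, "px, image", x$image_size[1], "x",
      x$image_size[2], "px\n  centre (mm):", format(x$C, digits = 4), "\n")
  invisible(x)
}

#' Standard two-camera rig for posterior-pole imaging
#'
#' Two pinhole cameras on an arc above the posterior pole of the globe,
#' symmetric about the pole axis (+z), converging on the pole.  This mimics a
#' camera pair of a multi-camera DIC rig viewing the posterior sclera.
#'
#' @param distance_mm camera-to-globe-centre distance (mm).
#' @param half_angle_deg half of the pair's angular baseline (deg).
#' @param focal_px focal length in px.
#' @param image_size image width/height in px.
#' @param target_mm world point both cameras converge on (default: the
#'   posterior pole of a 12 mm globe at the origin).
#' @return list of two `pinhole_camera` objects.
#' @export
camera_pair_rig <- function(distance_mm = 112, half_angle_deg = 10,
                            focal_px = 3000, image_size = c(640, 640),
                            target_mm = c(0, 0, 12)) {
  a <- half_angle_deg * pi / 180
  mk <- function(s) {
    pos <- distance_mm * c(s * sin(a), 0, cos(a))
    pinhole_camera(pos, target_mm, up = c(0, 1, 0),
                   focal_px = focal_px, image_size = image_size)
  }
  list(mk(-1), mk(+1))
}
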