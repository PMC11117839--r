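# Shared fixtures, built once per test run (rendering and matching are the
# expensive steps; every test that can share a scene does).

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# compact rig for unit tests (full-size scenes only where accuracy demands)
small_rig <- function() {
  camera_pair_rig(distance_mm = 100, half_angle_deg = 10, focal_px = 1800,
                  image_size = c(384, 384))
}

small_scene <- function(deformation, noise_sigma = 0, seed = 3) {
  render_speckle_scene(scene_spec(cameras = small_rig(),
                                  deformation = deformation,
                                  noise_sigma = noise_sigma, seed = seed))
}

# flat textured image pair with an exact uniform subpixel shift: a
# fronto-parallel camera turns an in-plane translation t into the uniform
# image shift f * t / Z
shifted_plane_images <- function(shift_px, seed = 2, image_size = 512,
                                 f = 3000, Z = 112, noise_sigma = 0) {
  cam <- pinhole_camera(c(0, 0, Z), c(0, 0, 0), focal_px = f,
                        image_size = c(image_size, image_size))
  set.seed(seed)
  n <- 2000
  X <- cbind(stats::runif(n, -8, 8), stats::runif(n, -8, 8), 0)
  amp <- stats::runif(n, 0.5, 0.9)
  rad <- rep(0.05, n)
  shift_mm <- shift_px * Z / f
  ref <- scleradic:::render_dots(cam, X, rad, amp)
  def <- scleradic:::render_dots(cam, sweep(X, 2, c(shift_mm, 0, 0), `+`),
                                 rad, amp)
  if (noise_sigma > 0) {
    ref <- ref + matrix(stats::rnorm(length(ref), 0, noise_sigma), nrow(ref))
    def <- def + matrix(stats::rnorm(length(def), 0, noise_sigma), nrow(def))
  }
  list(ref = ref, def = def, shift_px = shift_px)
}

square_roi <- function(lo = 100, hi = 400, step = 10, subset = 21) {
  roi_grid(cbind(c(lo, hi, hi, lo), c(lo, lo, hi, hi)),
           grid_step = step, subset_size = subset)
}

# deterministic non-coplanar point cloud for calibration tests
random_cloud <- function(n = 50, seed = 4) {
  set.seed(seed)
  cbind(stats::runif(n, -10, 10), stats::runif(n, -10, 10),
        stats::runif(n, 2, 16))
}

nasal_band_mean <- function(field, spec = region_spec()) {
  tab <- regionalize(field, spec)
  tab$mean[tab$sector == "nasal" & tab$annulus == "0-1 mm"]
}

# triangle area by the shoelace formula (2D), used by mesh oracles
shoelace <- function(p) {
  n <- nrow(p)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}
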