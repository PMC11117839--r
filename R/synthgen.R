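#' Prescribed deformations for synthetic scenes
#'
#' Three deformation families drive the synthetic scenes: rigid translation
#' (area-preserving), concentric inflation about the globe centre (every
#' surface area scales by k^2), and a tether-like localized compression of
#' the sclera adjacent to the optic-nerve sheath.  The tether field displaces
#' material tangentially along meridians toward the sheath margin with a
#' compactly supported radial profile, so the surface is untouched beyond
#' `2 * decay_mm` of the sheath boundary; its amplitude is calibrated at
#' scene-build time so that the mean face area ratio in the nasal 1 mm
#' annulus equals `nasal_ratio`.
#'
#' @param translation_mm numeric length-3 displacement (mm).
#' @return an object of class `scene_deformation`.
#' @name deformations
NULL

#' @rdname deformations
#' @export
deformation_rigid <- function(translation_mm = c(0, 0, 0)) {
  stopifnot(length(translation_mm) == 3, all(is.finite(translation_mm)))
  structure(list(type = "rigid_translation", t = as.numeric(translation_mm)),
            class = "scene_deformation")
}

#' @rdname deformations
#' @param scale radial scale factor k about the globe centre; face areas
#'   scale by k^2.
#' @export
deformation_inflation <- function(scale = 1.01) {
  stopifnot(scale > 0)
  structure(list(type = "inflation", k = scale), class = "scene_deformation")
}

#' @rdname deformations
#' @param nasal_ratio target mean face area ratio in the nasal annulus within
#'   1 mm of the sheath margin (dimensionless; < 1 compresses).
#' @param decay_mm radial decay scale of the tether field (mm); displacement
#'   is exactly zero beyond `2 * decay_mm` from the sheath margin.
#' @param azimuth_deg azimuth of the compressed (nasal) direction in the
#'   surface frame (deg; nasal = 0).
#' @param width_deg azimuthal half-width of the tether field (deg).
#' @export
deformation_tether <- function(nasal_ratio = 0.977, decay_mm = 1,
                               azimuth_deg = 0, width_deg = 60) {
  stopifnot(nasal_ratio > 0, nasal_ratio < 2, decay_mm > 0, width_deg > 0)
  structure(list(type = "tether", nasal_ratio = nasal_ratio,
                 decay = decay_mm, azimuth = azimuth_deg,
                 width = width_deg, amplitude = NA_real_),
            class = "scene_deformation")
}

#' @export
print.scene_deformation <- function(x, ...) {
  cat("scene deformation:", x$type, "\n")
  invisible(x)
}

# Tether displacement map on a sphere of radius R0 centred at the origin,
# posterior pole along +z, nasal azimuth at alpha = 0 (the +x axis).
# Points at arc distance s from the sheath-boundary circle (polar angle beta)
# are moved along their meridian toward the boundary by
#   u(s) = -A * s * (1 - (s / S)^2)^2 * w(alpha),   0 < s < S = 2 * decay,
# with a compact azimuthal window w.  u(0) = 0 and u(S) = 0, so the map is
# continuous and the identity outside the band.
tether_map <- function(X, R0, beta, A, decay, azimuth_rad, width_rad) {
  X <- rbind(X)
  r <- sqrt(rowSums(X^2))
  dirn <- X / r
  ct <- pmin(1, pmax(-1, dirn[, 3]))
  theta <- acos(ct)
  alpha <- atan2(dirn[, 2], dirn[, 1])
  s <- R0 * (theta - beta)
  S <- 2 * decay
  d_alpha <- (alpha - azimuth_rad + pi) %% (2 * pi) - pi
  w <- ifelse(abs(d_alpha) < width_rad,
              (1 - (d_alpha / width_rad)^2)^2, 0)
  act <- s > 0 & s < S & w > 0
  u <- numeric(length(s))
  u[act] <- -A * s[act] * (1 - (s[act] / S)^2)^2 * w[act]
  theta2 <- theta + u / R0
  out <- cbind(r * sin(theta2) * cos(alpha),
               r * sin(theta2) * sin(alpha),
               r * cos(theta2))
  out
}

# Build the concrete point map X -> X' for a deformation, given the globe
# geometry (radius R0 and sheath boundary polar angle beta, radians).
deformation_fn <- function(def, R0 = NA, beta = NA) {
  switch(def$type,
    rigid_translation = function(X) sweep(rbind(X), 2, def$t, `+`),
    inflation = function(X) def$k * rbind(X),
    tether = {
      if (!is.finite(def$amplitude))
        stop("tether amplitude not calibrated; use render_speckle_scene() ",
             "or calibrate_tether()")
      force(R0); force(beta)
      az <- def$azimuth * pi / 180
      wd <- def$width * pi / 180
      function(X) tether_map(X, R0, beta, def$amplitude, def$decay, az, wd)
    },
    stop("unknown deformation type: ", def$type))
}

#' Scene specification for the synthetic speckle generator
#'
#' Describes a speckled spherical surface (the posterior globe) viewed by a
#' set of pinhole cameras under a prescribed deformation.  All lengths in mm,
#' angles in degrees; the surface frame has the posterior pole along +z and
#' the nasal direction along +x (superior +y, temporal -x).
#'
#' @param globe_radius globe radius (mm).
#' @param sheath_outer_radius optic-nerve sheath outer radius (mm); the
#'   sheath boundary circle sits at polar angle `asin(sheath/globe)`.
#' @param speckle_density speckle dots per mm^2 of surface.
#' @param dot_radius_mean mean speckle dot radius (mm).
#' @param cameras list of `pinhole_camera` objects (at least one; pairs for
#'   stereo work).
#' @param deformation a `scene_deformation`.
#' @param noise_sigma additive Gaussian image noise SD, on a 0..1 intensity
#'   scale.
#' @param cap_angle_deg angular extent of the speckled cap from the pole.
#' @param seed integer seed fixing every stochastic draw.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(globe_radius = 12, sheath_outer_radius = 3.2,
                       speckle_density = 40, dot_radius_mean = 0.05,
                       cameras = camera_pair_rig(),
                       deformation = deformation_rigid(),
                       noise_sigma = 0.005, cap_angle_deg = 35, seed = 1L) {
  stopifnot(globe_radius > sheath_outer_radius, sheath_outer_radius > 0,
            speckle_density > 0, dot_radius_mean > 0, noise_sigma >= 0,
            length(cameras) >= 1)
  for (cm in cameras) {
    stopifnot(inherits(cm, "pinhole_camera"))
    if (any(cm$image_size < 256)) stop("image size must be at least 256 px")
  }
  structure(list(globe_radius = globe_radius,
                 sheath_outer_radius = sheath_outer_radius,
                 speckle_density = speckle_density,
                 dot_radius_mean = dot_radius_mean,
                 cameras = cameras, deformation = deformation,
                 noise_sigma = noise_sigma, cap_angle_deg = cap_angle_deg,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("synthetic speckle scene: globe", x$globe_radius, "mm, sheath",
      x$sheath_outer_radius, "mm,", length(x$cameras), "cameras,",
      "deformation", x$deformation$type, "\n")
  invisible(x)
}

# Fine latitude-longitude ground-truth mesh of the speckled cap.
# Returns vertices (n x 3), faces (m x 3, 1-based), and per-vertex polar
# angle/azimuth.  Used both for exact ground truth and for calibrating the
# tether amplitude.
cap_mesh <- function(R0, theta_min, theta_max, d_arc = 0.1) {
  n_th <- max(8L, ceiling(R0 * (theta_max - theta_min) / d_arc))
  n_al <- max(16L, ceiling(2 * pi * R0 * sin(theta_max) / d_arc))
  th <- seq(theta_min, theta_max, length.out = n_th + 1L)
  al <- seq(0, 2 * pi, length.out = n_al + 1L)[-(n_al + 1L)]
  g <- expand.grid(al = al, th = th)  # al varies fastest
  V <- cbind(R0 * sin(g$th) * cos(g$al),
             R0 * sin(g$th) * sin(g$al),
             R0 * cos(g$th))
  idx <- function(i_th, i_al) (i_th - 1L) * n_al + ((i_al - 1L) %% n_al) + 1L
  i_th <- rep(seq_len(n_th), each = n_al)
  i_al <- rep(seq_len(n_al), times = n_th)
  a <- idx(i_th, i_al);     b <- idx(i_th, i_al + 1L)
  cc <- idx(i_th + 1L, i_al); d <- idx(i_th + 1L, i_al + 1L)
  faces <- rbind(cbind(a, b, cc), cbind(b, d, cc))
  list(vertices = V, faces = unname(faces), theta = g$th, alpha = g$al)
}

# triangle areas for a vertex/face mesh (cross-product form)
mesh_face_areas <- function(V, F) {
  e1 <- V[F[, 2], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  e2 <- V[F[, 3], , drop = FALSE] - V[F[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

mesh_face_centroids <- function(V, F) {
  (V[F[, 1], , drop = FALSE] + V[F[, 2], , drop = FALSE] +
     V[F[, 3], , drop = FALSE]) / 3
}

#' Calibrate the tether amplitude for a scene geometry
#'
#' Solves for the tangential displacement amplitude such that the mean
#' ground-truth face area ratio over the nasal annulus within 1 mm of the
#' sheath margin (30 degree sector centred on the tether azimuth) equals the
#' requested `nasal_ratio`.
#'
#' @param def a tether `scene_deformation`.
#' @param globe_radius,sheath_outer_radius globe geometry (mm).
#' @param sector_deg full central angle of the calibration sector (deg).
#' @return the deformation with its `amplitude` filled in.
#' @export
calibrate_tether <- function(def, globe_radius, sheath_outer_radius,
                             sector_deg = 30) {
  stopifnot(def$type == "tether")
  R0 <- globe_radius
  beta <- asin(sheath_outer_radius / R0)
  S <- 2 * def$decay
  gm <- cap_mesh(R0, beta, beta + (S + 0.5) / R0, d_arc = 0.05)
  cen <- mesh_face_centroids(gm$vertices, gm$faces)
  r <- sqrt(rowSums(cen^2))
  th <- acos(pmin(1, cen[, 3] / r))
  al <- atan2(cen[, 2], cen[, 1])
  s <- R0 * (th - beta)
  d_al <- (al - def$azimuth * pi / 180 + pi) %% (2 * pi) - pi
  sel <- s > 0 & s <= 1 & abs(d_al) <= sector_deg / 2 * pi / 180
  if (!any(sel)) stop("calibration annulus is empty")
  a_ref <- mesh_face_areas(gm$vertices, gm$faces)[sel]
  az <- def$azimuth * pi / 180
  wd <- def$width * pi / 180
  mean_ratio <- function(A) {
    Vd <- tether_map(gm$vertices, R0, beta, A, def$decay, az, wd)
    mean(mesh_face_areas(Vd, gm$faces)[sel] / a_ref)
  }
  f <- function(A) mean_ratio(A) - def$nasal_ratio
  sol <- stats::uniroot(f, c(0, 0.5), tol = 1e-10)
  def$amplitude <- sol$root
  def
}

# Sample speckle dot centres uniformly on the spherical cap, with per-dot
# radius and brightness jitter.  Draws depend only on the current RNG state.
sample_speckles <- function(R0, theta_max, density, radius_mean) {
  cap_area <- 2 * pi * R0^2 * (1 - cos(theta_max))
  n <- max(50L, stats::rpois(1, density * cap_area))
  ct <- stats::runif(n, cos(theta_max), 1)
  st <- sqrt(1 - ct^2)
  al <- stats::runif(n, 0, 2 * pi)
  X <- cbind(R0 * st * cos(al), R0 * st * sin(al), R0 * ct)
  list(centers = X,
       radius = radius_mean * exp(stats::rnorm(n, 0, 0.2)),
       amp = stats::runif(n, 0.5, 0.9))
}

# Render one grayscale image of a dot cloud through a camera.
# Dots are anti-aliased Gaussians; sigma_px is the projected dot radius
# scaled by 2/3 (a dot "radius" covers about 1.5 sigma).  Back-facing dots
# (surface normal pointing away from the camera) are culled.
render_dots <- function(cam, centers, radius, amp, normals = NULL,
                        background = 0.15) {
  if (!is.null(normals)) {
    view <- sweep(-centers, 2, cam$C, `+`)
    keep <- rowSums(view * normals) > 0
    centers <- centers[keep, , drop = FALSE]
    radius <- radius[keep]; amp <- amp[keep]
  }
  z <- camera_depth(cam, centers)
  if (any(z <= 0)) stop("speckled surface behind camera")
  uv <- project_points(cam, centers)
  w <- cam$image_size[1]; h <- cam$image_size[2]
  inside <- uv[, 1] > -10 & uv[, 1] < w + 10 & uv[, 2] > -10 & uv[, 2] < h + 10
  sigma_px <- (radius / 1.5) * cam$f / z
  img <- render_dots_cpp(h, w, uv[inside, 1], uv[inside, 2],
                         sigma_px[inside], amp[inside], background)
  img
}

quantize16 <- function(img) {
  img[img < 0] <- 0
  img[img > 1] <- 1
  round(img * 65535) / 65535
}

#' Render a synthetic stereo speckle scene with exact ground truth
#'
#' Scatters Gaussian speckle dots on the posterior spherical cap, applies the
#' prescribed deformation to the dot material points, and renders reference
#' and deformed grayscale images through every camera of the spec.  An exact
#' ground-truth triangulated surface (reference and deformed vertex
#' positions, per-face area ratios, and per-camera projections) accompanies
#' the images.  Identical specs (including seed) give bit-identical output.
#'
#' @param spec a `scene_spec`.
#' @return list with elements `images` (per camera: `ref`, `def` matrices on
#'   a 0..1 scale, 16-bit quantized), `ground_truth` (vertices_ref,
#'   vertices_def, faces, face_ratio, face_s_mm, face_azimuth_deg,
#'   projections), `spec` (with any tether amplitude calibrated), and
#'   `speckles`.
#' @export
render_speckle_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  R0 <- spec$globe_radius
  beta <- asin(spec$sheath_outer_radius / R0)
  theta_max <- spec$cap_angle_deg * pi / 180
  def <- spec$deformation
  if (def$type == "tether" && !is.finite(def$amplitude)) {
    def <- calibrate_tether(def, R0, spec$sheath_outer_radius)
    spec$deformation <- def
  }
  fmap <- deformation_fn(def, R0, beta)

  # field-of-view check: the pole and the cap rim must project inside every
  # camera, and the cameras must be outside the globe
  rim <- rbind(c(0, 0, R0),
               R0 * cbind(sin(theta_max) * cos(c(0, pi / 2, pi, 3 * pi / 2)),
                          sin(theta_max) * sin(c(0, pi / 2, pi, 3 * pi / 2)),
                          cos(theta_max)))
  for (cm in spec$cameras) {
    if (sqrt(sum(cm$C^2)) <= R0)
      stop("camera inside the globe: invalid configuration")
    uv <- tryCatch(project_points(cm, rim),
                   error = function(e) stop("globe behind camera: ",
                                            conditionMessage(e)))
    if (any(uv[, 1] < 0 | uv[, 1] > cm$image_size[1] |
            uv[, 2] < 0 | uv[, 2] > cm$image_size[2]))
      stop("globe cap outside camera field of view")
  }

  set.seed(spec$seed)
  sp <- sample_speckles(R0, theta_max, spec$speckle_density,
                        spec$dot_radius_mean)
  sp$centers_def <- fmap(sp$centers)

  gm <- cap_mesh(R0, 0.03, theta_max, d_arc = 0.1)
  Vd <- fmap(gm$vertices)
  a_ref <- mesh_face_areas(gm$vertices, gm$faces)
  a_def <- mesh_face_areas(Vd, gm$faces)
  cen <- mesh_face_centroids(gm$vertices, gm$faces)
  r_c <- sqrt(rowSums(cen^2))
  th_c <- acos(pmin(1, cen[, 3] / r_c))
  al_c <- atan2(cen[, 2], cen[, 1])
  gt <- list(vertices_ref = gm$vertices, vertices_def = Vd,
             faces = gm$faces, face_ratio = a_def / a_ref,
             face_s_mm = R0 * (th_c - beta),
             face_azimuth_deg = (al_c * 180 / pi) %% 360,
             projections = lapply(spec$cameras, function(cm)
               list(ref = project_points(cm, gm$vertices),
                    def = project_points(cm, Vd))))

  normals_ref <- sp$centers / sqrt(rowSums(sp$centers^2))
  normals_def <- sp$centers_def / sqrt(rowSums(sp$centers_def^2))
  images <- lapply(spec$cameras, function(cm) {
    iref <- render_dots(cm, sp$centers, sp$radius, sp$amp, normals_ref)
    idef <- render_dots(cm, sp$centers_def, sp$radius, sp$amp, normals_def)
    if (spec$noise_sigma > 0) {
      iref <- iref + matrix(stats::rnorm(length(iref), 0, spec$noise_sigma),
                            nrow(iref))
      idef <- idef + matrix(stats::rnorm(length(idef), 0, spec$noise_sigma),
                            nrow(idef))
    }
    list(ref = quantize16(iref), def = quantize16(idef))
  })
  list(images = images, ground_truth = gt, spec = spec, speckles = sp)
}

#' Planar random-pattern translation standard
#'
#' A sheet of random speckle pattern on the plane z = 0, translated rigidly;
#' the digital analogue of a vernier-stage validation standard.  Used to
#' verify that measured displacements are veridical and surface area ratios
#' stay at unity.
#'
#' @param translation_mm length-3 rigid translation of the pattern (mm).
#' @param extent_mm half-extent of the speckled square (mm).
#' @param cameras list of `pinhole_camera`s (default: stereo rig looking at
#'   the plane).
#' @param speckle_density dots per mm^2.
#' @param dot_radius_mean mean dot radius (mm).
#' @param noise_sigma additive image noise SD (0..1 scale).
#' @param seed integer seed.
#' @return list like [render_speckle_scene()] (planar ground truth).
#' @export
render_plane_scene <- function(translation_mm = c(0, 0, 0), extent_mm = 8,
                               cameras = camera_pair_rig(target_mm = c(0, 0, 0)),
                               speckle_density = 40, dot_radius_mean = 0.05,
                               noise_sigma = 0.005, seed = 1L) {
  set.seed(as.integer(seed))
  n <- max(50L, stats::rpois(1, speckle_density * (2 * extent_mm)^2))
  X <- cbind(stats::runif(n, -extent_mm, extent_mm),
             stats::runif(n, -extent_mm, extent_mm), 0)
  radius <- dot_radius_mean * exp(stats::rnorm(n, 0, 0.2))
  amp <- stats::runif(n, 0.5, 0.9)
  Xd <- sweep(X, 2, as.numeric(translation_mm), `+`)
  images <- lapply(cameras, function(cm) {
    iref <- render_dots(cm, X, radius, amp)
    idef <- render_dots(cm, Xd, radius, amp)
    if (noise_sigma > 0) {
      iref <- iref + matrix(stats::rnorm(length(iref), 0, noise_sigma),
                            nrow(iref))
      idef <- idef + matrix(stats::rnorm(length(idef), 0, noise_sigma),
                            nrow(idef))
    }
    list(ref = quantize16(iref), def = quantize16(idef))
  })
  list(images = images,
       ground_truth = list(translation = as.numeric(translation_mm)),
       cameras = cameras,
       speckles = list(centers = X, centers_def = Xd))
}

#' Cylindrical calibration target
#'
#' Known 3D feature points on the surface of a cylinder (default diameter
#' 25.4 mm, similar to a human eye) together with their projections in each
#' camera, optionally perturbed by Gaussian pixel noise.  Feature points are
#' arranged as a rings-by-columns grid on the camera-facing half of the
#' cylinder, its axis vertical through the nominal globe pole.
#'
#' @param diameter cylinder diameter (mm).
#' @param cameras list of `pinhole_camera`s.
#' @param n_rings number of feature rings along the axis.
#' @param n_per_ring features per ring.
#' @param height_mm axial extent of the feature grid (mm).
#' @param arc_deg angular extent of the feature grid about the camera-facing
#'   line (deg).
#' @param center_mm world position of the cylinder axis midpoint (mm).
#' @param noise_sigma_px Gaussian pixel noise SD added to projections.
#' @param seed integer seed (used only when `noise_sigma_px > 0`).
#' @return list with `points3d` (n x 3 mm), `points2d` (per camera, n x 2
#'   px, noisy if requested), `points2d_true` (noiseless), `visible` (per
#'   camera logical).
#' @export
make_cylinder_target <- function(diameter = 25.4,
                                 cameras = camera_pair_rig(target_mm = c(0, 0, 12)),
                                 n_rings = 9, n_per_ring = 9,
                                 height_mm = 12, arc_deg = 100,
                                 center_mm = c(0, 0, 0),
                                 noise_sigma_px = 0, seed = 1L) {
  stopifnot(diameter > 0, n_rings >= 2, n_per_ring >= 3)
  rad <- diameter / 2
  ang <- seq(-arc_deg / 2, arc_deg / 2, length.out = n_per_ring) * pi / 180
  y <- seq(-height_mm / 2, height_mm / 2, length.out = n_rings)
  g <- expand.grid(ang = ang, y = y)
  pts <- cbind(rad * sin(g$ang), g$y, rad * cos(g$ang))
  pts <- sweep(pts, 2, as.numeric(center_mm), `+`)
  normals <- cbind(sin(g$ang), 0, cos(g$ang))
  set.seed(as.integer(seed))
  proj <- lapply(cameras, function(cm) {
    view <- sweep(-pts, 2, cm$C, `+`)
    facing <- rowSums(view * normals) > 0
    uv <- project_points(cm, pts)
    vis <- facing & uv[, 1] >= 0 & uv[, 1] <= cm$image_size[1] &
      uv[, 2] >= 0 & uv[, 2] <= cm$image_size[2]
    uvn <- uv
    if (noise_sigma_px > 0)
      uvn <- uv + matrix(stats::rnorm(length(uv), 0, noise_sigma_px),
                         ncol = 2)
    list(true = uv, noisy = uvn, visible = vis)
  })
  for (i in seq_along(proj)) {
    if (sum(proj[[i]]$visible) < 6)
      stop("insufficient calibration features visible in camera ", i)
  }
  if (length(cameras) >= 2) {
    both <- Reduce(`&`, lapply(proj, `[[`, "visible"))
    if (sum(both) < 20)
      warning("fewer than 20 features visible in all cameras")
  }
  list(points3d = pts,
       points2d = lapply(proj, `[[`, "noisy"),
       points2d_true = lapply(proj, `[[`, "true"),
       visible = lapply(proj, `[[`, "visible"))
}

#' Synthetic uniaxial stress-strain curve with a toe-region transition
#'
#' Generates an engineering stress-strain curve whose log-log transform is
#' exactly piecewise linear: stress follows `scale * (strain / breakpoint)^g`
#' with exponent `gamma_low` below the breakpoint and `gamma_high` above it
#' (continuous at the breakpoint).  Optional multiplicative Gaussian noise is
#' applied to stress only.  With `gamma_low == gamma_high` the curve is a
#' single power law and downstream bilinear fits are degenerate.
#'
#' The sheath-like defaults reproduce the tissue's reported behaviour: a
#' toe-region transition at 3.4% strain, and (with the 0.037 MPa stress
#' scale and exponents 1.2 / 1.7) tangent moduli of about 1.3 MPa at 3%
#' strain and 3.0 MPa at 7%.
#'
#' @param region_label tissue region label (e.g. "ON_sheath").
#' @param gamma_low,gamma_high log-log slopes below/above the breakpoint.
#' @param breakpoint_strain transition strain (dimensionless; sheath-like
#'   default 0.034).
#' @param scale stress at the breakpoint (MPa).
#' @param noise_sigma relative noise SD on stress.
#' @param n_samples number of strain samples.
#' @param strain_max maximum strain.
#' @param seed integer seed.
#' @return a `stress_strain_curve` with attribute `ground_truth`.
#' @export
synth_tensile <- function(region_label = "ON_sheath",
                          gamma_low = 1.2, gamma_high = 1.7,
                          breakpoint_strain = 0.034, scale = 0.037,
                          noise_sigma = 0.02, n_samples = 120,
                          strain_max = 0.12, seed = 1L) {
  stopifnot(gamma_low > 0, gamma_high > 0, scale > 0,
            breakpoint_strain > 0, breakpoint_strain < strain_max,
            n_samples >= 8)
  eps <- seq(strain_max / n_samples, strain_max, length.out = n_samples)
  if (any(eps <= 0)) stop("non-positive strains requested")
  g <- ifelse(eps <= breakpoint_strain, gamma_low, gamma_high)
  sig <- scale * (eps / breakpoint_strain)^g
  set.seed(as.integer(seed))
  if (noise_sigma > 0)
    sig <- sig * (1 + stats::rnorm(n_samples, 0, noise_sigma))
  cur <- stress_strain_curve(eps, sig, region_label)
  attr(cur, "ground_truth") <- list(gamma_low = gamma_low,
                                    gamma_high = gamma_high,
                                    breakpoint_strain = breakpoint_strain,
                                    scale = scale)
  cur
}

#' Synthetic force-elongation tensile record
#'
#' Inverts a stress-strain backbone into the raw quantities a tensile rig
#' logs (force in N, grip separation in mm at 5 Hz), including an initial
#' ramp below the 0.02 N preload, for exercising [to_stress_strain()].
#'
#' @param curve a `stress_strain_curve` backbone.
#' @param width,thickness specimen cross-section (mm).
#' @param gauge_length_0 grip separation at preload (mm).
#' @param preload preload force (N).
#' @return a `tensile_record` list.
#' @export
synth_tensile_record <- function(curve, width = 2.11, thickness = 0.5,
                                 gauge_length_0 = 8.43, preload = 0.02) {
  area <- width * thickness
  f_pre <- preload
  force <- f_pre + curve$stress * area
  len <- gauge_length_0 * (1 + curve$strain)
  # prepend a short ramp reaching the preload exactly at gauge_length_0, so
  # the strain reference of the reconstructed curve matches the backbone
  n0 <- 6L
  force <- c(seq(0, f_pre, length.out = n0), force)
  len <- c(seq(gauge_length_0 * 0.995, gauge_length_0, length.out = n0), len)
  tensile_record(force = force, grip_length = len, width = width,
                 thickness = thickness, region_label = curve$region,
                 preload = preload, sample_rate_hz = 5)
}
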