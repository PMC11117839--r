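#' Calibrate a camera rig against a cylindrical target
#'
#' Renders (projects) the cylindrical calibration target through each
#' camera and estimates DLT parameters per camera, exactly as a physical
#' rig is calibrated before measurement.
#'
#' @param cameras list of `pinhole_camera`s.
#' @param target optional precomputed [make_cylinder_target()] output.
#' @param noise_sigma_px feature-localization noise (px).
#' @param seed seed for the feature noise.
#' @param ... passed to [make_cylinder_target()].
#' @return list of `camera_dlt` objects.
#' @export
calibrate_rig <- function(cameras, target = NULL, noise_sigma_px = 0,
                          seed = 1L, ...) {
  if (is.null(target))
    target <- make_cylinder_target(cameras = cameras,
                                   noise_sigma_px = noise_sigma_px,
                                   seed = seed, ...)
  lapply(seq_along(cameras), function(i) {
    vis <- target$visible[[i]]
    dlt_calibrate(target$points3d[vis, , drop = FALSE],
                  target$points2d[[i]][vis, , drop = FALSE],
                  image_size = cameras[[i]]$image_size)
  })
}

# ROI polygon for the scleral annulus around the sheath, built from the
# known specimen geometry (not from deformation ground truth): the
# projection through a camera of the circle at geodesic distance s from
# the sheath margin.
ring_polygon <- function(cam, globe_radius, sheath_radius, s_mm,
                         n = 72) {
  beta <- asin(sheath_radius / globe_radius)
  th <- beta + s_mm / globe_radius
  al <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  X <- globe_radius * cbind(sin(th) * cos(al), sin(th) * sin(al),
                            rep(cos(th), n))
  if (inherits(cam, "camera_dlt")) dlt_project(cam, X)
  else project_points(cam, X)
}

#' Reconstruct matched surfaces from a rendered stereo scene
#'
#' The full measurement chain on a synthetic scene: DLT calibration from a
#' cylindrical target, stereo subset matching between the two reference
#' images, temporal subset matching within each camera, two-view
#' triangulation of both states, triangulation-residual rejection, and
#' meshing of the surviving grid points (connectivity shared across
#' states).
#'
#' @param scene output of [render_speckle_scene()] (two cameras or more;
#'   the first two are used).
#' @param params a [dic_params()].
#' @param roi optional [roi_grid()] on camera 1; default is an annulus
#'   from 0.05 to 2.8 mm outside the sheath margin, built from the
#'   specimen geometry.
#' @param residual_max triangulation residual rejection threshold (px).
#' @param calib_noise_px calibration feature noise (px).
#' @return list with `reference` and `loaded` `surface_mesh`es, the
#'   `field` ([area_ratio()]), the DLT `cams`, match tables, and the kept
#'   grid points.
#' @export
reconstruct_scene <- function(scene, params = dic_params(), roi = NULL,
                              residual_max = 1, calib_noise_px = 0) {
  spec <- scene$spec
  if (length(spec$cameras) < 2)
    stop("stereo reconstruction needs at least two cameras")
  cams_pin <- spec$cameras[1:2]
  if (max(abs(cams_pin[[1]]$C - cams_pin[[2]]$C)) < 1e-9)
    stop("degenerate stereo geometry: identical cameras (zero baseline)")
  dlt <- calibrate_rig(cams_pin, noise_sigma_px = calib_noise_px)
  pair <- camera_pair(dlt[[1]], dlt[[2]])

  if (is.null(roi)) {
    outer <- ring_polygon(cams_pin[[1]], spec$globe_radius,
                          spec$sheath_outer_radius, 2.8)
    inner <- ring_polygon(cams_pin[[1]], spec$globe_radius,
                          spec$sheath_outer_radius, 0.05)
    # finer grid and a smaller subset than the generic defaults: the tether
    # field varies over ~1 mm (~30 px), and a large subset low-passes it
    roi <- roi_grid(outer, grid_step = 4, subset_size = 17,
                    exclude = inner)
  }

  im1 <- scene$images[[1]]; im2 <- scene$images[[2]]
  st <- stereo_match(im1$ref, im2$ref, roi, params)
  t1 <- correlate(im1$ref, im1$def, roi, params)

  ok <- st$status == "ok" & t1$status == "ok"
  # temporal match in camera 2 at the (rounded) stereo partner locations,
  # initialized from camera 1's displacement
  pts2 <- cbind(round(st$def_u - 0.5), round(st$def_v - 0.5))
  bad2 <- !ok | !is.finite(pts2[, 1]) | !is.finite(pts2[, 2])
  pts2[bad2, ] <- 0L
  roi2 <- roi
  roi2$points <- pts2
  init2 <- cbind(round(t1$dx), round(t1$dy))
  init2[!is.finite(init2)] <- 0L
  t2 <- correlate(im2$ref, im2$def, roi2, params, init = init2)
  ok <- ok & t2$status == "ok"
  if (sum(ok) < 3) stop("fewer than 3 grid points survived matching")

  # subpixel camera-2 positions: stereo partner plus its local temporal
  # displacement
  ref_a <- cbind(st$ref_u, st$ref_v)
  ref_b <- cbind(st$def_u, st$def_v)
  def_a <- cbind(t1$def_u, t1$def_v)
  def_b <- ref_b + cbind(t2$dx, t2$dy)

  tri_ref <- triangulate(pair, ref_a[ok, , drop = FALSE],
                         ref_b[ok, , drop = FALSE])
  tri_def <- triangulate(pair, def_a[ok, , drop = FALSE],
                         def_b[ok, , drop = FALSE])
  keep <- tri_ref$residual_px < residual_max &
    tri_def$residual_px < residual_max
  if (sum(keep) < 3) stop("triangulation-residual filter left < 3 points")

  uv <- roi$points[ok, , drop = FALSE][keep, , drop = FALSE]
  meshes <- build_mesh(tri_ref$points3d[keep, , drop = FALSE],
                       tri_def$points3d[keep, , drop = FALSE],
                       uv = uv, provenance = "dic")
  field <- area_ratio(meshes$reference, meshes$loaded)
  list(reference = meshes$reference, loaded = meshes$loaded,
       field = field, cams = dlt, stereo = st, temporal_1 = t1,
       temporal_2 = t2, grid_uv = uv,
       residual_ref = tri_ref$residual_px[keep],
       residual_def = tri_def$residual_px[keep])
}

#' Validate the pipeline on a planar translation standard
#'
#' Renders a planar random-pattern standard, translates it rigidly by each
#' requested magnitude in the normal (out-of-plane) and tangential
#' (in-plane) directions, runs the full stereo DIC chain, and reports the
#' measured displacement against the true one together with the mean
#' surface area ratio (ideal: veridical displacement, ratio of unity).
#' Correlation failures are reported per magnitude, not fatal.
#'
#' @param magnitudes_mm translation magnitudes (mm).
#' @param directions subset of c("normal", "tangential").
#' @param extent_mm half-extent of the pattern (mm).
#' @param params a [dic_params()].
#' @param noise_sigma image noise SD.
#' @param seed scene seed.
#' @return data.frame: direction, magnitude_mm, measured_mm, error_mm,
#'   mean_area_ratio, n_points, failed.
#' @export
validate_translation_standard <- function(magnitudes_mm = c(0.5, 1, 1.5, 2),
                                          directions = c("normal",
                                                         "tangential"),
                                          extent_mm = 8,
                                          params = dic_params(),
                                          noise_sigma = 0.005,
                                          seed = 1L) {
  directions <- match.arg(directions, c("normal", "tangential"),
                          several.ok = TRUE)
  cams <- camera_pair_rig(target_mm = c(0, 0, 0))
  target <- make_cylinder_target(cameras = cams,
                                 center_mm = c(0, 0, -12.7))
  dlt <- calibrate_rig(cams, target = target)
  pair <- camera_pair(dlt[[1]], dlt[[2]])
  sq <- 0.75 * extent_mm
  poly <- project_points(cams[[1]],
                         cbind(c(-sq, sq, sq, -sq), c(-sq, -sq, sq, sq), 0))
  roi <- roi_grid(poly, grid_step = 6, subset_size = 21)

  rows <- list()
  for (dir in directions) {
    for (m in magnitudes_mm) {
      tvec <- if (dir == "normal") c(0, 0, m) else c(m, 0, 0)
      run <- length(rows) + 1L  # independent pattern/noise per run
      row <- tryCatch({
        sc <- render_plane_scene(tvec, extent_mm = extent_mm,
                                 cameras = cams,
                                 noise_sigma = noise_sigma,
                                 seed = seed + run)
        # rigid translation can reach tens of px: find it once at a seed
        # point with a wide window, then a narrow search everywhere else
        p <- params
        disp_px <- max(20, ceiling(abs(m) * cams[[1]]$f / 100) + 8)
        seed_roi <- roi
        seed_roi$points <- roi$points[which.min(rowSums(sweep(
          roi$points, 2, colMeans(roi$points))^2)), , drop = FALSE]
        p$search <- disp_px
        t_seed <- correlate(sc$images[[1]]$ref, sc$images[[1]]$def,
                            seed_roi, p)
        if (t_seed$status[1] != "ok") stop("temporal seed match failed")
        p$search <- 6
        init_t <- round(c(t_seed$dx[1], t_seed$dy[1]))
        st <- stereo_match(sc$images[[1]]$ref, sc$images[[2]]$ref, roi, p)
        t1 <- correlate(sc$images[[1]]$ref, sc$images[[1]]$def, roi, p,
                        init = init_t)
        ok <- st$status == "ok" & t1$status == "ok"
        pts2 <- cbind(round(st$def_u - 0.5), round(st$def_v - 0.5))
        pts2[!is.finite(pts2)] <- 0L
        ok <- ok & is.finite(st$def_u)
        roi2 <- roi; roi2$points <- pts2
        # camera 2 needs its own seed: out-of-plane motion shifts the two
        # (opposed) cameras in opposite image directions
        seed2 <- roi2
        seed2$points <- pts2[which(ok)[1], , drop = FALSE]
        p$search <- disp_px
        t2_seed <- correlate(sc$images[[2]]$ref, sc$images[[2]]$def,
                             seed2, p)
        if (t2_seed$status[1] != "ok")
          stop("temporal seed match failed in camera 2")
        p$search <- 6
        t2 <- correlate(sc$images[[2]]$ref, sc$images[[2]]$def, roi2, p,
                        init = round(c(t2_seed$dx[1], t2_seed$dy[1])))
        ok <- ok & t2$status == "ok"
        tri_r <- triangulate(pair, cbind(st$ref_u, st$ref_v)[ok, ],
                             cbind(st$def_u, st$def_v)[ok, ])
        tri_d <- triangulate(pair, cbind(t1$def_u, t1$def_v)[ok, ],
                             (cbind(st$def_u, st$def_v) +
                                cbind(t2$dx, t2$dy))[ok, ])
        keep <- tri_r$residual_px < 1 & tri_d$residual_px < 1
        disp <- tri_d$points3d[keep, , drop = FALSE] -
          tri_r$points3d[keep, , drop = FALSE]
        mag <- sqrt(rowSums(disp^2))
        msh <- build_mesh(tri_r$points3d[keep, , drop = FALSE],
                          tri_d$points3d[keep, , drop = FALSE],
                          uv = roi$points[ok, , drop = FALSE][keep, ,
                                                              drop = FALSE])
        fld <- area_ratio(msh$reference, msh$loaded)
        data.frame(direction = dir, magnitude_mm = m,
                   measured_mm = mean(mag),
                   error_mm = mean(mag) - m,
                   mean_area_ratio = mean(fld$ratio),
                   n_points = sum(keep), failed = FALSE)
      }, error = function(e)
        data.frame(direction = dir, magnitude_mm = m,
                   measured_mm = NA_real_, error_mm = NA_real_,
                   mean_area_ratio = NA_real_, n_points = 0L,
                   failed = TRUE))
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write scene images and ground truth to disk
#'
#' Images as 8-bit grayscale PNG plus (when the tiff package is installed)
#' lossless 16-bit grayscale TIFF; the ground-truth vertex table as CSV
#' with columns x_mm, y_mm, z_mm, u_px, v_px, camera_id, state.
#'
#' @param scene output of [render_speckle_scene()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  has_tiff <- requireNamespace("tiff", quietly = TRUE)
  for (i in seq_along(scene$images)) {
    for (st in c("ref", "def")) {
      img <- scene$images[[i]][[st]]
      png::writePNG(img, file.path(dir, sprintf("cam%d_%s.png", i, st)))
      if (has_tiff)
        tiff::writeTIFF(img, file.path(dir, sprintf("cam%d_%s.tif", i, st)),
                        bits.per.sample = 16L)
    }
  }
  gt <- scene$ground_truth
  tabs <- lapply(seq_along(gt$projections), function(i) {
    rbind(data.frame(x_mm = gt$vertices_ref[, 1],
                     y_mm = gt$vertices_ref[, 2],
                     z_mm = gt$vertices_ref[, 3],
                     u_px = gt$projections[[i]]$ref[, 1],
                     v_px = gt$projections[[i]]$ref[, 2],
                     camera_id = i, state = "reference"),
          data.frame(x_mm = gt$vertices_def[, 1],
                     y_mm = gt$vertices_def[, 2],
                     z_mm = gt$vertices_def[, 3],
                     u_px = gt$projections[[i]]$def[, 1],
                     v_px = gt$projections[[i]]$def[, 2],
                     camera_id = i, state = "loaded"))
  })
  utils::write.csv(do.call(rbind, tabs),
                   file.path(dir, "ground_truth.csv"), row.names = FALSE)
  write_ply(surface_mesh(gt$vertices_ref, gt$faces, "reference",
                         "synthetic"),
            file.path(dir, "ground_truth_ref.ply"))
  invisible(dir)
}

#' Scene specification YAML I/O
#'
#' Serializes the full scene description (geometry, speckle statistics,
#' cameras, deformation, noise, seed) so a scene can be regenerated
#' bit-identically elsewhere.
#'
#' @param spec a [scene_spec()].
#' @param path YAML file path.
#' @export
write_scene_yaml <- function(spec, path) {
  cams <- lapply(spec$cameras, function(cm)
    list(position = cm$C, rotation = as.numeric(t(cm$R)),
         focal_px = cm$f, principal = cm$pp,
         image_size = cm$image_size))
  d <- spec$deformation
  yaml::write_yaml(list(globe_radius = spec$globe_radius,
                        sheath_outer_radius = spec$sheath_outer_radius,
                        speckle_density = spec$speckle_density,
                        dot_radius_mean = spec$dot_radius_mean,
                        noise_sigma = spec$noise_sigma,
                        cap_angle_deg = spec$cap_angle_deg,
                        seed = spec$seed,
                        cameras = cams,
                        deformation = unclass(d)), path, precision = 17)
  invisible(path)
}

#' @rdname write_scene_yaml
#' @export
read_scene_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cams <- lapply(y$cameras, function(cm) {
    obj <- structure(list(R = matrix(as.numeric(cm$rotation), 3, 3,
                                     byrow = TRUE),
                          C = as.numeric(cm$position),
                          f = cm$focal_px, pp = as.numeric(cm$principal),
                          image_size = as.integer(cm$image_size)),
                     class = "pinhole_camera")
    obj
  })
  d <- y$deformation
  def <- switch(d$type,
    rigid_translation = deformation_rigid(as.numeric(d$t)),
    inflation = deformation_inflation(d$k),
    tether = {
      td <- deformation_tether(d$nasal_ratio, d$decay, d$azimuth, d$width)
      if (!is.null(d$amplitude) && is.finite(d$amplitude))
        td$amplitude <- d$amplitude
      td
    },
    stop("unknown deformation type in YAML"))
  scene_spec(globe_radius = y$globe_radius,
             sheath_outer_radius = y$sheath_outer_radius,
             speckle_density = y$speckle_density,
             dot_radius_mean = y$dot_radius_mean,
             cameras = cams, deformation = def,
             noise_sigma = y$noise_sigma,
             cap_angle_deg = y$cap_angle_deg, seed = y$seed)
}
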