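#' Per-face surface area ratio between matched mesh states
#'
#' The deformation metric of the pipeline: for each triangular face, the
#' loaded area divided by the reference area.  Ratios below one indicate
#' local compression, above one expansion.  Faces with reference area below
#' `min_area` are excluded and logged.  The metric deliberately replaces
#' surface strain, which assumes negligible thickness change and is invalid
#' for compressive tether loading.
#'
#' @param reference,loaded `surface_mesh`es with identical connectivity.
#' @param min_area reference-area floor (mm^2).
#' @return object of class `area_ratio_field`: `ratio` (per face),
#'   `centroids` (reference, mm), `face_area_ref` (mm^2), `faces` (kept
#'   connectivity rows), `excluded` (indices of dropped faces).
#' @export
area_ratio <- function(reference, loaded, min_area = 1e-9) {
  stopifnot(inherits(reference, "surface_mesh"),
            inherits(loaded, "surface_mesh"))
  if (!identical(dim(reference$faces), dim(loaded$faces)) ||
      any(reference$faces != loaded$faces))
    stop("reference and loaded meshes must share connectivity")
  a_ref <- mesh_face_areas(reference$vertices, reference$faces)
  a_def <- mesh_face_areas(loaded$vertices, loaded$faces)
  excl <- which(a_ref < min_area)
  keep <- setdiff(seq_along(a_ref), excl)
  if (length(excl))
    message(length(excl), " face(s) with near-zero reference area excluded")
  structure(list(ratio = a_def[keep] / a_ref[keep],
                 centroids = mesh_face_centroids(reference$vertices,
                                                 reference$faces)[keep, ,
                                                                  drop = FALSE],
                 face_area_ref = a_ref[keep],
                 face_area_loaded = a_def[keep],
                 faces = reference$faces[keep, , drop = FALSE],
                 excluded = excl),
            class = "area_ratio_field")
}

#' @export
print.area_ratio_field <- function(x, ...) {
  cat("area ratio field:", length(x$ratio), "faces, mean",
      format(mean(x$ratio), digits = 5), ", range",
      paste(format(range(x$ratio), digits = 5), collapse = " .. "), "\n")
  invisible(x)
}

#' Least-squares sphere fit
#'
#' Fits a sphere to a point cloud by the linear algebraic method
#' (|X|^2 = 2 c.X + (R^2 - |c|^2)).  Used to measure geodesic arc lengths on
#' the reconstructed, approximately spherical scleral surface.
#'
#' @param X n x 3 points (mm).
#' @return list with `center` (mm) and `radius` (mm).
#' @export
fit_sphere <- function(X) {
  X <- as.matrix(X)
  A <- cbind(2 * X, 1)
  b <- rowSums(X^2)
  th <- qr.solve(A, b)
  ctr <- th[1:3]
  r2 <- th[4] + sum(ctr^2)
  if (r2 <= 0) stop("sphere fit failed (non-positive radius)")
  list(center = ctr, radius = sqrt(r2))
}

#' Regional layout around the optic-nerve sheath
#'
#' Defines the analysis regions on the scleral surface: fan-shaped sectors
#' of a given central angle in the nasal, superior and temporal directions,
#' each divided into annular bands by geodesic distance from the sheath
#' margin, plus narrow strips along the three directions.  The inferior
#' sector is absent (occluded by the nerve gripper in the physical rig).
#'
#' @param sheath_center 3D point on the surface at the centre of the sheath
#'   footprint (mm).
#' @param sheath_boundary_radius sheath outer radius (mm); the margin circle
#'   from which geodesic distances are measured.
#' @param nasal_direction world vector fixing azimuth zero.
#' @param sector_azimuths named azimuths (deg) of the sector centres.
#' @param sector_angle full central angle of each sector (deg).
#' @param annuli k x 2 matrix of radial bands (mm from the sheath margin),
#'   non-overlapping and ordered.
#' @param strip_width strip width (mm).
#' @return object of class `region_spec`.
#' @export
region_spec <- function(sheath_center = c(0, 0, 12),
                        sheath_boundary_radius = 3.2,
                        nasal_direction = c(1, 0, 0),
                        sector_azimuths = c(nasal = 0, superior = 90,
                                            temporal = 180),
                        sector_angle = 30,
                        annuli = rbind(c(0, 1), c(1, 2)),
                        strip_width = 0.1) {
  annuli <- rbind(annuli)
  stopifnot(sector_angle > 0, strip_width > 0,
            sheath_boundary_radius > 0, ncol(annuli) == 2,
            all(annuli[, 2] > annuli[, 1]))
  if (nrow(annuli) > 1 &&
      any(annuli[-1, 1] < annuli[-nrow(annuli), 2] - 1e-12))
    stop("annular bands must be non-overlapping and ordered")
  structure(list(sheath_center = as.numeric(sheath_center),
                 sheath_boundary_radius = sheath_boundary_radius,
                 nasal_direction = as.numeric(nasal_direction),
                 sector_azimuths = sector_azimuths,
                 sector_angle = sector_angle, annuli = annuli,
                 strip_width = strip_width),
            class = "region_spec")
}

# Geodesic coordinates of face centroids relative to the sheath margin:
# arc distance s (mm, measured on the best-fit sphere of the reference
# surface) and azimuth (deg, 0 = nasal).  Geodesic rather than chord
# distance: regions live on a curved surface; the difference is
# second-order at 1-2 mm on a 12 mm globe.
surface_coords <- function(field, spec, sphere = NULL) {
  if (is.null(sphere)) sphere <- fit_sphere(field$centroids)
  pole <- spec$sheath_center - sphere$center
  pole <- pole / sqrt(sum(pole^2))
  e1 <- spec$nasal_direction -
    sum(spec$nasal_direction * pole) * pole
  n1 <- sqrt(sum(e1^2))
  if (n1 < 1e-9) stop("nasal direction is parallel to the pole axis")
  e1 <- e1 / n1
  e2 <- pracma_cross(pole, e1)
  V <- sweep(field$centroids, 2, sphere$center)
  V <- V / sqrt(rowSums(V^2))
  ang <- acos(pmin(1, pmax(-1, V %*% pole)))
  rad_ratio <- min(1, spec$sheath_boundary_radius / sphere$radius)
  beta <- asin(rad_ratio)
  s <- sphere$radius * (as.numeric(ang) - beta)
  az <- atan2(as.numeric(V %*% e2), as.numeric(V %*% e1)) * 180 / pi
  list(s = s, azimuth = az, sphere = sphere, pole = pole, e1 = e1, e2 = e2)
}

#' Regional summary of an area-ratio field
#'
#' Labels each face by sector and annulus and summarizes the per-face area
#' ratios per region: unweighted mean and SD (the default convention),
#' face-area-weighted mean, and face count.  Empty regions are flagged and
#' carry NA statistics.
#'
#' @param field an `area_ratio_field`.
#' @param spec a [region_spec()].
#' @return data.frame with one row per sector x annulus.
#' @export
regionalize <- function(field, spec) {
  co <- surface_coords(field, spec)
  half <- spec$sector_angle / 2
  rows <- list()
  for (sec in names(spec$sector_azimuths)) {
    az0 <- spec$sector_azimuths[[sec]]
    d_az <- (co$azimuth - az0 + 180) %% 360 - 180
    in_sec <- abs(d_az) <= half
    for (b in seq_len(nrow(spec$annuli))) {
      lo <- spec$annuli[b, 1]; hi <- spec$annuli[b, 2]
      sel <- in_sec & co$s > lo & co$s <= hi
      n <- sum(sel)
      rows[[length(rows) + 1L]] <- data.frame(
        sector = sec, annulus = sprintf("%g-%g mm", lo, hi),
        n_faces = n,
        mean = if (n) mean(field$ratio[sel]) else NA_real_,
        sd = if (n > 1) stats::sd(field$ratio[sel]) else NA_real_,
        weighted_mean = if (n)
          sum(field$ratio[sel] * field$face_area_ref[sel]) /
            sum(field$face_area_ref[sel]) else NA_real_,
        empty = n == 0L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$empty)) warning(sum(out$empty), " empty region(s) flagged")
  out
}

#' Strip profile of area ratio versus distance from the sheath margin
#'
#' Mean face area ratio in a narrow strip along one of the principal
#' directions, binned by geodesic distance from the sheath margin at the
#' strip-width resolution.  Bin centres start at 0; ties at bin edges go to
#' the lower bin.
#'
#' @param field an `area_ratio_field`.
#' @param spec a [region_spec()].
#' @param direction name of an azimuth in `spec$sector_azimuths`.
#' @param max_distance profile extent (mm).
#' @return data.frame with columns distance_mm, ratio_mean, ratio_sd, n.
#' @export
strip_profile <- function(field, spec, direction = "nasal",
                          max_distance = 3) {
  if (!direction %in% names(spec$sector_azimuths))
    stop("unknown direction '", direction, "'")
  co <- surface_coords(field, spec)
  az0 <- spec$sector_azimuths[[direction]]
  # perpendicular arc distance from the meridian plane of the direction
  e_dir <- cos(az0 * pi / 180) * co$e1 + sin(az0 * pi / 180) * co$e2
  nrm <- pracma_cross(co$pole, e_dir)
  V <- sweep(field$centroids, 2, co$sphere$center)
  V <- V / sqrt(rowSums(V^2))
  t_arc <- co$sphere$radius * asin(pmin(1, pmax(-1, V %*% nrm)))
  d_az <- (co$azimuth - az0 + 180) %% 360 - 180
  sel <- abs(t_arc) <= spec$strip_width / 2 & abs(d_az) < 90 &
    co$s > -spec$strip_width / 2 & co$s <= max_distance
  if (!any(sel)) stop("no faces in the ", direction, " strip")
  wd <- spec$strip_width
  bin <- floor(co$s[sel] / wd + 0.5 - 1e-9)  # ties at edges -> lower bin
  agg <- tapply(field$ratio[sel], bin, function(r)
    c(mean(r), stats::sd(r), length(r)))
  k <- as.integer(names(agg))
  m <- do.call(rbind, agg)
  data.frame(distance_mm = k * wd, ratio_mean = m[, 1],
             ratio_sd = m[, 2], n = m[, 3], row.names = NULL)
}

#' Mean absolute difference of area ratios from unity, per region
#'
#' The magnitude summary used to compare loading modes: for each sector x
#' annulus region, the mean over faces of |ratio - 1|.
#'
#' @param field an `area_ratio_field`.
#' @param spec a [region_spec()].
#' @return data.frame with columns sector, annulus, mad, n_faces.
#' @export
mad_from_unity <- function(field, spec) {
  co <- surface_coords(field, spec)
  half <- spec$sector_angle / 2
  rows <- list()
  for (sec in names(spec$sector_azimuths)) {
    az0 <- spec$sector_azimuths[[sec]]
    d_az <- (co$azimuth - az0 + 180) %% 360 - 180
    in_sec <- abs(d_az) <= half
    for (b in seq_len(nrow(spec$annuli))) {
      sel <- in_sec & co$s > spec$annuli[b, 1] & co$s <= spec$annuli[b, 2]
      rows[[length(rows) + 1L]] <- data.frame(
        sector = sec,
        annulus = sprintf("%g-%g mm", spec$annuli[b, 1], spec$annuli[b, 2]),
        mad = if (any(sel)) mean(abs(field$ratio[sel] - 1)) else NA_real_,
        n_faces = sum(sel))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Heat-map rendering of an area-ratio field
#'
#' Draws the per-face ratios as colored triangles on a 2D projection of the
#' reference mesh (through a camera, or onto the best-fit plane) and
#' optionally writes a PNG.
#'
#' @param field an `area_ratio_field`.
#' @param mesh the reference `surface_mesh` the field was computed on.
#' @param camera optional `pinhole_camera` or `camera_dlt` used for the
#'   projection; default is the best-fit plane of the vertices.
#' @param path optional PNG output path.
#' @param zlim color range for the ratio.
#' @param n_colors colormap resolution.
#' @return invisibly, the projected vertex coordinates.
#' @export
plot_area_ratio <- function(field, mesh, camera = NULL, path = NULL,
                            zlim = c(0.95, 1.05), n_colors = 64) {
  V <- mesh$vertices
  if (is.null(camera)) {
    ctr <- colMeans(V)
    sv <- svd(sweep(V, 2, ctr))
    P <- sweep(V, 2, ctr) %*% sv$v[, 1:2]
  } else if (inherits(camera, "pinhole_camera")) {
    P <- project_points(camera, V)
  } else if (inherits(camera, "camera_dlt")) {
    P <- dlt_project(camera, V)
  } else stop("unsupported camera object")
  pal <- grDevices::hcl.colors(n_colors, "Blue-Red 3")
  idx <- pmin(n_colors, pmax(1L, 1L + floor((field$ratio - zlim[1]) /
                                              diff(zlim) * (n_colors - 1L))))
  if (!is.null(path)) {
    grDevices::png(path, width = 700, height = 700)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(range(P[, 1]), range(P[, 2]), type = "n", asp = 1,
                 xlab = "u", ylab = "v",
                 main = "surface area ratio (loaded / reference)")
  for (k in seq_len(nrow(field$faces))) {
    f <- field$faces[k, ]
    graphics::polygon(P[f, 1], P[f, 2], col = pal[idx[k]], border = NA)
  }
  invisible(P)
}

#' Mean absolute difference between two area-ratio fields
#'
#' Repeatability metric between two independent runs over the same surface:
#' fields are matched face-to-face when connectivity is shared, otherwise by
#' nearest reference centroid, and the mean |difference| of ratios over the
#' common domain is returned.
#'
#' @param field_a,field_b `area_ratio_field`s.
#' @return mean absolute ratio difference (dimensionless).
#' @export
heatmap_difference <- function(field_a, field_b) {
  if (length(field_a$ratio) == length(field_b$ratio) &&
      isTRUE(all.equal(field_a$centroids, field_b$centroids,
                       tolerance = 1e-8)))
    return(mean(abs(field_a$ratio - field_b$ratio)))
  # nearest-centroid matching; the mean is estimated over at most 2000
  # evenly spaced probe faces to keep the metric cheap on dense meshes
  idx <- seq_along(field_a$ratio)
  if (length(idx) > 2000)
    idx <- idx[seq(1, length(idx), length.out = 2000)]
  B <- field_b$centroids
  nb <- vapply(idx, function(i) {
    d2 <- (B[, 1] - field_a$centroids[i, 1])^2 +
      (B[, 2] - field_a$centroids[i, 2])^2 +
      (B[, 3] - field_a$centroids[i, 3])^2
    which.min(d2)
  }, 0L)
  mean(abs(field_a$ratio[idx] - field_b$ratio[nb]))
}

#' Write a regional summary table to CSV
#'
#' @param summary data.frame from [regionalize()] or [mad_from_unity()].
#' @param path output file.
#' @export
write_region_csv <- function(summary, path) {
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}
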