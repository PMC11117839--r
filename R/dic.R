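#' Region-of-interest grid for subset correlation
#'
#' Lays a regular grid of integer-pixel subset centres inside a polygonal
#' region of interest, optionally excluding an inner polygon (e.g. the
#' optic-nerve sheath footprint).
#'
#' Image coordinates: a pixel at matrix position `[i, j]` (1-based row i =
#' vertical, column j = horizontal) has px coordinates `(u, v) = (j - 0.5,
#' i - 0.5)`, matching [project_points()].  Grid points are stored as 0-based
#' integer array indices `(x, y) = (u - 0.5, v - 0.5)`.
#'
#' @param polygon n x 2 matrix of (u, v) px vertices of the ROI boundary.
#' @param grid_step grid spacing in px.
#' @param subset_size correlation subset size in px (odd, >= 11).
#' @param exclude optional n x 2 polygon; grid points inside it are dropped.
#' @return object of class `roi_grid` with integer point matrix `$points`
#'   (columns x, y).
#' @export
roi_grid <- function(polygon, grid_step = 5, subset_size = 21,
                     exclude = NULL) {
  polygon <- rbind(polygon)
  stopifnot(ncol(polygon) == 2, nrow(polygon) >= 3,
            grid_step >= 1, subset_size >= 11, subset_size %% 2 == 1)
  xr <- range(polygon[, 1]); yr <- range(polygon[, 2])
  xs <- seq(ceiling(xr[1]), floor(xr[2]), by = grid_step)
  ys <- seq(ceiling(yr[1]), floor(yr[2]), by = grid_step)
  g <- as.matrix(expand.grid(x = xs, y = ys))
  keep <- point_in_polygon(g[, 1] + 0.5, g[, 2] + 0.5, polygon)
  if (!is.null(exclude))
    keep <- keep & !point_in_polygon(g[, 1] + 0.5, g[, 2] + 0.5,
                                     rbind(exclude))
  pts <- g[keep, , drop = FALSE]
  if (nrow(pts) == 0) stop("ROI polygon contains no grid points")
  structure(list(points = pts, polygon = polygon, grid_step = grid_step,
                 subset_size = as.integer(subset_size)),
            class = "roi_grid")
}

#' @export
print.roi_grid <- function(x, ...) {
  cat("ROI grid:", nrow(x$points), "points, step", x$grid_step,
      "px, subset", x$subset_size, "px\n")
  invisible(x)
}

# even-odd ray-casting point-in-polygon, vectorized over points
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Correlation parameters
#'
#' Defaults are deliberate desk-scale choices: 21 px subsets on a 5 px grid
#' with a 0.8 ZNCC acceptance cutoff, integer search followed by
#' Gauss-Newton subpixel refinement.
#'
#' @param search integer search half-range (px) around the initial guess.
#' @param score_cutoff minimum acceptable ZNCC score for same-camera
#'   (temporal) matching.
#' @param score_cutoff_stereo minimum ZNCC score for cross-camera matching
#'   (the affine-warped subset model keeps cross-camera scores high, so the
#'   default matches the temporal cutoff; lower it for strongly convergent
#'   rigs).
#' @param min_sd minimum subset intensity SD (contrast floor, 0..1 scale).
#' @param max_iter Gauss-Newton iteration cap.
#' @param search_seed integer search half-range for the stereo seed point.
#' @param search_grow integer search half-range during stereo growth.
#' @return a list of class `dic_params`.
#' @export
dic_params <- function(search = 15, score_cutoff = 0.8,
                       score_cutoff_stereo = 0.8, min_sd = 0.01,
                       max_iter = 25, search_seed = 80, search_grow = 8) {
  structure(list(search = search, score_cutoff = score_cutoff,
                 score_cutoff_stereo = score_cutoff_stereo,
                 min_sd = min_sd, max_iter = max_iter,
                 search_seed = search_seed, search_grow = search_grow),
            class = "dic_params")
}

status_labels <- c(`0` = "ok", `2` = "low_contrast", `3` = "search_edge",
                   `4` = "out_of_range", `5` = "low_score")

match_table <- function(pts, raw, score_cutoff) {
  status <- raw[, 4]
  status[status == 0 & (is.na(raw[, 3]) | raw[, 3] < score_cutoff)] <- 5
  data.frame(ref_x = pts[, 1], ref_y = pts[, 2],
             ref_u = pts[, 1] + 0.5, ref_v = pts[, 2] + 0.5,
             dx = raw[, 1], dy = raw[, 2],
             def_u = pts[, 1] + 0.5 + raw[, 1],
             def_v = pts[, 2] + 0.5 + raw[, 2],
             score = raw[, 3],
             status = unname(status_labels[as.character(status)]),
             row.names = NULL)
}

#' Subset correlation between reference and deformed images
#'
#' Zero-normalized cross-correlation (ZNCC) integer search followed by
#' Gauss-Newton subpixel refinement, per ROI grid point.  Matches failing
#' the contrast floor, landing on the search-window edge, or scoring below
#' the cutoff are marked rejected with a reason code; nothing is silently
#' dropped.
#'
#' @param ref_image,def_image grayscale matrices on a 0..1 scale, same size.
#' @param roi a [roi_grid()].
#' @param params a [dic_params()].
#' @param init initial displacement guess: length-2 vector or n x 2 matrix.
#' @return data.frame with columns ref_u, ref_v, def_u, def_v, dx, dy,
#'   score, status ("ok" or a rejection reason).
#' @export
correlate <- function(ref_image, def_image, roi, params = dic_params(),
                      init = c(0, 0)) {
  stopifnot(is.matrix(ref_image), is.matrix(def_image),
            all(dim(ref_image) == dim(def_image)),
            inherits(roi, "roi_grid"))
  pts <- roi$points
  n <- nrow(pts)
  init_m <- if (is.matrix(init)) round(init) else
    matrix(round(init), n, 2, byrow = TRUE)
  raw <- dic_match_cpp(ref_image, def_image,
                       matrix(as.integer(pts), ncol = 2),
                       matrix(as.integer(init_m), ncol = 2),
                       roi$subset_size, as.integer(params$search),
                       params$min_sd, as.integer(params$max_iter))
  match_table(pts, raw, params$score_cutoff)
}

#' Cross-camera subset matching for stereo reconstruction
#'
#' Matches the reference image of camera A against the reference image of
#' camera B with a seed-and-grow strategy: the grid point nearest the ROI
#' centroid is matched with a wide search window, then matches propagate
#' outward, each point initialized from its nearest already-matched
#' neighbour with a narrow search.  This absorbs the large, smoothly varying
#' stereo disparity of a curved surface without a global search at every
#' point.
#'
#' @param image_a,image_b same-state grayscale images from the two cameras.
#' @param roi a [roi_grid()] on image A.
#' @param params a [dic_params()]; `search_seed` and `search_grow` control
#'   the two search ranges.
#' @param init_disparity optional length-2 integer disparity guess for the
#'   seed point.
#' @return data.frame as in [correlate()], mapping image-A points (ref_*)
#'   to image-B points (def_*).
#' @export
stereo_match <- function(image_a, image_b, roi, params = dic_params(),
                         init_disparity = c(0, 0)) {
  stopifnot(is.matrix(image_a), is.matrix(image_b),
            inherits(roi, "roi_grid"))
  cutoff <- if (is.null(params$score_cutoff_stereo)) params$score_cutoff
            else params$score_cutoff_stereo
  pts <- roi$points
  n <- nrow(pts)
  ctr <- colMeans(pts)
  ord <- order((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  raw <- matrix(NA_real_, n, 4)
  raw[, 4] <- 4
  matched <- rep(FALSE, n)
  disp <- matrix(NA_real_, n, 2)

  one <- function(k, init, search) {
    dic_match_cpp(image_a, image_b,
                  matrix(as.integer(pts[k, ]), 1, 2),
                  matrix(as.integer(round(init)), 1, 2),
                  roi$subset_size, as.integer(search),
                  params$min_sd, as.integer(params$max_iter),
                  affine = 1L)[1, ]
  }

  # seed: try the most central points with the wide search window
  seed_at <- NA_integer_
  for (k in ord[seq_len(min(25L, n))]) {
    r <- one(k, init_disparity, params$search_seed)
    if (r[4] == 0 && !is.na(r[3]) && r[3] >= cutoff) {
      raw[k, ] <- r; matched[k] <- TRUE; disp[k, ] <- r[1:2]
      seed_at <- k
      break
    }
    raw[k, ] <- r
  }
  if (is.na(seed_at))
    stop("stereo seed match failed: no central grid point correlates ",
         "between the two cameras")

  for (k in ord) {
    if (k == seed_at || matched[k]) next
    idx <- which(matched)
    d2 <- (pts[idx, 1] - pts[k, 1])^2 + (pts[idx, 2] - pts[k, 2])^2
    nb <- idx[which.min(d2)]
    r <- one(k, disp[nb, ], params$search_grow)
    raw[k, ] <- r
    if (r[4] == 0 && !is.na(r[3]) && r[3] >= cutoff) {
      matched[k] <- TRUE; disp[k, ] <- r[1:2]
    }
  }
  match_table(pts, raw, cutoff)
}

#' Write a match table to CSV
#'
#' @param matches data.frame from [correlate()] or [stereo_match()].
#' @param path output file.
#' @export
write_matches_csv <- function(matches, path) {
  utils::write.csv(matches[, c("ref_u", "ref_v", "def_u", "def_v",
                               "score", "status")],
                   path, row.names = FALSE)
  invisible(path)
}
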