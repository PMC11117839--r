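#' Triangulated surface mesh
#'
#' Container for a triangulated 3D surface.  Vertex indices are material
#' point identities: the reference and loaded states of the same surface
#' share connectivity, and face `k` refers to the same patch of tissue in
#' both.
#'
#' @param vertices n x 3 matrix (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param state "reference" or "loaded".
#' @param provenance one of "dic", "fem", "synthetic".
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces, state = "reference",
                         provenance = "synthetic") {
  vertices <- as.matrix(vertices); faces <- as.matrix(faces)
  dimnames(vertices) <- NULL; dimnames(faces) <- NULL
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            max(faces) <= nrow(vertices), min(faces) >= 1)
  state <- match.arg(state, c("reference", "loaded"))
  provenance <- match.arg(provenance, c("dic", "fem", "synthetic"))
  structure(list(vertices = vertices, faces = faces, state = state,
                 provenance = provenance),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface mesh (", x$state, ", ", x$provenance, "): ",
      nrow(x$vertices), " vertices, ", nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  cbind(ux, uy, (ux - ax)^2 + (uy - ay)^2)
}

#' Delaunay triangulation in the plane
#'
#' Incremental Bowyer-Watson triangulation.  Regular grids make every grid
#' square exactly cocircular, so an infinitesimal deterministic jitter
#' (2^-26 of the bounding-box diagonal, a hash of the point index) breaks
#' ties; the jitter is used only for the topology, vertex coordinates are
#' returned untouched.
#'
#' @param pts n x 2 matrix of 2D points.
#' @return m x 3 matrix of 1-based triangle indices.
#' @export
delaunay2d <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points to triangulate")
  rng <- apply(pts, 2, range)
  diam <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  if (diam < 1e-12) stop("degenerate (coincident) point cloud")
  sv <- svd(cbind(pts[, 1] - mean(pts[, 1]), pts[, 2] - mean(pts[, 2])))$d
  if (sv[2] < 1e-10 * sv[1]) stop("degenerate (collinear) point cloud")
  # deterministic index-hash jitter, topology only
  jit <- function(i, salt) {
    x <- sin(i * 12.9898 + salt * 78.233) * 43758.5453
    (x - floor(x) - 0.5) * diam * 2^-26
  }
  px <- pts[, 1] + jit(seq_len(n), 1)
  py <- pts[, 2] + jit(seq_len(n), 2)

  cx0 <- mean(rng[, 1]); cy0 <- mean(rng[, 2]); s <- 20 * diam
  px <- c(px, cx0 - s, cx0 + s, cx0)
  py <- c(py, cy0 - s, cy0 - s, cy0 + s)
  sup <- n + 1:3

  cap <- 6 * n + 16
  tri <- matrix(NA_integer_, cap, 3)
  cc <- matrix(NA_real_, cap, 3)  # ccx, ccy, r^2
  active <- logical(cap)
  tri[1, ] <- sup
  cc[1, ] <- circumcircle(px[sup[1]], py[sup[1]], px[sup[2]], py[sup[2]],
                          px[sup[3]], py[sup[3]])
  active[1] <- TRUE
  ntri <- 1L
  eps <- 1e-9 * diam^2

  for (p in seq_len(n)) {
    act <- which(active[seq_len(ntri)])
    d2 <- (px[p] - cc[act, 1])^2 + (py[p] - cc[act, 2])^2
    bad <- act[d2 < cc[act, 3] - eps]
    if (length(bad) == 0L) {
      # numerically on a circle everywhere; nudge tolerance
      bad <- act[which.min(d2 - cc[act, 3])]
    }
    e <- rbind(tri[bad, c(1, 2), drop = FALSE],
               tri[bad, c(2, 3), drop = FALSE],
               tri[bad, c(3, 1), drop = FALSE])
    key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    bnd <- e[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    active[bad] <- FALSE
    if (ntri + nrow(bnd) > cap) {  # compact out deactivated rows
      keep <- which(active[seq_len(ntri)])
      ntri <- length(keep)
      tri[seq_len(ntri), ] <- tri[keep, ]
      cc[seq_len(ntri), ] <- cc[keep, ]
      active[] <- FALSE
      active[seq_len(ntri)] <- TRUE
    }
    for (i in seq_len(nrow(bnd))) {
      ntri <- ntri + 1L
      if (ntri > cap) stop("triangulation overflow")
      tri[ntri, ] <- c(bnd[i, 1], bnd[i, 2], p)
      cc[ntri, ] <- circumcircle(px[bnd[i, 1]], py[bnd[i, 1]],
                                 px[bnd[i, 2]], py[bnd[i, 2]],
                                 px[p], py[p])
      active[ntri] <- TRUE
    }
  }
  keep <- active[seq_len(ntri)] &
    !apply(matrix(tri[seq_len(ntri), ] %in% sup, ncol = 3), 1, any)
  out <- tri[seq_len(ntri), , drop = FALSE][keep, , drop = FALSE]
  unname(out)
}

#' Build matched reference/loaded surface meshes from corresponded points
#'
#' Triangulates the reference point cloud on a 2D parameterization (Delaunay)
#' and applies the identical connectivity to the loaded state, so every face
#' is a material patch trackable across states.  Faces degenerate in the
#' reference state (area below `min_area` mm^2) are dropped from both.
#'
#' @param ref_points n x 3 reference positions (mm).
#' @param loaded_points n x 3 loaded positions, same row order
#'   (correspondence by index), or NULL.
#' @param uv optional n x 2 parameterization for the triangulation (e.g. the
#'   DIC grid coordinates in the reference camera); defaults to projection
#'   onto the best-fit plane of the reference points.
#' @param provenance mesh provenance tag.
#' @param min_area face-area floor (mm^2).
#' @return list with `reference` and (if given) `loaded` `surface_mesh`es.
#' @export
build_mesh <- function(ref_points, loaded_points = NULL, uv = NULL,
                       provenance = "dic", min_area = 1e-9) {
  ref_points <- as.matrix(ref_points)
  if (nrow(ref_points) < 3) stop("need at least 3 points")
  if (is.null(uv)) {
    ctr <- colMeans(ref_points)
    sv <- svd(sweep(ref_points, 2, ctr))
    if (sv$d[2] < 1e-10 * sv$d[1])
      stop("degenerate (collinear) point cloud")
    uv <- sweep(ref_points, 2, ctr) %*% sv$v[, 1:2]
  }
  faces <- delaunay2d(uv)
  areas <- mesh_face_areas(ref_points, faces)
  drop <- areas < min_area
  if (any(drop)) {
    message(sum(drop), " degenerate face(s) dropped (area < ", min_area,
            " mm^2)")
    faces <- faces[!drop, , drop = FALSE]
  }
  out <- list(reference = surface_mesh(ref_points, faces, "reference",
                                       provenance))
  if (!is.null(loaded_points)) {
    loaded_points <- as.matrix(loaded_points)
    stopifnot(nrow(loaded_points) == nrow(ref_points))
    out$loaded <- surface_mesh(loaded_points, faces, "loaded", provenance)
  }
  out
}

#' Read/write a triangulated mesh as ascii PLY
#'
#' @param mesh a `surface_mesh`.
#' @param path file path.
#' @export
write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  writeLines(c("ply", "format ascii 1.0",
               paste("comment state", mesh$state, "provenance",
                     mesh$provenance),
               paste("element vertex", nv),
               "property double x", "property double y", "property double z",
               paste("element face", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(apply(mesh$vertices, 1, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "ply" || !grepl("ascii", lines[2]))
    stop("only ascii PLY is supported")
  hdr_end <- which(lines == "end_header")[1]
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  cm <- grep("^comment state", lines, value = TRUE)
  state <- "reference"; prov <- "synthetic"
  if (length(cm)) {
    tok <- strsplit(cm[1], " ")[[1]]
    state <- tok[3]; prov <- tok[5]
  }
  v <- do.call(rbind, lapply(lines[hdr_end + seq_len(nv)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  f <- do.call(rbind, lapply(lines[hdr_end + nv + seq_len(nf)], function(s)
    as.integer(strsplit(trimws(s), "\\s+")[[1]])[-1] + 1L))
  surface_mesh(v, f, state, prov)
}

#' FEM surface export I/O (CSV node/connectivity dialect)
#'
#' Reads or writes the documented plain-text dialect for surface exports
#' from an external finite-element solve: a node table with columns
#' `node_id,x,y,z` per state and an element table `elem_id,n1,n2,n3`.
#' Node ids may be arbitrary; connectivity refers to them.
#'
#' @param nodes_ref,nodes_loaded paths to node CSVs (reference and loaded
#'   states; loaded may be NULL).
#' @param elems path to the element CSV.
#' @return list with `reference` and optionally `loaded` `surface_mesh`es.
#' @export
read_fem_surface <- function(nodes_ref, elems, nodes_loaded = NULL) {
  nr <- utils::read.csv(nodes_ref)
  el <- utils::read.csv(elems)
  stopifnot(all(c("node_id", "x", "y", "z") %in% names(nr)),
            all(c("elem_id", "n1", "n2", "n3") %in% names(el)))
  idx <- match(c(el$n1, el$n2, el$n3), nr$node_id)
  if (anyNA(idx)) stop("element refers to unknown node id")
  faces <- matrix(idx, ncol = 3)
  out <- list(reference = surface_mesh(as.matrix(nr[, c("x", "y", "z")]),
                                       faces, "reference", "fem"))
  if (!is.null(nodes_loaded)) {
    nl <- utils::read.csv(nodes_loaded)
    stopifnot(identical(nl$node_id, nr$node_id))
    out$loaded <- surface_mesh(as.matrix(nl[, c("x", "y", "z")]),
                               faces, "loaded", "fem")
  }
  out
}

#' @rdname read_fem_surface
#' @param mesh a `surface_mesh` to write.
#' @param nodes_path,elems_path output CSV paths.
#' @export
write_fem_surface <- function(mesh, nodes_path, elems_path) {
  utils::write.csv(data.frame(node_id = seq_len(nrow(mesh$vertices)),
                              x = mesh$vertices[, 1],
                              y = mesh$vertices[, 2],
                              z = mesh$vertices[, 3]),
                   nodes_path, row.names = FALSE)
  utils::write.csv(data.frame(elem_id = seq_len(nrow(mesh$faces)),
                              n1 = mesh$faces[, 1], n2 = mesh$faces[, 2],
                              n3 = mesh$faces[, 3]),
                   elems_path, row.names = FALSE)
  invisible(nodes_path)
}
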