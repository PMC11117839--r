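test_that("self-correlation gives zero displacement and perfect score", {
  im <- fixture("plane_im", shifted_plane_images(0.3))
  roi <- square_roi(step = 20)
  m <- correlate(im$ref, im$ref, roi)
  ok <- m$status == "ok"
  expect_gt(mean(ok), 0.95)
  expect_true(all(m$status[!ok] == "low_contrast"))
  expect_lt(max(abs(c(m$dx[ok], m$dy[ok]))), 1e-10)
  expect_true(all(m$score[ok] > 1 - 1e-10))
})

test_that("pure integer shifts are recovered exactly", {
  im <- fixture("plane_im", shifted_plane_images(0.3))
  ref <- im$ref
  h <- nrow(ref); w <- ncol(ref)
  def <- matrix(0.15, h, w)
  def[1:(h - 3), 8:w] <- ref[4:h, 1:(w - 7)]  # shift by (+7, -3)
  m <- correlate(ref, def, square_roi(step = 20))
  ok <- m$status == "ok"
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(m$dx[ok] - 7)), 1e-6)
  expect_lt(max(abs(m$dy[ok] + 3)), 1e-6)
})

test_that("a 0.3 px subpixel shift is recovered with mean error under
           0.05 px", {
  im <- fixture("plane_im", shifted_plane_images(0.3))
  m <- correlate(im$ref, im$def, square_roi(step = 10))
  ok <- m$status == "ok"
  expect_gt(sum(ok), 500)
  expect_lt(mean(abs(m$dx[ok] - im$shift_px)), 0.05)
  expect_lt(mean(abs(m$dy[ok])), 0.05)
})

test_that("displacements are equivariant under a common integer shift of
           both images", {
  im <- fixture("plane_im", shifted_plane_images(0.3))
  sh <- 6L
  crop <- function(x) x[(1 + sh):nrow(x), (1 + sh):ncol(x)]
  roi_a <- square_roi(lo = 140, hi = 360, step = 20)
  m_a <- correlate(im$ref, im$def, roi_a)
  roi_b <- roi_a
  roi_b$points <- roi_a$points - sh
  m_b <- correlate(crop(im$ref), crop(im$def), roi_b)
  ok <- m_a$status == "ok" & m_b$status == "ok"
  expect_gt(mean(ok), 0.95)
  expect_lt(max(abs(m_a$dx[ok] - m_b$dx[ok])), 1e-8)
  expect_lt(max(abs(m_a$dy[ok] - m_b$dy[ok])), 1e-8)
})

test_that("scores and displacements are invariant under affine intensity
           changes", {
  im <- fixture("plane_im", shifted_plane_images(0.3))
  roi <- square_roi(step = 25)
  m1 <- correlate(im$ref, im$def, roi)
  m2 <- correlate(im$ref, 0.5 * im$def + 0.1, roi)
  ok <- m1$status == "ok" & m2$status == "ok"
  expect_lt(max(abs(m1$score[ok] - m2$score[ok])), 1e-9)
  expect_lt(max(abs(m1$dx[ok] - m2$dx[ok])), 1e-7)
})

test_that("match error degrades monotonically with image noise", {
  base <- fixture("plane_im", shifted_plane_images(0.3))
  roi <- square_roi(step = 15)
  mae <- vapply(c(0, 0.02, 0.05, 0.1), function(sg) {
    set.seed(7)
    ref <- base$ref + matrix(rnorm(length(base$ref), 0, sg), nrow(base$ref))
    def <- base$def + matrix(rnorm(length(base$def), 0, sg), nrow(base$def))
    m <- correlate(ref, def, roi)
    mean(abs(m$dx[m$status == "ok"] - base$shift_px))
  }, 0)
  expect_true(all(diff(mae) >= 0))
})

test_that("textureless subsets are rejected with a low-contrast code", {
  im <- fixture("plane_im", shifted_plane_images(0.3))
  ref <- im$ref
  ref[200:320, 200:320] <- 0.4  # flat patch
  m <- correlate(ref, ref, square_roi(lo = 220, hi = 300, step = 20))
  expect_true(all(m$status == "low_contrast"))
})

test_that("displacements at the search-window edge are rejected", {
  im <- fixture("plane_im", shifted_plane_images(0.3))
  ref <- im$ref
  h <- nrow(ref); w <- ncol(ref)
  def <- matrix(0.15, h, w)
  big <- 12L  # beyond the default +/- 15 px after init 0? use search 10
  def[, (big + 1):w] <- ref[, 1:(w - big)]
  p <- dic_params(search = 10)
  m <- correlate(ref, def, square_roi(step = 25), p)
  expect_true(all(m$status %in% c("search_edge", "low_score")))
})

test_that("an occluded region rejects its matches rather than reporting
           silently wrong ones", {
  im <- fixture("plane_im", shifted_plane_images(0.3))
  def <- im$def
  def[220:320, 220:320] <- 0  # occlusion mask
  m <- correlate(im$ref, def, square_roi(step = 12))
  inside <- m$ref_x >= 240 & m$ref_x <= 300 & m$ref_y >= 240 & m$ref_y <= 300
  expect_true(all(m$status[inside] != "ok"))
  # accepted matches carry no gross errors (partially occluded subsets at
  # the mask boundary may be biased by a fraction of a pixel, never by a
  # false match)
  ok <- m$status == "ok"
  expect_lt(max(abs(m$dx[ok] - im$shift_px)), 1)
})

test_that("stereo matching on a textured sphere reconstructs 3D points to
           tens of micrometres", {
  sc <- fixture("rigid_full",
                render_speckle_scene(scene_spec(
                  deformation = deformation_rigid(c(0, 0, 0)), seed = 9)))
  dlt <- calibrate_rig(sc$spec$cameras)
  pair <- camera_pair(dlt[[1]], dlt[[2]])
  outer <- scleradic:::ring_polygon(sc$spec$cameras[[1]], 12, 3.2, 2.8)
  roi <- roi_grid(outer, grid_step = 6, subset_size = 21)
  st <- stereo_match(sc$images[[1]]$ref, sc$images[[2]]$ref, roi)
  ok <- st$status == "ok"
  expect_gt(mean(ok), 0.9)
  tri <- triangulate(pair, cbind(st$ref_u, st$ref_v)[ok, ],
                     cbind(st$def_u, st$def_v)[ok, ])
  err <- abs(sqrt(rowSums(tri$points3d^2)) - sc$spec$globe_radius)
  expect_gt(mean(err < 0.030), 0.9)
})

test_that("roi grids respect polygons, exclusions, and size floors", {
  roi <- roi_grid(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)),
                  grid_step = 10,
                  exclude = cbind(c(40, 60, 60, 40), c(40, 40, 60, 60)))
  expect_true(all(roi$points >= 0 & roi$points <= 100))
  inside_excl <- roi$points[, 1] > 40 & roi$points[, 1] < 60 &
    roi$points[, 2] > 40 & roi$points[, 2] < 60
  expect_false(any(inside_excl))
  expect_error(roi_grid(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                        subset_size = 9), "subset_size")
  expect_error(roi_grid(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)),
                        subset_size = 20), "subset_size")
})

test_that("match tables serialize to CSV", {
  im <- fixture("plane_im", shifted_plane_images(0.3))
  m <- correlate(im$ref, im$def, square_roi(step = 40))
  f <- tempfile(fileext = ".csv")
  write_matches_csv(m, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(m))
  expect_named(back, c("ref_u", "ref_v", "def_u", "def_v", "score",
                       "status"))
})
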