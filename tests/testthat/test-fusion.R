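k_test <- camera_intrinsics(150, 150, 159.5, 89.5, 320, 180)

test_that("solid rectangle yields one point per band at the band means", {
  labels <- matrix(0L, 40, 40)
  labels[1:28, 11:20] <- 1L   # rows 0..27, cols 10..19 in 0-based coords
  pts <- extract_navigation_points(instance_masks(labels),
                                   fusion_config(n_bands = 14))
  expect_equal(nrow(pts), 14)
  expect_equal(pts$band, 0:13)
  expect_equal(pts$u, rep(14.5, 14))
  expect_equal(pts$v, seq(0.5, 26.5, by = 2))
})

test_that("degenerate band counts behave per contract", {
  labels <- matrix(0L, 30, 30)
  labels[5:20, 3:12] <- 2L
  m <- instance_masks(labels)
  one <- extract_navigation_points(m, fusion_config(n_bands = 1))
  px <- which(labels == 2L, arr.ind = TRUE)
  expect_equal(nrow(one), 1)
  expect_equal(c(one$u, one$v), c(mean(px[, 2] - 1), mean(px[, 1] - 1)))
  # 5-px-tall instance with 14 bands: at most 5 occupied bands
  short <- matrix(0L, 30, 30)
  short[10:14, 5:8] <- 1L
  pts <- extract_navigation_points(instance_masks(short), fusion_config(14))
  expect_lte(nrow(pts), 5)
  expect_error(extract_navigation_points(m, fusion_config(), ids = 7),
               "absent")
})

test_that("extraction matches the brute-force double loop on random blobs", {
  set.seed(41)
  for (i in 1:50) {
    labels <- random_blob_mask(sample(20:60, 1), sample(20:60, 1),
                               n_instances = sample(1:3, 1))
    if (!any(labels > 0)) next
    n_bands <- sample(c(1, 5, 14), 1)
    got <- extract_navigation_points(instance_masks(labels),
                                     fusion_config(n_bands = n_bands))
    want <- oracle_nav_points(labels, n_bands)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("navigation points stay within their instance bounding box", {
  set.seed(42)
  for (i in 1:10) {
    labels <- random_blob_mask(40, 40, 2)
    if (!any(labels > 0)) next
    pts <- extract_navigation_points(instance_masks(labels), fusion_config())
    for (id in unique(pts$instance_id)) {
      px <- which(labels == id, arr.ind = TRUE)
      sel <- pts[pts$instance_id == id, ]
      expect_lte(nrow(sel), 14)
      expect_true(all(sel$u >= min(px[, 2] - 1) & sel$u <= max(px[, 2] - 1)))
      expect_true(all(sel$v >= min(px[, 1] - 1) & sel$v <= max(px[, 1] - 1)))
    }
  }
})

test_that("attach_depth keeps in-range points and drops missing/far ones", {
  pts <- data.frame(instance_id = 1L, band = 0:2,
                    u = c(14.5, 14.5, 14.5), v = c(0.5, 2.5, 4.5))
  d <- matrix(2, 10, 30)
  # nearest pixel of (u=14.5, v=2.5) is 0-based (15, 3) = 1-based [4, 16]
  d[4, 16] <- 0
  d[6, 16] <- 6.2   # nearest pixel of v=4.5, beyond the 5 m filter
  dm <- depth_map(d)
  out <- attach_depth(pts, dm, fusion_config(max_depth = 5))
  expect_equal(nrow(out), 1)
  expect_equal(out$depth, 2)
  expect_equal(out$band, 0L)
})

test_that("depth lookup ties round upward and bilinear skips missing neighbours", {
  d <- matrix(0, 4, 4)
  d[3, 3] <- 7  # 0-based (u=2, v=2)
  dm <- depth_map(d)
  # (1.5, 1.5) is equidistant between pixels 1 and 2; ties go up -> (2,2)
  expect_equal(monorow:::lookup_depth(dm, 1.5, 1.5, "nearest"), 7)
  # bilinear with a missing neighbour falls back to nearest
  expect_equal(monorow:::lookup_depth(dm, 1.5, 1.5, "bilinear"), 7)
  full <- depth_map(matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE))
  expect_equal(monorow:::lookup_depth(full, 0.5, 0.5, "bilinear"), 2.5)
})

test_that("camera-frame conversion is consistent with projection", {
  set.seed(43)
  pts <- data.frame(instance_id = 1L, band = 0:9,
                    u = runif(10, 0, 319), v = runif(10, 0, 179),
                    depth = runif(10, 0.5, 5))
  p3 <- to_camera_frame(pts, k_test)
  back <- project_points(as.matrix(p3[, c("x", "y", "z")]), k_test)
  expect_lt(max(abs(back$u - pts$u)), 1e-9)
  expect_lt(max(abs(back$v - pts$v)), 1e-9)
  expect_equal(p3$z, pts$depth)
  empty <- to_camera_frame(pts[0, ], k_test)
  expect_equal(nrow(empty), 0)
})

test_that("row point clouds back-project exactly the valid near pixels", {
  labels <- matrix(0L, 20, 20)
  labels[5:15, 4:9] <- 1L
  d <- matrix(2, 20, 20)
  d[6, 5] <- 0       # missing
  d[7, 5] <- 9       # beyond 5 m
  clouds <- row_point_clouds(instance_masks(labels), depth_map(d), k_test,
                             fusion_config(max_depth = 5))
  expect_named(clouds, "1")
  expect_equal(nrow(clouds[["1"]]), sum(labels == 1L) - 2)
  expect_true(all(clouds[["1"]][, "z"] == 2))
  # all-missing instance flagged empty
  d0 <- depth_map(matrix(0, 20, 20))
  c0 <- row_point_clouds(instance_masks(labels), d0, k_test, fusion_config())
  expect_equal(nrow(c0[["1"]]), 0)
  expect_true(attr(c0[["1"]], "empty"))
})

test_that("fuse with identical prediction and label gives zero chamfer distances", {
  sc <- render_scene(scene_config())
  res <- fuse(sc$masks, sc$depth, sc$camera, fusion_config(),
              depth_label = sc$depth)
  expect_equal(res$cd_navigation, 0)
  expect_equal(res$cd_row_clouds, 0)
  # label-filtered pred and label points are position-matched pairs
  expect_equal(res$points[, c("u", "v")], res$points_label[, c("u", "v")])
  expect_equal(nrow(res$points), nrow(res$points_label))
})

test_that("fused 3D navigation points equal the analytic scene ground truth", {
  sc <- render_scene(scene_config(), n_bands = 14, nav_max_depth = 5)
  res <- fuse(sc$masks, sc$depth, sc$camera,
              fusion_config(n_bands = 14, max_depth = 5))
  m <- merge(res$points, sc$gt_points, by = c("instance_id", "band"))
  expect_equal(nrow(m), nrow(sc$gt_points))
  expect_equal(nrow(m), nrow(res$points))
  expect_lt(max(abs(m$x.x - m$x.y), abs(m$y.x - m$y.y), abs(m$z.x - m$z.y)),
            1e-6)
})

test_that("chamfer distances shrink continuously as prediction error vanishes", {
  sc <- render_scene(scene_config())
  cds <- vapply(c(0.05, 0.01, 0.002), function(eps) {
    pred <- depth_map(unclass(sc$depth) * (1 + eps), max_range = Inf)
    res <- fuse(sc$masks, pred, sc$camera, fusion_config(),
                depth_label = sc$depth)
    c(res$cd_navigation, res$cd_row_clouds)
  }, numeric(2))
  expect_true(all(cds > 0))
  expect_true(all(diff(cds[1, ]) < 0))
  expect_true(all(diff(cds[2, ]) < 0))
})

test_that("a mask with no instances fuses to an empty result with a warning", {
  d <- depth_map(matrix(2, 10, 10))
  expect_warning(res <- fuse(instance_masks(matrix(0L, 10, 10)), d, k_test),
                 "no instances")
  expect_equal(nrow(res$points), 0)
  expect_length(res$clouds, 0)
})

test_that("point clouds and navigation points serialize to the stated formats", {
  sc <- render_scene(scene_config())
  res <- fuse(sc$masks, sc$depth, sc$camera)
  xyz <- withr::local_tempfile(fileext = ".xyz")
  ply <- withr::local_tempfile(fileext = ".ply")
  nav <- withr::local_tempfile(fileext = ".json")
  write_xyz(res$clouds[[1]], xyz)
  lines <- readLines(xyz)
  expect_length(lines, nrow(res$clouds[[1]]))
  expect_equal(length(strsplit(lines[1], " ")[[1]]), 3)
  write_ply(res$clouds[[1]], ply)
  expect_equal(readLines(ply)[1], "ply")
  write_navigation_json(res$points, nav)
  j <- jsonlite::read_json(nav)
  expect_length(j, nrow(res$points))
  expect_named(j[[1]], c("instance_id", "band", "u", "v", "depth",
                         "x", "y", "z"))
})
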