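test_that("extent_to_angle reproduces the experiment's gap angles", {
  expect_equal(signif(extent_to_angle(14.22, 54), 3), 15.0)
  expect_equal(round(extent_to_angle(0.30, 54), 2), 0.32)
  expect_identical(extent_to_angle(0, 54), 0)
  expect_error(extent_to_angle(1, 0), "positive")
  expect_error(extent_to_angle(-1, 54), "non-negative")
})

test_that("extent_to_angle is monotone in extent and distance", {
  ext <- seq(0.1, 30, length.out = 50)
  expect_true(all(diff(extent_to_angle(ext, 54)) > 0))
  dist <- seq(20, 120, length.out = 50)
  expect_true(all(diff(extent_to_angle(10, dist)) < 0))
})

test_that("pixel/degree conversion is centred, symmetric and invertible", {
  geom <- display_geometry()
  ctr <- pixel_to_degree(data.frame(x_px = 640, y_px = 512), geom)
  expect_equal(ctr$x_deg, 0)
  expect_equal(ctr$y_deg, 0)

  # symmetric pixels give equal magnitude, opposite sign
  pts <- pixel_to_degree(data.frame(x_px = c(140, 1140), y_px = c(12, 1012)), geom)
  expect_equal(pts$x_deg[1], -pts$x_deg[2])
  expect_equal(pts$y_deg[1], -pts$y_deg[2])

  # half-width pixel offset matches the half-screen visual angle
  p <- pixel_to_degree(data.frame(x_px = 1280, y_px = 512), geom)
  expect_equal(p$x_deg, extent_to_angle(33.7, 54) / 2, tolerance = 1e-12)

  # screen corners round-trip to the angular half-extents within 1e-9 deg
  corners <- data.frame(x_px = c(0, 1280, 0, 1280), y_px = c(0, 0, 1024, 1024))
  cc <- pixel_to_degree(corners, geom)
  half <- screen_half_extent_deg(geom)
  expect_equal(abs(cc$x_deg), rep(half[["x"]], 4), tolerance = 1e-9)
  expect_equal(abs(cc$y_deg), rep(half[["y"]], 4), tolerance = 1e-9)

  # degree_to_pixel inverts pixel_to_degree
  rt <- degree_to_pixel(cc, geom)
  expect_equal(rt$x_px, corners$x_px, tolerance = 1e-9)
  expect_equal(rt$y_px, corners$y_px, tolerance = 1e-9)
})

test_that("display_geometry and layout validate their inputs", {
  expect_error(display_geometry(viewing_distance_cm = 0), "positive")
  expect_error(stimulus_layout("standard", gap_deg = -1))
  lay <- stimulus_layout("far")
  expect_gt(lay$top_row_center[["y"]], lay$bottom_row_center[["y"]])
  expect_equal(lay$top_row_center[["y"]], 15 / 2 + 0.34 / 2)
})

test_that("default maps honour the printed distance anchors", {
  m_std <- default_aoi_map("standard")
  expect_equal(nrow(m_std), 6L)
  d_top <- aoi_distances(m_std, "top")
  expect_equal(d_top$distance_deg[d_top$label == "ST2"], 3.75)
  expect_equal(d_top$distance_deg[d_top$label == "ST1"], 10)
  expect_equal(d_top$distance_deg[d_top$label == "ST3"], 0) # embedded
  d_bot <- aoi_distances(m_std, "bottom")
  expect_equal(d_bot$distance_deg[d_bot$label == "SB2"], 3.75)

  m_far <- default_aoi_map("far")
  expect_equal(m_far$stimulus_row[m_far$label == "T2"], "top")
  expect_equal(m_far$stimulus_row[m_far$label == "B2"], "bottom")
  d_far <- aoi_distances(m_far, "top")
  expect_equal(d_far$distance_deg[d_far$label == "T2"], 0)
})

test_that("assign_aoi is a partition agreeing with a brute-force scan", {
  withr::local_seed(42)
  for (gc in c("standard", "far")) {
    m <- default_aoi_map(gc)
    x <- runif(10000, -20, 20)
    y <- runif(10000, -16, 16)
    got <- assign_aoi(x = x, y = y, map = m)
    # brute force: per-point loop over rectangles
    brute <- vapply(seq_along(x), function(i) {
      hits <- which(m$x_min <= x[i] & x[i] < m$x_max &
                      m$y_min <= y[i] & y[i] < m$y_max)
      if (length(hits) == 0L) NA_character_ else m$label[hits]
    }, character(1L))
    expect_identical(got, brute)
    # at most one region can claim any point
    claims <- vapply(seq_along(x), function(i) {
      sum(m$x_min <= x[i] & x[i] < m$x_max & m$y_min <= y[i] & y[i] < m$y_max)
    }, numeric(1L))
    expect_true(all(claims <= 1))
  }
})

test_that("shared boundaries belong to the upper region (half-open rule)", {
  m <- default_aoi_map("far")
  b <- m$y_min[m$label == "T2"] # boundary between T2 and T3
  expect_identical(assign_aoi(x = 0, y = b, map = m), "T2")
  expect_identical(assign_aoi(x = 0, y = b - 1e-12, map = m), "T3")
  expect_true(is.na(assign_aoi(x = 50, y = 50, map = m)))
})

test_that("aoi_map rejects invalid region sets", {
  m <- default_aoi_map("far")
  bad <- tibble::as_tibble(m)
  bad$y_min[1] <- bad$y_min[2] # overlap regions 1 and 2
  expect_error(aoi_map(bad, "far"), "overlap")
  bad2 <- tibble::as_tibble(m)
  bad2$label[2] <- bad2$label[1]
  expect_error(aoi_map(bad2, "far"), "unique")
  bad3 <- tibble::as_tibble(m)
  bad3$x_max[3] <- bad3$x_min[3]
  expect_error(aoi_map(bad3, "far"), "degenerate")
  expect_error(aoi_map(tibble::as_tibble(m)[1:5, ], "far"), "six")
})

test_that("AOI config serialises and reads back unchanged", {
  path <- withr::local_tempfile(fileext = ".json")
  geom <- display_geometry()
  lay <- stimulus_layout("far")
  m <- default_aoi_map("far", geom, lay)
  write_aoi_config(m, geom, lay, path)
  back <- read_aoi_config(path)
  expect_equal(unclass(back$geometry), unclass(geom))
  expect_equal(back$layout$gap_deg, 15)
  expect_equal(as.data.frame(back$map), as.data.frame(m))
})
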