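make_hm <- function(h, z_step = 2) {
  structure(list(heights = h, z_step = z_step, grid_size = NA_integer_,
                 z_scale = 0.1), class = "height_map")
}

# analytic height surface: flat monolayer plus spherical caps
cap_surface <- function(n, mono, caps) {
  h <- matrix(mono, n, n)
  for (k in seq_len(nrow(caps))) {
    dx2 <- (seq_len(n) - caps$x[k])^2
    dy2 <- (seq_len(n) - caps$y[k])^2
    d2 <- outer(dy2, dx2, `+`) / caps$r[k]^2
    lift <- caps$h[k] * sqrt(pmax(0, 1 - d2))
    h <- pmax(h, mono + lift)
  }
  h
}

test_that("height map encodes the top foreground section", {
  one <- matrix(TRUE, 6, 6)
  expect_equal(height_map(list(one), z_step = 2)$heights,
               matrix(2, 6, 6))
  none <- matrix(FALSE, 6, 6)
  expect_equal(height_map(list(none, none), z_step = 2)$heights,
               matrix(0, 6, 6))
  # QC-excluded sections do not contribute
  hm <- height_map(list(one, one), z_step = 2,
                   qc = section_qc(0:1, c(FALSE, TRUE), c("", "bad")))
  expect_equal(hm$heights, matrix(2, 6, 6))
})

test_that("phantom dome apex sits monolayer + cap height above membrane", {
  domes <- data.frame(x = 80, y = 80, radius_px = 30, cap_height_um = 10)
  spec <- tiny_phantom_spec(seed = 8, n_sections = 16L, domes = domes)
  hm <- height_map(generate_phantom(spec)$truth$masks, spec$z_step)
  expect_lte(abs(max(hm$heights) -
                   (spec$monolayer_height_um + 10)), spec$z_step)
})

test_that("block-mean resampling preserves means and exact blocks", {
  const <- make_hm(matrix(7, 64, 64))
  expect_equal(resample_grid(const, 16L)$heights, matrix(7, 16, 16))

  withr::with_seed(3, blocks <- matrix(runif(128 * 128), 128, 128))
  big <- blocks[rep(1:128, each = 2), rep(1:128, each = 2)]
  rs <- resample_grid(make_hm(big), 128L)
  expect_equal(rs$heights, blocks)

  withr::with_seed(4, m <- matrix(runif(96 * 96), 96, 96))
  rs2 <- resample_grid(make_hm(m), 32L)
  expect_equal(mean(rs2$heights), mean(m), tolerance = 1e-9)
  expect_error(resample_grid(make_hm(m), 200L), "larger")
})

test_that("a flat surface yields no domes", {
  expect_equal(nrow(detect_domes(make_hm(matrix(14, 128, 128)))), 0L)
})

test_that("spherical caps are detected with their heights and footprints", {
  caps <- data.frame(x = c(30, 95, 64), y = c(30, 40, 100),
                     r = c(12, 10, 11), h = c(10, 8, 12))
  hm <- make_hm(cap_surface(128, 14, caps))
  dd <- detect_domes(hm, min_prominence_um = 4, min_area_px = 25L)
  expect_equal(nrow(dd), 3L)
  ord <- order(dd$centroid_x)
  want <- caps[order(caps$x), ]
  expect_equal(dd$max_height_um[ord], want$h, tolerance = 0.1)
  expect_equal(dd$centroid_x[ord], want$x, tolerance = 1)
  expect_true(all(dd$eccentricity < 0.2))
})

test_that("caps merged into one elevated region fuse into one dome", {
  caps <- data.frame(x = c(60, 72), y = c(64, 64), r = c(12, 12),
                     h = c(10, 10))
  hm <- make_hm(cap_surface(128, 14, caps))
  dd <- detect_domes(hm)
  expect_equal(nrow(dd), 1L)
  expect_gt(dd$area_px, pi * 12^2)         # combined footprint
})

test_that("tissue islands on bare membrane are not reported as domes", {
  h <- matrix(0, 128, 128)
  h[40:70, 40:70] <- 14                    # isolated monolayer island
  expect_equal(nrow(detect_domes(make_hm(h), close_radius_px = 0L)), 0L)
  # the same plateau on a monolayer is a dome-like elevation
  h2 <- matrix(14, 128, 128)
  h2[40:70, 40:70] <- 24
  expect_equal(nrow(detect_domes(make_hm(h2), close_radius_px = 0L)), 1L)
})

test_that("an isolated cap is visible from all four views", {
  caps <- data.frame(x = 64, y = 64, r = 12, h = 10)
  hm <- make_hm(cap_surface(128, 14, caps))
  dd <- detect_domes(hm)
  vw <- count_per_angle_view(hm, dd)
  expect_equal(unname(vw$per_view), rep(1, 4))
  expect_equal(vw$average_per_view, 1)
  expect_equal(vw$domes$views_detected, 4L)
})

test_that("occlusion hides a small cap behind a tall ridge in one view", {
  h <- cap_surface(128, 14, data.frame(x = 90, y = 64, r = 12, h = 8))
  h[5:124, 60:68] <- 40                    # tall wall crossing the field
  hm <- make_hm(h)
  dd <- detect_domes(hm, close_radius_px = 0L)
  vw <- count_per_angle_view(hm, dd)
  cap_row <- which.min(abs(vw$domes$centroid_x - 90))
  expect_lt(vw$domes$views_detected[cap_row], 4L)
  expect_lt(vw$average_per_view, nrow(dd))
  # average never exceeds the total dome count
  expect_lte(vw$average_per_view, nrow(dd))
})

test_that("rotating the surface by 90 degrees permutes per-view counts", {
  h <- cap_surface(128, 14, data.frame(x = 90, y = 64, r = 12, h = 8))
  h[5:124, 60:68] <- 40
  rot <- t(h)[ncol(h):1, ]
  a <- count_per_angle_view(make_hm(h), detect_domes(make_hm(h),
                                                     close_radius_px = 0L))
  b <- count_per_angle_view(make_hm(rot), detect_domes(make_hm(rot),
                                                       close_radius_px = 0L))
  expect_equal(a$average_per_view, b$average_per_view)
  expect_setequal(unname(a$per_view), unname(b$per_view))
})
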