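test_that("connected-component labeling honors 4- vs 8-connectivity", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- m[3, 3] <- TRUE               # diagonal touch
  expect_equal(max(label_regions(m, 8L)), 1L)
  expect_equal(max(label_regions(m, 4L)), 2L)

  sq <- matrix(FALSE, 10, 10)
  sq[2:4, 2:4] <- TRUE; sq[7:9, 7:9] <- TRUE
  expect_equal(max(label_regions(sq, 8L)), 2L)
  expect_equal(max(label_regions(matrix(FALSE, 5, 5), 8L)), 0L)
})

test_that("labeling agrees with a flood-fill oracle on random masks", {
  for (seed in 1:6) {
    withr::with_seed(seed, m <- matrix(runif(40 * 40) < 0.4, 40, 40))
    for (conn in c(4L, 8L)) {
      got <- label_regions(m, conn)
      want <- flood_fill_label(m, conn)
      expect_equal(max(got), max(want))
      # same partition: labels correspond one-to-one
      expect_true(all(tapply(want[m], got[m],
                             function(v) length(unique(v))) == 1))
      expect_identical(got > 0, m)
    }
  }
})

test_that("eccentricity follows the ellipse closed form", {
  disk <- ellipse_mask(40, 40)
  f <- region_features(label_regions(disk))
  expect_lte(f$eccentricity, 0.05)

  ell <- ellipse_mask(60, 30)              # a = 2b
  f2 <- region_features(label_regions(ell))
  expect_equal(f2$eccentricity, sqrt(3) / 2, tolerance = 0.02)

  bar <- matrix(TRUE, 1, 100)
  f3 <- region_features(label_regions(bar))
  expect_gte(f3$eccentricity, 0.99)

  # single pixel: degenerate, e defined as 0
  px <- matrix(FALSE, 5, 5); px[3, 3] <- TRUE
  expect_equal(region_features(label_regions(px))$eccentricity, 0)
})

test_that("eccentricity is invariant under rotation and uniform scaling", {
  ell <- ellipse_mask(45, 15)
  e0 <- region_features(label_regions(ell))$eccentricity
  rot <- t(ell)[ncol(ell):1, ]             # 90 degree rotation
  expect_equal(region_features(label_regions(rot))$eccentricity, e0,
               tolerance = 1e-9)
  big <- ellipse_mask(90, 30)
  expect_equal(region_features(label_regions(big))$eccentricity, e0,
               tolerance = 0.02)
})

test_that("region features agree with EBImage moments as a cross-check", {
  withr::with_seed(4, m <- matrix(runif(50 * 50) < 0.45, 50, 50))
  m <- domescope:::as_plain(EBImage::fillHull(
    EBImage::opening(m * 1, EBImage::makeBrush(3, "box")))) > 0
  lab <- label_regions(m, 4L)              # bwlabel's own connectivity
  f <- region_features(lab)
  ref <- EBImage::computeFeatures.moment(lab)
  if (nrow(f) > 1) {
    # match by centroid (EBImage x/y are transposed relative to rows/cols)
    ord <- order(f$centroid_y, f$centroid_x)
    ref_ord <- order(ref[, "m.cy"], ref[, "m.cx"])
    expect_equal(f$eccentricity[ord],
                 unname(ref[ref_ord, "m.eccentricity"]), tolerance = 1e-6)
  }
  # area conservation: component areas sum to total foreground
  expect_equal(sum(f$area_px), sum(m))
})

test_that("coverage profiles report fractions and respect QC exclusions", {
  full <- matrix(TRUE, 8, 8)
  half <- full; half[, 1:4] <- FALSE
  qc <- section_qc(0:2, c(FALSE, FALSE, TRUE), c("", "", "artifact"))
  prof <- coverage_profile(list(full, half, full), z_step = 2, qc = qc,
                           replicate_id = "r1", condition = "static",
                           timepoint = "T1")
  expect_equal(prof$coverage, c(1, 0.5, NA))
  expect_equal(prof$height_um, c(0, 2, 4))
  expect_true(prof$excluded[3])
  expect_error(coverage_profile(list(), z_step = 2), "length")
})

test_that("phantom coverage profile matches the analytic ground truth", {
  domes <- data.frame(x = c(45, 115), y = c(50, 105),
                      radius_px = c(20, 24), cap_height_um = c(8, 10))
  spec <- tiny_phantom_spec(seed = 3, domes = domes)
  ph <- generate_phantom(spec)
  prof <- coverage_profile(ph$truth$masks, spec$z_step)
  analytic <- ground_truth_coverage(spec)
  quant_tol <- (2 * pi * sum(domes$radius_px) + 8) /
    (spec$width * spec$height)
  expect_true(all(abs(prof$coverage - analytic) <=
                    pmax(quant_tol, 1e-3)))
  # monotone non-increasing with height for monolayer + caps geometry
  expect_true(all(diff(prof$coverage) <= 1e-9))
})

test_that("object counts per section match phantom truth and symmetry", {
  domes <- data.frame(x = c(40, 80, 120), y = c(40, 110, 60),
                      radius_px = c(15, 14, 16),
                      cap_height_um = c(8, 9, 10))
  spec <- tiny_phantom_spec(seed = 6, n_sections = 14L, domes = domes)
  ph <- generate_phantom(spec)
  counts <- object_count_profile(ph$truth$masks)
  # first section above the monolayer top: one object per dome
  s_above <- ceiling(spec$monolayer_height_um / spec$z_step)
  expect_equal(counts$n_objects[counts$section == s_above], 3L)
  # last section lies above every cap apex: nothing left
  expect_equal(counts$n_objects[spec$n_sections], 0L)

  m <- ph$truth$masks[, , s_above + 1L]
  rot <- t(m)[ncol(m):1, ]
  expect_equal(max(label_regions(rot)), max(label_regions(m)))
})

test_that("cross-replicate averages are flagged full vs partial", {
  mk <- function(rid, cov) {
    data.frame(replicate_id = rid, condition = "dynamic", timepoint = "T2",
               section = 0:2, height_um = c(0, 2, 4), coverage = cov,
               excluded = is.na(cov))
  }
  prof <- rbind(mk("r1", c(0.9, 0.8, NA)), mk("r2", c(0.7, 0.6, 0.5)))
  agg <- aggregate_profiles(prof)
  expect_equal(agg$average_type, c("full", "full", "partial"))
  expect_equal(agg$mean_coverage, c(0.8, 0.7, 0.5))
  expect_equal(agg$n_used, c(2L, 2L, 1L))
})
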