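test_that("normalize_intensity maps the clip range onto [0, 1]", {
  img <- matrix(seq(10, 250, length.out = 100), 10, 10)
  out <- normalize_intensity(img, c(0, 100))
  expect_equal(min(out), 0)
  expect_equal(max(out), 1)
  expect_equal(out[5, 5], (img[5, 5] - 10) / 240)

  expect_equal(normalize_intensity(matrix(7, 4, 4)),
               matrix(0, 4, 4))

  # idempotent on already-normalized input at clip (0, 100)
  twice <- normalize_intensity(normalize_intensity(img, c(0, 100)), c(0, 100))
  expect_equal(twice, normalize_intensity(img, c(0, 100)))
})

test_that("percentile clipping saturates hot pixels as the oracle predicts", {
  withr::with_seed(5, {
    img <- matrix(runif(1e4, 0, 0.5), 100, 100)
    hot <- sample(1e4, 100)
    img[hot] <- 50
  })
  out <- normalize_intensity(img, c(1, 99))
  expect_true(all(out[hot] == 1))
  q <- quantile(img, c(0.01, 0.99), names = FALSE)
  oracle <- (pmin(pmax(median(img), q[1]), q[2]) - q[1]) / (q[2] - q[1])
  expect_equal(median(out), oracle)
})

test_that("grayscale projection is the weighted channel sum", {
  withr::with_seed(2, arr <- array(runif(6 * 6 * 2 * 2), c(6, 6, 2, 2)))
  zs <- zstack(arr, z_step = 2, channel_names = c("mucus", "nuclei"))
  c1 <- normalize_intensity(arr[, , 1, 1], c(1, 99))
  c2 <- normalize_intensity(arr[, , 1, 2], c(1, 99))
  expect_equal(to_grayscale(zs, 0, c(1, 0)), c1)
  expect_equal(to_grayscale(zs, 0, c(0.7, 0.3)),
               pmin(pmax(0.7 * c1 + 0.3 * c2, 0), 1))
  # identical channels: any weights give the channel back
  zs2 <- zstack(array(rep(arr[, , , 1], 2), c(6, 6, 2, 2)), z_step = 2)
  expect_equal(to_grayscale(zs2, 0, c(0.5, 0.5)), c1)
  expect_error(to_grayscale(zs, 0, c(1, 0, 0)), "match")
})

test_that("gamma enhancement brightens dim pixels and preserves order", {
  img <- matrix(c(0.25, 0.5, 0.04, 1), 2, 2)
  expect_equal(enhance_weak_signal(img, 1), img)
  expect_equal(enhance_weak_signal(img, 0.5)[1, 1], 0.5)
  expect_error(enhance_weak_signal(img, 0), "enhance_gamma")
  for (g in c(0.3, 0.7, 1.8)) {
    withr::with_seed(g * 100, v <- runif(50))
    expect_identical(order(v^g), order(v))
  }
})

test_that("adaptive binarization recovers a disk, also on a gradient", {
  expect_equal(sum(adaptive_binarize(matrix(0.5, 64, 64), 21L, 0.01)), 0)

  disk <- domescope:::disk_mask(200, 200, 100, 100, 40)
  img <- ifelse(disk, 0.9, 0.1)
  got <- adaptive_binarize(img, 51L, 0.05)
  got <- clean_mask(got, 20L, fill_holes = TRUE)
  expect_gte(mask_iou(got, disk), 0.95)

  # linear illumination gradient 0.1-0.5 defeats any global threshold
  grad <- img + matrix(seq(0.1, 0.5, length.out = 200), 200, 200,
                       byrow = TRUE)
  got2 <- clean_mask(adaptive_binarize(grad, 51L, 0.05), 20L,
                     fill_holes = TRUE)
  expect_gte(mask_iou(got2, disk), 0.9)

  # invariant to adding a constant to the whole image
  expect_identical(adaptive_binarize(img, 31L, 0.02),
                   adaptive_binarize(img + 0.17, 31L, 0.02))
  expect_error(adaptive_binarize(matrix(0, 8, 8), 21L, 0), "larger")
})

test_that("mask hygiene removes specks and fills holes as requested", {
  m <- matrix(FALSE, 40, 40)
  m[5:6, 5:6] <- TRUE                       # 4-px speck
  expect_equal(sum(clean_mask(m, 10L, FALSE)), 0)

  ring <- domescope:::disk_mask(60, 60, 30, 30, 15) &
    !domescope:::disk_mask(60, 60, 30, 30, 8)
  filled <- clean_mask(ring, 0L, fill_holes = TRUE)
  expect_identical(unname(filled), domescope:::disk_mask(60, 60, 30, 30, 15))

  # surviving component count equals a flood-fill oracle
  withr::with_seed(9, m2 <- matrix(runif(60 * 60) < 0.25, 60, 60))
  cleaned <- clean_mask(m2, 5L, fill_holes = FALSE, connectivity = 8L)
  o <- flood_fill_label(m2, 8L)
  survivors <- sum(tabulate(o[o > 0]) >= 5L)
  expect_equal(max(label_regions(cleaned, 8L)), survivors)
})

test_that("line artifacts are flagged, clean stacks are not", {
  spec <- tiny_phantom_spec(seed = 21, n_sections = 8L)
  ph <- generate_phantom(spec)
  expect_false(any(flag_artifact_sections(ph$stack)$excluded))

  zs <- ph$stack
  zs$data[101:102, , 4, 1] <- 1      # 2-px full-width line on section 3
  qc <- flag_artifact_sections(zs)
  expect_true(qc$excluded[qc$section_index == 3])
  expect_match(qc$reason[qc$section_index == 3], "line")

  qc2 <- flag_artifact_sections(ph$stack, manual_exclude = c(0L, 7L))
  expect_setequal(domescope:::excluded_sections(qc2), c(0L, 7L))
  expect_match(qc2$reason[qc2$section_index == 0], "manual")
})
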