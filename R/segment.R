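#' Segmentation configuration
#'
#' Bundles every tunable of the per-section binarization chain:
#' percentile-clip normalization to a 0-1 range, weighted grayscale
#' projection, optional gamma enhancement of weak signal, local-mean
#' adaptive thresholding, and mask hygiene.
#'
#' Defaults: coverage is defined on the mucus/WGA channel
#' (`channel_weights = c(1, 0)`), since WGA labels cellular presence and the
#' apical mucus layer; the adaptive threshold is the local mean over a 51 px
#' window plus a 0.02 offset; 8-connectivity for blob-like objects.
#'
#' @param clip_percentiles length-2 numeric `(low, high)` in percent,
#'   `0 <= low < high <= 100`.
#' @param channel_weights per-channel weights summing to 1.
#' @param block_size odd window size (px) of the local-mean threshold.
#' @param offset constant added to the local mean (0-1 intensity units).
#' @param min_object_px objects smaller than this are removed.
#' @param fill_holes fill interior holes after speck removal?
#' @param connectivity 4 or 8.
#' @param enhance_gamma gamma exponent; `< 1` brightens dim regions, 1 is
#'   the identity. Applied between grayscale projection and thresholding.
#' @param smooth_sigma Gaussian pre-smoothing of each section before
#'   thresholding, px (0 disables). Suppresses pixel noise so that the
#'   small threshold offset discriminates structure, not noise.
#' @param floor_method `"otsu"` (default) or `"none"`. The local-mean rule
#'   is a contrast detector: deep inside a cell-covered region wider than
#'   the window, the window saturates and nothing exceeds its own mean.
#'   With `"otsu"`, a pixel is also foreground when it exceeds a global
#'   intensity floor (Otsu's threshold of the normalized volume), which
#'   recovers the interior of extended sheets; the adaptive rule still
#'   captures locally contrasted structure under illumination gradients.
#' @return object of class `segmentation_config`.
#' @export
segmentation_config <- function(clip_percentiles = c(1, 99),
                                channel_weights = c(1, 0),
                                block_size = 51L,
                                offset = 0.02,
                                min_object_px = 64L,
                                fill_holes = FALSE,
                                connectivity = 8L,
                                enhance_gamma = 1,
                                smooth_sigma = 2,
                                floor_method = c("otsu", "none")) {
  stopifnot(length(clip_percentiles) == 2L,
            clip_percentiles[1] >= 0, clip_percentiles[2] <= 100,
            clip_percentiles[1] < clip_percentiles[2],
            is_count(block_size), block_size %% 2L == 1L, block_size >= 3L,
            is_scalar_num(offset),
            is_count(min_object_px),
            is.logical(fill_holes),
            connectivity %in% c(4L, 8L),
            is_scalar_num(enhance_gamma), enhance_gamma > 0,
            is_scalar_num(smooth_sigma), smooth_sigma >= 0,
            abs(sum(channel_weights) - 1) < 1e-9)
  floor_method <- match.arg(floor_method)
  structure(list(clip_percentiles = as.numeric(clip_percentiles),
                 channel_weights = as.numeric(channel_weights),
                 block_size = as.integer(block_size),
                 offset = offset,
                 min_object_px = as.integer(min_object_px),
                 fill_holes = isTRUE(fill_holes),
                 connectivity = as.integer(connectivity),
                 enhance_gamma = enhance_gamma,
                 smooth_sigma = smooth_sigma,
                 floor_method = floor_method),
            class = "segmentation_config")
}

#' Percentile-clip normalization to the 0-1 range
#'
#' Values are clipped at the given intensity percentiles and then mapped
#' affinely onto `[0, 1]`. A constant image maps to all zeros.
#'
#' @param img numeric matrix (or array) with finite, non-negative values.
#' @param clip_percentiles `(low, high)` in percent.
#' @return object of the same shape with values in `[0, 1]`.
#' @export
normalize_intensity <- function(img, clip_percentiles = c(1, 99)) {
  stopifnot(all(is.finite(img)), all(img >= 0))
  q <- quantile(img, clip_percentiles / 100, names = FALSE, type = 7)
  out <- img
  if (q[2] <= q[1]) {
    out[] <- 0
  } else {
    out[] <- (pmin(pmax(img, q[1]), q[2]) - q[1]) / (q[2] - q[1])
  }
  out
}

#' Weighted grayscale projection of one section
#'
#' Channels are normalized individually, combined as a weighted sum, and
#' re-clipped to `[0, 1]`.
#'
#' @param zs a [zstack()].
#' @param section 0-based section index.
#' @param channel_weights weight per channel (must match channel count).
#' @param clip_percentiles passed to [normalize_intensity()].
#' @return matrix in `[0, 1]`.
#' @export
to_grayscale <- function(zs, section, channel_weights = c(1, 0),
                         clip_percentiles = c(1, 99)) {
  stopifnot(inherits(zs, "zstack"))
  n_ch <- dim(zs$data)[4L]
  if (length(channel_weights) != n_ch)
    stop("channel_weights length (", length(channel_weights),
         ") does not match channel count (", n_ch, ")")
  acc <- matrix(0, dim(zs$data)[1L], dim(zs$data)[2L])
  for (ch in seq_len(n_ch)) {
    if (channel_weights[ch] == 0) next
    acc <- acc + channel_weights[ch] *
      normalize_intensity(get_section(zs, section, ch), clip_percentiles)
  }
  pmin(pmax(acc, 0), 1)
}

#' Gamma enhancement of weak signal
#'
#' Reproducible, parameterized stand-in for interactive contrast enhancement
#' of dim cellular signal: `x^gamma` with `gamma < 1` brightens dim regions
#' while preserving pixel ordering; `gamma = 1` is the identity. The value
#' used is recorded in the run manifest by [analyze()].
#'
#' @param img matrix in `[0, 1]`.
#' @param enhance_gamma positive exponent.
#' @export
enhance_weak_signal <- function(img, enhance_gamma = 1) {
  if (!is_scalar_num(enhance_gamma) || enhance_gamma <= 0)
    stop("enhance_gamma must be > 0")
  img^enhance_gamma
}

#' Local-mean adaptive binarization
#'
#' A pixel is foreground iff its value exceeds the mean over the surrounding
#' `block_size x block_size` window plus `offset`. Borders use reflected
#' padding. Being local, the rule is invariant to adding a constant to the
#' whole image and robust to the smooth illumination gradients of tiled
#' mosaics, which defeat a single global threshold.
#'
#' @param img matrix in `[0, 1]`.
#' @param block_size odd window size, px.
#' @param offset constant offset in intensity units.
#' @return logical matrix.
#' @export
adaptive_binarize <- function(img, block_size = 51L, offset = 0.02) {
  stopifnot(block_size %% 2L == 1L)
  img > box_mean(img, as.integer(block_size)) + offset
}

#' Binary mask hygiene
#'
#' Removes connected components smaller than `min_object_px` and optionally
#' fills interior holes (background regions not connected to the image
#' border).
#'
#' @param mask logical matrix.
#' @param min_object_px minimum surviving object size, px.
#' @param fill_holes fill enclosed holes?
#' @param connectivity 4 or 8.
#' @return logical matrix.
#' @export
clean_mask <- function(mask, min_object_px = 64L, fill_holes = TRUE,
                       connectivity = 8L) {
  m <- mask
  if (min_object_px > 1L && any(m)) {
    lab <- label_regions(m, connectivity)
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_object_px)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (fill_holes && any(m)) {
    m <- as_plain(EBImage::fillHull(m * 1L)) > 0
  }
  m
}

#' Flag optical sections corrupted by line-shaped artifacts
#'
#' Glass-slide grid artifacts appear as thin, bright, straight lines
#' spanning the field. Each section's grayscale row and column mean
#' profiles are scanned for a sharp excursion: a line a few pixels wide
#' lifts its own profile bin far above the bins two pixels away, whereas
#' genuine tissue texture produces many comparable bumps. A section is
#' flagged when its peak excursion exceeds both `line_contrast` (an
#' absolute floor in intensity units) and 25 robust standard deviations of
#' the profile's own second differences: genuine tissue texture, including
#' sections holding only a few bright dome caps, stays below ~20 robust
#' sds, while a thin full-width line sits far above (~80+). A manual exclusion list is always
#' honored verbatim.
#'
#' @param zs a [zstack()].
#' @param line_contrast absolute flag floor on the profile excursion
#'   (0-1 intensity units).
#' @param channel_weights,clip_percentiles grayscale projection settings
#'   (percentiles taken over the stack volume).
#' @param manual_exclude 0-based section indices to exclude unconditionally.
#' @return a [section_qc()] data frame covering every section.
#' @export
flag_artifact_sections <- function(zs, line_contrast = 0.1,
                                   channel_weights = c(1, 0),
                                   clip_percentiles = c(1, 99),
                                   manual_exclude = integer()) {
  stopifnot(inherits(zs, "zstack"))
  gray <- grayscale_volume(zs, channel_weights, clip_percentiles)
  S <- dim(zs$data)[3L]
  idx <- excl <- reason <- vector("list", S)
  for (s in seq_len(S)) {
    s0 <- s - 1L
    idx[[s]] <- s0
    if (s0 %in% manual_exclude) {
      excl[[s]] <- TRUE
      reason[[s]] <- "manual exclusion"
      next
    }
    g <- gray[, , s]
    score <- max(profile_line_score(rowMeans(g), line_contrast),
                 profile_line_score(colMeans(g), line_contrast))
    if (score > 0) {
      excl[[s]] <- TRUE
      reason[[s]] <- sprintf("line artifact (profile contrast %.3f)", score)
    } else {
      excl[[s]] <- FALSE
      reason[[s]] <- ""
    }
  }
  section_qc(unlist(idx), unlist(excl), unlist(reason))
}

# peak sharp excursion of a 1-d intensity profile relative to the values
# two bins away (second-difference top-hat); returns the excursion when it
# is both above the absolute floor and a >= 25 robust-sd outlier of the
# profile's own second differences, else 0
profile_line_score <- function(p, floor) {
  n <- length(p)
  if (n < 7L) return(0)
  i <- 3L:(n - 2L)
  d <- p[i] - (p[i - 2L] + p[i + 2L]) / 2
  top <- max(d)
  if (top > floor && top > 25 * stats::mad(d, center = 0)) top else 0
}

gaussian_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  size <- 2L * ceiling(3 * sigma) + 1L
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  as_plain(EBImage::filter2(img, k, boundary = "replicate"))
}

# normalize each channel over the whole volume, then combine with weights.
# Normalizing per stack rather than per section keeps optical sections near
# or above the tissue top - which contain little or no signal - from being
# stretched to full range, which would turn detector noise into foreground.
grayscale_volume <- function(zs, channel_weights, clip_percentiles) {
  d <- dim(zs$data)
  if (length(channel_weights) != d[4L])
    stop("channel_weights length does not match channel count")
  acc <- array(0, d[1:3])
  for (ch in seq_len(d[4L])) {
    if (channel_weights[ch] == 0) next
    acc <- acc + channel_weights[ch] *
      normalize_intensity(zs$data[, , , ch], clip_percentiles)
  }
  pmin(pmax(acc, 0), 1)
}

#' Segment every section of a stack
#'
#' Runs the full binarization chain over all sections: stack-level
#' percentile normalization of each channel, weighted grayscale projection,
#' gamma enhancement, Gaussian pre-smoothing, local-mean adaptive
#' binarization and mask hygiene. Normalization percentiles are taken over
#' the whole volume (not per section) so that empty top sections are not
#' noise-stretched to full range.
#'
#' @param zs a [zstack()].
#' @param config a [segmentation_config()].
#' @return logical array `[y, x, section]` of cell-covered pixels.
#' @export
segment_stack <- function(zs, config = segmentation_config()) {
  stopifnot(inherits(zs, "zstack"), inherits(config, "segmentation_config"))
  gray <- grayscale_volume(zs, config$channel_weights,
                           config$clip_percentiles)
  d <- dim(gray)
  if (config$enhance_gamma != 1)
    gray <- enhance_weak_signal(gray, config$enhance_gamma)
  for (s in seq_len(d[3L]))
    gray[, , s] <- gaussian_smooth(gray[, , s], config$smooth_sigma)
  floor_thr <- if (config$floor_method == "otsu") {
    EBImage::otsu(EBImage::Image(matrix(gray, d[1L] * d[3L], d[2L])),
                  range = c(0, 1))
  } else Inf
  masks <- array(FALSE, d)
  for (s in seq_len(d[3L])) {
    g <- gray[, , s]
    m <- adaptive_binarize(g, config$block_size, config$offset) |
      (g > floor_thr)
    masks[, , s] <- clean_mask(m, config$min_object_px, config$fill_holes,
                               config$connectivity)
  }
  masks
}
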