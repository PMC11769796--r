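#' Reconstruct the epithelial top surface as a height map
#'
#' For every lateral position, the height of the tissue top:
#' `z_step * (1 + highest 0-based section index whose mask is foreground)`,
#' and 0 where no section is foreground. QC-excluded sections do not
#' contribute. The map depends only on the binary masks, so it is invariant
#' to any intensity rescaling of the source stack.
#'
#' @param masks per-section binary masks (array `[y, x, section]` or list).
#' @param z_step axial spacing, um.
#' @param qc optional [section_qc()] table.
#' @return object of class `height_map`: list with `heights` (um matrix),
#'   `z_step`, `grid_size` (`NA` until [resample_grid()]), and `z_scale`
#'   (display-only vertical exaggeration, default 0.1; never used in
#'   measurements).
#' @export
height_map <- function(masks, z_step, qc = NULL) {
  arr <- coerce_mask_array(masks)
  stopifnot(is_scalar_num(z_step), z_step > 0)
  S <- dim(arr)[3L]
  excl <- (seq_len(S) - 1L) %in% excluded_sections(qc)
  h <- matrix(0, dim(arr)[1L], dim(arr)[2L])
  for (s in seq_len(S)) {
    if (excl[s]) next
    h[arr[, , s]] <- s * z_step  # = z_step * (1 + 0-based index)
  }
  structure(list(heights = h, z_step = z_step, grid_size = NA_integer_,
                 z_scale = 0.1),
            class = "height_map")
}

#' @export
print.height_map <- function(x, ...) {
  cat(sprintf("<height_map> %d x %d, range %g-%g um%s\n",
              ncol(x$heights), nrow(x$heights), min(x$heights),
              max(x$heights),
              if (is.na(x$grid_size)) "" else
                sprintf(" (resampled to grid %d)", x$grid_size)))
  invisible(x)
}

#' Block-mean resampling of a height map
#'
#' Downsamples to a `grid_size x grid_size` surface by averaging the source
#' pixels falling in each grid cell. A grid of 128 gives the working
#' resolution for surface rendering and dome detection. The overall mean
#' height is conserved when the map divides evenly into blocks.
#'
#' @param hm a [height_map()].
#' @param grid_size target grid edge, `>= 8`.
#' @return a resampled `height_map`.
#' @export
resample_grid <- function(hm, grid_size = 128L) {
  stopifnot(inherits(hm, "height_map"), is_count(grid_size), grid_size >= 8L)
  H <- nrow(hm$heights); W <- ncol(hm$heights)
  if (grid_size > H || grid_size > W)
    stop("grid_size larger than the height map")
  bin_r <- ceiling(seq_len(H) / H * grid_size)
  bin_c <- ceiling(seq_len(W) / W * grid_size)
  sums <- rowsum(t(rowsum(hm$heights, bin_r)), bin_c)
  cnt <- outer(tabulate(bin_c, grid_size), tabulate(bin_r, grid_size))
  out <- hm
  out$heights <- unname(t(sums / cnt))
  out$grid_size <- as.integer(grid_size)
  out
}

#' Detect domes as prominent elevations of the height map
#'
#' The height map is first regularized by a grayscale closing with a small
#' disk, which bridges sub-cellular gaps in the monolayer (without it,
#' every gap would pull the baseline to the membrane and narrow monolayer
#' ridges would masquerade as prominences). The local monolayer level is
#' then estimated from the closed map, by default as a running median over
#' a `(2 * baseline_radius_px + 1)` square window: the median tracks the
#' monolayer top as long as neither residual gaps nor dome footprints
#' occupy half the window, so nearby domes are never bridged into the
#' baseline. A classic rolling-disk (grayscale opening) baseline is
#' available as an alternative; it assumes all monolayer gaps have been
#' closed, since any remaining hole wider than the disk collapses the
#' baseline around it. Dome candidates are the connected regions where the
#' closed surface rises at least `min_prominence_um` above the baseline,
#' keeping footprints of at least `min_area_px`.
#' Adjacent caps whose elevated regions merge are reported as a single dome
#' with the combined footprint (fusion semantics). Each dome is scored by
#' footprint area, maximum height above baseline, and footprint
#' eccentricity.
#'
#' @param hm a [height_map()] (typically after [resample_grid()]).
#' @param min_prominence_um minimum elevation above baseline, um.
#' @param min_area_px minimum footprint, px of the current grid.
#' @param baseline_radius_px radius of the baseline window (median) or
#'   opening disk, px. Set to about twice the largest expected dome radius
#'   so domes are flattened into the baseline while broader tissue relief
#'   is preserved.
#' @param close_radius_px radius of the gap-bridging closing disk, px
#'   (0 disables). Should exceed the typical monolayer gap radius and stay
#'   well below the dome radius.
#' @param baseline_method `"median"` (default) or `"opening"`.
#' @param min_baseline_um a dome is an elevation of the epithelial sheet:
#'   candidates whose median baseline is below this (i.e. plateaus of
#'   tissue standing on essentially bare membrane, such as isolated
#'   monolayer islands) are not reported as domes. One axial step is a
#'   sensible value; 0 disables the distinction.
#' @param min_baseline_frac relative form of the same criterion: the
#'   median baseline under a dome must also reach this fraction of the
#'   map's typical tissue level (the median baseline over pixels at or
#'   above `min_baseline_um`). Rejects tissue patches in sparsely covered
#'   pockets, whose local baseline is far below the monolayer, without a
#'   fixed height cut. 0 disables.
#' @param exclude_border drop candidates whose footprint touches the map
#'   edge (default FALSE; footprints and occlusion geometry of border-cut
#'   domes are incomplete, but fields cropped from larger mosaics
#'   legitimately contain them).
#' @param connectivity 4 or 8.
#' @return data frame of class `dome_records`: `dome_id`, `area_px`,
#'   `max_height_um` (above baseline), `eccentricity`, `centroid_x`,
#'   `centroid_y`, plus attributes `labels` (footprint label matrix) and
#'   `baseline` (opening surface) used by [count_per_angle_view()].
#' @export
detect_domes <- function(hm, min_prominence_um = 4, min_area_px = 25L,
                         baseline_radius_px = 25L, close_radius_px = 8L,
                         baseline_method = c("median", "opening"),
                         min_baseline_um = hm$z_step,
                         min_baseline_frac = 0.5,
                         exclude_border = FALSE,
                         connectivity = 8L) {
  baseline_method <- match.arg(baseline_method)
  stopifnot(inherits(hm, "height_map"),
            is_scalar_num(min_prominence_um), min_prominence_um > 0,
            is_count(min_area_px), min_area_px >= 1,
            is_count(close_radius_px))
  h0 <- hm$heights
  # EBImage grayscale morphology expects intensities in [0, 1]; erosion,
  # dilation and the median commute with positive scaling, so work on
  # h / scale exactly. All filters run on a reflect-padded copy: with a
  # truncated border window the closing cannot bridge gaps that touch the
  # edge and the baseline under-fills with membrane-level zeros, faking
  # prominence along the image edge.
  scale <- max(h0, 1)
  r <- as.integer(baseline_radius_px)
  pad <- r + as.integer(close_radius_px)
  hp <- reflect_pad(h0 / scale, pad)
  if (close_radius_px > 0) {
    cb <- EBImage::makeBrush(2L * as.integer(close_radius_px) + 1L,
                             shape = "disc")
    hp <- as_plain(EBImage::closing(hp, cb))
  }
  bp <- if (baseline_method == "median") {
    as_plain(EBImage::medianFilter(hp, r))
  } else {
    as_plain(EBImage::opening(hp,
      EBImage::makeBrush(2L * r + 1L, shape = "disc")))
  }
  crop <- function(m) m[(pad + 1L):(pad + nrow(h0)),
                        (pad + 1L):(pad + ncol(h0))] * scale
  h <- crop(hp)           # closed surface, measurement reference
  baseline <- crop(bp)
  excess <- h - baseline
  excess <- h - baseline
  cand <- excess >= min_prominence_um
  lab <- label_regions(cand, connectivity)
  feats <- region_features(lab)
  base_under <- vapply(feats$label, function(k)
    median(baseline[lab == k]), numeric(1))
  base_floor <- min_baseline_um
  if (min_baseline_frac > 0 && any(baseline >= min_baseline_um)) {
    typical <- median(baseline[baseline >= min_baseline_um])
    base_floor <- max(base_floor, min_baseline_frac * typical)
  }
  keep <- feats$area_px >= min_area_px & base_under >= base_floor
  if (exclude_border) keep <- keep & !feats$border
  feats <- feats[keep, , drop = FALSE]
  # drop filtered labels from the map, renumber survivors
  relab <- integer(max(lab, 1L))
  relab[feats$label] <- seq_len(nrow(feats))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  max_h <- vapply(seq_len(nrow(feats)), function(k)
    max(excess[lab == k]), numeric(1))
  out <- data.frame(dome_id = seq_len(nrow(feats)),
                    area_px = feats$area_px,
                    max_height_um = max_h,
                    eccentricity = feats$eccentricity,
                    centroid_x = feats$centroid_x,
                    centroid_y = feats$centroid_y)
  attr(out, "labels") <- lab
  attr(out, "baseline") <- baseline
  attr(out, "min_prominence_um") <- min_prominence_um
  class(out) <- c("dome_records", class(out))
  out
}

# running max of occluder heights seen before each pixel from one of the
# four axis-aligned viewing directions; the first pixel on each ray has no
# occluder (0 = membrane level)
occlusion_surface <- function(h, view) {
  shift_cummax_rows <- function(m) {           # viewer at x = -Inf (left)
    t(apply(m, 1L, function(v) cummax(c(0, v[-length(v)]))))
  }
  switch(view,
    "0"   = shift_cummax_rows(h),                          # along +x
    "90"  = t(shift_cummax_rows(t(h))),                    # along +y
    "180" = shift_cummax_rows(h[, ncol(h):1])[, ncol(h):1],
    "270" = t(shift_cummax_rows(t(h)[, nrow(h):1]))[nrow(h):1, ],
    stop("unknown view"))
}

#' Dome visibility from four angle views
#'
#' Emulates multi-angle inspection of a rendered surface with an explicit
#' geometric criterion: from each of four azimuths (0, 90, 180, 270
#' degrees), a dome is visible when some point of its footprint rises at
#' least `min_prominence_um` above both the local baseline and the running
#' maximum of the terrain in front of it along the viewing direction (the
#' dome's own footprint is flattened to baseline when computing its
#' occluders, so a dome never hides itself). Reported are the per-view
#' counts, their mean, and per-dome `views_detected` (0-4).
#'
#' @param hm the [height_map()] passed to [detect_domes()].
#' @param domes a [detect_domes()] result.
#' @param min_prominence_um visibility threshold, um; defaults to the
#'   detection prominence.
#' @param n_views number of equally spaced azimuths (4 supported).
#' @return list with `average_per_view`, `per_view` (named counts),
#'   and `domes` (the input table with a `views_detected` column).
#' @export
count_per_angle_view <- function(hm, domes, min_prominence_um = NULL,
                                 n_views = 4L) {
  stopifnot(inherits(hm, "height_map"), inherits(domes, "dome_records"))
  if (n_views != 4L)
    stop("only the four axis-aligned views (n_views = 4) are supported")
  prom <- min_prominence_um %||% attr(domes, "min_prominence_um")
  lab <- attr(domes, "labels")
  baseline <- attr(domes, "baseline")
  h <- hm$heights
  stopifnot(identical(dim(h), dim(lab)))
  views <- c("0", "90", "180", "270")
  n_domes <- nrow(domes)
  vis <- matrix(FALSE, n_domes, length(views),
                dimnames = list(NULL, views))
  for (k in seq_len(n_domes)) {
    inside <- lab == k
    hmod <- h
    hmod[inside] <- baseline[inside]   # self-occlusion off
    for (v in views) {
      occ <- occlusion_surface(hmod, v)
      ref <- pmax(occ[inside], baseline[inside])
      vis[k, v] <- any(h[inside] - ref >= prom)
    }
  }
  per_view <- colSums(vis)
  domes$views_detected <- as.integer(rowSums(vis))
  list(average_per_view = mean(per_view),
       per_view = per_view,
       domes = domes)
}
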