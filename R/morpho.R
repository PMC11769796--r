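#' Label connected foreground components
#'
#' Each maximal connected foreground component receives a unique positive
#' label; background is 0. Connectivity 4 counts only edge-adjacent pixels
#' as neighbors, connectivity 8 also counts diagonal contact.
#'
#' @details 4-connected labeling is delegated to [EBImage::bwlabel()].
#' 8-connected labeling maps the mask onto a double-resolution grid where
#' edge-adjacent and diagonally-adjacent foreground pixels are joined by
#' explicit bridge cells, labels that grid 4-connectedly, and samples the
#' result back; the bridge construction only ever joins pixels that are
#' 8-neighbors in the original mask.
#'
#' @param mask logical (or 0/1) matrix.
#' @param connectivity 4 or 8 (default).
#' @return integer matrix of labels `0..K`, numbered in column-major order
#'   of first appearance.
#' @export
label_regions <- function(mask, connectivity = 8L) {
  stopifnot(connectivity %in% c(4L, 8L))
  m <- as_plain(mask) > 0
  if (!any(m)) return(matrix(0L, nrow(m), ncol(m)))
  if (connectivity == 4L) {
    lab <- as_plain(EBImage::bwlabel(m * 1L))
  } else {
    H <- nrow(m); W <- ncol(m)
    oi <- seq.int(1L, 2L * H - 1L, 2L)
    oj <- seq.int(1L, 2L * W - 1L, 2L)
    E <- matrix(FALSE, 2L * H - 1L, 2L * W - 1L)
    E[oi, oj] <- m
    if (H > 1L) E[oi[-H] + 1L, oj] <- m[-H, , drop = FALSE] &
        m[-1L, , drop = FALSE]
    if (W > 1L) E[oi, oj[-W] + 1L] <- m[, -W, drop = FALSE] &
        m[, -1L, drop = FALSE]
    if (H > 1L && W > 1L) {
      dg <- (m[-H, -W, drop = FALSE] & m[-1L, -1L, drop = FALSE]) |
            (m[-1L, -W, drop = FALSE] & m[-H, -1L, drop = FALSE])
      # a diagonal contact is wired through three bridge cells; the side
      # cells only touch originals that are already 4- or 8-neighbors
      E[oi[-H] + 1L, oj[-W]]      <- E[oi[-H] + 1L, oj[-W]]      | dg
      E[oi[-H] + 1L, oj[-W] + 1L] <- E[oi[-H] + 1L, oj[-W] + 1L] | dg
      E[oi[-H] + 1L, oj[-W] + 2L] <- E[oi[-H] + 1L, oj[-W] + 2L] | dg
    }
    lab <- as_plain(EBImage::bwlabel(E * 1L))[oi, oj, drop = FALSE]
  }
  lab <- matrix(as.integer(lab), nrow(m), ncol(m))
  # renumber consecutively in order of first appearance
  pos <- lab[lab > 0L]
  u <- unique(pos)
  lab[lab > 0L] <- match(pos, u)
  lab
}

#' Area, eccentricity and centroid of labeled regions
#'
#' Shape scoring of contiguous cell-covered objects. The eccentricity of a
#' region is that of the ellipse matching its second central moments: with
#' semi-axes `a >= b`, `e = sqrt(1 - (b/a)^2)`, equivalently the distance
#' between the foci over the major-axis length; 0 is a circle, values near
#' 1 are highly elongated. Degenerate regions (single pixels, zero spread)
#' get `e = 0`.
#'
#' @param labels integer label matrix from [label_regions()].
#' @param section_index 0-based section index recorded with each row.
#' @return data frame with columns `label`, `area_px`, `eccentricity`,
#'   `centroid_x`, `centroid_y`, `border` (does the region touch the image
#'   edge?) and `section_index`.
#' @export
region_features <- function(labels, section_index = NA_integer_) {
  labels <- as_plain(labels)
  idx <- which(labels > 0L)
  if (!length(idx)) {
    return(data.frame(label = integer(), area_px = numeric(),
                      eccentricity = numeric(), centroid_x = numeric(),
                      centroid_y = numeric(), border = logical(),
                      section_index = integer()))
  }
  H <- nrow(labels); W <- ncol(labels)
  g <- labels[idx]
  y <- (idx - 1L) %% H + 1L
  x <- (idx - 1L) %/% H + 1L
  n <- max(g)
  area <- tabulate(g, n)
  cx <- rowsum(x, g)[, 1L] / area
  cy <- rowsum(y, g)[, 1L] / area
  dx <- x - cx[g]; dy <- y - cy[g]
  mu20 <- rowsum(dx * dx, g)[, 1L] / area
  mu02 <- rowsum(dy * dy, g)[, 1L] / area
  mu11 <- rowsum(dx * dy, g)[, 1L] / area
  common <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + common
  l2 <- (mu20 + mu02) / 2 - common
  ecc <- ifelse(l1 <= .Machine$double.eps, 0, sqrt(pmax(0, 1 - l2 / l1)))
  border <- rowsum((x == 1L | x == W | y == 1L | y == H) * 1L, g)[, 1L] > 0
  data.frame(label = seq_len(n), area_px = area, eccentricity = ecc,
             centroid_x = cx, centroid_y = cy, border = border,
             section_index = as.integer(section_index))
}

coerce_mask_array <- function(masks) {
  if (is.list(masks)) {
    stopifnot(length(masks) >= 1L)
    d <- dim(masks[[1L]])
    stopifnot(all(vapply(masks, function(m) identical(dim(m), d), logical(1))))
    arr <- array(FALSE, c(d, length(masks)))
    for (s in seq_along(masks)) arr[, , s] <- masks[[s]] > 0
    arr
  } else if (is.array(masks) && length(dim(masks)) == 3L) {
    masks > 0
  } else if (is.matrix(masks)) {
    array(masks > 0, c(dim(masks), 1L))
  } else stop("masks must be a matrix, a 3-d array, or a list of matrices")
}

#' Per-section cell-coverage profile
#'
#' Coverage of one optical section is the fraction of its pixels classified
#' as cell-covered. QC-excluded sections carry `NA`, not zero, so they are
#' skipped (never counted as empty) by downstream averaging and statistics.
#'
#' @param masks per-section binary masks: logical `[y, x, section]` array or
#'   list of matrices (section 0 first).
#' @param z_step axial spacing, um.
#' @param qc optional [section_qc()] table.
#' @param replicate_id,condition,timepoint labels carried into the output.
#' @return data frame of class `coverage_profile`: `replicate_id`,
#'   `condition`, `timepoint`, `section`, `height_um`, `coverage`,
#'   `excluded`.
#' @export
coverage_profile <- function(masks, z_step, qc = NULL, replicate_id = "r1",
                             condition = NA_character_,
                             timepoint = NA_character_) {
  arr <- coerce_mask_array(masks)
  S <- dim(arr)[3L]
  cov <- apply(arr, 3L, mean)
  excl <- (seq_len(S) - 1L) %in% excluded_sections(qc)
  cov[excl] <- NA_real_
  out <- data.frame(replicate_id = replicate_id, condition = condition,
                    timepoint = timepoint, section = seq_len(S) - 1L,
                    height_um = (seq_len(S) - 1L) * z_step,
                    coverage = cov, excluded = excl,
                    stringsAsFactors = FALSE)
  class(out) <- c("coverage_profile", class(out))
  out
}

#' Per-section contiguous-object counts
#'
#' @inheritParams coverage_profile
#' @param connectivity 4 or 8.
#' @return data frame with `section` and `n_objects` (`NA` for excluded
#'   sections).
#' @export
object_count_profile <- function(masks, connectivity = 8L, qc = NULL) {
  arr <- coerce_mask_array(masks)
  S <- dim(arr)[3L]
  excl <- (seq_len(S) - 1L) %in% excluded_sections(qc)
  n <- vapply(seq_len(S), function(s) {
    if (excl[s]) return(NA_integer_)
    max(label_regions(arr[, , s], connectivity))
  }, integer(1))
  data.frame(section = seq_len(S) - 1L, n_objects = n)
}

#' Region features for every section of a mask stack
#'
#' @inheritParams object_count_profile
#' @return row-bound [region_features()] tables, one per non-excluded
#'   section.
#' @export
region_features_stack <- function(masks, connectivity = 8L, qc = NULL) {
  arr <- coerce_mask_array(masks)
  S <- dim(arr)[3L]
  excl <- (seq_len(S) - 1L) %in% excluded_sections(qc)
  out <- lapply(seq_len(S), function(s) {
    if (excl[s]) return(NULL)
    region_features(label_regions(arr[, , s], connectivity),
                    section_index = s - 1L)
  })
  do.call(rbind, out)
}

#' Per-section eccentricity profile
#'
#' The paper-style geometric profile: one aggregate eccentricity per optical
#' section over all objects in it. Both mean and median are available since
#' the aggregation statistic is a free choice; mean is the default.
#'
#' @inheritParams object_count_profile
#' @param stat `"mean"` or `"median"`.
#' @return data frame with `section`, `n_objects`, `eccentricity`.
#' @export
eccentricity_profile <- function(masks, connectivity = 8L, qc = NULL,
                                 stat = c("mean", "median")) {
  stat <- match.arg(stat)
  f <- region_features_stack(masks, connectivity, qc)
  arr <- coerce_mask_array(masks)
  S <- dim(arr)[3L]
  agg <- function(s) {
    e <- f$eccentricity[f$section_index == s]
    if (!length(e)) return(c(0L, NA_real_))
    c(length(e), if (stat == "mean") mean(e) else median(e))
  }
  res <- vapply(seq_len(S) - 1L, agg, numeric(2))
  data.frame(section = seq_len(S) - 1L, n_objects = as.integer(res[1L, ]),
             eccentricity = res[2L, ])
}

#' Cross-replicate coverage averages, flagged full vs partial
#'
#' For each condition, timepoint and section, the mean coverage over
#' replicates. A section's average is `"full"` when every replicate
#' contributes a non-missing value there and `"partial"` otherwise (uneven
#' cell scattering or QC exclusions can blank a section in only some
#' replicates); the two kinds are emitted together but flagged distinctly.
#'
#' @param profiles a row-bound set of [coverage_profile()] tables.
#' @return data frame with `condition`, `timepoint`, `section`, `height_um`,
#'   `mean_coverage`, `n_replicates`, `n_used`, `average_type`.
#' @export
aggregate_profiles <- function(profiles) {
  stopifnot(is.data.frame(profiles))
  key <- interaction(profiles$condition, profiles$timepoint,
                     profiles$section, drop = TRUE)
  rows <- lapply(split(profiles, key), function(d) {
    ok <- !is.na(d$coverage)
    data.frame(condition = d$condition[1L], timepoint = d$timepoint[1L],
               section = d$section[1L], height_um = d$height_um[1L],
               mean_coverage = if (any(ok)) mean(d$coverage[ok]) else NA_real_,
               n_replicates = nrow(d), n_used = sum(ok),
               average_type = if (all(ok)) "full" else "partial",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$condition, out$timepoint, out$section), ]
  rownames(out) <- NULL
  out
}
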