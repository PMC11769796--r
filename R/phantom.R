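#' Specify a synthetic domed-monolayer phantom
#'
#' The phantom emulates what the real co-culture stacks look like after 1-3
#' weeks of differentiation: a near-confluent epithelial monolayer occupying
#' the first ~14 um above the membrane, carrying spherical-cap domes, imaged
#' as a mucus/WGA channel (moderate signal through the cell body, bright
#' shell at the top surface) plus a nuclei channel of scattered Gaussian
#' blobs, with additive Gaussian noise. Every geometric quantity has a
#' closed form, so segmentation and dome detection can be validated against
#' exact ground truth.
#'
#' @param width,height canvas size in pixels.
#' @param n_sections number of optical sections.
#' @param z_step axial spacing, um.
#' @param pixel_size lateral pixel size, um.
#' @param base_coverage fraction of the canvas covered by the monolayer,
#'   in `[0, 1]`.
#' @param monolayer_height_um thickness of the flat monolayer, um. Sections
#'   at height `< monolayer_height_um` carry the base mask.
#' @param domes data frame with columns `x`, `y` (center, pixels), `radius_px`
#'   and `cap_height_um`; `NULL` for no domes. Domes rise as spherical caps
#'   from the monolayer top.
#' @param nuclei_density expected nucleus count per 100 x 100 px of canvas.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (intensity units; channels are generated on a 0-1 scale).
#' @param coverage_scale_px correlation length of the random monolayer
#'   pattern (Gaussian smoothing sigma of the underlying random field, px).
#'   Sets the size of cell islands and of the gaps between them.
#' @param seed integer seed; identical specs give bit-identical phantoms.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(width = 512, height = 512, n_sections = 28,
                         z_step = 2, pixel_size = 1, base_coverage = 0.8,
                         monolayer_height_um = 14, domes = NULL,
                         nuclei_density = 8, noise_sd = 0.05,
                         coverage_scale_px = 16, seed = 1L) {
  stopifnot(is_count(width), width > 0, is_count(height), height > 0,
            is_count(n_sections), n_sections >= 1,
            is_scalar_num(z_step), z_step > 0,
            is_scalar_num(pixel_size), pixel_size > 0,
            is_scalar_num(base_coverage), base_coverage >= 0,
            base_coverage <= 1,
            is_scalar_num(monolayer_height_um), monolayer_height_um > 0,
            is_scalar_num(nuclei_density), nuclei_density >= 0,
            is_scalar_num(noise_sd), noise_sd >= 0,
            is_scalar_num(coverage_scale_px), coverage_scale_px > 0,
            is_count(abs(seed)))
  if (!is.null(domes)) {
    domes <- as.data.frame(domes)
    stopifnot(all(c("x", "y", "radius_px", "cap_height_um") %in%
                    names(domes)))
    if (nrow(domes)) {
      if (any(domes$radius_px <= 0) || any(domes$cap_height_um <= 0))
        stop("dome radius and cap height must be positive")
      if (any(domes$cap_height_um > n_sections * z_step))
        stop("dome cap_height exceeds stack depth")
      inside <- domes$x - domes$radius_px >= 1 &
        domes$x + domes$radius_px <= width &
        domes$y - domes$radius_px >= 1 &
        domes$y + domes$radius_px <= height
      if (!all(inside)) stop("domes overlap the image border")
    }
  } else {
    domes <- data.frame(x = numeric(), y = numeric(),
                        radius_px = numeric(), cap_height_um = numeric())
  }
  structure(
    list(width = as.integer(width), height = as.integer(height),
         n_sections = as.integer(n_sections), z_step = z_step,
         pixel_size = pixel_size, base_coverage = base_coverage,
         monolayer_height_um = monolayer_height_um, domes = domes,
         nuclei_density = nuclei_density, noise_sd = noise_sd,
         coverage_scale_px = coverage_scale_px, seed = as.integer(seed)),
    class = "phantom_spec")
}

#' Place random non-overlapping domes
#'
#' Rejection-samples dome centers so that footprints stay inside the canvas
#' and are separated by at least `min_gap_px` edge to edge.
#'
#' @param spec a [phantom_spec()] (geometry source; its `domes` are ignored).
#' @param n number of domes.
#' @param radius_px range (min, max) of footprint radii, px.
#' @param cap_height_um range of cap heights, um.
#' @param min_gap_px minimum edge-to-edge separation, px.
#' @param seed integer seed.
#' @return data frame suitable as the `domes` argument of [phantom_spec()].
#' @export
random_domes <- function(spec, n, radius_px = c(30, 50),
                         cap_height_um = c(8, 16), min_gap_px = 40,
                         seed = 1L) {
  withr::with_seed(seed, {
    out <- data.frame(x = numeric(), y = numeric(), radius_px = numeric(),
                      cap_height_um = numeric())
    tries <- 0L
    while (nrow(out) < n && tries < 20000L) {
      tries <- tries + 1L
      r <- runif(1, radius_px[1], radius_px[2])
      x <- runif(1, r + 2, spec$width - r - 2)
      y <- runif(1, r + 2, spec$height - r - 2)
      if (nrow(out)) {
        d <- sqrt((out$x - x)^2 + (out$y - y)^2)
        if (any(d < out$radius_px + r + min_gap_px)) next
      }
      out <- rbind(out, data.frame(
        x = x, y = y, radius_px = r,
        cap_height_um = runif(1, cap_height_um[1], cap_height_um[2])))
    }
    if (nrow(out) < n) stop("could not place ", n, " non-overlapping domes")
    out
  })
}

# radius of a spherical-cap cross-section at height h above the monolayer top
cap_radius <- function(radius_px, cap_height_um, h_um) {
  ifelse(h_um >= cap_height_um, 0,
         radius_px * sqrt(pmax(0, 1 - (h_um / cap_height_um)^2)))
}

# logical disk mask on a height x width canvas (pixel centers at integers)
disk_mask <- function(height, width, cx, cy, r) {
  if (r <= 0) return(matrix(FALSE, height, width))
  dx2 <- (seq_len(width) - cx)^2
  dy2 <- (seq_len(height) - cy)^2
  outer(dy2, dx2, `+`) <= r^2
}

# union of all dome cross-sections at height h above the monolayer top
dome_section_mask <- function(spec, h_um) {
  m <- matrix(FALSE, spec$height, spec$width)
  d <- spec$domes
  for (k in seq_len(nrow(d))) {
    r <- cap_radius(d$radius_px[k], d$cap_height_um[k], h_um)
    if (r > 0) m <- m | disk_mask(spec$height, spec$width, d$x[k], d$y[k], r)
  }
  m
}

# monolayer footprint: exactly round(base_coverage * area) pixels, always
# including the dome footprints, remainder drawn from a smoothed random
# field so islands/gaps have the configured correlation length
base_mask_for <- function(spec) {
  n_px <- spec$height * spec$width
  target <- round(spec$base_coverage * n_px)
  dm <- dome_section_mask(spec, 0)
  if (sum(dm) >= target) return(dm)
  if (spec$base_coverage >= 1) return(matrix(TRUE, spec$height, spec$width))
  field <- matrix(rnorm(n_px), spec$height, spec$width)
  # kernel radius capped so tiny canvases remain valid
  rad <- min(2L * ceiling(3 * spec$coverage_scale_px) + 1L,
             min(dim(field)) %/% 2L * 2L - 1L)
  field <- as_plain(EBImage::gblur(field, sigma = spec$coverage_scale_px,
                                   radius = rad))
  field[dm] <- -Inf                      # dome pixels are chosen separately
  need <- target - sum(dm)
  thr <- sort(field[!dm], decreasing = TRUE)[need]
  out <- dm | (field >= thr & !dm)
  # exact count even under float ties
  if (sum(out) != target) {
    extra <- which(!out & field == thr)
    out[extra[seq_len(min(length(extra), target - sum(out)))]] <- TRUE
  }
  out
}

#' Generate a synthetic two-channel z-stack with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `stack` (a [zstack()] with channels
#'   `mucus`, `nuclei`) and `truth`, a list holding `masks` (logical
#'   `[y, x, section]` array of cell-covered pixels), `coverage_by_section`,
#'   `dome_count`, `per_dome` (area px, max height um, eccentricity) and
#'   `top_index` (0-based highest covered section per pixel, -1 where bare).
#' @details
#' Intensity model (0-1 scale before noise): background 0; mucus channel
#' 0.4 through the cell body and 1.0 in a one-section shell at the local top
#' surface, mirroring WGA labelling of cellular presence plus the bright
#' apical mucus layer; nuclei are isotropic Gaussian blobs (sigma 3 px,
#' amplitude 1) at random positions inside the cell body. Additive Gaussian
#' noise with `noise_sd` is clipped at zero.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  H <- spec$height; W <- spec$width; S <- spec$n_sections
  base <- base_mask_for(spec)
  masks <- array(FALSE, c(H, W, S))
  heights <- (seq_len(S) - 1L) * spec$z_step
  for (s in seq_len(S)) {
    h <- heights[s]
    if (h < spec$monolayer_height_um) {
      masks[, , s] <- base
    } else {
      masks[, , s] <- dome_section_mask(spec, h - spec$monolayer_height_um)
    }
  }
  # 0-based index of the highest covered section per pixel (-1 if none)
  top <- matrix(-1L, H, W)
  for (s in seq_len(S)) top[masks[, , s]] <- s - 1L

  mucus <- array(0, c(H, W, S))
  for (s in seq_len(S)) {
    body <- masks[, , s]
    plane <- ifelse(body, 0.4, 0)
    shell <- body & (top == s - 1L)
    plane[shell] <- 1
    mucus[, , s] <- plane
  }

  nuclei <- array(0, c(H, W, S))
  n_nuc <- round(spec$nuclei_density * H * W / 1e4)
  covered <- which(base)
  if (n_nuc > 0 && length(covered) > 0) {
    centers <- sample(covered, n_nuc, replace = TRUE)
    cy <- (centers - 1L) %% H + 1L
    cx <- (centers - 1L) %/% H + 1L
    sig <- 3
    half <- 9L  # 3 sigma support
    kern <- outer(exp(-(( -half:half)^2) / (2 * sig^2)),
                  exp(-(( -half:half)^2) / (2 * sig^2)))
    for (k in seq_len(n_nuc)) {
      zi <- sample.int(top[cy[k], cx[k]] + 1L, 1L)  # within the cell body
      ys <- max(1L, cy[k] - half):min(H, cy[k] + half)
      xs <- max(1L, cx[k] - half):min(W, cx[k] + half)
      nuclei[ys, xs, zi] <- pmin(1, nuclei[ys, xs, zi] +
        kern[ys - cy[k] + half + 1L, xs - cx[k] + half + 1L])
    }
  }

  if (spec$noise_sd > 0) {
    mucus <- pmax(0, mucus + rnorm(length(mucus), sd = spec$noise_sd))
    nuclei <- pmax(0, nuclei + rnorm(length(nuclei), sd = spec$noise_sd))
  }

  data <- array(0, c(H, W, S, 2L))
  data[, , , 1L] <- mucus
  data[, , , 2L] <- nuclei

  per_dome <- spec$domes
  if (nrow(per_dome)) {
    per_dome$area_px <- vapply(seq_len(nrow(per_dome)), function(k)
      sum(disk_mask(H, W, per_dome$x[k], per_dome$y[k],
                    per_dome$radius_px[k])), numeric(1))
    per_dome$max_height_um <- per_dome$cap_height_um
    per_dome$eccentricity <- 0
  } else {
    per_dome$area_px <- numeric()
    per_dome$max_height_um <- numeric()
    per_dome$eccentricity <- numeric()
  }

  truth <- list(
    masks = masks,
    coverage_by_section = apply(masks, 3L, mean),
    dome_count = nrow(per_dome),
    per_dome = per_dome,
    top_index = top)

  list(stack = zstack(data, z_step = spec$z_step,
                      pixel_size = spec$pixel_size,
                      channel_names = c("mucus", "nuclei")),
       truth = truth)
}

#' Analytic per-section coverage of a phantom
#'
#' Closed form, no rasterization: sections below the monolayer top have
#' coverage `base_coverage`; above it each dome contributes a disk of radius
#' `r * sqrt(1 - (h / cap_height)^2)` (spherical cap), so coverage is the sum
#' of `pi r(h)^2` over domes divided by the canvas area. Assumes disjoint
#' domes (as produced by [random_domes()]).
#'
#' @param spec a [phantom_spec()].
#' @return numeric vector of per-section coverage fractions.
#' @export
ground_truth_coverage <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_px <- spec$height * spec$width
  heights <- (seq_len(spec$n_sections) - 1L) * spec$z_step
  vapply(heights, function(h) {
    if (h < spec$monolayer_height_um) {
      spec$base_coverage  # dome footprints are part of the base mask
    } else {
      r <- cap_radius(spec$domes$radius_px, spec$domes$cap_height_um,
                      h - spec$monolayer_height_um)
      sum(pi * r^2) / n_px
    }
  }, numeric(1))
}
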