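#' Construct a calibrated multichannel z-stack
#'
#' A `zstack` holds a two-(or more-)channel confocal volume together with its
#' physical calibration. Sections are ordered bottom to top, starting at the
#' Transwell membrane: section index `i` (0-based) sits at height
#' `i * z_step` micrometres.
#'
#' @param data numeric array indexed `[y, x, section, channel]`. A matrix is
#'   promoted to a single-section, single-channel stack.
#' @param z_step axial spacing between optical sections, micrometres.
#' @param pixel_size lateral pixel size, micrometres.
#' @param channel_names character vector of channel labels, e.g.
#'   `c("mucus", "nuclei")`.
#' @return An object of class `zstack` with fields `data`, `z_step`,
#'   `pixel_size`, `channel_names`.
#' @examples
#' zs <- zstack(array(0, c(8, 8, 3, 2)), z_step = 2, pixel_size = 0.5,
#'              channel_names = c("mucus", "nuclei"))
#' section_heights(zs)
#' @export
zstack <- function(data, z_step, pixel_size = 1,
                   channel_names = NULL) {
  if (is.matrix(data)) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L)
  if (!is_scalar_num(z_step) || z_step <= 0) stop("z_step must be > 0")
  if (!is_scalar_num(pixel_size) || pixel_size <= 0)
    stop("pixel_size must be > 0")
  nch <- dim(data)[4L]
  channel_names <- channel_names %||% paste0("ch", seq_len(nch))
  if (length(channel_names) != nch)
    stop("channel_names length must equal the number of channels")
  if (any(!is.finite(data)) || any(data < 0))
    stop("intensities must be finite and non-negative")
  structure(
    list(data = data, z_step = z_step, pixel_size = pixel_size,
         channel_names = channel_names),
    class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<zstack> %d x %d px, %d sections (z step %g um, 0-%g um), channels: %s\n",
    d[2L], d[1L], d[3L], x$z_step, (d[3L] - 1L) * x$z_step,
    paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' @rdname zstack
#' @export
n_sections <- function(data) {
  stopifnot(inherits(data, "zstack"))
  dim(data$data)[3L]
}

#' Heights of the optical sections
#'
#' @param data a [zstack()].
#' @return numeric vector; the 0-based section `i` lies at `i * z_step` um.
#' @export
section_heights <- function(data) {
  stopifnot(inherits(data, "zstack"))
  (seq_len(dim(data$data)[3L]) - 1L) * data$z_step
}

#' Extract one channel of one section as a matrix
#'
#' @param zs a [zstack()].
#' @param section 0-based section index.
#' @param channel channel name or 1-based index.
#' @export
get_section <- function(zs, section, channel = 1L) {
  stopifnot(inherits(zs, "zstack"))
  if (is.character(channel))
    channel <- match(channel, zs$channel_names)
  s <- as.integer(section) + 1L
  stopifnot(s >= 1L, s <= dim(zs$data)[3L], !is.na(channel))
  zs$data[, , s, channel]
}

sidecar_path <- function(path) paste0(path, ".json")

# Pull z/xy calibration out of a TIFF ImageDescription tag. Understands
# OME-XML (PhysicalSizeZ/PhysicalSizeX) and ImageJ-style "spacing=" text.
parse_tiff_calibration <- function(desc) {
  out <- list(z_step = NULL, pixel_size = NULL)
  if (is.null(desc) || !nzchar(desc)) return(out)
  if (grepl("<OME", desc, fixed = TRUE) &&
      requireNamespace("xml2", quietly = TRUE)) {
    doc <- tryCatch(suppressWarnings(xml2::read_xml(desc)),
                    error = function(e) NULL)
    if (!is.null(doc)) {
      px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
      if (!inherits(px, "xml_missing")) {
        z <- xml2::xml_attr(px, "PhysicalSizeZ")
        x <- xml2::xml_attr(px, "PhysicalSizeX")
        if (!is.na(z)) out$z_step <- as.numeric(z)
        if (!is.na(x)) out$pixel_size <- as.numeric(x)
      }
    }
  } else if (grepl("spacing=", desc, fixed = TRUE)) {
    m <- regmatches(desc, regexpr("spacing=[0-9.eE+-]+", desc))
    if (length(m)) out$z_step <- as.numeric(sub("spacing=", "", m))
  }
  out
}

#' Read a multichannel z-stack from a (OME-)TIFF file
#'
#' Planes are expected channel-interleaved within each section (section-major
#' order, as written by [write_stack()]). Calibration is resolved in this
#' priority order: explicit arguments (user config), a JSON sidecar
#' (`<path>.json`, written by [write_stack()]), then the TIFF
#' ImageDescription tag (OME-XML or ImageJ `spacing=`). When an explicit
#' argument disagrees with file metadata the argument wins, with a warning:
#' microscope exports are inconsistent and user intent is explicit.
#'
#' @param path TIFF / OME-TIFF file.
#' @param channel_map named integer vector mapping channel label to 1-based
#'   channel index within a section, e.g. `c(mucus = 1, nuclei = 2)`. If
#'   `NULL`, channel names come from the sidecar, else a single channel is
#'   assumed.
#' @param z_step,pixel_size calibration overrides in micrometres.
#' @return a [zstack()]; sections ordered bottom (membrane) to top.
#' @export
read_stack <- function(path, channel_map = NULL, z_step = NULL,
                       pixel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.null(z_step) && (!is_scalar_num(z_step) || z_step <= 0))
    stop("non-positive calibration: z_step")
  if (!is.null(pixel_size) &&
      (!is_scalar_num(pixel_size) || pixel_size <= 0))
    stop("non-positive calibration: pixel_size")
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  n_planes <- length(pages)
  stopifnot(n_planes >= 1L)

  meta <- list()
  sc <- sidecar_path(path)
  if (file.exists(sc))
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  tagcal <- parse_tiff_calibration(attr(pages[[1L]], "description"))

  if (!is.null(channel_map)) {
    ch_names <- names(channel_map)
    ch_idx <- as.integer(channel_map)
    if (is.null(ch_names) || any(!nzchar(ch_names)))
      stop("channel_map must be a named vector")
  } else if (!is.null(meta$channel_names)) {
    ch_names <- meta$channel_names
    ch_idx <- seq_along(ch_names)
  } else {
    ch_names <- "ch1"
    ch_idx <- 1L
  }
  n_ch <- max(ch_idx)
  if (n_planes %% n_ch != 0L)
    stop("plane count (", n_planes, ") not divisible by channel count (",
         n_ch, ")")
  n_sec <- n_planes %/% n_ch

  resolve <- function(user, side, tag, what) {
    fileval <- side %||% tag
    if (!is.null(user)) {
      if (!is.null(fileval) && abs(user - fileval) > 1e-9)
        warning(sprintf("%s: config value %g overrides file metadata %g",
                        what, user, fileval))
      return(user)
    }
    fileval
  }
  z <- as.numeric(resolve(z_step, meta$z_step, tagcal$z_step, "z_step"))
  px <- resolve(pixel_size, meta$pixel_size, tagcal$pixel_size, "pixel_size")
  if (length(px)) px <- as.numeric(px)
  if (!length(z)) z <- NULL
  if (!length(px)) px <- NULL
  if (is.null(z)) stop("z_step not found in metadata; pass z_step explicitly")
  if (is.null(px)) {
    warning("pixel_size not found in metadata; assuming 1 um")
    px <- 1
  }
  if (!is_scalar_num(z) || z <= 0 || !is_scalar_num(px) || px <= 0)
    stop("non-positive calibration")

  first <- pages[[1L]]
  if (length(dim(first)) == 3L) first <- first[, , 1L]  # drop RGB-style planes
  dimyx <- dim(first)
  arr <- array(0, c(dimyx, n_sec, length(ch_idx)))
  for (s in seq_len(n_sec)) {
    for (k in seq_along(ch_idx)) {
      p <- pages[[(s - 1L) * n_ch + ch_idx[k]]]
      if (length(dim(p)) == 3L) p <- p[, , 1L]
      arr[, , s, k] <- p
    }
  }
  arr <- arr * (meta$intensity_scale %||% 1)
  zstack(arr, z_step = z, pixel_size = px, channel_names = ch_names)
}

#' Write a z-stack to multi-page float TIFF (+ JSON calibration sidecar)
#'
#' Planes are written in section-major, channel-interleaved order as 32-bit
#' float. Because TIFF float storage is defined for the `[0, 1]` range,
#' stacks with intensities above 1 are scaled down on write and the scale
#' factor recorded in the sidecar; [read_stack()] undoes it, so voxel
#' values round-trip to 32-bit float precision. Calibration and channel
#' names go to `<path>.json`.
#'
#' @param zs a [zstack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(zs, path) {
  stopifnot(inherits(zs, "zstack"))
  d <- dim(zs$data)
  intensity_scale <- max(1, max(zs$data))
  planes <- vector("list", d[3L] * d[4L])
  k <- 0L
  for (s in seq_len(d[3L])) for (ch in seq_len(d[4L])) {
    k <- k + 1L
    planes[[k]] <- zs$data[, , s, ch] / intensity_scale
  }
  tiff::writeTIFF(planes, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(z_step = zs$z_step, pixel_size = zs$pixel_size,
         channel_names = zs$channel_names,
         n_sections = d[3L], n_channels = d[4L],
         intensity_scale = intensity_scale),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write feature / coverage / statistics records to CSV
#'
#' One row per record, header included, numeric columns at full double
#' precision (17 significant digits) so values survive a round trip.
#'
#' @param records a non-empty data frame.
#' @param path output CSV path.
#' @export
write_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data frame")
  out <- records
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA
      out[[j]] <- v
    }
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Section quality-control table
#'
#' Records which optical sections are excluded from downstream profiles and
#' why (e.g. glass-slide grid artifacts). Every excluded section must carry a
#' non-empty reason.
#'
#' @param section_index 0-based integer indices.
#' @param excluded logical vector.
#' @param reason character vector.
#' @return data frame of class `section_qc`.
#' @export
section_qc <- function(section_index = integer(), excluded = logical(),
                       reason = character()) {
  df <- data.frame(section_index = as.integer(section_index),
                   excluded = as.logical(excluded),
                   reason = as.character(reason),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$section_index)) stop("duplicate section indices")
  if (any(df$excluded & !nzchar(df$reason)))
    stop("excluded sections must carry a reason")
  class(df) <- c("section_qc", class(df))
  df
}

excluded_sections <- function(qc) {
  if (is.null(qc) || nrow(qc) == 0L) return(integer())
  qc$section_index[qc$excluded]
}
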