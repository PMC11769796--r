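#' Assemble and validate a pipeline run configuration
#'
#' @param inputs list of input descriptors, one per replicate stack. Each
#'   element is a list with `replicate_id`, `condition`, `timepoint`, and
#'   either `path` (a TIFF readable by [read_stack()], plus optional
#'   `channel_map`, `z_step`, `pixel_size`) or `phantom` (a
#'   [phantom_spec()], generated at run time).
#' @param segmentation a [segmentation_config()].
#' @param dome list of dome-detection settings: `grid_size` (height-map
#'   resampling, skipped when the map is already smaller),
#'   `min_prominence_um`, `min_area_px`, `baseline_radius_px`.
#' @param qc list: `line_contrast` for [flag_artifact_sections()] and
#'   `manual_exclude` (0-based sections dropped in every replicate).
#' @param stats list: `partial` passed to [per_section_comparison()].
#' @param seed integer master seed for the run.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(inputs,
                       segmentation = segmentation_config(),
                       dome = list(),
                       qc = list(),
                       stats = list(),
                       seed = 1L) {
  dome <- utils::modifyList(
    list(grid_size = 128L, min_prominence_um = 4, min_area_px = 25L,
         baseline_radius_px = 25L, close_radius_px = 8L), dome)
  qc <- utils::modifyList(
    list(line_contrast = 0.1, manual_exclude = integer()), qc)
  stats <- utils::modifyList(list(partial = "skip"), stats)
  cfg <- structure(list(inputs = inputs, segmentation = segmentation,
                        dome = dome, qc = qc, stats = stats,
                        seed = as.integer(seed)),
                   class = "run_config")
  validate_run_config(cfg)
  cfg
}

#' @rdname run_config
#' @param config object to validate.
#' @export
validate_run_config <- function(config) {
  if (!inherits(config, "run_config")) stop("not a run_config")
  if (!inherits(config$segmentation, "segmentation_config"))
    stop("config$segmentation must be a segmentation_config")
  if (!length(config$inputs)) stop("config lists no inputs")
  for (inp in config$inputs) {
    if (is.null(inp$replicate_id)) stop("input without replicate_id")
    has_path <- !is.null(inp$path)
    has_phantom <- !is.null(inp$phantom)
    if (has_path == has_phantom)
      stop("each input needs exactly one of 'path' or 'phantom'")
    if (has_phantom && !inherits(inp$phantom, "phantom_spec"))
      stop("input 'phantom' must be a phantom_spec")
  }
  d <- config$dome
  stopifnot(is_count(d$grid_size), d$grid_size >= 8,
            is_scalar_num(d$min_prominence_um), d$min_prominence_um > 0,
            is_count(d$min_area_px),
            is_count(d$baseline_radius_px),
            is_count(d$close_radius_px))
  if (!config$stats$partial %in% c("skip", "allow"))
    stop("stats$partial must be 'skip' or 'allow'")
  invisible(config)
}

#' Build a run configuration from a JSON file
#'
#' Schema mirrors [run_config()]; `segmentation` keys are passed to
#' [segmentation_config()] and `phantom` entries to [phantom_spec()], so
#' every invariant (odd block size, weights summing to one, domes inside
#' the canvas, ...) is enforced before any computation starts.
#'
#' @param path JSON file.
#' @return a validated `run_config`.
#' @export
run_config_from_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  seg <- do.call(segmentation_config, lapply(j$segmentation %||% list(),
                                             unlist))
  inputs <- lapply(j$inputs, function(inp) {
    if (!is.null(inp$phantom)) {
      ph <- inp$phantom
      if (!is.null(ph$domes))
        ph$domes <- do.call(rbind, lapply(ph$domes, as.data.frame))
      inp$phantom <- do.call(phantom_spec, ph)
    }
    inp
  })
  run_config(inputs = inputs, segmentation = seg,
             dome = lapply(j$dome %||% list(), unlist),
             qc = lapply(j$qc %||% list(), unlist),
             stats = lapply(j$stats %||% list(), unlist),
             seed = j$seed %||% 1L)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass_deep(config), tmp, auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  unname(tools::md5sum(tmp))
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

write_or_header <- function(df, template, path) {
  if (nrow(df) > 0) write_table(df, path)
  else write.csv(template, path, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates stack loading (or phantom generation), section QC,
#' segmentation, coverage / object / eccentricity profiling, height-map
#' reconstruction with dome detection and per-angle-view counts, and (when
#' two conditions are present with >= 2 replicates each) per-section
#' Mann-Whitney comparisons. Results are written as CSV plus a JSON run
#' manifest; a failure in any stage aborts with a stage-named diagnostic
#' and removes partial outputs. Given identical inputs, configuration and
#' seed, reruns are byte-identical.
#'
#' @param config a [run_config()] (or a JSON path accepted by
#'   [run_config_from_json()]).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the result tables (`coverage`, `objects`,
#'   `domes`, `stats`, `per_view`) and the manifest.
#' @export
analyze <- function(config, out_dir) {
  if (is.character(config)) config <- run_config_from_json(config)
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("coverage.csv", "objects.csv", "domes.csv",
                                "stats.csv", "manifest.json"))
  stage <- "setup"
  res <- tryCatch(
    withr::with_seed(config$seed, {
      coverage <- list(); objects <- list(); domes <- list()
      per_view <- list(); exclusions <- list()
      for (inp in config$inputs) {
        rid <- inp$replicate_id
        stage <- paste0("load[", rid, "]")
        zs <- if (!is.null(inp$path)) {
          read_stack(inp$path, channel_map = inp$channel_map,
                     z_step = inp$z_step, pixel_size = inp$pixel_size)
        } else {
          generate_phantom(inp$phantom)$stack
        }
        stage <- paste0("qc[", rid, "]")
        qc <- flag_artifact_sections(
          zs, line_contrast = config$qc$line_contrast,
          channel_weights = config$segmentation$channel_weights,
          clip_percentiles = config$segmentation$clip_percentiles,
          manual_exclude = config$qc$manual_exclude)
        exclusions[[rid]] <- qc[qc$excluded, , drop = FALSE]
        stage <- paste0("segment[", rid, "]")
        masks <- segment_stack(zs, config$segmentation)
        stage <- paste0("morpho[", rid, "]")
        cov <- coverage_profile(masks, zs$z_step, qc = qc,
                                replicate_id = rid,
                                condition = inp$condition %||% NA_character_,
                                timepoint = inp$timepoint %||% NA_character_)
        coverage[[rid]] <- cov
        ft <- region_features_stack(masks, config$segmentation$connectivity,
                                    qc = qc)
        if (!is.null(ft) && nrow(ft)) {
          ft$replicate_id <- rid
          objects[[rid]] <- ft
        }
        stage <- paste0("dome3d[", rid, "]")
        hm <- height_map(masks, zs$z_step, qc = qc)
        if (config$dome$grid_size <= min(dim(hm$heights)))
          hm <- resample_grid(hm, config$dome$grid_size)
        dr <- detect_domes(hm,
                           min_prominence_um = config$dome$min_prominence_um,
                           min_area_px = config$dome$min_area_px,
                           baseline_radius_px =
                             config$dome$baseline_radius_px,
                           close_radius_px = config$dome$close_radius_px,
                           connectivity = config$segmentation$connectivity)
        vw <- count_per_angle_view(hm, dr)
        per_view[[rid]] <- vw$per_view
        if (nrow(vw$domes)) {
          d <- vw$domes
          d$replicate_id <- rid
          d$condition <- inp$condition %||% NA_character_
          d$timepoint <- inp$timepoint %||% NA_character_
          domes[[rid]] <- as.data.frame(d)
        }
      }

      stage <- "stats"
      cov_all <- do.call(rbind, coverage)
      stat_rows <- list()
      conds <- unique(cov_all$condition)
      if (length(conds) == 2L) {
        for (tp in unique(cov_all$timepoint)) {
          sub <- cov_all[cov_all$timepoint %in% tp, ]
          pa <- sub[sub$condition == conds[1L], ]
          pb <- sub[sub$condition == conds[2L], ]
          if (length(unique(pa$replicate_id)) >= 2L &&
              length(unique(pb$replicate_id)) >= 2L) {
            cmp <- per_section_comparison(pa, pb,
                                          partial = config$stats$partial)
            cmp$comparison <- paste(conds[1L], "vs", conds[2L])
            cmp$timepoint <- tp
            stat_rows[[as.character(tp)]] <- as.data.frame(cmp)
          }
        }
      }
      stats_all <- if (length(stat_rows)) do.call(rbind, stat_rows) else
        data.frame(level = character(), section = integer(), U = numeric(),
                   n1 = integer(), n2 = integer(), p = numeric(),
                   p_holm = numeric(), method = character(),
                   comparison = character(), timepoint = character())

      stage <- "write"
      write_table(cov_all, paths[1L])
      obj_all <- if (length(objects)) do.call(rbind, objects) else
        data.frame(label = integer(), area_px = numeric(),
                   eccentricity = numeric(), centroid_x = numeric(),
                   centroid_y = numeric(), border = logical(),
                   section_index = integer(), replicate_id = character())
      write_or_header(obj_all, obj_all[0, ], paths[2L])
      dome_all <- if (length(domes)) do.call(rbind, domes) else
        data.frame(dome_id = integer(), area_px = numeric(),
                   max_height_um = numeric(), eccentricity = numeric(),
                   centroid_x = numeric(), centroid_y = numeric(),
                   views_detected = integer(), replicate_id = character(),
                   condition = character(), timepoint = character())
      write_or_header(dome_all, dome_all[0, ], paths[3L])
      write_or_header(stats_all, stats_all[0, ], paths[4L])

      manifest <- list(
        package = "domescope",
        version = as.character(utils::packageVersion("domescope")),
        seed = config$seed,
        config_hash = config_hash(config),
        enhance_gamma = config$segmentation$enhance_gamma,
        n_inputs = length(config$inputs),
        qc_exclusions = lapply(exclusions, function(d)
          if (nrow(d)) d$section_index else integer()),
        outputs = basename(paths[1:4]))
      jsonlite::write_json(manifest, paths[5L], auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
      list(coverage = cov_all, objects = obj_all, domes = dome_all,
           stats = stats_all, per_view = per_view, manifest = manifest)
    }),
    error = function(e) {
      unlink(paths)
      stop("stage ", stage, ": ", conditionMessage(e), call. = FALSE)
    })
  invisible(res)
}

#' Phantom-driven end-to-end self test
#'
#' Builds a two-condition phantom experiment (a high-coverage "dynamic"
#' group against a lower-coverage "static" group, three replicates each,
#' with a few domes) and runs the complete pipeline on it. Useful as a
#' smoke test with no imaging data at hand.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param width,height,n_sections phantom canvas (kept modest by default so
#'   the test is quick).
#' @return the [analyze()] result bundle, invisibly.
#' @export
self_test <- function(out_dir, seed = 1L, width = 256L, height = 256L,
                      n_sections = 28L) {
  base <- phantom_spec(width = width, height = height,
                       n_sections = n_sections, seed = seed)
  mk <- function(cond, coverage, k) {
    sd <- seed + 1000L * k
    phantom_spec(width = width, height = height, n_sections = n_sections,
                 base_coverage = coverage,
                 domes = random_domes(base, 3, radius_px = c(18, 26),
                                      cap_height_um = c(8, 12),
                                      min_gap_px = 30, seed = sd),
                 seed = sd)
  }
  inputs <- c(
    lapply(1:3, function(k) list(
      replicate_id = paste0("dyn", k), condition = "dynamic",
      timepoint = "T2", phantom = mk("dynamic", 0.8, k))),
    lapply(1:3, function(k) list(
      replicate_id = paste0("sta", k), condition = "static",
      timepoint = "T2", phantom = mk("static", 0.5, k + 10L))))
  analyze(run_config(inputs, seed = seed), out_dir)
}
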