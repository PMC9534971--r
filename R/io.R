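#' Registered multi-channel image of one well
#'
#' A thin container for a set of registered single-channel rasters sharing
#' one pixel grid. Channel roles follow the staining panel of the coculture
#' assay: `EC` (VE-cadherin + ERG1 composite), `SMC` (cell tracker), `Fn`
#' (labeled plasma fibronectin), `DAPI`, `Ki67`, `ERG1`. `EC`, `SMC` and
#' `DAPI` are required; the others are optional and their absence is
#' recorded so downstream quantifications can report missing results
#' instead of failing.
#'
#' @param channels named list of numeric matrices with identical dimensions.
#' @param pixel_size_um physical pixel size.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size_um = 4) {
  if (!length(channels) || is.null(names(channels)) || any(names(channels) == "")) {
    stop_wm("`channels` must be a non-empty named list.", "format_error")
  }
  unknown <- setdiff(names(channels), WM_CHANNELS)
  if (length(unknown)) {
    stop_wm(paste0("Unknown channel role(s): ", paste(unknown, collapse = ", ")),
      "format_error")
  }
  dims <- lapply(channels, function(ch) dim(as_mat(ch)))
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop_wm("All channels must share the same dimensions.", "format_error")
  }
  channels <- lapply(channels, as_mat)
  structure(
    list(
      channels = channels,
      pixel_size_um = pixel_size_um,
      missing_channels = setdiff(WM_CHANNELS, names(channels))
    ),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<channel_stack> %d x %d px, %.3g um/px, channels: %s\n",
    d[1], d[2], x$pixel_size_um, paste(names(x$channels), collapse = ", ")
  ))
  if (length(x$missing_channels)) {
    cat("  missing:", paste(x$missing_channels, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read / write a multi-channel well mosaic as TIFF
#'
#' `write_stack()` writes one 16-bit TIFF page per channel plus a YAML
#' sidecar (`<path>.yaml`) recording channel names and pixel size.
#' `read_stack()` accepts either such a multi-page TIFF (channel names from
#' the sidecar or the `channel_names` argument) or a directory containing a
#' `manifest.yaml` with `pixel_size_um` and a `channels:` map of
#' role-to-filename entries. Missing optional channels are tolerated and
#' flagged on the returned stack; mismatched channel dimensions are an
#' error.
#'
#' @param stack a [channel_stack()].
#' @param path file (or directory, for the manifest layout) path.
#' @param channel_names optional character vector naming the TIFF pages.
#' @return `read_stack()` returns a [channel_stack()]; `write_stack()`
#'   returns `path` invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  tiff::writeTIFF(
    lapply(stack$channels, clamp01), path,
    bits.per.sample = 16, compression = "none"
  )
  yaml::write_yaml(
    list(channels = names(stack$channels), pixel_size_um = stack$pixel_size_um),
    paste0(path, ".yaml")
  )
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path, channel_names = NULL) {
  if (dir.exists(path)) {
    mf_path <- file.path(path, "manifest.yaml")
    if (!file.exists(mf_path)) {
      stop_wm("Directory input needs a manifest.yaml.", "format_error")
    }
    mf <- yaml::read_yaml(mf_path)
    channels <- lapply(mf$channels, function(f) {
      read_tiff_page(file.path(path, f))
    })
    names(channels) <- names(mf$channels)
    return(channel_stack(channels, pixel_size_um = mf$pixel_size_um %||% 4))
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE),
    error = function(e) stop_wm(paste0("read_stack: ", conditionMessage(e)), "format_error")
  )
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, collapse_gray)
  sidecar <- paste0(path, ".yaml")
  px <- 4
  if (is.null(channel_names) && file.exists(sidecar)) {
    meta <- yaml::read_yaml(sidecar)
    channel_names <- unlist(meta$channels)
    px <- meta$pixel_size_um %||% 4
  }
  if (is.null(channel_names)) {
    channel_names <- WM_CHANNELS[seq_along(pages)]
  }
  if (length(channel_names) != length(pages)) {
    stop_wm("Number of TIFF pages does not match channel names.", "format_error")
  }
  names(pages) <- channel_names
  missing_req <- setdiff(WM_REQUIRED_CHANNELS, channel_names)
  if (length(missing_req)) {
    stop_wm(paste0("Required channel(s) missing: ", paste(missing_req, collapse = ", ")),
      "format_error")
  }
  channel_stack(pages, pixel_size_um = px)
}

read_tiff_page <- function(f) {
  collapse_gray(tiff::readTIFF(f))
}

collapse_gray <- function(m) {
  if (length(dim(m)) == 3) m <- m[, , 1]
  m
}

#' Write a region label map to disk
#'
#' Writes the integer label codes as an 8-bit grayscale PNG (values
#' `code/255`), and optionally a false-color rendering with the standard
#' palette: gap black, island purple, network green, outside dark gray.
#'
#' @param labels a `region_labelmap` (integer matrix of codes).
#' @param path output PNG path.
#' @param color write the false-color rendering instead of raw codes.
#' @export
write_labelmap <- function(labels, path, color = FALSE) {
  m <- as_mat(labels)
  if (!color) {
    png::writePNG(m / 255, path)
  } else {
    pal <- list(
      gap = c(0, 0, 0), island = c(0.62, 0.12, 0.94),
      network = c(0.0, 0.8, 0.2), outside = c(0.25, 0.25, 0.25)
    )
    nm <- class_name_of(m)
    rgb <- array(0, c(nrow(m), ncol(m), 3))
    for (cls in names(pal)) {
      sel <- nm == cls
      for (k in 1:3) {
        plane <- rgb[, , k]
        plane[sel] <- pal[[cls]][k]
        rgb[, , k] <- plane
      }
    }
    png::writePNG(rgb, path)
  }
  invisible(path)
}

#' @rdname write_labelmap
#' @export
read_labelmap <- function(path) {
  m <- collapse_gray(png::readPNG(path))
  new_labelmap(
    matrix(as.integer(round(m * 255)), nrow(m), ncol(m)),
    provenance = list(source = path)
  )
}

#' Write a nucleus table as CSV
#'
#' Columns: `x_px`, `y_px`, `is_EC`, `is_proliferative` plus any zone/class
#' assignment present. Coordinates are pixel units, top-left origin.
#'
#' @param nuclei nucleus tibble.
#' @param path output CSV path.
#' @export
write_nuclei <- function(nuclei, path) {
  out <- dplyr::rename(nuclei, x_px = "x", y_px = "y", is_EC = "is_ec")
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]: either a
#' simulation config or an input stack path, the segmentation parameters,
#' quantification options, the shear model and the output directory. All
#' randomness is routed through the single `seed`.
#'
#' @param simulate a [scene_config()], or `NULL` to read `input`.
#' @param input path to a stack readable by [read_stack()].
#' @param out_dir output directory (`NULL` for no artifacts on disk).
#' @param seg_params a [segmentation_params()].
#' @param n_bins radial profile bins.
#' @param n_min minimum SMC nuclei per (zone, class) for a percentage.
#' @param n_rois annular-sector ROIs per zone (`NULL` disables ROI output).
#' @param shear a [shear_model()].
#' @param seed integer seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, input = NULL, out_dir = NULL,
                            seg_params = segmentation_params(),
                            n_bins = 30L, n_min = 20L, n_rois = NULL,
                            shear = shear_model(), seed = 1L) {
  if (is.null(simulate) && is.null(input)) {
    stop_wm("Provide either `simulate` or `input`.", "config_error")
  }
  structure(
    list(
      simulate = simulate, input = input, out_dir = out_dir,
      seg_params = seg_params, n_bins = as.integer(n_bins),
      n_min = as.integer(n_min), n_rois = n_rois,
      shear = shear, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full quantification pipeline on one well
#'
#' Executes the whole chain: obtain the stack (simulate or read), fit the
#' well geometry, binarize the EC channel, classify island/network/gap
#' regions, detect nuclei, and compute all region-coupled statistics
#' (coverage fractions, SMC proliferation by region, SMC layering index,
#' radial profiles, alignment order) plus the orbital shear summary. When
#' `out_dir` is set, every table is written as CSV with a metadata header
#' (package version, config hash, seed), the label map as PNG, and the
#' config echo as YAML; identical config + seed gives byte-identical
#' outputs.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `well_report` with elements `geom`, `labels`,
#'   `nuclei`, `coverage`, `proliferation`, `layering`, `profiles`,
#'   `alignment`, `shear`, and (for simulated input) `truth`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_wm(sprintf("[%s] %s", name, conditionMessage(e)), "pipeline_error")
    })
  }

  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_cfg <- config$simulate
    sim_cfg$seed <- config$seed
    scene <- stage("simulate", generate_scene(sim_cfg))
    stack <- scene$stack
    truth <- scene$truth
    geom <- truth$geom
  } else {
    stack <- stage("read_stack", read_stack(config$input))
    geom <- stage("fit_well", fit_well(stack))
  }

  bw <- stage("binarize_ec", binarize_ec(stack$channels$EC, config$seg_params, geom))
  labels <- stage("classify_regions", classify_regions(bw, geom, config$seg_params))
  nuclei <- stage("detect_nuclei", detect_nuclei(
    stack$channels$DAPI, stack$channels$ERG1, stack$channels$Ki67,
    geom = geom
  ))
  nuclei <- assign_regions(nuclei, labels, geom)

  coverage <- stage("coverage_fractions", coverage_fractions(labels, geom))
  coverage_roi <- if (!is.null(config$n_rois)) {
    stage("coverage_fractions", coverage_fractions(labels, geom, rois = config$n_rois))
  }
  prolif <- stage(
    "proliferation_by_region",
    proliferation_by_region(nuclei, n_min = config$n_min)
  )
  layering <- stage(
    "smc_layering_index",
    smc_layering_index(stack$channels$SMC, labels, geom)
  )
  profiles <- stage("radial_profiles", radial_profiles(
    stack, labels, geom,
    n_bins = config$n_bins
  ))
  alignment <- stage(
    "alignment_order",
    alignment_order(stack$channels$EC, labels, geom)
  )
  shear <- stage("zone_shear_summary", zone_shear_summary(config$shear, geom))

  report <- structure(
    list(
      geom = geom, labels = labels, nuclei = nuclei,
      coverage = coverage, coverage_roi = coverage_roi,
      proliferation = prolif, layering = layering,
      profiles = profiles, alignment = alignment, shear = shear,
      truth = truth, config = config
    ),
    class = "well_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

config_hash <- function(config) {
  v <- unclass(config)
  v$out_dir <- NULL
  rlang::hash(v)
}

write_csv_meta <- function(df, path, meta_lines) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(meta_lines, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- c(
    paste0("# wellmosaic ", as.character(packageVersion("wellmosaic"))),
    paste0("# config_hash ", config_hash(report$config)),
    paste0("# seed ", report$config$seed)
  )
  region <- dplyr::full_join(
    report$coverage[report$coverage$region_class != "ec_total", ],
    report$proliferation,
    by = c("zone", "region_class")
  )
  region <- dplyr::full_join(region, report$layering[, c("zone", "region_class", "smc_intensity_norm")],
    by = c("zone", "region_class")
  )
  write_csv_meta(region, file.path(out_dir, "region_table.csv"), meta)
  write_csv_meta(report$profiles, file.path(out_dir, "profile_table.csv"), meta)
  write_csv_meta(report$alignment, file.path(out_dir, "alignment_table.csv"), meta)
  write_csv_meta(report$shear, file.path(out_dir, "shear_table.csv"), meta)
  write_nuclei(report$nuclei, file.path(out_dir, "nuclei.csv"))
  write_labelmap(report$labels, file.path(out_dir, "labelmap.png"))
  write_labelmap(report$labels, file.path(out_dir, "labelmap_color.png"), color = TRUE)
  write_geometry(report$geom, file.path(out_dir, "geometry.yaml"))
  if (!is.null(report$truth)) {
    write_scene_config(report$truth$config, file.path(out_dir, "scene_config.yaml"))
  }
  invisible(out_dir)
}

#' @export
print.well_report <- function(x, ...) {
  cat("<well_report>\n")
  cat("  coverage:\n")
  print(x$coverage, n = 8)
  invisible(x)
}
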