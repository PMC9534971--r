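#' Configuration of a synthetic well scene
#'
#' Defines all parameters of one synthetic whole-well mosaic: the coculture
#' model, flow condition, well size, per-zone target area fractions of the
#' endothelial (EC) region classes, SMC corrugation amplitude, per-region
#' proliferation probabilities, nucleus densities, texture scales and the
#' imaging noise model. The same config plus the same seed regenerates a
#' bit-identical scene.
#'
#' Model presets encode the qualitative structure of the three coculture
#' models: `"quiescent"` (near-confluent endothelium, no corrugations, low
#' proliferation), `"IH_low_density"` (defected endothelium with islands,
#' networks and gaps, corrugated SMC multilayers under the defects, elevated
#' SMC proliferation in gaps and networks), `"high_density"` (confluent
#' periphery, small central defects, corrugations suppressed), plus the two
#' monocultures. Under `condition = "shear"` the IH preset carries more
#' island and less network area than under `"static"`, peripheral island
#' cells are elongated tangentially to the flow, and corrugation ridges are
#' tangentially aligned in the periphery.
#'
#' @param model coculture model preset.
#' @param condition `"shear"` (orbital shaker) or `"static"`.
#' @param well_radius_px well radius in pixels.
#' @param canvas_px square canvas side in pixels; must hold the whole well.
#' @param pixel_size_um physical pixel size (µm/px).
#' @param split_fraction center/periphery split, see [well_geometry()].
#' @param island_fraction,network_fraction target area fractions per zone;
#'   either a scalar (both zones) or a named vector
#'   `c(center = ..., periphery = ...)`. `NULL` uses the model preset.
#' @param corrugation_multiplier fold-change of SMC cell-tracker intensity
#'   on corrugation ridges relative to the monolayer baseline (>= 1);
#'   corrugations are rendered only for models that form them and only in
#'   gap/network regions.
#' @param prolif_rates list with elements `smc` (a scalar, a named vector
#'   over classes `island`/`network`/`gap`, or a list with `center` and
#'   `periphery` vectors) and `ec` (scalar): Bernoulli probabilities for the
#'   ki-67 proliferation flag. `NULL` uses the model preset.
#' @param densities list with `ec_nuclei_per_mm2`, `smc_nuclei_per_mm2`.
#' @param texture list of texture scales in pixels:
#'   `cell_diameter_px` (island cobblestone cell size),
#'   `island_scale_px` (island blob correlation length),
#'   `min_island_px` (minimum confluent-patch area; smaller blobs are not
#'   rendered as islands),
#'   `network_scale_px` (correlation length of the field whose level sets
#'   trace the network cords),
#'   `cord_halfwidth_px` (half-width of a network cord),
#'   `elongation` (tangential axis ratio of peripheral cells under shear),
#'   `ridge_scale_px` (corrugation ridge width scale).
#' @param noise list with `poisson_scale` (expected photons at unit
#'   intensity; 0 disables shot noise), `gaussian_sd` (additive read noise),
#'   `vignette_amplitude` (per-tile gain spread of the stitching grid) and
#'   `stitch_grid_period_px` (tile size).
#' @param seed integer RNG seed for the scene.
#' @return An object of class `scene_config`.
#' @examples
#' cfg <- scene_config(model = "IH_low_density", seed = 1, well_radius_px = 120,
#'                     canvas_px = 256)
#' cfg$island_fraction
#' @export
scene_config <- function(model = c(
                           "IH_low_density", "quiescent", "high_density",
                           "monoculture_EC", "monoculture_SMC"
                         ),
                         condition = c("shear", "static"),
                         well_radius_px = 480,
                         canvas_px = 1024,
                         pixel_size_um = 4,
                         split_fraction = 0.5,
                         island_fraction = NULL,
                         network_fraction = NULL,
                         corrugation_multiplier = 2.5,
                         prolif_rates = NULL,
                         densities = list(),
                         texture = list(),
                         noise = list(),
                         seed = 1L) {
  model <- match.arg(model)
  condition <- match.arg(condition)

  preset <- model_preset(model, condition)
  island_fraction <- zone_fractions(island_fraction %||% preset$island)
  network_fraction <- zone_fractions(network_fraction %||% preset$network)

  bad <- island_fraction < 0 | island_fraction > 1 |
    network_fraction < 0 | network_fraction > 1 |
    island_fraction + network_fraction > 1 + 1e-12
  if (any(bad)) {
    stop_wm(
      "Per-zone island and network fractions must lie in [0, 1] and sum to at most 1.",
      "config_error"
    )
  }
  if (corrugation_multiplier < 1) {
    stop_wm("`corrugation_multiplier` must be >= 1.", "config_error")
  }
  if (2 * well_radius_px > canvas_px) {
    stop_wm("Well does not fit the canvas: 2 * well_radius_px > canvas_px.",
      "geometry_error")
  }

  prolif <- normalize_prolif_rates(prolif_rates %||% preset$prolif)
  if (any(unlist(prolif$smc) < 0 | unlist(prolif$smc) > 1) ||
      prolif$ec < 0 || prolif$ec > 1) {
    stop_wm("Proliferation probabilities must lie in [0, 1].", "config_error")
  }

  densities <- modifyList(
    list(ec_nuclei_per_mm2 = 800, smc_nuclei_per_mm2 = 1200),
    densities
  )
  texture <- modifyList(
    list(
      cell_diameter_px = 7.5, island_scale_px = 32, network_scale_px = 24,
      cord_halfwidth_px = 5, min_island_px = 600,
      elongation = 2.5, ridge_scale_px = 6
    ),
    texture
  )
  noise <- modifyList(
    list(
      poisson_scale = 200, gaussian_sd = 0.01,
      vignette_amplitude = 0.05, stitch_grid_period_px = 256
    ),
    noise
  )

  structure(
    list(
      model = model, condition = condition,
      well_radius_px = well_radius_px, canvas_px = as.integer(canvas_px),
      pixel_size_um = pixel_size_um, split_fraction = split_fraction,
      island_fraction = island_fraction, network_fraction = network_fraction,
      corrugation_multiplier = corrugation_multiplier,
      corrugations = preset$corrugations,
      has_ec = preset$has_ec, has_smc = preset$has_smc,
      prolif_rates = prolif,
      densities = densities, texture = texture, noise = noise,
      seed = as.integer(seed)
    ),
    class = "scene_config"
  )
}

zone_fractions <- function(x) {
  if (length(x) == 1 && is.null(names(x))) {
    x <- c(center = unname(x), periphery = unname(x))
  }
  if (!all(c("center", "periphery") %in% names(x))) {
    stop_wm("Zone fractions need `center` and `periphery` entries (or a scalar).",
      "config_error")
  }
  x[c("center", "periphery")]
}

normalize_prolif_rates <- function(p) {
  smc <- p$smc %||% 0.05
  per_zone <- function(v) {
    if (length(v) == 1 && is.null(names(v))) {
      v <- c(island = unname(v), network = unname(v), gap = unname(v))
    }
    if (!all(c("island", "network", "gap") %in% names(v))) {
      stop_wm("SMC proliferation rates need island/network/gap entries.",
        "config_error")
    }
    v[c("island", "network", "gap")]
  }
  if (is.list(smc)) {
    smc <- list(center = per_zone(smc$center), periphery = per_zone(smc$periphery))
  } else {
    v <- per_zone(smc)
    smc <- list(center = v, periphery = v)
  }
  list(smc = smc, ec = p$ec %||% 0.15)
}

model_preset <- function(model, condition) {
  shear <- condition == "shear"
  switch(model,
    IH_low_density = list(
      island = if (shear) 0.30 else 0.15,
      network = if (shear) 0.20 else 0.35,
      prolif = list(smc = c(island = 0.05, network = 0.25, gap = 0.30), ec = 0.15),
      corrugations = TRUE, has_ec = TRUE, has_smc = TRUE
    ),
    quiescent = list(
      island = c(center = 0.72, periphery = 0.88),
      network = c(center = 0.04, periphery = 0.02),
      prolif = list(smc = 0.05, ec = 0.26),
      corrugations = FALSE, has_ec = TRUE, has_smc = TRUE
    ),
    high_density = list(
      island = if (shear) c(center = 0.60, periphery = 0.90) else
        c(center = 0.50, periphery = 0.75),
      network = if (shear) c(center = 0.06, periphery = 0.03) else
        c(center = 0.12, periphery = 0.06),
      prolif = list(
        smc = list(
          center = c(island = 0.05, network = 0.05, gap = 0.25),
          periphery = c(island = 0.05, network = 0.05, gap = 0.05)
        ),
        ec = 0.06
      ),
      corrugations = FALSE, has_ec = TRUE, has_smc = TRUE
    ),
    monoculture_EC = list(
      island = c(center = 0.70, periphery = 0.92),
      network = c(center = 0.05, periphery = 0.02),
      prolif = list(smc = 0, ec = 0.30),
      corrugations = FALSE, has_ec = TRUE, has_smc = FALSE
    ),
    monoculture_SMC = list(
      island = 0, network = 0,
      prolif = list(smc = 0.05, ec = 0),
      corrugations = FALSE, has_ec = FALSE, has_smc = TRUE
    )
  )
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf(
    "<scene_config> %s / %s, well r=%d px @ %.3g um/px, canvas %d^2, seed %d\n",
    x$model, x$condition, round(x$well_radius_px), x$pixel_size_um,
    x$canvas_px, x$seed
  ))
  cat(sprintf(
    "  island: center %.2f, periphery %.2f; network: center %.2f, periphery %.2f\n",
    x$island_fraction["center"], x$island_fraction["periphery"],
    x$network_fraction["center"], x$network_fraction["periphery"]
  ))
  invisible(x)
}

#' Serialize / read a scene config as YAML
#'
#' Round-trips all fields; `read_scene_config()` re-validates via
#' [scene_config()].
#'
#' @param config a [scene_config()].
#' @param path file path.
#' @export
write_scene_config <- function(config, path) {
  v <- unclass(config)
  v$island_fraction <- as.list(v$island_fraction)
  v$network_fraction <- as.list(v$network_fraction)
  v$prolif_rates <- list(
    smc = lapply(v$prolif_rates$smc, as.list),
    ec = v$prolif_rates$ec
  )
  v$corrugations <- NULL
  v$has_ec <- NULL
  v$has_smc <- NULL
  yaml::write_yaml(v, path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  v <- yaml::read_yaml(path)
  scene_config(
    model = v$model, condition = v$condition,
    well_radius_px = v$well_radius_px, canvas_px = v$canvas_px,
    pixel_size_um = v$pixel_size_um, split_fraction = v$split_fraction,
    island_fraction = unlist(v$island_fraction),
    network_fraction = unlist(v$network_fraction),
    corrugation_multiplier = v$corrugation_multiplier,
    prolif_rates = list(
      smc = lapply(v$prolif_rates$smc, unlist),
      ec = v$prolif_rates$ec
    ),
    densities = v$densities, texture = v$texture, noise = v$noise,
    seed = v$seed
  )
}
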