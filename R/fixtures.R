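#' Standard fixture configurations
#'
#' Named scene configs covering the three coculture models under shear and
#' static conditions, with fixed seeds derived from `base_seed`. Effect
#' sizes follow the model presets, which are deliberately large so that
#' pipeline recovery is unambiguous at modest image sizes.
#'
#' @param well_radius_px,canvas_px scene size shared by all fixtures.
#' @param base_seed fixture `i` uses seed `base_seed + i`.
#' @return A named list of [scene_config()] objects.
#' @export
fixture_configs <- function(well_radius_px = 220, canvas_px = 480,
                            base_seed = 42L) {
  specs <- list(
    quiescent_shear = list(model = "quiescent", condition = "shear"),
    quiescent_static = list(model = "quiescent", condition = "static"),
    ih_shear = list(model = "IH_low_density", condition = "shear"),
    ih_static = list(model = "IH_low_density", condition = "static"),
    high_density_shear = list(model = "high_density", condition = "shear"),
    high_density_static = list(model = "high_density", condition = "static")
  )
  out <- purrr::imap(specs, function(sp, nm) {
    i <- match(nm, names(specs))
    scene_config(
      model = sp$model, condition = sp$condition,
      well_radius_px = well_radius_px, canvas_px = canvas_px,
      seed = base_seed + i
    )
  })
  out
}

#' Build the fixture scenes
#'
#' Generates every fixture scene from [fixture_configs()]; with `outdir`
#' set, writes each scene's stack (multi-page TIFF), ground-truth label map
#' (PNG), nucleus table (CSV) and config echo (YAML) into a subdirectory
#' per fixture. Rebuilding from the same configs is bit-identical.
#'
#' @param outdir optional output directory.
#' @param configs fixture configs, by default [fixture_configs()].
#' @return A named list of `well_scene` objects (invisibly carries an
#'   `index` attribute tibble with per-fixture summaries).
#' @export
build_fixtures <- function(outdir = NULL, configs = fixture_configs()) {
  scenes <- purrr::map(configs, generate_scene)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    purrr::iwalk(scenes, function(sc, nm) {
      d <- file.path(outdir, nm)
      dir.create(d, showWarnings = FALSE)
      write_stack(sc$stack, file.path(d, "stack.tiff"))
      write_labelmap(sc$truth$labels, file.path(d, "gt_labels.png"))
      write_nuclei(sc$truth$nuclei, file.path(d, "gt_nuclei.csv"))
      write_scene_config(sc$truth$config, file.path(d, "config.yaml"))
    })
  }
  index <- purrr::imap_dfr(scenes, function(sc, nm) {
    tibble(
      fixture = nm,
      model = sc$truth$config$model,
      condition = sc$truth$config$condition,
      seed = sc$truth$config$seed,
      n_nuclei = nrow(sc$truth$nuclei)
    )
  })
  attr(scenes, "index") <- index
  invisible(scenes)
}

#' Recovery report: pipeline outputs versus generator ground truth
#'
#' Runs segmentation and quantification on each fixture and evaluates the
#' directional patterns the coculture models encode, through the full
#' pipeline (never from ground-truth labels):
#' * the IH model has a larger defected (gap + network) peripheral fraction
#'   than the high-density model;
#' * IH SMC proliferation is higher in gaps and networks than under islands
#'   in both zones; in the high-density model proliferation is elevated
#'   only in central gaps;
#' * the IH SMC layering index exceeds 1 in peripheral defect regions while
#'   the high-density model stays near 1 everywhere;
#' * shear shifts the IH model toward more island and less network area
#'   than static culture.
#'
#' @param fixtures named list of `well_scene` objects from
#'   [build_fixtures()] (needs the six standard names).
#' @param params a [segmentation_params()].
#' @param n_min minimum SMC nuclei per cell for proliferation percentages.
#' @return A tibble with one row per check: `check`, `detail`, `value_a`,
#'   `value_b`, `pass`; empty input gives an empty report.
#' @export
run_recovery_report <- function(fixtures, params = segmentation_params(),
                                n_min = 20L) {
  empty <- tibble(
    check = character(), detail = character(),
    value_a = numeric(), value_b = numeric(), pass = logical()
  )
  if (!length(fixtures)) {
    return(empty)
  }
  quant <- purrr::map(fixtures, function(sc) {
    geom <- sc$truth$geom
    bw <- binarize_ec(sc$stack$channels$EC, params, geom)
    labels <- classify_regions(bw, geom, params)
    nuclei <- detect_nuclei(
      sc$stack$channels$DAPI, sc$stack$channels$ERG1, sc$stack$channels$Ki67,
      geom = geom
    )
    nuclei <- assign_regions(nuclei, labels, geom)
    list(
      coverage = coverage_fractions(labels, geom),
      prolif = proliferation_by_region(nuclei, n_min = n_min),
      layering = smc_layering_index(sc$stack$channels$SMC, labels, geom)
    )
  })
  cov_at <- function(nm, zone, cls) {
    cv <- quant[[nm]]$coverage
    sum(cv$area_fraction[cv$zone == zone & cv$region_class %in% cls])
  }
  pct_at <- function(nm, zone, cls) {
    pr <- quant[[nm]]$prolif
    pr$smc_prolif_pct[pr$zone == zone & pr$region_class == cls]
  }
  lay_at <- function(nm, zone, cls) {
    ly <- quant[[nm]]$layering
    ly$smc_intensity_norm[ly$zone == zone & ly$region_class == cls]
  }

  rows <- list()
  add <- function(check, detail, a, b, pass) {
    rows[[length(rows) + 1]] <<- tibble(
      check = check, detail = detail,
      value_a = a, value_b = b, pass = pass
    )
  }

  if (all(c("ih_shear", "high_density_shear") %in% names(quant))) {
    a <- cov_at("ih_shear", "periphery", c("gap", "network"))
    b <- cov_at("high_density_shear", "periphery", c("gap", "network"))
    add(
      "defect_fraction", "IH periphery gap+network > high-density periphery",
      a, b, a > b
    )
  }
  if ("ih_shear" %in% names(quant)) {
    for (z in c("center", "periphery")) {
      isl <- pct_at("ih_shear", z, "island")
      for (cls in c("gap", "network")) {
        v <- pct_at("ih_shear", z, cls)
        add(
          "ih_proliferation",
          sprintf("IH %s: %s prolif > island prolif", z, cls),
          v, isl, isTRUE(v > isl)
        )
      }
    }
    peri_def <- max(lay_at("ih_shear", "periphery", "gap"),
      lay_at("ih_shear", "periphery", "network"),
      na.rm = TRUE
    )
    add(
      "ih_layering", "IH periphery gap/network layering index > 1",
      peri_def, 1, peri_def > 1.1
    )
  }
  if ("high_density_shear" %in% names(quant)) {
    cg <- pct_at("high_density_shear", "center", "gap")
    others <- c(
      pct_at("high_density_shear", "center", "island"),
      pct_at("high_density_shear", "periphery", "island"),
      pct_at("high_density_shear", "periphery", "gap")
    )
    others <- others[!is.na(others)]
    add(
      "hd_proliferation", "high-density: prolif elevated only in center gaps",
      cg, max(others), isTRUE(cg > max(others)) && all(others < 15)
    )
    lays <- purrr::map_dbl(
      c("center", "periphery"),
      function(z) {
        v <- c(lay_at("high_density_shear", z, "gap"),
               lay_at("high_density_shear", z, "network"))
        max(abs(v - 1), na.rm = TRUE)
      }
    )
    add(
      "hd_layering", "high-density layering index ~ 1 everywhere",
      max(lays), 0.15, max(lays) <= 0.15
    )
  }
  if (all(c("ih_shear", "ih_static") %in% names(quant))) {
    ish <- cov_at("ih_shear", "center", "island") +
      cov_at("ih_shear", "periphery", "island")
    ist <- cov_at("ih_static", "center", "island") +
      cov_at("ih_static", "periphery", "island")
    nsh <- cov_at("ih_shear", "center", "network") +
      cov_at("ih_shear", "periphery", "network")
    nst <- cov_at("ih_static", "center", "network") +
      cov_at("ih_static", "periphery", "network")
    add("shear_direction", "IH island fraction: shear > static", ish, ist, ish > ist)
    add("shear_direction", "IH network fraction: shear < static", nsh, nst, nsh < nst)
  }
  dplyr::bind_rows(rows)
}
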