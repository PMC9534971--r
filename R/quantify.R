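#' Area coverage fractions per zone and region class
#'
#' Computes the fraction of each zone's area covered by EC islands, EC
#' networks and gaps, plus the total EC coverage (islands + networks) per
#' zone and for the whole well. Per zone the island/network/gap fractions
#' partition the area and sum to one. With `rois` set, the same fractions
#' are additionally reported per annular-sector ROI, exposing the local
#' variance of coverage across the well.
#'
#' @param labelmap a `region_labelmap`.
#' @param geom a [well_geometry()].
#' @param rois optional integer: number of sector ROIs per zone.
#' @return A tibble with columns `zone`, `region_class` (including an
#'   `"ec_total"` row per zone and for `zone = "well"`), `n_px`,
#'   `area_fraction`, and `roi` when `rois` is given.
#' @export
coverage_fractions <- function(labelmap, geom, rois = NULL) {
  lab <- as_mat(labelmap)
  zm <- zone_map(geom, dim(lab))
  if (!any(zm == "center") || !any(zm == "periphery")) {
    stop_wm("Empty zone: the well geometry does not cover both zones.",
      "geometry_error")
  }
  if (!is.null(rois)) {
    rm <- roi_map(geom, dim(lab), rois)
    df <- tibble(
      zone = as.vector(zm), roi = as.vector(rm),
      code = as.vector(lab)
    )
    df <- df[df$zone != "outside", ]
    out <- df |>
      dplyr::count(.data$zone, .data$roi, .data$code, name = "n_px") |>
      dplyr::group_by(.data$zone, .data$roi) |>
      tidyr::complete(code = unname(WM_CLASSES), fill = list(n_px = 0L)) |>
      dplyr::mutate(
        region_class = class_name_of(.data$code),
        area_fraction = .data$n_px / sum(.data$n_px)
      ) |>
      dplyr::ungroup() |>
      dplyr::select("zone", "roi", "region_class", "n_px", "area_fraction")
    return(out)
  }
  df <- tibble(zone = as.vector(zm), code = as.vector(lab))
  df <- df[df$zone != "outside", ]
  per_zone <- df |>
    dplyr::count(.data$zone, .data$code, name = "n_px") |>
    dplyr::group_by(.data$zone) |>
    tidyr::complete(code = unname(WM_CLASSES), fill = list(n_px = 0L)) |>
    dplyr::mutate(
      region_class = class_name_of(.data$code),
      area_fraction = .data$n_px / sum(.data$n_px)
    ) |>
    dplyr::ungroup()
  ec_zone <- per_zone |>
    dplyr::filter(.data$region_class != "gap") |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(n_px = sum(.data$n_px), .groups = "drop") |>
    dplyr::mutate(region_class = "ec_total")
  zone_tot <- per_zone |>
    dplyr::group_by(.data$zone) |>
    dplyr::summarise(tot = sum(.data$n_px), .groups = "drop")
  ec_zone <- dplyr::left_join(ec_zone, zone_tot, by = "zone") |>
    dplyr::mutate(area_fraction = .data$n_px / .data$tot) |>
    dplyr::select(-"tot")
  ec_well <- tibble(
    zone = "well", region_class = "ec_total",
    n_px = sum(ec_zone$n_px), area_fraction = sum(ec_zone$n_px) / sum(zone_tot$tot)
  )
  dplyr::bind_rows(
    dplyr::select(per_zone, "zone", "region_class", "n_px", "area_fraction"),
    ec_zone, ec_well
  )
}

#' Detect nuclei and assign marker identities
#'
#' Finds nucleus centroids as local maxima of the smoothed DAPI channel
#' above an Otsu threshold with a minimum separation, then reads the mean
#' ERG1 and ki-67 intensity in a small disk around each centroid: ERG1
#' marks endothelial nuclei, ki-67 proliferative ones. Missing marker
#' channels yield `NA` flags; blank DAPI yields an empty table.
#'
#' @param dapi DAPI channel matrix.
#' @param erg1,ki67 optional marker channels.
#' @param geom optional [well_geometry()] restricting detection to the well.
#' @param blur_sigma_px DAPI presmoothing.
#' @param min_separation_px minimum centroid separation (max-filter radius).
#' @param disk_radius_px radius of the marker read-out disk.
#' @param marker_threshold mean in-disk marker intensity at or above which a
#'   flag is set.
#' @return A tibble with columns `x`, `y`, `is_ec`, `is_proliferative`.
#' @export
detect_nuclei <- function(dapi, erg1 = NULL, ki67 = NULL, geom = NULL,
                          blur_sigma_px = 0.6, min_separation_px = 1L,
                          disk_radius_px = 2L, marker_threshold = 0.2) {
  dapi <- as_mat(dapi)
  empty <- tibble(
    x = numeric(), y = numeric(),
    is_ec = logical(), is_proliferative = logical()
  )
  if (diff(range(dapi)) == 0) {
    return(empty)
  }
  sm <- blur_xy(dapi, blur_sigma_px, boundary = "replicate")
  support <- if (!is.null(geom)) {
    radius_map(geom, dim(dapi)) <= geom$radius_px
  } else {
    matrix(TRUE, nrow(dapi), ncol(dapi))
  }
  thr <- otsu_threshold(sm[support])
  brush <- EBImage::makeBrush(2 * min_separation_px + 1, "disc")
  mx <- as_mat(EBImage::dilate(EBImage::Image(sm), brush))
  peaks <- which(sm >= mx & sm >= thr & support, arr.ind = TRUE)
  if (!nrow(peaks)) {
    return(empty)
  }
  out <- tibble(x = as.numeric(peaks[, 2]), y = as.numeric(peaks[, 1]))

  disk <- EBImage::makeBrush(2 * disk_radius_px + 1, "disc")
  disk <- disk / sum(disk)
  read_marker <- function(ch) {
    if (is.null(ch)) {
      return(rep(NA, nrow(out)))
    }
    mm <- as_mat(EBImage::filter2(as_mat(ch), disk, boundary = "replicate"))
    mm[peaks] >= marker_threshold
  }
  out$is_ec <- read_marker(erg1)
  out$is_proliferative <- read_marker(ki67)
  out
}

#' Assign nuclei to zones and region classes
#'
#' Each nucleus takes the zone and region class of the pixel under its
#' centroid (a deterministic point-statistics rule).
#'
#' @param nuclei tibble with `x`, `y` columns.
#' @param labelmap a `region_labelmap`.
#' @param geom a [well_geometry()].
#' @return The input tibble with `zone` and `region_class` columns.
#' @export
assign_regions <- function(nuclei, labelmap, geom) {
  lab <- as_mat(labelmap)
  if (!nrow(nuclei)) {
    nuclei$zone <- character()
    nuclei$region_class <- character()
    return(nuclei)
  }
  idx <- cbind(
    pmin(pmax(round(nuclei$y), 1L), nrow(lab)),
    pmin(pmax(round(nuclei$x), 1L), ncol(lab))
  )
  nuclei$zone <- zone_of(nuclei, geom)
  nuclei$region_class <- class_name_of(lab[idx])
  nuclei
}

#' SMC proliferation percentage by zone and region class
#'
#' The central proliferation readout: among SMC nuclei (DAPI+, ERG1-) in
#' each (zone, region class), the percentage carrying the ki-67 flag.
#' Cells below `n_min` SMC nuclei are reported as missing (`NA`), never as
#' zero, to guard against unstable small-count ratios.
#'
#' @param nuclei nucleus tibble with `zone`, `region_class`, `is_ec`,
#'   `is_proliferative` columns (see [assign_regions()]).
#' @param n_min minimum SMC nuclei per cell for a percentage.
#' @return A tibble with `zone`, `region_class`, `n_smc`, `n_prolif`,
#'   `smc_prolif_pct`.
#' @export
proliferation_by_region <- function(nuclei, n_min = 20L) {
  grid <- tidyr::expand_grid(
    zone = c("center", "periphery"),
    region_class = c("island", "network", "gap")
  )
  smc <- dplyr::filter(nuclei, !.data$is_ec, .data$zone != "outside")
  counts <- smc |>
    dplyr::group_by(.data$zone, .data$region_class) |>
    dplyr::summarise(
      n_smc = dplyr::n(),
      n_prolif = sum(.data$is_proliferative, na.rm = TRUE),
      .groups = "drop"
    )
  grid |>
    dplyr::left_join(counts, by = c("zone", "region_class")) |>
    dplyr::mutate(
      n_smc = dplyr::coalesce(.data$n_smc, 0L),
      n_prolif = dplyr::coalesce(.data$n_prolif, 0L),
      smc_prolif_pct = dplyr::if_else(
        .data$n_smc >= n_min,
        100 * .data$n_prolif / .data$n_smc,
        NA_real_
      )
    )
}

#' Island-normalized SMC intensity (layering index)
#'
#' The cell-tracker dye carries approximately constant intensity per cell,
#' so background-subtracted mean intensity is proportional to the local
#' number of stacked SMCs. Within each zone, mean intensity per region
#' class is divided by the mean over that zone's island pixels, making the
#' island class exactly 1 and any multilayered (corrugated) region > 1.
#' Background is the median intensity of outside-well pixels. Ratios are
#' invariant under any global gain. If a zone has no island pixels the
#' zone mean is used as fallback normalizer and flagged.
#'
#' @param smc cell-tracker channel matrix.
#' @param labelmap a `region_labelmap`.
#' @param geom a [well_geometry()].
#' @return A tibble with `zone`, `region_class`, `n_px`,
#'   `smc_intensity_norm`, `normalizer`.
#' @export
smc_layering_index <- function(smc, labelmap, geom) {
  smc <- as_mat(smc)
  lab <- as_mat(labelmap)
  zm <- zone_map(geom, dim(smc))
  outside <- zm == "outside"
  bg <- if (any(outside)) median(smc[outside]) else 0
  v <- pmax(smc - bg, 0)

  purrr::map_dfr(c("center", "periphery"), function(z) {
    zsel <- zm == z
    isl <- zsel & lab == WM_ISLAND
    if (any(isl)) {
      denom <- mean(v[isl])
      normalizer <- "island"
    } else {
      denom <- mean(v[zsel])
      normalizer <- "zone_mean"
    }
    purrr::map_dfr(names(WM_CLASSES), function(cls) {
      sel <- zsel & lab == WM_CLASSES[[cls]]
      tibble(
        zone = z, region_class = cls, n_px = sum(sel),
        smc_intensity_norm = if (any(sel)) mean(v[sel]) / denom else NA_real_,
        normalizer = normalizer
      )
    })
  })
}

#' Radial intensity and occupancy profiles
#'
#' Summarizes the well from rim to center in equal-width annular bins
#' (bin 1 at the rim): mean background-subtracted SMC and fibronectin
#' intensities, the same profiles min-max rescaled to the 0-255 display
#' scale across bins (per channel), the island/network/gap occupancy
#' fractions per bin, and the fibronectin-to-SMC ratio computed on the raw
#' background-subtracted values (so it is gain-invariant), undefined where
#' the SMC signal falls below `smc_floor`.
#'
#' @param stack a [channel_stack()] (needs `SMC`; `Fn` optional).
#' @param labelmap a `region_labelmap`.
#' @param geom a [well_geometry()].
#' @param n_bins number of annular bins (>= 10).
#' @param smc_floor minimum background-subtracted SMC intensity for the
#'   ratio.
#' @return A tibble with one row per bin: `bin`, `r_inner_px`, `r_mid_px`,
#'   `r_outer_px`, `n_px`, `smc_raw`, `fn_raw`, `smc_0_255`, `fn_0_255`,
#'   `fn_over_smc`, `frac_island`, `frac_network`, `frac_gap`.
#' @export
radial_profiles <- function(stack, labelmap, geom, n_bins = 30L,
                            smc_floor = 1e-3) {
  if (n_bins < 10) stop_wm("`n_bins` must be >= 10.", "config_error")
  lab <- as_mat(labelmap)
  smc <- as_mat(stack$channels$SMC)
  fn <- if (!is.null(stack$channels$Fn)) as_mat(stack$channels$Fn)
  rm <- radius_map(geom, dim(lab))
  zm <- zone_map(geom, dim(lab))
  outside <- zm == "outside"
  bg_smc <- if (any(outside)) median(smc[outside]) else 0
  v_smc <- pmax(smc - bg_smc, 0)
  v_fn <- if (!is.null(fn)) {
    bg_fn <- if (any(outside)) median(fn[outside]) else 0
    pmax(fn - bg_fn, 0)
  }

  edges <- seq(geom$radius_px, 0, length.out = n_bins + 1)
  rows <- purrr::map_dfr(seq_len(n_bins), function(b) {
    sel <- !outside & rm <= edges[b] & rm > edges[b + 1]
    if (b == n_bins) sel <- sel | (!outside & rm <= edges[n_bins + 1])
    n_px <- sum(sel)
    if (n_px == 0) {
      return(tibble(
        bin = b, r_outer_px = edges[b], r_inner_px = edges[b + 1],
        r_mid_px = (edges[b] + edges[b + 1]) / 2, n_px = 0L,
        smc_raw = NA_real_, fn_raw = NA_real_, fn_over_smc = NA_real_,
        frac_island = NA_real_, frac_network = NA_real_, frac_gap = NA_real_
      ))
    }
    s <- mean(v_smc[sel])
    f <- if (!is.null(v_fn)) mean(v_fn[sel]) else NA_real_
    codes <- lab[sel]
    tibble(
      bin = b, r_outer_px = edges[b], r_inner_px = edges[b + 1],
      r_mid_px = (edges[b] + edges[b + 1]) / 2, n_px = n_px,
      smc_raw = s, fn_raw = f,
      fn_over_smc = if (!is.na(f) && s >= smc_floor) f / s else NA_real_,
      frac_island = mean(codes == WM_ISLAND),
      frac_network = mean(codes == WM_NETWORK),
      frac_gap = mean(codes == WM_GAP)
    )
  })
  rescale255 <- function(v) {
    fin <- is.finite(v)
    if (!any(fin)) return(v)
    rng <- range(v[fin])
    if (diff(rng) == 0) {
      return(replace(rep(NA_real_, length(v)), fin, 0))
    }
    (v - rng[1]) / diff(rng) * 255
  }
  rows$smc_0_255 <- rescale255(rows$smc_raw)
  rows$fn_0_255 <- rescale255(rows$fn_raw)
  rows[, c(
    "bin", "r_outer_px", "r_inner_px", "r_mid_px", "n_px",
    "smc_raw", "fn_raw", "smc_0_255", "fn_0_255", "fn_over_smc",
    "frac_island", "frac_network", "frac_gap"
  )]
}
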