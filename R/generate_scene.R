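#' Generate a synthetic multi-channel well mosaic with ground truth
#'
#' Renders one whole-well mosaic of an EC/SMC coculture as six registered
#' channels — `EC` (VE-cadherin membrane signal composited with ERG1
#' nuclei), `SMC` (cytoplasmic cell tracker), `Fn` (labeled plasma
#' fibronectin fibers), `DAPI`, `Ki67` and `ERG1` — together with the exact
#' ground truth used to render it: the region label map (island / network /
#' gap / outside), the nucleus table with EC identity and proliferation
#' flags, the corrugation and fibronectin masks, and the geometry.
#'
#' The endothelial layer is laid out by per-zone area-fraction targets:
#' islands are compact patches carved from a long-wavelength random field
#' (top quantile per zone, so ground-truth fractions hit their targets to
#' within one pixel), textured as a cobblestone tessellation of cells with
#' bright membranes and dark interiors; networks are curvilinear cords
#' traced along level sets of a second random field. Under shear, island
#' cells in the periphery are elongated tangentially to the flow. The SMC
#' channel is a smooth monolayer baseline multiplied by
#' `corrugation_multiplier` on ridged corrugation profiles that exist only
#' under EC defects (gap/network regions); fibronectin fibers are likewise
#' restricted to defected regions with intensity tied to local SMC
#' intensity. Nuclei are placed on a jittered grid (a hard-core-like point
#' process: real nuclei do not overlap) with EC nuclei only under EC signal,
#' and per-nucleus proliferation flags drawn Bernoulli from the configured
#' per-(zone, class) rates. Photon shot noise, read noise and a per-tile
#' stitching vignette are applied last; ground truth is independent of the
#' noise and of any global gain.
#'
#' @param config a [scene_config()].
#' @return A list of class `well_scene` with elements `stack` (a
#'   [channel_stack()]) and `truth` (class `ground_truth`: `labels`,
#'   `nuclei`, `corrugation_mask`, `fn_mask`, `geom`, `config`).
#' @examples
#' sc <- generate_scene(scene_config(well_radius_px = 60, canvas_px = 128,
#'                                   seed = 1))
#' table(class_name_of(sc$truth$labels))
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  withr::with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  n <- config$canvas_px
  dim_yx <- c(n, n)
  geom <- well_geometry(
    (n + 1) / 2, (n + 1) / 2, config$well_radius_px,
    pixel_size_um = config$pixel_size_um,
    split_fraction = config$split_fraction
  )
  zm <- zone_map(geom, dim_yx)
  in_well <- zm != "outside"
  tx <- config$texture

  ## ---- region label map: exact per-zone area-fraction targets ----
  labels <- matrix(WM_OUTSIDE, n, n)
  labels[in_well] <- WM_GAP
  ## islands: top quantile of a long-wavelength field per zone, with blobs
  ## below the minimum confluent-patch size removed and the selection
  ## trimmed back to the exact per-zone pixel count (skin-first)
  f_island <- smooth_noise(dim_yx, tx$island_scale_px)
  k_isl <- ord <- list()
  cand <- matrix(FALSE, n, n)
  for (z in c("center", "periphery")) {
    zpix <- which(zm == z)
    if (!length(zpix)) next
    k_isl[[z]] <- round(config$island_fraction[[z]] * length(zpix))
    ord[[z]] <- zpix[order(f_island[zpix], decreasing = TRUE)]
    take <- min(length(zpix), round(1.2 * k_isl[[z]]))
    if (take > 0) cand[ord[[z]][seq_len(take)]] <- TRUE
  }
  if (any(cand)) {
    cl <- as_mat(EBImage::bwlabel(cand))
    sizes <- tabulate(cl[cl > 0])
    small <- which(sizes < tx$min_island_px)
    if (length(small)) cand[cl %in% small] <- FALSE
    for (z in names(k_isl)) {
      keep <- ord[[z]][cand[ord[[z]]]]
      labels[head(keep, k_isl[[z]])] <- WM_ISLAND
    }
  }
  ## network cords: bands of bounded half-width around level-set contours
  ## of a second random field (curvilinear, branching/looping, width 1-2
  ## cell diameters); extra levels are pulled in until each zone can meet
  ## its target, then the band is trimmed pixel-exactly per zone
  f_net <- smooth_noise(dim_yx, tx$network_scale_px)
  v_net <- cord_distance(f_net, in_well, labels, zm, config, tx$cord_halfwidth_px)
  for (z in c("center", "periphery")) {
    zpix <- which(zm == z)
    if (!length(zpix)) next
    k_net <- round(config$network_fraction[[z]] * length(zpix))
    if (k_net > 0) {
      free <- zpix[labels[zpix] == WM_GAP & is.finite(v_net[zpix])]
      sel <- free[order(v_net[free])[seq_len(min(k_net, length(free)))]]
      labels[sel] <- WM_NETWORK
    }
  }
  island <- labels == WM_ISLAND
  network <- labels == WM_NETWORK
  defect <- in_well & !island

  shear <- config$condition == "shear"

  ## ---- EC channel: cobblestone membranes in islands, cords in networks ----
  ec <- matrix(0, n, n)
  if (config$has_ec && any(island | network)) {
    if (any(island)) {
      sigma_cell <- tx$cell_diameter_px / 2.4
      t_iso <- smooth_noise(dim_yx, sigma_cell)
      if (shear && tx$elongation > 1) {
        t_pol <- polar_field(geom, dim_yx, sigma_cell, tx$elongation)
        peri <- zm == "periphery"
        t_iso[peri] <- t_pol[peri]
      }
      ws <- as_mat(EBImage::watershed(EBImage::Image(rescale01(t_iso)),
        tolerance = 0.02, ext = 1
      ))
      mem <- label_borders(ws)
      mem <- blur_xy(mem * 1, 0.6, boundary = "replicate")
      mem <- mem / max(mem)
      ## interiors carry weak junctional/cytoplasmic signal so island and
      ## network mean brightness are comparable; the classes differ by
      ## texture, not by gain
      ec <- ec + island * (0.25 + 0.65 * mem)
    }
    if (any(network)) {
      tex_n <- rescale01(smooth_noise(dim_yx, 2))
      ec <- ec + network * (0.42 + 0.25 * tex_n)
    }
  }

  ## ---- SMC channel: monolayer baseline x corrugation profile ----
  smc <- matrix(0, n, n)
  corrugation_mask <- matrix(FALSE, n, n)
  profile_sm <- matrix(0, n, n)
  if (config$has_smc) {
    base <- 0.35 * (1 + 0.5 * (rescale01(smooth_noise(dim_yx, 40)) - 0.5))
    if (config$corrugations && any(defect)) {
      w <- ridge_field(geom, dim_yx, zm, tx$ridge_scale_px, shear)
      profile <- defect * (0.55 + 0.45 * w)
      corrugation_mask <- defect & (profile > 0.5)
      profile_sm <- blur_xy(profile, 1.5, boundary = "replicate")
      profile_sm[!in_well] <- 0
    }
    smc <- base * (1 + (config$corrugation_multiplier - 1) * profile_sm)
    smc[!in_well] <- 0
  }

  ## ---- fibronectin: oriented fibers only where the endothelium is defected ----
  fn <- matrix(0, n, n)
  fn_mask <- matrix(FALSE, n, n)
  if (config$has_smc) {
    fn_region <- if (config$has_ec) defect else in_well
    if (any(fn_region)) {
      w2 <- ridge_field(geom, dim_yx, zm, 2, shear, elong = 6)
      thr <- quantile(w2[fn_region], 0.65, names = FALSE)
      fiber <- fn_region & (w2 >= thr)
      smc_rel <- smc / max(mean(smc[fn_region]), .Machine$double.eps)
      fn <- fiber * (0.45 + 0.35 * w2) * smc_rel
      fn_mask <- fiber
    }
  }

  ## ---- nuclei ----
  ## One jittered-grid (hard-core) point process at the combined EC+SMC
  ## density, spatially thinned to the local density (SMC everywhere on
  ## the SMC layer, plus EC nuclei only under EC signal) and then assigned
  ## an identity by the local EC/SMC rate ratio. A single hard-core
  ## process keeps every pair of nuclei separable in the DAPI projection.
  px_mm <- config$pixel_size_um / 1000
  lam_ec <- if (config$has_ec) config$densities$ec_nuclei_per_mm2 * px_mm^2 else 0
  lam_smc <- if (config$has_smc) config$densities$smc_nuclei_per_mm2 * px_mm^2 else 0
  ec_region <- config$has_ec & (island | network)
  lam_max <- lam_ec + lam_smc
  nuclei <- tibble(
    x = numeric(), y = numeric(),
    is_ec = logical(), zone = character(), region_class = character(),
    is_proliferative = logical()
  )
  if (lam_max > 0) {
    pts <- sample_grid_points(dim_yx, lam_max, in_well)
    if (nrow(pts)) {
      idx <- cbind(
        pmin(pmax(round(pts$y), 1L), n),
        pmin(pmax(round(pts$x), 1L), n)
      )
      on_ec <- ec_region[idx]
      lam_here <- lam_smc + lam_ec * on_ec
      keep <- runif(nrow(pts)) < lam_here / lam_max
      pts <- pts[keep, , drop = FALSE]
      idx <- idx[keep, , drop = FALSE]
      on_ec <- on_ec[keep]
      lam_here <- lam_here[keep]
      is_ec <- on_ec & (runif(nrow(pts)) < lam_ec / pmax(lam_here, .Machine$double.eps))
      zone <- zm[idx]
      region_class <- class_name_of(labels[idx])
      rate <- numeric(nrow(pts))
      rate[is_ec] <- config$prolif_rates$ec
      smc_i <- which(!is_ec)
      if (length(smc_i)) {
        for (z in c("center", "periphery")) {
          for (cls in c("island", "network", "gap")) {
            sel <- smc_i[zone[smc_i] == z & region_class[smc_i] == cls]
            rate[sel] <- config$prolif_rates$smc[[z]][[cls]]
          }
        }
      }
      nuclei <- tibble(
        x = pts$x, y = pts$y, is_ec = is_ec,
        zone = zone, region_class = region_class,
        is_proliferative = runif(nrow(pts)) < rate
      )
    }
  }

  dapi <- render_spots(dim_yx, nuclei, sigma = 1.1, amp = 0.85)
  erg1 <- render_spots(dim_yx, nuclei[nuclei$is_ec, ], sigma = 1.1, amp = 0.8)
  ki67 <- render_spots(dim_yx, nuclei[nuclei$is_proliferative, ],
    sigma = 1.1, amp = 0.8
  )
  ec <- ec + 0.5 * erg1 # composite VE-cadherin + ERG1 acquisition

  channels <- list(
    EC = clamp01(ec), SMC = clamp01(smc), Fn = clamp01(fn),
    DAPI = clamp01(dapi), Ki67 = clamp01(ki67), ERG1 = clamp01(erg1)
  )
  channels <- apply_imaging_noise(channels, config$noise, dim_yx)

  truth <- structure(
    list(
      labels = new_labelmap(labels, provenance = list(source = "generator")),
      nuclei = nuclei,
      corrugation_mask = corrugation_mask,
      fn_mask = fn_mask,
      geom = geom,
      config = config
    ),
    class = "ground_truth"
  )
  structure(
    list(stack = channel_stack(channels, config$pixel_size_um), truth = truth),
    class = "well_scene"
  )
}

## Distance of each pixel to the nearest admissible cord centerline.
## Level-set contours of `f` are added (median outward) until every zone
## has at least its target number of gap pixels within `half_w` of a
## centerline. Centerline pixels closer than `min_sep` to an already
## accepted centerline, or closer than `clearance` to an island, are
## rejected so that distinct cords (and cords vs island rims) stay
## resolvable after binarization. Pixels beyond `half_w` stay Inf.
cord_distance <- function(f, in_well, labels, zm, config, half_w) {
  dist_min <- matrix(Inf, nrow(f), ncol(f))
  targets <- vapply(c("center", "periphery"), function(z) {
    round(config$network_fraction[[z]] * sum(zm == z))
  }, numeric(1))
  if (all(targets == 0)) return(dist_min)
  clearance <- half_w + 6
  island <- labels == WM_ISLAND
  d_isl <- if (any(island)) {
    as_mat(EBImage::distmap(EBImage::Image((!island) * 1)))
  } else {
    matrix(Inf, nrow(f), ncol(f))
  }
  qs <- c(0.5, 0.35, 0.65, 0.2, 0.8, 0.12, 0.88, 0.05, 0.95, 0.28, 0.72, 0.42, 0.58)
  qs_fine <- setdiff(seq(0.04, 0.96, by = 0.04), round(qs, 2))
  qs_finer <- setdiff(seq(0.03, 0.97, by = 0.02), c(round(qs, 2), qs_fine))
  done <- FALSE
  ## later passes allow progressively tighter cord packing (down to a
  ## braided mesh) when the target density is too high for comfortably
  ## separated cords
  for (pass in 1:3) {
    min_sep <- switch(pass, 2 * half_w + 8, 2 * half_w + 3, half_w + 2)
    for (q in switch(pass, qs, qs_fine, qs_finer)) {
      l <- quantile(f[in_well], q, names = FALSE)
      s <- f >= l
      contour <- s & (
        rbind(!s[-1, ], FALSE) | rbind(FALSE, !s[-nrow(s), ]) |
          cbind(!s[, -1], FALSE) | cbind(FALSE, !s[, -ncol(s)])
      )
      contour <- contour & in_well & dist_min > min_sep & d_isl > clearance
      if (!any(contour)) next
      d <- as_mat(EBImage::distmap(EBImage::Image((!contour) * 1)))
      dist_min <- pmin(dist_min, d)
      avail <- vapply(c("center", "periphery"), function(z) {
        sum(dist_min <= half_w & zm == z & labels == WM_GAP)
      }, numeric(1))
      if (all(avail >= targets)) {
        done <- TRUE
        break
      }
    }
    if (done) break
  }
  dist_min[dist_min > half_w] <- Inf
  dist_min
}

## Anisotropic random field sampled on a polar grid so that the long axis
## of its features follows the tangential (flow) direction everywhere.
polar_field <- function(geom, dim_yx, sigma, elong) {
  R <- geom$radius_px
  n_r <- max(8L, ceiling(R))
  n_th <- max(64L, round(2 * pi * 0.75 * R))
  P <- matrix(rnorm(n_r * n_th), n_r, n_th)
  P <- blur_xy(P, sigma_y = sigma / sqrt(elong), sigma_x = sigma * sqrt(elong))
  rm <- radius_map(geom, dim_yx)
  g <- pixel_grid(dim_yx)
  theta <- atan2(g$y - geom$center_y, g$x - geom$center_x)
  ri <- pmin(pmax(round(rm), 1), n_r)
  ti <- (floor((theta + pi) / (2 * pi) * n_th) %% n_th) + 1L
  out <- matrix(0, dim_yx[1], dim_yx[2])
  inw <- rm <= R
  out[inw] <- P[cbind(ri[inw], ti[inw])]
  out
}

## Ridged noise in [0, 1]; tangentially elongated in the periphery under
## shear, isotropic otherwise.
ridge_field <- function(geom, dim_yx, zm, sigma, shear, elong = 4) {
  iso <- rescale01(smooth_noise(dim_yx, sigma))
  if (shear) {
    pol <- rescale01(polar_field(geom, dim_yx, sigma, elong))
    peri <- zm == "periphery"
    iso[peri] <- pol[peri]
  }
  iso
}

label_borders <- function(lab) {
  d <- dim(lab)
  b <- matrix(FALSE, d[1], d[2])
  b[, -d[2]] <- b[, -d[2]] | (lab[, -d[2]] != lab[, -1])
  b[-d[1], ] <- b[-d[1], ] | (lab[-d[1], ] != lab[-1, ])
  b
}

## Jittered-grid point process at target intensity `lambda` (points per
## px^2) restricted to `mask`. Grid spacing 1/sqrt(lambda), jitter +/-0.22
## spacing, hence a guaranteed minimum separation (~0.56 spacing).
sample_grid_points <- function(dim_yx, lambda, mask) {
  empty <- tibble(x = numeric(), y = numeric())
  if (is.logical(mask) && length(mask) == 1) {
    return(empty)
  }
  if (!any(mask) || lambda <= 0) {
    return(empty)
  }
  spacing <- 1 / sqrt(lambda)
  off <- runif(2, 0, spacing)
  gx <- seq(off[1], dim_yx[2], by = spacing)
  gy <- seq(off[2], dim_yx[1], by = spacing)
  if (!length(gx) || !length(gy)) {
    return(empty)
  }
  pts <- expand.grid(x = gx, y = gy, KEEP.OUT.ATTRS = FALSE)
  m <- nrow(pts)
  pts$x <- pts$x + runif(m, -0.22, 0.22) * spacing
  pts$y <- pts$y + runif(m, -0.22, 0.22) * spacing
  keep <- pts$x >= 1 & pts$x <= dim_yx[2] & pts$y >= 1 & pts$y <= dim_yx[1]
  pts <- pts[keep, , drop = FALSE]
  idx <- cbind(round(pts$y), round(pts$x))
  tibble(x = pts$x, y = pts$y)[mask[idx], ]
}

## Gaussian spots of peak height `amp` at the given points.
render_spots <- function(dim_yx, pts, sigma = 1.3, amp = 0.85) {
  m <- matrix(0, dim_yx[1], dim_yx[2])
  if (!nrow(pts)) {
    return(m)
  }
  iy <- pmin(pmax(round(pts$y), 1L), dim_yx[1])
  ix <- pmin(pmax(round(pts$x), 1L), dim_yx[2])
  lin <- (ix - 1L) * dim_yx[1] + iy
  counts <- tabulate(lin, nbins = prod(dim_yx))
  m[] <- counts * amp * 2 * pi * sigma^2
  blur_xy(m, sigma, boundary = "replicate")
}

apply_imaging_noise <- function(channels, noise, dim_yx) {
  v <- NULL
  if (noise$vignette_amplitude > 0 && noise$stitch_grid_period_px > 0) {
    p <- noise$stitch_grid_period_px
    g <- pixel_grid(dim_yx)
    tix <- floor((g$x - 1) / p)
    tiy <- floor((g$y - 1) / p)
    tid <- tix * (max(tiy) + 1) + tiy + 1
    gains <- rnorm(max(tid), 0, noise$vignette_amplitude)
    v <- 1 + matrix(gains[tid], dim_yx[1], dim_yx[2])
  }
  lapply(channels, function(ch) {
    if (!is.null(v)) ch <- ch * v
    if (noise$poisson_scale > 0) {
      ch <- matrix(
        rpois(length(ch), pmax(ch, 0) * noise$poisson_scale) / noise$poisson_scale,
        dim_yx[1], dim_yx[2]
      )
    }
    if (noise$gaussian_sd > 0) {
      ch <- ch + matrix(rnorm(length(ch), 0, noise$gaussian_sd), dim_yx[1], dim_yx[2])
    }
    clamp01(ch)
  })
}

#' Generate a time series of scenes sharing one well
#'
#' Emulates the network-to-island transition of a maturing endothelium:
#' successive days keep the well geometry and differ only in the configured
#' island/network area fractions. With `transition = TRUE` the schedule must
#' have non-decreasing island and non-increasing network fractions; with
#' `conserve_total = TRUE` the summed EC fraction must stay approximately
#' constant across days (tolerance `total_tol`).
#'
#' @param base a [scene_config()] providing everything except the per-day
#'   fractions.
#' @param schedule a data frame with one row per day and columns
#'   `island_fraction`, `network_fraction` (scalars applied to both zones).
#' @param transition enforce the island-up / network-down direction.
#' @param conserve_total require island + network approximately constant.
#' @param total_tol tolerance for `conserve_total`.
#' @return A list of `well_scene` objects, one per schedule row; scene `i`
#'   uses seed `base$seed + i - 1`.
#' @export
generate_time_series <- function(base, schedule, transition = TRUE,
                                 conserve_total = FALSE, total_tol = 0.05) {
  stopifnot(inherits(base, "scene_config"))
  schedule <- as.data.frame(schedule)
  if (!nrow(schedule)) stop_wm("`schedule` must be non-empty.", "config_error")
  if (!all(c("island_fraction", "network_fraction") %in% names(schedule))) {
    stop_wm("`schedule` needs island_fraction and network_fraction columns.",
      "config_error")
  }
  if (transition && nrow(schedule) > 1) {
    if (any(diff(schedule$island_fraction) < -1e-9) ||
        any(diff(schedule$network_fraction) > 1e-9)) {
      stop_wm(
        "With `transition = TRUE` island fractions must be non-decreasing and network fractions non-increasing.",
        "config_error"
      )
    }
  }
  if (conserve_total) {
    tot <- schedule$island_fraction + schedule$network_fraction
    if (diff(range(tot)) > total_tol) {
      stop_wm("Total EC fraction is not conserved across the schedule.",
        "config_error")
    }
  }
  lapply(seq_len(nrow(schedule)), function(i) {
    cfg <- scene_config(
      model = base$model, condition = base$condition,
      well_radius_px = base$well_radius_px, canvas_px = base$canvas_px,
      pixel_size_um = base$pixel_size_um, split_fraction = base$split_fraction,
      island_fraction = schedule$island_fraction[i],
      network_fraction = schedule$network_fraction[i],
      corrugation_multiplier = base$corrugation_multiplier,
      prolif_rates = base$prolif_rates,
      densities = base$densities, texture = base$texture, noise = base$noise,
      seed = base$seed + i - 1L
    )
    generate_scene(cfg)
  })
}

new_labelmap <- function(m, provenance = list()) {
  structure(m, class = c("region_labelmap", class(m)), provenance = provenance)
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(class_name_of(as_mat(x$labels)))
  cat("<ground_truth>", nrow(x$nuclei), "nuclei; label pixels:\n")
  print(tab)
  invisible(x)
}

#' @export
print.well_scene <- function(x, ...) {
  cat(sprintf(
    "<well_scene> %s/%s, %d x %d px, %d nuclei\n",
    x$truth$config$model, x$truth$config$condition,
    nrow(as_mat(x$stack$channels[[1]])), ncol(as_mat(x$stack$channels[[1]])),
    nrow(x$truth$nuclei)
  ))
  invisible(x)
}
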