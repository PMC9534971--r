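#' Parameters of the texture-based region classifier
#'
#' The classifier distinguishing confluent EC islands from cord-like EC
#' networks uses two transparent features: local EC coverage density (the
#' fraction of EC-positive pixels in a sliding window, computed with
#' support-normalized windows so the well rim carries no bias) and
#' connected-component elongation (major/minor axis ratio). Dense, compact
#' EC regions are islands; sparse or elongated ones are networks;
#' EC-negative in-well pixels are gaps.
#'
#' @param ec_threshold_method `"otsu"` (default, offset-invariant),
#'   `"adaptive"` (local-mean offset threshold) or `"fixed"`.
#' @param fixed_threshold threshold for `method = "fixed"`, and the offset
#'   above the local mean for `"adaptive"`.
#' @param blur_sigma_px Gaussian presmoothing of the EC channel before
#'   thresholding; bridges the dark interiors of cobblestone cells.
#' @param density_window_px sliding-window side (px) for local EC coverage;
#'   must be >= 3 and should span a few cord widths.
#' @param island_density_min minimum local coverage for island pixels; EC
#'   pixels below it are network regardless of thickness.
#' @param island_core_radius_px half-width separating "thick" island bodies
#'   from cord-like networks: EC regions that do not survive an erosion of
#'   this radius are cords; surviving cores are regrown over their rim.
#' @param cord_elongation_min axis ratio at or above which an island-labeled
#'   component is reassigned to network.
#' @param min_object_px components smaller than this are merged into the
#'   surrounding class.
#' @param closing_radius_px morphological closing radius for the binary EC
#'   mask.
#' @param hole_fill_max_px holes in the EC mask up to this area are filled
#'   (dark cobblestone interiors); larger enclosed gaps are kept.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(ec_threshold_method = c("otsu", "adaptive", "fixed"),
                                fixed_threshold = 0.2,
                                blur_sigma_px = 1,
                                density_window_px = 31L,
                                island_density_min = 0.35,
                                island_core_radius_px = 8L,
                                cord_elongation_min = 4,
                                min_object_px = 64L,
                                closing_radius_px = 2L,
                                hole_fill_max_px = 80L) {
  ec_threshold_method <- match.arg(ec_threshold_method)
  if (density_window_px < 3) {
    stop_wm("`density_window_px` must be >= 3.", "config_error")
  }
  if (island_density_min < 0 || island_density_min > 1) {
    stop_wm("`island_density_min` must lie in [0, 1].", "config_error")
  }
  structure(
    list(
      ec_threshold_method = ec_threshold_method,
      fixed_threshold = fixed_threshold,
      blur_sigma_px = blur_sigma_px,
      density_window_px = as.integer(density_window_px),
      island_density_min = island_density_min,
      island_core_radius_px = as.integer(island_core_radius_px),
      cord_elongation_min = cord_elongation_min,
      min_object_px = as.integer(min_object_px),
      closing_radius_px = as.integer(closing_radius_px),
      hole_fill_max_px = as.integer(hole_fill_max_px)
    ),
    class = "segmentation_params"
  )
}

#' Binarize the endothelial channel
#'
#' Produces the EC-positive mask underlying region classification:
#' Gaussian presmoothing (so membrane-stained cobblestone cells become
#' filled patches), thresholding (Otsu on in-well intensities by default),
#' morphological closing, hole filling and small-object removal. The Otsu
#' threshold is computed on range-anchored histogram bins, making the mask
#' exactly invariant under a constant intensity offset. A constant image
#' yields an empty mask, not an error.
#'
#' Otsu assumes a genuine background class; on a confluent well it would
#' split membranes from cell interiors instead. When geometry is available
#' the below-threshold pixels are therefore compared with the outside-well
#' background (median + 6 MAD): if they sit well above it, no background
#' class exists in the well and the background-referenced floor is used as
#' the threshold instead. All statistics involved shift equally under a
#' constant offset, so the invariance is preserved.
#'
#' @param ec single-channel EC image (matrix).
#' @param params a [segmentation_params()].
#' @param geom optional [well_geometry()]; restricts thresholding and the
#'   mask to in-well pixels.
#' @return A logical matrix, `TRUE` on EC-positive pixels.
#' @export
binarize_ec <- function(ec, params = segmentation_params(), geom = NULL) {
  ec <- as_mat(ec)
  sm <- blur_xy(ec, params$blur_sigma_px, boundary = "replicate")
  in_well <- if (!is.null(geom)) {
    radius_map(geom, dim(ec)) <= geom$radius_px
  } else {
    matrix(TRUE, nrow(ec), ncol(ec))
  }
  vals <- sm[in_well]
  if (diff(range(vals)) == 0) {
    return(matrix(FALSE, nrow(ec), ncol(ec)))
  }
  thr_otsu <- otsu_threshold(vals)
  if (params$ec_threshold_method == "otsu" && !is.null(geom) && !all(in_well)) {
    bg <- sm[!in_well]
    bg_floor <- median(bg) + 6 * stats::mad(bg)
    below <- vals[vals < thr_otsu]
    if (length(below) && median(below) > bg_floor) thr_otsu <- bg_floor
  }
  mask <- switch(params$ec_threshold_method,
    otsu = sm >= thr_otsu,
    fixed = sm >= params$fixed_threshold,
    adaptive = sm >= local_mean(sm, in_well, params$density_window_px) +
      params$fixed_threshold
  )
  mask <- mask & in_well
  if (params$closing_radius_px > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2 * params$closing_radius_px + 1, shape = "disc")
    mask <- as_mat(EBImage::closing(EBImage::Image(mask * 1), brush)) > 0.5
    mask <- mask & in_well
  }
  if (params$hole_fill_max_px > 0 && any(mask)) {
    holes <- in_well & !mask
    hl <- as_mat(EBImage::bwlabel(holes))
    hs <- tabulate(hl[hl > 0])
    fill <- which(hs <= params$hole_fill_max_px)
    if (length(fill)) mask[hl %in% fill] <- TRUE
  }
  if (params$min_object_px > 0 && any(mask)) {
    lab <- as_mat(EBImage::bwlabel(mask))
    sizes <- tabulate(lab[lab > 0])
    drop <- which(sizes < params$min_object_px)
    if (length(drop)) mask[lab %in% drop] <- FALSE
  }
  mask
}

#' Classify in-well pixels into island / network / gap
#'
#' Classifies by texture thickness and coverage: EC regions thick enough to
#' survive an erosion of `island_core_radius_px` are island bodies, regrown
#' over their rim by a constrained dilation; the remaining thin, cord-like
#' EC pixels are network. Local EC coverage density (support-normalized
#' sliding window) acts as a floor — island pixels below
#' `island_density_min` revert to network — and island-labeled connected
#' components whose axis ratio exceeds `cord_elongation_min` are reassigned
#' to network; components smaller than `min_object_px` are merged into the
#' class surrounding them. The result partitions the well exactly:
#' every in-well pixel carries one of island/network/gap, every outside
#' pixel the outside code. Ties at the density threshold go to island, the
#' denser phase by definition.
#'
#' @param ec_mask logical EC mask from [binarize_ec()].
#' @param geom a [well_geometry()].
#' @param params a [segmentation_params()].
#' @return A `region_labelmap` (integer matrix with the class codes and a
#'   `provenance` attribute recording the parameters).
#' @export
classify_regions <- function(ec_mask, geom, params = segmentation_params()) {
  ec_mask <- as_mat(ec_mask) > 0.5
  dim_yx <- dim(ec_mask)
  in_well <- radius_map(geom, dim_yx) <= geom$radius_px
  ec_mask <- ec_mask & in_well

  r_core <- params$island_core_radius_px
  if (r_core > 0 && any(ec_mask)) {
    ## opening removes everything thinner than 2 * r_core (the cords) and
    ## restores the surviving island bodies without spilling onto
    ## attached cords
    island <- as_mat(EBImage::opening(
      EBImage::Image(ec_mask * 1), EBImage::makeBrush(2 * r_core + 1, "disc")
    )) > 0.5
    island <- island & ec_mask
  } else {
    island <- ec_mask
  }
  dens <- local_mean(ec_mask * 1, in_well, params$density_window_px)
  island <- island & (dens >= params$island_density_min)
  network <- ec_mask & !island

  ## elongated "island" components are cords seen at high coverage
  if (any(island)) {
    lab <- EBImage::bwlabel(island)
    n_comp <- max(lab)
    if (n_comp > 0) {
      ft <- EBImage::computeFeatures.moment(lab)
      ecc <- ft[, "m.eccentricity"]
      ratio <- 1 / sqrt(pmax(1 - ecc^2, 1e-12))
      cords <- which(ratio >= params$cord_elongation_min)
      if (length(cords)) {
        sel <- as_mat(lab) %in% cords
        network[sel] <- TRUE
        island[sel] <- FALSE
      }
    }
  }

  labels <- matrix(WM_OUTSIDE, dim_yx[1], dim_yx[2])
  labels[in_well] <- WM_GAP
  labels[network] <- WM_NETWORK
  labels[island] <- WM_ISLAND
  labels <- merge_small_components(labels, in_well, params$min_object_px)
  new_labelmap(labels, provenance = list(source = "classify_regions", params = unclass(params)))
}

## Reassign connected components smaller than min_px to the majority class
## of their dilated border.
merge_small_components <- function(labels, in_well, min_px) {
  if (min_px <= 0) return(labels)
  for (code in c(WM_ISLAND, WM_NETWORK, WM_GAP)) {
    m <- labels == code
    if (!any(m)) next
    lab <- as_mat(EBImage::bwlabel(m))
    sizes <- tabulate(lab[lab > 0])
    small <- which(sizes < min_px)
    for (s in small) {
      comp <- lab == s
      ring <- as_mat(EBImage::dilate(
        EBImage::Image(comp * 1),
        EBImage::makeBrush(3, "box")
      )) > 0.5
      ring <- ring & !comp & in_well
      if (!any(ring)) next
      neigh <- labels[ring]
      neigh <- neigh[neigh != code]
      if (!length(neigh)) next
      labels[comp] <- as.integer(names(which.max(table(neigh))))
    }
  }
  labels
}

#' Calibrate segmentation parameters against ground truth
#'
#' Deterministic grid search maximizing the mean per-class Jaccard index of
#' [classify_regions()] output against ground-truth label maps over one or
#' more training scenes. The default parameter set is always part of the
#' grid, so the returned parameters never score below it. Ties resolve to
#' the earliest grid entry. If a training scene lacks a class entirely the
#' returned parameters carry a `"degenerate_training"` warning flag
#' attribute.
#'
#' @param scenes list of `well_scene` objects (or lists with `stack` and
#'   `truth`).
#' @param grid optional data frame of candidate parameter combinations with
#'   any subset of the [segmentation_params()] fields.
#' @param params baseline parameters completing unspecified fields.
#' @return The best-scoring [segmentation_params()]; attribute `score`
#'   holds its mean Jaccard, attribute `warning_flag` any degeneracy note.
#' @export
calibrate_params <- function(scenes, grid = NULL, params = segmentation_params()) {
  if (!length(scenes)) stop_wm("Empty training set.", "config_error")
  if (is.null(grid)) {
    grid <- expand.grid(
      island_core_radius_px = c(6L, 8L, 10L, 12L),
      island_density_min = c(0.25, 0.35, 0.45),
      KEEP.OUT.ATTRS = FALSE
    )
  }
  ## baseline first so ties can never beat the defaults
  base_row <- as.data.frame(unclass(params)[names(grid)])
  grid <- unique(rbind(base_row, grid))

  degenerate <- FALSE
  truths <- lapply(scenes, function(sc) {
    gt <- as_mat(sc$truth$labels)
    present <- WM_CLASSES %in% gt
    if (!all(present)) degenerate <<- TRUE
    gt
  })

  scores <- vapply(seq_len(nrow(grid)), function(i) {
    p <- params
    for (nm in names(grid)) p[[nm]] <- grid[[nm]][i]
    mean(vapply(seq_along(scenes), function(j) {
      sc <- scenes[[j]]
      bw <- binarize_ec(sc$stack$channels$EC, p, sc$truth$geom)
      pred <- as_mat(classify_regions(bw, sc$truth$geom, p))
      mean_class_jaccard(pred, truths[[j]])
    }, numeric(1)))
  }, numeric(1))

  best <- which.max(scores)
  out <- params
  for (nm in names(grid)) out[[nm]] <- grid[[nm]][best]
  out <- do.call(segmentation_params, unclass(out))
  attr(out, "score") <- scores[best]
  attr(out, "warning_flag") <- if (degenerate) "degenerate_training" else NULL
  out
}

#' Per-class Jaccard index between two label maps
#'
#' @param pred,truth integer label maps sharing the class codes.
#' @param classes named integer vector of codes to evaluate.
#' @return A named numeric vector of Jaccard indices (`NaN` for classes
#'   absent from both maps).
#' @export
class_jaccard <- function(pred, truth, classes = WM_CLASSES) {
  pred <- as_mat(pred)
  truth <- as_mat(truth)
  vapply(classes, function(code) {
    a <- pred == code
    b <- truth == code
    u <- sum(a | b)
    if (u == 0) return(NaN)
    sum(a & b) / u
  }, numeric(1))
}

mean_class_jaccard <- function(pred, truth) {
  j <- class_jaccard(pred, truth)
  mean(j[is.finite(j)])
}

#' Flow-alignment order parameter per zone
#'
#' Quantifies how strongly the endothelial texture aligns with the local
#' flow direction. The local orientation of the EC membrane signal is
#' estimated from the smoothed structure tensor; within island pixels the
#' unsigned angle to the tangential flow direction enters
#' `order = mean(cos(2 * delta))`: 1 for perfect tangential alignment, 0
#' for isotropy, negative for radial bias. Pixels with negligible gradient
#' energy carry no orientation and are excluded; zones without usable
#' island pixels are reported as missing.
#'
#' @param ec EC channel image.
#' @param labelmap a `region_labelmap` restricting the estimate to island
#'   pixels.
#' @param geom a [well_geometry()].
#' @param tensor_sigma_px smoothing of the structure tensor.
#' @param energy_quantile pixels below this quantile of gradient energy
#'   (among island pixels) are treated as orientation-free.
#' @return A tibble with columns `zone`, `order`, `n_px`.
#' @export
alignment_order <- function(ec, labelmap, geom, tensor_sigma_px = 4,
                            energy_quantile = 0.25) {
  ec <- as_mat(ec)
  lab <- as_mat(labelmap)
  sobel_x <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  gx <- as_mat(EBImage::filter2(ec, sobel_x, boundary = "replicate"))
  gy <- as_mat(EBImage::filter2(ec, t(sobel_x), boundary = "replicate"))
  jxx <- blur_xy(gx * gx, tensor_sigma_px, boundary = "replicate")
  jyy <- blur_xy(gy * gy, tensor_sigma_px, boundary = "replicate")
  jxy <- blur_xy(gx * gy, tensor_sigma_px, boundary = "replicate")
  ## dominant gradient orientation; the texture (edge) runs perpendicular
  phi <- 0.5 * atan2(2 * jxy, jxx - jyy)
  edge_or <- phi + pi / 2
  energy <- jxx + jyy

  tangent <- tangent_angle_map(geom, dim(ec))
  delta <- ((edge_or - tangent + pi / 2) %% pi) - pi / 2
  zm <- zone_map(geom, dim(ec))

  purrr::map_dfr(c("center", "periphery"), function(z) {
    sel <- lab == WM_ISLAND & zm == z
    if (!any(sel)) {
      return(tibble(zone = z, order = NA_real_, n_px = 0L))
    }
    e <- energy[sel]
    floor_e <- quantile(e, energy_quantile, names = FALSE)
    ok <- sel & energy > pmax(floor_e, 1e-12)
    if (!any(ok)) {
      return(tibble(zone = z, order = NA_real_, n_px = 0L))
    }
    tibble(zone = z, order = mean(cos(2 * delta[ok])), n_px = sum(ok))
  })
}
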