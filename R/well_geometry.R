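#' Circular well geometry with a center/periphery partition
#'
#' Describes the circular culture well underlying a stitched mosaic: its
#' center and radius in pixel units, the physical pixel size, and the radial
#' fraction at which the well is split into a central zone (disturbed,
#' multidirectional flow on an orbital shaker) and a peripheral zone
#' (pulsatile, near-laminar flow). The default split at half the radius
#' follows the common practice of segmenting whole-well images at the middle
#' of the radial position.
#'
#' @param center_x,center_y well center in pixel coordinates.
#' @param radius_px well radius in pixels.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param split_fraction radial fraction in (0, 1) separating center from
#'   periphery. Points at exactly `split_fraction * radius_px` are assigned
#'   to the periphery (outward tie-break).
#' @param border_clipped logical; set by [fit_well()] when the fitted disk
#'   touches the image border and the radius is estimated from visible area.
#' @return An object of class `well_geometry`.
#' @examples
#' geom <- well_geometry(512, 512, 480)
#' zone_of(data.frame(x = 512, y = 512), geom)
#' @export
well_geometry <- function(center_x, center_y, radius_px, pixel_size_um = 4,
                          split_fraction = 0.5, border_clipped = FALSE) {
  if (!is.numeric(radius_px) || radius_px <= 0) {
    stop_wm("`radius_px` must be positive.", "geometry_error")
  }
  if (split_fraction <= 0 || split_fraction >= 1) {
    stop_wm("`split_fraction` must lie strictly between 0 and 1.", "geometry_error")
  }
  if (pixel_size_um <= 0) {
    stop_wm("`pixel_size_um` must be positive.", "geometry_error")
  }
  structure(
    list(
      center_x = as.numeric(center_x),
      center_y = as.numeric(center_y),
      radius_px = as.numeric(radius_px),
      pixel_size_um = as.numeric(pixel_size_um),
      split_fraction = as.numeric(split_fraction),
      border_clipped = isTRUE(border_clipped)
    ),
    class = "well_geometry"
  )
}

#' @export
print.well_geometry <- function(x, ...) {
  cat(sprintf(
    "<well_geometry> center (%.1f, %.1f) px, radius %.1f px (%.2f mm), split %.2f R%s\n",
    x$center_x, x$center_y, x$radius_px,
    x$radius_px * x$pixel_size_um / 1000, x$split_fraction,
    if (x$border_clipped) ", border-clipped" else ""
  ))
  invisible(x)
}

#' Fit the well disk from an image or mask
#'
#' Locates the circular well in a mosaic as the largest bright connected
#' component of a max-projection (or of an explicit logical mask), and
#' returns its centroid and equivalent-area radius. When the disk touches
#' the image border the radius is computed from the visible area and the
#' geometry is flagged `border_clipped`.
#'
#' @param x a `channel_stack`, a single-channel matrix, or a logical mask.
#' @param pixel_size_um pixel size to record; taken from the stack when
#'   available.
#' @param split_fraction forwarded to [well_geometry()].
#' @return A [well_geometry()] object.
#' @export
fit_well <- function(x, pixel_size_um = NULL, split_fraction = 0.5) {
  if (inherits(x, "channel_stack")) {
    pixel_size_um <- pixel_size_um %||% x$pixel_size_um
    proj <- Reduce(pmax, x$channels)
  } else {
    proj <- as_mat(x)
  }
  pixel_size_um <- pixel_size_um %||% 4
  if (is.logical(proj)) {
    bw <- proj
  } else {
    if (diff(range(proj)) == 0) {
      stop_wm("No disk found: image is constant.", "geometry_error")
    }
    bw <- proj >= otsu_threshold(as.numeric(proj))
  }
  if (!any(bw)) stop_wm("No disk found: empty foreground.", "geometry_error")
  lab <- as_mat(EBImage::bwlabel(bw))
  sizes <- tabulate(lab[lab > 0])
  big <- which.max(sizes)
  sel <- lab == big
  g <- pixel_grid(dim(sel))
  cx <- mean(g$x[sel])
  cy <- mean(g$y[sel])
  r <- sqrt(sum(sel) / pi)
  on_border <- any(sel[1, ]) || any(sel[nrow(sel), ]) ||
    any(sel[, 1]) || any(sel[, ncol(sel)])
  well_geometry(cx, cy, r,
    pixel_size_um = pixel_size_um,
    split_fraction = split_fraction, border_clipped = on_border
  )
}

#' Assign points to well zones
#'
#' Labels points (or all pixels of a raster) as `"center"`, `"periphery"` or
#' `"outside"` by radial distance from the well center. A point at radial
#' distance `r` is central when `r < split_fraction * radius`, peripheral
#' when `split_fraction * radius <= r <= radius` (the boundary is assigned
#' outward), and outside beyond the rim.
#'
#' @param points a data frame with columns `x` and `y` (pixel coordinates).
#' @param geom a [well_geometry()].
#' @return A character vector of zone labels, one per row of `points`.
#' @seealso [zone_map()] for a full-raster version.
#' @export
zone_of <- function(points, geom) {
  stopifnot(inherits(geom, "well_geometry"))
  r <- sqrt((points$x - geom$center_x)^2 + (points$y - geom$center_y)^2)
  split_r <- geom$split_fraction * geom$radius_px
  dplyr::case_when(
    r > geom$radius_px ~ "outside",
    r < split_r ~ "center",
    TRUE ~ "periphery"
  )
}

#' Zone label raster for a well
#'
#' @param geom a [well_geometry()].
#' @param dim_yx integer vector `c(ny, nx)` of the raster size.
#' @return A character matrix of `"center"`, `"periphery"`, `"outside"`.
#' @export
zone_map <- function(geom, dim_yx) {
  g <- pixel_grid(dim_yx)
  r <- sqrt((g$x - geom$center_x)^2 + (g$y - geom$center_y)^2)
  split_r <- geom$split_fraction * geom$radius_px
  out <- matrix("outside", dim_yx[1], dim_yx[2])
  out[r <= geom$radius_px] <- "periphery"
  out[r < split_r] <- "center"
  out
}

radius_map <- function(geom, dim_yx) {
  g <- pixel_grid(dim_yx)
  sqrt((g$x - geom$center_x)^2 + (g$y - geom$center_y)^2)
}

#' Local flow direction on the orbital shaker
#'
#' Returns the tangential unit vector (counter-clockwise when the image is
#' viewed in its standard orientation) at each query point. The direction of
#' the rotating wave is tangential at every radius; at the well center the
#' direction is undefined and a null direction is returned. Alignment
#' metrics built on this field use unsigned angles, so the handedness
#' convention does not affect any observable.
#'
#' @param geom a [well_geometry()].
#' @param points data frame with columns `x`, `y`.
#' @param eps_px radius below which the direction is reported null.
#' @return A tibble with columns `x`, `y`, `tx`, `ty` (unit tangent; `ty`
#'   negative means toward the top of the image) and `null_direction`.
#' @export
flow_direction <- function(geom, points, eps_px = 1e-6) {
  ux <- points$x - geom$center_x
  uy <- points$y - geom$center_y
  r <- sqrt(ux^2 + uy^2)
  null_dir <- r < eps_px
  tx <- ifelse(null_dir, NA_real_, uy / r)
  ty <- ifelse(null_dir, NA_real_, -ux / r)
  tibble(
    x = points$x, y = points$y,
    tx = tx, ty = ty, null_direction = null_dir
  )
}

## Tangential orientation angle (mod pi) of the flow at each pixel.
tangent_angle_map <- function(geom, dim_yx) {
  g <- pixel_grid(dim_yx)
  ux <- g$x - geom$center_x
  uy <- g$y - geom$center_y
  ## orientation of the tangent line; atan2(-ux, uy) gives the tangent
  ## vector's angle, reduced mod pi downstream
  atan2(-ux, uy)
}

#' Annular-sector regions of interest
#'
#' Partitions each zone of the well into `n_rois` equal angular sectors, the
#' standard way of sampling local variance of coverage statistics across a
#' well. ROI ids are `1..n_rois` within each zone.
#'
#' @param geom a [well_geometry()].
#' @param dim_yx raster size `c(ny, nx)`.
#' @param n_rois sectors per zone.
#' @return An integer matrix of ROI ids (`NA` outside the well).
#' @export
roi_map <- function(geom, dim_yx, n_rois = 8L) {
  stopifnot(n_rois >= 1)
  g <- pixel_grid(dim_yx)
  theta <- atan2(g$y - geom$center_y, g$x - geom$center_x)
  sector <- pmin(floor((theta + pi) / (2 * pi) * n_rois) + 1L, n_rois)
  out <- matrix(NA_integer_, dim_yx[1], dim_yx[2])
  zm <- zone_map(geom, dim_yx)
  inw <- zm != "outside"
  out[inw] <- sector[inw]
  out
}

#' Serialize / read well geometry as YAML
#'
#' @param geom a [well_geometry()].
#' @param path file path.
#' @return `write_geometry()` returns `path` invisibly; `read_geometry()`
#'   returns a [well_geometry()].
#' @export
write_geometry <- function(geom, path) {
  yaml::write_yaml(unclass(geom), path)
  invisible(path)
}

#' @rdname write_geometry
#' @export
read_geometry <- function(path) {
  v <- yaml::read_yaml(path)
  well_geometry(v$center_x, v$center_y, v$radius_px,
    pixel_size_um = v$pixel_size_um,
    split_fraction = v$split_fraction,
    border_clipped = isTRUE(v$border_clipped)
  )
}
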