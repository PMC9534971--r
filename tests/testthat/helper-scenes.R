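## Shared scene cache: most tests exercise the same moderate-size synthetic
## wells, so scenes are generated once per session and reused.
.wm_cache <- new.env(parent = emptyenv())

wm_scene <- function(model = "IH_low_density", condition = "shear", seed = 7,
                     well_radius_px = 220, canvas_px = 480, ...) {
  key <- paste(model, condition, seed, well_radius_px, canvas_px,
    rlang::hash(list(...)),
    sep = "|"
  )
  if (is.null(.wm_cache[[key]])) {
    cfg <- scene_config(
      model = model, condition = condition, seed = seed,
      well_radius_px = well_radius_px, canvas_px = canvas_px, ...
    )
    .wm_cache[[key]] <- generate_scene(cfg)
  }
  .wm_cache[[key]]
}

wm_fixtures <- function() {
  if (is.null(.wm_cache$fixtures)) {
    .wm_cache$fixtures <- build_fixtures()
  }
  .wm_cache$fixtures
}

wm_segmented <- function(scene) {
  key <- paste0("seg|", rlang::hash(scene$truth$config))
  if (is.null(.wm_cache[[key]])) {
    geom <- scene$truth$geom
    bw <- binarize_ec(scene$stack$channels$EC, geom = geom)
    .wm_cache[[key]] <- classify_regions(bw, geom)
  }
  .wm_cache[[key]]
}

wm_detected <- function(scene, labelmap = NULL) {
  key <- paste0("det|", rlang::hash(scene$truth$config), is.null(labelmap))
  if (is.null(.wm_cache[[key]])) {
    nu <- detect_nuclei(
      scene$stack$channels$DAPI, scene$stack$channels$ERG1,
      scene$stack$channels$Ki67,
      geom = scene$truth$geom
    )
    lab <- labelmap %||% scene$truth$labels
    .wm_cache[[key]] <- assign_regions(nu, lab, scene$truth$geom)
  }
  .wm_cache[[key]]
}

## Greedy nearest matching of detected points to ground-truth points.
match_points <- function(truth, detected, max_dist = 5) {
  if (!nrow(truth) || !nrow(detected)) {
    return(list(hits = 0, pairs = integer(0)))
  }
  used <- rep(FALSE, nrow(detected))
  pairs <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    d2 <- (detected$x - truth$x[i])^2 + (detected$y - truth$y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= max_dist^2) {
      used[j] <- TRUE
      pairs[i] <- j
    }
  }
  list(hits = sum(!is.na(pairs)), pairs = pairs)
}

radius_map_test <- function(geom, dim_yx) wellmosaic:::radius_map(geom, dim_yx)

zone_fraction_of <- function(labels, geom, zone, code) {
  zm <- zone_map(geom, dim(labels))
  sel <- zm == zone
  mean(unclass(labels)[sel] == code)
}
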