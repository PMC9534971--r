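test_that("EC binarization recovers the ground-truth EC footprint", {
  sc <- wm_scene()
  gt <- sc$truth
  bw <- binarize_ec(sc$stack$channels$EC, geom = gt$geom)
  ec_gt <- unclass(gt$labels) %in% c(1L, 2L)
  dim(ec_gt) <- dim(bw)
  jac <- sum(bw & ec_gt) / sum(bw | ec_gt)
  expect_gte(jac, 0.8)
})

test_that("binarization handles degenerate inputs", {
  expect_equal(sum(binarize_ec(matrix(0, 60, 60))), 0)
  expect_equal(sum(binarize_ec(matrix(0.7, 60, 60))), 0)
})

test_that("Otsu binarization is invariant to a constant intensity offset", {
  sc <- wm_scene()
  ec <- sc$stack$channels$EC * 0.8
  bw0 <- binarize_ec(ec, geom = sc$truth$geom)
  bw1 <- binarize_ec(ec + 0.07, geom = sc$truth$geom)
  expect_identical(bw0, bw1)
})

test_that("internal Otsu threshold matches the brute-force criterion", {
  withr::with_seed(2, {
    v <- c(rnorm(4000, 0.2, 0.04), rnorm(2000, 0.7, 0.06))
  })
  v <- pmin(pmax(v, 0), 1)
  ours <- wellmosaic:::otsu_threshold(v)
  ## exhaustive maximization of the between-class variance
  cand <- sort(unique(round(v, 4)))
  bc <- vapply(cand, function(t) {
    w0 <- mean(v < t)
    if (w0 == 0 || w0 == 1) return(-Inf)
    (mean(v[v < t]) - mean(v[v >= t]))^2 * w0 * (1 - w0)
  }, numeric(1))
  expect_lt(abs(ours - cand[which.max(bc)]), 0.01)
})

test_that("region classification agrees with ground truth in both zones", {
  sc <- wm_scene()
  gt <- sc$truth
  lab <- wm_segmented(sc)
  zm <- zone_map(gt$geom, dim(lab))
  for (z in c("center", "periphery")) {
    sel <- zm == z
    agreement <- mean(unclass(lab)[sel] == unclass(gt$labels)[sel])
    expect_gte(agreement, 0.85)
  }
})

test_that("the confluent and pure-network limits classify correctly", {
  conf <- wm_scene("high_density", "shear",
    seed = 9, well_radius_px = 130,
    canvas_px = 290, island_fraction = 0.95, network_fraction = 0.02
  )
  lab <- wm_segmented(conf)
  zm <- zone_map(conf$truth$geom, dim(lab))
  in_well <- zm != "outside"
  expect_gte(mean(unclass(lab)[in_well] == 1L), 0.9)
  expect_lte(mean(unclass(lab)[in_well] == 2L), 0.05)

  pure <- wm_scene("IH_low_density", "shear",
    seed = 9, well_radius_px = 130,
    canvas_px = 290, island_fraction = 0, network_fraction = 0.25
  )
  labp <- wm_segmented(pure)
  zmp <- zone_map(pure$truth$geom, dim(labp))
  expect_lte(mean(unclass(labp)[zmp != "outside"] == 1L), 0.05)
})

test_that("island, network and gap partition the well for any input", {
  sc <- wm_scene()
  lab <- wm_segmented(sc)
  zm <- zone_map(sc$truth$geom, dim(lab))
  in_well <- zm != "outside"
  codes <- unclass(lab)
  expect_equal(
    sum(codes == 0L) + sum(codes == 1L) + sum(codes == 2L),
    sum(in_well)
  )
  expect_true(all(codes[!in_well] == 255L))
  expect_true(all(codes[in_well] %in% c(0L, 1L, 2L)))
})

test_that("classification is equivariant under a 90-degree rotation", {
  sc <- wm_scene("IH_low_density", "shear",
    seed = 21, well_radius_px = 100,
    canvas_px = 222
  )
  geom <- sc$truth$geom
  ec <- sc$stack$channels$EC
  rot90 <- function(m) t(m[nrow(m):1, ])
  p <- segmentation_params()
  lab <- classify_regions(binarize_ec(ec, p, geom), geom, p)
  lab_rot <- classify_regions(binarize_ec(rot90(ec), p, geom), geom, p)
  agreement <- mean(unclass(lab_rot) == rot90(unclass(lab)))
  expect_gte(agreement, 0.98)
})

test_that("raising the island density floor never grows the island class", {
  sc <- wm_scene()
  geom <- sc$truth$geom
  bw <- binarize_ec(sc$stack$channels$EC, geom = geom)
  areas <- vapply(c(0.2, 0.5, 0.8), function(th) {
    p <- segmentation_params(island_density_min = th, min_object_px = 0L)
    sum(unclass(classify_regions(bw, geom, p)) == 1L)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("parameter calibration is deterministic and never below default", {
  scenes <- lapply(c(3, 4), function(s) {
    wm_scene("IH_low_density", "shear",
      seed = s, well_radius_px = 110,
      canvas_px = 240
    )
  })
  grid <- expand.grid(
    island_core_radius_px = c(6L, 8L, 10L),
    island_density_min = c(0.25, 0.35)
  )
  p1 <- calibrate_params(scenes, grid = grid)
  p2 <- calibrate_params(scenes, grid = grid)
  expect_identical(unclass(p1), unclass(p2))

  default_score <- mean(vapply(scenes, function(sc) {
    bw <- binarize_ec(sc$stack$channels$EC, geom = sc$truth$geom)
    lab <- classify_regions(bw, sc$truth$geom)
    wellmosaic:::mean_class_jaccard(unclass(lab), unclass(sc$truth$labels))
  }, numeric(1)))
  expect_gte(attr(p1, "score"), default_score)

  expect_error(calibrate_params(list()), class = "wellmosaic_config_error")
})

test_that("degenerate all-gap training flags a warning", {
  sc <- wm_scene("monoculture_SMC", "shear",
    seed = 6, well_radius_px = 90,
    canvas_px = 200
  )
  p <- calibrate_params(list(sc), grid = data.frame(island_density_min = 0.35))
  expect_equal(attr(p, "warning_flag"), "degenerate_training")
})

test_that("flow alignment is tangential at the sheared periphery only", {
  sc <- wm_scene()
  ao <- alignment_order(sc$stack$channels$EC, wm_segmented(sc), sc$truth$geom)
  peri <- ao$order[ao$zone == "periphery"]
  ctr <- ao$order[ao$zone == "center"]
  expect_gt(peri, ctr)
  expect_gt(peri, 0.2)

  static <- wm_scene("quiescent", "static", seed = 7)
  aos <- alignment_order(
    static$stack$channels$EC, wm_segmented(static), static$truth$geom
  )
  expect_true(all(abs(aos$order) <= 0.1))
})

test_that("orientation-free islands report missing alignment", {
  geom <- well_geometry(51, 51, 40)
  lab <- wellmosaic:::new_labelmap(matrix(1L, 101, 101))
  ao <- alignment_order(matrix(0.5, 101, 101), lab, geom)
  expect_true(all(is.na(ao$order)))
})
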