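test_that("invalid scene configurations are rejected", {
  expect_error(
    scene_config(island_fraction = 0.7, network_fraction = 0.5),
    class = "wellmosaic_config_error"
  )
  expect_error(
    scene_config(island_fraction = -0.1),
    class = "wellmosaic_config_error"
  )
  expect_error(
    scene_config(corrugation_multiplier = 0.5),
    class = "wellmosaic_config_error"
  )
  expect_error(
    scene_config(well_radius_px = 300, canvas_px = 500),
    class = "wellmosaic_geometry_error"
  )
  expect_error(
    scene_config(prolif_rates = list(smc = 1.4, ec = 0.1)),
    class = "wellmosaic_config_error"
  )
})

test_that("ground-truth area fractions hit the configured targets per zone", {
  ## the spec case: island 0.3 / network 0.2, counted directly on GT pixels
  sc <- wm_scene("IH_low_density", "shear",
    seed = 1, well_radius_px = 150,
    canvas_px = 330, island_fraction = 0.3, network_fraction = 0.2
  )
  gt <- sc$truth
  for (z in c("center", "periphery")) {
    expect_lt(abs(zone_fraction_of(gt$labels, gt$geom, z, 1L) - 0.3), 0.03)
    expect_lt(abs(zone_fraction_of(gt$labels, gt$geom, z, 2L) - 0.2), 0.03)
  }
  ## and for the asymmetric high-density preset
  sc2 <- wm_scene("high_density", "shear",
    seed = 4, well_radius_px = 150,
    canvas_px = 330
  )
  cfg2 <- sc2$truth$config
  for (z in c("center", "periphery")) {
    expect_lt(
      abs(zone_fraction_of(sc2$truth$labels, sc2$truth$geom, z, 1L) -
        cfg2$island_fraction[[z]]), 0.03
    )
    expect_lt(
      abs(zone_fraction_of(sc2$truth$labels, sc2$truth$geom, z, 2L) -
        cfg2$network_fraction[[z]]), 0.03
    )
  }
})

test_that("an EC-free configuration renders background only", {
  sc <- wm_scene("IH_low_density", "shear",
    seed = 2, well_radius_px = 100,
    canvas_px = 220, island_fraction = 0, network_fraction = 0
  )
  expect_equal(sum(sc$truth$nuclei$is_ec), 0)
  expect_lt(mean(sc$stack$channels$EC), 0.05)
  expect_equal(sum(unclass(sc$truth$labels) %in% c(1L, 2L)), 0)
})

test_that("identical config and seed give bit-identical scenes", {
  cfg <- scene_config(
    model = "IH_low_density", seed = 31,
    well_radius_px = 90, canvas_px = 200
  )
  a <- generate_scene(cfg)
  b <- generate_scene(cfg)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  expect_identical(unclass(a$truth$labels), unclass(b$truth$labels))
})

test_that("ground truth is independent of the imaging noise settings", {
  base <- list(
    model = "IH_low_density", seed = 13, well_radius_px = 90, canvas_px = 200
  )
  a <- generate_scene(do.call(scene_config, base))
  b <- generate_scene(do.call(scene_config, c(base, list(
    noise = list(gaussian_sd = 0.05, poisson_scale = 50, vignette_amplitude = 0.12)
  ))))
  expect_identical(unclass(a$truth$labels), unclass(b$truth$labels))
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  expect_identical(a$truth$corrugation_mask, b$truth$corrugation_mask)
})

test_that("corrugations exist only under EC defects and Fn avoids islands", {
  sc <- wm_scene()
  gt <- sc$truth
  island <- unclass(gt$labels) == 1L
  expect_equal(sum(gt$corrugation_mask & island), 0)
  defect <- unclass(gt$labels) %in% c(0L, 2L)
  expect_lte(mean(gt$fn_mask[island]), mean(gt$fn_mask[defect]))
})

test_that("proliferation flags are Bernoulli at the configured rates", {
  sc <- wm_scene()
  nuc <- sc$truth$nuclei
  cfg <- sc$truth$config
  smc <- nuc[!nuc$is_ec, ]
  by_cell <- dplyr::summarise(
    dplyr::group_by(smc, zone, region_class),
    n = dplyr::n(), rate = mean(is_proliferative), .groups = "drop"
  )
  by_cell <- by_cell[by_cell$n >= 100, ]
  expect_gt(nrow(by_cell), 3)
  for (i in seq_len(nrow(by_cell))) {
    p <- cfg$prolif_rates$smc[[by_cell$zone[i]]][[by_cell$region_class[i]]]
    tol <- 3 * sqrt(p * (1 - p) / by_cell$n[i])
    expect_lt(abs(by_cell$rate[i] - p), tol)
  }
  ## EC nuclei only under EC signal
  idx <- cbind(round(nuc$y[nuc$is_ec]), round(nuc$x[nuc$is_ec]))
  expect_true(all(unclass(sc$truth$labels)[idx] %in% c(1L, 2L)))
})

test_that("time series follows the schedule and enforces the transition", {
  base <- scene_config(
    model = "IH_low_density", seed = 5,
    well_radius_px = 110, canvas_px = 240
  )
  sched <- data.frame(
    island_fraction = c(0.05, 0.25, 0.40),
    network_fraction = c(0.45, 0.25, 0.10)
  )
  series <- generate_time_series(base, sched)
  expect_length(series, 3)
  for (i in 1:3) {
    gt <- series[[i]]$truth
    for (z in c("center", "periphery")) {
      expect_lt(
        abs(zone_fraction_of(gt$labels, gt$geom, z, 1L) - sched$island_fraction[i]),
        0.03
      )
      expect_lt(
        abs(zone_fraction_of(gt$labels, gt$geom, z, 2L) - sched$network_fraction[i]),
        0.03
      )
    }
  }
  ## geometry shared across days
  expect_equal(series[[1]]$truth$geom, series[[3]]$truth$geom)

  ## single-entry schedule reproduces generate_scene exactly
  single <- generate_time_series(base, sched[2, ], transition = FALSE)
  direct <- generate_scene(scene_config(
    model = "IH_low_density", seed = 5, well_radius_px = 110, canvas_px = 240,
    island_fraction = sched$island_fraction[2],
    network_fraction = sched$network_fraction[2]
  ))
  expect_identical(single[[1]]$stack$channels, direct$stack$channels)
  expect_identical(single[[1]]$truth$nuclei, direct$truth$nuclei)

  ## contract violations
  bad <- data.frame(
    island_fraction = c(0.4, 0.2), network_fraction = c(0.1, 0.3)
  )
  expect_error(generate_time_series(base, bad), class = "wellmosaic_config_error")
  expect_error(
    generate_time_series(base, sched[0, ]),
    class = "wellmosaic_config_error"
  )
  ## the example schedule conserves total EC coverage; a shrinking total
  ## violates the conservation contract
  shrink <- data.frame(
    island_fraction = c(0.1, 0.2), network_fraction = c(0.4, 0.1)
  )
  expect_error(
    generate_time_series(base, shrink, conserve_total = TRUE, total_tol = 0.05),
    class = "wellmosaic_config_error"
  )
  expect_length(
    generate_time_series(base, sched, conserve_total = TRUE, total_tol = 0.01), 3
  )
})
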