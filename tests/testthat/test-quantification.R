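test_that("coverage fractions count ground-truth label pixels exactly", {
  sc <- wm_scene()
  gt <- sc$truth
  cov <- coverage_fractions(gt$labels, gt$geom)
  for (z in c("center", "periphery")) {
    isl <- cov$area_fraction[cov$zone == z & cov$region_class == "island"]
    net <- cov$area_fraction[cov$zone == z & cov$region_class == "network"]
    expect_equal(isl, 0.30, tolerance = 1e-3)
    expect_equal(net, 0.20, tolerance = 1e-3)
    ## total EC = island + network
    tot <- cov$area_fraction[cov$zone == z & cov$region_class == "ec_total"]
    expect_equal(tot, isl + net, tolerance = 1e-12)
    ## partition: fractions sum to one at machine precision
    main <- cov$area_fraction[cov$zone == z &
      cov$region_class %in% c("island", "network", "gap")]
    expect_equal(sum(main), 1, tolerance = 1e-12)
  }
})

test_that("an all-gap label map yields (0, 0, 1) fractions", {
  geom <- well_geometry(41, 41, 30)
  m <- matrix(255L, 81, 81)
  m[radius_map_test(geom, c(81, 81)) <= 30] <- 0L
  cov <- coverage_fractions(wellmosaic:::new_labelmap(m), geom)
  for (z in c("center", "periphery")) {
    expect_equal(cov$area_fraction[cov$zone == z & cov$region_class == "gap"], 1)
    expect_equal(cov$area_fraction[cov$zone == z & cov$region_class == "island"], 0)
  }
})

test_that("per-ROI coverage exposes local variance and keeps the partition", {
  sc <- wm_scene()
  cov <- coverage_fractions(sc$truth$labels, sc$truth$geom, rois = 8)
  expect_setequal(unique(cov$roi), 1:8)
  sums <- dplyr::summarise(
    dplyr::group_by(cov, zone, roi),
    s = sum(area_fraction), .groups = "drop"
  )
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)
  ## island coverage varies across ROIs (local variance is real)
  isl <- cov$area_fraction[cov$region_class == "island"]
  expect_gt(stats::sd(isl), 0)
})

test_that("nucleus detection matches ground truth with high fidelity", {
  sc <- wm_scene()
  gt <- sc$truth
  det <- detect_nuclei(
    sc$stack$channels$DAPI, sc$stack$channels$ERG1, sc$stack$channels$Ki67,
    geom = gt$geom
  )
  expect_gt(nrow(gt$nuclei), 3000)
  m <- match_points(gt$nuclei, det, max_dist = 5)
  recall <- m$hits / nrow(gt$nuclei)
  precision <- m$hits / nrow(det)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)

  ## marker identity accuracy on matched pairs
  ok <- !is.na(m$pairs)
  ec_acc <- mean(det$is_ec[m$pairs[ok]] == gt$nuclei$is_ec[ok])
  prolif_acc <- mean(det$is_proliferative[m$pairs[ok]] == gt$nuclei$is_proliferative[ok])
  expect_gte(ec_acc, 0.95)
  expect_gte(prolif_acc, 0.95)
})

test_that("blank channels yield an empty nucleus table, missing markers NA", {
  det <- detect_nuclei(matrix(0, 50, 50))
  expect_equal(nrow(det), 0)

  sc <- wm_scene()
  det2 <- detect_nuclei(sc$stack$channels$DAPI, erg1 = NULL, ki67 = NULL,
    geom = sc$truth$geom)
  expect_gt(nrow(det2), 0)
  expect_true(all(is.na(det2$is_ec)))
})

test_that("proliferation percentages follow the counting rule", {
  nuc <- tibble::tibble(
    x = 1, y = 1,
    zone = "periphery", region_class = "gap",
    is_ec = FALSE,
    is_proliferative = rep(c(TRUE, FALSE), c(10, 90))
  )
  pr <- proliferation_by_region(nuc)
  expect_equal(
    pr$smc_prolif_pct[pr$zone == "periphery" & pr$region_class == "gap"], 10
  )
  ## cells under n_min are missing, never zero
  expect_true(is.na(pr$smc_prolif_pct[pr$zone == "center" & pr$region_class == "gap"]))
  expect_equal(pr$n_smc[pr$zone == "center" & pr$region_class == "gap"], 0L)
})

test_that("configured proliferation rates are recovered through detection", {
  sc <- wm_scene()
  cfg <- sc$truth$config
  nuc <- wm_detected(sc)
  pr <- proliferation_by_region(nuc)
  pr <- pr[!is.na(pr$smc_prolif_pct) & pr$n_smc >= 100, ]
  expect_gt(nrow(pr), 3)
  for (i in seq_len(nrow(pr))) {
    p <- cfg$prolif_rates$smc[[pr$zone[i]]][[pr$region_class[i]]]
    tol <- 3 * sqrt(p * (1 - p) / pr$n_smc[i])
    expect_lt(abs(pr$smc_prolif_pct[i] / 100 - p), tol)
  }
})

test_that("the SMC layering index recovers the corrugation multiplier", {
  sc <- wm_scene()
  idx <- smc_layering_index(sc$stack$channels$SMC, sc$truth$labels, sc$truth$geom)
  expect_equal(
    idx$smc_intensity_norm[idx$region_class == "island"], c(1, 1)
  )
  defect <- idx$smc_intensity_norm[idx$region_class %in% c("gap", "network")]
  expect_true(all(defect >= 2 & defect <= 3))
})

test_that("layering index is exactly 1 for a uniform SMC field and gain-proof", {
  geom <- well_geometry(41, 41, 30)
  inw <- radius_map_test(geom, c(81, 81)) <= 30
  smc <- matrix(0, 81, 81)
  smc[inw] <- 0.5
  m <- matrix(255L, 81, 81)
  m[inw] <- rep_len(c(0L, 1L, 2L), sum(inw))
  lab <- wellmosaic:::new_labelmap(m)
  idx <- smc_layering_index(smc, lab, geom)
  expect_equal(idx$smc_intensity_norm, rep(1, 6), tolerance = 1e-12)

  sc <- wm_scene()
  i1 <- smc_layering_index(sc$stack$channels$SMC, sc$truth$labels, sc$truth$geom)
  i2 <- smc_layering_index(2.3 * sc$stack$channels$SMC, sc$truth$labels, sc$truth$geom)
  expect_equal(i1$smc_intensity_norm, i2$smc_intensity_norm, tolerance = 1e-12)
})

test_that("radial profiles obey the 0-255 min-max contract", {
  sc <- wm_scene()
  pr <- radial_profiles(sc$stack, sc$truth$labels, sc$truth$geom, n_bins = 20)
  expect_equal(nrow(pr), 20)
  expect_equal(min(pr$smc_0_255, na.rm = TRUE), 0)
  expect_equal(max(pr$smc_0_255, na.rm = TRUE), 255)
  expect_equal(min(pr$fn_0_255, na.rm = TRUE), 0)
  expect_equal(max(pr$fn_0_255, na.rm = TRUE), 255)
  occ <- pr$frac_island + pr$frac_network + pr$frac_gap
  expect_equal(occ, rep(1, 20), tolerance = 1e-12)
})

test_that("the Fn/SMC ratio tracks endothelial defects across bins", {
  sc <- wm_scene()
  pr <- radial_profiles(sc$stack, sc$truth$labels, sc$truth$geom, n_bins = 30)
  pr <- pr[!is.na(pr$fn_over_smc), ]
  lo <- pr$fn_over_smc[pr$frac_island <= stats::median(pr$frac_island)]
  hi <- pr$fn_over_smc[pr$frac_island > stats::median(pr$frac_island)]
  expect_gt(mean(lo), mean(hi))
  ## ratio is gain invariant
  stack2 <- sc$stack
  stack2$channels <- lapply(stack2$channels, function(ch) ch * 1.7)
  pr2 <- radial_profiles(stack2, sc$truth$labels, sc$truth$geom, n_bins = 30)
  expect_equal(pr$fn_over_smc, pr2$fn_over_smc[!is.na(pr2$fn_over_smc)],
    tolerance = 1e-9
  )
})

test_that("uniform channels give flat rescaled profiles", {
  geom <- well_geometry(41, 41, 30)
  inw <- radius_map_test(geom, c(81, 81)) <= 30
  ch <- matrix(0, 81, 81)
  ch[inw] <- 0.4
  stack <- channel_stack(list(EC = ch, SMC = ch, Fn = ch, DAPI = ch))
  m <- matrix(255L, 81, 81)
  m[inw] <- 0L
  pr <- radial_profiles(stack, wellmosaic:::new_labelmap(m), geom, n_bins = 10)
  expect_equal(stats::sd(pr$smc_0_255), 0)
  expect_error(
    radial_profiles(stack, wellmosaic:::new_labelmap(m), geom, n_bins = 5),
    class = "wellmosaic_config_error"
  )

  ## a well extending past the canvas leaves its outermost annuli empty,
  ## which become missing rows rather than errors
  big <- well_geometry(41, 41, 60)
  m2 <- matrix(255L, 81, 81)
  m2[radius_map_test(big, c(81, 81)) <= 60] <- 0L
  pr2 <- radial_profiles(stack, wellmosaic:::new_labelmap(m2), big, n_bins = 30)
  expect_equal(nrow(pr2), 30)
  expect_true(is.na(pr2$smc_raw[1]) && pr2$n_px[1] == 0)
})

test_that("one-way ANOVA plus Tukey behaves across null and extreme cases", {
  ## type-I error under the null, 100 seeded replicates
  res <- withr::with_seed(101, {
    vapply(1:100, function(i) {
      df <- data.frame(
        g = rep(c("a", "b"), each = 20),
        v = rnorm(40)
      )
      glance(compare_groups(df, v, g))$p.value
    }, numeric(1))
  })
  expect_gte(mean(res > 0.05), 0.9)

  ## separated constant groups: p reported effectively zero, degenerate flag
  df0 <- data.frame(g = rep(c("a", "b"), each = 3), v = rep(c(0, 1), each = 3))
  fit0 <- compare_groups(df0, v, g)
  expect_true(glance(fit0)$degenerate)
  expect_lt(glance(fit0)$p.value, 1e-6)

  expect_error(
    compare_groups(data.frame(g = "a", v = 1:3), v, g),
    class = "wellmosaic_config_error"
  )
  expect_error(
    compare_groups(data.frame(g = c("a", "a", "b"), v = 1:3), v, g),
    class = "wellmosaic_config_error"
  )
})

test_that("Tukey-adjusted p-values dominate unadjusted pairwise p-values", {
  df <- withr::with_seed(17, data.frame(
    g = rep(letters[1:4], each = 8),
    v = rnorm(32) + rep(c(0, 0.3, 0.5, 1), each = 8)
  ))
  fit <- compare_groups(df, v, g)
  td <- tidy(fit)
  raw <- stats::pairwise.t.test(df$v, df$g, p.adjust.method = "none",
    pool.sd = TRUE)$p.value
  for (i in seq_len(nrow(td))) {
    gs <- strsplit(td$contrast[i], "-", fixed = TRUE)[[1]]
    p_raw <- raw[max(gs), min(gs)]
    expect_gte(td$adj.p.value[i] + 1e-12, p_raw)
  }
})

test_that("significance stars follow the caption thresholds", {
  stars <- wellmosaic:::p_stars(
    c(0.0005, 0.005, 0.05, 0.3, 0.7),
    sort(c("****" = 0.001, "***" = 0.01, "**" = 0.1, "*" = 0.5))
  )
  expect_equal(stars, c("****", "***", "**", "*", "ns"))
})
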