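test_that("zone assignment follows the radial rule with outward tie-break", {
  geom <- well_geometry(100, 100, 80, split_fraction = 0.5)
  pts <- data.frame(
    x = c(100, 100 + 40, 100 + 39.9, 100 + 80, 100 + 81),
    y = rep(100, 5)
  )
  expect_equal(
    zone_of(pts, geom),
    c("center", "periphery", "center", "periphery", "outside")
  )
})

test_that("center-zone area fraction converges to split_fraction^2", {
  geom <- well_geometry(0, 0, 1, split_fraction = 0.5)
  withr::with_seed(11, {
    n <- 40000
    r <- sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    pts <- data.frame(x = r * cos(th), y = r * sin(th))
    frac <- mean(zone_of(pts, geom) == "center")
  })
  ## 3 binomial SDs at n = 40000, p = 0.25
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / 40000))
})

test_that("zone assignment is rotation invariant about the well center", {
  geom <- well_geometry(50, 60, 40)
  withr::with_seed(3, {
    r <- sqrt(runif(500)) * 39.5
    th <- runif(500, 0, 2 * pi)
    pts <- data.frame(x = 50 + r * cos(th), y = 60 + r * sin(th))
    rot <- data.frame(
      x = 50 + r * cos(th + 1.1), y = 60 + r * sin(th + 1.1)
    )
  })
  expect_equal(zone_of(pts, geom), zone_of(rot, geom))
})

test_that("center and periphery pixels partition the well raster", {
  geom <- well_geometry(61, 61, 50)
  zm <- zone_map(geom, c(121, 121))
  in_well <- radius_map_test(geom, c(121, 121)) <= 50
  expect_equal(sum(zm == "center") + sum(zm == "periphery"), sum(in_well))
  expect_true(all(zm[!in_well] == "outside"))
})

test_that("flow direction is tangential, unit length, null at center", {
  geom <- well_geometry(100, 100, 80)
  ## due east -> tangent points north (toward image top)
  fd <- flow_direction(geom, data.frame(x = 150, y = 100))
  expect_equal(fd$tx, 0)
  expect_equal(fd$ty, -1)
  expect_false(fd$null_direction)

  ctr <- flow_direction(geom, data.frame(x = 100, y = 100))
  expect_true(ctr$null_direction)
  expect_true(is.na(ctr$tx))

  withr::with_seed(5, {
    pts <- data.frame(x = 100 + rnorm(50, sd = 20), y = 100 + rnorm(50, sd = 20))
  })
  fd <- flow_direction(geom, pts)
  expect_equal(sqrt(fd$tx^2 + fd$ty^2), rep(1, 50), tolerance = 1e-12)
  ## tangent is perpendicular to the radial vector
  dot <- fd$tx * (pts$x - 100) + fd$ty * (pts$y - 100)
  expect_equal(dot, rep(0, 50), tolerance = 1e-9)
})

test_that("fit_well recovers a synthetic disk and flags clipped wells", {
  dim_yx <- c(500, 500)
  g <- expand.grid(y = 1:500, x = 1:500)
  disk <- matrix(
    sqrt((g$x - 250)^2 + (g$y - 255)^2) <= 220, 500, 500
  )
  geom <- fit_well(disk * 0.9)
  expect_lt(abs(geom$center_x - 250), 2)
  expect_lt(abs(geom$center_y - 255), 2)
  expect_lt(abs(geom$radius_px - 220) / 220, 0.01)
  expect_false(geom$border_clipped)

  expect_error(fit_well(matrix(0, 50, 50)), class = "wellmosaic_geometry_error")

  clipped <- matrix(
    sqrt((g$x - 20)^2 + (g$y - 250)^2) <= 150, 500, 500
  )
  gc <- fit_well(clipped)
  expect_true(gc$border_clipped)
})

test_that("geometry round-trips through YAML", {
  geom <- well_geometry(123.5, 456.25, 480, pixel_size_um = 3.5,
    split_fraction = 0.45)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_geometry(geom, path)
  expect_equal(read_geometry(path), geom)
})

test_that("sector ROIs cover every in-well pixel exactly once per zone", {
  geom <- well_geometry(61, 61, 50)
  rm <- roi_map(geom, c(121, 121), n_rois = 8)
  zm <- zone_map(geom, c(121, 121))
  expect_true(all(!is.na(rm[zm != "outside"])))
  expect_true(all(is.na(rm[zm == "outside"])))
  expect_setequal(unique(na.omit(as.vector(rm))), 1:8)
})
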