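cal1 <- bimonthly_calendar(2020, 2020)

test_that("bimonthly_mean averages rasters whose timestamps fall in each period", {
  r <- list(matrix(10, 2, 2), matrix(20, 2, 2))
  d <- as.Date(c("2020-01-05", "2020-02-10"))
  out <- suppressWarnings(bimonthly_mean(r, d, cal1))
  expect_equal(out[, , 1], matrix(15, 2, 2))
  expect_true(all(is.na(out[, , 2:6])))
  # single raster in a period passes through
  out1 <- suppressWarnings(bimonthly_mean(list(matrix(7, 2, 2)),
                                          as.Date("2020-06-10"), cal1))
  expect_equal(out1[, , 3], matrix(7, 2, 2))
})

test_that("bimonthly_mean of an 8-day series equals the brute-force mean of covered timestamps", {
  # linearly increasing constants every 8 days over Jan-Feb
  d <- seq(as.Date("2020-01-04"), as.Date("2020-02-26"), by = 8)
  vals <- seq_along(d) * 1.5
  r <- lapply(vals, function(v) matrix(v, 3, 3))
  out <- suppressWarnings(bimonthly_mean(r, d, cal1))
  expect_equal(out[1, 1, 1], mean(vals))
})

test_that("bimonthly_mean commutes with affine unit changes", {
  set.seed(2)
  d <- seq(as.Date("2020-01-02"), as.Date("2020-12-28"), by = 8)
  r <- lapply(seq_along(d), function(i) matrix(rnorm(9), 3, 3))
  m1 <- bimonthly_mean(r, d, cal1)
  r2 <- lapply(r, function(m) 1.8 * m + 32)
  m2 <- bimonthly_mean(r2, d, cal1)
  expect_equal(m2, 1.8 * m1 + 32, ignore_attr = TRUE)
})

test_that("empty periods warn and produce all-NA rasters", {
  w <- capture_warnings(out <- bimonthly_mean(list(matrix(1, 2, 2)),
                                              as.Date("2020-01-15"), cal1))
  expect_length(w, 5L)  # one per empty period
  expect_true(all(grepl("no inputs", w)))
  expect_true(all(is.na(out[, , 2:6])))
})

mkscene <- function(v, date, cc, dim = c(4, 4)) {
  m <- matrix(v, dim[1], dim[2])
  list(red = m, nir = m, swir1 = m, date = as.Date(date), cloud_cover = cc)
}

test_that("compositing weights scenes by clearness and renormalizes over clear pixels", {
  sc <- list(mkscene(0.2, "2020-01-10", 0), mkscene(0.4, "2020-02-10", 0.5))
  out <- composite_reflectance(sc, cal1)
  expect_equal(out$red[1, 1, 1], (1 * 0.2 + 0.5 * 0.4) / 1.5)
  expect_equal(out$red[1, 1, 1], 0.26666667, tolerance = 1e-7)
  # a single clear scene passes through
  one <- composite_reflectance(list(mkscene(0.33, "2020-03-10", 0.2)), cal1)
  expect_equal(one$red[, , 2], matrix(0.33, 4, 4))
  # pixel cloudy in all scenes -> missing
  sc2 <- list(mkscene(0.2, "2020-05-10", 0.1), mkscene(0.4, "2020-06-10", 0.1))
  sc2[[1]]$red[1, 1] <- NA; sc2[[2]]$red[1, 1] <- NA
  out2 <- composite_reflectance(sc2, cal1)
  expect_true(is.na(out2$red[1, 1, 3]))
  expect_false(anyNA(out2$red[, , 3][-1]))
})

test_that("equal-weight compositing equals the unweighted mean; zero weights fall back", {
  set.seed(9)
  a <- matrix(runif(16), 4); b <- matrix(runif(16), 4)
  sc <- list(mkscene(0, "2020-01-10", 0.3), mkscene(0, "2020-02-10", 0.3))
  sc[[1]]$red <- a; sc[[2]]$red <- b
  out <- composite_reflectance(sc, cal1)
  expect_equal(out$red[, , 1], (a + b) / 2)
  # fully cloudy scenes: weights all zero at clear pixels -> unweighted mean
  scz <- list(mkscene(0.2, "2020-01-10", 1), mkscene(0.4, "2020-02-10", 1))
  expect_warning(outz <- composite_reflectance(scz, cal1), "unweighted")
  expect_equal(outz$red[1, 1, 1], 0.3)
})

test_that("downscaling reproduces constants exactly and linear fields to tolerance", {
  cg <- lue_grid(6, 5, 240)
  tg <- lue_grid(48, 40, 30)
  const <- downscale(matrix(3.7, 5, 6), cg, tg)
  expect_equal(const, matrix(3.7, 40, 48))
  # plane: f(x, y) = 2 + 0.01 x - 0.005 y evaluated at cell centers
  f <- function(x, y) 2 + 0.01 * x - 0.005 * y
  coarse <- outer(grid_ycoords(cg), grid_xcoords(cg),
                  function(y, x) f(x, y))
  fine <- downscale(coarse, cg, tg)
  truth <- outer(grid_ycoords(tg), grid_xcoords(tg), function(y, x) f(x, y))
  inside_x <- grid_xcoords(tg) >= min(grid_xcoords(cg)) &
    grid_xcoords(tg) <= max(grid_xcoords(cg))
  inside_y <- grid_ycoords(tg) >= min(grid_ycoords(cg)) &
    grid_ycoords(tg) <= max(grid_ycoords(cg))
  expect_lt(max(abs(fine[inside_y, inside_x] - truth[inside_y, inside_x])),
            1e-6)
})

test_that("downscaling a smooth field aggregates back to the coarse values within 5%", {
  cg <- lue_grid(8, 8, 240)
  tg <- lue_grid(64, 64, 30)
  smooth <- outer(seq_len(8), seq_len(8),
                  function(r, c) 10 + 3 * sin(r / 3) * cos(c / 3))
  fine <- downscale(smooth, cg, tg)
  # block means back to the coarse grid
  agg <- matrix(0, 8, 8)
  for (r in 1:8) for (c in 1:8)
    agg[r, c] <- mean(fine[(8 * r - 7):(8 * r), (8 * c - 7):(8 * c)])
  expect_lt(max(abs(agg - smooth) / abs(smooth)), 0.05)
})

test_that("degenerate single-cell coarse input fills with a constant, and a lower bound clamps", {
  cg <- lue_grid(1, 1, 960)
  tg <- lue_grid(8, 8, 30)
  expect_equal(downscale(matrix(5, 1, 1), cg, tg), matrix(5, 8, 8))
  # overshoot below the bound is clamped with a message
  cg2 <- lue_grid(4, 1, 120)
  tg2 <- lue_grid(16, 1, 30)
  expect_message(out <- downscale(matrix(c(3, 0.01, 0.01, 3), 1, 4),
                                  cg2, tg2, lower = 0),
                 "clamped")
  expect_true(all(out >= 0))
})

test_that("causal same-season gap fill uses past years only", {
  per <- expand.grid(period = 1:6, year = 2020:2021)[, c("year", "period")]
  arr <- array(0.5, c(2, 2, 12))
  arr[1, 1, 3] <- 0.7   # 2020 p3
  arr[1, 1, 9] <- NA    # 2021 p3 gap -> fill from 2020 p3
  arr[2, 2, 2] <- NA    # 2020 p2 gap, no past -> stays NA
  cube <- refl_cube(arr, arr, arr, per)
  filled <- gapfill_passthrough(cube)
  expect_equal(filled$red[1, 1, 9], 0.7)
  expect_true(is.na(filled$red[2, 2, 2]))
  # complete cube unchanged
  full <- refl_cube(array(0.4, c(2, 2, 12)), array(0.4, c(2, 2, 12)),
                    array(0.4, c(2, 2, 12)), per)
  expect_identical(gapfill_passthrough(full)$nir, full$nir)
})

test_that("driver unit conversions apply the documented factors", {
  expect_equal(suppressMessages(wm2_to_mj_day(100)), 8.64)
  expect_equal(suppressMessages(lst_k02_to_celsius(273.15 / 0.02)), 0)
})
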