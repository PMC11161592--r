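test_that("netCDF write/read round-trips values, coordinates and units", {
  dir <- withr::local_tempdir()
  set.seed(181)
  cube <- grid_cube(array(rnorm(3 * 4 * 5), c(3, 4, 5)),
                    lat = c(10.05, 10.15, 10.25),
                    lon = c(-0.15, -0.05, 0.05, 0.15),
                    time = 1:5, product = "demo")
  path <- file.path(dir, "demo.nc")
  write_product(cube, path)
  back <- read_product(path)
  expect_identical(back$values, cube$values)
  expect_equal(back$lat, cube$lat)
  expect_equal(back$lon, cube$lon)
  expect_equal(back$product, "demo")
  # refuses silent overwrite
  expect_error(write_product(cube, path), "refusing")
  expect_silent(invisible(write_product(cube, path, overwrite = TRUE)))
  # missing values survive as NA
  cube$values[2, 2, 2] <- NA
  write_product(cube, path, overwrite = TRUE)
  expect_true(is.na(read_product(path)$values[2, 2, 2]))
})

test_that("reader normalizes descending latitude and unknown variables fail loudly", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "desc.nc")
  lat_desc <- c(30.25, 30.15, 30.05)
  vals <- array(seq_len(3 * 2 * 2), c(2, 3, 2))   # lon, lat, day order
  dl <- ncdf4::ncdim_def("lon", "degrees_east", c(100.05, 100.15))
  da <- ncdf4::ncdim_def("lat", "degrees_north", lat_desc)
  dd <- ncdf4::ncdim_def("day", "day of year", 1:2)
  var <- ncdf4::ncvar_def("Ec", "mm day-1", list(dl, da, dd),
                          missval = -9999, prec = "double")
  nc <- ncdf4::nc_create(path, var)
  ncdf4::ncvar_put(nc, var, vals)
  ncdf4::nc_close(nc)
  cube <- read_product(path)
  expect_equal(cube$lat, rev(lat_desc))
  # row that was first (lat 30.25) must now be last
  expect_equal(cube$values[3, , 1], vals[, 1, 1])
  expect_error(read_product(path, "Tveg"), "available: Ec")
})

test_that("merged files follow the published naming and layout", {
  dir <- withr::local_tempdir()
  dates <- seq(as.Date("2002-01-01"), as.Date("2002-12-31"), by = 8)
  cube <- grid_cube(array(1, c(2, 2, length(dates))),
                    lat = c(0.05, 0.15), lon = c(0.05, 0.15), time = dates)
  path <- write_merged(cube, dir, 2002)
  expect_equal(basename(path), "Merged.Tveg.2002.nc")
  nc <- ncdf4::nc_open(path)
  expect_setequal(c(names(nc$dim), names(nc$var)), c("lat", "lon", "day", "Ec"))
  expect_equal(as.numeric(nc$dim$day$vals[1:3]), c(1, 9, 17))
  ncdf4::nc_close(nc)
  # leap year: daily time axis has 366 days
  dates_leap <- seq(as.Date("2004-01-01"), as.Date("2004-12-31"), by = 1)
  expect_length(dates_leap, 366)
  cube_leap <- grid_cube(array(0, c(1, 2, 366)), lat = 0.05,
                         lon = c(0.05, 0.15), time = dates_leap)
  p2 <- write_merged(cube_leap, dir, 2004)
  nc2 <- ncdf4::nc_open(p2)
  expect_equal(length(nc2$dim$day$vals), 366)
  ncdf4::nc_close(nc2)
})

test_that("regridding is exact on linear fields and conservative on masks", {
  lat <- seq(0.125, 0.875, by = 0.25)
  lon <- seq(0.125, 1.875, by = 0.25)
  # plane f(lat, lon) = 3 lat + 2 lon + 1
  f <- outer(3 * lat, rep(1, length(lon))) +
    outer(rep(1, length(lat)), 2 * lon + 1)
  cube <- grid_cube(array(f, c(length(lat), length(lon), 1)), lat, lon, 1)
  # identity regrid
  same <- regrid(cube, lat, lon)
  expect_equal(same$values, cube$values)
  # finer target inside the source extent: bilinear reproduces the plane
  lat2 <- seq(0.2, 0.8, by = 0.1)
  lon2 <- seq(0.2, 1.8, by = 0.1)
  fine <- regrid(cube, lat2, lon2)
  expect_equal(fine$values[, , 1],
               outer(3 * lat2, rep(1, length(lon2))) +
                 outer(rep(1, length(lat2)), 2 * lon2 + 1),
               tolerance = 1e-12)
  # constant field stays constant under refinement
  cc <- grid_cube(array(7, c(length(lat), length(lon), 1)), lat, lon, 1)
  expect_equal(max(abs(regrid(cc, lat2, lon2)$values - 7)), 0,
               tolerance = 1e-12)
  # nearest neighbour picks the closest source cell
  nn <- regrid(cube, c(0.13), c(0.13), method = "nearest")
  expect_equal(nn$values[1, 1, 1], f[1, 1])
  # masked source cell propagates to dependent target cells
  f2 <- cube
  f2$values[2, 2, 1] <- NA
  masked <- regrid(f2, c(0.3), c(0.3))  # between rows 1-2, cols 1-2
  expect_true(is.na(masked$values[1, 1, 1]))
  # disjoint extents rejected
  expect_error(regrid(cube, lat + 50, lon), "disjoint")
})
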