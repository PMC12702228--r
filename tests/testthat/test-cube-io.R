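test_that("container round-trip is the identity on data, axis and metadata", {
  cube <- make_test_cube(4, 4, 8)
  path <- tempfile(fileext = ".h5")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_identical(back$data, cube$data)
  expect_identical(back$wavenumbers, cube$wavenumbers)
  expect_equal(back$pixel_size, cube$pixel_size)
  expect_equal(back$integration_time, cube$integration_time)
  expect_equal(back$provenance, cube$provenance)
  unlink(path)
})

test_that("a 58 x 58 x 812 cube over 600-1800 1/cm round-trips with shape and axis intact", {
  set.seed(3)
  cube <- hyper_cube(as_float32(array(rnorm(58 * 58 * 812), c(58, 58, 812))),
                     seq(600, 1800, length.out = 812))
  path <- tempfile(fileext = ".h5")
  write_cube(cube, path)
  back <- read_cube(path)
  expect_identical(dim(back$data), c(58L, 58L, 812L))
  expect_identical(back$data, cube$data)
  expect_equal(back$wavenumbers[1], 600)
  expect_equal(back$wavenumbers[812], 1800)
  unlink(path)
})

test_that("container errors name the missing element and reject bad shapes", {
  cube <- make_test_cube()
  path <- tempfile(fileext = ".h5")
  # file missing the wavenumber axis
  rhdf5::h5createFile(path)
  rhdf5::h5write(cube$data, path, "cube")
  expect_error(read_cube(path), "wavenumber_cm1")
  unlink(path)
  # file missing the cube dataset
  rhdf5::h5createFile(path)
  rhdf5::h5write(cube$wavenumbers, path, "wavenumber_cm1")
  expect_error(read_cube(path), "/cube")
  unlink(path)
  # axis length mismatch
  rhdf5::h5createFile(path)
  rhdf5::h5write(cube$data, path, "cube")
  rhdf5::h5write(cube$wavenumbers[-1], path, "wavenumber_cm1")
  expect_error(read_cube(path), "shape error")
  unlink(path)
  expect_error(read_cube(tempfile()), "not found")
})

test_that("writing refuses to overwrite without the explicit flag", {
  cube <- make_test_cube()
  path <- tempfile(fileext = ".h5")
  write_cube(cube, path)
  expect_error(write_cube(cube, path), "overwrite")
  expect_silent(write_cube(cube, path, overwrite = TRUE))
  unlink(path)
})

test_that("cube validation enforces the container invariants", {
  expect_error(hyper_cube(matrix(1, 2, 2), 1:2), "3 axes")
  expect_error(hyper_cube(array(1, c(2, 2, 3)), c(1, 2)), "does not match")
  expect_error(hyper_cube(array(1, c(2, 2, 3)), c(3, 2, 1)),
               "strictly increasing")
  bad <- array(1, c(2, 2, 3)); bad[1] <- NaN
  expect_error(hyper_cube(bad, 1:3), "NaN")
})

test_that("min-max normalization follows the global scaling formula", {
  cube <- hyper_cube(array(c(0, 5, 10, 5, 0, 10, 10, 5), c(2, 2, 2)), c(1, 2))
  nz <- min_max_normalize(cube)
  expect_equal(sort(unique(as.numeric(nz$cube$data))), c(0, 0.5, 1))
  expect_equal(nz$scale$x_min, 0)
  expect_equal(nz$scale$x_max, 10)
  expect_false(nz$scale$degenerate)
})

test_that("a constant cube normalizes to zeros with the degenerate flag, not an error", {
  cube <- hyper_cube(array(7, c(3, 3, 4)), 1:4)
  nz <- min_max_normalize(cube)
  expect_true(nz$scale$degenerate)
  expect_true(all(nz$cube$data == 0))
  back <- denormalize_cube(nz$cube, nz$scale)
  expect_true(all(back$data == 7))
})

test_that("normalization inverts within 1e-6 relative error and is idempotent", {
  cube <- make_test_cube(5, 6, 10, seed = 8)
  nz <- min_max_normalize(cube)
  expect_equal(min(nz$cube$data), 0)
  expect_equal(max(nz$cube$data), 1)
  back <- denormalize_cube(nz$cube, nz$scale)
  expect_lt(max(abs(back$data - cube$data)) / max(abs(cube$data)), 1e-6)
  twice <- min_max_normalize(nz$cube)
  expect_lt(max(abs(twice$cube$data - nz$cube$data)), 1e-12)
})

test_that("normalization uses one global extremum pair, not per-band extrema", {
  # band 2 spans [10, 20] while band 1 spans [0, 100]: per-band scaling
  # would stretch band 2 to [0, 1]
  d <- array(0, c(2, 2, 2))
  d[, , 1] <- c(0, 50, 75, 100)
  d[, , 2] <- c(10, 12, 15, 20)
  nz <- min_max_normalize(hyper_cube(d, 1:2))
  expect_equal(max(nz$cube$data[, , 2]), 0.2)
  expect_gt(min(nz$cube$data[, , 2]), 0)
})

test_that("spectrum export writes the two-column table for a pixel", {
  cube <- make_test_cube()
  path <- tempfile(fileext = ".csv")
  export_spectrum(cube, 2, 3, path)
  tab <- read.csv(path)
  expect_named(tab, c("wavenumber_cm1", "intensity"))
  expect_equal(tab$intensity, cube$data[2, 3, ])
  expect_error(export_spectrum(cube, 99, 1, path), "outside")
  unlink(path)
})
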