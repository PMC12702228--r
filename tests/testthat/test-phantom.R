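test_that("component spectra are sums of lineshape kernels on the axis", {
  axis <- seq(500, 1800, length.out = 500)
  one <- spectral_component("p", cbind(center = 1450, fwhm = 20, amplitude = 1),
                            lineshape = "gaussian")
  s <- make_component_spectrum(one, axis)
  expect_equal(which.max(s), which.min(abs(axis - 1450)))
  expect_true(all(s >= 0))
  expect_equal(max(s), 1, tolerance = 1e-2)  # grid does not hit the center exactly

  empty <- spectral_component("none", cbind(center = numeric(0),
                                            fwhm = numeric(0),
                                            amplitude = numeric(0)))
  expect_equal(make_component_spectrum(empty, axis), numeric(500))

  # additivity: two well-separated peaks equal the sum of single peaks
  two <- spectral_component("q", cbind(center = c(800, 1600),
                                       fwhm = c(15, 25),
                                       amplitude = c(2, 1)))
  a <- spectral_component("a", cbind(center = 800, fwhm = 15, amplitude = 2))
  b <- spectral_component("b", cbind(center = 1600, fwhm = 25, amplitude = 1))
  expect_lt(max(abs(make_component_spectrum(two, axis) -
                      make_component_spectrum(a, axis) -
                      make_component_spectrum(b, axis))), 1e-12)

  out <- spectral_component("bad", cbind(center = 2000, fwhm = 10, amplitude = 1))
  expect_error(make_component_spectrum(out, axis), "outside the axis range")
  expect_error(make_component_spectrum(one, rev(axis)), "strictly increasing")
})

test_that("rendered cubes satisfy the linear mixing identity exactly", {
  ph <- render_phantom(tiny_phantom(seed = 5))
  recon <- array(tiny_phantom()$background_level, dim(ph$cube$data))
  for (k in seq_along(ph$abundance))
    recon <- recon + outer(ph$abundance[[k]], ph$spectra[[k]])
  expect_lt(max(abs(recon - ph$cube$data)), 1e-10)
  expect_true(all(unlist(ph$abundance) >= 0))
})

test_that("a cell-free phantom is uniform background everywhere", {
  spec <- tiny_phantom(n_cells = 0, background_level = 20)
  ph <- render_phantom(spec)
  # only background components remain; cube is constant in space
  flat <- apply(ph$cube$data, 3, function(m) max(m) - min(m))
  expect_true(all(flat < 1e-12))
  expect_true(all(ph$cube$data >= 20))
})

test_that("rendering is deterministic in the seed and varies across seeds", {
  a <- render_phantom(tiny_phantom(seed = 9))
  b <- render_phantom(tiny_phantom(seed = 9))
  c <- render_phantom(tiny_phantom(seed = 10))
  expect_identical(a$cube$data, b$cube$data)
  expect_gt(max(abs(a$cube$data - c$cube$data)), 0)
})

test_that("cell-bound abundance vanishes outside each cell's support", {
  ph <- render_phantom(tiny_phantom(seed = 2, n_cells = 2))
  cellish <- grep("^(protein|lipid|dna)\\.cell", names(ph$abundance), value = TRUE)
  expect_gt(length(cellish), 0)
  for (nm in cellish) {
    m <- ph$abundance[[nm]]
    expect_gt(sum(m > 0), 0)       # support exists
    expect_gt(sum(m == 0), 0)      # and is strictly inside the image
  }
  # nuclear (dna) support is contained in the union of cell supports
  cells <- Reduce(`|`, lapply(ph$abundance[grep("^protein", names(ph$abundance))],
                              function(m) m > 0))
  for (nm in grep("^dna", names(ph$abundance), value = TRUE))
    expect_true(all(cells[ph$abundance[[nm]] > 0]))
})

test_that("dataset generation is seeded per item and reproducible", {
  spec <- tiny_phantom()
  set3 <- generate_phantoms(spec, 3, base_seed = 40)
  expect_length(set3, 3)
  # pairwise distinct layouts
  expect_gt(max(abs(set3[[1]]$cube$data - set3[[2]]$cube$data)), 0)
  expect_gt(max(abs(set3[[2]]$cube$data - set3[[3]]$cube$data)), 0)
  # n = 1 collapses to render_phantom at the base seed
  spec1 <- spec; spec1$seed <- 40L
  expect_identical(generate_phantoms(spec, 1, base_seed = 40)[[1]]$cube$data,
                   render_phantom(spec1)$cube$data)
  # full regeneration is bit-identical
  again <- generate_phantoms(spec, 3, base_seed = 40)
  for (i in 1:3)
    expect_identical(set3[[i]]$cube$data, again[[i]]$cube$data)
})

test_that("non-overlap mode errors after bounded retries when cells cannot fit", {
  crowded <- tiny_phantom(n_cells = 30, allow_overlap = FALSE,
                          cell_radius_range = c(5, 5), seed = 1)
  expect_error(render_phantom(crowded), "without overlap")
})

test_that("phantom geometry is validated", {
  expect_error(phantom_spec(wn_start = 1800, wn_end = 500), "exceed")
  expect_error(phantom_spec(n_bands = 1), "n_bands")
  expect_error(phantom_spec(height = 8, width = 8, cell_radius_range = c(6, 10)),
               "do not fit")
})
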