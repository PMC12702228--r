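#' Define a spectral component for the phantom
#'
#' A named biochemical component (e.g. protein, lipid, DNA) as a sum of
#' peaks. Each peak is `(center, fwhm, amplitude)` in cm^-1 / cm^-1 /
#' arbitrary intensity units. Raman lines are near-Lorentzian, so the
#' Lorentzian lineshape is the default; a Gaussian is available.
#'
#' @param name Component label.
#' @param peaks Numeric matrix (or coercible data frame) with columns
#'   `center`, `fwhm`, `amplitude`. May have zero rows.
#' @param lineshape `"lorentzian"` (default) or `"gaussian"`.
#' @param abundance_range Length-2 numeric: per-cell abundance is drawn
#'   uniformly from this range.
#' @param region Where the component lives: `"cell"`, `"nucleus"` or
#'   `"background"`. Cell/nucleus components have zero abundance outside
#'   their region's support.
#' @return A `spectral_component` object.
#' @export
spectral_component <- function(name, peaks,
                               lineshape = c("lorentzian", "gaussian"),
                               abundance_range = c(0.5, 1),
                               region = c("cell", "nucleus", "background")) {
  lineshape <- match.arg(lineshape)
  region <- match.arg(region)
  peaks <- as.matrix(as.data.frame(peaks))
  if (ncol(peaks) > 0 && !all(c("center", "fwhm", "amplitude") %in% colnames(peaks)))
    stop("peaks must have columns center, fwhm, amplitude", call. = FALSE)
  if (nrow(peaks) > 0) {
    if (any(peaks[, "fwhm"] <= 0)) stop("peak fwhm must be > 0", call. = FALSE)
    if (any(peaks[, "amplitude"] < 0)) stop("peak amplitudes must be >= 0", call. = FALSE)
  }
  if (length(abundance_range) != 2 || diff(abundance_range) < 0 ||
      any(abundance_range < 0))
    stop("abundance_range must be nonnegative and nondecreasing", call. = FALSE)
  structure(list(name = name, peaks = peaks, lineshape = lineshape,
                 abundance_range = abundance_range, region = region),
            class = "spectral_component")
}

#' Default phantom component inventory
#'
#' Protein, lipid and DNA components with peak positions at well-known
#' Raman marker bands (phenylalanine 1003, CH2 deformation 1450, amide I
#' 1660, lipid 1078/1304/1746, nucleic-acid backbone 795/1095/1578 cm^-1).
#' Amplitudes are in detector-count scale so that Poisson shot noise is
#' meaningful on the rendered cubes.
#'
#' @param scale Multiplies all peak amplitudes (default 300 counts).
#' @return A list of [spectral_component] objects.
#' @export
default_components <- function(scale = 300) {
  pk <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    colnames(m) <- c("center", "fwhm", "amplitude")
    m[, "amplitude"] <- m[, "amplitude"] * scale
    m
  }
  list(
    spectral_component("protein",
                       pk(1003, 12, 0.9, 1450, 25, 0.7, 1660, 30, 1.0),
                       region = "cell"),
    spectral_component("lipid",
                       pk(1078, 20, 0.5, 1304, 22, 0.6, 1440, 20, 0.8, 1746, 18, 0.4),
                       region = "cell", abundance_range = c(0.2, 0.8)),
    spectral_component("dna",
                       pk(795, 15, 0.8, 1095, 18, 0.6, 1578, 16, 0.7),
                       region = "nucleus", abundance_range = c(0.6, 1.2))
  )
}

#' Specify a synthetic cellular phantom
#'
#' Geometry plus spectral recipe for a clean hyperspectral cube. Defaults
#' emulate a 64 x 64 px field of view over 500-1800 cm^-1; cells are
#' ellipses with a nucleus sub-ellipse carrying elevated DNA abundance.
#'
#' @param height,width Image size in pixels.
#' @param n_bands Number of spectral bands (>= 2).
#' @param wn_start,wn_end Wavenumber range in cm^-1 (`wn_end > wn_start`).
#' @param n_cells Number of cells to place (>= 0).
#' @param cell_radius_range Length-2 range of cell semi-axes in pixels;
#'   radii must fit inside the image.
#' @param components List of [spectral_component]s.
#' @param background_level Uniform background intensity (counts, >= 0).
#' @param blur_sigma Gaussian blur (pixels) applied to abundance maps so
#'   intensity line profiles are non-trivial; 0 disables.
#' @param allow_overlap Allow overlapping cells (default). When `FALSE`,
#'   placement retries up to 100 times per cell and then errors.
#' @param spectral_jitter List with `center_sd` (cm^-1), `fwhm_rel`,
#'   `amp_rel`: each cell carries its own spectral signature, with peak
#'   centers shifted by a Gaussian draw and widths/amplitudes scaled by
#'   relative uniform draws. This keeps rendered cubes from being exactly
#'   low-rank, as real cellular data is not; set all to 0 for shared
#'   spectra.
#' @param texture Relative amplitude of the smooth within-cell abundance
#'   variation (default 0.5 before blurring); 0 gives flat cells.
#' @param seed Integer RNG seed; identical specs render identical cubes.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(height = 64, width = 64, n_bands = 500,
                         wn_start = 500, wn_end = 1800,
                         n_cells = 3, cell_radius_range = c(6, 12),
                         components = default_components(),
                         background_level = 20, blur_sigma = 1,
                         allow_overlap = TRUE,
                         spectral_jitter = list(center_sd = 4,
                                                fwhm_rel = 0.15,
                                                amp_rel = 0.2),
                         texture = 0.5, seed = 1L) {
  if (wn_end <= wn_start) stop("wn_end must exceed wn_start", call. = FALSE)
  if (n_bands < 2) stop("n_bands must be >= 2", call. = FALSE)
  if (n_cells < 0) stop("n_cells must be >= 0", call. = FALSE)
  if (background_level < 0) stop("background_level must be >= 0", call. = FALSE)
  if (max(cell_radius_range) * 2 > min(height, width))
    stop("cell radii do not fit within the image", call. = FALSE)
  structure(list(height = height, width = width, n_bands = n_bands,
                 wn_start = wn_start, wn_end = wn_end, n_cells = n_cells,
                 cell_radius_range = cell_radius_range,
                 components = components,
                 background_level = background_level,
                 blur_sigma = blur_sigma, allow_overlap = allow_overlap,
                 spectral_jitter = spectral_jitter, texture = texture,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Evaluate a component's spectrum on a wavenumber axis
#'
#' Sum of the component's lineshape kernels. Lorentzian:
#' `a * g^2 / ((x - c)^2 + g^2)` with `g = fwhm / 2`; Gaussian:
#' `a * exp(-4 log(2) (x - c)^2 / fwhm^2)`. Both peak at amplitude `a`.
#'
#' @param component A [spectral_component].
#' @param axis Strictly increasing wavenumber axis (cm^-1).
#' @return Nonnegative numeric vector, `length(axis)`.
#' @export
make_component_spectrum <- function(component, axis) {
  if (length(axis) > 1 && any(diff(axis) <= 0))
    stop("axis must be strictly increasing", call. = FALSE)
  s <- numeric(length(axis))
  pk <- component$peaks
  if (nrow(pk) == 0) return(s)
  if (any(pk[, "center"] < min(axis)) || any(pk[, "center"] > max(axis)))
    stop(sprintf("component '%s' has a peak center outside the axis range",
                 component$name), call. = FALSE)
  for (i in seq_len(nrow(pk))) {
    c0 <- pk[i, "center"]; fwhm <- pk[i, "fwhm"]; a <- pk[i, "amplitude"]
    s <- s + if (component$lineshape == "lorentzian") {
      g <- fwhm / 2
      a * g^2 / ((axis - c0)^2 + g^2)
    } else {
      a * exp(-4 * log(2) * (axis - c0)^2 / fwhm^2)
    }
  }
  s
}

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# separable 2D Gaussian blur, reflecting edges; sigma in pixels
blur2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  reflect_idx <- function(i, n) {
    i <- abs(i - 1L) + 1L
    i[i > n] <- 2L * n - i[i > n] + 1L
    i
  }
  conv_rows <- function(x) {
    n <- nrow(x)
    out <- matrix(0, n, ncol(x))
    for (t in -r:r)
      out <- out + k[t + r + 1L] * x[reflect_idx(seq_len(n) + t, n), , drop = FALSE]
    out
  }
  t(conv_rows(t(conv_rows(m))))
}

# mask of an ellipse (and its nucleus) on an H x W grid
ellipse_mask <- function(h, w, cy, cx, ry, rx, theta) {
  yy <- matrix(seq_len(h), h, w) - cy
  xx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  u <- cos(theta) * yy + sin(theta) * xx
  v <- -sin(theta) * yy + cos(theta) * xx
  (u / ry)^2 + (v / rx)^2 <= 1
}

# draw a jittered copy of a component's spectral signature for one cell
jitter_component <- function(comp, jit, axis) {
  pk <- comp$peaks
  if (nrow(pk) > 0 && !is.null(jit)) {
    lo <- min(axis); hi <- max(axis)
    pk[, "center"] <- pmin(pmax(
      pk[, "center"] + stats::rnorm(nrow(pk), 0, jit$center_sd %||% 0),
      lo), hi)
    pk[, "fwhm"] <- pk[, "fwhm"] *
      stats::runif(nrow(pk), 1 - (jit$fwhm_rel %||% 0), 1 + (jit$fwhm_rel %||% 0))
    pk[, "amplitude"] <- pk[, "amplitude"] *
      stats::runif(nrow(pk), 1 - (jit$amp_rel %||% 0), 1 + (jit$amp_rel %||% 0))
  }
  comp$peaks <- pk
  comp
}

#' Render a clean phantom cube
#'
#' Places elliptical cells (each with a nucleus sub-ellipse carrying the
#' nuclear components), draws a per-cell abundance and a per-cell
#' spectral signature for every component (peak positions, widths and
#' amplitudes jittered per cell so the cube is not exactly low-rank),
#' modulates abundances with a smooth within-cell texture, blurs the
#' maps, and assembles the cube as the linear mixture
#' `background + sum_i abundance_i (outer) spectrum_i` over all rendered
#' component instances.
#'
#' @param spec A [phantom_spec].
#' @return A list with `cube` (the clean [hyper_cube]), `abundance`
#'   (named list of H x W maps, one per rendered component instance,
#'   named `component.cellN` for cell-bound components) and `spectra`
#'   (the matching length-B spectra). The cube equals the mixing sum of
#'   these returns to ~1e-10.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  axis <- seq(spec$wn_start, spec$wn_end, length.out = spec$n_bands)
  h <- spec$height; w <- spec$width

  res <- with_seed(spec$seed, {
    cell_mask <- matrix(FALSE, h, w)
    abundance <- list()
    spectra <- list()
    for (ci in seq_len(spec$n_cells)) {
      ok <- FALSE
      for (attempt in seq_len(100L)) {
        ry <- stats::runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
        rx <- stats::runif(1, spec$cell_radius_range[1], spec$cell_radius_range[2])
        cy <- stats::runif(1, 1 + ry, h - ry)
        cx <- stats::runif(1, 1 + rx, w - rx)
        theta <- stats::runif(1, 0, pi)
        m <- ellipse_mask(h, w, cy, cx, ry, rx, theta)
        if (spec$allow_overlap || !any(m & cell_mask)) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf("could not place cell %d without overlap after 100 attempts", ci),
             call. = FALSE)
      nuc <- ellipse_mask(h, w, cy, cx, 0.45 * ry, 0.45 * rx, theta)
      cell_mask <- cell_mask | m
      # smooth within-cell composition texture shared across components
      tex <- if (spec$texture > 0)
        1 + spec$texture * blur2d(matrix(stats::runif(h * w, -1, 1), h, w), 2)
      else matrix(1, h, w)
      for (k in seq_along(spec$components)) {
        comp <- spec$components[[k]]
        if (comp$region == "background") next
        ab <- stats::runif(1, comp$abundance_range[1], comp$abundance_range[2])
        support <- if (comp$region == "nucleus") nuc else m
        map <- matrix(0, h, w)
        map[support] <- ab * pmax(tex[support], 0)
        map <- blur2d(map, spec$blur_sigma)
        # blur leaks outside the support; re-mask so region confinement holds
        map[!support] <- 0
        nm <- sprintf("%s.cell%d", comp$name, ci)
        abundance[[nm]] <- map
        spectra[[nm]] <- make_component_spectrum(
          jitter_component(comp, spec$spectral_jitter, axis), axis)
      }
    }
    for (k in seq_along(spec$components)) {
      comp <- spec$components[[k]]
      if (comp$region != "background") next
      ab <- stats::runif(1, comp$abundance_range[1], comp$abundance_range[2])
      abundance[[comp$name]] <- matrix(ab, h, w)
      spectra[[comp$name]] <- make_component_spectrum(comp, axis)
    }
    list(abundance = abundance, spectra = spectra)
  })

  cube_data <- array(spec$background_level, c(h, w, spec$n_bands))
  for (k in seq_along(res$abundance))
    cube_data <- cube_data + outer(res$abundance[[k]], res$spectra[[k]])
  cube <- hyper_cube(cube_data, axis, provenance = "phantom")
  list(cube = cube, abundance = res$abundance, spectra = res$spectra)
}

#' Generate a collection of phantom cubes
#'
#' Renders `n` independent phantoms; item `i` uses seed `base_seed + i - 1`,
#' so a collection is reproducible and item 1 equals
#' `render_phantom` at `seed = base_seed`.
#'
#' @param spec A [phantom_spec] (its own `seed` field is ignored here).
#' @param n Number of cubes (>= 1).
#' @param base_seed Integer seed of the first item.
#' @return A list of `n` results as returned by [render_phantom].
#' @export
generate_phantoms <- function(spec, n, base_seed = 1L) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  lapply(seq_len(n) - 1L, function(i) {
    s <- spec
    s$seed <- as.integer(base_seed + i)
    render_phantom(s)
  })
}
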