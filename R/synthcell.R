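#' Parameters for the synthetic yeast-cell image generator
#'
#' Describes one simulated two-channel confocal acquisition of a
#' yeast-like cell: a spherical cell filled with a uniform cytosolic pool
#' of the tagged ABP, decorated either with cortical patches (3D Gaussian
#' puncta on a cortical shell) or with cables (Gaussian tubes running
#' along the mother-bud axis). The ABP channel carries cytosol plus
#' structure signal; the marker channel carries structure signal only.
#' Cellular autofluorescence is added uniformly inside the cell in both
#' channels, the whole stack is blurred with an anisotropic Gaussian PSF,
#' and Poisson shot noise plus Gaussian read noise is applied.
#'
#' Acquisition geometry mirrors the source protocol: 35 z-slices at
#' 0.2 um steps spanning the cell, 0.065 um pixels, cell radius
#' 2-2.5 um.
#'
#' If `structure_intensity` is `NULL` (the default) the structure
#' amplitude is solved analytically so that the pre-noise cytosolic
#' fraction equals `target_fraction`; otherwise the amplitude is used
#' as given and the fraction is emergent.
#'
#' @param cell_radius Cell radius, um.
#' @param structure_kind `"patch"`, `"cable"`, or `"none"`.
#' @param n_structures Number of patches or cables.
#' @param structure_intensity Peak amplitude of each structure, AU, or
#'   `NULL` to solve from `target_fraction`.
#' @param target_fraction Desired ground-truth cytosolic fraction when
#'   `structure_intensity` is `NULL`, in (0, 1].
#' @param structure_size Gaussian sigma of a patch / cable cross-section,
#'   um.
#' @param cytosol_intensity Uniform cytosolic signal, AU.
#' @param autofluorescence Uniform in-cell background added to both
#'   channels, AU.
#' @param psf_sigma Length-2 vector `c(lateral, axial)` PSF sigmas, um.
#' @param pixel_size Lateral pixel size, um.
#' @param z_step Z step, um.
#' @param n_slices Number of z slices.
#' @param gain Poisson gain (AU per photon-equivalent).
#' @param read_noise_sd Additive Gaussian read noise SD, AU.
#' @param margin Lateral padding around the cell, pixels.
#' @param seed Integer seed; fixes the whole stack bitwise.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(cell_radius = 2.25,
                         structure_kind = c("patch", "cable", "none"),
                         n_structures = 15,
                         structure_intensity = NULL,
                         target_fraction = 0.75,
                         structure_size = 0.1,
                         cytosol_intensity = 100,
                         autofluorescence = 10,
                         psf_sigma = c(0.1, 0.3),
                         pixel_size = 0.065,
                         z_step = 0.2,
                         n_slices = 35,
                         gain = 1,
                         read_noise_sd = 2,
                         margin = 20,
                         seed = 1L) {
  structure_kind <- match.arg(structure_kind)
  stopifnot(cell_radius > 0, n_structures >= 0, structure_size > 0,
            cytosol_intensity >= 0, autofluorescence >= 0,
            length(psf_sigma) == 2L, all(psf_sigma >= 0),
            pixel_size > 0, z_step > 0, n_slices >= 1,
            gain > 0, read_noise_sd >= 0, margin >= 0)
  if (is.null(structure_intensity)) {
    stopifnot(target_fraction > 0, target_fraction <= 1)
  } else {
    stopifnot(structure_intensity >= 0)
  }
  if (cell_radius * 2 > n_slices * z_step) {
    stop("cell does not fit in the axial extent of the stack", call. = FALSE)
  }
  structure(as.list(environment()), class = "synth_params")
}

#' Two-channel 3D image stack
#'
#' Container for a calibrated two-channel voxel array. Voxels are stored
#' as a 4D array indexed `[y, x, z, channel]` with channels named
#' `"abp"` and `"marker"`; physical calibration (`pixel_size`, `z_step`,
#' um) is carried alongside.
#'
#' @param voxels 4D numeric array `[y, x, z, channel]`, non-negative.
#' @param pixel_size Lateral pixel size, um.
#' @param z_step Axial step, um.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(voxels, pixel_size, z_step) {
  stopifnot(is.array(voxels), length(dim(voxels)) == 4L,
            dim(voxels)[4] == 2L, pixel_size > 0, z_step > 0)
  if (min(voxels) < 0) stop("intensities must be >= 0", call. = FALSE)
  dimnames(voxels)[[4]] <- c("abp", "marker")
  structure(list(voxels = voxels, pixel_size = pixel_size, z_step = z_step,
                 n_slices = dim(voxels)[3]),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "image_stack: %d x %d px, %d slices, 2 channels (%.3f um/px, %.2f um/z)\n",
    d[2], d[1], d[3], x$pixel_size, x$z_step))
  invisible(x)
}

#' Generate one synthetic two-channel cell stack with known ground truth
#'
#' Builds the noise-free fluorophore fields analytically, records the
#' ground-truth cytosolic fraction as (integrated cytosol signal) /
#' (integrated total cell signal) *before* background, PSF and noise are
#' applied, then blurs and corrupts the stack. Bitwise reproducible for a
#' fixed `params$seed`.
#'
#' @param params A [synth_params()] object.
#' @return A list with `stack` (an [image_stack()]) and `truth`, a
#'   `ground_truth` list: `true_cytosolic_fraction`, `cell_mask`
#'   (logical `[y, x, z]`), `structure_voxels` (logical `[y, x, z]`),
#'   `cell_area` (projected, um^2), `structure_intensity` (the amplitude
#'   actually used), `integrals` (pre-noise cytosol and structure signal
#'   integrals, before and after PSF blur), and `params`.
#' @export
#' @examples
#' sim <- generate_cell_stack(synth_params(n_structures = 0, seed = 7))
#' sim$truth$true_cytosolic_fraction  # 1: no F-actin structures
generate_cell_stack <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  old <- local_seed(params$seed)
  on.exit(restore_seed(old), add = TRUE)
  p <- params

  r_px <- ceiling(p$cell_radius / p$pixel_size)
  nx <- ny <- as.integer(2 * r_px + 2 * p$margin)
  nz <- as.integer(p$n_slices)
  xs <- (seq_len(nx) - (nx + 1) / 2) * p$pixel_size
  ys <- (seq_len(ny) - (ny + 1) / 2) * p$pixel_size
  zs <- (seq_len(nz) - (nz + 1) / 2) * p$z_step

  # squared distance from the cell centre, [y, x, z]
  lat2 <- outer(ys^2, xs^2, `+`)
  rad2 <- outer(lat2, zs^2, `+`)
  cell_mask <- rad2 <= p$cell_radius^2

  cytosol <- p$cytosol_intensity * cell_mask

  kind <- if (p$n_structures == 0) "none" else p$structure_kind
  struct_unit <- array(0, dim = c(ny, nx, nz))
  if (kind == "patch") {
    check_structure_volume(p)
    shell_r <- 0.8 * p$cell_radius
    u <- stats::runif(p$n_structures, -1, 1)       # uniform on a sphere
    phi <- stats::runif(p$n_structures, 0, 2 * pi)
    cx <- shell_r * sqrt(1 - u^2) * cos(phi)
    cy <- shell_r * sqrt(1 - u^2) * sin(phi)
    cz <- shell_r * u
    for (i in seq_len(p$n_structures)) {
      struct_unit <- struct_unit +
        gaussian_spot(ys, xs, zs, c(cy[i], cx[i], cz[i]), p$structure_size)
    }
  } else if (kind == "cable") {
    check_structure_volume(p)
    # tubes along the y (mother-bud) axis at random lateral/axial offsets
    rmax <- 0.7 * p$cell_radius
    rr <- rmax * sqrt(stats::runif(p$n_structures))
    th <- stats::runif(p$n_structures, 0, 2 * pi)
    x0 <- rr * cos(th)
    z0 <- rr * sin(th)
    for (i in seq_len(p$n_structures)) {
      gx <- exp(-(xs - x0[i])^2 / (2 * p$structure_size^2))
      gz <- exp(-(zs - z0[i])^2 / (2 * p$structure_size^2))
      struct_unit <- struct_unit +
        outer(outer(rep(1, ny), gx), gz)
    }
  }
  struct_unit[!cell_mask] <- 0                     # truncate to the cell

  unit_sum <- sum(struct_unit)
  cyt_sum <- sum(cytosol)
  if (kind == "none" || unit_sum == 0) {
    amp <- 0
  } else if (is.null(p$structure_intensity)) {
    # solve S = C * (1/f - 1) for the structure amplitude; with no
    # cytosol any positive amplitude gives fraction 0
    amp <- if (cyt_sum == 0) 1 else
      cyt_sum * (1 / p$target_fraction - 1) / unit_sum
  } else {
    amp <- p$structure_intensity
  }
  structure_field <- amp * struct_unit

  total <- cyt_sum + sum(structure_field)
  true_fraction <- if (total == 0) NA_real_ else cyt_sum / total

  abp <- cytosol + structure_field + p$autofluorescence * cell_mask
  marker <- structure_field + p$autofluorescence * cell_mask

  sig_px <- c(p$psf_sigma[1] / p$pixel_size,      # y
              p$psf_sigma[1] / p$pixel_size,      # x
              p$psf_sigma[2] / p$z_step)          # z
  cyt_blur_sum <- sum(gaussian_blur_3d(cytosol, sig_px))
  struct_blur_sum <- sum(gaussian_blur_3d(structure_field, sig_px))
  abp <- gaussian_blur_3d(abp, sig_px)
  marker <- gaussian_blur_3d(marker, sig_px)

  abp <- add_camera_noise(abp, p$gain, p$read_noise_sd)
  marker <- add_camera_noise(marker, p$gain, p$read_noise_sd)

  voxels <- array(c(abp, marker), dim = c(ny, nx, nz, 2))
  stack <- image_stack(voxels, p$pixel_size, p$z_step)

  proj_mask <- apply(cell_mask, c(1, 2), any)
  truth <- structure(list(
    true_cytosolic_fraction = true_fraction,
    cell_mask = cell_mask,
    structure_voxels = structure_field > 0.01 * max(structure_field, 1e-12),
    cell_area = sum(proj_mask) * p$pixel_size^2,
    structure_intensity = amp,
    integrals = list(cytosol = cyt_sum, structure = sum(structure_field),
                     cytosol_blurred = cyt_blur_sum,
                     structure_blurred = struct_blur_sum),
    params = p), class = "ground_truth")
  list(stack = stack, truth = truth)
}

# Internal: refuse structure sets that cannot fit inside the cell.
check_structure_volume <- function(p) {
  cell_vol <- 4 / 3 * pi * p$cell_radius^3
  struct_vol <- p$n_structures * 4 / 3 * pi * (2 * p$structure_size)^3
  if (struct_vol > cell_vol) {
    stop("structures exceed the cell volume", call. = FALSE)
  }
  invisible(NULL)
}

# Internal: one 3D Gaussian punctum, evaluated on a local window only.
gaussian_spot <- function(ys, xs, zs, centre, sigma) {
  gy <- exp(-(ys - centre[1])^2 / (2 * sigma^2))
  gx <- exp(-(xs - centre[2])^2 / (2 * sigma^2))
  gz <- exp(-(zs - centre[3])^2 / (2 * sigma^2))
  outer(outer(gy, gx), gz)
}

# Internal: separable anisotropic Gaussian blur of a 3D array.
# Kernels are renormalised at the boundary, so the integrated intensity is
# conserved up to boundary truncation.
gaussian_blur_3d <- function(a, sigma_px) {
  for (axis in 1:3) {
    s <- sigma_px[axis]
    if (s > 0) a <- blur_axis(a, gauss_kernel_matrix(dim(a)[axis], s), axis)
  }
  a
}

gauss_kernel_matrix <- function(n, sigma) {
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, `-`)^2 / (2 * sigma^2))
  K / colSums(K)   # each source voxel redistributes exactly its content
}

blur_axis <- function(a, K, axis) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = d[axis])
  aperm(array(m, dim = d[perm]), order(perm))
}

# Internal: Poisson shot noise with gain plus Gaussian read noise,
# clipped at zero as a camera would.
add_camera_noise <- function(field, gain, read_sd) {
  n <- length(field)
  shot <- gain * stats::rpois(n, lambda = as.numeric(field) / gain)
  out <- shot + stats::rnorm(n, sd = read_sd)
  array(pmax(out, 0), dim = dim(field))
}

#' Generate a population of synthetic cells
#'
#' Cells with projected areas drawn uniformly from `area_range` and
#' ground-truth cytosolic fractions following the requested law:
#' `"constant"` (every cell has fraction `fraction`) or
#' `"linear_in_area"` (`fraction + slope * (area - mid(area_range))`).
#' Per-cell seeds are derived from `seed`, so the population is
#' reproducible as a whole.
#'
#' With `render = TRUE` every cell's image stack is generated (slow for
#' large populations). With `render = FALSE` only the manifest is
#' returned, with a `measured_fraction` column emulating measurement
#' noise (`true + N(0, noise)`) and a `total_intensity` column drawn
#' lognormally with coefficient of variation `intensity_cv` — the fast
#' path for population-statistics work.
#'
#' @param n_cells Number of cells (>= 1).
#' @param area_range Length-2 range of projected cell areas, um^2.
#' @param fraction_law `"constant"` or `"linear_in_area"`.
#' @param fraction Baseline cytosolic fraction.
#' @param slope Fraction change per um^2 (linear law only).
#' @param noise Measurement-noise SD applied to `measured_fraction` in
#'   the un-rendered manifest.
#' @param intensity_cv Cell-to-cell coefficient of variation of total
#'   intensity in the un-rendered manifest.
#' @param mean_intensity Mean total intensity, AU.
#' @param params Template [synth_params()] for rendered cells
#'   (`cell_radius`, `target_fraction` and `seed` are overridden
#'   per cell).
#' @param seed Integer master seed.
#' @param render Generate actual image stacks?
#' @return A list with `manifest` (data frame: cell, seed, area_um2,
#'   radius_um, true_fraction, measured_fraction, total_intensity) and
#'   `cells` (list of `generate_cell_stack()` results, or `NULL`).
#' @export
generate_population <- function(n_cells,
                                area_range = c(12, 36),
                                fraction_law = c("constant",
                                                 "linear_in_area"),
                                fraction = 0.8,
                                slope = 0,
                                noise = 0.02,
                                intensity_cv = 0.25,
                                mean_intensity = 1000,
                                params = synth_params(),
                                seed = 1L,
                                render = FALSE) {
  fraction_law <- match.arg(fraction_law)
  stopifnot(n_cells >= 1, length(area_range) == 2L)
  if (!(area_range[1] < area_range[2]) || area_range[1] <= 0) {
    stop("area_range must be a non-empty positive interval", call. = FALSE)
  }
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  areas <- stats::runif(n_cells, area_range[1], area_range[2])
  radii <- sqrt(areas / pi)
  fr <- switch(fraction_law,
               constant = rep(fraction, n_cells),
               linear_in_area = fraction + slope * (areas - mean(area_range)))
  if (any(fr <= 0 | fr > 1)) {
    stop("fraction law produces fractions outside (0, 1]", call. = FALSE)
  }
  measured <- pmin(fr + stats::rnorm(n_cells, sd = noise), 1.2)
  sdlog <- sqrt(log(1 + intensity_cv^2))
  total <- stats::rlnorm(n_cells, meanlog = log(mean_intensity) -
                           sdlog^2 / 2, sdlog = sdlog)
  seeds <- as.integer(seed) + seq_len(n_cells)
  manifest <- data.frame(cell = seq_len(n_cells), seed = seeds,
                         area_um2 = areas, radius_um = radii,
                         true_fraction = fr, measured_fraction = measured,
                         total_intensity = total)
  cells <- NULL
  if (render) {
    cells <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      pi_ <- params
      pi_$cell_radius <- radii[i]
      pi_$structure_intensity <- NULL
      pi_$target_fraction <- fr[i]
      pi_$seed <- seeds[i]
      if (pi_$cell_radius * 2 > pi_$n_slices * pi_$z_step) {
        stop("population cell does not fit the stack axially", call. = FALSE)
      }
      cells[[i]] <- generate_cell_stack(pi_)
    }
  }
  list(manifest = manifest, cells = cells)
}

#' Write / read an image stack as multi-page TIFF plus JSON sidecar
#'
#' Each channel is written as its own 32-bit multi-page TIFF
#' (`<stem>_abp.tif`, `<stem>_marker.tif`; intensities scaled to [0, 1]
#' by a per-channel factor), and calibration plus the scale factors go to
#' `<stem>_meta.json`. `read_image_stack(stem)` reverses the round trip.
#'
#' @param stack An [image_stack()].
#' @param stem Path stem (no extension).
#' @return `write_image_stack` returns the paths written, invisibly;
#'   `read_image_stack` returns an [image_stack()].
#' @export
write_image_stack <- function(stack, stem) {
  stopifnot(inherits(stack, "image_stack"))
  paths <- character(0)
  scales <- numeric(2)
  for (ch in 1:2) {
    vox <- stack$voxels[, , , ch, drop = FALSE]
    dim(vox) <- dim(stack$voxels)[1:3]
    scales[ch] <- max(vox, 1e-12)
    pages <- lapply(seq_len(dim(vox)[3]), function(k) vox[, , k] / scales[ch])
    path <- sprintf("%s_%s.tif", stem, c("abp", "marker")[ch])
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    paths <- c(paths, path)
  }
  meta <- list(pixel_size = stack$pixel_size, z_step = stack$z_step,
               n_slices = stack$n_slices,
               scale = list(abp = scales[1], marker = scales[2]))
  meta_path <- paste0(stem, "_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, meta_path))
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(stem) {
  meta <- jsonlite::read_json(paste0(stem, "_meta.json"),
                              simplifyVector = TRUE)
  chans <- lapply(c(abp = "abp", marker = "marker"), function(ch) {
    pages <- tiff::readTIFF(sprintf("%s_%s.tif", stem, ch), all = TRUE)
    arr <- array(unlist(pages), dim = c(dim(pages[[1]]), length(pages)))
    arr * meta$scale[[ch]]
  })
  voxels <- array(c(chans$abp, chans$marker), dim = c(dim(chans$abp), 2))
  image_stack(voxels, meta$pixel_size, meta$z_step)
}
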