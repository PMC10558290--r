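#' Z-projection of one channel of an image stack
#'
#' Pixelwise mean or maximum over z. The cytosolic-fraction workflow uses
#' the *average* projection of the ABP channel (mean intensity per unit
#' area) and the *maximum* projection of the patch/cable marker channel
#' (to capture structures at any depth).
#'
#' @param stack An [image_stack()].
#' @param channel `"abp"` or `"marker"`.
#' @param mode `"average"` or `"maximum"`.
#' @return An object of class `projection`: `pixels` (matrix `[y, x]`),
#'   `mode`, `channel`, `pixel_size`.
#' @export
project <- function(stack, channel = c("abp", "marker"),
                    mode = c("average", "maximum")) {
  stopifnot(inherits(stack, "image_stack"))
  channel <- match.arg(channel)
  mode <- match.arg(mode)
  vox <- stack$voxels[, , , channel, drop = FALSE]
  dim(vox) <- dim(stack$voxels)[1:3]
  if (length(vox) == 0L) stop("empty stack", call. = FALSE)
  px <- if (mode == "average") {
    apply(vox, c(1, 2), mean)
  } else {
    apply(vox, c(1, 2), max)
  }
  structure(list(pixels = px, mode = mode, channel = channel,
                 pixel_size = stack$pixel_size),
            class = "projection")
}

#' Wrap a raw pixel matrix as a projection
#'
#' For projections produced outside [project()] (e.g., composites of
#' several cells, or images read from other software).
#'
#' @param pixels Numeric matrix `[y, x]`.
#' @param pixel_size Pixel size, um.
#' @param mode,channel Provenance labels.
#' @return A `projection` object.
#' @export
as_projection <- function(pixels, pixel_size, mode = "average",
                          channel = "abp") {
  stopifnot(is.matrix(pixels), pixel_size > 0)
  structure(list(pixels = pixels, mode = mode, channel = channel,
                 pixel_size = pixel_size),
            class = "projection")
}

#' @export
print.projection <- function(x, ...) {
  cat(sprintf("%s projection of '%s' channel: %d x %d px\n",
              x$mode, x$channel, nrow(x$pixels), ncol(x$pixels)))
  invisible(x)
}

# Internal: Otsu threshold of a numeric vector (between-class variance
# maximisation), delegated to EBImage on a rescaled copy so masked
# subsets can be thresholded too.
otsu_threshold <- function(values, levels = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  scaled <- (values - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(matrix(scaled, nrow = 1L)),
                      range = c(0, 1), levels = levels)
  rng[1] + th * diff(rng)
}

#' Segment cells in a projection
#'
#' Default threshold-based segmenter adequate for synthetic images:
#' global Otsu threshold, hole filling, connected-component labelling,
#' and a minimum-size filter. Cells touching the image border are
#' reported with `border = TRUE` so population statistics can exclude
#' them. Segmentation is a plug-in boundary: any externally produced
#' logical cell mask (e.g., from a learned segmenter) can be passed to
#' the downstream measurement functions instead.
#'
#' @param projection A [project()] result (typically the average ABP
#'   projection).
#' @param min_area Minimum object size, pixels.
#' @return A list of cells, each a list with `mask` (logical `[y, x]`),
#'   `area_px`, `area_um2`, `border`. Empty (with a warning) when no
#'   cell is found.
#' @export
segment_cells <- function(projection, min_area = 200L) {
  stopifnot(inherits(projection, "projection"))
  px <- projection$pixels
  if (max(px) <= 0) {
    warning("no cell found: blank projection")
    return(list())
  }
  # threshold in log space: cells are separated from the dark exterior by
  # orders of magnitude less than bright puncta are from the cytosol, so a
  # linear-scale Otsu would cut at the puncta instead of the cell outline
  th <- exp(otsu_threshold(as.numeric(log1p(px)))) - 1
  bw <- px > th
  if (!any(bw)) {
    warning("no cell found above threshold")
    return(list())
  }
  bw_img <- EBImage::fillHull(EBImage::Image(bw * 1))
  labels <- EBImage::bwlabel(bw_img)
  lab <- as.integer(EBImage::imageData(labels))
  dim(lab) <- dim(px)
  out <- list()
  for (id in setdiff(sort(unique(lab)), 0L)) {
    mask <- lab == id
    area <- sum(mask)
    if (area < min_area) next
    on_border <- any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)])
    out[[length(out) + 1L]] <- list(
      mask = mask, area_px = area,
      area_um2 = area * projection$pixel_size^2,
      border = on_border)
  }
  if (length(out) == 0L) warning("no cell found above minimum size")
  out
}

#' Estimate per-session autofluorescence background
#'
#' Mean in-cell intensity of cells that express no fluorophore, measured
#' on their average projections. Each projection is segmented with
#' [segment_cells()]; if no cell can be found (e.g., a truly blank
#' image), the projection's overall mean is used. The background is a
#' single scalar per imaging session, subtracted from all measurements.
#'
#' @param projections A list of [project()] results from label-free
#'   cells (a single projection is also accepted).
#' @param min_area Passed to [segment_cells()].
#' @return Background level, AU.
#' @export
estimate_background <- function(projections, min_area = 200L) {
  if (inherits(projections, "projection")) projections <- list(projections)
  stopifnot(length(projections) >= 1L)
  per_image <- vapply(projections, function(pr) {
    cells <- withCallingHandlers(segment_cells(pr, min_area = min_area),
                                 warning = function(w)
                                   invokeRestart("muffleWarning"))
    if (length(cells) == 0L) return(mean(pr$pixels))
    masks <- Reduce(`|`, lapply(cells, `[[`, "mask"))
    mean(pr$pixels[masks])
  }, numeric(1))
  mean(per_image)
}

#' Build the F-actin structure mask from the marker channel
#'
#' Pixels of the marker maximum projection at or above the set point.
#' The mask shrinks monotonically as the set point is raised.
#'
#' @param marker_projection A [project()] result (maximum projection of
#'   the marker channel).
#' @param set_point Threshold, AU (>= 0).
#' @return Logical matrix `[y, x]`; empty (with a warning) when the set
#'   point exceeds the maximum marker intensity.
#' @export
make_structure_mask <- function(marker_projection, set_point) {
  stopifnot(inherits(marker_projection, "projection"), set_point >= 0)
  px <- marker_projection$pixels
  if (set_point > max(px)) {
    warning("set point exceeds maximum marker intensity: empty mask")
  }
  px >= set_point
}

#' Automatic set point for the structure mask
#'
#' Otsu threshold of the log-transformed in-cell marker intensities.
#' The log transform compresses the very bright, sparse structure tail so
#' the threshold settles in the valley between the in-cell background
#' mode and the structure signal, keeping the mask generous enough to
#' exclude the blurred skirts of patches and cables (linear-scale Otsu on
#' images dominated by a few bright puncta lands near half the peak and
#' leaves most of the structure's blurred signal outside the mask).
#'
#' If the in-cell marker shows no structure signal (its maximum does not
#' stand at least ten MADs above the in-cell median — pure noise tops out
#' around four), no set point exists: the marker is background only and
#' masking it would carve noise out of the cytosol. In that case the
#' returned set point sits just above the maximum intensity, giving an
#' empty mask, with a warning.
#'
#' @param marker_projection Maximum projection of the marker channel.
#' @param cell_mask Logical cell mask.
#' @return Set point in AU.
#' @export
default_set_point <- function(marker_projection, cell_mask) {
  vals <- marker_projection$pixels[cell_mask]
  stopifnot(length(vals) > 0)
  if (max(vals) < stats::median(vals) + 10 * stats::mad(vals)) {
    warning("no structure signal detected in the marker channel; ",
            "using an empty mask")
    return(max(vals) * (1 + 1e-6))
  }
  exp(otsu_threshold(log1p(vals))) - 1
}

#' Measure the cytosolic fraction of an ABP in one cell
#'
#' The background scalar is first subtracted from every pixel; the
#' fraction is then the mean intensity over the unmasked in-cell region
#' (the cytosol) divided by the mean intensity over the whole cell.
#' Values marginally above 1 can occur on noisy input and are flagged,
#' not clipped, so population statistics stay unbiased.
#'
#' @param abp_projection Average projection of the ABP channel.
#' @param cell_mask Logical cell mask `[y, x]`.
#' @param structure_mask Logical F-actin mask `[y, x]` (intersected with
#'   the cell mask internally).
#' @param background Scalar background, AU (see [estimate_background()]).
#' @return An object of class `fraction_result`: `cytosolic_fraction`,
#'   `mean_cell`, `mean_cytosol`, `background`, `cell_area` (um^2),
#'   `flagged` (fraction > 1).
#' @export
cytosolic_fraction <- function(abp_projection, cell_mask, structure_mask,
                               background = 0) {
  stopifnot(inherits(abp_projection, "projection"))
  if (!any(cell_mask)) stop("empty cell mask", call. = FALSE)
  structure_mask <- structure_mask & cell_mask
  unmasked <- cell_mask & !structure_mask
  if (!any(unmasked)) {
    stop("undefined fraction: structure mask covers the whole cell",
         call. = FALSE)
  }
  px <- abp_projection$pixels - background
  mean_cell <- mean(px[cell_mask])
  if (mean_cell <= 0) {
    stop("whole-cell mean is not positive after background subtraction",
         call. = FALSE)
  }
  mean_cyt <- mean(px[unmasked])
  fr <- mean_cyt / mean_cell
  structure(list(cytosolic_fraction = fr,
                 mean_cell = mean_cell,
                 mean_cytosol = mean_cyt,
                 background = background,
                 cell_area = sum(cell_mask) * abp_projection$pixel_size^2,
                 flagged = fr > 1),
            class = "fraction_result")
}

#' @export
print.fraction_result <- function(x, ...) {
  cat(sprintf(
    "cytosolic fraction: %.3f%s (cell mean %.2f AU, cytosol mean %.2f AU)\n",
    x$cytosolic_fraction, if (x$flagged) " [>1, flagged]" else "",
    x$mean_cell, x$mean_cytosol))
  invisible(x)
}

#' Threshold-sensitivity sweep of the cytosolic fraction
#'
#' Recomputes the fraction with the structure-mask set point scaled by
#' each factor in `deltas` (default -25%, nominal, +25%) and reports the
#' maximum pairwise absolute difference as the sensitivity. A small
#' sensitivity shows the measurement does not depend on the exact
#' threshold used to build the F-actin mask.
#'
#' @param abp_projection Average ABP projection.
#' @param cell_mask Logical cell mask.
#' @param marker_projection Maximum marker projection.
#' @param set_point Nominal set point, AU (> 0).
#' @param deltas Multiplicative factors applied to `set_point`.
#' @param background Scalar background, AU.
#' @return A list with `results` (one [cytosolic_fraction()] result per
#'   delta), `fractions`, `set_points`, `sensitivity`.
#' @export
threshold_sweep <- function(abp_projection, cell_mask, marker_projection,
                            set_point, deltas = c(0.75, 1, 1.25),
                            background = 0) {
  if (set_point <= 0) stop("set_point must be > 0", call. = FALSE)
  sps <- set_point * deltas
  results <- lapply(sps, function(sp) {
    cytosolic_fraction(abp_projection, cell_mask,
                       make_structure_mask(marker_projection, sp),
                       background = background)
  })
  fr <- vapply(results, `[[`, numeric(1), "cytosolic_fraction")
  list(results = results, fractions = fr, set_points = sps,
       sensitivity = max(stats::dist(fr)))
}

#' End-to-end cytosolic-fraction measurement of one stack
#'
#' Convenience wrapper running the published pipeline on a single
#' two-channel stack: average ABP projection, maximum marker projection,
#' cell segmentation (largest object), automatic or manual set point,
#' structure masking (with optional dilation), and the fraction
#' computation.
#'
#' @param stack An [image_stack()].
#' @param set_point `"auto"` (Otsu within the cell, see
#'   [default_set_point()]) or a numeric threshold in AU.
#' @param background Scalar background, AU.
#' @param mask_dilate Dilation radius applied to the structure mask,
#'   pixels (0 = none).
#' @param cell_mask Optional externally supplied logical cell mask
#'   (plug-in segmentation boundary); default segments internally.
#' @return A list with the `fraction_result` (`result`), `set_point`,
#'   `cell_mask`, `structure_mask`.
#' @export
measure_stack <- function(stack, set_point = "auto", background = 0,
                          mask_dilate = 0, cell_mask = NULL) {
  abp_avg <- project(stack, "abp", "average")
  marker_max <- project(stack, "marker", "maximum")
  if (is.null(cell_mask)) {
    cells <- segment_cells(abp_avg)
    if (length(cells) == 0L) stop("no cell segmented", call. = FALSE)
    cell_mask <- cells[[order(vapply(cells, `[[`, numeric(1), "area_px"),
                              decreasing = TRUE)[1]]]$mask
  }
  sp <- if (identical(set_point, "auto")) {
    default_set_point(marker_max, cell_mask)
  } else {
    as.numeric(set_point)
  }
  smask <- make_structure_mask(marker_max, sp)
  if (mask_dilate > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(mask_dilate) + 1L, "disc")
    smask <- EBImage::imageData(
      EBImage::dilate(EBImage::Image(smask * 1), brush)) > 0
  }
  res <- cytosolic_fraction(abp_avg, cell_mask, smask,
                            background = background)
  list(result = res, set_point = sp, cell_mask = cell_mask,
       structure_mask = smask & cell_mask)
}

#' Measure a rendered synthetic population
#'
#' Runs [measure_stack()] over the cells of a rendered
#' [generate_population()] result and assembles the per-cell population
#' table used by the statistics layer.
#'
#' @param population A [generate_population()] result with rendered
#'   cells.
#' @param background Scalar background, AU.
#' @param ... Passed to [measure_stack()].
#' @return A data frame: `cell`, `area_um2`, `total_intensity` (mean
#'   in-cell intensity times area), `fraction`, `true_fraction`.
#' @export
measure_population <- function(population, background = 0, ...) {
  stopifnot(!is.null(population$cells))
  rows <- lapply(seq_along(population$cells), function(i) {
    m <- measure_stack(population$cells[[i]]$stack,
                       background = background, ...)
    data.frame(cell = i,
               area_um2 = m$result$cell_area,
               total_intensity = m$result$mean_cell * m$result$cell_area,
               fraction = m$result$cytosolic_fraction,
               true_fraction =
                 population$cells[[i]]$truth$true_cytosolic_fraction)
  })
  do.call(rbind, rows)
}
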