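#' Physical constants describing an average haploid yeast cell
#'
#' Bundles the cell-level constants that drive the conversion chain from
#' blot abundance (ng ABP per ug total protein) to molar concentration and
#' copy number: cell wet mass, cell density, the fraction of cell volume
#' occupied by cytoplasm, total protein mass per cell, and Avogadro's
#' number. Defaults are the published values for haploid
#' *S. cerevisiae*: wet mass ~6e-11 g, density ~1.1126 g/ml, cytoplasm
#' ~50% of cell volume, ~4e-12 g total protein per cell.
#'
#' `conversion_k` is an optional calibrated scalar in uM * kDa per (ng/ug)
#' (numerically equal to an effective cytoplasmic protein concentration in
#' g/L). When present it overrides the first-principles constant
#' `protein_mass_per_cell / cytosolic volume`; see
#' [conversion_constant()] for why the two differ.
#'
#' @param wet_mass Cell wet mass, g.
#' @param density Cell density, g/ml.
#' @param cytoplasm_fraction Fraction of cell volume that is cytoplasm, in
#'   (0, 1].
#' @param protein_mass_per_cell Total protein mass per cell, g.
#' @param avogadro Avogadro's number, 1/mol.
#' @param conversion_k Optional calibrated conversion constant,
#'   uM * kDa / (ng/ug). `NULL` means "derive from the other constants".
#' @return An object of class `cell_constants`.
#' @seealso [default_cell_constants()], [cytosolic_volume()],
#'   [abundance_to_concentration()]
#' @export
#' @examples
#' cc <- cell_constants()
#' cytosolic_volume(cc)  # ~27 fL
cell_constants <- function(wet_mass = 6e-11,
                           density = 1.1126,
                           cytoplasm_fraction = 0.5,
                           protein_mass_per_cell = 4e-12,
                           avogadro = 6.02214076e23,
                           conversion_k = NULL) {
  vals <- c(wet_mass = wet_mass, density = density,
            cytoplasm_fraction = cytoplasm_fraction,
            protein_mass_per_cell = protein_mass_per_cell,
            avogadro = avogadro)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("invalid cell constants: all constants must be finite and > 0",
         call. = FALSE)
  }
  if (cytoplasm_fraction > 1) {
    stop("invalid cell constants: cytoplasm_fraction must be in (0, 1]",
         call. = FALSE)
  }
  if (!is.null(conversion_k)) {
    stopifnot(is.numeric(conversion_k), length(conversion_k) == 1L)
    if (!is.finite(conversion_k) || conversion_k <= 0) {
      stop("invalid cell constants: conversion_k must be > 0", call. = FALSE)
    }
  }
  structure(
    list(wet_mass = wet_mass, density = density,
         cytoplasm_fraction = cytoplasm_fraction,
         protein_mass_per_cell = protein_mass_per_cell,
         avogadro = avogadro, conversion_k = conversion_k),
    class = "cell_constants"
  )
}

#' @export
print.cell_constants <- function(x, ...) {
  cat("Yeast cell constants\n")
  cat(sprintf("  wet mass:              %.3g g\n", x$wet_mass))
  cat(sprintf("  density:               %.6g g/ml\n", x$density))
  cat(sprintf("  cytoplasm fraction:    %.3g\n", x$cytoplasm_fraction))
  cat(sprintf("  protein mass per cell: %.3g g\n", x$protein_mass_per_cell))
  cat(sprintf("  cytosolic volume:      %.3f fL\n", cytosolic_volume(x)))
  if (!is.null(x$conversion_k)) {
    cat(sprintf("  conversion K (calibrated): %.4g uM*kDa/(ng/ug)\n",
                x$conversion_k))
  }
  invisible(x)
}

#' Default constants with the conversion scalar calibrated on the actin row
#'
#' Returns [cell_constants()] whose `conversion_k` has been calibrated so
#' that the packaged reference table's actin row (7.99 ng/ug, 41.8 kDa)
#' maps exactly onto its published concentration (13.2 uM). All other
#' concentrations in the reference table are then reproduced from their
#' abundances by the same scalar. See [conversion_constant()] for the
#' first-principles alternative.
#'
#' @return A `cell_constants` object with `conversion_k` set
#'   (~69.06 uM * kDa / (ng/ug)).
#' @export
default_cell_constants <- function() {
  ref <- abp_reference_table()
  act <- ref[ref$name == "Act1", ]
  cell_constants(conversion_k = calibrate_conversion_k(
    conc = act$cellular_conc, mw = act$mw, abundance = act$abundance))
}

#' Read cell constants from a YAML or JSON config file
#'
#' Recognised keys: `wet_mass`, `density`, `cytoplasm_fraction`,
#' `protein_mass_per_cell`, `avogadro`, `conversion_k`. Missing keys take
#' the package defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cell_constants` object.
#' @export
read_cell_constants <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("wet_mass", "density", "cytoplasm_fraction",
               "protein_mass_per_cell", "avogadro", "conversion_k")
  cfg <- cfg[intersect(names(cfg), allowed)]
  do.call(cell_constants, cfg)
}

#' Cytosolic volume of a haploid yeast cell
#'
#' Volume = wet mass / density x cytoplasm fraction. With the default
#' constants (6e-11 g, 1.1126 g/ml, 50% cytoplasm) this is ~27 fL;
#' with `cytoplasm_fraction = 1` it is the whole-cell volume (~54 fL).
#'
#' @param constants A `cell_constants` object.
#' @return Volume in femtolitres (fL).
#' @export
cytosolic_volume <- function(constants = cell_constants()) {
  stopifnot(inherits(constants, "cell_constants"))
  # g / (g/ml) = ml; 1 ml = 1e12 fL
  constants$wet_mass / constants$density * constants$cytoplasm_fraction * 1e12
}

#' The abundance-to-concentration conversion constant K
#'
#' K links blot abundance and molecular weight to molar concentration:
#' `conc_uM = abundance_ng_per_ug * K / mw_kDa`. Dimensionally K is the
#' cytoplasmic protein mass concentration in g/L (equivalently
#' uM * kDa per (ng/ug)).
#'
#' Two modes are provided because they disagree for this system:
#' \describe{
#'   \item{`"calibrated"`}{Uses `constants$conversion_k`, normally obtained
#'     from the reference actin row via [calibrate_conversion_k()]
#'     (~69.06 g/L). This mode reproduces the published concentration
#'     column.}
#'   \item{`"first_principles"`}{Computes
#'     `protein_mass_per_cell / cytosolic_volume` from the stated cell
#'     constants (~148 g/L). The published table is *not* internally
#'     consistent with this value; the factor ~2.1 discrepancy is surfaced
#'     rather than hidden so users can reason about it.}
#' }
#'
#' @param constants A `cell_constants` object.
#' @param mode `"calibrated"` (default, requires `conversion_k`) or
#'   `"first_principles"`.
#' @return K in uM * kDa / (ng/ug).
#' @export
conversion_constant <- function(constants = default_cell_constants(),
                                mode = c("calibrated", "first_principles")) {
  stopifnot(inherits(constants, "cell_constants"))
  mode <- match.arg(mode)
  if (mode == "calibrated") {
    if (is.null(constants$conversion_k)) {
      stop("constants carry no calibrated conversion_k; ",
           "use default_cell_constants() or mode = 'first_principles'",
           call. = FALSE)
    }
    return(constants$conversion_k)
  }
  v_l <- cytosolic_volume(constants) * 1e-15       # fL -> L
  constants$protein_mass_per_cell / v_l            # g/L
}

#' Calibrate the conversion constant from one reference protein
#'
#' Solves `conc = abundance * K / mw` for K given one protein whose
#' abundance, molecular weight and concentration are all known (the actin
#' row in the default workflow).
#'
#' @param conc Cellular concentration, uM.
#' @param mw Molecular weight, kDa.
#' @param abundance Abundance, ng per ug total protein.
#' @return K in uM * kDa / (ng/ug).
#' @export
calibrate_conversion_k <- function(conc, mw, abundance) {
  stopifnot(conc > 0, mw > 0, abundance > 0)
  conc * mw / abundance
}

#' Convert blot abundance to cellular concentration
#'
#' `conc_uM = abundance * K / mw`: linear in abundance, inverse in
#' molecular weight. K comes from [conversion_constant()].
#'
#' @param abundance ng ABP per ug total cellular protein (>= 0).
#' @param mw Molecular weight, kDa (> 0).
#' @param constants A `cell_constants` object.
#' @param mode Passed to [conversion_constant()].
#' @return Concentration in uM (vectorised over `abundance` and `mw`).
#' @export
#' @examples
#' cc <- default_cell_constants()
#' abundance_to_concentration(4.22, 23.5, cc)  # Tpm1: ~12.4 uM
abundance_to_concentration <- function(abundance, mw,
                                       constants = default_cell_constants(),
                                       mode = c("calibrated",
                                                "first_principles")) {
  if (any(mw <= 0, na.rm = TRUE)) stop("mw must be > 0", call. = FALSE)
  if (any(abundance < 0, na.rm = TRUE)) {
    stop("abundance must be >= 0", call. = FALSE)
  }
  abundance * conversion_constant(constants, match.arg(mode)) / mw
}

#' Convert a molar concentration to molecules per cell
#'
#' `count = conc * volume * N_A` in consistent units. 1 uM in 1 fL is
#' ~602 molecules.
#'
#' @param conc Concentration, uM (>= 0).
#' @param volume Compartment volume, fL (> 0).
#' @param avogadro Avogadro's number, 1/mol.
#' @return Number of molecules (not rounded).
#' @export
concentration_to_molecules <- function(conc, volume,
                                       avogadro = 6.02214076e23) {
  if (any(conc < 0, na.rm = TRUE)) stop("conc must be >= 0", call. = FALSE)
  if (any(volume <= 0, na.rm = TRUE)) stop("volume must be > 0", call. = FALSE)
  conc * 1e-6 * volume * 1e-15 * avogadro
}

#' Inverse of [concentration_to_molecules()]
#'
#' @param count Molecules per cell (>= 0).
#' @param volume Compartment volume, fL (> 0).
#' @param avogadro Avogadro's number, 1/mol.
#' @return Concentration, uM.
#' @export
molecules_to_concentration <- function(count, volume,
                                       avogadro = 6.02214076e23) {
  if (any(count < 0, na.rm = TRUE)) stop("count must be >= 0", call. = FALSE)
  if (any(volume <= 0, na.rm = TRUE)) stop("volume must be > 0", call. = FALSE)
  count / (1e-6 * volume * 1e-15 * avogadro)
}

#' Estimate a protein's abundance and concentration from a molar ratio
#'
#' Some proteins lack antibodies and are quantified relative to a measured
#' paralog (Tpm2 is ~6-fold less abundant than Tpm1). The reference
#' abundance is divided by the molar ratio and converted with the *target*
#' protein's molecular weight. Note the division is applied on the
#' abundance scale; dividing the reference *concentration* instead would
#' ignore the molecular-weight difference between the paralogs.
#'
#' @param ref_abundance Reference protein's abundance, ng/ug.
#' @param divisor Molar ratio reference:target (> 0); 6 for Tpm1:Tpm2.
#' @param mw Target protein's molecular weight, kDa.
#' @param constants A `cell_constants` object.
#' @return A list with `abundance` (ng/ug) and `concentration` (uM).
#' @export
#' @examples
#' cc <- default_cell_constants()
#' ratio_estimate_abundance(4.22, 6, 19.1, cc)  # Tpm2: 0.70 ng/ug, ~2.54 uM
ratio_estimate_abundance <- function(ref_abundance, divisor, mw,
                                     constants = default_cell_constants()) {
  if (divisor <= 0) stop("divisor must be > 0", call. = FALSE)
  ab <- ref_abundance / divisor
  list(abundance = ab,
       concentration = abundance_to_concentration(ab, mw, constants))
}

#' Construct a fitted-line summary
#'
#' Lightweight container for any fitted straight line in the pipeline
#' (blot standard curve, GFP calibration, fraction-vs-area regression):
#' slope, intercept, coefficient of determination, and the x interval over
#' which interpolation is considered valid.
#'
#' @param slope,intercept Line coefficients.
#' @param r_squared Coefficient of determination, in [0, 1].
#' @param x_range Length-2 increasing numeric vector: valid interpolation
#'   interval on x.
#' @return An object of class `linear_model`.
#' @export
linear_model <- function(slope, intercept, r_squared = NA_real_,
                         x_range = c(-Inf, Inf)) {
  stopifnot(is.numeric(slope), is.numeric(intercept), length(x_range) == 2L)
  if (!is.na(r_squared) && (r_squared < -1e-12 || r_squared > 1 + 1e-12)) {
    stop("r_squared must lie in [0, 1]", call. = FALSE)
  }
  if (x_range[1] > x_range[2]) stop("x_range must be ordered", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = min(max(r_squared, 0), 1),
                 x_range = as.numeric(x_range)),
            class = "linear_model")
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("linear model: y = %.6g x + %.6g  (R^2 = %.4f, x in [%g, %g])\n",
              x$slope, x$intercept, x$r_squared, x$x_range[1], x$x_range[2]))
  invisible(x)
}

#' Serialize / deserialize a `linear_model` as JSON
#' @param model A `linear_model`.
#' @param path File path.
#' @return `read_linear_model` returns a `linear_model`;
#'   `write_linear_model` returns `path` invisibly.
#' @export
write_linear_model <- function(model, path) {
  stopifnot(inherits(model, "linear_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_linear_model
#' @export
read_linear_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  linear_model(x$slope, x$intercept, x$r_squared, x$x_range)
}

# Internal: fit y ~ x by OLS and wrap as linear_model.
fit_line <- function(x, y) {
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("degenerate design: x values have zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  # noise-free standards give a perfect fit; summary.lm warns about it
  r2 <- suppressWarnings(summary(fit)$r.squared)
  linear_model(slope = unname(stats::coef(fit)[2L]),
               intercept = unname(stats::coef(fit)[1L]),
               r_squared = r2,
               x_range = range(x))
}
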