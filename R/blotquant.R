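#' Build a table of immunoblot lanes
#'
#' A lane is either a purified-protein standard (`loaded_mass` in ng) or a
#' lysate lane (`loaded_mass` in ug total protein); `signal` is the band's
#' densitometry readout in arbitrary units.
#'
#' @param label Character lane labels.
#' @param kind `"standard"` or `"lysate"`, recycled.
#' @param loaded_mass Loaded mass: ng (standards) or ug (lysates), > 0.
#' @param signal Band signal, AU, >= 0.
#' @return A data frame of class `blot_lanes`.
#' @export
blot_lanes <- function(label, kind, loaded_mass, signal) {
  df <- data.frame(label = as.character(label),
                   kind = as.character(kind),
                   loaded_mass = as.numeric(loaded_mass),
                   signal = as.numeric(signal),
                   stringsAsFactors = FALSE)
  if (!all(df$kind %in% c("standard", "lysate"))) {
    stop("kind must be 'standard' or 'lysate'", call. = FALSE)
  }
  if (any(df$loaded_mass <= 0)) stop("loaded_mass must be > 0", call. = FALSE)
  if (any(df$signal < 0)) stop("signal must be >= 0", call. = FALSE)
  class(df) <- c("blot_lanes", "data.frame")
  df
}

#' Read / write lane tables as CSV
#' @param path CSV path with columns label, kind, loaded_mass, signal.
#' @return `read_blot_lanes` returns a `blot_lanes` data frame.
#' @export
read_blot_lanes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  blot_lanes(df$label, df$kind, df$loaded_mass, df$signal)
}

#' @rdname read_blot_lanes
#' @param lanes A `blot_lanes` data frame.
#' @export
write_blot_lanes <- function(lanes, path) {
  utils::write.csv(lanes, path, row.names = FALSE)
  invisible(path)
}

#' Fit a densitometry standard curve
#'
#' Ordinary least-squares line of band signal (AU) against loaded mass of
#' purified protein (ng). The valid interpolation interval (`x_range`) is
#' the span of the standard masses: lysate bands are only quantified if
#' their inverse-predicted mass falls inside it ("linear range" rule).
#'
#' @param standards A `blot_lanes` table (only rows with
#'   `kind == "standard"` are used) or any data frame with `loaded_mass`
#'   and `signal`.
#' @return A [linear_model()] (signal = slope x mass + intercept).
#' @export
#' @examples
#' std <- blot_lanes(paste0("s", 1:3), "standard", c(1, 2, 3), c(10, 20, 30))
#' fit_standard_curve(std)  # slope 10, intercept 0
fit_standard_curve <- function(standards) {
  if ("kind" %in% names(standards)) {
    standards <- standards[standards$kind == "standard", , drop = FALSE]
  }
  if (nrow(standards) < 3L) {
    stop("need at least 3 standard lanes", call. = FALSE)
  }
  if (length(unique(standards$loaded_mass)) < 2L) {
    stop("degenerate standards: loaded masses have zero variance",
         call. = FALSE)
  }
  fit_line(standards$loaded_mass, standards$signal)
}

#' Quantify a lysate lane against a standard curve
#'
#' Inverse-predicts the mass of target protein in the lane from its band
#' signal, then normalises by the loaded mass of total protein:
#' `abundance = ((signal - intercept) / slope) / loaded_mass` in ng/ug.
#' Lanes whose predicted mass falls outside the standard curve's
#' interpolation range are rejected with an out-of-linear-range error.
#'
#' @param lane One-row `blot_lanes` table (or list) with `kind ==
#'   "lysate"`, `loaded_mass` in ug, and `signal` in AU.
#' @param curve A [linear_model()] from [fit_standard_curve()].
#' @return Abundance in ng target protein per ug total protein.
#' @export
quantify_lysate <- function(lane, curve) {
  stopifnot(inherits(curve, "linear_model"))
  if (is.data.frame(lane)) {
    stopifnot(nrow(lane) == 1L)
    lane <- as.list(lane)
  }
  if (!identical(lane$kind, "lysate")) {
    stop("lane is not a lysate lane", call. = FALSE)
  }
  mass <- (lane$signal - curve$intercept) / curve$slope
  if (mass < curve$x_range[1] || mass > curve$x_range[2]) {
    stop(sprintf(paste0("out of linear range: predicted mass %.3g ng lies ",
                        "outside the standard range [%.3g, %.3g] ng"),
                 mass, curve$x_range[1], curve$x_range[2]),
         call. = FALSE)
  }
  mass / lane$loaded_mass
}

#' Quantify every lysate lane on a blot, skipping out-of-range lanes
#'
#' Convenience wrapper over [quantify_lysate()]: lanes outside the linear
#' range are excluded (with a message naming them) rather than aborting
#' the whole blot, so they never contribute to the replicate aggregate.
#'
#' @param lanes A `blot_lanes` table.
#' @param curve A [linear_model()]; defaults to fitting the standards in
#'   `lanes`.
#' @return A data frame with columns `label`, `abundance`, `in_range`.
#' @export
quantify_blot <- function(lanes, curve = fit_standard_curve(lanes)) {
  lys <- lanes[lanes$kind == "lysate", , drop = FALSE]
  if (nrow(lys) == 0L) stop("no lysate lanes to quantify", call. = FALSE)
  res <- data.frame(label = lys$label, abundance = NA_real_,
                    in_range = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lys))) {
    ab <- tryCatch(quantify_lysate(lys[i, ], curve), error = function(e) e)
    if (inherits(ab, "error")) {
      message(sprintf("lane '%s' excluded: %s", lys$label[i],
                      conditionMessage(ab)))
    } else {
      res$abundance[i] <- ab
      res$in_range[i] <- TRUE
    }
  }
  res
}

#' Aggregate replicate abundance measurements
#'
#' Mean, sample standard deviation (n - 1 denominator; `NA` when only one
#' replicate), and replicate count, matching the "mean +/- SD over n
#' blots" convention of the reference table.
#'
#' @param abundances Numeric vector of replicate abundances (ng/ug).
#' @return A list with `mean`, `sd`, `n`.
#' @export
aggregate_replicates <- function(abundances) {
  abundances <- abundances[!is.na(abundances)]
  n <- length(abundances)
  if (n == 0L) stop("no replicate measurements", call. = FALSE)
  list(mean = mean(abundances),
       sd = if (n > 1L) stats::sd(abundances) else NA_real_,
       n = n)
}

#' Fit the GFP-intensity calibration line
#'
#' Least-squares line of per-cell GFP fluorescence intensity (AU, response)
#' against cellular concentration determined by quantitative Western
#' blotting (uM, predictor). The published calibration is
#' y = 102 x + 35.22. The orientation matches that printed line; use
#' [predict_concentration_from_gfp()] to invert it.
#'
#' @param pairs Data frame with columns `western_conc` (uM) and
#'   `gfp_intensity` (AU).
#' @return A [linear_model()] (intensity = slope x conc + intercept).
#' @export
fit_gfp_calibration <- function(pairs) {
  stopifnot(all(c("western_conc", "gfp_intensity") %in% names(pairs)))
  if (any(pairs$western_conc < 0) || any(pairs$gfp_intensity < 0)) {
    stop("calibration pairs must be non-negative", call. = FALSE)
  }
  fit_line(pairs$western_conc, pairs$gfp_intensity)
}

#' Estimate a cellular concentration from GFP intensity
#'
#' Inverts the calibration line: `conc = (intensity - intercept) / slope`.
#' Signals below the calibration intercept would imply a negative
#' concentration and are rejected.
#'
#' @param intensity Per-cell fluorescence, AU.
#' @param model A [linear_model()] from [fit_gfp_calibration()].
#' @return Concentration in uM.
#' @export
predict_concentration_from_gfp <- function(intensity, model) {
  stopifnot(inherits(model, "linear_model"))
  conc <- (intensity - model$intercept) / model$slope
  if (any(conc < 0)) {
    stop("signal below calibration: implied concentration is negative",
         call. = FALSE)
  }
  conc
}

#' Generate a synthetic quantitative-blot fixture
#'
#' Simulates one immunoblot: standard lanes at the given purified-protein
#' masses and three lysate lanes at the given total-protein loads, with
#' band signals drawn from a hidden linear signal-mass response plus
#' additive Gaussian noise. The true abundance (ng/ug) is known, so the
#' fixture exercises the whole standard-curve / interpolation path with a
#' recoverable ground truth. Deterministic for a fixed seed.
#'
#' @param true_abundance Ground-truth abundance, ng target per ug total
#'   protein.
#' @param standards Masses of the standard lanes, ng.
#' @param lysate_loads Total protein loaded in the lysate lanes, ug.
#'   Defaults put the lysate bands inside the default standard range.
#' @param slope,intercept Hidden detector response (AU per ng, AU).
#' @param noise_sd Additive Gaussian noise SD on every band signal, AU
#'   (>= 0).
#' @param seed Integer seed; fixes the fixture bitwise.
#' @return A list with `lanes` (a `blot_lanes` table) and `truth`
#'   (list: `abundance`, `slope`, `intercept`).
#' @export
#' @examples
#' fx <- generate_blot_fixture(7.99, seed = 1)
#' curve <- fit_standard_curve(fx$lanes)
#' quantify_blot(fx$lanes, curve)
generate_blot_fixture <- function(true_abundance,
                                  standards = c(2.5, 5, 10, 20, 40, 80),
                                  lysate_loads = c(1, 2, 4),
                                  slope = 50, intercept = 100,
                                  noise_sd = 0, seed = 1L) {
  stopifnot(true_abundance >= 0, noise_sd >= 0, length(standards) >= 3L)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  lys_mass <- true_abundance * lysate_loads          # ng of target per lane
  masses <- c(standards, lys_mass)
  signal <- slope * masses + intercept +
    stats::rnorm(length(masses), sd = noise_sd)
  signal <- pmax(signal, 0)
  lanes <- blot_lanes(
    label = c(sprintf("std_%gng", standards),
              sprintf("lysate_%gug", lysate_loads)),
    kind = rep(c("standard", "lysate"),
               c(length(standards), length(lysate_loads))),
    loaded_mass = c(standards, lysate_loads),
    signal = signal)
  list(lanes = lanes,
       truth = list(abundance = true_abundance, slope = slope,
                    intercept = intercept))
}

# Internal seed hygiene: set the RNG deterministically, restore on exit so
# generators do not disturb the caller's RNG stream.
local_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(as.integer(seed))
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
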