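#' Coefficient of variation
#'
#' Sample standard deviation divided by the mean — the scale-free
#' dispersion measure used to compare cell-to-cell variability of ABP
#' expression across proteins with very different mean intensities.
#'
#' @param values Numeric vector, n >= 2, positive mean.
#' @return CV (dimensionless).
#' @export
#' @examples
#' coefficient_of_variation(c(1, 3))  # 1.414 / 2 = 0.707
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L) stop("need at least 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean must be > 0", call. = FALSE)
  stats::sd(values) / m
}

#' Regress a per-cell quantity against cell area
#'
#' OLS regression of the cytosolic fraction (or total intensity) on
#' projected cell area (um^2), the proxy for cell-cycle stage. Reports
#' the slope with its 95% confidence interval and a `constant` verdict:
#' `TRUE` when the CI contains 0, i.e., no detectable trend of the
#' quantity over the cell cycle. (The CI criterion is this package's
#' operationalisation of "no major fluctuation"; it is reported alongside
#' the raw slope, and no multiplicity correction is applied when several
#' proteins are screened.)
#'
#' @param table Data frame with `area_um2` and the response column
#'   (`fraction`/`measured_fraction` or `total_intensity`).
#' @param response `"fraction"` or `"total_intensity"`.
#' @param level Confidence level for the slope CI.
#' @return A list with `model` (a [linear_model()]), `slope_ci`
#'   (length 2), `constant` (logical), `n`.
#' @export
regress_vs_area <- function(table, response = c("fraction",
                                                "total_intensity"),
                            level = 0.95) {
  response <- match.arg(response)
  col <- if (response == "fraction") {
    intersect(c("fraction", "measured_fraction", "true_fraction"),
              names(table))[1]
  } else "total_intensity"
  if (is.na(col) || !col %in% names(table)) {
    stop("table lacks a '", response, "' column", call. = FALSE)
  }
  keep <- stats::complete.cases(table[, c("area_um2", col)])
  x <- table$area_um2[keep]
  y <- table[[col]][keep]
  if (length(x) < 3L) stop("need at least 3 cells", call. = FALSE)
  if (length(unique(x)) < 2L) {
    stop("degenerate design: areas have zero variance", call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  ci <- stats::confint(fit, "x", level = level)
  model <- linear_model(slope = unname(stats::coef(fit)[2L]),
                        intercept = unname(stats::coef(fit)[1L]),
                        r_squared = summary(fit)$r.squared,
                        x_range = range(x))
  list(model = model, slope_ci = as.numeric(ci),
       constant = ci[1] <= 0 && ci[2] >= 0, n = length(x))
}

#' Compare cellular concentrations across quantification methods
#'
#' Joins per-protein concentration tables from quantitative Western
#' blotting, GFP-intensity calibration, and an external reference (e.g.,
#' mass-spectrometry meta-analysis) and reports pairwise ratios and
#' absolute differences against the Western values. Proteins missing
#' from a method stay `NA` (absent, never imputed).
#'
#' @param western,gfp,reference Data frames with columns `name` and
#'   `conc` (uM); `gfp` and `reference` may be `NULL`.
#' @return A data frame keyed by `name` with columns `western`, `gfp`,
#'   `reference`, `gfp_ratio` (gfp/western), `gfp_diff`,
#'   `reference_ratio`, `reference_diff`.
#' @export
#' @examples
#' mc <- method_comparison_table()
#' compare_methods(data.frame(name = mc$name, conc = mc$western),
#'                 data.frame(name = mc$name, conc = mc$gfp),
#'                 data.frame(name = mc$name, conc = mc$mass_spec))
compare_methods <- function(western, gfp = NULL, reference = NULL) {
  check_conc_table <- function(x, what) {
    if (!all(c("name", "conc") %in% names(x))) {
      stop(what, " table needs columns 'name' and 'conc'", call. = FALSE)
    }
    x[, c("name", "conc")]
  }
  western <- check_conc_table(western, "western")
  out <- data.frame(name = western$name, western = western$conc,
                    stringsAsFactors = FALSE)
  for (nm in c("gfp", "reference")) {
    tbl <- get(nm)
    if (is.null(tbl)) {
      out[[nm]] <- NA_real_
    } else {
      tbl <- check_conc_table(tbl, nm)
      out[[nm]] <- tbl$conc[match(out$name, tbl$name)]
    }
  }
  if (all(is.na(out$gfp)) && all(is.na(out$reference))) {
    stop("empty intersection: no protein measured by a second method",
         call. = FALSE)
  }
  out$gfp_ratio <- out$gfp / out$western
  out$gfp_diff <- abs(out$gfp - out$western)
  out$reference_ratio <- out$reference / out$western
  out$reference_diff <- abs(out$reference - out$western)
  out
}

# Internal: report-style rounding (3 significant figures, full precision
# kept internally).
round_report <- function(x, digits = 3L) signif(x, digits)

#' Rebuild the quantitative ABP summary from raw inputs
#'
#' Recomputes every derived column of the reference summary from the raw
#' measurements: abundance + molecular weight -> cellular concentration
#' (via the calibrated conversion constant), concentration -> molecules
#' per cell (via the cytosolic volume), and cellular concentration x
#' cytosolic fraction -> cytosolic concentration. Also attaches the actin
#' budget. Deterministic given its inputs; report values are rounded to
#' 3 significant figures while the returned tables keep full precision.
#'
#' @param records An `abp_table` carrying at least `name`, `mw`,
#'   `abundance`, and optionally `cytosolic_fraction`.
#' @param constants A `cell_constants` object.
#' @param kinetics A [cable_kinetics()] object for the budget.
#' @param path Optional output stem; writes `<stem>.csv` (full
#'   precision), `<stem>.json` (budget summary) and `<stem>.md`
#'   (rounded human-readable report).
#' @return A list of class `abp_report`: `table` (derived columns, full
#'   precision), `budget`, `constants`.
#' @export
build_report <- function(records = abp_reference_table(),
                         constants = default_cell_constants(),
                         kinetics = cable_kinetics(),
                         path = NULL) {
  need <- c("name", "mw", "abundance")
  if (!all(need %in% names(records))) {
    stop("records lack required columns: ",
         paste(setdiff(need, names(records)), collapse = ", "),
         call. = FALSE)
  }
  vol <- cytosolic_volume(constants)
  conc <- abundance_to_concentration(records$abundance, records$mw,
                                     constants)
  mols <- concentration_to_molecules(conc, vol,
                                     avogadro = constants$avogadro)
  frac <- if ("cytosolic_fraction" %in% names(records)) {
    records$cytosolic_fraction
  } else {
    rep(NA_real_, nrow(records))
  }
  cyt <- ifelse(is.na(frac), NA_real_, conc * frac)
  tbl <- data.frame(name = records$name, mw = records$mw,
                    abundance = records$abundance,
                    cellular_conc = conc,
                    molecules_per_cell = mols,
                    cytosolic_fraction = frac,
                    cytosolic_conc = cyt,
                    stringsAsFactors = FALSE)
  budget <- if (all(c("binds_f_actin", "binds_g_actin", "cellular_conc")
                    %in% names(records)) && "Act1" %in% records$name) {
    actin_budget(records, kinetics = kinetics)
  } else NULL
  report <- structure(list(table = tbl, budget = budget,
                           constants = constants), class = "abp_report")
  if (!is.null(path)) {
    utils::write.csv(tbl, paste0(path, ".csv"), row.names = FALSE)
    if (!is.null(budget)) write_budget_report(budget, paste0(path, "_budget"))
    writeLines(format_report_md(report), paste0(path, ".md"))
  }
  report
}

# Internal: markdown rendering of a report, rounded to summary precision.
format_report_md <- function(report) {
  tbl <- report$table
  lines <- c("# ABP quantitative summary", "",
             sprintf("Cytosolic volume: %.1f fL; conversion K: %.4g",
                     cytosolic_volume(report$constants),
                     conversion_constant(report$constants)), "",
             "| Protein | MW (kDa) | ng/ug | uM | Molecules/cell | Cytosolic fraction | Cytosolic uM |",
             "|---|---|---|---|---|---|---|")
  for (i in seq_len(nrow(tbl))) {
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s | %.3g | %s | %s |",
      tbl$name[i], tbl$mw[i], round_report(tbl$abundance[i]),
      round_report(tbl$cellular_conc[i]), tbl$molecules_per_cell[i],
      ifelse(is.na(tbl$cytosolic_fraction[i]), "-",
             round_report(tbl$cytosolic_fraction[i], 2L)),
      ifelse(is.na(tbl$cytosolic_conc[i]), "-",
             round_report(tbl$cytosolic_conc[i], 2L))))
  }
  if (!is.null(report$budget)) {
    b <- report$budget
    lines <- c(lines, "", "## Actin budget (uM)", "",
               sprintf("- Total actin: %.3g", b$total_actin),
               sprintf("- G-actin (kinetic estimate): %.3g", b$g_actin),
               sprintf("- F-actin (by subtraction): %.3g", b$f_actin),
               sprintf("- Sum of F-actin binders: %.3g (%.3gx F-actin)",
                       b$sum_f_binders, b$f_occupancy_ratio),
               sprintf("- Sum of G-actin binders: %.3g (%.3gx G-actin)",
                       b$sum_g_binders, b$g_occupancy_ratio))
  }
  lines
}

#' @export
print.abp_report <- function(x, ...) {
  cat(format_report_md(x), sep = "\n")
  invisible(x)
}
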