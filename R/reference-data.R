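#' The packaged reference table of yeast actin and actin-binding proteins
#'
#' Returns the quantitative summary of *S. cerevisiae* actin (Act1) plus
#' 14 conserved actin-binding proteins, as published: molecular weight
#' (kDa), cellular abundance (ng ABP per ug total protein, mean and SD,
#' with the number of Western replicates), cellular concentration (uM),
#' molecules per cell, the fraction of each protein free in the cytosol
#' (stored as a fraction in [0, 1]; the source prints percentages), and
#' the cytosolic concentration (uM). Three proteins were not quantified by
#' Western blotting: Pfy1 and Abp140 were measured by GFP-intensity
#' calibration and Tpm2 by a 1:6 molar ratio to Tpm1 (`method` column).
#'
#' Additional curation columns: `binds_f_actin` / `binds_g_actin` flag
#' membership in the F-actin-binder and G-actin-binder classes used by
#' [sum_binder_class()], and `oligomer_n` gives polypeptides per
#' functional unit (2 for the Cap1/2 heterodimer, whose concentration is
#' expressed per heterodimer; 6 for the Srv2 hexamer, whose concentration
#' is per polypeptide).
#'
#' Two printed molecule counts (Aip1 and Cap1/2) are not reproducible as
#' `cellular_conc x cytosolic volume x N_A`; they are shipped as printed.
#' See the package vignette for the data-integrity discussion.
#'
#' @param path Optional path to a CSV with the same columns; defaults to
#'   the copy installed with the package.
#' @return A data frame of class `abp_table` with 15 rows.
#' @export
#' @examples
#' ref <- abp_reference_table()
#' ref[ref$name == "Act1", c("abundance", "cellular_conc")]
abp_reference_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "abp_reference_table.csv",
                        package = "abpcensus", mustWork = TRUE)
  }
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_abp_table(tbl)
  class(tbl) <- c("abp_table", "data.frame")
  tbl
}

# Internal: integrity checks on a reference/abp table.
validate_abp_table <- function(tbl) {
  required <- c("name", "common_name", "mw", "abundance", "abundance_sd",
                "n_blots", "cellular_conc", "cellular_conc_sd",
                "molecules_per_cell", "cytosolic_fraction",
                "cytosolic_fraction_sd", "cytosolic_conc",
                "cytosolic_conc_sd", "method", "binds_f_actin",
                "binds_g_actin", "oligomer_n")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    stop("reference table corrupt: missing columns ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tbl$name)) {
    stop("reference table corrupt: duplicated protein names", call. = FALSE)
  }
  with(tbl, {
    if (any(mw <= 0)) stop("reference table corrupt: mw <= 0", call. = FALSE)
    if (any(abundance < 0, na.rm = TRUE)) {
      stop("reference table corrupt: negative abundance", call. = FALSE)
    }
    fr <- cytosolic_fraction
    if (any(fr < 0 | fr > 1, na.rm = TRUE)) {
      stop("reference table corrupt: cytosolic_fraction outside [0, 1]",
           call. = FALSE)
    }
    both <- !is.na(cytosolic_conc) & !is.na(cellular_conc)
    # published values are rounded to 2 significant figures; allow that slack
    if (any(cytosolic_conc[both] > cellular_conc[both] + 0.05)) {
      stop("reference table corrupt: cytosolic_conc exceeds cellular_conc",
           call. = FALSE)
    }
    if (any(oligomer_n < 1)) {
      stop("reference table corrupt: oligomer_n < 1", call. = FALSE)
    }
  })
  invisible(tbl)
}

#' Write an ABP table back to CSV
#'
#' Round-trips with [abp_reference_table()]: reading the written file
#' reproduces the same data.
#'
#' @param tbl An `abp_table` (or compatible data frame).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_abp_table <- function(tbl, path) {
  validate_abp_table(tbl)
  utils::write.csv(tbl, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Cross-method concentration comparison data
#'
#' Cellular concentrations (uM) of proteins measured by more than one
#' method: quantitative Western blotting and GFP-intensity calibration
#' (both from the same study) and a mass-spectrometry meta-analysis
#' (shipped as a comparison column only). Only the values printed in the
#' source are included; entries not printed are `NA`.
#'
#' @return A data frame with columns `name`, `western`, `gfp`, `mass_spec`
#'   (all concentrations in uM).
#' @seealso [compare_methods()]
#' @export
method_comparison_table <- function() {
  path <- system.file("extdata", "method_comparison.csv",
                      package = "abpcensus", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
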