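#' Kinetic constants for actin cable polymerization
#'
#' The three observations the G-actin estimate rests on: the in vivo cable
#' elongation rate (~0.3 um/s), the linear density of subunits in an actin
#' filament (370 subunits/um), and the formin-mediated elongation rate
#' coefficient with profilin-actin (~25 subunits s^-1 uM^-1).
#'
#' @param cable_rate Cable elongation rate, um/s.
#' @param subunits_per_um Actin subunits per um of filament.
#' @param formin_rate_coeff Elongation rate coefficient,
#'   subunits s^-1 uM^-1.
#' @return An object of class `cable_kinetics`.
#' @export
cable_kinetics <- function(cable_rate = 0.3, subunits_per_um = 370,
                           formin_rate_coeff = 25) {
  vals <- c(cable_rate, subunits_per_um, formin_rate_coeff)
  if (any(!is.finite(vals)) || any(vals < 0) || formin_rate_coeff == 0) {
    stop("cable kinetics must be finite, non-negative, with a positive ",
         "formin rate coefficient", call. = FALSE)
  }
  structure(list(cable_rate = cable_rate,
                 subunits_per_um = subunits_per_um,
                 formin_rate_coeff = formin_rate_coeff),
            class = "cable_kinetics")
}

#' Profilin-G-actin concentration needed to sustain cable growth
#'
#' A cable tip consuming `cable_rate x subunits_per_um` subunits/s at a
#' polymerase elongating at `formin_rate_coeff` subunits/s per uM of
#' profilin-actin requires a monomer pool of
#' `(cable_rate x subunits_per_um) / formin_rate_coeff` uM. With the
#' default constants this is 4.44 uM, the basis of the ~4.4 uM cytosolic
#' G-actin estimate.
#'
#' @param k A [cable_kinetics()] object.
#' @return Profilin-G-actin concentration, uM.
#' @export
#' @examples
#' estimate_g_actin(cable_kinetics())  # 4.44 uM
estimate_g_actin <- function(k = cable_kinetics()) {
  stopifnot(inherits(k, "cable_kinetics"))
  k$cable_rate * k$subunits_per_um / k$formin_rate_coeff
}

#' F-actin concentration by subtraction
#'
#' Total cellular actin minus the kinetically estimated G-actin pool.
#' With 13.2 uM total actin and 4.4 uM G-actin this gives 8.8 uM F-actin
#' (roughly two-thirds of the cellular actin in filamentous form).
#'
#' @param total_actin Total cellular actin, uM.
#' @param g_actin G-actin pool, uM (must not exceed `total_actin`).
#' @return F-actin concentration, uM.
#' @export
f_actin_by_subtraction <- function(total_actin, g_actin) {
  if (g_actin > total_actin) {
    stop("g_actin exceeds total actin", call. = FALSE)
  }
  total_actin - g_actin
}

#' Sum cellular concentrations of a binder class
#'
#' Adds the cellular concentrations of all proteins flagged as binding
#' F-actin (or G-actin). Actin itself is always excluded. On the packaged
#' reference table the 13 F-actin binders sum to ~42.2 uM and the 4
#' G-actin binders (Cof1, Pfy1, Srv2, Twf1) to ~19.3 uM.
#'
#' @param records An `abp_table` (see [abp_reference_table()]).
#' @param class `"f_actin"` or `"g_actin"`.
#' @return Summed concentration, uM.
#' @export
sum_binder_class <- function(records, class = c("f_actin", "g_actin")) {
  class <- match.arg(class)
  if (nrow(records) == 0L) return(0)
  flag <- if (class == "f_actin") records$binds_f_actin else
    records$binds_g_actin
  keep <- flag & records$name != "Act1"
  sum(records$cellular_conc[keep], na.rm = TRUE)
}

#' Cytosolic concentration from cellular concentration and free fraction
#'
#' @param cellular_conc Cellular concentration, uM.
#' @param cytosolic_fraction Fraction of the protein free in the cytosol,
#'   in [0, 1].
#' @return Cytosolic concentration, uM (never exceeds `cellular_conc`).
#' @export
cytosolic_concentration <- function(cellular_conc, cytosolic_fraction) {
  if (any(cytosolic_fraction < 0 | cytosolic_fraction > 1, na.rm = TRUE)) {
    stop("cytosolic_fraction must lie in [0, 1]", call. = FALSE)
  }
  cellular_conc * cytosolic_fraction
}

#' Concentration of functional oligomers from polypeptide concentration
#'
#' Some ABPs oligomerize: Srv2 forms hexamers, so ~3 uM Srv2 polypeptide
#' is ~0.5 uM hexamers competent to bind actin.
#'
#' @param polypeptide_conc Polypeptide concentration, uM.
#' @param oligomer_n Polypeptides per functional unit (>= 1).
#' @return Oligomer concentration, uM.
#' @export
oligomer_concentration <- function(polypeptide_conc, oligomer_n) {
  if (any(oligomer_n < 1)) stop("oligomer_n must be >= 1", call. = FALSE)
  polypeptide_conc / oligomer_n
}

#' Diffusion-limited binding kinetics
#'
#' @param k_on Association rate constant, s^-1 uM^-1 (~10 for
#'   diffusion-limited binding).
#' @param conc Cytosolic concentration of the binder, uM.
#' @return An object of class `binding_kinetics`.
#' @export
binding_kinetics <- function(k_on = 10, conc) {
  if (!is.finite(k_on) || k_on <= 0 || !is.finite(conc) || conc <= 0) {
    stop("k_on and conc must be finite and > 0", call. = FALSE)
  }
  structure(list(k_on = k_on, conc = conc), class = "binding_kinetics")
}

#' Characteristic time for a cytosolic binder to find new F-actin sites
#'
#' Mean waiting time of a pseudo-first-order association,
#' `1 / (k_on x conc)`. At a diffusion-limited on-rate of 10 s^-1 uM^-1,
#' 3.2 uM cytosolic Abp1 binds new filament sites within ~0.03 s of
#' polymerization.
#'
#' @param k A [binding_kinetics()] object.
#' @return Mean binding time, seconds.
#' @export
#' @examples
#' binding_timescale(binding_kinetics(10, 3.2))  # ~0.031 s
binding_timescale <- function(k) {
  stopifnot(inherits(k, "binding_kinetics"))
  1 / (k$k_on * k$conc)
}

#' Subunit consumption rate of a growing filament
#'
#' Product of the elongation rate and the filament's linear subunit
#' density: patches growing at ~0.05 um/s consume ~18.5 subunits/s;
#' cables at ~0.3 um/s consume ~111 subunits/s.
#'
#' @param growth_rate Filament elongation rate, um/s.
#' @param subunits_per_um Subunits per um of filament.
#' @return Subunits incorporated per second.
#' @export
filament_subunit_rate <- function(growth_rate, subunits_per_um = 370) {
  if (growth_rate < 0 || subunits_per_um <= 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  growth_rate * subunits_per_um
}

#' Assemble the cellular actin budget
#'
#' Runs the complete bookkeeping: kinetic G-actin estimate, F-actin by
#' subtraction, binder-class sums, per-protein cytosolic concentrations,
#' oligomer accounting for Srv2 and Cap1/2, and occupancy ratios
#' (summed binders / available actin form). Cofilin's cytosolic fraction
#' was not measurable with a functional GFP fusion; reports that need it
#' use an assumed value (default 0.76, the midpoint of the observed
#' 0.61-0.91 range across the other ABPs), labelled as assumed in the
#' output.
#'
#' @param records An `abp_table`; defaults to the packaged reference
#'   table.
#' @param kinetics A [cable_kinetics()] object.
#' @param cof1_fraction Assumed cytosolic fraction for Cof1.
#' @param k_on Diffusion-limited on-rate for binding timescales,
#'   s^-1 uM^-1.
#' @return A list of class `actin_budget`: `total_actin`, `g_actin`,
#'   `f_actin`, `sum_f_binders`, `sum_g_binders`, `f_occupancy_ratio`,
#'   `g_occupancy_ratio`, and a per-protein data frame `proteins` with
#'   cytosolic concentrations, oligomer concentrations and binding
#'   timescales.
#' @export
actin_budget <- function(records = abp_reference_table(),
                         kinetics = cable_kinetics(),
                         cof1_fraction = 0.76,
                         k_on = 10) {
  stopifnot(cof1_fraction >= 0, cof1_fraction <= 1)
  act <- records[records$name == "Act1", ]
  if (nrow(act) != 1L) stop("records must contain an Act1 row", call. = FALSE)
  total <- act$cellular_conc
  g <- estimate_g_actin(kinetics)
  f <- f_actin_by_subtraction(total, g)
  sum_f <- sum_binder_class(records, "f_actin")
  sum_g <- sum_binder_class(records, "g_actin")

  abp <- records[records$name != "Act1", , drop = FALSE]
  frac <- abp$cytosolic_fraction
  assumed <- is.na(frac) & abp$name == "Cof1"
  frac[assumed] <- cof1_fraction
  cyt <- ifelse(is.na(frac), NA_real_,
                cytosolic_concentration(abp$cellular_conc, frac))
  proteins <- data.frame(
    name = abp$name,
    cellular_conc = abp$cellular_conc,
    cytosolic_fraction = frac,
    fraction_assumed = assumed,
    cytosolic_conc = cyt,
    oligomer_n = abp$oligomer_n,
    oligomer_conc = oligomer_concentration(cyt, abp$oligomer_n),
    binding_time_s = ifelse(is.na(cyt) | cyt <= 0, NA_real_,
                            1 / (k_on * cyt)),
    stringsAsFactors = FALSE)

  structure(list(total_actin = total, g_actin = g, f_actin = f,
                 sum_f_binders = sum_f, sum_g_binders = sum_g,
                 f_occupancy_ratio = sum_f / f,
                 g_occupancy_ratio = sum_g / g,
                 k_on = k_on,
                 proteins = proteins),
            class = "actin_budget")
}

#' @export
print.actin_budget <- function(x, ...) {
  cat("Cellular actin budget (uM)\n")
  cat(sprintf("  total actin:      %5.2f\n", x$total_actin))
  cat(sprintf("  G-actin estimate: %5.2f\n", x$g_actin))
  cat(sprintf("  F-actin:          %5.2f\n", x$f_actin))
  cat(sprintf("  sum F-binders:    %5.2f  (%.1fx the F-actin pool)\n",
              x$sum_f_binders, x$f_occupancy_ratio))
  cat(sprintf("  sum G-binders:    %5.2f  (%.1fx the G-actin pool)\n",
              x$sum_g_binders, x$g_occupancy_ratio))
  invisible(x)
}

#' Write the budget report as CSV + JSON
#'
#' The per-protein table goes to `<stem>.csv`, and the scalar summary
#' (pools, sums and occupancy ratios) to `<stem>.json`.
#'
#' @param budget An [actin_budget()] result.
#' @param stem Output path stem (without extension).
#' @return Character vector of the two paths written, invisibly.
#' @export
write_budget_report <- function(budget, stem) {
  stopifnot(inherits(budget, "actin_budget"))
  csv <- paste0(stem, ".csv")
  json <- paste0(stem, ".json")
  utils::write.csv(budget$proteins, csv, row.names = FALSE)
  summary <- budget[c("total_actin", "g_actin", "f_actin",
                      "sum_f_binders", "sum_g_binders",
                      "f_occupancy_ratio", "g_occupancy_ratio")]
  jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, json))
}
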