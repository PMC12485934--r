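#' Fit a size-exclusion chromatography calibration
#'
#' Least-squares line of `log10(MW)` on elution volume, the standard
#' working range of a gel-filtration column (larger species elute earlier,
#' so a valid fit has negative slope). Void-volume markers (Blue Dextran by
#' default) are excluded from the regression: they elute at the void volume
#' regardless of mass.
#'
#' @param standards data.frame with columns `name`, `mw_kda`, `ve_ml`.
#' @param exclude_void exclude void markers matched by `void_pattern`
#'   (default `TRUE`).
#' @param void_pattern case-insensitive regular expression naming void
#'   markers; default `"blue\\s*dextran"`.
#' @return list of class `calibration_fit`: `slope` (per mL), `intercept`,
#'   `r_squared`, `calibration_range` (mL), `standards_used`.
#' @export
fit_calibration <- function(standards, exclude_void = TRUE,
                            void_pattern = "blue\\s*dextran") {
  stopifnot(all(c("name", "mw_kda", "ve_ml") %in% names(standards)))
  st <- standards[!is.na(standards$mw_kda) & !is.na(standards$ve_ml), , drop = FALSE]
  if (exclude_void) {
    st <- st[!grepl(void_pattern, st$name, ignore.case = TRUE), , drop = FALSE]
  }
  if (any(st$mw_kda <= 0)) stop("molecular weights must be positive")
  if (nrow(st) < 3 || length(unique(st$ve_ml)) < 3) {
    stop("insufficient standards: need >= 3 with distinct elution volumes")
  }
  if (stats::sd(st$ve_ml) == 0) stop("zero variance in elution volumes")
  fit <- stats::lm(log10(mw_kda) ~ ve_ml, data = st)
  slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
  if (slope >= 0) warning("non-negative slope: larger species should elute earlier")
  structure(list(slope = slope, intercept = intercept,
                 r_squared = suppressWarnings(summary(fit)$r.squared),
                 calibration_range = range(st$ve_ml),
                 standards_used = st$name),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> log10(MW kDa) = %.4f * Ve + %.4f  (r^2 = %.4f)\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  calibrated over Ve %.1f-%.1f mL from %d standard(s)\n",
              x$calibration_range[1], x$calibration_range[2],
              length(x$standards_used)))
  invisible(x)
}

#' Estimate molecular weight from an elution volume
#'
#' @param fit a [fit_calibration()] result.
#' @param ve elution volume in mL.
#' @return list: `mw_kda` = `10^(slope * ve + intercept)` and
#'   `extrapolated`, `TRUE` when `ve` lies outside the calibration range.
#' @export
estimate_mw <- function(fit, ve) {
  stopifnot(inherits(fit, "calibration_fit"), is.finite(ve))
  list(mw_kda = 10^(fit$slope * ve + fit$intercept),
       extrapolated = ve < fit$calibration_range[1] | ve > fit$calibration_range[2])
}

#' Oligomeric copy-number range from an apparent mass
#'
#' Converts an apparent (SEC-estimated) mass and a monomer mass into an
#' integer copy-number range under a relative mass tolerance:
#' `[max(1, floor(mw (1 - tol) / monomer)), ceil(mw (1 + tol) / monomer)]`.
#' The default 25% tolerance reflects the accuracy expected of globular
#' SEC calibration applied to a large non-globular assembly.
#'
#' @param mw_estimate apparent mass in kDa.
#' @param monomer_mw monomer mass in kDa.
#' @param rel_tol relative tolerance in `[0, 1)`; default 0.25.
#' @param extrapolated optional flag carried through from [estimate_mw()].
#' @return list of class `stoichiometry_estimate`: `mw_estimate`,
#'   `mw_interval`, `monomer_mw`, `copy_range`, `rel_tol`, `extrapolated`.
#' @export
stoichiometry_range <- function(mw_estimate, monomer_mw, rel_tol = 0.25,
                                extrapolated = FALSE) {
  if (mw_estimate <= 0 || monomer_mw <= 0) stop("masses must be positive")
  if (rel_tol < 0 || rel_tol >= 1) stop("rel_tol must be in [0, 1)")
  lo <- max(1L, as.integer(floor(mw_estimate * (1 - rel_tol) / monomer_mw + 1e-9)))
  hi <- as.integer(ceiling(mw_estimate * (1 + rel_tol) / monomer_mw - 1e-9))
  hi <- max(hi, lo)
  if (mw_estimate < monomer_mw) {
    warning("apparent mass below one monomer; copy range floored at 1")
  }
  structure(list(mw_estimate = mw_estimate,
                 mw_interval = c(mw_estimate * (1 - rel_tol), mw_estimate * (1 + rel_tol)),
                 monomer_mw = monomer_mw,
                 copy_range = c(lo, hi),
                 rel_tol = rel_tol,
                 extrapolated = extrapolated),
            class = "stoichiometry_estimate")
}

#' @export
print.stoichiometry_estimate <- function(x, ...) {
  cat(sprintf("<stoichiometry_estimate> apparent %.0f kDa / monomer %.0f kDa -> %d-%d copies (+/-%.0f%%)%s\n",
              x$mw_estimate, x$monomer_mw, x$copy_range[1], x$copy_range[2],
              100 * x$rel_tol, if (isTRUE(x$extrapolated)) " [extrapolated]" else ""))
  invisible(x)
}

#' Assembly size and mass bookkeeping
#'
#' Residue count and mass of a homo-oligomer, with the headline mass
#' rounded to the nearest MDa.
#'
#' @param monomer_residues monomer length in residues.
#' @param monomer_kda monomer mass in kDa.
#' @param copies copy number (default 4, a homotetramer).
#' @return list: `residues`, `mass_kda`, `mass_mda`, `mass_mda_headline`.
#' @export
assembly_summary <- function(monomer_residues, monomer_kda, copies = 4L) {
  stopifnot(monomer_residues > 0, monomer_kda > 0, copies >= 1)
  kda <- monomer_kda * copies
  list(residues = as.integer(monomer_residues) * as.integer(copies),
       mass_kda = kda,
       mass_mda = kda / 1000,
       mass_mda_headline = round(kda / 1000))
}
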