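#' Thermodynamic parameters
#'
#' Convenience constructor for the thermodynamic constants used by the
#' two-state model; `RT = R * T` in kcal/mol and `kappa` converts REU to
#' kcal/mol.
#'
#' @param T_kelvin temperature (K), default 298.
#' @param R_gas molar gas constant (kcal/mol/K).
#' @param kappa REU to kcal/mol scale factor (default 1).
#' @return list with `R`, `T`, `RT` (kcal/mol) and `kappa`.
#' @export
thermo_params <- function(T_kelvin = 298, R_gas = 0.0019872, kappa = 1) {
  stopifnot(T_kelvin > 0, kappa > 0)
  list(R = R_gas, T = T_kelvin, RT = R_gas * T_kelvin, kappa = kappa)
}

#' Basal activity from the ligand-free free-energy difference
#'
#' The allosteric two-state model: the basal activity equals the
#' active-state fraction of the ligand-free receptor,
#' `BA = K_R / (1 + K_R)` with `K_R = exp(-dG_apo / RT)`, i.e.
#' `BA = 1 / (1 + exp(kappa * dG_apo / RT))`. Energies in REU are converted
#' to kcal/mol by `kappa` (identity by default).
#'
#' @param dG_apo active-minus-inactive free energy of the apo receptor.
#' @param RT kcal/mol (default 0.593, room temperature).
#' @param kappa REU to kcal/mol scale (default 1).
#' @return Basal activity in (0, 1).
#' @export
ba_from_dg <- function(dG_apo, RT = 0.593, kappa = 1) {
  stopifnot(RT > 0, kappa > 0)
  1 / (1 + exp(kappa * dG_apo / RT))
}

#' Free-energy difference from basal activity
#'
#' Inverse of [ba_from_dg]: `dG_apo = -RT * ln(BA / (1 - BA))` (divided by
#' `kappa` to return REU). Basal activities at or outside the open interval
#' (0, 1) are rejected: they correspond to infinite free energies under the
#' two-state model.
#'
#' @param BA basal activity, strictly inside (0, 1).
#' @param RT kcal/mol (default 0.593).
#' @param kappa REU to kcal/mol scale (default 1).
#' @return Free-energy difference (same units as [ba_from_dg] input).
#' @export
dg_from_ba <- function(BA, RT = 0.593, kappa = 1) {
  stopifnot(RT > 0, kappa > 0)
  if (any(BA <= 0 | BA >= 1))
    stop("basal activity must be strictly inside (0, 1)")
  -RT * log(BA / (1 - BA)) / kappa
}

#' Quasi-linearity of the activity-energy relation over a basal range
#'
#' Samples the two-state curve densely over the free-energy interval implied
#' by a basal-activity range, fits a least-squares line, and reports the
#' maximum absolute residual and R^2. Near the inflection (BA around 0.5)
#' the logistic is quasi-linear, which is what licenses a direct linear
#' comparison of measured basal activities with computed energies.
#'
#' @param ba_range length-2 numeric strictly inside (0, 1).
#' @param RT kcal/mol (default 0.593).
#' @param n number of samples (default 501).
#' @return list `max_abs_dev`, `r_squared`, `slope`, `intercept`.
#' @export
quasilinearity_check <- function(ba_range = c(0.4, 0.6), RT = 0.593,
                                 n = 501L) {
  ba_range <- sort(as.numeric(ba_range))
  if (diff(ba_range) <= 0) stop("degenerate basal-activity range")
  if (ba_range[1] <= 0 || ba_range[2] >= 1)
    stop("range must be strictly inside (0, 1)")
  dgs <- seq(dg_from_ba(ba_range[2], RT), dg_from_ba(ba_range[1], RT),
             length.out = n)
  ba <- ba_from_dg(dgs, RT)
  fit <- stats::lm(ba ~ dgs)
  list(max_abs_dev = max(abs(stats::resid(fit))),
       r_squared = summary(fit)$r.squared,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]))
}

#' Fit the activity-energy relation across designs
#'
#' Ordinary least squares of measured basal activity on the computed
#' ligand-free energy difference, with the signed Pearson correlation
#' (scale-free: unchanged by the REU-to-kcal/mol factor).
#'
#' @param records data.frame with columns `basal_frac` and `ddG_apo` (one
#'   row per design; join of the activity and energy tables).
#' @return list `slope`, `intercept`, `pearson_r`, `n`.
#' @export
fit_activity_energy <- function(records) {
  if (nrow(records) < 3L) stop("insufficient data: need at least 3 designs")
  if (stats::sd(records$ddG_apo) == 0)
    stop("degenerate fit: zero variance in ddG_apo")
  fit <- stats::lm(basal_frac ~ ddG_apo, data = records)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = stats::cor(records$ddG_apo, records$basal_frac),
       n = nrow(records))
}

#' Read an activity table
#'
#' TSV `design_id<TAB>basal_frac<TAB>induced_frac<TAB>sem` (fractions of
#' maximal agonist-induced wild-type activity).
#' @param path TSV path.
#' @return data.frame.
#' @export
read_activity_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Read an energy table
#'
#' TSV `design_id<TAB>dG_inactive<TAB>dG_active<TAB>ddG_apo` (REU, relative
#' to the reference receptor).
#' @param path TSV path.
#' @return data.frame.
#' @export
read_energy_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
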