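#' Amino-group quotient from potentiometric titration
#'
#' The two inflection points of the pH curve recorded while titrating a
#' dissolved chitosan sample with NaOH bracket the neutralization of the
#' protonated amino groups; the NaOH consumed between them, per gram of
#' sample, is the molar quotient `Q = cm * dv / m` (mol amino groups per
#' gram chitosan) that feeds [deacetylation_degree()].
#'
#' @param cm Titrant (NaOH) molarity, mol/L; > 0.
#' @param dv Volume difference between the two inflection points, L; >= 0.
#' @param m Mass of the analyzed chitosan sample, g; > 0.
#'
#' @return Q in mol/g (vectorized over the inputs).
#' @examples
#' acetyl_quotient(cm = 0.1, dv = 0.005, m = 0.2) # 0.0025 mol/g
#' @export
acetyl_quotient <- function(cm, dv, m) {
  if (any(cm <= 0)) abort("`cm` must be > 0.")
  if (any(dv < 0)) abort("`dv` must be >= 0.")
  if (any(m <= 0)) abort("`m` (sample mass) must be > 0.")
  cm * dv / m
}

#' Degree of deacetylation from the amino-group quotient
#'
#' Converts the titration quotient `q` (mol amino groups / g chitosan) to
#' the percentage of deacetylated (glucosamine) units:
#' `DD% = 100 * 203 * q / (1 + 42 * q)`, where 203 g/mol is the molar mass
#' of the chitin monomer and 42 g/mol that of the acetyl group. The map is
#' strictly increasing in `q` and saturates at 100 * 203/42; values above
#' 100% are physically impossible and raise a warning rather than being
#' silently capped.
#'
#' @param q Amino-group quotient, mol/g; >= 0.
#' @return DD in percent.
#' @examples
#' deacetylation_degree(0.005) # 83.88 %
#' @export
deacetylation_degree <- function(q) {
  if (any(q < 0)) abort("`q` must be >= 0.")
  dd <- 100 * 203 * q / (1 + 42 * q)
  if (any(dd > 100)) {
    warn(paste0(
      sum(dd > 100), " deacetylation degree value(s) exceed 100% ",
      "(physically impossible); check the titration inputs."
    ))
  }
  dd
}

#' Viscometric molar mass via the Mark-Houwink-Sakurada equation
#'
#' Inverts `[eta] = K * Mv^a` to obtain the viscosity-average molar mass
#' `Mv = (eta / K)^(1/a)` from the measured intrinsic viscosity.
#' The defaults `k = 13.8e-3` mL/g and `a = 0.85` are the constants for
#' chitosan in the standard acetate buffer solvent system.
#'
#' @param eta Intrinsic viscosity, mL/g; > 0.
#' @param k Mark-Houwink constant K, mL/g; > 0.
#' @param a Mark-Houwink exponent; in (0, 1.5].
#'
#' @return Molar mass in g/mol. Divide by 1000 for kDa.
#' @examples
#' mv <- viscometric_molar_mass(245.4) # about 1e5 g/mol
#' intrinsic_viscosity(mv) # back to 245.4
#' @export
viscometric_molar_mass <- function(eta, k = 13.8e-3, a = 0.85) {
  if (any(eta <= 0)) abort("`eta` must be > 0 (Mv is undefined at zero viscosity).")
  if (any(k <= 0)) abort("`k` must be > 0.")
  if (any(a <= 0 | a > 1.5)) abort("`a` must lie in (0, 1.5].")
  (eta / k)^(1 / a)
}

#' @rdname viscometric_molar_mass
#' @param mv Molar mass, g/mol; > 0. `intrinsic_viscosity()` is the
#'   forward Mark-Houwink map `K * Mv^a`, the exact inverse of
#'   `viscometric_molar_mass()`.
#' @export
intrinsic_viscosity <- function(mv, k = 13.8e-3, a = 0.85) {
  if (any(mv <= 0)) abort("`mv` must be > 0.")
  if (any(k <= 0)) abort("`k` must be > 0.")
  k * mv^a
}

#' Chitosan extraction yield
#'
#' Mass yield of the deacetylation step: extracted chitosan over extracted
#' chitin, in percent.
#'
#' @param chitosan_g Mass of extracted chitosan, g; >= 0.
#' @param chitin_g Mass of extracted chitin, g; > 0.
#' @return Yield in percent.
#' @examples
#' chitosan_yield(0.736, 10) # 7.36 %
#' @export
chitosan_yield <- function(chitosan_g, chitin_g) {
  if (any(chitin_g <= 0)) abort("`chitin_g` must be > 0.")
  if (any(chitosan_g < 0)) abort("`chitosan_g` must be >= 0.")
  100 * chitosan_g / chitin_g
}

#' Compute response variables from raw characterization measurements
#'
#' Takes a measurement table (one row per sample) and appends whichever
#' response columns its inputs support: `q_mol_g` and `dd_pct` from
#' titration columns (`cm_mol_L`, `dv`, `m_g`), `mv_g_mol` and `mm_kda`
#' from viscometry (`eta_mL_g`), and `yield_pct` from the mass pair
#' (`chitosan_g`, `chitin_g`). An optional `dv_unit` column (`"L"` or
#' `"mL"`) declares the titration volume unit; volumes in mL are converted
#' to L on ingest.
#'
#' @param data Data frame of measurements.
#' @param k,a Mark-Houwink constants passed to [viscometric_molar_mass()].
#' @return The input as a tibble with computed columns appended.
#' @examples
#' library(tibble)
#' characterize(tibble(
#'   sample_id = 1, cm_mol_L = 0.1, dv = 5, dv_unit = "mL", m_g = 0.2,
#'   eta_mL_g = 245.4, chitosan_g = 0.736, chitin_g = 10
#' ))
#' @export
characterize <- function(data, k = 13.8e-3, a = 0.85) {
  out <- tibble::as_tibble(data)
  has <- function(...) all(c(...) %in% names(out))
  if (has("cm_mol_L", "dv", "m_g")) {
    dv_l <- out$dv
    if ("dv_unit" %in% names(out)) {
      bad <- !out$dv_unit %in% c("L", "mL")
      if (any(bad)) abort("`dv_unit` entries must be \"L\" or \"mL\".")
      dv_l <- ifelse(out$dv_unit == "mL", out$dv / 1000, out$dv)
    }
    out$q_mol_g <- acetyl_quotient(out$cm_mol_L, dv_l, out$m_g)
    out$dd_pct <- deacetylation_degree(out$q_mol_g)
  }
  if (has("eta_mL_g")) {
    out$mv_g_mol <- viscometric_molar_mass(out$eta_mL_g, k = k, a = a)
    out$mm_kda <- out$mv_g_mol / 1000
  }
  if (has("chitosan_g", "chitin_g")) {
    out$yield_pct <- chitosan_yield(out$chitosan_g, out$chitin_g)
  }
  out
}
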