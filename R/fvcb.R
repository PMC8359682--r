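#' Rubisco kinetic constants
#'
#' Container for the Michaelis-Menten kinetics of Rubisco and the CO2
#' compensation point used by the biochemical photosynthesis model. Defaults
#' are widely used tobacco-derived values at 25 degrees C; all computations in
#' this package are at a fixed 25 degrees C block temperature (no Arrhenius
#' scaling).
#'
#' @param Kc Michaelis constant of Rubisco for CO2 (Pa).
#' @param Ko Michaelis constant of Rubisco for O2 (kPa).
#' @param gamma_star CO2 compensation point in the absence of day respiration,
#'   Gamma* (Pa).
#' @param O chloroplast O2 partial pressure (kPa).
#' @return An object of class `kinetic_constants`.
#' @export
#' @examples
#' kinetic_constants()
kinetic_constants <- function(Kc = 27.2, Ko = 16.6, gamma_star = 3.74,
                              O = 21.0) {
  stopifnot(Kc > 0, Ko > 0, gamma_star > 0, O > 0)
  if (gamma_star >= Kc)
    stop("gamma_star must be smaller than Kc")
  structure(list(Kc = Kc, Ko = Ko, gamma_star = gamma_star, O = O),
            class = "kinetic_constants")
}

#' Biochemical model parameter set
#'
#' The five leaf-level parameters estimated from an A/Ci curve: maximum
#' carboxylation rate, electron transport rate at the measurement irradiance,
#' triose phosphate use, day respiration, and mesophyll resistance, together
#' with the Rubisco kinetic constants.
#'
#' @param Vcmax maximum Rubisco carboxylation rate (umol m-2 s-1).
#' @param Jmax electron transport rate at the measurement irradiance
#'   (umol m-2 s-1).
#' @param TPU triose phosphate use (umol m-2 s-1).
#' @param Rd day respiration (umol m-2 s-1).
#' @param rm mesophyll resistance to CO2 diffusion (m2 s Pa umol-1).
#' @param kinetics a [kinetic_constants()] object.
#' @return An object of class `fvcb_params`.
#' @export
#' @examples
#' fvcb_params(Vcmax = 60, Jmax = 120, TPU = 7, Rd = 1, rm = 0.5)
fvcb_params <- function(Vcmax, Jmax, TPU, Rd, rm = 0,
                        kinetics = kinetic_constants()) {
  stopifnot(Vcmax > 0, Jmax > 0, TPU > 0, Rd > 0, rm >= 0)
  structure(list(Vcmax = Vcmax, Jmax = Jmax, TPU = TPU, Rd = Rd, rm = rm,
                 kinetics = kinetics),
            class = "fvcb_params")
}

#' @export
print.fvcb_params <- function(x, ...) {
  cat("FvCB parameter set\n")
  cat(sprintf("  Vcmax %.2f  Jmax %.2f  TPU %.2f  Rd %.3f (umol m-2 s-1)\n",
              x$Vcmax, x$Jmax, x$TPU, x$Rd))
  cat(sprintf("  rm %.4f m2 s Pa umol-1\n", x$rm))
  invisible(x)
}

limitation_states <- c("rubisco", "rubp", "tpu")

# Effective Michaelis constant Kc(1 + O/Ko), Pa. O and Ko both in kPa so the
# ratio is dimensionless.
effective_km <- function(kin) kin$Kc * (1 + kin$O / kin$Ko)

# Net assimilation for the saturating-substrate family A = p(Cc - G*)/(Cc + q)
# - Rd coupled to Cc = Ci - rm*A. Eliminating Cc gives the quadratic
#   rm*A^2 - (Ci + q + rm*(p - Rd))*A + p*(Ci - G*) - Rd*(Ci + q) = 0
# whose lesser root is the physical branch (it reduces to the explicit form as
# rm -> 0). Vectorized over Ci; returns NA where the discriminant is negative.
solve_coupled_a <- function(ci, p, q, rd, rm, gamma_star) {
  cc_term <- ci + q
  const <- p * (ci - gamma_star) - rd * cc_term
  if (rm == 0) return(const / cc_term)
  b <- cc_term + rm * (p - rd)
  disc <- b * b - 4 * rm * const
  a <- rep(NA_real_, length(ci))
  ok <- disc >= 0
  a[ok] <- (b[ok] - sqrt(disc[ok])) / (2 * rm)
  a
}

# Vectorized net rate for one limitation state; workhorse shared by
# net_assimilation() and the curve fitter.
state_net_a <- function(ci, params, limitation) {
  kin <- params$kinetics
  switch(limitation,
    rubisco = solve_coupled_a(ci, params$Vcmax, effective_km(kin),
                              params$Rd, params$rm, kin$gamma_star),
    rubp = solve_coupled_a(ci, params$Jmax / 4, 2 * kin$gamma_star,
                           params$Rd, params$rm, kin$gamma_star),
    tpu = rep(3 * params$TPU - params$Rd, length(ci)),
    stop("unknown limitation state: ", limitation)
  )
}

#' Net assimilation at one intercellular CO2 partial pressure
#'
#' Solves the implicit coupling between the biochemical demand function and
#' CO2 drawdown across the mesophyll: `A = W(Cc)*(1 - Gamma*/Cc) - Rd` with
#' `Cc = Ci - rm*A`. For the Rubisco- and RuBP-regeneration-limited states the
#' elimination of `Cc` yields a quadratic in `A`; the lesser root is the
#' physical branch. The TPU-limited net rate `A = 3*TPU - Rd` is independent
#' of `Cc`.
#'
#' @param Ci intercellular CO2 partial pressure (Pa), scalar.
#' @param params an [fvcb_params()] object.
#' @param limitation one of `"rubisco"`, `"rubp"`, `"tpu"`.
#' @return An object of class `operating_point` with fields `Ci`, `Cc`, `A`,
#'   `Vc` (gross carboxylation rate), `limitation`, and logical flags
#'   `feasible` (positive-Cc root found) and `vc_defined` (`Cc > Gamma*`, so
#'   the gross rate is well defined).
#' @export
#' @examples
#' p <- fvcb_params(60, 120, 7, 1, rm = 0.05)
#' net_assimilation(30, p, "rubisco")
net_assimilation <- function(Ci, params, limitation = limitation_states) {
  limitation <- match.arg(limitation)
  stopifnot(length(Ci) == 1L, Ci > 0)
  a <- state_net_a(Ci, params, limitation)
  if (is.na(a))
    return(operating_point(Ci, NA_real_, NA_real_, NA_real_, limitation,
                           feasible = FALSE, vc_defined = FALSE))
  cc <- Ci - params$rm * a
  feasible <- cc > 0
  gs <- params$kinetics$gamma_star
  vc_defined <- feasible && cc > gs
  # Gross carboxylation Vc from A = Vc*(1 - G*/Cc) - Rd.
  vc <- if (vc_defined) (a + params$Rd) * cc / (cc - gs) else NA_real_
  operating_point(Ci, cc, a, vc, limitation, feasible, vc_defined)
}

operating_point <- function(Ci, Cc, A, Vc, limitation, feasible, vc_defined) {
  structure(list(Ci = Ci, Cc = Cc, A = A, Vc = Vc, limitation = limitation,
                 feasible = feasible, vc_defined = vc_defined),
            class = "operating_point")
}

#' @export
print.operating_point <- function(x, ...) {
  cat(sprintf(
    "Operating point [%s]: Ci %.3f Pa, Cc %.3f Pa, A %.4f, Vc %.4f\n",
    x$limitation, x$Ci, x$Cc, x$A, x$Vc))
  invisible(x)
}

#' Forward A/Ci curve with per-point limitation states
#'
#' Evaluates the three candidate rates at each `Ci` and keeps the minimum
#' (the co-limitation rule of the biochemical model). With the standard
#' parameterization the selected state is monotone non-decreasing in the
#' order rubisco -> rubp -> tpu along increasing `Ci`; violations are
#' reported via a warning, never silently reordered.
#'
#' @param ci_values intercellular CO2 partial pressures (Pa), all positive.
#' @param params an [fvcb_params()] object.
#' @return A list of `operating_point` objects, one per `Ci`.
#' @export
model_curve <- function(ci_values, params) {
  stopifnot(length(ci_values) >= 1L, all(ci_values > 0))
  pts <- lapply(ci_values, function(ci) {
    cand <- lapply(limitation_states, function(s) net_assimilation(ci, params, s))
    a <- vapply(cand, function(p) ifelse(p$feasible, p$A, Inf), numeric(1))
    if (all(!is.finite(a)))
      return(cand[[1L]])  # infeasible point, flagged by feasible = FALSE
    cand[[which.min(a)]]
  })
  labs <- vapply(pts, `[[`, character(1), "limitation")
  ord <- order(ci_values)
  ranks <- match(labs[ord], limitation_states)
  if (is.unsorted(ranks))
    warning("limitation labels are not monotone along increasing Ci")
  pts
}

#' Fraction of (photo)respiratory CO2 refixed
#'
#' Resistance-partition model of refixation. CO2 released by mitochondria at
#' cytosolic partial pressure `x_py` either escapes through the cell wall +
#' plasma membrane and stomata (flux proportional to
#' `x_py/(r_wp + r_sc)`) or diffuses into the chloroplast and is carboxylated
#' (flux proportional to `x_py/(r_ch + k_inv)`). The refixed fraction is the
#' carboxylation flux over the total, so `x_py` cancels:
#'
#' `P_r = (1 + (r_ch + k_inv)/(r_wp + r_sc))^-1`
#'
#' This is the "1 minus escape fraction" definition; it increases with the
#' outward resistances and decreases with the chloroplast-side ones.
#'
#' @param r_wp cell wall + plasma membrane resistance (m2 s Pa umol-1).
#' @param r_sc stomatal resistance to CO2 (m2 s Pa umol-1).
#' @param r_ch chloroplast resistance (m2 s Pa umol-1).
#' @param k_inv carboxylation resistance `Cc/Vc` (m2 s Pa umol-1).
#' @return Refixed fraction in `[0, 1]`. Vectorized over all arguments.
#' @export
#' @examples
#' refix_fraction(r_wp = 2, r_sc = 1, r_ch = 0.5, k_inv = 0.5)  # 0.75
refix_fraction <- function(r_wp, r_sc, r_ch, k_inv) {
  n <- max(length(r_wp), length(r_sc), length(r_ch), length(k_inv))
  r_wp <- rep_len(r_wp, n); r_sc <- rep_len(r_sc, n)
  r_ch <- rep_len(r_ch, n); k_inv <- rep_len(k_inv, n)
  if (any(r_wp < 0 | r_sc < 0 | r_ch < 0 | k_inv < 0))
    stop("resistances must be non-negative")
  out_r <- r_wp + r_sc   # escape pathway
  in_r <- r_ch + k_inv   # refixation pathway
  if (any(out_r == 0 & in_r == 0))
    stop("both pathway resistances are zero: refixed fraction undefined")
  ifelse(out_r == 0, 0, ifelse(in_r == 0, 1, 1 / (1 + in_r / out_r)))
}

#' Carboxylation resistance k^-1
#'
#' The resistance contributed by the carboxylation reaction itself, defined
#' as the chloroplast CO2 partial pressure over the gross carboxylation rate,
#' `k_inv = (Cc - 0) / Vc`.
#'
#' @param Cc chloroplast CO2 partial pressure (Pa).
#' @param Vc gross carboxylation rate (umol m-2 s-1), must be positive.
#' @return k^-1 in m2 s Pa umol-1.
#' @export
carboxylation_resistance <- function(Cc, Vc) {
  if (any(Vc <= 0)) stop("Vc must be positive (non-assimilating state)")
  Cc / Vc
}

#' Convert mesophyll resistance between molar and pressure-based units
#'
#' Diffusion inside the leaf is driven by the gradient in partial pressure, so
#' resistances are reported in m2 s Pa umol-1. The conversion from molar
#' units is `r[Pa units] = P * 1e-6 * r[molar units]` with `P` the
#' atmospheric pressure in Pa.
#'
#' @param rm_molar resistance in m2 s mol-1.
#' @param P atmospheric pressure (Pa).
#' @return Resistance in m2 s Pa umol-1.
#' @export
#' @examples
#' rm_pressure_from_molar(2.5, 101325)  # 0.2533125
rm_pressure_from_molar <- function(rm_molar, P) {
  stopifnot(all(P > 0))
  P * 1e-6 * rm_molar
}

#' @rdname rm_pressure_from_molar
#' @param rm_pressure resistance in m2 s Pa umol-1.
#' @export
rm_molar_from_pressure <- function(rm_pressure, P) {
  stopifnot(all(P > 0))
  rm_pressure / (P * 1e-6)
}

#' Partition mesophyll resistance into wall and chloroplast components
#'
#' The refixation model needs the split of `rm` into a cell-wall-plus-plasma-
#' membrane component (outward pathway) and a chloroplast component (inward
#' pathway). How the split should be made is not observable from gas exchange
#' alone, so it is an explicit, reported knob: `r_wp = phi_wall * rm`,
#' `r_ch = (1 - phi_wall) * rm`.
#'
#' @param rm mesophyll resistance (m2 s Pa umol-1), non-negative.
#' @param phi_wall fraction of `rm` assigned to the wall + membrane, in
#'   `[0, 1]`. Default 0.5 (even split).
#' @return A list with components `r_wp` and `r_ch`; their sum is exactly
#'   `rm`.
#' @export
partition_rm <- function(rm, phi_wall = 0.5) {
  stopifnot(all(rm >= 0))
  if (any(phi_wall < 0 | phi_wall > 1))
    stop("phi_wall must lie in [0, 1]")
  list(r_wp = phi_wall * rm, r_ch = (1 - phi_wall) * rm)
}

#' Stomatal resistance to CO2 in pressure units
#'
#' Converts measured stomatal conductance to water vapour into a stomatal
#' resistance to CO2: the CO2 conductance is `gsw / 1.6` (binary diffusivity
#' ratio of water vapour to CO2 in air), its reciprocal is the molar
#' resistance, and the molar resistance is converted to pressure units with
#' the same factor used for `rm`.
#'
#' @param gsw stomatal conductance to water vapour (mol m-2 s-1), positive.
#' @param P atmospheric pressure (Pa).
#' @return Stomatal resistance to CO2 in m2 s Pa umol-1.
#' @export
#' @examples
#' stomatal_resistance(1.6, 101325)  # 0.101325
stomatal_resistance <- function(gsw, P) {
  if (any(gsw <= 0)) stop("gsw must be positive")
  rm_pressure_from_molar(1 / (gsw / 1.6), P)
}

#' Convert a CO2 mole fraction to a partial pressure
#'
#' Single conversion point for p.p.m. to Pa: `ppm * 1e-6 * P`, using the
#' record's own atmospheric pressure.
#'
#' @param ppm CO2 mole fraction in p.p.m.
#' @param P atmospheric pressure (Pa).
#' @return Partial pressure in Pa.
#' @export
ppm_to_pa <- function(ppm, P) ppm * 1e-6 * P
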