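# Independent oracles used across tests. These deliberately avoid the code
# paths they check.

# Bisection solve of A = p*(Cc - G*)/(Cc + q) - Rd with Cc = Ci - rm*A,
# bracketing A in (-Rd, p). Independent of the quadratic-root implementation.
bisect_net_a <- function(Ci, p, q, rd, rm, gamma_star, tol = 1e-12) {
  h <- function(a) {
    cc <- Ci - rm * a
    p * (cc - gamma_star) / (cc + q) - rd - a
  }
  lo <- -rd - p
  # keep the bracket on the physical branch: Cc > 0 throughout
  hi <- if (rm > 0) min(p, (Ci / rm) * (1 - 1e-12)) else p
  if (h(lo) < 0 || h(hi) > 0) return(NA_real_)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (h(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

bisect_oracle <- function(Ci, params, limitation) {
  kin <- params$kinetics
  if (limitation == "rubisco") {
    p <- params$Vcmax
    q <- kin$Kc * (1 + kin$O / kin$Ko)
  } else {
    p <- params$Jmax / 4
    q <- 2 * kin$gamma_star
  }
  bisect_net_a(Ci, p, q, params$Rd, params$rm, kin$gamma_star)
}

# Explicit two-flux balance with an arbitrary mitochondrial partial pressure:
# escape and refixation fluxes computed separately, then the ratio.
flux_balance_refix <- function(r_wp, r_sc, r_ch, k_inv, x_py = 1) {
  escape <- x_py / (r_wp + r_sc)
  refix <- x_py / (r_ch + k_inv)
  refix / (refix + escape)
}

# Closed-form least squares via the normal equations.
normal_equations <- function(X, y) solve(t(X) %*% X, t(X) %*% y)

# Forward-model curve for a parameter set on the standard measured sequence,
# as a noise-free aci_curve (goes through the exported generator).
profile_params <- function(i, profiles = species_profiles()) {
  fvcb_params(profiles$Vcmax_mean[i], profiles$Jmax_mean[i],
              profiles$TPU_mean[i], profiles$Rd_mean[i], profiles$rm_mean[i])
}

noise_free_curve <- function(i, profiles = species_profiles()) {
  simulate_curve(profile_params(i, profiles), study_design(noise_sd = 0),
                 profiles$gsw_mean[i], paste0("nf", i), profiles$species[i])
}

rel_err <- function(fit_params, true_params,
                    fields = c("Vcmax", "Jmax", "TPU", "Rd", "rm")) {
  vapply(fields, function(nm)
    abs(fit_params[[nm]] - true_params[[nm]]) / abs(true_params[[nm]]),
    numeric(1))
}
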