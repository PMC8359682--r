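#' Default species trait profiles
#'
#' Generative per-species distributions (mean, sd) for the biochemical
#' parameters, stomatal conductance at the 400-p.p.m. operating point, and
#' leaf structural traits. Means are calibrated so that the emergent
#' refixed percentage per species, pushed through the full simulate -> fit ->
#' refix pipeline, approximates the magnitudes reported for these species
#' (evergreen climax species highest, deciduous broadleaves lowest); they are
#' calibration targets for pipeline testing, not ground-truth claims about
#' the species.
#'
#' @return A data.frame with one row per species: identifiers plus
#'   `<trait>_mean` and `<trait>_sd` columns for Vcmax, Jmax, TPU, Rd, rm,
#'   gsw, LMA, water content, cell-wall thickness (Tcw, um) and intercellular
#'   airspace fraction (Fias, %).
#' @export
species_profiles <- function() {
  sp <- study_species()
  prof <- data.frame(
    sp,
    Vcmax_mean = c(60, 65, 55, 50, 45, 40),
    Jmax_mean  = c(96, 104, 88, 80, 72, 64),
    TPU_mean   = c(6.9, 7.4, 6.3, 5.7, 4.6, 4.1),
    Rd_mean    = c(1.0, 1.1, 1.0, 0.9, 0.9, 0.8),
    rm_mean    = c(1.00, 0.55, 1.00, 0.85, 2.60, 2.80),
    gsw_mean   = c(0.193, 0.266, 0.172, 0.161, 0.067, 0.047),
    LMA_mean   = c(60, 75, 90, 150, 180, 140),
    wc_mean    = c(60, 55, 55, 50, 48, 52),
    Tcw_mean   = c(0.20, 0.22, 0.39, 0.90, 1.20, 0.80),
    Fias_mean  = c(38.2, 28.8, 35.5, 15.8, 21.7, 39.7),
    stringsAsFactors = FALSE)
  prof$Vcmax_sd <- 0.15 * prof$Vcmax_mean
  prof$Jmax_sd  <- 0.15 * prof$Jmax_mean
  prof$TPU_sd   <- 0.15 * prof$TPU_mean
  prof$Rd_sd    <- 0.20 * prof$Rd_mean
  prof$rm_sd    <- 0.25 * prof$rm_mean
  prof$gsw_sd   <- 0.20 * prof$gsw_mean
  prof$LMA_sd   <- 0.10 * prof$LMA_mean
  prof$wc_sd    <- 3.0
  prof$Tcw_sd   <- c(0.009, 0.02, 0.08, 0.08, 0.08, 0.08)
  prof$Fias_sd  <- c(9.7, 6.9, 6.0, 5.5, 5.1, 6.4)
  prof
}

# Multiplicative season effects on profile means. Photosynthetic capacity and
# LMA are lowest early in the season, water content highest early, stomatal
# conductance lowest (stomatal resistance highest) late; mesophyll resistance
# is held season-constant, matching the absence of a season signal on rm.
season_multipliers <- function() {
  data.frame(
    season = season_levels,
    photo = c(0.85, 1.00, 1.00),   # Vcmax, Jmax, TPU, Rd
    gsw   = c(1.10, 1.00, 0.75),
    LMA   = c(0.85, 1.00, 1.05),
    wc    = c(1.10, 1.00, 0.95),
    stringsAsFactors = FALSE)
}

#' Study design for the synthetic gas-exchange campaign
#'
#' Defaults reproduce the measurement protocol: the 10-step reference-CO2
#' sequence (400 appears twice), irradiance 1000 umol quanta m-2 s-1, block
#' temperature 25 C, relative humidity 50%, three seasons, and 9 replicate
#' branches per species x season (the protocol used 8-10), for
#' 6 x 3 x 9 = 162 curves, close to the 156 of the original campaign.
#'
#' @param replicates replicate branches per species x season cell.
#' @param co2_sequence reference CO2 steps (p.p.m.) in acquisition order.
#' @param Q irradiance (umol quanta m-2 s-1).
#' @param P atmospheric pressure (Pa).
#' @param Tleaf leaf temperature (C).
#' @param rh relative humidity (%).
#' @param noise_sd Gaussian measurement noise on net assimilation
#'   (umol m-2 s-1); 0.2 is a typical infrared gas-analyser repeatability.
#' @param rm_trait_correlation pairwise correlation between rm, LMA and
#'   cell-wall thickness in the generative draws.
#' @param seasons season subset to simulate.
#' @param species species subset (default all six study species).
#' @return A list of class `study_design`.
#' @export
study_design <- function(replicates = 9,
                         co2_sequence = c(400, 300, 200, 100, 50, 400, 600,
                                          800, 1000, 1200),
                         Q = 1000, P = 101325, Tleaf = 25, rh = 50,
                         noise_sd = 0.2, rm_trait_correlation = 0.5,
                         seasons = season_levels,
                         species = study_species()$species) {
  stopifnot(replicates >= 0, all(co2_sequence > 0), P > 0, noise_sd >= 0,
            rm_trait_correlation >= 0, rm_trait_correlation < 1)
  structure(list(replicates = replicates, co2_sequence = co2_sequence,
                 Q = Q, P = P, Tleaf = Tleaf, rh = rh, noise_sd = noise_sd,
                 rm_trait_correlation = rm_trait_correlation,
                 seasons = seasons, species = species),
            class = "study_design")
}

# Truncated-normal draw (truncation at zero) by rejection; exact mean when
# sd = 0. Means sit several sd above zero so rejection is essentially never
# triggered and the stated correlations are preserved.
rtruncnorm0 <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Draw one sample's parameters and traits from a species profile
#'
#' Biochemical capacities (Vcmax, Jmax, TPU) are truncated-normal draws
#' around the season-adjusted profile means that co-scale through a shared
#' photosynthetic-capacity factor (correlation 0.8), keeping the Jmax:Vcmax
#' and TPU:Jmax ratios near their conserved field values so that all three
#' limitation states stay expressed on the measured CO2 grid. rm, LMA and
#' cell-wall thickness share a latent leaf-construction factor with loading
#' `sqrt(rho)` each, giving pairwise correlation `rho` (default 0.5): leaves
#' built with high mesophyll resistance also tend to be heavy and
#' thick-walled, which is the structure the downstream regressions are
#' designed to detect.
#'
#' @param profile one row of [species_profiles()].
#' @param season one of `"early"`, `"mid"`, `"late"`.
#' @param rho pairwise correlation between rm, LMA and Tcw.
#' @param kinetics a [kinetic_constants()] object.
#' @return A list with `params` ([fvcb_params()]), `gsw`, and a `traits`
#'   list (LMA, water content, Tcw, Fias). Uses the current RNG stream.
#' @export
draw_parameters <- function(profile, season, rho = 0.5,
                            kinetics = kinetic_constants()) {
  m <- season_multipliers()
  m <- m[m$season == season, ]
  draw <- function(nm, mult = 1)
    rtruncnorm0(1, profile[[paste0(nm, "_mean")]] * mult,
                profile[[paste0(nm, "_sd")]])
  # co-scaling capacities: shared factor, loading 0.8
  zc <- stats::rnorm(1)
  cap_z <- 0.8 * zc + 0.6 * stats::rnorm(3)
  cap_draw <- function(nm, z1, mult) {
    mu <- profile[[paste0(nm, "_mean")]] * mult
    sd <- profile[[paste0(nm, "_sd")]]
    x <- mu + sd * z1
    while (x <= 0) x <- mu + sd * stats::rnorm(1)
    x
  }
  vcmax <- cap_draw("Vcmax", cap_z[1], m$photo)
  jmax <- cap_draw("Jmax", cap_z[2], m$photo)
  tpu <- cap_draw("TPU", cap_z[3], m$photo)
  rd <- draw("Rd", m$photo)
  gsw <- draw("gsw", m$gsw)
  # correlated construction block: z = lam*f + sqrt(1-lam^2)*e
  lam <- sqrt(rho)
  f <- stats::rnorm(1)
  z <- lam * f + sqrt(1 - lam^2) * stats::rnorm(3)
  corr_draw <- function(nm, z1, mult = 1) {
    mu <- profile[[paste0(nm, "_mean")]] * mult
    sd <- profile[[paste0(nm, "_sd")]]
    x <- mu + sd * z1
    while (x <= 0) x <- mu + sd * stats::rnorm(1)
    x
  }
  rm_v <- corr_draw("rm", z[1])
  lma <- corr_draw("LMA", z[2], m$LMA)
  tcw <- corr_draw("Tcw", z[3])
  wc <- min(95, corr_draw("wc", stats::rnorm(1), m$wc))
  fias <- corr_draw("Fias", stats::rnorm(1))
  list(params = fvcb_params(vcmax, jmax, tpu, rd, rm_v, kinetics),
       gsw = gsw,
       traits = list(LMA = lma, water_content = wc, Tcw = tcw, Fias = fias))
}

# Net assimilation at a given ambient CO2, solving the stomatal supply /
# biochemical demand balance Ci = Ca - A/gsc (ppm, mole-fraction units) with
# A = min-state model rate at Ci converted to Pa.
solve_supply_demand <- function(ca_ppm, params, gsc, P) {
  model_a <- function(a) {
    ci_ppm <- ca_ppm - a / gsc
    if (ci_ppm <= 0) return(NA_real_)
    cand <- vapply(limitation_states, function(s)
      state_net_a(ppm_to_pa(ci_ppm, P), params, s), numeric(1))
    cc <- ppm_to_pa(ci_ppm, P) - params$rm * cand
    cand[is.na(cand) | (!is.na(cc) & cc <= 0)] <- Inf
    if (all(!is.finite(cand))) return(NA_real_)
    min(cand)
  }
  lo <- -params$Rd - 1
  hi <- min(3 * params$TPU - params$Rd, 0.999 * ca_ppm * gsc)
  if (hi <= lo) hi <- lo + 0.1
  g <- function(a) model_a(a) - a
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-10)
  a <- root$root
  list(A = a, Ci_ppm = ca_ppm - a / gsc)
}

#' Simulate one A/Ci curve under the measurement protocol
#'
#' For each reference-CO2 step the operating point is found by balancing
#' stomatal supply against biochemical demand (`Ci = Ca - A/gsc`, gsc held
#' constant across steps: no stomatal kinetics), and Gaussian measurement
#' noise is added to the recorded net assimilation. The noiseless `Ci` is
#' recorded, emulating an analyser whose dominant error is on the flux.
#'
#' @param params an [fvcb_params()] object (the sample's true parameters).
#' @param design a [study_design()] object.
#' @param gsw stomatal conductance to water (mol m-2 s-1).
#' @param sample_id,species,season,leaf_area_cm2 sample metadata.
#' @return An [aci_curve()] object. Uses the current RNG stream for noise.
#' @export
simulate_curve <- function(params, design, gsw, sample_id = "S1",
                           species = "Betula pendula", season = "mid",
                           leaf_area_cm2 = NA_real_) {
  gsc <- gsw / 1.6
  ops <- lapply(design$co2_sequence, function(ca)
    solve_supply_demand(ca, params, gsc, design$P))
  a_true <- vapply(ops, `[[`, numeric(1), "A")
  ci <- vapply(ops, `[[`, numeric(1), "Ci_ppm")
  noise <- if (design$noise_sd > 0)
    stats::rnorm(length(a_true), 0, design$noise_sd) else 0
  rec <- data.frame(
    co2_ref_ppm = design$co2_sequence,
    A_umol_m2_s = a_true + noise,
    Ci_ppm = ci,
    gsw_mol_m2_s = gsw,
    Tleaf_C = design$Tleaf,
    Q_umol_m2_s = design$Q,
    P_Pa = design$P,
    rh_pct = design$rh)
  aci_curve(sample_id, species, season, rec, leaf_area_cm2)
}

#' Simulate the full study
#'
#' Generates the complete campaign: for every species x season x replicate, a
#' parameter draw, a simulated A/Ci curve, a trait record (fresh/dry mass and
#' leaf area consistent with the drawn LMA and water content; cell-wall
#' thickness and airspace fraction on the subsampling schedule of the
#' protocol: Fias on three replicates per cell, Tcw on two replicates per
#' species in early and mid season only), and a ground-truth row including
#' the true refixed percentage at the 400-p.p.m. operating point.
#'
#' Randomness is controlled by a single master seed with documented stream
#' splitting: each sample uses its own substream seeded by
#' `(seed * 1009 + 7919 * index) mod (2^31 - 1)`, so outputs are identical
#' regardless of evaluation order.
#'
#' @param design a [study_design()] object.
#' @param profiles a data.frame like [species_profiles()].
#' @param seed master seed (integer).
#' @param kinetics a [kinetic_constants()] object.
#' @param phi_wall wall fraction used for the true refixed percentage.
#' @return A list of class `synthetic_study` with `curves` (list of
#'   [aci_curve()]), `gas_exchange` (flat canonical data.frame), `traits`,
#'   `truth`, and `manifest`.
#' @export
simulate_study <- function(design = study_design(),
                           profiles = species_profiles(), seed = 1,
                           kinetics = kinetic_constants(), phi_wall = 0.5) {
  grid <- expand.grid(rep = seq_len(design$replicates),
                      season = design$seasons, species = design$species,
                      stringsAsFactors = FALSE)
  curves <- vector("list", nrow(grid))
  traits <- vector("list", nrow(grid))
  truth <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    prof <- profiles[profiles$species == g$species, ]
    set.seed((seed * 1009 + 7919 * i) %% (2^31 - 1))
    dr <- draw_parameters(prof, g$season, design$rm_trait_correlation,
                          kinetics)
    sid <- sprintf("%s_%s_r%02d", gsub("[^A-Za-z]", "", g$species),
                   g$season, g$rep)
    area <- if (prof$functional_type == "deciduous-broadleaf") 2.27
      else rtruncnorm0(1, 4, 0.5)
    curves[[i]] <- simulate_curve(dr$params, design, dr$gsw, sid,
                                  g$species, g$season, area)
    dry <- dr$traits$LMA * area * 1e-4
    fresh <- dry / (1 - dr$traits$water_content / 100)
    traits[[i]] <- data.frame(
      sample_id = sid, species = g$species, season = g$season,
      functional_type = prof$functional_type, succession = prof$succession,
      leaf_area_cm2 = area, fresh_mass_g = fresh, dry_mass_g = dry,
      Tcw_um = if (g$rep <= 2 && g$season != "late") dr$traits$Tcw
        else NA_real_,
      Fias_pct = if (g$rep <= 3) dr$traits$Fias else NA_real_,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      sample_id = sid, species = g$species, season = g$season,
      Vcmax = dr$params$Vcmax, Jmax = dr$params$Jmax, TPU = dr$params$TPU,
      Rd = dr$params$Rd, rm = dr$params$rm, gsw = dr$gsw,
      LMA = dr$traits$LMA, water_content = dr$traits$water_content,
      Tcw = dr$traits$Tcw, Fias = dr$traits$Fias,
      Pr_true = true_refix(dr$params, dr$gsw, design, phi_wall),
      stringsAsFactors = FALSE)
  }
  manifest <- list(seed = seed, n_curves = length(curves),
                   replicates = design$replicates,
                   species = design$species, seasons = design$seasons,
                   co2_sequence = design$co2_sequence,
                   noise_sd = design$noise_sd, phi_wall = phi_wall,
                   profile_hash = profile_hash(profiles))
  structure(list(curves = curves,
                 gas_exchange = curves_to_df(curves),
                 traits = do.call(rbind, traits),
                 truth = do.call(rbind, truth),
                 manifest = manifest),
            class = "synthetic_study")
}

# True refixed percentage implied by a parameter draw at the 400-ppm
# operating point (same chain the fitter applies to estimates).
true_refix <- function(params, gsw, design, phi_wall = 0.5) {
  op <- solve_supply_demand(400, params, gsw / 1.6, design$P)
  pt <- model_curve(ppm_to_pa(op$Ci_ppm, design$P), params)[[1L]]
  if (!isTRUE(pt$vc_defined)) return(NA_real_)
  part <- partition_rm(params$rm, phi_wall)
  rs <- stomatal_resistance(gsw, design$P)
  100 * refix_fraction(part$r_wp, rs, part$r_ch,
                       carboxylation_resistance(pt$Cc, pt$Vc))
}

# Stable content hash of the profile table (text digest, no external deps).
profile_hash <- function(profiles) {
  txt <- paste(utils::capture.output(utils::write.csv(profiles, stdout())),
               collapse = "\n")
  sum(utf8ToInt(txt) * (seq_len(nchar(txt)) %% 97 + 1)) %% 1e9
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("Synthetic study: %d curves (%d species x %d seasons), seed %s\n",
              length(x$curves), length(unique(x$truth$species)),
              length(unique(x$truth$season)), x$manifest$seed))
  invisible(x)
}
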