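#' Fitting control settings
#'
#' @param min_rubisco minimum number of lowest-Ci points assigned to the
#'   Rubisco-limited state (day respiration and Vcmax both need low-Ci
#'   leverage). Default 2.
#' @param phi_wall fraction of `rm` assigned to the wall + membrane pathway
#'   when computing the refixed fraction; see [partition_rm()].
#' @param tol_admiss tolerance (umol m-2 s-1) used when checking that each
#'   point's assigned state is the minimum of the three candidate rates.
#' @param lower,upper named bounds for `c(Vcmax, Jmax, TPU, Rd, rm)`.
#' @param eval_max maximum objective evaluations per segmentation.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(min_rubisco = 2, phi_wall = 0.5, tol_admiss = 1e-6,
                        lower = c(Vcmax = 1, Jmax = 2, TPU = 0.1,
                                  Rd = 0.01, rm = 0),
                        upper = c(Vcmax = 500, Jmax = 1000, TPU = 200,
                                  Rd = 20, rm = 10),
                        eval_max = 400) {
  stopifnot(min_rubisco >= 1, all(lower < upper))
  structure(list(min_rubisco = min_rubisco, phi_wall = phi_wall,
                 tol_admiss = tol_admiss, lower = lower, upper = upper,
                 eval_max = eval_max),
            class = "fit_control")
}

#' Enumerate contiguous limitation-state segmentations
#'
#' Over `n` points sorted by increasing Ci, a segmentation is an ordered pair
#' of boundaries `(b1, b2)` with `min_rubisco <= b1 <= b2 <= n`: the first
#' `b1` points are Rubisco-limited, points `b1+1 .. b2` are RuBP-limited, and
#' points `b2+1 .. n` are TPU-limited. Empty RuBP or TPU segments are
#' allowed.
#'
#' @param n number of points.
#' @param min_rubisco minimum size of the Rubisco segment.
#' @return A list of segmentations; each element has `b1`, `b2`, and a
#'   character vector `labels` of length `n`.
#' @export
enumerate_segmentations <- function(n, min_rubisco = 2) {
  stopifnot(min_rubisco >= 1)
  if (n < min_rubisco) stop("need at least min_rubisco points")
  segs <- list()
  for (b1 in min_rubisco:n) {
    for (b2 in b1:n) {
      labels <- rep("rubisco", n)
      if (b2 > b1) labels[(b1 + 1):b2] <- "rubp"
      if (b2 < n) labels[(b2 + 1):n] <- "tpu"
      segs[[length(segs) + 1L]] <- list(b1 = b1, b2 = b2, labels = labels)
    }
  }
  segs
}

# Predicted net A per point given labels; vectorized by state. Returns NA for
# infeasible points (no positive-Cc root).
predict_labeled <- function(ci, labels, params) {
  a <- numeric(length(ci))
  for (s in limitation_states) {
    idx <- labels == s
    if (any(idx)) a[idx] <- state_net_a(ci[idx], params, s)
  }
  cc <- ci - params$rm * a
  a[!is.na(cc) & cc <= 0] <- NA_real_
  a
}

params_from_theta <- function(theta, kinetics) {
  fvcb_params(theta[["Vcmax"]], theta[["Jmax"]], theta[["TPU"]],
              theta[["Rd"]], theta[["rm"]], kinetics)
}

#' Heuristic starting values from a raw curve
#'
#' Deterministic initialization: `Rd` from the (negated) intercept of a line
#' through the two lowest-Ci points, `Vcmax` from a zero-`rm` one-point
#' inversion of the Rubisco-limited form at low Ci, `Jmax` from the high-Ci
#' plateau, `TPU = (plateau + Rd)/3`, and `rm = 0.05` m2 s Pa umol-1. Values
#' are clamped to the fitting bounds; degenerate curves fall back to fixed
#' defaults.
#'
#' @param curve an [aci_curve()] object.
#' @param control a [fit_control()] object.
#' @param kinetics a [kinetic_constants()] object.
#' @return An [fvcb_params()] object.
#' @export
initial_params <- function(curve, control = fit_control(),
                           kinetics = kinetic_constants()) {
  rec <- curve$records
  ci <- ppm_to_pa(rec$Ci_ppm, rec$P_Pa)
  ord <- order(ci)
  ci <- ci[ord]; a <- rec$A_umol_m2_s[ord]
  n <- length(ci)
  defaults <- c(Vcmax = 50, Jmax = 100, TPU = 10, Rd = 1, rm = 0.05)
  clamp <- function(x, nm) min(max(x, control$lower[[nm]]), control$upper[[nm]])
  if (n < 3 || diff(range(a)) < 1e-9) {
    th <- defaults
  } else {
    slope <- (a[2] - a[1]) / (ci[2] - ci[1])
    intercept <- a[1] - slope * ci[1]
    rd <- if (is.finite(intercept) && -intercept > 0.01) -intercept else 1
    km <- effective_km(kinetics)
    i_low <- min(3L, n)
    vcmax <- (a[i_low] + rd) * (ci[i_low] + km) /
      max(ci[i_low] - kinetics$gamma_star, 0.5)
    plateau <- max(a)
    ci_hi <- ci[n]
    jmax <- 4 * (plateau + rd) * (ci_hi + 2 * kinetics$gamma_star) /
      max(ci_hi - kinetics$gamma_star, 0.5)
    tpu <- (plateau + rd) / 3
    th <- c(Vcmax = vcmax, Jmax = jmax, TPU = tpu, Rd = rd, rm = 0.05)
    th[!is.finite(th)] <- defaults[!is.finite(th)]
  }
  th <- vapply(names(th), function(nm) clamp(th[[nm]], nm), numeric(1))
  params_from_theta(th, kinetics)
}

#' Least-squares fit under a fixed limitation-state segmentation
#'
#' Minimizes the sum of squared deviations between observed and modelled net
#' assimilation, each point evaluated under its assigned state, with bounded
#' optimization over `(Vcmax, Jmax, TPU, Rd, rm)`. A parameter whose state
#' has no assigned points is unidentifiable and is frozen at its upper bound
#' (`Jmax`, `TPU`) rather than left to wander. The result records whether the
#' assigned states are self-consistent: `admissible` is true iff at every
#' point the assigned state attains the minimum of the three candidate rates
#' within `tol_admiss`.
#'
#' @param curve an [aci_curve()] object (records need not be pre-sorted).
#' @param seg one element of [enumerate_segmentations()] for the Ci-sorted
#'   points.
#' @param init an [fvcb_params()] starting point.
#' @param control a [fit_control()] object.
#' @return A list with `params`, `labels` (in the curve's storage order),
#'   `sse`, `admissible`, `converged`, `n_iter`, `frozen` (names of frozen
#'   parameters).
#' @export
fit_segmentation <- function(curve, seg, init, control = fit_control()) {
  rec <- curve$records
  ci_all <- ppm_to_pa(rec$Ci_ppm, rec$P_Pa)
  ord <- order(ci_all)
  ci <- ci_all[ord]
  aobs <- rec$A_umol_m2_s[ord]
  labels <- seg$labels
  stopifnot(length(labels) == length(ci))
  kin <- init$kinetics

  theta0 <- c(Vcmax = init$Vcmax, Jmax = init$Jmax, TPU = init$TPU,
              Rd = init$Rd, rm = init$rm)
  frozen <- character(0)
  if (!any(labels == "rubp")) frozen <- c(frozen, "Jmax")
  if (!any(labels == "tpu")) frozen <- c(frozen, "TPU")
  theta0[frozen] <- control$upper[frozen]
  active <- setdiff(names(theta0), frozen)

  # Tight inner loop: compiled SSE kernel (the R forward model in fvcb.R
  # remains the reference path, used for admissibility and all reporting).
  km <- effective_km(kin)
  gs <- kin$gamma_star
  state_code <- match(labels, limitation_states) - 1L
  active_idx <- match(active, names(theta0))
  th_work <- theta0
  objective <- function(x) {
    if (anyNA(x)) return(1e10)
    th_work[active_idx] <- x
    .fvcb_sse_kernel(th_work, ci, aobs, state_code, km, gs)
  }

  run_from <- function(start) {
    tryCatch(
      # optimizer warning chatter (NA/NaN probes near the feasibility
      # boundary) is expected; convergence is checked via the return flag
      suppressWarnings(stats::nlminb(start, objective,
                    lower = control$lower[active],
                    upper = control$upper[active],
                    control = list(eval.max = control$eval_max,
                                   iter.max = control$eval_max))),
      error = function(e) NULL)
  }
  start <- pmin(pmax(theta0[active], control$lower[active]),
                control$upper[active])
  opt <- run_from(start)
  # Deterministic multi-start: fixed jitter multipliers, no RNG.
  if (is.null(opt) || opt$convergence != 0 || opt$objective >= 1e8) {
    for (f in c(0.5, 2, 1.25)) {
      alt <- run_from(pmin(pmax(start * f, control$lower[active]),
                           control$upper[active]))
      if (!is.null(alt) && (is.null(opt) || alt$objective < opt$objective))
        opt <- alt
      if (!is.null(opt) && opt$convergence == 0 && opt$objective < 1e8) break
    }
  }
  if (is.null(opt)) {
    return(list(params = init, labels = labels[order(ord)], sse = Inf,
                admissible = FALSE, converged = FALSE, n_iter = 0L,
                frozen = frozen, b1 = seg$b1, b2 = seg$b2))
  }

  th <- theta0
  th[active] <- opt$par
  params <- params_from_theta(th, kin)
  sse <- objective(opt$par)

  # Admissibility: assigned state must attain the per-point minimum rate.
  cand <- vapply(limitation_states, function(s) {
    a <- state_net_a(ci, params, s)
    cc <- ci - params$rm * a
    a[!is.na(cc) & cc <= 0] <- NA_real_
    ifelse(is.na(a), Inf, a)
  }, numeric(length(ci)))
  assigned <- cand[cbind(seq_along(ci), match(labels, limitation_states))]
  amin <- apply(cand, 1L, min)
  tol <- control$tol_admiss * pmax(1, abs(amin))
  admissible <- all(is.finite(assigned)) && all(assigned <= amin + tol)

  labels_storage <- character(length(labels))
  labels_storage[ord] <- labels
  list(params = params, labels = labels_storage, sse = sse,
       admissible = admissible, converged = opt$convergence == 0,
       n_iter = as.integer(opt$iterations), frozen = frozen,
       b1 = seg$b1, b2 = seg$b2)
}

#' Fit the biochemical model to one A/Ci curve
#'
#' Runs [fit_segmentation()] over every contiguous segmentation of the
#' Ci-sorted points and selects the minimum-SSE admissible fit (ties broken
#' by fewer active states, then by smaller Rubisco segment boundary). If no
#' admissible fit exists the minimum-SSE fit is returned flagged
#' `admissible = FALSE`. The selected fit is then decorated with the derived
#' quantities: `Amax` (modelled net A at the highest measured Ci), `rs`
#' (stomatal resistance at the first 400-p.p.m. record), `k_inv`
#' (carboxylation resistance at that record's operating point) and `Pr` (the
#' refixed percentage from the resistance chain).
#'
#' @param curve an [aci_curve()] object.
#' @param control a [fit_control()] object.
#' @param kinetics a [kinetic_constants()] object.
#' @return An object of class `fit_result`.
#' @export
fit_aci <- function(curve, control = fit_control(),
                    kinetics = kinetic_constants()) {
  rec <- curve$records
  if (nrow(rec) < 6)
    stop("curve has fewer than 6 records; cannot identify 5 parameters")
  init <- initial_params(curve, control, kinetics)
  outliers <- flag_outliers(curve)
  if (any(outliers))
    warning(sum(outliers), " record(s) far from the running median in ",
            curve$sample_id, " (flagged, not dropped)")
  segs <- enumerate_segmentations(nrow(rec), control$min_rubisco)
  fits <- lapply(segs, function(s) fit_segmentation(curve, s, init, control))
  conv <- vapply(fits, `[[`, logical(1), "converged")
  if (!any(conv))
    stop("no segmentation converged for sample ", curve$sample_id)

  sse <- vapply(fits, `[[`, numeric(1), "sse")
  adm <- vapply(fits, `[[`, logical(1), "admissible")
  nstates <- vapply(fits, function(f)
    length(unique(f$labels)), numeric(1))
  b1 <- vapply(fits, `[[`, numeric(1), "b1")
  pool <- if (any(adm & conv)) which(adm & conv) else which(conv)
  best <- pool[order(sse[pool], nstates[pool], b1[pool])][1L]
  fit <- fits[[best]]

  res <- fit_derivatives(curve, fit, control)
  structure(c(fit, res,
              list(sample_id = curve$sample_id, species = curve$species,
                   season = curve$season,
                   functional_type = curve$functional_type,
                   succession = curve$succession, init = init,
                   outlier_flags = outliers,
                   all_sse = sse, all_admissible = adm)),
            class = "fit_result")
}

# QC screen: records whose A sits more than 5 residual-sd from a running
# median (window 3, along Ci) are flagged for inspection, never dropped.
flag_outliers <- function(curve, k = 5) {
  rec <- curve$records
  ci <- ppm_to_pa(rec$Ci_ppm, rec$P_Pa)
  ord <- order(ci)
  a <- rec$A_umol_m2_s[ord]
  med <- stats::runmed(a, 3)
  resid <- a - med
  # robust hybrid scale: MAD collapses on monotone stretches (running-median
  # residuals are exactly zero there) and sd is inflated by the outlier
  # itself; the floor is a multiple of typical analyser repeatability
  s <- max(stats::mad(resid), stats::sd(resid) / 3, 0.2)
  flags <- abs(resid) > k * s
  out <- logical(length(a))
  out[ord] <- flags
  out
}

# Derived quantities for a fitted curve: Amax at the top Ci, rs and the full
# refixation chain at the first 400-p.p.m. record (the acclimated operating
# point of the measurement protocol).
fit_derivatives <- function(curve, fit, control) {
  rec <- curve$records
  params <- fit$params
  ci_all <- ppm_to_pa(rec$Ci_ppm, rec$P_Pa)
  top <- which.max(ci_all)
  amax <- min(vapply(limitation_states, function(s) {
    p <- net_assimilation(ci_all[top], params, s)
    if (p$feasible) p$A else Inf
  }, numeric(1)))

  i400 <- which(rec$co2_ref_ppm == 400)[1L]
  rs <- NA_real_; pr <- NA_real_; k_inv <- NA_real_
  if (!is.na(i400) && is.finite(rec$gsw_mol_m2_s[i400]) &&
      rec$gsw_mol_m2_s[i400] > 0) {
    P <- rec$P_Pa[i400]
    rs <- stomatal_resistance(rec$gsw_mol_m2_s[i400], P)
    op <- model_curve(ci_all[i400], params)[[1L]]
    if (isTRUE(op$vc_defined) && op$Vc > 0) {
      k_inv <- carboxylation_resistance(op$Cc, op$Vc)
      part <- partition_rm(params$rm, control$phi_wall)
      pr <- 100 * refix_fraction(part$r_wp, rs, part$r_ch, k_inv)
    }
  }
  list(Amax = amax, rs = rs, k_inv = k_inv, Pr = pr,
       phi_wall = control$phi_wall)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("A/Ci fit for %s (%s, %s season)\n", x$sample_id, x$species,
              x$season))
  print(x$params)
  cat(sprintf("  SSE %.4g | admissible %s | converged %s\n", x$sse,
              x$admissible, x$converged))
  cat(sprintf("  Amax %.2f | rs %.4f | k_inv %.4f | Pr %.1f%%\n",
              x$Amax, x$rs, x$k_inv, x$Pr))
  invisible(x)
}

#' Fit every curve of a study and assemble the per-sample fit table
#'
#' @param curves a list of [aci_curve()] objects.
#' @param control a [fit_control()] object.
#' @param kinetics a [kinetic_constants()] object.
#' @param quiet suppress per-curve progress messages.
#' @return A data.frame with one row per curve: identifiers, the five fitted
#'   parameters, `rs`, `k_inv`, `Amax`, `Pr`, `sse`, `admissible`,
#'   `converged`. Curves for which no segmentation converges are reported as
#'   a row of NAs with `converged = FALSE`.
#' @export
fit_study <- function(curves, control = fit_control(),
                      kinetics = kinetic_constants(), quiet = TRUE) {
  rows <- lapply(curves, function(cv) {
    f <- tryCatch(fit_aci(cv, control, kinetics), error = function(e) NULL)
    if (!quiet) message("fit ", cv$sample_id, ": ",
                        if (is.null(f)) "FAILED" else sprintf("sse %.3g", f$sse))
    if (is.null(f)) {
      return(data.frame(sample_id = cv$sample_id, species = cv$species,
                        season = cv$season,
                        functional_type = cv$functional_type,
                        succession = cv$succession,
                        Vcmax = NA_real_, Jmax = NA_real_, TPU = NA_real_,
                        Rd = NA_real_, rm = NA_real_, rs = NA_real_,
                        k_inv = NA_real_, Amax = NA_real_, Pr = NA_real_,
                        sse = NA_real_, admissible = FALSE, converged = FALSE,
                        stringsAsFactors = FALSE))
    }
    data.frame(sample_id = f$sample_id, species = f$species,
               season = f$season, functional_type = f$functional_type,
               succession = f$succession,
               Vcmax = f$params$Vcmax, Jmax = f$params$Jmax,
               TPU = f$params$TPU, Rd = f$params$Rd, rm = f$params$rm,
               rs = f$rs, k_inv = f$k_inv, Amax = f$Amax, Pr = f$Pr,
               sse = f$sse, admissible = f$admissible, converged = f$converged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Recompute the refixed percentage from a fit table
#'
#' The fit table carries everything the resistance chain needs (`rm`, `rs`,
#' `k_inv`), so `Pr` can be recomputed for any wall/chloroplast split without
#' refitting.
#'
#' @param fit_table data.frame from [fit_study()].
#' @param phi_wall fraction of `rm` assigned to the wall + membrane pathway.
#' @return The table with its `Pr` and `phi_wall` columns replaced.
#' @export
refix_table <- function(fit_table, phi_wall = 0.5) {
  ok <- is.finite(fit_table$rm) & is.finite(fit_table$rs) &
    is.finite(fit_table$k_inv)
  pr <- rep(NA_real_, nrow(fit_table))
  if (any(ok)) {
    part <- partition_rm(fit_table$rm[ok], phi_wall)
    pr[ok] <- 100 * refix_fraction(part$r_wp, fit_table$rs[ok],
                                   part$r_ch, fit_table$k_inv[ok])
  }
  fit_table$Pr <- pr
  fit_table$phi_wall <- phi_wall
  fit_table
}
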