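test_that("zero mesophyll resistance reduces to the explicit closed forms", {
  kin <- kinetic_constants()
  p <- fvcb_params(60, 120, 7, 1, rm = 0)
  km <- kin$Kc * (1 + kin$O / kin$Ko)
  for (ci in c(5, 15, 30, 80)) {
    expect_equal(net_assimilation(ci, p, "rubisco")$A,
                 60 * (ci - kin$gamma_star) / (ci + km) - 1,
                 tolerance = 1e-12)
    expect_equal(net_assimilation(ci, p, "rubp")$A,
                 120 * (ci - kin$gamma_star) / (4 * ci + 8 * kin$gamma_star) - 1,
                 tolerance = 1e-12)
  }
})

test_that("A equals -Rd exactly at the compensation point Cc = gamma_star", {
  kin <- kinetic_constants()
  for (rm in c(0, 0.02, 0.1)) {
    p <- fvcb_params(60, 120, 7, 1, rm = rm)
    ci <- kin$gamma_star - rm * p$Rd  # chosen so Cc = gamma_star at A = -Rd
    op <- net_assimilation(ci, p, "rubisco")
    expect_equal(op$A, -p$Rd, tolerance = 1e-10)
    expect_equal(op$Cc, kin$gamma_star, tolerance = 1e-10)
  }
})

test_that("quadratic-root solution matches the bisection oracle", {
  p <- fvcb_params(60, 120, 7, 1, rm = 0.05)
  a_bis <- bisect_oracle(30, p, "rubisco")
  expect_equal(net_assimilation(30, p, "rubisco")$A, a_bis, tolerance = 1e-8)

  set.seed(11)
  for (i in 1:200) {
    vcmax <- runif(1, 20, 120)
    pars <- fvcb_params(vcmax, runif(1, 1.4, 1.9) * vcmax, runif(1, 4, 12),
                        runif(1, 0.3, 2.5), runif(1, 0, 2))
    ci <- runif(1, 5, 120)
    lim <- sample(c("rubisco", "rubp"), 1)
    op <- net_assimilation(ci, pars, lim)
    if (!op$feasible) next
    expect_equal(op$A, bisect_oracle(ci, pars, lim), tolerance = 1e-8)
    # operating-point invariant: Cc consistent with the solved A
    expect_equal(op$Cc, ci - pars$rm * op$A, tolerance = 1e-10)
  }
})

test_that("model_curve selects the per-point argmin state and is monotone", {
  p <- fvcb_params(60, 96, 6.9, 1, rm = 0.5)
  des <- study_design()
  ci <- sort(ppm_to_pa(des$co2_sequence, des$P))
  pts <- model_curve(ci, p)
  expect_length(pts, 10L)
  labs <- vapply(pts, `[[`, character(1), "limitation")
  for (k in seq_along(ci)) {
    cand <- vapply(c("rubisco", "rubp", "tpu"), function(s) {
      op <- net_assimilation(ci[k], p, s)
      if (op$feasible) op$A else Inf
    }, numeric(1))
    expect_identical(labs[k], names(cand)[which.min(cand)])
  }
  ranks <- match(labs, c("rubisco", "rubp", "tpu"))
  expect_false(is.unsorted(ranks))
  # A non-decreasing within rubisco/rubp segments
  a <- vapply(pts, `[[`, numeric(1), "A")
  sub <- labs != "tpu"
  expect_true(all(diff(a[sub]) > -1e-9))

  # an inactive TPU state never gets selected
  p2 <- fvcb_params(60, 96, TPU = 150, Rd = 1, rm = 0.1)
  lab1 <- model_curve(40, p2)[[1]]$limitation
  expect_true(lab1 %in% c("rubisco", "rubp"))
})

test_that("refix_fraction implements the two-flux balance", {
  expect_identical(refix_fraction(1, 1, 1, 1), 0.5)
  expect_equal(refix_fraction(1e9, 0, 1, 0), 1, tolerance = 1e-6)
  expect_equal(refix_fraction(2, 1, 0.5, 0.5), 0.75, tolerance = 1e-12)
  # x_py cancels in the flux balance
  for (x in c(0.1, 1, 37)) {
    expect_equal(refix_fraction(2, 1, 0.5, 0.5),
                 flux_balance_refix(2, 1, 0.5, 0.5, x), tolerance = 1e-14)
  }
  expect_error(refix_fraction(-1, 1, 1, 1), "non-negative")
  expect_error(refix_fraction(0, 0, 0, 0), "undefined")
  # degenerate single-open-pathway cases
  expect_identical(refix_fraction(0, 0, 1, 1), 0)
  expect_identical(refix_fraction(1, 1, 0, 0), 1)
})

test_that("refix_fraction is monotone in each resistance", {
  r <- c(0.5, 1, 2)
  base <- refix_fraction(r[1], r[2], r[3], 0.7)
  expect_gt(refix_fraction(r[1] + 0.1, r[2], r[3], 0.7), base)
  expect_gt(refix_fraction(r[1], r[2] + 0.1, r[3], 0.7), base)
  expect_lt(refix_fraction(r[1], r[2], r[3] + 0.1, 0.7), base)
  expect_lt(refix_fraction(r[1], r[2], r[3], 0.8), base)
})

test_that("carboxylation resistance is the direct pressure/rate ratio", {
  expect_identical(carboxylation_resistance(30, 20), 1.5)
  expect_identical(carboxylation_resistance(0, 20), 0)
  expect_identical(carboxylation_resistance(30, 20),
                   carboxylation_resistance(60, 40))
  expect_error(carboxylation_resistance(30, 0), "positive")
})

test_that("unit conversions apply the printed factor and round-trip", {
  expect_identical(rm_pressure_from_molar(0, 101325), 0)
  expect_equal(rm_pressure_from_molar(2.5, 101325), 0.2533125,
               tolerance = 1e-12)
  for (r in c(0.3, 2.5, 11)) {
    expect_equal(rm_molar_from_pressure(rm_pressure_from_molar(r, 98000),
                                        98000), r, tolerance = 1e-12)
  }
})

test_that("rm partition conserves the total and respects bounds", {
  expect_identical(partition_rm(1, 0.5), list(r_wp = 0.5, r_ch = 0.5))
  expect_identical(partition_rm(2.4, 1), list(r_wp = 2.4, r_ch = 0))
  set.seed(3)
  for (phi in runif(20)) {
    part <- partition_rm(1.7, phi)
    expect_equal(part$r_wp + part$r_ch, 1.7, tolerance = 1e-15)
  }
  expect_error(partition_rm(1, 1.2), "phi_wall")
})

test_that("stomatal resistance conversion chain", {
  expect_equal(stomatal_resistance(1.6, 101325), 0.101325, tolerance = 1e-12)
  expect_equal(stomatal_resistance(0.08, 101325),
               2 * stomatal_resistance(0.16, 101325), tolerance = 1e-12)
  expect_lt(stomatal_resistance(1e9, 101325), 1e-9)
  expect_error(stomatal_resistance(0, 101325), "positive")
})

test_that("compiled SSE kernel agrees with the R forward model", {
  kin <- kinetic_constants()
  km <- kin$Kc * (1 + kin$O / kin$Ko)
  set.seed(5)
  for (i in 1:50) {
    vcmax <- runif(1, 20, 120)
    pars <- fvcb_params(vcmax, 1.6 * vcmax, runif(1, 4, 12),
                        runif(1, 0.3, 2), runif(1, 0, 2))
    ci <- sort(runif(8, 5, 110))
    labels <- sort(sample(c("rubisco", "rubp", "tpu"), 8, replace = TRUE))
    a_ref <- vapply(seq_along(ci), function(k) {
      op <- net_assimilation(ci[k], pars, labels[k])
      if (op$feasible) op$A else NA_real_
    }, numeric(1))
    if (anyNA(a_ref)) next
    aobs <- a_ref + 0.3
    sse_ref <- sum((aobs - a_ref)^2)
    theta <- c(pars$Vcmax, pars$Jmax, pars$TPU, pars$Rd, pars$rm)
    sse_c <- refixr:::.fvcb_sse_kernel(theta, ci, aobs,
                                       match(labels, c("rubisco", "rubp",
                                                       "tpu")) - 1L,
                                       km, kin$gamma_star)
    expect_equal(sse_c, sse_ref, tolerance = 1e-10)
  }
})
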