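test_that("LMA and water content are direct, unit-checked arithmetic", {
  expect_equal(compute_lma(0.02, 2.27), 0.02 / 2.27e-4, tolerance = 1e-12)
  expect_equal(round(compute_lma(0.02, 2.27), 2), 88.11)
  expect_identical(compute_lma(0, 5), 0)
  expect_identical(compute_lma(0.02, 2.27), compute_lma(0.04, 4.54))
  expect_error(compute_lma(0.02, 0), "positive")

  expect_identical(compute_water_content(0.4, 0.4), 0)
  expect_identical(compute_water_content(0.4, 0), 100)
  expect_equal(compute_water_content(0.5, 0.2), 60, tolerance = 1e-12)
  expect_error(compute_water_content(0.3, 0.4), "between")
})

test_that("two-way ANOVA matches a hand-worked decomposition on balance", {
  # balanced 3 x 2 with 2 replicates per cell
  set.seed(21)
  d <- expand.grid(rep = 1:2, A = c("a1", "a2", "a3"), B = c("b1", "b2"))
  d$y <- rnorm(nrow(d), mean = c(10, 12, 15)[as.integer(factor(d$A))] +
                 c(0, 2)[as.integer(factor(d$B))])
  res <- two_way_anova(d, "y", c("A", "B"), transform = "none")

  # independent sequential decomposition (balanced: type I == type II)
  gm <- mean(d$y)
  ssa <- sum(tapply(d$y, d$A, function(v) length(v) * (mean(v) - gm)^2))
  ssb <- sum(tapply(d$y, d$B, function(v) length(v) * (mean(v) - gm)^2))
  cellfit <- ave(d$y, d$A) + ave(d$y, d$B) - gm
  rss <- sum((d$y - cellfit)^2)
  dfr <- nrow(d) - (3 - 1) - (2 - 1) - 1
  expect_equal(res$factors$A$F, (ssa / 2) / (rss / dfr), tolerance = 1e-10)
  expect_equal(res$factors$B$F, (ssb / 1) / (rss / dfr), tolerance = 1e-10)
  expect_equal(res$factors$A$p,
               pf((ssa / 2) / (rss / dfr), 2, dfr, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$df_residual, dfr)

  # type I equals type II under balance
  res1 <- two_way_anova(d, "y", c("A", "B"), ss = "I", transform = "none")
  expect_equal(res1$factors$A$F, res$factors$A$F, tolerance = 1e-10)
  expect_equal(res1$factors$B$F, res$factors$B$F, tolerance = 1e-10)
})

test_that("degenerate ANOVA inputs take the documented guards", {
  d <- expand.grid(rep = 1:3, A = c("a1", "a2"), B = c("b1", "b2"))
  d$y <- 7
  res <- two_way_anova(d, "y", c("A", "B"), transform = "none")
  expect_identical(res$factors$A$F, 0)
  expect_identical(res$factors$A$p, 1)

  # noise-free group effects: very large F, p -> 0
  d$y <- c(1, 5)[as.integer(factor(d$A))]
  res2 <- two_way_anova(d, "y", c("A", "B"), transform = "none")
  expect_identical(res2$factors$A$F, Inf)
  expect_identical(res2$factors$A$p, 0)
  expect_identical(res2$factors$B$F, 0)
})

test_that("normality screening triggers the documented transformation", {
  set.seed(8)
  d <- expand.grid(rep = 1:10, A = c("a1", "a2", "a3"), B = c("b1", "b2"))
  d$y <- exp(rnorm(nrow(d), 1 + (as.integer(factor(d$A)) - 1), 1))
  res <- two_way_anova(d, "y", c("A", "B"))
  expect_identical(res$transformation, "log")
  d$y <- d$y - 5  # not strictly positive -> rank fallback
  res2 <- two_way_anova(d, "y", c("A", "B"))
  expect_true(res2$transformation %in% c("rank", "none"))
})

test_that("Tukey HSD letters form a valid clique cover", {
  set.seed(31)
  d <- data.frame(g = rep(c("g1", "g2", "g3"), each = 10),
                  y = rnorm(30, rep(c(0, 0, 5), each = 10), 1))
  tk <- tukey_hsd(d, "y", "g")
  expect_identical(unname(tk$letters[c("g1", "g2")]), c("a", "a"))
  expect_identical(unname(tk$letters["g3"]), "b")

  # validity on random group structures: shared letter <=> p >= alpha
  for (seed in 1:5) {
    set.seed(seed)
    k <- sample(3:5, 1)
    d <- data.frame(g = rep(paste0("g", 1:k), each = 8),
                    y = rnorm(8 * k, rep(runif(k, 0, 4), each = 8)))
    tk <- tukey_hsd(d, "y", "g")
    for (r in seq_len(nrow(tk$pairs))) {
      gg <- strsplit(tk$pairs$pair[r], "-", fixed = TRUE)[[1]]
      shared <- length(intersect(strsplit(tk$letters[[gg[1]]], "")[[1]],
                                 strsplit(tk$letters[[gg[2]]], "")[[1]])) > 0
      expect_identical(shared, tk$pairs$p_adj[r] >= tk$alpha)
    }
  }
})

test_that("Tukey HSD edge cases", {
  set.seed(4)
  d <- data.frame(g = rep(c("x", "y"), each = 6), y = rnorm(12))
  tk <- tukey_hsd(d, "y", "g")
  expect_identical(unname(tk$letters), c("a", "a"))
  d$y <- d$y + c(0, 100)[as.integer(factor(d$g))]
  tk2 <- tukey_hsd(d, "y", "g")
  expect_identical(sort(unname(tk2$letters)), c("a", "b"))
  expect_error(tukey_hsd(data.frame(g = c("a", "a", "b"), y = 1:3), "y", "g"),
               "singleton")
})

test_that("nested OLS matches the normal-equations oracle", {
  # exact linear data: slope and intercept recovered, adj R2 = 1
  d <- data.frame(rm = seq(0.2, 3, length.out = 15))
  d$rs <- 0.5 + 0.1 * seq_len(15)
  d$LMA <- 50 + 5 * seq_len(15)
  d$Pr <- 2 + 3 * d$rm
  # exact fit: lm warns that the summary may be unreliable, which is the point
  res <- suppressWarnings(nested_ols(d))
  m1 <- res$models[[1]]
  expect_equal(m1$terms$estimate[m1$terms$term == "rm"], 3, tolerance = 1e-10)
  expect_equal(m1$terms$estimate[m1$terms$term == "(Intercept)"], 2,
               tolerance = 1e-10)
  expect_equal(m1$adj_r_squared, 1, tolerance = 1e-10)

  # orthogonal response
  d2 <- data.frame(rm = rep(c(-1, 1), 10), rs = 1, LMA = 1)
  d2$Pr <- rep(c(1, -1, -1, 1), 5)
  m <- suppressWarnings(nested_ols(d2))$models[[1]]
  expect_lt(abs(m$terms$estimate[m$terms$term == "rm"]), 1e-12)
  expect_lte(m$adj_r_squared, 0)

  # 20-point toy with noise: coefficients equal (X'X)^-1 X'y to 1e-10
  set.seed(12)
  d3 <- data.frame(rm = runif(20, 0, 3), rs = runif(20, 0, 2),
                   LMA = runif(20, 40, 180))
  d3$Pr <- 30 + 5 * d3$rm + 2 * d3$rs + 0.05 * d3$LMA + rnorm(20, 0, 2)
  m3 <- nested_ols(d3)$models[[3]]
  X <- cbind(1, d3$rm, d3$rs, d3$LMA)
  beta <- normal_equations(X, d3$Pr)
  expect_equal(m3$terms$estimate, as.numeric(beta), tolerance = 1e-10)
  expect_identical(m3$df_residual, 20L - 3L - 1L)

  # adjusted R2 non-decreasing across nested models on full-model data
  adj <- vapply(nested_ols(d3)$models, `[[`, numeric(1), "adj_r_squared")
  expect_true(all(diff(adj) > -0.05))
})

test_that("group summaries use the sample standard deviation", {
  d <- data.frame(g = c("a", "a", "a", "b"), y = c(1, 2, 3, 10))
  gs <- group_summary(d, "y", "g")
  expect_equal(gs$mean[gs$g == "a"], 2)
  expect_equal(gs$sd[gs$g == "a"], 1)
  expect_true(is.na(gs$sd[gs$g == "b"]))
  # two-pass oracle on a grouped synthetic table
  set.seed(9)
  d2 <- data.frame(g = sample(letters[1:4], 100, TRUE), y = rnorm(100))
  gs2 <- group_summary(d2, "y", "g")
  for (g in gs2$g) {
    v <- d2$y[d2$g == g]
    expect_equal(gs2$mean[gs2$g == g], sum(v) / length(v), tolerance = 1e-12)
    expect_equal(gs2$sd[gs2$g == g],
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)),
                 tolerance = 1e-12)
  }
})

test_that("study_table joins fits and traits through the trait formulas", {
  ft <- data.frame(sample_id = c("s1", "s2"), species = "Betula pendula",
                   season = "mid", Pr = c(40, 50), rm = c(1, 2),
                   rs = c(0.8, 1), stringsAsFactors = FALSE)
  tr <- data.frame(sample_id = c("s1", "s2"), leaf_area_cm2 = 2.27,
                   fresh_mass_g = c(0.05, 0.06), dry_mass_g = c(0.02, 0.03),
                   Tcw_um = c(0.2, NA), Fias_pct = c(38, 30))
  tab <- study_table(ft, tr)
  expect_equal(tab$LMA, compute_lma(tr$dry_mass_g, 2.27))
  expect_equal(tab$water_content,
               compute_water_content(tr$fresh_mass_g, tr$dry_mass_g))
  expect_true(is.na(tab$Tcw[2]))
})
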