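#' Leaf mass per area
#'
#' @param dry_mass_g leaf dry mass (g).
#' @param area_cm2 one-sided projected leaf area (cm2).
#' @return LMA in g m-2.
#' @export
#' @examples
#' compute_lma(0.02, 2.27)  # leaf-disc sample
compute_lma <- function(dry_mass_g, area_cm2) {
  if (any(area_cm2 <= 0)) stop("leaf area must be positive")
  if (any(dry_mass_g < 0)) stop("dry mass must be non-negative")
  dry_mass_g / (area_cm2 * 1e-4)
}

#' Leaf water content
#'
#' @param fresh_g fresh mass (g), positive.
#' @param dry_g dry mass (g), `0 <= dry <= fresh`.
#' @return Water content in percent of fresh mass.
#' @export
compute_water_content <- function(fresh_g, dry_g) {
  if (any(fresh_g <= 0)) stop("fresh mass must be positive")
  if (any(dry_g < 0) || any(dry_g > fresh_g))
    stop("dry mass must lie between 0 and fresh mass")
  100 * (fresh_g - dry_g) / fresh_g
}

# Residual sum of squares of a main-effects linear model.
rss_of <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  sum(stats::residuals(fit)^2)
}

#' Two-factor analysis of variance with main effects only
#'
#' Main-effects F and p for both factors, no interaction term. Sums of
#' squares are Type II by default (each factor adjusted for the other), which
#' coincides with the sequential decomposition when the design is balanced;
#' Type I (sequential, in the order given) is available. Residual normality
#' is screened with a Shapiro-Wilk test; on rejection at 0.05 the response is
#' log-transformed if strictly positive, otherwise rank-transformed, and the
#' model refit (`transform = "none"` disables this).
#'
#' @param table data.frame with the response and factor columns.
#' @param response name of the numeric response column.
#' @param factors character vector of two factor column names.
#' @param ss `"II"` (default) or `"I"`.
#' @param transform `"auto"` (default) or `"none"`.
#' @param alpha normality-screen level.
#' @return An object of class `anova_result`: per-factor `F`, `p`, `df`,
#'   residual df, the transformation applied, and the Shapiro-Wilk p-value
#'   on the final residuals.
#' @export
two_way_anova <- function(table, response, factors, ss = c("II", "I"),
                          transform = c("auto", "none"), alpha = 0.05) {
  ss <- match.arg(ss)
  transform <- match.arg(transform)
  stopifnot(length(factors) == 2, all(factors %in% names(table)),
            response %in% names(table))
  d <- table[stats::complete.cases(table[, c(response, factors)]),
             c(response, factors)]
  names(d) <- c("y", "A", "B")
  d$A <- factor(d$A); d$B <- factor(d$B)
  if (nlevels(d$A) < 2 || nlevels(d$B) < 2)
    stop("each factor needs at least 2 observed levels")

  applied <- "none"
  shapiro_p <- NA_real_
  fit_all <- function(dd) {
    full <- stats::lm(y ~ A + B, data = dd)
    res <- stats::residuals(full)
    sw <- if (stats::sd(res) > 0 && length(res) >= 3)
      stats::shapiro.test(res)$p.value else NA_real_
    list(full = full, shapiro = sw)
  }
  f0 <- fit_all(d)
  shapiro_p <- f0$shapiro
  if (transform == "auto" && !is.na(shapiro_p) && shapiro_p < alpha) {
    if (all(d$y > 0)) {
      d$y <- log(d$y); applied <- "log"
    } else {
      d$y <- rank(d$y); applied <- "rank"
    }
    f0 <- fit_all(d)
    shapiro_p <- f0$shapiro
  }
  full <- f0$full
  rss_full <- sum(stats::residuals(full)^2)
  df_res <- full$df.residual
  if (df_res <= 0) stop("zero residual degrees of freedom")
  mse <- rss_full / df_res

  ss_for <- function(factor_idx) {
    if (ss == "II") {
      reduced <- if (factor_idx == 1) y ~ B else y ~ A
      rss_of(reduced, d) - rss_full
    } else {
      if (factor_idx == 1) {
        rss_of(y ~ 1, d) - rss_of(y ~ A, d)
      } else {
        rss_of(y ~ A, d) - rss_full
      }
    }
  }
  out <- lapply(1:2, function(i) {
    df_i <- nlevels(d[[c("A", "B")[i]]]) - 1L
    ss_i <- max(ss_for(i), 0)
    if (mse <= .Machine$double.eps * max(1, abs(mean(d$y)))) {
      # degenerate: zero residual variance
      if (ss_i <= 1e-12) list(F = 0, p = 1, df = df_i, ss = 0)
      else list(F = Inf, p = 0, df = df_i, ss = ss_i)
    } else {
      f <- (ss_i / df_i) / mse
      list(F = f, p = stats::pf(f, df_i, df_res, lower.tail = FALSE),
           df = df_i, ss = ss_i)
    }
  })
  names(out) <- factors
  structure(list(factors = out, df_residual = df_res, ss_type = ss,
                 transformation = applied, shapiro_p = shapiro_p,
                 response = response),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("Two-way ANOVA (%s, type %s SS, transform: %s)\n",
              x$response, x$ss_type, x$transformation))
  for (nm in names(x$factors)) {
    f <- x$factors[[nm]]
    cat(sprintf("  %-14s F(%d, %d) = %.3g, p = %.3g\n", nm, f$df,
                x$df_residual, f$F, f$p))
  }
  invisible(x)
}

# Maximal cliques of an undirected graph over 1..n given a logical adjacency
# matrix (Bron-Kerbosch without pivoting; group counts here are tiny).
maximal_cliques <- function(adj) {
  n <- nrow(adj)
  cliques <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      cliques[[length(cliques) + 1L]] <<- sort(R)
      return(invisible())
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  cliques
}

#' Tukey honest significant difference test with compact letter display
#'
#' All-pairs comparisons via the studentized range (on a one-way layout),
#' with letters assigned so that two groups share a letter if and only if
#' their pairwise difference is not significant at `alpha`. Letters are the
#' maximal cliques of the non-significance graph, with "a" given to the
#' lowest-mean clique, so the display is deterministic and independent of
#' input order.
#'
#' @param table data.frame.
#' @param response numeric response column name.
#' @param grouping grouping factor column name.
#' @param alpha significance level (default 0.05).
#' @return An object of class `tukey_result` with `pairs` (data.frame of
#'   pairwise differences and adjusted p) and `letters` (named character
#'   vector, one entry per group).
#' @export
tukey_hsd <- function(table, response, grouping, alpha = 0.05) {
  d <- table[stats::complete.cases(table[, c(response, grouping)]),
             c(response, grouping)]
  names(d) <- c("y", "g")
  d$g <- factor(d$g)
  cnt <- table(d$g)
  if (nlevels(d$g) < 2) stop("need at least 2 groups")
  if (any(cnt < 2)) stop("singleton group(s): ",
                         paste(names(cnt)[cnt < 2], collapse = ", "))
  fit <- stats::aov(y ~ g, data = d)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pairs <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)

  groups <- levels(d$g)
  k <- length(groups)
  adj <- matrix(TRUE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(pairs))) {
    gg <- strsplit(pairs$pair[i], "-", fixed = TRUE)[[1]]
    sig <- pairs$p_adj[i] < alpha
    adj[gg[1], gg[2]] <- adj[gg[2], gg[1]] <- !sig
  }
  diag(adj) <- FALSE
  cliques <- maximal_cliques(adj)
  means <- tapply(d$y, d$g, mean)
  cliques <- cliques[order(vapply(cliques, function(cl) min(means[cl]),
                                  numeric(1)),
                           vapply(cliques, min, numeric(1)))]
  lett <- vapply(groups, function(g) "", character(1))
  for (j in seq_along(cliques))
    for (g in groups[cliques[[j]]])
      lett[g] <- paste0(lett[g], letters[j])
  structure(list(pairs = pairs, letters = lett, means = means,
                 alpha = alpha), class = "tukey_result")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat(sprintf("Tukey HSD (alpha = %.2f)\n", x$alpha))
  for (g in names(x$letters))
    cat(sprintf("  %-24s mean %8.3f  %s\n", g, x$means[[g]], x$letters[[g]]))
  invisible(x)
}

ols_one <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  sm <- summary(fit)
  co <- stats::coef(sm)
  fstat <- sm$fstatistic
  list(terms = data.frame(term = rownames(co), estimate = co[, 1],
                          t = co[, 3], p = co[, 4], row.names = NULL,
                          stringsAsFactors = FALSE),
       df_residual = fit$df.residual,
       adj_r_squared = sm$adj.r.squared,
       F = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
       p = if (is.null(fstat)) NA_real_ else
         stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
       n = length(stats::residuals(fit)),
       formula = deparse(formula))
}

#' Nested ordinary least squares models for the refixed percentage
#'
#' Fits the three nested models relating the refixed percentage to the
#' diffusional and structural traits --- `Pr ~ rm`, `Pr ~ rm + rs`,
#' `Pr ~ rm + rs + LMA` --- reporting per-term estimate, t and p, the
#' intercept, residual df, adjusted R-squared and the model F test.
#' Rank-deficient predictors are dropped with a warning.
#'
#' @param table data.frame containing `Pr`, `rm`, `rs`, `LMA` (rows with
#'   missing values in a model's variables are dropped per model).
#' @param response response column name (default `"Pr"`).
#' @return A list of class `nested_ols` with one `ols` element per model.
#' @export
nested_ols <- function(table, response = "Pr") {
  specs <- list(c("rm"), c("rm", "rs"), c("rm", "rs", "LMA"))
  models <- lapply(specs, function(vars) {
    keep <- intersect(vars, names(table))
    if (length(keep) < length(vars))
      warning("missing predictor(s) dropped: ",
              paste(setdiff(vars, keep), collapse = ", "))
    d <- table[stats::complete.cases(table[, c(response, keep)]),
               c(response, keep)]
    fm <- stats::as.formula(paste(response, "~",
                                  paste(keep, collapse = " + ")))
    fit <- stats::lm(fm, data = d)
    if (any(is.na(stats::coef(fit)))) {
      bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      warning("rank-deficient model; dropping term(s): ",
              paste(bad, collapse = ", "))
      keep <- setdiff(keep, bad)
      fm <- stats::as.formula(paste(response, "~",
                                    paste(keep, collapse = " + ")))
    }
    ols_one(fm, d)
  })
  structure(list(models = models, response = response), class = "nested_ols")
}

#' @export
print.nested_ols <- function(x, ...) {
  cat("Nested OLS models for", x$response, "\n")
  for (i in seq_along(x$models)) {
    m <- x$models[[i]]
    cat(sprintf("  [%d] %s  (n = %d, df = %d, adj R2 = %.3f, F = %.2f, p = %.3g)\n",
                i, m$formula, m$n, m$df_residual, m$adj_r_squared, m$F, m$p))
    for (j in seq_len(nrow(m$terms)))
      cat(sprintf("      %-12s %8.3f (t = %.2f, p = %.3g)\n",
                  m$terms$term[j], m$terms$estimate[j], m$terms$t[j],
                  m$terms$p[j]))
  }
  invisible(x)
}

#' Simple per-species and pooled trait regressions
#'
#' For each predictor, regresses the response on it across all samples and
#' within each species (the per-panel regression lines of the trait
#' scatterplots).
#'
#' @param table data.frame with `species`, the response and predictors.
#' @param response response column name.
#' @param predictors predictor column names.
#' @return A data.frame with one row per (scope, predictor): slope,
#'   intercept, p, adjusted R-squared, n.
#' @export
trait_regressions <- function(table, response = "Pr",
                              predictors = c("rm", "rs", "LMA")) {
  scopes <- c("all", unique(table$species))
  rows <- list()
  for (sc in scopes) {
    d0 <- if (sc == "all") table else table[table$species == sc, ]
    for (pv in predictors) {
      d <- d0[stats::complete.cases(d0[, c(response, pv)]), ]
      if (nrow(d) < 3) next
      m <- ols_one(stats::as.formula(paste(response, "~", pv)), d)
      rows[[length(rows) + 1L]] <- data.frame(
        scope = sc, predictor = pv,
        slope = m$terms$estimate[m$terms$term == pv],
        intercept = m$terms$estimate[m$terms$term == "(Intercept)"],
        p = m$terms$p[m$terms$term == pv],
        adj_r_squared = m$adj_r_squared, n = m$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Group means and standard deviations
#'
#' @param table data.frame.
#' @param response numeric response column name.
#' @param grouping grouping column name.
#' @return A data.frame with per-group `n`, `mean`, `sd` (sample sd, n - 1
#'   denominator; `NA` for singleton groups).
#' @export
group_summary <- function(table, response, grouping) {
  d <- table[stats::complete.cases(table[, c(response, grouping)]), ]
  g <- factor(d[[grouping]])
  out <- data.frame(
    group = levels(g),
    n = as.integer(table(g)),
    mean = as.numeric(tapply(d[[response]], g, mean)),
    sd = as.numeric(tapply(d[[response]], g, stats::sd)),
    stringsAsFactors = FALSE)
  names(out)[1] <- grouping
  out
}

#' Study-wide ANOVA summary table
#'
#' Runs [two_way_anova()] for each listed variable against species and
#' season, assembling the per-variable F and p columns of the study's summary
#' layout.
#'
#' @param table long-format study table (one row per sample).
#' @param variables numeric columns to test.
#' @param ... passed to [two_way_anova()].
#' @return A data.frame: variable, species F/p, season F/p, transformation.
#' @export
anova_table <- function(table,
                        variables = c("Pr", "rm", "rs", "Amax", "Vcmax",
                                      "Jmax", "TPU", "Rd", "water_content",
                                      "LMA", "Tcw", "Fias"),
                        ...) {
  rows <- lapply(intersect(variables, names(table)), function(v) {
    a <- tryCatch(two_way_anova(table, v, c("species", "season"), ...),
                  error = function(e) NULL)
    if (is.null(a)) return(NULL)
    data.frame(variable = v,
               F_species = a$factors$species$F, p_species = a$factors$species$p,
               F_season = a$factors$season$F, p_season = a$factors$season$p,
               transformation = a$transformation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Assemble the long-format study table
#'
#' Joins the per-sample fit table with the trait table, computing LMA and
#' water content from the recorded masses and leaf area.
#'
#' @param fit_table data.frame from [fit_study()].
#' @param traits trait data.frame with `sample_id`, `leaf_area_cm2`,
#'   `fresh_mass_g`, `dry_mass_g` and optionally `Tcw_um`, `Fias_pct`.
#' @return The merged study table with `LMA`, `water_content`, `Tcw`, `Fias`
#'   columns added.
#' @export
study_table <- function(fit_table, traits) {
  tr <- traits
  tr$LMA <- compute_lma(tr$dry_mass_g, tr$leaf_area_cm2)
  tr$water_content <- compute_water_content(tr$fresh_mass_g, tr$dry_mass_g)
  tr$Tcw <- if ("Tcw_um" %in% names(tr)) tr$Tcw_um else NA_real_
  tr$Fias <- if ("Fias_pct" %in% names(tr)) tr$Fias_pct else NA_real_
  merge(fit_table,
        tr[, c("sample_id", "LMA", "water_content", "Tcw", "Fias")],
        by = "sample_id", all.x = TRUE, sort = TRUE)
}
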