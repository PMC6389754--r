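#' Least-squares fit of a linear model
#'
#' Thin QR-based fitting substrate shared by the ANCOVA and permutation
#' machinery. Rank deficiency is an error that names the offending columns.
#'
#' @param y Response vector.
#' @param X Design matrix (full column rank), rows matching `y`.
#' @return List with `coefficients`, `fitted`, `residuals`, `df_residual`
#'   and `rss`.
#' @export
fit_linear_model <- function(y, X) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    bad <- colnames(X)[qd$pivot[(qd$rank + 1L):ncol(X)]] %||%
      qd$pivot[(qd$rank + 1L):ncol(X)]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qd, y)
  fitted <- drop(X %*% beta)
  res <- y - fitted
  list(coefficients = beta, fitted = fitted, residuals = res,
       df_residual = length(y) - ncol(X), rss = sum(res^2))
}

# residual sum of squares of the least-squares fit of y on X
.rss <- function(y, X) {
  f <- stats::lm.fit(X, y)
  sum(f$residuals^2)
}

# Type III sums of squares with sum-to-zero factor coding: the SS of each
# term is the RSS increase from dropping that term's columns from the full
# model. `data` holds the variables referenced by `formula`.
.type3_table <- function(y, formula, data, effects) {
  mf <- stats::model.frame(formula, data)
  fac <- vapply(mf, is.factor, logical(1))
  contr <- stats::setNames(as.list(rep("contr.sum", sum(fac))),
                           names(mf)[fac])
  X <- stats::model.matrix(formula, mf, contrasts.arg = contr)
  assign <- attr(X, "assign")
  term_labels <- attr(stats::terms(formula, data = data), "term.labels")
  full <- fit_linear_model(y, X)
  ss_total <- sum((y - mean(y))^2)
  rows <- lapply(effects, function(eff) {
    ti <- match(eff, term_labels)
    cols <- which(assign == ti)
    ss <- .rss(y, X[, -cols, drop = FALSE]) - full$rss
    df1 <- length(cols)
    Fv <- (ss / df1) / (full$rss / full$df_residual)
    data.frame(effect = eff, F = Fv, df_num = df1,
               df_den = full$df_residual,
               p = stats::pf(Fv, df1, full$df_residual, lower.tail = FALSE),
               eta_squared = ss / ss_total, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fit") <- full
  class(out) <- c("alphashift_anova", "data.frame")
  out
}

#' @export
print.alphashift_anova <- function(x, digits = 3, ...) {
  cat("Type III ANCOVA (sum-to-zero factor coding)\n")
  df <- as.data.frame(x)
  df$F <- round(df$F, digits)
  df$p <- signif(df$p, digits)
  df$eta_squared <- round(df$eta_squared, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' One-way ANCOVA on the global alpha-power shift
#'
#' Between-subjects ANCOVA of the log2 alpha-power shift on a (typically
#' three-level) group factor with age and gender as covariates. Type III
#' sums of squares with sum-to-zero factor coding; classical eta-squared
#' (SS_effect / SS_total) is reported. With three groups and two covariates
#' on N subjects the error df is N - 5.
#'
#' @param shift Numeric vector of per-subject global log2 shifts.
#' @param group Factor (>= 2 subjects per level).
#' @param age Numeric covariate (years).
#' @param gender Factor or character covariate.
#' @return An `alphashift_anova` data frame (rows: group, age, gender) with
#'   the full-model fit attached as attribute `fit`.
#' @export
ancova_oneway <- function(shift, group, age, gender) {
  group <- droplevels(as.factor(group))
  gender <- droplevels(as.factor(gender))
  if (any(table(group) < 2)) stop("every group level needs >= 2 subjects")
  dat <- data.frame(shift = shift, group = group, age = age, gender = gender)
  .type3_table(shift, ~ group + age + gender, dat, c("group", "age", "gender"))
}

#' 2 x 2 factorial ANCOVA on the patient cohort
#'
#' Syndrome-by-seizure-control factorial ANCOVA of the log2 alpha-power
#' shift with age, gender and total AED load as covariates. Type III sums
#' of squares with sum-to-zero coding; one consistent error df (N - 7 for
#' the full model) is reported for both main effects and the interaction.
#'
#' @param shift Numeric vector of per-subject global log2 shifts.
#' @param syndrome Two-level factor (e.g. FE / IGE).
#' @param control Two-level factor (e.g. GSC / PSC).
#' @param age,gender,aed_load Covariates.
#' @return An `alphashift_anova` data frame (rows: syndrome, control,
#'   interaction, covariates).
#' @export
ancova_factorial <- function(shift, syndrome, control, age, gender, aed_load) {
  syndrome <- droplevels(as.factor(syndrome))
  control <- droplevels(as.factor(control))
  gender <- droplevels(as.factor(gender))
  if (nlevels(syndrome) != 2 || nlevels(control) != 2) {
    stop("syndrome and control must each have exactly 2 levels")
  }
  if (any(table(syndrome, control) == 0)) {
    stop("all four syndrome x control cells must be non-empty")
  }
  dat <- data.frame(shift = shift, syndrome = syndrome, control = control,
                    age = age, gender = gender, aed_load = aed_load)
  .type3_table(shift, ~ syndrome * control + age + gender + aed_load, dat,
               c("syndrome", "control", "syndrome:control",
                 "age", "gender", "aed_load"))
}

.as_summary <- function(x, name) {
  if (is.numeric(x)) {
    if (length(x) < 2) stop(sprintf("sample '%s' needs >= 2 observations", name))
    list(mean = mean(x), sd = stats::sd(x), n = length(x), raw = x)
  } else if (is.list(x) && all(c("mean", "sd", "n") %in% names(x))) {
    if (x$n < 2) stop(sprintf("summary '%s' needs n >= 2", name))
    if (x$sd < 0) stop(sprintf("summary '%s' has negative sd", name))
    c(x, list(raw = NULL))
  } else {
    stop(sprintf("'%s' must be a numeric sample or a list(mean, sd, n)", name))
  }
}

#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance t with df = n_a + n_b - 2, accepting either raw
#' samples or `list(mean, sd, n)` summary statistics (both routes give
#' identical results on the same data). When raw samples are supplied,
#' Hedges' g (with bootstrap CI if `n_boot > 0`) is attached.
#'
#' @param a,b Numeric samples or `list(mean=, sd=, n=)` summaries.
#' @param n_boot Bootstrap resamples for the g confidence interval (0 to
#'   skip the CI).
#' @param seed Seed for the bootstrap.
#' @return An object of class `alphashift_contrast`: list with `t`, `df`,
#'   `p` (two-sided), per-group summaries, and `g` / `g_ci` where available.
#' @export
pooled_t <- function(a, b, n_boot = 0, seed = 1) {
  sa <- .as_summary(a, "a"); sb <- .as_summary(b, "b")
  df <- sa$n + sb$n - 2
  sp2 <- ((sa$n - 1) * sa$sd^2 + (sb$n - 1) * sb$sd^2) / df
  if (sp2 <= 0) {
    if (sa$mean != sb$mean) {
      stop("zero pooled variance with unequal means: degenerate input")
    }
    tv <- 0
  } else {
    tv <- (sa$mean - sb$mean) / sqrt(sp2 * (1 / sa$n + 1 / sb$n))
  }
  out <- list(t = tv, df = df, p = 2 * stats::pt(-abs(tv), df),
              group_means = data.frame(
                mean = c(sa$mean, sb$mean), sd = c(sa$sd, sb$sd),
                n = c(sa$n, sb$n)))
  if (sp2 > 0) {
    J <- 1 - 3 / (4 * (sa$n + sb$n) - 9)
    out$g <- J * (sa$mean - sb$mean) / sqrt(sp2)
    if (!is.null(sa$raw) && !is.null(sb$raw) && n_boot > 0) {
      hg <- hedges_g(sa$raw, sb$raw, n_boot = n_boot, seed = seed)
      out$g <- hg$g
      out$g_ci <- hg$ci
    }
  }
  class(out) <- "alphashift_contrast"
  out
}

#' @export
print.alphashift_contrast <- function(x, ...) {
  cat(sprintf("t(%g) = %.3f, p = %.4g", x$df, x$t, x$p))
  if (!is.null(x$g)) cat(sprintf(", g = %.3f", x$g))
  if (!is.null(x$g_ci)) cat(sprintf(" [%.3f, %.3f]", x$g_ci[1], x$g_ci[2]))
  cat("\n")
  invisible(x)
}

#' Hedges' g with percentile-bootstrap confidence interval
#'
#' Small-sample-corrected standardized mean difference
#' `g = J * (mean_a - mean_b) / s_pooled`, `J = 1 - 3 / (4 (n_a + n_b) - 9)`.
#' The CI is a percentile bootstrap resampling subjects within each group.
#'
#' @param a,b Numeric samples (>= 2 each).
#' @param n_boot Number of bootstrap resamples (default 5000).
#' @param seed Bootstrap seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `g` and `ci` (length-2 vector).
#' @export
hedges_g <- function(a, b, n_boot = 5000, seed = 1, conf = 0.95) {
  if (length(a) < 2 || length(b) < 2) stop("both samples need >= 2 observations")
  g_of <- function(x, y) {
    na <- length(x); nb <- length(y)
    sp2 <- ((na - 1) * stats::var(x) + (nb - 1) * stats::var(y)) / (na + nb - 2)
    if (sp2 <= 0) return(NA_real_)
    (1 - 3 / (4 * (na + nb) - 9)) * (mean(x) - mean(y)) / sqrt(sp2)
  }
  g <- g_of(a, b)
  if (is.na(g)) stop("zero pooled standard deviation: g undefined")
  ci <- NULL
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      ia <- matrix(sample.int(length(a), length(a) * n_boot, replace = TRUE),
                   ncol = n_boot)
      ib <- matrix(sample.int(length(b), length(b) * n_boot, replace = TRUE),
                   ncol = n_boot)
      vapply(seq_len(n_boot),
             function(j) g_of(a[ia[, j]], b[ib[, j]]), numeric(1))
    })
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE))
  }
  list(g = g, ci = ci)
}

#' Levene's test for equality of variances
#'
#' One-way ANOVA F on the absolute deviations from the group means (the
#' mean-centered form).
#'
#' @param x Numeric vector.
#' @param group Factor with >= 2 observations per level.
#' @return List with `W` (the F statistic), `df1`, `df2`, `p`.
#' @export
levene_test <- function(x, group) {
  group <- droplevels(as.factor(group))
  if (any(table(group) < 2)) stop("every group needs >= 2 observations")
  z <- abs(x - stats::ave(x, group))
  if (stats::var(z) == 0) stop("degenerate (constant) absolute deviations")
  k <- nlevels(group); n <- length(z)
  zbar <- mean(z); zg <- tapply(z, group, mean); ng <- tabulate(group)
  ss_b <- sum(ng * (zg - zbar)^2)
  ss_w <- sum((z - stats::ave(z, group))^2)
  Fv <- (ss_b / (k - 1)) / (ss_w / (n - k))
  list(W = Fv, df1 = k - 1, df2 = n - k,
       p = stats::pf(Fv, k - 1, n - k, lower.tail = FALSE))
}

#' Homogeneity of regression slopes
#'
#' F-test of the group-by-covariate interaction block on top of the additive
#' group + covariate model.
#'
#' @param x Response vector.
#' @param group Factor.
#' @param covariate Numeric covariate.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
slope_homogeneity <- function(x, group, covariate) {
  group <- droplevels(as.factor(group))
  dat <- data.frame(x = x, group = group, covariate = covariate)
  contr <- list(group = "contr.sum")
  Xf <- stats::model.matrix(~ group * covariate, dat, contrasts.arg = contr)
  Xr <- stats::model.matrix(~ group + covariate, dat, contrasts.arg = contr)
  rss_f <- .rss(x, Xf); rss_r <- .rss(x, Xr)
  q <- ncol(Xf) - ncol(Xr)
  df2 <- length(x) - ncol(Xf)
  Fv <- ((rss_r - rss_f) / q) / (rss_f / df2)
  list(F = Fv, df1 = q, df2 = df2,
       p = stats::pf(Fv, q, df2, lower.tail = FALSE))
}

#' Shapiro-Wilk normality check of model residuals
#'
#' @param residuals Numeric vector (3 to 5000 values).
#' @return List with `W` and `p`.
#' @export
normality_check <- function(residuals) {
  sw <- stats::shapiro.test(residuals)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction; df = (r - 1)(c - 1).
#'
#' @param table r x c matrix of counts.
#' @return List with `chisq`, `df`, `p`, `n`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || sum(table) == 0) stop("counts must be >= 0 with a positive total")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin: chi-square undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, n = sum(table))
}

#' Fisher's exact test (2 x 2), Mann-Whitney U, Kruskal-Wallis
#'
#' Standard nonparametric comparisons used for the cohort summary table:
#' two-sided Fisher's exact p (sum of hypergeometric probabilities no larger
#' than the observed table's), the Mann-Whitney U statistic with tie-corrected
#' p, and the Kruskal-Wallis H with tie correction.
#'
#' @param table 2 x 2 count matrix (Fisher).
#' @param a,b Numeric samples (Mann-Whitney).
#' @param samples List of numeric samples (Kruskal-Wallis).
#' @return `fisher_exact`: p-value. `mann_whitney_u`: list(U, p).
#'   `kruskal_wallis`: list(H, df, p).
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("fisher_exact expects a 2 x 2 table")
  stats::fisher.test(table)$p.value
}

#' @rdname fisher_exact
#' @export
mann_whitney_u <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample")
  wt <- suppressWarnings(stats::wilcox.test(a, b))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' @rdname fisher_exact
#' @export
kruskal_wallis <- function(samples) {
  if (any(!vapply(samples, length, integer(1)))) stop("empty sample")
  kt <- stats::kruskal.test(samples)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Spearman correlation between alpha shift and seizure frequency
#'
#' Rank correlation with tie handling; the p-value comes from a seeded
#' permutation test (two-sided) rather than the asymptotic approximation,
#' which suits small cohorts with tied integer counts.
#'
#' @param shift Numeric vector of global log2 shifts.
#' @param seizure_count Non-negative counts, same length (>= 3).
#' @param n_perm Number of random permutations (default 10000).
#' @param seed Permutation seed.
#' @return List with `rho` and `p`.
#' @export
shift_seizure_correlation <- function(shift, seizure_count, n_perm = 10000,
                                      seed = 1) {
  n <- length(shift)
  if (n != length(seizure_count) || n < 3) {
    stop("shift and seizure_count must have equal length >= 3")
  }
  if (stats::sd(shift) == 0 || stats::sd(seizure_count) == 0) {
    stop("constant input vector: correlation undefined")
  }
  rx <- rank(shift); ry <- rank(seizure_count)
  rho <- stats::cor(rx, ry)
  cx <- rx - mean(rx); cy <- ry - mean(ry)
  denom <- sqrt(sum(cx^2) * sum(cy^2))
  exceed <- with_seed(seed, {
    perm_rho <- vapply(seq_len(n_perm), function(i) {
      sum(cx * cy[sample.int(n)]) / denom
    }, numeric(1))
    sum(abs(perm_rho) >= abs(rho) - 1e-12)
  })
  list(rho = rho, p = (1 + exceed) / (1 + n_perm))
}

#' Planned pairwise contrasts on the global alpha-power shift
#'
#' Post hoc pooled two-sample t-tests (df = n_a + n_b - 2) between group
#' levels with Hedges' g and bootstrap CIs; p-values are Bonferroni-adjusted
#' across the requested family.
#'
#' @param shift Numeric vector.
#' @param group Factor.
#' @param pairs List of 2-element character vectors of level names; default
#'   all pairs.
#' @param n_boot Bootstrap resamples for the g CIs.
#' @param seed Bootstrap seed.
#' @return Data frame with one row per contrast (t, df, p, p_bonferroni, g,
#'   g CI, group means).
#' @export
posthoc_contrasts <- function(shift, group, pairs = NULL, n_boot = 5000,
                              seed = 1) {
  group <- droplevels(as.factor(group))
  if (is.null(pairs)) {
    pairs <- utils::combn(levels(group), 2, simplify = FALSE)
  }
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    a <- shift[group == pr[1]]; b <- shift[group == pr[2]]
    ct <- pooled_t(a, b, n_boot = n_boot, seed = child_seed(seed, i))
    data.frame(contrast = paste(pr, collapse = " - "), t = ct$t, df = ct$df,
               p = ct$p, g = ct$g %||% NA_real_,
               g_lo = if (is.null(ct$g_ci)) NA_real_ else ct$g_ci[1],
               g_hi = if (is.null(ct$g_ci)) NA_real_ else ct$g_ci[2],
               mean_a = ct$group_means$mean[1], sd_a = ct$group_means$sd[1],
               mean_b = ct$group_means$mean[2], sd_b = ct$group_means$sd[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Cohort summary-table statistics
#'
#' Recomputes the demographic/clinical comparisons of a three-group cohort
#' table: sex proportions (chi-square across HS/GSC/PSC), age
#' (Kruskal-Wallis), focal-syndrome proportion and AED load between the two
#' patient groups, and the seizure-count contrast implied by the
#' dichotomization.
#'
#' @param table A `cohort_table` data frame.
#' @return Data frame with columns variable, statistic, value, df, p.
#' @export
cohort_table_stats <- function(table) {
  grp <- analysis_groups(table)
  lv <- levels(grp)
  sex <- table(table$gender, grp)
  cs <- chi_square_independence(sex)
  rows <- list(data.frame(variable = "female_sex", statistic = "chisq",
                          value = cs$chisq, df = cs$df, p = cs$p))
  kt <- kruskal_wallis(split(table$age, grp))
  rows <- c(rows, list(data.frame(variable = "age", statistic = "H",
                                  value = kt$H, df = kt$df, p = kt$p)))
  pat <- table[grp != "HS", , drop = FALSE]
  if (nrow(pat) && nlevels(droplevels(factor(pat$seizure_control))) == 2) {
    fe <- table(pat$syndrome == "FE", pat$seizure_control)
    if (all(dim(fe) == c(2, 2))) {
      cf <- chi_square_independence(fe)
      rows <- c(rows, list(data.frame(variable = "fe_syndrome",
                                      statistic = "chisq", value = cf$chisq,
                                      df = cf$df, p = cf$p)))
    }
    u <- mann_whitney_u(pat$aed_load[pat$seizure_control == "GSC"],
                        pat$aed_load[pat$seizure_control == "PSC"])
    rows <- c(rows, list(data.frame(variable = "aed_load", statistic = "U",
                                    value = u$U, df = NA, p = u$p)))
  }
  do.call(rbind, rows)
}

#' Three-level analysis grouping of a cohort table
#'
#' Healthy subjects keep the label `HS`; patients are split by their
#' seizure-control label.
#'
#' @param table A `cohort_table`.
#' @return Factor with levels HS, GSC, PSC (present levels only).
#' @export
analysis_groups <- function(table) {
  g <- ifelse(table$group == "HS", "HS", table$seizure_control)
  factor(g, levels = intersect(c("HS", "GSC", "PSC"), unique(g)))
}
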