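test_that("linear-model fitting matches the normal equations and reports collinearity", {
  set.seed(10)
  X <- cbind(intercept = 1, a = rnorm(40), b = rnorm(40))
  beta <- c(2, -1, 0.5)
  y <- drop(X %*% beta)
  fit <- fit_linear_model(y, X)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)

  y2 <- rnorm(40)
  fit2 <- fit_linear_model(y2, X)
  oracle <- solve(crossprod(X), crossprod(X, y2))
  expect_equal(unname(fit2$coefficients), unname(drop(oracle)),
               tolerance = 1e-8)
  expect_lt(max(abs(crossprod(X, fit2$residuals))), 1e-8)

  fit3 <- fit_linear_model(y2, X[, 1, drop = FALSE])
  expect_equal(unname(fit3$coefficients), mean(y2))

  Xbad <- cbind(X, dup = X[, "a"])
  expect_error(fit_linear_model(y2, Xbad), "dup")
})

test_that("one-way ANCOVA has the documented dfs and agrees with car's Type III", {
  set.seed(21)
  n <- c(39, 25, 38)
  grp <- factor(rep(c("HS", "GSC", "PSC"), n), c("HS", "GSC", "PSC"))
  age <- rnorm(102, 34, 11)
  gender <- factor(sample(c("F", "M"), 102, TRUE))
  y <- rnorm(102) + 0.5 * (grp == "PSC")
  res <- ancova_oneway(y, grp, age, gender)
  grow <- res[res$effect == "group", ]
  expect_equal(grow$df_num, 2L)
  expect_equal(grow$df_den, 97L)

  ca <- car::Anova(lm(y ~ g + a + s,
                      data = data.frame(y = y, g = grp, a = age, s = gender),
                      contrasts = list(g = "contr.sum", s = "contr.sum")),
                   type = 3)
  expect_equal(grow$F, ca["g", "F value"], tolerance = 1e-10)
  expect_equal(res$F[res$effect == "age"], ca["a", "F value"],
               tolerance = 1e-10)

  tiny_grp <- factor(c("a", "a", "b", "b", "c", rep("a", 5)))
  expect_error(ancova_oneway(rnorm(10), tiny_grp, rnorm(10),
                             factor(rep(c("F", "M"), 5))), ">= 2")
})

test_that("ANCOVA is invariant to covariate centering and factor relabeling", {
  set.seed(22)
  grp <- factor(rep(c("a", "b", "c"), times = c(20, 24, 18)))
  age <- rnorm(62, 40, 10)
  gender <- factor(sample(c("F", "M"), 62, TRUE))
  y <- rnorm(62) + as.numeric(grp) * 0.3 + 0.01 * age
  r1 <- ancova_oneway(y, grp, age, gender)
  r2 <- ancova_oneway(y, grp, age - mean(age), gender)
  expect_equal(r1$F, r2$F, tolerance = 1e-10)
  relab <- factor(c(a = "z", b = "x", c = "y")[as.character(grp)])
  r3 <- ancova_oneway(y, relab, age, gender)
  expect_equal(r1$F[r1$effect == "group"], r3$F[r3$effect == "group"],
               tolerance = 1e-10)
})

test_that("group saturation drives eta squared toward one", {
  grp <- factor(rep(c("a", "b", "c"), each = 30))
  y <- as.numeric(grp) + rnorm(90, 0, 1e-4)
  age <- rnorm(90); gender <- factor(rep(c("F", "M"), 45))
  res <- ancova_oneway(y, grp, age, gender)
  expect_gt(res$eta_squared[res$effect == "group"], 0.98)
})

test_that("factorial ANCOVA reports one consistent error df and detects interactions", {
  set.seed(23)
  n <- 63
  syn <- factor(sample(c("FE", "IGE"), n, TRUE))
  ctl <- factor(sample(c("GSC", "PSC"), n, TRUE))
  age <- rnorm(n, 35, 10); gender <- factor(sample(c("F", "M"), n, TRUE))
  aed <- rgamma(n, 2, 1)
  y <- rnorm(n)
  res <- ancova_factorial(y, syn, ctl, age, gender, aed)
  expect_setequal(res$effect[1:3], c("syndrome", "control", "syndrome:control"))
  expect_true(all(res$df_den == n - 7L))

  # pure interaction dominates the three effect F statistics
  yint <- rnorm(n, 0, 0.3) + 2 * (syn == "FE") * (ctl == "PSC") -
    1 * (syn == "FE") - 1 * (ctl == "PSC")
  ri <- ancova_factorial(yint, syn, ctl, age, gender, aed)
  eff <- ri[match(c("syndrome", "control", "syndrome:control"), ri$effect), ]
  expect_equal(eff$effect[which.max(eff$F)], "syndrome:control")

  # balanced orthogonal design: Type III equals sequential sums of squares
  # (covariates repeat identically within every cell, so they are orthogonal
  # to the effects-coded factor columns)
  synb <- factor(rep(c("FE", "IGE"), each = 20))
  ctlb <- factor(rep(rep(c("GSC", "PSC"), each = 10), 2))
  yb <- rnorm(40)
  ageb <- rep(seq(20, 65, length.out = 10), 4)
  gdb <- factor(rep(rep(c("F", "M"), 5), 4))
  aedb <- rep(c(0.2, 1.5, 0.7, 2.1, 0.4, 1.1, 0.9, 1.8, 0.3, 1.3), 4)
  rb <- ancova_factorial(yb, synb, ctlb, ageb, gdb, aedb)
  seqa <- anova(lm(yb ~ ageb + gdb + aedb + synb * ctlb))
  for (pair in list(c("syndrome", "synb"), c("control", "ctlb"),
                    c("syndrome:control", "synb:ctlb"))) {
    expect_equal(rb$F[rb$effect == pair[1]], seqa[pair[2], "F value"],
                 tolerance = 1e-8)
  }

  expect_error(ancova_factorial(y[1:4], factor(c("FE", "FE", "FE", "FE")),
                                ctl[1:4], age[1:4], gender[1:4], aed[1:4]),
               "2 levels")
})

test_that("pooled t accepts raw or summary input identically", {
  set.seed(25)
  a <- rnorm(14, 1); b <- rnorm(11)
  raw <- pooled_t(a, b)
  summ <- pooled_t(list(mean = mean(a), sd = sd(a), n = length(a)),
                   list(mean = mean(b), sd = sd(b), n = length(b)))
  expect_equal(raw$t, summ$t, tolerance = 1e-12)
  expect_equal(raw$df, summ$df)
  expect_equal(raw$p, summ$p, tolerance = 1e-12)
  expect_equal(pooled_t(a, a)$t, 0)
  expect_error(pooled_t(list(mean = 1, sd = 0, n = 5),
                        list(mean = 2, sd = 0, n = 5)), "degenerate")
})

test_that("Hedges' g matches the textbook formula and behaves at limits", {
  set.seed(26)
  for (i in 1:10) {
    a <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
    expect_equal(hedges_g(a, b, n_boot = 0)$g, textbook_hedges_g(a, b),
                 tolerance = 1e-10)
  }
  a <- rnorm(30); b <- a + rnorm(30, 0, 1e-9)
  expect_lt(abs(hedges_g(a, b, n_boot = 0)$g), 1e-4)
  big_a <- rnorm(5000) + 1; big_b <- rnorm(5000)
  expect_equal(hedges_g(big_a, big_b, n_boot = 0)$g, 1, tolerance = 0.1)
  ci <- hedges_g(rnorm(20, 1), rnorm(20), n_boot = 500, seed = 4)
  expect_lt(ci$ci[1], ci$g)
  expect_gt(ci$ci[2], ci$g)
  expect_error(hedges_g(rep(1, 5), rep(1, 6)), "zero pooled")
})

test_that("Levene test detects variance inflation and matches car", {
  set.seed(27)
  g <- factor(rep(c("a", "b", "c"), each = 30))
  x <- rnorm(90)
  lt <- levene_test(x, g)
  cl <- car::leveneTest(x ~ g, center = mean)
  expect_equal(lt$W, cl[1, "F value"], tolerance = 1e-10)
  expect_equal(lt$p, cl[1, "Pr(>F)"], tolerance = 1e-10)

  x2 <- x
  x2[g == "a"] <- x2[g == "a"] * 10
  expect_lt(levene_test(x2, g)$p, 0.05)
})

test_that("slope homogeneity F vanishes when slopes are exactly parallel", {
  set.seed(30)
  g <- factor(rep(c("a", "b"), each = 25))
  cov <- rnorm(50)
  # noise residualized against the full (interaction) model: the interaction
  # block then explains exactly zero variance while the residual df stay full
  Xf <- model.matrix(~ g * cov)
  e <- lm.fit(Xf, rnorm(50))$residuals
  y <- 2 * cov + as.numeric(g) + e
  sh <- slope_homogeneity(y, g, cov)
  expect_lt(sh$F, 1e-10)
  y2 <- ifelse(g == "a", 2 * cov, -2 * cov) + rnorm(50, 0, 0.1)
  expect_lt(slope_homogeneity(y2, g, cov)$p, 1e-6)
})

test_that("chi-square independence reproduces hand-checkable tables", {
  even <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chi_square_independence(even)$chisq, 0, tolerance = 1e-12)
  expect_equal(chi_square_independence(even)$df, 2L)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "margin")
})

test_that("Fisher, Mann-Whitney and Kruskal-Wallis cover the summary-table cases", {
  # all 2x2 tables with margins (5,5)/(5,5): the observed diagonal table has
  # probability 1/choose(10,5) = 1/252, and only its mirror is as extreme
  expect_equal(fisher_exact(rbind(c(5, 0), c(0, 5))), 2 / 252,
               tolerance = 1e-12)
  a <- c(1, 2, 3, 4, 5); b <- a
  expect_equal(unname(mann_whitney_u(a, b)$U), length(a) * length(b) / 2)
  kw <- kruskal_wallis(list(rnorm(10), rnorm(10), rnorm(10)))
  expect_true(kw$p > 0 && kw$p <= 1)
  expect_error(kruskal_wallis(list(rnorm(5), numeric(0))), "empty")
})

test_that("shift-seizure correlation finds monotone links and rejects constants", {
  x <- 1:20
  r <- shift_seizure_correlation(x + 0.5, order(x), n_perm = 500, seed = 2)
  expect_equal(r$rho, 1)
  expect_lt(r$p, 0.01)
  expect_error(shift_seizure_correlation(rep(1, 10), 1:10), "constant")

  set.seed(28)
  co <- generate_cohort(cohort_design(
    n_per_group = c(GSC = 20, PSC = 40),
    group_oscillators = list(GSC = oscillator_spec(10.5, 2, 20, 0.2),
                             PSC = oscillator_spec(8, 2, 20, 0.6)),
    seed = 28))
  sh <- cohort_alpha_shifts(co$segments)
  pat <- co$table$group == "patient"
  r2 <- shift_seizure_correlation(sh$global[pat],
                                  co$table$seizure_count_12m[pat],
                                  n_perm = 2000, seed = 3)
  expect_gt(r2$rho, 0)
  expect_lt(r2$p, 0.05)
})

test_that("planned contrasts are Bonferroni-adjusted pooled t-tests", {
  set.seed(29)
  y <- c(rnorm(20), rnorm(20, 1), rnorm(20, 2))
  g <- factor(rep(c("a", "b", "c"), each = 20))
  pc <- posthoc_contrasts(y, g, n_boot = 200, seed = 5)
  expect_equal(nrow(pc), 3L)
  expect_true(all(pc$df == 38))
  expect_equal(pc$p_bonferroni, pmin(1, pc$p * 3))
  ab <- pooled_t(y[g == "a"], y[g == "b"])
  expect_equal(pc$t[pc$contrast == "a - b"], ab$t, tolerance = 1e-12)
})
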