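test_that("node-wise statistic equals the direct Welch t-test without covariates", {
  set.seed(41)
  g <- factor(rep(c("a", "b"), c(11, 14)))
  X <- cbind(a = as.numeric(g == "a"), b = as.numeric(g == "b"))
  Y <- matrix(rnorm(25 * 8), 25, 8)
  res <- voxel_t_map(Y, X, c(1, -1), g)
  for (j in 1:8) {
    tt <- t.test(Y[g == "a", j], Y[g == "b", j])
    expect_equal(res$t[j], unname(tt$statistic), tolerance = 1e-8)
    expect_equal(res$df[j], unname(tt$parameter), tolerance = 1e-8)
  }
})

test_that("adding a constant to all maps leaves group-contrast t-maps unchanged", {
  set.seed(42)
  g <- factor(rep(c("a", "b"), each = 10))
  X <- cbind(1, as.numeric(g == "a"), rnorm(20))
  Y <- matrix(rnorm(20 * 6), 20, 6)
  r1 <- voxel_t_map(Y, X, c(0, 1, 0), g)
  r2 <- voxel_t_map(Y + 57, X, c(0, 1, 0), g)
  expect_equal(r1$t, r2$t, tolerance = 1e-10)
})

test_that("null group contrasts give statistics symmetric around zero", {
  set.seed(43)
  g <- factor(rep(c("a", "b"), each = 15))
  X <- cbind(1, as.numeric(g == "a"))
  Y <- matrix(rnorm(30 * 2000), 30, 2000)
  res <- voxel_t_map(Y, X, c(0, 1), g)
  expect_lt(abs(mean(res$t)), 0.05)
  expect_lt(abs(mean(res$t > 0) - 0.5), 0.03)
})

test_that("Freedman-Lane is deterministic, ordered, and honest at n_perm = 1", {
  set.seed(44)
  g <- factor(rep(c("a", "b"), c(9, 9)))
  X <- cbind(1, as.numeric(g == "a"), age = rnorm(18))
  Y <- matrix(rnorm(18 * 12), 18, 12)
  Y[g == "a", 1:3] <- Y[g == "a", 1:3] + 2
  r1 <- freedman_lane(Y, X, c(0, 1, 0), n_perm = 300, seed = 7,
                      variance_groups = g)
  r2 <- freedman_lane(Y, X, c(0, 1, 0), n_perm = 300, seed = 7,
                      variance_groups = g)
  expect_identical(r1$p_fwe, r2$p_fwe)
  expect_identical(r1$null_max, r2$null_max)

  expect_true(all(r1$p_fwe >= r1$p_uncorrected - 1e-12))
  expect_true(all(r1$p_uncorrected > 0 & r1$p_uncorrected <= 1))
  expect_true(all(r1$p_fwe <= 1))
  expect_gte(min(r1$p_uncorrected), 1 / 300)
  # FWE p is monotone non-increasing in the observed statistic (it is
  # computed against the shared max-statistic null distribution)
  ord <- order(r1$t)
  expect_true(all(diff(r1$p_fwe[ord]) <= 1e-12))

  r3 <- freedman_lane(Y, X, c(0, 1, 0), n_perm = 1, seed = 7,
                      variance_groups = g)
  expect_true(all(r3$p_uncorrected == 1) && all(r3$p_fwe == 1))
})

test_that("with zero covariates Freedman-Lane equals exhaustive label permutation", {
  set.seed(45)
  g <- factor(rep(c("a", "b"), c(4, 3)))
  X <- cbind(1, as.numeric(g == "a"))
  Y <- matrix(rnorm(7 * 4), 7, 4)
  expect_warning(
    r <- freedman_lane(Y, X, c(0, 1), n_perm = 10000, seed = 1,
                       variance_groups = g),
    "exhaustively")
  # oracle: enumerate the choose(7, 4) group assignments directly
  combs <- combn(7, 4)
  for (j in 1:4) {
    welch <- function(ii) {
      unname(t.test(Y[ii, j], Y[-ii, j])$statistic)
    }
    tobs <- welch(which(g == "a"))
    vals <- apply(combs, 2, welch)
    expect_equal(r$p_uncorrected[j], mean(vals >= tobs - 1e-12),
                 tolerance = 1e-12)
  }
})

test_that("a strong simulated group effect is detected after FWE correction", {
  design <- cohort_design(
    n_per_group = c(GSC = 20, PSC = 20),
    group_oscillators = list(GSC = oscillator_spec(10.5, 2, 20, 0.2),
                             PSC = oscillator_spec(8, 2, 20, 0.6)),
    seed = 46)
  co <- generate_cohort(design)
  sh <- cohort_alpha_shifts(co$segments)
  mapper <- scalp_mapper(grid_n = 16)
  Y <- cohort_scalp_maps(sh$per_channel, mapper)
  grp <- co$table$cohort_group
  X <- cbind(1, as.numeric(grp == "PSC"), age = co$table$age,
             gender = as.numeric(factor(co$table$gender)) - 1)
  r <- freedman_lane(Y, X, c(0, 1, 0, 0), n_perm = 1000, seed = 2,
                     variance_groups = grp, mapper = mapper)
  expect_lte(min(r$p_fwe), 0.05)
})

test_that("effect-size maps agree with the scalar Hedges' g per node", {
  fix <- fixture_maps(12, 15, nodes = 6, delta = 0.8, seed = 47)
  es <- effect_size_map(fix$Y, fix$groups, n_boot = 0)
  for (j in 1:6) {
    expect_equal(es$g[j],
                 hedges_g(fix$Y[fix$groups == "a", j],
                          fix$Y[fix$groups == "b", j], n_boot = 0)$g,
                 tolerance = 1e-10)
  }
  null_fix <- fixture_maps(25, 25, nodes = 40, delta = 0, seed = 48)
  es0 <- effect_size_map(null_fix$Y, null_fix$groups, n_boot = 0)
  expect_lt(max(abs(es0$g)), 1.2)
  expect_lt(abs(mean(es0$g)), 0.2)
})

test_that("bootstrap CIs for node-wise g approximately cover the truth", {
  # known g: unit mean difference at unit variance, n = 40/40
  true_g <- (1 - 3 / (4 * 80 - 9)) * 1
  hits <- 0; reps <- 120
  for (i in seq_len(reps)) {
    fix <- fixture_maps(40, 40, nodes = 1, delta = 1, seed = 400 + i)
    es <- effect_size_map(fix$Y, fix$groups, n_boot = 400, seed = i)
    if (es$ci_lo[1] <= true_g && true_g <= es$ci_hi[1]) hits <- hits + 1
  }
  coverage <- hits / reps
  expect_gt(coverage, 0.86)
  expect_lte(coverage, 1)
})

test_that("nearest electrode lookup is exact, tie-broken alphabetically", {
  lay <- montage_1020()
  expect_equal(nearest_electrode(lay$xy["O1", ], lay), "O1")
  mid <- (lay$xy["C3", ] + lay$xy["Cz", ]) / 2
  expect_equal(nearest_electrode(mid, lay), "C3")
  set.seed(49)
  for (i in 1:20) {
    p <- runif(2, -70, 70)
    d <- sqrt(rowSums(sweep(lay$xy, 2, p)^2))
    expect_equal(nearest_electrode(p, lay), lay$labels[which.min(d)])
  }
})
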