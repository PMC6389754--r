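# Precompute design quantities for the Aspin-Welch GLM contrast t.
# variance_groups: factor of per-subject variance-group labels (residual
# variance is estimated separately per group); a single level gives the
# homoscedastic GLM t.
.welch_pre <- function(X, contrast, variance_groups) {
  X <- as.matrix(X)
  N <- nrow(X)
  vg <- droplevels(as.factor(variance_groups))
  if (any(table(vg) < 2)) stop("every variance group needs >= 2 subjects")
  qd <- qr(X)
  if (qd$rank < ncol(X)) stop("rank-deficient design matrix")
  XtX_inv <- chol2inv(qr.R(qd))
  pinvX <- XtX_inv %*% t(X)                       # p x N
  k <- drop(X %*% (XtX_inv %*% contrast))         # N, Var(c'b) = sum k_i^2 s_i^2
  lev <- rowSums(qr.Q(qd)^2)                      # leverages
  G <- outer(levels(vg), as.character(vg), "==") * 1  # B x N indicator
  nu <- drop(G %*% lev)
  nu <- drop(G %*% rep(1, N)) - nu                # n_b - sum of leverages
  if (any(nu <= 0)) stop("variance group too small for the model")
  a <- drop(G %*% k^2)                            # per-group contribution
  list(X = X, pinvX = pinvX, contrast = contrast, G = G, nu = nu, a = a)
}

# Aspin-Welch t and Welch-Satterthwaite df for each column of Y (N x nodes)
.welch_t <- function(Y, pre) {
  B <- pre$pinvX %*% Y
  E <- Y - pre$X %*% B
  S2 <- (pre$G %*% E^2) / pre$nu                  # per-group residual variance
  varc <- drop(crossprod(pre$a, S2))
  cb <- drop(crossprod(pre$contrast, B))
  tv <- cb / sqrt(varc)
  df <- varc^2 / drop(crossprod(pre$a^2 / pre$nu, S2^2))
  list(t = tv, df = df)
}

#' Node-wise unequal-variance GLM t-map
#'
#' At every unmasked node, fits the linear model and computes the
#' Aspin-Welch t for the contrast, with residual variance estimated
#' separately per variance group and Welch-Satterthwaite degrees of freedom.
#' With a two-group cell-means design and no covariates this reduces exactly
#' to the classical Welch two-sample t-test.
#'
#' @param Y Subjects x nodes matrix of map values (as from
#'   [cohort_scalp_maps()]).
#' @param design Design matrix (subjects x regressors), full rank.
#' @param contrast Numeric contrast vector over the design columns.
#' @param variance_groups Per-subject labels; variance is estimated per
#'   group (>= 2 subjects each). A single shared label gives the
#'   homoscedastic GLM t.
#' @return List with `t` and `df` vectors (one entry per node).
#' @export
voxel_t_map <- function(Y, design, contrast, variance_groups) {
  pre <- .welch_pre(design, contrast, variance_groups)
  .welch_t(as.matrix(Y), pre)
}

# all permutations of seq_len(n) as an n! x n matrix (small n only)
.all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Freedman-Lane permutation inference on scalp maps
#'
#' Tests a contrast of interest in the presence of nuisance covariates by
#' permuting the residuals of the nuisance-only model: the reduced model
#' (design columns with zero contrast weight) is fitted once, its residuals
#' are permuted, added back to the nuisance fit, and the full-model
#' Aspin-Welch contrast t is recomputed at every node. Family-wise error is
#' controlled with the permutation distribution of the maximum statistic
#' over nodes.
#'
#' The first of `n_perm` permutations is always the identity, so p-values
#' are bounded below by `1 / n_perm` and `n_perm = 1` returns p = 1
#' everywhere. When `n_perm` exceeds the number of distinct permutations (or
#' `exhaustive = TRUE`), all permutations are enumerated instead (supported
#' for up to 10 subjects).
#'
#' @param Y Subjects x nodes matrix of map values.
#' @param design Design matrix; columns with non-zero contrast weight form
#'   the effect of interest, the remaining columns the nuisance block.
#' @param contrast Contrast vector over design columns.
#' @param n_perm Number of permutations including the identity (default
#'   10000).
#' @param seed Permutation seed; identical seeds reproduce results exactly.
#' @param variance_groups Per-subject variance-group labels (default: one
#'   shared group).
#' @param alternative `"greater"` (one-sided in the contrast direction, the
#'   default) or `"two.sided"` (inference on |t|).
#' @param exhaustive Force exhaustive enumeration of all permutations.
#' @param mapper Optional [scalp_mapper()] to attach spatial metadata
#'   (enables map reconstruction and peak electrode lookup).
#' @return An object of class `perm_result`: `t`, `df`, `p_uncorrected`,
#'   `p_fwe` (vectors over nodes), `null_max` (per-permutation maxima),
#'   `n_perm`, and `peak` (statistic, df, node coordinates and nearest
#'   electrode when a mapper is supplied).
#' @export
freedman_lane <- function(Y, design, contrast, n_perm = 10000, seed = 1,
                          variance_groups = NULL,
                          alternative = c("greater", "two.sided"),
                          exhaustive = FALSE, mapper = attr(Y, "mapper")) {
  alternative <- match.arg(alternative)
  Y <- as.matrix(Y)
  X <- as.matrix(design)
  N <- nrow(Y)
  if (nrow(X) != N) stop("design rows must match subjects")
  if (length(contrast) != ncol(X)) stop("contrast length must match design columns")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(variance_groups)) variance_groups <- rep("all", N)
  pre <- .welch_pre(X, contrast, variance_groups)

  nuis <- which(abs(contrast) < 1e-12)
  if (length(nuis)) {
    Z <- X[, nuis, drop = FALSE]
    fz <- stats::lm.fit(Z, Y)
    Fz <- Z %*% fz$coefficients
    Ez <- Y - Fz
  } else {
    Fz <- matrix(0, N, ncol(Y))
    Ez <- Y
  }

  n_distinct <- factorial(N)
  if (n_perm > n_distinct && !exhaustive) {
    warning(sprintf("n_perm = %d exceeds the %d distinct permutations; enumerating exhaustively",
                    n_perm, n_distinct))
    exhaustive <- TRUE
  }
  if (exhaustive) {
    if (N > 10) stop("exhaustive enumeration supported for up to 10 subjects")
    perms <- .all_permutations(N)
  } else {
    perms <- with_seed(seed, {
      rbind(seq_len(N),
            t(vapply(seq_len(n_perm - 1L), function(i) sample.int(N),
                     integer(N))))
    })
  }
  m <- nrow(perms)

  obs <- .welch_t(Y, pre)
  score <- function(tv) if (alternative == "two.sided") abs(tv) else tv
  s_obs <- score(obs$t)
  eps <- 1e-12
  count_unc <- numeric(ncol(Y))
  null_max <- numeric(m)
  for (i in seq_len(m)) {
    Yp <- Fz + Ez[perms[i, ], , drop = FALSE]
    s <- score(.welch_t(Yp, pre)$t)
    count_unc <- count_unc + (s >= s_obs - eps)
    null_max[i] <- max(s)
  }
  p_unc <- count_unc / m
  p_fwe <- vapply(s_obs, function(s0) mean(null_max >= s0 - eps), numeric(1))

  peak_idx <- which.max(s_obs)
  peak <- list(statistic = obs$t[peak_idx], df = obs$df[peak_idx],
               node = peak_idx, p_fwe = p_fwe[peak_idx])
  if (!is.null(mapper)) {
    peak$xy <- mapper$interp$node_xy[peak_idx, ]
    peak$nearest_electrode <- nearest_electrode(peak$xy, mapper$interp$layout)
  }
  structure(list(t = obs$t, df = obs$df, p_uncorrected = p_unc,
                 p_fwe = p_fwe, null_max = null_max, n_perm = m,
                 alternative = alternative, peak = peak, mapper = mapper),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("Freedman-Lane permutation test (%d permutations, %s)\n",
              x$n_perm, x$alternative))
  cat(sprintf("  peak t(%.1f) = %.3f, p_fwe = %.4g", x$peak$df,
              x$peak$statistic, x$peak$p_fwe))
  if (!is.null(x$peak$nearest_electrode)) {
    cat(sprintf(", nearest electrode %s", x$peak$nearest_electrode))
  }
  cat(sprintf("\n  %d / %d nodes significant at p_fwe < 0.05\n",
              sum(x$p_fwe < 0.05), length(x$p_fwe)))
  invisible(x)
}

#' Reconstruct scalp maps from a permutation result
#'
#' @param x A `perm_result` produced with a mapper attached.
#' @param which One of `"t"`, `"p_uncorrected"`, `"p_fwe"`.
#' @return A `scalp_map`.
#' @export
perm_result_map <- function(x, which = c("t", "p_uncorrected", "p_fwe")) {
  which <- match.arg(which)
  if (is.null(x$mapper)) stop("perm_result carries no mapper metadata")
  .as_scalp_map(x[[which]], x$mapper$interp, sigma = x$mapper$sigma)
}

#' Node-wise Hedges' g effect-size map with bootstrap CIs
#'
#' Computes Hedges' g at every node between two groups of subjects, with
#' percentile-bootstrap confidence bands obtained by resampling subjects
#' (never nodes). Nodes with zero pooled variance are flagged NA.
#'
#' @param Y Subjects x nodes matrix.
#' @param groups Two-level factor over subjects (first level minus second).
#' @param n_boot Bootstrap resamples (default 5000; 0 skips the CI).
#' @param seed Bootstrap seed.
#' @param conf Confidence level.
#' @return List with vectors `g`, `ci_lo`, `ci_hi`.
#' @export
effect_size_map <- function(Y, groups, n_boot = 5000, seed = 1, conf = 0.95) {
  Y <- as.matrix(Y)
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2) stop("groups must have exactly 2 levels")
  ia <- which(groups == levels(groups)[1])
  ib <- which(groups == levels(groups)[2])
  if (length(ia) < 2 || length(ib) < 2) stop("both groups need >= 2 subjects")
  g_vec <- function(idxa, idxb) {
    A <- Y[idxa, , drop = FALSE]; B <- Y[idxb, , drop = FALSE]
    na <- length(idxa); nb <- length(idxb)
    va <- colMeans(A^2) - colMeans(A)^2
    vb <- colMeans(B^2) - colMeans(B)^2
    # biased col-variances recombine to the pooled unbiased variance
    sp2 <- (va * na + vb * nb) / (na + nb - 2)
    g <- (1 - 3 / (4 * (na + nb) - 9)) * (colMeans(A) - colMeans(B)) / sqrt(sp2)
    g[sp2 <= 0] <- NA_real_
    g
  }
  g <- g_vec(ia, ib)
  ci_lo <- ci_hi <- NULL
  if (n_boot > 0) {
    boots <- with_seed(seed, {
      out <- matrix(NA_real_, n_boot, ncol(Y))
      for (bi in seq_len(n_boot)) {
        out[bi, ] <- g_vec(sample(ia, replace = TRUE),
                           sample(ib, replace = TRUE))
      }
      out
    })
    alpha <- (1 - conf) / 2
    qs <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                na.rm = TRUE)
    ci_lo <- qs[1, ]; ci_hi <- qs[2, ]
  }
  list(g = g, ci_lo = ci_lo, ci_hi = ci_hi)
}

#' Nearest electrode to a scalp position
#'
#' Euclidean nearest electrode label; ties are broken alphabetically.
#'
#' @param xy Length-2 coordinate (mm).
#' @param layout A [montage_1020()] layout.
#' @return Electrode label.
#' @export
nearest_electrode <- function(xy, layout) {
  d <- sqrt((layout$xy[, 1] - xy[1])^2 + (layout$xy[, 2] - xy[2])^2)
  cand <- layout$labels[d <= min(d) + 1e-9]
  sort(cand)[1]
}
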