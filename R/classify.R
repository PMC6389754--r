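#' Train a Fisher linear discriminant
#'
#' Fisher discriminant direction from the ridge-regularized pooled
#' within-class covariance, `w = (Sw + ridge * tr(Sw)/d * I)^-1 (mu1 - mu0)`,
#' with the decision threshold at the equal-prior midpoint
#' `w' (mu0 + mu1) / 2`. The second factor level is scored positive.
#'
#' @param features Subjects x features numeric matrix (finite values).
#' @param labels Binary factor (>= 2 subjects per class).
#' @param ridge Regularization strength epsilon (default 1e-6); the ridge
#'   added is `epsilon * trace(Sw) / d`.
#' @return An object of class `lda_model`: list with `w`, `threshold`,
#'   `classes`, `means`.
#' @export
lda_train <- function(features, labels, ridge = 1e-6) {
  X <- as.matrix(features)
  if (any(!is.finite(X))) stop("features must be finite")
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stop("labels must have exactly 2 levels")
  if (any(table(y) < 2)) stop("both classes need >= 2 subjects")
  i0 <- y == levels(y)[1]; i1 <- y == levels(y)[2]
  mu0 <- colMeans(X[i0, , drop = FALSE])
  mu1 <- colMeans(X[i1, , drop = FALSE])
  if (all(mu0 == mu1) && all(apply(X, 2, stats::sd) == 0)) {
    stop("degenerate input: both classes identical and constant")
  }
  S0 <- stats::cov(X[i0, , drop = FALSE]) * (sum(i0) - 1)
  S1 <- stats::cov(X[i1, , drop = FALSE]) * (sum(i1) - 1)
  Sw <- (S0 + S1) / (nrow(X) - 2)
  d <- ncol(X)
  tr <- sum(diag(Sw))
  if (tr <= 0) tr <- 1
  Sr <- Sw + diag(ridge * tr / d, d)
  w <- drop(solve(Sr, mu1 - mu0))
  structure(list(w = w, threshold = sum(w * (mu0 + mu1)) / 2,
                 classes = levels(y), means = rbind(mu0, mu1)),
            class = "lda_model")
}

#' Discriminant scores and class predictions
#'
#' @param model An `lda_model`.
#' @param features Subjects x features matrix.
#' @return `lda_score`: numeric scores (higher favors the positive class).
#'   `lda_predict`: factor of predicted classes.
#' @export
lda_score <- function(model, features) {
  drop(as.matrix(features) %*% model$w)
}

#' @rdname lda_score
#' @export
lda_predict <- function(model, features) {
  factor(ifelse(lda_score(model, features) > model$threshold,
                model$classes[2], model$classes[1]),
         levels = model$classes)
}

# rank-based AUC (probability that a positive outscores a negative, ties 0.5)
.rank_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified k-fold cross-validated LDA
#'
#' Stratified folds are drawn within each class; per repeat, sensitivity and
#' specificity are computed from the pooled out-of-fold class predictions
#' and the AUC from the pooled out-of-fold discriminant scores (rank-based,
#' tie-corrected). Metrics are summarized as mean, SD and normal-approximation
#' 95% CI across repeats, on a percent scale.
#'
#' @param features Subjects x features matrix.
#' @param labels Binary factor; the second level is the positive class and
#'   each class must have at least `n_folds` members.
#' @param n_folds Folds (default 10).
#' @param n_repeats Repeats of the whole cross-validation (default 100).
#' @param seed Seed controlling fold assignment; identical seeds give
#'   identical reports.
#' @param ridge Passed to [lda_train()].
#' @return An object of class `classifier_report` with per-metric mean, sd
#'   and CI (percent), plus the pooled out-of-fold scores of the first
#'   repeat (for the AUC z-test).
#' @export
cross_validate <- function(features, labels, n_folds = 10, n_repeats = 100,
                           seed = 1, ridge = 1e-6) {
  X <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stop("labels must have exactly 2 levels")
  if (any(table(y) < n_folds)) {
    stop(sprintf("each class needs at least n_folds = %d members", n_folds))
  }
  pos <- levels(y)[2]
  metrics <- matrix(NA_real_, n_repeats, 3,
                    dimnames = list(NULL, c("sensitivity", "specificity", "auc")))
  first_scores <- NULL
  res <- with_seed(seed, {
    for (rep_i in seq_len(n_repeats)) {
      fold <- integer(length(y))
      for (cl in levels(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(n_folds), length(idx))
      }
      scores <- numeric(length(y))
      pred <- character(length(y))
      for (f in seq_len(n_folds)) {
        te <- fold == f
        m <- lda_train(X[!te, , drop = FALSE], y[!te], ridge = ridge)
        # pool decision values relative to each fold's threshold so that
        # out-of-fold scores from different folds share a common origin
        scores[te] <- lda_score(m, X[te, , drop = FALSE]) - m$threshold
        pred[te] <- as.character(lda_predict(m, X[te, , drop = FALSE]))
      }
      is_pos <- y == pos
      metrics[rep_i, "sensitivity"] <- mean(pred[is_pos] == pos)
      metrics[rep_i, "specificity"] <- mean(pred[!is_pos] != pos)
      metrics[rep_i, "auc"] <- .rank_auc(scores, is_pos)
      if (rep_i == 1L) first_scores <- scores
    }
    list(metrics = metrics, first_scores = first_scores)
  })
  m <- res$metrics * 100
  summ <- data.frame(
    metric = colnames(m),
    mean = colMeans(m),
    sd = apply(m, 2, stats::sd),
    row.names = NULL, stringsAsFactors = FALSE)
  half <- stats::qnorm(0.975) * summ$sd
  summ$ci_lo <- pmax(0, summ$mean - half)
  summ$ci_hi <- pmin(100, summ$mean + half)
  structure(list(summary = summ, n_folds = n_folds, n_repeats = n_repeats,
                 seed = seed, positive_class = pos,
                 oof_scores = res$first_scores, labels = y),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Cross-validated LDA (%d-fold, %d repeats; positive class '%s')\n",
              x$n_folds, x$n_repeats, x$positive_class))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.1f +/- %.1f%% [%.1f%%, %.1f%%]\n", s$metric[i],
                s$mean[i], s$sd[i], s$ci_lo[i], s$ci_hi[i]))
  }
  invisible(x)
}

#' z-test of the AUC against chance
#'
#' Tests whether out-of-fold discriminant scores separate the classes better
#' than chance using the rank-sum normal approximation with tie correction:
#' the Mann-Whitney U implied by the AUC is compared with its null mean and
#' variance.
#'
#' @param scores Numeric out-of-fold discriminant scores.
#' @param labels Binary factor (second level positive); both classes present.
#' @return List with `auc`, `z`, `p` (two-sided).
#' @export
auc_z_test <- function(scores, labels) {
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stop("both classes must be present")
  positive <- y == levels(y)[2]
  n1 <- sum(positive); n0 <- sum(!positive); N <- n1 + n0
  auc <- .rank_auc(scores, positive)
  U <- auc * n1 * n0
  ties <- table(scores)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  var_u <- n1 * n0 / 12 * ((N + 1) - tie_term)
  if (var_u <= 0) stop("degenerate scores: zero rank variance")
  z <- (U - n1 * n0 / 2) / sqrt(var_u)
  list(auc = auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}
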