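# Chemometric battery: scaling, regression against PMI, PCA, LDA, MANOVA
# with pairwise Hotelling post hoc comparisons.

#' Z-score scale a matrix
#'
#' Columns are centred to mean 0 and scaled to SD 1 (n-1 denominator).
#' Zero-variance columns pass through as zeros with a warning.
#'
#' @param x Numeric matrix or data frame with >= 2 rows.
#' @return Scaled numeric matrix.
#' @export
zscore_scale <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2)
    abort_ba("need >= 2 rows to scale", "insufficient_data_error")
  if (any(!is.finite(x)))
    abort_ba("non-finite values in matrix", "insufficient_data_error")
  s <- apply(x, 2, stats::sd)
  if (any(s == 0)) {
    warning(sprintf("zero-variance column(s) set to 0: %s",
                    paste(colnames(x)[s == 0], collapse = ", ")))
  }
  out <- sweep(x, 2, colMeans(x), "-")
  out[, s > 0] <- sweep(out[, s > 0, drop = FALSE], 2, s[s > 0], "/")
  out[, s == 0] <- 0
  out
}

#' Linear regression of a parameter against postmortem interval
#'
#' Ordinary least squares of `y` on `x` (days). `r` is the Pearson
#' correlation; the default p-value is the two-sided test of zero slope.
#' The protocol's null ("the parameter does not increase with PMI") reads
#' as one-sided, but significant negative correlations are treated as
#' rejections too in the source material, so two-sided is the coherent
#' default; `alternative = "greater"` gives the literal one-sided test.
#'
#' @param x Numeric vector of days.
#' @param y Numeric response.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return List of class `pmi_regression`: `slope`, `intercept`, `r`, `p`,
#'   `n`.
#' @export
regress_vs_pmi <- function(x, y, alternative = "two.sided") {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3)
    abort_ba("need >= 3 finite observations", "insufficient_data_error")
  if (stats::sd(x) == 0)
    abort_ba("x (days) is constant: degenerate design", "degenerate_design_error")
  fit <- stats::lm(y ~ x)
  r <- stats::cor(x, y)
  ct <- stats::cor.test(x, y, alternative = alternative)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = r, p = ct$p.value, n = length(x)),
            class = "pmi_regression")
}

#' Principal component analysis on z-scored data
#'
#' Eigendecomposition of the sample covariance of the scaled matrix
#' (equivalently, PCA on the correlation matrix of the raw data).
#' Components are ordered by decreasing variance; the sign convention
#' makes the largest-magnitude loading of each component positive.
#'
#' @param x Numeric matrix or data frame (rows = samples); scaled
#'   internally unless `scale. = FALSE`.
#' @param scale. Z-score the input first (default `TRUE`).
#' @return List of class `pca_result`: `explained` (percent variance per
#'   component), `loadings` (features x components, unit columns),
#'   `scores` (samples x components), `sdev`.
#' @export
pca_scaled <- function(x, scale. = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2)
    abort_ba("need >= 2 rows for PCA", "insufficient_data_error")
  if (scale.) x <- suppressWarnings(zscore_scale(x))
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rotation <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  vars <- pc$sdev^2
  structure(list(explained = 100 * vars / sum(vars), loadings = rotation,
                 scores = scores, sdev = pc$sdev),
            class = "pca_result")
}

#' Fisher linear discriminant analysis
#'
#' Discriminant directions are eigenvectors of W^-1 B, where W is the
#' pooled within-class scatter and B the between-class scatter. A ridge
#' term lambda = `ridge` * trace(W)/p stabilises W when it is singular or
#' near-singular. Posterior class probabilities ("confidence scores") come
#' from the pooled-covariance Gaussian model with proportional priors.
#'
#' @param x Numeric matrix or data frame (rows = samples).
#' @param labels Class labels, one per row; every class needs >= 2
#'   samples.
#' @param ridge Relative ridge shrinkage applied to W.
#' @return List of class `lda_result`: `coefficients` (features x
#'   discriminants, at most n_classes - 1), `scores`, `posterior`,
#'   `predicted`, `classes`, `accuracy` (training agreement with
#'   `labels`), plus the fitted `means`, `pooled_cov` and `priors` needed
#'   to classify new samples via [predict_lda()].
#' @export
lda_fit <- function(x, labels, ridge = 1e-6) {
  x <- as.matrix(x)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    abort_ba("need >= 2 classes", "insufficient_class_error")
  counts <- table(labels)
  if (any(counts < 2))
    abort_ba(sprintf("class(es) with < 2 samples: %s",
                     paste(names(counts)[counts < 2], collapse = ", ")),
             "insufficient_class_error")
  n <- nrow(x); p <- ncol(x); g <- length(classes)
  grand <- colMeans(x)
  means <- t(vapply(classes, function(cl) colMeans(x[labels == cl, , drop = FALSE]),
                    numeric(p)))
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (i in seq_along(classes)) {
    xi <- x[labels == classes[i], , drop = FALSE]
    ci <- sweep(xi, 2, means[i, ], "-")
    W <- W + crossprod(ci)
    d <- means[i, ] - grand
    B <- B + nrow(xi) * tcrossprod(d)
  }
  Wr <- W + diag(ridge * sum(diag(W)) / p, p)
  eig <- eigen(solve(Wr, B))
  k <- min(g - 1, p)
  vec <- Re(eig$vectors[, seq_len(k), drop = FALSE])
  vec <- apply(vec, 2, function(v) v / sqrt(sum(v^2)))
  vec <- matrix(vec, nrow = p)
  rownames(vec) <- colnames(x)
  pooled <- Wr / (n - g)
  priors <- as.numeric(counts[classes]) / n
  post <- gaussian_posteriors(x, means, pooled, priors, classes)
  predicted <- classes[max.col(post)]
  structure(list(coefficients = vec, scores = x %*% vec, posterior = post,
                 predicted = predicted, classes = classes,
                 accuracy = mean(predicted == labels),
                 means = means, pooled_cov = pooled, priors = priors),
            class = "lda_result")
}

gaussian_posteriors <- function(x, means, pooled, priors, classes) {
  inv <- solve(pooled)
  disc <- vapply(seq_along(classes), function(i) {
    mu <- means[i, ]
    drop(x %*% inv %*% mu) - 0.5 * drop(t(mu) %*% inv %*% mu) + log(priors[i])
  }, numeric(nrow(x)))
  disc <- matrix(disc, nrow = nrow(x))
  m <- apply(disc, 1, max)
  post <- exp(disc - m)
  post <- post / rowSums(post)
  colnames(post) <- classes
  post
}

#' Classify new samples with a fitted LDA
#'
#' @param fit An `lda_result`.
#' @param newdata Numeric matrix/data frame with the training columns.
#' @return List with `predicted` labels and `posterior` matrix.
#' @export
predict_lda <- function(fit, newdata) {
  x <- as.matrix(newdata)
  post <- gaussian_posteriors(x, fit$means, fit$pooled_cov, fit$priors,
                              fit$classes)
  list(predicted = fit$classes[max.col(post)], posterior = post)
}

#' Two-sample Hotelling T-squared test
#'
#' @param x1,x2 Numeric matrices (rows = samples) with equal columns.
#' @return List with `statistic` (T2), `f`, `df1`, `df2`, `p`.
#' @export
hotelling_t2 <- function(x1, x2) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  n1 <- nrow(x1); n2 <- nrow(x2); p <- ncol(x1)
  if (n1 + n2 - 2 < p)
    abort_ba("too few samples for Hotelling T2 with this many features",
             "singular_design_error")
  d <- colMeans(x1) - colMeans(x2)
  S <- (crossprod(sweep(x1, 2, colMeans(x1))) +
          crossprod(sweep(x2, 2, colMeans(x2)))) / (n1 + n2 - 2)
  t2 <- tryCatch(
    as.numeric(n1 * n2 / (n1 + n2) * t(d) %*% solve(S, d)),
    error = function(e) abort_ba(
      "singular pooled covariance in Hotelling T2; reduce features",
      "singular_design_error"))
  f <- (n1 + n2 - p - 1) / ((n1 + n2 - 2) * p) * t2
  df2 <- n1 + n2 - p - 1
  list(statistic = t2, f = f, df1 = p, df2 = df2,
       p = stats::pf(f, p, df2, lower.tail = FALSE))
}

#' MANOVA with pairwise multivariate comparison tests
#'
#' Omnibus one-way MANOVA (Wilks' lambda with Rao's F approximation)
#' followed by pairwise two-group Hotelling T-squared tests with Holm
#' adjustment across pairs.
#'
#' @param x Numeric matrix or data frame (rows = samples).
#' @param groups Group labels, one per row; >= 2 groups.
#' @param alpha Significance level recorded in the result.
#' @param p_adjust Multiplicity adjustment for the pairwise tests
#'   (`"holm"` default, `"bonferroni"` available).
#' @return List of class `manova_result`: `wilks_lambda`, `f`, `df`, `p`,
#'   `pairwise` (data frame: group pair, raw and adjusted p), `alpha`.
#' @export
manova_with_mct <- function(x, groups, alpha = 0.05, p_adjust = "holm") {
  x <- as.matrix(x)
  groups <- factor(groups)
  if (nlevels(groups) < 2)
    abort_ba("need >= 2 groups", "insufficient_class_error")
  if (nrow(x) <= ncol(x) + nlevels(groups))
    abort_ba("total n must exceed features + groups", "insufficient_data_error")
  fit <- stats::manova(x ~ groups)
  sm <- tryCatch(summary(fit, test = "Wilks"),
                 error = function(e) abort_ba(
                   paste0("singular within-group scatter; reduce features (",
                          conditionMessage(e), ")"),
                   "singular_design_error"))
  st <- sm$stats
  lambda <- st["groups", "Wilks"]
  lev <- levels(groups)
  pairs <- utils::combn(lev, 2)
  pw <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                   p_raw = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    h <- hotelling_t2(x[groups == pairs[1, i], , drop = FALSE],
                      x[groups == pairs[2, i], , drop = FALSE])
    pw$p_raw[i] <- h$p
  }
  pw$p_adj <- stats::p.adjust(pw$p_raw, method = p_adjust)
  structure(list(wilks_lambda = lambda,
                 f = st["groups", "approx F"],
                 df = c(st["groups", "num Df"], st["groups", "den Df"]),
                 p = st["groups", "Pr(>F)"],
                 pairwise = pw, alpha = alpha),
            class = "manova_result")
}
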