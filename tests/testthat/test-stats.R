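# The chemometric battery against closed-form and brute-force oracles.

test_that("z-scoring centres and scales with the n-1 convention", {
  expect_equal(as.numeric(zscore_scale(matrix(1:3))), c(-1, 0, 1))
  m <- matrix(rnorm(40), 10)
  z <- zscore_scale(m)
  expect_equal(zscore_scale(z), z, tolerance = 1e-12)
  expect_warning(zc <- zscore_scale(cbind(a = rep(2, 5), b = 1:5)),
                 "zero-variance")
  expect_equal(unname(zc[, "a"]), rep(0, 5))
  expect_error(zscore_scale(matrix(1, 1, 2)), class = "insufficient_data_error")
})

test_that("regression against PMI matches the Pearson formula oracle", {
  x <- c(0, 14, 34, 91, 180, 365)
  perfect <- regress_vs_pmi(x, 2 * x)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$slope, 2)

  set.seed(8)
  for (i in 1:10) {
    xs <- rnorm(10); ys <- rnorm(10)
    fit <- regress_vs_pmi(xs, ys)
    r_brute <- sum((xs - mean(xs)) * (ys - mean(ys))) /
      sqrt(sum((xs - mean(xs))^2) * sum((ys - mean(ys))^2))
    expect_equal(fit$r, r_brute, tolerance = 1e-10)
    expect_gte(fit$p, 0)
    expect_lte(fit$p, 1)
  }
  expect_error(regress_vs_pmi(rep(1, 5), rnorm(5)),
               class = "degenerate_design_error")
  expect_error(regress_vs_pmi(1:2, 1:2), class = "insufficient_data_error")
})

test_that("PCA explains variance per the covariance eigenstructure", {
  # rank-1 data: one direction carries everything
  v <- matrix(rnorm(30), 30, 1) %*% c(1, 2)
  p <- pca_scaled(v, scale. = FALSE)
  expect_equal(p$explained[1], 100)

  # known diagonal covariance (4, 1): 80/20 split at large n
  set.seed(9)
  big <- cbind(rnorm(20000, sd = 2), rnorm(20000, sd = 1))
  pb <- pca_scaled(big, scale. = FALSE)
  expect_equal(pb$explained, c(80, 20), tolerance = 0.03)

  sc <- pca_scaled(matrix(rnorm(60), 12, 5))
  expect_equal(sum(sc$explained), 100, tolerance = 1e-8)
  expect_equal(crossprod(sc$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # sign convention: dominant loading positive
  expect_true(all(apply(sc$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
})

test_that("LDA recovers the closed-form Fisher direction and separable classes", {
  sep <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
               matrix(rnorm(20, 5, 0.1), 10, 2))
  lab <- rep(c("a", "b"), each = 10)
  fit <- lda_fit(sep, lab)
  expect_equal(fit$accuracy, 1)
  expect_equal(rowSums(fit$posterior), rep(1, 20), tolerance = 1e-12)
  expect_identical(fit$predicted,
                   fit$classes[max.col(fit$posterior)])

  # 5-point toy set: direction proportional to pooled-Sigma^-1 (mu1 - mu2)
  x <- matrix(c(0.1, 0.2, 0.5, 0.3, 0.0, 0.4, 2.0, 1.8, 2.2, 2.1), 5, 2)
  labs <- c("a", "a", "a", "b", "b")
  f2 <- lda_fit(x, labs, ridge = 0)
  mu <- rbind(colMeans(x[1:3, ]), colMeans(x[4:5, ]))
  W <- crossprod(sweep(x[1:3, ], 2, mu[1, ])) +
    crossprod(sweep(x[4:5, ], 2, mu[2, ]))
  brute <- solve(W, mu[1, ] - mu[2, ])
  cosine <- abs(sum(brute * f2$coefficients[, 1])) /
    sqrt(sum(brute^2) * sum(f2$coefficients[, 1]^2))
  expect_gt(cosine, 0.9999)

  expect_error(lda_fit(sep, rep("a", 20)), class = "insufficient_class_error")
  expect_error(lda_fit(sep, c("a", rep("b", 19))),
               class = "insufficient_class_error")
})

test_that("LDA agrees with the reference implementation on a random problem", {
  skip_if_not_installed("MASS")
  set.seed(14)
  x <- rbind(matrix(rnorm(60, 0), 20, 3), matrix(rnorm(60, 1.5), 20, 3))
  lab <- rep(c("u", "b"), each = 20)
  mine <- lda_fit(x, lab)
  ref <- MASS::lda(x, grouping = lab)
  cosine <- abs(sum(ref$scaling[, 1] * mine$coefficients[, 1])) /
    sqrt(sum(ref$scaling[, 1]^2) * sum(mine$coefficients[, 1]^2))
  expect_gt(cosine, 0.9999)
  expect_identical(mine$predicted,
                   as.character(predict(ref, x)$class))
})

test_that("Hotelling T2 reduces to the squared t statistic in one dimension", {
  set.seed(15)
  a <- matrix(rnorm(12), 12, 1)
  b <- matrix(rnorm(15, 0.8), 15, 1)
  h <- hotelling_t2(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(h$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(h$p, tt$p.value, tolerance = 1e-10)
})

test_that("Wilks' lambda equals the brute-force determinant ratio", {
  set.seed(16)
  x <- matrix(rnorm(42), 21, 2)
  g <- rep(c("a", "b", "c"), each = 7)
  res <- manova_with_mct(x, g)
  grand <- colMeans(x)
  W <- matrix(0, 2, 2); B <- matrix(0, 2, 2)
  for (lv in unique(g)) {
    xi <- x[g == lv, ]
    W <- W + crossprod(sweep(xi, 2, colMeans(xi)))
    B <- B + nrow(xi) * tcrossprod(colMeans(xi) - grand)
  }
  expect_equal(res$wilks_lambda, det(W) / det(W + B), tolerance = 1e-10)
  expect_true(res$wilks_lambda > 0 && res$wilks_lambda <= 1)
  expect_true(all(res$pairwise$p_adj >= res$pairwise$p_raw))
})

test_that("identical groups give lambda near 1 and no rejections", {
  set.seed(18)
  base <- matrix(rnorm(30), 10, 3)
  x <- rbind(base, base + 1e-9 * matrix(rnorm(30), 10, 3))
  g <- rep(c("a", "b"), each = 10)
  res <- manova_with_mct(x, g)
  expect_equal(res$wilks_lambda, 1, tolerance = 1e-6)
  expect_gt(res$p, 0.99)

  expect_error(manova_with_mct(matrix(rnorm(8), 4, 2), rep("a", 4)),
               class = "insufficient_class_error")
  expect_error(manova_with_mct(matrix(rnorm(12), 6, 4), rep(c("a", "b"), 3)),
               class = "insufficient_data_error")
})

test_that("configured trend slopes are recovered in sign across seeded replicates", {
  hits <- 0
  for (seed in 1:20) {
    d <- study_design(data.frame(state = "unburnt",
                                 pmi_days = c(0, 14, 34, 91, 180, 365),
                                 n_specimens = 2), seed = seed)
    elem <- oxide_to_element(simulate_empa_table(d, seed = seed,
                                                 low_total_fraction = 0))
    ic <- elem[elem$zone == "IC", ]
    fit <- regress_vs_pmi(ic$pmi_days, ic$K)
    hits <- hits + (fit$slope < 0)
  }
  expect_gte(hits / 20, 0.95)
})
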