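# PCA, ridge-logistic regression, patient scoring, ROC metrics, bootstrap.

test_that("PCA recovers rank structure and matches a covariance oracle", {
  set.seed(1)
  # rank-1 data: one component explains everything
  v <- rnorm(12)
  x1 <- outer(rnorm(10), v) + matrix(rnorm(12), 10, 12, byrow = TRUE)
  m1 <- pca_fit(x1, k = 1)
  expect_gt(m1$explained_variance[1] /
            sum(diag(stats::cov(x1))), 1 - 1e-10)

  # full reconstruction with all components
  x <- matrix(rnorm(10 * 12), 10, 12)
  mf <- pca_fit(x, k = 9) # rank of a 10x12 centred matrix
  rec <- pca_transform(mf, x) %*% mf$components +
    matrix(mf$mean_spectrum, 10, 12, byrow = TRUE)
  expect_equal(rec, x, tolerance = 1e-8)

  # scores agree with an independent eigendecomposition up to sign
  m7 <- pca_fit(x, k = 7)
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  sc_mine <- pca_transform(m7, x)
  sc_oracle <- sweep(x, 2, colMeans(x)) %*% ev$vectors[, 1:7]
  for (j in 1:7) {
    expect_equal(abs(stats::cor(sc_mine[, j], sc_oracle[, j])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(m7$explained_variance, ev$values[1:7], tolerance = 1e-8)
  # orthonormal loadings, non-increasing variance
  expect_equal(m7$components %*% t(m7$components), diag(7), tolerance = 1e-8)
  expect_true(all(diff(m7$explained_variance) <= 1e-10))
  expect_error(pca_fit(x, k = 11), "rank")
})

test_that("ridge logistic regression satisfies its optimality contract", {
  # symmetric null: balanced labels, zero features -> zero coefficients
  m0 <- logistic_fit(matrix(0, 10, 2), rep(c(0, 1), 5))
  expect_equal(m0$intercept, 0, tolerance = 1e-8)
  expect_equal(m0$weights, c(0, 0), tolerance = 1e-8)

  # converged gradient is below tolerance by contract
  set.seed(2)
  x <- matrix(rnorm(40), 20, 2)
  y <- as.numeric(x[, 1] + 0.5 * rnorm(20) > 0)
  m <- logistic_fit(x, y)
  expect_lt(m$max_gradient, 1e-8)

  # separable 2-d toy with ridge 1: matches a fine grid search
  xs <- cbind(c(-2, -1.5, -1, 1, 1.5, 2), c(-1, 0, 1, -1, 0, 1))
  ys <- c(0, 0, 0, 1, 1, 1)
  fit <- logistic_fit(xs, ys, ridge_penalty = 1)
  obj <- function(b) {
    eta <- b[1] + xs %*% b[2:3]
    sum(ys * eta - log1p(exp(eta))) - 0.5 * (b[2]^2 + b[3]^2)
  }
  g <- expand.grid(b0 = seq(-0.5, 0.5, by = 0.01),
                   w1 = seq(fit$weights[1] - 0.05, fit$weights[1] + 0.05, by = 0.001),
                   w2 = seq(-0.05, 0.05, by = 0.01))
  vals <- apply(g, 1, obj)
  best <- g[which.max(vals), ]
  expect_equal(fit$weights[1], best$w1, tolerance = 1e-3)
  expect_equal(fit$intercept, best$b0, tolerance = 1e-2)
  expect_error(logistic_fit(x, rep(1, 20)), "both classes")
})

test_that("patient scores are per-patient medians with midpoint ties", {
  expect_equal(unname(patient_scores(0.73, "A")), 0.73)
  expect_equal(unname(patient_scores(c(0.2, 0.4, 0.9), rep("A", 3))), 0.4)
  expect_equal(unname(patient_scores(c(0.2, 0.4, 0.6, 1.0), rep("A", 4))), 0.5)
  s <- patient_scores(c(0.1, 0.9, 0.5), c("A", "B", "A"))
  expect_equal(s, c(A = 0.3, B = 0.9))
})

test_that("AUROC equals the all-pairs count and is rank-invariant", {
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.1)
  lab <- c(1, 1, 1, 0, 0, 0)
  expect_equal(auroc(sc, lab), 1.0)
  expect_equal(auroc(rep(0.5, 6), lab), 0.5)
  # one inversion
  sc2 <- c(0.9, 0.8, 0.35, 0.6, 0.4, 0.1)
  expect_equal(auroc(sc2, lab), pairs_auroc(sc2, lab))
  set.seed(3)
  for (i in 1:5) {
    s3 <- runif(10); l3 <- rbinom(10, 1, 0.5)
    if (length(unique(l3)) < 2) next
    expect_equal(auroc(s3, l3), pairs_auroc(s3, l3))
    # strictly monotone transforms leave AUROC unchanged
    expect_equal(auroc(qlogis(s3 * 0.98 + 0.01), l3), auroc(s3, l3))
  }
  expect_equal(unname(sens_spec(sc, lab, 0.5)), c(1, 2 / 3)) # 0.6 called high
  expect_equal(unname(sens_spec(sc, lab, 0.65)), c(1, 1))
  expect_error(auroc(sc, rep(1, 6)), "one class")
})

test_that("bootstrap evaluation is deterministic and leak-free", {
  co <- small_sim(seed = 17, n_patients = 10, core_size = 8, effect_size = 2,
                  class_prob = 0.4)
  pp <- lapply(names(co$cubes), function(id) {
    preprocess_cube(co$cubes[[id]], co$masks[[id]], co$refs)
  })
  ds <- bind_datasets(lapply(pp, `[[`, "dataset"))
  labels <- stats::setNames(ifelse(co$cohort$true_class == 1, "high", "low"),
                            co$cohort$patient_id)
  b1 <- bootstrap_evaluate(ds, labels, B = 25, seed = 5, keep_draws = TRUE)
  b2 <- bootstrap_evaluate(ds, labels, B = 25, seed = 5)
  expect_identical(b1$per_replicate, b2$per_replicate)
  expect_identical(b1$patient_scores, b2$patient_scores)
  expect_equal(b1$median_auroc, stats::median(b1$per_replicate$auroc))
  expect_equal(unname(b1$dispersion["auroc"]),
               diff(stats::quantile(b1$per_replicate$auroc, c(.25, .75),
                                    names = FALSE)) / 2)
  # no out-of-bag datapoint ever enters the fitting rows, in any replicate
  for (d in b1$draws) {
    expect_length(intersect(d$bag, d$oob), 0)
    expect_length(intersect(d$in_rows, d$oob_rows), 0)
  }
  expect_error(bootstrap_evaluate(ds, labels, B = 5), "config error")
})

test_that("the pipeline localises a planted single-peak class effect", {
  co <- small_sim(seed = 23, n_patients = 12, core_size = 8, effect_size = 4,
                  class_prob = 0.5)
  pp <- lapply(names(co$cubes), function(id) {
    preprocess_cube(co$cubes[[id]], co$masks[[id]], co$refs)
  })
  ds <- bind_datasets(lapply(pp, `[[`, "dataset"))
  labels <- stats::setNames(ifelse(co$cohort$true_class == 1, "high", "low"),
                            co$cohort$patient_id)
  pca <- pca_fit(ds$matrix, k = 7)
  model <- logistic_fit(pca_transform(pca, ds$matrix),
                        labels[ds$meta$patient_id] == "high")
  top <- which.max(abs(model$weights))
  loading <- pca$components[top, ]
  peak_wn <- ds$axis[which.max(abs(loading))]
  expect_lte(abs(peak_wn - 1240), 2 * 6) # within two axis steps
})
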