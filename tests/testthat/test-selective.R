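test_that("naive p-value matches the closed-form two-sided Z-test", {
  expect_equal(naive_p(0, 1), 1)
  expect_equal(naive_p(1.959964, 1), 0.05, tolerance = 1e-6)
  expect_equal(naive_p(-3, 2), 2 * pnorm(1.5, lower.tail = FALSE))
  withr::with_seed(81, {
    for (rep in 1:100) {
      z <- rnorm(1, sd = 2)
      sd <- runif(1, 0.5, 3)
      expect_equal(naive_p(z, sd),
                   selective_p(z, sd, interval_union(-Inf, Inf)),
                   tolerance = 1e-12)
    }
  })
})

test_that("test_feature assembles a coherent selective test result", {
  d <- make_fig2_data(seed = 7)
  fit <- fit_clusters(d$x, "average", k = 3)
  res <- test_feature(d$x, fit, feature = 1, pair = c(1, 2), sigma = d$sigma)
  expect_s3_class(res, "postclust_test")
  expect_true(res$p_selective >= 0 && res$p_selective <= 1)
  expect_true(res$p_naive >= 0 && res$p_naive <= 1)
  expect_true(interval_contains(res$truncation, res$stat,
                                scale = 1 + abs(res$stat)))
  expect_equal(res$null_sd, sqrt(d$sigma[1, 1] * (1 / 10 + 1 / 10)))

  td <- generics::tidy(res)
  expect_equal(nrow(td), 1L)
  expect_named(td, c("cluster_a", "cluster_b", "feature", "stat", "null_sd",
                     "p_naive", "p_selective", "n_intervals",
                     "truncation_intervals"))
  gl <- generics::glance(res)
  expect_equal(gl$n, 30L)
  expect_error(test_feature(d$x, fit, feature = 1, pair = c(1, 7),
                            sigma = d$sigma), "pair")
})

test_that("far-separated clusters show almost no selection effect", {
  withr::with_seed(82, {
    x <- cbind(c(rnorm(10, 0, 0.1), rnorm(10, 50, 0.1)), rnorm(20, 0, 0.1))
  })
  fit <- fit_clusters(x, "single", k = 2)
  res <- test_feature(x, fit, feature = 1, pair = c(1, 2), sigma = diag(2))
  expect_lt(res$p_selective, 1e-6)
  expect_equal(res$p_selective, res$p_naive, tolerance = 1e-4)
})

test_that("enlarging the truncation set moves the selective p toward the naive p", {
  withr::with_seed(83, {
    for (rep in 1:10) {
      z <- rnorm(1, sd = 2)
      sd <- runif(1, 0.5, 2)
      S1 <- interval_union(c(abs(z) - 0.3, -abs(z) - 1), c(abs(z) + 2, -abs(z)))
      S2 <- interval_union_all(list(S1, interval_union(-8 * sd, 8 * sd)))
      pn <- naive_p(z, sd)
      p1 <- selective_p(z, sd, S1)
      p2 <- selective_p(z, sd, S2)
      expect_lte(abs(p2 - pn), abs(p1 - pn) + 1e-12)
    }
  })
})

test_that("test_all_features returns one adjusted row per pair and feature", {
  d <- make_fig2_data(seed = 8)
  fit <- fit_clusters(d$x, "ward", k = 3)
  tbl <- test_all_features(d$x, fit, sigma = d$sigma)
  expect_equal(nrow(tbl), 3L * 2L)  # 3 pairs x 2 features
  expect_true(all(tbl$p_selective_bh >= tbl$p_selective - 1e-12))
  expect_equal(tbl$p_selective_bh, bh_adjust(tbl$p_selective))
  sub <- test_all_features(d$x, fit, sigma = d$sigma, features = 2,
                           pairs = rbind(c(1, 3)))
  expect_equal(nrow(sub), 1L)
  expect_equal(sub$feature, 2L)
})

test_that("benjamini-hochberg adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)))
})

test_that("covariance estimators behave on degenerate and clustered input", {
  x_same <- matrix(1, 10, 3)
  s <- estimate_sigma(x_same, "sample")
  expect_lt(max(abs(s - diag(diag(s)))), 1e-12)  # ridge-only off-diagonal
  expect_gt(min(eigen(s, symmetric = TRUE)$values), 0)

  withr::with_seed(84, x <- matrix(rnorm(60), 20, 3))
  one <- estimate_sigma(x, "residual", labels = rep(1, 20))
  expect_equal(one, estimate_sigma(x, "sample") * 19 / 19, tolerance = 1e-10)

  expect_error(estimate_sigma(x, "residual"), "labels")
  expect_error(estimate_sigma(x[1:2, ], "residual", labels = 1:2), "too few")
})

test_that("residual covariance is consistent under the equicorrelated model", {
  n <- 2000
  q <- 5
  sigma <- equicorr_sigma(q, 0.4)
  withr::with_seed(85, {
    truth <- rep(1:2, each = n / 2)
    mu <- matrix(0, n, q)
    mu[truth == 2, 1] <- 10
    x <- mu + matrix(rnorm(n * q), n, q) %*% chol(sigma)
  })
  est <- estimate_sigma(x, "residual", labels = truth)
  expect_lt(max(abs(est - sigma)), 0.1)
})

test_that("selective p-values on null features are uniform after k-means at K = 2", {
  # two-group design with signal in the outer features only; features 2..q-1
  # are global nulls for any estimated pair
  M <- 120
  alpha <- 0.05
  withr::with_seed(86, km_seeds <- sample.int(1e6, M))
  ps <- pn <- numeric(M)
  withr::with_seed(87, {
    for (m in seq_len(M)) {
      d <- simulate_design(150, 10, rho = 0.4, design = "fig1")
      fit <- fit_clusters(d$x, "kmeans", k = 2, seed = km_seeds[m])
      j <- sample(2:9, 1)
      res <- test_feature(d$x, fit, feature = j, pair = c(1, 2),
                          sigma = d$sigma)
      ps[m] <- res$p_selective
      pn[m] <- res$p_naive
    }
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # naive p-values are stochastically smaller than uniform
  expect_lt(stats::ks.test(pn, "punif", alternative = "greater")$p.value, 0.01)
})
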