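test_that("contrast vector encodes the difference in group means", {
  ct <- contrast_vector(4, test_spec(c(1, 2), 3, j = 1, n = 4, q = 2))
  expect_equal(ct$nu, c(1 / 2, 1 / 2, -1, 0))
  expect_equal(ct$nu_sq_norm, 3 / 2)

  ct <- contrast_vector(2, test_spec(1, 2, j = 1, n = 2, q = 1))
  expect_equal(ct$nu, c(1, -1))
  expect_equal(ct$nu_sq_norm, 2)

  ct <- contrast_vector(150, test_spec(1:75, 76:150, j = 1, n = 150, q = 3))
  expect_equal(ct$nu_sq_norm, 2 / 75)
  expect_equal(ct$nu_sq_norm, sum(ct$nu^2))
  expect_equal(sum(ct$nu), 0)
})

test_that("invalid test specs are rejected", {
  expect_error(test_spec(integer(), 1, 1, 4, 2), "non-empty")
  expect_error(test_spec(c(1, 2), c(2, 3), 1, 4, 2), "disjoint")
  expect_error(test_spec(1, 5, 1, 4, 2), "1..n")
  expect_error(test_spec(1, 2, 3, 4, 2), "1..q")
})

test_that("test statistic equals the brute-force group mean difference", {
  x <- matrix(c(1, 1, 0, 0), 4, 1)
  spec <- test_spec(c(1, 2), c(3, 4), 1, 4, 1)
  expect_equal(test_statistic(x, contrast_vector(4, spec), 1), 1)

  xc <- matrix(5, 6, 2)
  spec <- test_spec(1:2, 5:6, 2, 6, 2)
  expect_equal(test_statistic(xc, contrast_vector(6, spec), 2), 0)

  withr::with_seed(11, {
    x <- matrix(rnorm(30), 10, 3)
    spec <- test_spec(c(1, 4, 7), c(2, 8), 3, 10, 3)
    ct <- contrast_vector(10, spec)
    expect_equal(test_statistic(x, ct, 3),
                 mean(x[c(1, 4, 7), 3]) - mean(x[c(2, 8), 3]))
  })
})

test_that("perturbation line satisfies its four contract properties", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- sample(6:15, 1)
      q <- sample(2:5, 1)
      x <- matrix(rnorm(n * q), n, q)
      A <- matrix(rnorm(q * q), q)
      sigma <- crossprod(A) + diag(q)
      g <- sample(n, 3)
      gp <- setdiff(sample(n, 6), g)[1:2]
      j <- sample(q, 1)
      spec <- test_spec(g, gp, j, n, q)
      line <- perturbation_line(x, sigma, spec)
      ct <- line$contrast

      # (b) identity at phi_obs
      expect_equal(perturb_data(x, line, line$phi_obs), x, tolerance = 1e-12)

      phi <- line$phi_obs + rnorm(1, sd = 3)
      xp <- perturb_data(x, line, phi)
      # (a) the statistic moves exactly to phi
      expect_equal(test_statistic(xp, ct, j), phi, tolerance = 1e-10)
      # (c) rows outside the tested groups do not move
      still <- which(ct$nu == 0)
      expect_equal(xp[still, ], x[still, ], tolerance = 1e-12)
      # (d) other features co-move with slope sigma_jj' / sigma_jj
      for (jp in seq_len(q)) {
        expect_equal(test_statistic(xp, ct, jp),
                     test_statistic(x, ct, jp) +
                       (phi - line$phi_obs) * sigma[j, jp] / sigma[j, j],
                     tolerance = 1e-10)
      }
    }
  })
})

test_that("diagonal covariance perturbs only the tested feature's column", {
  withr::with_seed(5, {
    x <- matrix(rnorm(24), 8, 3)
    spec <- test_spec(1:3, 4:6, 2, 8, 3)
    line <- perturbation_line(x, diag(c(2, 1, 0.5)), spec)
    xp <- perturb_data(x, line, line$phi_obs + 4)
    expect_equal(xp[, c(1, 3)], x[, c(1, 3)])
    expect_false(isTRUE(all.equal(xp[, 2], x[, 2])))
  })
})

test_that("co-movement slope of a correlated feature is sigma_12 / sigma_11", {
  sigma <- matrix(c(0.2, 0.08, 0.08, 0.2), 2)
  withr::with_seed(3, x <- matrix(rnorm(20), 10, 2))
  spec <- test_spec(1:5, 6:10, 1, 10, 2)
  line <- perturbation_line(x, sigma, spec)
  ct <- line$contrast
  s2 <- function(phi) test_statistic(perturb_data(x, line, phi), ct, 2)
  slope <- (s2(3) - s2(-2)) / 5
  expect_equal(slope, 0.4, tolerance = 1e-12)
})

test_that("the part of the data orthogonal to the statistic is constant in phi", {
  withr::with_seed(8, {
    x <- matrix(rnorm(40), 10, 4)
    A <- matrix(rnorm(16), 4)
    sigma <- crossprod(A) + diag(4)
    spec <- test_spec(1:4, 5:7, 2, 10, 4)
    line <- perturbation_line(x, sigma, spec)
    ct <- line$contrast
    recon <- function(xm) {
      stat <- test_statistic(xm, ct, 2)
      xm - stat * (ct$nu / ct$nu_sq_norm) %*% t(line$direction)
    }
    u0 <- recon(x)
    for (phi in c(-7, 0, 2.5, 11)) {
      expect_equal(recon(perturb_data(x, line, phi)), u0, tolerance = 1e-10)
    }
  })
})

test_that("statistic and its orthogonal complement are uncorrelated under the model", {
  n <- 8; q <- 3
  sigma <- equicorr_sigma(q, 0.5)
  spec <- test_spec(1:3, 4:6, 2, n, q)
  ct <- contrast_vector(n, spec)
  ch <- chol(sigma)
  withr::with_seed(99, {
    nrep <- 2000
    stats_j <- numeric(nrep)
    u_entries <- matrix(0, nrep, n * q)
    for (r in seq_len(nrep)) {
      x <- matrix(rnorm(n * q), n, q) %*% ch
      stat <- test_statistic(x, ct, 2)
      u <- x - stat * (ct$nu / ct$nu_sq_norm) %*% t(sigma[, 2] / sigma[2, 2])
      stats_j[r] <- stat
      u_entries[r, ] <- as.vector(u)
    }
    cors <- suppressWarnings(cor(stats_j, u_entries))
    expect_lt(max(abs(cors), na.rm = TRUE), 0.08)
  })
})

test_that("covariance validation rejects asymmetric or indefinite matrices", {
  expect_error(gaussian_model(matrix(0, 3, 2), matrix(c(1, 0.5, 0.2, 1), 2)),
               "symmetric")
  expect_error(gaussian_model(matrix(0, 3, 2), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
  expect_error(gaussian_model(matrix(0, 3, 3), diag(2)), "dimension")
  m <- gaussian_model(matrix(0, 3, 2), diag(2))
  expect_s3_class(m, "gaussian_model")
})
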