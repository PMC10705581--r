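test_that("K = n puts every observation in its own cluster in one sweep", {
  withr::with_seed(71, x <- matrix(rnorm(12), 6, 2))
  tr <- kmeans_trace(x, 6, seed = 1)
  expect_equal(tr$T, 1L)
  expect_equal(sort(tr$labels), 1:6)
})

test_that("two far blobs are recovered in at most two iterations from any seed", {
  withr::with_seed(72, {
    x <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, mean = 50), 10, 2))
  })
  for (s in 1:10) {
    tr <- kmeans_trace(x, 2, seed = s)
    expect_lte(tr$T, 2L)
    expect_true(same_partition(tr$labels, rep(1:2, each = 10)))
  }
})

test_that("trace invariants hold: convergence row and non-empty clusters", {
  withr::with_seed(73, {
    for (rep in 1:5) {
      x <- matrix(rnorm(40 * 4), 40, 4)
      tr <- kmeans_trace(x, 3, seed = rep)
      expect_equal(tr$assignments[tr$T + 1, ], tr$assignments[tr$T, ])
      expect_equal(tr$labels, tr$assignments[tr$T + 1, ])
      for (t in seq_len(tr$T + 1)) {
        expect_equal(sort(unique(tr$assignments[t, ])), 1:3)
      }
      # deterministic given (x, K, seed)
      tr2 <- kmeans_trace(x, 3, seed = rep)
      expect_identical(tr$assignments, tr2$assignments)
    }
  })
})

test_that("well-separated three-group structure is usually recovered exactly", {
  # strong signal: the detection regime where conditional power is evaluated
  hits <- 0
  for (s in 1:30) {
    d <- simulate_design(150, 10, rho = 0.8, delta = 8, design = "power3",
                         seed = 2000 + s)
    tr <- tryCatch(kmeans_trace(d$x, 3, seed = s), error = function(e) NULL)
    if (!is.null(tr) && same_partition(tr$labels, d$truth)) hits <- hits + 1
  }
  expect_gte(hits, 15)
})

test_that("kmeans truncation set matches the grid oracle", {
  d <- make_fig2_data(seed = 6)
  tr <- kmeans_trace(d$x, 3, seed = 4)
  labs <- sort(unique(tr$labels))
  spec <- test_spec(which(tr$labels == labs[1]), which(tr$labels == labs[2]),
                    1, 30, 2)
  line <- perturbation_line(d$x, d$sigma, spec)
  S <- kmeans_truncation_set(d$x, tr, line)
  expect_true(interval_contains(S, line$phi_obs, scale = 1 + abs(line$phi_obs)))
  grid <- seq(line$phi_obs - 10, line$phi_obs + 10, length.out = 401)
  ok <- interval_boundary_dist(S, grid) > 1e-6
  oracle <- vapply(grid, function(p) {
    recluster_same(d$x, line, p, "kmeans", 3, seed = 4, trace = tr)
  }, logical(1))
  expect_equal(interval_contains(S, grid, scale = 1 + abs(line$phi_obs))[ok],
               oracle[ok])
})

test_that("iterate conditioning is at least as strict as final-partition conditioning", {
  withr::with_seed(74, {
    x <- rbind(matrix(rnorm(24), 12, 2), matrix(rnorm(24, 4), 12, 2))
  })
  tr <- kmeans_trace(x, 2, seed = 9)
  spec <- test_spec(which(tr$labels == 1), which(tr$labels == 2), 2, 24, 2)
  line <- perturbation_line(x, equicorr_sigma(2, 0.3), spec)
  S <- kmeans_truncation_set(x, tr, line)
  grid <- seq(line$phi_obs - 12, line$phi_obs + 12, length.out = 301)
  inS <- interval_contains(S, grid, scale = 1 + abs(line$phi_obs))
  final_same <- vapply(grid, function(p) {
    tr2 <- tryCatch(kmeans_trace(perturb_data(x, line, p), 2, seed = 9),
                    error = function(e) NULL)
    !is.null(tr2) && same_partition(tr2$labels, tr$labels)
  }, logical(1))
  ok <- interval_boundary_dist(S, grid) > 1e-6
  # membership implies the final partition is preserved; not conversely
  expect_true(all(!inS[ok] | final_same[ok]))
})

test_that("boundary region of the truncation set flips boundary points", {
  # K = 2 blobs: pushing the tested mean difference toward zero must exit
  # the conditioning set before the blobs overlap completely
  withr::with_seed(75, {
    x <- matrix(rnorm(24, sd = 0.4), 12, 2)
    x[7:12, 1] <- x[7:12, 1] + 8  # groups differ in the tested feature only
  })
  tr <- kmeans_trace(x, 2, seed = 3)
  spec <- test_spec(which(tr$labels == 1), which(tr$labels == 2), 1, 12, 2)
  line <- perturbation_line(x, diag(2), spec)
  S <- kmeans_truncation_set(x, tr, line)
  expect_false(interval_contains(S, 0))
})

test_that("runtime grows roughly linearly in K at fixed n and q", {
  withr::with_seed(76, x <- matrix(rnorm(120 * 5), 120, 5))
  counts <- vapply(c(2, 4, 8), function(K) {
    tr <- kmeans_trace(x, K, seed = 2)
    labs <- sort(unique(tr$labels))
    spec <- test_spec(which(tr$labels == labs[1]),
                      which(tr$labels == labs[2]), 1, 120, 5)
    line <- perturbation_line(x, diag(5), spec)
    S <- kmeans_truncation_set(x, tr, line)
    attr(S, "n_constraints") / (tr$T + 1)  # inequalities per iteration
  }, numeric(1))
  # n * (K - 1) inequalities per recorded iteration
  expect_equal(counts, 120 * (c(2, 4, 8) - 1))
})
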