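# Three well-separated planar groups of 10 with correlated features;
# small enough that grid oracles over 401 perturbations stay fast.
make_fig2_data <- function(seed = 1) {
  mu <- rbind(matrix(rep(c(0, 2.5), each = 10), 10),
              matrix(rep(c(2.5, 0), each = 10), 10),
              matrix(rep(c(-2.5, -2.5), each = 10), 10))
  sigma <- 0.2 * matrix(c(1, 0.4, 0.4, 1), 2)
  x <- withr::with_seed(seed, mu + matrix(rnorm(60), 30, 2) %*% chol(sigma))
  list(x = x, sigma = sigma, truth = rep(1:3, each = 10))
}

# random interval union with k intervals inside [-10, 10]
rand_iu <- function(k) {
  pts <- sort(stats::runif(2 * k, -10, 10))
  interval_union(pts[seq(1, 2 * k, 2)], pts[seq(2, 2 * k, 2)])
}

# reference pairwise intersection by direct interval clipping (O(n*m))
pair_intersect <- function(a, b) {
  lo <- numeric(0)
  hi <- numeric(0)
  if (nrow(a) == 0L || nrow(b) == 0L) return(interval_union(numeric(), numeric()))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      l <- max(a[i, 1], b[j, 1])
      h <- min(a[i, 2], b[j, 2])
      if (l <= h) {
        lo <- c(lo, l)
        hi <- c(hi, h)
      }
    }
  }
  interval_union(lo, hi)
}

# high-precision quadrature of normal mass over a set of intervals
quad_mass <- function(lo, hi, mean = 0, sd = 1) {
  tot <- 0
  for (i in seq_along(lo)) {
    l <- max(lo[i], mean - 40 * sd)
    h <- min(hi[i], mean + 40 * sd)
    if (l < h) {
      tot <- tot + stats::integrate(function(t) stats::dnorm(t, mean, sd),
                                    l, h, rel.tol = 1e-13, abs.tol = 0)$value
    }
  }
  tot
}

# brute-force membership of phi in the truncation set by re-clustering
recluster_same <- function(x, line, phi, method, K, seed = NULL, trace = NULL) {
  xp <- perturb_data(x, line, phi)
  if (method == "kmeans") {
    tr2 <- tryCatch(kmeans_trace(xp, K, seed = seed), error = function(e) NULL)
    !is.null(tr2) && identical(tr2$assignments, trace$assignments)
  } else {
    same_partition(hclust_trace(xp, method, K = K)$labels, trace$labels)
  }
}
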