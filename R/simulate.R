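#' Equicorrelated feature covariance
#'
#' `sigma[i, j] = 1` on the diagonal and `rho` off it; positive definite
#' for `rho` in `[0, 1)`.
#' @param q Number of features.
#' @param rho Common correlation.
#' @return A q x q matrix.
#' @export
equicorr_sigma <- function(q, rho = 0) {
  stopifnot(rho >= 0, rho < 1)
  (1 - rho) * diag(q) + rho * matrix(1, q, q)
}

#' Draw a synthetic observations-by-features matrix with planted groups
#'
#' Rows are independent q-variate Gaussians with equicorrelated covariance
#' and one of three mean patterns used throughout the validation
#' experiments:
#' \describe{
#'   \item{`"fig1"`}{two true groups differing in the first and last
#'     features only: rows 1..50 have mean 1 in feature 1, the remaining
#'     rows mean 1 in feature q. All in-between features satisfy the null
#'     for every pair of groups.}
#'   \item{`"null3"`}{the same mean pattern as `"fig1"`; named separately
#'     because it is clustered into K = 3 groups so that any tested pair
#'     and any feature 2..q-1 is a true null.}
#'   \item{`"power3"`}{three equal groups of 50: the first has mean
#'     `-delta` on the last `ceiling(q/2)` features, the second mean 0,
#'     the third `+delta` on the same features.}
#' }
#'
#' @param n Number of rows (`"power3"` requires `n = 150`; the split for
#'   `"fig1"`/`"null3"` is rows 1..50 versus the rest).
#' @param q Number of features.
#' @param rho Equicorrelation of the features.
#' @param delta Signal size (only used by `"power3"`).
#' @param design One of `"fig1"`, `"null3"`, `"power3"`.
#' @param seed Optional integer; when given, the draw is made in a local
#'   RNG scope so the caller's stream is untouched.
#' @return A list with `x` (n x q matrix), `truth` (integer vector of true
#'   group labels), `mu`, and `sigma`.
#' @export
simulate_design <- function(n = 150L, q = 10L, rho = 0, delta = 0,
                            design = c("fig1", "null3", "power3"),
                            seed = NULL) {
  design <- match.arg(design)
  stopifnot(q >= 2L)
  sigma <- equicorr_sigma(q, rho)
  mu <- matrix(0, n, q)
  if (design %in% c("fig1", "null3")) {
    stopifnot(n > 50L)
    truth <- c(rep(1L, 50L), rep(2L, n - 50L))
    mu[truth == 1L, 1L] <- 1
    mu[truth == 2L, q] <- 1
  } else {
    stopifnot(n == 150L)
    truth <- rep(1:3, each = 50L)
    sig_cols <- (floor(q / 2) + 1L):q
    mu[truth == 1L, sig_cols] <- -delta
    mu[truth == 3L, sig_cols] <- delta
  }
  draw <- function() {
    z <- matrix(stats::rnorm(n * q), n, q)
    mu + z %*% chol(sigma)
  }
  x <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  list(x = x, truth = truth, mu = mu, sigma = sigma)
}

run_one_test <- function(x, method, k, km_seed, pair_idx, feature, sigma,
                         max_reseed = 20L) {
  # k-means occasionally empties a cluster under an unlucky init; re-seed
  # and count, as the experiment protocol prescribes
  reseeds <- 0L
  repeat {
    fit <- tryCatch(
      fit_clusters(x, method, k = k, seed = km_seed + reseeds),
      error = function(e) e
    )
    if (!inherits(fit, "error")) break
    reseeds <- reseeds + 1L
    if (reseeds > max_reseed) stop(fit)
  }
  pairs <- t(utils::combn(sort(unique(fit$labels)), 2L))
  pair <- pairs[1L + (pair_idx - 1L) %% nrow(pairs), ]
  res <- test_feature(x, fit, feature = feature, pair = pair, sigma = sigma)
  list(res = res, fit = fit, reseeds = reseeds)
}

#' Type I error experiment under a global null for the tested features
#'
#' Generates `M` data sets from the `"null3"` design, clusters each into
#' `k` clusters with every requested method, tests a randomly chosen
#' cluster pair and a randomly chosen feature in `2..q-1` (all true
#' nulls), and records the naive and selective p-values. Selection
#' randomness (pair, feature, k-means seeds) is drawn from a stream seeded
#' with `seed + 1`, independent of the data stream seeded with `seed`, so
#' the two can be varied separately.
#'
#' @param methods Character vector of clustering methods (see
#'   [fit_clusters()]).
#' @param n,q,rho Data dimensions and feature equicorrelation.
#' @param M Number of replicates.
#' @param k Number of estimated clusters.
#' @param alpha Nominal level used in the returned rejection-rate summary.
#' @param seed Integer base seed.
#' @return A list of class `type1_experiment`: `replicates` (tibble, one
#'   row per replicate x method), `summary` (rejection rates at `alpha`),
#'   and the configuration. The number of re-seeded k-means runs is
#'   recorded in column `reseeds`.
#' @export
type1_experiment <- function(methods = c("kmeans", "single", "average", "centroid"),
                             n = 150L, q = 10L, rho = 0, M = 500L, k = 3L,
                             alpha = 0.05, seed = 1L) {
  sel <- withr::with_seed(seed + 1L, list(
    pair_idx = sample.int(choose(k, 2L), M, replace = TRUE),
    feature = sample(2:(q - 1L), M, replace = TRUE),
    km_seed = sample.int(.Machine$integer.max - 30L, M)
  ))
  sigma <- equicorr_sigma(q, rho)
  rows <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(M), function(m) {
      dat <- simulate_design(n, q, rho, design = "null3")
      purrr::map_dfr(methods, function(me) {
        out <- run_one_test(dat$x, me, k, sel$km_seed[m], sel$pair_idx[m],
                            sel$feature[m], sigma)
        tibble::tibble(replicate = m, method = me,
                       feature = sel$feature[m],
                       stat = out$res$stat,
                       p_naive = out$res$p_naive,
                       p_selective = out$res$p_selective,
                       n_intervals = nrow(out$res$truncation),
                       reseeds = out$reseeds)
      })
    })
  })
  summary <- rows |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      M = dplyr::n(),
      reject_selective = mean(.data$p_selective <= alpha),
      reject_naive = mean(.data$p_naive <= alpha),
      reseeds = sum(.data$reseeds),
      .groups = "drop")
  structure(list(replicates = rows, summary = summary,
                 config = list(n = n, q = q, rho = rho, M = M, k = k,
                               alpha = alpha, seed = seed)),
            class = "type1_experiment")
}

#' @export
print.type1_experiment <- function(x, ...) {
  cat(sprintf("Type I error experiment: n=%d q=%d rho=%.2f M=%d alpha=%.2f\n",
              x$config$n, x$config$q, x$config$rho, x$config$M, x$config$alpha))
  print(x$summary)
  invisible(x)
}

#' Conditional power and detection probability experiment
#'
#' Generates `M` data sets from the `"power3"` design (three true groups
#' separated by `delta` on half the features), clusters each into three
#' clusters, tests a random cluster pair and a random *signal* feature
#' (one of the last `ceiling(q/2)` features, where the tested null is
#' false whenever the estimated clusters are true groups), and summarises
#' two quantities per method: the *detection probability* -- how often both
#' tested estimated clusters coincide exactly with true groups -- and the
#' *conditional power* -- the rejection rate at `alpha` among those
#' replicates (set to 0 when no replicate detects the true groups).
#' Power is evaluated on signal features only so that it measures the
#' test's ability to reject a false null, not the share of features
#' carrying signal.
#'
#' @inheritParams type1_experiment
#' @param delta Mean separation of the outer groups.
#' @return A list of class `power_experiment` with `replicates` and
#'   `summary` tibbles.
#' @export
power_experiment <- function(methods = c("kmeans", "single", "average", "centroid"),
                             q = 10L, rho = 0, delta = 4, M = 300L,
                             alpha = 0.05, seed = 1L) {
  n <- 150L
  k <- 3L
  signal_features <- (floor(q / 2) + 1L):q
  sel <- withr::with_seed(seed + 1L, list(
    pair_idx = sample.int(choose(k, 2L), M, replace = TRUE),
    feature = sample(signal_features, M, replace = TRUE),
    km_seed = sample.int(.Machine$integer.max - 30L, M)
  ))
  sigma <- equicorr_sigma(q, rho)
  rows <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(M), function(m) {
      dat <- simulate_design(n, q, rho, delta, design = "power3")
      true_sets <- split(seq_len(n), dat$truth)
      purrr::map_dfr(methods, function(me) {
        out <- run_one_test(dat$x, me, k, sel$km_seed[m], sel$pair_idx[m],
                            sel$feature[m], sigma)
        est_a <- which(out$fit$labels == out$res$pair[1L])
        est_b <- which(out$fit$labels == out$res$pair[2L])
        detected <- any(vapply(true_sets, identical, logical(1L), est_a)) &&
          any(vapply(true_sets, identical, logical(1L), est_b))
        tibble::tibble(replicate = m, method = me,
                       feature = sel$feature[m],
                       p_selective = out$res$p_selective,
                       detected = detected,
                       reseeds = out$reseeds)
      })
    })
  })
  summary <- rows |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      M = dplyr::n(),
      detection_prob = mean(.data$detected),
      cond_power = ifelse(any(.data$detected),
                          mean(.data$p_selective[.data$detected] <= alpha), 0),
      reseeds = sum(.data$reseeds),
      .groups = "drop") |>
    dplyr::mutate(delta = delta, rho = rho, .before = 1L)
  structure(list(replicates = rows, summary = summary,
                 config = list(q = q, rho = rho, delta = delta, M = M,
                               alpha = alpha, seed = seed)),
            class = "power_experiment")
}

#' @export
print.power_experiment <- function(x, ...) {
  cat(sprintf("Power experiment: delta=%.1f rho=%.2f M=%d alpha=%.2f\n",
              x$config$delta, x$config$rho, x$config$M, x$config$alpha))
  print(x$summary)
  invisible(x)
}
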