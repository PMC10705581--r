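#' Cluster observations, keeping the trace the selective test conditions on
#'
#' Thin wrapper choosing between [hclust_trace()] (hierarchical, squared
#' Euclidean distances) and [kmeans_trace()] (Lloyd's algorithm). The
#' returned object carries everything needed to build conditioning sets:
#' the merge sequence and heights for hierarchical clustering, or the full
#' per-iteration assignment history for k-means.
#'
#' @param data n x q matrix or data frame of observations by features.
#' @param method `"kmeans"` or a hierarchical linkage: `"single"`,
#'   `"average"`, `"centroid"`, `"ward"`.
#' @param k Number of clusters.
#' @param seed Integer seed for the k-means initialisation (ignored for
#'   hierarchical methods, which are deterministic).
#' @param max_iter Lloyd iteration cap (k-means only).
#' @return A list of class `postclust_fit` with elements `method`, `k`,
#'   `seed`, `trace` and `labels` (integer cluster assignments 1..k).
#' @examples
#' x <- rbind(matrix(rnorm(20), 10), matrix(rnorm(20, 5), 10))
#' fit <- fit_clusters(x, "average", k = 2)
#' table(fit$labels)
#' @export
fit_clusters <- function(data,
                         method = c("kmeans", "single", "average", "centroid", "ward"),
                         k = 2L, seed = 1L, max_iter = 100L) {
  method <- match.arg(method)
  x <- as.matrix(data)
  trace <- if (method == "kmeans") {
    kmeans_trace(x, K = k, seed = seed, max_iter = max_iter)
  } else {
    hclust_trace(x, linkage = method, K = k)
  }
  structure(list(method = method, k = as.integer(k), seed = seed,
                 trace = trace, labels = trace$labels),
            class = "postclust_fit")
}

#' @export
print.postclust_fit <- function(x, ...) {
  cat("<postclust_fit>", x$method, "clustering,", x$k, "clusters\n")
  print(table(cluster = x$labels))
  invisible(x)
}

#' Naive two-sample Z p-value
#'
#' The classical two-sided p-value that treats the two clusters as
#' pre-specified groups. Anti-conservative when the groups were estimated
#' from the same data; provided as the baseline the selective p-value is
#' compared against.
#'
#' @param stat Observed difference in feature means.
#' @param null_sd Null standard deviation `sqrt(sigma_jj * ||nu||^2)`.
#' @return `2 * (1 - Phi(|stat| / null_sd))`.
#' @export
naive_p <- function(stat, null_sd) {
  stopifnot(null_sd > 0)
  2 * stats::pnorm(abs(stat) / null_sd, lower.tail = FALSE)
}

#' Selective test for a difference in one feature's means between clusters
#'
#' Tests whether the population mean of feature `feature` differs between
#' two estimated clusters, conditioning on the clustering event so that the
#' selective type I error rate is controlled at the nominal level when
#' `sigma` is the true feature covariance. For hierarchical clustering the
#' conditioning event is "the K-cluster partition is unchanged"; for
#' k-means it is "every intermediate Lloyd assignment is unchanged".
#'
#' @param data The matrix that was clustered.
#' @param fit A [fit_clusters()] object (or a [kmeans_trace()] /
#'   [hclust_trace()]).
#' @param feature Feature index to test.
#' @param pair Length-2 vector of cluster labels to compare.
#' @param sigma q x q feature covariance; the known covariance of the
#'   model, or a plug-in estimate from [estimate_sigma()] (in which case
#'   finite-sample error control is approximate).
#' @return An object of class `postclust_test` with the statistic, its
#'   null standard deviation, the truncation set, and the naive and
#'   selective p-values. Use [generics::tidy()] for a one-row tibble.
#' @export
test_feature <- function(data, fit, feature, pair = c(1L, 2L), sigma) {
  x <- as.matrix(data)
  trace <- if (inherits(fit, "postclust_fit")) fit$trace else fit
  labels <- trace$labels
  pair <- as.integer(pair)
  if (length(pair) != 2L || anyDuplicated(pair) ||
      !all(pair %in% unique(labels))) {
    stop("`pair` must name two distinct clusters present in the fit",
         call. = FALSE)
  }
  spec <- test_spec(which(labels == pair[1L]), which(labels == pair[2L]),
                    j = feature, n = nrow(x), q = ncol(x))
  line <- perturbation_line(x, sigma, spec)
  truncation <- if (inherits(trace, "kmeans_trace")) {
    kmeans_truncation_set(x, trace, line)
  } else {
    hier_truncation_set(x, trace, line)
  }
  stat <- line$phi_obs
  null_sd <- sqrt(sigma[feature, feature] * line$contrast$nu_sq_norm)
  structure(list(
    spec = spec,
    pair = pair,
    feature = as.integer(feature),
    stat = stat,
    null_sd = null_sd,
    truncation = truncation,
    p_naive = naive_p(stat, null_sd),
    p_selective = selective_p(stat, null_sd, truncation),
    method = if (inherits(trace, "kmeans_trace")) "kmeans" else trace$linkage,
    k = if (inherits(trace, "kmeans_trace")) trace$K else trace$K
  ), class = "postclust_test")
}

#' @export
print.postclust_test <- function(x, ...) {
  cat("Selective test for a difference in feature means after clustering\n")
  cat(sprintf("  method: %s (K = %d); clusters %d vs %d; feature %d\n",
              x$method, x$k, x$pair[1L], x$pair[2L], x$feature))
  cat(sprintf("  statistic: %.4f  (null sd %.4f)\n", x$stat, x$null_sd))
  cat(sprintf("  truncation set: %d interval(s)\n", nrow(x$truncation)))
  cat(sprintf("  p_naive = %.4g   p_selective = %.4g\n",
              x$p_naive, x$p_selective))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.postclust_test <- function(x, ...) {
  tibble::tibble(
    cluster_a = x$pair[1L], cluster_b = x$pair[2L], feature = x$feature,
    stat = x$stat, null_sd = x$null_sd,
    p_naive = x$p_naive, p_selective = x$p_selective,
    n_intervals = nrow(x$truncation),
    truncation_intervals = format(x$truncation)
  )
}

#' @export
glance.postclust_test <- function(x, ...) {
  tibble::tibble(method = x$method, k = x$k,
                 n = x$spec$n, q = x$spec$q,
                 n_intervals = nrow(x$truncation))
}

#' Test many (cluster pair, feature) combinations
#'
#' Runs [test_feature()] for every requested pair and feature and stacks
#' the tidied results, adding a Benjamini-Hochberg adjusted selective
#' p-value across all returned rows. Each feature's truncation set is
#' computed independently, because the perturbation direction
#' `sigma[, j] / sigma[j, j]` differs per feature.
#'
#' @inheritParams test_feature
#' @param features Integer vector of features to test (default: all).
#' @param pairs Two-column matrix of cluster-label pairs, or `NULL` for
#'   all unordered pairs.
#' @return A tibble, one row per (pair, feature), with columns
#'   `cluster_a`, `cluster_b`, `feature`, `stat`, `null_sd`, `p_naive`,
#'   `p_selective`, `p_selective_bh`, `n_intervals`,
#'   `truncation_intervals`.
#' @export
test_all_features <- function(data, fit, sigma, features = NULL, pairs = NULL) {
  x <- as.matrix(data)
  if (is.null(features)) features <- seq_len(ncol(x))
  labs <- sort(unique(fit$labels))
  if (is.null(pairs)) {
    pairs <- t(utils::combn(labs, 2L))
  }
  pairs <- matrix(as.integer(pairs), ncol = 2L)
  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(p) {
    purrr::map_dfr(features, function(j) {
      tidy(test_feature(x, fit, feature = j, pair = pairs[p, ], sigma = sigma))
    })
  })
  dplyr::mutate(rows,
                p_selective_bh = bh_adjust(.data$p_selective),
                .after = "p_selective")
}

#' Plug-in estimators of the feature covariance
#'
#' `"sample"` is the empirical covariance of the rows; `"residual"`
#' subtracts each row's cluster mean first and divides by `n - K`
#' (the within-cluster residual covariance used when the clustering has
#' soaked up mean structure). The estimate is symmetrised and, if
#' numerically rank-deficient, lifted to positive definiteness by adding a
#' small ridge.
#'
#' @param data n x q matrix or data frame.
#' @param mode `"sample"` or `"residual"`.
#' @param labels Cluster labels (required for `"residual"`).
#' @return A q x q positive-definite covariance matrix.
#' @export
estimate_sigma <- function(data, mode = c("sample", "residual"), labels = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(data)
  n <- nrow(x)
  if (mode == "sample") {
    if (n < 2L) stop("need at least two observations", call. = FALSE)
    sig <- stats::cov(x)
  } else {
    if (is.null(labels)) stop("residual mode requires cluster labels", call. = FALSE)
    stopifnot(length(labels) == n)
    labels <- as.integer(factor(labels))
    ncl <- max(labels)
    if (n - ncl < 1L) stop("too few observations for the residual denominator",
                           call. = FALSE)
    centers <- rowsum(x, labels) / as.vector(table(labels))
    resid <- x - centers[labels, , drop = FALSE]
    sig <- crossprod(resid) / (n - ncl)
  }
  sig <- (sig + t(sig)) / 2
  ev <- eigen(sig, symmetric = TRUE, only.values = TRUE)$values
  floor_ev <- 1e-8 * max(ev, 0)
  if (min(ev) <= floor_ev) {
    ridge <- floor_ev - min(ev) + 1e-8 * max(abs(diag(sig)), 1)
    sig <- sig + diag(ridge, ncol(sig))
  }
  sig
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (delegates to [stats::p.adjust()]).
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}
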