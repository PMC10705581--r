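#' Lloyd's k-means with a full iterate trace
#'
#' Runs plain Lloyd iterations from a seeded random-index initialisation
#' and records the cluster assignment of every observation at every
#' iteration, because the selective test for k-means conditions on *all*
#' intermediate assignments, not just the final partition. Initial
#' centroids are data rows sampled without replacement under `seed`;
#' iteration 0 assigns each observation to the nearest initial centroid;
#' thereafter centroids are cluster means and assignments are
#' nearest-centroid, stopping when the assignment vector repeats.
#' Nearest-centroid ties are broken by the smallest cluster label, so the
#' whole trace is a deterministic function of `(x, K, seed)`.
#'
#' @param x n x q numeric matrix (or data frame).
#' @param K Number of clusters (`K <= n`).
#' @param seed Integer seed for the initial centroid draw (the caller's RNG
#'   state is left untouched).
#' @param max_iter Iteration cap.
#' @return A list of class `kmeans_trace`: `K`, `T` (iterations run),
#'   `assignments` ((T+1) x n integer matrix, rows t = 0..T),
#'   `init_indices`, `seed`, and `labels` (the final row).
#' @export
kmeans_trace <- function(x, K, seed, max_iter = 100L) {
  x <- as.matrix(x)
  n <- nrow(x)
  K <- as.integer(K)
  stopifnot(K >= 1L, K <= n)
  init <- withr::with_seed(seed, sample.int(n, K))
  centers <- x[init, , drop = FALSE]
  assign_hist <- list()
  cl <- nearest_center(x, centers)
  if (length(unique(cl)) < K) {
    stop("empty cluster at initial assignment; re-run with a different seed",
         call. = FALSE)
  }
  assign_hist[[1L]] <- cl
  t <- 0L
  repeat {
    centers <- rowsum(x, cl) / as.vector(table(factor(cl, levels = seq_len(K))))
    new_cl <- nearest_center(x, centers)
    if (length(unique(new_cl)) < K) {
      stop("empty cluster during Lloyd update; re-run with a different seed",
           call. = FALSE)
    }
    t <- t + 1L
    assign_hist[[t + 1L]] <- new_cl
    if (identical(new_cl, cl) || t >= max_iter) break
    cl <- new_cl
  }
  assignments <- do.call(rbind, assign_hist)
  structure(list(K = K, T = t, assignments = assignments,
                 init_indices = init, seed = seed,
                 labels = assignments[t + 1L, ], n = n),
            class = "kmeans_trace")
}

nearest_center <- function(x, centers) {
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
  max.col(-d2, ties.method = "first")
}

#' Truncation set for k-means clustering
#'
#' Computes the set of perturbation values for which re-running the traced
#' Lloyd iterations on the perturbed data -- same initial rows, same number
#' of iterations -- reproduces every intermediate assignment. Both the
#' perturbed rows and the perturbed centroids (initial rows at iteration 0,
#' cluster means of the previous assignment afterwards) are affine in the
#' perturbation scalar, so each event "observation i stays closer to its
#' assigned centroid than to centroid k" is one quadratic inequality; the
#' set is the intersection of the n * (T+1) * (K-1) solution sets.
#' Perturbations that would empty a cluster are excluded automatically,
#' because such an assignment pattern differs from the trace.
#'
#' @param x Data matrix the trace was computed from.
#' @param trace A [kmeans_trace()] of `x`.
#' @param line A [perturbation_line()] whose tested groups are two clusters
#'   of `trace$labels`.
#' @return An [interval_union()] containing `line$phi_obs`.
#' @export
kmeans_truncation_set <- function(x, trace, line) {
  stopifnot(inherits(trace, "kmeans_trace"), inherits(line, "perturbation_line"))
  x <- as.matrix(x)
  n <- nrow(x)
  K <- trace$K
  scale <- 1 + abs(line$phi_obs)

  s <- line$contrast$nu / line$contrast$nu_sq_norm
  w <- line$direction
  w2 <- sum(w^2)
  g <- drop(x %*% w)

  qa <- list(); qb <- list(); qc <- list()
  ridx <- seq_len(n)

  for (t in 0:trace$T) {
    if (t == 0L) {
      centers <- x[trace$init_indices, , drop = FALSE]
      speeds <- s[trace$init_indices]
    } else {
      prev <- trace$assignments[t, ]
      fac <- factor(prev, levels = seq_len(K))
      cnt <- as.vector(table(fac))
      centers <- rowsum(x, prev) / cnt
      speeds <- as.vector(rowsum(matrix(s), prev)) / cnt
    }
    cl <- trace$assignments[t + 1L, ]
    # triple of ||x'_i - m'_k||^2 as a quadratic in psi = phi - phi_obs
    S_ik <- outer(s, speeds, "-")                       # n x K relative speed
    A_ik <- S_ik^2 * w2
    h_k <- drop(centers %*% w)
    B_ik <- 2 * S_ik * outer(g, h_k, "-")
    C_ik <- outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
    own <- cbind(ridx, cl)
    for (k in seq_len(K)) {
      keep <- cl != k
      if (!any(keep)) next
      qa[[length(qa) + 1L]] <- (A_ik[, k] - A_ik[own])[keep]
      qb[[length(qb) + 1L]] <- (B_ik[, k] - B_ik[own])[keep]
      qc[[length(qc) + 1L]] <- (C_ik[, k] - C_ik[own])[keep]
    }
  }

  a <- unlist(qa, use.names = FALSE)
  b <- unlist(qb, use.names = FALSE)
  cc <- unlist(qc, use.names = FALSE)
  mx <- pmax(abs(a), abs(b), abs(cc), 1)
  real <- abs(a) > 1e-10 * mx | abs(b) > 1e-10 * mx
  S_psi <- intersect_quad_constraints(a[real], b[real], cc[real], scale = scale)
  if (iu_is_empty(S_psi) || !interval_contains(S_psi, 0, scale = scale)) {
    stop("computed truncation set does not contain the observed data; ",
         "internal error in the truncation-set computation", call. = FALSE)
  }
  out <- new_interval_union(cbind(S_psi[, 1L] + line$phi_obs,
                                  S_psi[, 2L] + line$phi_obs))
  attr(out, "n_constraints") <- length(a)
  out
}
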