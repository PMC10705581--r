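#' Gaussian sampling model for an observations-by-features matrix
#'
#' The inferential framework assumes each row of the n x q data matrix is an
#' independent draw from a q-variate Gaussian with its own mean vector and a
#' shared, known, positive-definite feature covariance. This constructor
#' validates those assumptions (symmetry and positive-definiteness of the
#' covariance are checked via a symmetric eigendecomposition with tolerance
#' `1e-8` times the largest eigenvalue).
#'
#' @param mu n x q numeric matrix of per-observation means.
#' @param sigma q x q numeric feature covariance matrix.
#' @return A list of class `gaussian_model` with elements `mu` and `sigma`.
#' @export
gaussian_model <- function(mu, sigma) {
  mu <- as.matrix(mu)
  check_sigma(sigma, ncol(mu))
  structure(list(mu = mu, sigma = as.matrix(sigma)), class = "gaussian_model")
}

check_sigma <- function(sigma, q = NULL) {
  sigma <- as.matrix(sigma)
  if (!is.null(q) && ncol(sigma) != q) {
    stop("sigma dimension does not match the number of features", call. = FALSE)
  }
  if (nrow(sigma) != ncol(sigma) ||
      max(abs(sigma - t(sigma))) > 1e-8 * max(abs(sigma), 1)) {
    stop("sigma must be a symmetric square matrix", call. = FALSE)
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-8 * max(ev)) {
    stop("sigma must be positive definite", call. = FALSE)
  }
  invisible(sigma)
}

#' Specify which cluster pair and feature to test
#'
#' @param g,gprime Integer vectors of observation indices (1-based) for the
#'   two groups; must be non-empty and disjoint.
#' @param j Feature index (1-based).
#' @param n,q Number of observations and features of the data the spec will
#'   be applied to.
#' @return A list of class `test_spec`.
#' @export
test_spec <- function(g, gprime, j, n, q) {
  g <- as.integer(g)
  gprime <- as.integer(gprime)
  j <- as.integer(j)
  if (length(g) == 0L || length(gprime) == 0L) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(g, gprime)) > 0L) {
    stop("groups must be disjoint", call. = FALSE)
  }
  if (anyDuplicated(g) || anyDuplicated(gprime)) {
    stop("group indices must be unique", call. = FALSE)
  }
  if (any(c(g, gprime) < 1L) || any(c(g, gprime) > n)) {
    stop("group indices must lie in 1..n", call. = FALSE)
  }
  if (length(j) != 1L || j < 1L || j > q) {
    stop("feature index must lie in 1..q", call. = FALSE)
  }
  structure(list(g = sort(g), gprime = sort(gprime), j = j, n = as.integer(n),
                 q = as.integer(q)), class = "test_spec")
}

#' Contrast vector encoding a difference in cluster means
#'
#' Builds the n-vector whose inner product with a data column equals the
#' difference in empirical means of that feature between the two groups:
#' entries `1/|G|` on the first group, `-1/|G'|` on the second, 0 elsewhere.
#' Its squared norm is `1/|G| + 1/|G'|`.
#'
#' @param n Number of observations.
#' @param spec A [test_spec()] (the feature index is ignored here).
#' @return A list of class `contrast` with elements `nu` (length-n vector)
#'   and `nu_sq_norm`.
#' @examples
#' contrast_vector(4, test_spec(c(1, 2), 3, j = 1, n = 4, q = 2))
#' @export
contrast_vector <- function(n, spec) {
  stopifnot(inherits(spec, "test_spec"))
  if (max(c(spec$g, spec$gprime)) > n) {
    stop("group indices exceed n", call. = FALSE)
  }
  nu <- numeric(n)
  nu[spec$g] <- 1 / length(spec$g)
  nu[spec$gprime] <- -1 / length(spec$gprime)
  structure(list(nu = nu,
                 nu_sq_norm = 1 / length(spec$g) + 1 / length(spec$gprime)),
            class = "contrast")
}

#' Difference in cluster means of one feature
#'
#' @param x n x q data matrix (or data frame).
#' @param contrast A [contrast_vector()] result.
#' @param j Feature index.
#' @return The scalar statistic, i.e. the feature-`j` mean of the first
#'   group minus the feature-`j` mean of the second group.
#' @export
test_statistic <- function(x, contrast, j) {
  x <- as.matrix(x)
  stopifnot(inherits(contrast, "contrast"), length(contrast$nu) == nrow(x),
            j >= 1L, j <= ncol(x))
  sum(contrast$nu * x[, j])
}

#' One-parameter perturbation line through the observed data
#'
#' The selective p-value conditions on everything about the data except the
#' tested statistic. Varying that statistic while holding the rest fixed
#' traces a line of data matrices: sliding the tested pair's feature-j mean
#' difference to `phi` moves the rows of the two groups in opposite
#' directions along `sigma[, j] / sigma[j, j]`, so features correlated with
#' j co-move proportionally. At `phi = phi_obs` the original data are
#' recovered.
#'
#' @inheritParams test_statistic
#' @param sigma q x q feature covariance.
#' @param spec A [test_spec()] naming the groups and the tested feature.
#' @return A list of class `perturbation_line` with `phi_obs`, `direction`
#'   (the q-vector with 1 in position j), `contrast` and `j`.
#' @export
perturbation_line <- function(x, sigma, spec) {
  x <- as.matrix(x)
  sigma <- as.matrix(sigma)
  check_sigma(sigma, ncol(x))
  ct <- contrast_vector(nrow(x), spec)
  j <- spec$j
  direction <- sigma[, j] / sigma[j, j]
  phi_obs <- test_statistic(x, ct, j)
  structure(list(phi_obs = phi_obs, direction = direction, contrast = ct,
                 j = j), class = "perturbation_line")
}

#' Evaluate the perturbation line at a given value of the statistic
#'
#' @param x The data matrix the line was built from.
#' @param line A [perturbation_line()].
#' @param phi Target value of the feature-j mean difference.
#' @return An n x q matrix `x'` with `test_statistic(x', nu, j) == phi`;
#'   rows outside the two tested groups are unchanged, and
#'   `phi = phi_obs` returns `x` itself.
#' @export
perturb_data <- function(x, line, phi) {
  x <- as.matrix(x)
  stopifnot(inherits(line, "perturbation_line"))
  shift <- (phi - line$phi_obs) / line$contrast$nu_sq_norm
  x + (shift * line$contrast$nu) %*% t(line$direction)
}
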