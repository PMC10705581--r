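#' Quadratic coefficients of a perturbed squared distance
#'
#' Along the perturbation line, the squared Euclidean distance between rows
#' i and i' of the perturbed data is a quadratic `a*phi^2 + b*phi + c` in
#' the perturbation scalar: rows move along a common direction with speeds
#' proportional to their contrast entries, so only pairs straddling the two
#' tested groups (or one group and the rest) have non-constant distances.
#'
#' @param x Data matrix the line was built from.
#' @param line A [perturbation_line()].
#' @param i,iprime Distinct observation indices.
#' @return Named numeric vector `c(a, b, c)` with
#'   `||x'_i(phi) - x'_i'(phi)||^2 = a*phi^2 + b*phi + c`.
#' @export
perturbed_pair_coeffs <- function(x, line, i, iprime) {
  x <- as.matrix(x)
  stopifnot(i != iprime)
  s <- line$contrast$nu / line$contrast$nu_sq_norm
  w <- line$direction
  ds <- s[i] - s[iprime]
  d <- x[i, ] - x[iprime, ]
  # coefficients in psi = phi - phi_obs, then shifted to phi
  a <- ds^2 * sum(w^2)
  b0 <- 2 * ds * sum(d * w)
  c0 <- sum(d^2)
  ph <- line$phi_obs
  c(a = a,
    b = b0 - 2 * a * ph,
    c = c0 - b0 * ph + a * ph^2)
}

# window maxima of the first m merge heights: WM[i, j] = max(heights[i:j])
window_max <- function(h, m) {
  WM <- matrix(-Inf, m, m)
  for (i in seq_len(m)) WM[i, i:m] <- cummax(h[i:m])
  WM
}

#' Truncation set for hierarchical clustering
#'
#' Computes the set of perturbation values for which re-clustering the
#' perturbed data (same linkage, same K-cut) reproduces the observed
#' K-cluster partition. Along the perturbation line every dissimilarity
#' *within* a cluster of the cut is constant (rows of each tested group
#' move identically and other rows do not move), so the partition is
#' preserved exactly when, at each of the first n-K merge steps, the
#' original winning merge -- whose linkage value is the constant recorded
#' height -- still attains the minimal linkage among all co-alive cluster
#' pairs. Each such comparison is one quadratic inequality in the
#' perturbation scalar; one inequality per co-alive cluster pair suffices,
#' with threshold equal to the largest winner height over the steps the
#' pair is alive (capped at step n-K). Linkage values of merged clusters
#' are propagated as coefficient triples through the Lance-Williams
#' recursions, which are linear for average, centroid and Ward linkage;
#' single linkage reduces instead to one inequality per point pair
#' straddling two clusters of the cut.
#'
#' @param x Data matrix (n x q).
#' @param trace A [hclust_trace()] of `x`.
#' @param line A [perturbation_line()] whose tested groups are two clusters
#'   of `trace`'s K-cut.
#' @return An [interval_union()] of values of the tested mean difference;
#'   always contains the observed statistic `line$phi_obs`.
#' @export
hier_truncation_set <- function(x, trace, line) {
  stopifnot(inherits(trace, "dendro_trace"), inherits(line, "perturbation_line"))
  x <- as.matrix(x)
  n <- nrow(x)
  m <- n - trace$K
  scale <- 1 + abs(line$phi_obs)
  if (m == 0L) return(iu_reals())

  s <- line$contrast$nu / line$contrast$nu_sq_norm
  w <- line$direction
  w2 <- sum(w^2)
  g <- drop(x %*% w)
  labels <- trace$labels

  if (trace$linkage == "single") {
    co <- single_linkage_constraints(x, labels, s, g, w2, max(trace$heights[seq_len(m)]))
  } else {
    co <- lw_linkage_constraints(x, trace, s, g, w2, m)
  }

  S_psi <- intersect_quad_constraints(co$a, co$b, co$c, scale = scale)
  if (iu_is_empty(S_psi) || !interval_contains(S_psi, 0, scale = scale)) {
    stop("computed truncation set does not contain the observed data; ",
         "internal error in the truncation-set computation", call. = FALSE)
  }
  out <- new_interval_union(cbind(S_psi[, 1L] + line$phi_obs,
                                  S_psi[, 2L] + line$phi_obs))
  attr(out, "n_constraints") <- length(co$a)
  out
}

# single linkage: cross-cluster point pairs must keep squared distance
# >= the largest of the first n-K merge heights
single_linkage_constraints <- function(x, labels, s, g, w2, hmax) {
  n <- nrow(x)
  pair <- which(upper.tri(matrix(0, n, n)) &
                  outer(labels, labels, "!=") &
                  outer(s, s, "!="), arr.ind = TRUE)
  if (nrow(pair) == 0L) {
    return(list(a = numeric(), b = numeric(), c = numeric()))
  }
  d2 <- sq_dist_matrix(x)
  i <- pair[, 1L]; j <- pair[, 2L]
  ds <- s[i] - s[j]
  list(a = ds^2 * w2,
       b = 2 * ds * (g[i] - g[j]),
       c = d2[cbind(i, j)] - hmax)
}

# average / centroid / ward: replay the merge sequence on coefficient
# triples, emitting one inequality per co-alive moving cluster pair
lw_linkage_constraints <- function(x, trace, s, g, w2, m) {
  n <- nrow(x)
  A <- outer(s, s, "-")^2 * w2
  B <- 2 * outer(s, s, "-") * outer(g, g, "-")
  C <- sq_dist_matrix(x)
  moving <- outer(s, s, "!=")
  birth <- matrix(0L, n, n)
  WM <- window_max(trace$heights, m)

  sizes <- rep(1L, n)
  active <- rep(TRUE, n)
  rowof <- seq_len(n)  # cluster id -> matrix row

  ea <- vector("list", 2L * m + n)
  eb <- vector("list", 2L * m + n)
  ec <- vector("list", 2L * m + n)
  ne <- 0L

  emit <- function(r, cols, death) {
    # a pair born at step b first competes at step b+1; skip empty windows
    sel <- cols[moving[r, cols] & birth[r, cols] < death]
    if (length(sel) == 0L) return(invisible())
    th <- WM[cbind(birth[r, sel] + 1L, rep(death, length(sel)))]
    ne <<- ne + 1L
    ea[[ne]] <<- A[r, sel]
    eb[[ne]] <<- B[r, sel]
    ec[[ne]] <<- C[r, sel] - th
    invisible()
  }

  for (l in seq_len(m)) {
    p <- rowof[trace$merges[l, 1L]]
    q <- rowof[trace$merges[l, 2L]]
    others <- which(active)
    others <- others[others != p & others != q]

    # pairs involving p or q are candidates up to and including step l
    emit(p, others, l)
    emit(q, others, l)

    if (length(others) > 0L) {
      np <- sizes[p]; nq <- sizes[q]; no <- sizes[others]
      upd <- function(Tm) {
        tp <- Tm[p, others]; tq <- Tm[q, others]; tpq <- Tm[p, q]
        switch(trace$linkage,
          average  = (np * tp + nq * tq) / (np + nq),
          centroid = (np * tp + nq * tq) / (np + nq) -
                     (np * nq * tpq) / (np + nq)^2,
          ward     = ((np + no) * tp + (nq + no) * tq - no * tpq) /
                     (np + nq + no)
        )
      }
      newA <- upd(A); newB <- upd(B); newC <- upd(C)
      A[p, others] <- newA; A[others, p] <- newA
      B[p, others] <- newB; B[others, p] <- newB
      C[p, others] <- newC; C[others, p] <- newC
      mv <- moving[p, others] | moving[q, others]
      moving[p, others] <- mv; moving[others, p] <- mv
      birth[p, others] <- l; birth[others, p] <- l
    }
    active[q] <- FALSE
    sizes[p] <- sizes[p] + sizes[q]
    rowof[n + l] <- p
  }

  # pairs of the K surviving clusters: candidates through step m
  rem <- which(active)
  if (length(rem) > 1L) {
    for (i in seq_len(length(rem) - 1L)) {
      emit(rem[i], rem[(i + 1L):length(rem)], m)
    }
  }

  keep <- seq_len(ne)
  a <- unlist(ea[keep], use.names = FALSE)
  b <- unlist(eb[keep], use.names = FALSE)
  cc <- unlist(ec[keep], use.names = FALSE)
  # drop numerically-constant triples: they are satisfied by the observed
  # clustering for every phi (their value never changes along the line)
  mx <- pmax(abs(a), abs(b), abs(cc), 1)
  real <- abs(a) > 1e-10 * mx | abs(b) > 1e-10 * mx
  list(a = a[real], b = b[real], c = cc[real])
}
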