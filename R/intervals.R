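#' Interval unions: finite unions of disjoint closed real intervals
#'
#' A truncation set for the selective test is always a finite union of
#' closed intervals on the extended real line, arising as the intersection
#' of solution sets of quadratic inequalities in the perturbation scalar.
#' `interval_union()` builds such a set from endpoint vectors, normalising
#' so that intervals are sorted, disjoint and separated by more than the
#' merge tolerance.
#'
#' @param lower,upper Numeric vectors of equal length; `-Inf`/`Inf` allowed.
#' @param scale Positive scalar setting the absolute size of the merge
#'   tolerance (`1e-9 * scale`). Pass `1 + abs(phi_obs)` when the set lives
#'   on the perturbation axis.
#' @return An object of class `interval_union`: a two-column matrix with
#'   columns `lower`, `upper` (zero rows encode the empty set).
#' @examples
#' interval_union(c(0, 1), c(2, 3))   # merges to [0, 3]
#' interval_union(numeric(), numeric())  # empty set
#' @export
interval_union <- function(lower, upper, scale = 1) {
  stopifnot(length(lower) == length(upper), is.numeric(scale), scale > 0)
  if (length(lower) == 0L) {
    return(new_interval_union(matrix(numeric(), ncol = 2L)))
  }
  if (any(is.na(lower)) || any(is.na(upper))) {
    stop("interval endpoints must not be NA", call. = FALSE)
  }
  keep <- lower <= upper
  lower <- lower[keep]
  upper <- upper[keep]
  if (length(lower) == 0L) {
    return(new_interval_union(matrix(numeric(), ncol = 2L)))
  }
  ord <- order(lower, upper)
  lower <- lower[ord]
  upper <- upper[ord]
  tol <- 1e-9 * scale
  # single left-to-right sweep merging overlapping / near-touching intervals
  out_lo <- numeric(length(lower))
  out_hi <- numeric(length(lower))
  k <- 1L
  out_lo[1L] <- lower[1L]
  out_hi[1L] <- upper[1L]
  if (length(lower) > 1L) {
    for (i in 2L:length(lower)) {
      if (lower[i] <= out_hi[k] + tol) {
        out_hi[k] <- max(out_hi[k], upper[i])
      } else {
        k <- k + 1L
        out_lo[k] <- lower[i]
        out_hi[k] <- upper[i]
      }
    }
  }
  new_interval_union(cbind(out_lo[seq_len(k)], out_hi[seq_len(k)]))
}

new_interval_union <- function(m) {
  colnames(m) <- c("lower", "upper")
  structure(m, class = "interval_union")
}

#' @export
print.interval_union <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<interval_union> empty set\n")
  } else {
    cat("<interval_union>",
        paste(sprintf("[%g, %g]", x[, 1L], x[, 2L]), collapse = " U "), "\n")
  }
  invisible(x)
}

#' @export
format.interval_union <- function(x, digits = 10, ...) {
  if (nrow(x) == 0L) return("{}")
  paste(sprintf("[%.*g,%.*g]", digits, x[, 1L], digits, x[, 2L]),
        collapse = ";")
}

iu_empty <- function() new_interval_union(matrix(numeric(), ncol = 2L))
iu_reals <- function() new_interval_union(cbind(-Inf, Inf))

iu_is_empty <- function(x) nrow(x) == 0L

#' Complement of an interval union
#'
#' Closure of the set-complement in the extended reals; since intervals are
#' closed by convention, boundary points belong to both a set and its
#' complement (a measure-zero overlap that is irrelevant to the p-values
#' computed from these sets).
#' @param x An `interval_union`.
#' @return An `interval_union`.
#' @export
interval_complement <- function(x) {
  if (nrow(x) == 0L) return(iu_reals())
  lo <- c(-Inf, x[, 2L])
  hi <- c(x[, 1L], Inf)
  keep <- lo < hi  # drop degenerate gaps at +-Inf endpoints
  if (!any(keep)) return(iu_empty())
  new_interval_union(cbind(lo[keep], hi[keep]))
}

#' Union of several interval unions
#'
#' Endpoint-sort sweep, `O(N log N)` in the total number of intervals.
#' @param sets A list of `interval_union` objects.
#' @inheritParams interval_union
#' @return An `interval_union`.
#' @export
interval_union_all <- function(sets, scale = 1) {
  los <- unlist(lapply(sets, function(s) s[, 1L]), use.names = FALSE)
  his <- unlist(lapply(sets, function(s) s[, 2L]), use.names = FALSE)
  interval_union(los, his, scale = scale)
}

#' Intersection of several interval unions
#'
#' Computed as the complement of the union of complements, so a single
#' sorted sweep handles any number of sets in `O(N log N)`.
#' @param sets A list of `interval_union` objects.
#' @inheritParams interval_union
#' @return An `interval_union`; the empty set is a valid result.
#' @examples
#' a <- interval_union(0, 2); b <- interval_union(1, 3)
#' intervals_intersect(list(a, b))  # [1, 2]
#' @export
intervals_intersect <- function(sets, scale = 1) {
  if (length(sets) == 0L) return(iu_reals())
  comp <- lapply(sets, interval_complement)
  interval_complement(interval_union_all(comp, scale = scale))
}

#' Membership test with endpoint tolerance
#'
#' @param x An `interval_union`.
#' @param phi Numeric vector of query points.
#' @inheritParams interval_union
#' @return Logical vector; `TRUE` when the point is inside some interval or
#'   within `1e-8 * scale` of one of its endpoints.
#' @export
interval_contains <- function(x, phi, scale = 1) {
  tol <- 1e-8 * scale
  if (nrow(x) == 0L) return(rep(FALSE, length(phi)))
  vapply(phi, function(p) any(x[, 1L] - tol <= p & p <= x[, 2L] + tol),
         logical(1L))
}

#' Distance from points to the nearest interval boundary
#'
#' Used by the grid oracles to exclude grid points that sit on (or
#' numerically at) the boundary of a truncation set, where membership is a
#' tie by construction.
#' @inheritParams interval_contains
#' @return Numeric vector of distances to the nearest finite endpoint
#'   (`Inf` when the set has no finite endpoint).
#' @export
interval_boundary_dist <- function(x, phi) {
  ends <- c(x[, 1L], x[, 2L])
  ends <- ends[is.finite(ends)]
  if (length(ends) == 0L) return(rep(Inf, length(phi)))
  vapply(phi, function(p) min(abs(p - ends)), numeric(1L))
}

#' Total length helper (finite part); internal, used by plots
#' @noRd
iu_lengths <- function(x) if (nrow(x) == 0L) numeric() else x[, 2L] - x[, 1L]

#' Solve one quadratic inequality in a scalar
#'
#' Returns the exact solution set of `a*phi^2 + b*phi + c <= 0` (or `>= 0`)
#' as a union of closed intervals. Coefficients whose magnitude is below
#' `1e-10 * max(|a|, |b|, |c|, 1)` are treated as zero: the quadratics that
#' arise as differences of perturbed squared distances frequently cancel
#' their leading terms exactly in theory but not in floating point.
#'
#' @param a,b,c Finite numeric scalars.
#' @param sense `"<=0"` or `">=0"`.
#' @inheritParams interval_union
#' @return An `interval_union`.
#' @examples
#' solve_quadratic(1, 0, -1, "<=0")   # [-1, 1]
#' solve_quadratic(0, 0, 1, "<=0")    # empty
#' solve_quadratic(1, -2, 1, "<=0")   # the point [1, 1]
#' @export
solve_quadratic <- function(a, b, c, sense = c("<=0", ">=0"), scale = 1) {
  sense <- match.arg(sense)
  if (!all(is.finite(c(a, b, c)))) {
    stop("quadratic coefficients must be finite", call. = FALSE)
  }
  if (sense == "<=0") {
    a <- -a; b <- -b; c <- -c  # normalise to >= 0 internally
  }
  sol <- quad_nonneg_sets(a, b, c, scale = scale)
  interval_union(unlist(sol$lower), unlist(sol$upper), scale = scale)
}

# Solution set of a*phi^2 + b*phi + c >= 0 for vectors of coefficients.
# Returns list(lower, upper) of raw interval endpoints (possibly overlapping
# across inequalities; callers normalise). An all-negative inequality yields
# no intervals, so callers must track which inequalities produced nothing.
quad_nonneg_sets <- function(a, b, c, scale = 1) {
  mx <- pmax(abs(a), abs(b), abs(c), 1)
  tol <- 1e-10 * mx
  is_a0 <- abs(a) <= tol
  is_b0 <- abs(b) <= tol
  lo <- vector("list", length(a))
  hi <- vector("list", length(a))
  for (i in seq_along(a)) {
    if (is_a0[i] && is_b0[i]) {
      if (c[i] >= 0) { lo[[i]] <- -Inf; hi[[i]] <- Inf }
      # else: empty
    } else if (is_a0[i]) {
      r <- -c[i] / b[i]
      if (b[i] > 0) { lo[[i]] <- r; hi[[i]] <- Inf }
      else { lo[[i]] <- -Inf; hi[[i]] <- r }
    } else {
      disc <- b[i]^2 - 4 * a[i] * c[i]
      if (disc <= 0) {
        if (a[i] > 0) { lo[[i]] <- -Inf; hi[[i]] <- Inf }
        else if (disc == 0) { r <- -b[i] / (2 * a[i]); lo[[i]] <- r; hi[[i]] <- r }
        # a<0, disc<0: empty
      } else {
        s <- sqrt(disc)
        q <- -(b[i] + sign(b[i] + (b[i] == 0)) * s) / 2
        r1 <- q / a[i]
        r2 <- c[i] / q
        roots <- sort(c(r1, r2))
        if (a[i] > 0) {
          lo[[i]] <- c(-Inf, roots[2L]); hi[[i]] <- c(roots[1L], Inf)
        } else {
          lo[[i]] <- roots[1L]; hi[[i]] <- roots[2L]
        }
      }
    }
  }
  list(lower = lo, upper = hi)
}

# Intersection of the solution sets of many inequalities a_i phi^2 + b_i phi
# + c_i >= 0. The workhorse behind every truncation-set computation: the
# *violation* set of each inequality (where it fails) is at most one interval
# when a_i >= 0 -- the common case for perturbed-distance differences -- and
# the final set is the complement of the union of all violations.
intersect_quad_constraints <- function(a, b, c, scale = 1) {
  stopifnot(length(a) == length(b), length(b) == length(c))
  if (length(a) == 0L) return(iu_reals())
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(!is.finite(c))) {
    stop("quadratic coefficients must be finite", call. = FALSE)
  }
  mx <- pmax(abs(a), abs(b), abs(c), 1)
  tol <- 1e-10 * mx
  a <- ifelse(abs(a) <= tol, 0, a)
  b <- ifelse(abs(b) <= tol, 0, b)

  vlo <- numeric(0)
  vhi <- numeric(0)

  # constant inequalities: c < 0 means no phi works at all
  const <- a == 0 & b == 0
  if (any(const & c < 0)) return(iu_empty())

  lin <- a == 0 & b != 0
  if (any(lin)) {
    r <- -c[lin] / b[lin]
    pos <- b[lin] > 0
    vlo <- c(vlo, ifelse(pos, -Inf, r))
    vhi <- c(vhi, ifelse(pos, r, Inf))
  }

  up <- a > 0
  if (any(up)) {
    disc <- b[up]^2 - 4 * a[up] * c[up]
    has <- disc > 0
    if (any(has)) {
      aa <- a[up][has]; bb <- b[up][has]; cc <- c[up][has]
      s <- sqrt(disc[has])
      q <- -(bb + sign(bb + (bb == 0)) * s) / 2
      r1 <- q / aa
      r2 <- cc / q
      vlo <- c(vlo, pmin(r1, r2))
      vhi <- c(vhi, pmax(r1, r2))
    }
  }

  dn <- a < 0
  if (any(dn)) {
    disc <- b[dn]^2 - 4 * a[dn] * c[dn]
    bad <- disc < 0
    if (any(bad)) return(iu_empty())  # concave, never nonnegative
    aa <- a[dn]; bb <- b[dn]
    s <- sqrt(pmax(disc, 0))
    q <- -(bb + sign(bb + (bb == 0)) * s) / 2
    r1 <- q / aa
    r2 <- c[dn] / q
    vlo <- c(vlo, rep(-Inf, sum(dn)), pmax(r1, r2))
    vhi <- c(vhi, pmin(r1, r2), rep(Inf, sum(dn)))
  }

  if (length(vlo) == 0L) return(iu_reals())
  viol <- interval_union(vlo, vhi, scale = scale)
  interval_complement(viol)
}
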