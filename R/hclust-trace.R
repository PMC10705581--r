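#' Agglomerative clustering on squared Euclidean distances with a full trace
#'
#' Standard bottom-up clustering with Lance-Williams updates, run on the
#' *squared* Euclidean dissimilarity (the scale on which linkage values of
#' perturbed data are quadratic in the perturbation scalar). The merge
#' sequence, merge heights and the K-cluster cut are all recorded, because
#' the selective test conditions on them; ties in the minimal linkage are
#' broken by the lexicographically smallest (cluster-id, cluster-id) pair so
#' that re-clustering perturbed data is a deterministic function of the
#' input.
#'
#' Cluster ids follow the scipy convention: singletons are `1..n`, the
#' cluster formed at merge step `l` gets id `n + l`. Cutting "at K" means
#' taking the partition after `n - K` merges; with single, average or Ward
#' linkage heights are non-decreasing so this agrees with a height cut, while
#' centroid linkage may produce inversions and only the merge-count cut is
#' well-defined.
#'
#' @param x n x q numeric matrix (or data frame) of observations.
#' @param linkage One of `"single"`, `"average"`, `"centroid"`, `"ward"`.
#'   Ward uses the Lance-Williams coefficients for squared-distance input,
#'   i.e. merge heights are the classical within-cluster sum-of-squares
#'   increases (times 2).
#' @param K Number of clusters to cut at (`2 <= K <= n`).
#' @return A list of class `dendro_trace`: `merges` ((n-1) x 2 integer
#'   matrix of cluster ids), `heights` (squared-distance linkage value at
#'   each step), `linkage`, `K`, `labels` (n-vector, clusters numbered
#'   1..K by smallest member index), and `members` (list mapping each
#'   cluster id to its observation indices).
#' @examples
#' x <- matrix(c(0, 1, 10), ncol = 1)
#' hclust_trace(x, "single", K = 2)$labels  # 1 1 2
#' @export
hclust_trace <- function(x, linkage = c("single", "average", "centroid", "ward"),
                         K = 2L) {
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  n <- nrow(x)
  K <- as.integer(K)
  stopifnot(n >= 2L, K >= 2L, K <= n)

  d2 <- sq_dist_matrix(x)
  diag(d2) <- Inf
  ids <- seq_len(n)
  sizes <- rep(1L, n)
  members <- as.list(seq_len(n))
  active <- rep(TRUE, n)
  D <- d2  # current dissimilarities between active clusters (rows reused)

  merges <- matrix(0L, n - 1L, 2L)
  heights <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    # inactive rows/cols and the diagonal are held at Inf; every off-diagonal
    # minimum appears twice by symmetry, so more than two hits is a true tie
    wm <- which.min(D)
    h <- D[wm]
    if (sum(D == h) > 2L) {
      # lexicographic tie-break on sorted (id, id) pairs
      cand <- which(D == h, arr.ind = TRUE)
      cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
      pid <- cbind(pmin(ids[cand[, 1L]], ids[cand[, 2L]]),
                   pmax(ids[cand[, 1L]], ids[cand[, 2L]]))
      best <- order(pid[, 1L], pid[, 2L])[1L]
      p <- cand[best, 1L]
      q <- cand[best, 2L]
    } else {
      rc <- arrayInd(wm, dim(D))
      p <- min(rc)
      q <- max(rc)
    }

    merges[step, ] <- sort(c(ids[p], ids[q]))
    heights[step] <- h

    idx <- which(active)
    others <- idx[idx != p & idx != q]
    if (length(others) > 0L) {
      dp <- D[p, others]
      dq <- D[q, others]
      np <- sizes[p]; nq <- sizes[q]; no <- sizes[others]
      newd <- switch(linkage,
        single   = pmin(dp, dq),
        average  = (np * dp + nq * dq) / (np + nq),
        centroid = (np * dp + nq * dq) / (np + nq) -
                   (np * nq * h) / (np + nq)^2,
        ward     = ((np + no) * dp + (nq + no) * dq - no * h) / (np + nq + no)
      )
      D[p, others] <- newd
      D[others, p] <- newd
    }
    D[q, ] <- Inf
    D[, q] <- Inf
    active[q] <- FALSE
    sizes[p] <- sizes[p] + sizes[q]
    members[[p]] <- c(members[[p]], members[[q]])
    ids[p] <- n + step
  }

  labels <- cut_merges(merges, n, K)
  structure(list(merges = merges, heights = heights, linkage = linkage,
                 K = K, labels = labels, n = n),
            class = "dendro_trace")
}

sq_dist_matrix <- function(x) {
  g <- tcrossprod(x)
  s <- diag(g)
  d2 <- outer(s, s, "+") - 2 * g
  d2[d2 < 0] <- 0
  d2
}

# partition after the first n-K merges, labels 1..K ordered by smallest member
cut_merges <- function(merges, n, K) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  reps <- integer(n - 1L)  # representative observation of cluster id n+l
  id_to_obs <- function(id) if (id <= n) id else reps[id - n]
  nsteps <- n - K
  if (nsteps > 0L) {
    for (l in seq_len(nsteps)) {
      a <- find(id_to_obs(merges[l, 1L]))
      b <- find(id_to_obs(merges[l, 2L]))
      parent[b] <- a
      reps[l] <- a
    }
  } else {
    reps[] <- NA_integer_
  }
  # fill representatives for later merges so id_to_obs stays total (unused)
  roots <- vapply(seq_len(n), find, integer(1L))
  first <- match(unique(roots), roots)
  lab <- match(roots, roots[sort(first)])
  lab
}

#' Compare two partitions up to relabelling
#'
#' @param a,b Integer label vectors of equal length.
#' @return `TRUE` when the partitions are identical as set partitions.
#' @export
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  ca <- match(a, unique(a))
  cb <- match(b, unique(b))
  identical(ca, cb)
}
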