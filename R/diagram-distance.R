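# Exact solver for the square assignment problem (shortest augmenting path
# with dual potentials, O(n^3)). Returns for each column the assigned row.
# Written here because no assignment solver ships with the installed stack;
# diagram matchings are tiny, so exactness beats speed.
solveAssignment <- function(cost) {
  n <- base::nrow(cost)
  stopifnot(n == ncol(cost))
  if (n == 0L) return(integer(0))
  V <- n + 1L  # virtual column
  u <- numeric(n)
  v <- numeric(V)
  p <- integer(V)      # p[j] = row matched to column j (0 = none)
  way <- integer(V)
  for (i in seq_len(n)) {
    p[V] <- i
    j0 <- V
    minv <- rep(Inf, V)
    used <- rep(FALSE, V)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(V)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == V) break
    }
  }
  p[seq_len(n)]
}

# Augmented matching costs between the dim-k finite pairs of two diagrams:
# direct L-infinity costs plus each point's orthogonal projection onto the
# diagonal, with forbidden slots at `forbidden`.
.matchingCosts <- function(A, B, dimension) {
  pa <- .finitePairs(A, dimension)
  pb <- .finitePairs(B, dimension)
  m <- base::nrow(pa); n <- base::nrow(pb)
  size <- m + n
  if (size == 0L)
    return(list(cost = matrix(0, 0, 0), m = 0L, n = 0L, forbidden = 0))
  direct <- matrix(0, nrow = m, ncol = n)
  if (m && n) {
    for (i in seq_len(m)) {
      direct[i, ] <- pmax(abs(pa$birth[i] - pb$birth),
                          abs(pa$death[i] - pb$death))
    }
  }
  diagA <- (pa$death - pa$birth) / 2  # L-inf distance to the diagonal
  diagB <- (pb$death - pb$birth) / 2
  forbidden <- sum(direct) + sum(diagA) + sum(diagB) + 1
  cost <- matrix(0, size, size)
  if (m) {
    if (n) cost[seq_len(m), seq_len(n)] <- direct
    cost[seq_len(m), n + seq_len(m)] <- forbidden
    cost[cbind(seq_len(m), n + seq_len(m))] <- diagA
  }
  if (n) {
    cost[m + seq_len(n), seq_len(n)] <- forbidden
    cost[cbind(m + seq_len(n), seq_len(n))] <- diagB
  }
  # diagonal-to-diagonal slots stay 0
  list(cost = cost, m = m, n = n, forbidden = forbidden)
}

.finitePairs <- function(diagram, dimension) {
  p <- persistencePairs(diagram, dimension = dimension)
  p[is.finite(p$death), , drop = FALSE]
}

#' Wasserstein distance between persistence diagrams
#'
#' The p-th Wasserstein distance between the dimension-\code{k} parts of
#' two diagrams: the minimum over matchings of
#' \eqn{(\sum \|x - \phi(x)\|_\infty^p)^{1/p}}, where unmatched points are
#' sent to their orthogonal projection on the diagonal. Solved exactly by
#' optimal assignment on the diagonal-augmented cost matrix. Essential
#' (infinite-death) pairs are excluded.
#'
#' @param A,B \linkS4class{PersistenceDiagram} objects.
#' @param dimension homology dimension to compare (default 1).
#' @param p Wasserstein order, >= 1.
#' @return a nonnegative number.
#' @export
wassersteinDistance <- function(A, B, dimension = 1L, p = 1) {
  if (p < 1) stop("p must be >= 1")
  aug <- .matchingCosts(A, B, dimension)
  if (base::nrow(aug$cost) == 0L) return(0)
  assignment <- solveAssignment(aug$cost^p)
  matched <- aug$cost[cbind(assignment, seq_len(ncol(aug$cost)))]
  sum(matched^p)^(1 / p)
}

#' Bottleneck distance between persistence diagrams
#'
#' The minimax matched cost under the same diagonal-augmented matchings as
#' \code{\link{wassersteinDistance}} (the p = Inf limit). Computed by
#' binary search over the candidate costs, with a bipartite perfect-
#' matching feasibility check at each threshold.
#'
#' @inheritParams wassersteinDistance
#' @return a nonnegative number.
#' @export
bottleneckDistance <- function(A, B, dimension = 1L) {
  aug <- .matchingCosts(A, B, dimension)
  size <- base::nrow(aug$cost)
  if (size == 0L) return(0)
  candidates <- sort(unique(c(0, aug$cost[aug$cost < aug$forbidden])))
  feasible <- function(t) {
    adj <- aug$cost <= t + 1e-12
    g <- igraph::graph_from_biadjacency_matrix(adj)
    igraph::max_bipartite_match(g)$matching_size == size
  }
  lo <- 1L; hi <- length(candidates)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (feasible(candidates[mid])) hi <- mid else lo <- mid + 1L
  }
  candidates[lo]
}
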