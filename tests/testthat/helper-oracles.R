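# Independent oracles used to cross-check the package's implementations.
# These deliberately share no code with R/: ranks of boundary matrices over
# GF(2) for Betti numbers, exhaustive enumeration for diagram matchings and
# maxmin landmarks.

gf2Rank <- function(M) {
  if (is.null(dim(M)) || nrow(M) == 0L || ncol(M) == 0L) return(0L)
  M <- M %% 2L
  r <- 0L
  for (j in seq_len(ncol(M))) {
    if (r == nrow(M)) break
    piv <- which(M[(r + 1L):nrow(M), j] == 1L)
    if (!length(piv)) next
    piv <- piv[1L] + r
    if (piv != r + 1L) M[c(r + 1L, piv), ] <- M[c(piv, r + 1L), ]
    r <- r + 1L
    for (i in setdiff(which(M[, j] == 1L), r)) {
      M[i, ] <- (M[i, ] + M[r, ]) %% 2L
    }
  }
  r
}

# Betti numbers (b0, b1) of the Rips complex of `dmat` at scale eps,
# straight from the ranks of the boundary maps.
bruteBetti <- function(dmat, eps) {
  n <- nrow(dmat)
  edges <- which(upper.tri(dmat) & dmat <= eps, arr.ind = TRUE)
  ne <- nrow(edges)
  d1 <- matrix(0L, nrow = n, ncol = ne)
  if (ne) for (k in seq_len(ne)) d1[edges[k, ], k] <- 1L
  tris <- if (n >= 3L) utils::combn(n, 3L) else matrix(0L, 3L, 0L)
  if (ncol(tris)) {
    ok <- dmat[cbind(tris[1L, ], tris[2L, ])] <= eps &
          dmat[cbind(tris[1L, ], tris[3L, ])] <= eps &
          dmat[cbind(tris[2L, ], tris[3L, ])] <= eps
    tris <- tris[, ok, drop = FALSE]
  }
  nt <- ncol(tris)
  d2 <- matrix(0L, nrow = max(ne, 1L), ncol = nt)
  edgeId <- function(a, b) which(edges[, 1L] == a & edges[, 2L] == b)
  if (nt) {
    for (k in seq_len(nt)) {
      v <- tris[, k]
      d2[c(edgeId(v[1L], v[2L]), edgeId(v[1L], v[3L]),
           edgeId(v[2L], v[3L])), k] <- 1L
    }
  }
  r1 <- gf2Rank(d1)
  r2 <- if (ne) gf2Rank(d2) else 0L
  c(b0 = n - r1, b1 = ne - r1 - r2)
}

# Betti numbers implied by a persistence diagram at scale eps.
diagramBetti <- function(diagram, eps) {
  p <- persistencePairs(diagram)
  alive <- p$birth <= eps & p$death > eps
  c(b0 = sum(alive & p$dimension == 0L),
    b1 = sum(alive & p$dimension == 1L))
}

# All augmented matchings between two small sets of (birth, death) pairs:
# every point matches a distinct partner or its diagonal projection.
# Returns the list of matched-cost vectors.
enumerateMatchings <- function(pa, pb) {
  linf <- function(a, b) max(abs(a - b))
  diagCost <- function(p) (p[2L] - p[1L]) / 2
  m <- nrow(pa); n <- nrow(pb)
  out <- list()
  recurse <- function(i, usedB, costs) {
    if (i > m) {
      rest <- setdiff(seq_len(n), usedB)
      out[[length(out) + 1L]] <<- c(costs, vapply(
        rest, function(j) diagCost(as.numeric(pb[j, ])), numeric(1)))
      return(invisible())
    }
    a <- as.numeric(pa[i, ])
    recurse(i + 1L, usedB, c(costs, diagCost(a)))
    for (j in setdiff(seq_len(n), usedB)) {
      recurse(i + 1L, c(usedB, j), c(costs, linf(a, as.numeric(pb[j, ]))))
    }
  }
  recurse(1L, integer(0), numeric(0))
  out
}

bruteWasserstein <- function(A, B, dimension = 1L, p = 1) {
  pa <- persistencePairs(A, dimension)[, c("birth", "death")]
  pb <- persistencePairs(B, dimension)[, c("birth", "death")]
  matchings <- enumerateMatchings(pa, pb)
  if (!length(matchings)) return(0)
  min(vapply(matchings, function(cv) sum(cv^p)^(1 / p), numeric(1)))
}

bruteBottleneck <- function(A, B, dimension = 1L) {
  pa <- persistencePairs(A, dimension)[, c("birth", "death")]
  pb <- persistencePairs(B, dimension)[, c("birth", "death")]
  matchings <- enumerateMatchings(pa, pb)
  if (!length(matchings)) return(0)
  min(vapply(matchings, function(cv) if (length(cv)) max(cv) else 0,
             numeric(1)))
}

# Plain maxmin landmark selection from a given start index.
bruteMaxmin <- function(pts, m, start) {
  n <- nrow(pts)
  chosen <- start
  dmin <- sqrt(rowSums(sweep(pts, 2L, pts[start, ])^2))
  while (length(chosen) < m) {
    nxt <- which.max(dmin)
    chosen <- c(chosen, nxt)
    dmin <- pmin(dmin, sqrt(rowSums(sweep(pts, 2L, pts[nxt, ])^2)))
  }
  chosen
}

randomCloud <- function(n, d = 2) {
  PointCloud(matrix(stats::runif(n * d), ncol = d), tau = 1L)
}

randomH1Diagram <- function(npairs, maxScale = 10) {
  if (npairs == 0L)
    return(PersistenceDiagram(maxScale = maxScale))
  b <- stats::runif(npairs, 0, 2)
  d <- b + stats::runif(npairs, 0.05, 2)
  PersistenceDiagram(rep(1L, npairs), b, d, maxScale = maxScale)
}

toySeries <- function(values, group = "HC", id = "toy") {
  StrideSeries(id, group, timestamps = cumsum(values), values = values)
}
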