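# Independent oracles used across the suite. These deliberately avoid the
# package's own geometry and metric code paths.

# Monte-Carlo rejection oracles for hull volumes. Membership is tested by
# Frank-Wolfe projection onto the convex hull (.in_hull_fw_cpp), an
# algorithm entirely independent of the facet-based construction used by
# the package's volume and intersection code.

# rejection-sampling volume of hull(X) within its bounding box
mc_hull_volume <- function(X, n_samples = 20000) {
  lo <- apply(X, 2, min); hi <- apply(X, 2, max)
  U <- cbind(runif(n_samples, lo[1], hi[1]),
             runif(n_samples, lo[2], hi[2]),
             runif(n_samples, lo[3], hi[3]))
  inside <- traitpair:::.in_hull_fw_cpp(U, X)
  box <- prod(hi - lo)
  p <- mean(inside)
  list(volume = box * p, se = box * sqrt(p * (1 - p) / n_samples))
}

# rejection-sampling estimate of the intersection volume of two hulls
mc_intersection_volume <- function(A, B, n_samples = 1e5) {
  lo <- pmax(apply(A, 2, min), apply(B, 2, min))
  hi <- pmin(apply(A, 2, max), apply(B, 2, max))
  if (any(hi <= lo)) return(list(volume = 0, se = 0))
  U <- cbind(runif(n_samples, lo[1], hi[1]),
             runif(n_samples, lo[2], hi[2]),
             runif(n_samples, lo[3], hi[3]))
  inside <- traitpair:::.in_hull_fw_cpp(U, A) & traitpair:::.in_hull_fw_cpp(U, B)
  box <- prod(hi - lo)
  p <- mean(inside)
  list(volume = box * p, se = box * sqrt(p * (1 - p) / n_samples))
}

# decode a Pruefer sequence into the edge list of a labelled tree on 1..n
pruefer_tree <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 1L
  for (s in seq) {
    leaf <- min(which(degree == 1L))
    edges[k, ] <- c(leaf, s); k <- k + 1L
    degree[leaf] <- 0L
    degree[s] <- degree[s] - 1L
  }
  rest <- which(degree == 1L)
  edges[k, ] <- rest
  edges
}

# exact minimum spanning tree by exhaustive enumeration of all labelled
# trees (Cayley: n^(n-2)); practical for n <= 7
exhaustive_mst <- function(d) {
  n <- nrow(d)
  if (n == 2) return(matrix(c(1L, 2L), 1))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- NULL; bestw <- Inf
  for (i in seq_len(nrow(seqs))) {
    e <- pruefer_tree(seqs[i, ], n)
    w <- sum(d[e])
    if (w < bestw) { bestw <- w; best <- e }
  }
  best
}

# FEve computed from an explicitly supplied spanning tree edge list
feve_from_tree <- function(edges, d, p) {
  S <- length(p)
  ew <- d[edges] / (p[edges[, 1]] + p[edges[, 2]])
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

# brute-force fuzzy Gower: mean over groups of half Manhattan distance
gower_oracle <- function(A, groups) {
  gl <- split(seq_along(groups), groups)
  n <- nrow(A)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- 0
    for (cols in gl) acc <- acc + sum(abs(A[i, cols] - A[j, cols])) / 2
    D[i, j] <- acc / length(gl)
  }
  dimnames(D) <- list(rownames(A), rownames(A))
  D
}

# small normalised trait table built directly from a matrix
toy_traits <- function(A, groups) {
  normalize_fuzzy(trait_table(A, groups))
}

# compact synthetic scenario for fast tests
quick_scenario <- function(...) {
  synthetic_scenario(n_pairs = 10, pool_size = 60,
                     modalities_per_group = c(3, 4, 2),
                     n_trait_groups = 3, richness_range = c(8, 16),
                     uncoded_fraction = 0.2, seed = 11, ...)
}
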