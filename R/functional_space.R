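#' Gower dissimilarity among taxa from fuzzy-coded traits
#'
#' For relative-frequency trait profiles the Gower distance of a trait
#' group reduces to half the Manhattan distance between the group's
#' frequency vectors, so each group contributes a value in \[0, 1\]; the
#' overall dissimilarity is the unweighted mean over groups.
#'
#' @param traits a normalised `trait_table` with no missing groups among its
#'   taxa (run [fill_gaps()] first on real data).
#' @return symmetric taxon x taxon matrix with zero diagonal, values in
#'   \[0, 1\].
#' @export
gower_distance <- function(traits) {
  stopifnot(inherits(traits, "trait_table"))
  if (!traits$normalized) stop("trait table must be normalised (normalize_fuzzy)")
  if (!is.null(traits$missing) && any(traits$missing))
    stop("taxa with missing trait groups present; gap-fill before computing distances")
  gidx <- trait_group_index(traits)
  D <- 0
  for (cols in gidx) {
    D <- D + as.matrix(dist(traits$affinities[, cols, drop = FALSE],
                            method = "manhattan")) / 2
  }
  D <- D / length(gidx)
  dimnames(D) <- list(traits$taxa, traits$taxa)
  D
}

#' Principal coordinate analysis of a functional distance matrix
#'
#' Classical metric scaling (double-centering + eigendecomposition). Because
#' Gower matrices are generally non-Euclidean, a correction is applied
#' first: the default takes the square root of the dissimilarities (which
#' renders Manhattan-type distances Euclidean-embeddable); the Cailliez
#' additive constant is available as an alternative, or no correction.
#'
#' @param D symmetric dissimilarity matrix.
#' @param correction `"sqrt"` (default), `"cailliez"`, or `"none"`.
#' @return list of class `pcoa_space`: `coordinates` (taxa x axes, ordered
#'   by decreasing eigenvalue), `eigenvalues` (positive ones retained),
#'   `variance_explained`, `corrected_distance`, `correction`.
#' @export
pcoa_space <- function(D, correction = c("sqrt", "cailliez", "none")) {
  correction <- match.arg(correction)
  D <- as.matrix(D)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  Dc <- switch(correction, sqrt = sqrt(D), cailliez = D, none = D)
  add <- correction == "cailliez"
  fit <- suppressWarnings(cmdscale(as.dist(Dc), k = n - 1, eig = TRUE, add = add))
  eig <- fit$eig
  if (add) {
    # rebuild the corrected matrix actually embedded
    Dc <- as.matrix(as.dist(Dc + fit$ac)) ; diag(Dc) <- 0
  }
  tol <- max(abs(eig), 1e-300) * 1e-8
  pos <- which(eig > tol)
  pos <- pos[pos <= ncol(fit$points)]
  if (length(pos)) {
    coords <- fit$points[, pos, drop = FALSE]
    eig_pos <- eig[pos]
    varexp <- eig_pos / sum(eig_pos)
  } else {
    # fully degenerate (e.g. all taxa functionally identical): one zero axis
    coords <- matrix(0, n, 1)
    eig_pos <- 0
    varexp <- 0
  }
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  rownames(coords) <- rownames(D)
  structure(list(coordinates = coords,
                 eigenvalues = eig_pos,
                 variance_explained = varexp,
                 corrected_distance = Dc,
                 correction = correction),
            class = "pcoa_space")
}

#' Dimensionality quality by mean squared deviation
#'
#' For each candidate number of axes m, Euclidean distances in the first m
#' axes are compared with the original functional (Gower) distances after
#' rescaling both sets to \[0, 1\] by their maxima; the quality of m is the
#' mean squared deviation (mSD) over taxon pairs, and the chosen m minimises
#' mSD subject to an optional cap.
#'
#' @param D original dissimilarity matrix.
#' @param coordinates PCoA coordinates (taxa x axes).
#' @param m_candidates integer vector of candidate dimensionalities.
#' @param cap optional maximum m (candidates above it are dropped).
#' @return list: `quality` data.frame (m, msd), `m` chosen.
#' @export
dimension_quality <- function(D, coordinates, m_candidates = NULL, cap = NULL) {
  D <- as.matrix(D)
  nax <- ncol(coordinates)
  if (is.null(m_candidates)) m_candidates <- seq_len(min(nax, cap %||% nax))
  if (!is.null(cap)) m_candidates <- m_candidates[m_candidates <= cap]
  if (any(m_candidates > nax)) stop("candidate m exceeds available axes")
  dg <- D[lower.tri(D)]
  if (max(dg) > 0) dg <- dg / max(dg)
  msd <- vapply(m_candidates, function(m) {
    de <- as.vector(dist(coordinates[, seq_len(m), drop = FALSE]))
    if (max(de) > 0) de <- de / max(de)
    mean((dg - de)^2)
  }, numeric(1))
  qual <- data.frame(m = m_candidates, msd = msd)
  list(quality = qual, m = m_candidates[which.min(msd)])
}

#' Build a functional space from a trait table
#'
#' Convenience wrapper chaining [gower_distance()], [pcoa_space()] and
#' [dimension_quality()]; selects one dimensionality for alpha (convex-hull
#' richness) and one for beta (hull overlap) purposes, each capped (default
#' 3 axes for both, following common practice for hull-based metrics).
#'
#' @param traits normalised, gap-filled `trait_table`.
#' @param alpha_cap,beta_cap caps on the chosen dimensionalities.
#' @param correction eigenvalue correction passed to [pcoa_space()].
#' @return object of class `functional_space`: `distance` (Gower), the
#'   `pcoa_space` fields, `quality`, `m_alpha`, `m_beta`.
#' @export
build_functional_space <- function(traits, alpha_cap = 3, beta_cap = 3,
                                   correction = "sqrt") {
  D <- gower_distance(traits)
  sp <- pcoa_space(D, correction = correction)
  cand_max <- min(max(alpha_cap, beta_cap), ncol(sp$coordinates))
  qa <- dimension_quality(D, sp$coordinates,
                          m_candidates = if (cand_max < 2) 1 else 2:cand_max)
  qual <- qa$quality
  m_alpha <- qual$m[qual$m <= alpha_cap][which.min(qual$msd[qual$m <= alpha_cap])]
  m_beta <- qual$m[qual$m <= beta_cap][which.min(qual$msd[qual$m <= beta_cap])]
  structure(list(distance = D,
                 coordinates = sp$coordinates,
                 eigenvalues = sp$eigenvalues,
                 variance_explained = sp$variance_explained,
                 corrected_distance = sp$corrected_distance,
                 correction = sp$correction,
                 quality = qual,
                 m_alpha = m_alpha,
                 m_beta = m_beta),
            class = "functional_space")
}

#' @export
print.functional_space <- function(x, ...) {
  cat("Functional space:", nrow(x$coordinates), "taxa,",
      ncol(x$coordinates), "positive axes;",
      sprintf("m_alpha = %d, m_beta = %d\n", x$m_alpha, x$m_beta))
  cat(sprintf("  variance explained by first %d axes: %.1f%%\n", x$m_alpha,
              100 * sum(x$variance_explained[seq_len(x$m_alpha)])))
  invisible(x)
}

#' Kernel density of trait combinations on the first two axes
#'
#' Gaussian product-kernel density, optionally abundance-weighted, on a
#' regular grid spanning the points; a diagnostic of which trait
#' combinations are common in the functional space.
#'
#' @param coordinates taxa x axes matrix (first two axes used).
#' @param weights optional non-negative weights (e.g. abundances);
#'   normalised internally, so scaling all weights leaves the density
#'   unchanged.
#' @param grid_n grid resolution per axis (default 128).
#' @param bandwidth optional length-2 bandwidth; default Scott's rule with
#'   effective sample size for weighted data.
#' @return list: `x`, `y` grid vectors, `z` density matrix (integrates to 1
#'   over the grid), `bandwidth`.
#' @export
trait_density <- function(coordinates, weights = NULL, grid_n = 128,
                          bandwidth = NULL) {
  X <- as.matrix(coordinates)[, 1:2, drop = FALSE]
  if (nrow(unique(X)) < 3) stop("need at least 3 distinct points")
  w <- weights %||% rep(1, nrow(X))
  if (any(w < 0) || sum(w) <= 0) stop("weights must be non-negative, not all zero")
  w <- w / sum(w)
  n_eff <- 1 / sum(w^2)
  if (is.null(bandwidth)) {
    sdw <- function(v) sqrt(sum(w * (v - sum(w * v))^2))
    bandwidth <- vapply(1:2, function(j) sdw(X[, j]) * n_eff^(-1 / 6), numeric(1))
    bandwidth[bandwidth <= 0] <- 1e-3 * max(diff(apply(X, 2, range)))
  }
  gx <- seq(min(X[, 1]) - 4 * bandwidth[1], max(X[, 1]) + 4 * bandwidth[1],
            length.out = grid_n)
  gy <- seq(min(X[, 2]) - 4 * bandwidth[2], max(X[, 2]) + 4 * bandwidth[2],
            length.out = grid_n)
  kx <- outer(gx, X[, 1], function(a, b) stats::dnorm(a, b, bandwidth[1]))
  ky <- outer(gy, X[, 2], function(a, b) stats::dnorm(a, b, bandwidth[2]))
  z <- kx %*% (w * t(ky))
  list(x = gx, y = gy, z = z, bandwidth = bandwidth)
}
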