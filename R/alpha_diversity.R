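#' Community-weighted mean trait profile
#'
#' Weighs each trait modality of the relative-frequency trait matrix by the
#' relative abundance of the taxa carrying it: CWM_k = sum_i p_i * t_ik.
#' Because each taxon's profile sums to 1 within every trait group, the CWM
#' inherits that property.
#'
#' @param abundance named non-negative abundance vector over (a subset of)
#'   the trait table's taxa.
#' @param traits normalised `trait_table` covering all community taxa.
#' @return named numeric vector over modalities.
#' @export
cwm <- function(abundance, traits) {
  stopifnot(inherits(traits, "trait_table"), traits$normalized)
  abundance <- abundance[abundance > 0]
  if (!length(abundance)) stop("empty community")
  missing <- setdiff(names(abundance), traits$taxa)
  if (length(missing))
    stop("taxa without trait profiles (gap-fill first): ",
         paste(missing, collapse = ", "))
  p <- abundance / sum(abundance)
  as.vector(p %*% traits$affinities[names(abundance), , drop = FALSE]) |>
    setNames(colnames(traits$affinities))
}

# convex-hull volume in 1-3 dimensions; NA when the point set is degenerate
# (fewer than m+1 affinely independent points)
hull_volume <- function(X) {
  X <- unique(as.matrix(X))
  m <- ncol(X)
  if (nrow(X) <= m) return(NA_real_)
  if (m == 1) {
    v <- diff(range(X[, 1]))
    return(if (v > 0) v else NA_real_)
  }
  if (m == 2) {
    a <- .hull2_area_cpp(X)
    return(if (a > 0) a else NA_real_)
  }
  if (m == 3) {
    h <- .hull3_volume_cpp(X)
    return(if (h$degenerate) NA_real_ else h$volume)
  }
  stop("convex-hull volumes are supported for 1-3 axes")
}

#' Functional richness (convex-hull volume)
#'
#' Volume of the convex hull spanned by the community's taxa in the first m
#' functional axes; optionally standardised by the hull volume of the whole
#' taxon pool, giving a value in (0, 1]. Communities with too few distinct
#' points (S <= m, or a degenerate point configuration) are undefined and
#' return `NA`, never 0.
#'
#' @param abundance named abundance vector (presence is what matters).
#' @param space a `functional_space`.
#' @param m number of axes (default `space$m_alpha`).
#' @param standardize divide by the pool hull volume (default TRUE).
#' @param pool_volume precomputed pool hull volume (to avoid recomputation
#'   in loops); computed from the space when NULL and `standardize` is TRUE.
#' @param coords optional coordinate matrix overriding `space$coordinates`
#'   (used by the null-model machinery; the pool hull is unchanged by
#'   label shuffling).
#' @return numeric volume or `NA` if undefined.
#' @export
fric <- function(abundance, space, m = space$m_alpha, standardize = TRUE,
                 pool_volume = NULL, coords = NULL) {
  taxa <- names(abundance)[abundance > 0]
  X <- (coords %||% space$coordinates)[taxa, seq_len(m), drop = FALSE]
  v <- hull_volume(X)
  if (is.na(v) || !standardize) return(v)
  if (is.null(pool_volume))
    pool_volume <- hull_volume(space$coordinates[, seq_len(m), drop = FALSE])
  v / pool_volume
}

#' Functional evenness (minimum spanning tree regularity)
#'
#' Regularity of taxa along the minimum spanning tree of the community in
#' the full functional space, weighted by abundance: branch weights
#' EW_l = dist(i, j) / (p_i + p_j) are normalised to PEW_l and compared with
#' the regular value 1/(S-1):
#' FEve = (sum min(PEW_l, 1/(S-1)) - 1/(S-1)) / (1 - 1/(S-1)).
#'
#' @param abundance named abundance vector.
#' @param space a `functional_space` (all positive axes are used).
#' @param coords optional coordinate matrix overriding `space$coordinates`
#'   (used by the null-model machinery).
#' @return FEve in \[0, 1\], or `NA` when S < 3.
#' @export
feve <- function(abundance, space, coords = NULL) {
  abundance <- abundance[abundance > 0]
  S <- length(abundance)
  if (S < 3) return(NA_real_)
  X <- (coords %||% space$coordinates)[names(abundance), , drop = FALSE]
  p <- abundance / sum(abundance)
  d <- as.matrix(dist(X))
  mst <- vegan::spantree(as.dist(d))
  i <- 2:S
  j <- mst$kid
  ew <- d[cbind(i, j)] / (p[i] + p[j])
  if (sum(ew) <= 0) return(NA_real_)  # all taxa functionally identical
  pew <- ew / sum(ew)
  thr <- 1 / (S - 1)
  (sum(pmin(pew, thr)) - thr) / (1 - thr)
}

#' Functional dispersion
#'
#' Abundance-weighted mean distance of taxa to the community's
#' abundance-weighted centroid in the full functional space.
#'
#' @inheritParams feve
#' @return FDis >= 0 (0 for a single taxon).
#' @export
fdis <- function(abundance, space, coords = NULL) {
  abundance <- abundance[abundance > 0]
  if (!length(abundance)) stop("empty community")
  X <- (coords %||% space$coordinates)[names(abundance), , drop = FALSE]
  p <- abundance / sum(abundance)
  centroid <- colSums(p * X)
  sum(p * sqrt(rowSums(sweep(X, 2, centroid)^2)))
}

#' Rao's quadratic entropy, Simpson diversity, functional redundancy
#'
#' Rao's Q = sum_ij d_ij p_i p_j is the expected functional (Gower) distance
#' between two randomly drawn individuals; Simpson diversity
#' D = 1 - sum p_i^2; functional redundancy is their quotient FR = Q / D
#' (undefined for monocultures, where D = 0).
#'
#' @param abundance named abundance vector.
#' @param distance Gower distance matrix over (at least) the community taxa.
#' @return list with `rao`, `simpson`, `redundancy` (NA when D = 0).
#' @export
rao_simpson_redundancy <- function(abundance, distance) {
  abundance <- abundance[abundance > 0]
  if (!length(abundance)) stop("empty community")
  p <- abundance / sum(abundance)
  Dm <- distance[names(abundance), names(abundance), drop = FALSE]
  Q <- drop(p %*% Dm %*% p)
  simp <- 1 - sum(p^2)
  list(rao = Q, simpson = simp,
       redundancy = if (simp > 0) Q / simp else NA_real_)
}

#' Functional alpha diversity for every site
#'
#' Computes, per site: species richness S, the CWM vector over all
#' modalities, FRic (at `space$m_alpha` axes, standardised by the pool
#' hull), FEve, FDis (entire trait space), Rao's Q, Simpson diversity and
#' functional redundancy Q/D. Undefined metrics are `NA` and counted.
#'
#' @param comm site x taxon abundance matrix (rownames = site ids).
#' @param traits normalised `trait_table`.
#' @param space `functional_space` built from `traits`.
#' @param fric_standardize passed to [fric()].
#' @return list of class `alpha_result`: `metrics` data.frame (one row per
#'   site), `cwm` site x modality matrix, `n_undefined` named counts.
#' @export
alpha_diversity <- function(comm, traits, space, fric_standardize = TRUE) {
  comm <- as.matrix(comm)
  pool_vol <- if (fric_standardize)
    hull_volume(space$coordinates[, seq_len(space$m_alpha), drop = FALSE]) else NULL
  sites <- rownames(comm)
  cwm_mat <- matrix(NA_real_, length(sites), ncol(traits$affinities),
                    dimnames = list(sites, colnames(traits$affinities)))
  met <- data.frame(site = sites, S = NA_integer_, fric = NA_real_,
                    feve = NA_real_, fdis = NA_real_, rao = NA_real_,
                    simpson = NA_real_, redundancy = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(sites)) {
    ab <- comm[k, ]
    ab <- ab[ab > 0]
    met$S[k] <- length(ab)
    cwm_mat[k, ] <- cwm(ab, traits)
    met$fric[k] <- fric(ab, space, standardize = fric_standardize,
                        pool_volume = pool_vol)
    met$feve[k] <- feve(ab, space)
    met$fdis[k] <- fdis(ab, space)
    rsr <- rao_simpson_redundancy(ab, space$distance)
    met$rao[k] <- rsr$rao
    met$simpson[k] <- rsr$simpson
    met$redundancy[k] <- rsr$redundancy
  }
  structure(list(metrics = met, cwm = cwm_mat,
                 n_undefined = colSums(is.na(met[, c("fric", "feve", "redundancy")]))),
            class = "alpha_result")
}
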