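#' Convex-hull volumes and their intersection for two point sets
#'
#' Exact (up to floating point) volumes of the two hulls and of their
#' intersection polytope in m = 2 or 3 axes. The intersection is obtained
#' by clipping each hull's edges against the other's half-space
#' representation and taking the hull volume of the surviving vertices.
#'
#' @param points_a,points_b numeric matrices (points x m).
#' @param m number of axes (2 or 3; default 3).
#' @return list `v_a`, `v_b`, `v_shared`, `degenerate` (TRUE when either
#'   hull has no m-dimensional volume, in which case volumes are NA).
#' @export
hull_intersection_volume <- function(points_a, points_b, m = 3) {
  A <- unique(as.matrix(points_a)[, seq_len(m), drop = FALSE])
  B <- unique(as.matrix(points_b)[, seq_len(m), drop = FALSE])
  if (nrow(A) <= m || nrow(B) <= m)
    return(list(v_a = NA_real_, v_b = NA_real_, v_shared = NA_real_,
                degenerate = TRUE))
  r <- if (m == 3) .hull3_pair_cpp(A, B)
       else if (m == 2) .hull2_pair_cpp(A, B)
       else stop("hull intersection supported for m = 2 or 3")
  list(v_a = r$va, v_b = r$vb, v_shared = r$vshared,
       degenerate = isTRUE(r$degenerate))
}

#' Decompose functional beta diversity into turnover and nestedness
#'
#' Given the hull volumes of two communities and their shared volume, the
#' Jaccard-family decomposition uses B = V_a - V_shared and
#' C = V_b - V_shared:
#' beta_total = (B + C) / (V_shared + B + C),
#' beta_turn = 2 min(B, C) / (V_shared + 2 min(B, C)),
#' beta_nest = beta_total - beta_turn.
#' The Sorensen family replaces the denominators by 2 V_shared + B + C and
#' V_shared + min(B, C) respectively.
#'
#' @param v_a,v_b,v_shared non-negative volumes, `v_shared <= min(v_a, v_b)`.
#' @param family `"jaccard"` (default) or `"sorensen"`.
#' @return list `beta_total`, `beta_turn`, `beta_nest` (all NA when all
#'   volumes are zero).
#' @export
beta_decompose <- function(v_a, v_b, v_shared, family = c("jaccard", "sorensen")) {
  family <- match.arg(family)
  if (anyNA(c(v_a, v_b, v_shared)))
    return(list(beta_total = NA_real_, beta_turn = NA_real_, beta_nest = NA_real_))
  tol <- 1e-8 * max(v_a, v_b, 1e-300)
  if (v_shared > min(v_a, v_b) + tol)
    stop("internal error: shared volume exceeds a hull volume")
  v_shared <- min(v_shared, v_a, v_b)
  b <- max(v_a - v_shared, 0)
  c_ <- max(v_b - v_shared, 0)
  if (v_shared + b + c_ <= 0)
    return(list(beta_total = NA_real_, beta_turn = NA_real_, beta_nest = NA_real_))
  mn <- min(b, c_)
  if (family == "jaccard") {
    total <- (b + c_) / (v_shared + b + c_)
    turn <- if (v_shared + 2 * mn > 0) 2 * mn / (v_shared + 2 * mn) else 0
  } else {
    total <- (b + c_) / (2 * v_shared + b + c_)
    turn <- if (v_shared + mn > 0) mn / (v_shared + mn) else 0
  }
  list(beta_total = total, beta_turn = turn, beta_nest = total - turn)
}

#' Functional beta diversity between paired communities
#'
#' For each site pair, the convex hulls of the upstream and downstream
#' communities are built in the first `m` axes of the functional space
#' (default `space$m_beta`, typically 3); their volumes and exact
#' intersection volume yield total functional beta diversity and its
#' turnover and nestedness-resultant components. Pairs in which either
#' community spans no m-dimensional hull (S <= m or a degenerate
#' configuration) are flagged undefined.
#'
#' @param comm site x taxon abundance matrix.
#' @param pairs data.frame with columns `pair_id`, `up_site`, `down_site`.
#' @param space a `functional_space`.
#' @param m number of axes (default `space$m_beta`).
#' @param family dissimilarity family, see [beta_decompose()].
#' @param coords optional coordinates overriding `space$coordinates` (null
#'   models).
#' @return data.frame of class `beta_result`: one row per pair with volumes
#'   `v_up`, `v_down`, `v_shared`, components `beta_total`, `beta_turn`,
#'   `beta_nest`, and `undefined`.
#' @export
beta_diversity <- function(comm, pairs, space, m = space$m_beta,
                           family = "jaccard", coords = NULL) {
  comm <- as.matrix(comm)
  X <- (coords %||% space$coordinates)[, seq_len(m), drop = FALSE]
  out <- data.frame(pair_id = pairs$pair_id,
                    v_up = NA_real_, v_down = NA_real_, v_shared = NA_real_,
                    beta_total = NA_real_, beta_turn = NA_real_,
                    beta_nest = NA_real_, undefined = TRUE,
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pairs))) {
    up <- comm[pairs$up_site[k], ]
    dn <- comm[pairs$down_site[k], ]
    hv <- hull_intersection_volume(X[names(up)[up > 0], , drop = FALSE],
                                   X[names(dn)[dn > 0], , drop = FALSE], m = m)
    out$v_up[k] <- hv$v_a
    out$v_down[k] <- hv$v_b
    out$v_shared[k] <- hv$v_shared
    if (!hv$degenerate) {
      bd <- beta_decompose(hv$v_a, hv$v_b, hv$v_shared, family = family)
      out$beta_total[k] <- bd$beta_total
      out$beta_turn[k] <- bd$beta_turn
      out$beta_nest[k] <- bd$beta_nest
      out$undefined[k] <- FALSE
    }
  }
  class(out) <- c("beta_result", "data.frame")
  out
}
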