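#' Trait-shuffling permutations
#'
#' Null communities keep the number of taxa and their abundances constant
#' and only change the functional categorisation: taxon labels are permuted
#' on the trait matrix over the full taxon pool, so the pool of possible
#' randomisations is not limited by community size. Permutations are drawn
#' independently per randomisation from a single seeded generator.
#'
#' @param n_taxa pool size.
#' @param R number of randomisations (default 999).
#' @param seed integer seed.
#' @return R x n_taxa integer matrix; row r maps taxon i to the trait row
#'   of taxon `perm[r, i]`.
#' @export
null_permutations <- function(n_taxa, R = 999, seed = 1) {
  set.seed(derive_seed(seed, 7L))
  t(vapply(seq_len(R), function(r) sample.int(n_taxa), integer(n_taxa)))
}

#' Apply a taxon-label permutation to a trait table
#'
#' @param traits a `trait_table`.
#' @param perm integer permutation of `seq_along(traits$taxa)`.
#' @return a `trait_table` in which taxon i carries the trait profile of
#'   taxon `perm[i]`; the row multiset is unchanged.
#' @export
shuffle_traits <- function(traits, perm) {
  stopifnot(inherits(traits, "trait_table"),
            length(perm) == length(traits$taxa))
  out <- traits
  out$affinities <- traits$affinities[perm, , drop = FALSE]
  rownames(out$affinities) <- traits$taxa
  if (!is.null(out$missing)) {
    out$missing <- traits$missing[perm, , drop = FALSE]
    rownames(out$missing) <- traits$taxa
  }
  out
}

#' Standardised effect size and two-tailed Monte-Carlo test
#'
#' SES = (observed - mean(null)) / sd(null). The two-tailed p-value uses
#' the add-one rank convention,
#' p = 2 min(1 + #\{null <= obs\}, 1 + #\{null >= obs\}) / (R + 1), capped
#' at 1, so an observation beyond all R = 999 null values gets
#' p = 2/1000 = 0.002 and p is never exactly zero.
#'
#' @param observed observed metric value.
#' @param null_values numeric vector of null metric values (NAs dropped).
#' @param alpha significance level (default 0.05).
#' @return list `ses`, `p`, `significant`, `null_mean`, `null_sd`, `R`.
#'   A degenerate null (sd = 0) or undefined observed value yields NA SES
#'   and `significant = FALSE`.
#' @export
ses_and_test <- function(observed, null_values, alpha = 0.05) {
  null_values <- null_values[!is.na(null_values)]
  R <- length(null_values)
  if (is.na(observed) || R < 2)
    return(list(ses = NA_real_, p = NA_real_, significant = FALSE,
                null_mean = NA_real_, null_sd = NA_real_, R = R))
  mu <- mean(null_values)
  s <- sd(null_values)
  if (s == 0)
    return(list(ses = NA_real_, p = NA_real_, significant = FALSE,
                null_mean = mu, null_sd = 0, R = R))
  p <- min(1, 2 * min(1 + sum(null_values <= observed),
                      1 + sum(null_values >= observed)) / (R + 1))
  list(ses = (observed - mu) / s, p = p, significant = p <= alpha,
       null_mean = mu, null_sd = s, R = R)
}

#' Fraction of units with significant departure from the null
#'
#' @param ensembles data.frame with logical column `significant` and a
#'   `ses` column whose NAs mark undefined units.
#' @param exclude_undefined drop undefined units from the denominator
#'   (default TRUE).
#' @return list `count`, `n`, `proportion`.
#' @export
significant_fraction <- function(ensembles, exclude_undefined = TRUE) {
  if (!nrow(ensembles)) stop("no ensembles supplied")
  keep <- if (exclude_undefined) !is.na(ensembles$ses) else rep(TRUE, nrow(ensembles))
  n <- sum(keep)
  count <- sum(ensembles$significant[keep], na.rm = TRUE)
  list(count = count, n = n, proportion = if (n > 0) count / n else NA_real_)
}

#' Trait-shuffling null models for alpha and beta metrics
#'
#' Runs R randomisations in which taxon labels are permuted on the trait
#' matrix over the full pool; the same R shuffled tables are reused across
#' all metrics and units so results stay comparable. Because a label
#' permutation permutes the rows of the (fixed) pool distance matrix and
#' coordinates, null metrics are computed by row lookup without rebuilding
#' the functional space; the pool hull used to standardise FRic is
#' invariant under shuffling.
#'
#' @param comm site x taxon abundance matrix.
#' @param traits normalised, gap-filled `trait_table`.
#' @param space `functional_space` over the same taxa.
#' @param observed_alpha an `alpha_result` for the observed data.
#' @param pairs optional pair table; when supplied together with
#'   `observed_beta`, beta components get null ensembles too.
#' @param observed_beta a `beta_result` for the observed data.
#' @param R randomisations (default 999).
#' @param alpha significance level.
#' @param seed integer seed; determines all permutations.
#' @param workers parallel workers over randomisations (results are
#'   independent of the worker count because permutations are drawn up
#'   front).
#' @param metrics alpha metrics to test.
#' @param fric_standardize,family forwarded to the metric functions.
#' @return list of class `null_result`:
#'   `alpha` (site x metric ensemble table), `beta` (pair x component
#'   ensemble table or NULL), `R`, `alpha_level`.
#' @export
null_models <- function(comm, traits, space, observed_alpha,
                        pairs = NULL, observed_beta = NULL,
                        R = 999, alpha = 0.05, seed = 1, workers = 1,
                        metrics = c("fric", "feve", "fdis", "rao"),
                        fric_standardize = TRUE, family = "jaccard") {
  comm <- as.matrix(comm)
  taxa <- space_taxa <- rownames(space$coordinates)
  stopifnot(all(colnames(comm) %in% taxa))
  perms <- null_permutations(length(taxa), R = R, seed = seed)
  sites <- rownames(comm)
  pool_vol <- if ("fric" %in% metrics && fric_standardize)
    hull_volume(space$coordinates[, seq_len(space$m_alpha), drop = FALSE]) else NULL

  site_ab <- lapply(sites, function(s) { a <- comm[s, ]; a[a > 0] })
  names(site_ab) <- sites

  one_run <- function(r) {
    sig <- perms[r, ]
    coords_r <- space$coordinates[sig, , drop = FALSE]
    rownames(coords_r) <- taxa
    dist_r <- space$distance[sig, sig, drop = FALSE]
    dimnames(dist_r) <- list(taxa, taxa)
    am <- matrix(NA_real_, length(sites), length(metrics),
                 dimnames = list(sites, metrics))
    for (s in sites) {
      ab <- site_ab[[s]]
      if ("fric" %in% metrics)
        am[s, "fric"] <- fric(ab, space, standardize = fric_standardize,
                              pool_volume = pool_vol, coords = coords_r)
      if ("feve" %in% metrics) am[s, "feve"] <- feve(ab, space, coords = coords_r)
      if ("fdis" %in% metrics) am[s, "fdis"] <- fdis(ab, space, coords = coords_r)
      if ("rao" %in% metrics)
        am[s, "rao"] <- rao_simpson_redundancy(ab, dist_r)$rao
    }
    bm <- NULL
    if (!is.null(pairs)) {
      b <- beta_diversity(comm, pairs, space, family = family, coords = coords_r)
      bm <- as.matrix(b[, c("beta_total", "beta_turn", "beta_nest")])
    }
    list(alpha = am, beta = bm)
  }

  runs <- if (workers > 1)
    parallel::mclapply(seq_len(R), one_run, mc.cores = workers)
  else lapply(seq_len(R), one_run)

  alpha_tab <- do.call(rbind, lapply(metrics, function(m) {
    nulls <- vapply(runs, function(r) r$alpha[, m], numeric(length(sites)))
    if (length(sites) == 1) nulls <- matrix(nulls, nrow = 1)
    do.call(rbind, lapply(seq_along(sites), function(k) {
      obs <- observed_alpha$metrics[[m]][match(sites[k], observed_alpha$metrics$site)]
      st <- ses_and_test(obs, nulls[k, ], alpha = alpha)
      data.frame(site = sites[k], metric = m, observed = obs,
                 null_mean = st$null_mean, null_sd = st$null_sd,
                 ses = st$ses, p = st$p, significant = st$significant,
                 stringsAsFactors = FALSE)
    }))
  }))

  beta_tab <- NULL
  if (!is.null(pairs) && !is.null(observed_beta)) {
    comps <- c("beta_total", "beta_turn", "beta_nest")
    beta_tab <- do.call(rbind, lapply(comps, function(cc) {
      nulls <- vapply(runs, function(r) r$beta[, cc], numeric(nrow(pairs)))
      if (nrow(pairs) == 1) nulls <- matrix(nulls, nrow = 1)
      do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
        obs <- observed_beta[[cc]][match(pairs$pair_id[k], observed_beta$pair_id)]
        st <- ses_and_test(obs, nulls[k, ], alpha = alpha)
        data.frame(pair_id = pairs$pair_id[k], component = cc, observed = obs,
                   null_mean = st$null_mean, null_sd = st$null_sd,
                   ses = st$ses, p = st$p, significant = st$significant,
                   stringsAsFactors = FALSE)
      }))
    }))
  }

  structure(list(alpha = alpha_tab, beta = beta_tab, R = R, alpha_level = alpha),
            class = "null_result")
}
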