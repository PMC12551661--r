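# One-sample Wilcoxon signed-rank test of d against zero. Zeros are dropped
# (Wilcoxon convention); for n <= max_exact the null distribution of the
# signed-rank statistic V is enumerated over all 2^n sign patterns on the
# observed (mid)ranks, which stays exact under tied magnitudes; larger
# samples fall back to the normal approximation of stats::wilcox.test().
wilcox_signed <- function(d, max_exact = 14L) {
  d <- d[!is.na(d) & d != 0]
  n <- length(d)
  if (!n) return(list(statistic = NA_real_, p = 1))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (n <= max_exact) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    vals <- as.vector(signs %*% r)
    p <- min(1, 2 * min(mean(vals <= v), mean(vals >= v)))
  } else {
    p <- suppressWarnings(wilcox.test(d, mu = 0, exact = FALSE)$p.value)
  }
  list(statistic = v, p = p)
}

#' Delta-CWM and one-sample Wilcoxon tests per trait modality
#'
#' The paired design is summarised per modality as
#' delta = CWM(upstream) - CWM(downstream); each modality's deltas are
#' tested against zero with a one-sample Wilcoxon signed-rank test, exact
#' by sign-pattern enumeration for up to 14 non-zero deltas (valid under
#' ties) and a normal approximation beyond. Because group
#' CWMs each sum to 1, deltas within a trait group sum to 0 for every pair.
#' P-values are reported uncorrected by default, mirroring per-modality
#' reporting practice; `p_adjust = "BH"` applies Benjamini-Hochberg.
#'
#' @param cwm_up,cwm_down pair-aligned site x modality CWM matrices
#'   (row k of each belongs to pair k).
#' @param alpha significance level (default 0.05).
#' @param p_adjust `"none"` (default) or a method for [stats::p.adjust()].
#' @return list of class `delta_cwm`: `delta` (pair x modality matrix) and
#'   `tests` (data.frame: modality, median_delta, statistic, p, p_adjusted,
#'   significant; all-zero modalities are flagged undefined).
#' @export
delta_cwm_tests <- function(cwm_up, cwm_down, alpha = 0.05, p_adjust = "none") {
  stopifnot(all(dim(cwm_up) == dim(cwm_down)))
  delta <- cwm_up - cwm_down
  mods <- colnames(delta)
  tests <- do.call(rbind, lapply(mods, function(m) {
    d <- delta[, m]
    if (all(d == 0) || all(is.na(d)))
      return(data.frame(modality = m, median_delta = 0, statistic = NA_real_,
                        p = NA_real_, undefined = TRUE))
    wt <- wilcox_signed(d)
    data.frame(modality = m, median_delta = median(d),
               statistic = wt$statistic, p = wt$p,
               undefined = FALSE)
  }))
  tests$p_adjusted <- if (p_adjust == "none") tests$p else
    stats::p.adjust(tests$p, method = p_adjust)
  tests$significant <- !tests$undefined & !is.na(tests$p_adjusted) &
    tests$p_adjusted < alpha
  structure(list(delta = delta, tests = tests, alpha = alpha,
                 p_adjust = p_adjust), class = "delta_cwm")
}

#' Paired Wilcoxon test of a metric between upstream and downstream sites
#'
#' Pairs in which the metric is undefined for either member are excluded
#' (and counted); fewer than 3 usable pairs is an error. Identical up- and
#' downstream values in every pair yield p = 1 by convention.
#'
#' @param up,down numeric vectors aligned by pair.
#' @return list `statistic`, `p`, `n_used`, `n_excluded`.
#' @export
paired_tests <- function(up, down) {
  stopifnot(length(up) == length(down))
  ok <- !is.na(up) & !is.na(down)
  n_used <- sum(ok)
  if (n_used < 3)
    stop("fewer than 3 usable pairs; paired test refused")
  d <- up[ok] - down[ok]
  if (all(d == 0))
    return(list(statistic = NA_real_, p = 1, n_used = n_used,
                n_excluded = length(up) - n_used))
  wt <- wilcox_signed(d)
  list(statistic = wt$statistic, p = wt$p,
       n_used = n_used, n_excluded = length(up) - n_used)
}

#' Spearman correlations of beta SES with WWTP covariates
#'
#' Correlates each beta-diversity SES component with treatment-plant
#' characteristics: connected households and population equivalents on
#' their raw scale, effluent BOD, ammonium and total phosphorus after
#' natural-log transformation (zeros are offset by half the minimum
#' positive value before logging; rank correlations are invariant to any
#' monotone transform, so this only matters for reporting).
#'
#' @param beta_ses data.frame with `pair_id`, `component`, `ses` (the beta
#'   table of a `null_result`).
#' @param pairs pair table with covariate columns `households`, `pop_eq`,
#'   `bod`, `nh4`, `tp`.
#' @return data.frame: component x covariate rows with Spearman `rho` and
#'   `p` (tie-corrected, asymptotic); constant covariates yield NA and are
#'   flagged.
#' @export
covariate_correlations <- function(beta_ses, pairs) {
  covs <- c(households = FALSE, pop_eq = FALSE, bod = TRUE, nh4 = TRUE, tp = TRUE)
  log_offset <- function(x) {
    if (any(x <= 0, na.rm = TRUE)) {
      mp <- min(x[x > 0], na.rm = TRUE)
      x[x <= 0] <- mp / 2
    }
    log(x)
  }
  out <- list()
  for (comp in unique(beta_ses$component)) {
    sub <- beta_ses[beta_ses$component == comp, ]
    v <- sub$ses[match(pairs$pair_id, sub$pair_id)]
    for (cv in names(covs)) {
      x <- pairs[[cv]]
      if (covs[[cv]]) x <- log_offset(x)
      ok <- !is.na(v) & !is.na(x)
      if (sum(ok) < 3 || length(unique(x[ok])) < 2 || length(unique(v[ok])) < 2) {
        out[[length(out) + 1]] <- data.frame(component = comp, covariate = cv,
                                             rho = NA_real_, p = NA_real_,
                                             n = sum(ok), undefined = TRUE)
        next
      }
      ct <- suppressWarnings(cor.test(v[ok], x[ok], method = "spearman",
                                      exact = FALSE))
      out[[length(out) + 1]] <- data.frame(component = comp, covariate = cv,
                                           rho = unname(ct$estimate),
                                           p = ct$p.value, n = sum(ok),
                                           undefined = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Subset to EPT-dominated site pairs
#'
#' Retains the pairs whose upstream community holds at least `threshold`
#' (default 0.5, boundary inclusive) EPT individuals. The functional space
#' must be reconstructed from the subset's communities before re-running
#' metrics: this function only selects, [run_pipeline()] performs the
#' rebuild.
#'
#' @param comm site x taxon abundance matrix.
#' @param pairs pair table (`pair_id`, `up_site`, `down_site`, ...).
#' @param ept_flags named logical vector over taxa.
#' @param threshold minimum upstream EPT proportion (default 0.5).
#' @return list: `pairs` (subset pair table with an `ept_up` proportion
#'   column), `sites` (character: the subset's community ids), `comm`
#'   (subset community matrix restricted to taxa present in it).
#' @export
ept_subset <- function(comm, pairs, ept_flags, threshold = 0.5) {
  comm <- as.matrix(comm)
  prop_up <- vapply(seq_len(nrow(pairs)), function(k)
    ept_proportion(comm[pairs$up_site[k], ], ept_flags), numeric(1))
  keep <- prop_up >= threshold
  sub <- pairs[keep, , drop = FALSE]
  sub$ept_up <- prop_up[keep]
  sites <- unique(c(sub$up_site, sub$down_site))
  sc <- comm[sites, , drop = FALSE]
  sc <- sc[, colSums(sc) > 0, drop = FALSE]
  list(pairs = sub, sites = sites, comm = sc)
}
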