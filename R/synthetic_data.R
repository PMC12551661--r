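#' Define a synthetic paired-community scenario
#'
#' Describes the study design the generator emulates: a regional taxon pool
#' with fuzzy-coded traits in nine groups totalling 49 modalities, paired
#' upstream/downstream communities around treatment plants, an EPT-dominance
#' gradient, treatment-plant covariates whose effluent concentrations rise
#' as plant size class falls, and an optional known downstream
#' trait-filtering effect: taxa with affinity >= 0.5 for
#' `effect_modality` have their downstream expected abundance multiplied by
#' `effect_strength` (0 = extirpation, 1 = no effect).
#'
#' @param n_pairs number of site pairs (default 169).
#' @param pool_size taxa in the regional pool (default 444).
#' @param n_trait_groups number of trait groups (default 9).
#' @param modalities_per_group integer vector (entries >= 2) summing to the
#'   total modality count (default totals 49).
#' @param ept_fraction proportion of pool taxa flagged EPT (default 0.35).
#' @param dominance_alpha Dirichlet concentration of community abundance
#'   profiles (default 0.6; smaller = more dominance).
#' @param richness_range \[min, max\] taxa per community (default 15-55).
#' @param effect_modality modality column name or index filtered
#'   downstream, or NULL for no effect.
#' @param effect_strength multiplicative downstream abundance penalty in
#'   \[0, 1\] for high-affinity taxa (default 1 = no effect).
#' @param n_ept_dominant optionally force this many pairs to be
#'   EPT-dominated upstream (their EPT share is rescaled to a random target
#'   in \[0.55, 0.95\]).
#' @param ept_mult_sd log-scale SD of the per-pair EPT sampling-weight
#'   multiplier that creates the EPT-dominance gradient (default 0.8; 0
#'   switches the gradient off so only forced pairs are dominated).
#' @param uncoded_fraction fraction of pool taxa lacking species-level
#'   traits, to exercise gap-filling (default 0.25).
#' @param affinity_alpha Dirichlet concentration of fuzzy trait profiles
#'   (default 0.4).
#' @param affinity_scale integer fuzzy-coding scale (default 3, i.e. scores
#'   0-3 before normalisation).
#' @param share_intermediate reuse each pair's downstream site as the next
#'   pair's upstream site (dual-role intermediate sites; default FALSE).
#' @param total_mu,total_size negative-binomial mean and size of community
#'   totals (default 500 individuals, size 5).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the scenario.
#' @return validated list of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(n_pairs = 169, pool_size = 444,
                               n_trait_groups = 9,
                               modalities_per_group = c(5, 6, 5, 6, 6, 5, 6, 5, 5),
                               ept_fraction = 0.35, dominance_alpha = 0.6,
                               richness_range = c(15, 55),
                               effect_modality = NULL, effect_strength = 1,
                               n_ept_dominant = NULL, ept_mult_sd = 0.8,
                               uncoded_fraction = 0.25, affinity_alpha = 0.4,
                               affinity_scale = 3L,
                               share_intermediate = FALSE,
                               total_mu = 500, total_size = 5, seed = 1) {
  if (length(modalities_per_group) != n_trait_groups)
    stop("invalid scenario: modalities_per_group must have n_trait_groups entries")
  if (any(modalities_per_group < 2))
    stop("invalid scenario: every trait group needs >= 2 modalities")
  if (ept_fraction < 0 || ept_fraction > 1)
    stop("invalid scenario: ept_fraction must lie in [0, 1]")
  if (effect_strength < 0 || effect_strength > 1)
    stop("invalid scenario: effect_strength must lie in [0, 1]")
  if (richness_range[1] < 4 || richness_range[2] > pool_size ||
      richness_range[1] > richness_range[2])
    stop("invalid scenario: richness_range out of bounds")
  structure(list(n_pairs = n_pairs, pool_size = pool_size,
                 n_trait_groups = n_trait_groups,
                 modalities_per_group = modalities_per_group,
                 ept_fraction = ept_fraction, dominance_alpha = dominance_alpha,
                 richness_range = richness_range,
                 effect_modality = effect_modality,
                 effect_strength = effect_strength,
                 n_ept_dominant = n_ept_dominant,
                 ept_mult_sd = ept_mult_sd,
                 uncoded_fraction = uncoded_fraction,
                 affinity_alpha = affinity_alpha,
                 affinity_scale = as.integer(affinity_scale),
                 share_intermediate = isTRUE(share_intermediate),
                 total_mu = total_mu, total_size = total_size,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

rdirichlet1 <- function(n, alpha, k) {
  g <- matrix(rgamma(n * k, shape = alpha), n, k)
  g / rowSums(g)
}

#' Generate the trait table, taxonomy and EPT flags for a scenario
#'
#' Taxa are organised into a three-level taxonomy (family > genus >
#' species); per trait group, affinities are drawn from a Dirichlet,
#' fuzzy-discretised to an integer 0-`affinity_scale` score, and meant to be
#' normalised downstream by [normalize_fuzzy()]. A configurable fraction of
#' taxa lacks species-level traits (their score rows are zero), exercising
#' [fill_gaps()]; at least one taxon per family stays coded so every taxon
#' remains resolvable. EPT membership is assigned by family until the
#' target pool fraction is reached.
#'
#' @param scenario a `synthetic_scenario`.
#' @return list: `traits` (raw `trait_table`, zeros for uncoded taxa),
#'   `true_traits` (normalised table with no gaps: the generator's ground
#'   truth), `taxonomy` (`taxonomy_table`), `ept` (named logical),
#'   `scenario`.
#' @export
generate_trait_table <- function(scenario) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(derive_seed(scenario$seed, 1L))
  n <- scenario$pool_size

  # taxonomy: families of 1-4 genera, genera of 1-6 species
  fam <- character(n); gen <- character(n)
  i <- 1L; fi <- 0L
  while (i <= n) {
    fi <- fi + 1L
    fname <- sprintf("fam%03d", fi)
    for (g in seq_len(sample(1:4, 1))) {
      gname <- sprintf("%s_gen%d", fname, g)
      for (s in seq_len(sample(1:6, 1))) {
        if (i > n) break
        fam[i] <- fname; gen[i] <- gname; i <- i + 1L
      }
      if (i > n) break
    }
  }
  taxa <- sprintf("sp%04d", seq_len(n))
  taxonomy <- taxonomy_table(taxa, gen, fam, rep("species", n))

  # EPT flags by family
  fams <- unique(fam)
  ept <- setNames(rep(FALSE, n), taxa)
  for (f in sample(fams)) {
    if (mean(ept) >= scenario$ept_fraction) break
    ept[fam == f] <- TRUE
  }

  # fuzzy trait scores per group
  nmod <- sum(scenario$modalities_per_group)
  groups <- rep(sprintf("grp%d", seq_len(scenario$n_trait_groups)),
                scenario$modalities_per_group)
  mods <- unlist(lapply(seq_len(scenario$n_trait_groups), function(g)
    sprintf("grp%d_m%d", g, seq_len(scenario$modalities_per_group[g]))))
  A <- matrix(0L, n, nmod, dimnames = list(taxa, mods))
  col0 <- 0L
  for (g in seq_len(scenario$n_trait_groups)) {
    k <- scenario$modalities_per_group[g]
    pr <- rdirichlet1(n, scenario$affinity_alpha, k)
    sc <- round(pr * scenario$affinity_scale)
    allz <- rowSums(sc) == 0
    if (any(allz)) {
      am <- max.col(pr[allz, , drop = FALSE])
      sc[cbind(which(allz), am)] <- 1L
    }
    A[, col0 + seq_len(k)] <- sc
    col0 <- col0 + k
  }

  true_traits <- normalize_fuzzy(trait_table(A, groups))

  # remove species-level coding for a fraction of taxa (first taxon of each
  # family is always kept coded so families stay resolvable)
  keep_coded <- !duplicated(fam)
  n_uncoded <- round(scenario$uncoded_fraction * n)
  cand <- which(!keep_coded)
  uncoded <- sample(cand, min(n_uncoded, length(cand)))
  A_obs <- A
  A_obs[uncoded, ] <- 0L
  traits <- trait_table(A_obs, groups)

  list(traits = traits, true_traits = true_traits, taxonomy = taxonomy,
       ept = ept, scenario = scenario)
}

#' Generate paired communities, pair table and covariates for a scenario
#'
#' Each pair gets an upstream community (richness uniform on
#' `richness_range`, relative abundances Dirichlet, counts multinomial with
#' a negative-binomial total) and a downstream community resampled from the
#' upstream relative abundances after applying the trait-filtering penalty,
#' which couples the pair as in the sampling design. Treatment-plant size
#' classes follow the empirical frequency of a five-class system and
#' covariates are drawn lognormally with class-specific means/SDs in which
#' effluent BOD, ammonium and total phosphorus increase as size class
#' decreases.
#'
#' @param scenario a `synthetic_scenario`.
#' @param trait_gen output of [generate_trait_table()] for the same
#'   scenario.
#' @return list of class `synthetic_dataset`: `comm` (site x taxon counts),
#'   `sites` (site metadata), `pairs` (pair table with covariates),
#'   `ground_truth` (penalised taxa, effect sign), plus `traits`,
#'   `true_traits`, `taxonomy`, `ept`, `scenario` carried through.
#' @export
generate_pairs <- function(scenario, trait_gen) {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  set.seed(derive_seed(scenario$seed, 2L))
  n <- scenario$pool_size
  taxa <- trait_gen$true_traits$taxa
  np <- scenario$n_pairs

  # class-conditional covariate moments (means, SDs) for a five-class
  # size system; effluent concentrations increase with decreasing class
  cls_prob <- c(23, 47, 25, 70, 4) / 169
  mom <- list(
    households = cbind(c(536, 2253, 5990, 23553, 166000),
                       c(263, 931, 2346, 13322, 73539)),
    pop_eq = cbind(c(590, 2779, 7615, 34455, 248750),
                   c(291, 1017, 1496, 19333, 85865)),
    bod = cbind(c(10.8, 6.9, 4.4, 3.6, 3.8), c(11, 5.1, 1.8, 1.7, 0.8)),
    nh4 = cbind(c(7.1, 4.8, 1.3, 1.1, 0.8), c(9.4, 5.5, 1.1, 1.0, 0.6)),
    tp = cbind(c(2.5, 1.8, 1.7, 0.7, 0.4), c(2.4, 0.9, 1.0, 0.4, 0.2)))
  rlnorm_match <- function(m, s) {
    sdlog <- sqrt(log(1 + (s / m)^2))
    stats::rlnorm(length(m), log(m) - sdlog^2 / 2, sdlog)
  }
  size_class <- sample(1:5, np, replace = TRUE, prob = cls_prob)
  covs <- lapply(mom, function(ms)
    rlnorm_match(ms[size_class, 1], ms[size_class, 2]))

  # downstream penalty from the generator's true (gap-free) profiles
  penalty <- rep(1, n)
  penalized <- character(0)
  if (!is.null(scenario$effect_modality)) {
    aff <- trait_gen$true_traits$affinities[, scenario$effect_modality]
    penalized <- taxa[aff >= 0.5]
    penalty[aff >= 0.5] <- scenario$effect_strength
  }

  forced <- if (!is.null(scenario$n_ept_dominant))
    sample(np, min(scenario$n_ept_dominant, np)) else integer(0)
  ept_mult <- stats::rlnorm(np, 0, scenario$ept_mult_sd %||% 0.8)

  up_id <- sprintf("P%03d_up", seq_len(np))
  dn_id <- sprintf("P%03d_down", seq_len(np))
  if (scenario$share_intermediate && np > 1)
    up_id[2:np] <- dn_id[1:(np - 1)]

  sites <- unique(c(rbind(up_id, dn_id)))
  comm <- matrix(0, length(sites), n, dimnames = list(sites, taxa))
  exp_delta <- numeric(np)
  a_eff <- if (length(penalized))
    trait_gen$true_traits$affinities[, scenario$effect_modality] else NULL

  rtotal <- function() rnbinom(1, mu = scenario$total_mu,
                               size = scenario$total_size) +
    scenario$richness_range[2]

  for (i in seq_len(np)) {
    if (scenario$share_intermediate && i > 1) {
      rel_up <- comm[up_id[i], ] / sum(comm[up_id[i], ])
      members <- which(rel_up > 0)
      rel <- rel_up[members]
    } else {
      S <- sample(scenario$richness_range[1]:scenario$richness_range[2], 1)
      w <- rep(1, n)
      w[trait_gen$ept] <- ept_mult[i]
      members <- sample.int(n, S, prob = w)
      if (i %in% forced && !any(trait_gen$ept[members]) && any(trait_gen$ept)) {
        # a forced EPT-dominated pair needs EPT members to rescale
        epool <- which(trait_gen$ept)
        k <- min(length(epool), max(1L, round(S / 3)))
        members[seq_len(k)] <- sample(epool, k)
        members <- unique(members)
        S <- length(members)
      }
      rel <- as.vector(rdirichlet1(1, scenario$dominance_alpha, S))
      if (i %in% forced) {
        is_e <- trait_gen$ept[members]
        if (any(is_e) && any(!is_e)) {
          target <- runif(1, 0.55, 0.95)
          se <- sum(rel[is_e])
          if (se > 0 && se < target) {
            rel[is_e] <- rel[is_e] * (target / se)
            rel[!is_e] <- rel[!is_e] * ((1 - target) / (1 - se))
          }
        }
      }
      cnt <- rmultinom(1, rtotal(), rel)[, 1]
      comm[up_id[i], members] <- comm[up_id[i], members] + cnt
      rel_up <- comm[up_id[i], ] / sum(comm[up_id[i], ])
      members <- which(rel_up > 0)
      rel <- rel_up[members]
    }
    q <- rel * penalty[members]
    if (sum(q) <= 0)
      stop("effect extirpates the whole community; weaken effect_strength")
    q <- q / sum(q)
    cnt_dn <- rmultinom(1, rtotal(), q)[, 1]
    comm[dn_id[i], members] <- cnt_dn
    if (!is.null(a_eff))
      exp_delta[i] <- sum(rel * a_eff[members]) - sum(q * a_eff[members])
  }

  site_meta <- data.frame(
    site = sites,
    pair_id = NA_character_, position = NA_character_,
    stringsAsFactors = FALSE)
  # a dual-role site belongs to two pairs; record its first role here, the
  # pair table carries the full assignment
  for (i in seq_len(np)) {
    k <- match(up_id[i], site_meta$site)
    if (is.na(site_meta$position[k])) {
      site_meta$pair_id[k] <- sprintf("P%03d", i)
      site_meta$position[k] <- "upstream"
    }
    k <- match(dn_id[i], site_meta$site)
    if (is.na(site_meta$position[k])) {
      site_meta$pair_id[k] <- sprintf("P%03d", i)
      site_meta$position[k] <- "downstream"
    }
  }

  pairs <- data.frame(pair_id = sprintf("P%03d", seq_len(np)),
                      up_site = up_id, down_site = dn_id,
                      size_class = size_class,
                      households = covs$households, pop_eq = covs$pop_eq,
                      bod = covs$bod, nh4 = covs$nh4, tp = covs$tp,
                      stringsAsFactors = FALSE)

  gt <- list(effect_modality = scenario$effect_modality,
             effect_strength = scenario$effect_strength,
             penalized_taxa = penalized,
             expected_delta_cwm = if (length(penalized)) mean(exp_delta) else 0,
             expected_sign = if (length(penalized) && scenario$effect_strength < 1)
               1 else 0)

  structure(list(comm = comm, sites = site_meta, pairs = pairs,
                 ground_truth = gt,
                 traits = trait_gen$traits, true_traits = trait_gen$true_traits,
                 taxonomy = trait_gen$taxonomy, ept = trait_gen$ept,
                 scenario = scenario),
            class = "synthetic_dataset")
}

#' Generate a full synthetic dataset from a scenario
#'
#' @param scenario a `synthetic_scenario`.
#' @return a `synthetic_dataset`, see [generate_pairs()].
#' @export
generate_dataset <- function(scenario) {
  generate_pairs(scenario, generate_trait_table(scenario))
}
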