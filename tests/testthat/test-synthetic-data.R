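# Synthetic paired-community generator: structure, determinism, effect.

test_that("the default scenario mirrors the study's trait structure", {
  sc <- synthetic_scenario()
  expect_equal(sc$n_trait_groups, 9)
  expect_equal(sum(sc$modalities_per_group), 49)
  expect_equal(sc$pool_size, 444)
  expect_equal(sc$n_pairs, 169)
  tg <- generate_trait_table(quick_scenario())
  expect_equal(ncol(tg$traits$affinities), sum(quick_scenario()$modalities_per_group))
  expect_equal(length(unique(tg$traits$groups)), 3)
  # per-group profiles of the ground-truth table are relative frequencies
  gidx <- trait_group_index(tg$true_traits)
  for (g in names(gidx))
    expect_true(all(abs(rowSums(tg$true_traits$affinities[, gidx[[g]]]) - 1) < 1e-12))
})

test_that("invalid scenarios are rejected", {
  expect_error(synthetic_scenario(n_trait_groups = 2,
                                  modalities_per_group = c(1, 3)), "invalid")
  expect_error(synthetic_scenario(modalities_per_group = c(5, 5)), "invalid")
  expect_error(synthetic_scenario(effect_strength = 1.5), "invalid")
  expect_error(synthetic_scenario(ept_fraction = -0.1), "invalid")
})

test_that("generation is deterministic under the scenario seed", {
  sc <- quick_scenario()
  d1 <- generate_dataset(sc)
  d2 <- generate_dataset(sc)
  expect_identical(d1$comm, d2$comm)
  expect_identical(d1$traits$affinities, d2$traits$affinities)
  expect_identical(d1$pairs, d2$pairs)
  d3 <- generate_dataset(synthetic_scenario(n_pairs = 10, pool_size = 60,
                                            modalities_per_group = c(3, 4, 2),
                                            n_trait_groups = 3,
                                            richness_range = c(8, 16), seed = 99))
  expect_false(identical(d1$comm, d3$comm))
})

test_that("a 169-pair scenario yields 338 community rows", {
  sc <- synthetic_scenario(n_pairs = 169, pool_size = 120,
                           modalities_per_group = c(3, 4, 2), n_trait_groups = 3,
                           richness_range = c(8, 16), seed = 2)
  ds <- generate_dataset(sc)
  expect_equal(nrow(ds$comm), 338)
  expect_equal(nrow(ds$pairs), 169)
  expect_true(all(rowSums(ds$comm) > 0))
})

test_that("extirpation removes every high-affinity taxon downstream", {
  sc <- quick_scenario(effect_modality = "grp2_m1", effect_strength = 0)
  ds <- generate_dataset(sc)
  pen <- ds$ground_truth$penalized_taxa
  expect_gt(length(pen), 0)
  down <- ds$comm[ds$pairs$down_site, pen, drop = FALSE]
  expect_true(all(down == 0))
  # and high-affinity means affinity >= 0.5 on the target modality
  expect_true(all(ds$true_traits$affinities[pen, "grp2_m1"] >= 0.5))
})

test_that("no-effect pairs are exchangeable up/down at the CWM level", {
  # under effect_strength = 1 both members are multinomial resamples of the
  # same profile: the mean delta CWM across many pairs is ~0
  sc <- synthetic_scenario(n_pairs = 60, pool_size = 100,
                           modalities_per_group = c(4, 4), n_trait_groups = 2,
                           richness_range = c(10, 25), uncoded_fraction = 0,
                           seed = 31)
  ds <- generate_dataset(sc)
  tt <- normalize_fuzzy(ds$traits)
  gf <- fill_gaps(tt, ds$taxonomy, colnames(ds$comm))
  cw <- t(apply(ds$comm, 1, function(ab) cwm(ab[ab > 0], gf$traits)))
  delta <- cw[ds$pairs$up_site, ] - cw[ds$pairs$down_site, ]
  # every modality's mean delta within 3 SE of zero
  z <- colMeans(delta) / (apply(delta, 2, sd) / sqrt(nrow(delta)))
  expect_true(all(abs(z) < 4))
  expect_equal(ds$ground_truth$expected_sign, 0)
})

test_that("forced EPT dominance produces the requested subset", {
  sc <- synthetic_scenario(n_pairs = 20, pool_size = 100,
                           modalities_per_group = c(4, 4), n_trait_groups = 2,
                           richness_range = c(10, 25), ept_fraction = 0.15,
                           ept_mult_sd = 0, n_ept_dominant = 6, seed = 33)
  ds <- generate_dataset(sc)
  prop <- vapply(seq_len(nrow(ds$pairs)), function(k)
    ept_proportion(ds$comm[ds$pairs$up_site[k], ], ds$ept), numeric(1))
  expect_equal(sum(prop >= 0.5), 6)
})

test_that("dual-role intermediate sites are shared between neighbouring pairs", {
  sc <- quick_scenario(share_intermediate = TRUE)
  ds <- generate_dataset(sc)
  expect_equal(ds$pairs$up_site[2], ds$pairs$down_site[1])
  expect_equal(nrow(ds$comm), sc$n_pairs + 1)  # chain of shared sites
  # covariates from the size-class model are positive and present
  expect_true(all(ds$pairs$bod > 0 & ds$pairs$tp > 0 & ds$pairs$households > 0))
})

test_that("effluent covariates increase as size class decreases", {
  sc <- synthetic_scenario(n_pairs = 400, pool_size = 60,
                           modalities_per_group = c(3, 3), n_trait_groups = 2,
                           richness_range = c(8, 16), seed = 35)
  ds <- generate_pairs(sc, generate_trait_table(quick_scenario()))
  m <- aggregate(cbind(bod, nh4, tp, households) ~ size_class, ds$pairs, mean)
  expect_lt(cor(m$size_class, m$bod, method = "spearman"), 0)
  expect_lt(cor(m$size_class, m$nh4, method = "spearman"), 0)
  expect_gt(cor(m$size_class, m$households, method = "spearman"), 0)
})
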