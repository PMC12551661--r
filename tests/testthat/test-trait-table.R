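# Fuzzy-trait normalisation, taxonomic gap-filling, EPT proportions.

toy_raw <- function() {
  A <- rbind(sp1 = c(3, 1, 0, 2, 2),
             sp2 = c(0, 0, 0, 1, 1),
             sp3 = c(1, 1, 2, 0, 4))
  colnames(A) <- c("g1a", "g1b", "g1c", "g2a", "g2b")
  trait_table(A, c("g1", "g1", "g1", "g2", "g2"))
}

test_that("normalisation scales each group to relative frequencies", {
  tn <- normalize_fuzzy(toy_raw())
  expect_equal(unname(tn$affinities["sp1", 1:3]), c(0.75, 0.25, 0))
  expect_equal(unname(tn$affinities["sp1", 4:5]), c(0.5, 0.5))
  # all-zero group flagged missing, left at zero
  expect_true(tn$missing["sp2", "g1"])
  expect_equal(unname(tn$affinities["sp2", 1:3]), c(0, 0, 0))
  # idempotent
  tn2 <- normalize_fuzzy(tn)
  expect_equal(tn2$affinities, tn$affinities)
})

test_that("group-wise row sums are 1 after normalisation (property)", {
  set.seed(8)
  for (rep in 1:5) {
    A <- matrix(rpois(20 * 7, 2), 20, 7,
                dimnames = list(sprintf("t%02d", 1:20), sprintf("m%d", 1:7)))
    groups <- c("a", "a", "a", "b", "b", "c", "c")
    tn <- normalize_fuzzy(trait_table(A, groups))
    for (g in unique(groups)) {
      s <- rowSums(tn$affinities[, groups == g, drop = FALSE])
      expect_true(all(abs(s[!tn$missing[, g]] - 1) < 1e-12))
    }
  }
})

test_that("negative affinities are rejected", {
  A <- matrix(c(-1, 2, 1, 1), 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(trait_table(A, c("g", "g")), "negative")
})

test_that("gap-filling assigns the genus mean to an uncoded congener", {
  A <- rbind(sp1 = c(3, 1), sp2 = c(1, 3), sp3 = c(0, 0))
  colnames(A) <- c("m1", "m2")
  tn <- normalize_fuzzy(trait_table(A, c("g", "g")))
  taxo <- taxonomy_table(c("sp1", "sp2", "sp3"),
                         genus = c("gen1", "gen1", "gen1"),
                         family = c("fam1", "fam1", "fam1"),
                         level = rep("species", 3))
  gf <- fill_gaps(tn, taxo, community_taxa = c("sp1", "sp2", "sp3"))
  # sp3 raised to genus: mean of (0.75, 0.25) and (0.25, 0.75) = (0.5, 0.5)
  raised <- gf$mapping$final_taxon[gf$mapping$taxon == "sp3"]
  expect_equal(unname(gf$traits$affinities[raised, ]), c(0.5, 0.5))
  expect_equal(gf$mapping$resolved_level[gf$mapping$taxon == "sp3"], "genus")
})

test_that("fully coded pools pass through unchanged with 100% coverage", {
  A <- rbind(sp1 = c(3, 1), sp2 = c(1, 3))
  colnames(A) <- c("m1", "m2")
  tn <- normalize_fuzzy(trait_table(A, c("g", "g")))
  taxo <- taxonomy_table(c("sp1", "sp2"), c("gen1", "gen2"),
                         c("fam1", "fam1"), rep("species", 2))
  gf <- fill_gaps(tn, taxo, community_taxa = c("sp1", "sp2"))
  expect_equal(gf$traits$affinities[c("sp1", "sp2"), ], tn$affinities)
  expect_equal(gf$coverage$pct[gf$coverage$level == "original"], 100)
  expect_equal(length(gf$dropped), 0)
})

test_that("raising collapses taxa and conserves merged abundance", {
  # 10 community taxa designed to end as 7 final taxa:
  # sp03-sp05 (genus gc, none coded) -> family f1; sp09, sp10 (uncoded,
  # singleton genera) -> family f2; five coded species stay themselves
  taxa <- sprintf("sp%02d", 1:10)
  set.seed(7)
  A <- matrix(rpois(10 * 4, 3) + 1, 10, 4,
              dimnames = list(taxa, c("m1", "m2", "m3", "m4")))
  A[c(3, 4, 5), ] <- 0
  A[c(9, 10), ] <- 0
  groups <- c("g1", "g1", "g2", "g2")
  tn <- normalize_fuzzy(trait_table(A, groups))
  taxo <- taxonomy_table(
    taxa,
    genus = c("ga", "ga", "gc", "gc", "gc", "gd", "ge", "gf", "gg", "gh"),
    family = c(rep("f1", 5), rep("f2", 5)),
    level = rep("species", 10))
  gf <- fill_gaps(tn, taxo, community_taxa = taxa)
  expect_equal(gf$n_final, 7)  # sp03+sp04+sp05 -> f1, sp09+sp10 -> f2

  comm <- matrix(1:10, 1, 10, dimnames = list("s1", taxa))
  merged <- merge_by_mapping(comm, gf$mapping)
  expect_equal(sum(merged), sum(comm))       # abundance conserved
  f1_final <- gf$mapping$final_taxon[gf$mapping$taxon == "sp04"]
  expect_equal(unname(merged[1, f1_final]), 3 + 4 + 5)
  # the family profile is the mean over its coded descendants (sp01, sp02)
  expect_equal(unname(gf$traits$affinities[f1_final, ]),
               unname(colMeans(tn$affinities[c("sp01", "sp02"), ])))
})

test_that("gap-filling is order-independent", {
  set.seed(9)
  taxa <- sprintf("sp%02d", 1:12)
  A <- matrix(rpois(12 * 4, 2), 12, 4,
              dimnames = list(taxa, c("m1", "m2", "m3", "m4")))
  A[c(2, 7, 11), ] <- 0
  tn <- normalize_fuzzy(trait_table(A, c("g1", "g1", "g2", "g2")))
  taxo <- taxonomy_table(taxa,
                         genus = rep(c("g1", "g2", "g3"), each = 4),
                         family = rep(c("f1", "f2"), each = 6),
                         level = rep("species", 12))
  gf1 <- fill_gaps(tn, taxo, community_taxa = taxa)
  gf2 <- fill_gaps(tn, taxo, community_taxa = rev(taxa))
  common <- sort(rownames(gf1$traits$affinities))
  expect_equal(gf1$traits$affinities[common, ], gf2$traits$affinities[common, ])
})

test_that("unresolvable taxa are dropped with a warning, not silently", {
  A <- rbind(sp1 = c(1, 1), sp2 = c(0, 0))
  colnames(A) <- c("m1", "m2")
  tn <- normalize_fuzzy(trait_table(A, c("g", "g")))
  # sp2's genus and family contain no coded members
  taxo <- taxonomy_table(c("sp1", "sp2"), c("gen1", "gen2"),
                         c("fam1", "fam2"), rep("species", 2))
  expect_warning(gf <- fill_gaps(tn, taxo, community_taxa = c("sp1", "sp2")),
                 "sp2")
  expect_equal(gf$dropped, "sp2")
})

test_that("EPT proportion follows its definition and boundary rule", {
  ab <- c(a = 50, b = 50)
  flags <- c(a = TRUE, b = FALSE)
  expect_equal(ept_proportion(ab, flags), 0.5)
  expect_true(ept_proportion(ab, flags) >= 0.5)  # inclusive boundary
  expect_equal(ept_proportion(c(a = 10), c(a = TRUE)), 1)
  expect_equal(ept_proportion(c(a = 1, b = 3), c(a = TRUE, b = FALSE)), 0.25)
  expect_error(ept_proportion(c(a = 0, b = 0), flags), "undefined")
})
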