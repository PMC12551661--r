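# CWM, FRic, FEve, FDis, Rao's Q, Simpson, functional redundancy.

# small functional space built from explicit coordinates
space_from_coords <- function(X, D = NULL) {
  structure(list(coordinates = X,
                 distance = D %||% as.matrix(dist(X)),
                 m_alpha = ncol(X), m_beta = min(3, ncol(X))),
            class = "functional_space")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("CWM is the abundance-weighted trait profile", {
  A <- rbind(t1 = c(1, 0), t2 = c(0, 1), t3 = c(0.5, 0.5))
  colnames(A) <- c("m1", "m2")
  tt <- normalize_fuzzy(trait_table(A, c("g", "g")))
  # single taxon: profile itself
  expect_equal(unname(cwm(c(t1 = 5), tt)), c(1, 0))
  # equal-abundance midpoint
  expect_equal(unname(cwm(c(t1 = 2, t2 = 2), tt)), c(0.5, 0.5))
  # hand-computed weighted mean with abundances 1, 2, 7
  expected <- (1 * c(1, 0) + 2 * c(0, 1) + 7 * c(0.5, 0.5)) / 10
  expect_equal(unname(cwm(c(t1 = 1, t2 = 2, t3 = 7), tt)), expected)
  # group sums preserved
  expect_equal(sum(cwm(c(t1 = 1, t2 = 2, t3 = 7), tt)), 1)
  expect_error(cwm(c(t9 = 1), tt), "gap-fill")
})

test_that("FRic equals the convex-hull volume with pool standardisation", {
  X <- rbind(a = c(0, 0, 0), b = c(1, 0, 0), c = c(0, 1, 0), d = c(0, 0, 1),
             e = c(0.1, 0.1, 0.1))
  sp <- space_from_coords(X)
  # unit tetrahedron, unstandardised
  expect_equal(fric(c(a = 1, b = 1, c = 1, d = 1), sp, m = 3,
                    standardize = FALSE), 1 / 6, tolerance = 1e-12)
  # whole pool standardised to 1 (e is interior so the hull is unchanged)
  expect_equal(fric(setNames(rep(1, 5), rownames(X)), sp, m = 3), 1)
  # interior point does not change the volume
  expect_equal(fric(c(a = 1, b = 1, c = 1, d = 1, e = 1), sp, m = 3,
                    standardize = FALSE), 1 / 6, tolerance = 1e-12)
  # S <= m is undefined, flagged as NA
  expect_true(is.na(fric(c(a = 1, b = 1, c = 1), sp, m = 3)))
})

test_that("FEve is 1 for equally spaced, equally abundant taxa and drops with clumping", {
  X <- cbind(seq_len(5), 0)
  rownames(X) <- letters[1:5]
  sp <- space_from_coords(X)
  even <- setNames(rep(2, 5), letters[1:5])
  expect_equal(feve(even, sp), 1, tolerance = 1e-12)
  clumped <- setNames(c(20, 1, 1, 1, 20), letters[1:5])
  expect_lt(feve(clumped, sp), 1)
  expect_true(is.na(feve(c(a = 1, b = 1), sp)))
})

test_that("FEve agrees exactly with exhaustive spanning-tree enumeration", {
  set.seed(21)
  for (S in c(4, 5, 6, 7)) {
    X <- matrix(runif(S * 3), ncol = 3)
    rownames(X) <- sprintf("t%d", seq_len(S))
    sp <- space_from_coords(X)
    ab <- setNames(rgamma(S, 2) + 0.1, rownames(X))
    d <- as.matrix(dist(X))
    p <- ab / sum(ab)
    mst <- exhaustive_mst(d)
    expect_equal(feve(ab, sp), feve_from_tree(mst, d, p), tolerance = 1e-12)
  }
})

test_that("FDis follows its closed forms and invariances", {
  X <- rbind(a = c(0, 0), b = c(3, 0))
  sp <- space_from_coords(X)
  expect_equal(fdis(c(a = 1), sp), 0)
  expect_equal(fdis(c(a = 1, b = 1), sp), 1.5)  # d/2 for two equal taxa
  # translation invariance
  sp2 <- space_from_coords(sweep(X, 2, c(10, -4)))
  expect_equal(fdis(c(a = 2, b = 5), sp), fdis(c(a = 2, b = 5), sp2),
               tolerance = 1e-12)
})

test_that("Rao's Q, Simpson and redundancy satisfy the equal-distance identity", {
  set.seed(22)
  for (rep in 1:5) {
    S <- sample(3:8, 1)
    delta <- runif(1, 0.2, 0.9)
    D <- matrix(delta, S, S) - delta * diag(S)
    dimnames(D) <- list(sprintf("t%d", 1:S), sprintf("t%d", 1:S))
    ab <- setNames(rgamma(S, 1) + 0.05, rownames(D))
    r <- rao_simpson_redundancy(ab, D)
    # Q = delta * D_simpson, hence FR = delta exactly
    expect_equal(r$rao, delta * r$simpson, tolerance = 1e-12)
    expect_equal(r$redundancy, delta, tolerance = 1e-12)
  }
})

test_that("Rao's Q matches the double-loop oracle; degenerate cases flagged", {
  set.seed(23)
  S <- 6
  X <- matrix(runif(S * 3), ncol = 3)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(sprintf("t%d", 1:S), sprintf("t%d", 1:S))
  ab <- setNames(rgamma(S, 2), rownames(D))
  p <- ab / sum(ab)
  q_oracle <- 0
  for (i in 1:S) for (j in 1:S) q_oracle <- q_oracle + D[i, j] * p[i] * p[j]
  r <- rao_simpson_redundancy(ab, D)
  expect_equal(r$rao, unname(q_oracle), tolerance = 1e-12)
  expect_lte(r$rao, max(D) * r$simpson + 1e-12)
  # functionally identical taxa
  D0 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  r0 <- rao_simpson_redundancy(c(a = 1, b = 1, c = 1), D0)
  expect_equal(r0$rao, 0)
  expect_equal(r0$redundancy, 0)
  # monoculture: Simpson 0, redundancy undefined
  rm <- rao_simpson_redundancy(c(a = 4), D0)
  expect_true(is.na(rm$redundancy))
})

test_that("all alpha metrics are invariant to rescaling raw abundances", {
  set.seed(24)
  S <- 8
  X <- matrix(runif(S * 4), ncol = 4)
  rownames(X) <- sprintf("t%d", 1:S)
  sp <- space_from_coords(X)
  sp$m_alpha <- 3
  ab <- setNames(rpois(S, 6) + 1, rownames(X))
  for (f in list(feve, fdis)) {
    expect_equal(f(ab, sp), f(ab * 17, sp), tolerance = 1e-12)
  }
  expect_equal(fric(ab, sp, standardize = FALSE),
               fric(ab * 17, sp, standardize = FALSE), tolerance = 1e-12)
  r1 <- rao_simpson_redundancy(ab, sp$distance)
  r2 <- rao_simpson_redundancy(ab * 17, sp$distance)
  expect_equal(r1$rao, r2$rao, tolerance = 1e-12)
})

test_that("FRic agrees with Monte-Carlo volume estimates on random communities", {
  set.seed(25)
  for (rep in 1:4) {
    S <- sample(5:7, 1)
    X <- matrix(runif(S * 3), ncol = 3)
    rownames(X) <- sprintf("t%d", seq_len(S))
    sp <- space_from_coords(X)
    v <- fric(setNames(rep(1, S), rownames(X)), sp, m = 3, standardize = FALSE)
    if (is.na(v)) next
    mc <- mc_hull_volume(X, n_samples = 40000)
    expect_lt(abs(v - mc$volume), max(4 * mc$se, 0.02 * v))
  }
})

test_that("alpha_diversity assembles per-site metrics with NA flags", {
  set.seed(26)
  ds <- generate_dataset(quick_scenario())
  tn <- normalize_fuzzy(ds$traits)
  gf <- fill_gaps(tn, ds$taxonomy, colnames(ds$comm))
  comm <- merge_by_mapping(ds$comm, gf$mapping)
  keep <- colnames(comm)[colSums(comm) > 0]
  tt <- normalize_fuzzy(trait_table(gf$traits$affinities[keep, , drop = FALSE],
                                    gf$traits$groups, normalized = TRUE))
  space <- build_functional_space(tt)
  al <- alpha_diversity(comm[, keep], tt, space)
  expect_equal(nrow(al$metrics), nrow(comm))
  expect_true(all(al$metrics$simpson >= 0 & al$metrics$simpson < 1))
  expect_true(all(al$metrics$feve >= 0 & al$metrics$feve <= 1, na.rm = TRUE))
  expect_true(all(al$metrics$fric > 0 & al$metrics$fric <= 1, na.rm = TRUE))
  # CWM group sums are 1 for every site and group
  gidx <- trait_group_index(tt)
  for (g in names(gidx))
    expect_true(all(abs(rowSums(al$cwm[, gidx[[g]], drop = FALSE]) - 1) < 1e-12))
})
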