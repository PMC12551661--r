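# Gower dissimilarity, PCoA embedding, dimensionality quality, trait KDE.

test_that("Gower distance follows the per-group half-Manhattan block formula", {
  A <- rbind(t1 = c(1, 0, 0.5, 0.5),
             t2 = c(0, 1, 0.5, 0.5),
             t3 = c(0.5, 0.5, 1, 0))
  colnames(A) <- c("a1", "a2", "b1", "b2")
  tt <- trait_table(A, c("gA", "gA", "gB", "gB"), normalized = TRUE)
  tt <- normalize_fuzzy(tt)
  D <- gower_distance(tt)
  # hand computation: d(t1,t2) = mean(1, 0) = 0.5;
  # d(t1,t3) = mean(0.5, 0.5) = 0.5; d(t2,t3) = mean(0.5, 0.5) = 0.5
  expect_equal(unname(D["t1", "t2"]), 0.5)
  expect_equal(unname(D["t1", "t3"]), 0.5)
  expect_equal(unname(D["t2", "t3"]), 0.5)
  expect_equal(diag(D), setNames(rep(0, 3), rownames(A)))
})

test_that("Gower matches a brute-force double-loop oracle on random tables", {
  set.seed(12)
  A <- matrix(rpois(15 * 9, 2), 15, 9,
              dimnames = list(sprintf("t%02d", 1:15), sprintf("m%d", 1:9)))
  groups <- rep(c("g1", "g2", "g3"), each = 3)
  tt <- normalize_fuzzy(trait_table(A + 1, groups))  # +1 avoids all-zero groups
  D <- gower_distance(tt)
  expect_equal(D, gower_oracle(tt$affinities, groups), tolerance = 1e-12)
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
})

test_that("taxa concentrated on different modalities in every group are at distance 1", {
  A <- rbind(t1 = c(1, 0, 1, 0), t2 = c(0, 1, 0, 1))
  colnames(A) <- c("a1", "a2", "b1", "b2")
  tt <- normalize_fuzzy(trait_table(A, c("gA", "gA", "gB", "gB")))
  expect_equal(unname(gower_distance(tt)["t1", "t2"]), 1)
})

test_that("PCoA embeds Euclidean configurations exactly", {
  set.seed(13)
  X <- matrix(runif(14), ncol = 2)
  D <- as.matrix(dist(X))
  sp <- pcoa_space(D, correction = "none")
  Dhat <- as.matrix(dist(sp$coordinates))
  expect_equal(unname(Dhat), unname(D), tolerance = 1e-9)
  expect_lte(ncol(sp$coordinates), nrow(D) - 1)
})

test_that("equilateral three-point configuration has equal first two eigenvalues", {
  D <- matrix(1, 3, 3) - diag(3)
  dimnames(D) <- list(letters[1:3], letters[1:3])
  sp <- pcoa_space(D, correction = "none")
  expect_equal(sp$eigenvalues[1], sp$eigenvalues[2], tolerance = 1e-10)
})

test_that("full-dimensional embedding reproduces the corrected distances", {
  set.seed(14)
  A <- matrix(rpois(12 * 6, 2) + 1, 12, 6,
              dimnames = list(sprintf("t%02d", 1:12), sprintf("m%d", 1:6)))
  tt <- normalize_fuzzy(trait_table(A, rep(c("g1", "g2"), each = 3)))
  D <- gower_distance(tt)
  sp <- pcoa_space(D, correction = "sqrt")
  Dhat <- as.matrix(dist(sp$coordinates))
  expect_equal(unname(Dhat), unname(sp$corrected_distance), tolerance = 1e-8)
})

test_that("variance explained is positive and sums to at most 1", {
  set.seed(15)
  A <- matrix(rpois(10 * 6, 2) + 1, 10, 6,
              dimnames = list(sprintf("t%d", 1:10), sprintf("m%d", 1:6)))
  sp <- pcoa_space(gower_distance(
    normalize_fuzzy(trait_table(A, rep(c("g1", "g2"), each = 3)))))
  expect_true(all(sp$variance_explained > 0))
  expect_lte(sum(sp$variance_explained), 1 + 1e-12)
})

test_that("mSD is ~0 and m = 2 chosen for an exactly 2D configuration", {
  set.seed(16)
  X <- matrix(runif(16), ncol = 2)
  D <- as.matrix(dist(X))
  sp <- pcoa_space(D, correction = "none")
  q <- dimension_quality(D, sp$coordinates, m_candidates = 1:2)
  expect_lt(q$quality$msd[q$quality$m == 2], 1e-12)
  expect_equal(q$m, 2)
})

test_that("mSD matches a hand-rolled double-loop oracle and improves with a second axis", {
  set.seed(17)
  A <- matrix(rpois(9 * 6, 2) + 1, 9, 6,
              dimnames = list(sprintf("t%d", 1:9), sprintf("m%d", 1:6)))
  tt <- normalize_fuzzy(trait_table(A, rep(c("g1", "g2"), each = 3)))
  D <- gower_distance(tt)
  sp <- pcoa_space(D)
  mmax <- min(5, ncol(sp$coordinates))
  q <- dimension_quality(D, sp$coordinates, m_candidates = seq_len(mmax))
  # oracle: explicit pair loop with max-rescaling
  for (m in seq_len(mmax)) {
    n <- nrow(D)
    dg <- de <- c()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      dg <- c(dg, D[i, j])
      de <- c(de, sqrt(sum((sp$coordinates[i, 1:m] - sp$coordinates[j, 1:m])^2)))
    }
    msd <- mean((dg / max(dg) - de / max(de))^2)
    expect_equal(q$quality$msd[q$quality$m == m], msd, tolerance = 1e-12)
  }
  # adding a second informative axis improves the embedding quality, and the
  # minimiser is interior: the criterion genuinely selects a dimensionality
  expect_lt(q$quality$msd[q$quality$m == 2], q$quality$msd[q$quality$m == 1])
  expect_equal(q$m, q$quality$m[which.min(q$quality$msd)])
})

test_that("trait-combination density is normalised and weight-scale invariant", {
  set.seed(18)
  X <- matrix(rnorm(60), ncol = 2)
  w <- runif(30)
  d1 <- trait_density(X, weights = w, grid_n = 96)
  cell <- diff(d1$x[1:2]) * diff(d1$y[1:2])
  expect_equal(sum(d1$z) * cell, 1, tolerance = 0.01)
  d2 <- trait_density(X, weights = 2 * w, grid_n = 96)
  expect_equal(d1$z, d2$z)
})

test_that("density mode sits at the centre of a tight cluster", {
  set.seed(19)
  X <- matrix(rnorm(40, sd = 0.05), ncol = 2)
  d <- trait_density(X, grid_n = 64)
  peak <- which(d$z == max(d$z), arr.ind = TRUE)
  expect_lt(abs(d$x[peak[1]] - mean(X[, 1])), 0.05)
  expect_lt(abs(d$y[peak[2]] - mean(X[, 2])), 0.05)
  expect_error(trait_density(X[c(1, 1, 1), ]), "distinct")
})
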