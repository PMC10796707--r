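test_that("kNN weights match a brute-force distance sort", {
  # two spots, k = 1: mutual neighbours with weight 1
  w2 <- buildWeights(cbind(c(0, 1), c(0, 0)), "knn", k = 1)
  expect_equal(as.matrix(w2@weights), matrix(c(0, 1, 1, 0), 2, 2))

  for (s in 1:5) {
    co <- withr::with_seed(s, matrix(runif(10), 5, 2))
    w <- buildWeights(co, "knn", k = 2)
    expect_true(all(Matrix::diag(w@weights) == 0))
    expect_true(all(Matrix::rowSums(w@weights) == 2))
    d <- as.matrix(dist(co)); diag(d) <- Inf
    for (i in 1:5) {
      nb <- order(d[i, ], 1:5)[1:2]
      expect_equal(which(as.matrix(w@weights)[i, ] > 0), sort(nb))
    }
  }

  # row standardization divides each row by its neighbour count
  wr <- buildWeights(matrix(runif(12), 6, 2), "knn", k = 3,
                     rowStandardize = TRUE)
  expect_equal(unname(Matrix::rowSums(wr@weights)), rep(1, 6))
})

test_that("Moran's I and Geary's C match direct-sum oracles", {
  # 2x2 checkerboard with rook weights: I = -1, C = 1.5
  w <- buildWeights(rule = "grid_rook", mask = matrix(TRUE, 2, 2))
  x <- c(1, -1, -1, 1)
  expect_equal(moransI(x, w), -1)
  expect_equal(gearysC(x, w), 1.5)
  expect_error(moransI(rep(2, 4), w), "constant")
  expect_error(gearysC(rep(2, 4), w), "constant")

  # random instances against the double-loop oracles, queen and knn
  for (s in 1:5) {
    co <- withr::with_seed(s, matrix(runif(16), 8, 2))
    wk <- buildWeights(co, "knn", k = 3)
    x <- withr::with_seed(s + 10, rnorm(8))
    expect_equal(moransI(x, wk), moranOracle(x, wk@weights),
                 tolerance = 1e-10)
    expect_equal(gearysC(x, wk), gearyOracle(x, wk@weights),
                 tolerance = 1e-10)
  }
  mk <- matrix(TRUE, 3, 4)
  wq <- buildWeights(rule = "grid_queen", mask = mk)
  xg <- withr::with_seed(2, rnorm(12))
  expect_equal(moransI(xg, wq), moranOracle(xg, wq@weights),
               tolerance = 1e-10)

  # cross-check against ape on a row-standardized matrix
  skip_if_not_installed("ape")
  co <- withr::with_seed(7, matrix(runif(20), 10, 2))
  wk <- buildWeights(co, "knn", k = 3)
  x <- withr::with_seed(8, rnorm(10))
  expect_equal(moransI(x, wk),
               ape::Moran.I(x, as.matrix(wk@weights))$observed,
               tolerance = 1e-10)

  # smooth gradient on a path graph: C < 1 (positive autocorrelation)
  wp <- buildWeights(cbind(1:10, 0), "knn", k = 1)
  expect_lt(gearysC(as.numeric(1:10), wp), 1)
})

test_that("null moments match the exhaustive permutation distribution", {
  w <- buildWeights(rule = "grid_rook", mask = matrix(TRUE, 2, 2))
  x <- c(0.3, 1.2, -0.7, 2.5)
  perms <- allPerms(4)
  Is <- apply(perms, 1, function(p) moransI(x[p], w))
  expect_equal(mean(Is), -1 / 3, tolerance = 1e-12)
  mm <- moranMoments(x, w, "randomization")
  expect_equal(mm$expected_i, mean(Is), tolerance = 1e-10)
  expect_equal(mm$variance_i, mean((Is - mean(Is))^2), tolerance = 1e-10)

  # Geary's C averages to about 1 over the exhaustive permutations
  Cs <- apply(perms, 1, function(p) gearysC(x[p], w))
  expect_equal(mean(Cs), 1, tolerance = 0.1)

  expect_equal(moranMoments(rnorm(5), buildWeights(cbind(runif(5), runif(5)),
                                                   "knn", k = 2))$expected_i,
               -0.25)
  expect_equal(moranMoments(c(1, 2), w2 <- buildWeights(cbind(0:1, c(0, 0)),
                                                        "knn", k = 1))$expected_i,
               -1)
})

test_that("the parametric z-test is one-tailed in |z|", {
  expect_equal(parametricPValue(-0.25, -0.25, 0.1)$p_param, 0.5)
  expect_equal(parametricPValue(-0.25, -0.25, 0.1)$z, 0)
  v <- 0.04
  p <- parametricPValue(-0.1 + 1.959964 * sqrt(v), -0.1, v)
  expect_equal(p$p_param, 0.025, tolerance = 1e-6)
  pm <- parametricPValue(-0.1 - 1.959964 * sqrt(v), -0.1, v)
  expect_equal(p$p_param, pm$p_param)
  expect_error(parametricPValue(0, 0, 0), "positive")
})

test_that("permutation pseudo p-values follow (R+1)/(D+1) and batch equals loop", {
  # arithmetic of the pseudo p-value
  expect_equal((0 + 1) / (999 + 1), 0.001)
  co <- withr::with_seed(3, matrix(runif(24), 12, 2))
  w <- buildWeights(co, "knn", k = 3)
  x <- withr::with_seed(4, rpois(12, 3))
  b <- permutationTest(x, w, nPerms = 99, seed = 5, batch = TRUE)
  l <- permutationTest(x, w, nPerms = 99, seed = 5, batch = FALSE)
  expect_identical(b$n_exceed, l$n_exceed)
  expect_equal(b$p_perm, l$p_perm)
  expect_gte(b$p_perm, 1 / 100)
  expect_lte(b$p_perm, 1)

  # batch Moran column-wise equals the scalar implementation
  xm <- withr::with_seed(6, matrix(rnorm(36), 12, 3))
  expect_equal(batchMoransI(xm, w),
               apply(xm, 2, moransI, w = w), tolerance = 1e-12)
})

test_that("BH adjustment matches the hand step-up and dominates raw p", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.2), 0.2)
  p <- withr::with_seed(1, runif(50))
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  # monotone in p-rank
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("SVG calling requires both FDRs below alpha and a positive index", {
  pi <- S4Vectors::DataFrame(gene_id = c("a", "b", "c", "d"),
                             significance_raw = 1, separability_raw = 1,
                             significance_norm = 1, separability_norm = 1,
                             pi = c(0.1, 0.2, 0, 0.3),
                             rank = c(3L, 2L, 4L, 1L),
                             dropped = FALSE, drop_reason = NA_character_)
  ts <- S4Vectors::DataFrame(gene_id = c("a", "b", "c", "d"),
                             moran_i = 0.5, geary_c = 0.5, expected_i = -0.1,
                             variance_i = 0.01, z = 5, p_param = 1e-6,
                             p_perm = 0.001, n_exceed = 0L, n_perms = 999L,
                             fdr_param = c(0.01, 0.1, 0.01, 0.01),
                             fdr_perm = c(0.02, 0.02, 0.02, 0.02))
  out <- selectSVGs(pi, ts, alpha = 0.05)
  expect_identical(out$gene_id[out$is_svg], c("d", "a"))
  expect_false(out$is_svg[out$gene_id == "b"])   # fdr_param above alpha
  expect_false(out$is_svg[out$gene_id == "c"])   # pi not strictly positive
  expect_identical(out$gene_id[1], "d")          # sorted by descending pi
})

test_that("permuted gene columns behave as complete spatial randomness", {
  sim <- simulateSpotData(c(15, 15), nDomains = 3, nMarkersPerDomain = 1,
                          nNoiseGenes = 1, seed = 2)
  n <- ncol(sim@table)
  w <- buildWeights(spotCoords(sim@table), "knn", k = 4)
  Is <- vapply(1:40, function(s) {
    tb <- csrPermute(sim, 1, seed = s)
    moransI(as.numeric(assay(tb, "counts")[1, ]), w)
  }, numeric(1))
  # empirical mean close to E(I) = -1/(N-1) within Monte-Carlo error
  expect_lt(abs(mean(Is) + 1 / (n - 1)), 3 * sd(Is) / sqrt(40))
})
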