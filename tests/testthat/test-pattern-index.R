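test_that("isodata threshold matches hand-iterated oracles", {
  th <- adaptiveThreshold(asImage(matrix(c(rep(0.1, 8), rep(0.9, 8)), 4, 4)))
  expect_equal(attr(th, "threshold"), 0.5)
  expect_identical(sum(th), 8L)

  th2 <- adaptiveThreshold(asImage(matrix(c(0, 0.2, 0.4, 0.6, 0.8, 1), 2, 3)))
  expect_equal(attr(th2, "threshold"), 0.5)

  # general case: the converged threshold is a fixed point of the update
  set.seed(4)
  img <- asImage(matrix(runif(64), 8, 8))
  t3 <- attr(adaptiveThreshold(img), "threshold")
  v <- pixelValues(img)
  expect_equal(t3, (mean(v[v > t3]) + mean(v[v <= t3])) / 2,
               tolerance = 1e-5)

  expect_error(adaptiveThreshold(asImage(matrix(0.3, 3, 3))), "constant")
})

test_that("morphological closing fills interior holes and is idempotent on full masks", {
  full <- matrix(TRUE, 6, 6)
  expect_identical(morphClose(full, 3), full)
  empty <- matrix(FALSE, 6, 6)
  expect_identical(morphClose(empty, 3), empty)

  mk <- matrix(FALSE, 7, 7); mk[2:6, 2:6] <- TRUE; mk[4, 4] <- FALSE
  cl <- morphClose(mk, 3)
  expect_true(cl[4, 4])
  expect_identical(sum(cl), 25L)

  # agreement with EBImage for an odd square kernel
  skip_if_not_installed("EBImage")
  set.seed(9)
  m <- matrix(runif(400) < 0.4, 20, 20)
  ours <- morphClose(m, 5)
  eb <- EBImage::closing(m * 1, EBImage::makeBrush(5, "box")) > 0
  # compare away from the frame (border padding conventions differ)
  expect_identical(ours[6:15, 6:15], eb[6:15, 6:15])
})

test_that("region labeling is 8-connected and matches flood fill", {
  # diagonally touching pixels are one region
  diag2 <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  expect_identical(labelRegions(diag2)@nRegions, 1L)

  # a background row separates two regions
  two <- matrix(FALSE, 3, 2); two[1, ] <- TRUE; two[3, ] <- TRUE
  seg <- labelRegions(two)
  expect_identical(seg@nRegions, 2L)
  expect_identical(seg@regionSizes, c(2L, 2L))
  expect_identical(seg@backgroundSize, 2L)

  # random masks agree with the brute-force flood fill on region sizes
  for (s in 1:8) {
    m <- withr::with_seed(s, matrix(runif(48) < 0.45, 6, 8))
    seg <- labelRegions(m)
    fl <- floodLabels(m)
    expect_identical(seg@nRegions, max(fl))
    expect_identical(sort(seg@regionSizes), sort(tabulate(fl[fl > 0])))
  }
})

test_that("the foreground-fraction rule drops sparse patterns", {
  mk <- matrix(FALSE, 10, 10)
  seg0 <- labelRegions(mk)
  expect_false(applyDelRate(seg0, 100, 0.01))     # fraction 0
  mk[1, 1] <- TRUE                                # fraction 0.01, not > 1%
  expect_false(applyDelRate(labelRegions(mk), 100, 0.01))
  mk[1:5, ] <- TRUE                               # fraction 0.5
  expect_true(applyDelRate(labelRegions(mk), 100, 0.01))
})

test_that("Significance and Separability match hand-evaluated oracles", {
  img <- asImage(matrix(c(0.6, 1.0, 0.0, 0.2), 2, 2))
  seg <- labelRegions(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(significanceFactor(img, seg), 2.8, tolerance = 1e-8)

  img2 <- asImage(matrix(c(0.4, 0.8, 0.1, 0.1, 0.5, 0.9), 2, 3))
  seg2 <- labelRegions(matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE), 2, 3))
  expect_identical(seg2@nRegions, 2L)
  expect_equal(significanceFactor(img2, seg2),
               0.55 / (0.2 / 0.6 + 0.2 / 0.7), tolerance = 1e-9)

  # zero numerator when foreground means equal the background mean
  img3 <- asImage(matrix(c(0.4, 0.6, 0.3, 0.7), 2, 2))
  seg3 <- labelRegions(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(significanceFactor(img3, seg3), 0, tolerance = 1e-9)

  img4 <- asImage(matrix(c(0, 0, 0.4, 0.8), 2, 2))
  seg4 <- labelRegions(matrix(c(FALSE, FALSE, TRUE, TRUE), 2, 2))
  expect_equal(separabilityFactor(img4, seg4), 1 - 0.08 / 0.44,
               tolerance = 1e-12)

  # internally constant foreground regions give separability exactly 1
  img5 <- asImage(matrix(c(1, 1, 0, 0.5), 2, 2))
  seg5 <- labelRegions(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(separabilityFactor(img5, seg5), 1)
})

test_that("Separability stays in [0, 1] and matches brute-force sums", {
  for (s in 1:10) {
    px <- withr::with_seed(s, matrix(runif(36), 6, 6))
    img <- asImage(px)
    mk <- withr::with_seed(s + 50, matrix(runif(36) < 0.5, 6, 6))
    if (!any(mk) || all(mk)) next
    seg <- labelRegions(mk)
    sep <- separabilityFactor(img, seg)
    expect_gte(sep, 0); expect_lte(sep, 1)
    # independent accumulation of the within/total sums
    tot <- sum((px - mean(px))^2)
    within <- 0
    for (l in seq_len(seg@nRegions)) {
      y <- px[!is.na(seg@labels) & seg@labels == l]
      within <- within + sum((y - mean(y))^2)
    }
    expect_equal(sep, 1 - within / tot, tolerance = 1e-10)
  }
})

test_that("psi-normalized index ranks genes and preserves the raw factors", {
  rec <- patternIndex(c(1, 2, 3), c(0.2, 0.4, 0.2),
                      geneIds = c("a", "b", "c"))
  expect_equal(rec$significance_norm, c(0, 0.5, 1))
  expect_equal(rec$separability_norm, c(0, 1, 0))
  expect_equal(rec$pi, c(0, 0.5, 0))
  expect_identical(rec$rank, c(2L, 1L, 2L))       # dense rank, ties share
  expect_equal(rec$significance_raw, c(1, 2, 3))

  recId <- patternIndex(2, 0.5, psi = "identity", geneIds = "g")
  expect_equal(recId$pi, 1)
  expect_error(patternIndex(2, 0.5, psi = "minmax"), "at least 2")
})

test_that("a structured gene outscores its CSR permutation across seeds", {
  # one high-expression band plus noise, against the same values permuted
  H <- 16; W <- 16; n <- H * W
  band <- rep(rep(c(4, 0), c(5, 11)), times = W)
  wins <- 0L
  for (s in 1:20) {
    vals <- withr::with_seed(s, rpois(n, 1 + band))
    perm <- withr::with_seed(s + 1000, sample(vals))
    cnt <- rbind(structured = vals, permuted = perm, spare = seq_len(n))
    tab <- latticeTable(cnt, H, W)
    rec <- scoreGenePatterns(tab, psi = "identity")
    piS <- rec$pi[1]; piP <- rec$pi[2]
    if (is.na(piP) || (!is.na(piS) && piS > piP)) wins <- wins + 1L
  }
  expect_identical(wins, 20L)
})

test_that("gene scoring is deterministic and drops degenerate genes before psi", {
  sim <- simulateSpotData(c(12, 12), nDomains = 3, nMarkersPerDomain = 2,
                          nNoiseGenes = 4, seed = 5)
  tab <- sim@table
  cnt <- assay(tab, "counts")
  cnt <- rbind(cnt, flat = rep(3L, ncol(tab)))    # constant gene
  tab2 <- SpotTable(cnt, spotCoords(tab))
  r1 <- scoreGenePatterns(tab2)
  r2 <- scoreGenePatterns(tab2)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_true(r1$dropped[r1$gene_id == "flat"])
  expect_identical(r1$drop_reason[r1$gene_id == "flat"], "constant")
  expect_true(all(is.na(r1$pi[r1$dropped])))
  # dropped genes do not shift the psi normalization of the others
  r3 <- scoreGenePatterns(tab2[rownames(tab2) != "flat", ])
  expect_equal(r3$pi, r1$pi[!r1$dropped])
})
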