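#' Build a spatial weight matrix
#'
#' `rule = "knn"` connects each spot to its `k` nearest Euclidean
#' neighbours (binary weights; ties broken by (distance, index)
#' lexicographic order, with a warning when duplicate coordinates make
#' neighbours ambiguous). `rule = "grid_queen"` / `"grid_rook"` connect
#' adjacent valid pixels of a gene-image grid (queen: 8 neighbours, rook:
#' 4), matching the image-based pattern-index pipeline; pixel order is
#' column-major over the valid mask, the same order as [pixelValues()].
#'
#' @param coords n x 2 coordinate matrix (kNN rule).
#' @param rule `"knn"`, `"grid_queen"` or `"grid_rook"`.
#' @param k neighbours per spot (kNN rule).
#' @param rowStandardize divide each row by its sum (default `FALSE`,
#'   binary weights).
#' @param mask logical H x W valid mask (grid rules).
#' @return A [WeightMatrix-class].
#' @export
buildWeights <- function(coords = NULL,
                         rule = c("knn", "grid_queen", "grid_rook"),
                         k = 6L, rowStandardize = FALSE, mask = NULL) {
  rule <- match.arg(rule)
  if (rule == "knn") {
    stopifnot(!is.null(coords), nrow(coords) >= 2, k < nrow(coords))
    nbr <- knnIndices(coords, k)
    n <- nrow(coords)
    w <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nbr),
                              x = 1, dims = c(n, n))
  } else {
    stopifnot(!is.null(mask))
    idx <- which(mask)
    n <- length(idx)
    H <- nrow(mask); W <- ncol(mask)
    pos <- integer(H * W); pos[idx] <- seq_len(n)
    deltas <- list(c(1L, 0L), c(0L, 1L))
    if (rule == "grid_queen") deltas <- c(deltas, list(c(1L, 1L), c(1L, -1L)))
    ii <- jj <- integer(0)
    r <- ((idx - 1L) %% H) + 1L
    cc <- ((idx - 1L) %/% H) + 1L
    for (d in deltas) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
      nb <- (c2[ok] - 1L) * H + r2[ok]
      hit <- mask[nb]
      ii <- c(ii, pos[idx[ok][hit]]); jj <- c(jj, pos[nb[hit]])
    }
    w <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                              dims = c(n, n))
    k <- NA_integer_
  }
  if (rowStandardize) {
    rs <- Matrix::rowSums(w)
    rs[rs == 0] <- 1
    w <- Matrix::Diagonal(x = 1 / rs) %*% w
  }
  new("WeightMatrix", weights = methods::as(w, "generalMatrix"),
      rule = rule, k = as.integer(k), rowStandardized = rowStandardize)
}

# k nearest neighbours by brute-force sort; ties broken by (distance, index).
knnIndices <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  if (any(d[upper.tri(d)] == 0))
    warning("duplicate coordinates: neighbour ties broken by spot index")
  diag(d) <- Inf
  t(vapply(seq_len(n),
           function(i) order(d[i, ], seq_len(n))[seq_len(k)],
           integer(k)))
}

#' Moran's I
#'
#' `I = (N / W0) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2` with `W0 = sum_ij w_ij`. Values near `E(I) = -1/(N-1)` are
#' expected under complete spatial randomness; positive values indicate
#' spatial clustering.
#'
#' @param x numeric vector (non-constant).
#' @param w a [WeightMatrix-class] of matching dimension.
#' @return Moran's I.
#' @export
moransI <- function(x, w) {
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop("constant vector: undefined autocorrelation")
  W <- w@weights
  length(x) / sum(W) * sum(z * as.numeric(W %*% z)) / ss
}

#' Geary's C
#'
#' `C = ((N-1) / (2 W0)) * sum_ij w_ij (x_i - x_j)^2 / sum_i (x_i -
#' xbar)^2`; values below 1 indicate positive spatial autocorrelation.
#'
#' @inheritParams moransI
#' @return Geary's C.
#' @export
gearysC <- function(x, w) {
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop("constant vector: undefined autocorrelation")
  trip <- Matrix::summary(methods::as(w@weights, "TsparseMatrix"))
  num <- sum(trip$x * (x[trip$i] - x[trip$j])^2)
  (length(x) - 1) / (2 * sum(w@weights)) * num / ss
}

#' Moments of Moran's I under the null
#'
#' `E(I) = -1/(N-1)`; the variance uses the standard closed forms built on
#' the weight sums S0, S1, S2, under either the randomization assumption
#' (distribution-free, involves the sample kurtosis of `x`; the default
#' everywhere in this package) or the normality assumption.
#'
#' @inheritParams moransI
#' @param assumption `"randomization"` or `"normality"`.
#' @return `list(expected_i, variance_i)`.
#' @export
moranMoments <- function(x, w, assumption = c("randomization", "normality")) {
  assumption <- match.arg(assumption)
  n <- length(x)
  stopifnot(n >= 2)
  if (n < 4)   # variance closed forms need N >= 4
    return(list(expected_i = -1 / (n - 1), variance_i = NA_real_))
  W <- w@weights
  S0 <- sum(W)
  S1 <- sum((W + Matrix::t(W))^2) / 2
  S2 <- sum((Matrix::rowSums(W) + Matrix::colSums(W))^2)
  EI <- -1 / (n - 1)
  if (assumption == "normality") {
    VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / ((n^2 - 1) * S0^2) - EI^2
  } else {
    z <- x - mean(x)
    b2 <- n * sum(z^4) / sum(z^2)^2
    VI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * S0^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * S0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * S0^2) - EI^2
  }
  list(expected_i = EI, variance_i = VI)
}

#' Parametric z-test of Moran's I
#'
#' `z = (I - E(I)) / sqrt(V(I))`; the one-tailed p-value is
#' `1 - Phi(|z|)` with `Phi` the standard normal CDF, so `p` depends on
#' `|z|` only and lies in `[0, 0.5]`.
#'
#' @param i observed Moran's I.
#' @param expectedI,varianceI null moments from [moranMoments()].
#' @return `list(z, p_param)`.
#' @export
parametricPValue <- function(i, expectedI, varianceI) {
  if (varianceI <= 0) stop("variance_i must be positive")
  z <- (i - expectedI) / sqrt(varianceI)
  list(z = z, p_param = 1 - stats::pnorm(abs(z)))
}

# Permutation index matrix (n x D), drawn under `seed`; shared by the
# batch and loop implementations so they are comparable draw-for-draw.
permutationIndices <- function(n, nPerms, seed) {
  withSeed(seed, vapply(seq_len(nPerms), function(d) sample.int(n),
                        integer(n)))
}

#' Permutation (pseudo p-value) test of Moran's I
#'
#' The gene's values are randomly permuted over the locations D times and
#' `p = (R + 1) / (D + 1)` where R counts permutations whose Moran's I is
#' greater than or equal to the observed statistic (upper tail:
#' clustering). All permutations are evaluated in one vectorized batch —
#' the centered sum of squares is permutation-invariant, so each
#' permutation costs one sparse matrix-vector product.
#'
#' @inheritParams moransI
#' @param nPerms number of permutations D (default 999).
#' @param seed RNG seed for the permutation draws.
#' @param batch use the vectorized batch computation (default); `FALSE`
#'   recomputes each permutation with [moransI()] (reference path).
#' @return `list(p_perm, n_exceed, n_perms)`.
#' @export
permutationTest <- function(x, w, nPerms = 999L, seed = 1L, batch = TRUE) {
  stopifnot(nPerms >= 1)
  obs <- moransI(x, w)
  perms <- permutationIndices(length(x), nPerms, seed)
  if (batch) {
    iPerm <- batchMoransI(matrix(x[perms], nrow = length(x)), w)
  } else {
    iPerm <- apply(perms, 2, function(p) moransI(x[p], w))
  }
  R <- sum(iPerm >= obs - 1e-12)
  list(p_perm = (R + 1) / (nPerms + 1), n_exceed = R,
       n_perms = as.integer(nPerms))
}

#' Batch Moran's I over the columns of a matrix
#'
#' @param xmat numeric n x m matrix; Moran's I is computed for every
#'   column against the same weights.
#' @param w a [WeightMatrix-class].
#' @return Numeric vector of m Moran's I values.
#' @export
batchMoransI <- function(xmat, w) {
  z <- sweep(xmat, 2, colMeans(xmat))
  ss <- colSums(z^2)
  if (any(ss == 0)) stop("constant column: undefined autocorrelation")
  W <- w@weights
  as.numeric(nrow(xmat) / sum(W) * colSums(z * as.matrix(W %*% z)) / ss)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (monotone in p-rank, clipped at 1), applied
#' separately to the parametric and permutation p-value vectors.
#'
#' @param pvals numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values.
#' @export
bhAdjust <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' Run autocorrelation tests for every gene of a table
#'
#' For each gene the statistic is computed on the gene-image valid-pixel
#' values with grid-contiguity weights (default queen, matching the
#' image-based index pipeline) or on the raw spot values with kNN weights.
#' Produces Moran's I, Geary's C, the null moments, the parametric z-test
#' and the permutation pseudo p-value, with BH FDR per test family.
#' Constant genes get `NA` results.
#'
#' @param table a [SpotTable-class].
#' @param mapping optional precomputed [GridMapping-class] (grid rules).
#' @param rule `"grid_queen"`, `"grid_rook"` or `"knn"`.
#' @param k kNN neighbours (kNN rule).
#' @param rowStandardize row-standardize the weights (default `FALSE`).
#' @param assumption variance assumption for the parametric test.
#' @param nPerms permutations per gene (default 999).
#' @param seed base seed; per-gene permutation seeds are derived from it.
#' @return A [S4Vectors::DataFrame], one row per gene: `gene_id`,
#'   `moran_i`, `geary_c`, `expected_i`, `variance_i`, `z`, `p_param`,
#'   `p_perm`, `n_exceed`, `n_perms`, `fdr_param`, `fdr_perm`.
#' @export
runAutocorrTests <- function(table, mapping = NULL,
                             rule = c("grid_queen", "grid_rook", "knn"),
                             k = 6L, rowStandardize = FALSE,
                             assumption = "randomization",
                             nPerms = 999L, seed = 1L) {
  rule <- match.arg(rule)
  if (rule == "knn") {
    w <- buildWeights(spotCoords(table), rule = "knn", k = k,
                      rowStandardize = rowStandardize)
    vals <- lapply(seq_len(nrow(table)),
                   function(g) as.numeric(assay(table, "counts")[g, ]))
  } else {
    if (is.null(mapping)) mapping <- gridMapping(table)
    w <- buildWeights(rule = rule, mask = mapping@validMask,
                      rowStandardize = rowStandardize)
    vals <- lapply(seq_len(nrow(table)),
                   function(g) pixelValues(makeGeneImage(table, g, mapping)))
  }
  nG <- nrow(table)
  seeds <- subSeeds(seed, nG)
  cols <- c("moran_i", "geary_c", "expected_i", "variance_i", "z",
            "p_param", "p_perm")
  res <- matrix(NA_real_, nG, length(cols), dimnames = list(NULL, cols))
  nEx <- rep(NA_integer_, nG)
  for (g in seq_len(nG)) {
    x <- vals[[g]]
    if (diff(range(x)) <= 0) next
    mi <- moransI(x, w)
    mm <- moranMoments(x, w, assumption)
    pp <- parametricPValue(mi, mm$expected_i, mm$variance_i)
    pt <- permutationTest(x, w, nPerms = nPerms, seed = seeds[g])
    res[g, ] <- c(mi, gearysC(x, w), mm$expected_i, mm$variance_i,
                  pp$z, pp$p_param, pt$p_perm)
    nEx[g] <- pt$n_exceed
  }
  DataFrame(gene_id = rownames(table),
            as.data.frame(res),
            n_exceed = nEx, n_perms = as.integer(nPerms),
            fdr_param = bhAdjust(res[, "p_param"]),
            fdr_perm = bhAdjust(res[, "p_perm"]))
}

#' Call spatially variable genes
#'
#' Joins pattern-index records with autocorrelation test results and flags
#' as SVG the genes that pass both the parametric and the permutation test
#' at `fdr < alpha` and have a strictly positive pattern index.
#'
#' @param piRecords output of [scoreGenePatterns()].
#' @param testResults output of [runAutocorrTests()].
#' @param alpha FDR threshold (default 0.05).
#' @return A [S4Vectors::DataFrame] of the joined records plus `is_svg`,
#'   sorted by descending pattern index (called SVGs first).
#' @export
selectSVGs <- function(piRecords, testResults, alpha = 0.05) {
  stopifnot(identical(piRecords$gene_id, testResults$gene_id))
  out <- cbind(piRecords, testResults[, setdiff(colnames(testResults),
                                                "gene_id")])
  out$is_svg <- !is.na(out$pi) & out$pi > 0 &
    !is.na(out$fdr_param) & out$fdr_param < alpha &
    !is.na(out$fdr_perm) & out$fdr_perm < alpha
  out[order(-replace(out$pi, is.na(out$pi), -Inf)), ]
}
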