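#' Simulate spatial transcriptomics data with known domains and markers
#'
#' Spots sit on a regular `gridShape` lattice partitioned into K spatial
#' domains (`bands`: horizontal stripes; `rings`: concentric equal-count
#' annuli mimicking laminar tissue; `voronoi`: nearest-seed regions).
#' Marker gene g of domain d is drawn NB(mean = `baseMean * foldChange`)
#' inside d and NB(`baseMean`) outside; noise genes are NB(`baseMean`)
#' everywhere (complete spatial randomness). `var = mu + dispersion *
#' mu^2`. Independent dropout zeroes entries with probability
#' `dropoutRate`. Fully reproducible from `seed`.
#'
#' @param gridShape `c(rows, cols)` of the spot lattice.
#' @param layout `"bands"`, `"rings"` or `"voronoi"`.
#' @param nDomains number of domains K.
#' @param nMarkersPerDomain marker genes per domain.
#' @param nNoiseGenes CSR noise genes.
#' @param baseMean baseline negative-binomial mean (UMI per spot).
#' @param foldChange in-domain mean multiplier (> 1).
#' @param dispersion gene-level NB dispersion.
#' @param dropoutRate probability of a structural zero, in `[0, 1)`.
#' @param seed RNG seed.
#' @return A [SpotSimulation-class].
#' @export
simulateSpotData <- function(gridShape = c(40L, 40L),
                             layout = c("bands", "rings", "voronoi"),
                             nDomains = 5L, nMarkersPerDomain = 10L,
                             nNoiseGenes = 100L, baseMean = 2,
                             foldChange = 4, dispersion = 0.5,
                             dropoutRate = 0, seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(baseMean > 0, foldChange > 1, dispersion > 0,
            dropoutRate >= 0, dropoutRate < 1)
  H <- gridShape[1]; W <- gridShape[2]
  n <- H * W
  if (nDomains > n) stop("more domains than spots")
  row <- rep(seq_len(H), times = W)
  col <- rep(seq_len(W), each = H)
  withSeed(seed, {
    dom <- switch(layout,
      bands = as.integer(cut(row, nDomains, labels = FALSE)),
      rings = {
        r <- sqrt((row - (H + 1) / 2)^2 + (col - (W + 1) / 2)^2)
        as.integer(cut(rank(r, ties.method = "first"), nDomains,
                       labels = FALSE))
      },
      voronoi = {
        for (try in seq_len(50)) {
          seeds <- cbind(stats::runif(nDomains, 1, W),
                         stats::runif(nDomains, 1, H))
          d <- outer(col, seeds[, 1], `-`)^2 + outer(row, seeds[, 2], `-`)^2
          dm <- max.col(-d, ties.method = "first")
          if (length(unique(dm)) == nDomains) break
        }
        if (length(unique(dm)) < nDomains)
          stop("could not realize ", nDomains, " non-empty voronoi domains")
        as.integer(dm)
      })
    if (length(unique(dom)) < nDomains)
      stop("layout cannot represent ", nDomains, " non-empty domains")
    nMark <- nDomains * nMarkersPerDomain
    nGenes <- nMark + nNoiseGenes
    size <- 1 / dispersion
    counts <- matrix(0L, nGenes, n)
    gid <- character(nGenes)
    g <- 0L
    for (d in seq_len(nDomains)) for (m in seq_len(nMarkersPerDomain)) {
      g <- g + 1L
      mu <- baseMean * ifelse(dom == d, foldChange, 1)
      counts[g, ] <- stats::rnbinom(n, size = size, mu = mu)
      gid[g] <- sprintf("marker_d%02d_g%02d", d, m)
    }
    for (m in seq_len(nNoiseGenes)) {
      g <- g + 1L
      counts[g, ] <- stats::rnbinom(n, size = size, mu = baseMean)
      gid[g] <- sprintf("noise_g%03d", m)
    }
    if (dropoutRate > 0)
      counts[matrix(stats::runif(length(counts)) < dropoutRate,
                    nrow(counts))] <- 0L
    rownames(counts) <- gid
    colnames(counts) <- sprintf("s%04d", seq_len(n))
    tab <- SpotTable(counts, cbind(x = col, y = row), platform = "generic")
    new("SpotSimulation", table = tab, trueLabels = dom,
        trueSVG = c(rep(TRUE, nMark), rep(FALSE, nNoiseGenes)))
  })
}

#' Destroy the spatial structure of one gene
#'
#' Returns the table with the chosen gene's values randomly permuted over
#' the spots: the expression marginal is preserved while any spatial
#' pattern is replaced by complete spatial randomness.
#'
#' @param x a [SpotTable-class] or [SpotSimulation-class].
#' @param gene gene index or id.
#' @param seed RNG seed for the permutation.
#' @return The permuted [SpotTable-class].
#' @export
csrPermute <- function(x, gene, seed = 1L) {
  table <- if (is(x, "SpotSimulation")) x@table else x
  if (is.character(gene)) gene <- match(gene, rownames(table))
  stopifnot(!is.na(gene), gene >= 1, gene <= nrow(table))
  cnt <- assay(table, "counts")
  cnt[gene, ] <- withSeed(seed, sample(cnt[gene, ]))
  assay(table, "counts") <- cnt
  table
}
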