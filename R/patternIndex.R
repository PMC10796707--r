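#' Iterative-mean (isodata) adaptive threshold
#'
#' Splits the valid pixels of a (normalized, smoothed) gene image into
#' foreground and background. Starting from the global mean, the threshold
#' is iterated as `T <- (mean(values > T) + mean(values <= T)) / 2` until
#' it moves by less than `1e-6`; foreground pixels are those strictly above
#' the converged threshold.
#'
#' @param img a [GeneImage-class].
#' @return Logical H x W foreground mask (`FALSE` outside the valid mask),
#'   with the converged threshold in `attr(, "threshold")`.
#' @export
adaptiveThreshold <- function(img) {
  v <- pixelValues(img)
  if (diff(range(v)) <= 0)
    stop("constant image: no threshold exists")
  Tcur <- mean(v)
  for (iter in seq_len(100)) {
    hi <- v > Tcur
    if (!any(hi) || all(hi)) break
    Tnew <- (mean(v[hi]) + mean(v[!hi])) / 2
    done <- abs(Tnew - Tcur) < 1e-6
    Tcur <- Tnew
    if (done) break
  }
  mask <- matrix(FALSE, nrow(img@pixels), ncol(img@pixels))
  mask[img@validMask] <- img@pixels[img@validMask] > Tcur
  attr(mask, "threshold") <- Tcur
  mask
}

# Square-structuring-element dilation / erosion by matrix shifts.
# Anchor convention: offsets -floor((k-1)/2) .. ceiling((k-1)/2), so even
# kernel sizes (Stereo-seq: 6, SeqFISH: 8) are supported. Outside the
# frame is background (infinite-plane convention).
shiftApply2 <- function(mask, kernelSize, op) {
  k <- as.integer(kernelSize)
  off <- seq.int(-((k - 1L) %/% 2L), (k - 1L) - ((k - 1L) %/% 2L))
  H <- nrow(mask); W <- ncol(mask)
  out <- matrix(op == "min", H, W)
  for (dr in off) for (dc in off) {
    sh <- matrix(FALSE, H, W)
    rs <- seq_len(H) - dr; cs <- seq_len(W) - dc
    rok <- rs >= 1 & rs <= H; cok <- cs >= 1 & cs <= W
    sh[rok, cok] <- mask[rs[rok], cs[cok], drop = FALSE]
    out <- if (op == "max") out | sh else out & sh
  }
  out
}

#' Morphological closing of a binary mask
#'
#' Dilation followed by erosion with a square structuring element of side
#' `kernelSize`, used after binary segmentation to fill small holes inside
#' foreground regions. Platform defaults for the pattern-index pipeline:
#' 5 (Visium, Slide-seq), 6 (Stereo-seq), 8 (SeqFISH).
#'
#' @param mask logical matrix.
#' @param kernelSize side of the square structuring element (>= 1).
#' @return The closed logical matrix.
#' @export
morphClose <- function(mask, kernelSize = 5L) {
  stopifnot(kernelSize >= 1)
  mode(mask) <- "logical"
  k <- as.integer(kernelSize)
  # pad so the dilation can grow past the frame before the erosion
  # (infinite-plane closing: extensive, fills holes, never clips at the
  # frame)
  H <- nrow(mask); W <- ncol(mask)
  padded <- matrix(FALSE, H + 2L * k, W + 2L * k)
  padded[k + seq_len(H), k + seq_len(W)] <- mask
  closed <- shiftApply2(shiftApply2(padded, k, "max"), k, "min")
  closed[k + seq_len(H), k + seq_len(W), drop = FALSE]
}

.platformKernelSize <- function(platform) {
  switch(platform, visium = 5L, slide_seq = 5L, stereo_seq = 6L,
         seqfish = 8L, generic = 5L)
}

#' Label 8-connected foreground regions
#'
#' Foreground pixels that touch vertically, horizontally or diagonally
#' belong to the same region (8-connectivity). Valid pixels that are not
#' foreground form the background; invalid pixels belong to neither.
#'
#' @param mask logical H x W foreground mask.
#' @param validMask logical H x W tissue mask; defaults to all `TRUE`.
#' @return An [ImageSegmentation-class] with labels 1..L (0 = background,
#'   `NA` = invalid).
#' @export
labelRegions <- function(mask, validMask = NULL) {
  H <- nrow(mask); W <- ncol(mask)
  if (is.null(validMask)) validMask <- matrix(TRUE, H, W)
  mask <- mask & validMask
  idx <- which(mask)
  labels <- matrix(NA_integer_, H, W)
  labels[validMask] <- 0L
  if (length(idx)) {
    pos <- matrix(0L, H * W, 1)
    pos[idx] <- seq_along(idx)
    edges <- NULL
    for (d in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(1L, -1L))) {
      r <- ((idx - 1L) %% H) + 1L
      c <- ((idx - 1L) %/% H) + 1L
      r2 <- r + d[1]; c2 <- c + d[2]
      ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
      nb <- (c2[ok] - 1L) * H + r2[ok]
      hit <- mask[nb]
      edges <- rbind(edges, cbind(pos[idx[ok][hit]], pos[nb[hit]]))
    }
    g <- igraph::graph_from_edgelist(
      rbind(edges, cbind(seq_along(idx), seq_along(idx))), directed = FALSE)
    comp <- igraph::components(g)$membership
    labels[idx] <- as.integer(comp)
  }
  fgLab <- labels[!is.na(labels) & labels > 0L]
  sizes <- if (length(fgLab)) tabulate(fgLab) else integer(0)
  new("ImageSegmentation", labels = labels,
      nRegions = length(sizes), regionSizes = as.integer(sizes),
      backgroundSize = sum(labels == 0L, na.rm = TRUE))
}

#' Keep/drop decision from the foreground fraction
#'
#' A gene is considered only if the proportion of foreground pixels among
#' all valid pixels exceeds `delRate` (default 0.01, i.e. 1%).
#'
#' @param seg an [ImageSegmentation-class].
#' @param nPixels total number of valid pixels (N').
#' @param delRate drop threshold in `[0, 1)`.
#' @return `TRUE` to keep the gene, `FALSE` to drop it.
#' @export
applyDelRate <- function(seg, nPixels, delRate = 0.01) {
  stopifnot(delRate >= 0, delRate < 1)
  sum(seg@regionSizes) / nPixels > delRate
}

.regionStats <- function(img, seg) {
  v <- img@pixels
  lab <- seg@labels
  L <- seg@nRegions
  mu_l <- sig2_l <- numeric(L)
  for (l in seq_len(L)) {
    y <- v[!is.na(lab) & lab == l]
    mu_l[l] <- mean(y)
    sig2_l[l] <- mean((y - mu_l[l])^2)        # population variance
  }
  bg <- v[!is.na(lab) & lab == 0L]
  all <- v[!is.na(lab)]
  list(mu_l = mu_l, sig2_l = sig2_l, N_l = seg@regionSizes,
       mu_B = if (length(bg)) mean(bg) else NA_real_,
       N_B = length(bg), Nprime = length(all),
       sigma2 = mean((all - mean(all))^2))
}

#' Significance factor of a segmented gene image
#'
#' Mean foreground-minus-background contrast, averaged over the L
#' foreground regions, divided by the summed within-region relative
#' dispersion: `(1/L) * sum_l(mu_l - mu_B) / sum_l(sigma_l / mu_l)`.
#' Region variances are population variances (divisor `N_l`). An epsilon
#' of `1e-12` guards the denominator against perfectly homogeneous
#' regions.
#'
#' @param img a [GeneImage-class] (min-max normalized).
#' @param seg the matching [ImageSegmentation-class] with L >= 1 regions.
#' @return The Significance factor (real; sign follows the contrast).
#' @export
significanceFactor <- function(img, seg) {
  stopifnot(seg@nRegions >= 1)
  s <- .regionStats(img, seg)
  if (s$N_B == 0)
    stop("no background pixels: significance undefined")
  num <- mean(s$mu_l - s$mu_B)
  den <- sum(sqrt(s$sig2_l) / s$mu_l) + 1e-12
  num / den
}

#' Separability factor of a segmented gene image
#'
#' One minus the within-foreground-region variance fraction of the total
#' image variance: `1 - sum_l(N_l * sigma_l^2) / (N' * sigma^2)`, a
#' stratified-heterogeneity measure in `[0, 1]`.
#'
#' @inheritParams significanceFactor
#' @return The Separability factor in `[0, 1]`.
#' @export
separabilityFactor <- function(img, seg) {
  s <- .regionStats(img, seg)
  if (s$sigma2 <= 0)
    stop("constant image: separability undefined")
  1 - sum(s$N_l * s$sig2_l) / (s$Nprime * s$sigma2)
}

#' Combine Significance and Separability into the pattern index
#'
#' `PI_g = psi(sig)_g * psi(sep)_g`, where `psi` is min-max normalization
#' across the gene dimension (`psi = "identity"` multiplies the raw
#' factors). Records are ranked densely by descending index.
#'
#' @param sig,sep aligned numeric vectors of raw factors over genes.
#' @param psi `"minmax"` (default) or `"identity"`.
#' @param geneIds optional gene id vector.
#' @return A [S4Vectors::DataFrame] with columns `gene_id`,
#'   `significance_raw`, `separability_raw`, `significance_norm`,
#'   `separability_norm`, `pi`, `rank`.
#' @export
patternIndex <- function(sig, sep, psi = c("minmax", "identity"),
                         geneIds = names(sig)) {
  psi <- match.arg(psi)
  stopifnot(length(sig) == length(sep))
  if (psi == "minmax" && length(sig) < 2)
    stop("min-max normalization across genes needs at least 2 genes")
  sn <- if (psi == "minmax") minmaxVector(sig) else sig
  pn <- if (psi == "minmax") minmaxVector(sep) else sep
  pi <- sn * pn
  DataFrame(gene_id = geneIds %||% paste0("gene", seq_along(sig)),
            significance_raw = as.numeric(sig),
            separability_raw = as.numeric(sep),
            significance_norm = as.numeric(sn),
            separability_norm = as.numeric(pn),
            pi = as.numeric(pi),
            rank = as.integer(match(pi, sort(unique(pi),
                                             decreasing = TRUE))))
}

#' Score every gene of a table by the spatial pattern index
#'
#' Full per-gene image pipeline: grid rendering, min-max normalization,
#' masked Gaussian smoothing (and re-normalization to `[0, 1]`), isodata
#' thresholding, morphological closing, 8-connected region labeling, the
#' foreground-fraction drop rule, then the Significance and Separability
#' factors and their psi-normalized product. Genes whose image is constant
#' after normalization, whose foreground fraction does not exceed
#' `delRate`, or whose foreground covers every valid pixel are dropped
#' with a reason and excluded from psi and ranking.
#'
#' @param table a [SpotTable-class].
#' @param mapping optional precomputed [GridMapping-class].
#' @param sigma Gaussian kernel sd in grid units (default 1).
#' @param kernelSize closing kernel side; default by platform (5 for
#'   Visium/Slide-seq/generic, 6 for Stereo-seq, 8 for SeqFISH).
#' @param delRate foreground-fraction drop threshold (default 0.01).
#' @param psi `"minmax"` or `"identity"` gene-dimension normalization.
#' @param ... passed to [gridMapping()].
#' @return A [S4Vectors::DataFrame], one row per gene, with the
#'   [patternIndex()] columns plus `dropped` and `drop_reason`; dropped
#'   genes carry `NA` scores. Row order follows the table.
#' @export
scoreGenePatterns <- function(table, mapping = NULL, sigma = 1.0,
                              kernelSize = NULL, delRate = 0.01,
                              psi = "minmax", ...) {
  if (is.null(mapping)) mapping <- gridMapping(table, ...)
  if (is.null(kernelSize))
    kernelSize <- .platformKernelSize(spotPlatform(table))
  nG <- nrow(table)
  sig <- sep <- rep(NA_real_, nG)
  reason <- rep(NA_character_, nG)
  for (g in seq_len(nG)) {
    img <- makeGeneImage(table, g, mapping)
    if (diff(range(pixelValues(img))) <= 0) { reason[g] <- "constant"; next }
    img <- minmaxNormalize(gaussianSmooth(minmaxNormalize(img), sigma))
    if (diff(range(pixelValues(img))) <= 0) { reason[g] <- "constant"; next }
    fg <- adaptiveThreshold(img)
    fg <- morphClose(fg, kernelSize) & img@validMask
    seg <- labelRegions(fg, img@validMask)
    if (!applyDelRate(seg, nValidPixels(img), delRate)) {
      reason[g] <- "low_foreground"; next
    }
    if (seg@backgroundSize == 0) { reason[g] <- "no_background"; next }
    sig[g] <- significanceFactor(img, seg)
    sep[g] <- separabilityFactor(img, seg)
  }
  keep <- is.na(reason)
  out <- DataFrame(gene_id = rownames(table),
                   significance_raw = sig, separability_raw = sep,
                   significance_norm = NA_real_, separability_norm = NA_real_,
                   pi = NA_real_, rank = NA_integer_,
                   dropped = !keep, drop_reason = reason)
  if (sum(keep) >= 2 || (sum(keep) >= 1 && psi == "identity")) {
    rec <- patternIndex(sig[keep], sep[keep], psi = psi,
                        geneIds = rownames(table)[keep])
    for (cn in c("significance_norm", "separability_norm", "pi", "rank"))
      out[[cn]][keep] <- rec[[cn]]
  } else if (sum(keep) > 0) {
    stop("fewer than 2 scored genes: psi normalization undefined")
  }
  metadata(out) <- list(sigma = sigma, kernelSize = kernelSize,
                        delRate = delRate, psi = psi,
                        gridMode = mapping@mode,
                        nDropped = sum(!keep))
  out
}
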