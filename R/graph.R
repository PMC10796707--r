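#' Pre-process expression for the embedding network
#'
#' Removes genes expressed in fewer than `minSpots` spots, divides each
#' spot's counts by its total UMI (so pre-log spot sums equal 1),
#' transforms to natural log scale with `log1p`, and restricts to the
#' `nSVGs` genes with the highest pattern index (all scored genes if fewer
#' are available, with a message). Spots with zero total count are dropped
#' with a warning.
#'
#' @param table a [SpotTable-class].
#' @param piRecords optional [scoreGenePatterns()] output used to rank
#'   genes; `NULL` keeps all surviving genes.
#' @param nSVGs number of top-ranked genes to keep (default 3000).
#' @param minSpots detection filter (default 10).
#' @return Numeric matrix, spots x genes, log scale. The kept spot ids are
#'   the row names.
#' @export
preprocessExpression <- function(table, piRecords = NULL, nSVGs = 3000L,
                                 minSpots = 10L) {
  table <- filterGenes(table, minSpots)
  x <- t(assay(table, "counts"))                 # spots x genes
  tot <- rowSums(x)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " spots with zero total count dropped")
    x <- x[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  x <- log1p(x / tot)
  if (!is.null(piRecords)) {
    sc <- piRecords[!piRecords$dropped & piRecords$gene_id %in% colnames(x), ]
    sc <- sc[order(-sc$pi), ]
    if (nrow(sc) > nSVGs) sc <- sc[seq_len(nSVGs), ]
    else message("only ", nrow(sc), " scored genes available for nSVGs = ",
                 nSVGs, "; keeping all of them")
    x <- x[, sc$gene_id, drop = FALSE]
  }
  x
}

#' Build the directed kNN spot graph
#'
#' Each spot is connected to its `k` nearest Euclidean neighbours (ties by
#' index), giving the binary adjacency A used by the Laplacian smoothing
#' filter and the attention layer; both work with the self-looped
#' adjacency `I + A` (renormalization trick). Default `k`: 6 on Visium
#' (hex neighbours), 20 on cellular-resolution platforms.
#'
#' @param coords n x 2 spot coordinate matrix.
#' @param k neighbours per spot (`k < n`).
#' @return A [SpatialGraph-class].
#' @export
buildGraph <- function(coords, k = 6L) {
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of spots")
  nbr <- knnIndices(coords, k)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nbr),
                            x = 1, dims = c(n, n))
  new("SpatialGraph", adjacency = methods::as(A, "generalMatrix"),
      k = as.integer(k))
}

.platformGraphK <- function(platform) {
  switch(platform, visium = 6L, slide_seq = 20L, stereo_seq = 20L,
         seqfish = 20L, generic = 6L)
}

# n x k matrix of neighbour indices, rows ordered by source vertex.
neighborMatrix <- function(graph) {
  trip <- Matrix::summary(methods::as(graph@adjacency, "TsparseMatrix"))
  o <- order(trip$i, trip$j)
  matrix(trip$j[o], ncol = graph@k, byrow = TRUE)
}

#' Principal components of the processed expression
#'
#' Centered (not scaled) PCA; components are ordered by decreasing
#' explained variance and carry a deterministic sign convention (the
#' largest-magnitude loading of every component is positive).
#'
#' @param x numeric matrix, spots x genes.
#' @param nComponents number of components (default 50; clamped to the
#'   matrix rank bound).
#' @return Spots x `nComponents` score matrix X' with attributes
#'   `rotation`, `center` and `sdev`.
#' @export
pcaReduce <- function(x, nComponents = 50L) {
  nComponents <- min(nComponents, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = nComponents)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(pc$x, 2, flip, `*`)
  structure(scores,
            rotation = sweep(pc$rotation, 2, flip, `*`),
            center = pc$center, sdev = pc$sdev[seq_len(nComponents)])
}

#' Graph Laplacian smoothing filter
#'
#' Low-pass filters the principal components over the spot graph:
#' `X~ = H^t X'` with `H = I - gamma * D^(-1/2) (D - A^) D^(-1/2)`, where
#' `A^ = I + A` is the self-looped adjacency and `D` its degree matrix.
#' `gamma = 2/3` and `t = 2` by default.
#'
#' @param xPrime spots x d feature matrix (principal components).
#' @param graph a [SpatialGraph-class].
#' @param gamma filter strength in (0, 1].
#' @param t number of stacked filter applications (>= 0).
#' @return The smoothed feature matrix X~ (same shape as `xPrime`).
#' @export
laplacianSmooth <- function(xPrime, graph, gamma = 2 / 3, t = 2L) {
  stopifnot(gamma > 0, gamma <= 1, t >= 0)
  H <- smoothingFilter(graph, gamma)
  out <- as.matrix(xPrime)
  for (s in seq_len(t)) out <- as.matrix(H %*% out)
  out
}

# H = I - gamma * normalized Laplacian of the self-looped adjacency.
smoothingFilter <- function(graph, gamma) {
  Ahat <- selfLoopAdjacency(graph)
  dhat <- Matrix::rowSums(Ahat)
  Dihalf <- Matrix::Diagonal(x = 1 / sqrt(dhat))
  Ltilde <- Dihalf %*% (Matrix::Diagonal(x = dhat) - Ahat) %*% Dihalf
  Matrix::Diagonal(nrow(Ltilde)) - gamma * Ltilde
}

#' Construct a graph attention layer
#'
#' Parameters are initialized uniformly on `(-1/sqrt(fan_in),
#' 1/sqrt(fan_in))` under the given seed.
#'
#' @param dIn,dOut input/output feature dimensions (default 50 -> 50).
#' @param slope LeakyReLU negative slope (default 0.2).
#' @param aggregate `"self"` (sum of `theta_ij W h_i`) or `"neighbors"`
#'   (conventional `theta_ij W h_j`); see [AttentionModel-class].
#' @param seed RNG seed for the initialization.
#' @return An [AttentionModel-class].
#' @export
attentionModel <- function(dIn = 50L, dOut = 50L, slope = 0.2,
                           aggregate = c("self", "neighbors"), seed = 1L) {
  aggregate <- match.arg(aggregate)
  withSeed(seed, {
    W <- matrix(stats::runif(dOut * dIn, -1, 1) / sqrt(dIn), dOut, dIn)
    w <- stats::runif(2 * dOut, -1, 1) / sqrt(2 * dOut)
  })
  new("AttentionModel", W = W, w = w, slope = slope, aggregate = aggregate)
}

# Forward pass keeping every intermediate needed by the backward pass.
# Returns list(h, theta, z, pre, m, nbr).
.attnForward <- function(x, graph, model) {
  nbr <- neighborMatrix(graph)
  Z <- x %*% t(model@W)                       # n x dOut transformed features
  aL <- as.numeric(Z %*% model@w[seq_len(nrow(model@W))])
  aR <- as.numeric(Z %*% model@w[nrow(model@W) + seq_len(nrow(model@W))])
  pre <- aL + matrix(aR[nbr], nrow(nbr), ncol(nbr))      # e_ij pre-activation
  e <- ifelse(pre > 0, pre, model@slope * pre)           # LeakyReLU
  e <- e - apply(e, 1, max)
  theta <- exp(e) / rowSums(exp(e))                      # softmax over N_i
  m <- if (model@aggregate == "self") {
    Z * rowSums(theta)                                   # row sums are 1
  } else {
    S <- Matrix::sparseMatrix(i = rep(seq_len(nrow(nbr)), ncol(nbr)),
                              j = as.vector(nbr), x = as.vector(theta),
                              dims = dim(graph@adjacency))
    as.matrix(S %*% Z)
  }
  h <- ifelse(m > 0, m, exp(pmin(m, 0)) - 1)             # elu
  list(h = h, theta = theta, z = Z, pre = pre, m = m, nbr = nbr)
}

#' Graph attention forward pass
#'
#' Computes `e_ij = LeakyReLU(w^T [W h_i || W h_j])` over the first-order
#' neighbours, softmax-normalizes to attention coefficients `theta_ij`
#' (each row of coefficients sums to 1), aggregates, and applies the elu
#' output activation.
#'
#' @param x spots x dIn feature matrix (Laplacian-smoothed PCs).
#' @param graph a [SpatialGraph-class].
#' @param model an [AttentionModel-class].
#' @return `list(h, theta)`: the n x dOut embedding and the n x k matrix
#'   of attention coefficients aligned with the neighbour lists.
#' @export
attentionForward <- function(x, graph, model) {
  fw <- .attnForward(x, graph, model)
  list(h = fw$h, theta = fw$theta)
}

# Backward pass: gradient of the loss w.r.t. W and w given dL/dh.
.attnBackward <- function(G, fw, x, graph, model) {
  dOut <- nrow(model@W)
  dm <- G * ifelse(fw$m > 0, 1, exp(pmin(fw$m, 0)))      # elu'
  n <- nrow(x)
  if (model@aggregate == "self") {
    # m_i = z_i exactly (attention rows sum to 1), so theta carries no
    # gradient and neither does w.
    dZ <- dm
    dw <- numeric(2 * dOut)
  } else {
    nbr <- fw$nbr
    S <- Matrix::sparseMatrix(i = rep(seq_len(n), ncol(nbr)),
                              j = as.vector(nbr), x = as.vector(fw$theta),
                              dims = c(n, n))
    dZ <- as.matrix(Matrix::t(S) %*% dm)
    # dtheta_ij = dm_i . z_j, evaluated on edges only
    dtheta <- matrix(rowSums(dm[rep(seq_len(n), ncol(nbr)), , drop = FALSE] *
                               fw$z[as.vector(nbr), , drop = FALSE]),
                     n, ncol(nbr))
    dth_row <- rowSums(fw$theta * dtheta)
    de <- fw$theta * (dtheta - dth_row)
    dpre <- de * ifelse(fw$pre > 0, 1, model@slope)
    daL <- rowSums(dpre)
    dbR <- as.numeric(Matrix::colSums(Matrix::sparseMatrix(
      i = rep(seq_len(n), ncol(nbr)), j = as.vector(nbr),
      x = as.vector(dpre), dims = c(n, n))))
    wl <- model@w[seq_len(dOut)]
    wr <- model@w[dOut + seq_len(dOut)]
    dZ <- dZ + outer(daL, wl) + outer(dbR, wr)
    dw <- c(as.numeric(t(fw$z) %*% daL), as.numeric(t(fw$z) %*% dbR))
  }
  list(dW = t(dZ) %*% x, dw = dw)
}
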