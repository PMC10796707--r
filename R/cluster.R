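#' Initialize cluster centers on an embedding
#'
#' Model-based (`mclust`, the default, or its alias `gmm`) or `kmeans`
#' initialization for a given number of clusters K; `louvain` / `leiden`
#' community detection on a kNN graph of the embedding for a given
#' resolution. Centers are the per-cluster means of the initial hard
#' partition; the whole step is deterministic under a fixed seed.
#'
#' @param h spots x d embedding matrix.
#' @param method `"mclust"`, `"gmm"`, `"kmeans"`, `"louvain"` or
#'   `"leiden"`.
#' @param k number of clusters (mclust/kmeans; `k <= n`).
#' @param resolution community-detection resolution (louvain/leiden).
#' @param seed RNG seed.
#' @param graphK neighbours for the embedding kNN graph used by
#'   louvain/leiden (default 15).
#' @return `list(centers, labels)`: K x d center matrix and the initial
#'   integer partition.
#' @export
initCenters <- function(h, method = c("mclust", "gmm", "kmeans", "louvain",
                                      "leiden"),
                        k = NULL, resolution = 1, seed = 1L, graphK = 15L) {
  method <- match.arg(method)
  n <- nrow(h)
  if (method %in% c("mclust", "gmm", "kmeans")) {
    stopifnot(!is.null(k))
    if (k > n) stop("more clusters than spots")
  }
  labels <- withSeed(seed, switch(
    method,
    mclust = ,
    gmm = {
      mclustBIC <- mclust::mclustBIC   # Mclust resolves this in our frame
      fit <- mclust::Mclust(h, G = k, verbose = FALSE)
      as.integer(fit$classification)
    },
    kmeans = as.integer(stats::kmeans(h, centers = k, nstart = 10L,
                                      iter.max = 100L)$cluster),
    louvain = ,
    leiden = {
      nbr <- knnIndices(h, min(graphK, n - 1L))
      g <- igraph::graph_from_edgelist(
        cbind(rep(seq_len(n), ncol(nbr)), as.vector(nbr)), directed = FALSE)
      g <- igraph::simplify(g)
      comm <- if (method == "louvain")
        igraph::cluster_louvain(g, resolution = resolution)
      else igraph::cluster_leiden(g, objective_function = "modularity",
                                  resolution = resolution, n_iterations = 5L)
      as.integer(igraph::membership(comm))
    }))
  centers <- rowsum(h, labels) / as.vector(table(labels))
  list(centers = unname(as.matrix(centers)), labels = labels)
}

#' Student's-t soft cluster assignment
#'
#' `q_ik` is proportional to `(1 + ||h_i - phi_k||^2 / nu)^(-(nu + 1)/2)`,
#' normalized over the K centers; `nu` defaults to 0.5.
#'
#' @param h spots x d embedding.
#' @param centers K x d center matrix.
#' @param nu Student's-t degrees of freedom (> 0).
#' @return n x K soft assignment matrix with unit row sums.
#' @export
softAssign <- function(h, centers, nu = 0.5) {
  stopifnot(nu > 0)
  d2 <- outer(rowSums(h^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(h)), rowSums(centers^2)) -
    2 * h %*% t(centers)
  d2[d2 < 0] <- 0
  q <- (1 + d2 / nu)^(-(nu + 1) / 2)
  q / rowSums(q)
}

#' Auxiliary target distribution
#'
#' Sharpens the soft assignment: `p_ik` proportional to
#' `q_ik^2 / sum_i q_ik`, row-normalized. Empty clusters (zero column
#' sum) are excluded with a warning.
#'
#' @param q n x K soft assignment matrix.
#' @return n x K target matrix with unit row sums.
#' @export
targetDistribution <- function(q) {
  f <- colSums(q)
  if (any(f == 0)) {
    warning(sum(f == 0), " empty cluster column(s) excluded from the target")
    f[f == 0] <- Inf
  }
  w <- sweep(q^2, 2, f, `/`)
  w / rowSums(w)
}

#' Kullback-Leibler clustering loss
#'
#' `L = sum_ik p_ik log(p_ik / q_ik)` with the `0 log 0 = 0` convention.
#'
#' @param p,q matched n x K distributions (rows sum to 1).
#' @return The scalar loss (>= 0).
#' @export
klLoss <- function(p, q) {
  stopifnot(identical(dim(p), dim(q)))
  pos <- p > 0
  sum(p[pos] * log(p[pos] / q[pos]))
}

#' Analytic gradients of the clustering loss
#'
#' Closed forms of `dL/dh_i` and `dL/dphi_k` for the Student's-t kernel
#' loss with the target held constant:
#' `dL/dh_i = (nu+1)/nu * sum_k (1 + ||h_i - phi_k||^2/nu)^(-1)
#' (p_ik - q_ik)(h_i - phi_k)` and `dL/dphi_k` its negative counterpart
#' summed over spots. These feed the optimizer directly and are verified
#' against finite differences in the test suite.
#'
#' @param h spots x d embedding.
#' @param centers K x d centers.
#' @param p,q target and soft assignment matrices.
#' @param nu Student's-t degrees of freedom.
#' @return `list(grad_h, grad_centers)`.
#' @export
clusterGradients <- function(h, centers, p, q, nu = 0.5) {
  d2 <- outer(rowSums(h^2), rep(1, nrow(centers))) +
    outer(rep(1, nrow(h)), rowSums(centers^2)) -
    2 * h %*% t(centers)
  d2[d2 < 0] <- 0
  A <- (p - q) / (1 + d2 / nu)
  cfac <- (nu + 1) / nu
  gh <- cfac * (h * rowSums(A) - A %*% centers)
  gphi <- -cfac * (t(A) %*% h - colSums(A) * centers)
  list(grad_h = unname(as.matrix(gh)), grad_centers = unname(as.matrix(gphi)))
}

# One Adam step; st carries m, v and the step counter.
adamStep <- function(st, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  st$delta <- -lr * mhat / (sqrt(vhat) + eps)
  st
}

adamInit <- function(param) list(m = param * 0, v = param * 0, t = 0L)

#' Self-supervised training of the attention embedding and clusters
#'
#' Joint optimization of the attention parameters (W, w) and the cluster
#' centers by Adam on the KL loss between the Student's-t soft assignment
#' Q and the sharpened target P. P is recomputed every `pUpdateEvery`
#' epochs (default 3) from all embedded spots; training stops when the
#' fraction of spots changing hard label between consecutive target
#' updates falls below `tol`, or at `maxEpochs`. The run is deterministic
#' given the model initialization and centers.
#'
#' @param xTilde spots x d smoothed feature matrix.
#' @param graph the [SpatialGraph-class].
#' @param model an [AttentionModel-class] (its parameters are trained).
#' @param centers initial K x d centers (see [initCenters()]).
#' @param nu Student's-t degrees of freedom (default 0.5).
#' @param lr Adam learning rate (default 1e-3).
#' @param maxEpochs epoch budget (default 500).
#' @param tol stopping threshold on the label-change fraction
#'   (default 1e-3).
#' @param pUpdateEvery target-refresh period in epochs (default 3).
#' @return A [ClusterState-class].
#' @export
trainCluster <- function(xTilde, graph, model, centers, nu = 0.5,
                         lr = 1e-3, maxEpochs = 500L, tol = 1e-3,
                         pUpdateEvery = 3L) {
  centers <- as.matrix(centers)
  stW <- adamInit(model@W); stw <- adamInit(model@w)
  stC <- adamInit(centers)
  loss <- numeric(0)
  prevLabels <- NULL
  p <- NULL
  for (epoch in seq_len(maxEpochs)) {
    fw <- .attnForward(xTilde, graph, model)
    q <- softAssign(fw$h, centers, nu)
    if ((epoch - 1L) %% pUpdateEvery == 0L) {
      p <- targetDistribution(q)
      labels <- max.col(q, ties.method = "first")
      if (!is.null(prevLabels) && mean(labels != prevLabels) < tol) break
      prevLabels <- labels
    }
    L <- klLoss(p, q)
    if (!is.finite(L))
      stop("training diverged: non-finite loss at epoch ", epoch)
    loss <- c(loss, L)
    gr <- clusterGradients(fw$h, centers, p, q, nu)
    bk <- .attnBackward(gr$grad_h, fw, xTilde, graph, model)
    stW <- adamStep(stW, bk$dW, lr); model@W <- model@W + stW$delta
    stw <- adamStep(stw, bk$dw, lr); model@w <- model@w + stw$delta
    stC <- adamStep(stC, gr$grad_centers, lr); centers <- centers + stC$delta
  }
  fw <- .attnForward(xTilde, graph, model)
  q <- softAssign(fw$h, centers, nu)
  new("ClusterState", model = model, centers = centers, q = q,
      p = targetDistribution(q), nu = nu,
      labels = as.integer(max.col(q, ties.method = "first")),
      embedding = fw$h, lossHistory = loss)
}

#' Spatial smoothing of cluster labels
#'
#' Each spot is reassigned to the strict-majority label of its k nearest
#' neighbours when that majority exceeds half the neighbourhood and
#' differs from the spot's own label; ties and sub-majority neighbourhoods
#' keep the original label. Applied `nPasses` times (default 1),
#' simultaneously within each pass.
#'
#' @param labels integer label vector.
#' @param coords spot coordinates aligned with `labels`.
#' @param k neighbourhood size (default 6).
#' @param nPasses number of passes.
#' @return The smoothed label vector.
#' @export
postprocessLabels <- function(labels, coords, k = 6L, nPasses = 1L) {
  stopifnot(length(labels) == nrow(coords))
  nbr <- knnIndices(coords, min(k, nrow(coords) - 1L))
  out <- as.integer(labels)
  for (pass in seq_len(nPasses)) {
    nl <- matrix(out[nbr], nrow(nbr), ncol(nbr))
    newLab <- vapply(seq_along(out), function(i) {
      tb <- tabulate(nl[i, ])
      top <- which.max(tb)
      if (tb[top] * 2L > ncol(nbr) && top != out[i]) top else out[i]
    }, integer(1))
    if (identical(newLab, out)) break
    out <- newLab
  }
  out
}

.checkPartitions <- function(a, b) {
  if (length(a) != length(b))
    stop("partition length mismatch: ", length(a), " vs ", length(b))
  list(as.integer(factor(a)), as.integer(factor(b)))
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance (permutation-invariant;
#' 1 for identical partitions).
#'
#' @param a,b label vectors of equal length.
#' @return The ARI.
#' @export
ariScore <- function(a, b) {
  ab <- .checkPartitions(a, b)
  if (identical(ab[[1]], ab[[2]])) return(1)
  igraph::compare(ab[[1]], ab[[2]], method = "adjusted.rand")
}

#' Normalized mutual information between two partitions
#'
#' Mutual information normalized by the arithmetic mean of the two
#' entropies (Danon normalization).
#'
#' @inheritParams ariScore
#' @return The NMI in `[0, 1]`.
#' @export
nmiScore <- function(a, b) {
  ab <- .checkPartitions(a, b)
  if (identical(ab[[1]], ab[[2]])) return(1)
  igraph::compare(ab[[1]], ab[[2]], method = "nmi")
}
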