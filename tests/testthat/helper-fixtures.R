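library(SummarizedExperiment)

# GeneImage from a plain matrix (all pixels valid unless a mask is given)
asImage <- function(px, valid = NULL) {
  px <- as.matrix(px)
  if (is.null(valid)) valid <- matrix(TRUE, nrow(px), ncol(px))
  new("GeneImage", pixels = px, validMask = valid,
      spotToPixel = cbind(row = 1L, col = 1L))
}

# tiny SpotTable on an integer lattice
latticeTable <- function(counts, H, W, platform = "generic") {
  counts <- as.matrix(counts)
  colnames(counts) <- sprintf("s%03d", seq_len(ncol(counts)))
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  co <- cbind(x = rep(seq_len(W), each = H), y = rep(seq_len(H), times = W))
  SpotTable(counts, co, platform = platform)
}

# all permutations of 1..n (n small)
allPerms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# independent brute-force flood fill, 8-connectivity
floodLabels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (!mask[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        r <- p[1] + di; c <- p[2] + dj
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- cur
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# direct-sum Moran's I and Geary's C oracles
moranOracle <- function(x, W) {
  W <- as.matrix(W)
  z <- x - mean(x)
  num <- 0
  for (i in seq_along(x)) for (j in seq_along(x))
    num <- num + W[i, j] * z[i] * z[j]
  length(x) / sum(W) * num / sum(z^2)
}
gearyOracle <- function(x, W) {
  W <- as.matrix(W)
  num <- 0
  for (i in seq_along(x)) for (j in seq_along(x))
    num <- num + W[i, j] * (x[i] - x[j])^2
  (length(x) - 1) / (2 * sum(W)) * num / sum((x - mean(x))^2)
}

# pair-counting ARI oracle over all spot pairs
ariOracle <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  tot <- choose(n, 2)
  exp_ri <- (s11 + s10) * (s11 + s01) / tot
  (s11 - exp_ri) / ((s11 + s10 + s11 + s01) / 2 - exp_ri)
}
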