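#' Spot-to-grid mapping shared by all gene images of a table
#'
#' Computed once per `SpotTable` and reused by [makeGeneImage()] so that
#' every gene of a table shares the same grid, valid mask and valid-pixel
#' count. Two modes:
#'
#' * `"one_to_one"` (array platforms, e.g. Visium): spots map one-to-one to
#'   grid cells through their integer array row/column indices (taken from
#'   `colData` columns `array_row`/`array_col` when present, otherwise from
#'   rounded coordinates). Cells not covered by a spot — including the
#'   half-empty checkerboard cells of the Visium hex layout — are invalid.
#' * `"linear"`: spot values are interpolated linearly (Delaunay /
#'   barycentric) onto the nodes of a regular grid whose resolution targets
#'   about one node per spot; nodes outside the convex hull of the spots
#'   are invalid.
#'
#' `mode = "auto"` picks `"one_to_one"` when the (offset) coordinates are
#' integer-valued with no collisions, `"linear"` otherwise.
#'
#' @slot mode `"one_to_one"` or `"linear"`.
#' @slot H,W grid dimensions.
#' @slot validMask logical H x W matrix.
#' @slot spotToPixel integer n_spots x 2 (row, col) matrix.
#' @slot pixelIndex one-to-one mode: linear pixel index of every spot.
#' @slot interp linear mode: sparse (H*W) x n_spots interpolation matrix.
#' @export
setClass("GridMapping",
         representation(mode = "character", H = "integer", W = "integer",
                        validMask = "matrix", spotToPixel = "matrix",
                        pixelIndex = "integer", interp = "Matrix"))

setMethod("show", "GridMapping", function(object) {
  cat("GridMapping:", object@mode, "mode,", object@H, "x", object@W,
      "grid,", sum(object@validMask), "valid pixels\n")
})

#' @rdname GridMapping-class
#' @param table a [SpotTable-class].
#' @param mode `"auto"`, `"one_to_one"` or `"linear"`.
#' @param shape optional `c(H, W)` for linear mode; default targets
#'   `H * W` approximately equal to the number of spots.
#' @param flipY if `TRUE` the grid row index increases with decreasing y
#'   (image convention); default `FALSE`, row increases with y.
#' @return A `GridMapping`.
#' @export
gridMapping <- function(table, mode = c("auto", "one_to_one", "linear"),
                        shape = NULL, flipY = FALSE) {
  mode <- match.arg(mode)
  co <- spotCoords(table)
  cd <- colData(table)
  hasArray <- all(c("array_row", "array_col") %in% colnames(cd))
  if (mode == "auto") {
    if (hasArray) mode <- "one_to_one"
    else {
      ij <- cbind(round(co[, 2] - min(co[, 2])), round(co[, 1] - min(co[, 1])))
      intish <- max(abs(co[, 2] - min(co[, 2]) - ij[, 1]),
                    abs(co[, 1] - min(co[, 1]) - ij[, 2])) < 1e-6
      mode <- if (intish && !anyDuplicated(ij)) "one_to_one" else "linear"
    }
  }
  if (mode == "one_to_one") {
    if (hasArray) {
      r0 <- cd$array_row - min(cd$array_row)
      c0 <- cd$array_col - min(cd$array_col)
    } else {
      r0 <- round(co[, 2] - min(co[, 2]))
      c0 <- round(co[, 1] - min(co[, 1]))
    }
    if (flipY) r0 <- max(r0) - r0
    H <- as.integer(max(r0) + 1); W <- as.integer(max(c0) + 1)
    pix <- as.integer(r0 + 1 + c0 * H)          # column-major linear index
    if (anyDuplicated(pix))
      stop("one-to-one mapping error: ", sum(duplicated(pix)),
           " spots collide on the same grid cell")
    vm <- matrix(FALSE, H, W); vm[pix] <- TRUE
    new("GridMapping", mode = "one_to_one", H = H, W = W, validMask = vm,
        spotToPixel = cbind(row = as.integer(r0 + 1), col = as.integer(c0 + 1)),
        pixelIndex = pix, interp = Matrix::Matrix(0, 0, 0, sparse = TRUE))
  } else {
    n <- nrow(co)
    if (n < 3) stop("linear interpolation requires at least 3 spots")
    rx <- diff(range(co[, 1])); ry <- diff(range(co[, 2]))
    if (rx <= 0 || ry <= 0) stop("degenerate (collinear) spot coordinates")
    if (is.null(shape)) {
      H <- max(2L, as.integer(round(sqrt(n * ry / rx))))
      W <- max(2L, as.integer(round(n / H)))
    } else { H <- as.integer(shape[1]); W <- as.integer(shape[2]) }
    gx <- seq(min(co[, 1]), max(co[, 1]), length.out = W)
    gy <- seq(min(co[, 2]), max(co[, 2]), length.out = H)
    if (flipY) gy <- rev(gy)
    nodes <- cbind(rep(gx, each = H), rep(gy, W))   # column-major over (H, W)
    interp <- barycentricWeights(co, nodes)
    vm <- matrix(as.vector(Matrix::rowSums(interp) > 0), H, W)
    nearestRow <- as.integer(round((co[, 2] - min(gy[1], gy[H])) /
                                     (abs(gy[H] - gy[1]) / (H - 1)))) + 1L
    if (flipY) nearestRow <- H + 1L - nearestRow
    nearestCol <- as.integer(round((co[, 1] - gx[1]) /
                                     ((gx[W] - gx[1]) / (W - 1)))) + 1L
    new("GridMapping", mode = "linear", H = H, W = W, validMask = vm,
        spotToPixel = cbind(row = pmin(pmax(nearestRow, 1L), H),
                            col = pmin(pmax(nearestCol, 1L), W)),
        pixelIndex = integer(0), interp = interp)
  }
}

# Bowyer-Watson Delaunay triangulation. Coordinates are rescaled to the
# unit box and perturbed by a deterministic ~1e-9 jitter to break the exact
# cocircularity of lattice-like inputs; the jitter affects only the
# triangulation, not the barycentric weights computed from it.
delaunayTriangles <- function(pts) {
  n <- nrow(pts)
  mins <- c(min(pts[, 1]), min(pts[, 2]))
  scale <- max(max(pts[, 1]) - mins[1], max(pts[, 2]) - mins[2])
  p <- cbind((pts[, 1] - mins[1]) / scale, (pts[, 2] - mins[2]) / scale)
  jit <- withSeed(991L, matrix(runif(2 * n, -1, 1) * 1e-9, n, 2))
  p <- p + jit
  P <- rbind(p, c(-10, -10), c(30, -10), c(-10, 30))
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), nrow = 1)
  cc <- matrix(0, 1, 3)                       # circumcenter x, y, r^2
  circum <- function(t) {
    a <- P[t[1], ]; b <- P[t[2], ]; c <- P[t[3], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
                c[1] * (a[2] - b[2]))
    ux <- ((a[1]^2 + a[2]^2) * (b[2] - c[2]) +
             (b[1]^2 + b[2]^2) * (c[2] - a[2]) +
             (c[1]^2 + c[2]^2) * (a[2] - b[2])) / d
    uy <- ((a[1]^2 + a[2]^2) * (c[1] - b[1]) +
             (b[1]^2 + b[2]^2) * (a[1] - c[1]) +
             (c[1]^2 + c[2]^2) * (b[1] - a[1])) / d
    c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
  }
  cc[1, ] <- circum(tris[1, ])
  for (i in seq_len(n)) {
    bad <- (P[i, 1] - cc[, 1])^2 + (P[i, 2] - cc[, 2])^2 < cc[, 3]
    if (!any(bad)) next
    badTris <- tris[bad, , drop = FALSE]
    edges <- rbind(badTris[, c(1, 2)], badTris[, c(2, 3)], badTris[, c(3, 1)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    newTris <- cbind(boundary, i)
    tris <- rbind(tris, newTris)
    cc <- rbind(cc, t(apply(newTris, 1, circum)))
  }
  keep <- apply(tris <= n, 1, all)
  tris[keep, , drop = FALSE]
}

# Sparse (n_nodes x n_spots) matrix of barycentric interpolation weights;
# rows of nodes outside the convex hull of the spots are all zero.
barycentricWeights <- function(spots, nodes) {
  tris <- delaunayTriangles(spots)
  nn <- nrow(nodes)
  assigned <- rep(FALSE, nn)
  ti <- integer(0); tj <- integer(0); tw <- numeric(0)
  for (t in seq_len(nrow(tris))) {
    todo <- which(!assigned)
    if (!length(todo)) break
    v <- tris[t, ]
    a <- spots[v[1], ]; b <- spots[v[2], ]; c <- spots[v[3], ]
    det <- (b[2] - c[2]) * (a[1] - c[1]) + (c[1] - b[1]) * (a[2] - c[2])
    l1 <- ((b[2] - c[2]) * (nodes[todo, 1] - c[1]) +
             (c[1] - b[1]) * (nodes[todo, 2] - c[2])) / det
    l2 <- ((c[2] - a[2]) * (nodes[todo, 1] - c[1]) +
             (a[1] - c[1]) * (nodes[todo, 2] - c[2])) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    hit <- todo[inside]
    if (!length(hit)) next
    assigned[hit] <- TRUE
    ti <- c(ti, rep(hit, 3))
    tj <- c(tj, rep(v, each = length(hit)))
    tw <- c(tw, pmax(c(l1[inside], l2[inside], l3[inside]), 0))
  }
  Matrix::sparseMatrix(i = ti, j = tj, x = tw,
                       dims = c(nn, nrow(spots)))
}

#' Render one gene as a grid image
#'
#' @param table a [SpotTable-class].
#' @param gene gene index or gene id.
#' @param mapping a [GridMapping-class]; computed from `table` if `NULL`
#'   (pass a precomputed one when rendering many genes).
#' @param ... passed to [gridMapping()] when `mapping` is `NULL`.
#' @return A [GeneImage-class]; pixels outside the tissue are `NA` and
#'   excluded from all downstream statistics.
#' @export
makeGeneImage <- function(table, gene, mapping = NULL, ...) {
  if (is.null(mapping)) mapping <- gridMapping(table, ...)
  if (is.character(gene)) gene <- match(gene, rownames(table))
  stopifnot(length(gene) == 1, !is.na(gene), gene >= 1, gene <= nrow(table))
  v <- as.numeric(assay(table, "counts")[gene, ])
  px <- matrix(NA_real_, mapping@H, mapping@W)
  if (mapping@mode == "one_to_one") {
    px[mapping@pixelIndex] <- v
  } else {
    val <- as.numeric(mapping@interp %*% v)
    px[mapping@validMask] <- val[mapping@validMask]
  }
  new("GeneImage", pixels = px, validMask = mapping@validMask,
      spotToPixel = mapping@spotToPixel)
}

#' Min-max normalize a gene image to [0, 1]
#'
#' Valid pixels are rescaled linearly to `[0, 1]`; a constant image maps to
#' all zeros (0/0 convention) and is flagged as degenerate downstream.
#'
#' @param img a [GeneImage-class].
#' @return The rescaled [GeneImage-class].
#' @export
minmaxNormalize <- function(img) {
  stopifnot(nValidPixels(img) >= 1)
  img@pixels[img@validMask] <- minmaxVector(img@pixels[img@validMask])
  img
}

#' Masked Gaussian smoothing of a gene image
#'
#' Discrete Gaussian filtering restricted to the valid mask: the kernel is
#' renormalized over the valid support at every pixel (masked normalized
#' convolution), so invalid pixels neither receive nor contribute weight
#' and a constant image is preserved exactly. The kernel is truncated at
#' `4 * sigma`.
#'
#' @param img a [GeneImage-class].
#' @param sigma kernel standard deviation in grid units (default 1).
#' @return The smoothed [GeneImage-class].
#' @export
gaussianSmooth <- function(img, sigma = 1.0) {
  stopifnot(sigma > 0)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  g <- stats::dnorm(-r:r, sd = sigma)
  g <- g / sum(g)
  m <- img@validMask * 1
  z <- ifelse(img@validMask, img@pixels, 0)
  conv1 <- function(x, along) {
    out <- matrix(0, nrow(x), ncol(x))
    for (o in -r:r) {
      w <- g[o + r + 1]
      if (w == 0) next
      if (along == 1) {                       # shift rows
        src <- seq_len(nrow(x)) - o
        ok <- src >= 1 & src <= nrow(x)
        out[ok, ] <- out[ok, ] + w * x[src[ok], , drop = FALSE]
      } else {
        src <- seq_len(ncol(x)) - o
        ok <- src >= 1 & src <= ncol(x)
        out[, ok] <- out[, ok] + w * x[, src[ok], drop = FALSE]
      }
    }
    out
  }
  num <- conv1(conv1(z, 1), 2)
  den <- conv1(conv1(m, 1), 2)
  sm <- img@pixels
  sm[img@validMask] <- num[img@validMask] / den[img@validMask]
  img@pixels <- sm
  img
}
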