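#' @import methods
#' @importFrom Matrix Matrix rowSums colSums t diag sparseMatrix
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assay<- assayNames colData rowData
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment reducedDim reducedDim<-
NULL

.PLATFORMS <- c("visium", "slide_seq", "stereo_seq", "seqfish", "generic")

#' Spot-level spatial expression container
#'
#' `SpotTable` extends [SingleCellExperiment::SingleCellExperiment] and holds
#' a UMI count matrix (features in rows, spots in columns, assay `"counts"`),
#' 2-D spatial coordinates of every spot (columns `x`, `y` of `colData`) and
#' a platform tag (one of `r paste(.PLATFORMS, collapse = ", ")`) stored in
#' `metadata(x)$platform`. Array platforms (Visium) may additionally carry
#' integer `array_row` / `array_col` columns in `colData`, used for
#' one-to-one gene-image rendering.
#'
#' @slot .. inherited from `SingleCellExperiment`.
#' @seealso [SpotTable()], [spotCoords()], [readSpotTable()]
#' @export
setClass("SpotTable", contains = "SingleCellExperiment")

setValidity("SpotTable", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cnt <- assay(object, "counts")
    if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  }
  cd <- colData(object)
  if (!all(c("x", "y") %in% colnames(cd)))
    msg <- c(msg, "colData must contain spot coordinates 'x' and 'y'")
  else if (!all(is.finite(cd$x)) || !all(is.finite(cd$y)))
    msg <- c(msg, "spot coordinates must be finite")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "spot ids must be unique")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids must be unique")
  pf <- metadata(object)$platform
  if (is.null(pf) || !pf %in% .PLATFORMS)
    msg <- c(msg, sprintf("metadata$platform must be one of: %s",
                          paste(.PLATFORMS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a SpotTable
#'
#' @param counts numeric matrix of UMI counts, genes in rows and spots in
#'   columns (dense or `Matrix` sparse). Row and column names are the gene
#'   and spot ids.
#' @param coords two-column numeric matrix or data.frame of spot positions
#'   (x, y), one row per spot, in the same order as `colnames(counts)`.
#' @param platform character scalar platform tag.
#' @param array_indices optional integer matrix/data.frame with columns
#'   `array_row`, `array_col` for array platforms.
#' @return A [SpotTable-class] object.
#' @examples
#' cnt <- matrix(rpois(12, 2), nrow = 3,
#'               dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' st <- SpotTable(cnt, cbind(x = c(0, 1, 0, 1), y = c(0, 0, 1, 1)))
#' st
#' @export
SpotTable <- function(counts, coords, platform = "generic",
                      array_indices = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("spot", seq_len(ncol(counts)))
  coords <- as.matrix(coords)
  if (nrow(coords) != ncol(counts))
    stop("alignment error: ", nrow(coords), " coordinate rows for ",
         ncol(counts), " spots")
  cd <- DataFrame(x = as.numeric(coords[, 1]), y = as.numeric(coords[, 2]),
                  row.names = colnames(counts))
  if (!is.null(array_indices)) {
    ai <- as.data.frame(array_indices)
    cd$array_row <- as.integer(ai$array_row)
    cd$array_col <- as.integer(ai$array_col)
  }
  sce <- SingleCellExperiment(assays = list(counts = counts), colData = cd)
  metadata(sce)$platform <- match.arg(platform, .PLATFORMS)
  new("SpotTable", sce)
}

#' @describeIn SpotTable spot coordinates as an n_spots x 2 matrix.
#' @param x a `SpotTable`.
#' @export
spotCoords <- function(x) {
  cd <- colData(x)
  m <- cbind(x = cd$x, y = cd$y)
  rownames(m) <- colnames(x)
  m
}

#' @describeIn SpotTable the platform tag.
#' @export
spotPlatform <- function(x) metadata(x)$platform

setMethod("show", "SpotTable", function(object) {
  cat("SpotTable:", nrow(object), "genes x", ncol(object), "spots,",
      "platform =", spotPlatform(object), "\n")
  callNextMethod()
})

#' A single gene rendered as a grid image
#'
#' Pixels form an H x W matrix; `validMask` marks pixels covered by tissue.
#' `spotToPixel` maps each spot to its (row, col) grid cell (the nearest
#' grid node under linear interpolation).
#'
#' @slot pixels numeric matrix H x W; `NA` outside the valid mask.
#' @slot validMask logical matrix H x W.
#' @slot spotToPixel integer matrix n_spots x 2 (row, col).
#' @export
setClass("GeneImage",
         representation(pixels = "matrix", validMask = "matrix",
                        spotToPixel = "matrix"))

setValidity("GeneImage", function(object) {
  msg <- character()
  if (!identical(dim(object@pixels), dim(object@validMask)))
    msg <- c(msg, "pixels and validMask dimensions differ")
  if (!is.logical(object@validMask))
    msg <- c(msg, "validMask must be logical")
  v <- object@pixels[object@validMask]
  if (length(v) && !all(is.finite(v)))
    msg <- c(msg, "pixel values must be finite on the valid mask")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneImage number of valid pixels (N').
#' @param x a `GeneImage`.
#' @export
nValidPixels <- function(x) sum(x@validMask)

#' @describeIn GeneImage valid-pixel values as a vector (column-major order).
#' @export
pixelValues <- function(x) x@pixels[x@validMask]

setMethod("show", "GeneImage", function(object) {
  cat("GeneImage:", nrow(object@pixels), "x", ncol(object@pixels),
      "grid,", nValidPixels(object), "valid pixels\n")
})

#' Foreground/background segmentation of a gene image
#'
#' Integer label matrix: 0 = background, 1..L = 8-connected foreground
#' regions; pixels outside the valid mask are `NA`.
#'
#' @slot labels integer matrix H x W.
#' @slot nRegions integer, number of foreground regions L.
#' @slot regionSizes integer vector of region pixel counts.
#' @slot backgroundSize integer, number of background pixels.
#' @export
setClass("ImageSegmentation",
         representation(labels = "matrix", nRegions = "integer",
                        regionSizes = "integer", backgroundSize = "integer"))

setValidity("ImageSegmentation", function(object) {
  msg <- character()
  lab <- object@labels[!is.na(object@labels)]
  L <- object@nRegions
  if (L > 0 && !setequal(setdiff(unique(lab), 0L), seq_len(L)))
    msg <- c(msg, "region labels must be contiguous 1..L")
  if (length(object@regionSizes) != L)
    msg <- c(msg, "regionSizes length must equal nRegions")
  if (sum(object@regionSizes) + object@backgroundSize != length(lab))
    msg <- c(msg, "region sizes + background must cover all valid pixels")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ImageSegmentation", function(object) {
  cat("ImageSegmentation:", object@nRegions, "foreground regions (",
      paste(object@regionSizes, collapse = ", "), "pixels ),",
      object@backgroundSize, "background pixels\n")
})

#' Spatial weight matrix for autocorrelation statistics
#'
#' @slot weights sparse numeric n x n matrix with zero diagonal.
#' @slot rule neighbourhood rule: `"knn"`, `"grid_rook"` or `"grid_queen"`.
#' @slot k integer, neighbours per spot (kNN rule only, `NA` otherwise).
#' @slot rowStandardized logical.
#' @export
setClass("WeightMatrix",
         representation(weights = "Matrix", rule = "character",
                        k = "integer", rowStandardized = "logical"))

setValidity("WeightMatrix", function(object) {
  msg <- character()
  w <- object@weights
  if (nrow(w) != ncol(w)) msg <- c(msg, "weights must be square")
  if (any(Matrix::diag(w) != 0)) msg <- c(msg, "diagonal must be zero")
  if (any(w@x < 0)) msg <- c(msg, "weights must be non-negative")
  if (!object@rule %in% c("knn", "grid_rook", "grid_queen"))
    msg <- c(msg, "unknown neighbour rule")
  if (length(msg)) msg else TRUE
})

setMethod("show", "WeightMatrix", function(object) {
  cat("WeightMatrix:", nrow(object@weights), "spots, rule =", object@rule,
      if (!is.na(object@k)) paste0("(k = ", object@k, ")") else "",
      if (object@rowStandardized) "row-standardized" else "binary", "\n")
})

#' k-nearest-neighbour spot graph
#'
#' Directed kNN graph on spot coordinates. `adjacency` is the binary matrix
#' A with `A[i, j] = 1` iff spot j is one of the k nearest neighbours of
#' spot i; the self-looped adjacency used by the Laplacian smoothing filter
#' and the attention layer is `I + A` (renormalization trick).
#'
#' @slot adjacency sparse binary n x n matrix A.
#' @slot k integer.
#' @export
setClass("SpatialGraph",
         representation(adjacency = "Matrix", k = "integer"))

setValidity("SpatialGraph", function(object) {
  msg <- character()
  if (any(Matrix::rowSums(object@adjacency) != object@k))
    msg <- c(msg, "every row of the adjacency must have exactly k ones")
  if (any(Matrix::diag(object@adjacency) != 0))
    msg <- c(msg, "adjacency must have a zero diagonal (self-loops are added separately)")
  if (length(msg)) msg else TRUE
})

#' @describeIn SpatialGraph self-looped adjacency `I + A`.
#' @param x a `SpatialGraph`.
#' @export
selfLoopAdjacency <- function(x) {
  Matrix::Diagonal(nrow(x@adjacency)) + x@adjacency
}

setMethod("show", "SpatialGraph", function(object) {
  cat("SpatialGraph:", nrow(object@adjacency), "spots, k =", object@k, "\n")
})

#' Single-head graph attention layer parameters
#'
#' One 50 -> 50 (by default) graph-attention layer: a shared linear map `W`,
#' an attention vector `w` of length `2 * d_out` scoring concatenated
#' transformed features through a LeakyReLU, softmax-normalised over each
#' vertex's neighbours, and an elu output activation. `aggregate` selects
#' the aggregand: `"self"` sums `theta_ij W h_i` (so the neighbours enter
#' only through the attention weights, which row-sum to one), while
#' `"neighbors"` sums the conventional `theta_ij W h_j`.
#'
#' @slot W numeric d_out x d_in weight matrix.
#' @slot w numeric attention vector, length `2 * d_out`.
#' @slot slope LeakyReLU negative slope.
#' @slot aggregate `"self"` or `"neighbors"`.
#' @export
setClass("AttentionModel",
         representation(W = "matrix", w = "numeric", slope = "numeric",
                        aggregate = "character"))

setValidity("AttentionModel", function(object) {
  msg <- character()
  if (length(object@w) != 2L * nrow(object@W))
    msg <- c(msg, "attention vector length must be 2 * nrow(W)")
  if (!object@aggregate %in% c("self", "neighbors"))
    msg <- c(msg, "aggregate must be 'self' or 'neighbors'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AttentionModel", function(object) {
  cat("AttentionModel:", ncol(object@W), "->", nrow(object@W),
      "single-head graph attention, LeakyReLU slope", object@slope,
      ", aggregate =", object@aggregate, "\n")
})

#' State of the self-supervised clustering
#'
#' Returned by [trainCluster()]: trained attention parameters, cluster
#' centers, soft assignments Q (Student's-t kernel), target distribution P,
#' hard labels (argmax of Q rows) and the loss history.
#'
#' @slot model the trained [AttentionModel-class].
#' @slot centers K x d matrix of cluster centers.
#' @slot q n x K soft assignment matrix (rows sum to 1).
#' @slot p n x K target distribution (rows sum to 1).
#' @slot nu Student's-t degrees of freedom.
#' @slot labels integer vector of hard assignments.
#' @slot embedding n x d final embedding h'.
#' @slot lossHistory numeric vector of KL loss per epoch.
#' @export
setClass("ClusterState",
         representation(model = "AttentionModel", centers = "matrix",
                        q = "matrix", p = "matrix", nu = "numeric",
                        labels = "integer", embedding = "matrix",
                        lossHistory = "numeric"))

setValidity("ClusterState", function(object) {
  msg <- character()
  if (any(abs(rowSums(object@q) - 1) > 1e-8))
    msg <- c(msg, "rows of q must sum to 1")
  if (any(abs(rowSums(object@p) - 1) > 1e-8))
    msg <- c(msg, "rows of p must sum to 1")
  if (!identical(object@labels,
                 as.integer(max.col(object@q, ties.method = "first"))))
    msg <- c(msg, "labels must be the argmax of q rows")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterState", function(object) {
  cat("ClusterState:", length(object@labels), "spots in",
      ncol(object@q), "clusters; final loss",
      format(utils::tail(object@lossHistory, 1), digits = 4), "after",
      length(object@lossHistory), "epochs\n")
})

#' Synthetic spatial-transcriptomics dataset with known structure
#'
#' @slot table the simulated [SpotTable-class].
#' @slot trueLabels integer vector of domain memberships (1..K).
#' @slot trueSVG logical vector per gene: TRUE for domain-restricted
#'   markers, FALSE for CSR noise genes.
#' @export
setClass("SpotSimulation",
         representation(table = "SpotTable", trueLabels = "integer",
                        trueSVG = "logical"))

setValidity("SpotSimulation", function(object) {
  msg <- character()
  if (length(object@trueLabels) != ncol(object@table))
    msg <- c(msg, "one true label per spot required")
  if (length(object@trueSVG) != nrow(object@table))
    msg <- c(msg, "one SVG flag per gene required")
  if (any(tabulate(object@trueLabels) == 0))
    msg <- c(msg, "every domain must contain at least one spot")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpotSimulation", function(object) {
  cat("SpotSimulation:", ncol(object@table), "spots,",
      nrow(object@table), "genes,", max(object@trueLabels), "domains,",
      sum(object@trueSVG), "true markers\n")
})
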