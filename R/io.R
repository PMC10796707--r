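#' Read spot-level spatial expression data
#'
#' Two on-disk layouts are supported. `format = "csv_pair"`: a count matrix
#' CSV (spots in rows, header row of gene ids, first column the spot id)
#' plus a coordinate TSV (`spot_id`, `x`, `y`, optionally `array_row`,
#' `array_col`). `format = "mtx_dir"`: a 10x-style filtered feature matrix
#' directory containing `matrix.mtx[.gz]` (genes x barcodes),
#' `barcodes.tsv[.gz]`, `features.tsv[.gz]` (or `genes.tsv`) and a position
#' table (`tissue_positions_list.csv`, `tissue_positions.csv` or
#' `positions.csv`; either `barcode,x,y` or the Visium
#' `barcode,in_tissue,array_row,array_col,pxl_row,pxl_col` dialect, in
#' which case `array_col`/`array_row` become the x/y coordinates and the
#' array indices are retained).
#'
#' Counts are aligned to coordinates by spot id. Genes expressed in zero
#' spots are retained; filtering is a separate step ([filterGenes()]).
#'
#' @param path counts CSV file (`csv_pair`) or matrix directory (`mtx_dir`).
#' @param format `"csv_pair"` or `"mtx_dir"`.
#' @param coordPath coordinate TSV for `csv_pair`; defaults to
#'   `<path without extension>_coords.tsv`.
#' @param platform platform tag stored on the result.
#' @return A [SpotTable-class].
#' @export
readSpotTable <- function(path, format = c("csv_pair", "mtx_dir"),
                          coordPath = NULL, platform = "generic") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input path does not exist: ", path)
  if (format == "csv_pair") {
    if (is.null(coordPath))
      coordPath <- paste0(sub("\\.[ct]sv(\\.gz)?$", "", path), "_coords.tsv")
    if (!file.exists(coordPath))
      stop("format error: coordinate file not found: ", coordPath)
    cnt <- data.table::fread(path, header = TRUE, data.table = FALSE)
    spotIds <- as.character(cnt[[1]])
    mat <- t(as.matrix(cnt[, -1, drop = FALSE]))   # genes x spots
    colnames(mat) <- spotIds
    pos <- data.table::fread(coordPath, header = TRUE, data.table = FALSE)
    names(pos)[1] <- "spot_id"
  } else {
    f <- function(base) {
      hits <- file.path(path, c(base, paste0(base, ".gz")))
      hits[file.exists(hits)][1]
    }
    mtx <- f("matrix.mtx"); bc <- f("barcodes.tsv")
    ft <- f("features.tsv"); if (is.na(ft)) ft <- f("genes.tsv")
    if (is.na(mtx) || is.na(bc) || is.na(ft))
      stop("format error: matrix.mtx / barcodes.tsv / features.tsv ",
           "not all present in ", path)
    mat <- as.matrix(Matrix::readMM(mtx))          # genes x barcodes
    barcodes <- data.table::fread(bc, header = FALSE, data.table = FALSE)[[1]]
    feats <- data.table::fread(ft, header = FALSE, data.table = FALSE)[[1]]
    if (length(barcodes) != ncol(mat) || length(feats) != nrow(mat))
      stop("alignment error: barcode/feature counts do not match the matrix")
    dimnames(mat) <- list(feats, barcodes)
    posFile <- vapply(c("tissue_positions_list.csv", "tissue_positions.csv",
                        "positions.csv"),
                      function(b) f(b), character(1))
    posFile <- posFile[!is.na(posFile)][1]
    if (is.na(posFile))
      stop("format error: no position table found in ", path)
    pos <- data.table::fread(posFile, header = TRUE, data.table = FALSE)
    if (!"x" %in% names(pos)) {
      # Visium dialect: barcode,in_tissue,array_row,array_col,pxl_row,pxl_col
      names(pos)[1:4] <- c("spot_id", "in_tissue", "array_row", "array_col")
      pos <- pos[pos$in_tissue == 1, , drop = FALSE]
      pos$x <- pos$array_col
      pos$y <- pos$array_row
    } else names(pos)[1] <- "spot_id"
  }
  pos$spot_id <- as.character(pos$spot_id)
  idx <- match(colnames(mat), pos$spot_id)
  if (anyNA(idx))
    stop("alignment error: ", sum(is.na(idx)),
         " spots have no coordinates (first: ",
         colnames(mat)[which(is.na(idx))[1]], ")")
  pos <- pos[idx, , drop = FALSE]
  ai <- if (all(c("array_row", "array_col") %in% names(pos)))
    pos[, c("array_row", "array_col")] else NULL
  SpotTable(mat, cbind(pos$x, pos$y), platform = platform,
            array_indices = ai)
}

#' Write a SpotTable as a CSV pair
#'
#' Inverse of `readSpotTable(format = "csv_pair")`: writes the count matrix
#' (spots x genes, first column `spot_id`) and the coordinate TSV.
#'
#' @param table a [SpotTable-class].
#' @param path output counts CSV path.
#' @param coordPath output coordinate TSV; default derived from `path`.
#' @return Invisibly, the two paths written.
#' @export
writeSpotTable <- function(table, path, coordPath = NULL) {
  if (is.null(coordPath))
    coordPath <- paste0(sub("\\.[ct]sv(\\.gz)?$", "", path), "_coords.tsv")
  cnt <- t(assay(table, "counts"))
  out <- data.frame(spot_id = colnames(table), cnt, check.names = FALSE)
  data.table::fwrite(out, path)
  cd <- colData(table)
  pos <- data.frame(spot_id = colnames(table), x = cd$x, y = cd$y)
  if (all(c("array_row", "array_col") %in% colnames(cd))) {
    pos$array_row <- cd$array_row
    pos$array_col <- cd$array_col
  }
  data.table::fwrite(pos, coordPath, sep = "\t")
  invisible(c(path, coordPath))
}

#' Drop genes detected in too few spots
#'
#' Keeps genes with nonzero expression in at least `minSpots` spots (the
#' neural-network pre-processing removes genes seen in fewer than ten
#' spots). Gene order is preserved.
#'
#' @param table a [SpotTable-class].
#' @param minSpots minimum number of spots with nonzero counts.
#' @return The filtered [SpotTable-class].
#' @export
filterGenes <- function(table, minSpots = 10L) {
  stopifnot(minSpots >= 0)
  nz <- rowSums(assay(table, "counts") > 0)
  keep <- nz >= minSpots
  if (!any(keep))
    stop("all ", nrow(table), " genes removed at minSpots = ", minSpots)
  table[keep, ]
}
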