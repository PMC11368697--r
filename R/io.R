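# Readers and writers for standard plain formats: MatrixMarket (MTX) with
# gene/barcode sidecars, delimited text, coordinates CSV, gene lists, and
# model checkpoints.

#' Read an expression matrix from MatrixMarket files
#'
#' Expects the CellRanger-style layout: `<prefix>matrix.mtx` with genes as
#' rows and samples as columns, plus `<prefix>genes.tsv` and
#' `<prefix>barcodes.tsv` sidecars (one id per line).
#'
#' @param prefix path prefix (e.g. `"dir/ref_"`).
#' @param axisRole `"cells"` or `"spots"`.
#' @return An [ExpressionMatrix-class] (samples x genes).
#' @export
readExpressionMtx <- function(prefix, axisRole = c("cells", "spots")) {
  axisRole <- match.arg(axisRole)
  m <- Matrix::readMM(paste0(prefix, "matrix.mtx"))
  genes <- readLines(paste0(prefix, "genes.tsv"))
  genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1L)
  cells <- readLines(paste0(prefix, "barcodes.tsv"))
  ExpressionMatrix(t(as.matrix(m)), sampleIds = cells, geneIds = genes,
                   axisRole = axisRole)
}

#' Write an expression matrix as MatrixMarket files
#'
#' @param x an [ExpressionMatrix-class].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writeExpressionMtx <- function(x, prefix) {
  stopifnot(is(x, "ExpressionMatrix"))
  m <- Matrix::Matrix(t(exprValues(x)), sparse = TRUE)
  Matrix::writeMM(m, paste0(prefix, "matrix.mtx"))
  writeLines(geneIds(x), paste0(prefix, "genes.tsv"))
  writeLines(sampleIds(x), paste0(prefix, "barcodes.tsv"))
  invisible(prefix)
}

#' Read an expression matrix from delimited text
#'
#' First column = sample ids, header row = gene ids.
#'
#' @param path file path (CSV or TSV; separator inferred from extension).
#' @param axisRole `"cells"` or `"spots"`.
#' @param sep field separator; default inferred.
#' @return An [ExpressionMatrix-class].
#' @export
readExpressionDelim <- function(path, axisRole = c("cells", "spots"),
                                sep = NULL) {
  axisRole <- match.arg(axisRole)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- read.delim(path, sep = sep, check.names = FALSE, row.names = 1L)
  ExpressionMatrix(as.matrix(df), sampleIds = rownames(df),
                   geneIds = colnames(df), axisRole = axisRole)
}

#' Write an expression matrix as delimited text
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output path (`.tsv` for tab-separated, else comma).
#' @return `path`, invisibly.
#' @export
writeExpressionDelim <- function(x, path) {
  stopifnot(is(x, "ExpressionMatrix"))
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(sample = sampleIds(x), exprValues(x),
                   check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read spot coordinates from CSV
#'
#' Expects columns `spot_id`, `x`, `y` (header required).
#'
#' @param path CSV path.
#' @return Numeric Ns x 2 matrix with spot-id rownames.
#' @export
readCoordsCsv <- function(path) {
  df <- read.delim(path, sep = ",", check.names = FALSE)
  .coerceCoords(df)
}

#' Write spot coordinates to CSV
#'
#' @param coords Ns x 2 matrix with spot-id rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCoordsCsv <- function(coords, path) {
  xy <- .coerceCoords(coords)
  df <- data.frame(spot_id = rownames(xy), x = xy[, 1], y = xy[, 2])
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load a fitted mapping model
#'
#' The checkpoint is a single RDS archive of a plain list: raw parameter
#' matrices, mode, K, vClip, axis ids, training config and loss trace.
#'
#' @param model a [MappingModel-class].
#' @param path checkpoint path.
#' @return `path` invisibly (`saveMappingModel`); the restored
#'   [MappingModel-class] (`loadMappingModel`).
#' @export
saveMappingModel <- function(model, path) {
  stopifnot(is(model, "MappingModel"))
  obj <- list(
    mode = model@mode, clusterMode = model@clusterMode, K = model@K,
    rawU = model@rawU, rawV = model@rawV, rawW = model@rawW,
    vClip = model@vClip, geneIds = model@geneIds, cellIds = model@cellIds,
    spotIds = model@spotIds, fitted = model@fitted,
    trace = model@trace, config = model@config)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname saveMappingModel
#' @export
loadMappingModel <- function(path) {
  if (!file.exists(path))
    stop("model checkpoint not found: ", path)
  obj <- readRDS(path)
  m <- newMappingModel(
    mode = obj$mode,
    rawW = if (length(obj$rawW)) obj$rawW else NULL,
    rawU = if (length(obj$rawU)) obj$rawU else NULL,
    rawV = if (length(obj$rawV)) obj$rawV else NULL,
    vClip = obj$vClip, geneIds = obj$geneIds, cellIds = obj$cellIds,
    spotIds = obj$spotIds, clusterMode = obj$clusterMode,
    fitted = obj$fitted)
  m@trace <- obj$trace
  m@config <- obj$config
  m
}

#' Write a gene list, one id per line
#'
#' @param genes character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGeneList <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
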