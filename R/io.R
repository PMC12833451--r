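#' Read a spatial dataset from a MatrixMarket directory
#'
#' Expects a directory with `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and
#' `coords.tsv`. The gene list may have one column (symbols) or two (id,
#' symbol: the second column is used, as in 10x-style triplets). The matrix
#' orientation (genes as rows or columns) is auto-detected by matching the
#' header dimensions against the gene-list length. `coords.tsv` is
#' tab-separated with a header and columns `barcode`, `x`, `y` and optionally
#' `domain` (integer ground-truth annotation); rows are matched to barcodes
#' by ID, so file order never silently permutes spots — the spot order is
#' taken from `barcodes.tsv`.
#'
#' @param path directory containing the four files.
#' @param format only `"mtx_dir"` is supported.
#' @return A [SpatialTissue-class] with truth labels attached when a
#'   `domain` column is present.
#' @seealso [writeSpatialDataset()] for the inverse.
#' @export
readSpatialDataset <- function(path, format = c("mtx_dir")) {
  format <- match.arg(format)
  if (!dir.exists(path)) {
    stopIO("dataset directory not found: ", path)
  }
  need <- c("matrix.mtx", "genes.tsv", "barcodes.tsv", "coords.tsv")
  for (f in need) {
    if (!file.exists(file.path(path, f))) {
      stopIO("missing required file: ", file.path(path, f))
    }
  }
  mat <- Matrix::readMM(file.path(path, "matrix.mtx"))
  genes <- read.delim(file.path(path, "genes.tsv"), header = FALSE,
                      stringsAsFactors = FALSE)
  symbols <- as.character(genes[[ncol(genes)]])
  barcodes <- read.delim(file.path(path, "barcodes.tsv"), header = FALSE,
                         stringsAsFactors = FALSE)[[1L]]
  m <- length(symbols)
  if (nrow(mat) == m) {
    # genes x spots, as stored
  } else if (ncol(mat) == m) {
    mat <- Matrix::t(mat)
  } else {
    stopValidation("gene list length (", m, ") matches neither matrix rows (",
                   nrow(mat), ") nor columns (", ncol(mat), ")")
  }
  if (ncol(mat) != length(barcodes)) {
    stopValidation("barcode list length (", length(barcodes),
                   ") does not match matrix spot count (", ncol(mat), ")")
  }
  mat <- methods::as(mat, "CsparseMatrix")
  dimnames(mat) <- list(symbols, barcodes)
  co <- read.delim(file.path(path, "coords.tsv"), stringsAsFactors = FALSE)
  if (!all(c("barcode", "x", "y") %in% colnames(co))) {
    stopValidation("coords.tsv must have columns 'barcode', 'x', 'y'")
  }
  idx <- match(barcodes, co$barcode)
  if (anyNA(idx)) {
    stopValidation(sum(is.na(idx)), " barcode(s) missing from coords.tsv, e.g. ",
                   barcodes[which(is.na(idx))[1L]])
  }
  co <- co[idx, , drop = FALSE]
  domains <- if ("domain" %in% colnames(co)) as.integer(co$domain) else NULL
  SpatialTissue(mat, coords = cbind(co$x, co$y), domains = domains)
}

#' Write a spatial dataset as a MatrixMarket directory
#'
#' Inverse of [readSpatialDataset()]: writes `matrix.mtx` (genes x spots),
#' `genes.tsv`, `barcodes.tsv` and `coords.tsv` (with a `domain` column when
#' truth labels are present). Integer counts round-trip bit-exactly.
#'
#' @param tissue a [SpatialTissue-class].
#' @param path output directory (created if needed).
#' @return `path`, invisibly.
#' @export
writeSpatialDataset <- function(tissue, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  mat <- SummarizedExperiment::assay(tissue, 1L)
  Matrix::writeMM(methods::as(methods::as(mat, "CsparseMatrix"), "generalMatrix"),
                  file.path(path, "matrix.mtx"))
  writeLines(rownames(tissue), file.path(path, "genes.tsv"))
  writeLines(colnames(tissue), file.path(path, "barcodes.tsv"))
  xy <- spatialCoords(tissue)
  co <- data.frame(barcode = colnames(tissue), x = xy[, 1L], y = xy[, 2L])
  tr <- domainTruth(tissue)
  if (!is.null(tr)) co$domain <- tr
  utils::write.table(co, file.path(path, "coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-embedding lookup table
#'
#' Reads a delimited file with one gene-symbol column and a fixed number of
#' numeric embedding columns (e.g. precomputed text-description embeddings).
#'
#' @param path CSV/TSV file (delimiter auto-detected by [data.table::fread]).
#' @param key_column column name or index holding the gene symbols
#'   (default: first column).
#' @param dim_check optional expected vector width; a mismatch is an error.
#' @return A [GeneEmbeddingTable-class].
#' @export
readGeneEmbeddingTable <- function(path, key_column = 1L, dim_check = NULL) {
  if (!file.exists(path)) {
    stopIO("embedding table not found: ", path)
  }
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (is.character(key_column)) {
    if (!key_column %in% colnames(dt)) {
      stopValidation("key column '", key_column, "' not present")
    }
    key_idx <- match(key_column, colnames(dt))
  } else {
    key_idx <- as.integer(key_column)
  }
  symbols <- as.character(dt[[key_idx]])
  vals <- dt[, -key_idx, drop = FALSE]
  if (ncol(vals) < 1L) {
    stopValidation("embedding table needs at least one numeric column")
  }
  for (j in seq_len(ncol(vals))) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        stopValidation("non-numeric value in column '", colnames(vals)[j],
                       "' at row ", bad[1L], ": '", col[bad[1L]], "'")
      }
      vals[[j]] <- num
    }
  }
  folded <- foldSymbols(symbols)
  if (anyDuplicated(folded)) {
    dup <- unique(symbols[duplicated(folded) | duplicated(folded, fromLast = TRUE)])
    stopValidation("duplicate gene symbols after case-folding: ",
                   paste(head(dup, 10L), collapse = ", "))
  }
  emb <- as.matrix(vals)
  rownames(emb) <- trimws(symbols)
  if (!is.null(dim_check) && ncol(emb) != dim_check) {
    stopValidation("embedding width ", ncol(emb),
                   " does not match expected dim_check = ", dim_check)
  }
  if (any(!is.finite(emb))) {
    stopValidation("embedding table contains non-finite values")
  }
  GeneEmbeddingTable(emb)
}

#' Write an embedding table to CSV
#'
#' @param table a [GeneEmbeddingTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeGeneEmbeddingTable <- function(table, path) {
  emb <- embeddingMatrix(table)
  df <- data.frame(gene = rownames(emb), emb, row.names = NULL,
                   check.names = FALSE)
  colnames(df) <- c("gene", sprintf("d%03d", seq_len(ncol(emb))))
  data.table::fwrite(df, path)
  invisible(path)
}

#' Write predicted (or true) domain labels
#'
#' Two-column CSV `spot_id,domain`; rereading with [readDomainLabels()]
#' reproduces the labels exactly. Empty label vectors produce a header-only
#' file.
#'
#' @param labels integer domain labels.
#' @param spot_ids spot identifiers, same length as `labels`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeDomainLabels <- function(labels, spot_ids, path) {
  if (length(labels) != length(spot_ids)) {
    stopValidation("labels length (", length(labels),
                   ") does not match spot_ids length (", length(spot_ids), ")")
  }
  df <- data.frame(spot_id = as.character(spot_ids),
                   domain = as.integer(labels))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDomainLabels
#' @return `readDomainLabels` returns a named integer vector of labels.
#' @export
readDomainLabels <- function(path) {
  if (!file.exists(path)) stopIO("label file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(as.integer(df$domain), as.character(df$spot_id))
}
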