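#' Expression matrix container
#'
#' Lightweight container for a cells x genes expression matrix together with
#' cell/gene identifiers, an optional per-cell batch label and a layer tag
#' recording what the values are (raw counts, log-normalized values, or the
#' output of a further transform).
#'
#' @param values numeric matrix or \code{Matrix} sparse matrix, cells in rows,
#'   genes in columns. All entries must be nonnegative; for
#'   \code{layer = "counts"} they must be integer-valued.
#' @param cell_ids character vector of unique cell identifiers (defaults to
#'   rownames of \code{values}).
#' @param gene_ids character vector of unique gene identifiers (defaults to
#'   colnames of \code{values}).
#' @param batch optional per-cell batch label (length = number of cells).
#' @param layer one of \code{"counts"}, \code{"lognorm"}, \code{"transformed"}.
#'
#' @return An object of class \code{"masi_expr"}: a list with elements
#'   \code{values}, \code{cell_ids}, \code{gene_ids}, \code{batch},
#'   \code{layer}.
#' @export
masi_expr <- function(values, cell_ids = rownames(values),
                      gene_ids = colnames(values), batch = NULL,
                      layer = c("counts", "lognorm", "transformed")) {
  layer <- match.arg(layer)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(cell_ids))
    stop("number of rows (", nrow(values), ") != number of cell_ids (",
         length(cell_ids), ")")
  if (ncol(values) != length(gene_ids))
    stop("number of columns (", ncol(values), ") != number of gene_ids (",
         length(gene_ids), ")")
  if (anyDuplicated(cell_ids))
    stop("duplicate cell identifiers: ",
         paste(utils::head(unique(cell_ids[duplicated(cell_ids)]), 3),
               collapse = ", "))
  if (anyDuplicated(gene_ids))
    stop("duplicate gene identifiers: ",
         paste(utils::head(unique(gene_ids[duplicated(gene_ids)]), 3),
               collapse = ", "))
  mn <- if (inherits(values, "sparseMatrix")) min(values@x, 0) else min(values, 0)
  if (mn < 0) stop("expression values must be nonnegative")
  if (layer == "counts") {
    x <- if (inherits(values, "sparseMatrix")) values@x else as.numeric(values)
    if (length(x) && any(abs(x - round(x)) > 1e-8))
      stop("layer 'counts' requires integer-valued entries")
  }
  if (!is.null(batch)) {
    if (length(batch) != length(cell_ids))
      stop("batch must have one label per cell")
    batch <- as.character(batch)
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 batch = batch, layer = layer),
            class = "masi_expr")
}

#' @exportS3Method print masi_expr
print.masi_expr <- function(x, ...) {
  cat(sprintf("masi_expr: %d cells x %d genes [layer: %s]\n",
              length(x$cell_ids), length(x$gene_ids), x$layer))
  if (!is.null(x$batch))
    cat("batches:", paste(names(table(x$batch)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.masi_expr <- function(x) dim(x$values)

# Subset cells (i) and/or genes (j) keeping metadata in sync.
#' @export
`[.masi_expr` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$cell_ids)
  if (missing(j)) j <- seq_along(x$gene_ids)
  masi_expr(x$values[i, j, drop = FALSE],
            cell_ids = x$cell_ids[seq_along(x$cell_ids)][i],
            gene_ids = x$gene_ids[seq_along(x$gene_ids)][j],
            batch = if (!is.null(x$batch)) x$batch[i],
            layer = x$layer)
}

#' Read a Matrix Market expression directory
#'
#' Reads a 10x-style directory holding a Matrix Market triplet file plus gene
#' and barcode TSVs. Orientation on disk (genes x cells vs cells x genes) is
#' inferred from the lengths of the two TSVs and the result is always returned
#' cells x genes. A square matrix, where the lengths cannot disambiguate, is
#' taken to follow the 10x on-disk convention (genes x cells).
#'
#' @param dir_path directory containing one \code{.mtx} file, a gene/feature
#'   TSV (\code{features.tsv} or \code{genes.tsv}) and \code{barcodes.tsv}.
#' @param batch optional per-cell batch vector attached to the result.
#' @return A \code{"masi_expr"} with \code{layer = "counts"}.
#' @export
read_mtx <- function(dir_path, batch = NULL) {
  if (!dir.exists(dir_path)) stop("no such directory: ", dir_path)
  mtx <- list.files(dir_path, pattern = "\\.mtx$", full.names = TRUE)
  if (length(mtx) != 1)
    stop("expected exactly one .mtx file in ", dir_path, ", found ",
         length(mtx))
  feat <- file.path(dir_path, c("features.tsv", "genes.tsv"))
  feat <- feat[file.exists(feat)][1]
  bc <- file.path(dir_path, "barcodes.tsv")
  if (is.na(feat) || !file.exists(bc))
    stop("directory must contain features.tsv (or genes.tsv) and barcodes.tsv")
  m <- Matrix::readMM(mtx[1])
  genes <- utils::read.delim(feat, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  cells <- utils::read.delim(bc, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  # 10x convention is genes x cells on disk; prefer it when the matrix is
  # square and the TSV lengths cannot disambiguate
  if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)
  } else if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
    # already cells x genes
  } else {
    stop("matrix dimensions ", nrow(m), " x ", ncol(m),
         " match neither orientation of ", length(cells), " barcodes x ",
         length(genes), " features")
  }
  masi_expr(methods::as(m, "CsparseMatrix"), cell_ids = cells,
            gene_ids = genes, batch = batch, layer = "counts")
}

#' Write an expression matrix as a Matrix Market directory
#'
#' Inverse of [read_mtx()]: writes \code{matrix.mtx}, \code{features.tsv} and
#' \code{barcodes.tsv} (genes x cells on disk, the 10x convention).
#'
#' @param expr a \code{"masi_expr"}.
#' @param dir_path output directory (created if needed).
#' @return \code{dir_path}, invisibly.
#' @export
write_mtx <- function(expr, dir_path) {
  stopifnot(inherits(expr, "masi_expr"))
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::t(Matrix::Matrix(expr$values, sparse = TRUE)),
                   "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir_path, "matrix.mtx"))
  writeLines(expr$gene_ids, file.path(dir_path, "features.tsv"))
  writeLines(expr$cell_ids, file.path(dir_path, "barcodes.tsv"))
  invisible(dir_path)
}

#' Read a dense expression table
#'
#' Reads a dense TSV/CSV with cell identifiers in the first column and gene
#' identifiers in the header.
#'
#' @param path file path; delimiter inferred from the extension
#'   (\code{.csv} vs anything else = tab).
#' @param layer layer tag for the result.
#' @param batch optional per-cell batch vector.
#' @return A \code{"masi_expr"}.
#' @export
read_dense <- function(path, layer = "counts", batch = NULL) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  masi_expr(as.matrix(df), batch = batch, layer = layer)
}

# ---- marker tables -------------------------------------------------------

#' Construct a marker table
#'
#' A marker table holds, per cell type, an ordered marker-gene list with
#' rank-derived weights (see [assign_weights()]). It is the unit the
#' marker-collection CSV format stores.
#'
#' @param markers named list; each element a character vector of gene ids
#'   ordered by marker rank (rank 1 first) for one cell type.
#' @param weights optional named list of numeric weights parallel to
#'   \code{markers}; computed by [assign_weights()] when omitted.
#' @return An object of class \code{"masi_markers"}.
#' @export
masi_markers <- function(markers, weights = NULL) {
  if (length(markers) == 0) stop("empty marker table")
  if (is.null(names(markers)) || any(names(markers) == ""))
    stop("marker list must be named by cell type")
  if (anyDuplicated(names(markers)))
    stop("duplicate cell-type names: ",
         paste(unique(names(markers)[duplicated(names(markers))]),
               collapse = ", "))
  for (ct in names(markers)) {
    g <- as.character(markers[[ct]])
    if (length(g) == 0) stop("cell type '", ct, "' has no markers")
    if (anyDuplicated(g))
      stop("duplicate marker gene within cell type '", ct, "': ",
           paste(unique(g[duplicated(g)]), collapse = ", "))
    markers[[ct]] <- g
  }
  obj <- structure(list(markers = markers, weights = weights),
                   class = "masi_markers")
  if (is.null(weights)) obj <- assign_weights(obj)
  obj
}

#' @exportS3Method print masi_markers
print.masi_markers <- function(x, ...) {
  ns <- vapply(x$markers, length, integer(1))
  cat(sprintf("masi_markers: %d cell types (%d-%d markers per type)\n",
              length(ns), min(ns), max(ns)))
  invisible(x)
}

#' Read a marker-table CSV
#'
#' The canonical on-disk format is a wide CSV: one column per cell type
#' (header = cell-type name), rows are marker genes ordered by rank, ragged
#' columns padded with empty cells. A long format with columns
#' \code{cell_type,gene} (optionally \code{rank}) is auto-detected from the
#' header and also accepted. New cell types can be added to a collection by
#' concatenating columns from further tables (see \code{\link{c.masi_markers}}).
#'
#' @param path CSV file path.
#' @return A \code{"masi_markers"} with weights assigned.
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0 && ncol(df) == 0) stop("empty marker table file: ", path)
  hdr <- names(df)
  if (all(c("cell_type", "gene") %in% hdr)) {          # long format
    if ("rank" %in% hdr) df <- df[order(as.integer(df$rank)), , drop = FALSE]
    markers <- split(df$gene, factor(df$cell_type, unique(df$cell_type)))
    return(masi_markers(as.list(markers)))
  }
  if (anyDuplicated(hdr))
    stop("duplicate cell-type column names: ",
         paste(unique(hdr[duplicated(hdr)]), collapse = ", "))
  markers <- lapply(df, function(col) col[!is.na(col) & col != ""])
  masi_markers(markers)
}

#' Write a marker table as a wide CSV
#'
#' @param markers a \code{"masi_markers"}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  stopifnot(inherits(markers, "masi_markers"))
  ns <- vapply(markers$markers, length, integer(1))
  n <- max(ns)
  cols <- lapply(markers$markers, function(g) c(g, rep("", n - length(g))))
  utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Combine marker tables
#'
#' Concatenates the cell-type columns of several marker tables into one
#' collection, so new cell types from additional references can be appended to
#' an existing table. Duplicate cell-type names are an error.
#'
#' @param ... \code{"masi_markers"} objects.
#' @return A combined \code{"masi_markers"}.
#' @export
c.masi_markers <- function(...) {
  tabs <- list(...)
  markers <- do.call(c, lapply(tabs, function(t) t$markers))
  masi_markers(markers)
}

# ---- labels / annotation / scores I/O ------------------------------------

#' Read per-cell labels
#'
#' Reads a two-column TSV (\code{cell_id}, \code{label}). When \code{cell_ids}
#' is supplied the labels are checked against it and returned in that order.
#'
#' @param path TSV path (header required).
#' @param cell_ids optional cell identifiers to align against.
#' @return Named character vector of labels.
#' @export
read_labels <- function(path, cell_ids = NULL) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("labels file needs columns cell_id, label")
  labs <- stats::setNames(df[[2]], df[[1]])
  if (!is.null(cell_ids)) {
    unknown <- setdiff(names(labs), cell_ids)
    if (length(unknown))
      stop("labels file contains cell ids absent from the matrix: ",
           paste(utils::head(unknown, 3), collapse = ", "))
    missing <- setdiff(cell_ids, names(labs))
    if (length(missing))
      stop("labels missing for cells: ",
           paste(utils::head(missing, 3), collapse = ", "))
    labs <- labs[cell_ids]
  }
  labs
}

#' Write per-cell labels
#' @param labels named character vector (names = cell ids).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(cell_id = names(labels), label = unname(labels)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read an annotation result
#'
#' The annotation TSV has columns \code{cell_id}, \code{label},
#' \code{certainty}, \code{tie_flag}; writing then reading returns an equal
#' object up to float print precision.
#'
#' @param result a \code{"masi_annotation"} (see [annotate()]).
#' @param path TSV path.
#' @return \code{path} (write) / a \code{"masi_annotation"} (read).
#' @export
write_annotation <- function(result, path) {
  stopifnot(inherits(result, "masi_annotation"))
  df <- data.frame(cell_id = result$cell_id, label = result$label,
                   certainty = result$certainty, tie_flag = result$tie_flag)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  masi_annotation(cell_id = as.character(df$cell_id),
                  label = as.character(df$label),
                  certainty = as.numeric(df$certainty),
                  tie_flag = as.logical(df$tie_flag))
}

#' Annotation result container
#'
#' @param cell_id character cell identifiers.
#' @param label per-cell consensus label (cell-type name or "unassigned").
#' @param certainty per-cell certainty score in [0,1] (NA when no reference
#'   centroids were available).
#' @param tie_flag logical, TRUE where the argmax label was tied.
#' @param mapped_labels optional matrix (cells x clustering runs) of per-run
#'   mapped labels.
#' @return A \code{"masi_annotation"} data frame.
#' @export
masi_annotation <- function(cell_id, label, certainty = rep(NA_real_, length(cell_id)),
                            tie_flag = rep(FALSE, length(cell_id)),
                            mapped_labels = NULL) {
  stopifnot(length(label) == length(cell_id),
            length(certainty) == length(cell_id),
            length(tie_flag) == length(cell_id))
  ok <- is.na(certainty) | (certainty >= 0 & certainty <= 1)
  if (!all(ok)) stop("certainty scores must lie in [0, 1]")
  df <- data.frame(cell_id = as.character(cell_id), label = as.character(label),
                   certainty = as.numeric(certainty),
                   tie_flag = as.logical(tie_flag),
                   stringsAsFactors = FALSE)
  attr(df, "mapped_labels") <- mapped_labels
  class(df) <- c("masi_annotation", "data.frame")
  df
}

#' Write / read a cell-type score matrix
#'
#' TSV with a \code{cell_id} column followed by one column per cell type
#' (1 + number of cell types columns in total).
#'
#' @param scores numeric matrix, cells x cell types, with dimnames.
#' @param path TSV path.
#' @return \code{path} (write) / score matrix (read).
#' @export
write_scores <- function(scores, path) {
  df <- data.frame(cell_id = rownames(scores), as.data.frame(scores),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
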