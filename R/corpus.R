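#' Construct an expression matrix container
#'
#' The basic data container of the package: a dense cells-by-genes matrix of
#' nonnegative expression values (raw counts or normalized values) together
#' with unique cell and gene identifiers, a per-cell batch label and an
#' optional per-cell cell-type label.
#'
#' @param counts numeric matrix, cells in rows, genes in columns; no negative
#'   entries.
#' @param cell_ids character vector of unique cell identifiers (barcodes).
#' @param gene_ids character vector of unique gene identifiers.
#' @param batch per-cell batch label; recycled to length one if scalar.
#' @param cell_type optional per-cell cell-type label.
#' @return an object of class `sclm_expr`.
#' @export
expression_matrix <- function(counts, cell_ids = rownames(counts),
                              gene_ids = colnames(counts),
                              batch = "batch1", cell_type = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    stop2("id lengths do not match matrix dimensions")
  if (anyDuplicated(cell_ids)) stop2("duplicate cell_ids")
  if (anyDuplicated(gene_ids)) stop2("duplicate gene_ids")
  if (anyNA(counts) || min(counts) < 0) stop2("negative or missing entries in counts")
  if (length(batch) == 1L) batch <- rep(batch, nrow(counts))
  if (length(batch) != nrow(counts)) stop2("batch length must equal number of cells")
  if (!is.null(cell_type) && length(cell_type) != nrow(counts))
    stop2("cell_type length must equal number of cells")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids,
                 batch = as.character(batch),
                 cell_type = if (is.null(cell_type)) NULL else as.character(cell_type)),
            class = "sclm_expr")
}

#' @export
print.sclm_expr <- function(x, ...) {
  cat(sprintf("<sclm_expr> %d cells x %d genes; %d batch(es)%s\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$batch)),
              if (is.null(x$cell_type)) "" else
                sprintf("; %d cell type(s)", length(unique(x$cell_type)))))
  invisible(x)
}

#' @export
dim.sclm_expr <- function(x) dim(x$counts)

#' Subset an expression matrix by cells and/or genes
#' @param x an `sclm_expr`.
#' @param i cell index (logical, integer or cell id).
#' @param j gene index.
#' @param ... ignored.
#' @export
`[.sclm_expr` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  cnt <- x$counts[i, j, drop = FALSE]
  expression_matrix(cnt, rownames(cnt), colnames(cnt),
                    batch = x$batch[match(rownames(cnt), x$cell_ids)],
                    cell_type = if (is.null(x$cell_type)) NULL
                    else x$cell_type[match(rownames(cnt), x$cell_ids)])
}

#' Read an expression matrix from disk
#'
#' Supports the standard Matrix Market triplet directory layout
#' (`matrix.mtx` + `features.tsv` + `barcodes.tsv`, optionally gzipped) and
#' dense CSV/TSV with cell and gene identifiers in the row/column headers.
#' On-disk orientation is declared with `cells_as`; the returned object is
#' always cells-as-rows. MTX directories default to the 10x convention
#' (genes in rows, cells in columns); dense tables default to cells-as-rows.
#'
#' @param path file (csv/tsv) or directory (mtx_dir).
#' @param format one of `"mtx_dir"`, `"csv"`, `"tsv"`.
#' @param cells_as `"rows"` or `"cols"`: orientation of the on-disk matrix.
#' @param annotations optional path to an annotation TSV with header columns
#'   `barcode`, `cell_type`, `batch`; matched to the matrix by barcode.
#' @return an [expression_matrix()] object.
#' @export
read_expression <- function(path, format = c("mtx_dir", "csv", "tsv"),
                            cells_as = NULL, annotations = NULL) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    cells_as <- cells_as %||% "cols"
    if (!dir.exists(path)) stop2("path is not a directory: ", path)
    find1 <- function(base) {
      for (f in file.path(path, c(base, paste0(base, ".gz"))))
        if (file.exists(f)) return(f)
      stop2("missing file ", base, " in ", path)
    }
    m <- as.matrix(Matrix::readMM(find1("matrix.mtx")))
    feats <- utils::read.table(find1("features.tsv"), sep = "\t",
                               header = FALSE, stringsAsFactors = FALSE)[[1L]]
    bars <- utils::read.table(find1("barcodes.tsv"), sep = "\t",
                              header = FALSE, stringsAsFactors = FALSE)[[1L]]
    if (cells_as == "cols") {
      if (nrow(m) != length(feats) || ncol(m) != length(bars))
        stop2("dimension mismatch between matrix and id files")
      m <- t(m)
    } else if (nrow(m) != length(bars) || ncol(m) != length(feats)) {
      stop2("dimension mismatch between matrix and id files")
    }
    out <- expression_matrix(m, bars, feats)
  } else {
    cells_as <- cells_as %||% "rows"
    sep <- if (format == "csv") "," else "\t"
    tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                             check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(tab)
    if (cells_as == "cols") m <- t(m)
    if (anyDuplicated(colnames(m))) stop2("duplicate gene_ids")
    if (anyDuplicated(rownames(m))) stop2("duplicate cell_ids")
    out <- expression_matrix(m, rownames(m), colnames(m))
  }
  if (!is.null(annotations)) {
    ann <- read_annotations(annotations)
    idx <- match(out$cell_ids, ann$barcode)
    if (anyNA(idx)) stop2("annotation file is missing some barcodes")
    out$batch <- as.character(ann$batch[idx])
    out$cell_type <- as.character(ann$cell_type[idx])
  }
  out
}

#' Read a cell annotation table
#'
#' @param path TSV with required header columns `barcode`, `cell_type`,
#'   `batch`.
#' @return data.frame with those columns.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("barcode", "cell_type", "batch")
  if (!all(need %in% names(ann)))
    stop2("annotation TSV must have header columns: ", paste(need, collapse = ", "))
  ann
}

#' Write an expression matrix as an MTX directory
#'
#' Writes the 10x-style triplet layout (`matrix.mtx` genes-by-cells,
#' `features.tsv`, `barcodes.tsv`) plus `annotations.tsv` (barcode,
#' cell_type, batch). [read_expression()] round-trips the result bit-exactly
#' for integer counts.
#'
#' @param m an `sclm_expr`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_expression <- function(m, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(t(m$counts)), "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(m$gene_ids, file.path(dir, "features.tsv"))
  writeLines(m$cell_ids, file.path(dir, "barcodes.tsv"))
  ann <- data.frame(barcode = m$cell_ids,
                    cell_type = m$cell_type %||% NA_character_,
                    batch = m$batch)
  utils::write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Total-count normalize and log-transform
#'
#' Scales every cell to `target_sum` total counts, then applies `log(1 + x)`.
#' Zeros stay exactly zero and within-cell expression ranking is preserved.
#'
#' @param m an `sclm_expr` of nonnegative counts.
#' @param target_sum per-cell total after scaling (default 1e4).
#' @return an `sclm_expr` of normalized values.
#' @export
normalize_log <- function(m, target_sum = 1e4) {
  stopifnot(inherits(m, "sclm_expr"), target_sum > 0)
  tot <- rowSums(m$counts)
  if (any(tot == 0)) stop2("all-zero cell(s): ",
                           paste(utils::head(m$cell_ids[tot == 0], 3), collapse = ", "))
  out <- m
  out$counts <- log1p(m$counts * (target_sum / tot))
  out
}

#' Select highly variable genes by dispersion
#'
#' Ranks genes by dispersion (variance / mean) of their log-normalized
#' values and keeps the top `n_top`. Genes with zero mean get dispersion 0.
#' Ties at the cutoff are broken by lexicographic gene id, smaller id kept.
#'
#' @param m an `sclm_expr` (raw counts; normalized internally for ranking,
#'   the returned values are taken from `m` unchanged).
#' @param n_top number of genes to keep.
#' @return an `sclm_expr` restricted to the selected genes, in rank order.
#' @export
select_hvgs <- function(m, n_top) {
  stopifnot(inherits(m, "sclm_expr"))
  if (n_top <= 0) stop2("n_top must be positive")
  if (n_top > ncol(m$counts)) stop2("n_top exceeds number of genes")
  ln <- normalize_log(m)$counts
  mu <- colMeans(ln)
  v <- apply(ln, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  ord <- order(-disp, m$gene_ids)
  m[, ord[seq_len(n_top)]]
}

#' Bin expression values per cell by quantile rank
#'
#' Zeros map to the reserved bin 0. Nonzero values are ranked within each
#' cell (average ranks for ties) and binned as
#' `ceiling(rank / n_nonzero * (n_bins - 1))`, giving bins in
#' `1 .. n_bins - 1`. The result depends only on within-cell ranks, so it is
#' invariant under any strictly monotone per-cell transform and independent
#' of sequencing depth.
#'
#' @param m an `sclm_expr` of nonnegative (typically log-normalized) values.
#' @param n_bins total number of bins including the reserved zero bin
#'   (default 51).
#' @return an object of class `sclm_binned`: list with integer matrix `bins`
#'   and `n_bins`.
#' @export
bin_expression <- function(m, n_bins = 51L) {
  stopifnot(inherits(m, "sclm_expr"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop2("n_bins must be at least 2")
  x <- m$counts
  bins <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (i in seq_len(nrow(x))) {
    nz <- which(x[i, ] > 0)
    if (!length(nz)) next
    r <- rank(x[i, nz], ties.method = "average") / length(nz)
    bins[i, nz] <- as.integer(ceiling(r * (n_bins - 1L)))
  }
  structure(list(bins = bins, n_bins = n_bins, cell_ids = m$cell_ids,
                 gene_ids = m$gene_ids), class = "sclm_binned")
}

#' Build a gene-token vocabulary
#'
#' Token ids are contiguous from 0: the three reserved ids PAD = 0, CLS = 1,
#' MASK = 2, followed by the gene ids in lexicographic order. The mapping is
#' deterministic and invertible.
#'
#' @param gene_ids character vector of unique gene identifiers.
#' @return an object of class `sclm_vocab`: list with named integer vector
#'   `gene_to_token` and `special_tokens` (`PAD`, `CLS`, `MASK`).
#' @export
build_vocabulary <- function(gene_ids) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop2("duplicate gene ids in vocabulary")
  genes <- sort(gene_ids)
  tok <- seq_along(genes) + 2L
  names(tok) <- genes
  structure(list(gene_to_token = tok,
                 special_tokens = c(PAD = 0L, CLS = 1L, MASK = 2L)),
            class = "sclm_vocab")
}

#' @export
print.sclm_vocab <- function(x, ...) {
  cat(sprintf("<sclm_vocab> %d genes + %d special tokens\n",
              length(x$gene_to_token), length(x$special_tokens)))
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$gene_to_token) + length(vocab$special_tokens)

vocab_genes <- function(vocab) names(vocab$gene_to_token)

vocab_hash <- function(vocab) {
  # order-stable fingerprint used to refuse checkpoint/vocabulary mismatches
  s <- paste(names(vocab$gene_to_token), vocab$gene_to_token,
             collapse = ";", sep = "=")
  sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1))
}

#' Save / load a gene vocabulary
#'
#' JSON (single object, stable key order) or TSV (`gene`, `token` columns;
#' special tokens as `#PAD`/`#CLS`/`#MASK` rows).
#'
#' @param vocab an `sclm_vocab`.
#' @param path output file.
#' @param format `"json"` or `"tsv"` (guessed from the extension by default).
#' @return `path`, invisibly.
#' @export
save_vocabulary <- function(vocab, path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "tsv")
  if (format == "json") {
    jsonlite::write_json(list(special_tokens = as.list(vocab$special_tokens),
                              gene_to_token = as.list(vocab$gene_to_token)),
                         path, auto_unbox = TRUE)
  } else {
    df <- data.frame(
      gene = c(paste0("#", names(vocab$special_tokens)), names(vocab$gene_to_token)),
      token = c(unname(vocab$special_tokens), unname(vocab$gene_to_token)))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_vocabulary
#' @export
load_vocabulary <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "tsv")
  if (format == "json") {
    obj <- jsonlite::read_json(path)
    tok <- vapply(obj$gene_to_token, as.integer, integer(1))
    sp <- vapply(obj$special_tokens, as.integer, integer(1))
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, comment.char = "")
    is_sp <- startsWith(df$gene, "#")
    sp <- stats::setNames(as.integer(df$token[is_sp]), sub("^#", "", df$gene[is_sp]))
    tok <- stats::setNames(as.integer(df$token[!is_sp]), df$gene[!is_sp])
  }
  structure(list(gene_to_token = tok, special_tokens = sp[c("PAD", "CLS", "MASK")]),
            class = "sclm_vocab")
}
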