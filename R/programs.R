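#' Extract the learned gene-token embedding table
#'
#' Context-free gene embeddings: the rows of the gene-id embedding table for
#' the vocabulary's genes (special tokens excluded), aligned to vocabulary
#' order.
#'
#' @param state a trained `sclm_model` with an attached vocabulary.
#' @return genes x d_model numeric matrix with gene ids as row names.
#' @export
extract_gene_embeddings <- function(state) {
  stopifnot(inherits(state, "sclm_model"))
  if (is.null(state$vocab)) stop2("model carries no vocabulary")
  tok <- state$vocab$gene_to_token
  emb <- state$params$E_id[tok + 1L, , drop = FALSE]
  rownames(emb) <- names(tok)
  emb
}

#' Discover gene programs from gene embeddings
#'
#' Communities of genes with similar learned embeddings, found by Louvain
#' on a symmetrized kNN graph of the embedding rows. The number of programs
#' is emergent, not prescribed.
#'
#' @param table gene embedding matrix (genes x d, row names = gene ids),
#'   e.g. from [extract_gene_embeddings()].
#' @param n_neighbors kNN size (default 15).
#' @param resolution Louvain resolution (default 1).
#' @param seed integer seed.
#' @return an object of class `sclm_programs`: data.frame `assignment`
#'   (gene, program; 0-based contiguous program ids) and `n_programs`.
#' @export
cluster_programs <- function(table, n_neighbors = 15L, resolution = 1,
                             seed = 1L) {
  table <- as.matrix(table)
  if (nrow(table) < n_neighbors + 1L) stop2("too few genes for the kNN graph")
  cl <- louvain_sweep(table, resolutions = resolution,
                      n_neighbors = n_neighbors, seed = seed)[[1L]]
  assignment <- data.frame(gene = rownames(table), program = cl$cluster,
                           stringsAsFactors = FALSE)
  structure(list(assignment = assignment,
                 n_programs = length(unique(cl$cluster)),
                 resolution = resolution), class = "sclm_programs")
}

#' @export
print.sclm_programs <- function(x, ...) {
  cat(sprintf("<sclm_programs> %d genes in %d programs (resolution %g)\n",
              nrow(x$assignment), x$n_programs, x$resolution))
  invisible(x)
}

#' Program activity across cell types
#'
#' For every gene, the mean log-normalized expression per cell type is
#' z-scored across types (genes constant across types contribute 0); a
#' program's activity in a type is the mean over its genes. Rows therefore
#' average to ~0 across types, and the most activated type stands out.
#'
#' @param assign an [cluster_programs()] result.
#' @param expr an `sclm_expr` of raw counts with `cell_type` labels; genes
#'   are matched by id, and at least one gene must be shared.
#' @return programs x types numeric matrix of class `sclm_activity`.
#' @export
program_activity <- function(assign, expr) {
  stopifnot(inherits(assign, "sclm_programs"), inherits(expr, "sclm_expr"))
  if (is.null(expr$cell_type)) stop2("expression matrix lacks cell_type labels")
  shared <- intersect(assign$assignment$gene, expr$gene_ids)
  if (!length(shared)) stop2("no genes shared between assignment and matrix")
  ln <- normalize_log(expr)$counts[, shared, drop = FALSE]
  types <- sort(unique(expr$cell_type))
  by_type <- vapply(types, function(t)
    colMeans(ln[expr$cell_type == t, , drop = FALSE]), numeric(length(shared)))
  if (length(shared) == 1L) by_type <- matrix(by_type, nrow = 1L,
                                              dimnames = list(shared, types))
  mu <- rowMeans(by_type)
  sd <- apply(by_type, 1L, stats::sd)
  z <- (by_type - mu) / ifelse(sd > 0, sd, 1)
  z[sd == 0, ] <- 0
  prog <- assign$assignment$program[match(shared, assign$assignment$gene)]
  act <- rowsum(z, prog) / as.vector(table(prog))
  rownames(act) <- paste0("program", sort(unique(prog)))
  structure(act, class = c("sclm_activity", "matrix"))
}

#' Write program assignment and activity tables
#'
#' @param assign an `sclm_programs` object.
#' @param activity an optional [program_activity()] matrix.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_programs <- function(assign, activity = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(assign$assignment, file.path(dir, "programs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(activity))
    utils::write.table(unclass(activity), file.path(dir, "activity.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
  invisible(dir)
}
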