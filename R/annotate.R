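#' Zero-shot cell-type annotation (reference mapping)
#'
#' Applies a pretrained classifier directly to a new corpus without any
#' parameter update. Genes absent from the model's vocabulary are dropped
#' before encoding; the prediction universe is the model's training label
#' set.
#'
#' @param state a pretrained `sclm_model` with a classifier head.
#' @param x an `sclm_expr` of raw counts, or an already tokenized
#'   `sclm_corpus`.
#' @param batch_size evaluation batch size.
#' @return an object of class `sclm_labels`: data.frame columns `barcode`,
#'   `predicted`, `confidence`, plus `reference` when the input carries
#'   cell-type labels, with the label universe as an attribute.
#' @export
zero_shot_annotate <- function(state, x, batch_size = 64L) {
  if (is.null(state$params$cls_W)) stop2("model has no classifier head")
  ref <- if (inherits(x, "sclm_corpus")) x$cell_type else x$cell_type
  df <- predict(state, x, type = "class", batch_size = batch_size)
  if (!is.null(ref)) df$reference <- ref
  structure(df, class = c("sclm_labels", "data.frame"),
            universe = state$classes)
}

#' Louvain clustering over a resolution grid
#'
#' Builds a symmetrized k-nearest-neighbor graph (Euclidean distances on the
#' raw embeddings) once, then runs Louvain community detection at each
#' resolution. Deterministic given `seed`.
#'
#' @param embeddings cells x d numeric matrix.
#' @param resolutions positive resolution values.
#' @param n_neighbors neighbors per cell (default 15).
#' @param seed integer seed.
#' @return list of clusterings, each `list(cluster, resolution, modularity)`
#'   with 0-based contiguous cluster ids.
#' @export
louvain_sweep <- function(embeddings, resolutions, n_neighbors = 15L, seed = 1L) {
  embeddings <- as.matrix(embeddings)
  n <- nrow(embeddings)
  if (n < n_neighbors + 1L) stop2("need at least n_neighbors + 1 cells")
  g <- knn_graph(embeddings, n_neighbors)
  lapply(resolutions, function(res) {
    stopifnot(res > 0)
    set.seed(seed)
    cl <- igraph::cluster_louvain(g, resolution = res)
    memb <- as.integer(igraph::membership(cl))
    list(cluster = match(memb, sort(unique(memb))) - 1L, resolution = res,
         modularity = max(igraph::modularity(cl)))
  })
}

knn_graph <- function(embeddings, k) {
  n <- nrow(embeddings)
  D <- as.matrix(stats::dist(embeddings))
  diag(D) <- Inf
  edges <- integer(0)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[seq_len(k)]
    edges <- c(edges, rbind(i, nb))
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2L, byrow = TRUE),
                                   directed = FALSE)
  igraph::simplify(g)
}

#' Adjusted Rand index between two labelings
#'
#' Permutation-model chance-adjusted agreement from the contingency table;
#' 1 for identical partitions (up to relabeling), ~0 at chance.
#'
#' @param a,b label vectors of equal length.
#' @return a real number (at most 1).
#' @export
ari <- function(a, b) {
  if (length(a) != length(b)) stop2("labelings differ in length")
  tab <- table(a, b)
  n <- length(a)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(1)  # both partitions trivial in the same way
  (sij - expected) / (mx - expected)
}

#' Normalized mutual information between two labelings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies. By declared convention the score is 1 when both labelings are
#' constant (identical trivial partitions) and 0 when exactly one entropy
#' is zero.
#'
#' @param a,b label vectors of equal length.
#' @return a real number in `[0, 1]`.
#' @export
nmi <- function(a, b) {
  if (length(a) != length(b)) stop2("labelings differ in length")
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab); pb <- colSums(tab)
  ha <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hb <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  pij <- tab[tab > 0]
  exp_ <- outer(pa, pb)[tab > 0]
  mi <- sum(pij * log(pij / exp_))
  min(1, max(0, mi / ((ha + hb) / 2)))
}

#' Mean silhouette score
#'
#' For each point, `a` is its mean Euclidean distance to its own cluster's
#' other members and `b` the smallest mean distance to another cluster; the
#' silhouette is `(b - a) / max(a, b)`, with singleton clusters
#' contributing 0. Returns the mean over points.
#'
#' @param embeddings points x d numeric matrix.
#' @param labels cluster/type label per point; at least two distinct labels.
#' @return a real number in `[-1, 1]`.
#' @export
silhouette_score <- function(embeddings, labels) {
  embeddings <- as.matrix(embeddings)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop2("need at least two clusters")
  D <- as.matrix(stats::dist(embeddings))
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Confusion matrix between reference and predicted labels
#'
#' Rows are reference labels, columns predictions. Accuracy is the exact
#' label match rate; when a `merge_map` is supplied (named vector
#' `from -> to`, e.g. collapsing protoxylem and metaxylem into xylem) both
#' sides are recoded first and a subtype-adjusted accuracy is also reported.
#'
#' @param labels an [zero_shot_annotate()] result carrying a `reference`
#'   column, or a data.frame with `predicted` and `reference`.
#' @param merge_map optional named character vector mapping labels onto a
#'   coarser universe.
#' @return an object of class `sclm_confusion`: `counts` matrix,
#'   `accuracy`, and `accuracy_merged` when a map was given.
#' @export
confusion <- function(labels, merge_map = NULL) {
  if (is.null(labels$reference)) stop2("reference labels missing")
  ref <- as.character(labels$reference)
  pred <- as.character(labels$predicted)
  universe <- sort(unique(c(ref, pred)))
  counts <- table(factor(ref, universe), factor(pred, universe))
  out <- list(counts = unclass(counts), accuracy = mean(ref == pred))
  if (!is.null(merge_map)) {
    recode <- function(x) ifelse(x %in% names(merge_map), merge_map[x], x)
    out$accuracy_merged <- mean(recode(ref) == recode(pred))
  }
  structure(out, class = "sclm_confusion")
}

#' @export
print.sclm_confusion <- function(x, ...) {
  cat(sprintf("<sclm_confusion> accuracy %.4f", x$accuracy))
  if (!is.null(x$accuracy_merged))
    cat(sprintf(" (merged universe: %.4f)", x$accuracy_merged))
  cat("\n")
  print(x$counts)
  invisible(x)
}

#' Write a confusion matrix as TSV
#' @param x an `sclm_confusion`.
#' @param path output file.
#' @export
write_confusion <- function(x, path) {
  utils::write.table(x$counts, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Integration benchmark over a Louvain resolution sweep
#'
#' Clusters the embeddings at every resolution, scores each partition
#' against the reference labels with ARI and NMI, computes the silhouette
#' of the reference cell types on the embedding, and reports per-resolution
#' curves plus the best value per metric.
#'
#' @param embeddings cells x d numeric matrix.
#' @param reference per-cell reference labels.
#' @param resolutions resolution grid (default 0.1 to 1.5 by 0.1).
#' @param n_neighbors kNN size (default 15).
#' @param seed integer seed.
#' @return an object of class `sclm_benchmark`: data.frame `curves`
#'   (resolution, n_clusters, ari, nmi), scalar `sil`, named `best`.
#' @export
benchmark <- function(embeddings, reference,
                      resolutions = seq(0.1, 1.5, by = 0.1),
                      n_neighbors = 15L, seed = 1L) {
  cls <- louvain_sweep(embeddings, resolutions, n_neighbors, seed)
  curves <- data.frame(
    resolution = resolutions,
    n_clusters = vapply(cls, function(cl) length(unique(cl$cluster)), integer(1)),
    ari = vapply(cls, function(cl) ari(cl$cluster, reference), numeric(1)),
    nmi = vapply(cls, function(cl) nmi(cl$cluster, reference), numeric(1)))
  sil <- silhouette_score(embeddings, reference)
  structure(list(curves = curves, sil = sil,
                 best = c(ari = max(curves$ari), nmi = max(curves$nmi), sil = sil)),
            class = "sclm_benchmark")
}

#' @export
print.sclm_benchmark <- function(x, ...) {
  cat(sprintf("<sclm_benchmark> best ARI %.3f | best NMI %.3f | SIL %.3f (%d resolutions)\n",
              x$best[["ari"]], x$best[["nmi"]], x$best[["sil"]], nrow(x$curves)))
  invisible(x)
}
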