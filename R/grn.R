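#' Per-cell gene-gene attention matrix
#'
#' Runs the encoder on one cell sentence, averages the attention maps over
#' heads of the chosen layer(s), removes the CLS row/column, symmetrizes as
#' `(A + t(A)) / 2` and min-max normalizes the off-diagonal scores to
#' `[0, 1]` (a constant matrix maps to all zeros). The diagonal is set to 0
#' and excluded from neighbor ranking.
#'
#' @param state a (typically MLM-pretrained) `sclm_model`.
#' @param sentence an [encode_cell()] result with at least 2 genes.
#' @param aggregation `"last_layer_mean_heads"` (default) or `"mean_all"`
#'   (mean over all layers and heads).
#' @param cell_id optional cell identifier recorded in the result.
#' @return an object of class `sclm_attention`: `genes`, square `scores`
#'   matrix in `[0, 1]`, `cell_id`, `aggregation`.
#' @export
cell_attention_matrix <- function(state, sentence,
                                  aggregation = c("last_layer_mean_heads", "mean_all"),
                                  cell_id = NA_character_) {
  aggregation <- match.arg(aggregation)
  stopifnot(inherits(sentence, "sclm_sentence"))
  if (sentence$length < 3L) stop2("sentence too short: need at least 2 genes")
  bt <- pad_batch(list(sentence), n_bins = state$n_bins %||% 51L)
  out <- sclm_forward(state, bt, return_attentions = TRUE, heads = character(0))
  layers <- if (aggregation == "mean_all") seq_along(out$attentions)
            else length(out$attentions)
  L <- sentence$length
  A <- matrix(0, L, L)
  cnt <- 0L
  for (l in layers) {
    Ab <- out$attentions[[l]][[1L]]
    for (hd in seq_len(dim(Ab)[1L])) {
      A <- A + Ab[hd, , ]
      cnt <- cnt + 1L
    }
  }
  A <- A / cnt
  A <- A[-1L, -1L, drop = FALSE]         # drop CLS
  A <- (A + t(A)) / 2
  off <- row(A) != col(A)
  rng <- range(A[off])
  S <- matrix(0, nrow(A), ncol(A))
  if (diff(rng) > 0) S[off] <- (A[off] - rng[1L]) / (rng[2L] - rng[1L])
  dimnames(S) <- list(sentence$genes, sentence$genes)
  structure(list(genes = sentence$genes, scores = S, cell_id = cell_id,
                 aggregation = aggregation), class = "sclm_attention")
}

#' @export
print.sclm_attention <- function(x, ...) {
  cat(sprintf("<sclm_attention> %d genes, %s aggregation%s\n",
              length(x$genes), x$aggregation,
              if (is.na(x$cell_id)) "" else paste0(", cell ", x$cell_id)))
  invisible(x)
}

#' Select hub genes by total attention
#'
#' Ranks genes by the row sum of their normalized attention scores (total
#' attention mass), ties broken by gene id; returns the top `n_hubs`.
#'
#' @param att an [cell_attention_matrix()] result.
#' @param n_hubs number of hubs.
#' @return character vector of hub gene ids.
#' @export
select_hubs <- function(att, n_hubs) {
  if (n_hubs <= 0) stop2("n_hubs must be positive")
  if (n_hubs > length(att$genes)) stop2("n_hubs exceeds number of genes")
  sums <- rowSums(att$scores)
  att$genes[order(-sums, att$genes)][seq_len(n_hubs)]
}

# deterministic top-k partners of `gene` among `candidates`
top_partners <- function(att, gene, candidates, k) {
  candidates <- setdiff(candidates, gene)
  if (!length(candidates)) return(character(0))
  sc <- att$scores[gene, candidates]
  candidates[order(-sc, candidates)][seq_len(min(k, length(candidates)))]
}

expand_from <- function(att, hubs, k, depth, universe) {
  nodes <- data.frame(gene = hubs, role = "hub", level = 0L,
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = character(0), target = character(0),
                      weight = numeric(0), level = integer(0),
                      stringsAsFactors = FALSE)
  frontier <- hubs
  lev <- 0L
  while (lev < depth && length(frontier)) {
    lev <- lev + 1L
    nxt <- character(0)
    for (node in frontier) {
      cand <- setdiff(universe, nodes$gene)
      new <- top_partners(att, node, cand, k)
      for (p in new) {
        nodes <- rbind(nodes, data.frame(gene = p, role = "neighbor",
                                         level = lev, stringsAsFactors = FALSE))
        edges <- rbind(edges, data.frame(source = node, target = p,
                                         weight = att$scores[node, p],
                                         level = lev, stringsAsFactors = FALSE))
      }
      nxt <- c(nxt, new)
    }
    frontier <- nxt
  }
  structure(list(nodes = nodes, edges = edges, hubs = hubs,
                 k = as.integer(k), depth = as.integer(depth), att = att),
            class = "sclm_network")
}

#' Expand a gene network from hub genes
#'
#' Breadth-first expansion on the attention matrix: level 1 attaches each
#' hub's `k` highest-scoring partners; level `l + 1` attaches each level-`l`
#' node's `k` highest-scoring partners not yet in the network. Edges carry
#' the attention score and the level at which they were added. Deterministic
#' (score descending, gene id ascending tie-break; hubs processed in the
#' given order).
#'
#' @param att an [cell_attention_matrix()] result.
#' @param hubs hub gene ids (subset of `att$genes`).
#' @param k neighbors per node (default 5).
#' @param depth expansion depth (default 2); 0 gives hubs only.
#' @return an object of class `sclm_network`: `nodes` (gene, role, level),
#'   `edges` (source, target, weight, level), plus the expansion settings
#'   and the attention matrix for later reduction.
#' @export
expand_network <- function(att, hubs, k = 5L, depth = 2L) {
  stopifnot(inherits(att, "sclm_attention"), k >= 1L, depth >= 0L)
  if (!all(hubs %in% att$genes)) stop2("unknown hub gene(s)")
  expand_from(att, hubs, k, depth, universe = att$genes)
}

#' Reduce a network to its strongest direct interactions
#'
#' Re-expands from the same hubs with a smaller `k` and `depth`, restricted
#' to the original network's node universe, yielding a focused subgraph
#' (e.g. top 2 partners at depth 1) whose nodes are contained in the
#' original network's.
#'
#' @param net an [expand_network()] result.
#' @param k neighbors per node (default 2); must not exceed the original.
#' @param depth depth (default 1); must not exceed the original.
#' @return an `sclm_network`.
#' @export
reduce_subgraph <- function(net, k = 2L, depth = 1L) {
  stopifnot(inherits(net, "sclm_network"))
  if (k > net$k || depth > net$depth)
    stop2("reduction k/depth must not exceed the original network's")
  expand_from(net$att, net$hubs, k, depth, universe = net$nodes$gene)
}

#' @export
print.sclm_network <- function(x, ...) {
  cat(sprintf("<sclm_network> %d hub(s), k=%d, depth=%d: %d nodes, %d edges\n",
              length(x$hubs), x$k, x$depth, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Export / import a gene network
#'
#' `edge_tsv` writes the edge list (source, target, weight, level) preceded
#' by commented node records (`# node <gene> <role> <level>`) so isolated
#' hubs round-trip; `graphml` writes GraphML via igraph with the same node
#' and edge attributes. Both round-trip losslessly through
#' [import_network()].
#'
#' @param net an `sclm_network`.
#' @param path output file.
#' @param format `"edge_tsv"` or `"graphml"` (guessed from the extension by
#'   default).
#' @return `path` invisibly (`export`), or the network (`import`; the
#'   attention matrix is not serialized, so a reimported network cannot be
#'   further reduced).
#' @export
export_network <- function(net, path, format = NULL) {
  format <- format %||% (if (grepl("\\.graphml$", path)) "graphml" else "edge_tsv")
  if (format == "edge_tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# meta\tk=%d\tdepth=%d", net$k, net$depth), con)
    writeLines(sprintf("# node\t%s\t%s\t%d", net$nodes$gene, net$nodes$role,
                       net$nodes$level), con)
    writeLines("source\ttarget\tweight\tlevel", con)
    if (nrow(net$edges))
      writeLines(sprintf("%s\t%s\t%.17g\t%d", net$edges$source, net$edges$target,
                         net$edges$weight, net$edges$level), con)
  } else {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("source", "target", "weight", "level")],
      directed = FALSE, vertices = net$nodes)
    igraph::graph_attr(g, "k") <- net$k
    igraph::graph_attr(g, "depth") <- net$depth
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname export_network
#' @export
import_network <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.graphml$", path)) "graphml" else "edge_tsv")
  if (format == "edge_tsv") {
    lines <- readLines(path)
    meta <- strsplit(sub("^# meta\t", "", lines[startsWith(lines, "# meta")]), "\t")[[1L]]
    kv <- vapply(strsplit(meta, "="), `[`, character(1), 2L)
    nd <- do.call(rbind, strsplit(sub("^# node\t", "",
                                      lines[startsWith(lines, "# node")]), "\t"))
    nodes <- data.frame(gene = nd[, 1L], role = nd[, 2L],
                        level = as.integer(nd[, 3L]), stringsAsFactors = FALSE)
    body <- lines[!startsWith(lines, "#")]
    edges <- utils::read.table(text = paste(body, collapse = "\n"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE,
                               colClasses = c("character", "character",
                                              "numeric", "integer"))
    k <- as.integer(kv[1L]); depth <- as.integer(kv[2L])
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- data.frame(gene = igraph::vertex_attr(g, "name"),
                        role = igraph::vertex_attr(g, "role"),
                        level = as.integer(igraph::vertex_attr(g, "level")),
                        stringsAsFactors = FALSE)
    el <- igraph::as_edgelist(g)
    edges <- data.frame(source = el[, 1L], target = el[, 2L],
                        weight = igraph::edge_attr(g, "weight"),
                        level = as.integer(igraph::edge_attr(g, "level")),
                        stringsAsFactors = FALSE)
    k <- as.integer(igraph::graph_attr(g, "k"))
    depth <- as.integer(igraph::graph_attr(g, "depth"))
  }
  structure(list(nodes = nodes, edges = edges,
                 hubs = nodes$gene[nodes$role == "hub"], k = k, depth = depth,
                 att = NULL), class = "sclm_network")
}

#' Average normalized attention matrices over cells
#'
#' Computes [cell_attention_matrix()] for each sentence and averages every
#' gene pair's normalized score over the cells in which both genes occur,
#' giving a corpus-level gene-gene attention summary on a common gene
#' universe.
#'
#' @param state an `sclm_model`.
#' @param sentences list of `sclm_sentence` (e.g. from an `sclm_corpus`).
#' @param genes gene universe of the result (default: union over
#'   sentences).
#' @param aggregation per-cell aggregation, see [cell_attention_matrix()].
#' @return list with `scores` (genes x genes mean attention, NA for pairs
#'   never observed together) and `n_obs` (co-occurrence counts).
#' @export
average_attention <- function(state, sentences,
                              genes = NULL,
                              aggregation = "last_layer_mean_heads") {
  genes <- genes %||% sort(unique(unlist(lapply(sentences, `[[`, "genes"))))
  G <- length(genes)
  acc <- matrix(0, G, G, dimnames = list(genes, genes))
  cnt <- matrix(0L, G, G, dimnames = list(genes, genes))
  for (s in sentences) {
    att <- cell_attention_matrix(state, s, aggregation)
    ix <- match(att$genes, genes)
    ok <- !is.na(ix)
    acc[ix[ok], ix[ok]] <- acc[ix[ok], ix[ok]] + att$scores[ok, ok]
    cnt[ix[ok], ix[ok]] <- cnt[ix[ok], ix[ok]] + 1L
  }
  scores <- ifelse(cnt > 0L, acc / pmax(cnt, 1L), NA_real_)
  diag(scores) <- 0
  list(scores = scores, n_obs = cnt)
}

#' Rank AUC separating two score sets
#'
#' Probability that a randomly chosen positive score exceeds a randomly
#' chosen negative one (ties count half): the Wilcoxon/Mann-Whitney AUC.
#' Used to quantify how well within-module attention ranks above
#' between-module attention.
#'
#' @param pos,neg numeric score vectors (NAs dropped).
#' @return AUC in `[0, 1]`.
#' @export
rank_auc <- function(pos, neg) {
  pos <- pos[!is.na(pos)]; neg <- neg[!is.na(neg)]
  if (!length(pos) || !length(neg)) stop2("need nonempty score sets")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# pair-score pools for a planted module: within-module pairs vs
# module-by-background pairs, from an average_attention() score matrix
module_pair_scores <- function(scores, module_genes) {
  g <- rownames(scores)
  m <- intersect(module_genes, g)
  b <- setdiff(g, m)
  W <- scores[m, m]
  within <- W[upper.tri(W)]
  between <- as.vector(scores[m, b])
  list(within = within, between = between)
}
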