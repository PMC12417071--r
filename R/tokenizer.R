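# Value-channel token layout: bins 0..n_bins-1 use their own ids; three
# reserved ids follow so the value-embedding table has n_bins + 3 rows.
value_ids <- function(n_bins) {
  n_bins <- as.integer(n_bins)
  c(CLS = n_bins, MASK = n_bins + 1L, PAD = n_bins + 2L)
}

n_value_tokens <- function(n_bins) n_bins + 3L

#' Encode one cell as a cell sentence
#'
#' A cell sentence is the sequence of (gene token, value bin) pairs for the
#' cell's nonzero genes, ordered by bin descending then gene id ascending,
#' truncated to `max_len - 1` genes, with a CLS token prepended. Zero-bin
#' genes are excluded, so sentence length tracks the number of expressed
#' genes, and truncation keeps the most highly expressed ones.
#'
#' @param binned_row named integer vector of bins for one cell (names are
#'   gene ids; every name must be in the vocabulary).
#' @param vocab an [build_vocabulary()] object.
#' @param max_len maximum sentence length including CLS.
#' @param n_bins bin count used to produce `binned_row`.
#' @return an object of class `sclm_sentence`: integer vectors `gene_tokens`
#'   and `value_bins` (aligned, CLS first), character `genes` (without CLS),
#'   `length`.
#' @export
encode_cell <- function(binned_row, vocab, max_len = 512L, n_bins = 51L) {
  g <- names(binned_row)
  if (is.null(g)) stop2("binned_row must be named by gene id")
  max_len <- as.integer(max_len)
  keep <- binned_row > 0L
  if (!any(keep)) stop2("cell has no nonzero gene; cannot encode an empty sentence")
  g <- g[keep]; b <- as.integer(binned_row[keep])
  if (anyNA(vocab$gene_to_token[g])) stop2("gene(s) absent from vocabulary")
  ord <- order(-b, g)
  n_keep <- min(length(ord), max_len - 1L)
  ord <- ord[seq_len(n_keep)]
  vid <- value_ids(n_bins)
  structure(list(
    gene_tokens = c(vocab$special_tokens[["CLS"]], unname(vocab$gene_to_token[g[ord]])),
    value_bins = c(vid[["CLS"]], b[ord]),
    genes = g[ord],
    length = n_keep + 1L), class = "sclm_sentence")
}

#' Encode a whole binned matrix into sentences
#'
#' @param binned an [bin_expression()] result.
#' @param vocab vocabulary; built from the matrix's genes when `NULL`.
#'   Genes absent from a supplied vocabulary are dropped before encoding.
#' @param max_len maximum sentence length including CLS.
#' @return list of `sclm_sentence`, named by cell id, with the vocabulary and
#'   `n_bins` attached as attributes.
#' @export
encode_corpus <- function(binned, vocab = NULL, max_len = 512L) {
  stopifnot(inherits(binned, "sclm_binned"))
  vocab <- vocab %||% build_vocabulary(binned$gene_ids)
  known <- binned$gene_ids %in% vocab_genes(vocab)
  if (!any(known)) stop2("no overlap between corpus genes and vocabulary")
  bm <- binned$bins[, known, drop = FALSE]
  out <- vector("list", nrow(bm))
  for (i in seq_len(nrow(bm)))
    out[[i]] <- encode_cell(bm[i, ], vocab, max_len, binned$n_bins)
  names(out) <- binned$cell_ids
  attr(out, "vocab") <- vocab
  attr(out, "n_bins") <- binned$n_bins
  out
}

#' Pad cell sentences into a rectangular batch
#'
#' Right-pads with the PAD gene token and the PAD value id; `pad_flags`
#' marks padding. Content is bit-identical to the input sentences.
#'
#' @param sentences list of `sclm_sentence`.
#' @param max_len batch width; defaults to the longest sentence. Sentences
#'   longer than `max_len` are an error.
#' @param n_bins bin count (needed for the PAD value id).
#' @return an object of class `sclm_batch`: integer matrices `gene_tokens`,
#'   `value_bins` (batch x max_len), logical `pad_flags`, integer `lengths`,
#'   `n_bins`.
#' @export
pad_batch <- function(sentences, max_len = NULL, n_bins = 51L) {
  lens <- vapply(sentences, function(s) s$length, integer(1))
  max_len <- as.integer(max_len %||% max(lens))
  if (any(lens > max_len)) stop2("sentence longer than max_len")
  B <- length(sentences)
  vid <- value_ids(n_bins)
  gt <- matrix(0L, B, max_len)              # PAD gene token = 0
  vb <- matrix(vid[["PAD"]], B, max_len)
  pad <- matrix(TRUE, B, max_len)
  for (i in seq_len(B)) {
    l <- lens[i]
    gt[i, seq_len(l)] <- sentences[[i]]$gene_tokens
    vb[i, seq_len(l)] <- sentences[[i]]$value_bins
    pad[i, seq_len(l)] <- FALSE
  }
  structure(list(gene_tokens = gt, value_bins = vb, pad_flags = pad,
                 lengths = lens, n_bins = as.integer(n_bins),
                 cell_ids = names(sentences)),
            class = "sclm_batch")
}

#' Recover sentences from a padded batch
#' @param batch an `sclm_batch`.
#' @return list of `sclm_sentence` (without gene-id names, token level only).
#' @export
unpad_batch <- function(batch) {
  lapply(seq_len(nrow(batch$gene_tokens)), function(i) {
    l <- batch$lengths[i]
    structure(list(gene_tokens = batch$gene_tokens[i, seq_len(l)],
                   value_bins = batch$value_bins[i, seq_len(l)],
                   genes = NULL, length = l), class = "sclm_sentence")
  })
}

#' Apply masked-value corruption to a batch
#'
#' Per sentence, exactly `round(rate * n_maskable)` value positions are
#' chosen uniformly without replacement among the maskable positions
#' (non-CLS, non-PAD) and their value bins are replaced by the MASK
#' sentinel. The gene-token stream is never corrupted: the model must
#' reconstruct the hidden expression level of a known gene from the
#' remaining context. Deterministic given `seed`.
#'
#' @param batch an uncorrupted `sclm_batch`.
#' @param rate fraction of maskable positions to hide (default 0.15).
#' @param seed integer seed.
#' @return an object of class `sclm_masked_batch`: the batch fields plus
#'   corrupted `value_bins_in`, logical `mask_flags`, and `value_targets`
#'   (original bins at masked positions, NA elsewhere).
#' @export
apply_mask <- function(batch, rate = 0.15, seed = 1L) {
  stopifnot(inherits(batch, "sclm_batch"), rate >= 0, rate <= 1)
  vid <- value_ids(batch$n_bins)
  vb_in <- batch$value_bins
  mask <- matrix(FALSE, nrow(vb_in), ncol(vb_in))
  targets <- matrix(NA_integer_, nrow(vb_in), ncol(vb_in))
  set.seed(seed)
  for (i in seq_len(nrow(vb_in))) {
    maskable <- setdiff(seq_len(batch$lengths[i]), 1L)  # non-CLS, non-PAD
    n_mask <- round(rate * length(maskable))
    if (n_mask < 1L) next
    pos <- maskable[sample.int(length(maskable), n_mask)]
    mask[i, pos] <- TRUE
    targets[i, pos] <- vb_in[i, pos]
    vb_in[i, pos] <- vid[["MASK"]]
  }
  out <- batch
  out$value_bins_in <- vb_in
  out$mask_flags <- mask
  out$value_targets <- targets
  class(out) <- c("sclm_masked_batch", "sclm_batch")
  out
}

# masked targets in cell-major scan order (cell 1 positions left-to-right,
# then cell 2, ...), on the unit scale used by the regression head
masked_targets_vec <- function(mb) {
  tt <- t(mb$value_targets)
  as.numeric(tt[!is.na(tt)]) / (mb$n_bins - 1L)
}
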