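#' Model configuration
#'
#' Architecture hyperparameters of the cell-sentence encoder. The encoder is
#' a standard pre-norm transformer: `n_layers` layers (default 6) of
#' multi-head self-attention with `n_heads` heads (default 8) followed by a
#' position-wise feed-forward network. Token embeddings are the elementwise
#' sum of a gene-id embedding and a value-bin embedding; no positional
#' encoding is used, since a cell sentence is an unordered gene set.
#'
#' @param n_gene_tokens gene-token table size (vocabulary size incl. PAD,
#'   CLS, MASK).
#' @param n_value_tokens value-token table size (`n_bins + 3`).
#' @param n_layers encoder depth (default 6).
#' @param n_heads attention heads per layer (default 8); must divide
#'   `d_model`.
#' @param d_model hidden width (default 256).
#' @param d_ff feed-forward width (default `4 * d_model`).
#' @param n_classes classifier label count; 0 disables the head.
#' @param dropout dropout fraction on the residual branches during training.
#' @param max_len maximum sentence length including CLS.
#' @param pooling `"cls"` (default) or `"mean"`: how the cell embedding is
#'   read off the final token states.
#' @return an object of class `sclm_config`.
#' @export
model_config <- function(n_gene_tokens, n_value_tokens,
                         n_layers = 6L, n_heads = 8L, d_model = 256L,
                         d_ff = 4L * d_model, n_classes = 0L, dropout = 0,
                         max_len = 512L, pooling = c("cls", "mean")) {
  pooling <- match.arg(pooling)
  cfg <- list(n_gene_tokens = as.integer(n_gene_tokens),
              n_value_tokens = as.integer(n_value_tokens),
              n_layers = as.integer(n_layers), n_heads = as.integer(n_heads),
              d_model = as.integer(d_model), d_ff = as.integer(d_ff),
              n_classes = as.integer(n_classes), dropout = dropout,
              max_len = as.integer(max_len), pooling = pooling)
  with(cfg, {
    if (d_model %% n_heads != 0L) stop2("d_model must be divisible by n_heads")
    if (any(c(n_layers, n_heads, d_model, d_ff, max_len) <= 0L))
      stop2("all dimensions must be positive")
  })
  structure(cfg, class = "sclm_config")
}

# Parameters live in one flat named list so the optimizer and the numeric
# gradient checker can walk them uniformly.
model_params_init <- function(cfg, seed = 1L, sd = 0.02) {
  set.seed(seed)
  d <- cfg$d_model
  p <- list(E_id = rand_mat(cfg$n_gene_tokens, d, sd),
            E_expr = rand_mat(cfg$n_value_tokens, d, sd))
  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("L", l, "_")
    p[[paste0(pre, "ln1_g")]] <- rep(1, d)
    p[[paste0(pre, "ln1_b")]] <- rep(0, d)
    for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, w)]] <- rand_mat(d, d, sd)
    for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <- rep(0, d)
    p[[paste0(pre, "ln2_g")]] <- rep(1, d)
    p[[paste0(pre, "ln2_b")]] <- rep(0, d)
    p[[paste0(pre, "W1")]] <- rand_mat(d, cfg$d_ff, sd)
    p[[paste0(pre, "b1")]] <- rep(0, cfg$d_ff)
    p[[paste0(pre, "W2")]] <- rand_mat(cfg$d_ff, d, sd)
    p[[paste0(pre, "b2")]] <- rep(0, d)
  }
  p$lnf_g <- rep(1, d)
  p$lnf_b <- rep(0, d)
  p$mlm_W1 <- rand_mat(d, d, sd)
  p$mlm_b1 <- rep(0, d)
  p$mlm_W2 <- rand_mat(d, 1L, sd)
  p$mlm_b2 <- 0.5  # bin-range midpoint on the unit scale
  if (cfg$n_classes > 0L) {
    p$cls_W <- rand_mat(d, cfg$n_classes, sd)
    p$cls_b <- rep(0, cfg$n_classes)
  }
  p
}

#' Initialize a fresh model
#'
#' @param cfg an [model_config()].
#' @param seed integer seed for parameter initialization.
#' @param vocab optional vocabulary to attach (checked at checkpoint load).
#' @param n_bins optional bin count used by the tokenizer feeding this model.
#' @return an object of class `sclm_model`: `config`, flat parameter list
#'   `params`, optional `vocab`, `n_bins`, and a `trained` stage record.
#' @export
model_init <- function(cfg, seed = 1L, vocab = NULL, n_bins = NULL) {
  structure(list(config = cfg, params = model_params_init(cfg, seed),
                 vocab = vocab, n_bins = n_bins,
                 classes = NULL, trained = character(0)),
            class = "sclm_model")
}

#' @export
print.sclm_model <- function(x, ...) {
  cfg <- x$config
  npar <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf("<sclm_model> %d-layer encoder, %d heads, d_model=%d (%s pooling)\n",
              cfg$n_layers, cfg$n_heads, cfg$d_model, cfg$pooling))
  cat(sprintf("  gene tokens: %d | value tokens: %d | classes: %d | parameters: %s\n",
              cfg$n_gene_tokens, cfg$n_value_tokens, cfg$n_classes,
              format(npar, big.mark = ",")))
  if (length(x$trained))
    cat("  trained stages:", paste(x$trained, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
summary.sclm_model <- function(object, ...) {
  print(object)
  if (!is.null(object$classes))
    cat("  label universe:", paste(object$classes, collapse = ", "), "\n")
  if (!is.null(object$vocab))
    cat("  vocabulary:", length(object$vocab$gene_to_token), "genes\n")
  invisible(object)
}

#' Extract learned embedding tables
#'
#' @param object an `sclm_model`.
#' @param ... ignored.
#' @return list with `gene` (gene-id embedding table) and `value`
#'   (value-bin embedding table).
#' @export
coef.sclm_model <- function(object, ...) {
  list(gene = object$params$E_id, value = object$params$E_expr)
}

layernorm_fwd <- function(x, g, b, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc / sd
  list(y = sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+"), xhat = xhat, sd = sd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxh <- sweep(dy, 2L, g, "*")
  dx <- (dxh - rowMeans(dxh) - xhat * rowMeans(dxh * xhat)) / cache$sd
  list(dx = dx, dg = dg, db = db)
}

#' Sum gene-id and value-bin embeddings into token embeddings
#'
#' The token embedding is the elementwise sum of the gene-identity embedding
#' and the binned-expression-value embedding, with no scaling.
#'
#' @param gene_tokens,value_bins integer matrices (batch x len), 0-based ids.
#' @param state an `sclm_model`.
#' @return numeric matrix of shape `(batch*len) x d_model`, rows in
#'   cell-major order (cell 1 positions first).
#' @export
embed_tokens <- function(gene_tokens, value_bins, state) {
  p <- state$params
  gid <- as.vector(t(gene_tokens)) + 1L
  vid <- as.vector(t(value_bins)) + 1L
  if (min(gid) < 1L || max(gid) > nrow(p$E_id)) stop2("gene token id out of range")
  if (min(vid) < 1L || max(vid) > nrow(p$E_expr)) stop2("value token id out of range")
  p$E_id[gid, , drop = FALSE] + p$E_expr[vid, , drop = FALSE]
}

#' Run the encoder forward
#'
#' Deterministic in evaluation mode (`train = FALSE`). PAD positions are
#' excluded from attention by masking the key dimension, so every attention
#' row is a distribution over the valid (non-PAD) tokens and PAD keys get
#' exactly zero mass.
#'
#' @param state an `sclm_model`.
#' @param batch an `sclm_batch` or `sclm_masked_batch` (the corrupted value
#'   channel is used when present).
#' @param return_attentions if TRUE, return all `n_layers x n_heads`
#'   attention matrices per sequence.
#' @param heads which output heads to compute: subset of `c("mlm","class")`.
#' @param train if TRUE, keep intermediate activations for backprop and
#'   apply dropout.
#' @param dropout_seed seed for dropout masks when training.
#' @return list with `token_states` ((batch*len) x d_model, cell-major rows),
#'   `cell_embedding` (batch x d_model), `mlm_pred` (batch x len, unit
#'   scale), `class_logits`, `attentions`, and (training only) `cache`.
#' @export
sclm_forward <- function(state, batch, return_attentions = FALSE,
                         heads = c("mlm", "class"), train = FALSE,
                         dropout_seed = 1L) {
  cfg <- state$config
  p <- state$params
  gt <- batch$gene_tokens
  vb <- if (!is.null(batch$value_bins_in)) batch$value_bins_in else batch$value_bins
  B <- nrow(gt); L <- ncol(gt)
  if (L > cfg$max_len) stop2("batch length exceeds config max_len")
  H <- cfg$n_heads; d <- cfg$d_model; dk <- d %/% H
  drop_p <- if (train) cfg$dropout else 0
  if (drop_p > 0) set.seed(dropout_seed)

  X <- embed_tokens(gt, vb, state)
  N <- B * L
  seq_rows <- function(b) ((b - 1L) * L + 1L):(b * L)
  valid <- lapply(seq_len(B), function(b) which(!batch$pad_flags[b, ]))

  cache <- if (train) list(gt = gt, vb = vb, B = B, L = L, layers = vector("list", cfg$n_layers))
  atts <- if (return_attentions) vector("list", cfg$n_layers)

  for (l in seq_len(cfg$n_layers)) {
    pre <- paste0("L", l, "_")
    lc <- list(x_in = if (train) X)
    ln1 <- layernorm_fwd(X, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    h <- ln1$y
    Q <- h %*% p[[paste0(pre, "Wq")]]; Q <- sweep(Q, 2L, p[[paste0(pre, "bq")]], "+")
    K <- h %*% p[[paste0(pre, "Wk")]]; K <- sweep(K, 2L, p[[paste0(pre, "bk")]], "+")
    V <- h %*% p[[paste0(pre, "Wv")]]; V <- sweep(V, 2L, p[[paste0(pre, "bv")]], "+")
    O <- matrix(0, N, d)
    A_store <- if (train || return_attentions) vector("list", B)
    for (b in seq_len(B)) {
      idx <- seq_rows(b)
      vk <- valid[[b]]
      Ab <- if (train || return_attentions) array(0, c(H, L, L))
      for (hd in seq_len(H)) {
        cols <- ((hd - 1L) * dk + 1L):(hd * dk)
        S <- (Q[idx, cols, drop = FALSE] %*% t(K[idx, cols, drop = FALSE])) / sqrt(dk)
        A <- matrix(0, L, L)
        A[, vk] <- row_softmax(S[, vk, drop = FALSE])
        O[idx, cols] <- A %*% V[idx, cols, drop = FALSE]
        if (!is.null(Ab)) Ab[hd, , ] <- A
      }
      if (!is.null(A_store)) A_store[[b]] <- Ab
    }
    attn_out <- sweep(O %*% p[[paste0(pre, "Wo")]], 2L, p[[paste0(pre, "bo")]], "+")
    if (drop_p > 0) {
      m1 <- matrix(stats::rbinom(N * d, 1L, 1 - drop_p), N, d) / (1 - drop_p)
      attn_out <- attn_out * m1
      lc$drop1 <- m1
    }
    X <- X + attn_out
    ln2 <- layernorm_fwd(X, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    u <- sweep(ln2$y %*% p[[paste0(pre, "W1")]], 2L, p[[paste0(pre, "b1")]], "+")
    a <- gelu(u)
    f <- sweep(a %*% p[[paste0(pre, "W2")]], 2L, p[[paste0(pre, "b2")]], "+")
    if (drop_p > 0) {
      m2 <- matrix(stats::rbinom(N * d, 1L, 1 - drop_p), N, d) / (1 - drop_p)
      f <- f * m2
      lc$drop2 <- m2
    }
    if (train) {
      lc$ln1 <- ln1; lc$h <- h; lc$Q <- Q; lc$K <- K; lc$V <- V; lc$O <- O
      lc$A <- A_store; lc$x_mid <- X; lc$ln2 <- ln2; lc$u <- u; lc$a <- a
      cache$layers[[l]] <- lc
    }
    if (return_attentions) atts[[l]] <- A_store
    X <- X + f
  }
  if (train) cache$x_final_in <- X
  lnf <- layernorm_fwd(X, p$lnf_g, p$lnf_b)
  Xf <- lnf$y
  if (train) cache$lnf <- lnf

  cell_emb <- if (cfg$pooling == "cls") {
    Xf[(seq_len(B) - 1L) * L + 1L, , drop = FALSE]
  } else {
    np <- !as.vector(t(batch$pad_flags))
    grp <- rep(seq_len(B), each = L)[np]
    rowsum(Xf[np, , drop = FALSE], grp) / batch$lengths
  }
  rownames(cell_emb) <- batch$cell_ids

  out <- list(token_states = Xf, cell_embedding = cell_emb, B = B, L = L,
              attentions = atts, pad_flags = batch$pad_flags)
  if ("mlm" %in% heads) {
    Hm <- sweep(Xf %*% p$mlm_W1, 2L, p$mlm_b1, "+")
    Am <- gelu(Hm)
    P <- Am %*% p$mlm_W2 + p$mlm_b2
    out$mlm_pred <- matrix(P, B, L, byrow = TRUE)
    if (train) { cache$mlm_Hm <- Hm; cache$mlm_Am <- Am }
  }
  if ("class" %in% heads && cfg$n_classes > 0L && !is.null(p$cls_W)) {
    out$class_logits <- sweep(cell_emb %*% p$cls_W, 2L, p$cls_b, "+")
    colnames(out$class_logits) <- state$classes
  }
  if (train) out$cache <- cache
  class(out) <- "sclm_forward"
  out
}

#' Cell embeddings from a forward pass
#'
#' Returns the pooled per-cell representation (CLS token state by default).
#'
#' @param out an `sclm_forward` result.
#' @return batch x d_model numeric matrix.
#' @export
cell_embedding <- function(out) out$cell_embedding

#' Predicted values at masked positions
#'
#' One scalar prediction per masked position, on the unit scale
#' (`bin / (n_bins - 1)`), in cell-major scan order (all positions of cell 1
#' left-to-right, then cell 2, ...).
#'
#' @param out an `sclm_forward` result computed with the `"mlm"` head.
#' @param mask_flags logical batch x len matrix from [apply_mask()].
#' @return numeric vector, one entry per masked position.
#' @export
predict_masked_values <- function(out, mask_flags) {
  if (!any(mask_flags)) stop2("no masked positions")
  tp <- t(out$mlm_pred)
  tp[t(mask_flags)]
}

#' Class logits from a forward pass
#'
#' @param out an `sclm_forward` result.
#' @param state the model (used only to verify the head exists).
#' @return batch x n_classes logits; argmax is the predicted type.
#' @export
classify <- function(out, state) {
  if (is.null(out$class_logits)) stop2("classifier head absent or not computed")
  out$class_logits
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the parameters, the full
#' configuration, the attached vocabulary and its fingerprint. Loading
#' against a different vocabulary is refused.
#'
#' @param state an `sclm_model`.
#' @param path checkpoint file.
#' @param vocab optional vocabulary to check the checkpoint against.
#' @return `save_model`: `path` invisibly; `load_model`: the model.
#' @export
save_model <- function(state, path) {
  obj <- unclass(state)
  obj$vocab_fp <- if (!is.null(state$vocab)) vocab_hash(state$vocab)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path, vocab = NULL) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$params) || is.null(obj$config))
    stop2("corrupted checkpoint: ", path)
  if (!is.null(vocab) && !is.null(obj$vocab_fp) &&
      vocab_hash(vocab) != obj$vocab_fp)
    stop2("checkpoint vocabulary mismatch")
  obj$vocab_fp <- NULL
  class(obj$config) <- "sclm_config"
  if (!is.null(obj$vocab)) class(obj$vocab) <- "sclm_vocab"
  structure(obj, class = "sclm_model")
}
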