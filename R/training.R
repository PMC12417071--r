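#' Training configuration
#'
#' Defaults follow the hyperparameter study behind the model: batch size 64
#' and Adam learning rate 1e-4. All randomness in a run (shuffling, masking,
#' dropout, splits) derives from `seed`.
#'
#' @param stage one of `"mlm"`, `"annotate"`, `"finetune"`.
#' @param epochs number of passes over the corpus.
#' @param batch_size cells per step (default 64).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param mask_rate fraction of maskable value positions hidden per sentence
#'   in the MLM stage (default 0.15).
#' @param seed integer seed controlling the whole run.
#' @param max_len maximum sentence length including CLS (default 512).
#' @param holdout_frac held-out fraction for supervised stages (default 0.1,
#'   stratified by cell type).
#' @param freeze_encoder if TRUE, supervised stages update only the
#'   classifier head.
#' @return an object of class `sclm_train_config`.
#' @export
train_config <- function(stage = c("mlm", "annotate", "finetune"), epochs = 5L,
                         batch_size = 64L, learning_rate = 1e-4,
                         mask_rate = 0.15, seed = 1L, max_len = 512L,
                         holdout_frac = 0.1, freeze_encoder = FALSE) {
  stage <- match.arg(stage)
  if (batch_size < 1L) stop2("batch_size must be >= 1")
  if (mask_rate < 0 || mask_rate > 1) stop2("mask_rate must be in [0,1]")
  if (learning_rate <= 0) stop2("learning_rate must be positive")
  structure(list(stage = stage, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, mask_rate = mask_rate,
                 seed = as.integer(seed), max_len = as.integer(max_len),
                 holdout_frac = holdout_frac, freeze_encoder = freeze_encoder),
            class = "sclm_train_config")
}

#' Mean squared error over masked positions
#' @param pred,target equal-length numeric vectors (masked positions only).
#' @return nonnegative scalar.
#' @export
mse_masked_loss <- function(pred, target) {
  if (!length(pred) || length(pred) != length(target))
    stop2("pred and target must be nonempty and of equal length")
  mean((pred - target)^2)
}

#' Mean cross-entropy of class logits
#' @param logits batch x n_classes matrix.
#' @param labels integer class indices (1-based), or characters matched
#'   against `colnames(logits)`.
#' @return nonnegative scalar.
#' @export
cross_entropy_loss <- function(logits, labels) {
  if (is.character(labels) || is.factor(labels))
    labels <- match(as.character(labels), colnames(logits))
  labels <- as.integer(labels)
  if (anyNA(labels) || min(labels) < 1L || max(labels) > ncol(logits))
    stop2("label out of class range")
  lp <- logits - apply(logits, 1L, max)
  lse <- log(rowSums(exp(lp)))
  -mean(lp[cbind(seq_len(nrow(logits)), labels)] - lse)
}

#' Tokenize an expression matrix into a training corpus
#'
#' Convenience wrapper over the preprocessing chain: optional HVG selection,
#' total-count + log1p normalization, per-cell quantile binning, vocabulary
#' construction and sentence encoding.
#'
#' @param expr an `sclm_expr` of raw counts.
#' @param vocab optional fixed vocabulary (e.g. a pretrained model's); genes
#'   absent from it are dropped before encoding.
#' @param n_bins expression bins including the zero bin (default 51).
#' @param max_len maximum sentence length including CLS.
#' @param n_hvg optional number of highly variable genes to keep first.
#' @param target_sum normalization total (default 1e4).
#' @return an object of class `sclm_corpus`: `sentences`, `vocab`, `n_bins`,
#'   `cell_ids`, `cell_type`, `batch`.
#' @export
tokenize_corpus <- function(expr, vocab = NULL, n_bins = 51L, max_len = 512L,
                            n_hvg = NULL, target_sum = 1e4) {
  stopifnot(inherits(expr, "sclm_expr"))
  if (!is.null(n_hvg)) expr <- select_hvgs(expr, n_hvg)
  norm <- normalize_log(expr, target_sum)
  binned <- bin_expression(norm, n_bins)
  sentences <- encode_corpus(binned, vocab, max_len)
  structure(list(sentences = sentences, vocab = attr(sentences, "vocab"),
                 n_bins = as.integer(n_bins), cell_ids = expr$cell_ids,
                 cell_type = expr$cell_type, batch = expr$batch),
            class = "sclm_corpus")
}

#' @export
print.sclm_corpus <- function(x, ...) {
  lens <- vapply(x$sentences, function(s) s$length, integer(1))
  cat(sprintf("<sclm_corpus> %d cells; %d-gene vocabulary; %d bins; sentence length %d-%d (median %d)\n",
              length(x$sentences), length(x$vocab$gene_to_token), x$n_bins,
              min(lens), max(lens), as.integer(stats::median(lens))))
  invisible(x)
}

subset_corpus <- function(corpus, idx) {
  out <- corpus
  out$sentences <- corpus$sentences[idx]
  out$cell_ids <- corpus$cell_ids[idx]
  out$cell_type <- corpus$cell_type[idx]
  out$batch <- corpus$batch[idx]
  out
}

n_cells <- function(corpus) length(corpus$sentences)

stratified_indices <- function(strata, frac_test, seed) {
  set.seed(seed)
  test <- integer(0)
  for (s in unique(strata)) {
    ix <- which(strata == s)
    if (!length(ix)) stop2("empty stratum: ", s)
    n_test <- round(length(ix) * frac_test)
    if (n_test > 0L) test <- c(test, ix[sample.int(length(ix), n_test)])
  }
  sort(test)
}

batch_indices <- function(n, batch_size) {
  split(seq_len(n), ceiling(seq_len(n) / batch_size))
}

# one MLM optimization step; returns loss and updated (state, opt)
mlm_step <- function(state, corpus, idx, cfg, opt, step_id) {
  sents <- corpus$sentences[idx]
  bt <- pad_batch(sents, n_bins = corpus$n_bins)
  mb <- apply_mask(bt, cfg$mask_rate, seed = derive_seed(cfg$seed, step_id))
  out <- sclm_forward(state, mb, heads = "mlm", train = TRUE,
                      dropout_seed = derive_seed(cfg$seed, step_id + 1L))
  target <- masked_targets_vec(mb)
  pred <- predict_masked_values(out, mb$mask_flags)
  loss <- mse_masked_loss(pred, target)
  err <- 2 * (pred - target) / length(target)
  dmT <- matrix(0, ncol(mb$gene_tokens), nrow(mb$gene_tokens))
  dmT[t(mb$mask_flags)] <- err
  grads <- sclm_backward(state, out, d_mlm = t(dmT))
  upd <- adam_step(state$params, grads, opt, cfg$learning_rate)
  state$params <- upd$params
  list(state = state, opt = upd$opt, loss = loss)
}

#' Stage-1 masked-value pretraining
#'
#' Hides `mask_rate` of each sentence's expression bins and trains the
#' encoder plus a two-layer regression head to reconstruct them, minimizing
#' mean squared error on the unit-scaled bin values. Deterministic given
#' `cfg$seed` (single-threaded).
#'
#' @param corpus an [tokenize_corpus()] result.
#' @param cfg an [train_config()] with `stage = "mlm"`.
#' @param init optional `sclm_model` to continue from; a fresh model is
#'   created otherwise.
#' @param model_cfg optional [model_config()] for the fresh model; sensible
#'   table sizes are derived from the corpus when omitted.
#' @return list with `model` (an `sclm_model`) and `report` (per-epoch loss
#'   trajectory, per-step losses, final loss, step count).
#' @export
pretrain_mlm <- function(corpus, cfg, init = NULL, model_cfg = NULL) {
  stopifnot(inherits(corpus, "sclm_corpus"), cfg$stage == "mlm")
  if (!n_cells(corpus)) stop2("empty corpus")
  state <- init %||% {
    mc <- model_cfg %||% model_config(n_gene_tokens = vocab_size(corpus$vocab),
                                      n_value_tokens = n_value_tokens(corpus$n_bins))
    model_init(mc, seed = cfg$seed, vocab = corpus$vocab, n_bins = corpus$n_bins)
  }
  opt <- adam_init(state$params)
  n <- n_cells(corpus)
  epoch_loss <- numeric(0)
  step_losses <- numeric(0)
  steps <- 0L
  if (cfg$epochs > 0L) for (ep in seq_len(cfg$epochs)) {
    set.seed(derive_seed(cfg$seed, 500000L + ep))
    perm <- sample.int(n)
    losses <- numeric(0)
    for (chunk in batch_indices(n, cfg$batch_size)) {
      steps <- steps + 1L
      st <- mlm_step(state, corpus, perm[chunk], cfg, opt, ep * 100000L + steps * 2L)
      state <- st$state; opt <- st$opt
      losses <- c(losses, st$loss)
    }
    step_losses <- c(step_losses, losses)
    epoch_loss <- c(epoch_loss, mean(losses))
  }
  state$trained <- c(state$trained, "mlm")
  report <- structure(list(stage = "mlm", epoch_loss = epoch_loss,
                           step_loss = step_losses,
                           final_loss = if (length(epoch_loss)) utils::tail(epoch_loss, 1) else NA_real_,
                           steps = steps, metrics = list()),
                      class = "sclm_report")
  list(model = state, report = report)
}

#' @export
print.sclm_report <- function(x, ...) {
  cat(sprintf("<sclm_report> stage %s: %d epochs, %d steps, final loss %.5f\n",
              x$stage, length(x$epoch_loss), x$steps, x$final_loss))
  if (length(x$metrics))
    for (n in names(x$metrics)) cat(sprintf("  %s: %s\n", n,
      paste(signif(unlist(x$metrics[[n]]), 4), collapse = " ")))
  invisible(x)
}

attach_classifier <- function(state, classes, seed = 1L) {
  d <- state$config$d_model
  old_classes <- state$classes
  set.seed(derive_seed(seed, 99L))
  W <- rand_mat(d, length(classes))
  b <- numeric(length(classes))
  if (!is.null(old_classes) && !is.null(state$params$cls_W)) {
    shared <- intersect(classes, old_classes)
    W[, match(shared, classes)] <- state$params$cls_W[, match(shared, old_classes)]
    b[match(shared, classes)] <- state$params$cls_b[match(shared, old_classes)]
  }
  state$params$cls_W <- W
  state$params$cls_b <- b
  state$config$n_classes <- length(classes)
  state$classes <- classes
  state
}

classifier_step <- function(state, corpus, idx, y, cfg, opt, step_id) {
  sents <- corpus$sentences[idx]
  bt <- pad_batch(sents, n_bins = corpus$n_bins)
  out <- sclm_forward(state, bt, heads = "class", train = TRUE,
                      dropout_seed = derive_seed(cfg$seed, step_id))
  logits <- out$class_logits
  loss <- cross_entropy_loss(logits, y[idx])
  sm <- row_softmax(logits)
  sm[cbind(seq_along(idx), y[idx])] <- sm[cbind(seq_along(idx), y[idx])] - 1
  grads <- sclm_backward(state, out, d_logits = sm / length(idx))
  if (cfg$freeze_encoder)
    grads <- grads[c("cls_W", "cls_b")]
  upd <- adam_step(state$params, grads, opt, cfg$learning_rate)
  state$params <- upd$params
  list(state = state, opt = upd$opt, loss = loss)
}

train_classifier <- function(state, corpus, cfg) {
  if (is.null(corpus$cell_type)) stop2("corpus has no cell_type labels")
  classes <- sort(unique(corpus$cell_type))
  if (length(classes) < 2L) stop2("need at least two cell types to train a classifier")
  new_labels <- if (is.null(state$classes)) classes else setdiff(classes, state$classes)
  universe <- if (is.null(state$classes)) classes else c(state$classes, new_labels)
  state <- attach_classifier(state, universe, seed = cfg$seed)
  y <- match(corpus$cell_type, universe)

  hold <- stratified_indices(corpus$cell_type, cfg$holdout_frac,
                             derive_seed(cfg$seed, 7L))
  train_ix <- setdiff(seq_len(n_cells(corpus)), hold)
  opt <- adam_init(state$params)
  epoch_loss <- numeric(0)
  hold_acc <- numeric(0)
  steps <- 0L
  if (cfg$epochs > 0L) for (ep in seq_len(cfg$epochs)) {
    set.seed(derive_seed(cfg$seed, 600000L + ep))
    perm <- train_ix[sample.int(length(train_ix))]
    losses <- numeric(0)
    for (chunk in batch_indices(length(perm), cfg$batch_size)) {
      steps <- steps + 1L
      st <- classifier_step(state, corpus, perm[chunk], y, cfg, opt,
                            ep * 100000L + steps * 2L)
      state <- st$state; opt <- st$opt
      losses <- c(losses, st$loss)
    }
    epoch_loss <- c(epoch_loss, mean(losses))
    if (length(hold)) {
      pr <- model_predict(state, subset_corpus(corpus, hold), cfg$batch_size)
      hold_acc <- c(hold_acc, mean(pr$label == corpus$cell_type[hold]))
    }
  }
  report <- structure(list(stage = cfg$stage, epoch_loss = epoch_loss,
                           step_loss = NULL,
                           final_loss = if (length(epoch_loss)) utils::tail(epoch_loss, 1) else NA_real_,
                           steps = steps,
                           metrics = list(holdout_accuracy = hold_acc,
                                          holdout_n = length(hold))),
                      class = "sclm_report")
  list(model = state, report = report)
}

#' Stage-2 cell-type annotation pretraining
#'
#' Attaches a linear classifier to the pooled cell embedding and trains it
#' (jointly with the encoder unless `cfg$freeze_encoder`) by cross-entropy,
#' leveraging the representations learned in the MLM stage when `init` is a
#' stage-1 model. A stratified held-out split tracks accuracy per epoch.
#'
#' @param corpus labeled [tokenize_corpus()] result (cell_type required).
#' @param cfg an [train_config()] with `stage = "annotate"`.
#' @param init an `sclm_model` (typically stage-1 pretrained); a fresh
#'   randomly initialized model is created when `NULL`, which is the
#'   no-MLM control.
#' @param model_cfg optional [model_config()] when `init` is `NULL`.
#' @return list with `model` and `report` (per-epoch loss and held-out
#'   accuracy).
#' @export
pretrain_annotation <- function(corpus, cfg, init = NULL, model_cfg = NULL) {
  stopifnot(inherits(corpus, "sclm_corpus"), cfg$stage == "annotate")
  state <- init %||% {
    mc <- model_cfg %||% model_config(n_gene_tokens = vocab_size(corpus$vocab),
                                      n_value_tokens = n_value_tokens(corpus$n_bins))
    model_init(mc, seed = cfg$seed, vocab = corpus$vocab, n_bins = corpus$n_bins)
  }
  res <- train_classifier(state, corpus, cfg)
  res$model$trained <- c(res$model$trained, "annotate")
  res
}

#' Fine-tune a pretrained model on a small labeled corpus
#'
#' New labels extend the classifier head (old-class weights preserved at
#' init); the encoder is warm-started from `state`. The report carries
#' zero-shot (before) and fine-tuned (after) accuracy on a held-out slice.
#'
#' @param state a pretrained `sclm_model` with a classifier head.
#' @param corpus labeled [tokenize_corpus()] result, tokenized with the
#'   model's vocabulary.
#' @param cfg an [train_config()] with `stage = "finetune"`.
#' @return list with `model` and `report`.
#' @export
fine_tune <- function(state, corpus, cfg) {
  stopifnot(inherits(state, "sclm_model"), cfg$stage == "finetune")
  if (!length(intersect(vocab_genes(state$vocab %||% corpus$vocab),
                        vocab_genes(corpus$vocab))))
    stop2("corpus vocabulary has no overlap with the model's vocabulary")
  hold <- stratified_indices(corpus$cell_type, cfg$holdout_frac,
                             derive_seed(cfg$seed, 7L))
  before <- if (length(hold) && !is.null(state$params$cls_W)) {
    pr <- model_predict(state, subset_corpus(corpus, hold), cfg$batch_size)
    mean(pr$label == corpus$cell_type[hold])
  } else NA_real_
  res <- train_classifier(state, corpus, cfg)
  res$model$trained <- c(res$model$trained, "finetune")
  res$report$metrics$accuracy_before <- before
  res$report$metrics$accuracy_after <-
    if (length(res$report$metrics$holdout_accuracy))
      utils::tail(res$report$metrics$holdout_accuracy, 1) else NA_real_
  res
}

#' Transfer a pretrained model to a new species' vocabulary
#'
#' Re-initializes the gene-id embedding table for the new vocabulary while
#' retaining the encoder, the value-bin embedding table (bins are
#' species-agnostic) and the output heads, ready for further pretraining or
#' fine-tuning on the new species.
#'
#' @param state a pretrained `sclm_model`.
#' @param new_vocab an [build_vocabulary()] object for the new species.
#' @param seed seed for the fresh gene-embedding table.
#' @return the transferred `sclm_model`.
#' @export
transfer_species <- function(state, new_vocab, seed = 1L) {
  stopifnot(inherits(state, "sclm_model"), inherits(new_vocab, "sclm_vocab"))
  set.seed(derive_seed(seed, 13L))
  state$config$n_gene_tokens <- vocab_size(new_vocab)
  state$params$E_id <- rand_mat(vocab_size(new_vocab), state$config$d_model)
  state$vocab <- new_vocab
  state$trained <- c(state$trained, "transfer")
  state
}

# batched evaluation forward: labels (if head present), confidences, embeddings
model_predict <- function(state, corpus, batch_size = 64L, embeddings = FALSE) {
  n <- n_cells(corpus)
  labs <- character(0); conf <- numeric(0)
  emb <- if (embeddings) vector("list", 0L)
  for (chunk in batch_indices(n, batch_size)) {
    bt <- pad_batch(corpus$sentences[chunk], n_bins = corpus$n_bins)
    out <- sclm_forward(state, bt,
                        heads = if (is.null(state$params$cls_W)) character(0) else "class")
    if (!is.null(out$class_logits)) {
      sm <- row_softmax(out$class_logits)
      k <- max.col(sm, ties.method = "first")
      labs <- c(labs, state$classes[k])
      conf <- c(conf, sm[cbind(seq_along(k), k)])
    }
    if (embeddings) emb[[length(emb) + 1L]] <- out$cell_embedding
  }
  list(label = labs, confidence = conf,
       embedding = if (embeddings) do.call(rbind, emb))
}

#' Predict from a fitted cell-sentence model
#'
#' @param object an `sclm_model`.
#' @param newdata an `sclm_corpus` (tokenized with the model's vocabulary)
#'   or an `sclm_expr` of raw counts (tokenized internally; genes absent
#'   from the model's vocabulary are dropped).
#' @param type `"class"` (predicted label + confidence), `"prob"` is the
#'   same with `confidence` only, or `"embedding"` (cell embeddings).
#' @param batch_size evaluation batch size.
#' @param ... ignored.
#' @return data.frame (class) or numeric matrix (embedding).
#' @export
predict.sclm_model <- function(object, newdata, type = c("class", "embedding"),
                               batch_size = 64L, ...) {
  type <- match.arg(type)
  corpus <- if (inherits(newdata, "sclm_corpus")) newdata else
    tokenize_corpus(newdata, vocab = object$vocab, n_bins = object$n_bins %||% 51L,
                    max_len = object$config$max_len)
  pr <- model_predict(object, corpus, batch_size, embeddings = type == "embedding")
  if (type == "embedding") return(pr$embedding)
  if (!length(pr$label)) stop2("model has no classifier head; use type = 'embedding'")
  data.frame(barcode = corpus$cell_ids, predicted = pr$label,
             confidence = pr$confidence, stringsAsFactors = FALSE)
}
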