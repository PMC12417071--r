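#' Desk-scale calibration protocol
#'
#' The package's standard reference experiment on the
#' [calibration_config()] corpus: train/evaluate the full sequential
#' pipeline at desk scale and measure the quantities the test suite and the
#' acceptance script assert. One batch of the two-batch corpus is held out
#' entirely; the other is used for the two pretraining stages.
#'
#' Protocol (all seeded from `seed`):
#' 1. Stage 1: masked-value MLM, 5 epochs.
#' 2. Stage 2 "warm": annotation pretraining initialized from stage 1.
#' 3. Stage 2 "cold": identical run from random initialization (the
#'    sequential-pretraining control).
#' 4. Zero-shot annotation of the held-out batch with the warm model.
#' 5. Masked-MSE comparison against the constant mean-bin predictor on a
#'    freshly masked pass over the training corpus.
#' 6. Integration benchmark (ARI/NMI/SIL over a Louvain resolution sweep)
#'    of the held-out-batch embeddings.
#'
#' The encoder used here is the desk-scale one (2 layers, 4 heads,
#' d_model 32, mean pooling); training uses learning rate 1e-3 because a
#' 2000-cell corpus yields only a few hundred optimizer steps (the
#' config *defaults* remain batch 64 / lr 1e-4).
#'
#' @param seed integer seed for the whole study.
#' @param resolutions benchmark resolution grid.
#' @return list with `mlm` (stage-1 report), `baseline_mse`, `model_mse`,
#'   `warm`, `cold` (stage-2 results), `warm_accuracy`, `cold_accuracy`,
#'   `zero_shot` (labels), `zero_shot_accuracy`, `benchmark`, and the
#'   trained `model`.
#' @export
calibration_study <- function(seed = 7L, resolutions = seq(0.2, 1.2, by = 0.2)) {
  syn <- generate_corpus(calibration_config(seed))
  hold_batch <- sort(unique(syn$expr$batch))[1L]
  train_expr <- syn$expr[syn$expr$batch != hold_batch, ]
  test_expr <- syn$expr[syn$expr$batch == hold_batch, ]
  corpus <- tokenize_corpus(train_expr, n_bins = 51L, max_len = 101L)
  mc <- calibration_encoder(corpus$vocab)

  s1 <- pretrain_mlm(corpus, calibration_train("mlm", seed), model_cfg = mc)

  # constant mean-bin baseline on an independently masked pass
  bt <- pad_batch(corpus$sentences, n_bins = corpus$n_bins)
  mb <- apply_mask(bt, rate = 0.15, seed = derive_seed(seed, 421L))
  targ <- masked_targets_vec(mb)
  baseline_mse <- mean((targ - mean(targ))^2)
  out <- sclm_forward(s1$model, mb, heads = "mlm")
  model_mse <- mse_masked_loss(predict_masked_values(out, mb$mask_flags), targ)

  warm <- pretrain_annotation(corpus, calibration_train("annotate", seed),
                              init = s1$model)
  cold <- pretrain_annotation(corpus, calibration_train("annotate", seed),
                              model_cfg = mc)

  zs <- zero_shot_annotate(warm$model, test_expr)
  zs_acc <- mean(zs$predicted == zs$reference)
  emb <- predict(warm$model, test_expr, type = "embedding")
  bench <- benchmark(emb, test_expr$cell_type, resolutions, seed = seed)

  list(mlm = s1$report, baseline_mse = baseline_mse, model_mse = model_mse,
       warm = warm$report, cold = cold$report,
       warm_accuracy = utils::tail(warm$report$metrics$holdout_accuracy, 1),
       cold_accuracy = utils::tail(cold$report$metrics$holdout_accuracy, 1),
       zero_shot = zs, zero_shot_accuracy = zs_acc, benchmark = bench,
       model = warm$model, stage1 = s1$model)
}

#' @rdname calibration_study
#' @param vocab vocabulary for the encoder tables.
#' @param n_bins,max_len tokenizer geometry of the calibration runs.
#' @export
calibration_encoder <- function(vocab, n_bins = 51L, max_len = 101L) {
  model_config(n_gene_tokens = vocab_size(vocab),
               n_value_tokens = n_value_tokens(n_bins),
               n_layers = 2L, n_heads = 4L, d_model = 32L,
               max_len = max_len, pooling = "mean")
}

#' @rdname calibration_study
#' @param stage `"mlm"` or `"annotate"`.
#' @export
calibration_train <- function(stage, seed) {
  if (stage == "mlm")
    train_config("mlm", epochs = 5L, batch_size = 64L, learning_rate = 1e-3,
                 seed = seed, max_len = 101L)
  else
    train_config("annotate", epochs = 8L, batch_size = 32L,
                 learning_rate = 3e-3, seed = seed, max_len = 101L)
}

#' Attention module-recovery study
#'
#' Generates a corpus with four independently co-activated 15-gene modules
#' (rho = 0.8), pretrains the desk-scale encoder with the masked-value
#' objective, averages normalized attention over 100 cells, and scores how
#' well within-module gene pairs rank above module-by-background pairs
#' (Mann-Whitney AUC), once per seed.
#'
#' @param seeds integer seeds, one study per seed.
#' @param epochs MLM epochs per study.
#' @return list with per-seed `auc`, `margin` (mean within minus mean
#'   between attention) and their means.
#' @export
module_recovery_study <- function(seeds = 1:10, epochs = 4L) {
  auc <- margin <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    seed <- seeds[i]
    syn <- generate_corpus(module_recovery_config(seed))
    corpus <- tokenize_corpus(syn$expr, n_bins = 51L, max_len = 61L)
    mc <- model_config(n_gene_tokens = vocab_size(corpus$vocab),
                       n_value_tokens = n_value_tokens(51L),
                       n_layers = 1L, n_heads = 2L, d_model = 32L,
                       max_len = 61L, pooling = "mean")
    s1 <- pretrain_mlm(corpus,
                       train_config("mlm", epochs = epochs, batch_size = 32L,
                                    learning_rate = 3e-3, seed = seed,
                                    max_len = 61L), model_cfg = mc)
    av <- average_attention(s1$model, corpus$sentences[seq_len(100L)])
    g <- rownames(av$scores)
    memb <- rep(NA_integer_, length(g))
    names(memb) <- g
    mods <- truth_labels(syn)$modules
    for (m in seq_along(mods)) memb[intersect(mods[[m]]$genes, g)] <- m
    ut <- which(upper.tri(av$scores), arr.ind = TRUE)
    same <- !is.na(memb[ut[, 1]]) & !is.na(memb[ut[, 2]]) &
      memb[ut[, 1]] == memb[ut[, 2]]
    cross <- !(is.na(memb[ut[, 1]]) & is.na(memb[ut[, 2]])) & !same
    sc <- av$scores[upper.tri(av$scores)]
    ok <- !is.na(sc)
    auc[i] <- rank_auc(sc[same & ok], sc[cross & ok])
    margin[i] <- mean(sc[same & ok]) - mean(sc[cross & ok])
  }
  list(auc = auc, margin = margin, mean_auc = mean(auc),
       mean_margin = mean(margin))
}

#' @rdname module_recovery_study
#' @param seed generator seed.
#' @export
module_recovery_config <- function(seed) {
  synth_config(n_cells = 300L, n_genes = 80L, n_types = 2L,
               markers_per_type = 5L, marker_fold = 3, n_batches = 1L,
               batch_scale_sd = 0,
               modules = lapply(0:3, function(m)
                 list(genes = 21L + m * 15L + 0:14, rho = 0.8)),
               library_size_mean = 250, dispersion = 0.5, seed = seed)
}
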