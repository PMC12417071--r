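#' Pipeline configuration
#'
#' Bundles the stage configurations of an end-to-end run: synthesize (or
#' load) a corpus, preprocess/tokenize, pretrain (MLM then annotation),
#' zero-shot annotate a held-out slice, benchmark the embeddings, build an
#' attention network and discover gene programs.
#'
#' @param seed global seed; every stage derives its randomness from it.
#' @param synth an [synth_config()] (default: the calibration corpus with
#'   this seed).
#' @param n_bins,max_len tokenizer settings.
#' @param d_model,n_layers,n_heads encoder size for the run (desk-scale
#'   defaults; the architecture defaults of [model_config()] remain
#'   6 layers / 8 heads).
#' @param mlm_epochs,annot_epochs,learning_rate training lengths and rate.
#' @param resolutions benchmark resolution grid.
#' @param grn_hubs,grn_k,grn_depth network settings.
#' @return an object of class `sclm_pipeline_config`.
#' @export
pipeline_config <- function(seed = 7L, synth = calibration_config(seed),
                            n_bins = 51L, max_len = 101L,
                            d_model = 32L, n_layers = 2L, n_heads = 4L,
                            mlm_epochs = 5L, annot_epochs = 4L,
                            learning_rate = 1e-3,
                            resolutions = seq(0.2, 1.2, by = 0.2),
                            grn_hubs = 2L, grn_k = 5L, grn_depth = 2L) {
  structure(list(seed = as.integer(seed), synth = synth, n_bins = n_bins,
                 max_len = max_len, d_model = d_model, n_layers = n_layers,
                 n_heads = n_heads, mlm_epochs = mlm_epochs,
                 annot_epochs = annot_epochs, learning_rate = learning_rate,
                 resolutions = resolutions, grn_hubs = grn_hubs,
                 grn_k = grn_k, grn_depth = grn_depth),
            class = "sclm_pipeline_config")
}

config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 251 + 1)) %% .Machine$integer.max)
}

#' Run the full pipeline
#'
#' Executes synth -> preprocess -> MLM pretraining -> annotation pretraining
#' -> zero-shot annotation of the held-out batch -> integration benchmark ->
#' attention network -> gene programs, writing every artifact plus a
#' manifest (JSON listing artifacts and the config hash) into `out_dir`.
#'
#' @param cfg an [pipeline_config()].
#' @param out_dir output directory.
#' @return list with the fitted model, reports and artifact paths,
#'   invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir) {
  stopifnot(inherits(cfg, "sclm_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop2(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e))))
  }
  hash <- config_hash(cfg)
  artifacts <- character(0)
  put <- function(f) { artifacts <<- c(artifacts, f); f }

  synth <- stage("synth", function() generate_corpus(cfg$synth))
  write_expression(synth$expr, put(file.path(out_dir, "corpus")))

  # hold out one batch for zero-shot evaluation; train on the rest
  hold_batch <- sort(unique(synth$expr$batch))[1L]
  train_expr <- synth$expr[synth$expr$batch != hold_batch, ]
  test_expr <- synth$expr[synth$expr$batch == hold_batch, ]

  corpus <- stage("preprocess", function()
    tokenize_corpus(train_expr, n_bins = cfg$n_bins, max_len = cfg$max_len))
  save_vocabulary(corpus$vocab, put(file.path(out_dir, "vocab.json")))

  mc <- model_config(n_gene_tokens = vocab_size(corpus$vocab),
                     n_value_tokens = n_value_tokens(cfg$n_bins),
                     n_layers = cfg$n_layers, n_heads = cfg$n_heads,
                     d_model = cfg$d_model, max_len = cfg$max_len)
  s1 <- stage("pretrain_mlm", function()
    pretrain_mlm(corpus, train_config("mlm", epochs = cfg$mlm_epochs,
                                      learning_rate = cfg$learning_rate,
                                      seed = cfg$seed, max_len = cfg$max_len),
                 model_cfg = mc))
  save_model(s1$model, put(file.path(out_dir, "stage1.rds")))

  s2 <- stage("pretrain_annotation", function()
    pretrain_annotation(corpus, train_config("annotate", epochs = cfg$annot_epochs,
                                             learning_rate = cfg$learning_rate,
                                             seed = cfg$seed, max_len = cfg$max_len),
                        init = s1$model))
  save_model(s2$model, put(file.path(out_dir, "stage2.rds")))

  labels <- stage("annotate", function() zero_shot_annotate(s2$model, test_expr))
  utils::write.table(as.data.frame(labels), put(file.path(out_dir, "labels.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  conf <- confusion(labels)
  write_confusion(conf, put(file.path(out_dir, "confusion.tsv")))

  bench <- stage("benchmark", function() {
    emb <- predict(s2$model, test_expr, type = "embedding")
    benchmark(emb, test_expr$cell_type, cfg$resolutions, seed = cfg$seed)
  })
  jsonlite::write_json(list(config_hash = hash, accuracy = conf$accuracy,
                            best = as.list(bench$best), curves = bench$curves,
                            sil = bench$sil),
                       put(file.path(out_dir, "report.json")),
                       auto_unbox = TRUE, digits = NA)

  net <- stage("grn", function() {
    sent <- corpus$sentences[[1L]]
    att <- cell_attention_matrix(s2$model, sent, cell_id = corpus$cell_ids[1L])
    expand_network(att, select_hubs(att, cfg$grn_hubs), k = cfg$grn_k,
                   depth = cfg$grn_depth)
  })
  export_network(net, put(file.path(out_dir, "network.graphml")))
  export_network(net, put(file.path(out_dir, "network_edges.tsv")))

  progs <- stage("programs", function() {
    emb <- extract_gene_embeddings(s2$model)
    cluster_programs(emb, seed = cfg$seed)
  })
  act <- program_activity(progs, synth$expr)
  write_programs(progs, act, put(file.path(out_dir, "programs")))

  manifest <- list(config_hash = hash,
                   artifacts = lapply(artifacts, function(f)
                     list(path = basename(f), config_hash = hash)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(model = s2$model, mlm_report = s1$report,
                 annot_report = s2$report, labels = labels, confusion = conf,
                 benchmark = bench, network = net, programs = progs,
                 activity = act, out_dir = out_dir, config_hash = hash))
}
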