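# Shared fixtures, all built in code.

# small deterministic count matrix with names
tiny_counts <- function(n_cells = 3L, n_genes = 4L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_genes, 3), n_cells, n_genes,
              dimnames = list(paste0("c", seq_len(n_cells)),
                              paste0("g", seq_len(n_genes))))
  m
}

tiny_expr <- function(...) expression_matrix(tiny_counts(...))

# small random corpus + untrained model, for shape/determinism tests
tiny_model_fixture <- function(n_cells = 8L, n_genes = 30L, n_layers = 2L,
                               n_heads = 2L, d_model = 8L, n_bins = 11L,
                               max_len = 20L, n_classes = 0L, seed = 11L) {
  syn <- generate_corpus(synth_config(
    n_cells = n_cells, n_genes = n_genes, n_types = 2L, markers_per_type = 3L,
    marker_fold = 3, n_batches = 1L, batch_scale_sd = 0,
    library_size_mean = 80, dispersion = 0.4, seed = seed))
  corp <- tokenize_corpus(syn$expr, n_bins = n_bins, max_len = max_len)
  mc <- model_config(n_gene_tokens = length(corp$vocab$gene_to_token) + 3L,
                     n_value_tokens = n_bins + 3L, n_layers = n_layers,
                     n_heads = n_heads, d_model = d_model,
                     n_classes = n_classes, max_len = max_len)
  model <- model_init(mc, seed = seed, vocab = corp$vocab, n_bins = n_bins)
  if (n_classes > 0L) model$classes <- paste0("type", seq_len(n_classes))
  list(syn = syn, corpus = corp, model = model, config = mc)
}

# the desk-scale encoder used by cheap training tests (the calibration
# protocol itself lives in the package: calibration_encoder/_train)
calib_model_config <- function(vocab, n_bins = 51L, max_len = 101L) {
  calibration_encoder(vocab, n_bins, max_len)
}
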