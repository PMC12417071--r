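test_that("token embedding is the elementwise sum of the two tables", {
  fx <- tiny_model_fixture(d_model = 2, n_layers = 1, n_heads = 1)
  m <- fx$model
  # zero tables -> zero embeddings
  m0 <- m
  m0$params$E_id[] <- 0; m0$params$E_expr[] <- 0
  gt <- matrix(c(1L, 4L), 1); vb <- matrix(c(11L, 3L), 1)
  expect_true(all(embed_tokens(gt, vb, m0) == 0))
  # hand-set toy tables: E_id[g] = (1,0), E_expr[b] = (0,2) -> token (1,2)
  m1 <- m0
  m1$params$E_id[5, ] <- c(1, 0)    # token id 4 (0-based)
  m1$params$E_expr[4, ] <- c(0, 2)  # value id 3
  expect_equal(embed_tokens(matrix(4L), matrix(3L), m1)[1, ], c(1, 2))
  # channels are distinct unless the tables happen to agree
  swapped <- embed_tokens(matrix(3L), matrix(4L), m1)
  expect_false(isTRUE(all.equal(swapped, embed_tokens(matrix(4L), matrix(3L), m1))))
  expect_error(embed_tokens(matrix(999L), matrix(0L), m), "out of range")
})

test_that("eval-mode forward is deterministic and duplicate cells agree", {
  fx <- tiny_model_fixture()
  s <- fx$corpus$sentences[[1]]
  b <- pad_batch(list(s, fx$corpus$sentences[[2]], s), n_bins = fx$corpus$n_bins)
  out <- sclm_forward(fx$model, b)
  expect_equal(out$cell_embedding[1, ], out$cell_embedding[3, ])
  out2 <- sclm_forward(fx$model, b)
  expect_identical(out$token_states, out2$token_states)
})

test_that("default architecture instantiates 6 layers of 8 heads and exposes all attention maps", {
  cfg <- model_config(n_gene_tokens = 20, n_value_tokens = 10)
  expect_equal(cfg$n_layers, 6L)
  expect_equal(cfg$n_heads, 8L)
  m <- model_init(cfg, seed = 1)
  expect_length(grep("^L[0-9]+_Wq$", names(m$params)), 6L)
  v <- build_vocabulary(sprintf("g%02d", 1:17))
  bins <- c(rep(3L, 10), rep(0L, 7)); names(bins) <- sprintf("g%02d", 1:17)
  s <- encode_cell(bins, v, max_len = 12, n_bins = 7)
  b <- pad_batch(list(s), n_bins = 7)
  out <- sclm_forward(m, b, return_attentions = TRUE)
  expect_length(out$attentions, 6L)
  expect_equal(dim(out$attentions[[1]][[1]]), c(8L, 11L, 11L))
})

test_that("attention rows are stochastic over valid keys with zero mass on PAD", {
  fx <- tiny_model_fixture(n_cells = 6)
  b <- pad_batch(fx$corpus$sentences[1:6], n_bins = fx$corpus$n_bins)
  out <- sclm_forward(fx$model, b, return_attentions = TRUE)
  for (l in seq_along(out$attentions)) for (i in seq_len(6)) {
    A <- out$attentions[[l]][[i]]
    pads <- which(b$pad_flags[i, ])
    for (h in seq_len(dim(A)[1])) {
      expect_equal(rowSums(A[h, , ]), rep(1, ncol(b$gene_tokens)),
                   tolerance = 1e-5)
      if (length(pads)) expect_true(all(A[h, , pads] == 0))
    }
  }
})

test_that("a 1-layer 1-head model reproduces hand-computed attention", {
  fx <- tiny_model_fixture(n_layers = 1, n_heads = 1, d_model = 4)
  m <- fx$model
  s <- fx$corpus$sentences[[1]]
  b <- pad_batch(list(s), n_bins = fx$corpus$n_bins)
  out <- sclm_forward(m, b, return_attentions = TRUE)
  # independent linear-algebra oracle
  p <- m$params
  X <- p$E_id[as.vector(b$gene_tokens) + 1, ] + p$E_expr[as.vector(b$value_bins) + 1, ]
  ln <- t(apply(X, 1, function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2) + 1e-5)))
  h <- sweep(ln %*% diag(p$L1_ln1_g), 2, p$L1_ln1_b, "+")
  Q <- sweep(h %*% p$L1_Wq, 2, p$L1_bq, "+")
  K <- sweep(h %*% p$L1_Wk, 2, p$L1_bk, "+")
  S <- Q %*% t(K) / sqrt(4)
  A <- t(apply(S, 1, function(r) exp(r - max(r)) / sum(exp(r - max(r)))))
  expect_equal(out$attentions[[1]][[1]][1, , ], A, tolerance = 1e-10)
})

test_that("cell embedding is order-invariant within a sentence", {
  fx <- tiny_model_fixture()
  s <- fx$corpus$sentences[[1]]
  perm <- c(1L, 1L + sample(s$length - 1L))
  s2 <- structure(list(gene_tokens = s$gene_tokens[perm],
                       value_bins = s$value_bins[perm],
                       genes = s$genes[perm[-1] - 1L], length = s$length),
                  class = "sclm_sentence")
  b <- pad_batch(list(s, s2), n_bins = fx$corpus$n_bins)
  out <- sclm_forward(fx$model, b)
  expect_equal(out$cell_embedding[1, ], out$cell_embedding[2, ], tolerance = 1e-10)
})

test_that("masked-value head has the contracted shape and order", {
  fx <- tiny_model_fixture()
  b <- pad_batch(fx$corpus$sentences[1:3], n_bins = fx$corpus$n_bins)
  mb <- apply_mask(b, 0.4, seed = 2)
  out <- sclm_forward(fx$model, mb, heads = "mlm")
  preds <- predict_masked_values(out, mb$mask_flags)
  expect_length(preds, sum(mb$mask_flags))
  expect_true(all(is.finite(preds)))
  # scan order: predictions follow cell-major position order
  k <- 0L
  for (i in seq_len(3)) for (j in seq_len(ncol(mb$mask_flags)))
    if (mb$mask_flags[i, j]) {
      k <- k + 1L
      expect_equal(preds[k], out$mlm_pred[i, j])
    }
  expect_error(predict_masked_values(out, mb$mask_flags & FALSE), "no masked")
})

test_that("classifier head emits logits that softmax to 1 and match an affine oracle", {
  fx <- tiny_model_fixture(n_classes = 5)
  b <- pad_batch(fx$corpus$sentences[1:4], n_bins = fx$corpus$n_bins)
  out <- sclm_forward(fx$model, b, heads = "class")
  lg <- classify(out, fx$model)
  expect_equal(dim(lg), c(4L, 5L))
  sm <- exp(lg) / rowSums(exp(lg))
  expect_equal(unname(rowSums(sm)), rep(1, 4))
  oracle <- sweep(out$cell_embedding %*% fx$model$params$cls_W, 2,
                  fx$model$params$cls_b, "+")
  dimnames(oracle) <- NULL
  expect_equal(unname(lg), oracle)
  no_head <- tiny_model_fixture()$model
  out2 <- sclm_forward(no_head, b, heads = "class")
  expect_error(classify(out2, no_head), "absent")
})

test_that("zeroed value table makes output a function of gene identity only", {
  fx <- tiny_model_fixture()
  m <- fx$model
  m$params$E_expr[] <- 0
  s <- fx$corpus$sentences[[1]]
  s2 <- s
  s2$value_bins <- c(s$value_bins[1], rev(s$value_bins[-1]))
  b <- pad_batch(list(s, s2), n_bins = fx$corpus$n_bins)
  out <- sclm_forward(m, b)
  expect_equal(out$cell_embedding[1, ], out$cell_embedding[2, ], tolerance = 1e-12)
})

test_that("checkpoints reload to bit-identical forwards and refuse foreign vocabularies", {
  fx <- tiny_model_fixture()
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(fx$model, f)
  back <- load_model(f, vocab = fx$corpus$vocab)
  b <- pad_batch(fx$corpus$sentences[1:2], n_bins = fx$corpus$n_bins)
  expect_identical(sclm_forward(fx$model, b)$token_states,
                   sclm_forward(back, b)$token_states)
  other <- build_vocabulary(c("x1", "x2"))
  expect_error(load_model(f, vocab = other), "vocabulary mismatch")
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(oops = 1), bad)
  expect_error(load_model(bad), "corrupted checkpoint")
})

test_that("analytic gradients match finite differences on a tiny model", {
  fx <- tiny_model_fixture(n_cells = 4, n_layers = 2, n_heads = 2, d_model = 8,
                           n_classes = 2, max_len = 12)
  m <- fx$model
  b <- pad_batch(fx$corpus$sentences[1:3], n_bins = fx$corpus$n_bins)
  mb <- apply_mask(b, 0.3, seed = 5)
  y <- c(1L, 2L, 1L)
  loss_fn <- function(state) {
    out <- sclm_forward(state, mb, heads = c("mlm", "class"), train = TRUE)
    tt <- t(mb$value_targets)
    targ <- as.numeric(tt[!is.na(tt)]) / (mb$n_bins - 1)
    mse_masked_loss(predict_masked_values(out, mb$mask_flags), targ) +
      cross_entropy_loss(out$class_logits, y)
  }
  out <- sclm_forward(m, mb, heads = c("mlm", "class"), train = TRUE)
  tt <- t(mb$value_targets)
  targ <- as.numeric(tt[!is.na(tt)]) / (mb$n_bins - 1)
  pr <- predict_masked_values(out, mb$mask_flags)
  err <- 2 * (pr - targ) / length(targ)
  dmT <- matrix(0, ncol(mb$gene_tokens), nrow(mb$gene_tokens))
  dmT[t(mb$mask_flags)] <- err
  sm <- exp(out$class_logits - apply(out$class_logits, 1, max))
  sm <- sm / rowSums(sm)
  sm[cbind(1:3, y)] <- sm[cbind(1:3, y)] - 1
  g <- sclm:::sclm_backward(m, out, d_mlm = t(dmT), d_logits = sm / 3)
  set.seed(77)
  eps <- 1e-5
  for (nm in c("E_id", "E_expr", "L1_Wq", "L1_W1", "L2_Wo", "lnf_g",
               "mlm_W1", "mlm_W2", "cls_W")) {
    w <- m$params[[nm]]
    for (i in sample(length(w), 2)) {
      mp <- m; mp$params[[nm]][i] <- w[i] + eps
      mm <- m; mm$params[[nm]][i] <- w[i] - eps
      num <- (loss_fn(mp) - loss_fn(mm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})
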