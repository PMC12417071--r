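# Reverse-mode gradients for the encoder and its heads. Parameters are a
# flat named list, so gradients are returned in the same shape. Only the
# loss heads actually used contribute: pass d_mlm (batch x len matrix of
# dLoss/dPrediction, zeros off-mask) and/or d_logits (batch x n_classes).
sclm_backward <- function(state, out, d_mlm = NULL, d_logits = NULL) {
  cfg <- state$config
  p <- state$params
  cache <- out$cache
  if (is.null(cache)) stop2("forward pass was not run with train = TRUE")
  B <- cache$B; L <- cache$L; N <- B * L
  d <- cfg$d_model; H <- cfg$n_heads; dk <- d %/% H
  g <- lapply(p, function(w) if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else numeric(length(w)))

  Xf <- out$token_states
  dXf <- matrix(0, N, d)

  if (!is.null(d_mlm)) {
    dP <- matrix(as.vector(t(d_mlm)), ncol = 1L)
    g$mlm_W2 <- g$mlm_W2 + t(cache$mlm_Am) %*% dP
    g$mlm_b2 <- g$mlm_b2 + sum(dP)
    dAm <- dP %*% t(p$mlm_W2)
    dHm <- dAm * gelu_grad(cache$mlm_Hm)
    g$mlm_W1 <- g$mlm_W1 + t(Xf) %*% dHm
    g$mlm_b1 <- g$mlm_b1 + colSums(dHm)
    dXf <- dXf + dHm %*% t(p$mlm_W1)
  }
  if (!is.null(d_logits)) {
    emb <- out$cell_embedding
    g$cls_W <- g$cls_W + t(emb) %*% d_logits
    g$cls_b <- g$cls_b + colSums(d_logits)
    dcell <- d_logits %*% t(p$cls_W)
    if (cfg$pooling == "cls") {
      rows <- (seq_len(B) - 1L) * L + 1L
      dXf[rows, ] <- dXf[rows, ] + dcell
    } else {
      np <- !as.vector(t(out$pad_flags))
      lens <- rowSums(!out$pad_flags)
      spread <- dcell[rep(seq_len(B), each = L), , drop = FALSE] /
        lens[rep(seq_len(B), each = L)]
      spread[!np, ] <- 0
      dXf <- dXf + spread
    }
  }

  r <- layernorm_bwd(dXf, cache$lnf, p$lnf_g)
  g$lnf_g <- g$lnf_g + r$dg
  g$lnf_b <- g$lnf_b + r$db
  dX <- r$dx

  for (l in rev(seq_len(cfg$n_layers))) {
    pre <- paste0("L", l, "_")
    lc <- cache$layers[[l]]
    # feed-forward branch: X_out = x_mid + f(ln2(x_mid))
    d_f <- if (!is.null(lc$drop2)) dX * lc$drop2 else dX
    g[[paste0(pre, "W2")]] <- g[[paste0(pre, "W2")]] + t(lc$a) %*% d_f
    g[[paste0(pre, "b2")]] <- g[[paste0(pre, "b2")]] + colSums(d_f)
    da <- d_f %*% t(p[[paste0(pre, "W2")]])
    du <- da * gelu_grad(lc$u)
    g[[paste0(pre, "W1")]] <- g[[paste0(pre, "W1")]] + t(lc$ln2$y) %*% du
    g[[paste0(pre, "b1")]] <- g[[paste0(pre, "b1")]] + colSums(du)
    r2 <- layernorm_bwd(du %*% t(p[[paste0(pre, "W1")]]), lc$ln2, p[[paste0(pre, "ln2_g")]])
    g[[paste0(pre, "ln2_g")]] <- g[[paste0(pre, "ln2_g")]] + r2$dg
    g[[paste0(pre, "ln2_b")]] <- g[[paste0(pre, "ln2_b")]] + r2$db
    dX_mid <- dX + r2$dx
    # attention branch: x_mid = x_in + attn(ln1(x_in))
    d_attn <- if (!is.null(lc$drop1)) dX_mid * lc$drop1 else dX_mid
    g[[paste0(pre, "Wo")]] <- g[[paste0(pre, "Wo")]] + t(lc$O) %*% d_attn
    g[[paste0(pre, "bo")]] <- g[[paste0(pre, "bo")]] + colSums(d_attn)
    dO <- d_attn %*% t(p[[paste0(pre, "Wo")]])
    dQ <- matrix(0, N, d); dK <- matrix(0, N, d); dV <- matrix(0, N, d)
    for (b in seq_len(B)) {
      idx <- ((b - 1L) * L + 1L):(b * L)
      for (hd in seq_len(H)) {
        cols <- ((hd - 1L) * dk + 1L):(hd * dk)
        A <- lc$A[[b]][hd, , ]
        dOh <- dO[idx, cols, drop = FALSE]
        dA <- dOh %*% t(lc$V[idx, cols, drop = FALSE])
        dV[idx, cols] <- dV[idx, cols] + t(A) %*% dOh
        dS <- A * (dA - rowSums(dA * A))
        dQ[idx, cols] <- dQ[idx, cols] + dS %*% lc$K[idx, cols, drop = FALSE] / sqrt(dk)
        dK[idx, cols] <- dK[idx, cols] + t(dS) %*% lc$Q[idx, cols, drop = FALSE] / sqrt(dk)
      }
    }
    h <- lc$h
    g[[paste0(pre, "Wq")]] <- g[[paste0(pre, "Wq")]] + t(h) %*% dQ
    g[[paste0(pre, "Wk")]] <- g[[paste0(pre, "Wk")]] + t(h) %*% dK
    g[[paste0(pre, "Wv")]] <- g[[paste0(pre, "Wv")]] + t(h) %*% dV
    g[[paste0(pre, "bq")]] <- g[[paste0(pre, "bq")]] + colSums(dQ)
    g[[paste0(pre, "bk")]] <- g[[paste0(pre, "bk")]] + colSums(dK)
    g[[paste0(pre, "bv")]] <- g[[paste0(pre, "bv")]] + colSums(dV)
    dh <- dQ %*% t(p[[paste0(pre, "Wq")]]) + dK %*% t(p[[paste0(pre, "Wk")]]) +
      dV %*% t(p[[paste0(pre, "Wv")]])
    r1 <- layernorm_bwd(dh, lc$ln1, p[[paste0(pre, "ln1_g")]])
    g[[paste0(pre, "ln1_g")]] <- g[[paste0(pre, "ln1_g")]] + r1$dg
    g[[paste0(pre, "ln1_b")]] <- g[[paste0(pre, "ln1_b")]] + r1$db
    dX <- dX_mid + r1$dx
  }

  gid <- as.vector(t(cache$gt)) + 1L
  rs <- rowsum(dX, gid)
  ids <- as.integer(rownames(rs))
  g$E_id[ids, ] <- g$E_id[ids, ] + rs
  vid <- as.vector(t(cache$vb)) + 1L
  rs <- rowsum(dX, vid)
  ids <- as.integer(rownames(rs))
  g$E_expr[ids, ] <- g$E_expr[ids, ] + rs
  g
}

adam_init <- function(params) {
  zero <- lapply(params, function(w)
    if (is.matrix(w)) matrix(0, nrow(w), ncol(w)) else numeric(length(w)))
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (n in names(params)) {
    if (is.null(grads[[n]])) next
    opt$m[[n]] <- beta1 * opt$m[[n]] + (1 - beta1) * grads[[n]]
    opt$v[[n]] <- beta2 * opt$v[[n]] + (1 - beta2) * grads[[n]]^2
    params[[n]] <- params[[n]] -
      lr * (opt$m[[n]] / bc1) / (sqrt(opt$v[[n]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}
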