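# hand-built attention object for expansion tests
mk_att <- function(S, genes = sprintf("g%02d", seq_len(nrow(S)))) {
  dimnames(S) <- list(genes, genes)
  structure(list(genes = genes, scores = S, cell_id = "cell",
                 aggregation = "last_layer_mean_heads"),
            class = "sclm_attention")
}

test_that("per-cell attention matrices are normalized to [0,1], symmetric, deterministic", {
  fx <- tiny_model_fixture(n_cells = 4)
  s <- fx$corpus$sentences[[1]]
  att <- cell_attention_matrix(fx$model, s)
  expect_true(all(att$scores >= 0 & att$scores <= 1))
  expect_equal(att$scores, t(att$scores))
  expect_true(all(diag(att$scores) == 0))
  expect_true(any(att$scores == 0) && any(att$scores == 1))  # min-max attained
  att2 <- cell_attention_matrix(fx$model, s)
  expect_identical(att$scores, att2$scores)
  short <- structure(list(gene_tokens = c(1L, 4L), value_bins = c(11L, 3L),
                          genes = "gA", length = 2L), class = "sclm_sentence")
  expect_error(cell_attention_matrix(fx$model, short), "too short")
})

test_that("symmetrize-then-normalize maps a constant matrix to zeros", {
  # raw [[.,2],[4,.]] symmetrizes to a constant 3 -> all zeros by convention
  A <- matrix(c(0, 4, 2, 0), 2, 2)
  M <- (A + t(A)) / 2
  off <- row(M) != col(M)
  rng <- range(M[off])
  expect_equal(diff(rng), 0)
  S <- matrix(0, 2, 2)
  if (diff(rng) > 0) S[off] <- (M[off] - rng[1]) / diff(rng)
  expect_true(all(S == 0))
})

test_that("min-max normalization is invariant to positive rescaling of raw scores", {
  set.seed(6)
  fx <- tiny_model_fixture(n_cells = 2)
  att <- cell_attention_matrix(fx$model, fx$corpus$sentences[[1]])
  # rescaling the normalized matrix and renormalizing reproduces it
  for (c_ in c(0.1, 3, 200)) {
    M <- att$scores * c_
    off <- row(M) != col(M)
    rng <- range(M[off])
    S <- matrix(0, nrow(M), ncol(M))
    S[off] <- (M[off] - rng[1]) / diff(rng)
    expect_equal(S, unname(att$scores), tolerance = 1e-12)
  }
})

test_that("hub selection ranks by attention row sum with lexicographic ties", {
  S <- matrix(0.1, 20, 20); diag(S) <- 0
  S[3, ] <- S[, 3] <- 0.9; S[17, ] <- S[, 17] <- 0.8
  diag(S) <- 0
  att <- mk_att(S)
  expect_identical(select_hubs(att, 2), c("g03", "g17"))
  tie <- mk_att(matrix(0.5, 3, 3) - diag(0.5, 3), genes = c("gb", "ga", "gc"))
  expect_identical(select_hubs(tie, 2), c("ga", "gb"))
  expect_error(select_hubs(att, 0), "positive")
  expect_error(select_hubs(att, 21), "exceeds")
})

test_that("network expansion follows the top-k breadth-first contract", {
  set.seed(8)
  S <- matrix(runif(400), 20, 20); S <- (S + t(S)) / 2; diag(S) <- 0
  att <- mk_att(S)
  hubs <- select_hubs(att, 1)
  n0 <- expand_network(att, hubs, k = 5, depth = 0)
  expect_equal(nrow(n0$nodes), 1)
  expect_equal(nrow(n0$edges), 0)
  n1 <- expand_network(att, hubs, k = 5, depth = 1)
  expect_equal(nrow(n1$edges), 5)
  expect_setequal(n1$edges$target,
                  names(sort(att$scores[hubs, setdiff(att$genes, hubs)],
                             decreasing = TRUE))[1:5])
  # 4-gene hand matrix
  H <- matrix(c(0, .9, .2, .5,
                .9, 0, .1, .3,
                .2, .1, 0, .4,
                .5, .3, .4, 0), 4, 4, byrow = TRUE)
  ah <- mk_att(H, genes = paste0("g", 1:4))
  nh <- expand_network(ah, "g1", k = 2, depth = 1)
  expect_setequal(nh$edges$target, c("g2", "g4"))
  expect_equal(sort(nh$edges$weight, decreasing = TRUE), c(0.9, 0.5))
  expect_error(expand_network(att, "nope", 5, 2), "unknown hub")
})

test_that("node counts respect the geometric bound and levels are recorded", {
  set.seed(12)
  for (r in 1:5) {
    S <- matrix(runif(900), 30, 30); S <- (S + t(S)) / 2; diag(S) <- 0
    att <- mk_att(S, sprintf("g%02d", 1:30))
    hubs <- select_hubs(att, 2)
    net <- expand_network(att, hubs, k = 3, depth = 2)
    expect_lte(nrow(net$nodes), 2 * (1 + 3 + 9))
    expect_true(all(net$edges$level <= 2))
    expect_true(all(net$nodes$level[net$nodes$role == "hub"] == 0))
    # edge weights equal the attention entries
    for (e in seq_len(nrow(net$edges)))
      expect_equal(net$edges$weight[e],
                   att$scores[net$edges$source[e], net$edges$target[e]])
  }
})

test_that("subgraph reduction is contained, bounded and idempotent at full size", {
  set.seed(13)
  S <- matrix(runif(400), 20, 20); S <- (S + t(S)) / 2; diag(S) <- 0
  att <- mk_att(S)
  hubs <- select_hubs(att, 2)
  net <- expand_network(att, hubs, k = 5, depth = 2)
  red <- reduce_subgraph(net, k = 2, depth = 1)
  expect_true(all(red$nodes$gene %in% net$nodes$gene))
  for (h in hubs)
    expect_lte(sum(red$edges$source == h), 2)
  same <- reduce_subgraph(net, k = 5, depth = 2)
  expect_equal(same$nodes, net$nodes)
  expect_equal(same$edges, net$edges)
  expect_error(reduce_subgraph(net, k = 6, depth = 1), "must not exceed")
})

test_that("networks round-trip through edge TSV and GraphML", {
  set.seed(14)
  S <- matrix(runif(144), 12, 12); S <- (S + t(S)) / 2; diag(S) <- 0
  att <- mk_att(S, sprintf("g%02d", 1:12))
  net <- expand_network(att, select_hubs(att, 2), k = 3, depth = 2)
  ft <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, ft)
  bt <- import_network(ft)
  expect_equal(bt$nodes, net$nodes)
  expect_equal(bt$edges, net$edges)
  expect_identical(bt$hubs, net$hubs)
  expect_equal(nrow(bt$edges), nrow(net$edges))

  fg <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, fg)
  bg <- import_network(fg)
  expect_setequal(bg$nodes$gene, net$nodes$gene)
  eo <- net$edges[order(net$edges$source, net$edges$target), ]
  ei <- bg$edges[order(bg$edges$source, bg$edges$target), ]
  expect_equal(ei$weight, eo$weight)
  expect_equal(ei$level, eo$level)
  # hub-only network (no edges) still round-trips
  n0 <- expand_network(att, select_hubs(att, 2), k = 3, depth = 0)
  f0 <- withr::local_tempfile(fileext = ".tsv")
  export_network(n0, f0)
  expect_equal(import_network(f0)$nodes, n0$nodes)
})

test_that("GraphML export is well-formed XML with the GraphML namespace", {
  skip_if_not_installed("xml2")
  set.seed(15)
  S <- matrix(runif(100), 10, 10); S <- (S + t(S)) / 2; diag(S) <- 0
  att <- mk_att(S)
  net <- expand_network(att, select_hubs(att, 1), k = 3, depth = 1)
  fg <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, fg)
  doc <- xml2::read_xml(fg)
  expect_match(xml2::xml_name(doc), "graphml")
  expect_match(xml2::xml_ns(doc)[[1]], "graphml", ignore.case = TRUE)
})

test_that("attention averaging pools pair scores over co-occurring cells", {
  fx <- tiny_model_fixture(n_cells = 6)
  av <- average_attention(fx$model, fx$corpus$sentences[1:5])
  expect_true(all(diag(av$scores) == 0))
  obs <- av$scores[av$n_obs > 0 & row(av$n_obs) != col(av$n_obs)]
  expect_true(all(obs >= 0 & obs <= 1))
  expect_equal(av$scores, t(av$scores))
})

test_that("rank AUC behaves like the Mann-Whitney statistic", {
  expect_equal(rank_auc(c(3, 4), c(1, 2)), 1)
  expect_equal(rank_auc(c(1, 2), c(3, 4)), 0)
  expect_equal(rank_auc(c(1, 2), c(1, 2)), 0.5)
  set.seed(16)
  pos <- rnorm(50, 1); neg <- rnorm(80)
  w <- wilcox.test(pos, neg)$statistic
  expect_equal(rank_auc(pos, neg), unname(w) / (50 * 80), tolerance = 1e-12)
})
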