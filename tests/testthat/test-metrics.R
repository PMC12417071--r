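# independent brute-force oracles, written against the definitions
oracle_ari <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  n11 <- sum(same_a & same_b); n00 <- sum(!same_a & !same_b)
  n10 <- sum(same_a & !same_b); n01 <- sum(!same_a & same_b)
  tot <- choose(n, 2)
  exp_idx <- (n11 + n10) * (n11 + n01) / tot
  mx <- ((n11 + n10) + (n11 + n01)) / 2
  if (mx == exp_idx) return(1)
  (n11 - exp_idx) / (mx - exp_idx)
}

oracle_nmi <- function(a, b) {
  n <- length(a)
  H <- function(x) {
    p <- table(x) / n
    -sum(p * log(p))
  }
  ha <- H(a); hb <- H(b)
  if (ha == 0 && hb == 0) return(1)
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (u in unique(a)) for (v in unique(b)) {
    puv <- mean(a == u & b == v)
    if (puv > 0) mi <- mi + puv * log(puv / (mean(a == u) * mean(b == v)))
  }
  mi / ((ha + hb) / 2)
}

oracle_sil <- function(emb, lab) {
  D <- as.matrix(dist(emb))
  mean(vapply(seq_along(lab), function(i) {
    own <- setdiff(which(lab == lab[i]), i)
    if (!length(own)) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(l) mean(D[i, lab == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1)))
}

test_that("ARI limiting cases are exact", {
  a <- c(1, 1, 2, 2, 3)
  expect_equal(ari(a, c("x", "x", "y", "y", "z")), 1)       # relabeled identity
  expect_equal(ari(c(1, 1, 2, 2), c(1, 2, 2, 2)), 0)        # worked contingency example
  expect_equal(ari(1:6, rep(1, 6)), 0)                      # singletons vs one cluster
  expect_error(ari(1:3, 1:4), "length")
})

test_that("NMI conventions and limiting cases hold", {
  expect_equal(nmi(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(nmi(c(1, 2, 1, 2), rep(1, 4)), 0)            # constant labeling
  expect_equal(nmi(rep(1, 4), rep(2, 4)), 1)                # both constant
  a <- c(1, 1, 1, 2, 2, 2); b <- c(1, 1, 2, 2, 2, 2)
  expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-12)
})

test_that("silhouette matches hand computation and its conventions", {
  emb <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  lab <- c("a", "a", "b", "b")
  expect_equal(silhouette_score(emb, lab), oracle_sil(emb, lab), tolerance = 1e-12)
  # two tight far-apart clusters: near 1
  expect_gt(silhouette_score(emb, lab), 0.97)
  # singleton clusters contribute 0
  expect_equal(silhouette_score(matrix(c(0, 5, 5.1), 3, 1), c("a", "b", "b")),
               oracle_sil(matrix(c(0, 5, 5.1), 3, 1), c("a", "b", "b")))
  expect_error(silhouette_score(emb, rep("a", 4)), "two clusters")
})

test_that("random labels on one blob give near-zero silhouette", {
  set.seed(10)
  emb <- matrix(rnorm(60 * 2), 60, 2)
  vals <- vapply(1:20, function(s) {
    set.seed(s)
    silhouette_score(emb, sample(c("a", "b"), 60, replace = TRUE))
  }, numeric(1))
  expect_lt(max(abs(vals)), 0.1)
})

test_that("ari/nmi/silhouette agree with brute force on 50 random labelings", {
  set.seed(123)
  for (r in 1:50) {
    n <- sample(4:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    expect_equal(ari(a, b), oracle_ari(a, b), tolerance = 1e-9)
    expect_equal(nmi(a, b), oracle_nmi(a, b), tolerance = 1e-9)
    if (length(unique(a)) >= 2) {
      emb <- matrix(rnorm(n * 2), n, 2)
      expect_equal(silhouette_score(emb, a), oracle_sil(emb, a), tolerance = 1e-9)
    }
  }
})

test_that("ari/nmi are symmetric and invariant under label permutation", {
  set.seed(7)
  for (r in 1:10) {
    a <- sample(1:4, 20, replace = TRUE)
    b <- sample(1:3, 20, replace = TRUE)
    expect_equal(ari(a, b), ari(b, a), tolerance = 1e-12)
    expect_equal(nmi(a, b), nmi(b, a), tolerance = 1e-12)
    perm <- sample(4)
    expect_equal(ari(perm[a], b), ari(a, b), tolerance = 1e-12)
    expect_equal(nmi(perm[a], b), nmi(a, b), tolerance = 1e-12)
  }
})

test_that("metrics agree with independent package implementations", {
  skip_if_not_installed("mclust")
  skip_if_not_installed("cluster")
  set.seed(31)
  for (r in 1:10) {
    a <- sample(1:3, 15, replace = TRUE)
    b <- sample(1:3, 15, replace = TRUE)
    expect_equal(ari(a, b), mclust::adjustedRandIndex(a, b), tolerance = 1e-9)
  }
  emb <- matrix(rnorm(40), 20, 2)
  lab <- rep(1:2, each = 10)
  sil <- cluster::silhouette(lab, dist(emb))
  expect_equal(silhouette_score(emb, lab), mean(sil[, "sil_width"]),
               tolerance = 1e-9)
})

test_that("louvain sweep recovers well-separated blobs deterministically", {
  set.seed(2)
  emb <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
               matrix(rnorm(40, 8, 0.2), 20, 2))
  truth <- rep(c("a", "b"), each = 20)
  cls <- louvain_sweep(emb, resolutions = c(0.5, 1.0, 1.5), n_neighbors = 15,
                       seed = 9)
  expect_length(cls, 3)
  expect_equal(ari(cls[[2]]$cluster, truth), 1)
  expect_equal(min(cls[[2]]$cluster), 0)
  cls2 <- louvain_sweep(emb, resolutions = c(0.5, 1.0, 1.5), n_neighbors = 15,
                        seed = 9)
  expect_identical(lapply(cls, `[[`, "cluster"), lapply(cls2, `[[`, "cluster"))
  expect_error(louvain_sweep(emb[1:4, ], 1.0, n_neighbors = 5), "at least")
})

test_that("benchmark reports per-resolution curves and consistent maxima", {
  set.seed(3)
  ref <- sample(paste0("t", 1:3), 45, replace = TRUE)
  onehot <- diag(3)[match(ref, paste0("t", 1:3)), ] +
    matrix(rnorm(45 * 3, 0, 0.01), 45, 3)
  res <- seq(0.4, 1.2, by = 0.4)
  bm <- benchmark(onehot, ref, resolutions = res, n_neighbors = 5, seed = 4)
  expect_equal(nrow(bm$curves), length(res))
  expect_equal(bm$best[["ari"]], 1)
  expect_equal(bm$best[["nmi"]], 1)
  expect_true(all(bm$best[["ari"]] >= bm$curves$ari))
  expect_true(all(bm$best[["nmi"]] >= bm$curves$nmi))
  # embeddings built from shuffled labels carry no information about ref
  set.seed(5)
  shuf <- diag(3)[match(sample(ref), paste0("t", 1:3)), ] +
    matrix(rnorm(45 * 3, 0, 0.01), 45, 3)
  bm0 <- benchmark(shuf, ref, resolutions = res, n_neighbors = 5, seed = 4)
  expect_lt(bm0$best[["ari"]], 0.1)
})

test_that("confusion matrices count correctly and support label merging", {
  labs <- structure(data.frame(
    predicted = c("protoxylem", "metaxylem", "phloem", "phloem"),
    reference = c("xylem", "xylem", "phloem", "xylem")),
    class = c("sclm_labels", "data.frame"))
  cm <- confusion(labs)
  expect_equal(sum(cm$counts), 4)
  expect_equal(cm$accuracy, 0.25)
  cm2 <- confusion(labs, merge_map = c(protoxylem = "xylem", metaxylem = "xylem"))
  expect_equal(cm2$accuracy_merged, 0.75)
  perfect <- structure(data.frame(predicted = c("a", "b"), reference = c("a", "b")),
                       class = c("sclm_labels", "data.frame"))
  pc <- confusion(perfect)
  expect_equal(pc$accuracy, 1)
  expect_true(all(pc$counts[row(pc$counts) != col(pc$counts)] == 0))
  expect_error(confusion(data.frame(predicted = "a")), "reference")
})
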