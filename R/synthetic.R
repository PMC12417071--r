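#' Synthetic corpus configuration
#'
#' Declares the generative model for a multi-batch scRNA-seq corpus with
#' ground truth: gene base means are log-normal; each cell type multiplies
#' its (disjoint) marker genes by `marker_fold`; each batch applies a
#' per-gene log-normal scaling with log-sd `batch_scale_sd`; each planted
#' module is co-activated through a shared per-cell latent factor whose
#' strength grows with the module's `rho`; counts are negative binomial with
#' a common dispersion. Marker blocks are assigned deterministically (type
#' `t` owns genes `(t-1)*markers_per_type + 1 .. t*markers_per_type`), so
#' the truth map is a pure function of the configuration.
#'
#' @param n_cells,n_genes,n_types corpus dimensions.
#' @param markers_per_type marker genes per cell type (disjoint blocks).
#' @param marker_fold mean multiplier of a marker in its own type (> 1).
#' @param n_batches number of batches (cells assigned uniformly).
#' @param batch_scale_sd log-sd of the per-batch per-gene scaling (>= 0).
#' @param modules list of planted modules, each
#'   `list(genes = <ids or indices>, rho = <co-activation strength in [0,1]>)`.
#' @param library_size_mean mean per-cell total count.
#' @param dispersion negative-binomial dispersion (NB size = 1/dispersion).
#' @param seed integer seed; the corpus is a deterministic function of the
#'   full configuration.
#' @return an object of class `sclm_synth_config`.
#' @export
synth_config <- function(n_cells = 2000L, n_genes = 500L, n_types = 4L,
                         markers_per_type = 20L, marker_fold = 5,
                         n_batches = 2L, batch_scale_sd = 0.3,
                         modules = list(), library_size_mean = 2000,
                         dispersion = 0.4, seed = 7L) {
  if (marker_fold <= 1) stop2("marker_fold must exceed 1")
  if (batch_scale_sd < 0) stop2("batch_scale_sd must be nonnegative")
  if (n_types * markers_per_type > n_genes)
    stop2("marker blocks exceed the gene universe")
  cfg <- structure(list(n_cells = as.integer(n_cells),
                        n_genes = as.integer(n_genes),
                        n_types = as.integer(n_types),
                        markers_per_type = as.integer(markers_per_type),
                        marker_fold = marker_fold,
                        n_batches = as.integer(n_batches),
                        batch_scale_sd = batch_scale_sd, modules = modules,
                        library_size_mean = library_size_mean,
                        dispersion = dispersion, seed = as.integer(seed)),
                   class = "sclm_synth_config")
  gid <- synth_gene_ids(cfg)
  for (m in modules) {
    g <- if (is.numeric(m$genes)) gid[m$genes] else as.character(m$genes)
    if (!all(g %in% gid)) stop2("module genes outside the gene universe")
    if (is.null(m$rho) || m$rho < 0 || m$rho > 1) stop2("module rho must be in [0,1]")
  }
  cfg
}

synth_gene_ids <- function(cfg) sprintf("g%04d", seq_len(cfg$n_genes))

#' The standard calibration corpus configuration
#'
#' 2000 cells, 500 genes, 4 well-separated cell types with 20 markers each
#' at fold 5, 2 batches (log-sd 0.3), and one planted 25-gene module at
#' rho = 0.8 occupying the last 25 genes. Seed 7. This is the fixture the
#' package's calibration experiments and examples refer to.
#'
#' @param seed seed override (default 7).
#' @return an [synth_config()].
#' @export
calibration_config <- function(seed = 7L) {
  synth_config(n_cells = 2000L, n_genes = 500L, n_types = 4L,
               markers_per_type = 20L, marker_fold = 5, n_batches = 2L,
               batch_scale_sd = 0.3,
               modules = list(list(genes = 476:500, rho = 0.8)),
               library_size_mean = 400, dispersion = 0.5, seed = seed)
}

#' Generate a synthetic corpus
#'
#' @param cfg an [synth_config()].
#' @return an object of class `sclm_synth`: `expr` (an `sclm_expr` with
#'   cell_type and batch filled) and `truth` (marker map, module map, config
#'   echo).
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "sclm_synth_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes; n <- cfg$n_cells; K <- cfg$n_types
  gid <- synth_gene_ids(cfg)
  cid <- sprintf("c%05d", seq_len(n))
  types <- paste0("type", sample.int(K, n, replace = TRUE))
  batches <- paste0("batch", sample.int(cfg$n_batches, n, replace = TRUE))

  base <- exp(stats::rnorm(G, 0, 1.2))
  markers <- lapply(seq_len(K), function(t)
    gid[((t - 1L) * cfg$markers_per_type + 1L):(t * cfg$markers_per_type)])
  names(markers) <- paste0("type", seq_len(K))
  modules <- lapply(cfg$modules, function(m)
    list(genes = if (is.numeric(m$genes)) gid[m$genes] else as.character(m$genes),
         rho = m$rho))

  # per-batch per-gene multiplicative effect, mean-one on the natural scale
  bf <- matrix(exp(stats::rnorm(cfg$n_batches * G, -cfg$batch_scale_sd^2 / 2,
                                cfg$batch_scale_sd)), cfg$n_batches, G)
  W <- matrix(base, n, G, byrow = TRUE)
  for (t in seq_len(K)) {
    cols <- match(markers[[t]], gid)
    rows <- types == paste0("type", t)
    W[rows, cols] <- W[rows, cols] * cfg$marker_fold
  }
  W <- W * bf[as.integer(sub("batch", "", batches)), , drop = FALSE]
  for (m in modules) {
    alpha <- 1.5 * m$rho
    z <- stats::rnorm(n)
    cols <- match(m$genes, gid)
    W[, cols] <- W[, cols] * exp(alpha * z - alpha^2 / 2)
  }
  lib <- stats::rlnorm(n, log(cfg$library_size_mean) - 0.25^2 / 2, 0.25)
  mu <- W / rowSums(W) * lib
  counts <- matrix(stats::rnbinom(n * G, mu = as.vector(mu),
                                  size = 1 / cfg$dispersion), n, G)
  # a cell with zero total cannot be tokenized; redraw such cells once
  for (i in which(rowSums(counts) == 0))
    counts[i, ] <- stats::rnbinom(G, mu = mu[i, ], size = 1 / cfg$dispersion)
  dimnames(counts) <- list(cid, gid)

  expr <- expression_matrix(counts, cid, gid, batch = batches, cell_type = types)
  structure(list(expr = expr,
                 truth = list(markers = markers, modules = modules, config = cfg)),
            class = "sclm_synth")
}

#' @export
print.sclm_synth <- function(x, ...) {
  cat("<sclm_synth> synthetic corpus\n")
  print(x$expr)
  cat(sprintf("  truth: %d marker sets, %d module(s)\n",
              length(x$truth$markers), length(x$truth$modules)))
  invisible(x)
}

#' Ground-truth labels of a synthetic corpus
#'
#' @param corpus an [generate_corpus()] result.
#' @return list with `cell_type` (reference label vector), `markers` (type
#'   -> gene ids), `modules` (planted module list).
#' @export
truth_labels <- function(corpus) {
  stopifnot(inherits(corpus, "sclm_synth"))
  list(cell_type = corpus$expr$cell_type, markers = corpus$truth$markers,
       modules = corpus$truth$modules)
}

#' Stratified split of a corpus
#'
#' @param x an `sclm_synth` or `sclm_expr`.
#' @param fractions named numeric vector summing to 1 (e.g.
#'   `c(train = 0.9, test = 0.1)`).
#' @param stratify_by `"cell_type"` or `"batch"`.
#' @param seed integer seed.
#' @return named list of `sclm_expr` objects, one per fraction; disjoint,
#'   their union is the corpus, per-stratum proportions preserved to
#'   rounding.
#' @export
split_corpus <- function(x, fractions = c(train = 0.9, test = 0.1),
                         stratify_by = c("cell_type", "batch"), seed = 1L) {
  stratify_by <- match.arg(stratify_by)
  expr <- if (inherits(x, "sclm_synth")) x$expr else x
  stopifnot(inherits(expr, "sclm_expr"))
  if (abs(sum(fractions) - 1) > 1e-8) stop2("fractions must sum to 1")
  strata <- expr[[stratify_by]]
  if (is.null(strata)) stop2("corpus lacks ", stratify_by, " labels")
  n <- nrow(expr$counts)
  assign <- integer(n)
  set.seed(seed)
  for (s in unique(strata)) {
    ix <- which(strata == s)
    if (!length(ix)) stop2("empty stratum: ", s)
    ix <- ix[sample.int(length(ix))]
    bounds <- round(cumsum(fractions) * length(ix))
    lo <- c(0L, utils::head(bounds, -1L)) + 1L
    for (k in seq_along(fractions))
      if (bounds[k] >= lo[k]) assign[ix[lo[k]:bounds[k]]] <- k
  }
  out <- lapply(seq_along(fractions), function(k) expr[assign == k, ])
  names(out) <- names(fractions) %||% paste0("part", seq_along(fractions))
  out
}
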