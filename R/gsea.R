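#' Construct an expression dataset
#'
#' Probes-by-samples intensity matrix with a two-class phenotype and the
#' probe -> gene -> EC annotation needed for enzyme-level collapsing.
#'
#' @param exprs Numeric matrix, probes in rows (rownames = probe ids),
#'   samples in columns.
#' @param classes Factor (or coercible) of length `ncol(exprs)` with exactly
#'   two levels; the first level is the "positive" phenotype: positive SNR /
#'   NES means enriched in that class.
#' @param probe_gene `data.frame(probe, gene)`.
#' @param gene_ec `data.frame(gene, ec)`; a gene may map to several ECs.
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(exprs, classes, probe_gene, gene_ec) {
  stopifnot(is.matrix(exprs), !is.null(rownames(exprs)))
  if (!all(is.finite(exprs))) stop("expression matrix must be finite")
  classes <- as.factor(classes)
  if (nlevels(classes) != 2L) stop("exactly two phenotype classes required")
  if (anyNA(classes)) stop("missing phenotype labels")
  if (length(classes) != ncol(exprs)) stop("one label per sample required")
  if (min(table(classes)) < 2L) stop("need >= 2 samples per class")
  stopifnot(all(c("probe", "gene") %in% names(probe_gene)),
            all(c("gene", "ec") %in% names(gene_ec)))
  if (nrow(merge(probe_gene, gene_ec, by = "gene")) < 1L) {
    stop("annotation maps no probe to any EC node")
  }
  structure(list(exprs = exprs, classes = classes,
                 probe_gene = probe_gene, gene_ec = gene_ec),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat("expression_dataset:", nrow(x$exprs), "probes x", ncol(x$exprs),
      "samples (", paste(levels(x$classes), table(x$classes), collapse = " vs "),
      ")\n")
  invisible(x)
}

#' Construct a node-set collection
#'
#' Named modules (KEGG-style) whose members are enzyme-activity nodes
#' (EC identifiers).
#'
#' @param sets Named list of character vectors of EC node ids.
#' @param descriptions Optional display names, recycled from set names.
#' @return Object of class `node_set_collection` (a named list).
#' @export
node_set_collection <- function(sets, descriptions = NULL) {
  stopifnot(is.list(sets))
  if (length(sets) == 0L) {
    return(structure(stats::setNames(list(), character(0)),
                     descriptions = character(0),
                     class = "node_set_collection"))
  }
  stopifnot(!is.null(names(sets)), all(nzchar(names(sets))))
  if (anyDuplicated(names(sets))) stop("module ids must be unique")
  if (any(vapply(sets, length, 1L) == 0L)) stop("node sets must be non-empty")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- names(sets)
  structure(sets, descriptions = stats::setNames(descriptions, names(sets)),
            class = "node_set_collection")
}

#' @export
print.node_set_collection <- function(x, ...) {
  sz <- vapply(x, length, 1L)
  cat("node_set_collection:", length(x), "modules, ",
      min(sz), "-", max(sz), "nodes each\n")
  invisible(x)
}

# sd floor shared by all SNR computations: guards near-constant probes the
# same way canonical two-class ranking implementations do
.floor_sd <- function(s, m, rel = 0.2, abs_floor = 0.005) {
  pmax(s, rel * abs(m), abs_floor)
}

#' Signal-to-noise ratio ranking metric
#'
#' Two-class ranking statistic `(mean_a - mean_b) / (sd_a + sd_b)` with each
#' standard deviation floored at `max(sd, 0.2 |mean|, 0.005)` to avoid
#' division blow-ups on near-constant probes.  Antisymmetric under swapping
#' the groups.
#'
#' @param values_a,values_b Numeric vectors of length >= 2 (one group each).
#' @return Scalar SNR.
#' @export
#' @examples
#' snr_metric(c(2, 2.5, 3), c(1, 1.2, 0.8))
snr_metric <- function(values_a, values_b) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs >= 2 values")
  }
  ma <- mean(values_a); mb <- mean(values_b)
  sa <- .floor_sd(stats::sd(values_a), ma)
  sb <- .floor_sd(stats::sd(values_b), mb)
  (ma - mb) / (sa + sb)
}

# SNR for all probes under many label assignments at once.
# X: probes x samples; A: samples x P 0/1 membership of group a (complement = b).
# Returns probes x P matrix.
.snr_matrix <- function(X, A) {
  na <- colSums(A)
  nb <- nrow(A) - na
  X2 <- X * X
  Sa <- X %*% A;  Sb <- rowSums(X) - Sa
  Qa <- X2 %*% A; Qb <- rowSums(X2) - Qa
  ma <- sweep(Sa, 2L, na, "/"); mb <- sweep(Sb, 2L, nb, "/")
  va <- sweep(Qa - sweep(ma^2, 2L, na, "*"), 2L, na - 1L, "/")
  vb <- sweep(Qb - sweep(mb^2, 2L, nb, "*"), 2L, nb - 1L, "/")
  sa <- .floor_sd(sqrt(pmax(va, 0)), ma)
  sb <- .floor_sd(sqrt(pmax(vb, 0)), mb)
  (ma - mb) / (sa + sb)
}

# probe-row indices contributing to each EC node, rows sorted by probe id so
# that max-|metric| ties resolve to the lexicographically first probe
.ec_probe_index <- function(dataset) {
  ann <- merge(dataset$probe_gene, dataset$gene_ec, by = "gene")
  ann <- ann[ann$probe %in% rownames(dataset$exprs), , drop = FALSE]
  if (nrow(ann) == 0L) stop("annotation maps no probe to any EC node")
  ann <- ann[order(ann$ec, ann$probe), ]
  ann$row <- match(ann$probe, rownames(dataset$exprs))
  split(ann$row, ann$ec)
}

# collapse probe-level metric matrix (probes x P) to node-level signed
# max-|metric| matrix (nodes x P)
.collapse_matrix <- function(S, ec_index) {
  P <- ncol(S)
  out <- matrix(0, length(ec_index), P, dimnames = list(names(ec_index), NULL))
  for (i in seq_along(ec_index)) {
    rows <- ec_index[[i]]
    if (length(rows) == 1L) {
      out[i, ] <- S[rows, ]
    } else {
      sub <- S[rows, , drop = FALSE]
      j <- max.col(t(abs(sub)), ties.method = "first")
      out[i, ] <- sub[cbind(j, seq_len(P))]
    }
  }
  out
}

#' Collapse probes to enzyme-activity nodes
#'
#' For every EC node, all probesets of all genes annotated to that activity
#' are candidates; the probeset with maximum absolute SNR is retained (signed
#' value kept).  Genes annotated to several ECs contribute their probesets to
#' each.  The result is a ranked node list, sorted by decreasing metric with
#' deterministic tie-breaking (metric, then node id).
#'
#' @param dataset An [expression_dataset()].
#' @return `data.frame(node, metric)` of class `ranked_node_list`, one row
#'   per represented EC, descending by metric.
#' @export
collapse_to_nodes <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  ec_index <- .ec_probe_index(dataset)
  A <- matrix(as.numeric(dataset$classes == levels(dataset$classes)[1L]), ncol = 1L)
  S <- .snr_matrix(dataset$exprs, A)
  metric <- .collapse_matrix(S, ec_index)[, 1L]
  ranked_node_list(names(ec_index), metric)
}

#' Construct a ranked node list
#'
#' @param node Character node ids.
#' @param metric Numeric ranking metric per node.
#' @return `data.frame(node, metric)` sorted descending by metric, ties
#'   broken by node id; class `ranked_node_list`.
#' @export
ranked_node_list <- function(node, metric) {
  stopifnot(length(node) == length(metric), !anyDuplicated(node))
  o <- order(-metric, node)
  structure(data.frame(node = as.character(node)[o], metric = metric[o],
                       row.names = NULL),
            class = c("ranked_node_list", "data.frame"))
}

# running-sum enrichment score from the ranked positions of the hits.
# pos: sorted hit positions in 1..N; w: |metric|^q of hits in the same order.
.es_from_hits <- function(pos, w, N) {
  k <- length(pos)
  if (k == N) return(1)        # degenerate: no misses possible
  sw <- sum(w)
  if (sw == 0) { w <- rep(1, k); sw <- k }
  Pc <- cumsum(w) / sw
  dec <- (pos - seq_len(k)) / (N - k)   # misses before each hit / (N - k)
  after <- Pc - dec
  before <- c(0, Pc[-k]) - dec
  hi <- max(after); lo <- min(before)
  # ties between the positive and negative extreme resolve to the positive
  # deviation; the comparison carries a tolerance so floating-point summation
  # order cannot flip the sign of an exact tie
  if (hi >= -lo - 1e-12) hi else lo
}

#' Running-sum enrichment score
#'
#' Classic weighted Kolmogorov-Smirnov-like statistic: walking down the
#' ranked node list, hits increment the running sum by
#' `|metric|^weight_exponent` (normalised over the hits) and misses decrement
#' by `1 / (N - N_hits)`; the ES is the signed maximum deviation from zero,
#' always in `[-1, 1]`.
#'
#' @param ranked A [ranked_node_list()].
#' @param node_set Character vector of node ids.
#' @param weight_exponent Non-negative weighting exponent (0 = unweighted).
#' @return Scalar ES.
#' @export
enrichment_score <- function(ranked, node_set, weight_exponent = 1) {
  stopifnot(inherits(ranked, "ranked_node_list"), weight_exponent >= 0)
  hit <- ranked$node %in% node_set
  if (!any(hit)) stop("module not represented in the ranked list")
  .es_from_hits(which(hit), abs(ranked$metric[hit])^weight_exponent,
                nrow(ranked))
}

#' Retain modules represented by 3 to 500 nodes
#'
#' A module's represented-node count is the number of its members present in
#' the ranked list; modules with fewer than `min_nodes` or more than
#' `max_nodes` represented nodes are excluded.  Idempotent.
#'
#' @param collection A [node_set_collection()].
#' @param ranked A [ranked_node_list()].
#' @param min_nodes,max_nodes Inclusive bounds (defaults 3 and 500).
#' @return Filtered `node_set_collection`.
#' @export
filter_modules <- function(collection, ranked, min_nodes = 3L, max_nodes = 500L) {
  stopifnot(inherits(collection, "node_set_collection"),
            inherits(ranked, "ranked_node_list"))
  n_rep <- vapply(collection, function(s) sum(s %in% ranked$node), 1L)
  keep <- n_rep >= min_nodes & n_rep <= max_nodes
  node_set_collection(unclass(collection)[keep],
                      attr(collection, "descriptions")[keep])
}

# shared permutation engine: scores every set of `collection` against the
# dataset, re-collapsing and re-ranking under each phenotype permutation.
.gsea_engine <- function(dataset, collection, n_perm, seed, weight_exponent,
                         perm_mode) {
  X <- dataset$exprs
  cls <- dataset$classes
  pos_class <- levels(cls)[1L]
  n <- ncol(X)
  na <- sum(cls == pos_class)
  ec_index <- .ec_probe_index(dataset)
  M <- length(ec_index)
  sets_idx <- lapply(collection, function(s) which(names(ec_index) %in% s))
  if (any(vapply(sets_idx, length, 1L) == 0L)) {
    stop("module not represented in the ranked list")
  }

  if (perm_mode == "phenotype") {
    A <- matrix(0, n, n_perm + 1L)
    A[cbind(which(cls == pos_class), 1L)] <- 1
    withr::with_seed(seed, {
      for (p in seq_len(n_perm)) A[cbind(sample.int(n, na), p + 1L)] <- 1
    })
    S <- .snr_matrix(X, A)
    node_metric <- .collapse_matrix(S, ec_index)
  } else {
    # node-set permutation: observed ranking is fixed; nulls drawn per set below
    A <- matrix(as.numeric(cls == pos_class), ncol = 1L)
    node_metric <- .collapse_matrix(.snr_matrix(X, A), ec_index)
  }

  node_ids <- names(ec_index)
  P <- ncol(node_metric)
  # rank position of each node per column, ties broken by node id
  pos_mat <- matrix(0L, M, P)
  for (p in seq_len(P)) {
    pos_mat[order(-node_metric[, p], node_ids), p] <- seq_len(M)
  }
  absw <- abs(node_metric)^weight_exponent

  es_obs <- numeric(length(sets_idx))
  null_es <- matrix(NA_real_, length(sets_idx), n_perm)
  for (i in seq_along(sets_idx)) {
    idx <- sets_idx[[i]]
    o <- order(pos_mat[idx, 1L])
    es_obs[i] <- .es_from_hits(pos_mat[idx, 1L][o], absw[idx, 1L][o], M)
  }
  if (perm_mode == "phenotype") {
    for (i in seq_along(sets_idx)) {
      idx <- sets_idx[[i]]
      for (p in seq_len(n_perm)) {
        pp <- pos_mat[idx, p + 1L]
        o <- order(pp)
        null_es[i, p] <- .es_from_hits(pp[o], absw[idx, p + 1L][o], M)
      }
    }
  } else {
    withr::with_seed(seed, {
      for (i in seq_along(sets_idx)) {
        k <- length(sets_idx[[i]])
        for (p in seq_len(n_perm)) {
          idx <- sample.int(M, k)
          o <- order(pos_mat[idx, 1L])
          null_es[i, p] <- .es_from_hits(pos_mat[idx, 1L][o], absw[idx, 1L][o], M)
        }
      }
    })
  }
  list(es = es_obs, null = null_es, n_nodes = vapply(sets_idx, length, 1L),
       classes = levels(cls))
}

# NES / p from an observed ES and its same-sign null distribution
.normalize_es <- function(es, nulls, n_perm) {
  same <- if (es >= 0) nulls[nulls >= 0] else nulls[nulls < 0]
  if (length(same) == 0L) {
    return(list(nes = NA_real_, p = 1 / (n_perm + 1), flagged = TRUE))
  }
  list(nes = es / mean(abs(same)),
       p = (1 + sum(abs(same) >= abs(es))) / (1 + length(same)),
       flagged = FALSE)
}

#' Score a collection of modules with permutation-normalised enrichment
#'
#' For each module: the observed ES from the true phenotype labels; a null ES
#' distribution from `n_perm` phenotype-label permutations (the probe-level
#' SNR, EC collapsing and ranking are recomputed for every permutation);
#' `NES = ES / mean(|null ES| of the same sign)`; and the permutation p-value
#' as the same-sign tail fraction with a +1 pseudo-count.  When either class
#' has fewer than 7 samples, node-set permutation is used instead (mode
#' `"auto"`).
#'
#' @param dataset An [expression_dataset()].
#' @param collection A [node_set_collection()] (pre-filter with
#'   [filter_modules()] if desired).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; all randomness flows from it.
#' @param weight_exponent Hit-weighting exponent, default 1.
#' @param perm_mode `"auto"`, `"phenotype"` or `"nodeset"`.
#' @return `data.frame` of class `module_enrichment` with columns
#'   `module, n_nodes, es, nes, p, q, enriched_in, flagged` (q = Benjamini-
#'   Hochberg over the collection).
#' @export
run_gsea <- function(dataset, collection, n_perm = 1000L, seed = 1L,
                     weight_exponent = 1,
                     perm_mode = c("auto", "phenotype", "nodeset")) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(collection, "node_set_collection"))
  if (n_perm < 100L) stop("n_perm must be >= 100")
  perm_mode <- match.arg(perm_mode)
  if (perm_mode == "auto") {
    perm_mode <- if (min(table(dataset$classes)) >= 7L) "phenotype" else "nodeset"
  }
  eng <- .gsea_engine(dataset, collection, n_perm, seed, weight_exponent,
                      perm_mode)
  res <- lapply(seq_along(eng$es), function(i) {
    .normalize_es(eng$es[i], eng$null[i, ], n_perm)
  })
  nes <- vapply(res, `[[`, 1, "nes")
  out <- data.frame(
    module = names(collection),
    n_nodes = eng$n_nodes,
    es = eng$es,
    nes = nes,
    p = vapply(res, `[[`, 1, "p"),
    q = NA_real_,
    enriched_in = ifelse(eng$es >= 0, eng$classes[1L], eng$classes[2L]),
    flagged = vapply(res, `[[`, TRUE, "flagged"),
    row.names = NULL)
  out$q <- stats::p.adjust(out$p, "BH")
  class(out) <- c("module_enrichment", "data.frame")
  out
}

#' Permutation-normalised enrichment of a single module
#'
#' Convenience wrapper around [run_gsea()] for one node set.
#'
#' @inheritParams run_gsea
#' @param node_set Character vector of EC node ids.
#' @return One-row `module_enrichment` data frame.
#' @export
permutation_nes <- function(dataset, node_set, n_perm = 1000L, seed = 1L,
                            weight_exponent = 1,
                            perm_mode = c("auto", "phenotype", "nodeset")) {
  run_gsea(dataset,
           node_set_collection(list(module = node_set)),
           n_perm = n_perm, seed = seed, weight_exponent = weight_exponent,
           perm_mode = match.arg(perm_mode))
}

#' Compare NES profiles of two datasets
#'
#' Pairs per-module NES values over the modules scored in both datasets and
#' reports Pearson and Spearman correlations plus the shared enriched lists:
#' modules with `NES > tau` in both datasets (shared up, i.e. enriched in the
#' first phenotype class) and `NES < -tau` in both (shared down).
#'
#' @param enrich_a,enrich_b [run_gsea()] results for the two datasets.
#' @param tau NES cut-off, default 1.2.
#' @return List of class `concordance_result`: `pairs` (module, nes_a,
#'   nes_b), `pearson`, `spearman`, `shared_up`, `shared_down`, `tau`.
#' @export
cross_dataset_concordance <- function(enrich_a, enrich_b, tau = 1.2) {
  stopifnot(is.data.frame(enrich_a), is.data.frame(enrich_b))
  pairs <- merge(enrich_a[, c("module", "nes")],
                 enrich_b[, c("module", "nes")],
                 by = "module", suffixes = c("_a", "_b"))
  pairs <- pairs[stats::complete.cases(pairs), , drop = FALSE]
  if (nrow(pairs) < 3L) stop("need >= 3 modules scored in both datasets")
  structure(list(
    pairs = pairs,
    pearson = stats::cor(pairs$nes_a, pairs$nes_b, method = "pearson"),
    spearman = stats::cor(pairs$nes_a, pairs$nes_b, method = "spearman"),
    shared_up = pairs$module[pairs$nes_a > tau & pairs$nes_b > tau],
    shared_down = pairs$module[pairs$nes_a < -tau & pairs$nes_b < -tau],
    tau = tau), class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("concordance over", nrow(x$pairs), "modules: Pearson r =",
      round(x$pearson, 3), ", Spearman rho =", round(x$spearman, 3), "\n")
  cat("shared NES > ", x$tau, ": ", length(x$shared_up),
      " modules; shared NES < -", x$tau, ": ", length(x$shared_down),
      " modules\n", sep = "")
  invisible(x)
}
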