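#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same samples.
#' Invariant to cluster relabeling and sample order; 1 for identical
#' partitions, approximately 0 for random agreement.
#'
#' @param a,b Cluster assignments (any atomic type), same length.
#' @return Scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(0)   # degenerate (e.g. all-singletons)
  (sum_ij - expected) / (max_idx - expected)
}

#' Partition samples by their labeling-index profiles
#'
#' Clusters samples on Euclidean distance between fractional-contribution
#' vectors.  Metabolites with any invalid (NA) index are dropped listwise
#' before the distance computation.  Hierarchical clustering (default
#' Ward linkage) is cut to `k` groups; `"kmedoids"` uses partitioning around
#' medoids.  When reference labels are supplied, the adjusted Rand index
#' against them is reported.
#'
#' @param table A [labeling_index()] matrix (metabolites x samples).
#' @param k Number of clusters (default 2).
#' @param method `"hierarchical"` or `"kmedoids"`.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param labels Optional reference labels per sample.
#' @param seed Integer seed (k-medoids initialisation).
#' @return List of class `partition_result`: `assignment`, `k`, `method`,
#'   `tree` (hclust object or NULL), `ari`, `degenerate` flag.
#' @export
cluster_partition <- function(table, k = 2L, method = c("hierarchical", "kmedoids"),
                              linkage = "ward.D2", labels = NULL, seed = 1L) {
  method <- match.arg(method)
  mat <- unclass(table)
  valid <- !apply(is.na(mat), 1L, any)
  mat <- mat[valid, , drop = FALSE]
  n <- ncol(mat)
  if (k > n) stop("k (", k, ") exceeds number of samples (", n, ")")
  d <- stats::dist(t(mat))
  degenerate <- all(d < 1e-12)
  if (degenerate) warning("all samples identical: single effective cluster")
  tree <- NULL
  if (method == "hierarchical") {
    tree <- stats::hclust(d, method = linkage)
    assignment <- stats::cutree(tree, k = k)
  } else {
    assignment <- withr::with_seed(seed, cluster::pam(d, k = k, cluster.only = TRUE))
  }
  ari <- if (!is.null(labels)) adjusted_rand_index(assignment, labels) else NA_real_
  structure(list(assignment = assignment, k = k, method = method,
                 tree = tree, ari = ari, degenerate = degenerate,
                 n_metabolites_used = nrow(mat)),
            class = "partition_result")
}

#' Per-metabolite differential labeling between two groups
#'
#' Two-tailed Student's t test (pooled variance by default, Welch by flag)
#' on the fractional contributions of each metabolite, flagging metabolites
#' with uncorrected `p < alpha`.  No multiple-testing correction is applied
#' to the flag; Benjamini-Hochberg q-values are reported alongside.
#' Metabolites are tested wherever both groups have >= 2 valid values.
#'
#' @param table A [labeling_index()] matrix.
#' @param labels Two-level group labels per sample (column order).
#' @param alpha Significance threshold for the flag (default 0.05).
#' @param welch Use the Welch unequal-variance test instead of pooled.
#' @return `data.frame` of class `differential_labeling`: `metabolite,
#'   mean_a, mean_b, t, p, q, significant, degenerate`.
#' @export
differential_labeling <- function(table, labels, alpha = 0.05, welch = FALSE) {
  mat <- unclass(table)
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("exactly two groups required")
  if (length(labels) != ncol(mat)) stop("one label per sample required")
  ia <- labels == levels(labels)[1L]
  ib <- labels == levels(labels)[2L]
  res <- lapply(rownames(mat), function(met) {
    xa <- mat[met, ia]; xb <- mat[met, ib]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L) {
      return(data.frame(metabolite = met, mean_a = NA_real_, mean_b = NA_real_,
                        t = NA_real_, p = NA_real_, degenerate = TRUE))
    }
    na <- length(xa); nb <- length(xb)
    ma <- mean(xa); mb <- mean(xb)
    va <- stats::var(xa); vb <- stats::var(xb)
    degen <- FALSE
    if (welch) {
      se2 <- va / na + vb / nb
      if (se2 == 0) {
        tt <- 0; pp <- 1
        if (ma != mb) { pp <- 0; degen <- TRUE }
      } else {
        tt <- (ma - mb) / sqrt(se2)
        df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
        pp <- 2 * stats::pt(-abs(tt), df)
      }
    } else {
      sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
      if (sp2 == 0) {
        if (ma == mb) { tt <- 0; pp <- 1 } else { tt <- Inf * sign(ma - mb); pp <- 0; degen <- TRUE }
      } else {
        tt <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
        pp <- 2 * stats::pt(-abs(tt), na + nb - 2)
      }
    }
    data.frame(metabolite = met, mean_a = ma, mean_b = mb, t = tt, p = pp,
               degenerate = degen)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, "BH")
  out$significant <- !is.na(out$p) & out$p < alpha
  out <- out[, c("metabolite", "mean_a", "mean_b", "t", "p", "q",
                 "significant", "degenerate")]
  class(out) <- c("differential_labeling", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Chi-square over-representation of a metabolite category
#'
#' Builds the 2x2 table (significant / not) x (in category / not) over a
#' metabolite universe and tests independence with a Pearson chi-square
#' (df = 1), optionally Yates-corrected.  When any expected cell is below 1
#' a warning is raised and a Fisher exact p-value is reported alongside.
#'
#' @param significant Metabolites flagged differentially labeled.
#' @param category Metabolites in the category of interest (e.g. nucleotide
#'   precursors).
#' @param universe All tested metabolites.
#' @param correction `"none"` (default) or `"yates"`.
#' @return List of class `category_enrichment`: `table` (2x2), `chi2`, `df`,
#'   `p`, `fisher_p` (NA unless expected counts are small), `correction`.
#' @export
category_overrepresentation <- function(significant, category, universe,
                                        correction = c("none", "yates")) {
  correction <- match.arg(correction)
  significant <- unique(significant); category <- unique(category)
  universe <- unique(universe)
  if (length(universe) < 4L) stop("universe must contain >= 4 metabolites")
  if (!all(significant %in% universe)) stop("significant set not within universe")
  if (!all(category %in% universe)) stop("category not within universe")
  a <- length(intersect(significant, category))
  b <- length(setdiff(significant, category))
  cc <- length(setdiff(category, significant))
  d <- length(universe) - a - b - cc
  tab <- matrix(c(a, b, cc, d), 2L, byrow = TRUE,
                dimnames = list(c("significant", "not_significant"),
                                c("in_category", "not_in_category")))
  N <- sum(tab)
  margins_r <- rowSums(tab); margins_c <- colSums(tab)
  det <- a * d - b * cc
  num <- if (correction == "yates") max(abs(det) - N / 2, 0)^2 else det^2
  denom <- prod(margins_r) * prod(margins_c)
  chi2 <- if (denom == 0) 0 else N * num / denom
  p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
  expected <- outer(margins_r, margins_c) / N
  fisher_p <- NA_real_
  if (any(expected < 1)) {
    warning("expected cell count < 1; reporting Fisher exact p alongside")
    fisher_p <- stats::fisher.test(tab)$p.value
  }
  structure(list(table = tab, chi2 = chi2, df = 1L, p = p,
                 fisher_p = fisher_p, correction = correction),
            class = "category_enrichment")
}

#' @export
print.category_enrichment <- function(x, ...) {
  print(x$table)
  cat("chi-square =", round(x$chi2, 4), "(df 1), p =", format.pval(x$p), "\n")
  invisible(x)
}
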