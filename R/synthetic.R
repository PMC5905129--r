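#' Ground truth for a synthetic two-group expression dataset
#'
#' @param planted Named numeric vector: module id -> effect direction (+1 =
#'   enriched in the first phenotype class, -1 = in the second).  May be
#'   empty for a null dataset.
#' @param effect_size Group-mean shift in units of the within-group SD
#'   (>= 0).
#' @param classes Two phenotype class labels; defaults to a mutant/wildtype
#'   design.
#' @param seed Integer seed.
#' @return List of class `expression_truth`.
#' @export
expression_truth <- function(planted = numeric(0), effect_size = 0,
                             classes = c("MUT", "WT"), seed = 1L) {
  stopifnot(is.numeric(effect_size), length(effect_size) == 1L, effect_size >= 0,
            length(classes) == 2L, !anyDuplicated(classes))
  if (length(planted)) {
    stopifnot(!is.null(names(planted)), all(planted %in% c(-1, 1)))
  }
  structure(list(planted = planted, effect_size = effect_size,
                 classes = as.character(classes), seed = as.integer(seed)),
            class = "expression_truth")
}

#' Simulate a two-group expression dataset with planted module signal
#'
#' Background probe intensities are i.i.d. standard normal on the log scale
#' (microarray convention).  Every EC node in `node_sets` is assigned one
#' gene with 1-3 probesets; probes of genes in a planted module receive a
#' group-mean difference of `effect_size` (in noise-SD units) in the planted
#' direction.  Any probes beyond the annotated ones are unannotated
#' background.  Identical seed and parameters give a bitwise-identical
#' matrix.
#'
#' @param n_probes Total number of probes (must cover the annotation).
#' @param samples_per_group Integer pair: samples in the first and second
#'   phenotype class.
#' @param node_sets A [node_set_collection()]; its EC universe defines the
#'   annotation.
#' @param truth An [expression_truth()].
#' @return An [expression_dataset()].
#' @export
#' @examples
#' ns <- node_set_collection(list(m1 = paste0("ec", 1:5), m2 = paste0("ec", 6:10)))
#' ds <- gen_expression_dataset(60, c(5, 5), ns,
#'   expression_truth(c(m1 = 1), effect_size = 2, seed = 7))
gen_expression_dataset <- function(n_probes, samples_per_group, node_sets,
                                   truth = expression_truth()) {
  stopifnot(inherits(node_sets, "node_set_collection"),
            inherits(truth, "expression_truth"),
            length(samples_per_group) == 2L)
  samples_per_group <- as.integer(samples_per_group)
  if (any(samples_per_group < 1L)) stop("samples_per_group must be positive")
  missing_mod <- setdiff(names(truth$planted), names(node_sets))
  if (length(missing_mod)) {
    stop("planted module(s) absent from node_sets: ",
         paste(missing_mod, collapse = ", "))
  }
  ecs <- sort(unique(unlist(node_sets)))
  withr::with_seed(truth$seed, {
    probes_per_ec <- sample(1:3, length(ecs), replace = TRUE)
    if (all(probes_per_ec == 1L)) probes_per_ec[1L] <- 2L  # exercise collapsing
    n_annot <- sum(probes_per_ec)
    if (n_annot > n_probes) {
      stop("n_probes (", n_probes, ") too small for annotation (needs ",
           n_annot, ")")
    }
    n <- sum(samples_per_group)
    probe_ids <- sprintf("p%05d", seq_len(n_probes))
    genes <- paste0("g.", ecs)
    probe_gene <- data.frame(
      probe = probe_ids[seq_len(n_annot)],
      gene = rep(genes, probes_per_ec))
    gene_ec <- data.frame(gene = genes, ec = ecs)
    classes <- factor(rep(truth$classes, samples_per_group),
                      levels = truth$classes)
    X <- matrix(stats::rnorm(n_probes * n), n_probes, n,
                dimnames = list(probe_ids,
                                sprintf("s%03d_%s", seq_len(n), classes)))
    if (truth$effect_size > 0 && length(truth$planted)) {
      for (mod in names(truth$planted)) {
        dir <- truth$planted[[mod]]
        probes <- probe_gene$probe[probe_gene$gene %in%
                                     paste0("g.", node_sets[[mod]])]
        rows <- match(probes, probe_ids)
        shift <- dir * truth$effect_size / 2
        X[rows, classes == truth$classes[1L]] <-
          X[rows, classes == truth$classes[1L]] + shift
        X[rows, classes == truth$classes[2L]] <-
          X[rows, classes == truth$classes[2L]] - shift
      }
    }
  })
  expression_dataset(X, classes, probe_gene, gene_ec)
}

#' Ground truth for a synthetic tracer-labeling panel
#'
#' @param metabolites `data.frame(metabolite, formula)`.
#' @param fc Matrix of true fractional contributions, metabolites x groups
#'   (column names = group labels), or a single named vector for one group.
#'   All values in `[0, tracer_enrichment]`.
#' @param tracer_enrichment Fraction of tracer molecules labeled, in (0, 1];
#'   default 0.5 (a 50% labeled-glucose medium).
#' @param noise_sd Multiplicative log-normal replicate noise SD (default
#'   0.05, a typical LC-MS CV).
#' @param natural_abundance Convolve natural isotope abundance into the
#'   generated intensities?
#' @param base_intensity Expected total intensity per metabolite.
#' @param seed Integer seed.
#' @return List of class `flux_truth`.
#' @export
flux_truth <- function(metabolites, fc, tracer_enrichment = 0.5,
                       noise_sd = 0.05, natural_abundance = TRUE,
                       base_intensity = 1e6, seed = 1L) {
  stopifnot(all(c("metabolite", "formula") %in% names(metabolites)))
  if (is.null(dim(fc))) {
    fc <- matrix(fc, ncol = 1L,
                 dimnames = list(names(fc) %||% metabolites$metabolite, "all"))
  }
  stopifnot(nrow(fc) == nrow(metabolites), !is.null(colnames(fc)))
  if (is.null(rownames(fc))) rownames(fc) <- metabolites$metabolite
  if (any(fc < 0) || any(fc > 1)) stop("true fractional contributions must be in [0, 1]")
  if (tracer_enrichment <= 0 || tracer_enrichment > 1) {
    stop("tracer_enrichment must be in (0, 1]")
  }
  if (any(fc > tracer_enrichment + 1e-12)) {
    stop("true fractional contribution exceeds tracer enrichment (unreachable labeling)")
  }
  stopifnot(noise_sd >= 0)
  structure(list(metabolites = metabolites, fc = fc,
                 tracer_enrichment = tracer_enrichment, noise_sd = noise_sd,
                 natural_abundance = natural_abundance,
                 base_intensity = base_intensity, seed = as.integer(seed)),
            class = "flux_truth")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an isotopologue intensity panel under known fluxes
#'
#' For each metabolite and sample, the clean mass isotopologue distribution
#' is a binomial mixture: a fraction `fc / e` of molecules is tracer-derived
#' with per-atom labeling probability `e` (the tracer enrichment); the rest
#' sit at M+0.  Natural abundance is then (optionally) convolved in via the
#' forward correction matrix, intensities are scaled to `base_intensity` and
#' perturbed with multiplicative log-normal noise, and per-sample
#' internal-standard intensity and cell count are emitted.
#'
#' @param truth A [flux_truth()].
#' @param n_replicates Replicates per group (>= 1).
#' @return A [mid_panel()] whose samples carry the truth's group labels.
#' @export
gen_mid_panel <- function(truth, n_replicates = 3L) {
  stopifnot(inherits(truth, "flux_truth"), n_replicates >= 1L)
  groups <- colnames(truth$fc)
  e <- truth$tracer_enrichment
  samples <- data.frame(
    sample = paste0(rep(groups, each = n_replicates), "_r",
                    rep(seq_len(n_replicates), length(groups))),
    group = rep(groups, each = n_replicates))
  mets <- truth$metabolites
  withr::with_seed(truth$seed, {
    samples$internal_standard <- 1e5 * exp(stats::rnorm(nrow(samples), 0, truth$noise_sd))
    samples$cell_count <- pmax(1L, round(1e6 * exp(stats::rnorm(nrow(samples), 0, 0.1))))
    rows <- vector("list", nrow(mets) * nrow(samples))
    ri <- 0L
    for (mi in seq_len(nrow(mets))) {
      n <- parse_formula(mets$formula[mi])[["C"]]
      Cm <- if (truth$natural_abundance) {
        build_correction_matrix(mets$formula[mi])
      } else NULL
      tracer_mid <- stats::dbinom(0:n, n, e)
      for (si in seq_len(nrow(samples))) {
        f <- truth$fc[mi, samples$group[si]]
        p_tracer <- f / e
        clean <- (1 - p_tracer) * c(1, rep(0, n)) + p_tracer * tracer_mid
        obs <- if (is.null(Cm)) clean else as.numeric(Cm %*% clean)
        intens <- truth$base_intensity * obs
        if (truth$noise_sd > 0) {
          intens <- intens * exp(stats::rnorm(n + 1L, -truth$noise_sd^2 / 2,
                                              truth$noise_sd))
        }
        ri <- ri + 1L
        rows[[ri]] <- data.frame(metabolite = mets$metabolite[mi],
                                 isotopologue = 0:n,
                                 sample = samples$sample[si],
                                 intensity = intens)
      }
    }
  })
  mid_panel(mets[, c("metabolite", "formula")], do.call(rbind, rows),
            samples, tracer_enrichment = e)
}

#' Ground truth for a dual-tracer DNA-nucleoside panel
#'
#' Emulates DNA deoxycytidine labeled by fully labeled 13C-glucose (de novo
#' route, carbon shift in the deoxyribose) together with a [13C9,15N3]
#' deoxycytidine tracer (salvage route, three heavy nitrogens).
#'
#' @param f_preexisting,f_denovo,f_salvage Source fractions summing to 1.
#' @param scale Expected total intensity per sample.
#' @param noise_sd Multiplicative log-normal noise SD (default 0.05).
#' @param denovo_shift_probs Named probability vector over the de novo carbon
#'   mass shift; default a point mass at +5 (fully labeled deoxyribose).
#' @param group Group label attached to generated samples.
#' @param seed Integer seed.
#' @return List of class `source_truth`.
#' @export
source_truth <- function(f_preexisting, f_denovo, f_salvage, scale = 1e6,
                         noise_sd = 0.05, denovo_shift_probs = c("5" = 1),
                         group = "all", seed = 1L) {
  f <- c(f_preexisting, f_denovo, f_salvage)
  stopifnot(all(f >= 0), all(f <= 1))
  if (abs(sum(f) - 1) > 1e-12) stop("source fractions must sum to 1")
  stopifnot(scale > 0, noise_sd >= 0,
            abs(sum(denovo_shift_probs) - 1) < 1e-12,
            all(as.integer(names(denovo_shift_probs)) >= 3L))
  structure(list(f_preexisting = f_preexisting, f_denovo = f_denovo,
                 f_salvage = f_salvage, scale = scale, noise_sd = noise_sd,
                 denovo_shift_probs = denovo_shift_probs,
                 group = group, seed = as.integer(seed)),
            class = "source_truth")
}

#' Simulate a dual-tracer DNA deoxycytidine panel
#'
#' Distributes the total intensity across isotopologue channels:
#' pre-existing DNA at M+0 with no heavy nitrogen; de novo molecules at a
#' carbon shift drawn from the configured distribution (default +5) with no
#' heavy nitrogen; salvage molecules from the [13C9,15N3]dC tracer at carbon
#' shift +9 with 3 heavy nitrogens.  Multiplicative log-normal noise is
#' applied per channel; identical seed gives an identical panel.
#'
#' @param truth A [source_truth()].
#' @param n_samples Number of samples (>= 1).
#' @return Object of class `dual_tracer_panel`: list with `data`
#'   (`sample, carbon_shift, n15_count, intensity`) and `samples`
#'   (`sample, group`).
#' @export
gen_dual_tracer_panel <- function(truth, n_samples = 3L) {
  stopifnot(inherits(truth, "source_truth"), n_samples >= 1L)
  channels <- data.frame(
    carbon_shift = c(0L, as.integer(names(truth$denovo_shift_probs)), 9L),
    n15_count = c(0L, rep(0L, length(truth$denovo_shift_probs)), 3L),
    frac = c(truth$f_preexisting,
             truth$f_denovo * unname(truth$denovo_shift_probs),
             truth$f_salvage))
  withr::with_seed(truth$seed, {
    rows <- lapply(seq_len(n_samples), function(si) {
      noise <- if (truth$noise_sd > 0) {
        exp(stats::rnorm(nrow(channels), -truth$noise_sd^2 / 2, truth$noise_sd))
      } else rep(1, nrow(channels))
      data.frame(sample = sprintf("%s_r%d", truth$group, si),
                 carbon_shift = channels$carbon_shift,
                 n15_count = channels$n15_count,
                 intensity = truth$scale * channels$frac * noise)
    })
  })
  dual_tracer_panel(do.call(rbind, rows),
                    data.frame(sample = sprintf("%s_r%d", truth$group,
                                                seq_len(n_samples)),
                               group = truth$group))
}
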