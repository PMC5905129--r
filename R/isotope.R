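#' Default natural isotope abundance tables
#'
#' Per-element probability vectors over nominal mass shift (index 1 = M+0).
#' Values are standard terrestrial abundances; only shifts that matter at
#' unit-mass resolution are kept.
#'
#' @return Named list mapping element symbol to a numeric probability vector.
#' @export
natural_abundances <- function() {
  list(
    C = c(0.9893, 0.0107),
    H = c(0.999885, 0.000115),
    N = c(0.99636, 0.00364),
    O = c(0.99757, 0.00038, 0.00205),
    S = c(0.9499, 0.0075, 0.0425, 0.0001),
    P = 1
  )
}

#' Parse an elemental formula string
#'
#' @param formula Formula such as `"C6H12O6"` or `"C9H13N3O4"`.
#' @return Named integer vector of atom counts per element.
#' @export
#' @examples
#' parse_formula("C5H9NO2") # norvaline
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (!nzchar(paste(toks, collapse = "")) ||
      nchar(paste(toks, collapse = "")) != nchar(formula)) {
    stop("malformed formula: ", formula)
  }
  el <- sub("[0-9]*$", "", toks)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", toks),
                           sub("^[A-Za-z]+", "", toks), "1"))
  counts <- tapply(cnt, el, sum)
  storage.mode(counts) <- "integer"
  counts <- counts[unique(el)]
  counts
}

# convolve a shift distribution with itself n times (n atoms of one element),
# truncating at max_shift
.convolve_n <- function(dist, n, max_shift) {
  out <- 1
  for (i in seq_len(n)) {
    out <- .convolve_trunc(out, dist, max_shift)
  }
  out
}

.convolve_trunc <- function(a, b, max_shift) {
  la <- length(a); lb <- length(b)
  out <- numeric(min(la + lb - 1L, max_shift + 1L))
  for (j in seq_len(lb)) {
    lim <- length(out) - j + 1L
    if (lim < 1L) next
    idx <- seq_len(min(la, lim))
    out[idx + j - 1L] <- out[idx + j - 1L] + a[idx] * b[j]
  }
  out
}

#' Build a natural-abundance correction matrix
#'
#' Constructs the `(n+1) x (n+1)` matrix `C` whose entry `(i, j)` is the
#' probability that a molecule carrying `j` tracer-labeled atoms is observed
#' at nominal mass shift `i` (both zero-based).  The unlabeled `n - j` tracer
#' atoms contribute binomial natural abundance; every non-tracer atom
#' contributes its own natural mass-shift distribution, convolved in and
#' truncated at the modeled range, so columns sum to at most 1.
#'
#' @param formula Elemental formula string or named count vector.
#' @param tracer_element Element carrying the tracer label (default `"C"`).
#' @param abundances Per-element shift distributions, see
#'   [natural_abundances()].
#' @param n_atoms Number of traceable atoms; defaults to the tracer-element
#'   count in `formula`.
#' @return Matrix of class `correction_matrix`, lower-triangular in the
#'   labeled contribution.
#' @export
#' @examples
#' C1 <- build_correction_matrix("C1", abundances = list(C = c(0.989, 0.011)))
#' C1[, 1] # (0.989, 0.011)
build_correction_matrix <- function(formula, tracer_element = "C",
                                    abundances = natural_abundances(),
                                    n_atoms = NULL) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (!tracer_element %in% names(counts) || counts[[tracer_element]] < 1L) {
    stop("formula contains no ", tracer_element, " atoms")
  }
  unknown <- setdiff(names(counts), names(abundances))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  n <- if (is.null(n_atoms)) counts[[tracer_element]] else as.integer(n_atoms)
  if (n < 1L || n > counts[[tracer_element]]) {
    stop("n_atoms must be between 1 and the tracer-element count")
  }
  tr_dist <- abundances[[tracer_element]]
  p_heavy <- if (length(tr_dist) >= 2L) sum(tr_dist[-1L]) else 0

  # shift distribution of all atoms that are never tracer-labeled
  other <- 1
  for (el in names(counts)) {
    m <- counts[[el]] - if (el == tracer_element) n else 0L
    if (m > 0L) other <- .convolve_trunc(other, .convolve_n(abundances[[el]], m, n), n)
  }
  C <- matrix(0, n + 1L, n + 1L)
  for (j in 0:n) {
    # binomial NA of the n - j unlabeled tracer atoms (unit shift each)
    base <- stats::dbinom(0:(n - j), n - j, p_heavy)
    col <- .convolve_trunc(base, other, n - j)
    C[(j + seq_along(col)), j + 1L] <- col
  }
  structure(C, class = c("correction_matrix", "matrix"),
            tracer_element = tracer_element, n_atoms = n)
}

#' Remove natural-abundance signal from a measured MID
#'
#' Solves `C x = raw` for the natural-abundance-free isotopologue vector.
#' The triangular system is solved exactly; if the solution has negative
#' components (measurement noise), they are clipped to zero and the vector is
#' renormalised to the raw total so no intensity is invented.
#'
#' @param raw Observed isotopologue intensity vector (length `n + 1`).
#' @param C A [build_correction_matrix()] result.
#' @return Corrected non-negative isotopologue vector.
#' @export
correct_natural_abundance <- function(raw, C) {
  stopifnot(is.numeric(raw), length(raw) == nrow(C))
  if (!all(is.finite(raw)) || any(raw < 0)) stop("raw intensities must be finite and >= 0")
  if (sum(raw) == 0) return(raw)
  kap <- kappa(C, exact = FALSE)
  if (!is.finite(kap) || kap > 1e12) {
    stop("correction matrix is ill-conditioned (condition number ", format(kap), ")")
  }
  x <- as.numeric(qr.solve(C, raw))
  if (any(x < 0)) {
    x <- pmax(x, 0)
    s <- sum(x)
    if (s > 0) x <- x * (sum(raw) / s)
  }
  x
}

#' Relative metabolite amount
#'
#' Total isotopologue signal normalised to the internal-standard intensity
#' (e.g. spiked norvaline) and the cell count, giving an arbitrary per-cell
#' abundance comparable across runs.
#'
#' @param mid Isotopologue intensity vector.
#' @param internal_standard Internal-standard intensity, > 0.
#' @param cell_count Number of cells in the extract, > 0.
#' @return Scalar relative amount.
#' @export
relative_amount <- function(mid, internal_standard, cell_count) {
  stopifnot(is.numeric(mid), all(mid >= 0))
  if (!is.numeric(internal_standard) || internal_standard <= 0) {
    stop("internal_standard must be > 0")
  }
  if (!is.numeric(cell_count) || cell_count <= 0) stop("cell_count must be > 0")
  sum(mid) / (internal_standard * cell_count)
}

#' Fractional contribution of the tracer to a metabolite
#'
#' The single "percent label" summarising a mass isotopologue distribution.
#' Mode `"fractional"` is the atom-weighted average labeling
#' `sum(i * M_i) / (n * sum(M_i))`; mode `"one_minus_m0"` is the fraction of
#' molecules carrying at least one label, `1 - M_0 / sum(M_i)`.
#'
#' @param mid Isotopologue intensity vector `M_0 .. M_n`.
#' @param n_atoms Number of traceable atoms (`length(mid) - 1` expected).
#' @param mode `"fractional"` (default) or `"one_minus_m0"`.
#' @return Scalar in `[0, 1]`.
#' @export
fractional_contribution <- function(mid, n_atoms = length(mid) - 1L,
                                    mode = c("fractional", "one_minus_m0")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(mid), n_atoms >= 1L, length(mid) == n_atoms + 1L)
  if (any(mid < 0) || !all(is.finite(mid))) stop("intensities must be finite and >= 0")
  tot <- sum(mid)
  if (tot == 0) stop("zero total intensity: fractional contribution undefined")
  if (mode == "fractional") {
    sum((seq_along(mid) - 1L) * mid) / (n_atoms * tot)
  } else {
    1 - mid[1L] / tot
  }
}

#' Rescale a fractional contribution by the tracer enrichment
#'
#' When the medium contains only a fraction `e` of labeled tracer (e.g. 50%
#' 13C-glucose), the raw fractional contribution saturates at `e`; dividing by
#' `e` rescales to the fraction of the metabolite's carbon derived from the
#' tracer nutrient.  Values marginally above `e` (noise) are clipped to 1
#' with a warning.
#'
#' @param fc Raw fractional contribution.
#' @param e Tracer enrichment in `(0, 1]`.
#' @return `min(fc / e, 1)`.
#' @export
normalize_tracer_enrichment <- function(fc, e) {
  if (!is.numeric(e) || length(e) != 1L || e <= 0 || e > 1) {
    stop("tracer enrichment must be in (0, 1]")
  }
  stopifnot(is.numeric(fc), all(fc >= 0))
  out <- fc / e
  if (any(out > 1)) {
    warning("fractional contribution exceeds tracer enrichment; clipping to 1")
    out <- pmin(out, 1)
  }
  out
}

# ---- MID panel container ----------------------------------------------------

#' Construct a MID panel
#'
#' Container for per-metabolite isotopologue intensities across samples,
#' with elemental formulas, per-sample internal-standard intensity and cell
#' count, and the tracer enrichment of the labeling medium.
#'
#' @param metabolites `data.frame(metabolite, formula)`; one row per
#'   metabolite, formulas as strings.
#' @param data Long `data.frame(metabolite, isotopologue, sample, intensity)`
#'   with zero-based isotopologue index.
#' @param samples `data.frame(sample, group, internal_standard, cell_count)`.
#' @param tracer_enrichment Fraction of tracer molecules labeled, in (0, 1].
#' @param tracer_element Element carrying the label.
#' @return Object of class `mid_panel`.
#' @export
mid_panel <- function(metabolites, data, samples, tracer_enrichment = 1,
                      tracer_element = "C") {
  stopifnot(all(c("metabolite", "formula") %in% names(metabolites)),
            all(c("metabolite", "isotopologue", "sample", "intensity") %in% names(data)),
            all(c("sample", "internal_standard", "cell_count") %in% names(samples)))
  if (anyDuplicated(metabolites$metabolite)) stop("duplicate metabolite ids")
  if (anyDuplicated(samples$sample)) stop("duplicate sample ids")
  if (any(!is.finite(data$intensity)) || any(data$intensity < 0)) {
    stop("intensities must be finite and >= 0")
  }
  if (any(samples$internal_standard <= 0)) stop("internal_standard must be > 0")
  if (any(samples$cell_count <= 0)) stop("cell_count must be > 0")
  metabolites$n_atoms <- vapply(metabolites$formula, function(f) {
    cnt <- parse_formula(f)
    if (!tracer_element %in% names(cnt)) {
      stop("metabolite formula ", f, " lacks tracer element ", tracer_element)
    }
    as.integer(cnt[[tracer_element]])
  }, integer(1))
  structure(list(metabolites = metabolites, data = data, samples = samples,
                 tracer_enrichment = tracer_enrichment,
                 tracer_element = tracer_element),
            class = "mid_panel")
}

#' @export
print.mid_panel <- function(x, ...) {
  cat("MID panel:", nrow(x$metabolites), "metabolites x",
      nrow(x$samples), "samples; tracer", x$tracer_element,
      "at enrichment", x$tracer_enrichment, "\n")
  invisible(x)
}

# extract the isotopologue matrix (rows M+0..M+n, cols samples) of one metabolite;
# missing rows are zero-filled with a warning, as vendor exports often drop them
.mid_matrix <- function(panel, metabolite, warn_missing = TRUE) {
  meta <- panel$metabolites
  n <- meta$n_atoms[match(metabolite, meta$metabolite)]
  d <- panel$data[panel$data$metabolite == metabolite, , drop = FALSE]
  samp <- panel$samples$sample
  mat <- matrix(0, n + 1L, length(samp), dimnames = list(NULL, samp))
  idx <- cbind(d$isotopologue + 1L, match(d$sample, samp))
  if (any(d$isotopologue > n)) stop("isotopologue index exceeds atom count for ", metabolite)
  mat[idx] <- d$intensity
  expected <- (n + 1L) * length(samp)
  if (warn_missing && nrow(d) < expected) {
    warning("metabolite ", metabolite, ": ", expected - nrow(d),
            " missing isotopologue rows treated as zero intensity")
  }
  mat
}

#' Natural-abundance correct every MID in a panel
#'
#' @param panel A [mid_panel()].
#' @param abundances Isotope table, see [natural_abundances()].
#' @return A new `mid_panel` with corrected intensities.
#' @export
correct_panel <- function(panel, abundances = natural_abundances()) {
  stopifnot(inherits(panel, "mid_panel"))
  out <- lapply(panel$metabolites$metabolite, function(met) {
    mat <- .mid_matrix(panel, met, warn_missing = FALSE)
    C <- build_correction_matrix(
      panel$metabolites$formula[match(met, panel$metabolites$metabolite)],
      tracer_element = panel$tracer_element, abundances = abundances)
    corr <- apply(mat, 2L, correct_natural_abundance, C = C)
    data.frame(metabolite = met,
               isotopologue = rep(0:(nrow(mat) - 1L), ncol(mat)),
               sample = rep(colnames(mat), each = nrow(mat)),
               intensity = as.numeric(corr))
  })
  panel$data <- do.call(rbind, out)
  panel
}

#' Labeling-index table of a panel
#'
#' Computes the per-(metabolite, sample) fractional contribution, returning a
#' metabolite-by-sample matrix with a per-metabolite validity flag (a
#' metabolite is invalid if any sample has zero total intensity).
#'
#' @param panel A [mid_panel()], usually after [correct_panel()].
#' @param mode Passed to [fractional_contribution()].
#' @param normalize_enrichment If `TRUE`, divide by the panel's tracer
#'   enrichment via [normalize_tracer_enrichment()]; off by default so that
#'   raw indices are clustered, matching a 50%-tracer design.
#' @return Matrix of class `labeling_index` with attribute `valid`.
#' @export
labeling_index <- function(panel, mode = c("fractional", "one_minus_m0"),
                           normalize_enrichment = FALSE) {
  stopifnot(inherits(panel, "mid_panel"))
  mode <- match.arg(mode)
  mets <- panel$metabolites$metabolite
  fc <- matrix(NA_real_, length(mets), nrow(panel$samples),
               dimnames = list(mets, panel$samples$sample))
  for (met in mets) {
    mat <- .mid_matrix(panel, met)
    n <- nrow(mat) - 1L
    fc[met, ] <- apply(mat, 2L, function(v) {
      if (sum(v) == 0) NA_real_ else fractional_contribution(v, n, mode)
    })
  }
  if (normalize_enrichment) {
    fc[] <- suppressWarnings(normalize_tracer_enrichment(
      pmin(fc, 1), panel$tracer_enrichment))
  }
  structure(fc, valid = !apply(is.na(fc), 1L, any), class = c("labeling_index", "matrix"))
}

#' Relative amounts of all metabolites in a panel
#'
#' @param panel A [mid_panel()].
#' @return Metabolite-by-sample matrix of per-cell relative amounts.
#' @export
relative_amounts <- function(panel) {
  stopifnot(inherits(panel, "mid_panel"))
  mets <- panel$metabolites$metabolite
  out <- matrix(NA_real_, length(mets), nrow(panel$samples),
                dimnames = list(mets, panel$samples$sample))
  for (met in mets) {
    mat <- .mid_matrix(panel, met, warn_missing = FALSE)
    out[met, ] <- colSums(mat) /
      (panel$samples$internal_standard * panel$samples$cell_count)
  }
  out
}
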