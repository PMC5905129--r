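#' Read a GCT 1.2 expression matrix
#'
#' @param path File path.
#' @return Numeric matrix (probes x samples) with a `description` attribute.
#' @export
read_gct <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3L || trimws(lines[1L]) != "#1.2") {
    stop("not a GCT 1.2 file (line 1): ", path)
  }
  dims <- as.integer(strsplit(lines[2L], "\t")[[1L]])
  if (length(dims) < 2L || anyNA(dims)) stop("malformed GCT dimension line (line 2)")
  body <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                            stringsAsFactors = FALSE)
  if (nrow(body) != dims[1L] || ncol(body) - 2L != dims[2L]) {
    stop("GCT declares ", dims[1L], " x ", dims[2L], " but body is ",
         nrow(body), " x ", ncol(body) - 2L)
  }
  if (anyDuplicated(body[[1L]])) stop("duplicate row ids in GCT")
  mat <- as.matrix(body[, -(1:2), drop = FALSE])
  rownames(mat) <- body[[1L]]
  attr(mat, "description") <- body[[2L]]
  mat
}

#' Write a GCT 1.2 expression matrix
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output path.
#' @param description Optional per-row description column.
#' @export
write_gct <- function(mat, path, description = rownames(mat)) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(mat), ncol(mat), sep = "\t")), con)
  df <- data.frame(NAME = rownames(mat), Description = description,
                   mat, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-class CLS phenotype file
#'
#' @param path File path.
#' @return Factor of per-sample class labels (first declared class first).
#' @export
read_cls <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("CLS file needs 3 lines: ", path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "[ \t]+")[[1L]])
  classes <- strsplit(trimws(sub("^#\\s*", "", lines[2L])), "[ \t]+")[[1L]]
  labels <- strsplit(trimws(lines[3L]), "[ \t]+")[[1L]]
  if (length(classes) != 2L) stop("exactly two classes required in CLS")
  if (!is.na(hdr[1L]) && hdr[1L] != length(labels)) {
    stop("CLS declares ", hdr[1L], " samples but lists ", length(labels))
  }
  # labels may be class names or 0/1 indices
  if (all(labels %in% classes)) {
    factor(labels, levels = classes)
  } else {
    factor(classes[as.integer(labels) + 1L], levels = classes)
  }
}

#' Write a two-class CLS phenotype file
#'
#' @param classes Factor of per-sample labels (two levels).
#' @param path Output path.
#' @export
write_cls <- function(classes, path) {
  classes <- as.factor(classes)
  stopifnot(nlevels(classes) == 2L)
  writeLines(c(paste(length(classes), 2L, 1L),
               paste("#", paste(levels(classes), collapse = " ")),
               paste(as.character(classes), collapse = " ")), path)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path File path; one set per line: name, description, members
#'   (tab-separated).
#' @return A [node_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 3L)
  if (length(bad)) stop("GMT line ", bad[1L], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  node_set_collection(sets, vapply(fields, `[[`, "", 2L))
}

#' Write gene sets in GMT format
#'
#' @param collection A [node_set_collection()].
#' @param path Output path.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "descriptions")
  writeLines(vapply(names(collection), function(id) {
    paste(c(id, desc[[id]], collection[[id]]), collapse = "\t")
  }, ""), path)
  invisible(path)
}

#' Read a MID panel from long-format CSVs
#'
#' @param data_path CSV with columns `metabolite, formula, isotopologue_index,
#'   sample, intensity`.
#' @param samples_path CSV with columns `sample, internal_standard_intensity,
#'   cell_count` and optionally `group`.
#' @param tracer_enrichment Tracer enrichment of the labeling medium.
#' @return A [mid_panel()].
#' @export
read_mid_csv <- function(data_path, samples_path, tracer_enrichment = 1) {
  d <- utils::read.csv(data_path, stringsAsFactors = FALSE)
  need <- c("metabolite", "formula", "isotopologue_index", "sample", "intensity")
  if (!all(need %in% names(d))) {
    stop("MID CSV must have columns: ", paste(need, collapse = ", "))
  }
  s <- utils::read.csv(samples_path, stringsAsFactors = FALSE)
  need_s <- c("sample", "internal_standard_intensity", "cell_count")
  if (!all(need_s %in% names(s))) {
    stop("sample CSV must have columns: ", paste(need_s, collapse = ", "))
  }
  mets <- unique(d[, c("metabolite", "formula")])
  if (anyDuplicated(mets$metabolite)) stop("metabolite with conflicting formulas")
  samples <- data.frame(sample = s$sample,
                        group = s$group %||% "all",
                        internal_standard = s$internal_standard_intensity,
                        cell_count = s$cell_count)
  mid_panel(mets,
            data.frame(metabolite = d$metabolite,
                       isotopologue = d$isotopologue_index,
                       sample = d$sample, intensity = d$intensity),
            samples, tracer_enrichment = tracer_enrichment)
}

#' Write a MID panel to long-format CSVs
#'
#' @param panel A [mid_panel()].
#' @param data_path,samples_path Output paths.
#' @export
write_mid_csv <- function(panel, data_path, samples_path) {
  stopifnot(inherits(panel, "mid_panel"))
  d <- panel$data
  d$formula <- panel$metabolites$formula[match(d$metabolite,
                                               panel$metabolites$metabolite)]
  out <- data.frame(metabolite = d$metabolite, formula = d$formula,
                    isotopologue_index = d$isotopologue,
                    sample = d$sample, intensity = d$intensity)
  utils::write.csv(out, data_path, row.names = FALSE, quote = FALSE)
  s <- panel$samples
  utils::write.csv(
    data.frame(sample = s$sample, group = s$group %||% "all",
               internal_standard_intensity = s$internal_standard,
               cell_count = s$cell_count),
    samples_path, row.names = FALSE, quote = FALSE)
  invisible(data_path)
}

#' Read a dual-tracer panel from CSV
#'
#' @param path CSV with columns `sample, carbon_shift, n15_count, intensity`.
#' @param labels_path Optional CSV with columns `sample, group`.
#' @return A [dual_tracer_panel()].
#' @export
read_dual_tracer_csv <- function(path, labels_path = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "carbon_shift", "n15_count", "intensity")
  if (!all(need %in% names(d))) {
    stop("dual-tracer CSV must have columns: ", paste(need, collapse = ", "))
  }
  samples <- if (!is.null(labels_path)) {
    utils::read.csv(labels_path, stringsAsFactors = FALSE)
  } else NULL
  dual_tracer_panel(d, samples)
}

#' Write a dual-tracer panel to CSV
#'
#' @param panel A [dual_tracer_panel()].
#' @param path Output path.
#' @param labels_path Optional path for the sample -> group table.
#' @export
write_dual_tracer_csv <- function(panel, path, labels_path = NULL) {
  utils::write.csv(panel$data, path, row.names = FALSE, quote = FALSE)
  if (!is.null(labels_path)) {
    utils::write.csv(panel$samples, labels_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read/write a labeling-index matrix as TSV
#'
#' @param table A [labeling_index()] matrix.
#' @param path Output path.
#' @export
write_labeling_index <- function(table, path) {
  df <- data.frame(metabolite = rownames(table), unclass(table),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_labeling_index
#' @export
read_labeling_index <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  structure(mat, valid = !apply(is.na(mat), 1L, any),
            class = c("labeling_index", "matrix"))
}
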