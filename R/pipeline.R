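# stage names in dependency order; run_pipeline executes the selected subset
.stage_order <- c("simulate", "gsea", "concordance", "mid", "labeling_stats",
                  "nucleotide_sources")

.allowed_stage_keys <- list(
  simulate = c("expression", "mid", "dualtracer"),
  gsea = c("expr", "cls", "probe_map", "ec_map", "gmt", "n_perm", "seed",
           "min_nodes", "max_nodes", "weight_exponent", "perm_mode", "out"),
  concordance = c("a", "b", "tau", "out"),
  mid = c("input", "samples", "correct_na", "mode", "tracer_enrichment",
          "normalize_enrichment", "out_index", "out_amounts"),
  labeling_stats = c("index", "labels", "categories", "alpha", "k", "method",
                     "linkage", "seed", "out_partition", "out_differential",
                     "out_enrichment"),
  nucleotide_sources = c("input", "labels", "denovo_min_shift", "out",
                         "out_summary"))

#' Read a pipeline run configuration
#'
#' Configurations are YAML or JSON with top-level keys `seed`, `output_dir`
#' and `stages`; every seed is explicit (no wall-clock seeding).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Validated configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Configuration list.
#' @export
validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), c("seed", "output_dir", "stages"))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) stop("config must set an explicit seed")
  if (is.null(cfg$output_dir)) stop("config must set output_dir")
  if (is.null(cfg$stages) || !length(cfg$stages)) stop("config selects no stages")
  bad_stage <- setdiff(names(cfg$stages), .stage_order)
  if (length(bad_stage)) stop("unknown stage(s): ", paste(bad_stage, collapse = ", "))
  for (st in names(cfg$stages)) {
    unknown <- setdiff(names(cfg$stages[[st]]), .allowed_stage_keys[[st]])
    if (length(unknown)) {
      stop("unknown key(s) in stage '", st, "': ", paste(unknown, collapse = ", "))
    }
  }
  cfg
}

.resolve <- function(path, outdir) {
  if (file.exists(path)) path else file.path(outdir, path)
}

.require_input <- function(path, stage, what) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' is missing required input '", what, "': ", path)
  }
  path
}

#' Execute a multi-stage analysis run
#'
#' Runs the selected stages in dependency order (simulate, gsea,
#' concordance, mid, labeling_stats, nucleotide_sources), writing all
#' outputs under `output_dir` together with a manifest JSON recording the
#' package version, parameters, seeds, input checksums and per-stage output
#' paths.  Two runs with identical configuration and inputs produce
#' identical result files; only the manifest timestamp differs.
#'
#' @param config Configuration list (see [read_run_config()]) or a path to a
#'   YAML/JSON config file.
#' @return The manifest, invisibly; also written to
#'   `output_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_run_config(config) else validate_run_config(config)
  outdir <- cfg$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "spheretrace",
    version = as.character(utils::packageVersion("spheretrace")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed, stages = list())
  for (st in intersect(.stage_order, names(cfg$stages))) {
    params <- cfg$stages[[st]]
    message("[spheretrace] stage ", st)
    rec <- switch(st,
      simulate = .stage_simulate(params, cfg, outdir),
      gsea = .stage_gsea(params, cfg, outdir),
      concordance = .stage_concordance(params, outdir),
      mid = .stage_mid(params, outdir),
      labeling_stats = .stage_labeling(params, cfg, outdir),
      nucleotide_sources = .stage_sources(params, outdir))
    rec$parameters <- params
    rec$output_md5 <- as.list(tools::md5sum(unlist(rec$outputs)))
    manifest$stages[[st]] <- rec
  }
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(manifest)
}

.stage_simulate <- function(params, cfg, outdir) {
  outputs <- list(); warnings <- character()
  if (!is.null(params$expression)) {
    p <- params$expression
    gmt <- read_gmt(.require_input(.resolve(p$gmt, outdir), "simulate", "gmt"))
    planted <- stats::setNames(as.numeric(unlist(p$planted)), names(p$planted))
    ds <- gen_expression_dataset(
      p$n_probes, unlist(p$samples_per_group), gmt,
      expression_truth(planted, p$effect_size %||% 0,
                       seed = p$seed %||% cfg$seed))
    write_gct(ds$exprs, file.path(outdir, "expression.gct"))
    write_cls(ds$classes, file.path(outdir, "expression.cls"))
    utils::write.table(ds$probe_gene, file.path(outdir, "probe_gene.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ds$gene_ec, file.path(outdir, "gene_ec.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(planted = as.list(planted),
                              effect_size = p$effect_size %||% 0),
                         file.path(outdir, "expression_truth.json"),
                         auto_unbox = TRUE)
    outputs$expression <- file.path(outdir, c("expression.gct", "expression.cls",
                                              "probe_gene.tsv", "gene_ec.tsv",
                                              "expression_truth.json"))
  }
  if (!is.null(params$mid)) {
    p <- params$mid
    mets <- data.frame(metabolite = unlist(p$metabolites),
                       formula = unlist(p$formulas))
    fc <- do.call(cbind, lapply(p$fc, unlist))
    rownames(fc) <- mets$metabolite
    truth <- flux_truth(mets, fc,
                        tracer_enrichment = p$tracer_enrichment %||% 0.5,
                        noise_sd = p$noise_sd %||% 0.05,
                        seed = p$seed %||% cfg$seed)
    panel <- gen_mid_panel(truth, p$n_replicates %||% 3L)
    write_mid_csv(panel, file.path(outdir, "mid.csv"),
                  file.path(outdir, "mid_samples.csv"))
    jsonlite::write_json(list(fc = apply(fc, 2L, as.list),
                              tracer_enrichment = truth$tracer_enrichment),
                         file.path(outdir, "mid_truth.json"), auto_unbox = TRUE)
    outputs$mid <- file.path(outdir, c("mid.csv", "mid_samples.csv",
                                       "mid_truth.json"))
  }
  if (!is.null(params$dualtracer)) {
    p <- params$dualtracer
    truth <- source_truth(p$f_preexisting, p$f_denovo, p$f_salvage,
                          noise_sd = p$noise_sd %||% 0.05,
                          group = p$group %||% "all",
                          seed = p$seed %||% cfg$seed)
    panel <- gen_dual_tracer_panel(truth, p$n_samples %||% 3L)
    write_dual_tracer_csv(panel, file.path(outdir, "dualtracer.csv"),
                          file.path(outdir, "dualtracer_labels.csv"))
    jsonlite::write_json(truth[c("f_preexisting", "f_denovo", "f_salvage")],
                         file.path(outdir, "dualtracer_truth.json"),
                         auto_unbox = TRUE)
    outputs$dualtracer <- file.path(outdir, c("dualtracer.csv",
                                              "dualtracer_labels.csv",
                                              "dualtracer_truth.json"))
  }
  list(outputs = outputs)
}

.read_expr_any <- function(path) {
  first <- readLines(path, n = 1L)
  if (trimws(first) == "#1.2") return(read_gct(path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat
}

.stage_gsea <- function(params, cfg, outdir) {
  expr <- .read_expr_any(.require_input(.resolve(params$expr, outdir), "gsea", "expr"))
  cls <- read_cls(.require_input(.resolve(params$cls, outdir), "gsea", "cls"))
  pg <- utils::read.delim(.require_input(.resolve(params$probe_map, outdir),
                                         "gsea", "probe_map"))
  ge <- utils::read.delim(.require_input(.resolve(params$ec_map, outdir),
                                         "gsea", "ec_map"))
  gmt <- read_gmt(.require_input(.resolve(params$gmt, outdir), "gsea", "gmt"))
  ds <- expression_dataset(expr, cls, pg, ge)
  ranked <- collapse_to_nodes(ds)
  keep <- filter_modules(gmt, ranked, params$min_nodes %||% 3L,
                         params$max_nodes %||% 500L)
  res <- run_gsea(ds, keep, n_perm = params$n_perm %||% 1000L,
                  seed = params$seed %||% cfg$seed,
                  weight_exponent = params$weight_exponent %||% 1,
                  perm_mode = params$perm_mode %||% "auto")
  out <- file.path(outdir, params$out %||% "gsea.tsv")
  utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  list(outputs = list(gsea = out))
}

.stage_concordance <- function(params, outdir) {
  a <- utils::read.delim(.require_input(.resolve(params$a, outdir), "concordance", "a"))
  b <- utils::read.delim(.require_input(.resolve(params$b, outdir), "concordance", "b"))
  conc <- cross_dataset_concordance(a, b, tau = params$tau %||% 1.2)
  out_json <- file.path(outdir, params$out %||% "concordance.json")
  out_tsv <- sub("\\.json$", ".tsv", out_json)
  jsonlite::write_json(conc[c("pearson", "spearman", "shared_up",
                              "shared_down", "tau")],
                       out_json, auto_unbox = TRUE, digits = NA)
  utils::write.table(conc$pairs, out_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(outputs = list(json = out_json, pairs = out_tsv))
}

.stage_mid <- function(params, outdir) {
  panel <- read_mid_csv(
    .require_input(.resolve(params$input, outdir), "mid", "input"),
    .require_input(.resolve(params$samples, outdir), "mid", "samples"),
    tracer_enrichment = params$tracer_enrichment %||% 1)
  if (params$correct_na %||% TRUE) panel <- correct_panel(panel)
  idx <- labeling_index(panel, mode = params$mode %||% "fractional",
                        normalize_enrichment = params$normalize_enrichment %||% FALSE)
  amounts <- relative_amounts(panel)
  out_index <- file.path(outdir, params$out_index %||% "labeling_index.tsv")
  out_amounts <- file.path(outdir, params$out_amounts %||% "relative_amounts.tsv")
  write_labeling_index(idx, out_index)
  utils::write.table(data.frame(metabolite = rownames(amounts), amounts,
                                check.names = FALSE),
                     out_amounts, sep = "\t", quote = FALSE, row.names = FALSE)
  list(outputs = list(index = out_index, amounts = out_amounts))
}

.stage_labeling <- function(params, cfg, outdir) {
  idx <- read_labeling_index(.require_input(.resolve(params$index, outdir),
                                            "labeling_stats", "index"))
  lab <- utils::read.csv(.require_input(.resolve(params$labels, outdir),
                                        "labeling_stats", "labels"))
  groups <- lab$group[match(colnames(idx), lab$sample)]
  part <- cluster_partition(idx, k = params$k %||% 2L,
                            method = params$method %||% "hierarchical",
                            linkage = params$linkage %||% "ward.D2",
                            labels = groups, seed = params$seed %||% cfg$seed)
  diff <- differential_labeling(idx, groups, alpha = params$alpha %||% 0.05)
  out_part <- file.path(outdir, params$out_partition %||% "partition.json")
  out_diff <- file.path(outdir, params$out_differential %||% "differential.tsv")
  jsonlite::write_json(list(assignment = as.list(part$assignment),
                            k = part$k, ari = part$ari,
                            merge_heights = if (!is.null(part$tree)) part$tree$height,
                            degenerate = part$degenerate),
                       out_part, auto_unbox = TRUE, digits = NA)
  utils::write.table(diff, out_diff, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- list(partition = out_part, differential = out_diff)
  if (!is.null(params$categories)) {
    cat_df <- utils::read.csv(.resolve(params$categories, outdir))
    enr <- category_overrepresentation(
      diff$metabolite[diff$significant], cat_df$metabolite, diff$metabolite)
    out_enr <- file.path(outdir, params$out_enrichment %||% "enrichment.json")
    jsonlite::write_json(list(table = as.list(as.data.frame(enr$table)),
                              chi2 = enr$chi2, p = enr$p),
                         out_enr, auto_unbox = TRUE, digits = NA)
    outputs$enrichment <- out_enr
  }
  list(outputs = outputs)
}

.stage_sources <- function(params, outdir) {
  panel <- read_dual_tracer_csv(
    .require_input(.resolve(params$input, outdir), "nucleotide_sources", "input"),
    if (!is.null(params$labels)) .resolve(params$labels, outdir))
  part <- source_fractions(panel, denovo_min_shift = params$denovo_min_shift %||% 3L)
  out <- file.path(outdir, params$out %||% "source_fractions.tsv")
  out_summary <- file.path(outdir, params$out_summary %||% "source_summary.json")
  utils::write.table(part$per_sample, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(part$group_summary, out_summary, auto_unbox = TRUE,
                       digits = NA)
  list(outputs = list(fractions = out, summary = out_summary))
}

# ---- command-line front end -------------------------------------------------

.parse_cli <- function(args) {
  opts <- list(); positional <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--no-")) {
      opts[[gsub("-", "_", substring(a, 6L))]] <- FALSE
    } else if (startsWith(a, "--")) {
      key <- gsub("-", "_", substring(a, 3L))
      if (i < length(args) && !startsWith(args[i + 1L], "--")) {
        opts[[key]] <- args[i + 1L]; i <- i + 1L
      } else {
        opts[[key]] <- TRUE
      }
    } else {
      positional <- c(positional, a)
    }
    i <- i + 1L
  }
  list(opts = opts, positional = positional)
}

.cli_num <- function(x, default) if (is.null(x)) default else as.numeric(x)

#' Command-line entry point
#'
#' Dispatches the `spheretrace` subcommands (`run`, `gsea`, `concordance`,
#' `mid`, `labeling-stats`, `nucleotide-sources`, `simulate`); invoke as
#' `Rscript -e 'spheretrace::spheretrace_main()' <subcommand> [flags]` or
#' through the installed `exec/spheretrace` script.
#'
#' @param args Character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Exit status, invisibly.
#' @export
spheretrace_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1L] %in% c("--help", "-h")) {
    cat("usage: spheretrace {run|simulate|gsea|concordance|mid|labeling-stats|nucleotide-sources} [--flags]\n")
    return(invisible(0L))
  }
  if (args[1L] == "--version") {
    cat("spheretrace", as.character(utils::packageVersion("spheretrace")), "\n")
    return(invisible(0L))
  }
  cmd <- args[1L]
  parsed <- .parse_cli(args[-1L])
  o <- parsed$opts
  seed <- as.integer(.cli_num(o$seed, 1))
  outdir <- o$out_dir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  switch(cmd,
    run = run_pipeline(o$config %||% stop("run requires --config")),
    simulate = {
      what <- parsed$positional[1L] %||% stop("simulate requires a target")
      stage <- stats::setNames(list(switch(what,
        expression = list(n_probes = as.integer(.cli_num(o$n_probes, 500)),
                          samples_per_group = c(as.integer(.cli_num(o$n_a, 10)),
                                                as.integer(.cli_num(o$n_b, 10))),
                          gmt = o$gmt %||% stop("--gmt required"),
                          effect_size = .cli_num(o$effect_size, 0),
                          seed = seed),
        mid = stop("mid simulation via CLI requires a config file; use 'run'"),
        dualtracer = list(f_preexisting = .cli_num(o$f_preexisting, 0.4),
                          f_denovo = .cli_num(o$f_denovo, 0.3),
                          f_salvage = .cli_num(o$f_salvage, 0.3),
                          n_samples = as.integer(.cli_num(o$n_samples, 3)),
                          seed = seed),
        stop("unknown simulate target: ", what))), what)
      run_pipeline(list(seed = seed, output_dir = outdir,
                        stages = list(simulate = stage)))
    },
    gsea = run_pipeline(list(seed = seed, output_dir = outdir, stages = list(
      gsea = list(expr = o$expr, cls = o$cls, probe_map = o$probe_map,
                  ec_map = o$ec_map, gmt = o$gmt,
                  n_perm = as.integer(.cli_num(o$n_perm, 1000)),
                  min_nodes = as.integer(.cli_num(o$min_nodes, 3)),
                  max_nodes = as.integer(.cli_num(o$max_nodes, 500)),
                  seed = seed)))),
    concordance = run_pipeline(list(seed = seed, output_dir = outdir,
      stages = list(concordance = list(a = o$a, b = o$b,
                                       tau = .cli_num(o$tau, 1.2))))),
    mid = run_pipeline(list(seed = seed, output_dir = outdir, stages = list(
      mid = list(input = o$input, samples = o$samples,
                 correct_na = o$correct_na %||% TRUE,
                 mode = o$mode %||% "fractional",
                 tracer_enrichment = .cli_num(o$tracer_enrichment, 1),
                 normalize_enrichment = o$normalize_enrichment %||% FALSE)))),
    `labeling-stats` = run_pipeline(list(seed = seed, output_dir = outdir,
      stages = list(labeling_stats = list(
        index = o$index, labels = o$labels, categories = o$categories,
        alpha = .cli_num(o$alpha, 0.05), k = as.integer(.cli_num(o$k, 2)),
        method = o$method %||% "hierarchical", seed = seed)))),
    `nucleotide-sources` = run_pipeline(list(seed = seed, output_dir = outdir,
      stages = list(nucleotide_sources = list(
        input = o$input, labels = o$labels,
        denovo_min_shift = as.integer(.cli_num(o$denovo_min_shift, 3)))))),
    stop("unknown subcommand: ", cmd))
  invisible(0L)
}
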