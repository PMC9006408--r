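#' Assemble a pipeline configuration
#'
#' @param cq path to the Cq TSV (first column `gene_id`).
#' @param samples path to the sample sheet TSV (`sample_id`, `tissue`).
#' @param obo character vector of OBO file paths (merged disjointly).
#' @param annotations path to the two-column gene/term TSV.
#' @param out_dir output directory for reports.
#' @param reference_gene normalisation reference (default `"Hsp90"`).
#' @param alpha pairwise significance level (default 0.01).
#' @param dss_delta separation-filter threshold in delta-Cq (default 1.25).
#' @param eval_fns,min_levels rule-induction grid.
#' @param max_rules,max_conjuncts,beam_width search limits.
#' @param min_difference selection filter (default 3).
#' @param seed integer seed.
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(cq, samples, obo, annotations, out_dir,
                            reference_gene = "Hsp90", alpha = 0.01,
                            dss_delta = 1.25,
                            eval_fns = c("ACC", "AUC", "F1"),
                            min_levels = c(0L, 2L, 3L, 4L, 5L, 6L),
                            max_rules = 10L, max_conjuncts = 3L,
                            beam_width = 20L, min_difference = 3L,
                            seed = 1L) {
  cfg <- list(cq = cq, samples = samples, obo = obo,
              annotations = annotations, out_dir = out_dir,
              reference_gene = reference_gene, alpha = alpha,
              dss_delta = dss_delta, eval_fns = eval_fns,
              min_levels = as.integer(min_levels),
              max_rules = as.integer(max_rules),
              max_conjuncts = as.integer(max_conjuncts),
              beam_width = as.integer(beam_width),
              min_difference = as.integer(min_difference),
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; unknown keys error.
#'
#' @param path YAML file.
#' @param overrides named list applied on top of the file.
#' @return A `PipelineConfig`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, vals)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Executes the stages in order — read Cq + sample sheet, impute, normalise,
#' per-gene ANOVA with Tukey post-hoc, comparison labelings, per-labeling
#' term enrichment with coverage, rule-induction grid, rule selection — and
#' writes `stats.tsv`, `labelings.tsv`, `enrichment_<group>.tsv`,
#' `rules.tsv`/`rules.json`, `selection.tsv`/`selection.json` plus
#' `run_log.txt` containing the package version, the seed, and a hash of
#' the configuration, so identical configs yield identical reports.
#'
#' @param config a [pipeline_config()].
#' @param stage last stage to execute: `"labelings"`, `"enrichment"`,
#'   `"rules"`, or `"all"` (default; adds selection).
#' @return Invisibly, a list with the in-memory stage results and the
#'   report paths.
#' @export
run_pipeline <- function(config, stage = c("all", "labelings", "enrichment",
                                           "rules")) {
  stage <- match.arg(stage)
  stopifnot(inherits(config, "PipelineConfig"))
  for (p in c(config$cq, config$samples, config$obo, config$annotations)) {
    if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  graphs <- lapply(config$obo, load_obo)
  graph <- if (length(graphs) == 1L) graphs[[1]] else merge_ontologies(graphs)

  cq <- read_cq(config$cq, config$samples, reference_gene = config$reference_gene)
  cq <- impute_missing(cq)
  expr <- normalize_cq(cq)
  ann <- load_annotations(config$annotations, graph, rownames(expr$values))

  stats <- anova_tukey(expr)
  labelings <- label_groups(stats, alpha = config$alpha)
  upreg <- count_upregulated(labelings)
  upreg_sets <- attr(upreg, "genes")

  stats_df <- data.frame(gene = rownames(stats$p_adj), anova_p = stats$anova_p,
                         stats$p_adj, check.names = FALSE)
  write_tsv(stats_df, file.path(config$out_dir, "stats.tsv"))

  lab_rows <- do.call(rbind, lapply(names(labelings), function(nm) {
    l <- labelings[[nm]]
    data.frame(gene = names(l$significant), comparison = nm,
               significant = unname(l$significant),
               up_in = unname(l$up_in), p = unname(l$p_value),
               stringsAsFactors = FALSE)
  }))
  write_tsv(lab_rows, file.path(config$out_dir, "labelings.tsv"))
  if (stage == "labelings") {
    return(invisible(list(graph = graph, expr = expr, annotations = ann,
                          stats = stats, labelings = labelings,
                          upregulated = upreg, out_dir = config$out_dir)))
  }

  for (nm in names(labelings)) {
    rep_df <- enrichment_report(labelings[[nm]], ann, upreg_sets, graph = graph)
    write_tsv(rep_df, file.path(config$out_dir,
                                paste0("enrichment_", gsub("\\W+", "_", nm), ".tsv")))
  }
  if (stage == "enrichment") {
    return(invisible(list(graph = graph, expr = expr, annotations = ann,
                          stats = stats, labelings = labelings,
                          upregulated = upreg, out_dir = config$out_dir)))
  }

  pool <- run_grid(labelings, ann, graph, eval_fns = config$eval_fns,
                   min_levels = config$min_levels,
                   max_rules = config$max_rules,
                   max_conjuncts = config$max_conjuncts,
                   beam_width = config$beam_width, seed = config$seed)
  pool_df <- pool_as_data_frame(pool, graph)
  write_tsv(pool_df, file.path(config$out_dir, "rules.tsv"))
  jsonlite::write_json(pool_df, file.path(config$out_dir, "rules.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (stage == "rules") {
    return(invisible(list(graph = graph, expr = expr, annotations = ann,
                          stats = stats, labelings = labelings,
                          upregulated = upreg, pool = pool,
                          out_dir = config$out_dir)))
  }

  sel <- select_rules(pool, expr, min_difference = config$min_difference)
  sel_df <- pool_as_data_frame(sel, graph)
  write_tsv(sel_df, file.path(config$out_dir, "selection.tsv"))
  jsonlite::write_json(sel_df, file.path(config$out_dir, "selection.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  cfg_hash <- digest::digest(unclass(config))
  log_lines <- c(
    paste0("ontorules version: ", as.character(utils::packageVersion("ontorules"))),
    paste0("timestamp: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    paste0("seed: ", config$seed),
    paste0("config_hash: ", cfg_hash),
    paste0("alpha: ", config$alpha),
    paste0("upregulated: ",
           paste(sprintf("%s=%d", names(upreg), upreg), collapse = ", ")),
    paste0("pool entries: ", length(pool$entries),
           " (", pool$n_runs, " runs, ", pool$n_failed, " failed)"),
    paste0("selected entries: ", length(sel$entries)))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(graph = graph, expr = expr, annotations = ann,
                 stats = stats, labelings = labelings,
                 upregulated = upreg, pool = pool, selection = sel,
                 config_hash = cfg_hash, out_dir = config$out_dir))
}

cli_stop <- function(...) stop(..., call. = FALSE)

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic scenario), `stats` (ontology
#' statistics for an OBO file), and the staged pipeline entry points
#' `diffexpr` (stats + labelings), `enrich` (adds term enrichment), `rules`
#' (adds the induction grid), `select` and `run` (full pipeline including
#' rule selection). Invoke from a shell as
#' `Rscript -e 'ontorules::run_cli()' -- <subcommand> [options]` or via the
#' wrapper installed under `inst/scripts/ontorules`.
#'
#' @param argv character vector of arguments (defaults to the command line).
#' @return Invisibly, the subcommand's result.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    cat("usage: ontorules <simulate|diffexpr|stats|run> [options]\n")
    return(invisible(NULL))
  }
  sub <- argv[[1]]
  rest <- argv[-1]
  switch(
    sub,
    stats = {
      if (!length(rest)) cli_stop("usage: ontorules stats <file.obo>")
      ontology_stats(load_obo(rest[[1]]))
    },
    simulate = {
      opts <- optparse::parse_args(optparse::OptionParser(option_list = list(
        optparse::make_option("--out", type = "character", default = "scenario"),
        optparse::make_option("--seed", type = "integer", default = 1L),
        optparse::make_option("--n-genes", type = "integer", default = 370L,
                              dest = "n_genes"),
        optparse::make_option("--noise", type = "double", default = 0.0),
        optparse::make_option("--missing-rate", type = "double", default = 0.05,
                              dest = "missing_rate"))), args = rest)
      sc <- synthetic_scenario(seed = opts$seed, n_genes = opts$n_genes,
                               noise = opts$noise,
                               missing_rate = opts$missing_rate)
      paths <- write_scenario(sc, opts$out)
      message("scenario written to ", opts$out)
      invisible(paths)
    },
    diffexpr = ,
    enrich = ,
    rules = ,
    select = ,
    run = {
      opt_list <- list(
        optparse::make_option("--config", type = "character", default = NULL),
        optparse::make_option("--cq", type = "character"),
        optparse::make_option("--samples", type = "character"),
        optparse::make_option("--obo", type = "character"),
        optparse::make_option("--annotations", type = "character"),
        optparse::make_option("--out-dir", type = "character",
                              default = "ontorules_out", dest = "out_dir"),
        optparse::make_option("--alpha", type = "double", default = 0.01),
        optparse::make_option("--dss-delta", type = "double", default = 1.25,
                              dest = "dss_delta"),
        optparse::make_option("--min-level", type = "character",
                              default = "0,2,3,4,5,6", dest = "min_level"),
        optparse::make_option("--eval-fn", type = "character",
                              default = "ACC,AUC,F1", dest = "eval_fn"),
        optparse::make_option("--max-rules", type = "integer", default = 10L,
                              dest = "max_rules"),
        optparse::make_option("--min-difference", type = "integer", default = 3L,
                              dest = "min_difference"),
        optparse::make_option("--seed", type = "integer", default = 1L))
      opts <- optparse::parse_args(optparse::OptionParser(option_list = opt_list),
                                   args = rest)
      overrides <- list(
        out_dir = opts$out_dir, alpha = opts$alpha, dss_delta = opts$dss_delta,
        min_levels = as.integer(strsplit(opts$min_level, ",")[[1]]),
        eval_fns = strsplit(opts$eval_fn, ",")[[1]],
        max_rules = opts$max_rules, min_difference = opts$min_difference,
        seed = opts$seed)
      cfg <- if (!is.null(opts$config)) {
        read_pipeline_config(opts$config, overrides)
      } else {
        for (k in c("cq", "samples", "obo", "annotations")) {
          if (is.null(opts[[k]])) cli_stop("missing required option --", k)
        }
        do.call(pipeline_config,
                c(list(cq = opts$cq, samples = opts$samples,
                       obo = strsplit(opts$obo, ",")[[1]],
                       annotations = opts$annotations), overrides))
      }
      stage <- switch(sub, diffexpr = "labelings", enrich = "enrichment",
                      rules = "rules", "all")
      invisible(run_pipeline(cfg, stage = stage))
    },
    cli_stop("unknown subcommand: ", sub)
  )
}
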