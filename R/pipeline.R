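# End-to-end orchestration: disorder summaries -> fragment scan and
# duplication plan -> term enrichment -> network comparison, with every
# stage's table written to the output directory and a consolidated summary.

#' Assemble a pipeline run configuration
#'
#' @param scores Path to per-residue disorder scores (file or directory).
#' @param genome_map Path to the gene map TSV.
#' @param out_dir Output directory for stage tables and the summary.
#' @param proteome Optional proteome FASTA; when given it is read,
#'   redundancy-filtered and its id set checked against the map.
#' @param edges Optional interaction edge list (TSV).
#' @param gaf,obo Optional annotation (GAF) and ontology (OBO) files.
#' @param cutoff Score binarisation cutoff.
#' @param thresholds Long-disorder run-length thresholds.
#' @param T Focal threshold used for scans and the plan.
#' @param queries List of scan queries (chromosome labels or
#'   `list(chromosome, start_ordinal, k)` fragments). Defaults to the
#'   budget-feasible chromosome chosen by [postdict()].
#' @param budget Gene budget for the duplication plan.
#' @param extra_sizes Extra fragment sizes for the plan.
#' @param alpha FDR level for term enrichment.
#' @param bootstrap_reps Bootstrap replicates for chromosome summaries.
#' @param seed Seed for the bootstrap.
#' @param map_format Format of the gene map file.
#' @return A `run_config` list.
#' @export
run_config <- function(scores, genome_map, out_dir,
                       proteome = NULL, edges = NULL, gaf = NULL, obo = NULL,
                       cutoff = 0.5, thresholds = c(30L, 50L, 80L), T = 30L,
                       queries = NULL, budget = NULL,
                       extra_sizes = integer(0), alpha = 0.05,
                       bootstrap_reps = 1000L, seed = 42L,
                       map_format = c("tsv", "gff3")) {
  cfg <- list(scores = scores, genome_map = genome_map, out_dir = out_dir,
              proteome = proteome, edges = edges, gaf = gaf, obo = obo,
              cutoff = cutoff, thresholds = as.integer(thresholds),
              T = as.integer(T), queries = queries, budget = budget,
              extra_sizes = as.integer(extra_sizes), alpha = alpha,
              bootstrap_reps = as.integer(bootstrap_reps),
              seed = as.integer(seed),
              map_format = match.arg(map_format))
  for (f in c("scores", "genome_map", "proteome", "edges", "gaf", "obo")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) {
      stop("input '", f, "' does not exist: ", cfg[[f]])
    }
  }
  if (!cfg$T %in% cfg$thresholds) cfg$thresholds <- sort(c(cfg$thresholds,
                                                           cfg$T))
  class(cfg) <- "run_config"
  cfg
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the complete analysis pipeline
#'
#' Stages: (1) read inputs and call long disorder per protein; (2)
#' per-chromosome disorder summaries; (3) fragment scan of each query plus
#' the budgeted duplication plan and its proteome-wide disorder delta; (4)
#' term enrichment of the planned duplication against the whole map; (5)
#' interaction-network features and chromosome-group comparison. Each stage
#' writes its table under `out_dir`; a failure aborts with the stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with all stage results (`calls`, `summaries`,
#'   `scans`, `plan`, `delta`, `enrichment`, `features`, `groups`,
#'   `summary_lines`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  inputs <- with_stage("read-inputs", {
    gm <- read_genome_map(config$genome_map, config$map_format)
    scores <- read_disorder_scores(config$scores)
    if (!is.null(config$proteome)) {
      prot <- dedup_proteome(read_fasta(config$proteome))
      missing <- setdiff(gm$protein_id, prot$id)
      if (length(missing) > 0L) {
        warning(length(missing), " mapped gene(s) absent from the ",
                "redundancy-filtered proteome")
      }
    }
    list(gm = gm, scores = scores)
  })
  gm <- inputs$gm

  calls <- with_stage("disorder-calls", {
    disorder_calls(inputs$scores, config$cutoff, config$thresholds)
  })

  summaries <- with_stage("chromosome-summaries", {
    s <- summarize_chromosomes(gm, calls, config$thresholds,
                               config$bootstrap_reps, config$seed)
    write_tsv(s, file.path(config$out_dir, "disorder_by_chromosome.tsv"))
    s
  })

  plan <- NULL; delta <- NA_real_; scans <- list()
  with_stage("fragment-scan", {
    budget <- config$budget
    if (is.null(budget)) {
      budget <- stats::quantile(as.numeric(table(gm$chromosome)), 0.25,
                                names = FALSE)
    }
    plan <- postdict(gm, calls, budget, config$T, config$extra_sizes)
    delta <- disorder_delta(gm, calls, plan, config$T)
    queries <- config$queries
    if (is.null(queries)) queries <- list(plan$primary_region)
    scans <- lapply(queries, function(q) {
      scan_percentile(gm, calls, q, config$T)
    })
    scan_df <- do.call(rbind, lapply(scans, function(s) {
      data.frame(chromosome = s$chromosome,
                 start_ordinal = s$start_ordinal, k = s$k, T = s$T,
                 query_pct = s$query_pct, windows_total = s$windows_total,
                 windows_leq_query = s$windows_leq_query,
                 percentile = s$percentile, stringsAsFactors = FALSE)
    }))
    write_tsv(scan_df, file.path(config$out_dir, "scan_results.tsv"))
    writeLines(c(utils::capture.output(print(plan)),
                 sprintf("proteome %%long delta if executed: %+.3f pp",
                         delta)),
               file.path(config$out_dir, "duplication_plan.txt"))
    writeLines(plan$duplicated_ids,
               file.path(config$out_dir, "duplicated_ids.txt"))
  })

  enrich <- NULL
  if (!is.null(config$gaf)) {
    enrich <- with_stage("term-enrichment", {
      ann <- read_annotations(config$gaf, config$obo)
      e <- term_enrichment(intersect(plan$duplicated_ids, gm$protein_id),
                           ann, gm$protein_id, config$alpha)
      write_tsv(e, file.path(config$out_dir, "enrichment.tsv"))
      e
    })
  }

  features <- NULL; groups <- NULL
  if (!is.null(config$edges)) {
    with_stage("network", {
      g <- largest_component(build_graph(read_edges(config$edges)))
      features <- node_features(g)
      groups <- group_summary(features, gm)
      write_tsv(features, file.path(config$out_dir,
                                    "network_features.tsv"))
      write_tsv(groups, file.path(config$out_dir, "network_groups.tsv"))
    })
  }

  summary_lines <- with_stage("summary", {
    pcol <- paste0("pct_long_", config$T)
    rank <- summaries[order(summaries[[pcol]]), ]
    lines <- c(
      sprintf("dupscan pipeline (T = %d, cutoff = %.2f, seed = %d)",
              config$T, config$cutoff, config$seed),
      "",
      sprintf("chromosomes ranked by %%long%d (lowest first):", config$T),
      sprintf("  %-10s n=%4d  %%long%d = %5.1f", rank$chromosome,
              rank$n_proteins, config$T, rank[[pcol]]),
      "",
      utils::capture.output(print(plan)),
      sprintf("proteome %%long delta if executed: %+.3f pp", delta),
      "",
      "scan percentiles:",
      vapply(scans, function(s) {
        sprintf("  %s[%d..%d) k=%d: %.2f%% of windows as disorder-poor",
                s$chromosome, s$start_ordinal, s$start_ordinal + s$k, s$k,
                100 * s$percentile)
      }, character(1)))
    if (!is.null(enrich)) {
      top <- utils::head(enrich, 5L)
      lines <- c(lines, "", "top enriched terms (by q):",
                 sprintf("  %-12s k=%3d K=%4d fold=%5.2f q=%.3g", top$term,
                         top$k, top$K, top$fold, top$q))
    }
    if (!is.null(groups)) {
      gdeg <- groups[order(groups$mean_degree), ]
      lines <- c(lines, "",
                 sprintf("lowest mean degree group: %s (mean %.1f +/- %.1f)",
                         gdeg$group[1], gdeg$mean_degree[1],
                         gdeg$se_degree[1]))
    }
    writeLines(lines, file.path(config$out_dir, "summary.txt"))
    lines
  })

  invisible(list(calls = calls, summaries = summaries, scans = scans,
                 plan = plan, delta = delta, enrichment = enrich,
                 features = features, groups = groups,
                 summary_lines = summary_lines))
}
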