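## One-shot orchestration: simulate (or load) -> [synthesize + demux] ->
## enrichment test -> filter cascade -> family clustering, with a
## machine-readable run report and optional on-disk intermediates.

#' Default pipeline configuration
#'
#' All analysis thresholds default to the reference values: FDR 0.05,
#' 100-fold cut, 60% identity, 0.1% minimum family frequency.
#'
#' @param sim list of [sim_config()] arguments (or an existing `sim_config`).
#' @param use_reads logical; synthesize reads and re-count them by
#'   demultiplexing (exercises the read path) instead of using the
#'   simulator's count table directly.
#' @param counts_file optional TSV of a pre-built count table; overrides the
#'   simulation.
#' @param test list: `group_early`, `group_late`, `n_resamples`,
#'   `fdr_threshold`.
#' @param filter list: `baseline`, `final`, `monotonic_rounds`,
#'   `fold_threshold`, `final_rounds`.
#' @param cluster list: `min_identity`, `min_members`, `min_final_freq`.
#' @param seed master seed.
#' @return a nested configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = list(), use_reads = FALSE,
                            counts_file = NULL,
                            test = list(), filter = list(), cluster = list(),
                            seed = 1L) {
  structure(list(sim = sim, use_reads = use_reads, counts_file = counts_file,
                 test = test, filter = filter, cluster = cluster,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order and assembles a self-contained run report.
#' When the input is simulated, recovery metrics against the ground truth are
#' included: `sensitivity` (fraction of spiked clones surviving the cascade),
#' `null_inclusion` (fraction of non-spiked clones surviving), and
#' `survivor_fdp` (non-spiked fraction among survivors).
#'
#' @param config a [pipeline_config()], a YAML file path of one, or a plain
#'   list with the same fields.
#' @param out_dir optional directory; when given, all intermediates are
#'   written (`counts.tsv`, `enrichment.tsv`, `trace.json`, `families.tsv`,
#'   `report.json`, and `reads.fastq.gz` if the read path is exercised).
#' @return the run report (list of class `run_report`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  if (!inherits(config, "pipeline_config")) {
    config <- do.call(pipeline_config, config)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL
  qc <- NULL
  if (!is.null(config$counts_file)) {
    counts <- read_count_table(config$counts_file)
  } else {
    sim_args <- config$sim
    if (!inherits(sim_args, "sim_config")) {
      if (!("seed" %in% names(sim_args))) sim_args$seed <- config$seed
      sim_args <- do.call(sim_config, sim_args)
    }
    exper <- simulate_experiment(sim_args)
    truth <- exper$truth
    counts <- exper$counts
    if (isTRUE(config$use_reads)) {
      fastq <- if (is.null(out_dir)) tempfile(fileext = ".fastq.gz") else
        file.path(out_dir, "reads.fastq.gz")
      synthesize_reads(counts, sim_args, path = fastq)
      dm <- demux_count(fastq, sim_args$index_map)
      counts <- dm$counts
      qc <- dm$qc
      if (is.null(out_dir)) unlink(fastq)
    }
  }

  rounds <- counts$rounds
  test_args <- config$test
  if (!("group_early" %in% names(test_args))) {
    test_args$group_early <- intersect(c("naive", "R3a", "R3"), rounds)
  }
  if (!("group_late" %in% names(test_args))) {
    test_args$group_late <- intersect(c("R5", "R7", "R8"), rounds)
  }
  if (!("seed" %in% names(test_args))) test_args$seed <- config$seed
  tcfg <- do.call(test_config, test_args)
  enr <- enrichment_test(counts, tcfg)

  filt_args <- config$filter
  trace <- do.call(run_cascade,
                   c(list(counts = counts, enrichment = enr), filt_args))
  survivors <- cascade_survivors(trace)

  cl_args <- config$cluster
  fam_all <- build_families(counts, survivors,
                            min_identity = cl_args$min_identity %||% 0.60)
  fam_sel <- select_families(fam_all,
                             min_members = cl_args$min_members %||% 2L,
                             min_final_freq = cl_args$min_final_freq %||% 0.001)

  report <- list(
    version = as.character(utils::packageVersion("clonesift")),
    seed = config$seed,
    rounds = rounds,
    depths = as.list(depths(counts)),
    n_clones = nrow(counts$counts),
    n_enriched = sum(enr$direction == "enriched"),
    n_depleted = sum(enr$direction == "depleted"),
    stage_counts = as.list(trace$counts),
    n_families = nrow(fam_all),
    n_retained_families = nrow(fam_sel),
    qc = qc
  )
  if (!is.null(truth)) {
    spiked <- truth$clone_id[truth$is_spiked]
    nulls <- truth$clone_id[!truth$is_spiked]
    report$recovery <- list(
      n_spiked = length(spiked),
      sensitivity = if (length(spiked)) {
        mean(spiked %in% survivors)
      } else NA_real_,
      null_inclusion = mean(nulls %in% survivors),
      survivor_fdp = if (length(survivors)) {
        mean(!survivors %in% spiked)
      } else 0
    )
  }

  out <- structure(list(report = report, counts = counts, enrichment = enr,
                        trace = trace, families = fam_all,
                        retained_families = fam_sel, truth = truth),
                   class = "run_report")
  if (!is.null(out_dir)) {
    write_count_table(counts, file.path(out_dir, "counts.tsv"))
    data.table::fwrite(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t")
    jsonlite::write_json(c(list(stages = lapply(trace$stages, identity)),
                           list(counts = as.list(trace$counts))),
                         file.path(out_dir, "trace.json"), auto_unbox = TRUE)
    if (nrow(fam_all)) {
      data.table::fwrite(fam_all, file.path(out_dir, "families.tsv"),
                         sep = "\t")
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("<run_report> %d clones over %s\n", r$n_clones,
              paste(r$rounds, collapse = ", ")))
  cat(sprintf("  enriched %d / depleted %d at FDR\n", r$n_enriched,
              r$n_depleted))
  cat("  cascade:", paste(sprintf("%s=%d", names(r$stage_counts),
                                  unlist(r$stage_counts)), collapse = " > "),
      "\n")
  cat(sprintf("  families %d, retained %d\n", r$n_families,
              r$n_retained_families))
  if (!is.null(r$recovery)) {
    cat(sprintf("  recovery: sensitivity %.3f, null inclusion %.4f\n",
                r$recovery$sensitivity, r$recovery$null_inclusion))
  }
  invisible(x)
}
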