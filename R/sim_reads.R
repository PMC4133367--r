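## Synthesis of indexed 100-base single-end reads from a count table.

READ_LENGTH <- 100L

#' Synthesize indexed amplicon reads from a count table
#'
#' Each VH-end read is laid out as
#' `[2-base round index][20-base VH-FR3 primer tail][CDR3 DNA][FR4 anchor +
#' framework filler]`, truncated to 100 bases, with per-base substitution
#' errors applied at `cfg$error_rate`. Read counts per clone and round equal
#' the count table exactly. Qualities are constant Q30 and are never used
#' downstream.
#'
#' @param counts a `clone_counts` from [evolve_rounds()].
#' @param cfg the [sim_config()].
#' @param path optional FASTQ output path (gzipped when it ends in `.gz`).
#' @param seed overrides the error RNG stream (default `cfg$seed + 2`).
#' @return invisibly, a data.frame with columns `id`, `sequence`, `round`.
#' @export
synthesize_reads <- function(counts, cfg, path = NULL, seed = NULL) {
  stopifnot(inherits(counts, "clone_counts"), inherits(cfg, "sim_config"))
  if (!all(counts$rounds %in% names(cfg$index_map))) {
    stop("count table columns missing from index_map")
  }
  tail_len <- nchar(VH_PRIMER_TAIL)
  max_loop <- READ_LENGTH - 2L - tail_len - nchar(VH_FR4_ANCHOR)
  too_long <- nchar(counts$clones$cdr3_dna) > max_loop
  if (any(too_long)) {
    stop("CDR3 of clone ", counts$clones$clone_id[which(too_long)[1]],
         " too long to fit a ", READ_LENGTH, "-base read")
  }
  template <- substr(paste0(VH_PRIMER_TAIL, counts$clones$cdr3_dna,
                            VH_FR4_ANCHOR, FR4_FILLER),
                     1L, READ_LENGTH - 2L)

  all_reads <- character(0)
  all_ids <- character(0)
  all_round <- character(0)
  for (r in counts$rounds) {
    cc <- counts$counts[, r]
    keep <- which(cc > 0L)
    if (!length(keep)) next
    reads <- paste0(cfg$index_map[[r]], rep(template[keep], cc[keep]))
    ids <- sprintf("%s:%07d", r, seq_along(reads))
    all_reads <- c(all_reads, reads)
    all_ids <- c(all_ids, ids)
    all_round <- c(all_round, rep(r, length(reads)))
  }

  with_seed(seed %||% (cfg$seed + 2L), {
    all_reads <- apply_sequencing_errors(all_reads, cfg$error_rate)
  })

  if (!is.null(path)) {
    write_fastq(all_ids, all_reads, path)
  }
  invisible(data.frame(id = all_ids, sequence = all_reads, round = all_round,
                       stringsAsFactors = FALSE))
}

# Uniform per-base substitutions at rate `rate`; the replacement base is drawn
# from the three alternatives (a substitution never reproduces the original).
apply_sequencing_errors <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  widths <- nchar(reads)
  total <- sum(widths)
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(reads)
  pos <- sort(sample.int(total, n_err))
  ends <- cumsum(widths)
  read_i <- findInterval(pos - 1L, ends) + 1L
  offset <- pos - c(0L, ends)[read_i]
  shift <- sample.int(3L, n_err, replace = TRUE)
  for (k in seq_len(n_err)) {
    i <- read_i[k]; p <- offset[k]
    orig <- substr(reads[i], p, p)
    b <- match(orig, DNA_BASES)
    newb <- DNA_BASES[((b - 1L + shift[k]) %% 4L) + 1L]
    substr(reads[i], p, p) <- newb
  }
  reads
}

write_fastq <- function(ids, reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  qual <- strrep("?", nchar(reads))  # constant Q30
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Run a full synthetic selection experiment
#'
#' Draws the library, evolves it over the configured rounds, fills the
#' realized fold into the ground truth, and (optionally) synthesizes reads.
#'
#' @param cfg a [sim_config()].
#' @param reads logical; also synthesize a read set?
#' @param fastq optional FASTQ path (implies `reads = TRUE`).
#' @return list with `config`, `clones`, `truth` (including
#'   `true_total_fold`, the realized naive-to-final frequency ratio), `counts`
#'   (a `clone_counts`) and, when requested, `reads`.
#' @export
simulate_experiment <- function(cfg, reads = FALSE, fastq = NULL) {
  lib <- draw_library(cfg)
  counts <- evolve_rounds(lib$clones, lib$truth, cfg)
  lib$truth$true_total_fold <-
    unname(realized_fold(counts)[lib$truth$clone_id])
  out <- list(config = cfg, clones = lib$clones, truth = lib$truth,
              counts = counts)
  if (reads || !is.null(fastq)) {
    out$reads <- synthesize_reads(counts, cfg, path = fastq)
  }
  out
}
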