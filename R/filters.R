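## The ordered post-test filter cascade. Stages, in fixed order:
##   present_both  — clone observed (> 0 reads) in both the naive and the
##                   final endpoint library;
##   fdr_enriched  — called enriched by the permutation-FDR test;
##   no_stop       — loop translates cleanly: no stop codon and in frame;
##   monotonic     — frequency strictly increases naive < R3 < R5 < R7;
##   fold100       — enrichment factor strictly above the fold threshold.
## Comparisons are on frequencies, never raw counts, since depths differ by
## round. Survivor sets are nested by construction.

#' Clones present in both endpoint libraries
#'
#' @param counts a `clone_counts`.
#' @param baseline,final the endpoint round labels.
#' @return character vector of surviving clone ids.
#' @export
filter_present_both <- function(counts, baseline = "naive", final = "R7") {
  stopifnot(inherits(counts, "clone_counts"),
            all(c(baseline, final) %in% counts$rounds))
  keep <- counts$counts[, baseline] > 0L & counts$counts[, final] > 0L
  counts$clones$clone_id[keep]
}

#' Strict monotonic-frequency filter
#'
#' `TRUE` for clones whose frequency strictly increases along the stated
#' rounds (any tie fails).
#'
#' @param counts a `clone_counts`.
#' @param clone_id clone ids to test (default all).
#' @param rounds the ordered rounds the increase is required over.
#' @return named logical vector.
#' @export
filter_monotonic <- function(counts, clone_id = NULL,
                             rounds = c("naive", "R3", "R5", "R7")) {
  stopifnot(inherits(counts, "clone_counts"),
            all(rounds %in% counts$rounds))
  fr <- freqs(counts)[, rounds, drop = FALSE]
  ok <- rep(TRUE, nrow(fr))
  for (j in seq_len(length(rounds) - 1L)) {
    ok <- ok & fr[, j] < fr[, j + 1L]
  }
  names(ok) <- rownames(fr)
  if (!is.null(clone_id)) ok <- ok[clone_id]
  ok
}

#' Strict fold-enrichment filter
#'
#' `TRUE` when the enrichment factor exceeds `threshold` strictly (an exact
#' 100-fold clone fails the default).
#'
#' @inheritParams filter_monotonic
#' @param threshold fold threshold (default 100).
#' @param baseline,final_rounds as in [enrichment_factor()].
#' @return named logical vector (zero naive frequency gives `FALSE`).
#' @details The strict comparison is evaluated on integer cross-products
#'   (`count_final * depth_naive > threshold * count_naive * depth_final`),
#'   so a clone at exactly the threshold fold is rejected without
#'   floating-point ambiguity.
#' @export
filter_fold <- function(counts, clone_id = NULL, threshold = 100,
                        baseline = "naive", final_rounds = c("R7", "R8")) {
  stopifnot(inherits(counts, "clone_counts"))
  final_rounds <- intersect(final_rounds, counts$rounds)
  if (!baseline %in% counts$rounds || !length(final_rounds)) {
    stop("count table lacks the baseline or final rounds")
  }
  d <- depths(counts)
  cb <- as.numeric(counts$counts[, baseline])
  ok <- rep(FALSE, nrow(counts$counts))
  for (r in final_rounds) {
    cr <- as.numeric(counts$counts[, r])
    # exact for counts*depths below 2^53
    ok <- ok | (cb > 0 & cr * d[[baseline]] > threshold * cb * d[[r]])
  }
  names(ok) <- rownames(counts$counts)
  if (!is.null(clone_id)) ok <- ok[clone_id]
  ok
}

#' Run the full filter cascade
#'
#' Applies the five stages in their fixed order and records the surviving
#' clone set and count after each stage.
#'
#' @param counts a `clone_counts`.
#' @param enrichment the data.frame returned by [enrichment_test()] on the
#'   same table.
#' @param baseline,final endpoint rounds for the presence filter.
#' @param monotonic_rounds rounds for the strict-increase filter.
#' @param fold_threshold fold cut (strict).
#' @param final_rounds final rounds the fold is maximised over.
#' @return an object of class `filter_trace`: list with `stages` (named list
#'   of surviving clone-id vectors, in stage order) and `counts` (named
#'   integer vector).
#' @export
run_cascade <- function(counts, enrichment,
                        baseline = "naive", final = "R7",
                        monotonic_rounds = c("naive", "R3", "R5", "R7"),
                        fold_threshold = 100,
                        final_rounds = c("R7", "R8")) {
  stopifnot(inherits(counts, "clone_counts"))
  stopifnot(all(counts$clones$clone_id %in% enrichment$clone_id))

  s1 <- filter_present_both(counts, baseline, final)

  enriched <- enrichment$clone_id[enrichment$direction == "enriched"]
  s2 <- intersect(s1, enriched)

  cl <- counts$clones
  clean <- cl$clone_id[!is.na(cl$has_stop) & !cl$has_stop & cl$in_frame]
  s3 <- intersect(s2, clean)

  mono <- filter_monotonic(counts, rounds = monotonic_rounds)
  s4 <- intersect(s3, names(mono)[mono])

  fold <- filter_fold(counts, threshold = fold_threshold,
                      baseline = baseline, final_rounds = final_rounds)
  s5 <- intersect(s4, names(fold)[fold])

  stages <- list(present_both = s1, fdr_enriched = s2, no_stop = s3,
                 monotonic = s4, fold100 = s5)
  structure(list(stages = stages,
                 counts = vapply(stages, length, integer(1))),
            class = "filter_trace")
}

#' @export
print.filter_trace <- function(x, ...) {
  cat("<filter_trace>\n")
  for (s in names(x$counts)) cat(sprintf("  %-14s %d\n", s, x$counts[[s]]))
  invisible(x)
}

#' Survivors of the full cascade
#' @param trace a `filter_trace`.
#' @return character vector of clone ids surviving the final stage.
#' @export
cascade_survivors <- function(trace) {
  stopifnot(inherits(trace, "filter_trace"))
  trace$stages[[length(trace$stages)]]
}
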