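## Discrete-generation selection dynamics and read sampling.

#' Evolve a library over selection rounds and sample read counts
#'
#' Applies the discrete-generation replicator model: at generation `g` the
#' frequency of clone `c` is `f0(c) * w_c^g`, renormalised over clones. Each
#' round is then observed as an independent multinomial sample of its
#' configured depth. Two rounds sharing a generation (e.g. a round sequenced
#' before and after recloning) are two independent samples of the same
#' frequency vector.
#'
#' @param library,truth output of [draw_library()].
#' @param cfg the [sim_config()] used to draw them.
#' @param seed overrides the evolution RNG stream (default `cfg$seed + 1`).
#' @return a [new_clone_counts()] table with one column per round.
#' @export
evolve_rounds <- function(library, truth, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  f0 <- library$abundance
  stopifnot(abs(sum(f0) - 1) < 1e-9)
  w <- truth$selection_coefficient[match(library$clone_id, truth$clone_id)]
  with_seed(seed %||% (cfg$seed + 1L), {
    counts <- matrix(0L, nrow = length(f0), ncol = length(cfg$rounds),
                     dimnames = list(library$clone_id, cfg$rounds))
    for (j in seq_along(cfg$rounds)) {
      g <- cfg$generations[j]
      fg <- f0 * w^g
      fg <- fg / sum(fg)
      counts[, j] <- rmultinom(1L, size = cfg$depth_per_round[j], prob = fg)
    }
    new_clone_counts(counts, library[, c("clone_id", "cdr3_dna", "cdr3_aa",
                                         "has_stop", "in_frame")])
  })
}

#' Deterministic (pre-sampling) frequency trajectory
#'
#' The expected frequency of each clone at each round under the replicator
#' model, before multinomial sampling. Columns sum to 1.
#'
#' @inheritParams evolve_rounds
#' @return numeric matrix, clones by rounds.
#' @export
expected_freqs <- function(library, truth, cfg) {
  f0 <- library$abundance
  w <- truth$selection_coefficient[match(library$clone_id, truth$clone_id)]
  out <- sapply(cfg$generations, function(g) {
    fg <- f0 * w^g
    fg / sum(fg)
  })
  dimnames(out) <- list(library$clone_id, cfg$rounds)
  out
}

#' Realized naive-to-final fold enrichment from a count table
#'
#' Frequency ratio between the last and the first round; `NA` for clones with
#' zero count in the first round.
#'
#' @param counts a `clone_counts`.
#' @param baseline,final round labels (defaults: first and last column).
#' @return named numeric vector.
#' @export
realized_fold <- function(counts, baseline = NULL, final = NULL) {
  fr <- freqs(counts)
  baseline <- baseline %||% counts$rounds[1]
  final <- final %||% counts$rounds[length(counts$rounds)]
  out <- ifelse(fr[, baseline] > 0, fr[, final] / fr[, baseline], NA_real_)
  setNames(out, rownames(fr))
}
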