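## Configuration of a synthetic selection experiment.

#' Configure a synthetic library-selection experiment
#'
#' The defaults describe the reference in-silico experiment: a naive scFv/VH
#' CDR3 library with symmetric-Dirichlet (heavy-tailed) clone abundances, 20%
#' of clones defective (stop codon or frameshift), a handful of truly
#' selectable clones ("spikes") whose per-round multiplicative fitness is
#' calibrated to a configured total naive-to-final fold enrichment, multinomial
#' read sampling per round, and 100-base single-end indexed reads.
#'
#' @param n_clones number of distinct CDR3 DNA clonotypes in the naive library.
#' @param abundance_alpha concentration of the symmetric Dirichlet from which
#'   naive clone frequencies are drawn; values < 1 give the heavy-tailed
#'   rank-frequency structure of combinatorial libraries.
#' @param frac_stop fraction of clones carrying an in-loop stop codon.
#' @param frac_frameshift fraction of clones whose loop length is not a
#'   multiple of 3. The two defect classes are disjoint.
#' @param n_spiked number of truly enriched clones.
#' @param spike_fold_range length-2 numeric, the (min, max) total
#'   naive-to-final fold enrichment; folds are drawn uniformly on this range.
#' @param spike_freq_range length-2 numeric, the naive-frequency band from
#'   which spiked clones are picked. The default balances two constraints:
#'   a spike's expected naive read count must stay well above zero (presence
#'   and fold estimates need a measurable baseline), while the total spiked
#'   mass after selection must remain a small fraction of the library so that
#'   the frequency decline it imposes on every null clone stays below
#'   per-clone counting noise (rare clones rising from low frequency is the
#'   regime the selection operates in).
#' @param spike_n_clusters optional number of mutational clusters the spikes
#'   are organised into (cluster members share a loop length and are >= 60%
#'   identical at the amino-acid level; distinct clusters are unrelated).
#'   `NULL` means all spikes are unrelated singletons.
#' @param rounds ordered round labels.
#' @param generations integer vector, one per round: the number of selection
#'   generations elapsed at that round (0 = naive). Two rounds may share a
#'   generation, which models re-sequencing of the same pool (e.g. before and
#'   after a recloning step). Default `0, 1, 2, ...` in round order, except
#'   that labels `R3a`/`R3` are both assigned generation 1 when present.
#' @param depth_per_round reads per round; a scalar is recycled.
#' @param error_rate per-base substitution probability of the sequencer.
#' @param cdr3_len_range length-2 integer, (min, max) loop length in amino
#'   acids.
#' @param index_map named character vector mapping round label to its 2-base
#'   multiplexing index; defaults to a fixed assignment over the rounds.
#' @param seed integer seed; the whole experiment is reproducible from it.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 5000,
                       abundance_alpha = 0.5,
                       frac_stop = 0.10,
                       frac_frameshift = 0.10,
                       n_spiked = 10,
                       spike_fold_range = c(100, 500),
                       spike_freq_range = c(5e-6, 2e-5),
                       spike_n_clusters = NULL,
                       rounds = c("naive", "R3", "R5", "R7", "R8"),
                       generations = NULL,
                       depth_per_round = 1e5,
                       error_rate = 0.001,
                       cdr3_len_range = c(8L, 20L),
                       index_map = NULL,
                       seed = 1L) {
  stopifnot_scalar_prob(frac_stop, "frac_stop")
  stopifnot_scalar_prob(frac_frameshift, "frac_frameshift")
  stopifnot_scalar_prob(error_rate, "error_rate")
  if (frac_stop + frac_frameshift > 1) {
    stop("frac_stop + frac_frameshift must not exceed 1")
  }
  n_clones <- as.integer(n_clones)
  n_spiked <- as.integer(n_spiked)
  stopifnot(n_clones > 0, n_spiked >= 0, n_spiked <= n_clones)
  if (n_spiked > 0 && spike_fold_range[1] <= 1) {
    stop("spike_fold_range minimum must exceed 1")
  }
  stopifnot(length(spike_fold_range) == 2, diff(spike_fold_range) >= 0,
            length(spike_freq_range) == 2, all(spike_freq_range > 0),
            diff(spike_freq_range) >= 0)
  rounds <- as.character(rounds)
  if (anyDuplicated(rounds)) stop("round labels must be distinct")
  if (is.null(generations)) {
    generations <- cumsum(c(0L, rounds[-1] != sub("a$", "", rounds[-length(rounds)])))
    # consecutive generations, except that a round preceded by its own label
    # plus a trailing "a" shares that predecessor's generation
    # (e.g. R3a/R3 are one pool sequenced twice)
  }
  generations <- as.integer(generations)
  if (length(generations) != length(rounds)) {
    stop("`generations` must have one entry per round")
  }
  if (generations[1] != 0L || any(diff(generations) < 0L)) {
    stop("`generations` must start at 0 and be non-decreasing")
  }
  depth_per_round <- as.numeric(depth_per_round)
  if (length(depth_per_round) == 1L) {
    depth_per_round <- rep(depth_per_round, length(rounds))
  }
  if (length(depth_per_round) != length(rounds) || any(depth_per_round <= 0)) {
    stop("depth_per_round must be positive, one value per round")
  }
  cdr3_len_range <- as.integer(cdr3_len_range)
  stopifnot(length(cdr3_len_range) == 2, cdr3_len_range[1] >= 2,
            diff(cdr3_len_range) >= 0)
  if (is.null(index_map)) index_map <- default_index_map(rounds)
  if (!all(rounds %in% names(index_map))) {
    stop("index_map must cover every round label")
  }
  index_map <- index_map[rounds]
  if (any(nchar(index_map) != 2L) || any(!grepl("^[ACGT]{2}$", index_map))) {
    stop("every index must be 2 bases over A/C/G/T")
  }
  if (anyDuplicated(index_map)) stop("round indexes must be distinct")
  if (!is.null(spike_n_clusters)) {
    spike_n_clusters <- as.integer(spike_n_clusters)
    stopifnot(spike_n_clusters >= 1, spike_n_clusters <= max(n_spiked, 1L))
  }
  structure(list(
    n_clones = n_clones, abundance_alpha = abundance_alpha,
    frac_stop = frac_stop, frac_frameshift = frac_frameshift,
    n_spiked = n_spiked, spike_fold_range = as.numeric(spike_fold_range),
    spike_freq_range = as.numeric(spike_freq_range),
    spike_n_clusters = spike_n_clusters,
    rounds = rounds, generations = generations,
    depth_per_round = depth_per_round, error_rate = error_rate,
    cdr3_len_range = cdr3_len_range, index_map = index_map,
    seed = as.integer(seed)), class = "sim_config")
}

#' Default 2-base round indexes
#' @param rounds character vector of round labels.
#' @return named character vector round -> 2-base index.
#' @export
default_index_map <- function(rounds) {
  pool <- c("AA", "CC", "GG", "TT", "AC", "CA", "GT", "TG", "AG", "GA", "CT", "TC")
  if (length(rounds) > length(pool)) stop("too many rounds for the default index pool")
  setNames(pool[seq_along(rounds)], rounds)
}

#' Six-round study design with a round-3 recloning replicate
#'
#' Convenience constructor for the reference two-class design: rounds
#' naive, R3a, R3 (the same generation-1 pool sequenced before and after a
#' recloning step), R5, R7, R8, with mildly unequal per-round depths emulating
#' lane-yield variation.
#'
#' @param depth nominal reads per round.
#' @param ... passed to [sim_config()].
#' @return a `sim_config`.
#' @export
sim_config_sixround <- function(depth = 1e6, ...) {
  rounds <- c("naive", "R3a", "R3", "R5", "R7", "R8")
  sim_config(rounds = rounds,
             generations = c(0L, 1L, 1L, 2L, 3L, 4L),
             depth_per_round = depth * c(0.90, 1.10, 0.85, 1.05, 1.15, 0.95),
             ...)
}
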