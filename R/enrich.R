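## Two-class unpaired resampling rank test on clone counts with
## permutation-estimated FDR (SAM-seq style): per resample, every sample is
## thinned to the minimum depth by binomial downsampling so counts are
## exchangeable, then a centred Wilcoxon rank-sum statistic (midranks) of the
## late-round group against the early-round group is computed; the statistic
## is the average over resamples. The null distribution comes from all
## distinct group-label permutations of the samples, and the FDR at a cutoff
## is the median permutation exceedance count over the observed count.

# Midranks within each row of a matrix, by pairwise column comparison.
row_midranks <- function(M) {
  k <- ncol(M)
  R <- matrix(1, nrow = nrow(M), ncol = k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      R[, i] <- R[, i] + (M[, j] < M[, i]) + 0.5 * (M[, j] == M[, i])
    }
  }
  R
}

# Poisson thinning of every column to the minimum depth (the SAM-seq
# resampling scheme): X' ~ Poisson(x * dmin/d). Poisson (rather than
# binomial) draws keep resampling noise alive even for the least-deep sample,
# so a null clone whose samples happen to separate cleanly does not stay at
# the extreme rank-sum in every resample.
thin_to_min_depth <- function(M, depth) {
  dmin <- min(depth)
  p <- rep(dmin / depth, each = nrow(M))
  out <- stats::rpois(length(M), as.vector(M) * p)
  matrix(out, nrow = nrow(M), ncol = ncol(M), dimnames = dimnames(M))
}

# Core: observed and permutation statistics for every row.
# Returns list(obs = numeric(n), perm = n x P matrix, n_perm = P).
rank_stat_core <- function(M, depth, late_idx, n_resamples) {
  n <- nrow(M)
  k <- ncol(M)
  n_late <- length(late_idx)
  center <- n_late * (k + 1) / 2
  sets <- combn(k, n_late)          # all distinct late-group assignments
  P <- ncol(sets)
  obs_col <- which(apply(sets, 2L, function(s) setequal(s, late_idx)))
  equal_depth <- length(unique(depth)) == 1L
  B <- if (equal_depth) 1L else n_resamples

  acc <- matrix(0, nrow = n, ncol = P)
  for (b in seq_len(B)) {
    Mb <- if (equal_depth) M else thin_to_min_depth(M, depth)
    R <- row_midranks(Mb)
    for (p in seq_len(P)) {
      acc[, p] <- acc[, p] +
        rowSums(R[, sets[, p], drop = FALSE]) - center
    }
  }
  acc <- acc / B
  list(obs = acc[, obs_col], perm = acc, n_perm = P)
}

#' Resampled rank-sum statistic for one clone
#'
#' The averaged, centred Wilcoxon rank-sum statistic of the late-group counts
#' against the early-group counts after binomial thinning to the minimum
#' depth. Zero means no difference; swapping the groups negates the
#' statistic; when all depths are equal the thinning step is skipped and the
#' statistic is deterministic.
#'
#' @param x non-negative integer count vector, one entry per sample.
#' @param depth per-sample sequencing depths (same length as `x`).
#' @param early,late disjoint index vectors into `x` (each of length >= 2).
#' @param n_resamples thinning resamples to average over (default 20).
#' @param seed optional seed for the thinning draws.
#' @return the statistic (a single number).
#' @export
resampled_rank_statistic <- function(x, depth, early, late,
                                     n_resamples = 20L, seed = NULL) {
  stopifnot(length(x) == length(depth), length(intersect(early, late)) == 0,
            length(early) >= 2, length(late) >= 2)
  M <- matrix(as.numeric(x[c(early, late)]), nrow = 1)
  d <- depth[c(early, late)]
  late_idx <- length(early) + seq_along(late)
  with_seed(seed, rank_stat_core(M, d, late_idx, n_resamples)$obs)
}

#' Test configuration for the enrichment analysis
#'
#' @param group_early,group_late round labels of the early and late groups
#'   (defaults: naive, R3a, R3 versus R5, R7, R8).
#' @param n_resamples thinning resamples (default 20).
#' @param fdr_threshold FDR call threshold (default 0.05).
#' @param seed seed for the thinning draws.
#' @return a list of class `test_config`.
#' @export
test_config <- function(group_early = c("naive", "R3a", "R3"),
                        group_late = c("R5", "R7", "R8"),
                        n_resamples = 20L, fdr_threshold = 0.05,
                        seed = 1L) {
  stopifnot(length(intersect(group_early, group_late)) == 0,
            length(group_early) >= 2, length(group_late) >= 2,
            fdr_threshold > 0, fdr_threshold < 1)
  structure(list(group_early = group_early, group_late = group_late,
                 n_resamples = as.integer(n_resamples),
                 fdr_threshold = fdr_threshold, seed = seed),
            class = "test_config")
}

#' Enrichment test with permutation-estimated FDR
#'
#' Computes the resampled rank statistic for every clone, builds the null
#' from all distinct label permutations of the samples (20 for a 3v3 design),
#' and estimates each clone's q-value as the smallest plug-in FDR — median
#' permutation exceedance count divided by observed exceedance count, clipped
#' to \[0, 1\] — at which the clone is called. Clones are `enriched` when
#' `qvalue < fdr_threshold` and the statistic is positive, `depleted` for the
#' mirrored negative case, `null` otherwise.
#'
#' @param counts a `clone_counts` whose columns include both groups.
#' @param cfg a [test_config()].
#' @return data.frame with `clone_id`, `statistic`, `qvalue`, `direction`,
#'   `enrichment_factor` (see [enrichment_factor()]; `NA` when undefined or
#'   when the endpoint rounds are absent).
#' @export
enrichment_test <- function(counts, cfg = test_config()) {
  stopifnot(inherits(counts, "clone_counts"), inherits(cfg, "test_config"))
  groups <- c(cfg$group_early, cfg$group_late)
  missing <- setdiff(groups, counts$rounds)
  if (length(missing)) {
    stop("count table lacks round(s): ", paste(missing, collapse = ", "))
  }
  # keep the table's native column order so the thinning draws (and hence the
  # result) are invariant to how the groups are listed
  cols <- counts$rounds[counts$rounds %in% groups]
  M <- counts$counts[, cols, drop = FALSE]
  storage.mode(M) <- "double"
  depth <- depths(counts)[cols]
  late_idx <- which(cols %in% cfg$group_late)

  core <- with_seed(cfg$seed,
                    rank_stat_core(M, depth, late_idx, cfg$n_resamples))
  if (core$n_perm < 10L) {
    warning("only ", core$n_perm, " distinct label permutations; ",
            "FDR estimates will be coarse")
  }
  stat_max <- length(cfg$group_early) * length(cfg$group_late) / 2
  q <- qvalues_from_perms(core$obs, core$perm, stat_max)
  direction <- rep("null", nrow(M))
  direction[q < cfg$fdr_threshold & core$obs > 0] <- "enriched"
  direction[q < cfg$fdr_threshold & core$obs < 0] <- "depleted"

  ef <- tryCatch(enrichment_factor(counts), error = function(e) {
    rep(NA_real_, nrow(M))
  })
  data.frame(clone_id = counts$clones$clone_id,
             statistic = core$obs, qvalue = q, direction = direction,
             enrichment_factor = unname(ef), stringsAsFactors = FALSE)
}

# q-values from observed statistics and the permutation statistic matrix.
# Candidate cutoffs are the rank statistic's natural half-integer lattice
# (the values a single-resample centred rank sum can take): the averaged
# statistic only leaves the lattice through thinning noise, and evaluating
# the plug-in FDR at every distinct averaged value would let the single most
# extreme clone sit alone above a cutoff where the median permutation count
# is 0, yielding spurious q = 0 calls under a complete null. Both tails are
# handled symmetrically; q(0) = 1.
qvalues_from_perms <- function(obs, perm, stat_max) {
  n <- length(obs)
  q <- rep(1, n)
  ts <- seq(stat_max, 0.5, by = -0.5)  # descending lattice cutoffs
  for (side in c(1, -1)) {
    s <- side * obs
    Robs <- ts_exceedance(ts, s)
    V <- sapply(seq_len(ncol(perm)), function(p) {
      ts_exceedance(ts, side * perm[, p])
    })
    V <- matrix(V, nrow = length(ts))
    Vmed <- apply(V, 1L, median)
    fdr <- pmin(1, Vmed / pmax(Robs, 1))
    fdr[Robs == 0L] <- 1
    # a clone's q-value is the best FDR over the cutoffs that call it
    fdr <- rev(cummin(rev(fdr)))
    tfloor <- floor(s / 0.5 + 1e-9) * 0.5  # largest lattice cutoff <= s
    idx <- as.integer(round((stat_max - tfloor) / 0.5)) + 1L
    sel <- tfloor >= 0.5
    q[sel] <- pmin(q[sel], fdr[idx[sel]])
  }
  q
}

# #{x >= t} for each t of a decreasing threshold vector.
ts_exceedance <- function(ts, x) {
  xs <- sort(x)
  length(x) - findInterval(ts, xs, left.open = TRUE)
}

#' Enrichment factor of a clone
#'
#' `E(c) = max(f(c, R7), f(c, R8)) / f(c, naive)` — frequency ratio of the
#' best final round over the naive library. Undefined (`NA`) when the naive
#' frequency is zero; no pseudocount is applied.
#'
#' @param counts a `clone_counts`.
#' @param clone_id optional clone id(s); default all clones.
#' @param baseline the naive round label.
#' @param final_rounds the final-round labels to maximise over (those present
#'   in the table are used).
#' @return named numeric vector of enrichment factors.
#' @export
enrichment_factor <- function(counts, clone_id = NULL, baseline = "naive",
                              final_rounds = c("R7", "R8")) {
  stopifnot(inherits(counts, "clone_counts"))
  final_rounds <- intersect(final_rounds, counts$rounds)
  if (!baseline %in% counts$rounds || !length(final_rounds)) {
    stop("count table lacks the baseline or final rounds")
  }
  fr <- freqs(counts)
  best <- apply(fr[, final_rounds, drop = FALSE], 1L, max)
  ef <- ifelse(fr[, baseline] > 0, best / fr[, baseline], NA_real_)
  names(ef) <- rownames(fr)
  if (!is.null(clone_id)) ef <- ef[clone_id]
  ef
}
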