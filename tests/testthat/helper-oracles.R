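# Brute-force oracles, independent of the package implementations they check,
# plus small config factories used across tests.

# --- demultiplexing oracle: per-read loops with explicit position-by-position
# comparison against every index and primer.
oracle_demux <- function(reads, index_map, primers, max_mismatch = 1L) {
  out <- data.frame(round = rep(NA_character_, length(reads)),
                    chain = NA_character_, reason = "assigned",
                    stringsAsFactors = FALSE)
  for (i in seq_along(reads)) {
    r <- toupper(reads[i])
    idx <- substr(r, 1, 2)
    round <- NA_character_
    for (lbl in names(index_map)) {
      if (idx == index_map[[lbl]]) round <- lbl
    }
    if (is.na(round)) {
      out$reason[i] <- "bad_index"
      next
    }
    hits <- character(0)
    for (ch in names(primers)) {
      p <- primers[[ch]]
      mm <- 0L
      for (k in seq_len(nchar(p))) {
        b <- substr(r, 2 + k, 2 + k)
        if (b == "" || b != substr(p, k, k)) mm <- mm + 1L
      }
      if (mm <= max_mismatch) hits <- c(hits, ch)
    }
    if (length(hits) == 1L) {
      out$round[i] <- round
      out$chain[i] <- hits
    } else {
      out$reason[i] <- if (length(hits) == 0L) "bad_primer" else "ambiguous"
    }
  }
  out
}

# --- complete-linkage oracle: at every step recompute all active cluster
# distances from scratch as the max over member pairs, merge the closest pair,
# breaking ties on the lexicographically smallest sorted pair of cluster
# labels (label = smallest member).
oracle_complete_linkage <- function(D, cut) {
  labels <- rownames(D)
  clusters <- lapply(labels, identity)
  repeat {
    k <- length(clusters)
    if (k < 2) break
    best <- NULL
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) {
        d <- max(D[clusters[[a]], clusters[[b]]])
        lab <- sort(c(min(clusters[[a]]), min(clusters[[b]])))
        cand <- list(d = d, a = a, b = b, lab = lab)
        if (is.null(best) || d < best$d ||
            (d == best$d && (lab[1] < best$lab[1] ||
                             (lab[1] == best$lab[1] && lab[2] < best$lab[2])))) {
          best <- cand
        }
      }
    }
    if (best$d > cut) break
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters <- clusters[-best$b]
  }
  # membership vector, clusters numbered by smallest member label
  mins <- vapply(clusters, min, character(1))
  clusters <- clusters[order(mins)]
  m <- integer(length(labels))
  names(m) <- labels
  for (i in seq_along(clusters)) m[clusters[[i]]] <- i
  m
}

# --- resampled rank statistic oracle: base-R ranks and explicit Wilcoxon
# sums, replicating the documented thinning protocol (per resample, one
# column-major Poisson draw over the whole matrix at rate count*dmin/depth).
oracle_rank_stats <- function(M, depth, late_idx, B, seed) {
  k <- ncol(M)
  n_late <- length(late_idx)
  center <- n_late * (k + 1) / 2
  equal <- length(unique(depth)) == 1
  set.seed(seed)
  nb <- if (equal) 1 else B
  acc <- numeric(nrow(M))
  for (b in seq_len(nb)) {
    Mb <- if (equal) M else
      matrix(rpois(length(M), as.vector(M) * rep(min(depth) / depth,
                                                 each = nrow(M))),
             nrow = nrow(M))
    for (i in seq_len(nrow(M))) {
      rk <- rank(Mb[i, ])
      acc[i] <- acc[i] + sum(rk[late_idx]) - center
    }
  }
  acc / nb
}

# --- tiny manual count table builder for filter/cluster tests
manual_counts <- function(counts, seqs = NULL,
                          rounds = colnames(counts)) {
  counts <- as.matrix(counts)
  colnames(counts) <- rounds
  n <- nrow(counts)
  if (is.null(seqs)) {
    # distinct in-frame stop-free loops
    pool <- c("GCTAGGGATTAT", "GCTAGGGATGCT", "TGTGCTCGGTTT", "AAAGCTGATCGG",
              "GCGCGGACTACT", "TTTGCTGCGAAA", "CCTCGGAAAGAT", "GATACTGCGCGG",
              "ACTACTTATGCG", "CGGGCTTTTAAA", "GCTAAAGATTGG", "TATGCGAAACCT")
    seqs <- pool[seq_len(n)]
  }
  new_clone_counts(counts,
                   data.frame(clone_id = sprintf("m%03d", seq_len(n)),
                              cdr3_dna = seqs, stringsAsFactors = FALSE))
}

# small six-round config for fast end-to-end tests (scaled depth; the spike
# frequency band is raised to keep spikes measurable at the small depth)
small_sixround <- function(seed, n_clones = 1500, depth = 2e5,
                           n_spiked = 8, ...) {
  sim_config_sixround(depth = depth, n_clones = n_clones, n_spiked = n_spiked,
                      spike_freq_range = c(5e-5, 2e-4),
                      spike_fold_range = c(20, 60), seed = seed, ...)
}

# variant whose spikes clear the 100-fold filter, for cascade/family tests
# (the larger spiked mass makes renormalisation decline of big null clones
# detectable, so depleted calls are not asserted on this fixture)
small_sixround_strong <- function(seed, n_spiked = 6, ...) {
  sim_config_sixround(depth = 2e5, n_clones = 1500, n_spiked = n_spiked,
                      spike_freq_range = c(5e-5, 1.2e-4),
                      spike_fold_range = c(150, 350), seed = seed, ...)
}

random_aa_loops <- function(n, len_min = 6, len_max = 14) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    L <- sample(len_min:len_max, 1)
    paste(sample(aa, L, replace = TRUE), collapse = "")
  }, character(1))
}
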