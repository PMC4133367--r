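## Drawing the naive library: distinct CDR3 DNA clonotypes with configured
## defect fractions, Dirichlet abundances, and spiked (truly selectable)
## clones with calibrated selection coefficients.

#' Draw a naive CDR3 library with ground truth
#'
#' Generates `n_clones` distinct CDR3 DNA clonotypes. A configured fraction
#' carries an in-loop stop codon, another a frameshift (length not divisible
#' by 3); the remainder are clean. Naive abundances come from a symmetric
#' Dirichlet with concentration `abundance_alpha`. `n_spiked` clean clones are
#' flagged as truly enriched; their per-generation selection coefficients are
#' calibrated so the configured total fold equals the realized deterministic
#' naive-to-final frequency ratio (the renormalisation by the growing spiked
#' mass is solved in closed form). When `spike_n_clusters` is set, spikes are
#' organised into mutational clusters of >= 60% amino-acid identity.
#'
#' CDR3 loops are rejection-sampled so the downstream FR4 anchor motif never
#' occurs before the true loop end — the clonotype extraction round-trip is
#' then exact on error-free reads.
#'
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed` when given.
#' @return list with `clones` (data.frame: clone_id, cdr3_dna, cdr3_aa,
#'   has_stop, in_frame, abundance, chain) and `truth` (data.frame: clone_id,
#'   selection_coefficient, is_spiked, configured_fold, spike_cluster).
#' @export
draw_library <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  with_seed(seed %||% cfg$seed, {
    n <- cfg$n_clones
    n_stop <- round(cfg$frac_stop * n)
    n_fs <- round(cfg$frac_frameshift * n)
    shuffled <- sample.int(n)
    stop_ids <- shuffled[seq_len(n_stop)]
    fs_ids <- shuffled[n_stop + seq_len(n_fs)]
    category <- rep("clean", n)
    category[stop_ids] <- "stop"
    category[fs_ids] <- "frameshift"

    len_aa <- sample(seq(cfg$cdr3_len_range[1], cfg$cdr3_len_range[2]),
                     n, replace = TRUE)
    seqs <- generate_cdr3_pool(len_aa, category, max_retries = 100L)

    abundance <- rgamma(n, shape = cfg$abundance_alpha, rate = 1)
    abundance <- abundance / sum(abundance)

    clone_id <- sprintf("c%06d", seq_len(n))
    is_spiked <- rep(FALSE, n)
    spike_cluster <- rep(NA_integer_, n)
    fold <- rep(1, n)
    w <- rep(1, n)

    if (cfg$n_spiked > 0) {
      clean <- which(category == "clean")
      band <- cfg$spike_freq_range
      # distance 0 inside the band, else log-distance to the nearest edge
      dist_band <- pmax(0, pmax(log(band[1]) - log(abundance[clean]),
                                log(abundance[clean]) - log(band[2])))
      picked <- clean[order(dist_band)][seq_len(cfg$n_spiked)]
      is_spiked[picked] <- TRUE
      fold[picked] <- runif(cfg$n_spiked, cfg$spike_fold_range[1],
                            cfg$spike_fold_range[2])

      if (!is.null(cfg$spike_n_clusters)) {
        cl <- rep(seq_len(cfg$spike_n_clusters), length.out = cfg$n_spiked)
        spike_cluster[picked] <- sort(cl)
        seqs[picked] <- generate_spike_clusters(
          sort(cl), cfg$cdr3_len_range, existing = seqs[-picked])
      }

      # calibrate per-generation fitness: with f_G(c) = f0 w^G / Z and
      # Z = sum f0 w^G, requiring f_G/f0 = F for spikes (w = 1 elsewhere)
      # gives Z = (1 - m0) / (1 - sum_spike f0 F), w = (F Z)^(1/G).
      G <- max(cfg$generations)
      m0 <- sum(abundance[picked])
      S <- sum(abundance[picked] * fold[picked])
      if (S >= 0.9) {
        stop("configured spikes would take >90% of the final library; ",
             "lower spike_fold_range or spike_freq_range")
      }
      Z <- (1 - m0) / (1 - S)
      w[picked] <- (fold[picked] * Z)^(1 / G)
    }

    fl <- translate_and_flag(seqs)
    clones <- data.frame(clone_id = clone_id, cdr3_dna = seqs,
                         cdr3_aa = fl$cdr3_aa, has_stop = fl$has_stop,
                         in_frame = fl$in_frame, abundance = abundance,
                         chain = "VH", stringsAsFactors = FALSE)
    truth <- data.frame(clone_id = clone_id, selection_coefficient = w,
                        is_spiked = is_spiked, configured_fold = fold,
                        spike_cluster = spike_cluster,
                        stringsAsFactors = FALSE)
    stopifnot(all(!fl$has_stop[is_spiked]), all(fl$in_frame[is_spiked]))
    list(clones = clones, truth = truth)
  })
}

# Vectorised pool generation with per-category construction and rejection of
# duplicates / sequences in which the FR4 anchor appears before the loop end.
generate_cdr3_pool <- function(len_aa, category, max_retries = 100L) {
  n <- length(len_aa)
  seqs <- rep(NA_character_, n)
  todo <- seq_len(n)
  for (try in seq_len(max_retries)) {
    seqs[todo] <- vapply(todo, function(i) {
      make_cdr3(len_aa[i], category[i])
    }, character(1))
    bad <- duplicated(seqs) | !anchor_safe(seqs)
    todo <- which(bad)
    if (!length(todo)) return(seqs)
  }
  stop("could not generate distinct anchor-safe CDR3 sequences after ",
       max_retries, " retries")
}

make_cdr3 <- function(L, category) {
  codons <- sample(sense_codons(), L, replace = TRUE)
  if (category == "stop") {
    codons[sample.int(L, 1L)] <- sample(STOP_CODONS, 1L)
    return(paste(codons, collapse = ""))
  }
  s <- paste(codons, collapse = "")
  if (category == "frameshift") {
    s <- substr(s, 1L, nchar(s) - sample(1:2, 1L))
  }
  s
}

# TRUE when the FR4 anchor's first occurrence in loop+anchor is exactly at the
# loop end (so extraction recovers the loop verbatim).
anchor_safe <- function(seqs, anchor = VH_FR4_ANCHOR) {
  pos <- regexpr(anchor, paste0(seqs, anchor), fixed = TRUE)
  pos == nchar(seqs) + 1L
}

# Spike clusters: members of one cluster share a loop length and differ from a
# common clean base loop at a few amino-acid positions, keeping every pair
# within distance 2m/L <= 0.4 of each other (complete-linkage cut safe);
# distinct clusters are unrelated random loops.
generate_spike_clusters <- function(cluster_of, len_range, existing,
                                    max_retries = 100L) {
  k <- max(cluster_of)
  out <- character(length(cluster_of))
  taken <- existing
  bases_aa <- list()
  for (cl in seq_len(k)) {
    idx <- which(cluster_of == cl)
    for (try in seq_len(max_retries)) {
      L <- sample(seq(len_range[1], len_range[2]), 1L)
      base <- sample(sense_codons(), L, replace = TRUE)
      m <- max(1L, floor(0.15 * L))
      members <- vapply(seq_along(idx), function(j) {
        pos <- sample.int(L, m)
        cod <- base
        for (p in pos) {
          repeat {
            cand <- sample(sense_codons(), 1L)
            if (translate_codon(cand) != translate_codon(base[p])) break
          }
          cod[p] <- cand
        }
        paste(cod, collapse = "")
      }, character(1))
      ok <- !anyDuplicated(members) && all(anchor_safe(members)) &&
        !any(members %in% taken) &&
        cluster_far_enough(members, bases_aa, L)
      if (ok) {
        out[idx] <- members
        taken <- c(taken, members)
        bases_aa[[cl]] <- translate_and_flag(members)$cdr3_aa
        break
      }
      if (try == max_retries) stop("could not place spike cluster ", cl)
    }
  }
  out
}

translate_codon <- function(codon) {
  as.character(Biostrings::translate(Biostrings::DNAString(codon),
                                     no.init.codon = TRUE))
}

# guard: a new cluster's members must sit far (> 0.5) from all previous
# clusters at the amino-acid level, so clusters never merge at the 0.40 cut
cluster_far_enough <- function(members, bases_aa, L) {
  if (!length(bases_aa)) return(TRUE)
  aa_new <- translate_and_flag(members)$cdr3_aa
  for (prev in bases_aa) {
    for (a in aa_new) for (b in prev) {
      if (loop_distance(a, b) <= 0.5) return(FALSE)
    }
  }
  TRUE
}
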