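## Clonotype family clustering: length-aware normalized Hamming distance on
## amino-acid CDR3 loops, complete-linkage agglomeration cut at 60% identity,
## and family-level summaries. DNA variants translating to the same loop are
## pooled before clustering.

#' Normalized Hamming distance between two CDR3 loops
#'
#' 1 when the loop lengths differ; otherwise the fraction of mismatched
#' positions (a semimetric on loops: symmetric, zero iff identical for equal
#' lengths, bounded by 1).
#'
#' @param a,b non-empty amino-acid strings.
#' @return distance in \[0, 1\].
#' @export
loop_distance <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  la <- nchar(a)
  if (la != nchar(b)) return(1)
  sa <- strsplit(a, "", fixed = TRUE)[[1]]
  sb <- strsplit(b, "", fixed = TRUE)[[1]]
  sum(sa != sb) / la
}

#' Pairwise loop-distance matrix
#'
#' @param loops character vector of amino-acid loops; names become the matrix
#'   labels.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
loop_distance_matrix <- function(loops) {
  n <- length(loops)
  labels <- names(loops) %||% as.character(seq_len(n))
  D <- matrix(1, n, n, dimnames = list(labels, labels))
  diag(D) <- 0
  len <- nchar(loops)
  for (L in unique(len)) {
    idx <- which(len == L)
    if (length(idx) < 2L) next
    chars <- matrix(unlist(strsplit(loops[idx], "", fixed = TRUE)),
                    nrow = L)
    for (a in seq_along(idx)[-length(idx)]) {
      for (b in (a + 1L):length(idx)) {
        d <- sum(chars[, a] != chars[, b]) / L
        D[idx[a], idx[b]] <- d
        D[idx[b], idx[a]] <- d
      }
    }
  }
  D
}

#' Complete-linkage clustering cut at a distance height
#'
#' Agglomerative clustering where the distance between clusters is the
#' maximum pairwise member distance. Merging proceeds while the smallest
#' cluster distance is at most `cut`; ties are broken by merging the pair
#' whose sorted cluster labels are lexicographically smallest (a cluster is
#' labelled by its lexicographically smallest member). The cut at
#' `1 - min_identity` guarantees every within-cluster pair is at least
#' `min_identity` identical.
#'
#' @param D symmetric distance matrix with labels.
#' @param cut merge height; defaults to `1 - min_identity`.
#' @param min_identity within-family identity floor (default 0.60).
#' @return named integer vector: cluster membership per input label, numbered
#'   in order of each cluster's smallest label.
#' @export
complete_linkage_cluster <- function(D, cut = NULL, min_identity = 0.60) {
  cut <- cut %||% (1 - min_identity)
  n <- nrow(D)
  labels <- rownames(D)
  stopifnot(!is.null(labels), isTRUE(all.equal(D, t(D))),
            all(diag(D) == 0))
  members <- as.list(seq_len(n))
  cl_label <- labels
  CD <- D  # current complete-linkage distances between active clusters
  active <- rep(TRUE, n)
  repeat {
    act <- which(active)
    if (length(act) < 2L) break
    sub <- CD[act, act, drop = FALSE]
    sub[lower.tri(sub, diag = TRUE)] <- Inf
    m <- min(sub)
    if (m > cut) break
    hits <- which(sub == m, arr.ind = TRUE)
    # deterministic tie-break: lexicographically smallest sorted label pair
    pair_lab <- t(apply(hits, 1L, function(h) {
      sort(c(cl_label[act[h[1]]], cl_label[act[h[2]]]))
    }))
    ord <- order(pair_lab[, 1L], pair_lab[, 2L])[1L]
    i <- act[hits[ord, 1L]]
    j <- act[hits[ord, 2L]]
    # merge j into i
    members[[i]] <- c(members[[i]], members[[j]])
    cl_label[i] <- min(cl_label[i], cl_label[j])
    active[j] <- FALSE
    upd <- pmax(CD[i, ], CD[j, ])
    CD[i, ] <- upd
    CD[, i] <- upd
    CD[i, i] <- 0
  }
  act <- which(active)
  act <- act[order(cl_label[act])]
  membership <- integer(n)
  for (k in seq_along(act)) membership[members[[act[k]]]] <- k
  setNames(membership, labels)
}

#' Pool DNA clonotypes by amino-acid loop
#'
#' Sums the counts of DNA variants that translate to the same amino-acid
#' CDR3, keeping the member DNA clone ids.
#'
#' @param counts a `clone_counts`.
#' @param clone_id the (cascade-surviving) clones to pool; default all
#'   in-frame, stop-free clones.
#' @return list with `aa` (character vector of loops), `counts` (pooled
#'   integer matrix, rows = loops), `members` (list of DNA clone-id vectors),
#'   all in lexicographic loop order.
#' @export
pool_by_aa <- function(counts, clone_id = NULL) {
  stopifnot(inherits(counts, "clone_counts"))
  cl <- counts$clones
  if (is.null(clone_id)) {
    clone_id <- cl$clone_id[!is.na(cl$cdr3_aa)]
  }
  sel <- match(clone_id, cl$clone_id)
  aa <- cl$cdr3_aa[sel]
  if (any(is.na(aa))) stop("cannot pool clones without an in-frame translation")
  aa_u <- sort(unique(aa))
  g <- match(aa, aa_u)
  M <- counts$counts[sel, , drop = FALSE]
  pooled <- rowsum(M, g)
  rownames(pooled) <- aa_u
  members <- split(clone_id, g)
  names(members) <- aa_u
  list(aa = aa_u, counts = pooled, members = members)
}

#' Build clonotype families from cascade survivors
#'
#' Translates the surviving clones, pools DNA variants by amino-acid loop,
#' computes the loop-distance matrix, clusters by complete linkage at the
#' identity cutoff, and summarises each family.
#'
#' @param counts a `clone_counts`.
#' @param survivors clone ids that survived the filter cascade.
#' @param min_identity within-family identity floor (default 0.60).
#' @param baseline,final,final_rounds round labels used for the pooled
#'   frequencies and the family enrichment factor.
#' @return data.frame of class `family_table`, one row per family, sorted by
#'   pooled final-round frequency (descending): `family_id`, `size` (number
#'   of amino-acid loops), `n_dna` (DNA variants), `members`
#'   (comma-separated loops), `dna_members`, `representative` (loop of the
#'   member most abundant in the final round), `pooled_final_freq`,
#'   `family_enrichment`, `max_intra_distance`.
#' @export
build_families <- function(counts, survivors, min_identity = 0.60,
                           baseline = "naive", final = "R7",
                           final_rounds = c("R7", "R8")) {
  pooled <- pool_by_aa(counts, survivors)
  d <- depths(counts)
  if (length(pooled$aa) == 0L) {
    return(structure(data.frame(), class = c("family_table", "data.frame")))
  }
  D <- loop_distance_matrix(setNames(pooled$aa, pooled$aa))
  membership <- complete_linkage_cluster(D, min_identity = min_identity)

  final_rounds <- intersect(final_rounds, counts$rounds)
  rows <- lapply(split(pooled$aa, membership), function(loops) {
    idx <- match(loops, pooled$aa)
    cc <- pooled$counts[idx, , drop = FALSE]
    pooled_freq <- colSums(cc) / d[colnames(cc)]
    rep_loop <- loops[which.max(cc[, final])]
    fe <- if (pooled_freq[baseline] > 0) {
      max(pooled_freq[final_rounds]) / pooled_freq[baseline]
    } else NA_real_
    maxd <- if (length(loops) > 1L) {
      max(D[loops, loops])
    } else 0
    data.frame(size = length(loops),
               n_dna = length(unlist(pooled$members[loops])),
               members = paste(loops, collapse = ","),
               dna_members = paste(unlist(pooled$members[loops]),
                                   collapse = ","),
               representative = rep_loop,
               pooled_final_freq = unname(pooled_freq[final]),
               family_enrichment = unname(fe),
               max_intra_distance = maxd,
               stringsAsFactors = FALSE)
  })
  fam <- do.call(rbind, rows)
  fam <- fam[order(-fam$pooled_final_freq, fam$members), , drop = FALSE]
  fam <- cbind(family_id = sprintf("F%03d", seq_len(nrow(fam))), fam)
  rownames(fam) <- NULL
  structure(fam, class = c("family_table", "data.frame"))
}

#' Select families by size and final-round frequency
#'
#' Keeps families with at least `min_members` amino-acid loops (singleton
#' families are discarded) and pooled final-round frequency at or above
#' `min_final_freq` (the 0.1% floor), sorted by pooled frequency.
#'
#' @param families a `family_table` from [build_families()].
#' @param min_members minimum number of member loops (default 2).
#' @param min_final_freq minimum pooled final-round frequency (default 0.001).
#' @return the filtered `family_table`.
#' @export
select_families <- function(families, min_members = 2L,
                            min_final_freq = 0.001) {
  if (nrow(families) == 0L) return(families)
  keep <- families$size >= min_members &
    families$pooled_final_freq >= min_final_freq
  out <- families[keep, , drop = FALSE]
  out <- out[order(-out$pooled_final_freq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Family enrichment factor
#'
#' Pooled `max(f_R7, f_R8)` over pooled naive frequency for an explicit set
#' of member clones; reduces to the clone-level enrichment factor for a
#' single-member family.
#'
#' @param counts a `clone_counts`.
#' @param clone_id the family's member (DNA) clone ids.
#' @param baseline,final_rounds round labels.
#' @return a single fold value (`NA` when the pooled naive frequency is 0).
#' @export
family_enrichment <- function(counts, clone_id, baseline = "naive",
                              final_rounds = c("R7", "R8")) {
  stopifnot(inherits(counts, "clone_counts"))
  final_rounds <- intersect(final_rounds, counts$rounds)
  idx <- match(clone_id, counts$clones$clone_id)
  stopifnot(!anyNA(idx))
  d <- depths(counts)
  pooled <- colSums(counts$counts[idx, , drop = FALSE]) / d
  if (pooled[baseline] == 0) return(NA_real_)
  unname(max(pooled[final_rounds]) / pooled[baseline])
}
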