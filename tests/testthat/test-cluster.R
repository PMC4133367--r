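# Loop distance, complete-linkage families, family selection.

test_that("loop distance follows the length-aware normalized Hamming rule", {
  expect_equal(loop_distance("ARDY", "ARDYV"), 1)   # lengths differ
  expect_equal(loop_distance("ARDY", "ARDY"), 0)
  expect_equal(loop_distance("ABCD", "ABXD"), 0.25)
  # semimetric properties on random pairs
  set.seed(5)
  loops <- random_aa_loops(20)
  for (i in 1:20) {
    a <- sample(loops, 1); b <- sample(loops, 1)
    d1 <- loop_distance(a, b)
    expect_equal(d1, loop_distance(b, a))
    expect_gte(d1, 0); expect_lte(d1, 1)
    if (a == b) expect_equal(d1, 0)
    if (nchar(a) == nchar(b) && a != b) expect_gt(d1, 0)
  }
})

test_that("distance matrix equals direct per-position comparison on all pairs", {
  set.seed(6)
  loops <- unique(random_aa_loops(40))
  names(loops) <- sprintf("s%02d", seq_along(loops))
  D <- loop_distance_matrix(loops)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  for (i in seq_along(loops)) {
    for (j in seq_along(loops)) {
      if (i == j) next
      a <- loops[i]; b <- loops[j]
      expected <- if (nchar(a) != nchar(b)) 1 else {
        mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      }
      expect_identical(unname(D[i, j]), expected)
    }
  }
})

test_that("trivial clusterings come out right", {
  # three loops of three different lengths: all singletons
  D <- loop_distance_matrix(c(a = "ARDY", b = "ARDYV", c = "ARD"))
  m <- complete_linkage_cluster(D)
  expect_equal(length(unique(m)), 3)
  # two identical + one at distance > cut
  D2 <- loop_distance_matrix(c(a = "AAAA", b = "AAAA", c = "AAYY"))
  m2 <- complete_linkage_cluster(D2)
  expect_equal(unname(m2[c("a", "b")]), c(1L, 1L))
  expect_false(m2[["c"]] == m2[["a"]])
  # single sequence: one singleton family
  D3 <- loop_distance_matrix(c(x = "ARNDC"))
  expect_equal(unname(complete_linkage_cluster(D3)), 1L)
})

test_that("partition matches the brute-force agglomerative oracle", {
  for (seed in c(11, 12, 13)) {
    set.seed(seed)
    # mixture of mutational clusters and unrelated loops, ties likely
    base <- random_aa_loops(4, 8, 12)
    loops <- character(0)
    for (b in base) {
      for (k in 1:4) {
        v <- strsplit(b, "")[[1]]
        pos <- sample(seq_along(v), sample(0:3, 1))
        v[pos] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         length(pos), TRUE)
        loops <- c(loops, paste(v, collapse = ""))
      }
    }
    loops <- c(loops, random_aa_loops(14, 8, 12))
    loops <- unique(loops)[1:min(30, length(unique(loops)))]
    names(loops) <- sprintf("q%02d", seq_along(loops))
    D <- loop_distance_matrix(loops)
    expect_identical(complete_linkage_cluster(D, cut = 0.4),
                     oracle_complete_linkage(D, cut = 0.4))
  }
})

test_that("partition agrees with hclust on tie-free distances", {
  set.seed(21)
  n <- 25
  D <- matrix(0, n, n, dimnames = list(sprintf("h%02d", 1:n),
                                       sprintf("h%02d", 1:n)))
  v <- runif(n * (n - 1) / 2)  # almost surely unique
  D[lower.tri(D)] <- v
  D <- D + t(D)
  ours <- complete_linkage_cluster(D, cut = 0.4)
  hc <- stats::cutree(stats::hclust(stats::as.dist(D), method = "complete"),
                      h = 0.4)
  # same partition up to label renumbering
  expect_equal(length(unique(ours)), length(unique(hc)))
  expect_true(all(tapply(hc, ours, function(z) length(unique(z))) == 1))
})

test_that("input order does not change the partition", {
  set.seed(31)
  loops <- unique(random_aa_loops(20, 6, 9))
  names(loops) <- sprintf("p%02d", seq_along(loops))
  D <- loop_distance_matrix(loops)
  m1 <- complete_linkage_cluster(D)
  perm <- sample(length(loops))
  m2 <- complete_linkage_cluster(D[perm, perm])
  # compare as partitions of the label set
  split1 <- split(names(m1), m1)
  split2 <- split(names(m2), m2)
  norm <- function(s) sort(vapply(s, function(z) paste(sort(z), collapse = "|"),
                                  character(1)))
  expect_identical(norm(split1), norm(split2))
})

test_that("families pool amino-acid synonyms and respect selection rules", {
  # two DNA variants of the same loop + one singleton + a 3-member family
  seqs <- c("GCTCGGGAT", "GCACGGGAT",               # both ARD
            "TGGTGGTGGTGG",                          # WWWW singleton
            "AAAGCTGCTAAA", "AAAGCTGCGAAA", "AAAGCCGCTAAA")  # KAAK x3
  M <- rbind(c(2L, 10L, 40L),
             c(1L, 5L, 20L),
             c(500L, 400L, 300L),
             c(1L, 40L, 200L), c(1L, 30L, 150L), c(1L, 20L, 100L))
  M <- rbind(M, 1000L - colSums(M))
  ct <- new_clone_counts(`colnames<-`(M, c("naive", "R7", "R8")),
                         data.frame(clone_id = sprintf("d%02d", 1:7),
                                    cdr3_dna = c(seqs, "GGGGGGAAACCC")))
  fam <- build_families(ct, survivors = sprintf("d%02d", 1:6),
                        final = "R7")
  expect_equal(nrow(fam), 3)
  ard <- fam[fam$representative == "ARD", ]
  expect_equal(ard$size, 1)      # one amino-acid loop
  expect_equal(ard$n_dna, 2)     # two DNA variants pooled
  expect_equal(ard$pooled_final_freq, 15 / 1000)
  # family enrichment = pooled max(f_R7, f_R8) / pooled f_naive
  kaak <- fam[grepl("KAAK", fam$members), ]
  expect_equal(kaak$family_enrichment, (450 / 1000) / (3 / 1000))
  sel <- select_families(fam, min_members = 2, min_final_freq = 0.001)
  expect_false("WWWW" %in% sel$representative)  # singleton excluded
  sel2 <- select_families(fam, min_members = 1, min_final_freq = 0.5)
  expect_equal(nrow(sel2), 0)    # frequency floor excludes everything
})

test_that("family enrichment reduces to the clone enrichment factor", {
  M <- rbind(c(2L, 30L, 10L), c(98L, 70L, 90L))
  ct <- new_clone_counts(`colnames<-`(M, c("naive", "R7", "R8")),
                         data.frame(clone_id = c("x1", "x2"),
                                    cdr3_dna = c("GCTGCT", "CGGCGG")))
  expect_equal(family_enrichment(ct, "x1"),
               unname(enrichment_factor(ct)["x1"]))
  # arithmetic: pooled naive 1e-6, pooled R7 1.5e-4 -> 150
  M2 <- rbind(c(1L, 150L, 10L), c(999999L, 999850L, 999990L))
  ct2 <- new_clone_counts(`colnames<-`(M2, c("naive", "R7", "R8")),
                          data.frame(clone_id = c("y1", "y2"),
                                     cdr3_dna = c("GCTGCT", "CGGCGG")))
  expect_equal(family_enrichment(ct2, "y1"), 150)
})

test_that("every retained family satisfies the complete-linkage identity floor", {
  cfg <- small_sixround_strong(seed = 63, spike_n_clusters = 3)
  ex <- simulate_experiment(cfg)
  enr <- enrichment_test(ex$counts, test_config(seed = 63))
  surv <- cascade_survivors(run_cascade(ex$counts, enr))
  fam <- build_families(ex$counts, surv)
  if (nrow(fam)) {
    expect_true(all(fam$max_intra_distance <= 0.4))
  }
  sel <- select_families(fam)
  # retained families correspond to seeded spike clusters only
  if (nrow(sel)) {
    dna <- unlist(strsplit(sel$dna_members, ","))
    expect_true(all(dna %in% ex$truth$clone_id[ex$truth$is_spiked]))
  }
})
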