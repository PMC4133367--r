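# Demultiplexing rules, CDR3 extraction, counting, and translation flags.

vh_read <- function(index, loop, tail = "CTGTTTATTACTGTGTGAGA",
                    anchor = "TGGGGC") {
  r <- paste0(index, tail, loop, anchor, strrep("CAAGGGACCACG", 10))
  substr(r, 1, 100)
}

test_that("index must match exactly, primer within one mismatch", {
  im <- c(naive = "AA", R3 = "CC")
  loop <- "GCTAGGGATTATACTTTTGATTAT"
  r_ok <- vh_read("AA", loop)
  got <- demultiplex(r_ok, im)
  expect_equal(got$round, "naive")
  expect_equal(got$chain, "VH")
  # one mismatch in the index: unassigned even though the primer is perfect
  r_idx <- vh_read("AG", loop)
  expect_equal(demultiplex(r_idx, im)$reason, "bad_index")
  # one mismatch in the primer tail: still assigned
  tail1 <- "CTGTTTATTACTGTGTGAGC"
  expect_equal(demultiplex(vh_read("AA", loop, tail = tail1), im)$round,
               "naive")
  # two mismatches: unassigned
  tail2 <- "CTGTTTATTACTGTGTGTGC"
  expect_equal(demultiplex(vh_read("AA", loop, tail = tail2), im)$reason,
               "bad_primer")
  # N counts as a mismatch; one N passes, N plus a substitution fails
  tailN <- "NTGTTTATTACTGTGTGAGA"
  expect_equal(demultiplex(vh_read("AA", loop, tail = tailN), im)$round,
               "naive")
  tailN2 <- "NTGTTTATTACTGTGTGAGC"
  expect_equal(demultiplex(vh_read("AA", loop, tail = tailN2), im)$reason,
               "bad_primer")
})

test_that("a read matching two primers within tolerance is ambiguous", {
  primers <- c(A = "AAAA", B = "AAAT")
  got <- demultiplex(paste0("CC", "AAAA", strrep("G", 40)),
                     c(naive = "CC"), primers = primers)
  expect_equal(got$reason, "ambiguous")
  expect_true(is.na(got$round))
})

test_that("demultiplexing agrees with an exhaustive per-read oracle", {
  cfg <- sim_config(n_clones = 60, n_spiked = 0, rounds = c("naive", "R3"),
                    depth_per_round = 500, error_rate = 0.05, seed = 21)
  ex <- simulate_experiment(cfg, reads = TRUE)
  im <- cfg$index_map
  got <- demultiplex(ex$reads$sequence, im)
  ora <- oracle_demux(ex$reads$sequence, im,
                      c(VH = "CTGTTTATTACTGTGTGAGA",
                        VL = "CTTGGTCCCTCCGCCGAA"))
  expect_identical(got, ora)
  # per-bin counts match the oracle's
  expect_equal(table(got$round), table(ora$round))
})

test_that("demultiplexing is independent of read order", {
  cfg <- sim_config(n_clones = 40, n_spiked = 0, rounds = c("naive", "R3"),
                    depth_per_round = 300, error_rate = 0.02, seed = 22)
  ex <- simulate_experiment(cfg, reads = TRUE)
  perm <- sample(nrow(ex$reads))
  a <- demux_count(ex$reads$sequence, cfg$index_map)
  b <- demux_count(ex$reads$sequence[perm], cfg$index_map)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$counts$clones$cdr3_dna, b$counts$clones$cdr3_dna)
})

test_that("CDR3 extraction returns the anchored loop, or a 25-base key", {
  loop30 <- "GCTAGGGATTATACTTTTGATTATTGGATT"
  r <- vh_read("AA", loop30)
  expect_equal(extract_cdr3(r, "VH"), loop30)
  # anchor destroyed -> falls back to the first 25 bases
  r_noanchor <- paste0("AA", "CTGTTTATTACTGTGTGAGA", loop30,
                       strrep("A", 48))
  r_noanchor <- substr(r_noanchor, 1, 100)
  expect_equal(extract_cdr3(r_noanchor, "VH"), substr(loop30, 1, 25))
  # prefix25 mode always keys on the first 25 bases
  expect_equal(extract_cdr3(r, "VH", mode = "prefix25"),
               substr(paste0(loop30, "TGGGGC"), 1, 25))
  # fewer than 25 usable bases and no anchor -> dropped
  short <- substr(paste0("AA", "CTGTTTATTACTGTGTGAGA", "GCTGCTGCT"), 1, 31)
  expect_true(is.na(extract_cdr3(short, "VH")))
})

test_that("VL-end reads are reverse-complemented to coding sense", {
  loop <- "GCTCGGTTTGGGACTAAA"
  read <- paste0("AA", "CTTGGTCCCTCCGCCGAA", revcomp(loop),
                 revcomp("TACTGT"), strrep("G", 40))
  read <- substr(read, 1, 100)
  got <- demultiplex(read, c(naive = "AA"))
  expect_equal(got$chain, "VL")
  expect_equal(extract_cdr3(read, "VL"), loop)
})

test_that("count table building is exact and deterministic", {
  empty <- build_count_table(character(0), character(0),
                             round_order = c("naive", "R3"))
  expect_equal(nrow(empty$counts), 0)
  expect_equal(empty$rounds, c("naive", "R3"))
  tab <- build_count_table(c("AAA", "AAA", "CCC"),
                           c("naive", "naive", "R3"),
                           round_order = c("naive", "R3"))
  expect_equal(unname(tab$counts), matrix(c(2L, 0L, 0L, 1L), nrow = 2))
  expect_equal(tab$clones$cdr3_dna, c("AAA", "CCC"))
})

test_that("assigned + unassigned + dropped partitions the reads", {
  cfg <- sim_config(n_clones = 50, n_spiked = 0, rounds = c("naive", "R3"),
                    depth_per_round = 400, error_rate = 0.05, seed = 23)
  ex <- simulate_experiment(cfg, reads = TRUE)
  qc <- demux_count(ex$reads$sequence, cfg$index_map)$qc
  expect_equal(qc$assigned + qc$dropped + sum(qc$unassigned), qc$total)
})

test_that("error-free reads round-trip to the simulator's exact counts", {
  cfg <- sim_config(n_clones = 300, n_spiked = 3, depth_per_round = 3000,
                    spike_freq_range = c(1e-3, 1e-2),
                    spike_fold_range = c(5, 20), error_rate = 0,
                    seed = 24)
  ex <- simulate_experiment(cfg, reads = TRUE)
  dm <- demux_count(ex$reads$sequence, cfg$index_map)
  seen <- rowSums(ex$counts$counts) > 0
  ord <- order(ex$counts$clones$cdr3_dna[seen])
  expect_identical(ex$counts$clones$cdr3_dna[seen][ord],
                   dm$counts$clones$cdr3_dna)
  expect_identical(unname(ex$counts$counts[seen, , drop = FALSE][ord, ]),
                   unname(dm$counts$counts))
})

test_that("translation flags stops, frameshifts and invalid characters", {
  fl <- translate_and_flag(c("TAAGCTGCT", "GCTGCTGCTGCTGCTGCTGCTGCTG",
                             "GCTCGG", "GCNCGG"))
  expect_true(fl$has_stop[1])
  expect_true(fl$in_frame[1])
  expect_false(fl$in_frame[2])   # 25 bases
  expect_true(is.na(fl$cdr3_aa[2]))
  expect_equal(fl$cdr3_aa[3], "AR")
  expect_false(fl$valid[4])
  # flags of a simulated pool match its configuration
  cfg <- sim_config(n_clones = 2000, frac_stop = 0.15, frac_frameshift = 0.1,
                    n_spiked = 0, seed = 25)
  lib <- draw_library(cfg)
  fl2 <- translate_and_flag(lib$clones$cdr3_dna)
  expect_lt(abs(mean(fl2$has_stop) - 0.15), 0.02)
  expect_lt(abs(mean(!fl2$in_frame) - 0.1), 0.02)
})

test_that("count table TSV round-trips", {
  cfg <- sim_config(n_clones = 50, n_spiked = 0, depth_per_round = 500,
                    seed = 26)
  ex <- simulate_experiment(cfg)
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_count_table(ex$counts, f)
  back <- read_count_table(f)
  expect_identical(unname(back$counts), unname(ex$counts$counts))
  expect_identical(back$clones$cdr3_dna, ex$counts$clones$cdr3_dna)
  # frequencies per round sum to one
  expect_equal(unname(colSums(freqs(back))), rep(1, 5))
})
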