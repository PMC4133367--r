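# Synthetic selection experiments: library composition, selection dynamics,
# read synthesis.

test_that("drawn library matches configured composition", {
  cfg <- sim_config(n_clones = 20000, frac_stop = 0.2, frac_frameshift = 0.1,
                    n_spiked = 20, depth_per_round = 1e4, seed = 5)
  lib <- draw_library(cfg)
  cl <- lib$clones
  expect_equal(nrow(cl), 20000)
  expect_false(anyDuplicated(cl$cdr3_dna) > 0)
  expect_equal(sum(cl$abundance), 1, tolerance = 1e-12)
  # defect fractions within +-2% at this size
  expect_lt(abs(mean(cl$has_stop) - 0.2), 0.02)
  expect_lt(abs(mean(!cl$in_frame) - 0.1), 0.02)
  # spikes are clean and flagged consistently
  sp <- lib$truth$is_spiked
  expect_equal(sum(sp), 20)
  expect_true(all(!cl$has_stop[sp]))
  expect_true(all(cl$in_frame[sp]))
  expect_true(all(lib$truth$selection_coefficient[sp] > 1))
  expect_true(all(lib$truth$selection_coefficient[!sp] == 1))
})

test_that("tiny forced config yields exactly what it says", {
  cfg <- sim_config(n_clones = 10, frac_stop = 0, frac_frameshift = 0,
                    n_spiked = 2, depth_per_round = 100,
                    spike_freq_range = c(1e-3, 0.05),
                    spike_fold_range = c(2, 4), seed = 1)
  lib <- draw_library(cfg)
  expect_equal(length(unique(lib$clones$cdr3_dna)), 10)
  expect_true(all(lib$clones$in_frame))
  expect_true(all(!lib$clones$has_stop))
  expect_equal(sum(lib$truth$is_spiked), 2)
})

test_that("library drawing is seed-deterministic", {
  cfg <- sim_config(n_clones = 300, seed = 9)
  expect_identical(draw_library(cfg), draw_library(cfg))
})

test_that("config validation rejects bad inputs", {
  expect_error(sim_config(frac_stop = 1.5), "frac_stop")
  expect_error(sim_config(n_spiked = 2, spike_fold_range = c(0.5, 2)),
               "exceed 1")
  expect_error(sim_config(rounds = c("a", "a")), "distinct")
  expect_error(sim_config(index_map = c(naive = "AAA", R3 = "CC", R5 = "GG",
                                        R7 = "TT", R8 = "AC")),
               "2 bases")
})

test_that("neutral evolution keeps expected frequencies flat", {
  cfg <- sim_config(n_clones = 50, n_spiked = 0, depth_per_round = 1e4,
                    seed = 2)
  lib <- draw_library(cfg)
  ef <- expected_freqs(lib$clones, lib$truth, cfg)
  for (j in 2:ncol(ef)) expect_equal(ef[, j], ef[, 1])
})

test_that("one generation of selection renormalises as f*w / sum(f*w)", {
  clones <- data.frame(clone_id = c("a", "b"), abundance = c(0.5, 0.5),
                       stringsAsFactors = FALSE)
  truth <- data.frame(clone_id = c("a", "b"),
                      selection_coefficient = c(2, 1),
                      stringsAsFactors = FALSE)
  cfg <- sim_config(n_clones = 2, rounds = c("naive", "R3"),
                    generations = c(0L, 1L), depth_per_round = 10,
                    n_spiked = 0, seed = 1)
  ef <- expected_freqs(clones, truth, cfg)
  expect_equal(unname(ef[, "R3"]), c(2 / 3, 1 / 3))
})

test_that("calibrated spike fitness realises the configured fold exactly in expectation", {
  cfg <- sim_config(n_clones = 2000, n_spiked = 10, depth_per_round = 1e5,
                    seed = 3)
  lib <- draw_library(cfg)
  ef <- expected_freqs(lib$clones, lib$truth, cfg)
  sp <- lib$truth$is_spiked
  det_fold <- ef[sp, ncol(ef)] / ef[sp, 1]
  expect_equal(unname(det_fold), lib$truth$configured_fold[sp],
               tolerance = 1e-8)
})

test_that("sampled counts honour depths and spike expectations", {
  cfg <- sim_config_sixround(depth = 1e6, n_clones = 2000, n_spiked = 5,
                             seed = 4)
  lib <- draw_library(cfg)
  counts <- evolve_rounds(lib$clones, lib$truth, cfg)
  expect_equal(unname(depths(counts)), cfg$depth_per_round)
  # each spiked clone's final count within 4 sd of its analytic expectation
  ef <- expected_freqs(lib$clones, lib$truth, cfg)
  sp <- which(lib$truth$is_spiked)
  last <- length(cfg$rounds)
  mu <- ef[sp, last] * cfg$depth_per_round[last]
  obs <- counts$counts[sp, last]
  expect_true(all(abs(obs - mu) < 4 * sqrt(mu) + 1))
})

test_that("error-free reads follow the documented layout", {
  cfg <- sim_config(n_clones = 5, frac_stop = 0, frac_frameshift = 0,
                    n_spiked = 0, rounds = c("naive", "R3"),
                    depth_per_round = 20, error_rate = 0, seed = 6)
  lib <- draw_library(cfg)
  counts <- evolve_rounds(lib$clones, lib$truth, cfg)
  rd <- synthesize_reads(counts, cfg)
  expect_true(all(nchar(rd$sequence) == 100))
  r1 <- rd[rd$round == "naive", ][1, ]
  idx <- cfg$index_map[["naive"]]
  expect_equal(substr(r1$sequence, 1, 2), unname(idx))
  expect_equal(substr(r1$sequence, 3, 22), "CTGTTTATTACTGTGTGAGA")
  # the read contains one of the clone loops right after the primer,
  # terminated by the FR4 anchor
  body <- substr(r1$sequence, 23, 100)
  hit <- vapply(lib$clones$cdr3_dna, function(s) {
    startsWith(body, paste0(s, "TGGGGC"))
  }, logical(1))
  expect_equal(sum(hit), 1L)
  # per-round read counts equal the count table
  expect_equal(as.integer(table(rd$round)[cfg$rounds]),
               as.integer(colSums(counts$counts)))
})

test_that("read synthesis is byte-deterministic and errors hit the configured rate", {
  cfg <- sim_config(n_clones = 100, n_spiked = 0, rounds = c("naive", "R3"),
                    depth_per_round = 1e4, error_rate = 0.01, seed = 8)
  lib <- draw_library(cfg)
  counts <- evolve_rounds(lib$clones, lib$truth, cfg)
  rd1 <- synthesize_reads(counts, cfg)
  rd2 <- synthesize_reads(counts, cfg)
  expect_identical(rd1, rd2)
  cfg0 <- sim_config(n_clones = 100, n_spiked = 0, rounds = c("naive", "R3"),
                     depth_per_round = 1e4, error_rate = 0, seed = 8)
  rd0 <- synthesize_reads(counts, cfg0)
  a <- strsplit(rd1$sequence, "")
  b <- strsplit(rd0$sequence, "")
  mism <- sum(mapply(function(x, y) sum(x != y), a, b))
  rate <- mism / (length(a) * 100)
  expect_gt(rate, 0.009)
  expect_lt(rate, 0.011)
})

test_that("FASTQ output round-trips through a gzipped file", {
  cfg <- sim_config(n_clones = 20, n_spiked = 0, rounds = c("naive", "R3"),
                    depth_per_round = 200, error_rate = 0, seed = 10)
  ex <- simulate_experiment(cfg)
  f <- tempfile(fileext = ".fastq.gz")
  on.exit(unlink(f))
  synthesize_reads(ex$counts, cfg, path = f)
  got <- as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
  rd <- synthesize_reads(ex$counts, cfg)
  expect_equal(unname(got), rd$sequence)
})

test_that("overlong CDR3 fails with the clone named", {
  long_loop <- paste(rep("GCT", 30), collapse = "")  # 90 bases
  counts <- manual_counts(matrix(c(1L, 1L), nrow = 1,
                                 dimnames = list(NULL, c("naive", "R3"))),
                          seqs = long_loop)
  cfg <- sim_config(n_clones = 1, rounds = c("naive", "R3"),
                    depth_per_round = 10, n_spiked = 0, seed = 1)
  expect_error(synthesize_reads(counts, cfg), "m001")
})
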