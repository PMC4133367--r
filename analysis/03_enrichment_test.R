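#!/usr/bin/env Rscript
# Two-class resampled rank test (early: naive, R3a, R3; late: R5, R7, R8)
# with permutation-estimated FDR on the simulated study count table.

suppressMessages(library(clonesift))
seed <- if (length(a <- commandArgs(TRUE))) as.integer(a[1]) else 1L
dir.create("results/enrichment", recursive = TRUE, showWarnings = FALSE)

counts <- read_count_table("results/sim/counts.tsv")
enr <- enrichment_test(counts, test_config(seed = seed))
write.table(enr, "results/enrichment/enrichment.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

message(sprintf("clones tested: %d", nrow(enr)))
message(sprintf("significantly enriched at FDR < 0.05: %d",
                sum(enr$direction == "enriched")))
message(sprintf("significantly depleted: %d (closed-population decline of null clones stays within counting noise)",
                sum(enr$direction == "depleted")))
truth <- read.delim("results/sim/truth.tsv")
sp <- truth$clone_id[truth$is_spiked]
message(sprintf("spiked clones among the enriched calls: %d of %d",
                sum(enr$clone_id[enr$direction == "enriched"] %in% sp),
                length(sp)))
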