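# clonesift

Analysis of intracellular antibody (intrabody) library selections read out by
amplicon sequencing.

## The problem

A combinatorial scFv/VH library is expressed inside cells and enriched over
successive FACS selection rounds for a cellular phenotype (here:
inhibition of FcεRI-triggered mast-cell degranulation). Because each cell can
carry several intrabodies, the sorted pools contain *passenger* clones
co-selected with the causal ones, and the phenotypic signal per round is weak.
Deep sequencing of the VH CDR3 region of every round turns the selection into
a statistical problem: which clonotypes rise over rounds more than sampling
noise allows, and which related sequences form antibody families?

`clonesift` implements that analysis end to end, for people running (or
simulating) multi-round selections:

1. **Simulation** (`sim_config()`, `simulate_experiment()`) — a naive library
   of distinct CDR3 DNA clonotypes with symmetric-Dirichlet abundances, a
   stated fraction of stop-codon/frameshift clones, per-clone multiplicative
   selection over rounds (`f_{g+1}(c) ∝ f_g(c)·w_c`), multinomial read
   sampling per round, and indexed 100-base single-end reads with per-base
   substitution errors. Ground truth (which clones are truly enriched, at
   what fold) is retained so every downstream stage is testable.
2. **Demultiplexing and counting** (`demux_count()`) — reads are sorted by
   their first 2 bases (round index, no mismatch allowed) and the next 18–20
   bases (VH-FR3 / VL-FR4 primer tail, one mismatch allowed); the CDR3 loop is
   extracted up to the downstream framework anchor (25-base prefix fallback)
   and counted into a clone × round table.
3. **Enrichment testing** (`enrichment_test()`) — a two-class unpaired
   resampling rank test: counts are Poisson-thinned to the minimum round
   depth, the centred Wilcoxon rank-sum statistic of late rounds
   (R5, R7, R8) against early rounds (naive, R3a, R3) is averaged over
   resamples, and the FDR is estimated from all 20 label permutations as
   median permutation exceedance / observed exceedance.
4. **Filter cascade** (`run_cascade()`) — in fixed order: present in both
   naive and R7; FDR < 0.05; no stop codon and in frame; frequency strictly
   increasing naive < R3 < R5 < R7; enrichment factor
   `E(c) = max(f_R7, f_R8)/f_naive` strictly above 100.
5. **Family clustering** (`build_families()`) — survivors are translated,
   DNA synonyms pooled, pairwise distances computed as the length-aware
   normalized Hamming distance (1 if loop lengths differ, else the fraction
   of mismatched positions), clustered by complete linkage at 60% identity,
   and families retained at ≥ 2 member loops and ≥ 0.1% pooled final-round
   frequency.
6. **Phenotype statistics** (`release_percent()`, `stimulation_index()`,
   `jarque_bera()`, `fit_two_normal_mixture()`) — the degranulation readout
   `100·S1/(S1+S2)`, the stimulated/unstimulated MFI ratio, Jarque–Bera and
   D'Agostino normality/skewness tests, and a two-component normal mixture
   fit (EM) of clone release distributions.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on a simulated
study (5,000 clones, rounds naive/R3a/R3/R5/R7/R8 at ~10⁶ reads each, 20
truly-selectable clones in 10 mutational clusters, total fold 100–500×):

```sh
Rscript analysis/01_simulate_selection.R 1
Rscript analysis/02_demux_count.R 1
Rscript analysis/03_enrichment_test.R 1
Rscript analysis/04_filter_cluster.R 1
Rscript analysis/05_phenotype_stats.R 1
```

Output of the run with seed 1 (abridged):

```
library: 5000 clones; 80% clean (no stop, in frame)
spikes: 20 in 10 clusters; realized naive->R8 fold 139-952
reads: 100000 total; 99807 assigned, 1 dropped, 192 unassigned
significantly enriched at FDR < 0.05: 20
significantly depleted: 0
  present_both   4657
  fdr_enriched   20
  no_stop        20
  monotonic      20
  fold100        20
cascade survivors: 20 (20 of 20 spikes; 0 nulls)
families: 10 total, 9 retained at the size/frequency rules
retained family enrichment: 219-499x
Jarque-Bera: JB = 7.050, p = 0.02945 (n = 126)
Skewness -0.564; D'Agostino z = -2.566, p = 0.01028
<mixture_fit ml> pi = 0.817, mu = (110.82, 63.79), sigma = (14.66, 8.90)
```

Reading this: all 20 seeded clones (and no null clone) survive the cascade;
the survivors cluster back into their seeded families; nothing is called
significantly depleted even though every null clone declines slightly as the
selected mass grows. The phenotype block shows a 126-clone release
distribution that rejects normality (JB p ≈ 0.03), is left-skewed
(p ≈ 0.01), and decomposes into a major mode near 110% of control and a
minor inhibitory mode near 65% holding ~20% of the clones.

`run_pipeline()` performs stages 1–5 in one call from an R list or YAML
config and returns a machine-readable report (per-stage clone counts,
retained families, and recovery metrics against the simulation ground
truth).

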