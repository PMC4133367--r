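---
title: "Methods: selection-round enrichment analysis of CDR3 clonotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection-round enrichment analysis of CDR3 clonotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonesift)
```

## The model

An intrabody selection experiment carries a combinatorial VH/scFv library
through successive FACS rounds. `clonesift` models the library as a set of
distinct CDR3 DNA clonotypes with naive frequencies $f_0(c)$ and treats each
selection round as one discrete generation of replicator dynamics,

$$ f_g(c) \;=\; \frac{f_0(c)\, w_c^{\,g}}{\sum_{c'} f_0(c')\, w_{c'}^{\,g}}, $$

where $w_c$ is a per-generation multiplicative selection coefficient
($w_c = 1$ for clones invisible to the sort). Sequencing of round $r$
(generation $g_r$) is a multinomial draw of $d_r$ reads from $f_{g_r}$. Two
library preparations of the same pool — for example a round-3 pool sequenced
before and after a recloning step — are modelled as two independent
multinomial samples of the same generation.

The analysis asks, per clonotype, whether its frequency trajectory over
rounds rises beyond what multinomial sampling noise allows, then filters and
clusters the significant clonotypes into antibody families.

## The synthetic-data generator

No public read set accompanies this kind of screen, so the generator is a
first-class, tested component. It emulates:

* **Abundance structure.** Naive frequencies are symmetric-Dirichlet with
  concentration `abundance_alpha` (default 0.5), giving the heavy-tailed
  rank-frequency curve of combinatorial libraries; at the default desk scale
  (5,000 clones) clone frequencies span roughly $10^{-8}$ to $10^{-2}$.
* **Library defects.** A configured fraction of clones carries an in-loop
  stop codon (default 10%) and another a frameshift, i.e. loop length not
  divisible by 3 (default 10%); the two classes are disjoint by
  construction and the 80% remainder is clean, translatable sequence.
* **True positives.** `n_spiked` clean clones get $w_c > 1$. Their total
  naive-to-final fold $F_c$ is drawn uniformly from `spike_fold_range`
  (default 100–500), and $w_c$ is *calibrated* so the configured fold equals
  the realized deterministic enrichment: with
  $Z = (1 - m_0)/(1 - \sum_{\text{spikes}} f_0 F)$ (the accumulated
  renormalisation constant), $w_c = (F_c Z)^{1/G}$. A naive
  $w_c = F_c^{1/G}$ would understate the realized fold whenever the spiked
  mass grows appreciably.
* **Spike placement.** Spikes are drawn from clones with naive frequency in
  `spike_freq_range` (default $5\times10^{-6}$–$2\times10^{-5}$). The band
  balances two constraints: the lowest spike still has ~4.5 expected naive
  reads at the default depths (presence and fold estimation need a nonzero,
  low-variance baseline), while the spiked final mass stays near 7% of the
  library so that the frequency decline it imposes on every null clone
  (selection is a closed population) remains below per-clone counting noise.
  Rare clones rising from low frequency while the bulk drifts down slowly is
  the regime such screens operate in.
* **Spike families.** With `spike_n_clusters`, spikes are organised into
  mutational clusters: members share a loop length and differ from a common
  base at $\lfloor 0.15\,L \rfloor$ amino-acid positions, so every within-
  cluster pair is at distance $\le 0.3$ (inside the 0.40 clustering cut)
  while distinct clusters are unrelated loops (distance > 0.5, enforced by
  rejection).
* **Reads.** Each VH-end read is
  `[2-base round index][20-base FR3 primer tail][CDR3][FR4 anchor + framework filler]`,
  truncated to 100 bases, with iid per-base substitutions at `error_rate`
  (default $10^{-3}$) and constant Q30 qualities. The generator
  rejection-samples loops in which the FR4 anchor motif would appear before
  the true loop end, so error-free demultiplex + count reproduces the
  simulated count table bit-exactly — the round-trip the test suite asserts.
* **Depths.** Per-round depths default to a fixed pattern of unequal values
  (0.85–1.15 × nominal in the six-round design), emulating lane-yield
  variation. This is not cosmetic: the enrichment test normalises depth by
  resampling, and with exactly equal depths that step is skipped (see below).

What the generator does **not** emulate: PCR amplification bias and chimera
formation, indel sequencing errors, paired reads, within-round selection
kinetics, and cell-level co-occurrence of several intrabodies (passengers
are simply additional enriched clones). Passing tests therefore demonstrate
the statistical machinery under multinomial sampling with substitution
noise, not robustness to amplification artefacts.

## The enrichment test

For each clonotype the test compares late rounds (default R5, R7, R8)
against early rounds (default naive, R3a, R3):

1. **Depth normalisation by thinning.** Each sample's count is replaced by a
   Poisson draw with mean `count × d_min/d`, putting all samples at the
   minimum depth in expectation. Poisson (rather than binomial) thinning is
   deliberate: binomial thinning leaves the minimum-depth column with zero
   resampling noise, so a null clone whose accidental sample ordering hinges
   on that column never flips across resamples; a handful of such clones per
   permutation puts a hard floor under the estimated FDR at the statistic's
   saturation point and masks genuine positives. Poisson draws keep every
   column noisy. When all depths are equal the thinning step is skipped and
   the statistic is deterministic.
2. **Statistic.** The Wilcoxon rank-sum of the late group (midranks for
   ties), centred so 0 means no difference, averaged over `n_resamples`
   (default 20) thinning draws. For a 3v3 design the statistic saturates at
   ±4.5 (all late counts above all early counts in every resample).
3. **Permutation FDR.** The null comes from all distinct label permutations
   of the six samples ($\binom{6}{3} = 20$, identity included). For a cutoff
   $t$, $\widehat{FDR}(t) = \mathrm{med}_b\,\#\{c: s_c^{(b)} \ge t\} \,/\,
   \#\{c: s_c \ge t\}$, clipped to $[0,1]$; a clone's q-value is the
   smallest $\widehat{FDR}$ over the cutoffs that call it, and both tails
   are treated symmetrically.
4. **Cutoff lattice.** Candidate cutoffs are the half-integer lattice of the
   single-resample rank statistic, not every distinct averaged value. The
   averaged statistic leaves the lattice only through thinning noise;
   evaluating the FDR at every observed value would let the single most
   extreme null clone sit alone above a cutoff where the median permutation
   count is zero, yielding spurious q = 0 calls in fully-null data. With the
   lattice, fully-null experiments produce no call in the large majority of
   seeds; the residual per-experiment false-call probability is the
   irreducible $1/20$ chance that the most extreme clone's ordering aligns
   with the observed labelling.
5. **Directions.** `enriched` requires q below the threshold (default 0.05)
   and a positive statistic; `depleted` is the mirrored case. With only
   positive selection simulated, depletion calls stay at zero under the
   default conditions because each null clone's renormalisation decline is
   within its counting noise.

Clones absent from every early sample still receive a statistic (computed on
zeros); their enrichment factor is undefined (no pseudocount) and they cannot
pass the presence filter anyway.

## Filter cascade

Stages run in a fixed order, each on the survivors of the previous one:
present in both naive and R7 (count > 0); called enriched at FDR < 0.05; no
stop codon and in frame (frameshifted loops have no translation and cannot
be clustered); frequency strictly increasing naive < R3 < R5 < R7 (ties
fail; R3 is the post-recloning pool — the pre-recloning replicate R3a enters
only the test's early group); enrichment factor strictly above 100. All
comparisons are on frequencies, since depths differ by round; the strict
fold comparison is evaluated on integer cross-products
(`count_final · depth_naive > threshold · count_naive · depth_final`) so a
clone at exactly the threshold is rejected without floating-point ambiguity.
Survivor sets are nested by construction and the trace records per-stage
counts.

## Family clustering

Survivors are translated and DNA synonyms pooled by amino-acid loop. The
distance between two loops is 1 when their lengths differ and otherwise the
fraction of mismatched positions (position-wise comparison of equal-length
loops is exactly what a gapped antibody numbering scheme reduces to in this
case, so no alignment is needed). Complete-linkage agglomeration proceeds
while the smallest cluster distance is ≤ 0.40 (= 1 − 60% identity), which
guarantees every within-family pair is at least 60% identical — asserted
post hoc on every retained family. Ties are broken deterministically by
merging the pair whose sorted cluster labels (label = lexicographically
smallest member) are smallest; the brute-force oracle in the test suite
implements the same rule independently, and `stats::hclust` serves as an
additional cross-check on tie-free inputs. Families are summarised by pooled
final-round frequency and family enrichment
(pooled $\max(f_{R7}, f_{R8})$ / pooled $f_{naive}$) and retained at
≥ 2 member loops and ≥ 0.1% pooled final frequency.

## Phenotype statistics

* `release_percent()`: $100\,S_1/(S_1+S_2)$, optionally rescaled to a
  control clone's release; scale-invariant in $(S_1, S_2)$.
* `stimulation_index()`: ratio of geometric-mean fluorescence of stimulated
  to unstimulated cells; 1.0 means the response is abolished.
* `jarque_bera()`: $JB = \tfrac{n}{6}(S^2 + K^2/4)$ against $\chi^2_2$, plus
  D'Agostino's skewness z-test (the standard normalising transform of sample
  skewness). Both match an independent reference implementation to ten
  decimals on a frozen sample. Note that for a bimodal 80/20 mixture of
  normals at $n = 126$ the JB test's power is ~0.65 (estimated by a
  4,000-replicate reference simulation) — a single dataset can reject
  normality convincingly while a substantial minority of replicates would
  not.
* `fit_two_normal_mixture()`: maximum-likelihood EM on the raw values with a
  k-means start plus 5 random restarts, tolerance $10^{-8}$ on the
  log-likelihood, at most 500 iterations; the per-iteration log-likelihood
  trace is returned and is non-decreasing (asserted in tests). Components
  are reported high-mode-first. A restart whose component standard deviation
  collapses below $10^{-6}\,\mathrm{sd}(x)$ is discarded; if all restarts
  degenerate the fit is flagged failed. Fitting the raw values is
  statistically cleaner than fitting a histogram and testable by parameter
  recovery; a histogram least-squares mode is provided for comparability
  with curve-to-distribution fits.

## Numerical and design choices

* 0-based half-open coordinates internally; sequences handled uppercase.
* `N` bases never match anywhere; primer matching is Hamming (no indels) at
  each primer's own length (20 nt for the VH-FR3 tail, 18 nt for the VL-FR4
  tail).
* VL-end reads are sequenced from the reverse strand; their keys are
  extracted in read space and reverse-complemented to coding sense. The
  default analysis uses VH only.
* The clonotype key is the full anchored loop by default (translation and
  clustering need full loops); a 25-base-prefix mode reproduces plain
  prefix counting.
* Deterministic seeds everywhere: a `sim_config` seed fixes the library, the
  dynamics, and the reads (byte-identical FASTQ); the test seed fixes the
  thinning draws; identical configs reproduce identical pipeline reports.
* Problem sizes: the reference in-silico study uses 5,000 clones at ~10⁶
  reads/round; unit tests run scaled-down variants (hundreds to thousands of
  clones, 10⁴–10⁵ reads) chosen so every assertion retains comfortable
  statistical margins.

## Known limitations

* The 3v3 rank statistic is coarse; with very few true positives the
  permutation FDR cannot resolve q-values much below ~1/20 per cutoff, and
  single-clone discoveries at extreme cutoffs carry the irreducible 1/20
  alignment probability discussed above.
* The plug-in FDR is a population-level estimate, not a per-clone
  probability; with tiny call sets it is unstable by nature.
* Selection coefficients are constant per generation; frequency-dependent or
  epistatic selection, and cell-level linkage between co-expressed clones,
  are out of scope.
* The error model is substitution-only; indels would shift the anchor and
  are dropped rather than recovered.
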