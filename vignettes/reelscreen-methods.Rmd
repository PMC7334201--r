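---
title: "Identifying functional SNPs from cyclic gel-shift screens with reelscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying functional SNPs from cyclic gel-shift screens with reelscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reelscreen)
```

## The screen and its model

A cyclic gel-shift (EMSA-based) screen asks, for thousands of disease-associated
SNPs at once, whether nuclear proteins bind the two alleles of a SNP with
different affinity. Each SNP is synthesized as a 31-bp variable region — the
variant at position 16, 15-nt flanks either side — between two constant primers
(75 bp total with the default 22-nt primers). The pooled library is incubated
with nuclear extract (NE, the *sample* condition) or buffer (*control*), run on
a native gel, and the **unshifted** band is recovered and PCR-regenerated for
the next cycle. Protein-bound molecules shift out of that band, so an allele
that binds protein more strongly is progressively depleted relative to its
partner. Ten cycles are run with five independent control and five independent
sample libraries; all 40 libraries from cycles 1, 4, 7 and 10 are barcoded and
sequenced.

`reelscreen` implements the computational arm of such a screen:

* **library model** — validated SNP records, construct assembly, TSV/FASTA I/O;
* **simulator** — a forward model of the selection with known ground truth;
* **read counting** — exact-match demultiplexing and amplicon counting plus
  the completeness quality-control filter;
* **screen statistics** — allele ratios, the cycle-10 Student's *t* test, the
  normalized-ratio trajectory, its slope, and the three-way call;
* **SDCP filter** — spectral-count triage of DNA-pulldown proteomics tables.

### The selection model

Let each sequence $i$ of a library have shift probability $p_i$ per cycle
(probability that a molecule leaves the unshifted band). One cycle maps relative
frequencies $f_i$ to

$$f_i' = \frac{f_i\,(1-p_i)}{\sum_j f_j\,(1-p_j)},$$

renormalization standing in for PCR regeneration: only relative frequencies are
observable at fixed sequencing depth, so explicit molecule duplication would add
nothing. For a SNP whose risk and non-risk alleles shift with $p_r$ and $p_n$ in
the sample condition, and with allele-independent losses in the buffer control,
the sample/control normalized allele ratio after $c$ cycles is exactly

$$R(c) = \left(\frac{1-p_r}{1-p_n}\right)^{c},$$

which `expected_normalized_ratio()` exposes and the deterministic simulator
reproduces to floating-point accuracy — the package's internal oracle.

### The statistics

Following the screen's design, for every SNP (risk allele against each non-risk
allele; multi-allelic SNPs get one result per pair and their strongest call):

1. **allele ratio** per replicate: risk count / non-risk count (raw, no
   pseudocounts — QC guarantees finiteness);
2. **cycle-10 *t* test**: two-tailed pooled-variance Student's *t* comparing the
   five control with the five sample ratios (df = 8), uncorrected for multiple
   testing; Welch's variant and a BH-adjusted column are opt-in flags;
3. **trajectory**: per sequenced cycle, mean of the five sample ratios divided
   by the mean of the five control ratios (means of ratios, then one division —
   the closest reading of the screen's normalization);
4. **slope**: ordinary least-squares slope of the trajectory against the cycle
   number (x = 1, 4, 7, 10). Regressing on cycle rather than snapshot rank is a
   deliberate choice: cycles are the physical selection count, and the ±0.05
   cutoff is then "per cycle"; `slope_x = "rank"` preserves the alternative,
   whose slopes are exactly 3× larger;
5. **classification**: *candidate* if $p < 0.05$ and $|\text{slope}| > 0.05$,
   *putative* if $p < 0.05$ but $|\text{slope}| \le 0.05$, otherwise
   *non-fSNP*. Inequalities are strict, so boundary values fall in the weaker
   class. Both cutoffs are arguments.

Replicate quality is summarized as the squared Pearson correlation of per-SNP
sample/control ratio-of-ratios between consecutive replicate pairs at the test
cycle (`replicate_correlation()`).

Degenerate *t*-test inputs are handled explicitly: two constant equal groups
give $p = 1$; constant unequal groups give $p = 0$, an underflow sentinel for an
infinite *t*. This matters for the deterministic simulator, whose replicates are
identical by construction.

## Counting reads

Counting is strictly exact-match, mirroring a perfect-match analysis: a read is
assigned to a library iff one barcode matches its 5′ end exactly (the map must
be prefix-free, so at most one can), and contributes a count iff the 31-mer
bracketed by exact hits of both constant primers equals a library variable
region exactly. Everything else is tallied as `bad_barcode`,
`primer_mismatch` or `region_mismatch`, so assigned + discarded = total per
library. Reads are retried on their reverse complement by default
(`orient = "forward"` disables this), since sequencing orientation is a
platform detail. There is no quality trimming, fuzzy matching or error
correction — by design, failures surface in the discard tallies instead.

**Completeness QC**: a SNP is analyzed only if every one of its alleles has at
least `min_count` (default 1) reads in *all* 40 libraries. This is the
strictest operationalization of requiring "complete sequencing data" across
cycles, and it is what guarantees every downstream ratio is finite with raw
counts. The threshold is exposed because a screen might plausibly demand more
than one read; 1 is the default because nothing stricter is implied by the
rule itself.

## What the simulator emulates — and what it does not

`simulate_screen()` draws a fraction of SNPs as functional (one allele,
risk or non-risk with equal probability, gets `baseline_p + delta_p`), evolves
each of the ten replicate libraries as an **independent lineage** from the
uniform initial pool (matching a real run, where each replicate has its own
selection history), optionally jitters each cycle with lognormal per-sequence
PCR noise, and sequences multinomially at fixed depth after the selection step
of each sequenced cycle. A single seed fixes truth assignment, lineage noise
and sequencing draws, in that order; reruns are byte-identical.
`emit_fastq()` turns a count matrix into barcode + construct reads (uniform
quality), optionally corrupted by an i.i.d. per-base substitution process, and
`count_reads()` on error-free output reproduces the count matrix exactly — a
round trip the test suite asserts at one million reads.

Defaults state the screen conditions: 5 + 5 replicates, 10 cycles, snapshots at
1, 4, 7, 10. Depth (5 × 10⁴ reads/library) and the effect distribution (10%
functional, Δp = 0.3 over a 0.1 nonspecific baseline, buffer loss 0) are
declared defaults, not inferred quantities: a real screen publishes neither its
per-library depth nor its effect-size distribution. The simulator does not
model gel physics, protein titration, synthesis errors, PCR chimeras, or
sequence-composition biases; passing its tests shows the *statistics* behave as
designed under the stated noise model, not that any particular wet screen will.

Two emergent behaviours of the model are worth knowing:

* **Null calibration.** On all-null simulations the full pipeline's type-I
  rate at $\alpha = 0.05$ is near-nominal but mildly conservative (≈ 0.037–0.049
  across seeds at 2000 SNPs, depth 5 × 10⁴): ratios of modest counts are
  skewed, and the *t* test on five-vs-five skewed replicates slightly
  under-rejects. The acceptance suite checks the rate against the exact
  binomial 99% interval around 0.05.
* **QC–effect interaction.** Strong fSNPs deplete one allele geometrically; at
  Δp = 0.3 over baseline 0.1 the preferred allele is down ~57-fold by cycle 10,
  so at 5 × 10⁴ reads over 1000 sequences its expected cycle-10 count is below
  one read and the completeness filter removes most true fSNPs before they can
  be classified. This is a faithful consequence of pairing a strict
  completeness rule with raw-ratio statistics, and it is why
  `score_recovery()` reports sensitivity both among classifiable (QC-passing)
  fSNPs — effectively 100% under these conditions — and overall, with
  QC-dropped fSNPs counted as misses. Real screens sit in a gentler regime
  (smaller effects, higher depth); users simulating strong effects should
  raise `depth` accordingly.

## Filtering pulldown proteomics tables

`call_bindings()` implements the spectral-count triage for SNP-specific DNA
competition pulldowns run with several baits in parallel, two replicate
pulldowns per bait, each bait serving as the others' control. The filter order
is fixed and mirrors the procedure it models: first remove proteins present
(count ≥ `min_count`, default 1) in **every** replicate column of every bait
(ubiquitous, nonspecific binders); then remove proteins with no bait supported
by **both** replicates (irreproducible); retain the rest with their
reproducibly bound baits and a specificity class (`one_bait`, `two_baits`,
`multi_bait` — classes rather than a hard-coded bait count, so the module
generalizes beyond three baits). The calls are invariant under row and bait
permutations, and zeroing any count can only remove, never add, a bound bait.

The packaged example (`sdcp_example()`) is the 19-protein table recovered on
three fSNP baits of the *FGFR2* breast-cancer risk locus (rs7895676, rs2981578,
rs2981584). Counts are as published for that screen. Two caveats are recorded
rather than resolved: the typeset source does not disambiguate which two baits
some two-bait proteins belong to, so the packaged assignment follows the
per-bait protein lists published alongside the table where given (TEAD1 on
rs2981578; NFIB on rs2981584) and otherwise fills columns left to right; and
TCERG1, present in the table but absent from those lists, falls out as
`two_baits` under the rule, which is why the packaged summary counts 11
two-bait proteins where the accompanying lists name ten.

## Numerical and interface choices

* Ratios are raw throughout (the screen's statistics are on ratios);
  `log_ratios = TRUE` is available but off.
* Risk allele in the numerator, fixed: the slope's sign encodes which allele
  sheds protein-bound material faster (negative ⇔ risk allele preferentially
  bound).
* Coordinates: 1-based in all reporting (the SNP is position 16 of 31);
  internal string arithmetic is R's 1-based `substr`.
* The vectorized screen slope uses the OLS closed form
  $\hat\beta = \sum_k (x_k - \bar x) y_k / \sum_k (x_k-\bar x)^2$ and is tested
  against `lm()`; the scalar `fit_slope()` simply calls `lm()`.
* Per-base read errors are generated exactly (Binomial total over uniformly
  chosen distinct positions ≡ i.i.d. Bernoulli per base) and validated against
  the $(1-e)^L$ perfect-match retention law.
* Problem sizes in the shipped tests — 2000-SNP null calibration, 500-SNP
  recovery, $10^6$-read round trip — were chosen to make distributional checks
  tight while keeping the default suite in tens of seconds.

## Known limitations

* Exact matching discards all reads with any error in barcode, primers or
  variable region; at realistic error rates most reads survive, but highly
  degraded runs will mostly land in the discard tallies.
* The *t* test is applied to ratios whose distribution at low per-sequence
  depth is skewed; with five replicates this is mildly conservative (above).
* Completeness QC with `min_count = 1` interacts with strong depletion as
  described; the package reports dropped SNPs with the first failing
  (allele, library) so such losses are visible, not silent.
* The SDCP filter is presence/absence triage of spectral counts; it is not
  label-free quantification and performs no FDR control over identifications.
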