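---
title: "Modeling replication-coupled DNA demethylation in meiotic prophase"
author: "meiometh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling replication-coupled DNA demethylation in meiotic prophase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meiometh)
```

## The phenomenon and the model

Male meiosis begins with a final round of DNA replication (meiotic S phase,
the preleptotene stage, PL) followed by the prophase substages leptotene
(L), zygotene (Z), pachytene (P) and diplotene (D). Spermatogonia (Spg)
enter this program with a highly methylated genome (median CpG methylation
above 80%). If maintenance methylation — the DNMT1/UHRF1-mediated copying
of methylation from the template strand onto the newly synthesized strand
at hemimethylated CpG dyads — is delayed or inefficient during meiotic S
phase, every replicated duplex dilutes its methylation passively: each CpG
dyad that was methylated on both strands (`MM`) becomes, in each daughter
duplex, methylated on the template strand only (`MU`/`UM`,
hemimethylated), unless maintenance restores it. This produces a
genome-wide, transient reduction of DNA methylation (TRDM) whose
signatures this package simulates and measures.

The central arithmetic is the dilution closed form. For starting
strand-level methylation $s_0$, replicated genome fraction $r$ and
maintenance efficiency $m$,

$$ s = s_0 \left[(1 - r) + r\,\frac{1 + m}{2}\right], $$

because replicated DNA keeps every template strand and regains a fraction
$m$ on new strands. With $r = 1$ and $m = 0$ this gives $s_0 / 2$ — the
theoretical maximum reduction of purely passive demethylation is 50% of
the starting level. `expected_strand_methylation()` implements this form
and serves as the closed-form oracle for the stochastic simulator.

"Strand-level methylation" here is the per-CpG-site average of the
fraction of methylated strand copies, with equal weight per site. During
S phase, already-replicated regions hold twice the DNA; a pooled
strand-count average would overweight them, whereas per-site averaging is
what a coverage-normalized WGBS measurement estimates.

## The duplex simulator

`make_genome()` builds a population of cells, each carrying one duplex
per chromosome over a fixed list of CpG dyad coordinates (homologs are
not modeled: passive dilution is a per-duplex phenomenon, so a second
identical duplex adds nothing testable). Dyads start `MM` with
probability $s_0$ and `UU` otherwise; $s_0$ can be overridden per
annotation class (CpG islands default to 0.05, synthetic maternal
imprinted DMRs to 0.02, so classes with nothing to dilute stay flat
through S phase — the expected control behavior). A configurable fraction
of LINE-1-like elements instead starts *strand-coherently
hemimethylated* (top strand methylated at every dyad, bottom strand not),
representing the incompletely methylated L1 subpopulation of
spermatogonia.

`replicate_population()` assigns each cell a fraction of S phase
completed and replicates replication-timing (RT) domains in strictly
decreasing `rt_value` order (higher values replicate earlier; ties break
by genomic coordinate) until at least that fraction of CpGs is
replicated. Replication is semiconservative: each replicated duplex is
replaced by two daughters that keep their template strands, and each
new-strand CpG is methylated with probability $m$ only when its template
partner is methylated. The default S-progress distribution for PL is an
equal mixture of 0.25, 0.5 and 0.9, reflecting EdU-labeling evidence that
replicating preleptotene cells are mostly in middle and late S phase; it
is configurable.

Two direct consequences anchor the test suite:

* a coherently hemimethylated element yields, deterministically, one
  hemimethylated and one *fully unmethylated* daughter per duplex, so a
  4% hemimethylated input produces 2% fully unmethylated molecules after
  one unmaintained replication;
* in mid-S cells, unreplicated (late) domains hold half the DNA of
  replicated (early) domains, so fragment coverage in 5-kb windows shows
  a ~0.5× ratio that vanishes after S phase.

### Stage series and remethylation

`simulate_stage_series()` produces the Spg→PL→L→Z→P trajectory. Post-S
stages apply cumulative recovery: hemimethylated dyads convert to `MM`
with per-stage probabilities (defaults `L = 0.5`, `Z = 0.75`, `P = 0.97`,
`D = 0.98`, `Spz = 0.99`). These rates are generator defaults chosen once
to give a PL drop of roughly 15 percentage points from an 0.86 start
(the observed scale of the dip) and monotone recovery to premeiotic
levels by pachytene; the assertions on the simulated series are ordering
and shape properties, not specific medians. Recovery is graded by
replication timing (`rt_coupling`): regions replicated earlier have had
more time to remethylate. This grading is what reverses the
methylation-versus-timing correlation after S phase. The default
maintenance efficiency during meiotic S phase is `m = 0.3`, encoding
partially effective maintenance (consistent with reduced UHRF1 and
diffuse DNMT1 localization in PL) rather than total failure.

The negative control (`replication_coupling = FALSE`) imposes the same
per-stage mean methylation by thinning methylated strand-CpGs uniformly,
with no relationship to replication timing; it is the substrate for
showing that the correlation sign switch requires replication coupling.

### What the generator does and does not emulate

The toy genome has regularly spaced CpGs, rectangular RT domains with
Gaussian `rt_value` jitter, and annotation classes placed at regular
offsets. Defaults: 4 chromosomes × 4,000 CpGs at 200-bp spacing (16,000
dyads, 0.8-Mb chromosomes), RT domains of 1,000 CpGs (200 kb) so that
domains are larger than the 100-kb analysis windows, as in real genomes;
60 cells per stage; WGBS depth 8 per CpG strand. These sizes keep the
full simulated series under a minute while leaving enough late-domain
windows (16 at 100 kb) for stable correlations. Real methylomes add CpG
density heterogeneity, irregular domain structure, copy-number and
mappability artifacts, PCR duplicates and batch effects, none of which
are modeled; passing tests demonstrate internal consistency of the
method under the passive-dilution model, not performance on real data.

## WGBS-style summarization

`sample_wgbs()` emulates the observable: per CpG and strand a Poisson
number of reads samples strand copies across molecules, with two error
rates — failed bisulfite conversion (unmethylated C appears methylated,
default 0.005) and inappropriate conversion (methylated C appears
unmethylated, default 0.005). Summaries follow standard methylome
practice: strand merging into dyad records (plus-strand record at $p$
plus minus-strand record at $p+1$), restriction to CpGs covered in all
samples, non-overlapping 500-CpG bins (stage medians), 100-kb windows
(chromosome traces), per-feature aggregation in 100-CpG chunks, and 5-kb
read-count windows corrected to the largest sample's total. Internal
coordinates are 0-based half-open; the Bismark coverage dialect (1-based
inclusive) is converted at the file boundary. Non-CpG contexts are out
of scope (negligible in this system and excluded from all summaries).
Trailing partial bins and chunks are dropped and counted rather than
emitted short, so bin statistics are never mixtures of unequal sample
sizes.

## Differentially methylated blocks

TRDM manifests as very large blocks of methylation difference (tens of
kb, hundreds of CpGs). `call_blocks()` detects them in three steps:

1. coverage-weighted kernel smoothing of per-CpG fractions
   (`smooth_methylation()`, uniform kernel over ±2 CpGs by default;
   weights are kernel × coverage, an intentionally light-weight
   replacement for local-likelihood smoothing — at block scale the
   estimand is a long plateau and the smoother's exact form matters
   little);
2. candidate runs where the smoothed difference exceeds `diff_cutoff`
   (default 0.1) with consistent sign, bridging up to `max_gap` (2)
   sub-threshold CpGs;
3. boundary refinement on the *raw* differences: candidate edges are
   first trimmed of smoothing spill-over, then extended while the raw
   signed difference stays beyond the cutoff. Kernel smoothing
   attenuates step edges by about one bandwidth; refining on raw values
   restores block bounds to CpG resolution, which the planted-block
   recovery tests check to ±2 CpGs.

Blocks need `min_cpgs` (10) CpGs; `mean_diff` is always computed on raw
fractions. Replicates are pooled by count addition before smoothing
(`pool_replicates()`; averaging fractions instead is deliberately not the
default because it overweights low-coverage replicates). Comparisons
refuse mismatched CpG universes rather than aligning silently.
Block significance is not calibrated genome-wide; block calls are
descriptive, and the cross-stage accounting (`cpg_proportions()`,
`intersect_fraction()`, `fisher_overlap()`) operates on the called sets.

## Replication-timing correlation

`stage_correlation_series()` joins 100-kb methylation windows with RT
intervals (half-open overlap, as a `bedtools intersect -wa -wb` would)
restricted to late-replicating domains — defined, since published RT
tracks come without a threshold, as `rt_value` below the track median
(configurable). Within late domains, mid-S populations leave the very
latest domains unreplicated and therefore relatively hypermethylated
(negative Pearson r against `rt_value`), while after S phase the latest
domains are the least remethylated (positive r). The `sign_switch` flag
requires opposite signs *and* both $|r| \ge 0.3$: at the toy genome's
scale (tens of windows) two near-zero correlations cross zero by chance
about half the time, so a magnitude floor is needed for the flag to mean
a prominent directionality switch rather than noise. The correlation is
invariant to affine rescaling of `rt_value`, and switch detection is
stable for window widths between 50 and 200 kb on simulated data.

## Hairpin-bisulfite simulation and calling

Hairpin-bisulfite sequencing reads both strands of the *same* molecule:
the duplex is cut (BspEI, `TCCGGA`) and the strands joined by a hairpin
linker (`CCGGGGGCCTATATAGTATAGGCCC`, cytosines unmethylated), so after
bisulfite conversion and PCR a read pair reports a dyad's two strands
independently. The target is the 179-nt L1MdTf 5′ promoter consensus;
its 7 CpG positions are always derived by scanning the sequence. The
simulated fold is `top arm + linker + reverse complement of the arm`;
read 1 and read 2 come from the two ends of the PCR product with random
strand orientation, so pairs land in the {OT, CTOB} or {CTOT, OB}
bisulfite strand classes.

The caller aligns each read ungapped against the four
bisulfite-converted consensus strands in collapsed alphabets (consensus
C positions accept C/T on the top-reporting classes, G positions accept
G/A on the bottom-reporting ones), scanning all offsets with up to
`max_mismatch = 3` mismatches and at least 20 nt overlap — deliberately
brute-force so an independent re-implementation can verify every
alignment, with the inner loop in C++ for throughput. Ties for best
placement discard the read as ambiguous (an unconverted molecule, for
instance, matches OT and CTOB equally). Pairs whose reads report the
same strand are dropped and counted. Stitching yields one row of dyad
codes (`MM`/`MU`/`UM`/`UU`/`·`) per pair; a dyad counts only when both
strands are called.

`summarize_dyads()` reports, per dyad, the hemimethylation proportion,
methylation *including* hemimethylation ($\tfrac{2\,n_{MM} +
n_{hemi}}{2\,(n_{MM} + n_{hemi} + n_{UU})}$, a strand-level quantity)
and *excluding* hemimethylation ($\tfrac{n_{MM}}{n_{MM} + n_{UU}}$).
These definitions were an open design choice; they are the pair under
which passive dilution shows its diagnostic signature: one unmaintained
replication drives hemimethylation toward 1 and halves the inclusive
statistic, while the exclusive statistic tracks the premeiotic level
whenever maintenance is partial ($m > 0$) or replication incomplete —
excluding hemimethylated molecules "erases" the dip. In the degenerate
corner $m = 0$ with complete replication, no `MM` dyad survives at all
and the exclusive ratio is undefined; the summary flags such dyads
rather than reporting a misleading 0. A read is *fully unmethylated*
when all assayed dyads are `UU` on both strands; which dyads are assayed
is configurable (all interior dyads by default, since the subset scored
in targeted designs is primer-dependent). Trimming (`trim_reads()`) is a
plain 3′ clip with a minimum-length filter, not a byte-for-byte
re-creation of any particular trimmer.

## Numerical and degenerate-input choices

* All randomness flows from explicit integer seeds; derived seeds are
  small offsets of the master seed, and simulation outputs record their
  seed.
* Threshold comparisons in block calling use a $10^{-9}$ tolerance so
  count-quantized fractions (e.g. a planted difference of exactly 0.1 at
  integer coverage) are not lost to floating-point representation.
* Dyads with zero informative reads, correlation sets with fewer than 3
  pairs or zero variance, and empty block sets propagate as flagged
  `NA`s, never as silent zeros.
* `restrict_common()` with a sample sharing no covered CpGs warns and
  returns an empty universe; duplicate strand records and mismatched CpG
  universes are hard errors (they indicate corrupted input, not data to
  be reconciled).

## Problem sizes used by the checks

The shipped verification uses 200 cells × 5,000 dyads for the dilution
closed form (27-point $(s_0, r, m)$ grid, three Monte-Carlo standard
errors), 10,000 L1 molecules and 50,000 error-free read pairs for the
fully-unmethylated-read fraction, a 50,000-CpG universe with six planted
blocks (10–300 CpGs, differences 0.1–0.4) for block recovery, and the
default 16,000-dyad stage series for the shape properties. These sizes
were chosen as the smallest at which the Monte-Carlo tolerances above
are decisive.

## Known limitations

* One duplex per chromosome; no homolog pairing, recombination, or
  sister-chromatid exchange.
* No active (TET/5hmC) demethylation pathway; the late-prophase
  hypomethylation the real system shows at P→D is outside the model.
* Uniform PCR amplification in the hairpin simulator: no duplicate or
  amplification-bias modeling, and no multi-locus mapping of L1 copies
  (one consensus stands for the family).
* The WGBS sampler draws reads per CpG independently rather than
  simulating fragments through alignment, so read-level correlation
  between neighboring CpGs is not represented.
* Block calling is descriptive (no genome-wide significance
  calibration), matching its role of delineating large regions whose
  properties are then measured directly.
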