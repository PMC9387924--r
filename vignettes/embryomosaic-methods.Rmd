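---
title: "Models and methods behind embryomosaic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind embryomosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(embryomosaic)
```

## The problem

A preimplantation embryo is chromosomally mosaic when it contains two or more
cell lines with different karyotypes. Clinical aneuploidy screening (PGT-A)
profiles a 5-10 cell trophectoderm (TE) biopsy as bulk DNA, so it reports an
average over cells; single-cell sequencing instead resolves the karyotype of
each cell, at the price of low coverage (roughly 0.3x) and strong
whole-genome-amplification noise. embryomosaic implements the complete
analysis path from binned single-cell read counts to embryo-level mosaicism
statistics, together with a ground-truthed simulator, so every stage can be
validated without access to patient data.

The pipeline stages and their contracts:

1. **bin counts** on a fixed 1 Mb grid (`read_counts()`, or
   `count_reads_from_alignments()` for SAM/BAM);
2. **bias correction** (`correct_counts()`): remove GC and mappability bias,
   anchor each cell at median 1;
3. **QC** (`variability_score()`, `filter_cells()`): exclude the most
   variable cells of the batch;
4. **copy-number decoding** (`infer_copy_number()`, `segment_states()`,
   `call_karyotypes()`): integer states by a hidden Markov model, reported
   as CNV calls of at least 10 Mb;
5. **embryo analytics** (`classify_embryos()`, `classify_origin()`,
   `te_icm_discordance()`, `find_complementary_pairs()`,
   `simulate_multicell_biopsy()`, ...).

## Bias correction

Counts in 1 Mb bins at 0.3x coverage average about 1000 reads and carry a
smooth dependence on local GC content plus mappability losses. For each cell
a robust loess curve of count versus GC is fitted on unmasked autosomal bins
(span 0.3, symmetric family; a binned-median curve when too few bins are
available, and a constant median when GC carries no information); counts are
divided by the fitted curve and by mappability, and scaled so the median
over unmasked autosomal bins is 1. The contract is the *property* that
corrected values are independent of GC (the tests require |r| < 0.05 on
simulated data with a strong planted bias), not bit-compatibility with any
particular external tool. Bins with mappability below 0.8 or missing GC are
masked throughout. Cells with fewer than 20 informative bins (e.g. failed
amplification) are flagged unanalyzable instead of raising an error, so
batch runs proceed.

The median anchor assumes most of the genome sits at baseline ploidy. Cells
violating this -- near-triploid genomes, for instance -- cannot be resolved by
any median-normalized method; `call_karyotypes()` flags cells whose calls
cover more than 60% of the analyzable genome as possible ploidy shifts
rather than reporting them as trustworthy karyotypes.

## Copy-number model

Decoding uses a 6-state HMM (copy 0-5) per chromosome. On the corrected
scale a copy-$s$ bin has mean $s/2$ (state 0 uses a floor of 0.05 for
residual background). Emissions are Gaussian with a per-cell SD estimated
robustly as $\mathrm{MAD}(\Delta x)/\sqrt{2}$ from first differences of the
profile (floored at 0.05), mixed with a small flat outlier component
(weight 0.01, density 0.1) so isolated amplification-dropout bins do not
flip the path. Transitions keep the current state with probability
$1-10^{-5}$ and switch uniformly otherwise; with typical noise
($\sigma \approx 0.15$) this makes events shorter than about 5 bins
unlikely to be decoded, consistent with reporting only CNVs of at least
10 Mb on a 1 Mb grid. Viterbi decoding is deterministic given inputs, and
the test suite verifies it against exhaustive enumeration of all state
paths on chromosomes of up to 8 bins.

Segments are maximal constant-state runs over unmasked bins; a masked gap
does not break a run, which implements the rule that same-delta calls
separated only by masked bins merge before the size filter. Non-baseline
segments of at least `min_cnv_size` (default 10 Mb) become CNV calls,
classed `whole` when they cover at least `whole_fraction` (default 0.9) of
the chromosome's analyzable length -- the 0.9 boundary maps calls onto the
whole/segmental dichotomy, which has no universal definition -- and
`segmental` otherwise. Baselines come from the declared sex (XX: two copies
of every autosome and X; XY: one X and one Y).

## Variability score

The QC statistic mirrors the standard windowed-SD recipe: for each
chromosome, the corrected counts are covered by exactly 30 equal-length
windows with evenly spaced starts (overlapping when the chromosome has
fewer than 30 x window-length bins, disjoint when possible; chromosomes
with fewer than 30 usable bins fall back to one-bin windows and are
flagged); the sample SD (n-1 denominator) is computed per window and the
30 SDs averaged; the cell's VS is the mean of its five largest
per-chromosome averages. Because the published recipe does not fix window
length or step, this interpretation is frozen here and checked against an
independent brute-force implementation to 1e-10 per cell. VS is
scale-equivariant and zero exactly when the profile is constant within
every window.

Exclusion is cohort-relative: exactly `floor(n * 0.15)` cells with the
highest VS are dropped (77 of 515 at the scale of a typical study), with
boundary ties broken by stable input order and a warning. An absolute
cutoff mode exists for reuse outside batch settings. Mean VS on real data
depends on the amplification chemistry and genome build and is therefore
not a quantity the simulator tries to match.

## Embryo-level definitions

* **Karyotype equality**: two call sets are equal iff a one-to-one matching
  pairs calls with the same chromosome and delta at reciprocal overlap
  >= 0.8. Equality of euploid (empty) karyotypes is true.
* **Mosaic**: an evaluable lineage set (>= 3 cells; smaller sets never enter
  any denominator) with >= 2 karyotype classes -- a single divergent cell
  suffices. The major karyotype is the most frequent class; ties prefer the
  euploid class, then stable cell order with a warning. The mosaic rate is
  the fraction of cells outside the major class.
* **Subtype**: from the union of CNV classes among the divergent cells'
  *non-shared* calls (calls matching the major karyotype are ignored --
  otherwise a shared meiotic trisomy would force every mosaic to `complex`).
  When the divergent cells have no private calls (euploid divergents under
  an aneuploid major), the major karyotype's own non-shared calls are typed
  instead. Whole-only gives `whole`, segmental-only `segmental`, both
  `complex`.
* **Origin**: all analyzed cells of the embryo are pooled across lineages;
  individual calls are clustered across cells by the same reciprocal-overlap
  rule; a clustered event carried by every analyzed cell is meiotic, by a
  proper subset mitotic. The strict all-cells rule is the default; a
  tolerance knob (`meiotic_tolerance`) exists because a caller false
  negative in one cell would otherwise demote a true meiotic event, but it
  defaults to 1 (no allowance).
* **TE-ICM discordance**: per resample, `min(|TE|, |ICM|)` cells are drawn
  from each lineage without replacement and paired at random; the statistic
  is the mean fraction of unequal pairs over resamples. Since draw and
  pairing are uniform, the expectation equals the mean inequality over all
  TE x ICM pairs, available exactly via `method = "exact"` and verified
  against exhaustive enumeration in the tests. The per-embryo
  concordant/discordant label compares the *sets* of karyotype classes
  seen in the two lineages.
* **Complementary pairs and masking**: reciprocal gain/loss calls over the
  same region in two cells are the signature of a mitotic non-disjunction.
  Their summed read counts are flat, so `simulate_multicell_biopsy()` --
  which sums raw counts over a sampled subset and re-runs the full caller --
  returns a euploid bulk karyotype over the shared region while both
  members are aneuploid. This reproduces, end to end, the mechanism by
  which bulk multi-cell assays under-report balanced mosaicism; at the
  default caller settings a 20% minority trisomy in a 10-cell pseudo-bulk
  is likewise invisible.

## The simulator

`simulate_embryo()` grows a balanced binary lineage tree (default 6
generations). The balanced tree is a deliberate simplification: it gives
every leaf a unique root-to-leaf path and gives mitotic events the
subset-sharing structure the origin classifier needs, without modelling
asynchronous cleavage. A meiotic event (probability 0.38 per embryo,
whole-chromosome with probability 0.9) is applied to every cell. At each
division, with probability 0.05 (a documented assumption -- no per-division
error rate is measurable from published embryo data), a mitotic error
occurs: a non-disjunction gives reciprocal +1/-1 daughter lineages over
identical bins, an anaphase lag a single -1 daughter. Placements that would
drive copy number below zero are re-drawn. TE and ICM cells are a random
partition of sampled leaves; hESC cells are drawn from ICM-descended leaves,
optionally with a per-aneuploid-chromosome fitness penalty (default 0, i.e.
no selection -- lower hESC mosaicism is an observation, not a mechanism the
package asserts).

Counts are negative binomial with mean
$\mathrm{copy}/2 \times \mathrm{depth} \times g(\mathrm{GC}) \times
\mathrm{mappability}$, where $g$ is a smooth positive bump (rescaled to
mean 1) and depth defaults to 1000 reads per 1 Mb bin, the scale of 0.3x
coverage with ~100 bp reads. The per-cell dispersion $\alpha$
($\mathrm{var} = \mu + \alpha\mu^2$) is lognormal with mean 0.02 and sdlog
0.5, emulating cell-to-cell amplification variability; 1% of bins drop out
entirely. $\alpha \to 0$ recovers Poisson counts, and the emission-law
tests verify the trisomic/disomic mean-count ratio of 1.5 in that limit.

What the simulator does *not* model: read-level artifacts, chimeric
amplification, wave artifacts correlated along the genome, replication
timing, segmental events below 10 Mb, uniparental disomy, and real MALBAC
GC curves. Passing recovery tests on this generator therefore demonstrates
correctness of the algorithms under a realistic noise magnitude, not
performance on any particular chemistry.

## Problem sizes and numerical choices

The validation suite uses a 100-embryo cohort of 5 cells each on the full
1 Mb grid for caller recovery (whole-chromosome recovery >= 95%, segmental
>= 20 Mb recovery >= 90%, < 5% of euploid cells with any >= 10 Mb call),
1000 synthetic cells for the VS oracle, 100,000 resamples for the
discordance estimator (agreement with enumeration within 0.005), and
exhaustive path enumeration up to 8 bins and $6^8$ paths for the HMM; these
sizes keep the full suite in the minutes range on one CPU while leaving the
Monte-Carlo error well below every tolerance tested. Ties in `filter_cells`
and major-karyotype selection are resolved by stable input order so that
repeated runs are identical; all stochastic entry points take explicit
seeds.

## The built-in demonstration cohort

`demo_cohort()` is a deterministic, karyotype-level cohort of 39 embryos
(35 evaluable TE sets, 15 ICM, 6 hESC, 12 embryos with both TE and ICM, one
embryo below per-lineage evaluability that still has 3 pooled cells). Its
cell-level call sets are constructed so that the classifiers produce the
class proportions seen in single-cell blastocyst studies -- TE incidence
23/35, ICM 9/15, hESC 2/6, 16/23 complex mosaics in TE, 4/9 + 4/9
complex/segmental in ICM, 10/12 TE-ICM discordant, and an origin
distribution of 4/19/11 (meiotic-only / mitotic-only / both) among 34
aneuploid embryos. It exists to exercise every classification rule --
including denominator discipline and the subtype fallback -- with exactly
known answers, and it is what `scripts/acceptance.R` evaluates first.

```{r demo}
demo <- demo_cohort()
cl <- classify_embryos(demo$calls, demo$metadata)
cohort_incidence(cl)
glance(classify_origin(demo$calls, demo$metadata))
```

## Known limitations

* Whole-genome ploidy shifts are flagged, not called.
* Sub-10 Mb CNVs, SNV/LOH analysis and breakpoint refinement below bin
  resolution are out of scope.
* The meiotic/mitotic origin rule is strict by default; real data with
  caller dropout may need `meiotic_tolerance` slightly below 1.
* The `whole_fraction = 0.9` boundary and the 30-window VS recipe are
  frozen conventions, stated here because the underlying literature leaves
  them open.
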