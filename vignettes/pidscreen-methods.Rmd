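---
title: "Methods: array-based genetic screening for primary immunodeficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: array-based genetic screening for primary immunodeficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pidscreen)
```

# The screening problem

Primary immunodeficiency disorders (PID) are monogenic diseases of the
immune system. A genotyping array carrying a genome-wide SNP backbone plus
custom probes targeting known pathogenic variants can screen patients at a
small fraction of sequencing cost. The analytical challenge is that the
array's interesting probes are precisely the ones standard array pipelines
handle worst: rare variants, where a cohort contains zero or one carrier
and the usual population-scale clustering has nothing to cluster. This
package implements the full analysis chain — calling, QC, the SNV and CNV
screens, and the validation statistics — together with a synthetic data
generator so the chain can be validated against known planted truth.

# Signal model and genotype calling

Each biallelic probe yields two channel intensities, `x` for the A allele
and `y` for B. We work in polar coordinates: the normalized angle
`theta = (2/pi) * atan(y/x)` in [0, 1] and the total intensity
`R = x + y`. Diploid genotypes form three clusters on the angle axis,
AA near 0, AB near 0.5, BB near 1.

Per probe, a three-component 1-D Gaussian mixture is fitted to the angles
by EM, 20 iterations, initialized at the canonical centers (0.05, 0.5,
0.95) with an ordering constraint AA < AB < BB. Two numerical safeguards
matter:

* component spreads are floored at 0.005 so a zero-variance cluster
  (for example under noise-free simulation) cannot degenerate the
  likelihood;
* a component only moves off its canonical anchor once it has at least 3
  effective members, and clusters with fewer than 3 assigned points are
  re-imputed at the canonical position with the default spread (0.05).

The anchoring rule deserves emphasis. Without it, the EM will happily
relocate an empty component onto the single carrier of a rare variant,
which silently "solves" rare-variant calling in a way no population
caller actually does — production callers form clusters from many samples
and treat isolated points with suspicion. Anchoring reproduces the
realistic failure mode (rare heterozygotes near a boundary become
no-calls) that the recalling stage exists to repair, and lets the package
demonstrate that repair rather than assume it away.

A sample's call is the nearest cluster on the angle axis, scored 1 at the
center and falling linearly to 0 at the decision boundary (the midpoint
between adjacent centers); scores below the no-call threshold (default
0.15, the conventional magnitude for array call-confidence cutoffs)
become no-calls. A probe needs at least 10 measurable samples to be
callable at all.

## Rare-variant recalling

The recalling stage revisits no-calls at rare probes (all non-major
clusters together hold fewer than 5 samples). Decision thresholds are set
in raw channel space from homozygote cluster statistics: the y threshold
is the mean y among AA-cluster members plus `z` times its spread, and
symmetrically for x among BB members; `z = 7` follows the cited recalling
method's convention. A point beyond both thresholds carries real signal
on both channels and is recalled AB; beyond exactly one, the matching
homozygote. When a homozygote cluster is absent (the typical rare-variant
case) its channel statistics are mirrored from the other homozygote,
which is justified when the chemistry is approximately symmetric between
channels; degenerate zero spreads are floored at 1% of the channel mean.
Recalled entries are tagged `caller = "recalled"`, never overwrite a
confident primary call, and carry a fixed mid-range score of 0.5 since
their confidence is by construction lower than a cluster-interior call.

# QC cascade

Filters run in a fixed order: probe call rate ≥ 97.5% on primary calls,
then sample call rate ≥ 97.5%, then exact Hardy-Weinberg exclusion at
`P < 1e-4`, then recalling, then the stricter 98% probe and sample
call-rate filters on the recalled matrix. Within a stage probes are
filtered before samples; each excluded item records the first rule it
failed. One consequence of the probes-before-samples order is worth
knowing: in very small cohorts a badly failing sample can tip many probes
below the probe threshold first, leaving its own call rate computed over
the surviving (biased) probes. At realistic cohort sizes (tens of
samples and up) the effect vanishes; the test suite uses 60-sample
cohorts for the sample-failure checks for exactly this reason.

The Hardy-Weinberg test is the exact conditional test: given the observed
allele counts, heterozygote-count probabilities follow a closed-form
distribution computed by an outward recurrence from the modal
configuration, and the two-sided p-value sums all configurations no more
probable than the observed one. It is validated in the test suite against
an independent direct log-factorial enumeration over every genotype
triple with up to 30 samples. The test uses all retained samples
(patients and controls); with one causal variant per patient and
thousands of probes, patient enrichment at any single probe is negligible,
and the recurrence filter downstream independently guards against
artifact probes. X-chromosome tests use inferred females only; Y is never
tested. Sex is inferred from X heterozygosity (male below 0.05, female
above 0.20, ambiguous otherwise or with fewer than 50 called X probes) —
conventional magnitudes, all configurable.

# The SNV screen

The cascade order is: pathogenicity class, population frequency strictly
below 0.005, cohort singleton, male X-heterozygote removal, cluster-
quality review, inheritance matching. Points worth recording:

* Carrier counts for the recurrence rule come from the full post-QC call
  matrix, not the surviving candidate list, so earlier per-probe filters
  cannot mask a recurrent artifact.
* The cluster-quality check formalizes what an analyst does with a SNP
  intensity plot: a candidate more than `k = 3` spreads from its called
  cluster center, or with total intensity below the probe's 5th
  percentile, is excluded; between 2 and 3 spreads it is kept but flagged
  for review. Recalled candidates are exempt from the distance rule —
  they lie outside the primary clusters by construction and have already
  passed the channel-threshold criterion — but are always flagged for
  review, preserving the manual-scrutiny semantics rare recalls deserve.
  The intensity quantile rule means roughly 5% of true candidates are
  sacrificed to dropout screening under noise; the zero-noise limit is
  exact because the comparison is strict (with a relative tolerance of
  1e-9 so that floating-point ties at the quantile do not discard valid
  candidates).
* Inheritance matching: dominant genes diagnose on one variant;
  recessive genes need a homozygote or two distinct heterozygous variants
  in the same gene, assumed in trans since the array cannot phase;
  X-linked genes need a hemizygous male or homozygous female. Ambiguous-
  sex samples keep their X candidates, flagged.

# The CNV screen

`LRR = log2(R / R_expected)` with the diploid expectation taken as the
cohort median total at the probe, so copy number `c` sits near
`log2(c/2)`. The B-allele frequency interpolates the angle piecewise-
linearly through the fitted cluster centers (anchored 0, 0.5, 1) and is
defined only at polymorphic probes. Chromosome X is handled explicitly:
with known or inferred sexes the X expectation comes from females, male X
LRR is recentred by +1 (one copy is their baseline), and without sex
information X is left unmeasured rather than silently wrong; Y is
excluded throughout.

Segmentation is binary change-point search on the LRR series per
chromosome: the best split by the two-sample z statistic is accepted
while it exceeds the normal quantile matching the significance threshold,
recursing into both halves; probes more than 1 Mb apart never share a
segment. A segment becomes a called event when it has ≥ 4 probes, its
mean log2 crosses a class threshold (−0.3 / −1.1 for single / double
loss, +0.2 / +0.7 for single / double gain), and the two-sided Gaussian
p-value of its mean against the sample's robust noise (scaled MAD of
successive LRR differences, floored at 1e-3, insensitive to true steps)
is below 5e-6. The significance threshold is read as a per-segment
acceptance p-value — the only operational reading of a single
"significance threshold for CNV calling" — and the proprietary
segmentation algorithm of the commercial tool is replaced by this
transparent change-point procedure with identical parameter semantics.

Aneuploidy is detected per chromosome: trisomy needs a median LRR at
least half the ideal `log2(3/2)` shift plus the heterozygote BAF band
split towards 1/3 and 2/3; monosomy needs half of `log2(1/2)` plus an
absent heterozygote band. The 50% tolerance acknowledges intensity
compression on real arrays; discordant LRR/BAF evidence still emits the
event, flagged. This automates what is otherwise a visual review of
whole-genome LRR/BAF plots.

LCSH detection scans for maximal runs of homozygous BAF
(`|BAF − 0.5| > 0.4`) tolerating one heterozygous probe plus one per 50
run probes, accepted at ≥ 5 Mb, ≥ 50 probes, and `|mean LRR| < 0.15` —
the last condition is what distinguishes copy-neutral homozygosity from
deletion, keeping LCSH and loss calls disjoint. The 5 Mb / 50 probe
minimums are conventional run-of-homozygosity magnitudes. Total LCSH span
above 50 Mb flags the sample as likely consanguineous.

CNV filters: events must overlap a custom-content gene footprint;
heterozygous (single-copy) events tolerate zero overlap with the known
benign-CNV track while homozygous/double events are exempt; events whose
reciprocal-overlap match (≥ 50%, same direction) occurs in two or more
samples are removed. Reciprocal overlap at 50% defines "the same CNV"
because no matching rule is standard across tools; recurrence is counted
on the post-gene/benign-filter set, mirroring a filter chain whose
frequency step runs last.

# The synthetic cohort generator

The generator exists so that every claim above is testable. It emulates:
a probe manifest (custom probes clustered in genes, including INDEL
probes with token alleles, plus an evenly spaced backbone), an annotation
table (pathogenicity classes, population frequencies, gene-level
inheritance), truth genotypes (backbone in Hardy-Weinberg equilibrium at
per-probe frequencies drawn from U(0.05, 0.5); custom probes homozygous
reference except planted carriers), planted pathogenic genotypes with
inheritance-consistent zygosity, CNV events (total intensity scaled by
`c/2` with a 7% background floor at copy 0; heterozygote channel balance
shifted to 1/3 : 2/3 in trisomy; hemizygous genotypes in single-copy
regions), LCSH regions (forced homozygosity at normal intensity),
probe/sample failures (garbage angles, inflated noise), and a second
re-noised run over a configurable sample overlap. Every planted event is
recorded exactly once in a ledger; CNVs covering fewer than 4 probes are
flagged sub-detectable rather than omitted, so the minimum-probe rule can
be tested.

Default cohort structure follows the two-run screening design the
pipeline targets: 95 patients and 56 controls on run 1, 41 patients and
55 controls re-assayed on run 2; one planted pathogenic genotype per
patient; 5% probe and 2% sample failure rates (the magnitudes such
screens lose to QC); cluster separation 0.45 (canonical centers);
heterozygote angular noise 0.05.

The noise model is angular Gaussian noise scaled by
`0.2 + 0.8 * sqrt(4 f (1 − f))` for allelic fraction `f`: heterozygote
clusters are the widest and homozygote clusters roughly five times
tighter. This reflects real chemistry — at a homozygote the off channel
sits near background, so the allelic ratio barely fluctuates — and it is
load-bearing for the recalling stage: the channel thresholds at
`mean + 7 spreads` of homozygote background only discriminate when that
background is tight relative to heterozygote signal, which is exactly the
regime the recalling method was designed for.

What the generator does not model: batch effects, genomic waves,
GC-content intensity bias, cross-hybridization between nearby variants,
mosaicism. Passing tests therefore demonstrate the pipeline's logic and
its behaviour under idealized noise, not robustness to structured
artifacts of production arrays; the cluster-quality review and
flagged-for-review fields are where such artifacts would surface for a
human analyst.

# Reporting conventions

Internal coordinates are 0-based half-open everywhere; conversion to
1-based happens only in the VCF writer (SEG and BED stay 0-based). INDEL
probes are genotyped like SNVs (the chemistry is identical) but flagged
so the sequencing-concordance comparison can restrict to SNV probes,
where short-read truth is reliable. Percentages are rounded half away
from zero at the precision conventional for each statistic: one decimal
for concordance, confirmation and reproducibility, integers for
sensitivity and yield. The sensitivity denominator is restricted to
known variants with a probe on the manifest; variants without probes are
counted separately (a screen cannot be penalized for content it was never
given, but the report must say how much that is). The non-reference
mismatch rate is emitted against both defensible denominators
(non-reference calls, and all compared calls) rather than choosing one.
The VCF header is static so identical seeds yield byte-identical outputs.

# Problem sizes

The test suite and acceptance script run simulated cohorts of 20–151
samples over 380–4,300 probes, with the exhaustive Hardy-Weinberg sweep
covering all genotype triples to n = 30 and the recalling comparison
running 20 paired replicates. These sizes were chosen so the whole suite
exercises every stage — including two full runs and both screens — in a
few minutes on one core while keeping planted-event recovery
deterministic at the configured noise levels.

# Known limitations

* Rare-variant recalling repairs no-calls only; a rare heterozygote
  miscalled into a homozygote cluster is not revisited.
* Segmentation calls abutting events of the same class as separate
  segments only when the change-point statistic separates them; two
  adjacent events of identical depth merge.
* The consanguinity indicator is a span threshold, not an inbreeding
  coefficient estimate.
* The cost model is the linear two-arm comparison; no discounting,
  throughput, or confirmation-cost terms.
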