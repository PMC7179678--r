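# pidscreen

Genetic screening for primary immunodeficiency disorders (PID) with a
customized genotyping microarray: an R implementation of the complete
analysis pipeline, from raw two-channel probe intensities to per-patient
diagnostic reports and cohort-level validation statistics.

PID comprises hundreds of monogenic inborn errors of immunity. Sequencing
every suspected patient is expensive; a SNP array enriched with custom
probes for known pathogenic variants can screen patients for a fraction of
the cost, deferring sequencing to the patients the screen leaves
undiagnosed. This package is for researchers and diagnostic developers who
want to analyse such arrays — or stress-test the analysis itself, since the
package ships a synthetic array-data generator with complete planted truth,
so every stage is testable without access to patient data.

## What the pipeline computes

**Genotype calling.** Raw channel pairs `(x, y)` are mapped to a normalized
angle `theta = (2/pi) * atan(y/x)` and total intensity `R = x + y`. Per
probe, a three-component Gaussian mixture on the angle axis (EM with
canonical initialization and an ordering constraint AA < AB < BB) models
the genotype clusters; calls score 1 at a cluster center, falling to 0 at
the decision boundary, with calls under 0.15 treated as no-calls. A
zCall-style recalling stage then rescues rare-variant no-calls: channel
thresholds are set at the opposite homozygote cluster's mean plus `z = 7`
spreads; a point beyond both thresholds is recalled heterozygous, beyond
one the matching homozygote.

**QC cascade.** Probe and sample call-rate filters at 97.5% on primary
calls, exact Hardy-Weinberg exclusion at `P < 1e-4` (conditional-on-allele-
counts exact test; X tested in females only), then stricter 98% probe and
sample filters after recalling. Sample sex is inferred from X-chromosome
heterozygosity.

**SNV screen.** Non-reference calls at disease-annotated probes pass, in
order: population frequency `< 0.5%` (strict), cohort singleton (recurrent
variants indicate faulty probes), male X-heterozygote removal, and an
automated cluster-quality review replacing manual intensity-plot
inspection. Surviving variants are matched against gene inheritance
patterns (AD / AR incl. compound heterozygotes / XL) to call a per-patient
genetic diagnosis.

**CNV screen.** Per probe, `LRR = log2(R / R_expected)` (cohort-median
expectation; `log2(c/2)` for copy number `c`) and a B-allele frequency
interpolated through the fitted cluster centers. Binary change-point
segmentation per chromosome calls events with at least 4 probes, mean log2
beyond −0.3 / −1.1 (single / double loss) or +0.2 / +0.7 (single / double
gain), and `p < 5e-6` against the sample's robust noise; probes more than
1 Mb apart never share a segment. Whole-chromosome LRR shifts with the
matching BAF pattern (AAB/ABB bands at 1/3 and 2/3, or an absent
heterozygote band) flag trisomy and monosomy; long runs of homozygous BAF
at normal LRR become LCSH segments and a per-sample consanguinity
indicator. Called CNVs are filtered to PID-gene overlap, zero tolerated
benign-track overlap for heterozygous events, and cohort singletons.

**Evaluation.** Concordance against sequencing truth over custom SNV
probes, variant-level sensitivity (probe-covered known variants, plus
confirmation-tested new ones), patient-level diagnostic yield, inter-run
reproducibility (genotype discordance and causal-variant replication), and
a screen-then-sequence vs sequence-everyone cost model.

## Worked example

```r
library(pidscreen)

man <- simulate_manifest(n_custom = 300, n_backbone = 1200, n_genes = 20, seed = 1)
ann <- simulate_annotation(man, seed = 1)
cfg <- simulation_config(n_patients = 40, n_controls = 20, noise_sd = 0.05, seed = 1)
coh <- simulate_cohort(cfg, man, ann)

cg <- call_genotypes(coh$run1)
qc <- apply_qc(cg, man)
qc$report
#> QC report: 1417/1500 probes retained, 60/60 samples retained
#> low_call_rate
#>            83

truth <- truth_as_genotypes(coh, rownames(qc$genotypes$calls))
concordance(qc$genotypes, truth, man)
#> Concordance: 13500/13500 (100.0%); non-reference mismatches 0 of 34 non-ref calls

scr <- screen_snv(qc, ann, man, cg$models, coh$run1, coh$patients)
scr$attrition
#> nonref_calls disease_causing  frequency  singleton  male_x_het  cluster_quality
#>        31292              38         38         36          36               36

diagnostic_yield(scr$diagnoses)$yield_percent
#> [1] 88

cost_compare(cost_model(40, 1000, 100, 0.4))
#> $initial_array_cost: 4000   $screen_then_sequence_total: 64000
#> $sequence_all_total: 100000 $saving: 36000
```

The generator planted one pathogenic genotype per patient and failed 5% of
probes; QC removes exactly the failed probes, calling is perfectly
concordant with the planted truth at this noise level, the cascade narrows
31,292 non-reference calls down to the 36 planted singleton pathogenic
variants, and 35 of the 40 patients end with a matching-inheritance
diagnosis (the rest lost their variant to probe failures or the recurrence
rule). The cost comparison says screening 100 patients at EUR 40 before
sequencing the undiagnosed 60% saves EUR 36,000 over sequencing everyone.

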