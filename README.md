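# magtrack

Quantifying donor microbiota engraftment after microbiota transplant
therapy (MTT/FMT) from shotgun metagenomic reads.

## The problem

After a microbiota transplant, the recipient's gut contains a collision of
two communities — the donor's and the patient's own pre-treatment
microbiota — plus whatever novel strains arrive from diet and environment.
The pharmacokinetics of a live biotherapeutic hinge on one number: what
fraction of the post-treatment community is donor-derived (*engrafted*),
versus retained pre-treatment content (*persistent*), versus novel?

`magtrack` answers this without any external reference database. Reference
databases are assembled de novo from the donor sample and from the
patient's pre-treatment (baseline) sample; every post-treatment read is
aligned against both and binned four ways:

* **uniquely donor-aligned** — engrafted,
* **uniquely patient-aligned** — persistent,
* **ambiguous** (aligns to both) — resolved statistically, below,
* **unmapped** — corrected for expected read loss, the remainder called
  novel.

## The model

For an ambiguous read, let `z` be the hidden event that its true source is
the donor, and let `(p, d)` be the observed flags that it aligned to the
patient and donor databases. The posterior that the read is engrafted is

```
P(z | p, d) = P(p, d | z) P(z) / [ P(p, d | z) P(z) + P(p, d | ¬z) P(¬z) ]
```

with every term estimated empirically from the study's own data:

* the priors `P(z)`, `P(¬z)` are the proportions of the sample's uniquely
  assigned reads that went to donor and patient, respectively;
* the likelihoods `P(p, d | z)` and `P(p, d | ¬z)` come from a
  *self-alignment profile*: each source sample's reads are aligned against
  both databases, and the fraction aligning to both estimates how often a
  read of that origin looks ambiguous.

All ambiguous reads of a sample share the observation `(p = d = TRUE)`, so
the posterior is one scalar per sample; the ambiguous bin is reallocated
fractionally (the deterministic expectation). The same self-alignment step
yields each source's self-unmapped rate, giving the expected number of
unmapped reads due to sequencing error and unassembled rare strains; only
the excess over that expectation is called novel.

Alignment identity is `1 − edit distance / read length`; the default
threshold is 1.00 (exact), which minimises false-positive engraftment
calls, with 0.98/0.99 available to trade against false negatives. The
built-in aligner is an exhaustive seeded ungapped best-hit aligner
(compiled, both strands, deterministic tie-breaks); an adapter for external
SAM-producing aligners (e.g. minimap2) is included.

The package also ships the full validation machinery: a seeded synthetic
cohort generator (controllable donor/patient genome overlap, per-base
substitution errors, contaminant sources), exact-composition mixture
construction at fixed donor fractions, contamination spike-ins,
depth-downsampling experiments, and type-I/type-II/absolute-error
evaluation against the simulator's provenance labels.

## Worked example

Simulate a donor/patient pair whose genomes share 20% of their content,
with 0.5% per-base sequencing error, mix a post-treatment sample at 30%
donor, and estimate:

```r
library(magtrack)

cohort <- generate_synthetic_cohort(shared_fraction = 0.2, error_rate = 0.005,
                                    depth = 20000, seed = 42)
dbs <- build_databases(cohort$donor, cohort$patient,
                       donor_assembler   = assembler_coverage(cohort$genomes$donor),
                       patient_assembler = assembler_coverage(cohort$genomes$patient),
                       min_identity = 0.98)
mix <- make_mixture(cohort$donor, cohort$patient, depth = 20000, f = 0.3, seed = 7)
fit <- track_engraftment(mix$reads, dbs$donor_db, dbs$patient_db,
                         dbs$profiles[["0.98"]], min_identity = 0.98)
summary(fit)
#> Engraftment estimate for sample 'mix_f30'
#>   reads: 20000 total | 4739 unique donor, 11080 unique patient, 3880 ambiguous, 301 unmapped
#>   ambiguous-read posterior (donor): 0.2947
#>   expected unmapped: 282.2 (novel: 18.8)
#>   proportions:
#>  engrafted persistent      novel 
#>     0.2983     0.7007     0.0009 
```

The true donor fraction is 0.30; the estimate is 0.2983. The 3880
ambiguous reads (roughly the 20% shared content) were reallocated with a
posterior of 0.2947, and of the 301 unmapped reads, 282 were expected from
the 0.5% error rate at the 0.98 identity threshold, leaving a novel
fraction near zero — as it should be, since the simulation contains no
third source. Checking against the simulator's provenance labels:

```r
evaluate_engraftment(fit, mix)$absolute_error
#> [1] 0.001665165
```

`write_report()`, `write_engrafted_reads()` and `write_per_mag()` export
the estimate, the engrafted read list with best-hit scaffolds, and the
per-scaffold engrafted mass for downstream binning/taxonomy. A thin
command-line front end (`inst/scripts/magtrack`) exposes the pipeline as
`magtrack track | simulate | evaluate` for manifest-driven runs.

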