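---
title: "Methods: MAG-based engraftment tracking and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MAG-based engraftment tracking and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical model, its
numerical choices, and what its simulation-based validation does and does
not demonstrate.

## The estimation procedure

One patient contributes three kinds of samples: a **donor** sample (one or
more sequencing files, concatenated — e.g. multiple stool preparations from
the same donor), a **baseline** (pre-treatment) sample, and one or more
**post-treatment** samples. The procedure per post-treatment sample:

1. **Databases.** Scaffolds are assembled de novo from the donor and
   baseline reads, each set forming one reference database. No minimum
   scaffold length is imposed: short scaffolds carry the only information
   available about rare, incompletely assembled strains, and dropping them
   would bias the estimator against exactly the strains whose engraftment
   is most interesting.
2. **Classification.** Every post-treatment read is aligned against both
   databases and binned: uniquely donor, uniquely patient, ambiguous
   (both), unmapped (neither). The four bins partition the sample exactly;
   this invariant is property-tested.
3. **Ambiguity resolution.** The ambiguous bin is reallocated by Bayes'
   theorem. With `z` the hidden donor-origin indicator and `(p, d)` the
   two alignment flags,
   `P(z | p,d) = L_d π_d / (L_d π_d + L_p π_p)`,
   where the priors `π` are the proportions of the sample's *uniquely*
   assigned reads going to each source, and the likelihoods `L` are the
   both-database alignment rates measured by aligning each source sample's
   own reads against both databases (the *self-alignment profile*). The
   denominator of each likelihood is all reads of that source sample, a
   deliberate, auditable reading of "proportion of reads that aligned with
   both".
4. **Unmapped correction.** Each source's self-unmapped rate (its own
   reads failing to align to its own database) estimates read loss from
   sequencing error and unassembled content. The expected unmapped count
   of the post sample is the mapped-mass-weighted combination of the two
   rates; observed unmapped reads beyond that expectation are **novel**,
   and the expected part is returned to the donor/patient pools in
   proportion to the mapped-mass split, since lost reads arise from
   whichever source contributed them.
5. **Report.** Engrafted / persistent / novel proportions (summing to 1),
   the scalar posterior, the four counts, a per-scaffold engrafted mass
   table, and the engrafted-read list for downstream binning or taxonomy.

### Why one scalar posterior

The observation model conditions only on the pair of Boolean alignment
flags. Every ambiguous read has the identical observation
`(p = TRUE, d = TRUE)`, so the posterior is necessarily one number per
sample, and the ambiguous bin is split fractionally (the deterministic
expectation) rather than by per-read sampling — reproducible without a
random seed. Per-read labels in the engrafted-reads file use
`posterior > 0.5`, ties going to the patient (the conservative direction
for an engraftment claim). Finer conditioning (per-scaffold or
per-identity posteriors) is deliberately out of scope of the model.

### Numerical conventions and degenerate inputs

* **Identity** is `1 − edit distance / read length`; a read aligns iff its
  best hit reaches the threshold. The mismatch budget for a read of length
  `L` at threshold `t` is `floor((1 − t) L)` (with a 1e-9 guard against
  representation error in `t`).
* **Equal likelihoods** (`L_d = L_p`, including both zero) carry no
  information; the posterior short-circuits to the prior *exactly*,
  avoiding floating-point residue in the algebraically cancelling ratio.
  Both-zero additionally warns.
* **No uniquely assigned reads**: priors fall back to (0.5, 0.5) with a
  warning.
* **Novel mass is clamped at zero** when observed unmapped falls below
  expectation (a deficit is uninterpretable as novel content); the
  clamping is flagged on the estimate, and only the actually available
  unmapped mass is redistributed, so the three proportions still sum to 1
  exactly.
* **Empty post sample**: an error, not a degenerate estimate.
* **Tie-breaks** in the aligner are deterministic: fewest mismatches, then
  first scaffold in database order, then forward strand, then leftmost
  position. Two runs with the same inputs produce byte-identical reports.
* **Paired-end data** are treated as independent reads (mates classified
  separately, identifiers disambiguated on reading); the proportion
  arithmetic of the priors and likelihoods is per-read throughout.

## The built-in aligner

The default backend is an ungapped best-hit aligner over both strands of
every scaffold, written in C++. It uses pigeonhole seeding: a read of
length `L` placed with at most `m` mismatches must contain an exact
`k`-mer at one of `floor(L/k)` disjoint offsets whenever
`k ≤ floor(L/(m+1))`, so a hash of scaffold k-mers finds *every* placement
within the mismatch budget — exhaustive for all hits at or above the
identity threshold, which is all the alignment contract requires.
Sub-budget placements missed by no seed do not exist; placements over
budget are recorded as unaligned regardless. An independent brute-force
sliding-window oracle in the test suite cross-checks the aligned set and
mismatch counts at several thresholds.

The external-backend adapter accepts any command producing SAM (a
minimap2 preset is included), reads it back through `Rsamtools` using the
`NM` tag, and counts clipped bases toward the edit distance so that local
alignments are scored under the same whole-read identity semantics. The
external route exists for scale and for gapped alignment; the naive
backend is the reference implementation and the one the tests treat as
ground truth. Substitution-only simulation keeps the ungapped aligner an
exact oracle; indel robustness is delegated to the external backend and is
not validated by the simulation suite.

## The simulator: what it emulates, and what it does not

`generate_synthetic_cohort()` is a desk-scale stand-in for a real
donor/baseline pair of sequencing runs:

* **Genomes.** One (or more) random genome per source, 50 kb each by
  default. A `shared_fraction` of donor content is copied verbatim into
  the patient genome — modelling strains common to both communities, the
  source of ambiguous reads. A contaminant source can share content with
  the donor the same way (from the opposite end of the genome, so the two
  shared regions are disjoint). Independently generated content is
  screened for chance shared 31-mers (a shared read-length match implies
  one) and resampled, making "disjoint" exact rather than probabilistic.
* **Reads.** Uniform positions, both strands, fixed read length (100 bp
  default), per-base substitution errors at `error_rate`, never to the
  original base. 20 000 reads per source by default — the desk-scale
  analogue of a sequencing run, chosen so the full validation suite runs
  in minutes on one core; the mixture constructors take the replication
  depth (8.75 M reads; the design is also quoted as 10 M in places, and
  the depth is therefore an explicit parameter) when replication at scale
  is wanted.
* **Provenance.** Every read carries its true source, genome and position,
  giving exact ground truth for mixture composition (counts, not
  expectations), per-genome abundance, and the type-I/type-II metrics.

**Assembly in simulation.** Real assembly is delegated to external tools
behind an adapter (the de Bruijn graph machinery is explicitly not
reimplemented). For simulation the package provides an idealised
*coverage-limited assembler*: using read provenance, it emits exactly the
maximal genome intervals covered by the input reads. Its databases are
perfect where there is coverage and absent where there is none — which
isolates the one property of assembly the validation needs, namely that
database completeness degrades with source sequencing depth. A fixture
adapter (pass-through of caller-supplied scaffolds) covers the case of
externally assembled data.

What the simulator does **not** emulate: real instrument error profiles
and quality scores, indels, uneven strain abundance within a source
(except via explicit genome weights), chimeric assembly artifacts, and
contamination of the *source* samples themselves. Passing the simulation
suite therefore demonstrates the estimator's correctness — its
arithmetic, its Bayesian reallocation, its response to shared content,
contamination, noise and depth — on data satisfying the model's
assumptions; it does not certify accuracy on real stool metagenomes,
where database quality is governed by a real assembler.

## The validation experiments

* **Mixture series.** 11 mixtures at donor fractions 0–100% in 10% steps
  (the replication design: 15 pairs × 11 fractions = 165 samples; the
  harness follows the 15-pair/165-sample figure of the design). With
  disjoint sources, error-free reads and identity 1.0, the estimate equals
  the true fraction exactly — the mixture composition is exact by
  construction, every read classifies uniquely, and the estimator reduces
  to counting. With 30% shared content, recovery holds within binomial
  noise; with 0.5% per-base error at identity 0.98 the mean absolute error
  over the series stays below 0.02 across seeds.
* **Contamination.** 20% contaminant reads with the donor:patient remainder
  preserved (50/50 becomes 20/40/40). A contaminant disjoint from both
  sources produces a type-I rate of exactly 0 at identity 1.0; when the
  contaminant shares donor content, relaxing identity from 1.00 to 0.98
  can only admit more false positives (per-read threshold monotonicity),
  and the measured rates quantify how much.
* **Downsampling.** Shallow *post* samples against full-depth databases
  leave the estimate unbiased at every depth (5000 down to 500 reads here,
  mirroring the 5 M–500 k design at scale); shallow *source* samples
  before assembly degrade the databases and inflate the error sharply at
  the lowest depths — the practical advice being to spend sequencing depth
  on the donor and baseline samples rather than the post samples.

The problem sizes used throughout (50 kb genomes, 20 k-read sources and
mixtures, 1–5 seeds per experiment) are the package's chosen desk-scale
study conditions; all experiment functions accept larger values.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `min_identity` | 1.00 | alignment identity threshold; 1.00 minimises type-I error, 0.98 reduces type-II error; also selectable per-profile |
| `shared_fraction` | 0 | donor content copied into the patient genome (simulation) |
| `error_rate` | 0 | per-base substitution probability (simulation) |
| `read_length` | 100 bp | simulated read length (trimmed short-read scale) |
| `depth` | 20 000 | reads per source / per mixture at desk scale |
| `c` (contaminant fraction) | 0.2 | spike-in fraction in contamination runs |

## Known limitations

* High donor/patient overlap (related donors, autologous transplants)
  inflates the ambiguous bin; the posterior then leans heavily on the
  priors, and per-read recall of donor material drops even while the
  aggregate proportion stays unbiased. Identity 1.00 is recommended in
  that regime.
* The unmapped correction redistributes expected-unmapped mass
  proportionally to the mapped-mass split. The alternative — dropping the
  expected-unmapped mass from the denominator — was considered and
  rejected because it silently changes the meaning of the reported
  proportions; all three quantities of the correction are reported so the
  choice is auditable.
* The model conditions on two Boolean flags only; it cannot distinguish
  *which* shared strain an ambiguous read came from.
* Novel-strain detection is a residual after an expectation-based
  correction, not a positive identification; small novel fractions are
  within the correction's noise.
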