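---
title: "Mendelian-inconsistent calls in trio sequencing: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian-inconsistent calls in trio sequencing: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In parent–child trio whole-genome sequencing, a Mendelian-inconsistent call
(MIC) is a combination of (child, mother, father) genotypes at a locus that
cannot be produced by transmitting one allele from each parent under diploid
ploidy. True de novo mutations are rare (about 1.2e-8 per bp per generation,
a few dozen per child), so the overwhelming majority of MIC are genotype-call
errors — but not all. When a child inherits a hemizygous deletion from one
parent, a diploid caller reports the hemizygous samples as homozygous for
their remaining allele, producing MIC that reflect genuine biology. Treating
all MIC as errors discards that signal; treating them all as candidate de
novo mutations admits floods of false positives. `triomic` separates the two
regimes.

## The signature taxonomy

A biallelic unphased genotype is coded by alternate-allele dose: 0 (hom-ref),
1 (het), 2 (hom-alt). Of the 27 possible trio triples, exactly 12 are
Mendelian-inconsistent; `triomic` fixes their ordinals as

| ordinals | triples (c,m,f) | deletion category |
|---|---|---|
| 1–4 | 0,2,0 / 0,2,1 / 2,0,1 / 2,0,2 | maternal deletion possible |
| 5–8 | 0,2,2 / 1,0,0 / 1,2,2 / 2,0,0 | no single-parent deletion explains them |
| 9–12 | 0,0,2 / 0,1,2 / 2,1,0 / 2,2,0 | paternal deletion possible |

The deletion-compatible set is derived, not asserted: enumerating every
scenario (carrier parent × remaining allele × other parent's genotype ×
transmitted allele), calling hemizygous samples homozygous for the remaining
allele, and keeping the Mendelian-inconsistent outcomes yields exactly these
eight triples. The test suite re-derives the set with an independent
brute-force oracle. Swapping the parents maps the maternal set onto the
paternal set and permutes the non-deletion set within itself; this symmetry
is tested as a property.

## Supporting metrics

Three quantitative annotations separate deletion-driven MIC from error-like
MIC:

* **Normalized parental depth ratio** — `(mother DP / maternal mean
  coverage) / (father DP / paternal mean coverage)`. Within a maternally
  inherited deletion the mother and child each carry one copy, so the ratio
  concentrates near 0.5; near 2 for paternal deletions; near 1 when both or
  neither parent is deleted (which is why the 2,0,2 and 2,2,0 signatures are
  less informative). The ratio is undefined when the paternal depth is 0 and
  such records are excluded from medians rather than imputed.
* **Alignability** — per-position uniqueness score in [0, 1]. Error-like MIC
  concentrate in low-alignability repeats; deletion-compatible MIC do not,
  since deletions fall anywhere.
* **Allele balance (AB)** — alt reads / (ref + alt) from the AD field.
  Clean heterozygous calls sit near 0.5; error-driven het calls skew low.
  The field does not define AB uniquely; alt-fraction (not minor-allele
  fraction) is used here, stated once and applied everywhere.

## Quality filters

Calls must satisfy DP ≥ 25% of the sample's mean coverage, GQ ≥ 30, and (for
heterozygous calls only) AB ≥ 0.25. All comparisons are inclusive and the DP
threshold is compared as a real number, not rounded. "Mean coverage" is the
mean FORMAT/DP over called autosomal sites for the sample, computed in a
first pass, unless a coverage table is supplied. The filter's scope is a
genuine design choice: `triomic` requires **all three** trio members to pass
for a record to count as filtered-pass, on the grounds that a single
unreliable member call suffices to make the violation unreliable. Failing
records are kept with `pass = FALSE` and per-member reasons, so raw and
filtered tallies are both derivable from one table.

Missing genotypes (including half-calls like `./1`) remove the trio from the
site; multiallelic and symbolic records are skipped with logged counts;
phased genotypes are unphased before coding. Sites on sex chromosomes and
mitochondria are excluded.

## Deletion candidate regions

High-confidence inherited-deletion candidates are deletion-category SNV MIC
with alignability ≥ 1.0 and depth ratio strictly below 0.5 (maternal) or
strictly above 2.0 (paternal), optionally restricted to a repeat class such
as LINE, where deletion-compatible MIC at full alignability are most
credible. Strict inequality for the ratio and an inclusive alignability
minimum mirror how the thresholds are stated for the selection procedure this
implements. Candidates are clustered per trio and chromosome: maximal runs
with inter-MIC gaps ≤ `max_gap` (default 10 kb) and at least
`min_cluster_size` members (default 2) become regions. No clustering
parameters are canonical for this procedure; the defaults are conservative
and CLI-exposed, and `min_cluster_size = 1` reproduces a selection that
admits isolated candidates.

## Population windows and PCA

Parents are assigned ancestry by k-means clustering (k = 5 by default) on
PCs 1–3 of externally supplied coordinates; a sample takes its cluster's
population label only when its silhouette exceeds 0.6 (strictly), otherwise
`OTHERS`. A trio joins a population group only when both parents carry the
same label (two `OTHERS` parents form an `OTHERS` group; discordant parents
exclude the trio).

Filtered-pass SNV MIC are counted per trio in 1 Mb windows tiling the
autosomes, separately for deletion-compatible and non-deletion signatures.
PCA is column-mean-centered and unscaled — the minimal default, since no
transformation is canonical for these counts; PC1's sign is fixed so that its
scores correlate positively with per-trio totals. Empirically PC1 tracks
overall MIC load, while PC2 of the deletion-signature matrix separates
populations when a deletion region is population-specific; the non-deletion
matrix shows no such structure. "Stratifies" is made testable as a
between/within-population variance ratio of PC2 scores rather than a visual
claim. Windows are ranked by |PC2 loading| with ties broken by genomic
order.

Population bedGraph tracks list every position with a filtered-pass MIC in
at least one grouped trio, valued by the number of distinct trios; whether
tracks should count raw or filtered MIC is not specified anywhere
authoritative, and filtered is used.

## Flagging candidate de novo mutations

Candidates intersect the population tracks by exact position. A candidate
observed as MIC in ≥ 2 trios (configurable) is `LIKELY_ERROR`: true de novo
mutations are essentially non-recurrent, so positional recurrence across
unrelated trios marks systematic error. A candidate inside a candidate
deletion region, or whose own trio triple is deletion-compatible, is
`REVIEW` (an inherited deletion must be ruled out), as is one overlapping an
annotated repeat when that annotation is provided. The verdict is a
deterministic, monotone function of the flags. Repeat and region inputs are
optional: recurrence is the primary evidence, and repeat overlap alone is a
weak reason to discard a candidate (a third of the genome is repetitive).

## The synthetic cohort

The simulator produces the statistical structure the analysis assumes, at
desk scale: 2 chromosomes of 3 Mb, two populations of 300 trios, 40×
coverage, one polymorphic SNV per kb. It is a genotype-level simulator — no
reads, no alignment.

* **Genome tracks.** Repeat elements are placed by rejection of overlaps:
  Alu-like SINEs (250–350 nt, ~12% of the genome) with 20 nt poly-T heads
  and poly-A tails, LINEs (500–8000 nt, ~18%), plus LTR/simple/satellite/
  low-complexity/DNA classes. Alignability is 1 in unique sequence, low in
  SINEs and simple repeats, and near 1 in LINEs (60% exactly 1), reproducing
  the contrast that makes LINE deletion candidates selectable at
  alignability 1.
* **Genotypes.** Parental haplotypes are Bernoulli draws from shared allele
  frequencies (uniform on 0.05–0.95; frequencies are shared across
  populations so that non-deletion MIC carry no population signal by
  construction). Hemizygous deletion carriers are drawn per region at
  per-parent carrier frequencies and transmit the deleted haplotype with
  probability 1/2; a non-transmitting carrier passes its remaining
  haplotype. Hemizygous samples are called homozygous for the remaining
  allele with DP ~ Poisson(coverage × copies / 2); a child deleted on both
  haplotypes has copy number 0 and is emitted as a missing call.
* **Errors.** Per-genotype error probability is `base_rate ×
  class_multiplier × (1 + 4 × (1 − alignability))`, capped at 0.3, with
  `base_rate = 1e-3` and multipliers up to 40 for simple repeats and 25 for
  SINEs; errors flip the call to a uniformly chosen different code, carry
  degraded GQ ~ U{10..50} and skewed het AB (binomial p = 0.3). Monomorphic
  1-bp indel sites inside homopolymer runs take a slippage rate of 0.02
  instead — the systematic, position-recurrent error mode. The base rate is
  set so that errors dominate deletion-driven MIC cohort-wide, the regime
  trio studies consistently report; at lower error rates the deletion and
  error contributions are comparable, which is unrealistic.
* **Load heterogeneity.** Real cohorts show severalfold differences in
  per-trio MIC load. Two mechanisms supply it: a per-family lognormal
  error-rate multiplier (sdlog 0.6; families are sequenced together, so
  batch effects act at the trio level) and per-sample "callability" ~
  U(0.35, 0.95), the probability that a clean call is emitted at GQ 99
  rather than degraded. Without such a common factor a six-window count
  matrix has an almost flat eigen-spectrum and no meaningful load axis;
  with it, PC1 is the load direction, as observed in real cohorts.
* **Deletion regions.** Five shared 60 kb regions (6% per-parent frequency)
  in distinct windows plus one 60 kb region specific to the second
  population at 40% vs 0% — the population-specific deletion the PCA is
  meant to find. Region sizes and shared frequencies were chosen so that
  the population-specific window variance exceeds any single shared
  window's noise (it must rank first on PC2) while staying below the
  batch-load eigenvalue (it must not hijack PC1).
* **De novo mutations** are child-only clean heterozygous calls at fresh
  positions, Binomial(genome length, 1.2e-8) per child.
* **Ancestry PCs** are well-separated per-population Gaussian blobs
  (sd 0.3 around centers 6 units apart), so silhouette-gated assignment is
  exercised without re-implementing reference-panel projection, which is an
  input to this package, not part of it.

Every detected MIC on simulated data is attributable to exactly one cause —
deletion, injected error, or de novo — and the suite asserts zero
unexplained records. The same seed yields byte-identical output files.

### What a green test does and does not establish

The generator emulates the *statistical* structure of trio cohorts:
hemizygous depth halving, error concentration in repeats and homopolymers,
per-trio load heterogeneity, population-specific deletion frequencies. It
does not emulate linkage disequilibrium, mapping artifacts beyond a scalar
alignability, multi-nucleotide or complex variants, sex chromosomes,
structural variants other than clean deletions, or joint-calling behavior.
Passing tests establish that the pipeline recovers the planted structure
under its stated model, not that it would perform identically on any real
cohort.

## Numerical and interface choices

* Coordinates: VCF positions are 1-based; BED/bedGraph are 0-based
  half-open; conversions are centralized in two helpers.
* Repeat overlap tie-break: the shortest covering interval wins (most
  specific, as with nested RepeatMasker elements), ties to the leftmost
  start. Indels are anchored at POS for all interval queries.
* SINE offsets are measured from the BED start regardless of strand; strand
  handling for the poly-A/T asymmetry is deliberately not modelled, and the
  simulator flags homopolymer runs directly rather than deriving them from
  sequence.
* Missing alignability is reported as missing and excluded from summaries,
  never imputed as 0.
* DP comes from FORMAT/DP, not the AD sum, when both are present.
* k-means uses 25 restarts under a caller-supplied seed; silhouettes come
  from `cluster::silhouette`.
* All stage randomness derives from one master seed.

## Known limitations

* Deletion detection requires polymorphic sites inside the deletion: a
  hemizygous region with no informative site yields no MIC and is
  invisible.
* The 2,0,2 / 2,2,0 signatures mix single- and double-parent deletion
  scenarios; their depth ratios concentrate near 1 and the candidate
  selector deliberately relies on the ratio bounds instead of trusting the
  category label alone.
* The recurrence threshold separating systematic error from plausible de
  novo recurrence has no canonical value; 2 is a configurable stand-in.
* Breakpoints are not refined: candidate regions span member MIC, which
  under-covers the true deletion extent by up to the local inter-site
  spacing on each side.
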