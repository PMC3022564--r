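---
title: "Surveying mitochondrial polymorphism in two populations: methods and design"
author: "mitosurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying mitochondrial polymorphism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitosurvey)
```

## The problem

Human mitochondrial DNA segregates thousands of single-nucleotide
polymorphisms, and their population distribution is informative about
mutation, selection, drift — and about how variants get *discovered*. A
genome-wide survey comparing an African-rooted population (L haplogroups)
with the out-of-Africa population (M/N haplogroups) finds the African sample
more variable in every functional category (synonymous, nonsynonymous,
benign, damaging), except one: variants catalogued as *pathogenic*, which
are more frequent and more numerous per genome in the non-African sample.
Because strongly deleterious variants should, if anything, be depleted where
diversity is lower, the inversion is best explained by ascertainment bias —
pathogenic variants are discovered in the clinics and cohorts that
predominantly sample non-African patients, so the catalogue itself is
population-biased.

`mitosurvey` re-implements that survey as a reusable, fully testable
pipeline: from an aligned set of complete mtDNA genomes with population
labels, gene models, an external effect annotation (benign/damaging, from a
variant-effect predictor run upstream) and a pathogenic catalogue, it
produces the four report tables and the ratio summaries. A synthetic-data
module generates complete input bundles with planted truth, so every stage
is checked end to end without any external download.

## The statistics

**Minor alleles.** A polymorphic site is an alignment column with more than
one called nucleotide (gaps and `N` are missing data and excluded from
alleles and denominators everywhere). At each such column the most frequent
pooled allele is the major allele (ties broken alphabetically, `A<C<G<T`,
which is deterministic and order-independent); every other observed allele
is a minor allele, with its within-population frequency
`count / (population size − missing at that column)`. Minor alleles are
defined on the pooled two-population sample so that both population columns
of the report refer to the same alleles; per-population re-calling is
available as the `minor_definition = "population"` switch.

**Functional categories.** Alleles in protein genes are substituted into the
codon formed by the major alleles at the other two positions (the
*major-allele background*, complemented for minus-strand genes) and
classified synonymous or nonsynonymous under the vertebrate mitochondrial
genetic code (NCBI table 2: `ATA`=Met, `TGA`=Trp, `AGA`/`AGG`=stop).
Synonymous changes at four-fold degenerate positions are flagged. Background
codons containing missing bases are `unknown-codon` and excluded from
synonymous/nonsynonymous tallies. Sites inside overlapping protein genes are
classified against each gene and counted once, nonsynonymous-if-any (a
conservative rule for a deleteriousness survey; occurrences are logged).
Effect classes (`benign`/`damaging`; absent ⇒ `unknown`) attach only to
nonsynonymous alleles. The pathogenic flag — an allele matching a
`Reported`/`Confirmed` catalogue entry — is cross-cutting: it subdivides by
compartment (coding/tRNA/rRNA) without changing the allele's category.

**Nucleotide diversity.** π is the average per-site proportion of differing
alleles over all within-population sequence pairs. For all sites the package
uses the algebraically identical site-wise form
π = Σ~s~ [1 − Σ~a~ C(c~a~,2)/C(m~s~,2)] / L, which avoids the O(n²)
pairwise pass; with missing data L counts columns with ≥2 called bases and
the site-wise form weights pairs per column rather than per pair (the two
estimators coincide exactly on complete data, which is how the equivalence
is tested). The four-fold class applies the same formula restricted to
columns whose background codon is four-fold degenerate. The synonymous and
nonsynonymous classes use the Nei–Gojobori (1986) method, which is
inherently pairwise: per codon, each position contributes `s/3` synonymous
sites (`s` = single-nucleotide changes preserving the amino acid; changes
creating a stop count as nonsynonymous), and the differences between two
codons are averaged over all orderings of the differing positions, excluding
pathways through stop codons (if all pathways are excluded, all are used
with stop-passing steps counted nonsynonymous — the convention of the
standard desktop implementations). Codons with missing data or a stop in
either sequence are deleted pairwise at codon granularity. π~syn~ is the
across-pair mean of `sd/S` (and π~nonsyn~ of `nd/N`); no multiple-hit
correction is applied because intra-human mitochondrial distances are ≲0.01,
where the correction is far below the reporting precision.

**Standard errors.** The source survey prints ± values without stating their
construction, and we do not attempt to reproduce their magnitudes. This
package states its own: π SEs are a seeded bootstrap over alignment (or
codon) columns, 1000 resamples by default; frequency-table SEs are sample
SD/√k over the k contributing alleles (0 when k = 1, absent — not zero —
when k = 0); burden SEs are SEM across genomes; Monte-Carlo column SEs are
SEM across replicates; ratio SEs use first-order propagation
SE(r) = r·√((s₁/m₁)² + (s₂/m₂)²).

**Monte-Carlo equalisation.** With 401 vs 4057 genomes, frequency summaries
conditioned on segregation are not comparable across samples. The pipeline
therefore re-estimates the larger population's per-category mean minor-allele
frequency on 1000 seeded subsamples of 401 genomes drawn without
replacement, re-calling minor alleles within each subsample (sites
monomorphic in a subsample drop out; `subsample_recall = FALSE` freezes the
pooled catalog instead). The production path operates only on the pooled
polymorphic columns with classification fixed at the pooled background —
this is the same computation as the generic restriction-and-recompute
operator, to which it is equality-tested.

**Tests and ratios.** Group contrasts use the two-sided Mann-Whitney U-test:
exact by full enumeration when n₁+n₂ ≤ 12 without ties, otherwise the normal
approximation with tie and continuity correction (a comparison with zero
rank variance yields p = 1). The survey's tables do not state the
observational unit of their tests, so the package fixes and documents its
own: burden tests compare the per-genome count vectors of the two
populations; frequency tests compare the reference population's per-allele
frequencies against the Monte-Carlo replicate means. Ratio summaries divide
the larger-population value by the smaller-population value; burden ratios
use the full samples, frequency ratios use the Monte-Carlo column as the
numerator — at full sample sizes the pathogenic frequency contrast is
dominated by the sample-size disparity itself, and the equal-sample-size
construction is precisely what the Monte-Carlo column exists for.

## The synthetic study design

The generator emulates the published survey's design, not merely "some"
polymorphism data. Each planted variant belongs to a stratum with
(i) a count of variants, (ii) a per-population *presence* probability
(whether the variant segregates in that population at all) and (iii) a
frequency distribution given presence; carriers are then drawn binomially.
Defaults come from the published tables read jointly:

* counts and presence from the variable-site table — e.g. 2574 synonymous
  sites of which 792 (30.8%) segregate in the African population and 2422
  (94.1%) in the non-African one; 922 benign and 338 damaging nonsynonymous
  sites; 87 pathogenic sites split 55/25/7 by compartment;
* given-presence mean frequencies from the frequency table — African
  synonymous 0.027 vs non-African 0.0040, benign 0.026/0.0042, damaging
  0.0089/0.00082 (severalfold below benign, as published);
* the *product* of the three is the per-genome burden, and the published
  burden table confirms the factorisation: 2574 × 0.308 × 0.027 ≈ 21.4
  (printed 21.5) synonymous minor alleles per African genome,
  2574 × 0.941 × 0.0040 ≈ 9.7 (printed 9.7) per non-African genome, and
  87 × 0.31 × 0.0077 ≈ 0.21 vs 87 × 0.98 × 0.0037 ≈ 0.31 for pathogenic —
  the published tables are mutually consistent under this generative model,
  which is the main reason it was adopted.

Frequencies are Beta-distributed with the stated mean; the shape parameter
sets the skew. For the non-African strata the shape (0.18 for most
categories, 0.15 for damaging) was fixed once, at design time, so that the
conditional mean frequency in a 401-genome subsample lands at the published
Monte-Carlo column magnitudes (≈0.011 from a raw mean of 0.004); this is a
property of the published numbers, not of any test outcome. Catalogued
pathogenic variants use a two-point rare/common mixture in the non-African
population (75% at 5×10⁻⁴, 25% at the value giving the published mean):
ascertained pathogenic variants are mostly rare with a discovered-common
minority, and a smooth heavy-tailed distribution cannot simultaneously match
the published full-sample and subsample means. The African pathogenic
frequencies are tight (Beta shape 10) around the published means. Under the
default `ascertainment = "non-African-only"` knob only variants that
actually segregate in the non-African population enter the catalogue, which
is what produces — and is the package's operational definition of — the
ascertainment-bias signature: pathogenic burden and equal-sample-size
frequency ratios above 1 while every other category sits below 1. The
published pathogenic frequency margin is itself small (0.0084 vs 0.0077), so
the frequency half of the signature is reproduced with a modest, not a
comfortable, margin.

Missing data are sprinkled as `N`s at a rate of 10⁻³ per base (typical of
archival complete-genome submissions), *after* planting; the truth manifest
records counts re-read from the final alignment, so manifest and alignment
cannot disagree. Planted coding categories are verified post hoc with the
pipeline's own classifier against the reference background.

What the generator deliberately does **not** emulate: linkage and haplogroup
structure (variants are planted independently — every statistic in the
survey is site-wise or per-genome-count-wise, so haplotype structure would
add realism but no test power), recurrent mutation, heteroplasmy, indels and
alignment error. Consequently, passing tests demonstrate correctness of the
estimators and of the survey logic under the stated sampling model; they do
not validate robustness to misalignment or to phylogenetic
pseudo-replication in real data. Binomial (rather than hypergeometric)
carrier sampling means realised counts scatter around targets; all recovery
checks therefore compare against *realised* planted truth from the manifest.

## Numerical and engineering choices

* Alignment columns are the coordinate system for everything, 1-based in all
  files (GFF3 convention) and 0-based half-open internally; no rCRS liftover
  is attempted, and how a curated alignment maps catalogue positions through
  indel columns is left to the user's preprocessing.
* The genetic code ships via the Biostrings code tables, selectable by NCBI
  id; NG86 site/difference counting is precomputed once per code as 64 and
  64×64 lookup tables, making the pairwise pass a table scan.
* All randomness (bootstrap, Monte-Carlo, subsampling, generation) flows
  through one seed with fixed offsets, preserving the caller's RNG state;
  a run with the same config and seed is byte-identical.
* The quadratic NG86 diversity pass is capped by `pi_max_genomes` (default
  60 genomes ⇒ 1770 pairs, a seeded subsample per population) — across-pair
  means stabilise well below that, and the cap keeps the per-pair × per-codon
  bootstrap matrices in memory; `pi_boot` (default 1000) controls the
  bootstrap. The default test and acceptance runs use the full 401/4057
  design for counting, frequency and burden statistics, the 60-genome cap
  for NG86 diversity, and 1000×401 Monte-Carlo replicates.
* Degenerate inputs are defined, not accidental: an empty catalogue is
  valid (pathogenic rows report zero), a monomorphic alignment produces
  zero-count tables, a category absent from a population is `NA` (absent)
  rather than 0, zero-denominator percentages and ratios are flagged
  undefined, and a pair with no usable codons yields a flagged undefined
  NG86 estimate.

## Known limitations

Population structure within each label is ignored (the survey treats each
sample as exchangeable); the effect annotation is consumed as ground truth
(the upstream predictor's biases propagate); the site-wise π estimator
weights pairs per column under missing data (documented above). The
continuity-corrected normal approximation of the U-test is accurate to
about 0.006 in the decision-relevant tail (exact two-sided p ≤ 0.2 at
n₁ = n₂ = 6) but deviates by up to ~0.016 from the exact enumeration in the
centre of the null distribution — an intrinsic property of the
approximation, verified by full enumeration in the test suite. And the
three percentage cells of the published variable-site table that do not
re-derive from their own printed counts at one-decimal rounding (African
four-fold 53.0 vs 52.9; damaging 26.7 vs 26.8 and 26.3 vs 26.2) are treated
as printing artefacts and excluded from the internal-consistency check.
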