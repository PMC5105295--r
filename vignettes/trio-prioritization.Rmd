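---
title: "Trio variant prioritization and case-control replication: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio variant prioritization and case-control replication: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioscreen)
```

## The design this package implements

A family in which a phenotype passes from an affected mother to an
affected daughter while the father is unaffected is the smallest unit in
which autosomal-dominant inheritance can be exploited to prioritize
whole-genome variants: the causal allele should be carried (typically
heterozygously) by both affected samples and by neither control. Because
a genome contains millions of variants and the family contributes only
three samples, prioritization is not a test but a cascade of filters,
each encoding one piece of prior knowledge: sequencing confidence,
population frequency, predicted molecular impact, segregation, and
biological plausibility. The handful of survivors is then genotyped in
independent case-control cohorts and assessed with small-sample exact
statistics.

`trioscreen` implements both phases against tabular data: a variant table
(one row per VCF record, with a nested per-sample calls tibble), an
annotation table keyed by `(chrom, pos, ref, alt)`, a pedigree, a
directed gene network with a disease-gene set, and 2×3 genotype count
tables.

## The cascade

Stages run in a fixed order and a variant's trace records stages only up
to the first removal, which makes conservation — every input is either
kept through all five stages or removed at exactly one — directly
testable.

**1. Confidence.** A carrier call is a call with at least one alternate
allele. A group (cases, controls) satisfies the criterion when it has at
least one carrier call with non-missing quality and all such qualities
are ≥ 20 Phred (99 % call accuracy, `phred_accuracy(20)`). The default
rule keeps a variant when *either* group qualifies. An OR here is
unusual — an AND would demand confident observations on both sides — but
it is the rule this cascade design states, so it is the default, with
`quality_group_rule = "all_groups"` as the switch. A group with carrier
calls but no quality information cannot qualify; if neither group has
any usable carrier quality the variant is removed as `"no qualified
call"`. The quality FORMAT key is configurable (default `GQ`) because
call quality is platform-specific; qualities are compared as fractions
of a Phred scale with an inclusive threshold (exactly 20.0 passes, 19.9
does not).

**2. Common variants.** An allele is common when any of the three panel
frequencies is ≥ 0.03 — the boundary is removed, and printed percentages
are compared as fractions. A missing frequency is evidence of absence
from that panel, not of commonness, so it compares as rare; a variant
absent from all three panels (the novel-variant case) passes.

**3. Predicted deleterious.** A disjunction of evidence: a clinical
assertion in {pathogenic, possibly pathogenic, unknown significance}; a
gain-of-function flag (literature, inferred activating, BSIFT); a
microRNA-site flag; a frameshift, in-frame indel, stop change or
structural consequence; a missense not predicted innocuous by SIFT; or a
splice-region change at most 2 bases into the intron. Two missing-value
rules matter. A missense with *no* SIFT score is kept — the criterion is
"not predicted to be innocuous", and no prediction is not a prediction
of innocuousness. A variant with no annotation row at all carries no
evidence and is removed: this stage is keep-on-evidence, unlike stage 2
which is remove-on-evidence.

**4. Genetic model.** Case carriers are counted at the gene level among
the variants that survived stages 1–3: a variant is kept when its gene
accumulates ≥ 2 distinct case samples with a qualifying genotype
(heterozygous, homozygous alternate, two distinct alternates, ambiguous
heterozygous, or hemizygous with the alternate) and the variant itself
is carried by no control. Gene-level counting is what lets compound
heterozygotes — each case carrying a different variant of the same
gene — survive a filter that a per-variant count would fail. Two
genuinely open points were closed as follows. First, "haploinsufficient"
appears in genotype-characteristic lists of this kind although it is a
gene property, not a genotype; since the annotation schema carries no
such flag and the qualifying-genotype list already covers every
alternate-bearing class, the clause is inert here. Second, whether
gene-level counting should consider all variants or only
cascade-surviving ones is ambiguous; counting survivors is used, as it
matches the cascade semantics (a gene's evidence should itself have
survived scrutiny). With exactly two cases, the default thresholds make
the in-sample model fully penetrant: both affected samples must carry.

**5. Biological context.** Keep when the variant's gene is in the
disease-gene set or shares a directed edge with a member, in either
direction (one hop). Self-loops add nothing; variants without a gene
symbol are removed (`"no gene"`).

**Multi-allelic records** are not decomposed — the genotype classes
`heterozygous_alt` and `heterozygous_amb` only exist on them. For the
annotation-driven stages (2, 3) each alternate allele meets its own
annotation row and the record is kept if any alternate passes; a record
is thus retained as long as one of its alleles is a live candidate.

## The synthetic trio

The generator emulates the conditions the cascade is designed for, not a
sequencing instrument. Defaults: 2000 background variants; population
allele frequencies from Beta(0.3, 3) truncated to (0.0005, 0.5), so both
common (≥ 3 %) and rare alleles occur and stage 2 cuts in both
directions; Phred call qualities N(45, 8²) clipped to [0, 99] with a 15 %
fraction re-drawn uniformly below 20, exercising stage 1; panel
frequencies tracking the simulation frequency with log-normal noise and
10 % missingness; consequence classes drawn with missense and synonymous
dominating (35 % and 32 %) and severe classes rare; 10 % of background
genes wired to a small disease-gene set. Parental genotypes are HWE
draws at the population frequency *conditioned on at least one alternate
allele among the four parental copies* — a family variant list only
contains sites called in the family, and the daughter can only inherit
what a parent carries; the daughter receives one uniformly chosen allele
from each parent, which makes Mendelian consistency an invariant rather
than a statistic. The planted variant is a rare frameshift-class
deletion-insertion, heterozygous in mother and daughter, absent from the
father, confidently called, absent from all panels, and inside the
disease-gene set — it survives every stage by construction, and a
contradictory specification (a planted panel frequency at or above the
3 % cutoff) is rejected at generation time. The `penetrance` parameter
(default 1) is the probability that each affected sample carries the
planted allele; below 1 it degrades the dominant pattern and with it the
guaranteed recovery.

What the generator does **not** emulate: linkage disequilibrium between
background variants, per-chromosome length differences (positions are
uniform on a 250 Mb scale), read-level errors (qualities are drawn, not
derived), population structure, and genotyping error in the cohort
tables. Passing the recovery and size properties therefore shows the
cascade and the tests behave correctly under their stated assumptions —
not that they are robust to structure the generator never produces.

One global seed drives a named stream per component (trio, cohort), so
changing `n_background` cannot perturb cohort draws made under the same
seed; identical spec and seed give byte-identical outputs.

## The cohort model and the statistics

Controls are multinomial draws from HWE at allele frequency *p*; case
probabilities are HWE reweighted by (1, γ, γ²) and renormalized — the
standard multiplicative genotype-relative-risk model, chosen because it
is the default single-locus generative model for case-control data. The
study's cohort sizes (109/111, and 73/32 for the smaller cohort) are the
defaults, with *p* = 0.2 as a typical common-variant frequency.

**HWE** uses the χ² goodness of fit with the allele frequency estimated
from the data, hence 1 df, and no continuity correction. Monomorphic
samples return χ² = 0 with a flag rather than an error.

**Exact Fisher tests** enumerate every table with the observed margins —
feasible at cohort scale, where the 2×3 enumeration grid is on the order
of 10⁴ tables — and sum the multivariate-hypergeometric probabilities of
tables no more probable than the observed one. This two-sided
point-probability ("minlike") criterion matches the convention of the
standard R implementation, and ties are accepted within a relative
tolerance of 10⁻⁷ so that equal-probability tables are not dropped to
floating-point jitter. Zero genotype columns are dropped (reducing to a
2×2 or degenerate problem; a single non-zero column gives p = 1). The
allele test collapses each arm to (2·hom-ref + het, 2·hom-alt + het)
first.

**The Armitage trend test** uses scores (0, 1, 2) by default. The
asymptotic mode refers the classical trend χ² to 1 df. The Monte-Carlo
mode permutes case/control labels by sampling, conditional on all
margins, from the multivariate hypergeometric distribution — always
sampling the smaller arm, which makes the draw and hence the p-value at
a fixed seed symmetric under exchanging the two labels — and estimates
p with the add-one estimator (r + 1)/(R + 1), a valid p-value that can
never be zero (its floor is 1/(R + 1)). Tables in which the pooled
sample is concentrated on a single score have no trend variance and
return p = 1 with a `zero_variance` flag.

A consequence worth stating explicitly: the permutation distribution of
the trend statistic is discrete — the statistic is a function of the
integer case score-sum — and the probability atom at the observed value
is O(1/√n). The exact (inclusive) permutation p-value therefore sits
about half an atom above the asymptotic tail, which behaves like a
mid-p. At a few hundred samples this gap is a few percent, far larger
than Monte-Carlo noise at 10⁵ replicates, and it is a property of exact
tests on lattices, not an estimation error; the two modes agree in the
limit, not to Monte-Carlo precision at cohort scale. The same inclusion
of the observed table is what makes the exact Fisher tests conservative,
which the type-I-error suite checks (rejection at or below the binomial
envelope of the nominal 5 %).

## Numerical choices and conventions

* Coordinates are 1-based throughout (VCF convention); no conversions.
* Boundary conventions: quality ≥ 20 passes; panel frequency ≥ 0.03 is
  removed; SIFT ≤ 0.05 is damaging; PROVEAN exactly −2.5 is classified
  neutral — the published binary split (deleterious < −2.5, neutral
  > −2.5) leaves equality undefined, and neutral is the conservative,
  non-deleterious call.
* Codon index is ⌈CDS position/3⌉ of the first affected base; for a
  multi-base change the index refers to where the change begins.
  Deletion-insertions are classified purely by net length (equal →
  substitution; net not divisible by 3 → frameshift; else in-frame).
  Reported residue letters are carried from annotation, never computed —
  that would require transcript sequences. The HGVS parser accepts the
  two forms the reporting needs (`c.NX>Y`, `c.N_MdelXXinsYY`) and
  refuses anything else explicitly.
* The trace records the first failing stage only; `run_cascade()` output
  satisfies `n_removed + n_kept = n_in` per stage and chains across
  stages.
* Missing annotation values are never zeros, and every filter states its
  own missing-value rule (see above).

## Problem sizes in the test suite

The suite validates the exact 2×3 test against a brute-force enumeration
oracle exhaustively for all tables with n ≤ 12 (about 18 000 tables),
checks the test's size on 2000 simulated null cohorts of 109/111, runs
100 seeded trio simulations of 2001 variants for planted-variant
recovery and trace conservation, and compares Monte-Carlo and asymptotic
trend p-values at 10⁵ replicates. These sizes were chosen so each
property is measured where the method is meant to operate — cohort-scale
margins, whole-trio variant lists — while the exhaustive checks stay
exact.

## Limitations

Only the dominant segregation logic ships; recessive, X-linked and
de-novo models are configuration hooks without implementations. The
package consumes predictor scores and clinical assertions as inputs and
never recomputes them. The gene network is a user-supplied edge list; no
curated interaction knowledge base is bundled. No covariate adjustment,
meta-analysis across cohorts, or multiple-testing correction is applied
in replication — raw p-values are reported and flagged at 0.05, exactly
as computed. Principal-component-based checks of population structure
are out of scope; users with stratified cohorts should address structure
before the counts reach this package.
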