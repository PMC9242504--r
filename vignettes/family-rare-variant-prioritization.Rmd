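---
title: "Prioritizing rare variants in a consanguineous multi-disease family"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing rare variants in a consanguineous multi-disease family}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kindred)
```

## The problem

A nuclear family presents with several autoimmune diseases in three members
— the mother and her two sons — while the father and a third sibling are
healthy. The parents are blood relatives, which raises the prior for
recessive inheritance; yet exome-wide, no single gene's variant segregates
under the classical autosomal recessive, autosomal dominant or
compound-heterozygous model in a way that is biologically plausible. The
hypothesis this package operationalizes is *oligogenic* inheritance: the
affected state arises from jointly carrying several rare variants in
several genes, with each affected individual homozygous for at least one
of them.

`kindred` turns that analysis into a reusable, testable pipeline:
multi-sample VCF in, filter cascade, model filters, candidate-set search,
and population co-occurrence frequency out. Because the underlying patient
exomes are not shareable, an equally first-class part of the package is a
gene-drop simulator that can regenerate a faithful synthetic version of the
whole analysis at will.

## The filter cascade

Variants are filtered in a fixed stage order:

1. **quality** — the VCF `FILTER` column (`PASS` or `.` passes; the paper
   trail of upstream callers differs, so this is configurable only in the
   sense that the flag is computed at VCF ingestion);
2. **region** — keep `coding` and `regulatory` variants;
3. **consequence** — keep `missense`, `frameshift`, `inframe_indel` and
   `splice_site`; synonymous changes are dropped *unless* they are splice
   sites, which in this data model simply means the `splice_site` class is
   kept;
4. **frequency** — drop variants with minor allele frequency at or above
   1.5% (`maf_threshold = 0.015`, a fraction of alleles). Under the default
   `any_db_exceeds_excludes` policy one common database entry suffices to
   drop; a variant *absent* from all databases is novel and always
   survives this stage — novelty is evidence of rarity, not of commonness;
5. **predictor** — under the default `require_deleterious` policy a
   variant is kept if at least one available predictor calls it damaging:
   SIFT ≤ 0.05 or FATHMM-MKL ≥ 0.5.

Every stage is a pure predicate on the variant's annotations, so the
surviving *set* is independent of stage order; the per-individual stage
*counts* are not, and follow the order above. Counts tally only variants
the individual actually carries (`het` or `hom_alt`) after the quality
stage, which is why each family member shows different totals.

Two conventions deserve a note. The frequency threshold is a fraction
(0.015 = 1.5%): the example annotations carry sub-percent frequencies near
10⁻² that must survive the cut, which pins down the scale. And the
predictor defaults deliberately encode "keep damaging" (low SIFT, high
FATHMM-MKL retained); an `exclude_benign` policy — drop only when every
available predictor votes tolerated — and an `off` switch are available
for reproducing more literal filter readings.

Missing annotations (`missing_annotation_policy = "keep"` by default) pass
the region, consequence and predictor stages rather than fail them: a
prioritization pipeline should not silently discard a variant because an
annotator had no opinion.

## Segregation models

With affected set $A$ and healthy set $U$ over unphased diploid calls:

* **AR**: $\forall a \in A:\ g_a = \text{hom\_alt}$ and
  $\forall u \in U:\ g_u \ne \text{hom\_alt}$;
* **AD**: $\forall a \in A:\ g_a = \text{het}$ and
  $\forall u \in U:\ g_u = \text{hom\_ref}$;
* **shared rare**: $\forall a \in A:\ g_a \in \{\text{het},
  \text{hom\_alt}\}$ and $\forall u \in U:\ g_u \ne \text{hom\_alt}$.

AR and AD hits are both subsets of the shared-rare hits, which is asserted
property-style in the tests. The **compound-heterozygote** model works on
pairs within one gene: every affected must be `het` for both variants, and
— since phase is discarded at ingestion — trans configuration is inferred
from parents: one variant must be transmissible only from the father
(father carries it, mother `hom_ref`) and the other only from the mother.
When both parents carry one of the variants, cis and trans are both
Mendelian-consistent and the pair is reported only in permissive mode,
flagged ambiguous. Healthy members other than the affecteds' own parents
must not carry both variants of a pair; the parents are exempt since each
necessarily carries one, and their carrying both is exactly the ambiguity
the orientation test adjudicates.

**Missing genotypes** default to a conservative policy: a missing call
fails any affected-side requirement (no-calls must not *create* hits), and
on the healthy side a missing call is never counted as a disqualifying
homozygote except under the strict exclusivity mode below. The alternative
`wildcard` policy lets missing match anything; conservative results are
provably a subset of wildcard results, also tested as a property.

## The multigene candidate-set search

`find_multigene_sets()` enumerates k-subsets of shared-rare survivors in k
distinct genes with:

1. every affected carrying all k variants,
2. every affected homozygous for at least one of them,
3. no healthy member homozygous for any of them.

Condition (3) is the hard rule the analysis states; the observation that
healthy relatives carry "only one or two" of the k variants is implied
rather than required, so it is exposed as the optional
`exclusivity = "strict"` mode (no healthy member may satisfy (1)+(2)
themselves, with missing healthy calls treated pessimistically) rather
than baked into the default. A curated disease-gene list can be supplied
as `gene_panel`; functional-relevance triage is judgment, not computation,
so the package takes the list rather than trying to derive it. All output
is deterministically ordered (gene tuple lexicographically, variants by
gene then position) so runs are byte-reproducible.

The search is validated against brute-force subset enumeration on random
instances with up to 25 survivors — at these sizes $\binom{25}{3} = 2300$
subsets are cheap to enumerate exactly, making the oracle airtight.

## Population co-occurrence frequency

For a candidate set, `joint_cooccurrence()` multiplies per-database allele
frequencies, skipping variants with no entry (novel alleles) under the
default policy, and refusing to report a product over an empty set. This
raw-allele-frequency product is the field's back-of-envelope convention
and reproduces the published style of estimate exactly; the
`carrier = TRUE` mode substitutes the Hardy–Weinberg carrier frequency
$2q(1-q) + q^2$ per locus, which is the statistically better-motivated
probability that one individual carries at least one copy, and is roughly
$2^k$-fold larger for k rare loci. Linkage disequilibrium is ignored — the
example loci lie on chromosomes 2, 3 and 6 — and database frequencies are
treated as point values without sampling error.

## The synthetic-data generator

`simulate_cohort()` emulates, at desk scale, the variant data a family
exome study produces:

* **Pedigree** — the five-member nuclear family; `extended = TRUE` embeds
  it in a minimal consanguineous loop in which the parents are first
  cousins ($\varphi = 1/16$, child $F = 0.0625$). The true ancestral loop
  of any real family is usually deeper and partially unknown; first
  cousins is the smallest embedding consistent with consanguinity, and
  only the inbreeding coefficient it induces matters downstream.
* **Background variants** — `n_background = 5000` by default. Each variant
  draws independent pass/fail labels for the five cascade stages
  (marginal pass rates 0.98, 0.32, 0.40, 0.25, 0.65), and its annotations
  are then constructed to agree with those labels exactly. The joint pass
  rate is ≈ 2% — the survivor share one expects from a rare-missense
  cascade — and the labels make *exact* recovery testable: the cascade
  must keep precisely the all-pass variants, zero tolerance. Population
  frequencies come from a right-skewed Beta(0.3, 8), truncated to the
  rare or common side per the label, with small per-database jitter (and
  15% of rare variants novel in all databases) to exercise the
  frequency-policy options.
* **Genotypes** — gene-dropped through the pedigree at each locus's own
  founder frequency, so every emitted dataset is Mendelian-consistent by
  construction and `verify_mendelian()` doubles as a guard on hand-built
  fixtures. Background variants that would survive the cascade are
  re-dropped (still by gene drop) if their genotype vector would let them
  join a candidate set — carried by every affected, no healthy homozygote
  — so the planted three-gene configuration is the *unique* answer and
  end-to-end runs are deterministic in outcome. For rare founder
  frequencies such collisions are vanishingly unlikely anyway; if one
  survived 100 redraws the variant's quality flag is cleared instead,
  keeping the uniqueness guarantee unconditional.
* **The planted fixture** — `build_family_fixture()` encodes the reference
  trigenic configuration: mother `hom_alt` for the PAK2 (chr3 T>C) and
  PLCL1 (chr2 T>A) variants and `het` for TAP2 (chr6 G>A); sons `het` for
  PAK2/PLCL1 (obligate, from a homozygous mother) and `hom_alt` for TAP2;
  father carrying only TAP2 (`het`). The healthy sibling V.3 is an
  obligate `het` for PAK2 and PLCL1 — a homozygous mother leaves no other
  Mendelian option — and therefore must be `hom_ref` for TAP2 to carry
  no more than two of the three variants; that is the only assignment
  consistent with both the transmission rules and the reported carriage
  pattern of the healthy members.

What the simulator does **not** emulate: sequencing depth and genotype
quality (no read-level error model — `missing` calls are injected, not
generated from coverage), linkage between loci (every locus drops
independently), site-frequency-spectrum realism beyond the Beta shape,
population stratification across the frequency databases, and annotation
error (labels and annotations agree by construction). Passing the
exact-recovery tests therefore demonstrates that the *logic* of the
cascade and the models is correct, not that the pipeline is robust to
noisy real-world annotations.

## Numerical and design choices

* **Kinship** uses the classical recursion
  $\varphi(a,b) = \tfrac12[\varphi(f_a,b) + \varphi(m_a,b)]$ with
  founders unrelated and non-inbred, memoized, recursing through the
  parents of the individual with greater founder depth (which can never
  be an ancestor of the shallower one). It is validated against a
  founder-allele label-drop Monte Carlo on random pedigrees.
* **Multi-allelic VCF sites** are split into one bi-allelic record per
  alternate allele with genotypes recoded against that allele; the total
  non-reference allele count per sample is invariant under the split
  (tested). Phase separators are accepted and ignored; haploid or
  malformed GT entries are coerced to missing with a warning, since the
  pipeline is autosomal-only.
* **Frequency boundary**: "below 1.5%" is implemented as strictly
  `maf < 0.015`; a variant at exactly the threshold is dropped.
* **Determinism**: every simulator draw descends from `sim_config(seed)`;
  file emission is purely deterministic, so fixed-seed runs are
  byte-identical. Tie-breaks in all outputs are lexicographic.
* **Problem sizes** in the validation suite — 20 replicates of 5,000
  labelled variants for exact recovery, 50 random instances of ≤ 25
  survivors for the brute-force equivalence, $10^5$ gene drops for the
  transmission and inbred-homozygosity checks — are chosen so each check
  has either exhaustive coverage or ≥ 3-standard-error resolution while
  the whole suite stays interactive.

## Known limitations

Real per-member stage counts from the original exomes (on the order of
10⁵ variants per sample) cannot be reproduced because those data are not
public; the package substitutes exact-recovery properties on labelled
synthetic cohorts of 5,000 variants, which test the same code paths at a
scale where truth is knowable. X-linked, mitochondrial and de novo models
are out of scope, as are linkage/LOD statistics — the candidate-set search
is a filter, not a significance test, and its output is a shortlist for
functional follow-up, not proof of causality. The intermediate manual step
of a real analysis — curating hundreds of shared-rare survivors down to a
handful by biological relevance — is represented only by the `gene_panel`
hook.
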