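# kindred

Family-based rare-variant prioritization for small disease pedigrees, built
around the situation where the classical single-gene inheritance models fail:
several affected relatives, a consanguineous mating, and no single variant
that segregates cleanly. `kindred` is aimed at analysts working with
multi-sample exome VCFs from such families — it takes a VCF, a PED pedigree
and a variant annotation table, applies a rare-missense filter cascade, tests
the classical segregation models, and then searches for *oligogenic*
candidate sets: combinations of k rare variants in k different genes that
jointly explain the affection pattern.

## The models

For a bi-allelic autosomal variant with unphased calls
(`hom_ref`/`het`/`hom_alt`) in a family with affected set *A* and healthy
set *U*:

* **Autosomal recessive (AR):** every *a* ∈ *A* is `hom_alt`; no *u* ∈ *U*
  is `hom_alt`.
* **Autosomal dominant (AD):** every *a* ∈ *A* is `het`; every *u* ∈ *U* is
  `hom_ref`.
* **Compound heterozygote:** two variants in one gene, every affected `het`
  for both, one variant transmissible only from the father and the other
  only from the mother (origin inferred from parental genotypes, not
  phase), and no healthy sibling carrying both.
* **Shared rare ("complex"):** every *a* ∈ *A* carries the variant (`het`
  or `hom_alt`); no *u* ∈ *U* is `hom_alt`.

The oligogenic search then enumerates k-subsets of shared-rare survivors in
k distinct genes such that (i) every affected carries all k variants,
(ii) every affected is homozygous for **at least one** of them, and (iii) no
healthy member is homozygous for any — the configuration in which each
affected individual has both copies of at least one gene hit while healthy
relatives never do.

For a candidate set found, the expected population frequency of one person
carrying all k variants is the product of their per-database allele
frequencies q₁·q₂·…·q_k (the loci sit on different chromosomes; variants
never observed in a database contribute no factor), with an optional
carrier-frequency mode using 2q(1−q)+q² per locus.

Because real family exome data of this kind cannot be shared, the package
ships a first-class synthetic-data module: a gene-drop simulator (founders
drawn from Hardy–Weinberg at frequency q, each child receiving one random
allele per parent, so an inbred child is `hom_alt` at rate q² + Fq(1−q)),
per-variant truth labels for every cascade stage, a Mendelian-consistency
checker, and a planted three-gene fixture family — an affected mother
homozygous for two of the variants, two affected sons homozygous for the
third, and healthy members never homozygous for any.

## Worked example

Simulate the fixture family plus 1,000 labelled background variants, write
it out as VCF + PED + annotation sidecar, and run the whole pipeline from
the files:

```r
library(kindred)
sim   <- simulate_cohort(config = sim_config(seed = 42, n_background = 1000))
paths <- emit_dataset(sim$ped, sim$gm, "demo")
res   <- run_pipeline(paths[["vcf"]], paths[["ped"]], paths[["ann"]], k = 3)
res$counts
#>   individual total het hom coding_regulatory missense_class rare damaging
#> 1       IV.6   130 123   7                45             13    2        2
#> 2       IV.5   120 110  10                40             13    3        3
#> 3        V.1   119 109  10                38             14    4        4
#> 4        V.2   117 102  15                39             11    3        3
#> 5        V.3   118 110   8                39             11    3        3
res$candidate_sets[[1]]
#> candidate_set: PAK2 + PLCL1 + TAP2
#>                 IV.6      IV.5      V.1       V.2       V.3
#> 3:196782774:T:C "hom_ref" "hom_alt" "het"     "het"     "het"
#> 2:198084920:T:A "hom_ref" "hom_alt" "het"     "het"     "het"
#> 6:32830662:G:A  "het"     "het"     "hom_alt" "hom_alt" "hom_ref"
```

`res$counts` is the per-member accounting through the cascade: how many
variants each individual carries after the quality stage (split het/hom),
and how many of those survive the region, consequence, frequency
(MAF < 1.5%) and predictor stages. The single candidate set is the planted
trigenic configuration: the affected mother IV.5 homozygous for the PAK2
and PLCL1 variants, both affected sons homozygous for TAP2, every affected
carrying all three, and neither healthy member (father IV.6, sibling V.3)
homozygous for any.

Population co-occurrence of the three variants (PAK2 is novel — absent from
all databases — and contributes no factor):

```r
fx <- build_family_fixture()
joint_cooccurrence(fx$freqs, c("PAK2", "TAP2", "PLCL1"), "SHGP")
#> [1] 8e-07
joint_cooccurrence(fx$freqs, c("PAK2", "TAP2", "PLCL1"), "GME")
#> [1] 4e-06
```

Pedigree arithmetic for the consanguineous embedding (parents are first
cousins):

```r
ext <- family_pedigree(extended = TRUE)
kinship(ext, "IV.5", "IV.6")   # 0.0625 = 1/16
inbreeding(ext, "V.1")         # 0.0625
```

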