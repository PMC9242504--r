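test_that("gene drop fixes the degenerate frequencies and is seed-deterministic", {
  ped <- family_pedigree()
  expect_true(all(gene_drop(ped, 0, n = 50, seed = 1) == "hom_ref"))
  expect_true(all(gene_drop(ped, 1, n = 50, seed = 1) == "hom_alt"))
  a <- gene_drop(ped, 0.2, n = 100, seed = 7)
  b <- gene_drop(ped, 0.2, n = 100, seed = 7)
  expect_identical(a, b)
})

test_that("heterozygous parents transmit the alternate allele half the time", {
  trio <- parse_ped(c("F dad 0 0 1 1", "F mom 0 0 2 1", "F kid dad mom 1 1"))
  calls <- gene_drop(trio, 0.5, n = 2e4, seed = 21)
  sel <- calls[, "dad"] == "het" & calls[, "mom"] == "hom_ref"
  kid <- calls[sel, "kid"]
  expect_true(all(kid %in% c("hom_ref", "het")))
  n <- length(kid)
  p_hat <- mean(kid == "het")
  se <- sqrt(0.25 / n)
  expect_lt(abs(p_hat - 0.5), 4 * se)
})

test_that("consanguinity inflates homozygosity by F q (1 - q)", {
  ext <- family_pedigree(extended = TRUE)
  f <- inbreeding(ext, "V.1")
  expect_equal(f, 0.0625)
  q <- 0.2
  calls <- gene_drop(ext, q, n = 2e4, seed = 13)
  p_hom <- mean(calls[, "V.1"] == "hom_alt")
  expected <- q^2 + f * q * (1 - q)
  se <- sqrt(expected * (1 - expected) / 2e4)
  expect_lt(abs(p_hom - expected), 4 * se)
})

test_that("verify_mendelian flags impossible transmissions only", {
  ped <- parse_ped(c("F dad 0 0 1 1", "F mom 0 0 2 1", "F kid dad mom 1 1"))
  ok <- matrix(c("hom_ref", "hom_alt", "het"), 1, 3,
               dimnames = list("v1", c("dad", "mom", "kid")))
  expect_equal(nrow(verify_mendelian(ped, ok)), 0)

  bad <- matrix(c("hom_ref", "hom_ref", "hom_alt"), 1, 3,
                dimnames = list("v1", c("dad", "mom", "kid")))
  viol <- verify_mendelian(ped, bad)
  expect_equal(nrow(viol), 1)
  expect_equal(viol$individual, "kid")

  # a het child of hom_ref x hom_ref parents is also impossible
  bad2 <- matrix(c("hom_ref", "hom_ref", "het"), 1, 3,
                 dimnames = list("v1", c("dad", "mom", "kid")))
  expect_equal(nrow(verify_mendelian(ped, bad2)), 1)

  # a missing call itself constrains nothing...
  m <- matrix(c(NA, "het", "hom_alt"), 1, 3,
              dimnames = list("v1", c("dad", "mom", "kid")))
  expect_equal(nrow(verify_mendelian(ped, m)), 0)
  m2 <- matrix(c("hom_ref", "hom_ref", NA), 1, 3,
               dimnames = list("v1", c("dad", "mom", "kid")))
  expect_equal(nrow(verify_mendelian(ped, m2)), 0)
  # ...but the genotyped parent still does: hom_ref mother cannot yield a
  # hom_alt child whatever the ungenotyped father carried
  m3 <- matrix(c(NA, "hom_ref", "hom_alt"), 1, 3,
               dimnames = list("v1", c("dad", "mom", "kid")))
  expect_equal(nrow(verify_mendelian(ped, m3)), 1)
})

test_that("the family fixture encodes the reported three-gene genotype configuration", {
  fx <- build_family_fixture()
  expect_equal(nrow(verify_mendelian(fx$ped, fx$gm)), 0)

  seg <- segregate(fx$gm, fx$ped)
  expect_true(all(seg$shared_rare))
  expect_false(any(seg$ar))            # mother het TAP2; sons het PAK2/PLCL1
  expect_false(any(seg$ad))

  sets <- find_multigene_sets(fx$gm, fx$ped, k = 3)
  expect_length(sets, 1)
  expect_equal(sets[[1]]$genes, c("PAK2", "PLCL1", "TAP2"))
  zyg <- sets[[1]]$zygosity
  keys <- sets[[1]]$variant_keys
  pak2 <- keys[sets[[1]]$genes == "PAK2"]
  tap2 <- keys[sets[[1]]$genes == "TAP2"]
  plcl1 <- keys[sets[[1]]$genes == "PLCL1"]
  expect_equal(unname(zyg[rownames(zyg) == pak2, "IV.5"]), "hom_alt")
  expect_equal(unname(zyg[rownames(zyg) == plcl1, "IV.5"]), "hom_alt")
  expect_equal(unname(zyg[rownames(zyg) == tap2, "IV.5"]), "het")
  for (son in c("V.1", "V.2")) {
    expect_equal(unname(zyg[rownames(zyg) == tap2, son]), "hom_alt")
    expect_equal(unname(zyg[rownames(zyg) == pak2, son]), "het")
  }
  # every affected is hom for at least one variant
  expect_true(all(lengths(sets[[1]]$hom_coverage) >= 1))

  # healthy sibling: carries at most two of the variants, hom for none
  v3 <- fx$gm$calls[, "V.3"]
  expect_lte(sum(v3 %in% c("het", "hom_alt")), 2)
  expect_false(any(v3 == "hom_alt"))
  # healthy father carries only TAP2
  iv6 <- fx$gm$calls[, "IV.6"]
  expect_equal(sum(iv6 %in% c("het", "hom_alt")), 1)
})

test_that("simulated cohorts are Mendelian, label-consistent and seed-reproducible", {
  cfg <- sim_config(seed = 404, n_background = 500)
  sim <- simulate_cohort(config = cfg)
  expect_equal(nrow(sim$gm$variants), 503)
  expect_equal(nrow(verify_mendelian(sim$ped, sim$gm)), 0)

  # annotations agree with the drawn stage labels, stage by stage
  keep <- apply_cascade(sim$gm)$keep
  for (stage in colnames(keep)) {
    expect_equal(unname(keep[, stage]), sim$truth[[stage]],
                 info = stage)
  }

  sim2 <- simulate_cohort(config = cfg)
  expect_identical(sim$gm$variants, sim2$gm$variants)
  expect_identical(sim$gm$calls, sim2$gm$calls)

  # planting off: background only
  sim0 <- simulate_cohort(config = sim_config(seed = 2, n_background = 50),
                          plant = FALSE)
  expect_equal(nrow(sim0$gm$variants), 50)
  expect_false(any(sim0$truth$planted))
})

test_that("emitted datasets round-trip exactly and are byte-stable", {
  sim <- simulate_cohort(config = sim_config(seed = 31, n_background = 200))
  d1 <- tempfile(); d2 <- tempfile()
  p1 <- emit_dataset(sim$ped, sim$gm, d1, truth = sim$truth)
  p2 <- emit_dataset(sim$ped, sim$gm, d2, truth = sim$truth)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  ped2 <- parse_ped(p1[["ped"]])
  expect_setequal(ped2$members$id, sim$ped$members$id)
  gm2 <- attach_annotations(read_vcf(p1[["vcf"]], ped2), p1[["ann"]])
  m <- match(variant_key(sim$gm$variants), variant_key(gm2$variants))
  expect_false(anyNA(m))
  expect_identical(unname(sim$gm$calls),
                   unname(gm2$calls[m, sim$ped$members$id]))
  expect_equal(sim$gm$variants$maf_SHGP, gm2$variants$maf_SHGP[m])
  expect_equal(sim$gm$variants$qual_pass, gm2$variants$qual_pass[m])

  # a planted-only emission carries just the fixture variants
  fx <- simulate_cohort(config = sim_config(seed = 1, n_background = 0))
  p3 <- emit_dataset(fx$ped, fx$gm, tempfile())
  expect_equal(length(readLines(p3[["vcf"]])) - 5, 3)
})
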