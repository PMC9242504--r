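family5 <- function() family_pedigree()

test_that("single-variant model predicates match truth-table enumeration over all call assignments", {
  ped <- family5()
  samples <- ped$members$id
  states <- c("hom_ref", "het", "hom_alt", NA)
  grid <- expand.grid(rep(list(states), length(samples)),
                      stringsAsFactors = FALSE)
  names(grid) <- samples
  for (policy in c("conservative", "wildcard")) {
    for (i in seq_len(nrow(grid))) {
      calls <- unlist(grid[i, ])
      for (model in c("ar", "ad", "shared_rare")) {
        got <- switch(model,
                      ar = model_ar(calls, ped, policy),
                      ad = model_ad(calls, ped, policy),
                      shared_rare = model_shared_rare(calls, ped, policy))
        want <- oracle_model(calls, ped, model, policy)
        if (!identical(got, want)) {
          fail(sprintf("%s/%s mismatch at [%s]: got %s want %s",
                       model, policy, paste(calls, collapse = ","), got, want))
        }
      }
    }
  }
  succeed()
})

test_that("model definitions behave on the canonical genotype patterns", {
  ped <- family5()
  aff_hom <- c(IV.6 = "het", IV.5 = "hom_alt", V.1 = "hom_alt",
               V.2 = "hom_alt", V.3 = "hom_ref")
  expect_true(model_ar(aff_hom, ped))
  expect_false(model_ar(replace(aff_hom, "V.1", "het"), ped))
  expect_false(model_ar(replace(aff_hom, "V.3", "hom_alt"), ped))

  ad <- c(IV.6 = "hom_ref", IV.5 = "het", V.1 = "het", V.2 = "het",
          V.3 = "hom_ref")
  expect_true(model_ad(ad, ped))
  expect_false(model_ad(replace(ad, "V.3", "het"), ped))
  expect_false(model_ad(replace(ad, "IV.5", "hom_alt"), ped))

  shared <- c(IV.6 = "het", IV.5 = "het", V.1 = "hom_alt", V.2 = "hom_alt",
              V.3 = "hom_ref")
  expect_true(model_shared_rare(shared, ped))
  expect_false(model_shared_rare(replace(shared, "V.3", "hom_alt"), ped))
  expect_false(model_shared_rare(replace(shared, "IV.5", "hom_ref"), ped))
})

test_that("AR and AD hits are always shared-rare hits", {
  ped <- family5()
  set.seed(33)
  calls <- random_calls(400, ped$members$id, p_missing = 0.05)
  for (i in seq_len(nrow(calls))) {
    cc <- calls[i, ]
    if (model_ar(cc, ped)) expect_true(model_shared_rare(cc, ped))
    if (model_ad(cc, ped)) expect_true(model_shared_rare(cc, ped))
  }
})

test_that("compound-het pairs require opposite parental origin and clean healthy members", {
  ped <- family5()
  mk <- function(u, w) {
    v <- data.frame(chrom = "1", pos = c(10L, 20L), ref = "A", alt = "T",
                    gene = "GENE1", stringsAsFactors = FALSE)
    genotype_matrix(v, rbind(u, w), ped$members$id)
  }
  ids <- family5()$members$id  # IV.6 IV.5 V.1 V.2 V.3
  # classic trans pair: u paternal, w maternal (sons affected need het/het;
  # the affected mother has no genotyped parents so she constrains origin
  # only through her own calls)
  u <- c("het", "hom_ref", "het", "het", "het")[match(ids, ids)]
  names(u) <- ids
  u[] <- c(IV.6 = "het", IV.5 = "het", V.1 = "het", V.2 = "het",
           V.3 = "hom_ref")[ids]
  w <- c(IV.6 = "hom_ref", IV.5 = "het", V.1 = "het", V.2 = "het",
         V.3 = "het")[ids]
  # not a valid strict pair: mother carries u herself (she is affected and
  # must be het/het), so origin of u in the sons is ambiguous
  res_strict <- model_comp_het(mk(u, w), ped, policy = "strict")
  res_perm <- model_comp_het(mk(u, w), ped, policy = "permissive")
  expect_equal(nrow(res_strict), 0)
  expect_equal(nrow(res_perm), 1)
  expect_true(res_perm$ambiguous)

  # genotyped unaffected parents with complementary carriage resolve the
  # origin: u transmissible only from the father, w only from the mother
  ped2 <- parse_ped(c(
    "F IV.6 0 0 1 1", "F IV.5 0 0 2 1",
    "F V.1 IV.6 IV.5 1 2", "F V.2 IV.6 IV.5 1 2", "F V.3 IV.6 IV.5 2 1"))
  u_r <- c(IV.6 = "het", IV.5 = "hom_ref", V.1 = "het", V.2 = "het",
           V.3 = "hom_ref")[ids]
  w_r <- c(IV.6 = "hom_ref", IV.5 = "het", V.1 = "het", V.2 = "het",
           V.3 = "het")[ids]
  res2 <- model_comp_het(mk(u_r, w_r), ped2, policy = "strict")
  expect_equal(nrow(res2), 1)
  expect_false(res2$ambiguous)

  # healthy sibling carrying both variants kills the pair
  u2 <- replace(u, "V.3", "het")
  expect_equal(nrow(model_comp_het(mk(u2, w), ped2, policy = "permissive")), 0)

  # both parents het for both variants: cis/trans ambiguous
  u3 <- c(IV.6 = "het", IV.5 = "het", V.1 = "het", V.2 = "het",
          V.3 = "hom_ref")[ids]
  w3 <- u3
  gm3 <- mk(u3, w3)
  gm3$variants$pos <- c(10L, 20L)
  expect_equal(nrow(model_comp_het(gm3, ped2, policy = "strict")), 0)
  amb <- model_comp_het(gm3, ped2, policy = "permissive")
  expect_equal(nrow(amb), 1)
  expect_true(amb$ambiguous)

  # pairs must lie in the same gene
  gm4 <- mk(u, w)
  gm4$variants$gene <- c("GENE1", "GENE2")
  expect_equal(nrow(model_comp_het(gm4, ped2, policy = "permissive")), 0)
})

test_that("multigene search equals brute-force enumeration on random instances", {
  ped <- family5()
  set.seed(77)
  for (rep in 1:10) {
    n <- sample(6:14, 1)
    v <- data.frame(chrom = "1", pos = seq_len(n) * 10L, ref = "A", alt = "T",
                    gene = sprintf("G%02d", sample(seq_len(n - 2), n, TRUE)),
                    stringsAsFactors = FALSE)
    calls <- random_calls(n, ped$members$id, p_missing = 0.03)
    gm <- genotype_matrix(v, calls, ped$members$id)
    k <- sample(2:3, 1)
    got <- find_multigene_sets(gm, ped, k = k)
    got_genes <- lapply(got, function(cs) sort(cs$genes))
    want_genes <- oracle_multigene_genes(gm, ped, k)
    expect_equal(
      sort(vapply(got_genes, paste, character(1), collapse = "|")),
      sort(vapply(want_genes, paste, character(1), collapse = "|")))
  }
})

test_that("multigene search honours gene panels, k bounds and exclusivity", {
  fx <- build_family_fixture()
  expect_length(find_multigene_sets(fx$gm, fx$ped, k = 4), 0)
  expect_length(
    find_multigene_sets(fx$gm, fx$ped, k = 3, gene_panel = c("PAK2", "TAP2")),
    0)
  expect_length(
    find_multigene_sets(fx$gm, fx$ped, k = 3,
                        gene_panel = c("PAK2", "TAP2", "PLCL1")), 1)
  # k = 2: only pairs containing TAP2 give the sons a homozygote
  pairs <- find_multigene_sets(fx$gm, fx$ped, k = 2)
  expect_length(pairs, 2)
  expect_true(all(vapply(pairs, function(cs) "TAP2" %in% cs$genes, logical(1))))
  # strict exclusivity: still one trigenic set (no healthy member carries
  # all three with a homozygote)
  expect_length(find_multigene_sets(fx$gm, fx$ped, k = 3,
                                    exclusivity = "strict"), 1)
})

test_that("conservative missing-genotype policy never finds more than wildcard", {
  ped <- family5()
  set.seed(99)
  for (rep in 1:5) {
    calls <- random_calls(200, ped$members$id, p_missing = 0.15)
    v <- data.frame(chrom = "1", pos = seq_len(200), ref = "A", alt = "T",
                    gene = sprintf("G%03d", seq_len(200)),
                    stringsAsFactors = FALSE)
    gm <- genotype_matrix(v, calls, ped$members$id)
    cons <- segregate(gm, ped, policy = "conservative")
    wild <- segregate(gm, ped, policy = "wildcard")
    for (col in c("ar", "ad", "shared_rare")) {
      expect_true(all(wild[[col]][cons[[col]]]))
    }
  }
})
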