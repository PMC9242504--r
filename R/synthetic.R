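#' @importFrom stats rbinom runif qbeta pbeta setNames
NULL

.members_in_depth_order <- function(ped) {
  ped$members$id[order(ped$depth[ped$members$id])]
}

#' Gene-drop simulation through a pedigree
#'
#' Forward simulation of a single bi-allelic autosomal locus: founder
#' genotypes are drawn from Hardy-Weinberg proportions at alternate-allele
#' frequency `founder_q`, and every non-founder receives one uniformly
#' chosen allele from each parent. Consanguineous loops in the pedigree are
#' what produce the excess homozygosity this models: for an individual with
#' inbreeding coefficient F, the hom_alt rate is `q^2 + F q (1 - q)`.
#'
#' @param ped A [pedigree][parse_ped] (acyclic by construction).
#' @param founder_q Alternate-allele frequency among founders; a vector
#'   simulates one locus per element.
#' @param n Number of loci/replicates (default `length(founder_q)`;
#'   `founder_q` is recycled).
#' @param seed Optional integer seed for reproducibility.
#' @return Character matrix `n` x members of calls
#'   (`hom_ref`/`het`/`hom_alt`).
#' @export
gene_drop <- function(ped, founder_q, n = length(founder_q), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- rep_len(founder_q, n)
  stopifnot(all(q >= 0 & q <= 1))
  mem <- ped$members
  ids <- .members_in_depth_order(ped)
  a1 <- matrix(0L, n, nrow(mem), dimnames = list(NULL, mem$id))
  a2 <- a1
  for (id in ids) {
    i <- match(id, mem$id)
    fa <- mem$father_id[i]; mo <- mem$mother_id[i]
    a1[, id] <- if (is.na(fa)) rbinom(n, 1L, q) else {
      pick <- runif(n) < 0.5
      ifelse(pick, a1[, fa], a2[, fa])
    }
    a2[, id] <- if (is.na(mo)) rbinom(n, 1L, q) else {
      pick <- runif(n) < 0.5
      ifelse(pick, a1[, mo], a2[, mo])
    }
  }
  calls <- matrix(CALL_LEVELS[a1 + a2 + 1L], n, nrow(mem),
                  dimnames = list(NULL, mem$id))
  calls
}

.transmissible <- function(call) {
  switch(call,
         hom_ref = 0L, het = c(0L, 1L), hom_alt = 1L,
         c(0L, 1L))                                    # missing parent
}

#' Check genotype calls for Mendelian consistency
#'
#' Flags every (variant, child) pair whose unphased call is impossible
#' given the parental calls — e.g. hom_ref x hom_ref parents with a het
#' child. A missing parent or child call constrains nothing.
#'
#' @param ped A [pedigree][parse_ped].
#' @param calls Character matrix (variants x individuals) of calls, or a
#'   [genotype_matrix()].
#' @return data.frame of violations with columns `variant`, `individual`,
#'   `call`, `father_call`, `mother_call`; zero rows when consistent.
#' @export
verify_mendelian <- function(ped, calls) {
  if (inherits(calls, "genotype_matrix")) calls <- calls$calls
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1,
                                           dimnames = list(NULL, names(calls)))
  mem <- ped$members
  out <- list()
  dose <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
  for (ci in seq_len(nrow(mem))) {
    id <- mem$id[ci]
    fa <- mem$father_id[ci]; mo <- mem$mother_id[ci]
    if (!id %in% colnames(calls)) next
    if ((is.na(fa) || !fa %in% colnames(calls)) &&
        (is.na(mo) || !mo %in% colnames(calls))) next
    for (vi in seq_len(nrow(calls))) {
      child <- calls[vi, id]
      if (is.na(child)) next
      fcall <- if (!is.na(fa) && fa %in% colnames(calls)) calls[vi, fa] else NA
      mcall <- if (!is.na(mo) && mo %in% colnames(calls)) calls[vi, mo] else NA
      tf <- if (is.na(fcall)) c(0L, 1L) else .transmissible(fcall)
      tm <- if (is.na(mcall)) c(0L, 1L) else .transmissible(mcall)
      possible <- outer(tf, tm, "+")
      if (!dose[[child]] %in% possible) {
        out[[length(out) + 1L]] <- data.frame(
          variant = if (!is.null(rownames(calls))) rownames(calls)[vi] else vi,
          individual = id, call = child,
          father_call = as.character(fcall), mother_call = as.character(mcall),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(variant = character(0), individual = character(0),
                      call = character(0), father_call = character(0),
                      mother_call = character(0)))
  }
  do.call(rbind, out)
}

#' The five-member study family
#'
#' A consanguineous nuclear family with an affected mother (IV.5), two
#' affected sons (V.1, V.2), a healthy father (IV.6) and a healthy sibling
#' (V.3). With `extended = TRUE` the minimal consanguineous embedding is
#' added: the parents IV.5 and IV.6 are first cousins (their fathers are
#' brothers), giving the children an inbreeding coefficient of 1/16. The
#' exact ancestral loop of the real family is not on record; first cousins
#' is the smallest embedding consistent with a consanguineous mating.
#'
#' @param extended Include the two ancestral generations.
#' @return A [pedigree][parse_ped].
#' @export
family_pedigree <- function(extended = FALSE) {
  nuclear <- c(
    "FAM1 IV.6 0 0 1 1",
    "FAM1 IV.5 0 0 2 2",
    "FAM1 V.1 IV.6 IV.5 1 2",
    "FAM1 V.2 IV.6 IV.5 1 2",
    "FAM1 V.3 IV.6 IV.5 2 1")
  if (!extended) return(parse_ped(nuclear))
  parse_ped(c(
    "FAM1 II.1 0 0 1 0",
    "FAM1 II.2 0 0 2 0",
    "FAM1 III.1 II.1 II.2 1 0",
    "FAM1 III.2 0 0 2 0",
    "FAM1 III.3 II.1 II.2 1 0",
    "FAM1 III.4 0 0 2 0",
    "FAM1 IV.5 III.1 III.2 2 2",
    "FAM1 IV.6 III.3 III.4 1 1",
    "FAM1 V.1 IV.6 IV.5 1 2",
    "FAM1 V.2 IV.6 IV.5 1 2",
    "FAM1 V.3 IV.6 IV.5 2 1"))
}

#' Build the three-gene family fixture
#'
#' The reference dataset every pipeline stage can be exercised on: the
#' five-member family with its three rare missense variants, genotyped as
#' reported — the mother homozygous for the PAK2 (chr3, T>C) and PLCL1
#' (chr2, T>A) variants and heterozygous for TAP2 (chr6, G>A); both
#' affected sons heterozygous for PAK2/PLCL1 (obligate, from their
#' homozygous mother) and homozygous for TAP2 (one copy from each carrier
#' parent); the father carrying only TAP2 (het); the healthy sibling an
#' obligate PAK2/PLCL1 heterozygote who drew the reference TAP2 allele
#' from both parents, hence carrying two variants and homozygous for none.
#' The genotype map passes [verify_mendelian()] with zero violations.
#'
#' Two frequency sets circulate for these variants; both are returned. The
#' annotation columns (`maf_SHGP` etc.) carry the per-variant table values
#' used by the filter cascade, while `freqs` carries the narrative values
#' from which the published joint co-occurrence products derive
#' (PLCL1 SHGP 4e-4, TAP2 SHGP 2e-3; GME 2.5e-3 and 1.6e-3). PAK2 is
#' absent from all databases (novel).
#'
#' @return List with `ped` (nuclear [pedigree][parse_ped]), `gm` (annotated
#'   [genotype_matrix()]), and `freqs` (a [frequency_table()] keyed by gene
#'   symbol).
#' @export
build_family_fixture <- function() {
  ped <- family_pedigree()
  variants <- data.frame(
    chrom = c("2", "3", "6"),
    pos = c(198084920L, 196782774L, 32830662L),
    ref = c("T", "T", "G"),
    alt = c("A", "C", "A"),
    gene = c("PLCL1", "PAK2", "TAP2"),
    region = "coding",
    consequence = "missense",
    qual_pass = TRUE,
    maf_SHGP = c(0.0098, NA, 0.0106),
    maf_GME = c(0.0025, NA, 0.0016),
    maf_gnomAD = c(2.04085e-05, NA, 4.148104e-05),
    sift = c(0.01, 0.0, 0.02),
    fathmm_mkl = c(0.96, 0.98, 0.91),
    rsid = c("rs754994541", NA, "rs765178638"),
    cdna = c("c.1403T>A", "c.128T>C", "c.1417G>A"),
    protein_effect = c("p.Phe468Tyr", "p.Val43Ala", "p.Val473Ile"),
    stringsAsFactors = FALSE)
  calls <- rbind(
    PLCL1 = c(IV.6 = "hom_ref", IV.5 = "hom_alt", V.1 = "het",
              V.2 = "het", V.3 = "het"),
    PAK2  = c(IV.6 = "hom_ref", IV.5 = "hom_alt", V.1 = "het",
              V.2 = "het", V.3 = "het"),
    TAP2  = c(IV.6 = "het", IV.5 = "het", V.1 = "hom_alt",
              V.2 = "hom_alt", V.3 = "hom_ref"))
  calls <- calls[, ped$members$id, drop = FALSE]
  gm <- genotype_matrix(variants, calls, ped$members$id)
  freqs <- frequency_table(list(
    PAK2 = stats::setNames(numeric(0), character(0)),
    PLCL1 = c(SHGP = 0.0004, GME = 0.0025, gnomAD = 2.398e-05),
    TAP2 = c(SHGP = 0.002, GME = 0.0016, gnomAD = 4.461e-05)))
  list(ped = ped, gm = gm, freqs = freqs)
}

#' Simulation configuration
#'
#' Controls the synthetic cohort generator. The stage-pass fractions are
#' chosen so that roughly 2% of background variants survive the default
#' rare-missense cascade, the survivor share a desk-scale exome cohort
#' would show after the same prioritization.
#'
#' @param seed Integer seed; every draw the generator makes descends from
#'   it.
#' @param n_background Number of background variants (default 5000).
#' @param maf_beta Shape parameters of the Beta distribution population
#'   allele frequencies are drawn from (default `c(0.3, 8)`: right-skewed,
#'   most mass on rare alleles).
#' @param fraction_quality,fraction_coding,fraction_missense,fraction_rare,fraction_damaging
#'   Marginal probabilities that a background variant passes, respectively,
#'   the quality, region, consequence, frequency and predictor stages.
#' @param fraction_novel Probability that a rare variant is absent from all
#'   frequency databases.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_background = 5000L,
                       maf_beta = c(0.3, 8),
                       fraction_quality = 0.98,
                       fraction_coding = 0.32,
                       fraction_missense = 0.40,
                       fraction_rare = 0.25,
                       fraction_damaging = 0.65,
                       fraction_novel = 0.15) {
  fr <- c(fraction_quality, fraction_coding, fraction_missense,
          fraction_rare, fraction_damaging, fraction_novel)
  stopifnot(all(fr >= 0 & fr <= 1), n_background >= 0,
            length(maf_beta) == 2, all(maf_beta > 0))
  structure(list(seed = as.integer(seed), n_background = as.integer(n_background),
                 maf_beta = maf_beta, fraction_quality = fraction_quality,
                 fraction_coding = fraction_coding,
                 fraction_missense = fraction_missense,
                 fraction_rare = fraction_rare,
                 fraction_damaging = fraction_damaging,
                 fraction_novel = fraction_novel),
            class = "sim_config")
}

# Draw from Beta(a, b) conditioned on q < cut (rare = TRUE) or q >= cut.
.rbeta_cond <- function(n, shape, cut, rare) {
  p_cut <- pbeta(cut, shape[1], shape[2])
  u <- if (rare) runif(n, 0, p_cut) else runif(n, p_cut, 1)
  qbeta(u, shape[1], shape[2])
}

#' Simulate a labelled synthetic cohort for the study family
#'
#' Generates `n_background` background variants with per-variant truth
#' labels for every cascade stage, plus the planted three-gene fixture
#' configuration, and gene-drops genotypes for the background loci through
#' the pedigree at each locus's own founder frequency. Annotations are
#' constructed to agree with the drawn labels exactly, so the filter
#' cascade can be validated against the truth with zero tolerance.
#'
#' Background variants that would survive the cascade are re-dropped (still
#' Mendelian, up to a bounded number of attempts) whenever their genotype
#' vector would let them join a multigene candidate set — carried by every
#' affected with no homozygote among the healthy — so the planted
#' configuration is the unique candidate answer and end-to-end runs are
#' deterministic in outcome, not just in seed.
#'
#' @param ped A [pedigree][parse_ped] (default the nuclear study family).
#' @param config A [sim_config()].
#' @param plant Include the three-gene fixture variants (default `TRUE`).
#' @return List with `gm` (annotated [genotype_matrix()]), `truth`
#'   (data.frame: per-variant stage labels, `cascade_pass`, `planted`), and
#'   `ped`.
#' @export
simulate_cohort <- function(ped = family_pedigree(), config = sim_config(),
                            plant = TRUE) {
  set.seed(config$seed)
  n <- config$n_background
  cut <- 0.015
  shape <- config$maf_beta

  lab <- data.frame(
    quality = runif(n) < config$fraction_quality,
    region = runif(n) < config$fraction_coding,
    consequence = runif(n) < config$fraction_missense,
    maf = runif(n) < config$fraction_rare,
    predictor = runif(n) < config$fraction_damaging)

  region <- ifelse(lab$region,
                   sample(c("coding", "regulatory"), n, TRUE, c(0.85, 0.15)),
                   sample(c("intronic", "intergenic", "upstream", "downstream"),
                          n, TRUE, c(0.55, 0.2, 0.125, 0.125)))
  consequence <- ifelse(lab$consequence,
                        sample(c("missense", "splice_site", "frameshift",
                                 "inframe_indel"), n, TRUE,
                               c(0.8, 0.08, 0.08, 0.04)),
                        sample(c("synonymous", "other"), n, TRUE, c(0.6, 0.4)))

  q_true <- ifelse(lab$maf,
                   .rbeta_cond(n, shape, cut, rare = TRUE),
                   .rbeta_cond(n, shape, cut, rare = FALSE))
  novel <- lab$maf & runif(n) < config$fraction_novel
  jitter_db <- function() {
    f <- pmin(pmax(q_true * runif(n, 0.85, 1.15), 1e-6), 0.999)
    # jitter must not move a frequency across the rarity threshold
    f <- ifelse(lab$maf, pmin(f, cut * 0.999), pmax(f, cut))
    ifelse(novel, NA_real_, f)
  }
  maf_SHGP <- jitter_db(); maf_GME <- jitter_db(); maf_gnomAD <- jitter_db()

  sift <- rep(NA_real_, n); fathmm <- rep(NA_real_, n)
  dmg_via_sift <- runif(n) < 0.5
  sift[lab$predictor & dmg_via_sift] <-
    runif(sum(lab$predictor & dmg_via_sift), 0, 0.05)
  fathmm[lab$predictor & !dmg_via_sift] <-
    runif(sum(lab$predictor & !dmg_via_sift), 0.5, 1)
  sift[!lab$predictor] <- runif(sum(!lab$predictor), 0.06, 1)
  fathmm[!lab$predictor] <- runif(sum(!lab$predictor), 0, 0.49)

  variants <- data.frame(
    chrom = as.character(sample(1:22, n, TRUE)),
    pos = sample.int(2.4e8, n, replace = TRUE),
    ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = rep(NA_character_, n),
    gene = sprintf("BG%05d", seq_len(n)),
    region = region, consequence = consequence,
    qual_pass = lab$quality,
    maf_SHGP = maf_SHGP, maf_GME = maf_GME, maf_gnomAD = maf_gnomAD,
    sift = sift, fathmm_mkl = fathmm,
    rsid = rep(NA_character_, n), cdna = rep(NA_character_, n),
    protein_effect = rep(NA_character_, n),
    stringsAsFactors = FALSE)
  if (n > 0) {
    variants$alt <- vapply(variants$ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), character(1))
    while (anyDuplicated(variant_key(variants))) {
      dup <- duplicated(variant_key(variants))
      variants$pos[dup] <- sample.int(2.4e8, sum(dup), replace = TRUE)
    }
  }

  samples <- ped$members$id
  aff <- affected_ids(ped)
  una <- unaffected_ids(ped)
  calls <- if (n > 0) gene_drop(ped, q_true) else
    matrix(character(0), 0, length(samples), dimnames = list(NULL, samples))
  cascade_pass <- lab$quality & lab$region & lab$consequence &
    lab$maf & lab$predictor
  if (n > 0) {
    joins <- function(cc) {
      all(cc[aff] %in% c("het", "hom_alt")) && !any(cc[una] == "hom_alt")
    }
    for (i in which(cascade_pass)) {
      tries <- 0L
      while (joins(calls[i, ]) && tries < 100L) {
        calls[i, ] <- gene_drop(ped, q_true[i])
        tries <- tries + 1L
      }
      if (joins(calls[i, ])) {
        # essentially unreachable for rare founder frequencies; demote the
        # variant's quality label so the planted answer stays unique
        variants$qual_pass[i] <- FALSE
        lab$quality[i] <- FALSE
        cascade_pass[i] <- FALSE
      }
    }
  }

  truth <- cbind(lab, cascade_pass = cascade_pass,
                 planted = rep(FALSE, n))
  if (plant) {
    fx <- build_family_fixture()
    fx_var <- fx$gm$variants
    variants <- rbind(variants, fx_var[, names(variants)])
    calls <- rbind(calls, fx$gm$calls[, samples, drop = FALSE])
    np <- nrow(fx_var)
    truth <- rbind(truth, data.frame(
      quality = rep(TRUE, np), region = TRUE, consequence = TRUE, maf = TRUE,
      predictor = TRUE, cascade_pass = TRUE, planted = TRUE))
  }
  rownames(variants) <- NULL
  gm <- genotype_matrix(variants, calls, samples)
  truth$key <- variant_key(variants)
  list(gm = gm, truth = truth, ped = ped)
}

#' Write a simulated dataset as VCF + sidecar TSV + PED
#'
#' Emits a minimal valid VCF v4.2 (GT-only FORMAT, FILTER `PASS`/`q10`
#' from `qual_pass`), the annotation sidecar keyed on chrom/pos/ref/alt,
#' and a 6-column PED. Writing is purely deterministic, so a dataset
#' generated at a fixed seed emits byte-identical files on every run.
#' Round-tripping through [read_vcf()] + [attach_annotations()] preserves
#' every genotype call and annotation.
#'
#' @param ped A [pedigree][parse_ped].
#' @param gm A [genotype_matrix()] over the pedigree members.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix (default `"sim"`).
#' @param truth Optional truth data.frame to write as `<prefix>.truth.tsv`.
#' @return Named character vector of the paths written, invisibly.
#' @export
emit_dataset <- function(ped, gm, dir, prefix = "sim", truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  v <- gm$variants
  ord <- order(suppressWarnings(as.integer(v$chrom)), v$chrom, v$pos, v$alt)
  v <- v[ord, , drop = FALSE]
  calls <- gm$calls[ord, , drop = FALSE]

  vcf_path <- file.path(dir, paste0(prefix, ".vcf"))
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  gt <- matrix(gt_code[calls], nrow(calls), ncol(calls))
  gt[is.na(gt)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=kindred-simulator",
    "##FILTER=<ID=q10,Description=\"Below quality threshold\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t"))
  body <- paste(v$chrom, v$pos, ifelse(is.na(v$rsid), ".", v$rsid),
                v$ref, v$alt, ".",
                ifelse(v$qual_pass, "PASS", "q10"), ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)

  ann_path <- file.path(dir, paste0(prefix, ".ann.tsv"))
  ann_cols <- c("chrom", "pos", "ref", "alt", "gene", "region", "consequence",
                grep("^maf_", names(v), value = TRUE), "sift", "fathmm_mkl",
                "rsid", "cdna", "protein_effect")
  ann_cols <- ann_cols[ann_cols %in% names(v)]
  write.table(v[, ann_cols], ann_path, sep = "\t", quote = FALSE,
              row.names = FALSE)

  ped_path <- file.path(dir, paste0(prefix, ".ped"))
  m <- ped$members
  sex_code <- c(male = "1", female = "2", unknown = "0")
  st_code <- c(affected = "2", unaffected = "1", unknown = "0")
  writeLines(paste("FAM1", m$id,
                   ifelse(is.na(m$father_id), "0", m$father_id),
                   ifelse(is.na(m$mother_id), "0", m$mother_id),
                   sex_code[m$sex], st_code[m$status]),
             ped_path)

  paths <- c(vcf = vcf_path, ann = ann_path, ped = ped_path)
  if (!is.null(truth)) {
    truth_path <- file.path(dir, paste0(prefix, ".truth.tsv"))
    write.table(truth[ord, , drop = FALSE], truth_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}
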