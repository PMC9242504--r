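#' @importFrom utils read.delim write.table
NULL

REGION_LEVELS <- c("coding", "regulatory", "intronic", "intergenic",
                   "upstream", "downstream", "unknown")
CONSEQUENCE_LEVELS <- c("missense", "synonymous", "splice_site", "frameshift",
                        "inframe_indel", "other")
CALL_LEVELS <- c("hom_ref", "het", "hom_alt")

#' Construct a genotype matrix
#'
#' The central container of the pipeline: one row per normalized bi-allelic
#' variant, one column per genotyped individual, with unphased diploid calls
#' `hom_ref`, `het`, `hom_alt`, or `NA` for missing.
#'
#' @param variants data.frame with at least `chrom`, `pos`, `ref`, `alt`;
#'   annotation columns (`gene`, `region`, `consequence`, `qual_pass`,
#'   `sift`, `fathmm_mkl`, `rsid`, `maf_<db>`...) are added by
#'   [attach_annotations()] or may be supplied directly.
#' @param calls character matrix, `nrow(variants)` x `length(samples)`,
#'   values in `hom_ref`/`het`/`hom_alt` or `NA`.
#' @param samples character vector of individual ids (column order of
#'   `calls`).
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(variants, calls, samples) {
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt") %in% names(variants)))
  calls <- as.matrix(calls)
  if (nrow(calls) != nrow(variants) || ncol(calls) != length(samples)) {
    stop("calls dimensions inconsistent with variants/samples")
  }
  bad <- !is.na(calls) & !calls %in% CALL_LEVELS
  if (any(bad)) stop("invalid genotype call: ", calls[bad][1])
  if (any(variants$pos < 1)) stop("variant position must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref and alt alleles identical")
  for (col in c("gene", "rsid")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_character_
  }
  if (!"region" %in% names(variants)) variants$region <- "unknown"
  if (!"consequence" %in% names(variants)) variants$consequence <- NA_character_
  if (!"qual_pass" %in% names(variants)) variants$qual_pass <- TRUE
  for (col in c("sift", "fathmm_mkl")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_real_
  }
  dimnames(calls) <- list(variant_key(variants), samples)
  structure(list(variants = variants, calls = calls, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  invisible(x)
}

#' Canonical variant key
#'
#' @param variants data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @return `chrom:pos:ref:alt` strings.
#' @export
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses a VCF v4.x file (via \pkg{vcfR}), restricts and orders the sample
#' columns to the pedigree members, splits multi-allelic sites into one
#' bi-allelic record per alternate allele (genotypes recoded against that
#' alt), and maps GT strings to unphased zygosity calls. Phase separators
#' (`|`) are treated as unphased; `./.` and malformed or haploid GT entries
#' become missing calls (the latter with a warning, as the pipeline is
#' autosomal-only). The VCF FILTER column populates `qual_pass`
#' (`PASS` or `.` passes).
#'
#' @param file Path to a VCF file (plain or bgzipped).
#' @param ped A [pedigree][parse_ped]; every member must be present in the
#'   VCF sample header.
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(file, ped) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  vcf_samples <- colnames(v@gt)[-1]
  absent <- setdiff(ped$members$id, vcf_samples)
  if (length(absent)) {
    stop("pedigree member(s) absent from VCF: ", paste(absent, collapse = ", "))
  }
  samples <- ped$members$id
  gt_raw <- gt_raw[, samples, drop = FALSE]
  qual_pass <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")

  out_var <- list()
  out_calls <- list()
  n_warn <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    alleles <- lapply(gt_raw[i, ], function(g) {
      if (is.na(g)) return(NULL)
      a <- strsplit(g, "[/|]")[[1]]
      if (length(a) != 2L || !all(grepl("^([0-9]+|\\.)$", a))) return(NA)
      a
    })
    for (k in seq_along(alts)) {
      calls <- vapply(alleles, function(a) {
        if (is.null(a)) return(NA_character_)               # ./.
        if (length(a) == 1L && is.na(a)) {
          n_warn <<- n_warn + 1L                            # malformed/haploid
          return(NA_character_)
        }
        if (any(a == ".")) return(NA_character_)
        CALL_LEVELS[sum(a == as.character(k)) + 1L]
      }, character(1))
      out_var[[length(out_var) + 1L]] <- data.frame(
        chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k], qual_pass = qual_pass[i],
        stringsAsFactors = FALSE)
      out_calls[[length(out_calls) + 1L]] <- calls
    }
  }
  if (n_warn > 0L) {
    warning(n_warn, " malformed or haploid GT entr",
            if (n_warn == 1L) "y" else "ies", " coerced to missing")
  }
  variants <- do.call(rbind, out_var)
  calls <- do.call(rbind, out_calls)
  genotype_matrix(variants, calls, samples)
}

#' Attach a variant annotation table to a genotype matrix
#'
#' The sidecar is keyed on `chrom`, `pos`, `ref`, `alt` and supplies `gene`,
#' `region`, `consequence`, per-database allele frequencies (`maf_<db>`
#' columns, e.g. `maf_SHGP`), predictor scores (`sift`, `fathmm_mkl`) and
#' optionally `rsid`, `cdna`, `protein_effect`. Variants with no matching
#' sidecar row carry absent annotations; how those are filtered is decided
#' by the filter configuration, not here. Absent frequency means "not
#' observed in that database" (a novel allele), never zero.
#'
#' @param gm A [genotype_matrix()].
#' @param ann data.frame or path to a TSV sidecar.
#' @return The genotype matrix with annotation columns filled in.
#' @export
attach_annotations <- function(gm, ann) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.character(ann)) {
    ann <- read.delim(ann, stringsAsFactors = FALSE,
                      na.strings = c("NA", "", "Novel", "."))
  }
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  }
  maf_cols <- grep("^maf_", names(ann), value = TRUE)
  for (col in maf_cols) {
    bad <- which(!is.na(ann[[col]]) & (ann[[col]] < 0 | ann[[col]] > 1))
    if (length(bad)) {
      stop("frequency outside [0,1] in column ", col, ", row ", bad[1])
    }
  }
  for (col in c("sift", "fathmm_mkl")) {
    if (col %in% names(ann)) {
      bad <- which(!is.na(ann[[col]]) & (ann[[col]] < 0 | ann[[col]] > 1))
      if (length(bad)) stop("score outside [0,1] in column ", col, ", row ", bad[1])
    }
  }
  if ("region" %in% names(ann)) {
    bad <- which(!is.na(ann$region) & !ann$region %in% REGION_LEVELS)
    if (length(bad)) stop("unknown region class '", ann$region[bad[1]],
                          "' in annotation row ", bad[1])
  }
  if ("consequence" %in% names(ann)) {
    bad <- which(!is.na(ann$consequence) & !ann$consequence %in% CONSEQUENCE_LEVELS)
    if (length(bad)) stop("unknown consequence class '", ann$consequence[bad[1]],
                          "' in annotation row ", bad[1])
  }
  idx <- match(variant_key(gm$variants), variant_key(ann))
  copy_cols <- setdiff(names(ann), need)
  for (col in copy_cols) {
    gm$variants[[col]] <- ann[[col]][idx]
  }
  if ("region" %in% copy_cols) {
    gm$variants$region[is.na(gm$variants$region)] <- "unknown"
  }
  gm
}

#' Frequency-database columns present on a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Database names (the `<db>` part of `maf_<db>` columns).
#' @export
maf_databases <- function(gm) {
  sub("^maf_", "", grep("^maf_", names(gm$variants), value = TRUE))
}

#' Subset a genotype matrix by variant index
#'
#' @param gm A [genotype_matrix()].
#' @param i Logical or integer index over variants.
#' @return The subsetted genotype matrix.
#' @export
subset_variants <- function(gm, i) {
  genotype_matrix(gm$variants[i, , drop = FALSE],
                  gm$calls[i, , drop = FALSE],
                  gm$samples)
}

#' Write a candidate variant report table
#'
#' One row per candidate variant with gene, genomic location
#' (`chrom-pos`), cDNA change, effect, protein effect, rsid, the SHGP, GME
#' and gnomAD allele frequencies, and one zygosity column per sample.
#' Absent frequencies and rsids print as `"Novel"`.
#'
#' @param candidates A list of [candidate_set][find_multigene_sets] objects,
#'   or a [genotype_matrix()] whose variants should all be reported.
#' @param path Output TSV path.
#' @return The report data.frame, invisibly.
#' @export
write_candidate_table <- function(candidates, path) {
  if (inherits(candidates, "genotype_matrix")) {
    gm <- candidates
  } else if (length(candidates) == 0L) {
    hdr <- c("gene", "genomic_location", "cdna", "effect", "protein_effect",
             "rsid", "maf_SHGP", "maf_GME", "maf_gnomAD")
    df <- as.data.frame(setNames(rep(list(character(0)), length(hdr)), hdr))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(df))
  } else {
    gm <- candidates[[1]]$matrix
    keys <- unique(unlist(lapply(candidates, function(cs) cs$variant_keys)))
    gm <- subset_variants(gm, variant_key(gm$variants) %in% keys)
  }
  v <- gm$variants
  novel <- function(x) ifelse(is.na(x), "Novel", as.character(x))
  grab <- function(col) if (col %in% names(v)) v[[col]] else rep(NA, nrow(v))
  df <- data.frame(
    gene = novel(v$gene),
    genomic_location = paste(v$chrom, v$pos, sep = "-"),
    cdna = novel(grab("cdna")),
    effect = novel(v$consequence),
    protein_effect = novel(grab("protein_effect")),
    rsid = novel(v$rsid),
    maf_SHGP = novel(grab("maf_SHGP")),
    maf_GME = novel(grab("maf_GME")),
    maf_gnomAD = novel(grab("maf_gnomAD")),
    stringsAsFactors = FALSE, check.names = FALSE)
  zyg <- gm$calls
  zyg[is.na(zyg)] <- "missing"
  df <- cbind(df, as.data.frame(zyg, stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
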