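#' Build a per-database allele frequency table
#'
#' @param entries Named list: variant label -> named numeric vector of
#'   allele frequencies keyed by database name. A variant with no entry for
#'   a database is "not observed" there (novel), which is distinct from
#'   frequency zero.
#' @return A `frequency_table` object.
#' @export
#' @examples
#' ft <- frequency_table(list(
#'   PLCL1 = c(SHGP = 0.0004, GME = 0.0025),
#'   TAP2  = c(SHGP = 0.002,  GME = 0.0016),
#'   PAK2  = c()
#' ))
#' joint_cooccurrence(ft, c("PAK2", "TAP2", "PLCL1"), "SHGP")
frequency_table <- function(entries) {
  stopifnot(is.list(entries), !is.null(names(entries)))
  for (nm in names(entries)) {
    f <- entries[[nm]]
    if (length(f) && (any(f < 0) || any(f > 1))) {
      stop("allele frequency outside [0,1] for ", nm)
    }
  }
  structure(list(entries = entries), class = "frequency_table")
}

#' Frequency table from an annotated genotype matrix
#'
#' Collects the `maf_<db>` columns of the variant table into a
#' [frequency_table()], keyed by gene symbol (falling back to the variant
#' key where the gene is absent).
#'
#' @param gm An annotated [genotype_matrix()].
#' @return A `frequency_table`.
#' @export
frequency_table_from_matrix <- function(gm) {
  v <- gm$variants
  dbs <- maf_databases(gm)
  labels <- ifelse(is.na(v$gene), variant_key(v), v$gene)
  entries <- lapply(seq_len(nrow(v)), function(i) {
    f <- vapply(dbs, function(db) v[[paste0("maf_", db)]][i], numeric(1))
    f[!is.na(f)]
  })
  names(entries) <- labels
  frequency_table(entries)
}

#' Joint co-occurrence frequency of a variant set
#'
#' The expected population frequency of one individual carrying all the
#' listed variants together, taken as the product of their allele
#' frequencies in one database — the loci sit on different chromosomes, so
#' independence is assumed. Variants with no entry in the database (novel
#' alleles) contribute no factor under `novel_policy = "skip"`; under
#' `"zero"` the joint frequency is 0, the strict reading that an allele
#' never observed in the database has frequency indistinguishable from
#' zero. If no variant in the set has an entry the product would be empty,
#' which is an error rather than a misleading 1.
#'
#' This multiplies raw allele frequencies. `carrier = TRUE` switches to the
#' Hardy-Weinberg carrier frequency `2q(1-q) + q^2` per variant, the
#' probability that an individual holds at least one copy — statistically
#' the more defensible estimate of co-carriage, at roughly double the raw
#' product for rare alleles.
#'
#' @param ft A [frequency_table()].
#' @param variants Variant labels (nonempty).
#' @param db Database name.
#' @param novel_policy `"skip"` (default) or `"zero"`.
#' @param carrier Multiply carrier frequencies instead of allele
#'   frequencies.
#' @return Joint frequency in `[0, 1]`.
#' @export
joint_cooccurrence <- function(ft, variants, db,
                               novel_policy = c("skip", "zero"),
                               carrier = FALSE) {
  novel_policy <- match.arg(novel_policy)
  stopifnot(inherits(ft, "frequency_table"), length(variants) > 0)
  unknown <- setdiff(variants, names(ft$entries))
  if (length(unknown)) stop("variant not in frequency table: ", unknown[1])
  q <- vapply(variants, function(v) {
    f <- ft$entries[[v]]
    if (db %in% names(f)) f[[db]] else NA_real_
  }, numeric(1))
  if (all(is.na(q))) {
    stop("no variant in the set has a frequency entry in database ", db)
  }
  if (novel_policy == "zero" && anyNA(q)) return(0)
  q <- q[!is.na(q)]
  if (carrier) q <- 2 * q * (1 - q) + q^2
  prod(q)
}

#' Hardy-Weinberg genotype frequencies
#'
#' For alternate-allele frequency `q`, returns the genotype frequencies
#' `((1-q)^2, 2q(1-q), q^2)`. This is the founder genotype model of the
#' gene-drop simulator.
#'
#' @param q Allele frequency in `[0, 1]` (vectorized).
#' @return Matrix with columns `hom_ref`, `het`, `hom_alt`; one row per
#'   element of `q`. Rows sum to 1.
#' @export
hwe_genotype_freqs <- function(q) {
  if (any(q < 0 | q > 1)) stop("allele frequency must be in [0, 1]")
  cbind(hom_ref = (1 - q)^2, het = 2 * q * (1 - q), hom_alt = q^2)
}
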