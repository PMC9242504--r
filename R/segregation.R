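#' @name segregation-models
#' @title Inheritance-model segregation filters
#'
#' @description
#' Single-variant predicates over the family's genotype calls:
#'
#' * **AR** (autosomal recessive): every affected individual is homozygous
#'   for the alternate allele; every unaffected member is a heterozygous
#'   carrier or homozygous reference.
#' * **AD** (autosomal dominant): every affected individual carries exactly
#'   one copy; the variant is absent from every unaffected member.
#' * **shared rare** ("complex"): every affected individual carries the
#'   variant (het or hom_alt) and no unaffected member is homozygous for it.
#'   This is the relaxation under which oligogenic candidate sets are
#'   searched ([find_multigene_sets()]).
#'
#' Every AR hit and every AD hit is also a shared-rare hit.
#'
#' Missing genotypes are handled per `policy`: `"conservative"` (default)
#' fails any affected-side requirement on a missing call, so prioritization
#' is never driven by no-calls; `"wildcard"` lets a missing call satisfy any
#' requirement. On the unaffected side a missing call is never treated as a
#' disqualifying homozygote under either policy (see the `exclusivity`
#' argument of [find_multigene_sets()] for the stricter reading).
#'
#' @param calls Named character vector of calls (`hom_ref`/`het`/`hom_alt`/
#'   `NA`) covering the pedigree members with genotype data, or a one-row
#'   slice of a [genotype_matrix()]'s `calls`.
#' @param ped A [pedigree][parse_ped].
#' @param policy Missing-genotype policy: `"conservative"` or `"wildcard"`.
#' @return `TRUE` if the variant segregates under the model.
NULL

.split_calls <- function(calls, ped) {
  aff <- intersect(affected_ids(ped), names(calls))
  una <- intersect(unaffected_ids(ped), names(calls))
  list(aff = calls[aff], una = calls[una])
}

.aff_ok <- function(calls, allowed, policy) {
  ifelse(is.na(calls), policy == "wildcard", calls %in% allowed)
}

#' @rdname segregation-models
#' @export
model_ar <- function(calls, ped, policy = c("conservative", "wildcard")) {
  policy <- match.arg(policy)
  s <- .split_calls(calls, ped)
  all(.aff_ok(s$aff, "hom_alt", policy)) &&
    !any(s$una == "hom_alt", na.rm = TRUE)
}

#' @rdname segregation-models
#' @export
model_ad <- function(calls, ped, policy = c("conservative", "wildcard")) {
  policy <- match.arg(policy)
  s <- .split_calls(calls, ped)
  all(.aff_ok(s$aff, "het", policy)) &&
    !any(s$una %in% c("het", "hom_alt"), na.rm = TRUE)
}

#' @rdname segregation-models
#' @export
model_shared_rare <- function(calls, ped,
                              policy = c("conservative", "wildcard")) {
  policy <- match.arg(policy)
  s <- .split_calls(calls, ped)
  all(.aff_ok(s$aff, c("het", "hom_alt"), policy)) &&
    !any(s$una == "hom_alt", na.rm = TRUE)
}

.carries <- function(call) !is.na(call) & call %in% c("het", "hom_alt")

#' Compound-heterozygote pairs within one gene
#'
#' Searches all unordered pairs of variants in a single gene for the
#' compound-heterozygous pattern: every affected individual heterozygous for
#' both variants, the two variants arriving one from each parent, and no
#' unaffected member carrying both. Parents of an affected individual are
#' exempt from that last rule: each necessarily carries one of the pair,
#' and a parent carrying both is the cis/trans-ambiguous situation handled
#' by the orientation test rather than grounds for rejection — the rule
#' screens out healthy siblings and other relatives who hold the same two
#' variants without disease. Because the genotype model is unphased,
#' parental origin is inferred from parental genotypes rather than phase:
#' for each affected individual whose parents are genotyped, one variant
#' must be transmissible only from the father (father carries it, mother is
#' hom_ref) and the other only from the mother. When both parents carry one
#' of the variants the cis/trans configuration is ambiguous, and the pair is
#' reported only under `policy = "permissive"`, flagged `ambiguous`.
#' Families with no genotyped parent pair for any affected can likewise only
#' yield permissive-mode flagged pairs.
#'
#' @param gm A [genotype_matrix()] restricted to (or containing) the gene's
#'   variants; pairs are formed within each gene symbol.
#' @param ped A [pedigree][parse_ped].
#' @param gene Optional single gene symbol to restrict to.
#' @param policy `"strict"` (default) or `"permissive"`.
#' @return data.frame with one row per pair: `gene`, `variant_a`,
#'   `variant_b` (keys, lexicographic order), `ambiguous`.
#' @export
model_comp_het <- function(gm, ped, gene = NULL,
                           policy = c("strict", "permissive")) {
  policy <- match.arg(policy)
  v <- gm$variants
  genes <- if (is.null(gene)) unique(stats::na.omit(v$gene)) else gene
  aff <- intersect(affected_ids(ped), gm$samples)
  mem <- ped$members
  aff_parents <- stats::na.omit(c(mem$father_id[mem$id %in% aff],
                                  mem$mother_id[mem$id %in% aff]))
  una <- setdiff(intersect(unaffected_ids(ped), gm$samples), aff_parents)
  out <- list()
  for (g in sort(genes)) {
    idx <- which(!is.na(v$gene) & v$gene == g)
    if (length(idx) < 2L) next
    keys <- variant_key(v[idx, , drop = FALSE])
    for (a in seq_along(idx)[-length(idx)]) for (b in (a + 1):length(idx)) {
      ca <- gm$calls[idx[a], ]
      cb <- gm$calls[idx[b], ]
      if (!isTRUE(all(ca[aff] == "het")) ||
          !isTRUE(all(cb[aff] == "het"))) next
      if (any(.carries(ca[una]) & .carries(cb[una]))) next
      # orientation test at each affected with both parents genotyped:
      # resolved if one variant can only be paternal and the other only
      # maternal; ambiguous if transmission is possible but unresolvable
      # (e.g. both parents carry a variant); impossible if no genotyped
      # parent could have transmitted a variant the child holds
      status <- "none"
      for (ind in aff) {
        i <- match(ind, mem$id)
        fa <- mem$father_id[i]; mo <- mem$mother_id[i]
        if (is.na(fa) || is.na(mo) ||
            !fa %in% gm$samples || !mo %in% gm$samples) next
        orient <- function(pat, mat) {
          .carries(pat[fa]) && identical(unname(pat[mo]), "hom_ref") &&
          .carries(mat[mo]) && identical(unname(mat[fa]), "hom_ref")
        }
        if (orient(ca, cb) || orient(cb, ca)) {
          status <- "resolved"
        } else {
          plausible <- (.carries(ca[fa]) || .carries(ca[mo])) &&
                       (.carries(cb[fa]) || .carries(cb[mo]))
          if (!plausible) { status <- "impossible"; break }
          if (status == "none") status <- "ambiguous"
        }
      }
      if (status == "impossible") next
      ambiguous <- status != "resolved"
      if (ambiguous && policy == "strict") next
      out[[length(out) + 1L]] <- data.frame(
        gene = g,
        variant_a = min(keys[a], keys[b]),
        variant_b = max(keys[a], keys[b]),
        ambiguous = ambiguous, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene = character(0), variant_a = character(0),
                      variant_b = character(0), ambiguous = logical(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$gene, res$variant_a, res$variant_b), , drop = FALSE]
}

#' Run all single-variant segregation models over a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param ped A [pedigree][parse_ped].
#' @param policy Missing-genotype policy (see [segregation-models]).
#' @return data.frame with one row per variant and logical columns `ar`,
#'   `ad`, `shared_rare`.
#' @export
segregate <- function(gm, ped, policy = c("conservative", "wildcard")) {
  policy <- match.arg(policy)
  n <- nrow(gm$variants)
  res <- data.frame(
    key = variant_key(gm$variants),
    ar = logical(n), ad = logical(n), shared_rare = logical(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    calls <- gm$calls[i, ]
    res$ar[i] <- model_ar(calls, ped, policy)
    res$ad[i] <- model_ad(calls, ped, policy)
    res$shared_rare[i] <- model_shared_rare(calls, ped, policy)
  }
  res
}

#' Search for k-gene candidate sets under the complex-inheritance rule
#'
#' Enumerates k-subsets of shared-rare survivor variants lying in k distinct
#' genes such that (i) every affected individual carries all k variants
#' (het or hom_alt), (ii) every affected individual is homozygous for at
#' least one of them, and (iii) no unaffected member is homozygous for any
#' of them. Under `exclusivity = "strict"`, additionally no unaffected
#' member may satisfy (i) and (ii) themselves — the full causal genotype
#' configuration must be private to the affected — and a missing unaffected
#' call is conservatively treated as a potential homozygote.
#'
#' Input variants not passing [model_shared_rare()] are removed before the
#' search. Output order is deterministic: candidate sets sorted by their
#' gene tuple, variants within a set by gene then position.
#'
#' @param gm A [genotype_matrix()] of cascade survivors.
#' @param ped A [pedigree][parse_ped].
#' @param k Set size (>= 2).
#' @param gene_panel Optional character vector; all k genes must belong to
#'   it. This is the hook for curated disease-relevance gene lists.
#' @param exclusivity `"stated"` (default: rule (iii) only) or `"strict"`.
#' @param policy Missing-genotype policy for the shared-rare pre-filter.
#' @return A list of `candidate_set` objects, each with `genes`,
#'   `variant_keys`, `hom_coverage` (affected id -> variant keys held
#'   hom_alt), `zygosity` (call matrix), and `matrix` (the k-variant
#'   genotype matrix).
#' @export
find_multigene_sets <- function(gm, ped, k = 3, gene_panel = NULL,
                                exclusivity = c("stated", "strict"),
                                policy = c("conservative", "wildcard")) {
  exclusivity <- match.arg(exclusivity)
  policy <- match.arg(policy)
  stopifnot(k >= 2)
  seg <- segregate(gm, ped, policy)
  gm <- subset_variants(gm, seg$shared_rare)
  v <- gm$variants
  keep <- !is.na(v$gene)
  if (!is.null(gene_panel)) keep <- keep & v$gene %in% gene_panel
  gm <- subset_variants(gm, keep)
  v <- gm$variants
  if (length(unique(v$gene)) < k) return(list())

  aff <- intersect(affected_ids(ped), gm$samples)
  una <- intersect(unaffected_ids(ped), gm$samples)
  calls <- gm$calls
  n <- nrow(v)
  combs <- utils::combn(n, k, simplify = FALSE)
  out <- list()
  for (idx in combs) {
    if (anyDuplicated(v$gene[idx])) next
    sub <- calls[idx, , drop = FALSE]
    carries <- !is.na(sub) & (sub == "het" | sub == "hom_alt")
    hom <- !is.na(sub) & sub == "hom_alt"
    if (!all(carries[, aff])) next                        # (i)
    if (!all(colSums(hom[, aff, drop = FALSE]) >= 1)) next  # (ii)
    if (any(hom[, una])) next                             # (iii)
    if (exclusivity == "strict" && length(una)) {
      hom_or_missing <- is.na(sub) | sub == "hom_alt"
      carries_or_missing <- is.na(sub) | carries
      fits <- vapply(una, function(u) {
        all(carries_or_missing[, u]) && any(hom_or_missing[, u])
      }, logical(1))
      if (any(fits)) next
    }
    ord <- idx[order(v$gene[idx], v$pos[idx])]
    zyg <- calls[ord, , drop = FALSE]
    hom_cov <- lapply(aff, function(a) {
      variant_key(v[ord, ])[!is.na(zyg[, a]) & zyg[, a] == "hom_alt"]
    })
    names(hom_cov) <- aff
    out[[length(out) + 1L]] <- structure(list(
      genes = v$gene[ord],
      variant_keys = variant_key(v[ord, ]),
      hom_coverage = hom_cov,
      zygosity = zyg,
      matrix = subset_variants(gm, ord)
    ), class = "candidate_set")
  }
  if (length(out) > 1L) {
    key <- vapply(out, function(cs) paste(cs$genes, collapse = "|"), character(1))
    out <- out[order(key)]
  }
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("candidate_set:", paste(x$genes, collapse = " + "), "\n")
  print(x$zygosity)
  invisible(x)
}
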