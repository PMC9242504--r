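#' kindred: family-based rare-variant prioritization
#'
#' Tools for prioritizing rare variants in small disease families from
#' multi-sample exome VCFs: a quality/region/consequence/frequency/
#' predictor filter cascade with per-individual accounting, segregation
#' filters for the classical autosomal recessive, autosomal dominant and
#' compound-heterozygous models plus a relaxed shared-rare model, a search
#' for k-gene oligogenic candidate sets in which every affected individual
#' is homozygous for at least one member variant and no healthy member is
#' homozygous for any, joint population co-occurrence frequency arithmetic,
#' and a gene-drop simulator producing labelled synthetic cohorts.
#'
#' @keywords internal
"_PACKAGE"

#' Run the full prioritization pipeline
#'
#' Convenience wrapper: read the pedigree and VCF, attach annotations,
#' apply the filter cascade, evaluate the single-variant segregation
#' models on the survivors, and search for k-gene candidate sets.
#'
#' @param vcf Path to a multi-sample VCF.
#' @param ped Path to a PED file, or a [pedigree][parse_ped].
#' @param ann Path to an annotation sidecar TSV, or a data.frame.
#' @param cfg A [filter_config()].
#' @param k Candidate-set size (default 3); `NULL` skips the multigene
#'   search.
#' @param gene_panel Optional curated gene list for the multigene search.
#' @return List with `gm` (annotated input matrix), `counts` (cascade
#'   stage counts per individual), `survivors`, `models` (per-survivor
#'   segregation calls), `comp_het` (compound-het pairs among survivors),
#'   and `candidate_sets`.
#' @export
run_pipeline <- function(vcf, ped, ann, cfg = filter_config(), k = 3,
                         gene_panel = NULL) {
  if (!inherits(ped, "pedigree")) ped <- parse_ped(ped)
  gm <- read_vcf(vcf, ped)
  gm <- attach_annotations(gm, ann)
  cascade <- apply_cascade(gm, cfg)
  survivors <- cascade$survivors
  models <- segregate(survivors, ped)
  sets <- if (is.null(k)) list() else
    find_multigene_sets(survivors, ped, k = k, gene_panel = gene_panel)
  list(gm = gm, counts = cascade$counts, survivors = survivors,
       models = models,
       comp_het = model_comp_het(survivors, ped, policy = "permissive"),
       candidate_sets = sets)
}
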