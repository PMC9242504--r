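#' Filter cascade configuration
#'
#' Bundles the thresholds of the rare-missense prioritization cascade.
#' Defaults encode the published-style workflow: keep quality-passing
#' variants in coding or regulatory regions whose consequence is missense,
#' frameshift, in-frame indel or splice-site (synonymous changes are dropped
#' unless they hit a splice site), with minor allele frequency below 1.5%
#' (`maf_threshold = 0.015`, a fraction) in every consulted database, and a
#' deleteriousness requirement from SIFT/FATHMM-MKL.
#'
#' @param maf_threshold Exclusive upper bound on the allele frequency
#'   (fraction; default 0.015 = 1.5%).
#' @param maf_databases Databases consulted, in priority order; `NULL` means
#'   every `maf_<db>` column present.
#' @param maf_policy `"any_db_exceeds_excludes"` (default: a variant at or
#'   above threshold in any consulted database is dropped) or
#'   `"all_dbs_must_exceed"`. A missing frequency never excludes: a variant
#'   absent from the databases is novel and must survive.
#' @param keep_consequences,keep_regions Consequence and region classes
#'   retained.
#' @param predictor_policy `"require_deleterious"` (default: keep a variant
#'   only if at least one available predictor calls it damaging),
#'   `"exclude_benign"` (drop only when every available predictor calls it
#'   tolerated), or `"off"`. SIFT calls a variant damaging at or below
#'   `sift_deleterious_max`; FATHMM-MKL at or above
#'   `fathmm_deleterious_min`.
#' @param sift_deleterious_max,fathmm_deleterious_min Predictor cutoffs.
#' @param missing_annotation_policy `"keep"` (default) or `"drop"`: fate of
#'   variants whose region/consequence annotation is absent.
#' @return A `filter_config` list.
#' @export
filter_config <- function(maf_threshold = 0.015,
                          maf_databases = NULL,
                          maf_policy = c("any_db_exceeds_excludes",
                                         "all_dbs_must_exceed"),
                          keep_consequences = c("missense", "frameshift",
                                                "inframe_indel", "splice_site"),
                          keep_regions = c("coding", "regulatory"),
                          predictor_policy = c("require_deleterious",
                                               "exclude_benign", "off"),
                          sift_deleterious_max = 0.05,
                          fathmm_deleterious_min = 0.5,
                          missing_annotation_policy = c("keep", "drop")) {
  stopifnot(maf_threshold > 0, maf_threshold < 1,
            sift_deleterious_max >= 0, sift_deleterious_max <= 1,
            fathmm_deleterious_min >= 0, fathmm_deleterious_min <= 1)
  structure(list(
    maf_threshold = maf_threshold,
    maf_databases = maf_databases,
    maf_policy = match.arg(maf_policy),
    keep_consequences = keep_consequences,
    keep_regions = keep_regions,
    predictor_policy = match.arg(predictor_policy),
    sift_deleterious_max = sift_deleterious_max,
    fathmm_deleterious_min = fathmm_deleterious_min,
    missing_annotation_policy = match.arg(missing_annotation_policy)
  ), class = "filter_config")
}

#' Read a filter configuration from YAML or JSON
#'
#' Field names mirror [filter_config()] arguments; unspecified fields take
#' the defaults.
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  unknown <- setdiff(names(vals), names(formals(filter_config)))
  if (length(unknown)) stop("unknown filter config field: ", unknown[1])
  do.call(filter_config, vals)
}

# Per-stage keep predicates over the variants table; each is a pure function
# of the annotations so the surviving set is order-independent.
.stage_quality <- function(v, cfg) v$qual_pass %in% TRUE

.stage_region <- function(v, cfg) {
  known <- !is.na(v$region) & v$region %in% cfg$keep_regions
  if (cfg$missing_annotation_policy == "keep") {
    known | is.na(v$region) | v$region == "unknown"
  } else known
}

.stage_consequence <- function(v, cfg) {
  known <- !is.na(v$consequence) & v$consequence %in% cfg$keep_consequences
  if (cfg$missing_annotation_policy == "keep") {
    known | is.na(v$consequence)
  } else known
}

.stage_maf <- function(v, cfg) {
  dbs <- cfg$maf_databases
  if (is.null(dbs)) dbs <- sub("^maf_", "", grep("^maf_", names(v), value = TRUE))
  cols <- paste0("maf_", dbs)
  cols <- cols[cols %in% names(v)]
  if (length(cols) == 0L) return(rep(TRUE, nrow(v)))
  freq <- as.matrix(v[, cols, drop = FALSE])
  common <- freq >= cfg$maf_threshold                   # TRUE = too common
  n_obs <- rowSums(!is.na(freq))
  if (cfg$maf_policy == "any_db_exceeds_excludes") {
    !(rowSums(common, na.rm = TRUE) > 0)
  } else {
    # drop only if every database that observed the allele finds it common
    !(n_obs > 0 & rowSums(common, na.rm = TRUE) == n_obs)
  }
}

.stage_predictor <- function(v, cfg) {
  if (cfg$predictor_policy == "off") return(rep(TRUE, nrow(v)))
  sift_dmg <- !is.na(v$sift) & v$sift <= cfg$sift_deleterious_max
  fat_dmg <- !is.na(v$fathmm_mkl) & v$fathmm_mkl >= cfg$fathmm_deleterious_min
  n_obs <- (!is.na(v$sift)) + (!is.na(v$fathmm_mkl))
  if (cfg$predictor_policy == "require_deleterious") {
    keep_missing <- cfg$missing_annotation_policy == "keep"
    ifelse(n_obs == 0, keep_missing, sift_dmg | fat_dmg)
  } else {                                              # exclude_benign
    !(n_obs > 0 & !sift_dmg & !fat_dmg)
  }
}

CASCADE_STAGES <- c("quality", "region", "consequence", "maf", "predictor")

.stage_fun <- list(quality = .stage_quality, region = .stage_region,
                   consequence = .stage_consequence, maf = .stage_maf,
                   predictor = .stage_predictor)

#' Apply the variant filter cascade
#'
#' Runs the fixed stage order quality -> region -> consequence -> frequency
#' -> predictor over an annotated genotype matrix. Each stage is a pure
#' predicate on variant annotations, so the surviving set does not depend on
#' stage order; the per-individual stage counts do, and follow the stated
#' order. Counts tally only variants an individual actually carries (het or
#' hom_alt), which is why they differ between family members.
#'
#' @param gm An annotated [genotype_matrix()].
#' @param cfg A [filter_config()].
#' @return A list with `survivors` (genotype matrix of variants passing all
#'   stages), `counts` (a `cascade_counts` data.frame: per individual, the
#'   carried-variant totals and het/hom split after the quality stage, then
#'   `coding_regulatory`, `missense_class`, `rare`, `damaging` counts), and
#'   `keep` (logical matrix of per-stage predicate values, for truth-label
#'   comparisons).
#' @export
apply_cascade <- function(gm, cfg = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(cfg, "filter_config"))
  v <- gm$variants
  keep <- vapply(CASCADE_STAGES, function(s) .stage_fun[[s]](v, cfg),
                 logical(nrow(v)))
  keep <- matrix(keep, nrow = nrow(v),
                 dimnames = list(NULL, CASCADE_STAGES))
  cum <- keep
  for (j in seq_along(CASCADE_STAGES)[-1]) {
    cum[, j] <- cum[, j - 1] & keep[, j]
  }
  carried <- !is.na(gm$calls) & gm$calls %in% c("het", "hom_alt")
  carried_het <- !is.na(gm$calls) & gm$calls == "het"
  carried_hom <- !is.na(gm$calls) & gm$calls == "hom_alt"
  counts <- data.frame(
    individual = gm$samples,
    total = colSums(carried & cum[, "quality"]),
    het = colSums(carried_het & cum[, "quality"]),
    hom = colSums(carried_hom & cum[, "quality"]),
    coding_regulatory = colSums(carried & cum[, "region"]),
    missense_class = colSums(carried & cum[, "consequence"]),
    rare = colSums(carried & cum[, "maf"]),
    damaging = colSums(carried & cum[, "predictor"]),
    row.names = NULL, stringsAsFactors = FALSE)
  class(counts) <- c("cascade_counts", "data.frame")
  list(survivors = subset_variants(gm, cum[, "predictor"]),
       counts = counts,
       keep = keep)
}

#' Count het and hom-alt calls for one individual
#'
#' Missing and hom_ref calls count toward neither tally.
#'
#' @param gm A [genotype_matrix()].
#' @param individual Sample id.
#' @return Named integer vector `c(het = ..., hom = ...)`.
#' @export
count_zygosity <- function(gm, individual) {
  if (!individual %in% gm$samples) {
    stop("unknown individual: ", individual)
  }
  calls <- gm$calls[, individual]
  c(het = sum(calls == "het", na.rm = TRUE),
    hom = sum(calls == "hom_alt", na.rm = TRUE))
}
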