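# Independent oracles used to validate the package implementations.
# Written straight from the definitions, deliberately without sharing code
# paths with the package.

# Per-variant cascade predicate: plain per-row if/else logic.
oracle_cascade_keep <- function(variants, cfg = filter_config()) {
  vapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    if (!isTRUE(v$qual_pass)) return(FALSE)
    reg <- v$region
    if (is.na(reg) || reg == "unknown") {
      if (cfg$missing_annotation_policy == "drop") return(FALSE)
    } else if (!reg %in% cfg$keep_regions) return(FALSE)
    csq <- v$consequence
    if (is.na(csq)) {
      if (cfg$missing_annotation_policy == "drop") return(FALSE)
    } else if (!csq %in% cfg$keep_consequences) return(FALSE)
    dbs <- cfg$maf_databases
    if (is.null(dbs)) dbs <- sub("^maf_", "", grep("^maf_", names(variants), value = TRUE))
    freqs <- unlist(v[paste0("maf_", dbs)])
    freqs <- freqs[!is.na(freqs)]
    if (length(freqs)) {
      common <- freqs >= cfg$maf_threshold
      if (cfg$maf_policy == "any_db_exceeds_excludes" && any(common)) return(FALSE)
      if (cfg$maf_policy == "all_dbs_must_exceed" && all(common)) return(FALSE)
    }
    if (cfg$predictor_policy != "off") {
      s <- v$sift; f <- v$fathmm_mkl
      s_dmg <- !is.na(s) && s <= cfg$sift_deleterious_max
      f_dmg <- !is.na(f) && f >= cfg$fathmm_deleterious_min
      n_obs <- (!is.na(s)) + (!is.na(f))
      if (cfg$predictor_policy == "require_deleterious") {
        if (n_obs == 0) {
          if (cfg$missing_annotation_policy == "drop") return(FALSE)
        } else if (!s_dmg && !f_dmg) return(FALSE)
      } else {
        if (n_obs > 0 && !s_dmg && !f_dmg) return(FALSE)
      }
    }
    TRUE
  }, logical(1))
}

# Segregation-model predicates, from the stated definitions.
oracle_model <- function(calls, ped, model, policy = "conservative") {
  aff <- calls[intersect(affected_ids(ped), names(calls))]
  una <- calls[intersect(unaffected_ids(ped), names(calls))]
  ok_aff <- function(allowed) {
    all(vapply(aff, function(c) {
      if (is.na(c)) policy == "wildcard" else c %in% allowed
    }, logical(1)))
  }
  una_has <- function(bad) any(!is.na(una) & una %in% bad)
  switch(model,
    ar = ok_aff("hom_alt") && !una_has("hom_alt"),
    ad = ok_aff("het") && !una_has(c("het", "hom_alt")),
    shared_rare = ok_aff(c("het", "hom_alt")) && !una_has("hom_alt"))
}

# Brute-force k-subset enumeration for the multigene search: all C(n, k)
# subsets checked directly against the three stated conditions plus the
# shared-rare prerequisite for each member variant.
oracle_multigene_genes <- function(gm, ped, k) {
  n <- nrow(gm$variants)
  if (n < k) return(list())
  aff <- intersect(affected_ids(ped), gm$samples)
  una <- intersect(unaffected_ids(ped), gm$samples)
  hits <- list()
  for (idx in utils::combn(n, k, simplify = FALSE)) {
    genes <- gm$variants$gene[idx]
    if (any(is.na(genes)) || length(unique(genes)) < k) next
    ok <- TRUE
    for (i in idx) {
      if (!oracle_model(gm$calls[i, ], ped, "shared_rare")) { ok <- FALSE; break }
    }
    if (!ok) next
    for (a in aff) {
      cc <- gm$calls[idx, a]
      if (!all(!is.na(cc) & cc %in% c("het", "hom_alt"))) { ok <- FALSE; break }
      if (!any(!is.na(cc) & cc == "hom_alt")) { ok <- FALSE; break }
    }
    if (!ok) next
    for (u in una) {
      cc <- gm$calls[idx, u]
      if (any(!is.na(cc) & cc == "hom_alt")) { ok <- FALSE; break }
    }
    if (!ok) next
    hits[[length(hits) + 1L]] <- sort(genes)
  }
  hits
}

# Drop founder-allele labels through a pedigree; the Monte-Carlo estimate
# of kinship(a, b) is the mean over replicates of the probability that a
# randomly chosen allele of a matches (is the same founder copy as) a
# randomly chosen allele of b.
mc_kinship <- function(ped, a, b, n = 2e4) {
  mem <- ped$members
  ids <- mem$id[order(ped$depth[mem$id])]
  lab1 <- matrix(0L, n, nrow(mem), dimnames = list(NULL, mem$id))
  lab2 <- lab1
  next_label <- 1L
  for (id in ids) {
    i <- match(id, mem$id)
    fa <- mem$father_id[i]; mo <- mem$mother_id[i]
    if (is.na(fa)) {
      lab1[, id] <- next_label; next_label <- next_label + 1L
    } else {
      pick <- stats::runif(n) < 0.5
      lab1[, id] <- ifelse(pick, lab1[, fa], lab2[, fa])
    }
    if (is.na(mo)) {
      lab2[, id] <- next_label; next_label <- next_label + 1L
    } else {
      pick <- stats::runif(n) < 0.5
      lab2[, id] <- ifelse(pick, lab1[, mo], lab2[, mo])
    }
  }
  x <- ((lab1[, a] == lab1[, b]) + (lab1[, a] == lab2[, b]) +
        (lab2[, a] == lab1[, b]) + (lab2[, a] == lab2[, b])) / 4
  list(est = mean(x), se = stats::sd(x) / sqrt(n))
}

# Random acyclic pedigree: founders plus layered non-founders.
random_pedigree <- function(n_members = 10) {
  n_founders <- max(2, rbinom(1, n_members - 2, 0.4) + 2)
  sex <- sample(c("male", "female"), n_members, TRUE)
  sex[1:2] <- c("male", "female")
  id <- sprintf("P%02d", seq_len(n_members))
  father <- mother <- rep(NA_character_, n_members)
  for (i in (n_founders + 1):n_members) {
    males <- which(sex[1:(i - 1)] == "male")
    females <- which(sex[1:(i - 1)] == "female")
    if (!length(males) || !length(females)) next
    father[i] <- id[males[sample.int(length(males), 1)]]
    mother[i] <- id[females[sample.int(length(females), 1)]]
  }
  new_pedigree(data.frame(
    id = id, father_id = father, mother_id = mother, sex = sex,
    status = sample(c("affected", "unaffected"), n_members, TRUE),
    stringsAsFactors = FALSE))
}

# Random call matrix over the study family.
random_calls <- function(n, samples, p_missing = 0) {
  m <- matrix(sample(c("hom_ref", "het", "hom_alt"), n * length(samples),
                     TRUE, c(0.5, 0.35, 0.15)),
              n, length(samples), dimnames = list(NULL, samples))
  if (p_missing > 0) m[runif(length(m)) < p_missing] <- NA
  m
}
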