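#' Parse a PED-format pedigree
#'
#' Reads the standard whitespace-delimited 6-column PED encoding
#' (family, individual, father, mother, sex, phenotype). Columns beyond the
#' sixth are ignored for compatibility with the many PED dialects in
#' circulation. A parent id of `"0"` means unknown; phenotype codes `2` =
#' affected, `1` = unaffected, and `0` or `-9` = unknown.
#'
#' Consanguineous loops (mating between relatives) are legitimate pedigree
#' structure and are permitted; only cycles through parent edges (an
#' individual among its own ancestors) are rejected.
#'
#' @param file Path to a PED file, or a character vector of PED lines.
#' @return A `pedigree` object: a list with a `members` data.frame
#'   (columns `id`, `father_id`, `mother_id`, `sex`, `status`).
#' @export
#' @examples
#' ped <- parse_ped(c(
#'   "FAM1 dad 0 0 1 1",
#'   "FAM1 mom 0 0 2 2",
#'   "FAM1 kid dad mom 1 2"
#' ))
#' affected_ids(ped)
parse_ped <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("empty PED input")
  tok <- strsplit(lines, "[ \t]+")
  nfield <- vapply(tok, length, integer(1))
  if (any(nfield < 6L)) {
    stop("PED line ", which(nfield < 6L)[1], " has fewer than 6 columns")
  }
  m <- do.call(rbind, lapply(tok, function(x) x[1:6]))
  sex_code <- m[, 5]
  phe_code <- m[, 6]
  members <- data.frame(
    id        = m[, 2],
    father_id = ifelse(m[, 3] == "0", NA_character_, m[, 3]),
    mother_id = ifelse(m[, 4] == "0", NA_character_, m[, 4]),
    sex       = c("1" = "male", "2" = "female")[sex_code],
    status    = c("2" = "affected", "1" = "unaffected")[phe_code],
    stringsAsFactors = FALSE
  )
  members$sex[is.na(members$sex)] <- "unknown"
  members$status[is.na(members$status)] <- "unknown"
  new_pedigree(members)
}

#' Construct a pedigree from a members table
#'
#' Validates structural invariants: unique non-empty ids, all referenced
#' parents present, parent sexes consistent where known, and no individual
#' its own ancestor.
#'
#' @param members data.frame with columns `id`, `father_id`, `mother_id`,
#'   `sex`, `status` (parent ids `NA` when unknown).
#' @return A `pedigree` object.
#' @export
new_pedigree <- function(members) {
  stopifnot(is.data.frame(members),
            all(c("id", "father_id", "mother_id", "sex", "status") %in% names(members)))
  if (any(!nzchar(members$id)) || anyNA(members$id)) stop("empty individual id")
  if (anyDuplicated(members$id)) {
    stop("duplicate individual id: ", members$id[duplicated(members$id)][1])
  }
  refs <- stats::na.omit(c(members$father_id, members$mother_id))
  missing_ref <- setdiff(refs, members$id)
  if (length(missing_ref)) {
    stop("parent id not present in pedigree: ", missing_ref[1])
  }
  fa_sex <- members$sex[match(members$father_id, members$id)]
  mo_sex <- members$sex[match(members$mother_id, members$id)]
  if (any(fa_sex == "female", na.rm = TRUE)) stop("father with female sex")
  if (any(mo_sex == "male", na.rm = TRUE)) stop("mother with male sex")

  ped <- structure(list(members = members), class = "pedigree")
  # depth doubles as the acyclicity check: it fails to terminate finitely on
  # parent-edge cycles, which we detect with a visited stack
  depth <- integer(nrow(members))
  names(depth) <- members$id
  depth[] <- NA_integer_
  visit <- function(id, stack) {
    if (id %in% stack) stop("pedigree cycle involving individual ", id)
    if (!is.na(depth[[id]])) return(depth[[id]])
    i <- match(id, members$id)
    pars <- stats::na.omit(c(members$father_id[i], members$mother_id[i]))
    d <- if (length(pars) == 0L) 0L else
      1L + max(vapply(pars, visit, integer(1), stack = c(stack, id)))
    depth[[id]] <<- d
    d
  }
  for (id in members$id) visit(id, character(0))
  ped$depth <- depth
  ped
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree with", nrow(x$members), "members (",
      length(affected_ids(x)), "affected,",
      length(unaffected_ids(x)), "unaffected,",
      length(founder_ids(x)), "founders )\n")
  invisible(x)
}

#' Pedigree member subsets
#'
#' @param ped A `pedigree`.
#' @return Character vector of individual ids.
#' @export
affected_ids <- function(ped) ped$members$id[ped$members$status == "affected"]

#' @rdname affected_ids
#' @export
unaffected_ids <- function(ped) ped$members$id[ped$members$status == "unaffected"]

#' @rdname affected_ids
#' @export
founder_ids <- function(ped) {
  ped$members$id[is.na(ped$members$father_id) & is.na(ped$members$mother_id)]
}

.ped_check_id <- function(ped, id) {
  if (!id %in% ped$members$id) stop("unknown individual id: ", id)
}

#' Kinship coefficient between two pedigree members
#'
#' Wright's kinship coefficient phi(a, b): the probability that an allele
#' sampled at random from `a` and one sampled from `b` are identical by
#' descent, computed by the classical recursion with founders assumed
#' unrelated and non-inbred. Self-kinship is `(1 + F_a) / 2` where `F_a` is
#' the inbreeding coefficient.
#'
#' @param ped A `pedigree`.
#' @param a,b Individual ids.
#' @return Kinship coefficient in `[0, 0.75]`.
#' @export
#' @examples
#' ped <- parse_ped(c("F p1 0 0 1 1", "F p2 0 0 2 1", "F c p1 p2 1 1"))
#' kinship(ped, "p1", "c")  # parent-offspring: 0.25
kinship <- function(ped, a, b) {
  .ped_check_id(ped, a)
  .ped_check_id(ped, b)
  mem <- ped$members
  depth <- ped$depth
  memo <- new.env(parent = emptyenv())
  phi <- function(x, y) {
    if (is.na(x) || is.na(y)) return(0)
    key <- if (x <= y) paste0(x, "\r", y) else paste0(y, "\r", x)
    got <- memo[[key]]
    if (!is.null(got)) return(got)
    val <- if (x == y) {
      i <- match(x, mem$id)
      0.5 * (1 + phi(mem$father_id[i], mem$mother_id[i]))
    } else {
      # recurse through the parents of the deeper individual, which can
      # never be an ancestor of the shallower one
      if (depth[[x]] < depth[[y]]) { tmp <- x; x <- y; y <- tmp }
      i <- match(x, mem$id)
      if (is.na(mem$father_id[i]) && is.na(mem$mother_id[i])) 0
      else 0.5 * (phi(mem$father_id[i], y) + phi(mem$mother_id[i], y))
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

#' Inbreeding coefficient of a pedigree member
#'
#' `F_a` equals the kinship between the parents of `a`; founders and
#' offspring of unrelated parents have `F = 0`. Offspring of a first-cousin
#' mating have `F = 1/16`.
#'
#' @param ped A `pedigree`.
#' @param a Individual id.
#' @return Inbreeding coefficient in `[0, 0.5]`.
#' @export
inbreeding <- function(ped, a) {
  .ped_check_id(ped, a)
  i <- match(a, ped$members$id)
  fa <- ped$members$father_id[i]
  mo <- ped$members$mother_id[i]
  if (is.na(fa) || is.na(mo)) return(0)
  kinship(ped, fa, mo)
}
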