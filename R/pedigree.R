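AFFECTION_LEVELS <- c("psychosis", "other_mental_disorder", "unaffected",
  "unknown")

#' Read a 6-column PED pedigree file
#'
#' Columns are family, member id, father id, mother id, sex and phenotype,
#' whitespace-delimited, with `0` meaning unknown parent (founder). The
#' phenotype column extends the PLINK convention with a third affection
#' level: `0`/`-9` unknown, `1` unaffected, `2` affected by psychosis,
#' `3` affected by a non-psychotic mental disorder.
#'
#' @param path Path to a PED file.
#' @param nuclear Optional character vector of member ids forming the
#'   nuclear-family analysis scope. Defaults to all members.
#' @return A validated pedigree tibble (see [as_pedigree()]).
#' @export
read_ped <- function(path, nuclear = NULL) {
  raw <- utils::read.table(path,
    header = FALSE, colClasses = "character",
    col.names = c("family", "member_id", "father_id", "mother_id", "sex",
      "phenotype")
  )
  ped <- tibble::tibble(
    member_id = raw$member_id,
    father_id = dplyr::na_if(raw$father_id, "0"),
    mother_id = dplyr::na_if(raw$mother_id, "0"),
    sex = dplyr::case_match(raw$sex,
      "1" ~ "male", "2" ~ "female", .default = "unknown"
    ),
    affection = dplyr::case_match(raw$phenotype,
      "1" ~ "unaffected", "2" ~ "psychosis", "3" ~ "other_mental_disorder",
      .default = "unknown"
    ),
    sequenced = FALSE,
    arrayed = FALSE,
    nuclear = if (is.null(nuclear)) TRUE else raw$member_id %in% nuclear
  )
  as_pedigree(ped)
}

#' Validate a pedigree tibble
#'
#' Checks the structural invariants of a family graph: unique member ids,
#' parents either both present or both absent, parent references resolving
#' within the pedigree, no self-parentage, no directed cycles, and parental
#' sexes consistent where known.
#'
#' @param ped A data frame with columns `member_id`, `father_id`,
#'   `mother_id`, `sex`, `affection`, and optionally `sequenced`, `arrayed`,
#'   `nuclear` (missing flag columns are filled with defaults).
#' @return The pedigree as a tibble of class `pedseg_pedigree`.
#' @export
as_pedigree <- function(ped) {
  ped <- tibble::as_tibble(ped)
  for (flag in c("sequenced", "arrayed")) {
    if (!flag %in% names(ped)) ped[[flag]] <- FALSE
  }
  if (!"nuclear" %in% names(ped)) ped$nuclear <- TRUE
  if (anyDuplicated(ped$member_id) > 0L) {
    abort("duplicated member ids in pedigree")
  }
  if (!all(ped$affection %in% AFFECTION_LEVELS)) {
    abort("affection must be psychosis, other_mental_disorder, unaffected or unknown")
  }
  one_parent <- xor(is.na(ped$father_id), is.na(ped$mother_id))
  if (any(one_parent)) {
    abort(paste0(
      "members with exactly one known parent: ",
      paste(ped$member_id[one_parent], collapse = ", ")
    ))
  }
  parents <- c(ped$father_id, ped$mother_id)
  unresolved <- setdiff(parents[!is.na(parents)], ped$member_id)
  if (length(unresolved) > 0L) {
    abort(paste0(
      "parent ids absent from pedigree: ", paste(unresolved, collapse = ", ")
    ))
  }
  if (any(ped$member_id == ped$father_id, na.rm = TRUE) ||
    any(ped$member_id == ped$mother_id, na.rm = TRUE)) {
    abort("self-parentage in pedigree")
  }
  check_acyclic(ped)
  bad_father <- ped$sex[match(ped$father_id, ped$member_id)] == "female"
  bad_mother <- ped$sex[match(ped$mother_id, ped$member_id)] == "male"
  if (any(bad_father, na.rm = TRUE) || any(bad_mother, na.rm = TRUE)) {
    abort("father must be male and mother female where sex is known")
  }
  class(ped) <- c("pedseg_pedigree", class(ped))
  ped
}

# depth-first ancestry walk; revisiting an in-progress node means a cycle
check_acyclic <- function(ped) {
  parent_of <- function(id) {
    i <- match(id, ped$member_id)
    c(ped$father_id[i], ped$mother_id[i])
  }
  state <- setNames(rep("new", nrow(ped)), ped$member_id)
  visit <- function(id) {
    if (state[[id]] == "done") return(invisible())
    if (state[[id]] == "open") abort("cyclic parentage in pedigree")
    state[[id]] <<- "open"
    for (p in parent_of(id)) {
      if (!is.na(p)) visit(p)
    }
    state[[id]] <<- "done"
  }
  for (id in ped$member_id) visit(id)
  invisible()
}

#' The packaged family pedigree
#'
#' Loads the packaged pedigree fixture: a nuclear family of a mother
#' (SCA-3, schizoaffective disorder), her husband (subject 2) and their
#' five children (three affected sons SCZ-7, SCZ-8, SCA-9 and unaffected
#' twin daughters 10 and 11), plus the analyzed extended members (the
#' mother's unaffected sister 4 with husband 14 and son 13, and the couple
#' 5/6 with their daughter BD-12, affected by bipolar I disorder).
#' Sequenced/arrayed flags record which platforms each member was assayed
#' on: exomes for SCA-3, SCZ-7, SCZ-8, subject 10 and BD-12; arrays for
#' everyone.
#'
#' @return A pedigree tibble with the nuclear scope set to the
#'   (2, SCA-3) couple and their children.
#' @export
majorcan_pedigree <- function() {
  ped <- read_ped(
    pedseg_example("majorcan_family.ped"),
    nuclear = c("2", "SCA-3", "SCZ-7", "SCZ-8", "SCA-9", "10", "11")
  )
  ped$sequenced <- ped$member_id %in% c("SCA-3", "SCZ-7", "SCZ-8", "10",
    "BD-12")
  ped$arrayed <- TRUE
  ped
}

#' Members affected by psychosis within a scope
#'
#' Only `affection == "psychosis"` counts as affected; members with
#' non-psychotic mental disorders are neither affected nor unaffected for
#' filtering purposes.
#'
#' @param ped A pedigree tibble.
#' @param scope `"nuclear"` (members flagged in the nuclear scope) or
#'   `"extended"` (all members).
#' @return Character vector of member ids.
#' @export
affected_set <- function(ped, scope = c("nuclear", "extended")) {
  scope <- match.arg(scope)
  members <- if (scope == "nuclear") ped[ped$nuclear, ] else ped
  if (nrow(members) == 0L) abort("empty pedigree scope")
  members$member_id[members$affection == "psychosis"]
}

#' Is a carrier set consistent with inherited transmission?
#'
#' A carrier configuration is consistent with inheritance when every
#' non-founder carrier has at least one parent who is a carrier or whose
#' carrier status is unknowable (parent not in the genotyped set); otherwise
#' some carrier would require a de novo event.
#'
#' @param ped A pedigree tibble.
#' @param carriers Character vector of carrier member ids.
#' @param genotyped Member ids whose carrier status is known (default: all
#'   members, i.e. absence from `carriers` means non-carrier).
#' @return `"consistent_inherited"` or `"requires_de_novo"`.
#' @export
transmission_path <- function(ped, carriers, genotyped = ped$member_id) {
  if (!all(carriers %in% ped$member_id)) {
    abort("carriers must be pedigree members")
  }
  for (id in carriers) {
    i <- match(id, ped$member_id)
    parents <- c(ped$father_id[i], ped$mother_id[i])
    parents <- parents[!is.na(parents)]
    if (length(parents) == 0L) next # founder: origin outside the pedigree
    possible <- parents %in% carriers | !(parents %in% genotyped)
    if (!any(possible)) {
      return("requires_de_novo")
    }
  }
  "consistent_inherited"
}

#' List Mendelian violations of a variant in a pedigree
#'
#' For every child with two parents, checks that the trio's genotypes are
#' possible under biallelic Mendelian inheritance. Trios with any missing
#' genotype are skipped.
#'
#' @param ped A pedigree tibble.
#' @param record Long genotype rows for a single variant (columns
#'   `sample_id`, `gt`).
#' @return A tibble with columns `child`, `reason`; zero rows when the
#'   variant transmits cleanly.
#' @export
mendelian_check <- function(ped, record) {
  gt_of <- setNames(record$gt, record$sample_id)
  kids <- ped[!is.na(ped$father_id), ]
  out <- purrr::pmap(
    list(kids$member_id, kids$father_id, kids$mother_id),
    function(child, father, mother) {
      trio <- gt_of[c(child, father, mother)]
      if (anyNA(trio) || any(trio == "missing")) {
        return(NULL)
      }
      if (trio_possible(trio[[1]], trio[[2]], trio[[3]])) {
        return(NULL)
      }
      tibble::tibble(
        child = child,
        reason = paste0(
          "child ", trio[[1]], " impossible from parents ",
          trio[[2]], " x ", trio[[3]]
        )
      )
    }
  )
  violations <- dplyr::bind_rows(out)
  if (nrow(violations) == 0L) {
    violations <- tibble::tibble(child = character(), reason = character())
  }
  violations
}

# enumerate transmitted-allele counts: gt -> possible alt doses per gamete
trio_possible <- function(child, father, mother) {
  gametes <- list(hom_ref = 0L, het = 0:1, hom_alt = 1L)
  child_dose <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)[[child]]
  any(outer(gametes[[father]], gametes[[mother]], `+`) == child_dose)
}
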