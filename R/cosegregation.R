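SNV_TIERS <- c(sanger = 2L, wes = 1L)
CNV_TIERS <- c(ddpcr = 2L, array = 1L)

#' Build a member-by-lesion carrier matrix from multi-platform evidence
#'
#' Combines genotype evidence from different platforms into one carrier
#' state per (member, lesion) pair. Within a lesion, sources are ranked by
#' validation tier — Sanger over exome sequencing for single-nucleotide
#' lesions, droplet digital PCR over SNP array for copy-number lesions —
#' and the highest available tier wins. A lower-tier observation
#' contradicting the winning tier is resolved by precedence with a
#' warning; contradictory observations within the same tier leave the
#' state `unknown` with a warning. Pairs without evidence are `unknown`.
#'
#' @param evidence Long tibble with columns `member_id`, `lesion`,
#'   `source` (`wes`, `sanger`, `array`, `ddpcr`) and `state`
#'   (`carrier`/`non_carrier`).
#' @param ped Pedigree tibble; the matrix covers every member.
#' @param lesions Optional lesion ordering (default: first appearance in
#'   `evidence`).
#' @return A tibble of class `carrier_matrix` with columns `member_id`,
#'   `lesion`, `state`, `evidence` (comma-joined sources behind the
#'   resolved state).
#' @export
build_carrier_matrix <- function(evidence, ped, lesions = NULL) {
  stopifnot(all(c("member_id", "lesion", "source", "state")
    %in% names(evidence)))
  if (!all(evidence$member_id %in% ped$member_id)) {
    abort("evidence for members absent from the pedigree")
  }
  if (!all(evidence$source %in% c(names(SNV_TIERS), names(CNV_TIERS)))) {
    abort("evidence source must be wes, sanger, array or ddpcr")
  }
  lesions <- lesions %||% unique(evidence$lesion)
  tier_of <- c(SNV_TIERS, CNV_TIERS)

  evidence$tier <- unname(tier_of[evidence$source])
  groups <- split(
    evidence,
    list(evidence$member_id, evidence$lesion),
    drop = TRUE, sep = "\r"
  )
  resolved <- purrr::map(groups, function(g) {
    tibble::tibble(
      member_id = g$member_id[1], lesion = g$lesion[1],
      state = resolve_states(g$state, g$tier, g$member_id[1], g$lesion[1]),
      evidence = paste(sort(unique(g$source)), collapse = ",")
    )
  }) |>
    dplyr::bind_rows()
  if (nrow(evidence) == 0L) {
    resolved <- tibble::tibble(
      member_id = character(), lesion = character(),
      state = character(), evidence = character()
    )
  }

  grid <- tidyr::expand_grid(
    member_id = ped$member_id, lesion = lesions
  )
  out <- grid |>
    dplyr::left_join(resolved, by = c("member_id", "lesion")) |>
    dplyr::mutate(
      state = dplyr::coalesce(.data$state, "unknown"),
      evidence = dplyr::coalesce(.data$evidence, "")
    )
  class(out) <- c("carrier_matrix", class(out))
  out
}

resolve_states <- function(states, tiers, member, lesion) {
  top <- tiers == max(tiers)
  top_states <- unique(states[top])
  if (length(top_states) > 1L) {
    warn(paste0(
      "same-tier conflicting evidence for ", member, " / ", lesion,
      "; state set to unknown"
    ))
    return("unknown")
  }
  if (length(unique(states)) > 1L) {
    warn(paste0(
      "lower-tier evidence for ", member, " / ", lesion,
      " overridden by the validation tier"
    ))
  }
  top_states
}

#' Specify a digenic risk rule
#'
#' The rule predicts a member at risk when they carry the named
#' single-nucleotide lesion (if any is named) together with at least one
#' of the named copy-number lesions.
#'
#' @param snv Lesion id of the SNV component, or `NULL` for a
#'   duplications-only rule.
#' @param cnvs Character vector of copy-number lesion ids (at least one).
#' @return A list of class `digenic_model`.
#' @export
digenic_model <- function(snv, cnvs) {
  stopifnot(length(cnvs) >= 1)
  structure(list(snv = snv, cnvs = cnvs), class = "digenic_model")
}

#' Evaluate a digenic rule against observed affection
#'
#' For every member in scope, predicts risk under the rule and compares
#' the prediction with affection status. Members are excluded from the
#' consistency denominator when their affection is neither psychosis nor
#' unaffected (non-psychotic mental disorders are uninformative for the
#' psychosis rule) or when the carrier states required by the rule cannot
#' be determined. In `strict` mode (complete penetrance) a member is
#' consistent iff at-risk equals affected; in `asymmetric` mode
#' (incomplete penetrance allowed) only affected members lacking the risk
#' genotype count as inconsistent.
#'
#' @param matrix A [build_carrier_matrix()] result.
#' @param ped Pedigree tibble.
#' @param model A [digenic_model()].
#' @param scope `"nuclear"` or `"extended"`.
#' @param mode `"strict"` or `"asymmetric"`.
#' @return A list of class `digenic_result`: per-member tibble `members`,
#'   `consistency_fraction` (`NA` when no member is evaluable),
#'   `n_evaluable`, `inconsistent_members`, and the `model`.
#' @export
evaluate_digenic <- function(matrix, ped, model,
                             scope = c("nuclear", "extended"),
                             mode = c("strict", "asymmetric")) {
  scope <- match.arg(scope)
  mode <- match.arg(mode)
  required <- c(model$snv, model$cnvs)
  absent <- setdiff(required, unique(matrix$lesion))
  if (length(absent) > 0L) {
    abort(paste0("model references absent lesion(s): ",
      paste(absent, collapse = ", ")))
  }
  members <- if (scope == "nuclear") ped[ped$nuclear, ] else ped

  state_of <- function(member, lesion) {
    matrix$state[matrix$member_id == member & matrix$lesion == lesion]
  }
  predicted <- vapply(members$member_id, function(m) {
    snv_state <- if (is.null(model$snv)) "carrier" else
      state_of(m, model$snv)
    cnv_states <- vapply(model$cnvs, state_of, character(1), member = m)
    if (snv_state == "unknown") {
      return("unknown")
    }
    if (snv_state == "non_carrier") {
      return("not_at_risk")
    }
    if (any(cnv_states == "carrier")) {
      return("at_risk")
    }
    if (any(cnv_states == "unknown")) {
      return("unknown")
    }
    "not_at_risk"
  }, character(1))

  tab <- tibble::tibble(
    member_id = members$member_id,
    affection = members$affection,
    predicted = predicted,
    evaluable = .data_evaluable(members$affection, predicted)
  )
  tab$consistent <- ifelse(!tab$evaluable, NA,
    if (mode == "strict") {
      (tab$predicted == "at_risk") == (tab$affection == "psychosis")
    } else {
      !(tab$affection == "psychosis" & tab$predicted == "not_at_risk")
    }
  )
  n_eval <- sum(tab$evaluable)
  frac <- if (n_eval == 0L) NA_real_ else
    sum(tab$consistent, na.rm = TRUE) / n_eval
  structure(
    list(
      members = tab,
      consistency_fraction = frac,
      n_evaluable = n_eval,
      inconsistent_members = tab$member_id[!is.na(tab$consistent) &
        !tab$consistent],
      model = model, scope = scope, mode = mode
    ),
    class = "digenic_result"
  )
}

.data_evaluable <- function(affection, predicted) {
  affection %in% c("psychosis", "unaffected") & predicted != "unknown"
}

#' Score every single-SNV plus duplication-subset rule
#'
#' Enumerates all rules pairing one SNV lesion with a non-empty subset of
#' the copy-number lesions, scores each with [evaluate_digenic()], and
#' ranks by consistency (ties broken by fewer required lesions).
#'
#' @param matrix A [build_carrier_matrix()] result.
#' @param ped Pedigree tibble.
#' @param snvs Candidate SNV lesion ids.
#' @param cnvs Candidate copy-number lesion ids (at most a dozen lesions
#'   in total; the enumeration is exhaustive).
#' @inheritParams evaluate_digenic
#' @return A tibble ranked best-first with columns `snv`, `cnvs`
#'   (comma-joined), `n_lesions`, `consistency_fraction`, `n_evaluable`.
#' @export
exhaustive_model_scan <- function(matrix, ped, snvs, cnvs,
                                  scope = "nuclear", mode = "strict") {
  if (length(snvs) + length(cnvs) > 12L) {
    abort("lesion pool too large for exhaustive enumeration")
  }
  if (length(snvs) == 0L || length(cnvs) == 0L) {
    return(tibble::tibble(
      snv = character(), cnvs = character(), n_lesions = integer(),
      consistency_fraction = double(), n_evaluable = integer()
    ))
  }
  subsets <- unlist(
    lapply(seq_along(cnvs), function(k) {
      asplit(utils::combn(cnvs, k), 2L)
    }),
    recursive = FALSE
  )
  rows <- purrr::map(snvs, function(s) {
    purrr::map(subsets, function(sub) {
      res <- evaluate_digenic(matrix, ped, digenic_model(s, sub),
        scope = scope, mode = mode)
      tibble::tibble(
        snv = s, cnvs = paste(sub, collapse = ","),
        n_lesions = 1L + length(sub),
        consistency_fraction = res$consistency_fraction,
        n_evaluable = res$n_evaluable
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  dplyr::arrange(rows, dplyr::desc(.data$consistency_fraction),
    .data$n_lesions)
}

#' @export
print.digenic_result <- function(x, ...) {
  rule <- paste0(
    if (is.null(x$model$snv)) "any()" else x$model$snv,
    " + any(", paste(x$model$cnvs, collapse = ", "), ")"
  )
  cat("Digenic co-segregation (", x$scope, " scope, ", x$mode, " mode)\n",
    sep = "")
  cat("  rule:", rule, "\n")
  cat("  consistency:",
    format(x$consistency_fraction, digits = 3), "over", x$n_evaluable,
    "evaluable members\n")
  if (length(x$inconsistent_members) > 0L) {
    cat("  inconsistent:", paste(x$inconsistent_members, collapse = ", "),
      "\n")
  }
  invisible(x)
}

#' @rdname evaluate_digenic
#' @param x A `digenic_result`.
#' @param ... Unused.
#' @method tidy digenic_result
#' @export
tidy.digenic_result <- function(x, ...) {
  x$members
}

#' @rdname evaluate_digenic
#' @method glance digenic_result
#' @export
glance.digenic_result <- function(x, ...) {
  tibble::tibble(
    snv = x$model$snv %||% NA_character_,
    cnvs = paste(x$model$cnvs, collapse = ","),
    consistency_fraction = x$consistency_fraction,
    n_evaluable = x$n_evaluable,
    n_inconsistent = length(x$inconsistent_members)
  )
}

#' Published carrier evidence for the family lesions
#'
#' Reconstructs, in code, the per-member evidence behind the published
#' carrier pattern for the four family lesions (the MACF1 and GLI2
#' missense variants and the two duplications), with the platform each
#' call came from: exome genotypes for the five sequenced members, Sanger
#' validation/screening for the rest, SNP-array calls for array-passing
#' members and droplet-PCR validation for everyone. SCA-9's duplication
#' states rest on ddPCR only (his array sample failed quality control).
#' Two states not narrated outright are encoded as the figure implies:
#' SCZ-8 as DUP3p26.3 non-carrier, and subject 11's MACF1 non-carrier
#' state as Sanger-tier.
#'
#' @return A long evidence tibble suitable for [build_carrier_matrix()].
#' @export
majorcan_carrier_evidence <- function() {
  ped <- majorcan_pedigree()
  all_members <- ped$member_id
  sequenced <- c("SCA-3", "SCZ-7", "SCZ-8", "10", "BD-12")
  arrayed <- setdiff(all_members, "SCA-9") # SCA-9 failed array QC

  lesion_rows <- function(lesion, carriers, source_of) {
    tibble::tibble(
      member_id = names(source_of),
      lesion = lesion,
      source = unname(source_of),
      state = ifelse(names(source_of) %in% carriers, "carrier",
        "non_carrier")
    )
  }
  snv_sources <- function() {
    setNames(
      ifelse(all_members %in% sequenced, "wes", "sanger"), all_members
    )
  }
  macf1 <- lesion_rows("SNV_MACF1",
    carriers = c("SCA-3", "SCZ-7", "SCZ-8", "SCA-9"), snv_sources())
  gli2 <- lesion_rows("SNV_GLI2",
    carriers = c("SCA-3", "SCZ-7", "SCZ-8"), snv_sources())

  dup3_carriers <- c("SCA-3", "SCZ-7", "SCA-9", "10", "11")
  dup16_carriers <- c("SCA-3", "SCZ-8", "SCA-9", "10", "11", "4", "13")
  cnv_rows <- function(lesion, carriers) {
    dplyr::bind_rows(
      lesion_rows(lesion, carriers,
        setNames(rep("array", length(arrayed)), arrayed)),
      lesion_rows(lesion, carriers,
        setNames(rep("ddpcr", length(all_members)), all_members))
    )
  }
  dplyr::bind_rows(
    macf1, gli2,
    cnv_rows("DUP3p26.3", dup3_carriers),
    cnv_rows("DUP16q23.3", dup16_carriers)
  )
}
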