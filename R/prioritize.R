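#' Cascade configuration
#'
#' Collects the tunable thresholds of the rare-variant prioritization
#' cascade. Defaults reproduce the published filtering: read depth strictly
#' greater than 10, all available population frequencies below 0.01,
#' missense consequences only, a conserved-region rule (SiPhy >= 8, or
#' GERP RS >= 4 together with phyloP100 >= 1), and a protein-impact
#' consensus of at least 6 damaging calls out of the 8 categorical
#' predictors.
#'
#' @param min_depth Strict lower bound on per-sample read depth.
#' @param maf_threshold Upper bound (exclusive) on population allele
#'   frequency; `NA` frequencies pass.
#' @param keep_consequence Consequence classes retained.
#' @param siphy_min,gerp_min,phylop_min Conserved-region rule parameters.
#' @param min_calls Damaging calls required for the protein-impact
#'   consensus flag.
#' @return A named list of class `cascade_config`.
#' @export
cascade_config <- function(min_depth = 10, maf_threshold = 0.01,
                           keep_consequence = "missense",
                           siphy_min = 8, gerp_min = 4, phylop_min = 1,
                           min_calls = 6) {
  stopifnot(min_depth >= 0, maf_threshold > 0, maf_threshold <= 1,
    min_calls >= 1)
  structure(
    list(
      min_depth = min_depth, maf_threshold = maf_threshold,
      keep_consequence = keep_consequence, siphy_min = siphy_min,
      gerp_min = gerp_min, phylop_min = phylop_min, min_calls = min_calls
    ),
    class = "cascade_config"
  )
}

variant_key <- function(x) {
  if (nrow(x) == 0L) {
    return(character())
  }
  paste0(x$chrom, ":", format(x$pos, scientific = FALSE, trim = TRUE),
    ":", x$ref, ">", x$alt)
}

#' Filter variants on per-sample read depth
#'
#' Keeps variants whose read depth is strictly greater than `min_depth` in
#' every one of the given samples.
#'
#' @param records Long genotype tibble (see [read_vcf()]).
#' @param samples Sample ids that must all satisfy the depth bound.
#' @param min_depth Strict lower bound (default 10; a depth of exactly 10
#'   fails).
#' @return The surviving records (all samples retained).
#' @export
filter_depth <- function(records, samples, min_depth = 10) {
  stopifnot(min_depth >= 0)
  absent <- setdiff(samples, unique(records$sample_id))
  if (nrow(records) > 0L && length(absent) > 0L) {
    abort(paste0("samples absent from records: ", paste(absent, collapse = ", ")))
  }
  keep <- records |>
    dplyr::filter(.data$sample_id %in% .env$samples) |>
    dplyr::summarise(
      ok = all(!is.na(.data$depth) & .data$depth > .env$min_depth),
      .by = c("chrom", "pos", "ref", "alt")
    ) |>
    dplyr::filter(.data$ok)
  dplyr::semi_join(records, keep, by = c("chrom", "pos", "ref", "alt"))
}

#' Rare-frequency predicate
#'
#' `TRUE` when every non-missing frequency among ExAC, gnomAD and 1000G is
#' below the threshold. Variants absent from all three databases pass, with
#' a warning (nothing is known about them, and the published variant set
#' contains rows unobserved in 1000G).
#'
#' @param ann Annotation tibble rows.
#' @param threshold Frequency bound, exclusive.
#' @return Logical vector along the rows of `ann`.
#' @export
filter_maf <- function(ann, threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 1)
  freqs <- cbind(ann$maf_exac, ann$maf_gnomad, ann$maf_1000g)
  all_null <- rowSums(!is.na(freqs)) == 0L
  if (any(all_null)) {
    warn(paste0(
      sum(all_null),
      " variant(s) have no frequency in any database; passing the MAF filter"
    ))
  }
  apply(freqs, 1L, function(f) all(is.na(f) | f < threshold))
}

#' Keep variants shared by affected carriers and absent from controls
#'
#' A variant survives when every member of `carriers_required` carries the
#' alternate allele (het or hom_alt) and every member of `must_be_absent`
#' is homozygous reference. A missing genotype in either set drops the
#' variant (conservative: sharing cannot be established).
#'
#' @param records Long genotype tibble.
#' @param carriers_required Sample ids that must carry the allele.
#' @param must_be_absent Sample ids that must not carry it.
#' @return The surviving records.
#' @export
shared_only_in_affected <- function(records, carriers_required,
                                    must_be_absent) {
  if (length(intersect(carriers_required, must_be_absent)) > 0L) {
    abort("carrier and exclusion sets must be disjoint")
  }
  keep <- records |>
    dplyr::summarise(
      ok = all(.data$gt[.data$sample_id %in% .env$carriers_required]
        %in% c("het", "hom_alt")) &&
        all(.data$gt[.data$sample_id %in% .env$must_be_absent] == "hom_ref"),
      .by = c("chrom", "pos", "ref", "alt")
    ) |>
    dplyr::filter(.data$ok)
  dplyr::semi_join(records, keep, by = c("chrom", "pos", "ref", "alt"))
}

#' Consequence predicate and nonsense counter
#'
#' @param ann Annotation tibble rows.
#' @param keep Consequence classes to retain.
#' @return `filter_consequence()`: logical vector; `count_nonsense()`: the
#'   number of stop-gain rows.
#' @export
filter_consequence <- function(ann, keep = "missense") {
  ann$consequence %in% keep
}

#' @rdname filter_consequence
#' @export
count_nonsense <- function(ann) {
  sum(ann$consequence == "nonsense", na.rm = TRUE)
}

#' Conserved-region predicate
#'
#' A site counts as conserved when SiPhy reaches `siphy_min`, or when both
#' GERP RS and phyloP100 reach their bounds. The rule is deliberately a
#' loose standard-practice consensus: strong evidence from the 29-mammal
#' log-odds alone suffices, otherwise two vertebrate-scale scores must
#' agree.
#'
#' @param ann Annotation tibble rows (columns `siphy`, `gerp_rs`,
#'   `phylop100`).
#' @param siphy_min,gerp_min,phylop_min Rule parameters.
#' @return Logical vector; rows with all three scores missing raise an
#'   error.
#' @export
is_conserved <- function(ann, siphy_min = 8, gerp_min = 4, phylop_min = 1) {
  all_null <- is.na(ann$siphy) & is.na(ann$gerp_rs) & is.na(ann$phylop100)
  if (any(all_null)) {
    abort("conservation profile with no scores at all")
  }
  siphy_ok <- !is.na(ann$siphy) & ann$siphy >= siphy_min
  pair_ok <- !is.na(ann$gerp_rs) & !is.na(ann$phylop100) &
    ann$gerp_rs >= gerp_min & ann$phylop100 >= phylop_min
  siphy_ok | pair_ok
}

#' Cerebral-cortex expression predicate
#'
#' Keeps genes expressed in cerebral cortex at any level (`yes`,
#' `yes_low`, `yes_very_low`); only `no` (or missing) fails.
#'
#' @param ann Annotation tibble rows.
#' @return Logical vector.
#' @export
filter_expression <- function(ann) {
  !is.na(ann$cortex_expressed) & ann$cortex_expressed != "no"
}

#' Protein-impact consensus over categorical predictors
#'
#' Counts damaging calls over the 8 categorical predictors (SIFT `D`;
#' PolyPhen2 `D` or `P`; MutationAssessor `H` or `M`; MetaSVM `D`;
#' MetaLR `D`; FATHMM `D`; LRT `D`; MutationTaster `A` or `D`). Missing
#' calls never count. VEST3 reports only a score and is excluded.
#'
#' @param ann Annotation tibble rows.
#' @param min_calls Damaging calls required to raise the consensus flag.
#' @return A tibble with columns `n_damaging` and `flag`.
#' @export
consensus_deleterious <- function(ann, min_calls = 6) {
  stopifnot(min_calls >= 1)
  damaging <- cbind(
    ann$sift_call %in% "D",
    ann$polyphen2_call %in% c("D", "P"),
    ann$mutassessor_call %in% c("H", "M"),
    ann$metasvm_call %in% "D",
    ann$metalr_call %in% "D",
    ann$fathmm_call %in% "D",
    ann$lrt_call %in% "D",
    ann$muttaster_call %in% c("A", "D")
  )
  n <- rowSums(damaging)
  tibble::tibble(n_damaging = as.integer(n), flag = n >= min_calls)
}

#' Rank genes by intolerance to functional variation
#'
#' Ascending by RVIS (more negative = more intolerant), ties broken by
#' LOEUF (lower = more constrained); genes without scores sort last.
#'
#' @param genes A tibble with columns `gene`, `rvis`, `loeuf`.
#' @return The same tibble, ordered most-intolerant first.
#' @export
rank_intolerance <- function(genes) {
  if (all(is.na(genes$rvis) & is.na(genes$loeuf))) {
    abort("at least one gene needs a non-missing constraint score")
  }
  dplyr::arrange(genes, .data$rvis, .data$loeuf)
}

#' Run the full rare-variant prioritization cascade
#'
#' Applies, in order: read depth, population frequency, consequence class,
#' sharing among the sequenced affected members with absence in the
#' sequenced unaffected member(s), and the conserved-region rule. The
#' survivors of that cascade are the shared rare missense set. The
#' cortex-expression filter is then applied, and three triage views are
#' computed on the expressed survivors: the clinically uncertain (VUS)
#' subset, its protein-impact consensus subset, and the
#' schizophrenia-associated (DisGeNET) subset. Final candidates are the
#' intersection of the VUS and DisGeNET views; DisGeNET hits classified
#' benign or likely benign are retained separately as caveat candidates
#' worth a segregation follow-up despite their classification.
#'
#' @param records Long genotype tibble covering every annotated variant.
#' @param annotations Annotation tibble (see [load_annotation_fixture()]).
#' @param ped Pedigree tibble; by default the carrier set is the sequenced
#'   nuclear members affected by psychosis and the exclusion set the
#'   sequenced unaffected nuclear members.
#' @param config A [cascade_config()].
#' @param carriers_required,must_be_absent Optional explicit sample sets
#'   overriding the pedigree-derived defaults.
#' @return An object of class `cascade_result`: a list with the annotation
#'   tibbles `survivors` (shared rare missense set), `expressed`, `vus`,
#'   `consensus`, `disgenet`, `candidates`, `caveat`, a per-variant `trace`
#'   tibble, a one-row `counts` tibble and the `config` used. Supports
#'   [tidy()], [glance()] and [autoplot()].
#' @export
run_cascade <- function(records, annotations, ped, config = cascade_config(),
                        carriers_required = NULL, must_be_absent = NULL) {
  nuclear_seq <- ped[ped$nuclear & ped$sequenced, ]
  if (is.null(carriers_required)) {
    carriers_required <- nuclear_seq$member_id[
      nuclear_seq$affection == "psychosis"
    ]
  }
  if (is.null(must_be_absent)) {
    must_be_absent <- nuclear_seq$member_id[
      nuclear_seq$affection == "unaffected"
    ]
  }
  if (length(intersect(carriers_required, must_be_absent)) > 0L) {
    abort("carrier and exclusion sets must be disjoint")
  }

  variants <- dplyr::distinct(records, .data$chrom, .data$pos, .data$ref,
    .data$alt)
  ann <- dplyr::inner_join(
    dplyr::mutate(annotations, chrom = as.character(.data$chrom)),
    dplyr::mutate(variants, chrom = as.character(.data$chrom)),
    by = c("chrom", "pos", "ref", "alt")
  )
  if (nrow(ann) != nrow(variants)) {
    orphan <- dplyr::anti_join(
      dplyr::mutate(variants, chrom = as.character(.data$chrom)),
      dplyr::mutate(annotations, chrom = as.character(.data$chrom)),
      by = c("chrom", "pos", "ref", "alt")
    )
    abort(paste0(
      "records without annotation rows: ",
      paste(variant_key(orphan), collapse = ", ")
    ))
  }

  wes_samples <- union(carriers_required, must_be_absent)
  passed_key <- function(recs) {
    unique(variant_key(dplyr::distinct(recs, .data$chrom, .data$pos,
      .data$ref, .data$alt)))
  }
  key <- variant_key(ann)

  depth_ok <- key %in% passed_key(
    filter_depth(records, wes_samples, config$min_depth)
  )
  maf_ok <- filter_maf(ann, config$maf_threshold)
  conseq_ok <- filter_consequence(ann, config$keep_consequence)
  shared_ok <- key %in% passed_key(
    shared_only_in_affected(records, carriers_required, must_be_absent)
  )
  conserved_ok <- is_conserved(ann, config$siphy_min, config$gerp_min,
    config$phylop_min)
  expressed_ok <- filter_expression(ann)

  stages <- tibble::tibble(
    variant = key, gene = ann$gene,
    depth = depth_ok, maf = maf_ok, consequence = conseq_ok,
    shared = shared_ok, conserved = conserved_ok, expressed = expressed_ok
  )
  trace <- stages |>
    tidyr::pivot_longer(
      cols = c("depth", "maf", "consequence", "shared", "conserved",
        "expressed"),
      names_to = "stage", values_to = "passed"
    ) |>
    dplyr::mutate(
      reason = dplyr::if_else(.data$passed, "pass",
        paste0("failed ", .data$stage)),
      .by = "variant"
    ) |>
    dplyr::filter(cumsum(dplyr::lag(!.data$passed, default = FALSE)) == 0L,
      .by = "variant")

  survivors <- ann[depth_ok & maf_ok & conseq_ok & shared_ok & conserved_ok, ]
  expressed <- survivors[filter_expression(survivors), ]
  cons <- consensus_deleterious(expressed, config$min_calls)
  expressed <- dplyr::mutate(expressed,
    n_damaging = cons$n_damaging,
    consensus_flag = cons$flag,
    vus = .data$varsome_class == "VUS"
  )
  vus <- expressed[expressed$vus, ]
  consensus <- vus[vus$consensus_flag, ]
  disgenet <- expressed[expressed$disgenet_scz, ]
  candidates <- disgenet[disgenet$vus, ]
  caveat <- dplyr::mutate(disgenet[!disgenet$vus, ],
    caveat = "benign-classified DisGeNET hit")

  counts <- tibble::tibble(
    n_input = nrow(ann),
    n_depth = sum(depth_ok),
    n_survivors = nrow(survivors),
    n_nonsense = count_nonsense(ann[depth_ok & maf_ok & shared_ok, ]),
    n_expressed = nrow(expressed),
    n_vus = nrow(vus),
    n_benign = nrow(expressed) - nrow(vus),
    n_consensus = nrow(consensus),
    n_disgenet = nrow(disgenet),
    n_final = nrow(candidates)
  )

  structure(
    list(
      survivors = survivors, expressed = expressed, vus = vus,
      consensus = consensus, disgenet = disgenet,
      candidates = candidates, caveat = caveat,
      trace = trace, counts = counts, config = config,
      carriers_required = carriers_required, must_be_absent = must_be_absent
    ),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Rare-variant prioritization cascade\n")
  cat("  carriers required:", paste(x$carriers_required, collapse = ", "),
    "\n")
  cat("  must be absent:  ", paste(x$must_be_absent, collapse = ", "), "\n")
  with(x$counts, cat(sprintf(
    "  %d input -> %d shared rare missense -> %d cortex-expressed -> %d VUS + %d benign -> %d consensus-deleterious; %d DisGeNET -> %d final\n",
    n_input, n_survivors, n_expressed, n_vus, n_benign, n_consensus,
    n_disgenet, n_final
  )))
  if (nrow(x$candidates) > 0L) {
    cat("  final candidate gene(s):",
      paste(x$candidates$gene, collapse = ", "), "\n")
  }
  if (nrow(x$caveat) > 0L) {
    cat("  caveat (benign-classified) gene(s):",
      paste(x$caveat$gene, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @rdname run_cascade
#' @param x,object A `cascade_result`.
#' @param ... Unused.
#' @method tidy cascade_result
#' @export
tidy.cascade_result <- function(x, ...) {
  x$trace
}

#' @rdname run_cascade
#' @method glance cascade_result
#' @export
glance.cascade_result <- function(x, ...) {
  x$counts
}
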