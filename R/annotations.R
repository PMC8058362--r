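ANNOTATION_COLS <- c(
  "chrom", "pos", "ref", "alt", "rsid", "gene", "consequence", "aa_change",
  "cortex_expressed", "varsome_class", "disgenet_scz",
  "maf_exac", "maf_gnomad", "maf_1000g",
  "siphy", "gerp_rs", "gerp_nr", "phylop100", "phastcons100",
  "sift_score", "sift_call", "polyphen2_score", "polyphen2_call",
  "mutassessor_score", "mutassessor_call", "metasvm_score", "metasvm_call",
  "metalr_score", "metalr_call", "vest3_score", "fathmm_score",
  "fathmm_call", "lrt_score", "lrt_call", "muttaster_score",
  "muttaster_call", "rvis", "rvis_percentile", "loeuf"
)

#' Load a per-variant annotation table
#'
#' Reads the delimited-text annotation fixture: one row per exome variant
#' with population allele frequencies (ExAC, gnomAD, 1000G), a cerebral
#' cortex expression flag, clinical classification, schizophrenia
#' disease-association flag, five conservation scores, nine protein-impact
#' predictions and per-gene constraint scores (RVIS and LOEUF). Empty cells
#' load as `NA` and are never coerced to 0 — a missing population
#' frequency means "not observed", which the frequency filter must treat
#' as passing, not as common.
#'
#' @param path Path to a tab-delimited annotation table; defaults to the
#'   packaged table of the 19 rare missense variants shared by the affected
#'   family members.
#' @return A tibble with one row per variant, keyed by
#'   (`chrom`, `pos`, `ref`, `alt`).
#' @export
load_annotation_fixture <- function(path = pedseg_example("variant_annotations.tsv")) {
  ann <- readr::read_tsv(path,
    na = c("", "NA"),
    col_types = readr::cols(
      chrom = readr::col_character(),
      pos = readr::col_integer(),
      disgenet_scz = readr::col_logical(),
      .default = readr::col_guess()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  missing_cols <- setdiff(ANNOTATION_COLS, names(ann))
  if (length(missing_cols) > 0L) {
    abort(paste0(
      "annotation table lacks columns: ", paste(missing_cols, collapse = ", ")
    ))
  }
  key <- paste(ann$chrom, ann$pos, ann$ref, ann$alt)
  if (anyDuplicated(key) > 0L) {
    abort("duplicated (chrom, pos, ref, alt) keys in annotation table")
  }
  bad_freq <- dplyr::filter(
    ann,
    dplyr::if_any(
      dplyr::all_of(c("maf_exac", "maf_gnomad", "maf_1000g")),
      ~ !is.na(.x) & (.x < 0 | .x > 1)
    )
  )
  if (nrow(bad_freq) > 0L) {
    abort("allele frequencies must lie in [0, 1]")
  }
  if (any(is.na(ann$gene) | ann$gene == "")) {
    abort("every annotation row needs a gene symbol")
  }
  ann
}

#' Read a gene-interval table
#'
#' A BED-like tab-delimited table with a header and columns `chrom`,
#' `start`, `end` (1-based, inclusive) and `gene`.
#'
#' @param path Path to the interval file; defaults to the packaged GRCh37
#'   intervals for CNTN6 and CDH13, the genes inside the two family
#'   duplications.
#' @return A tibble with columns `chrom`, `start`, `end`, `gene`.
#' @export
read_gene_intervals <- function(path = pedseg_example("genes_grch37.tsv")) {
  genes <- readr::read_tsv(path,
    col_types = readr::cols(
      chrom = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer(),
      gene = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  if (any(genes$start > genes$end)) {
    abort("gene intervals must have start <= end")
  }
  genes
}
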