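GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

#' Read a multi-sample VCF into a long genotype table
#'
#' Parses a VCF 4.2 file carrying `GT` and `DP` FORMAT fields and returns one
#' row per variant per sample. Multi-allelic rows are decomposed into one
#' record per ALT allele; the per-sample genotype is then expressed relative
#' to that allele (`hom_ref`, `het`, `hom_alt`, or `missing`) and the read
#' depth is carried onto every decomposed record.
#'
#' @param path Path to a VCF file.
#' @return A tibble with columns `chrom`, `pos` (1-based), `id` (`NA` for
#'   `.`), `ref`, `alt`, `sample_id`, `gt`, `depth`, ordered by variant
#'   (file order) then sample (header order). The header sample order is
#'   attached as `attr(, "samples")`.
#' @seealso [write_vcf()] for the inverse operation.
#' @export
read_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE, checkFile = FALSE)
  samples <- colnames(vcf@gt)[-1]
  if (nrow(vcf@fix) == 0L) {
    out <- tibble::tibble(
      chrom = character(), pos = integer(), id = character(),
      ref = character(), alt = character(), sample_id = character(),
      gt = character(), depth = integer()
    )
    attr(out, "samples") <- samples
    return(out)
  }
  fmt <- vcf@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt))) {
    abort("VCF FORMAT lacks the GT field; genotypes cannot be read")
  }
  gt_mat <- vcfR::extract.gt(vcf, element = "GT")
  dp_mat <- suppressWarnings(
    vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  )
  fix <- vcfR::getFIX(vcf)

  pos <- suppressWarnings(as.integer(fix[, "POS"]))
  if (anyNA(pos)) {
    abort(paste0(
      "malformed VCF row: non-integer POS at data line ",
      which(is.na(pos))[1]
    ))
  }

  rows <- purrr::map(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    purrr::map(seq_along(alts), function(k) {
      tibble::tibble(
        chrom = fix[i, "CHROM"],
        pos = pos[i],
        id = ifelse(is.na(fix[i, "ID"]) || fix[i, "ID"] == ".",
          NA_character_, fix[i, "ID"]
        ),
        ref = fix[i, "REF"],
        alt = alts[k],
        sample_id = samples,
        gt = decode_gt(gt_mat[i, samples], k),
        depth = as.integer(dp_mat[i, samples])
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  if (!all(out$ref != out$alt)) {
    abort("malformed VCF: REF equals ALT for at least one record")
  }
  attr(out, "samples") <- samples
  out
}

# genotype string -> {hom_ref, het, hom_alt, missing} relative to ALT index k
decode_gt <- function(gt_str, k) {
  alleles <- strsplit(unname(ifelse(is.na(gt_str), ".", gt_str)), "[/|]")
  vapply(alleles, function(a) {
    if (any(a == ".") || length(a) != 2L) {
      return("missing")
    }
    n_alt <- sum(a == as.character(k))
    GT_LEVELS[n_alt + 1L]
  }, character(1))
}

#' Write a long genotype table as a VCF 4.2 file
#'
#' Emits a minimal VCF with `GT:DP` per-sample fields such that
#' `read_vcf(write_vcf(x, samples, path))` reproduces `x` exactly. Variants
#' are written in first-appearance order.
#'
#' @param records A long genotype tibble as returned by [read_vcf()] or
#'   [simulate_pedigree_vcf()].
#' @param samples Ordered character vector of sample ids for the header
#'   columns; every record must have a call for every sample.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, samples, path) {
  stopifnot(is.data.frame(records), is.character(samples))
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t")
  )
  if (nrow(records) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  key <- paste(records$chrom, records$pos, records$ref, records$alt,
    sep = "\r"
  )
  groups <- split(seq_len(nrow(records)), factor(key, levels = unique(key)))
  body <- vapply(groups, function(idx) {
    calls <- records[idx, ]
    if (!setequal(calls$sample_id, samples) ||
      anyDuplicated(calls$sample_id) > 0L) {
      abort(paste0(
        "record ", calls$chrom[1], ":", calls$pos[1], " ", calls$ref[1],
        ">", calls$alt[1], " does not have exactly one call per sample"
      ))
    }
    calls <- calls[match(samples, calls$sample_id), ]
    gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
      missing = "./.")[calls$gt]
    dp <- ifelse(is.na(calls$depth), ".", as.character(calls$depth))
    paste(c(
      calls$chrom[1], calls$pos[1],
      ifelse(is.na(calls$id[1]), ".", calls$id[1]),
      calls$ref[1], calls$alt[1], ".", ".", ".",
      "GT:DP", paste0(gt_code, ":", dp)
    ), collapse = "\t")
  }, character(1), USE.NAMES = FALSE)
  writeLines(c(header, body), path)
  invisible(path)
}
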