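#' Run the whole analysis pipeline on an input bundle
#'
#' Executes, in order: the rare-variant prioritization cascade, array
#' sample QC and copy-number segmentation (QC-failing samples are
#' excluded and listed), droplet-PCR copy-number estimation, carrier
#' matrix construction from all evidence tiers, and the digenic
#' co-segregation evaluation with an exhaustive rule scan.
#'
#' @param bundle A list as produced by [simulate_study_bundle()]:
#'   `records`, `annotations`, `ped`, `probes`, `wells`, `genes`,
#'   `cnv_loci`.
#' @param cascade_cfg,cnv_cfg Stage configurations.
#' @param min_size_bp Minimum copy-number segment span retained.
#' @return A list of class `pipeline_report` with per-stage tables, the
#'   configuration echo and a `status` code (0 when the cascade produced
#'   at least one final candidate, 3 otherwise).
#' @export
run_pipeline <- function(bundle, cascade_cfg = cascade_config(),
                         cnv_cfg = cnv_config(), min_size_bp = 80000) {
  ped <- bundle$ped

  cascade <- run_cascade(bundle$records, bundle$annotations, ped,
    cascade_cfg)

  qc <- bundle$probes |>
    dplyr::summarise(
      missing_call_rate = mean(.data$call == "NC"),
      .by = "sample_id"
    ) |>
    dplyr::mutate(qc = dplyr::if_else(.data$missing_call_rate > 0.01,
      "fail", "pass"))
  passing <- qc$sample_id[qc$qc == "pass"]

  segments <- purrr::map(passing, function(m) {
    segs <- bundle$probes |>
      dplyr::filter(.data$sample_id == m) |>
      call_cnv_segments(cnv_cfg) |>
      filter_segments(min_size_bp) |>
      annotate_segment_genes(bundle$genes)
    if (nrow(segs) > 0L) segs$sample_id <- m
    segs
  }) |>
    dplyr::bind_rows()
  if (nrow(segments) > 0L) {
    segments <- dplyr::relocate(segments, "sample_id") |>
      dplyr::mutate(genes = purrr::map_chr(.data$genes, paste,
        collapse = ","))
  }

  cn_estimates <- estimate_copy_numbers(bundle$wells)

  snv_lesions <- dplyr::bind_rows(cascade$candidates, cascade$caveat)
  evidence <- dplyr::bind_rows(
    snv_evidence(snv_lesions, bundle$records, ped),
    array_evidence(segments, bundle$cnv_loci, passing),
    ddpcr_evidence(cn_estimates)
  )
  lesion_order <- c(paste0("SNV_", snv_lesions$gene), bundle$cnv_loci$lesion)
  matrix <- build_carrier_matrix(evidence, ped, lesions = lesion_order)

  digenic <- scan <- NULL
  if (nrow(cascade$candidates) > 0L) {
    model <- digenic_model(
      paste0("SNV_", cascade$candidates$gene[1]), bundle$cnv_loci$lesion
    )
    digenic <- evaluate_digenic(matrix, ped, model)
    scan <- exhaustive_model_scan(matrix, ped,
      snvs = paste0("SNV_", snv_lesions$gene),
      cnvs = bundle$cnv_loci$lesion
    )
  }

  structure(
    list(
      cascade = cascade,
      qc = qc,
      excluded_samples = qc$sample_id[qc$qc == "fail"],
      segments = segments,
      cn_estimates = cn_estimates,
      carrier_matrix = matrix,
      digenic = digenic,
      model_scan = scan,
      config = list(cascade = unclass(cascade_cfg), cnv = unclass(cnv_cfg),
        min_size_bp = min_size_bp),
      version = as.character(utils::packageVersion("pedseg")),
      status = if (nrow(cascade$candidates) > 0L) 0L else 3L
    ),
    class = "pipeline_report"
  )
}

snv_evidence <- function(snv_lesions, records, ped) {
  if (nrow(snv_lesions) == 0L) {
    return(NULL)
  }
  purrr::pmap(
    snv_lesions[, c("chrom", "pos", "ref", "alt", "gene")],
    function(chrom, pos, ref, alt, gene) {
      calls <- records[records$chrom == chrom & records$pos == pos &
        records$ref == ref & records$alt == alt, ]
      calls <- calls[calls$gt != "missing", ]
      tibble::tibble(
        member_id = calls$sample_id,
        lesion = paste0("SNV_", gene),
        source = dplyr::if_else(
          ped$sequenced[match(calls$sample_id, ped$member_id)],
          "wes", "sanger"
        ),
        state = dplyr::if_else(calls$gt == "hom_ref", "non_carrier",
          "carrier")
      )
    }
  ) |>
    dplyr::bind_rows()
}

array_evidence <- function(segments, cnv_loci, passing) {
  purrr::pmap(cnv_loci, function(lesion, chrom, start, end) {
    carrier <- if (nrow(segments) == 0L) character() else {
      unique(segments$sample_id[
        segments$chrom == chrom & segments$copy_number > 2 &
          segments$start <= end & segments$end >= start
      ])
    }
    tibble::tibble(
      member_id = passing, lesion = lesion, source = "array",
      state = dplyr::if_else(passing %in% carrier, "carrier", "non_carrier")
    )
  }) |>
    dplyr::bind_rows()
}

ddpcr_evidence <- function(cn_estimates) {
  est <- cn_estimates[cn_estimates$call %in% c("duplication", "deletion",
    "normal"), ]
  tibble::tibble(
    member_id = est$sample_id,
    lesion = est$locus,
    source = "ddpcr",
    state = dplyr::if_else(est$call == "normal", "non_carrier", "carrier")
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  print(x$cascade)
  cat("Array QC: ", sum(x$qc$qc == "pass"), " samples pass",
    if (length(x$excluded_samples) > 0L) {
      paste0("; excluded: ", paste(x$excluded_samples, collapse = ", "))
    },
    "\n",
    sep = ""
  )
  cat("Copy-number segments (>=", x$config$min_size_bp, " bp): ",
    nrow(x$segments), "\n", sep = "")
  print(glance(x$cn_estimates))
  if (!is.null(x$digenic)) print(x$digenic)
  invisible(x)
}

#' Write a pipeline report to a directory
#'
#' Emits a markdown summary plus tab-delimited tables (candidates, trace,
#' QC, segments, copy-number estimates, carrier matrix, model scan). The
#' output is a pure function of the report object: regenerating from the
#' same inputs gives byte-identical files.
#'
#' @param report A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) {
    readr::write_tsv(x, file.path(dir, name), progress = FALSE)
  }
  w(report$cascade$counts, "cascade_counts.tsv")
  w(dplyr::bind_rows(report$cascade$candidates, report$cascade$caveat),
    "candidates.tsv")
  w(report$cascade$trace, "trace.tsv")
  w(report$qc, "array_qc.tsv")
  w(report$segments, "segments.tsv")
  w(report$cn_estimates, "copy_number.tsv")
  w(report$carrier_matrix, "carrier_matrix.tsv")
  if (!is.null(report$model_scan)) w(report$model_scan, "model_scan.tsv")

  summary <- list(
    version = report$version,
    status = report$status,
    cascade = as.list(report$cascade$counts),
    excluded_samples = report$excluded_samples,
    n_segments = nrow(report$segments),
    digenic = if (!is.null(report$digenic)) {
      list(
        snv = report$digenic$model$snv,
        cnvs = report$digenic$model$cnvs,
        consistency_fraction = report$digenic$consistency_fraction,
        n_evaluable = report$digenic$n_evaluable
      )
    }
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null")

  counts <- report$cascade$counts
  lines <- c(
    "# Pedigree variant analysis report",
    "",
    paste0("pedseg version: ", report$version),
    "",
    "## Rare-variant cascade",
    "",
    sprintf(
      "%d shared rare missense variants / %d cortex-expressed / %d VUS + %d benign / %d consensus-deleterious / %d disease-associated / %d final candidate(s)",
      counts$n_survivors, counts$n_expressed, counts$n_vus,
      counts$n_benign, counts$n_consensus, counts$n_disgenet,
      counts$n_final
    ),
    "",
    paste0("Final candidate gene(s): ",
      paste(report$cascade$candidates$gene, collapse = ", ")),
    paste0("Caveat (benign-classified) gene(s): ",
      paste(report$cascade$caveat$gene, collapse = ", ")),
    "",
    "## Array QC",
    "",
    paste0("Excluded samples: ",
      if (length(report$excluded_samples) > 0L) {
        paste(report$excluded_samples, collapse = ", ")
      } else "none"),
    "",
    "## Copy-number segments",
    "",
    paste0(nrow(report$segments), " segment(s) after the size filter (",
      report$config$min_size_bp, " bp)"),
    "",
    "## Digenic co-segregation",
    ""
  )
  if (!is.null(report$digenic)) {
    lines <- c(lines, sprintf(
      "Rule %s + any(%s): consistency %.3f over %d evaluable members",
      report$digenic$model$snv,
      paste(report$digenic$model$cnvs, collapse = ", "),
      report$digenic$consistency_fraction, report$digenic$n_evaluable
    ))
  } else {
    lines <- c(lines, "No final candidate; digenic evaluation skipped.")
  }
  lines <- c(lines, "", paste0("Exit status: ", report$status))
  writeLines(lines, file.path(dir, "report.md"))
  invisible(dir)
}
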