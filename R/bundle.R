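DUP3_INTERVAL <- list(chrom = "3", start = 1159787L, end = 1781739L)
DUP16_INTERVAL <- list(chrom = "16", start = 82180075L, end = 83664582L)

#' Simulate the full family study as one input bundle
#'
#' Generates every input of the pipeline under the published carrier
#' configuration: a multi-sample genotype table planting the 19 shared
#' rare missense variants (heterozygous in the affected mother and her
#' affected sons, homozygous reference in the unaffected twin and the
#' distant affected relative) plus ten decoy variants that each violate
#' exactly one cascade filter; chr3 and chr16 BAF/LRR probe tracks with
#' the two duplications planted at their published coordinates in
#' carriers (the contaminated sample's track gets a 10.92% missing call
#' rate); droplet-PCR well pairs at the true copy number of every member;
#' and the annotation and gene-interval fixtures.
#'
#' @param seed Integer seed; the bundle is a deterministic function of it.
#' @param n_droplets Droplets per ddPCR well.
#' @param baf_sd,lrr_sd Array noise levels.
#' @param probe_spacing Array probe spacing in bp.
#' @return A list with elements `ped`, `records`, `annotations`, `probes`,
#'   `wells`, `genes`, `cnv_loci` and `truth` (the planted configuration).
#' @export
simulate_study_bundle <- function(seed = 1, n_droplets = 20000,
                                  baf_sd = 0.03, lrr_sd = 0.15,
                                  probe_spacing = 2000) {
  ped <- majorcan_pedigree()
  annotations <- load_annotation_fixture()
  genes <- read_gene_intervals()

  shared3 <- c("SCA-3", "SCZ-7", "SCZ-8")
  carriers19 <- purrr::map(annotations$gene, function(g) {
    switch(g,
      MACF1 = c(shared3, "SCA-9"),
      shared3
    )
  })
  planted <- tibble::tibble(
    chrom = as.character(annotations$chrom), pos = annotations$pos,
    ref = annotations$ref, alt = annotations$alt, id = annotations$rsid,
    carriers = carriers19
  )
  decoys <- decoy_variants(shared3)
  planted <- dplyr::bind_rows(planted, decoys$planted)

  records <- simulate_pedigree_vcf(ped, planted = planted, depth = 40,
    seed = seed)
  records <- decoys$edit_records(records)
  annotations <- dplyr::bind_rows(annotations, decoys$annotations)

  dup3_carriers <- c("SCA-3", "SCZ-7", "SCA-9", "10", "11")
  dup16_carriers <- c("SCA-3", "SCZ-8", "SCA-9", "10", "11", "4", "13")

  probes <- purrr::imap(setNames(ped$member_id, ped$member_id), function(m, nm) {
    nc <- if (m == "SCA-9") 0.1092 else 0.005
    chr3 <- simulate_array_track(m, "3",
      n_probes = 2000, probe_spacing = probe_spacing,
      cn_profile = if (m %in% dup3_carriers) {
        tibble::tibble(start = DUP3_INTERVAL$start, end = DUP3_INTERVAL$end,
          cn = 3L)
      },
      baf_sd = baf_sd, lrr_sd = lrr_sd, nc_rate = nc,
      seed = seed + 100L + match(m, ped$member_id)
    )
    chr16 <- simulate_array_track(m, "16",
      n_probes = 2000, probe_spacing = probe_spacing, offset = 81e6,
      cn_profile = if (m %in% dup16_carriers) {
        tibble::tibble(start = DUP16_INTERVAL$start,
          end = DUP16_INTERVAL$end, cn = 3L)
      },
      baf_sd = baf_sd, lrr_sd = lrr_sd, nc_rate = nc,
      seed = seed + 200L + match(m, ped$member_id)
    )
    dplyr::bind_rows(chr3, chr16)
  }) |>
    dplyr::bind_rows()

  wells <- purrr::map(seq_len(nrow(ped)), function(i) {
    m <- ped$member_id[i]
    set.seed(seed + 300L + i)
    lam_ref <- 0.8
    cn3 <- if (m %in% dup3_carriers) 3 else 2
    cn16 <- if (m %in% dup16_carriers) 3 else 2
    tibble::tibble(
      sample_id = m,
      assay = c("DUP3p26.3", "DUP16q23.3", "reference_rpp30"),
      n_droplets = as.integer(n_droplets),
      n_positive = c(
        rbinom(1L, n_droplets, 1 - exp(-lam_ref * cn3 / 2)),
        rbinom(1L, n_droplets, 1 - exp(-lam_ref * cn16 / 2)),
        rbinom(1L, n_droplets, 1 - exp(-lam_ref))
      )
    )
  }) |>
    dplyr::bind_rows()

  cnv_loci <- tibble::tibble(
    lesion = c("DUP3p26.3", "DUP16q23.3"),
    chrom = c(DUP3_INTERVAL$chrom, DUP16_INTERVAL$chrom),
    start = c(DUP3_INTERVAL$start, DUP16_INTERVAL$start),
    end = c(DUP3_INTERVAL$end, DUP16_INTERVAL$end)
  )

  list(
    ped = ped, records = records, annotations = annotations,
    probes = probes, wells = wells, genes = genes, cnv_loci = cnv_loci,
    truth = list(
      seed = seed,
      snv_carriers = setNames(planted$carriers, paste0(planted$chrom, ":",
        planted$pos)),
      dup3_carriers = dup3_carriers, dup16_carriers = dup16_carriers,
      dup3 = DUP3_INTERVAL, dup16 = DUP16_INTERVAL,
      decoy_genes = decoys$annotations$gene
    )
  )
}

# ten decoys, each violating exactly one cascade filter
decoy_variants <- function(shared3) {
  base_ann <- function(gene, pos, ...) {
    defaults <- list(
      chrom = "7", pos = as.integer(pos), ref = "A", alt = "G",
      rsid = NA_character_,
      gene = gene, consequence = "missense", aa_change = "A-1-V",
      cortex_expressed = "yes", varsome_class = "VUS", disgenet_scz = FALSE,
      maf_exac = 1e-4, maf_gnomad = 1e-4, maf_1000g = NA_real_,
      siphy = 15, gerp_rs = 5, gerp_nr = 5, phylop100 = 5,
      phastcons100 = 1
    )
    dots <- list(...)
    defaults[names(dots)] <- dots
    tibble::as_tibble(defaults)
  }
  ann <- dplyr::bind_rows(
    base_ann("DECOY_LOWDEPTH", 1e6),
    base_ann("DECOY_DEPTH10", 2e6),
    base_ann("DECOY_COMMON", 3e6, maf_gnomad = 0.02),
    base_ann("DECOY_MAFBOUND", 4e6, maf_exac = 0.01),
    base_ann("DECOY_NONSENSE", 5e6, consequence = "nonsense"),
    base_ann("DECOY_SYNON", 6e6, consequence = "other"),
    base_ann("DECOY_INTWIN", 7e6),
    base_ann("DECOY_NOTSHARED", 8e6),
    base_ann("DECOY_MISSING", 9e6),
    base_ann("DECOY_NEUTRAL", 10e6,
      siphy = 2, gerp_rs = 0.5, phylop100 = -1, phastcons100 = 0.01)
  )
  planted <- tibble::tibble(
    chrom = ann$chrom, pos = as.integer(ann$pos), ref = ann$ref,
    alt = ann$alt, id = ann$rsid,
    carriers = list(
      shared3, shared3, shared3, shared3, shared3, shared3,
      c(shared3, "10"), # present in the healthy twin
      setdiff(shared3, "SCZ-8"), # not shared by every affected
      shared3, # genotype blanked below
      shared3
    )
  )
  edit_records <- function(records) {
    records |>
      dplyr::mutate(
        depth = dplyr::case_when(
          .data$pos == 1e6 & .data$chrom == "7" &
            .data$sample_id == "SCZ-7" ~ 8L,
          .data$pos == 2e6 & .data$chrom == "7" &
            .data$sample_id == "10" ~ 10L,
          .default = .data$depth
        ),
        gt = dplyr::if_else(
          .data$pos == 9e6 & .data$chrom == "7" &
            .data$sample_id == "SCA-3",
          "missing", .data$gt
        )
      )
  }
  list(annotations = ann, planted = planted, edit_records = edit_records)
}
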