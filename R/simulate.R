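#' Simulate pedigree-structured genotypes with planted variants
#'
#' Background variants are drawn under Hardy–Weinberg equilibrium in the
#' founders (allele frequencies log-uniform over `maf_range`, positions
#' uniform over a toy chromosome) and transmitted to offspring by random
#' Mendelian segregation of one allele per parent. Planted variants force
#' a heterozygous genotype onto a named carrier set (everyone else is
#' homozygous reference); a planted carrier set that cannot arise by
#' transmission — a non-founder carrier with two known non-carrier
#' parents — is rejected with an error. Per-sample read depths are drawn
#' from a Poisson truncated at 1 unless fixed.
#'
#' @param ped Pedigree tibble.
#' @param planted Optional tibble with columns `chrom`, `pos`, `ref`,
#'   `alt`, `id` and a list-column `carriers` of member ids.
#' @param n_background Number of background variants.
#' @param maf_range Range of background minor-allele frequencies.
#' @param background_chrom,chrom_length Toy chromosome name and length for
#'   background positions.
#' @param depth Fixed read depth for every call, or `NULL` to draw from
#'   `Poisson(depth_mean)` truncated at 1.
#' @param depth_mean Mean of the depth distribution.
#' @param seed Random seed (`NULL` to use the current RNG state).
#' @return A long genotype tibble (one row per variant per member) as
#'   produced by [read_vcf()], with `attr(, "samples")` in pedigree order.
#' @export
simulate_pedigree_vcf <- function(ped, planted = NULL, n_background = 0,
                                  maf_range = c(1e-4, 0.5),
                                  background_chrom = "1",
                                  chrom_length = 5e6,
                                  depth = NULL, depth_mean = 40,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  members <- ped$member_id
  gen_order <- generation_order(ped)

  variants <- list()
  doses <- list()

  if (!is.null(planted)) {
    for (i in seq_len(nrow(planted))) {
      carriers <- planted$carriers[[i]]
      bad <- setdiff(carriers, members)
      if (length(bad) > 0L) {
        abort(paste0("planted carriers not in pedigree: ",
          paste(bad, collapse = ", ")))
      }
      check_plantable(ped, carriers)
      d <- setNames(as.integer(members %in% carriers), members)
      variants[[length(variants) + 1L]] <- planted[i, c("chrom", "pos",
        "ref", "alt", "id")]
      doses[[length(doses) + 1L]] <- d
    }
  }

  if (n_background > 0L) {
    pos <- sort(sample.int(chrom_length, n_background))
    maf <- exp(runif(n_background, log(maf_range[1]), log(maf_range[2])))
    bases <- c("A", "C", "G", "T")
    for (i in seq_len(n_background)) {
      ref <- sample(bases, 1L)
      alt <- sample(setdiff(bases, ref), 1L)
      d <- transmit_dose(ped, gen_order, maf[i])
      variants[[length(variants) + 1L]] <- tibble::tibble(
        chrom = background_chrom, pos = pos[i], ref = ref, alt = alt,
        id = NA_character_
      )
      doses[[length(doses) + 1L]] <- d
    }
  }

  if (length(variants) == 0L) {
    out <- tibble::tibble(
      chrom = character(), pos = integer(), id = character(),
      ref = character(), alt = character(), sample_id = character(),
      gt = character(), depth = integer()
    )
    attr(out, "samples") <- members
    return(out)
  }

  n_var <- length(variants)
  depths <- if (is.null(depth)) {
    pmax(1L, rpois(n_var * length(members), depth_mean))
  } else {
    rep(as.integer(depth), n_var * length(members))
  }
  out <- purrr::map2(variants, doses, function(v, d) {
    tibble::tibble(
      chrom = v$chrom, pos = as.integer(v$pos), id = v$id,
      ref = v$ref, alt = v$alt,
      sample_id = members,
      gt = GT_LEVELS[d[members] + 1L]
    )
  }) |>
    dplyr::bind_rows() |>
    dplyr::mutate(depth = depths) |>
    dplyr::relocate("chrom", "pos", "id", "ref", "alt", "sample_id", "gt",
      "depth")
  attr(out, "samples") <- members
  out
}

# members ordered so parents precede children
generation_order <- function(ped) {
  remaining <- ped$member_id
  placed <- character()
  while (length(remaining) > 0L) {
    i <- match(remaining, ped$member_id)
    ready <- (is.na(ped$father_id[i]) | ped$father_id[i] %in% placed) &
      (is.na(ped$mother_id[i]) | ped$mother_id[i] %in% placed)
    if (!any(ready)) abort("pedigree is not acyclic")
    placed <- c(placed, remaining[ready])
    remaining <- remaining[!ready]
  }
  placed
}

check_plantable <- function(ped, carriers) {
  for (id in carriers) {
    i <- match(id, ped$member_id)
    parents <- c(ped$father_id[i], ped$mother_id[i])
    parents <- parents[!is.na(parents)]
    if (length(parents) > 0L && !any(parents %in% carriers)) {
      abort(paste0(
        "planted carrier set is Mendelian-impossible: ", id,
        " carries the variant but neither parent does"
      ))
    }
  }
  invisible()
}

transmit_dose <- function(ped, gen_order, maf) {
  dose <- setNames(integer(nrow(ped)), ped$member_id)
  for (id in gen_order) {
    i <- match(id, ped$member_id)
    if (is.na(ped$father_id[i])) {
      dose[[id]] <- rbinom(1L, 2L, maf)
    } else {
      gamete <- function(parent_dose) {
        if (parent_dose == 1L) rbinom(1L, 1L, 0.5) else parent_dose %/% 2L
      }
      dose[[id]] <- gamete(dose[[ped$father_id[i]]]) +
        gamete(dose[[ped$mother_id[i]]])
    }
  }
  dose
}

#' Simulate a BAF/LRR SNP-array probe track
#'
#' Probes are placed every `probe_spacing` bp. Each probe's B-allele dose
#' is binomial in the local copy number at population frequency
#' `pop_freq`, giving cluster means at \{0, 1/2, 1\} for two copies,
#' \{0, 1/3, 2/3, 1\} inside a duplication and \{0, 1\} inside a deletion;
#' Gaussian noise is added and the BAF clipped to \[0, 1\]. LRR is the
#' state mean (0, `+lrr_dup`, `-lrr_del`) plus Gaussian noise. A fixed
#' number of no-call probes (`round(nc_rate * n_probes)`) is injected at
#' random positions so the realized missing call rate hits the target.
#'
#' @param sample_id Sample identifier for the track.
#' @param chrom Chromosome name.
#' @param n_probes Number of probes.
#' @param probe_spacing Distance between consecutive probes in bp.
#' @param cn_profile Optional tibble (`start`, `end`, `cn`) of planted
#'   non-diploid intervals (1-based inclusive, non-overlapping).
#' @param offset Position of the track start; probe i sits at
#'   `offset + i * probe_spacing`.
#' @param pop_freq Population B-allele frequency at every probe.
#' @param baf_sd,lrr_sd Gaussian noise standard deviations (0 for
#'   noise-free tracks).
#' @param lrr_dup,lrr_del LRR displacement of three- and one-copy states.
#' @param nc_rate Target missing call rate.
#' @param seed Random seed (`NULL` to use the current RNG state).
#' @return A probe tibble (`sample_id`, `probe_id`, `chrom`, `pos`,
#'   `call`, `baf`, `lrr`) sorted by position.
#' @export
simulate_array_track <- function(sample_id, chrom, n_probes,
                                 probe_spacing = 2000, cn_profile = NULL,
                                 offset = 0, pop_freq = 0.5,
                                 baf_sd = 0.03, lrr_sd = 0.15,
                                 lrr_dup = 0.4, lrr_del = 0.6,
                                 nc_rate = 0.005, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pos <- offset + probe_spacing * seq_len(n_probes)
  cn <- rep(2L, n_probes)
  if (!is.null(cn_profile)) {
    for (i in seq_len(nrow(cn_profile))) {
      inside <- pos >= cn_profile$start[i] & pos <= cn_profile$end[i]
      cn[inside] <- as.integer(cn_profile$cn[i])
    }
  }
  b_dose <- rbinom(n_probes, cn, pop_freq)
  baf_mean <- b_dose / cn
  baf <- pmin(1, pmax(0, baf_mean + rnorm(n_probes, 0, baf_sd)))
  lrr_mean <- c(-lrr_del, 0, lrr_dup)[match(cn, c(1L, 2L, 3L))]
  lrr <- lrr_mean + rnorm(n_probes, 0, lrr_sd)
  call <- dplyr::case_when(
    baf < 0.25 ~ "AA",
    baf > 0.75 ~ "BB",
    .default = "AB"
  )
  n_nc <- round(nc_rate * n_probes)
  if (n_nc > 0L) {
    call[sample.int(n_probes, n_nc)] <- "NC"
  }
  tibble::tibble(
    sample_id = sample_id,
    probe_id = paste0(chrom, "_", pos),
    chrom = chrom, pos = as.integer(pos),
    call = call, baf = baf, lrr = lrr
  )
}

#' Simulate a droplet digital PCR well pair
#'
#' The reference assay sees concentration `lambda_reference` (two copies);
#' the target assay sees `lambda_reference * true_cn / 2`. Each well's
#' positive-droplet count is binomial with success probability
#' `1 - exp(-lambda)` — the Poisson probability that a droplet receives at
#' least one template copy.
#'
#' @param sample_id Sample identifier.
#' @param true_cn True copy number at the target locus.
#' @param lambda_reference Reference concentration in copies per droplet.
#' @param n_droplets Droplets per well.
#' @param assay Target assay name.
#' @param seed Random seed (`NULL` to use the current RNG state).
#' @return A two-row well tibble (target and `reference_rpp30`).
#' @export
simulate_ddpcr_wells <- function(sample_id, true_cn,
                                 lambda_reference = 0.8,
                                 n_droplets = 20000,
                                 assay = "target_dup", seed = NULL) {
  stopifnot(lambda_reference > 0, true_cn >= 0)
  if (!is.null(seed)) set.seed(seed)
  lam_t <- lambda_reference * true_cn / 2
  tibble::tibble(
    sample_id = sample_id,
    assay = c(assay, "reference_rpp30"),
    n_droplets = as.integer(n_droplets),
    n_positive = c(
      rbinom(1L, n_droplets, 1 - exp(-lam_t)),
      rbinom(1L, n_droplets, 1 - exp(-lambda_reference))
    )
  )
}
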