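# Brute-force cascade oracle: evaluates every filter predicate
# independently per variant with plain base-R logic, sharing no code with
# run_cascade(). Returns the keys of variants passing all five core
# stages (depth, frequency, consequence, sharing, conservation).
brute_force_survivors <- function(records, ann, carriers, absent,
                                  min_depth = 10, maf_threshold = 0.01) {
  keys <- character()
  for (i in seq_len(nrow(ann))) {
    v <- ann[i, ]
    rows <- records[records$chrom == v$chrom & records$pos == v$pos &
      records$ref == v$ref & records$alt == v$alt, ]
    wes <- union(carriers, absent)
    depth_ok <- TRUE
    for (s in wes) {
      d <- rows$depth[rows$sample_id == s]
      if (length(d) != 1 || is.na(d) || d <= min_depth) depth_ok <- FALSE
    }
    maf_ok <- TRUE
    for (f in c(v$maf_exac, v$maf_gnomad, v$maf_1000g)) {
      if (!is.na(f) && f >= maf_threshold) maf_ok <- FALSE
    }
    conseq_ok <- !is.na(v$consequence) && v$consequence == "missense"
    shared_ok <- TRUE
    for (s in carriers) {
      g <- rows$gt[rows$sample_id == s]
      if (length(g) != 1 || !(g %in% c("het", "hom_alt"))) shared_ok <- FALSE
    }
    for (s in absent) {
      g <- rows$gt[rows$sample_id == s]
      if (length(g) != 1 || g != "hom_ref") shared_ok <- FALSE
    }
    cons_ok <- (!is.na(v$siphy) && v$siphy >= 8) ||
      (!is.na(v$gerp_rs) && !is.na(v$phylop100) &&
        v$gerp_rs >= 4 && v$phylop100 >= 1)
    if (depth_ok && maf_ok && conseq_ok && shared_ok && cons_ok) {
      keys <- c(keys, paste0(v$chrom, ":", v$pos, ":", v$ref, ">", v$alt))
    }
  }
  keys
}

# Random small cascade instance: up to `n_var` variants and the given
# samples, with genotypes, depths and annotations drawn to exercise every
# predicate (missing genotypes, NA frequencies, boundary depths included).
random_cascade_instance <- function(n_var, samples) {
  ann <- tibble::tibble(
    chrom = "1",
    pos = sort(sample.int(1e6, n_var)),
    ref = "A", alt = "G", rsid = NA_character_,
    gene = paste0("G", seq_len(n_var)),
    consequence = sample(c("missense", "nonsense", "other"), n_var,
      replace = TRUE, prob = c(0.7, 0.15, 0.15)),
    aa_change = "X-1-Y",
    cortex_expressed = sample(c("yes", "yes_low", "no"), n_var,
      replace = TRUE),
    varsome_class = sample(c("VUS", "benign", "likely_benign"), n_var,
      replace = TRUE),
    disgenet_scz = sample(c(TRUE, FALSE), n_var, replace = TRUE),
    maf_exac = sample(c(NA, 1e-4, 5e-3, 0.01, 0.02), n_var, replace = TRUE),
    maf_gnomad = sample(c(NA, 1e-4, 0.015), n_var, replace = TRUE),
    maf_1000g = sample(c(NA, 1e-3), n_var, replace = TRUE),
    siphy = sample(c(2, 7.9, 8, 15), n_var, replace = TRUE),
    gerp_rs = sample(c(NA, 0.5, 4, 5.5), n_var, replace = TRUE),
    gerp_nr = 5,
    phylop100 = sample(c(-1, 0.9, 1, 6), n_var, replace = TRUE),
    phastcons100 = stats::runif(n_var),
    sift_call = sample(c(NA, "D", "T"), n_var, replace = TRUE),
    polyphen2_call = sample(c(NA, "D", "P", "B"), n_var, replace = TRUE),
    mutassessor_call = sample(c(NA, "H", "M", "L", "N"), n_var,
      replace = TRUE),
    metasvm_call = sample(c(NA, "D", "T"), n_var, replace = TRUE),
    metalr_call = sample(c(NA, "D", "T"), n_var, replace = TRUE),
    fathmm_call = sample(c(NA, "D", "T"), n_var, replace = TRUE),
    lrt_call = sample(c(NA, "D", "N", "U"), n_var, replace = TRUE),
    muttaster_call = sample(c(NA, "A", "D", "N", "P"), n_var,
      replace = TRUE)
  )
  records <- tidyr::expand_grid(
    dplyr::select(ann, chrom, pos, ref, alt),
    sample_id = samples
  ) |>
    dplyr::mutate(
      id = NA_character_,
      gt = sample(c("hom_ref", "het", "hom_alt", "missing"),
        dplyr::n(), replace = TRUE, prob = c(0.35, 0.35, 0.15, 0.15)),
      depth = sample(c(5L, 10L, 11L, 40L), dplyr::n(), replace = TRUE,
        prob = c(0.1, 0.1, 0.2, 0.6))
    )
  list(ann = ann, records = records)
}

# variant keys of a (possibly empty) survivor table
survivor_keys <- function(df) {
  if (nrow(df) == 0L) {
    return(character())
  }
  paste0(df$chrom, ":", df$pos, ":", df$ref, ">", df$alt)
}

# pedigree used across tests without touching the packaged fixture
toy_trio_ped <- function() {
  as_pedigree(tibble::tibble(
    member_id = c("F", "M", "C1", "C2"),
    father_id = c(NA, NA, "F", "F"),
    mother_id = c(NA, NA, "M", "M"),
    sex = c("male", "female", "male", "female"),
    affection = c("unaffected", "psychosis", "psychosis", "unaffected"),
    sequenced = TRUE, arrayed = TRUE, nuclear = TRUE
  ))
}
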