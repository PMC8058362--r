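test_that("depth filter is strict at the boundary and counts by construction", {
  ped <- toy_trio_ped()
  planted <- tibble::tibble(
    chrom = "1", pos = 1:100 * 10L, ref = "A", alt = "G",
    id = NA_character_, carriers = rep(list("M"), 100)
  )
  recs <- simulate_pedigree_vcf(ped, planted = planted, depth = 40, seed = 2)
  # push 40 chosen variants to a failing depth in one sample each
  low <- recs$pos %in% (1:40 * 10L) & recs$sample_id == "C1"
  recs$depth[low] <- rep(c(5L, 10L), 20) # both clearly low and boundary
  kept <- filter_depth(recs, c("M", "C1"), min_depth = 10)
  expect_identical(dplyr::n_distinct(kept$pos), 60L)
  # depth 11 passes the strict > 10 rule
  recs11 <- dplyr::mutate(recs, depth = 11L)
  expect_identical(
    dplyr::n_distinct(filter_depth(recs11, c("M", "C1"))$pos), 100L
  )
  expect_error(filter_depth(recs, "ghost"), "absent")
})

test_that("frequency filter treats NA as pass and bounds strictly", {
  ann <- load_annotation_fixture()
  expect_true(filter_maf(ann[ann$gene == "MACF1", ]))
  expect_true(filter_maf(ann[ann$gene == "PDXP", ]))
  decoy <- dplyr::mutate(ann[1, ], maf_gnomad = 0.02)
  expect_false(filter_maf(decoy))
  boundary <- dplyr::mutate(ann[1, ], maf_exac = 0.01)
  expect_false(filter_maf(boundary))
  all_na <- dplyr::mutate(ann[1, ], maf_exac = NA, maf_gnomad = NA,
    maf_1000g = NA)
  expect_warning(res <- filter_maf(all_na), "no frequency")
  expect_true(res)
})

test_that("sharing filter requires carriers, excludes controls, drops missing", {
  recs <- tidyr::expand_grid(
    tibble::tibble(chrom = "1", pos = c(10L, 20L, 30L, 40L), ref = "A",
      alt = "G"),
    sample_id = c("m", "s1", "s2", "twin")
  ) |>
    dplyr::mutate(id = NA_character_, depth = 40L, gt = "hom_ref")
  set_gt <- function(recs, pos, sample, gt) {
    recs$gt[recs$pos == pos & recs$sample_id %in% sample] <- gt
    recs
  }
  recs <- recs |>
    set_gt(10L, c("m", "s1", "s2"), "het") |> # clean sharing
    set_gt(20L, c("m", "s1", "s2", "twin"), "het") |> # in the control
    set_gt(30L, c("m", "s1"), "het") |> # not shared by s2
    set_gt(40L, c("m", "s1"), "het") |>
    set_gt(40L, "s2", "missing") # unestablishable
  kept <- shared_only_in_affected(recs, c("m", "s1", "s2"), "twin")
  expect_identical(unique(kept$pos), 10L)
  # hom_alt counts as carrying
  kept2 <- shared_only_in_affected(set_gt(recs, 30L, "s2", "hom_alt"),
    c("m", "s1", "s2"), "twin")
  expect_setequal(unique(kept2$pos), c(10L, 30L))
  expect_error(shared_only_in_affected(recs, "m", "m"), "disjoint")
})

test_that("conservation rule matches the published profiles and rejects neutral ones", {
  ann <- load_annotation_fixture()
  expect_true(all(is_conserved(ann)))
  neutral <- dplyr::mutate(ann[1, ], siphy = 2, gerp_rs = 0.5,
    phylop100 = -1)
  expect_false(is_conserved(neutral))
  # the two-score branch works without SiPhy
  pair <- dplyr::mutate(ann[1, ], siphy = NA, gerp_rs = 4.5, phylop100 = 2)
  expect_true(is_conserved(pair))
  all_na <- dplyr::mutate(ann[1, ], siphy = NA, gerp_rs = NA,
    phylop100 = NA)
  expect_error(is_conserved(all_na), "no scores")
})

test_that("expression filter keeps low-expression categories, drops blanks", {
  ann <- load_annotation_fixture()
  expect_false(filter_expression(ann[ann$gene == "ACTBL2", ]))
  expect_true(filter_expression(ann[ann$gene == "ZPLD1", ]))
  expect_identical(sum(filter_expression(ann)), 17L)
})

test_that("protein-impact consensus counts the 8 categorical predictors", {
  ann <- load_annotation_fixture()
  cons <- consensus_deleterious(ann)
  n_of <- function(g) cons$n_damaging[ann$gene == g]
  expect_identical(n_of("ZRANB3"), 8L)
  expect_identical(n_of("MACF1"), 3L)
  expect_identical(n_of("MTMR11"), 7L) # NA cell (LRT) does not count
  expect_identical(n_of("TINF2"), 7L)
  flagged <- ann$gene[cons$flag]
  expect_setequal(intersect(flagged, ann$gene[ann$varsome_class == "VUS" &
    filter_expression(ann)]), c("MTMR11", "TINF2", "ZRANB3"))
  empty <- consensus_deleterious(dplyr::mutate(ann[1, ],
    dplyr::across(dplyr::ends_with("_call"), ~NA_character_)))
  expect_identical(empty$n_damaging, 0L)
  expect_false(empty$flag)
})

test_that("intolerance ranking is RVIS-primary with LOEUF tie-break, NA last", {
  genes <- tibble::tibble(
    gene = c("A", "B", "C", "D"),
    rvis = c(-1, -3.92, -1, NA),
    loeuf = c(0.5, 0.084, 0.1, 0.2)
  )
  expect_identical(rank_intolerance(genes)$gene, c("B", "C", "A", "D"))
  single <- genes[2, ]
  expect_identical(rank_intolerance(single)$gene, "B")
  ann <- load_annotation_fixture()
  ranked <- rank_intolerance(
    dplyr::select(ann, "gene", "rvis", "loeuf")
  )
  expect_identical(ranked$gene[1], "MACF1")
})

test_that("the full cascade reproduces the published funnel on the fixture", {
  b <- simulate_study_bundle(seed = 1)
  res <- run_cascade(b$records, b$annotations, b$ped)
  expect_identical(res$counts$n_survivors, 19L)
  # the planted stop-gain decoy is counted among shared rare variants
  expect_identical(res$counts$n_nonsense, 1L)
  expect_identical(res$counts$n_expressed, 17L)
  expect_identical(res$counts$n_vus, 9L)
  expect_identical(res$counts$n_benign, 8L)
  expect_setequal(res$consensus$gene, c("MTMR11", "TINF2", "ZRANB3"))
  expect_setequal(res$disgenet$gene, c("GLI2", "MACF1", "MCTP2"))
  expect_identical(res$candidates$gene, "MACF1")
  expect_setequal(res$caveat$gene, c("GLI2", "MCTP2"))
  # every decoy fails, none survives to the shared rare missense set
  expect_false(any(grepl("^DECOY", res$survivors$gene)))
  # glance/tidy expose counts and trace
  expect_identical(glance(res)$n_final, 1L)
  expect_true(all(c("variant", "stage", "passed") %in% names(tidy(res))))
})

test_that("each decoy fails at exactly its designated stage", {
  b <- simulate_study_bundle(seed = 1)
  res <- run_cascade(b$records, b$annotations, b$ped)
  failed_at <- tidy(res) |>
    dplyr::filter(!passed) |>
    dplyr::select(gene, stage)
  expected <- c(
    DECOY_LOWDEPTH = "depth", DECOY_DEPTH10 = "depth",
    DECOY_COMMON = "maf", DECOY_MAFBOUND = "maf",
    DECOY_NONSENSE = "consequence", DECOY_SYNON = "consequence",
    DECOY_INTWIN = "shared", DECOY_NOTSHARED = "shared",
    DECOY_MISSING = "shared", DECOY_NEUTRAL = "conserved"
  )
  for (g in names(expected)) {
    expect_identical(failed_at$stage[failed_at$gene == g],
      unname(expected[g]), info = g)
  }
  # the 19 family variants never fail a stage before expression
  fam_fail <- failed_at[!grepl("^DECOY", failed_at$gene), ]
  expect_true(all(fam_fail$stage == "expressed"))
  expect_setequal(fam_fail$gene, c("COL6A3", "ACTBL2"))
})

test_that("removing the top candidate leaves only caveat candidates", {
  b <- simulate_study_bundle(seed = 1)
  keep <- !(b$annotations$gene == "MACF1")
  ann2 <- b$annotations[keep, ]
  recs2 <- dplyr::anti_join(b$records,
    b$annotations[b$annotations$gene == "MACF1", ],
    by = c("chrom", "pos", "ref", "alt"))
  res <- run_cascade(recs2, ann2, b$ped)
  expect_identical(nrow(res$candidates), 0L)
  expect_setequal(res$caveat$gene, c("GLI2", "MCTP2"))
})

test_that("cascade stages are monotone and order-independent", {
  set.seed(42)
  samples <- c("a", "b", "c", "twin")
  for (i in 1:10) {
    inst <- random_cascade_instance(10, samples)
    res <- suppressWarnings(run_cascade(inst$records, inst$ann,
      toy_trio_ped(),
      carriers_required = c("a", "b"), must_be_absent = "twin"))
    # monotone: each successive set is a subset of the previous
    expect_true(all(res$expressed$gene %in% res$survivors$gene))
    expect_true(all(res$vus$gene %in% res$expressed$gene))
    expect_true(all(res$consensus$gene %in% res$vus$gene))
    expect_true(all(res$candidates$gene %in% res$disgenet$gene))
    # permuting inputs never changes the survivor set
    perm_ann <- inst$ann[sample(nrow(inst$ann)), ]
    perm_rec <- inst$records[sample(nrow(inst$records)), ]
    res_perm <- suppressWarnings(run_cascade(perm_rec, perm_ann,
      toy_trio_ped(),
      carriers_required = c("a", "b"), must_be_absent = "twin"))
    expect_setequal(res_perm$survivors$gene, res$survivors$gene)
  }
})

test_that("cascade matches the brute-force per-predicate oracle", {
  set.seed(7)
  for (i in 1:40) {
    n_var <- sample(3:12, 1)
    samples <- paste0("s", seq_len(sample(2:6, 1)))
    carriers <- samples[1]
    absent <- samples[length(samples)]
    if (identical(carriers, absent)) next
    inst <- random_cascade_instance(n_var, samples)
    res <- suppressWarnings(run_cascade(inst$records, inst$ann,
      toy_trio_ped(),
      carriers_required = carriers, must_be_absent = absent))
    got <- survivor_keys(res$survivors)
    want <- brute_force_survivors(inst$records, inst$ann, carriers, absent)
    expect_setequal(got, want)
  }
})

test_that("an empty record set yields an all-zero cascade", {
  b <- simulate_study_bundle(seed = 1)
  empty <- b$records[0, ]
  res <- run_cascade(empty, b$annotations, b$ped)
  expect_identical(res$counts$n_survivors, 0L)
  expect_identical(nrow(res$candidates), 0L)
  expect_identical(nrow(res$trace), 0L)
})
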