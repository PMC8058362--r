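test_that("the carrier matrix reproduces the published carrier sets", {
  ped <- majorcan_pedigree()
  m <- build_carrier_matrix(majorcan_carrier_evidence(), ped)
  carriers <- function(lesion) {
    m$member_id[m$lesion == lesion & m$state == "carrier"]
  }
  expect_setequal(carriers("DUP3p26.3"),
    c("SCA-3", "SCZ-7", "SCA-9", "10", "11"))
  expect_setequal(carriers("DUP16q23.3"),
    c("SCA-3", "SCZ-8", "SCA-9", "10", "11", "4", "13"))
  expect_setequal(carriers("SNV_MACF1"),
    c("SCA-3", "SCZ-7", "SCZ-8", "SCA-9"))
  expect_setequal(carriers("SNV_GLI2"), c("SCA-3", "SCZ-7", "SCZ-8"))
  # every (member, lesion) pair is present
  expect_identical(nrow(m), nrow(ped) * 4L)
})

test_that("evidence tiers resolve by precedence and flag conflicts", {
  ped <- toy_trio_ped()
  ev <- tibble::tibble(
    member_id = c("C1", "C1", "C2", "C2", "F"),
    lesion = "DUP1",
    source = c("array", "ddpcr", "ddpcr", "ddpcr", "array"),
    state = c("carrier", "non_carrier", "carrier", "non_carrier", "carrier")
  )
  expect_warning(
    expect_warning(m <- build_carrier_matrix(ev, ped), "overridden"),
    "conflicting"
  )
  # ddPCR overrides the array call
  expect_identical(m$state[m$member_id == "C1"], "non_carrier")
  # same-tier contradiction is unknown
  expect_identical(m$state[m$member_id == "C2"], "unknown")
  expect_identical(m$state[m$member_id == "F"], "carrier")
  # no evidence at all
  expect_identical(m$state[m$member_id == "M"], "unknown")
})

test_that("removing evidence only moves states toward unknown", {
  ped <- majorcan_pedigree()
  ev <- majorcan_carrier_evidence()
  full <- build_carrier_matrix(ev, ped)
  set.seed(31)
  for (i in 1:20) {
    sub <- ev[sample(nrow(ev), nrow(ev) %/% 2), ]
    reduced <- suppressWarnings(
      build_carrier_matrix(sub, ped, lesions = unique(ev$lesion))
    )
    j <- dplyr::inner_join(full, reduced, by = c("member_id", "lesion"),
      suffix = c("_full", "_red"))
    changed <- j$state_full != j$state_red
    expect_true(all(j$state_red[changed] == "unknown"))
  }
})

test_that("the published digenic rule is fully consistent; alternatives are not", {
  ped <- majorcan_pedigree()
  m <- build_carrier_matrix(majorcar <- majorcan_carrier_evidence(), ped)
  dups <- c("DUP3p26.3", "DUP16q23.3")

  res <- evaluate_digenic(m, ped, digenic_model("SNV_MACF1", dups))
  expect_identical(res$consistency_fraction, 1)
  expect_identical(res$n_evaluable, 7L)

  # duplications alone over-predict: the healthy twins carry both
  dup_only <- evaluate_digenic(m, ped, digenic_model(NULL, dups))
  expect_lt(dup_only$consistency_fraction, 1)
  expect_setequal(dup_only$inconsistent_members, c("10", "11"))

  # the GLI2 rule misses the affected non-carrier SCA-9
  gli2 <- evaluate_digenic(m, ped, digenic_model("SNV_GLI2", dups))
  expect_true("SCA-9" %in% gli2$inconsistent_members)

  scan <- exhaustive_model_scan(m, ped,
    snvs = c("SNV_MACF1", "SNV_GLI2"), cnvs = dups)
  expect_identical(nrow(scan), 6L)
  expect_identical(scan$snv[1], "SNV_MACF1")
  expect_identical(scan$cnvs[1], "DUP3p26.3,DUP16q23.3")
  expect_identical(scan$consistency_fraction[1], 1)

  expect_error(evaluate_digenic(m, ped, digenic_model("SNV_NOPE", dups)),
    "absent lesion")
})

test_that("consistency is symmetric under member and lesion relabelling", {
  ped <- majorcan_pedigree()
  ev <- majorcan_carrier_evidence()
  base <- evaluate_digenic(build_carrier_matrix(ev, ped), ped,
    digenic_model("SNV_MACF1", c("DUP3p26.3", "DUP16q23.3")))
  relabel <- function(x) paste0("L_", x)
  ev2 <- dplyr::mutate(ev, lesion = relabel(lesion))
  res2 <- evaluate_digenic(build_carrier_matrix(ev2, ped), ped,
    digenic_model("L_SNV_MACF1", relabel(c("DUP3p26.3", "DUP16q23.3"))))
  expect_identical(res2$consistency_fraction, base$consistency_fraction)
  expect_identical(res2$n_evaluable, base$n_evaluable)
})

test_that("an all-unknown matrix reports no evaluable members", {
  ped <- toy_trio_ped()
  ev <- tibble::tibble(
    member_id = character(), lesion = character(),
    source = character(), state = character()
  )
  m <- build_carrier_matrix(ev, ped, lesions = c("SNV_X", "DUP_Y"))
  res <- evaluate_digenic(m, ped, digenic_model("SNV_X", "DUP_Y"))
  expect_identical(res$n_evaluable, 0L)
  expect_true(is.na(res$consistency_fraction))
})

test_that("asymmetric mode tolerates unaffected at-risk carriers", {
  ped <- toy_trio_ped()
  ev <- tidyr::expand_grid(
    member_id = ped$member_id, lesion = c("SNV_X", "DUP_Y")
  ) |>
    dplyr::mutate(source = "sanger", state = "carrier")
  m <- build_carrier_matrix(ev, ped, lesions = c("SNV_X", "DUP_Y"))
  model <- digenic_model("SNV_X", "DUP_Y")
  strict <- evaluate_digenic(m, ped, model, mode = "strict")
  lenient <- evaluate_digenic(m, ped, model, mode = "asymmetric")
  # everyone carries both lesions; F and C2 are unaffected
  expect_identical(strict$consistency_fraction, 0.5)
  expect_identical(lenient$consistency_fraction, 1)
})

test_that("a planted fully penetrant digenic rule is always ranked first", {
  set.seed(77)
  for (rep in 1:50) {
    ped <- toy_trio_ped()
    lesions <- c("SNV_A", "SNV_B", "DUP_1", "DUP_2")
    states <- matrix(
      sample(c("carrier", "non_carrier"), nrow(ped) * 4, replace = TRUE),
      nrow(ped), 4, dimnames = list(ped$member_id, lesions)
    )
    # plant the rule SNV_A + any(DUP_1): affection follows it exactly
    at_risk <- states[, "SNV_A"] == "carrier" & states[, "DUP_1"] == "carrier"
    ped$affection <- ifelse(at_risk, "psychosis", "unaffected")
    ev <- tidyr::expand_grid(member_id = ped$member_id, lesion = lesions) |>
      dplyr::mutate(
        source = "sanger",
        state = states[cbind(member_id, lesion)]
      )
    m <- build_carrier_matrix(ev, ped, lesions = lesions)
    planted <- evaluate_digenic(m, ped, digenic_model("SNV_A", "DUP_1"))
    expect_identical(planted$consistency_fraction, 1)
    scan <- exhaustive_model_scan(m, ped, snvs = c("SNV_A", "SNV_B"),
      cnvs = c("DUP_1", "DUP_2"))
    top <- scan[scan$consistency_fraction == 1, ]
    expect_true(any(top$snv == "SNV_A" & grepl("DUP_1", top$cnvs)))
  }
})
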