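test_that("eligibility requires a presentation arm and a context arm", {
  # bicytopenia with pediatric onset
  rec <- mk_record(cbc = cbc1(age = 3, hb = 9, plt = 90000))
  el <- check_eligibility(rec, profile1(rec), test_catalog, test_config)
  expect_true(el$eligible)
  # nothing at all
  empty <- mk_record()
  expect_false(check_eligibility(empty, profile1(empty), test_catalog, test_config)$eligible)
  # no cytopenia, but EPI + short stature (two organ systems) + consanguinity
  pheno <- mk_record(
    feats = c("HP:0001738", "HP:0004322"),
    family = family_history(consanguinity_degree = 3)
  )
  el2 <- check_eligibility(pheno, profile1(pheno), test_catalog, test_config)
  expect_true(el2$eligible)
  expect_true(any(grepl("family history", el2$reasons)))
  # two terms in ONE organ system do not satisfy the manifestation arm
  one_sys <- mk_record(feats = c("HP:0012758", "HP:0001250"))
  expect_false(check_eligibility(one_sys, profile1(one_sys), test_catalog, test_config)$eligible)
})

test_that("exclusion gate separates acquired causes and confirmed FA", {
  deb_pos <- mk_record(labs = lab_panel(deb_test = "positive"))
  expect_identical(exclusion_gate(deb_pos)$status, "FA_confirmed")
  clean <- mk_record(labs = lab_panel(
    deb_test = "negative", viral_serology_positive = FALSE,
    nutritional_deficiency = FALSE, drug_radiation_exposure = FALSE,
    pnh_clone = FALSE
  ))
  expect_identical(exclusion_gate(clean)$status, "none")
  expect_length(exclusion_gate(clean)$incomplete_workup, 0)
  b12 <- mk_record(labs = lab_panel(nutritional_deficiency = TRUE))
  out <- exclusion_gate(b12)
  expect_identical(out$status, "acquired")
  expect_identical(out$evidence, "nutritional_deficiency")
})

test_that("unknown work-up states never trigger exclusion", {
  fields <- c(
    "viral_serology_positive", "nutritional_deficiency",
    "drug_radiation_exposure", "pnh_clone"
  )
  for (f in fields) {
    args <- setNames(list(FALSE), f)
    neg <- mk_record(labs = do.call(lab_panel, args))
    args[[f]] <- NA
    unk <- mk_record(labs = do.call(lab_panel, args))
    expect_identical(exclusion_gate(neg)$status, "none", label = f)
    expect_identical(exclusion_gate(unk)$status, "none", label = f)
    expect_true(f %in% exclusion_gate(unk)$incomplete_workup)
  }
})

test_that("beacons follow the history definitions", {
  end <- mk_record(family = family_history(settlement_population = 3000))
  expect_true(detect_beacons(end, test_catalog, test_config)$endogamy)
  big <- mk_record(family = family_history(settlement_population = 5000))
  expect_false(detect_beacons(big, test_catalog, test_config)$endogamy)
  cons <- mk_record(family = family_history(consanguinity_degree = 3))
  expect_true(detect_beacons(cons, test_catalog, test_config)$consanguinity)
  blank <- mk_record()
  b <- detect_beacons(blank, test_catalog, test_config)
  expect_false(any(unlist(b)))
  phys <- mk_record(feats = "HP:0004322")
  expect_true(detect_beacons(phys, test_catalog, test_config)$physical_alterations)
})

test_that("DC rule: triad element plus cytopenia, or the complete triad alone", {
  thrombo_nail <- mk_record(
    feats = "HP:0002164",
    cbc = cbc1(age = 5, plt = 60000)
  )
  f <- evaluate_dc(thrombo_nail, profile1(thrombo_nail), test_catalog, test_config)
  expect_true(f$fired)
  expect_identical(f$pathway, "hematologic+phenotype")
  # the parent nail-abnormality term satisfies the nail element too
  parent_nail <- mk_record(feats = "HP:0001597", cbc = cbc1(age = 5, plt = 60000))
  expect_true(evaluate_dc(parent_nail, profile1(parent_nail), test_catalog, test_config)$fired)
  # pancytopenia without any triad element is not DC
  pan <- mk_record(cbc = cbc1(age = 5, hb = 8, anc = 300, plt = 40000))
  expect_false(evaluate_dc(pan, profile1(pan), test_catalog, test_config)$fired)
  # complete triad with a normal CBC fires phenotype-only
  triad <- mk_record(
    feats = c("HP:0002745", "HP:0002164", "HP:0007427"),
    cbc = cbc1()
  )
  f2 <- evaluate_dc(triad, profile1(triad), test_catalog, test_config)
  expect_true(f2$fired)
  expect_identical(f2$pathway, "phenotype_only")
  expect_true(f2$complete_triad)
  # one triad element without cytopenia does not fire
  partial <- mk_record(feats = "HP:0007427", cbc = cbc1())
  expect_false(evaluate_dc(partial, profile1(partial), test_catalog, test_config)$fired)
})

test_that("SDS rule: three associated features, or a positive fecal fat test", {
  three <- mk_record(
    feats = c("HP:0001738", "HP:0004322", "HP:0002024"),
    cbc = cbc1(age = 4, anc = 800)
  )
  expect_true(evaluate_sds(three, profile1(three), test_catalog, test_config)$fired)
  two <- mk_record(
    feats = c("HP:0004322", "HP:0002024"),
    cbc = cbc1(age = 4, anc = 800)
  )
  expect_false(evaluate_sds(two, profile1(two), test_catalog, test_config)$fired)
  # FFQT positive counts as EPI and fires phenotype-only without cytopenia
  ffqt <- mk_record(labs = lab_panel(ffqt = "positive"))
  f <- evaluate_sds(ffqt, profile1(ffqt), test_catalog, test_config)
  expect_true(f$fired)
  expect_identical(f$pathway, "phenotype_only")
  expect_true(any(f$matched_criteria$evidence == "FFQT positive"))
  # FFQT positive with cytopenia fires regardless of feature count
  ffqt_cyt <- mk_record(labs = lab_panel(ffqt = "positive"), cbc = cbc1(age = 4, anc = 800))
  expect_true(evaluate_sds(ffqt_cyt, profile1(ffqt_cyt), test_catalog, test_config)$fired)
})

test_that("DBA rule: macrocytic anemia with reticulocytopenia, minors score", {
  hit <- mk_record(
    feats = "HP:0000414", # bulbous nasal tip, a craniofacial minor
    cbc = cbc1(age = 2, hb = 8, mcv = 98, retic = 8)
  )
  f <- evaluate_dba(hit, profile1(hit), test_catalog, test_config)
  expect_true(f$fired)
  expect_identical(f$n_minor, 1L)
  expect_false(f$classic_dba)
  normo <- mk_record(cbc = cbc1(age = 2, hb = 8, mcv = 80, retic = 8))
  expect_false(evaluate_dba(normo, profile1(normo), test_catalog, test_config)$fired)
  # classic flag: onset < 1 y plus erythroid paucity on biopsy
  classic <- mk_record(
    cbc = cbc1(age = 0.7, hb = 8, mcv = 98, retic = 8),
    labs = lab_panel(bm_biopsy = c("hypocellular", "erythroid_paucity"))
  )
  expect_true(evaluate_dba(classic, profile1(classic), test_catalog, test_config)$classic_dba)
})

test_that("TAR rule: thrombocytopenia plus radial-ray defect, thumbs preserved", {
  tar <- mk_record(
    feats = c("HP:0003974", "HP:0001627"),
    cbc = cbc1(age = 0.1, plt = 40000)
  )
  f <- evaluate_tar(tar, profile1(tar), test_catalog, test_config)
  expect_true(f$fired)
  expect_false(f$fa_cross_flag)
  no_limb <- mk_record(cbc = cbc1(age = 0.1, plt = 40000))
  expect_false(evaluate_tar(no_limb, profile1(no_limb), test_catalog, test_config)$fired)
  # asserted thumb agenesis vetoes TAR and raises the FA cross-flag
  veto <- mk_record(
    feats = c("HP:0003974", "HP:0009777"),
    cbc = cbc1(age = 0.1, plt = 40000)
  )
  fv <- evaluate_tar(veto, profile1(veto), test_catalog, test_config)
  expect_false(fv$fired)
  expect_true(fv$fa_cross_flag)
  # a hypoplastic (present) thumb does not veto
  hypo <- mk_record(
    feats = c("HP:0003974", "HP:0009778"),
    cbc = cbc1(age = 0.1, plt = 40000)
  )
  expect_true(evaluate_tar(hypo, profile1(hypo), test_catalog, test_config)$fired)
})

test_that("SCN rule: lifelong or cyclic neutropenia with two associated features", {
  cyc <- data.frame(
    age_years = seq(0.2, by = 0.25, length.out = 6),
    hb = 12.5, mcv = 80,
    anc = c(400, 1700, 300, 1600, 350, 1700),
    platelets = 200000, retic_abs = 40
  )
  scn <- mk_record(feats = c("HP:0004322", "HP:0001627"), cbc = cyc, age = 2)
  expect_true(evaluate_scn(scn, profile1(scn), test_catalog, test_config)$fired)
  # one isolated neutropenic CBC fails persistence at the default fraction
  iso <- mk_record(
    feats = c("HP:0004322", "HP:0001627"),
    cbc = rbind(cbc1(age = 1), cbc1(age = 2, anc = 400), cbc1(age = 3), cbc1(age = 4))
  )
  expect_false(evaluate_scn(iso, profile1(iso), test_catalog, test_config)$fired)
  # persistent neutropenia with only one associated feature does not fire
  pers <- data.frame(
    age_years = 1:4, hb = 12.5, mcv = 80, anc = c(400, 350, 450, 300),
    platelets = 200000, retic_abs = 40
  )
  one <- mk_record(feats = "HP:0004322", cbc = pers, age = 5)
  expect_false(evaluate_scn(one, profile1(one), test_catalog, test_config)$fired)
})

test_that("FA referral: VACTERL-H/PHENOS pattern while the DEB test is outstanding", {
  fa <- mk_record(
    feats = c("HP:0000957", "HP:0000252"), # CALM + microcephaly
    cbc = cbc1(age = 2, hb = 8, mcv = 98, retic = 45)
  )
  f <- evaluate_fa(fa, profile1(fa), test_catalog, test_config)
  expect_true(f$fired)
  expect_identical(f$action, "order DEB test")
  out <- classify1(fa)
  expect_identical(out$primary, "FA_referral")
  # three-term phenotype-only arm with a normal CBC
  fa3 <- mk_record(feats = c("HP:0009777", "HP:0000077", "HP:0004322"), cbc = cbc1())
  f3 <- evaluate_fa(fa3, profile1(fa3), test_catalog, test_config)
  expect_true(f3$fired)
  expect_identical(f3$pathway, "phenotype_only")
  # a documented negative DEB test stands down the referral
  neg <- mk_record(
    feats = c("HP:0000957", "HP:0000252"),
    cbc = cbc1(age = 2, hb = 8, mcv = 98, retic = 45),
    labs = lab_panel(deb_test = "negative")
  )
  fneg <- evaluate_fa(neg, profile1(neg), test_catalog, test_config)
  expect_false(fneg$fired)
  expect_true(fneg$pattern_present)
  expect_identical(classify1(neg)$primary, "undefined_IBMFS")
})

test_that("classify applies precedence and keeps all fired findings", {
  # a record firing both TAR and DBA resolves to TAR with DBA in the audit
  dual <- mk_record(
    feats = "HP:0003974",
    cbc = cbc1(age = 1, hb = 8, mcv = 98, plt = 40000, retic = 8),
    labs = lab_panel(deb_test = "negative")
  )
  out <- classify1(dual)
  expect_identical(out$primary, "TAR")
  expect_true(out$findings$DBA$fired)
  expect_true(any(grepl("precedence: TAR over.*DBA", out$audit)))
  # eligible record firing nothing falls back to undefined
  ui <- mk_record(
    feats = "HP:0000414",
    cbc = cbc1(age = 3, hb = 9, mcv = 80, plt = 90000, retic = 40),
    labs = lab_panel(deb_test = "negative")
  )
  expect_identical(classify1(ui)$primary, "undefined_IBMFS")
  # ineligible record short-circuits with no findings
  blank <- mk_record()
  out_b <- classify1(blank)
  expect_identical(out_b$primary, "not_eligible")
  expect_length(out_b$findings, 0)
  # excluded record: no findings evaluated
  excl <- mk_record(
    cbc = cbc1(age = 3, hb = 8, plt = 60000),
    labs = lab_panel(nutritional_deficiency = TRUE)
  )
  out_e <- classify1(excl)
  expect_identical(out_e$excluded_as, "acquired")
  expect_length(out_e$findings, 0)
})

test_that("classification is deterministic including the audit log", {
  fixture <- build_reference_fixture(test_catalog)
  r1 <- classify(fixture[[13]], test_catalog, test_config)
  r2 <- classify(fixture[[13]], test_catalog, test_config)
  expect_identical(unclass(r1), unclass(r2))
})

test_that("exactly one primary label is assigned to every fixture record", {
  fixture <- build_reference_fixture(test_catalog)
  res <- classify_cohort(fixture, test_catalog, test_config)
  expect_true(all(nchar(res$primary) > 0))
  expect_length(res$primary, 48)
  valid <- c(
    "DC", "SDS", "DBA", "TAR", "SCN", "FA_referral",
    "undefined_IBMFS", "not_eligible"
  )
  expect_true(all(res$primary %in% valid))
})

test_that("tidy and glance methods expose findings as tibbles", {
  fixture <- build_reference_fixture(test_catalog)
  out <- classify(fixture[[20]], test_catalog, test_config)
  td <- tidy(out)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$syndrome, c("FA", "TAR", "SCN", "DC", "SDS", "DBA"))
  gl <- glance(out)
  expect_identical(nrow(gl), 1L)
  expect_identical(gl$primary, "DBA")
})
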