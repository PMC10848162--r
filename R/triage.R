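#' @title The triage decision algorithm
#' @description The classifier walks a fixed pipeline: an eligibility gate,
#'   exclusion of acquired causes (and of confirmed Fanconi anemia on a
#'   positive DEB breakage test), detection of hereditary-suspicion beacons,
#'   then six per-syndrome suspicion rules. When several rules fire, a fixed
#'   precedence — structural hallmark first: TAR > SCN > DC > SDS > DBA —
#'   picks the primary suspicion; all fired findings remain in the result.
#'   An eligible, non-excluded record firing no rule is labelled
#'   `undefined_IBMFS`.
#' @name triage
NULL

syndrome_labels <- c("DC", "SDS", "DBA", "TAR", "SCN")

# does the record carry any cytopenia or BMF evidence (CBC-based class or an
# asserted hematologic feature)
any_cytopenia <- function(record, profile, catalog) {
  profile$worst_class$value != "none" ||
    length(match_features(record, catalog$groups$hematologic, catalog)) > 0
}

#' Eligibility gate
#'
#' A record enters the triage pipeline when it shows
#' (a) any cytopenia/BMF evidence OR at least two non-hematological
#' manifestations in distinct organ-system groups of the catalog, AND
#' (b) at least one of: positive family history (consanguinity, endogamy or
#' familial hematologic disorder), at least one physical abnormality, or
#' hematologic onset before 18 years.
#'
#' @param record An `ibmfs_patient`.
#' @param profile Its [hematology_profile()].
#' @param catalog An `ibmfs_catalog`.
#' @param config Run configuration.
#' @return A list with `eligible` (logical) and `reasons` (character).
#' @export
check_eligibility <- function(record, profile, catalog = load_catalog(),
                              config = default_config()) {
  reasons <- character()
  cyt <- any_cytopenia(record, profile, catalog)
  if (cyt) reasons <- c(reasons, "cytopenia or BMF evidence")
  systems <- nonhematologic_systems(record, catalog)
  if (length(systems) >= 2) {
    reasons <- c(reasons, paste0(
      ">=2 non-hematological manifestations (",
      paste(systems, collapse = ", "), ")"
    ))
  }
  arm1 <- cyt || length(systems) >= 2

  fam <- record$family
  family_pos <- isTRUE(!is.na(fam$consanguinity_degree)) ||
    (!is.na(fam$settlement_population) &&
      fam$settlement_population < config$thresholds$endogamy_population_max) ||
    isTRUE(fam$hematological_disorder_in_family)
  if (family_pos) reasons <- c(reasons, "positive family history")
  physical <- length(systems) >= 1
  if (physical) reasons <- c(reasons, "physical abnormality")
  pediatric_onset <- !is.na(profile$onset_age_years) &&
    profile$onset_age_years < config$thresholds$onset_pediatric_max
  if (pediatric_onset) reasons <- c(reasons, "hematologic onset < 18 y")
  arm2 <- family_pos || physical || pediatric_onset

  list(eligible = arm1 && arm2, reasons = reasons)
}

# distinct non-hematologic organ systems with at least one asserted feature
nonhematologic_systems <- function(record, catalog) {
  sys <- catalog$organ_systems
  sys <- sys[names(sys) != "hematologic"]
  names(sys)[vapply(sys, function(root) has_feature(record, root, catalog), logical(1))]
}

#' Exclusion gate: acquired causes and confirmed Fanconi anemia
#'
#' A positive DEB chromosomal-breakage test is a confirmed FA diagnosis and
#' terminates triage. An explicit positive acquired-cause screen
#' (nutritional deficiency, positive viral serology, drug/radiation
#' exposure, PNH clone) excludes the record as acquired. Unknown (`NA`)
#' states never trigger exclusion; they are listed as incomplete work-up.
#'
#' @param record An `ibmfs_patient`.
#' @return List with `status` (`"none"`, `"acquired"`, `"FA_confirmed"`),
#'   `evidence` (character) and `incomplete_workup` (character).
#' @export
exclusion_gate <- function(record) {
  labs <- record$labs
  if (identical(labs$deb_test, "positive")) {
    return(list(
      status = "FA_confirmed", evidence = "deb_test positive",
      incomplete_workup = character()
    ))
  }
  screens <- c(
    nutritional_deficiency = labs$nutritional_deficiency,
    viral_serology_positive = labs$viral_serology_positive,
    drug_radiation_exposure = labs$drug_radiation_exposure,
    pnh_clone = labs$pnh_clone
  )
  incomplete <- names(screens)[is.na(screens)]
  if (identical(labs$deb_test, "not_done")) incomplete <- c(incomplete, "deb_test")
  positive <- names(screens)[!is.na(screens) & screens]
  if (length(positive) > 0) {
    return(list(
      status = "acquired", evidence = positive,
      incomplete_workup = incomplete
    ))
  }
  list(status = "none", evidence = character(), incomplete_workup = incomplete)
}

#' Detect hereditary-suspicion beacons
#'
#' Flags the history findings that raise hereditary suspicion:
#' consanguinity (any recorded degree), endogamy (settlement below 5,000
#' inhabitants), isonymy (shared parental surname), familial hematologic
#' disorder, personal early-onset malignancy, fetal growth restriction or
#' small-for-gestational-age birth, and physical alterations (any feature in
#' the growth, skeletal/visceral-malformation or dysmorphology groups).
#'
#' @param record An `ibmfs_patient`.
#' @param catalog An `ibmfs_catalog`.
#' @param config Run configuration.
#' @return A named logical list of class `ibmfs_beacons`.
#' @export
detect_beacons <- function(record, catalog = load_catalog(),
                           config = default_config()) {
  fam <- record$family
  physical_groups <- c(
    "HP:0001510", # short stature / growth
    "HP:0000924", # skeletal malformation
    "HP:0000119", # visceral (genitourinary)
    "HP:0001999" # dysmorphic features
  )
  physical <- any(vapply(
    physical_groups,
    function(g) has_feature(record, g, catalog), logical(1)
  )) || length(nonhematologic_systems(record, catalog)) > 0
  structure(
    list(
      consanguinity = !is.na(fam$consanguinity_degree),
      endogamy = !is.na(fam$settlement_population) &&
        fam$settlement_population < config$thresholds$endogamy_population_max,
      isonymy = isTRUE(fam$shared_surname),
      family_hematologic = isTRUE(fam$hematological_disorder_in_family),
      personal_early_malignancy = nrow(record$personal_malignancy) > 0,
      fgr_or_sga = isTRUE(record$prenatal$fgr) || isTRUE(record$prenatal$sga),
      physical_alterations = physical
    ),
    class = "ibmfs_beacons"
  )
}

new_finding <- function(syndrome, fired, matched, missing, pathway, extra = list()) {
  structure(
    c(
      list(
        syndrome = syndrome, fired = fired,
        matched_criteria = matched, missing_criteria = missing,
        score = nrow(matched), pathway = pathway
      ),
      extra
    ),
    class = "ibmfs_finding"
  )
}

crit <- function(criterion, evidence) {
  tibble(criterion = criterion, evidence = evidence)
}

no_crit <- function() tibble(criterion = character(), evidence = character())

#' Dyskeratosis congenita rule
#'
#' Fires when any cytopenia co-occurs with at least one element of the
#' mucocutaneous triad (oral leukoplakia, nail dysplasia, reticulated skin
#' pigmentation), or — without hematologic involvement — when the complete
#' triad is present. The nail element is satisfied by nail dysplasia or any
#' catalog nail abnormality. Supportive features (early hair graying, short
#' stature, eye anomalies, pulmonary fibrosis) add to the score.
#'
#' @param record An `ibmfs_patient`.
#' @param profile Its hematology profile.
#' @param catalog An `ibmfs_catalog`.
#' @param config Run configuration.
#' @return An `ibmfs_finding`.
#' @export
evaluate_dc <- function(record, profile, catalog = load_catalog(),
                        config = default_config()) {
  leuko <- has_feature(record, "HP:0002745", catalog)
  # nail abnormality (HP:0001597) or its descendant nail dysplasia both count
  nail <- has_feature(record, "HP:0001597", catalog)
  pigment <- has_feature(record, "HP:0007427", catalog)
  triad <- c(leukoplakia = leuko, nail_dysplasia = nail, reticulated_pigmentation = pigment)
  cyt <- any_cytopenia(record, profile, catalog)
  matched <- no_crit()
  for (el in names(triad)[triad]) matched <- bind_rows(matched, crit("triad", el))
  supportive <- matched_roots(record, catalog$groups$dc_supportive, catalog)
  for (s in supportive) matched <- bind_rows(matched, crit("supportive", catalog_label(catalog, s)))
  complete <- all(triad)
  fired <- (cyt && any(triad)) || complete
  pathway <- if (!fired) {
    "none"
  } else if (cyt) {
    "hematologic+phenotype"
  } else {
    "phenotype_only"
  }
  new_finding(
    "DC", fired, matched,
    missing = names(triad)[!triad], pathway,
    extra = list(complete_triad = complete)
  )
}

#' Shwachman-Diamond syndrome rule
#'
#' Fires when any cytopenia co-occurs with at least three of the eight
#' associated features (exocrine pancreatic insufficiency, malabsorption,
#' short stature, chondrodysplasia, thoracic abnormality, congenital heart
#' defect, otological malformation, hepatomegaly), or when a positive
#' 72-hour fecal fat test (pancreatic insufficiency, the SDS hallmark)
#' accompanies any cytopenia, or — phenotype-only — on a positive FFQT
#' alone. EPI counts as matched when the FFQT is positive or HP:0001738 is
#' asserted.
#'
#' @inheritParams evaluate_dc
#' @return An `ibmfs_finding`.
#' @export
evaluate_sds <- function(record, profile, catalog = load_catalog(),
                         config = default_config()) {
  ffqt_pos <- identical(record$labs$ffqt, "positive")
  assoc <- catalog$groups$sds_associated
  hit <- matched_roots(record, assoc, catalog)
  if (ffqt_pos && !"HP:0001738" %in% hit) hit <- c(hit, "HP:0001738")
  matched <- no_crit()
  for (h in hit) {
    ev <- if (h == "HP:0001738" && ffqt_pos) "FFQT positive" else catalog_label(catalog, h)
    matched <- bind_rows(matched, crit("associated", ev))
  }
  cyt <- any_cytopenia(record, profile, catalog)
  fired <- (cyt && length(hit) >= 3) || (ffqt_pos && cyt) || ffqt_pos
  pathway <- if (!fired) {
    "none"
  } else if (cyt) {
    "hematologic+phenotype"
  } else {
    "phenotype_only"
  }
  new_finding(
    "SDS", fired, matched,
    missing = setdiff(assoc, hit), pathway,
    extra = list(ffqt_positive = ffqt_pos)
  )
}

#' Diamond-Blackfan anemia rule
#'
#' Fires when some single CBC measurement shows macrocytic anemia with
#' co-occurring reticulocytopenia. Minor features (short stature,
#' microcephaly, craniofacial, neck, upper-limb, congenital heart defect,
#' genitourinary) add to the score. The classic-DBA flag marks onset before
#' 1 year with erythroid-precursor paucity on bone-marrow study.
#'
#' @inheritParams evaluate_dc
#' @return An `ibmfs_finding`.
#' @export
evaluate_dba <- function(record, profile, catalog = load_catalog(),
                         config = default_config()) {
  trigger <- isTRUE(profile$macrocytic_anemia_with_reticulocytopenia)
  matched <- no_crit()
  if (trigger) {
    matched <- bind_rows(matched, crit("trigger", "macrocytic anemia with reticulocytopenia"))
  }
  minors <- matched_roots(record, catalog$groups$dba_minor, catalog)
  for (m in minors) matched <- bind_rows(matched, crit("minor", catalog_label(catalog, m)))
  classic <- trigger &&
    !is.na(profile$onset_age_years) && profile$onset_age_years < 1 &&
    "erythroid_paucity" %in% record$labs$bm_biopsy
  new_finding(
    "DBA", trigger, matched,
    missing = if (trigger) character() else "macrocytic anemia with reticulocytopenia",
    pathway = if (trigger) "hematologic+phenotype" else "none",
    extra = list(classic_dba = classic, n_minor = length(minors))
  )
}

#' Thrombocytopenia-absent-radii rule
#'
#' Fires on ever-observed thrombocytopenia together with a radial-ray
#' alteration, provided thumb absence is NOT asserted: preserved thumbs
#' distinguish TAR from Fanconi anemia, so asserted thumb agenesis vetoes
#' TAR and raises an FA cross-flag instead. Congenital heart defect and
#' renal alterations add to the score.
#'
#' @inheritParams evaluate_dc
#' @return An `ibmfs_finding`.
#' @export
evaluate_tar <- function(record, profile, catalog = load_catalog(),
                         config = default_config()) {
  thrombo <- profile$ever_status$thrombocytopenia == "present" ||
    has_feature(record, "HP:0001873", catalog)
  radial_hits <- setdiff(
    match_features(record, catalog$groups$radial_ray, catalog),
    c("HP:0009777", "HP:0009778") # thumb findings alone are not a radius defect
  )
  thumb_absent <- has_feature(record, "HP:0009777", catalog)
  matched <- no_crit()
  if (thrombo) matched <- bind_rows(matched, crit("trigger", "thrombocytopenia"))
  for (r in radial_hits) matched <- bind_rows(matched, crit("radial_ray", catalog_label(catalog, r)))
  supportive <- matched_roots(record, catalog$groups$tar_supportive, catalog)
  for (s in supportive) matched <- bind_rows(matched, crit("supportive", catalog_label(catalog, s)))
  fired <- thrombo && length(radial_hits) > 0 && !thumb_absent
  new_finding(
    "TAR", fired, matched,
    missing = c(
      if (!thrombo) "thrombocytopenia",
      if (length(radial_hits) == 0) "radial ray alteration"
    ) %||% character(),
    pathway = if (fired) "hematologic+phenotype" else "none",
    extra = list(fa_cross_flag = thumb_absent && length(radial_hits) > 0)
  )
}

#' Severe congenital neutropenia rule
#'
#' Fires on lifelong (persistent) or cyclic neutropenia together with at
#' least two of the three associated features: short stature, congenital
#' heart defect, urogenital alteration.
#'
#' @inheritParams evaluate_dc
#' @return An `ibmfs_finding`.
#' @export
evaluate_scn <- function(record, profile, catalog = load_catalog(),
                         config = default_config()) {
  neut <- profile$persistent_neutropenia || profile$cyclic_neutropenia
  assoc <- matched_roots(record, catalog$groups$scn_associated, catalog)
  matched <- no_crit()
  if (neut) {
    kind <- if (profile$cyclic_neutropenia) "cyclic neutropenia" else "persistent neutropenia"
    matched <- bind_rows(matched, crit("trigger", kind))
  }
  for (a in assoc) matched <- bind_rows(matched, crit("associated", catalog_label(catalog, a)))
  fired <- neut && length(assoc) >= 2
  new_finding(
    "SCN", fired, matched,
    missing = c(
      if (!neut) "persistent or cyclic neutropenia",
      if (length(assoc) < 2) ">=2 associated features"
    ) %||% character(),
    pathway = if (fired) "hematologic+phenotype" else "none"
  )
}

#' Fanconi anemia referral rule
#'
#' FA is a referral flag rather than a primary suspicion here: DEB-positive
#' patients are confirmed FA and excluded upstream, and a documented
#' negative DEB test rules FA out, so the pattern is only actionable while
#' the test is outstanding. With the DEB result not yet available, the flag
#' fires on any cytopenia plus at least one VACTERL-H/PHENOS feature, or on
#' three such features without hematologic involvement, and carries the
#' action "order DEB test".
#'
#' @inheritParams evaluate_dc
#' @return An `ibmfs_finding` with an `action` element.
#' @export
evaluate_fa <- function(record, profile, catalog = load_catalog(),
                        config = default_config()) {
  roots <- union(catalog$groups$vacterl_h, catalog$groups$phenos)
  hit <- matched_roots(record, roots, catalog)
  cyt <- any_cytopenia(record, profile, catalog)
  deb <- record$labs$deb_test
  pattern <- (cyt && length(hit) >= 1) || (!cyt && length(hit) >= 3)
  fired <- pattern && !identical(deb, "negative")
  matched <- no_crit()
  for (h in hit) matched <- bind_rows(matched, crit("vacterl_h/phenos", catalog_label(catalog, h)))
  new_finding(
    "FA", fired, matched,
    missing = character(),
    pathway = if (!fired) "none" else if (cyt) "hematologic+phenotype" else "phenotype_only",
    extra = list(
      action = if (fired) "order DEB test" else NA_character_,
      pattern_present = pattern, deb_test = deb
    )
  )
}

#' Classify one patient record
#'
#' Runs the full decision pipeline — eligibility, exclusion, beacons, all
#' six syndrome rules — and assigns the primary suspicion under the fixed
#' precedence TAR > SCN > DC > SDS > DBA (configurable), with FA handled as
#' a referral when its pattern fires exclusively and the DEB test is
#' outstanding, and `undefined_IBMFS` as the fallback for eligible,
#' non-excluded records firing no rule.
#'
#' @param record An `ibmfs_patient`.
#' @param catalog An `ibmfs_catalog`.
#' @param config Run configuration from [load_config()].
#' @return An object of class `ibmfs_suspicion` with elements `patient_id`,
#'   `eligible`, `eligibility_reasons`, `excluded_as`, `beacons`, `findings`
#'   (named list of `ibmfs_finding`), `primary`, `profile` and `audit`
#'   (ordered log of every gate and rule evaluation).
#' @export
#' @examples
#' rec <- patient_record("ex",
#'   age_years = 4,
#'   features = data.frame(term_id = c("HP:0002164", "HP:0007427", "HP:0002745")),
#'   cbc_series = data.frame(age_years = 3, hb = 9, anc = 2000, platelets = 60000)
#' )
#' classify(rec)$primary
classify <- function(record, catalog = load_catalog(), config = default_config()) {
  audit <- character()
  log <- function(...) audit <<- c(audit, paste0(...))
  profile <- hematology_profile(record, catalog, config)
  elig <- check_eligibility(record, profile, catalog, config)
  log(
    "eligibility: ", if (elig$eligible) "eligible" else "not eligible",
    " (", paste(elig$reasons, collapse = "; "), ")"
  )
  beacons <- detect_beacons(record, catalog, config)
  log("beacons: ", paste(names(beacons)[unlist(beacons)], collapse = ", "))
  if (!elig$eligible) {
    return(new_suspicion(
      record, elig, "none", beacons,
      findings = list(), primary = "not_eligible", profile, audit
    ))
  }
  excl <- exclusion_gate(record)
  log("exclusion gate: ", excl$status,
    if (length(excl$evidence)) paste0(" [", paste(excl$evidence, collapse = ", "), "]") else "",
    if (length(excl$incomplete_workup)) {
      paste0(" (incomplete work-up: ", paste(excl$incomplete_workup, collapse = ", "), ")")
    } else {
      ""
    }
  )
  if (excl$status != "none") {
    return(new_suspicion(
      record, elig, excl$status, beacons,
      findings = list(),
      primary = if (excl$status == "FA_confirmed") "FA_confirmed" else "excluded_acquired",
      profile, audit
    ))
  }
  findings <- list(
    FA = evaluate_fa(record, profile, catalog, config),
    TAR = evaluate_tar(record, profile, catalog, config),
    SCN = evaluate_scn(record, profile, catalog, config),
    DC = evaluate_dc(record, profile, catalog, config),
    SDS = evaluate_sds(record, profile, catalog, config),
    DBA = evaluate_dba(record, profile, catalog, config)
  )
  for (f in findings) {
    log(
      "rule ", f$syndrome, ": ", if (f$fired) "fired" else "not fired",
      " (score ", f$score, ", pathway ", f$pathway, ")"
    )
  }
  fired_specific <- config$precedence[vapply(
    config$precedence,
    function(s) findings[[s]]$fired, logical(1)
  )]
  primary <- if (length(fired_specific) > 0) {
    fired_specific[[1]]
  } else if (findings$FA$fired && identical(record$labs$deb_test, "not_done")) {
    "FA_referral"
  } else {
    "undefined_IBMFS"
  }
  if (length(fired_specific) > 1) {
    log(
      "precedence: ", primary, " over ",
      paste(fired_specific[-1], " (score ",
        vapply(fired_specific[-1], function(s) findings[[s]]$score, numeric(1)),
        ")",
        sep = "", collapse = ", "
      )
    )
  }
  log("primary: ", primary)
  new_suspicion(record, elig, "none", beacons, findings, primary, profile, audit)
}

new_suspicion <- function(record, elig, excluded_as, beacons, findings,
                          primary, profile, audit) {
  structure(
    list(
      patient_id = record$patient_id,
      eligible = elig$eligible,
      eligibility_reasons = elig$reasons,
      excluded_as = excluded_as,
      beacons = beacons,
      findings = findings,
      primary = primary,
      profile = profile,
      audit = audit
    ),
    class = "ibmfs_suspicion"
  )
}

#' @export
print.ibmfs_suspicion <- function(x, ...) {
  cat("<ibmfs_suspicion> ", x$patient_id, ": ", x$primary, "\n", sep = "")
  fired <- names(x$findings)[vapply(x$findings, `[[`, TRUE, "fired")]
  if (length(fired)) cat("  fired: ", paste(fired, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify every record of a cohort
#'
#' @param cohort A list of `ibmfs_patient` records (e.g. from
#'   [read_cohort()] or [build_reference_fixture()]).
#' @param catalog An `ibmfs_catalog`.
#' @param config Run configuration.
#' @return A tibble with one row per patient: `patient_id`, `eligible`,
#'   `excluded_as`, `primary`, `fired` (comma-joined fired rules), per-rule
#'   scores, onset category, worst cytopenia class and the full result in a
#'   `result` list-column.
#' @export
classify_cohort <- function(cohort, catalog = load_catalog(),
                            config = default_config()) {
  results <- lapply(cohort, classify, catalog = catalog, config = config)
  tibble(
    patient_id = vapply(results, `[[`, "", "patient_id"),
    eligible = vapply(results, `[[`, TRUE, "eligible"),
    excluded_as = vapply(results, `[[`, "", "excluded_as"),
    primary = vapply(results, `[[`, "", "primary"),
    fired = vapply(results, function(r) {
      paste(names(r$findings)[vapply(r$findings, `[[`, TRUE, "fired")], collapse = ",")
    }, character(1)),
    score_DC = finding_score(results, "DC"),
    score_SDS = finding_score(results, "SDS"),
    score_DBA = finding_score(results, "DBA"),
    score_TAR = finding_score(results, "TAR"),
    score_SCN = finding_score(results, "SCN"),
    onset_category = vapply(results, function(r) r$profile$onset_category, character(1)),
    worst_class = vapply(results, function(r) r$profile$worst_class$value, character(1)),
    transfusion_dependent = vapply(results, function(r) r$profile$transfusion_dependent, logical(1)),
    result = results
  )
}

finding_score <- function(results, syndrome) {
  vapply(results, function(r) {
    if (length(r$findings) == 0) {
      return(NA_real_)
    }
    as.numeric(r$findings[[syndrome]]$score)
  }, numeric(1))
}

#' @export
tidy.ibmfs_suspicion <- function(x, ...) {
  purrr::map_dfr(x$findings, function(f) {
    tibble(
      patient_id = x$patient_id,
      syndrome = f$syndrome,
      fired = f$fired,
      score = f$score,
      pathway = f$pathway,
      matched = paste(f$matched_criteria$evidence, collapse = "; ")
    )
  })
}

#' @export
glance.ibmfs_suspicion <- function(x, ...) {
  tibble(
    patient_id = x$patient_id,
    eligible = x$eligible,
    excluded_as = x$excluded_as,
    primary = x$primary,
    n_fired = sum(vapply(x$findings, `[[`, TRUE, "fired")),
    onset_category = x$profile$onset_category,
    worst_class = x$profile$worst_class$value
  )
}
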