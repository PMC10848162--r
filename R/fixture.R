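#' @title Deterministic reference cohort
#' @description [build_reference_fixture()] constructs, entirely in code and
#'   without any random number generation, a 48-patient cohort realizing one
#'   feasible patient-level assignment consistent with the cohort-level
#'   characteristics the package is designed to reproduce: suspicion-group
#'   sizes 15 DBA / 9 SDS / 7 DC / 2 TAR / 2 SCN / 13 undefined, 48 patients
#'   from 46 families (one sibling pair in the DC group, one in the SDS
#'   group), 23 patients reaching pancytopenia, hematologic onset buckets
#'   22 / 9 / 14 over the 45 patients with onset, 10 transfusion-dependent
#'   patients, 40 with craniofacial features, 25 with neurological features,
#'   23 with integument features, 21 growth-restricted (8 of 9 SDS, 8 of 15
#'   DBA), the complete mucocutaneous triad in 4 of 7 DC patients, 29 males /
#'   19 females, and a mean evaluation age of 9.02 years. Marginals not
#'   constrained by those targets are filled minimally.
#' @name reference-fixture
NULL

# ---- CBC trajectory building blocks (units: g/dL, fL, cells/uL, 10^9/L) ----

fx_row <- function(age, hb, mcv, anc, plt, retic) {
  tibble(
    age_years = age, hb = hb, mcv = mcv, anc = anc, platelets = plt,
    wbc = NA_real_, retic_abs = retic, hbf_percent = NA_real_
  )
}

fx_normal <- function(age) fx_row(age, 12.5, 84, 3200, 280000, 45)

fx_patterns <- list(
  # isolated macrocytic anemia with reticulocytopenia (DBA trigger)
  macro = list(
    onset = function(a) fx_row(a, 7.8, 98, 3000, 260000, 8),
    later = function(a) fx_row(a, 7.2, 99, 3000, 250000, 6)
  ),
  # DBA trigger progressing to trilineage failure
  macro_pancyto = list(
    onset = function(a) fx_row(a, 7.8, 98, 3100, 260000, 8),
    later = function(a) fx_row(a, 7.5, 99, 900, 90000, 7)
  ),
  # DBA trigger with later severe neutropenia (bilineage)
  macro_neutro = list(
    onset = function(a) fx_row(a, 7.8, 98, 3000, 260000, 8),
    later = function(a) fx_row(a, 8.0, 97, 400, 230000, 9)
  ),
  # normocytic trilineage cytopenia, reticulocytes preserved
  pancyto = list(
    onset = function(a) fx_row(a, 8.5, 82, 800, 70000, 35),
    later = function(a) fx_row(a, 7.9, 82, 400, 45000, 30)
  ),
  thrombo = list(
    onset = function(a) fx_row(a, 12.8, 82, 2900, 60000, 40),
    later = function(a) fx_row(a, 12.6, 82, 2800, 50000, 40)
  ),
  bicyto_at = list( # anemia + thrombocytopenia
    onset = function(a) fx_row(a, 9.2, 82, 2700, 95000, 40),
    later = function(a) fx_row(a, 9.0, 82, 2600, 85000, 38)
  ),
  anemia_n = list( # isolated normocytic anemia
    onset = function(a) fx_row(a, 9.3, 82, 2800, 240000, 40),
    later = function(a) fx_row(a, 9.1, 82, 2700, 230000, 40)
  ),
  sds_neutro_mod = list(
    onset = function(a) fx_row(a, 12.6, 83, 800, 230000, 40),
    later = function(a) fx_row(a, 12.4, 83, 900, 220000, 40)
  ),
  sds_mild_anemia = list( # mild neutropenia + anemia
    onset = function(a) fx_row(a, 9.8, 82, 1200, 210000, 38),
    later = function(a) fx_row(a, 9.5, 82, 1300, 200000, 38)
  ),
  sds_pancyto = list(
    onset = function(a) fx_row(a, 8.4, 83, 300, 90000, 30),
    later = function(a) fx_row(a, 8.1, 83, 250, 80000, 28)
  ),
  sds_bicyto_at = list(
    onset = function(a) fx_row(a, 9.0, 82, 2600, 80000, 36),
    later = function(a) fx_row(a, 8.8, 82, 2600, 70000, 36)
  )
)

# standard four-point trajectory: normal baseline (when onset allows), first
# abnormal count at the intended onset age, and two follow-ups
fx_series <- function(pattern, onset_age, eval_age) {
  if (is.null(pattern)) {
    return(NULL)
  }
  if (pattern %in% c("cyclic_a", "cyclic_b")) {
    ancs <- if (pattern == "cyclic_a") {
      c(400, 1700, 300, 1600, 350, 1700)
    } else {
      c(180, 1750, 150, 1650, 190, 1600)
    }
    step <- if (eval_age - onset_age >= 1.4) 0.25 else 0.15
    ages <- onset_age + step * (seq_along(ancs) - 1)
    return(bind_rows(lapply(seq_along(ancs), function(i) {
      fx_row(ages[i], 12.5, 80, ancs[i], 200000, 40)
    })))
  }
  p <- fx_patterns[[pattern]]
  mid <- (onset_age + eval_age) / 2
  last <- eval_age - 0.2
  rows <- list()
  if (onset_age >= 0.45) rows <- c(rows, list(fx_normal(onset_age - 0.4)))
  rows <- c(rows, list(p$onset(onset_age)))
  if (mid > onset_age + 0.05) rows <- c(rows, list(p$later(mid)))
  if (last > mid + 0.05) rows <- c(rows, list(p$later(last)))
  bind_rows(rows)
}

fx_transfusions <- function(kind, onset_age) {
  d <- round(365 * onset_age) + 30
  switch(kind,
    none = NULL,
    dependent = tibble(
      age_days = c(d, d + 14L, d + 42L),
      product = "RBC", units = 1L
    ),
    single = tibble(age_days = d + 100L, product = "RBC", units = 1L),
    spaced = tibble(
      age_days = c(d + 100L, d + 140L),
      product = "RBC", units = 1L
    ),
    platelet = tibble(age_days = d + 60L, product = "platelet", units = 2L)
  )
}

fx_labs <- function(ffqt = "not_done", bm = "not_done") {
  lab_panel(
    deb_test = "negative", ffqt = ffqt, bm_biopsy = bm,
    viral_serology_positive = FALSE, nutritional_deficiency = FALSE,
    drug_radiation_exposure = FALSE, pnh_clone = FALSE
  )
}

fx_patient <- function(catalog, id, label, sex, age, onset = NA, pattern = NULL,
                       feats = character(), tx = "none",
                       ffqt = "not_done", bm = "not_done",
                       consang = NA, settlement = NA, surname = NA,
                       fam_heme = NA, fgr = NA, sga = NA,
                       malignancy = NULL, family_id = NULL) {
  rec <- patient_record(
    patient_id = id, sex = sex, age_years = age,
    features = if (length(feats)) tibble(term_id = feats) else NULL,
    cbc_series = if (is.null(pattern)) NULL else fx_series(pattern, onset, age),
    transfusions = fx_transfusions(tx, if (is.na(onset)) 0 else onset),
    labs = fx_labs(ffqt, bm),
    family = family_history(
      consanguinity_degree = consang,
      settlement_population = settlement,
      shared_surname = surname,
      hematological_disorder_in_family = fam_heme
    ),
    prenatal = list(fgr = fgr, sga = sga),
    personal_malignancy = malignancy,
    family_id = family_id,
    catalog = catalog
  )
  attr(rec, "intended_label") <- label
  rec
}

#' Build the 48-patient reference cohort
#'
#' Fully deterministic (no random number generation); see
#' \link{reference-fixture} for the cohort-level characteristics it encodes.
#' Classifying the cohort with [classify_cohort()] recovers every patient's
#' intended suspicion label.
#'
#' @param catalog An `ibmfs_catalog`.
#' @return An `ibmfs_cohort` of 48 records, with an `intended_labels`
#'   attribute (tibble of `patient_id`, `label`).
#' @export
#' @examples
#' \donttest{
#' cohort <- build_reference_fixture()
#' length(cohort)
#' }
build_reference_fixture <- function(catalog = load_catalog()) {
  # term id shorthands
  leuko <- "HP:0002745"; nails <- "HP:0002164"; pigm <- "HP:0007427"
  ss <- "HP:0004322"; chd <- "HP:0001627"; dd <- "HP:0012758"
  calm <- "HP:0000957"; macules <- "HP:0007441"
  malab <- "HP:0002024"; epi <- "HP:0001738"; hepat <- "HP:0002240"
  ear <- "HP:0000598"; thorax <- "HP:0045027"; chondro <- "HP:0005871"
  face_long <- "HP:0000276"; nose <- "HP:0000414"; midface <- "HP:0011800"
  retro <- "HP:0000308"; epic <- "HP:0000286"
  id_dis <- "HP:0001263"; cns <- "HP:0002011"; cogn <- "HP:0100543"
  seiz <- "HP:0001250"
  radius_abs <- "HP:0003974"; thumb_hypo <- "HP:0009778"
  renal <- "HP:0000077"; stones <- "HP:0000787"

  p <- function(...) fx_patient(catalog, ...)
  cohort <- list(
    # --- dyskeratosis congenita (7; sibling pair P04/P05) ---
    p("P01", "DC", "male", 9, 5.5, "thrombo", feats = c(pigm)),
    p("P02", "DC", "female", 4,
      feats = c(leuko, nails, pigm, epic)
    ), # complete triad, no hematologic history
    p("P03", "DC", "male", 13, 8.0, "pancyto",
      feats = c(pigm, ss, face_long), consang = 3
    ),
    p("P04", "DC", "male", 17, 9.0, "pancyto",
      feats = c(leuko, nails, pigm, dd),
      settlement = 3000, surname = TRUE, bm = "hypocellular",
      family_id = "FAM-DC"
    ),
    p("P05", "DC", "female", 11, 7.0, "pancyto",
      feats = c(leuko, nails, pigm),
      settlement = 3000, surname = TRUE, fam_heme = TRUE,
      bm = "hypocellular", family_id = "FAM-DC"
    ),
    p("P06", "DC", "male", 21, 2.5, "pancyto",
      feats = c(leuko, nails, pigm, ss, midface),
      tx = "dependent", bm = "hypocellular"
    ),
    p("P07", "DC", "male", 7, 1.5, "pancyto",
      feats = c(nails, pigm, id_dis, nose),
      tx = "platelet", bm = "normal"
    ),

    # --- Shwachman-Diamond (9; sibling pair P10/P11) ---
    p("P08", "SDS", "female", 2,
      feats = c(epi, ss, epic), ffqt = "positive"
    ),
    p("P09", "SDS", "male", 2,
      feats = c(epi, ss, nose), ffqt = "positive"
    ),
    p("P10", "SDS", "male", 6, 1.0, "sds_neutro_mod",
      feats = c(malab, ss, hepat, face_long, macules),
      settlement = 2800, ffqt = "negative", family_id = "FAM-SDS"
    ),
    p("P11", "SDS", "female", 2.3, 1.5, "sds_mild_anemia",
      feats = c(malab, ss, ear, retro, macules),
      settlement = 2800, fam_heme = TRUE, ffqt = "negative",
      family_id = "FAM-SDS"
    ),
    p("P12", "SDS", "male", 5, 2.0, "sds_pancyto",
      feats = c(epi, ss, malab, epic, dd),
      ffqt = "positive", bm = "hypocellular"
    ),
    p("P13", "SDS", "female", 1.5, 0.8, "sds_pancyto",
      feats = c(epi, ss, thorax, nose, dd),
      ffqt = "positive", consang = 4, bm = "hypocellular"
    ),
    p("P14", "SDS", "male", 9, 3.5, "sds_pancyto",
      feats = c(malab, ss, chondro, face_long, id_dis),
      settlement = 4000, sga = TRUE, bm = "hypocellular"
    ),
    p("P15", "SDS", "female", 12, 6.0, "sds_pancyto",
      feats = c(ss, ear, hepat, retro, cogn), bm = "normal"
    ),
    p("P16", "SDS", "male", 14, 4.5, "sds_bicyto_at",
      feats = c(malab, hepat, ear, epic, seiz, macules)
    ),

    # --- Diamond-Blackfan (15) ---
    p("P17", "DBA", "male", 1.5, 0.7, "macro_pancyto",
      feats = c(face_long, ss), tx = "dependent",
      settlement = 4500, bm = c("hypocellular", "erythroid_paucity")
    ),
    p("P18", "DBA", "male", 3, 0.6, "macro_pancyto",
      feats = c(nose, dd), tx = "dependent", bm = "hypocellular"
    ),
    p("P19", "DBA", "female", 6, 0.8, "macro_pancyto",
      feats = c(midface, ss, macules), tx = "dependent", bm = "hypocellular"
    ),
    p("P20", "DBA", "male", 2, 0.8, "macro_neutro",
      feats = c(face_long, nose, midface, retro, dd)
    ),
    p("P21", "DBA", "female", 1.7, 0.9, "macro_pancyto",
      feats = c(epic, ss, calm), tx = "dependent", bm = "hypocellular"
    ),
    p("P22", "DBA", "male", 9, 1.0, "macro_pancyto",
      feats = c(retro, id_dis), tx = "dependent", consang = 3, bm = "normal"
    ),
    p("P23", "DBA", "female", 13, 1.2, "macro_pancyto",
      feats = c(nose, ss, macules), tx = "dependent"
    ),
    p("P24", "DBA", "male", 4, 1.5, "macro_pancyto",
      feats = c(face_long, dd), tx = "dependent"
    ),
    p("P25", "DBA", "female", 7, 2.0, "macro_pancyto",
      feats = c(epic, ss, calm)
    ),
    p("P26", "DBA", "male", 16, 2.5, "macro",
      feats = c(nose, cogn), settlement = 3500
    ),
    p("P27", "DBA", "female", 10, 3.0, "macro",
      feats = c(face_long, ss, macules)
    ),
    p("P28", "DBA", "male", 19, 7.0, "macro",
      feats = c(retro, seiz), settlement = 2000
    ),
    p("P29", "DBA", "female", 12, 6.0, "macro",
      feats = c(nose, ss, calm)
    ),
    p("P30", "DBA", "male", 6, 4.5, "macro", feats = c(epic)),
    p("P31", "DBA", "female", 15, 9.0, "macro", feats = c(face_long, ss)),

    # --- thrombocytopenia with absent radii (2) ---
    p("P32", "TAR", "male", 0.8, 0.05, "thrombo",
      feats = c(radius_abs, chd), fgr = TRUE, bm = "normal"
    ),
    p("P33", "TAR", "female", 1, 0.1, "thrombo",
      feats = c(radius_abs, thumb_hypo, dd)
    ),

    # --- severe congenital neutropenia (2) ---
    p("P34", "SCN", "male", 1.2, 0.2, "cyclic_a",
      feats = c(ss, chd, dd, epic, calm), settlement = 3800, bm = "normal"
    ),
    p("P35", "SCN", "female", 0.9, 0.1, "cyclic_b",
      feats = c(chd, stones, cns, nose)
    ),

    # --- undefined IBMFS (13) ---
    p("P36", "UI", "male", 7, 0.5, "pancyto",
      feats = c(face_long, dd), tx = "dependent", consang = 3,
      bm = "hypocellular"
    ),
    p("P37", "UI", "male", 9, 1.0, "pancyto",
      feats = c(nose, cns), tx = "dependent",
      settlement = 1500, surname = TRUE, bm = "hypocellular"
    ),
    p("P38", "UI", "female", 13, 1.5, "pancyto",
      feats = c(midface, seiz, calm), bm = "hypocellular"
    ),
    p("P39", "UI", "male", 7, 2.0, "pancyto",
      feats = c(retro, cogn, macules), bm = "hypocellular",
      malignancy = tibble(type = "MDS", onset_age_years = 7)
    ),
    p("P40", "UI", "male", 10, 2.5, "pancyto",
      feats = c(epic, dd, calm), bm = "hypocellular",
      malignancy = tibble(type = "AML", onset_age_years = 9)
    ),
    p("P41", "UI", "female", 16, 3.0, "bicyto_at",
      feats = c(face_long, id_dis, macules), tx = "single", bm = "normal"
    ),
    p("P42", "UI", "male", 18, 4.0, "anemia_n",
      feats = c(nose, dd, calm)
    ),
    p("P43", "UI", "male", 21, 6.0, "anemia_n",
      feats = c(midface, cns, macules), settlement = 4800,
      malignancy = tibble(type = "MDS", onset_age_years = 16)
    ),
    p("P44", "UI", "female", 14, 7.0, "thrombo",
      feats = c(retro, seiz, ss)
    ),
    p("P45", "UI", "male", 17, 8.0, "thrombo",
      feats = c(epic, ss), tx = "spaced"
    ),
    p("P46", "UI", "male", 18, 8.0, "bicyto_at",
      bm = "mds", malignancy = tibble(type = "MDS", onset_age_years = 8)
    ),
    p("P47", "UI", "female", 8, 7.0, "pancyto", bm = "hypocellular"),
    p("P48", "UI", "male", 10.06, 9.0, "thrombo", feats = c(renal))
  )
  labels <- tibble(
    patient_id = vapply(cohort, `[[`, "", "patient_id"),
    label = vapply(cohort, function(r) attr(r, "intended_label"), character(1))
  )
  cohort <- lapply(cohort, function(r) {
    attr(r, "intended_label") <- NULL
    r
  })
  out <- as_cohort(cohort)
  attr(out, "intended_labels") <- labels
  out
}
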