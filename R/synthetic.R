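#' Default archetype parameters for the cohort simulator
#'
#' One archetype per suspicion group, with group sizes matching the
#' reference cohort (15 DBA, 9 SDS, 7 DC, 2 TAR, 2 SCN, 13 undefined;
#' total 48) and feature-sampling probabilities taken from the observed
#' per-group prevalences (e.g. growth restriction 8/9 in the SDS archetype
#' and 8/15 in the DBA archetype, oral leukoplakia 4/7 in DC). The CBC
#' trajectory of each archetype reproduces its group's qualitative course
#' (direction and severity), with measurement noise added at simulation
#' time.
#'
#' @return A list of archetype parameter lists (`label`, `n`,
#'   `feature_prevalence`, `cbc_pattern`, `lab_settings`).
#' @export
#' @examples
#' sum(vapply(default_params(), `[[`, 0, "n"))
default_params <- function() {
  list(
    list(
      label = "DBA", n = 15,
      feature_prevalence = c(
        "HP:0001999" = 1, # craniofacial (some minor feature in all)
        "HP:0004322" = 8 / 15, # growth restriction
        "HP:0000707" = 6 / 15, # neurological
        "HP:0007441" = 6 / 15 # integument macules
      ),
      cbc_pattern = "macro_pancyto",
      lab_settings = list(ffqt = 0, deb_negative = 1)
    ),
    list(
      label = "SDS", n = 9,
      feature_prevalence = c(
        "HP:0004322" = 8 / 9, # growth restriction
        "HP:0002024" = 5 / 9, # malabsorption
        "HP:0002240" = 4 / 9, # hepatomegaly
        "HP:0000598" = 4 / 9, # otological
        "HP:0000707" = 5 / 9, # neurological
        "HP:0001999" = 1 # craniofacial
      ),
      cbc_pattern = "sds_pancyto",
      lab_settings = list(ffqt = 4 / 9, deb_negative = 1)
    ),
    list(
      label = "DC", n = 7,
      feature_prevalence = c(
        "HP:0002745" = 4 / 7, # leukoplakia
        "HP:0002164" = 5 / 7, # nail dysplasia
        "HP:0007427" = 1, # reticulated pigmentation
        "HP:0004322" = 2 / 7,
        "HP:0001999" = 4 / 7
      ),
      cbc_pattern = "pancyto",
      lab_settings = list(ffqt = 0, deb_negative = 1)
    ),
    list(
      label = "TAR", n = 2,
      feature_prevalence = c(
        "HP:0003974" = 1, # absent radius (thumbs preserved)
        "HP:0001627" = 1 / 2,
        "HP:0000707" = 1 / 2
      ),
      cbc_pattern = "thrombo",
      lab_settings = list(ffqt = 0, deb_negative = 1)
    ),
    list(
      label = "SCN", n = 2,
      feature_prevalence = c(
        "HP:0004322" = 1 / 2,
        "HP:0001627" = 1,
        "HP:0000119" = 1 / 2,
        "HP:0000707" = 1,
        "HP:0001999" = 1
      ),
      cbc_pattern = "cyclic",
      lab_settings = list(ffqt = 0, deb_negative = 1)
    ),
    list(
      label = "UI", n = 13,
      feature_prevalence = c(
        "HP:0001999" = 10 / 13,
        "HP:0000707" = 9 / 13,
        "HP:0000957" = 6 / 13,
        "HP:0004322" = 2 / 13
      ),
      cbc_pattern = "pancyto",
      lab_settings = list(ffqt = 0, deb_negative = 1)
    )
  )
}

# representative leaf asserted when a group-root probability fires
sim_leaf <- c(
  "HP:0001999" = "HP:0000414", "HP:0000707" = "HP:0012758",
  "HP:0000119" = "HP:0000787"
)

sim_term <- function(root) unname(ifelse(root %in% names(sim_leaf), sim_leaf[root], root))

#' Simulate a cohort from archetype parameters
#'
#' Deterministically seeded: the same `seed` and parameters give an
#' identical cohort. Stream discipline is one substream per patient (the
#' patient substream seed is derived from the base seed and the patient
#' index), so inserting or removing an archetype does not perturb other
#' patients' draws. Features are sampled independently per patient from the
#' archetype prevalences; the CBC series follows the archetype trajectory
#' with multiplicative measurement noise. Each record carries the archetype
#' it was drawn from, and `expected_label` marks whether its sampled
#' features still satisfy the archetype's minimal rule (records sampled
#' below threshold are expected to fall back to `undefined_IBMFS`).
#'
#' @param params List of archetype parameters, as from [default_params()].
#' @param seed Integer seed.
#' @param catalog An `ibmfs_catalog`.
#' @return An `ibmfs_cohort` with a `truth` attribute: tibble of
#'   `patient_id`, `archetype`, `expected_label`.
#' @export
#' @examples
#' cohort <- simulate_cohort(default_params(), seed = 1)
#' attr(cohort, "truth")
simulate_cohort <- function(params, seed, catalog = load_catalog()) {
  for (par in params) {
    pr <- par$feature_prevalence
    if (any(pr < 0 | pr > 1)) {
      abort(paste0("invalid feature probability in archetype ", par$label))
    }
    if (par$n < 0) abort("archetype n must be >= 0")
  }
  records <- list()
  truth <- list()
  idx <- 0L
  for (par in params) {
    for (k in seq_len(par$n)) {
      idx <- idx + 1L
      set.seed((as.integer(seed) * 1009L + idx * 7L) %% .Machine$integer.max)
      rec <- simulate_patient(par, sprintf("S%03d", idx), catalog)
      records <- c(records, list(rec$record))
      truth <- c(truth, list(tibble(
        patient_id = rec$record$patient_id,
        archetype = par$label,
        expected_label = rec$expected_label
      )))
    }
  }
  out <- as_cohort(records)
  attr(out, "truth") <- bind_rows(truth)
  out
}

simulate_patient <- function(par, id, catalog) {
  pr <- par$feature_prevalence
  drawn <- names(pr)[runif(length(pr)) < pr]
  feats <- vapply(drawn, sim_term, character(1))
  ffqt <- if (runif(1) < (par$lab_settings$ffqt %||% 0)) "positive" else "not_done"
  onset_age <- round(runif(1, 0.5, 3), 2)
  eval_age <- onset_age + round(runif(1, 2, 8), 2)
  noise <- function(x) x * exp(rnorm(length(x), 0, 0.04))
  base <- switch(par$cbc_pattern,
    macro_pancyto = fx_series("macro_pancyto", onset_age, eval_age),
    sds_pancyto = fx_series("sds_pancyto", onset_age, eval_age),
    pancyto = fx_series("pancyto", onset_age, eval_age),
    thrombo = fx_series("thrombo", onset_age, eval_age),
    cyclic = fx_series("cyclic_a", onset_age, eval_age),
    abort(paste0("unknown cbc_pattern: ", par$cbc_pattern))
  )
  for (col in c("hb", "anc", "platelets", "retic_abs")) {
    base[[col]] <- noise(base[[col]])
  }
  # noise must not blur the archetype's hematologic trigger
  if (par$cbc_pattern == "macro_pancyto") {
    i <- which(base$mcv > 90)
    base$hb[i] <- pmin(base$hb[i], 9.5)
    base$retic_abs[i] <- pmin(base$retic_abs[i], 15)
  }
  if (par$cbc_pattern == "cyclic") {
    base$anc <- ifelse(base$anc >= 1000, pmax(base$anc, 1500),
      pmin(base$anc, 450)
    )
    base$anc <- pmin(base$anc, 2400)
  }
  record <- patient_record(
    patient_id = id, sex = if (runif(1) < 29 / 48) "male" else "female",
    age_years = eval_age,
    features = if (length(feats)) tibble(term_id = unname(feats)) else NULL,
    cbc_series = base,
    labs = fx_labs(ffqt = ffqt),
    catalog = catalog
  )
  expected <- expected_label(par, record, ffqt, catalog)
  list(record = record, expected_label = expected)
}

# the archetype's minimal-rule check on the sampled record; mirrors the rule
# thresholds but intentionally simpler than the classifier
expected_label <- function(par, record, ffqt, catalog) {
  n_assoc <- length(matched_roots(
    record, catalog$groups$sds_associated, catalog
  )) + as.integer(ffqt == "positive" && !has_feature(record, "HP:0001738", catalog))
  switch(par$label,
    DBA = "DBA",
    DC = "DC", # pigmentation element sampled with probability 1
    TAR = "TAR",
    SDS = if (ffqt == "positive" || n_assoc >= 3) "SDS" else "undefined_IBMFS",
    SCN = if (length(matched_roots(record, catalog$groups$scn_associated, catalog)) >= 2) {
      "SCN"
    } else {
      "undefined_IBMFS"
    },
    UI = "undefined_IBMFS"
  )
}
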