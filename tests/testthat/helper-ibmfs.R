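# shared objects, built once per test run
test_catalog <- load_catalog()
test_config <- default_config()

# minimal record builder for rule tests
mk_record <- function(id = "t1", feats = character(), cbc = NULL,
                      labs = lab_panel(), family = family_history(),
                      age = 6, ...) {
  patient_record(
    patient_id = id, age_years = age,
    features = if (length(feats)) data.frame(term_id = feats) else NULL,
    cbc_series = cbc, labs = labs, family = family,
    catalog = test_catalog, ...
  )
}

# one-measurement CBC helpers
cbc1 <- function(age = 3, hb = 12.5, mcv = 84, anc = 3000, plt = 250000,
                 retic = 45) {
  data.frame(
    age_years = age, hb = hb, mcv = mcv, anc = anc,
    platelets = plt, retic_abs = retic
  )
}

classify1 <- function(rec) classify(rec, test_catalog, test_config)

profile1 <- function(rec) hematology_profile(rec, test_catalog, test_config)
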