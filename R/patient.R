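#' Construct a patient record
#'
#' Builds a validated `ibmfs_patient` object, the unit of input for the
#' triage engine. All history and laboratory fields are tri-state: `TRUE`,
#' `FALSE` or `NA` (unknown). An absent value always means unknown, never
#' negative — the decision algorithm distinguishes "test not done" from a
#' negative result. Units are fixed: hemoglobin g/dL, ANC and platelets
#' cells/uL, absolute reticulocytes 10^9/L, MCV fL, ages in years,
#' transfusion times in days of life.
#'
#' @param patient_id Unique identifier within a cohort.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param age_years Age at record evaluation, in years.
#' @param features Tibble/data frame with `term_id` (HPO id) and optional
#'   `onset_age_years`; ids are normalized via [normalize_hpo_id()] and must
#'   resolve in the catalog.
#' @param cbc_series Tibble/data frame with columns `age_years`, `hb`, `mcv`,
#'   `anc`, `platelets`, `wbc`, `retic_abs`, `hbf_percent` (missing columns
#'   are filled with `NA`); rows must be strictly increasing in `age_years`.
#' @param transfusions Tibble/data frame with `age_days` (integer, days of
#'   life), `product` (`"RBC"`, `"platelet"`, `"other"`) and `units` (>= 1).
#' @param labs List from [lab_panel()].
#' @param family List from [family_history()].
#' @param prenatal List with tri-state `fgr` and `sga`.
#' @param personal_malignancy Tibble/data frame with `type` (one of `"MDS"`,
#'   `"AML"`, `"ALL"`, `"solid_tumor"`) and `onset_age_years`.
#' @param family_id Optional family identifier (defaults to `patient_id`);
#'   used only for cohort-level family counting.
#' @param catalog Catalog used to validate feature ids (default
#'   [load_catalog()]).
#' @return An object of class `ibmfs_patient`.
#' @export
#' @examples
#' p <- patient_record("p1",
#'   sex = "female", age_years = 4,
#'   features = data.frame(term_id = "HP:0004322"),
#'   cbc_series = data.frame(age_years = 2, hb = 9, anc = 2000, platelets = 80000)
#' )
#' p$patient_id
patient_record <- function(patient_id, sex = "unknown", age_years = NA_real_,
                           features = NULL, cbc_series = NULL,
                           transfusions = NULL, labs = lab_panel(),
                           family = family_history(),
                           prenatal = list(fgr = NA, sga = NA),
                           personal_malignancy = NULL,
                           family_id = NULL,
                           catalog = load_catalog()) {
  if (!is.character(patient_id) || length(patient_id) != 1 || !nzchar(patient_id)) {
    abort("patient_id must be a non-empty string")
  }
  sex <- match.arg(sex, c("male", "female", "unknown"))
  if (!is.na(age_years) && (age_years < 0 || age_years >= 130)) {
    abort("age_years out of range [0, 130)")
  }
  rec <- structure(
    list(
      patient_id = patient_id,
      family_id = family_id %||% patient_id,
      sex = sex,
      age_years = round(as.numeric(age_years), 6),
      features = canon_features(features),
      cbc_series = canon_cbc(cbc_series),
      transfusions = canon_transfusions(transfusions),
      labs = canon_labs(labs),
      family = canon_family(family),
      prenatal = list(
        fgr = as_tristate(prenatal$fgr),
        sga = as_tristate(prenatal$sga)
      ),
      personal_malignancy = canon_malignancy(personal_malignancy)
    ),
    class = "ibmfs_patient"
  )
  validate_patient_record(rec, catalog)
  rec
}

#' Laboratory screening panel
#'
#' @param deb_test Diepoxybutane chromosomal-breakage result: `"positive"`,
#'   `"negative"` or `"not_done"`. A positive result confirms Fanconi anemia.
#' @param ffqt 72-hour fecal fat qualitative test (screens for exocrine
#'   pancreatic insufficiency): `"positive"`, `"negative"`, `"not_done"`.
#' @param bm_biopsy Character vector of bone-marrow findings, subset of
#'   `"hypocellular"`, `"normal"`, `"mds"`, `"aml"`, `"erythroid_paucity"`,
#'   or `"not_done"`.
#' @param viral_serology_positive,nutritional_deficiency,drug_radiation_exposure,pnh_clone
#'   Tri-state acquired-cause screens (`TRUE`/`FALSE`/`NA`); only explicit
#'   `TRUE` can trigger the acquired-cause exclusion.
#' @return A named list.
#' @export
lab_panel <- function(deb_test = "not_done", ffqt = "not_done",
                      bm_biopsy = "not_done",
                      viral_serology_positive = NA,
                      nutritional_deficiency = NA,
                      drug_radiation_exposure = NA,
                      pnh_clone = NA) {
  deb_test <- match.arg(deb_test, c("not_done", "positive", "negative"))
  ffqt <- match.arg(ffqt, c("not_done", "positive", "negative"))
  allowed <- c("hypocellular", "normal", "mds", "aml", "erythroid_paucity", "not_done")
  bad <- setdiff(bm_biopsy, allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown bm_biopsy values: ", paste(bad, collapse = ", ")))
  }
  list(
    deb_test = deb_test, ffqt = ffqt, bm_biopsy = bm_biopsy,
    viral_serology_positive = as_tristate(viral_serology_positive),
    nutritional_deficiency = as_tristate(nutritional_deficiency),
    drug_radiation_exposure = as_tristate(drug_radiation_exposure),
    pnh_clone = as_tristate(pnh_clone)
  )
}

#' Family history block
#'
#' @param consanguinity_degree Integer degree of parental consanguinity
#'   (>= 1), or `NA` if parents are not known consanguineous.
#' @param settlement_population Population of the family's settlement
#'   (endogamy screen), or `NA` if unknown.
#' @param shared_surname Tri-state isonymy flag.
#' @param hematological_disorder_in_family,malignancy_in_family Tri-state.
#' @return A named list.
#' @export
family_history <- function(consanguinity_degree = NA_integer_,
                           settlement_population = NA_real_,
                           shared_surname = NA,
                           hematological_disorder_in_family = NA,
                           malignancy_in_family = NA) {
  if (!is.na(consanguinity_degree) && consanguinity_degree < 1) {
    abort("consanguinity_degree, when present, must be >= 1")
  }
  if (!is.na(settlement_population) && settlement_population <= 0) {
    abort("settlement_population must be positive")
  }
  list(
    consanguinity_degree = as.integer(consanguinity_degree),
    settlement_population = as.numeric(settlement_population),
    shared_surname = as_tristate(shared_surname),
    hematological_disorder_in_family = as_tristate(hematological_disorder_in_family),
    malignancy_in_family = as_tristate(malignancy_in_family)
  )
}

as_tristate <- function(x) {
  if (is.null(x) || length(x) == 0) {
    return(NA)
  }
  as.logical(x)
}

cbc_columns <- c(
  "age_years", "hb", "mcv", "anc", "platelets", "wbc",
  "retic_abs", "hbf_percent"
)

canon_cbc <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    out <- as_tibble(setNames(
      rep(list(numeric()), length(cbc_columns)), cbc_columns
    ))
    return(out)
  }
  x <- as_tibble(x)
  for (col in setdiff(cbc_columns, names(x))) x[[col]] <- NA_real_
  extra <- setdiff(names(x), cbc_columns)
  if (length(extra) > 0) {
    abort(paste0("unknown cbc_series columns: ", paste(extra, collapse = ", ")))
  }
  x <- x[cbc_columns]
  # round to microscale so text serialization is exactly invertible
  x[] <- lapply(x, function(col) round(as.numeric(col), 6))
  x
}

canon_features <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(tibble(term_id = character(), onset_age_years = numeric()))
  }
  x <- as_tibble(x)
  if (!"term_id" %in% names(x)) {
    abort("features must have a term_id column")
  }
  if (!"onset_age_years" %in% names(x)) x$onset_age_years <- NA_real_
  x <- x[c("term_id", "onset_age_years")]
  x$term_id <- vapply(x$term_id, normalize_hpo_id, character(1), USE.NAMES = FALSE)
  x$onset_age_years <- round(as.numeric(x$onset_age_years), 6)
  distinct(x)
}

canon_transfusions <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(tibble(age_days = integer(), product = character(), units = integer()))
  }
  x <- as_tibble(x)[c("age_days", "product", "units")]
  x$age_days <- as.integer(x$age_days)
  x$units <- as.integer(x$units)
  if (any(x$age_days < 0)) abort("transfusion age_days must be non-negative")
  if (any(x$units < 1)) abort("transfusion units must be >= 1")
  bad <- setdiff(x$product, c("RBC", "platelet", "other"))
  if (length(bad) > 0) {
    abort(paste0("unknown transfusion products: ", paste(bad, collapse = ", ")))
  }
  arrange(x, .data$age_days)
}

canon_labs <- function(x) {
  do.call(lab_panel, x[intersect(names(x), names(formals(lab_panel)))])
}

canon_family <- function(x) {
  do.call(family_history, x[intersect(names(x), names(formals(family_history)))])
}

canon_malignancy <- function(x) {
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(tibble(type = character(), onset_age_years = numeric()))
  }
  x <- as_tibble(x)
  if (!"onset_age_years" %in% names(x)) x$onset_age_years <- NA_real_
  x <- x[c("type", "onset_age_years")]
  bad <- setdiff(x$type, c("MDS", "AML", "ALL", "solid_tumor"))
  if (length(bad) > 0) {
    abort(paste0("unknown malignancy types: ", paste(bad, collapse = ", ")))
  }
  x$onset_age_years <- round(as.numeric(x$onset_age_years), 6)
  x
}

#' Validate a patient record against a catalog
#'
#' Checks structural invariants (strictly increasing CBC ages, non-negative
#' counts) and that every asserted feature id resolves in the catalog; an
#' unknown id raises an error listing the nearest catalog terms.
#'
#' @param record An `ibmfs_patient`.
#' @param catalog An `ibmfs_catalog`.
#' @return The record, invisibly.
#' @export
validate_patient_record <- function(record, catalog = load_catalog()) {
  cbc <- record$cbc_series
  if (nrow(cbc) > 0) {
    if (any(is.na(cbc$age_years)) || any(cbc$age_years < 0) || any(cbc$age_years >= 130)) {
      abort("cbc_series age_years must be in [0, 130)")
    }
    if (is.unsorted(cbc$age_years, strictly = TRUE)) {
      abort("cbc_series not sorted: age_years must be strictly increasing")
    }
    counts <- unlist(cbc[c("hb", "mcv", "anc", "platelets", "wbc", "retic_abs")])
    if (any(counts < 0, na.rm = TRUE)) {
      abort("cbc_series counts must be non-negative")
    }
  }
  unknown <- setdiff(record$features$term_id, catalog$terms$term_id)
  if (length(unknown) > 0) {
    hints <- vapply(unknown, function(u) {
      d <- adist(u, catalog$terms$term_id)
      near <- catalog$terms$label[order(d)[1:3]]
      paste0(u, " (nearest: ", paste(near, collapse = "; "), ")")
    }, character(1))
    abort(paste0(
      "unknown feature term ids: ", paste(hints, collapse = " | ")
    ))
  }
  invisible(record)
}

#' @export
print.ibmfs_patient <- function(x, ...) {
  cat(
    "<ibmfs_patient> ", x$patient_id, " (", x$sex, ", ",
    format(x$age_years), " y): ", nrow(x$features), " features, ",
    nrow(x$cbc_series), " CBC measurements\n",
    sep = ""
  )
  invisible(x)
}

#' @export
format.ibmfs_patient <- function(x, ...) {
  paste0("<ibmfs_patient ", x$patient_id, ">")
}
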