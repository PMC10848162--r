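#' Grade neutropenia severity from an absolute neutrophil count
#'
#' Bands are half-open on the left so every non-negative ANC receives exactly
#' one grade: severe < 500, moderate \[500, 1000), mild \[1000, 1500), none
#' >= 1500 cells/uL.
#'
#' @param anc Absolute neutrophil count(s), cells/uL; must be >= 0.
#' @param config Run configuration (for the band edges).
#' @return Character vector: `"none"`, `"mild"`, `"moderate"` or `"severe"`.
#' @export
#' @examples
#' grade_neutropenia(c(400, 500, 999, 1000, 1500))
grade_neutropenia <- function(anc, config = default_config()) {
  if (any(is.na(anc)) || any(anc < 0)) {
    abort("anc must be non-negative and non-missing")
  }
  b <- config$thresholds$anc_bands
  dplyr::case_when(
    anc < b[["severe"]] ~ "severe",
    anc < b[["moderate"]] ~ "moderate",
    anc < b[["mild"]] ~ "mild",
    TRUE ~ "none"
  )
}

# age-banded MCV upper limit (fL); right-closed age bands
mcv_upper_limit <- function(age_years, config = default_config()) {
  tab <- config$thresholds$mcv_table
  if (is.null(tab)) {
    return(rep(config$thresholds$mcv_fallback, length(age_years)))
  }
  vapply(age_years, function(a) {
    if (is.na(a)) {
      return(config$thresholds$mcv_fallback)
    }
    tab$mcv_upper[[which(a <= tab$age_upper)[1]]]
  }, numeric(1))
}

#' Classify anemia on a single measurement
#'
#' A measurement is anemic when hemoglobin falls below the screening
#' threshold (default flat 10.5 g/dL). Anemia is macrocytic when the MCV
#' exceeds the age-banded macrocytosis cutoff; with the MCV unknown the
#' anemia is reported normocytic by default and flagged as such.
#'
#' @param hb Hemoglobin, g/dL.
#' @param mcv Mean corpuscular volume, fL, or `NA`.
#' @param age_years Age at measurement (selects the MCV band).
#' @param sex Unused by the flat default threshold; accepted so an age/sex
#'   reference table can be plugged in via config.
#' @param config Run configuration.
#' @return A list with `status` (`"none"`, `"normocytic"`, `"macrocytic"`)
#'   and `mcv_imputed` (`TRUE` when the MCV was unknown).
#' @export
#' @examples
#' classify_anemia(9.0, 102, age_years = 4)$status
classify_anemia <- function(hb, mcv = NA_real_, age_years = NA_real_,
                            sex = "unknown", config = default_config()) {
  if (is.na(hb) || hb < 0) abort("hb must be non-negative and non-missing")
  if (hb >= config$thresholds$hb_anemia) {
    return(list(status = "none", mcv_imputed = FALSE))
  }
  if (is.na(mcv)) {
    return(list(status = "normocytic", mcv_imputed = TRUE))
  }
  cutoff <- mcv_upper_limit(age_years, config)
  status <- if (mcv > cutoff) "macrocytic" else "normocytic"
  list(status = status, mcv_imputed = FALSE)
}

#' Per-lineage status of one CBC measurement
#'
#' @param m One row of a CBC series (list or single-row data frame) with
#'   `age_years`, `hb`, `mcv`, `anc`, `platelets`, `retic_abs`.
#' @param config Run configuration.
#' @return A list with `anemia` (`"none"`/`"normocytic"`/`"macrocytic"`),
#'   `neutropenia` (severity grade), `thrombocytopenia`
#'   (`"absent"`/`"present"`) and `reticulocytopenia`
#'   (`"absent"`/`"present"`/`"unknown"`).
#' @export
lineage_status <- function(m, config = default_config()) {
  m <- as.list(m)
  an <- if (is.na(m$hb %||% NA_real_)) {
    list(status = "none", mcv_imputed = FALSE)
  } else {
    classify_anemia(m$hb, m$mcv %||% NA_real_, m$age_years, config = config)
  }
  retic <- m$retic_abs %||% NA_real_
  list(
    anemia = an$status,
    mcv_imputed = an$mcv_imputed,
    neutropenia = if (is.na(m$anc)) "none" else grade_neutropenia(m$anc, config),
    thrombocytopenia = if (!is.na(m$platelets) && m$platelets < config$thresholds$plt_threshold) {
      "present"
    } else {
      "absent"
    },
    reticulocytopenia = if (is.na(retic)) {
      "unknown"
    } else if (retic < config$thresholds$retic_abs_min) {
      "present"
    } else {
      "absent"
    }
  )
}

#' Cytopenia class from a lineage status
#'
#' The class is a pure function of the number of affected lineages:
#' 0 none, 1 unilineage, 2 bilineage, 3 pancytopenia.
#'
#' @param s A lineage status from [lineage_status()].
#' @return A list with `value` and `affected_lineages` (subset of
#'   `"erythroid"`, `"myeloid"`, `"megakaryocytic"`).
#' @export
#' @examples
#' s <- lineage_status(list(age_years = 4, hb = 8, mcv = 80, anc = 300, platelets = 40000))
#' cytopenia_class(s)$value
cytopenia_class <- function(s) {
  affected <- c(
    if (s$anemia != "none") "erythroid",
    if (s$neutropenia != "none") "myeloid",
    if (s$thrombocytopenia == "present") "megakaryocytic"
  )
  value <- c("none", "unilineage", "bilineage", "pancytopenia")[length(affected) + 1]
  list(value = value, affected_lineages = affected %||% character())
}

#' Transfusion dependency by the sliding 28-day window rule
#'
#' A patient is transfusion-dependent when some window of at most
#' `rbc_window_days` days (inclusive span, default 28) contains at least
#' `rbc_units_min` RBC units (default 2). Non-RBC products are ignored;
#' events need not be pre-sorted.
#'
#' @param events Tibble/data frame with `age_days`, `product`, `units`.
#' @param config Run configuration.
#' @return Logical scalar.
#' @export
#' @examples
#' transfusion_dependent(data.frame(
#'   age_days = c(0, 20), product = "RBC", units = 1
#' ))
transfusion_dependent <- function(events, config = default_config()) {
  if (is.null(events) || nrow(events) == 0) {
    return(FALSE)
  }
  rbc <- events[events$product == "RBC", , drop = FALSE]
  if (nrow(rbc) == 0) {
    return(FALSE)
  }
  days <- sort(rep(rbc$age_days, rbc$units))
  w <- config$thresholds$rbc_window_days
  k <- config$thresholds$rbc_units_min
  n <- length(days)
  if (n < k) {
    return(FALSE)
  }
  # after sorting, a window holding k units is k-1 consecutive gaps <= w
  any(days[seq_len(n - k + 1) + (k - 1)] - days[seq_len(n - k + 1)] <= w)
}

#' Hematologic onset age and category
#'
#' Onset is the age of the first CBC measurement meeting any cytopenia
#' criterion; for records without a CBC series the earliest onset age of an
#' asserted hematologic HPO feature is used. Categories follow the pediatric
#' buckets: `le2` (<= 2 y), `gt2_le5` (> 2 and <= 5), `gt5_lt18`
#' (> 5 and < 18), `adult` (>= 18), `none` (never cytopenic).
#'
#' @param record An `ibmfs_patient`.
#' @param catalog Catalog (to recognize hematologic features).
#' @param config Run configuration.
#' @return A list with `onset_age_years` (or `NA`) and `onset_category`.
#' @export
onset <- function(record, catalog = load_catalog(), config = default_config()) {
  age <- NA_real_
  cbc <- record$cbc_series
  if (nrow(cbc) > 0) {
    for (i in seq_len(nrow(cbc))) {
      cls <- cytopenia_class(lineage_status(cbc[i, ], config))
      if (cls$value != "none") {
        age <- cbc$age_years[[i]]
        break
      }
    }
  }
  if (is.na(age)) {
    hem <- match_features(record, catalog$groups$hematologic, catalog)
    onsets <- record$features$onset_age_years[record$features$term_id %in% hem]
    onsets <- onsets[!is.na(onsets)]
    if (length(onsets) > 0) age <- min(onsets)
  }
  list(onset_age_years = age, onset_category = onset_category(age))
}

onset_category <- function(age) {
  if (is.na(age)) {
    "none"
  } else if (age <= 2) {
    "le2"
  } else if (age <= 5) {
    "gt2_le5"
  } else if (age < 18) {
    "gt5_lt18"
  } else {
    "adult"
  }
}

#' Persistent and cyclic neutropenia over a CBC series
#'
#' Persistent: ANC < 1500/uL in at least `persistence_fraction` (default 0.9)
#' of all measurements and never at or above `persistence_ceiling` (2500/uL).
#' Cyclic: the ANC crosses 1500/uL downward at least twice with at least one
#' nadir < 500/uL; series shorter than 4 measurements are reported `FALSE`
#' with an `insufficient` flag.
#'
#' @param series CBC tibble with an `anc` column.
#' @param config Run configuration.
#' @return `persistent_neutropenia()`: logical. `cyclic_pattern()`: logical
#'   with attribute `insufficient` when too few measurements.
#' @export
persistent_neutropenia <- function(series, config = default_config()) {
  anc <- series$anc[!is.na(series$anc)]
  if (length(anc) == 0) {
    return(FALSE)
  }
  th <- config$thresholds
  frac <- mean(anc < th$anc_bands[["mild"]])
  frac >= th$persistence_fraction && all(anc < th$persistence_ceiling)
}

#' @rdname persistent_neutropenia
#' @export
cyclic_pattern <- function(series, config = default_config()) {
  anc <- series$anc[!is.na(series$anc)]
  th <- config$thresholds
  if (length(anc) < th$cyclic_min_measurements) {
    return(structure(FALSE, insufficient = TRUE))
  }
  thr <- th$cyclic_threshold
  down <- sum(anc[-length(anc)] >= thr & anc[-1] < thr)
  down >= th$cyclic_min_crossings && min(anc) < th$cyclic_nadir
}

worst_of <- function(values, order) {
  order[max(match(values, order))]
}

#' Aggregate hematology profile of a patient record
#'
#' Deterministic aggregate of the per-measurement interpretations:
#' worst-ever grade per lineage, cumulative cytopenia class, onset age and
#' category, transfusion dependency, persistent/cyclic neutropenia, and the
#' Diamond-Blackfan trigger (some single measurement macrocytic-anemic with
#' absolute reticulocytes below the config threshold).
#'
#' @param record An `ibmfs_patient`.
#' @param catalog An `ibmfs_catalog`.
#' @param config Run configuration.
#' @return An object of class `ibmfs_hematology_profile`.
#' @export
#' @examples
#' p <- patient_record("p1", cbc_series = data.frame(
#'   age_years = c(1, 2), hb = c(12.5, 8.0), mcv = c(80, 98),
#'   anc = c(3000, 900), platelets = c(250000, 90000), retic_abs = c(45, 8)
#' ))
#' hematology_profile(p)$worst_class$value
hematology_profile <- function(record, catalog = load_catalog(),
                               config = default_config()) {
  cbc <- record$cbc_series
  statuses <- lapply(seq_len(nrow(cbc)), function(i) lineage_status(cbc[i, ], config))
  anemia_order <- c("none", "normocytic", "macrocytic")
  neut_order <- c("none", "mild", "moderate", "severe")
  ever <- list(
    anemia = if (length(statuses)) {
      worst_of(vapply(statuses, `[[`, "", "anemia"), anemia_order)
    } else {
      "none"
    },
    neutropenia = if (length(statuses)) {
      worst_of(vapply(statuses, `[[`, "", "neutropenia"), neut_order)
    } else {
      "none"
    },
    thrombocytopenia = if (length(statuses) &&
      any(vapply(statuses, `[[`, "", "thrombocytopenia") == "present")) {
      "present"
    } else {
      "absent"
    },
    reticulocytopenia = if (!length(statuses)) {
      "unknown"
    } else {
      r <- vapply(statuses, `[[`, "", "reticulocytopenia")
      if (any(r == "present")) "present" else if (any(r == "absent")) "absent" else "unknown"
    }
  )
  worst_class <- cytopenia_class(list(
    anemia = ever$anemia, neutropenia = ever$neutropenia,
    thrombocytopenia = ever$thrombocytopenia
  ))
  # DBA trigger must co-occur within one measurement
  macro_retic <- NA
  if (length(statuses) > 0) {
    per_meas <- vapply(seq_along(statuses), function(i) {
      s <- statuses[[i]]
      if (s$anemia != "macrocytic") {
        return("no")
      }
      switch(s$reticulocytopenia,
        present = "yes",
        absent = "no",
        unknown = "unknown"
      )
    }, character(1))
    macro_retic <- if (any(per_meas == "yes")) {
      TRUE
    } else if (any(per_meas == "unknown")) {
      NA
    } else {
      FALSE
    }
  }
  ons <- onset(record, catalog, config)
  structure(
    list(
      ever_status = ever,
      worst_class = worst_class,
      onset_age_years = ons$onset_age_years,
      onset_category = ons$onset_category,
      transfusion_dependent = transfusion_dependent(record$transfusions, config),
      persistent_neutropenia = persistent_neutropenia(cbc, config),
      cyclic_neutropenia = as.logical(cyclic_pattern(cbc, config)),
      macrocytic_anemia_with_reticulocytopenia = macro_retic,
      n_measurements = nrow(cbc)
    ),
    class = "ibmfs_hematology_profile"
  )
}

#' @export
print.ibmfs_hematology_profile <- function(x, ...) {
  cat("<ibmfs_hematology_profile>\n",
    "  worst class: ", x$worst_class$value,
    " [", paste(x$worst_class$affected_lineages, collapse = ", "), "]\n",
    "  onset: ", format(x$onset_age_years), " y (", x$onset_category, ")\n",
    "  transfusion-dependent: ", x$transfusion_dependent,
    "; persistent neutropenia: ", x$persistent_neutropenia,
    "; cyclic: ", x$cyclic_neutropenia, "\n",
    sep = ""
  )
  invisible(x)
}
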