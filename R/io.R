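#' @title Patient record JSON dialect
#' @description One JSON object per patient, with keys mirroring the fields
#'   of [patient_record()]: `patient_id`, `family_id`, `sex`, `age_years`,
#'   `features` (array of `{term_id, onset_age_years}`), `cbc_series` (array
#'   of measurement objects, or a string naming a sidecar CSV with header
#'   `age_years,hb,mcv,anc,platelets,wbc,retic_abs,hbf_percent`),
#'   `transfusions`, `labs`, `family`, `prenatal` and `personal_malignancy`.
#'   JSON `null` and absent keys both mean unknown, never negative. A cohort
#'   is a directory of `*.json` files or a single NDJSON file (one record per
#'   line).
#' @name record-io
NULL

#' Read a patient record from JSON
#'
#' @param source Path to a JSON file, or a JSON string.
#' @param catalog Catalog used for validation.
#' @return An `ibmfs_patient`.
#' @export
read_patient_record <- function(source, catalog = load_catalog()) {
  x <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  base_dir <- if (is.character(source) && file.exists(source)) dirname(source) else "."
  record_from_list(x, catalog, base_dir = base_dir)
}

record_from_list <- function(x, catalog, base_dir = ".") {
  if (is.null(x$patient_id)) {
    abort("missing patient_id at $.patient_id")
  }
  cbc <- x$cbc_series
  if (is.character(cbc) && length(cbc) == 1) {
    csv_path <- file.path(base_dir, cbc)
    if (!file.exists(csv_path)) {
      abort(paste0("cbc_series sidecar CSV not found: ", csv_path))
    }
    cbc_df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
    expected <- c("age_years", "hb", "mcv", "anc", "platelets", "wbc", "retic_abs", "hbf_percent")
    names(cbc_df)[names(cbc_df) == "retic_abs"] <- "retic_abs"
    if (!all(names(cbc_df) %in% expected)) {
      abort("sidecar CSV header must be age_years,hb,mcv,anc,platelets,wbc,retic_abs,hbf_percent")
    }
    cbc <- cbc_df
  } else if (!is.null(cbc)) {
    cbc <- rows_to_df(cbc, cbc_columns)
  }
  feats <- rows_to_df(x$features, c("term_id", "onset_age_years"))
  trans <- rows_to_df(x$transfusions, c("age_days", "product", "units"))
  malig <- rows_to_df(x$personal_malignancy, c("type", "onset_age_years"))
  patient_record(
    patient_id = x$patient_id,
    sex = x$sex %||% "unknown",
    age_years = x$age_years %||% NA_real_,
    features = feats,
    cbc_series = cbc,
    transfusions = trans,
    labs = as_plain_list(x$labs),
    family = as_plain_list(x$family),
    prenatal = list(
      fgr = x$prenatal$fgr %||% NA,
      sga = x$prenatal$sga %||% NA
    ),
    personal_malignancy = malig,
    family_id = x$family_id,
    catalog = catalog
  )
}

rows_to_df <- function(rows, cols) {
  if (is.null(rows) || length(rows) == 0) {
    return(NULL)
  }
  if (is.data.frame(rows)) {
    return(rows)
  }
  out <- purrr::map_dfr(rows, function(r) {
    r <- lapply(r, function(v) if (is.null(v)) NA else v)
    missing <- setdiff(cols, names(r))
    for (m in missing) r[[m]] <- NA
    as_tibble(r[cols])
  })
  out
}

as_plain_list <- function(x) {
  if (is.null(x)) {
    return(list())
  }
  lapply(x, function(v) if (is.null(v)) NA else unlist(v))
}

#' Write a patient record to JSON
#'
#' Serialization is lossless: unknown (tri-state `NA`) fields are written as
#' JSON `null`, so `read_patient_record(write_patient_record(r))` returns an
#' identical record.
#'
#' @param record An `ibmfs_patient`.
#' @param sink File path; `NULL` returns the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
write_patient_record <- function(record, sink = NULL) {
  x <- list(
    patient_id = record$patient_id,
    family_id = record$family_id,
    sex = record$sex,
    age_years = record$age_years,
    features = df_to_rows(record$features),
    cbc_series = df_to_rows(record$cbc_series),
    transfusions = df_to_rows(record$transfusions),
    labs = record$labs,
    family = record$family,
    prenatal = record$prenatal,
    personal_malignancy = df_to_rows(record$personal_malignancy)
  )
  json <- jsonlite::toJSON(x,
    auto_unbox = TRUE, null = "null", na = "null",
    digits = NA, pretty = TRUE
  )
  if (is.null(sink)) {
    return(json)
  }
  writeLines(json, sink)
  invisible(json)
}

df_to_rows <- function(df) {
  if (nrow(df) == 0) {
    return(list())
  }
  lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
}

#' Read a cohort of patient records
#'
#' @param path Directory of `*.json` patient files, or a single NDJSON file
#'   with one record per line.
#' @param catalog Catalog used for validation.
#' @return A list of `ibmfs_patient` records (class `ibmfs_cohort`). Per-file
#'   parse errors are aggregated into a single error message; duplicate
#'   patient ids are an error.
#' @export
read_cohort <- function(path, catalog = load_catalog()) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
    if (length(files) == 0) {
      abort(paste0("no .json records found in ", path))
    }
    parsed <- lapply(files, function(f) {
      tryCatch(list(ok = read_patient_record(f, catalog)),
        error = function(e) list(err = paste0(basename(f), ": ", conditionMessage(e)))
      )
    })
  } else if (file.exists(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parsed <- lapply(seq_along(lines), function(i) {
      tryCatch(list(ok = read_patient_record(lines[[i]], catalog)),
        error = function(e) list(err = paste0("line ", i, ": ", conditionMessage(e)))
      )
    })
  } else {
    abort(paste0("cohort path not found: ", path))
  }
  errs <- unlist(lapply(parsed, function(p) p$err))
  if (length(errs) > 0) {
    abort(paste0("cohort read errors:\n", paste(errs, collapse = "\n")))
  }
  records <- lapply(parsed, function(p) p$ok)
  ids <- vapply(records, function(r) r$patient_id, character(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(paste0("duplicate patient_id in cohort: ", paste(dup, collapse = ", ")))
  }
  as_cohort(records)
}

#' Write a cohort to a directory of JSON files
#'
#' @param cohort List of `ibmfs_patient` records.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (rec in cohort) {
    write_patient_record(rec, file.path(dir, paste0(rec$patient_id, ".json")))
  }
  invisible(dir)
}

as_cohort <- function(records) {
  structure(records, class = c("ibmfs_cohort", "list"))
}

#' @export
print.ibmfs_cohort <- function(x, ...) {
  cat("<ibmfs_cohort> ", length(x), " patient records\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.ibmfs_cohort <- function(x, ...) {
  tibble(
    patient_id = vapply(x, function(r) r$patient_id, character(1)),
    family_id = vapply(x, function(r) r$family_id, character(1)),
    sex = vapply(x, function(r) r$sex, character(1)),
    age_years = vapply(x, function(r) r$age_years, numeric(1)),
    n_features = vapply(x, function(r) nrow(r$features), integer(1)),
    n_cbc = vapply(x, function(r) nrow(r$cbc_series), integer(1)),
    record = x
  )
}
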