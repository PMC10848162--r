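#' Summarize a classified cohort
#'
#' Aggregates records and their triage results into the frequency tables a
#' cohort report needs: sex counts, onset-age categories (denominator =
#' patients with any hematologic onset), beacon counts, primary-label
#' counts, phenotype feature-group prevalence (exact term or catalog
#' descendant), per-label feature prevalence, median age by label, and the
#' transfusion-dependency, pancytopenia and bone-marrow-biopsy tallies.
#' Percentages are reported both raw and integer-truncated, since clinical
#' tables commonly print the truncated form.
#'
#' @param cohort List of `ibmfs_patient` records.
#' @param results Tibble from [classify_cohort()] (computed when `NULL`).
#' @param catalog An `ibmfs_catalog`.
#' @param config Run configuration.
#' @param groups Feature groups to tabulate prevalence for.
#' @return An object of class `ibmfs_cohort_summary` (a named list of
#'   tibbles and counts).
#' @export
#' @examples
#' \donttest{
#' cohort <- build_reference_fixture()
#' summ <- summarize_cohort(cohort)
#' summ$primary_label_counts
#' }
summarize_cohort <- function(cohort, results = NULL,
                             catalog = load_catalog(),
                             config = default_config(),
                             groups = c(
                               "craniofacial", "neurological",
                               "integument", "growth"
                             )) {
  if (is.null(results)) {
    results <- classify_cohort(cohort, catalog, config)
  }
  ids <- vapply(cohort, `[[`, "", "patient_id")
  if (!setequal(ids, results$patient_id) || length(ids) != nrow(results)) {
    abort("results do not align with cohort patient_ids")
  }
  # order-invariant: index records by id
  results <- arrange(results, match(.data$patient_id, sort(.data$patient_id)))
  cohort <- cohort[order(ids)]
  ids <- sort(ids)
  n <- length(cohort)
  if (n == 0) {
    return(empty_summary())
  }

  sexes <- vapply(cohort, `[[`, "", "sex")
  ages <- vapply(cohort, `[[`, 0, "age_years")
  profiles <- lapply(results$result, `[[`, "profile")
  onset_cat <- vapply(profiles, `[[`, "", "onset_category")
  with_onset <- sum(onset_cat != "none")

  beacons <- lapply(results$result, `[[`, "beacons")
  beacon_counts <- tibble(
    beacon = names(beacons[[1]]),
    count = vapply(
      names(beacons[[1]]),
      function(b) sum(vapply(beacons, function(x) isTRUE(x[[b]]), logical(1))),
      integer(1)
    )
  )

  label_counts <- count(results, .data$primary, name = "count")

  fg <- purrr::map_dfr(groups, function(g) {
    root <- catalog$groups[[g]]
    cnt <- sum(vapply(cohort, function(r) {
      any(vapply(root, function(t) has_feature(r, t, catalog), logical(1)))
    }, logical(1)))
    tibble(
      group = g, count = cnt,
      percent_raw = 100 * cnt / n,
      percent_trunc = trunc(100 * cnt / n)
    )
  })

  per_group <- purrr::map_dfr(unique(results$primary), function(lab) {
    in_lab <- results$patient_id[results$primary == lab]
    recs <- cohort[ids %in% in_lab]
    purrr::map_dfr(groups, function(g) {
      root <- catalog$groups[[g]]
      cnt <- sum(vapply(recs, function(r) {
        any(vapply(root, function(t) has_feature(r, t, catalog), logical(1)))
      }, logical(1)))
      tibble(
        label = lab, group = g, n_label = length(recs), count = cnt,
        percent_raw = 100 * cnt / length(recs),
        percent_trunc = trunc(100 * cnt / length(recs))
      )
    })
  })

  bm <- unlist(lapply(cohort, function(r) r$labs$bm_biopsy))
  bm_counts <- count(tibble(finding = bm), .data$finding, name = "count")

  structure(
    list(
      n = n,
      n_families = length(unique(vapply(cohort, `[[`, "", "family_id"))),
      sex_counts = count(tibble(sex = sexes), .data$sex, name = "count"),
      age_mean = mean(ages), age_sd = sd(ages), age_median = median(ages),
      onset_category_counts = count(
        tibble(onset_category = onset_cat[onset_cat != "none"]),
        .data$onset_category,
        name = "count"
      ),
      onset_denominator = with_onset,
      beacon_counts = beacon_counts,
      primary_label_counts = label_counts,
      n_specific = sum(results$primary %in% syndrome_labels),
      feature_group_prevalence = fg,
      per_group_feature_prevalence = per_group,
      median_age_by_label = results %>%
        mutate(age = ages[match(.data$patient_id, ids)]) %>%
        group_by(.data$primary) %>%
        summarise(median_age = median(.data$age), .groups = "drop"),
      transfusion_dependent_count = sum(results$transfusion_dependent),
      pancytopenia_count = sum(results$worst_class == "pancytopenia"),
      bm_biopsy_counts = bm_counts
    ),
    class = "ibmfs_cohort_summary"
  )
}

empty_summary <- function() {
  structure(
    list(
      n = 0L, n_families = 0L,
      sex_counts = tibble(sex = character(), count = integer()),
      age_mean = NA_real_, age_sd = NA_real_, age_median = NA_real_,
      onset_category_counts = tibble(onset_category = character(), count = integer()),
      onset_denominator = 0L,
      beacon_counts = tibble(beacon = character(), count = integer()),
      primary_label_counts = tibble(primary = character(), count = integer()),
      n_specific = 0L,
      feature_group_prevalence = tibble(
        group = character(), count = integer(),
        percent_raw = numeric(), percent_trunc = numeric()
      ),
      per_group_feature_prevalence = tibble(
        label = character(), group = character(), n_label = integer(),
        count = integer(), percent_raw = numeric(), percent_trunc = numeric()
      ),
      median_age_by_label = tibble(primary = character(), median_age = numeric()),
      transfusion_dependent_count = 0L,
      pancytopenia_count = 0L,
      bm_biopsy_counts = tibble(finding = character(), count = integer())
    ),
    class = "ibmfs_cohort_summary"
  )
}

#' @export
print.ibmfs_cohort_summary <- function(x, ...) {
  cat("<ibmfs_cohort_summary> n = ", x$n, " (", x$n_families, " families)\n", sep = "")
  if (x$n > 0) {
    cat("  specific suspicion: ", x$n_specific, "/", x$n, "\n", sep = "")
    lab <- x$primary_label_counts
    cat("  labels: ", paste(lab$primary, lab$count, sep = "=", collapse = ", "), "\n", sep = "")
    cat(
      "  pancytopenia: ", x$pancytopenia_count,
      "; transfusion-dependent: ", x$transfusion_dependent_count, "\n",
      sep = ""
    )
  }
  invisible(x)
}

#' @export
tidy.ibmfs_cohort_summary <- function(x, ...) {
  bind_rows(
    x$primary_label_counts %>%
      rename(level = "primary") %>%
      mutate(table = "primary_label"),
    x$sex_counts %>% rename(level = "sex") %>% mutate(table = "sex"),
    x$onset_category_counts %>%
      rename(level = "onset_category") %>%
      mutate(table = "onset_category"),
    x$beacon_counts %>% rename(level = "beacon") %>% mutate(table = "beacon"),
    x$feature_group_prevalence %>%
      select(level = "group", "count") %>%
      mutate(table = "feature_group")
  ) %>%
    select("table", "level", "count")
}

#' @export
glance.ibmfs_cohort_summary <- function(x, ...) {
  tibble(
    n = x$n, n_families = x$n_families, n_specific = x$n_specific,
    pancytopenia = x$pancytopenia_count,
    transfusion_dependent = x$transfusion_dependent_count,
    age_mean = x$age_mean, age_sd = x$age_sd
  )
}

#' Compare a variable across suspicion groups
#'
#' Categorical variables are compared with a chi-square test on the label ×
#' level contingency table (no continuity correction by default, matching
#' common practice for multi-level tables; toggle via `config$yates`);
#' continuous variables with one-way ANOVA. A warning flag is set when any
#' expected cell count falls below 5.
#'
#' @param cohort List of `ibmfs_patient` records.
#' @param results Tibble from [classify_cohort()].
#' @param variable One of `"sex"`, `"age_years"`, `"onset_category"`, or a
#'   numeric vector aligned with the cohort.
#' @param type `"categorical"` or `"continuous"`; inferred for the built-in
#'   variables.
#' @param config Run configuration.
#' @return A one-row tibble: `variable`, `method`, `statistic`, `df` (and
#'   `df2` for ANOVA), `p_value`, `low_expected_cells`, `significant` (at
#'   0.05).
#' @export
group_compare <- function(cohort, results, variable, type = NULL,
                          config = default_config()) {
  labels <- results$primary
  if (length(unique(labels)) < 2) {
    abort("group_compare needs at least 2 groups")
  }
  if (is.character(variable) && length(variable) == 1) {
    values <- switch(variable,
      sex = vapply(cohort, `[[`, "", "sex"),
      age_years = vapply(cohort, `[[`, 0, "age_years"),
      onset_category = results$onset_category,
      abort(paste0("unknown built-in variable: ", variable))
    )
    vname <- variable
    type <- type %||% if (is.numeric(values)) "continuous" else "categorical"
  } else {
    values <- variable
    vname <- "user_variable"
    type <- type %||% if (is.numeric(values)) "continuous" else "categorical"
  }
  if (type == "categorical") {
    tab <- table(labels, values)
    ct <- suppressWarnings(chisq.test(tab, correct = isTRUE(config$yates)))
    tibble(
      variable = vname, method = "chi-square",
      statistic = unname(ct$statistic), df = unname(ct$parameter), df2 = NA_real_,
      p_value = unname(ct$p.value),
      low_expected_cells = any(ct$expected < 5),
      significant = unname(ct$p.value) < 0.05
    )
  } else {
    fit <- aov(values ~ factor(labels))
    s <- summary(fit)[[1]]
    tibble(
      variable = vname, method = "anova",
      statistic = s[["F value"]][1], df = s[["Df"]][1], df2 = s[["Df"]][2],
      p_value = s[["Pr(>F)"]][1],
      low_expected_cells = NA,
      significant = s[["Pr(>F)"]][1] < 0.05
    )
  }
}

#' Descriptive statistics of a numeric vector
#'
#' @param values Numeric vector (`NA`s dropped).
#' @return One-row tibble with `n`, `mean`, `sd` (sample, n-1; `NA` for a
#'   single value), `median` (midpoint convention for even n), `min`, `max`.
#' @export
#' @examples
#' describe_values(c(1, 2, 3, 4))
describe_values <- function(values) {
  values <- values[!is.na(values)]
  tibble(
    n = length(values),
    mean = if (length(values)) mean(values) else NA_real_,
    sd = if (length(values) > 1) sd(values) else NA_real_,
    median = if (length(values)) median(values) else NA_real_,
    min = if (length(values)) min(values) else NA_real_,
    max = if (length(values)) max(values) else NA_real_
  )
}

#' Plot the primary-label distribution of a cohort summary
#'
#' @param object An `ibmfs_cohort_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ibmfs_cohort_summary <- function(object, ...) {
  df <- object$primary_label_counts
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$primary, -.data$count),
    y = .data$count
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "primary suspicion", y = "patients") +
    ggplot2::theme_minimal()
}

#' Plot a patient's CBC series against the cytopenia thresholds
#'
#' @param record An `ibmfs_patient`.
#' @param config Run configuration (threshold lines).
#' @return A ggplot faceted by analyte (Hb, ANC, platelets).
#' @export
plot_cbc_series <- function(record, config = default_config()) {
  cbc <- record$cbc_series
  long <- tidyr::pivot_longer(
    cbc[c("age_years", "hb", "anc", "platelets")],
    cols = c("hb", "anc", "platelets"),
    names_to = "analyte", values_to = "value"
  )
  th <- tibble(
    analyte = c("hb", "anc", "platelets"),
    threshold = c(
      config$thresholds$hb_anemia,
      unname(config$thresholds$anc_bands[["mild"]]),
      config$thresholds$plt_threshold
    )
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$age_years, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = th, ggplot2::aes(yintercept = .data$threshold),
      linetype = "dashed", colour = "firebrick"
    ) +
    ggplot2::facet_wrap(~analyte, scales = "free_y") +
    ggplot2::labs(
      x = "age (years)", y = NULL,
      title = paste0("CBC series: ", record$patient_id)
    ) +
    ggplot2::theme_minimal()
}
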