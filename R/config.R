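#' Default run configuration
#'
#' Returns the packaged defaults for every tunable threshold used by the CBC
#' interpreter and the triage rules, together with the syndrome precedence
#' order. All units follow conventional clinical usage: hemoglobin in g/dL,
#' absolute neutrophil count (ANC) and platelets in cells/uL, absolute
#' reticulocytes in 10^9/L, ages in years, transfusion windows in days.
#'
#' The thresholds block contains:
#' \describe{
#'   \item{hb_anemia}{Hemoglobin below which a measurement is anemic
#'     (flat 10.5 g/dL screening reference).}
#'   \item{anc_bands}{Named vector of half-open ANC band edges: severe < 500,
#'     moderate 500--<1000, mild 1000--<1500; >= 1500 is normal.}
#'   \item{plt_threshold}{Platelets below 150,000/uL define thrombocytopenia.}
#'   \item{retic_abs_min}{Absolute reticulocytes below 20 x 10^9/L define
#'     reticulocytopenia.}
#'   \item{mcv_table}{Age-banded MCV upper limits (fL) defining macrocytosis;
#'     bands are right-closed on age. \code{mcv_fallback} (100 fL) is used
#'     when the table is disabled.}
#'   \item{persistence_fraction}{Fraction of measurements that must be
#'     neutropenic (< 1500/uL) for persistent neutropenia; default 0.9 so a
#'     stray post-treatment normal value does not defeat the flag.}
#'   \item{persistence_ceiling}{An ANC at or above this value (2500/uL) is
#'     taken as a genuinely normal count and vetoes persistence.}
#'   \item{cyclic_threshold, cyclic_min_crossings, cyclic_nadir,
#'     cyclic_min_measurements}{Cyclic neutropenia requires >= 2 downward
#'     crossings of 1500/uL with at least one nadir < 500/uL, over a series of
#'     at least 4 measurements.}
#'   \item{rbc_window_days, rbc_units_min}{Transfusion dependency: >= 2 RBC
#'     units within any 28-day inclusive span.}
#'   \item{endogamy_population_max}{Settlement population below 5,000
#'     inhabitants flags endogamy.}
#'   \item{onset_pediatric_max}{Hematologic onset before 18 years satisfies
#'     the pediatric-onset eligibility arm.}
#' }
#'
#' @return A named list with elements `thresholds`, `precedence` (character
#'   vector, highest first) and `yates` (logical; continuity correction for
#'   chi-square tests).
#' @seealso [load_config()]
#' @export
#' @examples
#' default_config()$thresholds$hb_anemia
default_config <- function() {
  list(
    thresholds = list(
      hb_anemia = 10.5,
      anc_bands = c(severe = 500, moderate = 1000, mild = 1500),
      plt_threshold = 150000,
      retic_abs_min = 20,
      mcv_table = list(
        age_upper = c(0.5, 2, 6, 12, 18, Inf),
        mcv_upper = c(108, 86, 87, 95, 98, 100)
      ),
      mcv_fallback = 100,
      persistence_fraction = 0.9,
      persistence_ceiling = 2500,
      cyclic_threshold = 1500,
      cyclic_min_crossings = 2,
      cyclic_nadir = 500,
      cyclic_min_measurements = 4,
      rbc_window_days = 28,
      rbc_units_min = 2,
      endogamy_population_max = 5000,
      onset_pediatric_max = 18
    ),
    precedence = c("TAR", "SCN", "DC", "SDS", "DBA"),
    yates = FALSE,
    catalog = NULL
  )
}

#' Load a run configuration, optionally overridden from YAML
#'
#' Reads a YAML file whose top-level keys are a subset of
#' `thresholds`, `precedence`, `yates` and `catalog`, and merges it over
#' [default_config()]. Unknown top-level keys are rejected rather than
#' silently ignored. The `catalog` block (extra terms and group extensions)
#' is consumed by [load_catalog()].
#'
#' @param path Path to a YAML config file, or `NULL` for pure defaults.
#' @return A config list as described in [default_config()].
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) {
    return(cfg)
  }
  user <- yaml::read_yaml(path)
  if (!is.list(user)) {
    abort("config file must be a YAML mapping")
  }
  extra <- setdiff(names(user), names(cfg))
  if (length(extra) > 0) {
    abort(paste0("unknown config keys: ", paste(extra, collapse = ", ")))
  }
  if (!is.null(user$precedence)) {
    prec <- as.character(user$precedence)
    if (!setequal(prec, cfg$precedence)) {
      abort("precedence override must be a permutation of TAR, SCN, DC, SDS, DBA")
    }
    cfg$precedence <- prec
    user$precedence <- NULL
  }
  cfg <- modifyList(cfg, user)
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  stopifnot(
    is.numeric(th$hb_anemia), th$hb_anemia > 0,
    length(th$anc_bands) == 3, all(diff(unname(th$anc_bands)) > 0),
    th$plt_threshold > 0, th$retic_abs_min > 0,
    length(th$mcv_table$age_upper) == length(th$mcv_table$mcv_upper),
    th$persistence_fraction > 0, th$persistence_fraction <= 1,
    th$rbc_window_days > 0, th$rbc_units_min >= 1
  )
  invisible(cfg)
}
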