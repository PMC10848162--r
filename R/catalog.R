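#' @title Embedded phenotype feature catalog
#' @description The package ships a small curated table of HPO terms — the
#'   ~50 terms the triage rules and cohort summaries need — together with the
#'   parent links required for descendant matching and the named groups the
#'   rules consume (mucocutaneous triad, per-syndrome associated-feature sets,
#'   VACTERL-H/PHENOS screens, organ-system roots). It is not a full ontology:
#'   matching is exact-term-or-descendant within this catalog only.
#' @name catalog
NULL

default_term_table <- function() {
  tribble(
    ~term_id, ~label, ~parents,
    # craniofacial
    "HP:0001999", "Abnormal facial shape", character(),
    "HP:0000276", "Long face", "HP:0001999",
    "HP:0000414", "Bulbous nose", "HP:0001999",
    "HP:0011800", "Midface retrusion", "HP:0001999",
    "HP:0000308", "Microretrognathia", "HP:0001999",
    "HP:0000286", "Epicanthus", "HP:0001999",
    "HP:0000252", "Microcephaly", "HP:0001999",
    # neurological
    "HP:0000707", "Abnormality of the nervous system", character(),
    "HP:0002011", "Morphological central nervous system abnormality", "HP:0000707",
    "HP:0012758", "Neurodevelopmental delay", "HP:0000707",
    "HP:0001263", "Global developmental delay", "HP:0000707",
    "HP:0100543", "Cognitive impairment", "HP:0000707",
    "HP:0001250", "Seizure", "HP:0000707",
    "HP:0000238", "Hydrocephalus", "HP:0000707",
    # integument (skin, nails, hair, mucosae)
    "HP:0001574", "Abnormality of the integument", character(),
    "HP:0007441", "Hyper- and hypopigmented skin macules", "HP:0001574",
    "HP:0000957", "Cafe-au-lait spot", "HP:0001574",
    "HP:0007427", "Reticular hyperpigmentation", "HP:0001574",
    "HP:0001597", "Abnormality of the nail", "HP:0001574",
    "HP:0002164", "Nail dysplasia", "HP:0001597",
    "HP:0002216", "Premature graying of hair", "HP:0001574",
    "HP:0002745", "Oral leukoplakia", "HP:0001574",
    # growth
    "HP:0001510", "Growth delay", character(),
    "HP:0004322", "Short stature", "HP:0001510",
    "HP:0001511", "Intrauterine growth retardation", "HP:0001510",
    # eye / ear
    "HP:0000478", "Abnormality of the eye", character(),
    "HP:0000568", "Microphthalmia", "HP:0000478",
    "HP:0000598", "Abnormality of the ear", character(),
    # cardiac / pulmonary / hepatic / pancreatic
    "HP:0001627", "Abnormal heart morphology", character(),
    "HP:0002088", "Abnormal lung morphology", character(),
    "HP:0002206", "Pulmonary fibrosis", "HP:0002088",
    "HP:0001392", "Abnormality of the liver", character(),
    "HP:0002240", "Hepatomegaly", "HP:0001392",
    "HP:0001732", "Abnormality of the pancreas", character(),
    "HP:0001738", "Exocrine pancreatic insufficiency", "HP:0001732",
    # gastrointestinal
    "HP:0011024", "Abnormality of the gastrointestinal tract", character(),
    "HP:0002024", "Malabsorption", "HP:0011024",
    "HP:0002023", "Anal atresia", "HP:0011024",
    "HP:0002575", "Tracheoesophageal fistula", "HP:0011024",
    # genitourinary
    "HP:0000119", "Abnormality of the genitourinary system", character(),
    "HP:0000077", "Abnormality of the kidney", "HP:0000119",
    "HP:0000787", "Nephrolithiasis", "HP:0000077",
    # skeletal incl. radial ray
    "HP:0000924", "Abnormality of the skeletal system", character(),
    "HP:0000925", "Abnormality of the vertebral column", "HP:0000924",
    "HP:0005871", "Metaphyseal chondrodysplasia", "HP:0000924",
    "HP:0045027", "Abnormality of the thoracic cavity", "HP:0000924",
    "HP:0002817", "Abnormality of the upper limb", "HP:0000924",
    "HP:0410049", "Abnormality of the radial ray", "HP:0002817",
    "HP:0003974", "Absent radius", "HP:0410049",
    "HP:0002984", "Hypoplasia of the radius", "HP:0410049",
    "HP:0009777", "Absent thumb", "HP:0410049",
    "HP:0009778", "Short thumb", "HP:0410049",
    # hematologic
    "HP:0001871", "Abnormality of blood and blood-forming tissues", character(),
    "HP:0001876", "Pancytopenia", "HP:0001871",
    "HP:0001873", "Thrombocytopenia", "HP:0001871",
    "HP:0001875", "Neutropenia", "HP:0001871",
    "HP:0040289", "Cyclic neutropenia", "HP:0001875",
    "HP:0001882", "Leukopenia", "HP:0001871",
    "HP:0001972", "Macrocytic anemia", "HP:0001871",
    "HP:0001896", "Reticulocytopenia", "HP:0001871",
    "HP:0002863", "Myelodysplasia", "HP:0001871",
    "HP:0004808", "Acute myeloid leukemia", "HP:0001871",
    "HP:0001915", "Aplastic anemia", "HP:0001871"
  )
}

default_groups <- function() {
  list(
    # mucocutaneous triad of dyskeratosis congenita
    dc_triad = c("HP:0002745", "HP:0002164", "HP:0007427"),
    dc_supportive = c("HP:0002216", "HP:0004322", "HP:0000478", "HP:0002206"),
    # 8 associated features raising Shwachman-Diamond suspicion
    sds_associated = c(
      "HP:0001738", "HP:0002024", "HP:0004322", "HP:0005871",
      "HP:0045027", "HP:0001627", "HP:0000598", "HP:0002240"
    ),
    dba_minor = c(
      "HP:0004322", "HP:0000252", "HP:0001999", "HP:0000464",
      "HP:0002817", "HP:0001627", "HP:0000119"
    ),
    scn_associated = c("HP:0004322", "HP:0001627", "HP:0000119"),
    tar_supportive = c("HP:0001627", "HP:0000077"),
    radial_ray = "HP:0410049",
    thumb_absence = "HP:0009777",
    vacterl_h = c(
      "HP:0000925", "HP:0002023", "HP:0001627", "HP:0002575",
      "HP:0000077", "HP:0410049", "HP:0000238"
    ),
    phenos = c(
      "HP:0007441", "HP:0000957", "HP:0000252", "HP:0000478",
      "HP:0000707", "HP:0000598", "HP:0004322"
    ),
    craniofacial = "HP:0001999",
    neurological = "HP:0000707",
    integument = "HP:0001574",
    growth = "HP:0001510",
    hematologic = "HP:0001871"
  )
}

# dba_minor references neck abnormality which needs a term
default_extra_terms <- function() {
  tribble(
    ~term_id, ~label, ~parents,
    "HP:0000464", "Abnormality of the neck", character()
  )
}

# groups whose membership the rules depend on; user config may extend the
# catalog but never remove these members
rule_required_groups <- function() {
  c(
    "dc_triad", "dc_supportive", "sds_associated", "dba_minor",
    "scn_associated", "tar_supportive", "radial_ray", "thumb_absence",
    "vacterl_h", "phenos", "craniofacial", "neurological", "integument",
    "growth", "hematologic"
  )
}

# organ-system roots used to count distinct non-hematological manifestations
organ_systems <- function() {
  c(
    craniofacial = "HP:0001999", neurological = "HP:0000707",
    integument = "HP:0001574", growth = "HP:0001510",
    eye = "HP:0000478", ear = "HP:0000598",
    cardiac = "HP:0001627", pulmonary = "HP:0002088",
    hepatic = "HP:0001392", pancreatic = "HP:0001732",
    gastrointestinal = "HP:0011024", genitourinary = "HP:0000119",
    skeletal = "HP:0000924", hematologic = "HP:0001871"
  )
}

#' Load the feature catalog
#'
#' Builds the embedded catalog of HPO terms and rule groups, optionally
#' extended by the `catalog` block of a YAML config (see [load_config()]).
#' User configuration may add terms and add members to groups, but removing a
#' rule-required term from a rule group is an error: the triage rules are
#' defined over those sets.
#'
#' @param config Either `NULL`, a config list from [load_config()], or a path
#'   to a YAML config file.
#' @return An object of class `ibmfs_catalog`: a list with `terms` (tibble of
#'   `term_id`, `label`, `parents`), `groups` (named list of character
#'   vectors), `organ_systems` (named vector of system roots) and a
#'   precomputed `ancestors` map used for descendant matching.
#' @export
#' @examples
#' cat <- load_catalog()
#' cat$terms[cat$terms$term_id == "HP:0002745", "label"]
#' length(cat$groups$dc_triad)
load_catalog <- function(config = NULL) {
  if (is.character(config)) {
    config <- load_config(config)
  }
  terms <- bind_rows(default_term_table(), default_extra_terms())
  groups <- default_groups()
  ext <- config$catalog
  if (!is.null(ext)) {
    if (!is.null(ext$terms)) {
      add <- purrr::map_dfr(ext$terms, function(t) {
        tibble(
          term_id = normalize_hpo_id(t$term_id),
          label = t$label %||% t$term_id,
          parents = list(vapply(as.list(t$parent_ids %||% character()),
            normalize_hpo_id, character(1)
          ))
        )
      })
      terms <- bind_rows(terms, add)
    }
    if (!is.null(ext$groups)) {
      for (g in names(ext$groups)) {
        members <- vapply(as.list(ext$groups[[g]]), normalize_hpo_id, character(1))
        if (g %in% rule_required_groups()) {
          missing <- setdiff(groups[[g]], members)
          if (length(missing) > 0) {
            abort(paste0(
              "config may not remove rule-required terms from group '", g,
              "': ", paste(missing, collapse = ", ")
            ))
          }
        }
        groups[[g]] <- union(groups[[g]] %||% character(), members)
      }
    }
  }
  build_catalog(terms, groups)
}

build_catalog <- function(terms, groups) {
  if (anyDuplicated(terms$term_id)) {
    abort("duplicate term_id in catalog")
  }
  bad <- terms$term_id[!grepl("^HP:[0-9]{7}$", terms$term_id)]
  if (length(bad) > 0) {
    abort(paste0("malformed term ids: ", paste(bad, collapse = ", ")))
  }
  if (!is.list(terms$parents)) terms$parents <- as.list(terms$parents)
  parent_map <- setNames(terms$parents, terms$term_id)
  unknown_parents <- setdiff(unlist(parent_map), terms$term_id)
  if (length(unknown_parents) > 0) {
    abort(paste0("parent ids absent from catalog: ", paste(unknown_parents, collapse = ", ")))
  }
  ancestors <- compute_ancestors(parent_map)
  for (g in names(groups)) {
    missing <- setdiff(groups[[g]], terms$term_id)
    if (length(missing) > 0) {
      abort(paste0("group '", g, "' references unknown terms: ", paste(missing, collapse = ", ")))
    }
  }
  structure(
    list(
      terms = terms, groups = groups,
      organ_systems = organ_systems(), ancestors = ancestors
    ),
    class = "ibmfs_catalog"
  )
}

# ancestor closure (including self); errors on cycles
compute_ancestors <- function(parent_map) {
  ids <- names(parent_map)
  anc <- vector("list", length(ids))
  names(anc) <- ids
  visit <- function(id, seen) {
    if (id %in% seen) {
      abort(paste0("cycle in catalog parent links at ", id))
    }
    if (!is.null(anc[[id]])) {
      return(anc[[id]])
    }
    out <- id
    for (p in parent_map[[id]]) {
      out <- union(out, visit(p, c(seen, id)))
    }
    anc[[id]] <<- out
    out
  }
  for (id in ids) visit(id, character())
  anc
}

#' @export
print.ibmfs_catalog <- function(x, ...) {
  cat(
    "<ibmfs_catalog> ", nrow(x$terms), " terms, ",
    length(x$groups), " groups\n",
    sep = ""
  )
  invisible(x)
}

#' Normalize an HPO identifier
#'
#' Canonicalizes an HPO-style identifier to the zero-padded 7-digit form
#' `HP:NNNNNNN`. Truncated codes as sometimes printed in clinical text
#' (`HP:001972`, `HP:001,972`) are repaired with a warning; anything that is
#' not an `HP:` prefix followed by 1--7 digits is an error.
#'
#' @param id Character identifier.
#' @return The canonical identifier string.
#' @export
#' @examples
#' suppressWarnings(normalize_hpo_id("HP:001972"))
normalize_hpo_id <- function(id) {
  if (!is.character(id) || length(id) != 1 || is.na(id)) {
    abort("HPO id must be a single string")
  }
  clean <- gsub(",", "", trimws(id), fixed = TRUE)
  if (!grepl("^HP:[0-9]{1,7}$", clean)) {
    abort(paste0("malformed HPO id: '", id, "'"))
  }
  digits <- sub("^HP:", "", clean)
  padded <- sprintf("HP:%07d", as.integer(digits))
  if (!identical(padded, id)) {
    warn(paste0("normalized HPO id '", id, "' to '", padded, "'"))
  }
  padded
}

#' Does a record assert a feature (or a catalog descendant of it)?
#'
#' Matching is by exact term or by descendant within the embedded catalog
#' graph: a record asserting neurodevelopmental delay (HP:0012758) matches a
#' query for nervous-system abnormality (HP:0000707). Terms outside the
#' catalog never match.
#'
#' @param record An `ibmfs_patient` record.
#' @param term_id Catalog term to query (group root or leaf).
#' @param catalog An `ibmfs_catalog`.
#' @return Logical scalar.
#' @export
has_feature <- function(record, term_id, catalog) {
  feats <- record$features$term_id
  any(vapply(
    feats,
    function(f) term_id %in% (catalog$ancestors[[f]] %||% character()),
    logical(1)
  ))
}

# all asserted feature ids matching any of the given roots (by descent)
match_features <- function(record, roots, catalog) {
  feats <- record$features$term_id
  feats[vapply(
    feats,
    function(f) any(roots %in% (catalog$ancestors[[f]] %||% character())),
    logical(1)
  )]
}

# which of the given roots are matched by at least one asserted feature
matched_roots <- function(record, roots, catalog) {
  roots[vapply(
    roots,
    function(r) has_feature(record, r, catalog),
    logical(1)
  )]
}

catalog_label <- function(catalog, term_id) {
  i <- match(term_id, catalog$terms$term_id)
  ifelse(is.na(i), term_id, catalog$terms$label[i])
}
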