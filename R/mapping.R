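# Capability -> service-need mapping matrices.
#
# A mapping matrix is a *total* rule table: for a bound registry it holds
# exactly one rule per (indicator, score level 0..4) pair, each rule carrying
# one or more service items. Totality is what makes stage-1 need
# identification deterministic and exhaustive: every indicator of every
# portrait triggers exactly one rule.
#
# Intensity grades run 1 (lightest, preventive) to 5 (heaviest, full care)
# and in the shipped fixtures equal 5 - score_level: full capability (score
# 4) maps to preventive items, complete loss (score 0) to the heaviest care.

#' Controlled service category vocabulary
#'
#' The ten service categories used to tag items in the shipped mapping
#' fixtures, ordered from daily-living support to monitoring. The order is
#' also the deterministic tie-break order used in ranking.
#'
#' @return Character vector of category tokens.
#' @export
service_categories <- function() {
  c("daily_living_assistance", "nursing", "rehabilitation",
    "safety_home_modification", "nutrition", "psychological_support",
    "social_participation", "financial_welfare_linkage",
    "caregiver_training", "monitoring")
}

# Normalized service identity: casefolded, whitespace-collapsed label plus
# category. The dedup key across the two portrait kinds.
service_key <- function(label, category) {
  lab <- gsub("\\s+", " ", trimws(tolower(label)))
  paste0(lab, "||", category)
}

#' Load a capability-service need mapping matrix
#'
#' Reads a rule table from CSV (columns `portrait_kind`, `indicator_id`,
#' `score_level`, `item_label`, `category`, `intensity_grade`, optional
#' `provenance`) or from an equivalent JSON array, validates it against a
#' registry, and enforces totality: every (indicator, level) pair of the
#' registry must carry at least one item and no pair may be defined twice
#' across files. Two fixtures ship with the package:
#'
#' * `"family_v1"` — the full 8-indicator x 5-level family caregiving matrix
#'   (40 rules), every item transcribed.
#' * `"individual_demo"` — a total 28 x 5 individual matrix in which the
#'   eating, personal grooming and bathing rows are transcribed and the
#'   remaining 25 indicators carry clearly marked synthetic placeholder items
#'   (`provenance = "synthetic"`) so the full engine is exercisable.
#'
#' @param source fixture name (`"family_v1"`, `"individual_demo"`) or a file
#'   path ending in `.csv` or `.json`.
#' @param registry the `care_registry` the matrix binds to.
#' @return A `mapping_matrix`: list with `kind`, `rules` (data frame of item
#'   rows), and the binding registry.
#' @examples
#' fam <- load_mapping_matrix("family_v1", load_registry("family_v1"))
#' lookup(fam, "daily_caregiving_time", 0)$item_label
#' @export
load_mapping_matrix <- function(source, registry) {
  stopifnot(is.character(source), length(source) == 1L,
            inherits(registry, "care_registry"))
  path <- source
  if (source %in% c("family_v1", "individual_demo")) {
    path <- system.file("extdata", paste0("mapping_", source, ".csv"),
                        package = "caremap", mustWork = TRUE)
  } else if (!file.exists(source)) {
    stop("unknown mapping fixture or missing file: ", source, call. = FALSE)
  }
  rules <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path), stringsAsFactors = FALSE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  }
  new_mapping_matrix(rules, registry)
}

#' Construct and validate a mapping matrix from a rule data frame
#'
#' @param rules data frame with one row per service item; required columns
#'   `portrait_kind`, `indicator_id`, `score_level`, `item_label`,
#'   `category`, `intensity_grade`.
#' @param registry the binding `care_registry`.
#' @return A validated `mapping_matrix`.
#' @export
new_mapping_matrix <- function(rules, registry) {
  req <- c("portrait_kind", "indicator_id", "score_level", "item_label",
           "category", "intensity_grade")
  missing_cols <- setdiff(req, names(rules))
  if (length(missing_cols)) {
    stop("mapping rules missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!all(rules$portrait_kind == registry$kind)) {
    stop("rule portrait_kind does not match registry kind '",
         registry$kind, "'", call. = FALSE)
  }
  unknown <- setdiff(rules$indicator_id, registry$indicators$id)
  if (length(unknown)) {
    stop("unknown indicator_id: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(!rules$score_level %in% 0:4)) {
    stop("score_level must lie in 0..4", call. = FALSE)
  }
  if (any(!rules$intensity_grade %in% 1:5)) {
    stop("intensity_grade must lie in 1..5", call. = FALSE)
  }
  if (any(!nzchar(trimws(rules$item_label)))) {
    stop("empty item_label", call. = FALSE)
  }
  # totality: every (indicator, level) cell of the registry, exactly once
  have <- unique(paste(rules$indicator_id, rules$score_level, sep = "@"))
  want <- as.vector(outer(registry$indicators$id, 0:4, paste, sep = "@"))
  absent <- setdiff(want, have)
  if (length(absent)) {
    stop("mapping matrix not total; missing rule(s) for: ",
         paste(utils::head(absent, 5L), collapse = ", "),
         if (length(absent) > 5L) sprintf(" (and %d more)",
                                          length(absent) - 5L),
         call. = FALSE)
  }
  rules$score_level <- as.integer(rules$score_level)
  rules$intensity_grade <- as.integer(rules$intensity_grade)
  # fix row order: registry indicator order, then level, then file order
  ord <- order(match(rules$indicator_id, registry$indicators$id),
               rules$score_level)
  rules <- rules[ord, , drop = FALSE]
  rownames(rules) <- NULL
  structure(
    list(kind = registry$kind, rules = rules, registry = registry),
    class = "mapping_matrix"
  )
}

#' Number of distinct (indicator, level) rules in a matrix
#' @param matrix a `mapping_matrix`.
#' @return Integer rule count (items within a cell count once).
#' @export
n_rules <- function(matrix) {
  stopifnot(inherits(matrix, "mapping_matrix"))
  nrow(unique(matrix$rules[, c("indicator_id", "score_level")]))
}

#' @export
print.mapping_matrix <- function(x, ...) {
  cat(sprintf("<mapping_matrix: %s, %d rules (%d item rows)>\n",
              x$kind, n_rules(x), nrow(x$rules)))
  invisible(x)
}

#' Look up the service items for one capability state
#'
#' Pure function: returns the rule's items for an (indicator, score) pair,
#' unmodified and in fixture order.
#'
#' @param matrix a `mapping_matrix`.
#' @param indicator_id registry indicator token.
#' @param score score level 0..4.
#' @return Data frame with columns `item_label`, `category`,
#'   `intensity_grade`.
#' @export
lookup <- function(matrix, indicator_id, score) {
  stopifnot(inherits(matrix, "mapping_matrix"))
  hit <- matrix$rules$indicator_id == indicator_id &
    matrix$rules$score_level == score
  if (!any(hit)) {
    stop(sprintf("no rule for (%s, %s): matrix not total or bad key",
                 indicator_id, score), call. = FALSE)
  }
  out <- matrix$rules[hit, c("item_label", "category", "intensity_grade")]
  rownames(out) <- NULL
  out
}

#' Stage 1: map a portrait to its rule-triggered candidate needs
#'
#' Applies exactly one lookup per registry indicator and flattens the results
#' into candidate needs, preserving registry indicator order and item order
#' within each rule. Deterministic: identical inputs give identical output.
#'
#' @param portrait a `care_portrait` whose kind matches the matrix.
#' @param matrix a total `mapping_matrix`.
#' @return A `candidate_needs` data frame with columns `item_label`,
#'   `category`, `intensity_grade`, `source_kind`, `trigger_indicator`,
#'   `trigger_score`.
#' @export
map_portrait <- function(portrait, matrix) {
  stopifnot(inherits(portrait, "care_portrait"),
            inherits(matrix, "mapping_matrix"))
  if (portrait$kind != matrix$kind) {
    stop("portrait kind '", portrait$kind, "' does not match matrix kind '",
         matrix$kind, "'", call. = FALSE)
  }
  ids <- matrix$registry$indicators$id
  parts <- lapply(seq_along(ids), function(j) {
    items <- lookup(matrix, ids[j], portrait$scores[[j]])
    items$source_kind <- portrait$kind
    items$trigger_indicator <- ids[j]
    items$trigger_score <- portrait$scores[[j]]
    items
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "subject_id") <- portrait$subject_id
  class(out) <- c("candidate_needs", "data.frame")
  out
}

#' Merge individual and family candidate needs for one subject
#'
#' Takes the union of the two stage-1 candidate lists. Items with the same
#' normalized (label, category) identity are deduplicated keeping the higher
#' intensity grade, and every surviving candidate records all of its
#' triggers. The merge is commutative and idempotent.
#'
#' @param individual_needs,family_needs `candidate_needs` from the same
#'   subject (either may be NULL).
#' @return A `candidate_needs` data frame with an added list-column
#'   `triggers`, each entry a data frame of (source_kind, indicator, score)
#'   triggers, and a `key` column holding the dedup identity.
#' @export
merge_candidates <- function(individual_needs, family_needs) {
  both <- rbind(individual_needs, family_needs)
  if (is.null(both) || nrow(both) == 0L) {
    stop("nothing to merge", call. = FALSE)
  }
  sid_i <- attr(individual_needs, "subject_id")
  sid_f <- attr(family_needs, "subject_id")
  if (!is.null(sid_i) && !is.null(sid_f) && !identical(sid_i, sid_f)) {
    stop("candidate lists come from different subjects: ",
         sid_i, " vs ", sid_f, call. = FALSE)
  }
  both$key <- service_key(both$item_label, both$category)
  # canonical order of merged list: by key (locale-independent), so the
  # merge is order-insensitive in its arguments
  keys <- sort(unique(both$key), method = "radix")
  merged <- lapply(keys, function(k) {
    rows <- both[both$key == k, , drop = FALSE]
    best <- rows[which.max(rows$intensity_grade), , drop = FALSE]
    trig <- unique(rows[, c("source_kind", "trigger_indicator",
                            "trigger_score")])
    trig <- trig[order(trig$source_kind, trig$trigger_indicator,
                       method = "radix"), , drop = FALSE]
    rownames(trig) <- NULL
    best$triggers <- I(list(trig))
    best
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  attr(out, "subject_id") <- if (!is.null(sid_i)) sid_i else sid_f
  class(out) <- c("candidate_needs", "data.frame")
  out
}
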