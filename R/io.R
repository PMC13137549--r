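# Readers and writers for the package's plain-text interchange formats.
#
# Assessment CSV: header `subject_id, <28 individual ids>, <8 family ids>`
# plus optional demographic columns (age, gender, living_arrangement,
# health_status); one row per subject; UTF-8.

.DEMOGRAPHIC_COLS <- c("age", "gender", "living_arrangement", "health_status")

#' Read dual portraits from an assessment CSV
#'
#' Validates every row against the registries; failures are reported with
#' their row number. Column order for the score block must follow registry
#' order (the header is checked).
#'
#' @param path CSV file path.
#' @param individual_registry,family_registry registries the columns are
#'   aligned to (defaults: the built-in v1 registries).
#' @return List of `dual_portrait` objects in file order (empty for a
#'   header-only file).
#' @export
read_assessments <- function(path,
                             individual_registry = load_registry("individual_v1"),
                             family_registry = load_registry("family_v1")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        check.names = FALSE)
  ind_ids <- individual_registry$indicators$id
  fam_ids <- family_registry$indicators$id
  expected <- c("subject_id", ind_ids, fam_ids)
  missing_cols <- setdiff(expected, names(df))
  if (length(missing_cols)) {
    stop("assessment file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(list())
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    demo <- NULL
    have_demo <- intersect(.DEMOGRAPHIC_COLS, names(df))
    if (length(have_demo)) {
      demo <- as.list(row[have_demo])
      demo <- demo[!vapply(demo, function(v) is.na(v) || identical(v, ""),
                           logical(1))]
      if (!length(demo)) demo <- NULL
    }
    tryCatch(
      dual_portrait(
        validate_portrait(individual_registry, row$subject_id,
                          as.numeric(row[ind_ids])),
        validate_portrait(family_registry, row$subject_id,
                          as.numeric(row[fam_ids])),
        demographics = demo
      ),
      error = function(e) {
        stop(sprintf("row %d (subject %s): %s", i,
                     as.character(row$subject_id), conditionMessage(e)),
             call. = FALSE)
      }
    )
  })
}

#' Write dual portraits to an assessment CSV
#'
#' Inverse of [read_assessments()]: round-trips losslessly.
#'
#' @param duals list of `dual_portrait` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_assessments <- function(duals, path) {
  stopifnot(all(vapply(duals, inherits, logical(1), "dual_portrait")))
  rows <- lapply(duals, function(d) {
    base <- c(list(subject_id = d$subject_id),
              as.list(d$individual$scores), as.list(d$family$scores))
    demo <- d$demographics[intersect(.DEMOGRAPHIC_COLS,
                                     names(d$demographics))]
    as.data.frame(c(base, demo), stringsAsFactors = FALSE,
                  check.names = FALSE)
  })
  if (length(rows) == 0L) {
    reg_i <- load_registry("individual_v1")
    reg_f <- load_registry("family_v1")
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)),
          1 + nrow(reg_i$indicators) + nrow(reg_f$indicators)),
      c("subject_id", reg_i$indicators$id, reg_f$indicators$id)),
      check.names = FALSE)
  } else {
    all_cols <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
      r[setdiff(all_cols, names(r))] <- NA
      r[all_cols]
    })
    df <- do.call(rbind, rows)
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8",
                   quote = TRUE)
  invisible(path)
}

#' Write a recommendation list to JSON or CSV
#'
#' JSON is the canonical output: subject id, config snapshot, and ordered
#' records with label, category, intensity grade, priority level, the score
#' decomposition and the triggering (kind, indicator, score) tuples. The CSV
#' export flattens triggers into a `;`-separated string for spreadsheet use.
#'
#' @param rec a `recommendation_list`.
#' @param path output path.
#' @param format `"json"` (default) or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_recommendations <- function(rec, path, format = c("json", "csv")) {
  stopifnot(inherits(rec, "recommendation_list"))
  format <- match.arg(format)
  trig_str <- vapply(rec$triggers, function(t) {
    paste(sprintf("%s:%s:%d", t$source_kind, t$trigger_indicator,
                  t$trigger_score), collapse = ";")
  }, character(1))
  if (format == "csv") {
    df <- summary(rec)
    df$triggers <- trig_str
    df <- cbind(subject_id = attr(rec, "subject_id"), df)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(path))
  }
  cfg <- attr(rec, "config")
  records <- lapply(seq_len(nrow(rec)), function(i) {
    list(
      item_label = rec$item_label[i],
      category = rec$category[i],
      intensity_grade = rec$intensity_grade[i],
      priority_level = as.character(rec$priority_level[i]),
      score = list(
        severity = rec$severity_component[i],
        family_deficit = rec$family_deficit_component[i],
        support = rec$support_component[i],
        total = rec$total[i]
      ),
      triggers = rec$triggers[[i]]
    )
  })
  jsonlite::write_json(
    list(subject_id = attr(rec, "subject_id"),
         n_population = attr(rec, "n_population"),
         config = list(metric = cfg$metric,
                       k_neighbors = cfg$k_neighbors,
                       min_similarity = cfg$min_similarity,
                       weights = as.list(cfg$weights),
                       thresholds = as.list(cfg$thresholds)),
         recommendations = records),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
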