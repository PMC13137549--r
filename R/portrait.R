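# Portrait construction and validation.
#
# A portrait is a subject's capability state as an ordered integer vector
# aligned to a registry: length 28 (individual) or 8 (family), each entry in
# 0..4. Out-of-range, non-integer or missing values are rejected outright --
# there is no imputation.

#' Validate raw assessment scores into a typed portrait
#'
#' Checks a raw score vector against a registry and returns a typed portrait.
#' Validation is strict: the vector must have exactly one score per registry
#' indicator, every score must be a whole number in \[0, 4\], and missing
#' values are an error (scores are never imputed or coerced).
#'
#' @param registry a `care_registry` (see [load_registry()]).
#' @param subject_id opaque subject identifier (length-1 character or
#'   coercible).
#' @param raw_scores numeric vector aligned to `registry$indicators` order.
#' @return A `care_portrait`: list with `subject_id`, integer `scores` (named
#'   by indicator id), and `kind`.
#' @examples
#' reg <- load_registry("family_v1")
#' validate_portrait(reg, "S0001", c(0, 2, 1, 1, 1, 1, 1, 2))
#' @export
validate_portrait <- function(registry, subject_id, raw_scores) {
  stopifnot(inherits(registry, "care_registry"))
  subject_id <- as.character(subject_id)
  if (length(subject_id) != 1L || is.na(subject_id) || !nzchar(subject_id)) {
    stop("subject_id must be a single non-empty string", call. = FALSE)
  }
  n <- nrow(registry$indicators)
  if (length(raw_scores) != n) {
    stop(sprintf("expected %d scores for a %s portrait, got %d",
                 n, registry$kind, length(raw_scores)), call. = FALSE)
  }
  if (!is.numeric(raw_scores)) {
    stop("scores must be numeric", call. = FALSE)
  }
  if (anyNA(raw_scores)) {
    stop("missing score for indicator(s): ",
         paste(registry$indicators$id[is.na(raw_scores)], collapse = ", "),
         call. = FALSE)
  }
  if (any(raw_scores != round(raw_scores))) {
    stop("non-integer score for indicator(s): ",
         paste(registry$indicators$id[raw_scores != round(raw_scores)],
               collapse = ", "),
         call. = FALSE)
  }
  bad <- raw_scores < registry$scale_min | raw_scores > registry$scale_max
  if (any(bad)) {
    stop("score outside [0,4] for indicator(s): ",
         paste(registry$indicators$id[bad], collapse = ", "), call. = FALSE)
  }
  scores <- as.integer(raw_scores)
  names(scores) <- registry$indicators$id
  structure(
    list(subject_id = subject_id, scores = scores, kind = registry$kind),
    class = "care_portrait"
  )
}

#' @export
print.care_portrait <- function(x, ...) {
  cat(sprintf("<care_portrait %s [%s]> %s\n", x$subject_id, x$kind,
              paste(x$scores, collapse = " ")))
  invisible(x)
}

#' Pair an individual and a family portrait for one subject
#'
#' The dual portrait is the unit of analysis: the individual vector is the
#' source of potential service needs, the family vector the household's
#' capacity to meet them. Demographics are contextual only and never enter
#' validation, mapping or similarity.
#'
#' @param individual a `care_portrait` of kind `"individual"`.
#' @param family a `care_portrait` of kind `"family"` with the same
#'   `subject_id`.
#' @param demographics optional named list (e.g. age, gender,
#'   living_arrangement, health_status).
#' @return A `dual_portrait` object.
#' @export
dual_portrait <- function(individual, family, demographics = NULL) {
  stopifnot(inherits(individual, "care_portrait"),
            inherits(family, "care_portrait"))
  if (individual$kind != "individual" || family$kind != "family") {
    stop("dual_portrait() needs one individual and one family portrait",
         call. = FALSE)
  }
  if (individual$subject_id != family$subject_id) {
    stop("subject_id mismatch: ", individual$subject_id, " vs ",
         family$subject_id, call. = FALSE)
  }
  structure(
    list(subject_id = individual$subject_id,
         individual = individual,
         family = family,
         demographics = demographics),
    class = "dual_portrait"
  )
}

#' @export
print.dual_portrait <- function(x, ...) {
  cat(sprintf("<dual_portrait %s>\n", x$subject_id))
  cat("  individual:", paste(x$individual$scores, collapse = " "), "\n")
  cat("  family:    ", paste(x$family$scores, collapse = " "), "\n")
  invisible(x)
}

#' Stack same-kind portraits into a community capability matrix
#'
#' Aggregates the portraits of all subjects in a community into an N x p
#' score matrix (p = 28 for individual, 8 for family), one row per subject in
#' input order. Row i reproduces subject i's portrait exactly, so the
#' aggregation is lossless.
#'
#' @param portraits list of `care_portrait` objects, all of the same kind,
#'   with unique subject ids.
#' @return A `community_matrix`: list with `kind`, `subject_ids`, and the
#'   integer `scores` matrix (rownames = subject ids, colnames = indicator
#'   ids).
#' @export
assemble_community_matrix <- function(portraits) {
  if (length(portraits) == 0L) {
    stop("cannot assemble an empty community matrix", call. = FALSE)
  }
  stopifnot(all(vapply(portraits, inherits, logical(1), "care_portrait")))
  kinds <- vapply(portraits, `[[`, character(1), "kind")
  if (length(unique(kinds)) != 1L) {
    stop("all portraits must have the same kind; got: ",
         paste(unique(kinds), collapse = ", "), call. = FALSE)
  }
  ids <- vapply(portraits, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) {
    stop("duplicate subject_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  scores <- do.call(rbind, lapply(portraits, `[[`, "scores"))
  rownames(scores) <- ids
  structure(
    list(kind = kinds[1L], subject_ids = ids, scores = scores),
    class = "community_matrix"
  )
}

#' Extract one subject's portrait back out of a community matrix
#'
#' @param matrix a `community_matrix`.
#' @param i row index or subject id.
#' @param registry the registry the matrix is aligned to.
#' @return The `care_portrait` for that row.
#' @export
community_row <- function(matrix, i, registry) {
  stopifnot(inherits(matrix, "community_matrix"))
  if (is.character(i)) i <- match(i, matrix$subject_ids)
  validate_portrait(registry, matrix$subject_ids[i], matrix$scores[i, ])
}

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("<community_matrix: %d subjects x %d %s indicators>\n",
              nrow(x$scores), ncol(x$scores), x$kind))
  invisible(x)
}

#' Per-indicator capability distribution of a community
#'
#' Summarizes the distribution and heterogeneity of capability across the
#' community: for each indicator, the frequency of each score level 0..4
#' (summing to N), the mean score, and the share of subjects at score <= 1
#' (severe impairment band).
#'
#' @param matrix a `community_matrix`.
#' @return A `community_profile` data frame with columns `indicator`,
#'   `n0`..`n4`, `mean`, `low_share`.
#' @export
community_profile <- function(matrix) {
  stopifnot(inherits(matrix, "community_matrix"))
  counts <- t(apply(matrix$scores, 2,
                    function(col) tabulate(col + 1L, nbins = 5L)))
  colnames(counts) <- paste0("n", 0:4)
  out <- data.frame(
    indicator = colnames(matrix$scores),
    counts,
    mean = colMeans(matrix$scores),
    low_share = colMeans(matrix$scores <= 1L),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(out) <- c("community_profile", "data.frame")
  attr(out, "n_subjects") <- nrow(matrix$scores)
  attr(out, "kind") <- matrix$kind
  out
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("Community capability profile (%s, N = %d)\n",
              attr(x, "kind"), attr(x, "n_subjects")))
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Flag subjects at high risk from a community matrix
#'
#' Screens for potentially high-risk subjects using a simple threshold
#' policy: a subject is flagged when at least `m` of their indicators score
#' at or below `s`. The default (`m = 3`, `s = 1`) flags anyone with three or
#' more severely impaired capabilities. Relaxing the policy (smaller `m` or
#' larger `s`) can only grow the flagged set.
#'
#' @param matrix a `community_matrix`.
#' @param m minimum number of low-scoring indicators (>= 1).
#' @param s score threshold, in 0..4.
#' @return Character vector of flagged subject ids, in matrix row order.
#' @export
flag_high_risk <- function(matrix, m = 3L, s = 1L) {
  stopifnot(inherits(matrix, "community_matrix"))
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  if (!is.numeric(s) || length(s) != 1L || s < 0 || s > 4) {
    stop("s must lie in 0..4", call. = FALSE)
  }
  low <- rowSums(matrix$scores <= s)
  matrix$subject_ids[low >= m]
}
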