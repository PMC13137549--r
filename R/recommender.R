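# Two-stage need identification.
#
# Stage 1 (mapping.R) deterministically derives candidate services from the
# dual portrait through the total rule matrices. Stage 2 re-prioritizes --
# never adds or removes -- those candidates by fusing three components:
#
#   severity        how impaired the triggering capability is
#   family_deficit  how weak the household's caregiving capacity is
#   support         how prevalent the candidate is among the k most similar
#                   subjects (user-based collaborative filtering)
#
# total = w_severity * severity + w_family * family_deficit
#       + w_support * support,   all components and weights in [0, 1].

#' Configuration for similarity, score fusion and stratification
#'
#' @param metric similarity metric over normalized dual vectors: `"cosine"`
#'   (default; zero-vector similarity defined as 0) or
#'   `"inverse_euclidean"` (1 / (1 + distance)).
#' @param k_neighbors neighborhood size for collaborative filtering
#'   (default 5).
#' @param min_similarity neighbors below this similarity are dropped
#'   (default 0).
#' @param weights nonnegative fusion weights `c(severity, family, support)`
#'   summing to 1; default `c(0.5, 0.3, 0.2)`.
#' @param thresholds priority stratification cut points on the total score:
#'   `high` and `medium` lower bounds (closed), default 2/3 and 1/3.
#' @return A `similarity_config` list.
#' @export
similarity_config <- function(metric = c("cosine", "inverse_euclidean"),
                              k_neighbors = 5L,
                              min_similarity = 0,
                              weights = c(severity = 0.5, family = 0.3,
                                          support = 0.2),
                              thresholds = c(high = 2 / 3, medium = 1 / 3)) {
  metric <- match.arg(metric)
  if (!is.numeric(k_neighbors) || k_neighbors < 1 ||
      k_neighbors != round(k_neighbors)) {
    stop("k_neighbors must be a positive integer", call. = FALSE)
  }
  if (min_similarity < 0 || min_similarity > 1) {
    stop("min_similarity must lie in [0,1]", call. = FALSE)
  }
  weights <- unname(weights)
  if (length(weights) != 3L || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-9) {
    stop("weights must be 3 nonnegative values summing to 1", call. = FALSE)
  }
  thresholds <- unname(thresholds)
  if (length(thresholds) != 2L ||
      !(0 < thresholds[2L] && thresholds[2L] < thresholds[1L] &&
        thresholds[1L] < 1)) {
    stop("thresholds must satisfy 0 < medium < high < 1", call. = FALSE)
  }
  structure(
    list(metric = metric,
         k_neighbors = as.integer(k_neighbors),
         min_similarity = min_similarity,
         weights = c(severity = weights[1L], family = weights[2L],
                     support = weights[3L]),
         thresholds = c(high = thresholds[1L], medium = thresholds[2L])),
    class = "similarity_config"
  )
}

#' Flatten a dual portrait to a normalized feature vector
#'
#' Concatenates the 28 individual and 8 family scores and rescales to
#' \[0, 1\] by dividing by the scale maximum 4. This length-36 vector is the
#' feature space for portrait similarity.
#'
#' @param dual a `dual_portrait`.
#' @return Numeric vector of length 36 in \[0, 1\].
#' @export
dual_vector <- function(dual) {
  stopifnot(inherits(dual, "dual_portrait"))
  unname(c(dual$individual$scores, dual$family$scores)) / 4
}

#' Similarity between two dual-portrait vectors
#'
#' Cosine similarity u.v / (|u||v|), with the similarity of a zero vector to
#' anything defined as 0; or inverse Euclidean 1 / (1 + |u - v|). Both are
#' symmetric, bounded in \[0, 1\] for nonnegative vectors, and equal 1 for a
#' nonzero vector with itself.
#'
#' @param u,v equal-length numeric vectors (see [dual_vector()]).
#' @param config a `similarity_config` (only `metric` is used).
#' @return Similarity in \[0, 1\].
#' @export
similarity <- function(u, v, config = similarity_config()) {
  if (length(u) != length(v)) {
    stop("vectors differ in length: ", length(u), " vs ", length(v),
         call. = FALSE)
  }
  if (config$metric == "cosine") {
    nu <- sqrt(sum(u * u))
    nv <- sqrt(sum(v * v))
    if (nu == 0 || nv == 0) return(0)
    min(1, sum(u * v) / (nu * nv))
  } else {
    1 / (1 + sqrt(sum((u - v)^2)))
  }
}

#' Find a subject's nearest neighbors by portrait similarity
#'
#' Ranks the population by similarity to the target's dual vector and keeps
#' the top `k_neighbors` at or above `min_similarity`. Ties in similarity
#' are broken by subject id in lexicographic (C-locale) order, so the result
#' is deterministic. Subjects sharing the target's id are excluded.
#'
#' @param target a `dual_portrait`.
#' @param population list of `dual_portrait` objects.
#' @param config a `similarity_config`.
#' @return Data frame with columns `subject_id` and `similarity`, at most
#'   `k_neighbors` rows, sorted by descending similarity then id. Empty
#'   population gives zero rows.
#' @export
neighbors <- function(target, population, config = similarity_config()) {
  stopifnot(inherits(target, "dual_portrait"))
  population <- Filter(function(p) p$subject_id != target$subject_id,
                       population)
  if (length(population) == 0L) {
    return(data.frame(subject_id = character(0), similarity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  tv <- dual_vector(target)
  sims <- vapply(population, function(p) similarity(tv, dual_vector(p),
                                                    config), numeric(1))
  ids <- vapply(population, `[[`, character(1), "subject_id")
  keep <- sims >= config$min_similarity
  ids <- ids[keep]; sims <- sims[keep]
  ord <- order(-sims, ids, method = "radix")
  take <- utils::head(ord, config$k_neighbors)
  data.frame(subject_id = ids[take], similarity = sims[take],
             stringsAsFactors = FALSE)
}

#' Similarity-weighted neighbor support for a candidate service
#'
#' The collaborative-filtering signal: the fraction of neighbor similarity
#' mass whose stage-1 candidate set contains the candidate's service
#' identity, sum(sim_j * \[key in set_j\]) / sum(sim_j). Returns 0 for an
#' empty neighbor set (or when all retained similarities are 0).
#'
#' @param key candidate service key (see internals of [merge_candidates()]),
#'   or a vector of keys.
#' @param neighbor_set data frame from [neighbors()].
#' @param neighbor_keys named list mapping subject_id to the character
#'   vector of service keys in that neighbor's stage-1 candidate set.
#' @return Numeric support value(s) in \[0, 1\], same length as `key`.
#' @export
neighbor_support <- function(key, neighbor_set, neighbor_keys) {
  if (nrow(neighbor_set) == 0L) return(rep(0, length(key)))
  sims <- neighbor_set$similarity
  denom <- sum(sims)
  if (denom == 0) return(rep(0, length(key)))
  sets <- neighbor_keys[neighbor_set$subject_id]
  vapply(key, function(k) {
    carries <- vapply(sets, function(s) k %in% s, logical(1))
    sum(sims[carries]) / denom
  }, numeric(1), USE.NAMES = FALSE)
}

#' Rule-based priority components for merged candidates
#'
#' Computes, per candidate, the severity component (how far the triggering
#' capability is below full, `(4 - trigger score) / 4`) and the
#' family-deficit component: for individually triggered candidates the mean
#' family impairment `(4 - mean family score) / 4` (a weaker household
#' raises the priority of external services for every individual need); for
#' family-triggered candidates the deficit of the triggering family
#' indicator itself. Candidates carrying both kinds of trigger take the
#' larger value of each component.
#'
#' @param candidates merged `candidate_needs` (with `triggers` list-column)
#'   or a plain stage-1 `candidate_needs` data frame.
#' @param dual the subject's `dual_portrait`.
#' @return `candidates` with numeric columns `severity_component` and
#'   `family_deficit_component` appended.
#' @export
base_priority <- function(candidates, dual) {
  stopifnot(inherits(dual, "dual_portrait"))
  fam_deficit_mean <- (4 - mean(dual$family$scores)) / 4
  if (is.null(candidates$triggers)) {
    candidates$triggers <- lapply(seq_len(nrow(candidates)), function(i) {
      data.frame(source_kind = candidates$source_kind[i],
                 trigger_indicator = candidates$trigger_indicator[i],
                 trigger_score = candidates$trigger_score[i],
                 stringsAsFactors = FALSE)
    })
  }
  comp <- vapply(candidates$triggers, function(trig) {
    sev <- max((4 - trig$trigger_score) / 4)
    fam <- max(ifelse(trig$source_kind == "individual",
                      fam_deficit_mean,
                      (4 - trig$trigger_score) / 4))
    c(sev, fam)
  }, numeric(2))
  candidates$severity_component <- comp[1L, ]
  candidates$family_deficit_component <- comp[2L, ]
  candidates
}

#' Stage 2: fuse components and rank candidates
#'
#' Computes each candidate's total priority score as the weighted sum of
#' severity, family-deficit and neighbor-support components and sorts in
#' descending total. Ties are broken deterministically: higher intensity
#' grade first, then category order (position in [service_categories()]),
#' then label lexicographically (C locale). The output is always a
#' permutation of the input candidates.
#'
#' @param candidates output of [base_priority()] with a `support_component`
#'   column (use 0 when no population is available).
#' @param config a `similarity_config` (weights are used).
#' @return A `recommendation_list` data frame sorted by descending `total`.
#' @export
hybrid_rank <- function(candidates, config = similarity_config()) {
  w <- config$weights
  stopifnot(!is.null(candidates$severity_component),
            !is.null(candidates$support_component))
  candidates$total <- w[["severity"]] * candidates$severity_component +
    w[["family"]] * candidates$family_deficit_component +
    w[["support"]] * candidates$support_component
  cat_rank <- match(candidates$category, service_categories())
  cat_rank[is.na(cat_rank)] <- length(service_categories()) + 1L
  ord <- order(-candidates$total, -candidates$intensity_grade, cat_rank,
               candidates$item_label, method = "radix")
  out <- candidates[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("recommendation_list", "data.frame")
  out
}

#' Stratify ranked recommendations into priority levels
#'
#' Assigns `high` / `medium` / `low` from the total score alone, with closed
#' lower bounds: total >= high threshold is high, total >= medium threshold
#' is medium, else low. Monotone by construction.
#'
#' @param ranked a `recommendation_list` from [hybrid_rank()].
#' @param thresholds `c(high, medium)` lower bounds in (0, 1), strictly
#'   ordered; defaults taken from the list's config.
#' @return The list with a `priority_level` factor column added.
#' @export
stratify <- function(ranked, thresholds = NULL) {
  if (is.null(thresholds)) {
    thresholds <- attr(ranked, "config")$thresholds
  }
  if (is.null(thresholds)) thresholds <- c(high = 2 / 3, medium = 1 / 3)
  thresholds <- unname(thresholds)
  if (!(0 < thresholds[2L] && thresholds[2L] < thresholds[1L] &&
        thresholds[1L] < 1)) {
    stop("thresholds must satisfy 0 < medium < high < 1", call. = FALSE)
  }
  lev <- ifelse(ranked$total >= thresholds[1L], "high",
                ifelse(ranked$total >= thresholds[2L], "medium", "low"))
  ranked$priority_level <- factor(lev, levels = c("high", "medium", "low"))
  ranked
}

#' Identify and prioritize service needs for one subject
#'
#' The full two-stage pipeline. Stage 1 maps the individual and family
#' portraits through their total rule matrices and merges the candidates.
#' Stage 2 finds the subject's nearest neighbors in the population, computes
#' each candidate's neighbor support from the neighbors' own stage-1 sets,
#' fuses severity, family deficit and support into a total priority score,
#' ranks, and stratifies. Fully deterministic given inputs and config; with
#' an empty population (or zero support weight) the ranking reduces to the
#' rule-only ordering.
#'
#' @param dual the target subject's `dual_portrait`.
#' @param population list of other subjects' `dual_portrait`s (may be
#'   empty).
#' @param individual_matrix,family_matrix total `mapping_matrix` objects.
#' @param config a `similarity_config`.
#' @return A `recommendation_list`: the merged stage-1 candidates, ranked
#'   and stratified, with score decomposition columns and `triggers`.
#' @examples
#' ind_reg <- load_registry("individual_v1")
#' fam_reg <- load_registry("family_v1")
#' fx <- example_portraits()
#' zhang <- dual_portrait(fx$zhang_individual, fx$zhang_family)
#' rec <- recommend(zhang, list(),
#'                  load_mapping_matrix("individual_demo", ind_reg),
#'                  load_mapping_matrix("family_v1", fam_reg))
#' head(summary(rec))
#' @export
recommend <- function(dual, population, individual_matrix, family_matrix,
                      config = similarity_config()) {
  stopifnot(inherits(dual, "dual_portrait"))
  stage1 <- function(d) {
    merge_candidates(map_portrait(d$individual, individual_matrix),
                     map_portrait(d$family, family_matrix))
  }
  cand <- stage1(dual)
  cand <- base_priority(cand, dual)
  # with zero support weight the CF layer is a no-op: skip it entirely so
  # the output is literally invariant to the population argument
  nbrs <- if (config$weights[["support"]] == 0) {
    data.frame(subject_id = character(0), similarity = numeric(0))
  } else {
    neighbors(dual, population, config)
  }
  if (nrow(nbrs) > 0L) {
    pop_ids <- vapply(population, `[[`, character(1), "subject_id")
    neighbor_keys <- lapply(nbrs$subject_id, function(id) {
      stage1(population[[match(id, pop_ids)]])$key
    })
    names(neighbor_keys) <- nbrs$subject_id
    cand$support_component <- neighbor_support(cand$key, nbrs, neighbor_keys)
  } else {
    cand$support_component <- 0
  }
  out <- stratify(hybrid_rank(cand, config))
  attr(out, "subject_id") <- dual$subject_id
  attr(out, "n_population") <- length(population)
  out
}

#' @export
print.recommendation_list <- function(x, n = 10L, ...) {
  cat(sprintf("Service recommendations for %s (%d candidates, %d neighbors considered)\n",
              attr(x, "subject_id"), nrow(x),
              min(attr(x, "config")$k_neighbors,
                  attr(x, "n_population") %||% 0L)))
  show <- utils::head(summary(x), n)
  print.data.frame(show, digits = 3, row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("... and %d more\n", nrow(x) - n))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Flat summary of a recommendation list
#'
#' @param object a `recommendation_list`.
#' @param ... unused.
#' @return Plain data frame with label, category, intensity grade, priority
#'   level and the score decomposition.
#' @export
summary.recommendation_list <- function(object, ...) {
  data.frame(
    item_label = object$item_label,
    category = object$category,
    intensity_grade = object$intensity_grade,
    priority_level = as.character(object$priority_level),
    severity = object$severity_component,
    family_deficit = object$family_deficit_component,
    support = object$support_component,
    total = object$total,
    stringsAsFactors = FALSE
  )
}
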