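# Synthetic communities.
#
# Correlated ordinal scores are produced by a latent-Gaussian threshold
# model: each subject draws a 36-dimensional latent normal vector (28
# individual + 8 family coordinates) with exchangeable within-domain
# correlation and a cross-domain block, and each coordinate is cut into the
# 0..4 ordinal scale at thresholds calibrated so the marginal mean hits a
# target. Optional mixture clusters shift the latent mean to create
# subpopulations with distinct capability profiles.

#' Worked-example portraits shipped with the package
#'
#' Six reference score vectors used throughout the documentation and tests:
#' two individual community members (`A_1`, `A_100`), their family vectors
#' (`B_1`, `B_100`), and the end-to-end worked example "Mr. Zhang"
#' (`zhang_individual`, `zhang_family`). All validate against the built-in
#' registries.
#'
#' @return Named list of `care_portrait` objects.
#' @examples
#' example_portraits()$zhang_family$scores
#' @export
example_portraits <- function() {
  ind <- load_registry("individual_v1")
  fam <- load_registry("family_v1")
  list(
    A_1 = validate_portrait(ind, "A_1", c(
      1, 2, 1, 1, 1, 2, 2, 2, 1, 1, 2, 1, 2, 2,
      3, 2, 2, 2, 1, 2, 1, 2, 2, 2, 1, 2, 3, 2)),
    A_100 = validate_portrait(ind, "A_100", c(
      2, 1, 3, 1, 2, 1, 1, 1, 3, 2, 1, 3, 0, 4,
      1, 0, 2, 1, 1, 2, 1, 1, 3, 1, 1, 1, 1, 1)),
    B_1 = validate_portrait(fam, "A_1", c(2, 3, 1, 1, 3, 1, 2, 2)),
    B_100 = validate_portrait(fam, "A_100", c(3, 2, 1, 2, 2, 2, 1, 2)),
    zhang_individual = validate_portrait(ind, "zhang", c(
      1, 1, 1, 1, 2, 2, 1, 1, 1, 2, 1, 2, 3, 3,
      1, 1, 1, 1, 2, 1, 1, 3, 2, 1, 2, 1, 1, 1)),
    zhang_family = validate_portrait(fam, "zhang",
                                     c(0, 2, 1, 1, 1, 1, 1, 2))
  )
}

#' Generator profile for a synthetic community
#'
#' @param n population size (>= 0).
#' @param seed integer seed; the generator touches no global random state
#'   beyond a local [set.seed()].
#' @param mean_capability target marginal mean score per indicator
#'   (default 2.5 of 4, a moderately capable community).
#' @param domain_correlation latent correlation between indicators of the
#'   same portrait kind, in \[0, 1) (default 0.6: capabilities decline
#'   together).
#' @param cross_correlation latent correlation between individual and family
#'   coordinates (default 0.3: weaker coupling across the two portraits).
#' @param clusters optional data frame with columns `weight` (summing to 1)
#'   and `shift` (latent mean shift in SD units) defining mixture
#'   subpopulations.
#' @return A `generator_profile` list.
#' @export
generator_profile <- function(n, seed = 1L, mean_capability = 2.5,
                              domain_correlation = 0.6,
                              cross_correlation = 0.3,
                              clusters = NULL) {
  stopifnot(n >= 0, n == round(n))
  if (domain_correlation < 0 || domain_correlation >= 1) {
    stop("domain_correlation must lie in [0,1)", call. = FALSE)
  }
  if (mean_capability <= 0 || mean_capability >= 4) {
    stop("mean_capability must lie strictly inside (0,4)", call. = FALSE)
  }
  if (!is.null(clusters)) {
    stopifnot(all(c("weight", "shift") %in% names(clusters)),
              abs(sum(clusters$weight) - 1) < 1e-9,
              all(clusters$weight > 0))
  }
  sigma <- .latent_sigma(domain_correlation, cross_correlation)
  chol_sigma <- tryCatch(chol(sigma), error = function(e) {
    stop("infeasible correlation structure (not positive definite): ",
         conditionMessage(e), call. = FALSE)
  })
  structure(
    list(n = as.integer(n), seed = as.integer(seed),
         mean_capability = mean_capability,
         domain_correlation = domain_correlation,
         cross_correlation = cross_correlation,
         clusters = clusters,
         chol_sigma = chol_sigma),
    class = "generator_profile"
  )
}

.latent_sigma <- function(rho_within, rho_cross) {
  p <- 36L
  sigma <- matrix(rho_cross, p, p)
  sigma[1:28, 1:28] <- rho_within
  sigma[29:36, 29:36] <- rho_within
  diag(sigma) <- 1
  sigma
}

# Cut points on the standard-normal latent scale so that the marginal mean
# of the 0..4 score equals `target`. Equally spaced cuts around a location
# found by monotone root search: mean(delta) = sum_k P(Z > c_k - delta) is
# strictly increasing in delta.
.calibrate_cuts <- function(target) {
  base <- stats::qnorm(c(0.2, 0.4, 0.6, 0.8))
  mean_at <- function(delta) sum(1 - stats::pnorm(base - delta))
  delta <- stats::uniroot(function(d) mean_at(d) - target,
                          interval = c(-6, 6), tol = 1e-10)$root
  base - delta
}

#' Generate a synthetic community of dual portraits
#'
#' Draws `n` subjects from the profile's latent-Gaussian threshold model.
#' Deterministic given the profile seed; subject ids are `"S0001"`,
#' `"S0002"`, ... in draw order.
#'
#' @param profile a `generator_profile`.
#' @return List of `dual_portrait` objects (empty list when `n = 0`). Each
#'   portrait carries the generating cluster (if any) in
#'   `demographics$cluster`.
#' @examples
#' pop <- generate_population(generator_profile(n = 5, seed = 42))
#' pop[[1]]
#' @export
generate_population <- function(profile) {
  stopifnot(inherits(profile, "generator_profile"))
  n <- profile$n
  if (n == 0L) return(list())
  ind_reg <- load_registry("individual_v1")
  fam_reg <- load_registry("family_v1")
  cuts <- .calibrate_cuts(profile$mean_capability)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(profile$seed)
  z <- matrix(stats::rnorm(n * 36L), n, 36L) %*% profile$chol_sigma
  cluster <- rep(NA_integer_, n)
  if (!is.null(profile$clusters)) {
    cluster <- sample.int(nrow(profile$clusters), n, replace = TRUE,
                          prob = profile$clusters$weight)
    z <- z + profile$clusters$shift[cluster]
  }
  ids <- sprintf("S%04d", seq_len(n))
  lapply(seq_len(n), function(i) {
    scores <- colSums(outer(cuts, z[i, ], `<`))
    demo <- if (!is.na(cluster[i])) list(cluster = cluster[i])
    dual_portrait(
      validate_portrait(ind_reg, ids[i], scores[1:28]),
      validate_portrait(fam_reg, ids[i], scores[29:36]),
      demographics = demo
    )
  })
}

#' Generate a synthetic total mapping matrix for testing
#'
#' Builds a total rule table over a registry with one pseudo-random service
#' item per (indicator, level) cell, intensity grade `5 - level`, and
#' categories drawn from the controlled vocabulary. Deterministic given
#' `seed`. Intended for exercising the engine, not for content fidelity.
#'
#' @param registry a `care_registry`.
#' @param seed integer seed for label/category draws.
#' @return A total `mapping_matrix` (140 rules individual, 40 family).
#' @export
generate_rule_fixture <- function(registry, seed = 1L) {
  stopifnot(inherits(registry, "care_registry"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  ids <- registry$indicators$id
  grid <- expand.grid(indicator_id = ids, score_level = 0:4,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$indicator_id, ids), grid$score_level), ]
  tag <- replicate(nrow(grid),
                   paste(sample(letters, 6, replace = TRUE), collapse = ""))
  rules <- data.frame(
    portrait_kind = registry$kind,
    indicator_id = grid$indicator_id,
    score_level = grid$score_level,
    item_label = sprintf("synthetic service %s for %s at level %d",
                         tag, grid$indicator_id, grid$score_level),
    category = sample(service_categories(), nrow(grid), replace = TRUE),
    intensity_grade = 5L - grid$score_level,
    provenance = "synthetic",
    stringsAsFactors = FALSE
  )
  new_mapping_matrix(rules, registry)
}
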