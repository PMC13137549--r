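test_that("dual vectors normalize the concatenated scores into [0,1]", {
  zeros <- dual_portrait(
    validate_portrait(ind_reg, "z", rep(0, 28)),
    validate_portrait(fam_reg, "z", rep(0, 8)))
  expect_equal(dual_vector(zeros), rep(0, 36))
  ones <- dual_portrait(
    validate_portrait(ind_reg, "o", rep(4, 28)),
    validate_portrait(fam_reg, "o", rep(4, 8)))
  expect_equal(dual_vector(ones), rep(1, 36))
  zv <- dual_vector(zhang)
  expect_length(zv, 36)
  expect_equal(zv[1], 0.25)
  expect_equal(zv[29], 0)
})

test_that("similarity is symmetric, bounded, and matches the elementwise oracle", {
  cfg <- similarity_config()
  x <- dual_vector(zhang)
  expect_equal(similarity(x, x, cfg), 1)
  expect_equal(similarity(rep(0, 36), rep(1, 36), cfg), 0)
  expect_error(similarity(x, x[-1], cfg), "length")

  a1 <- dual_vector(dual_portrait(fx$A_1, fx$B_1))
  a100 <- dual_vector(dual_portrait(fx$A_100, fx$B_100))
  expect_equal(similarity(a1, a100, cfg), oracle_cosine(a1, a100),
               tolerance = 1e-14)

  set.seed(9)
  inv <- similarity_config(metric = "inverse_euclidean")
  for (i in 1:100) {
    u <- runif(36); v <- runif(36)
    expect_equal(similarity(u, v, cfg), oracle_cosine(u, v),
                 tolerance = 1e-14)
    expect_equal(similarity(u, v, cfg), similarity(v, u, cfg))
    s <- similarity(u, v, cfg)
    expect_true(s >= 0 && s <= 1)
    expect_equal(similarity(u, v, inv), 1 / (1 + sqrt(sum((u - v)^2))))
    expect_equal(similarity(u, u, inv), 1)
  }
})

test_that("neighbor search respects k, threshold, and the lexicographic tie rule", {
  cfg <- similarity_config(k_neighbors = 2)
  # three subjects equidistant from the target: identical portraits
  mk <- function(id, ind, fam) {
    dual_portrait(validate_portrait(ind_reg, id, ind),
                  validate_portrait(fam_reg, id, fam))
  }
  base_i <- rep(2, 28); base_f <- rep(2, 8)
  target <- mk("T", base_i, base_f)
  pop <- list(mk("c", base_i, base_f), mk("a", base_i, base_f),
              mk("b", base_i, base_f))
  nb <- neighbors(target, pop, cfg)
  expect_equal(nb$subject_id, c("a", "b"))
  expect_equal(nb$similarity, c(1, 1))

  # empty population and self-exclusion
  expect_equal(nrow(neighbors(target, list(), cfg)), 0L)
  expect_equal(nrow(neighbors(target, list(mk("T", base_i, base_f)), cfg)),
               0L)
  # single candidate below the similarity floor is dropped
  cfg_strict <- similarity_config(k_neighbors = 5, min_similarity = 0.999)
  far <- mk("f", c(rep(0, 27), 4), c(4, rep(0, 7)))
  expect_equal(nrow(neighbors(target, list(far), cfg_strict)), 0L)
  expect_equal(neighbors(target, list(far), cfg)$subject_id, "f")
})

test_that("neighbor support is the similarity-weighted carry fraction", {
  nb <- data.frame(subject_id = c("a", "b"), similarity = c(0.8, 0.2))
  sets <- list(a = c("k1", "k2"), b = c("k2"))
  expect_equal(neighbor_support("k1", nb, sets), 0.8)
  expect_equal(neighbor_support("k2", nb, sets), 1)
  expect_equal(neighbor_support("k3", nb, sets), 0)
  empty <- data.frame(subject_id = character(0), similarity = numeric(0))
  expect_equal(neighbor_support("k1", empty, list()), 0)
  zero <- data.frame(subject_id = "a", similarity = 0)
  expect_equal(neighbor_support("k1", zero, sets), 0)
})

test_that("priority components follow the impairment and family-deficit formulas", {
  cand <- map_portrait(fx$zhang_individual, ind_matrix)
  scored <- base_priority(merge_candidates(cand, NULL), zhang)
  expect_equal(scored$severity_component,
               vapply(scored$triggers,
                      function(t) max((4 - t$trigger_score) / 4),
                      numeric(1)))
  # mean family score 1.125 -> deficit (4 - 1.125)/4 for individual triggers
  expect_equal(mean(zhang$family$scores), 1.125)
  expect_true(all(scored$family_deficit_component == 0.71875))

  famc <- base_priority(
    merge_candidates(NULL, map_portrait(fx$zhang_family, fam_matrix)),
    zhang)
  expect_equal(famc$family_deficit_component,
               vapply(famc$triggers,
                      function(t) max((4 - t$trigger_score) / 4),
                      numeric(1)))
  # boundary cases
  expect_true(all(scored$severity_component[
    vapply(scored$triggers, function(t) all(t$trigger_score == 4),
           logical(1))] == 0))
})

test_that("hybrid ranking fuses components linearly and only permutes", {
  cand <- base_priority(
    merge_candidates(map_portrait(fx$zhang_individual, ind_matrix),
                     map_portrait(fx$zhang_family, fam_matrix)),
    zhang)
  cand$support_component <- 0
  r0 <- hybrid_rank(cand, similarity_config())
  expect_setequal(r0$key, cand$key)
  expect_equal(r0$total,
               0.5 * r0$severity_component +
                 0.3 * r0$family_deficit_component)
  expect_true(all(diff(r0$total) <= 0))

  # support 1 vs 0 under default weights moves the total by exactly 0.2
  cand2 <- cand
  cand2$support_component <- 1
  r1 <- hybrid_rank(cand2, similarity_config())
  m0 <- r0$total[match(cand$key, r0$key)]
  m1 <- r1$total[match(cand$key, r1$key)]
  expect_equal(m1 - m0, rep(0.2, nrow(cand)))

  # with zero support weight the ordering and totals ignore support
  wcfg <- similarity_config(weights = c(0.6, 0.4, 0))
  drop_support <- function(r) plain(r)[setdiff(names(r),
                                               "support_component")]
  expect_equal(drop_support(hybrid_rank(cand, wcfg)),
               drop_support(hybrid_rank(cand2, wcfg)))
  expect_error(similarity_config(weights = c(0.5, 0.5, 0.5)), "summing")
})

test_that("stratification uses closed lower bounds and is monotone", {
  cand <- data.frame(item_label = letters[1:5], category = "nursing",
                     intensity_grade = 3L,
                     severity_component = 1,
                     family_deficit_component = 1,
                     support_component = 1)
  r <- hybrid_rank(cand, similarity_config())
  r$total <- c(1, 2 / 3, 0.5, 1 / 3, 0.2)
  s <- stratify(r)
  expect_equal(as.character(s$priority_level),
               c("high", "high", "medium", "medium", "low"))
  expect_error(stratify(r, thresholds = c(0.2, 0.8)), "thresholds")
  # monotone: sort by total, levels never improve as total drops
  lv <- as.integer(s$priority_level[order(-s$total)])
  expect_true(all(diff(lv) >= 0))
})

test_that("recommend() is a deterministic permutation of stage 1 and CF only reorders", {
  set.seed(101)
  pop <- generate_population(generator_profile(n = 15, seed = 5))
  cfg <- similarity_config()
  rec <- recommend(zhang, pop, ind_matrix, fam_matrix, cfg)
  stage1 <- merge_candidates(map_portrait(zhang$individual, ind_matrix),
                             map_portrait(zhang$family, fam_matrix))
  expect_setequal(rec$key, stage1$key)
  expect_equal(nrow(rec), nrow(stage1))

  # byte-identical repeated runs
  rec2 <- recommend(zhang, pop, ind_matrix, fam_matrix, cfg)
  expect_identical(plain(rec), plain(rec2))

  # empty population: support is zero everywhere, rule-only ranking
  rec_empty <- recommend(zhang, list(), ind_matrix, fam_matrix, cfg)
  expect_true(all(rec_empty$support_component == 0))

  # with w_support = 0 the output is invariant to the population
  cfg0 <- similarity_config(weights = c(0.6, 0.4, 0))
  pop_b <- generate_population(generator_profile(n = 15, seed = 99))
  expect_equal(plain(recommend(zhang, pop, ind_matrix, fam_matrix, cfg0)),
               plain(recommend(zhang, pop_b, ind_matrix, fam_matrix, cfg0)))
  expect_equal(plain(recommend(zhang, list(), ind_matrix, fam_matrix, cfg0)),
               plain(recommend(zhang, pop, ind_matrix, fam_matrix, cfg0)))
})

test_that("weakening the family always raises individually-triggered priorities", {
  fam_hi <- validate_portrait(fam_reg, "zhang", rep(4, 8))
  fam_lo <- validate_portrait(fam_reg, "zhang", rep(0, 8))
  d_hi <- dual_portrait(fx$zhang_individual, fam_hi)
  d_lo <- dual_portrait(fx$zhang_individual, fam_lo)
  r_hi <- recommend(d_hi, list(), ind_matrix, fam_matrix)
  r_lo <- recommend(d_lo, list(), ind_matrix, fam_matrix)
  ind_only <- function(r) {
    r[vapply(r$triggers, function(t) all(t$source_kind == "individual"),
             logical(1)), ]
  }
  hi <- ind_only(r_hi); lo <- ind_only(r_lo)
  common <- intersect(hi$key, lo$key)
  expect_gt(length(common), 0)
  expect_true(all(lo$total[match(common, lo$key)] >=
                    hi$total[match(common, hi$key)]))

  # pointwise lowering (not just extremes), stepwise over random duals
  set.seed(33)
  for (i in 1:5) {
    d <- random_dual("s")
    fam_scores <- d$family$scores
    pos <- which(fam_scores > 0)
    j <- pos[sample.int(length(pos), 1)]
    fam_scores[j] <- fam_scores[j] - 1L
    d2 <- dual_portrait(d$individual,
                        validate_portrait(fam_reg, "s", fam_scores))
    ra <- ind_only(recommend(d, list(), ind_matrix, fam_matrix))
    rb <- ind_only(recommend(d2, list(), ind_matrix, fam_matrix))
    common <- intersect(ra$key, rb$key)
    expect_true(all(rb$total[match(common, rb$key)] >=
                      ra$total[match(common, ra$key)] - 1e-12))
  }
})

test_that("lowering an individual indicator never lowers the totals it triggers", {
  set.seed(44)
  for (i in 1:5) {
    d <- random_dual("s")
    ind_scores <- d$individual$scores
    pos <- which(ind_scores > 0)
    j <- pos[sample.int(length(pos), 1)]
    jid <- names(ind_scores)[j]
    ind_scores[j] <- ind_scores[j] - 1L
    d2 <- dual_portrait(validate_portrait(ind_reg, "s", ind_scores),
                        d$family)
    ra <- recommend(d, list(), ind_matrix, fam_matrix)
    rb <- recommend(d2, list(), ind_matrix, fam_matrix)
    ta <- ra[vapply(ra$triggers, function(t) jid %in% t$trigger_indicator,
                    logical(1)), ]
    tb <- rb[vapply(rb$triggers, function(t) jid %in% t$trigger_indicator,
                    logical(1)), ]
    # the triggered items change with the level; compare the strongest total
    expect_true(max(tb$total) >= max(ta$total) - 1e-12)
    expect_true(max(tb$intensity_grade) >= max(ta$intensity_grade))
  }
})
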