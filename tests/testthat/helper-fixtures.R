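# Shared test fixtures and independent oracles.

ind_reg <- load_registry("individual_v1")
fam_reg <- load_registry("family_v1")
ind_matrix <- load_mapping_matrix("individual_demo", ind_reg)
fam_matrix <- load_mapping_matrix("family_v1", fam_reg)
fx <- example_portraits()
zhang <- dual_portrait(fx$zhang_individual, fx$zhang_family)

# uniform random portrait (not via the package generator)
random_portrait <- function(registry, id) {
  validate_portrait(registry, id,
                    sample(0:4, nrow(registry$indicators), replace = TRUE))
}

random_dual <- function(id) {
  dual_portrait(random_portrait(ind_reg, id), random_portrait(fam_reg, id))
}

# independent stage-1 oracle: filter the raw rule table per indicator
oracle_map <- function(portrait, matrix) {
  rules <- matrix$rules
  ids <- matrix$registry$indicators$id
  out <- do.call(rbind, lapply(seq_along(ids), function(j) {
    hit <- rules[rules$indicator_id == ids[j] &
                   rules$score_level == portrait$scores[[j]],
                 c("item_label", "category", "intensity_grade")]
    hit$source_kind <- portrait$kind
    hit$trigger_indicator <- ids[j]
    hit$trigger_score <- portrait$scores[[j]]
    hit
  }))
  rownames(out) <- NULL
  out
}

# strip class/attribute decoration for plain data-frame comparison
plain <- function(df, cols = NULL) {
  df <- as.data.frame(df)
  class(df) <- "data.frame"
  attr(df, "subject_id") <- NULL
  attr(df, "config") <- NULL
  attr(df, "n_population") <- NULL
  if (!is.null(cols)) df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  df
}

# independent cosine oracle, written out elementwise
oracle_cosine <- function(u, v) {
  num <- 0; su <- 0; sv <- 0
  for (i in seq_along(u)) {
    num <- num + u[i] * v[i]
    su <- su + u[i]^2
    sv <- sv + v[i]^2
  }
  if (su == 0 || sv == 0) return(0)
  num / (sqrt(su) * sqrt(sv))
}

# normalized service identity, duplicated here so tests do not lean on the
# package's own key function
oracle_key <- function(label, category) {
  paste0(gsub("\\s+", " ", trimws(tolower(label))), "||", category)
}
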