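# Indicator registries: the fixed coordinate systems for capability portraits.
# Every indicator is scored on the same five-point ordinal scale 0..4, where
# 4 = full capability and 0 = complete loss (higher is better, by convention).

.SCALE_MIN <- 0L
.SCALE_MAX <- 4L

# 28 individual functional-capability indicators, in registry order.
# Order is binding: it is the coordinate order of every individual portrait.
.individual_v1 <- function() {
  data.frame(
    id = c(
      "eating", "personal_grooming", "bathing", "dressing_upper",
      "dressing_lower",
      "urinary_continence", "bowel_continence", "toileting",
      "bed_mobility", "bed_chair_transfer", "walking", "stair_climbing",
      "time_orientation", "spatial_orientation", "person_orientation",
      "memory",
      "comprehension", "expression",
      "aggressive_behavior", "depressive_symptoms",
      "consciousness", "vision", "hearing",
      "managing_daily_affairs", "using_transportation", "social_interaction",
      "digital_literacy",
      "chronic_disease_status"
    ),
    name = c(
      "Eating", "Personal grooming", "Bathing", "Dressing (upper body)",
      "Dressing (lower body & footwear)",
      "Urinary continence", "Bowel continence", "Toileting",
      "Bed mobility", "Bed-chair transfer", "Walking on level ground",
      "Stair climbing",
      "Time orientation", "Spatial orientation", "Person orientation",
      "Memory",
      "Comprehension", "Expression",
      "Aggressive behavior", "Depressive symptoms",
      "Level of consciousness", "Vision", "Hearing",
      "Managing daily affairs", "Using transportation", "Social interaction",
      "Digital literacy",
      "Chronic disease status"
    ),
    domain = c(
      rep("Basic ADL", 5),
      rep("Continence & toileting", 3),
      rep("Mobility", 4),
      rep("Cognitive orientation", 3),
      "Cognitive function",
      rep("Communication", 2),
      rep("Behavioral & emotional status", 2),
      rep("Consciousness & sensory function", 3),
      rep("Instrumental & social function", 4),
      "Health status"
    ),
    stringsAsFactors = FALSE
  )
}

# 8 family caregiving-capability indicators, in registry order.
.family_v1 <- function() {
  data.frame(
    id = c(
      "financial_resources", "medical_expenditure_burden",
      "housing_conditions",
      "daily_caregiving_time", "caregiving_skills",
      "communication_interaction", "decision_participation",
      "family_conflict_level"
    ),
    name = c(
      "Financial resources", "Medical expenditure burden",
      "Housing conditions",
      "Daily caregiving time", "Caregiving skills",
      "Communication and interaction", "Participation in decision-making",
      "Family conflict level"
    ),
    domain = c(
      rep("Economic capacity", 3),
      rep("Caregiving capacity", 2),
      rep("Emotional support capacity", 3)
    ),
    stringsAsFactors = FALSE
  )
}

.registry_cardinality <- c(individual = 28L, family = 8L)

#' Load an indicator registry
#'
#' A registry is the ordered list of capability indicators that defines the
#' coordinate system of a portrait vector. Two registries ship with the
#' package: `"individual_v1"` (28 indicators of individual functional
#' capability, grouped in 10 domains from basic ADL through health status)
#' and `"family_v1"` (8 indicators of family caregiving capability in 3
#' domains: economic, caregiving and emotional support capacity). A registry
#' can also be read from a JSON file with fields `kind` and an ordered
#' `indicators` array of `{id, name, domain}` records.
#'
#' All indicators are scored on the shared five-point ordinal scale 0 to 4,
#' higher meaning greater capability.
#'
#' @param source `"individual_v1"`, `"family_v1"`, or the path of a registry
#'   JSON file.
#' @return An object of class `care_registry`: a list with elements `kind`
#'   (`"individual"` or `"family"`), `indicators` (a data frame with columns
#'   `id`, `name`, `domain` in coordinate order), `scale_min` and `scale_max`.
#' @examples
#' reg <- load_registry("family_v1")
#' reg$indicators$id
#' @export
load_registry <- function(source) {
  stopifnot(is.character(source), length(source) == 1L)
  if (source == "individual_v1") {
    return(new_registry("individual", .individual_v1()))
  }
  if (source == "family_v1") {
    return(new_registry("family", .family_v1()))
  }
  if (!file.exists(source)) {
    stop("unknown registry name or missing file: ", source, call. = FALSE)
  }
  spec <- jsonlite::fromJSON(source, simplifyDataFrame = TRUE)
  if (is.null(spec$kind) || is.null(spec$indicators)) {
    stop("registry file must declare 'kind' and 'indicators'", call. = FALSE)
  }
  ind <- as.data.frame(spec$indicators, stringsAsFactors = FALSE)
  if (!all(c("id", "name", "domain") %in% names(ind))) {
    stop("registry indicators need id, name and domain fields", call. = FALSE)
  }
  if (!is.null(spec$scale_min) &&
      (spec$scale_min != .SCALE_MIN || spec$scale_max != .SCALE_MAX)) {
    stop("registry must use the 0..4 ordinal scale", call. = FALSE)
  }
  new_registry(spec$kind, ind[, c("id", "name", "domain")])
}

new_registry <- function(kind, indicators) {
  kind <- match.arg(kind, c("individual", "family"))
  if (anyDuplicated(indicators$id)) {
    stop("duplicate indicator id: ",
         paste(unique(indicators$id[duplicated(indicators$id)]),
               collapse = ", "),
         call. = FALSE)
  }
  expected <- .registry_cardinality[[kind]]
  if (nrow(indicators) != expected) {
    stop(sprintf("a %s registry must have exactly %d indicators, got %d",
                 kind, expected, nrow(indicators)), call. = FALSE)
  }
  structure(
    list(kind = kind,
         indicators = indicators,
         scale_min = .SCALE_MIN,
         scale_max = .SCALE_MAX),
    class = "care_registry"
  )
}

#' @export
print.care_registry <- function(x, ...) {
  cat(sprintf("<care_registry: %s, %d indicators, scale %d..%d>\n",
              x$kind, nrow(x$indicators), x$scale_min, x$scale_max))
  doms <- rle(x$indicators$domain)
  for (i in seq_along(doms$values)) {
    cat(sprintf("  %s (%d)\n", doms$values[i], doms$lengths[i]))
  }
  invisible(x)
}

#' Write a registry to JSON
#'
#' @param registry a `care_registry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  stopifnot(inherits(registry, "care_registry"))
  jsonlite::write_json(
    list(kind = registry$kind,
         scale_min = registry$scale_min,
         scale_max = registry$scale_max,
         indicators = registry$indicators),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}
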