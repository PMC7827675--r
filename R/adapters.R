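# Adapters that turn raw field measurements (Welfare Quality scores,
# wildlife capture tables, soil chemistry) into indicator percent scores.

#' Shannon-Wiener diversity index
#'
#' H' = -sum(p_i * log(p_i)) over relative abundances p_i, using the natural
#' logarithm. Zero counts are dropped; a single species gives H' = 0.
#'
#' @param counts Non-negative integer vector of per-species capture counts;
#'   at least one must be positive.
#' @return Non-negative scalar H' (<= log(richness)).
#' @examples
#' shannon_index(c(5, 5))       # log(2)
#' shannon_index(c(1, 1, 1, 1)) # log(4)
#' @export
shannon_index <- function(counts) {
  if (length(counts) == 0 || !is.numeric(counts) || any(is.na(counts)) ||
      any(counts < 0)) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    stop("at least one count must be positive", call. = FALSE)
  }
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Normalise a diversity index against the cohort maximum
#'
#' The greatest index observed across the farm cohort is assigned 100%;
#' other farms are scaled proportionally.
#'
#' @param h Diversity index for one farm (0 <= h <= h_max).
#' @param h_max The cohort maximum (> 0).
#' @return Percent in \[0, 100\].
#' @export
diversity_to_percent <- function(h, h_max) {
  if (!is.numeric(h) || !is.numeric(h_max) || is.na(h) || is.na(h_max)) {
    stop("h and h_max must be numeric", call. = FALSE)
  }
  if (h_max <= 0) {
    if (h > 0) stop("h_max must be positive when h > 0", call. = FALSE)
    stop("h_max must be positive", call. = FALSE)
  }
  if (h < 0 || h > h_max) {
    stop("h must lie in [0, h_max]; h_max must be the cohort maximum",
         call. = FALSE)
  }
  100 * h / h_max
}

#' Wild-species genetic diversity scores for a farm cohort
#'
#' Computes H' per taxon group and farm, normalises each group by the
#' cohort maximum for that group, and averages a farm's group percentages
#' into one indicator percent (farms without captures in a group score 0
#' for it). Taxon groups absent on every farm are skipped with a warning.
#'
#' @param captures Capture table for all farms: columns `farm_id`,
#'   `taxon_group`, `species`, `count` (and optionally the endemic /
#'   at_risk / introduced flags, ignored here).
#' @return A tibble with one row per farm: `farm_id`, `percent`, `rating`.
#' @export
genetic_diversity_rating <- function(captures) {
  captures <- validate_capture_table(captures)
  farms <- unique(captures$farm_id)
  groups <- unique(captures$taxon_group)
  h <- matrix(0, nrow = length(farms), ncol = length(groups),
              dimnames = list(farms, groups))
  for (g in groups) {
    gt <- captures[captures$taxon_group == g & captures$count > 0, ]
    if (nrow(gt) == 0) next
    for (f in unique(gt$farm_id)) {
      h[f, g] <- shannon_index(gt$count[gt$farm_id == f])
    }
  }
  keep <- logical(length(groups))
  for (j in seq_along(groups)) {
    tot <- sum(captures$count[captures$taxon_group == groups[j]])
    keep[j] <- tot > 0
  }
  if (!any(keep)) {
    stop("no taxon group has positive abundance cohort-wide", call. = FALSE)
  }
  if (any(!keep)) {
    warning("taxon group(s) with zero abundance everywhere skipped: ",
            paste(groups[!keep], collapse = ", "), call. = FALSE)
  }
  groups <- groups[keep]
  h <- h[, keep, drop = FALSE]
  pct <- h
  for (j in seq_along(groups)) {
    hmax <- max(h[, j])
    pct[, j] <- if (hmax > 0) 100 * h[, j] / hmax else 0
  }
  percent <- rowMeans(pct)
  tibble::tibble(farm_id = farms, percent = as.numeric(percent),
                 rating = percent_to_rating(as.numeric(percent)))
}

#' Rating from a count of endemic species
#'
#' Five or more endemic species rate best, four good, three moderate, two
#' limited, one or zero unacceptable (counts outside 1-5 are clamped to the
#' nearest defined rating).
#'
#' @param n Non-negative integer vector of endemic species counts.
#' @return Ordered rating factor.
#' @examples
#' endemic_count_to_rating(0:7)
#' @export
endemic_count_to_rating <- function(n) {
  if (!is.numeric(n) || any(is.na(n)) || any(n < 0) || any(n != floor(n))) {
    stop("n must be non-negative integer(s)", call. = FALSE)
  }
  idx <- pmin(pmax(as.integer(n), 1L), 5L)
  rating_factor(RATING_LEVELS[idx])
}

#' Default weights for the key-species score
#'
#' Species contribute points for being endemic or officially at risk and
#' lose a point for being introduced; per-species scores are floored at
#' zero. The maximum attainable per-species weight normalises the total.
#'
#' @param w_endemic,w_at_risk,w_introduced Non-negative weights.
#' @param w_max Maximum attainable per-species weight (default
#'   `w_endemic + w_at_risk`).
#' @return A list of class `key_species_weights`.
#' @export
key_species_weights <- function(w_endemic = 1, w_at_risk = 1,
                                w_introduced = 1, w_max = NULL) {
  if (any(c(w_endemic, w_at_risk, w_introduced) < 0)) {
    stop("weights must be non-negative", call. = FALSE)
  }
  w_max <- w_max %||% (w_endemic + w_at_risk)
  if (w_max <= 0) stop("w_max must be positive", call. = FALSE)
  structure(list(w_endemic = w_endemic, w_at_risk = w_at_risk,
                 w_introduced = w_introduced, w_max = w_max),
            class = "key_species_weights")
}

#' Key-species score for one farm's capture table
#'
#' Each species scores `w_endemic * endemic + w_at_risk * at_risk -
#' w_introduced * introduced`, floored at zero; the farm percent is
#' `100 * sum(scores) / (n_species * w_max)`, clamped to \[0, 100\].
#'
#' @param captures One farm's capture table with logical columns `endemic`,
#'   `at_risk`, `introduced`.
#' @param weights A [key_species_weights()] object.
#' @return Percent in \[0, 100\] (0 with a warning for an empty table).
#' @export
key_species_score <- function(captures, weights = key_species_weights()) {
  stopifnot(inherits(weights, "key_species_weights"))
  if (is.null(captures) || nrow(captures) == 0) {
    warning("empty capture table: key-species score is 0", call. = FALSE)
    return(0)
  }
  captures <- validate_capture_table(captures)
  if (length(unique(captures$farm_id)) > 1) {
    stop("key_species_score expects a single farm's table", call. = FALSE)
  }
  w <- weights$w_endemic * captures$endemic +
    weights$w_at_risk * captures$at_risk -
    weights$w_introduced * captures$introduced
  w <- pmax(w, 0)
  pct <- 100 * sum(w) / (nrow(captures) * weights$w_max)
  min(max(pct, 0), 100)
}

# properties required by each soil-quality indicator
SOIL_INDICATOR_PROPERTIES <- list(
  "soil-physical-structure" = c("texture_score", "organic_matter_pct"),
  "soil-chemical-quality" = c("no3_nh4_ratio", "total_organic_p"),
  "soil-biological-quality" = c("no3_nh4_ratio", "total_organic_c"),
  "soil-organic-matter" = "total_organic_c"
)

#' Soil-quality indicator percent from reference-normalised measurements
#'
#' Each soil property is expressed as the ratio of the farm measurement to
#' the value measured in undisturbed reference soil in the same area,
#' capped at 1 (references are maxima); the indicator percent is 100 times
#' the mean ratio over the properties the indicator requires:
#' physical structure uses texture and organic-matter percentage; chemical
#' quality the nitrate:ammonium ratio and total organic P; biological
#' quality the nitrate:ammonium ratio and total organic C; organic matter
#' the total organic C alone.
#'
#' @param soil One farm's soil table: columns `property`, `measured`
#'   (>= 0), `reference` (> 0).
#' @param indicator One of `"soil-physical-structure"`,
#'   `"soil-chemical-quality"`, `"soil-biological-quality"`,
#'   `"soil-organic-matter"`.
#' @return Percent in \[0, 100\].
#' @export
soil_indicator_percent <- function(soil, indicator) {
  props <- SOIL_INDICATOR_PROPERTIES[[indicator]]
  if (is.null(props)) {
    stop("unknown soil indicator '", indicator, "'", call. = FALSE)
  }
  missing <- setdiff(props, soil$property)
  if (length(missing) > 0) {
    stop("soil property '", paste(missing, collapse = "', '"),
         "' required by indicator '", indicator, "' is missing",
         call. = FALSE)
  }
  idx <- match(props, soil$property)
  measured <- soil$measured[idx]
  reference <- soil$reference[idx]
  if (any(is.na(measured)) || any(measured < 0)) {
    stop("measured values must be >= 0", call. = FALSE)
  }
  if (any(is.na(reference)) || any(reference <= 0)) {
    stop("reference values must be > 0", call. = FALSE)
  }
  ratios <- pmin(measured / reference, 1)
  100 * mean(ratios)
}

# Welfare Quality principle feeding each animal-welfare indicator
WQ_INDICATOR_MAP <- c(
  "animal-health-practices" = "good_feeding",
  "animal-health" = "good_health",
  "appropriate-animal-husbandry" = "appropriate_behavior",
  "freedom-of-stress" = "overall"
)

#' Animal-welfare indicator percents from Welfare Quality scores
#'
#' Welfare Quality principle scores already lie on 0-100 and are assigned
#' directly: Animal Health Practices takes the Good Feeding principle,
#' Animal Health the Good Health principle, Appropriate Animal Husbandry
#' the Appropriate Behavior principle, and Freedom of Stress the overall
#' farm score. Humane Animal Handling Practices combines criterion scores
#' by their unweighted mean when criterion-level scores are supplied, and
#' otherwise falls back to the overall score.
#'
#' @param wq A list (or one-row data frame) with principle scores
#'   `good_feeding`, `good_health`, `appropriate_behavior`, `overall`, all
#'   in \[0, 100\], and optionally `criterion_scores`, a named numeric
#'   vector of criterion scores.
#' @return Named numeric vector of indicator percents for the five
#'   animal-welfare indicators.
#' @export
wq_to_indicator_scores <- function(wq) {
  principles <- c("good_feeding", "good_health", "appropriate_behavior",
                  "overall")
  out <- numeric(0)
  for (ind in names(WQ_INDICATOR_MAP)) {
    key <- WQ_INDICATOR_MAP[[ind]]
    val <- wq[[key]]
    if (is.null(val) || is.na(val)) {
      stop("missing Welfare Quality principle '", key,
           "' blocks indicator '", ind, "'", call. = FALSE)
    }
    out[[ind]] <- val
  }
  crit <- wq[["criterion_scores"]]
  out[["humane-animal-handling-practices"]] <-
    if (!is.null(crit) && length(crit) > 0) mean(as.numeric(crit))
    else out[["freedom-of-stress"]]
  if (any(out < 0 | out > 100)) {
    stop("Welfare Quality scores must lie in [0, 100]", call. = FALSE)
  }
  out
}

validate_capture_table <- function(captures) {
  captures <- tibble::as_tibble(captures)
  needed <- c("farm_id", "taxon_group", "species", "count")
  missing <- setdiff(needed, names(captures))
  if (length(missing) > 0) {
    stop("capture table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(captures$count)) || any(captures$count < 0)) {
    stop("capture counts must be non-negative", call. = FALSE)
  }
  for (flag in c("endemic", "at_risk", "introduced")) {
    if (flag %in% names(captures)) {
      captures[[flag]] <- as.logical(captures[[flag]])
    }
  }
  key <- paste(captures$farm_id, captures$taxon_group, captures$species)
  if (anyDuplicated(key)) {
    stop("species must be unique within farm and taxon group", call. = FALSE)
  }
  captures
}

#' Read a wildlife capture table
#' @param path CSV with columns `farm_id,taxon_group,species,count,endemic,at_risk,introduced`.
#' @return Validated capture tibble.
#' @export
read_capture_table <- function(path) {
  validate_capture_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Read a soil measurement table
#' @param path CSV with columns `farm_id,property,measured,reference,units`.
#' @return Tibble of soil measurements.
#' @export
read_soil_table <- function(path) {
  tb <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  needed <- c("farm_id", "property", "measured", "reference")
  missing <- setdiff(needed, names(tb))
  if (length(missing) > 0) {
    stop("soil table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tb
}

#' Read a Welfare Quality score table
#'
#' @param path CSV with columns `farm_id,score_name,score_type,value` where
#'   `score_type` is `principle` or `criterion`.
#' @return A named list per farm with principle scores and a
#'   `criterion_scores` vector, suitable for [wq_to_indicator_scores()].
#' @export
read_wq_table <- function(path) {
  tb <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("farm_id", "score_name", "score_type", "value")
  missing <- setdiff(needed, names(tb))
  if (length(missing) > 0) {
    stop("WQ table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(split(tb, tb$farm_id), function(ft) {
    pr <- ft[ft$score_type == "principle", ]
    out <- as.list(setNames(pr$value, pr$score_name))
    cr <- ft[ft$score_type == "criterion", ]
    if (nrow(cr) > 0) out$criterion_scores <- setNames(cr$value, cr$score_name)
    out
  })
}
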