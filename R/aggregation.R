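# Upward aggregation: indicator percents -> subtheme -> theme scores and
# ratings, plus the per-theme data-quality (accuracy) label.
#
# The combiner at every level is the unweighted arithmetic mean, with
# not-evaluated children omitted from numerator and denominator. Ratings
# are derived from aggregated percents (never by aggregating ordinal
# ratings), and only excluded subthemes drop out of the totals.

#' Subtheme score from its indicators' percents
#'
#' @param percents Numeric vector of indicator percents for one subtheme.
#' @param excluded Is the subtheme excluded from the assessment?
#' @return The unweighted mean percent, or `NA` (not evaluated) for an
#'   excluded subtheme or one with no scored indicators (with a warning in
#'   the latter case).
#' @export
subtheme_score <- function(percents, excluded = FALSE) {
  if (isTRUE(excluded)) return(NA_real_)
  percents <- percents[!is.na(percents)]
  if (length(percents) == 0) {
    warning("non-excluded subtheme with no scored indicators is not evaluated",
            call. = FALSE)
    return(NA_real_)
  }
  mean(percents)
}

#' Theme score from its subthemes' percents
#'
#' @param subtheme_percents Numeric vector; `NA` marks not-evaluated
#'   subthemes, which are omitted.
#' @return Mean percent of evaluated subthemes.
#' @export
theme_score <- function(subtheme_percents) {
  vals <- subtheme_percents[!is.na(subtheme_percents)]
  if (length(vals) == 0) {
    stop("theme has no evaluated subtheme", call. = FALSE)
  }
  mean(vals)
}

#' Data-quality label for a theme
#'
#' Each indicator's accuracy tuple earns one point per satisfied criterion:
#' timeframe current, data type primary, methodology conforming to the
#' assessment guidelines (0-3 points). The theme label summarises the mean:
#' `>= 2.5` is 1 (high quality), `>= 1.5` is 2 (medium), otherwise 3 (low).
#'
#' @param timeframe,data_type,methodology Character vectors (one element
#'   per indicator): `current`/`outdated`, `primary`/`secondary`/`estimate`,
#'   `safa_conform`/`other`.
#' @return Integer 1, 2 or 3.
#' @export
accuracy_quality <- function(timeframe, data_type, methodology) {
  if (length(timeframe) == 0) {
    stop("at least one accuracy tuple is required", call. = FALSE)
  }
  pts <- (timeframe == "current") + (data_type == "primary") +
    (methodology == "safa_conform")
  m <- mean(pts)
  if (m >= 2.5) 1L else if (m >= 1.5) 2L else 3L
}

#' Compute adapter indicator scores for a farm cohort
#'
#' Runs the animal-welfare, biodiversity and soil adapters for every farm
#' in a study. Wild-species diversity is normalised against the cohort
#' maximum per taxon group, so adapter scores are defined for the cohort
#' as a whole, not farm by farm.
#'
#' @param farms List of per-farm input bundles, each a list with
#'   `farm_id`, `captures`, `soil`, `wq` (see [simulate_study()] for the
#'   layout).
#' @param framework A `safa_framework` (identifies the adapter indicators).
#' @param weights Key-species weights, see [key_species_weights()].
#' @return Tibble `farm_id, indicator_id, percent, timeframe, data_type,
#'   methodology` covering every adapter indicator for every farm.
#' @export
adapter_scores <- function(farms, framework, weights = key_species_weights()) {
  ind <- framework$indicators
  adapters <- ind[ind$indicator_type == "adapter", ]
  all_caps <- do.call(rbind, lapply(farms, function(f) f$captures))
  div <- genetic_diversity_rating(all_caps)
  fid_v <- character(0); iid_v <- character(0); pct_v <- numeric(0)
  add <- function(farm_id, indicator_id, percent) {
    fid_v <<- c(fid_v, farm_id)
    iid_v <<- c(iid_v, indicator_id)
    pct_v <<- c(pct_v, min(max(percent, 0), 100))
  }
  for (f in farms) {
    fid <- f$farm_id
    wq_scores <- wq_to_indicator_scores(f$wq)
    caps <- f$captures
    n_endemic <- 0L
    if (!is.null(caps) && nrow(caps) > 0) {
      n_endemic <- length(unique(caps$species[as.logical(caps$endemic)]))
    }
    for (i in seq_len(nrow(adapters))) {
      iid <- adapters$id[i]
      pct <- switch(
        adapters$adapter_kind[i],
        wq = wq_scores[[iid]],
        diversity = div$percent[div$farm_id == fid],
        endemic_count = {
          # the count-based rating enters the hierarchy as its band midpoint
          rating_ordinal(endemic_count_to_rating(n_endemic)) * 20 + 10
        },
        key_species = suppressWarnings(key_species_score(caps, weights)),
        soil = soil_indicator_percent(f$soil, iid),
        stop("unknown adapter kind '", adapters$adapter_kind[i], "'",
             call. = FALSE))
      if (length(pct) != 1 || is.na(pct)) {
        stop("adapter '", iid, "' produced no score for farm ", fid,
             call. = FALSE)
      }
      add(fid, iid, pct)
    }
  }
  tibble::tibble(farm_id = fid_v, indicator_id = iid_v, percent = pct_v,
                 timeframe = "current", data_type = "primary",
                 methodology = "other")
}

#' Assemble one farm's full assessment
#'
#' Combines generic (questionnaire-style) indicator scores with adapter
#' scores, aggregates to subtheme and theme percents, assigns ratings and
#' per-theme data-quality labels.
#'
#' @param farm A per-farm input bundle: list with `farm_id`, `system_type`,
#'   `indicator_scores` (tibble `indicator_id, percent, timeframe,
#'   data_type, methodology`).
#' @param framework A `safa_framework`, usually with exclusions applied.
#' @param adapters Adapter scores for the cohort from [adapter_scores()],
#'   or `NULL` if all indicator scores are already in `farm$indicator_scores`.
#' @return A `farm_assessment` object: list with `farm_id`, `system_type`,
#'   `indicator_scores`, `subtheme_scores`, `theme_results` (one row per
#'   theme: percent, rating, accuracy_quality).
#' @export
assess_farm <- function(farm, framework, adapters = NULL) {
  scores <- tibble::as_tibble(farm$indicator_scores)
  if (!is.null(adapters)) {
    mine <- adapters[adapters$farm_id == farm$farm_id,
                     setdiff(names(adapters), "farm_id")]
    scores <- rbind(scores[names(mine)], mine)
  }
  unknown <- setdiff(scores$indicator_id, framework$indicators$id)
  if (length(unknown) > 0) {
    stop("scores for unknown indicator(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(scores$percent)) ||
      any(scores$percent < 0 | scores$percent > 100)) {
    stop("indicator percents must lie in [0, 100]", call. = FALSE)
  }

  sub <- framework$subthemes
  scores$subtheme_id <- framework$indicators$subtheme_id[
    match(scores$indicator_id, framework$indicators$id)]
  scores$theme_id <- sub$theme_id[match(scores$subtheme_id, sub$id)]

  # subtheme level: mean of indicator percents; excluded -> not evaluated
  means <- tapply(scores$percent, factor(scores$subtheme_id, levels = sub$id),
                  mean)
  sub_percent <- as.numeric(means)
  sub_percent[sub$excluded] <- NA_real_
  subtheme_scores <- tibble::tibble(
    subtheme_id = sub$id, theme_id = sub$theme_id,
    percent = sub_percent, evaluated = !is.na(sub_percent))

  # theme level: mean of evaluated subthemes + accuracy label
  themes <- framework$themes
  active <- scores[!sub$excluded[match(scores$subtheme_id, sub$id)], ]
  tlev <- factor(sub$theme_id, levels = themes$id)
  theme_percent <- as.numeric(tapply(sub_percent, tlev,
                                     function(v) mean(v[!is.na(v)])))
  dead <- themes$id[is.na(theme_percent) | is.nan(theme_percent)]
  pts <- (active$timeframe == "current") + (active$data_type == "primary") +
    (active$methodology == "safa_conform")
  mean_pts <- tapply(pts, factor(active$theme_id, levels = themes$id), mean)
  theme_quality <- ifelse(mean_pts >= 2.5, 1L,
                          ifelse(mean_pts >= 1.5, 2L, 3L))
  theme_quality <- as.integer(theme_quality)
  if (length(dead) > 0) {
    stop("theme(s) with no evaluable content: ",
         paste(dead, collapse = ", "), call. = FALSE)
  }
  theme_results <- tibble::tibble(
    theme_id = themes$id, dimension_id = themes$dimension_id,
    percent = theme_percent,
    rating = percent_to_rating(theme_percent, framework$rating_scale),
    accuracy_quality = theme_quality)

  structure(
    list(farm_id = farm$farm_id,
         system_type = farm$system_type %||% NA_character_,
         indicator_scores = scores, subtheme_scores = subtheme_scores,
         theme_results = theme_results),
    class = "farm_assessment")
}

#' @export
print.farm_assessment <- function(x, ...) {
  tal <- table(x$theme_results$rating)
  cat("<farm_assessment> ", x$farm_id,
      if (!is.na(x$system_type)) paste0(" (", x$system_type, ")"), ": ",
      nrow(x$theme_results), " themes [",
      paste(names(tal), as.integer(tal), sep = "=", collapse = ", "),
      "]\n", sep = "")
  invisible(x)
}

#' Assess every farm in a study
#'
#' Runs the cohort-wide adapters once, then assembles a `farm_assessment`
#' per farm.
#'
#' @param study A list with a `farms` element (list of per-farm input
#'   bundles), e.g. from [simulate_study()].
#' @param framework A `safa_framework`; defaults to the bundled framework
#'   with the default smallholder exclusions applied.
#' @param weights Key-species weights.
#' @return Named list of `farm_assessment` objects.
#' @export
assess_study <- function(study,
                         framework = apply_exclusions(load_framework(),
                                                      default_exclusions()),
                         weights = key_species_weights()) {
  farms <- study$farms
  if (length(farms) == 0) stop("study has no farms", call. = FALSE)
  ad <- adapter_scores(farms, framework, weights)
  out <- lapply(farms, assess_farm, framework = framework, adapters = ad)
  names(out) <- vapply(farms, `[[`, "", "farm_id")
  out
}

#' Serialize a farm assessment to JSON
#' @param assessment A `farm_assessment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assessment_json <- function(assessment, path) {
  stopifnot(inherits(assessment, "farm_assessment"))
  doc <- list(
    farm_id = assessment$farm_id,
    system_type = assessment$system_type,
    theme_results = transform(assessment$theme_results,
                              rating = as.character(rating)),
    subtheme_scores = assessment$subtheme_scores,
    indicator_scores = assessment$indicator_scores)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
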