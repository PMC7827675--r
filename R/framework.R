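#' @importFrom stats rbeta rbinom rmultinom rnorm rpois runif setNames pnorm qnorm
#' @importFrom utils read.csv write.csv
NULL

RATING_LEVELS <- c("unacceptable", "limited", "moderate", "good", "best")

#' The five-level SAFA rating scale
#'
#' Ratings are defined over percent bands: unacceptable 0-20, limited 20-40,
#' moderate 40-60, good 60-80, best 80-100. Bands are lower-inclusive and
#' upper-exclusive except the top band, which is closed at 100, so every
#' percent in \[0, 100\] maps to exactly one level.
#'
#' @return A tibble with columns `label`, `ordinal` (0-4), `lower`, `upper`.
#' @export
rating_scale <- function() {
  tibble::tibble(
    label = RATING_LEVELS,
    ordinal = 0:4,
    lower = c(0, 20, 40, 60, 80),
    upper = c(20, 40, 60, 80, 100)
  )
}

#' Map a percent score to a rating level
#'
#' @param p Numeric vector of percent scores in \[0, 100\].
#' @param scale Rating scale as returned by [rating_scale()].
#' @return Ordered factor with levels unacceptable < limited < moderate <
#'   good < best.
#' @examples
#' percent_to_rating(c(0, 45, 60, 85, 100))
#' @export
percent_to_rating <- function(p, scale = rating_scale()) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 100)) {
    stop("percent scores must be numeric in [0, 100]", call. = FALSE)
  }
  # lower-inclusive bands; 100 belongs to the top band
  idx <- findInterval(p, scale$lower)
  rating_factor(scale$label[idx])
}

rating_factor <- function(labels) {
  factor(labels, levels = RATING_LEVELS, ordered = TRUE)
}

rating_ordinal <- function(rating) {
  as.integer(rating_factor(as.character(rating))) - 1L
}

#' Load a hierarchical assessment framework from a YAML/JSON config
#'
#' Reads a framework definition (dimensions, themes, subthemes, indicators
#' and the rating scale), resolves and validates all cross-references, and
#' checks that the number of indicators found under each dimension matches
#' the dimension's declared count.
#'
#' @param path Path to the config document. Defaults to the bundled
#'   framework: 4 dimensions, 21 themes, 58 subthemes, 116 indicators.
#' @return An object of class `safa_framework`: a list with tibbles
#'   `dimensions`, `themes`, `subthemes`, `indicators` and the `rating_scale`.
#' @examples
#' fw <- load_framework()
#' nrow(fw$themes)  # 21
#' @export
load_framework <- function(path = default_framework_path()) {
  doc <- yaml::read_yaml(path)
  required <- c("format_version", "rating_scale", "dimensions", "themes",
                "subthemes", "indicators")
  missing <- setdiff(required, names(doc))
  if (length(missing) > 0) {
    stop("framework config lacks keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  bind_records <- function(recs, fields, defaults = list()) {
    rows <- lapply(recs, function(r) {
      for (f in names(defaults)) if (is.null(r[[f]])) r[[f]] <- defaults[[f]]
      miss <- setdiff(fields, names(r))
      if (length(miss) > 0) {
        stop("framework record missing field(s) ", paste(miss, collapse = ", "),
             " in entry with id '", r$id %||% "?", "'", call. = FALSE)
      }
      tibble::as_tibble(r[fields])
    })
    do.call(rbind, rows)
  }

  scale <- bind_records(doc$rating_scale,
                        c("label", "ordinal", "lower", "upper"))
  if (!identical(scale$label, RATING_LEVELS) ||
      !identical(as.integer(scale$ordinal), 0:4)) {
    stop("rating scale must define the five levels ",
         paste(RATING_LEVELS, collapse = " < "), " in order", call. = FALSE)
  }

  dimensions <- bind_records(doc$dimensions,
                             c("id", "name", "declared_indicator_count"))
  themes <- bind_records(doc$themes, c("id", "name", "dimension_id"))
  subthemes <- bind_records(
    doc$subthemes, c("id", "name", "theme_id", "placeholder",
                     "excluded", "exclusion_justification"),
    defaults = list(placeholder = FALSE, excluded = FALSE,
                    exclusion_justification = NA_character_))
  indicators <- bind_records(
    doc$indicators, c("id", "name", "subtheme_id", "indicator_type",
                      "adapter_kind", "placeholder"),
    defaults = list(adapter_kind = NA_character_, placeholder = FALSE))

  for (tb in list(dimensions, themes, subthemes, indicators)) {
    dup <- tb$id[duplicated(tb$id)]
    if (length(dup) > 0) {
      stop("duplicate id(s): ", paste(unique(dup), collapse = ", "),
           call. = FALSE)
    }
  }
  check_ref <- function(child, field, parent_ids, what) {
    bad <- setdiff(unique(child[[field]]), parent_ids)
    if (length(bad) > 0) {
      stop(what, " reference(s) unresolved: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
  }
  check_ref(themes, "dimension_id", dimensions$id, "theme->dimension")
  check_ref(subthemes, "theme_id", themes$id, "subtheme->theme")
  check_ref(indicators, "subtheme_id", subthemes$id, "indicator->subtheme")

  ok_types <- c("performance", "practice", "target", "adapter")
  bad <- setdiff(unique(indicators$indicator_type), ok_types)
  if (length(bad) > 0) {
    stop("unknown indicator_type: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  # per-dimension indicator counts must match the declared counts
  ind_dim <- themes$dimension_id[match(
    subthemes$theme_id[match(indicators$subtheme_id, subthemes$id)],
    themes$id)]
  found <- table(factor(ind_dim, levels = dimensions$id))
  mism <- dimensions$declared_indicator_count != as.integer(found)
  if (any(mism)) {
    stop("indicator count mismatch for dimension(s) ",
         paste(sprintf("%s (declared %d, found %d)",
                       dimensions$id[mism],
                       dimensions$declared_indicator_count[mism],
                       as.integer(found)[mism]), collapse = "; "),
         call. = FALSE)
  }

  structure(
    list(dimensions = dimensions, themes = themes, subthemes = subthemes,
         indicators = indicators, rating_scale = scale,
         format_version = doc$format_version),
    class = "safa_framework")
}

#' Path to the bundled default framework config
#' @return File path of the YAML document shipped with the package.
#' @export
default_framework_path <- function() {
  system.file("extdata", "safa_framework.yaml", package = "safascore",
              mustWork = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.safa_framework <- function(x, ...) {
  cat("<safa_framework> ", nrow(x$dimensions), " dimensions, ",
      nrow(x$themes), " themes, ", nrow(x$subthemes), " subthemes (",
      sum(x$subthemes$excluded), " excluded), ", nrow(x$indicators),
      " indicators\n", sep = "")
  invisible(x)
}

#' Serialize a framework back to YAML
#'
#' Writing then re-loading the bundled framework yields an identical object
#' (round-trip property).
#'
#' @param framework A `safa_framework`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
serialize_framework <- function(framework, path) {
  stopifnot(inherits(framework, "safa_framework"))
  row_list <- function(tb, drop_na = character(0)) {
    lapply(seq_len(nrow(tb)), function(i) {
      r <- as.list(tb[i, ])
      for (f in drop_na) if (is.na(r[[f]])) r[[f]] <- NULL
      r
    })
  }
  doc <- list(
    format_version = framework$format_version,
    rating_scale = row_list(framework$rating_scale),
    dimensions = row_list(framework$dimensions),
    themes = row_list(framework$themes),
    subthemes = row_list(framework$subthemes,
                         drop_na = "exclusion_justification"),
    indicators = row_list(framework$indicators, drop_na = "adapter_kind")
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Flag subthemes as excluded from the assessment
#'
#' Contextualization may omit subthemes that cannot be measured; each
#' omission must carry a written justification. Excluded subthemes
#' contribute to no downstream score or accuracy total.
#'
#' @param framework A `safa_framework`.
#' @param exclusions A data frame (or list of lists) with columns
#'   `subtheme_id` and `justification`.
#' @return The framework with the subthemes flagged. Idempotent for a fixed
#'   exclusion list.
#' @seealso [default_exclusions()] for the bundled five-farm-study list.
#' @export
apply_exclusions <- function(framework, exclusions) {
  stopifnot(inherits(framework, "safa_framework"))
  if (is.list(exclusions) && !is.data.frame(exclusions)) {
    exclusions <- do.call(rbind, lapply(exclusions, tibble::as_tibble))
  }
  if (is.null(exclusions) || nrow(exclusions) == 0) return(framework)
  if (!all(c("subtheme_id", "justification") %in% names(exclusions))) {
    stop("exclusions need columns subtheme_id and justification",
         call. = FALSE)
  }
  unknown <- setdiff(exclusions$subtheme_id, framework$subthemes$id)
  if (length(unknown) > 0) {
    stop("unknown subtheme_id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  empty <- is.na(exclusions$justification) |
    !nzchar(trimws(exclusions$justification))
  if (any(empty)) {
    stop("every exclusion needs a non-empty justification (missing for: ",
         paste(exclusions$subtheme_id[empty], collapse = ", "), ")",
         call. = FALSE)
  }
  idx <- match(exclusions$subtheme_id, framework$subthemes$id)
  framework$subthemes$excluded[idx] <- TRUE
  framework$subthemes$exclusion_justification[idx] <- exclusions$justification
  framework
}

#' Default subtheme exclusions for smallholder cattle farms
#'
#' The five subthemes that typically cannot be measured on smallholder
#' cattle farms in the Yucatan study setting: Stability of Production
#' (own forage production), Air Quality and Water Quality (no feasible
#' standard measurements), Material Use (no records), and Product
#' Information (no calf traceability).
#'
#' @return A tibble with columns `subtheme_id`, `justification`.
#' @export
default_exclusions <- function() {
  tibble::tibble(
    subtheme_id = c("stability-of-production", "air-quality", "water-quality",
                    "material-use", "product-information"),
    justification = c(
      "Farms produce their own forage and act as their own providers.",
      "No formal air-contaminant reduction plans; standard pollution values unfeasible to measure.",
      "Empirical water-quality preservation measures unfeasible; residual water samples unobtainable.",
      "Minimal construction material use; no records to compute nutrient balance.",
      "Calves lack traceability after sale under the rural trading system.")
  )
}
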