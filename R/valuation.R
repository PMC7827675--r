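# Positive/negative theme valuation, rating-band construction and farm
# ranking: the summary procedure applied on top of the 21 theme ratings.

#' Round a valuation percentage
#'
#' The study's rounding convention: fractional parts up to and including
#' 0.5 round down, anything greater rounds up (so 13.4 -> 13, 9.52 -> 10).
#'
#' @param x Non-negative numeric vector.
#' @return Integer vector; always `floor(x)` or `ceiling(x)`, monotone
#'   non-decreasing in `x`.
#' @export
round_percent <- function(x) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0)) {
    stop("x must be non-negative", call. = FALSE)
  }
  f <- floor(x)
  as.integer(ifelse(x - f > 0.5, f + 1, f))
}

#' Tally theme ratings for one farm
#'
#' @param assessment A `farm_assessment` (21 theme results for the default
#'   framework).
#' @return Named integer vector of counts per rating level, summing to the
#'   number of themes.
#' @export
theme_tally <- function(assessment) {
  if (inherits(assessment, "farm_assessment")) {
    ratings <- assessment$theme_results$rating
  } else {
    ratings <- rating_factor(as.character(assessment))
  }
  if (length(ratings) == 0 || any(is.na(ratings))) {
    stop("assessment must provide a rating for every theme", call. = FALSE)
  }
  tab <- table(ratings)
  setNames(as.integer(tab), names(tab))
}

#' Positive and negative valuation percentages
#'
#' Themes rated best or good count as positive, limited or unacceptable as
#' negative; moderate themes are dropped. Each side is the rounded
#' percentage of the total theme count (counts are summed first, the
#' percentage rounded once).
#'
#' @param tally Named counts per rating level from [theme_tally()].
#' @param n_themes Total number of themes evaluated (denominator);
#'   defaults to `sum(tally)`.
#' @return List with integer `positive_pct` and `negative_pct`.
#' @examples
#' valuation(c(best = 8, good = 6, moderate = 4, limited = 2, unacceptable = 1))
#' @export
valuation <- function(tally, n_themes = sum(tally)) {
  cnt <- function(lv) if (lv %in% names(tally)) tally[[lv]] else 0L
  pos <- cnt("best") + cnt("good")
  neg <- cnt("limited") + cnt("unacceptable")
  list(positive_pct = round_percent(100 * pos / n_themes),
       negative_pct = round_percent(100 * neg / n_themes))
}

#' Build the five rating bands from a maximum valuation
#'
#' The cohort's highest valuation percentage is divided by five to obtain
#' the width of the lowest band; cut points are the rounded multiples
#' `k * max_value / 5` for k = 1..5, giving five contiguous integer
#' intervals covering 0..max_value. For positive valuations the labels
#' ascend toward best; for negative valuations they ascend toward
#' unacceptable (a high negative share is bad).
#'
#' @param max_value Highest observed valuation percentage (> 0).
#' @param direction `"positive"` or `"negative"`.
#' @return A `rating_bands` object: tibble of `label`, `lower`, `upper`
#'   plus the direction and maximum.
#' @examples
#' build_bands(67, "positive")
#' build_bands(38, "negative")
#' @export
build_bands <- function(max_value, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  if (!is.numeric(max_value) || length(max_value) != 1 || is.na(max_value) ||
      max_value <= 0) {
    stop("max_value must be a positive number", call. = FALSE)
  }
  cuts <- round_percent((1:5) * max_value / 5)
  lower <- c(0L, cuts[1:4] + 1L)
  upper <- cuts
  labels <- if (direction == "positive") RATING_LEVELS else rev(RATING_LEVELS)
  structure(
    tibble::tibble(label = labels, lower = lower, upper = upper),
    direction = direction, max_value = as.integer(max_value),
    class = c("rating_bands", class(tibble::tibble())))
}

#' Categorize a valuation percentage against rating bands
#'
#' @param v Integer valuation percentage(s) in `0..max_value`.
#' @param bands A [build_bands()] result.
#' @return Ordered rating factor (the label of the interval containing each
#'   `v`).
#' @export
categorize <- function(v, bands) {
  stopifnot(inherits(bands, "rating_bands"))
  if (any(is.na(v)) || any(v < 0) || any(v > attr(bands, "max_value"))) {
    stop("v must lie in [0, ", attr(bands, "max_value"),
         "], the range the bands cover", call. = FALSE)
  }
  idx <- findInterval(v, bands$lower)
  rating_factor(bands$label[idx])
}

#' Rank farms by positive and negative valuation
#'
#' Farms are listed by descending positive valuation; ties are broken by
#' ascending negative valuation; farms tied on both keep their input order
#' (stable sort). Each farm's valuations are then categorized against
#' bands built from the cohort maxima.
#'
#' @param valuations A data frame with columns `farm_id`, `positive_pct`,
#'   `negative_pct` (one row per farm), or a named list of
#'   `farm_assessment` objects whose valuations are computed first.
#' @param bands_from Either `"cohort"` (bands from the observed maxima,
#'   the default) or `"fixed"` (a 0-100 scale for cross-study comparison).
#' @return A tibble ordered by rank with columns `rank`, `farm_id`,
#'   `positive_pct`, `negative_pct`, `positive_category`,
#'   `negative_category`, plus the two band tables as attributes
#'   `positive_bands` / `negative_bands`.
#' @export
rank_farms <- function(valuations, bands_from = c("cohort", "fixed")) {
  bands_from <- match.arg(bands_from)
  if (!is.data.frame(valuations)) {
    rows <- lapply(valuations, function(a) {
      v <- valuation(theme_tally(a))
      tibble::tibble(farm_id = a$farm_id, positive_pct = v$positive_pct,
                     negative_pct = v$negative_pct)
    })
    valuations <- do.call(rbind, rows)
  }
  if (nrow(valuations) == 0) stop("at least one farm required", call. = FALSE)
  ord <- order(-valuations$positive_pct, valuations$negative_pct,
               method = "radix")  # stable: full ties keep input order
  out <- tibble::as_tibble(valuations[ord, ])
  out$rank <- seq_len(nrow(out))

  pos_max <- if (bands_from == "fixed") 100L else max(out$positive_pct)
  neg_max <- if (bands_from == "fixed") 100L else max(out$negative_pct)
  pos_bands <- if (pos_max > 0) build_bands(pos_max, "positive")
  neg_bands <- if (neg_max > 0) build_bands(neg_max, "negative")
  out$positive_category <- if (!is.null(pos_bands)) {
    categorize(out$positive_pct, pos_bands)
  } else rating_factor(rep("unacceptable", nrow(out)))
  out$negative_category <- if (!is.null(neg_bands)) {
    categorize(out$negative_pct, neg_bands)
  } else rating_factor(rep("best", nrow(out)))

  out <- out[, c("rank", "farm_id", "positive_pct", "negative_pct",
                 "positive_category", "negative_category")]
  attr(out, "positive_bands") <- pos_bands
  attr(out, "negative_bands") <- neg_bands
  out
}
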