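# Sustainability polygons (radar-style SVG, one spoke per theme) and
# report export. Rendering is deterministic: no timestamps, fixed number
# formatting, so identical assessments yield identical bytes.

RATING_COLORS <- c(
  best = "#1a7a1a",          # dark green
  good = "#7fd47f",          # light green
  moderate = "#f2d43d",      # yellow
  limited = "#f28c28",       # orange
  unacceptable = "#d42a2a")  # red

DIMENSION_COLORS <- c(
  "good-governance" = "#3a6fd8",         # blue
  "environmental-integrity" = "#3aa655", # green
  "economic-resilience" = "#e8c93d",     # yellow
  "social-well-being" = "#9a9a9a")       # grey

#' Render a farm's sustainability polygon to SVG
#'
#' Draws one spoke per theme (radius proportional to the rating ordinal
#' plus one, on a 1-5 scale), a closed rating line, rating-colored theme
#' markers, dimension group arcs, and theme labels annotated with the 1-3
#' data-quality number. Themes are ordered around the ring by dimension,
#' in framework order.
#'
#' @param assessment A `farm_assessment`.
#' @param path Output file path (`.svg`).
#' @param framework The `safa_framework` the assessment was built with
#'   (used for theme names and dimension grouping).
#' @return `path`, invisibly.
#' @export
render_polygon <- function(assessment, path, framework = load_framework()) {
  stopifnot(inherits(assessment, "farm_assessment"))
  tr <- assessment$theme_results
  themes <- framework$themes[framework$themes$id %in% tr$theme_id, ]
  tr <- tr[match(themes$id, tr$theme_id), ]
  n <- nrow(tr)
  if (n == 0) stop("assessment has no theme results", call. = FALSE)

  cx <- 330; cy <- 330
  r_unit <- 44  # one rating step in px
  r_max <- 5 * r_unit
  ang <- -pi / 2 + (seq_len(n) - 1) * 2 * pi / n
  px <- function(r, a) c(cx + r * cos(a), cy + r * sin(a))
  fmt <- function(x) sprintf("%.2f", x)

  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<svg xmlns="http://www.w3.org/2000/svg" width="660" height="660" viewBox="0 0 660 660">',
    sprintf('<title>Sustainability polygon: %s</title>', assessment$farm_id),
    '<rect width="660" height="660" fill="white"/>')

  # concentric guide rings, one per rating level
  for (k in 1:5) {
    out <- c(out, sprintf(
      '<circle cx="%d" cy="%d" r="%s" fill="none" stroke="#dddddd" stroke-width="1"/>',
      cx, cy, fmt(k * r_unit)))
  }

  # dimension group arcs just outside the outer ring
  half <- pi / n
  r_arc <- r_max + 12
  for (d in unique(themes$dimension_id)) {
    idx <- which(themes$dimension_id == d)
    a0 <- ang[min(idx)] - half
    a1 <- ang[max(idx)] + half
    p0 <- px(r_arc, a0); p1 <- px(r_arc, a1)
    large <- if ((a1 - a0) > pi) 1 else 0
    out <- c(out, sprintf(
      '<path d="M %s %s A %s %s 0 %d 1 %s %s" fill="none" stroke="%s" stroke-width="8" class="dimension-arc" data-dimension="%s"/>',
      fmt(p0[1]), fmt(p0[2]), fmt(r_arc), fmt(r_arc), large,
      fmt(p1[1]), fmt(p1[2]), DIMENSION_COLORS[[d]], d))
  }

  # spokes, rating markers and labels
  radii <- (rating_ordinal(tr$rating) + 1) * r_unit
  for (i in seq_len(n)) {
    tip <- px(r_max, ang[i])
    out <- c(out, sprintf(
      '<line x1="%d" y1="%d" x2="%s" y2="%s" stroke="#bbbbbb" stroke-width="1" class="spoke" data-theme="%s"/>',
      cx, cy, fmt(tip[1]), fmt(tip[2]), tr$theme_id[i]))
  }
  pts <- vapply(seq_len(n), function(i) px(radii[i], ang[i]), numeric(2))
  out <- c(out, sprintf(
    '<polygon points="%s" fill="none" stroke="#111111" stroke-width="2.5" class="rating-line"/>',
    paste(fmt(pts[1, ]), fmt(pts[2, ]), sep = ",", collapse = " ")))
  for (i in seq_len(n)) {
    out <- c(out, sprintf(
      '<circle cx="%s" cy="%s" r="7" fill="%s" stroke="#333333" stroke-width="1" class="theme-marker" data-theme="%s" data-rating="%s"/>',
      fmt(pts[1, i]), fmt(pts[2, i]),
      RATING_COLORS[[as.character(tr$rating[i])]], tr$theme_id[i],
      as.character(tr$rating[i])))
    lab <- px(r_max + 28, ang[i])
    anchor <- if (abs(cos(ang[i])) < 0.25) "middle"
      else if (cos(ang[i]) > 0) "start" else "end"
    out <- c(out, sprintf(
      '<text x="%s" y="%s" font-size="10" font-family="sans-serif" text-anchor="%s" class="theme-label" data-theme="%s">%s (%d)</text>',
      fmt(lab[1]), fmt(lab[2]), anchor, tr$theme_id[i],
      themes$name[i], tr$accuracy_quality[i]))
  }
  out <- c(out, sprintf(
    '<text x="%d" y="24" font-size="14" font-family="sans-serif" text-anchor="middle">%s</text>',
    cx, assessment$farm_id), "</svg>")

  writeLines(out, path)
  invisible(path)
}

#' Export assessment and ranking reports
#'
#' Writes the ranking table (CSV and JSON), the rating-band definitions
#' used for categorization (JSON), and a combined per-farm theme table
#' (CSV). Output is byte-stable for fixed input.
#'
#' @param assessments Named list of `farm_assessment` objects.
#' @param ranking A ranking tibble from [rank_farms()]; computed from the
#'   assessments when `NULL`.
#' @param dir Output directory (created if absent).
#' @return Character vector of the files written, invisibly.
#' @export
export_report <- function(assessments, ranking = NULL, dir = ".") {
  if (length(assessments) == 0) {
    stop("at least one assessment is required", call. = FALSE)
  }
  ids <- vapply(assessments, `[[`, "", "farm_id")
  if (is.null(ranking)) {
    ranking <- rank_farms(assessments)
  } else if (!setequal(ranking$farm_id, ids)) {
    stop("farm ids in ranking and assessments disagree", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(name) {
    p <- file.path(dir, name)
    files <<- c(files, p)
    p
  }

  rk <- transform(as.data.frame(ranking),
                  positive_category = as.character(positive_category),
                  negative_category = as.character(negative_category))
  write.csv(rk, emit("ranking.csv"), row.names = FALSE, quote = TRUE)
  jsonlite::write_json(rk, emit("ranking.json"), auto_unbox = TRUE,
                       digits = NA)

  bands <- list(
    positive = as.data.frame(attr(ranking, "positive_bands")),
    negative = as.data.frame(attr(ranking, "negative_bands")))
  jsonlite::write_json(bands, emit("bands.json"), auto_unbox = TRUE,
                       digits = NA)

  theme_tb <- do.call(rbind, lapply(assessments[order(ids)], function(a) {
    cbind(farm_id = a$farm_id,
          transform(as.data.frame(a$theme_results),
                    rating = as.character(rating)))
  }))
  write.csv(theme_tb, emit("theme_results.csv"), row.names = FALSE,
            quote = TRUE)
  invisible(files)
}
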