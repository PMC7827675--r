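# Seeded synthetic field data for three cattle-system archetypes:
# Native Silvopastoral (NS), Intensive Silvopastoral (IS) and Monoculture
# (MS). The generator emulates the four raw inputs the pipeline consumes:
# generic (questionnaire-style) indicator percents with accuracy metadata,
# wildlife capture tables, reference-paired soil measurements, and Welfare
# Quality scores.

# per-theme mean percents encoding the qualitative archetype contrasts:
# NS strong on Participation / Land / Biodiversity / Cultural Diversity,
# IS strong on Holistic Management, all archetypes weak on Atmosphere and
# Water, MS weakest overall. Synthetic calibration constants, not
# measured values.
ARCHETYPE_THEME_MEANS <- local({
  m <- rbind(
    `corporate-ethics`                = c(50, 50, 50),
    accountability                    = c(50, 50, 50),
    participation                     = c(85, 55, 50),
    `rule-of-law`                     = c(70, 70, 70),
    `holistic-management`             = c(55, 72, 50),
    atmosphere                        = c(28, 22, 12),
    water                             = c(30, 30, 30),
    land                              = c(78, 68, 50),
    biodiversity                      = c(70, 58, 32),
    `materials-and-energy`            = c(50, 50, 45),
    `animal-welfare`                  = c(80, 78, 72),
    investment                        = c(70, 70, 58),
    vulnerability                     = c(58, 52, 50),
    `product-quality-and-information` = c(50, 50, 50),
    `local-economy`                   = c(85, 85, 85),
    `decent-livelihood`               = c(30, 30, 45),
    `fair-trading-practices`          = c(70, 70, 70),
    `labor-rights`                    = c(65, 55, 60),
    equity                            = c(72, 65, 55),
    `human-safety-and-health`         = c(75, 60, 50),
    `cultural-diversity`              = c(70, 55, 45)
  )
  colnames(m) <- c("NS", "IS", "MS")
  m
})

#' Archetype profile for the synthetic-data generator
#'
#' Bundles the generator parameters for one production-system archetype:
#' per-theme mean percents and a common dispersion for generic indicators,
#' capture-rate parameters per taxon group (expected abundance, richness,
#' endemic / at-risk / introduced fractions), the mean soil
#' measurement-to-reference ratio, and Welfare Quality principle means.
#'
#' @param system_type `"NS"`, `"IS"` or `"MS"`.
#' @param theme_means Named numeric vector of mean percents per theme id;
#'   defaults to the package's archetype calibration.
#' @param dispersion Standard deviation of generic indicator percents
#'   around the theme mean (percents are truncated to \[0, 100\]).
#' @param richness,abundance Expected species richness and total captures
#'   per taxon group (Poisson means).
#' @param endemic_frac,at_risk_frac,introduced_frac Per-species flag
#'   probabilities.
#' @param soil_ratio_mean Mean of the Beta-distributed measurement /
#'   reference ratio.
#' @param wq_mean,wq_sd Mean and dispersion of Welfare Quality principle
#'   scores.
#' @return A list of class `archetype_profile`.
#' @export
archetype_profile <- function(system_type = c("NS", "IS", "MS"),
                              theme_means = NULL, dispersion = 8,
                              richness = NULL, abundance = NULL,
                              endemic_frac = NULL, at_risk_frac = NULL,
                              introduced_frac = NULL,
                              soil_ratio_mean = NULL,
                              wq_mean = NULL, wq_sd = 6) {
  system_type <- match.arg(system_type)
  defaults <- list(
    NS = list(richness = 8, abundance = 45, endemic_frac = 0.40,
              at_risk_frac = 0.15, introduced_frac = 0.05,
              soil_ratio_mean = 0.85, wq_mean = 80),
    IS = list(richness = 6, abundance = 35, endemic_frac = 0.30,
              at_risk_frac = 0.10, introduced_frac = 0.10,
              soil_ratio_mean = 0.70, wq_mean = 78),
    MS = list(richness = 3, abundance = 15, endemic_frac = 0.12,
              at_risk_frac = 0.05, introduced_frac = 0.25,
              soil_ratio_mean = 0.45, wq_mean = 70)
  )[[system_type]]
  tm <- theme_means %||% setNames(ARCHETYPE_THEME_MEANS[, system_type],
                                  rownames(ARCHETYPE_THEME_MEANS))
  if (any(tm < 0 | tm > 100)) {
    stop("theme means must lie in [0, 100]", call. = FALSE)
  }
  if (dispersion < 0) stop("dispersion must be >= 0", call. = FALSE)
  prof <- list(
    system_type = system_type, theme_means = tm, dispersion = dispersion,
    richness = richness %||% defaults$richness,
    abundance = abundance %||% defaults$abundance,
    endemic_frac = endemic_frac %||% defaults$endemic_frac,
    at_risk_frac = at_risk_frac %||% defaults$at_risk_frac,
    introduced_frac = introduced_frac %||% defaults$introduced_frac,
    soil_ratio_mean = soil_ratio_mean %||% defaults$soil_ratio_mean,
    wq_mean = wq_mean %||% defaults$wq_mean, wq_sd = wq_sd)
  rates <- unlist(prof[c("endemic_frac", "at_risk_frac", "introduced_frac")])
  if (any(rates < 0 | rates > 1)) {
    stop("flag fractions must lie in [0, 1]", call. = FALSE)
  }
  if (prof$soil_ratio_mean <= 0 || prof$soil_ratio_mean > 1) {
    stop("soil_ratio_mean must lie in (0, 1]", call. = FALSE)
  }
  structure(prof, class = "archetype_profile")
}

# normal truncated to [lo, hi] by inverse-CDF; degenerate sd gives the mean
rtruncnorm01 <- function(n, mean, sd, lo = 0, hi = 100) {
  if (sd == 0) return(pmin(pmax(rep_len(mean, n), lo), hi))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

TAXON_GROUPS <- c("birds", "bats", "rodents")

# undisturbed-reference soil values (units per property)
SOIL_REFERENCES <- tibble::tibble(
  property = c("texture_score", "organic_matter_pct", "no3_nh4_ratio",
               "total_organic_p", "total_organic_c"),
  reference = c(10, 8, 12, 650, 45),
  units = c("index", "%", "ratio", "mg/kg", "g/kg")
)

#' Simulate one farm's raw input bundle
#'
#' Generic indicator percents are drawn from a truncated normal around the
#' archetype's theme mean; species counts per taxon group follow a
#' Poisson richness / Poisson abundance / multinomial allocation, with
#' Bernoulli endemic, at-risk and introduced flags; soil measurements are
#' the reference values times Beta-distributed ratios; Welfare Quality
#' principle and criterion scores are truncated normal.
#'
#' @param profile An [archetype_profile()].
#' @param farm_id Farm identifier.
#' @param seed Integer seed; the same seed reproduces the bundle exactly.
#' @param framework A `safa_framework` (identifies the generic indicators
#'   and their themes).
#' @return A list: `farm_id`, `system_type`, `indicator_scores`,
#'   `captures`, `soil`, `wq`.
#' @export
simulate_farm <- function(profile, farm_id, seed,
                          framework = load_framework()) {
  stopifnot(inherits(profile, "archetype_profile"))
  set.seed(as.integer(seed) %% 2147483647L)

  ind <- framework$indicators
  generic <- ind[ind$indicator_type != "adapter", ]
  sub <- framework$subthemes
  theme_of <- sub$theme_id[match(generic$subtheme_id, sub$id)]
  mu <- profile$theme_means[theme_of]
  if (any(is.na(mu))) {
    stop("profile lacks theme mean(s) for: ",
         paste(unique(theme_of[is.na(mu)]), collapse = ", "), call. = FALSE)
  }
  n <- nrow(generic)
  indicator_scores <- tibble::tibble(
    indicator_id = generic$id,
    percent = rtruncnorm01(n, as.numeric(mu), profile$dispersion),
    timeframe = ifelse(runif(n) < 0.85, "current", "outdated"),
    data_type = c("primary", "secondary", "estimate")[
      1L + findInterval(runif(n), c(0.70, 0.90))],
    methodology = ifelse(runif(n) < 0.80, "safa_conform", "other"))

  caps <- list()
  for (g in TAXON_GROUPS) {
    r <- rpois(1, profile$richness)
    total <- rpois(1, profile$abundance)
    if (r == 0 || total == 0) next
    counts <- as.integer(rmultinom(1, total, rep(1 / r, r)))
    keep <- counts > 0
    if (!any(keep)) next
    nsp <- sum(keep)
    caps[[g]] <- tibble::tibble(
      farm_id = farm_id, taxon_group = g,
      species = sprintf("%s-sp-%02d", g, which(keep)),
      count = counts[keep],
      endemic = runif(nsp) < profile$endemic_frac,
      at_risk = runif(nsp) < profile$at_risk_frac,
      introduced = runif(nsp) < profile$introduced_frac)
  }
  captures <- if (length(caps) > 0) do.call(rbind, caps) else
    tibble::tibble(farm_id = character(0), taxon_group = character(0),
                   species = character(0), count = integer(0),
                   endemic = logical(0), at_risk = logical(0),
                   introduced = logical(0))

  conc <- 25  # Beta concentration: moderate farm-to-farm soil variation
  m <- profile$soil_ratio_mean
  ratios <- if (m >= 1) rep(1, nrow(SOIL_REFERENCES)) else
    rbeta(nrow(SOIL_REFERENCES), m * conc, (1 - m) * conc)
  soil <- tibble::tibble(
    farm_id = farm_id,
    property = SOIL_REFERENCES$property,
    measured = SOIL_REFERENCES$reference * ratios,
    reference = SOIL_REFERENCES$reference,
    units = SOIL_REFERENCES$units)

  wq_principles <- rtruncnorm01(4, profile$wq_mean, profile$wq_sd)
  wq_criteria <- rtruncnorm01(4, profile$wq_mean, profile$wq_sd)
  wq <- list(
    good_feeding = wq_principles[1], good_health = wq_principles[2],
    appropriate_behavior = wq_principles[3], overall = wq_principles[4],
    criterion_scores = setNames(
      wq_criteria, c("body_condition", "cleanliness", "lameness",
                     "avoidance_distance")))

  list(farm_id = farm_id, system_type = profile$system_type,
       indicator_scores = indicator_scores, captures = captures,
       soil = soil, wq = wq)
}

#' Simulate a multi-farm study
#'
#' Generates independent farm bundles for the three archetypes with
#' deterministic per-farm seeds derived from one root seed (counter-based,
#' so regenerating any single farm is stable). The default 3 + 3 + 3
#' layout mirrors a nine-farm study.
#'
#' @param n_ns,n_is,n_ms Farms per archetype (total >= 1).
#' @param seed Root integer seed.
#' @param profiles Optional named list of [archetype_profile()] overrides
#'   for `NS`, `IS`, `MS`.
#' @param framework A `safa_framework`.
#' @return A list of class `synthetic_study`: `seed`, `farms` (list of
#'   per-farm bundles).
#' @export
simulate_study <- function(n_ns = 3, n_is = 3, n_ms = 3, seed = 1,
                           profiles = NULL,
                           framework = load_framework()) {
  counts <- c(NS = n_ns, IS = n_is, MS = n_ms)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("at least one farm is required", call. = FALSE)
  }
  prefix <- c(NS = "NS", IS = "IS", MS = "M")
  farms <- list()
  k <- 0L
  for (st in names(counts)) {
    if (counts[[st]] == 0) next
    prof <- profiles[[st]] %||% archetype_profile(st)
    for (i in seq_len(counts[[st]])) {
      k <- k + 1L
      fid <- paste0(prefix[[st]], i)
      fseed <- (as.integer(seed) + 104729L * k) %% 2147483647L
      farms[[fid]] <- simulate_farm(prof, fid, fseed, framework)
    }
  }
  structure(list(seed = as.integer(seed), farms = farms),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study> seed ", x$seed, ", ", length(x$farms), " farms: ",
      paste(names(x$farms), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic study's raw input files
#'
#' Writes the four delimited input files (generic indicator scores,
#' captures, soil, Welfare Quality scores) plus a JSON manifest with the
#' seed, into a directory.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_fid <- function(get) {
    do.call(rbind, lapply(study$farms, function(f) {
      tb <- get(f)
      if (!"farm_id" %in% names(tb)) tb <- cbind(farm_id = f$farm_id, tb)
      tb
    }))
  }
  write.csv(with_fid(function(f) f$indicator_scores),
            file.path(dir, "indicator_scores.csv"), row.names = FALSE)
  write.csv(with_fid(function(f) f$captures),
            file.path(dir, "captures.csv"), row.names = FALSE)
  write.csv(with_fid(function(f) f$soil),
            file.path(dir, "soil.csv"), row.names = FALSE)
  wq_rows <- do.call(rbind, lapply(study$farms, function(f) {
    pr <- f$wq[c("good_feeding", "good_health", "appropriate_behavior",
                 "overall")]
    rbind(
      data.frame(farm_id = f$farm_id, score_name = names(pr),
                 score_type = "principle", value = as.numeric(pr)),
      if (!is.null(f$wq$criterion_scores)) {
        data.frame(farm_id = f$farm_id,
                   score_name = names(f$wq$criterion_scores),
                   score_type = "criterion",
                   value = as.numeric(f$wq$criterion_scores))
      })
  }))
  write.csv(wq_rows, file.path(dir, "wq_scores.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = study$seed, farms = names(study$farms)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a study back from its raw input files
#'
#' Inverse of [write_study_inputs()]: reassembles the per-farm bundles
#' from the four delimited files.
#'
#' @param dir Directory holding `indicator_scores.csv`, `captures.csv`,
#'   `soil.csv`, `wq_scores.csv`.
#' @return A list with a `farms` element usable by [assess_study()].
#' @export
read_study_inputs <- function(dir) {
  scores <- tibble::as_tibble(
    read.csv(file.path(dir, "indicator_scores.csv")))
  captures <- read_capture_table(file.path(dir, "captures.csv"))
  soil <- read_soil_table(file.path(dir, "soil.csv"))
  wq <- read_wq_table(file.path(dir, "wq_scores.csv"))
  ids <- unique(scores$farm_id)
  farms <- lapply(ids, function(fid) {
    list(farm_id = fid,
         indicator_scores = scores[scores$farm_id == fid,
                                   setdiff(names(scores), "farm_id")],
         captures = captures[captures$farm_id == fid, ],
         soil = soil[soil$farm_id == fid, ],
         wq = wq[[fid]])
  })
  names(farms) <- ids
  list(farms = farms)
}
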