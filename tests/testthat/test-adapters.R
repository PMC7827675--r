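test_that("shannon_index matches closed forms", {
  expect_equal(shannon_index(10), 0)
  expect_equal(shannon_index(c(5, 5)), log(2), tolerance = 1e-12)
  expect_equal(shannon_index(c(1, 1, 1, 1)), log(4), tolerance = 1e-12)
  for (n in 1:8) {
    expect_equal(shannon_index(rep(3, n)), log(n), tolerance = 1e-12)
  }
  expect_error(shannon_index(c(0, 0)), "positive")
  expect_error(shannon_index(numeric(0)))
})

test_that("shannon_index equals brute-force summation on small tables", {
  set.seed(42)
  for (i in 1:200) {
    counts <- sample(0:10, sample(1:5, 1), replace = TRUE)
    if (sum(counts) == 0) counts <- c(counts, 1)
    # independent oracle: explicit term-by-term accumulation
    pos <- counts[counts > 0]
    tot <- sum(pos)
    acc <- 0
    for (c in pos) acc <- acc - (c / tot) * log(c / tot)
    expect_equal(shannon_index(counts), acc, tolerance = 1e-12)
    # permutation and scale invariance
    perm <- counts[sample.int(length(counts))]
    expect_equal(shannon_index(perm), acc, tolerance = 1e-12)
    expect_equal(shannon_index(counts * 7), acc, tolerance = 1e-12)
  }
})

test_that("diversity_to_percent scales against the cohort maximum", {
  expect_equal(diversity_to_percent(1.2, 1.2), 100)
  expect_equal(diversity_to_percent(0, 1.2), 0)
  expect_equal(diversity_to_percent(log(2), log(4)), 50, tolerance = 1e-12)
  expect_error(diversity_to_percent(0.5, 0), "positive")
  expect_error(diversity_to_percent(1.5, 1.2), "cohort maximum")
})

test_that("genetic_diversity_rating normalises per group across the cohort", {
  caps <- rbind(
    capture_row("A", "birds", c("s1", "s2"), c(5, 5)),
    capture_row("B", "birds", c("s1", "s2", "s3", "s4"), c(1, 1, 1, 1)),
    capture_row("C", "birds", "s1", 0))
  res <- genetic_diversity_rating(caps)
  expect_equal(res$percent[res$farm_id == "B"], 100)
  expect_equal(res$percent[res$farm_id == "A"], 50, tolerance = 1e-12)
  expect_equal(res$percent[res$farm_id == "C"], 0)
  expect_equal(as.character(res$rating[res$farm_id == "B"]), "best")
  expect_equal(as.character(res$rating[res$farm_id == "C"]), "unacceptable")
  # exactly one farm attains 100 when the maximum is unique
  expect_equal(sum(res$percent == 100), 1)
})

test_that("taxon groups absent everywhere are skipped with a warning", {
  caps <- rbind(
    capture_row("A", "birds", "s1", 4),
    capture_row("A", "bats", "b1", 0),
    capture_row("B", "birds", c("s1", "s2"), c(2, 2)))
  expect_warning(res <- genetic_diversity_rating(caps), "bats")
  expect_equal(nrow(res), 2)
})

test_that("endemic species counts map to the five-step rating table", {
  expect_equal(as.character(endemic_count_to_rating(5)), "best")
  expect_equal(as.character(endemic_count_to_rating(4)), "good")
  expect_equal(as.character(endemic_count_to_rating(3)), "moderate")
  expect_equal(as.character(endemic_count_to_rating(2)), "limited")
  expect_equal(as.character(endemic_count_to_rating(1)), "unacceptable")
  # clamping outside 1..5, monotone overall
  expect_equal(as.character(endemic_count_to_rating(0)), "unacceptable")
  expect_equal(as.character(endemic_count_to_rating(7)), "best")
  ords <- as.integer(endemic_count_to_rating(0:10))
  expect_true(all(diff(ords) >= 0))
  expect_error(endemic_count_to_rating(-1), "non-negative")
})

test_that("key_species_score weights endemic/at-risk/introduced species", {
  w <- key_species_weights()
  expect_warning(
    expect_equal(key_species_score(capture_row("A", "birds",
                                               character(0), integer(0)), w),
                 0),
    "empty")
  all_good <- capture_row("A", "birds", c("s1", "s2"), c(3, 4),
                          endemic = TRUE, at_risk = TRUE)
  expect_equal(key_species_score(all_good, w), 100)
  mixed <- rbind(
    capture_row("A", "birds", "s1", 3, endemic = TRUE),
    capture_row("A", "birds", "s2", 2, introduced = TRUE))
  expect_equal(key_species_score(mixed, w), 25)
  # clamped to [0, 100] under any flags
  set.seed(7)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    tb <- capture_row("A", "birds", paste0("s", 1:n), sample(1:9, n, TRUE),
                      endemic = runif(n) < 0.5, at_risk = runif(n) < 0.5,
                      introduced = runif(n) < 0.5)
    s <- key_species_score(tb, w)
    expect_gte(s, 0)
    expect_lte(s, 100)
  }
})

test_that("soil indicators average capped measurement/reference ratios", {
  full <- tibble::tibble(
    farm_id = "A",
    property = c("texture_score", "organic_matter_pct", "no3_nh4_ratio",
                 "total_organic_p", "total_organic_c"),
    measured = c(10, 8, 12, 650, 45),
    reference = c(10, 8, 12, 650, 45))
  for (ind in c("soil-physical-structure", "soil-chemical-quality",
                "soil-biological-quality", "soil-organic-matter")) {
    expect_equal(soil_indicator_percent(full, ind), 100, info = ind)
  }
  half_c <- full
  half_c$measured[half_c$property == "total_organic_c"] <- 22.5
  expect_equal(soil_indicator_percent(half_c, "soil-organic-matter"), 50)
  over <- full
  over$measured <- over$measured * 1.5
  expect_equal(soil_indicator_percent(over, "soil-organic-matter"), 100)
  missing <- full[full$property != "total_organic_p", ]
  expect_error(soil_indicator_percent(missing, "soil-chemical-quality"),
               "total_organic_p")
})

test_that("Welfare Quality principles map directly to indicator percents", {
  wq <- list(good_feeding = 75, good_health = 80, appropriate_behavior = 65,
             overall = 100)
  s <- wq_to_indicator_scores(wq)
  expect_equal(s[["animal-health-practices"]], 75)
  expect_equal(as.character(percent_to_rating(s[["animal-health-practices"]])),
               "good")
  expect_equal(s[["animal-health"]], 80)
  expect_equal(s[["appropriate-animal-husbandry"]], 65)
  expect_equal(s[["freedom-of-stress"]], 100)
  # no criterion scores: handling practices fall back to the overall score
  expect_equal(s[["humane-animal-handling-practices"]], 100)

  wq$criterion_scores <- c(body_condition = 60, lameness = 80)
  expect_equal(wq_to_indicator_scores(wq)[["humane-animal-handling-practices"]],
               70)

  const <- list(good_feeding = 50, good_health = 50,
                appropriate_behavior = 50, overall = 50)
  s50 <- wq_to_indicator_scores(const)
  expect_true(all(s50 == 50))
  expect_true(all(percent_to_rating(as.numeric(s50)) == "moderate"))

  expect_error(wq_to_indicator_scores(list(good_feeding = 75)),
               "good_health")
})
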