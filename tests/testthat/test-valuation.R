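# The nine farms' printed valuation pairs, in published rank order.
table3 <- tibble::tibble(
  farm_id = c("Roble NS1", "Kampepem IS2", "Santa Teresa NS2", "Xhopel NS3",
              "UADY M2", "Kakalnah IS1", "Escalera M3", "Las Golondrinas IS3",
              "Ramonal M1"),
  positive_pct = c(67L, 62L, 57L, 48L, 48L, 48L, 33L, 33L, 24L),
  negative_pct = c(14L, 19L, 14L, 14L, 14L, 19L, 10L, 14L, 38L),
  positive_category = c("best", "best", "best", "good", "good", "good",
                        "moderate", "moderate", "limited"),
  negative_category = c("good", "moderate", "good", "good", "good",
                        "moderate", "good", "good", "unacceptable"))

test_that("round_percent rounds fractional parts above 0.5 up", {
  expect_equal(round_percent(13.4), 13L)
  expect_equal(round_percent(26.8), 27L)
  expect_equal(round_percent(9.52), 10L)
  expect_equal(round_percent(c(40.2, 53.6, 7.6, 15.2, 22.8, 30.4)),
               c(40L, 54L, 8L, 15L, 23L, 30L))
  expect_equal(round_percent(5.5), 5L)   # exactly .5 rounds down
  expect_equal(round_percent(5.0), 5L)
  expect_error(round_percent(-1), "non-negative")
})

test_that("round_percent is floor-or-ceiling and monotone", {
  set.seed(5)
  x <- sort(runif(500, 0, 100))
  r <- round_percent(x)
  expect_true(all(r == floor(x) | r == ceiling(x)))
  expect_true(all(diff(r) >= 0))
})

test_that("theme tallies count 21 themes", {
  a <- assess_farm(constant_farm(100), excluded_fw)
  tal <- theme_tally(a)
  expect_equal(sum(tal), 21)
  expect_equal(tal[["best"]], 21)
  mixed <- theme_tally(c(rep("best", 8), rep("good", 6), rep("moderate", 4),
                         rep("limited", 2), "unacceptable"))
  expect_equal(sum(mixed), 21)
  expect_error(theme_tally(character(0)))
})

test_that("valuation sums positive and negative counts then rounds once", {
  mk <- function(pos, neg, n = 21) {
    c(best = pos, good = 0L, moderate = n - pos - neg, limited = neg,
      unacceptable = 0L)
  }
  expect_equal(valuation(mk(14, 0))$positive_pct, 67L)
  expect_equal(valuation(mk(0, 8))$negative_pct, 38L)
  expect_equal(valuation(mk(0, 2))$negative_pct, 10L)
  expect_equal(valuation(mk(5, 5))$positive_pct, 24L)
  # all-moderate farms valuate to zero on both sides
  expect_equal(valuation(c(moderate = 21L)),
               list(positive_pct = 0L, negative_pct = 0L))
  # positive/negative/moderate partition the 21 themes
  for (pos in c(0, 7, 14, 21)) {
    for (neg in seq(0, 21 - pos, by = 3)) {
      tal <- mk(pos, neg)
      expect_equal(sum(tal), 21)
      v <- valuation(tal)
      expect_lte(v$positive_pct + v$negative_pct, 100)
    }
  }
})

test_that("band construction reproduces the published cut points", {
  pos <- build_bands(67, "positive")
  expect_equal(pos$label,
               c("unacceptable", "limited", "moderate", "good", "best"))
  expect_equal(pos$lower, c(0L, 14L, 28L, 41L, 55L))
  expect_equal(pos$upper, c(13L, 27L, 40L, 54L, 67L))

  neg <- build_bands(38, "negative")
  expect_equal(neg$label,
               c("best", "good", "moderate", "limited", "unacceptable"))
  expect_equal(neg$lower, c(0L, 9L, 16L, 24L, 31L))
  expect_equal(neg$upper, c(8L, 15L, 23L, 30L, 38L))

  even <- build_bands(100, "positive")
  expect_equal(even$upper, c(20L, 40L, 60L, 80L, 100L))
  expect_equal(even$lower, c(0L, 21L, 41L, 61L, 81L))

  expect_error(build_bands(0, "positive"), "positive number")
})

test_that("bands partition 0..max_value for every max in 1..100", {
  for (m in 1:100) {
    b <- build_bands(m, "positive")
    # intervals may be empty (lower > upper) when cut points coincide at
    # small maxima; the non-empty ones must tile 0..m without overlap
    keep <- b$lower <= b$upper
    covered <- unlist(Map(seq, b$lower[keep], b$upper[keep]))
    expect_equal(sort(covered), 0:m, info = paste("max =", m))
    expect_equal(b$upper[5], m)
    # and categorize resolves every value to exactly one level
    expect_false(any(is.na(categorize(0:m, b))))
  }
})

test_that("categorize picks the unique containing interval, monotonically", {
  pos <- build_bands(67, "positive")
  neg <- build_bands(38, "negative")
  expect_equal(as.character(categorize(62, pos)), "best")
  expect_equal(as.character(categorize(19, neg)), "moderate")
  expect_equal(as.character(categorize(0, pos)), "unacceptable")
  ords <- as.integer(categorize(0:67, pos))
  expect_true(all(diff(ords) >= 0))
  expect_error(categorize(68, pos), "range|0, 67")
})

test_that("rank_farms reproduces the published nine-farm ordering", {
  # shuffled input, keeping Xhopel before UADY (their valuations tie fully)
  shuffled <- table3[c(9, 4, 1, 7, 5, 2, 8, 3, 6),
                     c("farm_id", "positive_pct", "negative_pct")]
  stopifnot(which(shuffled$farm_id == "Xhopel NS3") <
              which(shuffled$farm_id == "UADY M2"))
  rk <- rank_farms(shuffled)
  expect_equal(rk$farm_id, table3$farm_id)
  expect_equal(rk$rank, 1:9)
  # tie on positive resolved by the lower negative share
  expect_lt(which(rk$farm_id == "Escalera M3"),
            which(rk$farm_id == "Las Golondrinas IS3"))
})

test_that("ranking is a stable permutation of its input", {
  single <- rank_farms(tibble::tibble(farm_id = "only", positive_pct = 30L,
                                      negative_pct = 5L))
  expect_equal(single$rank, 1L)
  set.seed(9)
  for (i in 1:50) {
    n <- sample(2:12, 1)
    v <- tibble::tibble(farm_id = paste0("f", 1:n),
                        positive_pct = sample(0:60, n, TRUE),
                        negative_pct = sample(0:40, n, TRUE))
    rk <- rank_farms(v)
    expect_setequal(rk$farm_id, v$farm_id)
    expect_true(all(diff(rk$positive_pct) <= 0))
    ties <- which(diff(rk$positive_pct) == 0)
    expect_true(all(diff(rk$negative_pct)[ties] >= 0))
    # full ties keep input order
    key <- paste(rk$positive_pct, rk$negative_pct)
    for (k in unique(key[duplicated(key)])) {
      grp <- rk$farm_id[key == k]
      expect_equal(grp, v$farm_id[v$farm_id %in% grp])
    }
  }
})

test_that("categorization of the published pairs matches the printed labels", {
  rk <- rank_farms(table3[, c("farm_id", "positive_pct", "negative_pct")])
  expect_equal(as.character(rk$positive_category), table3$positive_category)
  expect_equal(as.character(rk$negative_category), table3$negative_category)
})
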