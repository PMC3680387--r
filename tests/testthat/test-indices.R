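test_that("the prevalence score is the unweighted mean of its components", {
  expect_equal(compute_hhi_pd(40, 30, 50), 40)
  expect_equal(compute_hhi_pd(0, 0, 0), 0)
  expect_equal(compute_hhi_pd(100, 100, 100), 100)
  expect_true(is.na(compute_hhi_pd(40, NA, 50)))
  expect_error(compute_hhi_pd(140, 30, 50), "\\[0, 100\\]")
})

test_that("score bounds, monotonicity and symmetry hold over random triples", {
  set.seed(301)
  n <- 10000L
  s <- runif(n, 0, 100); a <- runif(n, 0, 100); v <- runif(n, 0, 100)
  sc <- compute_hhi_pd(s, a, v)
  expect_true(all(sc >= 0 & sc <= 100))
  eps <- runif(n, 1e-6, 5)
  bump <- pmin(s + eps, 100)
  expect_true(all(compute_hhi_pd(bump, a, v) >= sc))
  expect_true(all(compute_hhi_pd(bump, a, v)[bump > s] > sc[bump > s]))
  # equal weights: permutation invariance
  expect_equal(compute_hhi_pd(s, a, v), compute_hhi_pd(v, s, a))
  expect_equal(compute_hhi_pd(s, a, v), compute_hhi_pd(a, v, s))
})

test_that("severity categorization uses half-open bands at 20/35/45", {
  expect_identical(as.character(hhi_categorize(c(0, 19.9, 19.99))),
                   rep("mild", 3L))
  expect_identical(as.character(hhi_categorize(c(20, 34.9))),
                   rep("moderate", 2L))
  expect_identical(as.character(hhi_categorize(c(35, 44.9))),
                   rep("severe", 2L))
  expect_identical(as.character(hhi_categorize(c(45, 100))),
                   rep("alarmingly_high", 2L))
  expect_error(hhi_categorize(101), "\\[0, 100\\]")
  expect_error(hhi_categorize(-1), "\\[0, 100\\]")
})

test_that("category is non-decreasing in the score", {
  grid <- seq(0, 100, by = 0.1)
  cats <- hhi_categorize(grid)
  expect_true(all(diff(as.integer(cats)) >= 0))
})

test_that("burden indices sum iron, zinc and vitamin A and never iodine", {
  d <- make_dalys(iso3 = "Z01", iron = 1000, zinc = 2000, vita = 2870,
                  iodine = 500, total = 1e6, population = 1e5)
  expect_equal(compute_hhi_dba(d), 5870)
  d2 <- make_dalys(iso3 = "Z01", iron = 5, zinc = 5, vita = 5, iodine = 100,
                   total = 1e6, population = 1e5)
  expect_equal(compute_hhi_dba(d2), 15)
  expect_equal(compute_hhi_dba(make_dalys(iso3 = "Z01", iron = 0, zinc = 0,
                                          vita = 0, iodine = 0,
                                          total = 1, population = 1)), 0)
  # scale identity: at population 100,000 the two indices coincide
  expect_equal(compute_hhi_dbu(d2), compute_hhi_dba(d2))
  # absolute burden: rate 100 per 100,000 on a million people is 1,000
  d3 <- make_dalys(iso3 = "Z01", iron = 50, zinc = 30, vita = 20, iodine = 0,
                   total = 1e6, population = 1e6)
  expect_equal(compute_hhi_dbu(d3), 1000)
  # any missing component poisons the result
  d$daly_zinc <- NA
  expect_true(is.na(compute_hhi_dba(d)))
})

test_that("increasing any DALY component strictly increases the rate index", {
  set.seed(302)
  for (i in 1:50) {
    d <- make_dalys(iso3 = "Z01", iron = runif(1, 0, 3000),
                    zinc = runif(1, 0, 3000), vita = runif(1, 0, 3000),
                    iodine = 0, total = 1e6, population = 1e6)
    base <- compute_hhi_dba(d)
    col <- sample(c("daly_iron", "daly_zinc", "daly_vita"), 1L)
    d[[col]] <- d[[col]] + runif(1, 0.1, 100)
    expect_gt(compute_hhi_dba(d), base)
  }
})

test_that("ranking is descending with deterministic iso3 tie-breaks", {
  r <- data.frame(iso3 = c("AAA", "BBB", "CCC"),
                  hhi_pd = c(50, 30, 50), stringsAsFactors = FALSE)
  rk <- rank_countries(r, "hhi_pd")
  expect_identical(rk$iso3, c("AAA", "CCC", "BBB"))
  one <- rank_countries(data.frame(iso3 = "XYZ", hhi_pd = 10), "hhi_pd")
  expect_identical(one$iso3, "XYZ")
  r$hhi_pd[2L] <- NA
  rk2 <- rank_countries(r, "hhi_pd")
  expect_identical(attr(rk2, "omitted"), "BBB")
  expect_error(rank_countries(r, "not_a_key"))
})

test_that("top-20 ranking matches a brute-force full sort on the synthetic panel", {
  fx <- synthetic_appendix()
  h <- hhi(fx$countries, fx$dalys)
  rk <- rank_countries(h$results, "hhi_pd")
  # independent oracle: order() on the raw vector with the same tie rule
  v <- h$results$hhi_pd
  keep <- !is.na(v)
  oracle <- h$results$iso3[keep][order(-v[keep], h$results$iso3[keep])]
  expect_identical(rk$iso3[1:20], oracle[1:20])
  expect_identical(rk$iso3, oracle)
})

test_that("high-burden selection matches exhaustive prefix enumeration", {
  set.seed(303)
  n <- 10L
  x <- make_countries(n,
    stunting = runif(n, 5, 60),
    under5_population = round(runif(n, 1e5, 5e6)),
    population_2009 = 1e8)
  out <- select_high_burden(x, stunting_floor = 20, coverage = 0.9)
  # oracle: enumerate every prefix of the candidate list explicitly
  sc <- x$stunting / 100 * x$under5_population
  global <- sum(sc)
  cand <- order(-sc, x$iso3)
  cand <- cand[x$stunting[cand] >= 20]
  best <- NULL
  for (k in seq_along(cand)) {
    if (sum(sc[cand[seq_len(k)]]) >= 0.9 * global) { best <- k; break }
  }
  if (is.null(best)) best <- length(cand)
  expect_equal(nrow(out$selection), best)
  expect_identical(out$selection$iso3, x$iso3[cand[seq_len(best)]])
  expect_equal(out$achieved_coverage,
               sum(sc[cand[seq_len(best)]]) / global)
})

test_that("high-burden selection handles degenerate cases", {
  x <- make_countries(3L, stunting = c(5, 10, 15))
  out <- select_high_burden(x)
  expect_equal(nrow(out$selection), 0L)
  expect_equal(out$achieved_coverage, 0)
  y <- make_countries(3L, stunting = c(50, 10, 5),
                      under5_population = c(1e6, 0, 0))
  out2 <- select_high_burden(y)
  expect_equal(out2$selection$iso3, "Z01")
  expect_gte(out2$achieved_coverage, 0.9)
  z <- make_countries(2L, stunting = c(50, 40),
                      under5_population = c(1e6, NA))
  expect_warning(select_high_burden(z), "Z02")
})

test_that("percent of all-cause DALYs is the absolute burden share", {
  d <- make_dalys(iso3 = "Z01", iron = 50, zinc = 40, vita = 33, iodine = 0,
                  total = 1000, population = 1e5)
  expect_equal(percent_mnd_dalys(d), 12.3)
  d0 <- make_dalys(iso3 = "Z01", iron = 0, zinc = 0, vita = 0, iodine = 0,
                   total = 1000, population = 1e5)
  expect_equal(percent_mnd_dalys(d0), 0)
  dt <- make_dalys(iso3 = "Z01", iron = 500, zinc = 300, vita = 200,
                   iodine = 0, total = 1000, population = 1e5)
  expect_equal(percent_mnd_dalys(dt), 100)
  dt$total_all_cause_dalys <- NA
  expect_true(is.na(percent_mnd_dalys(dt)))
})

test_that("the hhi object carries consistent indices and methods work", {
  fx <- synthetic_appendix()
  h <- hhi(fx$countries, fx$dalys)
  r <- h$results
  both <- !is.na(r$hhi_dba) & !is.na(r$population_2009)
  expect_equal(r$hhi_dbu[both] / r$population_2009[both] * 1e5,
               r$hhi_dba[both])
  expect_true(all(na.omit(r$hhi_pd) >= 0 & na.omit(r$hhi_pd) <= 100))
  expect_identical(as.character(r$category[!is.na(r$hhi_pd)]),
                   as.character(hhi_categorize(r$hhi_pd[!is.na(r$hhi_pd)])))
  expect_s3_class(h, "hhi")
  expect_output(print(h), "Hidden hunger")
  expect_output(print(summary(h)), "Spearman")
  expect_identical(as.data.frame(h), r)
})
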