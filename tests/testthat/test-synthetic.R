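test_that("cohort specs validate their correlation matrix", {
  expect_s3_class(cohort_spec(), "hhi_cohort_spec")
  bad <- diag(4)
  bad[1, 2] <- bad[2, 1] <- 0.99
  bad[1, 3] <- bad[3, 1] <- 0.99
  bad[2, 3] <- bad[3, 2] <- -0.99
  expect_error(cohort_spec(latent_correlation = bad), "positive semi-definite")
  asym <- diag(4); asym[1, 2] <- 0.5
  expect_error(cohort_spec(latent_correlation = asym))
})

test_that("identical seeds reproduce identical cohorts, different seeds differ", {
  a <- generate_cohort(cohort_spec(n_countries = 149L, seed = 7L))
  b <- generate_cohort(cohort_spec(n_countries = 149L, seed = 7L))
  expect_identical(a$countries, b$countries)
  expect_identical(a$dalys, b$dalys)
  c <- generate_cohort(cohort_spec(n_countries = 149L, seed = 8L))
  expect_false(identical(a$countries$stunting, c$countries$stunting))
})

test_that("an identity copula yields near-zero pairwise correlations", {
  spec <- cohort_spec(n_countries = 2000L, latent_correlation = diag(4),
                      marginal_means = matrix(30, 6, 4,
                        dimnames = list(c("AFR", "AMR", "SEAR",
                                          "EUR", "EMR", "WPR"), NULL)),
                      missingness_rates = c(stunting = 0, anemia = 0, vad = 0,
                                            id = 0, hdi = 0, gdp = 0,
                                            under5 = 0, daly = 0),
                      seed = 5L)
  x <- generate_cohort(spec)$countries
  for (pair in list(c("stunting", "anemia"), c("stunting", "vad"),
                    c("stunting", "id"), c("anemia", "vad"),
                    c("anemia", "id"), c("vad", "id"))) {
    expect_lt(abs(spearman_rho(x[[pair[1]]], x[[pair[2]]])$rho), 0.05)
  }
})

test_that("sample rank correlations recover the copula targets within 0.05", {
  spec <- cohort_spec(n_countries = 2000L,
                      marginal_means = matrix(rep(c(30, 45, 25, 35), each = 6),
                        6, 4, dimnames = list(c("AFR", "AMR", "SEAR",
                                                "EUR", "EMR", "WPR"), NULL)),
                      missingness_rates = c(stunting = 0, anemia = 0, vad = 0,
                                            id = 0, hdi = 0, gdp = 0,
                                            under5 = 0, daly = 0),
                      seed = 11L)
  x <- generate_cohort(spec)$countries
  targets <- copula_rank_target(spec$latent_correlation)
  prs <- list(c("stunting", "anemia"), c("stunting", "vad"),
              c("anemia", "vad"), c("stunting", "id"), c("anemia", "id"),
              c("vad", "id"))
  for (pair in prs) {
    got <- spearman_rho(x[[pair[1]]], x[[pair[2]]])$rho
    expect_lt(abs(got - targets[pair[1], pair[2]]), 0.05)
  }
})

test_that("marginal means are recovered within sampling error", {
  spec <- cohort_spec(n_countries = 2000L,
                      missingness_rates = c(stunting = 0, anemia = 0, vad = 0,
                                            id = 0, hdi = 0, gdp = 0,
                                            under5 = 0, daly = 0),
                      seed = 13L)
  g <- generate_cohort(spec)
  x <- g$countries
  for (reg in c("AFR", "EUR")) {
    for (def in c("stunting", "anemia", "vad", "id")) {
      v <- x[[def]][x$who_region == reg]
      target <- spec$marginal_means[reg, def]
      sem <- spec$marginal_sds[[def]] / sqrt(length(v))
      # clamping pulls extreme-tail regions slightly inward; 3 sem + margin
      expect_lt(abs(mean(v) - target), 3 * sem + 0.8)
    }
  }
  expect_lt(g$truth$clamp_rate, 0.01)
})

test_that("the burden link induces a strong prevalence-burden rank correlation", {
  g <- generate_cohort(cohort_spec(n_countries = 2000L, seed = 17L))
  h <- hhi(g$countries, g$dalys)
  s <- summary(h)
  expect_gte(s$rho_pd_dba, 0.8)
  # and the development-index link is inverse
  r <- h$results
  expect_lt(index_vs_covariate(r, setNames(r$hdi_2007, r$iso3))$rho, -0.5)
})

test_that("generated cohorts pass harmonization without hard errors", {
  g <- generate_cohort(cohort_spec(n_countries = 300L, seed = 19L))
  expect_no_error(suppressWarnings(h <- hhi(g$countries, g$dalys)))
  parts <- suppressWarnings(apply_exclusions(g$countries))
  expect_equal(nrow(parts$included) + nrow(parts$excluded),
               nrow(g$countries))
  # some low-burden countries must cross the exclusion threshold by design
  expect_gt(nrow(parts$excluded), 0L)
})

test_that("the fixture suite is byte-identical under a fixed seed", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- make_fixture_suite(d1, seed = 7L)
  f2 <- make_fixture_suite(d2, seed = 7L)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]),
                     info = basename(f1[i]))
  }
})

test_that("fixture files parse back through the readers losslessly", {
  d <- withr::local_tempdir()
  make_fixture_suite(d, seed = 7L)
  w <- read_country_table(file.path(d, "worked10_countries.csv"))
  expect_identical(w$iso3, worked_example_countries()$iso3)
  expect_equal(w$stunting, worked_example_countries()$stunting)
  apx <- read_country_table(file.path(d, "synthetic_appendix_countries.csv"))
  expect_equal(nrow(apx), 190L)
  daly <- read_daly_table(file.path(d, "synthetic_appendix_dalys.csv"))
  expect_equal(nrow(daly), 136L)
  cohort <- read_country_table(file.path(d, "cohort_countries.csv"))
  expect_equal(nrow(cohort), 60L)
})

test_that("the worked ten-country table reproduces hand arithmetic exactly", {
  h <- hhi(worked_example_countries())
  r <- h$results
  # row 1: (40 + 0.6*30 + 50) / 3 ; row 2: (50 + 0.5*80 + 48) / 3
  expect_equal(r$hhi_pd[r$iso3 == "XAA"], (40 + 18 + 50) / 3)
  expect_equal(r$hhi_pd[r$iso3 == "XAB"], (50 + 40 + 48) / 3)
  expect_equal(r$hhi_pd[r$iso3 == "XAH"], (6 + 0.6 * 15 + 3) / 3)
  expect_identical(as.character(r$category[r$iso3 == "XAA"]), "severe")
  expect_identical(as.character(r$category[r$iso3 == "XAB"]),
                   "alarmingly_high")
  expect_identical(as.character(r$category[r$iso3 == "XAH"]), "mild")
})

test_that("edge-case table lands on the decided boundary rules", {
  e <- edge_case_countries()
  suppressWarnings(harm <- harmonize_countries(e))
  expect_true("XBB" %in% harm$excluded$iso3)   # development index exactly 0.9
  expect_true("XBA" %in% harm$excluded$iso3)   # no usable prevalence data
  inc <- harm$included
  expect_equal(inc$vad[inc$iso3 == "XBC"], 0)  # GDP exactly at the threshold
  expect_identical(inc$vad_prov[inc$iso3 == "XBC"], "assumed_zero")
  expect_true(all(is.na(inc$stunting[inc$iso3 %in% c("XBD", "XBE")])))
})
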