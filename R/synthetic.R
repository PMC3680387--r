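# Synthetic country-cohort generator: Gaussian copula over the four
# deficiency latents, clamped linear maps to regional prevalence marginals,
# log-normal populations, a linear DALY-rate link on the mean deficiency
# burden, and an inverse development-index link. Everything is driven by one
# seed so cohorts are reproducible.

.who_regions <- c("AFR", "AMR", "SEAR", "EUR", "EMR", "WPR")
.deficiencies <- c("stunting", "anemia", "vad", "id")

.default_corr <- function() {
  R <- matrix(0.6, 4, 4, dimnames = list(.deficiencies, .deficiencies))
  R[4, ] <- R[, 4] <- 0.05
  diag(R) <- 1
  R
}

.default_means <- function() {
  m <- rbind(
    AFR  = c(38, 60, 40, 40),
    AMR  = c(15, 25, 12, 20),
    SEAR = c(35, 55, 30, 30),
    EUR  = c(12, 20, 12, 44),
    EMR  = c(28, 45, 25, 47),
    WPR  = c(18, 30, 15, 25)
  )
  colnames(m) <- .deficiencies
  m
}

#' Specification of a synthetic country cohort
#'
#' Collects every parameter of the generator: cohort size, regional mix, the
#' latent correlation matrix of the four deficiencies (defaults: 0.6 among
#' stunting, anemia and vitamin A deficiency; 0.05 between iodine and the
#' rest, emulating deficiencies that co-occur except for iodine), per-region
#' prevalence marginals (percent), the linear DALY-rate link (DALYs per
#' 100,000 per percentage point of mean burden, plus Gaussian noise), the
#' inverse development-index link, the log-normal population law, per-field
#' missingness rates (completely at random), and the seed.
#'
#' @param n_countries Number of countries to generate.
#' @param region_weights Named proportions over the six WHO regions.
#' @param latent_correlation 4x4 correlation matrix over
#'   (stunting, anemia, vad, id) latents; must be symmetric with unit
#'   diagonal and positive semi-definite.
#' @param marginal_means 6x4 matrix (region x deficiency) of mean prevalences
#'   in percent.
#' @param marginal_sds Length-4 per-deficiency standard deviations (percent).
#' @param daly_link `c(slope, noise_sd)`: DALY rate = slope x mean burden +
#'   noise, truncated at zero.
#' @param hdi_link `c(intercept, slope, noise_sd)`: development index =
#'   intercept + slope x mean burden + noise, clamped to `[0.25, 0.98]`; the
#'   default slope is negative so low-burden countries cross the 0.9
#'   exclusion threshold.
#' @param population_log_mean,population_log_sd Log-normal population law.
#' @param missingness_rates Named per-field missingness proportions
#'   (`stunting`, `anemia`, `vad`, `id`, `hdi`, `gdp`, `under5`, `daly`).
#' @param seed Integer seed.
#' @return An object of class `"hhi_cohort_spec"`.
#' @export
cohort_spec <- function(n_countries = 190L,
                        region_weights = c(AFR = 0.24, AMR = 0.17,
                                           SEAR = 0.06, EUR = 0.27,
                                           EMR = 0.11, WPR = 0.15),
                        latent_correlation = .default_corr(),
                        marginal_means = .default_means(),
                        marginal_sds = c(stunting = 6, anemia = 10,
                                         vad = 6, id = 10),
                        daly_link = c(slope = 60, noise_sd = 300),
                        hdi_link = c(intercept = 1.00, slope = -0.009,
                                     noise_sd = 0.04),
                        population_log_mean = 16.1,
                        population_log_sd = 1.6,
                        missingness_rates = c(stunting = 0.05, anemia = 0.03,
                                              vad = 0.08, id = 0.35,
                                              hdi = 0.03, gdp = 0.05,
                                              under5 = 0.02, daly = 0.10),
                        seed = 1L) {
  stopifnot(
    n_countries >= 1,
    setequal(names(region_weights), .who_regions),
    all(region_weights >= 0), sum(region_weights) > 0,
    is.matrix(latent_correlation), all(dim(latent_correlation) == 4L),
    isTRUE(all.equal(latent_correlation, t(latent_correlation))),
    isTRUE(all.equal(unname(diag(latent_correlation)), rep(1, 4))),
    is.matrix(marginal_means), nrow(marginal_means) == 6L,
    ncol(marginal_means) == 4L,
    length(marginal_sds) == 4L, all(marginal_sds >= 0),
    all(missingness_rates >= 0 & missingness_rates <= 1)
  )
  if (min(eigen(latent_correlation, symmetric = TRUE,
                only.values = TRUE)$values) < -1e-8) {
    stop("latent_correlation must be positive semi-definite")
  }
  marginal_means <- marginal_means[.who_regions, , drop = FALSE]
  colnames(marginal_means) <- .deficiencies
  names(marginal_sds) <- .deficiencies
  dimnames(latent_correlation) <- list(.deficiencies, .deficiencies)
  structure(
    list(n_countries = as.integer(n_countries),
         region_weights = region_weights[.who_regions] /
           sum(region_weights),
         latent_correlation = latent_correlation,
         marginal_means = marginal_means,
         marginal_sds = marginal_sds,
         daly_link = daly_link, hdi_link = hdi_link,
         population_log_mean = population_log_mean,
         population_log_sd = population_log_sd,
         missingness_rates = missingness_rates,
         seed = as.integer(seed)),
    class = "hhi_cohort_spec"
  )
}

# synthetic ISO3-style codes: XAA, XAB, ... then YAA... (never real codes)
.synth_iso3 <- function(n) {
  stopifnot(n <= 26^3)
  i <- seq_len(n) - 1L
  paste0(LETTERS[24L - (i %/% 676L) %% 3L],  # X, W, V blocks
         LETTERS[(i %/% 26L) %% 26L + 1L],
         LETTERS[i %% 26L + 1L])
}

#' Rank-correlation target induced by a Gaussian copula
#'
#' For bivariate Gaussian latents with Pearson correlation `r`, the
#' population Spearman correlation of any monotone transforms is
#' `(6 / pi) * asin(r / 2)`. Generated prevalences are (near-)monotone maps
#' of the latents, so this is the recovery target for sample rank
#' correlations on large cohorts.
#'
#' @param r Latent Pearson correlation(s) in `[-1, 1]`.
#' @return Spearman correlation target(s).
#' @export
copula_rank_target <- function(r) (6 / pi) * asin(r / 2)

#' Generate a synthetic country cohort
#'
#' Draws correlated latent normals per country through the specification's
#' Gaussian copula, maps them to regional prevalence marginals (clamped to
#' `[0, 100]`; clamping events are counted and are rare at default settings),
#' assigns log-normal populations, builds DALY rates from the linear burden
#' link (iodine-attributed DALYs are generated independently), builds the
#' development index from the inverse link so that a fraction of low-burden
#' countries crosses the exclusion threshold, and applies completely-at-random
#' missingness. The same specification and seed always reproduce the same
#' tables.
#'
#' @param spec An [cohort_spec()].
#' @return A list with `countries` (country table), `dalys` (DALY table for
#'   the countries with burden data), and `truth` (generating latents, links,
#'   burdens and the clamping rate, for recovery tests).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "hhi_cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_countries
  iso3 <- .synth_iso3(n)
  region <- sample(.who_regions, n, replace = TRUE,
                   prob = spec$region_weights)
  z <- matrix(stats::rnorm(n * 4L), n, 4L) %*%
    chol(spec$latent_correlation)
  colnames(z) <- .deficiencies
  mu <- spec$marginal_means[region, , drop = FALSE]
  raw <- mu + sweep(z, 2L, spec$marginal_sds, `*`)
  prev <- pmin(pmax(raw, 0), 100)
  clamp_rate <- mean(raw < 0 | raw > 100)

  malaria_prob <- c(AFR = 0.85, AMR = 0.15, SEAR = 0.60, EUR = 0.02,
                    EMR = 0.30, WPR = 0.25)
  malaria <- stats::runif(n) < malaria_prob[region]
  ida <- prev[, "anemia"] * ifelse(malaria, 0.5, 0.6)
  burden <- (prev[, "stunting"] + ida + prev[, "vad"]) / 3

  hl <- spec$hdi_link
  hdi <- pmin(pmax(hl[["intercept"]] + hl[["slope"]] * burden +
                     stats::rnorm(n, 0, hl[["noise_sd"]]), 0.25), 0.98)
  lei <- pmin(pmax(hdi + stats::rnorm(n, 0, 0.02), 0.2), 1)
  gdp <- round(48000 * hdi^4 * exp(stats::rnorm(n, 0, 0.2)))
  pop <- round(stats::rlnorm(n, spec$population_log_mean,
                             spec$population_log_sd))
  pop <- pmax(pop, 1e4)
  u5frac <- pmin(pmax(0.05 + 0.0018 * burden +
                        stats::rnorm(n, 0, 0.01), 0.03), 0.20)
  under5 <- round(pop * u5frac)

  dl <- spec$daly_link
  rate <- pmax(dl[["slope"]] * burden + stats::rnorm(n, 0, dl[["noise_sd"]]), 0)
  w <- abs(matrix(stats::rnorm(n * 3L, rep(c(0.35, 0.35, 0.30), each = n),
                               0.05), n, 3L))
  w <- w / rowSums(w)
  iodine_rate <- pmax(stats::rnorm(n, 40, 30), 0)
  pct <- pmin(pmax(1 + 0.15 * burden + stats::rnorm(n, 0, 1), 0.3), 13)
  total <- round(rate * pop / 1e5 * 100 / pct)

  mr <- spec$missingness_rates
  drop_field <- function(x, field) {
    x[stats::runif(n) < mr[[field]]] <- NA
    x
  }
  stunting <- drop_field(prev[, "stunting"], "stunting")
  anemia <- drop_field(prev[, "anemia"], "anemia")
  vad <- drop_field(prev[, "vad"], "vad")
  idv <- drop_field(prev[, "id"], "id")
  hdi_o <- drop_field(hdi, "hdi")
  gdp_o <- drop_field(gdp, "gdp")
  under5_o <- drop_field(under5, "under5")
  prov <- function(x, base) ifelse(is.na(x), "missing", base)
  reg_prov <- function(x) ifelse(is.na(x), "missing",
                                 ifelse(stats::runif(n) < 0.25,
                                        "who_regression", "national_survey"))

  countries <- data.frame(
    iso3 = iso3, name = paste("Country", iso3), who_region = region,
    ssa_member = region == "AFR",
    hdi_2007 = hdi_o, lei_2007 = lei, gdp_2005 = gdp_o,
    population_2009 = pop, under5_population = under5_o,
    malaria_endemic = malaria,
    stunting = stunting, stunting_prov = prov(stunting, "national_survey"),
    anemia = anemia, anemia_prov = reg_prov(anemia),
    vad = vad, vad_prov = reg_prov(vad),
    id = idv, id_prov = prov(idv, "national_survey"),
    stringsAsFactors = FALSE
  )
  keep_daly <- stats::runif(n) >= mr[["daly"]]
  dalys <- data.frame(
    iso3 = iso3,
    daly_iron = rate * w[, 1L], daly_zinc = rate * w[, 2L],
    daly_vita = rate * w[, 3L],
    daly_iodine = iodine_rate,
    total_all_cause_dalys = total,
    population = pop,
    stringsAsFactors = FALSE
  )[keep_daly, , drop = FALSE]
  rownames(dalys) <- NULL

  truth <- list(
    latent = z, burden = burden, region = region, malaria = malaria,
    clamp_rate = clamp_rate,
    latent_correlation = spec$latent_correlation,
    rank_targets = copula_rank_target(spec$latent_correlation),
    daly_link = spec$daly_link, hdi_link = spec$hdi_link
  )
  list(countries = countries, dalys = dalys, truth = truth)
}

#' Write the seed-fixed fixture suite
#'
#' Writes small, reproducible fixture files: a ten-country worked table with
#' hand-checkable index arithmetic, the synthetic study tables from
#' [synthetic_appendix()] (149 scoreable countries; 136-country burden
#' table), an edge-case table (a country with every prevalence missing, a
#' development index exactly at the exclusion threshold, a GDP exactly at the
#' vitamin-A threshold with missing prevalence, and a region with no stunting
#' donors), plus a JSON sidecar recording the seed and the generating truth
#' of a generated cohort. Identical seeds give byte-identical files.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the generated-cohort member of the suite.
#' @return Character vector of the files written, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 7L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  w <- worked_example_countries()
  p <- file.path(out_dir, "worked10_countries.csv")
  write_country_table(w, p); paths <- c(paths, p)

  apx <- synthetic_appendix(out_dir)
  paths <- c(paths, file.path(out_dir, c("synthetic_appendix_countries.csv",
                                         "synthetic_appendix_dalys.csv")))

  e <- edge_case_countries()
  p <- file.path(out_dir, "edge_cases_countries.csv")
  write_country_table(e, p); paths <- c(paths, p)

  cohort <- generate_cohort(cohort_spec(n_countries = 60L, seed = seed))
  p <- file.path(out_dir, "cohort_countries.csv")
  write_country_table(cohort$countries, p); paths <- c(paths, p)
  p <- file.path(out_dir, "cohort_dalys.csv")
  write_daly_table(cohort$dalys, p); paths <- c(paths, p)

  p <- file.path(out_dir, "truth.json")
  jsonlite::write_json(
    list(seed = seed,
         clamp_rate = cohort$truth$clamp_rate,
         rank_targets = cohort$truth$rank_targets,
         daly_link = as.list(cohort$truth$daly_link),
         hdi_link = as.list(cohort$truth$hdi_link)),
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}

#' Ten-country worked table
#'
#' A fully observed ten-country table with round numbers, so every index can
#' be checked by hand (e.g. the first row: stunting 40, anemia 30 in a
#' non-malaria setting giving an iron-deficiency-anemia prevalence of 18,
#' vitamin A deficiency 50, hence a score of (40 + 18 + 50) / 3 = 36).
#'
#' @return A country table of ten synthetic countries.
#' @export
worked_example_countries <- function() {
  data.frame(
    iso3 = c("XAA", "XAB", "XAC", "XAD", "XAE",
             "XAF", "XAG", "XAH", "XAI", "XAJ"),
    name = paste("Workedland", 1:10),
    who_region = c("AFR", "AFR", "AFR", "SEAR", "SEAR",
                   "AMR", "AMR", "EUR", "EMR", "WPR"),
    ssa_member = c(TRUE, TRUE, TRUE, FALSE, FALSE,
                   FALSE, FALSE, FALSE, FALSE, FALSE),
    hdi_2007 = c(0.45, 0.50, 0.55, 0.60, 0.62,
                 0.70, 0.75, 0.85, 0.65, 0.80),
    lei_2007 = c(0.50, 0.55, 0.60, 0.65, 0.67,
                 0.75, 0.80, 0.88, 0.70, 0.85),
    gdp_2005 = c(800, 1000, 1500, 2000, 2200,
                 6000, 8000, 12000, 3000, 9000),
    population_2009 = c(2e7, 1e7, 5e6, 5e7, 8e7,
                        3e7, 1e7, 8e6, 2e7, 4e7),
    under5_population = c(3.4e6, 1.6e6, 8e5, 7e6, 1.04e7,
                          3e6, 9e5, 4e5, 2.2e6, 3.2e6),
    malaria_endemic = c(FALSE, TRUE, TRUE, FALSE, TRUE,
                        FALSE, FALSE, FALSE, FALSE, FALSE),
    stunting = c(40, 50, 45, 48, 36, 24, 15, 6, 30, 21),
    stunting_prov = "national_survey",
    anemia = c(30, 80, 70, 60, 64, 40, 25, 15, 50, 35),
    anemia_prov = "national_survey",
    vad = c(50, 48, 38, 31, 28, 14, 8, 3, 26, 10),
    vad_prov = "national_survey",
    id = c(10, 12, 35, 20, 18, 22, 40, 55, 46, 25),
    id_prov = "national_survey",
    stringsAsFactors = FALSE
  )
}

#' Edge-case table
#'
#' Five countries exercising the decided boundary rules: all prevalences
#' missing (excluded for lack of data), a development index of exactly 0.9
#' (excluded: the inclusion rule is strictly below the threshold), a GDP of
#' exactly US$ 15,000 with missing vitamin A data (assumption applies: the
#' threshold is closed), a WPR pair forming a region with no stunting donor.
#'
#' @return A country table of five synthetic countries.
#' @export
edge_case_countries <- function() {
  data.frame(
    iso3 = c("XBA", "XBB", "XBC", "XBD", "XBE"),
    name = paste("Edgeland", 1:5),
    who_region = c("AFR", "EUR", "AMR", "WPR", "WPR"),
    ssa_member = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    hdi_2007 = c(0.5, 0.9, 0.7, 0.6, 0.65),
    lei_2007 = c(0.55, 0.91, 0.75, 0.65, 0.7),
    gdp_2005 = c(900, 30000, 15000, 2000, 2500),
    population_2009 = c(1e7, 5e6, 2e7, 3e6, 4e6),
    under5_population = c(1.7e6, 2.5e5, 2e6, 3e5, 4e5),
    malaria_endemic = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    stunting = c(NA, 4, 20, NA, NA),
    stunting_prov = c("missing", "national_survey",
                      "national_survey", "missing", "missing"),
    anemia = c(NA, 10, 30, 25, 28),
    anemia_prov = c("missing", "national_survey", "national_survey",
                    "national_survey", "national_survey"),
    vad = c(NA, 2, NA, 12, 14),
    vad_prov = c("missing", "national_survey", "missing",
                 "national_survey", "national_survey"),
    id = c(NA, 30, 15, NA, 20),
    id_prov = c("missing", "national_survey", "national_survey",
                "missing", "national_survey"),
    stringsAsFactors = FALSE
  )
}
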