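# in-code fixture builders and independent oracles shared across tests

# minimal valid country table; override any column via ...
make_countries <- function(n = 3L, ...) {
  base <- data.frame(
    iso3 = sprintf("Z%02d", seq_len(n)),
    name = paste("Testland", seq_len(n)),
    who_region = rep_len(c("AFR", "SEAR", "EUR"), n),
    ssa_member = rep_len(c(TRUE, FALSE, FALSE), n),
    hdi_2007 = rep_len(c(0.5, 0.6, 0.8), n),
    lei_2007 = rep_len(c(0.55, 0.65, 0.85), n),
    gdp_2005 = rep_len(c(1000, 2000, 9000), n),
    population_2009 = rep_len(c(1e7, 2e7, 5e6), n),
    under5_population = rep_len(c(1.5e6, 2.5e6, 3e5), n),
    malaria_endemic = rep_len(c(TRUE, FALSE, FALSE), n),
    stunting = rep_len(c(40, 30, 10), n),
    stunting_prov = "national_survey",
    anemia = rep_len(c(60, 50, 20), n),
    anemia_prov = "national_survey",
    vad = rep_len(c(35, 25, 5), n),
    vad_prov = "national_survey",
    id = rep_len(c(20, 30, 40), n),
    id_prov = "national_survey",
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

make_dalys <- function(iso3 = c("Z01", "Z02"),
                       iron = c(1000, 100), zinc = c(800, 80),
                       vita = c(700, 70), iodine = c(50, 5),
                       total = c(5e6, 4e6), population = c(1e7, 2e7)) {
  data.frame(iso3 = iso3, daly_iron = iron, daly_zinc = zinc,
             daly_vita = vita, daly_iodine = iodine,
             total_all_cause_dalys = total, population = population,
             stringsAsFactors = FALSE)
}

# independent Spearman oracle: explicit average ranks, explicit Pearson
oracle_spearman <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
    }
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}
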