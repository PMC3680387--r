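test_that("choropleth fills match result categories and logs unmatched codes", {
  d <- withr::local_tempdir()
  gj <- file.path(d, "world.geojson")
  toy_world_geojson(gj, iso3 = c("XAA", "XAB", "XAC", "XAD", "XAE", "XAF"))
  h <- hhi(worked_example_countries())
  out <- file.path(d, "map.png")
  log <- render_choropleth(h$results, gj, out, excluded = h$excluded)
  expect_true(file.exists(out) && file.size(out) > 0)
  # 6 polygons drawn; countries beyond the toy world are logged
  expect_setequal(log$unmatched,
                  setdiff(h$results$iso3, c("XAA", "XAB", "XAC",
                                            "XAD", "XAE", "XAF")))
  expect_equal(log$matched, 6L)
  # per-class polygon counts equal per-class result counts for mapped codes
  mapped <- h$results[h$results$iso3 %in% sprintf("XA%s", LETTERS[1:6]), ]
  sty <- map_style()
  want <- table(sty$category_palette[as.integer(mapped$category)])
  got <- log$fill_counts[names(want)]
  expect_equal(as.integer(got), as.integer(want))
})

test_that("excluded countries take the excluded class and joins can fail hard", {
  d <- withr::local_tempdir()
  gj <- file.path(d, "world.geojson")
  toy_world_geojson(gj, iso3 = c("XBA", "XBB", "XBC", "XBD", "XBE", "ZZZ"))
  suppressWarnings(h <- hhi(edge_case_countries()))
  log <- render_choropleth(h$results, gj, file.path(d, "map.png"),
                           excluded = h$excluded)
  sty <- map_style()
  # two excluded countries (XBA, XBB) are on the map in the excluded colour
  expect_gte(log$fill_counts[[sty$excluded_col]], 2L)
  # zero joins is a hard error
  toy_world_geojson(gj, iso3 = sprintf("Q%02d", 1:6))
  expect_error(render_choropleth(h$results, gj, file.path(d, "m2.png")),
               "matches")
})

test_that("continuous burden maps render with a ramp", {
  d <- withr::local_tempdir()
  gj <- file.path(d, "world.geojson")
  toy_world_geojson(gj)
  fx <- synthetic_appendix()
  h <- hhi(worked_example_countries(),
           make_dalys(iso3 = c("XAA", "XAB"), iron = c(100, 10),
                      zinc = c(90, 9), vita = c(80, 8), iodine = c(0, 0),
                      total = c(1e6, 1e6), population = c(2e7, 1e7)))
  out <- file.path(d, "dba.svg")
  log <- render_choropleth(h$results, gj, out, value_key = "hhi_dba")
  expect_true(file.exists(out) && file.size(out) > 0)
  expect_equal(log$matched, 6L)
})

test_that("letter scatter omits and logs exactly the join misses", {
  d <- withr::local_tempdir()
  h <- hhi(worked_example_countries())
  r <- h$results
  cov <- setNames(r$hdi_2007, r$iso3)[1:7]  # three countries lack the covariate
  out <- file.path(d, "scatter.png")
  log <- render_letter_scatter(r, cov, out, xlab = "development index")
  expect_true(file.exists(out) && file.size(out) > 0)
  expect_setequal(log$omitted, r$iso3[8:10])
  expect_equal(log$n, 7L)
  # a single-country plot draws one glyph without error
  one <- render_letter_scatter(r[1, ], setNames(r$hdi_2007[1], r$iso3[1]),
                               file.path(d, "one.png"))
  expect_equal(length(one$omitted), 0L)
})

test_that("glyph size follows the area-proportional scaling law", {
  # the drawing core maps population to cex via sqrt(pop/max), so a 100x
  # population ratio gives a 10x difference on the sqrt scale
  r <- worked_example_countries()
  r$hhi_pd <- c(36, 44, 10, 20, 30, 15, 12, 6, 25, 18)
  s <- sqrt(r$population_2009 / max(r$population_2009))
  cex <- 0.5 + (3 - 0.5) * s
  i <- which.max(r$population_2009)
  j <- which.min(r$population_2009)
  expect_equal((cex[i] - 0.5) / (cex[j] - 0.5),
               sqrt(r$population_2009[i] / r$population_2009[j]))
})

test_that("plot.hhi draws on the current device and reports rho", {
  fx <- synthetic_appendix()
  h <- hhi(fx$countries, fx$dalys)
  p <- withr::local_tempfile(fileext = ".png")
  grDevices::png(p)
  log <- plot(h, covariate = "hdi_2007")
  grDevices::dev.off()
  expect_lt(log$rho, -0.9)
})

test_that("the cli subcommands run end to end and report failures", {
  d <- withr::local_tempdir()
  # simulate twice with the same seed: identical outputs
  o1 <- file.path(d, "run1"); o2 <- file.path(d, "run2")
  expect_equal(hhi_cli(c("simulate", "--seed", "7", "--n", "40",
                         "--out-dir", o1)), 0L)
  expect_equal(hhi_cli(c("simulate", "--seed", "7", "--n", "40",
                         "--out-dir", o2)), 0L)
  expect_identical(readLines(file.path(o1, "cohort_countries.csv")),
                   readLines(file.path(o2, "cohort_countries.csv")))
  # index without a DALY table still succeeds; burden columns stay empty
  o3 <- file.path(d, "run3")
  expect_equal(hhi_cli(c("index", "--countries",
                         file.path(o1, "cohort_countries.csv"),
                         "--out-dir", o3)), 0L)
  ranked <- read.csv(file.path(o3, "index_ranked.csv"))
  expect_true(all(is.na(ranked$hhi_dba)))
  log <- jsonlite::read_json(file.path(o3, "run_log.json"))
  expect_equal(log$n_daly, 0L)
  # report-all produces map, scatters and tables
  gj <- file.path(d, "world.geojson")
  toy_world_geojson(gj, iso3 = ranked$iso3[1:6])
  o4 <- file.path(d, "run4")
  expect_equal(hhi_cli(c("report-all", "--countries",
                         file.path(o1, "cohort_countries.csv"),
                         "--dalys", file.path(o1, "cohort_dalys.csv"),
                         "--boundaries", gj, "--out-dir", o4)), 0L)
  for (f in c("index_ranked.csv", "exclusions.csv", "correlations.csv",
              "map_hhi_pd.png", "scatter_hdi.png", "scatter_dba.png",
              "run_log.json")) {
    expect_true(file.exists(file.path(o4, f)), info = f)
  }
  # unknown subcommand: usage and non-zero status
  expect_message(st <- hhi_cli("frobnicate"), "usage")
  expect_equal(st, 2L)
  # hard error inside a subcommand: non-zero status, not an R error
  expect_message(st2 <- hhi_cli(c("index", "--countries", "no_such_file.csv",
                                  "--out-dir", d)), "error")
  expect_equal(st2, 1L)
})

test_that("cli honours a YAML config for policy and scale", {
  d <- withr::local_tempdir()
  cfg <- file.path(d, "config.yaml")
  writeLines(c("seed: 3",
               "policy:",
               "  ida_fraction_nonmalaria: 0.8",
               "  ida_fraction_malaria: 0.8",
               "scale:",
               "  boundaries: [10, 30, 60]"), cfg)
  x <- make_countries(3L, malaria_endemic = FALSE)
  p <- file.path(d, "countries.csv")
  write_country_table(x, p)
  o <- file.path(d, "out")
  expect_equal(hhi_cli(c("index", "--countries", p, "--config", cfg,
                         "--out-dir", o)), 0L)
  ranked <- read.csv(file.path(o, "index_ranked.csv"))
  i <- match("Z01", ranked$iso3)
  expect_equal(ranked$hhi_pd[i], (40 + 0.8 * 60 + 35) / 3)
})
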