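#' Harmonization and conversion policy
#'
#' Bundles the fixed assumptions used to turn raw country indicator tables
#' into analysis-ready records: the fraction of anemia attributed to iron
#' deficiency in non-malaria-endemic (0.60) and malaria-endemic (0.50)
#' settings, the 2005 GDP per capita threshold (US$ 15,000) above which a
#' country with no serum retinol data is assumed free of vitamin A deficiency,
#' and the development-index score (0.9) at or above which a country is
#' excluded from index construction.
#'
#' @param ida_fraction_nonmalaria Proportion of anemia attributed to iron
#'   deficiency where malaria is not endemic.
#' @param ida_fraction_malaria Proportion where malaria is endemic.
#' @param vad_free_gdp_threshold GDP per capita (US$) at or above which missing
#'   vitamin A deficiency is assumed to be zero.
#' @param hdi_exclusion_threshold Development-index score at or above which a
#'   country is excluded.
#' @return An object of class `"hhi_policy"`.
#' @export
hhi_policy <- function(ida_fraction_nonmalaria = 0.60,
                       ida_fraction_malaria = 0.50,
                       vad_free_gdp_threshold = 15000,
                       hdi_exclusion_threshold = 0.9) {
  stopifnot(
    is.numeric(ida_fraction_nonmalaria), length(ida_fraction_nonmalaria) == 1L,
    ida_fraction_nonmalaria >= 0, ida_fraction_nonmalaria <= 1,
    is.numeric(ida_fraction_malaria), length(ida_fraction_malaria) == 1L,
    ida_fraction_malaria >= 0, ida_fraction_malaria <= 1,
    is.numeric(vad_free_gdp_threshold), vad_free_gdp_threshold > 0,
    is.numeric(hdi_exclusion_threshold), hdi_exclusion_threshold > 0
  )
  structure(
    list(
      ida_fraction_nonmalaria = ida_fraction_nonmalaria,
      ida_fraction_malaria = ida_fraction_malaria,
      vad_free_gdp_threshold = vad_free_gdp_threshold,
      hdi_exclusion_threshold = hdi_exclusion_threshold
    ),
    class = "hhi_policy"
  )
}

#' @export
print.hhi_policy <- function(x, ...) {
  cat("Hidden hunger harmonization policy\n")
  cat(sprintf("  anemia -> IDA fraction: %.2f (non-malaria), %.2f (malaria-endemic)\n",
              x$ida_fraction_nonmalaria, x$ida_fraction_malaria))
  cat(sprintf("  VAD assumed zero at GDP >= US$ %s\n",
              format(x$vad_free_gdp_threshold, big.mark = ",")))
  cat(sprintf("  development-index exclusion at score >= %.2f\n",
              x$hdi_exclusion_threshold))
  invisible(x)
}

#' Convert anemia prevalence to iron deficiency anemia
#'
#' Applies the fixed attribution fractions: 60% of anemia is attributed to
#' iron deficiency where malaria is not endemic and 50% where it is. Missing
#' anemia stays missing; no default is substituted.
#'
#' @param anemia_prev Numeric vector of anemia prevalences on the 0-100 scale.
#' @param malaria_endemic Logical vector (recycled to length of `anemia_prev`).
#' @param policy An [hhi_policy()].
#' @return Numeric vector of iron-deficiency-anemia prevalences (0-100).
#' @examples
#' convert_anemia_to_ida(100, FALSE) # 60
#' convert_anemia_to_ida(100, TRUE)  # 50
#' @export
convert_anemia_to_ida <- function(anemia_prev, malaria_endemic,
                                  policy = hhi_policy()) {
  stopifnot(inherits(policy, "hhi_policy"), is.logical(malaria_endemic))
  ok <- !is.na(anemia_prev)
  if (any(anemia_prev[ok] < 0 | anemia_prev[ok] > 100)) {
    stop("anemia prevalence must lie in [0, 100]")
  }
  n <- max(length(anemia_prev), length(malaria_endemic))
  anemia_prev <- rep_len(anemia_prev, n)
  malaria_endemic <- rep_len(malaria_endemic, n)
  frac <- ifelse(isTRUE_vec(malaria_endemic),
                 policy$ida_fraction_malaria,
                 policy$ida_fraction_nonmalaria)
  anemia_prev * frac
}

# missing malaria flag is treated as non-endemic (the conservative 0.60)
isTRUE_vec <- function(x) !is.na(x) & x

#' Apply development-score and data-availability exclusions
#'
#' A country is excluded when its effective development score (the
#' development index, or the life-expectancy-index substitute when the former
#' is missing) is at or above the threshold, or when it has neither vitamin A
#' deficiency nor anemia data. Countries with no development score at all are
#' excluded with a warning rather than an error.
#'
#' @param countries Country table (see [read_country_table()]).
#' @param policy An [hhi_policy()].
#' @return A list with components `included` (country table) and `excluded`
#'   (country table with an extra `reason` column; one of
#'   `"hdi_at_or_above_threshold"`, `"lei_at_or_above_threshold"`,
#'   `"no_prevalence_data"`, `"no_development_score"`).
#' @export
apply_exclusions <- function(countries, policy = hhi_policy()) {
  stopifnot(inherits(policy, "hhi_policy"))
  thr <- policy$hdi_exclusion_threshold
  hdi <- countries$hdi_2007
  lei <- countries$lei_2007
  eff <- ifelse(is.na(hdi), lei, hdi)
  via_lei <- is.na(hdi) & !is.na(lei)

  reason <- rep(NA_character_, nrow(countries))
  no_score <- is.na(eff)
  reason[no_score] <- "no_development_score"
  hi <- !no_score & eff >= thr
  reason[hi & !via_lei] <- "hdi_at_or_above_threshold"
  reason[hi & via_lei] <- "lei_at_or_above_threshold"
  no_data <- is.na(countries$vad) & is.na(countries$anemia)
  reason[is.na(reason) & no_data] <- "no_prevalence_data"

  if (any(no_score)) {
    warning(sprintf("no development score for: %s (excluded)",
                    paste(countries$iso3[no_score], collapse = ", ")))
  }
  drop <- !is.na(reason)
  excluded <- countries[drop, , drop = FALSE]
  excluded$reason <- reason[drop]
  list(
    included = countries[!drop, , drop = FALSE],
    excluded = excluded
  )
}

#' Assume freedom from vitamin A deficiency in high-GDP countries
#'
#' Countries with 2005 GDP per capita at or above the policy threshold and a
#' missing vitamin A deficiency prevalence are assigned a prevalence of zero
#' with provenance `"assumed_zero"`. Survey or regression values are never
#' overwritten; countries with missing GDP are untouched.
#'
#' @inheritParams apply_exclusions
#' @return The country table with the assumption applied.
#' @export
assume_vad_free <- function(countries, policy = hhi_policy()) {
  stopifnot(inherits(policy, "hhi_policy"))
  hit <- !is.na(countries$gdp_2005) &
    countries$gdp_2005 >= policy$vad_free_gdp_threshold &
    is.na(countries$vad)
  countries$vad[hit] <- 0
  countries$vad_prov[hit] <- "assumed_zero"
  countries
}

#' Impute missing stunting prevalence by WHO region
#'
#' Missing stunting values receive the mean stunting prevalence of countries
#' in the same WHO region, weighted by 2009 population size. Imputation is
#' single-pass: only observed values donate, so imputed values never seed
#' further imputation and the result is order-independent. A region with no
#' observed donor leaves its missing values missing, with a warning.
#'
#' @param countries Country table.
#' @return The table with imputed values, provenance `"regional_imputation"`.
#' @export
impute_stunting <- function(countries) {
  miss <- is.na(countries$stunting)
  if (!any(miss)) return(countries)
  for (reg in unique(countries$who_region[miss])) {
    donors <- countries$who_region == reg & !is.na(countries$stunting)
    targets <- countries$who_region == reg & miss
    if (!any(donors)) {
      warning(sprintf("region %s has no stunting donors; values left missing", reg))
      next
    }
    w <- countries$population_2009[donors]
    v <- countries$stunting[donors]
    countries$stunting[targets] <- sum(v * w) / sum(w)
    countries$stunting_prov[targets] <- "regional_imputation"
  }
  countries
}

#' Harmonize a raw country table
#'
#' Runs the full harmonization sequence: GDP-based vitamin A assumption,
#' population-weighted regional imputation of stunting, development-score and
#' data-availability exclusions, and the anemia-to-iron-deficiency-anemia
#' conversion (added as columns `ida`, `ida_prov` on the included set).
#'
#' @inheritParams apply_exclusions
#' @param ida_adjust If `FALSE`, raw anemia is carried as the `ida` component
#'   unadjusted (sensitivity switch).
#' @return A list of class `"hhi_harmonized"` with components `included`,
#'   `excluded` and `policy`.
#' @export
harmonize_countries <- function(countries, policy = hhi_policy(),
                                ida_adjust = TRUE) {
  countries <- assume_vad_free(countries, policy)
  countries <- impute_stunting(countries)
  parts <- apply_exclusions(countries, policy)
  inc <- parts$included
  if (ida_adjust) {
    inc$ida <- convert_anemia_to_ida(inc$anemia, inc$malaria_endemic, policy)
  } else {
    inc$ida <- inc$anemia
  }
  inc$ida_prov <- inc$anemia_prov
  structure(
    list(included = inc, excluded = parts$excluded, policy = policy,
         ida_adjust = ida_adjust),
    class = "hhi_harmonized"
  )
}

#' @export
print.hhi_harmonized <- function(x, ...) {
  cat(sprintf("Harmonized country panel: %d included, %d excluded\n",
              nrow(x$included), nrow(x$excluded)))
  if (nrow(x$excluded)) {
    tab <- table(x$excluded$reason)
    for (r in names(tab)) cat(sprintf("  excluded (%s): %d\n", r, tab[[r]]))
  }
  invisible(x)
}
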