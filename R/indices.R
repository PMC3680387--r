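#' Prevalence-based hidden hunger score
#'
#' The score is the unweighted arithmetic mean of three prevalences among
#' preschool-age children: stunting (the population proxy for zinc
#' deficiency), anemia attributable to iron deficiency (the malaria-adjusted
#' value from [convert_anemia_to_ida()]), and low serum retinol (vitamin A
#' deficiency). Iodine deficiency is deliberately not a component. The score
#' runs from 0 (best) to 100 (worst). Any missing component yields a missing
#' score.
#'
#' @param stunting,ida,vad Numeric vectors of prevalences on the 0-100 scale.
#' @return Numeric vector of scores in `[0, 100]`.
#' @examples
#' compute_hhi_pd(40, 30, 50) # 40
#' @export
compute_hhi_pd <- function(stunting, ida, vad) {
  for (v in list(stunting, ida, vad)) {
    ok <- !is.na(v)
    if (any(v[ok] < 0 | v[ok] > 100)) stop("components must lie in [0, 100]")
  }
  (stunting + ida + vad) / 3
}

#' Severity scale for the prevalence-based score
#'
#' The default scale labels scores below 20 mild, 20 to below 35 moderate,
#' 35 to below 45 severe, and 45 and above alarmingly high. Intervals are
#' half-open on the right; scores are categorized at full precision.
#'
#' @param boundaries Strictly increasing cut points inside (0, 100).
#' @param labels Category labels, one more than there are boundaries.
#' @return An object of class `"hhi_scale"`.
#' @export
hhi_category_scale <- function(boundaries = c(20, 35, 45),
                               labels = c("mild", "moderate", "severe",
                                          "alarmingly_high")) {
  stopifnot(
    is.numeric(boundaries), !is.unsorted(boundaries, strictly = TRUE),
    all(boundaries > 0 & boundaries < 100),
    length(labels) == length(boundaries) + 1L
  )
  structure(list(boundaries = boundaries, labels = labels), class = "hhi_scale")
}

#' Categorize scores on the severity scale
#'
#' @param score Numeric vector of scores in `[0, 100]` (missing allowed).
#' @param scale An [hhi_category_scale()].
#' @return An ordered factor with the scale's labels.
#' @examples
#' hhi_categorize(c(19.9, 35, 45)) # mild, severe, alarmingly_high
#' @export
hhi_categorize <- function(score, scale = hhi_category_scale()) {
  stopifnot(inherits(scale, "hhi_scale"))
  ok <- !is.na(score)
  if (any(score[ok] < 0 | score[ok] > 100)) stop("score must lie in [0, 100]")
  cut(score, breaks = c(0, scale$boundaries, 100),
      labels = scale$labels, right = FALSE, include.lowest = TRUE,
      ordered_result = TRUE)
}

#' Burden-based hidden hunger indices
#'
#' `compute_hhi_dba()` sums the disability-adjusted-life-year rates (per
#' 100,000 population) attributed to iron, zinc and vitamin A deficiency.
#' Iodine-attributed DALYs are never included. `compute_hhi_dbu()` converts
#' the rate into the absolute country burden, rate x population / 100,000.
#'
#' @param dalys A DALY table (see [read_daly_table()]).
#' @return Numeric vector: DALYs per 100,000 (`compute_hhi_dba`) or absolute
#'   DALYs (`compute_hhi_dbu`); missing where any required input is missing.
#' @export
compute_hhi_dba <- function(dalys) {
  dalys$daly_iron + dalys$daly_zinc + dalys$daly_vita
}

#' @rdname compute_hhi_dba
#' @export
compute_hhi_dbu <- function(dalys) {
  pop <- dalys$population
  pop[!is.na(pop) & pop <= 0] <- NA
  compute_hhi_dba(dalys) * pop / 1e5
}

#' Rank countries on an index
#'
#' Orders countries by the chosen key, highest burden first. Ties are broken
#' by ISO3 code ascending so rankings are deterministic; countries missing the
#' key are dropped from the ranking and reported in the `"omitted"` attribute.
#'
#' @param results A data.frame with columns `iso3` and the key.
#' @param key One of `"hhi_pd"`, `"hhi_dba"`, `"hhi_dbu"`.
#' @return The data.frame reordered, with attribute `"omitted"` (ISO3 codes).
#' @export
rank_countries <- function(results, key = c("hhi_pd", "hhi_dba", "hhi_dbu")) {
  key <- match.arg(key)
  if (!key %in% names(results)) stop("results lack column ", key)
  v <- results[[key]]
  if (all(is.na(v))) stop("no non-missing values for key ", key)
  keep <- !is.na(v)
  out <- results[keep, , drop = FALSE]
  out <- out[order(-out[[key]], out$iso3), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "omitted") <- results$iso3[!keep]
  out
}

#' Select the high-stunting-burden country group
#'
#' Selects countries with stunting prevalence at or above the floor, orders
#' them by their estimated number of stunted children (prevalence x under-five
#' population), and cuts the list at the smallest prefix holding at least the
#' target share of all stunted children globally (the global total is taken
#' over every country with the needed data, above or below the floor).
#'
#' @param countries Country table with `stunting` and `under5_population`.
#' @param stunting_floor Minimum stunting prevalence (%), default 20.
#' @param coverage Target share of the global stunted-child total, default 0.90.
#' @return A list with `selection` (data.frame ordered by stunted children,
#'   with a `stunted_children` column), `achieved_coverage`, and
#'   `global_stunted` (the global total used).
#' @export
select_high_burden <- function(countries, stunting_floor = 20, coverage = 0.90) {
  have <- !is.na(countries$stunting) & !is.na(countries$under5_population)
  skipped <- !is.na(countries$stunting) & is.na(countries$under5_population) &
    countries$stunting >= stunting_floor
  if (any(skipped)) {
    warning("candidates skipped for missing under-five population: ",
            paste(countries$iso3[skipped], collapse = ", "))
  }
  x <- countries[have, , drop = FALSE]
  x$stunted_children <- x$stunting / 100 * x$under5_population
  global <- sum(x$stunted_children)
  cand <- x[x$stunting >= stunting_floor, , drop = FALSE]
  cand <- cand[order(-cand$stunted_children, cand$iso3), , drop = FALSE]
  if (nrow(cand) == 0L || global == 0) {
    return(list(selection = cand, achieved_coverage = 0, global_stunted = global))
  }
  cum <- cumsum(cand$stunted_children) / global
  n_sel <- if (any(cum >= coverage)) which(cum >= coverage)[1L] else nrow(cand)
  sel <- cand[seq_len(n_sel), , drop = FALSE]
  rownames(sel) <- NULL
  list(selection = sel, achieved_coverage = cum[n_sel], global_stunted = global)
}

#' Percent of all-cause DALYs attributed to micronutrient deficiencies
#'
#' 100 x absolute micronutrient-attributed DALYs (iron + zinc + vitamin A)
#' divided by the country's total all-cause DALYs.
#'
#' @inheritParams compute_hhi_dba
#' @return Numeric vector of percentages; missing where the total is missing
#'   or non-positive.
#' @export
percent_mnd_dalys <- function(dalys) {
  tot <- dalys$total_all_cause_dalys
  tot[!is.na(tot) & tot <= 0] <- NA
  100 * compute_hhi_dbu(dalys) / tot
}
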