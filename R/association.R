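#' Spearman rank correlation with pairwise-complete deletion
#'
#' Drops pairs with any missing value, then correlates the average-tie ranks
#' of the remainder (equivalently, the Pearson correlation of the rank
#' vectors). No p-value is computed. Fewer than three complete pairs yields an
#' undefined result (`rho = NA`).
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param names Optional character pair naming the variables.
#' @return An object of class `"hhi_cor"`: list with `variable_x`,
#'   `variable_y`, `rho` and `n` (complete pairs actually used).
#' @export
spearman_rho <- function(x, y, names = c(deparse1(substitute(x)),
                                         deparse1(substitute(y)))) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  rho <- if (n >= 3L) stats::cor(x[ok], y[ok], method = "spearman") else NA_real_
  structure(
    list(variable_x = names[1L], variable_y = names[2L], rho = rho, n = n),
    class = "hhi_cor"
  )
}

#' @export
print.hhi_cor <- function(x, ...) {
  if (is.na(x$rho)) {
    cat(sprintf("Spearman rho(%s, %s): undefined (n = %d < 3)\n",
                x$variable_x, x$variable_y, x$n))
  } else {
    cat(sprintf("Spearman rho(%s, %s) = %.3f (n = %d)\n",
                x$variable_x, x$variable_y, x$rho, x$n))
  }
  invisible(x)
}

#' Pairwise correlations among the four deficiencies
#'
#' Spearman rank correlations for every pair among stunting, iron deficiency
#' anemia, vitamin A deficiency and iodine deficiency on a harmonized country
#' table, each with the number of complete pairs used. Optionally restricted
#' to values with national-survey provenance (a sensitivity analysis against
#' regression-based estimates).
#'
#' @param included Harmonized included-country table (needs columns
#'   `stunting`, `ida`, `vad`, `id` and their `_prov` companions).
#' @param survey_only Restrict both members of each pair to
#'   `"national_survey"` provenance.
#' @return A data.frame with columns `variable_x`, `variable_y`, `rho`, `n`.
#' @export
pairwise_deficiency_correlations <- function(included, survey_only = FALSE) {
  vars <- c("stunting", "ida", "vad", "id")
  stopifnot(all(vars %in% names(included)))
  pairs <- utils::combn(vars, 2L)
  out <- data.frame(variable_x = pairs[1L, ], variable_y = pairs[2L, ],
                    rho = NA_real_, n = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1L, i]; b <- pairs[2L, i]
    x <- included[[a]]; y <- included[[b]]
    if (survey_only) {
      keep <- included[[paste0(a, "_prov")]] == "national_survey" &
        included[[paste0(b, "_prov")]] == "national_survey"
      x[!keep] <- NA; y[!keep] <- NA
    }
    r <- spearman_rho(x, y, names = c(a, b))
    out$rho[i] <- r$rho
    out$n[i] <- r$n
  }
  out
}

#' Correlate an index with a per-country covariate
#'
#' Joins a named covariate vector to index results by ISO3 code and delegates
#' to [spearman_rho()] on the joined pairs.
#'
#' @param results Data.frame with `iso3` and the index column.
#' @param covariate Named numeric vector (names are ISO3 codes).
#' @param key Index column name, default `"hhi_pd"`.
#' @return An `"hhi_cor"` object.
#' @export
index_vs_covariate <- function(results, covariate, key = "hhi_pd") {
  stopifnot(key %in% names(results), !is.null(names(covariate)))
  cov <- covariate[match(results$iso3, names(covariate))]
  spearman_rho(results[[key]], as.numeric(cov), names = c(key, "covariate"))
}

#' Overlap between the top-k of two rankings
#'
#' Counts the countries common to the first `k` entries of two ordered
#' rankings (as produced by [rank_countries()], or plain ISO3 vectors).
#'
#' @param rank_a,rank_b Ordered character vectors of ISO3 codes, or
#'   data.frames with an `iso3` column in rank order.
#' @param k Depth of the comparison; must not exceed either ranking's length.
#' @return Integer overlap count in `[0, k]`.
#' @export
top_k_overlap <- function(rank_a, rank_b, k) {
  ids <- function(r) if (is.data.frame(r)) r$iso3 else as.character(r)
  a <- ids(rank_a); b <- ids(rank_b)
  stopifnot(k >= 1)
  if (k > length(a) || k > length(b)) {
    stop("k exceeds the length of a ranking")
  }
  length(intersect(a[seq_len(k)], b[seq_len(k)]))
}
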