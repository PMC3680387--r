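#' Construct the hidden hunger indices for a country panel
#'
#' The main entry point: harmonizes a raw country indicator table, computes
#' the prevalence-based index (mean of stunting, iron-deficiency-anemia and
#' vitamin-A-deficiency prevalences among preschool children) with its
#' severity category, and, when a DALY table is supplied, the burden-based
#' indices (iron + zinc + vitamin A DALYs per 100,000, and the absolute
#' country burden). Iodine deficiency is carried through and reported
#' alongside but never enters an index. DALY indices are computed only for
#' countries not excluded by the development-index rule.
#'
#' @param countries Country indicator table (see [read_country_table()]).
#' @param dalys Optional DALY table (see [read_daly_table()]).
#' @param policy An [hhi_policy()].
#' @param ida_adjust Apply the anemia-to-iron-deficiency-anemia conversion
#'   (default). `FALSE` feeds raw anemia into the index as a sensitivity
#'   analysis.
#' @param scale An [hhi_category_scale()].
#' @return An object of class `"hhi"`: a list with
#'   \describe{
#'     \item{results}{per-country data.frame: identifiers, components
#'       (`stunting`, `ida`, `vad`, with provenance), `id` (iodine, reported
#'       separately), `hhi_pd`, `category`, `hhi_dba`, `hhi_dbu`,
#'       `pct_mnd_dalys`.}
#'     \item{excluded}{excluded countries with machine-readable reasons.}
#'     \item{dropped}{ISO3 codes of included countries lacking a component,
#'       hence with no prevalence-based score.}
#'     \item{policy, scale, ida_adjust}{the settings used.}
#'   }
#' @examples
#' fx <- synthetic_appendix()
#' h <- hhi(fx$countries, fx$dalys)
#' summary(h)
#' @export
hhi <- function(countries, dalys = NULL, policy = hhi_policy(),
                ida_adjust = TRUE, scale = hhi_category_scale()) {
  harm <- harmonize_countries(countries, policy, ida_adjust = ida_adjust)
  inc <- harm$included
  res <- inc[, intersect(
    c("iso3", "name", "who_region", "ssa_member", "hdi_2007", "lei_2007",
      "gdp_2005", "population_2009", "under5_population", "malaria_endemic",
      "stunting", "stunting_prov", "anemia", "anemia_prov", "ida", "ida_prov",
      "vad", "vad_prov", "id", "id_prov"),
    names(inc)), drop = FALSE]
  res$hhi_pd <- compute_hhi_pd(res$stunting, res$ida, res$vad)
  res$category <- hhi_categorize(res$hhi_pd, scale)
  dropped <- res$iso3[is.na(res$hhi_pd)]

  res$hhi_dba <- NA_real_
  res$hhi_dbu <- NA_real_
  res$pct_mnd_dalys <- NA_real_
  if (!is.null(dalys)) {
    d <- dalys[!dalys$iso3 %in% harm$excluded$iso3, , drop = FALSE]
    d$hhi_dba <- compute_hhi_dba(d)
    d$hhi_dbu <- compute_hhi_dbu(d)
    d$pct_mnd_dalys <- percent_mnd_dalys(d)
    m <- match(res$iso3, d$iso3)
    res$hhi_dba <- d$hhi_dba[m]
    res$hhi_dbu <- d$hhi_dbu[m]
    res$pct_mnd_dalys <- d$pct_mnd_dalys[m]
    extra <- d[!d$iso3 %in% res$iso3, , drop = FALSE]
    if (nrow(extra)) {
      add <- res[rep(NA_integer_, nrow(extra)), , drop = FALSE]
      add$iso3 <- extra$iso3
      add$population_2009 <- extra$population
      add$hhi_dba <- extra$hhi_dba
      add$hhi_dbu <- extra$hhi_dbu
      add$pct_mnd_dalys <- extra$pct_mnd_dalys
      res <- rbind(res, add)
    }
  }
  rownames(res) <- NULL
  structure(
    list(results = res, excluded = harm$excluded, dropped = dropped,
         policy = policy, scale = scale, ida_adjust = ida_adjust),
    class = "hhi"
  )
}

#' @export
print.hhi <- function(x, ...) {
  r <- x$results
  cat("Hidden hunger indices\n")
  cat(sprintf("  countries scored (prevalence index): %d\n", sum(!is.na(r$hhi_pd))))
  cat(sprintf("  countries with burden indices:       %d\n", sum(!is.na(r$hhi_dba))))
  cat(sprintf("  excluded by harmonization rules:     %d\n", nrow(x$excluded)))
  if (length(x$dropped)) {
    cat(sprintf("  included but unscored (missing component): %d\n",
                length(x$dropped)))
  }
  if (any(!is.na(r$hhi_pd))) {
    top <- rank_countries(r, "hhi_pd")
    k <- min(5L, nrow(top))
    cat("  highest prevalence-based scores:\n")
    for (i in seq_len(k)) {
      cat(sprintf("    %-4s %-30s %6.1f (%s)\n", top$iso3[i],
                  substr(ifelse(is.na(top$name[i]), "", top$name[i]), 1, 30),
                  top$hhi_pd[i], as.character(top$category[i])))
    }
  }
  invisible(x)
}

#' Summarize a hidden hunger index object
#'
#' Reports country counts, the severity-category distribution, the extremes
#' of both indices, the top-20 composition by sub-Saharan-Africa membership,
#' the top-20 overlap between the prevalence-based and burden-based rankings,
#' and their Spearman rank correlation over countries holding both.
#'
#' @param object An object of class `"hhi"`.
#' @param k Depth for top-k comparisons (default 20).
#' @param ... Unused.
#' @return A list of class `"summary.hhi"`.
#' @export
summary.hhi <- function(object, k = 20L, ...) {
  r <- object$results
  out <- list(
    n_scored = sum(!is.na(r$hhi_pd)),
    n_daly = sum(!is.na(r$hhi_dba)),
    n_excluded = nrow(object$excluded),
    n_dropped = length(object$dropped),
    categories = table(r$category[!is.na(r$hhi_pd)]),
    k = as.integer(k)
  )
  if (out$n_scored > 0) {
    rk <- rank_countries(r, "hhi_pd")
    out$max_pd <- rk[1L, c("iso3", "hhi_pd")]
    out$min_pd <- rk[nrow(rk), c("iso3", "hhi_pd")]
    if (out$n_scored >= k && "ssa_member" %in% names(rk)) {
      out$topk_pd <- rk$iso3[seq_len(k)]
      out$topk_pd_ssa <- sum(rk$ssa_member[seq_len(k)], na.rm = TRUE)
    }
  }
  if (out$n_daly > 0) {
    rkd <- rank_countries(r, "hhi_dba")
    out$max_dba <- rkd[1L, c("iso3", "hhi_dba")]
    out$min_dba <- rkd[nrow(rkd), c("iso3", "hhi_dba")]
    if (out$n_daly >= k) {
      out$topk_dba <- rkd$iso3[seq_len(k)]
      out$topk_dba_ssa <- sum(rkd$ssa_member[seq_len(k)], na.rm = TRUE)
    }
    if (out$n_scored >= k && out$n_daly >= k) {
      out$topk_overlap <- top_k_overlap(rank_countries(r, "hhi_pd"), rkd, k)
    }
    cor_pd_dba <- spearman_rho(r$hhi_pd, r$hhi_dba,
                               names = c("hhi_pd", "hhi_dba"))
    out$rho_pd_dba <- cor_pd_dba$rho
    out$n_common <- cor_pd_dba$n
  }
  class(out) <- "summary.hhi"
  out
}

#' @export
print.summary.hhi <- function(x, ...) {
  cat("Hidden hunger indices - summary\n")
  cat(sprintf("  scored countries: %d   burden countries: %d   excluded: %d\n",
              x$n_scored, x$n_daly, x$n_excluded))
  if (x$n_dropped) cat(sprintf("  unscored (missing component): %d\n", x$n_dropped))
  if (length(x$categories)) {
    cat("  severity categories: ",
        paste(sprintf("%s %d", names(x$categories), x$categories),
              collapse = ", "), "\n", sep = "")
  }
  if (!is.null(x$max_pd)) {
    cat(sprintf("  prevalence index: max %s (%.1f), min %s (%.1f)\n",
                x$max_pd$iso3, x$max_pd$hhi_pd, x$min_pd$iso3, x$min_pd$hhi_pd))
  }
  if (!is.null(x$max_dba)) {
    cat(sprintf("  burden index: max %s (%s/100k), min %s (%s/100k)\n",
                x$max_dba$iso3, format(round(x$max_dba$hhi_dba), big.mark = ","),
                x$min_dba$iso3, format(round(x$min_dba$hhi_dba), big.mark = ",")))
  }
  if (!is.null(x$topk_pd_ssa)) {
    cat(sprintf("  top-%d prevalence list: %d sub-Saharan African countries\n",
                x$k, x$topk_pd_ssa))
  }
  if (!is.null(x$topk_overlap)) {
    cat(sprintf("  top-%d overlap (prevalence vs burden ranking): %d\n",
                x$k, x$topk_overlap))
  }
  if (!is.null(x$rho_pd_dba) && !is.na(x$rho_pd_dba)) {
    cat(sprintf("  Spearman rho(prevalence, burden) = %.2f over %d countries\n",
                x$rho_pd_dba, x$n_common))
  }
  invisible(x)
}

#' @export
as.data.frame.hhi <- function(x, ...) x$results

#' Plot a hidden hunger index object
#'
#' Draws the population-scaled letter scatter on the current device: each
#' scored country appears as the first letter of its name, glyph area
#' proportional to 2009 population, colored by a seven-group regional scheme,
#' with the prevalence-based score on the vertical axis and the chosen
#' covariate on the horizontal axis. The Spearman rank correlation over the
#' plotted points is printed in the margin.
#'
#' @param x An object of class `"hhi"`.
#' @param covariate Covariate column in the results (default `"hdi_2007"`) or
#'   a named numeric vector keyed by ISO3.
#' @param ... Passed to the underlying renderer (e.g. `xlab`).
#' @return Invisibly, the renderer's log (omitted points and rho).
#' @export
plot.hhi <- function(x, covariate = "hdi_2007", ...) {
  r <- x$results
  if (is.character(covariate) && length(covariate) == 1L) {
    stopifnot(covariate %in% names(r))
    cov <- stats::setNames(r[[covariate]], r$iso3)
    lab <- covariate
  } else {
    cov <- covariate
    lab <- "covariate"
  }
  invisible(.draw_letter_scatter(r, cov, xlab = lab, ...))
}
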