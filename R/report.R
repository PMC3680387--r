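# Rendering: categorical choropleth maps from GeoJSON boundaries and
# population-scaled letter scatter plots, all base graphics. Boundaries are
# user-supplied GeoJSON with an iso3 property; a toy world ships for tests.

#' Map style
#'
#' Colors and join settings for [render_choropleth()]: one color per severity
#' category (a sequential colorblind-safe default), plus visually distinct
#' "no data" and "excluded" classes.
#'
#' @param category_palette Four ordered fill colors (mild to alarmingly
#'   high).
#' @param no_data_col,excluded_col Fills for unscored and excluded countries.
#' @param border_col Polygon border color.
#' @param join_key Property name holding the ISO3 code in the GeoJSON.
#' @return An object of class `"hhi_map_style"`.
#' @export
map_style <- function(category_palette = c("#FFFFB2", "#FECC5C",
                                           "#FD8D3C", "#E31A1C"),
                      no_data_col = "#BDBDBD",
                      excluded_col = "#FFFFFF",
                      border_col = "#636363",
                      join_key = "iso3") {
  stopifnot(length(category_palette) == 4L)
  structure(list(category_palette = category_palette,
                 no_data_col = no_data_col, excluded_col = excluded_col,
                 border_col = border_col, join_key = join_key),
            class = "hhi_map_style")
}

# minimal GeoJSON FeatureCollection reader: list of (iso3, rings)
.read_geojson_polygons <- function(path, join_key = "iso3") {
  g <- jsonlite::read_json(path)
  if (is.null(g$features)) stop("not a GeoJSON FeatureCollection: ", path)
  lapply(g$features, function(f) {
    iso3 <- f$properties[[join_key]]
    geom <- f$geometry
    rings <- switch(
      geom$type,
      Polygon = list(geom$coordinates),
      MultiPolygon = geom$coordinates,
      stop("unsupported geometry type: ", geom$type)
    )
    rings <- lapply(rings, function(poly) {
      lapply(poly, function(ring) {
        do.call(rbind, lapply(ring, function(pt) c(pt[[1L]], pt[[2L]])))
      })
    })
    list(iso3 = toupper(iso3), rings = rings)
  })
}

.open_device <- function(out, width = 9, height = 5) {
  ext <- tolower(tools::file_ext(out))
  switch(ext,
         png = grDevices::png(out, width = width, height = height,
                              units = "in", res = 150),
         svg = grDevices::svg(out, width = width, height = height),
         pdf = grDevices::pdf(out, width = width, height = height),
         stop("unsupported output format: .", ext))
}

#' Render a categorical choropleth map
#'
#' Fills each country polygon by its severity category (or, when
#' `value_key` names a numeric column such as `"hhi_dba"`, by a continuous
#' ramp over that column). Countries present in the results but without a
#' value take the "no data" class; countries in the supplied `excluded`
#' table take the "excluded" class. ISO3 codes in the results that match no
#' polygon are returned in the unmatched log.
#'
#' @param results Results data.frame (e.g. from [hhi()]), with `iso3` and
#'   `category` (or `value_key`).
#' @param boundaries Path to a GeoJSON FeatureCollection whose features
#'   carry the join key property.
#' @param out Output file path; format by extension (`.png`, `.svg`,
#'   `.pdf`).
#' @param style A [map_style()].
#' @param value_key `"category"` (default) for the categorical map or a
#'   numeric results column for a continuous ramp.
#' @param excluded Optional data.frame of excluded countries (needs `iso3`).
#' @param main Plot title.
#' @return Invisibly, a list with `unmatched` (ISO3 in results but not on
#'   the map), `matched` (count) and `fill_counts` (polygons per class).
#' @export
render_choropleth <- function(results, boundaries, out, style = map_style(),
                              value_key = "category", excluded = NULL,
                              main = "Hidden hunger index") {
  if (inherits(results, "hhi")) {
    if (is.null(excluded)) excluded <- results$excluded
    results <- results$results
  }
  polys <- .read_geojson_polygons(boundaries, style$join_key)
  map_iso <- vapply(polys, `[[`, "", "iso3")
  res_iso <- toupper(results$iso3)
  if (!any(res_iso %in% map_iso)) stop("no result country matches the boundaries")
  excl_iso <- if (is.null(excluded)) character(0) else toupper(excluded$iso3)

  if (value_key == "category") {
    cat_f <- results$category
    labs <- levels(cat_f)
    fill_for <- function(iso) {
      if (iso %in% excl_iso) return(style$excluded_col)
      i <- match(iso, res_iso)
      if (is.na(i) || is.na(cat_f[i])) return(style$no_data_col)
      style$category_palette[match(as.character(cat_f[i]), labs)]
    }
    legend_labs <- c(labs, "no data", "excluded")
    legend_cols <- c(style$category_palette, style$no_data_col,
                     style$excluded_col)
  } else {
    v <- results[[value_key]]
    rng <- range(v, na.rm = TRUE)
    ramp <- grDevices::colorRampPalette(style$category_palette)(100L)
    fill_for <- function(iso) {
      if (iso %in% excl_iso) return(style$excluded_col)
      i <- match(iso, res_iso)
      if (is.na(i) || is.na(v[i])) return(style$no_data_col)
      ramp[1L + round(99 * (v[i] - rng[1L]) / max(rng[2L] - rng[1L], 1e-12))]
    }
    legend_labs <- c(sprintf("%.0f", rng[1L]), sprintf("%.0f", rng[2L]),
                     "no data", "excluded")
    legend_cols <- c(ramp[1L], ramp[100L], style$no_data_col,
                     style$excluded_col)
  }

  .open_device(out)
  on.exit(grDevices::dev.off())
  xs <- unlist(lapply(polys, function(p)
    unlist(lapply(p$rings, function(po) lapply(po, function(r) r[, 1L])))))
  ys <- unlist(lapply(polys, function(p)
    unlist(lapply(p$rings, function(po) lapply(po, function(r) r[, 2L])))))
  graphics::plot(range(xs), range(ys), type = "n", asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = main)
  fills <- character(length(polys))
  for (i in seq_along(polys)) {
    f <- fill_for(polys[[i]]$iso3)
    fills[i] <- f
    for (poly in polys[[i]]$rings) {
      for (ring in poly) {
        graphics::polygon(ring[, 1L], ring[, 2L], col = f,
                          border = style$border_col, lwd = 0.4)
      }
    }
  }
  graphics::legend("bottomleft", legend = legend_labs, fill = legend_cols,
                   cex = 0.7, bty = "n")
  unmatched <- setdiff(res_iso, map_iso)
  invisible(list(unmatched = unmatched,
                 matched = sum(res_iso %in% map_iso),
                 fill_counts = table(fills)))
}

# seven-group regional color scheme for the letter scatters: Africa black;
# East Asia red; West/Central Asia yellow; Central and South America green;
# Pacific islands and Caribbean turquoise; South Asia purple; Europe, North
# America, Australia and New Zealand blue.
.region7 <- function(who_region, ssa_member, iso3) {
  south_asia <- c("AFG", "BGD", "BTN", "IND", "LKA", "MDV", "NPL", "PAK")
  east_asia <- c("CHN", "JPN", "KOR", "PRK", "MNG", "KHM", "LAO", "MMR",
                 "MYS", "IDN", "PHL", "SGP", "THA", "TLS", "VNM", "BRN")
  anz <- c("AUS", "NZL")
  out <- rep("west_central_asia", length(iso3))
  out[who_region == "AFR" | (!is.na(ssa_member) & ssa_member)] <- "africa"
  out[who_region == "EUR"] <- "europe_na_anz"
  out[who_region == "AMR"] <- "c_s_america"
  out[who_region == "WPR"] <- "pacific_caribbean"
  out[iso3 %in% c("USA", "CAN")] <- "europe_na_anz"
  out[iso3 %in% anz] <- "europe_na_anz"
  out[iso3 %in% east_asia] <- "east_asia"
  out[iso3 %in% south_asia] <- "south_asia"
  small_caribbean <- c("ATG", "BHS", "BRB", "CUB", "DMA", "DOM", "GRD",
                       "HTI", "JAM", "KNA", "LCA", "TTO", "VCT")
  out[iso3 %in% small_caribbean] <- "pacific_caribbean"
  out
}

.region7_cols <- c(africa = "black", east_asia = "red2",
                   west_central_asia = "goldenrod2", c_s_america = "green4",
                   pacific_caribbean = "turquoise3", south_asia = "purple3",
                   europe_na_anz = "blue3")

# shared drawing core: letters sized by sqrt(population) (area ~ population)
.draw_letter_scatter <- function(results, covariate, ykey = "hhi_pd",
                                 xlab = "covariate", ylab = NULL,
                                 main = NULL, cex_range = c(0.5, 3)) {
  cov <- covariate[match(results$iso3, names(covariate))]
  y <- results[[ykey]]
  keep <- !is.na(cov) & !is.na(y)
  omitted <- results$iso3[!keep]
  if (!any(keep)) stop("no complete (covariate, score) pair to plot")
  r <- results[keep, , drop = FALSE]
  cov <- as.numeric(cov[keep]); y <- y[keep]
  pop <- r$population_2009
  pop[is.na(pop)] <- stats::median(pop, na.rm = TRUE)
  s <- sqrt(pop / max(pop))
  cex <- cex_range[1L] + (cex_range[2L] - cex_range[1L]) * s
  grp <- .region7(r$who_region, r$ssa_member, r$iso3)
  letters1 <- toupper(substr(ifelse(is.na(r$name), r$iso3, r$name), 1L, 1L))
  rho <- spearman_rho(cov, y, names = c(xlab, ykey))
  if (is.null(ylab)) ylab <- ykey
  graphics::plot(cov, y, type = "n", xlab = xlab, ylab = ylab, main = main)
  graphics::text(cov, y, labels = letters1, cex = cex,
                 col = .region7_cols[grp])
  graphics::mtext(sprintf("Spearman rho = %.2f (n = %d)", rho$rho, rho$n),
                  side = 3L, adj = 1, cex = 0.8)
  list(omitted = omitted, rho = rho$rho, n = rho$n)
}

#' Render the population-scaled letter scatter
#'
#' Each country is drawn as the first letter of its name at (covariate,
#' score); glyph area is proportional to 2009 population and color follows
#' the seven-group regional scheme (Africa black; East Asia red;
#' West/Central Asia yellow; Central and South America green; Pacific and
#' Caribbean turquoise; South Asia purple; Europe, North America, Australia
#' and New Zealand blue). The Spearman rank correlation over the plotted
#' points is printed in the top margin. Countries missing the covariate or
#' the score are omitted and logged.
#'
#' @param results Results data.frame with `iso3`, `hhi_pd`,
#'   `population_2009`, `who_region`.
#' @param covariate Named numeric vector keyed by ISO3.
#' @param out Output file path (`.png`, `.svg`, `.pdf`).
#' @param xlab,main Labels.
#' @param ykey Score column for the vertical axis (default `"hhi_pd"`).
#' @return Invisibly, a list with `omitted` (ISO3 codes), `rho` and `n`.
#' @export
render_letter_scatter <- function(results, covariate, out,
                                  xlab = "covariate", main = NULL,
                                  ykey = "hhi_pd") {
  .open_device(out, width = 7, height = 6)
  on.exit(grDevices::dev.off())
  invisible(.draw_letter_scatter(results, covariate, ykey = ykey,
                                 xlab = xlab, main = main))
}

#' Write a toy world boundary file
#'
#' Six rectangular "countries" as a GeoJSON FeatureCollection with an `iso3`
#' property, for tests and examples of [render_choropleth()].
#'
#' @param path Output path.
#' @param iso3 Six ISO3 codes for the toy polygons.
#' @return `path`, invisibly.
#' @export
toy_world_geojson <- function(path,
                              iso3 = c("XAA", "XAB", "XAC",
                                       "XAD", "XAE", "XAF")) {
  stopifnot(length(iso3) == 6L)
  rect <- function(x0, y0) {
    list(list(list(c(x0, y0), c(x0 + 8, y0), c(x0 + 8, y0 + 6),
              c(x0, y0 + 6), c(x0, y0))))
  }
  feats <- lapply(seq_along(iso3), function(i) {
    x0 <- ((i - 1L) %% 3L) * 10
    y0 <- ((i - 1L) %/% 3L) * 8
    list(type = "Feature",
         properties = list(iso3 = iso3[i]),
         geometry = list(type = "Polygon", coordinates = rect(x0, y0)))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
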