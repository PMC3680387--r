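# Delimited-table I/O. Comma is the default dialect; tab is accepted.
# Empty cells are missing. Provenance columns, when absent, are derived from
# value presence (observed -> "national_survey", empty -> "missing").

.country_num_cols <- c("hdi_2007", "lei_2007", "gdp_2005", "population_2009",
                       "under5_population", "stunting", "anemia", "vad", "id")
.country_prov_cols <- c("stunting_prov", "anemia_prov", "vad_prov", "id_prov")
.country_log_cols <- c("ssa_member", "malaria_endemic")
.prov_levels <- c("national_survey", "who_regression", "regional_imputation",
                  "assumed_zero", "missing")
.daly_num_cols <- c("daly_iron", "daly_zinc", "daly_vita", "daly_iodine",
                    "total_all_cause_dalys", "population")

.as_num <- function(x, col, path) {
  if (is.numeric(x)) return(x)
  x <- trimws(as.character(x))
  x[x == ""] <- NA
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & is.na(out)
  if (any(bad)) {
    warning(sprintf("%s: %d unparseable value(s) in column '%s' set to missing",
                    basename(path), sum(bad), col))
  }
  out
}

.as_log <- function(x) {
  if (is.logical(x)) return(x)
  x <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[x %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

#' Read a country indicator table
#'
#' Reads a delimited country table with the documented header (`iso3`, `name`,
#' `who_region`, `ssa_member`, `hdi_2007`, `lei_2007`, `gdp_2005`,
#' `population_2009`, `under5_population`, `malaria_endemic`, plus the four
#' prevalence columns `stunting`, `anemia`, `vad`, `id` and their `_prov`
#' provenance companions). ISO3 codes are normalized to upper case;
#' unparseable numeric cells become missing with a warning; a duplicated ISO3
#' code or a missing mandatory column is a hard error.
#'
#' @param path Path to a delimited text file.
#' @param sep Field separator: `","` (default) or `"\t"`.
#' @return A data.frame, one row per country.
#' @export
read_country_table <- function(path, sep = ",") {
  stopifnot(file.exists(path))
  x <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                         stringsAsFactors = FALSE, comment.char = "",
                         na.strings = "", check.names = TRUE)
  mandatory <- c("iso3", "name", "who_region")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  x$iso3 <- toupper(trimws(x$iso3))
  dup <- unique(x$iso3[duplicated(x$iso3)])
  if (length(dup)) {
    stop("duplicate iso3 code(s): ", paste(dup, collapse = ", "))
  }
  for (col in .country_num_cols) {
    x[[col]] <- if (col %in% names(x)) .as_num(x[[col]], col, path) else NA_real_
  }
  for (col in .country_log_cols) {
    x[[col]] <- if (col %in% names(x)) .as_log(x[[col]]) else NA
  }
  for (i in seq_along(.country_prov_cols)) {
    pcol <- .country_prov_cols[i]
    vcol <- sub("_prov$", "", pcol)
    if (!pcol %in% names(x)) {
      x[[pcol]] <- ifelse(is.na(x[[vcol]]), "missing", "national_survey")
    } else {
      x[[pcol]] <- ifelse(is.na(x[[vcol]]), "missing", as.character(x[[pcol]]))
      bad <- !x[[pcol]] %in% .prov_levels
      if (any(bad)) {
        warning(sprintf("%s: unknown provenance value(s) in '%s' replaced",
                        basename(path), pcol))
        x[[pcol]][bad] <- ifelse(is.na(x[[vcol]][bad]), "missing", "national_survey")
      }
    }
  }
  for (col in c("stunting", "anemia", "vad", "id")) {
    out <- !is.na(x[[col]]) & (x[[col]] < 0 | x[[col]] > 100)
    if (any(out)) {
      warning(sprintf("%s: %d out-of-range value(s) in '%s' set to missing",
                      basename(path), sum(out), col))
      x[[col]][out] <- NA_real_
      x[[paste0(col, "_prov")]][out] <- "missing"
    }
  }
  if (any(!is.na(x$population_2009) & x$population_2009 <= 0)) {
    stop("population_2009 must be positive")
  }
  bad_u5 <- !is.na(x$under5_population) & !is.na(x$population_2009) &
    x$under5_population > x$population_2009
  if (any(bad_u5)) stop("under5_population exceeds population_2009 for: ",
                        paste(x$iso3[bad_u5], collapse = ", "))
  cols <- c("iso3", "name", "who_region", .country_log_cols[1], "hdi_2007",
            "lei_2007", "gdp_2005", "population_2009", "under5_population",
            .country_log_cols[2],
            rbind(c("stunting", "anemia", "vad", "id"), .country_prov_cols))
  x[, intersect(c(cols, setdiff(names(x), cols)), names(x)), drop = FALSE]
}

#' Read a DALY burden table
#'
#' Reads a delimited table of micronutrient-attributed disability-adjusted
#' life years with header `iso3`, `daly_iron`, `daly_zinc`, `daly_vita`,
#' `daly_iodine`, `total_all_cause_dalys`, `population`. Rates are DALYs per
#' 100,000 population; `total_all_cause_dalys` is absolute.
#'
#' @inheritParams read_country_table
#' @return A data.frame, one row per country.
#' @export
read_daly_table <- function(path, sep = ",") {
  stopifnot(file.exists(path))
  x <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                         stringsAsFactors = FALSE, comment.char = "",
                         na.strings = "", check.names = TRUE)
  if (!"iso3" %in% names(x)) stop("missing mandatory column(s): iso3")
  x$iso3 <- toupper(trimws(x$iso3))
  dup <- unique(x$iso3[duplicated(x$iso3)])
  if (length(dup)) stop("duplicate iso3 code(s): ", paste(dup, collapse = ", "))
  for (col in .daly_num_cols) {
    x[[col]] <- if (col %in% names(x)) .as_num(x[[col]], col, path) else NA_real_
  }
  for (col in c("daly_iron", "daly_zinc", "daly_vita", "daly_iodine")) {
    if (any(!is.na(x[[col]]) & x[[col]] < 0)) stop("negative DALY rate in ", col)
  }
  x
}

#' Write a country or DALY table
#'
#' Writes tables in the same dialect they are read in: header row, empty cell
#' for missing, unquoted numerics. Output is byte-stable for identical input.
#'
#' @param x Data.frame as returned by [read_country_table()] /
#'   [read_daly_table()] (or with the same columns).
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_country_table <- function(x, path, sep = ",") {
  utils::write.table(x, path, sep = sep, quote = TRUE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_country_table
#' @export
write_daly_table <- write_country_table
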