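# CSV schemas shared by readers, writers and the synthetic generator.
SURVEY_COLS <- c(
  "site_id", "site_name", "year", "lat", "lon", "distance_km",
  "animal_id", "sex", "shell_length_mm", "fresh_tissue_g", "dry_shell_g",
  "penis_length_mm", "vds_stage"
)
TISSUE_COLS <- c(
  "site_id", "year", "replicate_id", "analyte", "value_ug_kg_dw",
  "censored", "detection_limit"
)
TOXICITY_COLS <- c("species", "group", "endpoint_ug_kg_dw", "source")
SUMMARY_COLS <- c(
  "site_id", "year", "mean_vdsi", "median_vdsi", "pct_imposex",
  "pct_sterile_female", "rpsi", "condition_index", "n_females", "n_males"
)

#' Construct a single-site survey
#'
#' A `site_survey` bundles the site metadata of one sampling visit with the
#' individual-level records (one row per snail) collected there.
#'
#' @param site_id Integer site identifier (stable across survey years).
#' @param site_name Human-readable label; not used for joins.
#' @param year Survey year.
#' @param lat,lon Decimal-degree coordinates (may be `NA`).
#' @param distance_km Distance from the shore site to the nearest harbour,
#'   marina or other facility with intense shipping activity, in km
#'   (non-negative).
#' @param individuals Data frame with columns `animal_id`, `sex`
#'   (`"female"`/`"male"`), `shell_length_mm`, `fresh_tissue_g`,
#'   `dry_shell_g`, `penis_length_mm` and `vds_stage` (integer 0--6 for
#'   females, `NA` for males).
#'
#' @return An object of class `site_survey`.
#' @export
site_survey <- function(site_id, site_name, year, lat = NA_real_,
                        lon = NA_real_, distance_km = NA_real_,
                        individuals) {
  individuals <- as_tibble(individuals)
  if (nrow(individuals) < 1L) stopf("a site survey needs at least one individual")
  if (!is.na(distance_km) && distance_km < 0) {
    stopf("`distance_km` must be non-negative")
  }
  bad <- validate_individuals(individuals)
  if (length(bad)) stopf("invalid individual records:\n%s",
                         paste(bad, collapse = "\n"))
  structure(
    list(site_id = as.integer(site_id), site_name = as.character(site_name),
         year = as.integer(year), lat = lat, lon = lon,
         distance_km = distance_km, individuals = individuals),
    class = "site_survey"
  )
}

#' @export
print.site_survey <- function(x, ...) {
  cat(sprintf("<site_survey> site %d (%s), %d: %d individuals (%d F / %d M)\n",
              x$site_id, x$site_name, x$year, nrow(x$individuals),
              sum(x$individuals$sex == "female"),
              sum(x$individuals$sex == "male")))
  invisible(x)
}

# Returns a character vector of row-indexed violation messages (empty if ok).
validate_individuals <- function(ind) {
  msgs <- character()
  add <- function(rows, field, why) {
    if (length(rows)) {
      msgs <<- c(msgs, sprintf("row %d: %s %s", rows, field, why))
    }
    invisible(NULL)
  }
  n <- nrow(ind)
  add(which(!ind$sex %in% c("female", "male")), "sex",
      "must be 'female' or 'male'")
  add(which(!is.finite(ind$shell_length_mm) | ind$shell_length_mm <= 0),
      "shell_length_mm", "must be > 0")
  add(which(!is.na(ind$fresh_tissue_g) & ind$fresh_tissue_g <= 0),
      "fresh_tissue_g", "must be > 0 when present")
  add(which(!is.na(ind$dry_shell_g) & ind$dry_shell_g <= 0),
      "dry_shell_g", "must be > 0 when present")
  add(which(!is.na(ind$penis_length_mm) & ind$penis_length_mm < 0),
      "penis_length_mm", "must be >= 0")
  stage <- ind$vds_stage
  add(which(!is.na(stage) & (stage < 0 | stage > 6 | stage != round(stage))),
      "vds_stage", "must be an integer in 0..6")
  add(which(ind$sex == "male" & !is.na(stage)), "vds_stage",
      "must be absent for males")
  add(which(ind$sex == "female" & is.na(stage)), "vds_stage",
      "is required for females")
  msgs
}

#' Read an individual-level survey CSV
#'
#' Reads the `survey.csv` schema (one row per snail; see Details) and returns
#' one [site_survey()] per distinct `(site_id, year)`. Rows violating the
#' record invariants are reported with their file row numbers and the read is
#' rejected.
#'
#' @details The expected header is
#' `site_id,site_name,year,lat,lon,distance_km,animal_id,sex,shell_length_mm,fresh_tissue_g,dry_shell_g,penis_length_mm,vds_stage`.
#' Missing values are empty fields; the decimal separator is `.`.
#'
#' @param path Path to a CSV file.
#' @return A list of `site_survey` objects, ordered by `(year, site_id)`.
#' @export
read_survey <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = "")
  missing <- setdiff(SURVEY_COLS, names(raw))
  if (length(missing)) {
    stopf("schema error: missing columns: %s", paste(missing, collapse = ", "))
  }
  num_cols <- setdiff(SURVEY_COLS, c("site_name", "sex", "animal_id"))
  parsed <- raw
  for (col in num_cols) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(vals))
    if (length(bad)) {
      stopf("row %s: cannot parse %s value '%s' as a number",
            paste(bad + 1L, collapse = ","), col, raw[[col]][bad[1]])
    }
    parsed[[col]] <- vals
  }
  parsed <- as_tibble(parsed)
  key <- interaction(parsed$site_id, parsed$year, drop = TRUE)
  surveys <- lapply(split(seq_len(nrow(parsed)), key), function(idx) {
    block <- parsed[idx, ]
    ind <- block[, c("animal_id", "sex", "shell_length_mm", "fresh_tissue_g",
                     "dry_shell_g", "penis_length_mm", "vds_stage")]
    bad <- validate_individuals(ind)
    if (length(bad)) {
      # report positions in the file, not in the block (+1 for the header)
      local <- as.integer(sub("^row (\\d+):.*$", "\\1", bad))
      stopf("invalid rows in %s:\n%s", basename(path),
            paste(sprintf("file row %d: %s", idx[local] + 1L,
                          sub("^row \\d+: ", "", bad)), collapse = "\n"))
    }
    site_survey(block$site_id[1], block$site_name[1], block$year[1],
                block$lat[1], block$lon[1], block$distance_km[1], ind)
  })
  ord <- order(vapply(surveys, function(s) s$year * 1000L + s$site_id, 0L))
  unname(surveys[ord])
}

#' Write surveys back to the survey CSV schema
#'
#' @param surveys A list of [site_survey()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(surveys, path) {
  if (length(surveys) == 0L) stopf("nothing to write")
  rows <- lapply(surveys, function(s) {
    cbind(tibble(site_id = s$site_id, site_name = s$site_name, year = s$year,
                 lat = s$lat, lon = s$lon, distance_km = s$distance_km),
          s$individuals)
  })
  out <- dplyr::bind_rows(rows)[, SURVEY_COLS]
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write a tissue organotin panel CSV
#'
#' The long `tissue.csv` schema has one row per replicate x analyte:
#' `site_id,year,replicate_id,analyte,value_ug_kg_dw,censored,detection_limit`.
#' `analyte` is one of MBT, DBT, TBT, MPT, DPT, TPT; `censored` is
#' `TRUE`/`FALSE`; censored rows must carry a `detection_limit` and their
#' `value_ug_kg_dw` is ignored until a substitution policy is applied
#' (see [substitute_censored()]).
#'
#' @param path CSV path.
#' @return A tibble in the tissue schema.
#' @export
read_tissue <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(TISSUE_COLS, names(x))
  if (length(missing)) {
    stopf("schema error: missing columns: %s", paste(missing, collapse = ", "))
  }
  x$censored <- as.logical(x$censored)
  bad <- which(!x$analyte %in% OT_ANALYTES)
  if (length(bad)) {
    stopf("row %s: unknown analyte '%s'", paste(bad + 1L, collapse = ","),
          x$analyte[bad[1]])
  }
  bad <- which(!x$censored & (!is.finite(x$value_ug_kg_dw) | x$value_ug_kg_dw < 0))
  if (length(bad)) {
    stopf("row %s: uncensored value_ug_kg_dw must be >= 0",
          paste(bad + 1L, collapse = ","))
  }
  as_tibble(x[, TISSUE_COLS])
}

#' @rdname read_tissue
#' @param tissue A tibble in the tissue schema.
#' @export
write_tissue <- function(tissue, path) {
  if (nrow(tissue) == 0L) stopf("nothing to write")
  write.csv(tissue[, TISSUE_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read/write a toxicity-endpoint CSV for SSD construction
#'
#' Schema: `species,group,endpoint_ug_kg_dw,source` with `group` in
#' `{"BT","PT"}` and strictly positive tissue-residue endpoints
#' (chronic/sub-chronic no-effect body burdens, ug/kg dw).
#'
#' @param path CSV path.
#' @return A tibble in the toxicity schema.
#' @export
read_toxicity <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(TOXICITY_COLS, names(x))
  if (length(missing)) {
    stopf("schema error: missing columns: %s", paste(missing, collapse = ", "))
  }
  if (any(!x$group %in% c("BT", "PT"))) stopf("`group` must be 'BT' or 'PT'")
  check_positive(x$endpoint_ug_kg_dw, "endpoint_ug_kg_dw")
  as_tibble(x[, TOXICITY_COLS])
}

#' @rdname read_toxicity
#' @param endpoints A tibble in the toxicity schema.
#' @export
write_toxicity <- function(endpoints, path) {
  if (nrow(endpoints) == 0L) stopf("nothing to write")
  write.csv(endpoints[, TOXICITY_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write/read site-level imposex summaries
#'
#' One row per site-year with columns `site_id, year, mean_vdsi, median_vdsi,
#' pct_imposex, pct_sterile_female, rpsi, condition_index, n_females,
#' n_males`. Writing then reading reproduces the table exactly.
#'
#' @param summaries A tibble of summary rows (e.g. from [summarize_site()]).
#' @param path CSV path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_summaries <- function(summaries, path) {
  summaries <- as_tibble(summaries)
  if (nrow(summaries) == 0L) stopf("nothing to write")
  missing <- setdiff(SUMMARY_COLS, names(summaries))
  if (length(missing)) {
    stopf("schema error: missing columns: %s", paste(missing, collapse = ", "))
  }
  write.csv(summaries[, SUMMARY_COLS], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing <- setdiff(SUMMARY_COLS, names(x))
  if (length(missing)) {
    stopf("schema error: missing columns: %s", paste(missing, collapse = ", "))
  }
  as_tibble(x[, SUMMARY_COLS])
}

#' Published Hong Kong imposex survey table (2004-06, 2010, 2015)
#'
#' Returns the packaged transcription of the published site-level monitoring
#' table for 29 rocky-shore sites: mean and median VDSI, percentage imposex,
#' percentage sterile females, RPSI, condition index (2010 and 2015 surveys
#' only) and the distance from each site to the nearest facility with intense
#' shipping activity. Cells the source reports as not available (Heng On in
#' 2010) or not evaluated (the 19 sites not revisited in 2015, and all
#' 2004-06 condition indices) are `NA`.
#'
#' @return A tibble with one row per site x epoch
#'   (`epoch` in `"2004-06"`, `"2010"`, `"2015"`), columns `site_id`,
#'   `site_name`, `epoch`, `mean_vdsi`, `median_vdsi`, `pct_imposex`,
#'   `pct_sterile`, `rpsi`, `condition_index`, `distance_km`.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "hk_imposex_sites.csv", package = "otrisk",
                      mustWork = TRUE)
  x <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  x$epoch <- as.character(x$epoch)
  as_tibble(x)
}
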