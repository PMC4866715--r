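# End-to-end workflow wrappers. These are the programmatic equivalents of a
# command-line front end: each reads the standard CSV schemas, runs one stage
# of the analysis, and writes its output file(s).

#' Survey CSV to site-level imposex summaries
#'
#' @param survey_csv Path to an individual-level survey CSV
#'   (see [read_survey()]).
#' @param out_csv Output path for the summaries CSV.
#' @param sterile_threshold Lowest VDS stage counted as sterile (default 5).
#' @return The summaries tibble, invisibly; `out_csv` is written.
#' @export
run_indices <- function(survey_csv, out_csv,
                        sterile_threshold = 5L) {
  surveys <- read_survey(survey_csv)
  if (length(surveys) == 0L) stopf("no surveys in %s", survey_csv)
  cfg <- imposex_config(sterile_stage_threshold = sterile_threshold)
  summaries <- dplyr::bind_rows(lapply(surveys, summarize_site, config = cfg))
  write_summaries(summaries, out_csv)
  message(sprintf("indices: %d site-years -> %s", nrow(summaries), out_csv))
  invisible(summaries)
}

#' Tissue CSV to site-level chemistry summary
#'
#' @param tissue_csv Path to a tissue panel CSV (see [read_tissue()]).
#' @param out_csv Output path.
#' @param policy Censoring substitution policy.
#' @param moisture_fraction Tissue moisture for the ww-Sn conversion.
#' @return The chemistry summary tibble, invisibly.
#' @export
run_chem <- function(tissue_csv, out_csv, policy = "half_dl",
                     moisture_fraction = 0.80) {
  tissue <- read_tissue(tissue_csv)
  summary <- chem_site_summary(tissue, policy, moisture_fraction)
  write.csv(summary, out_csv, row.names = FALSE, na = "")
  message(sprintf("chem: %d site-years -> %s", nrow(summary), out_csv))
  invisible(summary)
}

#' Tissue + toxicity CSVs to a probabilistic risk report
#'
#' Full chain: censoring substitution, replicate totals, site means (one MTC
#' per site-year for the chosen analyte group), SSD fits for MTC and PNETC,
#' and the Monte-Carlo exceedance probability `P(RQ >= 1)`.
#'
#' @param tissue_csv,toxicity_csv Input CSV paths.
#' @param group `"BT"` (total butyltins) or `"PT"` (total phenyltins).
#' @param out_json Output path for the JSON report.
#' @param policy Censoring substitution policy.
#' @param iterations,repeats,seed Monte-Carlo settings.
#' @return The `risk_report`, invisibly; `out_json` is written.
#' @export
run_risk <- function(tissue_csv, toxicity_csv, group = c("BT", "PT"),
                     out_json, policy = "half_dl", iterations = 10000L,
                     repeats = 10L, seed = 1L) {
  group <- match.arg(group)
  tissue <- read_tissue(tissue_csv)
  endpoints <- read_toxicity(toxicity_csv)
  endpoints <- endpoints[endpoints$group == group, ]
  if (nrow(endpoints) == 0L) stopf("no %s endpoints in %s", group, toxicity_csv)
  chem <- chem_site_summary(tissue, policy)
  mtc <- if (group == "BT") chem$total_bts else chem$total_pts
  inputs <- risk_inputs(mtc, endpoints$endpoint_ug_kg_dw)
  report <- if (group == "BT") {
    risk_report(bt_inputs = inputs, iterations = iterations,
                repeats = repeats, seed = seed)
  } else {
    risk_report(pt_inputs = inputs, iterations = iterations,
                repeats = repeats, seed = seed)
  }
  jsonlite::write_json(risk_report_json(report), out_json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  message(sprintf("risk (%s): P(at risk) = %.4f -> %s", group,
                  report[[group]]$result$p_at_risk, out_json))
  invisible(report)
}

#' Trend tests and correlation tables from a site-level index table
#'
#' Runs the epoch-to-epoch paired comparisons and the distance/index
#' correlation families on a long site-level table (by default the packaged
#' published table) and writes `trends.csv` and `correlations.csv`.
#'
#' @param table1 A tibble in the format of [load_table1_fixture()].
#' @param out_dir Output directory (created if needed).
#' @param alpha Family-wise error rate for the Holm flags.
#' @return A list with elements `trends` and `correlations`, invisibly.
#' @export
run_trends <- function(table1 = load_table1_fixture(), out_dir = ".",
                       alpha = 0.05) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  epochs <- unique(table1$epoch)
  if (length(epochs) < 2L) {
    warning("fewer than two epochs: no paired comparisons possible")
    trends <- tibble()
  } else {
    trends <- epoch_trends(table1)
  }
  cors <- dplyr::bind_rows(lapply(intersect(c("2010", "2015"), epochs),
    function(e) {
      out <- distance_correlations(table1, epoch = e)
      out$epoch <- e
      out
    }))
  if (nrow(trends)) {
    write.csv(trends, file.path(out_dir, "trends.csv"), row.names = FALSE,
              na = "")
  }
  if (nrow(cors)) {
    write.csv(cors, file.path(out_dir, "correlations.csv"),
              row.names = FALSE, na = "")
  }
  message(sprintf("trends: %d comparisons, %d correlations -> %s",
                  nrow(trends), nrow(cors), out_dir))
  invisible(list(trends = trends, correlations = cors))
}

#' Write a full synthetic dataset to disk
#'
#' Generates surveys, tissue panels, and one toxicity endpoint set per group
#' with the given config, and writes `survey.csv`, `tissue.csv`,
#' `toxicity.csv` into `out_dir`.
#'
#' @param config A [generator_config()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
run_simulate <- function(config = generator_config(), out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(survey = file.path(out_dir, "survey.csv"),
             tissue = file.path(out_dir, "tissue.csv"),
             toxicity = file.path(out_dir, "toxicity.csv"))
  write_survey(generate_surveys(config), paths[["survey"]])
  write_tissue(generate_tissue(config), paths[["tissue"]])
  tox <- rbind(
    generate_toxicity("log_logistic", c(alpha = 2000, beta = 2), n = 6L,
                      group = "PT", seed = config$seed + 2L),
    generate_toxicity("log_logistic", c(alpha = 4000, beta = 2.5), n = 6L,
                      group = "BT", seed = config$seed + 3L)
  )
  write_toxicity(tox, paths[["toxicity"]])
  message(sprintf("simulate: seed %d -> %s", config$seed, out_dir))
  invisible(paths)
}
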