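# The six organotin analytes, in butyltin then phenyltin order.
OT_ANALYTES <- c("MBT", "DBT", "TBT", "MPT", "DPT", "TPT")
BT_ANALYTES <- c("MBT", "DBT", "TBT")
PT_ANALYTES <- c("MPT", "DPT", "TPT")

# Organotin cation masses from atomic masses (C 12.011, H 1.008, Sn 118.71):
# R_n Sn^(4-n)+ with R = butyl (C4H9) or phenyl (C6H5).
ot_cation_mass <- local({
  C <- 12.011; H <- 1.008; Sn <- 118.71
  butyl <- 4 * C + 9 * H
  phenyl <- 6 * C + 5 * H
  c(MBT = Sn + butyl, DBT = Sn + 2 * butyl, TBT = Sn + 3 * butyl,
    MPT = Sn + phenyl, DPT = Sn + 2 * phenyl, TPT = Sn + 3 * phenyl)
})

#' Tin mass fraction of an organotin cation
#'
#' Fraction of the cation mass contributed by the tin atom (Sn 118.71 g/mol),
#' used to express compound concentrations as tin equivalents.
#'
#' @param analyte One of `"MBT"`, `"DBT"`, `"TBT"`, `"MPT"`, `"DPT"`,
#'   `"TPT"` (vectorised).
#' @return Tin mass fractions in (0, 1).
#' @export
tin_fraction <- function(analyte) {
  bad <- setdiff(unique(analyte), OT_ANALYTES)
  if (length(bad)) stopf("unknown analyte: %s", paste(bad, collapse = ", "))
  unname(118.71 / ot_cation_mass[analyte])
}

#' Convert a dry-weight compound concentration to wet-weight tin equivalents
#'
#' Biomonitoring programmes report tissue residues either as ug of compound
#' per kg dry weight or as ug Sn per kg wet weight. With a tissue moisture
#' fraction `m`, 1 kg ww contains `(1 - m)` kg dw, so
#' `value_ww_Sn = value_dw * tin_fraction(analyte) * (1 - m)`.
#'
#' @param value Concentration in ug compound / kg dw (>= 0, vectorised).
#' @param analyte Analyte code (recycled against `value`).
#' @param moisture_fraction Tissue water content, default 0.80 (gastropod
#'   soft tissue is roughly 80% water).
#' @return Concentration in ug Sn / kg ww.
#' @export
dw_to_ww_sn <- function(value, analyte, moisture_fraction = 0.80) {
  if (any(!is.finite(value)) || any(value < 0)) stopf("`value` must be >= 0")
  if (any(moisture_fraction < 0) || any(moisture_fraction >= 1)) {
    stopf("`moisture_fraction` must be in [0, 1)")
  }
  value * tin_fraction(analyte) * (1 - moisture_fraction)
}

check_tissue <- function(tissue) {
  tissue <- as_tibble(tissue)
  missing <- setdiff(TISSUE_COLS, names(tissue))
  if (length(missing)) {
    stopf("tissue table is missing columns: %s", paste(missing, collapse = ", "))
  }
  bad <- setdiff(unique(tissue$analyte), OT_ANALYTES)
  if (length(bad)) stopf("unknown analyte: %s", paste(bad, collapse = ", "))
  tissue
}

#' Substitute left-censored concentrations
#'
#' Values flagged below the detection limit are replaced according to a
#' substitution policy; the `censored` flag itself is retained so downstream
#' analyses can still identify (or drop) censored-dominated replicates.
#'
#' @param tissue A tissue panel tibble (see [read_tissue()]).
#' @param policy `"half_dl"` (default, the common ecotoxicology convention),
#'   `"zero"`, or `"dl"`.
#' @return The tissue tibble with censored `value_ug_kg_dw` substituted.
#' @export
substitute_censored <- function(tissue,
                                policy = c("half_dl", "zero", "dl")) {
  policy <- match.arg(policy)
  tissue <- check_tissue(tissue)
  cen <- which(tissue$censored)
  if (length(cen)) {
    dl <- tissue$detection_limit[cen]
    if (any(!is.finite(dl) | dl <= 0)) {
      stopf("censored entries must carry a positive detection limit")
    }
    tissue$value_ug_kg_dw[cen] <- switch(policy,
      half_dl = dl / 2, zero = 0, dl = dl)
  }
  tissue
}

#' Organotin totals per replicate
#'
#' Sums the six-analyte panel into total organotins, total butyltins
#' (MBT + DBT + TBT) and total phenyltins (MPT + DPT + TPT) for every
#' `(site_id, year, replicate_id)`. Censoring substitution must already have
#' been applied (values must be numeric and non-negative).
#'
#' @param tissue A substituted tissue tibble.
#' @return A tibble with `site_id, year, replicate_id, total_ots, total_bts,
#'   total_pts`.
#' @export
total_ots <- function(tissue) {
  tissue <- check_tissue(tissue)
  if (any(!is.finite(tissue$value_ug_kg_dw) | tissue$value_ug_kg_dw < 0)) {
    stopf("values must be non-negative; apply substitute_censored() first")
  }
  tissue |>
    dplyr::group_by(.data$site_id, .data$year, .data$replicate_id) |>
    dplyr::summarise(
      total_ots = sum(.data$value_ug_kg_dw),
      total_bts = sum(.data$value_ug_kg_dw[.data$analyte %in% BT_ANALYTES]),
      total_pts = sum(.data$value_ug_kg_dw[.data$analyte %in% PT_ANALYTES]),
      .groups = "drop"
    )
}

#' Composition percentage of each analyte
#'
#' Share of each analyte in the replicate's total organotin burden.
#'
#' @param tissue A substituted tissue tibble.
#' @param analyte Optional analyte code to filter the result to.
#' @return A tibble with `site_id, year, replicate_id, analyte, pct`.
#' @export
composition_pct <- function(tissue, analyte = NULL) {
  tissue <- check_tissue(tissue)
  out <- tissue |>
    dplyr::group_by(.data$site_id, .data$year, .data$replicate_id) |>
    dplyr::mutate(total = sum(.data$value_ug_kg_dw)) |>
    dplyr::ungroup()
  if (any(out$total <= 0)) stopf("replicate with zero total organotins")
  out$pct <- 100 * out$value_ug_kg_dw / out$total
  out <- out[, c("site_id", "year", "replicate_id", "analyte", "pct")]
  if (!is.null(analyte)) {
    if (!analyte %in% OT_ANALYTES) stopf("unknown analyte: %s", analyte)
    out <- out[out$analyte == analyte, ]
  }
  out
}

#' Butyltin and phenyltin degradation indices
#'
#' `BDI = ([MBT] + [DBT]) / [TBT]` and `PDI = ([MPT] + [DPT]) / [TPT]`,
#' computed per replicate. Values above 1 indicate aged inputs dominated by
#' degradation products; values below 1 indicate recent inputs of the parent
#' triorganotin. A zero denominator leaves the index `NA` with its
#' `*_defined` flag set to `FALSE` (not an error: a site can be TBT-free).
#'
#' @param tissue A substituted tissue tibble.
#' @return A tibble with `site_id, year, replicate_id, bdi, bdi_defined,
#'   pdi, pdi_defined`.
#' @export
degradation_indices <- function(tissue) {
  tissue <- check_tissue(tissue)
  val <- function(block, a) {
    v <- block$value_ug_kg_dw[block$analyte == a]
    if (length(v) == 0L) 0 else sum(v)
  }
  tissue |>
    dplyr::group_by(.data$site_id, .data$year, .data$replicate_id) |>
    dplyr::group_modify(function(block, key) {
      tbt <- val(block, "TBT"); tpt <- val(block, "TPT")
      tibble(
        bdi = if (tbt > 0) (val(block, "MBT") + val(block, "DBT")) / tbt else NA_real_,
        bdi_defined = tbt > 0,
        pdi = if (tpt > 0) (val(block, "MPT") + val(block, "DPT")) / tpt else NA_real_,
        pdi_defined = tpt > 0
      )
    }) |>
    dplyr::ungroup()
}

#' Site-level chemistry summary
#'
#' Applies censoring substitution, averages the analytical replicates (each a
#' pool of 8--15 snails) per site-year, and derives totals, TPT composition,
#' degradation indices and wet-weight tin-equivalent totals from the mean
#' analyte concentrations.
#'
#' @param tissue A tissue tibble (censored entries still flagged).
#' @param policy Censoring substitution policy, see [substitute_censored()].
#' @param moisture_fraction Tissue moisture for the ww conversion.
#' @return A tibble with one row per site-year: mean analyte columns, totals
#'   (`total_ots`, `total_bts`, `total_pts`), `tpt_pct`, `bdi`, `pdi`, and
#'   `total_ots_sn_ww` (ug Sn / kg ww).
#' @export
chem_site_summary <- function(tissue, policy = "half_dl",
                              moisture_fraction = 0.80) {
  tissue <- substitute_censored(tissue, policy)
  means <- tissue |>
    dplyr::group_by(.data$site_id, .data$year, .data$analyte) |>
    dplyr::summarise(value = mean(.data$value_ug_kg_dw), .groups = "drop")
  wide <- as_tibble(stats::reshape(
    as.data.frame(means), idvar = c("site_id", "year"),
    timevar = "analyte", direction = "wide"
  ))
  names(wide) <- sub("^value\\.", "", names(wide))
  for (a in OT_ANALYTES) if (!a %in% names(wide)) wide[[a]] <- 0
  wide[is.na(wide)] <- 0
  wide$total_bts <- wide$MBT + wide$DBT + wide$TBT
  wide$total_pts <- wide$MPT + wide$DPT + wide$TPT
  wide$total_ots <- wide$total_bts + wide$total_pts
  wide$tpt_pct <- ifelse(wide$total_ots > 0, 100 * wide$TPT / wide$total_ots, NA)
  wide$bdi <- ifelse(wide$TBT > 0, (wide$MBT + wide$DBT) / wide$TBT, NA)
  wide$pdi <- ifelse(wide$TPT > 0, (wide$MPT + wide$DPT) / wide$TPT, NA)
  sn <- vapply(OT_ANALYTES, function(a) {
    dw_to_ww_sn(wide[[a]], a, moisture_fraction)
  }, numeric(nrow(wide)))
  wide$total_ots_sn_ww <- if (nrow(wide) == 1L) sum(sn) else rowSums(sn)
  wide[order(wide$year, wide$site_id),
       c("site_id", "year", OT_ANALYTES, "total_ots", "total_bts",
         "total_pts", "tpt_pct", "bdi", "pdi", "total_ots_sn_ww")]
}
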