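#' Configuration for imposex index calculations
#'
#' @param sterile_stage_threshold Lowest vas-deferens stage counted as
#'   reproductively sterile. Stages 5 and 6 block the oviduct, so the
#'   default is 5.
#' @param rpsi_exponent Exponent of the penis-length ratio in RPSI. The
#'   classical index cubes the ratio (penis bulk scales with length^3).
#' @return A list of class `imposex_config`.
#' @export
imposex_config <- function(sterile_stage_threshold = 5L, rpsi_exponent = 3L) {
  if (!sterile_stage_threshold %in% 1:6) {
    stopf("`sterile_stage_threshold` must be in 1..6")
  }
  if (rpsi_exponent < 1) stopf("`rpsi_exponent` must be >= 1")
  structure(list(sterile_stage_threshold = as.integer(sterile_stage_threshold),
                 rpsi_exponent = as.integer(rpsi_exponent)),
            class = "imposex_config")
}

check_stages <- function(stages) {
  if (length(stages) == 0L) stopf("no female VDS stages supplied")
  if (any(is.na(stages)) || any(stages < 0 | stages > 6)) {
    stopf("VDS stages must be in 0..6 with no missing values")
  }
  stages
}

#' Vas Deferens Sequence Index
#'
#' Mean and median imposex stage (0--6) over the females of a site.
#'
#' @param stages Integer vector of female VDS stages (0--6).
#' @return A list with elements `mean` and `median`.
#' @export
vdsi <- function(stages) {
  stages <- check_stages(stages)
  list(mean = mean(stages), median = median(stages))
}

#' Relative Penis Size Index
#'
#' `100 * (mean female penis length / mean male penis length)^3` (the
#' exponent is configurable). Females whose imposex penis is too small to
#' measure enter the female mean as 0 mm, which keeps the index defined and
#' conservative.
#'
#' @param female_lengths,male_lengths Penis lengths in mm (females may be 0).
#' @param config An [imposex_config()].
#' @return RPSI as a percentage (>= 0).
#' @export
rpsi <- function(female_lengths, male_lengths, config = imposex_config()) {
  if (length(male_lengths) == 0L) stopf("RPSI needs at least one male")
  if (length(female_lengths) == 0L) stopf("RPSI needs at least one female")
  female_lengths[is.na(female_lengths)] <- 0
  if (any(is.na(male_lengths)) || any(male_lengths < 0)) {
    stopf("male penis lengths must be non-negative and non-missing")
  }
  m <- mean(male_lengths)
  if (m <= 0) stopf("mean male penis length is zero; RPSI undefined")
  100 * (mean(female_lengths) / m)^config$rpsi_exponent
}

#' Percentage of females displaying imposex
#'
#' @inheritParams vdsi
#' @return Percentage of females with VDS stage > 0.
#' @export
pct_imposex <- function(stages) {
  stages <- check_stages(stages)
  100 * mean(stages > 0)
}

#' Percentage of sterile females
#'
#' @inheritParams vdsi
#' @inheritParams rpsi
#' @return Percentage of females at or above the sterile stage threshold.
#' @export
pct_sterile <- function(stages, config = imposex_config()) {
  stages <- check_stages(stages)
  100 * mean(stages >= config$sterile_stage_threshold)
}

#' Body condition index
#'
#' `fresh tissue weight x 100 / (fresh tissue weight + dry shell mass)`,
#' i.e. the soft-tissue share of total mass, in (0, 100).
#'
#' @param fresh_tissue_g,dry_shell_g Masses in grams (> 0). Vectorised.
#' @return Condition index values.
#' @export
condition_index <- function(fresh_tissue_g, dry_shell_g) {
  check_positive(fresh_tissue_g, "fresh_tissue_g")
  check_positive(dry_shell_g, "dry_shell_g")
  fresh_tissue_g * 100 / (fresh_tissue_g + dry_shell_g)
}

#' Summarise one site survey into a table row
#'
#' Computes all imposex indices and the mean condition index (over all
#' individuals of both sexes with both masses recorded) for one
#' [site_survey()].
#'
#' @param survey A `site_survey`.
#' @param config An [imposex_config()].
#' @return A one-row tibble in the summaries schema (see [write_summaries()]).
#' @export
summarize_site <- function(survey, config = imposex_config()) {
  stopifnot(inherits(survey, "site_survey"))
  ind <- survey$individuals
  females <- ind[ind$sex == "female", ]
  males <- ind[ind$sex == "male", ]
  if (nrow(females) == 0L) stopf("site %s has no females", survey$site_id)
  stages <- females$vds_stage
  v <- vdsi(stages)
  ci <- condition_index(
    ind$fresh_tissue_g[!is.na(ind$fresh_tissue_g) & !is.na(ind$dry_shell_g)],
    ind$dry_shell_g[!is.na(ind$fresh_tissue_g) & !is.na(ind$dry_shell_g)]
  )
  tibble(
    site_id = survey$site_id, year = survey$year,
    mean_vdsi = v$mean, median_vdsi = v$median,
    pct_imposex = pct_imposex(stages),
    pct_sterile_female = pct_sterile(stages, config),
    rpsi = rpsi(females$penis_length_mm, males$penis_length_mm, config),
    condition_index = mean(ci),
    n_females = nrow(females), n_males = nrow(males)
  )
}
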