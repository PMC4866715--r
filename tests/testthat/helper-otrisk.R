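# Shared builders and independent oracles for the test suite.

# One-replicate tissue panel from a named analyte vector.
make_panel <- function(values, site_id = 1L, year = 2010L,
                       replicate_id = 1L, censored = FALSE,
                       detection_limit = 1.0) {
  tibble::tibble(
    site_id = site_id, year = year, replicate_id = replicate_id,
    analyte = names(values), value_ug_kg_dw = unname(values),
    censored = rep_len(censored, length(values)),
    detection_limit = rep_len(detection_limit, length(values))
  )
}

# A small balanced survey with explicit female stages and penis lengths.
make_survey <- function(stages, female_penis, male_penis,
                        site_id = 1L, year = 2010L, distance_km = 1) {
  n_f <- length(stages); n_m <- length(male_penis)
  stopifnot(length(female_penis) == n_f)
  site_survey(
    site_id = site_id, site_name = "test", year = year,
    distance_km = distance_km,
    individuals = tibble::tibble(
      animal_id = sprintf("a%02d", seq_len(n_f + n_m)),
      sex = c(rep("female", n_f), rep("male", n_m)),
      shell_length_mm = 25,
      fresh_tissue_g = 1.5, dry_shell_g = 6,
      penis_length_mm = c(female_penis, male_penis),
      vds_stage = c(stages, rep(NA_integer_, n_m))
    )
  )
}

# Quadrature oracle for P(MTC / PNETC >= 1) under two fitted distributions:
# P(MTC >= PNETC) = E_PNETC[1 - F_MTC(PNETC)], integrated over the PNETC
# probability scale. Uses only the closed-form CDF/quantile, never the
# Monte-Carlo sampler.
quad_exceedance <- function(mtc_dist, pnetc_dist) {
  stats::integrate(function(u) {
    1 - ssd_cdf(mtc_dist, ssd_quantile(pnetc_dist, u))
  }, 0, 1, rel.tol = 1e-9)$value
}

# Exact two-sided signed-rank p-value by enumerating all 2^n sign patterns
# on the midranks of |d| (zeros dropped first).
exact_wilcoxon_p <- function(x, y) {
  d <- y - x
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}
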