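test_that("generation is deterministic for a fixed seed", {
  cfg <- generator_config(n_sites = 4, seed = 123)
  s1 <- generate_surveys(cfg); s2 <- generate_surveys(cfg)
  expect_identical(lapply(s1, unclass), lapply(s2, unclass))
  expect_identical(as.data.frame(generate_tissue(cfg)),
                   as.data.frame(generate_tissue(cfg)))
  t1 <- generate_toxicity("log_logistic", c(alpha = 100, beta = 2), seed = 6)
  t2 <- generate_toxicity("log_logistic", c(alpha = 100, beta = 2), seed = 6)
  expect_identical(t1$endpoint_ug_kg_dw, t2$endpoint_ug_kg_dw)
  # different seeds move the draws
  t3 <- generate_toxicity("log_logistic", c(alpha = 100, beta = 2), seed = 7)
  expect_false(identical(t1$endpoint_ug_kg_dw, t3$endpoint_ug_kg_dw))
})

test_that("a degenerate stage distribution propagates to every site index", {
  cfg <- generator_config(n_sites = 3, seed = 2,
                          stage_probs = c(0, 0, 0, 0, 1, 0, 0))
  for (s in generate_surveys(cfg)) {
    expect_equal(summarize_site(s)$mean_vdsi, 4.0)
  }
})

test_that("surveys respect the documented ranges and structure", {
  cfg <- generator_config(n_sites = 8, seed = 31)
  surveys <- generate_surveys(cfg)
  expect_length(surveys, 8)
  for (s in surveys) {
    ind <- s$individuals
    expect_equal(nrow(ind), 40)
    expect_true(all(ind$shell_length_mm >= 17 & ind$shell_length_mm <= 36))
    stages <- ind$vds_stage[ind$sex == "female"]
    expect_true(all(stages %in% 0:6))
    expect_true(all(is.na(ind$vds_stage[ind$sex == "male"])))
  }
})

test_that("the exposure gradient induces the expected censoring and composition", {
  # geometric means far above the detection limits: nothing censored
  clean <- generator_config(n_sites = 5, seed = 3,
                            analyte_gm = c(MBT = 500, DBT = 500, TBT = 500,
                                           MPT = 500, DPT = 500, TPT = 5000))
  expect_equal(sum(generate_tissue(clean)$censored), 0)

  # geometric mean at DL/10: the lognormal tail puts ~all draws below DL
  # (P(X < DL) = Phi(log 10 / log gsd) ~ 0.9998 at the default gsd 1.9)
  dim_cfg <- generator_config(n_sites = 5, seed = 3, exposure_sdlog = 0,
                              exposure_a = 0, exposure_b = 0,
                              analyte_gm = c(MBT = 0.15, DBT = 0.08,
                                             TBT = 0.05, MPT = 0.1,
                                             DPT = 0.04, TPT = 0.02))
  tis <- generate_tissue(dim_cfg)
  expect_gt(mean(tis$censored), 0.5)

  # TPT an order of magnitude above the rest dominates every site's total
  comp <- composition_pct(substitute_censored(generate_tissue(
    generator_config(n_sites = 6, seed = 5))), "TPT")
  agg <- tapply(comp$pct, comp$site_id, mean)
  expect_true(all(agg > 50))
})

test_that("a distance-decaying exposure yields a negative distance trend", {
  cfg <- generator_config(n_sites = 20, seed = 77)
  surveys <- generate_surveys(cfg)
  summaries <- dplyr::bind_rows(lapply(surveys, summarize_site))
  s <- spearman(cfg$distance_km, summaries$mean_vdsi)
  expect_lt(s$rho, 0)
  expect_lt(s$p_value, 0.05)
})

test_that("toxicity draws are positive and the truth is recoverable", {
  tox <- generate_toxicity("log_logistic", c(alpha = 100, beta = 2), n = 6,
                           seed = 40)
  expect_true(all(tox$endpoint_ug_kg_dw > 0))
  expect_equal(attr(tox, "truth")$family, "log_logistic")

  big <- generate_toxicity("log_logistic", c(alpha = 100, beta = 2),
                           n = 5000, seed = 41)
  f <- fit_loglogistic(big$endpoint_ug_kg_dw)
  expect_lt(abs(f$pars[["alpha"]] - 100) / 100, 0.05)

  two <- generate_toxicity("pareto", c(xm = 10, shape = 2), n = 2, seed = 1)
  expect_error(select_distribution(two$endpoint_ug_kg_dw), "n >= 3")
})
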