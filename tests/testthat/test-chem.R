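six <- function(mbt, dbt, tbt, mpt, dpt, tpt) {
  c(MBT = mbt, DBT = dbt, TBT = tbt, MPT = mpt, DPT = dpt, TPT = tpt)
}

test_that("censoring substitution follows the chosen policy", {
  panel <- make_panel(c(TBT = NA_real_, TPT = 50), censored = c(TRUE, FALSE),
                      detection_limit = c(1.0, 0.2))
  expect_equal(substitute_censored(panel, "half_dl")$value_ug_kg_dw, c(0.5, 50))
  expect_equal(substitute_censored(panel, "zero")$value_ug_kg_dw, c(0, 50))
  expect_equal(substitute_censored(panel, "dl")$value_ug_kg_dw, c(1.0, 50))
  expect_true(all(substitute_censored(panel)$censored == c(TRUE, FALSE)))

  clean <- make_panel(six(1, 1, 1, 1, 1, 1))
  expect_equal(substitute_censored(clean), clean)

  no_dl <- make_panel(c(TBT = NA_real_), censored = TRUE,
                      detection_limit = NA_real_)
  expect_error(substitute_censored(no_dl), "detection limit")
})

test_that("totals split into butyltin and phenyltin sums", {
  t1 <- total_ots(make_panel(six(1, 1, 1, 1, 1, 1)))
  expect_equal(c(t1$total_ots, t1$total_bts, t1$total_pts), c(6, 3, 3))

  t2 <- total_ots(make_panel(c(TPT = 500)))
  expect_equal(c(t2$total_ots, t2$total_bts, t2$total_pts), c(500, 0, 500))

  t3 <- total_ots(make_panel(six(10, 20, 40, 5, 15, 300)))
  expect_equal(c(t3$total_ots, t3$total_bts, t3$total_pts), c(390, 70, 320))

  expect_error(total_ots(make_panel(c(TBT = -1))), "non-negative")
})

test_that("composition percentages are shares of the replicate total", {
  panel <- make_panel(six(10, 20, 40, 5, 15, 300))
  tpt <- composition_pct(panel, "TPT")
  expect_equal(tpt$pct, 100 * 300 / 390, tolerance = 1e-9)

  expect_equal(composition_pct(make_panel(c(TPT = 500)))$pct, 100.0)
  expect_error(composition_pct(make_panel(six(0, 0, 0, 0, 0, 0))), "zero total")

  # shares over the six analytes always sum to 100
  set.seed(42)
  for (i in 1:5) {
    p <- make_panel(six(runif(1, 0, 50), runif(1, 0, 50), runif(1, 0, 400),
                        runif(1, 0, 30), runif(1, 0, 60), runif(1, 0, 9000)))
    expect_equal(sum(composition_pct(p)$pct), 100, tolerance = 1e-9)
  }
})

test_that("degradation indices flag undefined denominators instead of erroring", {
  d1 <- degradation_indices(make_panel(six(10, 10, 40, 0, 0, 100)))
  expect_equal(d1$bdi, 0.5)
  expect_true(d1$bdi_defined)
  expect_equal(d1$pdi, 0.0)

  d2 <- degradation_indices(make_panel(six(10, 10, 0, 5, 5, 100)))
  expect_false(d2$bdi_defined)
  expect_true(is.na(d2$bdi))
  expect_equal(d2$pdi, 0.1)
})

test_that("tin fractions come from cation masses built of C, H and Sn", {
  C <- 12.011; H <- 1.008; Sn <- 118.71
  butyl <- 4 * C + 9 * H; phenyl <- 6 * C + 5 * H
  expected <- Sn / c(MBT = Sn + butyl, DBT = Sn + 2 * butyl,
                     TBT = Sn + 3 * butyl, MPT = Sn + phenyl,
                     DPT = Sn + 2 * phenyl, TPT = Sn + 3 * phenyl)
  got <- tin_fraction(names(expected))
  expect_equal(got, unname(expected), tolerance = 1e-12)
  expect_true(all(got > 0 & got < 1))
  expect_error(tin_fraction("XBT"), "unknown analyte")
})

test_that("dw to ww-Sn conversion is linear in value and decreasing in moisture", {
  expect_equal(dw_to_ww_sn(0, "TBT"), 0)
  v <- dw_to_ww_sn(c(100, 200), "TPT")
  expect_equal(v[2], 2 * v[1], tolerance = 1e-12)
  expect_gt(dw_to_ww_sn(100, "TBT", 0.7), dw_to_ww_sn(100, "TBT", 0.8))
  expect_error(dw_to_ww_sn(-5, "TBT"), ">= 0")
})

test_that("the site summary averages replicates and keeps totals additive", {
  tissue <- generate_tissue(generator_config(n_sites = 6, seed = 9))
  cs <- chem_site_summary(tissue)
  expect_equal(nrow(cs), 6)
  expect_equal(cs$total_ots, cs$total_bts + cs$total_pts, tolerance = 1e-12)
  expect_equal(cs$total_bts, cs$MBT + cs$DBT + cs$TBT, tolerance = 1e-12)
  # replicate means recomputed by hand for one site
  sub <- substitute_censored(tissue[tissue$site_id == 1, ])
  expect_equal(cs$TPT[cs$site_id == 1],
               mean(tapply(sub$value_ug_kg_dw[sub$analyte == "TPT"],
                           sub$replicate_id[sub$analyte == "TPT"], mean)))
})
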