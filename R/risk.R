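# Probabilistic tissue-residue risk: RQ = MTC / PNETC, risk when RQ >= 1.

#' Bundle measured and no-effect tissue concentrations for risk analysis
#'
#' @param mtc_values Site-level measured tissue concentrations (one value per
#'   site-year, ug/kg dw of total butyltins or total phenyltins), all > 0.
#' @param pnetc_values Literature no-effect tissue-residue endpoints
#'   (ug/kg dw), all > 0, at least 3 (a 2-point MLE of a 2-parameter family
#'   is degenerate).
#' @return A list of class `risk_inputs`.
#' @export
risk_inputs <- function(mtc_values, pnetc_values) {
  check_positive(mtc_values, "mtc_values")
  check_positive(pnetc_values, "pnetc_values")
  if (length(pnetc_values) < 3L) stopf("need at least 3 PNETC endpoints")
  if (length(mtc_values) < 3L) stopf("need at least 3 MTC values")
  structure(list(mtc_values = as.numeric(mtc_values),
                 pnetc_values = as.numeric(pnetc_values)),
            class = "risk_inputs")
}

#' Monte-Carlo exceedance probability of the risk quotient
#'
#' Fits a species-sensitivity-style distribution to the measured tissue
#' concentrations (MTC) and to the no-effect endpoints (PNETC) with
#' [select_distribution()], then repeatedly draws independent (MTC, PNETC)
#' pairs, forms `RQ = MTC / PNETC`, truncates at `RQ >= 0` (vacuous for
#' positive-support families, retained for config extensibility) and
#' estimates `P(RQ >= 1)` as the exceedance fraction. The estimate is the
#' mean over `repeats` independent repetitions of `iterations` draws; their
#' spread is reported alongside.
#'
#' @param inputs A [risk_inputs()] object.
#' @param iterations Draws per repetition (default 10000).
#' @param repeats Number of repetitions averaged (default 10).
#' @param seed Integer seed; per-repeat substreams are derived from it, so a
#'   run is fully reproducible.
#' @param mtc_dist,pnetc_dist Optional pre-fitted `fitted_dist` objects that
#'   bypass the automatic selection (used e.g. to replay a fixed family).
#' @return A list of class `risk_result` with elements `p_at_risk`,
#'   `repeat_values`, `sd_over_repeats`, `rq_quantiles` (5/50/95% of the
#'   pooled RQ draws), `iterations`, `repeats`, `seed`, `mtc_dist`,
#'   `pnetc_dist`.
#' @export
monte_carlo_rq <- function(inputs, iterations = 10000L, repeats = 10L,
                           seed = 1L, mtc_dist = NULL, pnetc_dist = NULL) {
  if (iterations < 1L || repeats < 1L) stopf("iterations and repeats must be >= 1")
  if (is.null(mtc_dist) || is.null(pnetc_dist)) {
    if (!inherits(inputs, "risk_inputs")) {
      stopf("`inputs` must be a risk_inputs object (or supply fitted dists)")
    }
    mtc_dist <- mtc_dist %||% select_distribution(inputs$mtc_values)
    pnetc_dist <- pnetc_dist %||% select_distribution(inputs$pnetc_values)
  }
  stopifnot(inherits(mtc_dist, "fitted_dist"),
            inherits(pnetc_dist, "fitted_dist"))
  set.seed(as.integer(seed))
  repeat_seeds <- sample.int(.Machine$integer.max, repeats)
  repeat_values <- numeric(repeats)
  qprobs <- c(0.05, 0.5, 0.95)
  # streaming pooled quantiles would need all draws; keep them (bounded:
  # repeats x iterations doubles, ~16 MB at the default 1e5)
  pooled <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    set.seed(repeat_seeds[r])
    mtc <- ssd_sample(mtc_dist, iterations)
    pnetc <- ssd_sample(pnetc_dist, iterations)
    rq <- mtc / pnetc
    rq <- rq[rq >= 0]
    repeat_values[r] <- mean(rq >= 1)
    pooled[[r]] <- rq
  }
  rq_all <- unlist(pooled)
  structure(
    list(p_at_risk = mean(repeat_values), repeat_values = repeat_values,
         sd_over_repeats = sd(repeat_values),
         rq_quantiles = setNames(quantile(rq_all, qprobs, names = FALSE),
                                 c("q05", "q50", "q95")),
         iterations = as.integer(iterations), repeats = as.integer(repeats),
         seed = as.integer(seed), mtc_dist = mtc_dist,
         pnetc_dist = pnetc_dist),
    class = "risk_result"
  )
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf(
    "<risk_result> P(RQ >= 1) = %.4f (sd over %d repeats: %.4f)\n  MTC: %s  PNETC: %s\n  RQ quantiles (5/50/95%%): %.3g / %.3g / %.3g\n",
    x$p_at_risk, x$repeats, x$sd_over_repeats,
    x$mtc_dist$family, x$pnetc_dist$family,
    x$rq_quantiles[1], x$rq_quantiles[2], x$rq_quantiles[3]))
  invisible(x)
}

#' Full risk report for butyltins and phenyltins
#'
#' Runs [monte_carlo_rq()] per analyte group and tallies the "severely
#' impacted" sites: those whose measured tissue concentration exceeds the
#' lowest no-effect endpoint of the group.
#'
#' @param bt_inputs,pt_inputs [risk_inputs()] for total butyltins and total
#'   phenyltins; either may be `NULL` to skip the group.
#' @param iterations,repeats,seed Passed to [monte_carlo_rq()]. The first
#'   group present uses `seed`, the second `seed + 1`, so the two groups
#'   consume independent substreams.
#' @return A list of class `risk_report` with one entry per group, each
#'   holding the `risk_result`, both candidate fits, and
#'   `n_sites_above_min_pnetc`.
#' @export
risk_report <- function(bt_inputs = NULL, pt_inputs = NULL,
                        iterations = 10000L, repeats = 10L, seed = 1L) {
  if (is.null(bt_inputs) && is.null(pt_inputs)) {
    stopf("supply at least one of bt_inputs / pt_inputs")
  }
  one <- function(inputs, group, seed) {
    res <- monte_carlo_rq(inputs, iterations, repeats, seed)
    list(group = group, result = res,
         mtc_candidates = attr(res$mtc_dist, "candidates"),
         pnetc_candidates = attr(res$pnetc_dist, "candidates"),
         n_sites = length(inputs$mtc_values),
         n_sites_above_min_pnetc =
           sum(inputs$mtc_values > min(inputs$pnetc_values)))
  }
  out <- list()
  next_seed <- as.integer(seed)
  if (!is.null(bt_inputs)) {
    out$BT <- one(bt_inputs, "BT", next_seed)
    next_seed <- next_seed + 1L
  }
  if (!is.null(pt_inputs)) out$PT <- one(pt_inputs, "PT", next_seed)
  structure(c(out, list(iterations = as.integer(iterations),
                        repeats = as.integer(repeats),
                        seed = as.integer(seed))),
            class = "risk_report")
}

#' @export
print.risk_report <- function(x, ...) {
  for (g in intersect(c("BT", "PT"), names(x))) {
    cat(sprintf("%s: P(at risk) = %.3f; %d/%d sites above the lowest PNETC\n",
                g, x[[g]]$result$p_at_risk, x[[g]]$n_sites_above_min_pnetc,
                x[[g]]$n_sites))
  }
  invisible(x)
}

# Serialisable view of a risk report (used by run_risk() and tests).
risk_report_json <- function(report) {
  dist_json <- function(d) list(
    family = d$family, pars = as.list(d$pars), n_obs = d$n_obs,
    ks = signif(d$gof_statistic, 6), aic = signif(d$aic, 6)
  )
  grp <- function(g) list(
    p_at_risk = signif(g$result$p_at_risk, 6),
    sd_over_repeats = signif(g$result$sd_over_repeats, 6),
    repeat_values = signif(g$result$repeat_values, 6),
    rq_quantiles = as.list(signif(g$result$rq_quantiles, 6)),
    mtc = dist_json(g$result$mtc_dist),
    pnetc = dist_json(g$result$pnetc_dist),
    n_sites = g$n_sites,
    n_sites_above_min_pnetc = g$n_sites_above_min_pnetc
  )
  out <- list(schema = "otrisk/risk_report/1",
              iterations = report$iterations, repeats = report$repeats,
              seed = report$seed)
  for (g in intersect(c("BT", "PT"), names(report))) out[[g]] <- grp(report[[g]])
  out
}

#' Export the fitted and empirical SSD curves
#'
#' Tabulates the fitted CDF of a `fitted_dist` together with the empirical
#' CDF of the sample it was fitted to, for plotting.
#'
#' @param dist A `fitted_dist`.
#' @param values The sample (used for the empirical CDF and the x-range).
#' @param n_grid Number of log-spaced grid points.
#' @return A tibble with `x`, `fitted_cdf`, and (at sample points only)
#'   `empirical_cdf`.
#' @export
ssd_curve <- function(dist, values, n_grid = 200L) {
  check_positive(values, "values")
  grid <- exp(seq(log(min(values) / 10), log(max(values) * 10),
                  length.out = n_grid))
  x <- sort(unique(c(grid, values)))
  emp <- rep(NA_real_, length(x))
  idx <- match(sort(values), x)
  emp[idx] <- seq_along(values) / length(values)
  tibble(x = x, fitted_cdf = ssd_cdf(dist, x), empirical_cdf = emp)
}
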