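# Paired temporal comparisons and rank correlations for site-level indices.

drop_incomplete_pairs <- function(x, y) {
  if (length(x) != length(y)) stopf("`x` and `y` must have equal length")
  ok <- !is.na(x) & !is.na(y)
  list(x = x[ok], y = y[ok])
}

#' Paired t test on log10-transformed data
#'
#' Classical paired t test on `d_i = log10(y_i) - log10(x_i)` (so a positive
#' statistic means `y` exceeds `x`), two-sided. Pairs with a missing member
#' are dropped first; all retained values must be strictly positive.
#'
#' @param x,y Paired positive measurements (e.g. one site-level index in two
#'   survey epochs, aligned by site).
#' @return A list of class `paired_test` with `statistic`, `df`, `p_value`,
#'   `n_pairs`, `method`.
#' @export
paired_t_log10 <- function(x, y) {
  p <- drop_incomplete_pairs(x, y)
  if (length(p$x) < 2L) stopf("need at least 2 complete pairs")
  check_positive(p$x, "x")
  check_positive(p$y, "y")
  d <- log10(p$y) - log10(p$x)
  if (sd(d) == 0) stopf("degenerate: zero variance of paired differences")
  tt <- t.test(d)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value, n_pairs = length(d),
                 method = "paired_t_log10"),
            class = "paired_test")
}

#' Wilcoxon signed-rank test (normal approximation, tie-corrected)
#'
#' The dialect used by mainstream statistical GUIs for paired ordinal data:
#' zero differences are dropped, absolute differences are midranked,
#' `W+` is the rank sum of positive differences, and
#' `Z = (W+ - n(n+1)/4) / sigma` with the tie-corrected variance
#' `sigma^2 = n(n+1)(2n+1)/24 - sum(t^3 - t)/48` over tie groups `t`.
#' No continuity correction is applied; the two-sided p-value comes from the
#' normal approximation. The sign of `Z` is positive when `y` tends to
#' exceed `x`.
#'
#' @inheritParams paired_t_log10
#' @return A list of class `paired_test` with `statistic` (Z), `w_plus`,
#'   `p_value`, `n_pairs` (non-zero differences), `method`.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  p <- drop_incomplete_pairs(x, y)
  d <- p$y - p$x
  d <- d[d != 0]
  n <- length(d)
  if (n < 1L) stopf("degenerate: all paired differences are zero")
  r <- rank(abs(d))
  w_plus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sigma2 <= 0) stopf("degenerate: zero variance (all |d| tied at one value)")
  z <- (w_plus - mu) / sqrt(sigma2)
  structure(list(statistic = z, w_plus = w_plus,
                 p_value = 2 * pnorm(-abs(z)), n_pairs = n,
                 method = "wilcoxon_signed_rank"),
            class = "paired_test")
}

#' @export
print.paired_test <- function(x, ...) {
  lab <- if (x$method == "paired_t_log10") {
    sprintf("t = %.3f, df = %d", x$statistic, x$df)
  } else {
    sprintf("Z = %.3f", x$statistic)
  }
  cat(sprintf("<%s> %s, n = %d, two-sided p = %.4g\n",
              x$method, lab, x$n_pairs, x$p_value))
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Midrank-based rho; two-sided p from `t = rho * sqrt((n-2)/(1-rho^2))`
#' with `n - 2` degrees of freedom (`p = 0` when `|rho| = 1`).
#'
#' @param x,y Paired observations; incomplete pairs are dropped; `n >= 4`.
#' @return A list with `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  p <- drop_incomplete_pairs(x, y)
  n <- length(p$x)
  if (n < 4L) stopf("need at least 4 complete pairs")
  if (sd(p$x) == 0 || sd(p$y) == 0) stopf("constant vector: rho undefined")
  rho <- stats::cor(rank(p$x), rank(p$y))
  pv <- if (abs(rho) >= 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = pv, n = n)
}

#' Holm step-down (sequential Bonferroni) significance flags
#'
#' Orders the p-values ascending and flags `p_(i)` significant iff
#' `p_(j) <= alpha / (m - j + 1)` for every `j <= i`, stopping at the first
#' failure.
#'
#' @param p_values Numeric vector in `[0, 1]`.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Logical vector of flags in the original order.
#' @export
holm_adjust <- function(p_values, alpha = 0.05) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  m <- length(p_values)
  ord <- order(p_values)
  flags <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[ord[i]] <= alpha / (m - i + 1)) {
      flags[ord[i]] <- TRUE
    } else {
      break
    }
  }
  flags
}

#' Pairwise Spearman correlations with Holm correction
#'
#' All pairwise rank correlations among the columns of a site-level table,
#' treated as one family of tests for the Holm step-down flags.
#'
#' @param data A data frame of numeric site-level variables (rows = sites).
#' @param alpha Family-wise error rate.
#' @return A tibble with `var1`, `var2`, `rho`, `p_value`, `n`,
#'   `significant`.
#' @export
correlation_matrix <- function(data, alpha = 0.05) {
  data <- as.data.frame(data)
  vars <- names(data)
  if (length(vars) < 2L) stopf("need at least two variables")
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    s <- spearman(data[[pr[1]]], data[[pr[2]]])
    tibble(var1 = pr[1], var2 = pr[2], rho = s$rho, p_value = s$p_value,
           n = s$n)
  })
  out <- dplyr::bind_rows(rows)
  out$significant <- holm_adjust(out$p_value, alpha)
  out
}

#' Temporal trend tests on the packaged survey table
#'
#' Reproduces the published epoch-to-epoch comparisons of the site-level
#' indices: a paired t test on log10 data where the index is strictly
#' positive in both epochs, plus the Wilcoxon signed-rank test for mean
#' VDSI. Sites missing either epoch are excluded (pairing on `site_id`).
#'
#' @param table1 A tibble as returned by [load_table1_fixture()].
#' @return A tibble with `variable`, `epoch_from`, `epoch_to`, `method`,
#'   `statistic`, `df`, `n_pairs`, `p_value`.
#' @export
epoch_trends <- function(table1 = load_table1_fixture()) {
  wide <- function(var) {
    stats::reshape(as.data.frame(table1[, c("site_id", "epoch", var)]),
                   idvar = "site_id", timevar = "epoch", direction = "wide")
  }
  comparisons <- list(
    c("mean_vdsi", "2004-06", "2010", "wilcoxon"),
    c("mean_vdsi", "2010", "2015", "t_log10"),
    c("rpsi", "2004-06", "2010", "t_log10"),
    c("rpsi", "2010", "2015", "t_log10"),
    c("pct_sterile", "2010", "2015", "wilcoxon")
  )
  rows <- lapply(comparisons, function(cmp) {
    var <- cmp[1]; from <- cmp[2]; to <- cmp[3]; method <- cmp[4]
    w <- wide(var)
    x <- w[[paste0(var, ".", from)]]
    y <- w[[paste0(var, ".", to)]]
    res <- if (method == "t_log10") paired_t_log10(x, y)
           else wilcoxon_signed_rank(x, y)
    dfree <- if (method == "t_log10") as.numeric(res$df) else NA_real_
    tibble(variable = var, epoch_from = from, epoch_to = to,
           method = res$method, statistic = res$statistic, df = dfree,
           n_pairs = res$n_pairs, p_value = res$p_value)
  })
  dplyr::bind_rows(rows)
}

#' Distance-to-shipping correlations on the packaged survey table
#'
#' Spearman correlations (with Holm flags per epoch) between the distance to
#' the nearest shipping facility and each site-level index, within one
#' survey epoch.
#'
#' @param table1 A tibble as returned by [load_table1_fixture()].
#' @param epoch One of `"2004-06"`, `"2010"`, `"2015"`.
#' @return A tibble like [correlation_matrix()]'s, filtered to pairs
#'   involving `distance_km`.
#' @export
distance_correlations <- function(table1 = load_table1_fixture(),
                                  epoch = "2010") {
  sub <- table1[table1$epoch == epoch, ]
  vars <- c("distance_km", "mean_vdsi", "median_vdsi", "pct_sterile", "rpsi",
            "condition_index")
  vars <- vars[vapply(vars, function(v) sum(!is.na(sub[[v]])) >= 4, TRUE)]
  cm <- correlation_matrix(sub[, vars])
  cm[cm$var1 == "distance_km" | cm$var2 == "distance_km", ]
}
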