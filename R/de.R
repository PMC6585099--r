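#' Per-probe two-group linear model fits
#'
#' For each probe, computes the group effect on the expression scale
#' (logFC = mean in cases minus mean in controls), the pooled within-group
#' residual variance s2, the residual degrees of freedom
#' (n_case + n_control - 2) and the unit standard-error factor
#' v = 1/n_case + 1/n_control. This is the saturated two-group means model
#' (intercept plus group indicator); no covariates.
#'
#' @param x Expression matrix (probes x samples), e.g. from
#'   \code{\link{delta_normalize}}.
#' @param annotation Sample annotation covering the columns of `x`.
#' @return Data frame of class `probe_fits` with columns `probe_id`,
#'   `logFC`, `s2`, `df`, `v`, and attributes `n_case` / `n_control`.
#' @export
fit_probe_models <- function(x, annotation) {
  validate_annotation(annotation, x)
  grp <- annotation$group[match(colnames(x), annotation$sample_id)]
  case <- x[, grp == "case", drop = FALSE]
  ctrl <- x[, grp == "control", drop = FALSE]
  n1 <- ncol(case); n0 <- ncol(ctrl)
  if (n1 < 2 || n0 < 2) stop_("both groups need at least 2 samples")
  m1 <- rowMeans(case); m0 <- rowMeans(ctrl)
  ss1 <- rowSums((case - m1)^2)
  ss0 <- rowSums((ctrl - m0)^2)
  df <- n1 + n0 - 2L
  fits <- data.frame(
    probe_id = rownames(x),
    logFC = m1 - m0,
    s2 = (ss1 + ss0) / df,
    df = df,
    v = 1 / n1 + 1 / n0,
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(fits, "n_case") <- n1
  attr(fits, "n_control") <- n0
  class(fits) <- c("probe_fits", "data.frame")
  fits
}

# Invert the trigamma function by monotone root-finding (trigamma is
# strictly decreasing on (0, Inf)).
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))  # trigamma(x) ~ 1/x^2 as x -> 0
  lo <- 1e-8; hi <- 1e8
  if (trigamma(lo) < y) return(lo)
  if (trigamma(hi) > y) return(hi)
  stats::uniroot(function(x) trigamma(x) - y, c(lo, hi), tol = 1e-12)$root
}

#' Estimate empirical-Bayes variance-prior hyperparameters
#'
#' Method-of-moments estimation on log residual variances. Under the
#' hierarchical model s2_g ~ s0_sq * F(d_g, d0), the centered log variance
#' e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2) satisfies
#' E[e_g] = log(s0_sq) - digamma(d0/2) + log(d0/2) and
#' Var[e_g] = trigamma(d_g/2) + trigamma(d0/2). The estimator solves
#' trigamma(d0/2) = var(e) - trigamma(d_g/2) by monotone root-finding and
#' back-solves s0_sq; when the empirical variance of e is at or below the
#' sampling floor trigamma(d_g/2), the residual variances are essentially
#' exchangeable and d0 = +Inf with s0_sq = exp(mean(e)) is returned.
#'
#' @param fits A `probe_fits` data frame (probes with s2 = 0 or df = 0 are
#'   excluded from estimation).
#' @param min_probes Minimum usable probes (default 10).
#' @return List of class `ebayes_params` with elements `d0` and `s0_sq`.
#' @export
estimate_eb_hyperparams <- function(fits, min_probes = 10) {
  use <- fits$s2 > 0 & fits$df > 0
  if (sum(use) < min_probes) {
    stop_("need at least ", min_probes, " probes with positive s2; have ",
          sum(use))
  }
  s2 <- fits$s2[use]
  dg <- fits$df[use]
  e <- log(s2) - digamma(dg / 2) + log(dg / 2)
  emean <- mean(e)
  evar <- stats::var(e) - mean(trigamma(dg / 2))
  if (is.na(evar) || evar <= 0) {
    eb <- list(d0 = Inf, s0_sq = exp(emean))
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    eb <- list(d0 = d0, s0_sq = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
  structure(eb, class = "ebayes_params")
}

#' Moderated t-statistics and two-sided p-values
#'
#' Shrinks each probe's residual variance toward the prior by the
#' df-weighted average s2_post = (d0 * s0_sq + d_g * s2_g) / (d0 + d_g)
#' (limit s0_sq when d0 = +Inf), forms t = logFC / sqrt(s2_post * v_g), and
#' computes a two-sided p-value from the Student t distribution with
#' d0 + d_g degrees of freedom (standard normal when d0 = +Inf). Setting
#' d0 = 0 recovers the ordinary pooled two-sample t-test exactly.
#'
#' @param fits A `probe_fits` data frame (one or more rows).
#' @param eb An `ebayes_params` list (d0 may be 0 or +Inf).
#' @return Data frame with `probe_id`, `t`, `df_total`, `p_value`.
#' @export
moderated_t <- function(fits, eb) {
  d0 <- eb$d0; s0 <- eb$s0_sq
  if (is.null(d0) || is.null(s0) || d0 < 0 || s0 <= 0) {
    stop_("invalid empirical-Bayes parameters")
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s0, nrow(fits))
  } else {
    (d0 * s0 + fits$df * fits$s2) / (d0 + fits$df)
  }
  df_total <- d0 + fits$df
  denom <- sqrt(s2_post * fits$v)
  t <- ifelse(denom > 0, fits$logFC / denom, sign(fits$logFC) * Inf)
  t[denom == 0 & fits$logFC == 0] <- 0
  if (any(denom == 0)) {
    warning("degenerate posterior variance for ", sum(denom == 0),
            " probe(s); p set to 0 (or 1 for zero logFC)", call. = FALSE)
  }
  p <- 2 * stats::pt(-abs(t), df = df_total)
  data.frame(probe_id = fits$probe_id, t = t, df_total = df_total,
             p_value = p, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Sorts the p-values ascending, takes adj_(i) = min_{j >= i} (p_(j) * m / j)
#' clipped at 1, and maps the adjusted values back to the input order.
#'
#' @param p_values Numeric vector of p-values in \code{[0, 1]}.
#' @return Adjusted vector, same length and order; elementwise >= input.
#' @export
adjust_bh <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    stop_("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0) return(numeric(0))
  ord <- order(p)
  adj_sorted <- rev(cummin(rev(p[ord] * m / seq_len(m))))
  out <- numeric(m)
  # clamp to [p, 1]: p * (m/m) can round one ulp below p in floating point
  out[ord] <- pmin(pmax(adj_sorted, p[ord]), 1)
  out
}

#' Call dysregulated probes
#'
#' A probe is dysregulated when its BH-adjusted p-value is strictly below
#' `alpha` and |logFC| is at least `lfc_threshold` (non-strict, so printed
#' effects of exactly 1.00 pass). Results are partitioned into up
#' (logFC > 0) and down (logFC < 0).
#'
#' @param results Data frame with columns `logFC` and `adj_p_value`.
#' @param alpha Adjusted-p cutoff (default 0.05, strict).
#' @param lfc_threshold Absolute logFC cutoff (default 1, non-strict).
#' @return The dysregulated subset with an added `direction` column
#'   ("up"/"down").
#' @export
call_dysregulated <- function(results, alpha = 0.05, lfc_threshold = 1) {
  keep <- results$adj_p_value < alpha & abs(results$logFC) >= lfc_threshold
  out <- results[keep, , drop = FALSE]
  out$direction <- ifelse(out$logFC > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Full differential-expression analysis of an expression matrix
#'
#' Fits per-probe two-group models, estimates the variance prior, computes
#' moderated t-statistics and BH-adjusted p-values, and flags dysregulation.
#'
#' @inheritParams fit_probe_models
#' @inheritParams call_dysregulated
#' @return Data frame (one row per probe, input order) with `probe_id`,
#'   `logFC`, `t`, `p_value`, `adj_p_value`, `dysregulated`; the
#'   `ebayes_params` are attached as attribute `eb`.
#' @export
run_de <- function(x, annotation, alpha = 0.05, lfc_threshold = 1) {
  fits <- fit_probe_models(x, annotation)
  eb <- estimate_eb_hyperparams(fits)
  mt <- moderated_t(fits, eb)
  res <- data.frame(
    probe_id = fits$probe_id,
    logFC = fits$logFC,
    t = mt$t,
    p_value = mt$p_value,
    adj_p_value = adjust_bh(mt$p_value),
    row.names = NULL, stringsAsFactors = FALSE
  )
  res$dysregulated <- res$adj_p_value < alpha & abs(res$logFC) >= lfc_threshold
  attr(res, "eb") <- eb
  res
}

#' Write a differential-expression result table as TSV
#'
#' @param res Result data frame from \code{\link{run_de}}.
#' @param path File path.
#' @export
write_de_results <- function(res, path) {
  utils::write.table(res, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
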