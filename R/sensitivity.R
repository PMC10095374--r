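#' Cochran's Q heterogeneity test
#'
#' Weighted sum of squared deviations of the per-SNP Wald ratios about the
#' fixed-effect IVW estimate, `Q = sum(w (r - theta)^2)` with inverse
#' squared ratio SEs as weights, referred to a chi-square distribution with
#' J-1 degrees of freedom. This Q is also the quantity that scales the
#' multiplicative random-effects IVW standard error.
#'
#' @param x An [instrument_set()] with at least 2 instruments.
#' @return A list `(q, df, p)`.
#' @export
cochran_q <- function(x) {
  w <- wald_ratios(x)
  if (nrow(w) < 2) stop("Cochran's Q needs at least 2 instruments")
  core <- ivw_core(w$ratio, w$weight)
  df <- nrow(w) - 1L
  list(q = core$q, df = df,
       p = stats::pchisq(core$q, df, lower.tail = FALSE))
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' The intercept of the MR-Egger regression ([mr_egger()]) estimates the
#' average direct effect of the instruments on the outcome; an intercept
#' distinguishable from zero indicates directional pleiotropy.
#'
#' @param x An [instrument_set()] with at least 3 instruments.
#' @return A list `(intercept, se, p)`.
#' @export
egger_intercept_test <- function(x) {
  fit <- mr_egger(x)
  list(intercept = fit$intercept, se = fit$intercept_se,
       p = fit$intercept_p)
}

#' Leave-one-out IVW analysis
#'
#' Refits the fixed-effect IVW estimator J times, each time excluding one
#' instrument, to expose estimates driven by a single SNP. A final
#' `"All"` row holds the full-set estimate.
#'
#' @param x An [instrument_set()] with at least 3 instruments.
#' @return Data frame with one row per left-out SNP (in instrument order)
#'   plus the reference row: `snp, nsnp, b, se, pvalue, or, ci_low,
#'   ci_high`.
#' @export
leave_one_out <- function(x) {
  w <- wald_ratios(x)
  j <- nrow(w)
  if (j < 3) stop("leave-one-out needs at least 3 instruments")
  # row j is computed on the set literally excluding SNP j, so a corrupt
  # instrument can never leak into its own leave-out row
  b <- vapply(seq_len(j), function(i)
    sum(w$weight[-i] * w$ratio[-i]) / sum(w$weight[-i]), numeric(1))
  se <- vapply(seq_len(j), function(i)
    1 / sqrt(sum(w$weight[-i])), numeric(1))
  all_core <- ivw_core(w$ratio, w$weight)
  b <- c(b, all_core$b)
  se <- c(se, all_core$se_fixed)
  ci <- to_or(b, se)
  data.frame(snp = c(w$snp, "All"), nsnp = c(rep(j - 1L, j), j), b = b,
             se = se, pvalue = 2 * stats::pnorm(-abs(b / se)), or = ci$or,
             ci_low = ci$ci_low, ci_high = ci$ci_high,
             stringsAsFactors = FALSE)
}

#' MR-PRESSO global, outlier and distortion tests
#'
#' Simulation-based test for horizontal pleiotropy built on the
#' leave-one-out weighted residual sum of squares. For each SNP j the
#' fixed-effect IVW estimate excluding j predicts j's outcome effect; the
#' observed RSS is the `1/se_out^2`-weighted sum of squared residuals.
#' `n_sim` replicate datasets are then simulated, drawing each exposure
#' effect from `N(beta_exp, se_exp)` and each outcome effect from
#' `N(theta_-j * beta_exp, se_out)`, and the RSS is recomputed on every
#' replicate. The global p-value is `(1 + #{RSS* >= RSS_obs}) / (1 + n_sim)`
#' (never exactly zero); per-SNP outlier p-values compare each observed
#' squared residual with its simulated distribution and are flagged at the
#' Bonferroni threshold `outlier_alpha / J`. When outliers are flagged, a
#' distortion test compares the change in estimate after removing them with
#' the changes seen after removing random subsets of the same size.
#'
#' Randomness is drawn from per-SNP substreams keyed by rsID rank under one
#' root seed, so results are bit-reproducible and invariant to instrument
#' order.
#'
#' @param x An [instrument_set()] with at least 4 instruments.
#' @param n_sim Number of simulated replicates; default 1000.
#' @param outlier_alpha Nominal outlier level before Bonferroni correction;
#'   default 0.05.
#' @param seed Root seed (required for reproducibility).
#' @return An object of class `mr_presso`: `rss_obs, global_p, outlier_p`
#'   (named per SNP), `outliers`, `distortion_pct, distortion_p` (`NA`
#'   when no outliers), `n_sim, seed`.
#' @export
mr_presso <- function(x, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  df <- if (inherits(x, "instrument_set")) x$instruments else x
  j <- nrow(df)
  if (j < 4) stop("MR-PRESSO needs at least 4 instruments")
  w <- wald_ratios(x)
  s <- sum(w$weight * w$ratio); tot <- sum(w$weight)
  theta_loo <- (s - w$weight * w$ratio) / (tot - w$weight)
  w_out <- 1 / df$se_out^2
  d_obs <- df$beta_out - theta_loo * df$beta_exp
  rss_obs <- sum(w_out * d_obs^2)

  # per-SNP substreams keyed by rsID rank: draws do not depend on row order
  rank_of <- rank(df$snp, ties.method = "first")
  be <- matrix(NA_real_, j, n_sim)
  bo <- matrix(NA_real_, j, n_sim)
  for (i in seq_len(j)) {
    draws <- with_seed(substream_seed(seed, rank_of[i]),
                       stats::rnorm(2L * n_sim))
    be[i, ] <- df$beta_exp[i] + df$se_exp[i] * draws[seq_len(n_sim)]
    bo[i, ] <- theta_loo[i] * df$beta_exp[i] +
      df$se_out[i] * draws[n_sim + seq_len(n_sim)]
  }
  # leave-one-out IVW on each replicate, vectorised over replicates
  wald_w <- (be / df$se_out)^2              # j x n_sim
  num <- colSums(be * bo / df$se_out^2)     # sum w* r*
  den <- colSums(wald_w)
  theta_star <- (matrix(num, j, n_sim, byrow = TRUE) - be * bo / df$se_out^2) /
    (matrix(den, j, n_sim, byrow = TRUE) - wald_w)
  d_star <- bo - theta_star * be
  rss_star <- colSums(w_out * d_star^2)
  global_p <- (1 + sum(rss_star >= rss_obs)) / (1 + n_sim)
  outlier_p <- (1 + rowSums(d_star^2 >= d_obs^2)) / (1 + n_sim)
  names(outlier_p) <- df$snp
  outliers <- df$snp[outlier_p < outlier_alpha / j]

  distortion_pct <- NA_real_; distortion_p <- NA_real_
  if (length(outliers) && length(outliers) < j - 1) {
    b_all <- ivw_core(w$ratio, w$weight)$b
    keep <- !w$snp %in% outliers
    b_no <- ivw_core(w$ratio[keep], w$weight[keep])$b
    distortion_pct <- 100 * (b_all - b_no) / abs(b_no)
    k <- length(outliers)
    dist_star <- with_seed(substream_seed(seed, 0L), {
      vapply(seq_len(n_sim), function(i) {
        drop <- sample.int(j, k)
        b_sub <- ivw_core(w$ratio[-drop], w$weight[-drop])$b
        100 * (b_all - b_sub) / abs(b_sub)
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(dist_star) >= abs(distortion_pct))) /
      (1 + n_sim)
  }
  structure(list(rss_obs = rss_obs, global_p = global_p,
                 outlier_p = outlier_p, outliers = outliers,
                 distortion_pct = distortion_pct,
                 distortion_p = distortion_p, n_sim = n_sim, seed = seed),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  p_min <- 1 / (1 + x$n_sim)
  lab <- if (x$global_p <= p_min) sprintf("< %.3g", 1 / x$n_sim)
         else sprintf("%.3g", x$global_p)
  cat("MR-PRESSO (", x$n_sim, " simulations)\n", sep = "")
  cat("  observed RSS:", format(x$rss_obs, digits = 5),
      " global p:", lab, "\n")
  if (length(x$outliers)) {
    cat("  outliers:", paste(x$outliers, collapse = ", "), "\n")
    cat(sprintf("  distortion: %.2f%% (p = %.3g)\n", x$distortion_pct,
                x$distortion_p))
  } else cat("  no outliers at the Bonferroni threshold\n")
  invisible(x)
}

#' Run the full sensitivity battery
#'
#' Convenience wrapper computing Cochran's Q, the MR-Egger intercept test,
#' MR-PRESSO, the leave-one-out table, and the plot-ready scatter and
#' funnel tables in one object.
#'
#' @param x An [instrument_set()] with at least 4 instruments.
#' @param n_sim MR-PRESSO simulations; default 1000.
#' @param outlier_alpha MR-PRESSO outlier level; default 0.05.
#' @param seed Root seed for MR-PRESSO.
#' @return An object of class `mr_sensitivity` with components `q`
#'   (`q, df, p`), `egger` (`intercept, se, p`), `presso`, `loo`,
#'   `scatter_rows` (`snp, beta_exp, beta_out, se_exp, se_out`, oriented to
#'   positive exposure effect) and `funnel_rows` (`snp, ratio, precision`).
#' @examples
#' sens <- mr_sensitivity(metformin_ra_instruments(), n_sim = 200, seed = 7)
#' sens
#' @export
mr_sensitivity <- function(x, n_sim = 1000, outlier_alpha = 0.05, seed = 1) {
  stopifnot(inherits(x, "instrument_set"))
  df <- x$instruments
  w <- wald_ratios(x)
  s <- ifelse(df$beta_exp < 0, -1, 1)
  structure(list(
    q = cochran_q(x),
    egger = egger_intercept_test(x),
    presso = mr_presso(x, n_sim = n_sim, outlier_alpha = outlier_alpha,
                       seed = seed),
    loo = leave_one_out(x),
    scatter_rows = data.frame(snp = df$snp, beta_exp = s * df$beta_exp,
                              beta_out = s * df$beta_out,
                              se_exp = df$se_exp, se_out = df$se_out,
                              stringsAsFactors = FALSE),
    funnel_rows = data.frame(snp = w$snp, ratio = w$ratio,
                             precision = 1 / w$se,
                             stringsAsFactors = FALSE),
    exposure = x$exposure, outcome = x$outcome),
    class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat("Sensitivity analyses:", x$exposure, "->", x$outcome, "\n")
  cat(sprintf("  Cochran's Q: %.3f on %d df, p = %.3g\n", x$q$q, x$q$df,
              x$q$p))
  cat(sprintf("  Egger intercept: %.4f (SE %.4f), p = %.3g\n",
              x$egger$intercept, x$egger$se, x$egger$p))
  print(x$presso)
  loo <- x$loo[x$loo$snp != "All", ]
  cat(sprintf("  leave-one-out estimates span [%.3f, %.3f] (log-odds)\n",
              min(loo$b), max(loo$b)))
  invisible(x)
}

#' Export plot-ready sensitivity tables
#'
#' Writes four tab-separated tables (no figure rendering): `scatter.tsv`
#' (`snp, beta_exp, beta_out, se_exp, se_out`), `funnel.tsv`
#' (`snp, ratio, precision` with `precision = 1/se_ratio`), `forest.tsv`
#' (per-SNP Wald ratios with 95\% CIs plus the IVW summary row) and
#' `loo.tsv` (the leave-one-out table, rows in instrument order).
#'
#' @param report An `mr_sensitivity` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_plot_tables <- function(report, dir) {
  stopifnot(inherits(report, "mr_sensitivity"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(d, f) {
    path <- file.path(dir, f)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    path
  }
  fr <- report$funnel_rows
  forest <- data.frame(snp = fr$snp, b = fr$ratio, se = 1 / fr$precision,
                       stringsAsFactors = FALSE)
  all_row <- report$loo[report$loo$snp == "All", ]
  forest <- rbind(forest, data.frame(snp = "All (IVW)", b = all_row$b,
                                     se = all_row$se))
  forest$ci_low <- forest$b - 1.959964 * forest$se
  forest$ci_high <- forest$b + 1.959964 * forest$se
  paths <- c(wt(report$scatter_rows, "scatter.tsv"),
             wt(fr, "funnel.tsv"),
             wt(forest, "forest.tsv"),
             wt(report$loo, "loo.tsv"))
  invisible(paths)
}
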