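Z975 <- 1.959964

#' Per-SNP Wald ratios
#'
#' The Wald ratio of an instrument is its outcome effect divided by its
#' exposure effect — the causal log-odds per unit of exposure if that SNP
#' alone were a valid instrument. The default standard error is the
#' first-order delta approximation `se_out / |beta_exp|`, which ignores the
#' exposure-side uncertainty; `second_order = TRUE` adds the
#' `beta_out^2 * se_exp^2 / beta_exp^4` term.
#'
#' @param x An [instrument_set()] (or data frame in its layout).
#' @param second_order Use the second-order delta SE; default `FALSE`.
#' @return Data frame `(snp, ratio, se, weight)` with `weight = 1/se^2`.
#' @export
wald_ratios <- function(x, second_order = FALSE) {
  df <- if (inherits(x, "instrument_set")) x$instruments else x
  if (any(df$beta_exp == 0))
    stop("degenerate instrument(s) with beta_exp == 0: ",
         paste(df$snp[df$beta_exp == 0], collapse = ", "))
  ratio <- df$beta_out / df$beta_exp
  se <- df$se_out / abs(df$beta_exp)
  if (second_order)
    se <- sqrt(se^2 + df$beta_out^2 * df$se_exp^2 / df$beta_exp^4)
  data.frame(snp = df$snp, ratio = ratio, se = se, weight = 1 / se^2,
             stringsAsFactors = FALSE)
}

#' Log-odds estimate to odds ratio with 95\% CI
#'
#' @param beta Log-odds estimate(s).
#' @param se Standard error(s), `>= 0`.
#' @return A list with `or`, `ci_low`, `ci_high` (Wald interval on the log
#'   scale, multiplier 1.959964).
#' @export
to_or <- function(beta, se) {
  stopifnot(all(se >= 0))
  list(or = exp(beta), ci_low = exp(beta - Z975 * se),
       ci_high = exp(beta + Z975 * se))
}

# Weighted mean of ratios with fixed-effect SE and Cochran's Q about it.
ivw_core <- function(ratio, weight) {
  b <- sum(weight * ratio) / sum(weight)
  list(b = b, se_fixed = 1 / sqrt(sum(weight)),
       q = sum(weight * (ratio - b)^2))
}

mr_result <- function(method, b, se, pvalue, nsnp, ...) {
  ci <- to_or(b, se)
  structure(list(method = method, b = b, se = se, pvalue = pvalue,
                 or = ci$or, ci_low = ci$ci_low, ci_high = ci$ci_high,
                 nsnp = nsnp, ...), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s: b = %.4f (SE %.4f), p = %.3g\n  OR = %.4g (95%% CI %.4g, %.4g), %d SNPs\n",
              x$method, x$b, x$se, x$pvalue, x$or, x$ci_low, x$ci_high,
              x$nsnp))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4f (SE %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  invisible(x)
}

#' Inverse-variance-weighted estimator
#'
#' Pools the per-SNP Wald ratios by their inverse squared standard errors:
#' the fixed-effect estimate is `sum(w r) / sum(w)` with standard error
#' `1/sqrt(sum(w))`. The multiplicative random-effects variant inflates the
#' SE by `max(1, sqrt(Q/(J-1)))`, where Q is Cochran's heterogeneity
#' statistic, leaving the point estimate unchanged. P-values are two-sided
#' normal.
#'
#' @param x An [instrument_set()] with at least 2 instruments.
#' @param effects `"fixed"` (default) or `"random"` (multiplicative).
#' @param second_order Passed to [wald_ratios()].
#' @return An object of class `mr_result`.
#' @export
mr_ivw <- function(x, effects = c("fixed", "random"), second_order = FALSE) {
  effects <- match.arg(effects)
  w <- wald_ratios(x, second_order)
  j <- nrow(w)
  if (j < 2)
    stop("IVW needs at least 2 instruments; use the per-SNP Wald ratio ",
         "(wald_ratios) for a single instrument")
  core <- ivw_core(w$ratio, w$weight)
  scale <- if (effects == "random") max(1, sqrt(core$q / (j - 1))) else 1
  se <- core$se_fixed * scale
  mr_result(method = if (effects == "fixed") "ivw_fixed" else "ivw_random",
            b = core$b, se = se,
            pvalue = 2 * stats::pnorm(-abs(core$b / se)), nsnp = j,
            q = core$q, q_df = j - 1)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome effects on exposure effects
#' with a free intercept, each instrument first oriented so its exposure
#' effect is positive and weighted by `1/se_out^2`. The slope estimates the
#' causal effect allowing directional pleiotropy; the intercept estimates
#' the average direct (pleiotropic) effect and is the basis of the Egger
#' pleiotropy test. Coefficient standard errors are divided by
#' `min(sigma, 1)`, where `sigma` is the weighted residual standard
#' deviation, so underdispersion is never credited; p-values use the t
#' distribution with J-2 degrees of freedom.
#'
#' @param x An [instrument_set()] with at least 3 instruments.
#' @return An `mr_result` whose extras carry `intercept`, `intercept_se`,
#'   `intercept_p` and `sigma`.
#' @export
mr_egger <- function(x) {
  df <- if (inherits(x, "instrument_set")) x$instruments else x
  j <- nrow(df)
  if (j < 3) stop("MR-Egger needs at least 3 instruments")
  if (any(df$beta_exp == 0)) stop("degenerate instrument with beta_exp == 0")
  s <- ifelse(df$beta_exp < 0, -1, 1)
  bx <- s * df$beta_exp
  by <- s * df$beta_out
  w <- 1 / df$se_out^2
  sw <- sum(w); sx <- sum(w * bx); sy <- sum(w * by)
  sxx <- sum(w * bx^2); sxy <- sum(w * bx * by)
  denom <- sw * sxx - sx^2
  if (abs(denom) < .Machine$double.xmin * 1e6)
    stop("exposure effects are collinear; Egger regression is undefined")
  slope <- (sw * sxy - sx * sy) / denom
  intercept <- (sxx * sy - sx * sxy) / denom
  resid <- by - intercept - slope * bx
  sigma <- sqrt(sum(w * resid^2) / (j - 2))
  if (sigma > .Machine$double.eps^0.5) {
    floor <- min(sigma, 1)
    se_slope <- sigma * sqrt(sw / denom) / floor
    se_int <- sigma * sqrt(sxx / denom) / floor
    p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = j - 2)
    p_int <- 2 * stats::pt(-abs(intercept / se_int), df = j - 2)
  } else {
    # exact affine fit: no residual scale, coefficients are error-free
    se_slope <- se_int <- 0
    p_slope <- if (slope == 0) 1 else 0
    p_int <- if (intercept == 0) 1 else 0
  }
  mr_result(method = "egger", b = slope, se = se_slope, pvalue = p_slope,
            nsnp = j, intercept = intercept, intercept_se = se_int,
            intercept_p = p_int, sigma = sigma)
}

# Interpolated weighted median of ratios r with weights w.
weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  p <- (cumsum(w) - w / 2) / sum(w)
  stats::approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

# Parametric bootstrap SE: resample each beta from its observed normal,
# recompute ratios/weights, apply `point_fun(ratio, weight)`.
bootstrap_se <- function(df, point_fun, n_boot, seed) {
  j <- nrow(df)
  with_seed(seed, {
    est <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      be <- stats::rnorm(j, df$beta_exp, df$se_exp)
      bo <- stats::rnorm(j, df$beta_out, df$se_out)
      be[be == 0] <- .Machine$double.eps
      r <- bo / be
      w <- (be / df$se_out)^2
      est[b] <- point_fun(r, w)
    }
    stats::sd(est)
  })
}

#' Weighted-median estimator
#'
#' The inverse-variance-weighted median of the Wald ratios: ratios are
#' sorted, cumulative normalized weights are formed, and the estimate is the
#' linear interpolation of the ordered ratios at cumulative weight 0.5. It
#' is consistent when instruments carrying at least half the total weight
#' are valid. The standard error comes from a parametric bootstrap that
#' resamples each exposure and outcome beta from a normal with its observed
#' SE; the p-value is two-sided normal.
#'
#' @param x An [instrument_set()] with at least 3 instruments.
#' @param n_boot Bootstrap draws; default 1000.
#' @param seed Seed for the bootstrap (required for reproducibility).
#' @param second_order Passed to [wald_ratios()].
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(x, n_boot = 1000, seed = 1,
                               second_order = FALSE) {
  w <- wald_ratios(x, second_order)
  if (nrow(w) < 3) stop("weighted median needs at least 3 instruments")
  b <- weighted_median_point(w$ratio, w$weight)
  df <- if (inherits(x, "instrument_set")) x$instruments else x
  se <- bootstrap_se(df, weighted_median_point, n_boot, seed)
  mr_result(method = "weighted_median", b = b, se = se,
            pvalue = 2 * stats::pnorm(-abs(b / se)), nsnp = nrow(w),
            n_boot = n_boot, seed = seed)
}

# Gaussian-kernel weighted mode of ratios; returns NULL when the bandwidth
# degenerates (all ratios identical).
kde_mode <- function(r, w, phi) {
  h <- phi * 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(NULL)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 512L)
  dens <- colSums(w * stats::dnorm(outer(r, grid, "-") / h)) / (h * sum(w))
  grid[which.max(dens)]
}

#' Mode-based estimators
#'
#' The mode of the Wald-ratio distribution, located as the argmax of a
#' Gaussian kernel density evaluated on a 512-point grid spanning the ratio
#' range padded by three bandwidths. The bandwidth follows the modified
#' Silverman rule `phi * 0.9 * min(sd, MAD) * J^(-1/5)` (MAD scaled by
#' 1.4826 to be consistent for the normal). The `"weighted"` variant weights
#' each ratio by its normalized inverse variance; `"simple"` uses uniform
#' weights. Consistent when the largest group of instruments sharing a
#' causal estimate is valid. SE by the same parametric bootstrap as
#' [mr_weighted_median()]; p two-sided normal. When all ratios coincide the
#' common ratio is returned with the fixed-effect IVW standard error.
#'
#' @param x An [instrument_set()] with at least 3 instruments.
#' @param variant `"weighted"` or `"simple"`.
#' @param phi Bandwidth multiplier; default 1.
#' @param n_boot,seed Bootstrap settings.
#' @param second_order Passed to [wald_ratios()].
#' @return An `mr_result`.
#' @export
mr_mode <- function(x, variant = c("weighted", "simple"), phi = 1,
                    n_boot = 1000, seed = 1, second_order = FALSE) {
  variant <- match.arg(variant)
  w <- wald_ratios(x, second_order)
  j <- nrow(w)
  if (j < 3) stop("mode estimators need at least 3 instruments")
  wt <- if (variant == "weighted") w$weight else rep(1, j)
  b <- kde_mode(w$ratio, wt, phi)
  if (is.null(b)) {
    core <- ivw_core(w$ratio, w$weight)
    return(mr_result(method = paste0(variant, "_mode"), b = w$ratio[1],
                     se = core$se_fixed, pvalue = 2 * stats::pnorm(
                       -abs(w$ratio[1] / core$se_fixed)), nsnp = j,
                     phi = phi, degenerate = TRUE))
  }
  df <- if (inherits(x, "instrument_set")) x$instruments else x
  point <- if (variant == "weighted") {
    function(r, wt) kde_mode(r, wt, phi) %||% r[1]
  } else {
    function(r, wt) kde_mode(r, rep(1, length(r)), phi) %||% r[1]
  }
  se <- bootstrap_se(df, point, n_boot, seed)
  mr_result(method = paste0(variant, "_mode"), b = b, se = se,
            pvalue = 2 * stats::pnorm(-abs(b / se)), nsnp = j, phi = phi,
            n_boot = n_boot, seed = seed)
}

#' Fit the two-sample Mendelian randomization estimator battery
#'
#' Computes the requested causal estimators on a harmonized instrument set,
#' all on the log-odds scale, and collects them in a single model object
#' with odds-ratio transforms. With a single instrument only the Wald ratio
#' is available and is returned as method `"wald"`.
#'
#' @param x An [instrument_set()].
#' @param methods Subset of `"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"simple_mode"`, `"weighted_mode"` (all by default).
#' @param effects IVW variant, `"fixed"` (default) or `"random"`
#'   (multiplicative).
#' @param phi Mode bandwidth multiplier.
#' @param n_boot,seed Bootstrap settings for the median and mode SEs.
#' @param second_order Use second-order Wald-ratio SEs throughout.
#' @return An object of class `mr_fit` with components `results` (one row
#'   per method: `method, nsnp, b, se, pvalue, or, ci_low, ci_high`),
#'   `details` (the underlying `mr_result` objects, including the Egger
#'   intercept), `wald` (per-SNP ratio table) and `instruments`.
#' @examples
#' fit <- mr_fit(metformin_ra_instruments(), methods = c("ivw", "egger"))
#' fit
#' coef(fit)
#' @export
mr_fit <- function(x, methods = c("ivw", "egger", "weighted_median",
                                  "simple_mode", "weighted_mode"),
                   effects = c("fixed", "random"), phi = 1, n_boot = 1000,
                   seed = 1, second_order = FALSE) {
  stopifnot(inherits(x, "instrument_set"))
  effects <- match.arg(effects)
  methods <- match.arg(methods, several.ok = TRUE)
  j <- nrow(x$instruments)
  if (j == 0L) stop("empty instrument set")
  details <- list()
  if (j == 1L) {
    w <- wald_ratios(x, second_order)
    details$wald <- mr_result("wald", b = w$ratio, se = w$se,
                              pvalue = 2 * stats::pnorm(-abs(w$ratio / w$se)),
                              nsnp = 1L)
  } else {
    for (m in methods) {
      details[[m]] <- switch(m,
        ivw = mr_ivw(x, effects = effects, second_order = second_order),
        egger = mr_egger(x),
        weighted_median = mr_weighted_median(x, n_boot = n_boot, seed = seed,
                                             second_order = second_order),
        simple_mode = mr_mode(x, "simple", phi = phi, n_boot = n_boot,
                              seed = seed, second_order = second_order),
        weighted_mode = mr_mode(x, "weighted", phi = phi, n_boot = n_boot,
                                seed = seed, second_order = second_order))
    }
  }
  results <- do.call(rbind, lapply(details, function(d)
    data.frame(method = d$method, nsnp = d$nsnp, b = d$b, se = d$se,
               pvalue = d$pvalue, or = d$or, ci_low = d$ci_low,
               ci_high = d$ci_high, stringsAsFactors = FALSE)))
  rownames(results) <- NULL
  structure(list(results = results, details = details,
                 wald = wald_ratios(x, second_order), instruments = x,
                 effects = effects, call = match.call()),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample MR fit:", x$instruments$exposure, "->",
      x$instruments$outcome, "\n")
  cat(nrow(x$instruments$instruments), "instruments; IVW effects:",
      x$effects, "\n\n")
  df <- x$results
  df$b <- signif(df$b, digits); df$se <- signif(df$se, digits)
  df$pvalue <- signif(df$pvalue, 3)
  df$or <- signif(df$or, digits)
  df$ci_low <- signif(df$ci_low, digits)
  df$ci_high <- signif(df$ci_high, digits)
  print(df, row.names = FALSE)
  eg <- x$details$egger
  if (!is.null(eg))
    cat(sprintf("\nEgger intercept: %.4f (SE %.4f), p = %.3g\n",
                eg$intercept, eg$intercept_se, eg$intercept_p))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  het <- tryCatch(cochran_q(object$instruments), error = function(e) NULL)
  structure(list(fit = object, heterogeneity = het), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print(x$fit)
  if (!is.null(x$heterogeneity))
    cat(sprintf("\nCochran's Q = %.3f on %d df, p = %.3g\n",
                x$heterogeneity$q, x$heterogeneity$df, x$heterogeneity$p))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$b, object$results$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- cbind(object$results$b - z * object$results$se,
             object$results$b + z * object$results$se)
  dimnames(m) <- list(object$results$method,
                      sprintf("%.1f %%", c((1 - level) / 2,
                                           1 - (1 - level) / 2) * 100))
  m
}

#' @export
residuals.mr_fit <- function(object, ...) {
  w <- object$wald
  b <- object$results$b[match("ivw_fixed", object$results$method)]
  if (is.na(b)) b <- object$results$b[1]
  stats::setNames((w$ratio - b) * sqrt(w$weight), w$snp)
}

#' Scatter plot of instrument effects with fitted causal slopes
#'
#' Plots outcome effects against exposure effects (instruments oriented to
#' positive exposure effect) with one line per fitted method — through the
#' origin for all except MR-Egger, whose intercept is drawn as estimated.
#'
#' @param x An `mr_fit`.
#' @param ... Passed to [plot()].
#' @return Invisibly, the plotted data frame.
#' @export
plot.mr_fit <- function(x, ...) {
  df <- x$instruments$instruments
  s <- ifelse(df$beta_exp < 0, -1, 1)
  d <- data.frame(snp = df$snp, beta_exp = s * df$beta_exp,
                  beta_out = s * df$beta_out, se_exp = df$se_exp,
                  se_out = df$se_out)
  graphics::plot(d$beta_exp, d$beta_out, xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", pch = 19, ...)
  graphics::segments(d$beta_exp, d$beta_out - Z975 * d$se_out,
                     d$beta_exp, d$beta_out + Z975 * d$se_out,
                     col = "grey60")
  cols <- seq_len(nrow(x$results)) + 1L
  for (i in seq_len(nrow(x$results))) {
    m <- x$results$method[i]
    if (m == "egger")
      graphics::abline(x$details$egger$intercept, x$results$b[i],
                       col = cols[i])
    else graphics::abline(0, x$results$b[i], col = cols[i])
  }
  graphics::legend("topright", legend = x$results$method, col = cols,
                   lty = 1, cex = 0.8)
  invisible(d)
}
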