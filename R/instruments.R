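#' Instrument-selection settings
#'
#' @param p_threshold Genome-wide significance cutoff applied to exposure
#'   p-values (strict `<`); default `5e-8`.
#' @param r2_threshold Pairwise LD cutoff for clumping; default `0.001`.
#' @param window_kb Distance window (kb) for the distance-only clumping
#'   fallback; default `5000`.
#' @return A list of class `clump_config`.
#' @export
clump_config <- function(p_threshold = 5e-8, r2_threshold = 0.001,
                         window_kb = 5000) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            r2_threshold >= 0, r2_threshold <= 1, window_kb > 0)
  structure(list(p_threshold = p_threshold, r2_threshold = r2_threshold,
                 window_kb = window_kb), class = "clump_config")
}

#' Keep genome-wide significant records
#'
#' @param records Summary-statistics data frame with a `pvalue` column.
#' @param p_threshold Strict upper bound on the p-value; default `5e-8`.
#' @return The rows with `pvalue < p_threshold`.
#' @export
select_significant <- function(records, p_threshold = 5e-8) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  res <- records[records$pvalue < p_threshold, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Pairwise-r2 provider from an LD matrix
#'
#' Wraps a square r-squared matrix (or a tab-separated file holding one, with
#' rsIDs as row and column names) as a lookup function for [ld_clump()].
#'
#' @param x Square numeric matrix with identical row/column rsID names, or a
#'   path to a TSV rendering of one.
#' @return A function `(snp_a, snp_b) -> r2`, returning `NA` for pairs the
#'   matrix does not cover.
#' @export
ld_matrix_provider <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- as.matrix(utils::read.table(x, header = TRUE, sep = "\t",
                                     row.names = 1L, check.names = FALSE))
  }
  stopifnot(is.matrix(x), nrow(x) == ncol(x),
            identical(rownames(x), colnames(x)))
  if (any(abs(x - t(x)) > 1e-8, na.rm = TRUE))
    stop("LD matrix must be symmetric")
  if (any(abs(diag(x) - 1) > 1e-8, na.rm = TRUE))
    stop("LD matrix diagonal must be 1")
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("r2 values must lie in [0, 1]")
  function(a, b) {
    if (identical(a, b)) return(1)
    if (!a %in% rownames(x) || !b %in% rownames(x)) return(NA_real_)
    x[a, b]
  }
}

#' Greedy LD clumping
#'
#' Prunes correlated records, keeping the most significant representative of
#' each correlated group: records are visited in ascending p-value order
#' (ties broken by rsID, so the result is deterministic) and a record is
#' accepted iff its r-squared with every already-accepted record is below
#' `cfg$r2_threshold`. When no LD provider is available, a distance-only
#' fallback accepts a record iff no accepted record on the same chromosome
#' lies within `cfg$window_kb` (requires a `pos` column, base pairs).
#' Pairs with unknown r2 are treated as unlinked.
#'
#' @param records Summary-statistics data frame (`snp, pvalue`, plus `chr`
#'   and `pos` in distance-only mode).
#' @param cfg A [clump_config()].
#' @param ld Optional pairwise-r2 provider, e.g. [ld_matrix_provider()];
#'   `NULL` selects the distance-only fallback.
#' @return The accepted rows, in the original row order of `records`.
#' @export
ld_clump <- function(records, cfg = clump_config(), ld = NULL) {
  if (!nrow(records)) return(records)
  records <- records[!duplicated(records$snp), , drop = FALSE]
  if (is.null(ld)) {
    if (is.null(records$pos) || anyNA(records$pos))
      stop("distance-only clumping requires a complete 'pos' column; ",
           "supply an LD provider otherwise")
    if (is.null(records$chr) || anyNA(records$chr))
      stop("distance-only clumping requires a complete 'chr' column")
  }
  ord <- order(records$pvalue, records$snp)
  accepted <- integer(0)
  for (i in ord) {
    ok <- TRUE
    for (j in accepted) {
      if (!is.null(ld)) {
        r2 <- ld(records$snp[i], records$snp[j])
        if (!is.na(r2) && r2 >= cfg$r2_threshold) { ok <- FALSE; break }
      } else {
        same_chr <- records$chr[i] == records$chr[j]
        if (same_chr &&
            abs(records$pos[i] - records$pos[j]) <= cfg$window_kb * 1000) {
          ok <- FALSE; break
        }
      }
    }
    if (ok) accepted <- c(accepted, i)
  }
  res <- records[sort(accepted), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Instrument-strength F statistic
#'
#' For a single-SNP instrument the F statistic equals the squared z score of
#' its exposure association. `"from_p"` recovers z from the two-sided
#' p-value via the upper-tail normal quantile (evaluated on the log scale,
#' accurate down to p near 1e-300); `"from_beta_se"` uses `(beta/se)^2`.
#' On unrounded data the two agree; on published tables rounded to a few
#' digits they can differ, and `"from_p"` is the default because reported
#' p-values usually carry more relative precision than beta/se pairs.
#'
#' @param x Optional [instrument_set()] (or data frame with `p_exp`,
#'   `beta_exp`, `se_exp`) whose per-instrument F values are returned.
#' @param mode `"from_p"` or `"from_beta_se"`.
#' @param p,beta,se Direct numeric inputs, used when `x` is `NULL`.
#' @return Numeric vector of F values.
#' @examples
#' f_statistic(p = 5e-8)         # ~29.7, the genome-wide significance floor
#' f_statistic(beta = 2, se = 1) # 4
#' @export
f_statistic <- function(x = NULL, mode = c("from_p", "from_beta_se"),
                        p = NULL, beta = NULL, se = NULL) {
  mode <- match.arg(mode)
  if (!is.null(x)) {
    df <- if (inherits(x, "instrument_set")) x$instruments else x
    p <- df$p_exp; beta <- df$beta_exp; se <- df$se_exp
  }
  if (mode == "from_p") {
    if (is.null(p)) stop("mode 'from_p' requires p-values")
    if (any(p <= 0, na.rm = TRUE)) stop("p-values must be > 0")
    if (any(p > 1, na.rm = TRUE)) stop("p-values must be <= 1")
    z <- stats::qnorm(log(p) - log(2), lower.tail = FALSE, log.p = TRUE)
    z^2
  } else {
    if (is.null(beta) || is.null(se))
      stop("mode 'from_beta_se' requires beta and se")
    if (any(se <= 0, na.rm = TRUE)) stop("se must be > 0")
    (beta / se)^2
  }
}

#' Drop weak instruments
#'
#' Removes instruments with F below `f_min` (conventionally 10), recording
#' each drop in provenance with reason `weak_instrument`. Instruments whose
#' `f` field is `NA` are first annotated using [f_statistic()] in the given
#' mode; already-annotated values (e.g. published ones) are kept unless
#' `recompute = TRUE`.
#'
#' @param x An [instrument_set()].
#' @param f_min Minimum F to retain; default 10.
#' @param mode Passed to [f_statistic()].
#' @param recompute Recompute F for all instruments, overwriting existing
#'   annotations.
#' @return The filtered, F-annotated `instrument_set`.
#' @export
filter_weak <- function(x, f_min = 10, mode = c("from_p", "from_beta_se"),
                        recompute = FALSE) {
  stopifnot(inherits(x, "instrument_set"), f_min >= 0)
  mode <- match.arg(mode)
  df <- x$instruments
  if (nrow(df)) {
    todo <- if (recompute) rep(TRUE, nrow(df)) else is.na(df$f)
    if (any(todo))
      df$f[todo] <- f_statistic(df[todo, , drop = FALSE], mode = mode)
  }
  weak <- df$f < f_min
  if (any(weak)) {
    add <- data.frame(snp = df$snp[weak], reason = "weak_instrument",
                      detail = sprintf("F = %.4g < %.4g", df$f[weak], f_min),
                      stringsAsFactors = FALSE)
    x$provenance <- rbind(x$provenance, add)
  }
  x$instruments <- df[!weak, , drop = FALSE]
  rownames(x$instruments) <- NULL
  x
}

#' Steiger directionality filter
#'
#' Excludes instruments that explain more variance in the outcome than in
#' the exposure, a signature of reverse causation. Variance explained is
#' approximated from the association z score and sample size as
#' `r2 = z^2 / (z^2 + n - 2)`; an instrument is kept iff its exposure r2
#' strictly exceeds its outcome r2. Sample sizes are taken per SNP from the
#' instrument table (`n_exp`, `n_out`) and fall back to the `n_exp`/`n_out`
#' arguments; when either is unavailable the filter is skipped with a
#' warning and the set is returned unchanged.
#'
#' @param x An [instrument_set()].
#' @param n_exp,n_out Study-level sample sizes used where per-SNP sizes are
#'   missing.
#' @return The filtered `instrument_set`, with drops recorded in provenance
#'   as `steiger_reverse`.
#' @export
steiger_filter <- function(x, n_exp = NULL, n_out = NULL) {
  stopifnot(inherits(x, "instrument_set"))
  df <- x$instruments
  if (!nrow(df)) return(x)
  ne <- ifelse(is.na(df$n_exp), n_exp %||% NA_real_, df$n_exp)
  no <- ifelse(is.na(df$n_out), n_out %||% NA_real_, df$n_out)
  if (anyNA(ne) || anyNA(no)) {
    warning("Steiger filtering skipped: sample sizes unavailable for ",
            sum(is.na(ne) | is.na(no)), " instrument(s)")
    return(x)
  }
  zx2 <- (df$beta_exp / df$se_exp)^2
  zy2 <- (df$beta_out / df$se_out)^2
  r2x <- zx2 / (zx2 + ne - 2)
  r2y <- zy2 / (zy2 + no - 2)
  rev <- !(r2x > r2y)
  if (any(rev)) {
    add <- data.frame(snp = df$snp[rev], reason = "steiger_reverse",
                      detail = sprintf("r2_exposure %.3g <= r2_outcome %.3g",
                                       r2x[rev], r2y[rev]),
                      stringsAsFactors = FALSE)
    x$provenance <- rbind(x$provenance, add)
  }
  x$instruments <- df[!rev, , drop = FALSE]
  rownames(x$instruments) <- NULL
  x
}
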