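#' Define a synthetic two-sample GWAS scenario
#'
#' Describes a generative model for paired exposure/outcome summary
#' statistics with known ground truth. Per SNP, a minor-allele frequency is
#' drawn uniformly from `maf_range`; the true exposure effect is normal with
#' per-SNP variance explained `exposure_h2_per_snp`; standard errors follow
#' the GWAS approximation `sqrt(var_trait / (2 maf (1-maf) n))`, with the
#' trait variance set by the exposure prevalence and the outcome
#' case-control fraction; the true outcome effect is
#' `theta * beta_x + alpha`, where `alpha` is the SNP's direct
#' (pleiotropic) effect under the chosen law; observed betas are drawn
#' normal around the truth. Planted outliers receive a gross direct effect
#' of `outlier_scale` outcome standard errors. A configurable fraction of
#' SNPs get palindromic (A/T or C/G) allele pairs.
#'
#' Defaults mirror the metformin-use vs rheumatoid-arthritis setting: UK
#' Biobank-scale exposure GWAS (n = 462,933, betas on the linear binary
#' trait scale, hence tiny), outcome GWAS of n = 58,284, 32 instruments, a
#' causal log-odds of -3.76 per unit exposure, and about 6\% palindromic
#' SNPs.
#'
#' @param j_snps Number of SNPs; default 32.
#' @param n_exp,n_out GWAS sample sizes; defaults 462933 and 58284.
#' @param theta True causal effect (log-odds per exposure unit);
#'   default -3.76.
#' @param maf_range Uniform MAF bounds within (0, 0.5]; default
#'   `c(0.05, 0.5)`.
#' @param exposure_h2_per_snp Mean per-SNP fraction of exposure variance
#'   explained; default `7e-5`, which at the default `n_exp` reproduces the
#'   instrument-strength range seen after genome-wide-significance
#'   selection (F roughly 30-600, mean near 60).
#' @param exposure_prevalence Case fraction of the binary exposure trait
#'   scanned on the linear scale; its Bernoulli variance sets the exposure
#'   beta/SE units. Default `11552/462933`.
#' @param outcome_case_fraction Case fraction of the case-control outcome;
#'   its Bernoulli variance is the effective-sample-size factor in the
#'   log-odds SE approximation `1/sqrt(2 maf (1-maf) n u(1-u))`. Default
#'   `14361/58284`.
#' @param pleiotropy List describing the direct-effect law: `type` one of
#'   `"none"`, `"balanced"` (`sd`), `"directional"` (`mean`, `sd`),
#'   `"correlated"` (`strength`, `sd`; direct effects proportional to the
#'   exposure effect, violating the InSIDE assumption).
#' @param n_outliers Number of planted gross outliers; default 0.
#' @param outlier_scale Outlier direct effect in units of the SNP's outcome
#'   SE; default 10.
#' @param palindromic_frac Fraction of SNPs given palindromic allele pairs;
#'   default 0.06.
#' @param seed Root seed; per-SNP substreams are derived from it so the
#'   generated table does not depend on generation order.
#' @return A list of class `sim_scenario`.
#' @export
sim_scenario <- function(j_snps = 32, n_exp = 462933, n_out = 58284,
                         theta = -3.76, maf_range = c(0.05, 0.5),
                         exposure_h2_per_snp = 7e-5,
                         exposure_prevalence = 11552 / 462933,
                         outcome_case_fraction = 14361 / 58284,
                         pleiotropy = list(type = "none"),
                         n_outliers = 0, outlier_scale = 10,
                         palindromic_frac = 0.06, seed = 1) {
  stopifnot(j_snps >= 0, n_exp > 1, n_out > 1, is.finite(theta),
            length(maf_range) == 2, exposure_h2_per_snp > 0,
            exposure_prevalence > 0, exposure_prevalence < 1,
            outcome_case_fraction > 0, outcome_case_fraction < 1,
            n_outliers >= 0, n_outliers <= j_snps, outlier_scale >= 0,
            palindromic_frac >= 0, palindromic_frac <= 1)
  if (!(maf_range[1] > 0 && maf_range[1] < maf_range[2] &&
        maf_range[2] <= 0.5))
    stop("maf_range must satisfy 0 < low < high <= 0.5")
  pl <- utils::modifyList(list(type = "none", mean = 0, sd = 0, strength = 0),
                   as.list(pleiotropy))
  if (!pl$type %in% c("none", "balanced", "directional", "correlated"))
    stop("unknown pleiotropy type: ", pl$type)
  structure(list(j_snps = as.integer(j_snps), n_exp = n_exp, n_out = n_out,
                 theta = theta, maf_range = maf_range,
                 exposure_h2_per_snp = exposure_h2_per_snp,
                 exposure_prevalence = exposure_prevalence,
                 outcome_case_fraction = outcome_case_fraction,
                 pleiotropy = pl, n_outliers = as.integer(n_outliers),
                 outlier_scale = outlier_scale,
                 palindromic_frac = palindromic_frac, seed = seed),
            class = "sim_scenario")
}

NONPAL_PAIRS <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                         "G", "A", "G", "T", "T", "C", "T", "G"),
                       ncol = 2, byrow = TRUE)
PAL_PAIRS <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                    ncol = 2, byrow = TRUE)

# All stochastic primitives for SNP counter k, drawn in a fixed order from
# the SNP's own substream.
gen_snp_core <- function(sc, k) {
  with_seed(substream_seed(sc$seed, k), {
    u <- stats::runif(5)
    z <- stats::rnorm(4)
    maf <- sc$maf_range[1] + u[1] * diff(sc$maf_range)
    pal <- u[2] < sc$palindromic_frac
    pair <- if (pal) PAL_PAIRS[ceiling(u[3] * 4), ]
            else NONPAL_PAIRS[ceiling(u[3] * 8), ]
    # s: which allele is labelled the effect allele; the exposure-increasing
    # orientation is the reference frame for pleiotropic effects
    s <- if (u[4] < 0.5) 1 else -1
    eaf_pos <- if (u[5] < 0.5) maf else 1 - maf
    eaf <- if (s > 0) eaf_pos else 1 - eaf_pos
    v <- 2 * maf * (1 - maf)
    # trait-scale factors: exposure betas are on the linear binary-trait
    # scale (phenotypic variance u(1-u)); outcome SEs follow the log-odds
    # approximation with the case-control effective sample size
    var_exp <- sc$exposure_prevalence * (1 - sc$exposure_prevalence)
    var_out <- sc$outcome_case_fraction * (1 - sc$outcome_case_fraction)
    beta_x_pos <- abs(z[1]) * sqrt(sc$exposure_h2_per_snp * var_exp / v)
    se_x <- sqrt(var_exp / (v * sc$n_exp))
    se_y <- 1 / sqrt(v * sc$n_out * var_out)
    beta_x <- s * beta_x_pos
    list(k = k, maf = maf, eaf = eaf, ea = pair[1], oa = pair[2], s = s,
         beta_x = beta_x, beta_x_pos = beta_x_pos, se_x = se_x, se_y = se_y,
         beta_exp = beta_x + se_x * z[2], z_alpha = z[3], z_out = z[4],
         sign_outlier = if (stats::runif(1) < 0.5) -1 else 1)
  })
}

# Direct (pleiotropic) effect of one SNP, defined in the exposure-increasing
# allele frame and mapped back through the SNP's label orientation; planted
# outliers add a gross term of outlier_scale outcome SEs with random sign.
direct_effect <- function(core, sc, is_outlier) {
  pl <- sc$pleiotropy
  a <- switch(pl$type,
              none = 0,
              balanced = pl$sd * core$z_alpha,
              directional = pl$mean + pl$sd * core$z_alpha,
              correlated = pl$strength * core$beta_x_pos +
                pl$sd * core$z_alpha)
  a <- core$s * a
  if (is_outlier) a <- a + sc$outlier_scale * core$se_y * core$sign_outlier
  a
}

two_sided_p <- function(beta, se) {
  p <- 2 * stats::pnorm(-abs(beta / se))
  pmax(p, 1e-320)
}

assemble_records <- function(cores, sc, outlier_idx) {
  j <- length(cores)
  if (j == 0L) {
    empty <- data.frame(snp = character(), chr = character(),
                        ea = character(), oa = character(), eaf = numeric(),
                        beta = numeric(), se = numeric(), pvalue = numeric(),
                        n = numeric(), stringsAsFactors = FALSE)
    return(list(exposure = empty, outcome = empty,
                truth = list(theta = sc$theta, beta_x = numeric(),
                             alpha = numeric(), outlier_snps = character(),
                             scenario = sc)))
  }
  is_out <- seq_len(j) %in% outlier_idx
  alpha <- mapply(direct_effect, cores, MoreArgs = list(sc = sc),
                  is_outlier = is_out)
  g <- function(f) vapply(cores, f, numeric(1))
  ch <- function(f) vapply(cores, f, character(1))
  beta_x <- g(function(c) c$beta_x)
  beta_y <- sc$theta * beta_x + alpha
  se_y <- g(function(c) c$se_y)
  beta_out <- beta_y + se_y * g(function(c) c$z_out)
  kk <- as.integer(g(function(c) c$k))
  snp <- sprintf("rs%07d", kk)
  chr <- as.character((kk - 1L) %% 22L + 1L)
  exposure <- data.frame(
    snp = snp, chr = chr, ea = ch(function(c) c$ea),
    oa = ch(function(c) c$oa), eaf = g(function(c) c$eaf),
    beta = g(function(c) c$beta_exp), se = g(function(c) c$se_x),
    pvalue = two_sided_p(g(function(c) c$beta_exp), g(function(c) c$se_x)),
    n = sc$n_exp, stringsAsFactors = FALSE)
  outcome <- data.frame(
    snp = snp, chr = chr, ea = ch(function(c) c$ea),
    oa = ch(function(c) c$oa), eaf = g(function(c) c$eaf),
    beta = beta_out, se = se_y, pvalue = two_sided_p(beta_out, se_y),
    n = sc$n_out, stringsAsFactors = FALSE)
  truth <- list(theta = sc$theta, beta_x = stats::setNames(beta_x, snp),
                alpha = stats::setNames(alpha, snp),
                outlier_snps = snp[is_out], scenario = sc)
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Simulate paired exposure/outcome summary statistics
#'
#' Generates one exposure table and one outcome table of `j_snps` SNPs under
#' the scenario's generative model, together with a truth record (`theta`,
#' per-SNP true effects and direct effects, planted-outlier ids). All
#' randomness derives from the scenario seed through per-SNP substreams, so
#' output is reproducible and per-SNP values do not depend on `j_snps`.
#'
#' @param sc A [sim_scenario()].
#' @return A list `(exposure, outcome, truth)`; the two tables are
#'   [read_sumstats()]-shaped data frames that pass its validation.
#' @examples
#' sim <- simulate_pair(sim_scenario(j_snps = 5, seed = 42))
#' sim$exposure
#' @export
simulate_pair <- function(sc) {
  stopifnot(inherits(sc, "sim_scenario"))
  if (sc$j_snps == 0L)
    return(assemble_records(list(), sc, integer(0)))
  cores <- lapply(seq_len(sc$j_snps), function(k) gen_snp_core(sc, k))
  outlier_idx <- if (sc$n_outliers > 0)
    with_seed(substream_seed(sc$seed, 0L),
              sample.int(sc$j_snps, sc$n_outliers)) else integer(0)
  assemble_records(cores, sc, outlier_idx)
}

#' Simulate instruments that pass genome-wide significance
#'
#' Rejection-samples SNPs from the scenario's generative model until
#' `j_snps` of them reach exposure significance (`p < p_threshold`),
#' emulating instrument selection from a GWAS scan. Selection is on the
#' observed exposure association, so the returned set reflects the
#' significance filter of a real instrument search; outliers are planted
#' among the selected SNPs.
#'
#' @param sc A [sim_scenario()].
#' @param p_threshold Selection threshold; default `5e-8`.
#' @param max_attempts Cap on candidate SNPs; an error is raised when the
#'   scenario makes significance too rare (expected hit probability below
#'   1e-6) or the cap is exhausted.
#' @return As [simulate_pair()], restricted to the selected SNPs.
#' @export
simulate_significant_instruments <- function(sc, p_threshold = 5e-8,
                                             max_attempts = 1e6) {
  stopifnot(inherits(sc, "sim_scenario"))
  if (sc$j_snps == 0L)
    return(assemble_records(list(), sc, integer(0)))
  # marginal z is approx N(0, sqrt(1 + n * h2)): feasibility check
  z_thr <- stats::qnorm(p_threshold / 2, lower.tail = FALSE)
  p_hit <- 2 * stats::pnorm(-z_thr / sqrt(1 + sc$n_exp *
                                            sc$exposure_h2_per_snp))
  if (p_hit < 1e-6)
    stop("expected significance probability ", format(p_hit, digits = 3),
         " < 1e-6; increase n_exp or exposure_h2_per_snp")
  accepted <- list()
  k <- 0L
  while (length(accepted) < sc$j_snps && k < max_attempts) {
    k <- k + 1L
    core <- gen_snp_core(sc, k)
    if (two_sided_p(core$beta_exp, core$se_x) < p_threshold)
      accepted[[length(accepted) + 1L]] <- core
  }
  if (length(accepted) < sc$j_snps)
    stop("could not find ", sc$j_snps, " significant SNPs in ",
         max_attempts, " attempts")
  outlier_idx <- if (sc$n_outliers > 0)
    with_seed(substream_seed(sc$seed, 0L),
              sample.int(sc$j_snps, sc$n_outliers)) else integer(0)
  assemble_records(accepted, sc, outlier_idx)
}
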