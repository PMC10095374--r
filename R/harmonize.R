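COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonization settings
#'
#' Controls how strand-ambiguous (palindromic) SNPs are handled when aligning
#' exposure and outcome records to a common effect allele. A palindromic SNP
#' (A/T or C/G) cannot be oriented by its allele letters alone; orientation
#' falls back on allele-frequency agreement, which is unreliable when the
#' exposure effect-allele frequency is close to 0.5. SNPs whose exposure EAF
#' falls inside `[intermediate_low, intermediate_high]` (or is missing) are
#' therefore dropped.
#'
#' @param intermediate_low,intermediate_high Bounds of the intermediate
#'   frequency window; defaults 0.42 and 0.58 (symmetric about 0.5, the
#'   common two-sample MR convention).
#' @param drop_palindromic_always Drop every palindromic SNP regardless of
#'   frequency; default `FALSE`.
#' @return A list of class `harmonize_config`.
#' @export
harmonize_config <- function(intermediate_low = 0.42,
                             intermediate_high = 0.58,
                             drop_palindromic_always = FALSE) {
  stopifnot(intermediate_low > 0, intermediate_low < 0.5,
            intermediate_high > 0.5, intermediate_high < 1,
            abs(intermediate_low + intermediate_high - 1) < 1e-12,
            is.logical(drop_palindromic_always))
  structure(list(intermediate_low = intermediate_low,
                 intermediate_high = intermediate_high,
                 drop_palindromic_always = drop_palindromic_always),
            class = "harmonize_config")
}

check_alleles <- function(...) {
  a <- c(...)
  bad <- !a %in% c("A", "C", "G", "T")
  if (any(bad)) stop("invalid allele character: ",
                     paste(unique(a[bad]), collapse = ", "))
  invisible(TRUE)
}

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic (strand-ambiguous) when its two alleles are
#' complementary: A/T or C/G. For such SNPs the same pair of letters is seen
#' whichever strand a study reports, so allele letters cannot resolve
#' orientation.
#'
#' @param ea,oa Effect and other allele (single characters in A/C/G/T,
#'   distinct). Vectorised.
#' @return Logical vector.
#' @examples
#' is_palindromic("A", "T")  # TRUE
#' is_palindromic("C", "T")  # FALSE
#' @export
is_palindromic <- function(ea, oa) {
  ea <- toupper(ea); oa <- toupper(oa)
  check_alleles(ea, oa)
  if (any(ea == oa)) stop("effect and other allele must differ")
  unname(COMPLEMENT[ea] == oa)
}

as_record <- function(x) {
  if (is.data.frame(x)) x <- as.list(x[1, , drop = FALSE])
  x$ea <- toupper(x$ea); x$oa <- toupper(x$oa)
  x$eaf <- x$eaf %||% NA_real_
  x$n <- x$n %||% NA_real_
  x$chr <- x$chr %||% NA_character_
  x
}

#' Harmonize one exposure/outcome record pair
#'
#' Aligns the outcome association of a SNP to the exposure's effect allele.
#' If the outcome lists the same alleles in the same order the effect is
#' copied; if the alleles are swapped the outcome beta is negated and its
#' frequency complemented; if they match only after strand complement
#' (A<->T, C<->G) the complement is applied first and the same rules follow.
#' Palindromic SNPs are oriented by frequency agreement (both EAFs on the
#' same side of 0.5 after alignment) and are dropped when the exposure EAF is
#' inside the intermediate window or either EAF is missing.
#'
#' @param exp,out Records for the same SNP — lists or one-row data frames
#'   with fields `snp, ea, oa, beta, se, pvalue` and optional `eaf, chr, n`.
#' @param cfg A [harmonize_config()].
#' @return A list with `status` (`"ok"` or `"drop"`), `reason`
#'   (`NA`, `"palindromic_intermediate"` or `"allele_mismatch"`), `action`
#'   (how the outcome record was transformed) and, when kept, `instrument`,
#'   a one-row data frame in [instrument_set()] layout.
#' @export
harmonize_pair <- function(exp, out, cfg = harmonize_config()) {
  exp <- as_record(exp); out <- as_record(out)
  if (!identical(exp$snp, out$snp))
    stop("records are for different SNPs: ", exp$snp, " vs ", out$snp)
  check_alleles(exp$ea, exp$oa, out$ea, out$oa)
  if (exp$ea == exp$oa || out$ea == out$oa)
    stop("effect and other allele must differ")

  drop <- function(reason, detail = reason)
    list(status = "drop", reason = reason, action = "drop",
         instrument = NULL, detail = detail)
  keep <- function(beta_out, eaf_out, action) {
    inst <- data.frame(snp = exp$snp, chr = exp$chr, ea = exp$ea, oa = exp$oa,
                       eaf = exp$eaf, beta_exp = exp$beta, se_exp = exp$se,
                       p_exp = exp$pvalue, beta_out = beta_out,
                       se_out = out$se, p_out = out$pvalue, f = NA_real_,
                       eaf_out = eaf_out, n_exp = exp$n, n_out = out$n,
                       stringsAsFactors = FALSE)
    list(status = "ok", reason = NA_character_, action = action,
         instrument = inst, detail = NA_character_)
  }

  if (is_palindromic(exp$ea, exp$oa)) {
    # complement equals swap for a palindromic pair: letters can only say
    # whether the order matches, never the strand
    if (!setequal(c(out$ea, out$oa), c(exp$ea, exp$oa)))
      return(drop("allele_mismatch"))
    if (isTRUE(cfg$drop_palindromic_always))
      return(drop("palindromic_intermediate", "drop_palindromic_always"))
    if (is.na(exp$eaf) || is.na(out$eaf))
      return(drop("palindromic_intermediate", "missing EAF"))
    if (exp$eaf >= cfg$intermediate_low && exp$eaf <= cfg$intermediate_high)
      return(drop("palindromic_intermediate",
                  sprintf("exposure EAF %.4f in [%.2f, %.2f]", exp$eaf,
                          cfg$intermediate_low, cfg$intermediate_high)))
    if (out$ea == exp$ea) { b <- out$beta; f <- out$eaf }
    else { b <- -out$beta; f <- 1 - out$eaf }
    if (sign(exp$eaf - 0.5) == sign(f - 0.5))
      keep(b, f, "palindromic_keep")
    else
      keep(-b, 1 - f, "palindromic_flip")
  } else {
    eaf_o <- out$eaf
    if (out$ea == exp$ea && out$oa == exp$oa)
      keep(out$beta, eaf_o, "same")
    else if (out$ea == exp$oa && out$oa == exp$ea)
      keep(-out$beta, if (is.na(eaf_o)) NA_real_ else 1 - eaf_o, "swap")
    else if (COMPLEMENT[[out$ea]] == exp$ea && COMPLEMENT[[out$oa]] == exp$oa)
      keep(out$beta, eaf_o, "complement")
    else if (COMPLEMENT[[out$ea]] == exp$oa && COMPLEMENT[[out$oa]] == exp$ea)
      keep(-out$beta, if (is.na(eaf_o)) NA_real_ else 1 - eaf_o,
           "complement_swap")
    else
      drop("allele_mismatch")
  }
}

#' Harmonize exposure and outcome summary statistics
#'
#' Inner-joins two summary-statistics tables on SNP id and passes every
#' matched pair through [harmonize_pair()]. Dropped SNPs are recorded in the
#' returned set's provenance, one row per SNP with a machine-readable reason.
#'
#' @param exposure,outcome Validated summary-statistics data frames as
#'   returned by [read_sumstats()] (columns `snp, ea, oa, beta, se, pvalue`,
#'   optional `chr, eaf, n`).
#' @param cfg A [harmonize_config()].
#' @param exposure_name,outcome_name Trait labels for the result.
#' @return An [instrument_set()] of harmonized instruments.
#' @examples
#' sim <- simulate_pair(sim_scenario(j_snps = 10, seed = 1))
#' harmonize(sim$exposure, sim$outcome)
#' @export
harmonize <- function(exposure, outcome, cfg = harmonize_config(),
                      exposure_name = "exposure", outcome_name = "outcome") {
  shared <- intersect(exposure$snp, outcome$snp)
  rows <- vector("list", length(shared))
  prov <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    s <- shared[i]
    e <- exposure[match(s, exposure$snp), , drop = FALSE]
    o <- outcome[match(s, outcome$snp), , drop = FALSE]
    h <- harmonize_pair(e, o, cfg)
    if (h$status == "ok") rows[[i]] <- h$instrument
    else prov[[i]] <- data.frame(snp = s, reason = h$reason,
                                 detail = h$detail, stringsAsFactors = FALSE)
  }
  instruments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(instruments))
    instruments <- data.frame(snp = character(), chr = character(),
                              ea = character(), oa = character(),
                              eaf = numeric(), beta_exp = numeric(),
                              se_exp = numeric(), p_exp = numeric(),
                              beta_out = numeric(), se_out = numeric(),
                              p_out = numeric(), f = numeric(),
                              eaf_out = numeric(), n_exp = numeric(),
                              n_out = numeric(), stringsAsFactors = FALSE)
  provenance <- do.call(rbind, prov[!vapply(prov, is.null, logical(1))])
  if (is.null(provenance))
    provenance <- data.frame(snp = character(), reason = character(),
                             detail = character(), stringsAsFactors = FALSE)
  res <- instrument_set(instruments, exposure = exposure_name,
                        outcome = outcome_name, provenance = provenance)
  if (length(shared) == 0L)
    attr(res, "note") <- "zero SNP overlap between exposure and outcome"
  res
}
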