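# In-code fixtures shared across test files.

# A small instrument set with reproducible random effects.
random_instruments <- function(j, seed = 1, theta = -2) {
  set.seed(seed)
  data.frame(
    snp = sprintf("rs%03d", seq_len(j)),
    chr = as.character(rep_len(1:22, j)),
    ea = rep_len(c("A", "C", "G"), j),
    oa = rep_len(c("G", "T", "A"), j),
    eaf = runif(j, 0.1, 0.9),
    beta_exp = rnorm(j, 0, 0.003) + 0.002 * sample(c(-1, 1), j, TRUE),
    se_exp = runif(j, 2e-4, 6e-4),
    p_exp = runif(j, 1e-12, 1e-8),
    beta_out = NA_real_,
    se_out = runif(j, 0.01, 0.04),
    p_out = runif(j, 0.01, 0.9),
    stringsAsFactors = FALSE
  ) -> df
  df$beta_exp[abs(df$beta_exp) < 1e-4] <- 1e-3
  df$beta_out <- theta * df$beta_exp + rnorm(j, 0, df$se_out)
  instrument_set(df)
}

# One-row summary-statistic record as a list.
rec <- function(snp = "rs1", ea = "A", oa = "G", beta = 0.01, se = 0.002,
                pvalue = 1e-9, eaf = 0.3, chr = "1", n = NA_real_) {
  list(snp = snp, ea = ea, oa = oa, beta = beta, se = se, pvalue = pvalue,
       eaf = eaf, chr = chr, n = n)
}

write_sumstats_file <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
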