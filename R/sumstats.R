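#' Read a GWAS summary-statistics table
#'
#' Reads a tab- or comma-separated summary-statistics file (the plain
#' beta/se/pval dialect used by OpenGWAS exports) into a validated data frame
#' with one row per SNP. Rows that fail validation (bad alleles,
#' non-positive standard error, p-value outside (0, 1], unparseable numbers)
#' are dropped and reported, so that converted rows + rejected rows = input
#' rows.
#'
#' @param path Path to a text file with a header row.
#' @param column_map Named character vector mapping the canonical field names
#'   `snp, chr, ea, oa, eaf, beta, se, pvalue, n` to the column names used in
#'   the file. Canonical names and common synonyms (e.g. `rsid`,
#'   `effect_allele`, `pval`) are recognised without a map. `snp, ea, oa,
#'   beta, se, pvalue` are required; the rest are optional.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A `data.frame` with columns `snp, chr, ea, oa, eaf, beta, se,
#'   pvalue, n` (optional fields are `NA` when absent), alleles upper-cased.
#'   Rejected rows, if any, are reported in a warning and available as
#'   `attr(x, "rejected")`, a data frame of `(row, snp, reason)`.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("rsid\tea\toa\tbeta\tse\tpval",
#'              "rs1\ta\tg\t0.01\t0.002\t6.1e-9"), f)
#' read_sumstats(f)
#' @export
read_sumstats <- function(path, column_map = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           quote = "\"", comment.char = "")
  synonyms <- list(
    snp    = c("snp", "rsid", "rs_id", "snp_id", "markername", "id"),
    chr    = c("chr", "chrom", "chromosome"),
    ea     = c("ea", "effect_allele", "alt", "a1"),
    oa     = c("oa", "other_allele", "ref", "a2", "non_effect_allele"),
    eaf    = c("eaf", "effect_allele_frequency", "af", "maf", "freq"),
    beta   = c("beta", "b", "effect", "beta_exp"),
    se     = c("se", "standard_error", "sebeta"),
    pvalue = c("pvalue", "p", "pval", "p_value", "p-value"),
    n      = c("n", "samplesize", "sample_size")
  )
  cols <- tolower(names(raw))
  pick <- function(field) {
    if (!is.null(column_map) && field %in% names(column_map)) {
      j <- match(tolower(column_map[[field]]), cols)
      if (is.na(j)) stop("column_map names column '", column_map[[field]],
                         "' for field '", field, "' but it is not in the file")
      return(j)
    }
    j <- match(synonyms[[field]], cols)
    j <- j[!is.na(j)]
    if (length(j)) j[1] else NA_integer_
  }
  idx <- vapply(names(synonyms), pick, integer(1))
  required <- c("snp", "ea", "oa", "beta", "se", "pvalue")
  missing_req <- required[is.na(idx[required])]
  if (length(missing_req))
    stop("required column(s) not found: ", paste(missing_req, collapse = ", "),
         "; supply a column_map")

  get_col <- function(field) if (is.na(idx[[field]])) rep(NA_character_, nrow(raw))
                             else raw[[idx[[field]]]]
  out <- data.frame(
    snp    = get_col("snp"),
    chr    = get_col("chr"),
    ea     = toupper(get_col("ea")),
    oa     = toupper(get_col("oa")),
    eaf    = suppressWarnings(as.numeric(get_col("eaf"))),
    beta   = suppressWarnings(as.numeric(get_col("beta"))),
    se     = suppressWarnings(as.numeric(get_col("se"))),
    pvalue = suppressWarnings(as.numeric(get_col("pvalue"))),
    n      = suppressWarnings(as.numeric(get_col("n"))),
    stringsAsFactors = FALSE
  )
  v <- validate_sumstats(out)
  if (nrow(v$rejected))
    warning(nrow(v$rejected), " row(s) rejected during validation (rows ",
            paste(v$rejected$row, collapse = ", "), "); see attr(x, 'rejected')")
  res <- v$valid
  attr(res, "rejected") <- v$rejected
  res
}

# Split a raw summary-statistics frame into valid rows and rejected rows with
# machine-readable reasons. Totality: nrow(valid) + nrow(rejected) == nrow(x).
validate_sumstats <- function(x) {
  reason <- rep(NA_character_, nrow(x))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- FALSE
    reason[cond & is.na(reason)] <<- why
  }
  eaf_given <- !is.na(x$eaf)
  n_given <- !is.na(x$n)
  bad(is.na(x$snp) | x$snp == "", "missing snp id")
  bad(!x$ea %in% c("A", "C", "G", "T"), "invalid effect allele")
  bad(!x$oa %in% c("A", "C", "G", "T"), "invalid other allele")
  bad(x$ea == x$oa, "identical alleles")
  bad(is.na(x$beta) | !is.finite(x$beta), "unparseable beta")
  bad(is.na(x$se) | !is.finite(x$se) | x$se <= 0, "se not > 0")
  bad(is.na(x$pvalue) | x$pvalue <= 0 | x$pvalue > 1, "pvalue outside (0,1]")
  bad(eaf_given & (x$eaf <= 0 | x$eaf >= 1), "eaf outside (0,1)")
  bad(n_given & (x$n <= 0 | x$n != round(x$n)), "n not a positive integer")
  keep <- is.na(reason)
  rejected <- data.frame(row = which(!keep),
                         snp = x$snp[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  valid <- x[keep, , drop = FALSE]
  rownames(valid) <- NULL
  list(valid = valid, rejected = rejected)
}

instrument_columns <- c("snp", "chr", "ea", "oa", "eaf", "beta_exp", "se_exp",
                        "p_exp", "beta_out", "se_out", "p_out", "f",
                        "eaf_out", "n_exp", "n_out")

#' Construct an instrument set
#'
#' An `instrument_set` holds harmonized instruments — one row per SNP with
#' exposure and outcome effects expressed for the same effect allele —
#' together with trait names and a provenance table recording every SNP
#' dropped on the way, each with a machine-readable reason code
#' (`palindromic_intermediate`, `weak_instrument`, `steiger_reverse`,
#' `clumped`, `allele_mismatch`).
#'
#' @param instruments Data frame with columns `snp, ea, oa, beta_exp, se_exp,
#'   p_exp, beta_out, se_out, p_out`; optional `chr, eaf, eaf_out, f, n_exp,
#'   n_out` (filled with `NA` when absent). `eaf` is the exposure
#'   effect-allele frequency; `f` the instrument-strength F statistic.
#' @param exposure,outcome Trait labels.
#' @param provenance Data frame `(snp, reason, detail)` of dropped SNPs;
#'   empty by default.
#' @return An object of class `instrument_set`.
#' @seealso [harmonize()], [metformin_ra_instruments()]
#' @export
instrument_set <- function(instruments, exposure = "exposure",
                           outcome = "outcome", provenance = NULL) {
  stopifnot(is.data.frame(instruments))
  need <- c("snp", "ea", "oa", "beta_exp", "se_exp", "p_exp",
            "beta_out", "se_out", "p_out")
  miss <- setdiff(need, names(instruments))
  if (length(miss))
    stop("instruments lacks column(s): ", paste(miss, collapse = ", "))
  for (col in setdiff(instrument_columns, names(instruments)))
    instruments[[col]] <- if (col %in% c("snp", "chr", "ea", "oa"))
      NA_character_ else NA_real_
  instruments <- instruments[, instrument_columns]
  if (anyDuplicated(instruments$snp))
    stop("duplicate snp ids in instrument set")
  if (nrow(instruments)) {
    stopifnot(all(instruments$se_exp > 0), all(instruments$se_out > 0))
    f_known <- !is.na(instruments$f)
    if (any(f_known & (instruments$f < 0 | !is.finite(instruments$f))))
      stop("f statistics must be finite and >= 0")
  }
  if (is.null(provenance))
    provenance <- data.frame(snp = character(), reason = character(),
                             detail = character(), stringsAsFactors = FALSE)
  if (anyDuplicated(provenance$snp))
    stop("provenance must record each dropped SNP exactly once")
  rownames(instruments) <- NULL
  structure(list(instruments = instruments, exposure = exposure,
                 outcome = outcome, provenance = provenance),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("Instrument set:", nrow(x$instruments), "SNPs\n")
  cat("  exposure:", x$exposure, "\n  outcome: ", x$outcome, "\n")
  if (nrow(x$provenance)) {
    tab <- table(x$provenance$reason)
    cat("  dropped: ", paste(sprintf("%s (%d)", names(tab), tab),
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.instrument_set <- function(x, ...) x$instruments

#' @export
length.instrument_set <- function(x) nrow(x$instruments)

#' Subset an instrument set
#'
#' @param x An `instrument_set`.
#' @param i Row index or SNP ids.
#' @param ... Ignored.
#' @export
`[.instrument_set` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$instruments$snp)
  x$instruments <- x$instruments[i, , drop = FALSE]
  rownames(x$instruments) <- NULL
  x
}

#' Write and read harmonized instrument tables
#'
#' `write_instruments()` serialises an instrument set as a tab-separated
#' table with a fixed column order (`snp, chr, ea, oa, eaf, beta_exp, se_exp,
#' p_exp, beta_out, se_out, p_out, f, eaf_out, n_exp, n_out`) so that files
#' diff cleanly; numbers carry enough digits that `read_instruments()`
#' recovers each field exactly (round-trip identity to at least 10
#' significant digits). Missing optional values are written as `NA`.
#'
#' @param x An [instrument_set()].
#' @param path Output (input) file path.
#' @return `write_instruments()` returns `path` invisibly;
#'   `read_instruments()` returns an `instrument_set` (with empty
#'   provenance — provenance is an in-memory audit trail, not serialised).
#' @export
write_instruments <- function(x, path) {
  stopifnot(inherits(x, "instrument_set"))
  df <- x$instruments
  fmt <- function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "NA", sprintf("%.12g", v)) else
      ifelse(is.na(v), "NA", as.character(v))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(instrument_columns, collapse = "\t"), con)
  if (nrow(df)) {
    out <- vapply(df, fmt, character(nrow(df)))
    if (nrow(df) == 1L) out <- matrix(out, nrow = 1L,
                                      dimnames = list(NULL, names(df)))
    writeLines(apply(out, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_instruments
#' @param exposure,outcome Trait labels attached to the reloaded set.
#' @export
read_instruments <- function(path, exposure = "exposure",
                             outcome = "outcome") {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE)
  need <- c("snp", "ea", "oa", "beta_exp", "se_exp", "p_exp",
            "beta_out", "se_out", "p_out")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("instrument file lacks column(s): ", paste(miss, collapse = ", "))
  df <- data.frame(snp = raw$snp, stringsAsFactors = FALSE)
  chr_cols <- c("chr", "ea", "oa")
  for (col in setdiff(instrument_columns, "snp")) {
    if (!col %in% names(raw)) { df[[col]] <- NA; next }
    v <- raw[[col]]
    v[v == "NA"] <- NA
    df[[col]] <- if (col %in% chr_cols) as.character(v) else as.numeric(v)
  }
  df$ea <- toupper(df$ea); df$oa <- toupper(df$oa)
  instrument_set(df, exposure = exposure, outcome = outcome)
}

#' The metformin-use vs rheumatoid-arthritis instrument table
#'
#' Loads the bundled table of 32 harmonized instruments for genetically
#' proxied metformin use (UK Biobank GWAS of 462,933 individuals; 11,552
#' metformin users) against rheumatoid arthritis (GWAS meta-analysis of
#' 58,284 individuals; 14,361 cases). Each row carries the SNP's exposure
#' association (beta, SE, p on the metformin-use scale), its outcome
#' association (log-odds of RA), the exposure effect-allele frequency and the
#' published instrument-strength F statistic. Per-SNP sample sizes are not
#' available for this table (`n_exp`/`n_out` are `NA`); the study-level
#' totals are stored as `attr(x, "n_exposure")` and `attr(x, "n_outcome")`.
#'
#' @return An [instrument_set()] of 32 instruments.
#' @examples
#' ivs <- metformin_ra_instruments()
#' mr_fit(ivs, methods = "ivw")
#' @export
metformin_ra_instruments <- function() {
  path <- system.file("extdata", "metformin_ra_instruments.tsv",
                      package = "mrkit", mustWork = TRUE)
  x <- read_instruments(path,
                        exposure = "Metformin use (UK Biobank)",
                        outcome = "Rheumatoid arthritis (Okada 2014)")
  attr(x, "n_exposure") <- 462933L
  attr(x, "n_outcome") <- 58284L
  x
}
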