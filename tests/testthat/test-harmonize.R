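test_that("palindromic classification follows the complement rule", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("G", "C"))
  expect_false(is_palindromic("C", "T"))
  expect_false(is_palindromic("A", "G"))
  # symmetric in its arguments, over every valid pair
  for (a in c("A", "C", "G", "T")) for (b in setdiff(c("A", "C", "G", "T"), a))
    expect_identical(is_palindromic(a, b), is_palindromic(b, a))
  expect_error(is_palindromic("A", "N"), "invalid allele")
  expect_error(is_palindromic("A", "A"), "differ")
})

test_that("harmonize_pair handles direct, swapped and complemented alleles", {
  e <- rec(ea = "C", oa = "T", beta = -0.0019, eaf = 0.4051)

  direct <- harmonize_pair(e, rec(ea = "C", oa = "T", beta = 0.0101,
                                  se = 0.0136, eaf = 0.40))
  expect_equal(direct$action, "same")
  expect_equal(direct$instrument$beta_exp, -0.0019)
  expect_equal(direct$instrument$beta_out, 0.0101)

  swapped <- harmonize_pair(e, rec(ea = "T", oa = "C", beta = 0.0101,
                                   eaf = 0.60))
  expect_equal(swapped$action, "swap")
  expect_equal(swapped$instrument$beta_out, -0.0101)
  expect_equal(swapped$instrument$eaf_out, 0.40)

  comp <- harmonize_pair(e, rec(ea = "G", oa = "A", beta = 0.0101,
                                eaf = 0.40))
  expect_equal(comp$action, "complement")
  expect_equal(comp$instrument$beta_out, 0.0101)

  comp_swap <- harmonize_pair(e, rec(ea = "A", oa = "G", beta = 0.0101,
                                     eaf = 0.60))
  expect_equal(comp_swap$action, "complement_swap")
  expect_equal(comp_swap$instrument$beta_out, -0.0101)

  bad <- harmonize_pair(e, rec(ea = "A", oa = "C", beta = 0.0101))
  expect_equal(bad$status, "drop")
  expect_equal(bad$reason, "allele_mismatch")
})

test_that("palindromic SNPs drop at intermediate frequency, orient otherwise", {
  pal <- function(eaf_exp, eaf_out, out_ea = "A", out_oa = "T", ...)
    harmonize_pair(rec(ea = "A", oa = "T", beta = 0.002, eaf = eaf_exp),
                   rec(ea = out_ea, oa = out_oa, beta = 0.05, eaf = eaf_out),
                   ...)
  # the midpoint is always intermediate
  expect_equal(pal(0.50, 0.50)$reason, "palindromic_intermediate")
  expect_equal(pal(0.42, 0.30)$reason, "palindromic_intermediate")
  expect_equal(pal(NA, 0.30)$reason, "palindromic_intermediate")
  expect_equal(pal(0.30, NA)$reason, "palindromic_intermediate")
  # informative frequencies on the same side: keep as labelled
  keep <- pal(0.30, 0.28)
  expect_equal(keep$action, "palindromic_keep")
  expect_equal(keep$instrument$beta_out, 0.05)
  # opposite sides: the outcome file reported the other strand; flip
  flip <- pal(0.30, 0.72)
  expect_equal(flip$action, "palindromic_flip")
  expect_equal(flip$instrument$beta_out, -0.05)
  expect_equal(flip$instrument$eaf_out, 0.28)
  # swapped labels plus frequency agreement
  sw <- pal(0.30, 0.70, out_ea = "T", out_oa = "A")
  expect_equal(sw$instrument$beta_out, -0.05)
  # configurable hard drop
  cfg <- harmonize_config(drop_palindromic_always = TRUE)
  expect_equal(pal(0.10, 0.10, cfg = cfg)$reason, "palindromic_intermediate")
  # window bounds must be symmetric about 0.5
  expect_error(harmonize_config(0.42, 0.60), "1e-12|is not TRUE")
})

test_that("harmonize_pair matches an exhaustive hand truth table", {
  # Independent classification of every ordered allele configuration:
  # keep/copy, keep/negate, or drop, written from first principles.
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  alleles <- c("A", "C", "G", "T")
  expected_decision <- function(e_ea, e_oa, o_ea, o_oa) {
    pal <- comp[[e_ea]] == e_oa
    if (pal) {
      if (!setequal(c(o_ea, o_oa), c(e_ea, e_oa))) return("drop_mismatch")
      # exposure EAF 0.20, outcome EAF 0.25: same side of 0.5 when the
      # effect-allele labels agree, opposite when they are swapped
      if (o_ea == e_ea) "keep_copy" else "keep_negate"
    } else {
      if (o_ea == e_ea && o_oa == e_oa) return("keep_copy")
      if (o_ea == e_oa && o_oa == e_ea) return("keep_negate")
      if (comp[[o_ea]] == e_ea && comp[[o_oa]] == e_oa) return("keep_copy")
      if (comp[[o_ea]] == e_oa && comp[[o_oa]] == e_ea) return("keep_negate")
      "drop_mismatch"
    }
  }
  n_cases <- 0
  for (e_ea in alleles) for (e_oa in setdiff(alleles, e_ea))
    for (o_ea in alleles) for (o_oa in setdiff(alleles, o_ea)) {
      got <- harmonize_pair(rec(ea = e_ea, oa = e_oa, beta = 0.01,
                                eaf = 0.20),
                            rec(ea = o_ea, oa = o_oa, beta = 0.07,
                                eaf = if (o_ea == e_ea) 0.25 else 0.75))
      want <- expected_decision(e_ea, e_oa, o_ea, o_oa)
      label <- paste(e_ea, e_oa, "vs", o_ea, o_oa)
      if (want == "drop_mismatch") {
        expect_equal(got$reason, "allele_mismatch", info = label)
      } else {
        expect_equal(got$status, "ok", info = label)
        expect_equal(got$instrument$beta_out,
                     if (want == "keep_copy") 0.07 else -0.07, info = label)
      }
      n_cases <- n_cases + 1
    }
  expect_equal(n_cases, 144)
})

test_that("harmonization preserves magnitudes and is involutive under swap", {
  set.seed(42)
  for (i in 1:20) {
    b <- rnorm(1); se <- runif(1, 0.01, 0.1); eaf <- runif(1, 0.05, 0.95)
    e <- rec(ea = "A", oa = "G", beta = rnorm(1), eaf = 0.3)
    o1 <- rec(ea = "A", oa = "G", beta = b, se = se, eaf = eaf)
    o2 <- rec(ea = "G", oa = "A", beta = -b, se = se, eaf = 1 - eaf)
    h1 <- harmonize_pair(e, o1)
    h2 <- harmonize_pair(e, o2)  # doubly-swapped record: same content
    expect_equal(h1$instrument$beta_out, h2$instrument$beta_out)
    expect_equal(h1$instrument$eaf_out, h2$instrument$eaf_out)
    expect_equal(abs(h1$instrument$beta_out), abs(b))
    expect_equal(h1$instrument$se_out, se)
  }
})

test_that("harmonize joins, drops palindromic-intermediate SNPs and logs them", {
  set.seed(7)
  j <- 34
  exposure <- data.frame(
    snp = sprintf("rs%02d", 1:j), chr = "1",
    ea = rep("A", j), oa = rep("G", j),
    eaf = runif(j, 0.1, 0.35), beta = rnorm(j, 0, 0.003),
    se = rep(3e-4, j), pvalue = rep(1e-9, j), n = NA_real_,
    stringsAsFactors = FALSE)
  outcome <- exposure
  outcome$beta <- rnorm(j, 0, 0.02)
  outcome$se <- rep(0.02, j)
  outcome$pvalue <- runif(j)
  # two palindromic SNPs with intermediate frequency, as in the source study
  pali <- c(5, 20)
  exposure$ea[pali] <- "A"; exposure$oa[pali] <- "T"
  outcome$ea[pali] <- "A"; outcome$oa[pali] <- "T"
  exposure$eaf[pali] <- c(0.50, 0.43)

  h <- harmonize(exposure, outcome)
  expect_equal(length(h), 32)
  expect_equal(nrow(h$provenance), 2)
  expect_setequal(h$provenance$snp, sprintf("rs%02d", pali))
  expect_true(all(h$provenance$reason == "palindromic_intermediate"))

  # disjoint SNP sets: empty set, zero-overlap note
  outcome2 <- outcome
  outcome2$snp <- paste0(outcome2$snp, "x")
  h2 <- harmonize(exposure, outcome2)
  expect_equal(length(h2), 0)
  expect_match(attr(h2, "note"), "zero SNP overlap")

  # a strand-complemented record is retained with the hand-aligned sign
  outcome3 <- outcome[1, ]
  outcome3$ea <- "C"; outcome3$oa <- "T"  # complement-swap of A/G
  h3 <- harmonize(exposure[1, ], outcome3)
  expect_equal(length(h3), 1)
  expect_equal(h3$instruments$beta_out, -outcome3$beta)
})
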