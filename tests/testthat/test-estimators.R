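test_that("Wald ratios follow the delta method and its symmetries", {
  # direct division of the strongest published instrument's values
  x <- instrument_set(data.frame(
    snp = "rs34872471", ea = "C", oa = "T", beta_exp = 0.0086,
    se_exp = 0.0004, p_exp = 1.099e-127, beta_out = -0.0488,
    se_out = 0.0188, p_out = 0.009, stringsAsFactors = FALSE))
  w <- wald_ratios(x)
  expect_equal(w$ratio, -0.0488 / 0.0086)
  expect_equal(w$se, 0.0188 / 0.0086)
  expect_equal(w$weight, 1 / w$se^2)

  # null numerator; odd symmetry in the exposure effect
  y <- random_instruments(5)
  y$instruments$beta_out[1] <- 0
  wy <- wald_ratios(y)
  expect_equal(wy$ratio[1], 0)
  expect_equal(wy$se[1], y$instruments$se_out[1] /
                 abs(y$instruments$beta_exp[1]))
  flipped <- y
  flipped$instruments$beta_exp <- -flipped$instruments$beta_exp
  expect_equal(wald_ratios(flipped)$ratio, -wy$ratio)
  expect_equal(wald_ratios(flipped)$se, wy$se)

  # second-order SE adds the exposure-uncertainty term (vanishing only at
  # a null outcome effect)
  w2 <- wald_ratios(y, second_order = TRUE)
  nz <- y$instruments$beta_out != 0
  expect_true(all(w2$se[nz] > wy$se[nz]))
  expect_equal(w2$se[!nz], wy$se[!nz])

  z <- random_instruments(3)
  z$instruments$beta_exp[2] <- 0
  expect_error(wald_ratios(z), "degenerate")
})

test_that("IVW equals weighted least squares through the origin", {
  x <- random_instruments(5, seed = 11)
  fit <- mr_ivw(x)
  df <- x$instruments
  # independent oracle: WLS of beta_out on beta_exp without intercept,
  # weights 1/se_out^2 — algebraically identical to inverse-variance
  # pooling of the Wald ratios with first-order SEs
  ora <- lm(beta_out ~ 0 + beta_exp, data = df, weights = 1 / se_out^2)
  expect_equal(fit$b, unname(coef(ora)), tolerance = 1e-12)
  expect_equal(fit$nsnp, 5)

  # two identical instruments pool to their common ratio with se/sqrt(2)
  two <- instrument_set(data.frame(
    snp = c("rs1", "rs2"), ea = "A", oa = "G", beta_exp = 0.002,
    se_exp = 3e-4, p_exp = 1e-9, beta_out = -0.008, se_out = 0.02,
    p_out = 0.5, stringsAsFactors = FALSE))
  f2 <- mr_ivw(two)
  expect_equal(f2$b, -0.008 / 0.002)
  expect_equal(f2$se, (0.02 / 0.002) / sqrt(2))

  expect_error(mr_ivw(x[1]), "Wald ratio")
})

test_that("IVW is invariant to reordering and joint sign flips", {
  x <- random_instruments(8, seed = 5)
  base <- mr_ivw(x)
  perm <- x[sample(8)]
  expect_equal(mr_ivw(perm)$b, base$b)
  expect_equal(mr_ivw(perm)$se, base$se)
  flip <- x
  idx <- c(2, 5, 7)
  flip$instruments$beta_exp[idx] <- -flip$instruments$beta_exp[idx]
  flip$instruments$beta_out[idx] <- -flip$instruments$beta_out[idx]
  expect_equal(mr_ivw(flip)$b, base$b, tolerance = 1e-12)
})

test_that("random-effects IVW scales the SE by the heterogeneity factor", {
  x <- random_instruments(10, seed = 2)
  fixed <- mr_ivw(x, "fixed")
  random <- mr_ivw(x, "random")
  expect_equal(random$b, fixed$b)
  expect_equal(random$se,
               fixed$se * max(1, sqrt(fixed$q / (fixed$nsnp - 1))))
})

test_that("Egger regression matches an independent WLS solve with SE floor", {
  x <- random_instruments(6, seed = 9)
  fit <- mr_egger(x)
  df <- x$instruments
  s <- ifelse(df$beta_exp < 0, -1, 1)
  d <- data.frame(bx = s * df$beta_exp, by = s * df$beta_out,
                  w = 1 / df$se_out^2)
  ora <- summary(lm(by ~ bx, data = d, weights = w))
  floor <- min(ora$sigma, 1)
  expect_equal(fit$b, unname(ora$coefficients["bx", 1]), tolerance = 1e-10)
  expect_equal(fit$intercept, unname(ora$coefficients["(Intercept)", 1]),
               tolerance = 1e-10)
  expect_equal(fit$se, unname(ora$coefficients["bx", 2]) / floor,
               tolerance = 1e-10)
  expect_equal(fit$intercept_se,
               unname(ora$coefficients["(Intercept)", 2]) / floor,
               tolerance = 1e-10)
  expect_equal(fit$pvalue, 2 * pt(-abs(fit$b / fit$se), 4))

  # orientation invariance: relabelling effect alleles changes nothing
  flip <- x
  flip$instruments$beta_exp <- -flip$instruments$beta_exp
  flip$instruments$beta_out <- -flip$instruments$beta_out
  expect_equal(mr_egger(flip)$b, fit$b)
  expect_equal(mr_egger(flip)$intercept, fit$intercept)

  expect_error(mr_egger(random_instruments(2)), "at least 3")
})

test_that("Egger recovers an exact affine relation to machine precision", {
  x <- random_instruments(8, seed = 4)
  a <- 0.013; b <- -2.5
  x$instruments$beta_exp <- abs(x$instruments$beta_exp)
  x$instruments$beta_out <- a + b * x$instruments$beta_exp
  fit <- mr_egger(x)
  expect_equal(fit$intercept, a, tolerance = 1e-12)
  expect_equal(fit$b, b, tolerance = 1e-12)
  expect_equal(fit$sigma, 0, tolerance = 1e-6)
})

test_that("weighted median interpolates cumulative weights at one half", {
  # equal weights, odd count: plain sample median
  x <- random_instruments(7, seed = 8)
  w <- wald_ratios(x)
  x$instruments$se_out <- abs(x$instruments$beta_exp) # unit ratio SEs
  weq <- wald_ratios(x)
  expect_equal(weighted_median_point(weq$ratio, weq$weight),
               median(weq$ratio))

  # hand-computed breakpoint cases
  expect_equal(weighted_median_point(c(1, 2, 3, 4, 5), c(1, 1, 2, 1, 1)), 3)
  expect_equal(weighted_median_point(c(1, 2, 3, 4, 5), c(1, 1, 1, 1, 4)), 4.2)

  # brute-force breakpoint oracle on random weights
  oracle <- function(r, w) {
    o <- order(r); r <- r[o]; w <- w[o]
    p <- (cumsum(w) - w / 2) / sum(w)
    if (0.5 <= p[1]) return(r[1])
    if (0.5 >= p[length(p)]) return(r[length(r)])
    i <- max(which(p <= 0.5))
    r[i] + (r[i + 1] - r[i]) * (0.5 - p[i]) / (p[i + 1] - p[i])
  }
  set.seed(21)
  for (rep in 1:10) {
    r <- rnorm(5); w <- runif(5, 0.1, 3)
    expect_equal(weighted_median_point(r, w), oracle(r, w))
  }
})

test_that("bootstrap SEs are seed-reproducible and stable across seeds", {
  x <- metformin_ra_instruments()
  a <- mr_weighted_median(x, n_boot = 1000, seed = 42)
  b <- mr_weighted_median(x, n_boot = 1000, seed = 42)
  expect_identical(a$se, b$se)  # bit-for-bit under a fixed seed
  c2 <- mr_weighted_median(x, n_boot = 1000, seed = 99)
  cv <- abs(a$se - c2$se) / mean(c(a$se, c2$se))
  expect_lt(cv, 0.05)
  expect_equal(a$b, c2$b)  # the point estimate is deterministic
})

test_that("mode estimators find the dominant cluster", {
  # a tight cluster and one remote light-weight outlier: weighted mode
  # sits on the cluster
  df <- data.frame(
    snp = sprintf("rs%d", 1:6), ea = "A", oa = "G",
    beta_exp = c(rep(0.002, 5), 0.002), se_exp = 3e-4, p_exp = 1e-9,
    beta_out = c(rep(-0.006, 5), 0.02), se_out = c(rep(0.004, 5), 0.4),
    p_out = 0.5, stringsAsFactors = FALSE)
  x <- instrument_set(df)
  wm <- mr_mode(x, "weighted", n_boot = 50, seed = 1)
  expect_equal(wm$b, -3, tolerance = 0.05)

  # all ratios identical: degenerate bandwidth, common ratio with IVW SE
  df2 <- df
  df2$beta_out <- -3 * df2$beta_exp
  df2$se_out <- 0.01
  x2 <- instrument_set(df2)
  m2 <- mr_mode(x2, "simple", n_boot = 10, seed = 1)
  expect_equal(m2$b, -3)
  expect_equal(m2$se, mr_ivw(x2)$se)
  expect_true(isTRUE(m2$degenerate))

  # weighting matters: simple and weighted modes differ when weights are
  # concentrated away from the unweighted bulk
  x3 <- metformin_ra_instruments()
  ms <- mr_mode(x3, "simple", n_boot = 20, seed = 1)
  mw <- mr_mode(x3, "weighted", n_boot = 20, seed = 1)
  expect_false(isTRUE(all.equal(ms$b, mw$b)))
  # identical draws under the same seed
  expect_identical(mr_mode(x3, "weighted", n_boot = 100, seed = 5)$se,
                   mr_mode(x3, "weighted", n_boot = 100, seed = 5)$se)
})

test_that("odds-ratio transform exponentiates the Wald interval", {
  null <- to_or(0, 0.5)
  expect_equal(null$or, 1)
  expect_equal(null$ci_low * null$ci_high, 1, tolerance = 1e-12)
  point <- to_or(log(2), 0)
  expect_equal(unlist(point), c(or = 2, ci_low = 2, ci_high = 2))
  v <- to_or(c(-1, 1), c(0.1, 0.2))
  expect_equal(v$or, exp(c(-1, 1)))
  expect_true(all(v$ci_low < v$or & v$or < v$ci_high))
})

test_that("mr_fit assembles a coherent model object", {
  x <- metformin_ra_instruments()
  fit <- mr_fit(x, n_boot = 50, seed = 3)
  expect_s3_class(fit, "mr_fit")
  expect_equal(nrow(fit$results), 5)
  expect_setequal(fit$results$method,
                  c("ivw_fixed", "egger", "weighted_median", "simple_mode",
                    "weighted_mode"))
  expect_true(all(fit$results$nsnp == 32))
  expect_true(all(fit$results$ci_low < fit$results$or &
                    fit$results$or < fit$results$ci_high))
  expect_named(coef(fit), fit$results$method)
  expect_equal(dim(confint(fit)), c(5, 2))
  expect_output(print(fit), "Egger intercept")
  expect_output(print(summary(fit)), "Cochran's Q")
  expect_equal(length(residuals(fit)), 32)

  # single instrument: only the Wald ratio is available
  one <- mr_fit(x[1])
  expect_equal(one$results$method, "wald")
  expect_equal(one$results$b, with(x$instruments[1, ], beta_out / beta_exp))
})

test_that("IVW recovers the causal effect on synthetic data", {
  errs <- ses <- numeric(200)
  for (r in seq_len(200)) {
    sim <- simulate_pair(sim_scenario(j_snps = 32, seed = 4000 + r))
    h <- harmonize(sim$exposure, sim$outcome)
    fit <- mr_ivw(h)
    errs[r] <- abs(fit$b - sim$truth$theta)
    ses[r] <- fit$se
  }
  expect_lt(median(errs), 2 * mean(ses))
})
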