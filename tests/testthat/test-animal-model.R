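# the model-fitting tests run on reduced designs (8 sires, 12 families,
# 6 offspring per family) so the whole suite stays fast; full-scale
# parameter recovery lives in test-acceptance.R

test_that("build_design assembles y, X, Z1, Z2 and drops incomplete rows", {
  dat <- simulate_dataset(small_config(seed = 2))
  ph <- dat$phenotypes
  b <- build_design(ph, model_spec("y1"), dat$pedigree)
  expect_equal(b$n_used, nrow(ph))
  expect_equal(ncol(b$X), length(unique(ph$test_day)))  # intercept + k-1
  expect_equal(ncol(b$Z1), nrow(dat$pedigree))
  expect_equal(ncol(b$Z2), 12L)  # one hapa column per full-sib family
  expect_equal(unname(Matrix::rowSums(b$Z2)), rep(1, b$n_used))
  # a missing covariate removes that fish
  ph$wx <- rnorm(nrow(ph)); ph$wx[3] <- NA
  b2 <- build_design(ph, model_spec("y1", covariates = "wx"),
                     dat$pedigree)
  expect_equal(b2$n_used, nrow(ph) - 1L)
  expect_equal(b2$n_dropped, 1L)
  # fish not in the pedigree is a linkage error
  ph_bad <- ph; ph_bad$fish_id[1] <- "ghost"
  expect_error(build_design(ph_bad, model_spec("y1"), dat$pedigree),
               "absent from pedigree")
  # aliased fixed-effect columns are named in the error
  ph$dup <- ph$wx
  expect_error(build_design(ph, model_spec("y1",
                                           covariates = c("wx", "dup")),
                            dat$pedigree), "dup")
})

test_that("REML equals closed-form ANOVA-REML on a balanced half-sib design", {
  hs <- half_sib_data(s = 30, nper = 12, sa2 = 6, se2 = 10, seed = 7)
  b <- build_design(hs$phen, model_spec("y", fixed = character(0),
                                        random = "additive"), hs$ped)
  f <- reml_univariate(b, random = "additive",
                       options = list(se = FALSE, rel_tol = 1e-12))
  an <- half_sib_anova(hs$phen, nper = 12)
  expect_equal(f$sigma_a2, an$sigma_a2, tolerance = 1e-6)
  expect_equal(f$sigma_e2, an$sigma_e2, tolerance = 1e-6)
})

test_that("restricted log-likelihood is invariant to fixed-effect coding", {
  dat <- simulate_dataset(small_config(seed = 5))
  b <- build_design(dat$phenotypes, model_spec("y1"), dat$pedigree)
  f1 <- reml_univariate(b, options = list(se = FALSE))
  b_sum <- b
  day <- factor(dat$phenotypes$test_day)
  b_sum$X <- stats::model.matrix(~ day,
                                 contrasts.arg = list(day = "contr.sum"))
  f2 <- reml_univariate(b_sum, options = list(se = FALSE))
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-6)
  expect_equal(f1$h2, f2$h2, tolerance = 1e-4)
})

test_that("REML estimates agree across starting points", {
  dat <- simulate_dataset(small_config(seed = 11))
  b <- build_design(dat$phenotypes, model_spec("y1"), dat$pedigree)
  vy <- var(dat$phenotypes$y1)
  fits <- lapply(list(c(0.1, 0.05, 0.85), c(0.5, 0.2, 0.3),
                      c(0.8, 0.01, 0.19)),
                 function(w) reml_univariate(b, options = list(
                   se = FALSE, start = w * vy)))
  h2s <- vapply(fits, function(f) f$h2, 0)
  lls <- vapply(fits, function(f) f$loglik, 0)
  expect_lt(diff(range(h2s)), 1e-4)
  expect_lt(diff(range(lls)), 1e-6)
})

test_that("variance ratios stay in their simplex and match stored parts", {
  for (seed in c(3, 8)) {
    dat <- simulate_dataset(small_config(seed = seed))
    b <- build_design(dat$phenotypes, model_spec("y1"), dat$pedigree)
    f <- reml_univariate(b, options = list(se = FALSE))
    expect_gte(f$h2, 0); expect_gte(f$c2, 0)
    expect_lte(f$h2 + f$c2, 1)
    expect_equal(f$sigma_p2, f$sigma_a2 + f$sigma_c2 + f$sigma_e2)
    hh <- heritability(f)
    expect_equal(hh$h2, f$sigma_a2 / f$sigma_p2)
    expect_equal(hh$c2, f$sigma_c2 / f$sigma_p2)
  }
})

test_that("a design without genetic signal estimates h2 near the zero boundary", {
  # needs the full half-sib structure: on small designs the confounding
  # of family with additive variance lets either term absorb the signal
  cfg <- sim_config(traits = list(y1 = list(mean = 0, sigma_a2 = 0,
                                            sigma_c2 = 1.5, sigma_e2 = 8,
                                            test_day = TRUE)),
                    seed = 13)
  dat <- simulate_dataset(cfg)
  b <- build_design(dat$phenotypes, model_spec("y1"), dat$pedigree)
  f <- reml_univariate(b)
  expect_lt(f$h2, 0.08)
  expect_gt(f$c2, 0.05)  # the family signal lands on the hapa term
})

test_that("heritability works as a plain ratio with validation", {
  expect_equal(heritability(8.90, 18.45), 8.90 / 18.45)
  expect_equal(round(heritability(8.90, 18.45), 2), 0.48)
  expect_equal(heritability(0, 12), 0)
  expect_error(heritability(4, 0), "positive")
})

test_that("likelihood ratio tests follow the chi-square(1) convention", {
  eq <- lrt(-100, -100)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p_value, 1)
  l <- lrt(-98.08, -100)
  expect_equal(l$chi2, 3.84, tolerance = 1e-9)
  expect_equal(l$p_value, pchisq(3.84, 1, lower.tail = FALSE))
  expect_lt(abs(l$p_value - 0.05), 0.001)
  expect_equal(l$df, 1L)
  # boundary mixture halves the tail probability
  expect_equal(lrt(-98.08, -100, boundary_mixture = TRUE)$p_value,
               l$p_value / 2)
  expect_warning(lrt(-101, -100), "higher log-likelihood")
  # reduced-model fits are accepted directly
  dat <- simulate_dataset(small_config(seed = 4))
  b <- build_design(dat$phenotypes, model_spec("y1"), dat$pedigree)
  full <- reml_univariate(b, options = list(se = FALSE))
  red <- reml_univariate(b, random = "additive",
                         options = list(se = FALSE))
  out <- lrt(full, red)
  expect_gte(out$chi2, 0)
  expect_true(out$p_value >= 0 && out$p_value <= 1)
})

test_that("bivariate REML recovers near-unit correlations for duplicated traits", {
  cfg <- small_config(seed = 21)
  dat <- simulate_dataset(cfg)
  ph <- dat$phenotypes
  set.seed(1)
  ph$y2 <- ph$y1 + rnorm(nrow(ph), sd = 0.05 * sd(ph$y1))
  b1 <- build_design(ph, model_spec("y1"), dat$pedigree)
  b2 <- build_design(ph, model_spec("y2"), dat$pedigree, b1$ainv)
  f <- reml_bivariate(b1, b2, options = list(se = FALSE))
  expect_gt(f$rg, 0.95)
  expect_gt(f$re, 0.9)
  expect_gt(f$rp, 0.95)
  expect_true(f$boundary_cor)  # pinned correlations are flagged
})

test_that("bivariate REML handles per-trait records and missing data", {
  cfg <- small_config(seed = 31,
                      extra_traits = list(y2 = list(mean = 3, sigma_a2 = 2,
                                                    sigma_c2 = 0.5,
                                                    sigma_e2 = 3)),
                      r_a = matrix(c(1, .6, .6, 1), 2),
                      r_c = matrix(c(1, .3, .3, 1), 2),
                      r_e = matrix(c(1, .2, .2, 1), 2))
  dat <- simulate_dataset(cfg)
  ph <- dat$phenotypes
  ph$y2[1:10] <- NA  # trait 2 missing for some fish
  b1 <- build_design(ph, model_spec("y1"), dat$pedigree)
  b2 <- build_design(ph, model_spec("y2", fixed = character(0)),
                     dat$pedigree, b1$ainv)
  f <- reml_bivariate(b1, b2, options = list(se = FALSE))
  expect_equal(f$n_used, c(nrow(ph), nrow(ph) - 10L))
  expect_equal(f$n_dual, nrow(ph) - 10L)
  expect_true(all(abs(c(f$rg, f$rc, f$re)) <= 1))
  expect_true(all(eigen(f$G, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
  # phenotypic covariance recombines from the stored component matrices
  expect_equal(phenotypic_correlation(f), f$rp)
  # constrained genetic covariance is the LRT reduced model
  f0 <- reml_bivariate(b1, b2, fix_ra = 0, options = list(se = FALSE))
  expect_equal(f0$rg, 0)
  expect_lte(f0$loglik, f$loglik + 1e-6)
})

test_that("phenotypic correlation composes the fitted covariance parts", {
  base <- list(G = diag(c(2, 2)), C = diag(c(1, 1)), R = diag(c(3, 3)),
               sigma_p2 = c(6, 6), common_env = c(TRUE, TRUE))
  f0 <- structure(base, class = "reml_biv")
  expect_equal(phenotypic_correlation(f0), 0)
  half <- base
  half$G[1, 2] <- half$G[2, 1] <- 1
  half$C[1, 2] <- half$C[2, 1] <- 0.5
  half$R[1, 2] <- half$R[2, 1] <- 1.5
  expect_equal(phenotypic_correlation(structure(half,
                                                class = "reml_biv")), 0.5)
  # the hapa covariance is omitted when not fitted on both traits
  half$common_env <- c(TRUE, FALSE)
  expect_equal(phenotypic_correlation(structure(half,
                                                class = "reml_biv")),
               2.5 / 6)
})
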