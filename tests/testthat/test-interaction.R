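test_that("carrier_score handles probabilities, hard calls and dosages", {
  expect_equal(carrier_score(2), 1)
  expect_equal(carrier_score(0), 0)
  expect_equal(carrier_score(0.4), 0.4)
  expect_equal(carrier_score(1.7), 1)
  expect_equal(carrier_score(0.4, matrix(c(0.2, 0.5, 0.3), 1)), 0.8)
})

# Independent oracle: direct maximization of the 4-parameter ARDI
# likelihood (no covariates) with optim, compared to the IRLS route.
test_that("ARDI estimate matches brute-force likelihood maximization", {
  set.seed(101)
  sp <- sim_study_spec(100, 100, covariate_effects = NULL, seed = 11)
  dat <- simulate_case_control(
    sp, penetrance_model("ardi_carrier", gamma = log(0.6), b1 = 0.3,
                         b2 = 0.2))
  g1 <- dat$dosages[, "snp1"]; g2 <- dat$dosages[, "snp2"]
  y <- dat$phenotype
  nll <- function(th) {
    eta <- th[1] + th[2] * g1 + th[3] * g2 +
      th[4] * pmin(g1, 1) * pmin(g2, 1)
    -sum(y * eta - log1p(exp(eta)))
  }
  o <- optim(c(0, 0, 0, 0), nll, method = "BFGS",
             control = list(reltol = 1e-14))
  f <- gxg_test(dat, "snp1", "snp2", "ardi")
  expect_equal(f$estimate$beta, o$par[4], tolerance = 1e-4)

  # same oracle for ARDI with unrestricted mains
  nll_um <- function(th) {
    eta <- th[1] + th[2] * (g1 == 1) + th[3] * (g1 == 2) +
      th[4] * (g2 == 1) + th[5] * (g2 == 2) +
      th[6] * pmin(g1, 1) * pmin(g2, 1)
    -sum(y * eta - log1p(exp(eta)))
  }
  o2 <- optim(rep(0, 6), nll_um, method = "BFGS",
              control = list(reltol = 1e-14))
  f2 <- gxg_test(dat, "snp1", "snp2", "ardi_umain")
  expect_equal(f2$estimate$beta, o2$par[6], tolerance = 1e-4)
})

test_that("unrestricted saturated fit reproduces count cross-product ORs", {
  set.seed(55)
  sp <- sim_study_spec(700, 700, covariate_effects = NULL, seed = 5)
  dat <- simulate_case_control(
    sp, penetrance_model("ardi_carrier", gamma = log(0.5), b1 = 0.4,
                         b2 = 0.3))
  crude <- joint_or_table(dat, "snp1", "snp2", adjusted = FALSE)
  adj <- joint_or_table(dat, "snp1", "snp2", adjusted = TRUE)
  ok <- !is.na(crude$or)
  expect_equal(adj$or[ok], crude$or[ok], tolerance = 1e-6)
})

test_that("empty interaction cells reduce the unrestricted df", {
  set.seed(77)
  n <- 400
  g1 <- simulate_genotypes(n, 0.3)
  g2 <- simulate_genotypes(n, 0.3)
  g2[g1 == 2 & g2 == 2] <- 1  # empty the double-homozygote cell
  y <- rbinom(n, 1, plogis(0.2 * g1 - 0.1 * g2))
  dat <- make_dataset(cbind(a = g1, b = g2), y)
  f <- gxg_test(dat, "a", "b", "unrestricted")
  expect_equal(f$estimate$df, 3L)
  expect_equal(f$dropped_cells, "gamma_22")
})

test_that("identical SNP twice returns a result or flagged failure", {
  set.seed(12)
  d <- simulate_genotypes(500, 0.3)
  y <- rbinom(500, 1, 0.5)
  dat <- make_dataset(cbind(a = d, b = d), y)
  f <- gxg_test(dat, "a", "b", "multiplicative")
  expect_s3_class(f, "gxg_fit")
  expect_true(is.logical(f$estimate$converged))
})

test_that("constant SNP yields a flagged failure in the marginal test", {
  dat <- make_dataset(cbind(a = rep(1, 60)), rbinom(60, 1, 0.5))
  f <- marginal_test(dat, "a")
  expect_false(f$estimate$converged)
  expect_true(is.na(f$estimate$p))
})

test_that("marginal test recovers a known per-allele log-OR", {
  set.seed(31)
  n <- 20000
  g <- simulate_genotypes(n, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 + 0.2 * g))
  dat <- make_dataset(cbind(a = g), y)
  e <- marginal_test(dat, "a")$estimate
  expect_true(abs(e$beta - 0.2) < 3 * e$se)
})

test_that("marginal and multiplicative tests are allele-flip invariant;
           ARDI is not (carrier asymmetry)", {
  set.seed(21)
  sp <- sim_study_spec(600, 600, covariate_effects = NULL, seed = 3)
  dat <- simulate_case_control(
    sp, penetrance_model("multiplicative", gamma = 0.3, b1 = 0.2, b2 = 0.1))
  flip <- dat
  flip$dosages[, "snp1"] <- 2 - flip$dosages[, "snp1"]
  flip$snps$maf[1] <- compute_maf(flip$dosages[, "snp1"])

  pm <- marginal_test(dat, "snp1")$estimate
  pf <- marginal_test(flip, "snp1")$estimate
  expect_equal(pm$p, pf$p, tolerance = 1e-8)
  expect_equal(pm$beta, -pf$beta, tolerance = 1e-8)

  mm <- gxg_test(dat, "snp1", "snp2", "multiplicative")$estimate
  # flipped coding G1 -> 2 - G1 re-expresses the same model: the
  # interaction column becomes (2 - G1) G2 = 2 G2 - G1 G2, a linear
  # recombination of existing columns, so the Wald p is unchanged
  mf <- gxg_test(flip, "snp1", "snp2", "multiplicative")$estimate
  expect_equal(mm$p, mf$p, tolerance = 1e-6)
  expect_equal(mm$beta, -mf$beta, tolerance = 1e-6)

  aa <- gxg_test(dat, "snp1", "snp2", "ardi")$estimate
  af <- gxg_test(flip, "snp1", "snp2", "ardi")$estimate
  expect_gt(abs(aa$beta - (-af$beta)), 1e-4)  # genuinely different model
})

test_that("Wald and LRT p-values for the ARDI parameter agree at large n", {
  set.seed(8)
  sp <- sim_study_spec(4000, 4000, covariate_effects = NULL, seed = 88)
  dat <- simulate_case_control(
    sp, penetrance_model("ardi_carrier", gamma = 0.08, b1 = 0.2, b2 = 0.1))
  f <- gxg_test(dat, "snp1", "snp2", "ardi")
  g1 <- dat$dosages[, "snp1"]; g2 <- dat$dosages[, "snp2"]
  f0 <- fit_logistic(cbind(1, g1, g2), dat$phenotype)
  lrt <- 2 * (f$fit$loglik - f0$loglik)
  p_lrt <- pchisq(lrt, 1, lower.tail = FALSE)
  expect_lt(abs(f$estimate$p - p_lrt), 0.01)
})

test_that("ARDI holds its size when mains are additive but inflates under
           heterozygote-only mains where the unrestricted-main variant
           stays calibrated", {
  set.seed(14)
  nrep <- 200
  tab <- matrix(0, 3, 3); tab[2, ] <- log(1.6)
  het <- penetrance_model("custom", table = tab)
  p_add <- p_um <- numeric(nrep)
  sp <- sim_study_spec(800, 800, covariate_effects = NULL,
                       n_null_snps = 1, seed = 1)
  for (i in seq_len(nrep)) {
    sp$seed <- 3000 + i
    dat <- simulate_case_control(sp, het)
    p_add[i] <- gxg_test(dat, "snp1", "null_001", "ardi")$estimate$p
    p_um[i] <- gxg_test(dat, "snp1", "null_001", "ardi_umain")$estimate$p
  }
  # rare sparse-cell fits are flagged (not silently estimated) and are
  # excluded, mirroring how the meta-analysis treats them
  expect_gt(mean(!is.na(p_um)), 0.9)
  size_add <- mean(p_add < 0.05, na.rm = TRUE)
  size_um <- mean(p_um < 0.05, na.rm = TRUE)
  expect_gt(size_add, 0.10)     # misspecification inflates additive-main ARDI
  expect_lt(size_um, 0.10)      # 2-df mains absorb the residual effect
})
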