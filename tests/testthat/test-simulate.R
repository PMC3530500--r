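test_that("HWE genotype frequencies and MAF are reproduced", {
  d5 <- simulate_genotypes(1e5, 0.5, seed = 1)
  fr <- tabulate(d5 + 1L, 3L) / 1e5
  expect_equal(fr, c(0.25, 0.5, 0.25), tolerance = 0.01)

  d3 <- simulate_genotypes(1e5, 0.3, seed = 2)
  expect_lt(abs(compute_maf(d3) - 0.3), 0.005)

  expect_identical(simulate_genotypes(100, 0.2, seed = 7),
                   simulate_genotypes(100, 0.2, seed = 7))
})

test_that("simulated genotypes pass a HWE test at the nominal rate", {
  set.seed(123)
  pvals <- replicate(200, {
    g <- simulate_genotypes(600, runif(1, 0.1, 0.5))
    n <- tabulate(g + 1L, 3L)
    q <- (n[2] + 2 * n[3]) / (2 * sum(n))
    e <- sum(n) * c((1 - q)^2, 2 * q * (1 - q), q^2)
    stat <- sum((n - e)^2 / e)
    pchisq(stat, df = 1, lower.tail = FALSE)
  })
  rej <- mean(pvals < 0.05)
  expect_lt(abs(rej - 0.05), 0.055)  # binomial 99.9% envelope at 200 reps
})

test_that("LD pairs hit their target r2 and flag infeasible targets", {
  pair1 <- simulate_ld_pair(2000, 0.3, 0.3, 1.0, seed = 3)
  expect_equal(pair1$d1, pair1$d2)

  pair0 <- simulate_ld_pair(10000, 0.3, 0.25, 0, seed = 4)
  expect_lt(ld_r2(pair0$d1, pair0$d2), 0.01)

  pair8 <- simulate_ld_pair(10000, 0.3, 0.3, 0.8, seed = 5)
  r2 <- ld_r2(pair8$d1, pair8$d2)
  expect_true(r2 > 0.75 && r2 < 0.85)

  expect_error(simulate_ld_pair(100, 0.1, 0.5, 0.9),
               "max achievable r2")
})

test_that("imputation noise reaches its target quality and identity at 1", {
  d <- simulate_genotypes(10000, 0.3, seed = 6)
  id <- add_imputation_noise(d, 1)
  expect_identical(id$dosages, d)
  expect_equal(id$achieved_r2, 1)

  half <- add_imputation_noise(d, 0.5, seed = 7)
  expect_true(half$achieved_r2 > 0.45 && half$achieved_r2 < 0.55)
  expect_true(all(half$dosages >= 0 & half$dosages <= 2))
})

test_that("noisier dosages give larger marginal standard errors", {
  ses <- vapply(c(1, 0.6, 0.3), function(r2) {
    sp <- sim_study_spec(1500, 1500, covariate_effects = NULL,
                         imputation_r2 = c(r2, 1), seed = 11)
    dat <- simulate_case_control(sp, penetrance_model("null", b1 = 0.25))
    marginal_test(dat, "snp1")$estimate$se
  }, numeric(1))
  expect_true(all(diff(ses) > 0))
})

test_that("case-control simulation meets quotas, respects the null preset
           and decouples covariates with zero effects", {
  sp <- sim_study_spec(300, 450, seed = 21,
                       covariate_effects = c(age = 0, sex = 0, pc1 = 0,
                                             pc2 = 0, pc3 = 0))
  dat <- simulate_case_control(sp, penetrance_model("null"))
  expect_equal(sum(dat$phenotype), 300L)
  expect_equal(sum(dat$phenotype == 0), 450L)
  expect_identical(
    dat$dosages,
    simulate_case_control(sp, penetrance_model("null"))$dosages)
  # zero-effect covariates are independent of status
  set.seed(31)
  ps <- replicate(30, {
    sp2 <- sim_study_spec(200, 200, seed = sample.int(1e6, 1),
                          covariate_effects = c(sex = 0))
    d2 <- simulate_case_control(sp2, penetrance_model("null"))
    suppressWarnings(chisq.test(table(d2$covariates$sex,
                                      d2$phenotype))$p.value)
  })
  expect_gt(mean(ps), 0.25)  # roughly uniform
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("penetrance presets build the documented odds-ratio tables", {
  mult <- penetrance_model("multiplicative", gamma = log(1.3),
                           b1 = log(1.1), b2 = log(1.2))
  expect_equal(mult$rr[1, 1], 1)
  expect_equal(mult$rr[3, 3], 1.1^2 * 1.2^2 * 1.3^4, tolerance = 1e-12)

  ac <- penetrance_model("ardi_carrier", gamma = log(0.75))
  expect_equal(unique(as.vector(ac$rr[2:3, 2:3])), 0.75)
  expect_equal(ac$rr[1, ], c(`0` = 1, `1` = 1, `2` = 1))

  thr <- penetrance_model("threshold", gamma = 0.5)
  expect_equal(sum(thr$table > 0), 3L)  # cells with g1+g2 >= 3

  expect_error(penetrance_model("custom",
                                table = matrix(1, 3, 3)), "reference")
})

test_that("consortium: homogeneous studies show no heterogeneity
           enrichment, heterogeneous interaction effects do", {
  set.seed(41)
  hom <- replicate(25, {
    specs <- lapply(1:5, function(i)
      sim_study_spec(400, 400, covariate_effects = NULL))
    studies <- simulate_consortium(
      specs, penetrance_model("ardi_carrier", gamma = 0.2),
      master_seed = sample.int(1e6, 1))
    est <- do.call(rbind, lapply(studies, function(st)
      gxg_test(st, "snp1", "snp2", "ardi")$estimate))
    cochran_q(est)$p_het
  })
  expect_gt(mean(hom), 0.3)           # roughly uniform p_het
  expect_lte(mean(hom < 0.05), 0.2)

  het <- replicate(15, {
    gammas <- c(-0.8, -0.4, 0, 0.4, 0.8)
    est <- do.call(rbind, lapply(seq_along(gammas), function(i) {
      sp <- sim_study_spec(400, 400, covariate_effects = NULL,
                           seed = sample.int(1e6, 1),
                           study_id = paste0("s", i))
      d <- simulate_case_control(
        sp, penetrance_model("ardi_carrier", gamma = gammas[i]))
      gxg_test(d, "snp1", "snp2", "ardi")$estimate
    }))
    cochran_q(est)$p_het
  })
  expect_gt(mean(het < 0.05), 0.4)
})

test_that("single-spec consortium equals simulate_case_control with the
           derived child seed", {
  specs <- list(sim_study_spec(150, 150, seed = 5))
  con <- simulate_consortium(specs, penetrance_model("null"),
                             master_seed = 17)
  set.seed(17)
  child <- sample.int(.Machine$integer.max, 1)
  sp <- specs[[1]]; sp$seed <- child; sp$study_id <- "study01"
  direct <- simulate_case_control(sp, penetrance_model("null"))
  expect_identical(con[[1]]$dosages, direct$dosages)
})
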