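#' Two-locus penetrance model for simulation
#'
#' Defines the disease model as a 3x3 table of odds ratios relative to the
#' double-reference genotype (entry \[0, 0\] is 1 by construction), applied
#' on the logit scale on top of a baseline disease probability. Presets
#' parameterise the describable two-locus interaction families; `gamma` is
#' the interaction log-OR and `b1`, `b2` the main-effect log-ORs:
#'
#' \describe{
#' \item{`null`}{log-additive mains only, no interaction (whatever `gamma`).}
#' \item{`multiplicative`}{`b1*g1 + b2*g2 + gamma*g1*g2`.}
#' \item{`ardi_carrier`}{`b1*g1 + b2*g2 + gamma*I(g1>=1)*I(g2>=1)`: the
#'   carrier-product interaction the ARDI test targets.}
#' \item{`dominant_dominant`}{dominant mains and carrier interaction:
#'   `b1*I(g1>=1) + b2*I(g2>=1) + gamma*I(g1>=1)*I(g2>=1)`.}
#' \item{`recessive_recessive`}{as above with `I(g==2)` codings.}
#' \item{`threshold`}{additive mains plus `gamma*I(g1+g2>=3)`.}
#' \item{`checkerboard`}{additive mains plus `gamma*I((g1+g2) %% 2 == 1)`.}
#' \item{`custom`}{user-supplied 3x3 log-OR `table` (entry \[1,1\] must
#'   be 0); useful e.g. for heterozygote-only main effects when probing
#'   main-effect misspecification.}
#' }
#'
#' @param preset Model family, see Details.
#' @param gamma Interaction log-OR.
#' @param b1,b2 Main-effect log-ORs per count allele (or per carrier for
#'   the dominant/recessive families).
#' @param baseline Disease probability of the reference genotype at
#'   covariate value zero.
#' @param table 3x3 log-OR matrix for `preset = "custom"`.
#' @return Object of class `penetrance_model` with the log-OR `table`,
#'   the OR table `rr`, `baseline` and the preset name.
#' @export
penetrance_model <- function(preset = c("null", "multiplicative",
                                        "ardi_carrier", "dominant_dominant",
                                        "recessive_recessive", "threshold",
                                        "checkerboard", "custom"),
                             gamma = 0, b1 = 0, b2 = 0, baseline = 0.1,
                             table = NULL) {
  preset <- match.arg(preset)
  g <- 0:2
  gr <- matrix(g, 3L, 3L)          # g1 varies over rows
  gc <- matrix(g, 3L, 3L, byrow = TRUE)
  cr <- pmin(gr, 1); cc <- pmin(gc, 1)
  logor <- switch(preset,
    null = b1 * gr + b2 * gc,
    multiplicative = b1 * gr + b2 * gc + gamma * gr * gc,
    ardi_carrier = b1 * gr + b2 * gc + gamma * cr * cc,
    dominant_dominant = b1 * cr + b2 * cc + gamma * cr * cc,
    recessive_recessive = b1 * (gr == 2) + b2 * (gc == 2) +
      gamma * (gr == 2) * (gc == 2),
    threshold = b1 * gr + b2 * gc + gamma * (gr + gc >= 3),
    checkerboard = b1 * gr + b2 * gc + gamma * ((gr + gc) %% 2 == 1),
    custom = {
      stopifnot(!is.null(table), identical(dim(as.matrix(table)), c(3L, 3L)))
      tab <- as.matrix(table)
      if (abs(tab[1L, 1L]) > 1e-12)
        stop("custom table entry [1,1] must be 0 (reference)")
      tab
    })
  dimnames(logor) <- list(g1 = 0:2, g2 = 0:2)
  stopifnot(baseline > 0, baseline < 1)
  structure(list(preset = preset, table = logor, rr = exp(logor),
                 gamma = gamma, b1 = b1, b2 = b2, baseline = baseline),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("penetrance_model '%s' (baseline %.3g)\nodds ratios:\n",
              x$preset, x$baseline))
  print(round(x$rr, 3))
  invisible(x)
}

#' Simulation specification for one study
#'
#' Collects the design of one simulated case-control study. Defaults mirror
#' a mid-size consortium study: MAFs 0.3 and 0.25 for the tested pair, no
#' LD between them, adjustment covariates (standardised age, sex, three
#' principal components) with modest disease effects, no study intercept
#' shift and perfect dosages.
#'
#' @param n_case,n_control Quota of cases and controls.
#' @param maf1,maf2 Minor-allele frequencies of the tested SNP pair.
#' @param ld_r2 LD r-squared between the pair (0 = independent).
#' @param covariate_effects Named numeric vector of log-ORs for the
#'   simulated covariates `age`, `sex`, `pc1`, `pc2`, `pc3`; `NULL` drops
#'   covariates entirely.
#' @param study_effect Additive shift on the logit intercept (study
#'   "center" effect).
#' @param imputation_r2 Length-2 vector: target imputation quality of the
#'   two SNPs (1 = genotyped, no noise).
#' @param n_null_snps Extra null SNPs (independent of disease) appended to
#'   the panel, e.g. to feed scans.
#' @param null_maf_range MAF range the null SNPs are drawn from.
#' @param seed Integer seed for all randomness of this study.
#' @param study_id,phase Labels for the resulting dataset.
#' @return List of class `sim_study_spec`.
#' @export
sim_study_spec <- function(n_case, n_control, maf1 = 0.3, maf2 = 0.25,
                           ld_r2 = 0,
                           covariate_effects = c(age = 0.1, sex = 0.3,
                                                 pc1 = 0.1, pc2 = -0.1,
                                                 pc3 = 0.05),
                           study_effect = 0, imputation_r2 = c(1, 1),
                           n_null_snps = 0L,
                           null_maf_range = c(0.05, 0.5),
                           seed = 1L, study_id = "sim_study",
                           phase = "phase1") {
  stopifnot(n_case > 0, n_control > 0, maf1 > 0, maf1 <= 0.5,
            maf2 > 0, maf2 <= 0.5, ld_r2 >= 0, ld_r2 <= 1)
  structure(list(n_case = as.integer(n_case),
                 n_control = as.integer(n_control), maf1 = maf1,
                 maf2 = maf2, ld_r2 = ld_r2,
                 covariate_effects = covariate_effects,
                 study_effect = study_effect,
                 imputation_r2 = imputation_r2,
                 n_null_snps = as.integer(n_null_snps),
                 null_maf_range = null_maf_range, seed = as.integer(seed),
                 study_id = study_id, phase = phase),
            class = "sim_study_spec")
}

#' Hardy-Weinberg genotype dosages
#'
#' Genotypes drawn with probabilities `((1-q)^2, 2q(1-q), q^2)`, `q = maf`.
#'
#' @param n Number of samples.
#' @param maf Count-allele frequency in (0, 0.5\].
#' @param seed Optional integer seed.
#' @return Integer dosage vector (0/1/2).
#' @export
simulate_genotypes <- function(n, maf, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(maf > 0, maf <= 0.5)
  q <- maf
  sample(0:2, n, replace = TRUE,
         prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
}

#' Pair of SNPs in linkage disequilibrium
#'
#' Draws haplotypes with disequilibrium coefficient D chosen so the
#' population allelic correlation satisfies `r^2 = target_r2` (positive D);
#' each sample's dosage is the allele count over its two haplotypes. The
#' achievable r is capped by `D_max = min(p1(1-p2), (1-p1)p2)`; an
#' infeasible target errors, naming the maximum achievable r-squared.
#'
#' @param n Number of samples.
#' @param maf1,maf2 Count-allele frequencies.
#' @param target_r2 Desired population r-squared in \[0, 1\].
#' @param seed Optional integer seed.
#' @return List with dosage vectors `d1`, `d2`.
#' @export
simulate_ld_pair <- function(n, maf1, maf2, target_r2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p1 <- maf1; p2 <- maf2
  denom <- sqrt(p1 * (1 - p1) * p2 * (1 - p2))
  d_max <- min(p1 * (1 - p2), (1 - p1) * p2)
  r_max2 <- (d_max / denom)^2
  if (target_r2 > r_max2 + 1e-9)
    stop(sprintf("target r2 %.3f infeasible for MAFs %.3g/%.3g; max achievable r2 = %.3f",
                 target_r2, maf1, maf2, r_max2))
  D <- sqrt(target_r2) * denom
  h <- c(p1 * p2 + D,              # count alleles at both loci
         p1 * (1 - p2) - D,
         (1 - p1) * p2 - D,
         (1 - p1) * (1 - p2) + D)
  h <- pmax(h, 0); h <- h / sum(h)
  hap <- matrix(sample.int(4L, 2L * n, replace = TRUE, prob = h), n, 2L)
  d1 <- rowSums(hap <= 2L)
  d2 <- rowSums(hap == 1L | hap == 3L)
  list(d1 = d1, d2 = d2)
}

#' Inject imputation noise into a dosage vector
#'
#' Blends the true dosage with Gaussian noise so that the squared
#' correlation between noisy and true dosage approximates `target_r2`
#' (shrinkage factor `a = target_r2`, noise variance
#' `target_r2 (1 - target_r2) var(d)`), then clamps to \[0, 2\]. Mimics the
#' variance shrinkage of expected dosages from imputation.
#'
#' @param dosages True dosage vector.
#' @param target_r2 Target imputation quality in (0, 1\].
#' @param seed Optional integer seed.
#' @return List with `dosages` (noisy) and `achieved_r2` (empirical squared
#'   correlation with the input).
#' @export
add_imputation_noise <- function(dosages, target_r2, seed = NULL) {
  stopifnot(target_r2 > 0, target_r2 <= 1)
  if (target_r2 == 1)
    return(list(dosages = dosages, achieved_r2 = 1))
  if (!is.null(seed)) set.seed(seed)
  mu <- mean(dosages, na.rm = TRUE)
  sdd <- stats::sd(dosages, na.rm = TRUE)
  e <- stats::rnorm(length(dosages), 0,
                    sqrt(target_r2 * (1 - target_r2)) * sdd)
  noisy <- pmin(pmax(mu + target_r2 * (dosages - mu) + e, 0), 2)
  list(dosages = noisy,
       achieved_r2 = stats::cor(noisy, dosages, use = "complete.obs")^2)
}

#' Simulate one case-control study under a two-locus model
#'
#' Draws population samples (genotypes under HWE with optional LD between
#' the tested pair, covariates, disease status from the logistic model
#' implied by the penetrance table, baseline probability, study intercept
#' shift and covariate effects) and rejection-samples until the case and
#' control quotas are met. Imputation noise is then applied to the tested
#' pair per the spec, and independent null SNPs are appended. The `null`
#' preset yields interaction-free data by construction.
#'
#' @param spec A [sim_study_spec()].
#' @param model A [penetrance_model()].
#' @return A [genotype_dataset()] whose first two SNPs are `snp1`, `snp2`.
#' @export
simulate_case_control <- function(spec, model = penetrance_model("null")) {
  stopifnot(inherits(spec, "sim_study_spec"),
            inherits(model, "penetrance_model"))
  set.seed(spec$seed)
  b0 <- stats::qlogis(model$baseline) + spec$study_effect
  ce <- spec$covariate_effects
  n_need <- spec$n_case + spec$n_control
  # sanity: expected yield of the rarer class must be non-negligible
  prev <- mean(stats::plogis(b0 + as.vector(model$table)))
  if (prev < 1e-4 || prev > 1 - 1e-4)
    stop("baseline probability makes case/control quotas infeasible")

  cases <- list(); controls <- list()
  n_cases <- 0L; n_controls <- 0L
  draws <- 0L
  block <- max(2L * n_need, 1000L)
  while ((n_cases < spec$n_case || n_controls < spec$n_control)) {
    draws <- draws + block
    if (draws > 500L * n_need)
      stop("rejection sampling exceeded its draw budget; check baseline")
    gg <- simulate_ld_pair(block, spec$maf1, spec$maf2, spec$ld_r2)
    eta <- b0 + model$table[cbind(gg$d1 + 1L, gg$d2 + 1L)]
    X <- NULL
    if (!is.null(ce)) {
      X <- cbind(age = stats::rnorm(block), sex = stats::rbinom(block, 1, 0.5),
                 pc1 = stats::rnorm(block), pc2 = stats::rnorm(block),
                 pc3 = stats::rnorm(block))
      X <- X[, names(ce), drop = FALSE]
      eta <- eta + drop(X %*% ce)
    }
    d <- stats::rbinom(block, 1L, stats::plogis(eta))
    for (cls in c(1L, 0L)) {
      idx <- which(d == cls)
      need <- if (cls == 1L) spec$n_case - n_cases else
        spec$n_control - n_controls
      if (need <= 0L || !length(idx)) next
      take <- idx[seq_len(min(need, length(idx)))]
      rec <- list(d1 = gg$d1[take], d2 = gg$d2[take],
                  X = if (!is.null(X)) X[take, , drop = FALSE] else NULL)
      if (cls == 1L) { cases[[length(cases) + 1L]] <- rec
        n_cases <- n_cases + length(take)
      } else { controls[[length(controls) + 1L]] <- rec
        n_controls <- n_controls + length(take) }
    }
  }
  pull <- function(recs, what) do.call(c, lapply(recs, `[[`, what))
  d1 <- c(pull(cases, "d1"), pull(controls, "d1"))
  d2 <- c(pull(cases, "d2"), pull(controls, "d2"))
  X <- if (!is.null(ce))
    rbind(do.call(rbind, lapply(cases, `[[`, "X")),
          do.call(rbind, lapply(controls, `[[`, "X"))) else NULL
  y <- c(rep(1L, spec$n_case), rep(0L, spec$n_control))

  r2 <- rep(1, 2)
  if (spec$imputation_r2[1L] < 1) {
    ni <- add_imputation_noise(d1, spec$imputation_r2[1L])
    d1 <- ni$dosages; r2[1L] <- ni$achieved_r2
  }
  if (spec$imputation_r2[2L] < 1) {
    ni <- add_imputation_noise(d2, spec$imputation_r2[2L])
    d2 <- ni$dosages; r2[2L] <- ni$achieved_r2
  }
  dos <- cbind(snp1 = d1, snp2 = d2)
  snps <- data.frame(snp_id = c("snp1", "snp2"), chrom = c("1", "2"),
                     pos = c(1000L, 2000L), ref_allele = "A",
                     count_allele = "G",
                     genotyped = spec$imputation_r2 >= 1,
                     imputation_r2 = r2, stringsAsFactors = FALSE)
  if (spec$n_null_snps > 0L) {
    mafs <- stats::runif(spec$n_null_snps, spec$null_maf_range[1L],
                         spec$null_maf_range[2L])
    null_dos <- vapply(mafs, function(q) simulate_genotypes(n_need, q),
                       numeric(n_need))
    colnames(null_dos) <- sprintf("null_%03d", seq_len(spec$n_null_snps))
    dos <- cbind(dos, null_dos)
    snps <- rbind(snps,
                  data.frame(snp_id = colnames(null_dos), chrom = "3",
                             pos = 3000L + seq_len(spec$n_null_snps),
                             ref_allele = "A", count_allele = "G",
                             genotyped = TRUE, imputation_r2 = 1,
                             stringsAsFactors = FALSE))
  }
  genotype_dataset(spec$study_id, dos, snps, y,
                   covariates = if (!is.null(X)) as.data.frame(X) else NULL,
                   phase = spec$phase)
}

#' Simulate a multi-study consortium
#'
#' Independent studies sharing one genetic model but differing in design
#' (sample sizes, covariates, intercept shifts, imputation noise) per their
#' specs. Per-study seeds are derived deterministically from `master_seed`,
#' overriding the seeds inside the specs, so one integer reproduces the
#' whole consortium.
#'
#' @param specs List of [sim_study_spec()] objects.
#' @param model Shared [penetrance_model()].
#' @param master_seed Integer master seed.
#' @return List of [genotype_dataset()] objects.
#' @export
simulate_consortium <- function(specs, model = penetrance_model("null"),
                                master_seed = 1L) {
  stopifnot(length(specs) >= 1L)
  set.seed(master_seed)
  child <- sample.int(.Machine$integer.max, length(specs))
  lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    sp$seed <- child[i]
    if (sp$study_id == "sim_study") sp$study_id <- sprintf("study%02d", i)
    simulate_case_control(sp, model)
  })
}
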