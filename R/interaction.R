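#' Carrier score for a SNP
#'
#' Probability that a sample carries at least one count allele, the dominant
#' coding used in the ARDI interaction term. With genotype probabilities the
#' score is `P(G=1) + P(G=2)`; with hard genotypes it is the indicator
#' `I(G >= 1)`; with an expected dosage only it is `min(d, 1)`, which is
#' exact whenever the homozygote probability is negligible and a bounded
#' approximation otherwise.
#'
#' @param dosage Numeric vector of dosages in \[0, 2\].
#' @param probs Optional n-by-3 matrix of genotype probabilities.
#' @return Numeric vector in \[0, 1\].
#' @export
carrier_score <- function(dosage, probs = NULL) {
  if (!is.null(probs)) return(probs[, 2L] + probs[, 3L])
  pmin(dosage, 1)
}

# Hard-call dosages to genotypes 0/1/2 by rounding.
hard_call <- function(dosage) as.integer(round(pmin(pmax(dosage, 0), 2)))

# Covariate matrix (possibly 0-column) for a dataset.
covariate_matrix <- function(data) {
  if (is.null(data$covariates))
    return(matrix(numeric(0L), length(data$phenotype), 0L))
  as.matrix(data$covariates)
}

# One-row data frame summarising a single tested effect.
effect_estimate <- function(study_id, model, snp1, snp2, term, beta, se,
                            df, p, n_case, n_control, converged) {
  z <- if (is.na(beta) || is.na(se) || se <= 0) NA_real_ else beta / se
  if (is.na(p) && !is.na(z)) p <- 2 * stats::pnorm(-abs(z))
  data.frame(study_id = study_id, model = model, snp1 = snp1,
             snp2 = if (is.null(snp2)) NA_character_ else snp2,
             term = term, beta = beta, se = se, z = z, p = p, df = df,
             n_case = n_case, n_control = n_control, converged = converged,
             stringsAsFactors = FALSE)
}

failed_estimate <- function(study_id, model, snp1, snp2, term, df,
                            n_case = NA_integer_, n_control = NA_integer_) {
  effect_estimate(study_id, model, snp1, snp2, term, NA_real_, NA_real_,
                  df, NA_real_, n_case, n_control, FALSE)
}

#' Test a SNP pair for gene-gene interaction in one study
#'
#' Fits a covariate-adjusted logistic regression for disease status on two
#' SNPs and returns a classed fit whose interaction estimate feeds the
#' meta-analysis. Four models are available:
#'
#' \describe{
#' \item{`ardi`}{Average Risk Due to Interaction: log-additive main effects
#'   (dosage coding) plus a single interaction term, the product of the two
#'   carrier scores. The one parameter is the averaged deviation of the four
#'   non-reference genotype cells from the main effects; a 1-df Wald test.}
#' \item{`multiplicative`}{log-additive mains plus the product of the two
#'   additive codings; 1-df Wald. Assumes the double-homozygote interaction
#'   is four times the double-heterozygote one on the log scale.}
#' \item{`unrestricted`}{2-df indicator mains per SNP plus four free cell
#'   interaction parameters, compared against the mains-only model by a
#'   likelihood-ratio test on (up to) 4 df. Requires hard-callable
#'   genotypes; empty cells drop their parameter and reduce the df, which is
#'   flagged in the fit.}
#' \item{`ardi_umain`}{ARDI's single carrier-product interaction on top of
#'   2-df unrestricted mains; guards against main-effect misspecification.}
#' }
#'
#' @param data A [genotype_dataset()].
#' @param snp1,snp2 SNP ids present in `data`.
#' @param model Interaction model, see Details.
#' @param firth Use Firth-penalised fits (helpful with sparse cells).
#' @return Object of class `gxg_fit` with components `estimate` (one-row
#'   data frame: `beta`, `se`, `z`, `p`, `df`, counts, `converged`), `fit`
#'   (the full [fit_logistic()] result), `null_fit` (LRT reference, when
#'   used), `dropped_cells`, and identifiers.
#' @seealso [marginal_test()], [fixed_effect_meta()], [scan_pairs()]
#' @export
gxg_test <- function(data, snp1, snp2,
                     model = c("ardi", "multiplicative", "unrestricted",
                               "ardi_umain"),
                     firth = FALSE) {
  model <- match.arg(model)
  d1 <- snp_dosage(data, snp1)
  d2 <- snp_dosage(data, snp2)
  X <- covariate_matrix(data)
  y <- data$phenotype
  cc <- stats::complete.cases(d1, d2, if (ncol(X)) X else NULL)
  d1 <- d1[cc]; d2 <- d2[cc]; y <- y[cc]
  X <- X[cc, , drop = FALSE]
  n_case <- sum(y == 1L); n_control <- sum(y == 0L)
  p1 <- snp_probs(data, snp1); p2 <- snp_probs(data, snp2)
  if (!is.null(p1)) p1 <- p1[cc, , drop = FALSE]
  if (!is.null(p2)) p2 <- p2[cc, , drop = FALSE]

  out <- list(model = model, snp1 = snp1, snp2 = snp2,
              study_id = data$study_id, n_case = n_case,
              n_control = n_control, dropped_cells = character(0L),
              null_fit = NULL)

  if (model %in% c("ardi", "multiplicative")) {
    int <- if (model == "ardi")
      carrier_score(d1, p1) * carrier_score(d2, p2) else d1 * d2
    des <- cbind("(Intercept)" = 1, g1 = d1, g2 = d2, X, interaction = int)
    fit <- fit_logistic(des, y, firth = firth)
    out$fit <- fit
    out$estimate <- wald_row(fit, "interaction", data$study_id, model,
                             snp1, snp2, n_case, n_control)
  } else {
    g1 <- hard_call(d1); g2 <- hard_call(d2)
    mains <- cbind(g1_het = as.numeric(g1 == 1L),
                   g1_hom = as.numeric(g1 == 2L),
                   g2_het = as.numeric(g2 == 1L),
                   g2_hom = as.numeric(g2 == 2L))
    mains <- mains[, colSums(mains) > 0, drop = FALSE]
    if (model == "ardi_umain") {
      int <- carrier_score(d1, p1) * carrier_score(d2, p2)
      des <- cbind("(Intercept)" = 1, mains, X, interaction = int)
      fit <- fit_logistic(des, y, firth = firth)
      out$fit <- fit
      out$estimate <- wald_row(fit, "interaction", data$study_id, model,
                               snp1, snp2, n_case, n_control)
    } else {
      ints <- sapply(c("1_1", "1_2", "2_1", "2_2"), function(jk) {
        jk <- as.integer(strsplit(jk, "_")[[1L]])
        as.numeric(g1 == jk[1L] & g2 == jk[2L])
      })
      colnames(ints) <- paste0("gamma_", c("11", "12", "21", "22"))
      keep <- colSums(ints) > 0
      out$dropped_cells <- colnames(ints)[!keep]
      ints <- ints[, keep, drop = FALSE]
      des0 <- cbind("(Intercept)" = 1, mains, X)
      des1 <- cbind(des0, ints)
      fit0 <- fit_logistic(des0, y, firth = firth)
      fit1 <- fit_logistic(des1, y, firth = firth)
      out$fit <- fit1
      out$null_fit <- fit0
      df <- ncol(ints)
      conv <- fit0$converged && fit1$converged
      p <- if (conv) {
        lrt <- 2 * (fit1$loglik - fit0$loglik)
        stats::pchisq(max(lrt, 0), df = df, lower.tail = FALSE)
      } else NA_real_
      out$estimate <- effect_estimate(data$study_id, model, snp1, snp2,
                                      "interaction_lrt", NA_real_, NA_real_,
                                      df, p, n_case, n_control, conv)
    }
  }
  class(out) <- "gxg_fit"
  out
}

# Wald 1-df effect row for a named coefficient of a logistic_fit.
wald_row <- function(fit, term, study_id, model, snp1, snp2,
                     n_case, n_control) {
  if (!fit$converged)
    return(failed_estimate(study_id, model, snp1, snp2, term, 1L,
                           n_case, n_control))
  j <- match(term, names(fit$coefficients))
  beta <- fit$coefficients[[j]]
  se <- sqrt(fit$vcov[j, j])
  effect_estimate(study_id, model, snp1, snp2, term, beta, se, 1L,
                  NA_real_, n_case, n_control, TRUE)
}

#' Marginal (single-SNP) association test
#'
#' Covariate-adjusted logistic regression of case status on one SNP with
#' additive genetic coding; 1-df Wald test. The same additive coding as the
#' ARDI main effects, which is what makes marginal screening independent of
#' the ARDI interaction test.
#'
#' @inheritParams gxg_test
#' @param snp SNP id.
#' @return A `gxg_fit` whose estimate row has `model = "marginal"`.
#' @export
marginal_test <- function(data, snp, firth = FALSE) {
  d <- snp_dosage(data, snp)
  X <- covariate_matrix(data)
  y <- data$phenotype
  cc <- stats::complete.cases(d, if (ncol(X)) X else NULL)
  d <- d[cc]; y <- y[cc]; X <- X[cc, , drop = FALSE]
  des <- cbind("(Intercept)" = 1, g = d, X)
  fit <- fit_logistic(des, y, firth = firth)
  out <- list(model = "marginal", snp1 = snp, snp2 = NULL,
              study_id = data$study_id, n_case = sum(y == 1L),
              n_control = sum(y == 0L), fit = fit, null_fit = NULL,
              dropped_cells = character(0L),
              estimate = wald_row(fit, "g", data$study_id, "marginal",
                                  snp, NULL, sum(y == 1L), sum(y == 0L)))
  class(out) <- "gxg_fit"
  out
}

#' @export
print.gxg_fit <- function(x, ...) {
  e <- x$estimate
  cat(sprintf("%s test, study %s: %s%s\n", x$model, x$study_id, x$snp1,
              if (!is.null(x$snp2)) paste0(" x ", x$snp2) else ""))
  if (!e$converged) {
    cat("  fit did not converge:", x$fit$diagnostic, "\n")
    return(invisible(x))
  }
  if (is.na(e$beta)) {
    cat(sprintf("  LRT chi-square on %d df, p = %.3g", e$df, e$p))
    if (length(x$dropped_cells))
      cat("  [empty cells dropped:",
          paste(x$dropped_cells, collapse = ", "), "]")
    cat("\n")
  } else {
    ci <- exp(e$beta + c(-1, 1) * stats::qnorm(0.975) * e$se)
    cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
                exp(e$beta), ci[1L], ci[2L], e$p))
  }
  cat(sprintf("  %d cases / %d controls\n", e$n_case, e$n_control))
  invisible(x)
}

#' @export
summary.gxg_fit <- function(object, ...) {
  co <- coef(object$fit)
  se <- sqrt(diag(object$fit$vcov))
  z <- co / se
  tab <- cbind(Estimate = co, `Std. Error` = se, `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(fit = object, coefficients = tab),
            class = "summary.gxg_fit")
}

#' @export
print.summary.gxg_fit <- function(x, ...) {
  print(x$fit)
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  invisible(x)
}

#' @export
coef.gxg_fit <- function(object, ...) coef(object$fit)

#' @export
vcov.gxg_fit <- function(object, ...) vcov(object$fit)

#' @export
confint.gxg_fit <- function(object, parm = "interaction", level = 0.95, ...) {
  e <- object$estimate
  zq <- stats::qnorm(1 - (1 - level) / 2)
  m <- matrix(c(e$beta - zq * e$se, e$beta + zq * e$se), 1L,
              dimnames = list(e$term, paste0(c((1 - level) / 2,
                                               1 - (1 - level) / 2) * 100,
                                             " %")))
  m
}

#' Extract the effect-estimate rows of one or more fits
#'
#' @param ... `gxg_fit` objects or lists of them.
#' @return Data frame, one row per fit, suitable for [fixed_effect_meta()].
#' @export
effect_estimates <- function(...) {
  fits <- list(...)
  if (length(fits) == 1L && !inherits(fits[[1L]], "gxg_fit"))
    fits <- fits[[1L]]
  do.call(rbind, lapply(fits, function(f) f$estimate))
}
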