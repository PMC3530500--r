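#' Inverse-variance fixed-effect meta-analysis
#'
#' Combines per-study log-OR estimates with weights `w_i = 1/se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1/sqrt(sum(w))`, two-sided normal p.
#' Estimates flagged as non-converged, with missing/non-positive SE, or with
#' SE above `se_max` (separation artifacts) are dropped with a message.
#' Because inverse-variance weights already shrink with imputation dosage
#' uncertainty, no extra imputation-quality weighting is applied.
#'
#' @param estimates Data frame with columns `beta`, `se` and optionally
#'   `converged`, `study_id` (as produced by [effect_estimates()]).
#' @param method `"fixed"` or `"random"` (DerSimonian-Laird).
#' @param se_max Largest admissible per-study SE on the log-OR scale.
#' @return Object of class `meta_result`: `beta`, `se`, `or`, `ci95`, `p`,
#'   `q`, `p_het`, `tau2`, `k`, `method`, `n_dropped`.
#' @export
fixed_effect_meta <- function(estimates, method = "fixed", se_max = 10) {
  est <- usable_estimates(estimates, se_max)
  k <- nrow(est)
  if (k == 0L) stop("no usable estimates to meta-analyze")
  w <- 1 / est$se^2
  beta <- sum(w * est$beta) / sum(w)
  se <- 1 / sqrt(sum(w))
  qh <- cochran_q(est)
  tau2 <- 0
  if (method == "random" && k >= 2L) {
    tau2 <- max(0, (qh$q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
    ws <- 1 / (est$se^2 + tau2)
    beta <- sum(ws * est$beta) / sum(ws)
    se <- 1 / sqrt(sum(ws))
  }
  meta_result(beta, se, qh$q, qh$p_het, tau2, k, method,
              n_dropped = attr(est, "n_dropped"))
}

#' @rdname fixed_effect_meta
#' @export
random_effect_meta <- function(estimates, se_max = 10) {
  est <- usable_estimates(estimates, se_max)
  if (nrow(est) < 2L) stop("random-effects meta needs at least 2 studies")
  fixed_effect_meta(estimates, method = "random", se_max = se_max)
}

usable_estimates <- function(estimates, se_max = 10) {
  est <- as.data.frame(estimates)
  if (nrow(est) == 0L) stop("empty estimate table")
  ok <- is.finite(est$beta) & is.finite(est$se) & est$se > 0 &
    est$se <= se_max
  if (!is.null(est$converged)) ok <- ok & est$converged
  if (any(!ok))
    message("meta-analysis: dropping ", sum(!ok),
            " non-converged/unstable estimate(s)")
  out <- est[ok, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

meta_result <- function(beta, se, q, p_het, tau2, k, method, n_dropped = 0L) {
  z <- beta / se
  structure(list(beta = beta, se = se, or = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
                 p = 2 * stats::pnorm(-abs(z)), q = q, p_het = p_het,
                 tau2 = tau2, k = k, method = method,
                 n_dropped = n_dropped),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effect meta-analysis of %d studies\n", x$method, x$k))
  cat(sprintf("  OR = %.3f (95%% CI %.3f-%.3f), p = %.3g\n",
              x$or, x$ci95[1L], x$ci95[2L], x$p))
  if (!is.na(x$p_het))
    cat(sprintf("  Cochran Q = %.3f, P_het = %.3g, tau^2 = %.4g\n",
                x$q, x$p_het, x$tau2))
  invisible(x)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_i (b_i - b_fixed)^2` with fixed-effect weights; the
#' heterogeneity p-value comes from chi-square on `k - 1` df. With a single
#' study Q is 0 and `p_het` is `NA` (undefined).
#'
#' @inheritParams fixed_effect_meta
#' @return List with `q` and `p_het`.
#' @export
cochran_q <- function(estimates, se_max = 10) {
  est <- usable_estimates(estimates, se_max)
  k <- nrow(est)
  w <- 1 / est$se^2
  bf <- sum(w * est$beta) / sum(w)
  q <- sum(w * (est$beta - bf)^2)
  p_het <- if (k >= 2L)
    stats::pchisq(q, df = k - 1L, lower.tail = FALSE) else NA_real_
  list(q = q, p_het = p_het)
}

#' Phase-wise and combined meta-analysis
#'
#' Splits per-study estimate rows by their `phase` tag, meta-analyzes
#' discovery (`phase1`) and replication (`phase2`) separately and combined.
#' Advanced-adenoma studies are carried in forest data but enter the
#' combined meta-analysis only when `include_adenoma = TRUE`.
#'
#' @param estimates Data frame of per-study estimates with a `phase` column
#'   (`"phase1"`, `"phase2"`, `"adenoma"`).
#' @param include_adenoma Include adenoma studies in the combined result.
#' @param method Meta-analysis flavour for all three results.
#' @return List with `phase1`, `phase2`, `combined` ([fixed_effect_meta()]
#'   results or `NULL` when a phase has no studies).
#' @export
phase_meta <- function(estimates, include_adenoma = FALSE,
                       method = "fixed") {
  est <- as.data.frame(estimates)
  if (is.null(est$phase)) stop("estimates need a phase column")
  one <- function(rows) {
    if (nrow(rows) == 0L) return(NULL)
    tryCatch(fixed_effect_meta(rows, method = method),
             error = function(e) NULL)
  }
  comb <- est[est$phase %in% c("phase1", "phase2",
                               if (include_adenoma) "adenoma"), ,
              drop = FALSE]
  list(phase1 = one(est[est$phase == "phase1", , drop = FALSE]),
       phase2 = one(est[est$phase == "phase2", , drop = FALSE]),
       combined = one(comb))
}

#' Forest-plot data for a set of per-study estimates
#'
#' @param estimates Data frame of per-study estimates (`study_id`, `beta`,
#'   `se`, optionally `phase`).
#' @return Data frame with per-study OR, 95% CI, inverse-variance weight
#'   percentage and phase; ready for TSV export or plotting.
#' @export
forest_data <- function(estimates) {
  est <- usable_estimates(estimates)
  w <- 1 / est$se^2
  data.frame(study_id = if (!is.null(est$study_id)) est$study_id else
               paste0("study", seq_len(nrow(est))),
             or = exp(est$beta),
             ci_low = exp(est$beta - stats::qnorm(0.975) * est$se),
             ci_high = exp(est$beta + stats::qnorm(0.975) * est$se),
             weight_pct = 100 * w / sum(w),
             phase = if (!is.null(est$phase)) est$phase else NA_character_,
             stringsAsFactors = FALSE)
}
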