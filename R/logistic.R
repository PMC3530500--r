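#' Maximum-likelihood logistic regression on a design matrix
#'
#' Thin engine under all interaction tests. Fits by iteratively reweighted
#' least squares (log-likelihood tolerance 1e-8, at most 100 iterations) and
#' reports convergence honestly: rank deficiency or a separation-like
#' solution yields `converged = FALSE` with a diagnostic message rather than
#' silent numbers. An optional Firth penalty (Jeffreys-prior score
#' correction) is available for sparse cells; it is off by default.
#'
#' @param design Numeric model matrix including the intercept column.
#' @param outcome Binary 0/1 response vector.
#' @param firth Use Firth's bias-reducing penalised likelihood.
#' @param maxit,tol IRLS iteration cap and log-likelihood change tolerance.
#' @return An object of class `logistic_fit`: list with `coefficients`,
#'   `vcov`, `loglik`, `iterations`, `converged`, `diagnostic`, `n`,
#'   `fitted`, `rank`.
#' @export
fit_logistic <- function(design, outcome, firth = FALSE,
                         maxit = 100L, tol = 1e-8) {
  design <- as.matrix(design)
  storage.mode(design) <- "double"
  y <- as.numeric(outcome)
  stopifnot(nrow(design) == length(y), all(y %in% c(0, 1)))
  p <- ncol(design)
  if (is.null(colnames(design)))
    colnames(design) <- paste0("x", seq_len(p))
  bad <- function(diag) {
    structure(list(coefficients = stats::setNames(rep(NA_real_, p),
                                                  colnames(design)),
                   vcov = matrix(NA_real_, p, p), loglik = NA_real_,
                   iterations = 0L, converged = FALSE, diagnostic = diag,
                   n = length(y), fitted = rep(NA_real_, length(y)),
                   rank = NA_integer_),
              class = "logistic_fit")
  }
  if (nrow(design) < p + 1L) return(bad("fewer observations than parameters"))
  qrx <- qr(design)
  if (qrx$rank < p) return(bad("rank-deficient design"))
  if (all(y == 0) || all(y == 1)) return(bad("outcome is constant"))

  if (firth) {
    fit <- firth_logistic(design, y, maxit = maxit, tol = tol)
  } else {
    g <- suppressWarnings(
      stats::glm.fit(design, y, family = stats::binomial(),
                     control = stats::glm.control(epsilon = tol,
                                                  maxit = maxit)))
    mu <- g$fitted.values
    w <- mu * (1 - mu)
    info <- crossprod(design * sqrt(w))
    vcov <- tryCatch(solve(info), error = function(e) NULL)
    ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
    fit <- list(coefficients = stats::setNames(g$coefficients,
                                               colnames(design)),
                vcov = vcov, loglik = ll, iterations = g$iter,
                converged = g$converged, fitted = mu)
  }
  diag_msg <- ""
  conv <- isTRUE(fit$converged)
  if (is.null(fit$vcov) || anyNA(fit$vcov)) {
    conv <- FALSE; diag_msg <- "singular information matrix"
  } else {
    se <- sqrt(pmax(diag(fit$vcov), 0))
    if (!firth && (max(abs(fit$coefficients)) > 15 || any(se > 50))) {
      conv <- FALSE
      diag_msg <- "quasi-complete separation suspected"
    } else if (!conv) diag_msg <- "IRLS did not converge"
  }
  structure(list(coefficients = fit$coefficients,
                 vcov = if (is.null(fit$vcov))
                   matrix(NA_real_, p, p) else fit$vcov,
                 loglik = fit$loglik, iterations = fit$iterations,
                 converged = conv, diagnostic = diag_msg, n = length(y),
                 fitted = fit$fitted, rank = qrx$rank),
            class = "logistic_fit")
}

# Firth-penalised logistic regression: Newton iterations on the modified
# score U*(b) = X'(y - mu + h (1/2 - mu)), h = hat diagonals.
firth_logistic <- function(X, y, maxit = 100L, tol = 1e-8) {
  p <- ncol(X)
  b <- rep(0, p)
  pll_old <- -Inf
  conv <- FALSE
  it <- 0L
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    cinfo <- tryCatch(chol(info), error = function(e) NULL)
    if (is.null(cinfo)) break
    # hat diagonals of W^1/2 X (X'WX)^-1 X' W^1/2
    h <- rowSums((XW %*% chol2inv(cinfo)) * XW)
    U <- crossprod(X, y - mu + h * (0.5 - mu))
    step <- chol2inv(cinfo) %*% U
    b_new <- b + drop(step)
    eta_n <- drop(X %*% b_new)
    mu_n <- stats::plogis(eta_n)
    ll <- sum(y * log(pmax(mu_n, 1e-300)) +
                (1 - y) * log(pmax(1 - mu_n, 1e-300)))
    wd <- mu_n * (1 - mu_n)
    pll <- ll + 0.5 * determinant(crossprod(X * sqrt(wd)),
                                  logarithm = TRUE)$modulus
    # step-halving if the penalised likelihood decreases
    halv <- 0L
    while (pll < pll_old && halv < 10L) {
      step <- step / 2
      b_new <- b + drop(step)
      mu_n <- stats::plogis(drop(X %*% b_new))
      wd <- mu_n * (1 - mu_n)
      ll <- sum(y * log(pmax(mu_n, 1e-300)) +
                  (1 - y) * log(pmax(1 - mu_n, 1e-300)))
      pll <- ll + 0.5 * determinant(crossprod(X * sqrt(wd)),
                                    logarithm = TRUE)$modulus
      halv <- halv + 1L
    }
    b <- b_new
    if (abs(pll - pll_old) < tol) { conv <- TRUE; pll_old <- pll; break }
    pll_old <- pll
  }
  mu <- stats::plogis(drop(X %*% b))
  info <- crossprod(X * sqrt(mu * (1 - mu)))
  vcov <- tryCatch(solve(info), error = function(e) NULL)
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  list(coefficients = stats::setNames(b, colnames(X)), vcov = vcov,
       loglik = ll, iterations = it, converged = conv, fitted = mu)
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("logistic_fit:", x$n, "obs,",
      length(x$coefficients), "coefficients;",
      if (x$converged) "converged" else paste("NOT converged:", x$diagnostic),
      "\n")
  if (x$converged) {
    se <- sqrt(diag(x$vcov))
    print(round(cbind(beta = x$coefficients, se = se), 4))
  }
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
vcov.logistic_fit <- function(object, ...) object$vcov

#' @export
logLik.logistic_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            class = "logLik")
}
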