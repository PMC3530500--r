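#' Two-locus joint odds-ratio table
#'
#' Builds the 3x3 genotype-combination table for a SNP pair: per-cell odds
#' ratio, 95% CI and p-value relative to the double-reference cell (0, 0),
#' plus case/control counts. With `adjusted = FALSE` the ORs are crude
#' cross-product ratios with Woolf (log-scale) confidence intervals; with
#' `adjusted = TRUE` they come from an unrestricted logistic fit with the
#' dataset's covariates (cell log-OR = main1 + main2 + cell interaction).
#' Dosages are hard-called by rounding since the table needs discrete
#' genotype cells.
#'
#' @param data A [genotype_dataset()].
#' @param snp1,snp2 SNP ids.
#' @param adjusted Use the covariate-adjusted unrestricted fit.
#' @return Object of class `joint_or_table`: 3x3 matrices `or`, `ci_low`,
#'   `ci_high`, `p`, `n_case`, `n_control` (rows = snp1 genotype 0/1/2,
#'   columns = snp2 genotype), plus ids.
#' @export
joint_or_table <- function(data, snp1, snp2, adjusted = FALSE) {
  g1 <- hard_call(snp_dosage(data, snp1))
  g2 <- hard_call(snp_dosage(data, snp2))
  y <- data$phenotype
  X <- covariate_matrix(data)
  cc <- stats::complete.cases(g1, g2, if (ncol(X)) X else NULL)
  g1 <- g1[cc]; g2 <- g2[cc]; y <- y[cc]; X <- X[cc, , drop = FALSE]
  n_case <- table(factor(g1[y == 1L], 0:2), factor(g2[y == 1L], 0:2))
  n_control <- table(factor(g1[y == 0L], 0:2), factor(g2[y == 0L], 0:2))
  tab <- joint_or_from_counts(unclass(n_case), unclass(n_control))
  tab$snp1 <- snp1; tab$snp2 <- snp2; tab$adjusted <- adjusted
  if (adjusted) {
    cells <- expand.grid(j = 0:2, k = 0:2)
    cols <- lapply(seq_len(nrow(cells)), function(i)
      as.numeric(g1 == cells$j[i] & g2 == cells$k[i]))
    des <- do.call(cbind, cols[-1L])  # baseline (0,0) absorbed by intercept
    colnames(des) <- sprintf("c%d%d", cells$j[-1L], cells$k[-1L])
    keep <- colSums(des) > 0
    des <- des[, keep, drop = FALSE]
    fit <- fit_logistic(cbind("(Intercept)" = 1, des, X), y)
    if (!fit$converged)
      warning("adjusted cell fit did not converge: ", fit$diagnostic)
    for (i in which(c(FALSE, keep))) {
      nm <- sprintf("c%d%d", cells$j[i], cells$k[i])
      b <- fit$coefficients[[nm]]
      se <- sqrt(fit$vcov[nm, nm])
      r <- cells$j[i] + 1L; cl <- cells$k[i] + 1L
      tab$or[r, cl] <- exp(b)
      tab$ci_low[r, cl] <- exp(b - stats::qnorm(0.975) * se)
      tab$ci_high[r, cl] <- exp(b + stats::qnorm(0.975) * se)
      tab$p[r, cl] <- 2 * stats::pnorm(-abs(b / se))
    }
  }
  tab
}

#' Joint OR table directly from genotype-combination counts
#'
#' Computes the crude 3x3 table from printed or tabulated case/control
#' counts (rows = genotype of SNP 1, columns = genotype of SNP 2, reference
#' in position \[1, 1\]). Cells with a zero margin get a missing OR but keep
#' their counts.
#'
#' @param n_case,n_control 3x3 integer matrices of counts.
#' @return A `joint_or_table`.
#' @export
joint_or_from_counts <- function(n_case, n_control) {
  n_case <- as.matrix(n_case); n_control <- as.matrix(n_control)
  stopifnot(identical(dim(n_case), dim(n_control)))
  dn <- list(g1 = as.character(seq_len(nrow(n_case)) - 1L),
             g2 = as.character(seq_len(ncol(n_case)) - 1L))
  dimnames(n_case) <- dimnames(n_control) <- dn
  a <- n_case[1L, 1L]; b <- n_control[1L, 1L]
  or <- ci_low <- ci_high <- p <- matrix(NA_real_, nrow(n_case),
                                         ncol(n_case), dimnames = dn)
  for (r in seq_len(nrow(n_case))) for (cl in seq_len(ncol(n_case))) {
    cs <- n_case[r, cl]; ct <- n_control[r, cl]
    if (r == 1L && cl == 1L) {
      or[r, cl] <- 1
      next
    }
    if (cs == 0L || ct == 0L || a == 0L || b == 0L) next
    o <- (cs * b) / (ct * a)
    se <- sqrt(1 / cs + 1 / ct + 1 / a + 1 / b)  # Woolf log-scale SE
    or[r, cl] <- o
    ci_low[r, cl] <- exp(log(o) - stats::qnorm(0.975) * se)
    ci_high[r, cl] <- exp(log(o) + stats::qnorm(0.975) * se)
    p[r, cl] <- 2 * stats::pnorm(-abs(log(o) / se))
  }
  structure(list(or = or, ci_low = ci_low, ci_high = ci_high, p = p,
                 n_case = unclass(n_case), n_control = unclass(n_control),
                 snp1 = NA_character_, snp2 = NA_character_,
                 adjusted = FALSE),
            class = "joint_or_table")
}

#' @export
print.joint_or_table <- function(x, digits = 2, ...) {
  cat(sprintf("joint OR table%s%s\n",
              if (!is.na(x$snp1)) paste0(": ", x$snp1, " x ", x$snp2) else "",
              if (x$adjusted) " (covariate-adjusted)" else " (crude)"))
  fmt <- matrix("", nrow(x$or), ncol(x$or), dimnames = dimnames(x$or))
  for (r in seq_len(nrow(x$or))) for (cl in seq_len(ncol(x$or))) {
    fmt[r, cl] <- if (is.na(x$or[r, cl]))
      sprintf("NA [%d/%d]", x$n_case[r, cl], x$n_control[r, cl])
    else if (r == 1L && cl == 1L)
      sprintf("1 [%d/%d]", x$n_case[r, cl], x$n_control[r, cl])
    else
      sprintf("%.*f (%.*f-%.*f) [%d/%d]", digits, x$or[r, cl], digits,
              x$ci_low[r, cl], digits, x$ci_high[r, cl],
              x$n_case[r, cl], x$n_control[r, cl])
  }
  print(fmt, quote = FALSE)
  invisible(x)
}

#' Stratified odds ratios from a joint table
#'
#' Within each stratum (row or column) of one SNP, recomputes the other
#' SNP's genotype ORs relative to that stratum's own reference cell. For
#' crude tables the algebraic identity
#' `joint(g1, g2) = row_main(g1) * stratified(g2 | g1)` holds exactly.
#'
#' @param table A [joint_or_table()] with counts.
#' @param stratify_by `"snp1"` (strata = rows; ORs of snp2 within each row)
#'   or `"snp2"`.
#' @return A `joint_or_table` whose reference column (or row) is all 1.
#' @export
stratified_or <- function(table, stratify_by = c("snp1", "snp2")) {
  stratify_by <- match.arg(stratify_by)
  ncs <- table$n_case; ncn <- table$n_control
  if (stratify_by == "snp2") { ncs <- t(ncs); ncn <- t(ncn) }
  dn <- dimnames(ncs)
  or <- ci_low <- ci_high <- p <- matrix(NA_real_, nrow(ncs), ncol(ncs),
                                         dimnames = dn)
  for (r in seq_len(nrow(ncs))) {
    a <- ncs[r, 1L]; b <- ncn[r, 1L]
    or[r, 1L] <- 1
    for (cl in 2:ncol(ncs)) {
      cs <- ncs[r, cl]; ct <- ncn[r, cl]
      if (cs == 0L || ct == 0L || a == 0L || b == 0L) next
      o <- (cs * b) / (ct * a)
      se <- sqrt(1 / cs + 1 / ct + 1 / a + 1 / b)
      or[r, cl] <- o
      ci_low[r, cl] <- exp(log(o) - stats::qnorm(0.975) * se)
      ci_high[r, cl] <- exp(log(o) + stats::qnorm(0.975) * se)
      p[r, cl] <- 2 * stats::pnorm(-abs(log(o) / se))
    }
  }
  back <- function(m) if (stratify_by == "snp2") t(m) else m
  structure(list(or = back(or), ci_low = back(ci_low),
                 ci_high = back(ci_high), p = back(p),
                 n_case = table$n_case, n_control = table$n_control,
                 snp1 = table$snp1, snp2 = table$snp2, adjusted = FALSE),
            class = "joint_or_table")
}

#' Collapse a 3x3 table to carrier-by-carrier 2x2
#'
#' Merges heterozygote and minor-homozygote genotypes of each SNP
#' (dominant coding) and recomputes crude ORs from the merged counts.
#'
#' @param table A [joint_or_table()] with counts.
#' @return A 2x2 `joint_or_table` (rows/columns `0` = non-carrier,
#'   `1` = carrier).
#' @export
collapse_carriers <- function(table) {
  merge2 <- function(m) {
    out <- matrix(0L, 2L, 2L, dimnames = list(g1 = c("0", "1"),
                                              g2 = c("0", "1")))
    out[1L, 1L] <- m[1L, 1L]
    out[1L, 2L] <- sum(m[1L, 2:3])
    out[2L, 1L] <- sum(m[2:3, 1L])
    out[2L, 2L] <- sum(m[2:3, 2:3])
    out
  }
  tab <- joint_or_from_counts(merge2(table$n_case),
                              merge2(table$n_control))
  tab$snp1 <- table$snp1; tab$snp2 <- table$snp2
  tab
}

#' Cell-level interaction odds ratio
#'
#' Departure of a joint genotype-combination OR from its no-interaction
#' expectation: `joint / (row_main * col_main)`, where the mains are the
#' corresponding single-SNP ORs against the common reference.
#'
#' @param joint_or Joint OR of the cell.
#' @param row_main_or,col_main_or Marginal ORs of the two genotypes.
#' @return The interaction OR (scalar, vectorised over inputs).
#' @export
cell_interaction_or <- function(joint_or, row_main_or, col_main_or) {
  if (any(c(joint_or, row_main_or, col_main_or) <= 0, na.rm = TRUE))
    stop("odds ratios must be positive")
  joint_or / (row_main_or * col_main_or)
}

#' No-interaction expected joint odds ratio
#'
#' Product of the two marginal ORs: the joint OR a genotype combination
#' would have if the two SNPs acted multiplicatively with no interaction.
#'
#' @inheritParams cell_interaction_or
#' @return `row_main_or * col_main_or`.
#' @export
expected_joint_or <- function(row_main_or, col_main_or) {
  if (any(c(row_main_or, col_main_or) <= 0, na.rm = TRUE))
    stop("odds ratios must be positive")
  row_main_or * col_main_or
}

#' Export a joint OR table as TSV
#'
#' Long format: one row per genotype cell with OR, CI, p and counts.
#'
#' @param table A [joint_or_table()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_or_table_tsv <- function(table, path) {
  cells <- expand.grid(g1 = rownames(table$or), g2 = colnames(table$or),
                       stringsAsFactors = FALSE)
  df <- data.frame(cells,
                   or = as.vector(table$or),
                   ci_low = as.vector(table$ci_low),
                   ci_high = as.vector(table$ci_high),
                   p = as.vector(table$p),
                   n_case = as.vector(table$n_case),
                   n_control = as.vector(table$n_control))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
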