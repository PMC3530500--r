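#' Screening configuration
#'
#' Thresholds driving the two published search strategies. Defaults: SNPs
#' must have MAF > 0.05 and mean imputation R-squared > 0.3; marginal
#' screening keeps SNPs with both fixed- and random-effects meta p < 1e-4;
#' LD pruning removes SNPs with r-squared > 0.8 to a stronger signal;
#' known-locus interactions advance to replication at p < 1e-6 and
#' all-pairs interactions at p < 5e-5; the family-wise level is 0.05.
#'
#' @param maf_min,r2_min,marginal_p_max,ld_r2_max,known_locus_select_p,pairs_select_p,alpha
#'   Numeric thresholds in (0, 1).
#' @param het_p_min Optional heterogeneity filter: keep only SNPs/pairs with
#'   `p_het` above this value (`NULL`, the default, disables it —
#'   heterogeneity is reported, not filtered).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(maf_min = 0.05, r2_min = 0.3,
                          marginal_p_max = 1e-4, ld_r2_max = 0.8,
                          known_locus_select_p = 1e-6,
                          pairs_select_p = 5e-5, alpha = 0.05,
                          het_p_min = NULL) {
  cfg <- list(maf_min = maf_min, r2_min = r2_min,
              marginal_p_max = marginal_p_max, ld_r2_max = ld_r2_max,
              known_locus_select_p = known_locus_select_p,
              pairs_select_p = pairs_select_p, alpha = alpha,
              het_p_min = het_p_min)
  num <- cfg[setdiff(names(cfg), "het_p_min")]
  stopifnot(all(unlist(num) > 0), all(unlist(num) < 1))
  class(cfg) <- "screen_config"
  cfg
}

#' Panel of known susceptibility loci
#'
#' The 14 previously confirmed colorectal-cancer risk loci against which the
#' genome-wide known-locus interaction scan runs.
#'
#' @return Data frame with `snp_id` and `region` columns (14 unique rows).
#' @export
known_locus_panel <- function() {
  data.frame(
    snp_id = c("rs6687758", "rs10936599", "rs16892766", "rs6983267",
               "rs10795668", "rs3802842", "rs7136702", "rs4444235",
               "rs4779584", "rs9929218", "rs4939827", "rs10411210",
               "rs961253", "rs4925386"),
    region = c("1q41", "3q16.2", "8q23.3", "8q24", "10p14", "11q23",
               "12q13.13", "14q22.2", "15q13", "16q22.1", "18q21",
               "19q13", "20p12.3", "20q13.33"),
    stringsAsFactors = FALSE)
}

#' Select marginal-screen candidate SNPs
#'
#' Keeps a SNP iff MAF exceeds `maf_min`, mean imputation R-squared across
#' studies exceeds `r2_min`, and BOTH the fixed- and random-effects marginal
#' meta-analysis p-values fall below `marginal_p_max` (requiring both avoids
#' selecting signals dominated by a few studies).
#'
#' @param marginal Data frame with one row per SNP: `snp_id`, `maf`,
#'   `mean_r2`, `p_fixed`, `p_random`.
#' @param cfg A [screen_config()].
#' @return Character vector of selected snp_ids.
#' @export
select_marginal_candidates <- function(marginal, cfg = screen_config()) {
  m <- as.data.frame(marginal)
  keep <- m$maf > cfg$maf_min & m$mean_r2 > cfg$r2_min &
    m$p_fixed < cfg$marginal_p_max & m$p_random < cfg$marginal_p_max
  keep[is.na(keep)] <- FALSE
  m$snp_id[keep]
}

#' Linkage-disequilibrium r-squared between two dosage vectors
#'
#' Squared Pearson correlation over jointly non-missing samples. Zero
#' variance in either vector makes the correlation undefined; it is treated
#' as 0 with a warning.
#'
#' @param d1,d2 Dosage vectors of equal length.
#' @return Value in \[0, 1\].
#' @export
ld_r2 <- function(d1, d2) {
  cc <- !is.na(d1) & !is.na(d2)
  x <- d1[cc]; y <- d2[cc]
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    warning("zero variance; LD r2 undefined, treated as 0")
    return(0)
  }
  stats::cor(x, y)^2
}

# Pairwise LD r2 matrix from a dosage matrix (columns = SNPs).
ld_r2_matrix <- function(dosages) {
  r <- suppressWarnings(stats::cor(dosages, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  r^2
}

#' Greedy LD pruning of a ranked SNP list
#'
#' SNPs are ranked by marginal p-value (ties broken by chromosome then
#' position for determinism). Starting from the strongest signal, every SNP
#' with LD r-squared above `cfg$ld_r2_max` to the current SNP is removed;
#' the sweep continues with the next surviving SNP until the end of the
#' list. The output is maximal: no surviving pair exceeds the threshold
#' under the greedy ordering.
#'
#' @param snps Data frame with `snp_id`, `p` and optionally `chrom`, `pos`.
#' @param r2 Symmetric LD r-squared matrix with dimnames = snp ids (e.g.
#'   from control dosages pooled across studies).
#' @param cfg A [screen_config()].
#' @return Character vector of surviving snp_ids in rank order.
#' @export
ld_prune <- function(snps, r2, cfg = screen_config()) {
  s <- as.data.frame(snps)
  ord <- order(s$p,
               if (!is.null(s$chrom)) s$chrom else seq_len(nrow(s)),
               if (!is.null(s$pos)) s$pos else seq_len(nrow(s)))
  ids <- s$snp_id[ord]
  alive <- rep(TRUE, length(ids))
  for (i in seq_along(ids)) {
    if (!alive[i]) next
    if (i < length(ids)) {
      later <- ids[(i + 1L):length(ids)]
      hit <- r2[ids[i], later] > cfg$ld_r2_max
      alive[(i + 1L):length(ids)][hit] <- FALSE
    }
  }
  ids[alive]
}

#' Bonferroni accounting for an all-pairs interaction scan
#'
#' @param n_snps Number of (pruned) SNPs entering the pair scan.
#' @param alpha Family-wise error level.
#' @return List with `n_tests = n(n-1)/2` and `threshold = alpha/n_tests`.
#' @export
bonferroni_pairs <- function(n_snps, alpha = 0.05) {
  if (n_snps < 2L) stop("need at least 2 SNPs for a pair scan")
  n_tests <- n_snps * (n_snps - 1L) / 2
  list(n_tests = n_tests, threshold = alpha / n_tests)
}

# Per-study fits + phase-aware meta for one pair; returns one result row.
meta_pair_row <- function(studies, snp1, snp2, model, cfg,
                          include_adenoma = FALSE, firth = FALSE) {
  est <- do.call(rbind, lapply(studies, function(st) {
    e <- tryCatch(gxg_test(st, snp1, snp2, model = model,
                           firth = firth)$estimate,
                  error = function(err)
                    failed_estimate(st$study_id, model, snp1, snp2,
                                    "interaction", 1L))
    e$phase <- st$phase
    e
  }))
  pm <- suppressMessages(phase_meta(est, include_adenoma = include_adenoma))
  row <- data.frame(snp1 = snp1, snp2 = snp2, model = model,
                    stringsAsFactors = FALSE)
  for (ph in c("phase1", "phase2", "combined")) {
    m <- pm[[ph]]
    row[[paste0(ph, "_or")]] <- if (is.null(m)) NA_real_ else m$or
    row[[paste0(ph, "_ci_low")]] <- if (is.null(m)) NA_real_ else m$ci95[1L]
    row[[paste0(ph, "_ci_high")]] <- if (is.null(m)) NA_real_ else m$ci95[2L]
    row[[paste0(ph, "_p")]] <- if (is.null(m)) NA_real_ else m$p
  }
  row$p_het <- if (is.null(pm$combined)) NA_real_ else pm$combined$p_het
  row$k <- if (is.null(pm$combined)) 0L else pm$combined$k
  attr(row, "estimates") <- est
  row
}

#' All-pairs interaction scan over a pruned SNP panel
#'
#' Tests every unordered pair of panel SNPs in each study, combines per-study
#' estimates by fixed-effect meta-analysis within phase, and reports
#' discovery-phase selection (`phase1_p < cfg$pairs_select_p`) plus nominal
#' and Bonferroni-adjusted significance of the combined p-value.
#'
#' @param studies List of [genotype_dataset()] objects.
#' @param snp_ids Pruned panel (character vector, length >= 2).
#' @param model Interaction model passed to [gxg_test()].
#' @param cfg A [screen_config()].
#' @param include_adenoma Passed to [phase_meta()].
#' @return Data frame with `choose(n, 2)` rows: per-phase OR/CI/p, `p_het`,
#'   `selected` (phase-1 flag), `bonferroni_p`, `significant`.
#' @export
scan_pairs <- function(studies, snp_ids, model = "ardi",
                       cfg = screen_config(), include_adenoma = FALSE) {
  bp <- bonferroni_pairs(length(snp_ids), cfg$alpha)
  pairs <- utils::combn(snp_ids, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(i)
    meta_pair_row(studies, pairs[1L, i], pairs[2L, i], model, cfg))
  res <- do.call(rbind, rows)
  res$selected <- !is.na(res$phase1_p) & res$phase1_p < cfg$pairs_select_p
  res$bonferroni_p <- pmin(res$combined_p * bp$n_tests, 1)
  res$significant <- !is.na(res$combined_p) & res$combined_p < bp$threshold
  attr(res, "n_tests") <- bp$n_tests
  attr(res, "threshold") <- bp$threshold
  res
}

#' Genome-wide interaction scan against known susceptibility loci
#'
#' For each panel locus, tests its interaction with every other SNP passing
#' the MAF and imputation-quality filters, meta-analyzes across studies,
#' and selects interactions with discovery p below
#' `cfg$known_locus_select_p`. SNPs in LD with the locus itself
#' (r-squared > `cfg$ld_r2_max`) are excluded as interactors (same-signal
#' pairs), and within an LD cluster of selected interactors only the most
#' significant SNP is reported.
#'
#' @param studies List of [genotype_dataset()] objects.
#' @param panel Data frame with a `snp_id` column ([known_locus_panel()]
#'   subset); loci absent from the data are skipped with a warning.
#' @param model,cfg,include_adenoma As in [scan_pairs()].
#' @return Data frame of per-(locus, SNP) rows with meta columns, a
#'   `selected` flag and a `reported` flag implementing the LD dedup rule.
#' @export
scan_known_loci <- function(studies, panel, model = "ardi",
                            cfg = screen_config(),
                            include_adenoma = FALSE) {
  snps1 <- studies[[1L]]$snps
  controls <- control_dosages(studies)
  res <- NULL
  for (locus in panel$snp_id) {
    if (!locus %in% snps1$snp_id) {
      warning("locus ", locus, " absent from data; skipped")
      next
    }
    pass <- snps1$snp_id[snps1$maf > cfg$maf_min &
                           mean_imputation_r2(studies) > cfg$r2_min]
    pass <- setdiff(pass, locus)
    if (!length(pass)) next
    r2_locus <- vapply(pass, function(s)
      ld_r2(controls[, locus], controls[, s]), numeric(1L))
    pass <- pass[r2_locus <= cfg$ld_r2_max]
    rows <- lapply(pass, function(s)
      meta_pair_row(studies, locus, s, model, cfg, include_adenoma))
    block <- do.call(rbind, rows)
    block$selected <- !is.na(block$phase1_p) &
      block$phase1_p < cfg$known_locus_select_p
    block$reported <- block$selected
    sel <- which(block$selected)
    if (length(sel) > 1L) {  # one representative per LD cluster
      ord <- sel[order(block$phase1_p[sel])]
      kept <- integer(0L)
      for (i in ord) {
        if (any(vapply(kept, function(j)
          ld_r2(controls[, block$snp2[i]],
                controls[, block$snp2[j]]) > cfg$ld_r2_max,
          logical(1L)))) {
          block$reported[i] <- FALSE
        } else kept <- c(kept, i)
      }
    }
    res <- rbind(res, block)
  }
  res
}

# Pooled control dosage matrix across studies (common SNP columns).
control_dosages <- function(studies) {
  common <- Reduce(intersect, lapply(studies, function(s) s$snps$snp_id))
  do.call(rbind, lapply(studies, function(s)
    s$dosages[s$phenotype == 0L, common, drop = FALSE]))
}

# Unweighted mean per-study imputation R2 per SNP (genotyped counts as 1).
mean_imputation_r2 <- function(studies) {
  ids <- studies[[1L]]$snps$snp_id
  r2 <- sapply(studies, function(s) {
    v <- ifelse(s$snps$genotyped, 1, s$snps$imputation_r2)
    v[match(ids, s$snps$snp_id)]
  })
  rowMeans(as.matrix(r2), na.rm = TRUE)
}
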