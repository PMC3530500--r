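#' Genome-wide marginal association scan with meta-analysis
#'
#' Runs [marginal_test()] for every SNP in every study and combines the
#' per-study estimates by fixed- and random-effects meta-analysis. The
#' output feeds [select_marginal_candidates()].
#'
#' @param studies List of [genotype_dataset()] objects.
#' @param snp_ids SNPs to scan (default: all SNPs of the first study).
#' @return Data frame with one row per SNP: `snp_id`, `maf` (first study),
#'   `mean_r2`, `beta_fixed`, `se_fixed`, `p_fixed`, `p_random`, `p_het`.
#' @export
scan_marginal <- function(studies, snp_ids = NULL) {
  if (is.null(snp_ids)) snp_ids <- studies[[1L]]$snps$snp_id
  mean_r2 <- mean_imputation_r2(studies)
  names(mean_r2) <- studies[[1L]]$snps$snp_id
  rows <- lapply(snp_ids, function(s) {
    est <- do.call(rbind, lapply(studies, function(st)
      marginal_test(st, s)$estimate))
    mf <- tryCatch(suppressMessages(fixed_effect_meta(est)),
                   error = function(e) NULL)
    mr <- if (nrow(est) >= 2L)
      tryCatch(suppressMessages(random_effect_meta(est)),
               error = function(e) NULL) else mf
    data.frame(snp_id = s,
               maf = studies[[1L]]$snps$maf[
                 match(s, studies[[1L]]$snps$snp_id)],
               mean_r2 = unname(mean_r2[s]),
               beta_fixed = if (is.null(mf)) NA_real_ else mf$beta,
               se_fixed = if (is.null(mf)) NA_real_ else mf$se,
               p_fixed = if (is.null(mf)) NA_real_ else mf$p,
               p_random = if (is.null(mr)) NA_real_ else mr$p,
               p_het = if (is.null(mf)) NA_real_ else mf$p_het,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Manifest: config snapshot + seed + per-stage counts, serialised to JSON.
run_manifest <- function(config, seed, stages = list()) {
  list(package_version = as.character(utils::packageVersion("ardi")),
       config = config, seed = seed, stages = stages,
       created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
}

manifest_digest <- function(manifest) {
  s <- jsonlite::toJSON(manifest[c("config", "seed", "stages")],
                        auto_unbox = TRUE, digits = NA)
  # small rolling-hash digest; provenance tag, not cryptographic
  v <- utf8ToInt(as.character(s))
  sprintf("%08x", Reduce(function(a, b) (a * 31 + b) %% 2^28, v, 7L))
}

write_result_tsv <- function(df, path, manifest) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ardi manifest %s", manifest_digest(manifest)), con)
  for (nm in names(manifest$config))
    writeLines(sprintf("# config %s = %s", nm,
                       paste(manifest$config[[nm]], collapse = ",")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Known-locus interaction search workflow
#'
#' Orchestrates the published known-locus strategy on the discovery
#' (phase-1) studies: per-locus genome-wide ARDI scan, genomic-inflation
#' diagnostic with the main-effect misspecification guard (loci with
#' lambda above the guard threshold are rerun with unrestricted-main
#' coding), discovery selection at `cfg$known_locus_select_p`, replication
#' and combined meta-analysis over all phases for selected pairs.
#'
#' @param studies List of [genotype_dataset()] objects (phases mixed; the
#'   scan itself uses the phase-1 studies).
#' @param panel Data frame with `snp_id` (default [known_locus_panel()]
#'   restricted to loci present in the data).
#' @param cfg A [screen_config()].
#' @param out_dir Optional directory; when given, writes
#'   `known_locus_results.tsv`, `inflation_report.tsv` and
#'   `manifest.json`.
#' @param guard_threshold Lambda threshold for [inflation_guard()].
#' @param seed Recorded in the manifest (the workflow itself is
#'   deterministic given the data).
#' @return List with `results` (selected rows incl. all-phase meta
#'   columns), `scan` (all tested rows), `inflation` (per-locus reports)
#'   and `manifest`.
#' @export
run_known_locus_workflow <- function(studies, panel = NULL,
                                     cfg = screen_config(), out_dir = NULL,
                                     guard_threshold = 1.05, seed = NA) {
  phase1 <- studies[vapply(studies, function(s) s$phase == "phase1",
                           logical(1L))]
  if (!length(phase1)) stop("no phase1 studies supplied")
  if (is.null(panel)) {
    panel <- known_locus_panel()
    panel <- panel[panel$snp_id %in% studies[[1L]]$snps$snp_id, ,
                   drop = FALSE]
  }
  if (!nrow(panel)) stop("no panel loci present in the data")
  scan <- scan_known_loci(phase1, panel, model = "ardi", cfg = cfg)
  inflation <- list()
  for (locus in unique(scan$snp1)) {
    pv <- scan$phase1_p[scan$snp1 == locus]
    pv <- pv[!is.na(pv)]
    rep0 <- suppressWarnings(
      inflation_guard(pv, threshold = guard_threshold, locus_id = locus))
    if (rep0$rerun) {
      idx <- which(scan$snp1 == locus)
      redo <- lapply(scan$snp2[idx], function(s)
        meta_pair_row(phase1, locus, s, "ardi_umain", cfg))
      redo <- do.call(rbind, redo)
      redo$selected <- !is.na(redo$phase1_p) &
        redo$phase1_p < cfg$known_locus_select_p
      redo$reported <- redo$selected
      scan[idx, names(redo)] <- redo
      pv2 <- redo$phase1_p[!is.na(redo$phase1_p)]
      rep0$lambda_after <- suppressWarnings(genomic_lambda(pv2))
    }
    inflation[[locus]] <- rep0
  }
  sel <- scan[scan$reported, , drop = FALSE]
  results <- NULL
  if (nrow(sel)) {
    results <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i)
      meta_pair_row(studies, sel$snp1[i], sel$snp2[i],
                    sel$model[i], cfg)))
  }
  config <- c(unclass(cfg), guard_threshold = guard_threshold)
  config$het_p_min <- NULL
  manifest <- run_manifest(config, seed,
                           stages = list(n_loci = nrow(panel),
                                         n_scan_rows = nrow(scan),
                                         n_selected = nrow(sel)))
  out <- list(results = results, scan = scan, inflation = inflation,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(results))
      write_result_tsv(results, file.path(out_dir,
                                          "known_locus_results.tsv"),
                       manifest)
    infl_df <- do.call(rbind, lapply(inflation, function(r)
      data.frame(locus = r$locus_id, lambda = r$lambda,
                 n_tests = r$n_tests, coding = r$coding_used,
                 lambda_after = if (is.null(r$lambda_after)) NA_real_
                 else r$lambda_after)))
    write_result_tsv(infl_df, file.path(out_dir, "inflation_report.tsv"),
                     manifest)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Two-stage all-pairs interaction search workflow
#'
#' Orchestrates the published two-stage strategy: marginal scan with fixed-
#' and random-effects meta-analysis on the phase-1 studies, candidate
#' selection (MAF, imputation quality, both meta p-values), greedy LD
#' pruning on pooled control dosages, all-pairs ARDI scan with Bonferroni
#' accounting, and phase-wise meta-analysis (phase-2 rows replicate
#' phase-1 selections; direction consistency is flagged).
#'
#' @param studies List of [genotype_dataset()] objects.
#' @param cfg A [screen_config()].
#' @param out_dir Optional output directory (writes `pair_scan_results.tsv`
#'   and `manifest.json`).
#' @param seed Recorded in the manifest.
#' @return List with `marginal`, `candidates`, `pruned`, `pairs` (scan
#'   table with `selected`, `significant`, `direction_consistent`),
#'   `n_tests`, `threshold`, `manifest`.
#' @export
run_pair_scan_workflow <- function(studies, cfg = screen_config(),
                                   out_dir = NULL, seed = NA) {
  phase1 <- studies[vapply(studies, function(s) s$phase == "phase1",
                           logical(1L))]
  if (!length(phase1)) stop("no phase1 studies supplied")
  marg <- scan_marginal(phase1)
  cand <- select_marginal_candidates(marg, cfg)
  if (length(cand) < 2L)
    stop("fewer than 2 candidate SNPs pass the marginal screen")
  controls <- control_dosages(phase1)
  r2 <- ld_r2_matrix(controls[, cand, drop = FALSE])
  snps1 <- studies[[1L]]$snps
  rank_df <- data.frame(snp_id = cand,
                        p = marg$p_fixed[match(cand, marg$snp_id)],
                        chrom = snps1$chrom[match(cand, snps1$snp_id)],
                        pos = snps1$pos[match(cand, snps1$snp_id)])
  pruned <- ld_prune(rank_df, r2, cfg)
  pairs <- scan_pairs(studies, pruned, model = "ardi", cfg = cfg)
  sel <- which(pairs$selected)
  pairs$direction_consistent <- NA
  if (length(sel))
    pairs$direction_consistent[sel] <-
      !is.na(pairs$phase2_or[sel]) &
      sign(log(pairs$phase2_or[sel])) == sign(log(pairs$phase1_or[sel]))
  config <- unclass(cfg); config$het_p_min <- NULL
  manifest <- run_manifest(config, seed,
                           stages = list(n_snps = nrow(marg),
                                         n_candidates = length(cand),
                                         n_pruned = length(pruned),
                                         n_tests = attr(pairs, "n_tests")))
  out <- list(marginal = marg, candidates = cand, pruned = pruned,
              pairs = pairs, n_tests = attr(pairs, "n_tests"),
              threshold = attr(pairs, "threshold"), manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(pairs, file.path(out_dir, "pair_scan_results.tsv"),
                     manifest)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
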