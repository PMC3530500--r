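# Shared fixtures built in code: tiny VCFs, hand-made datasets, and a
# multi-SNP panel study with LD clusters for screening/pipeline tests.

# Minimal dataset from explicit dosage columns and phenotype.
make_dataset <- function(dosages, y, study_id = "s1", covariates = NULL,
                         phase = "phase1", probs = NULL,
                         ref = "A", count = "G") {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  snps <- data.frame(snp_id = colnames(dosages), chrom = "1",
                     pos = seq_len(ncol(dosages)) * 100L,
                     ref_allele = ref, count_allele = count,
                     stringsAsFactors = FALSE)
  genotype_dataset(study_id, dosages, snps, y, covariates = covariates,
                   genotype_probs = probs, phase = phase)
}

# Write a small VCF to a temp file; `body` is a character vector of
# data lines (CHROM POS ID REF ALT QUAL FILTER INFO FORMAT samples...).
write_test_vcf <- function(body, samples = c("S1", "S2", "S3")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
    "##FORMAT=<ID=GP,Number=3,Type=Float,Description=\"Genotype probabilities\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), path)
  path
}

# Panel study: `k_clusters` LD clusters of `cluster_size` SNPs (within-
# cluster r2 ~ 0.9) with per-cluster main effects, plus an optional
# carrier-product interaction between the lead SNPs of clusters 1 and 2.
# Cohort-style sampling (balanced prevalence) keeps it fast; marginal
# signals are controlled by `beta_main`.
make_panel_study <- function(n = 3000, k_clusters = 3, cluster_size = 3,
                             maf = 0.3, beta_main = 0.25, gamma = 0,
                             seed = 1, study_id = "panel1",
                             phase = "phase1") {
  set.seed(seed)
  cols <- list()
  for (cl in seq_len(k_clusters)) {
    lead <- simulate_genotypes(n, maf)
    cols[[sprintf("c%d_s1", cl)]] <- lead
    for (j in seq_len(cluster_size - 1L)) {
      # LD partner: copy lead haplotype-wise with small flip probability
      part <- lead
      flip <- which(stats::runif(n) < 0.05)
      part[flip] <- simulate_genotypes(length(flip), maf)
      cols[[sprintf("c%d_s%d", cl, j + 1L)]] <- part
    }
  }
  dos <- do.call(cbind, cols)
  leads <- sprintf("c%d_s1", seq_len(k_clusters))
  eta <- -0.1 + dos[, leads, drop = FALSE] %*% rep(beta_main, k_clusters)
  if (gamma != 0)
    eta <- eta + gamma * pmin(dos[, "c1_s1"], 1) * pmin(dos[, "c2_s1"], 1)
  y <- stats::rbinom(n, 1L, stats::plogis(eta))
  make_dataset(dos, y, study_id = study_id, phase = phase)
}

# Deterministic per-study ARDI estimates for meta tests.
fake_estimates <- function(beta, se, phase = NULL, study_id = NULL) {
  k <- length(beta)
  df <- data.frame(
    study_id = if (is.null(study_id)) paste0("study", seq_len(k)) else
      study_id,
    beta = beta, se = se, converged = TRUE, stringsAsFactors = FALSE)
  if (!is.null(phase)) df$phase <- phase
  df
}
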