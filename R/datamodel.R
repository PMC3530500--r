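#' Construct a per-study genotype dataset
#'
#' Bundles one study's dosage matrix, optional genotype probabilities, SNP
#' metadata, binary phenotype and covariates into a validated container used
#' by all testing, screening and meta-analysis functions.
#'
#' @param study_id Character scalar identifying the study.
#' @param dosages Numeric sample-by-SNP matrix of expected count-allele
#'   dosages in \[0, 2\]; `NA` marks missing calls. Column names must be SNP
#'   ids, row names sample ids (generated if absent).
#' @param snps Data frame of SNP metadata with columns `snp_id`, `chrom`,
#'   `pos`, `ref_allele`, `count_allele` and optionally `maf`,
#'   `imputation_r2`, `genotyped`. One row per dosage column, same order.
#'   A missing `maf` is computed from the dosages.
#' @param phenotype Integer/numeric vector of case status (1 case,
#'   0 control), one per sample.
#' @param covariates Optional data frame or matrix of numeric adjustment
#'   covariates (age, sex, center indicators, principal components), one row
#'   per sample. `NULL` for unadjusted analyses.
#' @param genotype_probs Optional list of sample-by-3 matrices (one per SNP,
#'   named by `snp_id`) holding P(G=0), P(G=1), P(G=2); rows must sum to 1
#'   within 1e-6.
#' @param phase Character tag, typically `"phase1"`, `"phase2"` or
#'   `"adenoma"`; used by [phase_meta()].
#'
#' @return An object of class `genotype_dataset`.
#' @seealso [read_dosage_tsv()], [load_dosage_vcf()], [simulate_case_control()]
#' @export
genotype_dataset <- function(study_id, dosages, snps, phenotype,
                             covariates = NULL, genotype_probs = NULL,
                             phase = "phase1") {
  stopifnot(is.character(study_id), length(study_id) == 1L)
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages)
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("%s_s%d", study_id, seq_len(n))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (is.null(colnames(dosages))) colnames(dosages) <- snps$snp_id
  if (!identical(colnames(dosages), as.character(snps$snp_id)))
    stop("dosage columns and snps$snp_id must match in order")
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < -1e-9 || rng[2] > 2 + 1e-9)
    stop("dosages must lie in [0, 2] (or NA)")
  if (length(phenotype) != n) stop("phenotype length != number of samples")
  phenotype <- as.integer(phenotype)
  if (!all(phenotype %in% c(0L, 1L))) stop("phenotype must be 0/1")
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) stop("covariates rows != number of samples")
    if (!all(vapply(covariates, is.numeric, logical(1L))))
      stop("covariates must be numeric (code factors as indicators)")
  }
  if (!is.null(genotype_probs)) {
    for (nm in names(genotype_probs)) {
      gp <- genotype_probs[[nm]]
      if (nrow(gp) != n || ncol(gp) != 3L)
        stop("genotype_probs[['", nm, "']] must be n x 3")
      ok <- is.na(gp[, 1L]) | abs(rowSums(gp) - 1) <= 1e-6
      if (!all(ok))
        stop("genotype probability rows must sum to 1 (SNP ", nm, ")")
    }
  }
  snps <- complete_snp_table(snps, dosages)
  structure(
    list(study_id = study_id, dosages = dosages, snps = snps,
         phenotype = phenotype, covariates = covariates,
         genotype_probs = genotype_probs, phase = phase),
    class = "genotype_dataset")
}

# Fill derived/default SNP metadata columns and validate invariants.
complete_snp_table <- function(snps, dosages) {
  if (is.null(snps$maf) || anyNA(snps$maf))
    snps$maf <- vapply(seq_len(ncol(dosages)),
                       function(j) compute_maf(dosages[, j]), numeric(1L))
  if (is.null(snps$genotyped)) snps$genotyped <- TRUE
  if (is.null(snps$imputation_r2)) snps$imputation_r2 <- NA_real_
  # genotyped SNPs count as perfectly imputed in quality filters
  snps$imputation_r2 <- ifelse(snps$genotyped & is.na(snps$imputation_r2),
                               1, snps$imputation_r2)
  snps$imputation_r2 <- pmin(snps$imputation_r2, 1)  # tools can report >1
  if (any(snps$maf < -1e-9 | snps$maf > 0.5 + 1e-9, na.rm = TRUE))
    stop("maf must lie in [0, 0.5]")
  same <- !is.na(snps$ref_allele) & !is.na(snps$count_allele) &
    snps$ref_allele == snps$count_allele
  if (any(same)) stop("count_allele must differ from ref_allele")
  snps$ambiguous <- is_strand_ambiguous(snps$ref_allele, snps$count_allele)
  rownames(snps) <- NULL
  snps
}

is_strand_ambiguous <- function(a1, a2) {
  p <- paste0(toupper(ifelse(is.na(a1), "", a1)),
              toupper(ifelse(is.na(a2), "", a2)))
  p %in% c("AT", "TA", "CG", "GC")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("genotype_dataset:", x$study_id, sprintf("(%s)\n", x$phase))
  cat(sprintf("  %d samples (%d cases / %d controls), %d SNPs\n",
              length(x$phenotype), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), ncol(x$dosages)))
  if (!is.null(x$covariates))
    cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.genotype_dataset <- function(x) dim(x$dosages)

#' Minor allele frequency from dosages
#'
#' `min(f, 1 - f)` where `f = mean(dosage) / 2` over non-missing samples, so
#' the result is invariant under the allele flip `d -> 2 - d`.
#'
#' @param dosages Numeric vector of dosages in \[0, 2\], `NA` allowed.
#' @return Frequency in \[0, 0.5\].
#' @export
compute_maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) == 0L) stop("all dosages missing; MAF undefined")
  f <- mean(d) / 2
  min(f, 1 - f)
}

#' Read and write plain-text dosage matrices
#'
#' The TSV layout is samples in rows; the first column `sample_id`, remaining
#' columns one per SNP named by its id. `write_dosage_tsv()` uses full
#' precision (`%.17g`) so a write/read round trip reproduces finite values
#' bit-exactly.
#'
#' @param path File path.
#' @return `read_dosage_tsv()`: a numeric matrix with sample row names and
#'   SNP column names. `write_dosage_tsv()`: `path`, invisibly.
#' @export
read_dosage_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  m
}

#' @rdname read_dosage_tsv
#' @param dosages Sample-by-SNP numeric matrix.
#' @export
write_dosage_tsv <- function(dosages, path) {
  df <- data.frame(sample_id = rownames(dosages),
                   format(dosages, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' Expects a TSV with columns `sample_id`, `status` (0/1) and any number of
#' numeric covariate columns.
#'
#' @param path File path.
#' @return Data frame with `sample_id` as character and `status` as integer.
#' @export
read_phenotype_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(df)))
    stop("phenotype TSV needs sample_id and status columns")
  df$sample_id <- as.character(df$sample_id)
  df$status <- as.integer(df$status)
  df
}

#' Load a genotype dataset from VCF
#'
#' Parses dosages from the `DS` FORMAT field, falling back to genotype
#' probabilities (`GP`, stored and summed to a dosage) and finally to
#' hard-call `GT`. SNPs carrying none of the three are skipped with a
#' warning. By default the ALT allele is counted (VCF convention);
#' `count_allele_policy = "minor"` flips sites where the ALT allele is the
#' major one so that dosages count the minor allele.
#'
#' @param path Path to an uncompressed or bgzipped VCF.
#' @param study_id Study identifier; defaults to the file name.
#' @param count_allele_policy `"alt"` or `"minor"`.
#' @param phenotype,covariates,phase Passed through to [genotype_dataset()];
#'   `phenotype` defaults to all controls when absent (genotype-only use).
#' @return A [genotype_dataset()].
#' @export
load_dosage_vcf <- function(path, study_id = basename(path),
                            count_allele_policy = c("alt", "minor"),
                            phenotype = NULL, covariates = NULL,
                            phase = "phase1") {
  count_allele_policy <- match.arg(count_allele_policy)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix[, c("CHROM", "POS", "ID", "REF", "ALT"),
                               drop = FALSE],
                       stringsAsFactors = FALSE)
  fmt <- vcf@gt[, 1L]  # FORMAT column
  n_snp <- nrow(fix)
  samples <- colnames(vcf@gt)[-1L]
  n <- length(samples)

  has <- function(key) grepl(paste0("(^|:)", key, "(:|$)"), fmt)
  ds_ok <- has("DS"); gp_ok <- has("GP"); gt_ok <- has("GT")
  usable <- ds_ok | gp_ok | gt_ok
  if (!all(usable)) {
    warning(sum(!usable), " VCF record(s) without DS/GP/GT skipped")
  }
  ds <- if (any(ds_ok)) suppressWarnings(
    vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)) else NULL
  gp <- if (any(gp_ok)) vcfR::extract.gt(vcf, element = "GP") else NULL
  gt <- if (any(gt_ok)) vcfR::extract.gt(vcf, element = "GT") else NULL

  keep <- which(usable)
  dos <- matrix(NA_real_, n, length(keep),
                dimnames = list(samples, fix$ID[keep]))
  probs <- list()
  for (idx in seq_along(keep)) {
    i <- keep[idx]
    if (ds_ok[i] && !is.null(ds)) {
      dos[, idx] <- ds[i, ]
    }
    if (gp_ok[i] && !is.null(gp)) {
      pm <- t(vapply(strsplit(gp[i, ], ","),
                     function(v) as.numeric(v)[1:3], numeric(3L)))
      probs[[fix$ID[i]]] <- pm
      if (!ds_ok[i]) dos[, idx] <- pm[, 2L] + 2 * pm[, 3L]
    }
    if (is.na(dos[1L, idx]) && !ds_ok[i] && !gp_ok[i] && gt_ok[i]) {
      g <- gt[i, ]
      dos[, idx] <- vapply(strsplit(g, "[/|]"), function(v) {
        a <- suppressWarnings(as.numeric(v))
        if (anyNA(a)) NA_real_ else sum(a > 0)
      }, numeric(1L))
    }
  }
  fixk <- fix[keep, , drop = FALSE]
  snps <- data.frame(snp_id = fixk$ID, chrom = fixk$CHROM,
                     pos = as.integer(fixk$POS),
                     ref_allele = fixk$REF, count_allele = fixk$ALT,
                     stringsAsFactors = FALSE)
  if (count_allele_policy == "minor") {
    f <- colMeans(dos, na.rm = TRUE) / 2
    flip <- which(f > 0.5)
    for (j in flip) {
      dos[, j] <- 2 - dos[, j]
      tmp <- snps$ref_allele[j]
      snps$ref_allele[j] <- snps$count_allele[j]
      snps$count_allele[j] <- tmp
      nm <- snps$snp_id[j]
      if (!is.null(probs[[nm]])) probs[[nm]] <- probs[[nm]][, 3:1]
    }
  }
  if (is.null(phenotype)) phenotype <- rep(0L, n)
  genotype_dataset(study_id, dos, snps, phenotype, covariates,
                   genotype_probs = if (length(probs)) probs else NULL,
                   phase = phase)
}

#' Harmonize count alleles across studies
#'
#' Multi-study meta-analysis requires every study to count the same allele
#' per SNP. SNPs are matched by (snp_id, chrom, pos); the first study that
#' carries a SNP defines the reference orientation. Studies counting the
#' opposite allele are flipped (`d -> 2 - d`, metadata swapped); SNPs whose
#' allele pair cannot be reconciled are dropped from the offending study
#' with a message. Strand-ambiguous A/T and C/G SNPs are flagged in the
#' `ambiguous` column but never auto-flipped on frequency, which is
#' unreliable near MAF 0.5.
#'
#' @param studies List of [genotype_dataset()] objects.
#' @return The list with consistent orientations; the operation is
#'   idempotent.
#' @export
harmonize_alleles <- function(studies) {
  stopifnot(length(studies) >= 1L)
  ref <- list()  # key -> c(ref, count)
  out <- studies
  for (s in seq_along(out)) {
    st <- out[[s]]
    key <- paste(st$snps$snp_id, st$snps$chrom, st$snps$pos)
    drop <- integer(0L)
    for (j in seq_along(key)) {
      k <- key[j]
      al <- c(st$snps$ref_allele[j], st$snps$count_allele[j])
      if (is.null(ref[[k]])) { ref[[k]] <- al; next }
      r <- ref[[k]]
      if (identical(al, r)) next
      if (identical(al, r[2:1])) {  # counts the other allele: flip
        st$dosages[, j] <- 2 - st$dosages[, j]
        st$snps$ref_allele[j] <- r[1L]
        st$snps$count_allele[j] <- r[2L]
        nm <- st$snps$snp_id[j]
        if (!is.null(st$genotype_probs[[nm]]))
          st$genotype_probs[[nm]] <- st$genotype_probs[[nm]][, 3:1]
      } else {
        drop <- c(drop, j)
      }
    }
    if (length(drop)) {
      message("harmonize_alleles: dropping ", length(drop), " SNP(s) with ",
              "irreconcilable alleles from study ", st$study_id, ": ",
              paste(st$snps$snp_id[drop], collapse = ", "))
      st$dosages <- st$dosages[, -drop, drop = FALSE]
      st$snps <- st$snps[-drop, , drop = FALSE]
      rownames(st$snps) <- NULL
    }
    st$snps$maf <- vapply(seq_len(ncol(st$dosages)),
                          function(j) compute_maf(st$dosages[, j]),
                          numeric(1L))
    out[[s]] <- st
  }
  out
}

# Dosage vector for one SNP (by id) from a dataset.
snp_dosage <- function(data, snp) {
  j <- match(snp, data$snps$snp_id)
  if (is.na(j)) stop("SNP ", snp, " not present in study ", data$study_id)
  data$dosages[, j]
}

# Genotype probability matrix for one SNP, or NULL.
snp_probs <- function(data, snp) {
  if (is.null(data$genotype_probs)) return(NULL)
  data$genotype_probs[[snp]]
}
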