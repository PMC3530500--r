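test_that("marginal candidate selection applies the AND of all filters", {
  m <- data.frame(
    snp_id = c("a", "b", "c", "d"),
    maf = c(0.10, 0.04, 0.20, 0.30),
    mean_r2 = c(0.9, 0.9, 0.9, 0.2),
    p_fixed = c(1e-5, 1e-6, 5e-5, 1e-6),
    p_random = c(5e-5, 1e-6, 3e-4, 1e-6))
  expect_equal(select_marginal_candidates(m), "a")
})

test_that("LD r2 basics: identity, flip symmetry, independence, zero var", {
  set.seed(61)
  d <- simulate_genotypes(500, 0.3)
  expect_equal(ld_r2(d, d), 1)
  expect_equal(ld_r2(d, 2 - d), 1)
  e <- simulate_genotypes(10000, 0.3)
  f <- simulate_genotypes(10000, 0.25)
  expect_lt(ld_r2(e, f), 0.01)
  expect_warning(r0 <- ld_r2(d, rep(1, 500)), "zero variance")
  expect_equal(r0, 0)
})

test_that("greedy LD pruning follows the ranked sweep", {
  snps <- data.frame(snp_id = c("A", "B", "C"), p = c(1e-6, 1e-5, 1e-4))
  r2 <- matrix(0.1, 3, 3, dimnames = list(snps$snp_id, snps$snp_id))
  diag(r2) <- 1
  r2["A", "B"] <- r2["B", "A"] <- 0.9
  expect_equal(ld_prune(snps, r2), c("A", "C"))
  expect_equal(ld_prune(snps[1, , drop = FALSE],
                        r2[1, 1, drop = FALSE]), "A")
  r2["A", "B"] <- r2["B", "A"] <- 0.5
  expect_equal(ld_prune(snps, r2), c("A", "B", "C"))
})

test_that("pruned output is maximal under the greedy ordering", {
  set.seed(71)
  for (rep in 1:5) {
    k <- 12
    ids <- paste0("s", 1:k)
    r2 <- matrix(runif(k * k), k, k, dimnames = list(ids, ids))
    r2 <- (r2 + t(r2)) / 2; diag(r2) <- 1
    snps <- data.frame(snp_id = ids, p = runif(k))
    kept <- ld_prune(snps, r2)
    if (length(kept) > 1) {
      combs <- combn(kept, 2)
      expect_true(all(r2[t(combs)] <= 0.8))
    }
    # every removed SNP has a kept, stronger-ranked partner above threshold
    gone <- setdiff(ids, kept)
    for (g in gone) {
      stronger <- kept[snps$p[match(kept, snps$snp_id)] <=
                         snps$p[match(g, snps$snp_id)]]
      expect_true(any(r2[g, stronger] > 0.8))
    }
  }
})

test_that("Bonferroni pair accounting", {
  bp <- bonferroni_pairs(163, 0.05)
  expect_equal(bp$n_tests, 13203)
  expect_equal(bp$threshold, 0.05 / 13203)
  expect_equal(bonferroni_pairs(2, 0.05),
               list(n_tests = 1, threshold = 0.05))
  expect_equal(bonferroni_pairs(10, 0.05)$threshold, 0.05 / 45)
  expect_error(bonferroni_pairs(1), "at least 2")
})

test_that("scan_pairs enumerates C(n,2) rows and meta-analyzes per phase", {
  set.seed(81)
  studies <- list(
    make_panel_study(1200, k_clusters = 5, cluster_size = 1, seed = 1,
                     study_id = "p1", phase = "phase1"),
    make_panel_study(800, k_clusters = 5, cluster_size = 1, seed = 2,
                     study_id = "p2", phase = "phase2"))
  ids <- colnames(studies[[1]]$dosages)
  res <- scan_pairs(studies, ids)
  expect_equal(nrow(res), choose(5, 2))
  expect_equal(attr(res, "n_tests"), 10)
  expect_true(all(c("phase1_p", "phase2_p", "combined_p", "p_het")
                  %in% names(res)))
  expect_true(all(is.finite(res$combined_p)))
})

test_that("a planted carrier interaction is the top pair in the scan", {
  set.seed(91)
  hits <- 0L
  for (s in 1:6) {
    st <- make_panel_study(4000, k_clusters = 4, cluster_size = 1,
                           beta_main = 0.2, gamma = log(0.45),
                           seed = 400 + s)
    res <- scan_pairs(list(st), colnames(st$dosages))
    top <- which.min(res$combined_p)
    if (res$snp1[top] == "c1_s1" && res$snp2[top] == "c2_s1")
      hits <- hits + 1L
  }
  expect_gte(hits, 5L)
})

test_that("known-locus scan filters, selects and deduplicates LD partners", {
  set.seed(95)
  # locus c1_s1; its interactor c2_s1 has an r2 ~ 0.9 partner c2_s2
  st <- make_panel_study(6000, k_clusters = 3, cluster_size = 2,
                         beta_main = 0.15, gamma = log(0.4), seed = 77)
  cfg <- screen_config(known_locus_select_p = 1e-3)
  res <- scan_known_loci(list(st), data.frame(snp_id = "c1_s1"),
                         cfg = cfg)
  # own-cluster partner c1_s2 is excluded as a same-signal interactor
  expect_false("c1_s2" %in% res$snp2)
  sel <- res[res$selected, ]
  if (any(c("c2_s1", "c2_s2") %in% sel$snp2)) {
    reported <- res$snp2[res$reported]
    expect_equal(sum(c("c2_s1", "c2_s2") %in% reported), 1L)
  }
  # absent locus is skipped with a warning
  expect_warning(
    r2 <- scan_known_loci(list(st), data.frame(snp_id = "rs0")),
    "absent")
  expect_null(r2)
})

test_that("all-null known-locus scan selects nothing at 1e-6", {
  set.seed(97)
  st <- make_panel_study(800, k_clusters = 6, cluster_size = 1,
                         beta_main = 0, seed = 55)
  res <- scan_known_loci(list(st), data.frame(snp_id = "c1_s1"))
  expect_equal(sum(res$selected), 0L)
})

test_that("known_locus_panel lists 14 unique loci", {
  p <- known_locus_panel()
  expect_equal(nrow(p), 14L)
  expect_equal(anyDuplicated(p$snp_id), 0L)
  expect_true("rs10795668" %in% p$snp_id)
})

test_that("screen_config validates and carries defaults", {
  cfg <- screen_config()
  expect_equal(cfg$maf_min, 0.05)
  expect_equal(cfg$ld_r2_max, 0.8)
  expect_equal(cfg$pairs_select_p, 5e-5)
  expect_error(screen_config(maf_min = 0))
})
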