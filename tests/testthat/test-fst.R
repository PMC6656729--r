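test_that("fixed difference gives theta = 1, no differentiation <= 0", {
  fx <- geno_from_counts(c(0, 20), c(20, 20))
  expect_equal(snp_fst(fx$g, fx$pa)$theta, 1)
  same <- geno_from_counts(c(5, 5), c(20, 20))
  expect_lte(snp_fst(same$g, same$pa)$theta, 0)
})

test_that("theta matches the hand-evaluated WC84 haploid components", {
  fx <- geno_from_counts(c(1, 9), c(10, 10))
  # explicit arithmetic: p = (0.1, 0.9), MSB = 3.2, MSW = 0.1, nc = 10
  expect_equal(snp_fst(fx$g, fx$pa)$theta, 0.31 / 0.41, tolerance = 1e-12)
  expect_equal(wc_theta_oracle(c(1, 9), c(10, 10)), 0.31 / 0.41,
               tolerance = 1e-12)
})

test_that("theta is invariant to reference/alternate relabelling", {
  set.seed(31)
  for (i in 1:20) {
    sizes <- sample(2:6, sample(2:4, 1), replace = TRUE)
    counts <- vapply(sizes, function(n) sample(0:n, 1), integer(1))
    fx <- geno_from_counts(counts, sizes)
    fl <- geno_from_counts(sizes - counts, sizes)
    t1 <- snp_fst(fx$g, fx$pa)$theta
    t2 <- snp_fst(fl$g, fl$pa)$theta
    expect_equal(t1, t2, tolerance = 1e-12)
  }
})

test_that("monomorphic and underpowered SNPs are flagged NA, not 0", {
  dos <- cbind(rep(0, 8), c(1, rep(NA, 3), 0, 0, 0, 0))
  g <- toy_geno(dos)
  pa <- stats::setNames(rep(c("group_1", "group_2"), each = 4),
                        rownames(g$dosage))
  th <- snp_fst(g, pa)$theta
  expect_true(is.na(th[1]))  # monomorphic everywhere
  expect_true(is.na(th[2]))  # one population left with < 2 calls
})

test_that("multilocus combining: identity for one SNP, 1 for all-fixed", {
  fx <- geno_from_counts(c(1, 9), c(10, 10))
  per <- snp_fst(fx$g, fx$pa)
  ml <- multilocus_fst(per)
  expect_equal(ml$ratio_of_sums, per$theta)
  expect_equal(ml$mean_theta, per$theta)
  fixed <- toy_geno(cbind(rep(c(0, 1), each = 10), rep(c(0, 1), each = 10)))
  pa <- stats::setNames(rep(c("group_1", "group_2"), each = 10),
                        rownames(fixed$dosage))
  expect_equal(multilocus_fst(snp_fst(fixed, pa))$ratio_of_sums, 1)
})

test_that("permutation scan is seeded, flags fixed differences", {
  sim <- simulate_genotypes(n_pops = 3, pop_sizes = 15, n_snps = 120,
                            fst = 0.05, seed = 6)
  pa <- assign_populations(sim$q)
  # graft a fixed-difference SNP into the panel
  g <- sim$genotypes
  g$dosage[, 1] <- as.numeric(pa[rownames(g$dosage)] == "group_1")
  s1 <- fst_permutation_null(g, pa, n_perm = 200, seed = 42)
  s2 <- fst_permutation_null(g, pa, n_perm = 200, seed = 42)
  expect_identical(s1$significant, s2$significant)
  expect_identical(s1$null_q, s2$null_q)
  expect_true(s1$significant[1])
  expect_equal(s1$theta[1], 1)
  # significant implies observed theta above its null quantile
  sig <- which(s1$significant)
  expect_true(all(s1$theta[sig] > s1$null_q[sig]))
})

test_that("neutral Fst is the median of significant intergenic theta", {
  scan <- data.frame(theta = c(0.05, 0.10, 0.20, 0.90, 0.50),
                     intergenic = c(TRUE, TRUE, TRUE, FALSE, TRUE),
                     significant = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(neutral_fst(scan), 0.10)
  one <- data.frame(theta = 0.3, intergenic = TRUE, significant = TRUE)
  expect_equal(neutral_fst(one), 0.3)
  none <- data.frame(theta = 0.3, intergenic = FALSE, significant = TRUE)
  expect_error(neutral_fst(none), "intergenic")
})

test_that("significance filtering cannot lower the intergenic median", {
  for (s in 1:5) {
    sim <- simulate_genotypes(n_pops = 4, pop_sizes = 30, n_snps = 400,
                              fst = 0.1, seed = s)
    pa <- assign_populations(sim$q)
    scan <- fst_permutation_null(sim$genotypes, pa, n_perm = 200, seed = s)
    med_all <- stats::median(scan$theta[scan$intergenic], na.rm = TRUE)
    expect_gte(neutral_fst(scan), med_all)
  }
})

test_that("LD pruning drops in-window duplicates, keeps distant ones", {
  set.seed(12)
  base <- sample(0:1, 40, TRUE)
  # duplicate 1 kb away -> dropped; duplicate 60 kb away -> kept
  dos <- cbind(base, base, sample(0:1, 40, TRUE), base)
  g <- toy_geno(dos, pos = c(1000, 2000, 30000, 62000))
  kept <- ld_prune(g)
  expect_true(1 %in% kept)
  expect_false(2 %in% kept)
  expect_true(4 %in% kept)
  # zero-variance SNP is kept unless exactly duplicated
  dos2 <- cbind(base, rep(0, 40), rep(0, 40))
  g2 <- toy_geno(dos2, pos = c(1000, 2000, 3000))
  expect_equal(ld_prune(g2), c(1, 2))
})

test_that("independent SNPs survive pruning and no kept pair is in LD", {
  sim <- simulate_genotypes(n_pops = 1, pop_sizes = 300, n_snps = 400,
                            fst = 0, n_chrom = 1, seed = 19)
  g <- sim$genotypes
  kept <- ld_prune(g)
  expect_gte(length(kept) / 400, 0.99)
  # invariant on a correlated panel: no retained in-window pair at r2 >= 0.1
  g$dosage[, 2] <- g$dosage[, 1]
  g$dosage[, 5] <- g$dosage[, 4]
  kept2 <- ld_prune(g)
  pos <- g$snps$pos
  for (a in seq_along(kept2)) {
    for (b in seq_len(a - 1)) {
      i <- kept2[b]; j <- kept2[a]
      if (pos[j] - pos[i] <= 50000) {
        r2 <- suppressWarnings(stats::cor(g$dosage[, i], g$dosage[, j])^2)
        if (is.finite(r2)) expect_lt(r2, 0.1)
      }
    }
  }
})

test_that("kinship matrix has unit-scale diagonal and detects duplicates", {
  sim <- simulate_genotypes(n_pops = 1, pop_sizes = 30, n_snps = 1000,
                            fst = 0, seed = 23)
  g <- sim$genotypes
  g$dosage[2, ] <- g$dosage[1, ]  # identical accessions
  K <- kinship_matrix(g)
  expect_true(isSymmetric(K))
  expect_equal(K[1, 2], K[1, 1])
  expect_equal(K[1, 2], K[2, 2])
  expect_lt(abs(mean(diag(K)) - 1), 0.05)
  # unrelated accessions: off-diagonals near zero
  off <- K[upper.tri(K)][-1]
  expect_lt(max(abs(off)), 0.15)
})
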