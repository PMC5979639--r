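test_that("variant filters apply call-rate, mean-depth and MAF rules in order", {
  # 20 individuals; 4 SNPs engineered to each trip one rule
  n <- 20
  d <- matrix(1L, n, 4)
  d[, 1] <- rep(c(0L, 1L), each = 10)               # fine (MAF .25, full call)
  d[1:3, 2] <- NA_integer_                          # call rate 17/20 = .85
  d[, 3] <- c(1L, rep(0L, n - 1))                   # alt freq 1/40 = .025
  d[, 4] <- rep(c(0L, 2L), each = 10)               # fine
  dp <- matrix(50L, n, 4)
  dp[, 4] <- 150L                                   # mean depth above 100
  g <- toy_genotypes(d, depth = dp)

  fv <- filter_variants(g, filter_params(min_genotype_depth = NULL))
  expect_equal(fv$counts$removed, c(1L, 1L, 1L))
  expect_equal(fv$genotypes$variants$id, "s1")

  # idempotence
  fv2 <- filter_variants(fv$genotypes, filter_params(min_genotype_depth = NULL))
  expect_equal(sum(fv2$counts$removed), 0L)

  # no-op matrix passes unchanged, and MAF exactly at the bound is retained
  d3 <- matrix(rep(c(0L, 1L), 10), 20, 2)           # MAF .25
  d3[, 2] <- c(1L, 1L, rep(0L, 18))                 # alt freq 2/40 = 0.05
  g3 <- toy_genotypes(d3)
  fv3 <- filter_variants(g3, filter_params())
  expect_equal(ncol(fv3$genotypes$dosage), 2L)

  # everything removed is an explicit error
  g4 <- toy_genotypes(matrix(c(1L, rep(0L, 39)), 20, 2))
  expect_error(filter_variants(g4, filter_params()), "all variants removed")
})

test_that("HWE exact p-values match hand-enumerated cases", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 2, 0), 1.0)
  expect_equal(hwe_exact_test(5, 0, 0), 1.0)   # monomorphic: no test
  expect_error(hwe_exact_test(0, 0, 0), "no genotypes")
  # enumerated probabilities are a distribution
  pr <- urbanpopgen:::hwe_het_probs(25, 20)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})

test_that("HWE filter uses the reference site only", {
  # 10 reference + 10 other individuals, 2 SNPs
  # SNP1: ROU in exact HWE; MNO wildly out -> must be retained
  # SNP2: ROU all-het out of HWE -> removed
  rou <- cbind(c(rep(0L, 3), rep(1L, 4), rep(2L, 3)), rep(1L, 10))
  mno <- cbind(c(rep(0L, 5), rep(2L, 5)), c(rep(0L, 5), rep(2L, 5)))
  g <- toy_genotypes(rbind(rou, mno))
  samples <- tibble::tibble(
    id = g$samples, site = rep(c("ROU", "MNO"), each = 10),
    lat = 43, lon = 3, urb_nest = rep(c(-1.9, 2.3), each = 10),
    urb_site = rep(c(-1.9, 2.3), each = 10))
  out <- filter_hwe(g, samples, filter_params(hwe_alpha = 0.05))
  expect_equal(out$genotypes$variants$id, "s1")
  expect_equal(out$n_removed, 1L)
  # absent reference site is a configuration error
  expect_error(
    filter_hwe(g, samples, filter_params(hwe_reference_site = "XXX")),
    "reference site")
})

test_that("individual call-rate filter removes incomplete individuals", {
  d <- matrix(0L, 4, 100)
  d[2, 1:6] <- NA_integer_                 # 94% call rate
  g <- toy_genotypes(d)
  out <- filter_individuals(g, filter_params())
  expect_equal(out$removed, "ind_2")
  expect_equal(nrow(out$genotypes$dosage), 3L)
  # complete data: identity
  out2 <- filter_individuals(out$genotypes, filter_params())
  expect_length(out2$removed, 0)
})
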