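test_that("observed heterozygosity is the heterozygous fraction of called genotypes", {
  g <- toy_genotypes(rbind(c(0L, 1L, 2L, 1L),
                           c(0L, 0L, 2L, 2L),
                           c(NA, 1L, NA, 0L)))
  het <- observed_het(g)
  expect_equal(het$ho, c(0.5, 0, 0.5))
  # fully missing individuals are excluded with a warning
  g$dosage[3, ] <- NA_integer_
  expect_warning(het2 <- observed_het(g), "ind_3")
  expect_equal(nrow(het2), 2L)
})

test_that("IBS is the allele-sharing fraction over shared non-missing SNPs", {
  g <- toy_genotypes(rbind(a = c(0L, 1L), b = c(1L, 1L), c = c(2L, 2L)),
                     pos = c(100, 200))
  g$samples <- c("a", "b", "c"); rownames(g$dosage) <- g$samples
  ibs <- ibs_matrix(g)
  expect_equal(ibs["a", "b"], 0.75)          # (1-1/2 + 1-0)/2
  expect_equal(ibs["a", "c"], 0.25)          # (0 + 1/2)/2
  expect_equal(diag(ibs), c(a = 1, b = 1, c = 1))
  expect_true(isSymmetric(unclass(ibs)))
  # identical vectors -> 1; opposite homozygotes -> 0
  g2 <- toy_genotypes(rbind(rep(0L, 4), rep(0L, 4), rep(2L, 4)))
  ibs2 <- ibs_matrix(g2)
  expect_equal(ibs2[1, 2], 1)
  expect_equal(ibs2[1, 3], 0)
  # missingness: IBS computed on the shared subset only
  g3 <- toy_genotypes(rbind(c(0L, NA, 2L), c(0L, 1L, 0L)))
  expect_equal(ibs_matrix(g3)[1, 2], (1 + 0) / 2)
})

test_that("relative pruning is greedy, deterministic, and chain-aware", {
  ids <- c("A", "B", "C", "D")
  m <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(m) <- 1
  # chain: A-B and B-C above threshold, A-C below -> only B removed
  m["A", "B"] <- m["B", "A"] <- 0.85
  m["B", "C"] <- m["C", "B"] <- 0.85
  class(m) <- c("ibs_matrix", class(m))
  pr <- prune_related(m, 0.80)
  expect_equal(pr$removed, "B")
  expect_setequal(pr$kept, c("A", "C", "D"))
  # isolated pair: exactly one removed, tie broken by call rate then id
  m2 <- matrix(0.5, 4, 4, dimnames = list(ids, ids)); diag(m2) <- 1
  m2["C", "D"] <- m2["D", "C"] <- 0.9
  pr2 <- prune_related(m2, 0.80, call_rate = c(A = 1, B = 1, C = 0.99, D = 0.95))
  expect_equal(pr2$removed, "D")
  # no pair above threshold: identity
  expect_length(prune_related(m2, 0.95)$removed, 0)
  # invariant: no retained pair above threshold (random matrices)
  set.seed(1)
  for (i in 1:20) {
    n <- 8
    mm <- matrix(stats::runif(n * n, 0.6, 0.95), n, n)
    mm <- (mm + t(mm)) / 2; diag(mm) <- 1
    dimnames(mm) <- list(letters[1:n], letters[1:n])
    kept <- prune_related(mm, 0.80)$kept
    sub <- mm[kept, kept, drop = FALSE]; diag(sub) <- 0
    expect_true(all(sub <= 0.80))
  }
})

test_that("planted sibling pairs exceed the 0.80 IBS pruning threshold", {
  sim <- cached("family42", function() make_fixture("family"))
  ibs <- ibs_matrix(sim$genotypes)
  pr <- prune_related(ibs, 0.80)
  # two sibling pairs per site were planted in slots 1-4 of each site
  expect_gte(length(pr$removed), 10)
  site_of <- sim$samples$site[match(rownames(ibs), sim$samples$id)]
  for (s in unique(site_of)) {
    idx <- which(site_of == s)
    sibs <- ibs[idx[1], idx[2]]          # first planted pair
    expect_gt(sibs, 0.80)
  }
})

test_that("group comparison returns ANOVA, Tukey pairs and a letter display", {
  set.seed(2)
  v <- c(rnorm(30, 0), rnorm(30, 3), rnorm(30, 3.1))
  gl <- rep(c("x", "y", "z"), each = 30)
  cmp <- group_compare(v, gl)
  expect_gt(cmp$f, 50)
  expect_lt(cmp$p, 1e-10)
  expect_equal(nrow(cmp$tukey), 3)
  # x differs from y and z; y and z share a letter
  expect_false(cmp$letters[["x"]] == cmp$letters[["y"]])
  expect_true(any(strsplit(cmp$letters[["y"]], "")[[1]] %in%
                    strsplit(cmp$letters[["z"]], "")[[1]]))
  # two groups: F equals the squared two-sample t statistic
  v2 <- v[1:60]; g2 <- gl[1:60]
  cmp2 <- group_compare(v2, g2)
  tt <- t.test(v2 ~ g2, var.equal = TRUE)$statistic
  expect_equal(cmp2$f, unname(tt^2), tolerance = 1e-10)
})
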