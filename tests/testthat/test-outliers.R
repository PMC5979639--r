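test_that("uniform-kernel smoothing reproduces hand geometry", {
  # constant z: track constantly that value
  assoc <- tibble::tibble(chrom = "1", pos = seq(1e5, 2e6, by = 1e5), z = 2.5)
  tr <- smooth_zscores(assoc, window = 4e5, step = 1e5)
  expect_true(all(tr$z_smooth == 2.5))
  expect_equal(unique(diff(tr$pos)), 1e5)
  # single spike: elevated plateau exactly over grid points within window/2
  assoc2 <- tibble::tibble(chrom = "1", pos = seq(1e5, 2e6, by = 1e5),
                           z = c(rep(0, 9), 10, rep(0, 10)))
  spike_pos <- assoc2$pos[10]
  tr2 <- smooth_zscores(assoc2, window = 4e5, step = 1e5)
  elevated <- tr2$pos[tr2$z_smooth > 0]
  expect_true(all(abs(elevated - spike_pos) <= 2e5))
  expect_true(all(tr2$z_smooth[abs(tr2$pos - spike_pos) > 2e5] == 0))
  # conservation: total window-summed z equals the coverage-weighted sum of
  # per-SNP z (coverage counted by an explicit grid x SNP double loop)
  w <- vapply(assoc2$pos, function(ps)
    sum(abs(tr2$pos - ps) <= 2e5), numeric(1))
  expect_equal(sum(tr2$z_smooth * tr2$n_snps), sum(w * assoc2$z),
               tolerance = 1e-9)
  # a chromosome with no SNPs contributes no rows; window < step errors
  expect_error(smooth_zscores(assoc, window = 100, step = 1e5), "window")
})

test_that("outlier sets obey set algebra and inclusion-exclusion", {
  assoc <- tibble::tibble(
    test = rep(c("A", "B"), each = 4),
    id = rep(c("s1", "s2", "s3", "s4"), 2),
    q = c(.01, .02, .2, .9, .01, .6, .01, .9)
  )
  os <- outlier_sets(assoc, 0.05)
  expect_setequal(os$sets$A, c("s1", "s2"))
  expect_setequal(os$sets$B, c("s1", "s3"))
  expect_setequal(os$union, c("s1", "s2", "s3"))
  expect_equal(os$in_all, "s1")
  expect_equal(os$n_single, 2L)
  # Venn cells sum to the union size
  expect_equal(sum(os$venn$n_snps), length(os$union))
  # identical tests: intersection = union
  assoc2 <- dplyr::mutate(assoc, q = rep(c(.01, .9, .01, .9), 2))
  os2 <- outlier_sets(assoc2, 0.05)
  expect_setequal(os2$in_all, os2$union)
  # disjoint sets: union 3, no common outlier
  assoc3 <- tibble::tibble(test = c("A", "A", "B"), id = c("x", "y", "z"),
                           q = .01)
  os3 <- outlier_sets(assoc3, 0.05)
  expect_equal(length(os3$union), 3L)
  expect_length(os3$in_all, 0)
})

test_that("outlier-subset PCA r2 hits 1 when env is PC1 by construction", {
  set.seed(14)
  sim <- cached("medium17", function() {
    simulate_dataset(simulation_config(
      n_per_site = rep(8, 6), n_snps = 800, n_chromosomes = 4,
      chrom_lengths = rep(2.5e8, 4), causal_fraction = 0.02, beta_sd = 0.55,
      effect_dist = "fixed", family_pairs = c(GRA = 0), seed = 17))
  })
  g <- sim$genotypes
  pca <- genotype_pca(g[, 1:50], n_axes = 1)
  out <- suppressWarnings(   # lm warns about the (intended) perfect fit
    outlier_pca_r2(g, g$variants$id[1:50], env = pca$scores[, 1]))
  expect_equal(out$r2, 1, tolerance = 1e-10)
  expect_error(outlier_pca_r2(g, g$variants$id[1], rnorm(48)), ">= 2 SNPs")
  # axes = both uses PC1 + PC2
  out2 <- outlier_pca_r2(g, g$variants$id[1:50], sim$samples$urb_nest,
                         axes = "both")
  expect_gte(out2$r2, outlier_pca_r2(g, g$variants$id[1:50],
                                     sim$samples$urb_nest)$r2)
})

test_that("cumulative r2 curve: k = 1 closed form and full-set consistency", {
  sim <- cached("medium17", function() {
    simulate_dataset(simulation_config(
      n_per_site = rep(8, 6), n_snps = 800, n_chromosomes = 4,
      chrom_lengths = rep(2.5e8, 4), causal_fraction = 0.02, beta_sd = 0.55,
      effect_dist = "fixed", family_pairs = c(GRA = 0), seed = 17))
  })
  g <- sim$genotypes
  env <- sim$samples$urb_nest
  fit <- lfmm_associate(g, env, K = 1)
  ranking <- g$variants$id[order(-abs(fit$z))]
  cv <- cumulative_r2_curve(g, ranking, env, schedule = c(1, 10, 800),
                            n_random = 2, seed = 3)
  rk <- cv[cv$type == "ranked", ]
  # k = 1: squared correlation between env and the single top SNP
  top_snp <- g$dosage[, ranking[1]]
  expect_equal(rk$r2[rk$k == 1],
               cor(env, top_snp, use = "complete.obs")^2, tolerance = 1e-10)
  # k = p equals the full-set outlier PCA r2
  expect_equal(rk$r2[rk$k == 800],
               outlier_pca_r2(g, g$variants$id, env)$r2, tolerance = 1e-10)
  # schedule beyond the SNP count is truncated with a warning
  expect_warning(
    cumulative_r2_curve(g, ranking, env, schedule = c(10, 1e5), n_random = 1,
                        seed = 1), "truncated")
  expect_s3_class(autoplot(cv), "ggplot")
})
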