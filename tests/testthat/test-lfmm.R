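test_that("environment codings follow the six-test design", {
  samples <- tibble::tibble(
    id = paste0("i", 1:12),
    site = rep(c("ROU", "MNO", "ZOO"), each = 4),
    urb_nest = c(rnorm(4, -1.9, .1), rnorm(4, 2.3, .1), rnorm(4, -2.2, .1))
  ) |>
    dplyr::group_by(site) |>
    dplyr::mutate(urb_site = mean(urb_nest)) |>
    dplyr::ungroup()
  specs <- build_env_tests(samples, city_sites = c("MNO", "ZOO"),
                           forest_site = "ROU", excluded_site = "ZOO")
  expect_named(specs, c("A", "B", "C", "D", "E", "F"))
  # C: forest site coded 0, city sites coded 1
  expect_equal(unname(specs$C$env[samples$site == "ROU"]), rep(0, 4))
  expect_equal(unname(specs$C$env[paste0("i", 5:8)]), rep(1, 4))
  # D-F: ZOO individuals dropped from the design
  expect_false(any(paste0("i", 9:12) %in% specs$D$ids))
  expect_equal(specs$B$env[["i1"]], samples$urb_site[1])
  # single-site input refuses the contrasts B and C
  expect_warning(expect_warning(
    one <- build_env_tests(samples[samples$site == "ROU", ],
                           forest_site = "ROU", excluded_site = "ZOO"),
    "refused"), "refused")   # both the A-C and D-F contrasts are refused
  expect_false("B" %in% names(one))
})

test_that("ridge LFMM with K = 0 equals per-SNP OLS t-statistics", {
  set.seed(12)
  sim <- null_fixture()
  g <- sim$genotypes[, 1:300]
  env <- sim$samples$urb_nest
  fit <- lfmm_associate(g, env, K = 0, ridge_penalty = 0)
  t_ols <- apply(g$dosage, 2, function(col) {
    col <- as.numeric(col)
    col[is.na(col)] <- mean(col, na.rm = TRUE)
    summary(stats::lm(col ~ env))$coefficients[2, 3]
  })
  expect_equal(unname(fit$z), unname(t_ols), tolerance = 1e-8)
})

test_that("an infinite penalty on the latent block reduces to per-SNP regression", {
  sim <- null_fixture()
  g <- sim$genotypes[, 1:200]
  env <- sim$samples$urb_nest
  f0 <- lfmm_associate(g, env, K = 0, ridge_penalty = 0)
  fbig <- lfmm_associate(g, env, K = 2, ridge_penalty = 1e12)
  expect_equal(fbig$beta, f0$beta, tolerance = 1e-6)
})

test_that("ridge and Gibbs z-scores rank-agree on planted signal", {
  sim <- signal_fixture()
  keep <- unique(c(which(sim$truth$causal), seq_len(5000)))
  g <- sim$genotypes[, keep]
  env <- sim$samples$urb_nest
  fr <- lfmm_associate(g, env, K = 1)
  fg <- lfmm_associate(g, env, K = 1, method = "gibbs", runs = 2,
                       burn_in = 100, iterations = 400, seed = 5)
  expect_gt(cor(fr$z, fg$z, method = "spearman"), 0.9)
  # determinism of the sampler under a fixed seed
  fg2 <- lfmm_associate(g, env, K = 1, method = "gibbs", runs = 2,
                        burn_in = 100, iterations = 400, seed = 5)
  expect_identical(fg$z, fg2$z)
})

test_that("error paths: misaligned env, zero variance, K too large", {
  g <- toy_genotypes(matrix(rbinom(40, 2, .5), 4, 10))
  expect_error(lfmm_associate(g, rnorm(3), K = 0), "aligned")
  expect_error(lfmm_associate(g, rep(1, 4), K = 0), "zero variance")
  expect_error(lfmm_associate(g, rnorm(4), K = 4), "smaller")
})

test_that("q-value estimation: BH hand case, monotonicity, Storey pi0 on uniform p", {
  p <- c(rep(0.001, 10), rep(0.9, 90))
  q <- estimate_qvalues(p, method = "bh")
  expect_equal(q$q[1:10], rep(0.01, 10))
  expect_equal(q$pi0, 1)
  # storey with pi0 forced to 1 equals bh
  set.seed(13)
  p2 <- runif(5000)
  st <- estimate_qvalues(p2, method = "storey")
  bh <- estimate_qvalues(p2, method = "bh")
  expect_gt(st$pi0, 0.9)
  expect_lt(st$pi0, 1.1)
  # away from the clamp at 1, storey is exactly BH scaled by pi0
  o <- order(p2)
  low <- o[1:100]
  expect_equal(st$q[low], bh$q[low] * st$pi0, tolerance = 1e-12)
  # q monotone in p, bounded by 1
  expect_true(all(diff(st$q[o]) >= -1e-12))
  expect_true(all(st$q <= 1))
  expect_warning(estimate_qvalues(runif(50), method = "storey"), "fewer than 100")
})

test_that("run_all_tests is deterministic and returns one row per test x SNP", {
  sim <- cached("medium17", function() {
    simulate_dataset(simulation_config(
      n_per_site = rep(8, 6), n_snps = 800, n_chromosomes = 4,
      chrom_lengths = rep(2.5e8, 4), causal_fraction = 0.02, beta_sd = 0.55,
      effect_dist = "fixed", family_pairs = c(GRA = 0), seed = 17))
  })
  a1 <- run_all_tests(sim$genotypes, sim$samples, seed = 2, q_method = "bh")
  a2 <- run_all_tests(sim$genotypes, sim$samples, seed = 2, q_method = "bh")
  expect_equal(a1, a2)
  expect_equal(nrow(a1), 6 * 800)
  expect_equal(dplyr::n_distinct(a1$test), 6)
  info <- attr(a1, "test_info")
  expect_equal(info$test, LETTERS[1:6])
  expect_true(all(info$lambda > 0))
})
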