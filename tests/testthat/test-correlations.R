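test_that("LD decay: duplicated column gives r2 = 1 in its bin, null level ~ 1/n", {
  set.seed(16)
  n <- 50
  d <- matrix(rbinom(n * 40, 2, 0.5), n, 40)
  d[, 2] <- d[, 1]                       # perfect LD at distance 1000
  # the duplicated pair is the only one within the first bin (0, 2000]
  g <- toy_genotypes(d, pos = c(1000, 2000, seq(30000, by = 20000,
                                                length.out = 38)))
  ld <- ld_decay(g, max_distance = 2e4, bins = 10)
  expect_equal(ld$n_pairs[1], 1L)
  expect_equal(ld$mean_r2[1], 1, tolerance = 1e-12)
  # independent SNPs: mean r2 near 1/n
  d2 <- matrix(rbinom(n * 60, 2, 0.5), n, 60)
  g2 <- toy_genotypes(d2, pos = seq(1000, 60000, by = 1000))
  ld2 <- ld_decay(g2, max_distance = 3e4, bins = 5)
  pooled <- sum(ld2$mean_r2 * ld2$n_pairs) / sum(ld2$n_pairs)
  expect_lt(abs(pooled - 1 / n), 0.015)
  # single-SNP chromosome contributes no pairs
  g3 <- toy_genotypes(matrix(rbinom(n * 2, 2, .5), n, 2),
                      chrom = c("1", "2"), pos = c(100, 100))
  ld3 <- ld_decay(g3, max_distance = 1e4, bins = 2)
  expect_equal(sum(ld3$n_pairs), 0L)
})

test_that("gradient correlations recover engineered linear relationships", {
  set.seed(17)
  # six sites; Ho strictly linear in urbanization at the site level
  sites <- paste0("S", 1:6)
  urb <- c(2.3, 0.9, 0.7, -0.3, -1.9, -2.2)
  samples <- tibble::tibble(
    id = paste0("i", 1:30),
    site = rep(sites, each = 5),
    lat = rep(c(43.58, 43.60, 43.64, 43.62, 43.66, 43.64), each = 5),
    lon = rep(c(3.86, 3.83, 3.81, 3.93, 3.67, 3.88), each = 5),
    urb_nest = rep(urb, each = 5) + rnorm(30, 0, .05)
  ) |>
    dplyr::group_by(site) |>
    dplyr::mutate(urb_site = mean(urb_nest)) |>
    dplyr::ungroup()
  het <- tibble::tibble(id = samples$id,
                        ho = 0.30 - 0.002 * rep(urb, each = 5),
                        n_genotyped = 100L)
  fst <- tibble::tibble(site1 = rep(sites, 6)[upper.tri(diag(6))],
                        site2 = rep(sites, each = 6)[upper.tri(diag(6))],
                        theta = runif(15, 0.004, 0.009),
                        p_value = 0.001, n_snps_used = 1000L)
  rep_corr <- gradient_correlations(het, fst, NULL, samples)
  site_row <- rep_corr[rep_corr$response == "ho" & rep_corr$level == "site", ]
  expect_equal(site_row$r2, 1, tolerance = 1e-3)
  expect_lt(site_row$slope, 0)
  expect_equal(nrow(rep_corr), 4)   # ho x2, fst x2 (no IBS supplied)
  # fewer than 3 sites refuses the site-level regression
  small <- samples[samples$site %in% c("S1", "S2"), ]
  expect_error(
    gradient_correlations(het[1:10, ], fst[1, ], NULL, small), ">= 3 sites")
})

test_that("IBS regressions use individual pairs with haversine distances", {
  set.seed(18)
  samples <- tibble::tibble(
    id = c("a", "b", "c"), site = c("X", "X", "Y"),
    lat = c(43.60, 43.60, 43.70), lon = c(3.80, 3.80, 3.90),
    urb_nest = c(0, 0.1, 2), urb_site = c(0.05, 0.05, 2))
  het <- tibble::tibble(id = samples$id, ho = c(.29, .29, .28),
                        n_genotyped = 10L)
  ibs <- matrix(c(1, .8, .7, .8, 1, .72, .7, .72, 1), 3, 3,
                dimnames = list(samples$id, samples$id))
  fst <- NULL
  expect_error(gradient_correlations(het, fst, ibs, samples), ">= 3 sites")
  # with three sites it runs; check the IBS rows exist and n = 3 pairs
  samples2 <- dplyr::mutate(samples, site = c("X", "Y", "Z"),
                            urb_site = urb_nest)
  out <- gradient_correlations(het, fst, ibs, samples2)
  ibs_rows <- out[out$response == "ibs", ]
  expect_equal(nrow(ibs_rows), 2)
  expect_true(all(ibs_rows$n == 3))
})
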