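#' Configuration for the urban-gradient genotype simulator
#'
#' Defaults reproduce the shape of a six-site great tit sample from the
#' Montpellier urbanization gradient: 140 individuals in sites of very
#' unequal size, ~50k biallelic SNPs on 32 chromosomes (~1 Gb), genome-wide
#' differentiation around 0.007, a continuous urbanization score clustered
#' by site (site means from +2.32 down to -2.19), a small fraction of SNPs
#' whose allele frequencies follow the urbanization gradient, planted
#' full-sibling pairs within three sites, ~2% missing genotypes and
#' negative-binomial read depths (mean 72). A config plus a seed fully
#' determines the dataset.
#'
#' @param sites site labels.
#' @param n_per_site individuals per site.
#' @param urb_mean site mean urbanization scores (unitless PCA-score scale).
#' @param urb_sd within-site standard deviation of nest-level scores
#'   (0.62 reproduces the reported between/within-site variance ratio of
#'   the urbanization score, ANOVA F ~ 180 at the default design).
#' @param lat,lon site coordinates (decimal degrees).
#' @param n_snps number of biallelic SNPs.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_lengths chromosome lengths in bp (defaults to a decreasing
#'   karyotype summing to ~1 Gb).
#' @param fst target differentiation F* (total, cline + island components).
#' @param geo_share fraction of the neutral drift variance aligned with a
#'   longitudinal isolation-by-distance cline; the remainder is
#'   site-idiosyncratic Balding-Nichols drift. Makes the leading genetic
#'   axis geographic, as observed in wild urban-gradient samples.
#' @param causal_fraction fraction pi of SNPs with urbanization-driven
#'   allele-frequency clines.
#' @param beta_sd scale of the per-SNP cline effect (logit allele frequency
#'   per urbanization unit).
#' @param effect_dist `"normal"` draws `beta_j ~ N(0, beta_sd^2)`;
#'   `"fixed"` uses magnitude `beta_sd` with random sign (a tight effect
#'   distribution for power analyses).
#' @param family_pairs named integer vector: full-sibling pairs planted per
#'   site.
#' @param missing_rate per-genotype missingness probability.
#' @param depth_mean,depth_size negative-binomial read-depth model.
#' @param seed integer seed.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(
    sites = c("MNO", "FCO", "MOS", "GRA", "ROU", "ZOO"),
    n_per_site = c(18, 10, 5, 29, 47, 31),
    urb_mean = c(2.32, 0.87, 0.70, -0.31, -1.94, -2.19),
    urb_sd = 0.62,
    lat = c(43.586, 43.597, 43.637, 43.617, 43.664, 43.642),
    lon = c(3.862, 3.834, 3.812, 3.932, 3.668, 3.878),
    n_snps = 49969,
    n_chromosomes = 32,
    chrom_lengths = NULL,
    fst = 0.007,
    geo_share = 1 / 3,
    causal_fraction = 0.005,
    beta_sd = 0.55,
    effect_dist = c("normal", "fixed"),
    family_pairs = c(GRA = 3, ZOO = 6, ROU = 6),
    missing_rate = 0.02,
    depth_mean = 72,
    depth_size = 3.5,
    seed = 1) {
  effect_dist <- match.arg(effect_dist)
  stopifnot(length(n_per_site) == length(sites),
            length(urb_mean) == length(sites),
            fst > 0, fst < 1, geo_share >= 0, geo_share <= 1,
            causal_fraction >= 0, causal_fraction <= 1,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(chrom_lengths)) {
    w <- (n_chromosomes:1)^1.3
    chrom_lengths <- round(1.0e9 * w / sum(w))
  }
  stopifnot(length(chrom_lengths) == n_chromosomes, all(chrom_lengths > 0))
  structure(
    list(sites = sites, n_per_site = n_per_site, urb_mean = urb_mean,
         urb_sd = urb_sd, lat = lat, lon = lon, n_snps = n_snps,
         n_chromosomes = n_chromosomes, chrom_lengths = chrom_lengths,
         fst = fst, geo_share = geo_share,
         causal_fraction = causal_fraction, beta_sd = beta_sd,
         effect_dist = effect_dist,
         family_pairs = family_pairs, missing_rate = missing_rate,
         depth_mean = depth_mean, depth_size = depth_size, seed = seed),
    class = "sim_config"
  )
}

#' Simulate an urban-gradient genotype dataset
#'
#' Neutral SNPs combine two drift components totalling the target F*:
#' a longitude-aligned isolation-by-distance cline (share `geo_share`),
#' which makes the leading axis of genetic structure geographic the way it
#' is in wild urban-gradient samples, and site-idiosyncratic
#' Balding-Nichols drift (share `1 - geo_share`): ancestral frequency
#' `p0 ~ Uniform(0.1, 0.9)`, island component
#' `p_s ~ Beta(p0 (1 - Fi) / Fi, (1 - p0)(1 - Fi) / Fi)`, cline shift
#' `delta_j * lon_std_s` on the logit scale, genotypes `Binomial(2, p_s)`.
#' Causal SNPs (fraction pi) instead get deterministic clines
#' `logit(p_s) = logit(p0) + beta_j * u_s` with `u_s` the site urbanization
#' mean — the association target is allele frequency versus urbanization,
#' matching a gene-environment association design. Planted families are full-sibling
#' pairs (two offspring of two latent parents drawn from the site
#' frequencies, replacing two simulated individuals), nest scores are
#' site mean plus noise, missingness is uniform, depths negative-binomial.
#' SNPs are unlinked given site frequencies.
#'
#' @param config a [simulation_config()].
#' @return A list of class `sim_dataset`: `genotypes`
#'   ([genotype_matrix()]), `samples` (sample tibble), `truth` (per-SNP
#'   tibble with `id`, `causal`, `beta`, `p0` and per-site frequencies).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  local_seed(config$seed)
  S <- length(config$sites)
  n <- sum(config$n_per_site)
  p <- config$n_snps
  site_of <- rep(config$sites, config$n_per_site)
  ids <- sprintf("%s_%02d", site_of, unlist(lapply(config$n_per_site, seq_len)))

  # variant coordinates: uniform over a decreasing karyotype
  chrom_names <- as.character(seq_len(config$n_chromosomes))
  n_per_chrom <- stats::rmultinom(
    1, p, config$chrom_lengths / sum(config$chrom_lengths))[, 1]
  chrom <- rep(chrom_names, n_per_chrom)
  pos <- unlist(lapply(seq_len(config$n_chromosomes), function(k) {
    sort(sample.int(config$chrom_lengths[k], n_per_chrom[k]))
  }))

  # site allele frequencies
  p0 <- stats::runif(p, 0.1, 0.9)
  n_causal <- round(config$causal_fraction * p)
  causal <- rep(FALSE, p)
  causal[sample.int(p, n_causal)] <- TRUE
  beta <- ifelse(causal,
                 if (config$effect_dist == "fixed")
                   config$beta_sd * sample(c(-1, 1), p, replace = TRUE)
                 else stats::rnorm(p, 0, config$beta_sd),
                 0)
  fstar <- config$fst
  # neutral drift: a longitude-aligned cline (share geo_share of F*) plus
  # site-idiosyncratic Balding-Nichols drift (share 1 - geo_share); the
  # per-SNP cline effect delta_j is scaled by 1/(p0 q0) so every SNP's
  # cline component contributes geo_share * F* to its differentiation
  lon_std <- if (stats::sd(config$lon) > 0)
    (config$lon - mean(config$lon)) / stats::sd(config$lon) else rep(0, S)
  f_island <- (1 - config$geo_share) * fstar
  delta <- stats::rnorm(p, 0, sqrt(config$geo_share * fstar / (p0 * (1 - p0))))
  freq <- matrix(0, S, p)
  for (s in seq_len(S)) {
    a <- p0 * (1 - f_island) / f_island
    b <- (1 - p0) * (1 - f_island) / f_island
    freq[s, ] <- stats::plogis(
      stats::qlogis(stats::rbeta(p, a, b)) + delta * lon_std[s])
    if (any(causal))
      freq[s, causal] <- stats::plogis(
        stats::qlogis(p0[causal]) + beta[causal] * config$urb_mean[s])
  }
  # numerical guard: keep frequencies strictly inside (0,1)
  freq <- pmin(pmax(freq, 1e-6), 1 - 1e-6)

  dosage <- matrix(0L, n, p)
  for (s in seq_len(S)) {
    rows <- which(site_of == config$sites[s])
    dosage[rows, ] <- stats::rbinom(length(rows) * p, 2,
                                    rep(freq[s, ], each = length(rows)))
  }

  # planted full-sibling pairs: two offspring of two latent parents
  for (s in names(config$family_pairs)) {
    k <- config$family_pairs[[s]]
    if (k == 0) next
    rows <- which(site_of == s)
    if (length(rows) < 2 * k)
      stop("site ", s, " too small for ", k, " sibling pairs", call. = FALSE)
    slots <- rows[seq_len(2 * k)]
    fs <- freq[match(s, config$sites), ]
    for (fam in seq_len(k)) {
      par1 <- stats::rbinom(p, 2, fs)
      par2 <- stats::rbinom(p, 2, fs)
      for (o in 1:2) {
        child <- stats::rbinom(p, 1, par1 / 2) + stats::rbinom(p, 1, par2 / 2)
        dosage[slots[2 * (fam - 1) + o], ] <- child
      }
    }
  }

  depth <- matrix(stats::rnbinom(n * p, mu = config$depth_mean,
                                 size = config$depth_size), n, p)
  miss <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
  dosage[miss] <- NA_integer_

  bases <- c("A", "C", "G", "T")
  ref_idx <- sample.int(4, p, replace = TRUE)
  alt_idx <- ((ref_idx - 1 + sample.int(3, p, replace = TRUE)) %% 4) + 1
  variants <- tibble::tibble(
    chrom = chrom, pos = as.integer(pos),
    ref = bases[ref_idx], alt = bases[alt_idx],
    id = paste0(chrom, "_", pos)
  )
  g <- genotype_matrix(dosage, variants, samples = ids, depth = depth)

  samples <- tibble::tibble(
    id = ids,
    site = site_of,
    lat = config$lat[match(site_of, config$sites)] +
      stats::rnorm(n, 0, 0.002),
    lon = config$lon[match(site_of, config$sites)] +
      stats::rnorm(n, 0, 0.002),
    urb_nest = config$urb_mean[match(site_of, config$sites)] +
      stats::rnorm(n, 0, config$urb_sd)
  ) |>
    dplyr::group_by(.data$site) |>
    dplyr::mutate(urb_site = mean(.data$urb_nest)) |>
    dplyr::ungroup()

  truth <- dplyr::bind_cols(
    tibble::tibble(id = variants$id, causal = causal, beta = beta, p0 = p0),
    tibble::as_tibble(stats::setNames(
      as.data.frame(t(freq)), paste0("freq_", config$sites)))
  )
  structure(list(genotypes = g, samples = samples, truth = truth,
                 config = config),
            class = "sim_dataset")
}

#' Canned simulation fixtures
#'
#' Four seeded configurations used throughout the package's tests and
#' examples:
#' \describe{
#'   \item{tiny}{2 sites x 4 individuals, 40 SNPs on 2 chromosomes; small
#'     enough to check every statistic by hand.}
#'   \item{null}{6 sites x 20 individuals, 20k SNPs, F* = 0.007, no causal
#'     SNPs, no families: the calibration dataset.}
#'   \item{signal}{as `null` plus 0.5% causal SNPs with clearly
#'     detectable clines of fixed magnitude (|beta| = 0.55): the power
#'     dataset.}
#'   \item{family}{6 sites x 20 individuals, 5k SNPs, two full-sibling
#'     pairs planted per site.}
#' }
#'
#' @param name one of `"tiny"`, `"null"`, `"signal"`, `"family"`.
#' @param dir optional directory; when given, the dataset is also written
#'   as `genotypes.vcf`, `samples.tsv` and `truth.tsv`.
#' @param seed integer seed.
#' @return A `sim_dataset` list (see [simulate_dataset()]).
#' @export
make_fixture <- function(name = c("tiny", "null", "signal", "family"),
                         dir = NULL, seed = 42) {
  name <- match.arg(name)
  cfg <- switch(
    name,
    tiny = simulation_config(
      sites = c("ROU", "MNO"), n_per_site = c(4, 4),
      urb_mean = c(-1.94, 2.32), lat = c(43.664, 43.586),
      lon = c(3.668, 3.862), n_snps = 40, n_chromosomes = 2,
      chrom_lengths = c(2e6, 1e6), causal_fraction = 0,
      family_pairs = c(ROU = 0), missing_rate = 0.05, seed = seed),
    null = simulation_config(
      n_per_site = rep(20, 6), n_snps = 20000, causal_fraction = 0,
      family_pairs = c(GRA = 0), seed = seed),
    signal = simulation_config(
      n_per_site = rep(20, 6), n_snps = 20000, causal_fraction = 0.005,
      beta_sd = 0.55, effect_dist = "fixed",
      family_pairs = c(GRA = 0), seed = seed),
    family = simulation_config(
      n_per_site = rep(20, 6), n_snps = 5000, causal_fraction = 0,
      family_pairs = c(MNO = 2, FCO = 2, MOS = 2, GRA = 2, ROU = 2, ZOO = 2),
      seed = seed)
  )
  sim <- simulate_dataset(cfg)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(sim$genotypes, file.path(dir, "genotypes.vcf"))
    readr::write_tsv(sim$samples, file.path(dir, "samples.tsv"))
    readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  }
  sim
}
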