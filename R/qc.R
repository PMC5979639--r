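#' Genotype and variant quality-control parameters
#'
#' Default values reproduce a RAD-seq SNP filtering scheme for a six-site
#' urban-gradient sample: per-genotype depth >= 8 reads, variant call rate
#' >= 90% across all individuals pooled, mean depth across non-missing
#' genotypes within \[20, 100\] reads, pooled minor allele frequency >= 0.05,
#' Hardy-Weinberg exact-test p >= 0.01 computed in a single reference
#' (rural) site only, and per-individual call rate >= 95%.
#'
#' @param min_genotype_depth reads; genotypes below are masked missing.
#' @param min_call_rate_variant fraction of individuals genotyped per SNP.
#' @param min_mean_depth,max_mean_depth reads; bounds on a SNP's mean depth.
#' @param min_maf pooled minor allele frequency (inclusive bound).
#' @param hwe_alpha significance level of the exact Hardy-Weinberg test.
#' @param hwe_reference_site site label in which HWE is tested.
#' @param min_call_rate_individual fraction of loci genotyped per individual.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_genotype_depth = 8L,
                          min_call_rate_variant = 0.90,
                          min_mean_depth = 20,
                          max_mean_depth = 100,
                          min_maf = 0.05,
                          hwe_alpha = 0.01,
                          hwe_reference_site = "ROU",
                          min_call_rate_individual = 0.95) {
  stopifnot(
    min_call_rate_variant >= 0, min_call_rate_variant <= 1,
    min_maf >= 0, min_maf <= 1,
    hwe_alpha >= 0, hwe_alpha <= 1,
    min_call_rate_individual >= 0, min_call_rate_individual <= 1,
    min_mean_depth <= max_mean_depth
  )
  structure(
    list(min_genotype_depth = min_genotype_depth,
         min_call_rate_variant = min_call_rate_variant,
         min_mean_depth = min_mean_depth,
         max_mean_depth = max_mean_depth,
         min_maf = min_maf,
         hwe_alpha = hwe_alpha,
         hwe_reference_site = hwe_reference_site,
         min_call_rate_individual = min_call_rate_individual),
    class = "filter_params"
  )
}

#' Variant-level quality filters
#'
#' Applies, in order: per-genotype depth masking (when depths are present),
#' call rate, mean depth window (skipped without depths), and pooled MAF.
#' MAF is computed after masking, over all individuals from all sites
#' grouped; the bound is inclusive (a SNP at exactly `min_maf` is kept).
#' The returned counts make the accounting reproducible. Idempotent: running
#' the filters on already-filtered data removes nothing.
#'
#' @param x a [genotype_matrix()].
#' @param params a [filter_params()] list.
#' @return A list with `genotypes` (the filtered matrix) and `counts`, a
#'   tibble with per-stage `removed` / `retained` variant counts.
#' @export
filter_variants <- function(x, params = filter_params()) {
  if (!is.null(x$depth) && !is.null(params$min_genotype_depth))
    x <- mask_low_depth(x, params$min_genotype_depth)
  stages <- tibble::tibble(stage = character(), removed = integer(),
                           retained = integer())
  note <- function(stage, keep) {
    stages <<- dplyr::bind_rows(
      stages,
      tibble::tibble(stage = stage, removed = sum(!keep), retained = sum(keep)))
  }

  vs <- variant_stats(x)
  keep <- vs$call_rate >= params$min_call_rate_variant
  note("call_rate", keep)
  x <- x[, keep]

  if (!is.null(x$depth)) {
    vs <- variant_stats(x)
    keep <- !is.na(vs$mean_depth) &
      vs$mean_depth >= params$min_mean_depth &
      vs$mean_depth <= params$max_mean_depth
    note("mean_depth", keep)
    x <- x[, keep]
  }

  vs <- variant_stats(x)
  keep <- !is.na(vs$maf) & vs$maf >= params$min_maf
  note("maf", keep)
  x <- x[, keep]

  if (ncol(x$dosage) == 0)
    stop("filter_variants: all variants removed", call. = FALSE)
  list(genotypes = x, counts = stages)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact two-sided p-value from the conditional distribution of the
#' heterozygote count given the allele counts: all heterozygote counts
#' compatible with the observed allele counts are enumerated and the
#' probabilities of configurations no more probable than the observed one
#' are summed. Monomorphic inputs return p = 1 (no test possible).
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return The exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("hwe_exact_test: no genotypes", call. = FALSE)
  n_A <- 2L * n_AA + n_Aa
  n_a <- 2L * n_aa + n_Aa
  if (n_A == 0L || n_a == 0L) return(1.0)
  probs <- hwe_het_probs(n, n_A)
  obs <- probs[as.character(n_Aa)]
  sum(probs[probs <= obs * (1 + 1e-12)])
}

# Conditional probabilities of each possible heterozygote count given
# n diploids and n_A copies of the A allele; names are heterozygote counts.
hwe_het_probs <- function(n, n_A) {
  n_a <- 2L * n - n_A
  rare <- min(n_A, n_a)
  hets <- seq.int(rare %% 2L, rare, by = 2L)
  lp <- lfactorial(n) - lfactorial((n_A - hets) / 2) - lfactorial(hets) -
    lfactorial((n_a - hets) / 2) + hets * log(2) +
    lfactorial(n_A) + lfactorial(n_a) - lfactorial(2L * n)
  probs <- exp(lp)
  names(probs) <- hets
  probs
}

#' Hardy-Weinberg filter in a reference site
#'
#' Removes variants whose exact HWE test, computed on the individuals of one
#' reference site only, has p below `hwe_alpha`. Other sites are never
#' tested: with small per-site samples and high gene flow, deviations caused
#' by genotyping artefacts are expected to be detectable in the largest,
#' least-urbanized site, while selection-driven differentiation between
#' sites is left untouched.
#'
#' @param x a [genotype_matrix()].
#' @param samples aligned sample tibble (see [align_samples()]).
#' @param params a [filter_params()] list.
#' @return A list with `genotypes` and `n_removed`.
#' @export
filter_hwe <- function(x, samples, params = filter_params()) {
  samples <- align_samples(samples, x)
  ref <- samples$id[samples$site == params$hwe_reference_site]
  if (length(ref) == 0)
    stop("reference site not present: ", params$hwe_reference_site, call. = FALSE)
  if (length(ref) < 2)
    stop("reference site has fewer than 2 individuals", call. = FALSE)
  d <- x$dosage[match(ref, x$samples), , drop = FALSE]
  n_AA <- colSums(d == 0L, na.rm = TRUE)
  n_Aa <- colSums(d == 1L, na.rm = TRUE)
  n_aa <- colSums(d == 2L, na.rm = TRUE)
  pvals <- vapply(seq_along(n_AA), function(j) {
    if (n_AA[j] + n_Aa[j] + n_aa[j] == 0) return(1.0)
    hwe_exact_test(n_AA[j], n_Aa[j], n_aa[j])
  }, numeric(1))
  keep <- pvals >= params$hwe_alpha
  list(genotypes = x[, keep], n_removed = sum(!keep))
}

#' Individual call-rate filter
#'
#' Removes individuals genotyped for fewer than
#' `min_call_rate_individual` of all loci.
#'
#' @param x a [genotype_matrix()].
#' @param params a [filter_params()] list.
#' @return A list with `genotypes` and `removed` (character ids).
#' @export
filter_individuals <- function(x, params = filter_params()) {
  ss <- sample_stats(x)
  keep <- ss$call_rate >= params$min_call_rate_individual
  list(genotypes = x[keep, ], removed = ss$id[!keep])
}
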