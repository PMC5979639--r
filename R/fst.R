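#' Weir-Cockerham variance components per SNP
#'
#' Method-of-moments variance components for differentiation between
#' populations of unequal size, computed from genotype counts: `a` (among
#' populations), `b` (among individuals within populations), `c` (within
#' individuals), and the per-SNP estimator `theta = a / (a + b + c)`. Groups
#' with no non-missing genotype at a SNP drop out of that SNP's estimate;
#' SNPs observed in fewer than two groups, or monomorphic across all groups
#' (zero total variance), get `NA` theta and are excluded from ratio-of-sums
#' aggregation downstream. Negative per-SNP estimates are retained, not
#' clamped: they are part of the estimator's sampling distribution.
#'
#' @param x a [genotype_matrix()].
#' @param groups site labels aligned to the matrix's individuals.
#' @return A tibble with one row per SNP: `id`, `chrom`, `pos`, `a`, `b`,
#'   `c`, `theta`.
#' @export
wc_fst_per_snp <- function(x, groups) {
  stopifnot(length(groups) == nrow(x$dosage))
  comp <- wc_components(x$dosage, groups)
  tibble::tibble(
    id = x$variants$id,
    chrom = x$variants$chrom,
    pos = x$variants$pos,
    a = unname(comp$a), b = unname(comp$b), c = unname(comp$c),
    theta = unname(comp$a / (comp$a + comp$b + comp$c))
  )
}

# Vectorized Weir & Cockerham (1984) components for biallelic SNPs.
# d: dosage matrix (individuals x SNPs), groups: labels. Returns per-SNP
# a, b, c (NA where the estimator is undefined).
wc_components <- function(d, groups) {
  groups <- as.character(groups)
  obs <- !is.na(d)
  d0 <- d
  d0[!obs] <- 0L
  storage.mode(d0) <- "double"
  n_i <- rowsum(obs * 1, groups)            # group x SNP sample sizes
  alt <- rowsum(d0, groups)
  het <- rowsum(((d == 1L) & obs) * 1, groups)
  present <- n_i > 0
  p_i <- ifelse(present, alt / (2 * n_i), 0)
  h_i <- ifelse(present, het / n_i, 0)

  r <- colSums(present)
  n_tot <- colSums(n_i)
  nbar <- n_tot / r
  nc <- (n_tot - colSums(n_i^2) / n_tot) / (r - 1)
  pbar <- colSums(n_i * p_i) / n_tot
  s2 <- colSums(n_i * (p_i - rep(pbar, each = nrow(p_i)))^2 * present) /
    ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / n_tot

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2

  undef <- r < 2 | nbar <= 1 | !is.finite(a)
  mono <- abs(a + b + c_) < .Machine$double.eps * 100
  a[undef] <- NA_real_; b[undef] <- NA_real_; c_[undef] <- NA_real_
  a[mono & !undef] <- NA_real_; b[mono & !undef] <- NA_real_
  c_[mono & !undef] <- NA_real_
  list(a = a, b = b, c = c_)
}

#' Pairwise FST between sites with permutation tests
#'
#' For each pair of sites, the multilocus estimator is the ratio of sums of
#' the per-SNP variance components, `theta = sum(a) / sum(a + b + c)`, over
#' SNPs with defined components. Significance is assessed by permuting
#' individuals between the two sites; the p-value uses the add-one
#' estimator `(1 + #{theta_perm >= theta_obs}) / (n_perm + 1)`.
#'
#' @param x a [genotype_matrix()].
#' @param groups site labels aligned to individuals.
#' @param n_perm number of permutations (0 skips testing).
#' @param seed integer seed making the permutations reproducible.
#' @return A tibble with one row per site pair: `site1`, `site2`, `theta`,
#'   `p_value`, `n_snps_used`.
#' @export
pairwise_fst <- function(x, groups, n_perm = 1000, seed = 1) {
  stopifnot(length(groups) == nrow(x$dosage))
  groups <- as.character(groups)
  sites <- sort(unique(groups))
  small <- names(which(table(groups) < 2))
  if (length(small)) {
    warning("pairwise_fst: site(s) with < 2 individuals skipped: ",
            paste(small, collapse = ", "))
    sites <- setdiff(sites, small)
  }
  pairs <- utils::combn(sites, 2, simplify = FALSE)
  rng <- local_seed(seed)

  ratio_of_sums <- function(d, g) {
    comp <- wc_components(d, g)
    ok <- !is.na(comp$a)
    list(theta = sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok]),
         n = sum(ok))
  }

  res <- purrr::map_dfr(pairs, function(pr) {
    idx <- which(groups %in% pr)
    d <- x$dosage[idx, , drop = FALSE]
    g <- groups[idx]
    obs <- ratio_of_sums(d, g)
    p <- NA_real_
    if (n_perm > 0) {
      hits <- 0L
      for (b in seq_len(n_perm)) {
        gp <- sample(g)
        if (ratio_of_sums(d, gp)$theta >= obs$theta) hits <- hits + 1L
      }
      p <- (1 + hits) / (n_perm + 1)
    }
    tibble::tibble(site1 = pr[1], site2 = pr[2], theta = obs$theta,
                   p_value = p, n_snps_used = obs$n)
  })
  res
}

#' Reshape pairwise FST to a labeled square matrix
#'
#' @param fst tibble from [pairwise_fst()].
#' @param value which column to spread (`"theta"` or `"p_value"`).
#' @return A symmetric matrix with `NA` diagonal.
#' @export
fst_matrix <- function(fst, value = c("theta", "p_value")) {
  value <- match.arg(value)
  sites <- sort(unique(c(fst$site1, fst$site2)))
  m <- matrix(NA_real_, length(sites), length(sites),
              dimnames = list(sites, sites))
  for (k in seq_len(nrow(fst))) {
    m[fst$site1[k], fst$site2[k]] <- fst[[value]][k]
    m[fst$site2[k], fst$site1[k]] <- fst[[value]][k]
  }
  m
}

# Set the RNG seed inside the caller's frame without clobbering the global
# RNG state after the call exits.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  set.seed(seed)
  withr::defer({
    if (has_old) assign(".Random.seed", old, globalenv())
  }, envir = env)
  invisible(NULL)
}
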