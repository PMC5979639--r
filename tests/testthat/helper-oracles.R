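# Shared fixtures (memoised: the expensive simulated datasets are built once
# per test run) and independent oracle implementations used to cross-check
# the package's estimators.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, fun) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fun(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

toy_genotypes <- function(dosage, chrom = NULL, pos = NULL, depth = NULL) {
  p <- ncol(dosage)
  genotype_matrix(
    dosage,
    variants = tibble::tibble(
      chrom = if (is.null(chrom)) rep("1", p) else chrom,
      pos = if (is.null(pos)) seq_len(p) * 100L else as.integer(pos),
      ref = "A", alt = "T", id = paste0("s", seq_len(p))),
    depth = depth
  )
}

# ---- Weir-Cockerham (1984) oracle --------------------------------------
# Scalar, per-SNP, straight from the published moment equations; written
# independently of the vectorized implementation in R/fst.R.
wc_oracle_snp <- function(geno, groups) {
  keep <- !is.na(geno)
  geno <- geno[keep]
  groups <- as.character(groups[keep])
  labs <- unique(groups)
  r <- length(labs)
  if (r < 2) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  n_i <- p_i <- h_i <- numeric(r)
  for (k in seq_len(r)) {
    gk <- geno[groups == labs[k]]
    n_i[k] <- length(gk)
    p_i[k] <- sum(gk) / (2 * length(gk))
    h_i[k] <- mean(gk == 1)
  }
  nbar <- mean(n_i)
  if (nbar <= 1) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (abs(a + b + cc) < 1e-12) return(c(a = NA_real_, b = NA_real_, c = NA_real_))
  c(a = a, b = b, c = cc)
}

# ---- HWE exact-test oracle ---------------------------------------------
# Exhaustive enumeration of genotype-count vectors: every (nAA, nAa, naa)
# compatible with the observed allele counts is listed explicitly and
# weighted by its number of ordered allele arrangements (n! multinomial
# times 2^het).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  if (n_A == 0 || n_A == 2 * n) return(1.0)
  configs <- expand.grid(AA = 0:n, Aa = 0:n)
  configs$aa <- n - configs$AA - configs$Aa
  configs <- configs[configs$aa >= 0 & 2 * configs$AA + configs$Aa == n_A, ]
  w <- apply(configs, 1, function(k) {
    exp(lfactorial(n) - lfactorial(k["AA"]) - lfactorial(k["Aa"]) -
          lfactorial(k["aa"]) + k["Aa"] * log(2))
  })
  probs <- w / sum(w)
  obs <- probs[configs$Aa == n_Aa]
  sum(probs[probs <= obs + 1e-12])
}

# ---- RDA oracle ---------------------------------------------------------
# Plain regression + eigendecomposition, independent of vegan.
rda_oracle <- function(Y, X, Z = NULL) {
  Y <- scale(as.matrix(Y), scale = FALSE)
  X <- scale(as.matrix(X), scale = FALSE)
  if (!is.null(Z)) {
    Z <- scale(as.matrix(Z), scale = FALSE)
    Y <- stats::resid(stats::lm.fit(Z, Y))
    X <- stats::resid(stats::lm.fit(Z, X))
  }
  fitted <- X %*% solve(crossprod(X), crossprod(X, Y))
  eig <- eigen(crossprod(fitted), symmetric = TRUE, only.values = TRUE)$values
  eig <- eig[eig > 1e-9]
  tot <- sum(scale(as.matrix(Y), scale = FALSE)^2)
  list(prop = eig / tot, constrained_prop = sum(eig) / tot)
}

# Shared medium-size datasets -------------------------------------------
null_fixture <- function() cached("null42", function() make_fixture("null"))
signal_fixture <- function() cached("signal42", function() make_fixture("signal"))
signal_fit <- function() cached("signal42_fit", function() {
  sim <- signal_fixture()
  lfmm_associate(sim$genotypes, sim$samples$urb_nest, K = 1)
})
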