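#' Build the six urbanization environment codings
#'
#' Urbanization can act at several spatial scales, so association tests are
#' run under six codings: (A) the nest-level urbanization score, (B) the
#' site-mean score, (C) a binary contrast between the rural forest site
#' (coded 0) and the city sites (coded 1); and (D, E, F) the same three with
#' one semi-natural site (by default the zoo) removed from the design —
#' its individuals are re-projected in downstream outlier PCAs.
#'
#' @param samples sample tibble (`id`, `site`, `urb_nest`, `urb_site`).
#' @param city_sites sites coded 1 in the binary tests; defaults to every
#'   site except `forest_site`.
#' @param forest_site the rural reference site (coded 0).
#' @param excluded_site site dropped from the design in tests D-F.
#' @return A named list of six specs, each with `test`, `ids`, `env`,
#'   `excluded`.
#' @export
build_env_tests <- function(samples, city_sites = NULL, forest_site = "ROU",
                            excluded_site = "ZOO") {
  if (is.null(city_sites))
    city_sites <- setdiff(unique(samples$site), forest_site)
  miss <- is.na(samples$urb_nest)
  if (any(miss)) {
    warning("build_env_tests: dropped individual(s) with missing urbanization: ",
            paste(samples$id[miss], collapse = ", "))
    samples <- samples[!miss, ]
  }
  n_sites <- dplyr::n_distinct(samples$site)
  spec <- function(test, tab, env, excluded) {
    list(test = test, ids = tab$id,
         env = stats::setNames(env, tab$id), excluded = excluded)
  }
  make3 <- function(tab, suffix_tests, excluded) {
    out <- list()
    out[[suffix_tests[1]]] <- spec(suffix_tests[1], tab, tab$urb_nest, excluded)
    if (dplyr::n_distinct(tab$site) >= 2) {
      out[[suffix_tests[2]]] <- spec(suffix_tests[2], tab, tab$urb_site, excluded)
      binary <- ifelse(tab$site == forest_site, 0,
                       ifelse(tab$site %in% city_sites, 1, NA_real_))
      keep <- !is.na(binary)
      out[[suffix_tests[3]]] <- spec(suffix_tests[3], tab[keep, ],
                                     binary[keep], excluded)
    } else {
      warning("tests ", suffix_tests[2], "/", suffix_tests[3],
              " refused: only one site present")
    }
    out
  }
  out <- make3(samples, c("A", "B", "C"), character(0))
  tab_noex <- samples[samples$site != excluded_site, ]
  out <- c(out, make3(tab_noex, c("D", "E", "F"), excluded_site))
  out
}

#' Latent factor mixed model association
#'
#' Fits `G = U V' + x b' + E` with `K` latent factors absorbing population
#' structure while `b_j` measures each SNP's association with the
#' environmental variable.
#'
#' The default `"ridge"` method is deterministic and spectral: latent factor
#' scores are the top `K` left singular vectors of the genotype matrix
#' residualized on the environment, effects come from a ridge-penalized
#' joint regression on the environment and the factors (penalty on the
#' latent block only), and z-scores are the effect over its standard error.
#' With `K = 0` this reduces exactly to per-SNP ordinary least squares.
#' The `"gibbs"` method runs a conjugate Gibbs sampler on the same model
#' (normal priors on factors and effects, inverse-gamma on per-SNP residual
#' variances); z-scores are posterior mean over posterior standard deviation
#' of `b_j`, averaged over independent runs.
#'
#' P-values are genomic-inflation calibrated: `z^2 / lambda` is referred to
#' a 1-df chi-square, with `lambda = median(z^2) / qchisq(0.5, 1)`.
#'
#' @param x a [genotype_matrix()] (or plain dosage matrix).
#' @param env numeric environmental vector aligned to individuals.
#' @param K number of latent factors (>= 0).
#' @param method `"ridge"` or `"gibbs"`.
#' @param runs independent Gibbs runs averaged (gibbs only).
#' @param burn_in,iterations Gibbs chain lengths (gibbs only).
#' @param seed integer seed (gibbs only; ridge is deterministic).
#' @param ridge_penalty penalty on the latent-factor coefficients.
#' @return An object of class `lfmm_fit` with per-SNP `beta`, `se`, `z`,
#'   `p`, the factor scores `U`, loadings `V`, inflation factor `lambda`.
#' @export
lfmm_associate <- function(x, env, K = 1, method = c("ridge", "gibbs"),
                           runs = 5, burn_in = 10000, iterations = 100000,
                           seed = 1, ridge_penalty = 1e-6) {
  method <- match.arg(method)
  d <- if (inherits(x, "genotype_matrix")) x$dosage else as.matrix(x)
  variants <- if (inherits(x, "genotype_matrix")) x$variants else NULL
  if (length(env) != nrow(d))
    stop("environment vector not aligned to individuals", call. = FALSE)
  if (stats::var(env) == 0)
    stop("environmental variable has zero variance", call. = FALSE)
  n <- nrow(d); p <- ncol(d)
  if (K >= min(n, p)) stop("K must be smaller than both dimensions", call. = FALSE)
  Z <- d
  storage.mode(Z) <- "double"
  if (anyNA(Z)) {
    mu <- colMeans(Z, na.rm = TRUE)
    idx <- which(is.na(Z), arr.ind = TRUE)
    Z[idx] <- mu[idx[, 2]]
  }
  Z <- sweep(Z, 2, colMeans(Z), "-")
  xc <- env - mean(env)

  fit <- if (method == "ridge") {
    lfmm_ridge(Z, xc, K, ridge_penalty)
  } else {
    lfmm_gibbs(Z, xc, K, runs, burn_in, iterations, seed)
  }

  lambda <- stats::median(fit$z^2, na.rm = TRUE) / stats::qchisq(0.5, 1)
  if (!is.finite(lambda) || lambda <= 0) lambda <- 1
  pval <- stats::pchisq(fit$z^2 / lambda, df = 1, lower.tail = FALSE)
  pval <- pmax(pval, 1e-300)             # keep p strictly positive
  structure(
    list(beta = fit$beta, se = fit$se, z = fit$z, p = pval,
         U = fit$U, V = fit$V, lambda = lambda, K = K, method = method,
         runs = if (method == "gibbs") runs else 1L,
         variants = variants),
    class = "lfmm_fit"
  )
}

lfmm_ridge <- function(Z, xc, K, ridge_penalty) {
  n <- nrow(Z)
  sxx <- sum(xc^2)
  U <- NULL
  if (K > 0) {
    R <- Z - outer(xc, as.vector(crossprod(xc, Z)) / sxx)
    G <- tcrossprod(R)
    eg <- eigen(G, symmetric = TRUE)
    U <- eg$vectors[, seq_len(K), drop = FALSE] %*%
      diag(sqrt(pmax(eg$values[seq_len(K)], 0)), K)
  }
  M <- cbind(xc, U)
  q <- ncol(M)
  A <- crossprod(M) + diag(c(0, rep(ridge_penalty, q - 1)), q)
  Ainv <- solve(A)
  B <- Ainv %*% crossprod(M, Z)
  E <- Z - M %*% B
  df <- n - q - 1                      # intercept absorbed by centering
  sigma2 <- colSums(E^2) / df
  vb <- (Ainv %*% crossprod(M) %*% Ainv)[1, 1]
  beta <- B[1, ]
  se <- sqrt(sigma2 * vb)
  z <- beta / se
  z[!is.finite(z)] <- 0          # zero-variance SNPs carry no evidence
  V <- if (K > 0) t(B[-1, , drop = FALSE]) else NULL
  list(beta = beta, se = se, z = z, U = U, V = V)
}

lfmm_gibbs <- function(Z, xc, K, runs, burn_in, iterations, seed) {
  n <- nrow(Z); p <- ncol(Z)
  sb2 <- 100; sv2 <- 100                      # weak normal priors
  a0 <- 1; b0 <- 1                            # inverse-gamma on sigma_j^2
  zsum <- rep(0, p); bsum <- rep(0, p)
  U_last <- NULL; V_last <- NULL
  for (run in seq_len(runs)) {
    local_seed(seed + run * 1009L)
    b <- rep(0, p)
    V <- matrix(0, p, K)
    U <- matrix(stats::rnorm(n * K, 0, 1), n, K)
    s2 <- rep(1, p)
    bs <- rep(0, p); bss <- rep(0, p); kept <- 0L
    total <- burn_in + iterations
    for (it in seq_len(total)) {
      # b_j | rest
      R1 <- Z - if (K > 0) tcrossprod(U, V) else 0
      prec_b <- sum(xc^2) / s2 + 1 / sb2
      mean_b <- as.vector(crossprod(xc, R1)) / s2 / prec_b
      b <- stats::rnorm(p, mean_b, sqrt(1 / prec_b))
      if (K > 0) {
        # V_jk | rest, one factor at a time
        for (k in seq_len(K)) {
          Rk <- Z - outer(xc, b) -
            if (K > 1) tcrossprod(U[, -k, drop = FALSE], V[, -k, drop = FALSE]) else 0
          uk <- U[, k]
          prec_v <- sum(uk^2) / s2 + 1 / sv2
          mean_v <- as.vector(crossprod(uk, Rk)) / s2 / prec_v
          V[, k] <- stats::rnorm(p, mean_v, sqrt(1 / prec_v))
        }
        # U_i | rest: shared K x K posterior precision
        R2 <- Z - outer(xc, b)
        Dinv_V <- V / s2
        P_U <- crossprod(V, Dinv_V) + diag(K)
        P_U_inv <- solve(P_U)
        Mean_U <- R2 %*% Dinv_V %*% P_U_inv
        U <- Mean_U + matrix(stats::rnorm(n * K), n, K) %*% chol(P_U_inv)
      }
      # sigma_j^2 | rest
      E <- Z - outer(xc, b) - if (K > 0) tcrossprod(U, V) else 0
      rss <- colSums(E^2)
      s2 <- 1 / stats::rgamma(p, a0 + n / 2, b0 + rss / 2)
      if (it > burn_in) {
        bs <- bs + b; bss <- bss + b^2; kept <- kept + 1L
      }
    }
    pm <- bs / kept
    psd <- sqrt(pmax(bss / kept - pm^2, 1e-12))
    zsum <- zsum + pm / psd
    bsum <- bsum + pm
    U_last <- U; V_last <- V
  }
  z <- zsum / runs
  beta <- bsum / runs
  list(beta = beta, se = beta / z, z = z, U = U_last, V = V_last)
}

#' @export
print.lfmm_fit <- function(x, ...) {
  cat("<lfmm_fit> ", length(x$z), " SNPs, K = ", x$K, ", method = ",
      x$method, "\n", sep = "")
  cat("  genomic inflation lambda = ", round(x$lambda, 3), "\n", sep = "")
  invisible(x)
}

#' @rdname lfmm_associate
#' @param x an `lfmm_fit` object.
#' @param ... unused.
#' @method tidy lfmm_fit
#' @export
tidy.lfmm_fit <- function(x, ...) {
  out <- tibble::tibble(beta = x$beta, se = x$se, z = x$z, p = x$p)
  if (!is.null(x$variants))
    out <- dplyr::bind_cols(
      dplyr::select(x$variants, "id", "chrom", "pos"), out)
  out
}

#' @rdname lfmm_associate
#' @method glance lfmm_fit
#' @export
glance.lfmm_fit <- function(x, ...) {
  tibble::tibble(n_snps = length(x$z), K = x$K, method = x$method,
                 runs = x$runs, lambda = x$lambda)
}

#' Q-values from per-SNP p-values
#'
#' Storey's method estimates the true-null fraction `pi0` from the flat part
#' of the p-value histogram (natural cubic smoother on a lambda grid,
#' evaluated at the largest lambda) and converts each p-value to the
#' smallest FDR at which it would be called. `"bh"` is the same computation
#' with `pi0` fixed at 1 (Benjamini-Hochberg). Fewer than 100 p-values fall
#' back to BH with a warning.
#'
#' @param p vector of p-values in (0, 1].
#' @param method `"storey"` or `"bh"`.
#' @return A list with `q` (same length as `p`, monotone in `p`) and `pi0`.
#' @export
estimate_qvalues <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  stopifnot(all(p > 0 & p <= 1))
  m <- length(p)
  if (method == "storey" && m < 100) {
    warning("fewer than 100 p-values; falling back to BH")
    method <- "bh"
  }
  pi0 <- 1
  if (method == "storey") {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_lam <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
    fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
    pi0 <- min(max(stats::predict(fit, x = max(lam))$y, 1 / m), 1)
  }
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pi0 * m * p[o] / (m:1)
  q <- pmin(cummin(q), 1)[ro]
  list(q = q, pi0 = pi0)
}

#' Run the six association tests and attach q-values
#'
#' Executes the six environment codings of [build_env_tests()] with
#' [lfmm_associate()], estimating q-values per test separately, and returns
#' one merged tidy table.
#'
#' @param x a [genotype_matrix()].
#' @param samples aligned sample tibble.
#' @param K,method,runs,burn_in,iterations,seed passed to [lfmm_associate()].
#' @param q_method passed to [estimate_qvalues()].
#' @param city_sites,forest_site,excluded_site passed to [build_env_tests()].
#' @return A tibble of class `association_result`: one row per test x SNP
#'   with `test`, `id`, `chrom`, `pos`, `beta`, `z`, `p`, `q`; per-test
#'   `pi0` and `lambda` in `attr(, "test_info")`.
#' @export
run_all_tests <- function(x, samples, K = 1, method = "ridge",
                          runs = 5, burn_in = 10000, iterations = 100000,
                          seed = 1, q_method = "storey",
                          city_sites = NULL, forest_site = "ROU",
                          excluded_site = "ZOO") {
  samples <- align_samples(samples, x)
  specs <- build_env_tests(samples, city_sites, forest_site, excluded_site)
  info <- list()
  out <- purrr::imap_dfr(specs, function(sp, nm) {
    xs <- x[sp$ids, ]
    fit <- lfmm_associate(xs, sp$env[xs$samples], K = K, method = method,
                          runs = runs, burn_in = burn_in,
                          iterations = iterations,
                          seed = seed + match(nm, LETTERS))
    qv <- estimate_qvalues(fit$p, method = q_method)
    info[[nm]] <<- tibble::tibble(test = nm, pi0 = qv$pi0, lambda = fit$lambda)
    dplyr::mutate(tidy(fit), test = nm, q = qv$q, .before = 1)
  })
  attr(out, "test_info") <- dplyr::bind_rows(info)
  class(out) <- c("association_result", class(out))
  out
}
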