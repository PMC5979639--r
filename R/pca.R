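#' Principal component analysis of genotypes
#'
#' Centers each SNP's dosages by twice the sample allele frequency and,
#' under `"binomial"` scaling, divides by `sqrt(2 p (1 - p))` — the
#' variance-standardization used by the standard SNP-PCA toolkits. Missing
#' genotypes are mean-imputed (zero after centering) before decomposition,
#' a deterministic choice adequate at the low post-QC missingness this
#' pipeline targets. Monomorphic SNPs are dropped (with a count) under
#' binomial scaling. The decomposition uses the individuals-by-individuals
#' Gram matrix, so cost is driven by the sample size, not the SNP count.
#' Axis signs follow the convention that the largest-magnitude SNP loading
#' on each axis is positive.
#'
#' @param x a [genotype_matrix()].
#' @param n_axes number of axes to return.
#' @param scaling `"binomial"` (default) or `"none"` (plain centering).
#' @param loadings return SNP loadings as well?
#' @return An object of class `genotype_pca`: `scores` (individuals x axes,
#'   eigenvector times singular value), `eigenvalues` (all, variance scale),
#'   `prop_var`, optionally `loadings`, plus bookkeeping fields.
#' @export
genotype_pca <- function(x, n_axes = 10, scaling = c("binomial", "none"),
                         loadings = FALSE) {
  scaling <- match.arg(scaling)
  d <- x$dosage
  if (nrow(d) < 2 || ncol(d) < 2)
    stop("genotype_pca needs >= 2 individuals and >= 2 SNPs", call. = FALSE)
  nn <- colSums(!is.na(d))
  p_hat <- colSums(d, na.rm = TRUE) / (2 * pmax(nn, 1L))
  keep <- rep(TRUE, ncol(d))
  n_dropped <- 0L
  if (scaling == "binomial") {
    keep <- nn > 0 & p_hat > 0 & p_hat < 1
    n_dropped <- sum(!keep)
  }
  d <- d[, keep, drop = FALSE]
  p_hat <- p_hat[keep]
  Z <- sweep(d, 2, 2 * p_hat, "-")
  if (scaling == "binomial")
    Z <- sweep(Z, 2, sqrt(2 * p_hat * (1 - p_hat)), "/")
  Z[is.na(Z)] <- 0

  n <- nrow(Z)
  G <- tcrossprod(Z)
  eg <- eigen(G, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  n_axes <- min(n_axes, sum(lam > 1e-12))
  dsv <- sqrt(lam[seq_len(n_axes)])
  U <- eg$vectors[, seq_len(n_axes), drop = FALSE]
  V <- crossprod(Z, U) %*% diag(1 / dsv, n_axes)
  # sign convention: largest-magnitude loading positive per axis
  for (k in seq_len(n_axes)) {
    s <- sign(V[which.max(abs(V[, k])), k])
    if (s < 0) { V[, k] <- -V[, k]; U[, k] <- -U[, k] }
  }
  scores <- U %*% diag(dsv, n_axes)
  rownames(scores) <- x$samples
  colnames(scores) <- paste0("PC", seq_len(n_axes))
  structure(
    list(scores = scores,
         eigenvalues = lam / (n - 1),
         prop_var = lam / sum(lam),
         loadings = if (loadings) {
           rownames(V) <- x$variants$id[keep]
           colnames(V) <- colnames(scores)
           V
         },
         snp_ids = x$variants$id[keep],
         center = 2 * p_hat,
         scaling = scaling,
         n_dropped = n_dropped),
    class = "genotype_pca"
  )
}

#' @export
print.genotype_pca <- function(x, ...) {
  k <- ncol(x$scores)
  cat("<genotype_pca> ", nrow(x$scores), " individuals, ", k, " axes (",
      x$scaling, " scaling)\n", sep = "")
  cat("  variance explained:",
      paste0(round(100 * x$prop_var[seq_len(min(k, 5))], 2), "%",
             collapse = ", "), "...\n")
  invisible(x)
}

#' @rdname genotype_pca
#' @param x a `genotype_pca` object.
#' @param ... unused.
#' @method tidy genotype_pca
#' @export
tidy.genotype_pca <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "id") |>
    tidyr::pivot_longer(-"id", names_to = "axis", values_to = "score") |>
    dplyr::mutate(axis = as.integer(sub("PC", "", .data$axis)))
}

#' @rdname genotype_pca
#' @method glance genotype_pca
#' @export
glance.genotype_pca <- function(x, ...) {
  tibble::tibble(
    n_individuals = nrow(x$scores),
    n_snps = length(x$snp_ids),
    n_axes = ncol(x$scores),
    prop_var_pc1 = x$prop_var[1],
    prop_var_pc2 = if (length(x$prop_var) > 1) x$prop_var[2] else NA_real_,
    scaling = x$scaling
  )
}

#' Plot genotype PCA scores
#'
#' @param object a `genotype_pca` object.
#' @param axes which two axes to plot.
#' @param colour optional vector (site labels or urbanization scores)
#'   aligned to individuals.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot genotype_pca
#' @export
autoplot.genotype_pca <- function(object, axes = c(1, 2), colour = NULL, ...) {
  df <- tibble::tibble(
    x = object$scores[, axes[1]],
    y = object$scores[, axes[2]],
    colour = if (is.null(colour)) "all" else colour
  )
  pct <- round(100 * object$prop_var[axes], 2)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$colour)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = paste0("PC", axes[1], " (", pct[1], "%)"),
      y = paste0("PC", axes[2], " (", pct[2], "%)"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
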