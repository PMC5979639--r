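#' Linkage-disequilibrium decay curve
#'
#' For every intra-chromosomal SNP pair within `max_distance`, computes the
#' squared Pearson correlation of dosages (pairwise-complete), then averages
#' r-squared within equal-width distance bins. Pairs involving a SNP with
#' constant dosage are skipped. On unlinked SNPs the null expectation of
#' r-squared is about 1/n for n individuals.
#'
#' @param x a [genotype_matrix()].
#' @param max_distance largest pair distance considered (bp).
#' @param bins number of equal-width distance bins.
#' @param chromosomes optional subset of chromosome labels.
#' @return A tibble of class `ld_decay` with `bin_mid` (bp), `mean_r2`,
#'   `n_pairs`.
#' @export
ld_decay <- function(x, max_distance = 100e3, bins = 20, chromosomes = NULL) {
  v <- x$variants
  if (!is.null(chromosomes)) {
    keep <- v$chrom %in% chromosomes
    x <- x[, keep]
    v <- x$variants
  }
  breaks <- seq(0, max_distance, length.out = bins + 1)
  dist_all <- numeric(0)
  r2_all <- numeric(0)
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    if (length(idx) < 2) next
    idx <- idx[order(v$pos[idx])]
    pos <- v$pos[idx]
    d <- x$dosage[, idx, drop = FALSE]
    for (i in seq_len(length(idx) - 1)) {
      jmax <- i + findInterval(max_distance, pos[(i + 1):length(pos)] - pos[i])
      if (jmax <= i) next
      for (j in (i + 1):jmax) {
        r <- suppressWarnings(
          stats::cor(d[, i], d[, j], use = "pairwise.complete.obs"))
        if (is.na(r)) next                      # constant dosage in a pair
        dist_all <- c(dist_all, pos[j] - pos[i])
        r2_all <- c(r2_all, r^2)
      }
    }
  }
  bin <- cut(dist_all, breaks, include.lowest = TRUE)
  out <- tibble::tibble(
    bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    mean_r2 = as.numeric(tapply(r2_all, bin, mean)[levels(bin)]),
    n_pairs = as.integer(ifelse(is.na(tapply(r2_all, bin, length)[levels(bin)]),
                                0L, tapply(r2_all, bin, length)[levels(bin)]))
  )
  class(out) <- c("ld_decay", class(out))
  out
}
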