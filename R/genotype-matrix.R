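#' Genotype matrix container
#'
#' The central data structure of the package: an individuals-by-SNPs dosage
#' matrix (counts of the alternate allele, 0/1/2, `NA` for missing) together
#' with an aligned variant table and sample ids, and optionally a same-shape
#' per-genotype read-depth matrix. All statistics in the package consume this
#' object.
#'
#' Missing genotypes are always `NA`, never 0: observed heterozygosity, IBS
#' and the FST variance components all need missingness distinguished from
#' homozygous-reference calls.
#'
#' @param dosage integer matrix, individuals in rows, SNPs in columns; values
#'   in `{0, 1, 2, NA}`. Row names, when present, are taken as sample ids.
#' @param variants a data frame with one row per SNP: columns `chrom`, `pos`
#'   (1-based bp), `ref`, `alt`, `id`. Generated automatically when omitted.
#' @param samples character vector of unique sample ids (defaults to row
#'   names or `ind_1 ... ind_n`).
#' @param depth optional integer matrix of per-genotype read depths, same
#'   shape as `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants = NULL, samples = NULL, depth = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage)
  p <- ncol(dosage)
  if (is.null(samples)) {
    samples <- rownames(dosage)
    if (is.null(samples)) samples <- paste0("ind_", seq_len(n))
  }
  if (is.null(variants)) {
    variants <- tibble::tibble(
      chrom = "1",
      pos = seq_len(p),
      ref = "A",
      alt = "T",
      id = paste0("snp_", seq_len(p))
    )
  }
  variants <- tibble::as_tibble(variants)
  obj <- structure(
    list(dosage = dosage, depth = depth, variants = variants,
         samples = as.character(samples)),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(obj)
  rownames(obj$dosage) <- obj$samples
  colnames(obj$dosage) <- obj$variants$id
  if (!is.null(obj$depth)) dimnames(obj$depth) <- dimnames(obj$dosage)
  obj
}

validate_genotype_matrix <- function(x) {
  stopifnot(inherits(x, "genotype_matrix"))
  d <- x$dosage
  if (length(x$samples) != nrow(d))
    stop("sample id count (", length(x$samples), ") does not match dosage rows (",
         nrow(d), ")", call. = FALSE)
  if (anyDuplicated(x$samples))
    stop("duplicate sample ids: ",
         paste(unique(x$samples[duplicated(x$samples)]), collapse = ", "),
         call. = FALSE)
  if (nrow(x$variants) != ncol(d))
    stop("variant table rows (", nrow(x$variants),
         ") do not match dosage columns (", ncol(d), ")", call. = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "id")
  miss <- setdiff(need, names(x$variants))
  if (length(miss)) stop("variant table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(x$variants) > 0) {
    if (any(x$variants$pos < 1)) stop("variant positions must be >= 1", call. = FALSE)
    same <- x$variants$ref == x$variants$alt
    if (any(same)) stop("ref == alt at variant(s): ",
                        paste(utils::head(x$variants$id[same]), collapse = ", "),
                        call. = FALSE)
  }
  bad <- d[!is.na(d)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("dosages must be 0, 1, 2 or NA", call. = FALSE)
  if (!is.null(x$depth)) {
    if (!identical(dim(x$depth), dim(d)))
      stop("depth matrix shape does not match dosage", call. = FALSE)
    dp <- x$depth[!is.na(x$depth)]
    if (length(dp) && min(dp) < 0) stop("depths must be non-negative", call. = FALSE)
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$dosage), " individuals x ",
      ncol(x$dosage), " SNPs\n", sep = "")
  cat("  chromosomes: ", length(unique(x$variants$chrom)),
      "; missing genotypes: ",
      format(round(mean(is.na(x$dosage)), 4)),
      if (!is.null(x$depth)) "; depths present" else "", "\n", sep = "")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x a [genotype_matrix()].
#' @param i individual selector (indices, logical, or sample ids).
#' @param j variant selector (indices, logical, or variant ids).
#' @param ... ignored.
#' @return A `genotype_matrix` with aligned samples/variants/depths.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$variants))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$variants$id)
  genotype_matrix(
    dosage = x$dosage[i, j, drop = FALSE],
    variants = x$variants[j, , drop = FALSE],
    samples = x$samples[i],
    depth = if (!is.null(x$depth)) x$depth[i, j, drop = FALSE]
  )
}

#' Per-variant and per-individual summaries
#'
#' Call rate is the fraction of non-missing genotypes; allele frequency is the
#' alternate-allele frequency among non-missing calls; MAF folds it at 0.5.
#'
#' @param x a [genotype_matrix()].
#' @return `variant_stats()`: a tibble with one row per SNP (`id`, `chrom`,
#'   `pos`, `call_rate`, `alt_freq`, `maf`, `mean_depth`); `sample_stats()`:
#'   one row per individual (`id`, `call_rate`, `het`).
#' @export
variant_stats <- function(x) {
  d <- x$dosage
  nn <- colSums(!is.na(d))
  af <- colSums(d, na.rm = TRUE) / (2 * pmax(nn, 1L))
  af[nn == 0] <- NA_real_
  tibble::tibble(
    id = x$variants$id,
    chrom = x$variants$chrom,
    pos = x$variants$pos,
    call_rate = nn / nrow(d),
    alt_freq = af,
    maf = pmin(af, 1 - af),
    mean_depth = if (is.null(x$depth)) NA_real_ else {
      dp <- x$depth
      dp[is.na(d)] <- NA_integer_
      colMeans(dp, na.rm = TRUE)
    }
  )
}

#' @rdname variant_stats
#' @export
sample_stats <- function(x) {
  d <- x$dosage
  nn <- rowSums(!is.na(d))
  tibble::tibble(
    id = x$samples,
    call_rate = nn / ncol(d),
    het = rowSums(d == 1L, na.rm = TRUE) / pmax(nn, 1L)
  )
}
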