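#' Sliding-window smoothed z-score track
#'
#' Kernel-smoothing moving average of association z-scores along each
#' chromosome: at every grid point (spaced by `step`, starting at the first
#' SNP position rounded down to the step) the mean z of SNPs within
#' `window / 2` on either side (uniform kernel). Grid points covering no SNP
#' yield no row. Used to overlay Manhattan plots and spot genomic regions of
#' elevated average association.
#'
#' @param assoc tidy association table (`chrom`, `pos`, `z`), e.g. one test
#'   of [run_all_tests()] output.
#' @param window window length in bp.
#' @param step grid spacing in bp.
#' @param kernel `"uniform"` (boxcar, default) or `"gaussian"` (sd =
#'   window/4, truncated at window/2).
#' @return A tibble of class `smoothed_track`: `chrom`, `pos`, `z_smooth`,
#'   `n_snps`.
#' @export
smooth_zscores <- function(assoc, window = 10e6, step = 10e3,
                           kernel = c("uniform", "gaussian")) {
  kernel <- match.arg(kernel)
  if (window < step) stop("window must be >= step", call. = FALSE)
  stopifnot(all(c("chrom", "pos", "z") %in% names(assoc)))
  half <- window / 2
  out <- assoc |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(function(df, key) {
      df <- dplyr::arrange(df, .data$pos)
      pos <- df$pos
      z <- df$z
      grid <- seq(floor(min(pos) / step) * step, max(pos), by = step)
      # closed window on both edges (positions are integer bp)
      lo <- findInterval(grid - half - 0.5, pos) + 1L   # first SNP in window
      hi <- findInterval(grid + half, pos)              # last SNP in window
      n <- hi - lo + 1L
      keep <- n > 0L
      if (kernel == "uniform") {
        cz <- c(0, cumsum(z))
        zs <- (cz[hi + 1L] - cz[lo]) / n
      } else {
        zs <- vapply(which(keep), function(i) {
          idx <- lo[i]:hi[i]
          w <- stats::dnorm(pos[idx] - grid[i], sd = window / 4)
          sum(w * z[idx]) / sum(w)
        }, numeric(1))
        zs_full <- rep(NA_real_, length(grid)); zs_full[keep] <- zs
        zs <- zs_full
      }
      tibble::tibble(chrom = key$chrom, pos = grid[keep],
                     z_smooth = zs[keep], n_snps = n[keep])
    }, .keep = FALSE) |>
    dplyr::bind_rows()
  class(out) <- c("smoothed_track", class(out))
  out
}

#' Outlier sets, union and Venn counts across tests
#'
#' Thresholds each test's q-values and reports the per-test outlier sets,
#' their union, the count of SNPs significant in exactly one test, and the
#' cardinality of every membership pattern (the Venn-diagram cells).
#'
#' @param assoc tidy association table with `test`, `id`, `q`.
#' @param q_threshold q-value cutoff.
#' @return A list of class `outlier_sets`: `sets` (named list of id
#'   vectors), `union`, `n_single`, `venn` (tibble of membership pattern
#'   and count), `in_all` (ids significant in every test).
#' @export
outlier_sets <- function(assoc, q_threshold = 0.05) {
  stopifnot(all(c("test", "id", "q") %in% names(assoc)))
  sets <- assoc |>
    dplyr::filter(.data$q < q_threshold) |>
    dplyr::group_by(.data$test) |>
    dplyr::summarise(ids = list(unique(.data$id)))
  set_list <- stats::setNames(sets$ids, sets$test)
  tests <- sort(unique(assoc$test))
  for (t in setdiff(tests, names(set_list))) set_list[[t]] <- character(0)
  set_list <- set_list[tests]
  all_ids <- sort(unique(unlist(set_list)))
  member <- vapply(set_list, function(s) all_ids %in% s,
                   logical(length(all_ids)))
  if (length(all_ids) == 1) member <- matrix(member, nrow = 1,
                                             dimnames = list(NULL, tests))
  n_tests_per_id <- if (length(all_ids)) rowSums(member) else integer(0)
  venn <- if (length(all_ids)) {
    tibble::as_tibble(member) |>
      dplyr::mutate(id = all_ids) |>
      dplyr::count(dplyr::across(dplyr::all_of(tests)), name = "n_snps")
  } else tibble::tibble()
  structure(
    list(sets = set_list,
         union = all_ids,
         n_single = sum(n_tests_per_id == 1L),
         in_all = all_ids[n_tests_per_id == length(tests)],
         venn = venn,
         q_threshold = q_threshold),
    class = "outlier_sets"
  )
}

#' @export
print.outlier_sets <- function(x, ...) {
  cat("<outlier_sets> q <", x$q_threshold, "\n")
  for (nm in names(x$sets))
    cat("  test ", nm, ": ", length(x$sets[[nm]]), " SNPs\n", sep = "")
  cat("  union: ", length(x$union), "; in all tests: ", length(x$in_all),
      "; single-test only: ", x$n_single, "\n", sep = "")
  invisible(x)
}

#' Variance in urbanization explained by an outlier-subset PCA
#'
#' PCA (binomial scaling, all individuals — including any site excluded from
#' the association design, which is thereby re-projected) restricted to a
#' SNP subset, followed by a linear model of the environmental score on PC1,
#' PC2, or both; reports the model r-squared.
#'
#' @param x a [genotype_matrix()] (all individuals).
#' @param subset character vector of variant ids (>= 2).
#' @param env numeric score aligned to the matrix's individuals.
#' @param axes `"1"`, `"2"`, or `"both"`.
#' @return A one-row tibble: `axes`, `r2`, `p`, `n_snps`.
#' @export
outlier_pca_r2 <- function(x, subset, env, axes = c("1", "2", "both")) {
  axes <- match.arg(axes)
  subset <- intersect(subset, x$variants$id)
  if (length(subset) < 2)
    stop("outlier_pca_r2 needs >= 2 SNPs in the subset", call. = FALSE)
  pca <- genotype_pca(x[, subset], n_axes = 2)
  df <- data.frame(env = env,
                   pc1 = pca$scores[, 1],
                   pc2 = if (ncol(pca$scores) > 1) pca$scores[, 2] else 0)
  fit <- switch(axes,
    "1" = stats::lm(env ~ pc1, data = df),
    "2" = stats::lm(env ~ pc2, data = df),
    "both" = stats::lm(env ~ pc1 + pc2, data = df))
  s <- summary(fit)
  fp <- if (is.null(s$fstatistic)) NA_real_ else
    stats::pf(s$fstatistic[1], s$fstatistic[2], s$fstatistic[3],
              lower.tail = FALSE)
  tibble::tibble(axes = axes, r2 = s$r.squared, p = unname(fp),
                 n_snps = length(subset))
}

#' Cumulative top-k r-squared curve
#'
#' How polygenic is the association signal? For an increasing number k of
#' SNPs, taken in order of decreasing |z| from one association test, the
#' curve reports the r-squared of the environmental score on PC1 of the
#' top-k-subset PCA; a baseline repeats the computation on `n_random`
#' random subsets of each size (sampled without replacement). A polygenic
#' signal rises steeply within the top-ranked SNPs, plateaus, then declines
#' toward the full-set value as neutral SNPs dilute PC1, while the baseline
#' stays near the full-set level throughout.
#'
#' @param x a [genotype_matrix()].
#' @param ranking variant ids sorted by decreasing |z| (must cover the
#'   matrix columns; a full association table works via `ranking =
#'   dplyr::arrange(tidy(fit), dplyr::desc(abs(z)))$id`).
#' @param env numeric score aligned to individuals.
#' @param schedule increasing vector of subset sizes k.
#' @param n_random number of random baseline subsets per k.
#' @param seed integer seed for the baseline sampling.
#' @return A tibble of class `r2_curve`: `k`, `r2`, `type`
#'   (`"ranked"`/`"random"`), `replicate`.
#' @export
cumulative_r2_curve <- function(x, ranking, env,
                                schedule = NULL, n_random = 10, seed = 1) {
  p <- ncol(x$dosage)
  if (is.null(schedule))
    schedule <- unique(pmin(c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000,
                              2000, 5000, 10000, p), p))
  if (any(schedule > p)) {
    warning("schedule values above the SNP count truncated")
    schedule <- unique(pmin(schedule, p))
  }
  schedule <- sort(unique(schedule))
  miss <- setdiff(x$variants$id, ranking)
  if (length(miss))
    stop("ranking does not cover ", length(miss), " matrix column(s)",
         call. = FALSE)
  local_seed(seed)

  r2_of <- function(ids) {
    if (length(ids) < 2) {
      # single standardized SNP: squared correlation with env
      g <- x$dosage[, ids]
      return(suppressWarnings(stats::cor(env, g, use = "complete.obs"))^2)
    }
    pca <- genotype_pca(x[, ids], n_axes = 1)
    summary(stats::lm(env ~ pca$scores[, 1]))$r.squared
  }

  ranked <- purrr::map_dfr(schedule, function(k) tibble::tibble(
    k = k, r2 = r2_of(ranking[seq_len(k)]), type = "ranked", replicate = 0L))
  random <- purrr::map_dfr(schedule, function(k) {
    purrr::map_dfr(seq_len(n_random), function(b) tibble::tibble(
      k = k, r2 = r2_of(sample(x$variants$id, k)),
      type = "random", replicate = b))
  })
  out <- dplyr::bind_rows(ranked, random)
  class(out) <- c("r2_curve", class(out))
  out
}

#' Plot a cumulative r-squared curve
#'
#' @param object an `r2_curve` tibble.
#' @param ... unused.
#' @return A ggplot: ranked curve in colour, random baseline in grey.
#' @method autoplot r2_curve
#' @export
autoplot.r2_curve <- function(object, ...) {
  ggplot2::ggplot(mapping = ggplot2::aes(.data$k, .data$r2)) +
    ggplot2::geom_point(data = dplyr::filter(object, .data$type == "random"),
                        colour = "grey60", alpha = 0.6) +
    ggplot2::geom_line(data = dplyr::filter(object, .data$type == "ranked"),
                       colour = "firebrick") +
    ggplot2::geom_point(data = dplyr::filter(object, .data$type == "ranked"),
                        colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "number of top-ranked SNPs",
                  y = expression(r^2 ~ "of urbanization on PC1")) +
    ggplot2::theme_minimal()
}
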