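#' Individual observed heterozygosity
#'
#' Ho for individual i is the fraction of its non-missing genotypes that are
#' heterozygous. Individuals with no non-missing genotype are excluded with
#' a warning.
#'
#' @param x a [genotype_matrix()].
#' @param samples optional sample tibble; when given, the site label is
#'   attached to each row.
#' @return A tibble with columns `id`, `ho`, `n_genotyped` (+ `site`).
#' @export
observed_het <- function(x, samples = NULL) {
  d <- x$dosage
  nn <- rowSums(!is.na(d))
  empty <- nn == 0
  if (any(empty)) {
    warning("observed_het: excluded fully missing individual(s): ",
            paste(x$samples[empty], collapse = ", "))
  }
  out <- tibble::tibble(
    id = x$samples,
    ho = unname(rowSums(d == 1L, na.rm = TRUE) / nn),
    n_genotyped = unname(nn)
  )[!empty, ]
  if (!is.null(samples))
    out <- dplyr::left_join(out, dplyr::select(samples, "id", "site"), by = "id")
  out
}

#' Identity-by-state matrix
#'
#' IBS between two individuals is the allele-sharing fraction
#' `mean(1 - |g_i - g_j| / 2)` over SNPs non-missing in both; 1 for identical
#' genotype vectors, 0 for opposite homozygotes throughout. Pairs with no
#' shared non-missing SNP get `NA` with a warning.
#'
#' @param x a [genotype_matrix()].
#' @return A symmetric numeric matrix with unit diagonal, dimnames = sample
#'   ids, of class `ibs_matrix`.
#' @export
ibs_matrix <- function(x) {
  d <- x$dosage
  n <- nrow(d)
  obs <- !is.na(d)
  d0 <- d
  d0[!obs] <- 0L
  storage.mode(d0) <- "double"
  obs_d <- obs * 1
  # sum over shared SNPs of |g_i - g_j| decomposes on indicator columns:
  # |a-b| = a + b - 2*min(a,b); with dosages 0/1/2 use
  # |a-b| = |(a-b)|: compute via dot products of the three indicator matrices
  I0 <- (d == 0L) & obs; I1 <- (d == 1L) & obs; I2 <- (d == 2L) & obs
  M0 <- I0 * 1; M1 <- I1 * 1; M2 <- I2 * 1
  shared <- tcrossprod(obs_d)                  # SNPs non-missing in both
  # pairwise counts of (0,1),(1,2) -> diff 1 ; (0,2) -> diff 2
  n01 <- tcrossprod(M0, M1) + tcrossprod(M1, M0) +
    tcrossprod(M1, M2) + tcrossprod(M2, M1)
  n02 <- tcrossprod(M0, M2) + tcrossprod(M2, M0)
  absdiff <- n01 + 2 * n02
  ibs <- 1 - absdiff / (2 * shared)
  if (any(shared == 0)) {
    warning("ibs_matrix: ", sum(shared[upper.tri(shared)] == 0),
            " pair(s) share no non-missing SNP")
    ibs[shared == 0] <- NA_real_
  }
  diag(ibs) <- 1
  dimnames(ibs) <- list(x$samples, x$samples)
  class(ibs) <- c("ibs_matrix", class(ibs))
  ibs
}

#' Prune close relatives from an IBS matrix
#'
#' Greedy, deterministic removal so that no retained pair exceeds the IBS
#' threshold: repeatedly drop the individual involved in the most
#' above-threshold pairs, breaking ties by lower genotype call rate and then
#' lexicographic id. One individual per isolated related pair is removed;
#' chains (A-B and B-C related, A-C not) lose only the shared member.
#'
#' @param ibs an [ibs_matrix()].
#' @param threshold IBS above which a pair counts as first-degree related.
#' @param call_rate optional named numeric vector of per-individual call
#'   rates used for tie-breaking (defaults to equal).
#' @return A list with `kept` and `removed` character id vectors.
#' @export
prune_related <- function(ibs, threshold = 0.80, call_rate = NULL) {
  ids <- rownames(ibs)
  if (is.null(call_rate)) call_rate <- stats::setNames(rep(1, length(ids)), ids)
  adj <- !is.na(ibs) & ibs > threshold
  diag(adj) <- FALSE
  removed <- character(0)
  while (any(adj)) {
    deg <- rowSums(adj)
    cand <- which(deg == max(deg))
    if (length(cand) > 1) {
      cr <- call_rate[ids[cand]]
      cand <- cand[cr == min(cr)]
    }
    if (length(cand) > 1) cand <- cand[order(ids[cand])][1]
    removed <- c(removed, ids[cand])
    adj[cand, ] <- FALSE
    adj[, cand] <- FALSE
  }
  list(kept = setdiff(ids, removed), removed = removed)
}

#' Compare a per-individual statistic between sites
#'
#' One-way ANOVA with Tukey HSD post-hoc comparisons and a compact letter
#' display (groups sharing a letter are not significantly different at the
#' chosen level).
#'
#' @param values numeric vector (e.g. per-individual Ho).
#' @param groups group labels aligned to `values`.
#' @param alpha significance level for the letter display.
#' @return A list of class `group_compare` with elements `f`, `p`,
#'   `tukey` (tibble of pairwise comparisons) and `letters` (named character).
#' @export
group_compare <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  g <- factor(groups[keep])
  empty <- setdiff(levels(factor(groups)), levels(droplevels(g)))
  if (length(empty)) warning("group_compare: empty group(s) excluded: ",
                             paste(empty, collapse = ", "))
  if (nlevels(g) < 2 || length(values) < 2)
    stop("group_compare needs >= 2 groups and >= 2 values", call. = FALSE)
  dat <- data.frame(v = values, g = g)
  fit <- stats::aov(v ~ g, data = dat)
  an <- summary(fit)[[1]]
  tuk <- stats::TukeyHSD(fit)$g
  tuk_tbl <- tibble::tibble(
    pair = rownames(tuk),
    diff = tuk[, "diff"],
    lwr = tuk[, "lwr"],
    upr = tuk[, "upr"],
    p_adj = tuk[, "p adj"]
  )
  letters <- tryCatch({
    glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
    cl <- multcomp::cld(glht, level = alpha)
    cl$mcletters$Letters
  }, error = function(e) stats::setNames(rep(NA_character_, nlevels(g)), levels(g)))
  structure(
    list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1],
         tukey = tuk_tbl, letters = letters),
    class = "group_compare"
  )
}

#' @export
print.group_compare <- function(x, ...) {
  cat("One-way ANOVA: F =", format(x$f, digits = 4),
      ", p =", format.pval(x$p, digits = 3), "\n")
  cat("Letter display:",
      paste(names(x$letters), unname(x$letters), sep = ":", collapse = "  "),
      "\n")
  invisible(x)
}
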