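#' Redundancy analysis of genotypes on spatial and urbanization covariates
#'
#' Constrained ordination: the multivariate regression of the centered
#' dosage matrix on the constraint table is eigen-decomposed, so each
#' constrained axis carries the fraction of total genotypic variance
#' explained by the constraints. With a conditioning table the model is a
#' partial RDA: both response and constraints are first residualized on the
#' conditions. Inertia is computed on centered (not variance-scaled)
#' dosages. Missing genotypes are mean-imputed per SNP before centering.
#'
#' @param y a [genotype_matrix()] or a plain numeric matrix (rows =
#'   individuals).
#' @param x data frame of constraining variables (e.g. `lat`, `lon`,
#'   urbanization), rows aligned to `y`.
#' @param z optional data frame of conditioning variables (partial RDA).
#' @return An object of class `rda_fit`: the underlying vegan model plus
#'   `eig` (constrained eigenvalues), `prop` (per-axis proportion of total
#'   inertia), `constrained_prop`, `var_scores` (correlations of constraints
#'   with the constrained axes), `total_inertia`, `conditioned`.
#' @export
rda_fit <- function(y, x, z = NULL) {
  Y <- rda_response(y)
  X <- as.data.frame(x)
  qrX <- qr(scale(as.matrix(X), scale = FALSE))
  if (qrX$rank < ncol(X))
    warning("rda_fit: constraints are rank-deficient (rank ", qrX$rank,
            " < ", ncol(X), "); axes reduced")
  mod <- rda_model(Y, X, z)
  eig <- mod$CCA$eig
  if (is.null(eig)) eig <- numeric(0)
  tot <- mod$tot.chi
  var_scores <- NULL
  if (length(eig) > 0) {
    lc <- vegan::scores(mod, display = "lc",
                        choices = seq_along(eig), scaling = "none")
    var_scores <- suppressWarnings(stats::cor(X, lc))
    colnames(var_scores) <- paste0("RDA", seq_len(ncol(var_scores)))
  }
  structure(
    list(model = mod,
         eig = eig,
         prop = eig / tot,
         constrained_prop = sum(eig) / tot,
         var_scores = var_scores,
         total_inertia = tot,
         unconstrained_eig = mod$CA$eig,
         conditioned = if (is.null(z)) character(0) else colnames(as.data.frame(z))),
    class = "rda_fit"
  )
}

# Fit vegan's RDA through the formula interface (required by the marginal
# permutation test), keeping the response matrix in the formula environment.
rda_model <- function(Y, X, z = NULL) {
  dat <- as.data.frame(X)
  txt <- paste("Y ~", paste(names(dat), collapse = " + "))
  if (!is.null(z)) {
    zdat <- as.data.frame(z)
    names(zdat) <- paste0(".cond_", names(zdat))
    txt <- paste0(txt, " + Condition(",
                  paste(names(zdat), collapse = " + "), ")")
    dat <- cbind(dat, zdat)
  }
  fml <- stats::as.formula(txt)
  environment(fml) <- environment()
  vegan::rda(fml, data = dat)
}

rda_response <- function(y) {
  Y <- if (inherits(y, "genotype_matrix")) y$dosage else as.matrix(y)
  storage.mode(Y) <- "double"
  if (anyNA(Y)) {
    mu <- colMeans(Y, na.rm = TRUE)
    idx <- which(is.na(Y), arr.ind = TRUE)
    Y[idx] <- mu[idx[, 2]]
  }
  Y
}

#' Permutation tests for an RDA model
#'
#' Global mode permutes rows of the (residualized) response and compares the
#' constrained variance; marginal mode tests each constraint's added
#' variance with all other constraints as conditions. P-values use the
#' add-one estimator over `n_perm` permutations of individuals (free
#' permutation, no blocks).
#'
#' @param y,x,z as in [rda_fit()].
#' @param mode `"global"` or `"marginal"`.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return A tibble with `term`, `variance`, `f`, `p_value`.
#' @export
rda_permtest <- function(y, x, z = NULL, mode = c("global", "marginal"),
                         n_perm = 1000, seed = 1) {
  mode <- match.arg(mode)
  if (n_perm < 99)
    warning("rda_permtest: n_perm < 99 gives coarse p-value resolution")
  Y <- rda_response(y)
  X <- as.data.frame(x)
  local_seed(seed)
  mod <- rda_model(Y, X, z)
  an <- vegan::anova.cca(mod, permutations = n_perm,
                         by = if (mode == "marginal") "margin" else NULL,
                         parallel = 1)
  tibble::tibble(
    term = if (mode == "global") "model" else rownames(an)[seq_len(nrow(an) - 1)],
    variance = an$Variance[seq_len(nrow(an) - 1)],
    f = an$F[seq_len(nrow(an) - 1)],
    p_value = an$`Pr(>F)`[seq_len(nrow(an) - 1)]
  )
}

#' @export
print.rda_fit <- function(x, ...) {
  cat("<rda_fit> ", length(x$eig), " constrained axes",
      if (length(x$conditioned))
        paste0(" (conditioned on ", paste(x$conditioned, collapse = ", "), ")"),
      "\n", sep = "")
  cat("  % of total genotypic variance per axis: ",
      paste0(round(100 * x$prop, 2), "%", collapse = ", "), "\n", sep = "")
  cat("  constrained proportion: ",
      round(100 * x$constrained_prop, 2), "%\n", sep = "")
  invisible(x)
}

#' @rdname rda_fit
#' @param x an `rda_fit` object.
#' @param ... unused.
#' @method tidy rda_fit
#' @export
tidy.rda_fit <- function(x, ...) {
  axes <- tibble::tibble(term = paste0("RDA", seq_along(x$eig)),
                         eigenvalue = unname(x$eig),
                         prop_variance = unname(x$prop))
  if (is.null(x$var_scores)) return(axes)
  vs <- tibble::as_tibble(x$var_scores, rownames = "term")
  dplyr::bind_rows(
    axes,
    dplyr::mutate(vs, eigenvalue = NA_real_, prop_variance = NA_real_)
  )
}

#' @rdname rda_fit
#' @method glance rda_fit
#' @export
glance.rda_fit <- function(x, ...) {
  tibble::tibble(
    n_axes = length(x$eig),
    constrained_prop = x$constrained_prop,
    total_inertia = x$total_inertia,
    partial = length(x$conditioned) > 0
  )
}
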