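#' Run the full urban-gradient analysis pipeline
#'
#' Orchestrates the stages in dependency order: QC filters, observed
#' heterozygosity, IBS and relative pruning, pairwise and per-SNP FST, PCA,
#' RDA (nest- and site-level urbanization, full and partial), the six
#' gene-environment association tests with q-values, and the outlier
#' aggregation stages (smoothed z track for test A, outlier sets, outlier
#' PCA r-squared, cumulative curve). Optionally SNP-to-gene assignment and
#' term enrichment when an annotation and term map are supplied. Every
#' stage's table is written to `out_dir` as delimited text and the report
#' records parameters, per-stage counts and headline statistics; identical
#' config and seed reproduce identical numbers.
#'
#' @param config a named list (or path to a YAML file). Recognized fields:
#'   `fixture` (name for [make_fixture()]) or `vcf` + `samples` paths;
#'   optional `gff` and `term_map` paths; `params` (arguments to
#'   [filter_params()]); `seed`; `n_perm`; `K`; `method`; `q_threshold`;
#'   `stages` (character subset of qc, het, ibs, fst, pca, rda, gea,
#'   outliers, enrich); `out_dir`.
#' @return A list of class `pipeline_report`.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading a config file needs the yaml package", call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    fixture = NULL, vcf = NULL, samples = NULL, gff = NULL, term_map = NULL,
    params = list(), seed = 1, n_perm = 199, K = 1, method = "ridge",
    q_threshold = 0.05, prune_threshold = 0.80,
    stages = c("qc", "het", "ibs", "fst", "pca", "rda", "gea", "outliers"),
    forest_site = "ROU", excluded_site = "ZOO",
    out_dir = NULL
  ), config)
  params <- do.call(filter_params, cfg$params)
  report <- list(config = cfg, params = params, stages = list())
  out <- function(name, tbl) {
    if (!is.null(cfg$out_dir)) {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      readr::write_tsv(tbl, file.path(cfg$out_dir, paste0(name, ".tsv")))
    }
  }
  say <- function(...) message("[urbanpopgen] ", ...)
  stage_on <- function(s) s %in% cfg$stages

  # --- inputs -------------------------------------------------------------
  if (!is.null(cfg$fixture)) {
    sim <- make_fixture(cfg$fixture, seed = cfg$seed)
    g <- sim$genotypes; samples <- sim$samples
  } else {
    if (is.null(cfg$vcf) || is.null(cfg$samples))
      stop("config needs either `fixture` or `vcf` + `samples`", call. = FALSE)
    g <- read_vcf(cfg$vcf)
    samples <- read_samples(cfg$samples)
  }
  samples <- align_samples(samples, g)
  report$input <- list(n_individuals = nrow(g$dosage), n_snps = ncol(g$dosage))
  say("input: ", nrow(g$dosage), " individuals x ", ncol(g$dosage), " SNPs")

  # --- qc -----------------------------------------------------------------
  if (stage_on("qc")) {
    fv <- filter_variants(g, params)
    g <- fv$genotypes
    hw <- filter_hwe(g, samples, params)
    g <- hw$genotypes
    fi <- filter_individuals(g, params)
    g <- fi$genotypes
    samples <- align_samples(samples, g)
    report$stages$qc <- list(variant_counts = fv$counts,
                             hwe_removed = hw$n_removed,
                             individuals_removed = fi$removed,
                             n_snps = ncol(g$dosage),
                             n_individuals = nrow(g$dosage))
    out("qc_variant_counts", fv$counts)
    say("qc: ", ncol(g$dosage), " SNPs, ", nrow(g$dosage),
        " individuals retained (", hw$n_removed, " HWE removals)")
  }

  # --- diversity / relatedness -------------------------------------------
  het <- NULL
  if (stage_on("het")) {
    het <- observed_het(g, samples)
    cmp <- group_compare(het$ho, het$site)
    report$stages$het <- list(table = het, anova_f = cmp$f, anova_p = cmp$p,
                              letters = cmp$letters)
    out("het", het)
    say("het: site ANOVA F = ", round(cmp$f, 2))
  }
  ibs <- NULL; kept_ids <- g$samples
  if (stage_on("ibs")) {
    ibs <- ibs_matrix(g)
    pr <- prune_related(ibs, threshold = cfg$prune_threshold,
                        call_rate = stats::setNames(sample_stats(g)$call_rate,
                                                    g$samples))
    kept_ids <- pr$kept
    report$stages$ibs <- list(mean_ibs = mean(ibs[upper.tri(ibs)], na.rm = TRUE),
                              pruned = pr$removed)
    out("ibs", tibble::as_tibble(unclass(ibs), rownames = "id"))
    say("ibs: mean ", round(report$stages$ibs$mean_ibs, 3), "; pruned ",
        length(pr$removed), " relative(s)")
  }
  g_nft <- g[kept_ids, ]                       # no-family-ties dataset
  samples_nft <- align_samples(samples, g_nft)

  # --- differentiation ----------------------------------------------------
  fst_pair <- NULL
  if (stage_on("fst")) {
    fst_pair <- pairwise_fst(g_nft, samples_nft$site, n_perm = cfg$n_perm,
                             seed = cfg$seed)
    fst_snp <- wc_fst_per_snp(g_nft, samples_nft$site)
    report$stages$fst <- list(pairwise = fst_pair,
                              mean_theta = mean(fst_pair$theta),
                              per_snp_mean = mean(fst_snp$theta, na.rm = TRUE))
    out("fst_pairwise", fst_pair)
    out("fst_per_snp", fst_snp)
    say("fst: mean pairwise theta = ", signif(report$stages$fst$mean_theta, 3))
  }
  if (stage_on("pca")) {
    pca <- genotype_pca(g_nft, n_axes = 4)
    report$stages$pca <- list(prop_var = pca$prop_var[1:4],
                              scores = tibble::as_tibble(pca$scores,
                                                         rownames = "id"))
    out("pca_scores", report$stages$pca$scores)
  }
  if (stage_on("het") && stage_on("fst") && stage_on("ibs")) {
    corr <- tryCatch(gradient_correlations(het, fst_pair, ibs, samples),
                     error = function(e) {
                       say("correlations: skipped (", conditionMessage(e), ")")
                       NULL
                     })
    if (!is.null(corr)) {
      report$stages$correlations <- corr
      out("gradient_correlations", corr)
    }
  }

  # --- RDA ----------------------------------------------------------------
  if (stage_on("rda")) {
    rda_tbl <- purrr::map_dfr(c(nest = "urb_nest", site = "urb_site"),
                              function(v) {
      X <- data.frame(lat = samples$lat, lon = samples$lon,
                      urb = samples[[v]])
      full <- rda_fit(g, X)
      pg <- rda_permtest(g, X, n_perm = cfg$n_perm, seed = cfg$seed)
      pm <- rda_permtest(g, X, mode = "marginal", n_perm = cfg$n_perm,
                         seed = cfg$seed)
      part <- rda_fit(g, data.frame(urb = samples[[v]]),
                      z = data.frame(lat = samples$lat, lon = samples$lon))
      pp <- rda_permtest(g, data.frame(urb = samples[[v]]),
                         z = data.frame(lat = samples$lat,
                                        lon = samples$lon),
                         n_perm = cfg$n_perm, seed = cfg$seed)
      tibble::tibble(
        level = ifelse(v == "urb_nest", "nest", "site"),
        model = c("full", "partial"),
        constrained_pct = 100 * c(full$constrained_prop, part$constrained_prop),
        global_p = c(pg$p_value, pp$p_value),
        urb_marginal_p = c(pm$p_value[pm$term == "urb"], NA)
      )
    })
    report$stages$rda <- rda_tbl
    out("rda", rda_tbl)
    say("rda: site-level partial urbanization p = ",
        rda_tbl$global_p[rda_tbl$level == "site" & rda_tbl$model == "partial"])
  }

  # --- GEA ----------------------------------------------------------------
  assoc <- NULL
  if (stage_on("gea")) {
    assoc <- run_all_tests(g, samples, K = cfg$K, method = cfg$method,
                           seed = cfg$seed, forest_site = cfg$forest_site,
                           excluded_site = cfg$excluded_site)
    counts <- assoc |>
      dplyr::group_by(.data$test) |>
      dplyr::summarise(n_outliers = sum(.data$q < cfg$q_threshold))
    report$stages$gea <- list(outlier_counts = counts,
                              test_info = attr(assoc, "test_info"))
    out("association", assoc)
    say("gea: outliers per test at q<", cfg$q_threshold, ": ",
        paste(counts$test, counts$n_outliers, sep = "=", collapse = ", "))
  } else if (stage_on("outliers")) {
    say("outliers: skipped (gea stage disabled)")
  }

  # --- outlier aggregation ------------------------------------------------
  if (stage_on("outliers") && !is.null(assoc)) {
    track <- smooth_zscores(dplyr::filter(assoc, .data$test == "A"))
    sets <- outlier_sets(assoc, cfg$q_threshold)
    env <- samples$urb_nest
    pca_r2 <- purrr::map_dfr(names(sets$sets), function(t) {
      ids <- sets$sets[[t]]
      if (length(ids) < 2) return(tibble::tibble())
      dplyr::mutate(outlier_pca_r2(g, ids, env), set = t, .before = 1)
    })
    full_r2 <- dplyr::mutate(outlier_pca_r2(g, g$variants$id, env),
                             set = "all", .before = 1)
    pca_r2 <- dplyr::bind_rows(pca_r2, full_r2)
    rankA <- assoc |>
      dplyr::filter(.data$test == "A") |>
      dplyr::arrange(dplyr::desc(abs(.data$z)))
    curve <- cumulative_r2_curve(g, rankA$id, env, seed = cfg$seed)
    report$stages$outliers <- list(sets = sets, pca_r2 = pca_r2,
                                   curve = curve)
    out("smoothed_track_A", track)
    out("outlier_pca_r2", pca_r2)
    out("cumulative_r2_curve", curve)
  }

  # --- annotation / enrichment -------------------------------------------
  if (stage_on("enrich") && !is.null(cfg$gff) && !is.null(assoc)) {
    genes <- read_gff(cfg$gff)
    s2g <- snps_to_genes(g$variants, genes)
    report$stages$annotation <- list(
      n_genes_hit = dplyr::n_distinct(stats::na.omit(s2g$gene)))
    out("snp_genes", s2g)
    if (!is.null(cfg$term_map)) {
      tm <- readr::read_tsv(cfg$term_map, show_col_types = FALSE)
      sets <- outlier_sets(assoc, cfg$q_threshold)
      background <- unique(stats::na.omit(s2g$gene))
      hit_genes <- unique(stats::na.omit(
        s2g$gene[s2g$id %in% sets$union]))
      if (length(hit_genes)) {
        enr <- enrichment_hypergeom(hit_genes, background, tm)
        report$stages$enrichment <- enr
        out("enrichment", enr)
      }
    }
  }

  report$seed <- cfg$seed
  class(report) <- "pipeline_report"
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report> seed =", x$seed, "\n")
  cat("  input:", x$input$n_individuals, "individuals x",
      x$input$n_snps, "SNPs\n")
  for (nm in names(x$stages)) cat("  stage:", nm, "\n")
  invisible(x)
}
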