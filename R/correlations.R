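#' Correlations of diversity and differentiation with geography and
#' urbanization
#'
#' Mirrors the standard landscape-genomic gradient summaries:
#' \itemize{
#'   \item Ho regressed on urbanization at the site level (one point per
#'     site, unweighted) and at the individual level (nest-level score);
#'   \item linearized differentiation `fst / (1 - fst)` regressed on
#'     great-circle distance between site mean coordinates (km) and on the
#'     absolute difference of site urbanization;
#'   \item pairwise IBS between individuals regressed on nest-to-nest
#'     great-circle distance (km) and on the absolute difference of
#'     nest-level urbanization.
#' }
#'
#' @param het tibble from [observed_het()].
#' @param fst tibble from [pairwise_fst()].
#' @param ibs an [ibs_matrix()] (or `NULL` to skip the IBS regressions).
#' @param samples sample tibble with `id`, `site`, `lat`, `lon`,
#'   `urb_nest`, `urb_site`.
#' @return A tibble with one row per regression: `response`, `predictor`,
#'   `level`, `slope`, `r2`, `p`, `n`.
#' @export
gradient_correlations <- function(het, fst, ibs, samples) {
  rows <- list()
  lm_row <- function(response, predictor, level, y, x) {
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    fit <- stats::lm(y ~ x)
    s <- summary(fit)
    tibble::tibble(response = response, predictor = predictor, level = level,
                   slope = unname(stats::coef(fit)[2]), r2 = s$r.squared,
                   p = s$coefficients[2, 4], n = length(y))
  }

  site_tab <- samples |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(lat = mean(.data$lat), lon = mean(.data$lon),
                     urb = mean(.data$urb_nest))

  # Ho ~ urbanization
  het_s <- dplyr::left_join(het, dplyr::select(samples, "id", "site", "urb_nest"),
                            by = "id")
  if ("site.x" %in% names(het_s)) het_s <- dplyr::rename(het_s, site = "site.x")
  site_ho <- het_s |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(ho = mean(.data$ho)) |>
    dplyr::left_join(site_tab, by = "site")
  if (nrow(site_ho) < 3)
    stop("site-level regression needs >= 3 sites", call. = FALSE)
  rows$ho_site <- lm_row("ho", "urbanization", "site", site_ho$ho, site_ho$urb)
  rows$ho_ind <- lm_row("ho", "urbanization", "individual",
                        het_s$ho, het_s$urb_nest)

  # fst/(1-fst) ~ distance and ~ |delta urbanization| (site pairs)
  if (!is.null(fst) && nrow(fst) > 0) {
    i1 <- match(fst$site1, site_tab$site)
    i2 <- match(fst$site2, site_tab$site)
    dist_km <- geosphere::distHaversine(
      cbind(site_tab$lon[i1], site_tab$lat[i1]),
      cbind(site_tab$lon[i2], site_tab$lat[i2])) / 1000
    durb <- abs(site_tab$urb[i1] - site_tab$urb[i2])
    lin <- fst$theta / (1 - fst$theta)
    rows$fst_dist <- lm_row("fst_linearized", "distance_km", "site_pair",
                            lin, dist_km)
    rows$fst_urb <- lm_row("fst_linearized", "urbanization_difference",
                           "site_pair", lin, durb)
  }

  # IBS ~ distance and ~ |delta urbanization| (individual pairs)
  if (!is.null(ibs)) {
    ids <- rownames(ibs)
    meta <- samples[match(ids, samples$id), ]
    ut <- upper.tri(ibs)
    pair_i <- row(ibs)[ut]; pair_j <- col(ibs)[ut]
    dist_km <- geosphere::distHaversine(
      cbind(meta$lon[pair_i], meta$lat[pair_i]),
      cbind(meta$lon[pair_j], meta$lat[pair_j])) / 1000
    durb <- abs(meta$urb_nest[pair_i] - meta$urb_nest[pair_j])
    rows$ibs_dist <- lm_row("ibs", "distance_km", "individual_pair",
                            ibs[ut], dist_km)
    rows$ibs_urb <- lm_row("ibs", "urbanization_difference", "individual_pair",
                           ibs[ut], durb)
  }

  dplyr::bind_rows(rows)
}
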