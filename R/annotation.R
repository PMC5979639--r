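#' Assign SNPs to overlapping genes
#'
#' A SNP is assigned to every gene whose `[start, end]` interval, optionally
#' extended by `max_distance` on both sides, contains its position
#' (coordinates 1-based inclusive on both sides). SNPs overlapping no gene
#' are labeled intergenic (`NA` gene).
#'
#' @param variants variant tibble (`chrom`, `pos`, `id`), e.g.
#'   `x$variants`.
#' @param genes gene tibble from [read_gff()] (`chrom`, `start`, `end`,
#'   `gene`).
#' @param max_distance bp added to each side of every gene.
#' @return A tibble with `id`, `chrom`, `pos`, `gene` (one row per
#'   SNP-gene overlap; intergenic SNPs get one row with `gene = NA`).
#' @export
snps_to_genes <- function(variants, genes, max_distance = 0) {
  if (!requireNamespace("GenomicRanges", quietly = TRUE))
    stop("snps_to_genes needs the GenomicRanges package", call. = FALSE)
  snp_gr <- GenomicRanges::GRanges(
    variants$chrom, IRanges::IRanges(variants$pos, variants$pos))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - max_distance, 1),
                     genes$end + max_distance))
  hits <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  hit_tbl <- tibble::tibble(
    id = variants$id[S4Vectors::queryHits(hits)],
    chrom = variants$chrom[S4Vectors::queryHits(hits)],
    pos = variants$pos[S4Vectors::queryHits(hits)],
    gene = genes$gene[S4Vectors::subjectHits(hits)]
  )
  orphan <- !(variants$id %in% hit_tbl$id)
  dplyr::bind_rows(
    hit_tbl,
    tibble::tibble(id = variants$id[orphan], chrom = variants$chrom[orphan],
                   pos = variants$pos[orphan], gene = NA_character_)
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
}

#' Hypergeometric term enrichment
#'
#' For each term, the upper-tail hypergeometric probability of drawing at
#' least the observed number of term members when sampling `|gene_set|`
#' genes from the background without replacement; Benjamini-Hochberg
#' adjusted q-values. The background should be the full set of genes
#' represented in the SNP panel, not the genome.
#'
#' @param gene_set character vector of genes of interest (subset of
#'   `background`).
#' @param background character vector: the gene universe.
#' @param term_map data frame mapping `gene` to `term` (optionally with a
#'   `description` column).
#' @return A tibble sorted by p: `term`, `description`, `n_term`,
#'   `n_overlap`, `p`, `q`.
#' @export
enrichment_hypergeom <- function(gene_set, background, term_map) {
  stopifnot(all(c("gene", "term") %in% names(term_map)))
  gene_set <- unique(gene_set)
  background <- unique(background)
  extra <- setdiff(gene_set, background)
  if (length(extra))
    stop("gene_set has gene(s) outside the background: ",
         paste(utils::head(extra), collapse = ", "), call. = FALSE)
  term_map <- dplyr::filter(term_map, .data$gene %in% background)
  N <- length(background)
  n <- length(gene_set)
  out <- term_map |>
    dplyr::group_by(.data$term) |>
    dplyr::summarise(
      description = if ("description" %in% names(term_map))
        dplyr::first(.data$description) else NA_character_,
      n_term = dplyr::n_distinct(.data$gene),
      n_overlap = length(intersect(unique(.data$gene), gene_set))
    ) |>
    dplyr::filter(.data$n_term > 0) |>
    dplyr::mutate(
      p = stats::phyper(.data$n_overlap - 1, .data$n_term,
                        N - .data$n_term, n, lower.tail = FALSE),
      q = stats::p.adjust(.data$p, method = "BH")
    ) |>
    dplyr::arrange(.data$p)
  out
}
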