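#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses GT (and, when present, DP) fields of a VCF 4.x file. Only biallelic
#' single-nucleotide records are kept; multiallelic or indel records are
#' skipped with a reported count rather than an error. When per-genotype
#' depths are available and `min_genotype_depth` is given, genotypes below
#' that depth are set missing (the depth mask usually applied before any
#' variant-level filter).
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param min_genotype_depth minimum per-genotype read depth; genotypes with
#'   lower depth are masked to `NA`. `NULL` disables masking.
#' @return A [genotype_matrix()] with dosages = alternate-allele counts.
#' @export
read_vcf <- function(path, min_genotype_depth = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("VCF parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_field <- vcf@gt
  if (is.null(gt_field) || ncol(gt_field) < 2)
    stop("VCF has no sample genotypes: ", path, call. = FALSE)
  samples <- colnames(gt_field)[-1]

  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  snp <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt, fixed = TRUE)
  n_skipped <- sum(!snp)
  if (n_skipped > 0)
    message("read_vcf: skipped ", n_skipped, " multiallelic/non-SNP record(s)")
  if (!any(snp)) {
    return(genotype_matrix(
      dosage = matrix(NA_integer_, length(samples), 0),
      variants = tibble::tibble(chrom = character(), pos = integer(),
                                ref = character(), alt = character(),
                                id = character()),
      samples = samples
    ))
  }

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  # strip phasing, count alt alleles
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  dos <- (a1 == "1") + (a2 == "1")
  dos[a1 == "." | a2 == "." | is.na(gt)] <- NA_integer_
  dos <- matrix(as.integer(dos), nrow = nrow(gt), dimnames = dimnames(gt))

  depth <- NULL
  fmt <- gt_field[, 1]
  if (any(grepl("DP", fmt, fixed = TRUE))) {
    depth <- suppressWarnings(
      vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
    )[snp, , drop = FALSE]
    storage.mode(depth) <- "integer"
  }

  ids <- fix[snp, "ID"]
  pos <- as.integer(fix[snp, "POS"])
  chrom <- fix[snp, "CHROM"]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(chrom[no_id], "_", pos[no_id])

  g <- genotype_matrix(
    dosage = t(dos),
    variants = tibble::tibble(chrom = chrom, pos = pos,
                              ref = ref[snp], alt = alt[snp], id = ids),
    samples = samples,
    depth = if (!is.null(depth)) t(depth)
  )
  if (!is.null(min_genotype_depth)) g <- mask_low_depth(g, min_genotype_depth)
  g
}

#' Mask genotypes below a read-depth threshold
#'
#' Sets to missing every genotype whose read depth is below `min_depth`.
#' A no-op (with a message) when the matrix carries no depths. Idempotent.
#'
#' @param x a [genotype_matrix()].
#' @param min_depth minimum acceptable per-genotype depth (reads).
#' @return The masked `genotype_matrix`.
#' @export
mask_low_depth <- function(x, min_depth) {
  if (is.null(x$depth)) {
    message("mask_low_depth: no depth matrix present; nothing masked")
    return(x)
  }
  x$dosage[!is.na(x$depth) & x$depth < min_depth] <- NA_integer_
  x
}

#' Write a genotype matrix to a plain-text VCF
#'
#' Emits an uncompressed VCF 4.2 file with GT (and DP when depths are
#' present) that [read_vcf()] reads back bit-identically on dosages,
#' positions and alleles. Dosage 0/1/2 is serialized as `0/0`, `0/1`, `1/1`;
#' missing as `./.`.
#'
#' @param x a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  validate_genotype_matrix(x)
  has_dp <- !is.null(x$depth)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=urbanpopgen",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$samples), collapse = "\t")
  )
  p <- ncol(x$dosage)
  body <- character(0)
  if (p > 0) {
    gt_code <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = p, ncol = nrow(x$dosage))
    dos <- t(x$dosage)
    ok <- !is.na(dos)
    gt[ok] <- gt_code[dos[ok] + 1L]
    if (has_dp) {
      dp <- t(x$depth)
      dpc <- ifelse(is.na(dp), ".", as.character(dp))
      gt <- matrix(paste0(gt, ":", dpc), nrow = p)
    }
    v <- x$variants
    body <- paste(
      v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".",
      if (has_dp) "GT:DP" else "GT",
      apply(gt, 1, paste, collapse = "\t"),
      sep = "\t"
    )
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path, call. = FALSE))
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Read the per-individual sample table
#'
#' Expects delimited text (tab or comma, autodetected by readr) with one row
#' per individual and columns `id`, `site`, `lat`, `lon`, `urb_nest` and
#' optionally `urb_site`. When `urb_site` is absent it is recomputed as the
#' site mean of the nest-level urbanization scores.
#'
#' @param path path to the table.
#' @return A tibble (`sample_frame`) with columns `id`, `site`, `lat`, `lon`,
#'   `urb_nest`, `urb_site`.
#' @export
read_samples <- function(path) {
  tab <- readr::read_delim(path, delim = NULL, show_col_types = FALSE,
                           progress = FALSE)
  need <- c("id", "site", "lat", "lon", "urb_nest")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("sample table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  tab <- dplyr::mutate(tab, id = as.character(.data$id),
                       site = as.character(.data$site))
  if (!"urb_site" %in% names(tab)) {
    tab <- tab |>
      dplyr::group_by(.data$site) |>
      dplyr::mutate(urb_site = mean(.data$urb_nest)) |>
      dplyr::ungroup()
  }
  cst <- tab |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(ok = dplyr::n_distinct(.data$urb_site) == 1L)
  if (any(!cst$ok))
    stop("urb_site not constant within site(s): ",
         paste(cst$site[!cst$ok], collapse = ", "), call. = FALSE)
  dplyr::select(tab, "id", "site", "lat", "lon", "urb_nest", "urb_site")
}

#' Align a sample table to a genotype matrix
#'
#' Reorders the table to the genotype matrix's sample order and errors,
#' listing ids, when any genotyped individual is absent from the table.
#'
#' @param samples a sample tibble from [read_samples()].
#' @param x a [genotype_matrix()].
#' @return The reordered sample tibble.
#' @export
align_samples <- function(samples, x) {
  idx <- match(x$samples, samples$id)
  if (anyNA(idx))
    stop("individuals in genotype matrix missing from sample table: ",
         paste(x$samples[is.na(idx)], collapse = ", "), call. = FALSE)
  samples[idx, , drop = FALSE]
}

#' Read gene records from a GFF3 annotation
#'
#' Keeps only records of type `gene`, sorted by chromosome and start.
#' Records with start > end are rejected with a warning. Coordinates stay
#' 1-based inclusive, matching the GFF3 convention.
#'
#' @param path path to a GFF3 file.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`, `gene`.
#' @export
read_gff <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gff needs the rtracklayer package", call. = FALSE)
  gff <- as.data.frame(rtracklayer::readGFF(path))
  genes <- gff[gff$type == "gene", , drop = FALSE]
  bad <- genes$start > genes$end
  if (any(bad)) {
    warning("read_gff: rejected ", sum(bad), " gene record(s) with start > end")
    genes <- genes[!bad, , drop = FALSE]
  }
  name_col <- intersect(c("Name", "gene", "ID"), names(genes))[1]
  out <- tibble::tibble(
    chrom = as.character(genes$seqid),
    start = as.integer(genes$start),
    end = as.integer(genes$end),
    strand = as.character(genes$strand),
    gene = if (is.na(name_col)) NA_character_ else as.character(genes[[name_col]])
  )
  dplyr::arrange(out, .data$chrom, .data$start)
}
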