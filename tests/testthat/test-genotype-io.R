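test_that("VCF parsing produces alt-allele dosages, missing codes and depth masking", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "ind1", "ind2", "ind3"), collapse = "\t"),
    "1\t100\tsnp1\tA\tG\t.\tPASS\t.\tGT:DP\t0/0:20\t0/1:20\t1/1:20",
    "1\t200\tsnp2\tC\tT\t.\tPASS\t.\tGT:DP\t./.:0\t0/1:5\t0/0:30"
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)

  g <- read_vcf(path)
  expect_equal(unname(g$dosage[, "snp1"]), c(0L, 1L, 2L))
  expect_true(is.na(g$dosage["ind1", "snp2"]))
  expect_equal(g$samples, c("ind1", "ind2", "ind3"))

  # depth 5 < 8 masks that single genotype
  gm <- read_vcf(path, min_genotype_depth = 8)
  expect_true(is.na(gm$dosage["ind2", "snp2"]))
  expect_equal(unname(gm$dosage[, "snp1"]), c(0L, 1L, 2L))
  # masking is idempotent
  gm2 <- mask_low_depth(gm, 8)
  expect_identical(gm$dosage, gm2$dosage)
})

test_that("multiallelic and non-SNP records are skipped with a message", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "a", "b"), collapse = "\t"),
    "1\t100\t.\tA\tG,T\t.\t.\t.\tGT\t0/1\t0/0",
    "1\t200\t.\tAT\tA\t.\t.\t.\tGT\t0/1\t0/0",
    "1\t300\t.\tA\tC\t.\t.\t.\tGT\t1/1\t0/1"
  )
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  expect_message(g <- read_vcf(path), "skipped 2")
  expect_equal(ncol(g$dosage), 1L)
  expect_equal(g$variants$pos, 300L)
})

test_that("VCF round-trip is bit-identical on dosages, coordinates and alleles", {
  set.seed(5)
  d <- matrix(sample(c(0:2, NA), 50, replace = TRUE), 5, 10)
  g <- toy_genotypes(d, chrom = rep(c("1", "2"), each = 5),
                     pos = rep(seq(1000, 5000, by = 1000), 2))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path)
  g2 <- read_vcf(path)
  expect_identical(unname(g$dosage), unname(g2$dosage))
  expect_identical(g$variants$pos, g2$variants$pos)
  expect_identical(g$variants$ref, g2$variants$ref)
  expect_identical(g$variants$alt, g2$variants$alt)

  # empty variant list -> header-only VCF
  g0 <- g[, integer(0)]
  write_vcf(g0, path)
  expect_equal(nrow(read_vcf(path)$variants), 0L)
})

test_that("sample tables recompute site means and align to genotypes", {
  tab <- tibble::tibble(
    id = c("a1", "a2", "b1"),
    site = c("ROU", "ROU", "MNO"),
    lat = c(43.66, 43.67, 43.59),
    lon = c(3.67, 3.67, 3.86),
    urb_nest = c(-2.14, -1.74, 2.3)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tab, path)
  s <- read_samples(path)
  expect_equal(s$urb_site[s$site == "ROU"], rep(-1.94, 2))
  expect_equal(s$urb_site[s$site == "MNO"], 2.3)   # singleton = its nest score

  g <- toy_genotypes(matrix(0L, 3, 2))
  g$samples <- c("b1", "a1", "a2")
  rownames(g$dosage) <- g$samples
  expect_equal(align_samples(s, g)$id, c("b1", "a1", "a2"))
  g$samples[1] <- "zz"
  expect_error(align_samples(s, g), "zz")
})

test_that("GFF3 gene extraction keeps genes sorted and rejects bad intervals", {
  skip_if_not_installed("rtracklayer")
  gff <- c(
    "##gff-version 3",
    "2\tsrc\tgene\t500\t2000\t.\t+\t.\tID=gene2;Name=GENE2",
    "1\tsrc\tgene\t100\t900\t.\t+\t.\tID=gene1;Name=GENE1",
    "1\tsrc\texon\t100\t200\t.\t+\t.\tID=exon1",
    "1\tsrc\tgene\t5000\t4000\t.\t-\t.\tID=bad;Name=BAD"
  )
  path <- withr::local_tempfile(fileext = ".gff3")
  writeLines(gff, path)
  expect_warning(genes <- read_gff(path), "start > end")
  expect_equal(genes$gene, c("GENE1", "GENE2"))
  expect_equal(genes$chrom, c("1", "2"))
})

test_that("genotype matrix invariants are enforced", {
  expect_error(genotype_matrix(matrix(3L, 2, 1)), "dosages")
  expect_error(
    genotype_matrix(matrix(0L, 2, 1), samples = c("a", "a")), "duplicate")
  v <- tibble::tibble(chrom = "1", pos = 1L, ref = "A", alt = "A", id = "x")
  expect_error(genotype_matrix(matrix(0L, 2, 1), variants = v), "ref == alt")
})
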