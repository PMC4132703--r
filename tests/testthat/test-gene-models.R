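test_that("union model merges transcript exons; length matches distinct bases", {
  # two isoforms sharing exons: union equals the larger isoform's exon set
  tx <- tibble::tibble(
    transcript_id = c("iso1", "iso1", "iso2", "iso2", "iso2"),
    start = c(0L, 500L, 0L, 200L, 500L),
    end = c(100L, 600L, 100L, 300L, 600L)
  )
  gm <- gene_model("g", "chr1", tx[, c("start", "end")], transcripts = tx)
  expect_equal(gm$union_exons$start, c(0L, 200L, 500L))
  expect_equal(gm$union_exons$end, c(100L, 300L, 600L))
  expect_equal(gm$length_d, 300L)

  # identity case: one exon
  gm1 <- gene_model("g1", "chr1", data.frame(start = 100, end = 200))
  expect_equal(gm1$length_d, 100L)

  # overlapping exons merge; check against per-base set enumeration
  gm2 <- gene_model("g2", "chr1", data.frame(start = c(0, 30), end = c(50, 80)))
  expect_equal(gm2$union_exons, tibble::tibble(start = 0L, end = 80L))
  bases <- unique(c(0:49, 30:79))
  expect_equal(gm2$length_d, length(bases))
  expect_equal(sigfuge:::model_positions(gm2), sort(bases))
})

test_that("gene_model rejects empty and inverted intervals", {
  expect_error(gene_model("g", "chr1", data.frame(start = 5, end = 5)),
               "start >= end")
  expect_error(gene_model("g", "chr1", data.frame(start = integer(), end = integer())),
               "at least one exon")
})

test_that("GTF parsing builds per-gene union models with 0-based coordinates", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  lines <- c(
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\ttest\texon\t501\t600\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\ttest\texon\t101\t200\t.\t+\t.\tgene_id "gA"; transcript_id "gA.2";',
    'chr1\ttest\texon\t301\t400\t.\t+\t.\tgene_id "gA"; transcript_id "gA.2";',
    'chr1\ttest\texon\t501\t600\t.\t+\t.\tgene_id "gA"; transcript_id "gA.2";',
    'chr2\ttest\texon\t11\t50\t.\t-\t.\tgene_id "gB"; transcript_id "gB.1";'
  )
  writeLines(lines, gtf)
  models <- parse_annotations(gtf, "gtf")
  expect_named(models, c("gA", "gB"))
  # union of the cassette pair equals the three-exon isoform (1-based in,
  # 0-based half-open internally)
  expect_equal(models$gA$union_exons,
               tibble::tibble(start = c(100L, 300L, 500L), end = c(200L, 400L, 600L)))
  expect_equal(models$gA$length_d, 300L)
  expect_equal(models$gB$strand, "-")
  expect_equal(models$gB$union_exons, tibble::tibble(start = 10L, end = 50L))
})

test_that("BED12 blocks become absolute half-open exons", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(paste(
    "chr1", 100, 360, "tx1", 0, "+", 100, 360, "0", 2,
    "100,60,", "0,200,", sep = "\t"), bed)
  models <- parse_annotations(bed, "bed12")
  expect_equal(models$tx1$union_exons,
               tibble::tibble(start = c(100L, 300L), end = c(200L, 360L)))
})

test_that("tsv-exons dialect validates records and multi-chromosome genes are skipped", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene_id = c("g1", "g1", "g2"), transcript_id = c("t1", "t1", "t2"),
    chrom = c("chr1", "chr2", "chr3"), start = c(0L, 10L, 5L),
    end = c(50L, 60L, 25L), strand = "+"
  ), tsv)
  expect_warning(models <- parse_annotations(tsv, "tsv-exons"),
                 "multiple chromosomes")
  expect_named(models, "g2")

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    gene_id = "g", transcript_id = "t", chrom = "chr1",
    start = 50L, end = 10L, strand = "+"
  ), bad)
  expect_error(parse_annotations(bad, "tsv-exons"), "line 2")
})

test_that("matrix TSV round-trips and rejects invalid cells", {
  m <- coverage_matrix(matrix(c(0L, 1L, 2L, 3L, 4L, 5L), nrow = 2, byrow = TRUE),
                       sample_ids = c("a", "b"), gene_id = "rt")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(dim(tab), c(2L, 4L))  # sample_id + 3 positions

  m2 <- read_matrix(path, gene_id = "rt")
  expect_equal(m2$counts, m$counts)
  expect_equal(m2$sample_ids, m$sample_ids)
  expect_equal(m2$positions, m$positions)

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tchr1:0\tchr1:1", "s1\t3\t-1"), neg)
  expect_error(read_matrix(neg), "negative")
})

test_that("coverage_matrix validates its contract", {
  expect_error(coverage_matrix(matrix(-1L, 1, 2)), "non-negative")
  expect_error(coverage_matrix(matrix(0.5, 1, 2)), "integer")
  expect_error(coverage_matrix(matrix(0L, 2, 2), sample_ids = c("a", "a")),
               "unique")
  wide <- tibble::tibble(sample_id = c("x", "y"), `chr1:5` = c(1L, 2L),
                         `chr1:6` = c(0L, 4L))
  m <- sigfuge:::as_coverage_matrix(wide)
  expect_equal(m$positions$pos, c(5L, 6L))
  expect_equal(unname(m$counts[2, ]), c(2L, 4L))
})
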