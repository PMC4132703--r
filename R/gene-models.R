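#' Construct a union gene model
#'
#' A gene model is the merged ("union") set of exonic intervals over all
#' annotated transcripts of one gene.  It defines the coordinate axis of the
#' per-base expression curves: column `j` of a coverage matrix is the `j`-th
#' exonic base of the union model in ascending genomic order.  All
#' coordinates are 0-based half-open; conversion from 1-based annotation
#' formats happens at parse time only.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome / sequence name.
#' @param union_exons Data frame with integer columns `start`, `end`
#'   (0-based half-open).  Overlapping intervals are merged; book-ended
#'   ones remain distinct exons.
#' @param strand One of `"+"`, `"-"`, `"."`.  Curves are always laid out in
#'   ascending genomic order regardless of strand.
#' @param transcripts Optional tibble of the contributing transcripts with
#'   columns `transcript_id`, `start`, `end` (one row per exon).
#'
#' @return An object of class `gene_model` with fields `gene_id`, `chrom`,
#'   `strand`, `union_exons` (disjoint, sorted tibble), `length_d` (total
#'   exonic length in bp) and `transcripts`.
#' @examples
#' gm <- gene_model("g1", "chr1", data.frame(start = c(0, 30), end = c(50, 80)))
#' gm$length_d  # 80: [0,50) and [30,80) merge into [0,80)
#' @export
gene_model <- function(gene_id, chrom, union_exons, strand = ".",
                       transcripts = NULL) {
  stopifnot(is.character(gene_id), length(gene_id) == 1)
  strand <- match.arg(strand, c("+", "-", "."))
  ex <- tibble::as_tibble(union_exons)[, c("start", "end")]
  if (nrow(ex) == 0) abort("gene model must contain at least one exon")
  if (any(ex$start >= ex$end))
    abort(sprintf("gene %s: exon with start >= end", gene_id))
  ex <- merge_intervals(ex)
  structure(
    list(
      gene_id = gene_id, chrom = chrom, strand = strand,
      union_exons = ex,
      length_d = sum(ex$end - ex$start),
      transcripts = if (is.null(transcripts)) NULL else tibble::as_tibble(transcripts)
    ),
    class = "gene_model"
  )
}

# Merge overlapping intervals into a disjoint sorted set (0-based
# half-open).  Book-ended exons stay separate: they are distinct features
# of the gene model even though their bases are contiguous.
merge_intervals <- function(ex) {
  ir <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
  red <- IRanges::reduce(ir, min.gapwidth = 0L)
  tibble::tibble(start = IRanges::start(red) - 1L, end = IRanges::end(red))
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s%s), %d union exon(s), %d exonic bp\n",
              x$gene_id, x$chrom, x$strand, nrow(x$union_exons), x$length_d))
  invisible(x)
}

#' @export
format.gene_model <- function(x, ...) {
  sprintf("gene_model(%s)", x$gene_id)
}

# Vector of all exonic genomic positions (0-based), ascending.
model_positions <- function(model) {
  unlist(Map(function(s, e) seq.int(s, e - 1L),
             model$union_exons$start, model$union_exons$end),
         use.names = FALSE)
}

#' Parse gene annotations into union gene models
#'
#' Reads exon-level annotations and builds one [gene_model()] per gene: the
#' union of exon intervals over all of that gene's transcripts.  Supported
#' dialects: GTF and GFF3 (1-based inclusive on disk, converted internally),
#' BED12 (one transcript per line, blocks as exons; the `name` field is used
#' as both transcript and gene id, so duplicated names merge), and a plain
#' `tsv-exons` table with columns `gene_id`, `transcript_id`, `chrom`,
#' `start`, `end`, `strand` already in 0-based half-open coordinates.
#'
#' Genes whose transcripts span multiple chromosomes are skipped with a
#' warning.  Malformed `tsv-exons` records raise an error naming the line.
#'
#' @param path Annotation file.
#' @param dialect `"auto"` (from the file extension) or one of `"gtf"`,
#'   `"gff3"`, `"bed12"`, `"tsv-exons"`.
#' @return A named list of `gene_model` objects.
#' @export
parse_annotations <- function(path,
                              dialect = c("auto", "gtf", "gff3", "bed12", "tsv-exons")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      gtf = "gtf", gff = "gff3", gff3 = "gff3", bed = "bed12",
      tsv = "tsv-exons", txt = "tsv-exons",
      abort(sprintf("cannot infer annotation dialect from extension '.%s'", ext))
    )
  }
  exons <- switch(dialect,
    "gtf" = parse_exons_gxf(path, "gtf"),
    "gff3" = parse_exons_gxf(path, "gff3"),
    "bed12" = parse_exons_bed12(path),
    "tsv-exons" = parse_exons_tsv(path)
  )
  build_models(exons)
}

# exon table -> list of gene_model, skipping multi-chromosome genes
build_models <- function(exons) {
  split_ex <- split(exons, exons$gene_id)
  models <- list()
  for (gid in names(split_ex)) {
    ge <- split_ex[[gid]]
    if (length(unique(ge$chrom)) > 1L) {
      warn(sprintf("gene %s: transcripts on multiple chromosomes; skipped", gid))
      next
    }
    strand <- unique(ge$strand)
    models[[gid]] <- gene_model(
      gene_id = gid, chrom = ge$chrom[1],
      strand = if (length(strand) == 1) strand else ".",
      union_exons = ge[, c("start", "end")],
      transcripts = ge[, c("transcript_id", "start", "end")]
    )
  }
  models
}

parse_exons_gxf <- function(path, fmt) {
  gr <- rtracklayer::import(path, format = if (fmt == "gtf") "gtf" else "gff3")
  gr <- gr[!is.na(S4Vectors::mcols(gr)$type) & S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0) abort(sprintf("no exon records in %s", path))
  mc <- S4Vectors::mcols(gr)
  tx <- if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id)
        else if ("Parent" %in% names(mc)) as.character(unlist(mc$Parent))
        else abort("exon records carry neither transcript_id nor Parent")
  gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else tx
  if (anyNA(gid)) gid[is.na(gid)] <- tx[is.na(gid)]
  tibble::tibble(
    gene_id = gid, transcript_id = tx,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr))
  )
}

parse_exons_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!"blocks" %in% names(S4Vectors::mcols(gr)))
    abort(sprintf("%s is not BED12 (no block structure)", path))
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- paste0("tx", seq_along(gr))
  res <- lapply(seq_along(gr), function(i) {
    # blocks are 1-based relative to the feature start
    bl <- S4Vectors::mcols(gr)$blocks[[i]]
    tx_start0 <- GenomicRanges::start(gr)[i] - 1L
    tibble::tibble(
      gene_id = nm[i], transcript_id = nm[i],
      chrom = as.character(GenomicRanges::seqnames(gr))[i],
      start = tx_start0 + IRanges::start(bl) - 1L,
      end = tx_start0 + IRanges::end(bl),
      strand = as.character(GenomicRanges::strand(gr))[i]
    )
  })
  dplyr::bind_rows(res)
}

parse_exons_tsv <- function(path) {
  req <- c("gene_id", "transcript_id", "chrom", "start", "end", "strand")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(req %in% names(tab)))
    abort(sprintf("tsv-exons file must have columns: %s", paste(req, collapse = ", ")))
  bad <- which(!is.finite(tab$start) | !is.finite(tab$end) | tab$start >= tab$end)
  if (length(bad) > 0)
    abort(sprintf("malformed exon record at line %d of %s", bad[1] + 1L, path))
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tibble::as_tibble(tab[req])
}

#' Construct a per-base coverage matrix
#'
#' The central data structure of the per-base analysis: an integer matrix of
#' read depths with one row per sample and one column per exonic
#' base-position of a locus, columns in ascending genomic order.
#'
#' @param counts Integer matrix (samples x positions), non-negative.
#' @param sample_ids Unique sample identifiers (defaults to rownames).
#' @param gene_id Locus identifier.
#' @param positions Optional tibble with columns `chrom`, `pos` (0-based
#'   genomic position of each column); synthetic positions are generated
#'   when omitted.
#' @return An object of class `coverage_matrix`.
#' @export
coverage_matrix <- function(counts, sample_ids = rownames(counts),
                            gene_id = "gene", positions = NULL) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(counts)))
  if (anyDuplicated(sample_ids)) abort("sample_ids must be unique")
  if (length(sample_ids) != nrow(counts))
    abort("length(sample_ids) must equal nrow(counts)")
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    abort("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  dimnames(counts) <- NULL
  if (is.null(positions)) {
    positions <- tibble::tibble(chrom = "chrUn", pos = seq_len(ncol(counts)) - 1L)
  } else {
    positions <- tibble::as_tibble(positions)
    if (nrow(positions) != ncol(counts))
      abort("positions must have one row per matrix column")
  }
  rownames(counts) <- sample_ids
  structure(
    list(gene_id = gene_id, sample_ids = sample_ids,
         positions = positions, counts = counts),
    class = "coverage_matrix"
  )
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat(sprintf("<coverage_matrix> %s: %d sample(s) x %d exonic position(s)\n",
              x$gene_id, nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.coverage_matrix <- function(x) dim(x$counts)

#' @importFrom tibble as_tibble
#' @export
as_tibble.coverage_matrix <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$counts), .name_repair = "minimal")
  names(out) <- paste0(x$positions$chrom, ":", x$positions$pos)
  dplyr::bind_cols(tibble::tibble(sample_id = x$sample_ids), out)
}

# Accept either a coverage_matrix or a wide data frame
# (sample_id + position columns) anywhere a matrix is expected.
as_coverage_matrix <- function(x, gene_id = "gene") {
  if (inherits(x, "coverage_matrix")) return(x)
  if (is.data.frame(x)) {
    if (!"sample_id" %in% names(x))
      abort("data-frame input must have a sample_id column")
    ids <- as.character(x$sample_id)
    m <- as.matrix(x[setdiff(names(x), "sample_id")])
    pos <- parse_position_labels(colnames(m))
    return(coverage_matrix(m, ids, gene_id = gene_id, positions = pos))
  }
  if (is.matrix(x)) return(coverage_matrix(x, gene_id = gene_id))
  abort("cannot interpret input as a coverage matrix")
}

parse_position_labels <- function(labs) {
  if (is.null(labs) || !all(grepl(":", labs))) return(NULL)
  parts <- strsplit(labs, ":", fixed = TRUE)
  tibble::tibble(chrom = vapply(parts, `[`, "", 1L),
                 pos = as.integer(vapply(parts, `[`, "", 2L)))
}

#' Read / write coverage matrices as TSV
#'
#' Plain-text layout: a header row of position labels (`chrom:pos`), a first
#' column `sample_id`, and integer cells.  `write_matrix()` followed by
#' `read_matrix()` is an identity.
#'
#' @param path TSV file path.
#' @param gene_id Gene id to attach on read (the TSV stores positions only).
#' @return `read_matrix()` returns a [coverage_matrix()]; `write_matrix()`
#'   returns `path` invisibly.
#' @export
read_matrix <- function(path, gene_id = NULL) {
  if (!file.exists(path)) abort(sprintf("matrix file not found: %s", path))
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(sample_id = readr::col_character(),
                                                 .default = readr::col_double()))
  if (!"sample_id" %in% names(tab)) abort("matrix TSV must have a sample_id column")
  m <- as.matrix(tab[setdiff(names(tab), "sample_id")])
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    abort(sprintf("non-integer or negative count at row %d (sample %s), column %s",
                  bad[1, 1], tab$sample_id[bad[1, 1]], colnames(m)[bad[1, 2]]))
  coverage_matrix(m, as.character(tab$sample_id),
                  gene_id = gene_id %||% tools::file_path_sans_ext(basename(path)),
                  positions = parse_position_labels(colnames(m)))
}

#' @param m A [coverage_matrix()] (or wide data frame).
#' @rdname read_matrix
#' @export
write_matrix <- function(m, path) {
  m <- as_coverage_matrix(m)
  readr::write_tsv(as_tibble(m), path, progress = FALSE)
  invisible(path)
}

#' Extract per-base coverage over a union gene model from BAM files
#'
#' Builds the samples-by-base coverage matrix for one locus: entry `(i, j)`
#' counts the reads of sample `i` whose aligned bases cover the `j`-th
#' exonic position of the union model.  Intronic positions are excluded, so
#' a spliced read contributes only at the exonic columns its aligned
#' segments overlap.  Columns are in ascending genomic order regardless of
#' strand.  Secondary alignments and PCR duplicates are excluded by flag;
#' reads below `min_mapq` are dropped.
#'
#' @param bam_files Character vector of coordinate-sorted, indexed BAM
#'   paths (one sample per file); names, if given, become sample ids.
#' @param model A [gene_model()].
#' @param min_mapq Minimum mapping quality (default 0).
#' @return A [coverage_matrix()].  A BAM whose header lacks the model's
#'   chromosome yields an all-zero row with a warning; a missing index is
#'   an error.
#' @export
extract_coverage <- function(bam_files, model, min_mapq = 0) {
  stopifnot(inherits(model, "gene_model"))
  ids <- names(bam_files) %||% tools::file_path_sans_ext(basename(bam_files))
  pos <- model_positions(model)
  which_gr <- GenomicRanges::GRanges(
    model$chrom,
    IRanges::IRanges(start = model$union_exons$start + 1L, end = model$union_exons$end)
  )
  counts <- matrix(0L, nrow = length(bam_files), ncol = length(pos))
  for (i in seq_along(bam_files)) {
    bf <- bam_files[[i]]
    if (!file.exists(bf)) abort(sprintf("BAM not found: %s", bf))
    idx <- paste0(bf, ".bai")
    if (!file.exists(idx) && !file.exists(sub("\\.bam$", ".bai", bf)))
      abort(sprintf("BAM index (.bai) missing for %s", bf))
    hdr <- Rsamtools::scanBamHeader(bf)[[1]]$targets
    if (!model$chrom %in% names(hdr)) {
      warn(sprintf("%s: chromosome %s absent from BAM header; zero coverage row",
                   bf, model$chrom))
      next
    }
    pp <- Rsamtools::PileupParam(
      max_depth = 1000000L, min_base_quality = 0L,
      min_mapq = as.integer(min_mapq), min_nucleotide_depth = 1L,
      distinguish_strands = FALSE, distinguish_nucleotides = FALSE,
      include_deletions = FALSE, include_insertions = FALSE
    )
    sbp <- Rsamtools::ScanBamParam(
      which = which_gr,
      flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                    isDuplicate = FALSE,
                                    isUnmappedQuery = FALSE)
    )
    pu <- Rsamtools::pileup(bf, scanBamParam = sbp, pileupParam = pp)
    if (nrow(pu) > 0) {
      # which_label can duplicate positions if ranges abut; sum unique positions
      pu <- dplyr::summarise(dplyr::group_by(pu, .data$pos),
                             count = max(.data$count), .groups = "drop")
      j <- match(pu$pos - 1L, pos)  # pileup positions are 1-based
      keep <- !is.na(j)
      counts[i, j[keep]] <- as.integer(pu$count[keep])
    }
  }
  coverage_matrix(counts, ids, gene_id = model$gene_id,
                  positions = tibble::tibble(chrom = model$chrom, pos = pos))
}
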