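# Independent oracles and fixture builders shared across the test files.
# Everything is generated in code at test time; no binary fixtures.

# Exhaustive search over all 2-partitions: the global 2-means optimum for
# small n.  Returns the minimal within-SS and the cluster index.
enumerate_two_means <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  stopifnot(n >= 2, n <= 14)
  gmean <- colMeans(x)
  tss <- sum(sweep(x, 2, gmean)^2)
  best <- Inf
  for (m in seq_len(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(m))[seq_len(n)]  # sample n always in group 0
    wss <- 0
    for (g in 0:1) {
      xg <- x[lab == g, , drop = FALSE]
      wss <- wss + sum(sweep(xg, 2, colMeans(xg))^2)
    }
    if (wss < best) best <- wss
  }
  list(within_ss = best, total_ss = tss, CI = best / tss)
}

# Literal step-up FDR procedure evaluated from its definition.
brute_bh <- function(pvalues, q) {
  m <- length(pvalues)
  o <- order(pvalues)
  sorted <- pvalues[o]
  k <- which(sorted <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(k) > 0) reject[o[seq_len(max(k))]] <- TRUE
  qs <- rev(cummin(rev(sorted * m / seq_len(m))))
  qvalues <- numeric(m)
  qvalues[o] <- pmin(qs, 1)
  list(reject = reject, qvalues = qvalues)
}

# AUC by explicit pair counting, ties counted one half.
brute_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}

# Brute-force pileup: walk each read's CIGAR and count aligned bases per
# 0-based reference position.  `reads` is a data frame with pos (1-based)
# and cigar.
brute_pileup <- function(reads, positions) {
  depth <- stats::setNames(rep(0L, length(positions)), positions)
  for (r in seq_len(nrow(reads))) {
    ref <- reads$pos[r] - 1L
    ops <- regmatches(reads$cigar[r],
                      gregexpr("[0-9]+[MIDNSHP=X]", reads$cigar[r]))[[1]]
    for (op in ops) {
      len <- as.integer(sub("[A-Z=]", "", op))
      type <- sub("[0-9]+", "", op)
      if (type %in% c("M", "=", "X")) {
        covered <- ref:(ref + len - 1L)
        hit <- as.character(covered[covered %in% positions])
        depth[hit] <- depth[hit] + 1L
        ref <- ref + len
      } else if (type %in% c("D", "N")) {
        ref <- ref + len
      }
      # I, S, H, P do not consume reference
    }
  }
  unname(depth)
}

# Write a SAM file (one sample) and convert it to an indexed BAM.
# `reads`: data frame with qname, flag, pos (1-based), mapq, cigar.
make_bam <- function(reads, dir = withr::local_tempdir(.local_envir = parent.frame()),
                     chrom = "chr1", chrom_len = 10000, name = "sample") {
  sam <- file.path(dir, paste0(name, ".sam"))
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- character(0)
  if (nrow(reads) > 0) {
    rl <- vapply(reads$cigar, function(cg) {
      ops <- regmatches(cg, gregexpr("[0-9]+[MIS=X]", cg))[[1]]
      sum(as.integer(sub("[A-Z=]", "", ops)))
    }, integer(1))
    body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                    reads$qname, reads$flag, chrom, reads$pos, reads$mapq,
                    reads$cigar,
                    vapply(rl, function(k) strrep("A", k), ""),
                    vapply(rl, function(k) strrep("I", k), ""))
    body <- body[order(reads$pos)]
  }
  writeLines(c(header, body), sam)
  bam <- suppressMessages(Rsamtools::asBam(sam, file.path(dir, name),
                                           overwrite = TRUE))
  bam
}

# Small deterministic coverage matrix fixture.
toy_matrix <- function() {
  counts <- rbind(
    s1 = rep(10L, 10),
    s2 = c(7L, rep(0L, 9)),
    s3 = c(rep(0L, 4), rep(6L, 6)),
    s4 = rep(4L, 10)
  )
  coverage_matrix(counts, gene_id = "toy")
}
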