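# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: per-base enumeration for spliced geometry,
# per-read CIGAR walking for 5'-end tallies, and full labeling enumeration
# for the rank-sum null.

# spliced 5' UTR length by listing every exonic base in transcript order
oracle_utr5_length <- function(t) {
  pos <- unlist(mapply(seq, t$exon_starts, t$exon_ends, SIMPLIFY = FALSE))
  if (t$strand == "-") pos <- rev(pos)
  which(pos == t$cds_first_base) - 1L
}

# exonic genomic positions of the 5' UTR, by the same enumeration
oracle_utr5_positions <- function(t) {
  pos <- unlist(mapply(seq, t$exon_starts, t$exon_ends, SIMPLIFY = FALSE))
  if (t$strand == "-") pos <- rev(pos)
  k <- which(pos == t$cds_first_base)
  if (k <= 1L) integer() else pos[seq_len(k - 1L)]
}

# reference-consuming span of a CIGAR, walked operator by operator
oracle_cigar_ref_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  tot <- 0L
  for (o in ops) {
    n <- as.integer(sub(".$", "", o))
    if (grepl("[MDN=X]$", o)) tot <- tot + n
  }
  tot
}

# per-read brute-force 5'-end tally from an alignment table
oracle_5p_tally <- function(aln) {
  prim <- aln[bitwAnd(aln$flag, 4L + 256L + 2048L) == 0L, , drop = FALSE]
  reflen <- vapply(prim$cigar, oracle_cigar_ref_len, integer(1L))
  p5 <- ifelse(prim$strand == "+", prim$pos, prim$pos + reflen - 1L)
  bf <- aggregate(list(count = rep(1L, nrow(prim))),
                  by = data.frame(chrom = prim$chrom, pos = p5,
                                  strand = prim$strand,
                                  stringsAsFactors = FALSE),
                  FUN = sum)
  bf <- bf[order(bf$chrom, bf$strand, bf$pos), , drop = FALSE]
  rownames(bf) <- NULL
  bf
}

# per-strand single-base expansion of `bedtools genomecov -5 -bg` output
oracle_bedtools_5p <- function(bam, strand) {
  out <- system2("bedtools", c("genomecov", "-5", "-bg", "-strand", strand,
                               "-ibam", bam), stdout = TRUE)
  if (length(out) == 0L)
    return(data.frame(chrom = character(), pos = integer(),
                      count = integer()))
  bt <- read.table(text = out, stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "count"))
  ex <- do.call(rbind, lapply(seq_len(nrow(bt)), function(i)
    data.frame(chrom = bt$chrom[i], pos = seq(bt$start[i] + 1L, bt$end[i]),
               count = bt$count[i], stringsAsFactors = FALSE)))
  ex <- ex[order(ex$chrom, ex$pos), , drop = FALSE]
  rownames(ex) <- NULL
  ex
}

# exact two-sided rank-sum p by enumerating every C(n1+n2, n1) labeling
oracle_ranksum_exact <- function(a, b) {
  x <- c(a, b)
  n1 <- length(a)
  r <- rank(x)
  combos <- utils::combn(length(x), n1)
  Us <- apply(combos, 2L, function(idx) sum(r[idx])) - n1 * (n1 + 1) / 2
  uobs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  min(1, 2 * min(mean(Us <= uobs), mean(Us >= uobs)))
}

# minimal GENCODE-style GTF writer for hand-built cases
write_test_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}

gtf_row <- function(chrom, type, start, end, strand, gene, tx,
                    name = gene, tag = NULL) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                   gene, tx, name)
  if (!is.null(tag)) attrs <- paste0(attrs, sprintf(' tag "%s";', tag))
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
          chrom, type, start, end, strand, attrs)
}

# the two-exon worked geometry used in several places
two_exon_plus <- function() {
  transcript_model("TXP", "GP", "GENEP", "chr1", "+",
                   c(101L, 201L), c(150L, 250L),
                   cds_first_base = 221L, cds_last_base = 250L)
}
two_exon_minus <- function() {
  transcript_model("TXM", "GM", "GENEM", "chr1", "-",
                   c(101L, 201L), c(150L, 250L),
                   cds_first_base = 130L, cds_last_base = 101L)
}
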