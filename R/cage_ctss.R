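# CAGE transcription start site (CTSS) calling and alternative-promoter
# classification. Each read marks one capped 5' end: plus-strand reads at
# their lowest aligned reference base, minus-strand reads at their highest
# (the semantics of `bedtools genomecov -5 -bg` on the alignment span, soft
# clips excluded).

#' CTSS filter configuration
#'
#' Thresholds are applied inclusively (`>=`).
#'
#' @param min_tpm minimum tags-per-million (default 1.0).
#' @param min_count minimum raw read count (default 5).
#' @return list of class `ctss_filter_config`.
#' @export
ctss_filter_config <- function(min_tpm = 1.0, min_count = 5L) {
  stopifnot(min_tpm >= 0, min_count >= 0)
  structure(list(min_tpm = min_tpm, min_count = as.integer(min_count)),
            class = "ctss_filter_config")
}

#' Tally read 5' ends from a BAM file or stranded bedGraph pair
#'
#' Unmapped, secondary and supplementary alignments are skipped (and
#' counted); duplicates are kept. The 5' end is taken from the aligned span,
#' so soft-clipped bases do not shift it.
#'
#' @param bam path to a BAM file (indexed or streamable).
#' @param bedgraph_plus,bedgraph_minus alternative input: a pair of
#'   per-strand bedGraph files of 5'-end counts (0-based half-open).
#' @param min_mapq minimum mapping quality (default 0 = keep all mapped).
#' @return list with `tally` (data.frame `chrom`,`pos`,`strand`,`count`;
#'   `pos` 1-based), `total_mapped` (accepted read count) and `n_skipped`.
#' @export
extract_five_prime_ends <- function(bam = NULL, bedgraph_plus = NULL,
                                    bedgraph_minus = NULL, min_mapq = 0L) {
  if (!is.null(bam)) {
    if (!file.exists(bam)) stop("BAM file not found: ", bam)
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSecondaryAlignment = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq)
    aln <- GenomicAlignments::readGAlignments(bam, param = param)
    n_total <- Rsamtools::countBam(bam)$records
    strand <- as.character(GenomicAlignments::strand(aln))
    pos <- ifelse(strand == "+", GenomicAlignments::start(aln),
                  GenomicAlignments::end(aln))
    tal <- data.frame(
      chrom = as.character(GenomicAlignments::seqnames(aln)),
      pos = as.integer(pos), strand = strand, stringsAsFactors = FALSE)
    agg <- stats::aggregate(list(count = rep(1L, nrow(tal))),
                            by = tal[c("chrom", "pos", "strand")], FUN = sum)
    agg <- agg[order(agg$chrom, agg$strand, agg$pos), , drop = FALSE]
    rownames(agg) <- NULL
    if (nrow(tal) == 0L)
      agg <- data.frame(chrom = character(), pos = integer(),
                        strand = character(), count = integer())
    return(list(tally = agg, total_mapped = length(aln),
                n_skipped = n_total - length(aln)))
  }
  if (is.null(bedgraph_plus) || is.null(bedgraph_minus))
    stop("provide either a BAM file or both stranded bedGraph files")
  read_bg <- function(path, strand) {
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L)
      return(data.frame(chrom = character(), pos = integer(),
                        strand = character(), count = integer()))
    # expand multi-base intervals to single positions
    w <- GenomicRanges::width(gr)
    chrom <- rep(as.character(GenomicRanges::seqnames(gr)), w)
    pos <- unlist(mapply(seq, GenomicRanges::start(gr),
                         GenomicRanges::end(gr), SIMPLIFY = FALSE))
    data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
               count = as.integer(rep(gr$score, w)), stringsAsFactors = FALSE)
  }
  tal <- rbind(read_bg(bedgraph_plus, "+"), read_bg(bedgraph_minus, "-"))
  tal <- tal[order(tal$chrom, tal$strand, tal$pos), , drop = FALSE]
  rownames(tal) <- NULL
  list(tally = tal, total_mapped = sum(tal$count), n_skipped = 0L)
}

#' Convert raw CTSS counts to tags per million
#'
#' `tpm = count / total_mapped * 1e6`.
#'
#' @param tally data.frame `chrom`,`pos`,`strand`,`count`.
#' @param total_mapped accepted read count (> 0).
#' @return the tally with a `tpm` column appended.
#' @export
normalize_tpm <- function(tally, total_mapped) {
  if (is.null(total_mapped) || total_mapped <= 0)
    stop("total_mapped must be positive to normalize to TPM")
  tally$tpm <- tally$count / total_mapped * 1e6
  tally
}

#' Filter CTSS records on TPM and raw count
#'
#' @param records normalized CTSS records (with `tpm`).
#' @param cfg a [ctss_filter_config()].
#' @return surviving records.
#' @export
filter_ctss <- function(records, cfg = ctss_filter_config()) {
  stopifnot(inherits(cfg, "ctss_filter_config"), "tpm" %in% names(records))
  out <- records[records$tpm >= cfg$min_tpm & records$count >= cfg$min_count,
                 , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Signed genomic distance from a start codon to a position, strand-oriented
# (negative = upstream of the start codon).
signed_distance <- function(pos, cds_first_base, strand) {
  ifelse(strand == "+", pos - cds_first_base, cds_first_base - pos)
}

#' Annotate CTSS records against representative start codons
#'
#' Each CTSS is assigned to the same-strand, same-chromosome gene whose
#' start codon is nearest within `max_distance` (ties: smaller absolute
#' distance, then lexicographically smaller gene_id). The signed distance is
#' genomic and strand-oriented (negative = upstream of the start codon). The
#' implied 5' UTR length is spliced: for a CTSS inside the representative
#' transcript's exons it is the number of exonic bases from the CTSS up to
#' (excluding) the start codon; for a CTSS upstream of the transcript 5'
#' end it is the annotated UTR length plus the genomic gap (the new 5'
#' extension is unspliced); for an intronic CTSS it is `NA`.
#'
#' @param records filtered CTSS records.
#' @param representatives named list gene_id -> coding [transcript_model()].
#' @param max_distance maximum assignment distance in nt (default 50000).
#' @return data.frame with the CTSS fields plus `gene_id`,
#'   `signed_distance_nt`, `implied_utr5_length_nt`, `annotated_utr5_nt`.
#' @export
annotate_ctss <- function(records, representatives, max_distance = 50000L) {
  stopifnot(max_distance > 0)
  idx <- data.frame(
    gene_id = names(representatives),
    chrom = vapply(representatives, `[[`, character(1L), "chrom"),
    strand = vapply(representatives, `[[`, character(1L), "strand"),
    cfb = vapply(representatives, `[[`, integer(1L), "cds_first_base"),
    utr = vapply(representatives, compute_utr5_length, integer(1L)),
    stringsAsFactors = FALSE)

  n <- nrow(records)
  gene_id <- rep(NA_character_, n)
  sdist <- rep(NA_integer_, n)
  implied <- rep(NA_integer_, n)
  ann_utr <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    cand <- idx[idx$chrom == records$chrom[i] &
                idx$strand == records$strand[i], , drop = FALSE]
    if (nrow(cand) == 0L) next
    d <- signed_distance(records$pos[i], cand$cfb, cand$strand)
    keep <- abs(d) <= max_distance
    if (!any(keep)) next
    cand <- cand[keep, , drop = FALSE]
    d <- d[keep]
    o <- order(abs(d), cand$gene_id)
    g <- cand$gene_id[o[1L]]
    gene_id[i] <- g
    sdist[i] <- as.integer(d[o[1L]])
    ann_utr[i] <- cand$utr[o[1L]]
    t <- representatives[[g]]
    implied[i] <- implied_utr5_length(t, records$pos[i], sdist[i])
  }
  records$gene_id <- gene_id
  records$signed_distance_nt <- sdist
  records$implied_utr5_length_nt <- implied
  records$annotated_utr5_nt <- ann_utr
  records
}

# Implied (spliced) 5' UTR length of a transcript if it started at `pos`;
# NA when downstream of the start codon or intronic.
implied_utr5_length <- function(t, pos, sdist) {
  if (sdist > 0L) return(NA_integer_)
  s_pos <- genomic_to_spliced(t, pos)
  if (!is.na(s_pos)) {
    s_cds <- genomic_to_spliced(t, t$cds_first_base)
    return(as.integer(s_cds - s_pos))
  }
  tss <- transcript_tss(t)
  gap <- if (t$strand == "+") tss - pos else pos - tss
  if (gap > 0L)  # upstream of the annotated transcript 5' end
    return(as.integer(compute_utr5_length(t) + gap))
  NA_integer_  # intronic
}

#' Classify annotated CTSS records into TSS classes
#'
#' Classes: `annotated` (implied UTR within `tolerance` of the annotated
#' UTR), `utr_lengthening`, `utr_shortening`, `cds_truncating` (downstream
#' of the start codon) and `unassigned` (no gene within range). For intronic
#' CTSS (no spliced implied length) the genomic upstream distance stands in
#' for the implied UTR length.
#'
#' @param ann output of [annotate_ctss()].
#' @param tolerance nt window around the annotated UTR length treated as the
#'   annotated promoter (default 10).
#' @return `ann` with a `tss_class` column.
#' @export
classify_tss <- function(ann, tolerance = 10L) {
  stopifnot(tolerance >= 0)
  n <- nrow(ann)
  cls <- character(n)
  for (i in seq_len(n)) {
    if (is.na(ann$gene_id[i])) { cls[i] <- "unassigned"; next }
    if (ann$signed_distance_nt[i] > 0L) { cls[i] <- "cds_truncating"; next }
    imp <- ann$implied_utr5_length_nt[i]
    if (is.na(imp)) imp <- -ann$signed_distance_nt[i]  # intronic fallback
    a <- ann$annotated_utr5_nt[i]
    cls[i] <- if (abs(imp - a) <= tolerance) "annotated"
      else if (imp > a) "utr_lengthening" else "utr_shortening"
  }
  ann$tss_class <- cls
  ann
}

#' Summarize per-gene promoter usage
#'
#' Read counts are summed per TSS class and alternative usage is expressed
#' relative to the annotated start site, as a ratio of summed read counts.
#'
#' @param ann classified annotations (from [classify_tss()]).
#' @return data.frame per gene: `gene_id`, `reads_annotated`,
#'   `reads_utr_lengthening`, `reads_utr_shortening`, `reads_cds_truncating`,
#'   `reads_alternative` (their sum), `alt_ratio` and `ratio_defined`
#'   (`FALSE`, with `alt_ratio = NA`, when no annotated reads exist).
#' @export
promoter_usage <- function(ann) {
  ann <- ann[!is.na(ann$gene_id), , drop = FALSE]
  alt_classes <- c("utr_lengthening", "utr_shortening", "cds_truncating")
  rows <- lapply(split(ann, ann$gene_id), function(d) {
    cnt <- function(cl) sum(d$count[d$tss_class == cl])
    annotated <- cnt("annotated")
    alt <- vapply(alt_classes, cnt, numeric(1L))
    data.frame(gene_id = d$gene_id[1L],
               reads_annotated = annotated,
               reads_utr_lengthening = alt[[1L]],
               reads_utr_shortening = alt[[2L]],
               reads_cds_truncating = alt[[3L]],
               reads_alternative = sum(alt),
               alt_ratio = if (annotated > 0) sum(alt) / annotated else NA_real_,
               ratio_defined = annotated > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), reads_annotated = numeric(),
                      reads_utr_lengthening = numeric(),
                      reads_utr_shortening = numeric(),
                      reads_cds_truncating = numeric(),
                      reads_alternative = numeric(), alt_ratio = numeric(),
                      ratio_defined = logical())
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write CTSS records and annotations
#'
#' Emits `ctss.plus.bedGraph` and `ctss.minus.bedGraph` (0-based half-open,
#' width-1 intervals, count as score) and `ctss_annotated.tsv`.
#'
#' @param records CTSS records (`chrom`,`pos`,`strand`,`count`, optionally
#'   `tpm`).
#' @param dir output directory.
#' @param annotations optional classified annotation table.
#' @return (invisibly) the paths written.
#' @export
write_ctss <- function(records, dir, annotations = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (s in c("+", "-")) {
    d <- records[records$strand == s, , drop = FALSE]
    d <- d[order(d$chrom, d$pos), , drop = FALSE]
    bg <- data.frame(chrom = d$chrom, start = d$pos - 1L, end = d$pos,
                     score = d$count)
    p <- file.path(dir, sprintf("ctss.%s.bedGraph",
                                if (s == "+") "plus" else "minus"))
    write.table(bg, p, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(annotations)) {
    p <- file.path(dir, "ctss_annotated.tsv")
    write.table(annotations, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a per-strand CTSS bedGraph pair back into records
#' @param plus,minus bedGraph paths written by [write_ctss()].
#' @return data.frame `chrom`,`pos`,`strand`,`count`.
#' @export
read_ctss <- function(plus, minus) {
  extract_five_prime_ends(bedgraph_plus = plus, bedgraph_minus = minus)$tally
}
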