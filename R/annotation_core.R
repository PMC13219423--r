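#' @import methods
#' @importFrom stats rbinom rgeom rnorm runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

# ---- TranscriptModel -------------------------------------------------------

#' Construct a transcript model
#'
#' A `transcript_model` captures stranded multi-exon transcript geometry:
#' exons as 1-based closed genomic intervals (stored ascending, pairwise
#' disjoint) plus the genomic coordinates of the first and last CDS base in
#' transcript orientation. On the minus strand the transcript 5' end is the
#' maximal exon coordinate and `cds_first_base` is the maximal CDS
#' coordinate.
#'
#' @param transcript_id,gene_id,gene_name identifiers.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of equal length (1-based,
#'   closed intervals).
#' @param cds_first_base genomic coordinate of the first base of the start
#'   codon, or `NA` for non-coding transcripts.
#' @param cds_last_base genomic coordinate of the last CDS base in transcript
#'   orientation, or `NA`.
#' @param tags character vector of annotation tags (e.g. `"MANE_Select"`).
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_name, chrom, strand,
                             exon_starts, exon_ends,
                             cds_first_base = NA_integer_,
                             cds_last_base = NA_integer_,
                             tags = character()) {
  stopifnot(length(exon_starts) == length(exon_ends),
            length(exon_starts) >= 1L,
            strand %in% c("+", "-"))
  o <- order(exon_starts)
  exon_starts <- as.integer(exon_starts[o])
  exon_ends <- as.integer(exon_ends[o])
  if (any(exon_ends < exon_starts))
    stop("exon end precedes start in transcript ", transcript_id)
  if (length(exon_starts) > 1L &&
      any(exon_starts[-1L] <= exon_ends[-length(exon_ends)]))
    stop("overlapping or unsorted exons in transcript ", transcript_id)
  t <- structure(list(
    transcript_id = as.character(transcript_id),
    gene_id = as.character(gene_id),
    gene_name = as.character(gene_name),
    chrom = as.character(chrom),
    strand = strand,
    exon_starts = exon_starts,
    exon_ends = exon_ends,
    cds_first_base = as.integer(cds_first_base),
    cds_last_base = as.integer(cds_last_base),
    tags = as.character(tags)
  ), class = "transcript_model")
  for (p in c("cds_first_base", "cds_last_base")) {
    b <- t[[p]]
    if (!is.na(b) && !any(b >= exon_starts & b <= exon_ends))
      stop("CDS coordinate ", b, " outside exons in transcript ",
           transcript_id)
  }
  t
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s/%s) %s:%s %d exon(s), %s\n",
              x$transcript_id, x$gene_id, x$gene_name, x$chrom, x$strand,
              length(x$exon_starts),
              if (is_coding(x)) "coding" else "non-coding"))
  invisible(x)
}

#' Is a transcript model protein coding?
#' @param t a `transcript_model`.
#' @return `TRUE` if a CDS is annotated.
#' @export
is_coding <- function(t) !is.na(t$cds_first_base)

#' Spliced exonic length of a transcript
#' @param t a `transcript_model`.
#' @return integer number of exonic bases.
#' @export
spliced_length <- function(t) sum(t$exon_ends - t$exon_starts + 1L)

# Spliced CDS length (bases between cds_first_base and cds_last_base
# inclusive, restricted to exons).
spliced_cds_length <- function(t) {
  if (!is_coding(t)) return(0L)
  lo <- min(t$cds_first_base, t$cds_last_base)
  hi <- max(t$cds_first_base, t$cds_last_base)
  sum(pmax(0L, pmin(t$exon_ends, hi) - pmax(t$exon_starts, lo) + 1L))
}

#' Map a genomic position to its 1-based spliced transcript coordinate
#'
#' Position 1 is the transcript 5' end (the maximal exonic coordinate on the
#' minus strand).
#'
#' @param t a `transcript_model`.
#' @param pos genomic coordinate(s).
#' @return integer vector; `NA` where `pos` is not exonic.
#' @export
genomic_to_spliced <- function(t, pos) {
  vapply(pos, function(p) {
    hit <- which(p >= t$exon_starts & p <= t$exon_ends)
    if (length(hit) == 0L) return(NA_integer_)
    if (t$strand == "+") {
      before <- if (hit > 1L)
        sum(t$exon_ends[seq_len(hit - 1L)] - t$exon_starts[seq_len(hit - 1L)] + 1L)
        else 0L
      as.integer(before + (p - t$exon_starts[hit] + 1L))
    } else {
      n <- length(t$exon_starts)
      after <- if (hit < n)
        sum(t$exon_ends[(hit + 1L):n] - t$exon_starts[(hit + 1L):n] + 1L)
        else 0L
      as.integer(after + (t$exon_ends[hit] - p + 1L))
    }
  }, integer(1L))
}

#' Map a 1-based spliced transcript coordinate back to genomic space
#'
#' Inverse of [genomic_to_spliced()].
#'
#' @param t a `transcript_model`.
#' @param s spliced coordinate(s), 1 = transcript 5' end.
#' @return integer genomic coordinates; `NA` where `s` is out of range.
#' @export
spliced_to_genomic <- function(t, s) {
  widths <- t$exon_ends - t$exon_starts + 1L
  total <- sum(widths)
  vapply(s, function(p) {
    if (is.na(p) || p < 1L || p > total) return(NA_integer_)
    if (t$strand == "+") {
      cum <- cumsum(widths)
      i <- which(p <= cum)[1L]
      before <- if (i > 1L) cum[i - 1L] else 0L
      as.integer(t$exon_starts[i] + (p - before - 1L))
    } else {
      rev_w <- rev(widths)
      cum <- cumsum(rev_w)
      j <- which(p <= cum)[1L]
      before <- if (j > 1L) cum[j - 1L] else 0L
      i <- length(widths) - j + 1L
      as.integer(t$exon_ends[i] - (p - before - 1L))
    }
  }, integer(1L))
}

#' Genomic coordinate of the transcript 5' end
#' @param t a `transcript_model`.
#' @return integer genomic coordinate.
#' @export
transcript_tss <- function(t) {
  if (t$strand == "+") t$exon_starts[1L] else t$exon_ends[length(t$exon_ends)]
}

# ---- GTF parsing -----------------------------------------------------------

#' Parse a GTF file into transcript models
#'
#' Reads exon and CDS features (GENCODE-style attributes) and assembles one
#' [transcript_model()] per `transcript_id`. CDS boundaries are resolved
#' strand-aware: `cds_first_base` is the 5'-most CDS base in transcript
#' orientation. Transcripts without CDS features are kept and flagged
#' non-coding. `tag` attributes (e.g. `MANE_Select`) are collected.
#'
#' @param path GTF file path.
#' @param dialect `"gencode"` or `"generic"`; both are parsed by
#'   [rtracklayer::import()], the dialect only controls whether `tag` and
#'   `gene_name` attributes are expected.
#' @return A named list of `transcript_model` objects (names =
#'   transcript_id), with attribute `n_noncoding`.
#' @export
parse_gtf <- function(path, dialect = c("gencode", "generic")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gtf"),
    error = function(e) stop("malformed GTF '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  if (!all(c("type", "transcript_id", "gene_id") %in% colnames(md)))
    stop("GTF lacks required attributes transcript_id/gene_id: ", path)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0L) return(structure(list(), n_noncoding = 0L))
  gene_name <- if ("gene_name" %in% colnames(md)) md$gene_name else md$gene_id
  gene_name <- ifelse(is.na(gene_name), md$gene_id, gene_name)
  tag <- if ("tag" %in% colnames(md)) md$tag else rep(NA_character_, length(gr))

  df <- data.frame(
    tx = md$transcript_id, gene = md$gene_id, name = gene_name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    type = md$type, tag = as.character(tag),
    stringsAsFactors = FALSE)
  if (anyNA(df$tx)) stop("GTF exon/CDS row without transcript_id: ", path)

  out <- list()
  n_noncoding <- 0L
  for (rows in split(seq_len(nrow(df)), df$tx)) {
    d <- df[rows, , drop = FALSE]
    ex <- d[d$type == "exon", , drop = FALSE]
    cds <- d[d$type == "CDS", , drop = FALSE]
    if (nrow(ex) == 0L)  # CDS-only entry: treat CDS spans as exonic
      ex <- cds
    strand <- ex$strand[1L]
    if (!strand %in% c("+", "-"))
      stop("transcript ", d$tx[1L], " has unstranded features")
    cfb <- clb <- NA_integer_
    if (nrow(cds) > 0L) {
      if (strand == "+") {
        cfb <- min(cds$start); clb <- max(cds$end)
      } else {
        cfb <- max(cds$end); clb <- min(cds$start)
      }
    } else {
      n_noncoding <- n_noncoding + 1L
    }
    tags <- unique(d$tag[!is.na(d$tag)])
    m <- tryCatch(
      transcript_model(d$tx[1L], d$gene[1L], d$name[1L], ex$chrom[1L], strand,
                       ex$start, ex$end, cfb, clb, tags),
      error = function(e) stop("invalid transcript ", d$tx[1L], " in ", path,
                               ": ", conditionMessage(e), call. = FALSE))
    # CDS bases must all be exonic
    if (nrow(cds) > 0L) {
      inside <- vapply(seq_len(nrow(cds)), function(i) {
        any(cds$start[i] >= m$exon_starts & cds$end[i] <= m$exon_ends)
      }, logical(1L))
      if (!all(inside))
        stop("CDS outside exons in transcript ", d$tx[1L])
    }
    out[[m$transcript_id]] <- m
  }
  structure(out, n_noncoding = n_noncoding)
}

# ---- 5' UTR geometry -------------------------------------------------------

#' Spliced 5' UTR length of a coding transcript
#'
#' Counts exonic bases strictly 5' of the start codon in transcript
#' orientation (the spliced leader length).
#'
#' @param t a coding `transcript_model`.
#' @return integer length in nt (0 when transcription starts at the AUG).
#' @export
compute_utr5_length <- function(t) {
  if (!is_coding(t))
    stop("5' UTR length undefined for non-coding transcript ",
         t$transcript_id)
  if (t$strand == "+") {
    sum(pmax(0L, pmin(t$exon_ends, t$cds_first_base - 1L) - t$exon_starts + 1L))
  } else {
    sum(pmax(0L, t$exon_ends - pmax(t$exon_starts, t$cds_first_base + 1L) + 1L))
  }
}

#' Genomic intervals covering the 5' UTR
#'
#' @param t a coding `transcript_model`.
#' @return A list with `transcript_id`, `strand`, `intervals` (data.frame
#'   `start`,`end`, 1-based closed, ascending; zero rows for a 0 nt UTR) and
#'   `total_nt`.
#' @export
build_utr5_intervals <- function(t) {
  if (!is_coding(t))
    stop("5' UTR intervals undefined for non-coding transcript ",
         t$transcript_id)
  if (t$strand == "+") {
    s <- t$exon_starts
    e <- pmin(t$exon_ends, t$cds_first_base - 1L)
  } else {
    s <- pmax(t$exon_starts, t$cds_first_base + 1L)
    e <- t$exon_ends
  }
  keep <- e >= s
  iv <- data.frame(start = as.integer(s[keep]), end = as.integer(e[keep]))
  list(transcript_id = t$transcript_id, strand = t$strand,
       chrom = t$chrom, intervals = iv,
       total_nt = as.integer(sum(iv$end - iv$start + 1L)))
}

# ---- Expression and representative-transcript selection --------------------

#' Load Kallisto-style abundance tables
#'
#' Each file must have columns `target_id` and `tpm`. Multiple files are
#' joined on `target_id` (missing transcripts zero-filled) and averaged
#' with equal weight per sample.
#'
#' @param paths character vector of TSV paths.
#' @return data.frame with `transcript_id`, one `tpm.*` column per sample and
#'   `mean_tpm`.
#' @export
load_expression <- function(paths) {
  stopifnot(length(paths) >= 1L)
  tabs <- lapply(paths, function(p) {
    d <- read.delim(p, stringsAsFactors = FALSE)
    if (!all(c("target_id", "tpm") %in% names(d)))
      stop("abundance file lacks target_id/tpm columns: ", p)
    d[, c("target_id", "tpm")]
  })
  ids <- unique(unlist(lapply(tabs, `[[`, "target_id")))
  out <- data.frame(transcript_id = ids, stringsAsFactors = FALSE)
  for (i in seq_along(tabs)) {
    v <- setNames(tabs[[i]]$tpm, tabs[[i]]$target_id)[ids]
    v[is.na(v)] <- 0
    out[[paste0("tpm.", i)]] <- as.numeric(v)
  }
  out$mean_tpm <- rowMeans(out[, grep("^tpm\\.", names(out)), drop = FALSE])
  out
}

mean_abundance <- function(expr, transcript_id) {
  if (is.null(expr)) return(0)
  v <- expr$mean_tpm[match(transcript_id, expr$transcript_id)]
  ifelse(is.na(v), 0, v)
}

#' Select one representative transcript per gene
#'
#' Three strategies: `highest_expressed` picks the transcript with the
#' largest mean abundance (falling back to the longest spliced transcript
#' when no isoform of the gene is expressed); `mane_select` picks the
#' MANE_Select-tagged transcript (no tag: `NA` is returned and the gene
#' should be excluded); `longest_cds` picks the largest spliced CDS. Ties
#' break deterministically: longer spliced transcript, then lexicographically
#' smaller transcript_id.
#'
#' @param gene list of `transcript_model` objects belonging to one gene.
#' @param expr expression table from [load_expression()] (required for
#'   `highest_expressed`).
#' @param strategy selection strategy.
#' @return a transcript_id, or `NA_character_` when `mane_select` finds no
#'   tagged transcript.
#' @export
select_representative <- function(gene, expr = NULL,
                                  strategy = c("highest_expressed",
                                               "mane_select", "longest_cds")) {
  strategy <- match.arg(strategy)
  stopifnot(length(gene) >= 1L)
  ids <- vapply(gene, `[[`, character(1L), "transcript_id")
  splen <- vapply(gene, spliced_length, integer(1L))
  pick <- function(score) {
    # argmax with tie-break: longer spliced transcript, then smaller id
    o <- order(-score, -splen, ids)
    ids[o[1L]]
  }
  switch(strategy,
    highest_expressed = {
      if (is.null(expr))
        stop("highest_expressed strategy requires an expression table")
      ab <- mean_abundance(expr, ids)
      if (all(ab == 0)) pick(as.numeric(splen)) else pick(ab)
    },
    mane_select = {
      mane <- vapply(gene, function(t) "MANE_Select" %in% t$tags, logical(1L))
      if (!any(mane)) return(NA_character_)
      pick(as.numeric(mane))
    },
    longest_cds = {
      pick(as.numeric(vapply(gene, spliced_cds_length, integer(1L))))
    })
}

# ---- Kozak context ---------------------------------------------------------

#' Classify the Kozak context around an AUG
#'
#' The 10 nt window covers positions -6..-1 and +1..+4 (the A of the AUG is
#' +1). Strength is determined by the two dominant positions: a purine (A/G)
#' at -3 and a G at +4. Both determinants: `strong`; exactly one:
#' `moderate`; neither: `weak`.
#'
#' @param context 10 nt string; `T` is accepted for `U`; positions 7-9 must
#'   be the AUG. `N` never counts as a determinant.
#' @return one of `"strong"`, `"moderate"`, `"weak"`.
#' @export
classify_kozak <- function(context) {
  context <- toupper(gsub("T", "U", toupper(context)))
  if (nchar(context) != 10L)
    stop("Kozak context must be 10 nt (-6..+4), got ", nchar(context))
  if (substr(context, 7L, 9L) != "AUG")
    stop("positions +1..+3 of the context must be AUG, got ",
         substr(context, 7L, 9L))
  m3 <- substr(context, 4L, 4L)   # position -3
  p4 <- substr(context, 10L, 10L) # position +4
  hits <- (m3 %in% c("A", "G")) + (p4 == "G")
  c("weak", "moderate", "strong")[hits + 1L]
}

#' Extract the -6..+4 Kozak window of a transcript from genome sequence
#'
#' @param t a coding `transcript_model`.
#' @param genome a named [Biostrings::DNAStringSet] (names = chromosomes).
#' @return 10-character RNA string, left-padded with `N` when the 5' UTR is
#'   shorter than 6 nt.
#' @export
kozak_context <- function(t, genome) {
  if (!is_coding(t)) stop("Kozak context undefined for non-coding transcript")
  seq <- spliced_sequence(t, genome)
  ulen <- compute_utr5_length(t)
  pad <- max(0L, 6L - ulen)  # UTRs shorter than 6 nt: left-pad with N
  padded <- paste0(strrep("N", pad), seq)
  win <- substr(padded, ulen - 5L + pad, ulen + 4L + pad)
  gsub("T", "U", toupper(win))
}

#' Spliced transcript sequence from a genome
#' @param t a `transcript_model`.
#' @param genome a named [Biostrings::DNAStringSet].
#' @return character string in transcript orientation (5'->3').
#' @export
spliced_sequence <- function(t, genome) {
  if (!t$chrom %in% names(genome))
    stop("chromosome ", t$chrom, " absent from genome")
  chr <- genome[[t$chrom]]
  pieces <- mapply(function(s, e) as.character(Biostrings::subseq(chr, s, e)),
                   t$exon_starts, t$exon_ends)
  seq <- paste(pieces, collapse = "")
  if (t$strand == "-")
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  seq
}

# ---- Short-UTR gene sets ---------------------------------------------------

#' Per-gene 5' UTR lengths and the short-UTR gene set
#'
#' @param models named list of `transcript_model` objects.
#' @param representatives named character vector, gene_id -> transcript_id
#'   (entries with `NA` or ids absent from `models` are skipped).
#' @param threshold inclusive short-UTR cutoff in nt (default 40).
#' @return list with `table` (gene_id, gene_name, transcript_id,
#'   utr5_length_nt, is_short) and `genes` (sorted gene_ids with
#'   utr5_length <= threshold).
#' @export
short_utr_gene_set <- function(models, representatives, threshold = 40L) {
  stopifnot(threshold > 0)
  reps <- representatives[!is.na(representatives)]
  reps <- reps[reps %in% names(models)]
  rows <- lapply(names(reps), function(g) {
    t <- models[[reps[[g]]]]
    if (!is_coding(t)) return(NULL)
    len <- compute_utr5_length(t)
    data.frame(gene_id = g, gene_name = t$gene_name,
               transcript_id = t$transcript_id,
               utr5_length_nt = len, is_short = len <= threshold,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(gene_id = character(), gene_name = character(),
                      transcript_id = character(),
                      utr5_length_nt = integer(), is_short = logical())
  tab <- tab[order(tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, genes = sort(tab$gene_id[tab$is_short]))
}

#' Group transcript models by gene
#' @param models named list of `transcript_model` objects.
#' @return named list: gene_id -> list of models.
#' @export
group_by_gene <- function(models) {
  split(models, vapply(models, `[[`, character(1L), "gene_id"))
}

#' Select representatives for every gene
#' @inheritParams select_representative
#' @param models named list of `transcript_model` objects.
#' @return named character vector gene_id -> transcript_id (`NA` where the
#'   strategy yields no candidate).
#' @export
select_representatives <- function(models, expr = NULL,
                                   strategy = "highest_expressed") {
  by_gene <- group_by_gene(models)
  vapply(by_gene, select_representative, character(1L),
         expr = expr, strategy = strategy)
}

#' Write the UTR tables the downstream modules consume
#'
#' Emits `utr_lengths.tsv` and `utr_intervals.bed` (BED6, 0-based half-open,
#' name = transcript_id) into `dir`.
#'
#' @param models named list of `transcript_model` objects.
#' @param representatives gene_id -> transcript_id map.
#' @param dir output directory.
#' @param threshold short-UTR cutoff (nt).
#' @param genome optional `DNAStringSet` to add a `kozak_class` column.
#' @return (invisibly) the per-gene table.
#' @export
write_utr_tables <- function(models, representatives, dir, threshold = 40L,
                             genome = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  res <- short_utr_gene_set(models, representatives, threshold)
  tab <- res$table
  if (!is.null(genome) && nrow(tab) > 0L) {
    tab$kozak_class <- vapply(tab$transcript_id, function(id) {
      classify_kozak(kozak_context(models[[id]], genome))
    }, character(1L))
  }
  write.table(tab, file.path(dir, "utr_lengths.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bed <- do.call(rbind, lapply(tab$transcript_id, function(id) {
    u <- build_utr5_intervals(models[[id]])
    if (nrow(u$intervals) == 0L) return(NULL)
    data.frame(chrom = u$chrom, start = u$intervals$start - 1L,
               end = u$intervals$end, name = id, score = 0L,
               strand = u$strand, stringsAsFactors = FALSE)
  }))
  if (is.null(bed))
    bed <- data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = integer(),
                      strand = character())
  write.table(bed, file.path(dir, "utr_intervals.bed"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(tab)
}
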