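# Seeded synthetic-data generator: toy annotation + genome, CAGE tag
# pileups with known promoter weights, initiation-site tables under a known
# leaky-scanning model, and variant tables with well-formed HGVS names.
# Every draw is recorded in a truth manifest so downstream operations can be
# scored without re-simulation.

# Per-stage PRNG fork: one base seed, fixed label offsets, so adding a stage
# never perturbs earlier stages' draws.
.stage_seed <- function(seed, stage) {
  offsets <- c(reference = 1L, cage = 2L, initiation = 3L, variants = 4L,
               alignments = 5L)
  if (!stage %in% names(offsets)) stop("unknown PRNG stage: ", stage)
  (as.integer(seed) %% 10000000L) * 97L + offsets[[stage]]
}

#' Synthetic-study configuration
#'
#' Defaults describe the study conditions every simulation emulates: 5' UTR
#' lengths drawn from a short/long mixture (geometric-like over 1..40 nt
#' with weight `short_utr_weight`, else a shifted exponential over
#' 41..500 nt, matching a genome where roughly a third of genes sit in the
#' short-UTR regime and the long tail averages near 200 nt); per-gene
#' annotated/alternative promoter weights; N(0, jitter) positional noise and
#' uniform background on CAGE tags; a leaky-scanning model in which the
#' probability of producing an N-terminally truncated isoform is
#' `p_trunc_short` for UTRs <= 40 nt and `p_trunc_long` otherwise; and a
#' variant generator in which most indels are 1-2 nt with a heavy tail of
#' >= 10 nt events.
#'
#' @param seed integer seed; all stages fork from it by fixed labels.
#' @param n_genes number of toy genes.
#' @param strand_fraction_plus fraction of genes on the plus strand.
#' @param short_utr_weight mixture weight of the short (<= 40 nt) component.
#' @param w_annotated,w_alt per-gene promoter weights (normalized).
#' @param cage_depth total non-background CAGE tags across genes.
#' @param jitter_sd_nt SD of positional jitter on tag 5' ends (nt).
#' @param background_rate fraction of tags drawn uniformly over gene loci
#'   (must be < 1).
#' @param p_trunc_short,p_trunc_long truncation probabilities by UTR regime.
#' @param n_variants number of synthetic variant rows.
#' @param variant_kinds kinds to draw from (equal mix), a subset of
#'   deletion/insertion/duplication/indel.
#' @param fraction_in_utr fraction of variants placed wholly inside 5' UTRs.
#' @param emit_fasta whether [build_toy_reference()] should also write a
#'   genome FASTA.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_genes = 60L, strand_fraction_plus = 0.5,
                         short_utr_weight = 0.35,
                         w_annotated = 0.7, w_alt = 0.3,
                         cage_depth = 50000L, jitter_sd_nt = 0,
                         background_rate = 0,
                         p_trunc_short = 0.5, p_trunc_long = 0.1,
                         n_variants = 200L,
                         variant_kinds = c("deletion", "insertion",
                                           "duplication", "indel"),
                         fraction_in_utr = 0.8,
                         emit_fasta = FALSE) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              strand_fraction_plus = strand_fraction_plus,
              short_utr_weight = short_utr_weight,
              w_annotated = w_annotated, w_alt = w_alt,
              cage_depth = as.integer(cage_depth),
              jitter_sd_nt = jitter_sd_nt,
              background_rate = background_rate,
              p_trunc_short = p_trunc_short, p_trunc_long = p_trunc_long,
              n_variants = as.integer(n_variants),
              variant_kinds = variant_kinds,
              fraction_in_utr = fraction_in_utr,
              emit_fasta = isTRUE(emit_fasta))
  stopifnot(cfg$n_genes >= 1L,
            cfg$strand_fraction_plus >= 0, cfg$strand_fraction_plus <= 1,
            cfg$short_utr_weight >= 0, cfg$short_utr_weight <= 1,
            cfg$w_annotated > 0, cfg$w_alt >= 0,
            cfg$jitter_sd_nt >= 0,
            cfg$p_trunc_short >= 0, cfg$p_trunc_short <= 1,
            cfg$p_trunc_long >= 0, cfg$p_trunc_long <= 1,
            cfg$fraction_in_utr >= 0, cfg$fraction_in_utr <= 1,
            length(cfg$variant_kinds) >= 1L,
            all(cfg$variant_kinds %in%
                c("deletion", "insertion", "duplication", "indel")))
  if (cfg$background_rate < 0 || cfg$background_rate >= 1)
    stop("background_rate must lie in [0, 1)")
  w <- cfg$w_annotated + cfg$w_alt
  cfg$w_annotated <- cfg$w_annotated / w
  cfg$w_alt <- cfg$w_alt / w
  structure(cfg, class = "synth_config")
}

# Draw a 5' UTR length from the short/long mixture.
.draw_utr_len <- function(n, short_weight) {
  short <- runif(n) < short_weight
  len <- integer(n)
  len[short] <- pmin(1L + rgeom(sum(short), 1 / 12), 40L)
  len[!short] <- pmin(41L + as.integer(rexp(sum(!short), 1 / 180)), 500L)
  len
}

#' Build a toy reference annotation (and optionally genome)
#'
#' Lays out non-overlapping genes on toy chromosomes `chrS1..` (10 genes per
#' chromosome, 2 kb gaps), each with a known 5' UTR length, CDS and 3' UTR,
#' introns confined to the CDS/3' region, and an alternative promoter of a
#' known class (`utr_lengthening`, `utr_shortening` where the UTR permits,
#' or `cds_truncating`). When `emit_fasta` is set, each AUG is written into
#' the genome with the Kozak class recorded in the manifest.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory for `toy.gtf` (and `toy.fa`).
#' @return list of class `truth_manifest`: `config`, `gtf`, `fasta`
#'   (or `NULL`), `genes` (per-gene truth: coordinates, true UTR length,
#'   promoter weights, alternative promoter position/class and its implied
#'   UTR length, Kozak class) and `chrom_lengths`.
#' @export
build_toy_reference <- function(cfg, dir = tempfile("synthref")) {
  stopifnot(inherits(cfg, "synth_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(.stage_seed(cfg$seed, "reference"))

  n <- cfg$n_genes
  utr_len <- .draw_utr_len(n, cfg$short_utr_weight)
  cds_len <- 3L * sample(20:120, n, replace = TRUE)
  utr3_len <- sample(30:200, n, replace = TRUE)
  strand <- ifelse(seq_len(n) <= round(n * cfg$strand_fraction_plus),
                   "+", "-")
  kozak <- sample(c("strong", "moderate", "weak"), n, replace = TRUE)
  # a UTR shorter than 3 nt has no -3 position: a purine there (hence a
  # strong context) is not representable in sequence
  kozak[utr_len < 3L & kozak == "strong"] <- "moderate"
  alt_class <- character(n)
  for (i in seq_len(n)) {
    choices <- c("utr_lengthening", "cds_truncating")
    if (utr_len[i] >= 30L) choices <- c(choices, "utr_shortening")
    alt_class[i] <- choices[1L + (i %% length(choices))]
  }

  genes_per_chrom <- 10L
  gap <- 2000L
  rows <- list()
  gtf <- character()
  chrom_lengths <- integer()
  cursor <- gap
  chrom_i <- 1L
  for (i in seq_len(n)) {
    if ((i - 1L) %% genes_per_chrom == 0L && i > 1L) {
      chrom_lengths[paste0("chrS", chrom_i)] <- cursor + gap
      chrom_i <- chrom_i + 1L
      cursor <- gap
    }
    chrom <- paste0("chrS", chrom_i)
    total <- utr_len[i] + cds_len[i] + utr3_len[i]
    # introns only downstream of the 5' UTR (spliced breakpoint > UTR + 10)
    n_introns <- sample(0:2, 1L)
    lo <- utr_len[i] + 10L
    bps <- if (n_introns > 0L && total - 10L > lo + n_introns)
      sort(sample(seq(lo, total - 10L), n_introns)) else integer()
    ilens <- if (length(bps)) sample(60:400, length(bps), replace = TRUE)
             else integer()
    seg <- diff(c(0L, bps, total))  # spliced segment lengths, 5' to 3'
    if (strand[i] == "-") {  # genomic layout runs 3' to 5' on minus strand
      seg <- rev(seg)
      ilens <- rev(ilens)
    }
    gstart <- cursor
    ex_s <- integer(); ex_e <- integer()
    p <- gstart
    for (k in seq_along(seg)) {
      ex_s <- c(ex_s, p); ex_e <- c(ex_e, p + seg[k] - 1L)
      p <- p + seg[k] + if (k <= length(ilens)) ilens[k] else 0L
    }
    gid <- sprintf("GS%04d", i)
    tid <- sprintf("TS%04d.1", i)
    gname <- sprintf("SYNGENE%d", i)
    t <- transcript_model(tid, gid, gname, chrom, strand[i], ex_s, ex_e,
                          cds_first_base = NA, cds_last_base = NA)
    cfb <- spliced_to_genomic(t, utr_len[i] + 1L)
    clb <- spliced_to_genomic(t, utr_len[i] + cds_len[i])
    t <- transcript_model(tid, gid, gname, chrom, strand[i], ex_s, ex_e,
                          cfb, clb, tags = "MANE_Select")
    # alternative promoter position and implied UTR length
    tss <- transcript_tss(t)
    alt <- switch(alt_class[i],
      utr_lengthening = {
        pos <- if (strand[i] == "+") tss - 30L else tss + 30L
        list(pos = pos, implied = utr_len[i] + 30L)
      },
      utr_shortening = {
        implied <- utr_len[i] - 25L
        list(pos = spliced_to_genomic(t, utr_len[i] + 1L - implied),
             implied = implied)
      },
      cds_truncating = {
        list(pos = spliced_to_genomic(t, utr_len[i] + 3L + 30L),
             implied = NA_integer_)
      })

    attr_base <- sprintf(
      'gene_id "%s"; transcript_id "%s"; gene_name "%s"; tag "MANE_Select";',
      gid, tid, gname)
    feat <- function(type, s, e)
      sprintf("%s\tsynth\t%s\t%d\t%d\t.\t%s\t.\t%s",
              chrom, type, s, e, strand[i], attr_base)
    gtf <- c(gtf,
             feat("transcript", min(ex_s), max(ex_e)),
             unlist(mapply(feat, "exon", ex_s, ex_e, SIMPLIFY = FALSE)))
    u <- build_utr5_intervals(t)
    lo_c <- min(cfb, clb); hi_c <- max(cfb, clb)
    cds_s <- pmax(ex_s, lo_c); cds_e <- pmin(ex_e, hi_c)
    keep <- cds_e >= cds_s
    gtf <- c(gtf, unlist(mapply(feat, "CDS", cds_s[keep], cds_e[keep],
                                SIMPLIFY = FALSE)))
    rows[[i]] <- data.frame(
      gene_id = gid, transcript_id = tid, gene_name = gname,
      chrom = chrom, strand = strand[i],
      tss = tss, cds_first_base = cfb, cds_last_base = clb,
      utr5_len = utr_len[i], cds_len = cds_len[i], utr3_len = utr3_len[i],
      kozak_class = kozak[i],
      w_annotated = cfg$w_annotated, w_alt = cfg$w_alt,
      alt_class = alt_class[i], alt_tss = alt$pos,
      alt_implied_utr = alt$implied,
      gene_start = min(ex_s), gene_end = max(ex_e),
      stringsAsFactors = FALSE)
    cursor <- max(ex_e) + gap
  }
  chrom_lengths[paste0("chrS", chrom_i)] <- cursor + gap

  gtf_path <- file.path(dir, "toy.gtf")
  writeLines(gtf, gtf_path)
  genes <- do.call(rbind, rows)

  fasta_path <- NULL
  if (cfg$emit_fasta) {
    fasta_path <- file.path(dir, "toy.fa")
    models <- parse_gtf(gtf_path)
    .write_toy_fasta(genes, models, chrom_lengths, fasta_path, cfg$seed)
  }
  structure(list(config = cfg, gtf = gtf_path, fasta = fasta_path,
                 genes = genes, chrom_lengths = chrom_lengths),
            class = "truth_manifest")
}

# Random genome with each transcript's AUG (and Kozak determinants) patched
# in at the recorded coordinates, mapped through the real exon structure.
.write_toy_fasta <- function(genes, models, chrom_lengths, path, seed) {
  set.seed(.stage_seed(seed, "reference") + 1L)
  chroms <- lapply(chrom_lengths, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    t <- models[[g$transcript_id]]
    set_base <- function(spliced_pos, base) {
      gp <- spliced_to_genomic(t, spliced_pos)
      chroms[[g$chrom]][gp] <<- if (g$strand == "+") base else comp[[base]]
    }
    aug_at <- g$utr5_len + 1L
    set_base(aug_at, "A"); set_base(aug_at + 1L, "T")
    set_base(aug_at + 2L, "G")
    m3 <- switch(g$kozak_class, strong = "A", moderate = "A", weak = "T")
    p4 <- switch(g$kozak_class, strong = "G", moderate = "T", weak = "T")
    has_m3 <- aug_at - 3L >= 1L
    if (!has_m3 && g$kozak_class == "moderate")
      p4 <- "G"  # no -3 position: carry the single determinant at +4
    if (has_m3) set_base(aug_at - 3L, m3)
    set_base(aug_at + 3L, p4)
  }
  seqs <- Biostrings::DNAStringSet(vapply(chroms, paste, character(1L),
                                          collapse = ""))
  names(seqs) <- names(chrom_lengths)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Simulate CAGE 5'-end tags over the toy reference
#'
#' Distributes `cage_depth` tags across genes (equal expected depth per
#' gene), splits each gene's tags between its annotated and alternative
#' promoter by the configured weights, jitters positions by
#' `N(0, jitter_sd_nt)` (rounded), and adds uniform background tags on the
#' gene's strand at `background_rate` of the total.
#'
#' @param cfg a [synth_config()].
#' @param truth manifest from [build_toy_reference()].
#' @return list: `tags` (one row per tag: `chrom`,`pos`,`strand`,`gene_id`,
#'   `source` in annotated/alternative/background, `true_class`), `tally`
#'   (aggregated `chrom`,`pos`,`strand`,`count`) and `total_tags`.
#' @export
simulate_cage <- function(cfg, truth) {
  stopifnot(inherits(truth, "truth_manifest"))
  set.seed(.stage_seed(cfg$seed, "cage"))
  g <- truth$genes
  n <- nrow(g)
  per_gene <- as.vector(rmultinom(1L, cfg$cage_depth, rep(1 / n, n)))
  out <- list()
  for (i in seq_len(n)) {
    k <- per_gene[i]
    if (k == 0L) next
    n_alt <- rbinom(1L, k, g$w_alt[i])
    src <- c(rep("annotated", k - n_alt), rep("alternative", n_alt))
    pos <- c(rep(g$tss[i], k - n_alt), rep(g$alt_tss[i], n_alt))
    if (cfg$jitter_sd_nt > 0)
      pos <- pos + as.integer(round(rnorm(k, 0, cfg$jitter_sd_nt)))
    out[[i]] <- data.frame(
      chrom = g$chrom[i], pos = pos, strand = g$strand[i],
      gene_id = g$gene_id[i], source = src,
      true_class = ifelse(src == "annotated", "annotated", g$alt_class[i]),
      stringsAsFactors = FALSE)
  }
  tags <- do.call(rbind, out)
  if (cfg$background_rate > 0) {
    n_bg <- as.integer(round(cfg$background_rate * cfg$cage_depth /
                             (1 - cfg$background_rate)))
    gi <- sample(n, n_bg, replace = TRUE)
    bg <- data.frame(
      chrom = g$chrom[gi],
      pos = as.integer(g$gene_start[gi] +
        floor(runif(n_bg) * (g$gene_end[gi] - g$gene_start[gi] + 1L))),
      strand = g$strand[gi], gene_id = g$gene_id[gi],
      source = "background", true_class = NA_character_,
      stringsAsFactors = FALSE)
    tags <- rbind(tags, bg)
  }
  rownames(tags) <- NULL
  tal <- stats::aggregate(list(count = rep(1L, nrow(tags))),
                          by = tags[c("chrom", "pos", "strand")], FUN = sum)
  tal <- tal[order(tal$chrom, tal$strand, tal$pos), , drop = FALSE]
  rownames(tal) <- NULL
  list(tags = tags, tally = tal, total_tags = nrow(tags))
}

# ---- toy alignments / SAM --------------------------------------------------

#' Random toy alignments with indel- and clip-bearing CIGARs
#'
#' Generates single-end alignments on both strands with CIGARs drawn from
#' plain matches, insertions, deletions and soft-clipped ends — the shapes a
#' 5'-end extractor must handle. Optionally appends unmapped and secondary
#' records that a CTSS caller must skip.
#'
#' @param n number of primary mapped reads.
#' @param chrom_lengths named integer vector of toy chromosome lengths.
#' @param seed integer seed.
#' @param n_unmapped,n_secondary extra records to exercise read filters.
#' @return data.frame with SAM-ready fields: `qname`, `flag`, `chrom`,
#'   `pos` (1-based leftmost aligned base), `mapq`, `cigar`, `strand`.
#' @export
random_alignments <- function(n, chrom_lengths, seed = 1L,
                              n_unmapped = 0L, n_secondary = 0L) {
  set.seed(.stage_seed(seed, "alignments"))
  shapes <- c("%dM", "%dM2D%dM", "%dM1I%dM", "3S%dM", "%dM4S", "%dM3N%dM")
  mk <- function(i) {
    shape <- sample(shapes, 1L)
    a <- sample(8:25, 1L); b <- sample(8:25, 1L)
    cigar <- if (grepl("M.*M", shape)) sprintf(shape, a, b)
             else sprintf(shape, a)
    chrom <- sample(names(chrom_lengths), 1L)
    ref_len <- .cigar_ref_len(cigar)
    pos <- sample(seq_len(max(1L, chrom_lengths[[chrom]] - ref_len - 10L)), 1L)
    data.frame(qname = sprintf("r%06d", i),
               flag = if (runif(1) < 0.5) 0L else 16L,
               chrom = chrom, pos = pos, mapq = 60L, cigar = cigar,
               stringsAsFactors = FALSE)
  }
  aln <- do.call(rbind, lapply(seq_len(n), mk))
  aln$strand <- ifelse(bitwAnd(aln$flag, 16L) > 0L, "-", "+")
  extras <- list()
  if (n_unmapped > 0L)
    extras$un <- data.frame(
      qname = sprintf("u%06d", seq_len(n_unmapped)), flag = 4L,
      chrom = "*", pos = 0L, mapq = 0L, cigar = "*", strand = "*",
      stringsAsFactors = FALSE)
  if (n_secondary > 0L) {
    sec <- aln[sample(nrow(aln), n_secondary, replace = TRUE), , drop = FALSE]
    sec$flag <- sec$flag + 256L
    sec$qname <- sprintf("s%06d", seq_len(n_secondary))
    extras$sec <- sec
  }
  rbind(aln, do.call(rbind, extras))
}

# reference-consuming CIGAR length (M/D/N/=/X)
.cigar_ref_len <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  sum(vapply(ops, function(o) {
    n <- as.integer(sub("[A-Z=]$", "", o))
    if (grepl("[MDN=X]$", o)) n else 0L
  }, integer(1L)))
}

# read length implied by a CIGAR (M/I/S/=/X)
.cigar_read_len <- function(cigar) {
  if (cigar == "*") return(1L)
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1L]]
  sum(vapply(ops, function(o) {
    n <- as.integer(sub("[A-Z=]$", "", o))
    if (grepl("[MIS=X]$", o)) n else 0L
  }, integer(1L)))
}

#' Write alignments as SAM and convert to a sorted, indexed BAM
#'
#' @param aln alignment data.frame from [random_alignments()] or
#'   [tags_to_alignments()].
#' @param chrom_lengths named chromosome lengths for the header.
#' @param prefix output path prefix; `<prefix>.bam` is produced.
#' @return the BAM path.
#' @export
write_toy_bam <- function(aln, chrom_lengths, prefix = tempfile("toybam")) {
  sam <- file.path(paste0(prefix, ".sam"))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chrom_lengths),
                   as.integer(chrom_lengths)))
  body <- vapply(seq_len(nrow(aln)), function(i) {
    a <- aln[i, ]
    seq <- strrep("A", .cigar_read_len(a$cigar))
    paste(a$qname, a$flag, a$chrom, a$pos, a$mapq, a$cigar,
          "*", 0L, 0L, seq, "*", sep = "\t")
  }, character(1L))
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

#' Convert simulated CAGE tags into alignments with the right 5' ends
#'
#' Each tag becomes one aligned read whose strand-aware 5' end equals the
#' tag position: plus-strand reads start at the tag; minus-strand reads end
#' at it. A mix of CIGAR shapes (including indels and soft clips) is drawn
#' per read.
#'
#' @param tags tag table from [simulate_cage()].
#' @param seed integer seed.
#' @return alignment data.frame for [write_toy_bam()].
#' @export
tags_to_alignments <- function(tags, seed = 1L) {
  set.seed(.stage_seed(seed, "alignments") + 1L)
  n <- nrow(tags)
  shapes <- c("%dM", "%dM2D%dM", "%dM1I%dM", "%dM4S")
  cigar <- vapply(seq_len(n), function(i) {
    shape <- sample(shapes, 1L)
    a <- sample(10:20, 1L); b <- sample(10:20, 1L)
    if (grepl("M.*M", shape)) sprintf(shape, a, b) else sprintf(shape, a)
  }, character(1L))
  ref_len <- vapply(cigar, .cigar_ref_len, integer(1L))
  pos <- ifelse(tags$strand == "+", tags$pos, tags$pos - ref_len + 1L)
  data.frame(qname = sprintf("t%07d", seq_len(n)),
             flag = ifelse(tags$strand == "+", 0L, 16L),
             chrom = tags$chrom, pos = as.integer(pos), mapq = 60L,
             cigar = cigar, strand = tags$strand, stringsAsFactors = FALSE)
}

# ---- initiation sites ------------------------------------------------------

#' Simulate a start-site ribosome-profiling initiation table
#'
#' Every gene receives an annotated initiation site; with probability
#' `p_trunc_short` (true UTR <= 40 nt) or `p_trunc_long` (> 40 nt) it also
#' gains an in-frame downstream N-terminal-truncation site.
#'
#' @param cfg a [synth_config()].
#' @param truth manifest from [build_toy_reference()].
#' @return list: `sites` (initiation-site table), `truth_truncated` (named
#'   logical per gene).
#' @export
simulate_initiation_sites <- function(cfg, truth) {
  set.seed(.stage_seed(cfg$seed, "initiation"))
  g <- truth$genes
  short <- g$utr5_len <= 40L
  p <- ifelse(short, cfg$p_trunc_short, cfg$p_trunc_long)
  truncated <- runif(nrow(g)) < p
  ann <- data.frame(
    gene_id = g$gene_id, transcript_id = g$transcript_id,
    site_class = "annotated", codon = "AUG",
    transcript_position = g$utr5_len + 1L,
    reads = sample(20:200, nrow(g), replace = TRUE),
    stringsAsFactors = FALSE)
  k <- which(truncated)
  tr <- if (length(k) == 0L) ann[0, ] else data.frame(
    gene_id = g$gene_id[k], transcript_id = g$transcript_id[k],
    site_class = "n_terminal_truncation", codon = "AUG",
    transcript_position = g$utr5_len[k] + 1L +
      3L * sample(5:30, length(k), replace = TRUE),
    reads = sample(5:100, length(k), replace = TRUE),
    stringsAsFactors = FALSE)
  sites <- rbind(ann, tr)
  sites <- sites[order(sites$gene_id, sites$transcript_position), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites, truth_truncated = setNames(truncated, g$gene_id))
}

# ---- variants --------------------------------------------------------------

#' Simulate a ClinVar-style 5' UTR variant table
#'
#' Emits deletions, insertions, duplications and delins with coherent
#' genomic Start/Stop and HGVS `c.-X...` names in the supported dialect.
#' In-UTR variants are confined to a single UTR exon so the HGVS span and
#' the genomic span agree exactly; the remainder are placed in the CDS (and
#' fail the both-ends-in-UTR test). Sizes follow a 1 + geometric law with a
#' heavy >= 10 nt tail; deletions larger than the available UTR are
#' resampled.
#'
#' @param cfg a [synth_config()].
#' @param truth manifest from [build_toy_reference()].
#' @return list: `variants` (variant_summary-schema data.frame) and `truth`
#'   (per-variant `variation_id`, `kind`, `true_delta`, `in_utr`).
#' @export
simulate_variant_table <- function(cfg, truth) {
  set.seed(.stage_seed(cfg$seed, "variants"))
  g <- truth$genes
  models <- .truth_models(truth)
  kinds <- cfg$variant_kinds
  rows <- list(); tru <- list()
  n_resampled <- 0L
  i <- 0L
  vid <- 0L
  while (i < cfg$n_variants) {
    gi <- sample(nrow(g), 1L)
    t <- models[[g$transcript_id[gi]]]
    L <- g$utr5_len[gi]
    kind <- sample(kinds, 1L)
    in_utr <- runif(1) < cfg$fraction_in_utr
    size <- 1L + rgeom(1L, 0.5)
    if (runif(1) < 0.25) size <- sample(10:40, 1L)
    utr <- build_utr5_intervals(t)
    if (in_utr) {
      iv <- utr$intervals
      if (nrow(iv) == 0L) next  # 0 nt UTR: cannot host an in-UTR variant
      widths <- iv$end - iv$start + 1L
      need <- if (kind == "insertion") 2L else size
      ok <- which(widths >= need)
      if (length(ok) == 0L || (kind %in% c("deletion", "indel") && size >= L)) {
        n_resampled <- n_resampled + 1L
        next
      }
      e_i <- ok[sample(length(ok), 1L)]
      gstart <- iv$start[e_i] +
        sample(0:(widths[e_i] - need), 1L)
      gend <- gstart + need - 1L
    } else {
      # inside the CDS (both ends): always fails the both-ends-in-UTR rule
      lo <- min(t$cds_first_base, t$cds_last_base)
      hi <- max(t$cds_first_base, t$cds_last_base)
      span <- if (kind == "insertion") 2L else size
      if (hi - lo + 1L < span + 4L) next
      gstart <- lo + sample(0:(hi - lo + 1L - span), 1L)
      gend <- gstart + span - 1L
    }
    cpos <- function(p) genomic_to_spliced(t, p) - L - 1L
    c1 <- cpos(gstart); c2 <- cpos(gend)
    if (anyNA(c(c1, c2))) {  # intronic end on an out-of-UTR variant:
      c1 <- 10L              # positive CDS-style positions; such records
      c2 <- 10L + (gend - gstart)  # are filtered out before HGVS parsing
    }
    cs <- min(c1, c2); ce <- max(c1, c2)
    ctag <- function(a, b) if (a == b) sprintf("%d", a)
                           else sprintf("%d_%d", a, b)
    ins_len <- if (kind == "insertion") size else 1L + rgeom(1L, 0.4)
    ins_seq <- paste(sample(c("A", "C", "G", "T"), ins_len, replace = TRUE),
                     collapse = "")
    expr <- switch(kind,
      deletion = sprintf("c.%sdel", ctag(cs, ce)),
      duplication = sprintf("c.%sdup", ctag(cs, ce)),
      insertion = sprintf("c.%s_%dins%s", cs, ce, ins_seq),
      indel = sprintf("c.%sdelins%s", ctag(cs, ce), ins_seq))
    delta <- switch(kind,
      deletion = -(gend - gstart + 1L),
      duplication = gend - gstart + 1L,
      insertion = nchar(ins_seq),
      indel = nchar(ins_seq) - (gend - gstart + 1L))
    i <- i + 1L; vid <- vid + 1L
    rows[[i]] <- data.frame(
      Name = sprintf("NM_%06d.1(%s):%s", gi, g$gene_name[gi], expr),
      Type = c(deletion = "Deletion", insertion = "Insertion",
               duplication = "Duplication", indel = "Indel")[[kind]],
      GeneSymbol = g$gene_name[gi], Assembly = "GRCh38",
      Chromosome = g$chrom[gi], Start = gstart, Stop = gend,
      VariationID = vid,
      ClinicalSignificance = sample(c("Pathogenic", "Likely pathogenic",
                                      "Uncertain significance"), 1L),
      stringsAsFactors = FALSE)
    tru[[i]] <- data.frame(variation_id = as.character(vid), kind = kind,
                           gene_id = g$gene_id[gi],
                           true_delta = as.integer(delta), in_utr = in_utr,
                           wt_utr_len = L, stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  list(variants = variants, truth = do.call(rbind, tru),
       n_resampled = n_resampled)
}

# Rebuild transcript_model objects from the manifest without reparsing GTF.
.truth_models <- function(truth) {
  models <- parse_gtf(truth$gtf)
  models
}

#' Write the truth manifest as JSON
#' @param truth a `truth_manifest`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(truth, path) {
  obj <- list(seed = truth$config$seed,
              config = unclass(truth$config),
              config_hash = config_hash(truth$config),
              genes = truth$genes,
              chrom_lengths = as.list(truth$chrom_lengths))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Score classified CTSS calls against the simulated tag truth
#'
#' Each surviving CTSS position is matched to the simulated tags at that
#' exact position; its true class is the majority `true_class` of those
#' tags (background tags carry no truth and are excluded). The score is the
#' tag-count-weighted fraction of CTSS whose called class equals the truth.
#'
#' @param ann classified annotation table from [classify_tss()].
#' @param tags tag-level table from [simulate_cage()].
#' @return list: `accuracy` (weighted), `n_scored` (tags underlying the
#'   score).
#' @export
score_tss_classification <- function(ann, tags) {
  tags <- tags[!is.na(tags$true_class), , drop = FALSE]
  key <- function(d) paste(d$chrom, d$pos, d$strand)
  truth_by_pos <- tapply(tags$true_class, key(tags), function(x)
    names(sort(table(x), decreasing = TRUE))[1L])
  weight_by_pos <- tapply(rep(1L, nrow(tags)), key(tags), sum)
  k <- key(ann)
  scored <- !is.na(truth_by_pos[k])
  w <- as.numeric(weight_by_pos[k][scored])
  hit <- ann$tss_class[scored] == truth_by_pos[k][scored]
  list(accuracy = sum(w * hit) / sum(w), n_scored = sum(w))
}

#' Random multi-exon transcript models for property testing
#'
#' Unconstrained geometry: introns may fall anywhere, including inside the
#' 5' UTR, on either strand.
#'
#' @param n number of models.
#' @param seed integer seed.
#' @return list of coding `transcript_model` objects.
#' @export
random_transcript_models <- function(n, seed = 1L) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    n_ex <- sample(1:5, 1L)
    widths <- sample(5:80, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1L) sample(10:100, n_ex - 1L, replace = TRUE)
            else integer()
    starts <- 1000L + cumsum(c(0L, widths[-n_ex] + gaps))
    ends <- starts + widths - 1L
    strand <- sample(c("+", "-"), 1L)
    total <- sum(widths)
    t0 <- transcript_model(sprintf("RT%04d", i), sprintf("RG%04d", i),
                           sprintf("RGENE%d", i), "chrR", strand,
                           starts, ends)
    s_first <- sample(seq_len(max(1L, total - 3L)), 1L)
    s_last <- min(total, s_first + 3L * sample(1:10, 1L) - 1L)
    transcript_model(sprintf("RT%04d", i), sprintf("RG%04d", i),
                     sprintf("RGENE%d", i), "chrR", strand, starts, ends,
                     cds_first_base = spliced_to_genomic(t0, s_first),
                     cds_last_base = spliced_to_genomic(t0, s_last))
  })
}
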