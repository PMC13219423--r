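test_that("parse_gtf maps simple coding transcripts with strand-aware CDS", {
  p <- write_test_gtf(c(
    gtf_row("chr1", "exon", 100, 400, "+", "G1", "T1"),
    gtf_row("chr1", "CDS", 200, 350, "+", "G1", "T1"),
    gtf_row("chr1", "exon", 500, 600, "-", "G2", "T2", tag = "MANE_Select"),
    gtf_row("chr1", "exon", 700, 800, "-", "G2", "T2", tag = "MANE_Select"),
    gtf_row("chr1", "CDS", 550, 600, "-", "G2", "T2", tag = "MANE_Select"),
    gtf_row("chr1", "CDS", 700, 760, "-", "G2", "T2", tag = "MANE_Select"),
    gtf_row("chr1", "exon", 900, 950, "+", "G3", "T3")))
  models <- parse_gtf(p)
  expect_named(models, c("T1", "T2", "T3"), ignore.order = TRUE)
  expect_equal(models$T1$cds_first_base, 200L)
  expect_equal(models$T1$cds_last_base, 350L)
  # minus strand: exons stored ascending, 5' end and CDS first base maximal
  expect_equal(models$T2$exon_starts, c(500L, 700L))
  expect_equal(transcript_tss(models$T2), 800L)
  expect_equal(models$T2$cds_first_base, 760L)
  expect_equal(models$T2$cds_last_base, 550L)
  expect_true("MANE_Select" %in% models$T2$tags)
  expect_false(is_coding(models$T3))
  expect_equal(attr(models, "n_noncoding"), 1L)
})

test_that("parse_gtf rejects CDS outside exons and missing files", {
  p <- write_test_gtf(c(
    gtf_row("chr1", "exon", 100, 200, "+", "G1", "T1"),
    gtf_row("chr1", "CDS", 150, 250, "+", "G1", "T1")))
  expect_error(parse_gtf(p), "outside exons.*T1")
  expect_error(parse_gtf(tempfile()), "not found")
})

test_that("compute_utr5_length handles the worked two-exon cases", {
  # transcription starting at the start codon
  t0 <- transcript_model("T0", "G0", "G0", "chr1", "+", 100L, 200L,
                         cds_first_base = 100L, cds_last_base = 150L)
  expect_equal(compute_utr5_length(t0), 0L)
  expect_equal(compute_utr5_length(two_exon_plus()), 70L)
  expect_equal(compute_utr5_length(two_exon_minus()), 70L)
  nc <- transcript_model("TN", "GN", "GN", "chr1", "+", 100L, 200L)
  expect_error(compute_utr5_length(nc), "non-coding")
})

test_that("build_utr5_intervals covers exactly the counted bases", {
  t0 <- transcript_model("T0", "G0", "G0", "chr1", "+", 100L, 200L,
                         cds_first_base = 100L, cds_last_base = 150L)
  u0 <- build_utr5_intervals(t0)
  expect_equal(nrow(u0$intervals), 0L)
  expect_equal(u0$total_nt, 0L)

  up <- build_utr5_intervals(two_exon_plus())
  expect_equal(up$intervals, data.frame(start = c(101L, 201L),
                                        end = c(150L, 220L)))
  expect_equal(up$total_nt, 70L)

  um <- build_utr5_intervals(two_exon_minus())
  expect_equal(um$intervals, data.frame(start = c(131L, 201L),
                                        end = c(150L, 250L)))
  expect_equal(um$total_nt, 70L)
})

test_that("UTR length equals per-base enumeration on randomized models", {
  models <- random_transcript_models(200, seed = 11)
  for (t in models) {
    expect_equal(compute_utr5_length(t), oracle_utr5_length(t))
    u <- build_utr5_intervals(t)
    expect_equal(u$total_nt, compute_utr5_length(t))
    got <- if (nrow(u$intervals)) sort(unlist(mapply(
      seq, u$intervals$start, u$intervals$end, SIMPLIFY = FALSE)))
      else integer()
    expect_equal(got, sort(oracle_utr5_positions(t)))
  }
})

test_that("spliced length identity and strand-flip symmetry hold", {
  models <- random_transcript_models(100, seed = 12)
  for (t in models) {
    utr3 <- {
      pos <- unlist(mapply(seq, t$exon_starts, t$exon_ends, SIMPLIFY = FALSE))
      if (t$strand == "-") pos <- rev(pos)
      length(pos) - which(pos == t$cds_last_base)
    }
    lo <- min(t$cds_first_base, t$cds_last_base)
    hi <- max(t$cds_first_base, t$cds_last_base)
    cds_len <- sum(pmax(0L, pmin(t$exon_ends, hi) -
                          pmax(t$exon_starts, lo) + 1L))
    expect_identical(compute_utr5_length(t) + cds_len + utr3,
                     spliced_length(t))
    # reflect all coordinates through a fixed point and flip the strand
    M <- 100000L
    fl <- transcript_model(t$transcript_id, t$gene_id, t$gene_name, t$chrom,
                           if (t$strand == "+") "-" else "+",
                           rev(M - t$exon_ends), rev(M - t$exon_starts),
                           cds_first_base = M - t$cds_first_base,
                           cds_last_base = M - t$cds_last_base)
    expect_identical(compute_utr5_length(fl), compute_utr5_length(t))
  }
})

test_that("spliced/genomic coordinate maps are mutual inverses", {
  for (t in random_transcript_models(50, seed = 13)) {
    s <- seq_len(spliced_length(t))
    expect_equal(genomic_to_spliced(t, spliced_to_genomic(t, s)), s)
    expect_true(is.na(genomic_to_spliced(t, min(t$exon_starts) - 1L)))
  }
})

test_that("select_representative follows abundance, fallback and tie-breaks", {
  mk <- function(id, len, tags = character()) {
    transcript_model(id, "G", "GENE", "chr1", "+", 100L, 100L + len - 1L,
                     cds_first_base = 110L, cds_last_base = 130L, tags = tags)
  }
  gene <- list(mk("TA", 60), mk("TB", 90))
  expr <- data.frame(transcript_id = c("TA", "TB"), mean_tpm = c(5.0, 1.2))
  expect_equal(select_representative(gene, expr, "highest_expressed"), "TA")
  # nothing expressed -> longest spliced transcript
  expr0 <- data.frame(transcript_id = "TX", mean_tpm = 3)
  expect_equal(select_representative(gene, expr0, "highest_expressed"), "TB")
  # equal abundance -> longer transcript; equal length -> smaller id
  expr_tie <- data.frame(transcript_id = c("TA", "TB"), mean_tpm = c(2, 2))
  expect_equal(select_representative(gene, expr_tie, "highest_expressed"), "TB")
  gene_eq <- list(mk("TZ", 60), mk("TA", 60))
  expect_equal(select_representative(gene_eq, expr_tie, "highest_expressed"),
               "TA")
  # single-transcript gene under any strategy with a candidate
  expect_equal(select_representative(gene[1], expr, "highest_expressed"), "TA")
  expect_equal(select_representative(gene[1], strategy = "longest_cds"), "TA")
  # MANE
  gene_m <- list(mk("TA", 60), mk("TB", 90, tags = "MANE_Select"))
  expect_equal(select_representative(gene_m, strategy = "mane_select"), "TB")
  expect_true(is.na(select_representative(gene, strategy = "mane_select")))
  # determinism under input-order permutation
  expect_equal(select_representative(rev(gene), expr, "highest_expressed"),
               select_representative(gene, expr, "highest_expressed"))
  expect_error(select_representative(gene, NULL, "highest_expressed"),
               "requires an expression table")
})

test_that("Kozak classification keys on -3 purine and +4 G only", {
  expect_equal(classify_kozak("GCCACCAUGG"), "strong")
  expect_equal(classify_kozak("UUUUUUAUGU"), "weak")
  expect_equal(classify_kozak("UUUAUUAUGU"), "moderate")  # A at -3, U at +4
  expect_equal(classify_kozak("UUUUUUAUGG"), "moderate")  # only +4 G
  expect_equal(classify_kozak("gccaccatgg"), "strong")    # DNA, lower case
  expect_equal(classify_kozak("NNNNNNAUGU"), "weak")      # N is no determinant
  expect_error(classify_kozak("GCCACCAAGG"), "AUG")
  expect_error(classify_kozak("CCAUGG"), "10 nt")
})

test_that("short-UTR gene set uses an inclusive 40 nt boundary", {
  mk <- function(gid, tid, utr) {
    transcript_model(tid, gid, gid, "chr1", "+",
                     100L, 400L, cds_first_base = 100L + utr,
                     cds_last_base = 300L)
  }
  models <- list(A = mk("GA", "A", 40L), B = mk("GB", "B", 41L),
                 C = mk("GC", "C", 5L))
  reps <- c(GA = "A", GB = "B", GC = "C")
  res <- short_utr_gene_set(models, reps, threshold = 40)
  expect_equal(res$genes, c("GA", "GC"))
  expect_equal(res$table$utr5_length_nt[res$table$gene_id == "GB"], 41L)
  expect_false(res$table$is_short[res$table$gene_id == "GB"])
  empty <- short_utr_gene_set(list(), character(), threshold = 40)
  expect_equal(nrow(empty$table), 0L)
  expect_length(empty$genes, 0L)
})

test_that("expression loading averages samples with zero fill", {
  f1 <- tempfile(); f2 <- tempfile()
  write.table(data.frame(target_id = c("T1", "T2"), tpm = c(10, 2)),
              f1, sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(data.frame(target_id = c("T1", "T3"), tpm = c(4, 8)),
              f2, sep = "\t", row.names = FALSE, quote = FALSE)
  e <- load_expression(c(f1, f2))
  expect_equal(e$mean_tpm[match(c("T1", "T2", "T3"), e$transcript_id)],
               c(7, 1, 4))
})
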