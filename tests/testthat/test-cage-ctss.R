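test_that("read 5' ends land at the aligned span boundary per strand", {
  cl <- c(chr1 = 2000L)
  aln <- data.frame(qname = c("p", "m"), flag = c(0L, 16L), chrom = "chr1",
                    pos = c(1001L, 1001L), mapq = 60L, cigar = "50M",
                    strand = c("+", "-"), stringsAsFactors = FALSE)
  bam <- write_toy_bam(aln, cl, tempfile("tb"))
  fp <- extract_five_prime_ends(bam = bam)
  expect_equal(fp$total_mapped, 2L)
  plus <- fp$tally[fp$tally$strand == "+", ]
  minus <- fp$tally[fp$tally$strand == "-", ]
  expect_equal(plus$pos, 1001L)
  expect_equal(minus$pos, 1050L)
})

test_that("unmapped and secondary records are skipped and counted", {
  cl <- c(chrA = 4000L)
  aln <- random_alignments(200, cl, seed = 4, n_unmapped = 6, n_secondary = 9)
  bam <- write_toy_bam(aln, cl, tempfile("tb"))
  fp <- extract_five_prime_ends(bam = bam)
  expect_equal(fp$total_mapped, 200L)
  expect_equal(fp$n_skipped, 15L)
  expect_equal(sum(fp$tally$count), 200L)
  expect_equal(fp$tally[c("chrom", "pos", "strand", "count")],
               oracle_5p_tally(aln))
})

test_that("TPM normalization is exact and conserves mass", {
  one <- data.frame(chrom = "c", pos = 1L, strand = "+", count = 42L)
  expect_equal(normalize_tpm(one, 42L)$tpm, 1e6)
  r <- normalize_tpm(data.frame(chrom = "c", pos = 1L, strand = "+",
                                count = 5L), 5e6)
  expect_equal(r$tpm, 1.0)
  tal <- data.frame(chrom = "c", pos = 1:50, strand = "+",
                    count = sample(1:100, 50, replace = TRUE))
  norm <- normalize_tpm(tal, sum(tal$count))
  expect_equal(sum(norm$tpm), 1e6, tolerance = 1e-6)
  expect_error(normalize_tpm(tal, 0), "positive")
})

test_that("CTSS filter boundaries are inclusive and monotone", {
  recs <- data.frame(chrom = "c", pos = 1:3, strand = "+",
                     count = c(5L, 4L, 100L), tpm = c(1.0, 2.0, 0.9))
  kept <- filter_ctss(recs, ctss_filter_config(1.0, 5L))
  expect_equal(kept$pos, 1L)  # count 5 & tpm 1.0 kept; others dropped
  set.seed(99)
  base <- data.frame(chrom = "c", pos = 1:200, strand = "+",
                     count = sample(1:20, 200, TRUE),
                     tpm = runif(200, 0, 5))
  for (i in 1:100) {
    t1 <- runif(1, 0, 3); c1 <- sample(0:10, 1)
    k1 <- filter_ctss(base, ctss_filter_config(t1, c1))
    k2 <- filter_ctss(base, ctss_filter_config(t1 + runif(1, 0, 2),
                                               c1 + sample(0:5, 1)))
    expect_true(all(k2$pos %in% k1$pos))
  }
})

test_that("CTSS annotation computes signed distance and implied UTR", {
  # intronless plus-strand gene: TSS 1950, start codon 2000
  tp <- transcript_model("TP", "GP", "GP", "chr1", "+", 1950L, 2600L,
                         cds_first_base = 2000L, cds_last_base = 2500L)
  # minus-strand gene on another chromosome: start codon first base 5000
  tm <- transcript_model("TM", "GM", "GM", "chr2", "-", 4400L, 5060L,
                         cds_first_base = 5000L, cds_last_base = 4500L)
  reps <- list(GP = tp, GM = tm)
  recs <- data.frame(chrom = c("chr1", "chr1", "chr2"),
                     pos = c(2000L, 1980L, 5030L),
                     strand = c("+", "+", "-"),
                     count = 10L, tpm = 2.0, stringsAsFactors = FALSE)
  ann <- annotate_ctss(recs, reps)
  expect_equal(ann$gene_id, c("GP", "GP", "GM"))
  expect_equal(ann$signed_distance_nt, c(0L, -20L, -30L))
  expect_equal(ann$implied_utr5_length_nt, c(0L, 20L, 30L))
  # out-of-range CTSS stays unassigned
  far <- annotate_ctss(data.frame(chrom = "chr1", pos = 900000L,
                                  strand = "+", count = 10L, tpm = 2),
                       reps, max_distance = 50000L)
  expect_true(is.na(far$gene_id))
  expect_equal(classify_tss(far)$tss_class, "unassigned")
})

test_that("TSS classes follow implied-vs-annotated UTR comparison", {
  mk <- function(sdist, implied, annotated) {
    classify_tss(data.frame(chrom = "c", pos = 1L, strand = "+", count = 1L,
                            tpm = 1, gene_id = "G",
                            signed_distance_nt = sdist,
                            implied_utr5_length_nt = implied,
                            annotated_utr5_nt = annotated))$tss_class
  }
  # ALDH9A1-style: annotated 4 nt, alternative TSS implies 28 nt
  expect_equal(mk(-24L, 28L, 4L), "utr_lengthening")
  # GUK1-style: annotated 28 nt, alternative implies 2 nt
  expect_equal(mk(26L - 28L, 2L, 28L), "utr_shortening")
  expect_equal(mk(50L, NA, 28L), "cds_truncating")
  # tolerance window is inclusive
  expect_equal(mk(-10L, 38L, 28L), "annotated")
  expect_equal(mk(-11L, 39L, 28L), "utr_lengthening")
  # intronic fallback uses genomic distance
  expect_equal(mk(-35L, NA, 28L), "annotated")
  expect_equal(mk(-45L, NA, 28L), "utr_lengthening")
})

test_that("promoter usage ratios aggregate read counts per gene", {
  ann <- data.frame(
    chrom = "c", pos = 1:4, strand = "+",
    count = c(10L, 20L, 10L, 7L), tpm = 1,
    gene_id = c("G1", "G1", "G1", "G2"),
    signed_distance_nt = 0L, implied_utr5_length_nt = 0L,
    annotated_utr5_nt = 0L,
    tss_class = c("annotated", "utr_lengthening", "cds_truncating",
                  "utr_shortening"),
    stringsAsFactors = FALSE)
  u <- promoter_usage(ann)
  g1 <- u[u$gene_id == "G1", ]
  expect_equal(g1$alt_ratio, 3.0)
  expect_true(g1$ratio_defined)
  g2 <- u[u$gene_id == "G2", ]
  expect_false(g2$ratio_defined)
  expect_true(is.na(g2$alt_ratio))
  only_ann <- promoter_usage(ann[1, ])
  expect_equal(only_ann$alt_ratio, 0)
  expect_identical(promoter_usage(ann), promoter_usage(ann[sample(4), ]))
})

test_that("bedGraph round trip preserves records and the 0-based shift", {
  recs <- data.frame(chrom = c("c1", "c1", "c2"), pos = c(10L, 20L, 5L),
                     strand = c("+", "-", "+"), count = c(3L, 7L, 2L),
                     stringsAsFactors = FALSE)
  dir <- tempfile(); dir.create(dir)
  write_ctss(recs, dir)
  lines <- readLines(file.path(dir, "ctss.plus.bedGraph"))
  expect_equal(lines[1], "c1\t9\t10\t3")  # start = pos - 1
  back <- read_ctss(file.path(dir, "ctss.plus.bedGraph"),
                    file.path(dir, "ctss.minus.bedGraph"))
  expect_equal(back[order(back$chrom, back$strand, back$pos), ],
               recs[order(recs$chrom, recs$strand, recs$pos), ],
               ignore_attr = TRUE)
  # empty input yields empty, readable files
  dir2 <- tempfile(); dir.create(dir2)
  write_ctss(recs[0, ], dir2)
  expect_equal(nrow(read_ctss(file.path(dir2, "ctss.plus.bedGraph"),
                              file.path(dir2, "ctss.minus.bedGraph"))), 0L)
})
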