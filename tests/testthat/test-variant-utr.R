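write_variants <- function(d) {
  f <- tempfile(fileext = ".tsv")
  write.table(d, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("variant table parsing keeps only the four indel types on GRCh38", {
  d <- data.frame(
    Name = c("NM_1(X):c.-20_-11del", "NM_1(X):c.100A>G",
             "NM_1(X):c.-5dup", "NM_1(X):c.-9_-8insAA"),
    Type = c("Deletion", "single nucleotide variant", "Duplication",
             "Insertion"),
    GeneSymbol = "X", Assembly = c("GRCh38", "GRCh38", "GRCh37", "GRCh38"),
    Chromosome = "1", Start = c(100L, 200L, 300L, 400L),
    Stop = c(109L, 200L, 300L, 401L), VariationID = 1:4,
    ClinicalSignificance = "Pathogenic", stringsAsFactors = FALSE)
  v <- parse_variant_table(write_variants(d))
  expect_equal(v$variation_id, c("1", "4"))
  expect_equal(v$variant_type, c("deletion", "insertion"))
  # malformed coordinates: skipped and counted
  d$Start <- as.character(d$Start); d$Start[1] <- "oops"
  v2 <- parse_variant_table(write_variants(d))
  expect_equal(attr(v2, "n_skipped"), 1L)
  expect_equal(v2$variation_id, "4")
  expect_error(parse_variant_table(write_variants(d[, -1])), "lacks columns")
})

test_that("HGVS UTR indel parsing covers the supported dialect", {
  dup <- parse_hgvs_utr_indel("NM_1(X):c.-45_-36dup")
  expect_equal(dup$kind, "dup")
  expect_equal(dup$span, 10L)
  ins <- parse_hgvs_utr_indel("NM_1(X):c.-20_-19insACGT")
  expect_equal(ins$kind, "ins")
  expect_equal(ins$inserted_seq, "ACGT")
  delins <- parse_hgvs_utr_indel("NM_1(X):c.-50_-41delinsAC")
  expect_equal(delins$kind, "delins")
  expect_equal(delins$span, 10L)
  expect_equal(nchar(delins$inserted_seq), 2L)
  single <- parse_hgvs_utr_indel("c.-45del")
  expect_equal(single$span, 1L)
  expect_equal(single$c_start, -45L)
  # unsupported dialects are flagged, never guessed
  expect_equal(parse_hgvs_utr_indel("c.-10+5del")$kind, "unsupported")
  expect_equal(parse_hgvs_utr_indel("c.10_15del")$kind, "unsupported")
  expect_equal(parse_hgvs_utr_indel("c.-1_1insA")$kind, "unsupported")
  expect_equal(parse_hgvs_utr_indel("c.-30_-20inv")$kind, "unsupported")
  expect_equal(parse_hgvs_utr_indel("g.12345del")$kind, "unsupported")
  expect_equal(parse_hgvs_utr_indel("c.-20_-15insA")$kind, "unsupported")
})

test_that("length changes take the genomic route for deletions, HGVS otherwise", {
  # VHL-style: 30 nt deletion named c.-75_-46del
  vhl <- list(variant_type = "deletion", start = 10183532L, stop = 10183561L)
  h <- parse_hgvs_utr_indel("NM_000551.4(VHL):c.-75_-46del")
  chg <- compute_length_change(vhl, h)
  expect_equal(chg$delta_nt, -30L)
  expect_equal(chg$route, "genomic")
  expect_false(chg$discordant)
  # discordant when the HGVS span disagrees with the coordinates
  chg2 <- compute_length_change(list(variant_type = "deletion",
                                     start = 100L, stop = 120L), h)
  expect_true(chg2$discordant)
  ins <- compute_length_change(list(variant_type = "insertion",
                                    start = 1L, stop = 2L),
                               parse_hgvs_utr_indel("c.-9_-8insA"))
  expect_equal(ins$delta_nt, 1L)
  di <- compute_length_change(list(variant_type = "indel",
                                   start = 1L, stop = 10L),
                              parse_hgvs_utr_indel("c.-50_-41delinsAC"))
  expect_equal(di$delta_nt, -8L)
  un <- compute_length_change(list(variant_type = "insertion",
                                   start = 1L, stop = 2L),
                              parse_hgvs_utr_indel("c.-10+5insA"))
  expect_true(is.na(un$delta_nt))
  expect_equal(un$route, "unparsed")
})

test_that("both-ends-in-UTR membership is literal, with intron flag", {
  t <- two_exon_plus()  # UTR [101-150], [201-220]
  u <- build_utr5_intervals(t)
  expect_true(variant_within_utr(list(start = 110L, stop = 120L), u))
  # stop inside the CDS
  expect_false(variant_within_utr(list(start = 210L, stop = 230L), u))
  # ends in two different UTR exons: kept, flagged
  res <- variant_within_utr(list(start = 140L, stop = 210L), u)
  expect_true(res)
  expect_true(attr(res, "spans_intron"))
  # zero-length UTR
  t0 <- transcript_model("T0", "G0", "G0", "chr1", "+", 100L, 300L,
                         cds_first_base = 100L, cds_last_base = 250L)
  expect_false(variant_within_utr(list(start = 100L, stop = 101L),
                                  build_utr5_intervals(t0)))
})

test_that("minimum-size filter is inclusive at 10 bp and idempotent", {
  ch <- data.frame(variation_id = as.character(1:3),
                   delta_nt = c(10L, -9L, -30L))
  kept <- apply_min_size(ch, 10L)
  expect_equal(kept$variation_id, c("1", "3"))
  expect_identical(apply_min_size(kept, 10L), kept)
  expect_equal(nrow(apply_min_size(ch[0, ], 10L)), 0L)
})

test_that("scanning-effect classes follow the 40 nt regime", {
  # the worked VHL case: 57 nt wild type, 30 nt deletion
  vhl <- classify_scanning_effect(57L, -30L)
  expect_equal(vhl$mutant_utr_len, 27L)
  expect_equal(vhl$scanning_prediction, "enhanced_leaky_scanning")
  expect_equal(classify_scanning_effect(20L, 25L)$scanning_prediction,
               "suppressed_leaky_scanning")
  expect_equal(classify_scanning_effect(200L, -15L)$scanning_prediction,
               "minimal")
  # shortening an already-short UTR still enhances scanning
  expect_equal(classify_scanning_effect(20L, -11L)$scanning_prediction,
               "enhanced_leaky_scanning")
  # short-to-short lengthening does not cross the threshold
  expect_equal(classify_scanning_effect(20L, 10L)$scanning_prediction,
               "minimal")
  expect_error(classify_scanning_effect(20L, -25L), "negative")
})

test_that("waterfall summary is deterministic with tie-breaks and extremes", {
  ch <- data.frame(variation_id = c("b", "a", "c"),
                   delta_nt = c(5L, 5L, -12L),
                   scanning_prediction = c("minimal", "minimal",
                                           "enhanced_leaky_scanning"),
                   stringsAsFactors = FALSE)
  wf <- waterfall_summary(ch)
  expect_equal(wf$table$variation_id, c("a", "b", "c"))
  expect_equal(wf$max_delta, 5L)
  expect_equal(wf$min_delta, -12L)
  expect_equal(unname(wf$class_counts["enhanced_leaky_scanning"]), 1L)
  expect_identical(waterfall_summary(ch[c(3, 1, 2), ])$table, wf$table)
  empty <- waterfall_summary(ch[0, ])
  expect_true(is.na(empty$max_delta))
  expect_equal(sum(empty$class_counts), 0L)
})

test_that("synthetic variants round-trip deltas, membership and HGVS", {
  cfg <- synth_config(seed = 42, n_genes = 40, n_variants = 300)
  truth <- build_toy_reference(cfg)
  models <- parse_gtf(truth$gtf)
  vt <- simulate_variant_table(cfg, truth)
  v <- parse_variant_table(write_variants(vt$variants))
  reps <- setNames(truth$genes$transcript_id, truth$genes$gene_id)
  eng <- utr_variant_engine(v, models, reps)
  m <- merge(eng$changes, vt$truth, by = "variation_id")
  expect_equal(nrow(m), sum(vt$truth$in_utr))
  expect_true(all(m$delta_nt == m$true_delta))
  expect_true(all(m$mutant_utr_len == m$wt_utr_len.x + m$delta_nt))
  expect_true(all(m$mutant_utr_len >= 0))
  expect_false(any(eng$changes$discordant))
  # membership against brute-force per-base UTR sets
  utr_pos <- lapply(truth$genes$transcript_id,
                    function(id) oracle_utr5_positions(models[[id]]))
  names(utr_pos) <- truth$genes$gene_name
  inside <- vapply(seq_len(nrow(v)), function(i) {
    pos <- utr_pos[[v$gene_symbol[i]]]
    v$start[i] %in% pos && v$stop[i] %in% pos
  }, logical(1L))
  expect_equal(sort(eng$changes$variation_id), sort(v$variation_id[inside]))
  # HGVS-vs-genomic agreement on every deletion
  dels <- eng$changes[eng$changes$variant_type == "deletion", ]
  for (i in seq_len(nrow(dels))) {
    h <- parse_hgvs_utr_indel(dels$hgvs_name[i])
    expect_equal(-h$span, dels$delta_nt[i])
  }
  # filter pipeline is idempotent
  expect_identical(apply_min_size(eng$sized, 10L), eng$sized)
})

test_that("short-regime candidates split by direction and conversion", {
  ch <- data.frame(variation_id = as.character(1:4),
                   wt_utr_len = c(30L, 30L, 57L, 200L),
                   delta_nt = c(-12L, 15L, -30L, -50L),
                   mutant_utr_len = c(18L, 45L, 27L, 150L),
                   scanning_prediction = "x", stringsAsFactors = FALSE)
  sc <- short_regime_candidates(ch)
  expect_equal(sc$shortening$variation_id, "1")
  expect_equal(sc$lengthening$variation_id, "2")
  expect_equal(sc$long_to_short$variation_id, "3")
})
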