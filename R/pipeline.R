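# Orchestration: configuration validation, structured logging with
# per-stage record counts, and the end-to-end annotation -> CTSS ->
# classification -> statistics -> variant analysis run.

.config_defaults <- function() list(
  short_utr_threshold_nt = 40L,
  ctss_min_tpm = 1.0,
  ctss_min_count = 5L,
  min_indel_size_bp = 10L,
  max_assignment_distance_nt = 50000L,
  tss_tolerance_nt = 10L,
  bin_edges = c(20, 40, 100, 200),
  representative_strategy = "highest_expressed",
  seed = 1L)

#' Analysis configuration
#'
#' Defaults are the study's operating constants: the 40 nt short-UTR
#' threshold, CTSS filters of TPM >= 1 and count >= 5, the >= 10 bp minimum
#' indel size, 50 kb maximum start-codon assignment distance, and a 10 nt
#' annotated-TSS tolerance.
#'
#' @param ... overrides of the default keys (unknown keys are rejected).
#' @return list of class `analysis_config`.
#' @export
analysis_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  for (k in c("short_utr_threshold_nt", "ctss_min_tpm", "ctss_min_count",
              "min_indel_size_bp", "max_assignment_distance_nt")) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1L || cfg[[k]] <= 0)
      stop("config key ", k, " must be a positive number")
  }
  if (!is.numeric(cfg$tss_tolerance_nt) || cfg$tss_tolerance_nt < 0)
    stop("config key tss_tolerance_nt must be a non-negative number")
  if (!is.numeric(cfg$bin_edges) || is.unsorted(cfg$bin_edges, strictly = TRUE))
    stop("config key bin_edges must be strictly increasing numeric")
  if (!cfg$representative_strategy %in%
      c("highest_expressed", "mane_select", "longest_cds"))
    stop("config key representative_strategy must be one of ",
         "highest_expressed/mane_select/longest_cds")
  if (!is.numeric(cfg$seed)) stop("config key seed must be numeric")
  structure(cfg, class = "analysis_config")
}

#' Validate a JSON or YAML configuration file
#'
#' Unknown keys are rejected; missing keys take their defaults; the fully
#' resolved configuration is returned (and echoed into every pipeline
#' output header via its hash).
#'
#' @param path `.json`, `.yaml` or `.yml` file of key-value pairs; an empty
#'   file yields all defaults.
#' @return an [analysis_config()].
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
    if (!nzchar(trimws(txt))) list() else jsonlite::fromJSON(txt)
  } else {
    y <- yaml::read_yaml(path)
    if (is.null(y)) list() else y
  }
  if (!is.list(raw)) stop("config file must hold key-value pairs: ", path)
  do.call(analysis_config, raw)
}

#' Stable hash of a configuration
#'
#' MD5 of the canonical (key-sorted) JSON serialization; two runs with
#' different configurations never share a hash.
#'
#' @param cfg an `analysis_config` (or any named list).
#' @return character hash.
#' @export
config_hash <- function(cfg) {
  x <- unclass(cfg)
  x <- x[order(names(x))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

.write_tsv <- function(d, path, hash) {
  con <- file(path, "w")
  writeLines(sprintf("# leakyscan config_hash=%s", hash), con)
  write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  path
}

#' Run the full analysis pipeline
#'
#' Stages: annotation (GTF -> representative transcripts -> UTR tables),
#' CAGE (5'-end tallying -> TPM -> filtering -> start-codon annotation ->
#' TSS classification -> promoter usage), truncation statistics (UTR-length
#' bins, optional gene-set CDF comparison), and the ClinVar-style 5' UTR
#' variant engine. Any stage error aborts the run, removes partial outputs
#' and names the stage.
#'
#' @param cfg an [analysis_config()].
#' @param inputs named list of paths: `gtf` (required); `bam` or
#'   `bedgraph_plus`+`bedgraph_minus` for CAGE; optional `abundance`
#'   (character vector of Kallisto-style TSVs), `initiation` (TSV),
#'   `clinvar` (TSV), `mito_genes` (one symbol per line).
#' @param out_dir output directory (created).
#' @return (invisibly) the JSON summary as a list; files written under
#'   `out_dir` (`utr_lengths.tsv`, `utr_intervals.bed`, `ctss.*.bedGraph`,
#'   `ctss_annotated.tsv`, `promoter_usage.tsv`, `truncation_bins.tsv`,
#'   `utr_variants.tsv`, `utr_variants_waterfall.tsv`, `unparsed.tsv`,
#'   `summary.json`, `pipeline.log`).
#' @export
run_pipeline <- function(cfg, inputs, out_dir) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (is.null(inputs$gtf)) stop("inputs$gtf is required")
  for (k in c("gtf", "bam", "initiation", "clinvar", "mito_genes",
              "bedgraph_plus", "bedgraph_minus")) {
    p <- inputs[[k]]
    if (!is.null(p) && !all(file.exists(p)))
      stop("input file not found (", k, "): ", p[!file.exists(p)][1L])
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg)
  log_lines <- character()
  log <- function(stage, msg)
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, msg))
  stage <- "setup"
  summary <- list(config = unclass(cfg), config_hash = hash)

  res <- tryCatch({
    # ---- annotation ----
    stage <- "annotation"
    models <- parse_gtf(inputs$gtf)
    log(stage, sprintf("%d transcripts (%d non-coding)", length(models),
                       attr(models, "n_noncoding")))
    expr <- if (!is.null(inputs$abundance)) load_expression(inputs$abundance)
            else data.frame(transcript_id = character(), mean_tpm = numeric())
    reps <- select_representatives(models, expr,
                                   strategy = cfg$representative_strategy)
    log(stage, sprintf("%d genes, %d without representative",
                       length(reps), sum(is.na(reps))))
    utr_tab <- write_utr_tables(models, reps, out_dir,
                                threshold = cfg$short_utr_threshold_nt)
    # rewrite with the config-hash header
    .write_tsv(utr_tab, file.path(out_dir, "utr_lengths.tsv"), hash)
    short <- utr_tab$gene_id[utr_tab$is_short]
    summary$annotation <- list(
      n_transcripts = length(models),
      n_noncoding = attr(models, "n_noncoding"),
      n_genes = length(reps), n_no_representative = sum(is.na(reps)),
      n_short_utr_genes = length(short))
    rep_models <- list()
    for (g in names(reps))
      if (!is.na(reps[[g]]) && is_coding(models[[reps[[g]]]]))
        rep_models[[g]] <- models[[reps[[g]]]]

    # ---- CAGE ----
    usage <- NULL
    if (!is.null(inputs$bam) || !is.null(inputs$bedgraph_plus)) {
      stage <- "cage"
      fp <- extract_five_prime_ends(bam = inputs$bam,
                                    bedgraph_plus = inputs$bedgraph_plus,
                                    bedgraph_minus = inputs$bedgraph_minus)
      log(stage, sprintf("%d reads accepted, %d skipped, %d CTSS positions",
                         fp$total_mapped, fp$n_skipped, nrow(fp$tally)))
      recs <- normalize_tpm(fp$tally, fp$total_mapped)
      kept <- filter_ctss(recs, ctss_filter_config(cfg$ctss_min_tpm,
                                                   cfg$ctss_min_count))
      log(stage, sprintf("%d CTSS pass TPM>=%g & count>=%d", nrow(kept),
                         cfg$ctss_min_tpm, cfg$ctss_min_count))
      ann <- annotate_ctss(kept, rep_models,
                           max_distance = cfg$max_assignment_distance_nt)
      ann <- classify_tss(ann, tolerance = cfg$tss_tolerance_nt)
      write_ctss(kept, out_dir, annotations = ann)
      .write_tsv(ann, file.path(out_dir, "ctss_annotated.tsv"), hash)
      usage <- promoter_usage(ann)
      .write_tsv(usage, file.path(out_dir, "promoter_usage.tsv"), hash)
      cls <- table(ann$tss_class)
      multi <- vapply(split(ann, ann$gene_id), nrow, integer(1L))
      summary$cage <- list(
        total_mapped = fp$total_mapped, n_skipped = fp$n_skipped,
        n_ctss_prefilter = nrow(fp$tally), n_ctss_postfilter = nrow(kept),
        n_genes_with_tss = length(multi),
        n_genes_multi_tss = sum(multi > 1L),
        n_cds_truncating_tss = unname(cls["cds_truncating"]) %||% 0L,
        class_counts = as.list(cls))
    }

    # ---- truncation statistics ----
    if (!is.null(inputs$initiation)) {
      stage <- "truncation_stats"
      init <- load_initiation_sites(inputs$initiation)
      bins <- truncation_proportion_by_bin(utr_tab, init,
                                           bin_edges = cfg$bin_edges)
      .write_tsv(bins, file.path(out_dir, "truncation_bins.tsv"), hash)
      multi_iso <- intersect_short_utr_multi_isoform(short, init)
      log(stage, sprintf("%d initiation sites, %d short-UTR multi-isoform genes",
                         nrow(init), length(multi_iso)))
      summary$truncation <- list(
        n_sites = nrow(init),
        n_genes_excluded_no_initiation = attr(bins, "n_excluded"),
        bins = bins, short_utr_multi_isoform_genes = multi_iso)
      if (!is.null(inputs$mito_genes)) {
        mito <- readLines(inputs$mito_genes, warn = FALSE)
        mito <- mito[nzchar(trimws(mito))]
        cdf <- compare_gene_sets_cdf(utr_tab, mito)
        .write_tsv(data.frame(
          group = c(rep("in_set", length(cdf$in_set)),
                    rep("out_set", length(cdf$out_set))),
          utr5_length_nt = c(cdf$in_set, cdf$out_set)),
          file.path(out_dir, "cdf_groups.tsv"), hash)
        summary$gene_set_cdf <- list(
          W = cdf$test$statistic, p_two_sided = cdf$test$p_two_sided,
          method = cdf$test$method,
          n_in_set = length(cdf$in_set), n_out_set = length(cdf$out_set),
          n_unmatched = cdf$n_unmatched)
        jsonlite::write_json(summary$gene_set_cdf,
                             file.path(out_dir, "ranksum.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }

    # ---- variants ----
    if (!is.null(inputs$clinvar)) {
      stage <- "variants"
      variants <- parse_variant_table(inputs$clinvar)
      eng <- utr_variant_engine(variants, models, reps,
                                min_size = cfg$min_indel_size_bp,
                                short_threshold = cfg$short_utr_threshold_nt)
      wf <- waterfall_summary(eng$sized)
      .write_tsv(eng$changes, file.path(out_dir, "utr_variants.tsv"), hash)
      .write_tsv(wf$table, file.path(out_dir, "utr_variants_waterfall.tsv"),
                 hash)
      .write_tsv(eng$unparsed, file.path(out_dir, "unparsed.tsv"), hash)
      log(stage, sprintf(
        "%d indels in, %d inside UTRs, %d pass size >= %d",
        eng$counts$n_input, eng$counts$n_in_utr,
        eng$counts$n_pass_min_size, cfg$min_indel_size_bp))
      summary$variants <- c(eng$counts, list(
        max_delta = wf$max_delta, min_delta = wf$min_delta,
        class_counts = as.list(wf$class_counts)))
    }

    summary
  }, error = function(e) {
    unlink(out_dir, recursive = TRUE)
    stop("pipeline failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })

  jsonlite::write_json(res, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(c(sprintf("# leakyscan config_hash=%s", hash), log_lines),
             file.path(out_dir, "pipeline.log"))
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L || is.na(a)) b else a
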