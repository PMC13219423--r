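# Relating 5' UTR length to alternative N-terminal isoform production:
# binned truncation proportions, rank-sum comparison of UTR-length
# distributions, and the short-UTR x multi-isoform gene intersection.

#' Load start-site ribosome-profiling initiation calls
#'
#' Expected columns: `gene_id`, `transcript_id`, `site_class` (one of
#' `annotated`, `n_terminal_truncation`, `other`), `codon`,
#' `transcript_position`, `reads`. Duplicate (gene, class, position) rows
#' are collapsed by summing reads.
#'
#' @param path TSV path.
#' @return validated data.frame.
#' @export
load_initiation_sites <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "site_class", "transcript_position", "reads")
  if (!all(req %in% names(d)))
    stop("initiation table lacks columns: ",
         paste(setdiff(req, names(d)), collapse = ", "))
  if (nrow(d) == 0L) return(d)
  ok <- d$site_class %in% c("annotated", "n_terminal_truncation", "other")
  if (!all(ok))
    stop("unknown site_class at row(s) ",
         paste(head(which(!ok), 5L), collapse = ", "), ": ",
         paste(unique(d$site_class[!ok]), collapse = ", "))
  if (any(d$reads < 0)) stop("negative read counts in initiation table")
  key <- interaction(d$gene_id, d$site_class, d$transcript_position,
                     drop = TRUE)
  if (anyDuplicated(key)) {
    reads <- tapply(d$reads, key, sum)
    d <- d[!duplicated(key), , drop = FALSE]
    d$reads <- as.numeric(reads[as.character(
      interaction(d$gene_id, d$site_class, d$transcript_position, drop = TRUE))])
  }
  rownames(d) <- NULL
  d
}

# Genes with at least one truncation site backed by >= 1 read.
truncated_genes <- function(initiation) {
  unique(initiation$gene_id[
    initiation$site_class == "n_terminal_truncation" & initiation$reads >= 1])
}

#' Proportion of genes producing N-terminal truncations, by UTR-length bin
#'
#' Genes are binned by their representative 5' UTR length (left-open,
#' right-closed bins over (0, Inf)); within each bin the proportion with at
#' least one N-terminal truncation initiation site is reported. Genes
#' without initiation data are excluded (and counted).
#'
#' @param utr_table per-gene table with `gene_id` and `utr5_length_nt`
#'   (e.g. from [short_utr_gene_set()]).
#' @param initiation initiation-site table ([load_initiation_sites()]).
#' @param bin_edges increasing numeric vector of inner edges; bins are
#'   `(0, e1], (e1, e2], ..., (ek, Inf)`. Default `c(20, 40, 100, 200)`.
#' @return data.frame `bin`, `n_genes`, `n_truncated`, `proportion`, with
#'   attribute `n_excluded` (genes lacking initiation data).
#' @export
truncation_proportion_by_bin <- function(utr_table, initiation,
                                         bin_edges = c(20, 40, 100, 200)) {
  if (is.unsorted(bin_edges, strictly = TRUE) || any(bin_edges <= 0))
    stop("bin_edges must be strictly increasing and positive")
  edges <- c(0, bin_edges, Inf)
  eligible <- utr_table[utr_table$gene_id %in% initiation$gene_id, ,
                        drop = FALSE]
  n_excluded <- nrow(utr_table) - nrow(eligible)
  trunc <- truncated_genes(initiation)
  # UTR length 0 counts in the first bin: lowest break is closed below
  bin <- cut(pmax(eligible$utr5_length_nt, .Machine$double.eps), edges,
             include.lowest = FALSE)
  labs <- levels(bin)
  rows <- lapply(seq_along(labs), function(i) {
    g <- eligible$gene_id[which(as.integer(bin) == i)]
    data.frame(bin = labs[i], n_genes = length(g),
               n_truncated = sum(g %in% trunc),
               proportion = if (length(g)) mean(g %in% trunc) else NA_real_,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), n_excluded = n_excluded)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact enumeration (via the exact null distribution of the rank-sum
#' statistic) when `min(n1, n2) <= 8` and there are no ties; otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @return list of class `rank_sum_result` with `statistic` (W, the
#'   Mann-Whitney U of the first sample), `n1`, `n2`, `p_two_sided` and
#'   `method` (`"exact"` or `"normal_approx"`).
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty for the rank-sum test")
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && min(length(a), length(b)) <= 8L
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  structure(list(statistic = unname(wt$statistic),
                 n1 = length(a), n2 = length(b),
                 p_two_sided = unname(wt$p.value),
                 method = if (use_exact) "exact" else "normal_approx"),
            class = "rank_sum_result")
}

#' @export
print.rank_sum_result <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, n = (%d, %d), p = %.4g [%s]\n",
              x$statistic, x$n1, x$n2, x$p_two_sided, x$method))
  invisible(x)
}

#' Compare 5' UTR lengths of a gene set against all remaining genes
#'
#' Partitions the per-gene UTR table into the named set (matched
#' case-insensitively against `gene_name`, falling back to `gene_id`) and
#' its complement, and compares the two length distributions by
#' [rank_sum_test()]. The returned per-group length vectors are ready for
#' empirical CDF plotting.
#'
#' @param utr_table per-gene table with `gene_id`, `gene_name`,
#'   `utr5_length_nt`.
#' @param gene_set character vector of gene symbols (e.g. a MitoCarta-style
#'   list).
#' @return list with `test` (a `rank_sum_result`), `in_set` and `out_set`
#'   length vectors, and `n_unmatched` set symbols not found.
#' @export
compare_gene_sets_cdf <- function(utr_table, gene_set) {
  sym <- toupper(ifelse(is.na(utr_table$gene_name) | utr_table$gene_name == "",
                        utr_table$gene_id, utr_table$gene_name))
  set <- toupper(gene_set)
  inside <- sym %in% set
  n_unmatched <- sum(!set %in% sym)
  if (!any(inside))
    stop("gene_set does not intersect the annotation")
  if (all(inside))
    stop("gene_set covers every gene; the complement is empty")
  a <- utr_table$utr5_length_nt[inside]
  b <- utr_table$utr5_length_nt[!inside]
  list(test = rank_sum_test(a, b), in_set = a, out_set = b,
       n_unmatched = n_unmatched)
}

#' Short-UTR genes producing more than one translational isoform
#'
#' @param short_set character vector of short-UTR gene_ids (from
#'   [short_utr_gene_set()]).
#' @param initiation initiation-site table.
#' @return sorted character vector: genes in `short_set` with >= 2
#'   initiation sites of which >= 1 is an N-terminal truncation.
#' @export
intersect_short_utr_multi_isoform <- function(short_set, initiation) {
  if (length(short_set) == 0L || nrow(initiation) == 0L)
    stop("both the short-UTR set and the initiation table must be non-empty")
  keep <- vapply(short_set, function(g) {
    d <- initiation[initiation$gene_id == g & initiation$reads >= 1, ,
                    drop = FALSE]
    nrow(d) >= 2L && any(d$site_class == "n_terminal_truncation")
  }, logical(1L))
  sort(short_set[keep])
}
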