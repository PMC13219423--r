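# ClinVar-style 5' UTR indel engine: parse a variant_summary-like table,
# keep indels wholly inside representative 5' UTR intervals, compute signed
# UTR-length changes (genomic coordinates for deletions, HGVS c.-notation
# for insertions/duplications/delins), and predict leaky-scanning
# consequences relative to the 40 nt short-UTR regime.

.indel_types <- c("deletion", "insertion", "duplication", "indel")

#' Parse a ClinVar variant_summary-style table
#'
#' Restricts rows to one assembly and to the four indel classes (deletion,
#' insertion, duplication, indel). Rows with non-integer coordinates are
#' skipped and counted.
#'
#' @param path tab-delimited file with columns `Name`, `Type`, `GeneSymbol`,
#'   `Assembly`, `Chromosome`, `Start`, `Stop`, `VariationID` (and
#'   optionally `ClinicalSignificance`).
#' @param assembly assembly to retain (default `"GRCh38"`).
#' @return data.frame `variation_id`, `gene_symbol`, `hgvs_name`,
#'   `variant_type`, `assembly`, `chrom`, `start`, `stop`,
#'   `clinical_significance`; attribute `n_skipped` counts dropped
#'   malformed-coordinate rows.
#' @export
parse_variant_table <- function(path, assembly = "GRCh38") {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  quote = "", comment.char = "")
  names(d) <- sub("^#", "", names(d))
  req <- c("Name", "Type", "GeneSymbol", "Assembly", "Chromosome",
           "Start", "Stop", "VariationID")
  if (!all(req %in% names(d)))
    stop("variant table lacks columns: ",
         paste(setdiff(req, names(d)), collapse = ", "))
  d <- d[d$Assembly == assembly &
         tolower(d$Type) %in% .indel_types, , drop = FALSE]
  start <- suppressWarnings(as.integer(d$Start))
  stop_ <- suppressWarnings(as.integer(d$Stop))
  bad <- is.na(start) | is.na(stop_) | stop_ < start
  n_skipped <- sum(bad)
  d <- d[!bad, , drop = FALSE]
  out <- data.frame(
    variation_id = as.character(d$VariationID),
    gene_symbol = d$GeneSymbol,
    hgvs_name = d$Name,
    variant_type = tolower(d$Type),
    assembly = d$Assembly,
    chrom = as.character(d$Chromosome),
    start = start[!bad], stop = stop_[!bad],
    clinical_significance = if ("ClinicalSignificance" %in% names(d))
      d$ClinicalSignificance else NA_character_,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, n_skipped = n_skipped)
}

#' Is a variant wholly inside a 5' UTR interval set?
#'
#' Applies the literal both-ends rule: `TRUE` iff the start coordinate falls
#' in some UTR interval AND the stop coordinate falls in some UTR interval.
#' A variant whose ends sit in two different UTR exons (spanning an intron)
#' still passes and is flagged via the `spans_intron` attribute.
#'
#' @param v one row of the table from [parse_variant_table()] (a list or
#'   single-row data.frame with `start` and `stop`).
#' @param utr a UTR interval set from [build_utr5_intervals()].
#' @return logical, with attribute `spans_intron`.
#' @export
variant_within_utr <- function(v, utr) {
  iv <- utr$intervals
  if (nrow(iv) == 0L)
    return(structure(FALSE, spans_intron = FALSE))
  hit <- function(p) which(p >= iv$start & p <= iv$end)
  hs <- hit(v$start); he <- hit(v$stop)
  ok <- length(hs) > 0L && length(he) > 0L
  structure(ok, spans_intron = ok && hs[1L] != he[1L])
}

#' Parse an HGVS c.-notation 5' UTR indel
#'
#' Supported kinds: `del`, `dup`, `ins`, `delins`, with strictly negative
#' (5' UTR) positions and no intronic offsets. Anything else (intronic
#' offsets such as `c.-10+5del`, non-negative positions, inversions,
#' missing `c.` expression) yields kind `"unsupported"` with a reason —
#' never a silent guess.
#'
#' @param name HGVS string, e.g. `"NM_000551.4(VHL):c.-75_-46del"`.
#' @return list of class `hgvs_utr_indel`: `kind`, `c_start`, `c_end`
#'   (negative, `c_start <= c_end`, -1 = base before the AUG),
#'   `inserted_seq`, `span` (`c_end - c_start + 1`; 0 for pure insertions),
#'   or kind `"unsupported"` plus `reason`.
#' @export
parse_hgvs_utr_indel <- function(name) {
  unsupported <- function(reason)
    structure(list(kind = "unsupported", reason = reason, name = name),
              class = "hgvs_utr_indel")
  m <- regmatches(name, regexpr("c\\.[^ ;,)]+", name))
  if (length(m) == 0L) return(unsupported("no c. expression"))
  expr <- sub("^c\\.", "", m[[1L]])
  if (grepl("[+*]", expr))
    return(unsupported("intronic offset or 3' UTR position"))
  pat <- paste0("^(-\\d+)(?:_(-?\\d+))?",
                "(delins|del|dup|ins)([ACGTUacgtu]*)$")
  g <- regmatches(expr, regexec(pat, expr))[[1L]]
  if (length(g) == 0L)
    return(unsupported("unrecognized or non-UTR c. expression"))
  p1 <- as.integer(g[2L])
  p2 <- if (nzchar(g[3L])) as.integer(g[3L]) else p1
  kind <- g[4L]
  seq <- toupper(g[5L])
  if (p1 >= 0L || p2 >= 0L)
    return(unsupported("position not in the 5' UTR (non-negative)"))
  if (p2 < p1) return(unsupported("descending position range"))
  if (kind == "ins") {
    if (!nzchar(seq)) return(unsupported("insertion without sequence"))
    if (p2 != p1 + 1L)
      return(unsupported("insertion flanks must be adjacent"))
  }
  if (kind == "delins" && !nzchar(seq))
    return(unsupported("delins without inserted sequence"))
  if (kind %in% c("del", "dup")) seq <- ""  # reference bases, not an insert
  span <- if (kind == "ins") 0L else p2 - p1 + 1L
  structure(list(kind = kind, c_start = p1, c_end = p2,
                 inserted_seq = seq, span = span, name = name),
            class = "hgvs_utr_indel")
}

#' Signed 5' UTR length change of one variant
#'
#' Deletions use genomic coordinates (`-(stop - start + 1)`); insertions,
#' duplications and delins use the parsed HGVS expression. When both routes
#' are computable for a deletion they must agree, otherwise the record is
#' flagged discordant.
#'
#' @param v one variant record (list/row with `variant_type`, `start`,
#'   `stop`).
#' @param h parsed HGVS indel from [parse_hgvs_utr_indel()], or `NULL`.
#' @return list: `delta_nt` (`NA` when not computable), `route`
#'   (`"genomic"`, `"hgvs"` or `"unparsed"`), `discordant`.
#' @export
compute_length_change <- function(v, h = NULL) {
  type <- v$variant_type
  hgvs_ok <- !is.null(h) && h$kind != "unsupported"
  if (type == "deletion") {
    delta <- -(v$stop - v$start + 1L)
    disc <- hgvs_ok && h$kind == "del" && -h$span != delta
    return(list(delta_nt = as.integer(delta), route = "genomic",
                discordant = disc))
  }
  if (!hgvs_ok)
    return(list(delta_nt = NA_integer_, route = "unparsed",
                discordant = FALSE))
  delta <- switch(h$kind,
    dup = h$span,
    ins = nchar(h$inserted_seq),
    delins = nchar(h$inserted_seq) - h$span,
    del = -h$span,  # type/name mismatch tolerated: name wins
    NA_integer_)
  list(delta_nt = as.integer(delta), route = "hgvs", discordant = FALSE)
}

#' Keep variants whose absolute UTR-length change meets a minimum size
#'
#' @param changes data.frame with a `delta_nt` column.
#' @param threshold minimum absolute change in bp, inclusive (default 10).
#' @return the surviving rows.
#' @export
apply_min_size <- function(changes, threshold = 10L) {
  stopifnot(threshold >= 1)
  out <- changes[!is.na(changes$delta_nt) &
                 abs(changes$delta_nt) >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict the leaky-scanning consequence of a UTR-length change
#'
#' With the short-UTR regime at `short_threshold` (inclusive):
#' `enhanced_leaky_scanning` when the mutant UTR drops into the short
#' regime from above, or when an already-short UTR is shortened further;
#' `suppressed_leaky_scanning` when a short UTR is lengthened out of the
#' regime; otherwise `minimal`.
#'
#' @param wt_utr_len wild-type 5' UTR length (nt, >= 0).
#' @param delta signed length change (nt).
#' @param short_threshold short-UTR cutoff (default 40, inclusive).
#' @return list: `wt_utr_len`, `delta_nt`, `mutant_utr_len`,
#'   `scanning_prediction`.
#' @export
classify_scanning_effect <- function(wt_utr_len, delta, short_threshold = 40L) {
  mutant <- wt_utr_len + delta
  if (any(mutant < 0))
    stop("mutant 5' UTR length negative: wt ", wt_utr_len, " + delta ", delta)
  short_wt <- wt_utr_len <= short_threshold
  short_mut <- mutant <= short_threshold
  pred <- ifelse((short_mut & !short_wt) | (short_wt & delta < 0),
                 "enhanced_leaky_scanning",
          ifelse(short_wt & !short_mut, "suppressed_leaky_scanning",
                 "minimal"))
  list(wt_utr_len = wt_utr_len, delta_nt = delta,
       mutant_utr_len = mutant, scanning_prediction = pred)
}

#' Run the full 5' UTR variant engine over a variant table
#'
#' Filters to variants with both ends inside the gene's representative 5'
#' UTR intervals, computes signed length changes, applies the minimum-size
#' threshold and classifies the predicted scanning consequence.
#'
#' @param variants table from [parse_variant_table()].
#' @param models named list of `transcript_model` objects.
#' @param representatives gene_symbol/gene_id -> transcript_id map; genes
#'   without a representative are reported separately.
#' @param min_size minimum |delta| in bp (default 10).
#' @param short_threshold short-UTR cutoff in nt (default 40).
#' @return list: `changes` (one row per retained variant: variant fields +
#'   `wt_utr_len`, `delta_nt`, `mutant_utr_len`, `passes_min_size`,
#'   `scanning_prediction`, `spans_intron`, `discordant`, `route`),
#'   `unparsed` (variants whose HGVS was required but unsupported),
#'   `no_representative` (variants on genes without a representative), and
#'   `counts` (tallies at each filter step).
#' @export
utr_variant_engine <- function(variants, models, representatives,
                               min_size = 10L, short_threshold = 40L) {
  reps <- representatives[!is.na(representatives)]
  # match variants to genes by symbol against gene_name, then gene_id
  by_name <- list(); by_id <- list()
  for (g in names(reps)) {
    t <- models[[reps[[g]]]]
    if (is.null(t) || !is_coding(t)) next
    by_name[[toupper(t$gene_name)]] <- t
    by_id[[toupper(g)]] <- t
  }
  rows <- list(); unparsed <- list(); no_rep <- list()
  n_in_utr <- 0L
  for (i in seq_len(nrow(variants))) {
    v <- as.list(variants[i, ])
    t <- by_name[[toupper(v$gene_symbol)]]
    if (is.null(t)) t <- by_id[[toupper(v$gene_symbol)]]
    if (is.null(t)) { no_rep[[length(no_rep) + 1L]] <- variants[i, ]; next }
    utr <- build_utr5_intervals(t)
    inside <- variant_within_utr(v, utr)
    if (!inside) next
    n_in_utr <- n_in_utr + 1L
    h <- parse_hgvs_utr_indel(v$hgvs_name)
    chg <- compute_length_change(v, h)
    if (is.na(chg$delta_nt)) {
      unparsed[[length(unparsed) + 1L]] <- cbind(
        variants[i, ], reason = h$reason, stringsAsFactors = FALSE)
      next
    }
    wt <- utr$total_nt
    if (wt + chg$delta_nt < 0) {
      unparsed[[length(unparsed) + 1L]] <- cbind(
        variants[i, ], reason = "delta exceeds wild-type UTR length",
        stringsAsFactors = FALSE)
      next
    }
    eff <- classify_scanning_effect(wt, chg$delta_nt, short_threshold)
    rows[[length(rows) + 1L]] <- cbind(
      variants[i, ],
      data.frame(wt_utr_len = wt, delta_nt = chg$delta_nt,
                 mutant_utr_len = eff$mutant_utr_len,
                 passes_min_size = abs(chg$delta_nt) >= min_size,
                 scanning_prediction = eff$scanning_prediction,
                 spans_intron = attr(inside, "spans_intron"),
                 discordant = chg$discordant, route = chg$route,
                 stringsAsFactors = FALSE))
  }
  bind <- function(l, proto) {
    if (length(l)) { x <- do.call(rbind, l); rownames(x) <- NULL; x }
    else proto
  }
  changes <- bind(rows, NULL)
  if (is.null(changes))
    changes <- data.frame(variation_id = character(), gene_symbol = character(),
                          hgvs_name = character(), variant_type = character(),
                          assembly = character(), chrom = character(),
                          start = integer(), stop = integer(),
                          clinical_significance = character(),
                          wt_utr_len = integer(), delta_nt = integer(),
                          mutant_utr_len = integer(),
                          passes_min_size = logical(),
                          scanning_prediction = character(),
                          spans_intron = logical(), discordant = logical(),
                          route = character(), stringsAsFactors = FALSE)
  sized <- apply_min_size(changes, min_size)
  list(changes = changes,
       sized = sized,
       unparsed = bind(unparsed, variants[0, ]),
       no_representative = bind(no_rep, variants[0, ]),
       counts = list(n_input = nrow(variants),
                     n_in_utr = n_in_utr,
                     n_with_delta = nrow(changes),
                     n_pass_min_size = nrow(sized),
                     n_unparsed = length(unparsed),
                     n_no_representative = length(no_rep)))
}

#' Waterfall summary of UTR-length changes
#'
#' @param changes table with `variation_id`, `delta_nt`,
#'   `scanning_prediction`.
#' @return list: `table` (descending `delta_nt`, ties broken by
#'   `variation_id`), `max_delta`, `min_delta` (both `NA` when empty) and
#'   `class_counts` (named integer vector over the three predictions).
#' @export
waterfall_summary <- function(changes) {
  classes <- c("enhanced_leaky_scanning", "suppressed_leaky_scanning",
               "minimal")
  o <- order(-changes$delta_nt, changes$variation_id)
  tab <- changes[o, , drop = FALSE]
  rownames(tab) <- NULL
  cc <- vapply(classes, function(cl)
    sum(changes$scanning_prediction == cl), integer(1L))
  list(table = tab,
       max_delta = if (nrow(tab)) max(tab$delta_nt) else NA_integer_,
       min_delta = if (nrow(tab)) min(tab$delta_nt) else NA_integer_,
       class_counts = cc)
}

#' Short-UTR-regime candidate report
#'
#' Variants acting in the short-UTR regime: wild-type UTR within the
#' threshold and |delta| at least `min_size` (split into lengthening and
#' shortening), plus long-to-short converters (wild-type above the
#' threshold, mutant at or below it).
#'
#' @param changes output table of [utr_variant_engine()] (`$changes` or
#'   `$sized`).
#' @param min_size minimum |delta| (default 10).
#' @param short_threshold short-UTR cutoff (default 40).
#' @return list of data.frames: `shortening`, `lengthening`,
#'   `long_to_short`.
#' @export
short_regime_candidates <- function(changes, min_size = 10L,
                                    short_threshold = 40L) {
  big <- abs(changes$delta_nt) >= min_size
  short_wt <- changes$wt_utr_len <= short_threshold
  list(
    shortening = changes[big & short_wt & changes$delta_nt < 0, ,
                         drop = FALSE],
    lengthening = changes[big & short_wt & changes$delta_nt > 0, ,
                          drop = FALSE],
    long_to_short = changes[big & !short_wt &
                            changes$mutant_utr_len <= short_threshold, ,
                            drop = FALSE])
}
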