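#' Overlap ratio between a predicted and a known pre-miRNA
#'
#' `ratio = overlapping_bases / denominator_length`. Intervals on different
#' chromosomes (or, in strand-strict mode, different strands) overlap by 0
#' bases. The denominator defaults to the known (documented) pre-miRNA's
#' length, so re-identification measures recovery of known records;
#' alternatives are exposed.
#'
#' @param predicted,known one-row interval data frames (or lists with
#'   `chrom`, `start`, `end`, `strand`).
#' @param denominator one of `"known"`, `"predicted"`, `"shorter"`.
#' @param strand_strict require matching strands (default TRUE).
#' @return list: `overlapping_bases`, `denominator_length`, `ratio`.
#' @export
overlap_ratio <- function(predicted, known, denominator = "known",
                          strand_strict = TRUE) {
  denominator <- match.arg(denominator, c("known", "predicted", "shorter"))
  ov <- 0L
  if (predicted$chrom[1] == known$chrom[1] &&
      (!strand_strict || predicted$strand[1] == known$strand[1])) {
    ov <- max(0L, min(predicted$end[1], known$end[1]) -
                  max(predicted$start[1], known$start[1]))
  }
  lk <- known$end[1] - known$start[1]
  lp <- predicted$end[1] - predicted$start[1]
  den <- switch(denominator, known = lk, predicted = lp, shorter = min(lk, lp))
  list(overlapping_bases = as.integer(ov), denominator_length = as.integer(den),
       ratio = ov / den)
}

## All-pairs ratio matrix via interval overlap, vectorised per chromosome.
## Returns data frame (pred_idx, known_idx, overlap, ratio).
overlap_pairs <- function(predicted, known, denominator, strand_strict) {
  if (nrow(predicted) == 0L || nrow(known) == 0L)
    return(data.frame(pred_idx = integer(0), known_idx = integer(0),
                      overlap = integer(0), ratio = numeric(0)))
  out <- list()
  for (chrom in intersect(unique(predicted$chrom), unique(known$chrom))) {
    pi <- which(predicted$chrom == chrom)
    ki <- which(known$chrom == chrom)
    hits <- IRanges::findOverlaps(as_iranges0(predicted$start[pi], predicted$end[pi]),
                                  as_iranges0(known$start[ki], known$end[ki]))
    if (length(hits) == 0L) next
    p <- pi[S4Vectors::queryHits(hits)]
    k <- ki[S4Vectors::subjectHits(hits)]
    if (strand_strict) {
      keep <- predicted$strand[p] == known$strand[k]
      p <- p[keep]; k <- k[keep]
    }
    if (length(p) == 0L) next
    ov <- pmin(predicted$end[p], known$end[k]) - pmax(predicted$start[p], known$start[k])
    lk <- known$end[k] - known$start[k]
    lp <- predicted$end[p] - predicted$start[p]
    den <- switch(denominator, known = lk, predicted = lp, shorter = pmin(lk, lp))
    out[[chrom]] <- data.frame(pred_idx = p, known_idx = k,
                               overlap = ov, ratio = ov / den)
  }
  if (length(out) == 0L)
    return(data.frame(pred_idx = integer(0), known_idx = integer(0),
                      overlap = integer(0), ratio = numeric(0)))
  do.call(rbind, unname(out))
}

#' Cross-reference predictions against known pre-miRNAs
#'
#' A known pre-miRNA counts as re-identified when at least one prediction
#' reaches `ratio >= threshold` against it (the boundary is inclusive).
#' Each prediction is assigned to at most one known record — its best
#' ratio, ties broken by the smaller known start — and predictions whose
#' best ratio is below the threshold are novel.
#'
#' @param predicted,known interval data frames (with optional `name`).
#' @param threshold minimum overlap ratio (default 0.5).
#' @param denominator,strand_strict see [overlap_ratio()].
#' @return a `crossref_result` list: `summary` (see [crossref_summary()])
#'   and `pairs`, a per-prediction table of best matches.
#' @export
cross_reference <- function(predicted, known, threshold = 0.5,
                            denominator = "known", strand_strict = TRUE) {
  stopifnot(threshold > 0, threshold <= 1)
  denominator <- match.arg(denominator, c("known", "predicted", "shorter"))
  pr <- overlap_pairs(predicted, known, denominator, strand_strict)
  reidentified <- unique(pr$known_idx[pr$ratio >= threshold])
  ## per-prediction best match
  best <- data.frame(pred_idx = integer(0), known_idx = integer(0), ratio = numeric(0))
  if (nrow(pr)) {
    ord <- order(pr$pred_idx, -pr$ratio, known$start[pr$known_idx])
    pr2 <- pr[ord, ]
    best <- pr2[!duplicated(pr2$pred_idx), c("pred_idx", "known_idx", "ratio")]
  }
  matched_pred <- best$pred_idx[best$ratio >= threshold]
  s <- crossref_summary(n_known = nrow(known),
                        n_reidentified = length(reidentified),
                        n_novel = nrow(predicted) - length(matched_pred))
  pname <- if (!is.null(predicted$name)) predicted$name else as.character(seq_len(nrow(predicted)))
  kname <- if (!is.null(known$name)) known$name else as.character(seq_len(nrow(known)))
  pairs <- data.frame(
    predicted = pname,
    known = ifelse(seq_len(nrow(predicted)) %in% best$pred_idx,
                   kname[best$known_idx[match(seq_len(nrow(predicted)), best$pred_idx)]],
                   NA_character_),
    ratio = ifelse(seq_len(nrow(predicted)) %in% best$pred_idx,
                   best$ratio[match(seq_len(nrow(predicted)), best$pred_idx)], 0),
    stringsAsFactors = FALSE)
  pairs$reidentified <- !is.na(pairs$known) & pairs$ratio >= threshold
  structure(list(summary = s, pairs = pairs), class = "crossref_result")
}

#' Summarise re-identification counts
#'
#' `pct_reidentified = 100 * n_reidentified / n_known`, reported to two
#' decimal places (e.g. 601 of 655 known records gives 91.76). With no
#' known records the percentage is `NA`.
#'
#' @param n_known number of known pre-miRNAs.
#' @param n_reidentified number of them recovered at the ratio threshold.
#' @param n_novel predictions matching no known record.
#' @return list with the counts and `pct_reidentified`.
#' @export
crossref_summary <- function(n_known, n_reidentified, n_novel = NA_integer_) {
  stopifnot(is.na(n_reidentified) || n_reidentified <= n_known)
  pct <- if (n_known > 0) round(100 * n_reidentified / n_known, 2) else NA_real_
  list(n_known = as.integer(n_known), n_reidentified = as.integer(n_reidentified),
       n_novel = as.integer(n_novel), pct_reidentified = pct)
}

#' Predicted-vs-sequenced Venn counts
#'
#' Counts records identified by both the synteny-based predictions and the
#' sequencing-derived calls, and by each alone. A sequenced record is "both"
#' when some prediction overlaps it at `ratio >= threshold` with the
#' sequenced record's length as denominator; a prediction is "both" when it
#' reaches the threshold against some sequenced record.
#'
#' @param predicted,sequenced interval data frames.
#' @param threshold minimum overlap ratio (default 0.5).
#' @param strand_strict see [overlap_ratio()].
#' @return list: `n_predicted_only`, `n_both`, `n_sequenced_only`.
#' @export
venn_compare <- function(predicted, sequenced, threshold = 0.5,
                         strand_strict = TRUE) {
  pr <- overlap_pairs(predicted, sequenced, "known", strand_strict)
  hit <- pr[pr$ratio >= threshold, ]
  n_both <- length(unique(hit$known_idx))
  n_pred_matched <- length(unique(hit$pred_idx))
  list(n_predicted_only = nrow(predicted) - n_pred_matched,
       n_both = n_both,
       n_sequenced_only = nrow(sequenced) - n_both)
}
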