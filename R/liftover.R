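#' Build an index over chain reference spans
#'
#' Indexes the reference-side span of every chain per chromosome so that
#' [map_interval()] can retrieve exactly the chains overlapping a query
#' interval.
#'
#' @param chains list of `chain_alignment` objects from [parse_chain_file()].
#' @return a `chain_index` object.
#' @export
build_chain_index <- function(chains) {
  ids <- as.integer(vapply(chains, `[[`, numeric(1), "chain_id"))
  if (anyDuplicated(ids)) stop("duplicate chain_id", call. = FALSE)
  tab <- data.frame(
    chain_id = ids,
    chrom = vapply(chains, `[[`, character(1), "ref_chrom"),
    start = as.integer(vapply(chains, `[[`, numeric(1), "ref_start")),
    end   = as.integer(vapply(chains, `[[`, numeric(1), "ref_end")),
    score = vapply(chains, `[[`, numeric(1), "score"))
  by_chrom <- split(tab, tab$chrom)
  trees <- lapply(by_chrom, function(d) as_iranges0(d$start, d$end))
  structure(list(chains = stats::setNames(chains, ids),
                 by_chrom = by_chrom, trees = trees),
            class = "chain_index")
}

#' Query chains overlapping a reference interval
#' @param index a `chain_index`.
#' @param chrom,start,end query interval (internal 0-based half-open).
#' @return integer vector of chain ids (possibly empty).
#' @export
query_chains <- function(index, chrom, start, end) {
  d <- index$by_chrom[[chrom]]
  if (is.null(d)) return(integer(0))
  hits <- IRanges::overlapsAny(index$trees[[chrom]], as_iranges0(start, end))
  d$chain_id[hits]
}

## Walk one chain's block ladder against [s, e) on the reference.
## Returns forward-strand target spans of the aligned bases, in genomic order,
## adjacent spans merged (so a reference-only gap "closes" on the target).
walk_chain <- function(ch, s, e) {
  b <- ch$blocks
  r <- ch$ref_start
  q <- ch$tgt_start
  spans <- matrix(numeric(0), ncol = 2)
  for (k in seq_len(nrow(b))) {
    lo <- max(s, r); hi <- min(e, r + b[k, "size"])
    if (lo < hi) {
      qs <- q + (lo - r); qe <- q + (hi - r)
      if (ch$tgt_strand == "-") { t0 <- ch$tgt_size - qe; t1 <- ch$tgt_size - qs }
      else { t0 <- qs; t1 <- qe }
      spans <- rbind(spans, c(t0, t1))
    }
    r <- r + b[k, "size"] + b[k, "dt"]
    q <- q + b[k, "size"] + b[k, "dq"]
    if (r >= e) break
  }
  if (nrow(spans) == 0L) return(spans)
  spans <- spans[order(spans[, 1]), , drop = FALSE]
  merged <- spans[1, , drop = FALSE]
  for (k in seq_len(nrow(spans))[-1]) {
    if (spans[k, 1] == merged[nrow(merged), 2])
      merged[nrow(merged), 2] <- spans[k, 2]
    else merged <- rbind(merged, spans[k, ])
  }
  merged
}

flip_strand <- function(s) ifelse(s == "+", "-", "+")

#' Map one reference interval to the target genome through chains
#'
#' Each base of the interval is carried through the block ladder of every
#' candidate chain; bases falling in reference-side gaps (`dt`) are
#' unmatched. Among chains reaching `match_fraction >= min_match` the
#' highest-scoring one wins (ties to the lower `chain_id`). Status is
#' `mapped` when the winning chain's matched bases form one contiguous
#' target interval, `split` when they do not, `partial` when the best chain
#' aligns some but too few bases, `deleted` when every overlapping chain
#' aligns zero bases, and `unmapped` when no chain overlaps the interval.
#' Target coordinates are always reported on the forward strand; the strand
#' flag composes the source strand with the chain orientation.
#'
#' @param iv one-row [genomic_intervals()] data frame (or list with `chrom`,
#'   `start`, `end`, `strand`).
#' @param index a `chain_index`.
#' @param min_match minimum fraction of bases that must align (default 0.95).
#' @return a `lift_result` list: `source`, `status`, `mappings` (data frame
#'   of contiguous target pieces with `chain_id` and `matched_bases`),
#'   `matched_bases`, `match_fraction`, `chain_id`.
#' @export
map_interval <- function(iv, index, min_match = 0.95) {
  stopifnot(min_match > 0, min_match <= 1)
  s <- as.integer(iv$start[1]); e <- as.integer(iv$end[1])
  chrom <- as.character(iv$chrom[1]); strand <- as.character(iv$strand[1])
  width <- e - s
  empty <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), chain_id = integer(0),
                      matched_bases = integer(0))
  res <- function(status, mappings = empty, matched = 0L, chain_id = NA_integer_)
    structure(list(source = list(chrom = chrom, start = s, end = e, strand = strand),
                   status = status, mappings = mappings,
                   matched_bases = matched,
                   match_fraction = matched / width,
                   chain_id = chain_id),
              class = "lift_result")
  cand_ids <- query_chains(index, chrom, s, e)
  if (length(cand_ids) == 0L) return(res("unmapped"))
  walks <- lapply(cand_ids, function(id) walk_chain(index$chains[[as.character(id)]], s, e))
  matched <- vapply(walks, function(w) if (nrow(w)) sum(w[, 2] - w[, 1]) else 0, numeric(1))
  if (all(matched == 0)) return(res("deleted"))
  keep <- matched > 0
  cand_ids <- cand_ids[keep]; walks <- walks[keep]; matched <- matched[keep]
  mf <- matched / width
  score <- vapply(cand_ids, function(id) index$chains[[as.character(id)]]$score, numeric(1))
  ord <- order(-(mf >= min_match), -score, cand_ids)
  best <- ord[1]
  ch <- index$chains[[as.character(cand_ids[best])]]
  w <- walks[[best]]
  out_strand <- if (ch$tgt_strand == "+") strand else flip_strand(strand)
  mappings <- data.frame(chrom = ch$tgt_chrom,
                         start = as.integer(w[, 1]), end = as.integer(w[, 2]),
                         strand = out_strand, chain_id = ch$chain_id,
                         matched_bases = as.integer(w[, 2] - w[, 1]))
  status <- if (mf[best] < min_match) "partial"
            else if (nrow(w) == 1L) "mapped" else "split"
  res(status, mappings, as.integer(matched[best]), ch$chain_id)
}

#' Map many intervals through a chain index
#'
#' Vectorised wrapper around [map_interval()] returning one row per input
#' interval. For `split` results the row reports the largest contiguous
#' piece; downstream candidacy excludes splits unless `allow_split = TRUE`.
#'
#' @param ivs a [genomic_intervals()] data frame (extra columns carried
#'   through).
#' @param index a `chain_index`.
#' @param min_match minimum match fraction.
#' @param allow_split keep the largest piece of split mappings (default
#'   FALSE: splits stay non-mapped downstream).
#' @return data frame: input columns plus `status`, `tgt_chrom`,
#'   `tgt_start`, `tgt_end`, `tgt_strand`, `chain_id`, `matched_bases`,
#'   `match_fraction`.
#' @export
map_intervals <- function(ivs, index, min_match = 0.95, allow_split = FALSE) {
  n <- nrow(ivs)
  out <- ivs
  out$status <- character(n)
  out$tgt_chrom <- NA_character_
  out$tgt_start <- NA_integer_; out$tgt_end <- NA_integer_
  out$tgt_strand <- NA_character_
  out$chain_id <- NA_integer_; out$matched_bases <- NA_integer_
  out$match_fraction <- NA_real_
  for (i in seq_len(n)) {
    lr <- map_interval(ivs[i, ], index, min_match)
    out$status[i] <- lr$status
    out$matched_bases[i] <- lr$matched_bases
    out$match_fraction[i] <- lr$match_fraction
    out$chain_id[i] <- lr$chain_id
    m <- lr$mappings
    use <- lr$status == "mapped" || (lr$status == "split" && allow_split)
    if (use && nrow(m)) {
      j <- which.max(m$end - m$start)
      out$tgt_chrom[i] <- m$chrom[j]
      out$tgt_start[i] <- m$start[j]; out$tgt_end[i] <- m$end[j]
      out$tgt_strand[i] <- m$strand[j]
    }
  }
  out
}
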