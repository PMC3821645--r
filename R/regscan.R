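#' Classify a miRNA locus by genomic context
#'
#' `intronic` when the interval lies entirely within an intron of a gene
#' (host gene strand ignored for containment), `exonic` when it intersects
#' any exon, `intergenic` otherwise. When introns of several genes contain
#' the locus, the gene with the shortest containing intron hosts it (ties
#' to the smaller `gene_id`). The intron index is reported in transcription
#' order (for minus-strand genes, counted from the 3'-most exon).
#'
#' @param mirna one-row interval data frame.
#' @param genes list of `gene_model` objects.
#' @return a `genomic_context` list: `label`, `host_gene`, `host_symbol`,
#'   `intron_index`, and (for intronic loci) `intron_start`, `intron_end`,
#'   `host_strand`.
#' @export
classify_genomic_context <- function(mirna, genes) {
  s <- mirna$start[1]; e <- mirna$end[1]; chrom <- mirna$chrom[1]
  best <- NULL
  touches_exon <- FALSE
  for (g in genes) {
    if (g$chrom != chrom) next
    ex <- g$exons
    if (any(ex$start < e & ex$end > s)) touches_exon <- TRUE
    ins <- g$introns
    hit <- which(ins$start <= s & ins$end >= e)
    for (h in hit) {
      len <- ins$end[h] - ins$start[h]
      if (is.null(best) || len < best$len ||
          (len == best$len && g$gene_id < best$gene_id)) {
        best <- list(gene_id = g$gene_id, symbol = g$symbol, len = len,
                     index = ins$index[h], start = ins$start[h],
                     end = ins$end[h], strand = g$strand)
      }
    }
  }
  if (!is.null(best)) {
    return(structure(list(label = "intronic", host_gene = best$gene_id,
                          host_symbol = best$symbol,
                          intron_index = as.integer(best$index),
                          intron_start = best$start, intron_end = best$end,
                          host_strand = best$strand),
                     class = "genomic_context"))
  }
  if (touches_exon)
    return(structure(list(label = "exonic", host_gene = "", host_symbol = "",
                          intron_index = 0L), class = "genomic_context"))
  structure(list(label = "intergenic", host_gene = "", host_symbol = "",
                 intron_index = 0L), class = "genomic_context")
}

#' Extract the putative regulatory region of a miRNA gene
#'
#' Intronic miRNAs: the sequence from the host intron's transcription-order
#' start to the pre-miRNA's transcription-order start (empty when the miRNA
#' begins at the intron start). Intergenic miRNAs: `upstream_len` bases
#' upstream of the pre-miRNA start on its own strand, truncated at the
#' chromosome edge. The region is split at every run of `N` into N-free
#' segments; minus-strand regions are reported reverse-complemented, in
#' transcription orientation, with segments listed in genomic order.
#'
#' @param mirna one-row interval data frame (strand used for the upstream
#'   rule; needs `name` for labelling).
#' @param ctx the [classify_genomic_context()] result for `mirna`.
#' @param genome named character vector of chromosome sequences (or FASTA
#'   record list).
#' @param upstream_len upstream window for intergenic miRNAs (default 2000).
#' @return a `regulatory_region` list: `origin_mirna`, `rule_applied`,
#'   `strand`, `segments` (list of `list(chrom, start, end, seq)`).
#' @export
extract_regulatory_region <- function(mirna, ctx, genome, upstream_len = 2000L) {
  genome <- genome_as_vector(genome)
  chrom <- mirna$chrom[1]
  nm <- if (!is.null(mirna$name)) mirna$name[1] else "mirna"
  if (ctx$label == "exonic")
    stop("no regulatory-region rule for exonic miRNAs", call. = FALSE)
  if (ctx$label == "intronic") {
    strand <- ctx$host_strand
    if (strand == "+") { rs <- ctx$intron_start; re <- mirna$start[1] }
    else { rs <- mirna$end[1]; re <- ctx$intron_end }
    rule <- "intron_start_to_mirna_start"
  } else {
    strand <- mirna$strand[1]
    if (strand == "+") { rs <- max(0L, mirna$start[1] - upstream_len); re <- mirna$start[1] }
    else { rs <- mirna$end[1]; re <- min(nchar(genome[[chrom]]), mirna$end[1] + upstream_len) }
    rule <- "upstream_2000"
  }
  segments <- list()
  if (re > rs) {
    seq_fwd <- fetch_seq(genome, chrom, rs, re, "+")
    ## split on N runs, keeping genomic coordinates of each clean piece
    nons <- gregexpr("[^N]+", seq_fwd)[[1]]
    if (nons[1] != -1L) {
      lens <- attr(nons, "match.length")
      segments <- lapply(seq_along(nons), function(k) {
        a <- rs + nons[k] - 1L
        b <- a + lens[k]
        sq <- substr(seq_fwd, nons[k], nons[k] + lens[k] - 1L)
        if (strand == "-") sq <- revcomp(sq)
        list(chrom = chrom, start = a, end = b, seq = sq)
      })
    }
  }
  structure(list(origin_mirna = nm, rule_applied = rule, strand = strand,
                 segments = segments), class = "regulatory_region")
}

#' Log-odds position weight matrix from a PFM
#'
#' `p(b, i) = (count(b, i) + pseudocount * bg(b)) / (colsum(i) + pseudocount)`,
#' scores in log2 (bits): `log2(p / bg)`.
#'
#' @param pfm a `pfm` object.
#' @param background length-4 probability vector (A, C, G, T).
#' @param pseudocount total pseudocount distributed by background
#'   (default 0.8).
#' @return 4 x width numeric matrix of log2 odds, rows A, C, G, T.
#' @export
pfm_to_pwm <- function(pfm, background = rep(0.25, 4), pseudocount = 0.8) {
  stopifnot(abs(sum(background) - 1) < 1e-9, all(background > 0))
  cs <- colSums(pfm$counts)
  p <- sweep(pfm$counts + pseudocount * background, 2, cs + pseudocount, "/")
  log2(p / background)
}

## score every window of `seq` (N-free, upper-case ACGT) against a PWM
score_windows <- function(seq, pwm) {
  w <- ncol(pwm)
  n <- nchar(seq)
  if (n < w) return(numeric(0))
  idx <- match(strsplit(seq, "")[[1]], c("A", "C", "G", "T"))
  sc <- numeric(n - w + 1L)
  for (j in seq_len(w)) sc <- sc + pwm[cbind(idx[j:(j + n - w)], j)]
  sc
}

#' Scan a regulatory region with one PFM
#'
#' Both strands of every N-free segment are scanned (the minus strand via
#' the reverse-complemented PWM, so a hit's `position` is always the
#' window's offset in the segment as stored). A window is a hit when its
#' `relative_score = (score - min) / (max - min) >= rel_threshold`, where
#' min and max are the PWM's attainable score extremes. When an occupancy
#' track is supplied each hit gets the mean occupancy over its genomic
#' window, and hits with occupancy above `o_max` (if set) are dropped —
#' binding sites favour nucleosome-depleted sequence.
#'
#' @param region a [extract_regulatory_region()] result.
#' @param pfm a `pfm` object.
#' @param background length-4 base probabilities (A, C, G, T).
#' @param rel_threshold minimum relative score (default 0.8).
#' @param pseudocount see [pfm_to_pwm()].
#' @param occupancy optional bedGraph data frame from [read_bedgraph()].
#' @param o_max optional maximum occupancy for a hit to be kept.
#' @return data frame: `tf_name`, `segment`, `position`, `strand`,
#'   `log_odds`, `relative_score`, `occupancy`.
#' @export
scan_pfm <- function(region, pfm, background = rep(0.25, 4),
                     rel_threshold = 0.8, pseudocount = 0.8,
                     occupancy = NULL, o_max = NULL) {
  stopifnot(rel_threshold > 0, rel_threshold <= 1)
  pwm <- pfm_to_pwm(pfm, background, pseudocount)
  w <- ncol(pwm)
  smin <- sum(apply(pwm, 2, min)); smax <- sum(apply(pwm, 2, max))
  ## reverse-complement PWM: complement rows, reverse columns
  pwm_rc <- pwm[c(4, 3, 2, 1), rev(seq_len(w)), drop = FALSE]
  rownames(pwm_rc) <- c("A", "C", "G", "T")
  hits <- list()
  for (k in seq_along(region$segments)) {
    seg <- region$segments[[k]]
    for (str in c("+", "-")) {
      sc <- score_windows(seg$seq, if (str == "+") pwm else pwm_rc)
      rel <- (sc - smin) / (smax - smin)
      sel <- which(rel >= rel_threshold)
      if (length(sel) == 0L) next
      occ <- rep(NA_real_, length(sel))
      if (!is.null(occupancy)) {
        occ <- vapply(sel, function(p0) {
          ## genomic window of the hit: segment seq may itself be the
          ## reverse complement of the genomic segment
          if (region$strand == "+") { a <- seg$start + p0 - 1L; b <- a + w }
          else { b <- seg$end - (p0 - 1L); a <- b - w }
          occupancy_mean(occupancy, seg$chrom, a, b)
        }, numeric(1))
      }
      hits[[length(hits) + 1L]] <- data.frame(
        tf_name = pfm$tf_name, segment = k, position = sel - 1L,
        strand = str, log_odds = sc[sel], relative_score = rel[sel],
        occupancy = occ)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(tf_name = character(0), segment = integer(0),
                      position = integer(0), strand = character(0),
                      log_odds = numeric(0), relative_score = numeric(0),
                      occupancy = numeric(0)))
  out <- do.call(rbind, hits)
  if (!is.null(o_max)) out <- out[is.na(out$occupancy) | out$occupancy <= o_max, ]
  rownames(out) <- NULL
  out
}

#' Mean occupancy over a genomic window
#' @param track bedGraph data frame (`chrom`, `start`, `end`, `value`).
#' @param chrom,start,end the window (0-based half-open).
#' @return base-weighted mean of `value` over covered bases, NA if none.
#' @export
occupancy_mean <- function(track, chrom, start, end) {
  t <- track[track$chrom == chrom & track$start < end & track$end > start, ]
  if (nrow(t) == 0L) return(NA_real_)
  cov <- pmin(t$end, end) - pmax(t$start, start)
  sum(cov * t$value) / sum(cov)
}

#' Transcription factors shared across miRNA regulatory regions
#'
#' @param hitsets named list: miRNA name -> character vector of TF names
#'   with at least one binding-site hit in its regulatory region.
#' @param min_fraction minimum fraction of regions a TF must hit.
#' @return data frame sorted by `n_mirnas` (descending) then `tf_name`:
#'   `tf_name`, `n_mirnas`, `members` (comma-joined miRNA names).
#' @export
shared_tf_summary <- function(hitsets, min_fraction = 0.5) {
  stopifnot(length(hitsets) >= 1L)
  tfs <- sort(unique(unlist(hitsets)))
  rows <- lapply(tfs, function(tf) {
    members <- names(hitsets)[vapply(hitsets, function(s) tf %in% s, logical(1))]
    data.frame(tf_name = tf, n_mirnas = length(members),
               members = paste(members, collapse = ","))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(tf_name = character(0),
                                      n_mirnas = integer(0),
                                      members = character(0)))
  out <- out[out$n_mirnas >= min_fraction * length(hitsets), , drop = FALSE]
  out <- out[order(-out$n_mirnas, out$tf_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
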