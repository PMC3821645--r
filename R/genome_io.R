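#' Read a multi-record FASTA file
#'
#' Sequences are upper-cased on read; `U` is preserved (it is normalised to
#' `T` only where folding or motif scanning needs a DNA alphabet).
#'
#' @param path path to a FASTA file.
#' @return a list of records, each `list(id =, seq =)`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record '", ids[which(!nzchar(seqs))[1]], "' in ", path,
         call. = FALSE)
  }
  bad <- grepl("[^ACGTNU]", seqs)
  if (any(bad))
    stop("non-nucleotide characters in record '", ids[which(bad)[1]], "'", call. = FALSE)
  unname(Map(function(i, s) list(id = i, seq = s), ids, seqs))
}

#' Write records to FASTA
#' @param records list of `list(id =, seq =)` records (as from [read_fasta()]).
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  ss <- Biostrings::BStringSet(vapply(records, `[[`, character(1), "seq"))
  names(ss) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Parse a UCSC chain file
#'
#' A chain is a scored, block-gapped pairwise alignment between a segment of
#' the reference assembly (the chain format's "target"/`t` side, the assembly
#' coordinates are lifted *from*) and a segment of the query assembly (`q`
#' side, lifted *to*). Header:
#' `chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id`,
#' followed by alignment lines `size dt dq` (last line `size` only), where
#' `size` is an aligned block length, `dt` the gap on the reference side and
#' `dq` the gap on the query side.
#'
#' Every chain is checked against the format's arithmetic:
#' `sum(size) + sum(dt) == tEnd - tStart` and
#' `sum(size) + sum(dq) == qEnd - qStart`; violating chains abort the read.
#' Query-side coordinates of minus-strand chains are kept in chain
#' convention (counted from the start of the reverse-complemented
#' chromosome); [map_interval()] converts to forward-strand coordinates.
#'
#' @param path path to a chain file.
#' @return a list of `chain_alignment` objects with fields `chain_id`,
#'   `score`, `ref_chrom`, `ref_size`, `ref_start`, `ref_end`, `tgt_chrom`,
#'   `tgt_size`, `tgt_strand`, `tgt_start`, `tgt_end` and a `blocks` matrix
#'   with columns `size`, `dt`, `dq` (the final block's gaps are 0).
#' @export
parse_chain_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  hdr_idx <- grep("^chain\\b", lines)
  if (length(hdr_idx) == 0L) stop("no chain records in ", path, call. = FALSE)
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  chains <- vector("list", length(hdr_idx))
  for (k in seq_along(hdr_idx)) {
    f <- strsplit(trimws(lines[hdr_idx[k]]), "\\s+")[[1]]
    if (length(f) != 13L)
      stop("malformed chain header at line ", hdr_idx[k], call. = FALSE)
    body <- lines[(hdr_idx[k] + 1L):ends[k]]
    body <- body[nzchar(trimws(body))]
    rows <- lapply(strsplit(trimws(body), "\\s+"), as.numeric)
    nlast <- length(rows[[length(rows)]])
    if (nlast == 1L) rows[[length(rows)]] <- c(rows[[length(rows)]], 0, 0)
    if (any(lengths(rows) != 3L))
      stop("malformed block line in chain ", f[13], call. = FALSE)
    blocks <- do.call(rbind, rows)
    colnames(blocks) <- c("size", "dt", "dq")
    ch <- structure(list(
      chain_id  = as.integer(f[13]), score = as.numeric(f[2]),
      ref_chrom = f[3], ref_size = as.integer(f[4]),
      ref_start = as.integer(f[6]), ref_end = as.integer(f[7]),
      tgt_chrom = f[8], tgt_size = as.integer(f[9]), tgt_strand = f[10],
      tgt_start = as.integer(f[11]), tgt_end = as.integer(f[12]),
      blocks = blocks), class = "chain_alignment")
    if (f[5] != "+")
      stop("chain ", ch$chain_id, ": reference strand must be '+'", call. = FALSE)
    if (any(blocks[, "size"] <= 0) || any(blocks[, c("dt", "dq")] < 0))
      stop("chain ", ch$chain_id, ": block sizes must be > 0 and gaps >= 0",
           call. = FALSE)
    if (sum(blocks[, "size"]) + sum(blocks[, "dt"]) != ch$ref_end - ch$ref_start ||
        sum(blocks[, "size"]) + sum(blocks[, "dq"]) != ch$tgt_end - ch$tgt_start)
      stop("chain ", ch$chain_id, ": block sums contradict header spans",
           call. = FALSE)
    chains[[k]] <- ch
  }
  ids <- vapply(chains, `[[`, integer(1), "chain_id")
  if (anyDuplicated(ids)) stop("duplicate chain id(s) in ", path, call. = FALSE)
  chains
}

#' Write chain alignments in UCSC chain format
#' @param chains list of `chain_alignment` objects.
#' @param path output path.
#' @export
write_chain_file <- function(chains, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in chains) {
    writeLines(paste("chain", format(ch$score, scientific = FALSE),
                     ch$ref_chrom, ch$ref_size, "+", ch$ref_start, ch$ref_end,
                     ch$tgt_chrom, ch$tgt_size, ch$tgt_strand,
                     ch$tgt_start, ch$tgt_end, ch$chain_id), con)
    b <- ch$blocks
    n <- nrow(b)
    if (n > 1L)
      writeLines(paste(b[-n, "size"], b[-n, "dt"], b[-n, "dq"]), con)
    writeLines(c(as.character(b[n, "size"]), ""), con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects `gene` and `exon` features; exon `Parent` attributes must resolve
#' to a gene directly or through one intermediate transcript feature.
#' GFF3's 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention. Introns are derived as the gaps between
#' consecutive exons and indexed in transcription order (reverse of genomic
#' order for minus-strand genes).
#'
#' @param path path to a GFF3 file.
#' @return a list of `gene_model` objects: `gene_id`, `symbol`, `chrom`,
#'   `start`, `end`, `strand`, `exons` (data frame, genomic order),
#'   `introns` (data frame with transcription-order `index`).
#' @export
read_gene_models_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  is_exon <- md$type == "exon"
  gid <- as.character(md$ID)
  ## map transcript -> gene for one level of nesting
  parent_of <- function(p) vapply(p, function(x) if (length(x)) x[[1]] else NA_character_,
                                  character(1))
  parents <- parent_of(md$Parent)
  tx2gene <- stats::setNames(parents[!is_gene & !is_exon & !is.na(gid)],
                             gid[!is_gene & !is_exon & !is.na(gid)])
  genes <- which(is_gene)
  out <- vector("list", length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    this_id <- gid[g]
    ex_parent <- parents[is_exon]
    ex_parent[ex_parent %in% names(tx2gene)] <- tx2gene[ex_parent[ex_parent %in% names(tx2gene)]]
    sel <- which(is_exon)[ex_parent == this_id]
    if (length(sel) == 0L)
      stop("gene '", this_id, "' has no exons", call. = FALSE)
    ex <- data.frame(start = BiocGenerics::start(gr)[sel] - 1L,
                     end   = BiocGenerics::end(gr)[sel])
    ex <- ex[order(ex$start), , drop = FALSE]
    gm <- new_gene_model(
      gene_id = this_id,
      symbol  = if (!is.null(md$Name)) as.character(md$Name)[g] else this_id,
      chrom   = as.character(GenomicRanges::seqnames(gr))[g],
      start   = BiocGenerics::start(gr)[g] - 1L,
      end     = BiocGenerics::end(gr)[g],
      strand  = as.character(BiocGenerics::strand(gr))[g],
      exons   = ex)
    out[[i]] <- gm
  }
  out
}

## Constructor + invariant checks shared by the GFF3 reader and the simulator.
new_gene_model <- function(gene_id, symbol, chrom, start, end, strand, exons) {
  stopifnot(nrow(exons) >= 1L)
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("gene '", gene_id, "': overlapping exons", call. = FALSE)
  if (any(exons$start < start) || any(exons$end > end))
    stop("gene '", gene_id, "': exon outside gene interval", call. = FALSE)
  n <- nrow(exons)
  if (n > 1L) {
    introns <- data.frame(start = exons$end[-n], end = exons$start[-1])
    introns$index <- if (strand == "+") seq_len(n - 1L) else rev(seq_len(n - 1L))
  } else {
    introns <- data.frame(start = integer(0), end = integer(0), index = integer(0))
  }
  structure(list(gene_id = gene_id, symbol = symbol, chrom = chrom,
                 start = as.integer(start), end = as.integer(end),
                 strand = strand, exons = exons, introns = introns),
            class = "gene_model")
}

#' Write gene models as GFF3
#' @param genes list of `gene_model` objects.
#' @param path output path.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    writeLines(paste(g$chrom, "synmir", "gene", g$start + 1L, g$end, ".",
                     g$strand, ".", paste0("ID=", g$gene_id, ";Name=", g$symbol),
                     sep = "\t"), con)
    for (j in seq_len(nrow(g$exons)))
      writeLines(paste(g$chrom, "synmir", "exon",
                       g$exons$start[j] + 1L, g$exons$end[j], ".",
                       g$strand, ".",
                       paste0("ID=", g$gene_id, ".e", j, ";Parent=", g$gene_id),
                       sep = "\t"), con)
  }
  invisible(path)
}

#' Read a BED6 file of intervals
#'
#' BED is already 0-based half-open; the `name` column carries miRBase-style
#' names, `score` is free. Missing strand defaults to "+".
#'
#' @param path path to a BED file.
#' @return a [genomic_intervals()] data frame with `name` and `score`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, fill = TRUE)
  nm <- c("chrom", "start", "end", "name", "score", "strand")
  k <- min(ncol(df), 6L)
  names(df)[seq_len(k)] <- nm[seq_len(k)]
  if (is.null(df$name)) df$name <- paste0("iv", seq_len(nrow(df)))
  if (is.null(df$score)) df$score <- 0
  if (is.null(df$strand) || all(is.na(df$strand))) df$strand <- "+"
  genomic_intervals(df$chrom, df$start, df$end, df$strand,
                    name = df$name, score = df$score)
}

#' Write intervals as BED6
#' @param df a [genomic_intervals()] data frame (optional `name`, `score`).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  name <- if (!is.null(df$name)) df$name else paste0("iv", seq_len(nrow(df)))
  score <- if (!is.null(df$score)) df$score else 0
  utils::write.table(data.frame(df$chrom, df$start, df$end, name, score, df$strand),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read position frequency matrices in JASPAR text format
#'
#' Each record is a header line `>MATRIX_ID NAME` followed by four rows
#' `A [ n n ... ]`, `C [...]`, `G [...]`, `T [...]`. Counts are kept exactly
#' as read. A column whose four counts sum to zero is rejected.
#'
#' @param path path to a JASPAR-format text file.
#' @return a list of `pfm` objects: `tf_name`, `matrix_id`, `counts`
#'   (4 x width numeric matrix, rows A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) stop("no JASPAR records in ", path, call. = FALSE)
  lapply(hdr, function(h) {
    f <- strsplit(sub("^>", "", trimws(lines[h])), "\\s+")[[1]]
    matrix_id <- f[1]
    tf_name <- if (length(f) > 1L) paste(f[-1], collapse = " ") else f[1]
    if (h + 4L > length(lines))
      stop("truncated JASPAR record '", matrix_id, "'", call. = FALSE)
    rows <- lapply(lines[(h + 1L):(h + 4L)], function(l) {
      x <- sub("^\\s*[ACGTacgt]\\s*", "", l)
      x <- gsub("[][]", " ", x)
      toks <- strsplit(trimws(x), "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(toks))
      if (length(v) == 0L || anyNA(v))
        stop("unparseable count row in JASPAR record '", matrix_id, "'",
             call. = FALSE)
      v
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("row-length mismatch in JASPAR record '", matrix_id, "'", call. = FALSE)
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    if (ncol(counts) < 1L || any(colSums(counts) <= 0))
      stop("JASPAR record '", matrix_id,
           "': every column must have a positive count sum", call. = FALSE)
    structure(list(tf_name = tf_name, matrix_id = matrix_id, counts = counts),
              class = "pfm")
  })
}

#' Write PFMs in JASPAR text format
#' @param pfms list of `pfm` objects.
#' @param path output path.
#' @export
write_jaspar_pfm <- function(pfms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pfms) {
    writeLines(paste0(">", p$matrix_id, " ", p$tf_name), con)
    for (b in c("A", "C", "G", "T"))
      writeLines(paste0(b, "  [ ", paste(p$counts[b, ], collapse = " "), " ]"), con)
  }
  invisible(path)
}

#' Read a bedGraph occupancy track
#'
#' @param path path to a bedGraph file (`chrom start end value`, 0-based
#'   half-open).
#' @return data frame with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end   = BiocGenerics::end(gr),
             value = S4Vectors::mcols(gr)$score)
}
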