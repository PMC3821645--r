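#' Genomic intervals: the internal coordinate currency
#'
#' All coordinates inside the package are 0-based, half-open
#' (`[start, end)`) on the forward strand of the named chromosome.
#' External formats are converted at read time: GFF3 and UCSC browser-style
#' tables (1-based inclusive) lose 1 from their start on the way in and gain
#' it back on the way out; BED and chain files are already 0-based half-open.
#'
#' `genomic_intervals()` builds a validated data frame with columns
#' `chrom`, `start`, `end`, `strand` (plus any extra columns passed through
#' `...`), the shape every interval-consuming function in the package
#' expects.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive starts.
#' @param end integer vector, 0-based exclusive ends.
#' @param strand character vector of "+" or "-" (recycled).
#' @param ... further equal-length columns (e.g. `name`, `family`).
#' @return a `data.frame` with class `c("genomic_intervals", "data.frame")`.
#' @examples
#' genomic_intervals("chr1", 0L, 100L, "+", name = "hsa-mir-1")
#' @export
genomic_intervals <- function(chrom, start, end, strand = "+", ...) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom  = rep_len(as.character(chrom), n),
    start  = rep_len(as.integer(start), n),
    end    = rep_len(as.integer(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  validate_intervals(df)
  class(df) <- c("genomic_intervals", "data.frame")
  df
}

validate_intervals <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (nrow(df) == 0L) return(invisible(df))
  bad <- which(!(df$start >= 0L & df$start < df$end))
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(head(bad, 5), collapse = ", "),
         ": need 0 <= start < end", call. = FALSE)
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  invisible(df)
}

#' @rdname genomic_intervals
#' @param df an interval data frame.
#' @return `interval_width()`: integer widths (`end - start`).
#' @export
interval_width <- function(df) df$end - df$start

## 0-based half-open -> IRanges (1-based closed); boundary conversions for
## overlap queries only, never stored.
as_iranges0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

#' Reverse-complement a DNA string
#'
#' Vectorised over `x`; accepts A/C/G/T/N (and U, treated as T).
#' @param x character vector of sequences.
#' @return character vector.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(gsub("U", "T", toupper(x)))))
}

## Fetch the sequence of one interval from a named list/vector of chromosome
## sequences; minus-strand intervals come back reverse-complemented.
fetch_seq <- function(genome, chrom, start, end, strand = "+") {
  s <- genome[[chrom]]
  if (is.null(s)) stop("chromosome '", chrom, "' not in genome", call. = FALSE)
  if (end > nchar(s)) stop("interval beyond end of '", chrom, "'", call. = FALSE)
  sq <- substr(s, start + 1L, end)
  if (strand == "-") sq <- revcomp(sq) else sq
}

## genome as a named character vector keyed by record id
genome_as_vector <- function(records) {
  if (is.character(records)) return(records)
  stats::setNames(vapply(records, function(r) r$seq, character(1)),
                  vapply(records, function(r) r$id, character(1)))
}
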