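#' Transfer reference pre-miRNAs to the target genome
#'
#' Lifts every reference pre-miRNA through the chain index, keeps those
#' mapping to one contiguous target locus at `match_fraction >= min_match`
#' with a length inside `[min_len, max_len]`, and fetches the target
#' sequence (reverse-complemented for minus-strand candidates). Candidates
#' whose mapped interval falls outside the target chromosome are dropped
#' with a warning.
#'
#' @param refs interval data frame of reference pre-miRNAs with `name` and
#'   optionally `family` columns.
#' @param index a `chain_index` over reference-to-target chains.
#' @param target_genome named character vector or FASTA record list.
#' @param min_match minimum liftover match fraction (default 0.95).
#' @param min_len,max_len admissible candidate length in bases
#'   (defaults 40, 180).
#' @param allow_split accept the largest piece of split mappings.
#' @return data frame of candidates sorted by (chrom, start): `source_name`,
#'   `family`, `chrom`, `start`, `end`, `strand`, `match_fraction`,
#'   `sequence`, `assigned_name` (empty), `hairpin_verdict` ("untested").
#' @export
map_premirnas <- function(refs, index, target_genome, min_match = 0.95,
                          min_len = 40L, max_len = 180L, allow_split = FALSE) {
  stopifnot(min_len < max_len)
  genome <- genome_as_vector(target_genome)
  m <- map_intervals(refs, index, min_match, allow_split)
  keep <- !is.na(m$tgt_start)
  m <- m[keep, , drop = FALSE]
  len <- m$tgt_end - m$tgt_start
  m <- m[len >= min_len & len <= max_len, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(m))) {
    chrom <- m$tgt_chrom[i]
    if (is.null(genome[[chrom]]) || m$tgt_end[i] > nchar(genome[[chrom]])) {
      warning("candidate from '", m$name[i],
              "' maps beyond target chromosome bounds; dropped", call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      source_name = m$name[i],
      family = if (!is.null(m$family)) m$family[i] else "",
      chrom = chrom, start = m$tgt_start[i], end = m$tgt_end[i],
      strand = m$tgt_strand[i],
      match_fraction = m$match_fraction[i],
      sequence = fetch_seq(genome, chrom, m$tgt_start[i], m$tgt_end[i],
                           m$tgt_strand[i]),
      assigned_name = "", hairpin_verdict = "untested",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(source_name = character(0), family = character(0),
                      chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), match_fraction = numeric(0),
                      sequence = character(0), assigned_name = character(0),
                      hairpin_verdict = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse overlapping candidates of the same miRNA family
#'
#' When different members of one family map to overlapping target loci,
#' only one candidate represents the family at that locus: candidates of
#' the same family on the same chromosome and strand whose intervals
#' overlap by at least one base are clustered by single linkage, and each
#' cluster keeps its highest-`match_fraction` member (ties to the
#' lexicographically smallest `source_name`). Candidates with an empty
#' family label are never collapsed; different families are never merged.
#'
#' @param cands candidate data frame from [map_premirnas()].
#' @return the collapsed candidate data frame, original order preserved.
#' @export
collapse_family_overlaps <- function(cands) {
  if (nrow(cands) == 0L) return(cands)
  keep <- rep(TRUE, nrow(cands))
  fams <- setdiff(unique(cands$family), "")
  for (fam in fams) {
    idx <- which(cands$family == fam)
    for (key in unique(paste(cands$chrom[idx], cands$strand[idx]))) {
      sub <- idx[paste(cands$chrom[idx], cands$strand[idx]) == key]
      if (length(sub) < 2L) next
      sub <- sub[order(cands$start[sub])]
      ## single-linkage sweep: intervals chain while they touch the running max
      cluster <- list(sub[1]); max_end <- cands$end[sub[1]]
      clusters <- list()
      for (k in sub[-1]) {
        if (cands$start[k] < max_end) cluster[[length(cluster) + 1L]] <- k
        else { clusters[[length(clusters) + 1L]] <- unlist(cluster)
               cluster <- list(k) }
        max_end <- max(max_end, cands$end[k])
      }
      clusters[[length(clusters) + 1L]] <- unlist(cluster)
      for (cl in clusters) {
        if (length(cl) < 2L) next
        ord <- order(-cands$match_fraction[cl], cands$source_name[cl])
        keep[cl[ord[-1]]] <- FALSE
      }
    }
  }
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Name candidates in miRBase style
#'
#' Each candidate is christened `species_prefix + "-" + stem`, the stem
#' being the source name with its own species prefix removed
#' (`hsa-mir-2115` with prefix `ptr` becomes `ptr-mir-2115`). Distinct loci
#' that would collide on the same name get numeric suffixes `-1`, `-2`, ...
#' in coordinate order. A candidate overlapping a known target-species
#' pre-miRNA (same chromosome and strand, >= 1 base) adopts the known name
#' instead. The suffix rule is this package's convention for paralogous
#' loci, not a full reconstruction of community naming.
#'
#' @param cands candidate data frame.
#' @param species_prefix 3-letter species code (e.g. `cja`, `ptr`).
#' @param known optional interval data frame of known target-species
#'   pre-miRNAs with `name`.
#' @return `cands` with `assigned_name` filled.
#' @export
assign_candidate_names <- function(cands, species_prefix, known = NULL) {
  if (!grepl("^[a-z]{3}$", species_prefix))
    stop("species_prefix must be a 3-letter lower-case code", call. = FALSE)
  if (nrow(cands) == 0L) return(cands)
  stem <- sub("^[a-zA-Z]{3,4}-", "", cands$source_name)
  nm <- paste0(species_prefix, "-", stem)
  adopted <- rep(FALSE, nrow(cands))
  if (!is.null(known) && nrow(known) > 0L) {
    for (i in seq_len(nrow(cands))) {
      hit <- known$chrom == cands$chrom[i] & known$strand == cands$strand[i] &
        known$start < cands$end[i] & known$end > cands$start[i]
      if (any(hit)) { nm[i] <- known$name[which(hit)[1]]; adopted[i] <- TRUE }
    }
  }
  ## disambiguate collisions among the newly-minted names only
  for (dup in unique(nm[!adopted][duplicated(nm[!adopted])])) {
    loci <- which(nm == dup & !adopted)
    loci <- loci[order(cands$chrom[loci], cands$start[loci])]
    nm[loci] <- paste0(dup, "-", seq_along(loci))
  }
  cands$assigned_name <- nm
  cands
}

#' Read a two-column miRNA-to-family table
#' @param path TSV with columns `name`, `family` (no header).
#' @return named character vector: name -> family.
#' @export
read_family_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("name", "family"),
                          stringsAsFactors = FALSE)
  stats::setNames(df$family, df$name)
}
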