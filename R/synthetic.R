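#' Simulate a reference/target genome pair with a ground-truth chain
#'
#' Builds a random reference genome, derives a target genome from it by
#' seeded substitutions (`snp_rate`), short insertions/deletions
#' (`indel_rate`, lengths 1-8) and `n_inversions` segmental inversions, and
#' records the true alignment as UCSC-style chains (one chain per colinear
#' segment; inverted segments get minus-strand chains with chain-convention
#' query coordinates). The emitted chains always satisfy the chain
#' arithmetic checked by [parse_chain_file()], so the manifest is an exact
#' oracle for the liftover engine.
#'
#' @param n_chroms number of chromosomes (default 2).
#' @param chrom_len length of each chromosome in bases (>= 10000).
#' @param n_inversions total inverted segments across the genome.
#' @param indel_rate per-base probability of starting an indel (<= 0.1).
#' @param snp_rate per-base substitution probability (<= 0.1).
#' @param seed integer seed; identical inputs give byte-identical output.
#' @return a `simulation_manifest` list: `seed`, `params`, `ref_genome`,
#'   `tgt_genome` (named character vectors), `chains`,
#'   `planted_orthologs` (empty until [plant_features()]),
#'   `planted_motifs`, `gene_models`, `pfms`.
#' @export
simulate_synteny_pair <- function(n_chroms = 2L, chrom_len = 50000L,
                                  n_inversions = 1L, indel_rate = 0.002,
                                  snp_rate = 0.01, seed = 1L) {
  if (chrom_len < 10000L) stop("chrom_len must be >= 10 kb", call. = FALSE)
  if (indel_rate < 0 || indel_rate > 0.1 || snp_rate < 0 || snp_rate > 0.1)
    stop("rates must lie in [0, 0.1]", call. = FALSE)
  with_seed(seed, {
    ref <- list(); tgt <- list(); chains <- list()
    chain_id <- 0L
    ## spread the inversions over chromosomes
    inv_chrom <- if (n_inversions > 0)
      sort(sample.int(n_chroms, n_inversions, replace = TRUE)) else integer(0)
    for (c in seq_len(n_chroms)) {
      chrom <- paste0("chr", c)
      rseq <- paste(sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE),
                    collapse = "")
      ## non-overlapping inverted segments inside [1000, chrom_len - 1000)
      n_inv_here <- sum(inv_chrom == c)
      inv <- matrix(integer(0), ncol = 2)
      tries <- 0L
      while (nrow(inv) < n_inv_here && tries < 200L) {
        tries <- tries + 1L
        len <- sample(2000:4000, 1L)
        s <- sample.int(chrom_len - 2000L - len, 1L) + 1000L
        if (nrow(inv) == 0L || all(s + len <= inv[, 1] - 500L | s >= inv[, 2] + 500L))
          inv <- rbind(inv, c(s, s + len))
      }
      inv <- inv[order(inv[, 1]), , drop = FALSE]
      ## colinear segments: forward runs alternating with inversions
      bounds <- rbind(c(0L, if (nrow(inv)) inv[1, 1] else chrom_len))
      segs <- list()
      pos <- 0L
      for (k in seq_len(nrow(inv))) {
        if (inv[k, 1] > pos) segs[[length(segs) + 1L]] <- c(pos, inv[k, 1], 0L)
        segs[[length(segs) + 1L]] <- c(inv[k, 1], inv[k, 2], 1L)
        pos <- inv[k, 2]
      }
      if (pos < chrom_len) segs[[length(segs) + 1L]] <- c(pos, chrom_len, 0L)
      ## derive each target piece + its alignment blocks
      pieces <- character(length(segs))
      blocks_l <- vector("list", length(segs))
      for (k in seq_along(segs)) {
        L <- segs[[k]][2] - segs[[k]][1]
        al <- segment_alignment(L, indel_rate)
        piece <- mutate_copy(substr(rseq, segs[[k]][1] + 1L, segs[[k]][2]),
                             al, snp_rate)
        if (segs[[k]][3] == 1L) piece <- revcomp(piece)
        pieces[k] <- piece
        blocks_l[[k]] <- al
      }
      tseq <- paste(pieces, collapse = "")
      tlen <- nchar(tseq)
      offs <- cumsum(c(0L, nchar(pieces)))
      for (k in seq_along(segs)) {
        chain_id <- chain_id + 1L
        b <- blocks_l[[k]]
        ts <- offs[k]; te <- offs[k + 1L]
        inv_seg <- segs[[k]][3] == 1L
        chains[[chain_id]] <- structure(list(
          chain_id = chain_id, score = sum(b[, "size"]),
          ref_chrom = chrom, ref_size = chrom_len,
          ref_start = segs[[k]][1], ref_end = segs[[k]][2],
          tgt_chrom = chrom, tgt_size = tlen,
          tgt_strand = if (inv_seg) "-" else "+",
          tgt_start = if (inv_seg) tlen - te else ts,
          tgt_end   = if (inv_seg) tlen - ts else te,
          blocks = b), class = "chain_alignment")
      }
      ref[[chrom]] <- rseq
      tgt[[chrom]] <- tseq
    }
    structure(list(
      seed = seed,
      params = list(n_chroms = n_chroms, chrom_len = chrom_len,
                    n_inversions = n_inversions, indel_rate = indel_rate,
                    snp_rate = snp_rate),
      ref_genome = unlist(ref), tgt_genome = unlist(tgt), chains = chains,
      planted_orthologs = empty_ortholog_truth(),
      planted_motifs = data.frame(tf_name = character(0), chrom = character(0),
                                  offset = integer(0), strand = character(0)),
      gene_models = list(), pfms = list()),
      class = "simulation_manifest")
  })
}

empty_ortholog_truth <- function() {
  data.frame(name = character(0), family = character(0),
             ref_chrom = character(0), ref_start = integer(0), ref_end = integer(0),
             tgt_chrom = character(0), tgt_start = integer(0), tgt_end = integer(0),
             tgt_strand = character(0), sequence = character(0))
}

## Random block ladder for a colinear segment of reference length L:
## indel events (dt = reference-only gap, dq = target-only gap) spaced
## >= 12 bases apart so every aligned block is non-empty.
segment_alignment <- function(L, indel_rate) {
  n_ev <- stats::rbinom(1L, L, indel_rate)
  pos <- integer(0)
  if (n_ev > 0L && L > 40L) {
    cand <- sort(sample(seq(15L, L - 15L), min(n_ev, (L - 30L) %/% 14L)))
    keep <- c(TRUE, diff(cand) >= 14L)
    pos <- cand[keep]
  }
  if (length(pos) == 0L) {
    b <- matrix(c(L, 0, 0), ncol = 3)
    colnames(b) <- c("size", "dt", "dq")
    return(b)
  }
  type <- sample(c("dt", "dq"), length(pos), replace = TRUE)
  glen <- sample(1:8, length(pos), replace = TRUE)
  rows <- list(); r <- 0L
  for (k in seq_along(pos)) {
    rows[[k]] <- c(size = pos[k] - r, dt = if (type[k] == "dt") glen[k] else 0L,
                   dq = if (type[k] == "dq") glen[k] else 0L)
    r <- pos[k] + if (type[k] == "dt") glen[k] else 0L
  }
  rows[[length(rows) + 1L]] <- c(size = L - r, dt = 0L, dq = 0L)
  b <- do.call(rbind, rows)
  colnames(b) <- c("size", "dt", "dq")
  b
}

## Copy a reference segment through a block ladder: aligned bases with
## substitutions at snp_rate, dt gaps skipped, dq gaps filled randomly.
mutate_copy <- function(refseg, blocks, snp_rate) {
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  r <- 0L
  for (k in seq_len(nrow(blocks))) {
    chunk <- strsplit(substr(refseg, r + 1L, r + blocks[k, "size"]), "")[[1]]
    if (snp_rate > 0) {
      mut <- which(stats::runif(length(chunk)) < snp_rate)
      for (m in mut) chunk[m] <- sample(setdiff(bases, chunk[m]), 1L)
    }
    out <- c(out, chunk)
    if (blocks[k, "dq"] > 0)
      out <- c(out, sample(bases, blocks[k, "dq"], replace = TRUE))
    r <- r + blocks[k, "size"] + blocks[k, "dt"]
  }
  paste(out, collapse = "")
}

#' Plant ground-truthed hairpins, gene models and motifs into a manifest
#'
#' Hairpins are perfect inverted repeats (stem 20-35 bp, loop 4-10 nt)
#' written over matched positions of both genomes: each one sits wholly
#' inside one aligned chain block, and the identical sequence is written on
#' the reference and (reverse-complemented through minus-strand chains) on
#' the target, so the manifest coordinates are exact oracles for the whole
#' pipeline. A configurable fraction of hairpins gets a host gene built
#' around its target locus (two flanking exons; the hairpin falls in
#' intron 1); the rest stay intergenic. Motifs are the consensus strings of
#' the manifest's PFMs written at recorded target offsets.
#'
#' @param manifest a [simulate_synteny_pair()] result.
#' @param n_hairpins number of hairpins to plant (default 20).
#' @param n_motifs number of motif instances to plant (default 5).
#' @param seed integer seed.
#' @param intronic_fraction fraction of hairpins given a host gene
#'   (default 0.5).
#' @param pfms PFMs whose consensus is planted (default
#'   [demo_pfms()]`(5)`).
#' @return the updated manifest with `planted_orthologs`,
#'   `planted_motifs`, `gene_models`, `pfms` filled.
#' @export
plant_features <- function(manifest, n_hairpins = 20L, n_motifs = 5L,
                           seed = 1L, intronic_fraction = 0.5,
                           pfms = demo_pfms(5L)) {
  m <- manifest
  with_seed(seed, {
    used_ref <- list(); used_tgt <- list()   # per-chrom occupied windows
    free <- function(used, chrom, s, e, pad = 1500L) {
      u <- used[[chrom]]
      is.null(u) || all(e + pad <= u[, 1] | s >= u[, 2] + pad)
    }
    occupy <- function(used, chrom, s, e) {
      used[[chrom]] <- rbind(used[[chrom]], c(s, e)); used
    }
    ## candidate (chain, block) slots large enough for any hairpin
    slots <- list()
    for (ch in m$chains) {
      b <- ch$blocks
      r <- ch$ref_start; q <- ch$tgt_start
      for (k in seq_len(nrow(b))) {
        if (b[k, "size"] >= 120L)
          slots[[length(slots) + 1L]] <- list(ch = ch, r = r, q = q,
                                              size = b[k, "size"])
        r <- r + b[k, "size"] + b[k, "dt"]
        q <- q + b[k, "size"] + b[k, "dq"]
      }
    }
    if (length(slots) == 0L) stop("no aligned block large enough", call. = FALSE)
    truth <- empty_ortholog_truth()
    genes <- list()
    n_intronic <- round(intronic_fraction * n_hairpins)
    for (h in seq_len(n_hairpins)) {
      stem <- sample(20:35, 1L); loop <- sample(4:10, 1L)
      S <- paste(sample(c("A", "C", "G", "T"), stem, replace = TRUE), collapse = "")
      hp <- paste0(S, paste(sample(c("A", "C", "G", "T"), loop, replace = TRUE),
                            collapse = ""), revcomp(S))
      len <- nchar(hp)
      placed <- FALSE
      for (try in seq_len(400L)) {
        sl <- slots[[sample.int(length(slots), 1L)]]
        off <- sample.int(sl$size - len - 10L, 1L) + 5L
        rs <- sl$r + off; re <- rs + len
        qs <- sl$q + off; qe <- qs + len          # chain-convention coords
        ch <- sl$ch
        if (ch$tgt_strand == "-") { ts <- ch$tgt_size - qe; te <- ch$tgt_size - qs }
        else { ts <- qs; te <- qe }
        if (!free(used_ref, ch$ref_chrom, rs, re) ||
            !free(used_tgt, ch$tgt_chrom, ts, te)) next
        tgt_seq <- if (ch$tgt_strand == "-") revcomp(hp) else hp
        substr(m$ref_genome[[ch$ref_chrom]], rs + 1L, re) <- hp
        substr(m$tgt_genome[[ch$tgt_chrom]], ts + 1L, te) <- tgt_seq
        used_ref <- occupy(used_ref, ch$ref_chrom, rs, re)
        used_tgt <- occupy(used_tgt, ch$tgt_chrom, ts, te)
        nm <- sprintf("hsa-mir-%d", 100L + h)
        truth <- rbind(truth, data.frame(
          name = nm, family = sprintf("mir-%d", 100L + h),
          ref_chrom = ch$ref_chrom, ref_start = rs, ref_end = re,
          tgt_chrom = ch$tgt_chrom, tgt_start = ts, tgt_end = te,
          tgt_strand = ch$tgt_strand, sequence = hp))
        if (h <= n_intronic) {
          tlen <- nchar(m$tgt_genome[[ch$tgt_chrom]])
          gs <- max(0L, ts - 600L); ge <- min(tlen, te + 600L)
          genes[[length(genes) + 1L]] <- new_gene_model(
            gene_id = sprintf("g%03d", h), symbol = sprintf("HOST%d", h),
            chrom = ch$tgt_chrom, start = gs, end = ge, strand = "+",
            exons = data.frame(start = c(gs, ge - 50L), end = c(gs + 50L, ge)))
        }
        placed <- TRUE
        break
      }
      if (!placed) stop("insufficient space to plant hairpin ", h, call. = FALSE)
    }
    ## motifs: consensus strings at free target offsets
    motifs <- data.frame(tf_name = character(0), chrom = character(0),
                         offset = integer(0), strand = character(0))
    for (j in seq_len(n_motifs)) {
      p <- pfms[[(j - 1L) %% length(pfms) + 1L]]
      cons <- pfm_consensus(p)
      w <- nchar(cons)
      for (try in seq_len(400L)) {
        chrom <- sample(names(m$tgt_genome), 1L)
        ts <- sample.int(nchar(m$tgt_genome[[chrom]]) - w - 200L, 1L) + 100L
        if (!free(used_tgt, chrom, ts, ts + w, pad = 200L)) next
        substr(m$tgt_genome[[chrom]], ts + 1L, ts + w) <- cons
        used_tgt <- occupy(used_tgt, chrom, ts, ts + w)
        motifs <- rbind(motifs, data.frame(tf_name = p$tf_name, chrom = chrom,
                                           offset = ts, strand = "+"))
        break
      }
    }
    m$planted_orthologs <- truth
    m$planted_motifs <- motifs
    m$gene_models <- genes
    m$pfms <- pfms
    m
  })
}

#' Consensus string of a PFM (column-wise argmax, ties to A<C<G<T)
#' @param pfm a `pfm` object.
#' @return character string of length `ncol(counts)`.
#' @export
pfm_consensus <- function(pfm) {
  paste(rownames(pfm$counts)[apply(pfm$counts, 2, which.max)], collapse = "")
}

#' Small bundled demonstration PFMs
#'
#' Deterministic toy matrices with a strong consensus (count 10) over a
#' weak alternative (count 1 each), labelled `synthetic` - they stand in
#' for downloaded vertebrate matrices in examples and fixtures.
#'
#' @param n how many matrices (up to 5).
#' @return list of `pfm` objects.
#' @export
demo_pfms <- function(n = 5L) {
  consensi <- c(TFA = "TATAAAGC", TFB = "GGGCGGAACT", TFC = "CACGTGTT",
                TFD = "TGACTCATG", TFE = "GATAAGGA")[seq_len(min(n, 5L))]
  lapply(seq_along(consensi), function(i) {
    cons <- strsplit(consensi[[i]], "")[[1]]
    counts <- matrix(1, nrow = 4, ncol = length(cons),
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    counts[cbind(match(cons, c("A", "C", "G", "T")), seq_along(cons))] <- 10
    structure(list(tf_name = names(consensi)[i],
                   matrix_id = sprintf("SYN%04d.1", i), counts = counts),
              class = "pfm")
  })
}

#' Write a simulation manifest to disk
#'
#' Emits `ref.fa`, `tgt.fa`, `truth.chain`, `genes.gff3`,
#' `ref_mirnas.bed` / `tgt_mirnas.bed` (planted ortholog truth),
#' `families.tsv`, `pfms.jaspar`, `motifs.tsv` and `manifest.json`.
#'
#' @param manifest a `simulation_manifest`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(Map(function(i, s) list(id = i, seq = s),
                  names(manifest$ref_genome), manifest$ref_genome), p("ref.fa"))
  write_fasta(Map(function(i, s) list(id = i, seq = s),
                  names(manifest$tgt_genome), manifest$tgt_genome), p("tgt.fa"))
  write_chain_file(manifest$chains, p("truth.chain"))
  if (length(manifest$gene_models))
    write_gene_models_gff3(manifest$gene_models, p("genes.gff3"))
  tr <- manifest$planted_orthologs
  if (nrow(tr)) {
    write_bed(genomic_intervals(tr$ref_chrom, tr$ref_start, tr$ref_end, "+",
                                name = tr$name), p("ref_mirnas.bed"))
    write_bed(genomic_intervals(tr$tgt_chrom, tr$tgt_start, tr$tgt_end,
                                tr$tgt_strand, name = tr$name), p("tgt_mirnas.bed"))
    utils::write.table(data.frame(tr$name, tr$family), p("families.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  if (length(manifest$pfms)) write_jaspar_pfm(manifest$pfms, p("pfms.jaspar"))
  if (nrow(manifest$planted_motifs))
    utils::write.table(manifest$planted_motifs, p("motifs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(seed = manifest$seed, params = manifest$params,
                            planted_orthologs = manifest$planted_orthologs,
                            planted_motifs = manifest$planted_motifs),
                       p("manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
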