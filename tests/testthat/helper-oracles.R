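# Independent oracles and fixture builders shared across test files.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# ---- liftover: naive per-base chain walk ------------------------------------

# Carry every base of [s, e) through one chain individually; returns the set
# of forward-strand target positions of the aligned bases.
perbase_walk <- function(ch, s, e) {
  pos <- integer(0)
  b <- ch$blocks
  r <- ch$ref_start; q <- ch$tgt_start
  for (k in seq_len(nrow(b))) {
    lo <- max(s, r); hi <- min(e, r + b[k, "size"])
    if (lo < hi) {
      for (rp in lo:(hi - 1L)) {
        qp <- q + (rp - r)
        pos <- c(pos, if (ch$tgt_strand == "-") ch$tgt_size - 1L - qp else qp)
      }
    }
    r <- r + b[k, "size"] + b[k, "dt"]
    q <- q + b[k, "size"] + b[k, "dq"]
  }
  sort(pos)
}

# ---- folding: exhaustive enumeration of nested structures -------------------

pair_weight <- function(a, b) {
  key <- paste0(a, b)
  if (key %in% c("GC", "CG")) return(3)
  if (key %in% c("AT", "TA")) return(2)
  if (key %in% c("GT", "TG")) return(1)
  0
}

# All nested pair sets of seq under the loop constraint, as lists of c(i, j)
# (0-based); memoised per (i, j) span within one call.
enumerate_fold_score <- function(seq, min_loop = 3L) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  memo <- new.env(parent = emptyenv())
  structs <- function(i, j) {            # 1-based inclusive span
    if (j - i < min_loop + 1L) return(list(list()))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    res <- structs(i, j - 1L)            # j unpaired
    for (k in i:(j - min_loop - 1L)) {
      w <- pair_weight(s[k], s[j])
      if (w == 0) next
      left <- if (k > i) structs(i, k - 1L) else list(list())
      inner <- structs(k + 1L, j - 1L)
      for (L in left) for (I in inner)
        res[[length(res) + 1L]] <- c(L, I, list(c(k - 1L, j - 1L)))
    }
    memo[[key]] <- res
    res
  }
  all_s <- structs(1L, n)
  score_of <- function(ps) if (!length(ps)) 0 else
    sum(vapply(ps, function(p) pair_weight(s[p[1] + 1L], s[p[2] + 1L]), numeric(1)))
  max(vapply(all_s, score_of, numeric(1)))
}

# ---- sequence composition ---------------------------------------------------

dinuc_counts <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  if (length(s) < 2L) return(table(character(0)))
  table(paste0(s[-length(s)], s[-1]))
}

# ---- motif scanning: brute-force window scorer ------------------------------

brute_scan <- function(seq, pwm, rel_threshold) {
  w <- ncol(pwm)
  smin <- sum(apply(pwm, 2, min)); smax <- sum(apply(pwm, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- data.frame(position = integer(0), strand = character(0),
                     log_odds = numeric(0))
  bases <- strsplit(seq, "")[[1]]
  for (p in seq_len(nchar(seq) - w + 1L)) {
    win <- bases[p:(p + w - 1L)]
    fw <- sum(vapply(seq_len(w), function(j) pwm[win[j], j], numeric(1)))
    rcwin <- rev(unname(comp[win]))
    rv <- sum(vapply(seq_len(w), function(j) pwm[rcwin[j], j], numeric(1)))
    if ((fw - smin) / (smax - smin) >= rel_threshold)
      hits <- rbind(hits, data.frame(position = p - 1L, strand = "+", log_odds = fw))
    if ((rv - smin) / (smax - smin) >= rel_threshold)
      hits <- rbind(hits, data.frame(position = p - 1L, strand = "-", log_odds = rv))
  }
  hits
}

# ---- single-linkage clustering oracle for family collapsing -----------------

brute_collapse <- function(cands) {
  keep <- rep(TRUE, nrow(cands))
  for (fam in setdiff(unique(cands$family), "")) {
    for (key in unique(paste(cands$chrom, cands$strand))) {
      idx <- which(cands$family == fam & paste(cands$chrom, cands$strand) == key)
      if (length(idx) < 2L) next
      # grow clusters by repeated merging (transitive closure of overlap)
      adj <- outer(idx, idx, function(a, b)
        cands$start[a] < cands$end[b] & cands$start[b] < cands$end[a])
      comp <- seq_along(idx)
      repeat {
        changed <- FALSE
        for (a in seq_along(idx)) for (b in seq_along(idx))
          if (adj[a, b] && comp[b] != comp[a]) {
            comp[comp == comp[b]] <- comp[a]; changed <- TRUE
          }
        if (!changed) break
      }
      for (cl in unique(comp)) {
        mem <- idx[comp == cl]
        if (length(mem) < 2L) next
        rep_ <- mem[order(-cands$match_fraction[mem], cands$source_name[mem])][1]
        keep[setdiff(mem, rep_)] <- FALSE
      }
    }
  }
  cands[keep, , drop = FALSE]
}

# ---- printed host-gene/miRNA coordinate fixture -----------------------------

# 12 validated intronic miRNAs and their host genes (browser-style 1-based
# inclusive coordinates, converted to the internal convention on build).
# The PTOV1 row's miRNA ends one base past its host gene end as printed;
# `ptov1_extend` widens that gene by one base so containment can hold under
# the documented coordinate-convention caveat.
host_gene_table <- function() {
  read.table(header = TRUE, stringsAsFactors = FALSE, text = "
g_chrom g_start g_end symbol intron g_strand m_chrom m_start m_end mirna m_strand
chr1 196871470 196873147 PHC2 11 + chr1 196873044 196873102 ppy-mir-3605 +
chr7 130301326 130318076 EXOC4 3 + chr7 130303121 130303184 ppy-mir-4419a +
chr19 51404019 51404127 PTOV1 2 + chr19 51404069 51404128 ppy-mir-4706 +
chr20 13523168 13526970 POLR3F 2 + chr20 13524745 13524802 ppy-mir-3192 +
chr17_random 2435896 2459049 SKA2 1 + chr17_random 2439995 2440051 ppy-mir-301a +
chr3 49052547 49062118 SPINK8 2 - chr3 49059002 49059061 ptr-mir-2115 -
chr4 176472868 176516173 GALNT7 2 + chr4 176492588 176492646 ptr-mir-548t +
chr11 65715927 65719260 NDUFS8 6 + chr11 65716414 65716476 ptr-mir-4691 +
chr13 102152614 102687690 FGF14 4 - chr13 102247593 102247653 ptr-mir-2681 -
chr15 63169799 63174675 DENND4A 21 - chr15 63171059 63171120 ptr-mir-4511 -
chr21 26267629 26354246 DSCAM 22 - chr21 26290766 26290830 ptr-mir-4760 -
chr22 44543820 44616196 ATXN10 9 + chr22 44567304 44567367 ptr-mir-4762 +
")
}

# Build a gene model whose intron `k` (transcription order) contains the
# miRNA: k tiny exons stacked on the transcription-start side of the miRNA
# and one closing exon on the far side.
make_host_gene <- function(chrom, g_start, g_end, symbol, strand, k,
                           m_start, m_end) {
  if (strand == "+") {
    starts <- g_start + (seq_len(k) - 1L) * 2L
    exons <- data.frame(start = c(starts, g_end - 1L),
                        end = c(starts + 1L, g_end))
  } else {
    ends <- g_end - (seq_len(k) - 1L) * 2L
    exons <- data.frame(start = c(g_start, rev(ends - 1L)),
                        end = c(g_start + 1L, rev(ends)))
  }
  synmir:::new_gene_model(gene_id = symbol, symbol = symbol, chrom = chrom,
                          start = g_start, end = g_end, strand = strand,
                          exons = exons)
}

host_gene_fixture <- function(ptov1_extend = TRUE) {
  tab <- host_gene_table()
  genes <- list(); mirnas <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    g_start <- r$g_start - 1L            # 1-based inclusive -> internal
    g_end <- r$g_end
    if (r$symbol == "PTOV1" && ptov1_extend) g_end <- max(g_end, r$m_end + 1L)
    genes[[i]] <- make_host_gene(r$g_chrom, g_start, g_end, r$symbol,
                                 r$g_strand, r$intron, r$m_start - 1L, r$m_end)
    mirnas[[i]] <- genomic_intervals(r$m_chrom, r$m_start - 1L, r$m_end,
                                     r$m_strand, name = r$mirna)
  }
  list(table = tab, genes = genes, mirnas = mirnas)
}

# ---- re-identification fixture ----------------------------------------------

# n_known documented records; exactly n_matched of them get a prediction at
# ratio >= 0.5 (identical interval); the rest get a sub-threshold or no
# prediction; n_extra predictions land far away (novel).
reid_fixture <- function(n_known, n_matched, n_extra) {
  starts <- seq(1000L, by = 1000L, length.out = n_known)
  known <- genomic_intervals("chrK", starts, starts + 80L, "+",
                             name = sprintf("known-%04d", seq_len(n_known)))
  matched <- sort(sample.int(n_known, n_matched))
  unmatched <- setdiff(seq_len(n_known), matched)
  # sub-threshold decoys for half of the unmatched records: 20/80 = 0.25
  decoy <- unmatched[seq_len(length(unmatched) %/% 2)]
  p_start <- c(starts[matched], starts[decoy] + 60L,
               seq(2000000L, by = 1000L, length.out = n_extra))
  predicted <- genomic_intervals("chrK", p_start, p_start + 80L, "+",
                                 name = sprintf("pred-%04d", seq_along(p_start)))
  list(known = known, predicted = predicted)
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}
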