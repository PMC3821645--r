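simple_gene <- function(gene_id, chrom, start, end, strand, exon_starts,
                        exon_ends, symbol = gene_id) {
  synmir:::new_gene_model(gene_id, symbol, chrom, start, end, strand,
                          data.frame(start = exon_starts, end = exon_ends))
}

test_that("genomic-context labels follow containment rules", {
  g <- simple_gene("g1", "chr1", 0L, 1000L, "+",
                   c(0L, 300L, 700L), c(100L, 400L, 1000L))
  expect_equal(classify_genomic_context(genomic_intervals("chr1", 150, 230),
                                        list(g))$label, "intronic")
  expect_equal(classify_genomic_context(genomic_intervals("chr1", 150, 230),
                                        list(g))$intron_index, 1L)
  expect_equal(classify_genomic_context(genomic_intervals("chr1", 450, 530),
                                        list(g))$intron_index, 2L)
  expect_equal(classify_genomic_context(genomic_intervals("chr1", 350, 380),
                                        list(g))$label, "exonic")
  expect_equal(classify_genomic_context(genomic_intervals("chr1", 5000, 5100),
                                        list(g))$label, "intergenic")
  expect_equal(classify_genomic_context(genomic_intervals("chr2", 150, 230),
                                        list(g))$label, "intergenic")
  # minus-strand gene: same gaps, transcription-order indices reversed
  gm <- simple_gene("g2", "chr1", 0L, 1000L, "-",
                    c(0L, 300L, 700L), c(100L, 400L, 1000L))
  expect_equal(classify_genomic_context(genomic_intervals("chr1", 150, 230),
                                        list(gm))$intron_index, 2L)
  # nested hosts: the shorter containing intron wins
  big <- simple_gene("a_big", "chr1", 0L, 10000L, "+",
                     c(0L, 9900L), c(50L, 10000L))
  small <- simple_gene("b_small", "chr1", 100L, 600L, "+",
                       c(100L, 500L), c(150L, 600L))
  ctx <- classify_genomic_context(genomic_intervals("chr1", 200, 280),
                                  list(big, small))
  expect_equal(ctx$host_gene, "b_small")
})

test_that("random placements agree with a brute-force interval check", {
  set.seed(59)
  genes <- lapply(1:5, function(i) {
    gs <- (i - 1L) * 3000L + 200L
    simple_gene(paste0("g", i), "chr1", gs, gs + 2000L,
                sample(c("+", "-"), 1),
                c(gs, gs + 500L, gs + 1500L),
                c(gs + 100L, gs + 700L, gs + 2000L))
  })
  for (rep in 1:100) {
    s <- sample.int(16000, 1); e <- s + sample(50:100, 1)
    got <- classify_genomic_context(genomic_intervals("chr1", s, e), genes)$label
    # oracle: per-base membership tests
    in_exon <- any(vapply(genes, function(g)
      any(g$exons$start < e & g$exons$end > s), logical(1)))
    in_intron <- any(vapply(genes, function(g)
      any(g$introns$start <= s & g$introns$end >= e), logical(1)))
    want <- if (in_intron) "intronic" else if (in_exon) "exonic" else "intergenic"
    expect_equal(got, want, info = paste(s, e))
  }
})

test_that("printed host-gene coordinates classify intronic with printed indices", {
  fx <- host_gene_fixture(ptov1_extend = TRUE)
  for (i in seq_len(nrow(fx$table))) {
    ctx <- classify_genomic_context(fx$mirnas[[i]], fx$genes)
    expect_equal(ctx$label, "intronic", info = fx$table$mirna[i])
    expect_equal(ctx$intron_index, fx$table$intron[i], info = fx$table$mirna[i])
    expect_equal(ctx$host_gene, fx$table$symbol[i], info = fx$table$mirna[i])
  }
  # without the one-base gene extension the PTOV1 precursor is NOT contained:
  # its printed end exceeds the printed host gene end
  fx2 <- host_gene_fixture(ptov1_extend = FALSE)
  i <- which(fx2$table$symbol == "PTOV1")
  expect_false(classify_genomic_context(fx2$mirnas[[i]], fx2$genes)$label ==
                 "intronic")
})

test_that("regulatory regions follow the intergenic upstream-2000 rule", {
  set.seed(61)
  genome <- c(chr1 = random_dna(8000))
  mir <- genomic_intervals("chr1", 5000, 5100, "+", name = "mir-a")
  ctx <- classify_genomic_context(mir, list())
  reg <- extract_regulatory_region(mir, ctx, genome)
  expect_equal(reg$rule_applied, "upstream_2000")
  expect_length(reg$segments, 1L)
  expect_equal(reg$segments[[1]]$start, 3000L)
  expect_equal(reg$segments[[1]]$end, 5000L)
  expect_equal(nchar(reg$segments[[1]]$seq), 2000L)
  expect_equal(reg$segments[[1]]$seq, substr(genome[["chr1"]], 3001, 5000))

  # minus strand: downstream in genomic coordinates, reverse-complemented
  mir_m <- genomic_intervals("chr1", 5000, 5100, "-", name = "mir-b")
  reg_m <- extract_regulatory_region(mir_m, ctx, genome)
  expect_equal(reg_m$segments[[1]]$start, 5100L)
  expect_equal(reg_m$segments[[1]]$end, 7100L)
  expect_equal(reg_m$segments[[1]]$seq,
               revcomp(substr(genome[["chr1"]], 5101, 7100)))

  # chromosome-edge truncation
  mir_e <- genomic_intervals("chr1", 900, 1000, "+", name = "mir-c")
  reg_e <- extract_regulatory_region(mir_e, ctx, genome)
  expect_equal(reg_e$segments[[1]]$start, 0L)
})

test_that("N runs split regions into clean segments that tile the span", {
  set.seed(67)
  g <- random_dna(8000)
  substr(g, 4001, 4003) <- "NNN"   # genomic [4000, 4003)
  genome <- c(chr1 = g)
  mir <- genomic_intervals("chr1", 5000, 5100, "+", name = "mir-a")
  ctx <- classify_genomic_context(mir, list())
  reg <- extract_regulatory_region(mir, ctx, genome)
  expect_length(reg$segments, 2L)
  expect_equal(reg$segments[[1]]$start, 3000L)
  expect_equal(reg$segments[[1]]$end, 4000L)
  expect_equal(reg$segments[[2]]$start, 4003L)
  expect_equal(reg$segments[[2]]$end, 5000L)
  expect_false(any(grepl("N", vapply(reg$segments, `[[`, character(1), "seq"))))

  # property: segments tile the region minus N runs exactly
  for (rep in 1:10) {
    g2 <- random_dna(4000)
    for (k in seq_len(sample(0:4, 1))) {
      p <- sample.int(3500, 1)
      substr(g2, p, p + sample.int(30, 1)) <- strrep("N", sample.int(30, 1))
    }
    genome2 <- c(chr1 = g2)
    mir2 <- genomic_intervals("chr1", 3000, 3100, "+", name = "m")
    reg2 <- extract_regulatory_region(mir2, classify_genomic_context(mir2, list()),
                                      genome2)
    span <- substr(g2, 1001, 3000)
    rebuilt <- rep("N", 2000)
    for (sg in reg2$segments) {
      expect_false(grepl("N", sg$seq))
      rebuilt[(sg$start - 1000 + 1):(sg$end - 1000)] <- strsplit(sg$seq, "")[[1]]
    }
    expect_equal(paste(rebuilt, collapse = ""), span)
  }
})

test_that("intronic regions span intron start to miRNA start on both strands", {
  set.seed(71)
  genome <- c(chr1 = random_dna(6000))
  gp <- simple_gene("gp", "chr1", 1000L, 4000L, "+",
                    c(1000L, 3500L), c(1200L, 4000L))
  mir <- genomic_intervals("chr1", 2000, 2090, "+", name = "mir-i")
  ctx <- classify_genomic_context(mir, list(gp))
  reg <- extract_regulatory_region(mir, ctx, genome)
  expect_equal(reg$rule_applied, "intron_start_to_mirna_start")
  expect_length(reg$segments, 1L)
  expect_equal(reg$segments[[1]]$start, 1200L)  # intron 5' end (+)
  expect_equal(reg$segments[[1]]$end, 2000L)    # miRNA 5' end

  gm <- simple_gene("gm", "chr1", 1000L, 4000L, "-",
                    c(1000L, 3500L), c(1200L, 4000L))
  ctx_m <- classify_genomic_context(mir, list(gm))
  reg_m <- extract_regulatory_region(mir, ctx_m, genome)
  expect_equal(reg_m$segments[[1]]$start, 2090L) # miRNA 5' end on minus
  expect_equal(reg_m$segments[[1]]$end, 3500L)   # intron 5' end on minus
  expect_equal(reg_m$segments[[1]]$seq,
               revcomp(substr(genome[["chr1"]], 2091, 3500)))

  # miRNA starting at the intron start yields an empty region
  mir0 <- genomic_intervals("chr1", 1200, 1290, "+", name = "mir-0")
  reg0 <- extract_regulatory_region(mir0, classify_genomic_context(mir0, list(gp)),
                                    genome)
  expect_length(reg0$segments, 0L)

  # no rule for exonic loci
  mir_ex <- genomic_intervals("chr1", 1100, 1150, "+", name = "mir-e")
  expect_error(extract_regulatory_region(mir_ex,
                                         classify_genomic_context(mir_ex, list(gp)),
                                         genome), "exonic")
})

test_that("PFM scanning finds planted consensus sites on both strands", {
  pfm <- demo_pfms(1)[[1]]            # consensus TATAAAGC
  cons <- pfm_consensus(pfm)
  set.seed(73)
  seq <- random_dna(200)
  substr(seq, 101, 100 + nchar(cons)) <- cons
  reg <- structure(list(origin_mirna = "m", rule_applied = "upstream_2000",
                        strand = "+",
                        segments = list(list(chrom = "chr1", start = 0L,
                                             end = 200L, seq = seq))),
                   class = "regulatory_region")
  h <- scan_pfm(reg, pfm, rel_threshold = 0.99)
  expect_true(any(h$position == 100L & h$strand == "+" &
                    abs(h$relative_score - 1.0) < 1e-12))

  seq2 <- random_dna(200)
  substr(seq2, 101, 100 + nchar(cons)) <- revcomp(cons)
  reg2 <- reg; reg2$segments[[1]]$seq <- seq2
  h2 <- scan_pfm(reg2, pfm, rel_threshold = 0.99)
  expect_true(any(h2$position == 100L & h2$strand == "-" &
                    abs(h2$relative_score - 1.0) < 1e-12))

  # segment shorter than the motif yields no hits, silently
  reg3 <- reg; reg3$segments[[1]]$seq <- "ACG"
  expect_equal(nrow(scan_pfm(reg3, pfm)), 0L)
})

test_that("hit lists equal brute-force window scoring and recompute exactly", {
  set.seed(79)
  pfms <- demo_pfms(3)
  for (rep in 1:6) {
    seq <- random_dna(300)
    reg <- structure(list(origin_mirna = "m", rule_applied = "upstream_2000",
                          strand = "+",
                          segments = list(list(chrom = "chr1", start = 0L,
                                               end = 300L, seq = seq))),
                     class = "regulatory_region")
    for (pfm in pfms) {
      thr <- runif(1, 0.5, 0.9)
      got <- scan_pfm(reg, pfm, rel_threshold = thr)
      pwm <- pfm_to_pwm(pfm)
      want <- brute_scan(seq, pwm, thr)
      got_o <- got[order(got$position, got$strand), ]
      want_o <- want[order(want$position, want$strand), ]
      expect_equal(got_o$position, want_o$position)
      expect_equal(got_o$strand, want_o$strand)
      expect_equal(got_o$log_odds, want_o$log_odds, tolerance = 1e-12)
      # bit-exactness: recompute each hit's score from the PWM
      for (r in seq_len(nrow(got))) {
        w <- ncol(pwm)
        win <- substr(seq, got$position[r] + 1L, got$position[r] + w)
        if (got$strand[r] == "-") win <- revcomp(win)
        sc <- sum(pwm[cbind(match(strsplit(win, "")[[1]],
                                  c("A", "C", "G", "T")), 1:w)])
        expect_lt(abs(sc - got$log_odds[r]), 1e-9)
      }
    }
  }
})

test_that("occupancy annotation and filtering use the hit window mean", {
  pfm <- demo_pfms(1)[[1]]
  cons <- pfm_consensus(pfm)
  seq <- paste0(strrep("A", 50), cons, strrep("A", 50))
  reg <- structure(list(origin_mirna = "m", rule_applied = "upstream_2000",
                        strand = "+",
                        segments = list(list(chrom = "chr1", start = 1000L,
                                             end = 1000L + nchar(seq),
                                             seq = seq))),
                   class = "regulatory_region")
  track <- data.frame(chrom = "chr1", start = c(1000L, 1050L),
                      end = c(1050L, 1200L), value = c(0.1, 0.9))
  h <- scan_pfm(reg, pfm, rel_threshold = 0.99, occupancy = track)
  site <- h[h$position == 50L & h$strand == "+", ]
  expect_equal(site$occupancy, 0.9)   # hit window [1050, 1058) wholly in 0.9
  h2 <- scan_pfm(reg, pfm, rel_threshold = 0.99, occupancy = track, o_max = 0.5)
  expect_false(any(h2$position == 50L & h2$strand == "+"))
  expect_equal(occupancy_mean(track, "chr1", 1040L, 1060L),
               (10 * 0.1 + 10 * 0.9) / 20)
  expect_true(is.na(occupancy_mean(track, "chr2", 0L, 10L)))
})

test_that("shared-TF summary counts memberships like the brute force", {
  sets <- list(m1 = c("ETS1", "FOXL1", "HLTF"),
               m2 = c("ETS1", "FOXL1", "HLTF"),
               m3 = c("ETS1", "FOXL1", "HLTF"),
               m4 = c("ETS1", "FOXL1", "HLTF"),
               m5 = c("ETS1", "FOXL1", "HLTF", "GATA2"),
               m6 = c("ETS1", "FOXL1", "HLTF"),
               m7 = c("GATA2"))
  # three TFs present in six of seven regulatory regions
  out <- shared_tf_summary(sets, min_fraction = 6 / 7)
  expect_equal(out$tf_name, c("ETS1", "FOXL1", "HLTF"))
  expect_equal(out$n_mirnas, rep(6L, 3))
  expect_false("GATA2" %in% out$tf_name)

  full <- shared_tf_summary(list(a = "X", b = "X"), min_fraction = 1)
  expect_equal(full$members, "a,b")

  set.seed(83)
  for (rep in 1:10) {
    ns <- sample(3:8, 1)
    sets <- stats::setNames(lapply(seq_len(ns), function(i)
      sample(LETTERS[1:6], sample(0:4, 1))), paste0("m", seq_len(ns)))
    frac <- runif(1, 0.2, 1)
    out <- shared_tf_summary(sets, frac)
    for (tf in LETTERS[1:6]) {
      cnt <- sum(vapply(sets, function(s) tf %in% s, logical(1)))
      expect_equal(tf %in% out$tf_name, cnt >= frac * ns && cnt > 0)
    }
  }
})
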