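make_chain <- function(id, score, ref_chrom, ref_size, ref_start,
                       tgt_chrom, tgt_size, tgt_strand, tgt_start, blocks) {
  b <- matrix(unlist(blocks), ncol = 3, byrow = TRUE,
              dimnames = list(NULL, c("size", "dt", "dq")))
  structure(list(chain_id = id, score = score,
                 ref_chrom = ref_chrom, ref_size = ref_size,
                 ref_start = ref_start,
                 ref_end = ref_start + sum(b[, "size"]) + sum(b[, "dt"]),
                 tgt_chrom = tgt_chrom, tgt_size = tgt_size,
                 tgt_strand = tgt_strand, tgt_start = tgt_start,
                 tgt_end = tgt_start + sum(b[, "size"]) + sum(b[, "dq"]),
                 blocks = b), class = "chain_alignment")
}

iv1 <- function(chrom, s, e, strand = "+")
  list(chrom = chrom, start = s, end = e, strand = strand)

test_that("the chain index returns exactly the overlapping chains", {
  c1 <- make_chain(1, 10, "chr1", 1e4, 0, "chr1", 1e4, "+", 0,
                   list(c(1000, 0, 0)))
  c2 <- make_chain(2, 20, "chr1", 1e4, 100, "chr1", 1e4, "+", 2000,
                   list(c(500, 0, 0)))
  idx <- build_chain_index(list(c1, c2))
  expect_equal(query_chains(idx, "chr1", 10, 20), 1L)
  expect_equal(sort(query_chains(idx, "chr1", 150, 160)), c(1L, 2L))
  expect_equal(query_chains(idx, "chr2", 10, 20), integer(0))
  expect_error(build_chain_index(list(c1, c1)), "duplicate")

  # random chain sets: index answers equal a linear scan
  set.seed(5)
  chains <- lapply(1:40, function(i) {
    s <- sample.int(9000, 1)
    make_chain(i, i, sample(c("chr1", "chr2"), 1), 1e4, s, "chr1", 1e4, "+",
               0, list(c(sample.int(800, 1), 0, 0)))
  })
  idx <- build_chain_index(chains)
  for (q in 1:50) {
    chrom <- sample(c("chr1", "chr2"), 1)
    s <- sample.int(9500, 1); e <- s + sample.int(400, 1)
    scan <- vapply(chains, function(ch)
      ch$ref_chrom == chrom && ch$ref_start < e && ch$ref_end > s, logical(1))
    expect_setequal(query_chains(idx, chrom, s, e),
                    vapply(chains[scan], `[[`, integer(1), "chain_id"))
  }
})

test_that("identity chains map intervals onto themselves", {
  ch <- make_chain(1, 100, "chr1", 1000, 0, "chr1", 1000, "+", 0,
                   list(c(1000, 0, 0)))
  idx <- build_chain_index(list(ch))
  r <- map_interval(iv1("chr1", 120, 200), idx)
  expect_equal(r$status, "mapped")
  expect_equal(r$match_fraction, 1.0)
  expect_equal(r$mappings$start, 120L)
  expect_equal(r$mappings$end, 200L)
})

test_that("reference gaps lose bases but close on the target", {
  # blocks: 50 aligned, dt = 10 (reference-only gap), then 40 aligned
  ch <- make_chain(1, 90, "chr1", 1000, 0, "chr2", 1000, "+", 0,
                   list(c(50, 10, 0), c(40, 0, 0)))
  idx <- build_chain_index(list(ch))
  r <- map_interval(iv1("chr1", 40, 70), idx, min_match = 0.5)
  # bases 40..49 and 60..69 align; 50..59 fall in the gap
  expect_equal(r$matched_bases, 20L)
  expect_equal(r$match_fraction, 20 / 30)
  expect_equal(r$status, "mapped")       # the target gap is closed
  expect_equal(r$mappings$start, 40L)
  expect_equal(r$mappings$end, 60L)

  r <- map_interval(iv1("chr1", 52, 58), idx)
  expect_equal(r$status, "deleted")      # interval wholly inside the dt gap
})

test_that("target-side insertions split mappings; strict min_match demotes", {
  ch <- make_chain(1, 90, "chr1", 1000, 0, "chr2", 1000, "+", 0,
                   list(c(50, 0, 10), c(40, 0, 0)))
  idx <- build_chain_index(list(ch))
  r <- map_interval(iv1("chr1", 40, 70), idx)
  expect_equal(r$match_fraction, 1.0)    # every base aligns
  expect_equal(r$status, "split")        # but across the dq gap
  expect_equal(nrow(r$mappings), 2L)
  expect_equal(r$mappings$start, c(40L, 60L))
  expect_equal(r$mappings$end, c(50L, 80L))

  ch2 <- make_chain(1, 90, "chr1", 1000, 0, "chr2", 1000, "+", 0,
                    list(c(50, 10, 0), c(40, 0, 0)))
  idx2 <- build_chain_index(list(ch2))
  expect_equal(map_interval(iv1("chr1", 40, 70), idx2, min_match = 0.95)$status,
               "partial")
  expect_equal(map_interval(iv1("chr1", 900, 950), idx2)$status, "unmapped")
})

test_that("raising min_match never converts unmapped to mapped", {
  set.seed(8)
  m <- simulate_synteny_pair(1, 20000, 1, 0.005, 0.01, seed = 8)
  idx <- build_chain_index(m$chains)
  for (q in 1:60) {
    s <- sample.int(19000, 1); e <- s + sample(40:160, 1)
    st_low <- map_interval(iv1("chr1", s, e), idx, min_match = 0.5)$status
    st_high <- map_interval(iv1("chr1", s, e), idx, min_match = 0.99)$status
    if (st_low != "mapped") expect_false(st_high == "mapped" && st_low != "split")
    if (st_low == "unmapped") expect_equal(st_high, "unmapped")
  }
})

test_that("block-ladder mapping equals the naive per-base walk", {
  set.seed(13)
  m <- simulate_synteny_pair(2, 30000, 2, 0.004, 0.01, seed = 13)
  idx <- build_chain_index(m$chains)
  for (q in 1:150) {
    chrom <- sample(names(m$ref_genome), 1)
    s <- sample.int(nchar(m$ref_genome[[chrom]]) - 200L, 1)
    e <- s + sample(40:180, 1)
    r <- map_interval(iv1(chrom, s, e), idx, min_match = 0.9)
    if (r$status %in% c("unmapped", "deleted")) {
      cands <- Filter(function(ch) ch$ref_chrom == chrom &&
                        ch$ref_start < e && ch$ref_end > s, m$chains)
      expect_true(all(vapply(cands, function(ch)
        length(perbase_walk(ch, s, e)) == 0L, logical(1))))
      next
    }
    ch <- m$chains[[r$chain_id]]
    pos <- perbase_walk(ch, s, e)
    expect_equal(r$matched_bases, length(pos))
    expect_equal(min(r$mappings$start), min(pos))
    expect_equal(max(r$mappings$end), max(pos) + 1L)
    contiguous <- (max(pos) - min(pos) + 1L) == length(pos)
    expect_equal(r$status == "mapped" || r$status == "partial" && nrow(r$mappings) == 1L,
                 contiguous)
  }
})

test_that("minus-strand chains round-trip sequence through reverse complement", {
  # identical sequences, one inverted segment: mapped target sequence must
  # reverse-complement back to the reference bases
  m <- simulate_synteny_pair(1, 20000, 2, 0, 0, seed = 21)
  idx <- build_chain_index(m$chains)
  inv_chains <- Filter(function(ch) ch$tgt_strand == "-", m$chains)
  expect_gte(length(inv_chains), 1L)
  for (ch in inv_chains) {
    s <- ch$ref_start + 50L; e <- s + 80L
    r <- map_interval(iv1("chr1", s, e), idx)
    expect_equal(r$status, "mapped")
    expect_equal(r$mappings$strand, "-")
    tgt <- synmir:::fetch_seq(m$tgt_genome, r$mappings$chrom,
                              r$mappings$start, r$mappings$end, "-")
    expect_equal(tgt, substr(m$ref_genome[["chr1"]], s + 1L, e))
  }
})

test_that("liftover agrees with rtracklayer on plus-strand chains", {
  m <- simulate_synteny_pair(1, 20000, 0, 0.004, 0.01, seed = 31)
  f <- withr::local_tempfile(fileext = ".chain")
  write_chain_file(m$chains, f)
  chain <- rtracklayer::import.chain(f)
  idx <- build_chain_index(m$chains)
  set.seed(31)
  for (q in 1:40) {
    s <- sample.int(19000, 1); e <- s + sample(50:120, 1)
    r <- map_interval(iv1("chr1", s, e), idx, min_match = 1e-9)
    gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s + 1L, e))
    lifted <- unlist(rtracklayer::liftOver(gr, chain))
    if (length(lifted) == 0L) {
      expect_true(r$status %in% c("unmapped", "deleted"))
    } else {
      expect_equal(min(r$mappings$start), min(BiocGenerics::start(lifted)) - 1L)
      expect_equal(max(r$mappings$end), max(BiocGenerics::end(lifted)))
    }
  }
})
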