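#' Fold a candidate hairpin by weighted base-pair maximisation
#'
#' Finds the nested (pseudoknot-free) secondary structure maximising the
#' pairing score `sum(w)` with weights `w(GC) = 3`, `w(AU) = 2`, `w(GU) = 1`
#' under the hairpin-loop constraint `j - i > min_loop` for every pair, by
#' dynamic programming with a deterministic traceback. This is a
#' pseudo-energy objective, not a thermodynamic free-energy model; a
#' thermodynamic folder can be substituted behind the same return contract.
#'
#' @param seq nucleotide string (A/C/G/T/U; U is normalised to T).
#' @param min_loop minimum unpaired loop span (default 3).
#' @return a `fold_result` list: `structure` (dot-bracket), `n_pairs`,
#'   `pair_score`, `pairs` (two-column 0-based matrix of partner indices).
#' @export
fold_hairpin <- function(seq, min_loop = 3L) {
  seq <- gsub("U", "T", toupper(seq))
  if (nchar(seq) < 2L * min_loop)
    stop("sequence shorter than 2*min_loop", call. = FALSE)
  r <- .nussinov_fold(seq, as.integer(min_loop), TRUE)
  pairs <- cbind(i = r$pair_i, j = r$pair_j)
  pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(list(structure = r$structure, n_pairs = nrow(pairs),
                 pair_score = r$score, pairs = pairs),
            class = "fold_result")
}

## Score-only fold (no traceback); the randomization test's inner loop.
pair_score_only <- function(seq, min_loop = 3L) {
  .nussinov_fold(gsub("U", "T", toupper(seq)), as.integer(min_loop), FALSE)$score
}

#' Hairpin descriptors from a fold
#'
#' `longest_stem` is the number of pairs in the longest perfectly stacked
#' helix (pairs (i, j), (i+1, j-1), ...). `n_loops` counts hairpin loops:
#' pairs enclosing no other pair. `terminal_loop` is the unpaired span
#' closed by the innermost pair of the longest stem (0 when unpaired).
#' `randomization_p` is left `NA`; [randomization_test()] fills it.
#'
#' @param seq the folded sequence.
#' @param fold the matching [fold_hairpin()] result.
#' @return a `hairpin_features` list: `length`, `gc_content`,
#'   `paired_fraction`, `normalized_pair_score`, `longest_stem`,
#'   `terminal_loop`, `n_loops`, `randomization_p`.
#' @export
compute_features <- function(seq, fold) {
  seq <- gsub("U", "T", toupper(seq))
  n <- nchar(seq)
  stopifnot(nchar(fold$structure) == n)
  bases <- strsplit(seq, "")[[1]]
  p <- fold$pairs
  longest <- 0L; term_loop <- 0L
  if (nrow(p) > 0L) {
    ## stacked runs: consecutive rows with i+1, j-1
    run <- 1L; best_run <- 1L; best_end <- 1L
    if (nrow(p) > 1L) {
      ord <- order(p[, 1])
      p <- p[ord, , drop = FALSE]
      for (k in 2:nrow(p)) {
        if (p[k, 1] == p[k - 1, 1] + 1L && p[k, 2] == p[k - 1, 2] - 1L) run <- run + 1L
        else run <- 1L
        if (run > best_run) { best_run <- run; best_end <- k }
      }
    }
    longest <- best_run
    inner <- p[best_end, ]
    term_loop <- as.integer(inner[2] - inner[1] - 1L)
  }
  ## hairpin loops: pairs with no pair strictly inside
  n_loops <- 0L
  if (nrow(p) > 0L) {
    for (k in seq_len(nrow(p))) {
      inside <- p[, 1] > p[k, 1] & p[, 2] < p[k, 2]
      if (!any(inside)) n_loops <- n_loops + 1L
    }
  }
  structure(list(
    length = n,
    gc_content = mean(bases %in% c("G", "C")),
    paired_fraction = 2 * fold$n_pairs / n,
    normalized_pair_score = fold$pair_score / n,
    longest_stem = longest,
    terminal_loop = term_loop,
    n_loops = n_loops,
    randomization_p = NA_real_), class = "hairpin_features")
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Eulerian (Altschul-Erickson style) shuffle: the output is a uniform-ish
#' random sequence with exactly the same mono- and dinucleotide counts as
#' the input. Uses R's RNG; seed externally for reproducibility.
#'
#' @param seq nucleotide string, length >= 4.
#' @return shuffled string.
#' @export
dinuc_shuffle <- function(seq) {
  s <- strsplit(toupper(seq), "")[[1]]
  n <- length(s)
  if (n < 4L) stop("sequence too short to shuffle", call. = FALSE)
  verts <- unique(s)
  last <- s[n]
  ## edge lists: for each vertex, the multiset of successors
  edges <- lapply(verts, function(v) s[which(s[-n] == v) + 1L])
  names(edges) <- verts
  if (length(verts) == 1L) return(seq)
  ## choose a last edge for every vertex except `last`, s.t. following the
  ## chosen last edges from any vertex reaches `last` (arborescence check)
  others <- setdiff(verts, last)
  repeat {
    last_edge <- vapply(others, function(v) {
      e <- edges[[v]]
      e[sample.int(length(e), 1L)]
    }, character(1))
    ok <- all(vapply(others, function(v) {
      seen <- character(0)
      while (v != last && !(v %in% seen)) { seen <- c(seen, v); v <- last_edge[[v]] }
      v == last
    }, logical(1)))
    if (ok) break
  }
  ## permute remaining edges, append the designated last edge
  new_edges <- lapply(verts, function(v) {
    e <- edges[[v]]
    if (v %in% others) {
      k <- match(last_edge[[v]], e)
      e <- e[-k]
      c(if (length(e)) e[sample.int(length(e))], last_edge[[v]])
    } else {
      if (length(e) > 1L) e[sample.int(length(e))] else e
    }
  })
  names(new_edges) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  out <- character(n)
  out[1] <- s[1]
  for (k in 2:n) {
    v <- out[k - 1L]
    out[k] <- new_edges[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
  }
  paste(out, collapse = "")
}

#' Randomization test for hairpin pairing score
#'
#' Empirical p-value of the observed pairing score against
#' dinucleotide-preserving shuffles, with the add-one estimator
#' `p = (1 + #(shuffled score >= observed)) / (1 + n_shuffles)` so p is
#' never 0.
#'
#' @param seq nucleotide string.
#' @param n_shuffles number of shuffles (>= 19; default 99).
#' @param seed integer RNG seed (default 1).
#' @param min_loop loop constraint passed to the folder.
#' @return p-value in (0, 1].
#' @export
randomization_test <- function(seq, n_shuffles = 99L, seed = 1L, min_loop = 3L) {
  if (n_shuffles < 19L) stop("n_shuffles must be >= 19", call. = FALSE)
  seq <- gsub("U", "T", toupper(seq))
  obs <- pair_score_only(seq, min_loop)
  hits <- with_seed(seed, {
    sum(vapply(seq_len(n_shuffles), function(i) {
      pair_score_only(dinuc_shuffle(seq), min_loop) >= obs
    }, logical(1)))
  })
  (1 + hits) / (1 + n_shuffles)
}

#' Default hairpin classification thresholds
#'
#' @param min_len,max_len admissible precursor length in bases.
#' @param t_pf minimum paired fraction.
#' @param t_stem minimum longest stacked helix (pairs).
#' @param t_loops maximum number of hairpin loops.
#' @param t_p maximum randomization p-value.
#' @return named list of thresholds.
#' @export
hairpin_thresholds <- function(min_len = 40L, max_len = 180L, t_pf = 0.5,
                               t_stem = 14L, t_loops = 2L, t_p = 0.05) {
  list(min_len = min_len, max_len = max_len, t_pf = t_pf,
       t_stem = t_stem, t_loops = t_loops, t_p = t_p)
}

#' Classify a hairpin as real or pseudo
#'
#' A transparent rule set separating pre-miRNA-like hairpins from pseudo
#' hairpins: real iff length within `[min_len, max_len]`,
#' `paired_fraction >= t_pf`, `longest_stem >= t_stem`,
#' `n_loops <= t_loops` and `randomization_p <= t_p`.
#'
#' @param f a `hairpin_features` object with `randomization_p` set.
#' @param thresholds see [hairpin_thresholds()].
#' @return `"real"` or `"pseudo"`.
#' @export
classify_hairpin <- function(f, thresholds = hairpin_thresholds()) {
  t <- thresholds
  ok <- f$length >= t$min_len && f$length <= t$max_len &&
    f$paired_fraction >= t$t_pf &&
    f$longest_stem >= t$t_stem &&
    f$n_loops <= t$t_loops &&
    !is.na(f$randomization_p) && f$randomization_p <= t$t_p
  if (ok) "real" else "pseudo"
}

#' Fold, feature, test and classify a set of sequences
#'
#' @param seqs named character vector (or list of FASTA records).
#' @param n_shuffles shuffles per sequence for the randomization test.
#' @param seed base RNG seed; sequence i uses `seed + i - 1`.
#' @param thresholds see [hairpin_thresholds()].
#' @param min_loop folder loop constraint.
#' @return data frame: one row per sequence with every feature and `verdict`.
#' @export
filter_hairpins <- function(seqs, n_shuffles = 99L, seed = 1L,
                            thresholds = hairpin_thresholds(), min_loop = 3L) {
  if (is.list(seqs)) seqs <- genome_as_vector(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    sq <- gsub("U", "T", toupper(seqs[[i]]))
    f <- compute_features(sq, fold_hairpin(sq, min_loop))
    if (f$length >= 4L)
      f$randomization_p <- randomization_test(sq, n_shuffles, seed + i - 1L, min_loop)
    data.frame(id = ids[i], length = f$length, gc_content = f$gc_content,
               paired_fraction = f$paired_fraction,
               normalized_pair_score = f$normalized_pair_score,
               longest_stem = f$longest_stem, terminal_loop = f$terminal_loop,
               n_loops = f$n_loops, randomization_p = f$randomization_p,
               verdict = classify_hairpin(f, thresholds))
  })
  do.call(rbind, rows)
}

## Run code under a temporary RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
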