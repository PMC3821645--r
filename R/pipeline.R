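#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. Unknown keys
#' are rejected. Input paths default to `NULL` (stage skipped where
#' optional).
#'
#' @param chain chain file path (required by [run_pipeline()]).
#' @param ref_mirnas BED of reference pre-miRNAs (required).
#' @param target_fasta target genome FASTA (required).
#' @param families optional TSV mapping miRNA name to family.
#' @param known optional BED of known target-species pre-miRNAs.
#' @param sequenced optional BED of sequencing-derived calls.
#' @param genes optional GFF3 of target gene models.
#' @param pfms optional JASPAR PFM file.
#' @param occupancy optional bedGraph occupancy track.
#' @param prefix 3-letter species prefix for naming.
#' @param min_match liftover match fraction (default 0.95).
#' @param allow_split keep largest piece of split liftovers.
#' @param min_len,max_len candidate length bounds (40, 180).
#' @param threshold overlap-ratio threshold (0.5).
#' @param denominator overlap-ratio denominator mode.
#' @param strand_strict strand-strict overlap matching.
#' @param n_shuffles randomization-test shuffles (99).
#' @param seed RNG seed (1).
#' @param upstream_len intergenic upstream window (2000).
#' @param rel_threshold motif relative-score threshold (0.8).
#' @param pseudocount PWM pseudocount (0.8).
#' @param thresholds hairpin thresholds, see [hairpin_thresholds()].
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(chain = NULL, ref_mirnas = NULL, target_fasta = NULL,
                            families = NULL, known = NULL, sequenced = NULL,
                            genes = NULL, pfms = NULL, occupancy = NULL,
                            prefix = "tgt", min_match = 0.95,
                            allow_split = FALSE, min_len = 40L, max_len = 180L,
                            threshold = 0.5, denominator = "known",
                            strand_strict = TRUE, n_shuffles = 99L, seed = 1L,
                            upstream_len = 2000L, rel_threshold = 0.8,
                            pseudocount = 0.8,
                            thresholds = hairpin_thresholds()) {
  cfg <- as.list(environment())
  stopifnot(cfg$min_match > 0, cfg$min_match <= 1,
            cfg$threshold > 0, cfg$threshold <= 1,
            cfg$min_len < cfg$max_len, cfg$n_shuffles >= 19)
  cfg$denominator <- match.arg(denominator, c("known", "predicted", "shorter"))
  structure(cfg, class = "pipeline_config")
}

#' Run the full discovery pipeline
#'
#' Executes liftover, family collapsing, hairpin filtering and naming, then
#' (when inputs are configured) re-identification against known
#' annotations, the predicted-vs-sequenced comparison, and genomic-context
#' classification with regulatory-region motif scanning. Per-stage TSVs and
#' a run log with the resolved configuration, seed and per-stage record
#' counts are written under `outdir`. Candidate counts can only shrink
#' across filtering stages.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @return invisibly, a list with the stage results (`candidates`,
#'   `crossref`, `venn`, `contexts`, `hits`, `counts`).
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  for (f in c("chain", "ref_mirnas", "target_fasta"))
    if (is.null(config[[f]]) || !file.exists(config[[f]]))
      stop("missing required input: ", f, call. = FALSE)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  log <- c(paste0("synmir run ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           paste0("seed: ", config$seed))

  chains <- parse_chain_file(config$chain)
  index <- build_chain_index(chains)
  refs <- read_bed(config$ref_mirnas)
  if (!is.null(config$families)) {
    fam <- read_family_table(config$families)
    refs$family <- unname(fam[refs$name])
    refs$family[is.na(refs$family)] <- ""
  }
  genome <- genome_as_vector(read_fasta(config$target_fasta))
  counts$reference_mirnas <- nrow(refs)

  cands <- map_premirnas(refs, index, genome, config$min_match,
                         config$min_len, config$max_len, config$allow_split)
  counts$lifted_candidates <- nrow(cands)
  cands <- collapse_family_overlaps(cands)
  counts$after_family_collapse <- nrow(cands)

  hp <- filter_hairpins(stats::setNames(cands$sequence, cands$source_name),
                        config$n_shuffles, config$seed, config$thresholds)
  cands$hairpin_verdict <- hp$verdict
  known <- if (!is.null(config$known)) read_bed(config$known) else NULL
  cands <- assign_candidate_names(cands, config$prefix, known)
  real <- cands[cands$hairpin_verdict == "real", , drop = FALSE]
  counts$real_hairpins <- nrow(real)
  utils::write.table(cands, file.path(outdir, "candidates.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fasta(Map(function(i, s) list(id = i, seq = s),
                  real$assigned_name, real$sequence),
              file.path(outdir, "candidates.fa"))

  out <- list(candidates = cands, counts = counts)
  pred <- genomic_intervals(real$chrom, real$start, real$end, real$strand,
                            name = real$assigned_name)
  if (!is.null(known)) {
    cr <- cross_reference(pred, known, config$threshold, config$denominator,
                          config$strand_strict)
    utils::write.table(cr$pairs, file.path(outdir, "reidentified.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(cr$summary),
                       file.path(outdir, "crossref_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$crossref <- cr
    counts$reidentified_known <- cr$summary$n_reidentified
  }
  if (!is.null(config$sequenced)) {
    sq <- read_bed(config$sequenced)
    vn <- venn_compare(pred, sq, config$threshold, config$strand_strict)
    utils::write.table(as.data.frame(vn), file.path(outdir, "venn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out$venn <- vn
  }
  if (!is.null(config$genes)) {
    genes <- read_gene_models_gff3(config$genes)
    ctx_rows <- list(); hits_rows <- list()
    pfms <- if (!is.null(config$pfms)) read_jaspar_pfm(config$pfms) else list()
    occ <- if (!is.null(config$occupancy)) read_bedgraph(config$occupancy) else NULL
    for (i in seq_len(nrow(real))) {
      ctx <- classify_genomic_context(real[i, ], genes)
      ctx_rows[[i]] <- data.frame(name = real$assigned_name[i],
                                  label = ctx$label, host_gene = ctx$host_gene,
                                  intron_index = ctx$intron_index)
      if (ctx$label == "exonic" || length(pfms) == 0L) next
      reg <- extract_regulatory_region(real[i, ], ctx, genome,
                                       config$upstream_len)
      for (p in pfms) {
        h <- scan_pfm(reg, p, rel_threshold = config$rel_threshold,
                      pseudocount = config$pseudocount, occupancy = occ)
        if (nrow(h)) {
          h$mirna <- real$assigned_name[i]
          hits_rows[[length(hits_rows) + 1L]] <- h
        }
      }
    }
    ctxs <- do.call(rbind, ctx_rows)
    utils::write.table(ctxs, file.path(outdir, "contexts.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    out$contexts <- ctxs
    if (length(hits_rows)) {
      hits <- do.call(rbind, hits_rows)
      utils::write.table(hits, file.path(outdir, "tfbs_hits.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      out$hits <- hits
    }
  }
  out$counts <- counts
  log <- c(log, "config:",
           paste0("  ", names(config), " = ",
                  vapply(config, function(x) paste(format(unlist(x)), collapse = ","),
                         character(1))),
           "counts:",
           paste0("  ", names(counts), " = ", unlist(counts)))
  writeLines(log, file.path(outdir, "run_log.txt"))
  invisible(out)
}
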