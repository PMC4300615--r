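#' Detect fusion transcripts from paired-end RNA-seq alignments
#'
#' Runs the full pipeline: tiered breakpoint scan over chimeric, partial and
#' discordant alignments; grouping of calls (repeat-masked) into candidate
#' regions; regional de Bruijn assembly of the anchored abnormal read pairs;
#' contig re-alignment, chaining and two-gene junction detection; spanning /
#' encompassing support counting, Spanning Score, report gate, ranking,
#' final filtration, isoform merging and Intra/Inter + frame classification.
#'
#' @param alignments SAM/BAM path or an `aln_store`.
#' @param genome FASTA path, DNAStringSet or `ref_genome`.
#' @param genes GTF/BED12 path or `gene_model`.
#' @param repeats,selfchain optional BED paths or `interval_set`s.
#' @param config `scan_config`.
#' @param assembly_k,min_kmer_cov de Bruijn assembler parameters.
#' @param contigs_from optional FASTA of externally assembled contigs used
#'   instead of the internal assembler (applied to every region).
#' @param psl_from optional PSL file (e.g. BLAT output) of contig-to-genome
#'   alignments keyed by the `contigs_from` sequence names; replaces the
#'   internal seed-and-extend re-alignment for those contigs.
#' @param min_seed seed length for contig re-alignment.
#' @param max_overlap microhomology tolerance between partner alignments (nt).
#' @param min_side minimum aligned nt on each side for a spanning read.
#' @param report_min report gate: minimum non-redundant supporting reads.
#' @param min_total,min_ss final-filter thresholds.
#' @param low_q Q threshold for the `low_Q` flag.
#' @param workers regional assemblies dispatched over this many worker
#'   processes; results are ordered by region id, so the output is
#'   independent of the worker count.
#' @param out optional TSV report path ([write_report()]).
#' @param verbose log per-stage counts to stderr.
#' @return list of class `fusion_result`: `report` (final data.frame, 1-based
#'   breakpoints), `candidates` (pre-filter), `calls`, `regions`, `stats`,
#'   `thresholds`.
#' @export
detect_fusions <- function(alignments, genome, genes,
                           repeats = NULL, selfchain = NULL,
                           config = scan_config(),
                           assembly_k = 21L, min_kmer_cov = 2L,
                           contigs_from = NULL, psl_from = NULL,
                           min_seed = 15L, max_overlap = 15L,
                           min_side = 13L, report_min = 2L,
                           min_total = 5L, min_ss = 1,
                           low_q = 0.5, workers = 1L,
                           out = NULL, verbose = FALSE) {
  log_msg <- function(...) if (verbose) message("[refusion] ", ...)
  store <- if (inherits(alignments, "aln_store")) alignments
           else read_alignments(alignments)
  if (!inherits(genome, "ref_genome")) genome <- ref_genome(genome)
  model <- if (inherits(genes, "gene_model")) genes else load_gene_model(genes)
  if (!is.null(repeats) && !inherits(repeats, "interval_set"))
    repeats <- load_interval_set(repeats, "repeat")
  if (!is.null(selfchain) && !inherits(selfchain, "interval_set"))
    selfchain <- load_interval_set(selfchain, "selfchain")

  thresholds <- list(t1 = config$t1, t2 = config$t2, t3 = config$t3,
                     kmer = config$kmer, `max-intron` = config$max_intron,
                     `group-distance` = config$group_distance,
                     `region-halfwidth` = config$region_halfwidth,
                     `assembly-k` = assembly_k, `min-seed` = min_seed,
                     `max-overlap` = max_overlap, `min-span-side` = min_side,
                     `report-gate` = report_min, `min-total` = min_total,
                     `min-ss` = min_ss)

  calls <- call_breakpoints(store, config)
  log_msg(nrow(calls), " breakpoint call(s)")
  groups <- merge_calls(calls, repeats, config)
  regions <- candidate_regions(groups, genome$lengths, config)
  log_msg(nrow(regions), " candidate region(s)")

  ext_contigs <- NULL
  psl <- NULL
  if (!is.null(contigs_from)) {
    cs <- Biostrings::readDNAStringSet(contigs_from)
    ext_contigs <- data.frame(seq = as.character(cs),
                              name = names(cs) %||% as.character(seq_along(cs)),
                              support = NA_integer_,
                              stringsAsFactors = FALSE)
    if (!is.null(psl_from)) psl <- read_psl(psl_from)
  }

  assemble_region <- function(ri) {
    region <- regions[ri, ]
    pairs <- extract_anchored_pairs(region, store, config)
    contigs <- if (!is.null(ext_contigs)) ext_contigs
      else assemble_reads(c(pairs$seq1, pairs$seq2), k = assembly_k,
                          min_kmer_cov = min_kmer_cov)
    contigs <- contigs[nchar(contigs$seq) >= 2L * min_seed, , drop = FALSE]
    if (nrow(contigs) > 5L) contigs <- contigs[1:5, , drop = FALSE]
    list(region_id = region$region_id, pairs = pairs, contigs = contigs)
  }
  reg_results <- if (nrow(regions) == 0L) list()
    else if (workers > 1L)
      parallel::mclapply(seq_len(nrow(regions)), assemble_region,
                         mc.cores = workers)
    else lapply(seq_len(nrow(regions)), assemble_region)

  junctions <- list()
  n_contigs <- 0L
  for (rr in reg_results) {
    for (ci in seq_len(nrow(rr$contigs))) {
      contig <- rr$contigs$seq[ci]
      n_contigs <- n_contigs + 1L
      cname <- rr$contigs$name[ci]
      segs <- if (!is.null(psl) && !is.null(cname) && cname %in% psl$qname)
        psl[psl$qname == cname,
            c("qstart", "qend", "chrom", "gstart", "gend", "strand",
              "matches", "score")]
      else realign_contig(contig, genome, min_seed = min_seed)
      chained <- chain_paths(segs, nchar(contig), max_overlap = max_overlap,
                             extension_slack = 25L)
      if (is.na(chained$q1)) next
      j <- detect_junction(chained, model, genome, contig,
                           repeat_set = repeats, selfchain_set = selfchain,
                           max_overlap = max_overlap, low_q = low_q)
      if (is.null(j)) next
      j$region_id <- rr$region_id
      junctions[[length(junctions) + 1L]] <- j
    }
  }
  log_msg(n_contigs, " contig(s), ", length(junctions),
          " raw junction candidate(s)")

  empty_report <- data.frame(
    rank = integer(0), gene5 = character(0), gene3 = character(0),
    chrom5 = character(0), breakpoint5 = integer(0), strand5 = character(0),
    chrom3 = character(0), breakpoint3 = integer(0), strand3 = character(0),
    spanning = integer(0), encompassing = integer(0), total = integer(0),
    SS = numeric(0), Q = numeric(0), type = character(0), frame = character(0),
    flags = character(0), isoform_breakpoints = character(0),
    contig = character(0), stringsAsFactors = FALSE)

  result <- structure(list(report = empty_report, candidates = empty_report,
                           calls = calls, regions = regions,
                           thresholds = thresholds,
                           stats = c(calls = nrow(calls),
                                     regions = nrow(regions),
                                     contigs = n_contigs, reported = 0L)),
                      class = "fusion_result")
  if (length(junctions) == 0L) {
    if (!is.null(out)) write_report(result$report, out, thresholds)
    return(result)
  }

  jdf <- do.call(rbind, junctions)
  # one record per distinct junction; keep the longest contig
  key <- paste(jdf$gene5, jdf$gene3, jdf$chrom5, jdf$pos5, jdf$chrom3,
               jdf$pos3)
  jdf <- jdf[order(key, -nchar(jdf$contig)), , drop = FALSE]
  jdf <- jdf[!duplicated(paste(jdf$gene5, jdf$gene3, jdf$chrom5, jdf$pos5,
                               jdf$chrom3, jdf$pos3)), , drop = FALSE]

  # support pool: anchored pairs of the source region plus initially
  # unmapped pairs
  pair_pool <- setNames(lapply(reg_results, `[[`, "pairs"),
                        vapply(reg_results, `[[`, 0L, "region_id"))
  um <- store$unmapped
  um_pairs <- NULL
  if (nrow(um) > 0L) {
    ids <- intersect(um$read_id[um$end == 1L], um$read_id[um$end == 2L])
    if (length(ids) > 0L)
      um_pairs <- data.frame(
        read_id = ids,
        seq1 = um$seq[match(paste0(ids, 1L), paste0(um$read_id, um$end))],
        seq2 = um$seq[match(paste0(ids, 2L), paste0(um$read_id, um$end))],
        stringsAsFactors = FALSE)
  }

  cands <- list()
  for (i in seq_len(nrow(jdf))) {
    j <- jdf[i, ]
    pool <- pair_pool[[as.character(j$region_id)]]
    if (!is.null(um_pairs))
      pool <- rbind(pool, um_pairs[!(um_pairs$read_id %in% pool$read_id), ,
                                   drop = FALSE])
    sup <- collect_support(j, pool, min_side = min_side)
    if (!report_gate(sup$n_span, sup$encompassing, report_min)) next
    cl <- classify_candidate(j, model)
    cands[[length(cands) + 1L]] <- data.frame(
      gene5 = j$gene5, gene3 = j$gene3,
      chrom5 = j$chrom5, pos5 = j$pos5, strand5 = j$strand5,
      chrom3 = j$chrom3, pos3 = j$pos3, strand3 = j$strand3,
      spanning = sup$n_span, encompassing = sup$encompassing,
      total = sup$n_span + sup$encompassing,
      SS = spanning_score(sup$evidence), Q = j$Q,
      type = cl$type, frame = cl$frame, flags = j$flags,
      contig = j$contig, stringsAsFactors = FALSE)
  }
  if (length(cands) == 0L) {
    if (!is.null(out)) write_report(result$report, out, thresholds)
    return(result)
  }
  cdf <- rank_candidates(do.call(rbind, cands))
  result$candidates <- cdf
  final <- merge_isoforms(final_filter(cdf, min_total = min_total,
                                       min_ss = min_ss))
  if (nrow(final) > 0L) {
    final$rank <- seq_len(nrow(final))
    final$breakpoint5 <- final$pos5 + 1L
    final$breakpoint3 <- final$pos3 + 1L
  }
  result$report <- final
  result$stats["reported"] <- nrow(final)
  log_msg(nrow(final), " fusion(s) reported")
  if (!is.null(out)) write_report(final, out, thresholds)
  result
}

#' @export
print.fusion_result <- function(x, ...) {
  cat("fusion_result:", x$stats["calls"], "calls,", x$stats["regions"],
      "regions,", x$stats["contigs"], "contigs,", x$stats["reported"],
      "reported fusion(s)\n")
  if (nrow(x$report) > 0L)
    print(x$report[, c("rank", "gene5", "gene3", "spanning", "encompassing",
                       "total", "SS", "Q", "type", "frame")])
  invisible(x)
}
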