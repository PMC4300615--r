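# genomic pieces (chrom, gstart, gend) covering transcript interval [a, b)
# of a (possibly fused) transcript whose blocks carry a chrom column
blocks_for_interval <- function(blocks, a, b) {
  widths <- blocks$gend - blocks$gstart
  cum <- c(0L, cumsum(widths))
  out <- list()
  for (i in seq_len(nrow(blocks))) {
    lo <- max(a, cum[i]); hi <- min(b, cum[i + 1L])
    if (hi <= lo) next
    out[[length(out) + 1L]] <- data.frame(
      chrom = blocks$chrom[i],
      gstart = blocks$gstart[i] + (lo - cum[i]),
      gend = blocks$gstart[i] + (hi - cum[i]), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# CIGAR for one aligned side: leading/trailing soft clips plus M blocks
# separated by N gaps (introns)
side_cigar <- function(pieces, clip_left, clip_right) {
  ops <- character(0)
  if (clip_left > 0L) ops <- c(ops, paste0(clip_left, "S"))
  for (i in seq_len(nrow(pieces))) {
    if (i > 1L) {
      gap <- pieces$gstart[i] - pieces$gend[i - 1L]
      ops <- c(ops, paste0(gap, "N"))
    }
    ops <- c(ops, paste0(pieces$gend[i] - pieces$gstart[i], "M"))
  }
  if (clip_right > 0L) ops <- c(ops, paste0(clip_right, "S"))
  paste(ops, collapse = "")
}

# alignment record(s) for one read covering transcript interval [a, b);
# junction-crossing reads yield a primary partial alignment plus, when both
# sides reach the mapper seed size, a supplementary segment on the partner
# locus.  Returns a list of (chrom, pos, cigar, supplementary).
read_records <- function(meta, a, b, min_side = 15L) {
  J <- meta$junction
  crosses <- !is.na(J) && a < J && J < b
  sides <- if (crosses) list(c(a, J), c(J, b)) else list(c(a, b))
  if (crosses && min(J - a, b - J) < min_side)
    sides <- sides[which.max(c(J - a, b - J))]
  lapply(seq_along(sides), function(si) {
    lo <- sides[[si]][1]; hi <- sides[[si]][2]
    pieces <- blocks_for_interval(meta$blocks, lo, hi)
    list(chrom = pieces$chrom[1], pos = pieces$gstart[1],
         cigar = side_cigar(pieces, lo - a, b - hi),
         supplementary = si > 1L && !(crosses && length(sides) == 1L))
  })
}

#' Emit mapper-like SAM alignments for simulated reads
#'
#' An idealised mapper: every read is placed by construction from the
#' simulation truth.  Reads inside one gene become (spliced, N-CIGAR)
#' alignments; junction-crossing reads become a primary partial alignment
#' soft-clipped at the junction plus a supplementary segment on the partner
#' locus (or a partial alignment only, when the short side is below the
#' mapper seed size); pairs straddling the junction become discordant pairs.
#' Output is coordinate-sorted SAM with a proper header.
#'
#' @param reads data.frame from [simulate_reads()].
#' @param sim `sim_genome`.
#' @param fusion_txs `transcripts` element of [plant_fusions()] output.
#' @param config `sim_config`.
#' @param path output SAM path.
#' @return invisibly, `path`.
#' @export
emit_alignments <- function(reads, sim, fusion_txs, config, path) {
  metas <- list()
  for (g in sim$genes)
    metas[[g$gene_id]] <- list(
      blocks = cbind(g$exons, chrom = g$chrom, stringsAsFactors = FALSE),
      junction = NA_integer_)
  for (tx in fusion_txs)
    metas[[tx$tx_id]] <- list(blocks = tx$blocks, junction = tx$junction)

  rl <- config$read_len
  acc <- list(qname = list(), flag = list(), chrom = list(), pos = list(),
              cigar = list(), rnext = list(), pnext = list(), seq = list())
  seq2_sam <- revcomp(reads$seq2)
  for (i in seq_len(nrow(reads))) {
    meta <- metas[[reads$tx_id[i]]]
    fs <- reads$frag_start[i]; ins <- reads$insert[i]
    r1 <- read_records(meta, fs, fs + rl)
    r2 <- read_records(meta, fs + ins - rl, fs + ins)
    crosses1 <- length(r1) > 1L || grepl("S", r1[[1]]$cigar, fixed = TRUE)
    crosses2 <- length(r2) > 1L || grepl("S", r2[[1]]$cigar, fixed = TRUE)
    span <- max(r1[[1]]$pos + rl, r2[[1]]$pos + rl) -
      min(r1[[1]]$pos, r2[[1]]$pos)
    proper <- !crosses1 && !crosses2 && r1[[1]]$chrom == r2[[1]]$chrom &&
      span <= 200000L
    pflag <- if (proper) 2L else 0L
    for (k in seq_along(r1)) {
      n <- length(acc$qname) + 1L
      acc$qname[[n]] <- reads$read_id[i]
      acc$flag[[n]] <- 1L + pflag + 32L + 64L +
        (if (r1[[k]]$supplementary) 2048L else 0L)
      acc$chrom[[n]] <- r1[[k]]$chrom
      acc$pos[[n]] <- r1[[k]]$pos + 1L
      acc$cigar[[n]] <- r1[[k]]$cigar
      acc$rnext[[n]] <- r2[[1]]$chrom
      acc$pnext[[n]] <- r2[[1]]$pos + 1L
      acc$seq[[n]] <- reads$seq1[i]
    }
    for (k in seq_along(r2)) {
      n <- length(acc$qname) + 1L
      acc$qname[[n]] <- reads$read_id[i]
      acc$flag[[n]] <- 1L + pflag + 16L + 128L +
        (if (r2[[k]]$supplementary) 2048L else 0L)
      acc$chrom[[n]] <- r2[[k]]$chrom
      acc$pos[[n]] <- r2[[k]]$pos + 1L
      acc$cigar[[n]] <- r2[[k]]$cigar
      acc$rnext[[n]] <- r1[[1]]$chrom
      acc$pnext[[n]] <- r1[[1]]$pos + 1L
      acc$seq[[n]] <- seq2_sam[i]
    }
  }
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sim$chrom_lengths),
                   as.integer(sim$chrom_lengths)))
  if (length(acc$qname) > 0L) {
    v <- lapply(acc, function(col) unlist(col, use.names = FALSE))
    o <- order(match(v$chrom, names(sim$chrom_lengths)), v$pos, v$qname,
               v$flag)
    body <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t%s\t%d\t0\t%s\t%s",
                    v$qname[o], v$flag[o], v$chrom[o], v$pos[o], v$cigar[o],
                    v$rnext[o], v$pnext[o], v$seq[o],
                    strrep("I", nchar(v$seq[o])))
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Run the full simulation and write every artifact
#'
#' Writes genome.fa (+ .fai), genes.gtf, repeats.bed, selfchain.bed,
#' reads_1/2.fastq, aln.sam and truth.tsv (breakpoints 1-based in the file)
#' into `outdir`.  All randomness derives from `config$seed`.
#'
#' @param config `sim_config`.
#' @param outdir output directory (created if missing).
#' @return list with `sim`, `truth` (0-based breakpoints), `reads` and
#'   `paths`.
#' @export
simulate_run <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_genome(config)
  pf <- plant_fusions(sim, config)
  chrseq <- setNames(as.character(sim$genome), names(sim$genome))
  wt <- data.frame(
    id = names(sim$genes),
    seq = vapply(sim$genes, function(g)
      transcript_seq(chrseq[[g$chrom]], g$exons), ""),
    depth = 1, stringsAsFactors = FALSE)
  fu <- if (length(pf$transcripts) > 0L) data.frame(
    id = names(pf$transcripts),
    seq = vapply(pf$transcripts, `[[`, "", "seq"),
    depth = pf$truth$depth, stringsAsFactors = FALSE) else NULL
  transcripts <- rbind(wt, fu)
  reads <- simulate_reads(transcripts, config)
  paths <- write_genome_files(sim, outdir)
  paths <- c(paths, setNames(write_fastq(reads, file.path(outdir, "reads")),
                             c("fastq1", "fastq2")))
  sam <- file.path(outdir, "aln.sam")
  emit_alignments(reads, sim, pf$transcripts, config, sam)
  paths["sam"] <- sam
  truth_path <- file.path(outdir, "truth.tsv")
  tt <- pf$truth
  if (nrow(tt) > 0L) {
    tt_out <- tt
    tt_out$bp5 <- tt_out$bp5 + 1L
    tt_out$bp3 <- tt_out$bp3 + 1L
  } else tt_out <- tt
  utils::write.table(tt_out, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["truth"] <- truth_path
  list(sim = sim, truth = tt, transcripts = pf$transcripts, reads = reads,
       paths = paths)
}
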