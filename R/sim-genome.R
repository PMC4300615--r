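# fixed 300 nt motif tiled into the genome as the "repeat" annotation track
REPEAT_MOTIF <- paste0(
  "GATCGCGATCCATACGACAAAACGTATAGTTCATCGAGAACAATCACAAAGCCGCGAGCCAGTTTTCCCC",
  "ATGCTTAATTGCTTAACTCCTGATCTATACCAGTTCGCGAGAGCAGTACGCTTACACTGGCTTCCACCCT",
  "GTTGATTTAAAAAAAATCACACTGTCCGGTGATAACCTGGCCGGATAGCCTCCCTCTTCAAAACCTGGTG",
  "ACCCGCAGCTCTCCTGCGGCGAGTTATGGCTGGTGTTACGAGTGGTCTGCAGTCGTGCTCAGGTGAATGT",
  "GCGTCCCCTCCCCCGAGATC")

#' Simulation configuration
#'
#' Defaults emulate a paired-end 2 x 100 bp protocol with a 250 +/- 30 nt
#' insert and a 0.1% substitution error rate.  The default genome carries a
#' long chromosome (so that two genes on it are separated by more than the
#' maximum allowed intron length, making an intra-chromosomal fusion
#' detectable as chimeric) plus two short chromosomes for inter-chromosomal
#' events.
#'
#' @param seed integer master seed; fully determines every artifact.
#' @param chrom_lengths named vector of chromosome lengths (nt, each >= 10 kb).
#' @param n_genes number of genes, placed round-robin across chromosomes.
#' @param fusion_specs list of fusion specifications, each a list with
#'   `gene5`, `gene3` and either explicit 0-based genomic breakpoints
#'   (`bp5`, `bp3`) or a desired `frame` ("IF"/"OF"); optional
#'   `expression_depth` multiplier (default 2).
#' @param read_len,insert_mean,insert_sd,error_rate,coverage sequencing
#'   parameters.
#' @param plant_repeats write the fixed repeat motif and a duplicated
#'   self-chain segment into intergenic space (annotation BED tracks).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       chrom_lengths = c(chrA = 500000L, chrB = 60000L,
                                         chrC = 60000L),
                       n_genes = 4L,
                       fusion_specs = list(),
                       read_len = 100L, insert_mean = 250L, insert_sd = 30L,
                       error_rate = 0.001, coverage = 30L,
                       plant_repeats = TRUE) {
  stopifnot(all(chrom_lengths >= 10000L), n_genes >= 1L, read_len >= 30L,
            insert_mean >= read_len, coverage > 0)
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 n_genes = as.integer(n_genes), fusion_specs = fusion_specs,
                 read_len = as.integer(read_len),
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 error_rate = error_rate, coverage = coverage,
                 plant_repeats = isTRUE(plant_repeats)),
            class = "sim_config")
}

#' Generate a toy genome with a gene model
#'
#' Chromosomes are i.i.d. uniform ACGT.  Genes (forward strand, 2-5 exons of
#' 150-400 nt separated by 200-2000 nt introns, one transcript each with a
#' CDS leaving short UTRs) are placed in non-overlapping slots spread along
#' each chromosome; the first and last 3 kb of every chromosome are kept
#' gene-free for the repeat and self-chain tracks.
#'
#' @param config `sim_config`.
#' @return list of class `sim_genome`: `genome` (DNAStringSet), `genes`
#'   (list of per-gene structures), `model` (`gene_model`), `repeats` /
#'   `selfchain` (GRanges annotation tracks).
#' @export
make_genome <- function(config) {
  set.seed(config$seed)
  lens <- config$chrom_lengths
  if (is.null(names(lens)))
    names(lens) <- paste0("chr", seq_along(lens))
  seqs <- lapply(lens, function(L)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""))

  # assign genes round-robin, then slot them evenly within [3000, L - 3000)
  chrom_of <- names(lens)[(seq_len(config$n_genes) - 1L) %% length(lens) + 1L]
  genes <- list()
  for (ch in unique(chrom_of)) {
    idx <- which(chrom_of == ch)
    L <- lens[[ch]]
    lo <- 3000L; hi <- L - 3000L
    slot <- (hi - lo) %/% length(idx)
    for (j in seq_along(idx)) {
      gid <- paste0("gene", idx[j])
      n_ex <- sample(2:5, 1L)
      ex_len <- sample(250:450, n_ex, replace = TRUE)
      introns <- if (n_ex > 1L) sample(200:2000, n_ex - 1L, replace = TRUE)
                 else integer(0)
      span <- sum(ex_len) + sum(introns)
      if (span + 2000L > slot)
        stop("genes cannot be placed; enlarge the chromosomes or reduce n_genes")
      gstart <- lo + (j - 1L) * slot + 1000L
      ex_start <- gstart + c(0L, cumsum(ex_len[-n_ex] + introns))
      exons <- data.frame(gstart = ex_start, gend = ex_start + ex_len)
      tx_len <- sum(ex_len)
      utr5 <- sample(20:80, 1L); utr3 <- sample(20:80, 1L)
      cds_len <- tx_len - utr5 - utr3
      cds_len <- cds_len - cds_len %% 3L
      stopifnot(cds_len >= 90L)
      genes[[gid]] <- list(gene_id = gid, chrom = ch, strand = "+",
                           exons = exons, tx_len = tx_len,
                           cds_tx_start = utr5,           # 0-based tx offset
                           cds_tx_end = utr5 + cds_len)   # exclusive
    }
  }
  genes <- genes[order(names(genes))]

  repeats_gr <- GenomicRanges::GRanges()
  selfchain_gr <- GenomicRanges::GRanges()
  if (config$plant_repeats) {
    # tile the fixed motif into the reserved tail of each chromosome
    rep_rows <- list()
    for (ch in names(lens)) {
      L <- lens[[ch]]
      for (s in c(L - 2500L, L - 2000L)) {
        substr(seqs[[ch]], s + 1L, s + 300L) <- REPEAT_MOTIF
        rep_rows[[length(rep_rows) + 1L]] <-
          GenomicRanges::GRanges(ch, IRanges::IRanges(s + 1L, s + 300L))
      }
    }
    repeats_gr <- suppressWarnings(do.call(c, rep_rows))
    # self-chain: duplicate a 400 nt head segment between two locations
    src_ch <- names(lens)[1]
    dst_ch <- if (length(lens) >= 2L) names(lens)[2] else src_ch
    dst_at <- if (dst_ch == src_ch) 1800L else 1000L
    piece <- substr(seqs[[src_ch]], 1001L, 1400L)
    substr(seqs[[dst_ch]], dst_at + 1L, dst_at + 400L) <- piece
    selfchain_gr <- suppressWarnings(c(
      GenomicRanges::GRanges(src_ch, IRanges::IRanges(1001L, 1400L)),
      GenomicRanges::GRanges(dst_ch, IRanges::IRanges(dst_at + 1L,
                                                      dst_at + 400L))))
  }

  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(lens)
  exon_df <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene_id = g$gene_id, tx_id = paste0(g$gene_id, ".t1"),
               chrom = g$chrom, start = g$exons$gstart, end = g$exons$gend,
               strand = g$strand, stringsAsFactors = FALSE)))
  cds_df <- do.call(rbind, lapply(genes, function(g) {
    blocks <- tx_to_genomic_blocks(g$exons, g$cds_tx_start, g$cds_tx_end)
    data.frame(gene_id = g$gene_id, tx_id = paste0(g$gene_id, ".t1"),
               chrom = g$chrom, start = blocks$gstart, end = blocks$gend,
               strand = g$strand, stringsAsFactors = FALSE)
  }))
  structure(list(genome = genome, chrom_lengths = lens, genes = genes,
                 exon_df = exon_df, cds_df = cds_df,
                 model = gene_model(exon_df, cds_df),
                 repeats = repeats_gr, selfchain = selfchain_gr),
            class = "sim_genome")
}

# genomic blocks (0-based half-open) covering transcript interval [a, b);
# exons: data.frame(gstart, gend) in transcript order (forward strand)
tx_to_genomic_blocks <- function(exons, a, b) {
  widths <- exons$gend - exons$gstart
  cum <- c(0L, cumsum(widths))
  out <- list()
  for (i in seq_len(nrow(exons))) {
    lo <- max(a, cum[i]); hi <- min(b, cum[i + 1L])
    if (hi <= lo) next
    out[[length(out) + 1L]] <- data.frame(
      gstart = exons$gstart[i] + (lo - cum[i]),
      gend = exons$gstart[i] + (hi - cum[i]))
  }
  do.call(rbind, out)
}

# 0-based transcript position -> 0-based genomic position (forward strand)
tx_pos_to_genomic <- function(exons, t) {
  widths <- exons$gend - exons$gstart
  cum <- c(0L, cumsum(widths))
  i <- findInterval(t, cum)
  exons$gstart[i] + (t - cum[i])
}

# spliced transcript sequence of a forward-strand gene
transcript_seq <- function(chrom_seq, exons) {
  paste(substring(chrom_seq, exons$gstart + 1L, exons$gend), collapse = "")
}

#' Write the simulated genome and annotation to disk
#'
#' Emits genome.fa (+ .fai), genes.gtf, repeats.bed and selfchain.bed.
#'
#' @param sim `sim_genome`.
#' @param outdir output directory (created if missing).
#' @return named character vector of file paths.
#' @export
write_genome_files <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outdir, "genome.fa")
  Biostrings::writeXStringSet(sim$genome, fa)
  Rsamtools::indexFa(fa)
  gtf <- file.path(outdir, "genes.gtf")
  rows <- list()
  for (g in sim$genes) {
    ex <- sim$exon_df[sim$exon_df$gene_id == g$gene_id, ]
    cd <- sim$cds_df[sim$cds_df$gene_id == g$gene_id, ]
    mk <- function(df, type, phase = NA_integer_) GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start + 1L, df$end), strand = df$strand,
      type = type, gene_id = df$gene_id, transcript_id = df$tx_id,
      phase = phase)
    wid <- cd$end - cd$start
    phase <- as.integer((3L - c(0L, cumsum(wid)[-length(wid)]) %% 3L) %% 3L)
    rows[[length(rows) + 1L]] <- mk(ex, "exon")
    rows[[length(rows) + 1L]] <- mk(cd, "CDS", phase)
  }
  gr <- suppressWarnings(do.call(c, rows))
  rtracklayer::export(gr, gtf, format = "gtf")
  rep_bed <- file.path(outdir, "repeats.bed")
  sc_bed <- file.path(outdir, "selfchain.bed")
  rtracklayer::export(sim$repeats, rep_bed, format = "bed")
  rtracklayer::export(sim$selfchain, sc_bed, format = "bed")
  c(genome = fa, gtf = gtf, repeats = rep_bed, selfchain = sc_bed)
}
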