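#' Plant fusion transcripts into a simulated genome
#'
#' Each fused transcript joins the spliced 5' portion of one gene to the
#' spliced 3' portion of another at exonic breakpoints.  When a spec gives a
#' desired `frame` instead of explicit breakpoints, exonic CDS positions
#' with the matching codon-phase relation are drawn at random (at least
#' 60 nt away from exon boundaries and CDS ends, so junction-flanking
#' sequence is unambiguous).  Breakpoints are then canonicalised for
#' junction microhomology: while the 5' gene's next genomic base equals the
#' next fused-transcript base, both breakpoints shift one base 3'-wards, so
#' the recorded truth matches what any aligner can reconstruct from the
#' junction sequence.
#'
#' @param sim `sim_genome` from [make_genome()].
#' @param config `sim_config` whose `fusion_specs` reference genes in `sim`.
#' @return list with `truth` (data.frame: gene5, gene3, chrom5, bp5, strand5,
#'   chrom3, bp3, strand3, type, frame, tx_id, junction_seq, depth; bp are
#'   0-based: bp5 last retained base of the 5' partner, bp3 first retained
#'   base of the 3' partner) and `transcripts` (list of fused-transcript
#'   structures with sequence, per-side genomic blocks and junction offset).
#' @export
plant_fusions <- function(sim, config) {
  set.seed(config$seed + 1L)
  truth <- list(); txs <- list()
  chrseq <- setNames(as.character(sim$genome), names(sim$genome))
  for (fi in seq_along(config$fusion_specs)) {
    spec <- config$fusion_specs[[fi]]
    gA <- sim$genes[[spec$gene5]]
    gB <- sim$genes[[spec$gene3]]
    if (is.null(gA) || is.null(gB))
      stop("fusion spec references unknown gene(s)")
    txA <- transcript_seq(chrseq[[gA$chrom]], gA$exons)
    txB <- transcript_seq(chrseq[[gB$chrom]], gB$exons)

    if (!is.null(spec$bp5) && !is.null(spec$bp3)) {
      tposA <- genomic_to_tx_pos(gA$exons, spec$bp5) + 1L  # bases retained
      tposB <- genomic_to_tx_pos(gB$exons, spec$bp3)       # bases removed
      if (is.na(tposA) || is.na(tposB))
        stop("fusion breakpoint falls in an intron; exonic breakpoints only")
    } else {
      # margins keep junction flanks unambiguous; small genes fall back to
      # narrower margins rather than failing
      margins <- c(60L, 40L, 25L)
      candA <- candB <- integer(0)
      for (m in margins) {
        candA <- tryCatch(pick_breakpoint(gA, margin = m, all = TRUE),
                          error = function(e) integer(0))
        if (length(candA) > 0L) break
      }
      for (m in margins) {
        candB <- tryCatch(pick_breakpoint(gB, margin = m, all = TRUE),
                          error = function(e) integer(0))
        if (length(candB) > 0L) break
      }
      if (length(candA) == 0L || length(candB) == 0L)
        stop("gene too small to place a breakpoint")
      # keep each retained side at least one insert length long so that
      # read pairs can straddle and reads can cross the junction; without
      # this a short fused transcript hides its junction in the unsequenced
      # gap between the mates
      side_min <- config$insert_mean
      keepA <- candA >= side_min
      if (any(keepA)) candA <- candA[keepA]
      keepB <- gB$tx_len - candB >= side_min
      if (any(keepB)) candB <- candB[keepB]
      tposA <- candA[sample.int(length(candA), 1L)]
      want_if <- (spec$frame %||% "IF") == "IF"
      offA <- tposA - gA$cds_tx_start
      offB <- candB - gB$cds_tx_start
      ok <- if (want_if) (offA - offB) %% 3L == 0L
            else (offA - offB) %% 3L != 0L
      candB <- candB[ok]
      if (length(candB) == 0L) stop("no breakpoint with requested frame")
      tposB <- candB[sample.int(length(candB), 1L)]
    }

    fused <- paste0(substr(txA, 1L, tposA),
                    substr(txB, tposB + 1L, nchar(txB)))
    # canonicalise: shift 3'-wards while the 5' gene's genomic continuation
    # matches the next fused base
    shift <- 0L
    repeat {
      if (shift >= 30L) break
      # both shifted breakpoints must stay genomically contiguous (same exon)
      contigA <- tx_pos_to_genomic(gA$exons, tposA - 1L + shift + 1L) ==
        tx_pos_to_genomic(gA$exons, tposA - 1L + shift) + 1L
      contigB <- tx_pos_to_genomic(gB$exons, tposB + shift + 1L) ==
        tx_pos_to_genomic(gB$exons, tposB + shift) + 1L
      if (!isTRUE(contigA) || !isTRUE(contigB)) break
      gA_next <- tx_pos_to_genomic(gA$exons, tposA - 1L) + 1L + shift
      if (gA_next >= sim$chrom_lengths[[gA$chrom]]) break
      nxt <- tposA + shift                      # 0-based index into fused
      if (nxt >= nchar(fused)) break
      if (substr(chrseq[[gA$chrom]], gA_next + 1L, gA_next + 1L) !=
          substr(fused, nxt + 1L, nxt + 1L)) break
      shift <- shift + 1L
    }
    tposA <- tposA + shift
    tposB <- tposB + shift

    bp5 <- tx_pos_to_genomic(gA$exons, tposA - 1L)   # last retained base
    bp3 <- tx_pos_to_genomic(gB$exons, tposB)        # first retained base
    off5 <- tposA - gA$cds_tx_start                  # coding bases retained
    off3 <- tposB - gB$cds_tx_start                  # coding bases removed
    in_cds <- tposA - 1L >= gA$cds_tx_start & tposA - 1L < gA$cds_tx_end &
      tposB >= gB$cds_tx_start & tposB < gB$cds_tx_end
    frame <- if (!in_cds) "NA" else if ((off5 - off3) %% 3L == 0L) "IF" else "OF"
    type <- if (gA$chrom == gB$chrom) "Intra" else "Inter"
    tx_id <- paste0("fusion", fi)
    blocksA <- tx_to_genomic_blocks(gA$exons, 0L, tposA)
    blocksB <- tx_to_genomic_blocks(gB$exons, tposB, gB$tx_len)
    blocks <- rbind(cbind(blocksA, chrom = gA$chrom),
                    cbind(blocksB, chrom = gB$chrom))
    jwin <- 50L
    junction_seq <- substr(fused, max(1L, tposA - jwin + 1L), tposA + jwin)
    truth[[fi]] <- data.frame(
      tx_id = tx_id, gene5 = gA$gene_id, gene3 = gB$gene_id,
      chrom5 = gA$chrom, bp5 = bp5, strand5 = "+",
      chrom3 = gB$chrom, bp3 = bp3, strand3 = "+",
      type = type, frame = frame, junction_seq = junction_seq,
      depth = spec$expression_depth %||% 2, stringsAsFactors = FALSE)
    txs[[tx_id]] <- list(tx_id = tx_id, seq = fused, blocks = blocks,
                         junction = tposA, chrom5 = gA$chrom,
                         chrom3 = gB$chrom)
  }
  list(truth = if (length(truth)) do.call(rbind, truth) else
         data.frame(tx_id = character(0)),
       transcripts = txs)
}

# 0-based genomic position -> 0-based transcript position; NA when intronic
genomic_to_tx_pos <- function(exons, g) {
  widths <- exons$gend - exons$gstart
  cum <- c(0L, cumsum(widths))
  for (i in seq_len(nrow(exons)))
    if (g >= exons$gstart[i] && g < exons$gend[i])
      return(cum[i] + (g - exons$gstart[i]))
  NA_integer_
}

# candidate "bases retained" values: transcript positions whose breakpoint
# base lies inside the CDS and at least `margin` nt from exon boundaries
pick_breakpoint <- function(gene, margin = 60L, all = FALSE) {
  widths <- gene$exons$gend - gene$exons$gstart
  cum <- c(0L, cumsum(widths))
  cand <- integer(0)
  for (i in seq_along(widths)) {
    lo <- cum[i] + margin
    hi <- cum[i + 1L] - margin
    if (hi > lo) cand <- c(cand, lo:hi)
  }
  cand <- cand[cand >= gene$cds_tx_start + margin &
                 cand < gene$cds_tx_end - margin]
  if (length(cand) == 0L) stop("gene too small to place a breakpoint")
  if (all) return(cand)
  cand[sample.int(length(cand), 1L)]
}
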