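#' Detect a two-gene fusion junction in a chained contig alignment
#'
#' Scans the best chain for two consecutive segments assigned to two
#' different genes with a contig-coordinate overlap of at most `max_overlap`
#' nt (microhomology tolerance).  The junction is then refined: within a
#' window around the split, the contig break is placed at the point
#' maximising left-locus plus right-locus per-base matches, with ties broken
#' towards the rightmost position, so bases homologous to both loci are
#' assigned to the 5' partner and the reported breakpoints are canonical
#' under junction microhomology.  The 5'/3' partner order follows the fused
#' transcript's orientation: the left contig segment is the 5' partner when
#' it aligns in the sense of its gene, otherwise the contig is the reverse
#' complement of the fusion transcript and the partners swap.  Breakpoints
#' falling in the repeat or self-chain annotation set per-side flags; a low
#' alignment score sets `low_Q`.
#'
#' @param chained `chained_alignment` from [chain_paths()].
#' @param gene_model `gene_model`.
#' @param genome `ref_genome` (used for junction refinement).
#' @param contig the contig sequence that was chained.
#' @param repeat_set,selfchain_set optional `interval_set`s.
#' @param max_overlap maximum tolerated overlap between the two partner
#'   alignments (nt).
#' @param low_q Q threshold below which the `low_Q` flag is set.
#' @return a one-row data.frame (gene5, gene3, chrom5, pos5, strand5, chrom3,
#'   pos3, strand3, contig_break, Q, flags, contig) or NULL when no two-gene
#'   split exists.  Positions are 0-based: pos5 is the last retained base of
#'   the 5' partner, pos3 the first retained base of the 3' partner.
#' @export
detect_junction <- function(chained, gene_model, genome, contig,
                            repeat_set = NULL, selfchain_set = NULL,
                            max_overlap = 15L, low_q = 0.5) {
  path <- chained$best_path
  if (is.null(path) || nrow(path) < 2L) return(NULL)
  if (!inherits(genome, "ref_genome")) genome <- ref_genome(genome)
  genes <- lapply(seq_len(nrow(path)), function(i)
    gene_at_interval(gene_model, path$chrom[i], path$gstart[i], path$gend[i]))
  gids <- vapply(genes, `[[`, "", "gene_id")
  best <- NULL
  for (i in seq_len(nrow(path) - 1L)) {
    gl <- gids[i]; gr <- gids[i + 1L]
    if (is.na(gl) || is.na(gr) || gl == gr) next
    left <- path[i, ]; right <- path[i + 1L, ]
    sense <- !is.na(genes[[i]]$strand) && left$strand == genes[[i]]$strand
    ref <- refine_break(contig, left, right, genome,
                        prefer = if (sense) "right" else "left")
    if (ref$overlap > max_overlap) next
    flank <- min(ref$brk - left$qstart, right$qend - ref$brk)
    if (is.null(best) || flank > best$flank)
      best <- list(i = i, ref = ref, flank = flank)
  }
  if (is.null(best)) return(NULL)
  i <- best$i
  left <- path[i, ]; right <- path[i + 1L, ]
  ref <- best$ref
  # genomic coordinate of contig position p (0-based) under a segment mapping
  g_at <- function(seg, p) {
    if (seg$strand == "+") seg$gstart + (p - seg$qstart)
    else seg$gend - 1L - (p - seg$qstart)
  }
  brk <- ref$brk                               # bases left of break
  pos_left <- g_at(left, brk - 1L)             # last base of left partner
  pos_right <- g_at(right, brk)                # first base of right partner
  left_sense <- !is.na(genes[[i]]$strand) &&
    left$strand == genes[[i]]$strand
  if (left_sense) {
    gene5 <- gids[i]; gene3 <- gids[i + 1L]
    chrom5 <- left$chrom; pos5 <- pos_left; strand5 <- genes[[i]]$strand
    chrom3 <- right$chrom; pos3 <- pos_right; strand3 <- genes[[i + 1L]]$strand
  } else {
    gene5 <- gids[i + 1L]; gene3 <- gids[i]
    chrom5 <- right$chrom; pos5 <- pos_right; strand5 <- genes[[i + 1L]]$strand
    chrom3 <- left$chrom; pos3 <- pos_left; strand3 <- genes[[i]]$strand
  }
  flags <- character(0)
  if (interval_query(repeat_set, chrom5, pos5)) flags <- c(flags, "repeat5")
  if (interval_query(repeat_set, chrom3, pos3)) flags <- c(flags, "repeat3")
  if (interval_query(selfchain_set, chrom5, pos5))
    flags <- c(flags, "selfchain5")
  if (interval_query(selfchain_set, chrom3, pos3))
    flags <- c(flags, "selfchain3")
  if (!is.na(chained$Q) && chained$Q < low_q) flags <- c(flags, "low_Q")
  out <- data.frame(gene5 = gene5, gene3 = gene3,
                    chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
                    chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
                    contig_break = brk, Q = chained$Q,
                    flags = paste(flags, collapse = ","),
                    contig = contig, stringsAsFactors = FALSE)
  out
}

# Refine the split between two adjacent chained segments.  Scans candidate
# break positions s (number of contig bases assigned to the left segment)
# over a window spanning the raw overlap plus a margin; the score of s is
# (left-locus matches before s) + (right-locus matches from s).  The
# rightmost maximiser is taken; the plateau width of the maximum equals the
# true junction microhomology, returned as `overlap`.
refine_break <- function(contig, left, right, genome, margin = 20L,
                         prefer = "right") {
  n <- nchar(contig)
  cchars <- strsplit(contig, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  base_at <- function(seg, p) {
    # genome base matching contig position p (0-based) under seg's mapping,
    # complemented for minus-strand segments; NA outside the chromosome
    g <- if (seg$strand == "+") seg$gstart + (p - seg$qstart)
         else seg$gend - 1L - (p - seg$qstart)
    gl <- genome$lengths[[seg$chrom]]
    if (g < 0L || g >= gl) return(NA_character_)
    b <- genome$chars[[seg$chrom]][g + 1L]
    if (seg$strand == "+") b else comp[[b]]
  }
  lo <- max(0L, min(right$qstart, left$qend) - margin)
  hi <- min(n, max(right$qstart, left$qend) + margin)
  ps <- lo:(hi - 1L)
  lm <- vapply(ps, function(p) {
    b <- base_at(left, p); !is.na(b) && b == cchars[p + 1L]
  }, logical(1))
  rm_ <- vapply(ps, function(p) {
    b <- base_at(right, p); !is.na(b) && b == cchars[p + 1L]
  }, logical(1))
  # total(s) = const + sum_{p < s} (lm - rm); maximise over s in [lo, hi]
  d <- as.integer(lm) - as.integer(rm_)
  cum <- c(0L, cumsum(d))                      # cum[t+1] = sum over first t
  mx <- max(cum)
  argmax <- which(cum == mx)
  # ties (junction microhomology) are resolved towards the fused
  # transcript's 5' partner: rightmost in contig coordinates when the
  # contig reads in mRNA orientation, leftmost otherwise
  pick <- if (prefer == "right") argmax[length(argmax)] else argmax[1]
  s <- lo + pick - 1L
  plateau <- lo + argmax - 1L
  list(brk = s, overlap = max(plateau) - min(plateau))
}
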