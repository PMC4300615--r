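#' Genome object for contig re-alignment
#'
#' Wraps a `DNAStringSet` (or FASTA path) with cached per-chromosome
#' character vectors used during ungapped extension.
#'
#' @param x `DNAStringSet` or path to a FASTA file.
#' @return object of class `ref_genome`.
#' @export
ref_genome <- function(x) {
  if (is.character(x)) x <- Biostrings::readDNAStringSet(x)
  names(x) <- sub("\\s.*$", "", names(x))
  chars <- lapply(as.character(x), function(s) strsplit(s, "")[[1]])
  structure(list(seq = x, chars = chars,
                 lengths = setNames(Biostrings::width(x), names(x))),
            class = "ref_genome")
}

# ungapped X-drop extension. contig_chars/genome_chars: character vectors.
# Extends from (q0, g0) (1-based, exclusive start of extension) in direction
# dir (+1/-1); returns number of extended bases and matches at the maximal
# score point.
extend_xdrop <- function(contig_chars, genome_chars, q0, g0, dir, xdrop = 12L) {
  max_ext <- if (dir > 0L)
    min(length(contig_chars) - q0, length(genome_chars) - g0)
  else
    min(q0 - 1L, g0 - 1L)
  if (max_ext <= 0L) return(list(ext = 0L, matches = 0L))
  max_ext <- min(max_ext, 2000L)
  qi <- q0 + dir * seq_len(max_ext)
  gi <- g0 + dir * seq_len(max_ext)
  cmp <- contig_chars[qi] == genome_chars[gi]
  sc <- cumsum(ifelse(cmp, 1L, -1L))
  run_max <- cummax(sc)
  stop_at <- which(run_max - sc > xdrop)
  lim <- if (length(stop_at)) stop_at[1] - 1L else max_ext
  if (lim == 0L) return(list(ext = 0L, matches = 0L))
  best <- which.max(sc[seq_len(lim)])
  list(ext = best, matches = sum(cmp[seq_len(best)]))
}

#' Re-align a contig to the genome by seed-and-extend
#'
#' Exact seeds of length `min_seed` are placed every `min_seed` nt along the
#' contig (both strands) and located in the genome; each hit is extended
#' ungapped in both directions under an X-drop rule with +1/-1 scoring.
#' Segments sharing a contig interval that maps to more than one genomic
#' locus with score within `nonunique_frac` of the best are removed as
#' non-unique.
#'
#' @param contig nucleotide string.
#' @param genome `ref_genome` (or DNAStringSet / FASTA path).
#' @param min_seed seed length (default 15).
#' @param nonunique_frac near-best fraction above which multi-locus hits are
#'   discarded.
#' @param xdrop score drop terminating extension.
#' @return data.frame of segments: qstart, qend (0-based half-open on the
#'   contig, in contig orientation), chrom, gstart, gend (0-based half-open),
#'   strand, matches, score.
#' @export
realign_contig <- function(contig, genome, min_seed = 15L,
                           nonunique_frac = 0.95, xdrop = 12L) {
  if (!inherits(genome, "ref_genome")) genome <- ref_genome(genome)
  empty <- data.frame(qstart = integer(0), qend = integer(0),
                      chrom = character(0), gstart = integer(0),
                      gend = integer(0), strand = character(0),
                      matches = integer(0), score = integer(0),
                      stringsAsFactors = FALSE)
  n <- nchar(contig)
  if (n < min_seed) return(empty)
  segs <- list()
  for (strand in c("+", "-")) {
    query <- if (strand == "+") contig else revcomp(contig)
    qchars <- strsplit(query, "")[[1]]
    starts <- unique(c(seq(1L, n - min_seed + 1L, by = min_seed),
                       n - min_seed + 1L))
    for (s in starts) {
      pat <- substr(query, s, s + min_seed - 1L)
      if (grepl("N", pat, fixed = TRUE)) next
      hits <- Biostrings::vmatchPattern(pat, genome$seq)
      for (ci in seq_along(hits)) {
        ir <- hits[[ci]]
        if (length(ir) == 0L) next
        chrom <- names(genome$seq)[ci]
        gchars <- genome$chars[[chrom]]
        for (h in seq_along(ir)) {
          gs <- IRanges::start(ir)[h]          # 1-based
          left <- extend_xdrop(qchars, gchars, s, gs, -1L, xdrop)
          right <- extend_xdrop(qchars, gchars, s + min_seed - 1L,
                                gs + min_seed - 1L, 1L, xdrop)
          q1 <- s - left$ext                    # 1-based inclusive
          q2 <- s + min_seed - 1L + right$ext
          g1 <- gs - left$ext
          g2 <- gs + min_seed - 1L + right$ext
          matches <- min_seed + left$matches + right$matches
          alen <- q2 - q1 + 1L
          score <- matches - (alen - matches)
          if (strand == "+") {
            qs0 <- q1 - 1L; qe0 <- q2
          } else {
            qs0 <- n - q2; qe0 <- n - q1 + 1L
          }
          segs[[length(segs) + 1L]] <- data.frame(
            qstart = qs0, qend = qe0, chrom = chrom,
            gstart = g1 - 1L, gend = g2, strand = strand,
            matches = as.integer(matches), score = as.integer(score),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(segs) == 0L) return(empty)
  out <- do.call(rbind, segs)
  out <- out[!duplicated(out[, c("qstart", "qend", "chrom", "gstart",
                                 "strand")]), , drop = FALSE]
  # collapse hits on the same diagonal with near-identical contig intervals:
  # keep the best-scoring representative
  diag <- ifelse(out$strand == "+", out$gstart - out$qstart,
                 out$gend + out$qstart)
  key <- paste(out$chrom, out$strand, diag)
  o <- order(key, -out$score)
  out <- out[o, , drop = FALSE]
  out <- out[!duplicated(key[o]), , drop = FALSE]
  rownames(out) <- NULL
  # non-unique removal: contig intervals mapping to several near-best loci
  if (nrow(out) > 1L) {
    drop <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(out) - 1L)) {
      for (j in (i + 1L):nrow(out)) {
        ov <- min(out$qend[i], out$qend[j]) - max(out$qstart[i], out$qstart[j])
        wi <- out$qend[i] - out$qstart[i]
        wj <- out$qend[j] - out$qstart[j]
        if (ov <= 0L || ov < 0.8 * wi || ov < 0.8 * wj) next
        same_locus <- out$chrom[i] == out$chrom[j] &&
          out$strand[i] == out$strand[j] &&
          abs(out$gstart[i] - out$gstart[j]) < 50L
        if (same_locus) next
        if (min(out$score[i], out$score[j]) >=
            nonunique_frac * max(out$score[i], out$score[j]))
          drop[c(i, j)] <- TRUE
      }
    }
    out <- out[!drop, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}
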