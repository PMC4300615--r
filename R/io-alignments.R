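#' Read a SAM/BAM file into an alignment store
#'
#' Parses every aligned segment (primary and supplementary; secondary
#' alignments are dropped) into one record with 0-based half-open genomic
#' coordinates, clip structure and mate information.  Segments belonging to
#' the same end of the same read share a `group` identifier, which links the
#' pieces of a chimeric alignment regardless of how the mapper encoded them.
#' Unmapped reads are kept in a side channel (`unmapped`) so they can still
#' contribute junction support later.  Duplicate records (identical read id,
#' end, chromosome, start and CIGAR) are collapsed so downstream support
#' counts are non-redundant.
#'
#' Clip lengths include hard clips: the clipped sequence existed in the read
#' and matters for breakpoint geometry.  `clip5`/`clip3` are in read
#' orientation (5'/3' of the sequenced read); `clip_left`/`clip_right` are in
#' reference orientation.
#'
#' @param path SAM or BAM file (SAM is converted on the fly).
#' @param min_mapq drop mapped records below this mapping quality (default 0,
#'   i.e. no filter).
#' @return an object of class `aln_store`: list with `records` (data.frame),
#'   `unmapped` (data.frame of read_id, end, seq) and `n_skipped` (malformed
#'   CIGARs skipped).
#' @export
read_alignments <- function(path, min_mapq = 0L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  bam <- path
  if (ext == "sam") {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, dest, overwrite = TRUE,
                                             indexDestination = TRUE))
  }
  what <- c("qname", "flag", "rname", "pos", "mapq", "cigar", "mrnm",
            "mpos", "seq")
  x <- Rsamtools::scanBam(bam, param = Rsamtools::ScanBamParam(what = what))[[1]]
  flag <- x$flag
  seq <- as.character(x$seq)
  qname <- x$qname
  b <- function(bit) bitwAnd(flag, bit) > 0L
  frag_end <- ifelse(b(128L), 2L, 1L)

  is_unmapped <- b(4L)
  unmapped <- data.frame(read_id = qname[is_unmapped],
                         end = frag_end[is_unmapped],
                         seq = seq[is_unmapped],
                         stringsAsFactors = FALSE)

  keep <- !is_unmapped & !b(256L)                       # mapped, not secondary
  cigar <- x$cigar[keep]
  ok_cigar <- !is.na(cigar) & grepl("^(\\d+[MIDNSHP=X])+$", cigar)
  n_skipped <- sum(!ok_cigar)
  if (n_skipped > 0L)
    warning(n_skipped, " record(s) with malformed CIGAR skipped")
  idx <- which(keep)[ok_cigar]
  cigar <- x$cigar[idx]

  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  ref_len <- vapply(seq_along(ops), function(i)
    sum(lens[[i]][ops[[i]] %in% c("M", "D", "N", "=", "X")]), integer(1))
  q_len <- vapply(seq_along(ops), function(i)
    sum(lens[[i]][ops[[i]] %in% c("M", "I", "=", "X")]), integer(1))
  clip_left <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    j <- 1L; tot <- 0L
    while (j <= length(o) && o[j] %in% c("S", "H")) { tot <- tot + l[j]; j <- j + 1L }
    tot
  }, integer(1))
  clip_right <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    j <- length(o); tot <- 0L
    while (j >= 1L && o[j] %in% c("S", "H")) { tot <- tot + l[j]; j <- j - 1L }
    tot
  }, integer(1))
  # soft-clip lengths only (sequence present in SEQ), for N checks
  soft_left <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    j <- 1L
    while (j <= length(o) && o[j] == "H") j <- j + 1L
    if (j <= length(o) && o[j] == "S") l[j] else 0L
  }, integer(1))
  soft_right <- vapply(seq_along(ops), function(i) {
    o <- ops[[i]]; l <- lens[[i]]
    j <- length(o)
    while (j >= 1L && o[j] == "H") j <- j - 1L
    if (j >= 1L && o[j] == "S") l[j] else 0L
  }, integer(1))

  strand <- ifelse(bitwAnd(x$flag[idx], 16L) > 0L, "-", "+")
  seqr <- seq[idx]
  nch <- nchar(seqr)
  clip_left_seq <- ifelse(soft_left > 0L, substr(seqr, 1L, soft_left), "")
  clip_right_seq <- ifelse(soft_right > 0L,
                           substr(seqr, nch - soft_right + 1L, nch), "")
  clip_has_n <- grepl("N", clip_left_seq, fixed = TRUE) |
    grepl("N", clip_right_seq, fixed = TRUE)

  paired <- bitwAnd(x$flag[idx], 1L) > 0L
  mate_unmapped <- paired & bitwAnd(x$flag[idx], 8L) > 0L
  mate_chrom <- as.character(x$mrnm[idx])
  mate_chrom[!paired | mate_unmapped] <- NA_character_
  mate_pos <- x$mpos[idx] - 1L
  mate_pos[!paired | mate_unmapped] <- NA_integer_
  mate_strand <- ifelse(bitwAnd(x$flag[idx], 32L) > 0L, "-", "+")
  mate_strand[!paired | mate_unmapped] <- NA_character_

  rec <- data.frame(
    read_id = qname[idx],
    end = frag_end[idx],
    chrom = as.character(x$rname[idx]),
    start = x$pos[idx] - 1L,
    stop = x$pos[idx] - 1L + ref_len,
    strand = strand,
    aligned_ref = ref_len,
    aligned_query = q_len,
    clip_left = clip_left,
    clip_right = clip_right,
    clip5 = ifelse(strand == "+", clip_left, clip_right),
    clip3 = ifelse(strand == "+", clip_right, clip_left),
    clip_has_n = clip_has_n,
    read_len = q_len + clip_left + clip_right,
    supplementary = bitwAnd(x$flag[idx], 2048L) > 0L,
    proper = bitwAnd(x$flag[idx], 2L) > 0L,
    paired = paired,
    mate_unmapped = mate_unmapped,
    mate_chrom = mate_chrom,
    mate_pos = mate_pos,
    mate_strand = mate_strand,
    mapq = x$mapq[idx],
    cigar = cigar,
    seq = seqr,
    stringsAsFactors = FALSE
  )
  rec$group <- if (nrow(rec) > 0L) paste0(rec$read_id, "/", rec$end)
               else character(0)
  rec <- rec[!duplicated(rec[, c("read_id", "end", "chrom", "start", "cigar")]), ,
             drop = FALSE]
  if (min_mapq > 0L) rec <- rec[rec$mapq >= min_mapq | rec$supplementary, ,
                                drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec, unmapped = unmapped, n_skipped = n_skipped),
            class = "aln_store")
}

#' @export
print.aln_store <- function(x, ...) {
  cat("aln_store:", nrow(x$records), "mapped segment(s),",
      nrow(x$unmapped), "unmapped read(s)\n")
  invisible(x)
}

#' Build an alignment store from a records data.frame (no file I/O)
#'
#' Used by tests and the simulator-facing code paths to construct stores
#' programmatically; fills in the derived columns `read_alignments()` would
#' produce.
#'
#' @param records data.frame with at least read_id, end, chrom, start, stop,
#'   strand, clip_left, clip_right; other columns defaulted.
#' @param unmapped optional data.frame (read_id, end, seq).
#' @return `aln_store` object.
#' @export
aln_store <- function(records, unmapped = NULL) {
  defaults <- list(aligned_ref = NA_integer_, aligned_query = NA_integer_,
                   clip_left = 0L, clip_right = 0L, clip_has_n = FALSE,
                   read_len = 100L, supplementary = FALSE, proper = FALSE,
                   paired = TRUE, mate_unmapped = FALSE,
                   mate_chrom = NA_character_, mate_pos = NA_integer_,
                   mate_strand = NA_character_, mapq = 60L,
                   cigar = NA_character_, seq = NA_character_)
  for (nm in names(defaults))
    if (is.null(records[[nm]])) records[[nm]] <- defaults[[nm]]
  if (is.null(records$end)) records$end <- 1L
  if (is.null(records$aligned_ref) || anyNA(records$aligned_ref))
    records$aligned_ref <- records$stop - records$start
  records$clip5 <- ifelse(records$strand == "+", records$clip_left,
                          records$clip_right)
  records$clip3 <- ifelse(records$strand == "+", records$clip_right,
                          records$clip_left)
  if (is.null(records$group))
    records$group <- paste0(records$read_id, "/", records$end)
  if (is.null(unmapped))
    unmapped <- data.frame(read_id = character(0), end = integer(0),
                           seq = character(0), stringsAsFactors = FALSE)
  structure(list(records = records, unmapped = unmapped, n_skipped = 0L),
            class = "aln_store")
}
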