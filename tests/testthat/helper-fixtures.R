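# shared fixture builders: tiny SAM files, random genomes, record tables

write_sam <- function(lines, chroms = c(chr1 = 10000L, chr2 = 10000L),
                      path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(chroms), as.integer(chroms)))
  writeLines(c(hdr, lines), path)
  path
}

sam_line <- function(qname, flag, chrom, pos, cigar, rnext = "*",
                     pnext = 0L, seq = NULL, mapq = 60L) {
  if (is.null(seq)) {
    ops <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
    typ <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1]]
    seq <- strrep("A", sum(ops[typ %in% c("M", "I", "S", "=", "X")]))
  }
  paste(qname, flag, chrom, pos, mapq, cigar, rnext, pnext, 0L, seq,
        strrep("I", nchar(seq)), sep = "\t")
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# deterministic error-free paired reads tiling a template end to end
tile_pairs <- function(template, coverage = 20L, read_len = 75L,
                       insert = 220L) {
  len <- nchar(template)
  # mates must overlap so that every template position lands inside a read:
  # an unsequenced inner gap leaves k-mer holes on short templates
  insert <- min(insert, len, 2L * read_len - 10L)
  n <- max(2L, ceiling(coverage * len / (2L * read_len)))
  starts <- unique(round(seq(0L, len - insert, length.out = n)))
  starts <- c(starts, 0L, len - insert)   # cover both template ends twice
  r1 <- substring(template, starts + 1L, starts + read_len)
  r2 <- refusion::revcomp(substring(template, starts + insert - read_len + 1L,
                                    starts + insert))
  c(r1, r2)
}

# records data.frame builder with the columns aln_store() expects
rec <- function(read_id, chrom, start, stop, strand = "+", end = 1L,
                clip_left = 0L, clip_right = 0L, mate_chrom = NA,
                mate_pos = NA, mate_strand = NA, supplementary = FALSE,
                read_len = 100L, proper = FALSE, seq = NA_character_) {
  data.frame(read_id = read_id, end = end, chrom = chrom, start = start,
             stop = stop, strand = strand, clip_left = clip_left,
             clip_right = clip_right, mate_chrom = mate_chrom,
             mate_pos = mate_pos, mate_strand = mate_strand,
             supplementary = supplementary, read_len = read_len,
             proper = proper, seq = seq, stringsAsFactors = FALSE)
}

# a tier-2 scenario builder: one partial read plus n consistent discordant
# neighbors (all mates on chr9)
tier2_records <- function(n_neighbors, clip = 20L, read_len = 100L) {
  x <- rec("x", "chr1", 1000L, 1000L + (read_len - clip), "+",
           clip_right = clip, read_len = read_len,
           mate_chrom = "chr9", mate_pos = 500L, mate_strand = "+")
  nb <- lapply(seq_len(n_neighbors), function(i)
    rec(paste0("n", i), "chr1", 950L - i * 10L, 1050L - i * 10L, "+",
        mate_chrom = "chr9", mate_pos = 480L + i, mate_strand = "+"))
  do.call(rbind, c(list(x), nb))
}

# small two-gene GTF + equivalent BED12 fixture (shared by io tests)
write_gene_fixtures <- function(dir = tempdir()) {
  gtf <- file.path(dir, "genes_fixture.gtf")
  bed <- file.path(dir, "genes_fixture.bed")
  attr1 <- 'gene_id "g1"; transcript_id "g1.t1";'
  attr2 <- 'gene_id "g2"; transcript_id "g2.t1";'
  lines <- c(
    paste("chr1", "test", "exon", 101, 200, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "test", "exon", 301, 400, ".", "+", ".", attr1, sep = "\t"),
    paste("chr1", "test", "CDS", 131, 200, ".", "+", "0", attr1, sep = "\t"),
    paste("chr1", "test", "CDS", 301, 370, ".", "+", "2", attr1, sep = "\t"),
    paste("chr1", "test", "exon", 151, 350, ".", "-", ".", attr2, sep = "\t"))
  writeLines(lines, gtf)
  # BED12: chrom start end name score strand thickStart thickEnd rgb
  #        blockCount blockSizes blockStarts
  bed_lines <- c(
    paste("chr1", 100, 400, "g1.t1", 0, "+", 130, 370, "0", 2,
          "100,100", "0,200", sep = "\t"),
    paste("chr1", 150, 350, "g2.t1", 0, "-", 150, 151, "0", 1,
          "200", "0", sep = "\t"))
  writeLines(bed_lines, bed)
  list(gtf = gtf, bed = bed)
}
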