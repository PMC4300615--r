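#' Read segment alignments from a PSL file
#'
#' Accepts BLAT's tabular PSL output (with or without the 5-line header) so
#' precomputed contig-to-genome alignments can replace the internal
#' seed-and-extend aligner.  Each PSL row becomes one segment: query
#' coordinates are PSL's forward-strand qStart/qEnd, the score is
#' `matches - mismatches - qBaseInsert - tBaseInsert`.
#'
#' @param path PSL file.
#' @return data.frame: qname, qstart, qend, chrom, gstart, gend, strand,
#'   matches, score (coordinates 0-based half-open, as PSL).
#' @export
read_psl <- function(path) {
  if (!file.exists(path)) stop("PSL file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(psLayout|match|[- ]*$|\\s*mis)", lines)]
  lines <- lines[grepl("^[0-9]", lines)]
  if (length(lines) == 0L)
    return(data.frame(qname = character(0), qstart = integer(0),
                      qend = integer(0), chrom = character(0),
                      gstart = integer(0), gend = integer(0),
                      strand = character(0), matches = integer(0),
                      score = integer(0), stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  get <- function(i, as = as.integer) vapply(f, function(x) as(x[i]),
                                             if (identical(as, as.integer))
                                               integer(1) else character(1))
  data.frame(
    qname = get(10, as.character),
    qstart = get(12), qend = get(13),
    chrom = get(14, as.character), gstart = get(16), gend = get(17),
    strand = substr(get(9, as.character), 1L, 1L),
    matches = get(1),
    score = get(1) - get(2) - get(6) - get(8),
    stringsAsFactors = FALSE)
}
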