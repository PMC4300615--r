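#' Load a BED interval set (repeat or self-chain annotation)
#'
#' Overlapping input intervals are merged; membership queries use 0-based
#' half-open semantics, matching BED.
#'
#' @param path BED file (3+ columns).  An empty file yields an empty set.
#' @param label free-text label, e.g. "repeat" or "selfchain".
#' @return object of class `interval_set`.
#' @export
load_interval_set <- function(path, label = "repeat") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  info <- file.info(path)
  if (info$size == 0L) {
    gr <- GenomicRanges::GRanges()
  } else {
    raw <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    if (any(raw[[2]] < 0) || any(raw[[3]] < 0))
      stop("negative coordinates in BED file: ", path)
    gr <- GenomicRanges::GRanges(raw[[1]],
                                 IRanges::IRanges(raw[[2]] + 1L, raw[[3]]))
  }
  interval_set(gr, label)
}

#' Construct an interval set from a GRanges
#' @param gr GRanges (1-based closed, as usual).
#' @param label set label.
#' @return `interval_set`.
#' @export
interval_set <- function(gr, label = "repeat") {
  gr <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  structure(list(gr = gr, label = label), class = "interval_set")
}

#' Point membership in an interval set
#'
#' @param set `interval_set` (or NULL, which always answers FALSE).
#' @param chrom chromosome name(s).
#' @param pos 0-based position(s).
#' @return logical vector.
#' @export
interval_query <- function(set, chrom, pos) {
  if (is.null(set) || length(set$gr) == 0L || length(pos) == 0L)
    return(rep(FALSE, length(pos)))
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  suppressWarnings(
    GenomicRanges::countOverlaps(q, set$gr, ignore.strand = TRUE) > 0L)
}

#' @export
print.interval_set <- function(x, ...) {
  cat("interval_set(", x$label, "): ", length(x$gr), " merged interval(s)\n",
      sep = "")
  invisible(x)
}
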