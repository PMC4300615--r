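#' Rank fusion candidates
#'
#' Ordering criteria applied in order: Spanning Score (desc), number of
#' independent encompassing read pairs (desc), alignment score Q (desc);
#' residual ties broken by (gene5, gene3) lexicographically for
#' determinism.
#'
#' @param candidates data.frame with columns SS, encompassing, Q, gene5,
#'   gene3.
#' @return the data.frame reordered, with a `rank` column.
#' @export
rank_candidates <- function(candidates) {
  if (nrow(candidates) == 0L) {
    candidates$rank <- integer(0)
    return(candidates)
  }
  o <- order(-candidates$SS, -candidates$encompassing, -candidates$Q,
             candidates$gene5, candidates$gene3)
  out <- candidates[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Final filtration of ranked candidates
#'
#' A candidate is removed when its total non-redundant support is below
#' `min_total`, or its Spanning Score is below `min_ss`, or both of its
#' breakpoints reside in repeat or self-chain annotated regions.  The
#' thresholds are strict ("less than"), so total = 5 and SS = 1 survive.
#'
#' @param candidates ranked data.frame with columns total, SS, flags (and
#'   encompassing, when `repeat_rescue` is used).
#' @param min_total minimum total supporting reads (default 5).
#' @param min_ss minimum Spanning Score (default 1).
#' @param repeat_rescue when TRUE, a doubly flagged candidate is kept if it
#'   is also covered by at least one encompassing pair (the stricter
#'   repeat-handling rule of early versions of this approach; off by
#'   default).
#' @return the filtered data.frame, rank order preserved.
#' @export
final_filter <- function(candidates, min_total = 5L, min_ss = 1,
                         repeat_rescue = FALSE) {
  if (nrow(candidates) == 0L) return(candidates)
  fl <- strsplit(candidates$flags %||% rep("", nrow(candidates)), ",",
                 fixed = TRUE)
  side5 <- vapply(fl, function(f) any(f %in% c("repeat5", "selfchain5")),
                  logical(1))
  side3 <- vapply(fl, function(f) any(f %in% c("repeat3", "selfchain3")),
                  logical(1))
  flagged_out <- side5 & side3
  if (repeat_rescue) {
    enc <- candidates$encompassing %||% rep(0L, nrow(candidates))
    flagged_out <- flagged_out & enc < 1L
  }
  keep <- candidates$total >= min_total & candidates$SS >= min_ss &
    !flagged_out
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge isoform junctions of the same gene fusion
#'
#' Candidates sharing the ordered (gene5, gene3) pair collapse into one
#' record represented by their best-ranked junction; the supports reported
#' are the representative's, and all member breakpoints are listed in
#' `isoform_breakpoints`.  Swapped 5'/3' orientation is a distinct fusion
#' and is never merged.
#'
#' @param candidates ranked (and typically filtered) data.frame.
#' @return merged data.frame with columns `n_isoforms` and
#'   `isoform_breakpoints` added.
#' @export
merge_isoforms <- function(candidates) {
  if (nrow(candidates) == 0L) {
    candidates$n_isoforms <- integer(0)
    candidates$isoform_breakpoints <- character(0)
    return(candidates)
  }
  key <- paste(candidates$gene5, candidates$gene3, sep = ">")
  reps <- !duplicated(key)                     # input is rank-ordered
  out <- candidates[reps, , drop = FALSE]
  bp <- paste0(candidates$chrom5, ":", candidates$pos5 + 1L, "|",
               candidates$chrom3, ":", candidates$pos3 + 1L)
  out$n_isoforms <- as.integer(table(key)[key[reps]])
  out$isoform_breakpoints <- vapply(key[reps], function(k)
    paste(bp[key == k], collapse = ";"), "")
  rownames(out) <- NULL
  out
}

#' Classify a fusion candidate: chromosomal type and reading frame
#'
#' Type is `Intra` when both breakpoints are on one chromosome, `Inter`
#' otherwise.  Frame uses the longest-CDS transcript of each partner: with
#' `offset5` the number of coding bases retained in the 5' partner and
#' `offset3` the number of coding bases removed from the 3' partner, the
#' fusion is in frame (IF) when `offset5 = offset3 (mod 3)`, out of frame
#' (OF) otherwise, and NA when either breakpoint lies outside a CDS (or a
#' partner has none).
#'
#' @param candidate one-row data.frame with chrom5/pos5/gene5 and
#'   chrom3/pos3/gene3 (0-based positions).
#' @param model `gene_model` with CDS annotation.
#' @return list(type, frame).
#' @export
classify_candidate <- function(candidate, model) {
  type <- if (candidate$chrom5 == candidate$chrom3) "Intra" else "Inter"
  off5 <- cds_offset(model, candidate$gene5, candidate$pos5, inclusive = TRUE)
  off3 <- cds_offset(model, candidate$gene3, candidate$pos3, inclusive = FALSE)
  frame <- if (is.na(off5) || is.na(off3)) "NA"
           else if ((off5 - off3) %% 3 == 0) "IF" else "OF"
  list(type = type, frame = frame)
}

#' Write the fusion report as TSV
#'
#' Breakpoints are reported 1-based.  Threshold provenance is echoed as
#' `#` comment lines ahead of the header.
#'
#' @param candidates final candidate data.frame (0-based pos5/pos3
#'   internally).
#' @param path output file.
#' @param thresholds named list echoed into the header comments.
#' @return invisibly, the path.
#' @export
write_report <- function(candidates, path, thresholds = NULL) {
  cols <- c("rank", "gene5", "gene3", "chrom5", "breakpoint5", "strand5",
            "chrom3", "breakpoint3", "strand3", "spanning", "encompassing",
            "total", "SS", "Q", "type", "frame", "flags",
            "isoform_breakpoints", "contig_sequence")
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(thresholds))
    for (nm in names(thresholds))
      writeLines(sprintf("# %s=%s", nm, format(thresholds[[nm]])), con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(candidates) > 0L) {
    df <- data.frame(
      rank = candidates$rank,
      gene5 = candidates$gene5, gene3 = candidates$gene3,
      chrom5 = candidates$chrom5, breakpoint5 = candidates$pos5 + 1L,
      strand5 = candidates$strand5,
      chrom3 = candidates$chrom3, breakpoint3 = candidates$pos3 + 1L,
      strand3 = candidates$strand3,
      spanning = candidates$spanning, encompassing = candidates$encompassing,
      total = candidates$total,
      SS = sprintf("%.6g", candidates$SS), Q = sprintf("%.6g", candidates$Q),
      type = candidates$type, frame = candidates$frame,
      flags = ifelse(nzchar(candidates$flags), candidates$flags, "."),
      isoform_breakpoints = candidates$isoform_breakpoints %||%
        rep(".", nrow(candidates)),
      contig_sequence = candidates$contig,
      stringsAsFactors = FALSE)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
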