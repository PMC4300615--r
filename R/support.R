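#' Count spanning and encompassing support for a junction
#'
#' Each candidate improper pair is re-aligned to the junction contig (read
#' and reverse complement; exact full-length occurrence is tried first, then
#' a local alignment).  A read is a direct, spanning support when it crosses
#' the contig break with at least `min_side` nt aligned on both sides; a
#' pair is an indirect, encompassing support when its mates align on
#' opposite sides without crossing.  Reads with identical alignment offsets
#' (likely PCR duplicates) are counted once, and every pair contributes to
#' at most one category (spanning wins).
#'
#' @param junction one-row data.frame from [detect_junction()] (needs
#'   `contig` and `contig_break`).
#' @param pairs data.frame with read_id, seq1, seq2 (NA allowed).
#' @param min_side minimum aligned nt on each side of the fusion point for a
#'   spanning read (default 13).
#' @param min_score minimum local alignment score for a read to count as
#'   aligned to the contig.
#' @return list with `evidence` (data.frame read_id, L, R), `n_span`,
#'   `encompassing`.
#' @export
collect_support <- function(junction, pairs, min_side = 13L, min_score = 25L) {
  contig <- junction$contig
  brk <- junction$contig_break
  out_empty <- list(evidence = data.frame(read_id = character(0), L = integer(0),
                                          R = integer(0), stringsAsFactors = FALSE),
                    n_span = 0L, encompassing = 0L)
  if (is.null(pairs) || nrow(pairs) == 0L) return(out_empty)

  align_one_set <- function(seqs) {
    # returns data.frame(s0, e0, score) of the best placement of each read
    # (either orientation) on the contig; NA rows when unaligned
    res <- data.frame(s0 = rep(NA_integer_, length(seqs)),
                      e0 = NA_integer_, score = NA_real_)
    ok <- !is.na(seqs) & nzchar(seqs)
    if (!any(ok)) return(res)
    idx <- which(ok)
    fw <- seqs[idx]
    rc <- revcomp(fw)
    # stage 1: exact substring occurrence
    find_exact <- function(ss) {
      vapply(ss, function(s) {
        m <- regexpr(s, contig, fixed = TRUE)
        as.integer(m[1])
      }, integer(1))
    }
    pf <- find_exact(fw)
    pr <- find_exact(rc)
    for (j in seq_along(idx)) {
      if (pf[j] > 0L) {
        res$s0[idx[j]] <- pf[j] - 1L
        res$e0[idx[j]] <- pf[j] - 1L + nchar(fw[j])
        res$score[idx[j]] <- nchar(fw[j])
      } else if (pr[j] > 0L) {
        res$s0[idx[j]] <- pr[j] - 1L
        res$e0[idx[j]] <- pr[j] - 1L + nchar(rc[j])
        res$score[idx[j]] <- nchar(rc[j])
      }
    }
    # stage 2: local alignment for the rest (errors, contig-edge overlaps)
    left <- which(ok & is.na(res$s0))
    if (length(left) > 0L) {
      mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                      baseOnly = FALSE)
      subj <- Biostrings::DNAString(contig)
      for (j in left) {
        best <- NULL
        for (s in c(seqs[j], revcomp(seqs[j]))) {
          al <- Biostrings::pairwiseAlignment(
            Biostrings::DNAString(s), subj, type = "local",
            substitutionMatrix = mat, gapOpening = 2, gapExtension = 1)
          if (is.null(best) || Biostrings::score(al) > best$score)
            best <- list(score = Biostrings::score(al),
                         s0 = IRanges::start(Biostrings::subject(al)@range) - 1L,
                         e0 = IRanges::end(Biostrings::subject(al)@range))
        }
        if (best$score >= min_score) {
          res$s0[j] <- best$s0; res$e0[j] <- best$e0; res$score[j] <- best$score
        }
      }
    }
    res$score[!is.na(res$score) & res$score < min_score] <- NA_real_
    res$s0[is.na(res$score)] <- NA_integer_
    res$e0[is.na(res$score)] <- NA_integer_
    res
  }

  a1 <- align_one_set(pairs$seq1)
  a2 <- align_one_set(pairs$seq2)
  side_counts <- function(a) {
    L <- pmax(0L, pmin(a$e0, brk) - a$s0)
    R <- pmax(0L, a$e0 - pmax(a$s0, brk))
    data.frame(L = L, R = R)
  }
  c1 <- side_counts(a1); c2 <- side_counts(a2)
  span1 <- !is.na(c1$L) & c1$L >= min_side & c1$R >= min_side
  span2 <- !is.na(c2$L) & c2$L >= min_side & c2$R >= min_side

  ev <- list(); span_keys <- character(0)
  enc_keys <- character(0)
  for (i in seq_len(nrow(pairs))) {
    if (isTRUE(span1[i]) || isTRUE(span2[i])) {
      use1 <- isTRUE(span1[i])
      key <- paste(if (use1) a1$s0[i] else a2$s0[i],
                   if (use1) a2$s0[i] else a1$s0[i], sep = ":")
      if (key %in% span_keys) next
      span_keys <- c(span_keys, key)
      ev[[length(ev) + 1L]] <- data.frame(
        read_id = pairs$read_id[i],
        L = if (use1) c1$L[i] else c2$L[i],
        R = if (use1) c1$R[i] else c2$R[i], stringsAsFactors = FALSE)
    } else {
      if (is.na(a1$s0[i]) || is.na(a2$s0[i])) next
      side <- function(cc, i) if (cc$L[i] >= cc$R[i]) "L" else "R"
      if (side(c1, i) != side(c2, i)) {
        key <- paste(a1$s0[i], a2$s0[i], sep = ":")
        if (key %in% enc_keys) next
        enc_keys <- c(enc_keys, key)
      }
    }
  }
  evidence <- if (length(ev)) do.call(rbind, ev) else out_empty$evidence
  list(evidence = evidence, n_span = nrow(evidence),
       encompassing = length(enc_keys))
}

#' Spanning Score
#'
#' `SS = N - sum_i |L_i - R_i| / (L_i + R_i)` over the N independent
#' spanning reads: many well-balanced junction reads score high; an absent
#' read set scores 0.
#'
#' @param evidence data.frame with columns L and R (one row per independent
#'   spanning read), as produced by [collect_support()].
#' @return numeric SS.
#' @export
spanning_score <- function(evidence) {
  if (is.null(evidence) || nrow(evidence) == 0L) return(0)
  nrow(evidence) - sum(abs(evidence$L - evidence$R) /
                         (evidence$L + evidence$R))
}

#' Reporting gate: at least two non-redundant supporting reads
#'
#' @param n_span independent spanning reads.
#' @param encompassing independent encompassing pairs.
#' @param min_support gate (default 2).
#' @return logical.
#' @export
report_gate <- function(n_span, encompassing, min_support = 2L) {
  n_span + encompassing >= min_support
}
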