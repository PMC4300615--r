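#' Alignment score Q from best and second-best chained alignments
#'
#' `Q = exp((q1 - q0) / 10) - exp((q2 - q0) / 10)`, with the second term 0
#' when no second chain exists.  Q is 1 for a perfect unique alignment and 0
#' when the two best chains tie.
#'
#' @param q0 contig length (nt).
#' @param q1 aggregate score of the best chain.
#' @param q2 aggregate score of the second-best chain, or NA when absent.
#' @return numeric Q in [0, 1].
#' @export
alignment_score_q <- function(q0, q1, q2 = NA_real_) {
  second <- ifelse(is.na(q2), 0, exp((q2 - q0) / 10))
  exp((q1 - q0) / 10) - second
}

#' Chain contig segments into best and second-best concatenated alignments
#'
#' Dynamic-programming chaining over segments ordered by contig start.
#' Consecutive members may overlap by at most `max_overlap` nt in contig
#' coordinates (the overlap is subtracted from the chain score once so the
#' aggregate never exceeds the contig length); genomic jumps are free, so
#' introns and translocations cost nothing.  The two highest-scoring distinct
#' chains give `q1` and `q2`, from which `Q` is computed.
#'
#' @param segments data.frame from [realign_contig()].
#' @param contig_len contig length `q0` in nt.
#' @param max_overlap maximum tolerated contig-coordinate overlap between
#'   consecutive segments (microhomology tolerance, default 15).
#' @param extension_slack extra overlap allowed on top of `max_overlap`
#'   during chaining.  Ungapped X-drop extension can overshoot a junction by
#'   a few chance-matching bases, inflating the raw overlap beyond the true
#'   microhomology; the pipeline therefore chains with slack and enforces
#'   the microhomology cap on the refined junction instead
#'   (see [detect_junction()]).
#' @return object of class `chained_alignment`: list with q0, q1, q2, Q,
#'   `best_path` and `second_path` (data.frames of member segments, ordered
#'   by qstart).
#' @export
chain_paths <- function(segments, contig_len, max_overlap = 15L,
                        extension_slack = 0L) {
  max_overlap <- max_overlap + extension_slack
  out <- structure(list(q0 = contig_len, q1 = NA_real_, q2 = NA_real_,
                        Q = NA_real_, best_path = NULL, second_path = NULL),
                   class = "chained_alignment")
  if (is.null(segments) || nrow(segments) == 0L) return(out)
  seg <- segments[order(segments$qstart, segments$qend), , drop = FALSE]
  rownames(seg) <- NULL
  n <- nrow(seg)
  # dp[[i]]: list of up to 2 best distinct chains ending at segment i,
  # each a list(score, path = integer indices)
  dp <- vector("list", n)
  for (i in seq_len(n)) {
    cand <- list(list(score = seg$score[i], path = i))
    for (j in seq_len(max(0L, i - 1L))) {
      ov <- seg$qend[j] - seg$qstart[i]
      if (ov > max_overlap) next
      if (seg$qend[i] <= seg$qend[j] || seg$qstart[i] <= seg$qstart[j]) next
      pen <- max(0L, ov)
      for (entry in dp[[j]])
        cand[[length(cand) + 1L]] <- list(
          score = entry$score + seg$score[i] - pen,
          path = c(entry$path, i))
    }
    o <- order(vapply(cand, `[[`, 0, "score"), decreasing = TRUE)
    keep <- list()
    seen <- character(0)
    for (ci in o) {
      sig <- paste(cand[[ci]]$path, collapse = ",")
      if (sig %in% seen) next
      keep[[length(keep) + 1L]] <- cand[[ci]]
      seen <- c(seen, sig)
      if (length(keep) == 2L) break
    }
    dp[[i]] <- keep
  }
  all_chains <- do.call(c, dp)
  scores <- vapply(all_chains, `[[`, 0, "score")
  o <- order(scores, decreasing = TRUE)
  best <- all_chains[[o[1]]]
  best_sig <- paste(sort(best$path), collapse = ",")
  second <- NULL
  for (ci in o[-1]) {
    if (paste(sort(all_chains[[ci]]$path), collapse = ",") != best_sig) {
      second <- all_chains[[ci]]
      break
    }
  }
  out$q1 <- best$score
  out$best_path <- seg[best$path, , drop = FALSE]
  if (!is.null(second)) {
    out$q2 <- second$score
    out$second_path <- seg[second$path, , drop = FALSE]
  }
  out$Q <- alignment_score_q(out$q0, out$q1, out$q2)
  out
}

#' @export
print.chained_alignment <- function(x, ...) {
  cat("chained_alignment: q0=", x$q0, " q1=", x$q1, " q2=", x$q2,
      " Q=", round(x$Q, 4), " (", NROW(x$best_path), " segment(s))\n",
      sep = "")
  invisible(x)
}
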