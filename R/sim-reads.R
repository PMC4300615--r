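#' Simulate paired-end reads from transcripts
#'
#' Fragment lengths are Normal(`insert_mean`, `insert_sd`) truncated to
#' `[read_len, transcript length]`; fragment starts are uniform; read 1 is
#' the first `read_len` bases of the fragment, read 2 the reverse
#' complement of its last `read_len` bases.  Substitution errors are
#' injected at `error_rate` per base.  Read ids encode the source
#' transcript, fragment start and insert size.
#'
#' @param transcripts data.frame with columns id, seq, depth (expression
#'   multiplier; pairs are drawn to reach `depth * coverage` fold coverage).
#' @param config `sim_config`.
#' @return data.frame: read_id, tx_id, frag_start (0-based on transcript),
#'   insert, seq1, seq2.
#' @export
simulate_reads <- function(transcripts, config) {
  set.seed(config$seed + 2L)
  rl <- config$read_len
  out <- list()
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts$seq[i]
    len <- nchar(tx)
    if (len < rl) {
      warning("transcript ", transcripts$id[i],
              " shorter than read length; skipped")
      next
    }
    depth <- transcripts$depth[i] %||% 1
    n <- round(depth * config$coverage * len / (2 * rl))
    if (n < 1L) next
    ins <- as.integer(clamp(round(rnorm(n, config$insert_mean,
                                        config$insert_sd)), rl, len))
    fs <- vapply(ins, function(x) {
      if (len - x <= 0L) 0L else sample.int(len - x + 1L, 1L) - 1L
    }, integer(1))
    s1 <- substr_many(tx, fs, fs + rl)
    s2 <- revcomp(substr_many(tx, fs + ins - rl, fs + ins))
    if (config$error_rate > 0) {
      s1 <- mutate_seqs(s1, config$error_rate)
      s2 <- mutate_seqs(s2, config$error_rate)
    }
    out[[length(out) + 1L]] <- data.frame(
      read_id = sprintf("%s:p%05d:%d:%d", transcripts$id[i],
                        seq_len(n), fs, ins),
      tx_id = transcripts$id[i], frag_start = fs, insert = ins,
      seq1 = s1, seq2 = s2, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(read_id = character(0), tx_id = character(0),
                      frag_start = integer(0), insert = integer(0),
                      seq1 = character(0), seq2 = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# vectorised substring over one string: 0-based half-open [a, b)
substr_many <- function(s, a, b) substring(s, a + 1L, b)

# independent per-base substitution errors at the given rate
mutate_seqs <- function(seqs, rate) {
  n_err <- rbinom(length(seqs), nchar(seqs), rate)
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sample.int(nchar(seqs[i]), n_err[i])
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in pos)
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
    seqs[i] <- paste(ch, collapse = "")
  }
  seqs
}

#' Write simulated reads as a FASTQ pair
#'
#' @param reads data.frame from [simulate_reads()].
#' @param prefix path prefix; writes `<prefix>_1.fastq` and
#'   `<prefix>_2.fastq` with constant quality.
#' @return character vector of the two paths.
#' @export
write_fastq <- function(reads, prefix) {
  write_one <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
    path
  }
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  write_one(reads$seq1, paste0(reads$read_id, "/1"), p1)
  write_one(reads$seq2, paste0(reads$read_id, "/2"), p2)
  c(p1, p2)
}
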