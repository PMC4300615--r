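#' Extract abnormal read pairs anchored in a candidate region
#'
#' Harvests discordant pairs, singletons (mate unmapped), and partially or
#' chimerically aligned reads with at least one segment overlapping the
#' region window, then pulls in each mate even when it is mapped elsewhere
#' or unmapped.  Concordant fully aligned pairs are excluded.
#'
#' @param region one row of the [candidate_regions()] data.frame.
#' @param store `aln_store`.
#' @param config `scan_config`.
#' @return data.frame with read_id, seq1, seq2 (NA when an end is absent).
#' @export
extract_anchored_pairs <- function(region, store, config = scan_config()) {
  df <- annotate_records(store$records, config)
  abnormal <- df$discordant | df$partial | df$chimeric | df$mate_unmapped |
    df$supplementary
  hit <- abnormal & df$chrom == region$chrom &
    df$start < region$end & df$stop > region$start
  ids <- unique(df$read_id[hit])
  if (length(ids) == 0L)
    return(data.frame(read_id = character(0), seq1 = character(0),
                      seq2 = character(0), stringsAsFactors = FALSE))
  pick_seq <- function(id, end) {
    sub <- df[df$read_id == id & df$end == end & !is.na(df$seq), , drop = FALSE]
    if (nrow(sub) > 0L) {
      # prefer the record carrying the most sequence (primary over clipped supp)
      s <- sub$seq[which.max(nchar(sub$seq))]
      return(s)
    }
    um <- store$unmapped
    j <- which(um$read_id == id & um$end == end)
    if (length(j) > 0L) return(um$seq[j[1]])
    NA_character_
  }
  data.frame(read_id = ids,
             seq1 = vapply(ids, pick_seq, "", end = 1L),
             seq2 = vapply(ids, pick_seq, "", end = 2L),
             stringsAsFactors = FALSE, row.names = NULL)
}

# all k-mers of a set of sequences (forward orientation only)
extract_kmers <- function(seqs, k) {
  seqs <- seqs[!is.na(seqs) & nchar(seqs) >= k]
  if (length(seqs) == 0L) return(character(0))
  unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
}

canonical_kmer <- function(km) {
  rc <- revcomp(km)
  ifelse(km <= rc, km, rc)
}

#' Assemble reads into contigs with a single-k de Bruijn graph
#'
#' Counts canonical k-mers, prunes k-mers below `min_kmer_cov`, clips
#' dead-end tips shorter than `tip_len`, compresses unbranched paths and
#' emits every maximal unbranched path as a contig.  Contigs are reported in
#' a deterministic order (support descending, then lexicographic sequence)
#' and deduplicated up to reverse complement.
#'
#' @param reads character vector of ACGTN sequences (k-mers containing N are
#'   dropped).
#' @param k odd k-mer size >= 11.
#' @param min_kmer_cov minimum canonical k-mer coverage retained.
#' @param tip_len dead-end branches shorter than this many nt are clipped.
#' @return data.frame of contigs: seq, length, support, k.
#' @export
assemble_reads <- function(reads, k = 21L, min_kmer_cov = 2L,
                           tip_len = 2L * k) {
  if (k < 11L || k %% 2L == 0L)
    stop("k must be odd and >= 11 (unstable/palindromic k-mers otherwise)")
  empty <- data.frame(seq = character(0), length = integer(0),
                      support = integer(0), k = integer(0),
                      stringsAsFactors = FALSE)
  reads <- toupper(reads[!is.na(reads)])
  if (length(reads) == 0L) return(empty)
  if (all(nchar(reads) < k)) {
    warning("all reads shorter than k; nothing to assemble")
    return(empty)
  }
  km <- extract_kmers(reads, k)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0L) return(empty)
  cov <- table(canonical_kmer(km))
  cov <- cov[cov >= min_kmer_cov]
  if (length(cov) == 0L) return(empty)
  nodes <- unique(c(names(cov), revcomp(names(cov))))

  contigs <- NULL
  for (iter in 1:6) {
    res <- build_unitigs(nodes, k)
    tips <- find_tips(res, tip_len, k)
    if (length(tips) == 0L) { contigs <- res; break }
    drop_kmers <- unlist(lapply(res$unitigs[tips], function(s) {
      n <- nchar(s)
      kk <- substring(s, 1:(n - k + 1L), k:n)
      c(kk, revcomp(kk))
    }), use.names = FALSE)
    nodes <- setdiff(nodes, drop_kmers)
    if (length(nodes) == 0L) return(empty)
    contigs <- NULL
  }
  if (is.null(contigs)) contigs <- build_unitigs(nodes, k)

  seqs <- contigs$unitigs
  if (length(seqs) == 0L) return(empty)
  # dedupe up to reverse complement
  canon <- pmin(seqs, revcomp(seqs))
  seqs <- seqs[!duplicated(canon)]
  # support: number of reads sharing at least one k-mer with the contig
  canon_set <- unique(canonical_kmer(km))
  read_km <- lapply(reads, function(s) {
    if (nchar(s) < k) return(character(0))
    n <- nchar(s)
    unique(canonical_kmer(substring(s, 1:(n - k + 1L), k:n)))
  })
  support <- vapply(seqs, function(s) {
    n <- nchar(s)
    ck <- unique(canonical_kmer(substring(s, 1:(n - k + 1L), k:n)))
    sum(vapply(read_km, function(rk) any(rk %in% ck), logical(1)))
  }, integer(1))
  out <- data.frame(seq = seqs, length = nchar(seqs),
                    support = as.integer(support), k = as.integer(k),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$support, out$seq), , drop = FALSE]
}

# unbranched-path compression of a k-mer node set; returns unitigs plus
# per-unitig endpoint degree information
build_unitigs <- function(nodes, k) {
  env <- new.env(hash = TRUE, size = max(16L, length(nodes)))
  for (nd in nodes) assign(nd, TRUE, envir = env)
  bases <- c("A", "C", "G", "T")
  succs <- function(u) {
    cand <- paste0(substr(u, 2L, k), bases)
    cand[vapply(cand, exists, logical(1), envir = env, inherits = FALSE)]
  }
  preds <- function(u) {
    cand <- paste0(bases, substr(u, 1L, k - 1L))
    cand[vapply(cand, exists, logical(1), envir = env, inherits = FALSE)]
  }
  outdeg <- vapply(nodes, function(u) length(succs(u)), integer(1))
  indeg <- vapply(nodes, function(u) length(preds(u)), integer(1))
  names(outdeg) <- nodes; names(indeg) <- nodes

  visited <- new.env(hash = TRUE, size = max(16L, length(nodes)))
  unitigs <- character(0)
  deg_info <- list()
  is_start <- vapply(nodes, function(u) {
    if (indeg[[u]] != 1L) return(TRUE)
    p <- preds(u)
    outdeg[[p]] > 1L
  }, logical(1))
  walk_from <- function(u) {
    path <- u
    assign(u, TRUE, envir = visited)
    repeat {
      s <- succs(u)
      if (length(s) != 1L) break
      v <- s[1]
      if (indeg[[v]] != 1L) break
      if (exists(v, envir = visited, inherits = FALSE)) break
      path <- c(path, v)
      assign(v, TRUE, envir = visited)
      u <- v
    }
    path
  }
  for (u in nodes[is_start]) {
    if (exists(u, envir = visited, inherits = FALSE)) next
    path <- walk_from(u)
    seq <- paste0(path[1],
                  paste(substr(path[-1], k, k), collapse = ""))
    unitigs <- c(unitigs, seq)
    deg_info[[length(deg_info) + 1L]] <- c(
      indeg_start = indeg[[path[1]]],
      outdeg_end = outdeg[[path[length(path)]]])
  }
  # isolated cycles: sweep remaining nodes deterministically
  remaining <- nodes[!vapply(nodes, exists, logical(1), envir = visited,
                             inherits = FALSE)]
  while (length(remaining) > 0L) {
    u <- min(remaining)
    path <- walk_from(u)
    seq <- paste0(path[1], paste(substr(path[-1], k, k), collapse = ""))
    unitigs <- c(unitigs, seq)
    deg_info[[length(deg_info) + 1L]] <- c(indeg_start = 1L, outdeg_end = 1L)
    remaining <- remaining[!vapply(remaining, exists, logical(1),
                                   envir = visited, inherits = FALSE)]
  }
  list(unitigs = unitigs, deg = deg_info)
}

# indices of tip unitigs: short, dangling on one end, attached on the other
find_tips <- function(res, tip_len, k) {
  if (length(res$unitigs) == 0L) return(integer(0))
  lens <- nchar(res$unitigs)
  dangling_start <- vapply(res$deg, function(d) d["indeg_start"] == 0L,
                           logical(1))
  dangling_end <- vapply(res$deg, function(d) d["outdeg_end"] == 0L,
                         logical(1))
  which(lens < tip_len & xor(dangling_start, dangling_end))
}
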