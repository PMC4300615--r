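# Independent oracles, written as literal per-read loops over the tiered
# criteria and brute-force enumeration, deliberately unoptimised.

oracle_annotate <- function(records, config) {
  n <- nrow(records)
  grp_key <- paste0(records$read_id, "/", records$end)
  chimeric <- logical(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || grp_key[i] != grp_key[j]) next
      if (records$chrom[i] != records$chrom[j] ||
          records$strand[i] != records$strand[j] ||
          abs(records$start[i] - records$start[j]) > config$max_intron)
        chimeric[i] <- TRUE
    }
  }
  clip_len <- pmax(records$clip_left, records$clip_right)
  discordant <- logical(n)
  for (i in seq_len(n)) {
    if (!isTRUE(records$paired[i]) || isTRUE(records$mate_unmapped[i]) ||
        is.na(records$mate_chrom[i])) next
    discordant[i] <- records$mate_chrom[i] != records$chrom[i] ||
      records$mate_strand[i] == records$strand[i] ||
      abs(records$start[i] - records$mate_pos[i]) > config$max_intron
  }
  anchor <- integer(n)
  for (i in seq_len(n)) {
    if (clip_len[i] > 0L)
      anchor[i] <- if (records$clip_right[i] >= records$clip_left[i])
        records$stop[i] else records$start[i]
    else
      anchor[i] <- if (records$strand[i] == "+") records$stop[i]
        else records$start[i]
  }
  list(chimeric = chimeric, clip_len = clip_len, discordant = discordant,
       anchor = anchor)
}

# literal criterion-by-criterion re-implementation of the breakpoint scan;
# returns data.frame(chrom, pos, tier)
oracle_call_breakpoints <- function(records, config) {
  an <- oracle_annotate(records, config)
  n <- nrow(records)
  out <- list()
  called <- character(0)
  consistent_neighbors <- function(i) {
    ids <- character(0)
    for (j in seq_len(n)) {
      if (j == i || records$read_id[j] == records$read_id[i]) next
      if (!an$discordant[j]) next
      if (records$chrom[j] != records$chrom[i]) next
      if (records$strand[j] != records$strand[i]) next
      if (is.na(records$mate_chrom[j]) || is.na(records$mate_chrom[i])) next
      if (records$mate_chrom[j] != records$mate_chrom[i]) next
      if (records$mate_strand[j] != records$mate_strand[i]) next
      if (abs(an$anchor[j] - an$anchor[i]) > config$neighbor_window) next
      ids <- c(ids, records$read_id[j])
    }
    unique(ids)
  }
  # criterion (1): chimeric
  for (i in seq_len(n)) {
    if (!an$chimeric[i] || records$supplementary[i] || an$clip_len[i] == 0L)
      next
    if (records$read_id[i] %in% called) next
    pos <- if (records$clip_right[i] >= records$clip_left[i])
      records$stop[i] else records$start[i]
    out[[length(out) + 1L]] <- c(records$chrom[i], pos, 1L)
    called <- c(called, records$read_id[i])
  }
  # criteria (2)/(3): partial with discordant mate
  for (i in seq_len(n)) {
    if (an$chimeric[i] || an$clip_len[i] == 0L || !an$discordant[i]) next
    if (records$read_id[i] %in% called) next
    lmin <- min(max(records$read_len[i] / 5, config$kmer), 1.5 * config$kmer)
    has_n <- isTRUE(records$clip_has_n[i])
    long <- an$clip_len[i] >= lmin && !has_n
    nb <- length(consistent_neighbors(i))
    tier <- NA
    if (long && nb >= config$t1) tier <- 2L
    if (!long && nb >= config$t2) tier <- 3L
    if (is.na(tier)) next
    out[[length(out) + 1L]] <- c(records$chrom[i], an$anchor[i], tier)
    called <- c(called, records$read_id[i])
  }
  # criterion (4): groups of entirely aligned discordant pairs
  fa <- which(an$clip_len == 0L & !records$supplementary & an$discordant &
                !(records$read_id %in% called))
  if (length(fa) > 0L) {
    key <- paste(records$chrom[fa], records$strand[fa],
                 records$mate_chrom[fa], records$mate_strand[fa])
    for (k in unique(key)) {
      idx <- fa[key == k]
      idx <- idx[order(an$anchor[idx])]
      cluster <- list(idx[1])
      for (i in idx[-1]) {
        last <- cluster[[length(cluster)]]
        if (an$anchor[i] - an$anchor[last[length(last)]] <=
            config$neighbor_window)
          cluster[[length(cluster)]] <- c(last, i)
        else cluster[[length(cluster) + 1L]] <- i
      }
      for (cl in cluster) {
        if (length(unique(records$read_id[cl])) < config$t3) next
        pos <- if (records$strand[cl[1]] == "+") max(records$stop[cl])
          else min(records$start[cl])
        out[[length(out) + 1L]] <- c(records$chrom[cl[1]], pos, 4L)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      tier = integer(0), stringsAsFactors = FALSE))
  df <- data.frame(chrom = vapply(out, `[`, "", 1),
                   pos = as.integer(vapply(out, `[`, "", 2)),
                   tier = as.integer(vapply(out, `[`, "", 3)),
                   stringsAsFactors = FALSE)
  df[order(df$chrom, df$pos, df$tier), , drop = FALSE]
}

# random alignment-record sets exercising every criterion
gen_random_records <- function(seed, n_max = 50L) {
  set.seed(seed)
  recs <- list()
  rid <- 0L
  new_id <- function() { rid <<- rid + 1L; sprintf("r%03d", rid) }
  n_target <- sample(5:n_max, 1L)
  while (sum(vapply(recs, nrow, 0L)) < n_target) {
    kind <- sample(c("conc", "disc", "partial", "chim", "cluster"), 1L,
                   prob = c(0.2, 0.25, 0.25, 0.1, 0.2))
    id <- new_id()
    ch <- sample(c("chr1", "chr2"), 1L)
    pos <- sample.int(9000L, 1L)
    mch <- sample(c("chr1", "chr2"), 1L)
    mpos <- sample.int(9000L, 1L)
    if (kind == "conc") {
      recs[[length(recs) + 1L]] <- rec(id, ch, pos, pos + 100L, "+",
                                       mate_chrom = ch, mate_pos = pos + 200L,
                                       mate_strand = "-")
    } else if (kind == "disc") {
      recs[[length(recs) + 1L]] <- rec(id, ch, pos, pos + 100L,
                                       sample(c("+", "-"), 1L),
                                       mate_chrom = mch, mate_pos = mpos,
                                       mate_strand = sample(c("+", "-"), 1L))
    } else if (kind == "partial") {
      cl <- sample(c(5L, 10L, 20L, 30L, 40L), 1L)
      side <- sample(c("L", "R"), 1L)
      recs[[length(recs) + 1L]] <- rec(
        id, ch, pos, pos + 100L - cl, sample(c("+", "-"), 1L),
        clip_left = if (side == "L") cl else 0L,
        clip_right = if (side == "R") cl else 0L,
        mate_chrom = mch, mate_pos = mpos,
        mate_strand = sample(c("+", "-"), 1L))
    } else if (kind == "chim") {
      recs[[length(recs) + 1L]] <- rbind(
        rec(id, ch, pos, pos + 60L, "+", clip_right = 40L,
            mate_chrom = mch, mate_pos = mpos, mate_strand = "+"),
        rec(id, mch, mpos, mpos + 40L, "+", clip_left = 60L,
            supplementary = TRUE, mate_chrom = mch, mate_pos = mpos,
            mate_strand = "+"))
    } else {
      # a cluster of discordant pairs sharing a partner locus
      sz <- sample(2:6, 1L)
      for (q in seq_len(sz)) {
        jitter <- sample.int(150L, 1L)
        recs[[length(recs) + 1L]] <- rec(
          new_id(), ch, pos + jitter, pos + jitter + 100L, "+",
          mate_chrom = mch, mate_pos = mpos, mate_strand = "+")
      }
    }
  }
  df <- do.call(rbind, recs)
  df$clip_has_n <- FALSE
  df
}

# brute-force best and second-best chain over <= 8 segments
oracle_chain <- function(seg, max_overlap = 15L) {
  seg <- seg[order(seg$qstart, seg$qend), , drop = FALSE]
  n <- nrow(seg)
  best <- -Inf; second <- -Inf; best_set <- NULL
  for (mask in 1:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    ok <- TRUE; sc <- 0
    for (t in seq_along(idx)) {
      i <- idx[t]
      sc <- sc + seg$score[i]
      if (t > 1L) {
        j <- idx[t - 1L]
        ov <- seg$qend[j] - seg$qstart[i]
        if (ov > max_overlap || seg$qend[i] <= seg$qend[j] ||
            seg$qstart[i] <= seg$qstart[j]) { ok <- FALSE; break }
        sc <- sc - max(0L, ov)
      }
    }
    if (!ok) next
    if (sc > best) { second <- best; best <- sc; best_set <- idx }
    else if (sc > second) second <- sc
  }
  list(q1 = best, q2 = if (is.finite(second)) second else NA_real_)
}
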