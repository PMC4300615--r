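#' Configuration for the relaxed breakpoint scan
#'
#' Defaults follow the published method: a tier-2 call needs at least `t1 = 2`
#' other consistent discordant alignments, tier 3 needs `t2 = 3`, a tier-4
#' pairs-only call needs a group of `t3 = 4`; `kmer` is the mapper seed size
#' (at most 16); calls are grouped within `group_distance = 200` bp and each
#' group seeds a candidate region of `region_halfwidth = 250` bp on each side.
#'
#' @param t1,t2,t3 evidence thresholds for criteria (2), (3) and (4).
#' @param kmer mapper seed size in nt (<= 16); bounds the minimum unmapped
#'   part of a tier-2 partial alignment via
#'   `L_min = clamp(read_len / 5, kmer, 1.5 * kmer)`.
#' @param max_intron maximum allowed intron length in nt; longer mate or
#'   segment separations are discordant/chimeric.
#' @param neighbor_window window (bp) around a read within which supporting
#'   discordant alignments are counted as consistent.
#' @param group_distance single-linkage distance (bp) for grouping calls.
#' @param region_halfwidth half-width (bp) of each candidate region.
#' @return list of class `scan_config`.
#' @export
scan_config <- function(t1 = 2L, t2 = 3L, t3 = 4L, kmer = 15L,
                        max_intron = 200000L, neighbor_window = 200L,
                        group_distance = 200L, region_halfwidth = 250L) {
  stopifnot(t1 >= 1, t2 >= 1, t3 >= 1, kmer >= 1, kmer <= 16,
            max_intron > 0, neighbor_window > 0, group_distance > 0,
            region_halfwidth > 0)
  structure(list(t1 = as.integer(t1), t2 = as.integer(t2), t3 = as.integer(t3),
                 kmer = as.integer(kmer), max_intron = as.integer(max_intron),
                 neighbor_window = as.integer(neighbor_window),
                 group_distance = as.integer(group_distance),
                 region_halfwidth = as.integer(region_halfwidth)),
            class = "scan_config")
}

# Per-record derived flags used throughout the scan.  Returns the records
# data.frame with columns: chimeric, partial, discordant, fully_aligned,
# clip_len, anchor (0-based breakpoint-side position), anchor_side
# ("left-anchored": known sequence left of anchor).
annotate_records <- function(records, config) {
  df <- records
  n <- nrow(df)
  if (n == 0L) {
    for (cl in c("chimeric", "partial", "discordant", "fully_aligned"))
      df[[cl]] <- logical(0)
    df$clip_len <- integer(0); df$anchor <- integer(0)
    df$anchor_side <- character(0)
    return(df)
  }
  # chimeric: >= 2 segments of one read end spanning chrom/strand or a
  # distance beyond the maximum intron
  df$chimeric <- FALSE
  grp <- split(seq_len(n), df$group)
  for (ii in grp) {
    if (length(ii) < 2L) next
    ch <- df$chrom[ii]; st <- df$strand[ii]; ps <- df$start[ii]
    if (length(unique(ch)) > 1L || length(unique(st)) > 1L ||
        (max(ps) - min(ps)) > config$max_intron)
      df$chimeric[ii] <- TRUE
  }
  df$clip_len <- pmax(df$clip_left, df$clip_right)
  df$partial <- !df$chimeric & df$clip_len > 0L
  df$discordant <- df$paired & !df$mate_unmapped & !is.na(df$mate_chrom) &
    (df$mate_chrom != df$chrom | df$mate_strand == df$strand |
       abs(df$start - df$mate_pos) > config$max_intron)
  df$fully_aligned <- df$clip_left + df$clip_right == 0L & !df$supplementary
  # anchor: clipped boundary for clipped records, 3'-most end otherwise
  clipped <- df$clip_len > 0L
  right_clip_bigger <- df$clip_right >= df$clip_left
  df$anchor <- ifelse(clipped,
                      ifelse(right_clip_bigger, df$stop, df$start),
                      ifelse(df$strand == "+", df$stop, df$start))
  df$anchor_side <- ifelse(clipped,
                           ifelse(right_clip_bigger, "left-anchored",
                                  "right-anchored"),
                           ifelse(df$strand == "+", "left-anchored",
                                  "right-anchored"))
  df
}

#' Classify one read pair
#'
#' @param records data.frame of all alignment records for one fragment (one
#'   read id).
#' @param config `scan_config`.
#' @return one of "chimeric", "partial", "unmapped-mate", "discordant",
#'   "concordant".
#' @export
classify_pair <- function(records, config = scan_config()) {
  stopifnot(length(unique(records$read_id)) == 1L)
  if (length(unique(records$end)) > 2L || !all(records$end %in% 1:2))
    stop("fragment with more than two read ends: corrupt input")
  df <- annotate_records(aln_store(records)$records, config)
  if (any(df$chimeric)) return("chimeric")
  if (any(df$partial)) return("partial")
  if (any(df$mate_unmapped)) return("unmapped-mate")
  if (any(df$discordant)) return("discordant")
  "concordant"
}

# minimum unmapped part for a tier-2 partial: clamp(l/5, kmer, 1.5*kmer)
l_min <- function(read_len, kmer) clamp(read_len / 5, kmer, 1.5 * kmer)

#' Call potential breakpoints from classified alignments
#'
#' Emits one call per read satisfying the strongest of the tiered criteria:
#' tier 1, the read has a chimeric (split) alignment, called at the split
#' point; tier 2, the read is partially aligned with a discordant mate, its
#' unmapped part is at least `L_min = clamp(l/5, kmer, 1.5 kmer)` nt with no
#' undecided nucleotides, and at least `t1` other consistent discordant
#' alignments lie within the neighbor window; tier 3, as tier 2 but with a
#' shorter unmapped part and at least `t2` consistent neighbors; tier 4, a
#' group of at least `t3` entirely aligned discordant pairs consistent with
#' one fusion point, called where the reads' 3' ends extend farthest.
#' "Consistent" means: same chromosome and strand on the anchored side, same
#' mate chromosome and strand on the partner side, anchors within the
#' neighbor window.
#'
#' @param store `aln_store` or a records data.frame.
#' @param config `scan_config`.
#' @return data.frame of calls: chrom, pos (0-based), orientation, tier,
#'   partner_chrom, partner_pos, partner_strand, n_support and a list column
#'   `support_ids`.
#' @export
call_breakpoints <- function(store, config = scan_config()) {
  records <- if (inherits(store, "aln_store")) store$records else store
  df <- annotate_records(records, config)
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      orientation = character(0), tier = integer(0),
                      partner_chrom = character(0), partner_pos = integer(0),
                      partner_strand = character(0), n_support = integer(0),
                      stringsAsFactors = FALSE)
  empty$support_ids <- list()
  if (nrow(df) == 0L) return(empty)

  calls <- list()
  add_call <- function(chrom, pos, side, tier, pchrom, ppos, pstrand, ids) {
    calls[[length(calls) + 1L]] <<- list(
      chrom = chrom, pos = as.integer(pos), orientation = side,
      tier = as.integer(tier), partner_chrom = pchrom,
      partner_pos = as.integer(ppos), partner_strand = pstrand,
      n_support = length(unique(ids)), support_ids = unique(ids))
  }

  disc <- df[df$discordant, , drop = FALSE]

  # tiers 1-3: one call per qualifying read
  called_reads <- character(0)
  chim_primary <- df[df$chimeric & !df$supplementary & df$clip_len > 0L, ,
                     drop = FALSE]
  for (i in seq_len(nrow(chim_primary))) {
    r <- chim_primary[i, ]
    if (r$read_id %in% called_reads) next
    sibs <- df[df$group == r$group & df$supplementary, , drop = FALSE]
    if (nrow(sibs) == 0L)
      sibs <- df[df$group == r$group &
                   !(df$chrom == r$chrom & df$start == r$start), , drop = FALSE]
    if (nrow(sibs) > 0L) {
      pch <- sibs$chrom[1]; pps <- sibs$start[1]; pst <- sibs$strand[1]
    } else {
      pch <- NA_character_; pps <- NA_integer_; pst <- NA_character_
    }
    pos <- if (r$clip_right >= r$clip_left) r$stop else r$start
    side <- if (r$clip_right >= r$clip_left) "left-anchored" else "right-anchored"
    add_call(r$chrom, pos, side, 1L, pch, pps, pst, r$read_id)
    called_reads <- c(called_reads, r$read_id)
  }

  part <- df[df$partial & df$discordant, , drop = FALSE]
  for (i in seq_len(nrow(part))) {
    r <- part[i, ]
    if (r$read_id %in% called_reads) next
    lmin <- l_min(r$read_len, config$kmer)
    long <- r$clip_len >= lmin && !r$clip_has_n
    nb <- disc[disc$read_id != r$read_id &
                 disc$chrom == r$chrom & disc$strand == r$strand &
                 !is.na(disc$mate_chrom) &
                 disc$mate_chrom == r$mate_chrom &
                 disc$mate_strand == r$mate_strand &
                 abs(disc$anchor - r$anchor) <= config$neighbor_window, ,
               drop = FALSE]
    n_nb <- length(unique(nb$read_id))
    tier <- if (long && n_nb >= config$t1) 2L
            else if (!long && n_nb >= config$t2) 3L
            else NA_integer_
    if (is.na(tier)) next
    add_call(r$chrom, r$anchor, r$anchor_side, tier,
             r$mate_chrom, r$mate_pos, r$mate_strand,
             c(r$read_id, unique(nb$read_id)))
    called_reads <- c(called_reads, r$read_id)
  }

  # tier 4: groups of entirely aligned discordant pairs
  fa <- df[df$fully_aligned & df$discordant &
             !(df$read_id %in% called_reads), , drop = FALSE]
  if (nrow(fa) > 0L) {
    key <- paste(fa$chrom, fa$strand, fa$mate_chrom, fa$mate_strand, sep = "\r")
    for (k in unique(key)) {
      sub <- fa[key == k, , drop = FALSE]
      sub <- sub[order(sub$anchor), , drop = FALSE]
      brk <- c(0L, which(diff(sub$anchor) > config$neighbor_window),
               nrow(sub))
      for (j in seq_len(length(brk) - 1L)) {
        cl <- sub[(brk[j] + 1L):brk[j + 1L], , drop = FALSE]
        if (length(unique(cl$read_id)) < config$t3) next
        plus <- cl$strand[1] == "+"
        pos <- if (plus) max(cl$stop) else min(cl$start)
        side <- if (plus) "left-anchored" else "right-anchored"
        add_call(cl$chrom[1], pos, side, 4L, cl$mate_chrom[1],
                 cl$mate_pos[which.max(if (plus) cl$stop else -cl$start)],
                 cl$mate_strand[1], unique(cl$read_id))
      }
    }
  }

  if (length(calls) == 0L) return(empty)
  out <- data.frame(
    chrom = vapply(calls, `[[`, "", "chrom"),
    pos = vapply(calls, `[[`, 0L, "pos"),
    orientation = vapply(calls, `[[`, "", "orientation"),
    tier = vapply(calls, `[[`, 0L, "tier"),
    partner_chrom = vapply(calls, `[[`, "", "partner_chrom"),
    partner_pos = vapply(calls, `[[`, 0L, "partner_pos"),
    partner_strand = vapply(calls, `[[`, "", "partner_strand"),
    n_support = vapply(calls, `[[`, 0L, "n_support"),
    stringsAsFactors = FALSE)
  out$support_ids <- lapply(calls, `[[`, "support_ids")
  out[order(out$chrom, out$pos, out$tier), , drop = FALSE]
}

#' Group breakpoint calls
#'
#' Calls falling in the repeat annotation are removed first; the remaining
#' calls are single-linkage clustered per chromosome with link distance
#' `group_distance`.  The group representative is the call with the lowest
#' tier number, ties broken by larger support then smaller position.
#'
#' @param calls data.frame from [call_breakpoints()].
#' @param repeat_set optional `interval_set` of repetitive regions.
#' @param config `scan_config`.
#' @return data.frame of groups: chrom, pos (representative), tier,
#'   orientation, partner fields, n_support (union over members), n_calls,
#'   and list column `member_pos`.
#' @export
merge_calls <- function(calls, repeat_set = NULL, config = scan_config()) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      orientation = character(0), tier = integer(0),
                      partner_chrom = character(0), partner_pos = integer(0),
                      partner_strand = character(0), n_support = integer(0),
                      n_calls = integer(0), stringsAsFactors = FALSE)
  empty$member_pos <- list()
  if (nrow(calls) == 0L) return(empty)
  keep <- !interval_query(repeat_set, calls$chrom, calls$pos)
  calls <- calls[keep, , drop = FALSE]
  if (nrow(calls) == 0L) return(empty)
  groups <- list()
  for (ch in unique(calls$chrom)) {
    sub <- calls[calls$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    brk <- c(0L, which(diff(sub$pos) > config$group_distance), nrow(sub))
    for (j in seq_len(length(brk) - 1L)) {
      cl <- sub[(brk[j] + 1L):brk[j + 1L], , drop = FALSE]
      o <- order(cl$tier, -cl$n_support, cl$pos)
      rep_call <- cl[o[1], , drop = FALSE]
      ids <- unique(unlist(cl$support_ids))
      groups[[length(groups) + 1L]] <- data.frame(
        chrom = rep_call$chrom, pos = rep_call$pos,
        orientation = rep_call$orientation, tier = rep_call$tier,
        partner_chrom = rep_call$partner_chrom,
        partner_pos = rep_call$partner_pos,
        partner_strand = rep_call$partner_strand,
        n_support = length(ids), n_calls = nrow(cl),
        stringsAsFactors = FALSE)
      groups[[length(groups)]]$member_pos <- list(cl$pos)
    }
  }
  out <- do.call(rbind, groups)
  rownames(out) <- NULL
  out
}

#' Candidate regions around grouped breakpoint calls
#'
#' One region per group: the representative position extended by
#' `region_halfwidth` on each side, clipped at the chromosome bounds (never
#' discarded).  Overlapping regions are kept separate.
#'
#' @param groups data.frame from [merge_calls()].
#' @param genome_lengths named integer vector of chromosome lengths (nt).
#' @param config `scan_config`.
#' @return data.frame: region_id, chrom, start, end (0-based half-open),
#'   plus the representative call fields.
#' @export
candidate_regions <- function(groups, genome_lengths, config = scan_config()) {
  if (nrow(groups) == 0L)
    return(data.frame(region_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      pos = integer(0), tier = integer(0),
                      stringsAsFactors = FALSE))
  len <- genome_lengths[groups$chrom]
  if (anyNA(len)) stop("group on chromosome absent from genome_lengths")
  data.frame(region_id = seq_len(nrow(groups)),
             chrom = groups$chrom,
             start = pmax(0L, groups$pos - config$region_halfwidth),
             end = as.integer(pmin(len, groups$pos + config$region_halfwidth)),
             pos = groups$pos, tier = groups$tier,
             stringsAsFactors = FALSE)
}
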