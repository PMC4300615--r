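#' Load a gene model from GTF or BED12
#'
#' Builds an interval-indexed gene model used for assigning contig segments
#' to genes and for reading-frame classification.  For GTF input, `exon` and
#' `CDS` features are used (gene spans are derived from the exons when no
#' `gene` features are present).  For BED12 input each line is one
#' transcript: the name column is taken as both gene and transcript id (a
#' trailing `.tN` suffix, if present, separates transcript from gene), the
#' blocks as exons and the thick interval as the CDS.
#'
#' @param path GTF (.gtf/.gff) or BED12 (.bed) file.
#' @return object of class `gene_model` with GRanges components `genes`,
#'   `exons`, `cds` (1-based, as GRanges convention).
#' @export
load_gene_model <- function(path) {
  if (!file.exists(path)) stop("gene model file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("bed", "bed12")) {
    gr <- rtracklayer::import(path, format = "bed")
    if (length(gr) == 0L) stop("gene model contains zero genes")
    tx_id <- as.character(gr$name)
    gene_id <- sub("\\.t[0-9]+$", "", tx_id)
    blocks <- gr$blocks
    exons_list <- lapply(seq_along(gr), function(i) {
      bl <- if (!is.null(blocks)) blocks[[i]] else IRanges::IRanges(1L, GenomicRanges::width(gr)[i])
      GenomicRanges::GRanges(
        GenomicRanges::seqnames(gr)[i],
        IRanges::shift(bl, GenomicRanges::start(gr)[i] - 1L),
        strand = GenomicRanges::strand(gr)[i],
        gene_id = gene_id[i], tx_id = tx_id[i])
    })
    exons <- do.call(c, exons_list)
    thick <- gr$thick
    cds_list <- lapply(seq_along(gr), function(i) {
      ex <- exons_list[[i]]
      if (is.null(thick)) return(GenomicRanges::GRanges())
      th <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr)[i], thick[i],
                                   strand = GenomicRanges::strand(gr)[i])
      if (GenomicRanges::width(th) <= 1L) return(GenomicRanges::GRanges())
      out <- suppressWarnings(GenomicRanges::pintersect(
        ex, rep(th, length(ex)), drop.nohit.ranges = FALSE))
      out <- out[GenomicRanges::width(out) > 0L & out$hit]
      out$hit <- NULL
      out
    })
    cds_list <- cds_list[vapply(cds_list, length, integer(1)) > 0L]
    cds <- if (length(cds_list)) do.call(c, cds_list) else
      GenomicRanges::GRanges(gene_id = character(0), tx_id = character(0))
  } else {
    gr <- rtracklayer::import(path)
    if (is.null(gr$type)) stop("GTF without feature types")
    exons <- gr[gr$type == "exon"]
    cds <- gr[gr$type == "CDS"]
    keep_cols <- function(g) {
      mc <- S4Vectors::mcols(g)
      S4Vectors::mcols(g) <- S4Vectors::DataFrame(
        gene_id = as.character(mc$gene_id),
        tx_id = as.character(mc$transcript_id))
      g
    }
    exons <- keep_cols(exons)
    cds <- keep_cols(cds)
    # CDS whose transcript has no exon rows: warn, synthesize a transcript
    orphan <- !(cds$tx_id %in% exons$tx_id)
    if (any(orphan)) {
      warning(sum(orphan), " CDS feature(s) without parent transcript; ",
              "attached to synthetic transcript(s)")
      syn <- cds[orphan]
      exons <- c(exons, syn)
    }
  }
  if (length(exons) == 0L) stop("gene model contains zero genes")
  structure(list(genes = gene_spans(exons), exons = exons, cds = cds),
            class = "gene_model")
}

#' Construct a gene model directly from exon/CDS tables
#'
#' @param exons data.frame: gene_id, tx_id, chrom, start, end (0-based
#'   half-open), strand.
#' @param cds same layout, may be empty.
#' @return `gene_model`.
#' @export
gene_model <- function(exons, cds = NULL) {
  to_gr <- function(df) {
    if (is.null(df) || nrow(df) == 0L)
      return(GenomicRanges::GRanges(gene_id = character(0), tx_id = character(0)))
    GenomicRanges::GRanges(df$chrom,
                           IRanges::IRanges(df$start + 1L, df$end),
                           strand = df$strand,
                           gene_id = df$gene_id, tx_id = df$tx_id)
  }
  ex <- to_gr(exons)
  structure(list(genes = gene_spans(ex), exons = ex, cds = to_gr(cds)),
            class = "gene_model")
}

# per-gene span GRanges from an exon GRanges (one chrom/strand per gene)
gene_spans <- function(exons) {
  df <- data.frame(gene_id = exons$gene_id,
                   chrom = as.character(GenomicRanges::seqnames(exons)),
                   start = GenomicRanges::start(exons),
                   end = GenomicRanges::end(exons),
                   strand = as.character(GenomicRanges::strand(exons)),
                   stringsAsFactors = FALSE)
  agg <- do.call(rbind, lapply(split(df, df$gene_id), function(d)
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end), strand = d$strand[1],
               stringsAsFactors = FALSE)))
  agg <- agg[order(agg$chrom, agg$start), , drop = FALSE]
  suppressWarnings(GenomicRanges::GRanges(
    agg$chrom, IRanges::IRanges(agg$start, agg$end), strand = agg$strand,
    gene_id = agg$gene_id))
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", length(x$genes), "gene(s),",
      length(unique(x$exons$tx_id)), "transcript(s)\n")
  invisible(x)
}

#' Genes overlapping a genomic point
#'
#' @param model `gene_model`.
#' @param chrom chromosome name.
#' @param pos 0-based position.
#' @return data.frame of gene_id, strand (possibly 0 rows).
#' @export
query_genes <- function(model, chrom, pos) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, model$genes, ignore.strand = TRUE)
  g <- model$genes[S4Vectors::subjectHits(hits)]
  data.frame(gene_id = g$gene_id,
             strand = as.character(GenomicRanges::strand(g)),
             stringsAsFactors = FALSE)
}

# gene with the largest overlap with [start, end) (0-based); NA if none
gene_at_interval <- function(model, chrom, start, end) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, model$genes, ignore.strand = TRUE)
  if (length(hits) == 0L) return(list(gene_id = NA_character_, strand = NA_character_))
  g <- model$genes[S4Vectors::subjectHits(hits)]
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    rep(q, length(g)), g, ignore.strand = TRUE))
  i <- which.max(ov)
  list(gene_id = g$gene_id[i], strand = as.character(GenomicRanges::strand(g))[i])
}

# CDS blocks of the longest-CDS transcript of a gene, in transcript order.
# Returns NULL when the gene has no CDS.
longest_cds_tx <- function(model, gene_id) {
  cds <- model$cds[model$cds$gene_id == gene_id]
  if (length(cds) == 0L) return(NULL)
  totals <- tapply(GenomicRanges::width(cds), cds$tx_id, sum)
  tx <- names(totals)[which.max(totals)]
  blocks <- cds[cds$tx_id == tx]
  minus <- as.character(GenomicRanges::strand(blocks))[1] == "-"
  blocks[order(GenomicRanges::start(blocks), decreasing = minus)]
}

# Number of coding bases of gene's longest-CDS transcript located at or
# before (inclusive = TRUE) / strictly before (inclusive = FALSE) the 0-based
# genomic position pos, counting in transcript direction.  NA when pos is not
# inside the CDS.
cds_offset <- function(model, gene_id, pos, inclusive) {
  blocks <- longest_cds_tx(model, gene_id)
  if (is.null(blocks)) return(NA_real_)
  pos1 <- pos + 1L                                    # 1-based
  st <- GenomicRanges::start(blocks); en <- GenomicRanges::end(blocks)
  minus <- as.character(GenomicRanges::strand(blocks))[1] == "-"
  inside <- any(pos1 >= st & pos1 <= en)
  if (!inside) return(NA_real_)
  off <- 0
  for (i in seq_along(blocks)) {
    if (!minus) {
      if (pos1 > en[i]) { off <- off + (en[i] - st[i] + 1L); next }
      if (pos1 >= st[i]) {
        off <- off + (pos1 - st[i]) + if (inclusive) 1L else 0L
        return(off)
      }
      return(off)
    } else {
      if (pos1 < st[i]) { off <- off + (en[i] - st[i] + 1L); next }
      if (pos1 <= en[i]) {
        off <- off + (en[i] - pos1) + if (inclusive) 1L else 0L
        return(off)
      }
      return(off)
    }
  }
  off
}
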