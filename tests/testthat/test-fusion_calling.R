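# a synthetic junction contig: 200 nt with the fusion point at offset 100
fc_contig <- local({
  set.seed(321L)
  random_dna(200L)
})
fc_junction <- data.frame(contig = fc_contig, contig_break = 100L,
                          stringsAsFactors = FALSE)
# a read crossing the break with j nt on the left side
cross_read <- function(j, rl = 100L)
  substr(fc_contig, 100L - j + 1L, 100L - j + rl)

test_that("spanning support needs at least 13 aligned nt on both sides", {
  right_mate <- revcomp(substr(fc_contig, 101L, 200L))
  for (j in c(12L, 13L, 14L, 87L, 88L)) {
    pairs <- data.frame(read_id = "p", seq1 = cross_read(j),
                        seq2 = right_mate, stringsAsFactors = FALSE)
    sup <- collect_support(fc_junction, pairs)
    expect_equal(sup$n_span, if (j >= 13L && 100L - j >= 13L) 1L else 0L,
                 label = paste("left overhang", j))
  }
  # the 13|87 boundary read records its mapping distances
  sup <- collect_support(fc_junction, data.frame(
    read_id = "b", seq1 = cross_read(13L), seq2 = right_mate,
    stringsAsFactors = FALSE))
  expect_equal(sup$evidence$L, 13L)
  expect_equal(sup$evidence$R, 87L)
})

test_that("a 12 nt overhang read still supports the junction through its mate", {
  pairs <- data.frame(
    read_id = "p", seq1 = cross_read(12L),
    seq2 = revcomp(substr(fc_contig, 30L, 95L)), stringsAsFactors = FALSE)
  sup <- collect_support(fc_junction, pairs)
  expect_equal(sup$n_span, 0L)
  expect_equal(sup$encompassing, 1L)
})

test_that("PCR duplicates collapse in non-redundant support counting", {
  mate <- revcomp(substr(fc_contig, 120L, 190L))
  dup <- data.frame(read_id = c("a", "b", "c"),
                    seq1 = c(cross_read(50L), cross_read(50L),
                             cross_read(40L)),
                    seq2 = mate, stringsAsFactors = FALSE)
  sup <- collect_support(fc_junction, dup)
  expect_equal(sup$n_span, 2L)          # the identical pair counts once
  enc <- data.frame(read_id = c("d", "e"),
                    seq1 = substr(fc_contig, 11L, 90L),
                    seq2 = revcomp(substr(fc_contig, 111L, 190L)),
                    stringsAsFactors = FALSE)
  sup2 <- collect_support(fc_junction, enc)
  expect_equal(sup2$encompassing, 1L)
})

test_that("reads with errors still align and count via local alignment", {
  r <- cross_read(45L)
  substr(r, 20L, 20L) <- setdiff(c("A", "C", "G", "T"), substr(r, 20, 20))[1]
  sup <- collect_support(fc_junction, data.frame(
    read_id = "e", seq1 = r, seq2 = revcomp(substr(fc_contig, 130L, 200L)),
    stringsAsFactors = FALSE))
  expect_equal(sup$n_span, 1L)
})

test_that("the Spanning Score matches its closed form", {
  ev <- data.frame(L = c(50, 30, 10), R = c(50, 70, 90))
  expect_equal(spanning_score(ev), 1.8, tolerance = 1e-12)
  expect_equal(spanning_score(data.frame(L = 50, R = 50)), 1.0)
  expect_equal(spanning_score(data.frame(L = numeric(0), R = numeric(0))), 0)
  # 0 <= SS <= N, with equality iff perfectly balanced
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(1:20, 1)
    ev <- data.frame(L = sample(13:87, n, TRUE))
    ev$R <- 100 - ev$L
    ss <- spanning_score(ev)
    expect_true(ss >= 0 && ss <= n)
    if (all(ev$L == ev$R)) expect_equal(ss, n)
  }
})

test_that("the report gate requires two supporting reads of any kind", {
  expect_true(report_gate(1L, 1L))
  expect_false(report_gate(1L, 0L))
  expect_true(report_gate(0L, 5L))
  expect_true(report_gate(2L, 0L))
})

test_that("ranking applies SS, then encompassing count, then Q, in order", {
  cand <- data.frame(
    gene5 = c("a", "b", "c", "d"), gene3 = "x",
    SS = c(2.0, 1.5, 1.5, 1.5), encompassing = c(0L, 100L, 5L, 5L),
    Q = c(0.1, 0.2, 0.4, 0.9), stringsAsFactors = FALSE)
  ranked <- rank_candidates(cand)
  expect_equal(ranked$gene5, c("a", "b", "d", "c"))
  expect_equal(ranked$rank, 1:4)
})

test_that("the final filter removes low support, low SS, or doubly flagged calls", {
  mk <- function(total, SS, flags = "") data.frame(
    gene5 = "a", gene3 = "b", total = total, SS = SS, flags = flags,
    stringsAsFactors = FALSE)
  expect_equal(nrow(final_filter(mk(4L, 2.0))), 0L)
  expect_equal(nrow(final_filter(mk(5L, 1.0))), 1L)
  expect_equal(nrow(final_filter(mk(10L, 0.99))), 0L)
  # both breakpoints in annotated regions: removed even with strong support
  expect_equal(nrow(final_filter(mk(20L, 3.0, "repeat5,selfchain3"))), 0L)
  # one side flagged only: kept
  expect_equal(nrow(final_filter(mk(20L, 3.0, "repeat5"))), 1L)
  expect_equal(nrow(final_filter(mk(20L, 3.0, "repeat5,low_Q"))), 1L)
  # filtering is idempotent and never grows the list
  cand <- do.call(rbind, lapply(1:8, function(k) mk(k, 2.0)))
  f1 <- final_filter(cand)
  expect_true(nrow(f1) <= nrow(cand))
  expect_equal(final_filter(f1), f1)
})

test_that("isoform junctions of one gene fusion merge; swapped orientation stays separate", {
  cand <- data.frame(
    gene5 = c("EML4like", "EML4like", "ALKlike", "solo"),
    gene3 = c("ALKlike", "ALKlike", "EML4like", "other"),
    chrom5 = "chr2", pos5 = c(1000L, 2000L, 3000L, 4000L),
    chrom3 = "chr2", pos3 = c(9000L, 9000L, 500L, 600L),
    SS = c(5, 3, 2, 1), encompassing = c(2L, 1L, 1L, 1L),
    Q = 0.9, stringsAsFactors = FALSE)
  merged <- merge_isoforms(rank_candidates(cand))
  expect_equal(nrow(merged), 3L)
  em <- merged[merged$gene5 == "EML4like", ]
  expect_equal(em$n_isoforms, 2L)
  expect_equal(em$pos5, 1000L)           # best-ranked junction represents
  expect_match(em$isoform_breakpoints, "chr2:1001.*chr2:2001")
  expect_equal(merged$n_isoforms[merged$gene5 == "solo"], 1L)
})

test_that("candidates classify by chromosome and CDS codon phase", {
  # gene U: CDS 100-400 (1-based); gene D on another chrom: CDS 2000-2600
  model <- gene_model(
    exons = data.frame(
      gene_id = c("U", "D"), tx_id = c("U.t1", "D.t1"),
      chrom = c("chr2", "chr5"), start = c(49L, 1899L),
      end = c(500L, 2700L), strand = "+"),
    cds = data.frame(
      gene_id = c("U", "D"), tx_id = c("U.t1", "D.t1"),
      chrom = c("chr2", "chr5"), start = c(99L, 1999L),
      end = c(399L, 2599L), strand = "+"))
  cand <- function(pos5, chrom3 = "chr5", pos3 = 2449L) data.frame(
    gene5 = "U", gene3 = "D", chrom5 = "chr2", pos5 = pos5,
    chrom3 = chrom3, pos3 = pos3, stringsAsFactors = FALSE)
  # offset5 = pos5 - 99 + 1 retained coding bases; offset3 = pos3 - 1999
  # removed; IF iff they agree mod 3.  pos5 = 398 -> offset5 = 300;
  # pos3 = 2449 -> offset3 = 450: both multiples of 3 -> IF
  cl <- classify_candidate(cand(398L), model)
  expect_equal(cl$type, "Inter")
  expect_equal(cl$frame, "IF")
  expect_equal(classify_candidate(cand(397L), model)$frame, "OF")
  expect_equal(classify_candidate(cand(399L), model)$frame, "NA")  # 3' UTR
  # intra-chromosomal type
  model2 <- gene_model(
    exons = data.frame(gene_id = c("U", "D"), tx_id = c("U.t1", "D.t1"),
                       chrom = "chr2", start = c(49L, 1899L),
                       end = c(500L, 2700L), strand = "+"))
  cl2 <- classify_candidate(
    data.frame(gene5 = "U", gene3 = "D", chrom5 = "chr2", pos5 = 200L,
               chrom3 = "chr2", pos3 = 2000L), model2)
  expect_equal(cl2$type, "Intra")
  expect_equal(cl2$frame, "NA")          # no CDS annotated
})

test_that("repeat rescue keeps doubly flagged fusions that have encompassing cover", {
  cand <- data.frame(gene5 = "a", gene3 = "b", total = 20L, SS = 3,
                     flags = "repeat5,repeat3", encompassing = 2L,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(final_filter(cand)), 0L)
  expect_equal(nrow(final_filter(cand, repeat_rescue = TRUE)), 1L)
  cand$encompassing <- 0L
  expect_equal(nrow(final_filter(cand, repeat_rescue = TRUE)), 0L)
})
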