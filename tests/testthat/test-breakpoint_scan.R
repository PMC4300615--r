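cfg <- scan_config()

test_that("pair classification distinguishes concordant, discordant, partial and chimeric", {
  conc <- rbind(
    rec("p1", "chr1", 1000L, 1100L, "+", end = 1L, mate_chrom = "chr1",
        mate_pos = 1300L, mate_strand = "-"),
    rec("p1", "chr1", 1300L, 1400L, "-", end = 2L, mate_chrom = "chr1",
        mate_pos = 1000L, mate_strand = "+"))
  expect_equal(classify_pair(conc, cfg), "concordant")
  disc <- conc
  disc$chrom[2] <- "chr7"; disc$mate_chrom[1] <- "chr7"
  expect_equal(classify_pair(disc, cfg), "discordant")
  # distance beyond the maximum intron is also discordant
  far <- conc
  far$start[2] <- 1000L + 300000L; far$stop[2] <- far$start[2] + 100L
  far$mate_pos[1] <- far$start[2]
  expect_equal(classify_pair(far, cfg), "discordant")
  chim <- rbind(
    rec("c1", "chr2", 5e6L, 5e6L + 50L, "+", clip_right = 50L,
        mate_chrom = "chr2", mate_pos = 5e6L, mate_strand = "-"),
    rec("c1", "chr2", 10e6L, 10e6L + 50L, "+", clip_left = 50L,
        supplementary = TRUE, mate_chrom = "chr2", mate_pos = 5e6L,
        mate_strand = "-"))
  expect_equal(classify_pair(chim, cfg), "chimeric")
  part <- rec("q1", "chr1", 100L, 160L, "+", clip_right = 40L,
              mate_chrom = "chr1", mate_pos = 300L, mate_strand = "-")
  expect_equal(classify_pair(part, cfg), "partial")
  bad <- conc; bad$end <- c(1L, 3L)
  expect_error(classify_pair(bad, cfg), "corrupt")
})

test_that("a single chimeric read yields one tier-1 call at the split coordinate", {
  recs <- rbind(
    rec("c1", "chr1", 2000L, 2060L, "+", clip_right = 40L,
        mate_chrom = "chr1", mate_pos = 2000L, mate_strand = "-"),
    rec("c1", "chr2", 7000L, 7040L, "+", clip_left = 60L,
        supplementary = TRUE, mate_chrom = "chr1", mate_pos = 2000L,
        mate_strand = "-"))
  calls <- call_breakpoints(aln_store(recs), cfg)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$tier, 1L)
  expect_equal(calls$pos, 2060L)
  expect_equal(calls$partner_chrom, "chr2")
})

test_that("criterion (2) requires the unmapped part >= L_min and t1 consistent neighbors", {
  # clip 20 >= L_min = clamp(100/5, 15, 22.5) = 20; t1 = 2
  calls <- call_breakpoints(aln_store(tier2_records(2L)), cfg)
  expect_equal(calls$tier[calls$pos == 1080L], 2L)
  # one neighbor only: no tier-2 call from x
  calls1 <- call_breakpoints(aln_store(tier2_records(1L)), cfg)
  expect_false(any(calls1$tier == 2L))
  # short clip falls through to criterion (3), needing t2 = 3 neighbors
  calls3 <- call_breakpoints(aln_store(tier2_records(3L, clip = 10L)), cfg)
  expect_equal(calls3$tier[calls3$pos == 1090L], 3L)
  calls2 <- call_breakpoints(aln_store(tier2_records(2L, clip = 10L)), cfg)
  expect_false(any(calls2$tier %in% c(2L, 3L)))
  # N bases in the clipped sequence disqualify criterion (2)
  withN <- tier2_records(2L)
  withN$clip_has_n <- c(TRUE, FALSE, FALSE)
  callsN <- call_breakpoints(aln_store(withN), cfg)
  expect_false(any(callsN$tier == 2L))
})

test_that("criterion (4) calls groups of >= t3 aligned discordant pairs at the farthest 3' end", {
  mk <- function(n) do.call(rbind, lapply(seq_len(n), function(i)
    rec(paste0("d", i), "chr3", 4000L + i * 20L, 4100L + i * 20L, "+",
        mate_chrom = "chr5", mate_pos = 9000L, mate_strand = "+")))
  calls4 <- call_breakpoints(aln_store(mk(4L)), cfg)
  expect_equal(nrow(calls4), 1L)
  expect_equal(calls4$tier, 4L)
  expect_equal(calls4$pos, 4100L + 4L * 20L)    # farthest 3' extension
  expect_equal(nrow(call_breakpoints(aln_store(mk(3L)), cfg)), 0L)
})

test_that("breakpoint-scan equals the naive criterion-by-criterion oracle", {
  for (seed in 1:25) {
    recs <- gen_random_records(seed)
    got <- call_breakpoints(aln_store(recs), cfg)
    want <- oracle_call_breakpoints(aln_store(recs)$records, cfg)
    expect_equal(got[, c("chrom", "pos", "tier")], want,
                 ignore_attr = TRUE, label = paste("seed", seed))
  }
})

test_that("raising thresholds never adds calls; lowering never removes them", {
  key <- function(calls) paste(calls$chrom, calls$pos, calls$tier)
  for (seed in 1:10) {
    recs <- gen_random_records(seed + 100L)
    base <- call_breakpoints(aln_store(recs), cfg)
    loose <- call_breakpoints(aln_store(recs),
                              scan_config(t1 = 1L, t2 = 1L, t3 = 2L))
    strict <- call_breakpoints(aln_store(recs),
                               scan_config(t1 = 4L, t2 = 6L, t3 = 8L))
    expect_true(all(paste(base$chrom, base$pos) %in%
                      paste(loose$chrom, loose$pos)))
    expect_true(all(paste(strict$chrom, strict$pos) %in%
                      paste(base$chrom, base$pos)))
  }
})

test_that("call grouping respects the 200 bp linkage distance and repeat masking", {
  two_calls <- function(d) {
    recs <- rbind(
      rec("c1", "chr1", 2000L, 2060L, "+", clip_right = 40L,
          mate_chrom = "chr1", mate_pos = 2000L, mate_strand = "-"),
      rec("c1", "chr2", 7000L, 7040L, "+", clip_left = 60L,
          supplementary = TRUE, mate_chrom = "chr1", mate_pos = 2000L,
          mate_strand = "-"),
      rec("c2", "chr1", 2060L + d - 60L, 2120L + d - 60L, "+",
          clip_right = 40L, mate_chrom = "chr1", mate_pos = 2000L,
          mate_strand = "-"),
      rec("c2", "chr2", 7100L, 7140L, "+", clip_left = 60L,
          supplementary = TRUE, mate_chrom = "chr1", mate_pos = 2000L,
          mate_strand = "-"))
    call_breakpoints(aln_store(recs), cfg)
  }
  expect_equal(nrow(merge_calls(two_calls(150L), NULL, cfg)), 1L)
  expect_equal(nrow(merge_calls(two_calls(200L), NULL, cfg)), 1L)
  expect_equal(nrow(merge_calls(two_calls(201L), NULL, cfg)), 2L)
  # a call inside a repeat interval is removed before grouping
  calls <- two_calls(150L)
  rep_set <- interval_set(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(2050L, 2070L)))   # covers pos 2060 (0-based)
  grouped <- merge_calls(calls, rep_set, cfg)
  expect_equal(nrow(grouped), 1L)
  expect_equal(grouped$n_calls, 1L)
})

test_that("the group representative carries the strongest evidence", {
  calls <- data.frame(
    chrom = "chr1", pos = c(1000L, 1100L), orientation = "left-anchored",
    tier = c(4L, 1L), partner_chrom = "chr2", partner_pos = 5L,
    partner_strand = "+", n_support = c(6L, 1L), stringsAsFactors = FALSE)
  calls$support_ids <- list(paste0("a", 1:6), "b")
  g <- merge_calls(calls, NULL, cfg)
  expect_equal(nrow(g), 1L)
  expect_equal(g$tier, 1L)
  expect_equal(g$pos, 1100L)
  expect_equal(g$n_support, 7L)
})

test_that("candidate regions are +/- 250 bp windows clipped at chromosome bounds", {
  groups <- data.frame(
    chrom = c("chr1", "chr1"), pos = c(10000L, 100L),
    orientation = "left-anchored", tier = 1L, partner_chrom = "chr2",
    partner_pos = 1L, partner_strand = "+", n_support = 1L, n_calls = 1L,
    stringsAsFactors = FALSE)
  regions <- candidate_regions(groups, c(chr1 = 1000000L), cfg)
  expect_equal(regions$start, c(9750L, 0L))
  expect_equal(regions$end, c(10250L, 350L))
  expect_true(all(regions$end - regions$start <= 500L))
  expect_true(all(regions$pos >= regions$start & regions$pos < regions$end))
  empty <- candidate_regions(groups[0, ], c(chr1 = 1000L), cfg)
  expect_equal(nrow(empty), 0L)
})
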