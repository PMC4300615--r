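# two-chromosome toy genome used throughout this file
jd_genome <- local({
  set.seed(77L)
  Biostrings::DNAStringSet(c(chrA = random_dna(6000L),
                             chrB = random_dna(6000L)))
})
jd_ref <- ref_genome(jd_genome)
chrA <- as.character(jd_genome[["chrA"]])
chrB <- as.character(jd_genome[["chrB"]])

test_that("a contig equal to a unique genome substring aligns as one full segment", {
  contig <- substr(chrA, 1001L, 1300L)
  segs <- realign_contig(contig, jd_ref)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$qstart, 0L)
  expect_equal(segs$qend, 300L)
  expect_equal(segs$chrom, "chrA")
  expect_equal(segs$gstart, 1000L)
  expect_equal(segs$gend, 1300L)
  expect_equal(segs$matches, 300L)
  expect_equal(segs$strand, "+")
  # and on the reverse strand
  segs_rc <- realign_contig(revcomp(contig), jd_ref)
  expect_equal(segs_rc$strand, "-")
  expect_equal(segs_rc$gstart, 1000L)
  expect_equal(segs_rc$gend, 1300L)
  # a contig shorter than the seed yields nothing
  expect_equal(nrow(realign_contig("ACGTACGTAC", jd_ref)), 0L)
})

test_that("a planted junction contig yields one segment per side", {
  contig <- paste0(substr(chrA, 2001L, 2150L), substr(chrB, 4001L, 4150L))
  segs <- realign_contig(contig, jd_ref)
  segs <- segs[order(segs$qstart), ]
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$chrom, c("chrA", "chrB"))
  expect_equal(segs$qstart[1], 0L)
  expect_equal(segs$qend[2], 300L)
  # both sides of the junction are covered on the correct diagonals
  # (ungapped extension may overshoot the split by a few random matches)
  expect_equal(segs$gstart - segs$qstart, c(2000L, 3850L))
  expect_true(segs$qend[1] >= 150L && segs$qstart[2] <= 150L)
})

test_that("segments from duplicated loci are removed as non-unique", {
  dup <- substr(chrA, 3001L, 3300L)
  genome2 <- Biostrings::DNAStringSet(c(
    chrA = chrA, chrB = chrB,
    chrC = paste0(substr(chrB, 1L, 500L), dup, substr(chrB, 801L, 1300L))))
  segs <- realign_contig(dup, ref_genome(genome2))
  expect_equal(nrow(segs), 0L)
})

test_that("the alignment score Q matches its closed form", {
  expect_equal(alignment_score_q(100, 95, 80), exp(-0.5) - exp(-2),
               tolerance = 1e-12)
  expect_equal(alignment_score_q(100, 100, NA), 1.0)
  expect_equal(alignment_score_q(100, 90, 90), 0.0)
})

test_that("Q increases in q1 and decreases in q2", {
  q0 <- 200
  for (q2 in c(NA, 50, 100, 150)) {
    qs <- vapply(seq(100, 200, by = 10),
                 function(q1) alignment_score_q(q0, q1, q2), 0)
    expect_true(all(diff(qs) > 0))
  }
  for (q1 in c(150, 200)) {
    qs <- vapply(seq(50, q1, by = 10),
                 function(q2) alignment_score_q(q0, q1, q2), 0)
    expect_true(all(diff(qs) < 0))
  }
})

test_that("chaining matches brute-force enumeration on small segment sets", {
  gen_segs <- function(seed) {
    set.seed(seed)
    n <- sample(2:8, 1L)
    qs <- sort(sample(0:180, n))
    qe <- qs + sample(20:80, n, replace = TRUE)
    data.frame(qstart = qs, qend = qe, chrom = "chrA",
               gstart = sample(0:5000, n), gend = 0L,
               strand = sample(c("+", "-"), n, replace = TRUE),
               matches = qe - qs,
               score = as.integer(round((qe - qs) * runif(n, 0.5, 1))),
               stringsAsFactors = FALSE)
  }
  for (seed in 1:40) {
    seg <- gen_segs(seed)
    got <- chain_paths(seg, contig_len = 300L)
    want <- oracle_chain(seg)
    expect_equal(got$q1, want$q1, label = paste("q1 seed", seed))
    expect_equal(got$q2, want$q2, label = paste("q2 seed", seed))
  }
})

test_that("a perfect single-segment chain gives q1 = q0 and Q = 1", {
  contig <- substr(chrA, 501L, 800L)
  segs <- realign_contig(contig, jd_ref)
  ch <- chain_paths(segs, nchar(contig))
  expect_equal(ch$q1, ch$q0)
  expect_null(ch$second_path)
  expect_equal(ch$Q, 1.0)
  # no segments: q1 absent
  ch0 <- chain_paths(segs[0, ], 300L)
  expect_true(is.na(ch0$q1))
})

# helper: junction candidate from a planted two-gene contig
jd_model <- gene_model(data.frame(
  gene_id = c("gA", "gB"), tx_id = c("gA.t1", "gB.t1"),
  chrom = c("chrA", "chrB"), start = c(1500L, 3500L),
  end = c(2800L, 4800L), strand = "+"))

test_that("a two-gene best path yields a junction with exact facing breakpoints", {
  contig <- paste0(substr(chrA, 2001L, 2150L), substr(chrB, 4001L, 4150L))
  segs <- realign_contig(contig, jd_ref)
  ch <- chain_paths(segs, nchar(contig))
  j <- detect_junction(ch, jd_model, jd_ref, contig)
  expect_false(is.null(j))
  expect_equal(j$gene5, "gA")
  expect_equal(j$gene3, "gB")
  # microhomology canonicalisation can shift the split a few bases 3'-wards,
  # moving both sides in register
  shift <- j$pos5 - 2149L
  expect_true(shift >= 0L && shift <= 5L)
  expect_equal(j$pos3 - 4000L, shift)
  expect_equal(j$contig_break - 150L, shift)
  # the reverse-complement contig reports the same junction
  segs_rc <- realign_contig(revcomp(contig), jd_ref)
  ch_rc <- chain_paths(segs_rc, nchar(contig))
  j_rc <- detect_junction(ch_rc, jd_model, jd_ref, revcomp(contig))
  expect_equal(j_rc$gene5, "gA")
  expect_equal(j_rc$pos5, j$pos5)
  expect_equal(j_rc$pos3, j$pos3)
})

test_that("a path inside a single gene is not a junction", {
  contig <- substr(chrA, 1601L, 2400L)     # read-through within gA
  segs <- realign_contig(contig, jd_ref)
  ch <- chain_paths(segs, nchar(contig))
  expect_null(detect_junction(ch, jd_model, jd_ref, contig))
})

test_that("breakpoints in annotated intervals set per-side flags", {
  contig <- paste0(substr(chrA, 2001L, 2150L), substr(chrB, 4001L, 4150L))
  segs <- realign_contig(contig, jd_ref)
  ch <- chain_paths(segs, nchar(contig))
  sc <- interval_set(GenomicRanges::GRanges(
    "chrA", IRanges::IRanges(2100L, 2200L)), "selfchain")
  rp <- interval_set(GenomicRanges::GRanges(
    "chrB", IRanges::IRanges(3950L, 4100L)), "repeat")
  j <- detect_junction(ch, jd_model, jd_ref, contig,
                       repeat_set = rp, selfchain_set = sc)
  fl <- strsplit(j$flags, ",")[[1]]
  expect_true("selfchain5" %in% fl)
  expect_true("repeat3" %in% fl)
  expect_false("repeat5" %in% fl)
})

test_that("junction microhomology is tolerated up to the overlap cap", {
  # build a genome where h bases are shared at the junction:
  # chrA carries X + M, chrB carries M + Y; contig = X + M + Y
  for (h in c(0L, 6L, 15L, 16L, 20L)) {
    set.seed(900L + h)
    # terminal bases chosen to break homology exactly at the planted run
    X <- paste0(random_dna(149L), "T"); Y <- paste0("G", random_dna(149L))
    M <- random_dna(h)
    # force distinct flanking bases so the homology run is exactly h
    gA2 <- paste0(random_dna(200L), X, M, "A", random_dna(199L))
    gB2 <- paste0(random_dna(199L), "C", M, Y, random_dna(200L))
    contig <- paste0(X, M, Y)
    g2 <- ref_genome(Biostrings::DNAStringSet(c(chrA = gA2, chrB = gB2)))
    model2 <- gene_model(data.frame(
      gene_id = c("gA", "gB"), tx_id = c("gA.t1", "gB.t1"),
      chrom = c("chrA", "chrB"), start = c(100L, 100L),
      end = c(500L, 500L), strand = "+"))
    segs <- realign_contig(contig, g2)
    ch <- chain_paths(segs, nchar(contig), extension_slack = 25L)
    j <- detect_junction(ch, model2, g2, contig)
    if (h <= 15L) {
      expect_false(is.null(j), label = paste("h =", h))
    } else {
      expect_null(j, label = paste("h =", h))
    }
  }
})

test_that("PSL rows substitute for internal re-alignment", {
  psl <- tempfile(fileext = ".psl")
  # contig c1: 150 nt to chrA:2000 +, then 150 nt to chrB:4000 +
  writeLines(c(
    paste(150, 0, 0, 0, 0, 0, 0, 0, "+", "c1", 300, 0, 150,
          "chrA", 6000, 2000, 2150, 1, "150,", "0,", "2000,", sep = "\t"),
    paste(150, 0, 0, 0, 0, 0, 0, 0, "+", "c1", 300, 150, 300,
          "chrB", 6000, 4000, 4150, 1, "150,", "150,", "4000,", sep = "\t")),
    psl)
  segs <- read_psl(psl)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$qname, c("c1", "c1"))
  expect_equal(segs$score, c(150L, 150L))
  contig <- paste0(substr(chrA, 2001L, 2150L), substr(chrB, 4001L, 4150L))
  ch <- chain_paths(segs[, -1], nchar(contig))
  j <- detect_junction(ch, jd_model, jd_ref, contig)
  expect_equal(j$gene5, "gA")
  expect_equal(j$gene3, "gB")
})
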