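test_that("motif scanning finds 0-based GATC positions and rejects bad input", {
  expect_identical(scan_motif("GATCGATC"), c(0L, 4L))
  expect_identical(scan_motif("AAAA"), integer(0))
  expect_identical(scan_motif("NGATC"), 1L)  # N shifts, never matches
  expect_identical(scan_motif("AAAAGATCAAAAGATCAAAA"), c(4L, 12L))
  expect_error(scan_motif("ACGTX"), "non-DNA")
  expect_error(scan_motif(c("ACGT", "ACGT")), "single")
})

test_that("digestion tiles the chromosome exactly at the cut boundaries", {
  fr <- digest_chromosome(c(10L, 50L), 100L)
  expect_equal(BiocGenerics::start(fr), c(1L, 11L, 51L))
  expect_equal(BiocGenerics::end(fr), c(10L, 50L, 100L))
  # no cut sites: one fragment spanning the chromosome
  fr0 <- digest_chromosome(integer(0), 200L)
  expect_equal(as.data.frame(fr0)[, c("start", "end")],
               data.frame(start = 1L, end = 200L))
  # from raw sequence: GATC at 4 and 12 cuts [0,4) [4,12) [12,20)
  seq <- "AAAAGATCAAAAGATCAAAA"
  fr_seq <- digest_chromosome(scan_motif(seq), nchar(seq))
  expect_equal(BiocGenerics::start(fr_seq), c(1L, 5L, 13L))
  expect_equal(BiocGenerics::end(fr_seq), c(4L, 12L, 20L))
  expect_error(digest_chromosome(c(50L, 10L), 100L), "increasing")
  expect_error(digest_chromosome(c(0L, 10L), 100L), "inside")
  expect_error(digest_chromosome(c(10L, 100L), 100L), "inside")
})

test_that("sequence digestion matches a brute-force scan on random sequences", {
  set.seed(7)
  for (i in 1:1000) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 300, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
    expect_identical(scan_motif(s), brute_scan(s))
  }
  # and the resulting fragments always tile the sequence
  for (i in 1:25) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    fr <- digest_chromosome(scan_motif(s), nchar(s))
    expect_equal(sum(BiocGenerics::width(fr)), nchar(s))
    expect_equal(BiocGenerics::start(fr)[-1], head(BiocGenerics::end(fr), -1) + 1L)
  }
})

test_that("k-fragment concatenation groups, keeps coverage, ORs bait flags", {
  fmap <- fragment_map(list(chr1 = as.integer(c(4, 12, 20, 33))),
                       c(chr1 = 40L))
  f4 <- concatenate_fragments(fmap, 4L)
  expect_equal(BiocGenerics::start(f4), c(1L, 34L))
  expect_equal(BiocGenerics::end(f4), c(33L, 40L))
  expect_equal(f4$n_frag, c(4L, 1L))

  # 10 fragments -> bins of 4, 4, 2
  fmap10 <- fragment_map(list(chr1 = as.integer(seq(10, 90, by = 10))),
                         c(chr1 = 100L))
  f4b <- concatenate_fragments(fmap10, 4L)
  expect_equal(f4b$n_frag, c(4L, 4L, 2L))
  expect_equal(sum(BiocGenerics::width(f4b)), 100L)

  # k = 1 is the identity on coordinates
  f1 <- concatenate_fragments(fmap10, 1L)
  expect_equal(BiocGenerics::start(f1), BiocGenerics::start(fmap10))
  expect_equal(BiocGenerics::end(f1), BiocGenerics::end(fmap10))
  expect_error(concatenate_fragments(fmap10, 0L), "positive")

  # bait OR rule: one bait member baits the whole bin
  fmap10$bait[3] <- TRUE
  f4c <- concatenate_fragments(fmap10, 4L)
  expect_equal(f4c$bait, c(TRUE, FALSE, FALSE))
})

test_that("fragment-to-bin mapping is total and single-valued", {
  set.seed(11)
  cuts <- list(chr1 = sort(sample.int(49999L, 200L)),
               chr2 = sort(sample.int(29999L, 120L)))
  fmap <- fragment_map(cuts, c(chr1 = 50000L, chr2 = 30000L))
  f4 <- concatenate_fragments(fmap, 4L)
  idx <- fragment_bin_index(fmap, f4)
  expect_true(all(idx >= 1L))                       # total
  expect_equal(length(idx), length(fmap))           # one bin per fragment
  # containment: every fragment lies inside its bin
  expect_true(all(BiocGenerics::start(fmap) >= BiocGenerics::start(f4)[idx] &
                    BiocGenerics::end(fmap) <= BiocGenerics::end(f4)[idx]))
  # tiling preserved at both resolutions
  expect_equal(sum(BiocGenerics::width(fmap)), 80000L)
  expect_equal(sum(BiocGenerics::width(f4)), 80000L)
})

test_that("promoter windows are strand-aware and clipped at chromosome edges", {
  tx <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("g1", "g2", "g3"), gene_symbol = c("G1", "G2", "G3"),
    chrom = "chr1", strand = c("+", "-", "+"),
    tss0 = c(10000L, 10000L, 1000L), biotype = "protein_coding")
  w <- promoter_windows(tx, chrom_lengths = c(chr1 = 50000L))
  # + strand [8500,10500) 0-based -> 8501..10500 1-based
  expect_equal(BiocGenerics::start(w)[1], 8501L)
  expect_equal(BiocGenerics::end(w)[1], 10500L)
  # - strand [9500,11500)
  expect_equal(BiocGenerics::start(w)[2], 9501L)
  expect_equal(BiocGenerics::end(w)[2], 11500L)
  # clipped at chromosome start: [0,1500)
  expect_equal(BiocGenerics::start(w)[3], 1L)
  expect_equal(BiocGenerics::end(w)[3], 1500L)
  expect_true(all(BiocGenerics::width(w) <= 2000L))
  # clipped at chromosome end
  tx_end <- tx[1, ]; tx_end$tss0 <- 49900L
  w_end <- promoter_windows(tx_end, chrom_lengths = c(chr1 = 50000L))
  expect_equal(BiocGenerics::end(w_end), 50000L)
})

test_that("bait assignment flags any promoter-overlapping fragment", {
  fmap <- fragment_map(list(chr1 = c(8400L, 8600L)), c(chr1 = 20000L))
  w <- make_windows("chr1", 8501L, 10500L, "G1")
  fmap <- assign_baits(fmap, w)
  # fragment [8400,8600) 0-based = 8401..8600 overlaps window by 100 bp
  expect_equal(fmap$bait, c(FALSE, TRUE, TRUE))
  # fragment far from any window is not a bait
  expect_false(assign_baits(fragment_map(list(chr1 = 100L),
                                         c(chr1 = 200L)), w)$bait[1])
})

test_that("rmap/baitmap and transcript tables round-trip through disk", {
  dir <- withr::local_tempdir()
  fmap <- fragment_map(list(chr1 = c(4L, 12L, 20L), chr2 = c(7L, 15L)),
                       c(chr1 = 30L, chr2 = 25L))
  p <- file.path(dir, "x.rmap")
  write_rmap(fmap, p)
  back <- read_rmap(p, chrom_lengths = c(chr1 = 30L, chr2 = 25L))
  expect_equal(BiocGenerics::start(back), BiocGenerics::start(fmap))
  expect_equal(BiocGenerics::end(back), BiocGenerics::end(fmap))
  expect_equal(back$frag_id, fmap$frag_id)

  w <- make_windows("chr1", 3L, 14L, "G1")
  fmap <- assign_baits(fmap, w)
  bp <- file.path(dir, "x.baitmap")
  write_baitmap(fmap, w, bp)
  bm <- read.table(bp, sep = "\t")
  expect_equal(nrow(bm), sum(fmap$bait))
  expect_true(all(bm$V5 == "G1"))

  tx <- data.frame(transcript_id = "t1", gene_id = "g1", gene_symbol = "G1",
                   chrom = "chr1", strand = "+", tss0 = 999L,
                   biotype = "protein_coding")
  tp <- file.path(dir, "tx.tsv")
  write_transcripts(tx, tp)
  tx2 <- read_transcripts(tp)
  expect_equal(tx2$tss0, 999L)  # 1-based on disk, 0-based in memory
  expect_equal(tx2$gene_symbol, "G1")
})

test_that("FASTA-based digestion and minimal GTF import work end to end", {
  dir <- withr::local_tempdir()
  seqs <- c(chrA = "AAAAGATCAAAAGATCAAAA", chrB = "GATCGGGG")
  fa <- file.path(dir, "g.fa")
  writeLines(c(">chrA", seqs[[1]], ">chrB", seqs[[2]]), fa)
  fmap <- fragment_map_from_seqs(Biostrings::readDNAStringSet(fa))
  expect_equal(sum(BiocGenerics::width(fmap)), sum(nchar(seqs)))
  expect_equal(length(fmap[GenomeInfoDb::seqnames(fmap) == "chrA"]), 3L)

  skip_if_not_installed("rtracklayer")
  gtf <- file.path(dir, "g.gtf")
  writeLines(paste(
    c("chrA", "chrA"), "toy", "transcript", c(5L, 2L), c(18L, 9L), ".",
    c("+", "-"), ".",
    sprintf('gene_id "g%d"; transcript_id "t%d"; gene_name "GN%d";', 1:2, 1:2, 1:2),
    sep = "\t"), gtf)
  tx <- read_transcripts_gtf(gtf)
  expect_equal(tx$tss0, c(4L, 8L))  # plus strand: start; minus strand: end
  expect_equal(tx$gene_symbol, c("GN1", "GN2"))
})
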