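proxy_row <- function(rsid, chrom, pos0, sentinel = "rsS1", r2 = 1) {
  data.frame(rsid = rsid, chrom = chrom, pos0 = pos0,
             sentinel_rsid = sentinel, r2 = r2, stringsAsFactors = FALSE)
}

test_that("LD filtering is inclusive at the threshold", {
  px <- rbind(proxy_row("p1", "chr1", 100, r2 = 0.8),
              proxy_row("p2", "chr1", 200, r2 = 0.39),
              proxy_row("p3", "chr1", 300, r2 = 1.0))
  expect_equal(filter_proxies(px, 0.8)$rsid, c("p1", "p3"))
  expect_equal(filter_proxies(px, 0.4)$rsid, c("p1", "p3"))
  expect_equal(filter_proxies(px, 0.3)$rsid, c("p1", "p2", "p3"))
  expect_error(filter_proxies(px, 1.2), "\\[0, 1\\]")
  expect_error(filter_proxies(px, -0.1), "\\[0, 1\\]")
})

test_that("accessible-variant location honours half-open OCR boundaries", {
  atlas <- make_atlas(data.frame(chrom = "chr1", start1 = 101, end1 = 200,
                                 open_tfh = TRUE))
  # 1-based 150 (0-based 149) is inside [100,200); 1-based 201 is outside
  inside <- proxy_row("in", "chr1", 149L)
  outside <- proxy_row("out", "chr1", 200L)
  first <- proxy_row("first", "chr1", 100L)   # 0-based 100 = first base
  acc <- locate_in_ocr(rbind(inside, outside, first), atlas, "tfh")
  expect_setequal(acc$rsid, c("in", "first"))
  expect_equal(unique(acc$ocr_id), "chr1:100-200")
  # chromosome without OCRs contributes nothing
  acc2 <- suppressWarnings(
    locate_in_ocr(proxy_row("px", "chr9", 150L), atlas, "tfh"))
  expect_equal(nrow(acc2), 0L)
  # closed OCR does not qualify
  atlas$open_tfh <- FALSE
  expect_equal(nrow(locate_in_ocr(inside, atlas, "tfh")), 0L)
})

test_that("promoter-resident pairs require the SNP inside a window", {
  acc <- proxy_row("p1", "chr1", 149L)
  acc$ocr_id <- "chr1:100-200"
  w <- make_windows("chr1", c(120, 140), c(180, 210), c("G1", "G2"))
  pr <- promoter_resident_pairs(acc, w)
  expect_equal(nrow(pr), 2L)  # overlapping windows of two genes: two pairs
  expect_setequal(pr$gene_id, c("G1", "G2"))
  expect_true(all(pr$route == "promoter_resident"))
  # SNP outside every window: no promoter-route pair
  acc2 <- acc; acc2$pos0 <- 500L
  expect_equal(nrow(promoter_resident_pairs(acc2, w)), 0L)
})

test_that("interaction pairs nominate partner-promoter genes", {
  atlas <- make_atlas(data.frame(
    chrom = "chr1", start1 = c(101, 5001, 9001), end1 = c(400, 5400, 9400),
    open_tfh = TRUE))
  w <- make_windows("chr1", c(5001, 5050), c(5400, 5500), c("BGENE", "CGENE"))
  acc <- proxy_row("p1", "chr1", 200L)
  acc$ocr_id <- "chr1:100-400"
  it <- data.frame(ocr_a = "chr1:100-400", ocr_b = "chr1:5000-5400",
                   cell_type = "tfh", stringsAsFactors = FALSE)
  pairs <- interaction_pairs(acc, it, atlas, w)
  # partner overlaps windows of two genes: two pairs
  expect_setequal(pairs$gene_id, c("BGENE", "CGENE"))
  expect_true(all(pairs$route == "interaction"))
  expect_equal(unique(pairs$partner_ocr_id), "chr1:5000-5400")
  # orientation does not matter
  it_rev <- data.frame(ocr_a = "chr1:5000-5400", ocr_b = "chr1:100-400",
                       cell_type = "tfh", stringsAsFactors = FALSE)
  expect_equal(interaction_pairs(acc, it_rev, atlas, w)$gene_id,
               pairs$gene_id)
  # SNP OCR without interactions: no pairs
  acc2 <- acc; acc2$ocr_id <- "chr1:9000-9400"
  expect_equal(nrow(interaction_pairs(acc2, it, atlas, w)), 0L)
})

test_that("nearest gene minimizes TSS distance with lexicographic ties", {
  tx <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    gene_id = c("GB", "GA", "GC"), gene_symbol = c("GB", "GA", "GC"),
    chrom = "chr1", strand = "+",
    tss0 = c(105000L, 150000L, 300000L), biotype = "protein_coding")
  snp <- data.frame(rsid = "p1", chrom = "chr1", pos0 = 100000L)
  expect_equal(unname(nearest_gene(snp, tx)), "GB")  # 5 kb beats 50 kb
  # equidistant genes: lexicographically smaller id wins
  tie <- tx; tie$tss0 <- c(105000L, 95000L, 300000L)
  expect_equal(unname(nearest_gene(snp, tie)), "GA")
  # TSS distance, not gene-body containment, decides
  body <- data.frame(
    transcript_id = c("tHost", "tNear"),
    gene_id = c("HOST", "NEAR"), gene_symbol = c("HOST", "NEAR"),
    chrom = "chr1", strand = "+",
    tss0 = c(40000L, 101000L), biotype = "protein_coding")
  # SNP at 100 kb sits far into HOST's body but 1 kb from NEAR's TSS
  expect_equal(unname(nearest_gene(snp, body)), "NEAR")
  expect_error(nearest_gene(data.frame(rsid = "x", chrom = "chrZ",
                                       pos0 = 1L), tx), "chrZ")
})

test_that("variant categories partition interaction-connected proxies", {
  tx <- data.frame(
    transcript_id = paste0("t", 1:2),
    gene_id = c("NEARG", "FARG"), gene_symbol = c("NEARG", "FARG"),
    chrom = "chr1", strand = "+",
    tss0 = c(10000L, 200000L), biotype = "protein_coding")
  w <- promoter_windows(tx)
  proxies <- proxy_row("p1", "chr1", 20000L)
  mk_pairs <- function(genes) {
    data.frame(proxy_rsid = "p1", sentinel_rsid = "rsS1", r2 = 1,
               gene_id = genes, gene_symbol = genes, route = "interaction",
               cell_type = "tfh", ocr_id = "x", partner_ocr_id = "y",
               stringsAsFactors = FALSE)
  }
  cat_of <- function(genes) {
    categorize_variants(mk_pairs(genes), proxies, tx, windows = w)$category
  }
  expect_equal(cat_of("NEARG"), "nearest_only")
  expect_equal(cat_of(c("NEARG", "FARG")), "nearest_plus_distant")
  expect_equal(cat_of("FARG"), "skip")
  # promoter-resident-only proxies receive no category
  pr_only <- mk_pairs("NEARG"); pr_only$route <- "promoter_resident"
  expect_equal(nrow(categorize_variants(pr_only, proxies, tx, windows = w)), 0L)
})

test_that("category summaries count and normalize correctly", {
  cats <- data.frame(proxy_rsid = c("a", "b", "c"),
                     nearest_gene_id = "g",
                     category = c("nearest_only", "nearest_only", "skip"))
  s <- summarize_categories(cats)
  expect_equal(s$n, c(2L, 0L, 1L))
  expect_equal(s$fraction, c(2 / 3, 0, 1 / 3))
  expect_equal(sum(s$fraction), 1)
  s0 <- summarize_categories(cats[0, ])
  expect_equal(s0$n, c(0L, 0L, 0L))
  expect_equal(s0$fraction, c(0, 0, 0))
})

test_that("lowering the LD threshold only ever adds V2G pairs", {
  study <- small_study()
  tight <- run_v2g_on_study(study, r2_threshold = 0.8)
  relaxed <- run_v2g_on_study(study, r2_threshold = 0.4)
  key <- function(p) paste(p$proxy_rsid, p$gene_id, p$route)
  expect_true(all(key(tight$pairs) %in% key(relaxed$pairs)))
  expect_gt(nrow(relaxed$pairs), nrow(tight$pairs))
})
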