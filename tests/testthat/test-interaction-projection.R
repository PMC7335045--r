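test_that("ibed parsing validates shape and applies the inclusive score cut", {
  dir <- withr::local_tempdir()
  ok <- file.path(dir, "ok.ibed")
  writeLines(c(
    paste(c("bait_chr", "bait_start", "bait_end", "bait_name", "otherEnd_chr",
            "otherEnd_start", "otherEnd_end", "otherEnd_name", "N_reads",
            "score"), collapse = "\t"),
    "chr1\t100\t400\tG1\tchr1\t5000\t5400\t.\t12\t9.2",
    "chr1\t100\t400\tG1\tchr1\t9000\t9400\t.\t4\t4.9",
    "chr1\t100\t400\tG1\tchr1\t7000\t7400\t.\t6\t5"), ok)
  calls <- read_ibed(ok, "tfh", 1L)
  expect_equal(nrow(calls), 2L)        # 9.2 and exactly 5 kept, 4.9 dropped
  expect_equal(sort(calls$score), c(5, 9.2))
  expect_equal(unique(calls$cell_type), "tfh")

  bad9 <- file.path(dir, "bad9.ibed")
  writeLines(c(paste(capcv2g:::ibed_cols[1:9], collapse = "\t"),
               "chr1\t1\t2\tx\tchr1\t3\t4\t.\t5"), bad9)
  expect_error(read_ibed(bad9, "tfh", 1L), "10 columns")

  badrow <- file.path(dir, "badrow.ibed")
  writeLines(c(paste(capcv2g:::ibed_cols, collapse = "\t"),
               "chr1\t100\t400\tG1\tchr1\t5000\t5400\t.\t12\t9.2",
               "chr1\tXYZ\t400\tG1\tchr1\t5000\t5400\t.\t12\t9.2"), badrow)
  expect_error(read_ibed(badrow, "tfh", 1L), "line 3")

  neg <- file.path(dir, "neg.ibed")
  writeLines(c(paste(capcv2g:::ibed_cols, collapse = "\t"),
               "chr1\t100\t400\tG1\tchr1\t5000\t5400\t.\t12\t-1"), neg)
  expect_error(read_ibed(neg, "tfh", 1L, score_threshold = 0), "negative")
})

test_that("resolution merging keeps the max score and unions resolutions", {
  a <- make_calls("chr1", 100, 400, 5000, 5400, score = 6, resolution = 1L)
  b <- make_calls("chr1", 100, 400, 5000, 5400, score = 9, resolution = 4L)
  m <- merge_resolutions(a, b)
  expect_equal(nrow(m), 1L)
  expect_equal(m$score, 9)
  expect_equal(m$resolutions, "1,4")

  # reversed orientation still counts as the same coordinate pair
  b_rev <- make_calls("chr1", 5000, 5400, 100, 400, score = 9, resolution = 4L)
  m_rev <- merge_resolutions(a, b_rev)
  expect_equal(nrow(m_rev), 1L)
  expect_equal(m_rev$score, 9)

  # disjoint sets concatenate; merging with nothing is idempotent
  c2 <- make_calls("chr2", 10, 40, 500, 540, score = 7, resolution = 4L)
  m2 <- merge_resolutions(a, c2)
  expect_equal(nrow(m2), 2L)
  m3 <- merge_resolutions(m2, a[0, ])
  expect_equal(as.data.frame(m3), as.data.frame(m2))

  expect_error(merge_resolutions(a, make_calls("chr1", 1, 2, 3, 4, 6,
                                               cell_type = "naive")),
               "different cell types")
})

test_that("resolution merging never lowers a pair's max score nor duplicates", {
  set.seed(13)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    pool_s <- sample(seq(100, 2000, by = 100), 6)
    mk <- function(k) {
      bs <- sample(pool_s, k, replace = TRUE)
      os <- sample(pool_s, k, replace = TRUE)
      make_calls("chr1", bs, bs + 99, os, os + 99,
                 score = round(runif(k, 5, 20), 2),
                 resolution = sample(c(1L, 4L), k, replace = TRUE))
    }
    x <- mk(n); y <- mk(sample(5:40, 1))
    m <- merge_resolutions(x, y)
    key <- function(df) {
      lo <- pmin(df$bait_start, df$otherEnd_start)
      hi <- pmax(df$bait_start, df$otherEnd_start)
      paste(lo, hi)
    }
    max_in <- tapply(rbind(x, y)$score, key(rbind(x, y)), max)
    expect_false(anyDuplicated(key(m)) > 0)
    expect_equal(as.numeric(max_in[key(m)]), m$score)
    expect_setequal(names(max_in), key(m))
  }
})

test_that("projection requires openness and a promoter end, and unions evidence", {
  atlas <- make_atlas(data.frame(
    chrom = "chr1",
    start1 = c(101, 5001, 9001),
    end1 = c(400, 5400, 9400),
    open_tfh = c(TRUE, TRUE, FALSE)))
  windows <- make_windows("chr1", 150, 2100, "G1")
  call_open <- make_calls("chr1", 101, 400, 5001, 5400, score = 8)
  proj <- project_to_ocr(call_open, atlas, windows, "tfh")
  expect_equal(nrow(proj), 1L)
  expect_equal(proj$ocr_a, "chr1:100-400")
  expect_equal(proj$ocr_b, "chr1:5000-5400")
  expect_equal(proj$class_a, "prOCR")
  expect_equal(proj$class_b, "nonprOCR")

  # partner OCR closed in the cell type: no pair
  call_closed <- make_calls("chr1", 101, 400, 9001, 9400, score = 8)
  expect_equal(nrow(project_to_ocr(call_closed, atlas, windows, "tfh")), 0L)

  # neither end overlaps a promoter window: pair removed
  atlas2 <- make_atlas(data.frame(
    chrom = "chr1", start1 = c(5001, 9001), end1 = c(5400, 9400),
    open_tfh = c(TRUE, TRUE)))
  call_nopr <- make_calls("chr1", 5001, 5400, 9001, 9400, score = 8)
  expect_equal(nrow(project_to_ocr(call_nopr, atlas2, windows, "tfh")), 0L)

  # two interactions hitting the same pair: max score, unioned resolutions
  dup <- rbind(make_calls("chr1", 101, 400, 5001, 5400, 6, resolution = 1L),
               make_calls("chr1", 101, 400, 5001, 5400, 11, resolution = 4L))
  proj_dup <- project_to_ocr(dup, atlas, windows, "tfh")
  expect_equal(proj_dup$score, 11)
  expect_equal(proj_dup$resolutions, "1,4")

  expect_error(project_to_ocr(call_open, atlas, windows, "bcell"), "bcell")
})

test_that("projection matches the exhaustive brute-force oracle", {
  for (seed in 1:30) {
    inst <- random_projection_instance(seed)
    got <- project_to_ocr(inst$calls, inst$atlas, inst$windows, "tfh")
    want <- oracle_project(inst$calls, inst$atlas, inst$windows, "tfh")
    got_cmp <- got[order(got$ocr_a, got$ocr_b),
                   c("ocr_a", "ocr_b", "score", "resolutions",
                     "class_a", "class_b", "distance")]
    rownames(got_cmp) <- NULL
    expect_equal(got_cmp, want, info = paste("seed", seed))
    # every emitted pair satisfies the type invariants
    if (nrow(got)) {
      expect_true(all(got$ocr_a != got$ocr_b))
      expect_true(all(got$class_a == "prOCR" | got$class_b == "prOCR"))
      open_ids <- inst$atlas$ocr_id[inst$atlas$open_tfh]
      expect_true(all(got$ocr_a %in% open_ids & got$ocr_b %in% open_ids))
      chr_of <- function(id) sub(":.*", "", id)
      expect_true(all(chr_of(got$ocr_a) == chr_of(got$ocr_b)))
    }
  }
})

test_that("sub-threshold calls never change the projected set", {
  set.seed(99)
  dir <- withr::local_tempdir()
  inst <- random_projection_instance(4)
  base <- inst$calls
  low <- base[sample.int(nrow(base), 5), ]
  low$score <- runif(5, 0, 4.99)
  f1 <- file.path(dir, "base.ibed"); f2 <- file.path(dir, "aug.ibed")
  write_ibed(base, f1)
  write_ibed(rbind(base, low), f2)
  calls_base <- read_ibed(f1, "tfh", 1L)
  calls_aug <- read_ibed(f2, "tfh", 1L)
  expect_equal(project_to_ocr(calls_aug, inst$atlas, inst$windows, "tfh"),
               project_to_ocr(calls_base, inst$atlas, inst$windows, "tfh"))
})

test_that("end classification depends only on the OCR's own location", {
  atlas <- make_atlas(data.frame(
    chrom = "chr1", start1 = c(101, 5001), end1 = c(400, 5400),
    open_tfh = c(TRUE, TRUE)))
  # window of a different gene than the partner's: still prOCR
  windows <- make_windows("chr1", c(150, 5101), c(2100, 5200),
                          gene_id = c("G1", "G2"))
  it <- data.frame(ocr_a = "chr1:100-400", ocr_b = "chr1:5000-5400",
                   stringsAsFactors = FALSE)
  cls <- classify_ends(it, atlas, windows)
  expect_equal(cls$class_a, "prOCR")
  expect_equal(cls$class_b, "prOCR")
  # intronic OCR with no window at all
  cls2 <- classify_ends(it, atlas, make_windows("chr1", 150, 2100, "G1"))
  expect_equal(cls2$class_b, "nonprOCR")
})

test_that("connectivity stats count distinct partners and summarize distances", {
  atlas <- make_atlas(data.frame(
    chrom = "chr1",
    start1 = c(1001, 11001, 101001, 1001001),
    end1 = c(1400, 11400, 101400, 1001400),
    open_tfh = TRUE))
  windows <- make_windows("chr1", 1001, 1400, "G1")
  ids <- atlas$ocr_id
  it <- data.frame(ocr_a = ids[1], ocr_b = ids[2:4],
                   distance = c(10e3, 100e3, 1e6),
                   stringsAsFactors = FALSE)
  st <- connectivity_stats(it, atlas, windows)
  expect_equal(st$gene_counts$n_partner_ocr[st$gene_counts$gene_id == "G1"], 3L)
  expect_equal(unname(st$distances["median"]), 100e3)
  # gene with windows but no interactions has count 0
  w2 <- suppressWarnings(c(windows, make_windows("chr2", 500, 2000, "G0")))
  st2 <- suppressWarnings(connectivity_stats(it, atlas, w2))
  expect_equal(st2$gene_counts$n_partner_ocr[st2$gene_counts$gene_id == "G0"], 0L)
})
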