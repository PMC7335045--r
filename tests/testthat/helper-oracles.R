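# Fixture builders and independent brute-force oracles used across the
# suite. The oracles deliberately avoid GenomicRanges machinery: overlap
# logic is spelled out on plain integers so they constitute an independent
# second route.

# quick GRanges builder: gr("chr1", c(100, 300), c(200, 400)) is 1-based
gr <- function(chrom, start1, end1) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1))
}

# 1-based closed interval overlap on plain vectors
ivl_overlaps <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# brute-force motif scan: check every offset by substring comparison
brute_scan <- function(seq, motif = "GATC") {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(integer(0))
  hits <- vapply(seq_len(n - m + 1L), function(i) {
    substr(seq, i, i + m - 1L) == motif
  }, logical(1))
  which(hits) - 1L
}

# brute-force interval merge (sort + sweep, bookended joined); input/output
# data.frame(chrom, start1, end1)
brute_merge <- function(df) {
  out <- list()
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start1, d$end1), , drop = FALSE]
    cs <- d$start1[1]; ce <- d$end1[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start1[i] <= ce + 1L) {
        ce <- max(ce, d$end1[i])
      } else {
        out[[length(out) + 1L]] <- data.frame(chrom = ch, start1 = cs, end1 = ce)
        cs <- d$start1[i]; ce <- d$end1[i]
      }
    }
    out[[length(out) + 1L]] <- data.frame(chrom = ch, start1 = cs, end1 = ce)
  }
  do.call(rbind, out)
}

# atlas builder from a data.frame(chrom, start1, end1, open_<ct>...) --
# intervals must already be non-overlapping
make_atlas <- function(df) {
  atlas <- gr(df$chrom, df$start1, df$end1)
  atlas$ocr_id <- sprintf("%s:%d-%d", df$chrom, df$start1 - 1L, df$end1)
  for (cc in grep("^open_", names(df), value = TRUE)) {
    S4Vectors::mcols(atlas)[[cc]] <- df[[cc]]
  }
  sort(atlas)
}

make_windows <- function(chrom, start1, end1, gene_id,
                         gene_symbol = gene_id) {
  w <- gr(chrom, start1, end1)
  w$transcript_id <- paste0("T_", gene_id, "_", seq_along(w))
  w$gene_id <- gene_id
  w$gene_symbol <- gene_symbol
  w
}

make_calls <- function(chrom, bs, be, os, oe, score, resolution = 1L,
                       cell_type = "tfh") {
  data.frame(bait_chr = chrom, bait_start = bs, bait_end = be,
             bait_name = ".", otherEnd_chr = chrom, otherEnd_start = os,
             otherEnd_end = oe, otherEnd_name = ".",
             N_reads = 10L, score = score, resolution = resolution,
             cell_type = cell_type, stringsAsFactors = FALSE)
}

# exhaustive projection oracle: for every interaction, test every OCR pair
# by direct coordinate comparison; aggregate max score and union of
# resolutions; drop self/trans/non-promoter pairs
oracle_project <- function(calls, atlas, windows, cell_type) {
  open <- S4Vectors::mcols(atlas)[[paste0("open_", cell_type)]]
  ao <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(atlas)),
                   s = BiocGenerics::start(atlas),
                   e = BiocGenerics::end(atlas),
                   id = atlas$ocr_id, stringsAsFactors = FALSE)[open, ]
  ao <- ao[order(ao$chrom, ao$s, ao$e), ]
  wd <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(windows)),
                   s = BiocGenerics::start(windows),
                   e = BiocGenerics::end(windows))
  pr <- vapply(seq_len(nrow(ao)), function(i) {
    any(wd$chrom == ao$chrom[i] & ivl_overlaps(ao$s[i], ao$e[i], wd$s, wd$e))
  }, logical(1))
  res_str <- if ("resolutions" %in% names(calls)) {
    as.character(calls$resolutions)
  } else as.character(calls$resolution)
  acc <- list()
  for (k in seq_len(nrow(calls))) {
    ia <- which(ao$chrom == calls$bait_chr[k] &
                  ivl_overlaps(calls$bait_start[k], calls$bait_end[k],
                               ao$s, ao$e))
    ib <- which(ao$chrom == calls$otherEnd_chr[k] &
                  ivl_overlaps(calls$otherEnd_start[k], calls$otherEnd_end[k],
                               ao$s, ao$e))
    for (a in ia) for (b in ib) {
      lo <- min(a, b); hi <- max(a, b)
      if (lo == hi) next
      if (ao$chrom[lo] != ao$chrom[hi]) next
      if (!(pr[lo] || pr[hi])) next
      key <- paste(lo, hi)
      prev <- acc[[key]]
      if (is.null(prev)) {
        acc[[key]] <- list(lo = lo, hi = hi, score = calls$score[k],
                           res = strsplit(res_str[k], ",")[[1]])
      } else {
        acc[[key]]$score <- max(prev$score, calls$score[k])
        acc[[key]]$res <- union(prev$res, strsplit(res_str[k], ",")[[1]])
      }
    }
  }
  if (!length(acc)) {
    return(data.frame(ocr_a = character(0), ocr_b = character(0),
                      score = numeric(0), resolutions = character(0),
                      class_a = character(0), class_b = character(0),
                      distance = numeric(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(acc, function(x) {
    data.frame(ocr_a = ao$id[x$lo], ocr_b = ao$id[x$hi], score = x$score,
               resolutions = paste(sort(x$res), collapse = ","),
               class_a = if (pr[x$lo]) "prOCR" else "nonprOCR",
               class_b = if (pr[x$hi]) "prOCR" else "nonprOCR",
               distance = abs((ao$s[x$lo] + ao$e[x$lo]) / 2 -
                                (ao$s[x$hi] + ao$e[x$hi]) / 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$ocr_a, out$ocr_b), ]
  rownames(out) <- NULL
  out
}

# random projection test instance: fragment tiling, non-overlapping OCRs
# with random openness, a few promoter windows, random fragment-pair calls
random_projection_instance <- function(seed) {
  set.seed(seed)
  chroms <- paste0("chr", seq_len(sample(1:2, 1)))
  chrom_len <- 100000L
  fmap_cuts <- lapply(chroms, function(ch) {
    sort(sample.int(chrom_len - 1L, sample(50:199, 1)))
  })
  names(fmap_cuts) <- chroms
  fmap <- fragment_map(fmap_cuts, setNames(rep(chrom_len, length(chroms)),
                                           chroms))
  n_ocr <- sample(5:50, 1)
  ocr_df <- do.call(rbind, lapply(chroms, function(ch) {
    s <- sort(sample(seq(1L, chrom_len - 500L, by = 600L),
                     min(n_ocr, 40), replace = FALSE))
    data.frame(chrom = ch, start1 = s, end1 = s + sample(50:400,
                                                         length(s),
                                                         replace = TRUE))
  }))
  ocr_df$open_tfh <- runif(nrow(ocr_df)) < 0.8
  atlas <- make_atlas(ocr_df)
  n_win <- sample(2:8, 1)
  wch <- sample(chroms, n_win, replace = TRUE)
  ws <- sample.int(chrom_len - 2000L, n_win)
  windows <- make_windows(wch, ws, ws + 1999L,
                          gene_id = sprintf("G%03d", seq_len(n_win)))
  n_call <- sample(10:100, 1)
  ch <- sample(chroms, n_call, replace = TRUE)
  pick_frag <- function(ch1) {
    f <- fmap[as.character(GenomeInfoDb::seqnames(fmap)) == ch1]
    f[sample.int(length(f), 1)]
  }
  rows <- lapply(seq_len(n_call), function(i) {
    f1 <- pick_frag(ch[i]); f2 <- pick_frag(ch[i])
    make_calls(ch[i], BiocGenerics::start(f1), BiocGenerics::end(f1),
               BiocGenerics::start(f2), BiocGenerics::end(f2),
               score = round(runif(1, 5, 20), 2),
               resolution = sample(c(1L, 4L), 1))
  })
  calls <- do.call(rbind, rows)
  list(calls = calls, atlas = atlas, windows = windows)
}

# small simulated study shared by several test files (cached)
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42L, n_loci = 40L, n_chrom = 2L,
                        n_low_ld_proxies = 10L, n_inaccessible_proxies = 10L,
                        planted_eqtl_overlap = 5L)
      dir <- file.path(tempdir(), "capcv2g_small_study")
      cache <<- simulate_study(cfg, dir)
    }
    cache
  }
})

# run atlas + projection + v2g on a simulated bundle, in memory
run_v2g_on_study <- function(study, r2_threshold = 0.4,
                             cell_types = study$config$cell_types) {
  atlas <- study$atac$atlas
  windows <- study$interactions$windows
  target <- study$config$cell_types[1]
  calls1 <- read_ibed(study$files$ibed1, target, 1L,
                      score_threshold = study$config$score_threshold)
  calls4 <- read_ibed(study$files$ibed4, target, 4L,
                      score_threshold = study$config$score_threshold)
  merged <- merge_resolutions(calls1, calls4)
  projected <- project_to_ocr(merged, atlas, windows, target)
  proxies <- read_proxies(study$files$proxies)
  v2g <- v2g_map(proxies, atlas, projected, windows,
                 study$genome$transcripts, cell_types = cell_types,
                 r2_threshold = r2_threshold)
  c(v2g, list(projected = projected, merged = merged))
}
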