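## Seeded synthetic-study generator with a recorded truth table.
##
## The generator lays the genome out as independent locus blocks, one per
## planted accessible proxy SNP. Each block contains a nearby gene (A), a
## distant gene (B, 60-125 kb away), a non-promoter "source" OCR holding the
## SNP, promoter OCRs over both TSSs, a weak OCR (low counts, exercises the
## CPM filter) and an irreproducible peak (single replicate, exercises the
## two-replicate filter). The planted nearest-gene category of the block
## decides which promoter(s) the source OCR contacts:
##   nearest_only         -> gene A only
##   nearest_plus_distant -> genes A and B
##   skip                 -> gene B only
## Blocks are isolated so the realized per-SNP gene sets equal the plan
## exactly. All stages are deterministic given the config seed and write
## real files in the standard formats so the parsers are exercised.

seed_for <- function(seed, k) {
  as.integer((as.numeric(seed) * 8 + k) %% 2147483647)
}

#' Simulation configuration
#'
#' Collects every tunable of the synthetic study. Defaults mirror the
#' analysis constants (significance score 5, promoter window -1500/+500, CPM
#' rule 1.5 in half the samples, two-replicate rule, LD thresholds 0.8/0.4,
#' 5 Mb candidate pool, category mix 8.5/29/62.5%).
#'
#' @param seed Integer seed driving every stage.
#' @param n_loci Number of planted accessible proxies (one locus block each).
#' @param n_chrom Number of chromosomes the blocks are spread over.
#' @param locus_span Block width in bp.
#' @param gatc_per_kb Expected DpnII (GATC) cut-site density per kb.
#' @param cell_types Cell type labels; the first is the target cell type
#'   whose interactome is simulated.
#' @param n_replicates ATAC replicates per cell type.
#' @param peak_reproducibility Per-replicate emission probability for weak
#'   peaks.
#' @param peak_jitter Max boundary jitter (bp) applied per replicate peak.
#' @param other_ct_open_prob Probability a planted OCR is also open in the
#'   non-target cell type.
#' @param ocr_width_range,prom_ocr_flank_range Width ranges (bp) for source
#'   OCRs and promoter-OCR flanks around the TSS.
#' @param distal_tss_range Distance range (bp) from gene A's TSS to gene B's.
#' @param score_sig_range,score_decoy_range Score ranges for significant
#'   (>= 5) and decoy (< 5) interaction records.
#' @param decoy_per_locus Decoy interaction records per block.
#' @param res_probs Probabilities a planted contact is emitted at both
#'   resolutions, 1-fragment only, or 4-fragment only.
#' @param proxies_per_sentinel Loci sharing one sentinel SNP.
#' @param r2_high_fraction Fraction of planted proxies with r2 in (0.8, 1];
#'   the rest fall in (0.4, 0.8).
#' @param n_low_ld_proxies,n_inaccessible_proxies Extra decoy proxies below
#'   the relaxed LD threshold / outside open chromatin.
#' @param category_mix Planted nearest-gene category fractions
#'   (nearest_only, nearest_plus_distant, skip); must sum to 1.
#' @param planted_eqtl_overlap Number of realized sentinel-gene pairs copied
#'   into the synthetic eQTL list.
#' @param n_eqtl_decoy eQTL decoy pairs with genes absent from the
#'   annotation.
#' @param score_threshold,r2_thresholds,cpm_threshold,cpm_sample_fraction
#'   Analysis thresholds carried along for pipeline stages.
#' @param promoter_upstream,promoter_downstream Promoter window extent (bp).
#' @param eqtl_window_bp Candidate-pool half-width (bp).
#' @param eqtl_reps Resampling repetitions for the overlap test.
#' @param library_size Per-sample ATAC library size used for CPM.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_loci = 200L,
                       n_chrom = 4L,
                       locus_span = 160000L,
                       gatc_per_kb = 4,
                       cell_types = c("tfh", "naive"),
                       n_replicates = 3L,
                       peak_reproducibility = 0.9,
                       peak_jitter = 20L,
                       other_ct_open_prob = 0.7,
                       ocr_width_range = c(150L, 800L),
                       prom_ocr_flank_range = c(100L, 300L),
                       distal_tss_range = c(60000L, 125000L),
                       score_sig_range = c(5, 15),
                       score_decoy_range = c(0.1, 4.9),
                       decoy_per_locus = 1L,
                       res_probs = c(both = 0.4, only1 = 0.3, only4 = 0.3),
                       proxies_per_sentinel = 5L,
                       r2_high_fraction = 0.5,
                       n_low_ld_proxies = 30L,
                       n_inaccessible_proxies = 30L,
                       category_mix = c(nearest_only = 0.085,
                                        nearest_plus_distant = 0.29,
                                        skip = 0.625),
                       planted_eqtl_overlap = 12L,
                       n_eqtl_decoy = 25L,
                       score_threshold = 5,
                       r2_thresholds = c(tight = 0.8, relaxed = 0.4),
                       cpm_threshold = 1.5,
                       cpm_sample_fraction = 0.5,
                       promoter_upstream = 1500L,
                       promoter_downstream = 500L,
                       eqtl_window_bp = 5e6,
                       eqtl_reps = 100000L,
                       library_size = 2e6) {
  cfg <- as.list(environment())
  if (abs(sum(cfg$category_mix) - 1) > 1e-8) {
    stop_input("'category_mix' must sum to 1")
  }
  if (any(cfg$category_mix < 0) || cfg$n_loci < 1L) {
    stop_input("invalid simulation config")
  }
  structure(cfg, class = "sim_config")
}

## Exact per-category counts for n loci (largest-remainder rounding).
category_counts <- function(mix, n) {
  raw <- mix * n
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[extra] <- cnt[extra] + 1
  }
  as.integer(cnt)
}

#' Simulate the toy genome, annotation, and locus plan
#'
#' Places GATC cut sites at a Poisson density, lays out the locus blocks,
#' assigns gene strands uniformly, and fixes the planted category of every
#' block (exact largest-remainder counts of the configured mix, shuffled
#' across blocks). Deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `chrom_lengths`, `cut_sites`, `transcripts`, and the
#'   internal `loci` plan table.
#' @export
simulate_genome <- function(config) {
  set.seed(seed_for(config$seed, 0L))
  n <- config$n_loci
  span <- config$locus_span
  per_chrom <- ceiling(n / config$n_chrom)
  chroms <- paste0("chr", seq_len(config$n_chrom))
  locus_chrom_idx <- rep(seq_len(config$n_chrom), each = per_chrom)[seq_len(n)]
  locus_rank <- sequence(tabulate(locus_chrom_idx))
  chrom_lengths <- setNames(
    (tabulate(locus_chrom_idx, nbins = config$n_chrom)) * span + 10000L,
    chroms)
  chrom_lengths <- pmax(chrom_lengths, span + 10000L)

  base <- (locus_rank - 1L) * span
  tssA <- base + 10000L + sample(-2000L:2000L, n, replace = TRUE)
  distB <- round(runif(n, config$distal_tss_range[1L],
                       config$distal_tss_range[2L]))
  tssB <- tssA + as.integer(distB)
  strandA <- sample(c("+", "-"), n, replace = TRUE)
  strandB <- sample(c("+", "-"), n, replace = TRUE)

  w_src <- sample(config$ocr_width_range[1L]:config$ocr_width_range[2L], n,
                  replace = TRUE)
  src_c <- base + 20000L + sample(-2000L:2000L, n, replace = TRUE)
  src_s <- src_c - w_src %/% 2L
  src_e <- src_s + w_src
  flank <- function() sample(config$prom_ocr_flank_range[1L]:
                               config$prom_ocr_flank_range[2L], n,
                             replace = TRUE)
  pA_s <- tssA - flank(); pA_e <- tssA + flank()
  pB_s <- tssB - flank(); pB_e <- tssB + flank()
  w_wk <- sample(config$ocr_width_range[1L]:config$ocr_width_range[2L], n,
                 replace = TRUE)
  wk_s <- base + 143000L + sample(0L:3000L, n, replace = TRUE)
  wk_e <- wk_s + w_wk
  ir_s <- base + 152000L + sample(0L:2000L, n, replace = TRUE)
  ir_e <- ir_s + sample(150L:400L, n, replace = TRUE)

  counts <- category_counts(config$category_mix, n)
  category <- sample(rep(names(config$category_mix), counts))

  n_sent <- ceiling(n / config$proxies_per_sentinel)
  sentinel_idx <- rep(seq_len(n_sent),
                      each = config$proxies_per_sentinel)[seq_len(n)]

  loci <- data.frame(
    locus = seq_len(n),
    chrom = chroms[locus_chrom_idx],
    base = base,
    geneA = sprintf("GENE%05dA", seq_len(n)),
    geneB = sprintf("GENE%05dB", seq_len(n)),
    tssA0 = tssA, tssB0 = tssB,
    strandA = strandA, strandB = strandB,
    src_s0 = src_s, src_e0 = src_e,
    pA_s0 = pA_s, pA_e0 = pA_e,
    pB_s0 = pB_s, pB_e0 = pB_e,
    wk_s0 = wk_s, wk_e0 = wk_e,
    ir_s0 = ir_s, ir_e0 = ir_e,
    category = category,
    sentinel_rsid = sprintf("rs9%06d", sentinel_idx),
    proxy_rsid = sprintf("rs1%06d", seq_len(n)),
    stringsAsFactors = FALSE
  )

  ## second transcript (TSS +200) for ~10% of genes exercises multi-TSS genes
  tx_main <- data.frame(
    transcript_id = c(paste0("T_", loci$geneA), paste0("T_", loci$geneB)),
    gene_id = c(loci$geneA, loci$geneB),
    gene_symbol = c(loci$geneA, loci$geneB),
    chrom = c(loci$chrom, loci$chrom),
    strand = c(loci$strandA, loci$strandB),
    tss0 = c(loci$tssA0, loci$tssB0),
    biotype = "protein_coding",
    stringsAsFactors = FALSE
  )
  alt <- tx_main[runif(nrow(tx_main)) < 0.1, , drop = FALSE]
  if (nrow(alt)) {
    alt$transcript_id <- paste0(alt$transcript_id, "_2")
    alt$tss0 <- alt$tss0 + 200L
  }
  transcripts <- rbind(tx_main, alt)
  transcripts <- transcripts[order(transcripts$gene_id,
                                   transcripts$transcript_id), ]
  rownames(transcripts) <- NULL

  cut_sites <- lapply(chroms, function(ch) {
    len <- chrom_lengths[[ch]]
    n_sites <- rpois(1L, config$gatc_per_kb * len / 1000)
    n_sites <- min(n_sites, len - 2L)
    sort(sample.int(len - 1L, n_sites))
  })
  names(cut_sites) <- chroms

  list(chrom_lengths = chrom_lengths, cut_sites = cut_sites,
       transcripts = transcripts, loci = loci)
}

locus_gr <- function(loci, s_col, e_col) {
  GenomicRanges::GRanges(loci$chrom,
                         IRanges::IRanges(loci[[s_col]] + 1L, loci[[e_col]]))
}

jitter_gr <- function(gr, jitter) {
  if (jitter <= 0L) return(gr)
  n <- length(gr)
  s <- BiocGenerics::start(gr) + sample(-jitter:jitter, n, replace = TRUE)
  e <- BiocGenerics::end(gr) + sample(-jitter:jitter, n, replace = TRUE)
  s <- pmax(s, 1L)
  e <- pmax(e, s + 1L)
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(gr), IRanges::IRanges(s, e))
}

#' Simulate replicate ATAC peaks, counts, and the resulting atlas
#'
#' Emits per-replicate peak BEDs for each cell type (planted OCRs in every
#' replicate; weak OCRs with the configured reproducibility; irreproducible
#' peaks in a single replicate so the two-replicate rule removes them),
#' builds the reference atlas with openness calls, and writes a read-count
#' matrix in which planted open OCRs pass the CPM rule and weak OCRs fail
#' it.
#'
#' @param genome Output of [simulate_genome()].
#' @param config The [sim_config()].
#' @param out_dir Directory the peak/count files are written to.
#' @return List with `peaks` (nested replicate `GRanges`), `atlas`, `counts`,
#'   `library_sizes`, `truth` (planted OCR table with realized openness and
#'   reference ids), and `files`.
#' @export
simulate_atac <- function(genome, config, out_dir) {
  set.seed(seed_for(config$seed, 1L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  loci <- genome$loci
  target <- config$cell_types[1L]
  others <- setdiff(config$cell_types, target)

  planted <- rbind(
    data.frame(kind = "src", locus = loci$locus, gr_s = loci$src_s0,
               gr_e = loci$src_e0, chrom = loci$chrom),
    data.frame(kind = "promA", locus = loci$locus, gr_s = loci$pA_s0,
               gr_e = loci$pA_e0, chrom = loci$chrom),
    data.frame(kind = "promB", locus = loci$locus, gr_s = loci$pB_s0,
               gr_e = loci$pB_e0, chrom = loci$chrom),
    data.frame(kind = "weak", locus = loci$locus, gr_s = loci$wk_s0,
               gr_e = loci$wk_e0, chrom = loci$chrom),
    data.frame(kind = "irrep", locus = loci$locus, gr_s = loci$ir_s0,
               gr_e = loci$ir_e0, chrom = loci$chrom)
  )
  planted_gr <- GenomicRanges::GRanges(
    planted$chrom, IRanges::IRanges(planted$gr_s + 1L, planted$gr_e))

  strong <- planted$kind %in% c("src", "promA", "promB")
  open <- matrix(FALSE, nrow(planted), length(config$cell_types),
                 dimnames = list(NULL, config$cell_types))
  open[strong, target] <- TRUE
  for (ct in others) {
    open[strong, ct] <- runif(sum(strong)) < config$other_ct_open_prob
  }
  wk <- planted$kind == "weak"
  for (ct in config$cell_types) {
    open[wk, ct] <- runif(sum(wk)) < 0.5
  }
  open[planted$kind == "irrep", target] <- TRUE  # attempted, 1 replicate only

  peaks <- list()
  files <- list()
  for (ct in config$cell_types) {
    peaks[[ct]] <- list()
    for (r in seq_len(config$n_replicates)) {
      emit <- open[, ct] & ifelse(
        strong, TRUE,
        ifelse(planted$kind == "weak",
               runif(nrow(planted)) < config$peak_reproducibility,
               r == 1L))  # irreproducible peaks: first replicate only
      rep_gr <- jitter_gr(planted_gr[emit], config$peak_jitter)
      rep_gr <- sort(rep_gr)
      path <- file.path(out_dir, sprintf("atac_%s_rep%d.bed", ct, r))
      write_bed(rep_gr, path, name = rep(".", length(rep_gr)))
      peaks[[ct]][[r]] <- rep_gr
      files[[sprintf("%s_rep%d", ct, r)]] <- path
    }
  }

  merged <- lapply(peaks, merge_replicate_peaks, min_replicates = 2L)
  atlas <- build_reference_ocrs(merged)
  atlas <- call_openness(atlas, peaks)

  ## realized reference id of each planted OCR (NA when filtered out)
  hit <- GenomicRanges::findOverlaps(planted_gr, atlas)
  planted$ocr_id <- NA_character_
  planted$ocr_id[queryHits(hit)] <- atlas$ocr_id[subjectHits(hit)]
  planted <- cbind(planted, setNames(as.data.frame(open),
                                     paste0("open_", config$cell_types)))

  samples <- as.vector(outer(config$cell_types,
                             seq_len(config$n_replicates),
                             function(ct, r) sprintf("%s_rep%d", ct, r)))
  sample_ct <- rep(config$cell_types, times = config$n_replicates)
  lam <- matrix(1, length(atlas), length(samples),
                dimnames = list(atlas$ocr_id, samples))
  strong_ref <- IRanges::overlapsAny(atlas, planted_gr[strong])
  for (j in seq_along(samples)) {
    ct <- sample_ct[j]
    hi <- strong_ref & mcols(atlas)[[paste0("open_", ct)]]
    lam[hi, j] <- 30
  }
  counts <- matrix(rpois(length(lam), lam), nrow = nrow(lam),
                   dimnames = dimnames(lam))
  lib <- setNames(rep(config$library_size, length(samples)), samples)

  counts_path <- file.path(out_dir, "ocr_counts.tsv")
  fwrite(data.table(ocr_id = rownames(counts), as.data.table(counts)),
         counts_path, sep = "\t")
  lib_path <- file.path(out_dir, "library_sizes.tsv")
  fwrite(data.table(sample_id = names(lib), library_size = lib),
         lib_path, sep = "\t")
  files$counts <- counts_path
  files$library_sizes <- lib_path

  list(peaks = peaks, atlas = atlas, counts = counts, library_sizes = lib,
       truth = planted, files = files)
}

#' Simulate dual-resolution interaction calls with fragment maps
#'
#' Builds the DpnII fragment map of the toy genome, promoter windows, bait
#' flags and the four-fragment concatenation; writes rmap/baitmap files at
#' both resolutions; and emits ibed records realizing every planted
#' promoter contact (score >= 5, at one or both resolutions; every
#' 4-fragment record spans the bins containing its 1-fragment anchors) plus
#' sub-threshold decoys.
#'
#' @param genome Output of [simulate_genome()].
#' @param atac Output of [simulate_atac()].
#' @param config The [sim_config()].
#' @param out_dir Output directory.
#' @return List with `fmap1`, `fmap4`, `windows`, `contacts` (planted truth),
#'   and `files` (rmap/baitmap/ibed paths).
#' @export
simulate_interactions <- function(genome, atac, config, out_dir) {
  set.seed(seed_for(config$seed, 2L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  loci <- genome$loci
  target <- config$cell_types[1L]

  fmap1 <- fragment_map(genome$cut_sites, genome$chrom_lengths)
  windows <- promoter_windows(genome$transcripts,
                              upstream = config$promoter_upstream,
                              downstream = config$promoter_downstream,
                              chrom_lengths = genome$chrom_lengths)
  fmap1 <- assign_baits(fmap1, windows)
  fmap4 <- concatenate_fragments(fmap1, 4L)
  bin_of <- fragment_bin_index(fmap1, fmap4)

  files <- list(
    rmap1 = write_rmap(fmap1, file.path(out_dir, "fragments_1frag.rmap")),
    rmap4 = write_rmap(fmap4, file.path(out_dir, "fragments_4frag.rmap")),
    baitmap1 = write_baitmap(fmap1, windows,
                             file.path(out_dir, "fragments_1frag.baitmap")),
    baitmap4 = write_baitmap(fmap4, windows,
                             file.path(out_dir, "fragments_4frag.baitmap"))
  )

  frag_at <- function(chrom, pos0) {
    pt <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, width = 1L))
    hit <- GenomicRanges::findOverlaps(pt, fmap1)
    idx <- rep(NA_integer_, length(pt))
    idx[queryHits(hit)] <- subjectHits(hit)
    idx
  }

  targets <- list(nearest_only = "A", nearest_plus_distant = c("A", "B"),
                  skip = "B")
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    for (side in targets[[loci$category[i]]]) {
      tss <- if (side == "A") loci$tssA0[i] else loci$tssB0[i]
      gene <- if (side == "A") loci$geneA[i] else loci$geneB[i]
      rows[[length(rows) + 1L]] <- data.frame(
        locus = loci$locus[i], chrom = loci$chrom[i],
        bait_pos0 = tss, oe_pos0 = (loci$src_s0[i] + loci$src_e0[i]) %/% 2L,
        gene_id = gene, proxy_rsid = loci$proxy_rsid[i],
        sentinel_rsid = loci$sentinel_rsid[i],
        category = loci$category[i], stringsAsFactors = FALSE)
    }
  }
  contacts <- do.call(rbind, rows)
  contacts$bait_frag <- frag_at(contacts$chrom, contacts$bait_pos0)
  contacts$oe_frag <- frag_at(contacts$chrom, contacts$oe_pos0)
  contacts$score1 <- runif(nrow(contacts), config$score_sig_range[1L],
                           config$score_sig_range[2L])
  contacts$score4 <- runif(nrow(contacts), config$score_sig_range[1L],
                           config$score_sig_range[2L])
  res_draw <- sample(names(config$res_probs), nrow(contacts), replace = TRUE,
                     prob = config$res_probs)
  contacts$at_res1 <- res_draw %in% c("both", "only1")
  contacts$at_res4 <- res_draw %in% c("both", "only4")

  ibed_row <- function(fm, bi, oi, name, reads, score) {
    data.frame(
      bait_chr = as.character(GenomeInfoDb::seqnames(fm))[bi],
      bait_start = BiocGenerics::start(fm)[bi],
      bait_end = BiocGenerics::end(fm)[bi],
      bait_name = name,
      otherEnd_chr = as.character(GenomeInfoDb::seqnames(fm))[oi],
      otherEnd_start = BiocGenerics::start(fm)[oi],
      otherEnd_end = BiocGenerics::end(fm)[oi],
      otherEnd_name = ".",
      N_reads = reads, score = round(score, 2),
      stringsAsFactors = FALSE)
  }

  k1 <- which(contacts$at_res1)
  ibed1 <- ibed_row(fmap1, contacts$bait_frag[k1], contacts$oe_frag[k1],
                    contacts$gene_id[k1], rpois(length(k1), 50) + 5L,
                    contacts$score1[k1])
  k4 <- which(contacts$at_res4)
  ibed4 <- ibed_row(fmap4, bin_of[contacts$bait_frag[k4]],
                    bin_of[contacts$oe_frag[k4]],
                    contacts$gene_id[k4], rpois(length(k4), 80) + 5L,
                    contacts$score4[k4])

  ## decoys: sub-threshold records between random bait/non-bait fragments
  n_decoy <- config$decoy_per_locus * nrow(loci)
  if (n_decoy > 0) {
    bait_idx <- which(fmap1$bait)
    db <- sample(bait_idx, n_decoy, replace = TRUE)
    shift <- sample(5L:60L, n_decoy, replace = TRUE) *
      sample(c(-1L, 1L), n_decoy, replace = TRUE)
    do <- pmin(pmax(db + shift, 1L), length(fmap1))
    same_chr <- as.character(GenomeInfoDb::seqnames(fmap1))[db] ==
      as.character(GenomeInfoDb::seqnames(fmap1))[do]
    keep <- same_chr & db != do
    db <- db[keep]
    do <- do[keep]
    dec1 <- ibed_row(fmap1, db, do, ".", rpois(length(db), 8) + 1L,
                     runif(length(db), config$score_decoy_range[1L],
                           config$score_decoy_range[2L]))
    ibed1 <- rbind(ibed1, dec1)
    dec4 <- ibed_row(fmap4, bin_of[db], bin_of[do], ".",
                     rpois(length(db), 12) + 1L,
                     runif(length(db), config$score_decoy_range[1L],
                           config$score_decoy_range[2L]))
    dec4 <- dec4[!(dec4$bait_start == dec4$otherEnd_start &
                     dec4$bait_chr == dec4$otherEnd_chr), , drop = FALSE]
    ibed4 <- rbind(ibed4, dec4)
  }
  ibed1 <- ibed1[order(ibed1$bait_chr, ibed1$bait_start, ibed1$otherEnd_start), ]
  ibed4 <- ibed4[order(ibed4$bait_chr, ibed4$bait_start, ibed4$otherEnd_start), ]

  files$ibed1 <- write_ibed(ibed1, file.path(
    out_dir, sprintf("interactions_%s_1frag.ibed", target)))
  files$ibed4 <- write_ibed(ibed4, file.path(
    out_dir, sprintf("interactions_%s_4frag.ibed", target)))

  list(fmap1 = fmap1, fmap4 = fmap4, windows = windows, contacts = contacts,
       files = files)
}

#' Simulate sentinel/proxy SNP tables and eQTL pair lists
#'
#' Places one accessible proxy at the center of each block's source OCR (so
#' the planted category mix is realized exactly), adds low-LD and
#' inaccessible decoy proxies, draws r-squared values on both sides of the
#' 0.8 threshold, and builds an eQTL pair list containing exactly the
#' configured number of realized sentinel-gene pairs plus decoys with genes
#' absent from the annotation.
#'
#' @param genome Output of [simulate_genome()].
#' @param interactions Output of [simulate_interactions()].
#' @param config The [sim_config()].
#' @param out_dir Output directory.
#' @return List with `sentinels`, `proxies`, `eqtl`, `truth` (per-proxy
#'   planted category and gene set; planted eQTL overlap pairs), `files`.
#' @export
simulate_variants <- function(genome, interactions, config, out_dir) {
  set.seed(seed_for(config$seed, 3L))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  loci <- genome$loci
  n <- nrow(loci)

  sent <- unique(loci[, c("sentinel_rsid", "chrom", "base")])
  sent <- sent[!duplicated(sent$sentinel_rsid), ]
  sentinels <- data.frame(rsid = sent$sentinel_rsid, chrom = sent$chrom,
                          pos0 = sent$base + 30000L, stringsAsFactors = FALSE)

  n_hi <- ceiling(config$r2_high_fraction * n)
  r2 <- numeric(n)
  hi_idx <- sample.int(n, n_hi)
  r2[hi_idx] <- runif(n_hi, 0.801, 1)
  r2[-hi_idx] <- runif(n - n_hi, 0.401, 0.799)

  acc <- data.frame(
    rsid = loci$proxy_rsid, chrom = loci$chrom,
    pos0 = (loci$src_s0 + loci$src_e0) %/% 2L,
    sentinel_rsid = loci$sentinel_rsid, r2 = round(r2, 3),
    stringsAsFactors = FALSE)

  extra <- function(count, prefix, pos_fun, r2_fun) {
    if (count < 1L) return(acc[0, ])
    pick <- sample.int(n, count, replace = count > n)
    data.frame(
      rsid = sprintf("rs%s%06d", prefix, seq_len(count)),
      chrom = loci$chrom[pick], pos0 = pos_fun(pick),
      sentinel_rsid = loci$sentinel_rsid[pick],
      r2 = round(r2_fun(count), 3), stringsAsFactors = FALSE)
  }
  low_ld <- extra(config$n_low_ld_proxies, "3",
                  function(p) (loci$src_s0[p] + loci$src_e0[p]) %/% 2L + 5L,
                  function(k) runif(k, 0.05, 0.399))
  closed <- extra(config$n_inaccessible_proxies, "4",
                  function(p) loci$base[p] + 50000L,
                  function(k) runif(k, 0.401, 1))
  proxies <- rbind(acc, low_ld, closed)

  truth_sets <- stats::aggregate(gene_id ~ proxy_rsid,
                                 data = interactions$contacts,
                                 FUN = function(g) paste(sort(unique(g)),
                                                         collapse = ","))
  names(truth_sets)[2L] <- "planted_genes"
  truth <- merge(loci[, c("proxy_rsid", "sentinel_rsid", "category", "geneA")],
                 truth_sets, by = "proxy_rsid")
  names(truth)[names(truth) == "geneA"] <- "planted_nearest"
  truth <- truth[order(truth$proxy_rsid), ]
  rownames(truth) <- NULL

  sg <- unique(interactions$contacts[, c("sentinel_rsid", "gene_id")])
  k <- min(config$planted_eqtl_overlap, nrow(sg))
  planted_pairs <- sg[sample.int(nrow(sg), k), , drop = FALSE]
  decoy <- data.frame(
    sentinel_rsid = sample(sentinels$rsid, config$n_eqtl_decoy, replace = TRUE),
    gene_id = sprintf("EQDECOY%03d", seq_len(config$n_eqtl_decoy)),
    stringsAsFactors = FALSE)
  eqtl <- rbind(planted_pairs, decoy)
  eqtl <- data.frame(sentinel_rsid = eqtl$sentinel_rsid,
                     gene_symbol = eqtl$gene_id,
                     source_label = "synthetic_eqtl",
                     stringsAsFactors = FALSE)
  eqtl <- eqtl[order(eqtl$sentinel_rsid, eqtl$gene_symbol), ]
  rownames(eqtl) <- NULL

  files <- list()
  files$sentinels <- file.path(out_dir, "sentinels.tsv")
  fwrite(data.table(rsid = sentinels$rsid, chrom = sentinels$chrom,
                    pos_1based = sentinels$pos0 + 1L),
         files$sentinels, sep = "\t")
  files$proxies <- file.path(out_dir, "proxies.tsv")
  fwrite(data.table(rsid = proxies$rsid, chrom = proxies$chrom,
                    pos_1based = proxies$pos0 + 1L,
                    sentinel_rsid = proxies$sentinel_rsid, r2 = proxies$r2),
         files$proxies, sep = "\t")
  files$eqtl <- file.path(out_dir, "eqtl_pairs.tsv")
  fwrite(as.data.table(eqtl), files$eqtl, sep = "\t")

  list(sentinels = sentinels, proxies = proxies, eqtl = eqtl,
       truth = list(categories = truth, eqtl_overlap_pairs = planted_pairs,
                    planted_eqtl_overlap = k),
       files = files)
}

#' Simulate a complete study and write all inputs plus the truth table
#'
#' Runs [simulate_genome()], [simulate_atac()], [simulate_interactions()] and
#' [simulate_variants()] in order, writing every input file the analysis
#' pipeline consumes (peak BEDs, count matrix, rmap/baitmap, ibed, transcript
#' and SNP TSVs, eQTL list) under `out_dir`, together with `truth.json`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list bundling every stage's in-memory objects, the
#'   merged `files` list, and `truth`.
#' @export
simulate_study <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- simulate_genome(config)
  write_transcripts(genome$transcripts,
                    file.path(out_dir, "transcripts.tsv"))
  atac <- simulate_atac(genome, config, out_dir)
  inter <- simulate_interactions(genome, atac, config, out_dir)
  variants <- simulate_variants(genome, inter, config, out_dir)

  truth <- list(
    n_loci = config$n_loci,
    category_counts = as.list(table(genome$loci$category)),
    categories = variants$truth$categories,
    planted_eqtl_overlap = variants$truth$planted_eqtl_overlap,
    eqtl_overlap_pairs = variants$truth$eqtl_overlap_pairs,
    planted_ocrs = atac$truth
  )
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)

  files <- c(list(transcripts = file.path(out_dir, "transcripts.tsv"),
                  truth = file.path(out_dir, "truth.json")),
             atac$files, inter$files, variants$files)
  invisible(list(config = config, genome = genome, atac = atac,
                 interactions = inter, variants = variants,
                 truth = truth, files = files))
}
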