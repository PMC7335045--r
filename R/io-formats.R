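## Readers/writers for the standard on-disk formats used by the pipeline.
## Coordinate conventions per format:
##   BED / narrowPeak / rmap / baitmap : 0-based half-open
##   ibed                              : 1-based inclusive (caller export style)
##   SNP tables                        : 1-based positions
## Everything is converted to/from GRanges (1-based closed) at this boundary.

#' Read a fragment map (rmap) file
#'
#' An rmap is a headerless, tab-separated file with columns chrom, start,
#' end, fragment_id in 0-based half-open coordinates.
#'
#' @param path Path to the rmap file.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   attach seqinfo (the last fragment end of each chromosome is used when
#'   omitted).
#' @param resolution Resolution tag stored in the returned map (default 1).
#' @return A fragment-map `GRanges` (see [fragment_map()]).
#' @export
read_rmap <- function(path, chrom_lengths = NULL, resolution = 1L) {
  dt <- fread(path, header = FALSE, sep = "\t",
              col.names = c("chrom", "start", "end", "frag_id"))
  if (is.null(chrom_lengths)) {
    lens <- dt[, list(len = max(end)), by = chrom]
    chrom_lengths <- setNames(lens$len, lens$chrom)
  }
  gr <- GenomicRanges::GRanges(
    dt$chrom, IRanges::IRanges(dt$start + 1L, dt$end)
  )
  GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
  GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_lengths)
  gr$frag_id <- as.integer(dt$frag_id)
  gr$bait <- rep(FALSE, length(gr))
  S4Vectors::metadata(gr)$resolution <- as.integer(resolution)
  gr
}

#' Write a fragment map as an rmap file
#'
#' @param fmap Fragment map `GRanges`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_rmap <- function(fmap, path) {
  dt <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(fmap)),
    start = BiocGenerics::start(fmap) - 1L,
    end = BiocGenerics::end(fmap),
    frag_id = fmap$frag_id
  )
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write the baitmap companion of a fragment map
#'
#' The baitmap holds the bait-flagged fragments only, with a fifth annotation
#' column listing the gene symbols of the promoter windows each bait
#' overlaps.
#'
#' @param fmap Fragment map with bait flags set (see [assign_baits()]).
#' @param windows Promoter windows used to annotate baits.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_baitmap <- function(fmap, windows, path) {
  baits <- fmap[fmap$bait]
  hits <- GenomicRanges::findOverlaps(baits, windows, ignore.strand = TRUE)
  ann <- vapply(seq_along(baits), function(i) {
    g <- unique(windows$gene_symbol[subjectHits(hits)[queryHits(hits) == i]])
    if (!length(g)) "." else paste(sort(g), collapse = ",")
  }, character(1))
  dt <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(baits)),
    start = BiocGenerics::start(baits) - 1L,
    end = BiocGenerics::end(baits),
    frag_id = baits$frag_id,
    annotation = ann
  )
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a transcript annotation table
#'
#' Expects a tab-separated file with header columns `transcript_id`,
#' `gene_id`, `gene_symbol`, `chrom`, `strand`, `tss_1based`, `biotype`. The
#' 1-based TSS is converted to the internal 0-based `tss0`.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with columns `transcript_id`, `gene_id`,
#'   `gene_symbol`, `chrom`, `strand`, `tss0`, `biotype`.
#' @export
read_transcripts <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  need <- c("transcript_id", "gene_id", "gene_symbol", "chrom", "strand",
            "tss_1based", "biotype")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop_input("transcript file lacks columns: ",
                               paste(miss, collapse = ", "))
  out <- as.data.frame(dt[, need, with = FALSE])
  out$tss0 <- as.integer(out$tss_1based) - 1L
  out$tss_1based <- NULL
  out$chrom <- as.character(out$chrom)
  out
}

#' Write a transcript annotation table
#'
#' @param transcripts Transcript table (internal 0-based `tss0`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_transcripts <- function(transcripts, path) {
  dt <- as.data.table(transcripts)
  dt[, `:=`(tss_1based = tss0 + 1L, tss0 = NULL)]
  setcolorder(dt, c("transcript_id", "gene_id", "gene_symbol", "chrom",
                    "strand", "tss_1based", "biotype"))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read transcripts from a minimal GTF
#'
#' Imports `transcript` features (falling back to `exon` grouping when no
#' transcript rows exist) from a GTF file and derives the strand-aware TSS.
#' Requires the `rtracklayer` package.
#'
#' @param path Path to the GTF file.
#' @return Transcript table as in [read_transcripts()].
#' @export
read_transcripts_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop_input("reading GTF requires the 'rtracklayer' package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(mcols(gr)) && any(gr$type == "transcript")) {
    gr <- gr[gr$type == "transcript"]
  }
  str <- as.character(BiocGenerics::strand(gr))
  if (any(str == "*")) stop_input("GTF transcripts must be stranded")
  tss1 <- ifelse(str == "+", BiocGenerics::start(gr), BiocGenerics::end(gr))
  sym <- mcols(gr)$gene_name %||% mcols(gr)$gene_id
  data.frame(
    transcript_id = mcols(gr)$transcript_id %||% paste0("tx", seq_along(gr)),
    gene_id = mcols(gr)$gene_id,
    gene_symbol = sym,
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    strand = str,
    tss0 = as.integer(tss1) - 1L,
    biotype = mcols(gr)$gene_biotype %||%
      (mcols(gr)$gene_type %||% rep("protein_coding", length(gr))),
    stringsAsFactors = FALSE
  )
}

#' Read peak calls from a BED3+/narrowPeak file
#'
#' Only the first three columns (chrom, start, end; 0-based half-open) are
#' used; additional narrowPeak columns are ignored.
#'
#' @param path Path to the peak file.
#' @return `GRanges` of peaks.
#' @export
read_peaks <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) < 3L) stop_input("peak file must have at least 3 columns: ", path)
  GenomicRanges::GRanges(
    as.character(dt[[1L]]), IRanges::IRanges(dt[[2L]] + 1L, dt[[3L]])
  )
}

#' Write intervals as a BED file
#'
#' @param gr `GRanges` to write.
#' @param path Output path.
#' @param name Optional character vector for the BED name field (defaults to
#'   the `ocr_id`/`frag_id` column when present, else `.`).
#' @return Invisibly, `path`.
#' @export
write_bed <- function(gr, path, name = NULL) {
  if (is.null(name)) {
    name <- mcols(gr)$ocr_id %||% (mcols(gr)$frag_id %||% rep(".", length(gr)))
  }
  dt <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    name = as.character(name)
  )
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read an OCR read-count matrix
#'
#' Tab-separated with a header row: first column `ocr_id`, remaining columns
#' one per sample.
#'
#' @param path Path to the counts TSV.
#' @return Integer matrix with OCR ids as rownames and sample ids as
#'   colnames.
#' @export
read_count_matrix <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, with = FALSE])
  if (any(m < 0)) stop_input("counts must be non-negative")
  rownames(m) <- ids
  storage.mode(m) <- "integer"
  m
}

#' Read per-sample library sizes
#'
#' Tab-separated, header `sample_id`, `library_size`.
#'
#' @param path Path to the sidecar TSV.
#' @return Named numeric vector of library sizes.
#' @export
read_library_sizes <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  setNames(as.numeric(dt$library_size), as.character(dt$sample_id))
}

ibed_cols <- c("bait_chr", "bait_start", "bait_end", "bait_name",
               "otherEnd_chr", "otherEnd_start", "otherEnd_end",
               "otherEnd_name", "N_reads", "score")

#' Read significant interaction calls in ibed format
#'
#' An ibed file is tab-separated with a header line and ten columns
#' (`bait_chr`, `bait_start`, `bait_end`, `bait_name`, `otherEnd_chr`,
#' `otherEnd_start`, `otherEnd_end`, `otherEnd_name`, `N_reads`, `score`),
#' coordinates 1-based inclusive as exported by the upstream interaction
#' caller. Records below the score threshold are dropped; the threshold is
#' inclusive (score >= threshold is kept).
#'
#' @param path Path to the ibed file.
#' @param cell_type Cell type label attached to every record.
#' @param resolution Fragment resolution of the calls (1 or 4).
#' @param score_threshold Minimum score retained (default 5; set to 0 to keep
#'   everything).
#' @return `data.frame` of fragment interactions with the ten ibed columns
#'   plus `resolution` and `cell_type`.
#' @export
read_ibed <- function(path, cell_type, resolution, score_threshold = 5) {
  raw <- fread(path, sep = "\t", header = TRUE, colClasses = "character",
               fill = TRUE)
  if (ncol(raw) != 10L) {
    stop_input("ibed file must have 10 columns, found ", ncol(raw), ": ", path)
  }
  data.table::setnames(raw, ibed_cols)
  num_cols <- c("bait_start", "bait_end", "otherEnd_start", "otherEnd_end",
                "N_reads", "score")
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(raw[[cc]]))
    bad <- which(is.na(v) | !nzchar(raw[[cc]]))
    if (length(bad)) {
      stop_input("malformed ibed row at line ", bad[1L] + 1L, " (column ",
                 cc, "): ", path)
    }
    data.table::set(raw, j = cc, value = v)
  }
  if (any(raw$score < 0)) stop_input("negative interaction score in ", path)
  if (any(raw$bait_end < raw$bait_start) ||
      any(raw$otherEnd_end < raw$otherEnd_start)) {
    stop_input("interval end before start in ", path)
  }
  out <- raw[raw$score >= score_threshold]
  out[, `:=`(resolution = as.integer(resolution), cell_type = cell_type)]
  as.data.frame(out)
}

#' Write fragment interactions in ibed format
#'
#' @param interactions Interaction table with the ten ibed columns.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ibed <- function(interactions, path) {
  dt <- as.data.table(interactions)[, ibed_cols, with = FALSE]
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Read a sentinel SNP table
#'
#' Tab-separated with header `rsid`, `chrom`, `pos_1based`.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with `rsid`, `chrom`, `pos0` (0-based position).
#' @export
read_sentinels <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (anyDuplicated(dt$rsid)) stop_input("duplicate sentinel rsid in ", path)
  data.frame(rsid = as.character(dt$rsid), chrom = as.character(dt$chrom),
             pos0 = as.integer(dt$pos_1based) - 1L, stringsAsFactors = FALSE)
}

#' Read a proxy SNP table
#'
#' Tab-separated with header `rsid`, `chrom`, `pos_1based`, `sentinel_rsid`,
#' `r2`.
#'
#' @param path Path to the TSV.
#' @param sentinels Optional sentinel table; when given, every
#'   `sentinel_rsid` must appear in it.
#' @return `data.frame` with `rsid`, `chrom`, `pos0`, `sentinel_rsid`, `r2`.
#' @export
read_proxies <- function(path, sentinels = NULL) {
  dt <- fread(path, sep = "\t", header = TRUE)
  if (any(dt$r2 < 0 | dt$r2 > 1)) stop_input("r2 outside [0, 1] in ", path)
  if (!is.null(sentinels) && !all(dt$sentinel_rsid %in% sentinels$rsid)) {
    stop_input("proxy table references unknown sentinel rsids")
  }
  data.frame(rsid = as.character(dt$rsid), chrom = as.character(dt$chrom),
             pos0 = as.integer(dt$pos_1based) - 1L,
             sentinel_rsid = as.character(dt$sentinel_rsid),
             r2 = as.numeric(dt$r2), stringsAsFactors = FALSE)
}

#' Read an eQTL sentinel-gene pair list
#'
#' Tab-separated with header `sentinel_rsid`, `gene_symbol` and optionally
#' `source_label`.
#'
#' @param path Path to the TSV.
#' @return `data.frame` with `sentinel_rsid`, `gene_symbol`, `source_label`.
#' @export
read_eqtl_pairs <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  data.frame(sentinel_rsid = as.character(dt$sentinel_rsid),
             gene_symbol = as.character(dt$gene_symbol),
             source_label = as.character(dt$source_label %||%
                                           rep(NA_character_, nrow(dt))),
             stringsAsFactors = FALSE)
}
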