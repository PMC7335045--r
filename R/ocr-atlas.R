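## Reference open-chromatin atlas: replicate merging, openness calls, CPM
## retention filter.

#' Merge replicate peak sets with a reproducibility filter
#'
#' Union-merges the peaks of all replicates of one cell type (overlapping or
#' bookended intervals are coalesced), annotates each merged peak with the
#' number of replicates contributing at least one overlapping original peak,
#' and removes merged peaks supported by fewer than `min_replicates`
#' replicates.
#'
#' @param peak_sets List of `GRanges`, one per biological replicate.
#' @param min_replicates Minimum replicate support retained (default 2).
#' @return `GRanges` of merged peaks with a `support` metadata column.
#' @export
merge_replicate_peaks <- function(peak_sets, min_replicates = 2L) {
  if (!is.list(peak_sets) || length(peak_sets) == 0L) {
    stop_input("'peak_sets' must be a non-empty list of GRanges")
  }
  all_peaks <- suppressWarnings(do.call(c, unname(peak_sets)))
  merged <- GenomicRanges::reduce(all_peaks)  # default also joins bookended
  support <- Reduce(`+`, lapply(peak_sets, function(p) {
    as.integer(IRanges::overlapsAny(merged, p))
  }))
  merged$support <- support
  sort(GenomeInfoDb::sortSeqlevels(merged[support >= min_replicates]))
}

#' Build the reference OCR atlas across cell types
#'
#' Union-merges replicate-filtered peak sets from all cell types into
#' non-overlapping reference open chromatin regions (OCR), removes any OCR
#' overlapping a blacklist interval, and assigns deterministic ids of the
#' form `chrom:start-end` (BED-style 0-based coordinates).
#'
#' @param merged_sets Named list of `GRanges` (one per cell type), each
#'   already filtered with [merge_replicate_peaks()].
#' @param blacklist Optional `GRanges` of regions to exclude.
#' @return `GRanges` atlas with an `ocr_id` metadata column.
#' @export
build_reference_ocrs <- function(merged_sets, blacklist = NULL) {
  if (!is.list(merged_sets) || length(merged_sets) == 0L) {
    stop_input("'merged_sets' must be a non-empty list of GRanges")
  }
  ref <- GenomicRanges::reduce(suppressWarnings(do.call(c, unname(merged_sets))))
  if (!is.null(blacklist) && length(blacklist)) {
    ref <- ref[!IRanges::overlapsAny(ref, blacklist)]
  }
  ref <- sort(GenomeInfoDb::sortSeqlevels(ref))
  mcols(ref) <- NULL
  ref$ocr_id <- sprintf("%s:%d-%d",
                        as.character(GenomeInfoDb::seqnames(ref)),
                        BiocGenerics::start(ref) - 1L,
                        BiocGenerics::end(ref))
  ref
}

#' Call per-cell-type openness on the reference atlas
#'
#' A reference OCR is considered open in a cell type when at least one
#' replicate of that cell type has a peak overlapping it. Per-cell-type
#' replicate support counts are recorded alongside the boolean calls.
#'
#' @param atlas Reference atlas from [build_reference_ocrs()].
#' @param replicate_peaks Named list (cell type) of lists of replicate peak
#'   `GRanges`.
#' @return Atlas with added metadata columns `support_<cell_type>` (integer)
#'   and `open_<cell_type>` (logical).
#' @export
call_openness <- function(atlas, replicate_peaks) {
  if (is.null(names(replicate_peaks))) {
    stop_input("'replicate_peaks' must be named by cell type")
  }
  for (ct in names(replicate_peaks)) {
    reps <- replicate_peaks[[ct]]
    supp <- Reduce(`+`, lapply(reps, function(p) {
      as.integer(IRanges::overlapsAny(atlas, p))
    }))
    mcols(atlas)[[paste0("support_", ct)]] <- supp
    mcols(atlas)[[paste0("open_", ct)]] <- supp >= 1L
  }
  atlas
}

#' Cell types with openness calls in an atlas
#'
#' @param atlas Atlas with openness calls.
#' @return Character vector of cell type labels.
#' @export
atlas_cell_types <- function(atlas) {
  nm <- names(mcols(atlas))
  sub("^open_", "", nm[startsWith(nm, "open_")])
}

#' Openness indicator for one or more cell types
#'
#' @param atlas Atlas with openness calls.
#' @param cell_types Cell types; an OCR counts as open when open in any of
#'   them.
#' @return Logical vector along the atlas.
#' @export
ocr_is_open <- function(atlas, cell_types) {
  miss <- setdiff(cell_types, atlas_cell_types(atlas))
  if (length(miss)) {
    stop_input("no openness call for cell type(s): ",
               paste(miss, collapse = ", "))
  }
  open <- lapply(cell_types, function(ct) mcols(atlas)[[paste0("open_", ct)]])
  Reduce(`|`, open)
}

#' Count-based OCR retention filter
#'
#' Retains an OCR when at least `ceiling(sample_fraction * n_samples)`
#' samples individually reach `cpm_threshold` counts-per-million, i.e. the
#' "at least 1.5 CPM in the top half of samples" rule used before
#' differential accessibility testing. The CPM comparison is inclusive
#' (exactly 1.5 CPM passes).
#'
#' @param counts Integer matrix of de-duplicated read counts (rows = OCR ids,
#'   columns = samples).
#' @param library_sizes Named numeric vector of per-sample library sizes
#'   (names matching `colnames(counts)`).
#' @param cpm_threshold CPM cutoff (default 1.5).
#' @param sample_fraction Fraction of samples that must pass (default 0.5).
#' @return Character vector of retained OCR ids.
#' @export
cpm_filter <- function(counts, library_sizes, cpm_threshold = 1.5,
                       sample_fraction = 0.5) {
  if (is.null(colnames(counts))) stop_input("'counts' must have column names")
  library_sizes <- library_sizes[colnames(counts)]
  if (anyNA(library_sizes)) {
    stop_input("library sizes missing for some samples")
  }
  if (any(library_sizes <= 0)) stop_input("library sizes must be positive")
  cpm <- sweep(counts, 2L, library_sizes, "/") * 1e6
  pass <- cpm >= cpm_threshold
  need <- ceiling(sample_fraction * ncol(counts))
  rownames(counts)[rowSums(pass) >= need]
}
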