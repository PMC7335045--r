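## Dual-resolution interaction merging and fragment -> OCR projection.

#' Merge 1-fragment and 4-fragment interaction calls
#'
#' Collapses records whose two ends have identical coordinates (after
#' canonical orientation with the lower-coordinate end first) to a single
#' record carrying the maximum score over the duplicates and the union of
#' contributing resolutions. Calls that are merely nested (a 1-fragment call
#' inside a 4-fragment span) are not considered redundant and are all
#' retained; projection unions their evidence downstream.
#'
#' @param calls_1frag,calls_4frag Interaction tables from [read_ibed()] for
#'   the same cell type (either may be empty).
#' @return `data.frame` of merged interactions with a `resolutions` column
#'   (e.g. `"1"`, `"4"`, `"1,4"`) replacing `resolution`.
#' @export
merge_resolutions <- function(calls_1frag, calls_4frag) {
  norm <- function(df) {
    dt <- as.data.table(df)
    if (!nrow(dt)) {
      dt$res_ <- character(0)
    } else if ("resolutions" %in% names(dt)) {
      dt[, res_ := as.character(resolutions)]
    } else if ("resolution" %in% names(dt)) {
      dt[, res_ := as.character(resolution)]
    } else {
      dt[, res_ := NA_character_]
    }
    dt[, intersect(c("resolution", "resolutions"), names(dt)) := NULL]
    dt
  }
  x <- rbindlist(list(norm(calls_1frag), norm(calls_4frag)),
                 use.names = TRUE, fill = TRUE)
  if (!nrow(x)) {
    out <- as.data.frame(x)
    names(out)[names(out) == "res_"] <- "resolutions"
    return(out)
  }
  ct <- unique(x$cell_type)
  if (length(ct) > 1L) {
    stop_input("cannot merge interaction calls from different cell types: ",
               paste(ct, collapse = ", "))
  }
  swap <- (x$otherEnd_chr < x$bait_chr) |
    (x$otherEnd_chr == x$bait_chr &
       (x$otherEnd_start < x$bait_start |
          (x$otherEnd_start == x$bait_start & x$otherEnd_end < x$bait_end)))
  lo <- ifelse(swap,
               paste(x$otherEnd_chr, x$otherEnd_start, x$otherEnd_end),
               paste(x$bait_chr, x$bait_start, x$bait_end))
  hi <- ifelse(swap,
               paste(x$bait_chr, x$bait_start, x$bait_end),
               paste(x$otherEnd_chr, x$otherEnd_start, x$otherEnd_end))
  x[, key_ := paste(lo, hi, sep = "|")]
  x[, ord_ := seq_len(.N)]
  setorder(x, key_, -score, ord_)
  merged <- x[, c(.SD[1L][, !"res_"],
                  list(resolutions = paste(
                    sort(unique(unlist(strsplit(res_, ",", fixed = TRUE)))),
                    collapse = ","))),
              by = key_]
  merged[, c("key_", "ord_") := NULL]
  setorder(merged, bait_chr, bait_start, otherEnd_chr, otherEnd_start)
  as.data.frame(merged)
}

#' Promoter-overlap flags for atlas OCRs
#'
#' @param atlas Reference OCR atlas.
#' @param windows Promoter windows.
#' @return Logical vector: OCR overlaps at least one promoter window.
#' @export
ocr_promoter_flags <- function(atlas, windows) {
  IRanges::overlapsAny(atlas, windows, ignore.strand = TRUE)
}

#' Project fragment interactions onto OCR pairs
#'
#' Emits an OCR pair (O1, O2) when some significant fragment interaction has
#' one end overlapping O1 and the other overlapping O2, at either resolution,
#' with both OCRs called open in `cell_type`. Self pairs and
#' inter-chromosomal pairs are excluded, and pairs where neither OCR overlaps
#' a promoter window are removed. Each pair carries the maximum score over
#' its contributing interactions, the union of contributing resolutions, the
#' prOCR/nonprOCR class of each end, and the distance between OCR midpoints.
#'
#' @param calls Interaction table (typically from [merge_resolutions()];
#'   tables straight from [read_ibed()] also work).
#' @param atlas Reference atlas with openness called for `cell_type`.
#' @param windows Promoter windows.
#' @param cell_type Cell type whose openness calls gate the projection.
#' @return `data.frame` with columns `ocr_a`, `ocr_b`, `cell_type`, `score`,
#'   `resolutions`, `class_a`, `class_b`, `distance`, ordered
#'   deterministically by coordinates (`ocr_a` is the lower-coordinate end).
#' @export
project_to_ocr <- function(calls, atlas, windows, cell_type) {
  open <- ocr_is_open(atlas, cell_type)
  ocr_open <- sort(atlas[open])
  empty <- data.frame(ocr_a = character(0), ocr_b = character(0),
                      cell_type = character(0), score = numeric(0),
                      resolutions = character(0), class_a = character(0),
                      class_b = character(0), distance = numeric(0),
                      stringsAsFactors = FALSE)
  calls <- as.data.table(calls)
  if (!nrow(calls) || !length(ocr_open)) return(empty)
  res_str <- if ("resolutions" %in% names(calls)) {
    as.character(calls$resolutions)
  } else {
    as.character(calls$resolution)
  }
  bait_gr <- GenomicRanges::GRanges(
    calls$bait_chr, IRanges::IRanges(calls$bait_start, calls$bait_end))
  oe_gr <- GenomicRanges::GRanges(
    calls$otherEnd_chr, IRanges::IRanges(calls$otherEnd_start,
                                         calls$otherEnd_end))
  hb <- GenomicRanges::findOverlaps(bait_gr, ocr_open, ignore.strand = TRUE)
  ho <- GenomicRanges::findOverlaps(oe_gr, ocr_open, ignore.strand = TRUE)
  pairs <- merge(
    data.table(i = queryHits(hb), a = subjectHits(hb)),
    data.table(i = queryHits(ho), b = subjectHits(ho)),
    by = "i", allow.cartesian = TRUE
  )
  if (!nrow(pairs)) return(empty)
  pairs[, `:=`(A = pmin(a, b), B = pmax(a, b))]
  chrom <- as.character(GenomeInfoDb::seqnames(ocr_open))
  pairs <- pairs[A != B & chrom[A] == chrom[B]]
  if (!nrow(pairs)) return(empty)
  pr <- ocr_promoter_flags(ocr_open, windows)
  pairs <- pairs[pr[A] | pr[B]]
  if (!nrow(pairs)) return(empty)
  pairs[, `:=`(score = calls$score[i], res = res_str[i])]
  agg <- pairs[, list(
    score = max(score),
    resolutions = paste(sort(unique(unlist(strsplit(res, ",", fixed = TRUE)))),
                        collapse = ",")
  ), by = list(A, B)]
  mid <- (BiocGenerics::start(ocr_open) + BiocGenerics::end(ocr_open)) / 2
  out <- data.table(
    ocr_a = ocr_open$ocr_id[agg$A],
    ocr_b = ocr_open$ocr_id[agg$B],
    cell_type = cell_type,
    score = agg$score,
    resolutions = agg$resolutions,
    class_a = ifelse(pr[agg$A], "prOCR", "nonprOCR"),
    class_b = ifelse(pr[agg$B], "prOCR", "nonprOCR"),
    distance = abs(mid[agg$A] - mid[agg$B]),
    A = agg$A, B = agg$B
  )
  setorder(out, A, B)
  out[, c("A", "B") := NULL]
  as.data.frame(out)
}

#' (Re)classify interaction ends as prOCR/nonprOCR
#'
#' An end is a promoter OCR (prOCR) iff its OCR overlaps at least one
#' promoter window; its partner's identity plays no role. Used to attach or
#' refresh end classes on a projected interaction table.
#'
#' @param interactions Projected OCR interaction table.
#' @param atlas Reference atlas (supplies OCR coordinates by `ocr_id`).
#' @param windows Promoter windows.
#' @return `interactions` with `class_a`/`class_b` columns set.
#' @export
classify_ends <- function(interactions, atlas, windows) {
  pr_ids <- atlas$ocr_id[ocr_promoter_flags(atlas, windows)]
  interactions$class_a <- ifelse(interactions$ocr_a %in% pr_ids,
                                 "prOCR", "nonprOCR")
  interactions$class_b <- ifelse(interactions$ocr_b %in% pr_ids,
                                 "prOCR", "nonprOCR")
  interactions
}

#' Per-gene connectivity and distance summary
#'
#' For every gene with at least one promoter window, counts the distinct
#' partner OCRs its promoter-overlapping OCRs connect to, and summarizes the
#' cis distances of all interactions.
#'
#' @param interactions Projected OCR interaction table.
#' @param atlas Reference atlas.
#' @param windows Promoter windows.
#' @return List with `gene_counts` (`data.frame`: `gene_id`, `gene_symbol`,
#'   `n_partner_ocr`, ordered by `gene_id`) and `distances` (named vector:
#'   n, mean, median, q25, q75).
#' @export
connectivity_stats <- function(interactions, atlas, windows) {
  hits <- GenomicRanges::findOverlaps(atlas, windows, ignore.strand = TRUE)
  gene_map <- unique(data.table(
    ocr_id = atlas$ocr_id[queryHits(hits)],
    gene_id = windows$gene_id[subjectHits(hits)],
    gene_symbol = windows$gene_symbol[subjectHits(hits)]
  ))
  it <- as.data.table(interactions)
  links <- rbindlist(list(
    it[, list(ocr_id = ocr_a, partner = ocr_b)],
    it[, list(ocr_id = ocr_b, partner = ocr_a)]
  ))
  gl <- merge(links, gene_map, by = "ocr_id", allow.cartesian = TRUE)
  counts <- unique(gl[, list(gene_id, gene_symbol, partner)])[
    , list(n_partner_ocr = .N), by = list(gene_id, gene_symbol)]
  all_genes <- unique(data.table(gene_id = windows$gene_id,
                                 gene_symbol = windows$gene_symbol))
  counts <- merge(all_genes, counts, by = c("gene_id", "gene_symbol"),
                  all.x = TRUE)
  counts[is.na(n_partner_ocr), n_partner_ocr := 0L]
  setorder(counts, gene_id)
  d <- interactions$distance
  dist_sum <- c(n = length(d),
                mean = if (length(d)) mean(d) else NA_real_,
                median = if (length(d)) stats::median(d) else NA_real_,
                q25 = if (length(d)) unname(stats::quantile(d, 0.25)) else NA_real_,
                q75 = if (length(d)) unname(stats::quantile(d, 0.75)) else NA_real_)
  list(gene_counts = as.data.frame(counts), distances = dist_sum)
}
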