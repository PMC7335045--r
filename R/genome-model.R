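## Genomic scaffold: restriction fragment maps, promoter windows, baits.
##
## Conventions: all in-memory intervals are GRanges (1-based, closed), the
## standard Bioconductor representation. File formats keep their native
## conventions and are converted at read/write time: BED and rmap/baitmap are
## 0-based half-open, SNP positions are 1-based, ibed coordinates are 1-based
## inclusive. Motif/cut-site positions returned by scan_motif() are 0-based
## offsets (a cut site is the boundary *before* that base), which makes
## fragment boundaries the set {0, sites..., chrom_length} in 0-based space.

#' Scan a DNA sequence for a restriction motif
#'
#' Returns the 0-based start position of every occurrence of `motif` in
#' `sequence`. For a 5' four-cutter such as DpnII (GATC) these positions are
#' used directly as fragment boundaries. `N` bases never match.
#'
#' @param sequence A single character string or [Biostrings::DNAString] over
#'   the alphabet A, C, G, T, N.
#' @param motif Motif to search for (default `"GATC"`).
#' @return Sorted integer vector of 0-based match start positions.
#' @examples
#' scan_motif("GATCGATC")  # 0, 4
#' @export
scan_motif <- function(sequence, motif = "GATC") {
  if (methods::is(sequence, "DNAString")) {
    sequence <- as.character(sequence)
  }
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop_input("'sequence' must be a single DNA string")
  }
  sequence <- toupper(sequence)
  residue <- gsub("[ACGTN]", "", sequence)
  if (nzchar(residue)) {
    stop_input("sequence contains non-DNA characters: '",
               substr(residue, 1L, 10L), "'")
  }
  if (nchar(sequence) == 0L) return(integer(0))
  m <- Biostrings::matchPattern(motif, Biostrings::DNAString(sequence),
                                fixed = TRUE)
  as.integer(BiocGenerics::start(m)) - 1L
}

#' Digest one chromosome at given cut sites
#'
#' Cuts the interval `[0, chrom_length)` at each 0-based `cut_sites` position,
#' returning the resulting restriction fragments as an [IRanges::IRanges]
#' (1-based, closed). Fragments tile the chromosome exactly: the first starts
#' at base 1 and the last ends at `chrom_length`.
#'
#' @param cut_sites Strictly increasing 0-based cut positions, all in
#'   `(0, chrom_length)`.
#' @param chrom_length Chromosome length in bp.
#' @return [IRanges::IRanges] of fragments.
#' @examples
#' digest_chromosome(c(10, 50), 100)  # 1-10, 11-50, 51-100
#' @export
digest_chromosome <- function(cut_sites, chrom_length) {
  chrom_length <- as.integer(chrom_length)
  if (is.na(chrom_length) || chrom_length < 1L) {
    stop_input("'chrom_length' must be a positive integer")
  }
  cut_sites <- as.integer(cut_sites)
  if (length(cut_sites)) {
    if (anyNA(cut_sites)) stop_input("cut sites contain NA")
    if (is.unsorted(cut_sites, strictly = TRUE)) {
      stop_input("cut sites must be strictly increasing")
    }
    if (cut_sites[1L] <= 0L || cut_sites[length(cut_sites)] >= chrom_length) {
      stop_input("cut sites must lie strictly inside (0, chrom_length)")
    }
  }
  bounds <- c(0L, cut_sites, chrom_length)
  IRanges::IRanges(start = bounds[-length(bounds)] + 1L, end = bounds[-1L])
}

#' Build a genome-wide fragment map from cut-site lists
#'
#' @param cut_sites Named list (one element per chromosome) of 0-based cut
#'   positions; chromosomes absent from the list are treated as uncut.
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @return A `GRanges` fragment map with metadata columns `frag_id`
#'   (genome-wide unique, in chromosome order) and `bait` (all `FALSE`);
#'   `metadata(x)$resolution` is 1.
#' @seealso [fragment_map_from_seqs()], [concatenate_fragments()],
#'   [assign_baits()]
#' @export
fragment_map <- function(cut_sites, chrom_lengths) {
  if (is.null(names(chrom_lengths)) || anyNA(names(chrom_lengths))) {
    stop_input("'chrom_lengths' must be a named vector")
  }
  chroms <- names(chrom_lengths)
  per_chrom <- lapply(chroms, function(ch) {
    ir <- digest_chromosome(cut_sites[[ch]] %||% integer(0),
                            chrom_lengths[[ch]])
    GenomicRanges::GRanges(ch, ir)
  })
  gr <- suppressWarnings(do.call(c, per_chrom))
  GenomeInfoDb::seqlevels(gr) <- chroms
  GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_lengths)
  gr$frag_id <- seq_along(gr)
  gr$bait <- rep(FALSE, length(gr))
  S4Vectors::metadata(gr)$resolution <- 1L
  gr
}

#' Build a fragment map by in-silico digestion of sequences
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet] of
#'   chromosome sequences.
#' @param motif Restriction motif (default DpnII, `"GATC"`).
#' @return A resolution-1 fragment map (see [fragment_map()]).
#' @export
fragment_map_from_seqs <- function(seqs, motif = "GATC") {
  if (methods::is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) stop_input("sequences must be named")
  cuts <- lapply(seqs, function(s) {
    x <- scan_motif(s, motif = motif)
    x[x > 0L & x < nchar(s)]  # a motif flush at the start cuts nothing new
  })
  fragment_map(cuts, setNames(nchar(seqs), names(seqs)))
}

#' Concatenate consecutive fragments into k-fragment bins
#'
#' Groups every `k` consecutive restriction fragments of a chromosome into a
#' single bin (the standard trick to trade resolution for statistical power
#' in capture interaction calling). A trailing group of fewer than `k`
#' fragments is kept as a smaller bin so that coordinate coverage is
#' unchanged. A bin is flagged bait if any member fragment is a bait.
#'
#' @param fmap A resolution-1 fragment map from [fragment_map()].
#' @param k Positive integer bin size (default 4).
#' @return A `GRanges` fragment map at resolution `k` with columns `frag_id`
#'   (bin ids), `bait`, `first_frag`, `last_frag`, `n_frag`.
#' @export
concatenate_fragments <- function(fmap, k = 4L) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop_input("'k' must be a positive integer")
  if (!identical(as.integer(S4Vectors::metadata(fmap)$resolution %||% 1L), 1L)) {
    stop_input("'fmap' must be a single-fragment (resolution 1) map")
  }
  dt <- data.table(
    chrom = as.character(GenomeInfoDb::seqnames(fmap)),
    start = BiocGenerics::start(fmap),
    end = BiocGenerics::end(fmap),
    bait = fmap$bait,
    frag_id = fmap$frag_id
  )
  dt[, grp := (seq_len(.N) - 1L) %/% k, by = chrom]
  bins <- dt[, list(start = start[1L], end = end[.N], bait = any(bait),
                    first_frag = frag_id[1L], last_frag = frag_id[.N],
                    n_frag = .N),
             by = list(chrom, grp)]
  gr <- GenomicRanges::GRanges(
    bins$chrom, IRanges::IRanges(bins$start, bins$end),
    seqinfo = GenomeInfoDb::seqinfo(fmap)
  )
  gr$frag_id <- seq_along(gr)
  gr$bait <- bins$bait
  gr$first_frag <- bins$first_frag
  gr$last_frag <- bins$last_frag
  gr$n_frag <- bins$n_frag
  S4Vectors::metadata(gr)$resolution <- k
  gr
}

#' Map single-fragment ids to their containing k-fragment bin
#'
#' @param fmap1 Resolution-1 fragment map.
#' @param fmapk Concatenated map from [concatenate_fragments()].
#' @return Integer vector: for each fragment of `fmap1` (in `frag_id` order),
#'   the bin `frag_id` in `fmapk` containing it.
#' @export
fragment_bin_index <- function(fmap1, fmapk) {
  bin_id <- rep(fmapk$frag_id, fmapk$n_frag)
  member <- unlist(mapply(seq.int, fmapk$first_frag, fmapk$last_frag,
                          SIMPLIFY = FALSE))
  out <- integer(length(fmap1))
  out[member] <- bin_id
  out
}

#' Promoter windows around transcription start sites
#'
#' Builds the strand-aware promoter window of each transcript: 1500 bp
#' upstream to 500 bp downstream of the TSS by default. On the plus strand
#' this is `[tss - 1500, tss + 500)` in 0-based half-open coordinates; on the
#' minus strand `[tss - 500, tss + 1500)`. Windows are clipped at chromosome
#' edges when lengths are supplied.
#'
#' @param transcripts Transcript table as returned by [read_transcripts()]:
#'   columns `transcript_id`, `gene_id`, `gene_symbol`, `chrom`, `strand`,
#'   `tss0` (0-based TSS position), `biotype`.
#' @param upstream,downstream Window extent in bp (defaults 1500 / 500).
#' @param chrom_lengths Optional named vector used to clip windows.
#' @return `GRanges` of promoter windows with metadata columns
#'   `transcript_id`, `gene_id`, `gene_symbol`.
#' @export
promoter_windows <- function(transcripts, upstream = 1500L, downstream = 500L,
                             chrom_lengths = NULL) {
  tx <- as.data.frame(transcripts)
  need <- c("transcript_id", "gene_id", "gene_symbol", "chrom", "strand", "tss0")
  miss <- setdiff(need, names(tx))
  if (length(miss)) stop_input("transcript table lacks columns: ",
                               paste(miss, collapse = ", "))
  if (!all(tx$strand %in% c("+", "-"))) {
    stop_input("transcript strand must be '+' or '-'")
  }
  plus <- tx$strand == "+"
  lo0 <- ifelse(plus, tx$tss0 - upstream, tx$tss0 - downstream)
  hi0 <- ifelse(plus, tx$tss0 + downstream, tx$tss0 + upstream)
  lo0 <- pmax(lo0, 0L)
  if (!is.null(chrom_lengths)) {
    hi0 <- pmin(hi0, as.numeric(chrom_lengths[tx$chrom]))
  }
  keep <- hi0 > lo0
  tx <- tx[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(start = lo0[keep] + 1L, end = hi0[keep])
  )
  if (!is.null(chrom_lengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(chrom_lengths)
    GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_lengths)
  }
  gr$transcript_id <- tx$transcript_id
  gr$gene_id <- tx$gene_id
  gr$gene_symbol <- tx$gene_symbol
  gr
}

#' Flag bait fragments by promoter-window overlap
#'
#' A fragment is a bait iff it overlaps (>= 1 bp) at least one promoter
#' window, mirroring a capture design that targets the restriction fragments
#' containing promoters.
#'
#' @param fmap Fragment map (any resolution).
#' @param windows Promoter windows from [promoter_windows()].
#' @return `fmap` with its `bait` column updated.
#' @export
assign_baits <- function(fmap, windows) {
  fmap$bait <- IRanges::overlapsAny(fmap, windows, ignore.strand = TRUE)
  fmap
}
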