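## GWAS proxy SNP -> gene assignment and nearest-gene categorization.

#' Filter proxy SNPs by LD with their sentinel
#'
#' Retains proxies with `r2 >= r2_threshold` (inclusive). Sentinels listed in
#' the proxy table as their own proxies (r2 = 1) are retained at any
#' threshold.
#'
#' @param proxies Proxy table from [read_proxies()].
#' @param r2_threshold LD threshold in `[0, 1]` (the study's working values
#'   are 0.8 for tight LD and 0.4 relaxed).
#' @return Filtered proxy table.
#' @export
filter_proxies <- function(proxies, r2_threshold) {
  if (!is.numeric(r2_threshold) || length(r2_threshold) != 1L ||
      is.na(r2_threshold) || r2_threshold < 0 || r2_threshold > 1) {
    stop_input("'r2_threshold' must be a number in [0, 1]")
  }
  proxies[proxies$r2 >= r2_threshold, , drop = FALSE]
}

#' Locate proxies in open chromatin
#'
#' A proxy is accessible when its position falls inside a reference OCR
#' called open in at least one of `cell_types`. Because the atlas is
#' non-overlapping, a proxy can land in at most one OCR.
#'
#' @param proxies Proxy table (0-based `pos0`).
#' @param atlas Atlas with openness calls.
#' @param cell_types Cell type(s) whose openness gates accessibility.
#' @return Proxy table restricted to accessible proxies, with an added
#'   `ocr_id` column.
#' @export
locate_in_ocr <- function(proxies, atlas, cell_types) {
  open <- ocr_is_open(atlas, cell_types)
  ocr_open <- atlas[open]
  if (!nrow(proxies)) {
    out <- proxies
    out$ocr_id <- character(0)
    return(out)
  }
  snp_gr <- GenomicRanges::GRanges(
    proxies$chrom, IRanges::IRanges(proxies$pos0 + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(snp_gr, ocr_open, ignore.strand = TRUE)
  out <- proxies[queryHits(hits), , drop = FALSE]
  out$ocr_id <- ocr_open$ocr_id[subjectHits(hits)]
  rownames(out) <- NULL
  out
}

v2g_cols <- function() {
  data.frame(proxy_rsid = character(0), sentinel_rsid = character(0),
             r2 = numeric(0), gene_id = character(0),
             gene_symbol = character(0), route = character(0),
             cell_type = character(0), ocr_id = character(0),
             partner_ocr_id = character(0), stringsAsFactors = FALSE)
}

#' Promoter-resident variant-to-gene pairs
#'
#' Pairs an accessible proxy with every gene that has a promoter window
#' containing the SNP position (route `"promoter_resident"`). Overlapping
#' windows of several genes yield one pair per gene; pairs are deduplicated
#' per (proxy, sentinel, gene).
#'
#' @param accessible Accessible proxy table from [locate_in_ocr()].
#' @param windows Promoter windows.
#' @param cell_type Label recorded on the pairs.
#' @return V2G pair `data.frame` (see [v2g_map()] for columns).
#' @export
promoter_resident_pairs <- function(accessible, windows, cell_type = NA_character_) {
  if (!nrow(accessible)) return(v2g_cols())
  snp_gr <- GenomicRanges::GRanges(
    accessible$chrom, IRanges::IRanges(accessible$pos0 + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(snp_gr, windows, ignore.strand = TRUE)
  if (!length(hits)) return(v2g_cols())
  out <- data.table(
    proxy_rsid = accessible$rsid[queryHits(hits)],
    sentinel_rsid = accessible$sentinel_rsid[queryHits(hits)],
    r2 = accessible$r2[queryHits(hits)],
    gene_id = windows$gene_id[subjectHits(hits)],
    gene_symbol = windows$gene_symbol[subjectHits(hits)],
    route = "promoter_resident",
    cell_type = cell_type,
    ocr_id = accessible$ocr_id[queryHits(hits)],
    partner_ocr_id = NA_character_
  )
  out <- unique(out, by = c("proxy_rsid", "sentinel_rsid", "gene_id"))
  setorder(out, proxy_rsid, sentinel_rsid, gene_id)
  as.data.frame(out)
}

#' Interaction-derived variant-to-gene pairs
#'
#' For an accessible proxy residing in OCR O, every projected interaction
#' involving O nominates the genes whose promoter windows overlap the
#' partner OCR (route `"interaction"`). Pairs are deduplicated per (proxy,
#' sentinel, gene); supporting partner OCR ids are comma-collapsed.
#'
#' @param accessible Accessible proxy table from [locate_in_ocr()].
#' @param ocr_interactions Projected interactions from [project_to_ocr()].
#' @param atlas Reference atlas.
#' @param windows Promoter windows.
#' @return V2G pair `data.frame`.
#' @export
interaction_pairs <- function(accessible, ocr_interactions, atlas, windows) {
  if (!nrow(accessible) || !nrow(ocr_interactions)) return(v2g_cols())
  it <- as.data.table(ocr_interactions)
  links <- rbindlist(list(
    it[, list(ocr_id = ocr_a, partner = ocr_b, cell_type = cell_type)],
    it[, list(ocr_id = ocr_b, partner = ocr_a, cell_type = cell_type)]
  ))
  hits <- GenomicRanges::findOverlaps(atlas, windows, ignore.strand = TRUE)
  gene_map <- unique(data.table(
    partner = atlas$ocr_id[queryHits(hits)],
    gene_id = windows$gene_id[subjectHits(hits)],
    gene_symbol = windows$gene_symbol[subjectHits(hits)]
  ))
  acc <- as.data.table(accessible)
  joined <- merge(acc, links, by = "ocr_id", allow.cartesian = TRUE)
  if (!nrow(joined)) return(v2g_cols())
  joined <- merge(joined, gene_map, by = "partner", allow.cartesian = TRUE)
  if (!nrow(joined)) return(v2g_cols())
  out <- joined[, list(
    r2 = r2[1L],
    cell_type = cell_type[1L],
    ocr_id = ocr_id[1L],
    partner_ocr_id = paste(sort(unique(partner)), collapse = ",")
  ), by = list(proxy_rsid = rsid, sentinel_rsid, gene_id, gene_symbol)]
  out[, route := "interaction"]
  data.table::setcolorder(out, names(v2g_cols()))
  setorder(out, proxy_rsid, sentinel_rsid, gene_id)
  as.data.frame(out)
}

#' Nearest gene by TSS distance
#'
#' For each SNP, the gene minimizing the smallest `|TSS - position|` over its
#' transcripts; ties are broken by lexicographically smallest `gene_id`.
#'
#' @param snps `data.frame` with `rsid`, `chrom`, `pos0`.
#' @param transcripts Transcript table; restrict it beforehand to choose the
#'   gene universe (e.g. genes with captured promoters).
#' @return Character vector of nearest `gene_id`s, named by `rsid`.
#' @export
nearest_gene <- function(snps, transcripts) {
  if (!nrow(snps)) return(setNames(character(0), character(0)))
  tx <- as.data.table(transcripts)
  sn <- as.data.table(snps[, c("rsid", "chrom", "pos0")])
  missing_chr <- setdiff(unique(sn$chrom), unique(tx$chrom))
  if (length(missing_chr)) {
    stop_input("no transcripts on chromosome(s): ",
               paste(missing_chr, collapse = ", "))
  }
  j <- merge(sn, tx[, list(chrom, gene_id, tss0)], by = "chrom",
             allow.cartesian = TRUE)
  j[, d := abs(tss0 - pos0)]
  per_gene <- j[, list(d = min(d)), by = list(rsid, gene_id)]
  setorder(per_gene, rsid, d, gene_id)
  best <- per_gene[, .SD[1L], by = rsid]
  setNames(best$gene_id, best$rsid)[sn$rsid]
}

#' Categorize variants by their relation to the nearest gene
#'
#' Every proxy with at least one interaction-route gene receives exactly one
#' category: `nearest_only` when its interaction-derived gene set is exactly
#' the nearest gene, `nearest_plus_distant` when the set contains the
#' nearest gene plus at least one other, and `skip` when the nearest gene is
#' absent from the set. Proxies without interaction-route pairs are not
#' categorized.
#'
#' @param v2g_pairs V2G pair table (only `route == "interaction"` rows are
#'   used).
#' @param proxies Proxy table supplying SNP positions.
#' @param transcripts Transcript table defining the nearest-gene universe.
#' @param gene_universe `"captured"` (default) restricts the universe to
#'   genes with at least one promoter window in `windows`; `"all"` uses every
#'   annotated gene.
#' @param windows Promoter windows (required for `gene_universe =
#'   "captured"`).
#' @return `data.frame` with `proxy_rsid`, `nearest_gene_id`, `category`.
#' @export
categorize_variants <- function(v2g_pairs, proxies, transcripts,
                                gene_universe = c("captured", "all"),
                                windows = NULL) {
  gene_universe <- match.arg(gene_universe)
  pairs <- v2g_pairs[v2g_pairs$route == "interaction", , drop = FALSE]
  if (!nrow(pairs)) {
    return(data.frame(proxy_rsid = character(0),
                      nearest_gene_id = character(0),
                      category = character(0), stringsAsFactors = FALSE))
  }
  tx <- transcripts
  if (gene_universe == "captured") {
    if (is.null(windows)) {
      stop_input("'windows' is required for gene_universe = \"captured\"")
    }
    tx <- tx[tx$gene_id %in% unique(windows$gene_id), , drop = FALSE]
  }
  snps <- unique(proxies[proxies$rsid %in% pairs$proxy_rsid,
                         c("rsid", "chrom", "pos0")])
  nearest <- nearest_gene(snps, tx)
  sets <- split(pairs$gene_id, pairs$proxy_rsid)
  rsids <- names(sets)
  category <- vapply(rsids, function(rs) {
    gset <- unique(sets[[rs]])
    ng <- nearest[[rs]]
    if (identical(gset, ng)) return("nearest_only")
    if (ng %in% gset) return("nearest_plus_distant")
    "skip"
  }, character(1))
  out <- data.frame(proxy_rsid = rsids,
                    nearest_gene_id = unname(nearest[rsids]),
                    category = unname(category), stringsAsFactors = FALSE)
  out[order(out$proxy_rsid), , drop = FALSE]
}

#' Summarize variant categories
#'
#' @param categories Output of [categorize_variants()].
#' @return `data.frame` with one row per category (`nearest_only`,
#'   `nearest_plus_distant`, `skip`): `n` and `fraction` (fractions sum to 1
#'   for non-empty input; all zero otherwise).
#' @export
summarize_categories <- function(categories) {
  levels <- c("nearest_only", "nearest_plus_distant", "skip")
  n <- vapply(levels, function(l) sum(categories$category == l), integer(1))
  total <- sum(n)
  data.frame(category = levels, n = unname(n),
             fraction = if (total > 0) unname(n) / total else rep(0, 3L),
             stringsAsFactors = FALSE)
}

#' Full variant-to-gene map for one cell type
#'
#' Convenience wrapper: filters proxies by LD, locates them in open
#' chromatin, emits promoter-resident and interaction-route pairs, and
#' categorizes interaction-connected proxies.
#'
#' @param proxies Proxy table.
#' @param atlas Atlas with openness calls.
#' @param ocr_interactions Projected interactions (from [project_to_ocr()]).
#' @param windows Promoter windows.
#' @param transcripts Transcript table.
#' @param cell_types Cell type(s) gating accessibility (openness in any
#'   qualifies).
#' @param r2_threshold LD threshold (default 0.4, the study's relaxed
#'   threshold).
#' @param gene_universe Nearest-gene universe, see [categorize_variants()].
#' @return List with `accessible`, `pairs`, `categories`,
#'   `category_summary`.
#' @export
v2g_map <- function(proxies, atlas, ocr_interactions, windows, transcripts,
                    cell_types, r2_threshold = 0.4,
                    gene_universe = "captured") {
  kept <- filter_proxies(proxies, r2_threshold)
  accessible <- locate_in_ocr(kept, atlas, cell_types)
  prom <- promoter_resident_pairs(accessible, windows,
                                  cell_type = paste(cell_types, collapse = "|"))
  inter <- interaction_pairs(accessible, ocr_interactions, atlas, windows)
  pairs <- rbind(prom, inter)
  cats <- categorize_variants(pairs, accessible, transcripts,
                              gene_universe = gene_universe,
                              windows = windows)
  list(accessible = accessible, pairs = pairs, categories = cats,
       category_summary = summarize_categories(cats))
}

#' Write a V2G pair table with categories
#'
#' @param v2g Result of [v2g_map()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_v2g <- function(v2g, path) {
  dt <- as.data.table(v2g$pairs)
  cat_map <- setNames(v2g$categories$category, v2g$categories$proxy_rsid)
  dt[, category := ifelse(route == "interaction",
                          unname(cat_map[proxy_rsid]), NA_character_)]
  fwrite(dt, path, sep = "\t", na = "NA")
  invisible(path)
}
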