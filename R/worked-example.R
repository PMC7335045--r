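#' Worked eQTL-overlap example pair lists
#'
#' Loads the bundled sentinel-gene pair lists that reproduce the comparison
#' of a promoter Capture-C V2G map against a 41-pair eQTL catalog, in which
#' 14 pairs are shared (gene symbols ANKS1A, C6orf106, RMI2, SOCS1, PXK,
#' UHRF1BP1, LYST, NADSYN1, DHCR7, C15orf39, MPI, CSK, ULK3, FAM219B), an
#' overlap of 14/41 = 34%.
#'
#' Only the 14 shared gene symbols are real; every other row — the sentinel
#' rsids and the non-shared pairs on both sides — is a synthetic placeholder
#' (labelled as such in the `source_label` column), so the overlap count and
#' fraction are the only meaningful quantities.
#'
#' @return List with elements `v2g` and `eqtl`, each a pair `data.frame`
#'   (`sentinel_rsid`, `gene_symbol`, `source_label`).
#' @examples
#' ex <- eqtl_overlap_example()
#' overlap_statistic(ex$v2g, ex$eqtl)  # 14
#' @export
eqtl_overlap_example <- function() {
  dir <- system.file("extdata", "eqtl-worked-example", package = "capcv2g",
                     mustWork = TRUE)
  list(v2g = read_eqtl_pairs(file.path(dir, "capturec_pairs.tsv")),
       eqtl = read_eqtl_pairs(file.path(dir, "eqtl_pairs_41.tsv")))
}
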