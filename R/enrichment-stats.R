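## Empirical resampling test for V2G/eQTL overlap and one-sided Fisher
## feature enrichment.

canon_pairs <- function(df) {
  unique(data.frame(sentinel_rsid = as.character(df$sentinel_rsid),
                    gene_symbol = toupper(as.character(df$gene_symbol)),
                    stringsAsFactors = FALSE))
}

pair_key <- function(df) paste(df$sentinel_rsid, df$gene_symbol, sep = "\r")

#' Deduplicated sentinel-gene pairs from a V2G pair table
#'
#' @param v2g_pairs V2G pair table (any route).
#' @return `data.frame` with unique `sentinel_rsid`, upper-cased
#'   `gene_symbol` pairs.
#' @export
sentinel_gene_pairs <- function(v2g_pairs) {
  canon_pairs(v2g_pairs)
}

#' Overlap between two sentinel-gene pair sets
#'
#' Counts pairs present in both sets, matching on (sentinel rsid, upper-cased
#' gene symbol); duplicates within either input count once.
#'
#' @param v2g_pairs,eqtl_pairs Tables with `sentinel_rsid` and `gene_symbol`
#'   columns.
#' @return Integer overlap.
#' @export
overlap_statistic <- function(v2g_pairs, eqtl_pairs) {
  a <- canon_pairs(v2g_pairs)
  b <- canon_pairs(eqtl_pairs)
  sum(pair_key(a) %in% pair_key(b))
}

#' Candidate sentinel-gene pool within a distance window
#'
#' For each sentinel, collects every gene with at least one TSS within
#' `window_bp` of the sentinel position (the study uses 5 Mb); the pool is
#' the union of these (sentinel, gene) pairs, deduplicated. Sentinels on
#' chromosomes without annotation contribute nothing (with a warning).
#'
#' @param sentinels Sentinel table (`rsid`, `chrom`, `pos0`).
#' @param transcripts Transcript table.
#' @param window_bp Half-width of the candidate window in bp (default 5e6).
#' @return `data.frame` with `sentinel_rsid`, `gene_id`, `gene_symbol`.
#' @export
build_null_pool <- function(sentinels, transcripts, window_bp = 5e6) {
  tx <- as.data.table(transcripts)
  sn <- as.data.table(sentinels)
  orphan <- setdiff(unique(sn$chrom), unique(tx$chrom))
  if (length(orphan)) {
    warning("sentinel(s) on unannotated chromosome(s) contribute no pairs: ",
            paste(orphan, collapse = ", "))
  }
  j <- merge(sn[, list(sentinel_rsid = rsid, chrom, pos0)],
             tx[, list(chrom, gene_id, gene_symbol, tss0)],
             by = "chrom", allow.cartesian = TRUE)
  j <- j[abs(tss0 - pos0) <= window_bp]
  out <- unique(j[, list(sentinel_rsid, gene_id,
                         gene_symbol = toupper(gene_symbol))])
  setorder(out, sentinel_rsid, gene_symbol, gene_id)
  as.data.frame(out)
}

#' Empirical resampling test of V2G/eQTL overlap
#'
#' Computes the observed overlap between the V2G sentinel-gene pairs and the
#' eQTL pairs, then builds a Monte-Carlo null by repeatedly drawing the same
#' number of pairs from the candidate pool and counting their overlap with
#' the eQTL set. The empirical p-value uses the add-one correction
#' `p = (1 + #[null >= observed]) / (reps + 1)`, so it is never exactly 0;
#' fold enrichment is observed over the null mean.
#'
#' @param v2g_pairs V2G pair table (deduplicated internally at
#'   sentinel-gene level).
#' @param eqtl_pairs eQTL pair table.
#' @param pool Candidate pool from [build_null_pool()].
#' @param reps Number of resampling repetitions (the study uses 100,000).
#' @param seed Optional integer seed for reproducibility.
#' @param replace Draw pairs with replacement within a repetition? Default
#'   `FALSE`: each null draw is a set of distinct pairs, mimicking the
#'   observed pair set.
#' @return An object of class `empirical_test`: list with `observed`,
#'   `draw_size`, `reps`, `null_mean`, `null_hist` (`data.frame` of overlap
#'   value and count), `fold_enrichment` (`NA` when the null mean is 0),
#'   `p_value`, `seed`.
#' @export
empirical_overlap_test <- function(v2g_pairs, eqtl_pairs, pool, reps = 100000L,
                                   seed = NULL, replace = FALSE) {
  reps <- as.integer(reps)
  if (is.na(reps) || reps < 1L) stop_input("'reps' must be >= 1")
  obs_pairs <- canon_pairs(v2g_pairs)
  eqtl <- canon_pairs(eqtl_pairs)
  pool_c <- canon_pairs(pool)
  n_draw <- nrow(obs_pairs)
  n_pool <- nrow(pool_c)
  if (!replace && n_pool < n_draw) {
    stop_input("candidate pool (", n_pool, ") smaller than the number of ",
               "observed pairs (", n_draw, ")")
  }
  observed <- overlap_statistic(obs_pairs, eqtl)
  in_eqtl <- pair_key(pool_c) %in% pair_key(eqtl)
  if (!is.null(seed)) set.seed(as.integer(seed))
  null <- if (n_draw == 0L) {
    integer(reps)
  } else {
    vapply(seq_len(reps), function(i) {
      sum(in_eqtl[sample.int(n_pool, n_draw, replace = replace)])
    }, integer(1))
  }
  null_mean <- mean(null)
  hist <- as.data.frame(table(null), stringsAsFactors = FALSE)
  names(hist) <- c("overlap", "count")
  hist$overlap <- as.integer(hist$overlap)
  structure(list(
    observed = observed,
    draw_size = n_draw,
    reps = reps,
    null_mean = null_mean,
    null_hist = hist,
    fold_enrichment = if (null_mean > 0) observed / null_mean else NA_real_,
    p_value = (1 + sum(null >= observed)) / (reps + 1),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  ), class = "empirical_test")
}

#' @export
print.empirical_test <- function(x, ...) {
  cat("Empirical overlap test\n")
  cat(sprintf("  observed overlap : %d (of %d drawn pairs)\n",
              x$observed, x$draw_size))
  cat(sprintf("  null mean        : %.3f (%d reps)\n", x$null_mean, x$reps))
  cat(sprintf("  fold enrichment  : %s\n",
              ifelse(is.na(x$fold_enrichment), "undefined",
                     sprintf("%.2f", x$fold_enrichment))))
  cat(sprintf("  empirical p      : %.3g\n", x$p_value))
  invisible(x)
}

#' One-sided Fisher feature enrichment
#'
#' Compares hit rates between two feature sets with the cross-product odds
#' ratio `(hits_a * (total_b - hits_b)) / ((total_a - hits_a) * hits_b)` and
#' a one-sided (greater) p-value from the hypergeometric upper tail of
#' `hits_a` given the table margins.
#'
#' @param hits_a,total_a Hits and total for set A.
#' @param hits_b,total_b Hits and total for set B.
#' @return An object of class `fisher_enrichment`: list with `table` (2x2
#'   counts), `odds_ratio` (`NA` when a denominator is 0), `p_value`.
#' @export
fisher_feature_enrichment <- function(hits_a, total_a, hits_b, total_b) {
  if (any(c(hits_a, total_a, hits_b, total_b) < 0) ||
      hits_a > total_a || hits_b > total_b || total_a == 0 || total_b == 0) {
    stop_input("invalid 2x2 margins")
  }
  tab <- matrix(c(hits_a, total_a - hits_a, hits_b, total_b - hits_b),
                nrow = 2L, byrow = TRUE,
                dimnames = list(c("a", "b"), c("hit", "miss")))
  denom <- (total_a - hits_a) * hits_b
  or <- if (denom == 0) NA_real_ else (hits_a * (total_b - hits_b)) / denom
  white <- hits_a + hits_b
  black <- (total_a - hits_a) + (total_b - hits_b)
  p <- stats::phyper(hits_a - 1, white, black, total_a, lower.tail = FALSE)
  structure(list(table = tab, odds_ratio = or, p_value = p),
            class = "fisher_enrichment")
}

#' @export
print.fisher_enrichment <- function(x, ...) {
  cat("One-sided Fisher feature enrichment\n")
  print(x$table)
  cat(sprintf("  odds ratio : %s\n",
              ifelse(is.na(x$odds_ratio), "undefined",
                     sprintf("%.3f", x$odds_ratio))))
  cat(sprintf("  p (greater): %.3g\n", x$p_value))
  invisible(x)
}
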