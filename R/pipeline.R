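## Stage orchestration: reproducible end-to-end runs with a manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list with analysis defaults (score
#' threshold 5, relaxed LD threshold 0.4, CPM rule 1.5 in half the samples,
#' two-replicate rule, promoter window -1500/+500, 5 Mb eQTL pool, 100,000
#' resampling reps). `inputs` holds the file paths each stage consumes; the
#' `simulate` stage fills them in automatically.
#'
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return Named configuration list.
#' @export
default_config <- function(seed = 1L, out_dir = "capcv2g_run") {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    cell_types = c("tfh", "naive"),
    target_cell_type = "tfh",
    accessibility_cell_types = c("tfh", "naive"),
    min_replicates = 2L,
    score_threshold = 5,
    r2_threshold = 0.4,
    cpm_threshold = 1.5,
    cpm_sample_fraction = 0.5,
    promoter_upstream = 1500L,
    promoter_downstream = 500L,
    gene_universe = "captured",
    eqtl_window_bp = 5e6,
    eqtl_reps = 100000L,
    sim = list(),
    inputs = list()
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a YAML file and merges it over [default_config()]; unknown keys are
#' rejected.
#'
#' @param path Path to the YAML config.
#' @return Configuration list.
#' @export
load_config <- function(path) {
  check_input_file(path, "config")
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) {
    stop_input("unknown config key(s): ", paste(bad, collapse = ", "))
  }
  cfg[names(user)] <- user
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

check_input_file <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop_input("missing ", what, " input file: ",
               if (is.null(path)) "<not set>" else path)
  }
  invisible(path)
}

pipeline_stages <- c("simulate", "digest", "atlas", "project",
                     "map-variants", "eqtl-test", "run-all")

log_msg <- function(...) message("[capcv2g] ", sprintf(...))

manifest_add <- function(state, stage, outputs) {
  entry <- list(stage = stage,
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                outputs = lapply(outputs, function(p) {
                  list(path = p, md5 = unname(tools::md5sum(p)))
                }))
  state$manifest$stages[[stage]] <- entry
  state
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              null = "null"), tmp)
  unname(tools::md5sum(tmp))
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (write a synthetic study and register its files as
#' inputs), `digest` (fragment maps, promoter windows, baits), `atlas`
#' (replicate merge, reference OCRs, openness, CPM retention), `project`
#' (read + merge ibed calls, project onto OCR pairs), `map-variants` (V2G
#' pairs and nearest-gene categories), `eqtl-test` (empirical overlap test),
#' and `run-all` (everything in order plus the manifest).
#'
#' @param name Stage name.
#' @param config Configuration list (see [default_config()]).
#' @param state State list returned by a previous stage (carries in-memory
#'   objects between stages); a fresh one is created when `NULL`.
#' @return Updated state list; stage outputs are under
#'   `state$outputs[[name]]` and files under `config$out_dir`.
#' @export
run_stage <- function(name, config, state = NULL) {
  if (!name %in% pipeline_stages) {
    stop_input("unknown stage '", name, "'; expected one of: ",
               paste(pipeline_stages, collapse = ", "))
  }
  if (is.null(state)) {
    state <- list(config = config,
                  manifest = list(config_hash = config_hash(config),
                                  seed = config$seed, stages = list()),
                  outputs = list())
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(name,
         "simulate" = stage_simulate(config, state),
         "digest" = stage_digest(config, state),
         "atlas" = stage_atlas(config, state),
         "project" = stage_project(config, state),
         "map-variants" = stage_map_variants(config, state),
         "eqtl-test" = stage_eqtl(config, state),
         "run-all" = {
           for (s in c("simulate", "digest", "atlas", "project",
                       "map-variants", "eqtl-test")) {
             state <- run_stage(s, state$config, state)
           }
           manifest_path <- file.path(state$config$out_dir, "manifest.json")
           jsonlite::write_json(state$manifest, manifest_path,
                                auto_unbox = TRUE, digits = NA)
           log_msg("manifest written to %s", manifest_path)
           state
         })
}

stage_simulate <- function(config, state) {
  scfg <- do.call(sim_config, c(list(seed = config$seed), config$sim))
  data_dir <- file.path(config$out_dir, "data")
  bundle <- simulate_study(scfg, data_dir)
  log_msg("simulated study: %d loci, %d proxies, seed %d",
          scfg$n_loci, nrow(bundle$variants$proxies), config$seed)
  config$inputs$transcripts <- bundle$files$transcripts
  config$inputs$peaks <- lapply(setNames(nm = scfg$cell_types), function(ct) {
    unlist(bundle$files[sprintf("%s_rep%d", ct,
                                seq_len(scfg$n_replicates))],
           use.names = FALSE)
  })
  config$inputs$counts <- bundle$files$counts
  config$inputs$library_sizes <- bundle$files$library_sizes
  config$inputs$ibed_1frag <- bundle$files$ibed1
  config$inputs$ibed_4frag <- bundle$files$ibed4
  config$inputs$sentinels <- bundle$files$sentinels
  config$inputs$proxies <- bundle$files$proxies
  config$inputs$eqtl <- bundle$files$eqtl
  config$cell_types <- scfg$cell_types
  config$target_cell_type <- scfg$cell_types[1L]
  state$config <- config
  state$sim <- bundle
  state$outputs$simulate <- bundle$files
  manifest_add(state, "simulate",
               list(truth = bundle$files$truth))
}

stage_digest <- function(config, state) {
  check_input_file(config$inputs$transcripts, "transcript annotation")
  tx <- read_transcripts(config$inputs$transcripts)
  if (!is.null(state$sim)) {
    fmap1 <- state$sim$interactions$fmap1
    fmap4 <- state$sim$interactions$fmap4
    chrom_lengths <- state$sim$genome$chrom_lengths
  } else if (!is.null(config$inputs$fasta)) {
    check_input_file(config$inputs$fasta, "genome FASTA")
    seqs <- Biostrings::readDNAStringSet(config$inputs$fasta)
    fmap1 <- fragment_map_from_seqs(seqs)
    fmap4 <- NULL
    chrom_lengths <- GenomeInfoDb::seqlengths(fmap1)
  } else {
    check_input_file(config$inputs$rmap, "fragment map (rmap)")
    fmap1 <- read_rmap(config$inputs$rmap)
    fmap4 <- NULL
    chrom_lengths <- GenomeInfoDb::seqlengths(fmap1)
  }
  windows <- promoter_windows(tx, upstream = config$promoter_upstream,
                              downstream = config$promoter_downstream,
                              chrom_lengths = chrom_lengths)
  fmap1 <- assign_baits(fmap1, windows)
  if (is.null(fmap4)) fmap4 <- concatenate_fragments(fmap1, 4L)
  out <- list(
    rmap1 = write_rmap(fmap1, file.path(config$out_dir, "fragments_1frag.rmap")),
    rmap4 = write_rmap(fmap4, file.path(config$out_dir, "fragments_4frag.rmap")),
    baitmap1 = write_baitmap(fmap1, windows,
                             file.path(config$out_dir, "fragments_1frag.baitmap"))
  )
  log_msg("digest: %d fragments, %d bins, %d promoter windows",
          length(fmap1), length(fmap4), length(windows))
  state$transcripts <- tx
  state$fmap1 <- fmap1
  state$fmap4 <- fmap4
  state$windows <- windows
  state$outputs$digest <- out
  manifest_add(state, "digest", out)
}

stage_atlas <- function(config, state) {
  peak_files <- config$inputs$peaks
  if (is.null(peak_files)) stop_input("missing peak input files")
  peaks <- lapply(peak_files, function(paths) {
    lapply(paths, function(p) read_peaks(check_input_file(p, "peak")))
  })
  merged <- lapply(peaks, merge_replicate_peaks,
                   min_replicates = config$min_replicates)
  blacklist <- NULL
  if (!is.null(config$inputs$blacklist)) {
    blacklist <- read_peaks(check_input_file(config$inputs$blacklist,
                                             "blacklist"))
  }
  atlas <- build_reference_ocrs(merged, blacklist)
  atlas <- call_openness(atlas, peaks)
  retained <- NULL
  if (!is.null(config$inputs$counts)) {
    counts <- read_count_matrix(check_input_file(config$inputs$counts,
                                                 "count matrix"))
    lib <- read_library_sizes(check_input_file(config$inputs$library_sizes,
                                               "library sizes"))
    common <- intersect(rownames(counts), atlas$ocr_id)
    retained <- cpm_filter(counts[common, , drop = FALSE], lib,
                           cpm_threshold = config$cpm_threshold,
                           sample_fraction = config$cpm_sample_fraction)
  }
  atlas_path <- file.path(config$out_dir, "reference_ocrs.bed")
  write_bed(atlas, atlas_path)
  open_path <- file.path(config$out_dir, "ocr_openness.tsv")
  fwrite(as.data.table(as.data.frame(mcols(atlas))), open_path, sep = "\t")
  out <- list(atlas = atlas_path, openness = open_path)
  if (!is.null(retained)) {
    ret_path <- file.path(config$out_dir, "cpm_retained_ocrs.txt")
    writeLines(retained, ret_path)
    out$cpm_retained <- ret_path
  }
  log_msg("atlas: %d reference OCRs (%s)%s", length(atlas),
          paste(sprintf("%s open: %d", atlas_cell_types(atlas),
                        vapply(atlas_cell_types(atlas), function(ct)
                          sum(ocr_is_open(atlas, ct)), integer(1))),
                collapse = ", "),
          if (is.null(retained)) "" else
            sprintf("; %d pass the CPM filter", length(retained)))
  state$atlas <- atlas
  state$cpm_retained <- retained
  state$outputs$atlas <- out
  manifest_add(state, "atlas", out)
}

stage_project <- function(config, state) {
  if (is.null(state$windows)) state <- run_stage("digest", config, state)
  if (is.null(state$atlas)) state <- run_stage("atlas", state$config, state)
  config <- state$config
  ct <- config$target_cell_type
  calls1 <- read_ibed(check_input_file(config$inputs$ibed_1frag, "ibed"),
                      cell_type = ct, resolution = 1L,
                      score_threshold = config$score_threshold)
  calls4 <- read_ibed(check_input_file(config$inputs$ibed_4frag, "ibed"),
                      cell_type = ct, resolution = 4L,
                      score_threshold = config$score_threshold)
  merged <- merge_resolutions(calls1, calls4)
  projected <- project_to_ocr(merged, state$atlas, state$windows, ct)
  proj_path <- file.path(config$out_dir,
                         sprintf("ocr_interactions_%s.tsv", ct))
  fwrite(as.data.table(projected), proj_path, sep = "\t")
  summary <- list(
    cell_type = ct,
    n_fragment_calls = list(res1 = nrow(calls1), res4 = nrow(calls4),
                            merged = nrow(merged)),
    n_ocr_interactions = nrow(projected),
    end_classes = as.list(table(c(projected$class_a, projected$class_b))),
    distance_quantiles = if (nrow(projected)) as.list(stats::quantile(
      projected$distance, c(0.25, 0.5, 0.75))) else list()
  )
  sum_path <- file.path(config$out_dir,
                        sprintf("projection_summary_%s.json", ct))
  jsonlite::write_json(summary, sum_path, auto_unbox = TRUE, digits = NA)
  log_msg("project (%s): %d + %d calls -> %d merged -> %d OCR interactions",
          ct, nrow(calls1), nrow(calls4), nrow(merged), nrow(projected))
  state$interactions <- projected
  state$outputs$project <- list(interactions = proj_path, summary = sum_path)
  manifest_add(state, "project", state$outputs$project)
}

stage_map_variants <- function(config, state) {
  if (is.null(state$interactions)) {
    state <- run_stage("project", config, state)
    config <- state$config
  }
  sentinels <- read_sentinels(check_input_file(config$inputs$sentinels,
                                               "sentinel table"))
  proxies <- read_proxies(check_input_file(config$inputs$proxies,
                                           "proxy table"), sentinels)
  v2g <- v2g_map(proxies, state$atlas, state$interactions, state$windows,
                 state$transcripts,
                 cell_types = config$accessibility_cell_types,
                 r2_threshold = config$r2_threshold,
                 gene_universe = config$gene_universe)
  log_msg(paste("variants: %d proxies in -> %d at r2 >= %.2f -> %d accessible",
                "-> %d pairs (%d genes) -> %d categorized"),
          nrow(proxies), sum(proxies$r2 >= config$r2_threshold),
          config$r2_threshold, nrow(v2g$accessible), nrow(v2g$pairs),
          length(unique(v2g$pairs$gene_id)), nrow(v2g$categories))
  v2g_path <- file.path(config$out_dir, "v2g_pairs.tsv")
  write_v2g(v2g, v2g_path)
  summ <- list(
    n_proxies_in = nrow(proxies),
    n_accessible = nrow(v2g$accessible),
    n_pairs = nrow(v2g$pairs),
    n_genes = length(unique(v2g$pairs$gene_id)),
    categories = v2g$category_summary
  )
  sum_path <- file.path(config$out_dir, "v2g_summary.json")
  jsonlite::write_json(summ, sum_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  state$sentinels <- sentinels
  state$v2g <- v2g
  state$outputs[["map-variants"]] <- list(v2g = v2g_path, summary = sum_path)
  manifest_add(state, "map-variants", state$outputs[["map-variants"]])
}

stage_eqtl <- function(config, state) {
  if (is.null(state$v2g)) {
    state <- run_stage("map-variants", config, state)
    config <- state$config
  }
  eqtl <- read_eqtl_pairs(check_input_file(config$inputs$eqtl, "eQTL pairs"))
  pool <- build_null_pool(state$sentinels, state$transcripts,
                          window_bp = config$eqtl_window_bp)
  test <- empirical_overlap_test(state$v2g$pairs, eqtl, pool,
                                 reps = config$eqtl_reps,
                                 seed = config$seed)
  log_msg("eqtl-test: observed %d, null mean %.3f, fold %.2f, p %.3g",
          test$observed, test$null_mean,
          ifelse(is.na(test$fold_enrichment), NaN, test$fold_enrichment),
          test$p_value)
  res_path <- file.path(config$out_dir, "eqtl_overlap_test.json")
  jsonlite::write_json(
    list(observed = test$observed, draw_size = test$draw_size,
         reps = test$reps, null_mean = test$null_mean,
         fold_enrichment = test$fold_enrichment, p_value = test$p_value,
         seed = test$seed),
    res_path, auto_unbox = TRUE, digits = NA)
  hist_path <- file.path(config$out_dir, "eqtl_null_histogram.tsv")
  fwrite(as.data.table(test$null_hist), hist_path, sep = "\t")
  state$eqtl_test <- test
  state$outputs[["eqtl-test"]] <- list(result = res_path, histogram = hist_path)
  manifest_add(state, "eqtl-test", state$outputs[["eqtl-test"]])
}

#' Run the full pipeline
#'
#' Convenience wrapper for `run_stage("run-all", config)`.
#'
#' @param config Configuration list from [default_config()] or
#'   [load_config()].
#' @return Final state list (see [run_stage()]).
#' @export
run_pipeline <- function(config = default_config()) {
  run_stage("run-all", config)
}
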