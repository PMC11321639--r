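#' Extract pattern matrices for a cohort
#'
#' Reads each sample's fragment file, applies the MAPQ filter, computes the
#' requested fragmentation patterns over the region set, and assembles the
#' per-pattern samples x features matrices.
#'
#' @param sheet Sample sheet from [read_sample_sheet()].
#' @param rs Feature [region_set()].
#' @param ref `RefGenome` (needed for `edm`).
#' @param sizes Named chromosome sizes.
#' @param params A [pattern_params()].
#' @param patterns Subset of [pattern_names()].
#' @param min_mapq MAPQ filter threshold.
#' @return Named list of `PatternMatrix`.
#' @export
extract_cohort_features <- function(sheet, rs, ref = NULL, sizes,
                                    params = pattern_params(),
                                    patterns = pattern_names(), min_mapq = 30L) {
  feats <- lapply(seq_len(nrow(sheet)), function(i) {
    frags <- suppressMessages(quality_filter(read_frag(sheet$path[i]), min_mapq))
    compute_patterns(frags, rs, ref, sizes, params, patterns)
  })
  names(feats) <- sheet$sample
  build_pattern_matrices(feats)
}

#' Pipeline configuration
#'
#' Flat configuration driving [run_pipeline()]. Defaults mirror the
#' package's standard analysis: 200-bp standardized regions, Lowess span
#' 0.75, 10x10 cross-validation, PCA capped at 50 components, top-15000
#' region screen, alpha 0.01 differential threshold, 75-kb gene flank.
#'
#' @param sample_sheet,regions_bed,reference,chrom_sizes Input paths.
#' @param out_dir Output directory.
#' @param task `"binary"`, `"too"`, or `"simulate"`.
#' @param patterns Patterns to compute.
#' @param gc_span Lowess span for GC correction.
#' @param pca_dim PCA component cap (NULL disables reduction).
#' @param repeats,folds,seed Cross-validation settings.
#' @param positive Positive-class label for binary tasks.
#' @param top_k Regions kept by the importance screen.
#' @param sim Optional [sim_config()] for the simulate task.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(sample_sheet = NULL, regions_bed = NULL,
                            reference = NULL, chrom_sizes = NULL,
                            out_dir = ".", task = c("binary", "too", "simulate"),
                            patterns = pattern_names(), gc_span = 0.75,
                            pca_dim = 50L, repeats = 10L, folds = 10L,
                            seed = 1L, positive = "cancer", top_k = 15000L,
                            sim = NULL) {
  structure(list(sample_sheet = sample_sheet, regions_bed = regions_bed,
                 reference = reference, chrom_sizes = chrom_sizes,
                 out_dir = out_dir, task = match.arg(task), patterns = patterns,
                 gc_span = gc_span, pca_dim = pca_dim, repeats = repeats,
                 folds = folds, seed = as.integer(seed), positive = positive,
                 top_k = top_k, sim = sim),
            class = "PipelineConfig")
}

#' Run the end-to-end pipeline
#'
#' `simulate`: generates a synthetic cohort into `out_dir`. `binary`:
#' extracts features, GC-corrects and standardizes them, runs repeated
#' stratified cross-validation per pattern, stacks the IFP ensemble,
#' screens important regions, and writes feature TSVs plus an evaluation
#' report (TSV + JSON). `too`: one-vs-rest tissue-of-origin on the cancer
#' samples (labels taken from the sheet's `label` column). Deterministic
#' for a fixed seed.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a results list (task-dependent).
#' @export
run_pipeline <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (cfg$task == "simulate") {
    sim <- cfg$sim %||% sim_config(seed = cfg$seed)
    return(invisible(simulate_cohort(sim, cfg$out_dir)))
  }
  for (p in c(cfg$sample_sheet, cfg$regions_bed, cfg$reference, cfg$chrom_sizes)) {
    if (!file.exists(p)) stop("missing input file: ", p)
  }
  sizes <- read_chrom_sizes(cfg$chrom_sizes)
  rs <- read_bed(cfg$regions_bed, sizes = sizes)
  ref <- load_reference(cfg$reference)
  sheet <- read_sample_sheet(cfg$sample_sheet)
  mats <- extract_cohort_features(sheet, rs, ref, sizes,
                                  patterns = cfg$patterns)
  for (p in names(mats)) {
    write_pattern_matrix(mats[[p]], file.path(cfg$out_dir,
                                              paste0("features_", p, ".tsv")))
  }
  gc <- region_gc(rs, ref)
  prep <- preprocess_patterns(mats, gc, span = cfg$gc_span)

  if (cfg$task == "too") {
    cancer <- sheet$label != "healthy"
    sub <- lapply(prep, function(pm) {
      pm$values <- pm$values[cancer, , drop = FALSE]; pm
    })
    plan <- make_folds(sheet$label[cancer], cfg$repeats, cfg$folds, cfg$seed)
    too <- too_classify(sub, sheet$label[cancer], plan, pca_dim = cfg$pca_dim)
    jsonlite::write_json(list(first = as.list(too$first),
                              second = as.list(too$second),
                              overall_first = too$overall_first,
                              overall_second = too$overall_second),
                         file.path(cfg$out_dir, "too_report.json"),
                         auto_unbox = TRUE, digits = NA)
    return(invisible(list(too = too, mats = mats)))
  }

  plan <- make_folds(sheet$label, cfg$repeats, cfg$folds, cfg$seed)
  model <- train_ifp(prep, sheet$label, plan, cfg$positive, pca_dim = cfg$pca_dim)
  imp_models <- fit_importance_models(prep, sheet$label, cfg$positive,
                                      seed = cfg$seed)
  imp <- region_importance(imp_models, rs$id)
  top <- top_regions(imp, rs, cfg$top_k)
  fwrite(model$report, file.path(cfg$out_dir, "eval_report.tsv"), sep = "\t")
  jsonlite::write_json(model$report, file.path(cfg$out_dir, "eval_report.json"),
                       digits = NA)
  fwrite(imp, file.path(cfg$out_dir, "region_importance.tsv"), sep = "\t")
  write_bed(top, file.path(cfg$out_dir, "top_regions.bed"))
  scores <- data.table(sample = sheet$sample, label = sheet$label,
                       ifp = model$stack$score)
  fwrite(scores, file.path(cfg$out_dir, "ifp_scores.tsv"), sep = "\t")
  invisible(list(model = model, importance = imp, top_regions = top,
                 scores = scores, mats = mats, prep = prep, rs = rs,
                 sheet = sheet))
}
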