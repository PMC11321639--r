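# shared fixtures, memoized across test files within one run

.fix <- new.env(parent = emptyenv())

# reference with known tiny sequences for motif/GC tests
toy_ref <- function(seqs = c(chr1 = paste(rep("ACGT", 25), collapse = ""))) {
  structure(list(seqs = toupper(seqs),
                 sizes = setNames(nchar(seqs), names(seqs))),
            class = "RefGenome")
}

# small simulated cohort with a strong planted effect (fast; shared)
tiny_cohort <- function() {
  if (!is.null(.fix$tiny)) return(.fix$tiny)
  cfg <- sim_config(seed = 11, n_chrom = 2L, chrom_length = 200000L,
                    n_regions = 20L, n_healthy = 12L, n_cancer = 12L,
                    n_fragments = 3000L, tf_range = c(0.1, 0.5))
  dir <- file.path(tempdir(), "cfpattern-tiny")
  co <- simulate_cohort(cfg, dir)
  sizes <- read_chrom_sizes(co$sizes_path)
  rs <- read_bed(co$regions_bed, sizes = sizes)
  ref <- load_reference(co$ref_path)
  sheet <- read_sample_sheet(co$sheet_path)
  mats <- extract_cohort_features(sheet, rs, ref, sizes)
  prep <- suppressMessages(preprocess_patterns(mats, region_gc(rs, ref)))
  .fix$tiny <- list(cfg = cfg, co = co, sizes = sizes, rs = rs, ref = ref,
                    sheet = sheet, mats = mats, prep = prep)
  .fix$tiny
}

# the seeded default benchmark: 60 healthy vs 60 cancer, 30k fragments each
acceptance_benchmark <- function() {
  if (!is.null(.fix$bench)) return(.fix$bench)
  cfg <- sim_config(seed = 1)
  dir <- file.path(tempdir(), "cfpattern-bench")
  co <- simulate_cohort(cfg, dir)
  sizes <- read_chrom_sizes(co$sizes_path)
  rs <- read_bed(co$regions_bed, sizes = sizes)
  ref <- load_reference(co$ref_path)
  sheet <- read_sample_sheet(co$sheet_path)
  mats <- extract_cohort_features(sheet, rs, ref, sizes)
  prep <- suppressMessages(preprocess_patterns(mats, region_gc(rs, ref)))
  plan <- make_folds(sheet$label, repeats = 10L, folds = 10L, seed = 1L)
  cv <- cross_validate(prep, sheet$label, plan, positive = "cancer")
  st <- stack_ifp(cv, sheet$label, plan, positive = "cancer")
  .fix$bench <- list(cfg = cfg, co = co, sizes = sizes, rs = rs, ref = ref,
                     sheet = sheet, mats = mats, prep = prep, plan = plan,
                     cv = cv, stack = st)
  .fix$bench
}
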