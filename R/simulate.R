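#' Synthetic cohort configuration
#'
#' Parameters of the synthetic cfDNA cohort generator. The healthy
#' fragment-length model is a mono-nucleosomal normal (mean 166 bp, SD 10)
#' mixed with a sub-nucleosomal comb of narrow normals at 83-143 bp in
#' 10-bp steps, reproducing the characteristic nucleosome-protected length
#' peak and 10-bp periodicity of plasma cfDNA. Tumor-derived fragments are
#' shorter (mean 145 bp) with a heavier sub-nucleosomal component; a
#' cancer sample draws each fragment from the tumor model with probability
#' equal to its tumor fraction. Tumor-derived draws see the openness of
#' planted informative regions multiplied by `openness_fold`, and carry an
#' end-motif bias implemented by rejection sampling against the actual
#' reference sequence.
#'
#' @param seed Top-level seed; every downstream draw derives from it.
#' @param n_chrom,chrom_length Toy genome geometry.
#' @param n_regions Regions per chromosome (standardized to 200 bp).
#' @param n_healthy,n_cancer Cohort sizes.
#' @param n_fragments Fragments per sample.
#' @param healthy_len_mean,healthy_len_sd Mono-nucleosomal length model.
#' @param w_sub,sub_means,sub_sd Sub-nucleosomal comb weight and centers.
#' @param tumor_len_mean,tumor_len_sd,tumor_w_sub Tumor length model.
#' @param tf_range Tumor-fraction range; cancer samples draw log-uniformly
#'   within it.
#' @param planted_fraction Fraction of regions planted as informative.
#' @param openness_fold Openness fold-change of planted regions for
#'   tumor-derived draws.
#' @param motif,motif_factor End-motif enriched in tumor fragments and its
#'   enrichment factor.
#' @param bg_fraction Fraction of fragments placed uniformly off-region.
#' @param pos_sd SD (bp) of fragment midpoints around region centers.
#' @param gc_amp Amplitude of a sinusoidal GC landscape (0 = uniform GC).
#' @return A `SimConfig` list.
#' @export
sim_config <- function(seed = 1L, n_chrom = 4L, chrom_length = 1e6L,
                       n_regions = 50L, n_healthy = 60L, n_cancer = 60L,
                       n_fragments = 30000L,
                       healthy_len_mean = 166, healthy_len_sd = 10,
                       w_sub = 0.15, sub_means = seq(83, 143, 10), sub_sd = 3,
                       tumor_len_mean = 145, tumor_len_sd = 10, tumor_w_sub = 0.3,
                       tf_range = c(0.01, 0.5),
                       planted_fraction = 0.1, openness_fold = 1.6,
                       motif = "CCCA", motif_factor = 3,
                       bg_fraction = 0.2, pos_sd = 40, gc_amp = 0) {
  cfg <- list(seed = as.integer(seed), n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              n_regions = as.integer(n_regions),
              n_healthy = as.integer(n_healthy), n_cancer = as.integer(n_cancer),
              n_fragments = as.integer(n_fragments),
              healthy_len_mean = healthy_len_mean, healthy_len_sd = healthy_len_sd,
              w_sub = w_sub, sub_means = sub_means, sub_sd = sub_sd,
              tumor_len_mean = tumor_len_mean, tumor_len_sd = tumor_len_sd,
              tumor_w_sub = tumor_w_sub, tf_range = tf_range,
              planted_fraction = planted_fraction, openness_fold = openness_fold,
              motif = motif, motif_factor = motif_factor,
              bg_fraction = bg_fraction, pos_sd = pos_sd, gc_amp = gc_amp)
  stopifnot(cfg$n_healthy >= 1L, cfg$n_cancer >= 0L, cfg$n_fragments >= 1L,
            w_sub >= 0, w_sub <= 1, tumor_w_sub >= 0, tumor_w_sub <= 1,
            bg_fraction >= 0, bg_fraction <= 1,
            planted_fraction >= 0, planted_fraction <= 1,
            healthy_len_mean > 0, healthy_len_mean < 400,
            tumor_len_mean > 0, tumor_len_mean < 400,
            all(tf_range >= 0), all(tf_range <= 1))
  structure(cfg, class = "SimConfig")
}

#' Generate a toy reference genome
#'
#' Random A/C/G/T sequence per chromosome (`chr1`, `chr2`, ...),
#' deterministic per seed; an optional sinusoidal GC landscape (period
#' 100 kb) can be planted via `gc_amp`.
#'
#' @param cfg A [sim_config()].
#' @return A `RefGenome` (see [load_reference()]).
#' @export
make_reference <- function(cfg) {
  set.seed(derive_seeds(cfg$seed, 1L, "reference"))
  len <- cfg$chrom_length
  seqs <- vapply(seq_len(cfg$n_chrom), function(i) {
    p_gc <- 0.5 + cfg$gc_amp * sin(2 * pi * seq_len(len) / 1e5)
    is_gc <- runif(len) < p_gc
    pick <- runif(len) < 0.5
    base <- ifelse(is_gc, ifelse(pick, "G", "C"), ifelse(pick, "A", "T"))
    paste(base, collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(cfg$n_chrom))
  structure(list(seqs = seqs, sizes = setNames(rep(len, cfg$n_chrom), names(seqs))),
            class = "RefGenome")
}

#' Write a reference genome to FASTA
#'
#' @param ref A `RefGenome`.
#' @param path Output FASTA path.
#' @return The path, invisibly.
#' @export
write_reference <- function(ref, path) {
  ss <- Biostrings::DNAStringSet(ref$seqs)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Generate simulated feature regions
#'
#' Places `n_regions` regularly spaced, jittered candidate regions per
#' chromosome (>= 1 kb apart, away from chromosome ends), standardizes
#' them to 200 bp via [standardize_width()], assigns each a log-normal
#' openness weight, and marks a configured fraction as planted informative
#' regions.
#'
#' @param cfg A [sim_config()].
#' @param sizes Named chromosome sizes (e.g. from [make_reference()]).
#' @return List: `rs` (the 200-bp [region_set()]), `openness` (named
#'   weights), `planted` (ids of informative regions).
#' @export
make_regions <- function(cfg, sizes) {
  set.seed(derive_seeds(cfg$seed, 1L, "regions"))
  margin <- 10000L
  out <- rbindlist(lapply(names(sizes), function(ch) {
    len <- sizes[[ch]]
    spacing <- (len - 2L * margin) / cfg$n_regions
    if (spacing < 1000) stop("chromosome too short for ", cfg$n_regions,
                             " regions with 1 kb spacing")
    ctr <- as.integer(margin + (seq_len(cfg$n_regions) - 1L) * spacing +
                        runif(cfg$n_regions, 400, spacing - 400))
    half <- sample(150:400, cfg$n_regions, replace = TRUE)
    data.table(chrom = ch, start = ctr - half, end = ctr + half,
               id = sprintf("%s_r%03d", ch, seq_len(cfg$n_regions)))
  }))
  raw <- region_set(out$chrom, out$start, out$end, id = out$id,
                    provenance = "simulated-OCR", sizes = sizes)
  rs <- standardize_width(raw, 200L, sizes)
  openness <- setNames(rlnorm(nrow(rs), 0, 0.5), rs$id)
  n_planted <- round(cfg$planted_fraction * nrow(rs))
  planted <- sort(sample(rs$id, n_planted))
  list(rs = rs, openness = openness, planted = planted)
}

# draw fragment lengths from the healthy or tumor mixture
.draw_lengths <- function(n, cfg, tumor) {
  if (n == 0L) return(integer())
  w <- if (tumor) cfg$tumor_w_sub else cfg$w_sub
  mu <- if (tumor) cfg$tumor_len_mean else cfg$healthy_len_mean
  sdv <- if (tumor) cfg$tumor_len_sd else cfg$healthy_len_sd
  sub <- runif(n) < w
  len <- numeric(n)
  len[!sub] <- rnorm(sum(!sub), mu, sdv)
  if (any(sub)) {
    len[sub] <- sample(cfg$sub_means, sum(sub), replace = TRUE) +
      rnorm(sum(sub), 0, cfg$sub_sd)
  }
  pmax(40L, pmin(499L, as.integer(round(len))))
}

#' Simulate one cfDNA sample
#'
#' Draws fragments as a mixture of on-region draws (regions weighted by
#' openness; planted regions up-weighted by `openness_fold` for
#' tumor-derived draws, whose midpoints sit near region centers) and
#' uniform background; lengths come from the healthy mixture or, with
#' probability `tumor_fraction`, the tumor mixture; tumor-derived
#' fragments are motif-biased by rejection against the reference. MAPQ is
#' 60, strands uniform, output sorted.
#'
#' @param cfg A [sim_config()].
#' @param ref A `RefGenome`.
#' @param regions Output of [make_regions()].
#' @param label `"healthy"` or `"cancer"`.
#' @param tumor_fraction Tumor fraction in `[0, 1]` (0 for healthy).
#' @param seed Integer seed for this sample.
#' @param path Optional `.frag`/`.frag.gz` output path.
#' @return Fragment `data.table` (invisibly when `path` given).
#' @export
simulate_sample <- function(cfg, ref, regions, label = c("healthy", "cancer"),
                            tumor_fraction = 0, seed = cfg$seed, path = NULL) {
  label <- match.arg(label)
  set.seed(seed)
  n <- cfg$n_fragments
  rs <- regions$rs
  chroms <- names(ref$sizes)
  tumor <- if (label == "cancer") runif(n) < tumor_fraction else rep(FALSE, n)
  planted_mask <- rs$id %in% regions$planted
  w_healthy <- regions$openness[rs$id]
  w_tumor <- w_healthy * ifelse(planted_mask, cfg$openness_fold, 1)
  ctr <- rs$start + (rs$end - rs$start) %/% 2L

  draw <- function(n_draw, tumor_flag) {
    if (n_draw == 0L) {
      return(data.table(chrom = character(), mid = integer(), len = integer()))
    }
    bg <- runif(n_draw) < cfg$bg_fraction
    n_on <- sum(!bg)
    w <- if (tumor_flag) w_tumor else w_healthy
    ridx <- sample.int(nrow(rs), n_on, replace = TRUE, prob = w)
    on <- data.table(chrom = rs$chrom[ridx],
                     mid = ctr[ridx] + as.integer(round(rnorm(n_on, 0, cfg$pos_sd))))
    bg_chrom <- sample(chroms, sum(bg), replace = TRUE,
                       prob = as.numeric(ref$sizes))
    off <- data.table(chrom = bg_chrom,
                      mid = as.integer(floor(runif(sum(bg), 500, ref$sizes[bg_chrom] - 500))))
    out <- rbind(on, off)
    out[, len := .draw_lengths(.N, cfg, tumor_flag)]
    out
  }

  frags <- rbind(draw(sum(!tumor), FALSE), draw(sum(tumor), TRUE))
  frags[, tumor := c(rep(FALSE, sum(!tumor)), rep(TRUE, sum(tumor)))]
  frags[, start := mid - len %/% 2L]
  # keep fragments inside the chromosome (regions sit >= 10 kb from ends,
  # so only background draws can overflow)
  frags[, start := as.integer(pmax(0L, pmin(start, ref$sizes[chrom] - len)))]
  frags[, end := start + len]
  frags[, strand := sample(c("+", "-"), .N, replace = TRUE)]

  if (label == "cancer" && cfg$motif_factor > 1 && any(frags$tumor)) {
    keep_p <- 1 / cfg$motif_factor
    for (iter in 1:20) {
      idx <- which(frags$tumor)
      if (!length(idx)) break
      motifs <- end_motif(frags[idx], ref, nchar(cfg$motif))
      hit <- !is.na(motifs) & motifs == cfg$motif
      reject <- !hit & runif(length(idx)) >= keep_p
      if (!any(reject)) break
      ri <- idx[reject]
      # redraw rejected tumor fragments afresh (positions and lengths)
      redo <- draw(length(ri), TRUE)
      redo[, tumor := TRUE]
      redo[, start := mid - len %/% 2L]
      redo[, start := as.integer(pmax(0L, pmin(start, ref$sizes[chrom] - len)))]
      redo[, end := start + len]
      redo[, strand := sample(c("+", "-"), .N, replace = TRUE)]
      frags[ri, (names(redo)) := redo]
      frags[setdiff(idx, ri), tumor := FALSE]  # accepted; stop resampling them
    }
    frags[, tumor := NULL]
  } else {
    frags[, tumor := NULL]
  }

  frags[, `:=`(mapq = 60L, mid = NULL, len = NULL)]
  frags <- frags[order(match(chrom, chroms), start)]
  frags <- frags[, .(chrom, start, end, mapq, strand)]
  if (!is.null(path)) {
    write_frag(frags, path)
    return(invisible(frags))
  }
  frags[]
}

#' Simulate a labelled cfDNA cohort
#'
#' Generates the toy reference (FASTA + chromosome sizes), the simulated
#' region set (BED), `.frag.gz` fragment files for every sample, a sample
#' sheet, and a ground-truth table (JSON) with per-sample labels, tumor
#' fractions, a stage surrogate (tumor-fraction tertile among cancers),
#' and the planted region ids. Everything is reproducible from
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return List with the config, file paths, sample sheet, `RefGenome`,
#'   region objects and truth table.
#' @export
simulate_cohort <- function(cfg, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_reference(cfg)
  regions <- make_regions(cfg, ref$sizes)
  ref_path <- file.path(out_dir, "reference.fa")
  write_reference(ref, ref_path)
  sizes_path <- file.path(out_dir, "chrom.sizes")
  write_chrom_sizes(ref$sizes, sizes_path)
  bed_path <- file.path(out_dir, "regions.bed")
  write_bed(regions$rs, bed_path)

  set.seed(derive_seeds(cfg$seed, 1L, "cohort"))
  n <- cfg$n_healthy + cfg$n_cancer
  samples <- c(sprintf("H%03d", seq_len(cfg$n_healthy)),
               sprintf("C%03d", seq_len(cfg$n_cancer)))
  labels <- rep(c("healthy", "cancer"), c(cfg$n_healthy, cfg$n_cancer))
  tf <- numeric(n)
  if (cfg$n_cancer > 0L) {
    lo <- max(cfg$tf_range[1], 1e-4)
    tf[labels == "cancer"] <- exp(runif(cfg$n_cancer, log(lo), log(cfg$tf_range[2])))
  }
  stage <- rep(NA_character_, n)
  if (cfg$n_cancer > 0L) {
    q <- quantile(tf[labels == "cancer"], c(1 / 3, 2 / 3))
    stage[labels == "cancer"] <- c("I", "II", "III")[
      findInterval(tf[labels == "cancer"], q) + 1L]
  }
  sample_seeds <- derive_seeds(cfg$seed, n, "samples")

  paths <- file.path(out_dir, paste0(samples, ".frag.gz"))
  for (i in seq_len(n)) {
    simulate_sample(cfg, ref, regions, label = labels[i], tumor_fraction = tf[i],
                    seed = sample_seeds[i], path = paths[i])
  }
  sheet <- data.table(sample = samples, path = paths, label = labels,
                      stage = stage, tumor_fraction = tf)
  sheet_path <- file.path(out_dir, "samples.csv")
  fwrite(sheet, sheet_path)
  truth <- list(samples = sheet[, .(sample, label, stage, tumor_fraction)],
                planted = regions$planted,
                config = unclass(cfg))
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(config = cfg, dir = out_dir, ref = ref, ref_path = ref_path,
       sizes_path = sizes_path, regions = regions, regions_bed = bed_path,
       sheet = sheet, sheet_path = sheet_path, truth = truth,
       truth_path = truth_path)
}
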