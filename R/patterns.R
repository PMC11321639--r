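#' Pattern computation parameters
#'
#' Tunables shared by the fragmentation-pattern calculators: the windowed
#' protection score (WPS) window (120 bp), the orientation-aware
#' fragmentation (OCF) flank offset (60 bp) and half-width (10 bp, giving
#' the 20-bp flank ranges), the end-motif length k (4), and the standardized
#' region width (200 bp).
#'
#' @param wps_window Sliding protection window in bp; must be even.
#' @param ocf_offset Flank offset from the region center in bp.
#' @param ocf_halfwidth Half-width of each flank range in bp.
#' @param motif_k End-motif length.
#' @param region_width Standardized region width in bp.
#' @param len_filter Optional inclusive length range `c(lo, hi)` applied to
#'   fragments before any calculator; default NULL (no filter).
#' @return A `PatternParams` list.
#' @export
pattern_params <- function(wps_window = 120L, ocf_offset = 60L,
                           ocf_halfwidth = 10L, motif_k = 4L,
                           region_width = 200L, len_filter = NULL) {
  stopifnot(wps_window > 0L, wps_window %% 2L == 0L, ocf_offset > 0L,
            ocf_halfwidth > 0L, motif_k >= 1L, region_width > 0L,
            ocf_offset + ocf_halfwidth <= region_width %/% 2L)
  structure(list(wps_window = as.integer(wps_window),
                 ocf_offset = as.integer(ocf_offset),
                 ocf_halfwidth = as.integer(ocf_halfwidth),
                 motif_k = as.integer(motif_k),
                 region_width = as.integer(region_width),
                 len_filter = len_filter),
            class = "PatternParams")
}

#' Fragment-length binning schemes
#'
#' Presets: `"length31"` — lengths below 300 bp in 30 bins of 10 bp plus one
#' class for fragments of 300 bp and longer (per-chromosome length profile);
#' `"fsd67"` — lengths 65-400 bp in 67 bins of 5 bp, the final bin closed at
#' 400 (fragment size distribution, FSD); `"pfe17"` — below 100 bp, fifteen
#' 10-bp bins over 100-250 bp, and 250 bp and longer (the 17 entropy
#' categories of the promoter fragmentation entropy, PFE).
#'
#' @param name One of `"length31"`, `"fsd67"`, `"pfe17"`.
#' @return A `BinningScheme`: list with `name`, `nbin`, `labels`, and
#'   `assign(len)` mapping lengths to bin index (NA = outside scheme).
#' @export
binning_scheme <- function(name = c("length31", "fsd67", "pfe17")) {
  name <- match.arg(name)
  sch <- switch(name,
    length31 = list(nbin = 31L,
      labels = c(sprintf("len%03d_%03d", seq(0L, 290L, 10L), seq(10L, 300L, 10L)), "len300plus"),
      assign = function(len) {
        i <- ifelse(len >= 300L, 31L, len %/% 10L + 1L)
        ifelse(len < 1L, NA_integer_, as.integer(i))
      }),
    fsd67 = list(nbin = 67L,
      labels = sprintf("fsd%03d_%03d", seq(65L, 395L, 5L), seq(70L, 400L, 5L)),
      assign = function(len) {
        ifelse(len < 65L | len > 400L, NA_integer_,
               as.integer(pmin((len - 65L) %/% 5L, 66L) + 1L))
      }),
    pfe17 = list(nbin = 17L,
      labels = c("lt100", sprintf("pfe%03d_%03d", seq(100L, 240L, 10L), seq(110L, 250L, 10L)), "ge250"),
      assign = function(len) {
        as.integer(ifelse(len < 100L, 1L,
                          ifelse(len >= 250L, 17L, (len - 100L) %/% 10L + 2L)))
      }))
  structure(c(list(name = name), sch), class = "BinningScheme")
}

#' Fragment size-class schemes
#'
#' Presets: `"fsr"` — short 65-150 bp, medium 151-220 bp, long 221-400 bp
#' (inclusive ranges; the fragment size ratio classes); `"delfi"` — short
#' 100-150 bp, long 151-220 bp for short/long ratios over large genome bins.
#'
#' @param name One of `"fsr"`, `"delfi"`.
#' @return A `SizeClassScheme` data.table with columns class, lo, hi.
#' @export
size_class_scheme <- function(name = c("fsr", "delfi")) {
  name <- match.arg(name)
  sch <- switch(name,
    fsr = data.table(class = c("short", "medium", "long"),
                     lo = c(65L, 151L, 221L), hi = c(150L, 220L, 400L)),
    delfi = data.table(class = c("short", "long"),
                       lo = c(100L, 151L), hi = c(150L, 220L)))
  setattr(sch, "scheme", name)
  sch[]
}

# internal: assigned fragments (region_idx not NA) with length column
.assigned <- function(frags, params = NULL) {
  len <- start <- end <- region_idx <- NULL
  a <- frags[!is.na(region_idx)]
  a[, len := end - start]
  if (!is.null(params) && !is.null(params$len_filter)) {
    a <- a[len >= params$len_filter[1] & len <= params$len_filter[2]]
  }
  a
}

# internal: per-chromosome fragment counts -> proportion blocks
.chrom_prop_blocks <- function(a, chroms, nbin, bin_col) {
  out <- numeric(length(chroms) * nbin)
  if (nrow(a)) {
    tab <- a[!is.na(get(bin_col)), .N, by = c("chrom", bin_col)]
    for (ci in seq_along(chroms)) {
      sub <- tab[chrom == chroms[ci]]
      if (nrow(sub)) {
        v <- numeric(nbin)
        v[sub[[bin_col]]] <- sub$N
        out[(ci - 1L) * nbin + seq_len(nbin)] <- v / sum(v)
      }
    }
  }
  out
}

#' Per-chromosome fragment-length profile
#'
#' For each chromosome, the proportion of its region-assigned fragments in
#' each length bin of the scheme; a chromosome's proportions sum to 1 (or
#' are all zero when it has no counted fragments). Blocks are concatenated
#' across chromosomes in the order of `chroms`, giving the 31 x n_chrom
#' length profile or the 67 x n_chrom FSD vector.
#'
#' @param frags Fragments annotated by [assign_to_regions()].
#' @param chroms Ordered chromosome names (feature-block order).
#' @param scheme A [binning_scheme()] (`"length31"` or `"fsd67"`).
#' @param params Optional [pattern_params()].
#' @return Named numeric vector of length `scheme$nbin * length(chroms)`.
#' @export
compute_length_profile <- function(frags, chroms, scheme = binning_scheme("length31"),
                                   params = NULL) {
  a <- .assigned(frags, params)
  a[, bin := scheme$assign(len)]
  v <- .chrom_prop_blocks(a, chroms, scheme$nbin, "bin")
  names(v) <- as.vector(outer(scheme$labels, chroms, function(b, c) paste0(c, ":", b)))
  v
}

#' Promoter fragmentation entropy (PFE) per region
#'
#' Shannon entropy (base 2) of the fragment-length category proportions
#' within each region, over 17 categories: below 100 bp, fifteen 10-bp bins
#' spanning 100-250 bp, and 250 bp and longer. Empty categories contribute
#' zero; a region with no assigned fragments scores 0. Bounded by
#' log2(17) ~ 4.087.
#'
#' @param frags Fragments annotated by [assign_to_regions()].
#' @param rs The [region_set()] scored.
#' @param params Optional [pattern_params()].
#' @return Named numeric vector, one entropy per region.
#' @export
compute_pfe <- function(frags, rs, params = NULL) {
  a <- .assigned(frags, params)
  sch <- binning_scheme("pfe17")
  out <- setNames(numeric(nrow(rs)), rs$id)
  if (nrow(a)) {
    a[, cat := sch$assign(len)]
    ent <- a[, .N, by = .(region_idx, cat)][
      , .(pfe = { p <- N / sum(N); -sum(p * log2(p)) }), by = region_idx]
    out[ent$region_idx] <- ent$pfe
  }
  out
}

#' Fragment size ratio (FSR) per region
#'
#' Proportion of each named size class (default short 65-150 / medium
#' 151-220 / long 221-400 bp) among a region's assigned fragments that fall
#' inside the scheme's covered length union; fragments outside every class
#' are excluded from the denominator. Regions with no in-range fragments
#' score zero in every class. Features are region-major (all classes of a
#' region adjacent).
#'
#' @param frags Fragments annotated by [assign_to_regions()].
#' @param rs The [region_set()] scored.
#' @param scheme A [size_class_scheme()].
#' @param params Optional [pattern_params()].
#' @return Named numeric vector of length `nrow(rs) * nrow(scheme)`.
#' @export
compute_fsr <- function(frags, rs, scheme = size_class_scheme("fsr"), params = NULL) {
  a <- .assigned(frags, params)
  ncls <- nrow(scheme)
  out <- setNames(numeric(nrow(rs) * ncls),
                  as.vector(t(outer(rs$id, scheme$class, paste, sep = ":"))))
  if (nrow(a)) {
    a[, cls := NA_integer_]
    for (i in seq_len(ncls)) {
      a[len >= scheme$lo[i] & len <= scheme$hi[i], cls := i]
    }
    tab <- a[!is.na(cls), .N, by = .(region_idx, cls)]
    tab[, prop := N / sum(N), by = region_idx]
    out[(tab$region_idx - 1L) * ncls + tab$cls] <- tab$prop
  }
  out
}

#' Fragment coverage per region
#'
#' Number of fragment midpoints falling inside each region.
#'
#' @inheritParams compute_pfe
#' @return Named numeric count vector, one per region.
#' @export
compute_coverage <- function(frags, rs, params = NULL) {
  a <- .assigned(frags, params)
  out <- setNames(numeric(nrow(rs)), rs$id)
  if (nrow(a)) {
    tab <- a[, .N, by = region_idx]
    out[tab$region_idx] <- tab$N
  }
  out
}

#' Fragment end counts per region
#'
#' Number of fragment end positions inside each region `[start, end)`: the
#' left end is the fragment start, the right end is its last covered base
#' (`end - 1`). A fragment contributes 0, 1 or 2 depending on how it
#' straddles the region; a fragment spanning the whole region contributes 0.
#' All fragments are considered, not only midpoint-assigned ones.
#'
#' @param frags Fragment `data.table` (midpoint assignment not required).
#' @param rs The [region_set()] scored.
#' @param params Optional [pattern_params()].
#' @return Named numeric count vector, one per region.
#' @export
compute_ends <- function(frags, rs, params = NULL) {
  f <- .with_len_filter(frags, params)
  rs_gr <- as_granges(rs)
  left <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start + 1L, width = 1L))
  right <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$end, width = 1L))
  out <- GenomicRanges::countOverlaps(rs_gr, left) +
    GenomicRanges::countOverlaps(rs_gr, right)
  setNames(as.numeric(out), rs$id)
}

.with_len_filter <- function(frags, params) {
  if (!is.null(params) && !is.null(params$len_filter)) {
    len <- start <- end <- NULL
    frags[(end - start) >= params$len_filter[1] & (end - start) <= params$len_filter[2]]
  } else frags
}

#' Orientation-aware cfDNA fragmentation (OCF) per region
#'
#' At each region's center c, upstream (U, left, smaller-coordinate) and
#' downstream (D, right) fragment-end counts are profiled, and the signed
#' imbalance is summed over two 20-bp flank ranges offset +/-60 bp from the
#' center:
#' \deqn{OCF = \sum_{p=c-70}^{c-50} (D_p - U_p) + \sum_{p=c+50}^{c+70} (U_p - D_p)}
#' Positive OCF indicates the end-orientation asymmetry characteristic of
#' nucleosome-depleted (open) regions. Reported raw (no depth
#' normalization).
#'
#' @param frags Fragment `data.table` (all fragments; midpoint assignment
#'   not required).
#' @param rs The [region_set()] scored (uniform width required).
#' @param params A [pattern_params()] providing `ocf_offset` and
#'   `ocf_halfwidth`.
#' @return Named numeric vector, one signed OCF per region.
#' @export
compute_ocf <- function(frags, rs, params = pattern_params()) {
  f <- .with_len_filter(frags, params)
  off <- params$ocf_offset; hw <- params$ocf_halfwidth
  widths <- rs$end - rs$start
  if (any(widths < 2L * (off + hw))) {
    stop("region narrower than 2*(ocf_offset + ocf_halfwidth)")
  }
  ctr <- rs$start + widths %/% 2L
  u_gr <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$start + 1L, width = 1L))
  d_gr <- GenomicRanges::GRanges(f$chrom, IRanges::IRanges(f$end, width = 1L))
  win <- function(lo, hi) GenomicRanges::GRanges(rs$chrom, IRanges::IRanges(lo + 1L, hi + 1L))
  up <- win(ctr - off - hw, ctr - off + hw)
  dn <- win(ctr + off - hw, ctr + off + hw)
  ocf <- (GenomicRanges::countOverlaps(up, d_gr) - GenomicRanges::countOverlaps(up, u_gr)) +
    (GenomicRanges::countOverlaps(dn, u_gr) - GenomicRanges::countOverlaps(dn, d_gr))
  setNames(as.numeric(ocf), rs$id)
}

#' Integrated fragmentation score (IFS) per region
#'
#' `IFS = n * (1 + l / L)` where n is the number of fragments whose
#' midpoint lies in the region, l their mean length, and L the mean length
#' of all region-assigned fragments on that chromosome. Regions with no
#' fragments (or on chromosomes with no fragments) score 0.
#'
#' @inheritParams compute_pfe
#' @param chroms Ordered chromosome names (defines the per-chromosome mean).
#' @return Named numeric vector, one IFS per region.
#' @export
compute_ifs <- function(frags, rs, chroms = chrom_order(rs$chrom), params = NULL) {
  a <- .assigned(frags, params)
  out <- setNames(numeric(nrow(rs)), rs$id)
  if (nrow(a) == 0L) return(out)
  Ltab <- a[, .(L = mean(len)), by = chrom]
  reg <- a[, .(n = .N, l = mean(len)), by = region_idx]
  reg[, chrom := rs$chrom[region_idx]]
  reg <- merge(reg, Ltab, by = "chrom")
  out[reg$region_idx] <- reg$n * (1 + reg$l / reg$L)
  out
}

#' Windowed protection score (WPS) per region
#'
#' For each locus p of a region, a window of `wps_window` bp (default 120)
#' centered at p (`[p - w/2, p + w/2)`) scores +1 for every fragment
#' spanning the whole window and -1 for every fragment overlapping the
#' window with at least one end inside it; the region's value is the mean
#' per-locus score over its loci. Computed in closed form per
#' fragment-region pair (each fragment's span / partial-overlap locus
#' counts have arithmetic expressions), which equals the per-locus sliding
#' evaluation.
#'
#' @param frags Fragment `data.table` (all fragments; midpoint assignment
#'   not required).
#' @param rs The [region_set()] scored.
#' @param params A [pattern_params()] providing `wps_window`.
#' @return Named numeric vector, one mean WPS per region.
#' @export
compute_wps <- function(frags, rs, params = pattern_params()) {
  f <- .with_len_filter(frags, params)
  half <- params$wps_window %/% 2L
  out <- setNames(numeric(nrow(rs)), rs$id)
  if (nrow(f) == 0L) return(out)
  reg <- data.table(chrom = rs$chrom, ps = rs$start, pe = rs$end - 1L,
                    idx = seq_len(nrow(rs)))
  fr <- data.table(chrom = f$chrom, os = f$start - half + 1L, oe = f$end + half - 1L,
                   fs = f$start, fe = f$end)
  setkey(reg, chrom, ps, pe)
  hits <- foverlaps(fr, reg, by.x = c("chrom", "os", "oe"), nomatch = NULL)
  if (nrow(hits)) {
    hits[, ov := pmin(pe, oe) - pmax(ps, os) + 1L]
    hits[, sp := pmax(0L, pmin(pe, fe - half) - pmax(ps, fs + half) + 1L)]
    tot <- hits[, .(s = sum(2 * as.numeric(sp) - ov)), by = idx]
    out[tot$idx] <- tot$s / (rs$end - rs$start)[tot$idx]
  }
  out
}

#' End-motif (EDM) proportions per chromosome
#'
#' The k (default 4) reference bases at the 5' end of each region-assigned
#' fragment are tallied per chromosome; proportions over the 4^k motifs
#' (lexicographic order) are concatenated across chromosomes. Motifs
#' containing N are skipped (excluded from numerator and denominator); a
#' chromosome with no usable motifs contributes an all-zero block.
#'
#' @param frags Fragments annotated by [assign_to_regions()].
#' @param ref A `RefGenome` from [load_reference()].
#' @param chroms Ordered chromosome names.
#' @param params A [pattern_params()] providing `motif_k`.
#' @return Named numeric vector of length `4^k * length(chroms)`.
#' @export
compute_edm <- function(frags, ref, chroms, params = pattern_params()) {
  a <- .assigned(frags, params)
  kmers <- all_kmers(params$motif_k)
  nb <- length(kmers)
  a[, motif := if (.N) end_motif(a, ref, params$motif_k) else character()]
  a[, bin := match(motif, kmers)]
  v <- .chrom_prop_blocks(a[!is.na(bin)], chroms, nb, "bin")
  names(v) <- as.vector(outer(kmers, chroms, function(b, c) paste0(c, ":", b)))
  v
}

#' DELFI-style short/long fragment ratio per bin
#'
#' Count ratio of short (100-150 bp) to long (151-220 bp) fragments among
#' each bin's midpoint-assigned fragments, for large genome bins (e.g. 5 Mb
#' tiles from [tile_genome()]). Bins with no long fragments score 0.
#'
#' @param frags Fragments annotated by [assign_to_regions()] against the bin
#'   set.
#' @param rs The bin [region_set()].
#' @param params Optional [pattern_params()].
#' @return Named numeric vector, one ratio per bin.
#' @export
compute_delfi_ratio <- function(frags, rs, params = NULL) {
  a <- .assigned(frags, params)
  sch <- size_class_scheme("delfi")
  out <- setNames(numeric(nrow(rs)), rs$id)
  if (nrow(a)) {
    tab <- a[, .(short = sum(len >= sch$lo[1] & len <= sch$hi[1]),
                 long = sum(len >= sch$lo[2] & len <= sch$hi[2])), by = region_idx]
    tab <- tab[long > 0]
    out[tab$region_idx] <- tab$short / tab$long
  }
  out
}

#' Compute all fragmentation patterns for one sample
#'
#' Runs the requested calculators over one sample's fragments and one
#' region set, returning the per-pattern feature vectors with deterministic
#' labels (`chrom:bin` for per-chromosome patterns, region ids otherwise).
#'
#' @param frags Fragment `data.table` (already quality-filtered).
#' @param rs The feature [region_set()].
#' @param ref A `RefGenome` (required for the `edm` pattern).
#' @param sizes Named chromosome sizes; defines chromosome block order.
#' @param params A [pattern_params()].
#' @param patterns Character subset of [pattern_names()].
#' @return Named list of numeric feature vectors, one per pattern.
#' @export
compute_patterns <- function(frags, rs, ref = NULL, sizes,
                             params = pattern_params(),
                             patterns = pattern_names()) {
  stopifnot(all(patterns %in% PATTERNS))
  if ("edm" %in% patterns && is.null(ref)) stop("edm pattern requires a reference genome")
  chroms <- names(sizes)
  a <- assign_to_regions(frags, rs)
  out <- list()
  for (p in patterns) {
    out[[p]] <- switch(p,
      length = compute_length_profile(a, chroms, binning_scheme("length31"), params),
      fsd = compute_length_profile(a, chroms, binning_scheme("fsd67"), params),
      pfe = compute_pfe(a, rs, params),
      fsr = compute_fsr(a, rs, size_class_scheme("fsr"), params),
      coverage = compute_coverage(a, rs, params),
      ends = compute_ends(a, rs, params),
      ocf = compute_ocf(a, rs, params),
      ifs = compute_ifs(a, rs, chroms, params),
      wps = compute_wps(a, rs, params),
      edm = compute_edm(a, ref, chroms, params))
  }
  out
}

#' Assemble per-sample feature lists into pattern matrices
#'
#' @param feature_list Named list (by sample id) of [compute_patterns()]
#'   outputs sharing identical feature axes.
#' @return Named list of `PatternMatrix` objects (samples x features).
#' @export
build_pattern_matrices <- function(feature_list) {
  stopifnot(length(feature_list) > 0L)
  patterns <- names(feature_list[[1]])
  out <- list()
  for (p in patterns) {
    m <- do.call(rbind, lapply(feature_list, `[[`, p))
    rownames(m) <- names(feature_list)
    axis <- if (p %in% REGION_PATTERNS) "region" else "chrom"
    out[[p]] <- pattern_matrix(p, m, axis)
  }
  out
}

#' PatternMatrix container
#'
#' A samples x features numeric matrix tagged with its pattern name, feature
#' axis kind, and preprocessing flags.
#'
#' @param pattern Pattern name.
#' @param values Numeric matrix with sample rownames and feature colnames.
#' @param axis `"region"` or `"chrom"`.
#' @param gc_corrected,standardized Preprocessing flags.
#' @return A `PatternMatrix` object.
#' @export
pattern_matrix <- function(pattern, values, axis = c("region", "chrom"),
                           gc_corrected = FALSE, standardized = FALSE) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    stop("PatternMatrix row/column labels must be unique")
  }
  if (any(!is.finite(values))) stop("PatternMatrix values must be finite")
  structure(list(pattern = pattern, values = values, axis = axis,
                 gc_corrected = gc_corrected, standardized = standardized),
            class = "PatternMatrix")
}

#' @export
print.PatternMatrix <- function(x, ...) {
  cat(sprintf("PatternMatrix '%s' (%s axis): %d samples x %d features%s%s\n",
              x$pattern, x$axis, nrow(x$values), ncol(x$values),
              if (x$gc_corrected) ", GC-corrected" else "",
              if (x$standardized) ", standardized" else ""))
  invisible(x)
}

#' Read / write pattern matrices as TSV
#'
#' Samples x features table; header columns are `pattern:feature-label`,
#' first column `sample`.
#'
#' @param pm A `PatternMatrix`.
#' @param path File path.
#' @return `write_pattern_matrix`: the path invisibly;
#'   `read_pattern_matrix`: a `PatternMatrix`.
#' @export
write_pattern_matrix <- function(pm, path) {
  dt <- as.data.table(pm$values)
  setnames(dt, paste0(pm$pattern, ":", colnames(pm$values)))
  dt <- cbind(data.table(sample = rownames(pm$values)), dt)
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_pattern_matrix
#' @param pattern Pattern name expected in the header prefix.
#' @param axis Feature-axis kind of the stored matrix.
#' @export
read_pattern_matrix <- function(path, pattern, axis = c("region", "chrom")) {
  dt <- fread(path, sep = "\t", header = TRUE)
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt[[1]]
  colnames(m) <- sub(paste0("^", pattern, ":"), "", colnames(m))
  pattern_matrix(pattern, m, match.arg(axis))
}
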