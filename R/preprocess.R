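#' GC fraction of each region's reference sequence
#'
#' G+C proportion with N bases excluded from numerator and denominator;
#' regions of all-N sequence are recorded as NA (missing) and excluded from
#' Lowess fitting downstream.
#'
#' @param rs A [region_set()].
#' @param ref A `RefGenome` from [load_reference()].
#' @return Named numeric vector (region id -> GC fraction in `[0, 1]`).
#' @export
region_gc <- function(rs, ref) {
  bad <- !(rs$chrom %in% names(ref$seqs)) |
    rs$end > ref$sizes[rs$chrom] | rs$start < 0L
  if (any(bad)) stop("region outside reference bounds: ", rs$id[which(bad)[1]])
  seqs <- Biostrings::DNAStringSet(substr(ref$seqs[rs$chrom], rs$start + 1L, rs$end))
  freq <- Biostrings::letterFrequency(seqs, c("G", "C", "N"))
  counted <- (rs$end - rs$start) - freq[, "N"]
  gc <- ifelse(counted > 0, (freq[, "G"] + freq[, "C"]) / counted, NA_real_)
  setNames(as.numeric(gc), rs$id)
}

#' GC-bias correction by locally weighted regression
#'
#' For each sample, fits a Lowess curve (span 0.75 by default) of pattern
#' score versus region GC fraction across regions and replaces scores by
#' residuals (observed minus fitted), removing smooth GC-dependent bias.
#' Applies to region-axis patterns only; per-chromosome matrices (length
#' profile, FSD, EDM) pass through unchanged.
#'
#' @param pm A `PatternMatrix`.
#' @param gc Named GC profile from [region_gc()] covering the matrix columns
#'   (NA = undefined, excluded from the fit).
#' @param span Lowess span (fraction of points in each local fit).
#' @return A `PatternMatrix` with residual values and `gc_corrected = TRUE`.
#' @export
gc_correct <- function(pm, gc, span = 0.75) {
  if (pm$axis != "region") return(pm)
  if (pm$gc_corrected) stop("matrix is already GC-corrected")
  feat <- colnames(pm$values)
  # FSR carries class-suffixed labels (region:class); map back to region ids
  rid <- if (all(feat %in% names(gc))) feat else sub(":[^:]+$", "", feat)
  if (!all(rid %in% names(gc))) {
    stop("GC profile missing for region(s): ",
         paste(head(setdiff(rid, names(gc)), 3), collapse = ", "))
  }
  x <- as.numeric(gc[rid])
  def <- is.finite(x)
  if (sum(def) < 10L) stop("fewer than 10 regions with defined GC; cannot fit Lowess")
  vals <- pm$values
  for (i in seq_len(nrow(vals))) {
    y <- vals[i, ]
    fit <- lowess(x[def], y[def], f = span)
    fitted <- approx(fit$x, fit$y, xout = x[def], rule = 2, ties = mean)$y
    res <- y
    res[def] <- y[def] - fitted
    res[!def] <- y[!def] - mean(fitted)
    vals[i, ] <- res
  }
  pattern_matrix(pm$pattern, vals, pm$axis, gc_corrected = TRUE,
                 standardized = pm$standardized)
}

#' Per-sample Z-score standardization
#'
#' Rescales each sample row to mean 0 and population (n-denominator)
#' standard deviation 1 across its features. Zero-variance rows become
#' all-zero (with a message).
#'
#' @param pm A `PatternMatrix`.
#' @return A standardized `PatternMatrix`.
#' @export
zscore_per_sample <- function(pm) {
  if (pm$standardized) stop("matrix is already standardized")
  vals <- pm$values
  m <- rowMeans(vals)
  s <- apply(vals, 1, pop_sd)
  flat <- s == 0
  if (any(flat)) message(sum(flat), " zero-variance sample row(s) set to 0")
  s[flat] <- 1
  vals <- (vals - m) / s
  vals[flat, ] <- 0
  pattern_matrix(pm$pattern, vals, pm$axis, gc_corrected = pm$gc_corrected,
                 standardized = TRUE)
}

#' Canonical preprocessing of a pattern-matrix list
#'
#' GC-corrects the region-axis matrices then Z-scores every matrix per
#' sample — the canonical order; flags prevent double application.
#'
#' @param mats Named list of `PatternMatrix`.
#' @param gc GC profile from [region_gc()].
#' @param span Lowess span.
#' @return Preprocessed list in the same order.
#' @export
preprocess_patterns <- function(mats, gc, span = 0.75) {
  lapply(mats, function(pm) zscore_per_sample(gc_correct(pm, gc, span)))
}

#' Fit / apply a PCA projection
#'
#' `fit_pca` fits principal components on training rows only (centering by
#' training means, no scaling); `apply_pca` projects any matrix with the
#' frozen training parameters, so held-out rows never influence the
#' projection.
#'
#' @param x Training matrix (samples x features).
#' @param n_components Number of components; must not exceed
#'   `min(nrow(x) - 1, ncol(x))`.
#' @return `fit_pca`: list with `center`, `rotation`, `explained`
#'   (variance ratios); `apply_pca`: the projected matrix.
#' @export
fit_pca <- function(x, n_components) {
  n_components <- as.integer(n_components)
  if (n_components > min(nrow(x) - 1L, ncol(x)) || n_components < 1L) {
    stop("n_components must be in [1, min(samples - 1, features)]")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  list(center = pc$center,
       rotation = pc$rotation,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)])
}

#' @rdname fit_pca
#' @param fit A fitted projection from `fit_pca`.
#' @export
apply_pca <- function(fit, x) {
  sweep(x, 2, fit$center) %*% fit$rotation
}
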