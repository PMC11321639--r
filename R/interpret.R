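#' Fit interpretation models on raw region features
#'
#' Trains one linear SVM per region-resolved pattern (PFE, FSR, coverage,
#' ends, OCF, IFS, WPS) on the full, un-reduced feature matrices — no PCA —
#' so each region keeps its own decision weight(s). Used only for
#' interpretation; classification performance is read from the
#' cross-validated models.
#'
#' The interpretation fit uses a heavily regularized margin (default cost
#' 0.01): with regions on the order of the sample count, the weight vector
#' of a lightly regularized SVM is dominated by margin noise, whereas under
#' strong regularization it approaches the class-centroid difference
#' direction, giving a stable region ranking. Classification models keep
#' the default cost.
#'
#' @param mats Named list of preprocessed `PatternMatrix` containing the
#'   region-resolved patterns.
#' @param labels Sample labels.
#' @param positive Positive-class label.
#' @param seed Integer seed.
#' @param cost SVM cost for the interpretation fit.
#' @return Named list of `BaseModel`, one per region-resolved pattern.
#' @export
fit_importance_models <- function(mats, labels, positive, seed = 1L, cost = 0.01) {
  pats <- intersect(region_pattern_names(), names(mats))
  if (!length(pats)) stop("no region-resolved pattern matrices supplied")
  seeds <- derive_seeds(seed, length(pats), "importance")
  models <- lapply(seq_along(pats), function(i) {
    train_base(mats[[pats[i]]]$values, labels, positive, seed = seeds[i],
               cost = cost)
  })
  names(models) <- pats
  models
}

#' Region importance from linear model weights
#'
#' Each region's importance in a pattern is the absolute value of its
#' linear SVM weight; FSR's three per-class weights are summed into one
#' value per region. Seven per-pattern importances plus their sum are
#' tabulated per region; the per-chromosome patterns (length profile, FSD,
#' EDM) carry no region-specific weights and are excluded.
#'
#' @param models Output of [fit_importance_models()].
#' @param region_ids Region ids defining the table order.
#' @return `data.table` with one row per region: id, one column per
#'   pattern, and `importance` (the row sum).
#' @export
region_importance <- function(models, region_ids) {
  out <- data.table(id = region_ids)
  for (p in names(models)) {
    w <- abs(models[[p]]$weights)
    feat <- names(w)
    if (identical(feat, region_ids) || all(feat %in% region_ids)) {
      v <- setNames(numeric(length(region_ids)), region_ids)
      v[feat] <- w
    } else {
      # class-suffixed labels (FSR): sum |weights| within each region
      rid <- sub(":[^:]+$", "", feat)
      if (!all(rid %in% region_ids)) stop("model features do not map to region ids: ", p)
      agg <- tapply(w, rid, sum)
      v <- setNames(numeric(length(region_ids)), region_ids)
      v[names(agg)] <- agg
    }
    out[, (p) := as.numeric(v)]
  }
  out[, importance := rowSums(.SD), .SDcols = names(models)]
  out[]
}

#' Select top-importance regions
#'
#' The k regions with the largest summed importance; ties are broken by
#' region id order (the table's order), so selections nest as k grows.
#'
#' @param imp Importance table from [region_importance()].
#' @param rs The [region_set()] the table refers to.
#' @param k Number of regions (default 15000); `k >= nrow` returns all.
#' @return A [region_set()] of the selected regions (sorted).
#' @export
top_regions <- function(imp, rs, k = 15000L) {
  stopifnot(k >= 1L)
  ord <- order(-imp$importance, seq_len(nrow(imp)))
  sel <- imp$id[ord[seq_len(min(k, nrow(imp)))]]
  sub <- rs[rs$id %in% sel]
  region_set(sub$chrom, sub$start, sub$end, id = sub$id,
             provenance = paste0(attr(rs, "provenance"), ":top", k))
}

#' Differentially low-IFS signature regions
#'
#' Per region, a two-sided Wilcoxon rank-sum test compares case and
#' control IFS scores; regions with a lower case mean and p below `alpha`
#' (default 0.01, unadjusted) form the signature. Exact enumeration is
#' used when both groups are below 20 samples and scores are tie-free;
#' otherwise the tie-corrected normal approximation.
#'
#' @param ifs A `PatternMatrix` of IFS scores (samples x regions; raw or
#'   preprocessed).
#' @param labels Sample labels.
#' @param alpha Retention p-value threshold.
#' @param positive Case label.
#' @return `data.table`: region id, case_mean, control_mean, p — retained
#'   regions only.
#' @export
differential_low_ifs <- function(ifs, labels, alpha = 0.01, positive = "cancer") {
  case <- labels == positive
  if (!any(case) || all(case)) stop("both classes must be present")
  x <- ifs$values
  res <- rbindlist(lapply(seq_len(ncol(x)), function(j) {
    a <- x[case, j]; b <- x[!case, j]
    exact <- max(sum(case), sum(!case)) < 20L && !anyDuplicated(c(a, b))
    p <- suppressWarnings(wilcox.test(a, b, exact = exact)$p.value)
    data.table(id = colnames(x)[j], case_mean = mean(a), control_mean = mean(b),
               p = p)
  }))
  res[case_mean < control_mean & p < alpha][]
}

#' Map regions to nearby genes
#'
#' Returns the unique genes whose body interval intersects any region
#' expanded by `flank` bp (default 75 kb) on both sides, optionally
#' restricted to a biotype (e.g. protein-coding).
#'
#' @param rs A [region_set()].
#' @param annotation `data.table` with columns chrom, start, end, gene and
#'   optionally biotype (see [read_gene_annotation()]).
#' @param flank Expansion in bp on each side of every region.
#' @param biotype Optional biotype filter.
#' @return Character vector of unique gene ids, in annotation order.
#' @export
map_genes <- function(rs, annotation, flank = 75000L, biotype = NULL) {
  ann <- as.data.table(annotation)
  if (!is.null(biotype) && "biotype" %in% names(ann)) {
    keep <- which(ann[["biotype"]] %in% biotype)
    ann <- ann[keep]
  }
  if (nrow(ann) == 0L || nrow(rs) == 0L) return(character())
  reg <- GenomicRanges::GRanges(rs$chrom,
    IRanges::IRanges(pmax(rs$start - flank, 0L) + 1L, rs$end + flank))
  genes <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(ann$start + 1L, ann$end))
  hit <- GenomicRanges::findOverlaps(genes, reg)
  unique(ann$gene[sort(unique(S4Vectors::queryHits(hit)))])
}

#' Read a gene annotation (BED6 or GFF3 gene lines)
#'
#' BED: chrom, start, end, gene name, (score, strand, optional biotype
#' column 7). GFF3: `gene` features; the gene name is taken from the
#' `gene_name`, `Name` or `ID` attribute and the biotype from
#' `gene_biotype`/`gene_type` (1-based GFF coordinates are converted to the
#' package's 0-based convention).
#'
#' @param path File path (`.bed`, `.gff`, `.gff3`).
#' @return `data.table` with columns chrom, start, end, gene, biotype.
#' @export
read_gene_annotation <- function(path) {
  if (grepl("\\.gff3?(\\.gz)?$", path)) {
    lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
    dt <- fread(text = lines, header = FALSE, sep = "\t")
    keep <- which(dt[[3]] == "gene")
    dt <- dt[keep]
    attr_get <- function(attrs, keys) {
      for (k in keys) {
        m <- regmatches(attrs, regexpr(paste0(k, "=[^;]+"), attrs))
        if (length(m) && nzchar(m)) return(sub(paste0(k, "="), "", m))
      }
      NA_character_
    }
    data.table(chrom = as.character(dt[[1]]), start = as.integer(dt[[4]]) - 1L,
               end = as.integer(dt[[5]]),
               gene = vapply(dt[[9]], attr_get, "", keys = c("gene_name", "Name", "ID")),
               biotype = vapply(dt[[9]], attr_get, "",
                                keys = c("gene_biotype", "gene_type")))
  } else {
    dt <- fread(path, header = FALSE, sep = "\t")
    data.table(chrom = as.character(dt[[1]]), start = as.integer(dt[[2]]),
               end = as.integer(dt[[3]]), gene = as.character(dt[[4]]),
               biotype = if (ncol(dt) >= 7L) as.character(dt[[7]]) else NA_character_)
  }
}

#' Spearman correlation between fragmentation patterns
#'
#' Symmetric Spearman correlation matrix with unit diagonal, applicable to
#' either correlation mode: columns are per-pattern sample prediction
#' probabilities (mode 1) or per-pattern healthy-median region vectors of
#' equal dimension (mode 2).
#'
#' @param x Numeric matrix, one column per pattern.
#' @return Patterns x patterns Spearman correlation matrix.
#' @export
pattern_correlation <- function(x) {
  cor(x, method = "spearman")
}

#' Healthy-median region vectors
#'
#' For each single-value-per-region pattern (PFE, coverage, ends, OCF, IFS,
#' WPS — the six patterns sharing the region dimension), the per-region
#' median over healthy samples, assembled for mode-2 pattern correlation.
#'
#' @param mats Named list of `PatternMatrix`.
#' @param labels Sample labels.
#' @param healthy Healthy-class label.
#' @return Regions x patterns numeric matrix.
#' @export
healthy_median_vectors <- function(mats, labels, healthy = "healthy") {
  pats <- intersect(setdiff(region_pattern_names(), "fsr"), names(mats))
  sel <- labels == healthy
  do.call(cbind, setNames(lapply(pats, function(p) {
    apply(mats[[p]]$values[sel, , drop = FALSE], 2, median)
  }), pats))
}
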