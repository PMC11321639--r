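#' Construct a region set
#'
#' A RegionSet is an ordered, id-labelled collection of genomic intervals in
#' 0-based half-open coordinates, the feature loci over which fragmentation
#' patterns are computed (open-chromatin regions, TSS windows, genome bins,
#' chromosome arms).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors; 0-based half-open interval bounds.
#' @param id Optional unique ids; defaults to `chrom:start-end`.
#' @param provenance Free-text label describing how the set was built.
#' @param sizes Optional named chromosome-length vector; when given, intervals
#'   on unknown chromosomes or exceeding the chromosome length are rejected.
#' @return A `RegionSet`: a `data.table` with columns chrom, start, end, id,
#'   sorted by (chrom, start), with a `provenance` attribute.
#' @export
region_set <- function(chrom, start, end, id = NULL, provenance = "", sizes = NULL) {
  start <- as.integer(start); end <- as.integer(end)
  chrom <- as.character(chrom)
  if (any(!nzchar(chrom))) stop("empty chromosome name")
  if (any(end <= start)) stop("region with end <= start")
  if (any(start < 0)) stop("region with negative start")
  if (!is.null(sizes)) {
    unknown <- setdiff(unique(chrom), names(sizes))
    if (length(unknown)) {
      stop("region(s) on chromosome(s) absent from chromosome sizes: ",
           paste(unknown, collapse = ", "))
    }
    if (any(end > sizes[chrom])) stop("region extends past chromosome end")
  }
  if (is.null(id)) id <- sprintf("%s:%d-%d", chrom, start, end)
  id <- as.character(id)
  if (anyDuplicated(id)) stop("region ids must be unique")
  rs <- data.table(chrom = chrom, start = start, end = end, id = id)
  co <- chrom_order(rs$chrom)
  rs <- rs[order(match(chrom, co), start)]
  setattr(rs, "provenance", provenance)
  setattr(rs, "class", c("RegionSet", class(rs)))
  rs[]
}

is_region_set <- function(x) inherits(x, "RegionSet")

as_granges <- function(rs) {
  GenomicRanges::GRanges(rs$chrom, IRanges::IRanges(rs$start + 1L, rs$end))
}

granges_to_rs <- function(gr, provenance = "", id = NULL, sizes = NULL) {
  region_set(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr),
             id = id, provenance = provenance, sizes = sizes)
}

#' Union-merge peak sets
#'
#' Collates several interval lists (e.g. DNase/ATAC broad peaks from multiple
#' cell types) into the minimal set of disjoint intervals covering their
#' union. Bookended (distance-0) intervals are merged.
#'
#' @param peak_sets A list of data.frames with columns chrom, start, end
#'   (0-based half-open), or a single such data.frame.
#' @param sizes Optional named chromosome sizes; intervals on chromosomes
#'   absent from it are rejected.
#' @return A [region_set()] labelled `"peak-union"`.
#' @export
merge_union <- function(peak_sets, sizes = NULL) {
  if (is.data.frame(peak_sets)) peak_sets <- list(peak_sets)
  all <- rbindlist(lapply(peak_sets, function(p)
    data.table(chrom = as.character(p[[1]]),
               start = as.integer(p[[2]]), end = as.integer(p[[3]]))))
  if (nrow(all) == 0L) return(region_set(character(), integer(), integer(),
                                         provenance = "peak-union"))
  if (any(all$end <= all$start)) stop("invalid interval with end <= start")
  if (!is.null(sizes)) {
    unknown <- setdiff(unique(all$chrom), names(sizes))
    if (length(unknown)) {
      stop("peak(s) on chromosome(s) absent from chromosome sizes: ",
           paste(unknown, collapse = ", "))
    }
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    all$chrom, IRanges::IRanges(all$start + 1L, all$end)))
  granges_to_rs(gr, provenance = "peak-union", sizes = sizes)
}

#' Standardize region widths around centroids
#'
#' Replaces each region by a fixed-width interval centered on its centroid
#' (floor of the midpoint), the standard preparation of open-chromatin
#' feature regions (default 200 bp: 100 bp up- and downstream of the
#' centroid). Regions whose standardized interval would leave the chromosome
#' are dropped, not clamped, so that all output regions share the exact
#' width required by position-offset patterns (WPS, OCF).
#'
#' @param rs A [region_set()].
#' @param width Even positive target width in bp (default 200).
#' @param sizes Named chromosome sizes used for the bounds check.
#' @return A [region_set()] of uniform width, retaining input ids.
#' @export
standardize_width <- function(rs, width = 200L, sizes) {
  width <- as.integer(width)
  stopifnot(width > 0L, width %% 2L == 0L)
  centroid <- (rs$start + rs$end) %/% 2L
  ns <- centroid - width %/% 2L
  ne <- centroid + width %/% 2L
  keep <- ns >= 0L & ne <= sizes[rs$chrom]
  keep[is.na(keep)] <- FALSE
  dropped <- sum(!keep)
  if (dropped) message(dropped, " region(s) dropped at chromosome bounds")
  region_set(rs$chrom[keep], ns[keep], ne[keep], id = rs$id[keep],
             provenance = paste0(attr(rs, "provenance"), ":width", width),
             sizes = sizes)
}

#' Strand-aware TSS windows
#'
#' Builds windows around transcription start sites: for a plus-strand TSS at
#' position p the window is `[p - upstream, p + downstream)`; minus-strand
#' windows are mirrored. Out-of-bounds windows are dropped.
#'
#' @param tss data.frame with columns chrom, pos (0-based), strand (`+`/`-`).
#' @param upstream,downstream Window extent in bp on each side of the TSS.
#' @param sizes Named chromosome sizes.
#' @return A [region_set()].
#' @export
tss_windows <- function(tss, upstream, downstream, sizes) {
  chrom <- as.character(tss[[1]]); pos <- as.integer(tss[[2]])
  strand <- as.character(tss[[3]])
  if (any(!strand %in% c("+", "-"))) stop("unknown strand symbol in TSS table")
  s <- ifelse(strand == "+", pos - upstream, pos - downstream)
  e <- ifelse(strand == "+", pos + downstream, pos + upstream)
  keep <- s >= 0L & e <= sizes[chrom] & e > s
  keep[is.na(keep)] <- FALSE
  if (any(!keep)) message(sum(!keep), " TSS window(s) dropped at chromosome bounds")
  region_set(chrom[keep], s[keep], e[keep],
             provenance = sprintf("TSS-%d/+%d", upstream, downstream),
             sizes = sizes)
}

#' Tile the genome into fixed bins
#'
#' Partitions each chromosome into consecutive non-overlapping bins; the
#' final partial bin is retained, so bins exactly partition each chromosome.
#'
#' @param sizes Named chromosome sizes.
#' @param bin Bin width in bp (default 5 Mb).
#' @return A [region_set()] labelled with the bin size.
#' @export
tile_genome <- function(sizes, bin = 5e6) {
  bin <- as.integer(bin)
  stopifnot(bin > 0L)
  out <- rbindlist(lapply(names(sizes), function(ch) {
    len <- as.integer(sizes[[ch]])
    s <- seq.int(0L, len - 1L, by = bin)
    data.table(chrom = ch, start = s, end = pmin(s + bin, len))
  }))
  region_set(out$chrom, out$start, out$end,
             provenance = sprintf("bins-%dbp", bin), sizes = sizes)
}

#' Chromosome arms from a cytoband table
#'
#' Collapses cytogenetic bands to one interval per chromosome arm (p/q),
#' spanning the minimum start to the maximum end of that arm's bands.
#'
#' @param cytoband data.frame in UCSC cytoBand dialect: chrom, start, end,
#'   band name (e.g. `p11.2`) or bare arm letter, (optional stain column).
#' @param sizes Optional chromosome sizes; chromosomes in `sizes` with no
#'   bands are omitted with a message.
#' @return A [region_set()] with ids like `chr1_p`.
#' @export
chrom_arms <- function(cytoband, sizes = NULL) {
  cb <- data.table(chrom = as.character(cytoband[[1]]),
                   start = as.integer(cytoband[[2]]),
                   end = as.integer(cytoband[[3]]),
                   arm = substr(as.character(cytoband[[4]]), 1L, 1L))
  if (any(!cb$arm %in% c("p", "q"))) stop("bands must be labelled p or q")
  if (!is.null(sizes)) {
    missing <- setdiff(names(sizes), unique(cb$chrom))
    if (length(missing)) {
      message("chromosome(s) with no cytobands omitted: ",
              paste(missing, collapse = ", "))
    }
  }
  arm <- NULL
  arms <- cb[, .(start = min(start), end = max(end)), by = .(chrom, arm)]
  region_set(arms$chrom, arms$start, arms$end,
             id = paste0(arms$chrom, "_", arms$arm),
             provenance = "chrom-arms", sizes = sizes)
}

#' Read / write BED region files
#'
#' BED3+ (tab-separated, no header); the region id travels in the BED name
#' column.
#'
#' @param path File path.
#' @param sizes Optional chromosome sizes for validation on read.
#' @param provenance Label for the set read.
#' @return `read_bed`: a [region_set()]; `write_bed`: the path, invisibly.
#' @export
read_bed <- function(path, sizes = NULL, provenance = basename(path)) {
  dt <- fread(path, header = FALSE, sep = "\t")
  id <- if (ncol(dt) >= 4L) as.character(dt[[4]]) else NULL
  region_set(dt[[1]], dt[[2]], dt[[3]], id = id,
             provenance = provenance, sizes = sizes)
}

#' @rdname read_bed
#' @param rs A [region_set()] to write.
#' @export
write_bed <- function(rs, path) {
  fwrite(data.table(rs$chrom, rs$start, rs$end, rs$id), path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a chromosome-sizes table
#'
#' Two-column TSV (name, length in bp).
#'
#' @param path File path.
#' @return Named integer vector of chromosome lengths, in natural order.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, sep = "\t")
  sizes <- setNames(as.integer(dt[[2]]), as.character(dt[[1]]))
  if (any(sizes <= 0L)) stop("chromosome lengths must be positive")
  sizes[chrom_order(names(sizes))]
}

#' @rdname read_chrom_sizes
#' @param sizes Named chromosome-length vector to write.
#' @export
write_chrom_sizes <- function(sizes, path) {
  fwrite(data.table(names(sizes), as.integer(sizes)), path,
         sep = "\t", col.names = FALSE)
  invisible(path)
}
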