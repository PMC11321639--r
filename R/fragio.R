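#' Read a cfDNA fragment file
#'
#' Reads fragment coordinate files in the FinaleDB-style `.frag` dialect: a
#' tab-separated file (optionally gzip-compressed, no header) with columns
#' chrom, start, end, MAPQ, strand in 0-based half-open coordinates. Plain
#' BED3 is accepted and padded with MAPQ 60 and strand `"."`. Unknown strand
#' symbols become `"."`; rows violating `end > start` or with malformed
#' numeric fields are rejected with their line number.
#'
#' @param path Path to a `.frag`, `.frag.gz` or BED file.
#' @return A `data.table` with columns chrom, start, end, mapq, strand, in
#'   file order.
#' @export
read_frag <- function(path) {
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      mapq = integer(), strand = character())
  if (file.exists(path) && file.size(path) == 0L) return(empty)
  dt <- if (endsWith(path, ".gz")) {
    con <- gzfile(path, "rt")
    on.exit(close(con))
    lines <- readLines(con)
    if (!length(lines)) data.table() else
      fread(text = lines, header = FALSE, sep = "\t", colClasses = "character")
  } else {
    fread(path, header = FALSE, sep = "\t", colClasses = "character")
  }
  if (nrow(dt) == 0L) return(empty)
  if (ncol(dt) < 3L) stop("fragment file needs >= 3 tab-separated columns: ", path)
  out <- data.table(chrom = dt[[1]],
                    start = suppressWarnings(as.integer(dt[[2]])),
                    end = suppressWarnings(as.integer(dt[[3]])))
  if (ncol(dt) >= 5L) {
    out[, `:=`(mapq = suppressWarnings(as.integer(dt[[4]])), strand = dt[[5]])]
  } else {
    out[, `:=`(mapq = 60L, strand = ".")]
  }
  bad <- which(is.na(out$start) | is.na(out$end) | is.na(out$mapq))
  if (length(bad)) stop("malformed numeric field at line ", bad[1], " of ", path)
  bad <- which(out$end <= out$start)
  if (length(bad)) stop("fragment with end <= start at line ", bad[1], " of ", path)
  out[!strand %in% c("+", "-"), strand := "."]
  out[]
}

#' Write fragments in `.frag` format
#'
#' @param frags Fragment `data.table` (chrom, start, end, mapq, strand).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return The path, invisibly.
#' @export
write_frag <- function(frags, path) {
  fwrite(frags[, c("chrom", "start", "end", "mapq", "strand"), with = FALSE],
         path, sep = "\t", col.names = FALSE,
         compress = if (endsWith(path, ".gz")) "gzip" else "none")
  invisible(path)
}

#' Filter fragments by mapping quality
#'
#' Keeps fragments with `mapq >= min_mapq` (default 30, the usual
#' high-quality cutoff for cfDNA alignments). For BAM-derived inputs the
#' upstream contract is proper pairs only, excluding unmapped / secondary /
#' duplicate / supplementary / QC-fail reads; this function enforces the
#' MAPQ clause on fragment streams.
#'
#' @param frags Fragment `data.table`.
#' @param min_mapq Minimum MAPQ retained (inclusive).
#' @return Filtered `data.table`; the number dropped is messaged.
#' @export
quality_filter <- function(frags, min_mapq = 30L) {
  mapq <- NULL
  out <- frags[mapq >= min_mapq]
  dropped <- nrow(frags) - nrow(out)
  if (dropped) message(dropped, " fragment(s) below MAPQ ", min_mapq, " dropped")
  out
}

#' Assign fragments to regions by midpoint
#'
#' A fragment belongs to region r iff its midpoint, `floor((start + end)/2)`,
#' lies in `[r.start, r.end)`. Over a disjoint region set each fragment is
#' assigned to at most one region. Full fragment coordinates are retained so
#' end-based patterns (ends, OCF, WPS) can be computed downstream.
#'
#' @param frags Fragment `data.table`.
#' @param rs A [region_set()] (sorted; assumed disjoint).
#' @return Copy of `frags` with columns mid, region_idx (row index into
#'   `rs`, NA if unassigned) and region_id.
#' @export
assign_to_regions <- function(frags, rs) {
  out <- copy(frags)
  out[, mid := (start + end) %/% 2L]
  if (nrow(out) == 0L) {
    out[, `:=`(region_idx = integer(), region_id = character())]
    return(out[])
  }
  mid_gr <- GenomicRanges::GRanges(out$chrom, IRanges::IRanges(out$mid + 1L, width = 1L))
  hit <- GenomicRanges::findOverlaps(mid_gr, as_granges(rs), select = "first")
  out[, region_idx := as.integer(hit)]
  out[, region_id := rs$id[region_idx]]
  out[]
}

#' In-memory reference genome
#'
#' Loads a FASTA file into an in-memory accessor used for end-motif and GC
#' lookups. Suitable for the toy genomes this package simulates and for
#' per-chromosome work on real references.
#'
#' @param fasta Path to a FASTA file.
#' @return A `RefGenome` object with named chromosome sequences and sizes.
#' @export
load_reference <- function(fasta) {
  ss <- Biostrings::readDNAStringSet(fasta)
  names(ss) <- sub("\\s.*$", "", names(ss))
  seqs <- setNames(toupper(as.character(ss)), names(ss))
  structure(list(seqs = seqs, sizes = setNames(nchar(seqs), names(seqs))),
            class = "RefGenome")
}

#' @rdname load_reference
#' @param ref A `RefGenome`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open window.
#' @return `ref_seq`: uppercase base string of length `end - start`.
#' @export
ref_seq <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref$seqs)) stop("unknown chromosome: ", chrom)
  if (start < 0L || end > ref$sizes[[chrom]] || end <= start) {
    stop("window out of reference bounds: ", chrom, ":", start, "-", end)
  }
  substr(ref$seqs[[chrom]], start + 1L, end)
}

#' Fragment 5' end motifs
#'
#' Extracts the k reference bases at each fragment's 5' end: for strand `+`
#' (and `.`, treated as plus) the bases at `[start, start + k)`; for strand
#' `-` the reverse complement of `[end - k, end)`. Motifs containing N or
#' running past the chromosome are returned as NA (the skip signal) and are
#' excluded from motif tallies.
#'
#' @param frags Fragment `data.table`.
#' @param ref A `RefGenome` from [load_reference()].
#' @param k Motif length (default 4).
#' @return Character vector of motifs (NA where skipped), one per fragment.
#' @export
end_motif <- function(frags, ref, k = 4L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  n <- nrow(frags)
  if (n == 0L) return(character())
  motif <- rep(NA_character_, n)
  known <- frags$chrom %in% names(ref$seqs)
  len <- ref$sizes[frags$chrom]
  minus <- frags$strand == "-"
  ok_plus <- known & !minus & frags$start >= 0L & frags$start + k <= len
  ok_minus <- known & minus & frags$end - k >= 0L & frags$end <= len
  if (any(ok_plus)) {
    motif[ok_plus] <- substr(ref$seqs[frags$chrom[ok_plus]],
                             frags$start[ok_plus] + 1L, frags$start[ok_plus] + k)
  }
  if (any(ok_minus)) {
    motif[ok_minus] <- revcomp(substr(ref$seqs[frags$chrom[ok_minus]],
                                      frags$end[ok_minus] - k + 1L,
                                      frags$end[ok_minus]))
  }
  motif[!is.na(motif) & grepl("[^ACGT]", motif)] <- NA_character_
  motif
}

#' Read a sample sheet
#'
#' CSV/TSV with header columns `sample`, `path`, `label` and optional
#' `stage` and `tumor_fraction` (in `[0, 1]`).
#'
#' @param path File path.
#' @param labels Optional declared label set; unknown labels are rejected.
#' @return A `data.table`, one row per sample.
#' @export
read_sample_sheet <- function(path, labels = NULL) {
  dt <- fread(path, header = TRUE)
  need <- c("sample", "path", "label")
  if (!all(need %in% names(dt))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(dt$sample)) stop("duplicate sample ids in sample sheet")
  if (!is.null(labels) && !all(dt$label %in% labels)) {
    stop("sample sheet labels outside declared set: ",
         paste(setdiff(unique(dt$label), labels), collapse = ", "))
  }
  if ("tumor_fraction" %in% names(dt)) {
    tf <- dt$tumor_fraction
    if (any(!is.na(tf) & (tf < 0 | tf > 1))) stop("tumor_fraction outside [0, 1]")
  }
  dt[]
}
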