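# shared internal helpers

# natural chromosome order: chr1..chr22 numerically, then others alphabetically
chrom_order <- function(chroms) {
  u <- unique(chroms)
  num <- suppressWarnings(as.integer(sub("^chr", "", u)))
  u[order(is.na(num), num, u)]
}

# derive reproducible child seeds from one top-level seed; keeps values < 2^31
derive_seeds <- function(seed, n, tag = "") {
  offset <- if (nzchar(tag)) sum(utf8ToInt(tag)) else 0L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
            suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed((as.integer(seed) + offset) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

# reverse complement of DNA strings (vectorized, uppercase in/out)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# all DNA k-mers in lexicographic order
all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  sort(do.call(paste0, expand.grid(rep(list(b), k), stringsAsFactors = FALSE)))
}

# population standard deviation
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
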