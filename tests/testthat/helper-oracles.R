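# independent brute-force oracles: naive loops over bases, loci and
# fragment/region pairs, kept deliberately separate from the package's
# vectorized implementations

frag_dt <- function(chrom, start, end, mapq = 60L, strand = "+") {
  data.table::data.table(chrom = chrom, start = as.integer(start),
                         end = as.integer(end),
                         mapq = as.integer(rep_len(mapq, length(start))),
                         strand = rep_len(strand, length(start)))
}

# per-base boolean union of intervals on one chromosome
oracle_union_1chrom <- function(starts, ends, maxlen) {
  covered <- logical(maxlen)
  for (i in seq_along(starts)) covered[(starts[i] + 1):ends[i]] <- TRUE
  r <- rle(covered)
  pos <- cumsum(c(0, r$lengths))
  keep <- which(r$values)
  data.frame(start = pos[keep], end = pos[keep + 1])
}

# nested-loop fragment -> region midpoint assignment
oracle_assign <- function(frags, rs) {
  out <- rep(NA_integer_, nrow(frags))
  for (i in seq_len(nrow(frags))) {
    mid <- (frags$start[i] + frags$end[i]) %/% 2
    for (j in seq_len(nrow(rs))) {
      if (frags$chrom[i] == rs$chrom[j] && mid >= rs$start[j] && mid < rs$end[j]) {
        out[i] <- j
        break
      }
    }
  }
  out
}

oracle_pfe_cat <- function(len) {
  if (len < 100) 1L else if (len >= 250) 17L else as.integer((len - 100) %/% 10 + 2)
}

oracle_pfe <- function(lens) {
  if (!length(lens)) return(0)
  cats <- vapply(lens, oracle_pfe_cat, integer(1))
  p <- table(cats) / length(cats)
  -sum(p * log2(p))
}

oracle_fsr <- function(lens) {
  s <- sum(lens >= 65 & lens <= 150)
  m <- sum(lens >= 151 & lens <= 220)
  l <- sum(lens >= 221 & lens <= 400)
  tot <- s + m + l
  if (tot == 0) c(0, 0, 0) else c(s, m, l) / tot
}

oracle_ifs <- function(lens, L) {
  if (!length(lens)) return(0)
  length(lens) * (1 + mean(lens) / L)
}

# per-locus WPS for one region: window [p-60, p+60) scores +1 per spanning
# fragment, -1 per fragment overlapping with an end inside
oracle_wps <- function(frags, rstart, rend, chrom, window = 120L) {
  half <- window %/% 2
  scores <- numeric(rend - rstart)
  for (k in seq_along(scores)) {
    p <- rstart + k - 1L
    ws <- p - half; we <- p + half   # window [ws, we)
    s <- 0L
    for (i in seq_len(nrow(frags))) {
      if (frags$chrom[i] != chrom) next
      fs <- frags$start[i]; fe <- frags$end[i]
      if (fs < we && fe > ws) {                 # overlap
        if (fs <= ws && fe >= we) s <- s + 1L   # spans the whole window
        else s <- s - 1L                        # >= 1 end inside the window
      }
    }
    scores[k] <- s
  }
  mean(scores)
}

# per-position OCF for one region
oracle_ocf <- function(frags, rstart, rend, chrom, offset = 60L, hw = 10L) {
  ctr <- rstart + (rend - rstart) %/% 2
  u_at <- function(p) sum(frags$chrom == chrom & frags$start == p)
  d_at <- function(p) sum(frags$chrom == chrom & frags$end - 1L == p)
  tot <- 0
  for (p in (ctr - offset - hw):(ctr - offset + hw)) tot <- tot + d_at(p) - u_at(p)
  for (p in (ctr + offset - hw):(ctr + offset + hw)) tot <- tot + u_at(p) - d_at(p)
  tot
}

oracle_ends <- function(frags, rstart, rend, chrom) {
  n <- 0L
  for (i in seq_len(nrow(frags))) {
    if (frags$chrom[i] != chrom) next
    if (frags$start[i] >= rstart && frags$start[i] < rend) n <- n + 1L
    if (frags$end[i] - 1L >= rstart && frags$end[i] - 1L < rend) n <- n + 1L
  }
  n
}

# AUC by enumeration of all positive/negative pairs (ties count 1/2)
oracle_auc <- function(scores, labels, positive) {
  pos <- which(labels == positive); neg <- which(labels != positive)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

oracle_sens_at_spec <- function(scores, labels, spec, positive) {
  pos <- labels == positive
  best <- 0
  for (t in c(sort(unique(scores)), Inf)) {
    pred <- scores >= t
    if (sum(!pred & !pos) / sum(!pos) >= spec) {
      best <- max(best, sum(pred & pos) / sum(pos))
    }
  }
  best
}

# random small fragment/region instance on a toy genome
random_instance <- function(seed, n_frags = 200L, n_regions = 5L,
                            chrom_len = 10000L) {
  set.seed(seed)
  rs <- region_set(chrom = "chr1",
                   start = seq(1000L, by = 1500L, length.out = n_regions),
                   end = seq(1000L, by = 1500L, length.out = n_regions) + 200L,
                   sizes = c(chr1 = chrom_len))
  start <- sample.int(chrom_len - 500L, n_frags, replace = TRUE)
  len <- sample(60:350, n_frags, replace = TRUE)
  frags <- frag_dt("chr1", start, pmin(start + len, chrom_len),
                   strand = sample(c("+", "-"), n_frags, TRUE))
  list(rs = rs, frags = frags, sizes = c(chr1 = chrom_len))
}
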