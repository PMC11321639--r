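mk_assigned <- function(frags, rs) assign_to_regions(frags, rs)

test_that("PFE matches its closed forms", {
  rs <- region_set("chr1", 1000L, 1200L)
  # all fragments in one category -> 0
  f <- mk_assigned(frag_dt("chr1", rep(1000L, 5), rep(1166L, 5)), rs)
  expect_equal(unname(compute_pfe(f, rs)), 0)
  # equal counts in two categories -> 1 bit
  f <- mk_assigned(frag_dt("chr1", rep(1000L, 4), 1000L + c(105, 105, 166, 166)), rs)
  expect_equal(unname(compute_pfe(f, rs)), 1)
  # equal counts in all 17 categories -> log2(17)
  lens <- c(90L, seq(105L, 245L, 10L), 260L)
  f <- mk_assigned(frag_dt("chr1", rep(1050L, 17), 1050L + lens), rs)
  expect_equal(unname(compute_pfe(f, rs)), log2(17))
  # empty region scores 0
  expect_equal(unname(compute_pfe(mk_assigned(frag_dt(character(0), integer(0),
                                                      integer(0)), rs), rs)), 0)
})

test_that("PFE category boundaries: <100 short class, >=250 long class", {
  rs <- region_set("chr1", 1000L, 1400L)
  # 99 and 100 straddle the short boundary; 249 and 250 the long one
  f <- mk_assigned(frag_dt("chr1", rep(1050L, 2), 1050L + c(99L, 100L)), rs)
  expect_equal(unname(compute_pfe(f, rs)), 1)  # two distinct categories
  f <- mk_assigned(frag_dt("chr1", rep(1050L, 2), 1050L + c(249L, 250L)), rs)
  expect_equal(unname(compute_pfe(f, rs)), 1)
  f <- mk_assigned(frag_dt("chr1", rep(1050L, 2), 1050L + c(250L, 340L)), rs)
  expect_equal(unname(compute_pfe(f, rs)), 0)  # both in the >=250 class
})

test_that("FSR proportions use the in-range denominator", {
  rs <- region_set("chr1", 1000L, 1400L)
  f <- mk_assigned(frag_dt("chr1", rep(1050L, 4), 1050L + c(100L, 100L, 180L, 300L)), rs)
  expect_equal(unname(compute_fsr(f, rs)), c(0.5, 0.25, 0.25))
  f <- mk_assigned(frag_dt("chr1", rep(1050L, 3), 1050L + rep(100L, 3)), rs)
  expect_equal(unname(compute_fsr(f, rs)), c(1, 0, 0))
  # only out-of-range lengths -> all zero
  f <- mk_assigned(frag_dt("chr1", rep(1050L, 2), 1050L + c(60L, 450L)), rs)
  expect_equal(unname(compute_fsr(f, rs)), c(0, 0, 0))
})

test_that("IFS matches its closed forms", {
  rs <- region_set("chr1", 1000L, 1200L)
  # l == L (single region) -> 2n
  f <- mk_assigned(frag_dt("chr1", rep(1020L, 7), rep(1180L, 7)), rs)
  expect_equal(unname(compute_ifs(f, rs)), 14)
  # n = 0 -> 0
  f <- mk_assigned(frag_dt("chr1", 5000L, 5166L), rs)
  expect_equal(unname(compute_ifs(f, rs)), 0)
  # n=10, l=150, L=166 via a second region fixing the chromosome mean
  rs2 <- region_set("chr1", c(1000L, 2000L), c(1200L, 2200L))
  f <- frag_dt("chr1", c(rep(1025L, 10), rep(2025L, 10)),
               c(rep(1175L, 10), 2025L + rep(182L, 10)))
  got <- compute_ifs(mk_assigned(f, rs2), rs2)
  expect_equal(unname(got[1]), 10 * (1 + 150 / 166))
})

test_that("coverage counts midpoints with half-open boundaries", {
  rs <- region_set("chr1", 100L, 300L)
  f <- mk_assigned(frag_dt("chr1", c(150L, 150L, 150L, 150L, 150L), rep(350L, 5)), rs)
  expect_equal(unname(compute_coverage(f, rs)), 5)
  # midpoint exactly at the exclusive end is not counted
  f <- mk_assigned(frag_dt("chr1", 290L, 310L), rs)  # midpoint 300
  expect_equal(unname(compute_coverage(f, rs)), 0)
  expect_equal(unname(compute_coverage(mk_assigned(frag_dt("chr1", 500L, 700L), rs), rs)), 0)
})

test_that("fragment end counts: inside = 2, straddling = 1, spanning = 0", {
  rs <- region_set("chr1", 400L, 600L)
  expect_equal(unname(compute_ends(frag_dt("chr1", 450L, 550L), rs)), 2)
  expect_equal(unname(compute_ends(frag_dt("chr1", 350L, 450L), rs)), 1)
  expect_equal(unname(compute_ends(frag_dt("chr1", 300L, 700L), rs)), 0)
})

test_that("OCF closed forms: empty, mirror-antisymmetric, single flank term", {
  rs <- region_set("chr1", 1000L, 1200L)  # center 1100
  params <- pattern_params()
  expect_equal(unname(compute_ocf(frag_dt(character(0), integer(0), integer(0)),
                                  rs, params)), 0)
  # 7 left ends exactly at c+60 -> +7
  f <- frag_dt("chr1", rep(1160L, 7), rep(1160L + 166L, 7))
  expect_equal(unname(compute_ocf(f, rs, params)), 7)
  # balanced U/D end profile (one fragment start and one fragment end at
  # each flank position) cancels to 0 by antisymmetry
  f <- frag_dt("chr1", c(1040L, 900L, 1160L, 1000L), c(1240L, 1041L, 1360L, 1161L))
  expect_equal(unname(compute_ocf(f, rs, params)), 0)
  expect_error(compute_ocf(f, region_set("chr1", 0L, 100L), params), "narrower")
})

test_that("WPS closed forms: fragment spanning all windows, fragment inside", {
  rs <- region_set("chr1", 400L, 600L)
  params <- pattern_params()
  expect_equal(unname(compute_wps(frag_dt(character(0), integer(0), integer(0)),
                                  rs, params)), 0)
  # [0,1000) spans the 120-bp window of every locus in [400,600) -> mean +1
  expect_equal(unname(compute_wps(frag_dt("chr1", 0L, 1000L), rs, params)), 1)
  # short fragment inside the region: every window it touches sees an end
  got <- compute_wps(frag_dt("chr1", 450L, 520L), rs, params)
  expect_equal(unname(got),
               oracle_wps(frag_dt("chr1", 450L, 520L), 400L, 600L, "chr1"))
  expect_lt(unname(got), 0)
  # adding a window-spanning fragment raises the mean by exactly 1
  base <- compute_wps(frag_dt("chr1", 450L, 520L), rs, params)
  plus <- compute_wps(frag_dt("chr1", c(450L, 0L), c(520L, 1000L)), rs, params)
  expect_equal(unname(plus - base), 1)
})

test_that("per-chromosome length profiles sum to 1 and respect the overflow class", {
  rs <- region_set(c("chr1", "chr2"), c(1000L, 1000L), c(1400L, 1400L))
  chroms <- c("chr1", "chr2")
  f <- mk_assigned(frag_dt("chr1", rep(1000L, 4), 1000L + c(166L, 166L, 300L, 310L)), rs)
  v <- compute_length_profile(f, chroms)
  expect_equal(sum(v[1:31]), 1)
  expect_equal(sum(v[32:62]), 0)          # chr2 empty -> zero block
  expect_equal(unname(v["chr1:len300plus"]), 0.5)  # 300 falls in >=300 class
  expect_equal(unname(v["chr1:len160_170"]), 0.5)
  # FSD: 67 bins over [65,400], length 400 in the final bin
  f <- mk_assigned(frag_dt("chr1", rep(1000L, 3), 1000L + c(65L, 400L, 500L)), rs)
  v <- compute_length_profile(f, chroms, binning_scheme("fsd67"))
  expect_equal(length(v), 134L)
  expect_equal(unname(v["chr1:fsd065_070"]), 0.5)
  expect_equal(unname(v["chr1:fsd395_400"]), 0.5)  # 500 is outside the scheme
})

test_that("EDM proportions per chromosome match hand counts", {
  ref <- toy_ref(c(chr1 = strrep("ACGTTTTTGGCCAAAA", 50)))
  rs <- region_set("chr1", 0L, 800L)
  # 8 plus-strand fragments starting at motifs ACGT (x3), CGTT (x3), GTTT (x2)
  starts <- c(0L, 16L, 32L, 1L, 17L, 33L, 2L, 18L)
  f <- mk_assigned(frag_dt("chr1", starts, starts + 150L), rs)
  v <- compute_edm(f, ref, "chr1")
  expect_equal(unname(v["chr1:ACGT"]), 3 / 8)
  expect_equal(unname(v["chr1:CGTT"]), 3 / 8)
  expect_equal(unname(v["chr1:GTTT"]), 2 / 8)
  expect_equal(sum(v), 1)
  expect_equal(length(v), 256L)
})

test_that("all calculators match brute-force oracles on random instances", {
  params <- pattern_params()
  for (seed in 1:5) {
    inst <- random_instance(seed, n_frags = 200L, n_regions = 5L)
    rs <- inst$rs; frags <- inst$frags
    a <- mk_assigned(frags, rs)
    idx <- oracle_assign(frags, rs)
    lens <- frags$end - frags$start
    L <- mean(lens[!is.na(idx)])
    for (j in seq_len(nrow(rs))) {
      sel <- lens[!is.na(idx) & idx == j]
      expect_equal(unname(compute_pfe(a, rs)[j]), oracle_pfe(sel), tolerance = 1e-9)
      expect_equal(unname(compute_coverage(a, rs)[j]), length(sel))
      expect_equal(matrix(compute_fsr(a, rs), nrow = 3)[, j], oracle_fsr(sel),
                   tolerance = 1e-9)
      expect_equal(unname(compute_ifs(a, rs)[j]),
                   if (length(sel)) oracle_ifs(sel, L) else 0, tolerance = 1e-9)
      expect_equal(unname(compute_ends(frags, rs)[j]),
                   oracle_ends(frags, rs$start[j], rs$end[j], "chr1"))
      expect_equal(unname(compute_ocf(frags, rs, params)[j]),
                   oracle_ocf(frags, rs$start[j], rs$end[j], "chr1"))
      expect_equal(unname(compute_wps(frags, rs, params)[j]),
                   oracle_wps(frags, rs$start[j], rs$end[j], "chr1"),
                   tolerance = 1e-9)
    }
  }
})

test_that("calculators are invariant to fragment order and proportions normalize", {
  inst <- random_instance(42, n_frags = 150L)
  rs <- inst$rs
  perm <- sample(nrow(inst$frags))
  a1 <- mk_assigned(inst$frags, rs)
  a2 <- mk_assigned(inst$frags[perm], rs)
  params <- pattern_params()
  expect_equal(compute_pfe(a1, rs), compute_pfe(a2, rs))
  expect_equal(compute_ifs(a1, rs), compute_ifs(a2, rs))
  expect_equal(compute_wps(inst$frags, rs, params),
               compute_wps(inst$frags[perm], rs, params))
  # PFE bounded by log2(17); zero iff <= 1 occupied category
  pfe <- compute_pfe(a1, rs)
  expect_true(all(pfe >= 0 & pfe <= log2(17)))
  # FSR blocks sum to 1 or are identically 0
  fsr <- matrix(compute_fsr(a1, rs), nrow = 3)
  expect_true(all(abs(colSums(fsr) - 1) < 1e-9 | colSums(fsr) == 0))
})

test_that("uniform lengths fill length-profile bins near-uniformly", {
  set.seed(8)
  rs <- region_set("chr1", 0L, 100000L)
  n <- 3000L
  lens <- sample(0:299, n, replace = TRUE) + 1L   # uniform over the 30 tracked bins
  starts <- sample.int(50000L, n, replace = TRUE)
  a <- mk_assigned(frag_dt("chr1", starts, starts + lens), rs)
  v <- compute_length_profile(a, "chr1")
  inner <- v[1:30]
  expect_true(all(abs(inner - 1 / 30) < 5 * sqrt((1 / 30) * (29 / 30) / n)))
})

test_that("pattern matrices assemble, tag axes, and round-trip as TSV", {
  tc <- tiny_cohort()
  mats <- tc$mats
  expect_setequal(names(mats), pattern_names())
  expect_equal(mats$pfe$axis, "region")
  expect_equal(mats$edm$axis, "chrom")
  expect_equal(nrow(mats$ifs$values), nrow(tc$sheet))
  p <- tempfile(fileext = ".tsv")
  write_pattern_matrix(mats$ifs, p)
  back <- read_pattern_matrix(p, "ifs", "region")
  expect_equal(back$values, mats$ifs$values, tolerance = 1e-12)
})
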