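test_that("fold plans are stratified, complete and reproducible", {
  labels <- rep(c("healthy", "cancer"), c(75, 25))
  plan <- make_folds(labels, repeats = 3, folds = 5, seed = 7)
  expect_equal(dim(plan$assign), c(100L, 3L))
  for (r in 1:3) {
    fa <- plan$assign[, r]
    expect_setequal(unique(fa), 1:5)
    # every fold sized n/folds, class ratio preserved within 1
    expect_true(all(table(fa) == 20))
    cc <- table(fa[labels == "cancer"])
    expect_true(all(abs(cc - 5) <= 1))
  }
  expect_identical(make_folds(labels, 3, 5, seed = 7)$assign, plan$assign)
  expect_false(identical(make_folds(labels, 3, 5, seed = 8)$assign, plan$assign))
  expect_error(make_folds(rep(c("a", "b"), c(50, 3)), folds = 5), "fewer folds")
})

test_that("AUC matches pair enumeration, handles ties, validates classes", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0), positive = 1), 0.75)
  expect_equal(auc(c(5, 4, 2, 1), c("b", "b", "a", "a"), positive = "b"), 1)
  expect_equal(auc(rep(1, 10), rep(c("a", "b"), 5), positive = "b"), 0.5)
  expect_error(auc(1:3, rep("a", 3), positive = "b"), "both classes")
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(10:50, 1)
    scores <- round(runif(n), 2)  # rounding induces ties
    labels <- sample(c("x", "y"), n, replace = TRUE, prob = c(0.6, 0.4))
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels, "y"), oracle_auc(scores, labels, "y"))
  }
})

test_that("sensitivity at fixed specificity matches exhaustive threshold sweep", {
  # perfect separation -> 1 at both levels
  sc <- c(rep(0.9, 5), rep(0.1, 5)); lb <- rep(c("c", "h"), each = 5)
  expect_equal(sens_at_spec(sc, lb, 0.95, "c"), 1)
  expect_equal(sens_at_spec(sc, lb, 0.85, "c"), 1)
  for (seed in 1:5) {
    set.seed(seed)
    sc <- round(runif(20), 2)
    lb <- sample(c("c", "h"), 20, replace = TRUE)
    if (length(unique(lb)) < 2) next
    for (sp in c(0.95, 0.85)) {
      expect_equal(sens_at_spec(sc, lb, sp, "c"),
                   oracle_sens_at_spec(sc, lb, sp, "c"))
    }
    # monotone in the specificity requirement
    expect_gte(sens_at_spec(sc, lb, 0.85, "c"), sens_at_spec(sc, lb, 0.95, "c"))
  }
})

test_that("linear SVM base models separate, expose weights, and are seeded", {
  set.seed(12)
  x <- rbind(matrix(rnorm(40, 2), 20, 2), matrix(rnorm(40, -2), 20, 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("cancer", "healthy"), each = 20)
  m <- train_base(x, y, positive = "cancer", seed = 5)
  expect_equal(length(m$weights), 2L)
  expect_equal(auc(predict_prob(m, x), y, "cancer"), 1)
  expect_true(all(predict_prob(m, x) >= 0 & predict_prob(m, x) <= 1))
  m2 <- train_base(x, y, positive = "cancer", seed = 5)
  expect_identical(predict_prob(m, x), predict_prob(m2, x))
  expect_error(train_base(x, rep("cancer", 40), "cancer"), "single class")
  # label permutation gives near-chance held-out performance
  set.seed(13)
  xr <- matrix(rnorm(60 * 5), 60, 5); colnames(xr) <- paste0("f", 1:5)
  yr <- sample(rep(c("cancer", "healthy"), each = 30))
  mr <- train_base(xr[1:40, ], yr[1:40], "cancer", seed = 1)
  a <- auc(predict_prob(mr, xr[41:60, ]), yr[41:60], "cancer")
  expect_lt(abs(a - 0.5), 0.35)  # wide null band for n = 20
})

test_that("fold-internal fitting is invariant to test-row perturbation", {
  tc <- tiny_cohort()
  labels <- tc$sheet$label
  train_idx <- 1:16
  fit1 <- fold_fit(tc$prep, labels, train_idx, positive = "cancer",
                   pca_dim = 5, seed = 3)
  pert <- lapply(tc$prep, function(pm) {
    pm$values[17:24, ] <- pm$values[17:24, ] + 1000
    pm
  })
  fit2 <- fold_fit(pert, labels, train_idx, positive = "cancer",
                   pca_dim = 5, seed = 3)
  for (p in names(fit1)) {
    expect_identical(fit1[[p]]$model$weights, fit2[[p]]$model$weights)
    expect_identical(fit1[[p]]$pca, fit2[[p]]$pca)
  }
  # predictions for unperturbed rows are identical too
  expect_identical(fold_predict(fit1, tc$prep, 1:16),
                   fold_predict(fit2, pert, 1:16))
})

test_that("cross-validation books every sample once per repeat and finds signal", {
  tc <- tiny_cohort()
  labels <- tc$sheet$label
  plan <- make_folds(labels, repeats = 2, folds = 4, seed = 2)
  cv <- cross_validate(tc$prep, labels, plan, positive = "cancer", pca_dim = 8)
  expect_equal(dim(cv$oof), c(24L, 10L, 2L))
  expect_true(all(is.finite(cv$oof)))        # exactly one prediction each
  expect_equal(dim(cv$auc_by_repeat), c(10L, 2L))
  # strongly separable cohort: length-based patterns carry the signal
  expect_gt(cv$report[pattern == "length", auc], 0.9)
  expect_gt(cv$report[pattern == "fsd", auc], 0.9)
  expect_true(all(cv$report$ci_lo <= cv$report$auc &
                    cv$report$auc <= cv$report$ci_hi))
  # sample-order mismatch is rejected
  bad <- tc$prep
  bad$pfe$values <- bad$pfe$values[rev(seq_len(24)), ]
  expect_error(cross_validate(bad, labels, plan, positive = "cancer"),
               "sample order")
})

test_that("IFP stacking uses out-of-fold probabilities and bounded scores", {
  tc <- tiny_cohort()
  labels <- tc$sheet$label
  plan <- make_folds(labels, repeats = 2, folds = 4, seed = 2)
  cv <- cross_validate(tc$prep, labels, plan, positive = "cancer", pca_dim = 8)
  st <- stack_ifp(cv, labels, plan, positive = "cancer")
  expect_true(all(st$score >= 0 & st$score <= 1))
  expect_gt(st$report$auc, 0.9)
  # bookkeeping: the meta model scoring fold f of repeat r is reproducible
  # from training rows only (out-of-fold by construction)
  r <- 1L; f <- 2L
  test <- which(plan$assign[, r] == f)
  seeds <- cfpattern:::derive_seeds(plan$seed, plan$repeats * plan$folds + 1L, "stack")
  m <- train_base(cv$oof[-test, , r], labels[-test], "cancer",
                  seed = seeds[(r - 1L) * plan$folds + f])
  expect_equal(unname(st$by_repeat[test, r]),
               unname(predict_prob(m, cv$oof[test, , r])))
  # meta-feature column mismatch rejected
  expect_error(stack_ifp(cv, labels, plan, "cancer", n_patterns = 7), "pattern count")
})

test_that("one pattern with signal is enough for the stacked ensemble", {
  set.seed(44)
  n <- 40L
  labels <- rep(c("cancer", "healthy"), each = n / 2)
  mk <- function(vals, p) {
    rownames(vals) <- paste0("s", 1:n); colnames(vals) <- paste0("f", 1:ncol(vals))
    pattern_matrix(p, vals, "region")
  }
  good <- mk(cbind(ifelse(labels == "cancer", 1, -1) + rnorm(n, 0, 0.3),
                   matrix(rnorm(n * 4), n)), "ifs")
  noise <- mk(matrix(rnorm(n * 5), n), "ocf")
  plan <- make_folds(labels, repeats = 2, folds = 4, seed = 9)
  cv <- cross_validate(list(ifs = good, ocf = noise), labels, plan,
                       positive = "cancer", pca = FALSE)
  st <- stack_ifp(cv, labels, plan, positive = "cancer")
  expect_gt(st$report$auc, 0.95)
})

test_that("independent validation freezes the model and checks feature axes", {
  tc <- tiny_cohort()
  labels <- tc$sheet$label
  plan <- make_folds(labels, repeats = 2, folds = 4, seed = 2)
  model <- train_ifp(tc$prep, labels, plan, positive = "cancer", pca_dim = 8)
  # external cohort simulated from the same generator, different seed
  cfg2 <- sim_config(seed = 77, n_chrom = 2L, chrom_length = 200000L,
                     n_regions = 20L, n_healthy = 8L, n_cancer = 8L,
                     n_fragments = 3000L, tf_range = c(0.1, 0.5))
  co2 <- simulate_cohort(cfg2, file.path(tempdir(), "cfpattern-ext"))
  # frozen training configuration: same regions/reference/preprocessing
  mats2 <- extract_cohort_features(co2$sheet, tc$rs, tc$ref, tc$sizes)
  prep2 <- suppressMessages(preprocess_patterns(mats2, region_gc(tc$rs, tc$ref)))
  val <- independent_validate(model, prep2, co2$sheet$label)
  expect_gt(val$report$auc, 0.85)
  # label shuffle ~ chance
  set.seed(1)
  expect_lt(abs(auc(val$score, sample(co2$sheet$label), "cancer") - 0.5), 0.35)
  # axis mismatch is an explicit error
  broken <- prep2
  broken$ifs$values <- broken$ifs$values[, -1, drop = FALSE]
  expect_error(independent_validate(model, broken), "mismatch")
})

test_that("tumor-fraction bins follow the 2% / 15% boundaries", {
  tf <- c(0, 0.019, 0.02, 0.1, 0.149, 0.15, 0.5, 1)
  expect_equal(as.character(tumor_fraction_bin(tf)),
               c("low", "low", "medium", "medium", "medium", "high", "high", "high"))
})

test_that("stratified evaluation reports per-stratum AUCs and tests", {
  set.seed(55)
  n_ctrl <- 30; labels <- rep(c("healthy", "cancer"), c(n_ctrl, 30))
  strata <- c(rep(NA, n_ctrl), rep(c("low", "medium", "high"), each = 10))
  strata <- factor(strata, levels = c("low", "medium", "high"), ordered = TRUE)
  score <- c(rnorm(n_ctrl, 0), rnorm(10, 0.5), rnorm(10, 1.5), rnorm(10, 3))
  out <- stratify_eval(score, labels, strata)
  expect_equal(out$table$n, rep(10L, 3))
  expect_true(all(diff(out$table$auc) > 0))   # planted monotone effect
  expect_lt(out$kruskal_p, 0.01)
  # identical scores give equal AUCs; empty stratum reported missing
  same <- rep(1, 60)
  out2 <- stratify_eval(same, labels, strata)
  expect_equal(unique(out2$table$auc), 0.5)
  strata3 <- factor(ifelse(is.na(strata) | strata == "low", as.character(strata), "medium"),
                    levels = c("low", "medium", "high"), ordered = TRUE)
  out3 <- stratify_eval(score, labels, strata3)
  expect_equal(out3$table[stratum == "high", n], 0L)
  expect_true(is.na(out3$table[stratum == "high", auc]))
})

test_that("tissue-of-origin ranks classes with nested top-2 accuracy", {
  set.seed(66)
  n_per <- 12L
  types <- rep(c("BRCA", "LIHC", "CRC"), each = n_per)
  n <- length(types)
  mk <- function(shift) {
    v <- cbind(shift + rnorm(n, 0, 0.5), matrix(rnorm(n * 2), n))
    rownames(v) <- paste0("s", 1:n); colnames(v) <- paste0("f", 1:3)
    pattern_matrix("ifs", v, "region")
  }
  # BRCA and LIHC are confusable (close shifts); CRC well separated
  shift <- c(BRCA = 1, LIHC = 1.6, CRC = 6)[types]
  mats <- list(ifs = mk(shift), cov = mk(shift * 0.8))
  mats$cov$pattern <- "coverage"
  plan <- make_folds(types, repeats = 2, folds = 3, seed = 4)
  too <- too_classify(mats, types, plan, pca = FALSE)
  expect_true(all(too$second >= too$first))
  expect_equal(dim(too$prob), c(n, 3L))
  expect_equal(sum(too$confusion), n)
  expect_equal(unname(too$first["CRC"]), 1)
  # confusion concentrated in the confusable pair
  off_diag <- too$confusion
  diag(off_diag) <- 0
  expect_gte(off_diag["BRCA", "LIHC"] + off_diag["LIHC", "BRCA"],
             sum(off_diag) - off_diag["BRCA", "LIHC"] - off_diag["LIHC", "BRCA"])
  expect_error(too_classify(mats, rep("BRCA", n), plan), ">= 2 cancer types")
})
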