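#' Repeated stratified cross-validation plan
#'
#' Builds the fold assignments for repeated stratified k-fold
#' cross-validation (default 10 repeats of 10-fold). Within each repeat,
#' every class is shuffled and dealt across folds, so the class ratio is
#' preserved in each fold up to one sample. Fully reproducible from the
#' seed.
#'
#' @param labels Class label per sample.
#' @param repeats,folds Number of repeats and folds.
#' @param seed Integer seed.
#' @return A `FoldPlan`: list with `repeats`, `folds`, `seed`, and `assign`
#'   (samples x repeats integer matrix of fold ids).
#' @export
make_folds <- function(labels, repeats = 10L, folds = 10L, seed = 1L) {
  labels <- as.character(labels)
  n <- length(labels)
  cnt <- table(labels)
  if (any(cnt < folds)) {
    stop("class '", names(cnt)[which.min(cnt)], "' has ", min(cnt),
         " sample(s) < ", folds, " folds; use fewer folds")
  }
  seeds <- derive_seeds(seed, repeats, "folds")
  assign <- matrix(NA_integer_, n, repeats)
  for (r in seq_len(repeats)) {
    set.seed(seeds[r])
    for (cl in names(cnt)) {
      idx <- sample(which(labels == cl))
      assign[idx, r] <- rep_len(seq_len(folds), length(idx))
    }
  }
  structure(list(repeats = as.integer(repeats), folds = as.integer(folds),
                 seed = as.integer(seed), assign = assign),
            class = "FoldPlan")
}

#' Train a linear-kernel SVM base classifier
#'
#' Fits a linear support vector machine with Platt probability calibration
#' on training rows only; linear because region importance reads the
#' absolute feature weights of the decision function. Deterministic for a
#' fixed seed (the calibration's internal cross-validation is seeded).
#'
#' @param x Training feature matrix.
#' @param y Training labels (two classes present).
#' @param positive Label of the positive (e.g. cancer) class.
#' @param seed Integer seed for the probability calibration.
#' @param cost SVM cost parameter (default 1).
#' @return A `BaseModel` list with the fitted svm, class levels, positive
#'   class, and the linear weight vector + intercept.
#' @export
train_base <- function(x, y, positive, seed = 1L, cost = 1) {
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) < 2L) stop("training set contains a single class")
  if (!positive %in% lev) stop("positive class absent from training labels")
  yf <- factor(y, levels = c(setdiff(lev, positive), positive))
  set.seed(seed)
  fit <- e1071::svm(x = x, y = yf, kernel = "linear", cost = cost,
                    probability = TRUE, scale = FALSE)
  w <- drop(crossprod(fit$coefs, fit$SV))
  structure(list(fit = fit, levels = levels(yf), positive = positive,
                 weights = setNames(as.numeric(w), colnames(x)),
                 intercept = -fit$rho),
            class = "BaseModel")
}

#' @rdname train_base
#' @param model A `BaseModel`.
#' @param newx Matrix of rows to score.
#' @return `predict_prob`: calibrated probability of the positive class,
#'   in `[0, 1]`.
#' @export
predict_prob <- function(model, newx) {
  pr <- predict(model$fit, newx, probability = TRUE)
  as.numeric(attr(pr, "probabilities")[, model$positive])
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks (equivalent to the scaled
#' Mann-Whitney U statistic); tied scores contribute 1/2.
#'
#' @param scores Numeric scores, higher = more positive-like.
#' @param labels Class labels.
#' @param positive Positive-class label.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels, positive) {
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity at fixed specificity
#'
#' Maximum sensitivity attainable by any score threshold whose specificity
#' is at least the target (predicting positive when score >= threshold).
#'
#' @param scores Numeric scores, higher = more positive-like.
#' @param labels Class labels.
#' @param spec Target specificity (e.g. 0.95 or 0.85).
#' @param positive Positive-class label.
#' @return Sensitivity in `[0, 1]`.
#' @export
sens_at_spec <- function(scores, labels, spec, positive) {
  pos <- labels == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thr <- c(sort(unique(scores)), Inf)
  best <- 0
  for (t in thr) {
    pred <- scores >= t
    specificity <- sum(!pred & !pos) / sum(!pos)
    if (specificity >= spec) best <- max(best, sum(pred & pos) / sum(pos))
  }
  best
}

# default PCA dimension: capped at 50 components (configurable upstream)
.default_pca_dim <- function(n_train, n_feat, pca_dim = NULL) {
  min(pca_dim %||% 50L, n_train - 1L, n_feat)
}

#' Fit one cross-validation fold
#'
#' Fits fold-internal preprocessing (PCA) and per-pattern base models using
#' the training rows only; held-out rows never enter any fitted statistic.
#' Exposed so leakage can be verified directly: the returned fit is
#' invariant to any change in non-training rows.
#'
#' @param mats Named list of preprocessed `PatternMatrix`.
#' @param labels Sample labels (aligned with matrix rows).
#' @param train_idx Integer indices of the training rows.
#' @param positive Positive-class label.
#' @param pca Logical; reduce each pattern by PCA before the SVM.
#' @param pca_dim Maximum number of components (default 50).
#' @param seed Integer seed.
#' @return A `FoldFit` list: per-pattern `pca` (or NULL) and `model`.
#' @export
fold_fit <- function(mats, labels, train_idx, positive, pca = TRUE,
                     pca_dim = NULL, seed = 1L) {
  seeds <- derive_seeds(seed, length(mats), "foldfit")
  fits <- vector("list", length(mats))
  names(fits) <- names(mats)
  for (i in seq_along(mats)) {
    x <- mats[[i]]$values[train_idx, , drop = FALSE]
    pfit <- NULL
    if (pca) {
      d <- .default_pca_dim(length(train_idx), ncol(x), pca_dim)
      if (d < ncol(x)) {
        pfit <- fit_pca(x, d)
        x <- apply_pca(pfit, x)
      }
    }
    fits[[i]] <- list(pca = pfit,
                      model = train_base(x, labels[train_idx], positive, seed = seeds[i]))
  }
  structure(fits, class = "FoldFit")
}

#' @rdname fold_fit
#' @param fit A `FoldFit`.
#' @param idx Row indices to score.
#' @return `fold_predict`: matrix of positive-class probabilities
#'   (length(idx) x patterns).
#' @export
fold_predict <- function(fit, mats, idx) {
  out <- matrix(NA_real_, length(idx), length(fit),
                dimnames = list(rownames(mats[[1]]$values)[idx], names(fit)))
  for (i in seq_along(fit)) {
    x <- mats[[i]]$values[idx, , drop = FALSE]
    if (!is.null(fit[[i]]$pca)) x <- apply_pca(fit[[i]]$pca, x)
    out[, i] <- predict_prob(fit[[i]]$model, x)
  }
  out
}

#' Per-pattern cross-validated probabilities
#'
#' Runs the fold plan over every pattern: within each fold, PCA (when
#' enabled) and the SVM are fitted on training rows only, and the held-out
#' rows receive out-of-fold probabilities. Every sample is scored exactly
#' once per repeat per pattern.
#'
#' @param mats Named list of preprocessed `PatternMatrix` sharing sample
#'   order.
#' @param labels Sample labels.
#' @param plan A [make_folds()] plan.
#' @param positive Positive-class label.
#' @param pca,pca_dim See [fold_fit()].
#' @return List with `oof` (samples x patterns x repeats array of
#'   out-of-fold probabilities), `mean_oof` (samples x patterns, averaged
#'   over repeats), `auc_by_repeat` (patterns x repeats), and `report` (an
#'   EvalReport `data.table`).
#' @export
cross_validate <- function(mats, labels, plan, positive, pca = TRUE,
                           pca_dim = NULL) {
  ids <- rownames(mats[[1]]$values)
  for (pm in mats) {
    if (!identical(rownames(pm$values), ids)) {
      stop("pattern matrices disagree on sample order")
    }
  }
  n <- length(ids)
  stopifnot(length(labels) == n)
  P <- length(mats); R <- plan$repeats
  oof <- array(NA_real_, c(n, P, R), dimnames = list(ids, names(mats), NULL))
  fold_seeds <- derive_seeds(plan$seed, R * plan$folds, "cv")
  for (r in seq_len(R)) {
    fa <- plan$assign[, r]
    for (f in seq_len(plan$folds)) {
      test <- which(fa == f)
      if (!length(test)) next
      fit <- fold_fit(mats, labels, setdiff(seq_len(n), test), positive,
                      pca = pca, pca_dim = pca_dim,
                      seed = fold_seeds[(r - 1L) * plan$folds + f])
      oof[test, , r] <- fold_predict(fit, mats, test)
    }
  }
  auc_by_repeat <- apply(oof, c(2, 3), function(s) auc(s, labels, positive))
  mean_oof <- apply(oof, c(1, 2), mean)
  report <- .eval_report(auc_by_repeat, mean_oof, labels, positive)
  list(oof = oof, mean_oof = mean_oof, auc_by_repeat = auc_by_repeat,
       report = report)
}

# EvalReport rows: AUC mean, 95% CI over repeat-level AUCs, sensitivity at
# 95%/85% specificity on repeat-averaged out-of-fold scores
.eval_report <- function(auc_by_repeat, pooled, labels, positive) {
  if (is.null(dim(auc_by_repeat))) auc_by_repeat <- matrix(auc_by_repeat, nrow = 1)
  R <- ncol(auc_by_repeat)
  rbindlist(lapply(seq_len(nrow(auc_by_repeat)), function(i) {
    a <- auc_by_repeat[i, ]
    half <- 1.96 * sd(a) / sqrt(R)
    if (!is.finite(half)) half <- 0
    sc <- if (is.matrix(pooled)) pooled[, i] else pooled
    data.table(pattern = rownames(auc_by_repeat)[i] %||% "score",
               auc = mean(a), ci_lo = mean(a) - half, ci_hi = mean(a) + half,
               sens_spec95 = sens_at_spec(sc, labels, 0.95, positive),
               sens_spec85 = sens_at_spec(sc, labels, 0.85, positive))
  }))
}

#' Stack per-pattern probabilities into the IFP score
#'
#' The Integrated Fragmentation Pattern (IFP) ensemble: per repeat, the
#' samples-x-patterns matrix of out-of-fold probabilities is itself
#' cross-validated with the same fold partition — a meta linear SVM is
#' fitted on the training rows' probabilities and scores the held-out rows
#' — so meta-features are always out-of-fold and the IFP score of a sample
#' never involves models that saw it. The final IFP score is the mean over
#' repeats, in `[0, 1]`, higher = more cancer-like.
#'
#' @param cv Result of [cross_validate()].
#' @param labels Sample labels.
#' @param plan The same [make_folds()] plan used for `cv`.
#' @param positive Positive-class label.
#' @param n_patterns Declared pattern count; mismatching meta-feature
#'   columns are rejected.
#' @return List with `score` (per-sample IFP), `by_repeat` (samples x
#'   repeats), `auc_by_repeat`, `report` (one EvalReport row), and
#'   `meta_model` (meta SVM trained on repeat-averaged probabilities, for
#'   scoring external cohorts).
#' @export
stack_ifp <- function(cv, labels, plan, positive, n_patterns = dim(cv$oof)[2]) {
  P <- dim(cv$oof)[2]
  if (P != n_patterns) {
    stop("meta-feature columns (", P, ") != declared pattern count (", n_patterns, ")")
  }
  n <- dim(cv$oof)[1]; R <- plan$repeats
  by_repeat <- matrix(NA_real_, n, R, dimnames = list(dimnames(cv$oof)[[1]], NULL))
  seeds <- derive_seeds(plan$seed, R * plan$folds + 1L, "stack")
  for (r in seq_len(R)) {
    meta_x <- cv$oof[, , r, drop = TRUE]
    fa <- plan$assign[, r]
    for (f in seq_len(plan$folds)) {
      test <- which(fa == f)
      if (!length(test)) next
      m <- train_base(meta_x[-test, , drop = FALSE], labels[-test], positive,
                      seed = seeds[(r - 1L) * plan$folds + f])
      by_repeat[test, r] <- predict_prob(m, meta_x[test, , drop = FALSE])
    }
  }
  score <- rowMeans(by_repeat)
  auc_by_repeat <- apply(by_repeat, 2, function(s) auc(s, labels, positive))
  meta_model <- train_base(cv$mean_oof, labels, positive, seed = seeds[R * plan$folds + 1L])
  report <- .eval_report(matrix(auc_by_repeat, nrow = 1, dimnames = list("IFP", NULL)),
                         matrix(score, ncol = 1), labels, positive)
  list(score = score, by_repeat = by_repeat, auc_by_repeat = auc_by_repeat,
       report = report, meta_model = meta_model)
}

#' Train the full IFP model bundle
#'
#' Cross-validates all patterns, stacks them into the IFP score, and fits
#' frozen full-data per-pattern models plus the meta SVM for later
#' independent validation. The bundle records feature axes so external
#' cohorts are checked against the training configuration.
#'
#' @inheritParams cross_validate
#' @return An `IFPModel` list: `base` (full-data `FoldFit`), `meta_model`,
#'   `cv`, `stack`, `report` (per-pattern rows + IFP row), `positive`,
#'   `feature_axes`.
#' @export
train_ifp <- function(mats, labels, plan, positive, pca = TRUE, pca_dim = NULL) {
  cv <- cross_validate(mats, labels, plan, positive, pca = pca, pca_dim = pca_dim)
  st <- stack_ifp(cv, labels, plan, positive)
  base <- fold_fit(mats, labels, seq_along(labels), positive, pca = pca,
                   pca_dim = pca_dim, seed = derive_seeds(plan$seed, 1L, "full"))
  structure(list(base = base, meta_model = st$meta_model, cv = cv, stack = st,
                 report = rbind(cv$report, st$report), positive = positive,
                 feature_axes = lapply(mats, function(m) colnames(m$values))),
            class = "IFPModel")
}

#' Score an external cohort with a frozen IFP model
#'
#' Applies the trained per-pattern models and meta SVM to an external
#' cohort without any refitting; feature axes must match the training
#' configuration exactly.
#'
#' @param model An `IFPModel` from [train_ifp()].
#' @param mats External preprocessed `PatternMatrix` list.
#' @param labels Optional external labels; when given, an EvalReport is
#'   computed.
#' @return List with `score` (external IFP scores), `probs` (per-pattern
#'   probabilities), and `report` (or NULL).
#' @export
independent_validate <- function(model, mats, labels = NULL) {
  for (p in names(model$feature_axes)) {
    if (is.null(mats[[p]])) stop("external cohort missing pattern: ", p)
    miss <- setdiff(model$feature_axes[[p]], colnames(mats[[p]]$values))
    if (length(miss)) {
      stop("feature axis mismatch for pattern '", p, "'; missing: ",
           paste(head(miss, 5), collapse = ", "))
    }
    mats[[p]]$values <- mats[[p]]$values[, model$feature_axes[[p]], drop = FALSE]
  }
  probs <- fold_predict(model$base, mats[names(model$feature_axes)],
                        seq_len(nrow(mats[[1]]$values)))
  score <- predict_prob(model$meta_model, probs)
  report <- NULL
  if (!is.null(labels)) {
    report <- .eval_report(matrix(auc(score, labels, model$positive), 1,
                                  dimnames = list("IFP-external", NULL)),
                           matrix(score, ncol = 1), labels, model$positive)
  }
  list(score = score, probs = probs, report = report)
}

#' Tissue-of-origin calling by one-vs-rest stacking
#'
#' For each cancer type, a one-vs-rest IFP ensemble (same per-pattern
#' cross-validated stacking) yields a per-sample probability of that type;
#' classes are ranked per sample (ties broken by fixed class order) and
#' accuracy of the first- and second-ranked calls is reported per class.
#'
#' @param mats Preprocessed `PatternMatrix` list (cancer samples only).
#' @param types Cancer-type label per sample (>= 2 types).
#' @param plan A [make_folds()] plan stratified on `types`.
#' @param pca,pca_dim See [fold_fit()].
#' @return A `TOOReport` list: `prob` (samples x types), `first`/`second`
#'   per-class accuracies, `overall_first`/`overall_second` (medians over
#'   classes), and `confusion` (truth x top-ranked call).
#' @export
too_classify <- function(mats, types, plan, pca = TRUE, pca_dim = NULL) {
  types <- as.character(types)
  classes <- sort(unique(types))
  if (length(classes) < 2L) stop("tissue-of-origin needs >= 2 cancer types")
  n <- length(types)
  prob <- matrix(NA_real_, n, length(classes),
                 dimnames = list(rownames(mats[[1]]$values), classes))
  for (cl in classes) {
    lab <- ifelse(types == cl, cl, "rest")
    cv <- cross_validate(mats, lab, plan, positive = cl, pca = pca, pca_dim = pca_dim)
    st <- stack_ifp(cv, lab, plan, positive = cl)
    prob[, cl] <- st$score
  }
  ord <- t(apply(prob, 1, function(p) order(-p, seq_along(p))))
  top1 <- classes[ord[, 1]]
  top2 <- classes[ord[, 2]]
  first <- vapply(classes, function(cl) mean(top1[types == cl] == cl), numeric(1))
  second <- vapply(classes, function(cl) {
    sel <- types == cl
    mean(top1[sel] == cl | top2[sel] == cl)
  }, numeric(1))
  confusion <- table(truth = factor(types, classes), predicted = factor(top1, classes))
  structure(list(prob = prob, first = first, second = second,
                 overall_first = median(first), overall_second = median(second),
                 confusion = confusion),
            class = "TOOReport")
}

#' Tumor-fraction bins
#'
#' Bins tumor fractions into low `[0, 2%)`, medium `[2%, 15%)` and high
#' `[15%, 100%]`.
#'
#' @param tf Tumor fractions in `[0, 1]`.
#' @return Ordered factor with levels low, medium, high.
#' @export
tumor_fraction_bin <- function(tf) {
  cut(tf, breaks = c(-Inf, 0.02, 0.15, Inf), labels = c("low", "medium", "high"),
      right = FALSE, ordered_result = TRUE)
}

#' Stratified evaluation of IFP scores
#'
#' AUC of each cancer stratum (clinical stage or tumor-fraction bin)
#' against the full control set, with per-stratum score summaries,
#' Wilcoxon rank-sum comparisons between consecutive strata, and a
#' Kruskal-Wallis test across all strata.
#'
#' @param score Per-sample IFP score.
#' @param labels Sample labels.
#' @param strata Stratum per sample (NA for controls is allowed); e.g.
#'   [tumor_fraction_bin()] output or stage labels.
#' @param positive Positive-class label.
#' @return List with `table` (stratum, n, auc vs controls, mean/median
#'   score), `pairwise` (Wilcoxon p between consecutive strata), and
#'   `kruskal_p`. Empty strata appear with NA, not an error.
#' @export
stratify_eval <- function(score, labels, strata, positive = "cancer") {
  ctrl <- labels != positive
  lv <- if (is.factor(strata)) levels(strata) else sort(unique(strata[!ctrl]))
  tab <- rbindlist(lapply(lv, function(s) {
    sel <- !ctrl & !is.na(strata) & strata == s
    if (!any(sel)) {
      return(data.table(stratum = s, n = 0L, auc = NA_real_,
                        mean_score = NA_real_, median_score = NA_real_))
    }
    sc <- c(score[sel], score[ctrl])
    lb <- c(rep(positive, sum(sel)), rep("control", sum(ctrl)))
    data.table(stratum = s, n = sum(sel), auc = auc(sc, lb, positive),
               mean_score = mean(score[sel]), median_score = median(score[sel]))
  }))
  pairwise <- NULL
  present <- tab$stratum[tab$n > 0L]
  if (length(present) >= 2L) {
    pairwise <- rbindlist(lapply(seq_len(length(present) - 1L), function(i) {
      a <- score[!ctrl & !is.na(strata) & strata == present[i]]
      b <- score[!ctrl & !is.na(strata) & strata == present[i + 1L]]
      data.table(a = present[i], b = present[i + 1L],
                 p = suppressWarnings(wilcox.test(a, b)$p.value))
    }))
  }
  kw <- NA_real_
  ok <- !ctrl & !is.na(strata)
  if (length(unique(strata[ok])) >= 2L) {
    kw <- kruskal.test(score[ok], factor(strata[ok]))$p.value
  }
  list(table = tab, pairwise = pairwise, kruskal_p = kw)
}
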