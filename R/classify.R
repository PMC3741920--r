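# Feature-set composition, SVM bootstrap evaluation, confusion metrics,
# ROC/AUC and ANOVA/LSD feature screening.

proposedLumenFeatures <- c("RMSAA", "TSAV", "AtypiaRatio", "NumAtypiaRegions")
proposedEpithelialFeatures <- c("CytoplasmLength", "CytoplasmLength_SD")

#' Feature-set definitions
#'
#' The thirteen feature sets evaluated in the classification experiments:
#' per-object classical sets (CNF, CLF, CEF), the proposed lumen and
#' epithelial sets (PLF, PEF), and their unions for the lumen (ALF),
#' epithelium (AEF), duct (CDF, PDF, ADF) and whole tissue
#' (CTF, PTF, ATF).
#'
#' @return named list of character vectors of feature-table column names.
#' @export
featureSetSpecs <- function() {
  CLF <- paste0("Lumen_", classicalFeatureNames)
  CEF <- paste0("EN_", classicalFeatureNames)
  CNF <- paste0("NEN_", classicalFeatureNames)
  PLF <- proposedLumenFeatures
  PEF <- proposedEpithelialFeatures
  list(CNF = CNF, CLF = CLF, PLF = PLF, ALF = c(CLF, PLF),
       CEF = CEF, PEF = PEF, AEF = c(CEF, PEF),
       CDF = c(CLF, CEF), PDF = c(PLF, PEF), ADF = c(CLF, CEF, PLF, PEF),
       CTF = c(CLF, CEF, CNF), PTF = c(PLF, PEF, CNF),
       ATF = c(CLF, CEF, PLF, PEF, CNF))
}

#' Assemble labelled datasets for every feature set
#'
#' @param feature_table data.frame of per-image averaged features including
#'   a `label` column.
#' @param positive label value mapped to class `+1`; every other label maps
#'   to `-1`. Defaults to the second sorted unique label.
#' @return named list of `list(x = matrix, y = factor(-1, +1))`, one per
#'   feature set.
#' @export
buildFeatureSets <- function(feature_table, positive = NULL) {
  specs <- featureSetSpecs()
  missing_cols <- setdiff(unique(unlist(specs)), colnames(feature_table))
  if (length(missing_cols))
    stop("feature table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"label" %in% colnames(feature_table)) stop("feature table needs a 'label' column")
  labs <- feature_table$label
  if (is.null(positive)) positive <- sort(unique(labs))[min(2, length(unique(labs)))]
  y <- factor(ifelse(labs == positive, 1, -1), levels = c(-1, 1))
  lapply(specs, function(cols)
    list(x = as.matrix(feature_table[, cols, drop = FALSE]), y = y))
}

#' Confusion-matrix performance measures
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values and accuracy, each in percent. Counts may be
#' fractional (bootstrap means). A zero denominator yields `NA` for that
#' measure.
#'
#' @param TP,FP,FN,TN non-negative counts.
#' @return named numeric vector `SN`, `SP`, `PPV`, `NPV`, `ACC` (percent).
#' @export
confusionMetrics <- function(TP, FP, FN, TN) {
  stopifnot(TP >= 0, FP >= 0, FN >= 0, TN >= 0)
  rate <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  c(SN = rate(TP, TP + FN), SP = rate(TN, TN + FP),
    PPV = rate(TP, TP + FP), NPV = rate(TN, TN + FN),
    ACC = rate(TP + TN, TP + TN + FP + FN))
}

#' SVM evaluation protocol
#'
#' The printed grids and split design: soft-margin RBF SVM, `C` in
#' `10^(-1), 10^(-0.5), ..., 10^4`, `gamma` in `2^(-5), 2^(-4.5), ..., 2^0`,
#' parameters chosen by 10-fold cross-validated accuracy on the training
#' split, 60:40 train:test, 10 evaluation repetitions.
#'
#' @param reps repetitions (training/testing set pairs).
#' @param train_frac training fraction of each split.
#' @param folds cross-validation folds of the grid search.
#' @param resample `"split"` for repeated stratified splits (default) or
#'   `"bootstrap"` for with-replacement resampling of the training set.
#' @param seed master seed for all protocol randomness.
#' @export
svmProtocol <- function(reps = 10, train_frac = 0.6, folds = 10,
                        resample = c("split", "bootstrap"), seed = 1) {
  list(C_grid = 10^seq(-1, 4, by = 0.5),
       gamma_grid = 2^seq(-5, 0, by = 0.5),
       reps = reps, train_frac = train_frac, folds = folds,
       resample = match.arg(resample), seed = as.integer(seed))
}

# stratified fold assignment, deterministic under the active RNG
foldAssign <- function(y, folds) {
  f <- integer(length(y))
  for (cl in levels(y)) {
    i <- which(y == cl)
    f[i] <- sample(rep_len(seq_len(folds), length(i)))
  }
  f
}

gridSearchCV <- function(x, y, proto) {
  folds <- foldAssign(y, proto$folds)
  best <- c(acc = -1, C = NA, gamma = NA)
  for (C in proto$C_grid) for (g in proto$gamma_grid) {
    correct <- 0
    for (f in seq_len(proto$folds)) {
      tr <- folds != f
      if (length(unique(y[tr])) < 2) next
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], type = "C-classification",
                        kernel = "radial", cost = C, gamma = g, scale = FALSE)
      correct <- correct + sum(predict(fit, x[!tr, , drop = FALSE]) == y[!tr])
    }
    acc <- correct / length(y)
    # strictly-greater keeps the smallest C, then smallest gamma, on ties
    if (acc > best["acc"] + 1e-12) best <- c(acc = acc, C = C, gamma = g)
  }
  best
}

#' Bootstrap evaluation of an SVM classifier on one labelled dataset
#'
#' For each repetition: a stratified 60/40 split (or bootstrap resample),
#' z-score standardization fitted on the training split, grid search for
#' `(C*, gamma*)` by 10-fold cross-validated accuracy (ties resolved
#' toward the smallest `C`, then the smallest `gamma`), a final RBF
#' soft-margin fit, and scoring on the test split. Confusion counts, the
#' derived percentage measures and the ROC/AUC are averaged across
#' repetitions.
#'
#' @param x numeric feature matrix.
#' @param y factor with levels `-1`, `+1` (`+1` = positive/disease class).
#' @param proto an [svmProtocol()].
#' @return list with `per_rep` (data.frame of counts, metrics, AUC and the
#'   chosen parameters), `mean`, `sd`, and `roc` (vertically averaged ROC
#'   curve over a common FPR grid).
#' @export
trainEvalBootstrap <- function(x, y, proto = svmProtocol()) {
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("training data must contain both classes")
  levels(y) <- as.character(levels(y))
  pos <- levels(y)[2]
  rows <- vector("list", proto$reps)
  rocs <- vector("list", proto$reps)
  withSeed(proto$seed, {
    for (r in seq_len(proto$reps)) {
      tr_idx <- integer(0)
      for (cl in levels(y)) {
        i <- which(y == cl)
        n_tr <- round(length(i) * proto$train_frac)
        picked <- sample(i, n_tr)
        tr_idx <- c(tr_idx, if (proto$resample == "bootstrap")
          sample(picked, length(picked), replace = TRUE) else picked)
      }
      te_idx <- setdiff(seq_along(y), unique(tr_idx))
      mu <- colMeans(x[tr_idx, , drop = FALSE])
      sg <- apply(x[tr_idx, , drop = FALSE], 2, stats::sd)
      sg[sg < 1e-12] <- 1
      xs <- sweep(sweep(x, 2, mu), 2, sg, "/")
      best <- gridSearchCV(xs[tr_idx, , drop = FALSE], y[tr_idx], proto)
      fit <- e1071::svm(xs[tr_idx, , drop = FALSE], y[tr_idx],
                        type = "C-classification", kernel = "radial",
                        cost = best["C"], gamma = best["gamma"], scale = FALSE)
      pred <- predict(fit, xs[te_idx, , drop = FALSE], decision.values = TRUE)
      dv <- attr(pred, "decision.values")[, 1]
      # orient decision values so that larger means more positive
      if (!grepl(paste0("^", pos, "/"), colnames(attr(pred, "decision.values"))[1]))
        dv <- -dv
      yt <- y[te_idx]
      TP <- sum(pred == pos & yt == pos); TN <- sum(pred != pos & yt != pos)
      FP <- sum(pred == pos & yt != pos); FN <- sum(pred != pos & yt == pos)
      roc <- rocAuc(dv, yt == pos)
      rocs[[r]] <- roc
      rows[[r]] <- data.frame(rep = r, TN = TN, FP = FP, FN = FN, TP = TP,
                              t(confusionMetrics(TP, FP, FN, TN)),
                              AUC = roc$auc, C = best["C"], gamma = best["gamma"])
    }
  })
  per_rep <- do.call(rbind, rows)
  num <- per_rep[, c("TN", "FP", "FN", "TP", "SN", "SP", "PPV", "NPV", "ACC", "AUC")]
  fpr_grid <- seq(0, 1, by = 0.01)
  tpr_avg <- rowMeans(vapply(rocs, function(rc)
    stats::approx(rc$fpr, rc$tpr, xout = fpr_grid, ties = "ordered",
                  yleft = 0, yright = 1)$y, numeric(length(fpr_grid))))
  list(per_rep = per_rep,
       mean = colMeans(num, na.rm = TRUE),
       sd = apply(num, 2, stats::sd, na.rm = TRUE),
       roc = data.frame(fpr = fpr_grid, tpr = tpr_avg))
}

#' ROC curve and AUC from decision scores
#'
#' Sweeps a threshold over the scores (ties handled jointly) and integrates
#' the curve by the trapezoid rule, which counts tied pairs one half.
#'
#' @param scores numeric decision values, larger = more positive.
#' @param labels logical or 0/1 vector, `TRUE` = positive.
#' @return list with `fpr`, `tpr` (threshold sweep, including both
#'   endpoints) and `auc`.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  P <- sum(labels); N <- sum(!labels)
  if (P == 0 || N == 0) stop("ROC needs both classes")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # advance over groups of tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- which(!duplicated(grp, fromLast = TRUE))
  tpr <- c(0, tp[last] / P); fpr <- c(0, fp[last] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Per-feature one-way ANOVA with Fisher LSD post-hoc screening
#'
#' Tests, for every feature column, the null hypothesis that all group
#' means are equal (one-way ANOVA F-test at level `alpha`); for rejected
#' features, computes Fisher's least significant difference
#' `LSD = t(1 - alpha/2, df_W) * sqrt(MS_W (1/n_a + 1/n_b))` and flags each
#' group pair whose absolute mean difference exceeds it.
#'
#' @param features data.frame or matrix of feature columns.
#' @param groups factor of group labels (>= 2 groups, >= 2 samples each).
#' @param alpha significance level.
#' @return data.frame with one row per feature x group pair: group means,
#'   `F`, `df1`, `df2`, `reject` flag, `mean_diff`, `LSD` and `pair_reject`.
#' @export
anovaLsd <- function(features, groups, alpha = 0.01) {
  groups <- droplevels(as.factor(groups))
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  features <- as.data.frame(features)
  pairs <- utils::combn(levels(groups), 2)
  out <- lapply(colnames(features), function(fn) {
    v <- features[[fn]]
    gm <- tapply(v, groups, mean)
    ni <- tabulate(groups)
    k <- nlevels(groups); n <- length(v)
    ssb <- sum(ni * (gm - mean(v))^2)
    ssw <- sum((v - gm[groups])^2)
    df1 <- k - 1; df2 <- n - k
    msb <- ssb / df1; msw <- ssw / df2
    F <- if (ssb < 1e-24 && ssw < 1e-24) 0 else if (msw < 1e-24) Inf else msb / msw
    crit <- stats::qf(1 - alpha, df1, df2)
    reject <- is.finite(F) && F > crit || is.infinite(F)
    do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      na <- sum(groups == a); nb <- sum(groups == b)
      lsd <- stats::qt(1 - alpha / 2, df2) * sqrt(msw * (1 / na + 1 / nb))
      md <- abs(gm[a] - gm[b])
      data.frame(feature = fn, group_a = a, group_b = b,
                 mean_a = gm[a], mean_b = gm[b],
                 F = F, df1 = df1, df2 = df2, reject = reject,
                 mean_diff = md, LSD = lsd,
                 pair_reject = if (reject) md > lsd else NA)
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
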