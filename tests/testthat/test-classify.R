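test_that("feature-set compositions have the published dimensions", {
  specs <- featureSetSpecs()
  dims <- vapply(specs, length, integer(1))
  expect_equal(dims, c(CNF = 12L, CLF = 12L, PLF = 4L, ALF = 16L,
                       CEF = 12L, PEF = 2L, AEF = 14L,
                       CDF = 24L, PDF = 6L, ADF = 30L,
                       CTF = 36L, PTF = 18L, ATF = 42L))
  expect_setequal(specs$ADF, union(specs$CDF, specs$PDF))
  expect_setequal(specs$PTF, c(specs$PLF, specs$PEF, specs$CNF))
  expect_equal(anyDuplicated(specs$ATF), 0)
})

test_that("datasets are assembled per set and missing columns are named", {
  cols <- unique(unlist(featureSetSpecs()))
  tab <- as.data.frame(matrix(rnorm(20 * length(cols)), 20,
                              dimnames = list(NULL, cols)))
  tab$label <- rep(c("Normal", "PDAC"), each = 10)
  ds <- buildFeatureSets(tab, positive = "PDAC")
  expect_named(ds, names(featureSetSpecs()))
  expect_equal(ncol(ds$PDF$x), 6)
  expect_equal(as.integer(table(ds$PDF$y)), c(10, 10))
  bad <- tab[, setdiff(colnames(tab), "RMSAA")]
  expect_error(buildFeatureSets(bad), "RMSAA")
})

test_that("confusion metrics reproduce the published accuracy values", {
  perfect <- confusionMetrics(TP = 1, FP = 0, FN = 0, TN = 1)
  expect_equal(unname(perfect), rep(100, 5))
  # mean confusion counts from the evaluation tables
  cnf <- confusionMetrics(TP = 25.70, FP = 6.30, FN = 5.50, TN = 26.50)
  expect_equal(round(unname(cnf["ACC"]), 2), 81.56)
  pdf <- confusionMetrics(TP = 30.60, FP = 1.40, FN = 2.20, TN = 29.80)
  expect_equal(round(unname(pdf["ACC"]), 2), 94.38)
  plf2 <- confusionMetrics(TP = 25.50, FP = 6.50, FN = 8.20, TN = 23.80)
  expect_equal(round(unname(plf2["ACC"]), 2), 77.03)
  # zero denominators give NA, never zero
  none <- confusionMetrics(TP = 0, FP = 0, FN = 3, TN = 5)
  expect_true(is.na(none["PPV"]))
  # complement identities on random fractional counts
  set.seed(8)
  for (i in 1:20) {
    v <- runif(4, 0, 50)
    m <- confusionMetrics(v[1], v[2], v[3], v[4])
    expect_equal(unname(m["SN"]), 100 * v[1] / (v[1] + v[3]))
    expect_equal(unname(m["ACC"]),
                 100 * (v[1] + v[4]) / sum(v))
  }
})

test_that("ROC/AUC matches hand values and the concordant-pair oracle", {
  expect_equal(rocAuc(c(1, 2, 3, 4), c(F, F, T, T))$auc, 1)
  expect_equal(rocAuc(c(4, 3, 2, 1), c(F, F, T, T))$auc, 0)
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(F, F, T, T))$auc, 0.75)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  set.seed(19)
  for (i in 1:25) {
    n <- sample(8:40, 1)
    sc <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # ties likely
    lb <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(lb)) < 2) next
    expect_equal(rocAuc(sc, lb)$auc, bruteAuc(sc, lb), tolerance = 1e-12)
  }
})

test_that("the SVM protocol separates well-separated classes and stays on-grid", {
  set.seed(4)
  x <- rbind(matrix(rnorm(40 * 4, 0, 1), 40), matrix(rnorm(40 * 4, 6, 1), 40))
  y <- factor(rep(c(-1, 1), each = 40))
  proto <- svmProtocol(reps = 3, seed = 12)
  ev <- trainEvalBootstrap(x, y, proto)
  expect_gte(ev$mean[["ACC"]], 99)
  expect_true(all(ev$per_rep$C %in% proto$C_grid))
  expect_true(all(ev$per_rep$gamma %in% proto$gamma_grid))
  expect_equal(ev$per_rep$TP + ev$per_rep$TN + ev$per_rep$FP + ev$per_rep$FN,
               rep(32, 3))  # 40% of 80
  expect_error(trainEvalBootstrap(x, factor(rep(1, 80))), "both classes")
  # repeated runs with the same protocol seed are identical
  ev2 <- trainEvalBootstrap(x, y, proto)
  expect_identical(ev$per_rep, ev2$per_rep)
})

test_that("one-way ANOVA with LSD matches the closed-form worked example", {
  v <- c(1, 2, 3, 4, 5, 6, 7, 8, 9)
  g <- factor(rep(c("N", "G1", "G2"), each = 3), levels = c("N", "G1", "G2"))
  res <- anovaLsd(data.frame(f = v), g)
  expect_equal(unique(res$F), 27)
  expect_equal(unique(res$df1), 2)
  expect_equal(unique(res$df2), 6)
  expect_true(all(res$reject))
  ident <- anovaLsd(data.frame(f = rep(c(1, 2, 3), 3)),
                    factor(rep(1:3, each = 3)))
  expect_equal(unique(ident$F), 0)
  expect_false(any(ident$reject))
})

test_that("ANOVA F and LSD flags agree with the stats-package route", {
  set.seed(55)
  for (i in 1:10) {
    v <- rnorm(30, mean = rep(c(0, 1, 3) * runif(1, 0, 2), each = 10))
    g <- factor(rep(c("a", "b", "c"), each = 10))
    res <- anovaLsd(data.frame(f = v), g, alpha = 0.01)
    ref <- anova(lm(v ~ g))
    expect_equal(unique(res$F), ref$`F value`[1], tolerance = 1e-10)
    msw <- ref$`Mean Sq`[2]
    lsd <- qt(1 - 0.01 / 2, ref$Df[2]) * sqrt(msw * (1 / 10 + 1 / 10))
    expect_equal(unique(res$LSD), lsd, tolerance = 1e-10)
    if (res$reject[1]) {
      means <- tapply(v, g, mean)
      want <- abs(means["a"] - means["b"]) > lsd
      expect_equal(res$pair_reject[res$group_a == "a" & res$group_b == "b"],
                   unname(want))
    }
  }
})
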