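# Classification metrics, ROC/AUC, Dice, Hausdorff and the aggregation
# conventions.

labels_from_counts <- function(tp, fn, tn, fp) {
  list(truth = rep(c("carcinoma", "non-carcinoma"), c(tp + fn, tn + fp)),
       pred = c(rep("carcinoma", tp), rep("non-carcinoma", fn),
                rep("non-carcinoma", tn), rep("carcinoma", fp)))
}

test_that("confusion matches a brute-force tally", {
  l <- labels_from_counts(10, 0, 10, 0)
  cc <- confusion(l$truth, l$pred)
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 10, TN = 10, FP = 0, FN = 0))

  # all predicted carcinoma: no FN, no TN
  cc2 <- confusion(l$truth, rep("carcinoma", 20))
  expect_equal(cc2$FN, 0); expect_equal(cc2$TN, 0)

  truth <- stainseg:::with_seed(5, sample(c("carcinoma", "non-carcinoma"),
                                          50, TRUE))
  pred <- stainseg:::with_seed(6, sample(c("carcinoma", "non-carcinoma"),
                                         50, TRUE))
  cc3 <- confusion(truth, pred)
  expect_equal(cc3$TP, sum(truth == "carcinoma" & pred == "carcinoma"))
  expect_equal(cc3$FP, sum(truth == "non-carcinoma" & pred == "carcinoma"))
  expect_equal(cc3$TP + cc3$TN + cc3$FP + cc3$FN, 50)

  expect_error(confusion(truth, rep("benign", 50)), "labels")
})

test_that("metrics reproduce the printed worked examples exactly", {
  # image-wise confusion: 36 test images, all errors are missed carcinomas
  m <- classification_metrics(list(TP = 15, FN = 3, TN = 18, FP = 0))
  expect_equal(m$accuracy, 91.67)
  expect_equal(m$sensitivity, 83.33)
  expect_equal(m$specificity, 100)
  expect_equal(m$precision, 100)
  expect_equal(m$f1, 90.91)

  # patch-wise confusion at 360 + 360 patches
  m2 <- classification_metrics(list(TP = 260, FN = 100, TN = 332, FP = 28))
  expect_equal(m2$accuracy, 82.22)
  expect_equal(m2$f1, 80.25)
  expect_equal(m2$sensitivity, 72.22)
  expect_equal(m2$specificity, 92.22)
  expect_equal(m2$precision, 90.28)

  perfect <- classification_metrics(list(TP = 5, FN = 0, TN = 5, FP = 0))
  expect_true(all(unlist(perfect) == 100))

  # undefined metrics reported as NA, not 0
  m3 <- classification_metrics(list(TP = 0, FN = 0, TN = 5, FP = 0))
  expect_true(is.na(m3$sensitivity))
  expect_error(classification_metrics(list(TP = 0, FN = 0, TN = 0, FP = 0)),
               "empty")
})

test_that("roc_auc agrees with the exhaustive pairwise estimator", {
  s <- c(3, 2, 1, -1, -2, -3)
  l <- rep(c("carcinoma", "non-carcinoma"), each = 3)
  r <- roc_auc(s, l)
  expect_equal(r$auc, 1)

  # identical scores: chance diagonal
  expect_equal(roc_auc(rep(0.5, 10),
                       rep(c("carcinoma", "non-carcinoma"), 5))$auc, 0.5)

  # 6-sample tie case against the pair oracle
  s2 <- c(2, 1, 1, 1, 0, -1)
  r2 <- roc_auc(s2, l)
  expect_equal(r2$auc, auc_oracle(s2, l))

  for (seed in 1:10) {
    n <- 20 + seed
    sc <- stainseg:::with_seed(seed, round(rnorm(n), 1))
    lb <- stainseg:::with_seed(seed + 50,
                               sample(c("carcinoma", "non-carcinoma"), n,
                                      TRUE, prob = c(0.6, 0.4)))
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb)$auc, auc_oracle(sc, lb), tolerance = 1e-12)
  }
  expect_error(roc_auc(1:5, rep("carcinoma", 5)), "both classes")
})

test_that("roc_auc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  sc <- stainseg:::with_seed(9, rnorm(40))
  lb <- stainseg:::with_seed(10, sample(c("carcinoma", "non-carcinoma"),
                                        40, TRUE))
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = lb, predictor = sc, levels = c("non-carcinoma", "carcinoma"),
    direction = "<", quiet = TRUE)))
  expect_equal(roc_auc(sc, lb)$auc, ref, tolerance = 1e-12)
})

test_that("dice satisfies its identities and worked example", {
  X <- matrix(0L, 4, 4); X[1:2, 1:2] <- 1L
  expect_equal(dice(X, X), 1)
  Y <- matrix(0L, 4, 4); Y[3:4, 3:4] <- 1L
  expect_equal(dice(X, Y), 0)
  # |X| = |Y| = 4, |X & Y| = 2 -> 0.5
  Z <- matrix(0L, 4, 4); Z[2:3, 1:2] <- 1L
  expect_equal(dice(X, Z), 0.5)
  expect_equal(dice(X, Z), dice(Z, X))
  expect_equal(dice(matrix(0L, 3, 3), matrix(0L, 3, 3)), 1)
  expect_error(dice(X, matrix(0L, 2, 2)), "shape")

  # growing the intersection at fixed sizes never decreases D
  A <- matrix(0L, 6, 6); A[1:3, 1:3] <- 1L
  B1 <- matrix(0L, 6, 6); B1[3:5, 3:5] <- 1L   # intersection 1
  B2 <- matrix(0L, 6, 6); B2[2:4, 2:4] <- 1L   # intersection 4
  expect_gte(dice(A, B2), dice(A, B1))
})

test_that("hausdorff is exact, symmetric and zero on identity", {
  X <- matrix(0L, 10, 10); X[1, 1] <- 1L
  Y <- matrix(0L, 10, 10); Y[4, 5] <- 1L       # 3-4-5 triangle
  expect_equal(hausdorff(X, Y), 5)
  expect_equal(hausdorff(X, X), 0)
  expect_equal(hausdorff(X, Y), hausdorff(Y, X))
  expect_error(hausdorff(X, matrix(0L, 10, 10)), "empty")

  for (s in 1:8) {
    A <- stainseg:::with_seed(s, matrix(rbinom(64, 1, 0.2), 8, 8))
    B <- stainseg:::with_seed(s + 20, matrix(rbinom(64, 1, 0.2), 8, 8))
    if (!any(A) || !any(B)) next
    expect_equal(hausdorff(A, B), hausdorff_oracle(A, B), tolerance = 1e-9)
  }
})

test_that("pseudo_ground_truth applies one shared global threshold", {
  dark <- array(40L, c(8, 8, 3))
  expect_true(all(pseudo_ground_truth(dark, threshold = 0.2) == 1))
  # constant image below threshold (bright, dark_objects): empty mask
  bright <- array(250L, c(8, 8, 3))
  expect_true(all(pseudo_ground_truth(bright, threshold = 0.5) == 0))

  # two-tone image: exact level-set mask
  img <- array(200L, c(8, 8, 3)); img[1:4, , ] <- 30L
  m <- pseudo_ground_truth(img, threshold = 0.5)
  expect_equal(m, rbind(matrix(1L, 4, 8), matrix(0L, 4, 8)))

  # the same configured threshold applies to different images
  img2 <- array(100L, c(8, 8, 3))
  expect_true(all(pseudo_ground_truth(img2, threshold = 0.5) == 1))
})

test_that("dice_aggregate averages overall and maximizes per category", {
  agg <- dice_aggregate(c(0.4, 0.6, 0.8), c("A", "A", "B"))
  expect_equal(agg$mean, 0.6)
  expect_equal(as.numeric(agg$max_per_category[c("A", "B")]), c(0.6, 0.8))

  one <- dice_aggregate(0.7, "A")
  expect_equal(one$mean, 0.7)
  expect_equal(as.numeric(one$max_per_category), 0.7)

  perm <- dice_aggregate(c(0.8, 0.4, 0.6), c("B", "A", "A"))
  expect_equal(perm$mean, agg$mean)
  expect_equal(perm$max_per_category[c("A", "B")],
               agg$max_per_category[c("A", "B")])
})
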