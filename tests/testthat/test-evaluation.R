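toy_cm <- function() {
  # N row: 8 correct, 2 predicted S; S row: 1 predicted N, 9 correct;
  # V, F, Q all 10 correct
  confusion_matrix5(
    c(rep("N", 10), rep("S", 10), rep("V", 10), rep("F", 10), rep("Q", 10)),
    c(rep("N", 8), "S", "S", "N", rep("S", 9), rep("V", 10), rep("F", 10),
      rep("Q", 10))
  )
}

test_that("the confusion matrix counts reference-by-predicted pairs", {
  cm <- confusion_matrix5(c("N", "N", "S"), c("N", "S", "S"))
  expect_identical(cm["N", "N"], 1L)
  expect_identical(cm["N", "S"], 1L)
  expect_identical(cm["S", "S"], 1L)
  expect_identical(sum(cm), 3L)

  truth <- sample(aami_classes, 200, TRUE)
  cm2 <- confusion_matrix5(truth, truth)
  expect_identical(sum(diag(cm2)), 200L)
  expect_identical(sum(cm2) - sum(diag(cm2)), 0L)
  expect_identical(unname(rowSums(cm2)),
                   as.numeric(table(factor(truth, levels = aami_classes))))

  expect_error(confusion_matrix5("N", c("N", "S")), "equal length")
  expect_error(confusion_matrix5("N", "X"), "labels must be")
})

test_that("per-class counts follow the TP/FP/TN/FN decomposition", {
  cm <- toy_cm()
  n_counts <- per_class_counts(cm, "N")
  expect_identical(n_counts$TP, 8L)
  expect_identical(n_counts$FN, 2L)
  expect_identical(n_counts$FP, 1L)
  expect_identical(n_counts$TN, 39L)
  all_counts <- per_class_counts(cm)
  expect_true(all(all_counts$TP + all_counts$FP + all_counts$TN +
                    all_counts$FN == sum(cm)))
  # diagonal matrix: no confusions anywhere
  diag_cm <- confusion_matrix5(rep(aami_classes, 4), rep(aami_classes, 4))
  dc <- per_class_counts(diag_cm)
  expect_true(all(dc$FP == 0L & dc$FN == 0L))
  expect_error(per_class_counts(cm, "X"), "invalid class")
})

test_that("metrics evaluate to the hand-computed percentages", {
  m <- class_metrics(toy_cm())
  n <- m[m$class == "N", ]
  expect_equal(n$Se, 80)
  expect_equal(n$Sp, 97.5)
  expect_equal(n$PPV, 800 / 9, tolerance = 1e-12) # 88.888...%
  expect_equal(n$Acc, 94)
  expect_equal(attr(m, "overall_accuracy"), 94)

  perfect <- class_metrics(
    confusion_matrix5(rep(aami_classes, 3), rep(aami_classes, 3))
  )
  expect_true(all(perfect$Se == 100 & perfect$Sp == 100 &
                    perfect$PPV == 100 & perfect$Acc == 100))
})

test_that("zero denominators yield NA rates, never errors", {
  cm <- confusion_matrix5(rep("N", 10), rep("N", 10)) # S,V,F,Q absent
  m <- class_metrics(cm)
  s <- m[m$class == "S", ]
  expect_true(is.na(s$Se))  # no S in truth
  expect_true(is.na(s$PPV)) # no S predicted
  expect_equal(s$Sp, 100)
  expect_equal(overall_accuracy(cm), 100)
})

test_that("per-class counts agree with brute-force enumeration", {
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(20:60, 1)
    truth <- sample(aami_classes, n, TRUE)
    pred <- sample(aami_classes, n, TRUE)
    cm <- confusion_matrix5(truth, pred)
    counts <- per_class_counts(cm)
    for (cl in aami_classes) {
      expect_identical(counts$TP[counts$class == cl],
                       sum(truth == cl & pred == cl))
      expect_identical(counts$FN[counts$class == cl],
                       sum(truth == cl & pred != cl))
      expect_identical(counts$FP[counts$class == cl],
                       sum(truth != cl & pred == cl))
      expect_identical(counts$TN[counts$class == cl],
                       sum(truth != cl & pred != cl))
    }
    expect_equal(overall_accuracy(cm), 100 * mean(truth == pred))
  }
})

test_that("metrics are independent of class enumeration order", {
  set.seed(13)
  truth <- sample(aami_classes, 100, TRUE)
  pred <- sample(aami_classes, 100, TRUE)
  m <- class_metrics(confusion_matrix5(truth, pred))
  # relabelling classes by a permutation permutes the metric rows
  perm <- c(N = "V", S = "Q", V = "N", F = "S", Q = "F")
  mp <- class_metrics(confusion_matrix5(unname(perm[truth]),
                                        unname(perm[pred])))
  for (cl in aami_classes) {
    expect_equal(m$Se[m$class == cl], mp$Se[mp$class == perm[[cl]]])
    expect_equal(m$PPV[m$class == cl], mp$PPV[mp$class == perm[[cl]]])
  }
})

test_that("tidy and CSV reporting round to two decimals only at the edge", {
  cm <- toy_cm()
  td <- tidy(cm)
  expect_identical(nrow(td), 25L)
  expect_identical(sum(td$n), 50L)
  path <- tempfile(fileext = ".csv")
  write_metrics_csv(class_metrics(cm), path)
  back <- read.csv(path)
  expect_equal(back$PPV[back$class == "N"], 88.89)
  # in-memory value keeps full precision
  m <- class_metrics(cm)
  expect_false(isTRUE(all.equal(m$PPV[m$class == "N"], 88.89)))
})
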