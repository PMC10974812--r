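worked_cm <- function() {
  matrix(c(3L, 1L, 2L, 4L), 2, 2, byrow = TRUE,
         dimnames = list(true = c("Fear", "Anger"),
                         predicted = c("Fear", "Anger")))
}

random_cm <- function(k, max_count = 20) {
  matrix(sample(0:max_count, k * k, TRUE), k, k,
         dimnames = list(true = letters[1:k], predicted = letters[1:k]))
}

test_that("overall accuracy is trace over total", {
  expect_equal(overall_accuracy(diag(1L, 2)), 1)
  expect_equal(overall_accuracy(worked_cm()), 0.7)
  off <- matrix(c(0L, 5L, 3L, 0L), 2, 2)
  expect_equal(overall_accuracy(off), 0)
  expect_error(overall_accuracy(matrix(0L, 2, 2)), "empty")
})

test_that("average recall per class matches the hand oracle", {
  expect_equal(average_recall_per_class(worked_cm()), (0.75 + 4 / 6) / 2,
               tolerance = 1e-9)
  expect_equal(average_recall_per_class(worked_cm()), 0.7083,
               tolerance = 1e-4)
  expect_equal(average_recall_per_class(diag(3L, 4)), 1)
  zs <- matrix(c(2L, 3L, 0L, 0L), 2, 2, byrow = TRUE)
  expect_error(average_recall_per_class(zs), "zero support")
  expect_warning(r <- average_recall_per_class(zs, zero_support = "mask"),
                 "masked")
  expect_equal(r, 2 / 5)
})

test_that("uniform random predictions give chance-level macro recall", {
  set.seed(10)
  k <- 5; n <- 50000
  true <- sample(k, n, TRUE, prob = c(0.4, 0.3, 0.15, 0.1, 0.05))
  pred <- sample(k, n, TRUE)
  cm <- confusion_matrix(emotion_levels()[true], emotion_levels()[pred],
                         emotion_levels()[1:k])
  expect_equal(average_recall_per_class(cm), 1 / k, tolerance = 0.02)
})

test_that("support-weighted recall equals overall accuracy on 1000 matrices", {
  set.seed(12)
  for (i in 1:1000) {
    k <- sample(2:7, 1)
    cm <- random_cm(k)
    while (sum(cm) == 0) cm <- random_cm(k)
    wm <- weighted_metrics(cm)
    expect_equal(wm$weighted_recall, overall_accuracy(cm),
                 tolerance = 1e-12)
  }
})

test_that("per-class metrics use the zero-denominator convention", {
  # one class never predicted: precision and F1 collapse to 0
  cm <- matrix(c(5L, 0L, 3L, 0L), 2, 2, byrow = TRUE,
               dimnames = list(c("Fear", "Anger"), c("Fear", "Anger")))
  pc <- weighted_metrics(cm)$per_class
  expect_equal(pc$precision[pc$class == "Anger"], 0)
  expect_equal(pc$f1[pc$class == "Anger"], 0)
  expect_equal(pc$recall[pc$class == "Anger"], 0)
  ident <- weighted_metrics(diag(4L, 3))
  expect_true(all(ident$per_class$recall == 1))
  expect_true(all(ident$per_class$precision == 1))
  expect_true(all(ident$per_class$f1 == 1))
  expect_equal(ident$weighted_accuracy, 1)
})

test_that("row normalization yields recall on the diagonal", {
  rn <- row_normalize(worked_cm())
  expect_equal(rn[1, ], c(Fear = 0.75, Anger = 0.25))
  expect_equal(rn[2, ], c(Fear = 1 / 3, Anger = 2 / 3), tolerance = 1e-9)
  expect_equal(unname(rowSums(rn)), c(1, 1))
  expect_equal(row_normalize(diag(2L, 3)), diag(1, 3),
               ignore_attr = TRUE)
  set.seed(13)
  for (i in 1:50) {
    cm <- random_cm(sample(2:7, 1))
    if (any(rowSums(cm) == 0)) next
    rn <- row_normalize(cm)
    expect_equal(unname(diag(rn)), unname(diag(cm) / rowSums(cm)))
    expect_true(all(abs(rowSums(rn) - 1) < 1e-9))
  }
  zr <- matrix(c(1L, 1L, 0L, 0L), 2, 2, byrow = TRUE)
  expect_warning(zn <- row_normalize(zr), "zero row")
  expect_equal(unname(zn[2, ]), c(0, 0))
})

test_that("quadrant aggregation conserves counts and splits errors", {
  cs <- emotion_levels()
  # all-correct: zero error rates are undefined (no errors) -> NaN
  perfect <- diag(5L, 7)
  dimnames(perfect) <- list(cs, cs)
  q <- quadrant_confusion(perfect)
  expect_true(is.nan(q$intra_quadrant_error_rate))
  expect_equal(sum(q$quadrant_matrix), sum(perfect))

  one_err <- function(from, to) {
    cm <- diag(2L, 7)
    dimnames(cm) <- list(cs, cs)
    cm[from, to] <- cm[from, to] + 1L
    cm
  }
  # Fear -> Anger: both negative-valence high-arousal (Q2): intra
  q1 <- quadrant_confusion(one_err("Fear", "Anger"))
  expect_equal(q1$intra_quadrant_error_rate, 1)
  expect_equal(q1$inter_quadrant_error_rate, 0)
  # Fear -> Sadness crosses Q2 -> Q3: inter
  q2 <- quadrant_confusion(one_err("Fear", "Sadness"))
  expect_equal(q2$intra_quadrant_error_rate, 0)
  expect_equal(q2$inter_quadrant_error_rate, 1)
  expect_equal(sum(q2$quadrant_matrix), sum(one_err("Fear", "Sadness")))
  # a label missing from the map is an error
  expect_error(quadrant_confusion(perfect, qmap = quadrant_map()[-3]),
               "missing")
})

test_that("eval reports collect consistent metrics", {
  set.seed(14)
  true <- sample(emotion_levels(), 300, TRUE)
  pred <- ifelse(runif(300) < 0.6, true, sample(emotion_levels(), 300, TRUE))
  cm <- confusion_matrix(true, pred, emotion_levels())
  expect_equal(sum(cm), 300L)
  rep_ <- eval_report(cm)
  expect_equal(rep_$overall_accuracy, sum(diag(cm)) / 300)
  expect_equal(rep_$weighted_recall, rep_$overall_accuracy)
  expect_true(all(rep_$per_class$recall >= 0 & rep_$per_class$recall <= 1))
  expect_equal(sum(rep_$quadrant$quadrant_matrix), 300L)
})
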