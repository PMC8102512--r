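test_that("confusion tallies exactly and validates input", {
  true <- c(0, 0, 1, 2, 3, 4, 4, 2, 1, 0)
  pred <- c(0, 1, 1, 2, 3, 4, 3, 2, 0, 0)
  cm <- confusion(true, pred)
  expect_identical(sum(cm), 10L)
  # manual tally
  expect_identical(cm["0", "0"], 2L)
  expect_identical(cm["0", "1"], 1L)
  expect_identical(cm["1", "0"], 1L)
  expect_identical(cm["1", "1"], 1L)
  expect_identical(cm["4", "3"], 1L)
  expect_identical(cm["4", "4"], 1L)
  perfect <- confusion(0:4, 0:4)
  expect_identical(unname(diag(perfect)), rep(1L, 5))
  expect_identical(sum(perfect) - sum(diag(perfect)), 0L)
  expect_error(confusion(integer(0), integer(0)), "true_grades")
  expect_error(confusion(c(0, 5), c(0, 1)), "grades")
})

test_that("perfect predictions score 1 on accuracy, kappa and Matthews", {
  cm <- confusion(rep(0:4, 10), rep(0:4, 10))
  rep_ <- overall_metrics(cm)
  expect_equal(rep_$accuracy, 1)
  expect_equal(rep_$kappa, 1)
  expect_equal(rep_$matthews, 1)
  expect_equal(rep_$se, 1)
  expect_equal(rep_$sp, 1)
})

test_that("single-class predictions on balanced truth give kappa 0", {
  cm <- confusion(rep(0:4, each = 20), rep(0L, 100))
  rep_ <- suppressWarnings(overall_metrics(cm))
  expect_equal(rep_$accuracy, 0.2)
  expect_equal(rep_$kappa, 0)
  expect_true(is.na(rep_$matthews))   # zero predicted-marginal variance
})

test_that("per-grade SE/SP match brute-force one-vs-rest enumeration", {
  cm <- matrix(c(30, 3, 1, 0, 0,
                 4, 20, 5, 1, 0,
                 2, 6, 25, 4, 1,
                 0, 1, 3, 15, 2,
                 0, 0, 1, 2, 10), 5, 5, byrow = TRUE,
               dimnames = list(true = 0:4, predicted = 0:4))
  got <- per_grade_se_sp(cm)
  n <- sum(cm)
  for (g in 0:4) {
    i <- g + 1
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- n - tp - fn - fp
    expect_equal(got$se[i], tp / (tp + fn))
    expect_equal(got$sp[i], tn / (tn + fp))
  }
  # macro means over the same enumeration
  rep_ <- overall_metrics(cm)
  expect_equal(rep_$se, mean(got$se))
  expect_equal(rep_$sp, mean(got$sp))
})

test_that("a grade never predicted and never true is NA, not zero", {
  cm <- confusion(c(0, 0, 1, 1), c(0, 0, 1, 1))
  got <- per_grade_se_sp(cm)
  expect_true(is.na(got$se[got$grade == 3]))
  expect_false(is.na(got$sp[got$grade == 3]))   # TN exist
  expect_warning(overall_metrics(cm), "undefined")
})

test_that("kappa and Matthews agree with independent references", {
  skip_if_not_installed("e1071")
  withr::with_seed(12, {
    for (rep in 1:10) {
      true <- sample(0:4, 200, replace = TRUE)
      pred <- ifelse(runif(200) < 0.6, true, sample(0:4, 200,
                                                    replace = TRUE))
      cm <- confusion(true, pred)
      expect_equal(cohens_kappa(cm),
                   e1071::classAgreement(cm)$kappa, tolerance = 1e-12)
    }
  })
  # binary case: multiclass MCC reduces to the classical formula
  cm2 <- matrix(0L, 5, 5)
  cm2[1, 1] <- 40; cm2[1, 2] <- 10; cm2[2, 1] <- 5; cm2[2, 2] <- 45
  tp <- 45; tn <- 40; fp <- 10; fn <- 5
  classic <- (tp * tn - fp * fn) /
    sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  expect_equal(matthews_mcc(cm2), classic, tolerance = 1e-12)
})

test_that("macro AUC of random scores on balanced labels is near 0.5", {
  withr::with_seed(2024, {
    n <- 2000
    true <- sample(0:4, n, replace = TRUE)
    scores <- matrix(runif(n * 5), n, 5)
    scores <- scores / rowSums(scores)
    auc <- mean(per_grade_auc(true, scores))
    expect_lt(abs(auc - 0.5), 0.05)
  })
})

test_that("perfectly separating scores give AUC 1", {
  true <- rep(0:4, each = 10)
  scores <- matrix(0.01, 50, 5)
  scores[cbind(1:50, true + 1)] <- 0.96
  expect_equal(unname(per_grade_auc(true, scores)), rep(1, 5))
  rep_ <- overall_metrics(confusion(true, max.col(scores) - 1L),
                          scores = scores, true_grades = true)
  expect_equal(rep_$auc, 1)
})

test_that("SE equals accuracy of the positive-restricted binary problem", {
  withr::with_seed(9, {
    true <- sample(0:4, 300, replace = TRUE)
    pred <- sample(0:4, 300, replace = TRUE)
    cm <- confusion(true, pred)
    got <- per_grade_se_sp(cm)
    for (g in 0:4) {
      pos <- true == g
      expect_equal(got$se[g + 1], mean(pred[pos] == g))
    }
  })
})
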