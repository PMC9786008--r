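test_that("the worked 2-sample 2-label example reproduces the derived values", {
  truth <- rbind(c(1, 0), c(0, 1))
  pred <- rbind(c(1, 0), c(1, 1))
  # sample 1 scores 2/2, sample 2 scores 1/2 -> 0.75
  expect_equal(ml_accuracy(truth, pred), 0.75)
  # label 1: TP 1 / (TP 1 + FP 1) = 1/2; label 2: 1/1 -> macro 0.75
  expect_equal(as.numeric(macro_precision(truth, pred)), 0.75)
  # both labels recall 1/1 -> 1.0
  expect_equal(as.numeric(macro_recall(truth, pred)), 1.0)
})

test_that("accuracy hits its extremes and is complement-symmetric", {
  set.seed(1)
  truth <- matrix(rbinom(40, 1, 0.4), 10, 4)
  expect_equal(ml_accuracy(truth, truth), 1.0)
  expect_equal(ml_accuracy(truth, 1 - truth), 0.0)
  pred <- matrix(rbinom(40, 1, 0.5), 10, 4)
  expect_equal(ml_accuracy(truth, pred), ml_accuracy(1 - truth, 1 - pred))
  expect_error(ml_accuracy(truth, pred[1:5, ]), class = "moladr_config_error")
})

test_that("macro precision/recall pool counts per label and report undefined labels", {
  truth <- rbind(c(1, 0, 0), c(1, 0, 1), c(0, 0, 1))
  pred <- rbind(c(1, 0, 0), c(0, 0, 1), c(1, 0, 1))
  # label 2 never predicted positive -> precision undefined there
  pr <- macro_precision(truth, pred)
  expect_equal(attr(pr, "excluded"), 2L)
  expect_equal(as.numeric(pr), mean(c(1 / 2, 1)))
  # label 2 has no true positives -> recall undefined there
  rc <- macro_recall(truth, pred)
  expect_equal(attr(rc, "excluded"), 2L)
  expect_equal(as.numeric(rc), mean(c(1 / 2, 1)))
})

test_that("perfect rankings give AUC 1 and constant scores give AUC 0.5", {
  truth <- cbind(c(1, 1, 0, 0), c(0, 1, 0, 1))
  scores <- cbind(c(0.9, 0.8, 0.2, 0.1), c(0.1, 0.9, 0.2, 0.8))
  expect_equal(as.numeric(macro_auc(truth, scores)), 1.0)
  const <- matrix(0.7, 4, 2)
  expect_equal(as.numeric(macro_auc(truth, const)), 0.5)
})

test_that("macro AUC equals the concordant-pair oracle on random matrices", {
  set.seed(42)
  for (rep in 1:8) {
    n <- sample(4:12, 1); L <- sample(2:4, 1)
    truth <- matrix(rbinom(n * L, 1, 0.5), n, L)
    scores <- matrix(round(runif(n * L), 2), n, L)   # rounding makes ties
    per <- vapply(seq_len(L),
                  function(j) auc_pair_oracle(truth[, j], scores[, j]),
                  numeric(1))
    got <- macro_auc(truth, scores)
    expect_equal(as.numeric(attr(got, "per_label")), per, tolerance = 1e-9)
    expect_equal(as.numeric(got), mean(per, na.rm = TRUE), tolerance = 1e-9)
    # single-class labels are excluded, not averaged as zeros
    expect_equal(attr(got, "excluded"), which(is.na(per)))
  }
})

test_that("macro AUC is invariant under strictly increasing score transforms", {
  set.seed(7)
  truth <- matrix(rbinom(30, 1, 0.5), 10, 3)
  scores <- matrix(runif(30), 10, 3)
  expect_equal(as.numeric(macro_auc(truth, scores)),
               as.numeric(macro_auc(truth, exp(3 * scores))), tolerance = 1e-12)
})

test_that("macro AUC agrees with an established ROC implementation", {
  set.seed(11)
  y <- rbinom(25, 1, 0.4); s <- runif(25)
  ours <- attr(macro_auc(cbind(y), cbind(s)), "per_label")
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(
    y, s, quiet = TRUE, direction = "<", levels = c(0, 1)))))
  expect_equal(as.numeric(ours), ref, tolerance = 1e-12)
})

test_that("macro AUPR equals the threshold-sweep average-precision oracle", {
  set.seed(13)
  for (rep in 1:6) {
    n <- sample(5:12, 1); L <- sample(2:4, 1)
    truth <- matrix(rbinom(n * L, 1, 0.5), n, L)
    scores <- matrix(round(runif(n * L), 1), n, L)
    per <- vapply(seq_len(L),
                  function(j) aupr_sweep_oracle(truth[, j], scores[, j]),
                  numeric(1))
    got <- macro_aupr(truth, scores)
    expect_equal(as.numeric(attr(got, "per_label")), per, tolerance = 1e-9)
  }
})

test_that("evaluate_predictions binarizes for counts, ranks for areas, and reports exclusions", {
  truth <- rbind(c(1, 0), c(0, 1), c(1, 0))
  perfect <- rbind(c(0.9, 0.1), c(0.1, 0.9), c(0.8, 0.2))
  rep1 <- evaluate_predictions(truth, perfect)
  expect_equal(rep1$accuracy, 1)
  expect_equal(rep1$precision, 1)
  expect_equal(rep1$recall, 1)
  expect_equal(rep1$auc, 1)
  expect_equal(rep1$aupr, 1)
  expect_true(all(c("accuracy", "precision", "recall", "auc", "aupr")
                  %in% names(rep1)))

  # a fold that lacks positives for label 2 reports the exclusion
  truth2 <- rbind(c(1, 0), c(0, 0), c(1, 0))
  rep2 <- evaluate_predictions(truth2, perfect)
  expect_true(2L %in% rep2$excluded$auc)
  expect_equal(nrow(rep2$per_label), 2)

  # the worked 2x2 example passes through the report path
  rep3 <- evaluate_predictions(rbind(c(1, 0), c(0, 1)),
                               rbind(c(0.9, 0.1), c(0.6, 0.7)))
  expect_equal(rep3$accuracy, 0.75)
  expect_equal(rep3$precision, 0.75)
  expect_equal(rep3$recall, 1.0)

  # report writer produces the CSV + JSON pair
  stem <- file.path(withr::local_tempdir(), "metrics")
  write_metrics_report(rep1, stem)
  expect_true(file.exists(paste0(stem, ".csv")))
  js <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(js$accuracy, 1)
})

test_that("all macro metrics are means of the reported per-label breakdown", {
  set.seed(17)
  truth <- matrix(rbinom(48, 1, 0.5), 12, 4)
  scores <- matrix(runif(48), 12, 4)
  rep <- evaluate_predictions(truth, scores, threshold = 0.4)
  expect_equal(rep$auc, mean(rep$per_label$auc, na.rm = TRUE))
  expect_equal(rep$aupr, mean(rep$per_label$aupr, na.rm = TRUE))
  expect_equal(rep$precision, mean(rep$per_label$precision, na.rm = TRUE))
  expect_equal(rep$recall, mean(rep$per_label$recall, na.rm = TRUE))
  for (v in c(rep$accuracy, rep$precision, rep$recall, rep$auc, rep$aupr)) {
    expect_gte(v, 0); expect_lte(v, 1)
  }
})
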