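test_that("metrics follow the confusion-count definitions exactly", {
  m <- compute_metrics(confusion_counts(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$sensitivity, 0.6)
  expect_equal(m$specificity, 0.8)
  perfect <- compute_metrics(confusion_counts(tp = 5, fp = 0, tn = 5,
                                              fn = 0))
  expect_equal(unlist(perfect[1, 1:3]), c(accuracy = 1, sensitivity = 1,
                                          specificity = 1))
  degen <- compute_metrics(confusion_counts(tp = 0, fp = 2, tn = 3,
                                            fn = 0))
  expect_true(is.na(degen$sensitivity))
  expect_match(degen$undefined, "sensitivity")
  expect_error(compute_metrics(confusion_counts(tp = 0, fp = 0, tn = 0,
                                                fn = 0)))
})

test_that("confusion counts tally logical prediction/truth vectors", {
  cc <- confusion_counts(c(TRUE, TRUE, FALSE, FALSE, TRUE),
                         c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(unlist(cc[c("tp", "fp", "tn", "fn")]),
               c(tp = 2L, fp = 1L, tn = 1L, fn = 1L))
})

test_that("roc_auc equals the Mann-Whitney oracle, with tie handling", {
  set.seed(25)
  for (i in 1:5) {
    scores <- round(runif(10), 1)     # rounding induces ties
    truth <- runif(10) > 0.5
    if (!any(truth) || all(truth)) next
    u <- 0
    for (a in scores[truth]) for (b in scores[!truth])
      u <- u + (a > b) + 0.5 * (a == b)
    expect_equal(roc_auc(scores, truth), u / (sum(truth) * sum(!truth)))
  }
  expect_equal(roc_auc(c(.1, .2, .8, .9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(rep(0.5, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(roc_auc(runif(4), rep(TRUE, 4)))
})

test_that("roc_auc agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(26)
  scores <- runif(40)
  truth <- runif(40) > 0.4
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(scores, truth), ref, tolerance = 1e-12)
})

test_that("image decisions use the inclusive fraction threshold", {
  preds <- tibble::tibble(decision = c("cancerous", rep("normal", 9)))
  r <- classify_image(preds, threshold = 0.10, image_id = "I1")
  expect_equal(r$fraction, 0.10)
  expect_equal(r$decision, "cancerous")   # inclusive comparison
  expect_equal(r$n_cancer, 1L)
  r0 <- classify_image(rep(FALSE, 25), threshold = 0.01)
  expect_equal(r0$decision, "normal")
  rempty <- classify_image(logical(0), threshold = 0.1)
  expect_equal(rempty$decision, "indeterminate")
  expect_true(is.na(rempty$fraction))
})

test_that("raising the threshold never converts normal to cancerous", {
  set.seed(27)
  calls <- runif(30) > 0.7
  last <- "cancerous"
  for (th in c(0.01, 0.05, 0.1, 0.2, 0.3, 0.6)) {
    d <- classify_image(calls, th)$decision
    expect_true(!(last == "normal" && d == "cancerous"))
    last <- d
  }
})

test_that("threshold selection matches brute force and breaks ties low", {
  # hand-built 20-image validation table
  set.seed(28)
  val <- tibble::tibble(
    fraction = c(runif(10, 0, 0.08), runif(10, 0.15, 0.9)),
    truth = rep(c("normal", "cancerous"), each = 10))
  cands <- c(.01, .05, .10, .20, .30)
  got <- select_image_threshold(val, cands)
  oracle <- vapply(cands, function(th)
    sum((val$fraction >= th) == (val$truth == "cancerous")), integer(1))
  expect_equal(sum((val$fraction >= got) == (val$truth == "cancerous")),
               max(oracle))
  # tie between two candidates resolves to the smaller
  tie <- tibble::tibble(fraction = c(0.02, 0.5), truth = c("normal",
                                                           "cancerous"))
  expect_equal(as.numeric(select_image_threshold(tie, c(.10, .20))), 0.10)
  # perfect separation picks the smallest candidate
  sep <- tibble::tibble(fraction = c(0.001, 0.005, 0.5, 0.8),
                        truth = c("normal", "normal", "cancerous",
                                  "cancerous"))
  expect_equal(as.numeric(select_image_threshold(sep, cands)), 0.01)
})

test_that("5% nucleus error propagates to reliable image calls", {
  # binomial check: with eps = 0.05 per-nucleus error, images with
  # >= 20 nuclei at threshold 10% classify correctly nearly always
  # per-image nucleus counts span the 20-200 range seen on real slides
  set.seed(29)
  n_img <- 400
  ok <- logical(n_img)
  for (i in seq_len(n_img)) {
    truth_cancer <- i %% 2 == 0
    n <- sample(20:200, 1)
    true_calls <- if (truth_cancer) rep(TRUE, n) else rep(FALSE, n)
    observed <- xor(true_calls, runif(n) < 0.05)
    d <- classify_image(observed, 0.10)$decision
    ok[i] <- d == (if (truth_cancer) "cancerous" else "normal")
  }
  expect_gte(mean(ok), 0.95)
})
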