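test_that("layer shapes reproduce the declared chain for both inputs", {
  for (ch in c(3L, 87L)) {
    sh <- cnn_shapes(cnn_config(ch))
    expect_equal(sh$out_h,
                 c(101, 97, 95, 47, 45, 43, 41, 21, 19, 17, 15, 13, 1, 1, 1))
    expect_equal(sh$out_c,
                 c(ch, 256, 256, 256, 384, 512, 768, 768, 768, 1024, 1536,
                   2048, 2048, 2048, 1))
  }
  expect_error(cnn_config(5L))
  expect_s3_class(cnn_config(5L, allow_any_channels = TRUE), "cnn_config")
})

test_that("width multiplier scales filters without touching the chain", {
  sh <- cnn_shapes(cnn_config(87L, width_multiplier = 1 / 32))
  expect_equal(sh$out_h[1:12],
               c(101, 97, 95, 47, 45, 43, 41, 21, 19, 17, 15, 13))
  expect_equal(sh$out_c[2], 8)
})

test_that("a zero patch forwards to a finite sigmoid probability", {
  cfg <- cnn_config(3L, width_multiplier = 1 / 64, input_size = 53L,
                    seed = 2L)
  m <- build_model(cfg)
  p <- predict_cnn(m, tibble::tibble(hsi_patch =
                                       list(array(0, c(53, 53, 3)))))
  expect_true(is.finite(p$probability) && p$probability > 0 &&
                p$probability < 1)
})

test_that("training augmentation quadruples records as exact rotations", {
  set.seed(18)
  recs <- toy_patch_records(3, "A", size = 9L)
  aug <- augment_train(recs)
  expect_equal(nrow(aug), 12L)
  expect_equal(aug$label, rep(recs$label, 4))
  base <- recs$hsi_patch[[1]]
  views <- aug$hsi_patch[aug$nucleus_id == recs$nucleus_id[1]]
  # pixel multisets identical per rotated view
  for (v in views) expect_equal(sort(as.vector(v)), sort(as.vector(base)))
  # 180-degree rotation is its own inverse
  expect_equal(views[[3]][9:1, 9:1, ], base[, , ])
  # rotationally symmetric patch -> identical copies
  sym <- tibble::tibble(nucleus_id = "s", patient_id = "A",
                        label = "normal",
                        hsi_patch = list(array(1, c(5, 5, 2))))
  av <- augment_train(sym)
  for (v in av$hsi_patch) expect_equal(v, av$hsi_patch[[1]])
  bad <- tibble::tibble(hsi_patch = list(array(0, c(4, 5, 2))),
                        label = "normal")
  expect_error(augment_train(bad))
})

test_that("evaluation views are the declared deterministic quartet", {
  set.seed(19)
  x <- array(runif(7 * 7 * 2), c(7, 7, 2))
  v <- augment_eval(x)
  expect_length(v, 4L)
  expect_equal(v$identity, x)
  expect_equal(v$flip_h, x[, 7:1, , drop = FALSE])
  expect_equal(v$flip_v, x[7:1, , , drop = FALSE])
  # symmetric patch -> all views identical -> mean equals single view
  s <- array(0.3, c(5, 5, 1))
  vs <- augment_eval(s)
  for (w in vs) expect_equal(w, s)
})

test_that("prediction averages exactly the four view probabilities", {
  cfg <- cnn_config(3L, width_multiplier = 1 / 64, input_size = 53L,
                    seed = 3L)
  m <- build_model(cfg)
  set.seed(20)
  x <- array(runif(53 * 53 * 3), c(53, 53, 3))
  pv <- vapply(augment_eval(x), function(v)
    hsinuc:::cnn_forward(m, v, train = FALSE), numeric(1))
  got <- predict_cnn(m, tibble::tibble(hsi_patch = list(x)))
  expect_equal(got$probability, mean(pv), tolerance = 1e-12)
})

test_that("zero learning rate freezes the loss; same seed reruns match", {
  tr <- toy_patch_records(8, "A", seed = 21)
  va <- toy_patch_records(4, "B", seed = 22)
  cfg0 <- cnn_config(3L, width_multiplier = 1 / 64, input_size = 53L,
                     dropout_range = c(0, 0),   # dropout is a stochastic loss
                     lr = 0, max_epochs = 2L, seed = 4L)
  m0 <- train(build_model(cfg0), tr, va)
  h <- tidy(m0)
  expect_equal(h$train_loss[1], h$train_loss[2], tolerance = 1e-9)
  cfg1 <- cnn_config(3L, width_multiplier = 1 / 64, input_size = 53L,
                     lr = 1e-3, max_epochs = 2L, seed = 4L)
  ma <- train(build_model(cfg1), tr, va)
  mb <- train(build_model(cfg1), tr, va)
  expect_identical(tidy(ma), tidy(mb))
  expect_identical(ma$params$dense2$W, mb$params$dense2$W)
})

test_that("patient overlap between partitions is a hard error", {
  tr <- toy_patch_records(4, "A")
  expect_error(train(build_model(cnn_config(3L, 1 / 64, input_size = 53L)),
                     tr, tr), regexp = "leakage")
})

test_that("the network learns a separable patch problem", {
  tr <- toy_patch_records(24, "A", mu = 0.25, seed = 23)
  va <- toy_patch_records(8, "B", mu = 0.25, seed = 24)
  cfg <- cnn_config(3L, width_multiplier = 1 / 64, input_size = 53L,
                    lr = 3e-3, max_epochs = 10L, patience = 6L, seed = 5L)
  m <- train(build_model(cfg), tr, va)
  expect_gte(max(tidy(m)$val_accuracy), 0.9)
  expect_s3_class(autoplot(m), "ggplot")
  expect_equal(glance(m)$best_epoch, m$best_epoch)
})

test_that("ROC threshold selection matches an exhaustive sweep oracle", {
  scores <- c(0.05, 0.2, 0.35, 0.4, 0.7, 0.9)
  truth <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  got <- select_threshold(scores, truth)
  # oracle: try every midpoint cut, maximize Youden J
  cuts <- seq(0, 1, by = 0.001)
  j <- vapply(cuts, function(ct)
    mean(scores[truth] >= ct) + mean(scores[!truth] < ct) - 1, numeric(1))
  expect_equal(max(vapply(got, function(ct)
    mean(scores[truth] >= ct) + mean(scores[!truth] < ct) - 1, numeric(1))),
    max(j))
  # separable scores return the midpoint of the gap
  expect_equal(select_threshold(c(0.1, 0.2, 0.8, 0.9),
                                c(FALSE, FALSE, TRUE, TRUE)), 0.5)
  # uninformative scores fall back to 0.5 with a warning
  expect_warning(
    thr <- select_threshold(rep(0.4, 6), rep(c(TRUE, FALSE), 3)))
  expect_equal(thr, 0.5)
  expect_error(select_threshold(runif(5), rep(TRUE, 5)))
})
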