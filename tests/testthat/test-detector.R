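# Detector construction, training schedule, matching and metrics.

test_anchors <- function() anchor_set(rbind(c(6, 6), c(10, 12), c(18, 16)))

test_that("input layer has kernel^2 * m * filters + filters parameters", {
  for (m in c(3, 8)) {
    model <- build_model(input_layer_spec(m), test_anchors(), seed = 1)
    expect_equal(layer_param_counts(model)[1], 6L * 6L * m * 32L + 32L)
  }
  expect_error(input_layer_spec(2), "m >= 3")
  expect_error(input_layer_spec(9), "m <= 8")
})

test_that("channel count is enforced and downstream shapes ignore m", {
  an <- test_anchors()
  m3 <- build_model(input_layer_spec(3), an, seed = 1)
  m8 <- build_model(input_layer_spec(8), an, seed = 1)
  x3 <- array(runif(48 * 64 * 3), dim = c(48, 64, 3))
  x8 <- array(runif(48 * 64 * 8), dim = c(48, 64, 8))
  expect_silent(predict_boxes(m3, x3))
  expect_error(predict_boxes(m8, x3), "8 input channels")
  expect_error(train(m3, list(list(x = x8, boxes = NULL)), train_config()),
               "3 input channels")
  # all layers after the input layer have identical shapes for any m
  expect_equal(layer_output_shapes(m3, 48, 64)[-1],
               layer_output_shapes(m8, 48, 64)[-1])
  # and the input layer output shape is m-independent too
  expect_equal(layer_output_shapes(m3, 48, 64)[[1]],
               layer_output_shapes(m8, 48, 64)[[1]])
})

test_that("SGD schedule follows the warm-up and linear decay settings", {
  cfg <- train_config()
  expect_equal(cfg$batch, 4L)
  s1 <- sgd_schedule(cfg, 1, 0)
  expect_equal(s1$momentum, 0.8)         # warm-up momentum at the start
  expect_equal(s1$lr, 0.01)              # nominal initial learning rate
  expect_equal(s1$lr_bias, 0.1)          # bias learning rate during warm-up
  expect_equal(s1$lr_weight, 0)
  s_after <- sgd_schedule(cfg, cfg$warmup_epochs + 1, 0)
  expect_equal(s_after$momentum, 0.937)  # full momentum after warm-up
  s_end <- sgd_schedule(cfg, cfg$max_epochs, 0)
  expect_equal(s_end$lr, 0.01 * 0.01, tolerance = 1e-12)  # decayed to 1%
  # nominal rate decays linearly
  mids <- vapply(1:20, function(e) sgd_schedule(cfg, e)$lr, numeric(1))
  expect_equal(diff(mids), rep(diff(mids)[1], 19))
})

test_that("a short training run reduces the loss on synthetic scenes", {
  K <- default_intrinsics(8)
  cfg <- pipeline_config(denoise = FALSE)
  ds <- make_dataset(20, tiny_scene_params(), K, seed = 3)
  samples <- lapply(seq_along(ds$scenes), function(i) {
    st <- run_preprocess(ds$scenes[[i]], cfg, "RGB+XYZ+D+F")
    list(x = fruitfusion:::training_view(st), boxes = ds$scenes[[i]]$labels)
  })
  boxes <- do.call(rbind, lapply(ds$scenes, `[[`, "labels"))
  model <- build_model(input_layer_spec(8), check_anchors(boxes), seed = 0)
  trained <- train(model, samples, train_config(seed = 0), epochs = 5)
  hist <- attr(trained, "loss_history")
  expect_length(hist, 5)
  expect_lt(tail(hist, 1), hist[1])
  expect_error(train(model, list(), train_config()), "non-empty")
})

test_that("seeded training is reproducible", {
  K <- default_intrinsics(8)
  cfg <- pipeline_config(denoise = FALSE)
  ds <- make_dataset(6, tiny_scene_params(), K, seed = 5)
  samples <- lapply(seq_along(ds$scenes), function(i) {
    st <- run_preprocess(ds$scenes[[i]], cfg, "RGB")
    list(x = st, boxes = ds$scenes[[i]]$labels)
  })
  an <- test_anchors()
  m1 <- train(build_model(input_layer_spec(3), an, seed = 2), samples,
              train_config(seed = 9), epochs = 2)
  m2 <- train(build_model(input_layer_spec(3), an, seed = 2), samples,
              train_config(seed = 9), epochs = 2)
  expect_identical(attr(m1, "loss_history"), attr(m2, "loss_history"))
  expect_identical(m1$layers[[1]]$W, m2$layers[[1]]$W)
})

test_that("detection matching is greedy, one-to-one and count-conserving", {
  truths <- data.frame(xmin = c(0, 20), ymin = c(0, 20),
                       xmax = c(10, 30), ymax = c(10, 30))
  preds <- cbind(truths, confidence = c(0.9, 0.8))
  m <- match_detections(preds, truths)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))

  none <- match_detections(preds[0, ], truths)
  expect_equal(c(none$tp, none$fp, none$fn), c(0L, 0L, 2L))

  # two predictions on one truth: one TP, one FP
  dup <- data.frame(xmin = c(0, 1), ymin = c(0, 0), xmax = c(10, 10),
                    ymax = c(10, 10), confidence = c(0.9, 0.95))
  m2 <- match_detections(dup, truths[1, ])
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 0L))
  # the higher-confidence prediction claims the truth
  expect_equal(m2$matched_pred, c(FALSE, TRUE))

  # count conservation on random inputs
  set.seed(11)
  for (i in 1:5) {
    np <- sample(0:8, 1); nt <- sample(0:8, 1)
    p <- data.frame(xmin = runif(np, 0, 50), ymin = runif(np, 0, 50))
    p$xmax <- p$xmin + runif(np, 2, 20); p$ymax <- p$ymin + runif(np, 2, 20)
    p$confidence <- runif(np)
    t <- data.frame(xmin = runif(nt, 0, 50), ymin = runif(nt, 0, 50))
    t$xmax <- t$xmin + runif(nt, 2, 20); t$ymax <- t$ymin + runif(nt, 2, 20)
    mm <- match_detections(p, t, 0.5)
    expect_equal(mm$tp + mm$fp, np)
    expect_equal(mm$tp + mm$fn, nt)
  }
})

test_that("precision/recall/F1 reproduce printed worked examples", {
  expect_equal(f1_score(79.7, 99), 88.31, tolerance = 1e-4)
  expect_equal(f1_score(95.8, 96.0), 95.9, tolerance = 1e-3)
  expect_equal(f1_score(50, 50), 50)
  expect_equal(precision_pct(8, 2), 80)
  expect_equal(recall_pct(8, 8), 50)
  expect_warning(p0 <- precision_pct(0, 0), "0")
  expect_equal(p0, 0)

  # F1 lies between min and max of P and R, and is symmetric
  set.seed(12)
  for (i in 1:20) {
    p <- runif(1, 1, 100); r <- runif(1, 1, 100)
    f <- f1_score(p, r)
    expect_gte(f, min(p, r)); expect_lte(f, max(p, r))
    expect_equal(f, f1_score(r, p))
  }
})

test_that("evaluation aggregates per-image counts and handles oracles", {
  K <- default_intrinsics(8)
  ds <- make_dataset(6, tiny_scene_params(), K, seed = 6)
  samples <- lapply(ds$scenes, function(sc) list(x = NULL, boxes = sc$labels))
  ev <- evaluate("oracle", samples)
  expect_equal(ev$P, 100); expect_equal(ev$R, 100); expect_equal(ev$F1, 100)

  # recount from the per-image table
  expect_equal(ev$tp, sum(ev$per_image$tp))
  expect_equal(suppressWarnings(precision_pct(ev$tp, ev$fp)), ev$P)

  # a detector that emits nothing has zero recall
  an <- test_anchors()
  mute <- build_model(input_layer_spec(3), an, seed = 1)
  mute$layers[[5]]$b[5 * (1:3 - 1) + 1] <- -50
  samples3 <- lapply(ds$scenes, function(sc) {
    list(x = sc$rgb / 255, boxes = sc$labels)
  })
  ev0 <- suppressWarnings(evaluate(mute, samples3))
  expect_equal(ev0$R, 0)
  expect_error(evaluate("oracle", list()), "empty")
})
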