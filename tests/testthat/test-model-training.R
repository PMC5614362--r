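test_that("descriptor matrix has the documented layout and values", {
  ph <- make_multiregion(size = 16, seed = 1)
  ws <- new_workspace(ph$volume)
  compute_channel(ws, "g", "gaussian", params = list(sigma = 1))
  svp <- compute_supervoxels(ws, shape = c(8, 8, 8), compactness = 20)
  X <- build_descriptors(ws, c("raw", "g"))
  expect_equal(ncol(X), 2 * 5)
  expect_equal(nrow(X), svp$n_regions)
  expect_true(all(is.finite(X)))
  # means match the per-region oracle
  expect_equal(unname(X[, "raw_mean"]),
               unname(region_means(svp$labels, roi_data(ws))))
  # constant channel: mean column constant, sd column zero
  compute_channel(ws, "c", "threshold", params = list(vmin = -Inf))
  Xc <- build_descriptors(ws, "c")
  expect_true(all(Xc[, "c_mean"] == 1))
  expect_true(all(Xc[, "c_sd"] == 0))
  expect_error(build_descriptors(ws, character(0)), "non-empty")
})

test_that("classifier separates a well-separated two-phase phantom", {
  tp <- two_phase_workspace()
  cfg <- train_config(tp$level, sources = "tv", seed = 3)
  pred <- train_predict(tp$ws, cfg)
  expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-9))
  expect_gte(min(pred$prob), 0)
  # training regions keep their user label
  ytr <- srvox:::region_training_labels(
    tp$ws$levels[[as.character(tp$level)]]$voxel_labels,
    supervoxel_labels(tp$ws))
  tr <- which(pred$train_mask)
  expect_equal(pred$labels_hat[tr], ytr[tr])
  # >= 99% of unlabeled supervoxels predicted to the correct phase
  svl <- supervoxel_labels(tp$ws)
  truth_sv <- srvox:::region_training_labels(
    ifelse(tp$ph$truth == 1, tp$labels[1], tp$labels[2]), svl)
  unl <- which(!pred$train_mask)
  expect_gte(mean(pred$labels_hat[unl] == truth_sv[unl]), 0.99)
})

test_that("all three classifier families run behind the same interface", {
  tp <- two_phase_workspace()
  for (clf in c("ensemble_rf", "svm", "online_linear")) {
    cfg <- train_config(tp$level, sources = "tv", classifier = clf,
                        seed = 4)
    # glmnet warns about the (deliberately) tiny scribble training set
    pred <- suppressWarnings(train_predict(tp$ws, cfg))
    expect_true(all(abs(rowSums(pred$prob) - 1) < 1e-6), info = clf)
    ytr <- pred$train_labels
    tr <- which(pred$train_mask)
    expect_equal(pred$labels_hat[tr], ytr[tr], info = clf)
  }
})

test_that("single-class training sets are rejected", {
  ph <- make_multiregion(size = 16, seed = 2)
  ws <- new_workspace(ph$volume)
  compute_supervoxels(ws, shape = c(8, 8, 8))
  lvl <- add_level(ws)
  a <- add_label(ws, lvl, "only")
  annotate(ws, lvl, a, matrix(c(2, 2, 2), 1), mode = "supervoxel")
  cfg <- train_config(lvl, sources = "raw")
  expect_error(train_predict(ws, cfg), "2 annotated classes")
})

test_that("refinement at zero coupling reproduces the argmax labels", {
  tp <- two_phase_workspace()
  cfg <- train_config(tp$level, sources = "tv", seed = 5)
  pred <- train_predict(tp$ws, cfg)
  ref0 <- refine_predictions(tp$ws, pred, "potts", 0, "tv")
  cls <- pred$classes[max.col(pred$prob, ties.method = "first")]
  expect_equal(ref0$labels_hat, cls)
})

test_that("ICM absorbs an isolated low-confidence hole and lowers energy", {
  tp <- two_phase_workspace()
  cfg <- train_config(tp$level, sources = "tv", seed = 6)
  pred <- train_predict(tp$ws, cfg)
  # corrupt one interior non-training region towards the wrong class
  svl <- supervoxel_labels(tp$ws)
  interior <- svl[8, 8, 8]
  if (pred$train_mask[interior])
    interior <- setdiff(unique(as.integer(svl[6:10, 6:10, 6:10])),
                        which(pred$train_mask))[1]
  right <- match(pred$labels_hat[interior], pred$classes)
  wrong <- if (right == 1) 2 else 1
  pred$prob[interior, ] <- 0.1
  pred$prob[interior, wrong] <- 0.9
  pred$prob[interior, ] <- pred$prob[interior, ] /
    sum(pred$prob[interior, ])
  pred$labels_hat[interior] <- pred$classes[wrong]
  ref <- refine_predictions(tp$ws, pred, "potts", 50, "tv")
  expect_equal(ref$labels_hat[interior], pred$classes[right])
  expect_true(all(diff(ref$energy_trace) <= 1e-9))
  # appearance kernel runs and also keeps energies non-increasing
  ref2 <- refine_predictions(tp$ws, pred, "appearance", 50, "tv")
  expect_true(all(diff(ref2$energy_trace) <= 1e-9))
})

test_that("confidence endpoints and monotonicity hold at commitment", {
  tp <- two_phase_workspace()
  cfg <- train_config(tp$level, sources = "tv", seed = 7)
  pred <- train_predict(tp$ws, cfg)
  counts <- vapply(c(0, 25, 50, 75, 100), function(cf) {
    ws2 <- new_workspace(tp$ws$volume)
    ws2$channels <- tp$ws$channels
    ws2$supervoxels <- tp$ws$supervoxels
    ws2$levels <- tp$ws$levels
    ws2$next_level_id <- tp$ws$next_level_id
    commit_predictions(ws2, pred, cf)
    sum(ws2$levels[[as.character(tp$level)]]$voxel_labels >= 0)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # confidence 0 leaves nothing unassigned
  ws0 <- new_workspace(tp$ws$volume)
  ws0$channels <- tp$ws$channels
  ws0$supervoxels <- tp$ws$supervoxels
  ws0$levels <- tp$ws$levels
  commit_predictions(ws0, pred, 0)
  expect_equal(sum(ws0$levels[[as.character(tp$level)]]$voxel_labels < 0),
               0)
  expect_error(commit_predictions(tp$ws, pred, 101), "confidence")
})

test_that("a perfectly ambiguous region is never committed at 100", {
  tp <- two_phase_workspace()
  cfg <- train_config(tp$level, sources = "tv", seed = 8)
  pred <- train_predict(tp$ws, cfg)
  amb <- which(!pred$train_mask)[1]
  pred$prob[amb, ] <- 0.5
  commit_predictions(tp$ws, pred, 100)
  svl <- supervoxel_labels(tp$ws)
  lab <- tp$ws$levels[[as.character(tp$level)]]$voxel_labels
  expect_true(all(lab[svl == amb] == -1L))
})

test_that("subregion and label selection restrict commitment", {
  tp <- two_phase_workspace()
  cfg <- train_config(tp$level, sources = "tv", seed = 9)
  pred <- train_predict(tp$ws, cfg)
  commit_predictions(tp$ws, pred, 0, subregion = c(1, 8, 1, 8, 1, 8))
  lab <- tp$ws$levels[[as.character(tp$level)]]$voxel_labels
  outside <- lab[9:32, 9:32, 9:32]
  svl_out <- supervoxel_labels(tp$ws)[9:32, 9:32, 9:32]
  train_sv <- which(pred$train_mask)
  expect_true(all(outside[!(svl_out %in% train_sv)] == -1L))
})

test_that("training is deterministic under a fixed seed", {
  tp1 <- two_phase_workspace()
  tp2 <- two_phase_workspace()
  cfg <- train_config(tp1$level, sources = "tv", seed = 123)
  p1 <- train_predict(tp1$ws, cfg)
  p2 <- train_predict(tp2$ws, cfg)
  expect_identical(p1$prob, p2$prob)
  expect_identical(p1$labels_hat, p2$labels_hat)
})

test_that("iterated training converges and matches the phantom truth", {
  tp <- two_phase_workspace()
  cfg <- train_config(tp$level, sources = "tv", refinement = "appearance",
                      refine_lambda = 50, confidence = 50, seed = 10)
  hist <- iterate_training(tp$ws, cfg, rounds = 3)
  lab <- tp$ws$levels[[as.character(tp$level)]]$voxel_labels
  expect_equal(sum(lab < 0), 0)
  expect_lte(nrow(hist), 3)
  truth <- ifelse(tp$ph$truth == 1, tp$labels[1], tp$labels[2])
  expect_true(all(dice_score(lab, truth) >= 0.9))
})
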