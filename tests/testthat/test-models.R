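# separable two-feature toy problem (hard margin) used across model tests
toy_binary <- function(n_per = 30L, labels = c("impact", "noise"), seed = 1L) {
  set.seed(seed)
  x <- rbind(matrix(runif(2 * n_per, 3, 5), ncol = 2),
             matrix(runif(2 * n_per, -5, -3), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, labels = rep(labels, each = n_per))
}

test_that("the impact model separates a separable toy problem", {
  toy <- toy_binary()
  m <- train_impact_model(toy$x, toy$labels, seed = 2)
  expect_equal(unname(predict(m, toy$x, type = "class")), toy$labels)
  probs <- predict(m, toy$x)
  expect_equal(colnames(probs), c("noise", "impact"))
  expect_equal(rowSums(probs), rep(1, nrow(probs)))
  expect_error(train_impact_model(toy$x, rep("impact", 60)), "both classes")
})

test_that("the rebound ensemble separates a separable toy problem", {
  toy <- toy_binary(labels = c("rebound", "noise"))
  cfg <- ensemble_config(n_trees = 50L, mlp_epochs = 50L)
  m <- train_rebound_ensemble(toy$x, toy$labels, cfg, seed = 2)
  expect_equal(unname(predict(m, toy$x, type = "class")), toy$labels)
})

test_that("soft voting is the arithmetic mean of member probabilities", {
  members <- list(
    matrix(c(0.6, 0.4), 1, dimnames = list(NULL, c("noise", "rebound"))),
    matrix(c(0.2, 0.8), 1, dimnames = list(NULL, c("noise", "rebound"))),
    matrix(c(0.55, 0.45), 1, dimnames = list(NULL, c("noise", "rebound"))))
  avg <- soft_vote(members)
  expect_equal(as.vector(avg), c(0.45, 0.55))
  # averaged probability favors rebound here; an exact 0.5 tie goes to noise
  expect_equal(unname(ifelse(avg[, "rebound"] > 0.5, "rebound", "noise")),
               "rebound")
  tie <- soft_vote(list(matrix(c(0.5, 0.5), 1,
                               dimnames = list(NULL, c("noise", "rebound")))))
  expect_equal(unname(ifelse(tie[, "rebound"] > 0.5, "rebound", "noise")),
               "noise")
})

test_that("training and CV are deterministic given the seed", {
  toy <- toy_binary(n_per = 25L)
  trainer <- function(x, l, s) train_impact_model(x, l, seed = s)
  a <- kfold_cv(toy$x, toy$labels, seed = 42, trainer = trainer)
  b <- kfold_cv(toy$x, toy$labels, seed = 42, trainer = trainer)
  expect_identical(a$fold_accuracy, b$fold_accuracy)
  expect_identical(a$folds, b$folds)
})

test_that("stratified folds partition the data with the stated sizes", {
  # 1400 samples in three classes divisible by five: 1120 train / 280 test
  labels <- rep(c("noise", "rebound", "impact"), c(500L, 450L, 450L))
  x <- matrix(rnorm(1400 * 2), ncol = 2)
  x[labels == "impact", ] <- x[labels == "impact", ] + 4
  trainer <- function(xx, ll, s) train_impact_model(
    xx, ifelse(ll == "impact", "impact", "noise"),
    impact_config(n_trees = 5L), s)
  # use a binary relabel inside the trainer but keep 3-class stratification
  folds <- NULL
  rep5 <- kfold_cv(x, labels, k = 5, seed = 1, trainer = function(xx, ll, s) {
    m <- trainer(xx, ll, s)
    m
  })
  expect_equal(rep5$fold_sizes, rep(280L, 5))
  expect_equal(sort(unique(rep5$folds)), 1:5)
  expect_length(rep5$folds, 1400)
  for (i in 1:5) {
    tr_n <- sum(rep5$folds != i)
    expect_equal(tr_n, 1120L)
    # stratification keeps class ratios within each fold
    expect_equal(as.vector(table(labels[rep5$folds == i])),
                 c(90L, 100L, 90L))
  }
})

test_that("perfectly learnable data yields all-1 fold accuracies", {
  # class-constant features: every fold model must classify perfectly
  x <- cbind(f1 = rep(c(1, -1), each = 50), f2 = rep(c(-2, 2), each = 50))
  labels <- rep(c("impact", "noise"), each = 50)
  rep5 <- kfold_cv(x, labels, seed = 3,
                   trainer = function(xx, l, s)
                     train_impact_model(xx, l, impact_config(n_trees = 20L), s))
  expect_equal(rep5$fold_accuracy, rep(1, 5))
  expect_equal(rep5$median_accuracy, 1)
})

test_that("grid search is exhaustive with first-in-grid tie-breaking", {
  toy <- toy_binary(n_per = 15L)
  grid <- list(impact_config(n_trees = 5L), impact_config(n_trees = 10L))
  gs <- grid_search(toy$x, toy$labels, grid, k = 3, seed = 4,
                    trainer_for = function(cfg)
                      function(x, l, s) train_impact_model(x, l, cfg, s))
  expect_equal(nrow(gs$table), 2L)
  expect_equal(gs$best_index, which.max(gs$table$mean_accuracy))
  single <- grid_search(toy$x, toy$labels, grid[1], k = 3, seed = 4,
                        trainer_for = function(cfg)
                          function(x, l, s) train_impact_model(x, l, cfg, s))
  expect_identical(single$best_config, grid[[1]])
})

test_that("bundle archives roundtrip with identical predictions", {
  bundle <- tiny_bundle()
  path <- withr::local_tempfile(fileext = ".rds")
  save_bundle(bundle, path)
  back <- load_bundle(path)
  seg <- extract_segment(tiny_bank()$clips[[1]], 0.05)
  xb <- feature_matrix(list(seg), "base")[, bundle$impact_selection$indices,
                                          drop = FALSE]
  xe <- feature_matrix(list(seg), "extended")[, bundle$rebound_selection$indices,
                                              drop = FALSE]
  expect_equal(predict(back$impact_model, xb), predict(bundle$impact_model, xb))
  expect_equal(predict(back$rebound_ensemble, xe),
               predict(bundle$rebound_ensemble, xe))
  # corrupted archives are refused
  payload <- readRDS(path)
  payload$hash <- payload$hash + 1
  saveRDS(payload, path)
  expect_error(load_bundle(path), "integrity")
})

test_that("classify_events pairs an impact with its rebound on a clean scene", {
  bundle <- cached("clean_scene_events", function() {
    sc <- render_scene(scene_preset("g1", seed = 21, n_shots = 4,
                                    ambient_snr_db = 50))
    list(scene = sc, events = classify_events(sc$clip, tiny_bundle()))
  })
  ev <- bundle$events
  sc <- bundle$scene
  expect_true(all(ev$label %in% c("impact", "rebound")))
  imp_truth <- sc$truth$time_s[sc$truth$label == "impact"]
  det_imp <- ev$time_s[ev$label == "impact"]
  # every true impact is found within 20 ms
  expect_equal(length(det_imp), length(imp_truth))
  expect_lt(max(abs(sort(det_imp) - sort(imp_truth))), 0.020)
  # paired rebounds precede their impact inside the rebound window
  tm <- executive_timing(ev)
  expect_true(all(tm$timing_s >= 0.4 & tm$timing_s <= 1.5))
})

test_that("classify_events returns an empty table on silence", {
  silent <- audio_clip(numeric(96000), 48000L)
  ev <- classify_events(silent, tiny_bundle())
  expect_equal(nrow(ev), 0)
  expect_named(ev, c("time_s", "label", "amplitude", "probability",
                     "impact_id"))
})
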