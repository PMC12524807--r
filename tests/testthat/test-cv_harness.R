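test_that("fold plans balance fold sizes and realize the 100-run protocol", {
  plan <- make_fold_plan(100, base_seed = 1)
  expect_equal(nrow(plan$runs), 100)         # 5 folds x 20 rounds
  for (r in 1:20) {
    expect_equal(as.integer(table(plan$folds[[r]])), rep(20L, 5))
  }
  plan2 <- make_fold_plan(103, n_rounds = 2, base_seed = 1)
  expect_equal(sort(as.integer(table(plan2$folds[[1]])), decreasing = TRUE),
               c(21L, 21L, 21L, 20L, 20L))
  expect_error(make_fold_plan(3, n_folds = 5),
               class = "coxformer_config_error")
})

test_that("roles are disjoint and exhaustive in every run", {
  plan <- make_fold_plan(53, n_folds = 5, n_rounds = 4, base_seed = 9)
  for (k in seq_len(nrow(plan$runs))) {
    rd <- plan$runs$round[k]
    labels <- plan$folds[[rd]]
    test_rows <- which(labels == plan$runs$test_fold[k])
    val_rows <- which(labels == plan$runs$val_fold[k])
    train_rows <- which(labels != plan$runs$test_fold[k] &
                          labels != plan$runs$val_fold[k])
    expect_length(intersect(test_rows, val_rows), 0)
    expect_length(intersect(test_rows, train_rows), 0)
    expect_length(intersect(val_rows, train_rows), 0)
    expect_setequal(c(test_rows, val_rows, train_rows), 1:53)
  }
  # each fold is the test fold exactly once per round
  for (r in 1:4) {
    expect_setequal(plan$runs$test_fold[plan$runs$round == r], 1:5)
  }
})

test_that("plans are reproducible and survive JSON serialization", {
  p1 <- make_fold_plan(40, n_rounds = 3, base_seed = 7)
  p2 <- make_fold_plan(40, n_rounds = 3, base_seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1$folds, make_fold_plan(40, n_rounds = 3,
                                                  base_seed = 8)$folds))
  path <- withr::local_tempfile(fileext = ".json")
  write_fold_plan(p1, path)
  p3 <- read_fold_plan(path)
  expect_identical(p3$folds, p1$folds)
  expect_equal(p3$runs$test_fold, p1$runs$test_fold)
})

test_that("run_cv is deterministic and its aggregates match the per-run table", {
  sim <- tiny_sim(n = 60, p = 6, signal = 2, seed = 20, censor = 0.4)
  plan <- make_fold_plan(60, n_rounds = 2, base_seed = 3)
  spec <- linear_cox_spec(fast_tcfg(learning_rate = 0.01, max_epochs = 20,
                                    patience = 5))
  r1 <- run_cv(sim$cohort, spec, plan)
  r2 <- run_cv(sim$cohort, spec, plan)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  expect_equal(nrow(r1), 10)
  sm <- summary(r1)
  ok <- r1[r1$status == "ok", ]
  expect_equal(sm$mean_test_c, mean(ok$test_c))
  expect_equal(sm$sd_test_c, sd(ok$test_c))
  # CSV export keeps both tables
  runs_csv <- withr::local_tempfile(fileext = ".csv")
  sum_csv <- withr::local_tempfile(fileext = ".csv")
  write_cv_result(r1, runs_csv, sum_csv)
  expect_equal(nrow(read.csv(runs_csv)), 10)
  expect_equal(read.csv(sum_csv)$mean_test_c, sm$mean_test_c)
})

test_that("degenerate folds are reported as failed runs, not dropped silently", {
  sim <- tiny_sim(n = 25, p = 4, signal = 1, seed = 21, censor = 0.4)
  co <- sim$cohort
  co$event[] <- 0L
  co$event[1:2] <- 1L   # events concentrated: some training folds see none
  plan <- make_fold_plan(25, n_rounds = 2, base_seed = 5)
  spec <- linear_cox_spec(fast_tcfg(learning_rate = 0.01, max_epochs = 5,
                                    patience = 2))
  res <- run_cv(co, spec, plan)
  expect_true(any(res$status == "failed"))
  expect_true(all(nzchar(res$reason[res$status == "failed"])))
  sm <- summary(res)
  expect_equal(sm$n_failed, sum(res$status == "failed"))
  expect_equal(sm$mean_test_c, mean(res$test_c[res$status == "ok"]))
})

test_that("models that need no validation train on all non-test folds", {
  seen <- new.env()
  spec <- new_model_spec("dummy", function(train, val, seed) {
    seen$train_n <- c(seen$train_n, nrow(train$X))
    seen$has_val <- c(seen$has_val, !is.null(val))
    structure(list(genes = train$genes, standardizer = NULL),
              class = "dummy_model")
  }, needs_validation = FALSE)
  assign("predict_risk.dummy_model",
         function(model, cohort) seq_len(nrow(cohort$X)),
         envir = globalenv())
  on.exit(rm("predict_risk.dummy_model", envir = globalenv()), add = TRUE)
  sim <- tiny_sim(n = 50, p = 4, seed = 22, censor = 0.3)
  plan <- make_fold_plan(50, n_rounds = 1, base_seed = 2)
  res <- run_cv(sim$cohort, spec, plan)
  expect_true(all(seen$train_n == 40))      # 4 of 5 folds
  expect_false(any(seen$has_val))
  expect_true(all(is.na(res$val_c)))
})

test_that("grid search returns the dominant point and a recomputable score", {
  sim <- tiny_sim(n = 50, p = 4, signal = 2, seed = 23, censor = 0.3)
  plan <- make_fold_plan(50, n_rounds = 1, base_seed = 4)
  # rigged factory: quality 1 predicts against survival order, quality 2 with it
  factory <- function(point) {
    q <- point$quality
    spec <- new_model_spec(paste0("rig", q), function(train, val, seed) {
      structure(list(genes = train$genes, standardizer = NULL, q = q),
                class = "rigged_model")
    })
    spec
  }
  assign("predict_risk.rigged_model", function(model, cohort) {
    if (model$q == 2) -cohort$time else cohort$time
  }, envir = globalenv())
  on.exit(rm("predict_risk.rigged_model", envir = globalenv()), add = TRUE)
  gs <- grid_search(sim$cohort, list(quality = c(1, 2)), plan,
                    spec_factory = factory)
  expect_equal(gs$best$quality, 2)
  # bookkeeping: the reported score equals mean(train_c + val_c) per point
  for (i in 1:2) {
    ok <- gs$results[[i]][gs$results[[i]]$status == "ok", ]
    expect_equal(gs$scores$selection_score[i], mean(ok$train_c + ok$val_c),
                 tolerance = 1e-9)
  }
  # singleton grid returns its only point
  gs1 <- grid_search(sim$cohort, list(quality = 2), plan,
                     spec_factory = factory)
  expect_equal(gs1$best$quality, 2)
  expect_error(grid_search(sim$cohort, list(), plan),
               class = "coxformer_config_error")
})
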