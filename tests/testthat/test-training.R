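test_that("zero epochs returns the freshly initialized model and an empty record", {
  sim <- tiny_sim(n = 30, p = 8, seed = 1)
  mcfg <- model_config(8, token_dim = 4, num_heads = 2, num_blocks = 1)
  m <- train_coxformer(sim$cohort, NULL, mcfg, fast_tcfg(max_epochs = 0),
                       standardize = FALSE)
  expect_identical(unlist(m$params), unlist(coxformer_init(mcfg, seed = 1)))
  expect_equal(nrow(m$record), 0)
})

test_that("training is bit-reproducible from its seed", {
  sim <- tiny_sim(n = 40, p = 8, seed = 2)
  tr <- subset_cohort(sim$cohort, 1:30)
  va <- subset_cohort(sim$cohort, 31:40)
  mcfg <- model_config(8, token_dim = 4, num_heads = 2, num_blocks = 1,
                       dropout = 0.2)
  m1 <- train_coxformer(tr, va, mcfg, fast_tcfg(max_epochs = 15, patience = 5,
                                                seed = 3))
  m2 <- train_coxformer(tr, va, mcfg, fast_tcfg(max_epochs = 15, patience = 5,
                                                seed = 3))
  expect_identical(unlist(m1$params), unlist(m2$params))
  expect_identical(m1$record$train_loss, m2$record$train_loss)
})

test_that("optimization reduces the training loss on a simulated cohort", {
  sim <- tiny_sim(n = 120, p = 16, signal = 4, seed = 5, censor = 0.4)
  mcfg <- model_config(16, token_dim = 8, num_heads = 2, num_blocks = 1,
                       dropout = 0)
  m <- train_coxformer(sim$cohort, NULL, mcfg, fast_tcfg(max_epochs = 40))
  expect_lt(tail(m$record$train_loss, 1), m$record$train_loss[1])
})

test_that("the linear baseline recovers the sign of a planted effect", {
  sim <- tiny_sim(n = 500, p = 10, signal = 1, beta = 1, seed = 6,
                  censor = 0.3)
  tr <- subset_cohort(sim$cohort, 1:400)
  va <- subset_cohort(sim$cohort, 401:500)
  m <- train_linear_cox(tr, va, fast_tcfg(learning_rate = 0.01,
                                          max_epochs = 150, patience = 20))
  expect_gt(m$beta[["G0001"]], 0)
  expect_gt(abs(m$beta[["G0001"]]), max(abs(m$beta[-1])))
})

test_that("the linear baseline approaches the oracle on an estimable problem", {
  sim <- tiny_sim(n = 1000, p = 20, signal = 5, beta = 1, seed = 7,
                  censor = 0.5)
  tr <- subset_cohort(sim$cohort, 1:700)
  va <- subset_cohort(sim$cohort, 701:850)
  te <- subset_cohort(sim$cohort, 851:1000)
  m <- train_linear_cox(tr, va, fast_tcfg(learning_rate = 0.01,
                                          weight_decay = 0.01,
                                          max_epochs = 400, patience = 60))
  test_c <- concordance_index(predict_risk(m, te), te$time, te$event)$cindex
  oracle <- concordance_index(sim$truth$true_risk[851:1000], te$time,
                              te$event)$cindex
  expect_lt(abs(test_c - oracle), 0.05)
})

test_that("a signal-free cohort yields chance-level test concordance", {
  cs <- vapply(1:8, function(seed) {
    sim <- tiny_sim(n = 300, p = 10, signal = 0, beta = 0, seed = seed + 50,
                    censor = 0.4)
    tr <- subset_cohort(sim$cohort, 1:200)
    va <- subset_cohort(sim$cohort, 201:250)
    te <- subset_cohort(sim$cohort, 251:300)
    m <- train_linear_cox(tr, va, fast_tcfg(learning_rate = 0.01,
                                            max_epochs = 60, patience = 10,
                                            seed = seed))
    concordance_index(predict_risk(m, te), te$time, te$event, "half")$cindex
  }, numeric(1))
  expect_lt(abs(mean(cs) - 0.5), 0.05)
})

test_that("divergence raises an error naming the epoch", {
  sim <- tiny_sim(n = 40, p = 8, seed = 9)
  expect_error(
    train_linear_cox(sim$cohort, NULL,
                     fast_tcfg(learning_rate = 1e12, max_epochs = 50)),
    "epoch", class = "coxformer_divergence_error")
})

test_that("minibatch mode trains deterministically", {
  sim <- tiny_sim(n = 60, p = 8, seed = 10, censor = 0.3)
  tr <- subset_cohort(sim$cohort, 1:45)
  va <- subset_cohort(sim$cohort, 46:60)
  mcfg <- model_config(8, token_dim = 4, num_heads = 2, num_blocks = 1)
  tc <- fast_tcfg(max_epochs = 10, patience = 0, batch_size = 16, seed = 4)
  m1 <- train_coxformer(tr, va, mcfg, tc)
  m2 <- train_coxformer(tr, va, mcfg, tc)
  expect_identical(unlist(m1$params), unlist(m2$params))
})

test_that("the selected epoch attains the best validation criterion seen", {
  sim <- tiny_sim(n = 80, p = 8, seed = 11, censor = 0.4)
  tr <- subset_cohort(sim$cohort, 1:60)
  va <- subset_cohort(sim$cohort, 61:80)
  m <- train_linear_cox(tr, va, fast_tcfg(learning_rate = 0.01,
                                          max_epochs = 50, patience = 50))
  best <- attr(m$record, "best_epoch")
  expect_equal(m$record$val_cindex[best], max(m$record$val_cindex))
})

test_that("checkpoints round trip and reproduce predictions", {
  sim <- tiny_sim(n = 50, p = 8, seed = 12)
  tr <- subset_cohort(sim$cohort, 1:40)
  va <- subset_cohort(sim$cohort, 41:50)
  mcfg <- model_config(8, token_dim = 4, num_heads = 2, num_blocks = 1)
  m <- train_coxformer(tr, va, mcfg, fast_tcfg(max_epochs = 10, patience = 5))
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_equal(predict_risk(m2, sim$cohort), predict_risk(m, sim$cohort))
  # the record exports as a per-epoch CSV
  csv <- withr::local_tempfile(fileext = ".csv")
  write_train_record(m, csv)
  rec <- read.csv(csv)
  expect_identical(names(rec), c("epoch", "train_loss", "val_loss",
                                 "val_cindex"))
})

test_that("feature-count mismatches and missing validation sets are rejected", {
  sim <- tiny_sim(n = 30, p = 8, seed = 13)
  mcfg <- model_config(16, token_dim = 8, num_heads = 2, num_blocks = 1)
  expect_error(train_coxformer(sim$cohort, NULL, mcfg, fast_tcfg()),
               class = "coxformer_validation_error")
  mcfg2 <- model_config(8, token_dim = 4, num_heads = 2, num_blocks = 1)
  expect_error(train_coxformer(sim$cohort, NULL, mcfg2,
                               train_config(patience = 5)),
               class = "coxformer_config_error")
  m <- train_coxformer(sim$cohort, NULL, mcfg2, fast_tcfg(max_epochs = 2))
  other <- tiny_sim(n = 10, p = 6, seed = 14)$cohort
  expect_error(predict_risk(m, other), class = "coxformer_validation_error")
})
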