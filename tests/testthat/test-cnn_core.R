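tiny_config <- function(...) {
  suppressWarnings(model_config(n_filters = 4L, kernel_size = 3L,
                                dense_units = 6L, batch_size = 16L, ...))
}

tiny_motif_data <- function(n_pos, n_neg) {
  mk <- function(n, pos) vapply(seq_len(n), function(i) {
    s <- sample(c("a", "t", "c", "g"), 100, TRUE)
    if (pos) {
      o <- sample(10:70, 1)
      s[o:(o + 9)] <- strsplit("atcaccccac", "")[[1]]
      s[(o + 14):(o + 18)] <- strsplit("ccaat", "")[[1]]
    }
    paste(s, collapse = "")
  }, character(1))
  data.frame(sequence = c(mk(n_pos, TRUE), mk(n_neg, FALSE)),
             label = rep(c(1L, 0L), c(n_pos, n_neg)))
}

test_that("analytic gradients agree with finite differences", {
  withr::local_seed(51)
  m <- build_model(tiny_config(rng_seed = 52L))
  codes <- encode_codes(random_window(4))
  y <- c(1, 0, 1, 0)
  lg <- srescan:::cpp_cnn_loss_grad(m$weights, codes, y)
  for (wn in names(m$weights)) {
    idx <- sample(seq_along(m$weights[[wn]]),
                  min(4L, length(m$weights[[wn]])))
    for (i in idx) {
      eps <- 1e-6
      wp <- m$weights; wp[[wn]][i] <- wp[[wn]][i] + eps
      wm <- m$weights; wm[[wn]][i] <- wm[[wn]][i] - eps
      num <- (srescan:::cpp_cnn_loss_grad(wp, codes, y)$loss -
              srescan:::cpp_cnn_loss_grad(wm, codes, y)$loss) / (2 * eps)
      ana <- if (wn == "b4") lg$grads[[wn]] else lg$grads[[wn]][i]
      expect_equal(ana, num, tolerance = 1e-5)
    }
  }
})

test_that("untrained models emit probabilities in (0,1), reproducibly", {
  m1 <- build_model(tiny_config(rng_seed = 53L))
  m2 <- build_model(tiny_config(rng_seed = 53L))
  expect_identical(m1$weights, m2$weights)
  withr::local_seed(54)
  p <- predict_proba(m1, random_window(8))
  expect_length(p, 8L)
  expect_true(all(p > 0 & p < 1))
  # order-preserving with input
  x <- random_window(3)
  expect_identical(predict_proba(m1, x)[2], predict_proba(m1, x[2]))
})

test_that("parameter count matches a layer-by-layer sum", {
  count_for <- function(nf, k, D = 64L) {
    conv1 <- (5L * k) * nf + nf
    conv2 <- (k * nf) * nf + nf
    dense <- nf * D + D
    out <- D + 1L
    conv1 + conv2 + dense + out
  }
  m <- build_model(model_config(n_filters = 64L, kernel_size = 6L))
  expect_identical(n_params(m), count_for(64L, 6L))
  m2 <- build_model(model_config(n_filters = 32L, kernel_size = 12L))
  expect_identical(n_params(m2), count_for(32L, 12L))
})

test_that("training learns a planted composite motif quickly", {
  withr::local_seed(55)
  tr <- tiny_motif_data(300, 300)
  va <- tiny_motif_data(80, 80)
  cfg <- suppressWarnings(model_config(
    n_filters = 16L, kernel_size = 6L, dense_units = 16L, batch_size = 64L,
    epoch_blocks = 20L, patience_per_block = 5L, rng_seed = 56L))
  m <- train_cnn(build_model(cfg), tr, va)
  expect_gte(m$history$best_val_accuracy, 0.95)
  expect_lte(nrow(m$history$epochs), 20L)
})

test_that("early stopping ends a block after patience epochs without improvement", {
  withr::local_seed(57)
  tr <- tiny_motif_data(20, 20)
  va <- tiny_motif_data(10, 10)
  # zero learning rate freezes the model, so validation accuracy is constant:
  # epoch 1 sets the best, epoch 2 exhausts patience 1
  cfg <- tiny_config(learning_rate = 0, epoch_blocks = c(10L, 10L),
                     patience_per_block = c(1L, 1L), rng_seed = 58L)
  m <- train_cnn(build_model(cfg), tr, va)
  expect_identical(m$history$epochs$epoch[m$history$epochs$block == 1],
                   1:2)
  expect_lte(nrow(m$history$epochs), 4L)
  # and the history never exceeds the block budget
  expect_lte(nrow(m$history$epochs), sum(cfg$epoch_blocks))
})

test_that("training is deterministic under a fixed seed and rejects bad sets", {
  withr::local_seed(59)
  tr <- tiny_motif_data(30, 30)
  va <- tiny_motif_data(10, 10)
  cfg <- tiny_config(epoch_blocks = 2L, patience_per_block = 2L,
                     rng_seed = 60L)
  h1 <- train_cnn(build_model(cfg), tr, va)$history$epochs
  h2 <- train_cnn(build_model(cfg), tr, va)$history$epochs
  expect_identical(h1, h2)
  expect_error(train_cnn(build_model(cfg), tr[tr$label == 1, ], va),
               "both classes")
  expect_error(train_cnn(build_model(cfg), tr[0, ], va))
})

test_that("evaluate_classifier reproduces the confusion arithmetic", {
  p <- c(rep(0.9, 9), 0.9, rep(0.1, 9), 0.1)
  y <- c(rep(1, 9), 0, rep(0, 9), 1)
  met <- evaluate_classifier(p, y)
  expect_identical(c(met$tp, met$fp, met$fn, met$tn), c(9L, 1L, 1L, 9L))
  expect_equal(met$accuracy, 0.9)
  expect_equal(met$precision, 0.9)
  expect_equal(met$recall, 0.9)
  expect_equal(met$f1, 0.9)
  perfect <- evaluate_classifier(c(0.99, 0.01), c(1, 0))
  expect_equal(unlist(perfect[c("accuracy", "precision", "recall", "f1")]),
               c(accuracy = 1, precision = 1, recall = 1, f1 = 1))
  anti <- evaluate_classifier(c(0.99, 0.01), c(0, 1))
  expect_equal(anti$accuracy, 0)
  expect_error(evaluate_classifier(numeric(0), numeric(0)))

  # brute-force recount on random data
  withr::local_seed(61)
  for (i in 1:10) {
    p <- runif(50); y <- rbinom(50, 1, 0.4); thr <- runif(1, 0.2, 0.8)
    met <- evaluate_classifier(p, y, thr)
    expect_identical(met$tp, sum(p >= thr & y == 1))
    expect_identical(met$tn, sum(p < thr & y == 0))
    expect_equal(met$accuracy, mean((p >= thr) == (y == 1)))
    if (!is.na(met$f1)) {
      expect_equal(met$f1,
                   2 * met$precision * met$recall / (met$precision + met$recall))
    }
  }
})

test_that("checkpoints round-trip through save_model/load_model", {
  withr::local_seed(62)
  m <- build_model(tiny_config(rng_seed = 63L))
  tf <- withr::local_tempfile(fileext = ".rds")
  save_model(m, tf)
  back <- load_model(tf)
  x <- random_window(4)
  expect_identical(predict_proba(back, x), predict_proba(m, x))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_model(bad), "checkpoint")
})
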