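test_that("the network learns representable functions and is deterministic", {
  set.seed(9)
  X <- matrix(rnorm(2000 * 10), 2000, 10)
  W <- matrix(rnorm(10 * 2), 10, 2)
  Y <- X %*% W
  net <- train_mlp(X[1:1600, ], Y[1:1600, ], layer_sizes = c(10, 40, 20, 2),
                   seed = 1,
                   schedule = list(epochs = 1500, patience = 1500,
                                   lr = 5e-3, lr_decay = 0.9975,
                                   batch = 128))
  rep <- evaluate_net(net, X[1601:2000, ], Y[1601:2000, ])
  sd_per_dim <- sqrt(mean(sweep(Y, 2, colMeans(Y))^2))
  expect_lt(rep$mean_error, 0.01 * sd_per_dim)
  expect_true(all(rep$per_dimension$correlation > 0.999))
  ## constant targets: the network predicts the constant
  netc <- train_mlp(X[1:500, ], matrix(2.5, 500, 1),
                    layer_sizes = c(10, 20, 1), seed = 1,
                    schedule = list(epochs = 40, patience = 40))
  expect_equal(as.numeric(predict(netc, X[501:520, ])), rep(2.5, 20),
               tolerance = 0.05)
  ## identical seeds give identical weights
  n1 <- train_mlp(X[1:300, ], Y[1:300, ], layer_sizes = c(10, 16, 8, 2),
                  seed = 4, schedule = list(epochs = 5))
  n2 <- train_mlp(X[1:300, ], Y[1:300, ], layer_sizes = c(10, 16, 8, 2),
                  seed = 4, schedule = list(epochs = 5))
  expect_identical(n1$weights, n2$weights)
  expect_error(train_mlp(matrix(c(1, NA), 2, 1), matrix(1:2, 2, 1)),
               "non-finite")
})

test_that("evaluation reports behave at the reference points", {
  Y <- matrix(rnorm(50 * 3), 50, 3)
  rep <- evaluate_net(function(X) Y, Y, Y)   # perfect predictor
  expect_equal(rep$mean_error, 0)
  expect_true(all(rep$per_dimension$correlation > 1 - 1e-12))
  ## mean predictor: zero correlations
  rep2 <- evaluate_net(function(X) matrix(colMeans(Y), 50, 3, byrow = TRUE),
                       Y, Y)
  expect_true(all(abs(rep2$per_dimension$correlation) < 1e-8))
})

test_that("the LIF population decodes planted targets and gains with capacity", {
  set.seed(12)
  B <- matrix(0, 9, 16); idx <- 0
  for (fx in 0:2) for (fy in 0:2) {
    idx <- idx + 1
    B[idx, ] <- as.numeric(outer(cos(fx * pi * (1:4) / 4),
                                 cos(fy * pi * (1:4) / 4)))
  }
  X <- matrix(rnorm(600 * 9), 600, 9) %*% B * 0.1
  v <- rnorm(16) / 4
  y <- as.numeric(X %*% v); y <- (y - mean(y)) / stats::sd(y)
  tr <- 1:450; va <- 451:600
  nrmse <- sapply(c(500, 1000, 3000), function(n) {
    pop <- train_nef_population(X[tr, ], y[tr], n_neurons = n, seed = 3,
                                kernel_spec = list(n_grid = 4L,
                                                   n_channels = 1L),
                                reg = 1e-3)
    yh <- predict(pop, X[va, ])
    sqrt(mean((yh - y[va])^2)) / stats::sd(y[va])
  })
  expect_lt(nrmse[2], 0.1)              # planted linear, n = 1000
  expect_true(all(diff(nrmse) < 0))     # error decreases with capacity
  ## zero-variance feature dimensions stay harmless under ridge
  X0 <- cbind(X[, 1:8], 0)
  dimnames(X0) <- NULL
  pop0 <- train_nef_population(X0[tr, ], y[tr], n_neurons = 300, seed = 3,
                               kernel_spec = list(n_grid = 3L,
                                                  n_channels = 1L))
  expect_true(all(is.finite(predict(pop0, X0[va, ]))))
})

test_that("training diagnostics reflect early stopping and the angle wall", {
  ct <- acc_contrast()
  ## checkpointed holdout loss is non-increasing
  for (run in ct$runs) {
    h <- run$net_isomap$history
    ck <- h$holdout_loss[h$checkpoint]
    expect_true(all(diff(ck) <= 1e-12))
  }
  ## superquadric angle error concentrates near the canonical-range
  ## boundaries (the discontinuity signature)
  rs <- ct$runs[[1]]$superquadric
  db <- acc_db()
  Ysq <- ct$Ysq[ct$sub_va, ]
  P <- rs$predictions
  box <- db$label[ct$sub_va] == "box-like"
  ang_err <- rowMeans(abs(P[, 7:9] - Ysq[, 7:9]))[box]
  prox <- pmax(abs(Ysq[, 7]), abs(Ysq[, 8]), abs(Ysq[, 9]))[box]
  hi <- ang_err[prox >= stats::quantile(prox, 0.9)]
  lo <- ang_err[prox <= stats::quantile(prox, 0.1)]
  expect_gt(mean(hi), 1.3 * mean(lo))
})

test_that("the pipeline runs end to end, deterministically", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  cfg <- pipeline_config(n_shapes = 200, seed = 3, d = 4,
                         targets = "isomap",
                         schedule = list(epochs = 8L))
  a1 <- suppressWarnings(run_pipeline(cfg, out_dir = dir1))
  a2 <- suppressWarnings(run_pipeline(cfg, out_dir = dir2))
  expect_identical(readLines(file.path(dir1, "embedding.csv")),
                   readLines(file.path(dir2, "embedding.csv")))
  expect_identical(readLines(file.path(dir1, "database.csv")),
                   readLines(file.path(dir2, "database.csv")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_s3_class(a1$reports$isomap, "eval_report")
  expect_error(run_pipeline(pipeline_config(n_shapes = 0)), "generate")
})
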