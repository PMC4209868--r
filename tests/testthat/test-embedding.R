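test_that("a linear manifold embeds like PCA", {
  set.seed(5)
  Z <- matrix(runif(400 * 2), 400, 2)
  Q <- qr.Q(qr(matrix(rnorm(100 * 2), 100, 2)))
  X <- Z %*% t(Q)
  emb <- isomap_fit(X, k = 20, d = 2)
  ## embedding distances reproduce the true planar distances
  r2 <- stats::cor(as.numeric(stats::dist(Z)),
                   as.numeric(stats::dist(emb$coordinates)))^2
  expect_gt(r2, 0.999)
  expect_lt(emb$residual_variance, 0.01)
  ## coordinates are centered
  expect_lt(max(abs(colMeans(emb$coordinates))), 1e-8)
  ## agreement with an independent Isomap implementation on the same
  ## graph size (vegan), compared through the distance structure
  skip_if_not_installed("vegan")
  vi <- vegan::isomap(stats::dist(X), ndim = 2, k = 20)
  r2v <- stats::cor(as.numeric(stats::dist(vi$points)),
                    as.numeric(stats::dist(emb$coordinates)))^2
  expect_gt(r2v, 0.999)
})

test_that("disconnected neighborhood graphs are refused with component sizes", {
  X <- rbind(matrix(rnorm(20, mean = 0, sd = 0.01), 10, 2),
             matrix(rnorm(20, mean = 50, sd = 0.01), 10, 2))
  expect_error(isomap_fit(X, k = 3, d = 2), "component sizes")
})

test_that("a one-parameter shape family embeds monotonically", {
  radii <- seq(0.01, 0.06, length.out = 300)
  grid <- acc_grid()
  feats <- t(sapply(radii, function(r)
    flatten_stack(derivative_stack(render_depth(
      superquadric(rep(r, 3), c(1, 1, 1), label = "sphere-like"), grid)),
      c("dx", "dy", "dxx", "dyy"))))
  e1 <- isomap_fit(feats, k = 10, d = 1)
  expect_gt(abs(stats::cor(e1$coordinates[, 1], radii,
                           method = "spearman")), 0.99)
  ## on this essentially one-dimensional manifold the residual variance
  ## is already near zero at d = 1 and stays there
  e8 <- isomap_fit(feats, k = 10, d = 8)
  rv <- c(residual_variance_at(e8, 1), residual_variance_at(e8, 4),
          residual_variance_at(e8, 8))
  expect_lt(max(rv), 1e-3)
  expect_true(all(diff(rv) <= 1e-3))
})

test_that("residual variance decreases with embedding dimension", {
  f <- db400()
  emb <- isomap_fit(f$deriv, k = 10, d = 8)
  rv <- c(residual_variance_at(emb, 2), residual_variance_at(emb, 4),
          residual_variance_at(emb, 8))
  expect_true(all(diff(rv) < 0))
  expect_equal(rv[3], emb$residual_variance, tolerance = 1e-10)
  expect_true(all(rv >= 0 & rv <= 1))
})

test_that("landmark Isomap approximates the exact embedding", {
  set.seed(5)
  Z <- matrix(runif(600 * 2), 600, 2)
  Q <- qr.Q(qr(matrix(rnorm(60 * 2), 60, 2)))
  X <- Z %*% t(Q)
  ex <- isomap_fit(X, k = 15, d = 2)
  lm_ <- isomap_fit(X, k = 15, d = 2, landmark_threshold = 100,
                    n_landmarks = 150, seed = 1)
  r2 <- stats::cor(as.numeric(stats::dist(ex$coordinates)),
                   as.numeric(stats::dist(lm_$coordinates)))^2
  expect_gt(r2, 0.999)
  ## the landmark mode embeds all points, not just landmarks, and its
  ## transform reproduces stored coordinates for training points
  expect_equal(nrow(lm_$coordinates), 600L)
  tr <- isomap_transform(lm_, X[33, ])
  expect_lt(max(abs(tr - lm_$coordinates[33, ])), 1e-7)
})

test_that("out-of-sample transform is consistent, continuous and stable", {
  set.seed(5)
  Z <- matrix(runif(200 * 2), 200, 2)
  Q <- qr.Q(qr(matrix(rnorm(50 * 2), 50, 2)))
  X <- Z %*% t(Q)
  emb <- isomap_fit(X, k = 8, d = 2)
  ## a training point maps to its training coordinate
  tr <- isomap_transform(emb, X[c(3, 77, 200), , drop = FALSE])
  expect_lt(max(abs(tr - emb$coordinates[c(3, 77, 200), ])), 1e-7)
  ## midpoint of two close training shapes lands between them
  d2 <- shapecode:::squared_distance_matrix(X)
  j <- which.min(replace(d2[17, ], 17, Inf))
  mid <- isomap_transform(emb, (X[17, ] + X[j, ]) / 2)
  seg <- rbind(emb$coordinates[17, ], emb$coordinates[j, ])
  pad <- 0.1 * (apply(seg, 2, max) - apply(seg, 2, min)) + 1e-9
  expect_true(all(mid >= apply(seg, 2, min) - pad &
                  mid <= apply(seg, 2, max) + pad))
  ## permuting the training order leaves transforms unchanged
  set.seed(1)
  emb_p <- isomap_fit(X[sample(200), ], k = 8, d = 2)
  expect_equal(isomap_transform(emb, X[42, ]),
               isomap_transform(emb_p, X[42, ]), tolerance = 1e-6)
  ## far-outside queries are flagged
  expect_warning(out <- isomap_transform(emb, X[42, ] + 50),
                 "outside the training support")
  expect_true(attr(out, "out_of_support"))
})

test_that("embedding is continuous over the shape manifold, unlike angles", {
  set.seed(13)
  f <- db400()
  db <- f$db; grid <- acc_grid()
  ## perturb shapes by 1% of a parameter range and embed originals and
  ## perturbed copies jointly
  idx <- sample(nrow(db), 60)
  pert <- db[idx, ]
  pert$A1 <- pmin(0.06, pert$A1 + 0.0005)       # 1% of the scale range
  pert$theta1 <- pert$theta1 + 0.005 * pi       # 1% of the angle range
  pf <- feature_matrix(render_database(pert, grid),
                       channels = c("dx", "dy", "dxx", "dyy"))
  emb <- isomap_fit(rbind(f$deriv, pf), k = 10, d = 8)
  co <- emb$coordinates
  n0 <- nrow(db)
  pd <- sqrt(shapecode:::squared_distance_matrix(co[seq_len(n0), ]))
  q05 <- stats::quantile(pd[upper.tri(pd)], 0.05)
  dd <- sqrt(rowSums((co[n0 + seq_len(60), ] - co[idx, ])^2))
  ## perturbed pairs sit far below typical inter-shape distances; a
  ## small tail reflects the finite 16x16 grid, where sharp-edged
  ## shapes respond steeply to sub-pixel pose changes
  expect_gt(mean(dd < q05), 0.85)
  expect_lt(stats::median(dd), q05 / 2)
  ## contrast: a tall box just below +pi/4 and the equivalent wide box
  ## just above -pi/4 are nearly the same shape with distant parameters
  delta <- 0.02
  tall <- superquadric(c(0.02, 0.05, 0.02), c(0.1, 0.1, 0.1),
                       c(pi / 4 - delta, 0, 0), "box-like")
  wide <- superquadric(c(0.02, 0.02, 0.05), c(0.1, 0.1, 0.1),
                       c(-pi / 4 + delta, 0, 0), "box-like")
  fb <- t(sapply(list(tall, wide), function(s)
    flatten_stack(derivative_stack(render_depth(s, grid)),
                  c("dx", "dy", "dxx", "dyy"))))
  co <- suppressWarnings(isomap_transform(emb, fb))
  emb_dist <- sqrt(sum((co[1, ] - co[2, ])^2))
  par_dist <- sqrt(sum((c(tall$A, tall$theta) - c(wide$A, wide$theta))^2))
  expect_lt(emb_dist, q05)
  expect_gt(par_dist, 1)    # mostly the angle gap of nearly pi/2
})

test_that("distance histograms share binning and summarize both sets", {
  set.seed(14)
  co <- matrix(rnorm(100 * 3), 100, 3)
  errs <- rep(1e-6, 50)
  h <- distance_histograms(co, errs, breaks = 30)
  expect_equal(h$error_counts[1], 50)          # zero errors: first bin
  expect_equal(sum(h$distance_counts), choose(100, 2))
  ## errors equal to shuffled pairwise distances: histograms coincide
  pd <- sqrt(shapecode:::squared_distance_matrix(co))
  pd <- pd[upper.tri(pd)]
  h2 <- distance_histograms(co, sample(pd), breaks = 30)
  expect_equal(h2$error_counts, h2$distance_counts)
})
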