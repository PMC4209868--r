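test_that("inside-outside function matches its closed form", {
  sph <- superquadric(rep(0.05, 3), c(1, 1, 1), label = "sphere-like")
  expect_equal(inside_outside(c(0.05, 0, 0), sph), 1)
  expect_equal(inside_outside(c(0, 0, 0), sph), 0)
  expect_equal(inside_outside(c(0.1, 0, 0), sph), 4)
  ## strictly increasing along any ray from the center
  set.seed(1)
  for (i in 1:20) {
    sq <- superquadric(runif(3, 0.01, 0.06), runif(3, 0.05, 1.5))
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    f <- inside_outside(outer(seq(0.001, 0.1, length.out = 50), u), sq)
    expect_true(all(diff(f) > 0))
  }
  expect_error(superquadric(c(-0.01, 0.02, 0.02), c(1, 1, 1)),
               "invalid parameter")
  expect_error(superquadric(c(0.01, 0.02, 0.02), c(0, 1, 1)),
               "invalid parameter")
})

test_that("rotation matrix is orthonormal with the printed convention", {
  expect_equal(rotation_matrix(0, 0, 0), diag(3))
  expect_equal(rotation_matrix(0, pi / 2, 0),
               matrix(c(0, 0, -1, 0, 1, 0, 1, 0, 0), 3, byrow = TRUE))
  set.seed(2)
  for (i in 1:1000) {
    th <- runif(3, -pi, pi)
    R <- rotation_matrix(th[1], th[2], th[3])
    expect_lt(max(abs(crossprod(R) - diag(3))), 1e-12)
    expect_equal(det(R), 1, tolerance = 1e-12)
  }
})

test_that("canonicalization gives an equivalent shape in the restricted range", {
  ## box with a quarter-turn comes back with theta = 0 and axes relabeled
  b <- superquadric(c(0.02, 0.03, 0.05), c(0.1, 0.3, 0.8), c(pi / 2, 0, 0),
                    "box-like")
  bc <- canonicalize(b)
  expect_equal(bc$theta, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(sort(bc$A), sort(b$A))
  ## a sphere loses its angles entirely
  s <- superquadric(rep(0.04, 3), c(1, 1, 1), c(0.3, -1, 2), "sphere-like")
  expect_equal(canonicalize(s)$theta, c(0, 0, 0))
  ## idempotence and geometry preservation across random shapes
  set.seed(3)
  grid <- acc_grid()
  for (i in 1:12) {
    lab <- sample(c("box-like", "cylinder-like"), 1)
    sq <- if (lab == "box-like") {
      superquadric(runif(3, 0.02, 0.06), runif(3, 0.05, 1),
                   runif(3, -pi, pi), lab)
    } else {
      a <- runif(1, 0.015, 0.04)
      superquadric(c(a, a, runif(1, a, 0.06)), c(1, 1, runif(1, 0.05, 1)),
                   runif(3, -pi, pi), lab)
    }
    sqc <- canonicalize(sq)
    expect_lt(max(abs(render_depth(sq, grid)$values -
                      render_depth(sqc, grid)$values)), 1e-6)
    sqcc <- canonicalize(sqc)
    expect_equal(c(sqcc$A, sqcc$eps, sqcc$theta),
                 c(sqc$A, sqc$eps, sqc$theta), tolerance = 1e-9)
  }
})

test_that("database sampling reproduces the stated distributions", {
  db <- sample_database(3000, seed = 7)
  expect_identical(as.data.frame(db),
                   as.data.frame(sample_database(3000, seed = 7)))
  ## classes within 5% of each other
  counts <- table(db$label)
  expect_length(counts, 3)
  expect_lt(max(counts) - min(counts), 0.05 * 1000)
  ## split disjoint and exhaustive, 70/30
  expect_equal(sort(unique(db$split)), c("train", "validation"))
  expect_equal(sum(db$split == "train"), 2100)
  ## width bounds and positive parameters
  A <- as.matrix(db[, c("A1", "A2", "A3")])
  expect_true(all(A >= 0.01 - 1e-12 & A <= 0.06 + 1e-12))
  expect_true(all(as.matrix(db[, c("eps1", "eps2", "eps3")]) >= 0.01))
  expect_equal(n_shape_parameters(db), 9L)
  expect_error(sample_database(0), "invalid argument")
  ## squared-edge exponents follow the shifted exponential
  set.seed(8)
  e <- sample_edge_exponent(10000)
  expect_true(all(e >= 0.01))
  expect_equal(mean(e), 0.11, tolerance = 0.03)
  ks <- suppressWarnings(
    stats::ks.test(e, function(q) stats::pexp(q - 0.01, rate = 10)))
  expect_gt(ks$p.value, 0.01)
})

test_that("stimulus enumeration removes exactly the symmetry-redundant poses", {
  stim <- acc_stimuli()
  expect_equal(nrow(stim), 36L)
  ## per-shape distinct orientation counts: sphere 1, cube 2, plate 3,
  ## cylinder 3, each at 4 sizes
  counts <- table(stim$shape) / 4
  expect_equal(unname(counts[c("sphere", "cube", "plate", "cylinder")]),
               c(1, 2, 3, 3), ignore_attr = TRUE)
  ## spheres only: rotation invariance leaves one stimulus per size
  sph_only <- enumerate_stimuli(base_stimulus_shapes()["sphere"])
  expect_equal(nrow(sph_only), 4L)
  ## renderer as oracle: removed duplicates match their representative,
  ## kept stimuli stay distinct
  v <- verify_stimulus_symmetries(stim, acc_grid())
  expect_lt(v$max_duplicate_discrepancy, 1e-6)
  expect_gt(v$min_distinct_discrepancy, 1e-3)
  expect_equal(v$n_duplicates_checked, 28L)
})

test_that("database round-trips through CSV with metadata", {
  db <- sample_database(40, seed = 3)
  path <- file.path(withr::local_tempdir(), "db.csv")
  write_database(db, path)
  db2 <- read_database(path)
  expect_equal(as.data.frame(db)$A1, db2$A1, tolerance = 1e-12)
  expect_equal(attr(db2, "seed"), 3L)
  sq <- db_shape(db2, 5)
  expect_s3_class(sq, "superquadric")
})
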