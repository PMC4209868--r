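test_that("augmented curves combine shape, size and orientation factors", {
  stim <- acc_stimuli()
  base <- c(sphere = 8, cube = 10, plate = 35, cylinder = 35)
  ## size-invariant: all sizes of one shape/orientation share a rate
  inv <- augment(base, augmentation_spec("invariant",
                                         orientation_pref_deg = 0),
                 stim)
  for (sh in unique(stim$shape)) for (po in unique(inv$orient_id[inv$shape == sh])) {
    rates <- inv$rate[inv$shape == sh & inv$orient_id == po]
    expect_lt(diff(range(rates)), 1e-12)
  }
  ## base rates reproduced at reference size and preferred orientation
  ## (the sphere has a single pose and no orientation factor)
  expect_equal(inv$rate[inv$shape == "cylinder" & inv$size_id == 4 &
                        inv$pose_angle_deg == 0], 35)
  expect_equal(inv$rate[inv$shape == "sphere" & inv$size_id == 4], 8)
  ## plate and cylinder equal at matched pose and size
  for (zi in 1:4) for (po in c(2, 3)) {
    expect_equal(inv$rate[inv$shape == "plate" & inv$size_id == zi &
                          inv$orient_id == po],
                 inv$rate[inv$shape == "cylinder" & inv$size_id == zi &
                          inv$orient_id == po])
  }
  ## monotone mode: rates nondecreasing across the four sizes
  mon <- augment(base, augmentation_spec("monotone",
                                         orientation_pref_deg = 0), stim)
  for (sh in unique(stim$shape)) for (po in unique(mon$orient_id[mon$shape == sh])) {
    rates <- mon$rate[mon$shape == sh & mon$orient_id == po]
    expect_true(all(diff(rates) >= -1e-12))
  }
  expect_true(all(mon$rate >= 0))
  expect_error(augment(c(sphere = -1, cube = 1, plate = 1, cylinder = 1),
                       augmentation_spec(), stim), "non-negative")
})

test_that("the bundled archetypes give 13 valid augmented curves", {
  curves <- augmented_curve_archetypes(acc_stimuli())
  expect_length(curves, 13L)
  for (cv in curves) {
    expect_equal(nrow(cv), 36L)
    expect_true(all(cv$rate >= 0))
  }
  ## size-selective variants really are size-monotone
  expect_true(all(diff(curves$n3_sizesel$rate[
    curves$n3_sizesel$shape == "cylinder" &
    curves$n3_sizesel$orient_id == 1]) >= 0))
})

test_that("multistart fitting recovers planted cosine-LIF neurons", {
  stim <- acc_stimuli()
  X <- stimulus_features(stim)
  set.seed(42)
  for (i in 1:3) {
    phi <- rnorm(8, sd = 0.8); b <- runif(1, 0.5, 1.5)
    true <- cosine_lif(phi, b, tau_rc = runif(1, 0.02, 0.2))
    r <- neuron_rate(X, true)
    if (max(r) < 5) next
    fit <- fit_cosine_lif(r, X, n_restarts = 200, seed = i)
    expect_lt(sqrt(mean((fit$model_rates - r)^2)), 1e-3)
    ## best-so-far error is non-increasing in the number of restarts
    expect_true(all(diff(fit$best_sse_by_restart) <= 1e-12))
  }
  ## constant curve: bias-only solution, error SD ~ 0
  fc <- fit_cosine_lif(rep(20, 36), X, n_restarts = 50, seed = 1)
  expect_lt(fc$error_sd, 1e-3)
  ## all-zero curve: subthreshold everywhere
  f0 <- fit_cosine_lif(rep(0, 36), X, n_restarts = 20, seed = 1)
  expect_equal(max(f0$model_rates), 0)
  expect_error(fit_cosine_lif(rep(1, 36), X, n_restarts = 0), "n_restarts")
})

test_that("noisy-mode fitting recovers a planted noisy neuron", {
  stim <- acc_stimuli()
  X <- stimulus_features(stim)
  tab <- build_noisy_table(I_grid = seq(-1, 4, 0.1),
                           sigma_grid = seq(0, 1, 0.25),
                           duration = 2, seed = 2)
  true <- cosine_lif(0.5 * c(0.5, -0.3, 0.8, 0.2, -0.6, 0.4, 0.7, -0.2),
                     b = 1.0, tau_rc = 0.02, sigma_noise = 0.5)
  r <- neuron_rate(X, true, tab)
  fit <- fit_cosine_lif(r, X, n_restarts = 100, noise_mode = "on",
                        table = tab, seed = 1)
  expect_lt(sqrt(mean(fit$errors^2)), 0.5)
  ## the noise amplitude is identified along with the tuning
  expect_equal(fit$neuron$sigma_noise, 0.5, tolerance = 0.1)
  expect_error(fit_cosine_lif(r, X, noise_mode = "on"), "table")
})

test_that("size-invariant curves shrink the size components of phi", {
  stim <- acc_stimuli()
  X <- stimulus_features(stim)
  curves <- augmented_curve_archetypes(stim)
  for (nm in c("n3", "n5")) {
    fi <- fit_cosine_lif(curves[[paste0(nm, "_sizeinv")]], X,
                         n_restarts = 200, seed = 1)
    fm <- fit_cosine_lif(curves[[paste0(nm, "_sizesel")]], X,
                         n_restarts = 200, seed = 1)
    ## scale (A) components of the preferred direction are smaller when
    ## the curve carries no size information
    expect_lt(sum(abs(fi$neuron$phi[1:3])), sum(abs(fm$neuron$phi[1:3])))
  }
})

test_that("error statistics and Levene's test match their definitions", {
  f <- structure(list(errors = c(1, -1)), class = "fit_result")
  es <- error_stats(f)
  expect_equal(unname(es["mean"]), 0)
  expect_equal(unname(es["sd"]), sqrt(2))
  ## identical groups: W = 0
  lv0 <- levene_test(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(lv0$W, 0)
  ## oracle equivalence: one-way ANOVA on absolute deviations (car)
  a <- c(1, 2, 3, 4); b <- c(2, 4, 6, 8)
  lv <- levene_test(a, b)
  skip_if_not_installed("car")
  cl <- car::leveneTest(c(a, b), factor(rep(1:2, each = 4)),
                        center = mean)
  expect_equal(lv$W, cl[1, "F value"], tolerance = 1e-10)
  expect_equal(lv$p_value, cl[1, "Pr(>F)"], tolerance = 1e-10)
  ## degrees of freedom for two groups of 456
  set.seed(11)
  lv2 <- levene_test(rnorm(456), rnorm(456, sd = 2))
  expect_equal(lv2$df, c(1, 910))
  expect_error(levene_test(c(1, 1, 1), c(2, 2, 2)), "degenerate")
})
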