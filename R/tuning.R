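#' Augmentation specification for AIP tuning curves
#'
#' Published AIP shape-tuning curves contain only a handful of stimuli —
#' fewer points than even the simplest cosine-tuned model has parameters.
#' Augmented tuning curves extend a measured base rate per shape with
#' extrapolated sizes and orientations consistent with aggregate
#' selectivity statistics: most object-type visual-dominant neurons are
#' orientation selective (roughly Gaussian, fairly narrow tuning), and a
#' majority are size selective with rate increasing monotonically with
#' size.
#'
#' @param size_mode `"invariant"` (all sizes share a rate) or
#'   `"monotone"` (rate increases linearly with the size scale, reaching
#'   the base rate at the largest size).
#' @param orientation_pref_deg preferred pose angle in degrees (0 =
#'   vertical, 90 = horizontal, +/-45 = tilts).
#' @param orientation_sd_deg SD of the Gaussian orientation profile
#'   (default 45, "fairly narrow").
#' @param baseline background rate in spikes/s (default 0).
#' @return An `augmentation_spec`.
#' @export
augmentation_spec <- function(size_mode = c("invariant", "monotone"),
                              orientation_pref_deg = 0,
                              orientation_sd_deg = 45,
                              baseline = 0) {
  size_mode <- match.arg(size_mode)
  stopifnot(baseline >= 0, orientation_sd_deg > 0)
  structure(list(size_mode = size_mode,
                 orientation_pref_deg = orientation_pref_deg,
                 orientation_sd_deg = orientation_sd_deg,
                 baseline = baseline),
            class = "augmentation_spec")
}

## pose-angle difference respecting each base shape's rotational
## symmetry: a sphere looks identical at all poses, a cube repeats every
## 90 degrees, plates and cylinders every 180 degrees.
pose_angle_difference <- function(psi_deg, pref_deg, shape) {
  period <- c(sphere = 0, cube = 90, plate = 180, cylinder = 180)[shape]
  period[is.na(period)] <- 180
  d <- (psi_deg - pref_deg) %% ifelse(period == 0, 360, period)
  d <- pmin(d, ifelse(period == 0, 360, period) - d)
  d[period == 0] <- 0
  d
}

#' Build an augmented tuning curve
#'
#' Combines per-shape base rates with size and orientation factors:
#' `rate = baseline + (base_rate(shape) - baseline) * size_factor *
#' orientation_factor`, clipped at 0. The size factor is 1 for
#' size-invariant curves and `size_scale / max(size_scale)` for
#' size-monotone curves; the orientation factor is a Gaussian in the pose
#' angle (period respecting each shape's symmetry). At the reference
#' (largest) size and preferred orientation the curve reproduces the base
#' rates exactly.
#'
#' @param base_shape_rates named rates (spikes/s, `>= 0`) for `sphere`,
#'   `cube`, `plate`, `cylinder` at reference size/orientation.
#' @param spec an [augmentation_spec()].
#' @param stimuli a `stimulus_set` from [enumerate_stimuli()].
#' @return A `tuning_curve`: the stimulus set with a `rate` column and
#'   the spec stored as an attribute.
#' @export
augment <- function(base_shape_rates, spec, stimuli = enumerate_stimuli()) {
  stopifnot(inherits(spec, "augmentation_spec"))
  need <- unique(stimuli$shape)
  if (!all(need %in% names(base_shape_rates)))
    stop("base_shape_rates must be named for each base shape")
  if (any(base_shape_rates < 0)) stop("base rates must be non-negative")
  pref <- base_shape_rates[stimuli$shape] - spec$baseline
  size_factor <- if (spec$size_mode == "invariant") 1
                 else stimuli$size_scale / max(stimuli$size_scale)
  dpsi <- pose_angle_difference(stimuli$pose_angle_deg,
                                spec$orientation_pref_deg,
                                stimuli$shape)
  ## spheres have no orientation; their factor is 1 by symmetry
  dpsi[stimuli$shape == "sphere"] <- 0
  orient_factor <- exp(-dpsi^2 / (2 * spec$orientation_sd_deg^2))
  rate <- pmax(0, spec$baseline + pref * size_factor * orient_factor)
  out <- stimuli
  out$rate <- as.numeric(rate)
  attr(out, "augmentation") <- spec
  class(out) <- c("tuning_curve", class(stimuli))
  out
}

#' Synthetic augmented tuning-curve archetypes
#'
#' Loads the bundled synthetic base-rate table
#' (`extdata/augmented_curves_synthetic.csv`) describing 13 augmented
#' tuning curves: six neuron archetypes, each in a size-selective and a
#' size-invariant variant, plus one orientation-selective curve that
#' responds equally to plates and cylinders. The base rates are synthetic
#' stand-ins shaped after qualitative descriptions of object-type
#' visual-dominant AIP neurons (e.g. a low-rate neuron, a sharply
#' cylinder-selective neuron, a broadly tuned cylinder-preferring neuron,
#' a plate-and-cylinder neuron); no published values are reproduced.
#'
#' @param stimuli a `stimulus_set`.
#' @return Named list of `tuning_curve` objects.
#' @export
augmented_curve_archetypes <- function(stimuli = enumerate_stimuli()) {
  path <- system.file("extdata", "augmented_curves_synthetic.csv",
                      package = "shapecode", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(tab))) {
    r <- tab[i, ]
    spec <- augmentation_spec(size_mode = r$size_mode,
                              orientation_pref_deg = r$orientation_pref_deg,
                              orientation_sd_deg = r$orientation_sd_deg,
                              baseline = r$baseline)
    rates <- c(sphere = r$sphere, cube = r$cube, plate = r$plate,
               cylinder = r$cylinder)
    out[[r$curve_id]] <- augment(rates, spec, stimuli)
  }
  out
}

## inverse of lif_rate at mid-range tau_rc, used to scale random restarts
lif_current_for_rate <- function(r, tau_ref = 0.005, tau_rc = 0.1) {
  if (r <= 0) return(1)
  denom <- 1 - exp((tau_ref - 1 / r) / tau_rc)
  if (denom <= 0) return(4)
  min(4, 1 / denom)
}

#' Fit a cosine-tuned LIF neuron to a tuning curve
#'
#' Least-squares fit of the cosine-LIF model to target rates by
#' multistart bounded Levenberg-Marquardt. In the default noiseless mode
#' the free parameters are the preferred direction `phi`, bias `b`, and
#' membrane constant `tau_rc` constrained to `[0.02, 0.2]` s. In noisy
#' mode `tau_rc = 0.02` and `tau_ref = 0.005` s are fixed and the noise
#' SD is optimized instead, with rates interpolated from a simulated
#' lookup table. Each restart draws `phi` from a normal with SD set by
#' the target-rate scale, `b` uniform on `[-2, 2]`, and `tau_rc` uniform
#' over its bounds; the best of `n_restarts` local fits is returned.
#'
#' @param rates target rates (spikes/s), one per stimulus. A
#'   `tuning_curve` may be passed; its `rate` column is used.
#' @param features stimulus feature matrix (one row per stimulus), e.g.
#'   [stimulus_features()] or Isomap coordinates.
#' @param n_restarts random restarts (default 200; larger values increase
#'   the chance of finding the global optimum).
#' @param noise_mode `"off"` (deterministic LIF) or `"on"` (noisy LIF via
#'   `table`).
#' @param table a [build_noisy_table()], required for `noise_mode = "on"`.
#' @param tau_ref refractory period, seconds.
#' @param seed RNG seed for the restarts.
#' @return A `fit_result`: fitted `neuron` ([cosine_lif()]),
#'   `model_rates`, `errors` (target - model), `error_mean`, `error_sd`,
#'   `sse`, `n_restarts`, and `best_sse_by_restart` (cumulative best,
#'   non-increasing).
#' @export
fit_cosine_lif <- function(rates, features, n_restarts = 200L,
                           noise_mode = c("off", "on"), table = NULL,
                           tau_ref = 0.005, seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  if (inherits(rates, "tuning_curve")) rates <- rates$rate
  X <- as.matrix(features)
  stopifnot(nrow(X) == length(rates))
  if (n_restarts < 1) stop("n_restarts must be >= 1")
  if (noise_mode == "on" && is.null(table))
    stop("noise_mode = 'on' requires a noisy_rate_table")
  d <- ncol(X)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  model_fun <- if (noise_mode == "off") {
    function(p) {
      I <- as.numeric(X %*% p[1:d] + p[d + 1L])
      lif_rate(I, tau_ref, p[d + 2L])
    }
  } else {
    Imin <- min(table$I_grid); Imax <- max(table$I_grid)
    smin <- min(table$sigma_grid); smax <- max(table$sigma_grid)
    function(p) {
      I <- as.numeric(X %*% p[1:d] + p[d + 1L])
      noisy_rate(pmin(pmax(I, Imin), Imax),
                 pmin(pmax(p[d + 2L], smin), smax), table)
    }
  }
  if (noise_mode == "off") {
    lower <- c(rep(-Inf, d + 1L), 0.02)
    upper <- c(rep(Inf, d + 1L), 0.2)
  } else {
    lower <- c(rep(-Inf, d + 1L), 1e-3)
    upper <- c(rep(Inf, d + 1L), max(table$sigma_grid))
  }

  I_top <- lif_current_for_rate(max(rates), tau_ref)
  phi_sd <- max(0.5, I_top / sqrt(d))

  best <- NULL
  best_trace <- numeric(n_restarts)
  for (k in seq_len(n_restarts)) {
    p0 <- c(stats::rnorm(d, sd = phi_sd), stats::runif(1, -2, 2),
            if (noise_mode == "off") stats::runif(1, 0.02, 0.2)
            else stats::runif(1, 1e-3, max(table$sigma_grid)))
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0,
                         fn = function(p) rates - model_fun(p),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      sse <- sum(fit$fvec^2)
      if (is.null(best) || sse < best$sse)
        best <- list(par = fit$par, sse = sse)
    }
    best_trace[k] <- if (is.null(best)) Inf else best$sse
  }
  p <- best$par
  neuron <- if (noise_mode == "off") {
    cosine_lif(phi = p[1:d], b = p[d + 1L], tau_rc = p[d + 2L],
               tau_ref = tau_ref)
  } else {
    cosine_lif(phi = p[1:d], b = p[d + 1L], tau_rc = table$tau_rc,
               tau_ref = tau_ref, sigma_noise = p[d + 2L])
  }
  model_rates <- model_fun(p)
  errors <- rates - model_rates
  structure(list(neuron = neuron, model_rates = model_rates,
                 errors = errors,
                 error_mean = mean(errors),
                 error_sd = stats::sd(errors),
                 sse = best$sse, n_restarts = as.integer(n_restarts),
                 best_sse_by_restart = best_trace,
                 noise_mode = noise_mode),
            class = "fit_result")
}

#' Mean and SD of tuning-curve fit errors
#'
#' Sample mean and SD (n - 1 denominator) of `target - model` over the
#' grid of shapes, sizes and orientations.
#'
#' @param fit a `fit_result`.
#' @return named numeric `c(mean, sd)`.
#' @export
error_stats <- function(fit) {
  stopifnot(inherits(fit, "fit_result"))
  c(mean = mean(fit$errors), sd = stats::sd(fit$errors))
}

#' Levene's test for equality of variances
#'
#' Classical Levene W: a one-way ANOVA on absolute deviations from the
#' group means, with `W ~ F(k - 1, N - k)` under the null of equal
#' variances.
#'
#' @param ... two or more numeric vectors (groups), or a single list of
#'   them.
#' @return list with `W`, `p_value`, `df` (numerator, denominator).
#' @export
levene_test <- function(...) {
  groups <- list(...)
  if (length(groups) == 1L && is.list(groups[[1L]])) groups <- groups[[1L]]
  if (length(groups) < 2L) stop("need at least two groups")
  if (any(vapply(groups, length, 1L) < 2L))
    stop("each group needs size >= 2")
  dev <- lapply(groups, function(g) abs(g - mean(g)))
  z <- unlist(dev)
  k <- length(groups); N <- length(z)
  zbar <- mean(z)
  zg <- vapply(dev, mean, numeric(1))
  ssb <- sum(lengths(dev) * (zg - zbar)^2)
  ssw <- sum(unlist(lapply(dev, function(d) (d - mean(d))^2)))
  if (ssw <= 0) {
    if (ssb <= 0) stop("degenerate: zero variance of deviations in all groups")
    return(list(W = Inf, p_value = 0, df = c(k - 1, N - k)))
  }
  W <- (ssb / (k - 1)) / (ssw / (N - k))
  list(W = W, p_value = stats::pf(W, k - 1, N - k, lower.tail = FALSE),
       df = c(k - 1, N - k))
}
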