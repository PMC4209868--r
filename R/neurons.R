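#' Cosine-tuned LIF neuron
#'
#' A model neuron whose driving current is the inner product of the
#' stimulus vector with a preferred-direction vector plus a bias,
#' `I = phi' x + b`, passed through the normalized leaky
#' integrate-and-fire rate function (optionally with Gaussian background
#' current noise).
#'
#' @param phi preferred-direction vector (current units per stimulus
#'   unit).
#' @param b bias current (dimensionless, normalized LIF).
#' @param tau_rc membrane time constant, seconds (fitted values are
#'   constrained to `[0.02, 0.2]`).
#' @param tau_ref refractory period, seconds (default 0.005).
#' @param sigma_noise SD of Gaussian background current noise (0 =
#'   noiseless).
#' @return A `cosine_lif` object.
#' @export
cosine_lif <- function(phi, b, tau_rc = 0.02, tau_ref = 0.005,
                       sigma_noise = 0) {
  stopifnot(tau_rc > 0, tau_ref > 0, sigma_noise >= 0)
  structure(list(phi = as.numeric(phi), b = as.numeric(b),
                 tau_rc = tau_rc, tau_ref = tau_ref,
                 sigma_noise = sigma_noise),
            class = "cosine_lif")
}

#' Driving current of a cosine-tuned neuron
#'
#' `I = phi' x + b`.
#'
#' @param x stimulus vector, or a matrix with one stimulus per row.
#' @param neuron a [cosine_lif()].
#' @return current(s) `I`.
#' @export
drive_current <- function(x, neuron) {
  stopifnot(inherits(neuron, "cosine_lif"))
  if (is.matrix(x)) {
    if (ncol(x) != length(neuron$phi))
      stop("dimension mismatch between x and phi")
    as.numeric(x %*% neuron$phi + neuron$b)
  } else {
    if (length(x) != length(neuron$phi))
      stop("dimension mismatch between x and phi")
    sum(neuron$phi * x) + neuron$b
  }
}

#' Normalized LIF rate function
#'
#' `r = 1 / (tau_ref - tau_rc * log(1 - 1/I))` for `I > 1`, and 0 at or
#' below the unit threshold. The rate increases with current and
#' saturates at `1 / tau_ref`.
#'
#' @param I driving current (vectorized).
#' @param tau_ref refractory period, seconds.
#' @param tau_rc membrane time constant, seconds.
#' @return firing rate in spikes/s.
#' @export
lif_rate <- function(I, tau_ref = 0.005, tau_rc = 0.02) {
  stopifnot(tau_ref > 0, tau_rc > 0)
  r <- numeric(length(I))
  sup <- which(I > 1)
  r[sup] <- 1 / (tau_ref - tau_rc * log(1 - 1 / I[sup]))
  r
}

#' Simulated rate lookup table for the noisy LIF model
#'
#' Simulates the normalized LIF (`tau_rc * dV/dt = -V + I + noise`; spike
#' at `V >= 1`, reset to 0, hold for `tau_ref`) on a grid of currents and
#' noise amplitudes by Euler-Maruyama. The Gaussian background current
#' noise is white with amplitude scaled to the membrane time constant so
#' that the stationary SD of the subthreshold potential equals `sigma`
#' (per-step increment `sigma * sqrt(2 * dt / tau_rc)`); this is the
#' scaling under which the noise meaningfully smooths the threshold
#' rather than vanishing as `dt` shrinks. Rates are spike count /
#' duration.
#' [noisy_rate()] interpolates the table bilinearly. With noise the
#' effective rate function smooths from compressive through sigmoidal
#' toward nearly linear, which is why the noisy variant can fit expansive
#' tuning curves that the deterministic model cannot.
#'
#' @param I_grid current grid (monotone; default `seq(0, 4, 0.05)`).
#' @param sigma_grid noise-SD grid (monotone; default `seq(0, 2, 0.1)`).
#' @param dt Euler step, seconds (default 1e-4; must be well below
#'   `tau_rc`).
#' @param duration simulated time per cell, seconds (default 5).
#' @param seed RNG seed.
#' @param tau_rc,tau_ref LIF constants (defaults 0.02 and 0.005 s, the
#'   values fixed during noisy fitting).
#' @return A `noisy_rate_table` with fields `I_grid`, `sigma_grid`,
#'   `rates` (length(I) x length(sigma)), and the simulation parameters.
#' @export
build_noisy_table <- function(I_grid = seq(0, 4, by = 0.05),
                              sigma_grid = seq(0, 2, by = 0.1),
                              dt = 1e-4, duration = 5, seed = 1L,
                              tau_rc = 0.02, tau_ref = 0.005) {
  stopifnot(!is.unsorted(I_grid), !is.unsorted(sigma_grid), dt < tau_rc)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  cells <- expand.grid(I = I_grid, sigma = sigma_grid)
  m <- nrow(cells)
  V <- numeric(m)
  refr <- numeric(m)            # remaining refractory time
  counts <- integer(m)
  n_steps <- round(duration / dt)
  Ic <- cells$I; sg <- cells$sigma
  noisy <- sg > 0
  a <- dt / tau_rc
  noise_amp <- sg * sqrt(2 * a) / a   # per-step, before the a factor
  for (s in seq_len(n_steps)) {
    Inow <- Ic
    if (any(noisy))
      Inow[noisy] <- Inow[noisy] +
        noise_amp[noisy] * stats::rnorm(sum(noisy))
    active <- refr <= 0
    V[active] <- V[active] + a * (Inow[active] - V[active])
    refr[!active] <- refr[!active] - dt
    spk <- active & V >= 1
    counts[spk] <- counts[spk] + 1L
    V[spk] <- 0
    refr[spk] <- tau_ref
  }
  structure(list(I_grid = I_grid, sigma_grid = sigma_grid,
                 rates = matrix(counts / duration, length(I_grid),
                                length(sigma_grid)),
                 dt = dt, duration = duration, seed = as.integer(seed),
                 tau_rc = tau_rc, tau_ref = tau_ref),
            class = "noisy_rate_table")
}

#' Interpolated rate of the noisy LIF model
#'
#' Bilinear interpolation in the simulated lookup table.
#'
#' @param I current(s).
#' @param sigma noise SD(s) (scalar or same length as `I`).
#' @param table a [build_noisy_table()] result.
#' @return rate(s) in spikes/s.
#' @export
noisy_rate <- function(I, sigma, table) {
  stopifnot(inherits(table, "noisy_rate_table"))
  if (length(sigma) == 1L) sigma <- rep(sigma, length(I))
  gi <- table$I_grid; gs <- table$sigma_grid
  if (any(I < gi[1] - 1e-12) || any(I > gi[length(gi)] + 1e-12) ||
      any(sigma < gs[1] - 1e-12) || any(sigma > gs[length(gs)] + 1e-12))
    stop("extrapolation error: query outside the simulated table grid")
  I <- pmin(pmax(I, gi[1]), gi[length(gi)])
  sigma <- pmin(pmax(sigma, gs[1]), gs[length(gs)])
  ii <- pmin(findInterval(I, gi), length(gi) - 1L)
  si <- pmin(findInterval(sigma, gs), length(gs) - 1L)
  fx <- (I - gi[ii]) / (gi[ii + 1L] - gi[ii])
  fy <- (sigma - gs[si]) / (gs[si + 1L] - gs[si])
  r00 <- table$rates[cbind(ii, si)]
  r10 <- table$rates[cbind(ii + 1L, si)]
  r01 <- table$rates[cbind(ii, si + 1L)]
  r11 <- table$rates[cbind(ii + 1L, si + 1L)]
  (1 - fx) * (1 - fy) * r00 + fx * (1 - fy) * r10 +
    (1 - fx) * fy * r01 + fx * fy * r11
}

#' Rate of a cosine-tuned LIF neuron for a stimulus matrix
#'
#' @param x stimulus matrix (one stimulus per row) or vector.
#' @param neuron a [cosine_lif()].
#' @param table optional [build_noisy_table()]; required when
#'   `neuron$sigma_noise > 0`.
#' @return rates in spikes/s.
#' @export
neuron_rate <- function(x, neuron, table = NULL) {
  I <- drive_current(x, neuron)
  if (neuron$sigma_noise > 0) {
    if (is.null(table)) stop("a noisy_rate_table is required when sigma_noise > 0")
    noisy_rate(I, neuron$sigma_noise, table)
  } else {
    lif_rate(I, neuron$tau_ref, neuron$tau_rc)
  }
}

#' Nonlinear dendritic-branch neuron model
#'
#' A receptive-field model in which each of `n_branches` dendritic
#' branches is cosine tuned to a small depth patch: the branch output is
#' a logistic sigmoid of the inner product of the stimulus with the
#' branch's random linear kernel, and the spike rate is a weighted sum of
#' branch outputs. The readout weights are fit by least squares using a
#' truncated-SVD pseudoinverse.
#'
#' @param n_inputs stimulus dimension (e.g. 9 for a 3x3 depth patch).
#' @param n_branches number of branches (default 50).
#' @param seed RNG seed for the standard-normal kernels.
#' @param kernel_sd SD of kernel entries (default 1).
#' @return A `dendritic_model` with zero readout weights (fit with
#'   [fit_dendritic_readout()]).
#' @export
dendritic_model <- function(n_inputs, n_branches = 50L, seed = 1L,
                            kernel_sd = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  K <- matrix(stats::rnorm(n_branches * n_inputs, sd = kernel_sd),
              n_branches, n_inputs)
  structure(list(kernels = K, weights = numeric(n_branches),
                 n_singular = NA_integer_),
            class = "dendritic_model")
}

## branch outputs for a stimulus matrix (n_stimuli x n_inputs)
dendritic_branch_outputs <- function(X, model) {
  1 / (1 + exp(-(X %*% t(model$kernels))))
}

#' Response of the dendritic-branch model
#'
#' @param stimulus numeric vector (e.g. a flattened 3x3 depth patch) or a
#'   matrix with one stimulus per row.
#' @param model a [dendritic_model()].
#' @param rectify clip negative rates at 0 for reporting (default TRUE).
#' @return rate(s) in spikes/s.
#' @export
dendritic_response <- function(stimulus, model, rectify = TRUE) {
  X <- if (is.matrix(stimulus)) stimulus else matrix(stimulus, nrow = 1L)
  r <- as.numeric(dendritic_branch_outputs(X, model) %*% model$weights)
  if (rectify) r <- pmax(r, 0)
  r
}

#' Fit the dendritic readout by truncated-SVD pseudoinverse
#'
#' Solves the least-squares problem for the branch readout weights,
#' retaining exactly `n_singular` singular values in the pseudoinverse.
#'
#' @param stimuli stimulus matrix (one per row).
#' @param target_rates target spike rates (one per stimulus).
#' @param model a [dendritic_model()].
#' @param n_singular retained singular values (typical values 14, 20,
#'   40); must not exceed `min(#stimuli, n_branches)`.
#' @return The model with fitted `weights` and `n_singular` recorded.
#' @export
fit_dendritic_readout <- function(stimuli, target_rates, model,
                                  n_singular = 14L) {
  stopifnot(inherits(model, "dendritic_model"))
  B <- dendritic_branch_outputs(stimuli, model)
  if (n_singular > min(nrow(B), ncol(B)))
    stop("n_singular exceeds min(#stimuli, n_branches)")
  if (nrow(B) < n_singular)
    stop("need at least n_singular stimuli")
  sv <- svd(B)
  k <- seq_len(n_singular)
  model$weights <- as.numeric(sv$v[, k, drop = FALSE] %*%
                              ((t(sv$u[, k, drop = FALSE]) %*% target_rates) /
                               sv$d[k]))
  model$n_singular <- as.integer(n_singular)
  model
}

#' Fit linear population decoders (NEF)
#'
#' Finds the decoding matrix `Phi` minimizing the regularized squared
#' error of the linear parameter estimate `p_hat = Phi r_pre` from
#' presynaptic rates. Ridge regularization uses
#' `lambda = reg * mean(diag(Gram))`, the standard noise term of
#' population decoding.
#'
#' @param rates population rate matrix (one stimulus per row, one neuron
#'   per column).
#' @param targets parameter matrix (one stimulus per row).
#' @param reg regularization fraction (default 0.1).
#' @return A `decoder_set` with matrix `Phi` (`d x n_neurons`).
#' @export
fit_decoders <- function(rates, targets, reg = 0.1) {
  targets <- as.matrix(targets)
  G <- crossprod(rates)                   # n x n Gram
  lambda <- reg * mean(diag(G))
  if (lambda <= 0) lambda <- 1e-8
  Phi <- t(solve(G + lambda * diag(nrow(G)), crossprod(rates, targets)))
  structure(list(Phi = Phi, lambda = lambda), class = "decoder_set")
}

#' Decode parameter estimates from rates
#'
#' @param decoders a [fit_decoders()] result.
#' @param rates rate matrix (stimuli x neurons) or vector.
#' @return decoded estimates (stimuli x d).
#' @export
decode <- function(decoders, rates) {
  r <- if (is.matrix(rates)) rates else matrix(rates, nrow = 1L)
  r %*% t(decoders$Phi)
}

#' Compose synaptic weights from a preferred direction and decoders
#'
#' The cosine tuning `G(phi' p_hat + b)` over decoded parameters
#' `p_hat = Phi r_pre` is realized exactly by direct synaptic weights
#' `w' = phi' Phi`, i.e. `w' r_pre = phi' (Phi r_pre)` identically.
#'
#' @param phi preferred-direction vector in parameter space (length d).
#' @param Phi decoding matrix (`d x n_neurons`) or a `decoder_set`.
#' @return weight vector of length `n_neurons`.
#' @export
compose_weights <- function(phi, Phi) {
  if (inherits(Phi, "decoder_set")) Phi <- Phi$Phi
  stopifnot(length(phi) == nrow(Phi))
  as.numeric(crossprod(matrix(phi, ncol = 1L), Phi))
}
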