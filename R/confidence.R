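#' Confidence-pipeline configuration
#'
#' Bundles the parameters of the confidence-regularization machinery:
#'
#' * `beta_noise` — stochastic scaling factor for injected confidence noise
#'   (default 0.2); 0 disables noise.
#' * `noise_base_sd` — base standard deviation of the noise before scaling
#'   by `beta_noise` (default 0.05), so the injected noise has sd
#'   `beta_noise * noise_base_sd`.
#' * `lambda_complexity` — feature complexity normalizer (default 20):
#'   confidences of longer features are shrunk as `c^(1 + tokens/lambda)`.
#' * `alpha_feedback` — EMA coefficient of the cross-epoch confidence
#'   feedback loop (default 0.7; weight on the previous epoch's estimate).
#' * `tau_init`, `tau_final` — endpoints of the dynamic confidence
#'   threshold schedule (defaults 0.6 and 0.7).
#' * `clip_eps` — confidences are clipped to `[clip_eps, 1 - clip_eps]`
#'   after noise injection (default 1e-4).
#' * `use_geometric_mean` — aggregate token probabilities by geometric mean
#'   (default `TRUE`); arithmetic mean available for sensitivity analysis.
#' * `f1_coupled_threshold` — couple the threshold to the prior epoch's F1
#'   instead of the epoch index (default `FALSE`, linear-in-epoch).
#'
#' @param beta_noise,noise_base_sd,lambda_complexity,alpha_feedback,tau_init,tau_final,clip_eps,seed,use_geometric_mean,f1_coupled_threshold See above.
#' @return A list of class `confidence_config`.
#' @export
confidence_config <- function(beta_noise = 0.2,
                              noise_base_sd = 0.05,
                              lambda_complexity = 20,
                              alpha_feedback = 0.7,
                              tau_init = 0.6,
                              tau_final = 0.7,
                              clip_eps = 1e-4,
                              seed = 1L,
                              use_geometric_mean = TRUE,
                              f1_coupled_threshold = FALSE) {
  stopifnot(
    beta_noise >= 0, lambda_complexity > 0,
    alpha_feedback >= 0, alpha_feedback <= 1,
    tau_init <= tau_final, clip_eps > 0, clip_eps < 0.5
  )
  structure(
    list(
      beta_noise = beta_noise, noise_base_sd = noise_base_sd,
      lambda_complexity = lambda_complexity, alpha_feedback = alpha_feedback,
      tau_init = tau_init, tau_final = tau_final, clip_eps = clip_eps,
      seed = as.integer(seed), use_geometric_mean = use_geometric_mean,
      f1_coupled_threshold = f1_coupled_threshold
    ),
    class = "confidence_config"
  )
}

#' Epoch state for the training loop
#'
#' Tracks where training stands: the current epoch, the total number of
#' epochs, the previous epoch's F1 (drives the F1-coupled threshold
#' variant), and the EMA-smoothed mean confidence.
#'
#' @param epoch_index 0-based epoch index, `< total_epochs`.
#' @param total_epochs Total number of epochs, >= 1.
#' @param prev_f1 Previous epoch's F1 in \[0,1\], or `NA` before epoch 1.
#' @param smoothed_confidence EMA-smoothed confidence, or `NA` initially.
#' @return A list of class `epoch_state`.
#' @export
epoch_state <- function(epoch_index = 0L, total_epochs = 5L,
                        prev_f1 = NA_real_, smoothed_confidence = NA_real_) {
  stopifnot(total_epochs >= 1L, epoch_index >= 0L, epoch_index < total_epochs)
  structure(
    list(
      epoch_index = as.integer(epoch_index),
      total_epochs = as.integer(total_epochs),
      prev_f1 = prev_f1, smoothed_confidence = smoothed_confidence
    ),
    class = "epoch_state"
  )
}

#' Aggregate token probabilities into a feature confidence
#'
#' The per-feature confidence is the geometric mean of the token-level
#' probabilities, `exp(mean(log p))` — simultaneously an average and a
#' length normalization, since the score of a constant-probability sequence
#' does not depend on its length. An arithmetic mean is available for
#' sensitivity analysis.
#'
#' @param token_probs Non-empty numeric vector with values in (0, 1\].
#' @param use_geometric_mean Use the geometric (default) or arithmetic mean.
#' @return A confidence in (0, 1\].
#' @export
#' @examples
#' aggregate_confidence(c(0.9, 0.9, 0.9))  # 0.9
#' aggregate_confidence(c(0.5, 0.125))     # 0.25
aggregate_confidence <- function(token_probs, use_geometric_mean = TRUE) {
  if (length(token_probs) == 0L || any(!is.finite(token_probs)) ||
    any(token_probs <= 0) || any(token_probs > 1)) {
    stop("token_probs must be a non-empty vector with values in (0, 1]",
      call. = FALSE
    )
  }
  if (use_geometric_mean) {
    exp(mean(log(token_probs)))
  } else {
    mean(token_probs)
  }
}

#' Shrink confidence by feature complexity
#'
#' Longer features are harder to extract exactly, so their raw confidence is
#' shrunk as `c^(1 + count / lambda)`: identity at zero tokens, a fixed
#' point at c = 1, monotone in both arguments, and range-preserving on
#' (0, 1\]. With the default `lambda = 20`, a 20-token feature at c = 0.9 is
#' adjusted to 0.81.
#'
#' @param c Raw confidence in (0, 1\].
#' @param feature_token_count Number of tokens in the feature text, >= 0.
#' @param lambda_complexity Complexity normalizer, > 0 (default 20).
#' @return Adjusted confidence in (0, 1\].
#' @export
complexity_adjust <- function(c, feature_token_count, lambda_complexity = 20) {
  stopifnot(c > 0, c <= 1, feature_token_count >= 0)
  if (lambda_complexity <= 0) {
    stop("lambda_complexity must be > 0", call. = FALSE)
  }
  c^(1 + feature_token_count / lambda_complexity)
}

#' Inject controlled stochastic noise into a confidence
#'
#' Adds seeded Gaussian noise `beta_noise * noise_base_sd * z` to the
#' confidence and clips to `[clip_eps, 1 - clip_eps]`. The noise prevents
#' confidence collapse during training; it is the identity when
#' `beta_noise = 0` (and should be disabled at inference). Uses the current
#' RNG stream, so seeding is controlled by the caller (or [run_epoch()]).
#'
#' @param c Confidence(s) in \[0, 1\] (vectorized).
#' @param cfg A [confidence_config()].
#' @return Noisy clipped confidence(s).
#' @export
inject_noise <- function(c, cfg = confidence_config()) {
  if (cfg$beta_noise == 0) {
    return(c)
  }
  z <- stats::rnorm(length(c))
  pmin(pmax(c + cfg$beta_noise * cfg$noise_base_sd * z, cfg$clip_eps), 1 - cfg$clip_eps)
}

#' Dynamic confidence threshold schedule
#'
#' The overconfidence threshold tau rises across training, curriculum-style,
#' from `tau_init` (default 0.6) to `tau_final` (default 0.7). Two modes:
#'
#' * linear (default): `tau = tau_init + (tau_final - tau_init) *
#'   epoch_index / (total_epochs - 1)`, monotone non-decreasing in the
#'   epoch; a single-epoch run uses `tau_final`.
#' * F1-coupled (`cfg$f1_coupled_threshold = TRUE`, requires
#'   `state$prev_f1`): `tau = tau_init + (tau_final - tau_init) * prev_f1`,
#'   clipped to `[tau_init, tau_final]`.
#'
#' @param state An [epoch_state()].
#' @param cfg A [confidence_config()].
#' @return The threshold tau in `[tau_init, tau_final]`.
#' @export
dynamic_threshold <- function(state, cfg = confidence_config()) {
  span <- cfg$tau_final - cfg$tau_init
  if (cfg$f1_coupled_threshold && !is.na(state$prev_f1)) {
    tau <- cfg$tau_init + span * state$prev_f1
  } else if (state$total_epochs == 1L) {
    tau <- cfg$tau_final
  } else {
    tau <- cfg$tau_init + span * state$epoch_index / (state$total_epochs - 1L)
  }
  min(max(tau, cfg$tau_init), cfg$tau_final)
}

#' Cross-epoch confidence feedback (EMA smoothing)
#'
#' Smooths confidence estimates across epochs to stabilize training:
#' `alpha * prev + (1 - alpha) * current`, initialized at `current` when no
#' previous value exists. The default `alpha = 0.7` weights history.
#'
#' @param prev Previous smoothed value in \[0,1\], or `NA` to initialize.
#' @param current Current epoch's value in \[0,1\].
#' @param alpha_feedback Feedback coefficient in \[0,1\] (default 0.7).
#' @return The smoothed value.
#' @export
#' @examples
#' ema_feedback(0.8, 0.6, 0.7)  # 0.74
ema_feedback <- function(prev, current, alpha_feedback = 0.7) {
  stopifnot(current >= 0, current <= 1, alpha_feedback >= 0, alpha_feedback <= 1)
  if (is.na(prev)) {
    return(current)
  }
  alpha_feedback * prev + (1 - alpha_feedback) * current
}

#' Full confidence pipeline for one extraction
#'
#' Aggregates token probabilities (geometric mean), applies the complexity
#' adjustment for the feature's token count, and optionally injects noise
#' (training only). With noise disabled the pipeline is deterministic.
#'
#' @param token_probs Token probabilities in (0, 1\].
#' @param feature_token_count Token count of the extracted text.
#' @param cfg A [confidence_config()].
#' @param training If `TRUE`, inject noise per `cfg`; default `FALSE`.
#' @return A confidence in (0, 1).
#' @export
feature_confidence <- function(token_probs, feature_token_count,
                               cfg = confidence_config(), training = FALSE) {
  c0 <- aggregate_confidence(token_probs, cfg$use_geometric_mean)
  c1 <- complexity_adjust(c0, feature_token_count, cfg$lambda_complexity)
  if (training) {
    c1 <- inject_noise(c1, cfg)
  }
  c1
}
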