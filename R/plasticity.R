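#' Eligibility-trace update
#'
#' Per-synapse memory of recent pre/post spike coincidences. The
#' continuous-time trace dynamics (decay with time constant `tau_e`,
#' potentiation when the post-synaptic neuron fires one step after the
#' pre-synaptic one, depression scaled by `f` for the reverse order) are
#' discretized by one forward-Euler step of unit size, matching the
#' network's discrete clock:
#'
#'   e' = e (1 - 1/tau_e) + s_post(t) s_pre(t-1) - f s_post(t-1) s_pre(t)
#'
#' @param e Trace matrix (post x pre).
#' @param s_post_now,s_post_prev Binary post-synaptic states at t and t-1.
#' @param s_pre_now,s_pre_prev Binary pre-synaptic states at t and t-1.
#' @param tau_e Time constant (> 1).
#' @param f Depression factor.
#' @param mask Optional binary mask; off-mask entries are forced to 0.
#' @return Updated trace matrix.
#' @export
update_eligibility <- function(e, s_post_now, s_post_prev, s_pre_now,
                               s_pre_prev, tau_e, f, mask = NULL) {
  if (tau_e <= 1)
    stop("tau_e must exceed 1: per-step decay factor would be <= 0",
         call. = FALSE)
  if (nrow(e) != length(s_post_now) || ncol(e) != length(s_pre_now))
    stop("trace matrix shape does not match the state vectors", call. = FALSE)
  e <- e * (1 - 1 / tau_e) +
    outer(s_post_now, s_pre_prev) - f * outer(s_post_prev, s_pre_now)
  if (!is.null(mask)) e <- e * mask
  e
}

#' Reward-gated weight update
#'
#' Converts eligibility into a weight change only when the reward deviates
#' from its baseline: `w' = w + eta * m * e` with neuromodulation factor
#' `m = r - b`. Weights are floored at zero (they are non-negative
#' throughout the model and the afferent normalization requires it), and
#' entries off the connectivity mask stay exactly zero.
#'
#' @param w Weight matrix.
#' @param e Eligibility-trace matrix of the same shape.
#' @param m Neuromodulation factor (reward minus baseline).
#' @param eta Learning rate.
#' @param mask Optional binary mask of existing connections.
#' @return Updated weight matrix.
#' @export
apply_reward <- function(w, e, m, eta, mask = NULL) {
  if (!all(dim(w) == dim(e)))
    stop("weights and eligibility traces differ in shape", call. = FALSE)
  w2 <- pmax(w + eta * m * e, 0)
  if (!is.null(mask)) w2 <- w2 * mask
  w2
}

#' Synaptic normalization
#'
#' Scales every afferent row with a positive sum so that it sums to 1,
#' inducing competition among the synapses converging on one neuron.
#' All-zero rows (neurons with no afferents) are left untouched.
#'
#' @param w Non-negative weight matrix.
#' @return Row-normalized matrix.
#' @export
normalize_rows <- function(w) {
  if (any(w < 0)) stop("negative weights cannot be normalized", call. = FALSE)
  rs <- rowSums(w)
  scale <- ifelse(rs > 0, 1 / rs, 1)
  w * scale
}

#' Intrinsic plasticity
#'
#' Threshold homeostasis toward a target firing rate: a neuron that fired
#' raises its threshold, a silent one lowers it, so the long-run rate
#' drifts to `mu_ip`:
#'
#'   theta' = theta + eta_ip (s - mu_ip)
#'
#' Applied to recurrent excitatory thresholds (scalar target) and to output
#' thresholds (per-neuron targets equal to the coded symbol's frequency);
#' inhibitory thresholds are never adapted.
#'
#' @param theta Threshold vector.
#' @param s Binary state vector.
#' @param mu_ip Target rate, scalar or one per neuron.
#' @param eta_ip Learning rate.
#' @return Updated thresholds.
#' @export
intrinsic_update <- function(theta, s, mu_ip, eta_ip) {
  if (length(theta) != length(s))
    stop("threshold and state vectors differ in length", call. = FALSE)
  theta + eta_ip * (s - mu_ip)
}

#' Structural plasticity step
#'
#' Prunes every existing connection whose weight has fallen below `w_th`
#' and grows new connections on currently unconnected off-diagonal pairs,
#' each independently with probability `p_sp`, at initial weight `w_new`.
#' Growth candidates are the pairs unconnected *before* the call, so a
#' connection pruned in this call cannot regrow in the same call. Applied
#' to the excitatory-to-excitatory synapses only.
#'
#' Uses the R random number generator; seed via [set.seed()].
#'
#' @param mask Binary connectivity matrix with zero diagonal.
#' @param w Weight matrix consistent with `mask`.
#' @param p_sp Growth probability per unconnected pair.
#' @param w_th Pruning threshold.
#' @param w_new Weight assigned to newborn connections (`> w_th`).
#' @param t Step stamp recorded in the event log.
#' @return List with updated `mask`, `w`, and `events`, a data frame with
#'   columns `t`, `kind` ("birth"/"death"), `i`, `j`, `w` (weight at death,
#'   `w_new` at birth).
#' @export
structural_step <- function(mask, w, p_sp, w_th, w_new, t = 0L) {
  if (any(diag(mask) != 0)) stop("mask has self-connections", call. = FALSE)
  if (w_th >= w_new)
    stop("w_th must be smaller than w_new", call. = FALSE)
  n <- nrow(mask)

  prune <- mask == 1 & w < w_th
  grow_candidates <- mask == 0
  diag(grow_candidates) <- FALSE

  deaths <- which(prune, arr.ind = TRUE)
  ev_death <- data.frame(t = rep(t, nrow(deaths)),
                         kind = rep("death", nrow(deaths)),
                         i = deaths[, 1], j = deaths[, 2],
                         w = w[prune])
  mask[prune] <- 0
  w[prune] <- 0

  rnd <- matrix(stats::runif(n * n), n, n)
  grow <- grow_candidates & rnd > 1 - p_sp
  births <- which(grow, arr.ind = TRUE)
  ev_birth <- data.frame(t = rep(t, nrow(births)),
                         kind = rep("birth", nrow(births)),
                         i = births[, 1], j = births[, 2],
                         w = rep(w_new, nrow(births)))
  mask[grow] <- 1
  w[grow] <- w_new

  events <- rbind(ev_death, ev_birth)
  rownames(events) <- NULL
  list(mask = mask, w = w, events = events)
}

#' Reward-baseline update
#'
#' The baseline is the exponential moving average of the reward,
#' `b' = (1 - alpha) b + alpha r`; the neuromodulation factor is the
#' deviation of the instantaneous reward from this baseline.
#'
#' @param b Current baseline.
#' @param r Instantaneous reward.
#' @param alpha Averaging coefficient in (0,1).
#' @return Updated baseline.
#' @export
update_baseline <- function(b, r, alpha) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)", call. = FALSE)
  (1 - alpha) * b + alpha * r
}
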