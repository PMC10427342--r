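#' Network configuration
#'
#' Builds and validates the full hyperparameter set for one network.
#' The inhibitory population is always 20% of the excitatory one
#' (`n_inhibitory = round(0.2 * n_excitatory)`) and is therefore derived,
#' not supplied.
#'
#' @param n_excitatory Number of excitatory neurons in the recurrent layer.
#' @param symbols Character vector of task symbols; one output neuron is
#'   created per symbol.
#' @param p_c Initial excitatory-to-excitatory connection fraction, in (0,1).
#' @param n_input_subset Number of excitatory neurons driven by each input
#'   symbol. Subsets for distinct symbols are disjoint. Default: 5% of the
#'   excitatory population (at least 10). The subsets anchor the recurrent
#'   dynamics to the task period, so their size must scale with the
#'   network for the entrainment to stay equally strong.
#' @param mu_ip Target firing rate for recurrent excitatory neurons, in
#'   `[0.05, 0.25]`.
#' @param mu_ip_output Per-output-neuron target firing rates. Each output
#'   neuron should fire at the stationary frequency of the symbol it codes
#'   for; if `NULL` the rates are filled in from the task when training
#'   starts.
#' @param eta Learning rate of the reward-modulated update of the
#'   recurrent E-E weights.
#' @param eta_oe Learning rate of the reward-modulated update of the
#'   readout weights; defaults to `eta`. Exposed separately because the
#'   two rates play different roles: readout updates do not feed back into
#'   the network state, whereas recurrent updates reshape the very orbit
#'   the readout is trying to decode.
#' @param eta_ip Learning rate of the intrinsic (threshold) plasticity.
#' @param tau_e Eligibility-trace time constant in steps; must exceed 1 so
#'   the per-step decay factor `1 - 1/tau_e` is positive. With a reward
#'   delivered every step, the trace must stay short relative to the task
#'   period or credit smears across the whole subsequence and potentiation
#'   at rewarded steps is cancelled by depression at later unrewarded ones.
#' @param f_ee,f_oe Dimensionless depression factors of the trace update for
#'   recurrent and output synapses (1 and 0.01 respectively).
#' @param p_sp Per-pair growth probability of structural plasticity.
#' @param w_th Pruning threshold: an existing connection whose weight falls
#'   below this is removed.
#' @param w_new Initial weight of a newly grown connection; must exceed
#'   `w_th` or every new synapse would be pruned immediately.
#' @param reward_incorrect Reward for an incorrect prediction: 0 or -1.
#'   The default 0 keeps the error signal proportional to the recent
#'   success rate; the -1 scheme punishes errors harder, which speeds up
#'   easy tasks but churns the recurrent layer too strongly on hard ones.
#' @param baseline_alpha Coefficient of the exponential moving-average
#'   reward baseline, in (0,1).
#' @param theta_e_range,theta_in_range,theta_o_range Intervals from which
#'   excitatory, inhibitory and output thresholds are drawn uniformly at
#'   initialization.
#' @param seed Integer seed governing all randomness of the run.
#'
#' @return A list of class `"sorn_config"`.
#' @export
sorn_config <- function(n_excitatory = 200,
                        symbols = c("a", "b", "c"),
                        p_c = 0.05,
                        n_input_subset = NULL,
                        mu_ip = 0.1,
                        mu_ip_output = NULL,
                        eta = 0.005,
                        eta_oe = NULL,
                        eta_ip = 0.001,
                        tau_e = 2,
                        f_ee = 1,
                        f_oe = 0.01,
                        p_sp = 3e-6,
                        w_th = 1e-4,
                        w_new = 0.001,
                        reward_incorrect = 0,
                        baseline_alpha = 0.05,
                        theta_e_range = c(0, 0.5),
                        theta_in_range = c(0, 1),
                        theta_o_range = c(0, 0.5),
                        seed = 1L) {
  if (is.null(n_input_subset))
    n_input_subset <- max(10L, as.integer(round(n_excitatory / 20)))
  cfg <- list(
    n_excitatory = as.integer(n_excitatory),
    n_inhibitory = as.integer(round(0.2 * n_excitatory)),
    symbols = as.character(symbols),
    n_output = length(symbols),
    p_c = p_c,
    n_input_subset = as.integer(n_input_subset),
    mu_ip = mu_ip,
    mu_ip_output = mu_ip_output,
    eta = eta,
    eta_oe = if (is.null(eta_oe)) eta else eta_oe,
    eta_ip = eta_ip,
    tau_e = tau_e,
    f_ee = f_ee,
    f_oe = f_oe,
    p_sp = p_sp,
    w_th = w_th,
    w_new = w_new,
    reward_incorrect = reward_incorrect,
    baseline_alpha = baseline_alpha,
    theta_e_range = theta_e_range,
    theta_in_range = theta_in_range,
    theta_o_range = theta_o_range,
    seed = as.integer(seed)
  )
  class(cfg) <- "sorn_config"
  validate_config(cfg)
  cfg
}

#' @keywords internal
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  fail <- function(msg) stop("invalid configuration: ", msg, call. = FALSE)
  if (cfg$n_excitatory < 1) fail("n_excitatory must be positive")
  if (cfg$n_inhibitory != as.integer(round(0.2 * cfg$n_excitatory)))
    fail("n_inhibitory must equal round(0.2 * n_excitatory)")
  if (cfg$n_output < 1) fail("at least one task symbol is required")
  if (anyDuplicated(cfg$symbols)) fail("symbols must be distinct")
  if (!(cfg$p_c > 0 && cfg$p_c < 1)) fail("p_c must lie in (0, 1)")
  if (cfg$n_input_subset < 1) fail("n_input_subset must be positive")
  if (cfg$n_output * cfg$n_input_subset > cfg$n_excitatory)
    fail("input subsets do not fit: n_symbols * n_input_subset > n_excitatory")
  if (cfg$mu_ip < 0.05 || cfg$mu_ip > 0.25)
    fail("mu_ip must lie in [0.05, 0.25]")
  if (!is.null(cfg$mu_ip_output) &&
      length(cfg$mu_ip_output) != cfg$n_output)
    fail("mu_ip_output must have one rate per output neuron")
  if (cfg$eta <= 0) fail("eta must be positive")
  if (cfg$eta_oe <= 0) fail("eta_oe must be positive")
  if (cfg$eta_ip <= 0) fail("eta_ip must be positive")
  if (cfg$tau_e <= 1) fail("tau_e must exceed 1 (decay factor 1 - 1/tau_e would be <= 0)")
  if (!(cfg$p_sp > 0 && cfg$p_sp < 1)) fail("p_sp must lie in (0, 1)")
  if (!(cfg$w_th > 0 && cfg$w_th < 1)) fail("w_th must lie in (0, 1)")
  if (cfg$w_th >= cfg$w_new)
    fail("w_th must be smaller than w_new (new connections would be pruned immediately)")
  if (!cfg$reward_incorrect %in% c(0, -1))
    fail("reward_incorrect must be 0 or -1")
  if (!(cfg$baseline_alpha > 0 && cfg$baseline_alpha < 1))
    fail("baseline_alpha must lie in (0, 1)")
  for (nm in c("theta_e_range", "theta_in_range", "theta_o_range")) {
    r <- cfg[[nm]]
    if (length(r) != 2 || r[1] >= r[2]) fail(paste(nm, "must be an increasing interval"))
  }
  invisible(cfg)
}

#' Training protocol
#'
#' Step counts of the two-stage alternating training scheme. In every
#' alternation the network first runs `stage1_steps` with all plasticity
#' rules active on the recurrent and output synapses, then `stage2_steps`
#' during which the recurrent layer (weights, mask, thresholds) is frozen
#' and only the readout weights and output thresholds keep adapting.
#'
#' @param stage1_steps Steps of the first (full-plasticity) stage.
#' @param stage2_steps Steps of the second (readout fine-tuning) stage.
#' @param alternations Number of stage-1/stage-2 alternations.
#' @param eval_steps Steps used by [infer()] / [evaluate_network()].
#' @param plasticity Named logical flags enabling individual rules, used
#'   for ablations. Names: `rstdp_ee`, `rstdp_oe`, `sn`, `ip_e`, `ip_o`,
#'   `sp`.
#' @return A list of class `"sorn_protocol"`.
#' @export
sorn_protocol <- function(stage1_steps = 100,
                          stage2_steps = 20000,
                          alternations = 200,
                          eval_steps = 1000,
                          plasticity = NULL) {
  toggles <- list(rstdp_ee = TRUE, rstdp_oe = TRUE, sn = TRUE,
                  ip_e = TRUE, ip_o = TRUE, sp = TRUE)
  if (!is.null(plasticity)) {
    unknown <- setdiff(names(plasticity), names(toggles))
    if (length(unknown))
      stop("unknown plasticity toggle(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    toggles[names(plasticity)] <- plasticity
  }
  p <- list(stage1_steps = as.integer(stage1_steps),
            stage2_steps = as.integer(stage2_steps),
            alternations = as.integer(alternations),
            eval_steps = as.integer(eval_steps),
            plasticity = toggles)
  if (p$stage1_steps < 0 || p$stage2_steps < 0 || p$alternations < 0 ||
      p$eval_steps < 1)
    stop("protocol step counts must be non-negative (eval_steps positive)",
         call. = FALSE)
  class(p) <- "sorn_protocol"
  p
}
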