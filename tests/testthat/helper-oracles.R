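# Independent brute-force oracles used to cross-check the vectorized
# implementations and the C++ engine. Everything here is written as plain
# double loops over scalars, on purpose.

naive_heaviside <- function(x) if (x >= 0) 1 else 0

# One recurrent update, scalar loops: inhibitory layer responds to the
# pre-step excitatory state first, then the excitatory update subtracts
# that same-step inhibitory response.
naive_step_recurrent <- function(s_e, s_in, w_ee, w_ei, w_ie,
                                 theta_e, theta_in, u) {
  ne <- length(s_e); ni <- length(s_in)
  s_in_new <- numeric(ni)
  for (i in seq_len(ni)) {
    acc <- 0
    for (j in seq_len(ne)) acc <- acc + w_ie[i, j] * s_e[j]
    s_in_new[i] <- naive_heaviside(acc - theta_in[i])
  }
  s_e_new <- numeric(ne)
  for (i in seq_len(ne)) {
    acc <- u[i] - theta_e[i]
    for (j in seq_len(ne)) acc <- acc + w_ee[i, j] * s_e[j]
    for (j in seq_len(ni)) acc <- acc - w_ei[i, j] * s_in_new[j]
    s_e_new[i] <- naive_heaviside(acc)
  }
  list(s_e = s_e_new, s_in = s_in_new)
}

naive_step_output <- function(s_e, w_oe, theta_o) {
  no <- nrow(w_oe)
  pot <- numeric(no); st <- numeric(no)
  for (q in seq_len(no)) {
    acc <- -theta_o[q]
    for (j in seq_along(s_e)) acc <- acc + w_oe[q, j] * s_e[j]
    pot[q] <- acc
    st[q] <- naive_heaviside(acc)
  }
  list(states = st, potentials = pot)
}

naive_eligibility <- function(e, post_now, post_prev, pre_now, pre_prev,
                              tau_e, f, mask = NULL) {
  out <- e
  for (i in seq_len(nrow(e))) for (j in seq_len(ncol(e))) {
    out[i, j] <- e[i, j] * (1 - 1 / tau_e) +
      post_now[i] * pre_prev[j] - f * post_prev[i] * pre_now[j]
    if (!is.null(mask) && mask[i, j] == 0) out[i, j] <- 0
  }
  out
}

naive_normalize <- function(w) {
  out <- w
  for (i in seq_len(nrow(w))) {
    rs <- 0
    for (j in seq_len(ncol(w))) rs <- rs + w[i, j]
    if (rs > 0) for (j in seq_len(ncol(w))) out[i, j] <- w[i, j] / rs
  }
  out
}

# A small random network bundle for oracle comparisons.
random_tiny_network <- function(seed, ne = 6, symbols = c("a", "b", "c"),
                                n_input_subset = 2, p_c = 0.5) {
  cfg <- sorn_config(n_excitatory = ne, symbols = symbols, p_c = p_c,
                     n_input_subset = n_input_subset, seed = seed)
  init_network(cfg)
}

# One full plastic step composed from the package's R-level operations in
# the documented order, mirroring the engine with structural plasticity
# disabled. Used to cross-check the C++ training step.
r_reference_step <- function(net, in_idx, mu_o, toggles, reward_mode = 1) {
  cfg <- net$config
  old_se <- net$s_e; old_so <- net$s_o
  out <- step_output(net)        # from pre-step s_e
  pred <- which.max(out$potentials)
  # the output layer competes winner-take-all: the emitted symbol's neuron
  # is the one treated as active in the plasticity updates
  so_new <- as.numeric(seq_len(cfg$n_output) == pred)
  u <- if (in_idx > 0)
    encode_input(cfg$symbols[in_idx], net$input_map, cfg$n_excitatory)
  else numeric(cfg$n_excitatory)
  net <- step_recurrent(net, u = u)
  net$s_o <- so_new

  r <- if (reward_mode == 1) {
    if (in_idx > 0 && pred == in_idx) 1 else cfg$reward_incorrect
  } else NA_real_

  if (toggles$rstdp_ee)
    net$e_ee <- update_eligibility(net$e_ee, net$s_e, old_se, net$s_e,
                                   old_se, cfg$tau_e, cfg$f_ee,
                                   mask = net$c_ee)
  if (toggles$rstdp_oe)
    net$e_oe <- update_eligibility(net$e_oe, so_new, old_so, net$s_e,
                                   old_se, cfg$tau_e, cfg$f_oe)
  m <- r - net$baseline
  net$baseline <- update_baseline(net$baseline, r, cfg$baseline_alpha)
  if (toggles$rstdp_ee && m != 0)
    net$w_ee <- apply_reward(net$w_ee, net$e_ee, m, cfg$eta,
                             mask = net$c_ee)
  if (toggles$rstdp_oe && m != 0)
    net$w_oe <- apply_reward(net$w_oe, net$e_oe, m, cfg$eta_oe)
  if (toggles$sn && toggles$rstdp_ee) net$w_ee <- normalize_rows(net$w_ee)
  if (toggles$sn && toggles$rstdp_oe) net$w_oe <- normalize_rows(net$w_oe)
  if (toggles$ip_e)
    net$theta_e <- intrinsic_update(net$theta_e, net$s_e, cfg$mu_ip,
                                    cfg$eta_ip)
  if (toggles$ip_o)
    net$theta_o <- intrinsic_update(net$theta_o, so_new, mu_o, cfg$eta_ip)
  list(network = net, pred = pred, reward = r)
}

# Run the engine and the stepwise R composition side by side.
engine_vs_reference <- function(seed, steps, toggles, ne = 8) {
  task <- make_counting_sequence(2, 5)
  cfg <- sorn_config(n_excitatory = ne, symbols = task$alphabet,
                     p_c = 0.5, n_input_subset = 2, seed = seed)
  net <- init_network(cfg)
  mu_o <- unname(symbol_rates(task)[cfg$symbols])
  inputs <- sornsp:::task_slice_idx(task, 0, steps, cfg$symbols)

  eng <- sornsp:::run_engine(net, inputs, steps, toggles,
                             reward_mode = 1L, mu_o = mu_o)
  ref <- net
  preds <- integer(steps); rewards <- numeric(steps)
  for (k in seq_len(steps)) {
    out <- r_reference_step(ref, inputs[k], mu_o, toggles)
    ref <- out$network
    preds[k] <- out$pred
    rewards[k] <- out$reward
  }
  list(eng = eng, ref = ref, preds = preds, rewards = rewards)
}
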