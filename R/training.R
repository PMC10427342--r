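stage1_toggles <- function(protocol) {
  tg <- protocol$plasticity
  list(rstdp_ee = isTRUE(tg$rstdp_ee), rstdp_oe = isTRUE(tg$rstdp_oe),
       sn = isTRUE(tg$sn), ip_e = isTRUE(tg$ip_e), ip_o = isTRUE(tg$ip_o),
       sp = isTRUE(tg$sp))
}

stage2_toggles <- function(protocol) {
  tg <- protocol$plasticity
  list(rstdp_ee = FALSE, rstdp_oe = isTRUE(tg$rstdp_oe),
       sn = isTRUE(tg$sn), ip_e = FALSE, ip_o = isTRUE(tg$ip_o),
       sp = FALSE)
}

toggles_off <- function() {
  list(rstdp_ee = FALSE, rstdp_oe = FALSE, sn = FALSE,
       ip_e = FALSE, ip_o = FALSE, sp = FALSE)
}

engine_par <- function(cfg) {
  list(eta = cfg$eta, eta_oe = cfg$eta_oe, eta_ip = cfg$eta_ip,
       tau_e = cfg$tau_e,
       f_ee = cfg$f_ee, f_oe = cfg$f_oe, p_sp = cfg$p_sp,
       w_th = cfg$w_th, w_new = cfg$w_new,
       reward_incorrect = cfg$reward_incorrect,
       baseline_alpha = cfg$baseline_alpha, mu_ip = cfg$mu_ip)
}

subsets_matrix <- function(net) {
  do.call(rbind, lapply(net$input_map, as.integer))
}

output_rates <- function(net, task) {
  if (!is.null(net$config$mu_ip_output)) return(net$config$mu_ip_output)
  unname(symbol_rates(task)[net$config$symbols])
}

# Map a window of the (cyclically extended) task sequence to the network's
# output-neuron indices.
task_slice_idx <- function(task, phase, steps, symbols) {
  len <- length(task$symbols)
  pos <- ((phase + seq_len(steps) - 1L) %% len) + 1L
  idx <- match(task$symbols[pos], symbols)
  if (anyNA(idx))
    stop("task contains symbols unknown to the network", call. = FALSE)
  idx
}

run_engine <- function(net, inputs_idx, steps, toggles, reward_mode,
                       feedback = FALSE, mu_o = NULL, prev_pred = 0L) {
  cfg <- net$config
  if (is.null(mu_o)) mu_o <- rep(cfg$mu_ip, cfg$n_output)
  res <- engine_run(net$w_ee, net$c_ee, net$w_ei, net$w_ie, net$w_oe,
                    net$theta_e, net$theta_in, net$theta_o,
                    net$s_e, net$s_in, net$s_o,
                    net$e_ee, net$e_oe,
                    net$baseline, net$t,
                    subsets_matrix(net),
                    as.integer(inputs_idx), feedback, as.integer(steps),
                    as.integer(reward_mode), toggles, engine_par(cfg),
                    as.numeric(mu_o), as.integer(prev_pred))
  for (nm in c("w_ee", "c_ee", "w_oe", "theta_e", "theta_o",
               "s_e", "s_in", "s_o", "e_ee", "e_oe", "baseline"))
    net[[nm]] <- res[[nm]]
  net$t <- as.integer(res$t)
  list(network = net, predictions = res$predictions,
       rewards = res$rewards, events = res$events,
       last_pred = res$last_pred)
}

#' First training stage
#'
#' Runs `steps` task-driven steps with every plasticity rule active on the
#' recurrent and output synapses: eligibility-trace R-STDP, synaptic
#' normalization, intrinsic plasticity of the excitatory and output
#' thresholds, and structural plasticity of the E-E connectivity.
#'
#' @param network A `"sorn_network"`.
#' @param task A `"symbol_sequence"` whose alphabet matches the network's
#'   symbols.
#' @param steps Number of steps.
#' @param protocol A [sorn_protocol()] (its `plasticity` toggles gate the
#'   rules, for ablations).
#' @param phase 0-based position in the cyclically extended task sequence
#'   at which to start.
#' @param feedback If `TRUE` (generation task), the read-out symbol is fed
#'   back as the next input and the reward is the longest-run generation
#'   reward; otherwise the true sequence drives the network and the reward
#'   scores next-element prediction.
#' @param prev_pred Internal: carried last read-out for feedback mode.
#' @return List with the updated `network`, per-step `rewards` and
#'   `predictions` (symbol indices), structural `events`, and `last_pred`.
#' @export
run_stage_one <- function(network, task, steps, protocol = sorn_protocol(),
                          phase = 0L, feedback = FALSE, prev_pred = 0L) {
  if (!setequal(task$alphabet, network$config$symbols))
    stop("task alphabet does not match the network's symbols", call. = FALSE)
  if (steps == 0)
    return(list(network = network, rewards = numeric(0),
                predictions = integer(0),
                events = empty_events(), last_pred = prev_pred))
  inputs <- task_slice_idx(task, phase, steps, network$config$symbols)
  mu_o <- output_rates(network, task)
  run_engine(network, inputs, steps, stage1_toggles(protocol),
             reward_mode = if (feedback) 2L else 1L,
             feedback = feedback, mu_o = mu_o, prev_pred = prev_pred)
}

#' Second training stage: readout fine-tuning
#'
#' The recurrent layer is frozen — E-E weights, connectivity mask and
#' excitatory thresholds are bit-identical after the call — and only the
#' output weights (R-STDP + normalization) and output thresholds
#' (intrinsic plasticity) keep adapting. No structural plasticity runs.
#' The eligibility traces of the frozen recurrent synapses are cleared on
#' entry; over a stage of thousands of steps they would decay to zero
#' anyway, and clearing keeps the frozen layer's state exactly stationary.
#'
#' @inheritParams run_stage_one
#' @return As [run_stage_one()].
#' @export
run_stage_two <- function(network, task, steps, protocol = sorn_protocol(),
                          phase = 0L, feedback = FALSE, prev_pred = 0L) {
  if (steps == 0)
    return(list(network = network, rewards = numeric(0),
                predictions = integer(0),
                events = empty_events(), last_pred = prev_pred))
  network$e_ee[] <- 0
  inputs <- task_slice_idx(task, phase, steps, network$config$symbols)
  mu_o <- output_rates(network, task)
  run_engine(network, inputs, steps, stage2_toggles(protocol),
             reward_mode = if (feedback) 2L else 1L,
             feedback = feedback, mu_o = mu_o, prev_pred = prev_pred)
}

empty_events <- function() {
  data.frame(t = integer(0), kind = character(0), i = integer(0),
             j = integer(0), w = numeric(0), stringsAsFactors = FALSE)
}

#' Two-stage alternating training
#'
#' Alternates the full-plasticity first stage with the readout-only second
#' stage for `protocol$alternations` rounds, carrying network state, task
#' phase and the reward baseline across stage boundaries. For the
#' generation task (`mode = "generation"`) the read-out symbol is fed back
#' as the next input throughout training and the reward is the longest-run
#' generation reward.
#'
#' @param network A freshly initialized or checkpointed `"sorn_network"`.
#' @param task A `"symbol_sequence"`.
#' @param protocol A [sorn_protocol()].
#' @param mode `"prediction"` or `"generation"`.
#' @param record `"alternation"` (default) keeps per-alternation summaries
#'   only; `"step"` additionally keeps the full per-step reward stream.
#' @return List of class `"sorn_training"`: `network` (trained),
#'   `history` (data frame per alternation: mean stage-1/stage-2 reward,
#'   connection fraction, baseline), `events` (structural event log),
#'   `step_rewards` (if requested), `steps_total`.
#' @export
train <- function(network, task, protocol = sorn_protocol(),
                  mode = c("prediction", "generation"),
                  record = c("alternation", "step")) {
  mode <- match.arg(mode)
  record <- match.arg(record)
  feedback <- mode == "generation"
  if (is.null(network$config$mu_ip_output))
    network$config$mu_ip_output <- output_rates(network, task)

  phase <- 0L
  prev_pred <- 0L
  hist <- vector("list", protocol$alternations)
  events <- vector("list", 2L * protocol$alternations)
  step_rewards <- if (record == "step") vector("list", 2L * protocol$alternations)
  steps_total <- 0L

  for (a in seq_len(protocol$alternations)) {
    r1 <- run_stage_one(network, task, protocol$stage1_steps, protocol,
                        phase = phase, feedback = feedback,
                        prev_pred = prev_pred)
    network <- r1$network
    phase <- (phase + protocol$stage1_steps) %% length(task$symbols)
    prev_pred <- r1$last_pred

    r2 <- run_stage_two(network, task, protocol$stage2_steps, protocol,
                        phase = phase, feedback = feedback,
                        prev_pred = prev_pred)
    network <- r2$network
    phase <- (phase + protocol$stage2_steps) %% length(task$symbols)
    prev_pred <- r2$last_pred

    steps_total <- steps_total + protocol$stage1_steps + protocol$stage2_steps
    hist[[a]] <- data.frame(
      alternation = a,
      reward_stage1 = mean(r1$rewards),
      reward_stage2 = mean(r2$rewards),
      p_c = connection_fraction(network$c_ee),
      baseline = network$baseline)
    events[[2 * a - 1]] <- r1$events
    events[[2 * a]] <- r2$events
    if (record == "step")
      step_rewards[[2 * a - 1]] <- r1$rewards
    if (record == "step")
      step_rewards[[2 * a]] <- r2$rewards
  }

  out <- list(network = network,
              history = do.call(rbind, hist),
              events = do.call(rbind, events),
              step_rewards = if (record == "step") unlist(step_rewards),
              steps_total = steps_total,
              mode = mode, task = task, protocol = protocol)
  class(out) <- "sorn_training"
  out
}

#' @export
print.sorn_training <- function(x, ...) {
  cat(sprintf("<sorn_training> %s task, %d alternations, %d steps total\n",
              x$mode, nrow(x$history), x$steps_total))
  if (nrow(x$history) > 0) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final mean reward (stage 2): %.3f; connection fraction: %.4f\n",
                last$reward_stage2, last$p_c))
  }
  invisible(x)
}

#' Inference with plasticity frozen
#'
#' Runs the trained network with every plasticity rule disabled. In
#' `"prediction"` mode the true task sequence is presented (starting at a
#' random phase offset drawn from the current RNG) and the read-out symbols
#' are recorded; in `"generation"` mode a single start symbol seeds the
#' network and read-outs are fed back autonomously.
#'
#' @param network A trained `"sorn_network"`.
#' @param task A `"symbol_sequence"`.
#' @param steps Number of inference steps.
#' @param mode `"prediction"` or `"generation"`.
#' @param seed_symbol Start symbol for generation mode; defaults to the
#'   first symbol of the task cycle.
#' @return List with `predicted` (read-out symbols), `presented` (inputs
#'   actually shown; for generation, `NA` past the seed), `phase` (offset
#'   used), and `network` (state advanced, weights untouched).
#' @export
infer <- function(network, task, steps, mode = c("prediction", "generation"),
                  seed_symbol = NULL) {
  mode <- match.arg(mode)
  cfg <- network$config
  if (mode == "prediction") {
    phase <- sample.int(length(task$symbols), 1L) - 1L
    inputs <- task_slice_idx(task, phase, steps, network$config$symbols)
    res <- run_engine(network, inputs, steps, toggles_off(),
                      reward_mode = 0L, feedback = FALSE)
    list(predicted = cfg$symbols[res$predictions],
         presented = cfg$symbols[inputs],
         phase = phase, network = res$network)
  } else {
    if (is.null(seed_symbol)) seed_symbol <- task$symbols[1]
    seed_idx <- match(seed_symbol, cfg$symbols)
    if (is.na(seed_idx)) stop("unknown seed symbol", call. = FALSE)
    res <- run_engine(network, seed_idx, steps, toggles_off(),
                      reward_mode = 0L, feedback = TRUE)
    list(predicted = cfg$symbols[res$predictions],
         presented = c(seed_symbol, rep(NA_character_, steps - 1L)),
         phase = 0L, network = res$network,
         seed_symbol = seed_symbol)
  }
}
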