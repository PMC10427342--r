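#' Initialize a network
#'
#' Draws connectivity, weights, thresholds and the input map for one
#' network from `config$seed`. Excitatory-to-excitatory connections are
#' sparse: each off-diagonal pair is connected independently with
#' probability `p_c` (no self-connections, no inhibitory-to-inhibitory
#' connections anywhere). All weights are drawn uniformly from [0, 1] and
#' every afferent row is then normalized to sum to 1. Eligibility traces,
#' states and the reward baseline start at zero.
#'
#' @param config A [sorn_config()] object.
#' @return A list of class `"sorn_network"` with elements `config`,
#'   the weight matrices `w_ee`, `c_ee` (binary mask), `w_ei`, `w_ie`,
#'   `w_oe`, state vectors `s_e`, `s_in`, `s_o`, thresholds `theta_e`,
#'   `theta_in`, `theta_o`, eligibility traces `e_ee`, `e_oe`, the reward
#'   `baseline`, the step counter `t`, and `input_map` (named list of
#'   neuron index subsets, one per symbol).
#' @export
init_network <- function(config) {
  validate_config(config)
  set.seed(config$seed)
  ne <- config$n_excitatory
  ni <- config$n_inhibitory
  no <- config$n_output

  c_ee <- matrix(as.numeric(stats::runif(ne * ne) < config$p_c), ne, ne)
  diag(c_ee) <- 0

  w_ee <- matrix(stats::runif(ne * ne), ne, ne) * c_ee
  w_ee <- normalize_rows(w_ee)
  w_ei <- normalize_rows(matrix(stats::runif(ne * ni), ne, ni))
  w_ie <- normalize_rows(matrix(stats::runif(ni * ne), ni, ne))
  w_oe <- normalize_rows(matrix(stats::runif(no * ne), no, ne))

  theta_e <- stats::runif(ne, config$theta_e_range[1], config$theta_e_range[2])
  theta_in <- stats::runif(ni, config$theta_in_range[1], config$theta_in_range[2])
  theta_o <- stats::runif(no, config$theta_o_range[1], config$theta_o_range[2])

  pool <- sample.int(ne, no * config$n_input_subset)
  input_map <- split(pool, rep(seq_len(no), each = config$n_input_subset))
  names(input_map) <- config$symbols

  net <- list(
    config = config,
    w_ee = w_ee, c_ee = c_ee, w_ei = w_ei, w_ie = w_ie, w_oe = w_oe,
    s_e = numeric(ne), s_in = numeric(ni), s_o = numeric(no),
    theta_e = theta_e, theta_in = theta_in, theta_o = theta_o,
    e_ee = matrix(0, ne, ne), e_oe = matrix(0, no, ne),
    baseline = 0, t = 0L,
    input_map = input_map
  )
  class(net) <- "sorn_network"
  net
}

#' @export
print.sorn_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<sorn_network> %d excitatory + %d inhibitory neurons, %d outputs\n",
              cfg$n_excitatory, cfg$n_inhibitory, cfg$n_output))
  cat(sprintf("  symbols: %s\n", paste(cfg$symbols, collapse = " ")))
  cat(sprintf("  E-E connection fraction: %.4f (initial p_c %.4f)\n",
              connection_fraction(x$c_ee), cfg$p_c))
  cat(sprintf("  steps simulated: %d\n", x$t))
  invisible(x)
}

#' Encode an input symbol as a drive vector
#'
#' Each symbol activates its fixed, disjoint subset of excitatory neurons:
#' the drive is 1 on the subset and 0 elsewhere. `NULL` (or `NA`) encodes a
#' silent step with no external drive, as used during generation warm-up.
#'
#' @param symbol A single symbol, or `NULL`/`NA` for no input.
#' @param input_map Named list of neuron index subsets from [init_network()].
#' @param n_excitatory Length of the drive vector.
#' @return Numeric 0/1 vector of length `n_excitatory`.
#' @export
encode_input <- function(symbol, input_map, n_excitatory) {
  u <- numeric(n_excitatory)
  if (is.null(symbol) || (length(symbol) == 1 && is.na(symbol))) return(u)
  symbol <- as.character(symbol)
  if (!symbol %in% names(input_map))
    stop("unknown symbol: '", symbol, "'", call. = FALSE)
  u[input_map[[symbol]]] <- 1
  u
}

heaviside <- function(x) as.numeric(x >= 0)

#' One synchronous recurrent update
#'
#' Advances the excitatory and inhibitory populations by one step. Both
#' updates derive from the pre-step excitatory state: the inhibitory layer
#' responds to it first, and the new excitatory state then thresholds the
#' recurrent excitatory input minus that same-step inhibitory response plus
#' the external drive (fast feedforward inhibition, which keeps excitation
#' and inhibition balanced within each step rather than lagging by one). A
#' neuron fires when its summed input reaches its threshold (the step
#' function takes value 1 at 0).
#'
#' @param state,weights Components of a `"sorn_network"` (the network
#'   object itself is accepted for both).
#' @param u External drive vector from [encode_input()].
#' @return The network/state object with `s_e`, `s_in` replaced and `t`
#'   incremented.
#' @export
step_recurrent <- function(state, weights = state, u) {
  ne <- length(state$s_e)
  if (length(u) != ne)
    stop("drive vector length does not match the excitatory population",
         call. = FALSE)
  s_in_new <- heaviside(drop(weights$w_ie %*% state$s_e) - state$theta_in)
  psi_e <- drop(weights$w_ee %*% state$s_e) -
    drop(weights$w_ei %*% s_in_new) + u - state$theta_e
  state$s_e <- heaviside(psi_e)
  state$s_in <- s_in_new
  state$t <- state$t + 1L
  state
}

#' Output-layer update
#'
#' Computes the output potentials `w_oe %*% s_e - theta_o` and the
#' thresholded binary output states. The raw potentials are returned as
#' well because the symbol readout picks their argmax.
#'
#' @param state,weights Components of a `"sorn_network"`.
#' @return List with `states` (binary vector) and `potentials`.
#' @export
step_output <- function(state, weights = state) {
  psi_o <- drop(weights$w_oe %*% state$s_e) - state$theta_o
  list(states = heaviside(psi_o), potentials = psi_o)
}

#' Read out the predicted symbol
#'
#' The symbol of the output neuron with the largest potential; exact ties
#' resolve to the lowest neuron index, so the readout is deterministic.
#'
#' @param potentials Output potentials from [step_output()].
#' @param symbols Symbol per output neuron; defaults to the neuron index.
#' @return A single symbol.
#' @export
readout_symbol <- function(potentials, symbols = as.character(seq_along(potentials))) {
  if (length(potentials) == 0) stop("empty potentials vector", call. = FALSE)
  if (length(symbols) != length(potentials))
    stop("symbols and potentials differ in length", call. = FALSE)
  symbols[which.max(potentials)]
}

#' Checkpoint a network to disk
#'
#' Serializes the full network (weights, mask, thresholds, traces, config,
#' step counter) together with the current R random-number-generator state,
#' so a resumed run continues bit-exactly.
#'
#' @param net A `"sorn_network"`.
#' @param path Output file path (`.rds`).
#' @export
save_network <- function(net, path) {
  rng <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(list(network = net, rng_state = rng,
               package_version = as.character(utils::packageVersion("sornsp"))),
          path)
  invisible(path)
}

#' Restore a checkpointed network
#'
#' @param path File written by [save_network()].
#' @return The `"sorn_network"`; the RNG state stored in the checkpoint is
#'   restored as a side effect.
#' @export
load_network <- function(path) {
  obj <- readRDS(path)
  if (!is.null(obj$rng_state))
    assign(".Random.seed", obj$rng_state, envir = globalenv())
  obj$network
}
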