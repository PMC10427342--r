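#' Counting-task sequence
#'
#' The periodic sequence `(a b^n c)^m`: each subsequence has a start flag
#' `a`, `n` repeats of `b`, and an end flag `c`. Predicting the end flag
#' after exactly `n` repeats is the part that requires counting.
#'
#' @param n Number of repeated elements per subsequence (>= 1).
#' @param m Number of subsequences (>= 1).
#' @param seed Unused (the sequence is deterministic); reserved for
#'   stochastic variants.
#' @return A list of class `"symbol_sequence"` with `symbols` (character),
#'   `boundaries` (m x 2 matrix of subsequence start/end positions),
#'   `alphabet`, `task_kind`, `n`, `m`.
#' @export
make_counting_sequence <- function(n, m, seed = NULL) {
  if (n < 1 || m < 1) stop("n and m must be positive", call. = FALSE)
  unit <- c("a", rep("b", n), "c")
  len <- n + 2L
  seq_out <- rep(unit, m)
  boundaries <- cbind(start = (seq_len(m) - 1L) * len + 1L,
                      end = seq_len(m) * len)
  structure(list(symbols = seq_out, boundaries = boundaries,
                 alphabet = c("a", "b", "c"),
                 task_kind = "counting", n = as.integer(n), m = as.integer(m)),
            class = "symbol_sequence")
}

#' Motion-task sequence
#'
#' The periodic sequence `(1 2 ... n)^m` of positions along an axis; used
#' both for next-position prediction and for autonomous generation.
#'
#' @param n Number of positions per cycle (>= 2).
#' @param m Number of cycles (>= 1).
#' @return A `"symbol_sequence"` (symbols are the characters "1".."n").
#' @export
make_motion_sequence <- function(n, m) {
  if (n < 2 || m < 1) stop("n must be >= 2 and m >= 1", call. = FALSE)
  alphabet <- as.character(seq_len(n))
  seq_out <- rep(alphabet, m)
  boundaries <- cbind(start = (seq_len(m) - 1L) * n + 1L,
                      end = seq_len(m) * n)
  structure(list(symbols = seq_out, boundaries = boundaries,
                 alphabet = alphabet,
                 task_kind = "motion", n = as.integer(n), m = as.integer(m)),
            class = "symbol_sequence")
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat(sprintf("<symbol_sequence> %s task, n = %d, m = %d, length %d\n",
              x$task_kind, x$n, x$m, length(x$symbols)))
  head_n <- min(20, length(x$symbols))
  cat("  ", paste(x$symbols[seq_len(head_n)], collapse = " "),
      if (length(x$symbols) > head_n) "..." else "", "\n")
  invisible(x)
}

#' Ground-truth next element
#'
#' The prediction target at `position` is the following element of the
#' sequence; at the last position the target wraps to the first element,
#' because the task sequences are periodic.
#'
#' @param sequence A `"symbol_sequence"`.
#' @param position 1-based position in the sequence.
#' @return The target symbol.
#' @export
next_target <- function(sequence, position) {
  len <- length(sequence$symbols)
  if (position < 1 || position > len)
    stop("position out of range", call. = FALSE)
  sequence$symbols[(position %% len) + 1L]
}

#' Prediction reward
#'
#' 1 for a correct prediction, `reward_incorrect` (0 or -1) otherwise.
#'
#' @param predicted,target Symbols.
#' @param reward_incorrect Penalty scheme: 0 or -1.
#' @return Numeric reward.
#' @export
prediction_reward <- function(predicted, target, reward_incorrect = 0) {
  if (!reward_incorrect %in% c(0, -1))
    stop("reward_incorrect must be 0 or -1", call. = FALSE)
  if (identical(as.character(predicted), as.character(target))) 1
  else reward_incorrect
}

#' Generation reward
#'
#' Reward proportional to the length of the correctly generated stretch:
#' with target cycle length n, the reward is L/n where L is the longest
#' suffix of the last n generated symbols that forms a consecutive run of
#' the cyclic target (ending at the current symbol). A full window that
#' traverses the cycle earns 1; a window whose last three symbols continue
#' the cycle earns 3/n; a window ending in a symbol that does not follow
#' its predecessor earns 1/n if that symbol belongs to the alphabet, else 0.
#'
#' @param recent_outputs The last `length(target_cycle)` generated symbols,
#'   most recent last; early on, left-pad with `NA` or any non-alphabet
#'   placeholder.
#' @param target_cycle The target cycle (e.g. `c("1","2","3","4")`).
#' @return Reward in `{0, 1/n, ..., 1}`.
#' @export
generation_reward <- function(recent_outputs, target_cycle) {
  n <- length(target_cycle)
  if (n == 0) stop("empty target cycle", call. = FALSE)
  w <- as.character(recent_outputs)
  if (length(w) > n) w <- w[(length(w) - n + 1L):length(w)]
  k <- length(w)
  if (k == 0) return(0)
  pos <- match(w, target_cycle)          # NA for placeholders / foreign symbols
  if (is.na(pos[k])) return(0)
  run <- 1L
  while (run < k) {
    prev <- pos[k - run]
    cur <- pos[k - run + 1L]
    expected_prev <- if (cur == 1L) n else cur - 1L
    if (is.na(prev) || prev != expected_prev) break
    run <- run + 1L
  }
  run / n
}

#' Write a sequence as plain text
#'
#' One symbol per line, for inspection and fixture pinning.
#' @param sequence A `"symbol_sequence"`.
#' @param path Output path.
#' @export
write_sequence <- function(sequence, path) {
  writeLines(sequence$symbols, path)
  invisible(path)
}

#' Read a plain-text sequence
#'
#' @param path File with one symbol per line.
#' @return Character vector of symbols.
#' @export
read_sequence <- function(path) readLines(path)

#' Stationary symbol frequencies of a task sequence
#'
#' Used as the per-output-neuron intrinsic-plasticity targets: each output
#' neuron should fire as often as its symbol occurs.
#'
#' @param sequence A `"symbol_sequence"`.
#' @return Named numeric vector over the alphabet, summing to 1.
#' @export
symbol_rates <- function(sequence) {
  tab <- table(factor(sequence$symbols, levels = sequence$alphabet))
  stats::setNames(as.numeric(tab) / length(sequence$symbols),
                  sequence$alphabet)
}
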