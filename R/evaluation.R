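#' Overall performance
#'
#' Fraction of positions at which the predicted stream matches the target
#' stream (matching of all letters).
#'
#' @param predicted,target Equal-length symbol vectors.
#' @return Fraction in `[0, 1]`.
#' @export
overall_performance <- function(predicted, target) {
  if (length(predicted) != length(target))
    stop("predicted and target streams differ in length", call. = FALSE)
  if (length(predicted) == 0) stop("empty streams", call. = FALSE)
  mean(as.character(predicted) == as.character(target))
}

#' Counting performance
#'
#' Per-subsequence accuracy on the counting task. The scored event of a
#' subsequence `a b^n c` is the counting transition: the prediction made at
#' the n-th repeated element, whose correct target is the end flag `c` —
#' the only prediction that requires having counted the repeats. In
#' `strict` mode a subsequence instead counts as correct only if every one
#' of its positions is predicted correctly.
#'
#' @param predicted,target Aligned symbol vectors.
#' @param boundaries Matrix with columns `start`, `end` delimiting complete
#'   subsequences of the target stream (1-based, inclusive); the end flag
#'   sits at `end`.
#' @param strict Score whole subsequences instead of end-flag transitions.
#' @return Fraction of correctly scored subsequences.
#' @export
counting_performance <- function(predicted, target, boundaries,
                                 strict = FALSE) {
  if (is.null(dim(boundaries)) || nrow(boundaries) == 0)
    stop("empty boundary list", call. = FALSE)
  if (length(predicted) != length(target))
    stop("predicted and target streams differ in length", call. = FALSE)
  predicted <- as.character(predicted)
  target <- as.character(target)
  ok <- vapply(seq_len(nrow(boundaries)), function(b) {
    s <- boundaries[b, 1]; e <- boundaries[b, 2]
    if (strict) all(predicted[s:e] == target[s:e])
    else predicted[e] == target[e]
  }, logical(1))
  mean(ok)
}

#' Generation performance
#'
#' Fraction of generated symbols that correctly continue the target cycle:
#' position t counts as correct when `generated[t]` is the cyclic successor
#' of `generated[t-1]`. The first position is scored against the seeded
#' start symbol if one is supplied, otherwise it is excluded. Scoring
#' successor validity (rather than mere alphabet membership) makes a
#' constant output stream score 0, not 1/n.
#'
#' @param generated Generated symbol stream.
#' @param target_cycle The target cycle, e.g. `c("1","2","3","4")`.
#' @param seed_symbol Optional symbol that preceded `generated[1]`.
#' @return Fraction in `[0, 1]`.
#' @export
generation_performance <- function(generated, target_cycle,
                                   seed_symbol = NULL) {
  if (length(generated) == 0) stop("empty generated stream", call. = FALSE)
  n <- length(target_cycle)
  pos <- match(as.character(generated), as.character(target_cycle))
  succ_ok <- function(prev, cur) {
    !is.na(prev) && !is.na(cur) && cur == (prev %% n) + 1
  }
  prev <- if (!is.null(seed_symbol))
    match(as.character(seed_symbol), as.character(target_cycle)) else NA
  ok <- logical(0)
  for (t in seq_along(pos)) {
    if (t == 1) {
      if (!is.null(seed_symbol)) ok <- c(ok, succ_ok(prev, pos[1]))
    } else {
      ok <- c(ok, succ_ok(pos[t - 1], pos[t]))
    }
  }
  if (length(ok) == 0) stop("nothing to score", call. = FALSE)
  mean(ok)
}

#' Evaluate a trained network on a task
#'
#' Runs [infer()] with plasticity off and computes the metrics appropriate
#' to the task: overall (and, for the counting task, counting) performance
#' in prediction mode, or generation performance in generation mode. For
#' prediction, the first `warmup` steps are presented but not scored, so
#' the metrics reflect the steady-state behaviour rather than the initial
#' transient from the zero state.
#'
#' @param network Trained `"sorn_network"`.
#' @param task A `"symbol_sequence"`.
#' @param steps Scored inference steps.
#' @param mode `"prediction"` or `"generation"`.
#' @param warmup Unscored leading steps (default: two task periods,
#'   at least 20).
#' @return A list of class `"eval_report"`: metrics plus provenance fields
#'   (`n`, `m`, `n_excitatory`, `seed`, `steps`, `mode`).
#' @export
evaluate_network <- function(network, task, steps = 1000,
                             mode = c("prediction", "generation"),
                             warmup = NULL) {
  mode <- match.arg(mode)
  period <- if (task$task_kind == "counting") task$n + 2L else task$n
  if (is.null(warmup)) warmup <- max(2L * period, 20L)
  total <- steps + warmup
  res <- infer(network, task, total, mode = mode)
  rep <- list(n = task$n, m = task$m,
              n_excitatory = network$config$n_excitatory,
              seed = network$config$seed, steps = steps, mode = mode,
              task_kind = task$task_kind)
  if (mode == "prediction") {
    keep <- (warmup + 1L):total
    pred <- res$predicted[keep]
    tgt <- res$presented[keep]
    rep$overall <- overall_performance(pred, tgt)
    if (task$task_kind == "counting") {
      ends <- which(tgt == "c")
      starts <- which(tgt == "a")
      # complete subsequences only: an 'a' followed by its 'c' within range
      b <- do.call(rbind, lapply(starts, function(s) {
        e <- s + task$n + 1L
        if (e <= length(tgt) && tgt[e] == "c") c(s, e) else NULL
      }))
      if (!is.null(b) && nrow(b) > 0)
        rep$counting <- counting_performance(pred, tgt, b)
    }
  } else {
    keep <- (warmup + 1L):total
    rep$generation <- generation_performance(res$predicted[keep],
                                             task$alphabet,
                                             seed_symbol = res$predicted[warmup])
  }
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s task (n = %d), N = %d, %d scored steps\n",
              x$task_kind, x$n, x$n_excitatory, x$steps))
  for (metric in c("overall", "counting", "generation"))
    if (!is.null(x[[metric]]))
      cat(sprintf("  %-10s %.2f%%\n", metric, 100 * x[[metric]]))
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the report as JSON, or as a tab-separated row (metric, n, N,
#' value) suitable for assembling benchmark tables.
#'
#' @param report An `"eval_report"`.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @export
write_eval_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    metrics <- intersect(c("overall", "counting", "generation"),
                         names(report))
    rows <- data.frame(metric = metrics,
                       n = report$n, N = report$n_excitatory,
                       value = unlist(report[metrics]))
    utils::write.table(rows, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
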